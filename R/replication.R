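#' Path to the packaged per-site 2x2 count fixture
#'
#' CSV of CHW-vs-physician cell counts (a = TP, b = FP, c = FN, d = TN, with
#' the physician as gold standard) for 17 signs/symptoms in each of three
#' study sites (Sylhet n = 278, Matiari n = 300, Karachi n = 300), together
#' with the published reference statistics (agreement, kappa, PABAK,
#' sensitivity, specificity, interval bounds). Cells published as "-" are
#' empty. The `note` column records the one count corrected for internal
#' consistency (a row whose printed cells did not sum to the site total).
#'
#' @return file path.
#' @export
fixture_path <- function() {
  system.file("extdata", "site_symptom_counts.csv", package = "ppsepsis",
              mustWork = TRUE)
}

#' Load and validate the per-site count fixture
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return data frame, one row per site x attribute.
#' @export
load_site_counts <- function(path = fixture_path()) {
  fx <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("site", "n_site", "attribute", "a", "b", "c", "d")
  missing <- setdiff(needed, names(fx))
  if (length(missing)) stop_("fixture lacks column(s): %s", paste(missing, collapse = ", "))
  sums <- fx$a + fx$b + fx$c + fx$d
  bad <- which(sums != fx$n_site)
  if (length(bad)) {
    stop_("fixture row(s) do not sum to the site total: %s",
          paste(paste(fx$site[bad], fx$attribute[bad]), collapse = "; "))
  }
  for (col in c("printed_pabak", "printed_kappa")) {
    out_of_range <- !is.na(fx[[col]]) & abs(fx[[col]]) > 1
    if (any(out_of_range)) stop_("fixture column %s outside [-1, 1]", col)
  }
  fx
}

# one comparison cell of the replication report
.cell <- function(site, attribute, quantity, computed, printed, tolerance,
                  in_pass) {
  match <- if (is.na(printed) || is.na(computed)) NA else
    abs(computed - printed) <= tolerance + 1e-9
  data.frame(site = site, attribute = attribute, quantity = quantity,
             computed = computed, printed = printed, tolerance = tolerance,
             match = match, in_pass = in_pass, stringsAsFactors = FALSE)
}

#' Recompute the published agreement and validity tables from counts
#'
#' For every fixture row the full kappa-family agreement summary and the
#' exact-interval sensitivity/specificity are recomputed from the four cell
#' counts and compared with the published values: kappa and PABAK within
#' +/- 0.01 (published values are rounded, occasionally truncated), overall
#' agreement within one percentage point, sensitivity and specificity exact
#' after rounding half-up to integer percent, and interval bounds within one
#' point (the publication's interval method is unstated). The positive and
#' negative agreement columns are compared informationally only: the
#' published positive-agreement column is not reconcilable with the standard
#' `2a/(2a+b+c)` statistic for many rows. Cells published as "-" are not
#' comparable and are excluded from the pass denominator; the report records
#' whether the computation yielded a defined value there.
#'
#' The pass criterion is that at least 95 percent of the comparable
#' pass-relevant cells (kappa, PABAK, overall agreement, sensitivity,
#' specificity) match within tolerance; every mismatch is listed with both
#' values, never silently accepted.
#'
#' @param fx fixture data frame from [load_site_counts()].
#' @param pass_rate required fraction of matching pass-relevant cells.
#' @return list of class `replication_report`: `cells` (one row per
#'   comparison), `mismatches`, `match_rate`, `n_pairs_total`, `pass`.
#' @export
replicate_tables <- function(fx = load_site_counts(), pass_rate = 0.95) {
  cells <- vector("list", nrow(fx))
  for (i in seq_len(nrow(fx))) {
    r <- fx[i, ]
    ct <- confusion_table(r$a, r$b, r$c, r$d)
    ag <- agreement_summary(ct)
    va <- sensitivity_specificity(ct)
    pct <- function(x) 100 * x
    cells[[i]] <- rbind(
      .cell(r$site, r$attribute, "kappa", ag$kappa, r$printed_kappa, 0.01, TRUE),
      .cell(r$site, r$attribute, "pabak", ag$pabak, r$printed_pabak, 0.01, TRUE),
      .cell(r$site, r$attribute, "overall_agreement",
            pct(ag$po), r$printed_overall, 1, TRUE),
      .cell(r$site, r$attribute, "sensitivity",
            round_half_up(pct(va$sensitivity)), r$printed_se, 0, TRUE),
      .cell(r$site, r$attribute, "specificity",
            round_half_up(pct(va$specificity)), r$printed_sp, 0, TRUE),
      .cell(r$site, r$attribute, "se_ci_low",
            pct(va$se_ci[1]), r$printed_se_lo, 1, FALSE),
      .cell(r$site, r$attribute, "se_ci_high",
            pct(va$se_ci[2]), r$printed_se_hi, 1, FALSE),
      .cell(r$site, r$attribute, "sp_ci_low",
            pct(va$sp_ci[1]), r$printed_sp_lo, 1, FALSE),
      .cell(r$site, r$attribute, "sp_ci_high",
            pct(va$sp_ci[2]), r$printed_sp_hi, 1, FALSE),
      .cell(r$site, r$attribute, "positive_agreement",
            pct(ag$ppos), r$printed_ppos, 1, FALSE),
      .cell(r$site, r$attribute, "negative_agreement",
            pct(ag$pneg), r$printed_pneg, 1, FALSE)
    )
  }
  cells <- do.call(rbind, cells)
  pass_cells <- cells[cells$in_pass & !is.na(cells$match), ]
  match_rate <- mean(pass_cells$match)
  mismatches <- cells[!is.na(cells$match) & !cells$match, ]
  n_pairs_total <- sum(fx$n_site[!duplicated(fx$site)])
  structure(list(cells = cells, mismatches = mismatches,
                 match_rate = match_rate,
                 n_compared = nrow(pass_cells),
                 n_pairs_total = n_pairs_total,
                 pass = match_rate >= pass_rate),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("table replication: %d comparable cells, %.1f%% within tolerance (%s)\n",
              x$n_compared, 100 * x$match_rate, if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("analysis pairs across sites: %d\n", x$n_pairs_total))
  mm <- x$mismatches[x$mismatches$in_pass, ]
  if (nrow(mm)) {
    cat(sprintf("%d pass-relevant mismatch(es):\n", nrow(mm)))
    for (i in seq_len(nrow(mm))) {
      cat(sprintf("  %s / %s / %s: computed %.3f vs published %.3f\n",
                  mm$site[i], mm$attribute[i], mm$quantity[i],
                  mm$computed[i], mm$printed[i]))
    }
  }
  invisible(x)
}

#' Write a replication report to CSV (cells) and JSON (summary)
#'
#' @param report [replicate_tables()] result.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the report.
#' @export
write_replication_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "replication_report"))
  if (!is.null(csv_path)) utils::write.csv(report$cells, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(match_rate = report$match_rate,
                              n_compared = report$n_compared,
                              n_pairs_total = report$n_pairs_total,
                              pass = report$pass,
                              mismatches = report$mismatches),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
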