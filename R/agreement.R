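#' Construct a 2x2 paired-rating confusion table
#'
#' Cell convention for CHW-vs-physician ratings of one attribute, with the
#' physician as gold standard: `a` both positive (TP), `b` CHW positive /
#' physician negative (FP), `c` CHW negative / physician positive (FN),
#' `d` both negative (TN).
#'
#' @param a,b,c,d non-negative integer cell counts; `a + b + c + d >= 1`.
#' @return object of class `confusion_table` with fields `a`, `b`, `c`, `d`,
#'   `n`.
#' @export
confusion_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop_("cell counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop_("confusion table must contain at least one pair")
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), n = as.integer(n)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(CHW = c("+", "-"), physician = c("+", "-")))
  print(m)
  invisible(x)
}

#' Tally a confusion table from matched CHW/physician assessment pairs
#'
#' `pairs` is in long format: exactly one CHW row and one PHYSICIAN row per
#' woman. Positivity for a symptom attribute is the symptom boolean; for the
#' `final_class` attribute it is classification as suspected puerperal
#' sepsis.
#'
#' @param pairs data frame with columns `woman_id`, `rater`
#'   (CHW/PHYSICIAN) and the attribute column.
#' @param attribute column name to tally, or `"final_class"`.
#' @return [confusion_table()].
#' @export
build_confusion <- function(pairs, attribute) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0) stop_("no assessment pairs supplied")
  if (!attribute %in% names(pairs)) stop_("attribute '%s' not found", attribute)
  if (!all(pairs$rater %in% c("CHW", "PHYSICIAN"))) {
    stop_("rater must be CHW or PHYSICIAN")
  }
  tab <- table(pairs$woman_id, pairs$rater)
  bad <- rownames(tab)[tab[, "CHW"] != 1 | tab[, "PHYSICIAN"] != 1]
  if (length(bad)) {
    stop_("unmatched or duplicated woman_id(s): %s",
          paste(utils::head(bad, 10), collapse = ", "))
  }
  positive <- function(x) {
    if (attribute == "final_class") as.character(x) == "SUSPECTED_PP_SEPSIS"
    else as.logical(x)
  }
  chw <- pairs[pairs$rater == "CHW", ]
  phys <- pairs[pairs$rater == "PHYSICIAN", ]
  phys <- phys[match(chw$woman_id, phys$woman_id), ]
  cp <- positive(chw[[attribute]])
  pp <- positive(phys[[attribute]])
  if (anyNA(cp) || anyNA(pp)) stop_("attribute '%s' contains NA", attribute)
  confusion_table(a = sum(cp & pp), b = sum(cp & !pp),
                  c = sum(!cp & pp), d = sum(!cp & !pp))
}

#' Observed agreement proportion
#'
#' @param ct [confusion_table()].
#' @return `(a + d) / n`.
#' @export
observed_agreement <- function(ct) (ct$a + ct$d) / ct$n

#' Chance-expected agreement proportion
#'
#' Product-of-marginals expected agreement used by Cohen's kappa.
#'
#' @param ct [confusion_table()].
#' @return `[(a+b)(a+c) + (c+d)(b+d)] / n^2`.
#' @export
expected_agreement <- function(ct) {
  with(ct, ((a + b) * (a + c) + (c + d) * (b + d)) / n^2)
}

#' Cohen's kappa for a 2x2 paired-rating table
#'
#' Chance-corrected agreement, with the large-sample asymptotic standard
#' error (Fleiss-Cohen-Everitt form) and a one-sided test of kappa > 0 using
#' the null-hypothesis variance. When the margins are degenerate (expected
#' agreement 1, e.g. both raters constant) kappa is undefined and returned as
#' `NA` with `undefined = TRUE` rather than propagating 0/0.
#'
#' @param ct [confusion_table()].
#' @return list with `kappa`, `se` (asymptotic SE), `se_null`, `p_value`
#'   (one-sided, kappa > 0), `po`, `pe`, `undefined`.
#' @export
cohen_kappa <- function(ct) {
  po <- observed_agreement(ct)
  pe <- expected_agreement(ct)
  if (isTRUE(all.equal(pe, 1))) {
    return(list(kappa = NA_real_, se = NA_real_, se_null = NA_real_,
                p_value = NA_real_, po = po, pe = pe, undefined = TRUE))
  }
  kappa <- (po - pe) / (1 - pe)
  n <- ct$n
  p <- matrix(c(ct$a, ct$c, ct$b, ct$d), 2, 2) / n  # rows: CHW +/-, cols: phys +/-
  prow <- rowSums(p)
  pcol <- colSums(p)
  # Fleiss, Cohen & Everitt large-sample variance
  A <- sum(diag(p) * (1 - (prow + pcol) * (1 - kappa))^2)
  B <- (1 - kappa)^2 * (p[1, 2] * (pcol[1] + prow[2])^2 +
                        p[2, 1] * (pcol[2] + prow[1])^2)
  C <- (kappa - pe * (1 - kappa))^2
  var_k <- (A + B - C) / (n * (1 - pe)^2)
  # null-hypothesis (kappa = 0) variance for the significance test
  var_0 <- (pe + pe^2 - sum(prow * pcol * (prow + pcol))) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  se0 <- sqrt(max(var_0, 0))
  p_value <- if (se0 > 0) stats::pnorm(kappa / se0, lower.tail = FALSE) else NA_real_
  list(kappa = kappa, se = se, se_null = se0, p_value = p_value,
       po = po, pe = pe, undefined = FALSE)
}

#' Prevalence-adjusted bias-adjusted kappa (PABAK)
#'
#' For a 2x2 table PABAK equals `2 * observed agreement - 1`; it is the value
#' kappa would take were the attribute prevalence balanced and the raters
#' unbiased.
#'
#' @param ct [confusion_table()].
#' @return numeric in \[-1, 1\].
#' @export
pabak <- function(ct) 2 * observed_agreement(ct) - 1

#' Prevalence index
#'
#' `|a - d| / n`: imbalance between the both-positive and both-negative
#' cells. A high prevalence index inflates chance agreement and depresses
#' kappa.
#'
#' @param ct [confusion_table()].
#' @return numeric in \[0, 1\].
#' @export
prevalence_index <- function(ct) abs(ct$a - ct$d) / ct$n

#' Bias index
#'
#' `|b - c| / n`: asymmetry of the raters' disagreement. Low values denote
#' symmetric CHW-physician disagreement.
#'
#' @param ct [confusion_table()].
#' @return numeric in \[0, 1\].
#' @export
bias_index <- function(ct) abs(ct$b - ct$c) / ct$n

#' Positive and negative agreement
#'
#' Agreement conditional on presence (`2a / (2a + b + c)`) or absence
#' (`2d / (2d + b + c)`) of the attribute. Undefined (returned as `NA`) when
#' the denominator is zero, mirroring suppressed cells in reported tables.
#'
#' @param ct [confusion_table()].
#' @return numeric in \[0, 1\] or `NA`.
#' @export
positive_agreement <- function(ct) {
  den <- 2 * ct$a + ct$b + ct$c
  if (den == 0) NA_real_ else 2 * ct$a / den
}

#' @rdname positive_agreement
#' @export
negative_agreement <- function(ct) {
  den <- 2 * ct$d + ct$b + ct$c
  if (den == 0) NA_real_ else 2 * ct$d / den
}

#' Full kappa-family agreement summary for one table
#'
#' Assembles observed and chance agreement, Cohen's kappa with SE and
#' one-sided p-value, PABAK, prevalence and bias indices, and positive and
#' negative agreement into one record. Undefined statistics are `NA` and
#' flagged.
#'
#' @param ct [confusion_table()].
#' @return object of class `agreement_result`.
#' @export
agreement_summary <- function(ct) {
  k <- cohen_kappa(ct)
  structure(list(
    table = ct,
    po = k$po,
    pe = k$pe,
    kappa = k$kappa,
    kappa_se = k$se,
    p_value = k$p_value,
    pabak = pabak(ct),
    prevalence_index = prevalence_index(ct),
    bias_index = bias_index(ct),
    ppos = positive_agreement(ct),
    pneg = negative_agreement(ct),
    kappa_undefined = k$undefined,
    ppos_undefined = is.na(positive_agreement(ct)),
    pneg_undefined = is.na(negative_agreement(ct))
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("CHW-physician agreement (n = %d pairs)\n", x$table$n))
  cat(sprintf("  observed agreement %.3f, chance %.3f\n", x$po, x$pe))
  if (x$kappa_undefined) {
    cat("  kappa undefined (degenerate margins)\n")
  } else {
    cat(sprintf("  kappa %.3f (SE %.3f, one-sided P = %.3g)\n",
                x$kappa, x$kappa_se, x$p_value))
  }
  cat(sprintf("  PABAK %.3f, prevalence index %.3f, bias index %.3f\n",
              x$pabak, x$prevalence_index, x$bias_index))
  cat(sprintf("  positive agreement %s, negative agreement %s\n",
              ifelse(is.na(x$ppos), "-", sprintf("%.3f", x$ppos)),
              ifelse(is.na(x$pneg), "-", sprintf("%.3f", x$pneg))))
  invisible(x)
}
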