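#' Read assessment records from CSV
#'
#' One row per (woman, visit day, rater). Expected columns: `woman_id`,
#' `cluster_id`, `site_id`, `days_postpartum`, `rater` (CHW or PHYSICIAN),
#' temperature columns `temp_value`, `temp_unit` (C|F), `temp_recorded`
#' (0|1), and one 0/1 column per symptom named as in [symptom_fields()].
#' Missing symptom values (absent column or NA cell) are interpreted as
#' "symptom not elicited, therefore not present" and set to `FALSE`; the
#' number of records affected is reported with a warning so silent data loss
#' is visible.
#'
#' @param path CSV file path.
#' @return data frame ready for [classify_profiles()].
#' @export
read_assessments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  n_patched <- 0L
  for (sname in symptom_fields()) {
    if (!sname %in% names(df)) {
      df[[sname]] <- FALSE
      n_patched <- n_patched + nrow(df)
    } else {
      x <- as.logical(df[[sname]])
      miss <- is.na(x)
      n_patched <- n_patched + sum(miss)
      x[miss] <- FALSE
      df[[sname]] <- x
    }
  }
  if (!"temp_recorded" %in% names(df)) {
    df$temp_recorded <- FALSE
    df$temp_value <- NA_real_
  }
  df$temp_recorded <- as.logical(df$temp_recorded)
  df$temp_recorded[is.na(df$temp_recorded)] <- FALSE
  if (!"temp_unit" %in% names(df)) df$temp_unit <- "C"
  if ("days_postpartum" %in% names(df)) {
    bad <- !is.na(df$days_postpartum) &
      (df$days_postpartum < 0 | df$days_postpartum > 59)
    if (any(bad)) stop_("days_postpartum outside 0-59 in %d record(s)", sum(bad))
  }
  if (n_patched > 0) {
    warning(sprintf("%d missing symptom value(s) treated as FALSE (not elicited)",
                    n_patched), call. = FALSE)
  }
  df
}
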