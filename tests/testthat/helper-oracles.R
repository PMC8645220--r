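# Independent oracles kept deliberately separate from the package internals.

# Table-driven classification oracle transcribed row by row from the
# published simplified algorithm: each row is a condition and a category;
# the final category is the highest severity among matching rows.
# Severity: sepsis > other illness > local infection > none.
oracle_classify <- function(sym, fever) {
  stopifnot(fever %in% c("NONE", "MODERATE", "HIGH"))
  g <- function(nm) isTRUE(sym[[nm]])
  fever_at_exam <- fever == "MODERATE"          # high fever is its own row
  fever_signal <- fever_at_exam || g("history_of_fever")
  companion <- g("lower_abdominal_pelvic_pain") || g("abnormal_foul_discharge")
  rows <- list(
    list(fever == "HIGH", "SUSPECTED_PP_SEPSIS"),                      # high fever
    list(fever_signal && companion, "SUSPECTED_PP_SEPSIS"),            # fever/history + pain or discharge
    list(g("severe_vaginal_bleeding"), "OTHER_SUSPECTED_ILLNESS"),
    list(g("severe_headache") && g("blurred_vision"), "OTHER_SUSPECTED_ILLNESS"),
    list(g("leaking_urine_stool"), "OTHER_SUSPECTED_ILLNESS"),
    list(g("convulsions_or_unconscious"), "OTHER_SUSPECTED_ILLNESS"),
    list(g("lower_abdominal_pelvic_pain") && fever == "NONE" &&
           !g("history_of_fever"), "OTHER_SUSPECTED_ILLNESS"),         # pain without fever
    list(fever_at_exam && !companion, "SUSPECTED_LOCAL_INFECTION"),    # fever only
    list(g("history_of_fever") && fever == "NONE" && !companion,
         "SUSPECTED_LOCAL_INFECTION"),                                 # history of fever only
    list(g("abnormal_foul_discharge") && fever == "NONE" &&
           !g("history_of_fever"), "SUSPECTED_LOCAL_INFECTION"),       # discharge without fever
    list(g("burning_on_micturition"), "SUSPECTED_LOCAL_INFECTION"),
    list(g("cough_or_difficulty_breathing"), "SUSPECTED_LOCAL_INFECTION"),
    list(g("wound_pus_or_pain"), "SUSPECTED_LOCAL_INFECTION"),
    list(g("breast_swollen_red_painful"), "SUSPECTED_LOCAL_INFECTION")
  )
  sev <- c(NO_INFECTION = 1, SUSPECTED_LOCAL_INFECTION = 2,
           OTHER_SUSPECTED_ILLNESS = 3, SUSPECTED_PP_SEPSIS = 4)
  best <- "NO_INFECTION"
  for (r in rows) if (r[[1]] && sev[r[[2]]] > sev[best]) best <- r[[2]]
  best
}

# the full input lattice: every boolean combination x fever category
full_lattice <- function() {
  k <- length(symptom_fields())
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(combos) <- symptom_fields()
  lat <- combos[rep(seq_len(nrow(combos)), times = 3), ]
  lat$fever <- rep(c("NONE", "MODERATE", "HIGH"), each = nrow(combos))
  rownames(lat) <- NULL
  lat
}

# brute-force agreement statistics straight from paired ratings
raw_pair_stats <- function(chw, phys) {
  n <- length(chw)
  po <- mean(chw == phys)
  pe <- mean(chw) * mean(phys) + mean(!chw) * mean(!phys)
  list(po = po, pe = pe, kappa = (po - pe) / (1 - pe), pabak = 2 * po - 1)
}

# expand a confusion table into paired ratings
pairs_from_counts <- function(a, b, c, d) {
  chw <- c(rep(TRUE, a), rep(TRUE, b), rep(FALSE, c), rep(FALSE, d))
  phys <- c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d))
  list(chw = chw, phys = phys)
}

# long-format pair data frame for build_confusion()
pair_df_from_counts <- function(a, b, c, d, attribute = "symptom") {
  p <- pairs_from_counts(a, b, c, d)
  n <- length(p$chw)
  df <- data.frame(
    woman_id = rep(sprintf("w%03d", seq_len(n)), 2),
    rater = rep(c("CHW", "PHYSICIAN"), each = n),
    stringsAsFactors = FALSE
  )
  df[[attribute]] <- c(p$chw, p$phys)
  df
}
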