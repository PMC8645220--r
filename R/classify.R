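#' Signs and symptoms screened by community health workers
#'
#' The boolean indicator fields of one assessment occasion, in canonical
#' order. "Severe headache and blurred vision" is stored as two separate
#' booleans and conjoined by the classification rule.
#'
#' @return character vector of column names.
#' @export
symptom_fields <- function() {
  c("history_of_fever",
    "lower_abdominal_pelvic_pain",
    "abnormal_foul_discharge",
    "severe_vaginal_bleeding",
    "severe_headache",
    "blurred_vision",
    "leaking_urine_stool",
    "convulsions_or_unconscious",
    "burning_on_micturition",
    "cough_or_difficulty_breathing",
    "wound_pus_or_pain",
    "breast_swollen_red_painful")
}

#' Illness classification categories, in increasing severity
#'
#' @return character vector, lowest severity first.
#' @export
illness_classes <- function() {
  c("NO_INFECTION", "SUSPECTED_LOCAL_INFECTION",
    "OTHER_SUSPECTED_ILLNESS", "SUSPECTED_PP_SEPSIS")
}

.as_class_factor <- function(x) {
  factor(x, levels = illness_classes(), ordered = TRUE)
}

#' Classify assessment profiles with the CHW screening algorithm
#'
#' Deterministic rule engine mapping signs and symptoms to a screening
#' category. Suspected puerperal sepsis requires a fever signal -- high
#' measured fever on its own, or moderate measured fever / reported history of
#' fever together with lower abdominal or pelvic pain or abnormal
#' foul-smelling discharge. Severe bleeding, headache-with-blurred-vision,
#' leaking urine or stool, convulsions/unconsciousness, and afebrile lower
#' abdominal pain indicate other suspected illness; isolated fever signals,
#' afebrile discharge, burning on micturition, cough or difficulty breathing,
#' wound pus or pain, and a swollen, red or painful breast indicate a
#' suspected local infection. When rules from several categories fire the
#' highest-severity category wins (sepsis dominates, matching the referral
#' logic in which only suspected sepsis triggers 24-hour follow-up).
#'
#' @param profiles data frame with one row per assessment occasion containing
#'   the logical (or 0/1) columns of [symptom_fields()] plus either a
#'   `fever` column (factor as returned by [fever_category()]) or
#'   `temp_value`/`temp_recorded` (and optionally `temp_unit`) columns.
#' @return `profiles` with columns `fever`, `final_class` (ordered factor,
#'   see [illness_classes()]) and `triggered_rules` (semicolon-joined rule
#'   identifiers, empty string when no rule fires) appended.
#' @export
#' @examples
#' p <- data.frame(temp_value = 39.5, temp_recorded = TRUE)
#' for (s in symptom_fields()) p[[s]] <- FALSE
#' classify_profiles(p)$final_class
classify_profiles <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  missing_sym <- setdiff(symptom_fields(), names(profiles))
  if (length(missing_sym)) {
    stop_("missing symptom column(s): %s", paste(missing_sym, collapse = ", "))
  }
  s <- lapply(profiles[symptom_fields()], function(x) {
    x <- as.logical(x)
    if (anyNA(x)) stop_("symptom columns may not contain NA; resolve missingness at ingest")
    x
  })

  if ("fever" %in% names(profiles)) {
    fev <- factor(as.character(profiles$fever), levels = c("NONE", "MODERATE", "HIGH"))
    if (anyNA(fev)) stop_("fever column must be NONE/MODERATE/HIGH")
  } else if (all(c("temp_value", "temp_recorded") %in% names(profiles))) {
    celsius <- temperature_celsius(profiles$temp_value, profiles$temp_recorded,
                                   profiles$temp_unit %||% "C")
    fev <- fever_category(celsius, as.logical(profiles$temp_recorded))
  } else {
    stop_("profiles need either a 'fever' column or 'temp_value' + 'temp_recorded'")
  }

  high <- fev == "HIGH"
  moderate <- fev == "MODERATE"
  none <- fev == "NONE"
  companion <- s$lower_abdominal_pelvic_pain | s$abnormal_foul_discharge
  fever_signal <- moderate | s$history_of_fever

  rules <- list(
    # suspected puerperal sepsis
    HIGH_FEVER            = high,
    FEVER_PLUS_SYMPTOM    = fever_signal & companion,
    # other suspected illness
    SEVERE_BLEEDING       = s$severe_vaginal_bleeding,
    HEADACHE_BLURRED      = s$severe_headache & s$blurred_vision,
    LEAKING_URINE_STOOL   = s$leaking_urine_stool,
    CONVULSIONS           = s$convulsions_or_unconscious,
    PAIN_WITHOUT_FEVER    = s$lower_abdominal_pelvic_pain & none & !s$history_of_fever,
    # suspected local infection
    FEVER_ONLY            = moderate & !companion,
    HISTORY_FEVER_ONLY    = s$history_of_fever & none & !companion,
    DISCHARGE_WITHOUT_FEVER = s$abnormal_foul_discharge & none & !s$history_of_fever,
    BURNING_MICTURITION   = s$burning_on_micturition,
    COUGH_BREATHING       = s$cough_or_difficulty_breathing,
    WOUND_PUS_PAIN        = s$wound_pus_or_pain,
    BREAST_SIGNS          = s$breast_swollen_red_painful
  )
  rule_class <- c(
    HIGH_FEVER = "SUSPECTED_PP_SEPSIS",
    FEVER_PLUS_SYMPTOM = "SUSPECTED_PP_SEPSIS",
    SEVERE_BLEEDING = "OTHER_SUSPECTED_ILLNESS",
    HEADACHE_BLURRED = "OTHER_SUSPECTED_ILLNESS",
    LEAKING_URINE_STOOL = "OTHER_SUSPECTED_ILLNESS",
    CONVULSIONS = "OTHER_SUSPECTED_ILLNESS",
    PAIN_WITHOUT_FEVER = "OTHER_SUSPECTED_ILLNESS",
    FEVER_ONLY = "SUSPECTED_LOCAL_INFECTION",
    HISTORY_FEVER_ONLY = "SUSPECTED_LOCAL_INFECTION",
    DISCHARGE_WITHOUT_FEVER = "SUSPECTED_LOCAL_INFECTION",
    BURNING_MICTURITION = "SUSPECTED_LOCAL_INFECTION",
    COUGH_BREATHING = "SUSPECTED_LOCAL_INFECTION",
    WOUND_PUS_PAIN = "SUSPECTED_LOCAL_INFECTION",
    BREAST_SIGNS = "SUSPECTED_LOCAL_INFECTION"
  )
  fired <- do.call(cbind, rules)  # n x n_rules logical matrix

  sev <- matrix(rep(match(rule_class, illness_classes()), each = nrow(fired)),
                nrow = nrow(fired))
  sev[!fired] <- 1L  # NO_INFECTION
  final_idx <- do.call(pmax, c(as.data.frame(sev), list(1L)))

  triggered <- rep("", nrow(fired))
  for (j in seq_along(rules)) {
    triggered <- paste0(triggered,
                        ifelse(fired[, j], paste0(names(rules)[j], ";"), ""))
  }
  triggered <- sub(";$", "", triggered)

  profiles$fever <- fev
  profiles$final_class <- .as_class_factor(illness_classes()[final_idx])
  profiles$triggered_rules <- triggered
  profiles
}

#' Classify a single assessment profile, returning the rule trace
#'
#' Convenience wrapper around [classify_profiles()] for one occasion.
#'
#' @param ... named symptom booleans (unnamed symptoms default to `FALSE`),
#'   plus optionally `temp_value`, `temp_recorded`, `temp_unit` or `fever`.
#' @return list with elements `final` (character class) and
#'   `triggered_rules` (character vector, possibly empty).
#' @export
#' @examples
#' classify_profile(history_of_fever = TRUE, lower_abdominal_pelvic_pain = TRUE)
classify_profile <- function(...) {
  args <- list(...)
  p <- as.data.frame(args, stringsAsFactors = FALSE)
  if (nrow(p) == 0) p <- data.frame(row.names = 1)
  for (sname in setdiff(symptom_fields(), names(p))) p[[sname]] <- FALSE
  if (!("fever" %in% names(p)) && !("temp_value" %in% names(p))) {
    p$temp_value <- NA_real_
    p$temp_recorded <- FALSE
  }
  out <- classify_profiles(p)
  rules <- out$triggered_rules[1]
  list(final = as.character(out$final_class[1]),
       triggered_rules = if (nzchar(rules)) strsplit(rules, ";", fixed = TRUE)[[1]] else character(0))
}
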