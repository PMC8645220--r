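#' Default per-symptom probabilities given infection status
#'
#' Conditional probabilities of each true symptom given that the woman has
#' (column `infected`) or does not have (column `uninfected`) puerperal
#' sepsis during the assessment window. Defaults are chosen to echo the
#' symptom frequencies seen in postpartum surveillance in South Asian sites:
#' reported history of fever and lower abdominal pain are the common sepsis
#' presentations, foul discharge less so; background rates of the non-sepsis
#' complaints are low.
#'
#' @return 12 x 2 numeric matrix, rows named as [symptom_fields()].
#' @export
default_symptom_probs <- function() {
  m <- rbind(
    history_of_fever              = c(0.85, 0.08),
    lower_abdominal_pelvic_pain   = c(0.75, 0.20),
    abnormal_foul_discharge       = c(0.55, 0.04),
    severe_vaginal_bleeding       = c(0.05, 0.010),
    severe_headache               = c(0.20, 0.10),
    blurred_vision                = c(0.15, 0.05),
    leaking_urine_stool           = c(0.01, 0.005),
    convulsions_or_unconscious    = c(0.01, 0.002),
    burning_on_micturition        = c(0.15, 0.05),
    cough_or_difficulty_breathing = c(0.10, 0.05),
    wound_pus_or_pain             = c(0.10, 0.03),
    breast_swollen_red_painful    = c(0.05, 0.02)
  )
  colnames(m) <- c("infected", "uninfected")
  m
}

#' Configuration for a synthetic postpartum surveillance cohort
#'
#' Defines the study conditions emulated by the generator: a surveillance
#' population followed over a fixed postpartum home-visit schedule, a true
#' sepsis prevalence, per-symptom conditional probabilities, CHW observation
#' error at both the symptom level and the screening-classification level,
#' an error-free physician gold standard (configurable), and nested
#' case-control sampling with 1:k controls matched on administrative cluster
#' and days postpartum.
#'
#' @param n_women surveillance population size.
#' @param n_clusters number of administrative areas.
#' @param visit_days postpartum home-visit schedule (days), strictly
#'   increasing within 0-59.
#' @param sepsis_prevalence probability a woman develops puerperal sepsis
#'   during the surveillance window.
#' @param chw_class_se,chw_class_sp per-woman sensitivity and specificity of
#'   the CHW screening classification relative to true infection status.
#' @param symptom_probs matrix as [default_symptom_probs()], or a function
#'   `(n, infected)` returning a logical matrix (hook for user-supplied joint
#'   samplers with symptom correlation).
#' @param chw_symptom_error length-2 `(se, sp)` applied to every symptom, or
#'   a 12 x 2 matrix (rows = symptoms).
#' @param physician_symptom_error as `chw_symptom_error`; default `c(1, 1)`
#'   (the physician is treated as gold standard).
#' @param temp_availability probability a thermometer measurement is taken
#'   at a visit.
#' @param temp_sd Gaussian measurement jitter (degrees C) on observed
#'   temperature, truncated to the plausibility window.
#' @param n_cases number of index cases to enrol (first screen-positives).
#' @param control_ratio controls per case.
#' @param match_window_days controls must have an assessment within this
#'   many days postpartum of the case's detection day.
#' @param seed optional integer seed used by [run_study()].
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_women = 10000,
                          n_clusters = 20,
                          visit_days = c(0, 6, 13, 20, 27, 34, 41, 48, 59),
                          sepsis_prevalence = 0.05,
                          chw_class_se = 0.82,
                          chw_class_sp = 0.90,
                          symptom_probs = default_symptom_probs(),
                          chw_symptom_error = c(se = 0.80, sp = 0.95),
                          physician_symptom_error = c(se = 1, sp = 1),
                          temp_availability = 0.95,
                          temp_sd = 0.2,
                          n_cases = 75,
                          control_ratio = 3,
                          match_window_days = 1,
                          seed = NULL) {
  if (n_women < 1) stop_("n_women must be positive")
  if (n_clusters < 1) stop_("need at least one cluster")
  if (any(diff(visit_days) <= 0) || min(visit_days) < 0 || max(visit_days) > 59) {
    stop_("visit_days must be strictly increasing within 0-59")
  }
  probs <- c(sepsis_prevalence, chw_class_se, chw_class_sp,
             temp_availability)
  if (any(probs < 0) || any(probs > 1)) stop_("probabilities must lie in [0, 1]")
  if (is.matrix(symptom_probs)) {
    if (!identical(rownames(symptom_probs), symptom_fields())) {
      stop_("symptom_probs rows must be symptom_fields() in order")
    }
    if (any(symptom_probs < 0) || any(symptom_probs > 1)) {
      stop_("symptom_probs must lie in [0, 1]")
    }
  } else if (!is.function(symptom_probs)) {
    stop_("symptom_probs must be a matrix or a sampler function")
  }
  structure(list(n_women = as.integer(n_women), n_clusters = as.integer(n_clusters),
                 visit_days = as.integer(visit_days),
                 sepsis_prevalence = sepsis_prevalence,
                 chw_class_se = chw_class_se, chw_class_sp = chw_class_sp,
                 symptom_probs = symptom_probs,
                 chw_symptom_error = .as_error_matrix(chw_symptom_error),
                 physician_symptom_error = .as_error_matrix(physician_symptom_error),
                 temp_availability = temp_availability, temp_sd = temp_sd,
                 n_cases = as.integer(n_cases),
                 control_ratio = as.integer(control_ratio),
                 match_window_days = as.integer(match_window_days),
                 seed = seed),
            class = "cohort_config")
}

.as_error_matrix <- function(err) {
  k <- length(symptom_fields())
  if (is.matrix(err)) {
    stopifnot(nrow(err) == k, ncol(err) == 2)
    m <- err
  } else {
    stopifnot(length(err) == 2)
    m <- matrix(rep(as.numeric(err), each = k), k, 2)
  }
  dimnames(m) <- list(symptom_fields(), c("se", "sp"))
  if (any(m < 0) || any(m > 1)) stop_("error rates must lie in [0, 1]")
  m
}

# draw a true-symptom logical matrix (n x 12)
.draw_symptoms <- function(cfg, infected) {
  n <- length(infected)
  if (is.function(cfg$symptom_probs)) {
    m <- cfg$symptom_probs(n, infected)
    stopifnot(is.logical(m), nrow(m) == n, ncol(m) == length(symptom_fields()))
    colnames(m) <- symptom_fields()
    return(m)
  }
  p <- cfg$symptom_probs[, ifelse(infected, "infected", "uninfected"), drop = FALSE]
  m <- matrix(stats::runif(n * nrow(p)) < t(p), nrow = n,
              dimnames = list(NULL, symptom_fields()))
  m
}

#' Generate the surveillance population with true status and symptoms
#'
#' One row per woman-visit, carrying the *true* symptom vector and true
#' temperature. Infected women carry an untreated, persistent sepsis episode:
#' their true profile at every visit satisfies the sepsis screening criteria
#' (fever signal plus pelvic pain or abnormal discharge), so an error-free
#' rater applying the algorithm classifies them as suspected sepsis whenever
#' they are assessed -- which is what makes the physician a coherent gold
#' standard for the woman's infection status regardless of when a matched
#' control assessment falls. Uninfected women's rows are drawn at background
#' symptom rates with any accidental sepsis-triggering combination
#' suppressed, so true classification equals true infection status. Actual
#' visit days jitter by up to one day around the schedule, which makes the
#' +/- 1 day matching window non-trivial.
#'
#' @param cfg [cohort_config()].
#' @return list with `women` (woman_id, cluster_id, infected) and `visits`
#'   (one row per woman-visit: ids, visit index, day, true symptom columns,
#'   `temp_value`, `temp_recorded`).
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_women
  nv <- length(cfg$visit_days)
  women <- data.frame(
    woman_id = sprintf("W%05d", seq_len(n)),
    cluster_id = sprintf("C%02d", sample.int(cfg$n_clusters, n, replace = TRUE)),
    infected = stats::runif(n) < cfg$sepsis_prevalence,
    stringsAsFactors = FALSE
  )

  visits <- data.frame(
    woman_id = rep(women$woman_id, each = nv),
    cluster_id = rep(women$cluster_id, each = nv),
    infected = rep(women$infected, each = nv),
    visit = rep(seq_len(nv), n),
    stringsAsFactors = FALSE
  )
  jitter <- sample(c(-1L, 0L, 1L), nrow(visits), replace = TRUE)
  visits$days_postpartum <- pmin(pmax(rep(cfg$visit_days, n) + jitter, 0L), 59L)

  inf <- visits$infected
  sym <- .draw_symptoms(cfg, inf)
  # infected rows must truly satisfy the sepsis criteria
  no_companion <- inf & !(sym[, "lower_abdominal_pelvic_pain"] | sym[, "abnormal_foul_discharge"])
  sym[no_companion, "lower_abdominal_pelvic_pain"] <- TRUE
  # true temperature: febrile while infected, afebrile otherwise
  temp <- stats::rnorm(nrow(visits), mean = ifelse(inf, 38.7, 36.9),
                       sd = ifelse(inf, 0.6, 0.35))
  temp[!inf] <- pmin(temp[!inf], 37.9)  # background temps stay below the fever cut
  temp <- pmin(pmax(temp, .TEMP_MIN), .TEMP_MAX)
  # fever signal: history of fever, or failing that measured fever
  need_signal <- inf & !sym[, "history_of_fever"] & temp < 38.05
  temp[need_signal] <- 38.7
  # uninfected rows must not truly satisfy the criteria
  acc <- !inf & sym[, "history_of_fever"] &
    (sym[, "lower_abdominal_pelvic_pain"] | sym[, "abnormal_foul_discharge"])
  sym[acc, "history_of_fever"] <- FALSE

  visits <- cbind(visits, as.data.frame(sym))
  visits$temp_value <- temp
  visits$temp_recorded <- TRUE
  list(women = women, visits = visits)
}

#' Apply per-symptom observation error to true profiles
#'
#' The measurement-error layer inducing rater disagreement: each boolean is
#' flipped independently according to the rater's per-symptom sensitivity
#' and specificity, and the measured temperature is reported with a given
#' availability and Gaussian jitter truncated to the plausibility window.
#'
#' @param visits data frame as `generate_population()$visits` (true
#'   profiles).
#' @param symptom_error length-2 `(se, sp)` or 12 x 2 matrix.
#' @param temp_availability probability the thermometer reading is taken.
#' @param temp_sd SD of Gaussian jitter on the observed temperature.
#' @return `visits` with symptom columns replaced by observed values and
#'   observed `temp_value` / `temp_recorded`.
#' @export
observe_profiles <- function(visits, symptom_error,
                             temp_availability = 1, temp_sd = 0) {
  err <- .as_error_matrix(symptom_error)
  n <- nrow(visits)
  for (sname in symptom_fields()) {
    truth <- visits[[sname]]
    u <- stats::runif(n)
    visits[[sname]] <- ifelse(truth, u < err[sname, "se"], u >= err[sname, "sp"])
  }
  rec <- visits$temp_recorded & (stats::runif(n) < temp_availability)
  tv <- visits$temp_value + stats::rnorm(n, 0, temp_sd)
  visits$temp_value <- ifelse(rec, pmin(pmax(tv, .TEMP_MIN), .TEMP_MAX), NA_real_)
  visits$temp_recorded <- rec
  visits
}

# CHW observation: symptom-level noise plus classification-level screening
# error imposed by construction. Whether the CHW ever recognises a woman as
# a suspected sepsis case is a single per-woman draw (her judgment of a
# given woman is stable over the surveillance window): infected women are
# recognised with probability chw_class_se at one visit (recognition timing
# uniform over the schedule), uninfected women trigger a false alarm with
# probability 1 - chw_class_sp at one random visit. The observed fever
# signal is edited so that classify() on the CHW profile screens positive
# exactly at the designated visit and nowhere else, making the per-woman
# screening operating characteristics equal to the configured values.
.observe_chw <- function(pop, cfg) {
  visits <- pop$visits
  obs <- observe_profiles(visits, cfg$chw_symptom_error,
                          cfg$temp_availability, cfg$temp_sd)
  women <- pop$women
  nv <- length(cfg$visit_days)
  detect <- stats::runif(nrow(women)) < cfg$chw_class_se
  false_pos <- stats::runif(nrow(women)) < (1 - cfg$chw_class_sp)
  flag_visit <- sample.int(nv, nrow(women), replace = TRUE)

  idx <- match(obs$woman_id, women$woman_id)
  designated <- ((women$infected[idx] & detect[idx]) |
                 (!women$infected[idx] & false_pos[idx])) &
    obs$visit == flag_visit[idx]

  cls0 <- classify_profiles(obs)
  screened_pos <- cls0$final_class == "SUSPECTED_PP_SEPSIS"
  # designated rows that the noisy observation alone would miss are forced
  # positive (the CHW recognises the case): elicit the fever history and,
  # if need be, the pain companion
  need <- designated & !screened_pos
  obs$history_of_fever[need] <- TRUE
  no_comp <- need & !(obs$lower_abdominal_pelvic_pain | obs$abnormal_foul_discharge)
  obs$lower_abdominal_pelvic_pain[no_comp] <- TRUE
  # suppress accidental screen positives elsewhere (only designated rows
  # were edited above, so cls0 is still valid for the rest)
  spurious <- !designated & screened_pos
  obs$history_of_fever[spurious] <- FALSE
  fev <- fever_category(obs$temp_value, obs$temp_recorded)
  still_feb <- spurious & fev != "NONE"
  obs$temp_value[still_feb] <- 37.6
  obs
}

#' Run one nested case-control validation study on a synthetic cohort
#'
#' The CHW classifies every woman at every scheduled visit with the
#' screening algorithm; the first suspected-sepsis visit defines an index
#' case (each woman enrols at most once). The first `n_cases` cases by
#' detection day are enrolled, and for each case `control_ratio` controls
#' are sampled uniformly without replacement from never-screen-positive
#' women in the same cluster with an assessment within
#' `match_window_days` days postpartum of the case's detection day
#' (shortfalls are recorded, never silent). All enrolled women are assessed
#' by the study physician (error-free by default, hence equal to truth), and
#' population screen totals are retained so that [begg_greenes()] can adjust
#' the enrolled-subset estimates for verification bias.
#'
#' @param cfg [cohort_config()]; `cfg$seed`, when set, makes the study
#'   reproducible.
#' @return object of class `ppsepsis_study`: `pairs` (long CHW/physician
#'   rows for enrolled women, for [build_confusion()]), `verification`
#'   ([verification_counts()]), `cases`, `controls`, `screen`
#'   (per-woman screening summary), `population_classes` (screen totals per
#'   classification), `shortfall` (missing control slots), `config`.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pop <- generate_population(cfg)
  obs <- .observe_chw(pop, cfg)
  cls <- classify_profiles(obs)

  sepsis_row <- cls$final_class == "SUSPECTED_PP_SEPSIS"
  # per-woman screening summary; rows are woman-major with visits in
  # chronological order (the +/- 1 day jitter cannot reorder visits >= 5
  # days apart), so the first positive row is the earliest positive visit
  nv <- length(cfg$visit_days)
  n <- cfg$n_women
  wix <- rep(seq_len(n), each = nv)
  screen_pos <- tabulate(wix[sepsis_row], nbins = n) > 0
  pos_rows <- which(sepsis_row)
  first_of_woman <- pos_rows[!duplicated(wix[pos_rows])]
  first_pos_row <- rep(NA_integer_, n)
  first_pos_row[wix[first_of_woman]] <- first_of_woman
  women <- pop$women
  screen <- data.frame(
    woman_id = women$woman_id, cluster_id = women$cluster_id,
    infected = women$infected, screen_pos = screen_pos,
    detection_day = ifelse(is.na(first_pos_row), NA_integer_,
                           cls$days_postpartum[first_pos_row]),
    detection_row = first_pos_row,
    stringsAsFactors = FALSE
  )
  # population screen totals per classification (highest severity per woman)
  sev_mat <- matrix(as.integer(cls$final_class), nrow = nv)
  max_sev <- do.call(pmax, lapply(seq_len(nv), function(i) sev_mat[i, ]))
  population_classes <- table(factor(illness_classes()[max_sev],
                                     levels = illness_classes()))

  # ---- enrol cases -------------------------------------------------------
  cand <- screen[screen$screen_pos, ]
  cand <- cand[order(cand$detection_day, cand$woman_id), ]
  n_cases <- min(cfg$n_cases, nrow(cand))
  if (n_cases == 0) stop_("no screen-positive women; cannot form a case series")
  cases <- cand[seq_len(n_cases), ]

  # ---- matched controls --------------------------------------------------
  days_mat <- matrix(obs$days_postpartum, nrow = nv)  # visits x women
  eligible <- !screen$screen_pos                      # sampled without replacement
  by_cluster <- split(seq_len(n), screen$cluster_id)
  controls <- vector("list", n_cases)
  shortfall <- 0L
  for (i in seq_len(n_cases)) {
    case_ix <- match(cases$woman_id[i], screen$woman_id)
    pool <- by_cluster[[screen$cluster_id[case_ix]]]
    pool <- pool[eligible[pool]]
    if (length(pool)) {
      dd <- abs(days_mat[, pool, drop = FALSE] - cases$detection_day[i])
      nearest_visit <- max.col(-t(dd), ties.method = "first")
      gap <- dd[cbind(nearest_visit, seq_along(pool))]
      ok <- which(gap <= cfg$match_window_days)
    } else {
      ok <- integer(0)
    }
    take <- min(cfg$control_ratio, length(ok))
    shortfall <- shortfall + (cfg$control_ratio - take)
    if (take > 0) {
      sel <- ok[sample.int(length(ok), take)]
      wsel <- pool[sel]
      eligible[wsel] <- FALSE
      controls[[i]] <- data.frame(
        woman_id = screen$woman_id[wsel],
        case_id = cases$woman_id[i],
        matched_day = days_mat[cbind(nearest_visit[sel], wsel)],
        stringsAsFactors = FALSE)
    }
  }
  controls <- do.call(rbind, controls[!vapply(controls, is.null, TRUE)])
  if (shortfall > 0) {
    message(sprintf("control matching shortfall: %d slot(s) unfilled", shortfall))
  }

  # ---- assessment pairs for enrolled women -------------------------------
  row_for <- function(ids, days) {
    key <- paste(obs$woman_id, obs$days_postpartum)
    match(paste(ids, days), key)
  }
  case_rows <- cases$detection_row
  ctrl_rows <- if (!is.null(controls)) row_for(controls$woman_id, controls$matched_day) else integer(0)
  enrolled_rows <- c(case_rows, ctrl_rows)
  roles <- c(rep("case", length(case_rows)), rep("control", length(ctrl_rows)))

  chw_pairs <- cls[enrolled_rows, c("woman_id", "cluster_id", "days_postpartum",
                                    symptom_fields(), "fever", "final_class")]
  chw_pairs$rater <- "CHW"
  # physician assessment: truth filtered through the physician's error model
  truth_rows <- pop$visits[enrolled_rows, ]
  phys_obs <- observe_profiles(truth_rows, cfg$physician_symptom_error,
                               temp_availability = 1, temp_sd = 0)
  phys <- classify_profiles(phys_obs)
  phys_pairs <- phys[, c("woman_id", "cluster_id", "days_postpartum",
                         symptom_fields(), "fever", "final_class")]
  phys_pairs$rater <- "PHYSICIAN"
  pairs <- rbind(chw_pairs, phys_pairs)
  pairs$role <- rep(roles, 2)
  pairs$infected <- screen$infected[match(pairs$woman_id, screen$woman_id)]
  rownames(pairs) <- NULL

  phys_sepsis <- phys_pairs$final_class == "SUSPECTED_PP_SEPSIS"
  case_dpos <- phys_sepsis[roles == "case"]
  ctrl_dpos <- phys_sepsis[roles == "control"]
  verification <- verification_counts(
    n_screen_pos = sum(screen$screen_pos),
    n_screen_neg = sum(!screen$screen_pos),
    vp_dpos = sum(case_dpos), vp_dneg = sum(!case_dpos),
    vn_dpos = sum(ctrl_dpos), vn_dneg = sum(!ctrl_dpos))

  structure(list(config = cfg, pairs = pairs, verification = verification,
                 cases = cases, controls = controls, screen = screen,
                 population_classes = population_classes,
                 shortfall = shortfall),
            class = "ppsepsis_study")
}

#' @export
print.ppsepsis_study <- function(x, ...) {
  cat(sprintf("synthetic validation study: %d women, %d screen-positive\n",
              x$config$n_women, sum(x$screen$screen_pos)))
  cat(sprintf("  enrolled %d cases + %d controls (shortfall %d)\n",
              nrow(x$cases), if (is.null(x$controls)) 0L else nrow(x$controls),
              x$shortfall))
  invisible(x)
}
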