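small_cfg <- function(...) {
  cohort_config(n_women = 2000, n_clusters = 8, n_cases = 20, ...)
}

test_that("population generation is reproducible and hits configured rates", {
  cfg <- small_cfg(seed = 42)
  set.seed(cfg$seed); p1 <- generate_population(cfg)
  set.seed(cfg$seed); p2 <- generate_population(cfg)
  expect_identical(p1, p2)
  # prevalence within Monte Carlo noise
  prev <- mean(p1$women$infected)
  se_mc <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(prev - 0.05), 3 * se_mc)
  # configured conditional symptom probability recovered by tally
  inf_rows <- p1$visits$infected
  emp <- mean(p1$visits$lower_abdominal_pelvic_pain[!inf_rows])
  expect_lt(abs(emp - default_symptom_probs()["lower_abdominal_pelvic_pain",
                                              "uninfected"]),
            3 * sqrt(0.2 * 0.8 / sum(!inf_rows)))
  # infected rows truly satisfy the sepsis screening criteria
  tr <- classify_profiles(p1$visits[inf_rows, ])
  expect_true(all(tr$final_class == "SUSPECTED_PP_SEPSIS"))
  # uninfected rows never do
  un <- classify_profiles(p1$visits[!inf_rows, ])
  expect_true(all(un$final_class != "SUSPECTED_PP_SEPSIS"))
  # zero prevalence: nobody infected
  cfg0 <- small_cfg(sepsis_prevalence = 0, seed = 1)
  set.seed(1)
  expect_false(any(generate_population(cfg0)$women$infected))
  expect_error(cohort_config(n_clusters = 0), "cluster")
  expect_error(cohort_config(visit_days = c(0, 70)), "visit_days")
})

test_that("observation error behaves at its extremes", {
  cfg <- small_cfg(seed = 3)
  set.seed(3)
  pop <- generate_population(cfg)
  truth <- pop$visits
  # error-free observation equals truth
  set.seed(4)
  same <- observe_profiles(truth, c(1, 1), temp_availability = 1, temp_sd = 0)
  expect_identical(same[symptom_fields()], truth[symptom_fields()])
  expect_equal(same$temp_value, truth$temp_value)
  # coin-flip observation is independent of truth: kappa near 0
  set.seed(5)
  noise <- observe_profiles(truth, c(0.5, 0.5))
  ct <- confusion_table(
    a = sum(noise$history_of_fever & truth$history_of_fever),
    b = sum(noise$history_of_fever & !truth$history_of_fever),
    c = sum(!noise$history_of_fever & truth$history_of_fever),
    d = sum(!noise$history_of_fever & !truth$history_of_fever))
  expect_lt(abs(cohen_kappa(ct)$kappa), 0.03)
  # thermometer never available: every fever category NONE
  set.seed(6)
  cold <- observe_profiles(truth, c(1, 1), temp_availability = 0)
  expect_true(all(fever_category(cold$temp_value, cold$temp_recorded) == "NONE"))
})

test_that("a study enrols matched controls that satisfy every constraint", {
  st <- run_study(small_cfg(seed = 11))
  expect_equal(nrow(st$cases), 20)
  expect_lte(nrow(st$controls), 60)
  # every control matches its case on cluster and the +/- 1 day window
  case_day <- st$cases$detection_day[match(st$controls$case_id, st$cases$woman_id)]
  expect_true(all(abs(st$controls$matched_day - case_day) <= 1))
  cl_control <- st$screen$cluster_id[match(st$controls$woman_id, st$screen$woman_id)]
  cl_case <- st$screen$cluster_id[match(st$controls$case_id, st$screen$woman_id)]
  expect_true(all(cl_control == cl_case))
  # controls are CHW screen-negative, sampled without replacement
  expect_false(any(st$controls$woman_id %in% st$screen$woman_id[st$screen$screen_pos]))
  expect_false(any(duplicated(st$controls$woman_id)))
  # pairs: one CHW and one physician row per enrolled woman
  tab <- table(st$pairs$woman_id, st$pairs$rater)
  expect_true(all(tab == 1))
  # verification counts line up with enrolment and the population
  expect_equal(st$verification$vp_dpos + st$verification$vp_dneg, nrow(st$cases))
  expect_equal(st$verification$n_screen_pos + st$verification$n_screen_neg,
               st$config$n_women)
  # reproducible under the same seed
  st2 <- run_study(small_cfg(seed = 11))
  expect_identical(st$pairs, st2$pairs)
})

test_that("per-woman screening error equals the configured classification error", {
  st <- run_study(cohort_config(n_women = 20000, n_clusters = 10,
                                n_cases = 75, seed = 21))
  se_hat <- with(st$screen, mean(screen_pos[infected]))
  sp_hat <- with(st$screen, mean(!screen_pos[!infected]))
  n_inf <- sum(st$screen$infected)
  expect_lt(abs(se_hat - 0.82), 3 * sqrt(0.82 * 0.18 / n_inf))
  expect_lt(abs(sp_hat - 0.90), 3 * sqrt(0.9 * 0.1 / (20000 - n_inf)))
  # CHW final classes in the pairs are algorithm output, sepsis iff enrolled case
  chw <- st$pairs[st$pairs$rater == "CHW", ]
  expect_true(all((chw$final_class == "SUSPECTED_PP_SEPSIS") == (chw$role == "case")))
})

test_that("an error-free CHW agrees perfectly with the physician", {
  cfg <- cohort_config(n_women = 3000, n_clusters = 6, n_cases = 15,
                       chw_class_se = 1, chw_class_sp = 1,
                       chw_symptom_error = c(1, 1),
                       temp_availability = 1, temp_sd = 0, seed = 8)
  st <- run_study(cfg)
  bg <- begg_greenes(st$verification)
  expect_equal(bg$sensitivity, 1)
  expect_equal(bg$specificity, 1)
  expect_equal(bg$naive_sensitivity, 1)
  expect_equal(bg$naive_specificity, 1)
  expect_equal(cohen_kappa(build_confusion(st$pairs, "final_class"))$kappa, 1)
  for (s in c("history_of_fever", "lower_abdominal_pelvic_pain",
              "abnormal_foul_discharge")) {
    k <- cohen_kappa(build_confusion(st$pairs, s))
    if (!k$undefined) expect_equal(k$kappa, 1)
  }
})

test_that("an exhausted matching pool is reported, never silent", {
  cfg <- cohort_config(n_women = 120, n_clusters = 40, n_cases = 10,
                       match_window_days = 0, sepsis_prevalence = 0.3,
                       seed = 17)
  expect_message(st <- run_study(cfg), "shortfall")
  expect_gt(st$shortfall, 0)
  expect_s3_class(st, "ppsepsis_study")
})

test_that("the classification score yields a sensible ROC for enrolled women", {
  st <- run_study(small_cfg(seed = 29))
  chw <- st$pairs[st$pairs$rater == "CHW", ]
  phys <- st$pairs[st$pairs$rater == "PHYSICIAN", ]
  phys <- phys[match(chw$woman_id, phys$woman_id), ]
  score <- as.integer(chw$fever != "NONE" | chw$history_of_fever) +
    as.integer(chw$lower_abdominal_pelvic_pain) +
    as.integer(chw$abnormal_foul_discharge)
  truth <- phys$final_class == "SUSPECTED_PP_SEPSIS"
  r <- roc_curve(truth, score)
  expect_gt(r$auroc, 0.7)  # informative well above chance
  expect_true(all(diff(r$points$tpr) >= 0))
})
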