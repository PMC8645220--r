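test_that("confusion tables are built and validated from matched pairs", {
  df <- pair_df_from_counts(3, 0, 0, 0)
  ct <- build_confusion(df, "symptom")
  expect_equal(unlist(ct[c("a", "b", "c", "d")]), c(a = 3, b = 0, c = 0, d = 0))
  # published row: Sylhet history of fever (TP 37, TN 214, FP 23, FN 4)
  ct2 <- build_confusion(pair_df_from_counts(37, 23, 4, 214), "symptom")
  expect_equal(unlist(ct2[c("a", "b", "c", "d")]),
               c(a = 37, b = 23, c = 4, d = 214))
  expect_error(build_confusion(df[0, ], "symptom"), "no assessment pairs")
  expect_error(confusion_table(0, 0, 0, 0), "at least one")
  expect_error(confusion_table(-1, 1, 1, 1), "non-negative")
  dup <- rbind(df, df[1, ])
  expect_error(build_confusion(dup, "symptom"), "unmatched or duplicated")
})

test_that("kappa, PABAK and companions reproduce hand-checked published rows", {
  # Sylhet lower abdominal/pelvic pain
  ct <- confusion_table(a = 107, b = 11, c = 81, d = 79)
  ag <- agreement_summary(ct)
  expect_equal(ag$po, 186 / 278)
  expect_equal(round_half_up(ag$kappa, 2), 0.37)
  expect_equal(round_half_up(ag$pabak, 2), 0.34)
  # Sylhet high fever: strong PABAK, weak kappa (extreme prevalence)
  ct <- confusion_table(a = 1, b = 7, c = 0, d = 270)
  expect_equal(round_half_up(cohen_kappa(ct)$kappa, 2), 0.22)
  expect_equal(round_half_up(pabak(ct), 2), 0.95)
  # Karachi burning on micturition (published 0.48/0.68; kappa is 0.475
  # from the counts, agreeing with the published value to +/- 0.01)
  ct <- confusion_table(a = 32, b = 17, c = 31, d = 220)
  expect_equal(round_half_up(pabak(ct), 2), 0.68)
  expect_lt(abs(cohen_kappa(ct)$kappa - 0.48), 0.0105)
  # negative agreement, Sylhet history of fever
  ct <- confusion_table(a = 37, b = 23, c = 4, d = 214)
  expect_equal(round_half_up(100 * negative_agreement(ct)), 94)
  # positive agreement, Karachi history of fever
  ct <- confusion_table(a = 87, b = 17, c = 39, d = 157)
  expect_equal(round_half_up(100 * positive_agreement(ct)), 76)
})

test_that("kappa edge cases: perfect agreement, independence, degeneracy", {
  expect_equal(cohen_kappa(confusion_table(5, 0, 0, 7))$kappa, 1)
  # margins independent by construction: po == pe == 0.82
  k0 <- cohen_kappa(confusion_table(1, 9, 9, 81))
  expect_equal(k0$po, 0.82)
  expect_equal(k0$pe, 0.82)
  expect_equal(k0$kappa, 0)
  # both raters constant: kappa undefined, flagged not NaN
  und <- cohen_kappa(confusion_table(0, 0, 0, 12))
  expect_true(und$undefined)
  expect_true(is.na(und$kappa))
  expect_true(agreement_summary(confusion_table(0, 0, 0, 12))$kappa_undefined)
  # zero-denominator conditional agreement
  expect_true(is.na(positive_agreement(confusion_table(0, 0, 0, 5))))
  expect_true(is.na(negative_agreement(confusion_table(5, 0, 0, 0))))
})

test_that("kappa-family identities hold across random tables", {
  set.seed(41)
  for (i in 1:200) {
    cnt <- rmultinom(1, sample(4:150, 1), prob = runif(4))[, 1]
    if (sum(cnt) == 0) next
    ct <- confusion_table(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(pabak(ct), 2 * observed_agreement(ct) - 1)
    # kappa invariant under swapping b and c; po under swapping a and d
    ct_swap <- confusion_table(cnt[1], cnt[3], cnt[2], cnt[4])
    k1 <- cohen_kappa(ct); k2 <- cohen_kappa(ct_swap)
    if (!k1$undefined) expect_equal(k1$kappa, k2$kappa)
    expect_equal(observed_agreement(confusion_table(cnt[4], cnt[2], cnt[3], cnt[1])),
                 observed_agreement(ct))
    # balanced prevalence and bias: kappa equals PABAK
    if (cnt[1] + cnt[2] > 0) {
      ctb <- confusion_table(cnt[1], cnt[2], cnt[2], cnt[1])
      kb <- cohen_kappa(ctb)
      if (!kb$undefined) expect_equal(kb$kappa, pabak(ctb))
    }
  }
})

test_that("statistics from raw pairs equal statistics from tallied tables", {
  set.seed(7)
  for (i in 1:50) {
    cnt <- rmultinom(1, sample(2:60, 1), prob = runif(4, 0.05, 1))[, 1]
    if (cnt[1] + cnt[4] == 0 || sum(cnt) < 2) next
    raw <- pairs_from_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    oracle <- raw_pair_stats(raw$chw, raw$phys)
    ct <- build_confusion(pair_df_from_counts(cnt[1], cnt[2], cnt[3], cnt[4]),
                          "symptom")
    k <- cohen_kappa(ct)
    expect_equal(k$po, oracle$po)
    expect_equal(k$pe, oracle$pe)
    if (!k$undefined) expect_equal(k$kappa, oracle$kappa)
    expect_equal(pabak(ct), oracle$pabak)
  }
})

test_that("kappa matches an independent library implementation", {
  skip_if_not_installed("e1071")
  set.seed(13)
  for (i in 1:25) {
    cnt <- rmultinom(1, 200, prob = runif(4, 0.05, 1))[, 1]
    ct <- confusion_table(cnt[1], cnt[2], cnt[3], cnt[4])
    tab <- matrix(c(cnt[1], cnt[3], cnt[2], cnt[4]), 2, 2)
    expect_equal(cohen_kappa(ct)$kappa, e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("asymptotic kappa SE is consistent with a resampling oracle", {
  set.seed(19)
  ct <- confusion_table(a = 107, b = 11, c = 81, d = 79)
  se_asym <- cohen_kappa(ct)$se
  raw <- pairs_from_counts(ct$a, ct$b, ct$c, ct$d)
  boots <- replicate(2000, {
    i <- sample.int(ct$n, ct$n, replace = TRUE)
    raw_pair_stats(raw$chw[i], raw$phys[i])$kappa
  })
  expect_equal(se_asym, sd(boots), tolerance = 0.15)
  # published SE for this row is 0.05
  expect_equal(round_half_up(se_asym, 2), 0.05)
})

test_that("the one-sided kappa test flags clear agreement and not independence", {
  strong <- cohen_kappa(confusion_table(40, 5, 5, 50))
  expect_lt(strong$p_value, 0.001)
  indep <- cohen_kappa(confusion_table(1, 9, 9, 81))
  expect_gt(indep$p_value, 0.4)
})
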