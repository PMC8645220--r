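#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Thin wrapper over [stats::binom.test()] returning just the bounds. At
#' `x = 0` the lower bound is exactly 0; at `x = n` the upper bound is
#' exactly 1.
#'
#' @param x number of successes.
#' @param n number of trials (`n >= 1`).
#' @param conf.level confidence level, default 0.95.
#' @return numeric length-2 vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(x, n, conf.level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  as.numeric(stats::binom.test(x, n, conf.level = conf.level)$conf.int)
}

#' Sensitivity and specificity with exact intervals
#'
#' With the physician as gold standard: sensitivity `a / (a + c)`,
#' specificity `d / (b + d)`, each with a two-sided Clopper-Pearson interval.
#' An empty denominator (no gold-standard positives, or no negatives) yields
#' an undefined estimate (`NA`, flagged), mirroring suppressed cells in
#' reported tables.
#'
#' @param ct [confusion_table()] with `a` = TP, `b` = FP, `c` = FN, `d` = TN.
#' @param conf.level confidence level for the intervals.
#' @return object of class `validity_result` with fields `sensitivity`,
#'   `se_ci`, `specificity`, `sp_ci`, the counts, and undefined flags.
#' @export
sensitivity_specificity <- function(ct, conf.level = 0.95) {
  npos <- ct$a + ct$c
  nneg <- ct$b + ct$d
  se <- if (npos > 0) ct$a / npos else NA_real_
  sp <- if (nneg > 0) ct$d / nneg else NA_real_
  se_ci <- if (npos > 0) clopper_pearson(ct$a, npos, conf.level) else c(NA_real_, NA_real_)
  sp_ci <- if (nneg > 0) clopper_pearson(ct$d, nneg, conf.level) else c(NA_real_, NA_real_)
  structure(list(
    tp = ct$a, fp = ct$b, fn = ct$c, tn = ct$d,
    sensitivity = se, se_ci = se_ci,
    specificity = sp, sp_ci = sp_ci,
    conf.level = conf.level,
    se_undefined = npos == 0, sp_undefined = nneg == 0
  ), class = "validity_result")
}

#' @export
print.validity_result <- function(x, ...) {
  fmt <- function(p, ci, undef) {
    if (undef) "- (undefined)"
    else sprintf("%.1f%% (%.0f%% CI %.1f-%.1f)", 100 * p, 100 * x$conf.level,
                 100 * ci[1], 100 * ci[2])
  }
  cat("sensitivity:", fmt(x$sensitivity, x$se_ci, x$se_undefined), "\n")
  cat("specificity:", fmt(x$specificity, x$sp_ci, x$sp_undefined), "\n")
  invisible(x)
}

#' Screen-level totals and verified-subset cross-tabulation
#'
#' The input to the verification-bias adjustment: how many subjects screened
#' positive and negative in the surveillance population, and the
#' gold-standard cross-tabulation among the subset actually verified
#' (all screen-positives plus sampled screen-negative controls in a nested
#' case-control design).
#'
#' @param n_screen_pos,n_screen_neg population screen totals.
#' @param vp_dpos,vp_dneg verified screen-positives that are gold-standard
#'   positive / negative.
#' @param vn_dpos,vn_dneg verified screen-negatives that are gold-standard
#'   positive / negative.
#' @return object of class `verification_counts`.
#' @export
verification_counts <- function(n_screen_pos, n_screen_neg,
                                vp_dpos, vp_dneg, vn_dpos, vn_dneg) {
  v <- c(n_screen_pos, n_screen_neg, vp_dpos, vp_dneg, vn_dpos, vn_dneg)
  if (anyNA(v) || any(v < 0) || any(v != round(v))) {
    stop_("verification counts must be non-negative integers")
  }
  if (vp_dpos + vp_dneg > n_screen_pos) {
    stop_("verified screen-positives exceed the screen-positive total")
  }
  if (vn_dpos + vn_dneg > n_screen_neg) {
    stop_("verified screen-negatives exceed the screen-negative total")
  }
  structure(list(n_screen_pos = n_screen_pos, n_screen_neg = n_screen_neg,
                 vp_dpos = vp_dpos, vp_dneg = vp_dneg,
                 vn_dpos = vn_dpos, vn_dneg = vn_dneg),
            class = "verification_counts")
}

.bg_point <- function(p1, p0, w1) {
  w0 <- 1 - w1
  se <- p1 * w1 / (p1 * w1 + p0 * w0)
  sp <- (1 - p0) * w0 / ((1 - p0) * w0 + (1 - p1) * w1)
  c(sensitivity = se, specificity = sp)
}

#' Verification-bias-adjusted sensitivity and specificity (Begg-Greenes)
#'
#' In a screen-dependent verification design -- all screen-positives verified
#' by the gold standard but only a sample of screen-negatives -- the naive
#' estimates computed from verified subjects alone are biased (sensitivity
#' upward). Assuming verification depends only on the screen result, the
#' Begg-Greenes correction reweights the verified disease rates by the
#' population screen fractions: with `p1 = P(D+|screen+)` and
#' `p0 = P(D+|screen-)` estimated from the verified strata and
#' `w1 = P(screen+)` from the population totals,
#' `Se = p1*w1 / (p1*w1 + p0*w0)` and
#' `Sp = (1-p0)*w0 / ((1-p0)*w0 + (1-p1)*w1)`. Under complete verification
#' the correction reduces exactly to the naive estimator.
#'
#' Intervals are by nonparametric bootstrap over verified subjects
#' (resampling within each screen stratum; percentile bounds), since no
#' closed-form interval is assumed.
#'
#' @param v [verification_counts()].
#' @param bootstrap number of bootstrap replicates (0 = no interval).
#' @param conf.level confidence level for bootstrap percentile intervals.
#' @param seed optional integer seed for the bootstrap.
#' @return list with `sensitivity`, `specificity`, optional `se_ci`/`sp_ci`,
#'   the naive verified-only estimates (`naive_sensitivity`,
#'   `naive_specificity`), and the stratum quantities `p1`, `p0`, `w1`.
#' @export
begg_greenes <- function(v, bootstrap = 0, conf.level = 0.95, seed = NULL) {
  stopifnot(inherits(v, "verification_counts"))
  n1 <- v$vp_dpos + v$vp_dneg
  n0 <- v$vn_dpos + v$vn_dneg
  if (n1 == 0) stop_("no verified subjects in the screen-positive stratum")
  if (n0 == 0) stop_("no verified subjects in the screen-negative stratum")
  p1 <- v$vp_dpos / n1
  p0 <- v$vn_dpos / n0
  w1 <- v$n_screen_pos / (v$n_screen_pos + v$n_screen_neg)
  adj <- .bg_point(p1, p0, w1)

  # naive estimator: treat the verified subset as if it were the population
  naive <- sensitivity_specificity(
    confusion_table(a = v$vp_dpos, b = v$vp_dneg, c = v$vn_dpos, d = v$vn_dneg))

  out <- list(sensitivity = unname(adj["sensitivity"]),
              specificity = unname(adj["specificity"]),
              naive_sensitivity = naive$sensitivity,
              naive_specificity = naive$specificity,
              p1 = p1, p0 = p0, w1 = w1)
  if (bootstrap > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    b1 <- stats::rbinom(bootstrap, n1, p1) / n1
    b0 <- stats::rbinom(bootstrap, n0, p0) / n0
    se_b <- b1 * w1 / (b1 * w1 + b0 * (1 - w1))
    sp_b <- (1 - b0) * (1 - w1) / ((1 - b0) * (1 - w1) + (1 - b1) * w1)
    alpha <- 1 - conf.level
    out$se_ci <- unname(stats::quantile(se_b, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
    out$sp_ci <- unname(stats::quantile(sp_b, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
    out$bootstrap <- bootstrap
  }
  out
}
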