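#' Case fraction implied by a case:control ratio
#'
#' In a controlled-sampling design the case:control ratio fixes the apparent
#' prevalence of the condition in the sample:
#' `n_cases / n_controls = prevalence / (1 - prevalence)`.
#'
#' @param n_cases,n_controls positive counts.
#' @return `n_cases / (n_cases + n_controls)`.
#' @export
#' @examples
#' implied_prevalence(75, 225) # 0.25
implied_prevalence <- function(n_cases, n_controls) {
  if (n_cases <= 0 || n_controls <= 0) stop_("case and control counts must be positive")
  n_cases / (n_cases + n_controls)
}

#' Precision-target specification for a nested case-control validation
#'
#' @param target_se,target_sp anticipated sensitivity and specificity.
#' @param margin_se,margin_sp desired half-widths of the confidence
#'   intervals.
#' @param alpha two-sided type-I error.
#' @param ratio controls per case (1:k design).
#' @return object of class `design_spec`.
#' @export
design_spec <- function(target_se = 0.95, target_sp = 0.85,
                        margin_se = 0.05, margin_sp = 0.15,
                        alpha = 0.05, ratio = 3) {
  props <- c(target_se, target_sp, margin_se, margin_sp, alpha)
  if (any(props <= 0) || any(props >= 1)) stop_("proportions must lie in (0, 1)")
  if (ratio < 1 || ratio != round(ratio)) stop_("ratio must be a positive integer")
  structure(list(target_se = target_se, target_sp = target_sp,
                 margin_se = margin_se, margin_sp = margin_sp,
                 alpha = alpha, ratio = as.integer(ratio),
                 design_prevalence = 1 / (1 + ratio)),
            class = "design_spec")
}

#' Required sample size for sensitivity/specificity precision targets
#'
#' Normal-approximation precision formula per arm:
#' `n = ceil(z^2 * p * (1 - p) / margin^2)` with `z` the two-sided
#' `1 - alpha/2` normal quantile; cases carry the sensitivity arm, controls
#' the specificity arm. The total enrolment is whichever arm is binding
#' after inflating by the design case fraction.
#'
#' @param spec [design_spec()].
#' @return list with `n_cases`, `n_controls`, `n_total`.
#' @export
#' @examples
#' required_sample(design_spec()) # 73 cases, 292 total at a 1:3 ratio
required_sample <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  z <- stats::qnorm(1 - spec$alpha / 2)
  arm <- function(p, margin) {
    if (margin >= min(p, 1 - p)) {
      warning(sprintf("margin %.2f >= min(p, 1-p) = %.2f: interval degenerate",
                      margin, min(p, 1 - p)), call. = FALSE)
    }
    ceiling(z^2 * p * (1 - p) / margin^2)
  }
  n_cases <- arm(spec$target_se, spec$margin_se)
  n_controls <- arm(spec$target_sp, spec$margin_sp)
  d <- spec$design_prevalence
  n_total <- max(ceiling(n_cases / d), ceiling(n_controls / (1 - d)))
  list(n_cases = n_cases, n_controls = n_controls, n_total = n_total)
}

#' Expected gold-standard prevalence in a screen-based case-control sample
#'
#' Cases are screen-positives and controls screen-negatives, so with an
#' imperfect screen the gold-standard-positive fraction of the sample is
#' `design_prevalence * PPV + (1 - design_prevalence) * (1 - NPV)`, with PPV
#' and NPV from Bayes' rule at the population prevalence. With a perfect
#' screen this returns the design prevalence; an imperfect screen at low
#' population prevalence dilutes it below the design value.
#'
#' @param se,sp screen sensitivity and specificity.
#' @param design_prevalence case fraction fixed by the sampling ratio.
#' @param population_prevalence true condition prevalence in the
#'   surveillance population.
#' @return expected gold-standard-positive fraction of the sample.
#' @export
#' @examples
#' expected_sample_prevalence(0.82, 0.90, 0.25, 0.05) # well below 0.25
expected_sample_prevalence <- function(se, sp, design_prevalence,
                                       population_prevalence) {
  v <- c(se, sp, design_prevalence, population_prevalence)
  if (any(v <= 0) || any(v >= 1)) stop_("all arguments must lie in (0, 1)")
  pi <- population_prevalence
  ppv <- se * pi / (se * pi + (1 - sp) * (1 - pi))
  npv <- sp * (1 - pi) / (sp * (1 - pi) + (1 - se) * pi)
  design_prevalence * ppv + (1 - design_prevalence) * (1 - npv)
}
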