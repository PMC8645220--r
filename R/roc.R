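#' Empirical ROC curve and AUROC for an ordinal screening score
#'
#' Threshold sweep over the observed score values: each point is
#' (1 - specificity, sensitivity) of the rule "positive if score >= t". The
#' area under the curve is computed by the trapezoid rule, which for a single
#' binary threshold reduces to `(Se + Sp) / 2`. A typical score here is the
#' count of positive sepsis-algorithm criteria (fever signal, pain,
#' discharge), but any ordinal works, and AUROC is invariant to strictly
#' monotone transforms of the score.
#'
#' @param truth logical (or 0/1) gold-standard status, one per subject.
#' @param score numeric or ordinal score, higher = more suspicious.
#' @return object of class `roc_curve`: data frame `points` with columns
#'   `fpr`, `tpr`, `threshold`, and scalar `auroc`.
#' @export
#' @examples
#' roc_curve(c(TRUE, TRUE, FALSE, FALSE), c(2, 1, 1, 0))$auroc
roc_curve <- function(truth, score) {
  truth <- as.logical(truth)
  stopifnot(length(truth) == length(score), !anyNA(truth), !anyNA(score))
  npos <- sum(truth)
  nneg <- sum(!truth)
  if (npos == 0 || nneg == 0) {
    stop_("gold standard must contain both positives and negatives")
  }
  thr <- sort(unique(as.numeric(score)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(truth & score >= t) / npos, 0)
  fpr <- vapply(thr, function(t) sum(!truth & score >= t) / nneg, 0)
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  # trapezoid rule over the sweep (last point is always (1, 1))
  auroc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auroc = auroc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, AUROC = %.3f\n",
              nrow(x$points) - 1, x$auroc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "b", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("AUROC = %.3f", x$auroc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
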