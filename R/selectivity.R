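# Recruitment curves, ROC construction against the worst-case non-target
# branch, AUC selectivity, and the windowed RMSE used to compare predicted
# voltage waveforms between simulation variants.

#' Recruitment curve from fiber thresholds
#'
#' The empirical CDF of the converged thresholds over an amplitude grid:
#' the fraction of fibers whose threshold lies at or below each amplitude.
#' Unconverged (never-activating) fibers are excluded from the
#' denominator and reported.
#'
#' @param thresholds list of \code{threshold_result}
#' @param amplitudes increasing amplitude grid (A)
#' @param branch optional branch label stored in the result
#' @return object of class \code{recruitment_curve}: \code{amplitudes},
#'   \code{fraction_active}, \code{n}, \code{n_unconverged}, \code{branch}
#' @export
recruitment <- function(thresholds, amplitudes, branch = NULL) {
  stopifnot(length(thresholds) > 0, is.numeric(amplitudes),
            !is.unsorted(amplitudes))
  th <- vapply(thresholds, `[[`, numeric(1L), "threshold")
  conv <- vapply(thresholds, `[[`, logical(1L), "converged")
  if (!any(conv)) stop("no converged thresholds")
  if (is.null(branch)) branch <- thresholds[[1L]]$branch
  thc <- th[conv]
  frac <- vapply(amplitudes, function(a) mean(thc <= a), numeric(1L))
  structure(list(amplitudes = amplitudes, fraction_active = frac,
                 n = sum(conv), n_unconverged = sum(!conv),
                 branch = branch),
            class = "recruitment_curve")
}

#' ROC points of target versus worst-case non-target recruitment
#'
#' At each stimulus amplitude the true positive rate is the target
#' recruitment fraction and the false positive rate the maximum
#' recruitment fraction over all non-target branches (the worst-case
#' branch). All curves must share one amplitude grid.
#'
#' @param target a [recruitment()] curve for the target branch
#' @param nontargets list of [recruitment()] curves
#' @return object of class \code{roc_result}: \code{fpr}, \code{tpr}
#'   ordered by amplitude, \code{amplitudes}, \code{auc},
#'   \code{worst_case_branch}
#' @export
roc_points <- function(target, nontargets) {
  stopifnot(inherits(target, "recruitment_curve"), length(nontargets) > 0)
  for (nt in nontargets) {
    if (length(nt$amplitudes) != length(target$amplitudes) ||
        any(nt$amplitudes != target$amplitudes))
      stop("all curves must share the amplitude grid")
  }
  fmat <- vapply(nontargets, `[[`, numeric(length(target$amplitudes)),
                 "fraction_active")
  fmat <- matrix(fmat, ncol = length(nontargets))
  fpr <- apply(fmat, 1, max)
  # worst case at the final amplitude; ties (e.g. all saturated) broken by
  # the branch that dominates over the whole grid
  final <- fmat[nrow(fmat), ]
  cand <- which(final == max(final))
  worst <- nontargets[[cand[which.max(colMeans(fmat)[cand])]]]$branch
  res <- structure(list(fpr = fpr, tpr = target$fraction_active,
                        amplitudes = target$amplitudes,
                        worst_case_branch = worst),
                   class = "roc_result")
  res$auc <- auc(res)
  res
}

#' Area under an ROC curve
#'
#' Trapezoidal integration of TPR over FPR after sorting by (FPR, TPR),
#' prepending (0, 0) and extending the final point horizontally to
#' FPR = 1; the result is clamped to [0, 1]. A target that saturates
#' before any non-target activates scores 1, a never-active target 0, and
#' identical target and non-target curves score 0.5.
#'
#' @param points a \code{roc_result}, or a list/data frame with
#'   \code{fpr} and \code{tpr}
#' @return AUC in [0, 1]
#' @export
auc <- function(points) {
  fpr <- points$fpr
  tpr <- points$tpr
  o <- order(fpr, tpr)
  x <- c(0, fpr[o], 1)
  y <- c(0, tpr[o], tpr[o][length(o)])
  a <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  min(max(a, 0), 1)
}

#' Windowed RMSE between two voltage waveforms
#'
#' Root mean square difference over the analysis window running from
#' 40 us before stimulus onset to 40 us after the stimulus ends, the
#' window used for all waveform comparisons in this package.
#'
#' @param series_a,series_b voltage series on the common time grid (V)
#' @param times time grid (s)
#' @param onset stimulus onset (s)
#' @param stim_end end of the stimulus (s)
#' @param margin window margin around the stimulus (s), default 40 us
#' @return RMSE in volts
#' @export
rmse_window <- function(series_a, series_b, times, onset, stim_end,
                        margin = 40e-6) {
  stopifnot(length(series_a) == length(series_b),
            length(series_a) == length(times))
  t0 <- onset - margin
  t1 <- stim_end + margin
  if (t0 < min(times) - 1e-12 || t1 > max(times) + 1e-12)
    stop("analysis window outside the series support")
  sel <- times >= t0 - 1e-12 & times <= t1 + 1e-12
  sqrt(mean((series_a[sel] - series_b[sel])^2))
}

#' Default amplitude grid for recruitment analysis
#'
#' 100 logarithmic steps spanning the observed converged-threshold range
#' widened by 20 % on both sides.
#'
#' @param thresholds list of \code{threshold_result} (all branches)
#' @param n grid size
#' @return increasing amplitude vector (A)
#' @export
amplitude_grid <- function(thresholds, n = 100L) {
  th <- vapply(thresholds, `[[`, numeric(1L), "threshold")
  th <- th[is.finite(th)]
  if (length(th) == 0L) stop("no converged thresholds")
  exp(seq(log(min(th) / 1.2), log(max(th) * 1.2), length.out = n))
}
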