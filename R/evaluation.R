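#' Tolerance-windowed detection metrics
#'
#' Scores a detected phase sequence against a reference, one-vs-rest per
#' phase, with a concurrence window centred at each time step (default
#' 60 ms, i.e. +/- 6 samples at 200 Hz). For phase p and sample i:
#' \itemize{
#'   \item test\[i\] = p: TP if the reference carries p anywhere within the
#'     half-window of i, else FP;
#'   \item test\[i\] != p: FN if ref\[i\] = p and the test carries p nowhere
#'     within the half-window, else TN.
#' }
#' Sensitivity = sum TP / (sum TP + sum FN) and specificity =
#' sum TN / (sum TN + sum FP), micro-averaged over the four phases. At
#' window 0 this collapses to the plain per-sample confusion matrix. If
#' neither sequence shows stride activity (no SW-to-HS onset and no SW
#' sample), sensitivity is defined as 1 (the no-stride rule; avoids 0/0
#' on non-walking trials).
#'
#' @param test,ref `phase_sequence`s of equal length and rate.
#' @param window_s full window width in seconds (default 0.060).
#' @return object of class `detection_metrics`: list with `sensitivity`,
#'   `specificity`, `window_s`, `per_phase` (4x4 count matrix with columns
#'   TP, FP, TN, FN), `stride_count_test`, `stride_count_ref`.
#' @export
windowed_metrics <- function(test, ref, window_s = 0.060) {
  stopifnot(inherits(test, "phase_sequence"), inherits(ref, "phase_sequence"))
  if (length(test$labels) != length(ref$labels))
    stop("data error: test and reference differ in length")
  if (test$rate_hz != ref$rate_hz)
    stop("data error: test and reference differ in rate")
  if (window_s < 0) stop("windowed_metrics: window_s must be >= 0")
  n <- length(test$labels)
  h <- round(window_s * test$rate_hz / 2)
  per_phase <- matrix(0, nrow = 4, ncol = 4,
                      dimnames = list(phase_names(), c("TP", "FP", "TN", "FN")))
  for (p in 0:3) {
    tp_mask <- test$labels == p
    rp_mask <- ref$labels == p
    ref_near <- window_any(rp_mask, h)
    test_near <- window_any(tp_mask, h)
    TP <- sum(tp_mask & ref_near)
    FP <- sum(tp_mask & !ref_near)
    FN <- sum(!tp_mask & rp_mask & !test_near)
    TN <- n - TP - FP - FN
    per_phase[p + 1, ] <- c(TP, FP, TN, FN)
  }
  tots <- colSums(per_phase)
  sens <- if ((tots[["TP"]] + tots[["FN"]]) > 0)
    tots[["TP"]] / (tots[["TP"]] + tots[["FN"]]) else NA_real_
  spec <- if ((tots[["TN"]] + tots[["FP"]]) > 0)
    tots[["TN"]] / (tots[["TN"]] + tots[["FP"]]) else NA_real_
  sc_test <- length(segment_cycles(test)$starts)
  sc_ref <- length(segment_cycles(ref)$starts)
  no_stride <- function(ps, onsets)
    onsets == 0 && !any(ps$labels == GAIT_PHASES[["SW"]])
  if (no_stride(test, sc_test) && no_stride(ref, sc_ref)) sens <- 1
  if (is.na(sens)) sens <- 1  # no positives at all in either role
  structure(list(sensitivity = sens, specificity = spec, window_s = window_s,
                 per_phase = per_phase,
                 stride_count_test = sc_test, stride_count_ref = sc_ref),
            class = "detection_metrics")
}

# TRUE at i if mask is TRUE anywhere in [i-h, i+h] (clipped to bounds)
window_any <- function(mask, h) {
  n <- length(mask)
  if (h == 0) return(mask)
  cs <- c(0, cumsum(mask))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) > 0
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("<detection_metrics> window %.0f ms: sensitivity %.4f, specificity %.4f\n",
              x$window_s * 1000, x$sensitivity, x$specificity))
  cat(sprintf("strides: test %d, ref %d\n", x$stride_count_test, x$stride_count_ref))
  invisible(x)
}

#' Tolerance window as a fraction of a step
#'
#' A 60 ms window is 6\% of a one-second-long step: at most one phase
#' transition of a typical gait pattern can fall inside it.
#'
#' @param window_s window width (s).
#' @param step_s step duration (s), > 0.
#' @return `window_s / step_s`.
#' @export
window_fraction_of_step <- function(window_s, step_s) {
  if (step_s <= 0) stop("window_fraction_of_step: step_s must be > 0")
  window_s / step_s
}

#' Percent time spent in each phase
#'
#' @param seq a `phase_sequence`.
#' @return named numeric 4-vector of percentages (sums to 100).
#' @export
percent_time_per_phase <- function(seq) {
  stopifnot(inherits(seq, "phase_sequence"))
  cnt <- tabulate(seq$labels + 1L, nbins = 4)
  out <- 100 * cnt / length(seq$labels)
  names(out) <- phase_names()
  out
}

#' Spearman correlation with t conversion
#'
#' Spearman's rank correlation R (average ranks on ties), converted to a
#' t statistic as t = R sqrt((N - 2) / (1 - R^2)) and tested two-tailed
#' against the t distribution with N - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length N >= 3; neither all-constant.
#' @param alpha significance level (default 0.05).
#' @return list with `R`, `t`, `df`, `p`, `significant`. |R| = 1 gives
#'   t = +/-Inf with p = 0 (significant).
#' @export
spearman_t <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("spearman_t: unequal lengths")
  N <- length(x)
  if (N < 3) stop("spearman_t: need N >= 3")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("undefined-correlation error: constant input")
  R <- stats::cor(x, y, method = "spearman")
  if (abs(R) >= 1 - 1e-15) {
    t <- sign(R) * Inf
    p <- 0
  } else {
    t <- R * sqrt((N - 2) / (1 - R^2))
    p <- 2 * stats::pt(-abs(t), df = N - 2)
  }
  list(R = R, t = t, df = N - 2, p = p, significant = p < alpha)
}
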