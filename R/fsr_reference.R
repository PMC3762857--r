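#' Binarize an FSR voltage channel
#'
#' A sample is "pressed" when its voltage strictly exceeds `threshold`.
#' Short pressed/unpressed runs (chatter around contact transitions) are
#' then debounced: any run strictly shorter than `debounce_s` is merged
#' into its neighbours, shortest runs first, ties resolved in favour of the
#' earlier run.
#'
#' @param fsr a `sampled_signal` of voltages.
#' @param threshold contact threshold in the same units as the signal; if
#'   `NULL`, the midpoint of the 5th and 95th percentile of the observed
#'   voltages (a subject-adaptive default).
#' @param debounce_s minimum run duration in seconds (default 0.020).
#' @return logical vector, `TRUE` = pressed.
#' @export
binarize <- function(fsr, threshold = NULL, debounce_s = 0.020) {
  stopifnot(inherits(fsr, "sampled_signal"))
  if (debounce_s < 0) stop("binarize: debounce_s must be >= 0")
  if (is.null(threshold)) {
    q <- stats::quantile(fsr$values, c(0.05, 0.95), names = FALSE)
    threshold <- mean(q)
  }
  pressed <- fsr$values > threshold
  min_run <- debounce_s * fsr$rate_hz  # runs with length < min_run are removed
  if (min_run <= 1) return(pressed)
  repeat {
    r <- rle(pressed)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_run)
    if (!length(short)) break
    # shortest first, earliest on ties
    k <- short[order(r$lengths[short], short)][1]
    r$values[k] <- !r$values[k]
    pressed <- inverse.rle(r)
  }
  pressed
}

#' Bundle binarized FSR channels
#'
#' @param heel,m1,m5 logical vectors of equal length (pressed = TRUE).
#' @param rate_hz rate of the contact grid (default 200).
#' @return object of class `contact_sequence`.
#' @export
contact_sequence <- function(heel, m1, m5, rate_hz = 200) {
  heel <- as.logical(heel); m1 <- as.logical(m1); m5 <- as.logical(m5)
  if (length(heel) != length(m1) || length(m1) != length(m5))
    stop("contact_sequence: channels must have equal length")
  if (!length(heel)) stop("contact_sequence: empty channels")
  structure(list(heel = heel, m1 = m1, m5 = m5, rate_hz = as.numeric(rate_hz)),
            class = "contact_sequence")
}

#' Label gait phases from foot contacts
#'
#' Per-sample mapping, total over all 8 contact combinations:
#' ST if heel and (m1 or m5); HO if not heel and (m1 or m5);
#' HS if heel and neither metatarsal; SW if nothing is pressed.
#'
#' @param contacts a `contact_sequence`.
#' @return a `phase_sequence` at the contact rate.
#' @export
label_phases <- function(contacts) {
  stopifnot(inherits(contacts, "contact_sequence"))
  toe <- contacts$m1 | contacts$m5
  lab <- ifelse(contacts$heel,
                ifelse(toe, GAIT_PHASES[["ST"]], GAIT_PHASES[["HS"]]),
                ifelse(toe, GAIT_PHASES[["HO"]], GAIT_PHASES[["SW"]]))
  phase_sequence(lab, rate_hz = contacts$rate_hz)
}

#' Partition a phase sequence into gait cycles
#'
#' A cycle begins at each SW-to-HS transition (heel strike). Cycles are the
#' half-open index ranges between consecutive starts; the trailing partial
#' cycle is excluded from per-cycle statistics.
#'
#' @param phases a `phase_sequence`.
#' @return object of class `cycle_segmentation`: list with `starts`
#'   (1-based sample indices of cycle onsets) and `n_cycles` (complete
#'   cycles, `max(0, length(starts) - 1)`).
#' @export
segment_cycles <- function(phases) {
  stopifnot(inherits(phases, "phase_sequence"))
  lab <- phases$labels
  n <- length(lab)
  starts <- integer(0)
  if (n >= 2) {
    i <- 2:n
    starts <- i[lab[i] == GAIT_PHASES[["HS"]] & lab[i - 1] == GAIT_PHASES[["SW"]]]
  }
  structure(list(starts = as.integer(starts),
                 n_cycles = max(0L, length(starts) - 1L)),
            class = "cycle_segmentation")
}

#' Per-cycle phase-time fractions
#'
#' For each complete cycle, the fraction of samples spent in each phase.
#' Each row sums to exactly 1 (sample counts over counts).
#'
#' @param phases a `phase_sequence`.
#' @param seg the `cycle_segmentation` derived from `phases`.
#' @return numeric matrix, one row per complete cycle, columns ST, HO, SW,
#'   HS; zero rows when fewer than two cycle onsets exist.
#' @export
phase_fractions <- function(phases, seg = segment_cycles(phases)) {
  stopifnot(inherits(phases, "phase_sequence"), inherits(seg, "cycle_segmentation"))
  k <- seg$n_cycles
  out <- matrix(numeric(0), nrow = 0, ncol = 4,
                dimnames = list(NULL, phase_names()))
  if (k < 1) return(out)
  out <- matrix(0, nrow = k, ncol = 4, dimnames = list(NULL, phase_names()))
  for (c_i in seq_len(k)) {
    idx <- seg$starts[c_i]:(seg$starts[c_i + 1] - 1L)
    cnt <- tabulate(phases$labels[idx] + 1L, nbins = 4)
    out[c_i, ] <- cnt / sum(cnt)
  }
  out
}

#' Canonical contact pattern for each phase
#'
#' The (heel, m1, m5) pattern used when reconstructing contacts from phase
#' labels: ST = (T,T,F), HO = (F,T,F), SW = (F,F,F), HS = (T,F,F).
#'
#' @param phases a `phase_sequence`.
#' @return a `contact_sequence` with `label_phases()` inverse to it.
#' @export
contacts_from_phases <- function(phases) {
  stopifnot(inherits(phases, "phase_sequence"))
  lab <- phases$labels
  heel <- lab == GAIT_PHASES[["ST"]] | lab == GAIT_PHASES[["HS"]]
  m1 <- lab == GAIT_PHASES[["ST"]] | lab == GAIT_PHASES[["HO"]]
  contact_sequence(heel, m1, rep(FALSE, length(lab)), rate_hz = phases$rate_hz)
}
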