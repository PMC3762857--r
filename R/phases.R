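#' Gait phase codes
#'
#' The four phases of the gait cycle, in cycle order, with integer codes
#' 0--3: stance (ST, whole sole on the floor), heel off (HO, toe contact
#' only), swing (SW, no contact) and heel strike (HS, heel contact only).
#'
#' @format Named integer vector of length 4.
#' @export
GAIT_PHASES <- c(ST = 0L, HO = 1L, SW = 2L, HS = 3L)

#' Phase names in code order
#' @keywords internal
phase_names <- function() names(GAIT_PHASES)

#' Construct a per-sample gait-phase sequence
#'
#' @param labels integer vector of phase codes in 0..3, or a character
#'   vector of phase names ("ST", "HO", "SW", "HS").
#' @param rate_hz sampling rate of the label grid in Hz (default 200, the
#'   common 5 ms processing grid).
#' @return An object of class `phase_sequence`: a list with `labels`
#'   (integer codes) and `rate_hz`.
#' @export
phase_sequence <- function(labels, rate_hz = 200) {
  if (is.character(labels)) {
    idx <- match(labels, phase_names())
    if (anyNA(idx)) stop("unknown phase name: ", paste(unique(labels[is.na(idx)]), collapse = ", "))
    labels <- idx - 1L
  }
  labels <- as.integer(labels)
  if (length(labels) < 1) stop("phase_sequence: labels must be non-empty")
  if (anyNA(labels) || any(labels < 0L | labels > 3L))
    stop("phase_sequence: labels must be integer codes in 0..3")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("phase_sequence: rate_hz must be positive")
  structure(list(labels = labels, rate_hz = as.numeric(rate_hz)),
            class = "phase_sequence")
}

#' @export
length.phase_sequence <- function(x) length(x$labels)

#' @export
print.phase_sequence <- function(x, ...) {
  tab <- table(factor(phase_names()[x$labels + 1L], levels = phase_names()))
  cat(sprintf("<phase_sequence> %d samples @ %g Hz (%.1f s)\n",
              length(x$labels), x$rate_hz, length(x$labels) / x$rate_hz))
  print(tab)
  invisible(x)
}

#' Write a phase sequence as CSV (time_s, phase_code, phase_name)
#'
#' @param phases a `phase_sequence`.
#' @param path output file path.
#' @export
write_phase_sequence <- function(phases, path) {
  stopifnot(inherits(phases, "phase_sequence"))
  df <- data.frame(
    time_s = (seq_along(phases$labels) - 1L) / phases$rate_hz,
    phase_code = phases$labels,
    phase_name = phase_names()[phases$labels + 1L]
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.10g", phases$rate_hz), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phase sequence written by [write_phase_sequence()]
#' @param path CSV path.
#' @return a `phase_sequence`.
#' @export
read_phase_sequence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  rate <- 200
  m <- regmatches(hdr, regexpr("rate_hz=[0-9.eE+-]+", hdr))
  if (length(m)) rate <- as.numeric(sub("rate_hz=", "", m[[1]]))
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  phase_sequence(df$phase_code, rate_hz = rate)
}
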