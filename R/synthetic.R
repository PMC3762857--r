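#' Construct a synthetic gait profile
#'
#' A compact description of one simulated subject/leg: cadence, the
#' phase-time split of a typical cycle, swing-peak angular velocity,
#' toe-walking severity (the hallmark of hemiplegic gait: stance time
#' shifting into heel-off as heel contact is reduced), cycle-duration
#' jitter and sensor noise levels.
#'
#' @param cadence_hz strides per second (> 0; slow treadmill gait of
#'   children is around 0.5 strides/s at 1.0 km/h).
#' @param phase_fractions 4-vector (ST, HO, SW, HS) summing to 1 before
#'   severity adjustment.
#' @param peak_swing_velocity peak mid-swing angular velocity in deg/s.
#' @param toe_walking_severity fraction in \[0, 1\]; shifts ST mass into HO:
#'   ST' = ST (1 - severity), HO' = HO + ST severity.
#' @param cycle_jitter_cv coefficient of variation of the (log-normal)
#'   cycle duration.
#' @param gyro_noise_std additive Gaussian noise on the gyro (deg/s).
#' @param fsr_levels list with `pressed`, `unpressed` voltages and
#'   `noise_std`.
#' @param seed integer seed making trial synthesis deterministic.
#' @return object of class `gait_profile`.
#' @export
gait_profile <- function(cadence_hz = 0.5,
                         phase_fractions = c(0.30, 0.30, 0.35, 0.05),
                         peak_swing_velocity = 150,
                         toe_walking_severity = 0,
                         cycle_jitter_cv = 0.03,
                         gyro_noise_std = 5,
                         fsr_levels = list(pressed = 1.0, unpressed = 0.0,
                                           noise_std = 0.02),
                         seed = 1L) {
  phase_fractions <- as.numeric(phase_fractions)
  if (length(phase_fractions) != 4 || any(phase_fractions < 0) ||
      abs(sum(phase_fractions) - 1) > 1e-9)
    stop("gait_profile: phase_fractions must be a non-negative 4-vector summing to 1")
  if (cadence_hz <= 0) stop("gait_profile: cadence_hz must be positive")
  if (toe_walking_severity < 0 || toe_walking_severity > 1)
    stop("gait_profile: toe_walking_severity must lie in [0, 1]")
  if (cycle_jitter_cv < 0) stop("gait_profile: cycle_jitter_cv must be >= 0")
  structure(list(cadence_hz = cadence_hz, phase_fractions = phase_fractions,
                 peak_swing_velocity = peak_swing_velocity,
                 toe_walking_severity = toe_walking_severity,
                 cycle_jitter_cv = cycle_jitter_cv,
                 gyro_noise_std = gyro_noise_std,
                 fsr_levels = fsr_levels, seed = as.integer(seed)),
            class = "gait_profile")
}

#' Severity-adjusted phase fractions
#' @param profile a `gait_profile`.
#' @return 4-vector (ST, HO, SW, HS) summing to 1.
#' @export
effective_fractions <- function(profile) {
  fr <- profile$phase_fractions
  sev <- profile$toe_walking_severity
  c(fr[1] * (1 - sev), fr[2] + fr[1] * sev, fr[3], fr[4])
}

# deterministic 31-bit sub-seed from a seed and a string tag
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "|")
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 131 + code) %% 2147483629
  as.integer(h)
}

# split n samples over 4 phases by largest remainder, keeping cycle length
split_counts <- function(fractions, n) {
  raw <- fractions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  # every phase with positive requested mass must appear at least once
  for (p in which(fractions > 0 & cnt == 0)) {
    donor <- which.max(cnt)
    cnt[donor] <- cnt[donor] - 1
    cnt[p] <- 1
  }
  as.integer(cnt)
}

# raised-cosine lobe amplitudes relative to peak_swing_velocity
LOBE_AMPLITUDES <- c(ST = 0, HO = -0.6, SW = 1.0, HS = -0.25)

#' Generate a synthetic walking trial
#'
#' Builds a ground-truth phase sequence at 200 Hz by concatenating gait
#' cycles (log-normally jittered durations; per-cycle phase splits from
#' the severity-adjusted fractions), then synthesizes the paired sensors:
#' a 50 Hz sagittal gyro made of raised-cosine lobes per cycle (flat
#' stance, negative push-off lobe over HO, dominant positive lobe peaking
#' mid-swing, small negative heel-strike lobe) plus Gaussian noise, and
#' 200 Hz FSR voltages following the canonical per-phase contact patterns
#' plus level noise. Deterministic given the profile's seed.
#'
#' @param profile a `gait_profile`.
#' @param duration_s trial duration in seconds (>= two cycles).
#' @param grid_rate_hz FSR/truth grid rate (default 200).
#' @param gyro_rate_hz gyro rate (default 50).
#' @return object of class `synthetic_trial`: list with `trial`
#'   (a `gait_trial`) and `truth` (a `phase_sequence`).
#' @export
generate_walking <- function(profile, duration_s = 60, grid_rate_hz = 200,
                             gyro_rate_hz = 50) {
  stopifnot(inherits(profile, "gait_profile"))
  if (duration_s < 2 / profile$cadence_hz)
    stop("generate_walking: duration must cover at least two cycles")
  set.seed(profile$seed)
  fr <- effective_fractions(profile)
  mean_dur <- 1 / profile$cadence_hz
  cv <- profile$cycle_jitter_cv
  sigma2 <- log(1 + cv^2)
  n_target <- round(duration_s * grid_rate_hz)

  labels <- integer(0)
  seg_bounds <- list()  # per cycle: cumulative phase boundary samples
  while (length(labels) < n_target) {
    dur <- if (cv > 0)
      stats::rlnorm(1, meanlog = log(mean_dur) - sigma2 / 2, sdlog = sqrt(sigma2))
    else mean_dur
    n_cyc <- max(4L, round(dur * grid_rate_hz))
    cnt <- split_counts(fr, n_cyc)
    seg_bounds[[length(seg_bounds) + 1]] <-
      c(start = length(labels), cumsum(cnt))
    labels <- c(labels, rep(0:3, times = cnt))
  }
  labels <- labels[seq_len(n_target)]
  truth <- phase_sequence(labels, rate_hz = grid_rate_hz)

  # gyro template evaluated at 50 Hz times on the continuous cycle structure
  n_gyro <- floor((n_target - 1) / grid_rate_hz * gyro_rate_hz) + 1
  t_gyro <- (seq_len(n_gyro) - 1) / gyro_rate_hz
  g <- vapply(t_gyro * grid_rate_hz, function(pos) {
    template_velocity(pos, seg_bounds, profile$peak_swing_velocity)
  }, numeric(1))
  g <- g + stats::rnorm(n_gyro, 0, profile$gyro_noise_std)

  trial <- assemble_trial(truth, g, profile, grid_rate_hz, gyro_rate_hz,
                          meta = list(task = "L1.0", kind = "walking"))
  structure(list(trial = trial, truth = truth), class = "synthetic_trial")
}

# velocity at fractional sample position `pos` (0-based, 200 Hz grid units)
template_velocity <- function(pos, seg_bounds, peak) {
  for (sb in seg_bounds) {
    start <- sb[["start"]]
    len <- sb[[5]]  # total cycle samples (last cumulative bound)
    if (pos >= start && pos < start + len) {
      u <- pos - start
      bounds <- c(0, sb[2:5])
      for (p in 1:4) {
        if (u >= bounds[p] && u < bounds[p + 1]) {
          amp <- LOBE_AMPLITUDES[[p]] * peak
          if (amp == 0) return(0)
          frac <- (u - bounds[p]) / (bounds[p + 1] - bounds[p])
          return(amp * sin(pi * frac)^2)
        }
      }
      return(0)
    }
  }
  0
}

# build FSR voltage channels from truth + noise and wrap everything
assemble_trial <- function(truth, gyro_values, profile, grid_rate_hz,
                           gyro_rate_hz, meta) {
  lev <- profile$fsr_levels
  contacts <- contacts_from_phases(truth)
  volts <- function(on) {
    v <- ifelse(on, lev$pressed, lev$unpressed)
    if (lev$noise_std > 0) v <- v + stats::rnorm(length(v), 0, lev$noise_std)
    v
  }
  gait_trial(
    gyro = sampled_signal(gyro_values, gyro_rate_hz, 0, "deg/s"),
    fsr_heel = sampled_signal(volts(contacts$heel), grid_rate_hz, 0, "V"),
    fsr_m1 = sampled_signal(volts(contacts$m1), grid_rate_hz, 0, "V"),
    fsr_m5 = sampled_signal(volts(contacts$m5), grid_rate_hz, 0, "V"),
    meta = meta
  )
}

#' Generate a synthetic non-walking trial
#'
#' Tasks: `"S"` (sit-to-stand), `"T"` (toe touch), `"CW"`/`"CCW"` (turning
#' in place with feet sliding on the floor). The truth is predominantly
#' stance (all contacts pressed) with no swing; positive toe-walking
#' severity replaces a matching fraction of stance with heel-off
#' (toe-standing bouts). The gyro carries low-amplitude, low-frequency
#' activity: body sway for S/T, a slow sustained rotation of the task's
#' sign for CW/CCW (CCW is the exact sign mirror of CW at the same seed).
#'
#' @param task one of "S", "T", "CW", "CCW".
#' @param profile a `gait_profile` (severity and noise fields are used).
#' @param duration_s trial duration in seconds.
#' @inheritParams generate_walking
#' @return a `synthetic_trial`.
#' @export
generate_nonwalking <- function(task, profile, duration_s = 30,
                                grid_rate_hz = 200, gyro_rate_hz = 50) {
  stopifnot(inherits(profile, "gait_profile"))
  if (!task %in% c("S", "T", "CW", "CCW"))
    stop("generate_nonwalking: unknown task code: ", task)
  if (duration_s <= 0) stop("generate_nonwalking: duration must be positive")
  # CW/CCW share a random stream so their traces mirror exactly
  base_task <- if (task %in% c("CW", "CCW")) "TURN" else task
  set.seed(derive_seed(profile$seed, "nonwalking", base_task))
  n <- round(duration_s * grid_rate_hz)
  sev <- profile$toe_walking_severity
  labels <- rep(GAIT_PHASES[["ST"]], n)
  if (sev > 0) {
    # toe-standing bouts: within each 2 s epoch, the last sev fraction is HO
    epoch <- 2 * grid_rate_hz
    pos_in_epoch <- (seq_len(n) - 1) %% epoch
    labels[pos_in_epoch >= (1 - sev) * epoch] <- GAIT_PHASES[["HO"]]
  }
  truth <- phase_sequence(labels, rate_hz = grid_rate_hz)

  n_gyro <- floor((n - 1) / grid_rate_hz * gyro_rate_hz) + 1
  t <- (seq_len(n_gyro) - 1) / gyro_rate_hz
  sway_amp <- 6  # deg/s, small against the swing peak
  g <- switch(base_task,
    S = sway_amp * sin(2 * pi * 0.25 * t) * pmin(t / 2, 1),
    T = sway_amp * sin(2 * pi * 0.20 * t),
    TURN = 10 * sin(pi * pmin(t / max(t), 1))  # one slow revolution bump
  )
  g <- g + stats::rnorm(n_gyro, 0, profile$gyro_noise_std)
  if (task == "CCW") g <- -g
  trial <- assemble_trial(truth, g, profile, grid_rate_hz, gyro_rate_hz,
                          meta = list(task = task, kind = "nonwalking"))
  structure(list(trial = trial, truth = truth), class = "synthetic_trial")
}

#' Walking-task variants
#'
#' Maps the four treadmill conditions (two speeds x two inclines) onto
#' cadence and swing-peak multipliers applied to a base profile; incline
#' has no separate mechanism.
#'
#' @param profile base `gait_profile` (the subject's L1.0 condition).
#' @param task one of "L1.0", "L1.5", "I1.0", "I1.5".
#' @param repetition integer; distinct repetitions get distinct sub-seeds
#'   (repetition 1 is the training trial, 2 the experimental trial).
#' @return a `gait_profile` for that condition.
#' @export
task_profile <- function(profile, task, repetition = 1) {
  mult <- switch(task,
    "L1.0" = c(cad = 1.00, peak = 1.00),
    "L1.5" = c(cad = 1.15, peak = 1.25),
    "I1.0" = c(cad = 0.95, peak = 0.95),
    "I1.5" = c(cad = 1.10, peak = 1.20),
    stop("task_profile: unknown walking task: ", task))
  p <- profile
  p$cadence_hz <- profile$cadence_hz * mult[["cad"]]
  p$peak_swing_velocity <- profile$peak_swing_velocity * mult[["peak"]]
  p$seed <- derive_seed(profile$seed, "task", task, repetition)
  p
}

#' Generate a synthetic cohort of subject profiles
#'
#' Emulates a study population of typically developing (TD) children and
#' children with hemiplegia (HC): TD profiles sit near typical phase
#' fractions with zero toe-walking severity; HC profiles draw severity
#' uniformly from \[0.2, 0.8\], walk with slower cadence, lower swing peak
#' and higher cycle jitter. Per-subject sub-seeds derive deterministically
#' from `seed`.
#'
#' @param n_td,n_hc subject counts (>= 0).
#' @param seed integer master seed.
#' @return list of `gait_profile`s with elements named `TD01..` / `HC01..`;
#'   each profile carries `$group` ("TD"/"HC") and `$subject`.
#' @export
generate_cohort <- function(n_td = 10, n_hc = 10, seed = 1L) {
  set.seed(derive_seed(seed, "cohort"))
  profiles <- list()
  mk <- function(group, i) {
    id <- sprintf("%s%02d", group, i)
    if (group == "TD") {
      sev <- 0
      cad <- stats::rnorm(1, 0.50, 0.04)
      jit <- 0.03
      peak <- stats::rnorm(1, 150, 15)
    } else {
      sev <- stats::runif(1, 0.2, 0.8)
      cad <- stats::rnorm(1, 0.42, 0.05)
      jit <- 0.08
      peak <- stats::rnorm(1, 120, 15)
    }
    fr <- c(0.30, 0.30, 0.35, 0.05) + stats::rnorm(4, 0, 0.01)
    fr <- pmax(fr, 0.02); fr <- fr / sum(fr)
    p <- gait_profile(cadence_hz = max(cad, 0.2), phase_fractions = fr,
                      peak_swing_velocity = max(peak, 60),
                      toe_walking_severity = sev, cycle_jitter_cv = jit,
                      seed = derive_seed(seed, "subject", id))
    p$group <- group
    p$subject <- id
    p
  }
  for (i in seq_len(n_td)) profiles[[sprintf("TD%02d", i)]] <- mk("TD", i)
  for (i in seq_len(n_hc)) profiles[[sprintf("HC%02d", i)]] <- mk("HC", i)
  profiles
}
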