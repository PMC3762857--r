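#' Synthetic cohort benchmark of the two decoders
#'
#' Runs the full study protocol on a synthetic cohort: for each subject a
#' dedicated training trial (L1.0 condition, repetition 1) is labelled by
#' the FSR reference and used to train that subject's model; experimental
#' trials (repetition 2) of the four walking tasks are decoded offline
#' with Viterbi and scored against the FSR reference (A_OL benchmark),
#' and with the forward algorithm scored against the Viterbi output
#' (A_RT-vs-A_OL benchmark); the four non-walking tasks are scored the
#' same way. Both decoders read the same zero-phase-treated signal, as in
#' the protocol the benchmark emulates (the gyro is filtered once before
#' analysis); the strictly causal streaming variant lives in
#' [cmd_detect()] `mode = "realtime"`.
#'
#' @param seed master seed for the cohort and all trials.
#' @param n_td,n_hc group sizes (default 10 + 10).
#' @param walking_s,nonwalking_s trial durations in seconds (defaults 60
#'   and 30).
#' @param config from [run_config()].
#' @param progress print one line per subject.
#' @return data.frame with one row per (subject, task, comparison):
#'   columns subject, group, task, kind ("walking"/"nonwalking"),
#'   comparison ("AOL_vs_FSR" or "ART_vs_AOL"), sensitivity, specificity.
#' @export
cohort_benchmark <- function(seed = 1L, n_td = 10, n_hc = 10,
                             walking_s = 60, nonwalking_s = 30,
                             config = run_config(), progress = FALSE) {
  cohort <- generate_cohort(n_td, n_hc, seed = seed)
  walking <- c("L1.0", "L1.5", "I1.0", "I1.5")
  nonwalking <- c("S", "T", "CW", "CCW")
  rows <- list()
  for (id in names(cohort)) {
    prof <- cohort[[id]]
    if (progress) message("subject ", id, " (severity ",
                          round(prof$toe_walking_severity, 2), ")")
    train_trial <- generate_walking(task_profile(prof, "L1.0", repetition = 1),
                                    walking_s)
    ref_tr <- reference_phases(train_trial$trial, config)
    obs_tr <- preprocess_gyro(train_trial$trial, config, "zero_phase")
    n <- min(length(obs_tr$values), length(ref_tr$labels))
    model <- train_gait_hmm(
      training_set(obs_tr$values[seq_len(n)],
                   phase_sequence(ref_tr$labels[seq_len(n)], ref_tr$rate_hz)),
      std_floor = config$std_floor,
      transition_floor = config$transition_floor,
      transitions = config$transitions)
    score <- function(st, task, kind) {
      obs <- preprocess_gyro(st$trial, config, "zero_phase")$values
      vit <- viterbi_decode(model, obs)
      fwd <- forward_decode(model, obs)
      ref <- reference_phases(st$trial, config)
      n <- min(length(vit$labels), length(ref$labels))
      trim <- function(p) phase_sequence(p$labels[seq_len(n)], p$rate_hz)
      m_ol <- windowed_metrics(trim(vit), trim(ref), config$window_s)
      m_rt <- windowed_metrics(fwd, vit, config$window_s)
      list(
        data.frame(subject = id, group = prof$group, task = task, kind = kind,
                   comparison = "AOL_vs_FSR", sensitivity = m_ol$sensitivity,
                   specificity = m_ol$specificity),
        data.frame(subject = id, group = prof$group, task = task, kind = kind,
                   comparison = "ART_vs_AOL", sensitivity = m_rt$sensitivity,
                   specificity = m_rt$specificity))
    }
    for (task in walking) {
      st <- generate_walking(task_profile(prof, task, repetition = 2), walking_s)
      rows <- c(rows, score(st, task, "walking"))
    }
    for (task in nonwalking) {
      st <- generate_nonwalking(task, prof, nonwalking_s)
      rows <- c(rows, score(st, task, "nonwalking"))
    }
  }
  do.call(rbind, rows)
}

#' Minimum group-mean metric for a benchmark slice
#'
#' Averages sensitivity and specificity per (group, task) and returns the
#' minimum over tasks, groups and the two metrics — the quantity compared
#' against the published lower bounds.
#'
#' @param rows output of [cohort_benchmark()].
#' @param comparison "AOL_vs_FSR" or "ART_vs_AOL".
#' @param kind "walking" or "nonwalking".
#' @return a single number.
#' @export
benchmark_floor <- function(rows, comparison, kind) {
  sel <- rows[rows$comparison == comparison & rows$kind == kind, ]
  if (!nrow(sel)) stop("benchmark_floor: empty selection")
  agg <- stats::aggregate(sel[c("sensitivity", "specificity")],
                          by = list(group = sel$group, task = sel$task), mean)
  min(agg$sensitivity, agg$specificity)
}
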