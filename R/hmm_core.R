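#' Construct a four-state left-right gait HMM
#'
#' States are the gait phases in cycle order ST, HO, SW, HS. Transitions
#' are cyclic left-right: from state i only i itself or the next phase
#' (i+1 mod 4) has nonzero probability. Emissions are scalar Gaussians on
#' the low-pass-filtered sagittal angular velocity (deg/s).
#'
#' @param pi initial state distribution (length 4, sums to 1).
#' @param A 4x4 row-stochastic transition matrix on the cyclic left-right
#'   support.
#' @param means,stds per-state emission mean and standard deviation (deg/s);
#'   `stds` must all be >= `std_floor`.
#' @param rate_hz grid rate the model was trained at (default 200).
#' @param std_floor minimum admissible emission standard deviation.
#' @param filter filter settings recorded for provenance (list with
#'   `cutoff_hz`, `order`, `mode`).
#' @return object of class `gait_hmm`.
#' @export
gait_hmm <- function(pi, A, means, stds, rate_hz = 200, std_floor = 0.5,
                     filter = list(cutoff_hz = 15, order = 4, mode = "zero_phase")) {
  pi <- as.numeric(pi); A <- matrix(as.numeric(A), 4, 4)
  means <- as.numeric(means); stds <- as.numeric(stds)
  if (length(pi) != 4 || abs(sum(pi) - 1) > 1e-12 || any(pi < 0))
    stop("gait_hmm: pi must be a 4-vector of non-negative entries summing to 1")
  if (any(abs(rowSums(A) - 1) > 1e-12) || any(A < 0))
    stop("gait_hmm: rows of A must sum to 1 with non-negative entries")
  off <- !left_right_support()
  if (any(A[off] != 0))
    stop("gait_hmm: A has mass outside the cyclic left-right support")
  if (length(means) != 4 || length(stds) != 4)
    stop("gait_hmm: need 4 emission means and stds")
  if (any(stds < std_floor) || std_floor <= 0)
    stop("gait_hmm: emission stds must be >= std_floor > 0")
  structure(list(pi = pi, A = A, means = means, stds = stds,
                 rate_hz = as.numeric(rate_hz), std_floor = std_floor,
                 filter = filter),
            class = "gait_hmm")
}

#' Cyclic left-right support mask (TRUE where transitions are allowed)
#' @keywords internal
left_right_support <- function() {
  m <- diag(4) == 1
  nxt <- c(2, 3, 4, 1)
  m[cbind(1:4, nxt)] <- TRUE
  m
}

#' @export
print.gait_hmm <- function(x, ...) {
  cat("<gait_hmm> 4-state cyclic left-right model @", x$rate_hz, "Hz\n")
  A <- x$A; dimnames(A) <- list(phase_names(), phase_names())
  print(round(A, 4))
  cat("emission means:", sprintf("%.2f", x$means), "deg/s\n")
  cat("emission stds: ", sprintf("%.2f", x$stds), "deg/s\n")
  invisible(x)
}

#' Assemble a supervised training set
#'
#' @param observations filtered angular velocity (deg/s) on the processing
#'   grid.
#' @param labels `phase_sequence` of equal length (the FSR reference).
#' @param cycle_fractions optional per-cycle phase-fraction matrix from
#'   [phase_fractions()] (used by the duration-based transition mode).
#' @return object of class `training_set`.
#' @export
training_set <- function(observations, labels, cycle_fractions = NULL) {
  stopifnot(inherits(labels, "phase_sequence"))
  observations <- as.numeric(observations)
  if (length(observations) != length(labels$labels))
    stop("training_set: observations and labels differ in length")
  if (is.null(cycle_fractions))
    cycle_fractions <- phase_fractions(labels)
  structure(list(observations = observations, labels = labels,
                 cycle_fractions = cycle_fractions),
            class = "training_set")
}

#' Train the gait HMM from one FSR-labelled trial
#'
#' Fully supervised, no operator intervention and no iterative
#' re-estimation: the transition matrix is the count MLE over consecutive
#' label pairs masked to the cyclic left-right support (permitted but
#' unobserved transitions receive `transition_floor` before row
#' renormalization); the initial distribution is fixed uniform; each
#' state's emission is the sample mean and standard deviation of the
#' observations carrying that label, with the standard deviation clamped
#' to `std_floor`.
#'
#' `transitions = "duration"` instead sets each self-transition from the
#' mean phase duration d_i (seconds) as a_ii = 1 - 1/(d_i * rate), with the
#' remaining mass on the advance transition.
#'
#' @param ts a `training_set`.
#' @param std_floor minimum emission standard deviation in deg/s
#'   (default 0.5).
#' @param transition_floor probability given to permitted-but-unobserved
#'   transitions (default 1e-6).
#' @param transitions "counts" (default) or "duration".
#' @return a `gait_hmm`.
#' @export
train_gait_hmm <- function(ts, std_floor = 0.5, transition_floor = 1e-6,
                           transitions = c("counts", "duration")) {
  stopifnot(inherits(ts, "training_set"))
  transitions <- match.arg(transitions)
  lab <- ts$labels$labels
  present <- sort(unique(lab))
  absent <- setdiff(0:3, present)
  if (length(absent))
    stop("training error: phase(s) absent from labels: ",
         paste(phase_names()[absent + 1L], collapse = ", "))
  support <- left_right_support()
  if (transitions == "counts") {
    counts <- matrix(0, 4, 4)
    if (length(lab) >= 2) {
      tab <- table(factor(lab[-length(lab)], levels = 0:3),
                   factor(lab[-1], levels = 0:3))
      counts <- matrix(as.numeric(tab), 4, 4)
    }
    counts[!support] <- 0
    counts[support & counts == 0] <- transition_floor
    A <- counts / rowSums(counts)
  } else {
    fr <- ts$cycle_fractions
    if (!nrow(fr)) stop("training error: duration mode needs at least one complete cycle")
    seg <- segment_cycles(ts$labels)
    cyc_len <- diff(seg$starts)  # samples per complete cycle
    mean_dur <- colMeans(fr * cyc_len) / ts$labels$rate_hz  # seconds per phase
    a_ii <- pmin(pmax(1 - 1 / (mean_dur * ts$labels$rate_hz), 0), 1 - transition_floor)
    A <- matrix(0, 4, 4)
    diag(A) <- a_ii
    A[cbind(1:4, c(2, 3, 4, 1))] <- 1 - a_ii
  }
  means <- stds <- numeric(4)
  for (s in 0:3) {
    xs <- ts$observations[lab == s]
    means[s + 1] <- mean(xs)
    stds[s + 1] <- if (length(xs) > 1) stats::sd(xs) else 0
  }
  stds <- pmax(stds, std_floor)
  gait_hmm(pi = rep(0.25, 4), A = A, means = means, stds = stds,
           rate_hz = ts$labels$rate_hz, std_floor = std_floor)
}

#' Emission log-density
#'
#' Log of the scalar Gaussian density of observation `x` under `state`'s
#' emission parameters.
#'
#' @param model a `gait_hmm`.
#' @param x observation(s) in deg/s.
#' @param state phase code 0..3 or phase name.
#' @return log-density, finite for finite `x`.
#' @export
log_likelihood_obs <- function(model, x, state) {
  stopifnot(inherits(model, "gait_hmm"))
  if (is.character(state)) state <- GAIT_PHASES[[state]]
  s <- as.integer(state) + 1L
  stats::dnorm(x, model$means[s], model$stds[s], log = TRUE)
}

# log emission matrix: T x 4
emission_logs <- function(model, obs) {
  vapply(1:4, function(s) stats::dnorm(obs, model$means[s], model$stds[s], log = TRUE),
         numeric(length(obs)))
}

#' Viterbi decoding (offline, A_OL)
#'
#' The jointly most probable state path under the model, computed in log
#' space. Ties at each backtracking choice are broken toward the lower
#' state code, so decoding is deterministic.
#'
#' @param model a `gait_hmm`.
#' @param obs numeric vector of filtered angular velocity on the model's
#'   grid.
#' @return a `phase_sequence`; attribute `"log_prob"` holds the joint log
#'   probability of the returned path.
#' @export
viterbi_decode <- function(model, obs) {
  stopifnot(inherits(model, "gait_hmm"))
  obs <- as.numeric(obs)
  if (!length(obs)) stop("viterbi_decode: empty observation sequence")
  T_ <- length(obs)
  logA <- log(model$A)
  logB <- matrix(emission_logs(model, obs), nrow = T_)
  delta <- log(model$pi) + logB[1, ]
  psi <- matrix(1L, nrow = T_, ncol = 4)
  if (T_ >= 2) for (t in 2:T_) {
    cand <- delta + logA  # cand[i, j] = delta[i] + logA[i, j]
    # which.max returns the first (lowest-code) maximiser: tie-break rule
    psi[t, ] <- apply(cand, 2, which.max)
    delta <- cand[cbind(psi[t, ], 1:4)] + logB[t, ]
  }
  path <- integer(T_)
  path[T_] <- which.max(delta)
  if (T_ >= 2) for (t in (T_ - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  out <- phase_sequence(path - 1L, rate_hz = model$rate_hz)
  attr(out, "log_prob") <- max(delta)
  out
}

#' One causal forward-filter update (A_RT)
#'
#' Computes the filtered posterior after observing `x`, from the previous
#' posterior: proportional to b(x) * (A^T prev), renormalized. Uses no
#' future samples. For the first sample pass `prev_posterior = NULL` (or
#' the model's `pi`): the posterior is then proportional to pi * b(x).
#'
#' @param model a `gait_hmm`.
#' @param prev_posterior previous filtered posterior (4-vector summing to
#'   1), or `NULL` at stream start.
#' @param x one observation (deg/s).
#' @return 4-vector posterior summing to 1.
#' @export
forward_step <- function(model, prev_posterior, x) {
  stopifnot(inherits(model, "gait_hmm"))
  prior <- if (is.null(prev_posterior)) model$pi
           else as.numeric(crossprod(model$A, prev_posterior))
  logw <- log(prior) + stats::dnorm(x, model$means, model$stds, log = TRUE)
  m <- max(logw)
  if (!is.finite(m)) stop("numerical error: forward_step underflow")
  w <- exp(logw - m)
  w / sum(w)
}

#' Forward-algorithm decoding (real time, A_RT)
#'
#' Runs [forward_step()] strictly sample by sample and returns the
#' per-sample argmax of the filtered posterior (ties toward the lower
#' state code). Causal: the decoded state at sample i depends only on
#' samples 1..i, so appending samples never changes earlier output.
#'
#' Because the per-sample argmax is not structurally constrained, the
#' decoded path can in principle break the left-right ordering; such
#' breaks are counted and reported in the `"support_violations"`
#' attribute rather than repaired.
#'
#' @inheritParams viterbi_decode
#' @return a `phase_sequence` with attribute `"support_violations"`.
#' @export
forward_decode <- function(model, obs) {
  stopifnot(inherits(model, "gait_hmm"))
  obs <- as.numeric(obs)
  if (!length(obs)) stop("forward_decode: empty observation sequence")
  T_ <- length(obs)
  path <- integer(T_)
  post <- NULL
  for (t in seq_len(T_)) {
    post <- forward_step(model, post, obs[t])
    path[t] <- which.max(post)
  }
  out <- phase_sequence(path - 1L, rate_hz = model$rate_hz)
  if (T_ >= 2) {
    i <- path[-T_] - 1L; j <- path[-1] - 1L
    attr(out, "support_violations") <- sum(j != i & j != (i + 1L) %% 4L)
  } else attr(out, "support_violations") <- 0L
  out
}

#' Save a gait HMM as JSON / load it back
#'
#' The JSON schema is versioned and stores all fields at full precision;
#' a round trip is lossless and loading re-checks all model invariants.
#'
#' @param model a `gait_hmm`.
#' @param path JSON file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gait_hmm"))
  obj <- list(
    schema = "gaitphase-hmm-v1",
    states = phase_names(),
    pi = model$pi,
    A = apply(model$A, 1, identity, simplify = FALSE),
    emissions = lapply(1:4, function(i) list(mean = model$means[i], std = model$stds[i])),
    rate_hz = model$rate_hz,
    std_floor = model$std_floor,
    filter = model$filter
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns a validated `gait_hmm`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model-file error: file not found: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("model-file error: malformed JSON: ",
                                           conditionMessage(e)))
  if (is.null(obj$schema) || !startsWith(obj$schema, "gaitphase-hmm"))
    stop("model-file error: missing or unknown schema tag")
  A <- if (is.matrix(obj$A)) obj$A else do.call(rbind, lapply(obj$A, as.numeric))
  em <- obj$emissions
  tryCatch(
    gait_hmm(pi = obj$pi, A = A, means = em$mean, stds = em$std,
             rate_hz = obj$rate_hz, std_floor = obj$std_floor,
             filter = as.list(obj$filter)),
    error = function(e) stop("model-file error: ", conditionMessage(e)))
}
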