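# shared fixture builders (all data built in code, no files)

# the 3-repetition training pattern: (ST x10, HO x10, SW x10, HS x5) x3
pattern_3rep <- function() {
  one <- rep(c(0L, 1L, 2L, 3L), times = c(10, 10, 10, 5))
  phase_sequence(rep(one, 3), rate_hz = 200)
}

# a random cyclic left-right gait HMM (valid invariants)
random_gait_hmm <- function() {
  self <- stats::runif(4, 0.2, 0.95)
  A <- matrix(0, 4, 4)
  diag(A) <- self
  A[cbind(1:4, c(2, 3, 4, 1))] <- 1 - self
  pi <- stats::runif(4); pi <- pi / sum(pi)
  means <- stats::rnorm(4, 0, 30)
  stds <- stats::runif(4, 0.5, 20)
  gait_hmm(pi = pi, A = A, means = means, stds = stds)
}

# observations drawn exactly at per-state means for a given label path
obs_at_means <- function(model, labels) model$means[labels + 1L]

# a clean separable model: means >= 6 std apart
separable_model <- function() {
  gait_hmm(pi = rep(0.25, 4),
           A = matrix(c(0.9, 0.1, 0, 0,
                        0, 0.9, 0.1, 0,
                        0, 0, 0.9, 0.1,
                        0.1, 0, 0, 0.9), 4, 4, byrow = TRUE),
           means = c(0, 60, 120, 180), stds = rep(5, 4))
}
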