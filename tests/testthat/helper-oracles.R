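# independent brute-force oracles; deliberately naive, no code shared with R/

# enumerate all 4^T state paths; return the max-probability path under the
# same tie-break (lowest code wins = first in lexicographic enumeration
# with state 0 varying slowest ... use explicit ordering below)
oracle_viterbi <- function(model, obs) {
  T_ <- length(obs)
  grid <- as.matrix(do.call(expand.grid, rev(replicate(T_, 1:4, simplify = FALSE))))
  grid <- grid[, rev(seq_len(T_)), drop = FALSE]  # column t = state at time t
  logp <- log(model$pi[grid[, 1]]) +
    dnorm(obs[1], model$means[grid[, 1]], model$stds[grid[, 1]], log = TRUE)
  if (T_ >= 2) for (t in 2:T_) {
    logp <- logp + log(model$A[cbind(grid[, t - 1], grid[, t])]) +
      dnorm(obs[t], model$means[grid[, t]], model$stds[grid[, t]], log = TRUE)
  }
  # lexicographically smallest maximiser = the lowest-code tie-break at
  # every position; order rows lexicographically and take the first max
  ord <- do.call(order, as.data.frame(grid))
  grid <- grid[ord, , drop = FALSE]
  logp <- logp[ord]
  best <- which.max(logp)
  list(path = as.integer(grid[best, ]) - 1L, log_prob = logp[best])
}

# naive unscaled forward recursion in probability space
oracle_forward_posteriors <- function(model, obs) {
  T_ <- length(obs)
  alpha <- matrix(0, T_, 4)
  for (s in 1:4)
    alpha[1, s] <- model$pi[s] * dnorm(obs[1], model$means[s], model$stds[s])
  if (T_ >= 2) for (t in 2:T_) for (s in 1:4) {
    acc <- 0
    for (r in 1:4) acc <- acc + alpha[t - 1, r] * model$A[r, s]
    alpha[t, s] <- acc * dnorm(obs[t], model$means[s], model$stds[s])
  }
  sweep(alpha, 1, rowSums(alpha), "/")
}

# naive per-sample windowed confusion tally (double loop per phase)
oracle_windowed_counts <- function(test_lab, ref_lab, h) {
  n <- length(test_lab)
  out <- matrix(0, 4, 4, dimnames = list(NULL, c("TP", "FP", "TN", "FN")))
  for (p in 0:3) {
    for (i in seq_len(n)) {
      win <- max(1, i - h):min(n, i + h)
      if (test_lab[i] == p) {
        if (any(ref_lab[win] == p)) out[p + 1, "TP"] <- out[p + 1, "TP"] + 1
        else out[p + 1, "FP"] <- out[p + 1, "FP"] + 1
      } else {
        if (ref_lab[i] == p && !any(test_lab[win] == p))
          out[p + 1, "FN"] <- out[p + 1, "FN"] + 1
        else out[p + 1, "TN"] <- out[p + 1, "TN"] + 1
      }
    }
  }
  out
}

# rank-then-Pearson Spearman oracle (no ties expected in callers)
oracle_spearman <- function(x, y) cor(rank(x), rank(y))
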