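test_that("gait_hmm validates its invariants", {
  m <- separable_model()
  expect_s3_class(m, "gait_hmm")
  bad_A <- m$A; bad_A[1, 3] <- 0.1; bad_A[1, 1] <- 0.8
  expect_error(gait_hmm(m$pi, bad_A, m$means, m$stds), "support")
  expect_error(gait_hmm(c(0.5, 0.5, 0, 0.1), m$A, m$means, m$stds), "sum")
  expect_error(gait_hmm(m$pi, m$A, m$means, c(5, 5, 5, 0.1)), "std")
})

test_that("train counts transitions on the left-right support with a floor", {
  # labels (ST x10, HO x10, SW x10, HS x10, ST): each row 9/10 self, 1/10 advance
  lab <- c(rep(0:3, each = 10), 0L)
  obs <- c(-1, 5, -8, 3)[lab + 1L]  # constant per state
  ts <- training_set(obs, phase_sequence(lab))
  m <- train_gait_hmm(ts, std_floor = 0.5)
  for (i in 1:4) {
    expect_equal(m$A[i, i], 9 / 10)
    expect_equal(m$A[i, (i %% 4) + 1], 1 / 10)
  }
  expect_equal(m$means, c(-1, 5, -8, 3))
  expect_equal(m$stds, rep(0.5, 4))  # zero variance clamps to the floor
  expect_equal(m$pi, rep(0.25, 4))
  # contract: rows sum to 1, off-support entries exactly 0
  expect_equal(rowSums(m$A), rep(1, 4))
  expect_true(all(m$A[!gaitphase:::left_right_support()] == 0))
})

test_that("train errors on an absent phase or length mismatch", {
  expect_error(
    train_gait_hmm(training_set(rnorm(100), phase_sequence(rep(0L, 100)))),
    "HO.*SW.*HS")
  expect_error(training_set(rnorm(5), phase_sequence(rep(0:3, 3))), "length")
})

test_that("unobserved permitted transitions get the transition floor", {
  # HS never advances back to ST inside the label stream
  lab <- c(rep(0L, 5), rep(1L, 5), rep(2L, 5), rep(3L, 5))
  ts <- training_set(rnorm(20), phase_sequence(lab))
  m <- train_gait_hmm(ts, transition_floor = 1e-6)
  expect_gt(m$A[4, 1], 0)
  expect_lt(m$A[4, 1], 1e-5)
  expect_equal(rowSums(m$A), rep(1, 4))
})

test_that("duration-mode training reproduces mean phase durations", {
  lab <- rep(rep(0:3, times = c(40, 30, 25, 5)), 8)  # 100-sample cycles
  ts <- training_set(rnorm(length(lab)), phase_sequence(lab))
  m <- train_gait_hmm(ts, transitions = "duration")
  # a_ii = 1 - 1/(d_i * fs); d_ST = 40 samples -> 0.2 s at 200 Hz
  expect_equal(diag(m$A), 1 - 1 / c(40, 30, 25, 5), tolerance = 1e-9)
  expect_equal(rowSums(m$A), rep(1, 4))
})

test_that("log_likelihood_obs is the scalar Gaussian log-density", {
  m <- gait_hmm(rep(0.25, 4), separable_model()$A,
                means = c(0, 60, 120, 180), stds = c(1, 5, 5, 5))
  expect_equal(log_likelihood_obs(m, 0, 0L), -0.5 * log(2 * pi))
  expect_equal(log_likelihood_obs(m, 2, "ST"), -2 - 0.5 * log(2 * pi))
  # symmetry: equidistant from two equal-std states
  expect_equal(log_likelihood_obs(m, 90, 1L), log_likelihood_obs(m, 90, 2L))
})

test_that("viterbi matches exhaustive path enumeration (oracle, random models)", {
  set.seed(101)
  n_cases <- 60
  for (k in seq_len(n_cases)) {
    m <- random_gait_hmm()
    T_ <- sample(1:8, 1)
    obs <- rnorm(T_, mean = sample(m$means, T_, replace = TRUE), sd = 10)
    got <- viterbi_decode(m, obs)
    want <- oracle_viterbi(m, obs)
    expect_equal(attr(got, "log_prob"), want$log_prob, tolerance = 1e-9)
    expect_identical(got$labels, want$path)
  }
})

test_that("single-observation viterbi maximizes pi * emission", {
  set.seed(3)
  for (k in 1:20) {
    m <- random_gait_hmm()
    x <- rnorm(1, 0, 50)
    got <- viterbi_decode(m, x)$labels
    want <- which.max(log(m$pi) + dnorm(x, m$means, m$stds, log = TRUE)) - 1L
    expect_identical(got, want)
    # T = 1 equivalence of the two decoders under uniform pi
    mu <- gait_hmm(rep(0.25, 4), m$A, m$means, m$stds)
    expect_identical(viterbi_decode(mu, x)$labels, forward_decode(mu, x)$labels)
  }
})

test_that("forward posteriors match the brute-force forward sums", {
  set.seed(202)
  for (k in 1:40) {
    m <- random_gait_hmm()
    T_ <- sample(2:8, 1)
    obs <- rnorm(T_, 0, 40)
    want <- oracle_forward_posteriors(m, obs)
    post <- NULL
    for (t in seq_len(T_)) {
      post <- forward_step(m, post, obs[t])
      expect_equal(post, want[t, ], tolerance = 1e-9)
      expect_equal(sum(post), 1, tolerance = 1e-9)
    }
  }
})

test_that("well-separated means are decoded back to the generating labels", {
  m <- separable_model()  # means 60 apart, stds 5 (>= 6 sd separation)
  lab <- rep(rep(0:3, times = c(30, 30, 35, 10)), 4)
  obs <- obs_at_means(m, lab)
  expect_identical(viterbi_decode(m, obs)$labels, lab)
  expect_identical(forward_decode(m, obs)$labels, lab)
})

test_that("forward_decode is causal", {
  set.seed(77)
  m <- random_gait_hmm()
  obs <- rnorm(60, 0, 30)
  full <- forward_decode(m, c(obs, rnorm(40, 100, 5)))
  prefix <- forward_decode(m, obs)
  expect_identical(full$labels[1:60], prefix$labels)
})

test_that("viterbi output always respects the left-right support", {
  set.seed(55)
  for (k in 1:10) {
    m <- random_gait_hmm()
    lab <- viterbi_decode(m, rnorm(300, 0, 50))$labels
    i <- lab[-300]; j <- lab[-1]
    expect_true(all(j == i | j == (i + 1L) %% 4L))
  }
})

test_that("supervised training recovers known parameters within sampling error", {
  set.seed(404)
  true_m <- separable_model()
  n_ok_A <- 0; n_rep <- 30
  for (rep_i in seq_len(n_rep)) {
    # simulate a labelled path from the true chain, obs from the emissions
    T_ <- 4000
    lab <- integer(T_); lab[1] <- 0L
    for (t in 2:T_) lab[t] <- sample(0:3, 1, prob = true_m$A[lab[t - 1] + 1, ])
    if (length(unique(lab)) < 4) next
    obs <- rnorm(T_, true_m$means[lab + 1], true_m$stds[lab + 1])
    fit <- train_gait_hmm(training_set(obs, phase_sequence(lab)))
    ok <- TRUE
    for (i in 1:4) {
      n_i <- sum(lab[-T_] == i - 1L)
      p <- true_m$A[i, i]
      se <- sqrt(p * (1 - p) / n_i)
      if (abs(fit$A[i, i] - p) > 3 * se + 1e-9) ok <- FALSE
      n_s <- sum(lab == i - 1L)
      if (abs(fit$means[i] - true_m$means[i]) > 3 * true_m$stds[i] / sqrt(n_s))
        ok <- FALSE
    }
    if (ok) n_ok_A <- n_ok_A + 1
  }
  # each replicate checks 8 parameters at 3 sigma; allow a few misses overall
  expect_gte(n_ok_A / n_rep, 0.8)
})

test_that("models survive a JSON round trip and reject tampering", {
  set.seed(8)
  m <- random_gait_hmm()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$pi, m$pi)
  expect_equal(back$A, m$A)
  expect_equal(back$means, m$means)
  expect_equal(back$stds, m$stds)
  expect_equal(back$rate_hz, m$rate_hz)

  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  obj$A[1, 1] <- obj$A[1, 1] - 0.1  # row sum 0.9
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path), "model-file error")
  writeLines("{not json", path)
  expect_error(load_model(path), "model-file error")
  expect_error(load_model(file.path(tempdir(), "missing.json")), "not found")
})

test_that("a round-tripped model decodes identically", {
  st <- generate_walking(gait_profile(seed = 12), 20)
  path <- withr::local_tempfile(fileext = ".json")
  model <- cmd_train(st$trial, path)
  back <- load_model(path)
  obs <- preprocess_gyro(st$trial, run_config(), "zero_phase")$values
  expect_identical(viterbi_decode(model, obs)$labels,
                   viterbi_decode(back, obs)$labels)
})
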