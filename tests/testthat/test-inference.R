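test_that("prior log-odds match the two-state transition ratio", {
  # symmetric chain at p = 1/2 carries no information
  expect_equal(prior_log_odds(0.5, 0.3, 0.3), 0)
  # certain-on previous state: only the on-row survives
  expect_equal(prior_log_odds(1, 0.7, 0.2), log(0.8 / 0.2))
  # direct evaluation
  expect_equal(prior_log_odds(0.8, 0.01, 0.2), log(0.642 / 0.358), tolerance = 1e-12)
  expect_error(prior_log_odds(1.2, 0.1, 0.1), "\\[0, 1\\]")
})

test_that("predicted input excludes the detector's own contribution", {
  Q <- matrix(c(1, 2), 1, 2)
  expect_equal(predicted_input(Q, 0.1, c(0.5, 0.5), 1), 0.1 + 2 * 0.5)
  expect_equal(predicted_input(Q, 0.1, c(0, 0), 1), 0.1)
  # single feature: prediction is the baseline regardless of p
  expect_equal(predicted_input(matrix(3, 4, 1), rep(0.2, 4), 0.9, 1), rep(0.2, 4))
  expect_error(predicted_input(Q, 0.1, c(0.5, 0.5), 3))
})

test_that("evidence log-ratio matches its exact and linearized forms", {
  cfg_exact <- inference_config(use_log1p_exact = TRUE)
  cfg_lin <- inference_config(use_log1p_exact = FALSE)
  # M = 1 worked example: shat = q0 + q2*p2 = 0.5 + 0.5 = 1
  Q <- matrix(c(0.5, 1.0), 1, 2)
  expect_equal(evidence_log_ratio(3, Q, 0.5, c(0.5, 0.5), 1, cfg_exact),
               3 * log(1.5) - 0.5, tolerance = 1e-12)
  expect_equal(evidence_log_ratio(3, Q, 0.5, c(0.5, 0.5), 1, cfg_lin), 1.0)
  # zero observations: both forms give -sum(q_ij)
  Q2 <- matrix(runif(8), 4, 2)
  expect_equal(evidence_log_ratio(rep(0, 4), Q2, 0.1, c(0.3, 0.3), 2, cfg_exact),
               -sum(Q2[, 2]))
  expect_equal(evidence_log_ratio(rep(0, 4), Q2, 0.1, c(0.3, 0.3), 2, cfg_lin),
               -sum(Q2[, 2]))
  # zero predictive field carries no evidence
  Q3 <- cbind(rep(0, 4), runif(4))
  expect_equal(evidence_log_ratio(rpois(4, 2), Q3, 0.1, c(0.5, 0.5), 1, cfg_exact), 0)
})

test_that("firing-rate readout is rectified and cancels perfect predictions", {
  set.seed(42)
  for (rep in 1:100) {
    M <- sample(2:8, 1); N <- sample(2:5, 1)
    Q <- matrix(runif(M * N), M, N)
    q0 <- runif(M, 0.05, 0.5)
    p <- runif(N)
    s <- rpois(M, 3)
    j <- sample(N, 1)
    shat <- predicted_input(Q, q0, p, j)
    # rectified-log-likelihood and divisive predictive-coding forms agree
    f1 <- firing_rate(s, Q, q0, p, j)
    f2 <- max(sum(Q[, j] * (s / shat - 1)), 0)
    expect_equal(f1, f2, tolerance = 1e-12)
  }
  # perfectly predicted input: every synapse cancelled
  Q <- matrix(c(1, 2, 0.5, 1), 2, 2)
  q0 <- c(0.1, 0.1); p <- c(0.4, 0.7)
  s_perfect <- predicted_input(Q, q0, p, 1)
  expect_equal(firing_rate(s_perfect, Q, q0, p, 1), 0)
  # surplus along the detector's own field passes rectification
  expect_gt(firing_rate(s_perfect + Q[, 1], Q, q0, p, 1), 0)
})

test_that("inference trace is logistically consistent and tracks the truth", {
  spec <- fixture_spec(n_features = 5, overlap = 0, duration_s = 50, seed = 7)
  st <- make_spectrogram(spec)
  obs <- sample_observations(st$params, st$traj, seed = 8)
  tr <- run_inference(obs, st$params)
  expect_equal(tr$P, 1 / (1 + exp(-tr$L)))
  expect_true(all(tr$F >= 0))
  on_mean <- mean(tr$P[st$traj$X == 1])
  off_mean <- mean(tr$P[st$traj$X == 0])
  expect_gt(on_mean, off_mean)
  # empty and deterministic cases
  expect_equal(ncol(run_inference(matrix(0, st$params$n_receptors, 0), st$params)$L), 0)
  expect_identical(run_inference(obs, st$params)$L, tr$L)
})

test_that("with no evidence the filter converges to the stationary prior", {
  Q <- matrix(0, 3, 2)
  gp <- generative_params(Q, q0 = 0.5, r_on = 1, r_off = 20, dt = 0.01)
  tr <- run_inference(matrix(0.5, 3, 200), gp)   # Q = 0: prior-only dynamics
  pi0 <- 0.01 / 0.21
  expect_equal(tr$P[, 200], rep(pi0, 2), tolerance = 1e-10)
})

test_that("mean-field filter equals the exact forward filter for N = 1", {
  set.seed(0)
  Q <- matrix(c(0, 0, 2, 3, 1, rep(0, 5)), 10, 1)
  gp <- generative_params(Q, q0 = 0.1, r_on = 1, r_off = 20, dt = 0.01)
  traj <- sample_features(gp, 300, seed = 2)
  obs <- sample_observations(gp, traj, seed = 3)
  expect_equal(max(abs(run_inference(obs, gp)$P - exact_filter_oracle(obs, gp))), 0,
               tolerance = 1e-10)
})

test_that("exact oracle factorizes over disjoint supports and obeys the prior", {
  spec <- fixture_spec(n_channels = 12, n_features = 2, overlap = 0,
                       duration_s = 3, seed = 4)
  Q <- make_pf_set(spec)
  gp <- generative_params(Q, q0 = 0.1, dt = 0.01)
  traj <- sample_features(gp, 300, seed = 5)
  obs <- sample_observations(gp, traj, seed = 6)
  marg <- exact_filter_oracle(obs, gp)
  # product of two independent single-feature filters
  for (j in 1:2) {
    gp1 <- generative_params(Q[, j, drop = FALSE], q0 = 0.1, dt = 0.01)
    expect_equal(marg[j, ], exact_filter_oracle(obs, gp1)[1, ], tolerance = 1e-9)
  }
  # uniform emission: marginals follow the prior chain exactly
  gp0 <- generative_params(matrix(0, 3, 2), q0 = 0.3)
  m0 <- exact_filter_oracle(matrix(1, 3, 50), gp0)
  pr <- rep(gp0$p_on / (gp0$p_on + gp0$p_off), 2)
  for (t in 1:50) {
    expect_equal(m0[, t], pr, tolerance = 1e-12)
    pr <- pr * (1 - gp0$p_off) + (1 - pr) * gp0$p_on
  }
  # enumeration guard
  gp_big <- generative_params(matrix(1, 2, 13), q0 = 0.1)
  expect_error(exact_filter_oracle(matrix(1, 2, 5), gp_big), "guard")
})

test_that("mean-field posterior stays close to exact marginals when PFs overlap", {
  spec <- fixture_spec(n_channels = 16, n_features = 3, overlap = 0.6,
                       duration_s = 3, seed = 9)
  Q <- make_pf_set(spec)
  gp <- generative_params(Q, q0 = 0.1, dt = 0.01)
  traj <- sample_features(gp, 300, seed = 10)
  obs <- sample_observations(gp, traj, seed = 11)
  mf <- run_inference(obs, gp)$P
  ex <- exact_filter_oracle(obs, gp)
  eps <- 1e-12
  kl <- mean(ex * log((ex + eps) / (mf + eps)) +
             (1 - ex) * log((1 - ex + eps) / (1 - mf + eps)))
  expect_true(is.finite(kl))
  expect_lt(kl, 0.3)   # regression bound on this fixture, not a theoretical guarantee
})

test_that("no-inhibition model removes competition between detectors", {
  gp <- two_feature_params()
  # N = 1: both models identical (nothing to explain away)
  gp1 <- generative_params(gp$Q[, 1, drop = FALSE], q0 = 0.1)
  S1 <- matrix(rpois(12 * 100, 1), 12, 100)
  expect_equal(run_inference(S1, gp1)$L, run_no_inhibition(S1, gp1)$L)
  # identical PFs, stimulus = that PF: equal responses without competition
  Qd <- cbind(gp$Q[, 1], gp$Q[, 1])
  gpd <- generative_params(Qd, q0 = 0.1)
  Sd <- matrix(rep(gp$Q[, 1], 50), 12, 50)
  trd <- run_no_inhibition(Sd, gpd)
  expect_equal(trd$F[1, ], trd$F[2, ])
  # explaining away only removes drive: summed no-inhibition rates dominate
  traj <- sample_features(gp, 1000, seed = 12)
  obs <- sample_observations(gp, traj, seed = 13)
  expect_gte(sum(run_no_inhibition(obs, gp)$F), sum(run_inference(obs, gp)$F))
})

test_that("a detector alone on another feature's input is quieter when inhibited", {
  gp <- two_feature_params(q_peak = 2)
  X <- matrix(0L, 2, 400); X[1, ] <- 1L   # feature 1 alone drives the stimulus
  traj <- structure(list(X = X, dt = 0.01), class = "feature_trajectory")
  obs <- sample_observations(gp, traj, seed = 14)
  f_int <- mean(run_inference(obs, gp)$F[2, ])
  f_no <- mean(run_no_inhibition(obs, gp)$F[2, ])
  expect_lt(f_int, f_no)
})

test_that("non-finite inputs are rejected", {
  gp <- two_feature_params()
  expect_error(inference_step(c(Inf, 0), rep(1, 12), gp), "finite")
  expect_error(inference_step(c(0, 0), c(NA, rep(1, 11)), gp), "finite")
})
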