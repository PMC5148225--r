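test_that("parameter validation enforces nonnegativity and rate bounds", {
  expect_error(generative_params(matrix(-1, 2, 1)), "nonnegative")
  expect_error(generative_params(matrix(1, 2, 1), r_on = -0.1), "rates")
  gp <- generative_params(matrix(1, 2, 1), q0 = 0)
  expect_true(all(gp$q0 >= 1e-6))  # baseline floor keeps likelihood ratios finite
  # rates in Hz are converted to per-bin probabilities, capped at 1
  gp2 <- generative_params(matrix(1, 2, 1), r_on = 1, r_off = 20, dt = 0.01)
  expect_equal(gp2$p_on, 0.01)
  expect_equal(gp2$p_off, 0.2)
  expect_equal(generative_params(matrix(1, 2, 1), r_off = 500, dt = 0.01)$p_off, 1)
})

test_that("feature trajectories follow the two-state chain edge cases", {
  Q <- matrix(1, 3, 2)
  # absorbing off state: r_on = 0, all-off start stays all-off
  gp <- generative_params(Q, r_on = 0, r_off = 20)
  X <- sample_features(gp, 50, seed = 1, initial_state = c(0, 0))$X
  expect_true(all(X == 0))
  # r_on = 1 per bin, r_off = 0: on from the second bin onward
  gp2 <- generative_params(Q, r_on = 100, r_off = 0, dt = 0.01)  # p_on = 1
  X2 <- sample_features(gp2, 10, seed = 1, initial_state = c(0, 0))$X
  expect_true(all(X2[, 2:10] == 1))
  # reproducibility
  expect_identical(sample_features(gp, 100, seed = 7)$X,
                   sample_features(gp, 100, seed = 7)$X)
})

test_that("empirical on-fraction matches the stationary distribution", {
  gp <- generative_params(matrix(1, 2, 3), r_on = 1, r_off = 20, dt = 0.01)
  X <- sample_features(gp, 1e5, seed = 11)$X
  pi_true <- 0.01 / 0.21
  # 3 standard errors, inflated for the chain's autocorrelation
  se <- sqrt(pi_true * (1 - pi_true) / 1e5) * sqrt(2 / 0.21)
  expect_true(all(abs(rowMeans(X) - pi_true) < 3 * se))
})

test_that("receptor intensity is affine in the feature state", {
  gp <- generative_params(matrix(c(2, 0), 2, 1), q0 = 0.1)
  expect_equal(receptor_intensity(gp, 0), gp$q0)
  expect_equal(receptor_intensity(gp, 1), c(2.1, 0.1))
  gp2 <- generative_params(matrix(1:6 / 10, 3, 2), q0 = 0.5)
  expect_equal(receptor_intensity(gp2, c(0, 1)), 0.5 + gp2$Q[, 2])
  expect_error(receptor_intensity(gp2, c(1, 0, 0)), "length")
  expect_error(receptor_intensity(gp2, c(2, 0)), "binary")
})

test_that("Poisson observations have the right moments and are reproducible", {
  Q <- matrix(5, 1, 1)
  gp <- generative_params(Q, q0 = 1e-6, r_on = 100, r_off = 0, dt = 0.01)
  traj <- sample_features(gp, 1e4, seed = 1, initial_state = 1)
  obs <- sample_observations(gp, traj, seed = 2)
  lam <- 5 + 1e-6
  expect_lt(abs(mean(obs$S) - lam), 3 * sqrt(lam / 1e4))
  expect_identical(obs$S, sample_observations(gp, traj, seed = 2)$S)
  # near-zero intensity gives all-zero counts
  gp0 <- generative_params(matrix(0, 2, 1), q0 = 0)
  tr0 <- sample_features(gp0, 200, seed = 3, initial_state = 0)
  expect_true(all(sample_observations(gp0, tr0, seed = 4)$S == 0))
})

test_that("receptor pools driven by disjoint features are uncorrelated", {
  Q <- rbind(cbind(rep(3, 5), 0), cbind(0, rep(3, 5)))  # disjoint supports
  gp <- generative_params(Q, q0 = 0.1, r_on = 2, r_off = 10)
  traj <- sample_features(gp, 2e4, seed = 5)
  obs <- sample_observations(gp, traj, seed = 6)
  pool1 <- colSums(obs$S[1:5, ]); pool2 <- colSums(obs$S[6:10, ])
  expect_lt(abs(cor(pool1, pool2)), 0.05)
})

test_that("observation means converge to the receptor intensity per bin", {
  gp <- two_feature_params()
  x <- c(1, 0)
  lam <- receptor_intensity(gp, x)
  traj <- structure(list(X = matrix(x, 2, 5000), dt = 0.01),
                    class = "feature_trajectory")
  obs <- sample_observations(gp, traj, seed = 8)
  expect_true(all(abs(rowMeans(obs$S) - lam) < 3 * sqrt(pmax(lam, 0.05) / 5000) + 0.01))
})
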