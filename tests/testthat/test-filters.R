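test_that("lagged design places stimulus history in the right columns", {
  S <- matrix(1:12, 3, 4)   # 3 channels, 4 bins
  D0 <- lagged_design(S, 0L)
  expect_equal(D0, t(S))
  # impulse at t0 with delays 0,1 fills exactly rows t0 and t0 + 1
  Si <- matrix(0, 2, 10); Si[, 4] <- c(1, 2)
  D <- lagged_design(Si, 0:1)
  nz <- which(rowSums(abs(D)) > 0)
  expect_equal(nz, c(4L, 5L))
  expect_equal(D[4, ], c(1, 0, 2, 0))   # channel-major, delay-fastest columns
  expect_equal(D[5, ], c(0, 1, 0, 2))
  # the full STRF grid: 30 channels x 25 delays = 750 free parameters
  expect_equal(ncol(lagged_design(matrix(0, 30, 40), 0:24)), 750)
  expect_error(lagged_design(S, c(1, 0)), "ascending")
  expect_error(lagged_design(S, -1L), "causal")
})

test_that("ridge shrinkage, identifiability, and CV-minimality hold", {
  set.seed(40)
  Tn <- 3000; M <- 20
  S <- matrix(rnorm(M * Tn), M, Tn)
  h <- exp(-((1:M) - 8)^2 / 4)
  y <- as.numeric(t(S) %*% h)
  D <- lagged_design(S, 0L)
  fit <- ridge_reverse_correlation(D, y)
  expect_gt(cor(fit$weights, h), 0.99)
  # chosen penalty attains the minimal mean validation error by construction
  expect_equal(fit$report$chosen_lambda,
               fit$report$lambda_grid[which.min(fit$report$mean_mse)])
  # very large penalty shrinks weights to nearly nothing
  big <- ridge_reverse_correlation(D, y, lambda_grid = 1e8)
  expect_lt(sqrt(sum(big$weights^2)), 1e-3 * sqrt(sum(fit$weights^2)))
})

test_that("autocorrelation normalization matters on correlated stimuli", {
  set.seed(41)
  Tn <- 4000; M <- 20
  # temporally and spectrally correlated stimulus
  Z <- matrix(rnorm(M * Tn), M, Tn)
  for (t in 2:Tn) Z[, t] <- 0.9 * Z[, t - 1] + sqrt(1 - 0.81) * Z[, t]
  K <- outer(1:M, 1:M, function(a, b) exp(-(a - b)^2 / 8))
  S <- K %*% Z
  h <- exp(-((1:M) - 8)^2 / 2)
  y <- as.numeric(t(S) %*% h) + rnorm(Tn)
  fit <- ridge_reverse_correlation(lagged_design(S, 0L), y)
  cc_norm <- cor(fit$weights, h)
  cc_plain <- cor(as.numeric(S %*% (y - mean(y))), h)  # unnormalized reverse correlation
  expect_gt(cc_norm, 0.95)
  expect_gt(cc_norm - cc_plain, 0.1)
})

test_that("encoding filters locate a model detector's preferred channel", {
  fx <- narrowing_fixture()
  enc <- estimate_encoding_filters(fx$st$S, fx$F_intact, delays = 0:2)
  for (j in 1:5) {
    bf_pf <- which.max(fx$st$params$Q[, j])
    bf_enc <- which.max(enc$W[, 1, j])
    # narrowing can shift the peak within the bump, but not off it
    expect_lte(abs(bf_enc - bf_pf), 2)
  }
  # constant response carries no structure
  flat <- estimate_encoding_filters(fx$st$S, matrix(1, 1, ncol(fx$st$S)), delays = 0:2)
  expect_lt(max(abs(flat$W)), 1e-6)
  # deterministic
  enc2 <- estimate_encoding_filters(fx$st$S, fx$F_intact, delays = 0:2)
  expect_identical(enc$W, enc2$W)
})

test_that("single-delay decoding recovers an indicator for a copied channel", {
  set.seed(42)
  S <- matrix(abs(rnorm(8 * 2000)), 8, 2000)
  R <- S[3, , drop = FALSE]            # neuron = copy of channel 3
  dec <- estimate_decoding_filters(R, S, delays = 0L)
  g <- dec$W[, 1, 1]
  expect_equal(which.max(g), 3L)
  expect_gt(cor(g, as.numeric(1:8 == 3)), 0.99)
  # zero responses give zero filters
  dec0 <- estimate_decoding_filters(matrix(0, 1, 2000), S, delays = 0L)
  expect_true(all(dec0$W == 0))
})

test_that("duplicate neurons split decoding weight symmetrically", {
  set.seed(43)
  S <- matrix(abs(rnorm(6 * 2000)), 6, 2000)
  r <- S[2, ] + rnorm(2000, 0, 0.1)
  # penalty small against the design scale: the split is near-exact while
  # the duplicated (singular) direction stays numerically damped
  single <- estimate_decoding_filters(matrix(r, 1), S, delays = 0L, lambda_grid = 1e-3)
  dupl <- estimate_decoding_filters(rbind(r, r), S, delays = 0L, lambda_grid = 1e-3)
  expect_equal(dupl$W[, 1, 1], dupl$W[, 1, 2], tolerance = 1e-8)
  summed <- dupl$W[, 1, 1] + dupl$W[, 1, 2]
  expect_equal(summed, single$W[, 1, 1], tolerance = 1e-6)
})

test_that("stimulus reconstruction behaves on identity and degenerate input", {
  S <- matrix(abs(rnorm(5 * 300)), 5, 300)
  # identity decoder: delta filters, no intercept
  W <- array(0, c(5, 1, 5)); for (i in 1:5) W[i, 1, i] <- 1
  bank <- structure(list(kind = "decoding", W = W, intercepts = rep(0, 5),
                         delays = 0L, dt = 0.01), class = "filter_bank")
  expect_equal(reconstruct_stimulus(S, bank), S)
  # zero responses: reconstruction collapses to the fitted channel means
  dec <- estimate_decoding_filters(S[1:2, ], S, delays = 0:1)
  rec0 <- reconstruct_stimulus(matrix(0, 2, 300), dec)
  expect_equal(rec0, matrix(dec$intercepts, 5, 300), tolerance = 1e-12)
})

test_that("reconstruction improves as informative neurons are added", {
  fx <- pipeline_bank()
  R_all <- fx$bank$rates
  cc <- sapply(c(1, 2, 4, 8, 12), function(k) {
    dec <- estimate_decoding_filters(R_all[1:k, , drop = FALSE], fx$S,
                                     delays = 0:3, lambda_grid = 1e-6, n_folds = 2L)
    reconstruction_cc(fx$S, reconstruct_stimulus(R_all[1:k, , drop = FALSE], dec))
  })
  expect_true(all(diff(cc) > -1e-6))
})

test_that("predictive-field extraction finds the planted delay and flags flat cells", {
  fx <- pipeline_bank()
  # responses delayed by exactly 5 bins relative to the stimulus
  Tn <- ncol(fx$S)
  R_delayed <- cbind(matrix(0, nrow(fx$R), 5), fx$R[, 1:(Tn - 5)])
  px <- extract_pf(R_delayed, fx$S, delay_scan = 0:8, n_folds = 3L)
  expect_equal(px$optimal_delay, 5L)
  # an anti-correlated cell yields an all-negative vector and is flagged
  set.seed(44)
  S <- matrix(abs(rnorm(6 * 1500)), 6, 1500)
  R <- rbind(S[2, ], max(S) - colMeans(S))
  px2 <- extract_pf(R, S, delay_scan = 0L)
  expect_false(px2$all_negative[1])
  expect_true(px2$all_negative[2])
  # kept fields are unit-max normalized
  expect_equal(max(px2$pf[, 1]), 1)
})

test_that("neuron selection keeps informative cells and drops noise", {
  set.seed(45)
  S <- matrix(abs(rnorm(6 * 2000)), 6, 2000)
  R <- rbind(S[2, ] + rnorm(2000, 0, 0.2),   # informative
             rnorm(2000))                    # pure noise
  sel <- select_neurons(R, S, threshold = 0.2, delays = 0:2, n_folds = 3L)
  expect_true(1 %in% sel$selected)
  expect_false(2 %in% sel$selected)
  expect_lt(abs(sel$cc[2]), 0.1)
  # threshold -1 +eps: only the negativity rule applies
  sel_all <- select_neurons(R, S, threshold = -0.999, delays = 0:2, n_folds = 3L)
  expect_equal(sel_all$selected, which(!sel_all$all_negative))
})

test_that("response delay optimization recovers a constructed shift", {
  set.seed(46)
  x <- as.numeric(stats::filter(rnorm(800), rep(0.2, 5), sides = 1)); x[is.na(x)] <- 0
  target <- c(rep(0, 3), x[1:797])    # target lags prediction by 3 bins
  od <- optimal_response_delay(x, target, scan_ms = seq(0, 100, 10), dt = 0.01)
  expect_equal(od$delay_bins, 3L)
  expect_gt(od$cc, 0.99)
  expect_equal(delayed_cc(x, target, od$delay_bins), od$cc)
  # uncorrelated series: small cc, delay still reported
  od2 <- optimal_response_delay(rnorm(500), rnorm(500), scan_ms = seq(0, 50, 10))
  expect_lt(abs(od2$cc), 0.2)
  # constant series score zero by convention
  expect_equal(optimal_response_delay(rep(1, 100), rnorm(100), scan_ms = 0)$cc, 0)
})

test_that("decoding filters are wider than encoding filters for model neurons", {
  fx <- narrowing_fixture()
  enc <- estimate_srf(fx$st$S, fx$F_intact, fixed_delay = 0L)
  px <- extract_pf(fx$F_intact, fx$st$S, delay_scan = 0:2)
  w_enc <- sapply(1:5, function(j) half_max_width(enc$W[, 1, j]))
  w_dec <- sapply(1:5, function(j) half_max_width(px$bank$W[, 1, j]))
  expect_gt(mean(w_dec, na.rm = TRUE), mean(w_enc, na.rm = TRUE))
})
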