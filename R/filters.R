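#' Time-lagged design matrix for convolutional filter fits
#'
#' Builds the regression design for a causal convolution
#' `yhat(t) = sum_i sum_tau w_i(tau) s_i(t - tau)`: rows indexed by time,
#' columns by (channel, delay) with channels outermost, entry
#' `S[i, t - delay]`; out-of-range lags are zero-padded so the design keeps
#' the stimulus length.
#'
#' @param S `M x T` matrix (channels/neurons x time).
#' @param delays nonnegative integer delays in bins, sorted ascending.
#' @return `T x (M * length(delays))` matrix.
#' @export
lagged_design <- function(S, delays) {
  if (!is.matrix(S)) S <- matrix(S, nrow = 1L)
  delays <- as.integer(delays)
  if (any(delays < 0)) stop("delays must be causal (>= 0)")
  if (is.unsorted(delays, strictly = TRUE)) stop("delays must be sorted ascending and unique")
  M <- nrow(S); Tn <- ncol(S); nd <- length(delays)
  D <- matrix(0, Tn, M * nd)
  for (i in seq_len(M)) {
    for (d in seq_len(nd)) {
      tau <- delays[d]
      col <- (i - 1L) * nd + d
      if (tau < Tn) D[(tau + 1L):Tn, col] <- S[i, 1L:(Tn - tau)]
    }
  }
  D
}

# Shared ridge solver with contiguous-block cross-validation.
# X: T x p design; Y: T x K targets. Returns weights (p x K), intercepts (K),
# chosen lambda per target and the fold x lambda x target validation MSEs.
# Columns of X and targets are centered on the training folds (via rank-one
# corrections of the crossproducts); the intercept absorbs the means.
ridge_cv_multi <- function(X, Y, lambda_grid, n_folds) {
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1L)
  stopifnot(nrow(X) == nrow(Y), all(lambda_grid > 0), n_folds >= 2)
  lambda_grid <- sort(lambda_grid)
  Tn <- nrow(X); p <- ncol(X); K <- ncol(Y); nl <- length(lambda_grid)
  folds <- contiguous_folds(Tn, n_folds)
  XtX_f <- vector("list", n_folds); XtY_f <- vector("list", n_folds)
  xs_f <- vector("list", n_folds); ys_f <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    Xf <- X[folds[[f]], , drop = FALSE]; Yf <- Y[folds[[f]], , drop = FALSE]
    XtX_f[[f]] <- crossprod(Xf); XtY_f[[f]] <- crossprod(Xf, Yf)
    xs_f[[f]] <- colSums(Xf); ys_f[[f]] <- colSums(Yf)
  }
  XtX <- Reduce(`+`, XtX_f); XtY <- Reduce(`+`, XtY_f)
  xs <- Reduce(`+`, xs_f); ys <- Reduce(`+`, ys_f)
  cv_mse <- array(NA_real_, c(n_folds, nl, K))
  for (f in seq_len(n_folds)) {
    nt <- Tn - length(folds[[f]])
    mu <- (xs - xs_f[[f]]) / nt
    ybar <- (ys - ys_f[[f]]) / nt
    Ct <- (XtX - XtX_f[[f]]) - nt * tcrossprod(mu)
    bt <- (XtY - XtY_f[[f]]) - nt * outer(mu, ybar)
    eg <- eigen(Ct, symmetric = TRUE)
    Ub <- crossprod(eg$vectors, bt)                       # p x K
    Xv <- sweep(X[folds[[f]], , drop = FALSE], 2L, mu)    # centered validation design
    Yv <- sweep(Y[folds[[f]], , drop = FALSE], 2L, ybar)
    XvV <- Xv %*% eg$vectors
    for (l in seq_len(nl)) {
      Wl <- Ub / (pmax(eg$values, 0) + lambda_grid[l])    # rotated weights
      Rv <- Yv - XvV %*% Wl
      cv_mse[f, l, ] <- colMeans(Rv^2)
    }
  }
  mean_mse <- apply(cv_mse, c(2L, 3L), mean)              # nl x K
  best <- apply(mean_mse, 2L, which.min)
  # refit on the full data at each target's chosen lambda
  mu <- xs / Tn; ybar <- ys / Tn
  Cfull <- XtX - Tn * tcrossprod(mu)
  bfull <- XtY - Tn * outer(mu, ybar)
  eg <- eigen(Cfull, symmetric = TRUE)
  Ub <- crossprod(eg$vectors, bfull)
  W <- matrix(NA_real_, p, K)
  for (l in unique(best)) {
    k <- which(best == l)
    W[, k] <- eg$vectors %*% (Ub[, k, drop = FALSE] / (pmax(eg$values, 0) + lambda_grid[l]))
  }
  intercepts <- ybar - as.numeric(crossprod(W, mu))
  list(W = W, intercepts = intercepts,
       lambda = lambda_grid[best], lambda_index = best,
       lambda_grid = lambda_grid, cv_mse = cv_mse, mean_mse = mean_mse,
       n_folds = n_folds)
}

#' Default logarithmic ridge penalty grid
#'
#' @param from,to,length grid range and size; defaults span `1e-4` to `1e4`
#'   in 13 logarithmic steps.
#' @return numeric vector of penalties.
#' @export
default_lambda_grid <- function(from = 1e-4, to = 1e4, length = 13) {
  exp(seq(log(from), log(to), length.out = length))
}

#' Ridge-regularized normalized reverse correlation
#'
#' Solves the normal equations `(C_SS + lambda I)^{-1} C_Sr` — the
#' stimulus-response cross-correlation whitened by the stimulus
#' autocorrelation — with the ridge penalty chosen by cross-validation over
#' contiguous time blocks (shuffled bins would leak through temporal
#' autocorrelation). Weights are refit on the full data at the CV-optimal
#' penalty.
#'
#' @param design `T x p` lagged design matrix (see [lagged_design()]).
#' @param target response vector of length `T`.
#' @param lambda_grid positive penalties (default [default_lambda_grid()]).
#' @param n_folds number of contiguous CV folds (>= 2).
#' @param seed kept for interface stability; the fit is deterministic
#'   (contiguous folds involve no randomness).
#' @return list with `weights`, `intercept`, and `report` (a `fit_report`
#'   with the grid, per-fold validation errors and chosen penalty).
#' @export
ridge_reverse_correlation <- function(design, target,
                                      lambda_grid = default_lambda_grid(),
                                      n_folds = 5L, seed = 1L) {
  fit <- ridge_cv_multi(design, target, lambda_grid, n_folds)
  report <- structure(list(
    cv_scheme = sprintf("%d contiguous time blocks", n_folds),
    lambda_grid = fit$lambda_grid,
    cv_mse = fit$cv_mse[, , 1L, drop = TRUE],
    mean_mse = fit$mean_mse[, 1L],
    chosen_lambda = fit$lambda[1L]
  ), class = "fit_report")
  list(weights = fit$W[, 1L], intercept = fit$intercepts[1L], report = report)
}

new_filter_bank <- function(kind, W, intercepts, delays, dt, channels = NULL,
                            ridge_lambda = NULL, fit = NULL) {
  stopifnot(kind %in% c("encoding", "decoding"), length(dim(W)) == 3L)
  structure(list(kind = kind, W = W, intercepts = intercepts,
                 delays = as.integer(delays), dt = dt, channels = channels,
                 ridge_lambda = ridge_lambda, fit = fit),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  d <- dim(x$W)
  cat(sprintf("%s filter bank: %d channels x %d delays x %d units (dt = %g s)\n",
              x$kind, d[1L], d[2L], d[3L], x$dt))
  invisible(x)
}

#' Estimate encoding filters (STRFs) by normalized reverse correlation
#'
#' One frequency x delay filter per neuron, predicting the neuron's rate
#' from the lagged spectrogram by ridge regression with per-neuron
#' cross-validated penalties.
#'
#' @param S `M x T` stimulus spectrogram.
#' @param R `n_neurons x T` response matrix, time-aligned with `S`.
#' @param delays nonnegative delays in bins (default `0:24`, i.e. 0-240 ms
#'   at 10 ms bins; with 30 channels that is the full 750-parameter STRF
#'   grid).
#' @param lambda_grid,n_folds,seed passed to the ridge solver.
#' @param dt bin width in seconds (metadata).
#' @return a `filter_bank` of kind `"encoding"` with `W[channel, delay,
#'   neuron]`, plus the fit report.
#' @export
estimate_encoding_filters <- function(S, R, delays = 0:24,
                                      lambda_grid = default_lambda_grid(),
                                      n_folds = 5L, seed = 1L, dt = 0.01) {
  if (!is.matrix(R)) R <- matrix(R, nrow = 1L)
  if (ncol(S) != ncol(R)) stop("stimulus and responses must have the same number of time bins")
  D <- lagged_design(S, delays)
  fit <- ridge_cv_multi(D, t(R), lambda_grid, n_folds)
  M <- nrow(S); nd <- length(delays); n <- nrow(R)
  W <- array(fit$W, c(nd, M, n))        # columns were channel-major, delay fastest
  W <- aperm(W, c(2L, 1L, 3L))          # -> channel x delay x neuron
  new_filter_bank("encoding", W, fit$intercepts, delays, dt,
                  ridge_lambda = fit$lambda, fit = fit)
}

#' Estimate spectral receptive fields (SRFs): single-delay encoding filters
#'
#' The reduced form of the full encoding filter with the delay fixed:
#' frequency-only weights (30 weights for a 30-channel spectrogram, plus the
#' optimized response delay fitted separately, giving the model 31 free
#' parameters per neuron).
#'
#' @inheritParams estimate_encoding_filters
#' @param fixed_delay single delay in bins at which the filter is estimated.
#' @return a `filter_bank` of kind `"encoding"` with one delay.
#' @export
estimate_srf <- function(S, R, fixed_delay = 0L,
                         lambda_grid = default_lambda_grid(),
                         n_folds = 5L, seed = 1L, dt = 0.01) {
  stopifnot(length(fixed_delay) == 1L)
  estimate_encoding_filters(S, R, delays = fixed_delay, lambda_grid = lambda_grid,
                            n_folds = n_folds, seed = seed, dt = dt)
}

#' Predict responses from an encoding filter bank
#'
#' Linear convolution of the stimulus with each neuron's filter; set
#' `rectify = TRUE` for the SRF response model (convolve, then rectify).
#'
#' @param bank an encoding `filter_bank`.
#' @param S `M x T` stimulus.
#' @param rectify clip predictions at zero.
#' @return `n_neurons x T` prediction matrix.
#' @export
predict_encoding <- function(bank, S, rectify = FALSE) {
  stopifnot(bank$kind == "encoding")
  d <- dim(bank$W)
  D <- lagged_design(S, bank$delays)
  Wm <- matrix(aperm(bank$W, c(2L, 1L, 3L)), nrow = d[1L] * d[2L])  # (delay fastest) x units
  P <- t(D %*% Wm) + bank$intercepts
  if (rectify) P <- pmax(P, 0)
  P
}

#' Estimate population decoding filters
#'
#' The linear map from lagged population responses back to the stimulus:
#' for each frequency channel `i`, `g_i = (C_RR + lambda I)^{-1} C_RS_i`
#' fitted over all neurons jointly (so the response autocorrelation is
#' normalized away), then regrouped per neuron into `g(tau, n)`.
#'
#' @param R `n_neurons x T` response matrix.
#' @param S `M x T` stimulus.
#' @param delays nonnegative delays in bins.
#' @param lambda_grid,n_folds,seed ridge options (penalty chosen per
#'   frequency channel).
#' @param dt bin width (metadata).
#' @return a `filter_bank` of kind `"decoding"` with `W[channel, delay,
#'   neuron]`.
#' @export
estimate_decoding_filters <- function(R, S, delays = 0:24,
                                      lambda_grid = default_lambda_grid(),
                                      n_folds = 5L, seed = 1L, dt = 0.01) {
  if (!is.matrix(R)) R <- matrix(R, nrow = 1L)
  if (ncol(S) != ncol(R)) stop("stimulus and responses must have the same number of time bins")
  D <- lagged_design(R, delays)
  fit <- ridge_cv_multi(D, t(S), lambda_grid, n_folds)
  n <- nrow(R); nd <- length(delays); M <- nrow(S)
  # fit$W is (n * nd) x M with neuron-major, delay-fastest rows
  W <- array(NA_real_, c(M, nd, n))
  for (i in seq_len(M)) {
    W[i, , ] <- matrix(fit$W[, i], nd, n)
  }
  new_filter_bank("decoding", W, fit$intercepts, delays, dt,
                  ridge_lambda = fit$lambda, fit = fit)
}

#' Reconstruct the stimulus from responses and decoding filters
#'
#' \deqn{\hat s_i(t) = \sum_n \sum_\tau g_i(\tau, n)\, r(t - \tau, n)}
#'
#' @param R `n_neurons x T` response matrix.
#' @param decoding a decoding `filter_bank`.
#' @return `M x T` reconstructed spectrogram estimate.
#' @export
reconstruct_stimulus <- function(R, decoding) {
  stopifnot(decoding$kind == "decoding")
  if (!is.matrix(R)) R <- matrix(R, nrow = 1L)
  d <- dim(decoding$W)
  if (nrow(R) != d[3L]) stop("response matrix does not match the decoding bank's neuron count")
  D <- lagged_design(R, decoding$delays)
  # flatten W to M x (n * nd) matching design column order (neuron-major, delay fastest)
  Gm <- matrix(aperm(decoding$W, c(1L, 2L, 3L)), d[1L], d[2L] * d[3L])
  Shat <- Gm %*% t(D) + decoding$intercepts
  Shat
}

#' Reconstruction accuracy
#'
#' Pearson correlation between a stimulus and its reconstruction, computed
#' per frequency channel and averaged (default, as reconstruction accuracies
#' are usually reported per channel), or pooled over all cells.
#'
#' @param S,Shat `M x T` stimulus and reconstruction.
#' @param method `"channel_mean"` or `"pooled"`.
#' @return scalar correlation.
#' @export
reconstruction_cc <- function(S, Shat, method = c("channel_mean", "pooled")) {
  method <- match.arg(method)
  stopifnot(all(dim(S) == dim(Shat)))
  if (method == "pooled") return(safe_cor(as.numeric(S), as.numeric(Shat)))
  mean(vapply(seq_len(nrow(S)), function(i) safe_cor(S[i, ], Shat[i, ]), 0))
}

#' Extract predictive fields: frequency-only decoding filters
#'
#' Restricts the decoding analysis to a single time delay to recover
#' frequency-only decoding filters (the empirical predictive fields).
#' Because responses lag the stimulus, the stimulus is shifted earlier in
#' time over a scan (default 0-200 ms in 10 ms steps: at shift `d` the fit
#' pairs the response `r(t)` with the stimulus `s(t - d)`); the shift
#' maximizing the channel-averaged training-set reconstruction correlation
#' is chosen, and the scan trace is returned. Neurons whose extracted vector
#' is completely negative are flagged (they would yield flat predictive
#' fields after clipping) for exclusion.
#'
#' @param R `n_neurons x T` responses.
#' @param S `M x T` stimulus.
#' @param lambda_grid,n_folds,seed ridge options.
#' @param delay_scan candidate stimulus shifts in bins (default 0:20 =
#'   0-200 ms at 10 ms bins).
#' @param dt bin width in seconds.
#' @return list with `bank` (single-delay decoding `filter_bank`; its
#'   reconstruction is aligned with the stimulus shifted by
#'   `optimal_delay`), `pf` (`M x n` matrix: weights clipped at zero and
#'   normalized to unit maximum, ready to use as model `Q`), `all_negative`
#'   (logical flags), `optimal_delay` (bins), `cc_by_delay`.
#' @export
extract_pf <- function(R, S, lambda_grid = default_lambda_grid(),
                       n_folds = 5L, delay_scan = 0:20, seed = 1L, dt = 0.01) {
  if (!is.matrix(R)) R <- matrix(R, nrow = 1L)
  Tn <- ncol(S)
  if (max(delay_scan) >= Tn) stop("delay scan exceeds the data length")
  cc_by_delay <- numeric(length(delay_scan))
  banks <- vector("list", length(delay_scan))
  for (k in seq_along(delay_scan)) {
    d <- delay_scan[k]
    rows <- (d + 1L):Tn                      # response bins
    Rk <- R[, rows, drop = FALSE]
    Sk <- S[, rows - d, drop = FALSE]        # stimulus d bins earlier
    b <- estimate_decoding_filters(Rk, Sk, delays = 0L,
                                   lambda_grid = lambda_grid,
                                   n_folds = n_folds, seed = seed, dt = dt)
    cc_by_delay[k] <- reconstruction_cc(Sk, reconstruct_stimulus(Rk, b))
    banks[[k]] <- b
  }
  best <- which.max(cc_by_delay)   # first maximum = smallest shift on ties
  bank <- banks[[best]]
  G <- bank$W[, 1L, , drop = TRUE]
  if (is.null(dim(G))) G <- matrix(G, ncol = 1L)
  all_negative <- apply(G, 2L, function(v) all(v <= 0))
  pf <- pmax(G, 0)
  mx <- apply(pf, 2L, max)
  pf <- sweep(pf, 2L, ifelse(mx > 0, mx, 1), `/`)
  list(bank = bank, pf = pf, all_negative = all_negative,
       optimal_delay = delay_scan[best], cc_by_delay = cc_by_delay)
}

#' Select neurons informative about the stimulus
#'
#' Reconstructs the stimulus from each neuron's responses alone and keeps
#' neurons whose single-neuron reconstruction correlates with the stimulus
#' above `threshold` (default 0.2); neurons with completely negative
#' decoding vectors are dropped regardless. The correlation is pooled over
#' all spectrogram cells (a single neuron informs only part of the spectrum,
#' so per-channel averaging would dilute its contribution).
#'
#' @param R `n_neurons x T` responses.
#' @param S `M x T` stimulus.
#' @param threshold correlation gate in `(-1, 1)`.
#' @param delays decoding delays in bins.
#' @param lambda_grid,n_folds,seed ridge options.
#' @param method correlation pooling, see [reconstruction_cc()].
#' @return list with `selected` (indices), `cc` (per-neuron reconstruction
#'   correlation), `all_negative` flags.
#' @export
select_neurons <- function(R, S, threshold = 0.2, delays = 0:10,
                           lambda_grid = default_lambda_grid(),
                           n_folds = 5L, seed = 1L, method = "pooled") {
  if (!is.matrix(R)) R <- matrix(R, nrow = 1L)
  stopifnot(threshold > -1, threshold < 1)
  n <- nrow(R)
  cc <- numeric(n); all_negative <- logical(n)
  for (j in seq_len(n)) {
    b <- estimate_decoding_filters(R[j, , drop = FALSE], S, delays = delays,
                                   lambda_grid = lambda_grid,
                                   n_folds = n_folds, seed = seed)
    cc[j] <- reconstruction_cc(S, reconstruct_stimulus(R[j, , drop = FALSE], b),
                               method = method)
    all_negative[j] <- all(b$W <= 0)
  }
  list(selected = which(cc > threshold & !all_negative), cc = cc,
       all_negative = all_negative)
}

#' Optimal response delay between a prediction and a target
#'
#' Shifts the target later in time over a scan (default 0-200 ms in 10 ms
#' steps) and returns the delay maximizing the Pearson correlation on the
#' given (training) segment; the delay is then held fixed for test
#' evaluation. Ties are broken toward the smallest delay; degenerate
#' (constant) overlaps score 0.
#'
#' @param pred,target numeric vectors of equal length.
#' @param scan_ms candidate delays in milliseconds.
#' @param dt bin width in seconds.
#' @return list with `delay_bins`, `delay_ms`, `cc`, `cc_by_delay`.
#' @export
optimal_response_delay <- function(pred, target, scan_ms = seq(0, 200, 10), dt = 0.01) {
  stopifnot(length(pred) == length(target))
  bins <- unique(as.integer(round(scan_ms / (1000 * dt))))
  Tn <- length(pred)
  if (max(bins) >= Tn) stop("delay scan exceeds the data length")
  cc <- vapply(bins, function(d) {
    if (d == 0) safe_cor(pred, target)
    else safe_cor(pred[1:(Tn - d)], target[(1 + d):Tn])
  }, 0)
  best <- which.max(cc)
  list(delay_bins = bins[best], delay_ms = bins[best] * dt * 1000,
       cc = cc[best], cc_by_delay = stats::setNames(cc, bins))
}

#' Shift a prediction by a fixed delay for test scoring
#'
#' @param pred,target numeric vectors; `target` is taken `delay_bins` later
#'   than `pred`.
#' @param delay_bins nonnegative integer delay.
#' @return Pearson correlation of the overlapping segment.
#' @export
delayed_cc <- function(pred, target, delay_bins) {
  Tn <- length(pred)
  if (delay_bins == 0) return(safe_cor(pred, target))
  safe_cor(pred[1:(Tn - delay_bins)], target[(1 + delay_bins):Tn])
}

#' Free-parameter counts of the simplified response models
#'
#' The reduced encoding (SRF) model has one weight per frequency channel
#' plus the optimized response delay (31 parameters at the standard
#' 30-channel binning). The simplified Bayesian decoding model has one
#' predictive-field weight per channel plus the delay and the three global
#' parameters `r_on`, `r_off` and gain (34 at 30 channels). The full STRF
#' has `n_channels * n_delays` weights (750 for the 30 x 25 grid).
#'
#' @param model one of `"srf"`, `"pf_decoding"`, `"strf"`.
#' @param n_channels number of frequency channels.
#' @param n_delays number of delays (STRF only).
#' @return integer parameter count.
#' @export
model_parameter_count <- function(model = c("srf", "pf_decoding", "strf"),
                                  n_channels = 30L, n_delays = 25L) {
  model <- match.arg(model)
  switch(model,
    srf = as.integer(n_channels + 1L),
    pf_decoding = as.integer(n_channels + 1L + 3L),
    strf = as.integer(n_channels * n_delays))
}
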