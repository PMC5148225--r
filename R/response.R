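#' Best frequency of a neuron from a frequency-only filter
#'
#' The channel at which the one-dimensional encoding filter is maximal;
#' ties are broken toward the lowest channel index. A constant filter has no
#' best frequency and is rejected.
#'
#' @param encoding_1d numeric vector over frequency channels.
#' @return integer channel index.
#' @export
best_frequency <- function(encoding_1d) {
  if (length(unique(encoding_1d)) == 1L) stop("constant filter has no best frequency")
  which.max(encoding_1d)
}

#' Detect sudden spectral events near a best frequency
#'
#' Averages the spectrogram over `bf +/- band_halfwidth` channels (clipped
#' at the edges), takes the first difference, finds its local maxima, and
#' greedily keeps the tallest peaks subject to a minimum separation; the top
#' `max_events` are returned sorted in time. Fewer qualifying peaks than
#' requested simply yields fewer events.
#'
#' @param S `M x T` spectrogram.
#' @param bf best-frequency channel index.
#' @param band_halfwidth half-width of the averaging band in channels
#'   (default 10).
#' @param max_events cap on the number of events (default 150).
#' @param min_sep_ms minimum separation between events in ms (default 200).
#' @param dt bin width in seconds.
#' @param smooth_bins optional moving-average window (in bins) applied to
#'   the band-averaged power before differencing; 1 = no smoothing.
#' @return integer vector of event time bins, sorted ascending.
#' @export
detect_events <- function(S, bf, band_halfwidth = 10L, max_events = 150L,
                          min_sep_ms = 200, dt = 0.01, smooth_bins = 1L) {
  stopifnot(bf >= 1, bf <= nrow(S))
  lo <- max(1L, bf - band_halfwidth); hi <- min(nrow(S), bf + band_halfwidth)
  band <- colMeans(S[lo:hi, , drop = FALSE])
  if (smooth_bins > 1L) {
    band <- stats::filter(band, rep(1 / smooth_bins, smooth_bins), sides = 2)
    band[is.na(band)] <- 0
  }
  d <- diff(as.numeric(band))
  if (length(d) < 3L) return(integer(0))
  # local maxima of the derivative (strictly above both neighbours)
  idx <- which(d[-c(1L, length(d))] > d[-((length(d) - 1L):length(d))] &
               d[-c(1L, length(d))] > d[-(1L:2L)]) + 1L
  idx <- idx[d[idx] > 0]
  if (length(idx) == 0L) return(integer(0))
  min_sep <- as.integer(round(min_sep_ms / (1000 * dt)))
  keep <- integer(0)
  for (i in idx[order(-d[idx])]) {        # greedy by peak height
    if (all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
    if (length(keep) >= max_events) break
  }
  # event time = bin index of the increase (diff d[i] = band[i+1]-band[i])
  sort(keep + 1L)
}

#' Event-windowed receptive fields and event-aligned responses
#'
#' Estimates encoding filters using only the time bins inside the chosen
#' windows after each event: `transient` covers the first 100 ms after an
#' event, `sustained` the following 100 ms (10 bins each at 10 ms binning;
#' other bin widths scale proportionally, rounding down). Also returns the
#' event-aligned mean response over the 200 ms following each event.
#' Events whose windows exceed the data length are dropped.
#'
#' @param S `M x T` spectrogram.
#' @param R `n_neurons x T` responses.
#' @param events integer event time bins.
#' @param window `"transient"` or `"sustained"`.
#' @param delays encoding delays in bins.
#' @param lambda_grid,n_folds,seed ridge options.
#' @param dt bin width in seconds.
#' @return list with `bank` (encoding `filter_bank`, `NULL` if no usable
#'   events), `aligned_mean` (`n_neurons x 2*w` matrix of event-aligned mean
#'   responses, `w` bins per window), `bins_used`.
#' @export
windowed_rf <- function(S, R, events, window = c("transient", "sustained"),
                        delays = 0:9, lambda_grid = default_lambda_grid(),
                        n_folds = 5L, seed = 1L, dt = 0.01) {
  window <- match.arg(window)
  if (!is.matrix(R)) R <- matrix(R, nrow = 1L)
  Tn <- ncol(S)
  w <- max(1L, as.integer(floor(0.1 / dt + 1e-9)))   # bins per 100 ms window
  events <- events[events + 2L * w - 1L <= Tn]
  if (length(events) == 0L) {
    return(list(bank = NULL, aligned_mean = NULL, bins_used = integer(0)))
  }
  offset <- if (window == "transient") 0L else w
  bins <- unique(sort(unlist(lapply(events, function(e) seq.int(e + offset, e + offset + w - 1L)))))
  D <- lagged_design(S, delays)
  fit <- ridge_cv_multi(D[bins, , drop = FALSE], t(R)[bins, , drop = FALSE],
                        lambda_grid, n_folds)
  M <- nrow(S); nd <- length(delays); n <- nrow(R)
  W <- aperm(array(fit$W, c(nd, M, n)), c(2L, 1L, 3L))
  bank <- new_filter_bank("encoding", W, fit$intercepts, delays, dt,
                          ridge_lambda = fit$lambda, fit = fit)
  aligned <- array(0, c(n, 2L * w))
  for (e in events) aligned <- aligned + R[, e:(e + 2L * w - 1L), drop = FALSE]
  list(bank = bank, aligned_mean = aligned / length(events), bins_used = bins)
}

#' Mean normalized cross-covariance between predictions and responses
#'
#' Per-neuron cross-correlation coefficient as a function of lag (positive
#' lag = prediction leads), averaged over neurons, with a bootstrap
#' confidence band over neurons.
#'
#' @param pred,target `n_neurons x T` matrices, time-aligned.
#' @param max_lag_bins maximum absolute lag.
#' @param n_boot bootstrap resamples of neurons (0 disables the band).
#' @param conf confidence level for the band.
#' @param seed integer seed for the bootstrap.
#' @return list with `lags`, `mean` profile, and `lower`/`upper` band (or
#'   `NULL`).
#' @export
mean_cross_covariance <- function(pred, target, max_lag_bins = 20L,
                                  n_boot = 200L, conf = 0.95, seed = 1L) {
  if (!is.matrix(pred)) pred <- matrix(pred, nrow = 1L)
  if (!is.matrix(target)) target <- matrix(target, nrow = 1L)
  stopifnot(all(dim(pred) == dim(target)))
  lags <- -max_lag_bins:max_lag_bins
  n <- nrow(pred); Tn <- ncol(pred)
  prof <- matrix(0, n, length(lags))
  for (j in seq_len(n)) {
    for (k in seq_along(lags)) {
      l <- lags[k]
      if (l >= 0) {
        prof[j, k] <- safe_cor(pred[j, 1:(Tn - l)], target[j, (1 + l):Tn])
      } else {
        prof[j, k] <- safe_cor(pred[j, (1 - l):Tn], target[j, 1:(Tn + l)])
      }
    }
  }
  m <- colMeans(prof)
  lower <- upper <- NULL
  if (n_boot > 0L && n > 1L) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    bm <- replicate(n_boot, colMeans(prof[sample.int(n, n, replace = TRUE), , drop = FALSE]))
    a <- (1 - conf) / 2
    lower <- apply(bm, 1L, stats::quantile, probs = a)
    upper <- apply(bm, 1L, stats::quantile, probs = 1 - a)
  }
  list(lags = lags, mean = m, lower = lower, upper = upper)
}

#' Correlation of response derivatives
#'
#' Pearson correlation of the first or second finite differences of a
#' prediction and a target — a measure of how well the fast dynamics (rather
#' than the slow envelope) are captured.
#'
#' @param pred,target numeric vectors of equal length.
#' @param order derivative order, 1 or 2.
#' @return correlation coefficient.
#' @export
derivative_match <- function(pred, target, order = 1L) {
  stopifnot(length(pred) == length(target), order %in% c(1L, 2L))
  safe_cor(diff(pred, differences = order), diff(target, differences = order))
}
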