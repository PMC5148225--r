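# Internal helpers shared across modules.

logistic <- function(x) 1 / (1 + exp(-x))

#' Convert a switching rate in Hz to a per-bin probability
#'
#' Per-bin switching probabilities are `min(rate * dt, 1)`; rates are the
#' public parameterization so that the same `r_on`/`r_off` can be used at any
#' bin width.
#'
#' @param rate nonnegative switching rate in 1/s.
#' @param dt bin width in seconds.
#' @return probability in `[0, 1]`.
#' @keywords internal
rate_to_prob <- function(rate, dt) {
  stopifnot(rate >= 0, dt > 0)
  min(rate * dt, 1)
}

# Stationary on-probability of the two-state chain (same in rate or
# probability parameterization as long as both use the same units).
stationary_on_prob <- function(p_on, p_off) {
  if (p_on + p_off == 0) return(0.5)
  p_on / (p_on + p_off)
}

# Pearson correlation that returns 0 for degenerate (constant) inputs.
safe_cor <- function(x, y) {
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# Split 1:n into k contiguous blocks (for time-series cross-validation;
# shuffling bins would leak through temporal autocorrelation).
contiguous_folds <- function(n, k) {
  stopifnot(k >= 2L, n >= k)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) seq.int(starts[i], ends[i]))
}

#' Full width at half maximum of a 1-D filter
#'
#' Width of the positive lobe around the global maximum, in channel units,
#' with linear interpolation of the half-max crossings. Values never crossing
#' half max before the edge extend the width to the edge.
#'
#' @param v numeric vector (a frequency-only filter).
#' @return width in channels (>= 0); `NA` if `v` has no positive maximum.
#' @export
half_max_width <- function(v) {
  m <- max(v)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  peak <- which.max(v)
  half <- m / 2
  # walk left
  left <- 1
  if (peak > 1L) {
    for (i in seq(peak, 2L)) {
      if (v[i - 1L] < half) {
        left <- (i - 1L) + (half - v[i - 1L]) / (v[i] - v[i - 1L])
        break
      }
      left <- i - 1L
    }
  }
  right <- length(v)
  if (peak < length(v)) {
    for (i in seq(peak, length(v) - 1L)) {
      if (v[i + 1L] < half) {
        right <- i + (v[i] - half) / (v[i] - v[i + 1L])
        break
      }
      right <- i + 1L
    }
  }
  right - left
}

#' Fraction of filter mass within k octaves of the best frequency
#'
#' Quantifies tuning width as the share of absolute filter mass lying within
#' plus/minus `k` octaves of the peak channel, given the channel density in
#' channels per octave.
#'
#' @param v numeric vector (frequency-only filter).
#' @param channels_per_octave channel density (e.g. 5 for 30 channels
#'   spanning 6 octaves).
#' @param k half-width in octaves (1 or 2 in typical use).
#' @return fraction in `[0, 1]`.
#' @export
octave_mass <- function(v, channels_per_octave, k = 1) {
  stopifnot(channels_per_octave > 0, k > 0)
  bf <- which.max(v)
  half <- k * channels_per_octave
  idx <- seq_along(v)
  sel <- abs(idx - bf) <= half
  tot <- sum(abs(v))
  if (tot == 0) return(NA_real_)
  sum(abs(v[sel])) / tot
}

#' Log-spaced frequency channel centers
#'
#' @param n number of channels.
#' @param f_min,f_max frequency range in Hz.
#' @return numeric vector of center frequencies in Hz.
#' @export
log_spaced_channels <- function(n = 30, f_min = 125, f_max = 8000) {
  stopifnot(n >= 2, f_min > 0, f_max > f_min)
  exp(seq(log(f_min), log(f_max), length.out = n))
}

check_nonneg_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and nonnegative", name), call. = FALSE)
  }
  invisible(x)
}
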