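#' Parameters of the generative model of sounds
#'
#' The generative model assumes that auditory scenes are composed of `N`
#' elementary spectral features that switch on and off independently as
#' two-state Markov chains, and combine linearly to set the Poisson intensity
#' of `M` sensory receptors (frequency channels of a spectrogram):
#' \deqn{\lambda_i(t) = q_{i0} + \sum_j q_{ij} x_j(t)}
#' The nonnegative column `q[, j]` is the predictive field (PF) of feature
#' `j`: its contribution to every receptor. The baseline `q0` plays the role
#' of an always-on feature and is floored at a small positive value so that
#' likelihood ratios stay finite.
#'
#' Switching dynamics are parameterized by rates in 1/s (`r_on`, `r_off`) and
#' converted internally to per-bin probabilities `min(rate * dt, 1)`; at the
#' default 10 ms binning the defaults 1 Hz / 20 Hz give per-bin switching
#' probabilities 0.01 and 0.2.
#'
#' @param Q nonnegative numeric matrix, `M` receptors x `N` features.
#' @param q0 nonnegative baseline intensity per receptor (length `M`, or a
#'   scalar recycled); floored at `1e-6`.
#' @param r_on,r_off switch-on / switch-off rates in 1/s.
#' @param dt bin width in seconds.
#' @return an object of class `generative_params`.
#' @examples
#' gp <- generative_params(Q = matrix(c(2, 0), 2, 1), q0 = 0.1)
#' gp$p_on   # per-bin switch-on probability
#' @export
generative_params <- function(Q, q0 = 0.1, r_on = 1, r_off = 20, dt = 0.01) {
  check_nonneg_matrix(Q, "Q")
  M <- nrow(Q)
  q0 <- rep_len(as.numeric(q0), M)
  if (any(!is.finite(q0)) || any(q0 < 0)) stop("`q0` must be finite and nonnegative")
  q0 <- pmax(q0, 1e-6)
  if (r_on < 0 || r_off < 0) stop("`r_on` and `r_off` must be nonnegative rates (1/s)")
  stopifnot(dt > 0)
  p_on <- rate_to_prob(r_on, dt)
  p_off <- rate_to_prob(r_off, dt)
  structure(
    list(Q = Q, q0 = q0, r_on = r_on, r_off = r_off,
         p_on = p_on, p_off = p_off, dt = dt,
         n_receptors = M, n_features = ncol(Q)),
    class = "generative_params"
  )
}

#' @export
print.generative_params <- function(x, ...) {
  cat(sprintf(
    "Generative model: %d receptors x %d features; dt = %g s; r_on = %g Hz, r_off = %g Hz (per-bin p = %.3g / %.3g)\n",
    x$n_receptors, x$n_features, x$dt, x$r_on, x$r_off, x$p_on, x$p_off))
  invisible(x)
}

#' Sample binary feature trajectories
#'
#' Each feature evolves as an independent two-state Markov chain with per-bin
#' probabilities `P(off -> on) = p_on` and `P(on -> off) = p_off`. By default
#' the initial state is drawn from the chain's stationary distribution
#' `p_on / (p_on + p_off)`.
#'
#' @param params a [generative_params()] object.
#' @param n_bins number of time bins `T`.
#' @param seed integer seed; the trajectory is reproducible given the seed.
#' @param initial_state optional binary vector of length `N` overriding the
#'   stationary draw.
#' @return a `feature_trajectory`: list with binary matrix `X` (`N x T`) and
#'   `dt`.
#' @export
sample_features <- function(params, n_bins, seed = 1L, initial_state = NULL) {
  stopifnot(inherits(params, "generative_params"), n_bins >= 0)
  N <- params$n_features
  p_on <- params$p_on
  p_off <- params$p_off
  X <- matrix(0L, N, n_bins)
  if (n_bins > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    pi0 <- stationary_on_prob(p_on, p_off)
    state <- if (is.null(initial_state)) {
      as.integer(stats::runif(N) < pi0)
    } else {
      stopifnot(length(initial_state) == N, all(initial_state %in% c(0, 1)))
      as.integer(initial_state)
    }
    X[, 1L] <- state
    if (n_bins > 1) {
      U <- matrix(stats::runif(N * (n_bins - 1L)), N, n_bins - 1L)
      for (t in 2:n_bins) {
        u <- U[, t - 1L]
        state <- ifelse(state == 1L,
                        as.integer(u >= p_off),  # stay on with prob 1 - p_off
                        as.integer(u < p_on))    # turn on with prob p_on
        X[, t] <- state
      }
    }
  }
  structure(list(X = X, dt = params$dt), class = "feature_trajectory")
}

#' Receptor Poisson intensity for a feature configuration
#'
#' @param params a [generative_params()] object.
#' @param x binary feature vector of length `N`.
#' @return nonnegative intensity vector `lambda` of length `M` with
#'   `lambda_i = q0_i + sum_j q_ij x_j`.
#' @export
receptor_intensity <- function(params, x) {
  stopifnot(inherits(params, "generative_params"))
  if (length(x) != params$n_features) stop("feature vector length must equal the number of features")
  if (!all(x %in% c(0, 1))) stop("`x` must be binary")
  as.numeric(params$q0 + params$Q %*% x)
}

#' Sample Poisson receptor observations along a trajectory
#'
#' Spike counts are drawn independently per receptor and bin,
#' `S[i, t] ~ Poisson(lambda_i(t))`, with the intensity given by
#' [receptor_intensity()] at each bin.
#'
#' @param params a [generative_params()] object.
#' @param traj a `feature_trajectory` from [sample_features()].
#' @param seed integer seed.
#' @return a `receptor_observations`: list with count matrix `S` (`M x T`)
#'   and `dt`.
#' @export
sample_observations <- function(params, traj, seed = 1L) {
  stopifnot(inherits(params, "generative_params"), inherits(traj, "feature_trajectory"))
  if (nrow(traj$X) != params$n_features) stop("trajectory does not match params: feature count differs")
  Tn <- ncol(traj$X)
  Lam <- params$q0 + params$Q %*% traj$X   # M x T intensities
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  S <- matrix(stats::rpois(length(Lam), lambda = Lam), nrow(Lam), Tn)
  structure(list(S = S, dt = params$dt), class = "receptor_observations")
}
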