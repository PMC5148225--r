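#' Inference configuration
#'
#' Options for the online mean-field filter.
#'
#' @param epsilon_floor small positive floor applied to predicted-input
#'   denominators; with `q0 > 0` this is a no-op in normal operation.
#' @param use_log1p_exact if `TRUE` (default) the likelihood log-ratio uses
#'   the exact `log(1 + q/shat)` form; if `FALSE` the linearized form
#'   `q/shat` (valid for small arguments) is used.
#' @param gain positive global gain multiplying the stimulus before
#'   inference.
#' @return an `inference_config` object.
#' @export
inference_config <- function(epsilon_floor = 1e-9, use_log1p_exact = TRUE, gain = 1) {
  stopifnot(epsilon_floor > 0, gain > 0)
  structure(list(epsilon_floor = epsilon_floor,
                 use_log1p_exact = isTRUE(use_log1p_exact),
                 gain = gain),
            class = "inference_config")
}

#' Prior log-odds of a feature being on at the next bin
#'
#' The two-state Markov prior contributes
#' \deqn{\log\frac{p(1 - r^{off}) + (1-p) r^{on}}{p\, r^{off} + (1-p)(1 - r^{on})}}
#' to the next-bin log-odds, where `p` is the previous posterior on-probability
#' and the rates are per-bin probabilities.
#'
#' @param p_prev previous posterior on-probability in `[0, 1]` (vectorized).
#' @param r_on_bin,r_off_bin per-bin switching probabilities in `[0, 1]`.
#' @param epsilon_floor clamp keeping the ratio away from `0` and `Inf`.
#' @return prior log-odds (finite).
#' @export
prior_log_odds <- function(p_prev, r_on_bin, r_off_bin, epsilon_floor = 1e-9) {
  if (any(p_prev < 0 | p_prev > 1) || r_on_bin < 0 || r_on_bin > 1 ||
      r_off_bin < 0 || r_off_bin > 1) {
    stop("`p_prev`, `r_on_bin`, `r_off_bin` must lie in [0, 1]")
  }
  num <- p_prev * (1 - r_off_bin) + (1 - p_prev) * r_on_bin
  den <- p_prev * r_off_bin + (1 - p_prev) * (1 - r_on_bin)
  log(pmax(num, epsilon_floor)) - log(pmax(den, epsilon_floor))
}

#' Predicted input to receptors by all detectors except one
#'
#' The mean-field prediction of receptor `i` by every feature but `j`:
#' \deqn{\hat s_i^j = q_{i0} + \sum_{k \neq j} q_{ik} p_k}
#' This is the divisive explaining-away denominator: input already accounted
#' for by other detectors.
#'
#' @param Q nonnegative `M x N` predictive-field matrix.
#' @param q0 baseline vector length `M`.
#' @param p posterior on-probabilities, length `N`.
#' @param j feature index (1-based).
#' @param epsilon_floor floor for the result.
#' @return nonnegative vector of length `M`.
#' @export
predicted_input <- function(Q, q0, p, j, epsilon_floor = 1e-9) {
  stopifnot(j >= 1, j <= ncol(Q), length(p) == ncol(Q), all(p >= 0 & p <= 1))
  shat <- q0 + Q %*% p - Q[, j] * p[j]
  pmax(as.numeric(shat), epsilon_floor)
}

# All-features predicted-input matrix: column j is predicted_input(..., j).
predicted_input_matrix <- function(Q, q0, p, epsilon_floor = 1e-9) {
  lam <- as.numeric(q0 + Q %*% p)          # M
  Shat <- lam - Q * rep(p, each = nrow(Q)) # M x N: remove own contribution
  pmax(Shat, epsilon_floor)
}

#' Log likelihood ratio (new evidence) for one feature
#'
#' The mean-field log-likelihood ratio of feature `j` being on versus off
#' given the current receptor observations:
#' exact form \eqn{\sum_i [ s_i \log(1 + q_{ij}/\hat s_i^j) - q_{ij} ]};
#' linearized form \eqn{\sum_i [ s_i q_{ij}/\hat s_i^j - q_{ij} ]}.
#'
#' @param s_t nonnegative observation vector (length `M`); real values
#'   (trial-averaged rates) are accepted.
#' @param Q,q0 model parameters.
#' @param p posterior on-probabilities of all features (previous bin).
#' @param j feature index.
#' @param config an [inference_config()].
#' @return scalar log evidence ratio.
#' @export
evidence_log_ratio <- function(s_t, Q, q0, p, j, config = inference_config()) {
  stopifnot(length(s_t) == nrow(Q))
  shat <- predicted_input(Q, q0, p, j, config$epsilon_floor)
  qj <- Q[, j]
  if (config$use_log1p_exact) {
    sum(s_t * log1p(qj / shat)) - sum(qj)
  } else {
    sum(s_t * qj / shat) - sum(qj)
  }
}

#' Rectified firing-rate readout of a feature detector
#'
#' Detector activity is proportional to the rectified new evidence (the
#' linearized log-likelihood ratio), equivalently the divisive
#' predictive-coding form
#' \deqn{f_j = \Big[\sum_i q_{ij}\,(s_i/\hat s_i^j - 1)\Big]_+}
#' where \eqn{s_i/\hat s_i^j - 1} is the fractional prediction error of
#' receptor `i`: when other detectors perfectly predict a receptor
#' (`s_i = shat_i`), its contribution is completely cancelled.
#'
#' @inheritParams evidence_log_ratio
#' @return nonnegative scalar firing rate.
#' @export
firing_rate <- function(s_t, Q, q0, p, j, config = inference_config()) {
  stopifnot(length(s_t) == nrow(Q))
  shat <- predicted_input(Q, q0, p, j, config$epsilon_floor)
  qj <- Q[, j]
  max(sum(s_t * qj / shat - qj), 0)
}

#' One synchronous step of the online mean-field filter
#'
#' All detectors are updated from the same previous-bin posterior
#' (synchronous update): with `p = logistic(L_prev)`,
#' `L_j(t) = evidence_log_ratio_j(s_t; p) + prior_log_odds(p_j)`, and the
#' firing-rate readout also uses the previous-bin `p` inside the
#' explaining-away denominator.
#'
#' @param L_prev finite log-odds vector, length `N`.
#' @param s_t observation vector, length `M` (already gain-scaled by the
#'   caller, or pass through [run_inference()]).
#' @param params a [generative_params()] object.
#' @param config an [inference_config()].
#' @param no_inhibition if `TRUE`, the explaining-away denominator is the
#'   baseline `q0` (feedforward model without inhibition).
#' @return list with vectors `L`, `p`, `f`.
#' @export
inference_step <- function(L_prev, s_t, params, config = inference_config(),
                           no_inhibition = FALSE) {
  if (any(!is.finite(L_prev))) stop("`L_prev` must be finite")
  if (any(!is.finite(s_t))) stop("`s_t` must be finite")
  Q <- params$Q
  q0 <- params$q0
  N <- ncol(Q)
  stopifnot(length(L_prev) == N, length(s_t) == nrow(Q))
  p_prev <- logistic(L_prev)
  Shat <- if (no_inhibition) {
    matrix(pmax(q0, config$epsilon_floor), nrow(Q), N)
  } else {
    predicted_input_matrix(Q, q0, p_prev, config$epsilon_floor)
  }
  qsum <- colSums(Q)
  if (config$use_log1p_exact) {
    logA <- colSums(s_t * log1p(Q / Shat)) - qsum
  } else {
    logA <- colSums(s_t * Q / Shat) - qsum
  }
  prior <- prior_log_odds(p_prev, params$p_on, params$p_off, config$epsilon_floor)
  L <- logA + prior
  f <- pmax(colSums(s_t * Q / Shat) - qsum, 0)
  list(L = L, p = logistic(L), f = f)
}

run_filter <- function(S, params, config, no_inhibition) {
  check_nonneg_matrix(S, "S")
  Tn <- ncol(S)
  N <- params$n_features
  L <- matrix(NA_real_, N, Tn)
  P <- matrix(NA_real_, N, Tn)
  F <- matrix(NA_real_, N, Tn)
  pi0 <- stationary_on_prob(params$p_on, params$p_off)
  pi0 <- min(max(pi0, config$epsilon_floor), 1 - config$epsilon_floor)
  L_prev <- rep(log(pi0 / (1 - pi0)), N)
  g <- config$gain
  for (t in seq_len(Tn)) {
    st <- inference_step(L_prev, g * S[, t], params, config, no_inhibition)
    L[, t] <- st$L
    P[, t] <- st$p
    F[, t] <- st$f
    L_prev <- st$L
  }
  structure(list(L = L, P = P, F = F, dt = params$dt,
                 no_inhibition = no_inhibition),
            class = "detector_trace")
}

#' Run the online mean-field filter over a stimulus
#'
#' Filters the whole observation matrix bin by bin, starting from the
#' stationary prior log-odds. Returns log-odds `L`, posteriors `P`
#' (`P = logistic(L)` at every bin) and rectified firing rates `F`, each
#' `N x T`.
#'
#' @param S nonnegative `M x T` observation matrix (spectrogram or receptor
#'   counts), or a `receptor_observations` object.
#' @param params a [generative_params()] object.
#' @param config an [inference_config()]; `config$gain` scales `S` before
#'   inference.
#' @return a `detector_trace` object.
#' @export
run_inference <- function(S, params, config = inference_config()) {
  if (inherits(S, "receptor_observations")) S <- S$S
  run_filter(S, params, config, no_inhibition = FALSE)
}

#' Run the feedforward model without inhibition
#'
#' Identical recursion to [run_inference()] except that the explaining-away
#' denominator is the baseline intensity `q0`, never other detectors'
#' predictions: detectors do not inhibit each other.
#'
#' @inheritParams run_inference
#' @return a `detector_trace` object.
#' @export
run_no_inhibition <- function(S, params, config = inference_config()) {
  if (inherits(S, "receptor_observations")) S <- S$S
  run_filter(S, params, config, no_inhibition = TRUE)
}

#' Exact forward filter over all joint feature configurations
#'
#' Brute-force hidden Markov forward filtering over all `2^N` joint binary
#' configurations (transition kernel the product of independent two-state
#' chains, emission the product-Poisson likelihood with
#' `lambda_i = q0_i + sum_k q_ik x_k`), returning the exact posterior
#' marginals `P(x_j(t) = 1 | s_{1..t})`. Used as an oracle to validate the
#' mean-field filter; refuses `N` above the enumeration guard.
#'
#' @inheritParams run_inference
#' @param max_features enumeration guard (default 12).
#' @return `N x T` matrix of exact posterior marginals.
#' @export
exact_filter_oracle <- function(S, params, config = inference_config(),
                                max_features = 12L) {
  if (inherits(S, "receptor_observations")) S <- S$S
  check_nonneg_matrix(S, "S")
  N <- params$n_features
  if (N > max_features) {
    stop(sprintf("exact filtering enumerates 2^N configurations; N = %d exceeds the guard (%d)",
                 N, max_features))
  }
  Tn <- ncol(S)
  n_cfg <- 2L^N
  # configurations as rows of a (2^N x N) binary matrix
  X <- as.matrix(expand.grid(rep(list(0:1), N)))
  storage.mode(X) <- "double"
  Lam <- params$q0 + params$Q %*% t(X)                 # M x 2^N
  logLam <- log(Lam)
  p_on <- params$p_on; p_off <- params$p_off
  # per-feature transition probs; joint transition = product over features
  trans1 <- function(from, to) {
    ifelse(from == 1,
           ifelse(to == 1, 1 - p_off, p_off),
           ifelse(to == 1, p_on, 1 - p_on))
  }
  Tr <- matrix(1, n_cfg, n_cfg)
  for (j in seq_len(N)) {
    Tr <- Tr * outer(X[, j], X[, j], trans1)
  }
  pi1 <- stationary_on_prob(p_on, p_off)
  alpha <- apply(X, 1L, function(x) prod(ifelse(x == 1, pi1, 1 - pi1)))
  marg <- matrix(NA_real_, N, Tn)
  g <- config$gain
  for (t in seq_len(Tn)) {
    s <- g * S[, t]
    pred <- as.numeric(crossprod(Tr, alpha))           # sum_x' alpha(x') P(x | x')
    loglik <- as.numeric(crossprod(logLam, s)) - colSums(Lam)
    logw <- log(pmax(pred, .Machine$double.xmin)) + loglik
    w <- exp(logw - max(logw))
    alpha <- w / sum(w)
    marg[, t] <- as.numeric(crossprod(X, alpha))
  }
  marg
}
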