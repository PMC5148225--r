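#' Learning configuration for predictive-field EM
#'
#' @param learning_rate positive stochastic-gradient step size; default
#'   `1e-3`, the simplest fixed schedule under which the per-epoch mean
#'   log-likelihood is non-decreasing on the reference fixtures.
#' @param n_epochs number of passes over the stimulus; the single-pass
#'   online mode is `n_epochs = 1`.
#' @param seed integer seed (used by random initialization).
#' @param init_mode one of `"random_bump"` (uniform noise plus a Gaussian
#'   bump at a designated center per feature), `"flat_random"` (uniform
#'   noise only), or `"given"` (use the supplied matrix unchanged).
#' @param bump_center optional integer channel index per feature for
#'   `"random_bump"`.
#' @param bump_width Gaussian bump standard deviation in channels.
#' @param decay if `TRUE`, the step size decays as `1/epoch`.
#' @return a `learning_config` object.
#' @export
learning_config <- function(learning_rate = 1e-3, n_epochs = 1L, seed = 1L,
                            init_mode = c("given", "random_bump", "flat_random"),
                            bump_center = NULL, bump_width = 2, decay = FALSE) {
  stopifnot(learning_rate > 0, n_epochs >= 1)
  structure(list(learning_rate = learning_rate, n_epochs = as.integer(n_epochs),
                 seed = as.integer(seed), init_mode = match.arg(init_mode),
                 bump_center = bump_center, bump_width = bump_width,
                 decay = isTRUE(decay)),
            class = "learning_config")
}

#' Random-bump initialization of a predictive-field matrix
#'
#' Uniform noise in `[0, 0.1 * peak]` plus a Gaussian bump (sd
#' `bump_width` channels, height `peak`) at each designated center — a weak
#' hint of where each feature's spectral energy lies, leaving the shape to be
#' learned.
#'
#' @param n_receptors number of frequency channels `M`.
#' @param centers integer channel index per feature (length `N`).
#' @param bump_width bump standard deviation in channels.
#' @param peak bump height.
#' @param seed integer seed.
#' @return nonnegative `M x N` matrix.
#' @export
init_pf_bump <- function(n_receptors, centers, bump_width = 2, peak = 1, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  N <- length(centers)
  noise <- matrix(stats::runif(n_receptors * N, 0, 0.1 * peak), n_receptors, N)
  bumps <- sapply(centers, function(c0) {
    peak * exp(-((seq_len(n_receptors) - c0)^2) / (2 * bump_width^2))
  })
  noise + bumps
}

#' M-step gradient of the expected complete-data log-likelihood
#'
#' Gradient of the Poisson log-likelihood of the observations given the
#' expected feature activations:
#' \deqn{G_{ij} = \sum_t p_j(t)\,\big(s_i(t)/\hat\lambda_i(t) - 1\big),
#' \qquad \hat\lambda_i(t) = q_{i0} + \sum_k q_{ik} p_k(t).}
#' At the likelihood's maximum this gradient is zero.
#'
#' @param S `M x T` observation matrix.
#' @param P_trace `N x T` matrix of posterior on-probabilities (E-step
#'   output, or ground-truth states for oracle checks).
#' @param Q,q0 current parameters.
#' @param epsilon_floor floor for `lambda_hat`.
#' @return `M x N` gradient matrix.
#' @export
m_step_gradient <- function(S, P_trace, Q, q0, epsilon_floor = 1e-9) {
  stopifnot(nrow(S) == nrow(Q), nrow(P_trace) == ncol(Q), ncol(S) == ncol(P_trace))
  LamHat <- pmax(q0 + Q %*% P_trace, epsilon_floor)   # M x T
  E <- S / LamHat - 1                                  # M x T prediction errors
  E %*% t(P_trace)                                     # M x N
}

#' Learn predictive fields by online expectation-maximization
#'
#' Alternates one mean-field inference step (E) with one stochastic-gradient
#' ascent step on the Poisson likelihood (M) per time bin. After every
#' gradient step the weights are clipped at zero: if an entry becomes
#' negative it is assigned to zero, keeping the predictive fields
#' nonnegative. The baseline `q0` is held fixed; only `Q` is learned.
#'
#' @param S `M x T` observation matrix (the stimulus spectrogram).
#' @param initial_Q nonnegative `M x N` starting point (ignored unless
#'   `learn_config$init_mode == "given"`).
#' @param q0 baseline vector (length `M` or scalar).
#' @param params a [generative_params()] carrying the switching rates and
#'   `dt` (its `Q` slot is ignored; the learned `Q` evolves).
#' @param learn_config a [learning_config()].
#' @param inference_config an [inference_config()].
#' @param inhibition if `TRUE` the E-step uses the intact explaining-away
#'   model; if `FALSE`, the feedforward no-inhibition variant.
#' @return list with `Q` (learned matrix), `objective` (per-epoch mean
#'   per-bin log-likelihood, up to the `lgamma(s+1)` constant), and
#'   `params` (a [generative_params()] wrapping the learned `Q`).
#' @export
online_em <- function(S, initial_Q, q0, params, learn_config = learning_config(),
                      inference_config = predecode::inference_config(),
                      inhibition = TRUE) {
  check_nonneg_matrix(S, "S")
  M <- nrow(S); Tn <- ncol(S)
  Q <- switch(learn_config$init_mode,
    given = {
      check_nonneg_matrix(initial_Q, "initial_Q")
      initial_Q
    },
    random_bump = {
      if (is.null(learn_config$bump_center)) stop("`bump_center` required for random_bump init")
      init_pf_bump(M, learn_config$bump_center, learn_config$bump_width,
                   peak = 1, seed = learn_config$seed)
    },
    flat_random = {
      old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
      set.seed(learn_config$seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      matrix(stats::runif(M * ncol(initial_Q), 0, 0.1), M, ncol(initial_Q))
    })
  N <- ncol(Q)
  q0 <- pmax(rep_len(as.numeric(q0), M), 1e-6)
  eps <- inference_config$epsilon_floor
  g <- inference_config$gain
  eta0 <- learn_config$learning_rate
  pi0 <- stationary_on_prob(params$p_on, params$p_off)
  pi0 <- min(max(pi0, eps), 1 - eps)
  objective <- numeric(learn_config$n_epochs)
  gp <- generative_params(Q, q0, params$r_on, params$r_off, params$dt)
  for (epoch in seq_len(learn_config$n_epochs)) {
    eta <- if (learn_config$decay) eta0 / epoch else eta0
    L_prev <- rep(log(pi0 / (1 - pi0)), N)
    obj <- 0
    for (t in seq_len(Tn)) {
      s_t <- g * S[, t]
      gp$Q <- Q   # constructor checks skipped in the hot loop; Q stays >= 0 by clipping
      st <- inference_step(L_prev, s_t, gp, inference_config,
                           no_inhibition = !inhibition)
      p_t <- st$p
      lam_hat <- pmax(q0 + as.numeric(Q %*% p_t), eps)
      obj <- obj + sum(s_t * log(lam_hat) - lam_hat)
      G_t <- (s_t / lam_hat - 1) %o% p_t          # M x N rank-one gradient
      Q <- pmax(Q + eta * G_t, 0)
      L_prev <- st$L
    }
    objective[epoch] <- obj / Tn
    if (!is.finite(objective[epoch])) {
      stop(sprintf("online_em diverged at epoch %d (non-finite objective); reduce the learning rate", epoch))
    }
  }
  list(Q = Q, objective = objective,
       params = generative_params(Q, q0, params$r_on, params$r_off, params$dt))
}

#' Match learned predictive fields to a reference set
#'
#' Finds the one-to-one assignment of learned columns to reference columns
#' maximizing the summed Pearson correlation (exact search over permutations
#' for up to 8 features, greedy above), and reports the per-pair
#' correlations. Ties are broken toward the lowest index.
#'
#' @param Q_learned,Q_true matrices with the same number of rows; `Q_true`
#'   may have a different number of columns (the smaller side is matched).
#' @return list with `cc` (per-matched-pair correlation), `assignment`
#'   (integer vector: `assignment[j]` is the `Q_true` column matched to
#'   learned column `j`, `NA` if unmatched), and `mean_cc`.
#' @export
pf_recovery_score <- function(Q_learned, Q_true) {
  stopifnot(nrow(Q_learned) == nrow(Q_true))
  nl <- ncol(Q_learned); nt <- ncol(Q_true)
  C <- matrix(0, nl, nt)
  for (j in seq_len(nl)) for (k in seq_len(nt)) {
    C[j, k] <- safe_cor(Q_learned[, j], Q_true[, k])
  }
  n_small <- min(nl, nt)
  if (n_small <= 8L) {
    # exact: enumerate injections of the smaller index set into the larger
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
      }
      out
    }
    if (nl <= nt) {
      cand <- utils::combn(nt, nl, simplify = FALSE)
      best <- NULL; best_val <- -Inf
      for (cols in cand) for (pp in perms(cols)) {
        val <- sum(C[cbind(seq_len(nl), pp)])
        if (val > best_val + 1e-12) { best_val <- val; best <- pp }
      }
      assignment <- best
    } else {
      cand <- utils::combn(nl, nt, simplify = FALSE)
      best <- NULL; best_val <- -Inf
      for (rows in cand) for (pp in perms(rows)) {
        val <- sum(C[cbind(pp, seq_len(nt))])
        if (val > best_val + 1e-12) { best_val <- val; best <- pp }
      }
      assignment <- rep(NA_integer_, nl)
      assignment[best] <- seq_len(nt)
    }
  } else {
    # greedy by decreasing correlation
    assignment <- rep(NA_integer_, nl)
    free_l <- rep(TRUE, nl); free_t <- rep(TRUE, nt)
    ord <- order(-C)
    for (idx in ord) {
      j <- (idx - 1L) %% nl + 1L
      k <- (idx - 1L) %/% nl + 1L
      if (free_l[j] && free_t[k]) {
        assignment[j] <- k
        free_l[j] <- FALSE; free_t[k] <- FALSE
        if (!any(free_l) || !any(free_t)) break
      }
    }
  }
  matched <- which(!is.na(assignment))
  cc <- C[cbind(matched, assignment[matched])]
  list(cc = cc, assignment = assignment, mean_cc = mean(cc))
}
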