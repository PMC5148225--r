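#' Write a matrix container (CSV + JSON metadata sidecar)
#'
#' Containers are plain CSV matrices with a sidecar `<path>.json` carrying
#' the required metadata: `dt` (bin width in seconds), `kind`
#' (`"spectrogram"`, `"responses"`, `"pf"`, ...), and optionally the channel
#' center frequencies. Values are written at full double precision.
#'
#' @param x numeric matrix (rows = channels/neurons, columns = time bins).
#' @param path output CSV path; metadata goes to `paste0(path, ".json")`.
#' @param dt bin width in seconds (required metadata).
#' @param kind free-form container kind tag.
#' @param channels optional numeric vector of channel center frequencies
#'   (Hz).
#' @return `path`, invisibly.
#' @export
write_matrix_container <- function(x, path, dt, kind = "matrix", channels = NULL) {
  stopifnot(is.matrix(x), is.numeric(dt), dt > 0)
  utils::write.table(format(x, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(dt = dt, kind = kind, n_rows = nrow(x), n_cols = ncol(x))
  if (!is.null(channels)) meta$channels <- channels
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a matrix container
#'
#' Reads a CSV matrix written by [write_matrix_container()] and validates
#' its metadata sidecar; schema violations name the missing attribute.
#'
#' @param path CSV path.
#' @return list with `x` (matrix), `dt`, `kind`, `channels` (or `NULL`).
#' @export
read_matrix_container <- function(path) {
  if (!file.exists(path)) stop(sprintf("container not found: %s", path))
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop(sprintf("missing metadata sidecar: %s", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("dt", "kind")) {
    if (is.null(meta[[field]])) {
      stop(sprintf("container schema violation in %s: missing attribute '%s'", meta_path, field))
    }
  }
  x <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(x) <- NULL
  list(x = x, dt = meta$dt, kind = meta$kind, channels = meta$channels)
}

#' End-to-end cross-validated response prediction
#'
#' The full pipeline comparing the Bayesian decoding models against the
#' reduced encoding (SRF) model on a stimulus/response pair: the data are
#' divided into contiguous folds over time; on each training set,
#' frequency-only decoding filters are extracted ([extract_pf()]) and
#' plugged into the model as predictive fields; the intact and
#' no-inhibition models are run on the gain-scaled stimulus; an SRF model is
#' fitted on the training bins; per neuron and model, the response delay is
#' optimized on the training set only and then held fixed to score held-out
#' correlation and derivative correlations on the test set, averaged over
#' folds.
#'
#' @param S `M x T` stimulus spectrogram.
#' @param R `n_neurons x T` trial-averaged responses.
#' @param dt bin width in seconds.
#' @param r_on,r_off global switching rates (1/s) shared by all model
#'   neurons.
#' @param n_folds_outer contiguous outer folds (default 10).
#' @param n_folds_inner inner folds for ridge penalties (default 5).
#' @param delay_scan_ms response-delay scan in ms.
#' @param pf_delay_scan delays (bins) scanned when extracting predictive
#'   fields.
#' @param lambda_grid ridge penalty grid.
#' @param srf_delay fixed delay (bins) at which the SRF is estimated.
#' @param seed integer seed (the pipeline is deterministic given the seed).
#' @param models subset of `c("intact", "no_inhibition", "srf")` to run.
#' @param gain_grid candidate global gains; the gain maximizing the mean
#'   training-set response correlation on the first fold is chosen once
#'   (the gain is a global fit parameter, like `r_on`/`r_off`) and reused.
#'   Pass a single value to fix the gain.
#' @return list with `summary` (data frame: model, mean test cc, mean
#'   derivative-cc of orders 1 and 2), `per_fold` (list of per-fold,
#'   per-neuron scores), and `gain` (chosen per model).
#' @export
run_predict <- function(S, R, dt = 0.01, r_on = 1, r_off = 20,
                        gain_grid = c(0.05, 0.1, 0.2, 0.5, 1),
                        n_folds_outer = 10L, n_folds_inner = 5L,
                        delay_scan_ms = seq(0, 200, 10), pf_delay_scan = 0:10,
                        lambda_grid = default_lambda_grid(), srf_delay = 0L,
                        seed = 1L, models = c("intact", "no_inhibition", "srf")) {
  if (!is.matrix(R)) R <- matrix(R, nrow = 1L)
  if (ncol(S) != ncol(R)) stop("stimulus and responses must be time-aligned (equal bin counts)")
  if (nrow(R) == 0L || all(R == 0)) stop("empty response matrix")
  Tn <- ncol(S)
  max_delay <- as.integer(round(max(delay_scan_ms) / (1000 * dt)))
  folds <- contiguous_folds(Tn, n_folds_outer)
  if (min(lengths(folds)) <= max_delay) {
    stop(sprintf("fold too short for the delay scan: need more than %d bins per fold", max_delay))
  }
  n <- nrow(R)
  per_fold <- vector("list", n_folds_outer)
  chosen_gain <- list()
  for (f in seq_len(n_folds_outer)) {
    test <- folds[[f]]; train <- setdiff(seq_len(Tn), test)
    scores <- list()
    preds <- list()
    if (any(c("intact", "no_inhibition") %in% models)) {
      pfx <- extract_pf(R[, train, drop = FALSE], S[, train, drop = FALSE],
                        lambda_grid = lambda_grid, n_folds = n_folds_inner,
                        delay_scan = pf_delay_scan, seed = seed, dt = dt)
      params <- generative_params(pfx$pf, q0 = 0.1, r_on = r_on, r_off = r_off, dt = dt)
      for (m in intersect(models, c("intact", "no_inhibition"))) {
        runner <- if (m == "intact") run_inference else run_no_inhibition
        if (f == 1L) {
          # global gain fit: one scan on the first training set
          best <- NULL; best_cc <- -Inf
          for (g in gain_grid) {
            Fm <- runner(S, params, inference_config(gain = g))$F
            cc <- mean(vapply(seq_len(n), function(j) safe_cor(Fm[j, train], R[j, train]), 0))
            if (is.finite(cc) && cc > best_cc) { best_cc <- cc; best <- list(g = g, F = Fm) }
          }
          chosen_gain[[m]] <- best$g
          preds[[m]] <- best$F
        } else {
          preds[[m]] <- runner(S, params, inference_config(gain = chosen_gain[[m]]))$F
        }
      }
    }
    if ("srf" %in% models) {
      srf <- estimate_srf(S[, train, drop = FALSE], R[, train, drop = FALSE],
                          fixed_delay = srf_delay, lambda_grid = lambda_grid,
                          n_folds = n_folds_inner, seed = seed, dt = dt)
      preds$srf <- predict_encoding(srf, S, rectify = TRUE)
    }
    for (m in names(preds)) {
      P <- preds[[m]]
      cc <- d1 <- d2 <- numeric(n)
      for (j in seq_len(n)) {
        od <- optimal_response_delay(P[j, train], R[j, train],
                                     scan_ms = delay_scan_ms, dt = dt)
        d <- od$delay_bins
        cc[j] <- delayed_cc(P[j, test], R[j, test], d)
        pt <- P[j, test]; rt <- R[j, test]
        if (d > 0) { pt <- pt[1:(length(pt) - d)]; rt <- rt[(1 + d):length(rt)] }
        d1[j] <- derivative_match(pt, rt, 1L)
        d2[j] <- derivative_match(pt, rt, 2L)
      }
      scores[[m]] <- data.frame(neuron = seq_len(n), cc = cc, dcc1 = d1, dcc2 = d2)
    }
    per_fold[[f]] <- scores
  }
  models_run <- names(per_fold[[1L]])
  summary <- do.call(rbind, lapply(models_run, function(m) {
    cc <- rowMeans(sapply(per_fold, function(s) s[[m]]$cc))
    d1 <- rowMeans(sapply(per_fold, function(s) s[[m]]$dcc1))
    d2 <- rowMeans(sapply(per_fold, function(s) s[[m]]$dcc2))
    data.frame(model = m, cc = mean(cc), dcc1 = mean(d1), dcc2 = mean(d2))
  }))
  list(summary = summary, per_fold = per_fold, gain = chosen_gain)
}

#' Compare stimulus reconstruction through real-response decoding filters
#'
#' The reconstruction comparison: full decoding filters are fitted on the
#' recorded responses (training segment); model responses (intact,
#' no-inhibition, SRF predictions) are then passed through those same
#' decoding filters and the reconstruction accuracy on the held-out segment
#' is compared with the reconstruction from the recorded responses
#' themselves.
#'
#' @param S `M x T` stimulus spectrogram.
#' @param R `n_neurons x T` recorded (trial-averaged) responses.
#' @param dt bin width in seconds.
#' @param r_on,r_off model switching rates (1/s).
#' @param gain_grid candidate global gains, fitted on the training segment
#'   by response correlation.
#' @param train_frac fraction of the time axis used for fitting; the rest
#'   is the held-out evaluation segment.
#' @param decoding_delays delays (bins) of the full decoding filters.
#' @param pf_delay_scan delays scanned when extracting predictive fields.
#' @param lambda_grid,n_folds_inner,seed ridge options.
#' @param srf_delay fixed SRF delay (bins).
#' @return list with `cc` (named vector: `real`, `intact`, `no_inhibition`,
#'   `srf` held-out reconstruction correlations) and `gain` (chosen per
#'   model).
#' @export
compare_reconstruction <- function(S, R, dt = 0.01, r_on = 1, r_off = 20,
                                   gain_grid = c(0.05, 0.1, 0.2, 0.5, 1),
                                   train_frac = 0.8, decoding_delays = 0:5,
                                   pf_delay_scan = 0:3,
                                   lambda_grid = default_lambda_grid(),
                                   n_folds_inner = 5L, srf_delay = 0L, seed = 1L) {
  if (!is.matrix(R)) R <- matrix(R, nrow = 1L)
  Tn <- ncol(S)
  train <- seq_len(round(train_frac * Tn))
  test <- setdiff(seq_len(Tn), train)
  dec <- estimate_decoding_filters(R[, train, drop = FALSE], S[, train, drop = FALSE],
                                   delays = decoding_delays, lambda_grid = lambda_grid,
                                   n_folds = n_folds_inner, seed = seed, dt = dt)
  pfx <- extract_pf(R[, train, drop = FALSE], S[, train, drop = FALSE],
                    lambda_grid = lambda_grid, n_folds = n_folds_inner,
                    delay_scan = pf_delay_scan, seed = seed, dt = dt)
  params <- generative_params(pfx$pf, q0 = 0.1, r_on = r_on, r_off = r_off, dt = dt)
  n <- nrow(R)
  fit_gain <- function(runner) {
    best <- NULL; best_cc <- -Inf
    for (g in gain_grid) {
      Fm <- runner(S, params, inference_config(gain = g))$F
      cc <- mean(vapply(seq_len(n), function(j) safe_cor(Fm[j, train], R[j, train]), 0))
      if (is.finite(cc) && cc > best_cc) { best_cc <- cc; best <- list(g = g, F = Fm) }
    }
    best
  }
  bi <- fit_gain(run_inference)
  bn <- fit_gain(run_no_inhibition)
  srf <- estimate_srf(S[, train, drop = FALSE], R[, train, drop = FALSE],
                      fixed_delay = srf_delay, lambda_grid = lambda_grid,
                      n_folds = n_folds_inner, seed = seed, dt = dt)
  Fs <- predict_encoding(srf, S, rectify = TRUE)
  cc_of <- function(Fm) {
    reconstruction_cc(S[, test, drop = FALSE],
                      reconstruct_stimulus(Fm, dec)[, test, drop = FALSE])
  }
  list(cc = c(real = cc_of(R), intact = cc_of(bi$F),
              no_inhibition = cc_of(bn$F), srf = cc_of(Fs)),
       gain = c(intact = bi$g, no_inhibition = bn$g))
}
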