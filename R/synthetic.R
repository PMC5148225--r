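#' Specification of a synthetic fixture
#'
#' Describes the stimulus regime emulated by the synthetic-data generator:
#' a spectrogram with 30 logarithmically spaced channels between 125 and
#' 8000 Hz, binned at 10 ms, driven by speech-like localized on/off spectral
#' events presented over several trials (default 5). Feature switching uses
#' the model's standard rates (1 Hz on, 20 Hz off).
#'
#' @param n_channels number of frequency channels (>= 4).
#' @param dt bin width in seconds.
#' @param n_features number of hidden features.
#' @param shape `"gaussian_bump"` or `"harmonic_stack"` (fundamental plus
#'   two harmonics, for speech-likeness).
#' @param overlap overlap factor in `[0, 1]`: 0 gives disjoint supports, 1
#'   makes adjacent features share at least half their mass.
#' @param duration_s stimulus duration in seconds.
#' @param n_trials number of trials for neuron banks.
#' @param r_on,r_off switching rates in 1/s.
#' @param q_peak peak predictive-field weight (per-bin intensity added by a
#'   feature at its preferred channel).
#' @param q0 baseline intensity per bin.
#' @param seed integer seed.
#' @return a `fixture_spec` object.
#' @export
fixture_spec <- function(n_channels = 30L, dt = 0.01, n_features = 5L,
                         shape = c("gaussian_bump", "harmonic_stack"),
                         overlap = 0, duration_s = 50, n_trials = 5L,
                         r_on = 1, r_off = 20, q_peak = 5, q0 = 0.1,
                         seed = 1L) {
  stopifnot(n_channels >= 4L, duration_s > 0, overlap >= 0, overlap <= 1,
            n_features >= 1L, q_peak > 0)
  structure(list(n_channels = as.integer(n_channels), dt = dt,
                 n_features = as.integer(n_features), shape = match.arg(shape),
                 overlap = overlap, duration_s = duration_s,
                 n_trials = as.integer(n_trials), r_on = r_on, r_off = r_off,
                 q_peak = q_peak, q0 = q0, seed = as.integer(seed),
                 channels = log_spaced_channels(n_channels),
                 n_bins = as.integer(round(duration_s / dt))),
            class = "fixture_spec")
}

#' Generate a ground-truth predictive-field set
#'
#' Gaussian-bump columns with controlled pairwise overlap, or harmonic
#' stacks (a fundamental bump plus bumps one and roughly 1.58 octaves above,
#' the second and third harmonics on a log-frequency axis). Columns are
#' normalized to unit maximum and scaled by `q_peak`. With `overlap = 0`
#' supports are hard-truncated to disjoint channel blocks; as overlap grows
#' the bumps widen beyond their blocks so adjacent features share mass.
#'
#' @param spec a [fixture_spec()].
#' @return nonnegative `n_channels x n_features` matrix.
#' @export
make_pf_set <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  M <- spec$n_channels; N <- spec$n_features
  block <- M / N
  if (block < 2 && spec$overlap == 0) {
    stop(sprintf("disjoint supports infeasible: %d features need at least %d channels", N, 2L * N))
  }
  centers <- (seq_len(N) - 0.5) * block
  # width: sd grows from block/5 (well separated) to block/1.2 (heavy sharing);
  # floored at one channel so dense banks (N approaching or exceeding M) keep
  # resolvable bumps
  sd0 <- block / 5
  sdv <- max(sd0 + spec$overlap * (block / 1.2 - sd0), 1)
  ch <- seq_len(M)
  bump <- function(c0, s) exp(-((ch - c0)^2) / (2 * s^2))
  Q <- sapply(seq_len(N), function(j) {
    v <- bump(centers[j], sdv)
    if (spec$shape == "harmonic_stack") {
      cpo <- (M - 1) / log2(spec$channels[M] / spec$channels[1])  # channels per octave
      v <- v + 0.6 * bump(centers[j] + cpo, sdv) + 0.4 * bump(centers[j] + cpo * log2(3), sdv)
    }
    if (spec$overlap == 0) {
      lo <- ceiling((j - 1) * block + 1e-9); hi <- floor(j * block)
      v[ch < lo | ch > hi] <- 0
    }
    v
  })
  Q <- sweep(Q, 2L, apply(Q, 2L, max), `/`) * spec$q_peak
  Q
}

#' Generate a synthetic spectrogram with known hidden features
#'
#' Samples the feature trajectories with the spec's switching rates, builds
#' the noiseless intensity `q0 + Q X`, and optionally adds Poisson
#' observation noise (off by default: the stimulus plays the role of a
#' deterministic spectrogram; receptor noise enters downstream).
#'
#' @param spec a [fixture_spec()].
#' @param Q predictive-field matrix (default [make_pf_set()] of the spec).
#' @param noise `"none"` or `"poisson"`.
#' @return list with `S` (`n_channels x T` spectrogram), `traj` (the
#'   ground-truth `feature_trajectory`), `params` (the
#'   [generative_params()] used), and `spec`.
#' @export
make_spectrogram <- function(spec, Q = make_pf_set(spec),
                             noise = c("none", "poisson")) {
  stopifnot(inherits(spec, "fixture_spec"))
  noise <- match.arg(noise)
  params <- generative_params(Q, q0 = spec$q0, r_on = spec$r_on,
                              r_off = spec$r_off, dt = spec$dt)
  traj <- sample_features(params, spec$n_bins, seed = spec$seed)
  S <- params$q0 + params$Q %*% traj$X
  if (noise == "poisson") {
    S <- sample_observations(params, traj, seed = spec$seed + 1L)$S
  }
  list(S = S, traj = traj, params = params, spec = spec)
}

#' Generate a synthetic "recorded" neuron bank
#'
#' Runs the chosen inference model on a fixture stimulus and emits per-trial
#' Poisson spike counts around the model firing rates: counts in trial `k`
#' are `Poisson(count_scale * f_j(t))`, and the trial-averaged rates
#' (`mean(counts) / count_scale`) play the role of recorded firing rates, as
#' in a recording with several stimulus repeats.
#'
#' @param spec a [fixture_spec()].
#' @param Q predictive-field matrix (defaults to the spec's PF set).
#' @param model `"intact"` or `"no_inhibition"`.
#' @param config an [inference_config()].
#' @param count_scale expected spikes per bin per unit model rate.
#' @param stim optional precomputed output of [make_spectrogram()] (so
#'   intact and ablated banks can share the identical stimulus).
#' @return list with `rates` (trial-averaged, `N x T`), `trials` (list of
#'   count matrices), `model_rates` (noiseless model rates `F`), `trace`,
#'   `S` (the stimulus), `traj`, `params`.
#' @export
make_neuron_bank <- function(spec, Q = make_pf_set(spec),
                             model = c("intact", "no_inhibition"),
                             config = inference_config(),
                             count_scale = 1, stim = NULL) {
  model <- match.arg(model)
  if (is.null(stim)) stim <- make_spectrogram(spec, Q)
  trace <- if (model == "intact") {
    run_inference(stim$S, stim$params, config)
  } else {
    run_no_inhibition(stim$S, stim$params, config)
  }
  F <- trace$F
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$seed + 1000L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  trials <- lapply(seq_len(spec$n_trials), function(k) {
    matrix(stats::rpois(length(F), lambda = count_scale * F), nrow(F), ncol(F))
  })
  rates <- Reduce(`+`, trials) / (spec$n_trials * count_scale)
  list(rates = rates, trials = trials, model_rates = F, trace = trace,
       S = stim$S, traj = stim$traj, params = stim$params, model = model)
}
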