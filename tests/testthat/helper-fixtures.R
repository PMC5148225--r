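# Shared fixture builders. All fixtures are generated in code at test time;
# expensive ones are memoized for the duration of a test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small generative model with two overlapping bump features
two_feature_params <- function(q_peak = 2, q0 = 0.1, r_on = 1, r_off = 20) {
  ch <- 1:12
  Q <- cbind(q_peak * exp(-(ch - 5)^2 / 4), q_peak * exp(-(ch - 8)^2 / 4))
  generative_params(Q, q0 = q0, r_on = r_on, r_off = r_off, dt = 0.01)
}

# canonical narrowing fixture: overlapping bumps, Poisson receptor noise
narrowing_fixture <- function() {
  memo("narrowing", {
    spec <- fixture_spec(n_features = 5, overlap = 1.0, duration_s = 60,
                         seed = 5, q_peak = 5)
    st <- make_spectrogram(spec, noise = "poisson")
    cfg <- inference_config()
    list(spec = spec, st = st,
         F_intact = run_inference(st$S, st$params, cfg)$F,
         F_noinh = run_no_inhibition(st$S, st$params, cfg)$F)
  })
}

# canonical pipeline fixture: 12-feature world, 4 recorded detectors
pipeline_bank <- function() {
  memo("pipeline_bank", {
    spec <- fixture_spec(n_features = 12, overlap = 1.0, duration_s = 60,
                         seed = 31, q_peak = 5)
    bank <- make_neuron_bank(spec, model = "intact", count_scale = 0.2)
    keep <- seq(1, 12, 3)
    list(S = bank$S, R = bank$rates[keep, , drop = FALSE], bank = bank, keep = keep)
  })
}
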