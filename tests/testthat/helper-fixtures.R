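# Shared fixtures, built in code at test time.

# One clean noiseless record (60 BPM, 120/80) reused across tests.
clean_record <- function(hr = 60, sbp = 120, dbp = 80, duration = 10,
                         fs = 125, ...) {
  generate_pulse_train(pulse_spec(heart_rate = hr, sbp = sbp, dbp = dbp, ...),
                       duration, fs, seed = 1L)
}

# A symmetric triangle cycle embedded in a flat baseline, with its poi row.
# rise = fall = half_T seconds.
triangle_cycle <- function(half_T = 0.4, fs = 1000) {
  n_half <- round(half_T * fs)
  pad <- round(0.1 * fs)
  ppg <- c(rep(0, pad), seq(0, 1, length.out = n_half + 1),
           seq(1, 0, length.out = n_half + 1)[-1], rep(0, pad))
  o <- pad + 1L
  s <- pad + n_half + 1L
  f <- pad + 2L * n_half + 1L
  list(ppg = ppg, fs = fs,
       poi = data.frame(o = o, w = o + n_half %/% 2L, s = s,
                        y = s + n_half %/% 2L, z = f - 2L,
                        a = o + 1L, b = s - 1L, c = s + 1L,
                        d = s + n_half %/% 2L, e = s + n_half %/% 2L + 1L,
                        f = f))
}

# Small clean cohort shared by pipeline-level tests (cached per session).
.fixture_env <- new.env(parent = emptyenv())

small_clean_cohort <- function() {
  if (is.null(.fixture_env$clean)) {
    .fixture_env$clean <- generate_cohort(
      cohort_spec(n_subjects = 8, segments_per_subject = 4,
                  noise_sd = 0.005, seed = 404L))
  }
  .fixture_env$clean
}

small_clean_features <- function() {
  if (is.null(.fixture_env$features)) {
    res <- run_pipeline(
      small_clean_cohort(),
      pipeline_config(distortion_thresholds = preset_distortion_thresholds()))
    .fixture_env$features <- res$features
  }
  .fixture_env$features
}

synthetic_pipeline_config <- function(...) {
  pipeline_config(distortion_thresholds = preset_distortion_thresholds(), ...)
}
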