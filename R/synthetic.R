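# Synthetic paired PPG/ABP generation.
#
# Each cardiac cycle is the sum of two smooth asymmetric Gaussian lobes: a
# systolic lobe and a smaller dicrotic lobe placed so that the dicrotic
# notch (the APG "e" landmark, the deceleration shoulder preceding the
# dicrotic wave crest) falls `notch_delay` seconds after the systolic peak.
# The shape is infinitely differentiable, so the VPG (w, y, z) and APG
# (a, b, c, d, e) landmarks all exist on the noiseless waveform.

#' Pulse morphology specification
#'
#' Parameters of one subject's synthetic cardiac waveform. The arterial
#' pressure channel spans exactly \[dbp, sbp\] mmHg in the noiseless case;
#' the PPG channel is unit-free in \[0, 1\] before noise and baseline wander,
#' and lags the pressure wave by `ppg_delay` seconds (the transit-time delay
#' between the measurement sites).
#'
#' @param heart_rate Heart rate in beats/min (> 0).
#' @param sbp,dbp Systolic / diastolic pressure in mmHg (`sbp > dbp`).
#' @param notch_delay Time of the dicrotic notch after the systolic peak, in
#'   seconds. `NULL` (default) scales with the cardiac period as
#'   `0.3 * 60 / heart_rate`.
#' @param notch_depth Relative amplitude of the dicrotic lobe in \[0, 1).
#'   `0` produces a single-lobe pulse with no notch landmark.
#' @param ppg_delay PPG lag behind ABP in seconds.
#' @param noise_sd Gaussian noise SD added to the PPG channel (PPG units).
#' @param bw_amplitude,bw_frequency Amplitude (PPG units) and frequency (Hz)
#'   of sinusoidal baseline wander added to the PPG channel.
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(heart_rate = 75, sbp = 120, dbp = 80,
                       notch_delay = NULL, notch_depth = 0.25,
                       ppg_delay = 0.2, noise_sd = 0,
                       bw_amplitude = 0, bw_frequency = 0.25) {
  check_number(heart_rate, "heart_rate", lower = 0, strict_lower = TRUE)
  check_number(sbp, "sbp")
  check_number(dbp, "dbp")
  if (sbp <= dbp) stop_spec("invalid pulse_spec: sbp (%g) must exceed dbp (%g)", sbp, dbp)
  if (is.null(notch_delay)) notch_delay <- 0.3 * 60 / heart_rate
  check_number(notch_delay, "notch_delay", lower = 0)
  check_number(notch_depth, "notch_depth", lower = 0)
  if (notch_depth >= 1) stop_spec("invalid pulse_spec: notch_depth must be in [0, 1)")
  check_number(ppg_delay, "ppg_delay", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(bw_amplitude, "bw_amplitude", lower = 0)
  check_number(bw_frequency, "bw_frequency", lower = 0)
  structure(list(heart_rate = heart_rate, sbp = sbp, dbp = dbp,
                 notch_delay = notch_delay, notch_depth = notch_depth,
                 ppg_delay = ppg_delay, noise_sd = noise_sd,
                 bw_amplitude = bw_amplitude, bw_frequency = bw_frequency),
            class = "pulse_spec")
}

# Smoothly asymmetric Gaussian lobe: the width interpolates sigmoidally from
# sigma_l (rise side) to sigma_r (fall side), keeping the shape C-infinity.
# The transition scale (0.8 sigma_l) is wide enough that the width change
# adds no local extrema of its own to the second derivative: each lobe
# contributes exactly one curvature maximum per flank.
asym_lobe <- function(tau, center, sigma_l, sigma_r) {
  s <- sigma_l + (sigma_r - sigma_l) / (1 + exp(-(tau - center) / (0.8 * sigma_l)))
  exp(-((tau - center)^2) / (2 * s^2))
}

# Raw periodic pulse shape evaluated at times t (seconds); cycle k starts at
# k * period with its onset valley, systolic lobe peak near 0.18 * period.
pulse_shape <- function(t, period, notch_delay, notch_depth) {
  t_sys <- 0.18 * period
  sig_l <- 0.055 * period
  sig_r <- 0.085 * period
  sig_d <- 0.032 * period
  # dicrotic lobe centred so its leading APG maximum (at sqrt(3) sigma before
  # the crest) sits at t_sys + notch_delay: the notch position is the contract
  t_dic <- t_sys + notch_delay + sqrt(3) * sig_d
  out <- numeric(length(t))
  k_range <- seq(floor(min(t) / period) - 1, ceiling(max(t) / period) + 1)
  for (k in k_range) {
    tau <- t - k * period
    out <- out + asym_lobe(tau, t_sys, sig_l, sig_r)
    if (notch_depth > 0) {
      out <- out + notch_depth * asym_lobe(tau, t_dic, sig_d, 1.6 * sig_d)
    }
  }
  out
}

# Unit-normalized shape: min -> 0, max -> 1, computed on a dense period.
unit_pulse_shape <- function(t, period, notch_delay, notch_depth) {
  dense <- seq(0, period, length.out = 4096L)
  ref <- pulse_shape(dense, period, notch_delay, notch_depth)
  lo <- min(ref); hi <- max(ref)
  (pulse_shape(t, period, notch_delay, notch_depth) - lo) / (hi - lo)
}

new_bp_record <- function(subject_id, record_id, fs, ppg, abp = NULL,
                          meta = list()) {
  structure(list(subject_id = subject_id, record_id = record_id,
                 fs = fs, n = length(ppg), ppg = ppg, abp = abp,
                 meta = meta),
            class = "bp_record")
}

#' @export
print.bp_record <- function(x, ...) {
  cat(sprintf("<bp_record %s/%s: %d samples @ %g Hz, %s ABP%s>\n",
              x$subject_id, x$record_id, x$n, x$fs,
              if (is.null(x$abp)) "no" else "paired",
              if (!is.null(x$meta$artifact) && !is.na(x$meta$artifact))
                paste0(", artifact=", x$meta$artifact) else ""))
  invisible(x)
}

#' Generate a paired PPG/ABP pulse train
#'
#' Synthesizes one record: an arterial-pressure waveform whose peaks reach
#' `sbp` and valleys `dbp` (noiseless case), and a unit-free PPG with the same
#' cycle structure delayed by `ppg_delay`, with optional additive noise and
#' sinusoidal baseline wander on the PPG channel. Deterministic for a fixed
#' seed.
#'
#' @param spec A [pulse_spec()].
#' @param duration Record duration in seconds (at least one cardiac period).
#' @param fs Sampling rate in Hz (>= 25).
#' @param seed Integer seed for the stochastic components.
#' @param subject_id,record_id Identifiers attached to the record.
#' @return A `bp_record`: list with `subject_id`, `record_id`, `fs`, `ppg`,
#'   `abp` and `meta` (spec echo, seed, artifact tag).
#' @examples
#' rec <- generate_pulse_train(pulse_spec(heart_rate = 60, sbp = 120, dbp = 80),
#'                             duration = 10, fs = 125, seed = 1)
#' range(rec$abp)
#' @export
generate_pulse_train <- function(spec, duration, fs, seed = 1L,
                                 subject_id = "S0001", record_id = "S0001_R01") {
  if (!inherits(spec, "pulse_spec")) stop_spec("`spec` must be a pulse_spec")
  check_number(fs, "fs", lower = 25)
  period <- 60 / spec$heart_rate
  if (duration < period) {
    stop_spec("duration (%g s) must cover at least one cardiac period (%g s)",
              duration, period)
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  u_abp <- unit_pulse_shape(t, period, spec$notch_delay, spec$notch_depth)
  abp <- spec$dbp + (spec$sbp - spec$dbp) * u_abp
  ppg <- unit_pulse_shape(t - spec$ppg_delay, period,
                          spec$notch_delay, spec$notch_depth)
  if (spec$noise_sd > 0 || spec$bw_amplitude > 0) {
    ppg <- with_seed(seed, {
      out <- ppg
      if (spec$bw_amplitude > 0) {
        phase <- runif(1, 0, 2 * pi)
        out <- out + spec$bw_amplitude *
          sin(2 * pi * spec$bw_frequency * t + phase)
      }
      if (spec$noise_sd > 0) out <- out + rnorm(n, 0, spec$noise_sd)
      out
    })
  }
  new_bp_record(subject_id, record_id, fs, ppg, abp,
                meta = list(pulse_spec = spec, seed = as.integer(seed),
                            duration = duration, artifact = NA_character_,
                            sbp = spec$sbp, dbp = spec$dbp))
}

artifact_kinds <- function() {
  c("flatline", "amplitude_spike", "extreme_bp", "low_pp",
    "tachy", "brady", "bw_drift")
}

# Artifact kinds that deterministically violate a removal criterion of the
# cleaning pipeline (bw_drift is correctable by spline subtraction, so it is
# not in this set).
removable_artifact_kinds <- function() {
  c("flatline", "amplitude_spike", "extreme_bp", "low_pp", "tachy", "brady")
}

#' Inject a tagged artifact into a record
#'
#' Produces a copy of `record` that violates exactly one cleaning criterion:
#' `flatline` (no detectable cycles), `amplitude_spike` (distorted PPG
#' intervals/amplitudes), `extreme_bp` (ABP above 220 mmHg), `low_pp` (pulse
#' pressure below 10 mmHg), `tachy`/`brady` (heart rate outside 35-140 BPM;
#' these regenerate the waveform from the record's stored pulse spec), and
#' `bw_drift` (adds a 0.2 Hz sinusoid; correctable, cycle structure
#' preserved). The input record is not modified.
#'
#' @param record A `bp_record`.
#' @param kind One of [artifact_kinds()].
#' @param seed Integer seed.
#' @return The modified `bp_record` with `meta$artifact` set to `kind`.
#' @export
inject_artifact <- function(record, kind, seed = 1L) {
  if (!inherits(record, "bp_record")) stop_spec("`record` must be a bp_record")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% artifact_kinds()) {
    stop_spec("unknown artifact kind '%s'; must be one of: %s",
              as.character(kind)[1], paste(artifact_kinds(), collapse = ", "))
  }
  out <- record
  n <- record$n
  t <- (seq_len(n) - 1) / record$fs
  out <- switch(kind,
    flatline = {
      out$ppg <- rep(median(record$ppg), n)
      if (!is.null(record$abp)) out$abp <- rep(median(record$abp), n)
      out
    },
    amplitude_spike = {
      rng <- diff(range(record$ppg))
      out$ppg <- with_seed(seed, {
        centers <- runif(3, 0.1 * max(t), 0.9 * max(t))
        sig <- record$ppg
        for (ct in centers) {
          sig <- sig + 1.5 * rng * exp(-((t - ct)^2) / (2 * 0.02^2))
        }
        sig
      })
      out
    },
    extreme_bp = {
      if (is.null(record$abp)) stop_spec("extreme_bp artifact requires an ABP channel")
      out$abp <- record$abp * (225 / max(record$abp))
      out
    },
    low_pp = {
      if (is.null(record$abp)) stop_spec("low_pp artifact requires an ABP channel")
      m <- mean(record$abp)
      pp <- diff(range(record$abp))
      out$abp <- m + (record$abp - m) * (8 / pp)
      out
    },
    tachy = ,
    brady = {
      spec <- record$meta$pulse_spec
      if (is.null(spec)) {
        stop_spec("%s artifact requires a record generated from a pulse_spec", kind)
      }
      hr <- if (kind == "tachy") 160 else 28
      spec2 <- pulse_spec(heart_rate = hr, sbp = spec$sbp, dbp = spec$dbp,
                          notch_depth = spec$notch_depth,
                          ppg_delay = spec$ppg_delay, noise_sd = spec$noise_sd,
                          bw_amplitude = spec$bw_amplitude,
                          bw_frequency = spec$bw_frequency)
      generate_pulse_train(spec2, record$meta$duration, record$fs, seed = seed,
                           subject_id = record$subject_id,
                           record_id = record$record_id)
    },
    bw_drift = {
      phase <- with_seed(seed, runif(1, 0, 2 * pi))
      amp <- 0.3 * diff(range(record$ppg))
      out$ppg <- record$ppg + amp * sin(2 * pi * 0.2 * t + phase)
      out
    })
  out$meta$artifact <- kind
  out
}

#' Cohort specification
#'
#' Parameters of a synthetic multi-subject cohort. Each subject draws a
#' latent (SBP, DBP) level from skewed shifted-log-normal distributions and a
#' latent heart rate; segments within a subject vary around the latent level
#' by `within_subject_sd`, so samples of one subject are correlated — the
#' property the subject-leakage experiments rely on. A fraction of records
#' receive an injected, ground-truth-tagged artifact drawn from the
#' filter-violating kinds.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param segments_per_subject Records (one segment each) per subject (>= 1).
#' @param sampling_rate Sampling rate in Hz.
#' @param segment_length Segment length in seconds.
#' @param sbp_distribution,dbp_distribution Lists with `mean`, `sd`, `skew`
#'   (mmHg) for the subject-level pressure distributions.
#' @param hr_distribution List with `mean`, `sd` (beats/min).
#' @param hr_jitter_sd Segment-level heart-rate jitter around the subject's
#'   latent rate, in beats/min; small values make subjects identifiable
#'   from rate-dependent features (the leakage experiments rely on this).
#' @param morph_ranges List with `notch_depth` and `notch_frac` ranges
#'   (two-element vectors): each subject draws a stable dicrotic-notch depth
#'   and a notch delay (as a fraction of the cardiac period) uniformly from
#'   these, giving subjects distinct waveform morphologies.
#' @param within_subject_sd SD (mmHg) of segment-level label variation
#'   around the subject's latent level.
#' @param artifact_fraction Probability that a record receives an injected
#'   artifact, in \[0, 1\].
#' @param artifact_kinds Artifact kinds to sample from; defaults to the six
#'   filter-violating kinds.
#' @param hr_sbp_link Optional list `(intercept, slope, sd)` making the
#'   subject-level SBP an affine function of the subject's heart rate plus
#'   Gaussian noise (a deliberately learnable cohort for harness
#'   validation); overrides `sbp_distribution`.
#' @param ppg_delay,noise_sd,bw_amplitude See [pulse_spec()].
#' @param align_margin Extra record duration (s) beyond `segment_length` so
#'   alignment truncation still leaves a full segment.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, segments_per_subject = 5,
                        sampling_rate = 125, segment_length = 5,
                        sbp_distribution = list(mean = 134.36, sd = 21.78, skew = 0.6),
                        dbp_distribution = list(mean = 65.37, sd = 10.51, skew = 0.6),
                        hr_distribution = list(mean = 75, sd = 8),
                        hr_jitter_sd = 2,
                        morph_ranges = list(notch_depth = c(0.18, 0.32),
                                            notch_frac = c(0.26, 0.34)),
                        within_subject_sd = 3,
                        artifact_fraction = 0,
                        artifact_kinds = removable_artifact_kinds(),
                        ppg_delay = 0.2, noise_sd = 0.01, bw_amplitude = 0,
                        align_margin = 1, hr_sbp_link = NULL, seed = 1L) {
  check_number(n_subjects, "n_subjects", lower = 1)
  check_number(segments_per_subject, "segments_per_subject", lower = 1)
  check_number(artifact_fraction, "artifact_fraction", lower = 0, upper = 1)
  check_number(within_subject_sd, "within_subject_sd", lower = 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 segments_per_subject = as.integer(segments_per_subject),
                 sampling_rate = sampling_rate, segment_length = segment_length,
                 sbp_distribution = sbp_distribution,
                 dbp_distribution = dbp_distribution,
                 hr_distribution = hr_distribution,
                 hr_jitter_sd = hr_jitter_sd, morph_ranges = morph_ranges,
                 within_subject_sd = within_subject_sd,
                 artifact_fraction = artifact_fraction,
                 artifact_kinds = artifact_kinds,
                 ppg_delay = ppg_delay, noise_sd = noise_sd,
                 bw_amplitude = bw_amplitude,
                 align_margin = align_margin, hr_sbp_link = hr_sbp_link,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Dataset-shaped cohort presets
#'
#' Returns a [cohort_spec()] whose SBP/DBP moments, sampling rate and segment
#' length emulate one of four published open BP datasets (a MIMIC-derived
#' multi-subject set, a large continuous ICU set, a bed-sensor set, and a
#' short-segment fingertip set).
#'
#' @param name One of `"sensors"`, `"uci"`, `"bcg"`, `"ppgbp"`.
#' @param n_subjects,segments_per_subject,seed Overrides passed through.
#' @param ... Further overrides for [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
cohort_preset <- function(name = c("sensors", "uci", "bcg", "ppgbp"),
                          n_subjects = 50, segments_per_subject = 9,
                          seed = 1L, ...) {
  name <- match.arg(name)
  p <- switch(name,
    sensors = list(sbp = list(mean = 134.36, sd = 21.78, skew = 0.6),
                   dbp = list(mean = 65.37, sd = 10.51, skew = 0.6),
                   fs = 125, seg = 5),
    uci     = list(sbp = list(mean = 131.57, sd = 11.16, skew = 0.6),
                   dbp = list(mean = 66.79, sd = 10.48, skew = 0.6),
                   fs = 125, seg = 5),
    bcg     = list(sbp = list(mean = 120.99, sd = 15.29, skew = 0.6),
                   dbp = list(mean = 67.23, sd = 9.30, skew = 0.6),
                   fs = 125, seg = 5),
    ppgbp   = list(sbp = list(mean = 128.02, sd = 20.50, skew = 0.6),
                   dbp = list(mean = 71.91, sd = 11.20, skew = 0.6),
                   fs = 125, seg = 2.1))
  cohort_spec(n_subjects = n_subjects,
              segments_per_subject = segments_per_subject,
              sampling_rate = p$fs, segment_length = p$seg,
              sbp_distribution = p$sbp, dbp_distribution = p$dbp,
              seed = seed, ...)
}

#' Generate a synthetic cohort of paired PPG/ABP records
#'
#' Draws per-subject latent blood-pressure levels from the configured skewed
#' distributions (rejection-sampling pairs with `sbp <= dbp`), per-segment
#' labels around them, and one record per segment; `artifact_fraction` of
#' records receive a tagged injected artifact.
#'
#' @param spec A [cohort_spec()].
#' @return A list of `bp_record` objects with attributes `rejection_rate`
#'   (fraction of resampled label draws) and `spec`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_spec("`spec` must be a cohort_spec")
  sdist <- spec$sbp_distribution
  ddist <- spec$dbp_distribution
  rejections <- 0L
  draws <- 0L
  draw_pair <- function(ns) {
    s <- rshifted_lnorm(ns, sdist$mean, sdist$sd, sdist$skew %||% 0)
    d <- rshifted_lnorm(ns, ddist$mean, ddist$sd, ddist$skew %||% 0)
    cbind(s, d)
  }
  records <- with_seed(spec$seed, {
    out <- vector("list", spec$n_subjects * spec$segments_per_subject)
    idx <- 1L
    for (i in seq_len(spec$n_subjects)) {
      hr_i <- min(max(rnorm(1, spec$hr_distribution$mean,
                            spec$hr_distribution$sd), 55), 95)
      nd_i <- runif(1, spec$morph_ranges$notch_depth[1],
                    spec$morph_ranges$notch_depth[2])
      nf_i <- runif(1, spec$morph_ranges$notch_frac[1],
                    spec$morph_ranges$notch_frac[2])
      repeat {
        draws <<- draws + 1L
        sl <- draw_pair(1L)
        if (!is.null(spec$hr_sbp_link)) {
          lk <- spec$hr_sbp_link
          sl[1] <- lk$intercept + lk$slope * hr_i + rnorm(1, 0, lk$sd)
        }
        if (sl[1] > sl[2]) break
        rejections <<- rejections + 1L
      }
      subject <- sprintf("S%04d", i)
      for (j in seq_len(spec$segments_per_subject)) {
        repeat {
          draws <<- draws + 1L
          sbp_ij <- sl[1] + rnorm(1, 0, spec$within_subject_sd)
          dbp_ij <- sl[2] + rnorm(1, 0, spec$within_subject_sd)
          if (sbp_ij > dbp_ij) break
          rejections <<- rejections + 1L
        }
        hr_ij <- min(max(hr_i + rnorm(1, 0, spec$hr_jitter_sd), 45), 120)
        ps <- pulse_spec(heart_rate = hr_ij, sbp = sbp_ij, dbp = dbp_ij,
                         notch_delay = nf_i * 60 / hr_ij, notch_depth = nd_i,
                         ppg_delay = spec$ppg_delay, noise_sd = spec$noise_sd,
                         bw_amplitude = spec$bw_amplitude)
        rec_seed <- child_seed(spec$seed, idx)
        rec <- generate_pulse_train(
          ps, spec$segment_length + spec$align_margin, spec$sampling_rate,
          seed = rec_seed, subject_id = subject,
          record_id = sprintf("%s_R%02d", subject, j))
        if (spec$artifact_fraction > 0 &&
            runif(1) < spec$artifact_fraction &&
            length(spec$artifact_kinds) > 0) {
          kind <- sample(spec$artifact_kinds, 1L)
          rec <- inject_artifact(rec, kind, seed = child_seed(rec_seed, 7L))
        }
        out[[idx]] <- rec
        idx <- idx + 1L
      }
    }
    out
  })
  attr(records, "rejection_rate") <- rejections / draws
  attr(records, "spec") <- spec
  records
}

`%||%` <- function(a, b) if (is.null(a)) b else a
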