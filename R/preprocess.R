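# Single-segment preprocessing operations: alignment, segmentation, ABP
# screening, label extraction, distortion statistics, baseline-wander
# removal and the skewness signal-quality index.

#' Align a PPG/ABP pair by cross-correlation
#'
#' Finds the integer lag (capped at `max_shift` seconds) maximizing the
#' cross-correlation magnitude of the mean-removed signals, advances the PPG
#' by that lag (positive shift means the PPG lags the ABP) and truncates both
#' to their overlap.
#'
#' @param ppg,abp Numeric vectors sampled at `fs`.
#' @param fs Sampling rate in Hz.
#' @param max_shift Maximum allowed shift in seconds.
#' @return List with `shift` (samples), `ppg`, `abp` (truncated overlap).
#' @export
align_signals <- function(ppg, abp, fs, max_shift = 1) {
  n <- min(length(ppg), length(abp))
  L <- round(max_shift * fs)
  if (n <= 2L * L) stop_spec("align_signals: signals too short for +/-%d-sample lag search", L)
  if (sd(ppg[seq_len(n)]) == 0 || sd(abp[seq_len(n)]) == 0) {
    stop_spec("align_signals: alignment undefined for constant input")
  }
  p <- ppg[seq_len(n)] - mean(ppg[seq_len(n)])
  a <- abp[seq_len(n)] - mean(abp[seq_len(n)])
  lags <- -L:L
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(p[(1 + k):n] * a[seq_len(n - k)])
    else sum(p[seq_len(n + k)] * a[(1 - k):n])
  }, numeric(1))
  shift <- lags[which.max(abs(cc))]
  if (shift >= 0) {
    list(shift = shift, ppg = ppg[(1 + shift):n], abp = abp[seq_len(n - shift)])
  } else {
    list(shift = shift, ppg = ppg[seq_len(n + shift)], abp = abp[(1 - shift):n])
  }
}

new_bp_segment <- function(subject_id, record_id, segment_index, fs,
                           ppg, abp = NULL, sbp_label = NA_real_,
                           dbp_label = NA_real_, artifact = NA_character_) {
  structure(list(subject_id = subject_id, record_id = record_id,
                 segment_index = segment_index, fs = fs,
                 ppg = ppg, abp = abp,
                 sbp_label = sbp_label, dbp_label = dbp_label,
                 status = "kept", removal_step = NA_integer_,
                 removal_reason = NA_character_,
                 artifact = artifact, cycles = NULL),
            class = "bp_segment")
}

#' Split a record into fixed-length non-overlapping segments
#'
#' @param record A `bp_record` (optionally already aligned).
#' @param segment_length Segment length in seconds (5 by default; short-
#'   record data may use e.g. 2.1).
#' @return List of `bp_segment` objects; empty (with a warning) if the
#'   record is shorter than one segment. Labels known from the generator
#'   metadata are carried onto the segments for PPG-only records.
#' @export
segment_record <- function(record, segment_length = 5) {
  ns <- round(record$fs * segment_length)
  n <- if (is.null(record$abp)) length(record$ppg)
       else min(length(record$ppg), length(record$abp))
  k <- n %/% ns
  if (k == 0L) {
    warning(sprintf("record %s shorter than one %gs segment; skipped",
                    record$record_id, segment_length))
    return(list())
  }
  lapply(seq_len(k), function(i) {
    idx <- ((i - 1L) * ns + 1L):(i * ns)
    new_bp_segment(record$subject_id, record$record_id, i, record$fs,
                   ppg = record$ppg[idx],
                   abp = if (is.null(record$abp)) NULL else record$abp[idx],
                   sbp_label = if (is.null(record$abp)) record$meta$sbp %||% NA_real_ else NA_real_,
                   dbp_label = if (is.null(record$abp)) record$meta$dbp %||% NA_real_ else NA_real_,
                   artifact = record$meta$artifact %||% NA_character_)
  })
}

#' Screen an ABP segment for extreme or implausible values
#'
#' Fails when any sample leaves `abp_range` mmHg, the median per-cycle pulse
#' pressure is not strictly above `pp_min` mmHg, the ABP-cycle heart rate
#' leaves `hr_range` BPM, or no cycle can be identified. All violated
#' criteria are reported (a segment can meet several simultaneously).
#'
#' @param segment A `bp_segment` carrying an ABP channel.
#' @param abp_range Admissible pressure interval in mmHg (closed).
#' @param pp_min Minimum pulse pressure in mmHg (strictly-greater rule).
#' @param hr_range Admissible heart-rate interval in BPM (closed).
#' @param ... Detector settings passed to [detect_cycles()].
#' @return List with `pass` (logical), `reasons` (character vector among
#'   `amplitude`, `pulse_pressure`, `heart_rate`, `no_cycles`) and `cycles`
#'   (the ABP `cycle_set`, or `NULL`).
#' @export
filter_abp_extreme <- function(segment, abp_range = c(30, 220), pp_min = 10,
                               hr_range = c(35, 140), ...) {
  if (is.null(segment$abp)) stop_spec("filter_abp_extreme: segment has no ABP channel")
  abp <- segment$abp
  reasons <- character(0)
  if (any(abp < abp_range[1] | abp > abp_range[2])) {
    reasons <- c(reasons, "amplitude")
  }
  cyc <- detect_cycles(abp, segment$fs, hr_range = hr_range, ...)
  if (is_fail(cyc)) {
    reasons <- c(reasons,
                 if (cyc$reason %in% c("p2p_bpm", "v2v_bpm")) "heart_rate" else "no_cycles")
    return(list(pass = length(reasons) == 0L, reasons = reasons, cycles = NULL))
  }
  pp <- abp[cyc$peak] - (abp[cyc$onset] + abp[cyc$offset]) / 2
  if (median(pp) <= pp_min) reasons <- c(reasons, "pulse_pressure")
  if (cyc$heart_rate < hr_range[1] || cyc$heart_rate > hr_range[2]) {
    reasons <- c(reasons, "heart_rate")
  }
  list(pass = length(reasons) == 0L, reasons = reasons, cycles = cyc)
}

#' Extract SBP/DBP labels from an ABP segment
#'
#' SBP is the median of the ABP values at the cycle systolic-peak indices;
#' DBP is the median over the pooled multiset of onset and offset values.
#' Medians of even counts are the mean of the two central values.
#'
#' @param abp Numeric ABP samples in mmHg.
#' @param cycles `cycle_set` detected on this ABP.
#' @return Named numeric vector `c(sbp = , dbp = )`.
#' @export
extract_bp_labels <- function(abp, cycles) {
  if (is_fail(cycles) || !inherits(cycles, "cycle_set") || length(cycles$peak) == 0L) {
    stop_spec("extract_bp_labels: no complete cycle available")
  }
  c(sbp = median(abp[cycles$peak]),
    dbp = median(abp[c(cycles$onset, cycles$offset)]))
}

#' Per-segment distortion statistics
#'
#' Sample standard deviations (n-1 denominator) of the peak-to-peak and
#' valley-to-valley intervals (seconds) and of the peak and valley
#' amplitudes, over the full detected extremum sequences.
#'
#' @param segment A `bp_segment` (its PPG channel is used).
#' @param cycles `cycle_set` for the segment.
#' @return Named numeric vector `sd_p2p`, `sd_v2v`, `sd_peak_amp`,
#'   `sd_valley_amp`; entries are `NA` when fewer than two intervals exist.
#' @export
distortion_statistics <- function(segment, cycles) {
  x <- segment$ppg
  fs <- segment$fs
  sd_or_na <- function(v) if (length(v) >= 2L) sd(v) else NA_real_
  c(sd_p2p = sd_or_na(diff(cycles$peaks) / fs),
    sd_v2v = sd_or_na(diff(cycles$valleys) / fs),
    sd_peak_amp = sd_or_na(x[cycles$peaks]),
    sd_valley_amp = sd_or_na(x[cycles$valleys]))
}

#' Threshold distortion statistics over a segment population
#'
#' A segment fails when any of its four distortion statistics strictly
#' exceeds its threshold. Thresholds are either supplied explicitly or
#' derived as the `q`-th cumulative percentile of each statistic over the
#' candidate population (the way thresholds are read off cumulative
#' percentage plots); derived thresholds are returned for the audit.
#'
#' @param stats_matrix Numeric matrix/data.frame, one row per segment,
#'   columns as in [distortion_statistics()].
#' @param thresholds Optional named numeric vector of explicit thresholds.
#' @param q Percentile (0-100) used when `thresholds` is `NULL`.
#' @param fail_undefined Treat undefined (NA) statistics as failures.
#' @return List with `pass` (logical vector) and `thresholds` (resolved).
#' @export
filter_distortion <- function(stats_matrix, thresholds = NULL, q = 97.5,
                              fail_undefined = TRUE) {
  m <- as.matrix(stats_matrix)
  if (is.null(thresholds)) {
    if (nrow(m) == 0L) stop_spec("filter_distortion: empty population in percentile mode")
    thresholds <- apply(m, 2, function(col) {
      col <- col[!is.na(col)]
      if (length(col) == 0L) Inf else unname(quantile(col, q / 100, type = 7))
    })
  }
  thresholds <- thresholds[colnames(m)]
  pass <- apply(m, 1, function(row) {
    if (anyNA(row)) return(!fail_undefined)
    all(row <= thresholds)
  })
  list(pass = unname(pass), thresholds = thresholds)
}

#' Remove baseline wander by cubic-spline interpolation of the valleys
#'
#' Fits a natural cubic spline through the (valley index, valley value)
#' knots of the segment, extends it to the segment ends by constant
#' extrapolation of the terminal knot values, and subtracts it; corrected
#' valleys sit at zero.
#'
#' @param segment A `bp_segment`.
#' @param cycles `cycle_set` for the segment (its full valley list is used).
#' @return The segment with corrected `ppg`; if fewer than 2 valleys exist
#'   the segment is returned unchanged with attribute `bw_skipped = TRUE`.
#' @export
remove_baseline_wander <- function(segment, cycles) {
  v <- sort(unique(cycles$valleys))
  if (length(v) < 2L) {
    attr(segment, "bw_skipped") <- TRUE
    return(segment)
  }
  x <- segment$ppg
  sp <- splinefun(v, x[v], method = "natural")
  idx <- seq_along(x)
  baseline <- sp(pmin(pmax(idx, v[1]), v[length(v)]))
  segment$ppg <- x - baseline
  segment
}

#' Decimate a record to a lower sampling rate
#'
#' Plain polyphase decimation (anti-aliasing FIR low-pass, then keep every
#' `factor`-th sample) of both channels, e.g. factor 8 for 1000 to 125 Hz.
#'
#' @param record A `bp_record`.
#' @param factor Integer decimation factor (>= 2).
#' @return The record resampled at `fs / factor`.
#' @export
decimate_record <- function(record, factor) {
  check_number(factor, "factor", lower = 2)
  factor <- as.integer(factor)
  # reflect-pad before filtering: the FIR warm-up transient would otherwise
  # dominate the amplitude range of short records
  dec1 <- function(x) {
    pad <- 25L * factor
    pad <- min(pad, length(x) - 1L)
    xp <- c(rev(x[seq_len(pad)]), x,
            rev(x[(length(x) - pad + 1L):length(x)]))
    y <- as.numeric(signal::decimate(xp, factor, ftype = "fir"))
    y[(pad %/% factor + 1L):(pad %/% factor + length(x) %/% factor)]
  }
  record$ppg <- dec1(record$ppg)
  if (!is.null(record$abp)) record$abp <- dec1(record$abp)
  record$fs <- record$fs / factor
  record$n <- length(record$ppg)
  record
}

#' Skewness signal-quality index of a PPG segment
#'
#' Fisher-Pearson moment skewness `m3 / m2^(3/2)`. Segments with strictly
#' negative skewness are rejected by the pipeline; zero-variance segments
#' return `NA` (rejected as degenerate).
#'
#' @param x Numeric PPG samples (a `bp_segment` is also accepted).
#' @return Skewness value, or `NA` for zero variance.
#' @export
sqi_skewness <- function(x) {
  if (inherits(x, "bp_segment")) x <- x$ppg
  if (length(x) < 3L) stop_spec("sqi_skewness: need at least 3 samples")
  moment_skewness(x)
}
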