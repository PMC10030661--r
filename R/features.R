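# Handcrafted PPG feature catalog: landmark localization on the PPG and its
# first (VPG) and second (APG) derivatives, then amplitude / elapsed-time /
# area / width / frequency / histogram / slope-deviation / quality / index
# features, aggregated per segment by the median across cycles.

#' Savitzky-Golay smoothing of a PPG segment
#'
#' Second-derivative landmarks amplify measurement noise by the square of
#' the sampling rate, so the feature extractor smooths the PPG with a
#' short cubic Savitzky-Golay filter (zero-phase, shape-preserving) before
#' differentiating. The default 11-sample window is 88 ms at 125 Hz.
#'
#' @param x Numeric waveform.
#' @param p Polynomial order.
#' @param n Window length in samples (odd).
#' @return Smoothed waveform of the same length.
#' @export
smooth_ppg <- function(x, p = 3, n = 11) {
  if (length(x) <= n) return(x)
  as.numeric(signal::sgolayfilt(x, p = p, n = n))
}

#' First and second derivatives of a PPG waveform
#'
#' Central differences scaled to per-second units (`fs` and `fs^2`); the end
#' samples use one-sided differences.
#'
#' @param ppg Numeric waveform.
#' @param fs Sampling rate in Hz.
#' @return List with `vpg` (velocity PPG) and `apg` (acceleration PPG).
#' @export
derivatives <- function(ppg, fs) {
  n <- length(ppg)
  if (n < 5L) stop_spec("derivatives: need at least 5 samples")
  vpg <- numeric(n)
  vpg[2:(n - 1)] <- (ppg[3:n] - ppg[1:(n - 2)]) / 2 * fs
  vpg[1] <- (ppg[2] - ppg[1]) * fs
  vpg[n] <- (ppg[n] - ppg[n - 1]) * fs
  apg <- numeric(n)
  apg[2:(n - 1)] <- (ppg[3:n] - 2 * ppg[2:(n - 1)] + ppg[1:(n - 2)]) * fs^2
  apg[1] <- (ppg[3] - 2 * ppg[2] + ppg[1]) * fs^2
  apg[n] <- (ppg[n] - 2 * ppg[n - 1] + ppg[n - 2]) * fs^2
  list(vpg = vpg, apg = apg)
}

# Interior local minima (mirror of local_maxima).
local_minima <- function(x) local_maxima(-x)

#' Locate the per-cycle points of interest on PPG, VPG and APG
#'
#' Per cycle: `o`, `s`, `f` are the onset valley, systolic peak and offset
#' valley; `w` (max upslope) is the VPG maximum in (o, s), `y` the VPG
#' minimum in (s, f), `z` (diastolic rise) the VPG maximum in (y, f). On the
#' APG, `a` is the maximum in (o, s) and `b` the first local minimum after
#' it (the deceleration trough at the peak). The dicrotic notch `e` is the
#' largest-valued interior local APG maximum in (s, f), certified by the
#' presence of a second maximum there (a dicrotic lobe contributes a notch
#' shoulder plus a trailing flank, while a notch-free falling limb carries
#' exactly one curvature maximum); `c` and `d` are the first local
#' maximum/minimum pair between `b` and `e`. A missing point fails the
#' segment with that point's name.
#'
#' @param segment A `bp_segment` (or a numeric PPG vector).
#' @param cycles `cycle_set` for the segment.
#' @param vpg,apg Derivatives from [derivatives()]; computed if `NULL`.
#' @return Data frame with one row per cycle and columns `o`, `w`, `s`, `y`,
#'   `z`, `a`, `b`, `c`, `d`, `e`, `f` (sample indices), or a failure token
#'   naming the first missing point.
#' @export
locate_points <- function(segment, cycles, vpg = NULL, apg = NULL) {
  ppg <- if (inherits(segment, "bp_segment")) segment$ppg else segment
  fs <- if (inherits(segment, "bp_segment")) segment$fs else cycles$fs
  if (is.null(vpg) || is.null(apg)) {
    d <- derivatives(ppg, fs)
    vpg <- d$vpg
    apg <- d$apg
  }
  rows <- vector("list", length(cycles$peak))
  for (k in seq_along(cycles$peak)) {
    o <- cycles$onset[k]; s <- cycles$peak[k]; f <- cycles$offset[k]
    win_os <- if (s - o >= 2L) (o + 1L):(s - 1L) else integer(0)
    win_sf <- if (f - s >= 2L) (s + 1L):(f - 1L) else integer(0)
    if (length(win_os) == 0L) return(bp_fail("w"))
    w <- win_os[which.max(vpg[win_os])]
    if (length(win_sf) == 0L) return(bp_fail("y"))
    y <- win_sf[which.max(-vpg[win_sf])]
    win_yf <- if (f - y >= 2L) (y + 1L):(f - 1L) else integer(0)
    if (length(win_yf) == 0L) return(bp_fail("z"))
    z <- win_yf[which.max(vpg[win_yf])]
    a <- win_os[which.max(apg[win_os])]
    seg_apg <- apg[o:f]
    mins <- local_minima(seg_apg) + o - 1L
    maxs <- local_maxima(seg_apg) + o - 1L
    b <- mins[mins > a][1]
    if (is.na(b)) return(bp_fail("b"))
    # dicrotic-wave certificate: a dicrotic lobe contributes two curvature
    # maxima after the systolic peak (notch shoulder + trailing flank); a
    # notch-free falling limb carries exactly one, so e is declared absent
    M <- maxs[maxs > s & maxs < f]
    if (length(M) < 2L) return(bp_fail("e"))
    e <- M[which.max(apg[M])]
    cc <- maxs[maxs > b & maxs < e][1]
    if (is.na(cc)) return(bp_fail("c"))
    d_ <- mins[mins > cc & mins < e][1]
    if (is.na(d_)) return(bp_fail("d"))
    rows[[k]] <- data.frame(o = o, w = w, s = s, y = y, z = z,
                            a = a, b = b, c = cc, d = d_, e = e, f = f)
  }
  do.call(rbind, rows)
}

poi_point_names <- function() c("o", "w", "s", "y", "z", "a", "b", "c", "d", "e", "f")
time_pair_points <- function() c("o", "w", "s", "e", "z", "f")

#' Amplitude, elapsed-time and area features of one cycle
#'
#' Amplitudes of PPG, VPG and APG at every landmark; elapsed times
#' `T_x_y` (absolute time differences) for all ordered pairs among
#' o, w, s, e, z, f; and trapezoidal areas of the baseline-corrected PPG
#' over the phases split at w, s, e: `A1` = \[o,w\], `A2` = \[w,s\],
#' `A3` = \[s,e\], `A4` = \[e,f\], with `A_sys = A1 + A2` and
#' `A_dia = A3 + A4`.
#'
#' @param poi One row of the [locate_points()] result (one cycle).
#' @param ppg Numeric PPG waveform the indices refer to.
#' @param fs Sampling rate in Hz.
#' @param vpg,apg Derivatives; computed if `NULL`.
#' @return Named numeric vector.
#' @export
time_amplitude_area_features <- function(poi, ppg, fs, vpg = NULL, apg = NULL) {
  if (is.null(vpg) || is.null(apg)) {
    d <- derivatives(ppg, fs)
    vpg <- d$vpg
    apg <- d$apg
  }
  pts <- poi_point_names()
  idx <- vapply(pts, function(p) as.integer(poi[[p]][1]), integer(1))
  amp <- c(setNames(ppg[idx], paste0("ppg_", pts)),
           setNames(vpg[idx], paste0("vpg_", pts)),
           setNames(apg[idx], paste0("apg_", pts)))
  tp <- time_pair_points()
  times <- c()
  for (i in seq_len(length(tp) - 1L)) {
    for (j in (i + 1L):length(tp)) {
      nm <- paste0("T_", tp[i], "_", tp[j])
      times[nm] <- abs(idx[tp[j]] - idx[tp[i]]) / fs
    }
  }
  o <- idx["o"]; w <- idx["w"]; s <- idx["s"]; e <- idx["e"]; f <- idx["f"]
  y0 <- min(ppg[o:f])
  area <- function(i1, i2) trapz(ppg[i1:i2] - y0, 1 / fs)
  A1 <- area(o, w); A2 <- area(w, s); A3 <- area(s, e); A4 <- area(e, f)
  c(amp, times,
    A1 = A1, A2 = A2, A3 = A3, A4 = A4,
    A_sys = A1 + A2, A_dia = A3 + A4)
}

#' Systolic/diastolic width features of one cycle
#'
#' At each elevation `p` of the onset-referenced systolic amplitude, the
#' systolic width `SW_p` is the time from the rising-limb crossing to the
#' peak and the diastolic width `DW_p` the time from the peak to the falling
#' crossing (crossings by linear interpolation); sums and `DW/SW` ratios are
#' added.
#'
#' @param ppg Numeric PPG waveform.
#' @param poi One row of the [locate_points()] result.
#' @param fs Sampling rate in Hz.
#' @param elevations Elevations as fractions of the peak amplitude.
#' @return Named numeric vector, or a failure token when a crossing is
#'   missing (malformed cycle).
#' @export
width_features <- function(ppg, poi, fs, elevations = c(0.25, 0.5, 0.75)) {
  o <- poi$o[1]; s <- poi$s[1]; f <- poi$f[1]
  base <- ppg[o]
  amp <- ppg[s] - base
  if (amp <= 0) return(bp_fail("width"))
  out <- c()
  for (p in elevations) {
    level <- base + p * amp
    # rising-limb crossing: walk left from the peak
    i <- s
    while (i > o && ppg[i - 1L] > level) i <- i - 1L
    if (i == o && ppg[o] > level) return(bp_fail("width"))
    cross_l <- if (ppg[i] <= level) i
               else (i - 1L) + (level - ppg[i - 1L]) / (ppg[i] - ppg[i - 1L])
    sw <- (s - cross_l) / fs
    # falling-limb crossing: walk right from the peak
    j <- s
    while (j < f && ppg[j + 1L] > level) j <- j + 1L
    if (j == f && ppg[f] > level) return(bp_fail("width"))
    cross_r <- if (ppg[j] <= level) j
               else j + (ppg[j] - level) / (ppg[j] - ppg[j + 1L])
    dw <- (cross_r - s) / fs
    tag <- sprintf("%02d", round(100 * p))
    out[paste0("SW_", tag)] <- sw
    out[paste0("DW_", tag)] <- dw
    out[paste0("SWDW_sum_", tag)] <- sw + dw
    out[paste0("DW_SW_ratio_", tag)] <- dw / sw
  }
  out
}

#' Spectral features of a PPG segment
#'
#' Magnitude spectrum of the mean-removed segment; `f_dom` is the frequency
#' of maximum magnitude inside `band`, `mag_dom` that magnitude, and
#' `mag_near` the mean magnitude within `f_dom` +/- `delta` Hz excluding the
#' peak bin.
#'
#' @param ppg Numeric PPG segment (>= 2 s recommended).
#' @param fs Sampling rate in Hz.
#' @param band Search band in Hz.
#' @param delta Half-width of the neighbourhood in Hz.
#' @return Named numeric vector `f_dom`, `mag_dom`, `mag_near`.
#' @export
frequency_features <- function(ppg, fs, band = c(0.5, 8), delta = 0.5) {
  n <- length(ppg)
  mag <- Mod(fft(ppg - mean(ppg)))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1L) * fs / n
  sel <- which(freq >= band[1] & freq <= band[2])
  if (length(sel) == 0L) stop_spec("frequency_features: empty search band")
  k <- sel[which.max(mag[sel])]
  near <- which(abs(freq - freq[k]) <= delta & seq_along(freq) != k)
  c(f_dom = freq[k], mag_dom = mag[k],
    mag_near = if (length(near)) mean(mag[near]) else 0)
}

#' Histogram density features of a phase
#'
#' Equal-width bins spanning the min-max range of the phase samples,
#' normalized to densities summing to 1. A constant phase degenerates to
#' density 1 in the first bin.
#'
#' @param x Numeric samples of one phase (systolic or diastolic).
#' @param bins Number of bins.
#' @return Numeric vector of `bins` densities.
#' @export
histogram_features <- function(x, bins) {
  if (length(x) < 1L) stop_spec("histogram_features: empty phase")
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(c(1, rep(0, bins - 1L)))
  breaks <- seq(lo, hi, length.out = bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE),
                               1L), bins), nbins = bins)
  counts / length(x)
}

#' Slope-deviation-curve features of one cycle
#'
#' Deviation of the systolic upstroke (onset to peak) and the diastolic fall
#' (peak to offset) from their straight chords: mean absolute deviation,
#' normalized by the peak-minus-onset amplitude so the feature is
#' scale-invariant.
#'
#' @param ppg Numeric PPG waveform.
#' @param poi One row of the [locate_points()] result.
#' @return Named numeric vector `SDC_sys`, `SDC_dia` (`NA` for zero
#'   amplitude).
#' @export
sdc_features <- function(ppg, poi) {
  o <- poi$o[1]; s <- poi$s[1]; f <- poi$f[1]
  amp <- ppg[s] - ppg[o]
  if (amp == 0) return(c(SDC_sys = NA_real_, SDC_dia = NA_real_))
  chord_dev <- function(i1, i2) {
    seg <- ppg[i1:i2]
    chord <- seq(ppg[i1], ppg[i2], length.out = length(seg))
    mean(abs(seg - chord)) / amp
  }
  c(SDC_sys = chord_dev(o, s), SDC_dia = chord_dev(s, f))
}

#' Quality and index features of one cycle
#'
#' Fisher-Pearson skewness and excess kurtosis of the cycle's PPG samples;
#' the aging index `AI = (b - c - d - e)/a` on the APG amplitudes; the
#' ratio `I_bd = b/d`; `I_bcda = (b - c - d)/a`; and
#' `I_sdoo = (t_d - t_s)/(t_f - t_o)` — the elapsed time from the systolic
#' peak to APG point d, normalized by the onset-to-onset cycle duration
#' (an adopted convention; the formula is isolated here so it can be
#' swapped).
#'
#' @param ppg Numeric PPG waveform.
#' @param poi One row of the [locate_points()] result.
#' @param apg APG waveform (second derivative).
#' @return Named numeric vector `skewness`, `kurtosis`, `AI`, `I_bd`,
#'   `I_bcda`, `I_sdoo`.
#' @export
sqi_index_features <- function(ppg, poi, apg) {
  o <- poi$o[1]; f <- poi$f[1]; s <- poi$s[1]
  cyc <- ppg[o:f]
  aa <- apg[poi$a[1]]; ab <- apg[poi$b[1]]; ac <- apg[poi$c[1]]
  ad <- apg[poi$d[1]]; ae <- apg[poi$e[1]]
  if (aa == 0 || ad == 0) return(bp_fail("index_undefined"))
  c(skewness = moment_skewness(cyc),
    kurtosis = moment_kurtosis(cyc),
    AI = (ab - ac - ad - ae) / aa,
    I_bd = ab / ad,
    I_bcda = (ab - ac - ad) / aa,
    I_sdoo = (poi$d[1] - s) / (f - o))
}

#' Extract the full feature vector of a cleaned segment
#'
#' Per-cycle features (amplitudes, elapsed times, areas, widths, SDC,
#' quality, indices) are aggregated across the segment's cycles by the
#' median; the spectral features are computed once per segment. The feature
#' schema (names and order) is identical for every segment. Any sub-
#' extractor failure marks the whole segment feature-failed.
#'
#' @param segment A `bp_segment` (cycles are detected if not cached).
#' @param cycles Optional `cycle_set` override.
#' @param smooth Apply [smooth_ppg()] before differentiating (recommended
#'   for noisy signals; landmark indices stay on the same time base).
#' @return Named numeric vector, or a failure token naming the failed part.
#' @export
extract_features <- function(segment, cycles = NULL, smooth = TRUE) {
  cyc <- cycles %||% segment$cycles
  if (is.null(cyc)) {
    cyc <- detect_cycles(segment$ppg, segment$fs)
    if (is_fail(cyc)) return(cyc)
  }
  ppg <- if (smooth) smooth_ppg(segment$ppg) else segment$ppg
  fs <- segment$fs
  d <- derivatives(ppg, fs)
  poi <- locate_points(segment, cyc, d$vpg, d$apg)
  if (is_fail(poi)) return(poi)
  per_cycle <- vector("list", nrow(poi))
  for (k in seq_len(nrow(poi))) {
    row <- poi[k, , drop = FALSE]
    taa <- time_amplitude_area_features(row, ppg, fs, d$vpg, d$apg)
    wf <- width_features(ppg, row, fs)
    if (is_fail(wf)) return(wf)
    sdc <- sdc_features(ppg, row)
    sqi <- sqi_index_features(ppg, row, d$apg)
    if (is_fail(sqi)) return(sqi)
    hists <- c()
    o <- row$o; s <- row$s; f <- row$f
    for (sig in c("ppg", "vpg", "apg")) {
      x <- switch(sig, ppg = ppg, vpg = d$vpg, apg = d$apg)
      hs <- histogram_features(x[o:s], 5L)
      hd <- histogram_features(x[s:f], 10L)
      hists <- c(hists,
                 setNames(hs, paste0(sig, "_sys_h", seq_len(5L))),
                 setNames(hd, paste0(sig, "_dia_h", seq_len(10L))))
    }
    per_cycle[[k]] <- c(taa, wf, sdc, sqi, hists)
  }
  mat <- do.call(rbind, per_cycle)
  agg <- apply(mat, 2, median)
  if (anyNA(agg)) return(bp_fail("undefined_feature"))
  c(agg, frequency_features(ppg, fs))
}

#' Names of the full feature schema
#'
#' @param fs,segment_length Used to synthesize a reference segment from
#'   which the schema is read; the schema does not depend on them.
#' @return Character vector of feature names in output order.
#' @export
feature_schema <- function(fs = 125, segment_length = 5) {
  rec <- generate_pulse_train(pulse_spec(heart_rate = 70), segment_length + 1,
                              fs, seed = 1L)
  seg <- segment_record(rec, segment_length)[[1]]
  names(extract_features(seg))
}
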