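# Peak/valley detection and cardiac-cycle assembly.
#
# Detector: local-extremum search filtered by topographic prominence and a
# minimum inter-peak spacing. The prominence floor is 40% of the segment's
# full amplitude range and the spacing floor is 0.3 s (200 BPM): the
# detector stays permissive above the physiological band on purpose, so that
# tachycardic rhythms reach the downstream 35-140 BPM filter instead of
# being silently thinned out at detection time.

# Failure token used by operations that can reject a segment.
bp_fail <- function(reason, detail = NULL) {
  structure(list(reason = reason, detail = detail), class = "bp_fail")
}

#' Test whether a pipeline operation returned a failure token
#' @param x Object returned by a detection/extraction operation.
#' @return `TRUE` if `x` is a failure token.
#' @export
is_fail <- function(x) inherits(x, "bp_fail")

#' Failure reason of a rejected segment
#' @param x A failure token.
#' @return The reason string, or `NA` if `x` is not a failure.
#' @export
fail_reason <- function(x) if (is_fail(x)) x$reason else NA_character_

# Indices of strict local maxima; plateaus contribute their first sample.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  dx <- diff(x)
  s <- sign(dx)
  # carry the previous non-zero slope through plateaus
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  s_f <- s
  last <- 0
  for (i in seq_len(n - 1L)) {
    if (s[i] != 0) last <- s[i] else s_f[i] <- last
  }
  which(diff(s_f) < 0 & s_f[-length(s_f)] > 0) + 1L
}

# Topographic prominence of candidate peaks: height above the higher of the
# two lowest saddle points separating the peak from higher terrain.
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left_min <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) {
      if (x[i] < left_min) left_min <- x[i]
      i <- i - 1L
    }
    if (i < 1L) left_min <- min(x[1:p])
    right_min <- h
    i <- p + 1L
    while (i <= length(x) && x[i] <= h) {
      if (x[i] < right_min) right_min <- x[i]
      i <- i + 1L
    }
    if (i > length(x)) right_min <- min(x[p:length(x)])
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Locate prominent peaks in a waveform
#'
#' @param x Numeric waveform.
#' @param fs Sampling rate in Hz.
#' @param prominence_frac Minimum prominence as a fraction of the full
#'   amplitude range.
#' @param min_spacing Minimum spacing between kept peaks in seconds.
#' @return Integer vector of peak indices, ascending.
#' @export
find_peaks <- function(x, fs, prominence_frac = 0.4, min_spacing = 0.3) {
  rng <- diff(range(x))
  if (!is.finite(rng) || rng < 1e-12) return(integer(0))
  cand <- local_maxima(x)
  if (length(cand) == 0L) return(integer(0))
  prom <- peak_prominence(x, cand)
  cand <- cand[prom >= prominence_frac * rng]
  if (length(cand) <= 1L) return(cand)
  # greedy suppression: keep taller peaks first, drop any candidate within
  # min_spacing of an already-kept peak (half-sample tolerance)
  min_gap <- min_spacing * fs - 0.5
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) > min_gap)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Locate prominent valleys in a waveform
#' @inheritParams find_peaks
#' @return Integer vector of valley indices, ascending.
#' @export
find_valleys <- function(x, fs, prominence_frac = 0.4, min_spacing = 0.3) {
  find_peaks(-x, fs, prominence_frac, min_spacing)
}

#' Detect cardiac cycles in a waveform segment
#'
#' Cycles are valley-peak-valley triplets: consecutive detected valleys with
#' exactly one detected peak strictly between them. The segment fails with
#' reason `no_extrema` when no such triplet exists, or `p2p_bpm` /
#' `v2v_bpm` when the heart rate implied by the median peak-to-peak or
#' valley-to-valley interval falls outside `hr_range` (closed bounds pass).
#'
#' @param x Numeric waveform (PPG or ABP).
#' @param fs Sampling rate in Hz.
#' @param hr_range Admissible resting heart-rate interval in beats/min.
#' @param prominence_frac,min_spacing Detector settings, see [find_peaks()].
#' @return A `cycle_set` (fields `onset`, `peak`, `offset`, `peaks`,
#'   `valleys`, `heart_rate`, `fs`) or a failure token (see [is_fail()]).
#' @export
detect_cycles <- function(x, fs, hr_range = c(35, 140),
                          prominence_frac = 0.4, min_spacing = 0.3) {
  if (anyNA(x) || any(!is.finite(x))) {
    stop_spec("detect_cycles: waveform contains non-finite samples")
  }
  peaks <- find_peaks(x, fs, prominence_frac, min_spacing)
  valleys <- find_valleys(x, fs, prominence_frac, min_spacing)
  if (length(peaks) == 0L || length(valleys) < 2L) {
    return(bp_fail("no_extrema"))
  }
  onset <- integer(0); peak <- integer(0); offset <- integer(0)
  for (i in seq_len(length(valleys) - 1L)) {
    inside <- peaks[peaks > valleys[i] & peaks < valleys[i + 1L]]
    if (length(inside) == 1L) {
      onset <- c(onset, valleys[i])
      peak <- c(peak, inside)
      offset <- c(offset, valleys[i + 1L])
    }
  }
  if (length(peak) == 0L) return(bp_fail("no_extrema"))
  if (length(peaks) >= 2L) {
    hr_p2p <- 60 * fs / median(diff(peaks))
    if (hr_p2p < hr_range[1] || hr_p2p > hr_range[2]) {
      return(bp_fail("p2p_bpm", detail = hr_p2p))
    }
  }
  hr_v2v <- 60 * fs / median(diff(valleys))
  if (hr_v2v < hr_range[1] || hr_v2v > hr_range[2]) {
    return(bp_fail("v2v_bpm", detail = hr_v2v))
  }
  hr <- if (length(peaks) >= 2L) 60 * fs / median(diff(peaks)) else hr_v2v
  structure(list(onset = onset, peak = peak, offset = offset,
                 peaks = peaks, valleys = valleys,
                 heart_rate = hr, fs = fs),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set: %d cycles, %d peaks/%d valleys, HR %.1f BPM>\n",
              length(x$peak), length(x$peaks), length(x$valleys),
              x$heart_rate))
  invisible(x)
}
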