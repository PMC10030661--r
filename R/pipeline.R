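# The staged cleaning pipeline: alignment + segmentation, ABP screening,
# PPG cycle identification, distortion elimination, baseline-wander removal
# with re-checks, feature-extraction screening, and skewness SQI rejection,
# with a per-step audit of deleted/kept counts.

#' Pipeline configuration
#'
#' @param segment_length Segment length in seconds.
#' @param max_shift Maximum alignment shift in seconds.
#' @param abp_range Admissible ABP interval in mmHg.
#' @param pp_min Minimum pulse pressure in mmHg (strictly-greater rule).
#' @param hr_range Admissible heart-rate interval in BPM.
#' @param prominence_frac,min_spacing Peak-detector settings.
#' @param distortion_thresholds Optional explicit named thresholds for the
#'   four distortion statistics; when `NULL` they are derived at the
#'   `distortion_q` percentile of the candidate population.
#' @param distortion_q Percentile (0-100) for derived thresholds.
#' @param fail_undefined Reject segments with undefined distortion
#'   statistics (fewer than two intervals).
#' @param extract_features Run the feature-extraction screening step.
#' @param align Align PPG/ABP pairs before segmentation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(segment_length = 5, max_shift = 1,
                            abp_range = c(30, 220), pp_min = 10,
                            hr_range = c(35, 140),
                            prominence_frac = 0.4, min_spacing = 0.3,
                            distortion_thresholds = NULL, distortion_q = 97.5,
                            fail_undefined = TRUE,
                            extract_features = TRUE, align = TRUE) {
  structure(list(segment_length = segment_length, max_shift = max_shift,
                 abp_range = abp_range, pp_min = pp_min, hr_range = hr_range,
                 prominence_frac = prominence_frac, min_spacing = min_spacing,
                 distortion_thresholds = distortion_thresholds,
                 distortion_q = distortion_q,
                 fail_undefined = fail_undefined,
                 extract_features = extract_features, align = align),
            class = "pipeline_config")
}

#' Distortion thresholds for the synthetic cohort presets
#'
#' Explicit thresholds frozen from inspecting the distortion-statistic
#' distributions of clean synthetic cohorts (the same procedure used to fix
#' thresholds from cumulative-percentage plots on real data): peak-to-peak
#' interval and amplitude statistics of clean pulses sit well below 0.03
#' (seconds / PPG units) while injected spike artifacts exceed 0.2; the
#' valley-to-valley bound is looser because valley positions on the flat
#' diastolic baseline jitter with noise even for clean pulses.
#'
#' @return Named numeric vector for `pipeline_config(distortion_thresholds=)`.
#' @export
preset_distortion_thresholds <- function() {
  c(sd_p2p = 0.08, sd_v2v = 0.5, sd_peak_amp = 0.08, sd_valley_amp = 0.08)
}

segment_to_record <- function(seg) {
  new_bp_record(seg$subject_id, seg$record_id, seg$fs, seg$ppg, seg$abp,
                meta = list(sbp = seg$sbp_label, dbp = seg$dbp_label,
                            artifact = seg$artifact))
}

audit_counts <- function(segments, keep_mask) {
  kept <- segments[keep_mask]
  c(segments = length(kept),
    subjects = length(unique(vapply(kept, `[[`, "", "subject_id"))),
    records = length(unique(vapply(kept, `[[`, "", "record_id"))))
}

#' Run the full cleaning pipeline
#'
#' Applies, in order: (0) alignment and segmentation; (1) ABP screening and
#' label extraction; (2) PPG cycle identification and BPM limits; (3)
#' distorted-waveform elimination; (4) baseline-wander removal followed by a
#' re-check of the cycle/BPM and distortion criteria; (5) feature-extraction
#' screening; (6) skewness-SQI rejection. Removed segments stay in the
#' output with their removal step and reason; the audit table reconciles
#' kept/deleted counts at every step.
#'
#' @param records List of `bp_record` (or `bp_segment`) objects.
#' @param config A [pipeline_config()].
#' @return List with `segments` (all, annotated), `kept` (the kept subset),
#'   `audit` (steps and per-criterion tallies), `features` (data frame for
#'   kept segments when feature screening is on), and `config_used` (the
#'   configuration with resolved distortion thresholds — re-running the kept
#'   segments under `config_used` removes nothing).
#' @export
run_pipeline <- function(records, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(records) > 0 && inherits(records[[1]], "bp_segment")) {
    records <- lapply(records, segment_to_record)
  }

  # -- step 0: alignment + segmentation ------------------------------------
  shifts <- numeric(0)
  segments <- list()
  for (rec in records) {
    if (!is.null(rec$abp) && config$align) {
      al <- tryCatch(
        align_signals(rec$ppg, rec$abp, rec$fs, config$max_shift),
        error = function(e) list(shift = 0L, ppg = rec$ppg, abp = rec$abp))
      rec$ppg <- al$ppg
      rec$abp <- al$abp
      shifts <- c(shifts, al$shift)
    }
    segs <- withCallingHandlers(
      segment_record(rec, config$segment_length),
      warning = function(w) invokeRestart("muffleWarning"))
    segments <- c(segments, segs)
  }
  n0 <- length(segments)
  status <- rep("kept", n0)
  step <- rep(NA_integer_, n0)
  reason <- rep(NA_character_, n0)
  criteria <- data.frame(step = integer(0), criterion = character(0),
                         n = integer(0))
  steps <- data.frame(step = 0L, deleted = 0L,
                      t(audit_counts(segments, rep(TRUE, n0))))

  mark_removed <- function(i, st, rs) {
    status[i] <<- "removed"
    step[i] <<- st
    reason[i] <<- rs
  }
  add_criterion <- function(st, tag, n) {
    if (n > 0) criteria <<- rbind(criteria,
                                  data.frame(step = st, criterion = tag, n = n))
  }
  close_step <- function(st) {
    deleted <- sum(step == st, na.rm = TRUE)
    steps <<- rbind(steps, data.frame(
      step = st, deleted = deleted,
      t(audit_counts(segments, status == "kept"))))
  }
  alive <- function() which(status == "kept")

  # -- step 1: extremely abnormal ABP removal + label extraction -----------
  tallies <- c(amplitude = 0L, pulse_pressure = 0L, heart_rate = 0L,
               no_cycles = 0L)
  for (i in alive()) {
    seg <- segments[[i]]
    if (is.null(seg$abp)) next
    res <- filter_abp_extreme(seg, config$abp_range, config$pp_min,
                              config$hr_range,
                              prominence_frac = config$prominence_frac,
                              min_spacing = config$min_spacing)
    for (r in res$reasons) tallies[r] <- tallies[r] + 1L
    if (!res$pass) {
      mark_removed(i, 1L, paste(res$reasons, collapse = "+"))
    } else {
      lab <- extract_bp_labels(seg$abp, res$cycles)
      segments[[i]]$sbp_label <- lab[["sbp"]]
      segments[[i]]$dbp_label <- lab[["dbp"]]
    }
  }
  for (tag in names(tallies)) add_criterion(1L, tag, tallies[[tag]])
  close_step(1L)

  # -- step 2: PPG cycle identification + BPM limits -----------------------
  tallies <- c(no_extrema = 0L, p2p_bpm = 0L, v2v_bpm = 0L)
  for (i in alive()) {
    cyc <- detect_cycles(segments[[i]]$ppg, segments[[i]]$fs,
                         hr_range = config$hr_range,
                         prominence_frac = config$prominence_frac,
                         min_spacing = config$min_spacing)
    if (is_fail(cyc)) {
      tallies[cyc$reason] <- tallies[cyc$reason] + 1L
      mark_removed(i, 2L, cyc$reason)
    } else {
      segments[[i]]$cycles <- cyc
    }
  }
  for (tag in names(tallies)) add_criterion(2L, tag, tallies[[tag]])
  close_step(2L)

  # -- step 3: distorted PPG waveform elimination --------------------------
  idx3 <- alive()
  thresholds <- config$distortion_thresholds
  if (length(idx3) > 0) {
    stats3 <- t(vapply(idx3, function(i) {
      distortion_statistics(segments[[i]], segments[[i]]$cycles)
    }, numeric(4)))
    res3 <- filter_distortion(stats3, thresholds, config$distortion_q,
                              config$fail_undefined)
    thresholds <- res3$thresholds
    fail_i <- idx3[!res3$pass]
    for (i in fail_i) mark_removed(i, 3L, "ppg_distortion")
    add_criterion(3L, "ppg_distortion", length(fail_i))
  }
  close_step(3L)

  # -- step 4: baseline-wander removal + re-check --------------------------
  tallies <- c(post_bw_cycles = 0L, post_bw_distortion = 0L)
  for (i in alive()) {
    seg <- remove_baseline_wander(segments[[i]], segments[[i]]$cycles)
    cyc <- detect_cycles(seg$ppg, seg$fs, hr_range = config$hr_range,
                         prominence_frac = config$prominence_frac,
                         min_spacing = config$min_spacing)
    if (is_fail(cyc)) {
      tallies["post_bw_cycles"] <- tallies[["post_bw_cycles"]] + 1L
      mark_removed(i, 4L, paste0("post_bw_", cyc$reason))
      next
    }
    seg$cycles <- cyc
    st <- distortion_statistics(seg, cyc)
    res <- filter_distortion(rbind(st), thresholds,
                             config$distortion_q, config$fail_undefined)
    if (!res$pass[1]) {
      tallies["post_bw_distortion"] <- tallies[["post_bw_distortion"]] + 1L
      mark_removed(i, 4L, "post_bw_distortion")
      next
    }
    segments[[i]] <- seg
  }
  for (tag in names(tallies)) add_criterion(4L, tag, tallies[[tag]])
  close_step(4L)

  # -- step 5: feature-extraction screening --------------------------------
  features <- NULL
  if (config$extract_features) {
    rows <- list()
    nfail <- 0L
    for (i in alive()) {
      fv <- extract_features(segments[[i]])
      if (is_fail(fv)) {
        nfail <- nfail + 1L
        mark_removed(i, 5L, paste0("feature_", fv$reason))
      } else {
        rows[[length(rows) + 1L]] <- c(list(.i = i), as.list(fv))
      }
    }
    add_criterion(5L, "feature_failure", nfail)
    if (length(rows) > 0) {
      features <- do.call(rbind, lapply(rows, function(r) {
        as.data.frame(r, check.names = FALSE)
      }))
    }
  }
  close_step(5L)

  # -- step 6: skewness SQI ------------------------------------------------
  nskew <- 0L
  for (i in alive()) {
    sk <- sqi_skewness(segments[[i]]$ppg)
    if (is.na(sk) || sk < 0) {
      nskew <- nskew + 1L
      mark_removed(i, 6L, if (is.na(sk)) "degenerate" else "negative_skewness")
    }
  }
  add_criterion(6L, "negative_skewness", nskew)
  close_step(6L)

  for (i in seq_len(n0)) {
    segments[[i]]$status <- status[i]
    segments[[i]]$removal_step <- step[i]
    segments[[i]]$removal_reason <- reason[i]
  }
  kept <- segments[status == "kept"]
  if (!is.null(features)) {
    keep_rows <- features$.i %in% which(status == "kept")
    meta <- do.call(rbind, lapply(features$.i[keep_rows], function(i) {
      data.frame(subject_id = segments[[i]]$subject_id,
                 record_id = segments[[i]]$record_id,
                 segment_index = segments[[i]]$segment_index,
                 sbp = segments[[i]]$sbp_label,
                 dbp = segments[[i]]$dbp_label)
    }))
    features <- cbind(meta, features[keep_rows, setdiff(names(features), ".i"),
                                     drop = FALSE])
    rownames(features) <- NULL
  }
  config_used <- config
  config_used$distortion_thresholds <- thresholds
  # kept segments are already aligned and cut to length; a rerun must not
  # re-shift (and thereby truncate) them
  config_used$align <- FALSE
  list(segments = segments, kept = kept,
       audit = list(steps = steps, criteria = criteria,
                    alignment_shifts = shifts),
       features = features, config_used = config_used)
}

#' Audit-table view of a pipeline run
#'
#' @param result Value of [run_pipeline()].
#' @return Data frame with one row per step: deleted and kept counts.
#' @export
audit_table <- function(result) result$audit$steps
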