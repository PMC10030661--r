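# Preprocessing operations: alignment, segmentation, ABP screening, label
# extraction, cycle detection, distortion statistics, baseline-wander
# removal, skewness SQI.

test_that("alignment returns lag 0 for identical signals and caps the window", {
  rec <- clean_record(duration = 6)
  al <- align_signals(rec$abp, rec$abp, rec$fs)
  expect_identical(al$shift, 0L)
  # a true delay beyond max_shift still yields a shift inside the window
  big <- clean_record(ppg_delay = 1.5, duration = 10)
  al2 <- align_signals(big$ppg, big$abp, big$fs, max_shift = 1)
  expect_gte(al2$shift, -125L)
  expect_lte(al2$shift, 125L)
  expect_error(align_signals(rep(1, 1000), rep(2, 1000), 125), "constant")
})

test_that("segmentation produces exact non-overlapping chunks", {
  rec <- clean_record(duration = 15)
  segs <- segment_record(rec, 5)
  expect_length(segs, 3L)
  expect_true(all(vapply(segs, function(s) length(s$ppg), numeric(1)) == 625))
  # concatenation reproduces the first 3 * 625 input samples
  expect_identical(unlist(lapply(segs, `[[`, "ppg")), rec$ppg[1:1875])
  rec2 <- clean_record(duration = 14.9)
  expect_length(segment_record(rec2, 5), 2L)
  short <- clean_record(duration = 3, hr = 60)
  expect_warning(out <- segment_record(short, 5), "shorter")
  expect_length(out, 0L)
})

test_that("ABP screening flags amplitude, pulse pressure and heart rate", {
  mk <- function(...) segment_record(clean_record(duration = 6, ...), 5)[[1]]
  ok <- mk(hr = 60, sbp = 120, dbp = 80)
  expect_true(filter_abp_extreme(ok)$pass)
  hi <- mk(hr = 60, sbp = 225, dbp = 80)
  expect_true("amplitude" %in% filter_abp_extreme(hi)$reasons)
  pp <- mk(hr = 60, sbp = 100, dbp = 92)
  expect_true("pulse_pressure" %in% filter_abp_extreme(pp)$reasons)
  fast <- segment_record(generate_pulse_train(
    pulse_spec(heart_rate = 160), 6, 125, seed = 1), 5)[[1]]
  expect_true("heart_rate" %in% filter_abp_extreme(fast)$reasons)
  noabp <- ok; noabp$abp <- NULL
  expect_error(filter_abp_extreme(noabp), "no ABP")
})

test_that("label extraction takes medians of peaks and pooled valleys", {
  # hand-built waveform: 4 cycles with peak values 118, 120, 122, 140
  fs <- 100
  peaks_v <- c(118, 120, 122, 140)
  abp <- rep(80, 420)
  cyc_on <- c(1, 101, 201, 301)
  cyc_pk <- cyc_on + 50
  cyc_of <- c(101, 201, 301, 401)
  for (k in 1:4) {
    idx <- cyc_on[k]:cyc_of[k]
    abp[idx] <- 80 + (peaks_v[k] - 80) *
      sin(pi * (idx - cyc_on[k]) / (cyc_of[k] - cyc_on[k]))
  }
  cyc <- structure(list(onset = cyc_on, peak = cyc_pk, offset = cyc_of,
                        peaks = cyc_pk, valleys = c(cyc_on, 401),
                        heart_rate = 60, fs = fs), class = "cycle_set")
  lab <- extract_bp_labels(abp, cyc)
  expect_equal(unname(lab["sbp"]), 121)   # mean of central pair 120, 122
  expect_equal(unname(lab["dbp"]), 80)
})

test_that("labels recover generator ground truth and scale affinely", {
  rec <- clean_record(hr = 75, sbp = 135, dbp = 65, duration = 6)
  cyc <- detect_cycles(rec$abp, rec$fs)
  lab <- extract_bp_labels(rec$abp, cyc)
  expect_lt(abs(lab[["sbp"]] - 135), 1)
  expect_lt(abs(lab[["dbp"]] - 65), 1)
  lab2 <- extract_bp_labels(1.1 * rec$abp + 5, cyc)
  expect_equal(unname(lab2), unname(1.1 * lab + 5))
})

test_that("cycle detection fails tachycardia, bradycardia and flatlines", {
  fast <- generate_pulse_train(pulse_spec(heart_rate = 150), 6, 125, seed = 1)
  expect_identical(fail_reason(detect_cycles(fast$ppg, 125)), "p2p_bpm")
  slow <- generate_pulse_train(pulse_spec(heart_rate = 28), 7, 125, seed = 1)
  f_slow <- detect_cycles(slow$ppg, 125)
  expect_true(fail_reason(f_slow) %in% c("p2p_bpm", "v2v_bpm"))
  expect_identical(fail_reason(detect_cycles(rep(0.5, 625), 125)), "no_extrema")
  expect_error(detect_cycles(c(1, NA, 2), 125), "non-finite")
  ok <- detect_cycles(clean_record(duration = 5)$ppg, 125)
  expect_gte(length(ok$peaks), 4L)
  expect_lte(length(ok$peaks), 5L)
  expect_lt(abs(ok$heart_rate - 60), 2)
  expect_true(all(ok$onset < ok$peak & ok$peak < ok$offset))
})

test_that("distortion statistics match hand-computed standard deviations", {
  seg <- segment_record(clean_record(duration = 6), 5)[[1]]
  cyc <- detect_cycles(seg$ppg, seg$fs)
  st <- distortion_statistics(seg, cyc)
  expect_true(all(st < 0.02))  # periodic noiseless train
  # perturb one peak amplitude by +50%: sd matches the direct formula
  seg2 <- seg
  seg2$ppg[cyc$peaks[2]] <- 1.5 * seg2$ppg[cyc$peaks[2]]
  st2 <- distortion_statistics(seg2, cyc)
  expect_equal(unname(st2["sd_peak_amp"]), sd(seg2$ppg[cyc$peaks]))
  # alternating intervals 0.8/1.2 s: closed-form two-point SD
  m <- 6
  pk <- cumsum(c(10, rep(c(80, 120), 3)))
  cyc3 <- structure(list(peaks = pk, valleys = pk - 5,
                         onset = pk[-length(pk)] - 5, peak = pk[-length(pk)],
                         offset = pk[-1] - 5, heart_rate = 60, fs = 100),
                    class = "cycle_set")
  seg3 <- seg; seg3$fs <- 100
  st3 <- distortion_statistics(seg3, cyc3)
  expect_equal(unname(st3["sd_p2p"]), 0.2 * sqrt(m / (m - 1)), tolerance = 1e-12)
})

test_that("distortion filtering honours explicit and percentile thresholds", {
  clean <- matrix(0, nrow = 99, ncol = 4,
                  dimnames = list(NULL, names(preset_distortion_thresholds())))
  pop <- rbind(clean, 1)  # one outlier among 99 clean
  res <- filter_distortion(pop, q = 97.5)
  expect_identical(sum(!res$pass), 1L)
  expect_false(res$pass[100])
  # vacuous explicit thresholds remove nothing
  res2 <- filter_distortion(pop, thresholds = setNames(rep(Inf, 4), colnames(pop)))
  expect_true(all(res2$pass))
  expect_error(filter_distortion(pop[0, ], q = 97.5), "empty population")
})

test_that("baseline-wander removal pins valleys to zero and recovers the clean shape", {
  clean <- clean_record(hr = 70, duration = 6)
  drift <- clean_record(hr = 70, duration = 6, bw_amplitude = 0.3,
                        bw_frequency = 0.2)
  seg_c <- segment_record(clean, 5)[[1]]
  seg_d <- segment_record(drift, 5)[[1]]
  cyc <- detect_cycles(seg_d$ppg, seg_d$fs)
  corr <- remove_baseline_wander(seg_d, cyc)
  v <- cyc$valleys
  expect_lt(max(abs(corr$ppg[v])), 1e-9)
  rng <- v[1]:v[length(v)]
  ref <- seg_c$ppg[rng] - min(seg_c$ppg[rng])
  rmse_corr <- sqrt(mean((corr$ppg[rng] - ref)^2))
  rmse_drift <- sqrt(mean((seg_d$ppg[rng] - seg_c$ppg[rng])^2))
  expect_lt(rmse_corr, rmse_drift / 5)
  # peak count is preserved (within 1)
  expect_lte(abs(length(find_peaks(corr$ppg, 125)) -
                 length(find_peaks(seg_c$ppg, 125))), 1L)
})

test_that("baseline correction leaves an already-flat signal unchanged", {
  seg <- segment_record(clean_record(duration = 6), 5)[[1]]
  cyc <- detect_cycles(seg$ppg, seg$fs)
  base <- min(seg$ppg)
  seg$ppg <- seg$ppg - base   # valleys already at ~0
  corr <- remove_baseline_wander(seg, cyc)
  v <- cyc$valleys
  rng <- v[1]:v[length(v)]
  expect_lt(max(abs(corr$ppg[rng] - seg$ppg[rng])), 1e-6)
})

test_that("skewness SQI follows the moment formula and its sign rules", {
  x <- c(0, 0, 0, 10)
  m <- mean(x); m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  expect_equal(sqi_skewness(x), m3 / m2^1.5)
  expect_gt(sqi_skewness(x), 0)
  seg <- segment_record(clean_record(duration = 6), 5)[[1]]
  sk <- sqi_skewness(seg$ppg)
  expect_gt(sk, 0)
  expect_equal(sqi_skewness(-seg$ppg), -sk, tolerance = 1e-12)
  expect_true(is.na(sqi_skewness(rep(1, 10))))
})

test_that("ABP and PPG screening read only their own channel", {
  seg <- segment_record(clean_record(duration = 6), 5)[[1]]
  poisoned <- seg; poisoned$ppg <- rep(1e6, length(seg$ppg))
  expect_identical(filter_abp_extreme(seg)$reasons,
                   filter_abp_extreme(poisoned)$reasons)
  poisoned2 <- seg; poisoned2$abp <- rep(1e6, length(seg$abp))
  c1 <- detect_cycles(seg$ppg, seg$fs)
  c2 <- detect_cycles(poisoned2$ppg, poisoned2$fs)
  expect_identical(c1$peaks, c2$peaks)
  expect_identical(distortion_statistics(seg, c1),
                   distortion_statistics(poisoned2, c2))
})

test_that("decimation preserves cycle structure at the reduced rate", {
  rec <- generate_pulse_train(pulse_spec(heart_rate = 70), 6, 1000, seed = 1)
  dec <- decimate_record(rec, 8)
  expect_identical(dec$fs, 125)
  expect_identical(dec$n, rec$n %/% 8L)
  c_hi <- detect_cycles(rec$abp, 1000)
  c_lo <- detect_cycles(dec$abp, 125)
  expect_lte(abs(length(c_hi$peaks) - length(c_lo$peaks)), 1L)
  expect_lt(abs(c_hi$heart_rate - c_lo$heart_rate), 2)
})
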