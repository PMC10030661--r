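# Feature catalog: derivatives, landmark localization, time/amplitude/area,
# widths, spectral, histogram, slope-deviation, quality/index features, and
# the segment-level extractor invariants.

test_that("derivatives match closed forms", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  ramp <- derivatives(t, fs)
  expect_true(all(abs(ramp$vpg[2:(length(t) - 1)] - 1) < 1e-9))
  expect_true(all(abs(ramp$apg[2:(length(t) - 1)]) < 1e-6))
  sine <- derivatives(sin(2 * pi * t), fs)
  interior <- 3:(length(t) - 2)
  expect_lt(max(abs(sine$vpg[interior] - 2 * pi * cos(2 * pi * t[interior]))),
            1e-3)
  flat <- derivatives(rep(2, 100), fs)
  expect_true(all(flat$vpg == 0) && all(flat$apg == 0))
})

test_that("landmarks sit where the generator put them", {
  rec <- clean_record(hr = 60, notch_delay = 0.30, duration = 10)
  seg <- segment_record(rec, 5)[[1]]
  cyc <- detect_cycles(seg$ppg, seg$fs)
  poi <- locate_points(seg, cyc)
  expect_s3_class(poi, "data.frame")
  # e (dicrotic notch) 0.30 +/- 0.02 s after the systolic peak, every cycle
  expect_true(all(abs((poi$e - poi$s) / seg$fs - 0.30) < 0.02))
  # ordering invariants
  expect_true(all(poi$o < poi$w & poi$w < poi$s & poi$s < poi$f))
  expect_true(all(poi$a < poi$b & poi$b < poi$c & poi$c < poi$d & poi$d < poi$e))
  expect_true(all(poi$e > poi$s & poi$e < poi$f))
})

test_that("a notch-free pulse fails at landmark e", {
  rec <- clean_record(hr = 60, notch_depth = 0, duration = 10)
  seg <- segment_record(rec, 5)[[1]]
  poi <- locate_points(seg, detect_cycles(seg$ppg, seg$fs))
  expect_true(is_fail(poi))
  expect_identical(fail_reason(poi), "e")
})

test_that("areas are additive and elapsed times recover the notch delay", {
  rec <- clean_record(hr = 60, notch_delay = 0.30, duration = 10)
  seg <- segment_record(rec, 5)[[1]]
  cyc <- detect_cycles(seg$ppg, seg$fs)
  d <- derivatives(seg$ppg, seg$fs)
  poi <- locate_points(seg, cyc, d$vpg, d$apg)
  fv <- time_amplitude_area_features(poi[1, ], seg$ppg, seg$fs, d$vpg, d$apg)
  expect_equal(fv[["A_sys"]], fv[["A1"]] + fv[["A2"]], tolerance = 1e-12)
  expect_equal(fv[["A_dia"]], fv[["A3"]] + fv[["A4"]], tolerance = 1e-12)
  # A_sys + A_dia equals the trapezoid over [o, f] exactly
  o <- poi$o[1]; f <- poi$f[1]
  y <- seg$ppg[o:f] - min(seg$ppg[o:f])
  total <- sum((y[-1] + y[-length(y)]) / 2) / seg$fs
  expect_equal(fv[["A_sys"]] + fv[["A_dia"]], total, tolerance = 1e-12)
  expect_lt(abs(fv[["T_s_e"]] - 0.30), 0.02)
  # all elapsed times are non-negative
  expect_true(all(fv[grepl("^T_", names(fv))] >= 0))
  # amplitude at the systolic peak is the cycle maximum
  expect_equal(fv[["ppg_s"]], max(seg$ppg[o:f]))
})

test_that("triangle-cycle widths follow the closed form", {
  tri <- triangle_cycle(half_T = 0.4, fs = 1000)
  wf <- width_features(tri$ppg, tri$poi, tri$fs)
  for (p in c(25, 50, 75)) {
    tag <- sprintf("%02d", p)
    expect_equal(wf[[paste0("SW_", tag)]], (1 - p / 100) * 0.4,
                 tolerance = 1e-2)
    expect_equal(wf[[paste0("DW_SW_ratio_", tag)]], 1, tolerance = 1e-6)
  }
  expect_equal(wf[["SW_25"]] / wf[["SW_75"]], 3, tolerance = 1e-2)
  # monotone in elevation
  expect_true(wf[["SW_25"]] >= wf[["SW_50"]] &&
                wf[["SW_50"]] >= wf[["SW_75"]])
  expect_true(wf[["DW_25"]] >= wf[["DW_50"]] &&
                wf[["DW_50"]] >= wf[["DW_75"]])
})

test_that("skewed pulses have diastole longer than systole at half height", {
  rec <- clean_record(hr = 60, duration = 10)
  seg <- segment_record(rec, 5)[[1]]
  cyc <- detect_cycles(seg$ppg, seg$fs)
  poi <- locate_points(seg, cyc)
  wf <- width_features(seg$ppg, poi[1, ], seg$fs)
  expect_gt(wf[["DW_SW_ratio_50"]], 1)
})

test_that("spectral features find the dominant tone", {
  fs <- 125
  t <- (0:624) / fs
  f1 <- frequency_features(sin(2 * pi * 1.2 * t), fs)
  expect_lt(abs(f1[["f_dom"]] - 1.2), fs / 625 + 1e-9)
  two <- sin(2 * pi * 1 * t) + 0.3 * sin(2 * pi * 2 * t)
  expect_lt(abs(frequency_features(two, fs)[["f_dom"]] - 1), fs / 625 + 1e-9)
  # white noise spreads energy: the neighbourhood ratio grows
  noise <- withr::with_seed(1, rnorm(625))
  r_tone <- f1[["mag_near"]] / f1[["mag_dom"]]
  fn <- frequency_features(noise, fs)
  expect_gt(fn[["mag_near"]] / fn[["mag_dom"]], r_tone)
})

test_that("histogram densities count correctly and sum to one", {
  expect_equal(histogram_features(seq(0, 1, length.out = 1000), 5),
               rep(0.2, 5), tolerance = 5e-3)
  expect_equal(histogram_features(c(rep(0, 50), rep(1, 50)), 5),
               c(0.5, 0, 0, 0, 0.5))
  for (i in 1:20) {
    x <- withr::with_seed(i, rnorm(100))
    expect_equal(sum(histogram_features(x, 10)), 1, tolerance = 1e-12)
  }
  expect_equal(histogram_features(rep(3, 10), 5), c(1, 0, 0, 0, 0))
})

test_that("slope-deviation features match the quadratic closed form", {
  tri <- triangle_cycle()
  sdc_tri <- sdc_features(tri$ppg, tri$poi)
  expect_lt(sdc_tri[["SDC_sys"]], 1e-9)
  expect_lt(sdc_tri[["SDC_dia"]], 1e-9)
  # quadratic upstroke y = x^2 against chord y = x: mean |x - x^2| = 1/6
  n <- 2000
  x <- seq(0, 1, length.out = n + 1)
  ppg <- c(x^2, seq(1, 0, length.out = 200)[-1])
  poi <- data.frame(o = 1L, s = n + 1L, f = n + 200L)
  sdc_q <- sdc_features(ppg, poi)
  expect_equal(sdc_q[["SDC_sys"]], 1 / 6, tolerance = 1e-3)
  # amplitude scaling leaves SDC unchanged
  sdc_s <- sdc_features(10 * ppg, poi)
  expect_equal(sdc_s[["SDC_sys"]], sdc_q[["SDC_sys"]], tolerance = 1e-12)
})

test_that("index features follow the documented conventions", {
  # place APG amplitudes (a..e) = (2, -1, 0.2, -0.4, 0.6) at known indices
  apg <- rep(0, 100)
  idx <- c(a = 10L, b = 20L, c = 30L, d = 40L, e = 50L)
  apg[idx] <- c(2, -1, 0.2, -0.4, 0.6)
  poi <- data.frame(o = 5L, w = 8L, s = 25L, y = 35L, z = 45L,
                    a = 10L, b = 20L, c = 30L, d = 40L, e = 50L, f = 95L)
  ppg <- c(seq(0, 1, length.out = 50), seq(1, 0, length.out = 50))
  out <- sqi_index_features(ppg, poi, apg)
  expect_equal(out[["AI"]], (-1 - 0.2 - (-0.4) - 0.6) / 2)  # = -0.7
  expect_equal(out[["AI"]], -0.7)
  expect_equal(out[["I_bd"]], 2.5)
  expect_equal(out[["I_bcda"]], (-1 - 0.2 + 0.4) / 2)
  expect_equal(out[["I_sdoo"]], (40 - 25) / (95 - 5))
  # symmetric cycle samples have ~zero skewness
  expect_lt(abs(out[["skewness"]]), 0.05)
})

test_that("segment extraction has a fixed schema and is shift/scale stable", {
  rec <- clean_record(hr = 60, duration = 10)
  seg <- segment_record(rec, 5)[[1]]
  fv <- extract_features(seg)
  expect_false(is_fail(fv))
  expect_identical(names(fv), feature_schema())
  # a different pulse yields the same schema
  seg2 <- segment_record(clean_record(hr = 80, duration = 6), 5)[[1]]
  expect_identical(names(extract_features(seg2)), names(fv))
  # circular shift by one whole cycle changes nothing materially
  period <- round(125 * 60 / 60)
  shifted <- seg
  shifted$ppg <- c(seg$ppg[(period + 1):length(seg$ppg)], seg$ppg[1:period])
  fv_s <- extract_features(shifted)
  common <- grepl("^T_|^SW_|^DW_|^SDC|^A", names(fv))
  expect_equal(fv[common], fv_s[common], tolerance = 0.05)
})

test_that("amplitude scaling affects exactly the documented feature groups", {
  seg <- segment_record(clean_record(hr = 70, duration = 6), 5)[[1]]
  seg10 <- seg; seg10$ppg <- 10 * seg$ppg
  f1 <- extract_features(seg)
  f10 <- extract_features(seg10)
  tnames <- grepl("^T_|^SW_\\d|^DW_\\d", names(f1))
  expect_equal(f1[tnames], f10[tnames], tolerance = 1e-9)
  anames <- grepl("^A[1-4]$|^A_sys$|^A_dia$|^ppg_[a-z]$", names(f1))
  expect_equal(10 * f1[anames], f10[anames], tolerance = 1e-9)
  inames <- grepl("^SDC|^skewness$|^kurtosis$|^AI$|^I_|_h\\d+$", names(f1))
  expect_equal(f1[inames], f10[inames], tolerance = 1e-9)
})

test_that("faster heart rates shorten the cycle-relative elapsed times", {
  ts <- vapply(c(60, 75, 90), function(hr) {
    seg <- segment_record(clean_record(hr = hr, duration = 6), 5)[[1]]
    extract_features(seg)[["T_o_f"]]
  }, numeric(1))
  expect_true(all(diff(ts) < 0))
})

test_that("two identical cycles aggregate to the single-cycle features", {
  seg <- segment_record(clean_record(hr = 60, duration = 6), 5)[[1]]
  cyc <- detect_cycles(seg$ppg, seg$fs)
  fv_all <- extract_features(seg)
  # medians over identical noiseless cycles equal any one cycle's features
  d <- derivatives(smooth_ppg(seg$ppg), seg$fs)
  poi <- locate_points(smooth_ppg(seg$ppg), cyc, d$vpg, d$apg)
  one <- time_amplitude_area_features(poi[1, ], smooth_ppg(seg$ppg), seg$fs,
                                      d$vpg, d$apg)
  expect_equal(fv_all[["T_s_e"]], one[["T_s_e"]], tolerance = 1e-9)
  expect_equal(fv_all[["A_sys"]], one[["A_sys"]], tolerance = 1e-3)
})
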