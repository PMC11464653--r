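test_that("occlusion test accepts unity transmission and rejects low ratios", {
  t <- seq(0, 8, by = 0.01)
  mk <- function(pes_scale) {
    paw <- 10 + 5 * sin(2 * pi * 1.7 * t)
    pressure_trace(data.frame(time_s = t, paw_cmh2o = paw,
                              pes_cmh2o = 10 + pes_scale * 5 * sin(2 * pi * 1.7 * t)),
                   fs = 100, annotations = NULL)
  }
  r1 <- occlusion_test(mk(1), c(0, 8))
  expect_equal(r1$ratio, 1, tolerance = 1e-9)
  expect_true(r1$valid)
  r06 <- occlusion_test(mk(0.6), c(0, 8))
  expect_equal(r06$ratio, 0.6, tolerance = 1e-9)
  expect_false(r06$valid)
  flat <- pressure_trace(data.frame(time_s = t, paw_cmh2o = 10,
                                    pes_cmh2o = 10), 100, NULL)
  expect_error(occlusion_test(flat, c(0, 8)), "no compression")
})

test_that("generator occlusion-test segments transmit swings near unity", {
  occ <- data.frame(start_s = 5, duration_s = 8, kind = "exp",
                    compressions = TRUE)
  ep <- data.frame(label = "e", start_s = 0, end_s = 5, kind = "cc_mechanical",
                   cc_amp = 12)
  w <- gen_pressure_traces(waveform_params(duration_s = 15, epochs = ep,
                                           occlusions = occ, noise_sd = 0.1,
                                           seed = 3))
  r <- occlusion_test(w$trace, c(5, 13))
  expect_gt(r$ratio, 0.95)
  expect_lt(r$ratio, 1.05)
  expect_true(r$valid)
})

test_that("compression cycles are detected at the generated rate", {
  w <- make_cc_trace(cc_amp = 12, noise_sd = 0.2, duration = 60, seed = 2)
  cyc <- detect_cc_cycles(w$trace, c(0, 60))
  expect_gte(nrow(cyc), 101)
  expect_lte(nrow(cyc), 103)
  expect_lt(abs(attr(cyc, "rate_per_min") - 102) / 102, 0.01)
  expect_false(attr(cyc, "rate_warning"))
  w120 <- make_cc_trace(cc_amp = 12, noise_sd = 0.2, duration = 60,
                        cc_rate = 120, seed = 3)
  cyc120 <- detect_cc_cycles(w120$trace, c(0, 60))
  expect_lt(abs(attr(cyc120, "rate_per_min") - 120) / 120, 0.01)
  # no compressions: nothing to detect
  ep0 <- data.frame(label = "b", start_s = 0, end_s = 30, kind = "baseline",
                    cc_amp = 0)
  w0 <- gen_pressure_traces(waveform_params(duration_s = 30, epochs = ep0,
                                            noise_sd = 0, seed = 1))
  expect_error(detect_cc_cycles(w0$trace, c(0, 30)), "no compression cycles")
})

test_that("per-cycle swings recover the constructed amplitude and ordering", {
  # noiseless pure pulse train without ventilation: swing = amplitude
  ep <- data.frame(label = "e", start_s = 0, end_s = 30, kind = "cc_mechanical",
                   cc_amp = 10)
  w <- gen_pressure_traces(waveform_params(duration_s = 30, epochs = ep,
                                           vt = 0.001, noise_sd = 0, seed = 1))
  cyc <- detect_cc_cycles(w$trace, c(0, 30))
  st <- pes_swing_stats(w$trace, cyc, ep, smooth_hz = NULL)
  expect_equal(st$epochs$mean_swing, 10, tolerance = 0.02) # sampling of the pulse apex

  # with ventilation superimposed: epoch mean within 3% of generator truth
  wv <- make_cc_trace(cc_amp = 12, noise_sd = 0.2, duration = 60, seed = 4)
  cycv <- detect_cc_cycles(wv$trace, c(0, 60))
  stv <- pes_swing_stats(wv$trace, cycv,
                         data.frame(label = "e1", start_s = 0, end_s = 60,
                                    kind = "cc_mechanical"))
  expect_lt(abs(stv$epochs$mean_swing /
                wv$truth$epoch_swings$e1$mean_swing - 1), 0.03)
  expect_error(pes_swing_stats(wv$trace, cycv[0, ]), "empty")
})

test_that("epochs with larger amplitude rank higher in mean swing", {
  ep <- data.frame(label = c("weak", "strong"), start_s = c(0, 40),
                   end_s = c(40, 80), kind = c("cc_manual", "cc_mechanical"),
                   cc_amp = c(8, 14), stringsAsFactors = FALSE)
  w <- gen_pressure_traces(waveform_params(duration_s = 80, epochs = ep,
                                           noise_sd = 0.2, seed = 5))
  st1 <- pes_swing_stats(w$trace, detect_cc_cycles(w$trace, c(0, 40)),
                         ep[1, , drop = FALSE])
  st2 <- pes_swing_stats(w$trace, detect_cc_cycles(w$trace, c(40, 80)),
                         ep[2, , drop = FALSE])
  expect_gt(st2$epochs$mean_swing, st1$epochs$mean_swing)
})

test_that("swing estimator is unbiased across stochastic replicates", {
  errs <- vapply(1:50, function(s) {
    w <- make_cc_trace(cc_amp = 12, noise_sd = 0.2, duration = 20, seed = s)
    cyc <- detect_cc_cycles(w$trace, c(0, 20))
    st <- pes_swing_stats(w$trace, cyc,
                          data.frame(label = "e1", start_s = 0, end_s = 20,
                                     kind = "cc_mechanical"))
    st$epochs$mean_swing - w$truth$epoch_swings$e1$mean_swing
  }, numeric(1))
  se <- stats::sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), max(se, 0.01 * 12))
})

test_that("plateau extraction settles to the true value", {
  t <- seq(0, 6, by = 0.01)
  const <- pressure_trace(data.frame(time_s = t, paw_cmh2o = 20,
                                     pes_cmh2o = 8), 100, NULL)
  p <- plateau_values(const, c(0, 6))
  expect_equal(p$paw_plateau, 20)
  expect_equal(p$pes_plateau, 8)
  # exponential settling to 15 with tau = 0.3 s
  expo <- pressure_trace(data.frame(time_s = t,
                                    paw_cmh2o = 15 + 6 * exp(-t / 0.3),
                                    pes_cmh2o = 8), 100, NULL)
  expect_lt(abs(plateau_values(expo, c(0, 6))$paw_plateau - 15), 0.1)
  # noisy constant: mean over the tail
  set.seed(31)
  noisy <- pressure_trace(data.frame(time_s = t,
                                     paw_cmh2o = 10 + rnorm(length(t), 0, 0.2),
                                     pes_cmh2o = 8), 100, NULL)
  expect_lt(abs(plateau_values(noisy, c(0, 6))$paw_plateau - 10), 0.2)
  # a ramp never settles
  ramp <- pressure_trace(data.frame(time_s = t, paw_cmh2o = 10 + 2 * t,
                                    pes_cmh2o = 8), 100, NULL)
  expect_error(plateau_values(ramp, c(0, 6)), "not settled")
  expect_error(plateau_values(const, c(0, 3)), "at least 5 s")
})

test_that("partitioned mechanics reproduces hand arithmetic and recovers truth", {
  # direct arithmetic: Pplat 20, PEEPtot 10, Pes plateaus 8/4, VT 500
  tr <- pressure_trace(data.frame(
    time_s = seq(0, 14, by = 0.01),
    paw_cmh2o = c(rep(20, 601), rep(10, 800)),
    pes_cmh2o = c(rep(8, 601), rep(4, 800))), 100, NULL)
  mp <- partitioned_mechanics(tr, c(0, 6), c(7, 14), vt = 500)
  expect_equal(mp$dp_rs, 10); expect_equal(mp$dp_cw, 4); expect_equal(mp$dp_l, 6)
  expect_equal(mp$crs, 50); expect_equal(mp$ccw, 125)
  expect_equal(mp$cl, 500 / 6, tolerance = 1e-12)
  expect_lt(abs(1 / mp$crs - 1 / mp$ccw - 1 / mp$cl), 1e-12)
  # generator truth, noiseless
  w <- make_cc_trace(cl = 50, ccw = 100, noise_sd = 0, duration = 30, seed = 1)
  mpg <- partitioned_mechanics(w$trace, c(35, 41), c(45, 51), vt = 500)
  expect_lt(abs(mpg$cl / 50 - 1), 0.01)
  expect_lt(abs(mpg$ccw / 100 - 1), 0.01)
  # degenerate: equal Pes plateaus
  bad <- pressure_trace(data.frame(
    time_s = seq(0, 14, by = 0.01),
    paw_cmh2o = c(rep(20, 601), rep(10, 800)),
    pes_cmh2o = rep(8, 1401)), 100, NULL)
  expect_error(partitioned_mechanics(bad, c(0, 6), c(7, 14), vt = 500),
               "chest-wall")
})

test_that("mechanics recovery holds across random configurations with noise", {
  set.seed(17)
  errs <- t(vapply(1:20, function(i) {
    cl <- runif(1, 25, 80); ccw <- runif(1, 60, 180)
    vt <- runif(1, 350, 650); r_aw <- runif(1, 5, 20)
    w <- make_cc_trace(cc_amp = 12, cl = cl, ccw = ccw, noise_sd = 0.2,
                       duration = 30, seed = 100 + i, vt = vt, r_aw = r_aw)
    mp <- partitioned_mechanics(w$trace, c(35, 41), c(45, 51), vt = vt)
    expect_lt(abs(1 / mp$crs - (1 / mp$cl + 1 / mp$ccw)), 1e-9)
    c(abs(mp$cl / cl - 1), abs(mp$ccw / ccw - 1))
  }, numeric(2)))
  expect_lt(stats::median(errs[, 1]), 0.02)
  expect_lt(stats::median(errs[, 2]), 0.02)
})

test_that("coronary perfusion pressure picks the decompression diastolic difference", {
  # constant channels: CPP is the plain difference each cycle
  w <- make_cc_trace(cc_amp = 12, noise_sd = 0, duration = 20, seed = 1,
                     vascular = TRUE, ao_pulse = 0, ra_pulse = 0,
                     ao_dia = 40, ra_base = 10)
  cyc <- detect_cc_cycles(w$trace, c(0, 20))
  cpp <- coronary_perfusion_pressure(w$trace, cyc)
  expect_true(all(abs(cpp$cpp_mmhg - 30) < 1e-9))
  # pulsatile channels: decompression minimum of Ao is its diastolic level
  wp <- make_cc_trace(cc_amp = 12, noise_sd = 0, duration = 20, seed = 2,
                      vascular = TRUE, ao_pulse = 35, ra_pulse = 30,
                      ao_dia = 25, ra_base = 10)
  cycp <- detect_cc_cycles(wp$trace, c(0, 20))
  cppp <- coronary_perfusion_pressure(wp$trace, cycp)
  expect_lt(abs(attr(cppp, "mean_cpp") / 15 - 1), 0.01)
  # identical channels: zero CPP
  weq <- make_cc_trace(cc_amp = 12, noise_sd = 0, duration = 20, seed = 3,
                       vascular = TRUE, ao_pulse = 30, ra_pulse = 30,
                       ao_dia = 20, ra_base = 20)
  cyce <- detect_cc_cycles(weq$trace, c(0, 20))
  cppe <- coronary_perfusion_pressure(weq$trace, cyce)
  expect_true(all(abs(cppe$cpp_mmhg) < 1e-9))
  no_vasc <- make_cc_trace(cc_amp = 12, noise_sd = 0, duration = 10, seed = 1)
  cycn <- detect_cc_cycles(no_vasc$trace, c(0, 10))
  expect_error(coronary_perfusion_pressure(no_vasc$trace, cycn), "channels")
})
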