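test_that("simulate_iap: noise-free profile hits the plateau exactly", {
  iap <- iap_profile_params(14, t_insufflate = 50, t_deflate = 400,
                            ramp_tau = 10, sigma = 0)
  s <- simulate_iap(iap, 450, seed = 1)
  expect_s3_class(s, "wave_signal")
  expect_equal(s$dt_nominal, 0.04)
  # pre-insufflation baseline is identically zero
  expect_true(all(s$v[s$t < 50] == 0))
  # late plateau (> 20 time constants in): equal to target
  late <- s$t > 350 & s$t < 400
  expect_equal(s$v[late], rep(14, sum(late)), tolerance = 1e-6)
  # deflation decays back toward zero
  expect_lt(s$v[length(s$v)], 0.2)
})

test_that("simulate_iap: plateau fluctuations are calibrated", {
  iap <- iap_profile_params(14, t_insufflate = 50, t_deflate = 600,
                            ramp_tau = 10, sigma = 0.5)
  s <- simulate_iap(iap, 650, seed = 42)
  plateau <- s$t > 150 & s$t <= 150 + 1e4 * 0.04  # 10^4 samples
  x <- s$v[plateau]
  expect_equal(length(x), 1e4)
  expect_lt(abs(mean(x) - 14), 0.1)
  expect_lt(abs(sd(x) - 0.5), 0.2)
})

test_that("simulate_iap: transient deflations dip and input errors raised", {
  iap <- iap_profile_params(12, t_insufflate = 40, t_deflate = 400,
                            ramp_tau = 8, sigma = 0,
                            transient_deflations = list(c(200, 60)))
  s <- simulate_iap(iap, 450, seed = 1)
  dip <- s$t > 240 & s$t < 260
  expect_lt(max(s$v[dip]), 6)          # dropped well below plateau
  expect_true(all(s$v >= 0))
  expect_error(simulate_iap(iap, -5), "positive")
  expect_error(simulate_iap(iap, 300), "t_deflate")
})

test_that("VCV with zero resistance reproduces PIP - PEEP = VT/C exactly", {
  ses <- simulate_subject(vcv_profile(C0 = 50, R_aw = 0, k = 0, VT = 500,
                                      PEEP = 5), 300)
  br <- breath_table(ses)
  # PIP carries a <= 0.1% clip from the 20 ms display sampling; the clip
  # cancels in Cdyn because VT is sampled on the same grid
  expect_equal(br$PIP, rep(15, nrow(br)), tolerance = 1e-3)
  expect_equal(br$Cdyn, rep(50, nrow(br)), tolerance = 1e-6)
})

test_that("PCV ideal matches the closed-form tidal volume within 1%", {
  prof <- pcv_profile(C0 = 40, R_aw = 0.01, k = 0, Pins = 20, PEEP = 5,
                      RR = 12, IE = 0.667)
  ses <- simulate_subject(prof, 300)
  br <- breath_table(ses)
  T_insp <- (60 / 12) * 0.667 / 1.667
  vt_ref <- pcv_vt_closed_form(15, 40, 0.01, T_insp)
  expect_lt(max(abs(br$VT - vt_ref)) / vt_ref, 0.01)
  expect_equal(br$PIP, rep(20, nrow(br)), tolerance = 1e-6)
})

test_that("IAP coupling raises VCV PIP during the plateau", {
  ses <- simulate_subject(vcv_profile(R_aw = 0.008, k = 1.2, sigma = 0.3,
                                      t_ins = 80, t_def = 280), 330)
  br <- breath_table(ses)
  pre <- br$t_insp_start < 70
  plat <- br$t_insp_start > 180 & br$t_insp_start < 270
  expect_gt(mean(br$PIP[plat]), mean(br$PIP[pre]))
  # and VT is strictly decreasing in IAP for ideal PCV
  ses2 <- simulate_subject(pcv_profile(k = 1.3, sigma = 0,
                                       t_ins = 80, t_def = 280), 330)
  br2 <- breath_table(ses2)
  ramp <- br2$t_insp_start > 85 & br2$t_insp_start < 140
  expect_true(all(diff(br2$VT[ramp]) < 0))
})

test_that("per-breath volume agrees with the integral of positive flow", {
  for (prof in list(vcv_profile(R_aw = 0.008, k = 1.2, sigma = 0.3),
                    pcv_profile(k = 1.3, sigma = 0.3))) {
    ses <- simulate_subject(prof, 300)
    # at the integrator's own resolution the books balance to 0.5%
    truth <- ses$truth_breaths
    mid <- truth[2:(nrow(truth) - 1L), ]
    expect_lt(max(abs(mid$vol_pos_flow - mid$VT) / mid$VT), 0.005)
    # the 20 ms device channels stay consistent to ~1 sample of flow
    br <- breath_table(ses)
    fl <- ses$streams$flow
    qmax <- max(fl$v) / 0.06
    for (b in sample(nrow(br), 10)) {
      w <- fl$t >= br$t_insp_start[b] & fl$t < br$t_end[b]
      q <- pmax(fl$v[w], 0) / 0.06          # l/min -> ml/s
      vint <- sum(q) * fl$dt_nominal
      expect_lt(abs(vint - br$VT[b]), 1.5 * qmax * fl$dt_nominal)
    }
  }
})

test_that("simulation is deterministic given profile and seed", {
  prof <- vcv_profile(k = 1.2, sigma = 0.4, seed = 7)
  s1 <- simulate_subject(prof, 300, sensor_noise = 0.05)
  s2 <- simulate_subject(prof, 300, sensor_noise = 0.05)
  expect_identical(s1$streams, s2$streams)
  expect_identical(s1$truth_breaths, s2$truth_breaths)
})

test_that("apply_acquisition: identity clocks and zero loss change nothing", {
  ses <- simulate_subject(vcv_profile(), 300)
  acq <- apply_acquisition(ses, clocks = list(), missing_rate = 0, seed = 1)
  for (nm in names(ses$streams)) {
    expect_equal(acq$streams[[nm]]$t, ses$streams[[nm]]$t)
    expect_equal(acq$streams[[nm]]$v, ses$streams[[nm]]$v)
  }
})

test_that("apply_acquisition: printed skew loses about 5 s over 3 h", {
  tt <- seq(0, 10800, by = 0.04)
  sig <- wave_signal("iap", tt, sin(tt / 100), 0.04, "mmHg")
  ses <- recording_session(
    list(iap = sig),
    settings_timeline(0, list(ventilation_settings(
      "VCV", VT_target = 450, RR = 12, IE = 0.667, PEEP_set = 5))))
  acq <- apply_acquisition(ses, clocks = list(iap = clock_model(4.63e-4, 0)),
                           missing_rate = 0, seed = 1)
  t_rel <- acq$streams$iap$t
  expect_equal((10800 - max(t_rel)) , 5.0, tolerance = 0.01)
})

test_that("apply_acquisition: deletions are binomial and fully logged", {
  tt <- seq(0, by = 0.04, length.out = 1e5)
  sig <- wave_signal("iap", tt, rep(10, 1e5), 0.04, "mmHg")
  ses <- recording_session(
    list(iap = sig),
    settings_timeline(0, list(ventilation_settings(
      "VCV", VT_target = 450, RR = 12, IE = 0.667, PEEP_set = 5))))
  acq <- apply_acquisition(ses, missing_rate = 0.01, seed = 11)
  n_del <- sum(grepl("^missing:iap", acq$event_log$label))
  expect_equal(length(acq$streams$iap$t), 1e5 - n_del)
  sigma3 <- 3 * sqrt(1e5 * 0.01 * 0.99)
  expect_lt(abs(n_del - 1000), sigma3)
  expect_error(apply_acquisition(ses, missing_rate = 0.5), "missing_rate")
})

test_that("scenario presets have their defining properties", {
  p <- scenario_preset("vcv_standard")
  expect_identical(p$settings_schedule[[1]]$settings$mode, "VCV")
  expect_equal(p$settings_schedule[[1]]$settings$VT_target, 450)
  expect_equal(p$iap$iap_target, 14)

  p <- scenario_preset("pcv_limited")
  expect_true(is.finite(p$insp_flow_limit))
  pins <- vapply(p$settings_schedule,
                 function(e) e$settings$Pins_max, numeric(1))
  expect_true(any(diff(pins) > 0))     # the mid-procedure raises

  p <- scenario_preset("repositioning")
  expect_gt(p$lung$dC_reposition, 0)
  expect_gt(length(p$reposition_times), 0)

  expect_error(scenario_preset("nope"), "vcv_standard")
})

test_that("pcv_limited: simulated PIP stays under Pins_max after the raise", {
  p <- scenario_preset("pcv_limited", seed = 4)
  ses <- simulate_subject(p, 1500)
  br <- breath_table(ses)
  phaseB <- br$t_insp_start > 950 & br$t_insp_start < 1350
  expect_true(all(br$PIP[phaseB] < 38))
  expect_true(all(br$Pins_max[phaseB] == 38))
})
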