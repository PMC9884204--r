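#' @useDynLib iaplung, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif
NULL

# run expr with a locally-seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

IAP_DT <- 0.04     # insufflator stream interval [s] (25 Hz)
WAVE_DT <- 0.02    # ventilator wave interval [s] (50 Hz)
SETTINGS_DT <- 60  # settings stream interval [s]
OU_TAU <- 2        # IAP fluctuation mean-reversion time constant [s]

#' Simulate the intra-abdominal pressure stream
#'
#' IAP is zero before insufflation, follows a first-order ramp (time
#' constant `ramp_tau`) toward `iap_target`, carries mean-reverting
#' (Ornstein-Uhlenbeck) fluctuations of stationary standard deviation
#' `sigma` while the abdomen is inflated, dips during any transient
#' partial deflations, and decays back to zero after `t_deflate`.
#' Sampled at the insufflator's 40 ms interval.
#'
#' @param iap [iap_profile_params()].
#' @param duration recording length \[s\], must exceed `t_deflate`.
#' @param seed integer seed.
#' @return A [wave_signal()] named `"iap"` in mmHg.
#' @export
simulate_iap <- function(iap, duration, seed = 1L) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  if (duration <= iap$t_deflate) {
    stop("duration must exceed t_deflate", call. = FALSE)
  }
  t <- seq(0, duration, by = IAP_DT)
  # target envelope: plateau between events, partial drop during transients
  u <- ifelse(t >= iap$t_insufflate & t < iap$t_deflate, iap$iap_target, 0)
  for (td in iap$transient_deflations) {
    u[t >= td[1] & t < td[1] + td[2]] <- 0.3 * iap$iap_target
  }
  a <- exp(-IAP_DT / iap$ramp_tau)
  env <- as.numeric(stats::filter((1 - a) * u, a, method = "recursive"))
  noise <- if (iap$sigma > 0) {
    b <- exp(-IAP_DT / OU_TAU)
    eps <- with_seed(seed, rnorm(length(t), 0, iap$sigma * sqrt(1 - b^2)))
    as.numeric(stats::filter(eps, b, method = "recursive"))
  } else {
    numeric(length(t))
  }
  # fluctuations only while inflated; hard floor at 0 (gauge pressure)
  v <- pmax(0, env + noise * pmin(1, env / max(iap$iap_target, 1e-9)))
  wave_signal("iap", t, v, IAP_DT, "mmHg")
}

#' Simulate one subject's full operating-room recording session
#'
#' Integrates the single-compartment lung model (see
#' [lung_model_params()]) against the subject's IAP trajectory and
#' scheduled ventilation settings at a 1 ms step, then resamples to the
#' device-native rates: airway pressure, flow and volume at 20 ms, IAP at
#' 40 ms, settings every 60 s. The session keeps the generating profile
#' and a per-breath ground-truth table (`$truth_breaths`: controller
#' onset times, delivered VT, mean effective compliance).
#'
#' @param profile [subject_profile()].
#' @param duration recording length \[s\]; must cover all scheduled events.
#' @param sensor_noise additive Gaussian noise s.d. on the pressure
#'   channel \[mbar\] (scaled equivalents on flow/volume); 0 disables.
#' @return A [recording_session()].
#' @export
simulate_subject <- function(profile, duration, sensor_noise = 0) {
  stopifnot(inherits(profile, "subject_profile"))
  last_sched <- profile$settings_schedule[[length(profile$settings_schedule)]]
  if (duration <= max(profile$iap$t_deflate, last_sched$time)) {
    stop("duration must cover all scheduled events", call. = FALSE)
  }
  iap_sig <- simulate_iap(profile$iap, duration + 1, profile$seed)

  sch <- profile$settings_schedule
  s_t <- vapply(sch, function(e) e$time, numeric(1))
  s_set <- lapply(sch, `[[`, "settings")
  mode_i <- vapply(s_set, function(s) if (s$mode == "PCV") 1L else 0L,
                   integer(1))
  num <- function(f, d = 0) {
    x <- vapply(s_set, function(s) as.numeric(s[[f]]), numeric(1))
    ifelse(is.na(x), d, x)
  }
  res <- lung_ode_cpp(
    duration = duration, dt = 0.001, out_stride = 20L,
    iap = iap_sig$v, iap_dt = IAP_DT,
    sched_t = s_t, sched_mode = mode_i,
    sched_vt = num("VT_target", 500), sched_pins = num("Pins_max", 20),
    sched_rr = num("RR", 12), sched_ie = num("IE", 0.667),
    sched_peep = num("PEEP_set", 5),
    C0 = profile$lung$C0, R_aw = profile$lung$R_aw, k = profile$lung$k,
    C_min = profile$lung$C_min, dC_repo = profile$lung$dC_reposition,
    repo_times = profile$reposition_times,
    slew = profile$rise_rate_limit, flow_limit = profile$insp_flow_limit
  )
  paw <- res$paw
  flow <- res$flow_ml_s * 0.06        # ml/s -> l/min
  vol <- res$volume
  if (sensor_noise > 0) {
    n <- length(paw)
    noise <- with_seed(profile$seed + 1L, rnorm(3L * n))
    paw <- paw + sensor_noise * noise[seq_len(n)]
    flow <- flow + 2 * sensor_noise * noise[n + seq_len(n)]
    vol <- vol + 5 * sensor_noise * noise[2L * n + seq_len(n)]
  }
  n_iap <- sum(iap_sig$t < duration)
  st <- seq(0, duration - 1e-9, by = SETTINGS_DT)
  # sample the schedule at the settings stream's 60 s interval
  timeline <- settings_timeline(
    st, settings_at(settings_timeline(s_t, s_set), st))

  ev <- data.frame(
    time = c(profile$iap$t_insufflate, profile$iap$t_deflate,
             profile$reposition_times, s_t[-1]),
    label = c("insufflate", "deflate",
              rep("reposition", length(profile$reposition_times)),
              rep("settings_change", length(s_t) - 1L)),
    stringsAsFactors = FALSE
  )
  ses <- recording_session(
    streams = list(
      airway_pressure = wave_signal("airway_pressure", res$t, paw,
                                    WAVE_DT, "mbar"),
      flow = wave_signal("flow", res$t, flow, WAVE_DT, "l/min"),
      volume = wave_signal("volume", res$t, vol, WAVE_DT, "ml"),
      iap = wave_signal("iap", iap_sig$t[seq_len(n_iap)],
                        iap_sig$v[seq_len(n_iap)], IAP_DT, "mmHg")
    ),
    settings = timeline, event_log = ev, ground_truth = profile
  )
  ses$truth_breaths <- data.frame(
    t_onset = res$breath_onset, t_exp_onset = res$breath_exp_onset,
    VT = res$breath_vt, C_eff = res$breath_ceff,
    C_eff_insp_end = res$breath_ceff_end_insp,
    C_eff_max = res$breath_ceff_max,
    vol_pos_flow = res$breath_qpos_int
  )
  ses
}

#' Degrade a session the way real acquisition does
#'
#' Rewrites each stream's timestamps onto its device's relative clock
#' (`t_rel = (t_abs - offset) * (1 - cf_true)`), deletes samples at
#' random (logged in the event log), and attaches paired
#' absolute/relative clock observations every 5 minutes per device --
#' the analogue of requesting the monitor's configuration telegram
#' during recording -- from which ingestion re-estimates the skew.
#'
#' @param session a [recording_session()].
#' @param clocks named list of [clock_model()] keyed by channel; channels
#'   without an entry keep an identity clock.
#' @param missing_rate per-sample deletion probability, in \[0, 0.1).
#' @param seed integer seed.
#' @return The degraded [recording_session()]; ground truth retained.
#' @export
apply_acquisition <- function(session, clocks = list(), missing_rate = 0,
                              seed = 1L) {
  stopifnot(inherits(session, "recording_session"),
            missing_rate >= 0, missing_rate < 0.1)
  ev <- session$event_log
  out <- session
  u_all <- with_seed(seed, runif(sum(vapply(session$streams,
                                            function(s) length(s$t),
                                            integer(1)))))
  pos <- 0L
  for (nm in names(session$streams)) {
    sig <- session$streams[[nm]]
    ck <- if (!is.null(clocks[[nm]])) clocks[[nm]] else clock_model(0, 0)
    t_rel <- (sig$t - ck$offset) * (1 - ck$cf_true)
    keep <- u_all[pos + seq_along(sig$t)] >= missing_rate
    pos <- pos + length(sig$t)
    n_del <- sum(!keep)
    if (n_del > 0) {
      ev <- rbind(ev, data.frame(
        time = sig$t[!keep],
        label = rep(paste0("missing:", nm), n_del),
        stringsAsFactors = FALSE))
    }
    # paired clock readings every 5 min, always including the stream end
    obs_t <- unique(c(seq(0, max(sig$t), by = 300), max(sig$t)))
    out$clock_obs[[nm]] <- data.frame(
      t_abs = obs_t, t_rel = (obs_t - ck$offset) * (1 - ck$cf_true))
    out$streams[[nm]] <- wave_signal(sig$channel, t_rel[keep],
                                     sig$v[keep], sig$dt_nominal, sig$units)
    out$clocks[[nm]] <- ck
  }
  out$event_log <- ev[order(ev$time), , drop = FALSE]
  out
}

#' Ready-made simulation scenarios
#'
#' Four documented subject profiles covering the qualitative regimes seen
#' during laparoscopy:
#' * `vcv_standard` -- volume-controlled subject; rising IAP stiffens the
#'   respiratory system and PIP rises while VT is held.
#' * `pcv_ideal` -- pressure-controlled subject with an ideal square
#'   pressure drive; PIP clamps at Pins_max and VT falls as IAP rises.
#' * `pcv_limited` -- pressure-controlled subject whose ventilator flow
#'   capacity binds after the anaesthesiologist raises Pins_max (+14 then
#'   +6 mbar); PIP then stays below Pins_max and tracks the elastic load
#'   while VT is flow-determined and stable.
#' * `repositioning` -- pressure-controlled subject moved from lithotomy
#'   to supine and back mid-procedure; compliance changes while IAP is
#'   constant, confounding the IAP-Cdyn relation.
#'
#' Parameter values sit in the clinically reported ranges (VT 400-560 ml,
#' Pins_max 12-38 mbar, RR 8-18, PEEP 5-9 mbar, target IAP 11-15 mmHg).
#' Each profile's natural duration is attached as attribute `"duration"`.
#'
#' @param name one of `"vcv_standard"`, `"pcv_ideal"`, `"pcv_limited"`,
#'   `"repositioning"`.
#' @param seed integer seed stored in the profile.
#' @return A [subject_profile()].
#' @export
scenario_preset <- function(name, seed = 1L) {
  presets <- c("vcv_standard", "pcv_ideal", "pcv_limited", "repositioning")
  if (!is.character(name) || length(name) != 1L || !(name %in% presets)) {
    stop("unknown preset; available: ", paste(presets, collapse = ", "),
         call. = FALSE)
  }
  sched <- function(...) {
    es <- list(...)
    lapply(es, function(e) list(time = e[[1]], settings = e[[2]]))
  }
  prof <- switch(
    name,
    vcv_standard = subject_profile(
      "vcv_standard",
      lung = lung_model_params(C0 = 50, R_aw = 0.008, k = 1.2, C_min = 12),
      iap = iap_profile_params(14, t_insufflate = 120, t_deflate = 1080,
                               ramp_tau = 25, sigma = 0.3,
                               transient_deflations = list(c(550, 90))),
      settings_schedule = sched(
        list(0, ventilation_settings("VCV", VT_target = 450, RR = 14,
                                     IE = 0.667, PEEP_set = 5))),
      seed = seed),
    pcv_ideal = subject_profile(
      "pcv_ideal",
      lung = lung_model_params(C0 = 48, R_aw = 0.010, k = 1.3, C_min = 12),
      iap = iap_profile_params(12, t_insufflate = 120, t_deflate = 1080,
                               ramp_tau = 25, sigma = 0.3,
                               transient_deflations = list(c(550, 90))),
      settings_schedule = sched(
        list(0, ventilation_settings("PCV", Pins_max = 22, RR = 12,
                                     IE = 0.667, PEEP_set = 8))),
      seed = seed),
    pcv_limited = subject_profile(
      "pcv_limited",
      lung = lung_model_params(C0 = 40, R_aw = 0.012, k = 1.0, C_min = 10),
      iap = iap_profile_params(14, t_insufflate = 100, t_deflate = 1400,
                               ramp_tau = 25, sigma = 0.3,
                               transient_deflations = list(c(420, 90),
                                                           c(1080, 90))),
      settings_schedule = sched(
        list(0, ventilation_settings("PCV", Pins_max = 18, RR = 12,
                                     IE = 0.667, PEEP_set = 5)),
        list(700, ventilation_settings("PCV", Pins_max = 32, RR = 12,
                                       IE = 0.667, PEEP_set = 5)),
        list(900, ventilation_settings("PCV", Pins_max = 38, RR = 12,
                                       IE = 0.667, PEEP_set = 5))),
      insp_flow_limit = 225,
      seed = seed),
    repositioning = subject_profile(
      "repositioning",
      lung = lung_model_params(C0 = 40, R_aw = 0.010, k = 1.0, C_min = 10,
                               dC_reposition = 12),
      iap = iap_profile_params(12, t_insufflate = 120, t_deflate = 1380,
                               ramp_tau = 25, sigma = 0.3),
      settings_schedule = sched(
        list(0, ventilation_settings("PCV", Pins_max = 20, RR = 12,
                                     IE = 0.667, PEEP_set = 5))),
      reposition_times = c(600, 1100),
      seed = seed)
  )
  attr(prof, "duration") <- switch(name,
                                   vcv_standard = 1200, pcv_ideal = 1200,
                                   pcv_limited = 1500, repositioning = 1500)
  prof
}

#' Draw a randomised subject profile from the clinical setting ranges
#'
#' Used to build simulated cohorts: ventilation settings are drawn
#' uniformly from the reported ranges (VCV: VT 400-560 ml; PCV: Pins_max
#' 14-30 mbar; RR 8-18; I:E 0.5-1.0; PEEP 5-9 mbar; target IAP
#' 11-15 mmHg), and lung parameters from realistic adult ranges
#' (C0 35-55 ml/mbar, R_aw 0.006-0.015 mbar s/ml).
#'
#' @param subject_id identifier.
#' @param mode `"VCV"` or `"PCV"`.
#' @param seed integer seed (drives both the draw and the simulation).
#' @param k IAP-compliance coupling \[ml/mbar per mmHg\]; 0 decouples.
#' @return A [subject_profile()] with attribute `"duration"` (900 s).
#' @export
random_subject_profile <- function(subject_id, mode = c("VCV", "PCV"),
                                   seed = 1L, k = 1.2) {
  mode <- match.arg(mode)
  with_seed(seed, {
    rr <- round(runif(1, 8, 18))
    ie <- round(runif(1, 0.5, 1.0), 3)
    peep <- round(runif(1, 5, 9))
    set <- if (mode == "VCV") {
      ventilation_settings("VCV", VT_target = round(runif(1, 400, 560)),
                           RR = rr, IE = ie, PEEP_set = peep)
    } else {
      ventilation_settings("PCV", Pins_max = round(runif(1, peep + 9, 30)),
                           RR = rr, IE = ie, PEEP_set = peep)
    }
    C0 <- runif(1, 35, 55)
    prof <- subject_profile(
      subject_id,
      lung = lung_model_params(C0 = C0, R_aw = runif(1, 0.006, 0.015),
                               k = k, C_min = 10),
      iap = iap_profile_params(round(runif(1, 11, 15)),
                               t_insufflate = 100, t_deflate = 780,
                               ramp_tau = 25, sigma = 0.3,
                               transient_deflations = list(c(400, 80))),
      settings_schedule = list(list(time = 0, settings = set)),
      seed = seed)
    attr(prof, "duration") <- 900
    prof
  })
}
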