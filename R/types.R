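#' Uniformly-timestamped waveform channel
#'
#' The basic container for one device channel: a timestamp vector, a value
#' vector (NA marks a flagged gap) and the channel's nominal sampling
#' interval. Timestamps are seconds from session start on whichever clock
#' the signal currently lives on (device-relative before ingestion, the
#' local-computer timebase after [correct_clock()]).
#'
#' @param channel channel name, e.g. `"airway_pressure"`.
#' @param t numeric vector of timestamps \[s\], strictly increasing.
#' @param v numeric vector of values, same length as `t`; `NA` allowed.
#' @param dt_nominal nominal sampling interval \[s\].
#' @param units unit string, e.g. `"mbar"`.
#' @return An object of class `wave_signal`.
#' @export
wave_signal <- function(channel, t, v, dt_nominal, units = "") {
  stopifnot(is.numeric(t), is.numeric(v), length(t) == length(v))
  if (length(t) == 0L) stop("wave_signal: empty signal", call. = FALSE)
  if (any(diff(t) <= 0)) {
    stop("wave_signal: timestamps must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(dt_nominal) || dt_nominal <= 0) {
    stop("wave_signal: dt_nominal must be > 0", call. = FALSE)
  }
  structure(
    list(channel = as.character(channel), t = as.numeric(t),
         v = as.numeric(v), dt_nominal = as.numeric(dt_nominal),
         units = as.character(units)),
    class = "wave_signal"
  )
}

#' @export
print.wave_signal <- function(x, ...) {
  cat(sprintf("<wave_signal '%s'> %d samples @ %g s [%s], span %.2f-%.2f s, %d NA\n",
              x$channel, length(x$t), x$dt_nominal, x$units,
              x$t[1], x$t[length(x$t)], sum(is.na(x$v))))
  invisible(x)
}

#' Ventilation settings record
#'
#' One row of the anaesthesia-machine settings stream. Exactly one of
#' `VT_target` (volume-controlled mode, VCV/IMV) or `Pins_max`
#' (pressure-controlled mode, PCV) is active; the inactive one is `NA`.
#' The I:E ratio is the single-decimal convention T_insp/T_exp
#' (1:1.5 -> 0.667).
#'
#' @param mode `"VCV"` or `"PCV"`.
#' @param VT_target target tidal volume \[ml\] (VCV only).
#' @param Pins_max pre-set inspiratory pressure \[mbar\] (PCV only).
#' @param RR respiration rate \[1/min\], in \[6, 30\].
#' @param IE inspiration/expiration time ratio, in (0, 2\].
#' @param PEEP_set set positive end-expiratory pressure \[mbar\].
#' @return An object of class `ventilation_settings`.
#' @export
ventilation_settings <- function(mode, VT_target = NA_real_,
                                 Pins_max = NA_real_, RR, IE, PEEP_set) {
  mode <- match.arg(mode, c("VCV", "PCV"))
  if (mode == "VCV") {
    if (!is.finite(VT_target) || VT_target <= 0) {
      stop("VCV requires a positive VT_target", call. = FALSE)
    }
    Pins_max <- NA_real_
  } else {
    if (!is.finite(Pins_max)) stop("PCV requires Pins_max", call. = FALSE)
    if (Pins_max <= PEEP_set) {
      stop("PCV requires Pins_max > PEEP_set", call. = FALSE)
    }
    VT_target <- NA_real_
  }
  stopifnot(RR >= 6, RR <= 30, IE > 0, IE <= 2, PEEP_set >= 0)
  structure(
    list(mode = mode, VT_target = VT_target, Pins_max = Pins_max,
         RR = RR, IE = IE, PEEP_set = PEEP_set),
    class = "ventilation_settings"
  )
}

#' Stepwise ventilation-settings timeline
#'
#' Settings are anaesthesiologist actions: each row holds from its
#' timestamp until the next row (previous-value-hold semantics).
#'
#' @param t numeric vector of timestamps \[s\], strictly increasing.
#' @param rows list of [ventilation_settings()] of the same length.
#' @return An object of class `settings_timeline`.
#' @export
settings_timeline <- function(t, rows) {
  stopifnot(length(t) == length(rows), length(t) >= 1L)
  if (any(diff(t) <= 0)) {
    stop("settings_timeline: t must be strictly increasing", call. = FALSE)
  }
  ok <- vapply(rows, inherits, logical(1), what = "ventilation_settings")
  if (!all(ok)) stop("rows must be ventilation_settings", call. = FALSE)
  structure(list(t = as.numeric(t), rows = rows), class = "settings_timeline")
}

#' Single-compartment lung model parameters
#'
#' Phenomenological model of the IAP-compliance coupling: the effective
#' respiratory-system compliance is
#' `C_eff(t) = max(C_min, C0 - k * IAP(t) + reposition term)`.
#' The coupling constant `k` is deliberately defined in ml/mbar per mmHg
#' of IAP so that no pressure-unit conversion is needed downstream
#' (correlation coefficients are scale invariant).
#'
#' @param C0 baseline compliance \[ml/mbar\].
#' @param R_aw airway resistance \[mbar s/ml\].
#' @param k IAP-to-compliance coupling \[ml/mbar per mmHg\].
#' @param C_min compliance floor \[ml/mbar\].
#' @param dC_reposition additive compliance step while the patient is
#'   repositioned (supine vs lithotomy) \[ml/mbar\].
#' @return An object of class `lung_model_params`.
#' @export
lung_model_params <- function(C0, R_aw = 0, k = 0, C_min = C0 / 5,
                              dC_reposition = 0) {
  stopifnot(C0 > 0, R_aw >= 0, k >= 0, C_min > 0, C_min <= C0)
  structure(
    list(C0 = C0, R_aw = R_aw, k = k, C_min = C_min,
         dC_reposition = dC_reposition),
    class = "lung_model_params"
  )
}

#' Insufflator pressure profile parameters
#'
#' The IAP trajectory: zero before insufflation, a first-order ramp with
#' time constant `ramp_tau` to the plateau `iap_target`, mean-reverting
#' fluctuations with stationary standard deviation `sigma` on the plateau,
#' optional transient partial deflations (e.g. trocar changes), and a
#' first-order decay back to zero at deflation.
#'
#' @param iap_target plateau pressure \[mmHg\], in \[0, 30\].
#' @param t_insufflate,t_deflate event times \[s\], `t_insufflate < t_deflate`.
#' @param ramp_tau ramp time constant \[s\].
#' @param sigma fluctuation standard deviation \[mmHg\].
#' @param transient_deflations list of `c(time, duration)` pairs \[s\].
#' @return An object of class `iap_profile_params`.
#' @export
iap_profile_params <- function(iap_target, t_insufflate, t_deflate,
                               ramp_tau = 20, sigma = 0.3,
                               transient_deflations = list()) {
  stopifnot(iap_target >= 0, iap_target <= 30,
            t_insufflate < t_deflate, ramp_tau > 0, sigma >= 0)
  structure(
    list(iap_target = iap_target, t_insufflate = t_insufflate,
         t_deflate = t_deflate, ramp_tau = ramp_tau, sigma = sigma,
         transient_deflations = transient_deflations),
    class = "iap_profile_params"
  )
}

#' Device clock model
#'
#' A device's relative clock runs at `(1 - cf_true)` times the absolute
#' (local-computer) rate and starts `offset` seconds after session start:
#' `t_rel = (t_abs - offset) * (1 - cf_true)`. For elapsed durations this
#' reproduces the correction-factor definition
#' `CF = (dt_abs - dt_rel) / dt_abs = cf_true`.
#'
#' @param cf_true fractional skew, `|cf_true| < 0.01`.
#' @param offset clock start offset \[s\].
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(cf_true = 0, offset = 0) {
  stopifnot(abs(cf_true) < 0.01)
  structure(list(cf_true = cf_true, offset = offset), class = "clock_model")
}

#' Simulated subject ground truth
#'
#' Everything needed to generate (and later verify) one synthetic
#' recording session: lung model, IAP profile, the scheduled ventilation
#' settings, ventilator limitations and repositioning events.
#'
#' @param subject_id identifier string.
#' @param lung [lung_model_params()].
#' @param iap [iap_profile_params()].
#' @param settings_schedule list of `list(time =, settings =)` entries,
#'   time-sorted, first at `time = 0`.
#' @param rise_rate_limit maximum slope of the ventilator drive pressure
#'   in PCV \[mbar/s\]; `Inf` for an ideal square drive.
#' @param insp_flow_limit maximum inspiratory flow the ventilator can
#'   deliver \[ml/s\]; `Inf` for unlimited. A binding flow limit produces
#'   the pressure-limited-from-below PCV regime in which PIP stays under
#'   Pins_max and tracks the load.
#' @param reposition_times times \[s\] at which the patient position is
#'   toggled (lithotomy <-> supine); an odd count of past toggles means
#'   the reposition compliance step is active.
#' @param seed integer seed for all of this subject's randomness.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, lung, iap, settings_schedule,
                            rise_rate_limit = Inf, insp_flow_limit = Inf,
                            reposition_times = numeric(0), seed = 1L) {
  stopifnot(inherits(lung, "lung_model_params"),
            inherits(iap, "iap_profile_params"),
            length(settings_schedule) >= 1L)
  st <- vapply(settings_schedule, function(e) e$time, numeric(1))
  if (st[1] != 0) stop("first settings entry must be at time 0", call. = FALSE)
  if (any(diff(st) <= 0)) {
    stop("settings_schedule must be time-sorted", call. = FALSE)
  }
  ok <- vapply(settings_schedule,
               function(e) inherits(e$settings, "ventilation_settings"),
               logical(1))
  if (!all(ok)) stop("schedule entries need $settings", call. = FALSE)
  stopifnot(rise_rate_limit > 0, insp_flow_limit > 0)
  structure(
    list(subject_id = as.character(subject_id), lung = lung, iap = iap,
         settings_schedule = settings_schedule,
         rise_rate_limit = rise_rate_limit,
         insp_flow_limit = insp_flow_limit,
         reposition_times = sort(as.numeric(reposition_times)),
         seed = as.integer(seed)),
    class = "subject_profile"
  )
}

#' Multi-device recording session
#'
#' Streams keyed by channel name (`airway_pressure` \[mbar\] and `flow`
#' \[l/min\] and `volume` \[ml\] at 20 ms; `iap` \[mmHg\] at 40 ms), the
#' 60 s settings timeline, per-device clock models, an event log and --
#' for synthetic sessions -- the generating [subject_profile()].
#'
#' @param streams named list of [wave_signal()].
#' @param settings [settings_timeline()].
#' @param clocks named list of [clock_model()], one per device stream.
#' @param event_log data.frame with columns `time`, `label`.
#' @param ground_truth [subject_profile()] or `NULL` (real data).
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(streams, settings, clocks = NULL,
                              event_log = NULL, ground_truth = NULL) {
  stopifnot(is.list(streams), length(streams) >= 1L,
            inherits(settings, "settings_timeline"))
  ok <- vapply(streams, inherits, logical(1), what = "wave_signal")
  if (!all(ok)) stop("streams must be wave_signal objects", call. = FALSE)
  if (is.null(event_log)) {
    event_log <- data.frame(time = numeric(0), label = character(0))
  }
  if (is.null(clocks)) {
    clocks <- lapply(streams, function(s) clock_model(0, 0))
  }
  structure(
    list(streams = streams, settings = settings, clocks = clocks,
         event_log = event_log[order(event_log$time), , drop = FALSE],
         ground_truth = ground_truth),
    class = "recording_session"
  )
}

#' @export
print.recording_session <- function(x, ...) {
  cat("<recording_session>\n")
  for (s in x$streams) {
    cat("  "); print(s)
  }
  cat(sprintf("  settings: %d rows; events: %d; ground truth: %s\n",
              length(x$settings$t), nrow(x$event_log),
              if (is.null(x$ground_truth)) "absent" else
                x$ground_truth$subject_id))
  invisible(x)
}

# internal: settings row active at time tq (previous-value hold)
settings_at <- function(timeline, tq) {
  idx <- findInterval(tq, timeline$t)
  idx[idx < 1L] <- 1L
  timeline$rows[idx]
}

# internal: flatten one ventilation_settings to a named numeric-ish list
settings_as_row <- function(s) {
  data.frame(mode = s$mode, VT_target = s$VT_target, Pins_max = s$Pins_max,
             RR = s$RR, IE = s$IE, PEEP_set = s$PEEP_set,
             stringsAsFactors = FALSE)
}
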