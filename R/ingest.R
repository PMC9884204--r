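#' Clock-skew correction factor
#'
#' The device-relative clock drifts linearly against the absolute
#' (local-computer) clock; over a common interval the correction factor
#' is `CF = (dt_abs - dt_rel) / dt_abs`. A 3 h recording that loses 5 s
#' has `CF = 5/10800 = 4.63e-4`.
#'
#' @param dt_abs elapsed absolute duration \[s\], > 0.
#' @param dt_rel elapsed relative duration \[s\].
#' @return Dimensionless correction factor.
#' @export
compute_correction_factor <- function(dt_abs, dt_rel) {
  if (!is.numeric(dt_abs) || any(dt_abs <= 0)) {
    stop("dt_abs must be > 0", call. = FALSE)
  }
  (dt_abs - dt_rel) / dt_abs
}

#' Estimate CF and offset from paired clock observations
#'
#' Least-squares fit of `t_abs = offset + slope * t_rel` over all paired
#' observations (the monitor's configuration telegram is requested
#' several times during recording, each yielding one pair). The skew is
#' `CF = 1 - 1/slope`, which reduces to [compute_correction_factor()]
#' for exactly two observations.
#'
#' @param t_abs,t_rel paired clock readings \[s\], length >= 2.
#' @return List with `cf` and `offset`.
#' @export
estimate_correction_factor <- function(t_abs, t_rel) {
  stopifnot(length(t_abs) == length(t_rel), length(t_abs) >= 2L)
  fit <- stats::lm.fit(cbind(1, t_rel), t_abs)
  slope <- fit$coefficients[[2]]
  if (!is.finite(slope) || slope <= 0) {
    stop("degenerate clock observations", call. = FALSE)
  }
  list(cf = 1 - 1 / slope, offset = fit$coefficients[[1]])
}

#' Map a signal from its device-relative clock to the absolute timebase
#'
#' Applies the correction factor to every relative timestamp:
#' `t_corrected = offset + t_rel * (1 + cf)`. Correcting a stream
#' generated with skew `cf_true` using `cf = cf_true` leaves a residual
#' of order `cf^2 * T` (a few milliseconds over 3 h), well under half a
#' sampling interval.
#'
#' @param signal a [wave_signal()] on a relative clock.
#' @param cf correction factor (from [estimate_correction_factor()]).
#' @param offset clock start offset \[s\].
#' @return The corrected [wave_signal()].
#' @export
correct_clock <- function(signal, cf, offset = 0) {
  stopifnot(inherits(signal, "wave_signal"))
  wave_signal(signal$channel, offset + signal$t * (1 + cf), signal$v,
              signal$dt_nominal, signal$units)
}

#' Regularise a signal onto its nominal grid, flagging gaps as NaN
#'
#' Snaps samples to the arithmetic grid `t0 + k * dt_nominal`; any grid
#' point without a sample within `dt_nominal / 2` becomes `NA`. Samples
#' are never shifted further than half an interval, so gaps are flagged
#' rather than silently bridged. The number of inserted NAs is attached
#' as attribute `"n_inserted"`.
#'
#' @param signal a [wave_signal()] on the absolute timebase.
#' @return A [wave_signal()] on the full grid.
#' @export
detect_gaps_insert_nan <- function(signal) {
  stopifnot(inherits(signal, "wave_signal"))
  if (length(signal$t) == 0L) stop("empty signal", call. = FALSE)
  dt <- signal$dt_nominal
  t0 <- signal$t[1]
  grid <- seq(t0, signal$t[length(signal$t)] + dt / 4, by = dt)
  idx <- round((signal$t - t0) / dt) + 1L
  ok <- abs(signal$t - (t0 + (idx - 1L) * dt)) <= dt / 2 &
    idx >= 1L & idx <= length(grid)
  v <- rep(NA_real_, length(grid))
  v[idx[ok]] <- signal$v[ok]
  out <- wave_signal(signal$channel, grid, v, dt, signal$units)
  attr(out, "n_inserted") <- sum(is.na(v)) - sum(is.na(signal$v[ok]))
  out
}

#' Crop all streams of a session to their common time span
#'
#' Streams are cut to `[max(starts), min(ends)]`; the settings timeline
#' is cropped with the last pre-crop row carried forward to the crop
#' start (previous-value-hold semantics). Idempotent.
#'
#' @param session a [recording_session()] whose streams share a timebase.
#' @return The cropped [recording_session()].
#' @export
align_and_crop <- function(session) {
  stopifnot(inherits(session, "recording_session"))
  starts <- vapply(session$streams, function(s) s$t[1], numeric(1))
  ends <- vapply(session$streams, function(s) s$t[length(s$t)], numeric(1))
  t0 <- max(starts); t1 <- min(ends)
  if (t1 <= t0) stop("streams have no common overlap", call. = FALSE)
  out <- session
  for (nm in names(session$streams)) {
    s <- session$streams[[nm]]
    keep <- s$t >= t0 - 1e-9 & s$t <= t1 + 1e-9
    out$streams[[nm]] <- wave_signal(s$channel, s$t[keep], s$v[keep],
                                     s$dt_nominal, s$units)
  }
  tl <- session$settings
  after <- tl$t >= t0 - 1e-9 & tl$t <= t1 + 1e-9
  idx0 <- findInterval(t0, tl$t)         # last row at or before crop start
  tt <- tl$t[after]; rr <- tl$rows[after]
  if (idx0 >= 1L && (length(tt) == 0L || tt[1] > t0 + 1e-9)) {
    tt <- c(t0, tt)
    rr <- c(tl$rows[idx0], rr)
  }
  if (length(tt) == 0L) stop("settings timeline empty after crop",
                             call. = FALSE)
  out$settings <- settings_timeline(tt, rr)
  out
}

#' Detect session start and end from ventilation activity
#'
#' The surgical session is bounded by connecting and disconnecting the
#' patient from the ventilator; in the waveforms that is the first and
#' last time sustained breathing activity (|flow| above threshold over
#' at least three consecutive breath periods) is present.
#'
#' @param flow flow [wave_signal()] \[l/min\].
#' @param pressure airway-pressure [wave_signal()] (used only for span
#'   sanity checks).
#' @param threshold activity threshold \[l/min\].
#' @param breath_period assumed nominal breath period \[s\].
#' @return `c(t_start, t_end)` \[s\].
#' @export
detect_session_bounds <- function(flow, pressure = NULL, threshold = 2,
                                  breath_period = 5) {
  stopifnot(inherits(flow, "wave_signal"))
  active <- !is.na(flow$v) & abs(flow$v) > threshold
  if (!any(active)) stop("no ventilation activity found", call. = FALSE)
  # sustained: any activity within each of 3 consecutive breath windows
  win <- max(1L, round(breath_period / flow$dt_nominal))
  n_win <- floor(length(active) / win)
  if (n_win < 3L) stop("signal too short for activity detection",
                       call. = FALSE)
  wact <- vapply(seq_len(n_win), function(i)
    any(active[((i - 1L) * win + 1L):(i * win)]), logical(1))
  runs <- rle(wact)
  good <- runs$values & runs$lengths >= 3L
  if (!any(good)) stop("no sustained ventilation activity", call. = FALSE)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  i0 <- starts[which(good)[1]]
  i1 <- ends[which(good)[sum(good)]]
  idx <- which(active)
  t_start <- flow$t[idx[idx >= (i0 - 1L) * win + 1L][1]]
  t_end <- flow$t[max(idx[idx <= i1 * win])]
  c(t_start, t_end)
}

#' Ingest an acquired session onto one synchronised timeline
#'
#' Full pre-processing chain: per-device CF estimation from the paired
#' clock observations, clock correction onto the local-computer
#' timebase, grid regularisation with NaN gap flagging, and cropping to
#' the common span. Repair actions (fitted CF per device, NaN counts)
#' are recorded in `$ingest_log`.
#'
#' @param session a [recording_session()] as returned by
#'   [apply_acquisition()] or [read_session()].
#' @return The synchronised [recording_session()].
#' @export
ingest_session <- function(session) {
  stopifnot(inherits(session, "recording_session"))
  out <- session
  log <- list()
  for (nm in names(session$streams)) {
    sig <- session$streams[[nm]]
    if (!is.null(session$clock_obs[[nm]])) {
      obs <- session$clock_obs[[nm]]
      est <- estimate_correction_factor(obs$t_abs, obs$t_rel)
      sig <- correct_clock(sig, est$cf, est$offset)
      log[[nm]] <- list(cf = est$cf, offset = est$offset)
    } else {
      log[[nm]] <- list(cf = 0, offset = 0)
    }
    sig <- detect_gaps_insert_nan(sig)
    log[[nm]]$n_nan_inserted <- attr(sig, "n_inserted")
    out$streams[[nm]] <- sig
  }
  out <- align_and_crop(out)
  out$ingest_log <- log
  out
}
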