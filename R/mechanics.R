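#' Segment breaths from the respiratory flow signal
#'
#' Inspiration onsets are upward crossings of a `+eps` threshold with
#' hysteresis: a candidate breath is only kept if the flow subsequently
#' crosses `-eps` (an expiration actually happened). A breath spans one
#' onset to the next; implausible cycles (shorter than `min_dur` or
#' longer than `max_dur`) are discarded and counted in attribute
#' `"n_discarded"`.
#'
#' @param flow flow [wave_signal()] \[l/min\] on a uniform grid.
#' @param eps flow threshold \[l/min\].
#' @param min_dur,max_dur admissible breath duration \[s\].
#' @return data.frame with `t_insp_start`, `t_exp_start`, `t_end` and
#'   index columns `i0`, `i1` into the flow grid.
#' @export
segment_breaths <- function(flow, eps = 2, min_dur = 1, max_dur = 15) {
  stopifnot(inherits(flow, "wave_signal"))
  v <- flow$v
  above <- !is.na(v) & v > eps
  beloweps <- !is.na(v) & v < -eps
  if (!any(above)) stop("no breaths found in flow signal", call. = FALSE)
  # hysteresis state machine over threshold excursions: an inspiration
  # onset is the first +eps sample after a -eps excursion (or at start);
  # decaying inspiratory flow re-crossing +eps does not retrigger
  ex <- which(above | beloweps)
  lab <- ifelse(above[ex], 1L, -1L)
  runs <- rle(lab)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  # +eps excursions separated only by deadband collapse into one run,
  # so each +1 run is one inspiration onset
  pos_runs <- which(runs$values == 1L)
  onset <- ex[run_start[pos_runs]]
  ends <- c(onset[-1L], length(v) + 1L)
  keep <- logical(length(onset))
  t_exp <- rep(NA_real_, length(onset))
  below0 <- !is.na(v) & v < 0
  for (b in seq_along(onset)) {
    rng <- onset[b]:(ends[b] - 1L)
    if (!any(beloweps[rng])) next        # no expiration seen: incomplete
    keep[b] <- TRUE
    t_exp[b] <- flow$t[rng[which(below0[rng])[1]]]
  }
  dt <- flow$dt_nominal
  t0 <- flow$t[onset]
  t1 <- c(flow$t[onset[-1L]], flow$t[length(v)] + dt)
  dur_ok <- (t1 - t0) >= min_dur & (t1 - t0) <= max_dur
  res <- data.frame(t_insp_start = t0, t_exp_start = t_exp, t_end = t1,
                    i0 = onset, i1 = ends - 1L)
  out <- res[keep & dur_ok, , drop = FALSE]
  if (nrow(out) == 0L) stop("no breaths found in flow signal",
                            call. = FALSE)
  rownames(out) <- NULL
  attr(out, "n_discarded") <- sum(!(keep & dur_ok))
  out
}

#' Extract per-breath PIP, PEEP and VT from the respiratory waves
#'
#' For each segmented breath: PIP is the maximum airway pressure within
#' the breath; PEEP is the mean airway pressure over the last 100 ms
#' before the inspiration onset (end-expiratory plateau); VT is the
#' maximum of the displayed volume minus its value at onset. Breaths
#' whose windows contain NA in any channel are dropped and counted in
#' attribute `"n_dropped_nan"`.
#'
#' @param pressure,flow,volume [wave_signal()]s on one common grid.
#' @param breaths data.frame from [segment_breaths()].
#' @param peep_window PEEP averaging window before onset \[s\].
#' @return data.frame of breath records (no Cdyn / IAP yet).
#' @export
extract_breath_params <- function(pressure, flow, volume, breaths,
                                  peep_window = 0.1) {
  stopifnot(inherits(pressure, "wave_signal"),
            inherits(volume, "wave_signal"))
  nmax <- length(pressure$t)
  if (any(breaths$i1 > nmax)) {
    stop("breath window outside channel span", call. = FALSE)
  }
  dt <- pressure$dt_nominal
  wlen <- max(1L, round(peep_window / dt))
  n <- nrow(breaths)
  PIP <- PEEP <- VT <- rep(NA_real_, n)
  ok <- logical(n)
  for (b in seq_len(n)) {
    rng <- breaths$i0[b]:breaths$i1[b]
    # PEEP needs a full end-expiratory window before the onset; the
    # session's first breath has no such history and is dropped
    if (breaths$i0[b] <= wlen) next
    pw <- (breaths$i0[b] - wlen):(breaths$i0[b] - 1L)
    p <- pressure$v[rng]; vv <- volume$v[rng]; pe <- pressure$v[pw]
    if (anyNA(p) || anyNA(vv) || anyNA(pe)) next
    PIP[b] <- max(p)
    PEEP[b] <- mean(pe)
    VT[b] <- max(vv) - vv[1]
    ok[b] <- TRUE
  }
  out <- data.frame(index = seq_len(n),
                    t_insp_start = breaths$t_insp_start,
                    t_exp_start = breaths$t_exp_start,
                    t_end = breaths$t_end,
                    PIP = PIP, PEEP = PEEP, VT = VT)[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_nan") <- sum(!ok)
  out
}

#' Dynamic lung compliance
#'
#' `Cdyn = VT / (PIP - PEEP)` in ml/mbar. All quantities are measured
#' from the waveforms, not taken from set values.
#'
#' @param VT tidal volume \[ml\], > 0.
#' @param PIP peak inspiratory pressure \[mbar\].
#' @param PEEP end-expiratory pressure \[mbar\], < PIP.
#' @return Cdyn \[ml/mbar\].
#' @export
compute_cdyn <- function(VT, PIP, PEEP) {
  if (any(!is.finite(VT) | VT <= 0)) {
    stop("VT must be positive", call. = FALSE)
  }
  if (any(PIP <= PEEP)) {
    stop("degenerate breath: PIP <= PEEP", call. = FALSE)
  }
  VT / (PIP - PEEP)
}

#' Per-breath ventilation settings by previous-value hold
#'
#' Settings are stepwise anaesthesiologist actions sampled every 60 s;
#' each breath takes the row in force at its inspiration onset (breaths
#' before the first row take the first row).
#'
#' @param settings a [settings_timeline()].
#' @param breath_times inspiration-onset times \[s\].
#' @return data.frame with columns mode, VT_target, Pins_max, RR, IE,
#'   PEEP_set; one row per breath.
#' @export
interpolate_settings <- function(settings, breath_times) {
  stopifnot(inherits(settings, "settings_timeline"))
  if (length(settings$t) == 0L) stop("empty settings timeline",
                                     call. = FALSE)
  rows <- settings_at(settings, breath_times)
  do.call(rbind, lapply(rows, settings_as_row))
}

#' Attach the per-breath mean filtered IAP
#'
#' Each breath gets the mean of the (filtered) IAP over its full span
#' `[t_insp_start, t_end]` -- robust to intra-breath fluctuation.
#' Breaths whose window is NA-majority are dropped.
#'
#' @param records breath data.frame.
#' @param iap_filtered IAP [wave_signal()] (see [filter_iap()]).
#' @return `records` with an `iap_mean` column.
#' @export
attach_iap <- function(records, iap_filtered) {
  stopifnot(inherits(iap_filtered, "wave_signal"))
  if (nrow(records) == 0L) return(cbind(records, iap_mean = numeric(0)))
  if (min(records$t_insp_start) < iap_filtered$t[1] - 1 ||
      max(records$t_end) > iap_filtered$t[length(iap_filtered$t)] + 1) {
    stop("filtered IAP does not cover the breath spans", call. = FALSE)
  }
  im <- vapply(seq_len(nrow(records)), function(b) {
    w <- iap_filtered$t >= records$t_insp_start[b] &
      iap_filtered$t <= records$t_end[b]
    x <- iap_filtered$v[w]
    if (length(x) == 0L || mean(is.na(x)) > 0.5) return(NA_real_)
    mean(x, na.rm = TRUE)
  }, numeric(1))
  out <- records
  out$iap_mean <- im
  out <- out[!is.na(im), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove the linear trend from the PIP series
#'
#' For subjects whose PIP carries a slow drift unrelated to IAP, an
#' ordinary-least-squares line of PIP against breath time is subtracted
#' and the mean level added back. The fitted slope \[mbar/s\] is
#' attached as attribute `"trend_slope"`.
#'
#' @param records breath data.frame with `PIP` and `t_insp_start`.
#' @return `records` with a `pip_detrended` column.
#' @export
detrend_pip <- function(records) {
  if (nrow(records) < 10L) {
    warning("fewer than 10 breaths; PIP not detrended")
    records$pip_detrended <- records$PIP
    attr(records, "trend_slope") <- NA_real_
    return(records)
  }
  fit <- stats::lm(PIP ~ t_insp_start, data = records)
  records$pip_detrended <- records$PIP - stats::fitted(fit) +
    mean(records$PIP)
  attr(records, "trend_slope") <- unname(stats::coef(fit)[2])
  records
}

#' Full per-breath mechanics table for one session
#'
#' Runs the mechanics chain: IAP filtering, breath segmentation from
#' flow, PIP/PEEP/VT extraction, Cdyn, per-breath settings, per-breath
#' mean IAP, and (optionally) PIP detrending. Degenerate breaths
#' (PIP <= PEEP or non-positive VT) are dropped.
#'
#' @param session a synchronised [recording_session()] (see
#'   [ingest_session()]; a pristine simulated session also works).
#' @param spec IAP [filter_spec()].
#' @param detrend logical; add `pip_detrended` (default `FALSE`).
#' @param eps flow threshold for [segment_breaths()] \[l/min\].
#' @return data.frame, one row per usable breath: times, PIP, PEEP, VT,
#'   Cdyn, iap_mean and the settings snapshot.
#' @export
breath_table <- function(session, spec = filter_spec(), detrend = FALSE,
                         eps = 2) {
  stopifnot(inherits(session, "recording_session"))
  need <- c("airway_pressure", "flow", "volume", "iap")
  if (!all(need %in% names(session$streams))) {
    stop("session lacks channels: ",
         paste(setdiff(need, names(session$streams)), collapse = ", "),
         call. = FALSE)
  }
  iap_f <- filter_iap(session$streams$iap, spec)
  br <- segment_breaths(session$streams$flow, eps = eps)
  rec <- extract_breath_params(session$streams$airway_pressure,
                               session$streams$flow,
                               session$streams$volume, br)
  good <- rec$PIP > rec$PEEP & rec$VT > 0
  rec <- rec[good, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no usable breaths", call. = FALSE)
  rec$Cdyn <- compute_cdyn(rec$VT, rec$PIP, rec$PEEP)
  rec <- cbind(rec, interpolate_settings(session$settings,
                                         rec$t_insp_start))
  rec <- attach_iap(rec, iap_f)
  if (detrend) rec <- detrend_pip(rec)
  rownames(rec) <- NULL
  rec
}
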