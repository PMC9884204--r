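#' Write a recording session to disk
#'
#' One CSV per stream with header `t_abs,t_rel,value` plus a JSON
#' manifest (`manifest.json`) holding the subject id, channel units and
#' nominal rates, the settings timeline, the event log, per-device clock
#' observations, and -- for synthetic sessions -- the ground-truth
#' profile and per-breath truth table. For a session that has been
#' through [apply_acquisition()] the absolute timestamp column is empty:
#' only the device-relative clock is observable, as on a real recorder.
#'
#' @param session a [recording_session()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  acquired <- !is.null(session$clock_obs)
  channels <- list()
  for (nm in names(session$streams)) {
    sig <- session$streams[[nm]]
    df <- data.frame(
      t_abs = if (acquired) rep(NA_real_, length(sig$t)) else sig$t,
      t_rel = sig$t, value = sig$v)
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
    channels[[nm]] <- list(units = sig$units, dt_nominal = sig$dt_nominal)
  }
  tl <- session$settings
  sdf <- do.call(rbind, lapply(tl$rows, settings_as_row))
  sdf <- cbind(t = tl$t, sdf)
  utils::write.csv(sdf, file.path(dir, "settings.csv"), row.names = FALSE)

  man <- list(
    subject_id = if (!is.null(session$ground_truth))
      session$ground_truth$subject_id else "unknown",
    channels = channels,
    event_log = session$event_log,
    clock_obs = session$clock_obs
  )
  if (!is.null(session$ground_truth)) {
    man$ground_truth <- profile_to_list(session$ground_truth)
  }
  if (!is.null(session$truth_breaths)) {
    man$truth_breaths <- session$truth_breaths
  }
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(dir)
}

#' Read a recording session from disk
#'
#' Inverse of [write_session()]. Streams come back on whichever clock
#' they were written on (absolute for pristine synthetic sessions,
#' device-relative after acquisition).
#'
#' @param dir directory written by [write_session()].
#' @return A [recording_session()].
#' @export
read_session <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in ", dir, call. = FALSE)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  streams <- list()
  for (nm in names(man$channels)) {
    df <- utils::read.csv(file.path(dir, paste0(nm, ".csv")))
    streams[[nm]] <- wave_signal(nm, df$t_rel, df$value,
                                 man$channels[[nm]]$dt_nominal,
                                 man$channels[[nm]]$units)
  }
  sdf <- utils::read.csv(file.path(dir, "settings.csv"),
                         stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(sdf)), function(i) {
    r <- sdf[i, ]
    ventilation_settings(r$mode, VT_target = r$VT_target,
                         Pins_max = r$Pins_max, RR = r$RR, IE = r$IE,
                         PEEP_set = r$PEEP_set)
  })
  ev <- as.data.frame(man$event_log)
  if (nrow(ev) == 0L) ev <- NULL
  ses <- recording_session(
    streams = streams, settings = settings_timeline(sdf$t, rows),
    event_log = ev,
    ground_truth = if (!is.null(man$ground_truth))
      profile_from_list(man$ground_truth) else NULL)
  if (!is.null(man$clock_obs)) {
    ses$clock_obs <- lapply(man$clock_obs, as.data.frame)
  }
  if (!is.null(man$truth_breaths)) {
    ses$truth_breaths <- as.data.frame(man$truth_breaths)
  }
  ses
}

profile_to_list <- function(p) {
  list(
    subject_id = p$subject_id,
    lung = unclass(p$lung),
    iap = list(iap_target = p$iap$iap_target,
               t_insufflate = p$iap$t_insufflate,
               t_deflate = p$iap$t_deflate, ramp_tau = p$iap$ramp_tau,
               sigma = p$iap$sigma,
               transient_deflations = p$iap$transient_deflations),
    settings_schedule = lapply(p$settings_schedule, function(e)
      c(list(time = e$time), unclass(e$settings))),
    rise_rate_limit = p$rise_rate_limit,
    insp_flow_limit = p$insp_flow_limit,
    reposition_times = p$reposition_times,
    seed = p$seed
  )
}

profile_from_list <- function(l) {
  num_or <- function(x, d) if (is.null(x) || !is.finite(as.numeric(x))) d
           else as.numeric(x)
  sched <- lapply(l$settings_schedule, function(e) {
    list(time = as.numeric(e$time),
         settings = ventilation_settings(
           e$mode,
           VT_target = if (is.null(e$VT_target)) NA_real_
                       else as.numeric(e$VT_target),
           Pins_max = if (is.null(e$Pins_max)) NA_real_
                      else as.numeric(e$Pins_max),
           RR = as.numeric(e$RR), IE = as.numeric(e$IE),
           PEEP_set = as.numeric(e$PEEP_set)))
  })
  tds <- lapply(l$iap$transient_deflations, as.numeric)
  subject_profile(
    l$subject_id,
    lung = lung_model_params(C0 = l$lung$C0, R_aw = l$lung$R_aw,
                             k = l$lung$k, C_min = l$lung$C_min,
                             dC_reposition = l$lung$dC_reposition),
    iap = iap_profile_params(l$iap$iap_target, l$iap$t_insufflate,
                             l$iap$t_deflate, l$iap$ramp_tau,
                             l$iap$sigma, tds),
    settings_schedule = sched,
    rise_rate_limit = num_or(l$rise_rate_limit, Inf),
    insp_flow_limit = num_or(l$insp_flow_limit, Inf),
    reposition_times = as.numeric(l$reposition_times %||% numeric(0)),
    seed = as.integer(l$seed)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
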