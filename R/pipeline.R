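#' Build an analysis configuration
#'
#' @param subjects list of subject entries; each entry is a list with an
#'   `id` and exactly one of: `preset` (a [scenario_preset()] name),
#'   `profile` (a [subject_profile()]), `dir` (a directory written by
#'   [write_session()]), or `mode` (`"VCV"`/`"PCV"`, a randomised
#'   profile drawn via [random_subject_profile()]; optional `k`).
#' @param detrend_subjects ids whose PIP is detrended before analysis.
#' @param exclude_subjects ids excluded from group summaries.
#' @param filter IAP [filter_spec()].
#' @param eps breath-segmentation flow threshold \[l/min\].
#' @param missing_rate acquisition sample-loss rate for simulated
#'   subjects.
#' @param clock_skew acquisition clock skew injected on simulated
#'   subjects' device clocks (ventilator channels get half of it).
#' @param sensor_noise additive sensor noise s.d. on simulated pressure
#'   channels \[mbar\] (see [simulate_subject()]); keeps degenerate
#'   zero-variance responses (PIP under ideal pressure control) off the
#'   correlation stage.
#' @param seed root seed; per-subject seeds are derived from it.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(subjects, detrend_subjects = character(0),
                            exclude_subjects = character(0),
                            filter = filter_spec(), eps = 2,
                            missing_rate = 0.002, clock_skew = 4.63e-4,
                            sensor_noise = 0.05, seed = 1L) {
  if (length(subjects) == 0L) stop("empty subject list", call. = FALSE)
  ids <- vapply(subjects, function(s) as.character(s$id), character(1))
  if (anyDuplicated(ids)) stop("subject ids must be unique", call. = FALSE)
  structure(list(subjects = subjects, detrend_subjects = detrend_subjects,
                 exclude_subjects = exclude_subjects, filter = filter,
                 eps = eps, missing_rate = missing_rate,
                 clock_skew = clock_skew, sensor_noise = sensor_noise,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

subject_session <- function(entry, cfg, idx) {
  seed_i <- cfg$seed + 1000L * idx
  if (!is.null(entry$dir)) {
    ses <- read_session(entry$dir)
  } else {
    prof <- if (!is.null(entry$profile)) {
      entry$profile
    } else if (!is.null(entry$preset)) {
      scenario_preset(entry$preset, seed = seed_i)
    } else if (!is.null(entry$mode)) {
      random_subject_profile(entry$id, entry$mode, seed = seed_i,
                             k = entry$k %||% 1.2)
    } else {
      stop("subject entry needs one of dir/profile/preset/mode",
           call. = FALSE)
    }
    dur <- entry$duration %||% attr(prof, "duration") %||% 900
    ses <- simulate_subject(prof, dur, sensor_noise = cfg$sensor_noise)
    ses <- apply_acquisition(
      ses,
      clocks = list(iap = clock_model(cfg$clock_skew, 0),
                    airway_pressure = clock_model(cfg$clock_skew / 2, 0),
                    flow = clock_model(cfg$clock_skew / 2, 0),
                    volume = clock_model(cfg$clock_skew / 2, 0)),
      missing_rate = cfg$missing_rate, seed = seed_i)
  }
  ingest_session(ses)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> acquire -> ingest -> per-breath mechanics ->
#' per-subject correlations -> group summary. Deterministic for a given
#' config and seed. When `out` is given, writes `breaths.csv` (all
#' subjects), `results.csv`, `summary.csv` and `run_log.json`.
#'
#' @param config an [analysis_config()].
#' @param out optional output directory.
#' @return List with `breaths`, `results`, `summary`, `log`.
#' @export
run_pipeline <- function(config, out = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  all_br <- list(); all_res <- list(); log <- list()
  for (i in seq_along(config$subjects)) {
    entry <- config$subjects[[i]]
    id <- as.character(entry$id)
    ses <- tryCatch(subject_session(entry, config, i), error = function(e)
      stop("stage simulate/ingest, subject ", id, ": ",
           conditionMessage(e), call. = FALSE))
    detrend <- id %in% config$detrend_subjects
    br <- tryCatch(
      breath_table(ses, spec = config$filter, detrend = detrend,
                   eps = config$eps),
      error = function(e) stop("stage mechanics, subject ", id, ": ",
                               conditionMessage(e), call. = FALSE))
    br <- cbind(subject = id, br)
    res <- tryCatch(
      suppressWarnings(subject_analysis(br, subject_id = id,
                                        use_detrended = detrend)),
      error = function(e) stop("stage stats, subject ", id, ": ",
                               conditionMessage(e), call. = FALSE))
    all_br[[id]] <- br
    all_res[[id]] <- res
    log[[id]] <- c(ses$ingest_log,
                   list(n_breaths = nrow(br), detrended = detrend))
  }
  breaths <- do.call(rbind, c(all_br, list(make.row.names = FALSE)))
  results <- do.call(rbind, c(all_res, list(make.row.names = FALSE)))
  summary <- group_summary(results, exclude = config$exclude_subjects)
  bundle <- list(breaths = breaths, results = results, summary = summary,
                 log = log, config = config)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(breaths, file.path(out, "breaths.csv"),
                     row.names = FALSE)
    utils::write.csv(results, file.path(out, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(log, file.path(out, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}

#' Render figures and a markdown report from a pipeline bundle
#'
#' Produces, under `out`: a waveform panel (airway pressure, flow,
#' volume, IAP) for the first subject with channels available, one
#' scatter-with-regression-line per (subject, response), and
#' `report.md` with the group table, the per-subject correlations, and
#' the filter/threshold configuration actually used.
#'
#' @param bundle result of [run_pipeline()].
#' @param out output directory.
#' @param session optional [recording_session()] for the waveform panel.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(bundle, out, session = NULL) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(session)) {
    f <- file.path(out, "waveforms.png")
    grDevices::png(f, width = 1200, height = 900)
    graphics::par(mfrow = c(4, 1), mar = c(3, 4.5, 1, 1))
    for (nm in c("airway_pressure", "flow", "volume", "iap")) {
      s <- session$streams[[nm]]
      if (is.null(s)) next
      graphics::plot(s$t, s$v, type = "l",
                     xlab = "t [s]",
                     ylab = paste0(nm, " [", s$units, "]"))
    }
    grDevices::dev.off()
    paths <- c(paths, f)
  }
  for (id in unique(bundle$results$subject_id)) {
    br <- bundle$breaths[bundle$breaths$subject == id, , drop = FALSE]
    for (resp in c("Cdyn", "PIP", "VT")) {
      row <- bundle$results[bundle$results$subject_id == id &
                              bundle$results$response == resp, ]
      if (nrow(row) == 0L || !row$applicable) next
      f <- file.path(out, sprintf("scatter_%s_%s.png", id, resp))
      grDevices::png(f, width = 700, height = 500)
      y <- if (resp == "PIP" && "pip_detrended" %in% names(br) &&
               id %in% bundle$config$detrend_subjects) {
        br$pip_detrended
      } else br[[resp]]
      graphics::plot(br$iap_mean, y, pch = 20, col = "grey30",
                     xlab = "mean IAP [mmHg]", ylab = resp,
                     main = sprintf("%s: %s vs IAP (r = %.3f)",
                                    id, resp, row$r_simple))
      graphics::abline(row$intercept, row$slope, col = "red3", lwd = 2)
      grDevices::dev.off()
      paths <- c(paths, f)
    }
  }
  md <- c("# IAP vs lung mechanics -- analysis report", "",
          "## Group summary (mean |r| simple, mean R multiple)", "",
          knit_table(bundle$summary), "",
          "## Per-subject correlations", "",
          knit_table(bundle$results[, c("subject_id", "response", "mode",
                                        "r_simple", "r_mlr", "n")]), "",
          "## Configuration", "",
          sprintf("- filter: passband %g Hz (%g dB), stopband %g Hz (%g dB), fs %g Hz",
                  bundle$config$filter$passband_hz,
                  bundle$config$filter$passband_ripple_db,
                  bundle$config$filter$stopband_hz,
                  bundle$config$filter$stopband_atten_db,
                  bundle$config$filter$fs_hz),
          sprintf("- breath flow threshold: %g l/min", bundle$config$eps),
          sprintf("- acquisition: missing rate %g, clock skew %g",
                  bundle$config$missing_rate, bundle$config$clock_skew),
          sprintf("- excluded from group summary: %s",
                  if (length(bundle$config$exclude_subjects)) {
                    paste(bundle$config$exclude_subjects, collapse = ", ")
                  } else "none"),
          sprintf("- seed: %d", bundle$config$seed))
  f <- file.path(out, "report.md")
  writeLines(md, f)
  invisible(c(paths, f))
}

knit_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, 4))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1L, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
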