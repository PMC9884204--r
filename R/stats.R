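#' Pearson correlation with two-sided p-value
#'
#' Pairwise-complete product-moment correlation; the p-value comes from
#' the usual t transform with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length.
#' @return List with `r`, `p` and `n` (complete pairs).
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Multiple correlation coefficient from an OLS fit
#'
#' Fits `y ~ X` with intercept by ordinary least squares and returns the
#' multiple correlation coefficient `R = sqrt(R^2)` (always in \[0, 1\])
#' with the overall F-test p-value. Constant predictors are dropped
#' (with a message); a rank-deficient design after dropping is an error.
#' With a single predictor, `R` equals `|Pearson r|`.
#'
#' @param y response vector.
#' @param X numeric predictor matrix (columns named).
#' @return List with `R`, `p`, `n`, and the `dropped` predictor names.
#' @export
mlr_correlation <- function(y, X) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  ok <- is.finite(y) & apply(X, 1L, function(r) all(is.finite(r)))
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  sds <- apply(X, 2L, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) > 0) {
    message("dropping constant predictors: ",
            paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  n <- length(y)
  p_k <- ncol(X)
  if (p_k < 1L) stop("no non-constant predictors", call. = FALSE)
  if (n < p_k + 2L) stop("too few rows for the predictor set",
                         call. = FALSE)
  if (qr(cbind(1, X))$rank < p_k + 1L) {
    stop("rank-deficient design after dropping constants", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, X), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("undefined correlation: zero response variance",
                     call. = FALSE)
  r2 <- max(0, 1 - rss / tss)
  fstat <- (r2 / p_k) / max((1 - r2) / (n - p_k - 1), .Machine$double.eps)
  p <- stats::pf(fstat, p_k, n - p_k - 1, lower.tail = FALSE)
  list(R = sqrt(r2), p = p, n = n, dropped = dropped)
}

#' Per-subject correlation analysis between IAP and lung mechanics
#'
#' For one subject's breath table, computes -- per response Cdyn, PIP
#' and VT -- the simple Pearson correlation against the per-breath mean
#' IAP ("C") and the multiple correlation after adding the ventilation
#' settings as predictors ("MLR": IAP, RR, I:E, set PEEP, plus VT_target
#' for VCV or Pins_max for PCV). VT against IAP is reported for
#' pressure-controlled subjects only: under volume control the delivered
#' VT is held at its target, so the row is marked not applicable.
#'
#' @param breaths per-breath data.frame from [breath_table()] (single
#'   subject).
#' @param subject_id identifier used in the output.
#' @param use_detrended use `pip_detrended` instead of `PIP` when
#'   present (for drifting pressure-limited subjects).
#' @param min_n below this usable-breath count results are flagged
#'   `low_n` with a warning.
#' @return data.frame, one row per response, with `r_simple`, `r_abs`,
#'   `p_simple`, `r_mlr`, `p_mlr`, `slope`, `intercept`, `n`,
#'   `applicable`, `low_n`.
#' @export
subject_analysis <- function(breaths, subject_id = "subject",
                             use_detrended = FALSE, min_n = 30L) {
  stopifnot(is.data.frame(breaths), nrow(breaths) >= 3L)
  mode <- breaths$mode[1]
  low_n <- nrow(breaths) < min_n
  if (low_n) warning("fewer than ", min_n, " usable breaths for ",
                     subject_id, "; results flagged low-n")
  pip <- if (use_detrended && "pip_detrended" %in% names(breaths)) {
    breaths$pip_detrended
  } else breaths$PIP
  responses <- list(Cdyn = breaths$Cdyn, PIP = pip, VT = breaths$VT)
  setcol <- if (mode == "VCV") "VT_target" else "Pins_max"
  X <- cbind(IAP = breaths$iap_mean, RR = breaths$RR, IE = breaths$IE,
             PEEP_set = breaths$PEEP_set, breaths[[setcol]])
  colnames(X)[5] <- setcol
  out <- lapply(names(responses), function(resp) {
    applicable <- !(resp == "VT" && mode == "VCV")
    if (!applicable) {
      return(data.frame(subject_id = subject_id, response = resp,
                        mode = mode, r_simple = NA_real_, r_abs = NA_real_,
                        p_simple = NA_real_, r_mlr = NA_real_,
                        p_mlr = NA_real_, slope = NA_real_,
                        intercept = NA_real_, n = nrow(breaths),
                        applicable = FALSE, low_n = low_n))
    }
    y <- responses[[resp]]
    # a response with no variance (e.g. PIP under an ideal pressure
    # controller) carries no correlation: degrade to not-applicable
    sim <- tryCatch(pearson(breaths$iap_mean, y), error = function(e) NULL)
    if (is.null(sim)) {
      return(data.frame(subject_id = subject_id, response = resp,
                        mode = mode, r_simple = NA_real_, r_abs = NA_real_,
                        p_simple = NA_real_, r_mlr = NA_real_,
                        p_mlr = NA_real_, slope = NA_real_,
                        intercept = NA_real_, n = nrow(breaths),
                        applicable = FALSE, low_n = low_n))
    }
    cf <- stats::coef(stats::lm(y ~ breaths$iap_mean))
    mlr <- suppressMessages(mlr_correlation(y, X))
    data.frame(subject_id = subject_id, response = resp, mode = mode,
               r_simple = sim$r, r_abs = abs(sim$r), p_simple = sim$p,
               r_mlr = mlr$R, p_mlr = mlr$p, slope = unname(cf[2]),
               intercept = unname(cf[1]), n = sim$n,
               applicable = TRUE, low_n = low_n)
  })
  do.call(rbind, out)
}

#' Group summaries of per-subject correlations
#'
#' Arithmetic means of |r| (simple) and R (multiple) per response over
#' four groups: all subjects, all minus configured exclusions, the
#' volume-controlled subjects, and the pressure-controlled subjects
#' minus exclusions. Exclusions (e.g. a repositioned subject whose
#' record confounds the IAP-compliance relation) are configuration
#' driven, never automatic.
#'
#' @param results row-bound output of [subject_analysis()] over subjects.
#' @param exclude character vector of subject ids to exclude.
#' @return data.frame: group x response means of `r_abs` and `r_mlr`,
#'   with subject counts.
#' @export
group_summary <- function(results, exclude = character(0)) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  groups <- list(
    all = unique(results$subject_id),
    excluded_removed = setdiff(unique(results$subject_id), exclude),
    vcv = unique(results$subject_id[results$mode == "VCV"]),
    pcv_excluded_removed = setdiff(
      unique(results$subject_id[results$mode == "PCV"]), exclude)
  )
  out <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (length(ids) == 0L) {
      warning("empty group '", g, "' omitted")
      next
    }
    sub <- results[results$subject_id %in% ids & results$applicable, ,
                   drop = FALSE]
    for (resp in unique(sub$response)) {
      rr <- sub[sub$response == resp, , drop = FALSE]
      if (nrow(rr) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        group = g, response = resp, n_subjects = nrow(rr),
        mean_r_abs = mean(rr$r_abs), mean_r_mlr = mean(rr$r_mlr))
    }
  }
  do.call(rbind, out)
}
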