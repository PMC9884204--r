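#' Low-pass FIR specification for the IAP channel
#'
#' The insufflator pressure is smoothed before correlation against
#' breath-level mechanics so that breath-frequency and measurement
#' fluctuations do not leak into the regressions. The published spec
#' gives a 40 mHz passband (0.5 dB) and 50 dB stopband attenuation at a
#' 25 Hz rate; a passband and stopband edge cannot coincide in a
#' realisable filter, so the stopband edge defaults to 80 mHz (one
#' octave above the passband).
#'
#' @param passband_hz passband edge \[Hz\].
#' @param stopband_hz stopband edge \[Hz\], > passband.
#' @param passband_ripple_db maximum passband ripple \[dB\].
#' @param stopband_atten_db minimum stopband attenuation \[dB\].
#' @param fs_hz sampling rate \[Hz\].
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(passband_hz = 0.040, stopband_hz = 0.080,
                        passband_ripple_db = 0.5, stopband_atten_db = 50,
                        fs_hz = 25) {
  stopifnot(passband_hz > 0, stopband_hz > passband_hz,
            stopband_hz < fs_hz / 2, passband_ripple_db > 0,
            stopband_atten_db > 0)
  structure(list(passband_hz = passband_hz, stopband_hz = stopband_hz,
                 passband_ripple_db = passband_ripple_db,
                 stopband_atten_db = stopband_atten_db, fs_hz = fs_hz),
            class = "filter_spec")
}

#' Design the linear-phase low-pass FIR filter
#'
#' Kaiser-window design: the window beta and tap count follow from the
#' required stopband attenuation and the transition width; the ideal
#' cutoff sits midway between the passband and stopband edges. The tap
#' count is forced odd so the group delay `(ntaps - 1) / 2` is an
#' integer number of samples. Coefficients are exactly symmetric
#' (linear phase) and normalised to unit DC gain. The design is checked
#' against the spec on a dense frequency grid and rejected if it misses.
#'
#' @param spec a [filter_spec()].
#' @return Numeric coefficient vector with attributes `"group_delay"`
#'   (samples) and `"spec"`.
#' @export
design_iap_filter <- function(spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  A <- spec$stopband_atten_db
  beta <- if (A > 50) {
    0.1102 * (A - 8.7)
  } else if (A >= 21) {
    0.5842 * (A - 21)^0.4 + 0.07886 * (A - 21)
  } else 0
  d_omega <- 2 * pi * (spec$stopband_hz - spec$passband_hz) / spec$fs_hz
  n <- ceiling((A - 7.95) / (2.285 * d_omega)) + 1L
  if (n %% 2L == 0L) n <- n + 1L
  if (n > 20001L) {
    stop("unmeetable FIR spec: transition band too narrow (",
         n, " taps required)", call. = FALSE)
  }
  fc <- (spec$passband_hz + spec$stopband_hz) / 2 / spec$fs_hz  # cycles/sample
  m <- (n - 1) / 2
  kk <- seq(-m, m)
  h_ideal <- 2 * fc * sinc(2 * fc * kk)
  w <- besselI(beta * sqrt(pmax(0, 1 - (kk / m)^2)), 0) / besselI(beta, 0)
  h <- h_ideal * w
  h <- h / sum(h)
  resp <- fir_response(h, spec$fs_hz,
                       f = seq(0, spec$fs_hz / 2, length.out = 4096))
  pass <- resp$f <= spec$passband_hz
  stopb <- resp$f >= spec$stopband_hz
  if (max(abs(resp$db[pass])) > spec$passband_ripple_db ||
      max(resp$db[stopb]) > -spec$stopband_atten_db) {
    stop("FIR design does not meet the spec; widen the transition band",
         call. = FALSE)
  }
  attr(h, "group_delay") <- m
  attr(h, "spec") <- spec
  h
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Frequency response of an FIR filter
#'
#' @param h coefficient vector.
#' @param fs_hz sampling rate \[Hz\].
#' @param f frequencies to evaluate \[Hz\].
#' @return List with `f`, complex `H`, and magnitude `db`.
#' @export
fir_response <- function(h, fs_hz, f = seq(0, fs_hz / 2, length.out = 2048)) {
  k <- seq_along(h) - 1
  H <- vapply(f, function(fi)
    sum(h * exp(-2i * pi * fi / fs_hz * k)), complex(1))
  list(f = f, H = H, db = 20 * log10(pmax(abs(H), 1e-300)))
}

#' Zero-lag low-pass filter the IAP signal
#'
#' Applies the FIR by FFT convolution with edge-replication padding and
#' shifts the output back by the constant group delay so the filtered
#' IAP stays aligned with the respiratory channels. NA runs shorter
#' than the filter length are linearly interpolated before filtering;
#' longer runs propagate NA through the affected span.
#'
#' @param iap an IAP [wave_signal()] on a uniform grid.
#' @param spec a [filter_spec()]; its `fs_hz` must match the signal.
#' @param h optional pre-designed coefficients (from
#'   [design_iap_filter()]); designed on the fly if missing.
#' @return The filtered [wave_signal()].
#' @export
filter_iap <- function(iap, spec = filter_spec(), h = NULL) {
  stopifnot(inherits(iap, "wave_signal"))
  if (abs(1 / iap$dt_nominal - spec$fs_hz) > 1e-6) {
    spec$fs_hz <- 1 / iap$dt_nominal
  }
  if (is.null(h)) h <- design_iap_filter(spec)
  n <- length(h)
  if (length(iap$v) <= n) {
    stop("signal shorter than the filter", call. = FALSE)
  }
  v <- iap$v
  na <- is.na(v)
  long_na <- logical(length(v))
  if (any(na)) {
    runs <- rle(na)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in which(runs$values)) {
      if (runs$lengths[i] >= n) long_na[starts[i]:ends[i]] <- TRUE
    }
    v <- stats::approx(iap$t[!na], v[!na], xout = iap$t, rule = 2)$y
  }
  m <- (n - 1) / 2
  padded <- c(rep(v[1], m), v, rep(v[length(v)], m))
  # FFT linear convolution, then take the zero-lag central segment
  nf <- stats::nextn(length(padded) + n - 1L, 2)
  conv <- Re(stats::fft(stats::fft(c(padded, numeric(nf - length(padded)))) *
                          stats::fft(c(h, numeric(nf - n))),
                        inverse = TRUE)) / nf
  out <- conv[(n):(n + length(v) - 1L)]
  out[long_na] <- NA_real_
  wave_signal(iap$channel, iap$t, out, iap$dt_nominal, iap$units)
}
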