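#' Heart-rate trace on the TR grid
#'
#' The analysis-ready form of the cardiac signal: one value per fMRI
#' volume, with the hemodynamic lag, detrending order and normalization
#' state recorded as provenance.
#'
#' @param values numeric vector, one value per volume.
#' @param tr_s repetition time (s).
#' @param applied_lag_s total lag (s) already applied to the series.
#' @param detrend_order drift polynomial order removed, or `NA`.
#' @param z_normalized logical flag.
#' @param provenance character vector of processing steps.
#' @return An object of class `hr_trace`.
#' @export
hr_trace <- function(values, tr_s, applied_lag_s = 0,
                     detrend_order = NA_integer_, z_normalized = FALSE,
                     provenance = character()) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("hr_trace values must be finite")
  if (tr_s <= 0) stop("tr_s must be > 0")
  if (isTRUE(z_normalized) && length(values) >= 2) {
    if (abs(mean(values)) > 1e-9 || abs(stats::sd(values) - 1) > 1e-9)
      stop("z_normalized trace must have mean 0 and sd 1")
  }
  structure(list(values = values, tr_s = tr_s,
                 applied_lag_s = applied_lag_s,
                 detrend_order = detrend_order,
                 z_normalized = isTRUE(z_normalized),
                 provenance = provenance),
            class = "hr_trace")
}

#' @export
print.hr_trace <- function(x, ...) {
  cat(sprintf(
    "<hr_trace> %d vols @ TR %.3g s, lag %.3g s, detrend %s, z=%s\n",
    length(x$values), x$tr_s, x$applied_lag_s,
    ifelse(is.na(x$detrend_order), "-", x$detrend_order),
    x$z_normalized))
  invisible(x)
}

#' Fill missing heart-rate samples
#'
#' Interior gaps are filled with a cubic spline through the valid samples;
#' leading/trailing gaps are back-/forward-filled with the first/last valid
#' value. With fewer than 4 valid samples the spline is underdetermined and
#' the fill falls back to linear interpolation (flagged in the returned
#' series' `provenance` attribute).
#'
#' @param s a [bpm_series()] possibly containing missing samples.
#' @return A gap-free `bpm_series`; valid samples are unchanged.
#' @export
interpolate_gaps <- function(s) {
  stopifnot(inherits(s, "bpm_series"))
  valid <- !s$missing
  n_valid <- sum(valid)
  if (n_valid < 2L)
    stop("cannot interpolate: fewer than 2 valid samples")
  tv <- s$time_s[valid]
  xv <- s$bpm[valid]
  out <- s$bpm
  prov <- "interpolate_gaps:cubic-spline"
  if (any(!valid)) {
    tm <- s$time_s[!valid]
    if (n_valid < 4L) {
      fill <- stats::approx(tv, xv, xout = tm, rule = 2)$y
      prov <- "interpolate_gaps:linear-fallback"
    } else {
      # fmm end conditions reproduce a single cubic exactly
      f <- stats::splinefun(tv, xv, method = "fmm")
      fill <- f(tm)
      # backward/forward fill outside the valid span
      fill[tm < tv[1]] <- xv[1]
      fill[tm > tv[n_valid]] <- xv[n_valid]
    }
    out[!valid] <- fill
  }
  res <- bpm_series(s$time_s, out, missing = rep(FALSE, length(out)))
  attr(res, "provenance") <- c(attr(s, "provenance"), prov)
  res
}

#' Savitzky-Golay smoothing of a heart-rate series
#'
#' Least-squares local-polynomial smoothing. Edge values come from the
#' polynomial fits of the first/last full window evaluated off-center, so a
#' polynomial of degree <= `polyorder` passes through unchanged everywhere.
#'
#' @param s a gap-free [bpm_series()].
#' @param window odd window length in samples (default 15, i.e. 15 s at
#'   1 Hz).
#' @param polyorder polynomial order (default 3), must be < `window`.
#' @return A smoothed `bpm_series`.
#' @export
savgol_smooth <- function(s, window = 15L, polyorder = 3L) {
  stopifnot(inherits(s, "bpm_series"))
  if (any(s$missing))
    stop("savgol_smooth requires a gap-free series; run interpolate_gaps")
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window > length(s$bpm)) stop("window exceeds series length")
  sm <- signal::sgolayfilt(s$bpm, p = polyorder, n = window)
  res <- bpm_series(s$time_s, sm, missing = rep(FALSE, length(sm)))
  attr(res, "provenance") <- c(attr(s, "provenance"),
                               sprintf("savgol:w=%d,p=%d", window, polyorder))
  res
}

#' Resample a heart-rate series to the TR grid with a hemodynamic lag
#'
#' Evaluates the continuous (linear) interpolant of the series at
#' `t_k = k * tr_s - lag_s` for `k = 0 .. n_vols - 1`. The lag is realized
#' in continuous time, so 6 s at TR 0.7 s is exactly 6 s, not a rounded
#' whole-TR shift. Times before the first sample take the first value (the
#' lag-induced head padding); times up to 2 s past the last sample take the
#' last value.
#'
#' @param s a gap-free [bpm_series()].
#' @param tr_s repetition time (s).
#' @param n_vols number of volumes to produce.
#' @param lag_s hemodynamic lag in seconds (default 6).
#' @return An [hr_trace()] of length `n_vols`.
#' @export
resample_with_lag <- function(s, tr_s, n_vols, lag_s = 6.0) {
  stopifnot(inherits(s, "bpm_series"))
  if (any(s$missing))
    stop("resample_with_lag requires a gap-free series")
  n_vols <- as.integer(n_vols)
  if (n_vols < 2L) stop("n_vols must be >= 2")
  span <- s$time_s[length(s$time_s)] - s$time_s[1]
  if (n_vols * tr_s - lag_s > span + 2)
    stop("requested scan duration exceeds BPM series span by more than 2 s")
  tk <- (seq_len(n_vols) - 1) * tr_s - lag_s
  vals <- stats::approx(s$time_s, s$bpm, xout = tk, rule = 2)$y
  hr_trace(vals, tr_s = tr_s, applied_lag_s = lag_s,
           provenance = c(attr(s, "provenance"),
                          sprintf("resample:tr=%g,lag=%g", tr_s, lag_s)))
}

#' Legendre polynomial basis on a uniform grid
#'
#' Degrees `0..order` evaluated on `n` points mapped to \[-1, 1\].
#'
#' @param n number of samples.
#' @param order maximum degree.
#' @return An `n x (order + 1)` matrix.
#' @export
legendre_basis <- function(n, order) {
  n <- as.integer(n); order <- as.integer(order)
  stopifnot(n >= 2L, order >= 0L)
  t <- seq(-1, 1, length.out = n)
  B <- matrix(0, n, order + 1L)
  B[, 1] <- 1
  if (order >= 1L) B[, 2] <- t
  if (order >= 2L) {
    for (k in 1L:(order - 1L)) {
      # (k+1) P_{k+1} = (2k+1) t P_k - k P_{k-1}
      B[, k + 2L] <- ((2 * k + 1) * t * B[, k + 1L] - k * B[, k]) / (k + 1)
    }
  }
  B
}

#' Remove low-frequency drift with a Legendre polynomial fit
#'
#' Projects the series onto Legendre polynomials of degree `0..order` (on
#' time mapped to \[-1, 1\]) and returns the residual, which is orthogonal
#' to every basis column.
#'
#' @param x numeric series.
#' @param order maximum polynomial degree; must be < `length(x)`.
#' @return Residual series of the same length.
#' @export
legendre_detrend <- function(x, order) {
  x <- as.numeric(x)
  n <- length(x)
  if (order >= n) stop("detrend order must be < series length")
  B <- legendre_basis(n, order)
  qr_B <- qr(B)
  if (qr_B$rank < ncol(B)) stop("rank-deficient detrending basis")
  as.numeric(qr.resid(qr_B, x))
}

#' Automatic drift polynomial order from run duration
#'
#' One polynomial order per 150 s of run duration plus the constant:
#' `order = 1 + floor(duration_s / seconds_per_order)`, the standard
#' automatic rule for fMRI drift removal.
#'
#' @param duration_s run duration in seconds.
#' @param seconds_per_order seconds of data per added order (default 150).
#' @return Integer polynomial order.
#' @export
auto_polort_order <- function(duration_s, seconds_per_order = 150) {
  stopifnot(duration_s > 0, seconds_per_order > 0)
  as.integer(1 + floor(duration_s / seconds_per_order))
}

#' Z-normalize a series
#'
#' `(x - mean) / sd` with the n-1 denominator. Errors on constant input.
#'
#' @param x numeric series of length >= 2.
#' @return Z-scored series (mean 0, sd 1).
#' @export
zscore <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("zscore needs at least 2 samples")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("constant series: zero variance")
  (x - mean(x)) / s
}

#' Full cardiac preprocessing chain
#'
#' Applies, in order: gap interpolation, Savitzky-Golay smoothing,
#' resampling to the TR grid with a hemodynamic lag, Legendre detrending
#' (order matched to the paired fMRI run's duration unless given), and
#' z-normalization. Each step is recorded in the trace's provenance.
#'
#' @param s a [bpm_series()].
#' @param tr_s repetition time (s).
#' @param n_vols number of fMRI volumes in the paired run.
#' @param lag_s hemodynamic lag (s), default 6.
#' @param detrend_order drift order; default `NULL` applies
#'   [auto_polort_order()] to the run duration `n_vols * tr_s`.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters (defaults 15
#'   samples / order 3).
#' @param seconds_per_order automatic detrending rule denominator.
#' @return An [hr_trace()] (z-normalized).
#' @export
prep_hr <- function(s, tr_s, n_vols, lag_s = 6.0, detrend_order = NULL,
                    sg_window = 15L, sg_polyorder = 3L,
                    seconds_per_order = 150) {
  s <- interpolate_gaps(s)
  s <- savgol_smooth(s, window = sg_window, polyorder = sg_polyorder)
  tr <- resample_with_lag(s, tr_s = tr_s, n_vols = n_vols, lag_s = lag_s)
  if (is.null(detrend_order))
    detrend_order <- auto_polort_order(n_vols * tr_s, seconds_per_order)
  vals <- legendre_detrend(tr$values, detrend_order)
  vals <- zscore(vals)
  hr_trace(vals, tr_s = tr_s, applied_lag_s = lag_s,
           detrend_order = detrend_order, z_normalized = TRUE,
           provenance = c(tr$provenance,
                          sprintf("detrend:order=%d", detrend_order),
                          "zscore"))
}
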