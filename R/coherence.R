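#' Trim two series to equal length by dropping the head of the longer
#'
#' Conditions of different duration are compared on equal footing by
#' omitting the first section of the longer condition, so measures that
#' grow with length (dynamic time warping distance) remain comparable.
#'
#' @param a,b numeric vectors (or series objects).
#' @return A list with elements `a` and `b` of equal length.
#' @export
match_condition_lengths <- function(a, b) {
  av <- series_values(a); bv <- series_values(b)
  if (length(av) == 0L || length(bv) == 0L) stop("empty series")
  n <- min(length(av), length(bv))
  list(a = av[(length(av) - n + 1L):length(av)],
       b = bv[(length(bv) - n + 1L):length(bv)])
}

#' Fisher z transform with finite-value guard
#'
#' `atanh(r)` with `r` clipped to `1 - 1e-7` in magnitude.
#'
#' @param r correlation coefficient(s).
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  atanh(pmax(-(1 - 1e-7), pmin(1 - 1e-7, r)))
}

new_record <- function(subject, condition, target, target_type, measure,
                       value, lag_s_at_max = NA_real_, n_used = NA_integer_,
                       flag = "") {
  data.frame(subject = subject, condition = condition, target = target,
             target_type = target_type, measure = measure, value = value,
             lag_s_at_max = lag_s_at_max, n_timepoints_used = n_used,
             flag = flag, stringsAsFactors = FALSE)
}

#' Bivariate brain-heart coherence
#'
#' The instantaneous association between the (hemodynamically lagged,
#' z-normalized) heart-rate trace and a z-normalized neural series:
#' the Fisher-transformed Pearson correlation.
#'
#' @param hr an [hr_trace()] (carries the 6 s lag from [prep_hr()]).
#' @param neural a [neural_series()], [edge_timeseries()] output, or
#'   numeric vector of the same length.
#' @param subject,condition provenance labels.
#' @param target,target_type target labels; default from `neural$source`.
#' @return One-row data frame (a coherence record) with
#'   `measure = "bivariate_z"`.
#' @export
bivariate_coherence <- function(hr, neural, subject = NA, condition = NA,
                                target = NULL, target_type = "roi") {
  h <- series_values(hr); x <- series_values(neural)
  if (length(h) != length(x)) stop("series lengths differ")
  if (stats::sd(h) == 0 || stats::sd(x) == 0)
    stop("constant series: correlation undefined")
  if (is.null(target)) target <- series_label(neural)
  z <- fisher_z(stats::cor(h, x))
  new_record(subject, condition, target, target_type, "bivariate_z",
             z, n_used = length(h))
}

#' Band-constrained dynamic time warping distance
#'
#' Dynamic-programming alignment with squared-difference local cost,
#' symmetric steps (diagonal, left, up), endpoints anchored at both ends,
#' and a Sakoe-Chiba band making cells with `|i - j| > band_trs`
#' infeasible. The distance is the square root of the accumulated cost; no
#' path-length normalization is applied (distances are compared between
#' length-matched conditions only).
#'
#' @param a,b numeric series.
#' @param band_trs Sakoe-Chiba band half-width in samples; `Inf` (or any
#'   value >= the series length) removes the constraint.
#' @return Non-negative distance; 0 iff the series are identical.
#' @export
dtw_distance <- function(a, b, band_trs = 14L) {
  a <- series_values(a); b <- series_values(b)
  band <- if (is.infinite(band_trs)) -1L else as.integer(band_trs)
  if (!is.infinite(band_trs) && band_trs < 0) stop("band_trs must be >= 0")
  .dtw_band_cost(a, b, band)
}

#' Dynamic time warping brain-heart coherence
#'
#' @param hr an [hr_trace()] (z-normalized).
#' @param neural a z-normalized series of equal length (apply
#'   [match_condition_lengths()] first when comparing conditions of
#'   unequal duration).
#' @param band_trs Sakoe-Chiba band half-width in TRs (default 14,
#'   ~10 s at TR 0.7 s).
#' @param subject,condition,target,target_type provenance labels.
#' @return One-row data frame with `measure = "dtw_distance"`.
#' @export
dtw_coherence <- function(hr, neural, band_trs = 14L, subject = NA,
                          condition = NA, target = NULL,
                          target_type = "roi") {
  h <- series_values(hr); x <- series_values(neural)
  if (length(h) != length(x))
    stop("series lengths differ; apply match_condition_lengths first")
  if (is.null(target)) target <- series_label(neural)
  d <- dtw_distance(h, x, band_trs = band_trs)
  new_record(subject, condition, target, target_type, "dtw_distance",
             d, n_used = length(h))
}

#' Maximum positive cross-correlation over a delay grid
#'
#' For each candidate delay `d` (in whole TRs, shifting the neural series
#' later relative to the heart-rate trace) the Pearson correlation is
#' computed on the overlapping samples. The value is the Fisher z of the
#' maximum positive correlation; when no delay yields a positive
#' correlation the value is 0 with `flag = "no positive peak"`. The
#' reported lag is `d * tr_s - lag_offset_s`, so passing the extra
#' heart-rate offset as `lag_offset_s` expresses lags relative to the
#' hemodynamically lagged heart rate (negative lags = BOLD precedes).
#'
#' @param hr an [hr_trace()]; for whole-brain use it carries the
#'   additional 10 s offset on top of the 6 s hemodynamic lag.
#' @param neural a series of the same length.
#' @param max_lag_trs largest delay searched, in TRs.
#' @param min_overlap minimum overlapping samples per delay (default 30).
#' @param lag_offset_s subtracted from `d * tr_s` in the reported lag.
#' @param subject,condition,target,target_type provenance labels.
#' @return One-row data frame with `measure = "xcorr_max_z"` and
#'   `lag_s_at_max` filled in.
#' @export
xcorr_max <- function(hr, neural, max_lag_trs, min_overlap = 30L,
                      lag_offset_s = 0, subject = NA, condition = NA,
                      target = NULL, target_type = "voxel") {
  h <- series_values(hr); x <- series_values(neural)
  n <- length(h)
  if (length(x) != n) stop("series lengths differ")
  tr_s <- if (is.list(hr) && !is.null(hr$tr_s)) hr$tr_s else 1
  max_lag_trs <- as.integer(max_lag_trs)
  lags <- 0:max_lag_trs
  lags <- lags[n - lags >= min_overlap]
  if (length(lags) == 0L)
    stop("overlap shorter than the minimum at every delay")
  rs <- vapply(lags, function(d) {
    stats::cor(h[seq_len(n - d)], x[(1 + d):n])
  }, numeric(1))
  if (is.null(target)) target <- series_label(neural)
  pos <- which(rs > 0)
  if (length(pos) == 0L) {
    return(new_record(subject, condition, target, target_type,
                      "xcorr_max_z", 0, lag_s_at_max = NA_real_,
                      n_used = n, flag = "no positive peak"))
  }
  best <- pos[which.max(rs[pos])]
  new_record(subject, condition, target, target_type, "xcorr_max_z",
             fisher_z(rs[best]),
             lag_s_at_max = lags[best] * tr_s - lag_offset_s,
             n_used = n - lags[best])
}

#' Voxel-wise cross-correlation lag map
#'
#' Applies [xcorr_max()] to every in-brain voxel (brain mask = voxels with
#' non-zero variance) of a residualized (and, typically, smoothed) volume.
#' Fully deterministic given its inputs.
#'
#' @param vol a [volume4d()] of residual BOLD data.
#' @param hr an [hr_trace()] carrying the hemodynamic plus extra offsets.
#' @param max_lag_trs largest delay searched, in TRs.
#' @param min_overlap minimum overlapping samples per delay.
#' @param lag_offset_s see [xcorr_max()].
#' @return A list of class `lag_map`: `z` (3D array of Fisher-z maxima,
#'   0 where no positive peak or out of brain), `lag_s` (3D array of
#'   argmax lags in seconds, `NA` where undefined), `affine`, `in_brain`
#'   (logical 3D array).
#' @export
lag_map <- function(vol, hr, max_lag_trs, min_overlap = 30L,
                    lag_offset_s = 0) {
  stopifnot(inherits(vol, "volume4d"))
  h <- series_values(hr)
  d <- dim(vol$data)
  n <- d[4]
  if (length(h) != n) stop("heart-rate trace length differs from volume")
  tr_s <- vol$tr_s
  nvox <- prod(d[1:3])
  M <- matrix(vol$data, nrow = nvox)        # voxels x time
  v <- apply(M, 1, stats::var)
  in_brain <- v > 0
  zmap <- numeric(nvox)
  lagmap <- rep(NA_real_, nvox)
  if (any(in_brain)) {
    Mb <- t(M[in_brain, , drop = FALSE])    # time x voxels
    lags <- 0:as.integer(max_lag_trs)
    lags <- lags[n - lags >= min_overlap]
    if (length(lags) == 0L)
      stop("overlap shorter than the minimum at every delay")
    R <- matrix(NA_real_, length(lags), ncol(Mb))
    for (ii in seq_along(lags)) {
      dd <- lags[ii]
      R[ii, ] <- as.numeric(stats::cor(h[seq_len(n - dd)],
                                       Mb[(1 + dd):n, , drop = FALSE]))
    }
    best_r <- apply(R, 2, max)
    best_i <- apply(R, 2, which.max)
    zb <- ifelse(best_r > 0, fisher_z(best_r), 0)
    lb <- ifelse(best_r > 0, lags[best_i] * tr_s - lag_offset_s, NA_real_)
    zmap[in_brain] <- zb
    lagmap[in_brain] <- lb
  }
  structure(list(z = array(zmap, d[1:3]),
                 lag_s = array(lagmap, d[1:3]),
                 affine = vol$affine,
                 in_brain = array(in_brain, d[1:3]),
                 tr_s = tr_s),
            class = "lag_map")
}
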