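#' Weighted Pearson correlation
#'
#' Pearson correlation under weighted means and covariances with the
#' weights normalized to sum to one. Uniform weights reduce to the ordinary
#' Pearson correlation.
#'
#' @param x,y numeric vectors of equal length.
#' @param w non-negative weights, `sum(w) > 0`.
#' @return Correlation in `[-1, 1]`.
#' @export
weighted_corr <- function(x, y, w) {
  x <- as.numeric(x); y <- as.numeric(y); w <- as.numeric(w)
  n <- length(x)
  if (length(y) != n || length(w) != n)
    stop("x, y and w must have equal length")
  if (any(w < 0) || sum(w) <= 0)
    stop("weights must be non-negative with positive sum")
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0)
    stop("zero weighted variance")
  r <- sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  max(-1, min(1, r))
}

#' Gaussian-weighted sliding-window connectivity series
#'
#' At each timepoint, Pearson correlation of the two series under Gaussian
#' weights centered there (sd `kernel_sd_trs`), truncated to
#' `(window_trs - 1) / 2` TRs either side and renormalized; the
#' correlation is Fisher-transformed (`atanh`, with `r` clipped to
#' `1 - 1e-7` in magnitude). Output is full length: windows at the edges
#' are truncated, not dropped, keeping the series aligned with the
#' heart-rate trace. If the Fisher-z series is constant it cannot be
#' z-scored; it is returned un-normalized with `flag = "constant"`.
#'
#' @param x,y [neural_series()] (or numeric vectors) of equal length.
#' @param window_trs odd window width in TRs (default 29, i.e. 20.3 s at
#'   TR 0.7 s).
#' @param kernel_sd_trs Gaussian kernel sd in TRs; default `window_trs / 3`
#'   keeps over 99% of the kernel mass inside the window.
#' @param tr_s repetition time, taken from `x` when it is a
#'   `neural_series`.
#' @param znorm z-normalize the Fisher-z series (default `TRUE`).
#' @return An object of class `edge_series` with fields `values`,
#'   `window_trs`, `kernel_sd_trs`, `z_normalized`, `source`, `flag`.
#' @export
edge_timeseries <- function(x, y, window_trs = 29L, kernel_sd_trs = NULL,
                            tr_s = NULL, znorm = TRUE) {
  lab_x <- if (inherits(x, "neural_series")) x$source else "x"
  lab_y <- if (inherits(y, "neural_series")) y$source else "y"
  if (is.null(tr_s))
    tr_s <- if (inherits(x, "neural_series")) x$tr_s else 1
  xv <- series_values(x); yv <- series_values(y)
  n <- length(xv)
  if (length(yv) != n) stop("series lengths differ")
  window_trs <- as.integer(window_trs)
  if (window_trs %% 2L == 0L)
    stop("window_trs must be odd (center undefined for even windows)")
  if (n < window_trs) stop("series shorter than the window")
  if (is.null(kernel_sd_trs)) kernel_sd_trs <- window_trs / 3
  half <- (window_trs - 1L) %/% 2L
  offs <- -half:half
  kern <- exp(-offs^2 / (2 * kernel_sd_trs^2))
  z <- numeric(n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - half); hi <- min(n, t + half)
    sel <- (lo - t + half + 1L):(hi - t + half + 1L)
    r <- weighted_corr(xv[lo:hi], yv[lo:hi], kern[sel])
    r <- max(-(1 - 1e-7), min(1 - 1e-7, r))
    z[t] <- atanh(r)
  }
  flag <- ""
  z_done <- FALSE
  if (isTRUE(znorm)) {
    zs <- tryCatch(zscore(z), error = function(e) NULL)
    if (is.null(zs)) {
      flag <- "constant"
    } else {
      z <- zs
      z_done <- TRUE
    }
  }
  structure(list(values = z, tr_s = tr_s,
                 source = paste(lab_x, lab_y, sep = "-"),
                 window_trs = window_trs, kernel_sd_trs = kernel_sd_trs,
                 z_normalized = z_done, flag = flag),
            class = "edge_series")
}

#' @export
print.edge_series <- function(x, ...) {
  cat(sprintf(
    "<edge_series> '%s', %d vols, window %d TRs, kernel sd %.3g TRs, z=%s%s\n",
    x$source, length(x$values), x$window_trs, x$kernel_sd_trs,
    x$z_normalized, if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Dynamic connectivity for every ROI pair
#'
#' One [edge_timeseries()] per unordered ROI pair, in deterministic
#' lexicographic label order; 10 ROIs yield 45 edges.
#'
#' @param rois named list of [neural_series()] (names are ROI labels; the
#'   series' `source` fields are used when names are absent).
#' @param ... passed to [edge_timeseries()].
#' @return Named list of `edge_series`, one per pair.
#' @export
all_edges <- function(rois, ...) {
  if (length(rois) < 2L) stop("need at least 2 ROIs")
  labels <- names(rois)
  if (is.null(labels))
    labels <- vapply(rois, function(r) r$source, character(1))
  if (anyDuplicated(labels))
    stop("duplicate ROI labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  ord <- order(labels)
  rois <- rois[ord]; labels <- labels[ord]
  pairs <- utils::combn(seq_along(labels), 2)
  out <- vector("list", ncol(pairs))
  nms <- character(ncol(pairs))
  for (e in seq_len(ncol(pairs))) {
    i <- pairs[1, e]; j <- pairs[2, e]
    es <- edge_timeseries(rois[[i]], rois[[j]], ...)
    es$source <- paste(labels[i], labels[j], sep = "-")
    out[[e]] <- es
    nms[e] <- es$source
  }
  names(out) <- nms
  out
}
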