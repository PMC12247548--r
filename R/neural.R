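#' Neural time series on the TR grid
#'
#' One ROI's activity, one ROI pair's windowed connectivity, or one voxel,
#' after denoising.
#'
#' @param values numeric vector, one value per volume.
#' @param tr_s repetition time (s).
#' @param source label: ROI name, edge label (`"a-b"`), or voxel index.
#' @param z_normalized logical flag.
#' @return An object of class `neural_series`.
#' @export
neural_series <- function(values, tr_s, source = "series",
                          z_normalized = FALSE) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("neural_series values must be finite")
  if (tr_s <= 0) stop("tr_s must be > 0")
  structure(list(values = values, tr_s = tr_s,
                 source = as.character(source),
                 z_normalized = isTRUE(z_normalized)),
            class = "neural_series")
}

#' @export
print.neural_series <- function(x, ...) {
  cat(sprintf("<neural_series> '%s', %d vols @ TR %.3g s, z=%s\n",
              x$source, length(x$values), x$tr_s, x$z_normalized))
  invisible(x)
}

series_values <- function(x) {
  if (inherits(x, c("neural_series", "hr_trace", "edge_series"))) x$values
  else as.numeric(x)
}

series_label <- function(x, default = "series") {
  if (is.list(x) && !is.null(x$source)) x$source else default
}

#' Expand 6 motion parameters to the 24-parameter set
#'
#' Columns 7-12 are first temporal differences (leading row zero); columns
#' 13-24 are element-wise squares of columns 1-12.
#'
#' @param motion6 matrix with 6 columns (3 rotations + 3 translations), one
#'   row per TR.
#' @return A matrix with 24 columns.
#' @export
expand_motion24 <- function(motion6) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L) stop("expected 6 motion columns")
  d <- rbind(0, diff(motion6))
  m12 <- cbind(motion6, d)
  out <- cbind(m12, m12^2)
  colnames(out) <- c(paste0("mot", 1:6), paste0("dmot", 1:6),
                     paste0("mot", 1:6, "_sq"), paste0("dmot", 1:6, "_sq"))
  out
}

#' Assemble the nuisance regression design matrix
#'
#' Columns are: Legendre drift polynomials of degree `0..polort_order`,
#' CSF and WM mean signals, and the 24-parameter motion set (expanded from
#' 6 raw parameters if needed).
#'
#' @param motion matrix with 6 raw or 24 expanded motion columns.
#' @param csf,wm numeric vectors of tissue mean signals (or `NULL`).
#' @param n_vols number of TRs.
#' @param polort_order drift polynomial order.
#' @return Design matrix with named columns.
#' @export
build_nuisance_matrix <- function(motion = NULL, csf = NULL, wm = NULL,
                                  n_vols, polort_order) {
  B <- legendre_basis(n_vols, polort_order)
  colnames(B) <- paste0("drift", 0:polort_order)
  X <- B
  if (!is.null(csf)) {
    if (length(csf) != n_vols) stop("csf length must equal n_vols")
    X <- cbind(X, csf = as.numeric(csf))
  }
  if (!is.null(wm)) {
    if (length(wm) != n_vols) stop("wm length must equal n_vols")
    X <- cbind(X, wm = as.numeric(wm))
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_vols) stop("motion rows must equal n_vols")
    if (ncol(motion) == 6L) motion <- expand_motion24(motion)
    if (ncol(motion) != 24L) stop("motion must have 6 or 24 columns")
    X <- cbind(X, motion)
  }
  # scaled condition number guards against duplicated/collinear columns
  Xs <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  sv <- svd(Xs, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > 1e10) {
    qr_X <- qr(Xs)
    bad <- colnames(X)[setdiff(seq_len(ncol(X)),
                               qr_X$pivot[seq_len(qr_X$rank)])]
    stop("collinear nuisance columns: ",
         paste(if (length(bad)) bad else "unknown", collapse = ", "))
  }
  X
}

#' Regress a design out of a series or volume
#'
#' Ordinary least squares residualization: `y - X (X'X)^-1 X' y`, applied
#' per series or per voxel. Residuals are orthogonal to every design
#' column.
#'
#' @param y numeric vector, `neural_series`, matrix (time x series), or
#'   [volume4d()].
#' @param X design matrix with one row per TR.
#' @return Residuals in the same container as `y`.
#' @export
residualize <- function(y, X) {
  X <- as.matrix(X)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) stop("rank-deficient design matrix")
  resid_mat <- function(M) {
    if (nrow(M) != nrow(X)) stop("time dimension mismatch with design")
    qr.resid(qr_X, M)
  }
  if (inherits(y, "volume4d")) {
    d <- dim(y$data)
    M <- matrix(aperm(y$data, c(4, 1, 2, 3)), nrow = d[4])
    R <- resid_mat(M)
    y$data <- aperm(array(R, dim = c(d[4], d[1:3])), c(2, 3, 4, 1))
    return(y)
  }
  if (inherits(y, "neural_series")) {
    y$values <- as.numeric(resid_mat(matrix(y$values, ncol = 1)))
    return(y)
  }
  if (is.matrix(y)) return(resid_mat(y))
  as.numeric(resid_mat(matrix(as.numeric(y), ncol = 1)))
}

#' Mean time series over an ROI mask
#'
#' @param vol a [volume4d()].
#' @param mask a [roi_mask()] on the same grid.
#' @return A [neural_series()] labelled with the mask's ROI name.
#' @export
extract_roi_mean <- function(vol, mask) {
  stopifnot(inherits(vol, "volume4d"), inherits(mask, "roi_mask"))
  if (!all(dim(vol$data)[1:3] == dim(mask$data)))
    stop("mask and volume grids differ")
  idx <- which(mask$data)
  if (length(idx) == 0L) stop("empty mask")
  nvox <- prod(dim(vol$data)[1:3])
  M <- matrix(vol$data, nrow = nvox)
  neural_series(colMeans(M[idx, , drop = FALSE]), tr_s = vol$tr_s,
                source = mask$label)
}

gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# 1D convolution along one axis of a 3D array, symmetric (reflecting)
# boundary; conserves the array sum for any normalized symmetric kernel
conv_axis3 <- function(a, k, axis) {
  r <- (length(k) - 1L) / 2L
  if (r == 0L) return(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  d <- dim(ap)
  n <- d[1]
  rr <- min(r, n)
  pad_idx <- c(rev(seq_len(rr)), seq_len(n), n:(n - rr + 1L))
  # if r > n, extend reflection periodically (tiny-grid guard)
  while (length(pad_idx) < n + 2 * r)
    pad_idx <- c(pad_idx[1], pad_idx, pad_idx[length(pad_idx)])
  M <- matrix(ap, nrow = n)
  P <- M[pad_idx, , drop = FALSE]
  out <- matrix(0, n, ncol(M))
  for (j in seq_along(k))
    out <- out + k[j] * P[(j - 1) + seq_len(n), , drop = FALSE]
  res <- array(out, dim = d)
  aperm(res, order(perm))
}

#' Spatial Gaussian smoothing of a 4D volume
#'
#' Separable 3D Gaussian convolution per timepoint, with
#' `sigma_mm = fwhm / sqrt(8 ln 2)` converted to voxels per axis and a
#' reflecting boundary (per-volume mass is conserved). `fwhm_mm = 0` is the
#' identity.
#'
#' @param vol a [volume4d()].
#' @param fwhm_mm target smoothing kernel FWHM in mm (default 6).
#' @return A smoothed [volume4d()].
#' @export
gaussian_smooth <- function(vol, fwhm_mm = 6.0) {
  stopifnot(inherits(vol, "volume4d"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(vol)
  sigma_mm <- fwhm_mm / sqrt(8 * log(2))
  sig_vox <- sigma_mm / vol$voxel_size_mm
  kernels <- lapply(sig_vox, gauss_kernel_1d)
  d <- dim(vol$data)
  for (t in seq_len(d[4])) {
    v <- vol$data[, , , t]
    for (ax in 1:3)
      if (length(kernels[[ax]]) > 1L) v <- conv_axis3(v, kernels[[ax]], ax)
    vol$data[, , , t] <- v
  }
  vol
}

#' Resample an ROI mask onto a target grid
#'
#' Nearest-neighbour resampling in world space: each target voxel takes the
#' mask value of the source voxel whose center is nearest to the target
#' voxel center's world coordinate.
#'
#' @param mask a [roi_mask()] carrying an affine.
#' @param target a [volume4d()] (or `roi_mask`) defining the output grid.
#' @return A [roi_mask()] on the target grid.
#' @export
resample_mask_to_grid <- function(mask, target) {
  stopifnot(inherits(mask, "roi_mask"))
  tdim <- if (inherits(target, "volume4d")) dim(target$data)[1:3]
          else dim(target$data)
  taff <- target$affine
  grid <- as.matrix(expand.grid(i = seq_len(tdim[1]) - 1,
                                j = seq_len(tdim[2]) - 1,
                                k = seq_len(tdim[3]) - 1))
  world <- cbind(grid, 1) %*% t(taff)
  src <- world %*% t(solve(mask$affine))
  idx <- round(src[, 1:3]) + 1
  sdim <- dim(mask$data)
  inside <- idx[, 1] >= 1 & idx[, 1] <= sdim[1] &
            idx[, 2] >= 1 & idx[, 2] <= sdim[2] &
            idx[, 3] >= 1 & idx[, 3] <= sdim[3]
  if (!any(inside))
    stop("disjoint fields of view: mask and target grids do not overlap")
  vals <- rep(FALSE, nrow(idx))
  lin <- (idx[inside, 3] - 1) * sdim[1] * sdim[2] +
         (idx[inside, 2] - 1) * sdim[1] + idx[inside, 1]
  vals[inside] <- as.vector(mask$data)[lin]
  out <- array(vals, dim = tdim)
  if (!any(out))
    stop("resampled mask is empty on the target grid")
  roi_mask(out, label = mask$label, affine = taff)
}
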