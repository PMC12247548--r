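#' Construct a beats-per-minute series
#'
#' A `bpm_series` holds heart-rate samples on a uniform time grid with an
#' explicit missing-sample mask. This is the raw cardiac input to the
#' pipeline: heartbeat detection from the oximeter waveform happens upstream.
#'
#' @param time_s numeric vector of sample times in seconds from scan start;
#'   must be strictly increasing and uniformly spaced.
#' @param bpm numeric vector of beats-per-minute values; `NA`/non-finite
#'   entries are treated as missing.
#' @param missing optional logical mask marking missing samples; defaults to
#'   `!is.finite(bpm)`.
#' @return An object of class `bpm_series` with fields `time_s`, `bpm`,
#'   `missing` and `rate_hz` (inferred from the median spacing).
#' @export
bpm_series <- function(time_s, bpm, missing = NULL) {
  time_s <- as.numeric(time_s)
  bpm <- as.numeric(bpm)
  if (length(time_s) != length(bpm))
    stop("time_s and bpm must have equal length")
  if (length(time_s) < 2L)
    stop("a bpm_series needs at least 2 samples")
  dt <- diff(time_s)
  if (any(dt <= 0))
    stop("non-monotone sample times in BPM series")
  spacing <- stats::median(dt)
  if (any(abs(dt - spacing) > 1e-6))
    stop("BPM sample times are not uniformly spaced")
  if (is.null(missing)) missing <- !is.finite(bpm)
  missing <- as.logical(missing)
  if (length(missing) != length(bpm))
    stop("missing mask length mismatch")
  missing <- missing | !is.finite(bpm)
  if (any(!is.finite(bpm[!missing])))
    stop("non-finite BPM value not flagged as missing")
  structure(
    list(time_s = time_s, bpm = bpm, missing = missing,
         rate_hz = 1 / spacing),
    class = "bpm_series")
}

#' @export
print.bpm_series <- function(x, ...) {
  cat(sprintf("<bpm_series> %d samples @ %.3g Hz, %d missing, span %.1f s\n",
              length(x$bpm), x$rate_hz, sum(x$missing),
              diff(range(x$time_s))))
  invisible(x)
}

#' @export
length.bpm_series <- function(x) length(x$bpm)

#' Read a beats-per-minute table
#'
#' Expects a plain text table (tab-, comma- or whitespace-separated) with
#' columns `time_s` and `bpm`; empty or non-numeric bpm cells mark missing
#' samples.
#'
#' @param path file path.
#' @return A [bpm_series()].
#' @export
read_bpm <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           strip.white = TRUE, blank.lines.skip = TRUE)
  need <- c("time_s", "bpm")
  if (!all(need %in% names(tab)))
    stop("BPM table must have columns time_s and bpm")
  time_s <- suppressWarnings(as.numeric(tab$time_s))
  if (any(!is.finite(time_s)))
    stop("unparseable time_s values in BPM table")
  bpm <- suppressWarnings(as.numeric(tab$bpm))
  bpm_series(time_s, bpm)
}

#' Write a beats-per-minute table
#' @param s a [bpm_series()].
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_bpm <- function(s, path) {
  stopifnot(inherits(s, "bpm_series"))
  out <- data.frame(time_s = s$time_s,
                    bpm = ifelse(s$missing, NA_real_, s$bpm))
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Construct a 4D volume
#'
#' Container for a BOLD run: a 4D intensity grid plus spatial metadata and
#' the repetition time.
#'
#' @param data 4D numeric array (x, y, z, t) with at least 2 timepoints.
#' @param voxel_size_mm length-3 voxel dimensions in mm.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @param tr_s repetition time in seconds.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(data, voxel_size_mm = c(2.5, 2.5, 2.5),
                     affine = NULL, tr_s = 0.7) {
  data <- as.array(data)
  if (length(dim(data)) != 4L)
    stop("volume4d requires a 4D array")
  if (any(dim(data)[1:3] < 1L) || dim(data)[4] < 2L)
    stop("spatial dims must be >= 1 and time dim >= 2")
  if (!is.numeric(tr_s) || tr_s <= 0)
    stop("missing TR: tr_s must be > 0")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive values")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) ||
      abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 affine = affine, tr_s = tr_s),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  cat(sprintf("<volume4d> %s, voxel %s mm, TR %.3g s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size_mm, 3), collapse = "x"), x$tr_s))
  invisible(x)
}

#' Construct an ROI mask
#'
#' @param data logical 3D array; `TRUE` marks in-mask voxels.
#' @param label region name.
#' @param affine optional 4x4 voxel-to-world matrix.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, label = "roi", affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("roi_mask requires a 3D array")
  data <- data != 0 & !is.na(data)
  if (!any(data))
    stop("empty mask: no in-mask voxels")
  if (is.null(affine)) affine <- diag(4)
  structure(list(data = data, label = as.character(label),
                 affine = as.matrix(affine)),
            class = "roi_mask")
}

# raw pixdim[4] (dt) from a NIfTI-1 header (gz or plain), or NULL when the
# field cannot be located (e.g. NIfTI-2)
raw_nifti_dt <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", n = 1, size = 4)
  endian <- .Platform$endian
  if (!identical(hdr_size, 348L)) {
    swapped <- readBin(writeBin(hdr_size, raw()), "integer", size = 4,
                       endian = if (endian == "little") "big" else "little")
    if (!identical(swapped, 348L)) return(NULL)
    endian <- if (endian == "little") "big" else "little"
  }
  skip <- readBin(con, "raw", n = 88)           # bytes 4..91
  readBin(con, "numeric", n = 1, size = 4, endian = endian)  # byte 92
}

#' Read a 4D NIfTI volume
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param tr_s optional TR override in seconds; required when the file
#'   header stores no repetition time.
#' @return A [volume4d()].
#' @export
read_volume <- function(path, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("expected a 4D volume, got %dD: %s", length(d), path))
  hdr <- RNifti::niftiHeader(img)
  tr_hdr <- hdr$pixdim[5]
  # the NIfTI library normalizes a zero dt to 1 on read, which would mask
  # a file with no stored TR; consult the raw header field
  raw_dt <- raw_nifti_dt(path)
  if (!is.null(raw_dt) && raw_dt <= 0) tr_hdr <- 0
  tr <- if (!is.null(tr_s)) tr_s else tr_hdr
  if (!is.numeric(tr) || !is.finite(tr) || tr <= 0)
    stop("missing TR in NIfTI header; supply tr_s")
  volume4d(array(as.numeric(img), dim = d),
           voxel_size_mm = abs(hdr$pixdim[2:4]),
           affine = unclass(RNifti::xform(img))[1:4, 1:4],
           tr_s = tr)
}

#' Write a 4D volume to NIfTI
#'
#' Round-trips data (float32 precision), affine and TR through
#' [read_volume()].
#'
#' @param vol a [volume4d()].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume4d"))
  hdr <- RNifti::niftiHeader(list(
    pixdim = c(1, vol$voxel_size_mm, vol$tr_s, 0, 0, 0)))
  img <- RNifti::asNifti(vol$data, hdr)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an ROI mask from NIfTI
#'
#' Voxels with intensity > 0 are in-mask.
#'
#' @param path NIfTI file (3D, or 4D with a single volume).
#' @param label region name to attach.
#' @return A [roi_mask()].
#' @export
read_mask <- function(path, label = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
  } else if (length(d) == 3L) {
    img2 <- array(as.numeric(img), dim = d)
  } else {
    stop("mask must be a 3D volume")
  }
  if (is.null(label))
    label <- sub("\\.nii(\\.gz)?$", "", basename(path))
  roi_mask(img2 > 0, label = label,
           affine = unclass(RNifti::xform(img))[1:4, 1:4])
}

record_columns <- c("subject", "condition", "target", "target_type",
                    "measure", "value", "lag_s_at_max",
                    "n_timepoints_used", "flag")

#' Write coherence records or group results to a TSV table
#'
#' Rows are sorted deterministically (subject, condition, target, measure
#' for records; target, measure for group results).
#'
#' @param records a data frame of coherence records or group results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- as.data.frame(records)
  keys <- intersect(c("subject", "condition", "target", "measure"),
                    names(records))
  if (nrow(records) > 0 && length(keys) > 0) {
    ord <- do.call(order, lapply(keys, function(k) records[[k]]))
    records <- records[ord, , drop = FALSE]
  }
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a records table written by [write_records()]
#' @param path TSV path.
#' @return A data frame.
#' @export
read_records <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Run configuration
#'
#' Collects every analysis parameter in one validated list. Defaults follow
#' the study design this package implements: TR 0.7 s, a 6 s hemodynamic
#' lag applied to heart rate, a 29-TR (20.3 s) Gaussian-weighted
#' connectivity window, a 14-TR (~10 s) Sakoe-Chiba band for dynamic time
#' warping, an additional 10 s heart-rate offset for the voxel-wise
#' cross-correlation search, 6 mm FWHM smoothing for voxel-wise analyses,
#' and one drift polynomial order per 150 s of run duration.
#'
#' @param tr_s repetition time (s).
#' @param lag_s hemodynamic lag applied to the heart-rate series (s).
#' @param window_trs sliding-window width for dynamic connectivity (odd TR
#'   count).
#' @param band_trs Sakoe-Chiba band half-width in TRs.
#' @param extra_hr_lag_s additional heart-rate offset for the voxel-wise
#'   cross-correlation search (s).
#' @param smooth_fwhm_mm spatial smoothing FWHM for voxel-wise analyses.
#' @param detrend_seconds_per_order run seconds per drift polynomial order
#'   (the automatic detrending rule is `1 + floor(duration / this)`).
#' @param alpha two-tailed significance level.
#' @param voxel_p cluster-forming voxel-wise p threshold.
#' @param n_permutations sign-flip permutations for cluster correction.
#' @param seed integer seed for stochastic stages.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(tr_s = 0.7, lag_s = 6.0, window_trs = 29L,
                       band_trs = 14L, extra_hr_lag_s = 10.0,
                       smooth_fwhm_mm = 6.0,
                       detrend_seconds_per_order = 150.0,
                       alpha = 0.05, voxel_p = 0.001,
                       n_permutations = 2000L, seed = 1L) {
  cfg <- list(tr_s = tr_s, lag_s = lag_s, window_trs = as.integer(window_trs),
              band_trs = as.integer(band_trs),
              extra_hr_lag_s = extra_hr_lag_s,
              smooth_fwhm_mm = smooth_fwhm_mm,
              detrend_seconds_per_order = detrend_seconds_per_order,
              alpha = alpha, voxel_p = voxel_p,
              n_permutations = as.integer(n_permutations),
              seed = as.integer(seed))
  stopifnot(cfg$tr_s > 0, cfg$lag_s >= 0, cfg$window_trs > 0,
            cfg$band_trs >= 0, cfg$extra_hr_lag_s >= 0,
            cfg$smooth_fwhm_mm >= 0, cfg$detrend_seconds_per_order > 0,
            cfg$alpha > 0, cfg$alpha < 1, cfg$voxel_p > 0, cfg$voxel_p < 1,
            cfg$n_permutations >= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#' @param path YAML (or JSON, a YAML subset) file whose keys match the
#'   arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown run_config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
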