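# advance an hr_trace earlier by a whole number of TRs, tail-padded with
# the last value. The cross-correlation search only scans delays of the
# neural series behind the heart rate; advancing the heart rate by the
# extra offset lets non-negative grid delays cover BOLD preceding the
# hemodynamically lagged heart rate by up to that offset.
advance_trace_trs <- function(hr, k_trs) {
  k <- as.integer(k_trs)
  v <- hr$values
  n <- length(v)
  if (k <= 0L) return(hr)
  if (k >= n) stop("shift exceeds series length")
  hr$values <- c(v[(k + 1L):n], rep(v[n], k))
  hr$applied_lag_s <- hr$applied_lag_s - k * hr$tr_s
  hr$z_normalized <- FALSE
  hr$provenance <- c(hr$provenance, sprintf("advance:%d TRs", k))
  hr
}

read_subject_condition <- function(data_dir, sub, cond) {
  bpm_path <- file.path(data_dir, sprintf("%s_%s_bpm.tsv", sub, cond))
  roi_path <- file.path(data_dir, sprintf("%s_%s_rois.tsv", sub, cond))
  missing <- c(bpm_path, roi_path)[!file.exists(c(bpm_path, roi_path))]
  if (length(missing) > 0)
    stop(sprintf("missing input for subject %s, condition %s: %s",
                 sub, cond, paste(basename(missing), collapse = ", ")))
  rois <- utils::read.table(roi_path, header = TRUE, sep = "\t",
                            check.names = FALSE)
  list(bpm = read_bpm(bpm_path), rois = as.matrix(rois),
       files = c(bpm_path, roi_path))
}

#' Run the full brain-heart coherence pipeline on a dataset directory
#'
#' Stages, in order: cardiac preprocessing (gap interpolation, smoothing,
#' TR-grid resampling with the hemodynamic lag, detrending,
#' z-normalization); neural preprocessing (Legendre detrending and
#' z-normalization of each ROI series); Gaussian-weighted sliding-window
#' dynamic connectivity over all ROI pairs; the three coherence measures
#' per subject x condition x target (bivariate Fisher-z at the hemodynamic
#' lag; band-constrained dynamic time warping on condition-length-matched
#' series; cross-correlation maximum over the delay grid with the extra
#' heart-rate offset); and paired group contrasts with Bonferroni
#' families.
#'
#' The directory must contain a `manifest.yaml` (as written by
#' [write_sim_dataset()]) and per-subject `"<sub>_<cond>_bpm.tsv"` /
#' `"<sub>_<cond>_rois.tsv"` tables.
#'
#' @param cfg a [run_config()].
#' @param data_dir dataset directory.
#' @param contrast conditions contrasted at group level (first minus
#'   second); default suspense minus control.
#' @param measures subset of `c("bivariate", "dtw", "xcorr")`.
#' @param out_dir optional directory: records and group tables are written
#'   there, and an existing records table from an identical configuration
#'   is reused instead of recomputed.
#' @return List of class `pipeline_result`: `records` (coherence record
#'   table), `group` (contrast table), `manifest` (config snapshot, input
#'   file hashes, output hash, timestamps).
#' @export
run_pipeline <- function(cfg, data_dir,
                         contrast = c("suspense", "control"),
                         measures = c("bivariate", "dtw", "xcorr"),
                         out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  measures <- match.arg(measures, several.ok = TRUE)
  man_path <- file.path(data_dir, "manifest.yaml")
  if (!file.exists(man_path))
    stop("no manifest.yaml in ", data_dir)
  man <- yaml::read_yaml(man_path)
  subjects <- man$subjects
  conditions <- man$conditions
  n_vols <- man$n_vols

  cfg_key <- paste(unlist(cfg), collapse = ",")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cache <- file.path(out_dir, "records.tsv")
    keyf <- file.path(out_dir, "records.key")
    if (file.exists(cache) && file.exists(keyf) &&
        identical(readLines(keyf, warn = FALSE), cfg_key)) {
      records <- read_records(cache)
      group <- contrast_table(records, contrast, alpha = cfg$alpha)
      return(structure(list(records = records, group = group,
                            manifest = list(config = unclass(cfg),
                                            cached = TRUE)),
                       class = "pipeline_result"))
    }
  }

  extra_trs <- as.integer(round(cfg$extra_hr_lag_s / cfg$tr_s))
  max_lag_trs <- extra_trs + as.integer(round(16 / cfg$tr_s))
  min_nvols <- min(unlist(n_vols))
  input_files <- character()
  recs <- list()

  for (sub in subjects) {
    per_cond <- list()
    for (cond in conditions) {
      dat <- read_subject_condition(data_dir, sub, cond)
      input_files <- c(input_files, dat$files)
      nv <- n_vols[[cond]]
      ord <- auto_polort_order(nv * cfg$tr_s, cfg$detrend_seconds_per_order)
      hr <- prep_hr(dat$bpm, tr_s = cfg$tr_s, n_vols = nv,
                    lag_s = cfg$lag_s, detrend_order = ord,
                    seconds_per_order = cfg$detrend_seconds_per_order)
      roi_series <- lapply(colnames(dat$rois), function(lbl) {
        neural_series(zscore(legendre_detrend(dat$rois[, lbl], ord)),
                      tr_s = cfg$tr_s, source = lbl, z_normalized = TRUE)
      })
      names(roi_series) <- colnames(dat$rois)
      edges <- all_edges(roi_series, window_trs = cfg$window_trs)
      per_cond[[cond]] <- list(hr = hr, rois = roi_series, edges = edges)
    }
    for (cond in conditions) {
      pc <- per_cond[[cond]]
      targets <- c(pc$rois, pc$edges)
      types <- c(rep("roi", length(pc$rois)),
                 rep("edge", length(pc$edges)))
      hr_x <- advance_trace_trs(pc$hr, extra_trs)
      for (ti in seq_along(targets)) {
        tgt <- targets[[ti]]
        if (!is.null(tgt$flag) && nzchar(tgt$flag)) next
        if ("bivariate" %in% measures)
          recs[[length(recs) + 1L]] <- bivariate_coherence(
            pc$hr, tgt, subject = sub, condition = cond,
            target_type = types[ti])
        if ("dtw" %in% measures) {
          m <- match_condition_lengths(
            pc$hr$values[seq_len(min_nvols) +
                           (length(pc$hr$values) - min_nvols)],
            tgt$values[seq_len(min_nvols) +
                         (length(tgt$values) - min_nvols)])
          recs[[length(recs) + 1L]] <- dtw_coherence(
            m$a, m$b, band_trs = cfg$band_trs, subject = sub,
            condition = cond, target = tgt$source,
            target_type = types[ti])
        }
        if ("xcorr" %in% measures)
          recs[[length(recs) + 1L]] <- xcorr_max(
            hr_x, tgt, max_lag_trs = max_lag_trs,
            lag_offset_s = extra_trs * cfg$tr_s, subject = sub,
            condition = cond, target = tgt$source,
            target_type = types[ti])
      }
    }
  }
  records <- do.call(rbind, recs)
  group <- contrast_table(records, contrast, alpha = cfg$alpha)

  manifest <- list(
    config = unclass(cfg),
    tool_version = as.character(utils::packageVersion("cardiocohere")),
    input_hashes = as.list(tools::md5sum(unique(input_files))),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    cached = FALSE)
  if (!is.null(out_dir)) {
    write_records(records, file.path(out_dir, "records.tsv"))
    write_records(group, file.path(out_dir, "group.tsv"))
    writeLines(cfg_key, file.path(out_dir, "records.key"))
    manifest$output_hashes <- as.list(tools::md5sum(
      c(file.path(out_dir, "records.tsv"), file.path(out_dir, "group.tsv"))))
  }
  structure(list(records = records, group = group, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d records, %d group contrasts\n",
              nrow(x$records), nrow(x$group)))
  sig <- x$group[x$group$significant_corrected, , drop = FALSE]
  if (nrow(sig) > 0) {
    cat("corrected-significant contrasts:\n")
    print(sig[, c("target", "measure", "t", "df", "p_two_tailed",
                  "cohens_d", "family")])
  }
  invisible(x)
}

#' Effect-size matrix report for a group contrast
#'
#' Lower-triangle-plus-diagonal matrix of paired Cohen's d for one
#' measure: the diagonal holds heart-rate/activity coherence effects per
#' ROI, the lower triangle heart-rate/connectivity effects per ROI pair.
#' Entries are annotated `**` when they pass the Bonferroni-corrected
#' threshold and `*` at the uncorrected level.
#'
#' @param group a contrast table from [contrast_table()] or
#'   [run_pipeline()].
#' @param measure which coherence measure to display (default
#'   `"bivariate_z"`).
#' @param rois ROI order for the matrix (default [roi_labels()]).
#' @param alpha uncorrected annotation level.
#' @return Object of class `coherence_report`: `d` (numeric matrix),
#'   `annot` (character matrix), `measure`, plus `note` if the edge family
#'   was absent.
#' @export
coherence_report <- function(group, measure = "bivariate_z",
                             rois = roi_labels(), alpha = 0.05) {
  g <- group[group$measure == measure, , drop = FALSE]
  if (nrow(g) == 0L) stop("no group results for measure ", measure)
  n <- length(rois)
  d <- matrix(NA_real_, n, n, dimnames = list(rois, rois))
  annot <- matrix("", n, n, dimnames = list(rois, rois))
  mark <- function(row) {
    if (row$significant_corrected) "**"
    else if (row$p_two_tailed < alpha) "*"
    else ""
  }
  for (i in seq_len(nrow(g))) {
    row <- g[i, ]
    if (row$target_type == "roi" && row$target %in% rois) {
      d[row$target, row$target] <- row$cohens_d
      annot[row$target, row$target] <- mark(row)
    } else if (row$target_type == "edge") {
      ends <- strsplit(row$target, "-", fixed = TRUE)[[1]]
      if (length(ends) == 2L && all(ends %in% rois)) {
        a <- max(match(ends, rois)); b <- min(match(ends, rois))
        d[a, b] <- row$cohens_d
        annot[a, b] <- mark(row)
      }
    }
  }
  note <- if (!any(g$target_type == "edge"))
    "no connectivity (edge) results: off-diagonal omitted" else NULL
  structure(list(d = d, annot = annot, measure = measure, note = note),
            class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  cat(sprintf("Paired Cohen's d matrix (%s)\n", x$measure))
  cat("diagonal: HR-activity coherence; below diagonal: HR-connectivity\n")
  cat("** corrected threshold, * p < .05 uncorrected\n")
  if (!is.null(x$note)) cat("note: ", x$note, "\n", sep = "")
  fmt <- ifelse(is.na(x$d), ".",
                paste0(formatC(x$d, digits = 2, format = "f"), x$annot))
  dimnames(fmt) <- dimnames(x$d)
  print(fmt, quote = FALSE)
  invisible(x)
}
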