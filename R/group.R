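#' Paired t-test on within-subject differences
#'
#' `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`, two-tailed p from the t
#' distribution, and paired Cohen's d `= mean(d) / sd(d)`.
#'
#' @param diffs numeric vector of per-subject differences, `n >= 3`.
#' @return List with `t`, `df`, `p`, `d`, `n`.
#' @export
paired_t <- function(diffs) {
  diffs <- as.numeric(diffs)
  n <- length(diffs)
  if (n < 3L) stop("need at least 3 paired differences")
  s <- stats::sd(diffs)
  if (s == 0) stop("zero-variance differences: t undefined")
  t <- mean(diffs) / (s / sqrt(n))
  df <- n - 1L
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       d = mean(diffs) / s, n = n)
}

#' Bonferroni-corrected significance level
#'
#' @param family_size number of tests in the family (>= 1).
#' @param alpha uncorrected level (default 0.05).
#' @return `alpha / family_size`. A family of 5 gives 0.01; the 55-test
#'   exploratory family (10 activation ROIs + 45 edges) gives 0.000909...,
#'   i.e. .0009 at 4 decimals.
#' @export
bonferroni <- function(family_size, alpha = 0.05) {
  stopifnot(family_size >= 1, alpha > 0, alpha < 1)
  alpha / family_size
}

#' Default preregistered hypothesis ROIs
#'
#' The five activation regions tested as primary hypotheses: left/right
#' amygdala, left/right anterior insula, and dmPFC.
#' @return Character vector of 5 ROI labels.
#' @export
hypothesis_rois <- function() {
  c("amygdala_L", "amygdala_R", "insula_ant_L", "insula_ant_R", "dmPFC")
}

#' Paired group contrasts over a coherence record table
#'
#' For every target x measure, subjects' condition-A minus condition-B
#' values are submitted to a paired t-test. Subjects missing either
#' condition are excluded listwise (count reported in the `n_excluded`
#' column). Targets whose differences have zero variance are dropped with a
#' warning. Each result is assigned a Bonferroni family: activation ROIs in
#' `hypothesis` get `alpha / length(hypothesis)`; all other ROI and edge
#' targets are exploratory with divisor `exploratory_family_size`, which
#' defaults to the total number of ROI + edge targets in the table.
#'
#' @param records data frame of coherence records (see
#'   [bivariate_coherence()] and friends).
#' @param contrast length-2 character vector, e.g.
#'   `c("suspense", "control")` for suspense minus control.
#' @param hypothesis character vector of hypothesis-family ROI labels.
#' @param alpha uncorrected two-tailed level.
#' @param exploratory_family_size Bonferroni divisor for the exploratory
#'   family; `NULL` uses the number of distinct roi/edge targets present.
#' @return Data frame with one row per target x measure: `t`, `df`,
#'   `p_two_tailed`, `cohens_d`, `family`, `alpha_corrected`,
#'   `significant_corrected`, `n`, `n_excluded`.
#' @export
contrast_table <- function(records, contrast,
                           hypothesis = hypothesis_rois(),
                           alpha = 0.05, exploratory_family_size = NULL) {
  records <- as.data.frame(records)
  stopifnot(length(contrast) == 2L)
  rec <- records[records$condition %in% contrast, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records for the requested conditions")
  if (is.null(exploratory_family_size)) {
    # the exploratory family counts all ROI + edge targets (55 in the
    # 10-ROI design), applied per measure
    exploratory_family_size <- max(1L, length(unique(
      rec$target[rec$target_type %in% c("roi", "edge")])))
  }
  combos <- unique(rec[, c("target", "target_type", "measure")])
  combos <- combos[order(combos$target, combos$measure), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- rec$target == combos$target[i] & rec$measure == combos$measure[i]
    a <- rec[sel & rec$condition == contrast[1], c("subject", "value")]
    b <- rec[sel & rec$condition == contrast[2], c("subject", "value")]
    m <- merge(a, b, by = "subject", suffixes = c("_a", "_b"))
    m <- m[is.finite(m$value_a) & is.finite(m$value_b), , drop = FALSE]
    n_total <- length(union(a$subject, b$subject))
    n_excluded <- n_total - nrow(m)
    if (nrow(m) < 3L)
      stop(sprintf("fewer than 3 complete subjects for %s/%s",
                   combos$target[i], combos$measure[i]))
    diffs <- m$value_a - m$value_b
    if (stats::sd(diffs) == 0) {
      warning(sprintf("zero-variance differences for %s/%s: excluded",
                      combos$target[i], combos$measure[i]))
      next
    }
    pt <- paired_t(diffs)
    fam <- if (combos$target_type[i] == "roi" &&
               combos$target[i] %in% hypothesis) "hypothesis"
           else if (combos$target_type[i] %in% c("roi", "edge"))
             "exploratory"
           else "none"
    ac <- switch(fam,
                 hypothesis = bonferroni(length(hypothesis), alpha),
                 exploratory = bonferroni(exploratory_family_size, alpha),
                 none = alpha)
    out[[length(out) + 1L]] <- data.frame(
      target = combos$target[i], target_type = combos$target_type[i],
      measure = combos$measure[i],
      contrast = paste(contrast, collapse = "-"),
      t = pt$t, df = pt$df, p_two_tailed = pt$p, cohens_d = pt$d,
      family = fam, alpha_corrected = ac,
      significant_corrected = pt$p < ac,
      n = pt$n, n_excluded = n_excluded,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("no testable target/measure combinations")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

neighbor_offsets <- function(connectivity = 1L) {
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(offs))
  keep <- switch(as.character(connectivity),
                 "1" = nz == 1,           # faces
                 "2" = nz >= 1 & nz <= 2, # faces + edges
                 "3" = nz >= 1,           # faces + edges + corners
                 stop("connectivity must be 1, 2 or 3"))
  offs[keep, , drop = FALSE]
}

#' Label connected clusters in a 3D logical array
#'
#' @param mask logical 3D array.
#' @param connectivity 1 (faces, default), 2 (+edges) or 3 (+corners).
#' @return Integer array of cluster labels (0 = background), with the
#'   number of clusters as attribute `n`.
#' @export
label_clusters <- function(mask, connectivity = 1L) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  offs <- neighbor_offsets(connectivity)
  lab <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L) {
    attr(lab, "n") <- 0L
    return(lab)
  }
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      v0 <- v - 1L
      i <- v0 %% d[1]
      j <- (v0 %/% d[1]) %% d[2]
      k <- v0 %/% (d[1] * d[2])
      ni <- i + offs[, 1]; nj <- j + offs[, 2]; nk <- k + offs[, 3]
      ok <- ni >= 0 & ni < d[1] & nj >= 0 & nj < d[2] & nk >= 0 & nk < d[3]
      nb <- 1L + ni[ok] + d[1] * (nj[ok] + d[2] * nk[ok])
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb) > 0L) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  attr(lab, "n") <- cur
  lab
}

max_cluster_extent <- function(mask, connectivity = 1L) {
  if (!any(mask)) return(0L)
  lab <- label_clusters(mask, connectivity)
  max(tabulate(lab[lab > 0L]))
}

#' Permutation-based cluster-extent correction for paired difference maps
#'
#' The observed per-voxel paired t map is thresholded two-tailed at
#' `voxel_p`; suprathreshold voxels are grouped into connected clusters.
#' The null distribution of the maximum cluster extent is built by
#' randomly sign-flipping each subject's difference map (exhaustive
#' enumeration when `2^n <= n_perms`, otherwise Monte-Carlo with the given
#' seed). The extent threshold is the ceiling of the `1 - alpha` quantile
#' of the null maxima; clusters exceeding it are reported with corrected
#' `p = (1 + #\{null max >= extent\}) / (n_used + 1)`.
#'
#' @param diff_maps 4D array (x, y, z, subject) of per-subject
#'   condition-difference maps, or a list of 3D arrays.
#' @param voxel_p cluster-forming two-tailed voxel-wise p (default 0.001).
#' @param alpha family-wise level (default 0.05).
#' @param n_perms requested permutations (>= 500).
#' @param seed integer seed for Monte-Carlo sign flips.
#' @param connectivity cluster connectivity (1 = faces, default).
#' @param affine optional 4x4 voxel-to-world matrix for peak coordinates.
#' @return List of class `cluster_result`: `clusters` (data frame with
#'   extent, peak world-mm coordinates rounded to integers, peak |t|,
#'   corrected p), `extent_threshold`, `null_max_extents`, `t_map`,
#'   `df`, `t_threshold`, `n_perms_used`, `exhaustive`.
#' @export
cluster_correct <- function(diff_maps, voxel_p = 0.001, alpha = 0.05,
                            n_perms = 1000L, seed = 1L,
                            connectivity = 1L, affine = NULL) {
  if (is.list(diff_maps))
    diff_maps <- array(unlist(diff_maps),
                       dim = c(dim(diff_maps[[1]]), length(diff_maps)))
  d <- dim(diff_maps)
  stopifnot(length(d) == 4L)
  n <- d[4]
  if (n < 8L) stop("need at least 8 subjects")
  n_perms <- as.integer(n_perms)
  if (n_perms < 500L) stop("need at least 500 permutations")
  dims3 <- d[1:3]
  nvox <- prod(dims3)
  D <- t(matrix(diff_maps, nrow = nvox))   # subjects x voxels
  df <- n - 1L
  tcrit <- stats::qt(1 - voxel_p / 2, df)
  ss <- colSums(D^2)
  t_from_signs <- function(s) {
    m <- as.numeric(s %*% D) / n
    v <- (ss - n * m^2) / df
    v[v <= 0] <- NA_real_
    tv <- m / sqrt(v / n)
    tv[!is.finite(tv)] <- 0
    tv
  }
  t_obs <- t_from_signs(rep(1, n))
  obs_mask <- array(abs(t_obs) > tcrit, dims3)
  lab <- label_clusters(obs_mask, connectivity)
  n_clust <- attr(lab, "n")

  exhaustive <- 2^n <= n_perms
  if (exhaustive) {
    n_used <- as.integer(2^n)
    signs_mat <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    n_used <- n_perms
    rs <- local({
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
      matrix(sample(c(-1, 1), n_used * n, replace = TRUE), n_used, n)
    })
    signs_mat <- rs
  }
  null_max <- integer(n_used)
  for (p in seq_len(n_used)) {
    tp <- t_from_signs(signs_mat[p, ])
    null_max[p] <- max_cluster_extent(array(abs(tp) > tcrit, dims3),
                                      connectivity)
  }
  k_thr <- as.integer(ceiling(stats::quantile(null_max, 1 - alpha,
                                              type = 1, names = FALSE)))
  clusters <- data.frame(cluster = integer(), extent = integer(),
                         peak_x_mm = integer(), peak_y_mm = integer(),
                         peak_z_mm = integer(), peak_abs_t = numeric(),
                         p_corrected = numeric())
  if (n_clust > 0L) {
    if (is.null(affine)) affine <- diag(4)
    rows <- list()
    for (cl in seq_len(n_clust)) {
      vox <- which(lab == cl)
      ext <- length(vox)
      if (ext <= k_thr) next
      tvals <- abs(t_obs)[vox]
      pk <- vox[which.max(tvals)]
      v0 <- pk - 1L
      ijk <- c(v0 %% dims3[1], (v0 %/% dims3[1]) %% dims3[2],
               v0 %/% (dims3[1] * dims3[2]))
      world <- as.numeric(affine %*% c(ijk, 1))[1:3]
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, extent = ext,
        peak_x_mm = as.integer(round(world[1])),
        peak_y_mm = as.integer(round(world[2])),
        peak_z_mm = as.integer(round(world[3])),
        peak_abs_t = max(tvals),
        p_corrected = (1 + sum(null_max >= ext)) / (n_used + 1))
    }
    if (length(rows) > 0L) clusters <- do.call(rbind, rows)
  }
  structure(list(clusters = clusters, extent_threshold = k_thr,
                 null_max_extents = null_max,
                 t_map = array(t_obs, dims3), df = df,
                 t_threshold = tcrit, n_perms_used = n_used,
                 exhaustive = exhaustive),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> df=%d, |t|>%.3f, extent threshold k>%d (%s, %d perms)\n",
    x$df, x$t_threshold, x$extent_threshold,
    if (x$exhaustive) "exhaustive sign-flips" else "Monte-Carlo",
    x$n_perms_used))
  if (nrow(x$clusters) == 0L) cat("no surviving clusters\n")
  else print(x$clusters)
  invisible(x)
}
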