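#' The ten defensive-response-network region labels
#' @return Character vector of 10 ROI labels.
#' @export
roi_labels <- function() {
  c("amygdala_L", "amygdala_R", "insula_ant_L", "insula_ant_R",
    "dmPFC", "vmPFC", "sgACC", "BNST", "hypothalamus", "PAG")
}

#' Simulation configuration
#'
#' Defines the synthetic study: a two-movie (suspense / control) plus rest
#' design with heart rate coupled to BOLD at a hemodynamic lag, and one or
#' more ROI pairs whose time-varying connectivity is modulated by lagged
#' heart rate with condition-dependent sign. Defaults mirror the study
#' design this package targets: 29 subjects; 480 s suspense, 330 s
#' control, 420 s rest; TR 0.7 s; subject baselines 66 +/- 9 bpm with the
#' suspense condition elevated above control; a 6 s coupling lag; and a
#' positive connectivity-coupling slope in the control condition that
#' reverses sign under suspense.
#'
#' @param n_subjects number of simulated subjects.
#' @param duration_s named condition durations in seconds.
#' @param tr_s repetition time.
#' @param hr_base_bpm population mean resting heart rate.
#' @param hr_base_sd between-subject sd of the baseline.
#' @param hr_cond_offset named per-condition mean offsets (bpm).
#' @param hr_ar_coef AR(1) coefficient of the 1 Hz heart-rate fluctuation
#'   (|coef| < 1).
#' @param hr_noise_sd AR(1) innovation sd (bpm).
#' @param hr_drift_amp amplitude of the slow sinusoidal drift (bpm).
#' @param coupling_lag_s lag at which BOLD tracks heart rate (s).
#' @param activity_coupling named per-condition standardized coupling
#'   strength between lagged z-scored HR and each ROI's activity.
#' @param connectivity_coupling named list: edge label (`"roiA-roiB"`) ->
#'   named per-condition gain-modulation slope `b`.
#' @param edge_gain_base gain intercept `a` of the shared-latent model.
#' @param edge_gain_max clip ceiling for the gain.
#' @param drift_order,drift_sd scanner drift: Legendre orders 1..order with
#'   N(0, drift_sd) coefficients.
#' @param noise_sd thermal noise sd of the BOLD signal.
#' @param missing_frac fraction of BPM samples masked at random (never the
#'   first or last sample); must be < 0.5.
#' @param seed integer master seed; all per-subject streams derive from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 29L,
                       duration_s = c(suspense = 480, control = 330,
                                      rest = 420),
                       tr_s = 0.7,
                       hr_base_bpm = 66, hr_base_sd = 9,
                       hr_cond_offset = c(suspense = 1.4, control = -1.4,
                                          rest = 0.5),
                       hr_ar_coef = 0.9, hr_noise_sd = 0.5,
                       hr_drift_amp = 2,
                       coupling_lag_s = 6.0,
                       activity_coupling = c(suspense = 0.2, control = 0.2,
                                             rest = 0.15),
                       connectivity_coupling = list(
                         "amygdala_R-dmPFC" = c(suspense = -0.4,
                                                control = 0.4, rest = 0)),
                       edge_gain_base = 0.6, edge_gain_max = 2,
                       drift_order = 3L, drift_sd = 1,
                       noise_sd = 1, missing_frac = 0.05,
                       seed = 1L) {
  stopifnot(n_subjects >= 1, all(duration_s >= 60), tr_s > 0,
            abs(hr_ar_coef) < 1, hr_noise_sd >= 0, hr_drift_amp >= 0,
            coupling_lag_s >= 0, missing_frac >= 0, missing_frac < 0.5,
            drift_order >= 0, drift_sd >= 0, noise_sd >= 0,
            edge_gain_base >= 0, edge_gain_max > 0)
  if (is.null(names(duration_s)) || any(!nzchar(names(duration_s))))
    stop("duration_s must be a named vector of conditions")
  cfg <- list(n_subjects = as.integer(n_subjects), duration_s = duration_s,
              tr_s = tr_s, hr_base_bpm = hr_base_bpm,
              hr_base_sd = hr_base_sd, hr_cond_offset = hr_cond_offset,
              hr_ar_coef = hr_ar_coef, hr_noise_sd = hr_noise_sd,
              hr_drift_amp = hr_drift_amp,
              coupling_lag_s = coupling_lag_s,
              activity_coupling = activity_coupling,
              connectivity_coupling = connectivity_coupling,
              edge_gain_base = edge_gain_base,
              edge_gain_max = edge_gain_max,
              drift_order = as.integer(drift_order), drift_sd = drift_sd,
              noise_sd = noise_sd, missing_frac = missing_frac,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# deterministic sub-stream seed below 2^31, independent of call order
sim_seed <- function(seed, subject, condition, salt = 0L) {
  cond_i <- sum(utf8ToInt(condition))
  as.integer((abs(as.numeric(seed)) * 10007 + subject * 101 +
                cond_i * 13 + salt * 7919) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

#' Simulate one subject-condition heart-rate series
#'
#' 1 Hz beats-per-minute: subject baseline (drawn once per subject from
#' the population distribution) + condition offset + slow sinusoidal drift
#' + AR(1) fluctuation. A fraction of interior samples is masked missing
#' at random. The returned latent path extends 30 s before scan start so
#' lagged coupling is defined from the first volume.
#'
#' @param cfg a [sim_config()].
#' @param subject subject index (1-based).
#' @param condition condition name (must appear in `cfg$duration_s`).
#' @return List with `bpm` (a [bpm_series()] with missing samples) and
#'   `latent` (list `time_s`, `values` on a dense 1 Hz grid from -30 s).
#' @export
simulate_hr <- function(cfg, subject, condition) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!condition %in% names(cfg$duration_s))
    stop("unknown condition: ", condition)
  dur <- cfg$duration_s[[condition]]
  base <- with_seed(sim_seed(cfg$seed, subject, "baseline", 1L),
                    stats::rnorm(1, cfg$hr_base_bpm, cfg$hr_base_sd))
  off <- if (condition %in% names(cfg$hr_cond_offset))
    cfg$hr_cond_offset[[condition]] else 0
  pad <- 30L
  with_seed(sim_seed(cfg$seed, subject, condition, 2L), {
    t_lat <- seq(-pad, dur - 1)
    n_lat <- length(t_lat)
    period <- stats::runif(1, 60, 180)
    phase <- stats::runif(1, 0, 2 * pi)
    drift <- cfg$hr_drift_amp * sin(2 * pi * t_lat / period + phase)
    ar <- numeric(n_lat)
    if (cfg$hr_noise_sd > 0) {
      innov <- stats::rnorm(n_lat, 0, cfg$hr_noise_sd)
      ar[1] <- innov[1] / sqrt(1 - cfg$hr_ar_coef^2)
      for (i in 2:n_lat) ar[i] <- cfg$hr_ar_coef * ar[i - 1] + innov[i]
    }
    latent <- base + off + drift + ar
    obs_idx <- which(t_lat >= 0)
    bpm_vals <- latent[obs_idx]
    n_obs <- length(bpm_vals)
    miss <- rep(FALSE, n_obs)
    n_miss <- floor(cfg$missing_frac * n_obs)
    if (n_miss > 0)
      miss[sample(2:(n_obs - 1), n_miss)] <- TRUE
    list(bpm = bpm_series(t_lat[obs_idx],
                          ifelse(miss, NA_real_, bpm_vals),
                          missing = miss),
         latent = list(time_s = t_lat, values = latent))
  })
}

# z-scored latent heart rate evaluated at the TR grid minus the lag
lagged_zhr <- function(cfg, latent, n_vols) {
  tk <- (seq_len(n_vols) - 1) * cfg$tr_s - cfg$coupling_lag_s
  v <- stats::approx(latent$time_s, latent$values, xout = tk, rule = 2)$y
  zscore(v)
}

#' Simulate one ROI's BOLD series coupled to lagged heart rate
#'
#' `y(t) = beta * zHR(t - lag) + drift + noise` on the TR grid, with
#' Legendre drift and white noise. With the coupling in standardized units
#' the population correlation between `y` (after drift removal) and the
#' lagged z-scored heart rate is `beta / sqrt(beta^2 + noise_sd^2)`.
#'
#' @param cfg a [sim_config()].
#' @param latent latent heart-rate path from [simulate_hr()].
#' @param condition condition name (selects the coupling strength unless
#'   `beta` is given).
#' @param n_vols number of volumes; default covers the condition duration.
#' @param beta optional coupling override.
#' @param seed optional RNG seed for the noise stream.
#' @return Numeric vector of length `n_vols` (raw, undetrended).
#' @export
simulate_roi_bold <- function(cfg, latent, condition, n_vols = NULL,
                              beta = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(n_vols))
    n_vols <- round(cfg$duration_s[[condition]] / cfg$tr_s)
  if (is.null(beta))
    beta <- if (condition %in% names(cfg$activity_coupling))
      cfg$activity_coupling[[condition]] else 0
  z <- lagged_zhr(cfg, latent, n_vols)
  gen <- function() {
    drift <- if (cfg$drift_order >= 1 && cfg$drift_sd > 0) {
      B <- legendre_basis(n_vols, cfg$drift_order)[, -1, drop = FALSE]
      as.numeric(B %*% stats::rnorm(ncol(B), 0, cfg$drift_sd))
    } else 0
    beta * z + drift + stats::rnorm(n_vols, 0, cfg$noise_sd)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate an ROI pair with heart-rate-modulated connectivity
#'
#' A shared standard-normal latent enters both series with gain
#' `g(t) = clip(a + b * zHR(t - lag), 0, g_max)`; each series adds
#' independent unit-variance noise. Larger `b` yields stronger positive
#' coherence between the pair's windowed correlation and lagged heart
#' rate; `b < 0` reverses the sign.
#'
#' @param cfg a [sim_config()].
#' @param latent latent heart-rate path from [simulate_hr()].
#' @param condition condition name.
#' @param b gain-modulation slope; default from
#'   `cfg$connectivity_coupling[[edge]]`.
#' @param edge edge label used to look up `b`.
#' @param n_vols number of volumes; default covers the condition.
#' @param seed optional RNG seed.
#' @return List with numeric vectors `x`, `y` and the gain path `g`.
#' @export
simulate_coupled_edge <- function(cfg, latent, condition, b = NULL,
                                  edge = names(cfg$connectivity_coupling)[1],
                                  n_vols = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(n_vols))
    n_vols <- round(cfg$duration_s[[condition]] / cfg$tr_s)
  if (is.null(b)) {
    bc <- cfg$connectivity_coupling[[edge]]
    b <- if (!is.null(bc) && condition %in% names(bc)) bc[[condition]] else 0
  }
  z <- lagged_zhr(cfg, latent, n_vols)
  g <- pmin(pmax(cfg$edge_gain_base + b * z, 0), cfg$edge_gain_max)
  gen <- function() {
    s <- stats::rnorm(n_vols)
    list(x = g * s + stats::rnorm(n_vols),
         y = g * s + stats::rnorm(n_vols),
         g = g)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate a small 4D volume with a coupled blob
#'
#' A contiguous blob of voxels carries a shared heart-rate-coupled signal
#' (coupling lag `blob_lag_s`, strength `blob_beta`) plus per-voxel noise;
#' background voxels carry drift plus noise only.
#'
#' @param cfg a [sim_config()].
#' @param latent latent heart-rate path from [simulate_hr()].
#' @param condition condition name.
#' @param dim spatial grid (default 12 x 12 x 12).
#' @param blob_lag_s lag of the blob signal behind heart rate (default
#'   the config's coupling lag).
#' @param blob_beta standardized blob coupling strength.
#' @param noise_sd per-voxel noise sd (default the config's).
#' @param n_vols number of volumes; default covers the condition.
#' @param voxel_size_mm voxel size (default 2.5 mm isotropic).
#' @param seed optional RNG seed.
#' @return List with `vol` (a [volume4d()]) and `blob` (a [roi_mask()]).
#' @export
simulate_volume <- function(cfg, latent, condition, dim = c(12L, 12L, 12L),
                            blob_lag_s = NULL, blob_beta = 0.8,
                            noise_sd = NULL, n_vols = NULL,
                            voxel_size_mm = c(2.5, 2.5, 2.5),
                            seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(n_vols))
    n_vols <- round(cfg$duration_s[[condition]] / cfg$tr_s)
  if (is.null(blob_lag_s)) blob_lag_s <- cfg$coupling_lag_s
  if (is.null(noise_sd)) noise_sd <- cfg$noise_sd
  tk <- (seq_len(n_vols) - 1) * cfg$tr_s - blob_lag_s
  zb <- zscore(stats::approx(latent$time_s, latent$values, xout = tk,
                             rule = 2)$y)
  ctr <- pmax(1L, round(dim / 2) - 1L)
  blob <- array(FALSE, dim)
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, ctr[a] - 1L); hi <- min(dim[a], ctr[a] + 2L)
    lo:hi
  })
  blob[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  nvox <- prod(dim)
  gen <- function() {
    B <- if (cfg$drift_order >= 1 && cfg$drift_sd > 0)
      legendre_basis(n_vols, cfg$drift_order)[, -1, drop = FALSE]
    else NULL
    M <- matrix(stats::rnorm(nvox * n_vols, 0, noise_sd), nvox, n_vols)
    if (!is.null(B)) {
      coefs <- matrix(stats::rnorm(nvox * ncol(B), 0, cfg$drift_sd),
                      nvox, ncol(B))
      M <- M + coefs %*% t(B)
    }
    bi <- which(blob)
    M[bi, ] <- M[bi, ] + rep(1, length(bi)) %o% (blob_beta * zb)
    aperm(array(t(M), dim = c(n_vols, dim)), c(2, 3, 4, 1))
  }
  data4 <- if (is.null(seed)) gen() else with_seed(seed, gen())
  aff <- diag(c(voxel_size_mm, 1))
  list(vol = volume4d(data4, voxel_size_mm = voxel_size_mm,
                      affine = aff, tr_s = cfg$tr_s),
       blob = roi_mask(blob, label = "blob", affine = aff))
}

#' Simulate a full multi-subject study
#'
#' For every subject and condition: a heart-rate series with missing
#' samples, and the ten ROI raw BOLD series (activity coupling on every
#' ROI plus gain-modulated shared latents on the configured edges). Fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param rois ROI labels (default [roi_labels()]).
#' @return A list of class `sim_study`: `config`, `rois`, and `subjects`
#'   (per subject, per condition: `bpm`, `latent`, `rois` matrix
#'   `n_vols x n_rois`, `n_vols`).
#' @export
simulate_study <- function(cfg, rois = roi_labels()) {
  stopifnot(inherits(cfg, "sim_config"))
  edges <- names(cfg$connectivity_coupling)
  for (e in edges) {
    ends <- strsplit(e, "-", fixed = TRUE)[[1]]
    if (length(ends) != 2L || !all(ends %in% rois))
      stop("connectivity_coupling edge not formed from ROI labels: ", e)
  }
  subjects <- vector("list", cfg$n_subjects)
  names(subjects) <- sprintf("sub-%02d", seq_len(cfg$n_subjects))
  for (s in seq_len(cfg$n_subjects)) {
    conds <- vector("list", length(cfg$duration_s))
    names(conds) <- names(cfg$duration_s)
    for (cond in names(cfg$duration_s)) {
      hr <- simulate_hr(cfg, s, cond)
      n_vols <- round(cfg$duration_s[[cond]] / cfg$tr_s)
      R <- matrix(0, n_vols, length(rois), dimnames = list(NULL, rois))
      for (ri in seq_along(rois)) {
        R[, ri] <- simulate_roi_bold(
          cfg, hr$latent, cond, n_vols = n_vols,
          seed = sim_seed(cfg$seed, s, cond, 100L + ri))
      }
      for (ei in seq_along(edges)) {
        ends <- strsplit(edges[ei], "-", fixed = TRUE)[[1]]
        ce <- simulate_coupled_edge(
          cfg, hr$latent, cond, edge = edges[ei], n_vols = n_vols,
          seed = sim_seed(cfg$seed, s, cond, 500L + ei))
        R[, ends[1]] <- R[, ends[1]] + ce$x
        R[, ends[2]] <- R[, ends[2]] + ce$y
      }
      conds[[cond]] <- list(bpm = hr$bpm, latent = hr$latent, rois = R,
                            n_vols = n_vols)
    }
    subjects[[s]] <- list(conditions = conds)
  }
  structure(list(config = cfg, rois = rois, subjects = subjects),
            class = "sim_study")
}

#' Write a simulated study to disk
#'
#' Per subject and condition: a BPM table (`<sub>_<cond>_bpm.tsv`) and an
#' ROI table (`<sub>_<cond>_rois.tsv`, one named column per ROI), plus a
#' `manifest.yaml` snapshot of the design (subjects, conditions, TR,
#' volume counts, coupling truth, seed).
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- study$config
  for (sub in names(study$subjects)) {
    for (cond in names(study$subjects[[sub]]$conditions)) {
      sc <- study$subjects[[sub]]$conditions[[cond]]
      write_bpm(sc$bpm, file.path(dir, sprintf("%s_%s_bpm.tsv", sub, cond)))
      utils::write.table(as.data.frame(sc$rois),
                         file.path(dir, sprintf("%s_%s_rois.tsv", sub, cond)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  manifest <- list(
    subjects = names(study$subjects),
    conditions = names(cfg$duration_s),
    tr_s = cfg$tr_s,
    n_vols = as.list(stats::setNames(
      as.integer(round(cfg$duration_s / cfg$tr_s)), names(cfg$duration_s))),
    rois = study$rois,
    coupling_lag_s = cfg$coupling_lag_s,
    activity_coupling = as.list(cfg$activity_coupling),
    connectivity_coupling = lapply(cfg$connectivity_coupling, as.list),
    seed = cfg$seed)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
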