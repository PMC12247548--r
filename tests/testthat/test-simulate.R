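test_that("heart-rate simulation is seed-deterministic with controlled degeneracies", {
  cfg <- sim_config(seed = 5)
  a <- simulate_hr(cfg, 3, "suspense")
  b <- simulate_hr(cfg, 3, "suspense")
  expect_identical(a$bpm$bpm, b$bpm$bpm)
  expect_identical(a$latent$values, b$latent$values)
  expect_identical(a$bpm$missing, b$bpm$missing)
  c_ <- simulate_hr(cfg, 4, "suspense")
  expect_false(identical(a$bpm$bpm, c_$bpm$bpm))

  # missing_frac = 0 -> nothing masked; first/last never masked otherwise
  cfg0 <- sim_config(missing_frac = 0, seed = 5)
  expect_false(any(simulate_hr(cfg0, 1, "control")$bpm$missing))
  cfgm <- sim_config(missing_frac = 0.3, seed = 5)
  mm <- simulate_hr(cfgm, 1, "control")$bpm$missing
  expect_equal(sum(mm), floor(0.3 * 330))
  expect_false(mm[1]); expect_false(mm[length(mm)])

  # no noise, no drift -> constant at baseline + offset
  cfgc <- sim_config(hr_noise_sd = 0, hr_drift_amp = 0, missing_frac = 0,
                     seed = 5)
  flat <- simulate_hr(cfgc, 2, "rest")
  expect_equal(length(unique(round(flat$bpm$bpm, 9))), 1L)

  expect_error(simulate_hr(cfg, 1, "nonexistent"), "unknown condition")
  expect_error(sim_config(missing_frac = 0.6), "missing_frac")
  expect_error(sim_config(hr_ar_coef = 1.2), "hr_ar_coef")
})

test_that("ROI coupling follows the closed-form correlation beta/sqrt(beta^2+sigma^2)", {
  cfg <- sim_config(seed = 8, drift_order = 3)
  # null coupling: |r| small for long series
  hr <- simulate_hr(cfg, 1, "suspense")
  y0 <- simulate_roi_bold(cfg, hr$latent, "suspense", n_vols = 600,
                          beta = 0, seed = 1)
  tk <- (0:599) * 0.7 - 6
  zl <- zscore(approx(hr$latent$time_s, hr$latent$values, xout = tk,
                      rule = 2)$y)
  expect_lt(abs(cor(legendre_detrend(y0, 3), zl)), 0.2)
  # near-noiseless limit -> r ~ 1
  cfg_q <- sim_config(seed = 8, noise_sd = 1e-6, drift_order = 0)
  y1 <- simulate_roi_bold(cfg_q, hr$latent, "suspense", n_vols = 600,
                          beta = 1, seed = 2)
  expect_gt(cor(y1, zl), 0.999)

  # Monte-Carlo against r = beta / sqrt(beta^2 + sigma^2) = 0.45, through
  # the full drift + detrending chain (detrending also removes the slow
  # part of the coupled signal, so the recovery is mildly attenuated)
  beta <- 0.5
  sigma <- beta * sqrt(1 / 0.45^2 - 1)
  cfg_mc <- sim_config(seed = 8, noise_sd = sigma, drift_order = 3)
  rs <- vapply(1:200, function(i) {
    y <- simulate_roi_bold(cfg_mc, hr$latent, "suspense", n_vols = 600,
                           beta = beta, seed = 1000 + i)
    cor(legendre_detrend(y, 3), zl)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.45), 0.05)
  # pure analytic control (no drift, no detrending): 1% precision
  cfg_p <- sim_config(seed = 8, noise_sd = sigma, drift_order = 0)
  rs2 <- vapply(1:200, function(i) {
    y <- simulate_roi_bold(cfg_p, hr$latent, "suspense", n_vols = 600,
                           beta = beta, seed = 4000 + i)
    cor(y, zl)
  }, numeric(1))
  expect_lt(abs(mean(rs2) - 0.45), 0.01 + 3 * sd(rs2) / sqrt(length(rs2)))
})

test_that("gain-modulated edges produce sign-symmetric coherence and b = 0 is null", {
  cfg <- sim_config(seed = 9)
  hr <- simulate_hr(cfg, 1, "control")
  n <- 471
  # b = 0: windowed correlation uncorrelated with lagged HR
  ce0 <- simulate_coupled_edge(cfg, hr$latent, "control", b = 0,
                               n_vols = n, seed = 3)
  es0 <- edge_timeseries(zscore(ce0$x), zscore(ce0$y), window_trs = 29,
                         tr_s = 0.7, znorm = FALSE)
  h <- prep_hr(hr$bpm, 0.7, n, lag_s = 6)
  expect_lt(abs(cor(es0$values, h$values)), 0.25)
  # b > 0 vs b < 0 with the same latent noise: opposite-signed coherence
  cp <- simulate_coupled_edge(cfg, hr$latent, "control", b = 0.5,
                              n_vols = n, seed = 4)
  cm <- simulate_coupled_edge(cfg, hr$latent, "control", b = -0.5,
                              n_vols = n, seed = 4)
  esp <- edge_timeseries(zscore(cp$x), zscore(cp$y), window_trs = 29,
                         tr_s = 0.7, znorm = FALSE)
  esm <- edge_timeseries(zscore(cm$x), zscore(cm$y), window_trs = 29,
                         tr_s = 0.7, znorm = FALSE)
  expect_gt(cor(esp$values, h$values), 0.1)
  expect_lt(cor(esm$values, h$values), -0.1)
  # gain path respects the clip
  expect_true(all(cp$g >= 0 & cp$g <= cfg$edge_gain_max))
})

test_that("volume simulation is byte-identical under a fixed seed with the blob coupled", {
  cfg <- sim_config(seed = 10, missing_frac = 0)
  hr <- simulate_hr(cfg, 1, "control")
  s1 <- simulate_volume(cfg, hr$latent, "control", dim = c(8, 8, 8),
                        n_vols = 150, seed = 42)
  s2 <- simulate_volume(cfg, hr$latent, "control", dim = c(8, 8, 8),
                        n_vols = 150, seed = 42)
  expect_identical(s1$vol$data, s2$vol$data)
  expect_s3_class(s1$blob, "roi_mask")
  expect_gt(sum(s1$blob$data), 8)
  # blob voxels share the coupled signal; background does not
  blob_mean <- extract_roi_mean(s1$vol, s1$blob)
  tk <- (0:149) * 0.7 - cfg$coupling_lag_s
  zl <- zscore(approx(hr$latent$time_s, hr$latent$values, xout = tk,
                      rule = 2)$y)
  expect_gt(cor(legendre_detrend(blob_mean$values, 3), zl), 0.5)
})

test_that("a full simulated study is reproducible and writes a loadable dataset", {
  cfg <- sim_config(n_subjects = 2, seed = 12,
                    duration_s = c(suspense = 70, control = 63))
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1$subjects[["sub-02"]]$conditions$control$rois,
                   st2$subjects[["sub-02"]]$conditions$control$rois)
  expect_equal(names(st1$subjects), c("sub-01", "sub-02"))
  expect_equal(dim(st1$subjects[["sub-01"]]$conditions$suspense$rois),
               c(100, 10))

  dir <- withr::local_tempdir()
  write_sim_dataset(st1, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  expect_true(file.exists(file.path(dir, "sub-01_suspense_bpm.tsv")))
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$subjects, c("sub-01", "sub-02"))
  expect_equal(man$n_vols$control, 90)
  back <- read_bpm(file.path(dir, "sub-01_suspense_bpm.tsv"))
  expect_equal(sum(back$missing),
               sum(st1$subjects[["sub-01"]]$conditions$suspense$bpm$missing))
})
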