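test_that("condition-length matching drops the head of the longer series", {
  a <- 1:686; b <- 1:471
  m <- match_condition_lengths(a, b)
  expect_length(m$a, 471)
  expect_equal(m$a, 216:686)  # first 215 samples dropped
  expect_equal(m$b, b)
  m2 <- match_condition_lengths(1:5, 1:5)
  expect_equal(m2$a, 1:5); expect_equal(m2$b, 1:5)
  m3 <- match_condition_lengths(1:10, 3)
  expect_length(m3$a, 1); expect_equal(m3$b, 3)
})

test_that("bivariate coherence is the Fisher z of the Pearson correlation", {
  set.seed(11)
  h <- hr_trace(rand_z(100), 0.7, applied_lag_s = 6, z_normalized = TRUE)
  # identical series: clipped z ~ 8.05
  r <- bivariate_coherence(h, h$values, "s1", "control", target = "self")
  expect_equal(r$value, atanh(1 - 1e-7), tolerance = 1e-6)
  # orthogonal by construction
  x <- rand_z(100)
  x_perp <- zscore(residualize(x, cbind(1, h$values)))
  r0 <- bivariate_coherence(h, x_perp, "s1", "control", target = "orth")
  expect_lt(abs(r0$value), 1e-10)
  # closed form: r = 0.5 -> z = 0.5493
  y <- h$values * 0.5 + sqrt(1 - 0.25) * x_perp
  robs <- cor(h$values, y)
  rec <- bivariate_coherence(h, y, "s1", "control", target = "mix")
  expect_equal(rec$value, atanh(robs), tolerance = 1e-12)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  # affine rescaling of the neural input leaves the value unchanged
  rec2 <- bivariate_coherence(h, 5 * y + 2, "s1", "control", target = "mix")
  expect_equal(rec2$value, rec$value, tolerance = 1e-12)
  expect_error(bivariate_coherence(h, rep(1, 100)), "constant")
})

test_that("banded DTW matches hand-computed dynamic programming tables", {
  expect_equal(dtw_distance(c(0, 0, 1), c(0, 1, 1), band_trs = 1), 0)
  expect_equal(dtw_distance(c(0, 0, 1), c(0, 1, 1), band_trs = 2), 0)
  expect_equal(dtw_distance(c(0, 1), c(1, 0), band_trs = 0), sqrt(2))
  expect_equal(dtw_distance(c(0, 1), c(1, 0), band_trs = 5), sqrt(2))
  x <- rand_z(30)
  expect_equal(dtw_distance(x, x, band_trs = 3), 0)
})

test_that("banded DTW equals the recursive oracle and is symmetric and band-monotone", {
  set.seed(12)
  for (rep in 1:40) {
    n <- sample(3:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    # non-binding band -> oracle equality
    expect_equal(dtw_distance(a, b, band_trs = n), dtw_reference(a, b),
                 tolerance = 1e-12)
    expect_equal(dtw_distance(a, b, band_trs = Inf), dtw_reference(a, b),
                 tolerance = 1e-12)
    # symmetry
    expect_equal(dtw_distance(a, b, band_trs = 2),
                 dtw_distance(b, a, band_trs = 2), tolerance = 1e-12)
    # widening the band never increases the distance
    ds <- vapply(0:n, function(w) dtw_distance(a, b, band_trs = w),
                 numeric(1))
    expect_true(all(diff(ds) <= 1e-12))
    # zero iff identical
    expect_gt(dtw_distance(a, a + 0.5, band_trs = n), 0)
  }
})

test_that("dtw_coherence records the band-constrained distance per condition", {
  set.seed(13)
  h <- hr_trace(rand_z(100), 0.7, applied_lag_s = 6, z_normalized = TRUE)
  x <- rand_z(120)
  m <- match_condition_lengths(h$values, x)
  rec <- dtw_coherence(m$a, m$b, band_trs = 14, subject = "s1",
                       condition = "suspense", target = "dmPFC")
  expect_equal(rec$measure, "dtw_distance")
  expect_gte(rec$value, 0)
  expect_equal(rec$n_timepoints_used, 100L)
  expect_error(dtw_coherence(h, x), "lengths differ")
})

test_that("the cross-correlation maximum recovers self-delays and known lags", {
  set.seed(14)
  n <- 400
  h <- hr_trace(rand_z(n), 0.7, z_normalized = TRUE)
  # neural = hr delayed by 7 TRs
  delayed <- c(rep(0, 7), h$values[1:(n - 7)])
  rec <- xcorr_max(h, delayed, max_lag_trs = 20)
  expect_equal(rec$lag_s_at_max, 7 * 0.7, tolerance = 1e-9)
  expect_gt(tanh(rec$value), 0.95)
  # with a lag offset the reported lag is relative to the offset trace
  rec2 <- xcorr_max(h, delayed, max_lag_trs = 20, lag_offset_s = 2 * 0.7)
  expect_equal(rec2$lag_s_at_max, 5 * 0.7, tolerance = 1e-9)
  # anti-correlated on the only searched delay -> flagged zero
  h2 <- hr_trace(rand_z(60), 0.7)
  rec3 <- xcorr_max(h2, -h2$values, max_lag_trs = 0, min_overlap = 30)
  expect_equal(rec3$value, 0)
  expect_equal(rec3$flag, "no positive peak")
  # overlap guard
  expect_error(xcorr_max(h, delayed, max_lag_trs = 5, min_overlap = 500),
               "overlap")
})

test_that("the grid maximum dominates the bivariate correlation at the nominal lag", {
  set.seed(15)
  cfg <- sim_config(seed = 21)
  hr <- simulate_hr(cfg, 1, "control")
  n <- 471
  h <- prep_hr(hr$bpm, 0.7, n, lag_s = 6)
  y <- simulate_roi_bold(cfg, hr$latent, "control", n_vols = n, beta = 0.5,
                         seed = 77)
  ns <- neural_series(zscore(legendre_detrend(y, 3)), 0.7, "roi", TRUE)
  biv <- bivariate_coherence(h, ns, target = "roi")
  # advance the HR by a whole number of TRs so the bivariate alignment
  # sits exactly on the non-negative search grid (at delay k)
  k <- 14L
  hx <- cardiocohere:::advance_trace_trs(h, k)
  xc <- xcorr_max(hx, ns, max_lag_trs = 30, lag_offset_s = k * 0.7)
  expect_gte(xc$value, biv$value - 0.05)  # grid value drops k overlap samples
  # and the advanced-grid correlation at delay k equals the bivariate r on
  # the unpadded overlap
  n <- length(h$values)
  expect_equal(cor(hx$values[seq_len(n - k)], ns$values[(k + 1):n]),
               cor(h$values[(k + 1):n], ns$values[(k + 1):n]),
               tolerance = 1e-12)
})

test_that("lag maps are deterministic and flat where there is no signal", {
  cfg <- sim_config(seed = 31, drift_order = 0, missing_frac = 0,
                    duration_s = c(control = 240), noise_sd = 0.3,
                    hr_cond_offset = c(control = 0))
  hr <- simulate_hr(cfg, 1, "control")
  n_vols <- round(240 / 0.7)
  sim <- simulate_volume(cfg, hr$latent, "control", dim = c(6, 6, 6),
                         blob_beta = 1.5, n_vols = n_vols,
                         blob_lag_s = 6, seed = 99)
  h <- prep_hr(hr$bpm, 0.7, n_vols, lag_s = 0)
  lm1 <- lag_map(sim$vol, h, max_lag_trs = 23)
  lm2 <- lag_map(sim$vol, h, max_lag_trs = 23)
  expect_identical(lm1$z, lm2$z)
  expect_identical(lm1$lag_s, lm2$lag_s)
  # blob voxels carry elevated coherence relative to background
  blob_z <- lm1$z[sim$blob$data]
  bg_z <- lm1$z[!sim$blob$data]
  expect_gt(min(blob_z), max(0, stats::quantile(bg_z, 0.5)))
  expect_gt(mean(blob_z), mean(bg_z) + 0.5)
  # blob argmax lag near the injected 6 s
  expect_lt(abs(median(lm1$lag_s[sim$blob$data]) - 6), 0.7 + 1e-9)
})
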