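test_that("the paired t statistic matches hand values and the stats oracle", {
  # symmetric differences -> t = 0, p = 1
  r <- paired_t(c(1, -1, 2, -2))
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  # hand computation: mean 4, sd 2, t = 4 / (2 / sqrt(3))
  r <- paired_t(c(2, 4, 6))
  expect_equal(r$t, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2L)
  expect_equal(r$d, 2)
  # df convention
  expect_equal(paired_t(rnorm(29))$df, 28L)
  # random-input equivalence with stats::t.test to 1e-10
  set.seed(17)
  for (rep in 1:25) {
    d <- rnorm(sample(3:40, 1))
    mine <- paired_t(d)
    ref <- t.test(d)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(paired_t(c(1, 1, 1)), "zero-variance")
  expect_error(paired_t(c(1, 2)), "at least 3")
})

test_that("Bonferroni families reproduce the design's corrected levels", {
  expect_equal(bonferroni(5), 0.01)
  expect_equal(bonferroni(55), 0.05 / 55)
  expect_equal(floor(bonferroni(55) * 1e4) / 1e4, 0.0009)
  expect_equal(bonferroni(1), 0.05)
})

test_that("contrast tables assign families, exclude incomplete subjects, and flag degenerates", {
  set.seed(18)
  mk_rec <- function(sub, cond, target, type, value)
    data.frame(subject = sub, condition = cond, target = target,
               target_type = type, measure = "bivariate_z", value = value,
               lag_s_at_max = NA_real_, n_timepoints_used = 100L,
               flag = "", stringsAsFactors = FALSE)
  recs <- do.call(rbind, c(
    lapply(1:10, function(s) mk_rec(s, "suspense", "amygdala_R", "roi",
                                    rnorm(1, -0.2))),
    lapply(1:10, function(s) mk_rec(s, "control", "amygdala_R", "roi",
                                    rnorm(1, 0.2))),
    lapply(1:10, function(s) mk_rec(s, "suspense", "PAG", "roi", rnorm(1))),
    lapply(1:10, function(s) mk_rec(s, "control", "PAG", "roi", rnorm(1))),
    lapply(1:9, function(s) mk_rec(s, "suspense", "amygdala_R-dmPFC",
                                   "edge", rnorm(1))),
    lapply(1:10, function(s) mk_rec(s, "control", "amygdala_R-dmPFC",
                                    "edge", rnorm(1)))))
  g <- contrast_table(recs, c("suspense", "control"),
                      exploratory_family_size = 55)
  expect_equal(nrow(g), 3L)
  amy <- g[g$target == "amygdala_R", ]
  expect_equal(amy$family, "hypothesis")
  expect_equal(amy$alpha_corrected, 0.01)
  pag <- g[g$target == "PAG", ]
  expect_equal(pag$family, "exploratory")
  expect_equal(pag$alpha_corrected, 0.05 / 55)
  edge <- g[g$target == "amygdala_R-dmPFC", ]
  expect_equal(edge$family, "exploratory")
  expect_equal(edge$n, 9L)         # listwise exclusion of subject 10
  expect_equal(edge$n_excluded, 1L)
  expect_true(all(g$df == g$n - 1L))
  expect_true(all(!g$significant_corrected |
                    g$p_two_tailed < g$alpha_corrected))

  # identical condition records -> zero-variance target dropped with warning
  recs2 <- rbind(
    do.call(rbind, lapply(1:5, function(s)
      mk_rec(s, "suspense", "vmPFC", "roi", 1))),
    do.call(rbind, lapply(1:5, function(s)
      mk_rec(s, "control", "vmPFC", "roi", 1))),
    recs)
  expect_warning(g2 <- contrast_table(recs2, c("suspense", "control")),
                 "zero-variance")
  expect_false("vmPFC" %in% g2$target)

  expect_error(contrast_table(recs[recs$subject <= 2, ],
                              c("suspense", "control")), "3 complete")
})

test_that("cluster labelling respects the requested connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE  # touch only at an edge
  lab1 <- label_clusters(m, 1)
  expect_equal(attr(lab1, "n"), 2L)
  lab2 <- label_clusters(m, 2)
  expect_equal(attr(lab2, "n"), 1L)
  m2 <- array(FALSE, c(4, 4, 4)); m2[1:2, 1, 1] <- TRUE; m2[4, 4, 4] <- TRUE
  lab <- label_clusters(m2, 1)
  expect_equal(attr(lab, "n"), 2L)
  expect_equal(sort(tabulate(lab[lab > 0])), c(1L, 2L))
})

test_that("cluster correction is deterministic, sign-symmetric, and recovers a strong blob", {
  set.seed(19)
  n_sub <- 12; d3 <- c(8, 8, 8)
  diffs <- array(rnorm(prod(d3) * n_sub), c(d3, n_sub))
  # inject a strong blob effect
  diffs[3:5, 3:5, 3:5, ] <- diffs[3:5, 3:5, 3:5, ] + 2
  cr1 <- cluster_correct(diffs, voxel_p = 0.001, alpha = 0.05,
                         n_perms = 500, seed = 7)
  cr2 <- cluster_correct(diffs, voxel_p = 0.001, alpha = 0.05,
                         n_perms = 500, seed = 7)
  expect_identical(cr1$extent_threshold, cr2$extent_threshold)
  expect_identical(cr1$clusters, cr2$clusters)
  expect_gte(nrow(cr1$clusters), 1L)
  # peak voxel lies inside the blob (identity affine -> 0-based mm coords)
  pk <- unlist(cr1$clusters[which.max(cr1$clusters$extent),
                            c("peak_x_mm", "peak_y_mm", "peak_z_mm")])
  expect_true(all(pk >= 2 & pk <= 4))
  expect_true(all(cr1$clusters$p_corrected <= 0.05 + 1e-12))

  # negating every difference map preserves t magnitudes and extents
  cr_neg <- cluster_correct(-diffs, voxel_p = 0.001, alpha = 0.05,
                            n_perms = 500, seed = 7)
  expect_equal(cr_neg$t_map, -cr1$t_map, tolerance = 1e-12)
  expect_equal(cr_neg$clusters$extent, cr1$clusters$extent)
  expect_identical(cr_neg$null_max_extents, cr1$null_max_extents)

  # extent threshold is monotone in alpha and in voxel_p strictness
  cr_a <- cluster_correct(diffs, voxel_p = 0.001, alpha = 0.2,
                          n_perms = 500, seed = 7)
  expect_lte(cr_a$extent_threshold, cr1$extent_threshold)
  cr_p <- cluster_correct(diffs, voxel_p = 0.01, alpha = 0.05,
                          n_perms = 500, seed = 7)
  expect_gte(cr_p$extent_threshold, cr1$extent_threshold)

  # exhaustive enumeration kicks in when 2^n <= n_perms
  small <- array(rnorm(6^3 * 9), c(6, 6, 6, 9))
  cr_ex <- cluster_correct(small, n_perms = 512, seed = 1)
  expect_true(cr_ex$exhaustive)
  expect_equal(cr_ex$n_perms_used, 512L)
  expect_error(cluster_correct(diffs, n_perms = 100), "500")
  expect_error(cluster_correct(diffs[, , , 1:5, drop = FALSE],
                               n_perms = 500), "8 subjects")
})
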