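# Independent reference implementations used as oracles.

# Unconstrained DTW by memoized recursion (squared local cost, symmetric
# steps, anchored endpoints) -- deliberately independent of the package's
# banded dynamic-programming kernel.
dtw_reference <- function(a, b) {
  n <- length(a); m <- length(b)
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return((a[1] - b[1])^2)
    if (i < 1 || j < 1) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- (a[i] - b[j])^2 + min(
      if (i > 1 && j > 1) rec(i - 1, j - 1) else Inf,
      if (i > 1) rec(i - 1, j) else Inf,
      if (j > 1) rec(i, j - 1) else Inf)
    memo[i, j] <<- v
    v
  }
  sqrt(rec(n, m))
}

# every ternary ({-1,0,1}) series of a given length, as a matrix (rows)
ternary_series <- function(len) {
  as.matrix(expand.grid(rep(list(c(-1, 0, 1)), len)))
}

# quick uniform z-scored test series
rand_z <- function(n) as.numeric(scale(stats::rnorm(n)))

# tiny two-condition simulation of the coupled-edge contrast used by
# several tests: returns per-subject bivariate coherence differences
edge_contrast_diffs <- function(cfg, n_sub, b_by_cond, seed_salt = 0L) {
  conds <- names(cfg$duration_s)
  vapply(seq_len(n_sub), function(s) {
    zs <- vapply(conds, function(cond) {
      hr <- simulate_hr(cfg, s, cond)
      nv <- round(cfg$duration_s[[cond]] / cfg$tr_s)
      ce <- simulate_coupled_edge(
        cfg, hr$latent, cond, b = b_by_cond[[cond]], n_vols = nv,
        seed = cardiocohere:::sim_seed(cfg$seed, s, cond, 900L + seed_salt))
      ord <- auto_polort_order(nv * cfg$tr_s)
      es <- edge_timeseries(
        neural_series(zscore(legendre_detrend(ce$x, ord)), cfg$tr_s, "a", TRUE),
        neural_series(zscore(legendre_detrend(ce$y, ord)), cfg$tr_s, "b", TRUE))
      h <- prep_hr(hr$bpm, cfg$tr_s, nv, lag_s = 6)
      bivariate_coherence(h, es, s, cond, target_type = "edge")$value
    }, numeric(1))
    zs[[1]] - zs[[2]]
  }, numeric(1))
}
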