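grid_mid <- simulate_bin_grid(n_chrom = 6L, chrom_size = 1.5e8, seed = 5)

test_that("the fraction is recovered given the true copy-number states", {
  s <- sim_sample(0.4, grid_mid, seed = 100)
  prof <- normalize_counts(s$counts, grid_mid)
  tf_hat <- fit_fraction(prof, s$truth$copy_number, dispersion = 500)
  expect_lt(abs(tf_hat - 0.4), 0.05)
})

test_that("golden-section search agrees with a dense grid search", {
  s <- sim_sample(0.3, grid_mid, seed = 101)
  prof <- normalize_counts(s$counts, grid_mid)
  cn <- s$truth$copy_number
  tf_hat <- fit_fraction(prof, cn, dispersion = 500)
  incl <- !prof$excluded
  w <- prof$weight[incl]; x <- prof$count[incl]; cni <- cn[incl]
  ll <- vapply(seq(0, 1, by = 0.001), function(tf) {
    m <- (1 - tf) * 2 + tf * cni
    mu <- pmax(w * m / weighted.mean(m, w), 1e-8)
    sum(dnbinom(x, mu = mu, size = 500, log = TRUE))
  }, numeric(1))
  tf_grid <- seq(0, 1, by = 0.001)[which.max(ll)]
  expect_lt(abs(tf_hat - tf_grid), 1e-3)
})

test_that("an all-neutral path makes the fraction unidentifiable", {
  s <- sim_sample(0, grid_mid, seed = 102)
  prof <- normalize_counts(s$counts, grid_mid)
  expect_error(fit_fraction(prof, rep(2L, length(prof$ratio)), 500),
               "unidentifiable")
})

test_that("a noiseless diploid sample is reported not_detected with tf 0", {
  g <- toy_grid(n_chrom = 2L, n_bins = 300L, gc = NULL, seed = 2)
  mu <- 500 * pmax(0.6 + 2 * g$gc - 2.5 * g$gc^2, 0.05)
  bc <- bin_counts(round(mu / mean(mu) * 500))
  est <- estimate_ctdna(bc, g, estimate_config(seed = 1))
  expect_identical(est$status, "not_detected")
  expect_identical(est$tumor_fraction, 0)
})

test_that("null samples never report a positive fraction as not_detected", {
  for (s in 1:3) {
    sm <- sim_sample(0, grid_mid, seed = 200 + s)
    est <- estimate_ctdna(sm$counts, grid_mid, estimate_config(seed = s))
    expect_true(est$status %in% c("not_detected", "excluded_noise"))
    if (est$status == "not_detected") expect_identical(est$tumor_fraction, 0)
    expect_true(est$tumor_fraction >= 0 && est$tumor_fraction <= 1)
  }
})

test_that("moderate fractions are recovered end to end", {
  for (tf in c(0.2, 0.4)) {
    sm <- sim_sample(tf, grid_mid, seed = 300 + round(100 * tf))
    est <- estimate_ctdna(sm$counts, grid_mid, estimate_config(seed = 7))
    expect_lt(abs(est$tumor_fraction - tf), 0.05)
  }
  # an extensive alteration load must also pass the noise gate
  sm <- sim_sample(0.4, grid_mid, seed = 340)
  est <- estimate_ctdna(sm$counts, grid_mid, estimate_config(seed = 7))
  expect_identical(est$status, "detected")
})

test_that("the default-fraction pass is taken and logged for faint signals", {
  sm <- sim_sample(0.03, grid_mid, seed = 400)
  est <- estimate_ctdna(sm$counts, grid_mid, estimate_config(seed = 9))
  expect_true(est$fallback_used)
  expect_true(any(grepl("default_fraction", est$iteration_log$event)))
})

test_that("estimates are invariant to a global rescaling of counts", {
  sm <- sim_sample(0.3, grid_mid, seed = 500)
  cfg <- estimate_config(seed = 3)
  e1 <- estimate_ctdna(sm$counts, grid_mid, cfg)
  e2 <- estimate_ctdna(bin_counts(sm$counts$counts * 3L, "x3"), grid_mid, cfg)
  expect_identical(e1$status, e2$status)
  expect_lt(abs(e1$tumor_fraction - e2$tumor_fraction), 0.01)
})

test_that("repeated runs with the same config and seed are identical", {
  sm <- sim_sample(0.25, grid_mid, seed = 600)
  cfg <- estimate_config(seed = 5)
  e1 <- estimate_ctdna(sm$counts, grid_mid, cfg)
  e2 <- estimate_ctdna(sm$counts, grid_mid, cfg)
  expect_identical(e1$tumor_fraction, e2$tumor_fraction)
  expect_identical(e1$qc, e2$qc)
})

test_that("coordinate ascent never decreases the joint log-likelihood", {
  for (tf in c(0.15, 0.35)) {
    sm <- sim_sample(tf, grid_mid, seed = 700 + round(100 * tf))
    est <- estimate_ctdna(sm$counts, grid_mid, estimate_config(seed = 2))
    ll <- est$iteration_log$log_likelihood
    ev <- est$iteration_log$event
    keep <- ev == "refit" & !is.na(ll)
    # monotone within each ascent (an alias rescue starts a new ascent)
    runs <- split(ll[keep], cumsum(ev == "alias_rescue")[keep])
    for (r in runs) if (length(r) > 1) expect_true(all(diff(r) >= -1e-6))
  }
})

test_that("the status decision tree honours its invariants", {
  for (s in 1:4) {
    tf <- c(0, 0.1, 0.3, 0.5)[s]
    sm <- sim_sample(tf, grid_mid, seed = 800 + s)
    est <- estimate_ctdna(sm$counts, grid_mid, estimate_config(seed = s))
    if (est$status == "detected") {
      expect_lte(est$qc$ks_p, 0.05)
      expect_lt(est$qc$centromere_deletion_share, 0.5 + 1e-12)
      expect_true(any(est$states$state != 2L))
    }
    if (est$status == "not_detected") expect_identical(est$tumor_fraction, 0)
  }
})
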