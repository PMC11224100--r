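grid6k <- simulate_bin_grid(n_chrom = 20L, chrom_size = 1.5e8, seed = 5)

test_that("a zero altered fraction gives an all-diploid profile", {
  tp <- simulate_cnv_profile(grid6k, tumor_fraction = 0,
                             altered_genome_fraction = 0, seed = 1)
  expect_true(all(tp$copy_number == 2L))
  expect_equal(nrow(tp$segments), 0L)
})

test_that("profiles are deterministic in the seed and reject bad targets", {
  a <- simulate_cnv_profile(grid6k, 0.3, seed = 11)
  b <- simulate_cnv_profile(grid6k, 0.3, seed = 11)
  expect_identical(a, b)
  expect_error(simulate_cnv_profile(grid6k, 0.3, altered_genome_fraction = 1),
               "must be < 1")
})

test_that("realized altered genome share is calibrated to its target", {
  shares <- vapply(1:100, function(s)
    mean(simulate_cnv_profile(grid6k, 0.3, altered_genome_fraction = 0.3,
                              seed = s)$copy_number != 2L), numeric(1))
  expect_lt(abs(mean(shares) - 0.3), 0.05)
})

test_that("copy_ratio implements the tumor/normal mixture arithmetic", {
  # tf = 0: no tumor signal, every ratio exactly 1
  expect_equal(copy_ratio(rep(2L, 50), 0), rep(1, 50))
  # one-copy loss at tf = 0.5 in a mostly diploid genome: raw ratio 0.75
  cn <- c(rep(2L, 999), 1L)
  r <- copy_ratio(cn, 0.5)
  expect_equal(r[1000], 0.75, tolerance = 1e-3)
  expect_error(copy_ratio(c(2L, -1L), 0.3), "non-negative")
})

test_that("simulated counts match negative-binomial moments", {
  g <- make_bin_grid(c(chr1 = 5e4 * 5e5))  # 50,000 bins
  g$gc <- rep(0.45, nrow(g))
  truth <- list(copy_number = rep(2L, nrow(g)), tumor_fraction = 0)
  mu <- 500; size <- 50
  bc <- simulate_cfdna_counts(g, truth, mean_depth_per_bin = mu,
                              gc_bias = c(1, 0, 0), dispersion = size,
                              seed = 99)
  expect_lt(abs(mean(bc$counts) / mu - 1), 0.02)
  expect_lt(abs(var(bc$counts) / (mu + mu^2 / size) - 1), 0.02)
})

test_that("a flat-bias tf = 0 simulation normalizes to median ratio 1", {
  truth <- simulate_cnv_profile(grid6k, 0, altered_genome_fraction = 0, seed = 2)
  bc <- simulate_cfdna_counts(grid6k, truth, gc_bias = c(1, 0, 0), seed = 3)
  prof <- normalize_counts(bc, grid6k)
  expect_lt(abs(median(prof$ratio[!prof$excluded]) - 1), 0.01)
})

test_that("cohort simulation honours its invariants and determinism", {
  expect_equal(nrow(simulate_cohort(0)), 0L)
  co <- simulate_cohort(400, seed = 21)
  expect_identical(co, simulate_cohort(400, seed = 21))
  expect_identical(co$pet_positive, co$psma_tv > 0)
  expect_identical(co$ctdna_detected, co$ctdna_conc > 0)
  expect_true(all(co$followup_months >= 0))
  expect_true(all(co$psa > 0))
  expect_identical(co$dominant_fraction == "none", !co$pet_positive)
})

test_that("the copula coupling reproduces the configured Spearman correlation", {
  prm <- cohort_params(pet_pos_prob = c(hsPC = 1, CRPC = 1),
                       ctdna_det_prob = c(hsPC = 1, CRPC = 1),
                       spearman_rho = 0.42)
  co <- simulate_cohort(5000, prm, seed = 31)
  # the copula couples the within-status severity scores; pooling statuses
  # with different marginals attenuates the pooled rank correlation
  for (st in c("hsPC", "CRPC")) {
    sel <- co$castration_status == st
    rho <- spearman_corr(co$ctdna_conc[sel], co$psma_tv[sel])$rho
    expect_lt(abs(rho - 0.42), 0.05)
  }
})

test_that("truth profiles serialize to BED plus JSON sidecar", {
  tp <- simulate_cnv_profile(grid6k, 0.3, seed = 4)
  bed <- withr::local_tempfile(fileext = ".bed")
  js <- withr::local_tempfile(fileext = ".json")
  write_truth(tp, bed, js, extra = list(seed = 4))
  seg <- read.table(bed, sep = "\t")
  expect_equal(nrow(seg), nrow(tp$segments))
  side <- jsonlite::read_json(js)
  expect_equal(side$tumor_fraction, 0.3)
})
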