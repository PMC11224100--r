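#' Simulate an annotated bin grid for a synthetic genome
#'
#' Builds a multi-chromosome grid with GC content drawn from a truncated
#' normal (mean 0.42, typical of mappable 500 kb bins) and the two central
#' bins of each chromosome flagged as centromeric.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_size Chromosome length in bp.
#' @param bin_size Bin width in bp.
#' @param seed Integer seed for the GC draw.
#' @return An annotated `bin_grid`.
#' @export
simulate_bin_grid <- function(n_chrom = 20L, chrom_size = 1.5e8,
                              bin_size = 500000L, seed = 1L) {
  sizes <- stats::setNames(rep(chrom_size, n_chrom),
                           sprintf("chr%02d", seq_len(n_chrom)))
  grid <- make_bin_grid(sizes, bin_size)
  grid$gc <- withr_seed(seed, pmin(pmax(stats::rnorm(nrow(grid), 0.42, 0.05),
                                        0.25), 0.65))
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch)
    mid <- idx[floor(length(idx) / 2) + c(0L, 1L)]
    grid$centromere[mid[!is.na(mid)]] <- TRUE
  }
  grid
}

#' Configuration for an end-to-end simulate/estimate/compare run
#'
#' @param seed Global seed; per-sample seeds are derived by a counter scheme
#'   so adding samples never perturbs earlier ones.
#' @param n_samples Simulated samples per tumor fraction.
#' @param tumor_fractions True fractions cycled across samples.
#' @param n_chrom,chrom_size,bin_size Synthetic genome geometry.
#' @param mean_depth_per_bin,dispersion,gc_bias Count-model parameters
#'   (see [simulate_cfdna_counts()]).
#' @param mean_segment_length,altered_genome_fraction CNV geometry
#'   (see [simulate_cnv_profile()]).
#' @param estimator [estimate_config()] for the per-sample fits.
#' @param n_cohort Patients in the simulated clinical cohort.
#' @param cohort [cohort_params()] for the cohort simulation.
#' @param psa_breaks PSA interval edges for the discovery tables.
#' @param out_dir Output directory.
#' @return Named list (`run_config`).
#' @export
run_config <- function(seed = 1L, n_samples = 4L,
                       tumor_fractions = c(0, 0.1, 0.2, 0.4),
                       n_chrom = 20L, chrom_size = 1.5e8, bin_size = 500000L,
                       mean_depth_per_bin = 500, dispersion = 500,
                       gc_bias = c(0.6, 2.0, -2.5),
                       mean_segment_length = 5e7,
                       altered_genome_fraction = 0.2,
                       estimator = estimate_config(),
                       n_cohort = 130L, cohort = cohort_params(),
                       psa_breaks = c(0, 0.5, 1, 2, 3689),
                       out_dir = tempfile("liquidfrac_run_")) {
  as.list(environment())
}

#' Run the full pipeline: simulate, estimate, compare, summarize
#'
#' Simulates a grid and a set of cfDNA samples at the configured true tumor
#' fractions, runs the fraction estimator on each, joins true and estimated
#' fractions, simulates a clinical cohort and computes its discovery-rate
#' and survival statistics, and writes JSON/CSV/BED outputs with an
#' md5-hashed manifest. Per-sample failures are recorded and the run
#' continues. Identical config and seed reproduce the outputs byte for
#' byte.
#'
#' @param config See [run_config()].
#' @return The run report (list), invisibly also written to
#'   `config$out_dir/report.json`.
#' @export
run_end_to_end <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- simulate_bin_grid(config$n_chrom, config$chrom_size,
                            config$bin_size, seed = config$seed)

  tfs <- rep(config$tumor_fractions, length.out =
               config$n_samples * length(config$tumor_fractions))
  samples <- list()
  for (i in seq_along(tfs)) {
    sid <- sprintf("S%03d", i)
    sample_seed <- config$seed * 10000L + i   # counter-based fan-out
    res <- tryCatch({
      truth <- simulate_cnv_profile(
        grid, tumor_fraction = tfs[i],
        mean_segment_length = config$mean_segment_length,
        altered_genome_fraction = if (tfs[i] == 0) 0 else config$altered_genome_fraction,
        seed = sample_seed)
      counts <- simulate_cfdna_counts(
        grid, truth, mean_depth_per_bin = config$mean_depth_per_bin,
        gc_bias = config$gc_bias, dispersion = config$dispersion,
        sample_id = sid, seed = sample_seed + 1L)
      cfg <- config$estimator
      cfg$seed <- sample_seed + 2L
      est <- estimate_ctdna(counts, grid, cfg)
      seg <- est$states$segments
      seg_path <- file.path(config$out_dir, paste0(sid, "_segments.bed"))
      utils::write.table(
        data.frame(seg$chrom, fmt_num(seg$start), fmt_num(seg$end), seg$copy_number),
        seg_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
      list(sample_id = sid, true_tf = tfs[i], seed = sample_seed,
           estimated_tf = est$tumor_fraction, status = est$status,
           iterations = est$iterations, converged = est$converged,
           log_likelihood = est$log_likelihood,
           ks_p = est$qc$ks_p, error = NA_character_)
    }, error = function(e) {
      list(sample_id = sid, true_tf = tfs[i], seed = sample_seed,
           estimated_tf = NA_real_, status = "failed", iterations = NA_integer_,
           converged = NA, log_likelihood = NA_real_, ks_p = NA_real_,
           error = conditionMessage(e))
    })
    samples[[i]] <- res
  }
  recovery <- if (length(samples) > 0)
    do.call(rbind, lapply(samples, function(s)
      as.data.frame(s, stringsAsFactors = FALSE)))
  else
    data.frame(sample_id = character(0), true_tf = numeric(0),
               seed = integer(0), estimated_tf = numeric(0),
               status = character(0), iterations = integer(0),
               converged = logical(0), log_likelihood = numeric(0),
               ks_p = numeric(0), error = character(0))
  utils::write.csv(recovery, file.path(config$out_dir, "recovery.csv"),
                   row.names = FALSE)

  cohort <- simulate_cohort(config$n_cohort, config$cohort,
                            seed = config$seed + 999L)
  write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
  stats <- cohort_report(cohort, config$psa_breaks)

  ok <- recovery$status %in% c("detected", "not_detected")
  by_tf <- NULL
  if (any(ok)) {
    agg <- stats::aggregate(
      abs(recovery$estimated_tf[ok] - recovery$true_tf[ok]),
      by = list(true_tf = recovery$true_tf[ok]), FUN = stats::median)
    names(agg)[2] <- "median_abs_error"
    by_tf <- agg
  }

  report <- list(
    config = config[setdiff(names(config), "out_dir")],
    n_samples = length(samples),
    samples = samples,
    recovery_by_tf = by_tf,
    cohort_stats = stats
  )
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)

  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files))))
  jsonlite::write_json(
    list(seed = config$seed, files = manifest),
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# the battery of comparative statistics run on a cohort table
cohort_report <- function(cohort, psa_breaks = c(0, 0.5, 1, 2, 3689)) {
  out <- list(discovery = discovery_table(cohort, psa_breaks))
  tab2x2 <- function(flag) {
    t(vapply(c("hsPC", "CRPC"), function(st) {
      sel <- cohort$castration_status == st
      c(sum(flag[sel]), sum(!flag[sel]))
    }, numeric(2)))
  }
  if (nrow(cohort) > 0 && length(unique(cohort$castration_status)) == 2) {
    pet_tab <- tab2x2(cohort$pet_positive)
    ct_tab <- tab2x2(cohort$ctdna_detected)
    if (all(rowSums(pet_tab) > 0) && all(colSums(pet_tab) > 0)) {
      out$pet_by_castration_p <- chi_squared_test(pet_tab, yates = TRUE)$p
      out$pet_by_castration_or <- odds_ratio_woolf(pet_tab)[c("or", "ci_low", "ci_high")]
    }
    if (all(rowSums(ct_tab) > 0) && all(colSums(ct_tab) > 0))
      out$ctdna_by_castration_p <- chi_squared_test(ct_tab, yates = TRUE)$p
  }
  both_pos <- cohort$psma_tv > 0 & cohort$ctdna_conc > 0
  if (sum(both_pos) >= 3 &&
      stats::sd(cohort$ctdna_conc[both_pos]) > 0 &&
      stats::sd(cohort$psma_tv[both_pos]) > 0)
    out$spearman_ctdna_psma <-
      spearman_corr(cohort$ctdna_conc[both_pos], cohort$psma_tv[both_pos])
  if (nrow(cohort) >= 10 && sum(cohort$death_event) >= 2) {
    g_ct <- median_split(cohort$ctdna_conc)
    g_tv <- median_split(cohort$psma_tv)
    out$logrank_ctdna <- km_logrank(cohort$followup_months,
                                    cohort$death_event, g_ct)[c("statistic", "p")]
    out$logrank_psma <- km_logrank(cohort$followup_months,
                                   cohort$death_event, g_tv)[c("statistic", "p")]
    out$cox <- tryCatch(
      cox_fit(cohort$followup_months, cohort$death_event,
              data.frame(ctdna_high = g_ct == "high", psma_high = g_tv == "high")),
      error = function(e) conditionMessage(e))
    if (length(unique(cohort$ctdna_detected)) == 2 &&
        stats::sd(cohort$psma_tv) > 0)
      out$roc_psma_for_ctdna <- roc_youden(cohort$psma_tv, cohort$ctdna_detected)
  }
  out
}

#' Bundled reference contingency counts from a 130-patient clinical cohort
#'
#' Discovery-rate counts of PSMA PET positivity and lpWGS ctDNA detection in
#' a mixed hormone-sensitive/castration-resistant prostate cancer cohort,
#' cross-tabulated by castration status and by PSA range. Used in the worked
#' examples and validation runs.
#'
#' @return list of integer matrices: `pet_by_castration`,
#'   `ctdna_by_castration` (rows hsPC/CRPC, columns positive/negative),
#'   `pet_by_psa`, `ctdna_by_psa` (rows PSA ranges, columns
#'   positive/negative).
#' @export
reference_tables <- function() {
  psa_rows <- c("(0, 0.5]", "(0.5, 1.0]", "(1.0, 2.0]", "(2.0, 3689.0]")
  list(
    pet_by_castration = matrix(c(40, 19, 62, 9), 2, 2, byrow = TRUE,
      dimnames = list(c("hsPC", "CRPC"), c("positive", "negative"))),
    ctdna_by_castration = matrix(c(15, 44, 25, 46), 2, 2, byrow = TRUE,
      dimnames = list(c("hsPC", "CRPC"), c("positive", "negative"))),
    pet_by_psa = matrix(c(13, 10, 5, 6, 12, 3, 72, 9), 4, 2, byrow = TRUE,
      dimnames = list(psa_rows, c("positive", "negative"))),
    ctdna_by_psa = matrix(c(3, 20, 2, 9, 6, 9, 29, 52), 4, 2, byrow = TRUE,
      dimnames = list(psa_rows, c("positive", "negative")))
  )
}

#' Write small deterministic fixtures for tests and documentation
#'
#' Writes (a) a 12-bin single-chromosome HMM toy with counts placed exactly
#' at state means, (b) the bundled reference contingency counts as CSV, and
#' (c) a 200-bin sample simulated at tumor fraction 0.3. Re-running with the
#' same seed overwrites with identical bytes.
#'
#' @param out_dir Writable directory.
#' @param seed Integer seed.
#' @return Paths of the written files, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  # 12-bin toy: counts exactly at the NB means of states 1,2,3 at tf = 0.4
  toy <- hmm_toy_12bin()
  p <- file.path(out_dir, "hmm_toy_12bin.tsv")
  write_bin_table(toy$grid, toy$counts, p, dialect = "tsv")
  paths <- c(paths, p)

  tabs <- reference_tables()
  for (nm in names(tabs)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(cbind(group = rownames(tabs[[nm]]),
                           as.data.frame(tabs[[nm]])), p, row.names = FALSE,
                     quote = FALSE)
    paths <- c(paths, p)
  }

  grid <- simulate_bin_grid(n_chrom = 2L, chrom_size = 5e7, seed = seed)
  truth <- simulate_cnv_profile(grid, tumor_fraction = 0.3, seed = seed)
  counts <- simulate_cfdna_counts(grid, truth, sample_id = "tf030",
                                  seed = seed + 1L)
  p <- file.path(out_dir, "sample_tf030.tsv")
  write_bin_table(grid, counts, p, dialect = "tsv")
  paths <- c(paths, p)
  invisible(paths)
}

# deterministic 12-bin toy used by the exhaustive-enumeration oracle tests:
# states {1,2,3}, tf = 0.4, counts at the exact emission means
hmm_toy_12bin <- function(depth = 1000, tf = 0.4) {
  grid <- make_bin_grid(c(chrT = 12 * 5e5), 5e5)
  grid$gc <- rep(0.45, 12)
  truth_cn <- c(2L, 2L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, 2L, 2L, 2L)
  m <- (1 - tf) * 2 + tf * truth_cn
  counts <- bin_counts(round(depth * m / mean(m)), sample_id = "toy12")
  list(grid = grid, counts = counts, truth_cn = truth_cn, tf = tf,
       depth = depth)
}
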