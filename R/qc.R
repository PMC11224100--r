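#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic `D = sup |ECDF_a - ECDF_b|`; p-value from the exact permutation
#' distribution when `n_a * n_b <= 10000` and from the asymptotic Kolmogorov
#' distribution otherwise.
#'
#' @param a,b Non-empty numeric samples.
#' @return list(statistic, p)
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  res <- suppressWarnings(
    stats::ks.test(a, b, exact = length(a) * length(b) <= 10000))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Permuted-bin noise gate for a fitted ctDNA model
#'
#' The primary model's residuals (observed minus fitted copy ratio over
#' included bins) are compared against residuals from a noise model: the
#' same bin data with bin order randomly permuted (destroying segmental
#' structure), refit with the same iterative procedure. `n_permutations`
#' noise replicates are pooled and the absolute residual distributions
#' compared with the two-sample KS test. A genuine copy-number signal makes
#' the primary fit beat the noise fit, giving a small KS p; the sample is
#' kept only when `ks_p <= ks_alpha`.
#'
#' @param profile A `normalized_profile`.
#' @param states The fitted `state_path`.
#' @param tf The fitted tumor fraction.
#' @param n_permutations Noise replicates pooled (default 3).
#' @param seed Seed for the permutations.
#' @param dispersion NB size parameter used by the fits.
#' @param config The estimator configuration (QC recursion is disabled for
#'   the noise fits).
#' @return list(ks_statistic, ks_p, residual_sd_primary, residual_sd_noise)
#' @export
residual_qc <- function(profile, states, tf, n_permutations = 3L, seed = 1L,
                        dispersion = NULL, config = estimate_config()) {
  incl <- !profile$excluded
  if (sum(incl) < 50L) stop("profile too short for QC")
  if (is.null(dispersion)) dispersion <- estimate_dispersion(profile)
  resid_primary <- model_residuals(profile, states$state, tf)

  noise_cfg <- config
  noise_cfg$run_qc <- FALSE
  resid_noise <- numeric(0)
  for (p in seq_len(n_permutations)) {
    perm_profile <- permute_bins(profile, seed = seed + p)
    core <- estimate_core(perm_profile, dispersion, noise_cfg)
    resid_noise <- c(resid_noise,
                     model_residuals(perm_profile, core$path$state, core$tf))
  }
  ks <- ks_two_sample(abs(resid_primary), abs(resid_noise))
  list(ks_statistic = ks$statistic, ks_p = ks$p,
       residual_sd_primary = stats::sd(resid_primary),
       residual_sd_noise = stats::sd(resid_noise))
}

# observed minus fitted copy ratio over included bins
model_residuals <- function(profile, cn, tf) {
  incl <- !profile$excluded
  m <- (1 - tf) * 2 + tf * cn
  pbar <- stats::weighted.mean(m[incl], profile$weight[incl])
  (profile$ratio - m / pbar)[incl]
}

# shuffle the included bins' (count, ratio, weight) jointly across genome
# positions; excluded bins stay put
permute_bins <- function(profile, seed) {
  incl <- which(!profile$excluded)
  perm <- withr_seed(seed, sample(incl))
  out <- profile
  out$count[incl] <- profile$count[perm]
  out$ratio[incl] <- profile$ratio[perm]
  out$weight[incl] <- profile$weight[perm]
  out
}

#' Peri-centromeric deletion artifact flag
#'
#' Samples whose called deletions cluster around centromeres are a sign of
#' unresolved technical bias. Computes the share of deletion bins (called
#' copy number < 2) that are centromere-flagged or lie within `window` bp of
#' a flagged bin on the same chromosome, and flags the sample when that
#' share exceeds `max_share` ("predominantly" peri-centromeric).
#'
#' @param states A `state_path` (or integer copy-number vector).
#' @param grid The `bin_grid` with centromere annotation.
#' @param window Distance in bp from a centromere-flagged bin that still
#'   counts as peri-centromeric (default 2 Mb).
#' @param max_share Flag threshold (default 0.5).
#' @return list(share, flag); zero deletion bins give share 0, flag FALSE.
#' @export
centromere_artifact_flag <- function(states, grid, window = 2e6,
                                     max_share = 0.5) {
  validate_bin_grid(grid)
  cn <- if (inherits(states, "state_path")) states$state else as.integer(states)
  stopifnot(length(cn) == nrow(grid))
  del <- which(cn < 2L)
  if (length(del) == 0L) return(list(share = 0, flag = FALSE))
  peri <- logical(length(del))
  for (ch in unique(grid$chrom[del])) {
    cen_idx <- which(grid$chrom == ch & grid$centromere)
    sel <- grid$chrom[del] == ch
    if (length(cen_idx) == 0L) next
    d_start <- grid$start[del[sel]]; d_end <- grid$end[del[sel]]
    near <- vapply(seq_along(d_start), function(i) {
      gap <- pmax(grid$start[cen_idx] - d_end[i], d_start[i] - grid$end[cen_idx])
      any(gap <= window)
    }, logical(1))
    peri[sel] <- near
  }
  share <- mean(peri)
  list(share = share, flag = share > max_share)
}
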