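# shared builders for synthetic fixtures; everything is generated in code

# small annotated grid: n_chrom chromosomes of n_bins 500 kb bins each
toy_grid <- function(n_chrom = 2L, n_bins = 100L, gc = NULL, seed = 1L) {
  grid <- simulate_bin_grid(n_chrom = n_chrom, chrom_size = n_bins * 5e5,
                            seed = seed)
  if (!is.null(gc)) grid$gc <- rep(gc, length.out = nrow(grid))
  grid
}

# a normalized_profile built directly from a ratio vector (flat weights);
# keeps the count == ratio * weight identity and the weighted-mean-1 centring
profile_from_ratios <- function(ratio, depth = 1000,
                                chrom = rep("chr01", length(ratio))) {
  n <- length(ratio)
  count <- round(ratio * depth)
  r <- count / depth
  centre <- mean(r)
  structure(list(
    ratio = r / centre,
    weight = rep(depth * centre, n),
    excluded = rep(FALSE, n),
    count = count,
    chrom = chrom,
    start = (seq_len(n) - 1) * 5e5,
    end = seq_len(n) * 5e5,
    centromere = rep(FALSE, n),
    sample_id = "toy"
  ), class = "normalized_profile")
}

# simulate one sample end to end and return everything
sim_sample <- function(tf, grid, seed, altered = if (tf == 0) 0 else 0.2,
                       depth = 500, dispersion = 500) {
  truth <- simulate_cnv_profile(grid, tumor_fraction = tf,
                                altered_genome_fraction = altered, seed = seed)
  counts <- simulate_cfdna_counts(grid, truth, mean_depth_per_bin = depth,
                                  dispersion = dispersion, seed = seed + 1L)
  list(truth = truth, counts = counts)
}

# brute-force two-sample KS: D and exact permutation p by full enumeration
# of which pooled positions belong to sample a
ks_brute_force <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  ord <- order(pooled)
  sorted <- pooled[ord]
  # ECDF differences are evaluated at the end of each tied block
  block_end <- c(diff(sorted) != 0, TRUE)
  d_of <- function(is_a_sorted) {
    gap <- abs(cumsum(is_a_sorted / n) - cumsum((!is_a_sorted) / m))
    max(gap[block_end])
  }
  d_obs <- d_of(c(rep(TRUE, n), rep(FALSE, m))[ord])
  combos <- utils::combn(n + m, n)
  ds <- apply(combos, 2, function(idx) {
    is_a <- rep(FALSE, n + m); is_a[idx] <- TRUE
    d_of(is_a[ord])  # same pooled values, relabelled
  })
  list(statistic = d_obs, p = mean(ds >= d_obs - 1e-12))
}

# exhaustive joint-likelihood path search for a small NB-HMM
enumerate_best_path <- function(profile, tf, states, stay, dispersion) {
  n <- sum(!profile$excluded)
  stopifnot(n == length(profile$ratio))  # toys have no excluded bins
  K <- length(states)
  logE <- liquidfrac:::nb_log_emissions(profile, tf, states, dispersion)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  emis <- matrix(logE[cbind(rep(seq_len(n), each = nrow(paths)),
                            as.vector(paths))], nrow = nrow(paths))
  score <- rowSums(emis) - log(K)
  loff <- log((1 - stay) / (K - 1)); lstay <- log(stay)
  for (t in 2:n) {
    score <- score + ifelse(paths[, t] == paths[, t - 1], lstay, loff)
  }
  states[paths[which.max(score), ]]
}
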