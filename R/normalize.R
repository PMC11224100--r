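#' Normalize binned read counts for library size and GC content
#'
#' Produces per-bin copy-ratio estimates on the scale where 1 is the
#' diploid genome average. Counts are scaled by the library total, the
#' GC-dependent expectation is removed by a robust local regression of count
#' on GC (median within GC deciles when the profile is short), extreme bins
#' are excluded by a median/MAD rule, and ratios are re-centred so their
#' weighted mean over included bins is exactly 1.
#'
#' @param counts A `bin_counts` object.
#' @param grid The matching `bin_grid` (GC annotated).
#' @param outlier_k Exclusion threshold in MAD units (default 8).
#' @param loess_span Span of the robust loess GC fit (default 0.3).
#' @param min_loess_bins Below this many usable bins, fall back to GC-decile
#'   medians (default 1000).
#' @return A `normalized_profile`: list with per-bin `ratio`, `weight`
#'   (fitted expected count under the copy-neutral model; emission weights
#'   for the HMM), `excluded` (masked, unannotated, non-positive-fit or
#'   outlier bins), `count`, and grid columns `chrom`, `start`, `end`,
#'   `centromere`.
#' @export
normalize_counts <- function(counts, grid, outlier_k = 8,
                             loess_span = 0.3, min_loess_bins = 1000L) {
  validate_bin_grid(grid)
  stopifnot(length(counts$counts) == nrow(grid))
  x <- as.numeric(counts$counts)
  if (sum(x) == 0) stop("empty sample")
  usable <- !grid$mask & !is.na(grid$gc) & grid$gc > 0 & grid$gc <= 1
  if (sum(usable) < 100L)
    stop("need at least 100 unmasked bins with positive GC annotation")

  gc <- grid$gc
  fitted <- rep(NA_real_, length(x))
  if (length(unique(gc[usable])) < 5L) {
    # essentially constant GC: library-size scaling only
    fitted[usable] <- stats::median(x[usable])
  } else if (sum(usable) >= min_loess_bins) {
    fit <- stats::loess(x[usable] ~ gc[usable], span = loess_span,
                        degree = 2, family = "symmetric")
    fitted[usable] <- stats::predict(fit, gc[usable])
  } else {
    qs <- unique(stats::quantile(gc[usable], probs = seq(0, 1, 0.1)))
    dec <- cut(gc[usable], breaks = qs, include.lowest = TRUE)
    med <- tapply(x[usable], dec, stats::median)
    fitted[usable] <- med[as.integer(dec)]
  }
  ok <- usable & !is.na(fitted) & fitted > 0
  ratio <- rep(NA_real_, length(x))
  ratio[ok] <- x[ok] / fitted[ok]

  med <- stats::median(ratio[ok])
  mad <- stats::mad(ratio[ok])
  outlier <- ok & mad > 0 & abs(ratio - med) > outlier_k * mad
  included <- ok & !outlier

  centre <- stats::weighted.mean(ratio[included], fitted[included])
  ratio <- ratio / centre
  weight <- fitted * centre   # keeps count == ratio * weight

  structure(list(
    ratio = ratio, weight = weight, excluded = !included, count = x,
    chrom = grid$chrom, start = grid$start, end = grid$end,
    centromere = grid$centromere, sample_id = counts$sample_id
  ), class = "normalized_profile")
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf("normalized_profile '%s': %d bins (%d excluded), median ratio %.3f\n",
              x$sample_id, length(x$ratio), sum(x$excluded),
              stats::median(x$ratio[!x$excluded])))
  invisible(x)
}

#' Method-of-moments dispersion estimate from copy-neutral-looking bins
#'
#' Uses the central 80% of included ratios (by quantile) as approximately
#' neutral and solves the negative-binomial relation
#' `Var[x]/mu^2 = 1/mu + 1/size` on the ratio scale. The trimmed variance
#' is rescaled by the central-80% truncation factor of a normal (0.4377) so
#' the estimate is consistent when the residuals are well-behaved, while
#' trimming keeps copy-altered bins from inflating it; residual
#' contamination only shrinks the size and makes the caller more
#' conservative.
#'
#' @param profile A `normalized_profile`.
#' @return Size parameter, clamped to `[1, 1e6]`.
#' @export
estimate_dispersion <- function(profile) {
  incl <- !profile$excluded
  r <- profile$ratio[incl]
  qs <- stats::quantile(r, c(0.1, 0.9))
  core <- r >= qs[1] & r <= qs[2]
  u <- (profile$count[incl][core] - profile$weight[incl][core]) /
    profile$weight[incl][core]
  # variance of the central 80% of a normal is 0.4377 of the full variance
  var_ratio <- stats::var(u) / 0.4377
  inv_size <- var_ratio - mean(1 / profile$weight[incl][core])
  if (inv_size <= 0) return(1e6)  # at or below Poisson
  min(max(1 / inv_size, 1), 1e6)
}
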