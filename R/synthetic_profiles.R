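#' Simulate a segmental copy-number profile at known tumor fraction
#'
#' Walks each chromosome alternating copy-neutral and altered segments with
#' geometrically distributed lengths, the simplest segmental structure a
#' copy-number caller must recover. Altered segments draw their copy number
#' from `state_weights`. The expected altered genome share equals
#' `altered_genome_fraction`; the realized share fluctuates with sampling.
#'
#' @param grid A `bin_grid`.
#' @param tumor_fraction True ctDNA fraction in `[0,1]`, carried in the truth.
#' @param mean_segment_length Mean altered-segment length in bp (>= bin size).
#'   Default 50 Mb: advanced prostate cancers carry large segmental gains and
#'   losses (chromosome-arm scale) rather than focal events at 500 kb scale.
#' @param altered_genome_fraction Target share of the unmasked genome carrying
#'   a non-neutral copy number, in `[0,1)`.
#' @param state_weights Named probabilities over altered copy numbers,
#'   default `c("0"=.1, "1"=.4, "3"=.4, "4"=.1)` (loss-heavy, as in PTEN/RB1
#'   driven prostate tumors).
#' @param seed Integer seed; the profile is a pure function of (params, seed).
#' @return A `truth_profile`: list with `copy_number` (per bin), `segments`
#'   (chrom/start/end/copy_number for non-neutral runs), `tumor_fraction`.
#' @export
simulate_cnv_profile <- function(grid, tumor_fraction = 0.3,
                                 mean_segment_length = 5e7,
                                 altered_genome_fraction = 0.2,
                                 state_weights = c("0" = 0.1, "1" = 0.4,
                                                   "3" = 0.4, "4" = 0.1),
                                 seed = 1L) {
  validate_bin_grid(grid)
  if (altered_genome_fraction >= 1) stop("altered_genome_fraction must be < 1")
  if (altered_genome_fraction < 0) stop("altered_genome_fraction must be >= 0")
  if (abs(sum(state_weights) - 1) > 1e-8) stop("state_weights must sum to 1")
  if (tumor_fraction < 0 || tumor_fraction > 1) stop("tumor_fraction must be in [0,1]")
  bs <- attr(grid, "bin_size")
  if (mean_segment_length < bs) stop("mean_segment_length must be >= bin_size")
  states <- as.integer(names(state_weights))
  if (any(states < 0) || any(states == 2)) stop("altered states must be non-negative and != 2")

  cn <- rep(2L, nrow(grid))
  f <- altered_genome_fraction
  if (f > 0) {
    withr_seed(seed, {
      la <- mean_segment_length / bs              # mean altered length, bins
      ln <- la * (1 - f) / f                      # mean neutral gap, bins
      for (ch in unique(grid$chrom)) {
        idx <- which(grid$chrom == ch)
        pos <- 1L
        altered <- stats::runif(1) < f            # random phase at chrom start
        while (pos <= length(idx)) {
          mean_len <- if (altered) la else ln
          len <- stats::rgeom(1, 1 / mean_len) + 1L
          stop_at <- min(pos + len - 1L, length(idx))
          if (altered) {
            cn[idx[pos:stop_at]] <- sample(states, 1L, prob = state_weights)
          }
          pos <- stop_at + 1L
          altered <- !altered
        }
      }
    })
  }
  segments <- runs_to_segments(grid, cn)
  structure(list(copy_number = cn, segments = segments,
                 tumor_fraction = tumor_fraction),
            class = "truth_profile")
}

# merge per-bin copy numbers into per-chromosome runs; keep non-neutral only
runs_to_segments <- function(grid, cn, keep_neutral = FALSE) {
  out <- list()
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch)
    r <- rle(cn[idx])
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    keep <- if (keep_neutral) seq_along(r$values) else which(r$values != 2L)
    for (k in keep) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = grid$start[idx[starts[k]]],
        end = grid$end[idx[stops[k]]],
        copy_number = r$values[k], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), copy_number = integer(0)))
  do.call(rbind, out)
}

#' Relative copy ratio of a mixed tumor/normal profile
#'
#' Read counts carry only relative copy number: the per-bin mixture mean
#' `(1 - tf) * 2 + tf * c_b` is divided by its weighted genome average so the
#' profile is mean-centred at 1. This encodes the identifiability limit that
#' motivates the iterative fraction/CNV estimation.
#'
#' @param copy_number Integer tumor copy number per bin.
#' @param tf Tumor fraction in `[0,1]`.
#' @param weights Averaging weights (expected neutral depth per bin);
#'   default equal.
#' @return Per-bin relative copy ratio, weighted mean 1.
#' @export
copy_ratio <- function(copy_number, tf, weights = NULL) {
  if (any(copy_number < 0)) stop("copy numbers must be non-negative")
  m <- (1 - tf) * 2 + tf * copy_number
  if (is.null(weights)) weights <- rep(1, length(m))
  m / stats::weighted.mean(m, weights)
}

#' Simulate binned cfDNA read counts
#'
#' Draws per-bin counts from a negative binomial whose mean is
#' `mean_depth_per_bin * gcfactor(gc_b) * r_b`, with `r_b` the mean-centred
#' relative copy ratio of the tumor/normal mixture (see [copy_ratio()]) and
#' `gcfactor` a quadratic in GC content emulating amplification bias.
#'
#' @param grid A `bin_grid` with `gc` annotated.
#' @param truth A `truth_profile`.
#' @param mean_depth_per_bin Expected reads per unbiased neutral bin
#'   (default 500, ~0.1-0.2x coverage at 500 kb bins).
#' @param gc_bias Coefficients `c(a0, a1, a2)` of `a0 + a1*gc + a2*gc^2`;
#'   default `c(0.6, 2.0, -2.5)` gives the familiar concave unimodal bias
#'   peaking near 40% GC. Use `c(1, 0, 0)` for no bias.
#' @param dispersion Negative-binomial size parameter (default 500: variance
#'   roughly twice Poisson at the default depth, typical of 500 kb lpWGS bins).
#' @param sample_id Label for the returned counts.
#' @param seed Integer seed.
#' @return A `bin_counts` object over all grid bins (masked bins receive
#'   neutral-ratio counts: reads fall there too, the model just ignores them).
#' @export
simulate_cfdna_counts <- function(grid, truth, mean_depth_per_bin = 500,
                                  gc_bias = c(0.6, 2.0, -2.5),
                                  dispersion = 500,
                                  sample_id = "sim", seed = 1L) {
  validate_bin_grid(grid)
  if (mean_depth_per_bin <= 0) stop("mean_depth_per_bin must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  stopifnot(length(truth$copy_number) == nrow(grid))
  gc <- ifelse(is.na(grid$gc), 0.5, grid$gc)
  gcf <- pmax(gc_bias[1] + gc_bias[2] * gc + gc_bias[3] * gc^2, 0.05)
  gcf <- gcf / mean(gcf)
  cn <- truth$copy_number
  cn[grid$mask] <- 2L
  r <- copy_ratio(cn, truth$tumor_fraction, weights = gcf)
  mu <- mean_depth_per_bin * gcf * r
  counts <- withr_seed(seed, stats::rnbinom(length(mu), mu = mu, size = dispersion))
  bin_counts(counts, sample_id = sample_id)
}

#' Write a truth profile as BED segments plus a JSON sidecar
#'
#' @param truth A `truth_profile`.
#' @param bed_path,json_path Output paths.
#' @param extra Named list merged into the JSON sidecar (seed, params, ...).
#' @export
write_truth <- function(truth, bed_path, json_path, extra = list()) {
  seg <- truth$segments
  utils::write.table(
    data.frame(seg$chrom, fmt_num(seg$start), fmt_num(seg$end), seg$copy_number),
    bed_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  side <- c(list(tumor_fraction = truth$tumor_fraction), extra)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(bed_path)
}

# run expr under a private RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
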