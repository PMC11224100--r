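#' Initial tumor fraction from the density of normalized copy ratios
#'
#' A kernel density estimate (Gaussian kernel, Silverman bandwidth) of the
#' included per-bin ratios is scanned for modes. The dominant mode is taken
#' as the copy-neutral level; the nearest secondary mode whose density
#' reaches at least `min_peak_frac` of the main peak is read as a one-copy
#' change, for which the mixture model gives `ratio = 1 -/+ tf/2`, hence
#' `tf0 = 2 * |m1 - m0|`, clipped to `[0.01, 0.95]`. Returns `NULL` when no
#' qualifying secondary mode exists (unimodal or degenerate profiles), in
#' which case the caller falls through to the default-fraction pass.
#'
#' @param profile A `normalized_profile`.
#' @param min_peak_frac Secondary-mode qualification threshold as a fraction
#'   of the main peak density (default 0.10).
#' @return Initial tumor fraction, or `NULL`.
#' @export
initial_fraction_from_density <- function(profile, min_peak_frac = 0.10) {
  r <- profile$ratio[!profile$excluded]
  r <- r[is.finite(r)]
  if (length(r) < 10L || stats::sd(r) == 0) return(NULL)
  d <- stats::density(r, bw = "nrd0")
  y <- d$y; xs <- d$x
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(is_max)
  if (length(peaks) == 0L) peaks <- which.max(y)
  main <- peaks[which.max(y[peaks])]
  qualifying <- peaks[y[peaks] >= min_peak_frac * y[main] & peaks != main]
  if (length(qualifying) == 0L) return(NULL)
  m1 <- xs[qualifying[which.min(abs(xs[qualifying] - xs[main]))]]
  tf0 <- 2 * abs(m1 - xs[main])
  min(max(tf0, 0.01), 0.95)
}
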