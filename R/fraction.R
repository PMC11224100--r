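#' Maximum-likelihood tumor fraction given fixed copy-number states
#'
#' Maximizes the negative-binomial log-likelihood of the included bins over
#' `tf` in `[0,1]` by bounded golden-section search, with emission means
#' mixing diploid and tumor copies at `tf` and mean-centred over the fixed
#' path (the same parameterization as [decode_states()]).
#'
#' @param profile A `normalized_profile`.
#' @param states A `state_path` or an integer copy-number vector.
#' @param dispersion Negative-binomial size parameter.
#' @param tol Search tolerance (default 1e-4).
#' @return Estimated tumor fraction.
#' @export
fit_fraction <- function(profile, states, dispersion, tol = 1e-4) {
  cn <- if (inherits(states, "state_path")) states$state else as.integer(states)
  incl <- !profile$excluded
  if (all(cn[incl] == 2L)) stop("fraction unidentifiable: all states neutral")
  w <- profile$weight[incl]; x <- profile$count[incl]; c_incl <- cn[incl]
  negll <- function(tf) {
    m <- (1 - tf) * 2 + tf * c_incl
    mu <- pmax(w * m / stats::weighted.mean(m, w), 1e-8)
    -sum(stats::dnbinom(x, mu = mu, size = dispersion, log = TRUE))
  }
  opt <- stats::optimize(negll, interval = c(0, 1), tol = tol)
  opt$minimum
}

#' Estimator configuration
#'
#' @param tf_default Fraction re-injected when a first pass finds no CNVs
#'   (default 0.05).
#' @param ks_alpha Significance level of the permuted-bin KS noise gate; a
#'   sample is kept only when its residuals differ from the noise model with
#'   `p <= ks_alpha` (default 0.05).
#' @param max_iter Maximum decode/refit iterations (default 20).
#' @param tf_tol Convergence tolerance on the fraction (default 1e-3).
#' @param n_permutations Permuted-bin noise replicates pooled for the KS
#'   gate (default 3).
#' @param outlier_k Normalization outlier threshold in MADs (default 8).
#' @param centromere_max_share Artifact threshold: flag when more than this
#'   share of deletion bins is peri-centromeric (default 0.5).
#' @param hmm See [hmm_params()].
#' @param run_qc Run the KS noise gate and artifact filter (default TRUE).
#' @param seed Seed for the permutation noise model.
#' @return Named list.
#' @export
estimate_config <- function(tf_default = 0.05, ks_alpha = 0.05,
                            max_iter = 20L, tf_tol = 1e-3,
                            n_permutations = 3L, outlier_k = 8,
                            centromere_max_share = 0.5,
                            hmm = hmm_params(), run_qc = TRUE, seed = 1L) {
  as.list(environment())
}

# Iterative decode/refit core shared by the primary fit and the permuted-bin
# noise fits. Coordinate ascent on the joint path likelihood: decode
# (Viterbi) maximizes over paths at fixed tf, the refit maximizes the
# emission term over tf at fixed path, and a worse optimizer result than the
# incumbent tf is discarded, so the objective never decreases.
#
# A profile whose non-neutral segments are all single-copy events is exactly
# aliased with a half-fraction solution that calls the same segments as
# two-copy events (homozygous deletion / double gain). When the converged
# path contains extreme states, a second ascent started at twice the
# fraction is compared by joint likelihood, preferring the near-neutral
# (larger-fraction) solution on ties: single-copy alterations are the
# parsimonious reading.
estimate_core <- function(profile, dispersion, config) {
  tf0 <- initial_fraction_from_density(profile)
  init_method <- if (is.null(tf0)) "default" else "density"
  tf_start <- if (is.null(tf0)) config$tf_default else tf0

  a <- ascend_once(profile, dispersion, config, tf_start,
                   allow_fallback = init_method == "density")
  if (init_method == "default")
    a$log_rows <- c(list(data.frame(
      iteration = 0L, tf = config$tf_default, log_likelihood = NA_real_,
      event = "default_fraction_start")), a$log_rows)
  if (!a$detected)
    return(c(a, list(init_method = init_method,
                     iteration_log = bind_log(a$log_rows))))

  incl <- !profile$excluded
  extremes <- any(a$path$viterbi[incl] %in% c(0L, 4L))
  if (extremes && 2 * a$tf <= 0.95) {
    b <- ascend_once(profile, dispersion, config, 2 * a$tf,
                     allow_fallback = FALSE)
    if (b$detected) {
      j_a <- path_log_joint(profile, a$path$viterbi, a$tf, config$hmm, dispersion)
      j_b <- path_log_joint(profile, b$path$viterbi, b$tf, config$hmm, dispersion)
      # near-ties (within 10 log units) go to the near-neutral solution:
      # genuine two-copy segments favor the half-fraction fit by far more
      if (j_b >= j_a - 10) {
        b$log_rows <- c(a$log_rows, list(data.frame(
          iteration = a$iterations, tf = b$tf, log_likelihood = j_b,
          event = "alias_rescue")), b$log_rows)
        b$iterations <- a$iterations + b$iterations
        a <- b
      }
    }
  }
  c(a, list(init_method = init_method, iteration_log = bind_log(a$log_rows)))
}

# one coordinate-ascent run from a fixed starting fraction
ascend_once <- function(profile, dispersion, config, tf_start, allow_fallback) {
  incl <- !profile$excluded
  tf_cur <- tf_start
  prior <- NULL
  fallback_done <- !allow_fallback
  log_rows <- list()
  converged <- FALSE
  iter <- 0L

  repeat {
    iter <- iter + 1L
    path <- decode_states(profile, tf_cur, params = config$hmm,
                          dispersion = dispersion, prior_states = prior)
    non_neutral <- any(path$viterbi[incl] != 2L)
    if (!non_neutral) {
      if (!fallback_done && abs(tf_cur - config$tf_default) > 1e-12) {
        fallback_done <- TRUE
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          iteration = iter, tf = config$tf_default, log_likelihood = NA_real_,
          event = "default_fraction_reinjection")
        tf_cur <- config$tf_default
        prior <- NULL
        next
      }
      return(list(detected = FALSE, tf = 0, path = path, iterations = iter,
                  converged = TRUE, log_likelihood = path$loglik,
                  fallback_used = fallback_done, log_rows = log_rows))
    }
    tf_new <- fit_fraction(profile, path$viterbi, dispersion, tol = 1e-4)
    # keep the incumbent if the 1-D search lands on a worse point
    j_new <- path_log_joint(profile, path$viterbi, tf_new, config$hmm, dispersion)
    j_old <- path_log_joint(profile, path$viterbi, tf_cur, config$hmm, dispersion)
    if (j_new < j_old) tf_new <- tf_cur
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      iteration = iter, tf = tf_new, log_likelihood = max(j_new, j_old),
      event = "refit")
    if (abs(tf_new - tf_cur) < config$tf_tol) {
      tf_cur <- tf_new
      converged <- TRUE
      break
    }
    tf_cur <- tf_new
    prior <- path$viterbi
    if (iter >= config$max_iter) break
  }

  list(detected = TRUE, tf = tf_cur, path = path, iterations = iter,
       converged = converged, log_likelihood = path$loglik,
       fallback_used = fallback_done, log_rows = log_rows)
}

bind_log <- function(rows) {
  if (length(rows) == 0L)
    return(data.frame(iteration = integer(0), tf = numeric(0),
                      log_likelihood = numeric(0), event = character(0)))
  do.call(rbind, rows)
}

#' Estimate the ctDNA fraction of a cfDNA sample from binned read counts
#'
#' The full pipeline: normalize counts for library size and GC
#' ([normalize_counts()]), read an initial fraction off the copy-ratio
#' density ([initial_fraction_from_density()]), then alternate copy-number
#' decoding ([decode_states()]) and fraction refitting ([fit_fraction()])
#' until the fraction moves less than `tf_tol`. When a first pass calls no
#' CNVs, the fraction is set to `tf_default` once and decoding repeated; if
#' still no CNVs are found the sample is reported `not_detected` with
#' fraction 0. Detected calls are gated by the permuted-bin
#' Kolmogorov-Smirnov noise model ([residual_qc()]) and the peri-centromeric
#' deletion artifact filter ([centromere_artifact_flag()]).
#'
#' @param counts A `bin_counts` object.
#' @param grid The matching `bin_grid`.
#' @param config See [estimate_config()].
#' @return A `fraction_estimate`: list with `tumor_fraction`, `status`
#'   (`detected`, `not_detected`, `excluded_noise`, `excluded_artifact`),
#'   `iterations`, `converged`, `log_likelihood`, `qc` (KS statistic and p,
#'   residual SDs, centromere deletion share), `states` (final
#'   `state_path`), `iteration_log`, `dispersion`, `sample_id`.
#' @export
estimate_ctdna <- function(counts, grid, config = estimate_config()) {
  profile <- normalize_counts(counts, grid, outlier_k = config$outlier_k)
  dispersion <- config$hmm$dispersion
  if (is.null(dispersion)) dispersion <- estimate_dispersion(profile)

  core <- estimate_core(profile, dispersion, config)
  qc <- list(ks_statistic = NA_real_, ks_p = NA_real_,
             residual_sd_primary = NA_real_, residual_sd_noise = NA_real_,
             centromere_deletion_share = NA_real_)
  if (!core$detected) {
    status <- "not_detected"
  } else if (!config$run_qc) {
    status <- "detected"
    qc$centromere_deletion_share <-
      centromere_artifact_flag(core$path, grid)$share
  } else {
    rq <- residual_qc(profile, core$path, core$tf,
                      n_permutations = config$n_permutations,
                      seed = config$seed, dispersion = dispersion,
                      config = config)
    cen <- centromere_artifact_flag(core$path, grid,
                                    max_share = config$centromere_max_share)
    qc <- c(rq, list(centromere_deletion_share = cen$share))
    status <- if (rq$ks_p > config$ks_alpha) "excluded_noise"
              else if (cen$flag) "excluded_artifact"
              else "detected"
  }

  structure(list(
    sample_id = counts$sample_id,
    tumor_fraction = if (status == "not_detected") 0 else core$tf,
    status = status, iterations = core$iterations,
    converged = core$converged, log_likelihood = core$log_likelihood,
    qc = qc, states = core$path, iteration_log = core$iteration_log,
    init_method = core$init_method, fallback_used = core$fallback_used,
    dispersion = dispersion
  ), class = "fraction_estimate")
}

#' @export
print.fraction_estimate <- function(x, ...) {
  cat(sprintf("fraction_estimate '%s': tf = %.3f, status = %s (%d iterations%s)\n",
              x$sample_id, x$tumor_fraction, x$status, x$iterations,
              if (x$converged) "" else ", not converged"))
  if (!is.na(x$qc$ks_p))
    cat(sprintf("  KS gate: D = %.3f, p = %.3g; centromeric deletion share %.2f\n",
                x$qc$ks_statistic, x$qc$ks_p, x$qc$centromere_deletion_share))
  invisible(x)
}
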