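#' Default HMM parameters for copy-number decoding
#'
#' @param stay_prob Per-bin probability of remaining in the same copy state
#'   (default `1 - 1e-3`; off-diagonal mass is spread uniformly).
#' @param states Copy-number state set (default `0:4`: homozygous deletion
#'   through two-copy gain).
#' @param dispersion Negative-binomial size parameter shared across states;
#'   `NULL` means estimate from data (see [estimate_dispersion()]).
#' @return Named list.
#' @export
hmm_params <- function(stay_prob = 1 - 1e-3, states = 0:4, dispersion = NULL) {
  stopifnot(stay_prob > 0, stay_prob < 1, length(states) >= 2)
  list(stay_prob = stay_prob, states = as.integer(states), dispersion = dispersion)
}

# Negative-binomial log emission matrix for included bins (excluded bins get
# flat zero log-density so the chain passes through without evidence).
# Emission mean for state c: weight_b * ((1-tf)*2 + tf*c) / Pbar, where Pbar
# mean-centres the mixture over the current path (counts carry only relative
# copy ratio).
nb_log_emissions <- function(profile, tf, states, dispersion, prior_cn = NULL) {
  n <- length(profile$ratio)
  incl <- !profile$excluded
  if (is.null(prior_cn)) prior_cn <- rep(2L, n)
  m_prior <- (1 - tf) * 2 + tf * prior_cn
  pbar <- stats::weighted.mean(m_prior[incl], profile$weight[incl])
  logE <- matrix(0, nrow = n, ncol = length(states))
  for (k in seq_along(states)) {
    mu <- pmax(profile$weight[incl] * ((1 - tf) * 2 + tf * states[k]) / pbar, 1e-8)
    logE[incl, k] <- stats::dnbinom(profile$count[incl], mu = mu,
                                    size = dispersion, log = TRUE)
  }
  logE
}

#' Decode per-bin copy-number states at a candidate tumor fraction
#'
#' Runs forward-backward (posterior decoding) and Viterbi over a
#' left-to-right chain whose negative-binomial emission means mix diploid
#' and tumor copies at fraction `tf`, mean-centred over the current path.
#' Chromosome boundaries reset the chain to its uniform initial
#' distribution. Reported states are the per-bin posterior argmax,
#' tie-broken toward copy-neutral; the Viterbi path and its joint
#' log-probability are carried alongside for the coordinate-ascent loop.
#'
#' @param profile A `normalized_profile`.
#' @param tf Candidate tumor fraction in `[0,1]`.
#' @param params See [hmm_params()]; `dispersion` must be set here or via
#'   the `dispersion` argument.
#' @param dispersion Overrides `params$dispersion`.
#' @param prior_states Integer copy numbers of the previous iteration's path
#'   used for mean-centring; default all-neutral.
#' @return A `state_path`: list with `state` (posterior-argmax copy number),
#'   `posterior` (bins x states), `viterbi`, `log_joint`, `loglik`
#'   (marginal), and `segments` (merged per-chromosome runs of `state`).
#' @export
decode_states <- function(profile, tf, params = hmm_params(),
                          dispersion = NULL, prior_states = NULL) {
  if (tf < 0 || tf > 1) stop("tf must be in [0,1]")
  disp <- if (!is.null(dispersion)) dispersion else params$dispersion
  if (is.null(disp) || disp <= 0) stop("dispersion must be positive")
  states <- params$states
  logE <- nb_log_emissions(profile, tf, states, disp, prior_states)
  chrom_id <- as.integer(factor(profile$chrom, levels = unique(profile$chrom)))

  fb <- fb_posterior(logE, params$stay_prob, chrom_id)
  vit <- viterbi_path(logE, params$stay_prob, chrom_id)

  post <- fb$posterior
  state <- argmax_pref_neutral(post, states)
  viterbi <- states[vit$path + 1L]

  grid_like <- data.frame(chrom = profile$chrom, start = profile$start,
                          end = profile$end, stringsAsFactors = FALSE)
  segments <- runs_to_segments(grid_like, state, keep_neutral = TRUE)
  structure(list(state = state, posterior = post, viterbi = viterbi,
                 log_joint = vit$log_joint, loglik = fb$loglik,
                 segments = segments, tf = tf, states = states,
                 dispersion = disp),
            class = "state_path")
}

# posterior argmax with ties broken toward copy 2, then toward the state
# closest to 2 (relevant when tf = 0 collapses all emission means)
argmax_pref_neutral <- function(post, states) {
  pref <- order(abs(states - 2L), states)
  best <- post[, pref[1L]]
  arg <- rep(pref[1L], nrow(post))
  for (j in pref[-1L]) {
    better <- post[, j] > best + 1e-12
    arg[better] <- j
    best[better] <- post[better, j]
  }
  states[arg]
}

#' @export
print.state_path <- function(x, ...) {
  nn <- sum(x$state != 2L)
  cat(sprintf("state_path at tf = %.3f: %d bins, %d non-neutral (%d segments)\n",
              x$tf, length(x$state), nn, nrow(x$segments)))
  invisible(x)
}

# joint log-probability of a fixed path at a given tf (emissions +
# transitions + uniform init); the coordinate-ascent objective
path_log_joint <- function(profile, cn, tf, params, dispersion) {
  states <- params$states
  idx <- match(cn, states)
  logE <- nb_log_emissions(profile, tf, states, dispersion, prior_cn = cn)
  emis <- sum(logE[cbind(seq_along(cn), idx)])
  chrom_id <- as.integer(factor(profile$chrom, levels = unique(profile$chrom)))
  new_chrom <- c(TRUE, chrom_id[-1L] != chrom_id[-length(chrom_id)])
  K <- length(states)
  stayed <- !new_chrom & c(NA, cn[-length(cn)] == cn[-1L])
  trans <- sum(ifelse(new_chrom, -log(K),
                      ifelse(stayed, log(params$stay_prob),
                             log((1 - params$stay_prob) / (K - 1)))))
  emis + trans
}
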