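#' Default parameters for the clinical cohort simulator
#'
#' Defaults emulate a mixed hormone-sensitive (hsPC) / castration-resistant
#' (CRPC) prostate cancer cohort: roughly balanced castration split, PSA
#' log-normal within status (heavier and wider in CRPC), zero-inflated
#' log-normal PSMA-positive tumor volume (PSMA-TV), ctDNA concentration
#' coupled to PSMA-TV through a Gaussian copula, and exponential survival
#' whose hazard is driven by above-median ctDNA and PSMA-TV burden.
#'
#' @param crpc_share Probability a patient is CRPC.
#' @param psa_meanlog,psa_sdlog Named (`hsPC`, `CRPC`) log-normal PSA params.
#' @param pet_pos_prob Named probability of any PSMA-positive lesion.
#' @param psma_meanlog,psma_sdlog Log-normal PSMA-TV (cm^3) given PET-positive.
#' @param ctdna_det_prob Named probability of ctDNA detection.
#' @param ctdna_meanlog,ctdna_sdlog Log-normal ctDNA ng/uL given detected.
#' @param spearman_rho Target Spearman correlation between ctDNA concentration
#'   and PSMA-TV on the fully observed (both positive) scale.
#' @param dominant_probs Named list of per-status probabilities over dominant
#'   lesion site (prostate/lymph_node/bone/organ) given PET-positive.
#' @param base_hazard Monthly baseline death hazard for low/low patients.
#' @param loghr_ctdna,loghr_psma Log hazard ratios of the above-median groups.
#' @param followup_max Administrative censoring horizon, months.
#' @return Named list of parameters for [simulate_cohort()].
#' @export
cohort_params <- function(
    crpc_share = 71 / 130,
    psa_meanlog = c(hsPC = log(4), CRPC = log(15)),
    psa_sdlog = c(hsPC = 1.5, CRPC = 2.2),
    pet_pos_prob = c(hsPC = 0.678, CRPC = 0.873),
    psma_meanlog = c(hsPC = log(8), CRPC = log(60)),
    psma_sdlog = c(hsPC = 1.3, CRPC = 1.6),
    ctdna_det_prob = c(hsPC = 0.254, CRPC = 0.352),
    ctdna_meanlog = c(hsPC = log(0.03), CRPC = log(0.15)),
    ctdna_sdlog = c(hsPC = 1.0, CRPC = 1.3),
    spearman_rho = 0.42,
    dominant_probs = list(
      hsPC = c(prostate = 0.425, lymph_node = 0.40, bone = 0.15, organ = 0.025),
      CRPC = c(prostate = 0.129, lymph_node = 0.242, bone = 0.613, organ = 0.016)),
    base_hazard = 0.004,
    loghr_ctdna = log(7.5),
    loghr_psma = log(6.5),
    followup_max = 50) {
  as.list(environment())
}

#' Simulate a clinical cohort with coupled biomarker and survival structure
#'
#' Pure function of `(n, params, seed)`. The invariants
#' `pet_positive == (psma_tv > 0)` and `ctdna_detected == (ctdna_conc > 0)`
#' hold by construction. The latent severity scores behind PSMA-TV and ctDNA
#' concentration are bivariate Gaussian with correlation
#' `2*sin(pi*spearman_rho/6)`, so on the fully observed scale the population
#' Spearman correlation equals `spearman_rho` exactly; zero-inflation
#' attenuates the rank correlation of the mixed (zero-augmented) variables.
#' Survival is exponential so configured hazard ratios have closed-form truth.
#'
#' @param n Number of patients (>= 0).
#' @param params See [cohort_params()].
#' @param seed Integer seed.
#' @return A data.frame (`cohort_table`) with one row per patient: `id`,
#'   `castration_status`, `psa`, `ctdna_conc`, `ctdna_detected`, `psma_tv`,
#'   `pet_positive`, `dominant_fraction`, `followup_months`, `death_event`.
#' @export
simulate_cohort <- function(n, params = cohort_params(), seed = 1L) {
  stopifnot(n >= 0)
  p <- params
  probs <- c(p$crpc_share, p$pet_pos_prob, p$ctdna_det_prob)
  if (any(probs < 0 | probs > 1)) stop("shares/probabilities must lie in [0,1]")
  cols <- c("id", "castration_status", "psa", "ctdna_conc", "ctdna_detected",
            "psma_tv", "pet_positive", "dominant_fraction",
            "followup_months", "death_event")
  if (n == 0L) {
    out <- data.frame(id = character(0), castration_status = character(0),
                      psa = numeric(0), ctdna_conc = numeric(0),
                      ctdna_detected = logical(0), psma_tv = numeric(0),
                      pet_positive = logical(0), dominant_fraction = character(0),
                      followup_months = numeric(0), death_event = logical(0))
    class(out) <- c("cohort_table", "data.frame")
    return(out)
  }

  withr_seed(seed, {
    status <- ifelse(stats::runif(n) < p$crpc_share, "CRPC", "hsPC")
    psa <- stats::rlnorm(n, p$psa_meanlog[status], p$psa_sdlog[status])

    # Gaussian copula between the two latent severity scores
    rho_l <- 2 * sin(pi * p$spearman_rho / 6)
    z1 <- stats::rnorm(n)
    z2 <- rho_l * z1 + sqrt(1 - rho_l^2) * stats::rnorm(n)
    u1 <- stats::pnorm(z1); u2 <- stats::pnorm(z2)

    pet_positive <- stats::runif(n) < p$pet_pos_prob[status]
    psma_tv <- ifelse(pet_positive,
                      stats::qlnorm(u1, p$psma_meanlog[status], p$psma_sdlog[status]),
                      0)
    ctdna_detected <- stats::runif(n) < p$ctdna_det_prob[status]
    ctdna_conc <- ifelse(ctdna_detected,
                         stats::qlnorm(u2, p$ctdna_meanlog[status], p$ctdna_sdlog[status]),
                         0)

    dominant <- vapply(seq_len(n), function(i) {
      if (!pet_positive[i]) return("none")
      w <- p$dominant_probs[[status[i]]]
      sample(names(w), 1L, prob = w)
    }, character(1))

    high_ct <- ctdna_conc > stats::median(ctdna_conc)
    high_tv <- psma_tv > stats::median(psma_tv)
    hazard <- p$base_hazard * exp(p$loghr_ctdna * high_ct + p$loghr_psma * high_tv)
    t_death <- stats::rexp(n, rate = hazard)
    t_cens <- stats::runif(n, 0, p$followup_max)
    followup <- pmin(t_death, t_cens)
    event <- t_death <= t_cens

    out <- data.frame(
      id = sprintf("P%04d", seq_len(n)),
      castration_status = status, psa = psa,
      ctdna_conc = ctdna_conc, ctdna_detected = ctdna_detected,
      psma_tv = psma_tv, pet_positive = pet_positive,
      dominant_fraction = dominant,
      followup_months = followup, death_event = event,
      stringsAsFactors = FALSE)
    class(out) <- c("cohort_table", "data.frame")
    stopifnot(identical(names(out), cols))
    out
  })
}

#' Write / read a cohort table as CSV
#' @param cohort A `cohort_table`.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$ctdna_detected <- as.logical(out$ctdna_detected)
  out$pet_positive <- as.logical(out$pet_positive)
  out$death_event <- as.logical(out$death_event)
  class(out) <- c("cohort_table", "data.frame")
  out
}
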