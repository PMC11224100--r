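#' Pearson chi-squared test on a contingency table
#'
#' Thin validated wrapper over [stats::chisq.test()]. With `yates = TRUE`
#' and a 2x2 table the continuity correction `|O - E| - 0.5` (floored at 0)
#' is applied; larger tables always use the uncorrected Pearson statistic.
#'
#' @param table Integer matrix, at least 2x2, non-negative cells.
#' @param yates Apply the continuity correction on 2x2 tables. Default TRUE,
#'   the conventional reporting choice for 2x2 discovery-rate comparisons.
#' @return list(statistic, df, p)
#' @export
chi_squared_test <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  check_contingency(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal row/column")
  res <- suppressWarnings(stats::chisq.test(table, correct = yates))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

check_contingency <- function(table) {
  if (!is.matrix(table) || nrow(table) < 2L || ncol(table) < 2L)
    stop("need at least a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("cells must be non-negative integers")
  invisible(table)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p summing hypergeometric probabilities no larger than that of
#' the observed table ([stats::fisher.test()]).
#'
#' @param table 2x2 non-negative integer matrix.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  check_contingency(table)
  if (nrow(table) != 2L || ncol(table) != 2L) stop("need a 2x2 table")
  stats::fisher.test(table)$p.value
}

#' Sample odds ratio with the Woolf log-normal confidence interval
#'
#' `OR = (a*d)/(b*c)` and
#' `CI = exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Tables with a
#' zero cell get the Haldane-Anscombe 0.5 correction on all cells, flagged
#' in the result.
#'
#' @param table 2x2 non-negative integer matrix.
#' @param conf_level Confidence level (default 0.95).
#' @return list(or, ci_low, ci_high, corrected)
#' @export
odds_ratio_woolf <- function(table, conf_level = 0.95) {
  table <- as.matrix(table)
  check_contingency(table)
  if (nrow(table) != 2L || ncol(table) != 2L) stop("need a 2x2 table")
  corrected <- any(table == 0)
  tt <- table + if (corrected) 0.5 else 0
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / tt))
  list(or = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se),
       corrected = corrected)
}

#' Kruskal-Wallis test with Dunn-Bonferroni post-hoc comparisons
#'
#' Global rank-based H with tie correction ([stats::kruskal.test()]); when
#' the global null is rejected at `alpha`, Dunn z-tests on mean ranks are
#' run for every group pair with Bonferroni-multiplied p-values.
#'
#' @param values Numeric measurements.
#' @param groups Group labels, same length.
#' @param bonferroni Multiply pairwise p by the number of comparisons
#'   (default TRUE).
#' @param alpha Gate for running the post-hoc tests (default 0.05).
#' @return list(H, df, p, pairwise) where `pairwise` is a data.frame with
#'   columns group1, group2, z, p_adjusted (NULL when the global test does
#'   not reject).
#' @export
kruskal_wallis_dunn <- function(values, groups, bonferroni = TRUE,
                                alpha = 0.05) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(tabulate(groups) == 0L)) stop("empty group")
  kw <- stats::kruskal.test(values, groups)

  pairwise <- NULL
  if (kw$p.value < alpha) {
    n <- length(values)
    rk <- rank(values)
    mean_rank <- tapply(rk, groups, mean)
    ni <- tabulate(groups)
    ties <- table(values)
    tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
    lv <- levels(groups)
    combs <- utils::combn(seq_along(lv), 2)
    k <- ncol(combs)
    rows <- lapply(seq_len(k), function(m) {
      i <- combs[1, m]; j <- combs[2, m]
      se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[i] + 1 / ni[j]))
      z <- (mean_rank[i] - mean_rank[j]) / se
      p <- 2 * stats::pnorm(-abs(z))
      data.frame(group1 = lv[i], group2 = lv[j], z = unname(z),
                 p_adjusted = min(if (bonferroni) p * k else p, 1))
    })
    pairwise <- do.call(rbind, rows)
  }
  list(H = unname(kw$statistic), df = unname(kw$parameter), p = kw$p.value,
       pairwise = pairwise)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks; `p` from
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return list(rho, p)
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("undefined correlation")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' ROC analysis with the Youden-optimal threshold
#'
#' AUC by the rank (Mann-Whitney) identity with mid-rank tie correction.
#' The threshold maximizes the Youden index `J = sensitivity + specificity
#' - 1` over observed cut-points (predict positive when `score >= t`); ties
#' on J are broken toward higher specificity (the larger cut-point).
#'
#' @param score Continuous marker.
#' @param label Logical outcome (TRUE = positive class).
#' @return list(auc, threshold, sensitivity, specificity)
#' @export
roc_youden <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  rk <- rank(score)
  auc <- (sum(rk[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  cuts <- sort(unique(score))
  best <- list(j = -Inf, threshold = NA_real_, sens = NA_real_, spec = NA_real_)
  for (t in cuts) {
    sens <- sum(label & score >= t) / n1
    spec <- sum(!label & score < t) / n0
    j <- sens + spec - 1
    if (j > best$j + 1e-12 || (abs(j - best$j) <= 1e-12 && spec > best$spec))
      best <- list(j = j, threshold = t, sens = sens, spec = spec)
  }
  list(auc = auc, threshold = best$threshold,
       sensitivity = best$sens, specificity = best$spec)
}

#' Kaplan-Meier curves and the logrank test for a two-group comparison
#'
#' Product-limit curves per group ([survival::survfit()]) and the logrank
#' statistic from observed-versus-expected events over the pooled risk sets
#' ([survival::survdiff()]), p on 1 degree of freedom.
#'
#' @param time Follow-up times (>= 0).
#' @param event Logical event indicator.
#' @param group Two-level grouping.
#' @return list(curves = survfit object, statistic, p)
#' @export
km_logrank <- function(time, event, group) {
  if (any(time < 0)) stop("negative follow-up time")
  if (sum(event) == 0L) stop("no events observed")
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L) stop("need exactly 2 groups")
  df <- data.frame(time = time, event = as.integer(event), group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(curves = fit, statistic = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Multivariate Cox proportional-hazards regression
#'
#' Partial-likelihood maximization with Breslow tie handling
#' ([survival::coxph()]); Wald confidence intervals and p-values per
#' coefficient.
#'
#' @param time,event Follow-up and event indicator.
#' @param covariates data.frame of binary (0/1 or logical) indicators.
#' @return data.frame with one row per covariate: `hr`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
cox_fit <- function(time, event, covariates) {
  covariates <- as.data.frame(lapply(covariates, as.numeric))
  const <- vapply(covariates, function(v) stats::sd(v) == 0, logical(1))
  if (any(const))
    stop("constant covariate: ", paste(names(covariates)[const], collapse = ", "))
  if (sum(event) < ncol(covariates))
    stop("fewer events than covariates")
  df <- cbind(data.frame(.time = time, .event = as.integer(event)), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~", paste(names(covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "breslow",
                         control = survival::coxph.control(eps = 1e-8))
  if (any(!is.finite(coef(fit))) || any(!is.finite(sqrt(diag(fit$var)))))
    stop("Cox fit did not converge or separated on: ",
         paste(names(coef(fit))[!is.finite(coef(fit))], collapse = ", "))
  s <- summary(fit)
  data.frame(covariate = rownames(s$coefficients),
             hr = s$coefficients[, "exp(coef)"],
             ci_low = s$conf.int[, "lower .95"],
             ci_high = s$conf.int[, "upper .95"],
             p = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL)
}

#' Discovery-rate contingency tables by PSA range
#'
#' Cross-tabulates PET positivity and ctDNA detection by PSA range with
#' left-open right-closed intervals, e.g. `(0, 0.5]`. PSA values outside
#' every interval are reported in an `overflow` row rather than dropped.
#'
#' @param cohort A `cohort_table`.
#' @param psa_breaks Strictly increasing interval edges, e.g.
#'   `c(0, 0.5, 1, 2, 3689)`.
#' @return list(pet, ctdna, totals): per-modality data.frames with counts
#'   and row percentages per PSA range, plus overall totals.
#' @export
discovery_table <- function(cohort, psa_breaks = c(0, 0.5, 1, 2, 3689)) {
  if (is.unsorted(psa_breaks, strictly = TRUE))
    stop("psa_breaks must be strictly increasing")
  labels <- sprintf("(%s, %s]", fmt_num(psa_breaks[-length(psa_breaks)]),
                    fmt_num(psa_breaks[-1]))
  rng <- cut(cohort$psa, breaks = psa_breaks, labels = labels, right = TRUE)
  overflow <- sum(is.na(rng))
  rng <- factor(as.character(rng), levels = labels)

  one <- function(flag) {
    pos <- tapply(flag, rng, sum, default = 0L)
    tot <- tapply(flag, rng, length, default = 0L)
    pos[is.na(pos)] <- 0L; tot[is.na(tot)] <- 0L
    df <- data.frame(psa_range = labels, positive = as.integer(pos),
                     negative = as.integer(tot - pos),
                     pct_positive = ifelse(tot > 0, 100 * pos / tot, NA_real_),
                     pct_negative = ifelse(tot > 0, 100 * (tot - pos) / tot, NA_real_),
                     row.names = NULL)
    df
  }
  keep <- !is.na(cut(cohort$psa, breaks = psa_breaks, right = TRUE))
  n_in <- sum(keep)
  list(
    pet = one(cohort$pet_positive),
    ctdna = one(cohort$ctdna_detected),
    totals = data.frame(
      n = n_in, overflow = overflow,
      pet_positive = sum(cohort$pet_positive[keep]),
      pct_pet_positive = if (n_in > 0) 100 * sum(cohort$pet_positive[keep]) / n_in else NA_real_,
      ctdna_positive = sum(cohort$ctdna_detected[keep]),
      pct_ctdna_positive = if (n_in > 0) 100 * sum(cohort$ctdna_detected[keep]) / n_in else NA_real_)
  )
}

#' Median-split grouping with ties going to "low"
#'
#' @param x Numeric marker.
#' @return Factor with levels `low`, `high`; values `<=` the in-sample
#'   median are `low`.
#' @export
median_split <- function(x) {
  factor(ifelse(x > stats::median(x), "high", "low"), levels = c("low", "high"))
}
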