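tabs <- reference_tables()

test_that("chi-squared tests reproduce the reference cohort p-values", {
  # PET discovery by castration status, 2x2 with continuity correction
  expect_equal(chi_squared_test(tabs$pet_by_castration, yates = TRUE)$p,
               0.013, tolerance = 0.05)
  # ctDNA discovery by castration status
  expect_equal(chi_squared_test(tabs$ctdna_by_castration, yates = TRUE)$p,
               0.311, tolerance = 0.01)
  # discovery by PSA range, 4x2 uncorrected Pearson
  expect_equal(chi_squared_test(tabs$ctdna_by_psa, yates = FALSE)$p,
               0.123, tolerance = 0.01)
  expect_lt(chi_squared_test(tabs$pet_by_psa, yates = FALSE)$p, 0.001)
})

test_that("chi-squared handles homogeneity and degenerate margins", {
  res <- chi_squared_test(matrix(c(10, 10, 10, 10), 2), yates = FALSE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(chi_squared_test(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "zero marginal")
})

test_that("uncorrected chi-squared p matches a permutation p within MC error", {
  tab <- tabs$ctdna_by_psa
  p_asy <- chi_squared_test(tab, yates = FALSE)$p
  p_perm <- withr::with_seed(8, suppressWarnings(
    chisq.test(tab, correct = FALSE, simulate.p.value = TRUE, B = 1e5)$p.value))
  expect_lt(abs(p_asy - p_perm), 3 * sqrt(p_asy * (1 - p_asy) / 1e5) + 0.01)
})

fisher_enum <- function(tab) {
  # enumerate all tables with the observed margins; two-sided p sums
  # hypergeometric probabilities <= that of the observed table
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, n - r1, c1)
  p_obs <- dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("Fisher's exact test equals full-margin enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2)), 1)
  t2 <- matrix(c(5, 0, 0, 5), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(t2), fisher_enum(t2), tolerance = 1e-10)
  # property: random tables with n <= 30
  for (s in 1:25) {
    tab <- withr::with_seed(s, matrix(rmultinom(1, sample(8:30, 1),
                                                rep(0.25, 4)), 2))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), fisher_enum(tab), tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(1, 3, 2)), "2x2")
})

test_that("Woolf odds ratio reproduces the reference estimate and CI", {
  res <- odds_ratio_woolf(tabs$pet_by_castration)
  expect_equal(res$or, 0.31, tolerance = 0.02)
  expect_equal(res$ci_low, 0.13, tolerance = 0.04)
  expect_equal(res$ci_high, 0.74, tolerance = 0.01)
  expect_equal(odds_ratio_woolf(matrix(c(10, 10, 10, 10), 2))$or, 1)
  expect_true(odds_ratio_woolf(matrix(c(5, 0, 3, 2), 2, byrow = TRUE))$corrected)
})

test_that("Woolf CI width matches a parametric bootstrap of the log-OR", {
  tab <- tabs$pet_by_castration
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  lor <- withr::with_seed(5, {
    as <- rbinom(1e5, a + b, a / (a + b)); cs <- rbinom(1e5, c + d, c / (c + d))
    log(((as + .5) * (c + d - cs + .5)) / ((a + b - as + .5) * (cs + .5)))
  })
  res <- odds_ratio_woolf(tab)
  or0 <- res$or
  expect_lt(abs(res$ci_low / (or0 * exp(-1.96 * sd(lor))) - 1), 0.1)
  expect_lt(abs(res$ci_high / (or0 * exp(1.96 * sd(lor))) - 1), 0.1)
})

test_that("Kruskal-Wallis H matches hand-computed ranks on a toy", {
  vals <- c(2.9, 3.0, 2.5, 2.6, 3.2, 3.8, 2.7, 4.0, 2.4)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_wallis_dunn(vals, grp)
  rk <- rank(vals)
  n <- 9
  h_hand <- 12 / (n * (n + 1)) *
    sum(tapply(rk, grp, function(r) length(r) * (mean(r) - (n + 1) / 2)^2))
  expect_equal(res$H, h_hand, tolerance = 1e-12)
  expect_error(kruskal_wallis_dunn(vals, rep("a", 9)), "2 groups")
})

test_that("well-separated groups reject globally and in every Dunn pair", {
  vals <- withr::with_seed(3, c(rnorm(20), rnorm(20, 10), rnorm(20, 20)))
  grp <- rep(c("a", "b", "c"), each = 20)
  res <- kruskal_wallis_dunn(vals, grp)
  expect_lt(res$p, 0.001)
  expect_true(all(res$pairwise$p_adjusted < 0.05))
})

test_that("the Kruskal-Wallis type-I error is calibrated near 5%", {
  rejections <- withr::with_seed(10, vapply(1:1000, function(i) {
    kruskal_wallis_dunn(rnorm(60), rep(c("a", "b", "c"), 20))$p < 0.05
  }, logical(1)))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("Spearman correlation matches the classical d^2 formula", {
  x <- c(3.1, 1.2, 5.5, 2.2, 4.9, 6.3, 0.4, 7.7, 9.1, 8.2)
  y <- c(2.0, 1.5, 4.2, 3.9, 5.5, 5.1, 0.9, 8.8, 7.6, 9.9)
  res <- spearman_corr(x, y)
  d <- rank(x) - rank(y)
  expect_equal(res$rho, 1 - 6 * sum(d^2) / (10 * (10^2 - 1)), tolerance = 1e-12)
  expect_equal(spearman_corr(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_corr(1:8, -(1:8))$rho, -1)
  expect_error(spearman_corr(rep(1, 5), 1:5), "undefined")
})

test_that("AUC equals brute-force pair counting and is rank invariant", {
  for (s in 1:10) {
    score <- withr::with_seed(s, round(rnorm(30), 1))  # forces some ties
    label <- withr::with_seed(s + 50, runif(30) < 0.4)
    if (!any(label) || all(label)) next
    res <- roc_youden(score, label)
    pos <- score[label]; neg <- score[!label]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(res$auc, mean(pairs), tolerance = 1e-12)
    # strictly monotone transform leaves the AUC unchanged
    expect_equal(roc_youden(exp(score), label)$auc, res$auc)
  }
})

test_that("the Youden threshold separates perfectly separable classes", {
  score <- c(1, 2, 3, 10, 11, 12)
  label <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  res <- roc_youden(score, label)
  expect_equal(res$auc, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_gt(res$threshold, 3); expect_lte(res$threshold, 10)
  expect_error(roc_youden(score, rep(TRUE, 6)), "both classes")
})

test_that("AUC is near 1/2 when the label is independent of the score", {
  score <- withr::with_seed(9, rnorm(4000))
  label <- withr::with_seed(10, runif(4000) < 0.5)
  expect_lt(abs(roc_youden(score, label)$auc - 0.5), 0.05)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  score <- withr::with_seed(12, rnorm(100))
  label <- withr::with_seed(13, runif(100) < plogis(score))
  got <- roc_youden(score, label)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(label, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("identical survival groups give a zero logrank statistic", {
  time <- c(5, 8, 12, 20, 5, 8, 12, 20)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  grp <- rep(c("a", "b"), each = 4)
  res <- km_logrank(time, event, grp)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  expect_error(km_logrank(time, rep(FALSE, 8), grp), "no events")
})

test_that("KM curves are proper survival curves", {
  co <- simulate_cohort(150, seed = 41)
  res <- km_logrank(co$followup_months, co$death_event,
                    median_split(co$psma_tv))
  s <- res$curves$surv
  expect_true(all(s <= 1 + 1e-12))
  for (grp_surv in split(s, rep(seq_along(res$curves$strata),
                                res$curves$strata)))
    expect_true(all(diff(grp_surv) <= 1e-12))
})

test_that("the logrank statistic matches a hand-computed O-E table", {
  # 8 subjects, no censoring before the last event
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- rep(TRUE, 8)
  grp <- c("a", "a", "b", "a", "b", "b", "a", "b")
  o_minus_e <- 0; v <- 0
  for (t in time) {
    at_risk <- time >= t
    n <- sum(at_risk); n_a <- sum(at_risk & grp == "a")
    d <- sum(time == t)
    o_minus_e <- o_minus_e + sum(time == t & grp == "a") - d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  expect_equal(km_logrank(time, event, grp)$statistic, o_minus_e^2 / v,
               tolerance = 1e-9)
})

test_that("Cox regression recovers a known hazard ratio", {
  n <- 2000
  x <- withr::with_seed(6, rbinom(n, 1, 0.5))
  t_death <- withr::with_seed(7, rexp(n, rate = 0.05 * exp(log(2) * x)))
  cens <- withr::with_seed(8, runif(n, 0, 40))
  res <- cox_fit(pmin(t_death, cens), t_death <= cens, data.frame(x = x))
  expect_lt(abs(res$hr - 2) / 2, 0.15)
  expect_error(cox_fit(pmin(t_death, cens), t_death <= cens,
                       data.frame(x = rep(1, n))), "constant covariate")
})

test_that("discovery tables reproduce the reference cohort percentages", {
  # rebuild a cohort with exactly the reference marginal counts
  mk <- function(psa, pet_pos, pet_n, ct_pos, n) {
    data.frame(psa = rep(psa, n),
               pet_positive = rep(c(TRUE, FALSE), c(pet_pos, n - pet_pos)),
               ctdna_detected = rep(c(TRUE, FALSE), c(ct_pos, n - ct_pos)))
  }
  co <- rbind(mk(0.3, 13, 10, 3, 23), mk(0.8, 5, 6, 2, 11),
              mk(1.5, 12, 3, 6, 15), mk(10, 72, 9, 29, 81))
  res <- discovery_table(co, psa_breaks = c(0, 0.5, 1, 2, 3689))
  expect_equal(res$totals$n, 130)
  expect_equal(res$totals$pct_pet_positive, 78.46, tolerance = 0.01)
  expect_equal(res$pet$pct_positive, c(56.52, 45.45, 80.00, 88.89),
               tolerance = 0.01)
  expect_equal(res$ctdna$pct_positive, c(13.04, 18.18, 40.00, 35.80),
               tolerance = 0.01)
  expect_equal(res$pet$positive + res$pet$negative,
               res$ctdna$positive + res$ctdna$negative)
  # row percentages always sum to 100
  expect_equal(res$pet$pct_positive + res$pet$pct_negative, rep(100, 4))

  empty <- discovery_table(data.frame(psa = numeric(0),
                                      pet_positive = logical(0),
                                      ctdna_detected = logical(0)))
  expect_true(all(empty$pet$positive == 0))
  expect_error(discovery_table(co, psa_breaks = c(1, 0.5)), "increasing")
})

test_that("median splits send ties to the low group", {
  g <- median_split(c(1, 2, 3, 4, 5))
  expect_equal(as.vector(table(g)), c(3, 2))  # ceiling(n/2) low
  g2 <- median_split(c(1, 1, 1, 5))
  expect_equal(sum(g2 == "low"), 3)
})
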