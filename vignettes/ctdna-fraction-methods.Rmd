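---
title: "Estimating ctDNA fractions from low-pass WGS bin counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ctDNA fractions from low-pass WGS bin counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cell-free DNA (cfDNA) in plasma carries a tumor-derived subset — circulating
tumor DNA (ctDNA) — whose proportion, the tumor fraction *tf*, is both a
detection signal and a prognostic biomarker in prostate cancer. At low-pass
whole-genome sequencing depths (~0.1–0.5x) point mutations are not callable,
but segmental copy-number variation (CNV), a genomic hallmark of prostate
cancer, leaves a dose-dependent footprint in the read depth of large genomic
bins. `liquidfrac` estimates *tf* from read counts in 500 kb bins by modeling
each bin count as a negative-binomial draw whose mean mixes two diploid
copies of normal cfDNA with *c* tumor copies at fraction *tf*:

$$
\mu_b(c) \;=\; w_b \,\frac{(1-tf)\cdot 2 + tf\cdot c_b}{\bar{P}},
\qquad
\bar{P} = \frac{\sum_b w_b\,[(1-tf)\,2 + tf\,c_b]}{\sum_b w_b},
$$

where $w_b$ is the GC- and library-size-adjusted expected count of bin $b$
under a copy-neutral genome. The divisor $\bar{P}$ mean-centres the profile
at 1: read counts carry only *relative* copy ratio, there is no absolute
ploidy anchor in depth data. This identifiability limit is the reason the
procedure is iterative — the fraction is only defined relative to a
copy-number segmentation, and the segmentation is only callable given a
fraction.

## The estimation procedure

1. **Normalization.** Counts are scaled by library size and corrected for
   GC bias by a robust local regression (loess, `family = "symmetric"`,
   span 0.3) of count on GC fraction; profiles with fewer than 1,000 usable
   bins fall back to medians within GC deciles. Bins more than 8 MADs from
   the median ratio are excluded, and ratios are re-centred to weighted
   mean 1. Masked bins (short terminal bins, missing or out-of-range GC)
   are excluded but retained positionally so indices stay aligned.

2. **Density initialization.** A kernel density estimate (Gaussian kernel,
   Silverman's bandwidth) of the included ratios is scanned for modes. The
   dominant mode is read as copy-neutral; the nearest secondary mode with at
   least 10% of the peak density is read as a one-copy change, giving
   $tf_0 = 2\,|m_1 - m_0|$ (clipped to [0.01, 0.95]). Unimodal profiles
   yield no initial value and proceed directly to the default-fraction pass.

3. **Copy-number decoding.** A hidden Markov model over copy states
   {0, 1, 2, 3, 4} with negative-binomial emissions (shared dispersion),
   per-bin stay probability $1 - 10^{-3}$, uniformly spread off-diagonal
   mass, and chromosome-boundary resets. Both forward–backward posteriors
   and the Viterbi path are computed; reported per-bin states are the
   posterior argmax (tie-broken toward copy 2), a marginally smoothed
   reading of the whole profile. Richer dynamic Bayesian networks with
   segment-level latent variables are conceivable here; we adopt the
   stationary HMM as the minimal such model consistent with binned count
   data.

4. **Fraction refitting.** Given a fixed path, *tf* is refit by bounded
   golden-section search of the negative-binomial likelihood on [0, 1]
   (tolerance $10^{-4}$). Decoding and refitting alternate until the
   fraction moves less than $10^{-3}$ or 20 iterations are reached.

5. **Default-fraction pass.** If a pass calls no non-neutral segment, the
   fraction is set once to the default 0.05 and decoding repeated; if still
   nothing is called the sample is reported `not_detected` with *tf* = 0.

6. **Noise gate.** Residuals of the primary fit (observed minus fitted
   ratio) are compared against residuals from a noise model: the same bin
   data with bin order randomly permuted, refit with the identical
   procedure; three permutation replicates are pooled. A two-sample
   Kolmogorov–Smirnov test on the absolute residuals must reject
   ($p \le 0.05$) — the fitted CNV structure must explain the data
   significantly better than it explains its own permutation — otherwise
   the sample is excluded as noise.

7. **Artifact filter.** Samples whose called deletions are predominantly
   peri-centromeric (more than half of deletion bins centromere-flagged or
   within 2 Mb of a flagged bin) are excluded as a technical artifact.

### Coordinate ascent and the tracked objective

The alternation is a true coordinate ascent on the joint path likelihood
$\log P(x, s \mid tf)$: the Viterbi step maximizes it over paths $s$ at
fixed *tf*, the refit maximizes the emission term over *tf* at fixed path
(transitions do not depend on *tf*), and a refit result worse than the
incumbent is discarded (a bounded 1-D search on a flat likelihood can
otherwise step backwards). The iteration log therefore shows a non-decreasing
objective within each ascent. Reported states remain the posterior argmax,
which coincides with the Viterbi path in all but pathological ties.

### The half-fraction alias

A profile whose alterations are all single-copy events is *exactly* aliased
with a solution at half the fraction that calls the same segments as
two-copy events (copy 1 at *tf* is indistinguishable from copy 0 at
*tf*/2). When the converged path contains extreme states (0 or 4), the
estimator runs a second ascent started at twice the fraction and compares
joint likelihoods. Genuine two-copy segments favor the half-fraction
solution by large margins (tens to hundreds of log units), so near-ties
(within 10 log units) are resolved toward the near-neutral solution:
single-copy alterations are the parsimonious biological reading. The 10-unit
margin sits well below the evidence a real 500 kb-resolution two-copy
segment contributes and well above segmentation jitter.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `bin_size` | 500,000 bp | counting resolution; the scale at which lpWGS depth carries CNV signal |
| `outlier_k` | 8 MADs | ratio outlier exclusion |
| `stay_prob` | 1 − 10⁻³ | per-bin probability of keeping the copy state; sets the ~500 kb-scale segment persistence |
| `states` | 0:4 | copy-number support; two-copy gains/losses bound the model |
| `dispersion` | estimated | NB size; method-of-moments on the central 80% of ratios with truncation correction, clamped to [1, 10⁶] |
| `tf_default` | 0.05 | fraction re-injected when nothing is called |
| `ks_alpha` | 0.05 | noise-gate significance level |
| `n_permutations` | 3 | pooled permuted-bin noise replicates |
| `centromere_max_share` | 0.5 | peri-centromeric deletion share that flags an artifact |
| `tf_tol`, `max_iter` | 10⁻³, 20 | convergence control |

## What the simulator emulates — and what it does not

`simulate_cnv_profile()` draws alternating neutral/altered segments with
geometric lengths (mean altered length 50 Mb by default — advanced prostate
cancers carry chromosome-arm-scale events) and altered copies from a
loss-heavy distribution over {0, 1, 3, 4}. `simulate_cfdna_counts()` draws
negative-binomial counts at mean depth 500 per bin (roughly 0.1–0.2x
coverage) with a quadratic GC-bias curve and NB size 500 (variance about
twice Poisson at that depth, typical of 500 kb bins after alignment
filtering). These defaults are the package's fixed study conditions and are
not adjusted per experiment.

The simulator reproduces the features the estimator must undo — segmental
structure, GC bias, overdispersion, the relative-ratio identifiability limit
— but not: fragment-length or nucleosome-footprint signal, mappability
artifacts, replication-timing waves, subclonal mixtures, or focal
amplifications below bin resolution. Passing recovery tests on simulated
data therefore demonstrates correctness of the inference machinery under
its own model assumptions, not clinical performance on patient plasma.

`simulate_cohort()` generates the clinical-covariate layer: a roughly
balanced hsPC/CRPC split, log-normal PSA per status, zero-inflated
log-normal PSMA-positive tumor volume, ctDNA concentration coupled to
PSMA-TV through a Gaussian copula, and exponential survival driven by
above-median ctDNA and PSMA-TV burden (so configured hazard ratios have
closed-form truth). The copula is parameterized directly by the target
Spearman correlation via $\rho_{latent} = 2\sin(\pi\rho_S/6)$; the coupling
is defined *within* castration status — pooling statuses with different
marginals, or re-introducing zero-inflation, attenuates the realized rank
correlation of the mixed variables, which is the expected behavior of
zero-inflated biomarkers. ctDNA detection is drawn independently of tumor
volume given castration status; this is a deliberate simplification (the
detection–volume coupling in real cohorts is carried by the concentration
coupling here).

## Numerical choices and degenerate inputs

- All randomness is seeded explicitly; generators are pure functions of
  (parameters, seed) and restore the caller's RNG state.
- Forward–backward runs in scaled linear space with per-bin renormalization;
  Viterbi in log space. Excluded bins contribute flat emissions so the
  chain passes through them without evidence.
- Emission means are floored at $10^{-8}$ so copy 0 at *tf* = 1 stays
  finite; posterior ties (all means equal at *tf* = 0) resolve to copy 2.
- All-zero samples, profiles with fewer than 100 GC-annotated bins, and
  profiles with fewer than 50 residuals for QC are rejected with explicit
  errors rather than degraded output.
- Constant-GC profiles skip the GC fit (library-size scaling only).
- The per-run problem sizes used by the validation suite — a 6,000-bin
  synthetic genome, 20 replicates per fraction, 200 null replicates, 5,000
  simulated patients — were chosen once as the smallest sizes at which the
  Monte-Carlo error of each check is comfortably below its tolerance.

## Statistics module conventions

The comparative statistics mirror standard biomarker-study reporting:
2×2 discovery-rate comparisons use the Yates-corrected chi-squared, larger
tables the uncorrected Pearson statistic; odds ratios use the Woolf
log-normal interval (Haldane 0.5 correction on zero cells, flagged);
Kruskal–Wallis is followed by Dunn's z-tests with Bonferroni multiplication
only when the global test rejects; ROC thresholds maximize the Youden index
with ties broken toward higher specificity; survival comparisons use
Kaplan–Meier/logrank and Cox regression with Breslow tie handling; PSA
strata are left-open right-closed intervals; median splits send ties to the
low group. The two-sample KS test uses the exact (permutation) null when
$n_a n_b \le 10{,}000$ and the asymptotic Kolmogorov distribution otherwise.

## Known limitations

- A stationary HMM cannot represent segment-level latent structure a richer
  dynamic Bayesian network could; boundary bins of short segments are the
  main casualty.
- The fraction is biased toward 0 for profiles whose true alterations fall
  below the noise gate's power, and fractions below ~0.03 at default depth
  are generally not callable — consistent with the detection limits reported
  for lpWGS CNV-based ctDNA assays.
- Dispersion is shared across states and estimated once; strongly amplified
  regions with state-dependent variance are mildly mis-weighted.
- The exact-alias tie rule (prefer single-copy explanations) is a
  convention; a genome whose events are truly all two-copy at fraction
  *tf*/2 will be reported at *tf*.

## A worked example

```{r, eval = FALSE}
library(liquidfrac)

grid   <- simulate_bin_grid(n_chrom = 20, chrom_size = 1.5e8, seed = 5)
truth  <- simulate_cnv_profile(grid, tumor_fraction = 0.3, seed = 7)
counts <- simulate_cfdna_counts(grid, truth, seed = 8)

est <- estimate_ctdna(counts, grid, estimate_config(seed = 11))
est
#> fraction_estimate 'sim': tf = 0.308, status = detected (5 iterations)
#>   KS gate: D = 0.040, p = 1.26e-06; centromeric deletion share 0.00
```
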