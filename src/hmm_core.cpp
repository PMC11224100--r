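#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over a left-to-right chain with uniform-off-diagonal
// transitions. `logE` holds per-bin log emission densities (n x K); `chrom`
// is an integer run id — whenever it changes, the chain resets to the uniform
// initial distribution (independent chromosomes). Returns per-bin posteriors
// and the total marginal log-likelihood.
// [[Rcpp::export]]
List fb_posterior(NumericMatrix logE, double stay, IntegerVector chrom) {
  const int n = logE.nrow(), K = logE.ncol();
  if (K < 2) stop("need at least 2 states");
  const double off = (1.0 - stay) / (K - 1);
  NumericMatrix alpha(n, K), beta(n, K), post(n, K);
  NumericVector scale(n), emax(n);
  NumericMatrix e(n, K);

  for (int t = 0; t < n; ++t) {
    double m = logE(t, 0);
    for (int k = 1; k < K; ++k) if (logE(t, k) > m) m = logE(t, k);
    emax[t] = m;
    for (int k = 0; k < K; ++k) e(t, k) = std::exp(logE(t, k) - m);
  }

  double loglik = 0.0;
  for (int t = 0; t < n; ++t) {
    double s = 0.0;
    if (t == 0 || chrom[t] != chrom[t - 1]) {
      for (int k = 0; k < K; ++k) { alpha(t, k) = e(t, k) / K; s += alpha(t, k); }
    } else {
      for (int k = 0; k < K; ++k) {
        // previous scaled alpha sums to 1: predictive = off + (stay-off)*a_k
        double pred = off + (stay - off) * alpha(t - 1, k);
        alpha(t, k) = pred * e(t, k);
        s += alpha(t, k);
      }
    }
    scale[t] = s;
    if (s <= 0) stop("forward underflow");
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    loglik += std::log(s) + emax[t];
  }

  for (int t = n - 1; t >= 0; --t) {
    if (t == n - 1 || chrom[t + 1] != chrom[t]) {
      for (int k = 0; k < K; ++k) beta(t, k) = 1.0;
    } else {
      double tot = 0.0;
      NumericVector eb(K);
      for (int j = 0; j < K; ++j) { eb[j] = e(t + 1, j) * beta(t + 1, j); tot += eb[j]; }
      for (int k = 0; k < K; ++k)
        beta(t, k) = (off * tot + (stay - off) * eb[k]) / scale[t + 1];
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) { post(t, k) = alpha(t, k) * beta(t, k); s += post(t, k); }
    for (int k = 0; k < K; ++k) post(t, k) /= s;
  }

  return List::create(_["posterior"] = post, _["loglik"] = loglik);
}

// Viterbi decoding under the same model; ties prefer staying in the previous
// state, then the lowest state index. Returns the 0-based path and the joint
// log-probability log P(x, path) including initial and transition terms.
// [[Rcpp::export]]
List viterbi_path(NumericMatrix logE, double stay, IntegerVector chrom) {
  const int n = logE.nrow(), K = logE.ncol();
  if (K < 2) stop("need at least 2 states");
  const double lstay = std::log(stay), loff = std::log((1.0 - stay) / (K - 1));
  const double linit = -std::log((double)K);
  NumericMatrix delta(n, K);
  IntegerMatrix from(n, K);

  for (int t = 0; t < n; ++t) {
    if (t == 0 || chrom[t] != chrom[t - 1]) {
      for (int k = 0; k < K; ++k) { delta(t, k) = linit + logE(t, k); from(t, k) = -1; }
    } else {
      // max over predecessors: either stay (k==j) or come from the best other
      for (int j = 0; j < K; ++j) {
        double best = delta(t - 1, j) + lstay;
        int arg = j;
        for (int k = 0; k < K; ++k) {
          if (k == j) continue;
          double v = delta(t - 1, k) + loff;
          if (v > best + 1e-12) { best = v; arg = k; }
        }
        delta(t, j) = best + logE(t, j);
        from(t, j) = arg;
      }
    }
  }

  IntegerVector path(n);
  double logp = 0.0;
  int t = n - 1;
  while (t >= 0) {
    // find start of this chromosome segment
    int s = t;
    while (s > 0 && chrom[s] == chrom[s - 1]) --s;
    int arg = 0;
    for (int k = 1; k < K; ++k) if (delta(t, k) > delta(t, arg) + 1e-12) arg = k;
    logp += delta(t, arg);
    path[t] = arg;
    for (int u = t; u > s; --u) { path[u - 1] = from(u, path[u]); }
    t = s - 1;
  }
  return List::create(_["path"] = path, _["log_joint"] = logp);
}
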