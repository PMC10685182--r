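#include <Rcpp.h>
using namespace Rcpp;

// Monte Carlo exact test of Hardy-Weinberg equilibrium on a multi-allelic
// genotype sample.
//
// Conditional on the allele counts, a uniformly random pairing of the 2n
// allele copies into n genotypes induces exactly the null distribution of
// genotype tables,
//   P(table) = n! prod(m_i!) 2^H / ( (2n)! prod(n_ij!) ),
// so the chain performs random transpositions of allele copies between
// individuals (always accepted: the target on labelled copy arrangements
// is uniform) and scores each visited table against the observed one by
// the variable part of log P(table),  H log 2 - sum(lgamma(n_ij + 1)).
// The p-value is the proportion of visited tables no more probable than
// the observed table, with a +1/+1 correction; its Monte Carlo standard
// error is estimated by batch means.

static inline int cell(int i, int j, int k) {
  if (i > j) std::swap(i, j);
  return i * k + j;
}

// [[Rcpp::export(name = ".hwe_chain")]]
List hwe_chain(IntegerVector a, IntegerVector b, int k,
               int dememorization, int steps, int nbatch = 50) {
  int n = a.size();
  std::vector<int> cnt((size_t)k * k, 0);
  int H = 0;
  double sumLg = 0.0;  // sum of lgamma(n_ij + 1)
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  for (int i = 0; i < n; ++i) {
    cnt[cell(av[i], bv[i], k)]++;
    if (av[i] != bv[i]) H++;
  }
  for (int i = 0; i < k; ++i)
    for (int j = i; j < k; ++j) sumLg += R::lgammafn(cnt[cell(i, j, k)] + 1.0);
  const double LOG2 = std::log(2.0);
  double curLog = H * LOG2 - sumLg;
  const double obsLog = curLog;
  const double tol = 1e-9;

  long long hits = 0;
  int batch_size = steps / nbatch;
  if (batch_size < 1) { batch_size = steps; nbatch = 1; }
  NumericVector batch_p(nbatch);
  long long batch_hits = 0;
  int ib = 0, in_batch = 0;

  int total = dememorization + steps;
  for (int s = 0; s < total; ++s) {
    int u = (int)(unif_rand() * n);
    int v = (int)(unif_rand() * (n - 1));
    if (v >= u) v++;
    bool pu = unif_rand() < 0.5, pv = unif_rand() < 0.5;
    int &xu = pu ? av[u] : bv[u];
    int &xv = pv ? av[v] : bv[v];
    if (xu != xv) {
      int c1 = cell(av[u], bv[u], k), c2 = cell(av[v], bv[v], k);
      int dH = -((av[u] != bv[u]) + (av[v] != bv[v]));
      double delta = 0.0;
      delta += R::lgammafn(cnt[c1] + 1.0) - R::lgammafn((double)cnt[c1]);
      cnt[c1]--;
      delta += R::lgammafn(cnt[c2] + 1.0) - R::lgammafn((double)cnt[c2]);
      cnt[c2]--;
      std::swap(xu, xv);
      int c3 = cell(av[u], bv[u], k), c4 = cell(av[v], bv[v], k);
      dH += (av[u] != bv[u]) + (av[v] != bv[v]);
      cnt[c3]++;
      delta -= R::lgammafn(cnt[c3] + 1.0) - R::lgammafn((double)cnt[c3]);
      cnt[c4]++;
      delta -= R::lgammafn(cnt[c4] + 1.0) - R::lgammafn((double)cnt[c4]);
      curLog += dH * LOG2 + delta;
      H += dH;
    }
    if (s >= dememorization) {
      bool hit = curLog <= obsLog + tol;
      hits += hit;
      batch_hits += hit;
      if (++in_batch == batch_size && ib < nbatch) {
        batch_p[ib++] = (double)batch_hits / batch_size;
        batch_hits = 0;
        in_batch = 0;
      }
    }
  }
  double p = (double)(hits + 1) / (double)(steps + 1);
  double se = NA_REAL;
  if (ib > 1) {
    double m = 0.0;
    for (int i = 0; i < ib; ++i) m += batch_p[i];
    m /= ib;
    double v2 = 0.0;
    for (int i = 0; i < ib; ++i) v2 += (batch_p[i] - m) * (batch_p[i] - m);
    se = std::sqrt(v2 / (ib - 1) / ib);
  }
  return List::create(_["p_value"] = p, _["se"] = se,
                      _["hits"] = (double)hits, _["steps"] = (double)steps,
                      _["obs_log_prob"] = obsLog);
}
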