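#include <Rcpp.h>
using namespace Rcpp;

// Extrinsic metric evaluations from an r x k contingency table flattened
// column-major in `cont`, with row sums a, col sums b, total N. Conventions
// match the R scalar implementations (natural log; degenerate NMI: both
// trivial -> 1, one trivial -> 0; ARI zero denominator -> 1).
static void metrics_from_table(const std::vector<double>& cont,
                               const std::vector<double>& a,
                               const std::vector<double>& b,
                               double N, int r, int k,
                               double& purity, double& nmi, double& ari) {
  // two-way harmonic purity
  double su = 0.0, sv = 0.0;
  for (int i = 0; i < r; ++i) {
    double m = 0.0;
    for (int j = 0; j < k; ++j) m = std::max(m, cont[j * r + i]);
    su += m;
  }
  for (int j = 0; j < k; ++j) {
    double m = 0.0;
    for (int i = 0; i < r; ++i) m = std::max(m, cont[j * r + i]);
    sv += m;
  }
  double u = su / N, v = sv / N;
  purity = (u + v > 0.0) ? 2.0 * u * v / (u + v) : 0.0;

  // NMI with plug-in probabilities, natural log
  double Ha = 0.0, Hb = 0.0, I = 0.0;
  for (int i = 0; i < r; ++i)
    if (a[i] > 0.0) Ha -= (a[i] / N) * std::log(a[i] / N);
  for (int j = 0; j < k; ++j)
    if (b[j] > 0.0) Hb -= (b[j] / N) * std::log(b[j] / N);
  for (int j = 0; j < k; ++j)
    for (int i = 0; i < r; ++i) {
      double nij = cont[j * r + i];
      if (nij > 0.0)
        I += (nij / N) * std::log(nij * N / (a[i] * b[j]));
    }
  if (Ha == 0.0 && Hb == 0.0) nmi = 1.0;
  else if (Ha == 0.0 || Hb == 0.0) nmi = 0.0;
  else nmi = I / ((Ha + Hb) / 2.0);

  // ARI from pair counts
  double sum_nij = 0.0, sum_a = 0.0, sum_b = 0.0;
  for (int j = 0; j < k; ++j)
    for (int i = 0; i < r; ++i) {
      double nij = cont[j * r + i];
      sum_nij += nij * (nij - 1.0) / 2.0;
    }
  for (int i = 0; i < r; ++i) sum_a += a[i] * (a[i] - 1.0) / 2.0;
  for (int j = 0; j < k; ++j) sum_b += b[j] * (b[j] - 1.0) / 2.0;
  double npairs = N * (N - 1.0) / 2.0;
  double expected = sum_a * sum_b / npairs;
  double denom = 0.5 * (sum_a + sum_b) - expected;
  ari = (denom == 0.0) ? 1.0 : (sum_nij - expected) / denom;
}

// All-pairs extrinsic distances (1 - similarity) for a cohort of partitions.
// `labels` is n_subj x n_nodes with dense integer labels 1..k per row.
// Returns purity / nmi / ari distance matrices in one pass (one shared
// contingency table per subject pair).
// [[Rcpp::export]]
List pairwise_extrinsic_cpp(IntegerMatrix labels) {
  const int n = labels.nrow(), N = labels.ncol();
  std::vector<int> kmax(n, 0);
  for (int s = 0; s < n; ++s)
    for (int v = 0; v < N; ++v)
      kmax[s] = std::max(kmax[s], labels(s, v));

  NumericMatrix dp(n, n), dn(n, n), da(n, n);
  for (int s1 = 0; s1 < n; ++s1) {
    for (int s2 = s1 + 1; s2 < n; ++s2) {
      int r = kmax[s1], k = kmax[s2];
      std::vector<double> cont(r * k, 0.0), a(r, 0.0), b(k, 0.0);
      for (int v = 0; v < N; ++v) {
        int i = labels(s1, v) - 1, j = labels(s2, v) - 1;
        cont[j * r + i] += 1.0;
        a[i] += 1.0;
        b[j] += 1.0;
      }
      double purity, nmi, ari;
      metrics_from_table(cont, a, b, (double)N, r, k, purity, nmi, ari);
      dp(s1, s2) = dp(s2, s1) = 1.0 - purity;
      dn(s1, s2) = dn(s2, s1) = 1.0 - nmi;
      da(s1, s2) = da(s2, s1) = 1.0 - ari;
    }
  }
  return List::create(_["purity"] = dp, _["nmi"] = dn, _["ari"] = da);
}
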