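#include <Rcpp.h>
using namespace Rcpp;

// Simulated annealing for the Potts spinglass Hamiltonian
//   H(sigma) = -sum_{i<j} (A_ij - gamma * k_i k_j / 2m) delta(sigma_i, sigma_j)
// Geometric cooling from t0 by factor `cool`, `sweeps` sweeps of n proposals
// per temperature level, stopping at t_min or when a whole level is frozen
// (no accepted move). Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List spinglass_anneal_cpp(NumericMatrix A, int q, double gamma,
                          double t0, double t_min, double cool, int sweeps) {
  const int n = A.nrow();
  NumericVector k(n);
  double two_m = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += A(i, j);
    k[i] = s;
    two_m += s;
  }
  // coupling J_ij = A_ij - gamma * k_i k_j / 2m; H = -sum_{i<j} J_ij delta
  NumericMatrix J(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      J(i, j) = A(i, j) - gamma * k[i] * k[j] / two_m;

  IntegerVector spin(n);
  for (int i = 0; i < n; ++i)
    spin[i] = (int)(unif_rand() * q);  // 0..q-1

  double H = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (spin[i] == spin[j]) H -= J(i, j);

  IntegerVector best = clone(spin);
  double bestH = H;
  bool frozen = false;

  for (double T = t0; T >= t_min; T *= cool) {
    int accepted = 0;
    const int proposals = sweeps * n;
    for (int it = 0; it < proposals; ++it) {
      int i = (int)(unif_rand() * n);
      int s_old = spin[i];
      int s_new = (int)(unif_rand() * (q - 1));
      if (s_new >= s_old) ++s_new;  // uniform over the other q-1 states
      // dH = -sum_{j != i} J_ij ([spin_j == s_new] - [spin_j == s_old])
      double dH = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        if (spin[j] == s_new) dH -= J(i, j);
        else if (spin[j] == s_old) dH += J(i, j);
      }
      if (dH <= 0.0 || unif_rand() < std::exp(-dH / T)) {
        spin[i] = s_new;
        H += dH;
        ++accepted;
        if (H < bestH) {
          bestH = H;
          best = clone(spin);
        }
      }
    }
    if (accepted == 0) { frozen = true; break; }
  }

  // relabel best state densely 1..n_used in order of first appearance
  IntegerVector out(n);
  std::vector<int> seen;
  for (int i = 0; i < n; ++i) {
    int lab = -1;
    for (size_t s = 0; s < seen.size(); ++s)
      if (seen[s] == best[i]) { lab = (int)s; break; }
    if (lab < 0) { seen.push_back(best[i]); lab = (int)seen.size() - 1; }
    out[i] = lab + 1;
  }
  return List::create(_["membership"] = out,
                      _["energy"] = bestH,
                      _["frozen"] = frozen);
}
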