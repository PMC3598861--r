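#include <Rcpp.h>
using namespace Rcpp;

// Sequential (Glauber) dynamics on binary {0,1} units with energy
// E(s) = -1/2 sum_{i!=j} w_ij s_i s_j + sum_i theta_i s_i.
// Local fields h_i = sum_j w_ij s_j - theta_i are maintained incrementally:
// an elementary step touches O(1) unless the chosen unit flips (O(N)).
// One Monte Carlo step (MCS) = N elementary moves. Frozen units (degenerate
// thresholds) keep their value and are never selected. Uses R's RNG so runs
// are reproducible under set.seed().

// [[Rcpp::export]]
IntegerMatrix glauber_chain_cpp(NumericMatrix W, NumericVector theta,
                                double temperature, IntegerVector init,
                                int n_mcs, LogicalVector frozen) {
  int n = W.nrow();
  if (temperature <= 0) stop("temperature must be positive");
  std::vector<int> free_idx;
  for (int i = 0; i < n; ++i) if (!frozen[i]) free_idx.push_back(i);
  int nf = free_idx.size();
  if (nf == 0) stop("all units are frozen");

  std::vector<int> s(init.begin(), init.end());
  std::vector<double> h(n);
  for (int i = 0; i < n; ++i) {
    double acc = -theta[i];
    for (int j = 0; j < n; ++j) acc += W(i, j) * s[j];
    h[i] = acc;
  }

  IntegerMatrix out(n, n_mcs);
  for (int mcs = 0; mcs < n_mcs; ++mcs) {
    for (int step = 0; step < n; ++step) {
      int i = free_idx[(int)(unif_rand() * nf) % nf];
      double p1 = 1.0 / (1.0 + std::exp(-h[i] / temperature));
      int snew = (unif_rand() < p1) ? 1 : 0;
      if (snew != s[i]) {
        double ds = snew - s[i];
        s[i] = snew;
        for (int j = 0; j < n; ++j) h[j] += W(j, i) * ds;
      }
    }
    for (int i = 0; i < n; ++i) out(i, mcs) = s[i];
  }
  return out;
}

// Zero-temperature asynchronous relaxation: s_i <- 1 iff h_i > 0, 0 iff
// h_i < 0, unchanged on ties. Stops early once no unit wants to move
// (checked once per MCS via the maintained fields).

// [[Rcpp::export]]
List zero_t_relax_cpp(NumericMatrix W, NumericVector theta,
                      IntegerVector init, int n_mcs) {
  int n = W.nrow();
  std::vector<int> s(init.begin(), init.end());
  std::vector<double> h(n);
  for (int i = 0; i < n; ++i) {
    double acc = -theta[i];
    for (int j = 0; j < n; ++j) acc += W(i, j) * s[j];
    h[i] = acc;
  }
  int mcs_done = 0;
  bool fixed = false;
  for (int mcs = 0; mcs < n_mcs && !fixed; ++mcs) {
    for (int step = 0; step < n; ++step) {
      int i = (int)(unif_rand() * n) % n;
      int snew = (h[i] > 0) ? 1 : (h[i] < 0 ? 0 : s[i]);
      if (snew != s[i]) {
        double ds = snew - s[i];
        s[i] = snew;
        for (int j = 0; j < n; ++j) h[j] += W(j, i) * ds;
      }
    }
    ++mcs_done;
    fixed = true;
    for (int i = 0; i < n; ++i) {
      if ((h[i] > 0 && s[i] == 0) || (h[i] < 0 && s[i] == 1)) {
        fixed = false;
        break;
      }
    }
  }
  return List::create(_["state"] = IntegerVector(s.begin(), s.end()),
                      _["mcs"] = mcs_done, _["fixed_point"] = fixed);
}
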