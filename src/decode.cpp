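#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Cross-temporal accuracy matrix for one pseudotrial array
// (units x conditions x pseudotrials x bins, column-major), using
// leave-one-pseudotrial-out cross-validation and the maximum-correlation
// classifier.  Per fold and training bin tp1, unit means/SDs are computed
// from the training pseudotrials over all conditions and applied to both
// the condition templates and the test vectors at every test bin tp2
// (zero-SD units are dropped from that fold/bin).  Exact correlation ties
// are broken uniformly at random with R's RNG.

// [[Rcpp::export]]
NumericMatrix decode_accuracy_cpp(NumericVector psv, IntegerVector dims) {
  const int nu = dims[0], nc = dims[1], np = dims[2], nb = dims[3];
  auto at = [&](int u, int c, int p, int b) {
    return psv[u + (R_xlen_t)nu * (c + (R_xlen_t)nc * (p + (R_xlen_t)np * b))];
  };
  NumericMatrix acc(nb, nb);
  const double ninf = -std::numeric_limits<double>::infinity();
  std::vector<double> mu(nu * nb), sdv(nu * nb), templ(nu * nc * nb);
  std::vector<double> T, Tnorm(nc), x;
  std::vector<int> ok, ties;

  for (int f = 0; f < np; ++f) {
    const int ntr = nc * (np - 1);
    for (int b = 0; b < nb; ++b) {
      for (int u = 0; u < nu; ++u) {
        double s = 0, s2 = 0;
        for (int c = 0; c < nc; ++c) {
          double sc = 0;
          for (int p = 0; p < np; ++p) {
            if (p == f) continue;
            double v = at(u, c, p, b);
            sc += v;
            s2 += v * v;
          }
          s += sc;
          templ[u + nu * (c + nc * b)] = sc / (np - 1);
        }
        double m = s / ntr;
        mu[u + nu * b] = m;
        double var = (s2 - ntr * m * m) / (ntr - 1);
        sdv[u + nu * b] = var > 0 ? std::sqrt(var) : 0.0;
      }
    }
    for (int tp1 = 0; tp1 < nb; ++tp1) {
      ok.clear();
      for (int u = 0; u < nu; ++u) {
        if (sdv[u + nu * tp1] > 0) ok.push_back(u);
      }
      const int K = (int)ok.size();
      if (K < 2) continue;
      T.assign((size_t)K * nc, 0.0);
      for (int c = 0; c < nc; ++c) {
        double mean = 0;
        for (int k = 0; k < K; ++k) {
          int u = ok[k];
          double z = (templ[u + nu * (c + nc * tp1)] - mu[u + nu * tp1]) /
                     sdv[u + nu * tp1];
          T[k + (size_t)K * c] = z;
          mean += z;
        }
        mean /= K;
        double nrm = 0;
        for (int k = 0; k < K; ++k) {
          T[k + (size_t)K * c] -= mean;
          nrm += T[k + (size_t)K * c] * T[k + (size_t)K * c];
        }
        Tnorm[c] = std::sqrt(nrm);
      }
      x.assign(K, 0.0);
      for (int tp2 = 0; tp2 < nb; ++tp2) {
        int hits = 0;
        for (int cc = 0; cc < nc; ++cc) {
          double mean = 0;
          for (int k = 0; k < K; ++k) {
            int u = ok[k];
            x[k] = (at(u, cc, f, tp2) - mu[u + nu * tp1]) /
                   sdv[u + nu * tp1];
            mean += x[k];
          }
          mean /= K;
          double nrm = 0;
          for (int k = 0; k < K; ++k) {
            x[k] -= mean;
            nrm += x[k] * x[k];
          }
          nrm = std::sqrt(nrm);
          double best = ninf;
          ties.clear();
          for (int c = 0; c < nc; ++c) {
            double r;
            if (nrm <= 0 || Tnorm[c] <= 0) {
              r = ninf;
            } else {
              double dot = 0;
              for (int k = 0; k < K; ++k) dot += x[k] * T[k + (size_t)K * c];
              r = dot / (nrm * Tnorm[c]);
            }
            if (r > best) {
              best = r;
              ties.clear();
              ties.push_back(c);
            } else if (r == best) {
              ties.push_back(c);
            }
          }
          int pred;
          if (best == ninf) {
            pred = (int)std::floor(unif_rand() * nc); // degenerate test
          } else if (ties.size() > 1) {
            pred = ties[(int)std::floor(unif_rand() * ties.size())];
          } else {
            pred = ties[0];
          }
          if (pred == cc) ++hits;
        }
        acc(tp1, tp2) += (double)hits / nc;
      }
    }
  }
  for (int i = 0; i < nb; ++i) {
    for (int j = 0; j < nb; ++j) acc(i, j) /= np;
  }
  return acc;
}
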