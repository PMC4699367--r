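#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Minimum-energy nested secondary structure under a simplified scoring:
// Watson-Crick and wobble pairs contribute fixed favorable energies
// (GC -2.0, AU -1.1, GU -0.6 kcal/mol) and a pair stacked directly on
// another receives an additional nearest-neighbor bonus (-1.0). Hairpin
// loops must enclose at least 3 unpaired bases. This is a Nussinov-style
// dynamic program over nested pairings, not a thermodynamic folder.

static inline double pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -2.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -1.1;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -0.6;
  return 1.0; // not pairable
}

// [[Rcpp::export]]
double fold_energy_cpp(std::string seq) {
  const int n = seq.size();
  const double STACK = -1.0;
  const int MINLOOP = 3;
  if (n < MINLOOP + 2) return 0.0;
  // P[i][j]: best energy with (i,j) paired; W[i][j]: best energy on [i,j]
  std::vector<std::vector<double>> P(n, std::vector<double>(n, 1e9));
  std::vector<std::vector<double>> W(n, std::vector<double>(n, 0.0));
  for (int len = MINLOOP + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double e = pair_energy(seq[i], seq[j]);
      if (e < 0) {
        double best = 0.0; // hairpin: nothing inside paired
        if (j - 1 >= i + 1) {
          best = std::min(best, W[i + 1][j - 1]);
          if (P[i + 1][j - 1] < 1e8)
            best = std::min(best, P[i + 1][j - 1] + STACK);
        }
        P[i][j] = e + best;
      }
      double w = std::min(W[i + 1][j], W[i][j - 1]);
      if (P[i][j] < 1e8) w = std::min(w, P[i][j]);
      for (int k = i; k < j; ++k)
        w = std::min(w, W[i][k] + W[k + 1][j]);
      W[i][j] = w;
    }
  }
  return W[0][n - 1];
}
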