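#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Simplified nearest-neighbour-free RNA folding energy: optimal nested
// secondary structure minimizing the sum of base-pair energies
// (GC = -3, AU = -2, GU = -1 kcal/mol; T treated as U; N unpairable) with a
// minimum hairpin loop of `min_loop` unpaired nucleotides and no
// pseudoknots. Dynamic programming over all nested structures.

static inline double pair_energy(char a, char b) {
  if (a == 'T') a = 'U';
  if (b == 'T') b = 'U';
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 1.0; // not pairable
}

// [[Rcpp::export(name = ".fold_energy_cpp")]]
NumericVector fold_energy_cpp(CharacterVector seqs, int min_loop = 3) {
  int n = seqs.size();
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    std::string seq = as<std::string>(seqs[s]);
    int L = seq.size();
    for (int i = 0; i < L; ++i) {
      char c = toupper(seq[i]);
      if (c != 'A' && c != 'C' && c != 'G' && c != 'U' && c != 'T' &&
          c != 'N') {
        stop("invalid character '%c' in sequence %d", seq[i], s + 1);
      }
      seq[i] = c;
    }
    if (L == 0) { out[s] = 0.0; continue; }
    // E[i][j]: minimal energy of subsequence i..j (inclusive)
    std::vector<double> E((size_t)L * L, 0.0);
    for (int len = min_loop + 2; len <= L; ++len) {
      for (int i = 0; i + len - 1 < L; ++i) {
        int j = i + len - 1;
        double best = E[(size_t)(i + 1) * L + j];          // i unpaired
        double v = E[(size_t)i * L + (j - 1)];             // j unpaired
        if (v < best) best = v;
        double e = pair_energy(seq[i], seq[j]);
        if (e < 0 && j - i > min_loop) {                   // pair (i, j)
          double w = e + (j - 1 >= i + 1 ? E[(size_t)(i + 1) * L + (j - 1)]
                                         : 0.0);
          if (w < best) best = w;
        }
        for (int k = i + 1; k < j; ++k) {                  // bifurcation
          double w = E[(size_t)i * L + k] + E[(size_t)(k + 1) * L + j];
          if (w < best) best = w;
        }
        E[(size_t)i * L + j] = best;
      }
    }
    out[s] = E[(size_t)0 * L + (L - 1)];
  }
  return out;
}
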