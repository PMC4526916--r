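#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <limits>
using namespace Rcpp;

// Smith-Waterman local alignment score with affine gaps. A gap of length L
// costs gap_open + L * gap_extend (the Biostrings gapOpening/gapExtension
// convention). Linear memory: one previous H row plus a running F column
// vector and a scalar E within each row.
// [[Rcpp::export]]
double sw_score_cpp(std::string a, std::string b, NumericMatrix S,
                    std::string alphabet, double gap_open,
                    double gap_extend) {
  const double NEG = -std::numeric_limits<double>::infinity();
  int idx[256];
  std::fill(idx, idx + 256, -1);
  for (size_t i = 0; i < alphabet.size(); ++i)
    idx[(unsigned char)alphabet[i]] = (int)i;

  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> ai(n), bj(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = idx[(unsigned char)a[i]];
    if (ai[i] < 0) stop("residue '%s' at position %d of first sequence not in substitution matrix",
                        std::string(1, a[i]).c_str(), i + 1);
  }
  for (int j = 0; j < m; ++j) {
    bj[j] = idx[(unsigned char)b[j]];
    if (bj[j] < 0) stop("residue '%s' at position %d of second sequence not in substitution matrix",
                        std::string(1, b[j]).c_str(), j + 1);
  }

  std::vector<double> Hup(m + 1, 0.0), Hcur(m + 1, 0.0), F(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double e = NEG;
    Hcur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      e = std::max(Hcur[j - 1] - (gap_open + gap_extend), e - gap_extend);
      F[j] = std::max(Hup[j] - (gap_open + gap_extend), F[j] - gap_extend);
      double h = Hup[j - 1] + S(ai[i - 1], bj[j - 1]);
      h = std::max(std::max(0.0, h), std::max(e, F[j]));
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hup, Hcur);
  }
  return best;
}
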