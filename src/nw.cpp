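// Global (Needleman-Wunsch) alignment with linear gap costs.
// Scoring: match +1, mismatch -1, gap -2 (the package-wide scheme used for
// clustering identity, center-star alignment and flank anchoring).
// Traceback prefers diagonal, then up (gap in b), then left (gap in a), so
// alignments are deterministic.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const int MATCH = 1, MISMATCH = -1, GAP = -2;

// fills score matrix and returns aligned strings via traceback
static void nw_core(const std::string& a, const std::string& b,
                    std::string& out_a, std::string& out_b) {
  const int m = a.size(), n = b.size();
  std::vector<int> score((m + 1) * (n + 1));
  std::vector<unsigned char> dir((m + 1) * (n + 1));
  // dir: 0 diag, 1 up (consume a), 2 left (consume b)
  for (int i = 1; i <= m; ++i) { score[i * (n + 1)] = GAP * i; dir[i * (n + 1)] = 1; }
  for (int j = 1; j <= n; ++j) { score[j] = GAP * j; dir[j] = 2; }
  for (int i = 1; i <= m; ++i) {
    const char ai = a[i - 1];
    int* row = &score[i * (n + 1)];
    const int* prev = &score[(i - 1) * (n + 1)];
    unsigned char* drow = &dir[i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      int d = prev[j - 1] + (ai == b[j - 1] ? MATCH : MISMATCH);
      int u = prev[j] + GAP;
      int l = row[j - 1] + GAP;
      int best = d; unsigned char bd = 0;
      if (u > best) { best = u; bd = 1; }
      if (l > best) { best = l; bd = 2; }
      row[j] = best; drow[j] = bd;
    }
  }
  out_a.clear(); out_b.clear();
  out_a.reserve(m + n); out_b.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    unsigned char d = dir[i * (n + 1) + j];
    if (i > 0 && j > 0 && d == 0) {
      out_a.push_back(a[--i]); out_b.push_back(b[--j]);
    } else if (i > 0 && (j == 0 || d == 1)) {
      out_a.push_back(a[--i]); out_b.push_back('-');
    } else {
      out_a.push_back('-'); out_b.push_back(b[--j]);
    }
  }
  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b) {
  std::string ra, rb;
  nw_core(a, b, ra, rb);
  return List::create(_["a"] = ra, _["b"] = rb);
}

// identity over the full global alignment (end gaps included):
// matching columns / alignment length
// [[Rcpp::export(name = ".nw_identity_cpp")]]
NumericVector nw_identity_cpp(CharacterVector patterns, std::string subject) {
  const int np = patterns.size();
  NumericVector out(np);
  std::string ra, rb;
  for (int p = 0; p < np; ++p) {
    std::string pat = as<std::string>(patterns[p]);
    nw_core(pat, subject, ra, rb);
    int matches = 0;
    for (size_t c = 0; c < ra.size(); ++c) {
      if (ra[c] == rb[c] && ra[c] != '-') ++matches;
    }
    out[p] = ra.empty() ? 0.0 : (double)matches / (double)ra.size();
  }
  return out;
}
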