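#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap alignment kernels shared by VR search, training-set
// partitioning and RT clustering. Scores follow the package convention:
// a gap of length g costs gap_open + g * gap_ext (both supplied negative).
//
// The adenine asymmetry lives in the substitution score: a mismatch in a
// column where the template (pattern) base is A costs mism_a (0 by
// default, i.e. neutral), any other mismatch costs mism_other. Setting
// mism_a == mism_other collapses the aligner to a textbook local aligner.

static inline double subst_score(char a, char b, double match_s,
                                 double mism_a, double mism_other) {
  if (a == b && a != 'N') return match_s;
  if (a == 'A') return mism_a;
  return mism_other;
}

// Local (Smith-Waterman, Gotoh affine) alignment of pattern a vs subject b.
// Returns 0-based half-open coordinates on both inputs plus gapped rows.
// [[Rcpp::export(name = ".cpp_local_align")]]
List cpp_local_align(std::string a, std::string b,
                     double match_s, double mism_a, double mism_other,
                     double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  const double gfirst = gap_open + gap_ext; // cost of opening (first gap char)
  // D: ends in a_i ~ b_j; E: ends with gap in b (consumes a); F: gap in a.
  std::vector<double> D((n + 1) * (m + 1), NEG), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  // traceback codes: for D, which matrix fed the diagonal (0=start,1=D,2=E,3=F)
  std::vector<unsigned char> tD((n + 1) * (m + 1), 0), tE((n + 1) * (m + 1), 0),
      tF((n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // E: gap in subject, from D or E above
      double eD = D[idx(i - 1, j)] + gfirst, eE = E[idx(i - 1, j)] + gap_ext;
      if (eD >= eE) { E[idx(i, j)] = eD; tE[idx(i, j)] = 1; }
      else          { E[idx(i, j)] = eE; tE[idx(i, j)] = 2; }
      // F: gap in pattern, from D or F on the left
      double fD = D[idx(i, j - 1)] + gfirst, fF = F[idx(i, j - 1)] + gap_ext;
      if (fD >= fF) { F[idx(i, j)] = fD; tF[idx(i, j)] = 1; }
      else          { F[idx(i, j)] = fF; tF[idx(i, j)] = 3; }
      // D: diagonal from best of {fresh start, D, E, F}; ties prefer
      // continuing the diagonal so neutral (template-A) columns chain
      double dD = D[idx(i - 1, j - 1)], dE = E[idx(i - 1, j - 1)],
             dF = F[idx(i - 1, j - 1)];
      double prev = 0.0; unsigned char code = 0;
      if (dD >= prev) { prev = dD; code = 1; }
      if (dE > prev) { prev = dE; code = 2; }
      if (dF > prev) { prev = dF; code = 3; }
      double s = subst_score(a[i - 1], b[j - 1], match_s, mism_a, mism_other);
      D[idx(i, j)] = prev + s;
      tD[idx(i, j)] = code;
      // >= : among equal-scoring end cells keep the last, i.e. longest
      if (D[idx(i, j)] >= best) { best = D[idx(i, j)]; bi = i; bj = j; }
    }
  }

  std::string ra, rb;
  int i = bi, j = bj;
  int state = 1; // end in D
  while (i > 0 && j > 0 && state != 0) {
    if (state == 1) {
      unsigned char code = tD[idx(i, j)];
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
      state = (code == 0) ? 0 : code;
    } else if (state == 2) {
      unsigned char code = tE[idx(i, j)];
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
      state = code;
    } else {
      unsigned char code = tF[idx(i, j)];
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
      state = code;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["score"] = best,
                      _["pattern_aln"] = ra, _["subject_aln"] = rb,
                      _["pattern_start"] = i, _["pattern_end"] = bi,
                      _["subject_start"] = j, _["subject_end"] = bj);
}

// Global (Needleman-Wunsch, Gotoh affine) alignment; end gaps penalized.
// Used for clustering identities, so only the gapped rows and score matter.
// [[Rcpp::export(name = ".cpp_global_align")]]
List cpp_global_align(std::string a, std::string b,
                      double match_s, double mism, double gap_open,
                      double gap_ext) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  const double gfirst = gap_open + gap_ext;
  std::vector<double> D((n + 1) * (m + 1), NEG), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> tD((n + 1) * (m + 1), 0), tE((n + 1) * (m + 1), 0),
      tF((n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  D[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    E[idx(i, 0)] = gfirst + gap_ext * (i - 1);
    tE[idx(i, 0)] = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= m; ++j) {
    F[idx(0, j)] = gfirst + gap_ext * (j - 1);
    tF[idx(0, j)] = (j == 1) ? 1 : 3;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double eD = D[idx(i - 1, j)] + gfirst, eE = E[idx(i - 1, j)] + gap_ext;
      if (eD >= eE) { E[idx(i, j)] = eD; tE[idx(i, j)] = 1; }
      else          { E[idx(i, j)] = eE; tE[idx(i, j)] = 2; }
      double fD = D[idx(i, j - 1)] + gfirst, fF = F[idx(i, j - 1)] + gap_ext;
      if (fD >= fF) { F[idx(i, j)] = fD; tF[idx(i, j)] = 1; }
      else          { F[idx(i, j)] = fF; tF[idx(i, j)] = 3; }
      double dD = D[idx(i - 1, j - 1)], dE = E[idx(i - 1, j - 1)],
             dF = F[idx(i - 1, j - 1)];
      double prev = dD; unsigned char code = 1;
      if (dE > prev) { prev = dE; code = 2; }
      if (dF > prev) { prev = dF; code = 3; }
      double s = (a[i - 1] == b[j - 1] && a[i - 1] != 'N') ? match_s : mism;
      D[idx(i, j)] = prev + s;
      tD[idx(i, j)] = code;
    }
  }
  double dv = D[idx(n, m)], ev = E[idx(n, m)], fv = F[idx(n, m)];
  int state = 1; double best = dv;
  if (ev > best) { best = ev; state = 2; }
  if (fv > best) { best = fv; state = 3; }

  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 1) {
      unsigned char code = tD[idx(i, j)];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
      state = code;
    } else if (state == 2) {
      unsigned char code = tE[idx(i, j)];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i;
      state = code;
    } else {
      unsigned char code = tF[idx(i, j)];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j;
      state = code;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = best,
                      _["pattern_aln"] = ra, _["subject_aln"] = rb);
}
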