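#include <Rcpp.h>
#include <string>
#include <vector>
#include <map>
#include <algorithm>
using namespace Rcpp;

// Adenine-wildcard k-mer seeding. A seed taken from the template at
// offset t matches the subject at position s when every non-A template
// base agrees exactly; template adenines match anything (they are the
// positions DGR mutagenesis rewrites). Seeds with fewer than
// min_informative non-A positions are skipped: in AAC-rich templates
// they carry almost no sequence signal and only produce noise. With
// wildcard_a = false this is plain exact-k-mer seeding (the BLAST-like
// control) and min_informative is ignored.

static inline bool seed_match(const std::string &pat, int t,
                              const std::string &sub, int s, int k,
                              bool wildcard_a) {
  for (int j = 0; j < k; ++j) {
    char p = pat[t + j];
    if (wildcard_a && p == 'A') continue;
    if (sub[s + j] != p) return false;
  }
  return true;
}

static std::vector<int> usable_offsets(const std::string &pattern, int k,
                                       int step, bool wildcard_a,
                                       int min_informative) {
  std::vector<int> offs;
  const int n = pattern.size();
  for (int t = 0; t + k <= n; t += step) {
    if (wildcard_a) {
      int informative = 0;
      for (int j = 0; j < k; ++j)
        if (pattern[t + j] != 'A') ++informative;
      if (informative < min_informative) continue;
    }
    offs.push_back(t);
  }
  return offs;
}

// Every projected template-start position (s - t for a seed at template
// offset t matching subject position s), duplicates retained so the
// caller can weigh diagonal support.
// [[Rcpp::export(name = ".cpp_seed_project")]]
IntegerVector cpp_seed_project(std::string pattern, std::string subject,
                               int k, int step, bool wildcard_a,
                               int min_informative) {
  const int m = subject.size();
  std::vector<int> hits;
  if ((int)pattern.size() < k || m < k) return IntegerVector(0);
  std::vector<int> offs = usable_offsets(pattern, k, step, wildcard_a,
                                         min_informative);
  for (size_t ti = 0; ti < offs.size(); ++ti) {
    int t = offs[ti];
    for (int s = 0; s + k <= m; ++s) {
      if (seed_match(pattern, t, subject, s, k, wildcard_a))
        hits.push_back(s - t);
    }
  }
  std::sort(hits.begin(), hits.end());
  return IntegerVector(hits.begin(), hits.end());
}

// Batch read screen: a read is a candidate when some diagonal collects
// at least min_support seed hits in one orientation.
// [[Rcpp::export(name = ".cpp_screen_reads")]]
LogicalVector cpp_screen_reads(std::string pattern, CharacterVector reads,
                               int k, int step, bool wildcard_a,
                               int min_informative, int min_support) {
  LogicalVector out(reads.size());
  std::vector<int> offs = usable_offsets(pattern, k, step, wildcard_a,
                                         min_informative);
  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev(fwd.rbegin(), fwd.rend());
    for (size_t i = 0; i < rev.size(); ++i) {
      switch (rev[i]) {
        case 'A': rev[i] = 'T'; break;
        case 'C': rev[i] = 'G'; break;
        case 'G': rev[i] = 'C'; break;
        case 'T': rev[i] = 'A'; break;
        default:  rev[i] = 'N';
      }
    }
    bool found = false;
    for (int ori = 0; ori < 2 && !found; ++ori) {
      const std::string &sub = ori == 0 ? fwd : rev;
      const int m = sub.size();
      std::map<int, int> diag;
      for (size_t ti = 0; ti < offs.size() && !found; ++ti) {
        int t = offs[ti];
        for (int s = 0; s + k <= m; ++s) {
          if (seed_match(pattern, t, sub, s, k, wildcard_a)) {
            if (++diag[s - t] >= min_support) {
              found = true;
              break;
            }
          }
        }
      }
    }
    out[r] = found;
  }
  return out;
}
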