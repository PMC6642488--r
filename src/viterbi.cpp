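#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Duration-explicit Viterbi over an ordered set of PWM motif states.
//
// A path is begin -> (subset of motif states, in model order) -> end.
// Score = sum of per-window PWM log-odds + log transition probabilities
// + log spacer-length probabilities for each consecutive motif pair.
// The position of the first motif is free (begin carries no duration).
//
// ltrans: (K+2) x (K+2) log-transition matrix over {begin, M1..MK, end};
//   -Inf marks forbidden transitions.
// lodds:  list of K matrices, width x 4 (columns A,C,G,T) of log-odds;
//   an N in the sequence contributes 0 at its column.
// gaps:   list of length K*K (row-major from-state k1, to-state k2 at
//   index (k1-1)*K + k2); each element NULL or list(dmin = int,
//   logp = numeric over dmin..dmax). NULL forbids the motif pair.
//
// Ties are broken by smaller path start, then smaller path end; inner
// predecessor ties keep the first candidate in (begin, then k' ascending,
// o' ascending) order. Returns score = -Inf and an empty path when no
// feasible placement exists.
// [[Rcpp::export(name = ".cpp_viterbi")]]
List cpp_viterbi(std::string seq, List lodds, NumericMatrix ltrans,
                 List gaps) {
  const int L = seq.size();
  const int K = lodds.size();
  const double NEG = R_NegInf;

  std::vector<int> code(L);
  for (int i = 0; i < L; ++i) {
    switch (seq[i]) {
      case 'A': code[i] = 0; break;
      case 'C': code[i] = 1; break;
      case 'G': code[i] = 2; break;
      case 'T': code[i] = 3; break;
      default:  code[i] = -1;
    }
  }

  std::vector<int> W(K);
  std::vector<NumericMatrix> LO(K);
  for (int k = 0; k < K; ++k) {
    LO[k] = as<NumericMatrix>(lodds[k]);
    W[k] = LO[k].nrow();
  }

  // emissions: emit[k][o], o in 0 .. L - W[k]
  std::vector<std::vector<double> > emit(K);
  for (int k = 0; k < K; ++k) {
    int no = L - W[k] + 1;
    if (no < 0) no = 0;
    emit[k].assign(no, 0.0);
    for (int o = 0; o < no; ++o) {
      double s = 0.0;
      for (int j = 0; j < W[k]; ++j) {
        int b = code[o + j];
        if (b >= 0) s += LO[k](j, b);
      }
      emit[k][o] = s;
    }
  }

  // pre-extract spacer distributions (avoid R list access in the loops)
  std::vector<int> gap_dmin(K * K, 0), gap_len(K * K, 0);
  std::vector<std::vector<double> > gap_lp(K * K);
  for (int i = 0; i < K * K; ++i) {
    SEXP g = gaps[i];
    if (Rf_isNull(g)) continue;
    List gl(g);
    gap_dmin[i] = as<int>(gl["dmin"]);
    NumericVector lp = gl["logp"];
    gap_len[i] = lp.size();
    gap_lp[i].assign(lp.begin(), lp.end());
  }

  // V[k][o], path start tracker, predecessor (k', o') with -1 = begin
  std::vector<std::vector<double> > V(K);
  std::vector<std::vector<int> > PSTART(K), PK(K), PO(K);
  for (int k = 0; k < K; ++k) {
    int no = emit[k].size();
    V[k].assign(no, NEG);
    PSTART[k].assign(no, 0);
    PK[k].assign(no, -1);
    PO[k].assign(no, -1);
  }

  for (int k = 0; k < K; ++k) {
    int no = emit[k].size();
    for (int o = 0; o < no; ++o) {
      double bestprev = NEG;
      int bk = -1, bo = -1, bstart = o;
      // from begin
      double tb = ltrans(0, k + 1);
      if (tb > NEG) { bestprev = tb; bk = -1; bo = -1; bstart = o; }
      // from earlier motif states
      for (int k2 = 0; k2 < k; ++k2) {
        double tr = ltrans(k2 + 1, k + 1);
        if (tr == NEG) continue;
        int gi = k2 * K + k;
        if (gap_len[gi] == 0) continue;
        int dmin = gap_dmin[gi];
        const std::vector<double> &lp = gap_lp[gi];
        int ndur = gap_len[gi];
        // o' + W[k2] + d == o, d in [dmin, dmin + ndur)
        int olo = o - W[k2] - (dmin + ndur - 1);
        int ohi = o - W[k2] - dmin;
        if (olo < 0) olo = 0;
        int nprev = V[k2].size();
        if (ohi >= nprev) ohi = nprev - 1;
        for (int o2 = olo; o2 <= ohi; ++o2) {
          if (V[k2][o2] == NEG) continue;
          int d = o - (o2 + W[k2]);
          double lg = lp[d - dmin];
          if (lg == NEG) continue;
          double cand = V[k2][o2] + tr + lg;
          if (cand > bestprev) {
            bestprev = cand; bk = k2; bo = o2; bstart = PSTART[k2][o2];
          }
        }
      }
      if (bestprev > NEG) {
        V[k][o] = bestprev + emit[k][o];
        PK[k][o] = bk; PO[k][o] = bo; PSTART[k][o] = bstart;
      }
    }
  }

  // terminate: choose best V[k][o] + ltrans(k+1, end)
  double best = NEG;
  int bestk = -1, besto = -1, beststart = -1, bestend = -1;
  for (int k = 0; k < K; ++k) {
    double te = ltrans(k + 1, K + 1);
    if (te == NEG) continue;
    int no = V[k].size();
    for (int o = 0; o < no; ++o) {
      if (V[k][o] == NEG) continue;
      double cand = V[k][o] + te;
      int cstart = PSTART[k][o], cend = o + W[k];
      bool better = false;
      if (cand > best) better = true;
      else if (cand == best && best > NEG) {
        if (cstart < beststart) better = true;
        else if (cstart == beststart && cend < bestend) better = true;
      }
      if (better) {
        best = cand; bestk = k; besto = o;
        beststart = cstart; bestend = cend;
      }
    }
  }

  if (bestk < 0) {
    return List::create(_["score"] = R_NegInf,
                        _["states"] = IntegerVector(0),
                        _["offsets"] = IntegerVector(0));
  }

  std::vector<int> rs, ro;
  int k = bestk, o = besto;
  while (k >= 0) {
    rs.push_back(k + 1);
    ro.push_back(o);
    int pk = PK[k][o], po = PO[k][o];
    k = pk; o = po;
  }
  std::reverse(rs.begin(), rs.end());
  std::reverse(ro.begin(), ro.end());
  return List::create(_["score"] = best,
                      _["states"] = IntegerVector(rs.begin(), rs.end()),
                      _["offsets"] = IntegerVector(ro.begin(), ro.end()));
}
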