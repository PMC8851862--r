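#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Frameshift- and intron-aware local alignment of a protein to a genomic
// segment (plus strand of the segment as passed; the caller handles strand).
//
// Cell (i, j): best-scoring local path ending with i amino acids and j
// nucleotides consumed. Moves into (i, j):
//   1 match       (i-1, j-3) + s(aa_i, translate(codon))      sense codon
//   2 stop        (i-1, j-3) + stop_pen                       in-frame stop traversed
//   3 del_codon   (i-1, j  ) + gap_codon                      aa unmatched (codon deleted)
//   4 ins_codon   (i,   j-3) + gap_codon                      extra codon in genome
//   5 fs_del1     (i-1, j-1) + fs_pen                         codon short by 2 nt
//   6 fs_del2     (i-1, j-2) + fs_pen                         codon short by 1 nt
//   7 fs_ins1     (i-1, j-4) + fs_pen                         codon long by 1 nt
//   8 fs_ins2     (i-1, j-5) + fs_pen                         codon long by 2 nt
//   9 intron      (i,   j-L) + intron_open (+ splice_bonus    L >= min_intron,
//                  when the skipped segment starts GT and ends AG)
// Local semantics: every cell may start a fresh path at 0 (move 0).
// Ties broken by fixed move priority (match/stop > frameshift > codon gaps >
// intron > start) and by the ascending (j outer, i inner) sweep, which keeps
// the leftmost-start solution.
//
// Naming note on frameshift moves: "fs_del" = nucleotides missing from the
// query locus relative to 3 x protein (a deletion in the query), "fs_ins" =
// extra nucleotides. Sizes are 1-2 nt by construction.

static inline int codon_id(const int *dna, int start) {
  int a = dna[start], b = dna[start + 1], c = dna[start + 2];
  if (a < 0 || b < 0 || c < 0) return -1;
  return a * 16 + b * 4 + c;
}

// [[Rcpp::export]]
List spliced_dp_cpp(IntegerVector prot, IntegerVector dna, NumericMatrix submat,
                    IntegerVector codon_aa, double fs_pen, double gap_codon,
                    double intron_open, double splice_bonus, double stop_pen,
                    int min_intron) {
  const int m = prot.size(), n = dna.size();
  const double NEG = -1e30, EPS = 1e-9;
  std::vector<double> dp((size_t)(m + 1) * (n + 1), 0.0);
  std::vector<unsigned char> mv((size_t)(m + 1) * (n + 1), 0);
  std::vector<double> rowAny(m + 1, NEG), rowGT(m + 1, NEG);
  const int *dn = INTEGER(dna);
  const double *S = REAL(submat);
  const int nrow = submat.nrow();

  double best = 0.0; int bi = 0, bj = 0;
  for (int j = 0; j <= n; ++j) {
    // cells at column j - min_intron become legal intron donors
    int jd = j - min_intron;
    if (jd >= 0) {
      bool gt = (jd + 1 < n) && dn[jd] == 2 && dn[jd + 1] == 3;
      for (int i = 0; i <= m; ++i) {
        double v = dp[(size_t)i * (n + 1) + jd];
        if (v > rowAny[i]) rowAny[i] = v;
        if (gt && v > rowGT[i]) rowGT[i] = v;
      }
    }
    bool ag = (j >= 2) && dn[j - 2] == 0 && dn[j - 1] == 2;
    for (int i = 0; i <= m; ++i) {
      size_t at = (size_t)i * (n + 1) + j;
      double v = 0.0; unsigned char b = 0;
      if (i >= 1 && j >= 3) { // match / stop traversal
        int cid = codon_id(dn, j - 3);
        if (cid >= 0) {
          int aa = codon_aa[cid];
          double cand;
          unsigned char mvc;
          if (aa < 0) { cand = dp[at - (size_t)(n + 1) - 3] + stop_pen; mvc = 2; }
          else { cand = dp[at - (size_t)(n + 1) - 3] + S[prot[i - 1] + (size_t)nrow * aa]; mvc = 1; }
          if (cand > v + EPS) { v = cand; b = mvc; }
        }
      }
      if (i >= 1 && j >= 1) { double c = dp[at - (size_t)(n + 1) - 1] + fs_pen; if (c > v + EPS) { v = c; b = 5; } }
      if (i >= 1 && j >= 2) { double c = dp[at - (size_t)(n + 1) - 2] + fs_pen; if (c > v + EPS) { v = c; b = 6; } }
      if (i >= 1 && j >= 4) { double c = dp[at - (size_t)(n + 1) - 4] + fs_pen; if (c > v + EPS) { v = c; b = 7; } }
      if (i >= 1 && j >= 5) { double c = dp[at - (size_t)(n + 1) - 5] + fs_pen; if (c > v + EPS) { v = c; b = 8; } }
      if (i >= 1)           { double c = dp[at - (size_t)(n + 1)] + gap_codon; if (c > v + EPS) { v = c; b = 3; } }
      if (j >= 3)           { double c = dp[at - 3] + gap_codon;               if (c > v + EPS) { v = c; b = 4; } }
      if (rowAny[i] > NEG / 2) { // intron close
        double src = rowAny[i];
        if (ag && rowGT[i] + splice_bonus > src) src = rowGT[i] + splice_bonus;
        double c = src + intron_open;
        if (c > v + EPS) { v = c; b = 9; }
      }
      dp[at] = v; mv[at] = b;
      if (v > best + EPS) { best = v; bi = i; bj = j; }
    }
  }

  // traceback
  std::vector<int> tmv, ti, tj, tlen;
  int i = bi, j = bj;
  while (true) {
    size_t at = (size_t)i * (n + 1) + j;
    unsigned char b = mv[at];
    if (b == 0) break;
    int len = 0, pi = i, pj = j;
    switch (b) {
      case 1: case 2: pi = i - 1; pj = j - 3; len = 3; break;
      case 3: pi = i - 1; pj = j; len = 0; break;
      case 4: pi = i; pj = j - 3; len = 3; break;
      case 5: pi = i - 1; pj = j - 1; len = 1; break;
      case 6: pi = i - 1; pj = j - 2; len = 2; break;
      case 7: pi = i - 1; pj = j - 4; len = 4; break;
      case 8: pi = i - 1; pj = j - 5; len = 5; break;
      case 9: {
        // recover leftmost source consistent with the stored value
        bool ag = (j >= 2) && dn[j - 2] == 0 && dn[j - 1] == 2;
        double v = dp[at]; pj = -1;
        for (int js = 0; js <= j - min_intron; ++js) {
          double src = dp[(size_t)i * (n + 1) + js];
          bool gt = (js + 1 < n) && dn[js] == 2 && dn[js + 1] == 3;
          double cand = src + intron_open;
          if (ag && gt) { double c2 = src + intron_open + splice_bonus; if (c2 > cand) cand = c2; }
          if (std::fabs(cand - v) < 1e-6) { pj = js; break; }
        }
        if (pj < 0) stop("internal: intron traceback failed");
        len = j - pj; break;
      }
    }
    tmv.push_back(b); ti.push_back(i); tj.push_back(j); tlen.push_back(len);
    i = pi; j = pj;
  }
  std::reverse(tmv.begin(), tmv.end()); std::reverse(ti.begin(), ti.end());
  std::reverse(tj.begin(), tj.end()); std::reverse(tlen.begin(), tlen.end());

  return List::create(_["score"] = best, _["i_end"] = bi, _["j_end"] = bj,
                      _["i_start"] = i, _["j_start"] = j,
                      _["move"] = tmv, _["i"] = ti, _["j"] = tj, _["len"] = tlen);
}
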