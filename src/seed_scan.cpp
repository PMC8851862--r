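#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Translated seed-and-extend search: exact amino-acid k-mer seeds between a
// query protein and six-frame translations of a genome, grouped by diagonal,
// extended ungapped (maximal positive-scoring segments along the diagonal).
// Classic two-hit seeding: a diagonal is extended only when it carries at
// least `min_seeds` seed matches, and extension is confined to a window
// around the seeds. One index over the frames serves every query (real
// proteins and shuffled decoys), and real and decoy queries go through the
// identical path, which keeps the empirical E-value calibration consistent.

static const int AAN = 25; // index space; lookup maps char -> [0, AAN)

struct Seg { int frame, qs, qe, ss, se; double score; };
struct DiagInfo { int count, minq, maxq; };

// [[Rcpp::export]]
List scan_proteins_cpp(CharacterVector queries, LogicalVector want_hits,
                       CharacterVector frames, int k, NumericMatrix submat,
                       IntegerVector char2idx, double min_seg_score,
                       int min_seeds = 2, int ext_margin = 32) {
  const int nf = frames.size();
  const double *S = REAL(submat);
  const int nrow = submat.nrow();
  const int *c2i = INTEGER(char2idx); // length 256, -1 = unknown

  std::vector<std::vector<int>> F(nf);
  for (int f = 0; f < nf; ++f) {
    const char *s = CHAR(STRING_ELT(frames, f));
    int L = LENGTH(STRING_ELT(frames, f));
    F[f].resize(L);
    for (int p = 0; p < L; ++p) F[f][p] = c2i[(unsigned char)s[p]];
  }

  // k-mer index over frames (k-mers containing stop/unknown skipped)
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> idx;
  int stop_idx = c2i[(unsigned char)'*'];
  for (int f = 0; f < nf; ++f) {
    const std::vector<int> &v = F[f];
    int L = (int)v.size();
    for (int p = 0; p + k <= L; ++p) {
      uint64_t key = 0; bool ok = true;
      for (int q = 0; q < k; ++q) {
        int a = v[p + q];
        if (a < 0 || a == stop_idx) { ok = false; break; }
        key = key * AAN + a;
      }
      if (!ok) continue;
      idx[key].push_back(std::make_pair(f, p));
    }
  }

  List out(queries.size());
  for (int qi = 0; qi < queries.size(); ++qi) {
    const char *qs = CHAR(STRING_ELT(queries, qi));
    int qlen = LENGTH(STRING_ELT(queries, qi));
    std::vector<int> Q(qlen);
    for (int p = 0; p < qlen; ++p) Q[p] = c2i[(unsigned char)qs[p]];

    std::unordered_map<uint64_t, DiagInfo> diags;
    for (int p = 0; p + k <= qlen; ++p) {
      uint64_t key = 0; bool ok = true;
      for (int q = 0; q < k; ++q) {
        int a = Q[p + q];
        if (a < 0 || a == stop_idx) { ok = false; break; }
        key = key * AAN + a;
      }
      if (!ok) continue;
      auto it = idx.find(key);
      if (it == idx.end()) continue;
      for (auto &fp : it->second) {
        int d = fp.second - p; // spos - qpos
        uint64_t dk = ((uint64_t)fp.first << 32) | (uint32_t)(d + 1000000);
        auto di = diags.find(dk);
        if (di == diags.end()) diags[dk] = DiagInfo{1, p, p};
        else {
          di->second.count++;
          di->second.minq = std::min(di->second.minq, p);
          di->second.maxq = std::max(di->second.maxq, p);
        }
      }
    }

    std::vector<Seg> segs;
    double maxscore = 0.0;
    for (auto &kv : diags) {
      if (kv.second.count < min_seeds) continue;
      int f = (int)(kv.first >> 32);
      int d = (int)(uint32_t)(kv.first & 0xffffffffu) - 1000000;
      const std::vector<int> &Fv = F[f];
      int flen = (int)Fv.size();
      int q0 = std::max(d < 0 ? -d : 0, kv.second.minq - ext_margin);
      int q1 = std::min(std::min(qlen, flen - d),
                        kv.second.maxq + k + ext_margin);
      double cur = 0, bestv = 0; int curs = q0, bests = q0, beste = q0;
      for (int p = q0; p <= q1; ++p) {
        bool flush = (p == q1);
        if (!flush) {
          int a = Q[p], b = Fv[p + d];
          double sc = (a < 0 || b < 0) ? -4.0 : S[a + (size_t)nrow * b];
          cur += sc;
          if (cur > bestv) { bestv = cur; bests = curs; beste = p + 1; }
          if (cur < 0) { cur = 0; curs = p + 1; flush = true; }
        }
        if (flush) {
          if (bestv > maxscore) maxscore = bestv; // null distribution sees sub-threshold segments too
          if (bestv >= min_seg_score) {
            Seg sg; sg.frame = f; sg.qs = bests; sg.qe = beste;
            sg.ss = bests + d; sg.se = beste + d; sg.score = bestv;
            segs.push_back(sg);
          }
        }
        if (flush) { bestv = 0; bests = curs; beste = curs; }
      }
    }
    if (!want_hits[qi]) {
      out[qi] = NumericVector::create(maxscore);
    } else {
      std::sort(segs.begin(), segs.end(), [](const Seg &a, const Seg &b) {
        if (a.frame != b.frame) return a.frame < b.frame;
        if (a.ss != b.ss) return a.ss < b.ss;
        return a.qs < b.qs;
      });
      int ns = (int)segs.size();
      IntegerVector fr(ns), a(ns), b(ns), c(ns), e(ns); NumericVector sc(ns);
      for (int s = 0; s < ns; ++s) {
        fr[s] = segs[s].frame + 1; a[s] = segs[s].qs; b[s] = segs[s].qe;
        c[s] = segs[s].ss; e[s] = segs[s].se; sc[s] = segs[s].score;
      }
      out[qi] = DataFrame::create(_["frame"] = fr, _["qstart"] = a, _["qend"] = b,
                                  _["sstart"] = c, _["send"] = e, _["score"] = sc);
    }
  }
  return out;
}
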