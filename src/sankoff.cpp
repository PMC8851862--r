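#include <Rcpp.h>
using namespace Rcpp;

// Joint codon-level parsimony (Sankoff) ancestral reconstruction.
// Per-site Fitch can recombine states from different lineages into ancestral
// codons that never existed, scattering phantom substitutions across
// branches; assigning whole codons under a nucleotide-Hamming cost removes
// that artefact. States are the 61 sense codons. Tip codons outside the
// state space (gaps, ambiguity, stops) carry zero cost for every state.
//
// edges: (nnode-1) x 2 matrix of 1-based (parent, child) ids in postorder;
// tips are 1..ntip, root = ntip+1. tipcod: ntip x ncod matrix of 0-based
// sense-codon indices, -1 = missing. D: 61x61 integer Hamming distances.
// Root ties break toward the codon carried by most tips, then lowest index;
// child ties prefer the parent's state.

// [[Rcpp::export]]
IntegerMatrix sankoff_codon_anc(IntegerMatrix tipcod, IntegerMatrix edges,
                                IntegerMatrix D, int nnode,
                                IntegerVector root_pref_tip) {
  const int ntip = tipcod.nrow(), ncod = tipcod.ncol(), NS = D.nrow();
  const int ne = edges.nrow();
  IntegerMatrix anc(nnode, ncod);
  std::vector<int> cost((size_t)nnode * NS);
  std::vector<int> tally(NS);
  const int BIG = 1 << 28;

  for (int c = 0; c < ncod; ++c) {
    // init
    for (int n = 0; n < nnode; ++n) {
      bool is_tip = n < ntip;
      int obs = is_tip ? tipcod(n, c) : -2;
      for (int s = 0; s < NS; ++s) {
        if (!is_tip) cost[(size_t)n * NS + s] = 0;
        else if (obs < 0) cost[(size_t)n * NS + s] = 0;
        else cost[(size_t)n * NS + s] = (s == obs) ? 0 : BIG;
      }
    }
    // down-pass (postorder): parent cost += min_t(child cost + D)
    for (int e = 0; e < ne; ++e) {
      int par = edges(e, 0) - 1, chl = edges(e, 1) - 1;
      for (int s = 0; s < NS; ++s) {
        int best = BIG;
        const int *cc = &cost[(size_t)chl * NS];
        for (int t = 0; t < NS; ++t) {
          int v = cc[t] + D(s, t);
          if (v < best) best = v;
        }
        cost[(size_t)par * NS + s] += best;
      }
    }
    // root choice: minimal cost, ties -> majority tip codon, then lowest id
    std::fill(tally.begin(), tally.end(), 0);
    for (int i = 0; i < ntip; ++i) if (tipcod(i, c) >= 0) tally[tipcod(i, c)]++;
    int root = ntip; // 0-based root id
    int best = BIG, bs = 0;
    for (int s = 0; s < NS; ++s) {
      int v = cost[(size_t)root * NS + s];
      if (v < best || (v == best && tally[s] > tally[bs])) { best = v; bs = s; }
    }
    if (root_pref_tip.size() == 1) { // outgroup-state anchor on exact ties
      int pt = root_pref_tip[0] - 1;
      int obs = (pt >= 0 && pt < ntip) ? tipcod(pt, c) : -1;
      if (obs >= 0 && cost[(size_t)root * NS + obs] == best) bs = obs;
    }
    anc(root, c) = bs;
    // up-pass (preorder): child state = argmin child_cost + D(parent_state, .)
    for (int e = ne - 1; e >= 0; --e) {
      int par = edges(e, 0) - 1, chl = edges(e, 1) - 1;
      int ps = anc(par, c);
      const int *cc = &cost[(size_t)chl * NS];
      int bv = BIG, bt = 0;
      for (int t = 0; t < NS; ++t) {
        int v = cc[t] + D(ps, t);
        if (v < bv || (v == bv && t == ps)) { bv = v; bt = t; }
      }
      anc(chl, c) = bt;
    }
  }
  return anc;
}
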