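// Collapsed Gibbs sampler + Metropolis-coupled chains for the signed
// group model. The per-block marginal likelihood term is
//   lgamma(K+1) + lgamma(Z+1) + lgamma(L-K+1) - log(1+L) - lgamma(L+Z+2)
// (uniform Beta priors on the connection and sign rates, integrated out).
// Reassigning one species only touches the blocks in its group's row and
// column, so a Gibbs update costs O(S + g^2) with lgamma tabulated.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

namespace {

struct LgTable {
  std::vector<double> lg;   // lg[n] = lgamma(n + 1)
  std::vector<double> lg1p; // lg1p[n] = log(1 + n)
  explicit LgTable(int nmax) : lg(nmax + 1), lg1p(nmax + 1) {
    for (int n = 0; n <= nmax; ++n) {
      lg[n] = std::lgamma(n + 1.0);
      lg1p[n] = std::log1p((double)n);
    }
  }
  inline double term(int L, int K, int Z) const {
    return lg[K] + lg[Z] + lg[L - K] - lg1p[L] - lg[L + Z + 1];
  }
};

struct ChainState {
  std::vector<int> assign;             // 0-based group per species
  int g;                               // number of non-empty groups
  std::vector<int> sizes;              // group sizes
  std::vector<std::vector<int>> L, K;  // g x g link / positive counts

  // recompute sizes and counts, relabeling groups by first appearance
  void rebuild(const IntegerMatrix& signs) {
    int S = signs.nrow();
    std::vector<int> relab(S, -1);
    int next = 0;
    for (int s = 0; s < S; ++s) {
      if (relab[assign[s]] < 0) relab[assign[s]] = next++;
    }
    for (int s = 0; s < S; ++s) assign[s] = relab[assign[s]];
    g = next;
    sizes.assign(g, 0);
    L.assign(g, std::vector<int>(g, 0));
    K.assign(g, std::vector<int>(g, 0));
    for (int s = 0; s < S; ++s) sizes[assign[s]]++;
    for (int i = 0; i < S; ++i)
      for (int j = 0; j < S; ++j) {
        int v = signs(i, j);
        if (v != 0) {
          L[assign[i]][assign[j]]++;
          if (v > 0) K[assign[i]][assign[j]]++;
        }
      }
  }

  void dropEmptyGroup(int a) {
    sizes.erase(sizes.begin() + a);
    L.erase(L.begin() + a);
    K.erase(K.begin() + a);
    for (size_t i = 0; i < L.size(); ++i) {
      L[i].erase(L[i].begin() + a);
      K[i].erase(K[i].begin() + a);
    }
    for (size_t s = 0; s < assign.size(); ++s)
      if (assign[s] > a) assign[s]--;
    --g;
  }

  double logMarginal(const LgTable& tab) const {
    double tot = 0.0;
    for (int i = 0; i < g; ++i)
      for (int j = 0; j < g; ++j)
        tot += tab.term(L[i][j], K[i][j], sizes[i] * sizes[j] - L[i][j]);
    return tot;
  }
};

// one collapsed Gibbs sweep over all species, tempered by beta
void gibbsSweep(const IntegerMatrix& signs, ChainState& st,
                double beta, int maxGroups, const LgTable& tab) {
  int S = signs.nrow();
  std::vector<int> order(S);
  for (int s = 0; s < S; ++s) order[s] = s;
  for (int s = S - 1; s > 0; --s) {
    int k = (int)std::floor(unif_rand() * (s + 1));
    if (k > s) k = s;
    std::swap(order[s], order[k]);
  }

  std::vector<int> outL, outK, inL, inK;
  std::vector<double> w;
  for (int pos = 0; pos < S; ++pos) {
    int s = order[pos];
    int a = st.assign[s];
    int g = st.g;

    // link profile of s toward each group (s itself excluded)
    outL.assign(g, 0); outK.assign(g, 0);
    inL.assign(g, 0);  inK.assign(g, 0);
    for (int t = 0; t < S; ++t) {
      if (t == s) continue;
      int gt = st.assign[t];
      int v = signs(s, t);
      if (v != 0) { outL[gt]++; if (v > 0) outK[gt]++; }
      v = signs(t, s);
      if (v != 0) { inL[gt]++; if (v > 0) inK[gt]++; }
    }
    int selfNZ = signs(s, s) != 0 ? 1 : 0;
    int selfPos = signs(s, s) > 0 ? 1 : 0;

    // remove s from the counts (its old group may become empty; it then
    // plays the role of the fresh-group candidate)
    for (int j = 0; j < g; ++j) {
      st.L[a][j] -= outL[j]; st.K[a][j] -= outK[j];
      st.L[j][a] -= inL[j];  st.K[j][a] -= inK[j];
    }
    st.L[a][a] -= selfNZ; st.K[a][a] -= selfPos;
    st.sizes[a]--;

    bool allowNew = (st.sizes[a] > 0) && (g < maxGroups);
    int ncand = g + (allowNew ? 1 : 0);
    w.assign(ncand, 0.0);
    for (int b = 0; b < ncand; ++b) {
      bool fresh = (b == g);
      int nb = fresh ? 0 : st.sizes[b];
      double sc = 0.0;
      for (int j = 0; j < g; ++j) {
        if (j == b) continue;
        int nj = st.sizes[j];
        int Lbj = fresh ? 0 : st.L[b][j], Kbj = fresh ? 0 : st.K[b][j];
        int Ljb = fresh ? 0 : st.L[j][b], Kjb = fresh ? 0 : st.K[j][b];
        sc += tab.term(Lbj + outL[j], Kbj + outK[j],
                       (nb + 1) * nj - (Lbj + outL[j]))
            - tab.term(Lbj, Kbj, nb * nj - Lbj);
        sc += tab.term(Ljb + inL[j], Kjb + inK[j],
                       nj * (nb + 1) - (Ljb + inL[j]))
            - tab.term(Ljb, Kjb, nj * nb - Ljb);
      }
      int Lbb = fresh ? 0 : st.L[b][b], Kbb = fresh ? 0 : st.K[b][b];
      int oL = fresh ? 0 : outL[b], oK = fresh ? 0 : outK[b];
      int iL = fresh ? 0 : inL[b], iK = fresh ? 0 : inK[b];
      int newL = Lbb + oL + iL + selfNZ;
      int newK = Kbb + oK + iK + selfPos;
      sc += tab.term(newL, newK, (nb + 1) * (nb + 1) - newL)
          - tab.term(Lbb, Kbb, nb * nb - Lbb);
      w[b] = beta * sc;
    }

    double mx = w[0];
    for (int b = 1; b < ncand; ++b) mx = std::max(mx, w[b]);
    double tot = 0.0;
    for (int b = 0; b < ncand; ++b) { w[b] = std::exp(w[b] - mx); tot += w[b]; }
    double u = unif_rand() * tot;
    int chosen = ncand - 1;
    double acc = 0.0;
    for (int b = 0; b < ncand; ++b) {
      acc += w[b];
      if (u <= acc) { chosen = b; break; }
    }

    if (chosen == st.g) {  // open a fresh group
      st.g++;
      st.sizes.push_back(0);
      for (size_t i = 0; i < st.L.size(); ++i) {
        st.L[i].push_back(0);
        st.K[i].push_back(0);
      }
      st.L.push_back(std::vector<int>(st.g, 0));
      st.K.push_back(std::vector<int>(st.g, 0));
      outL.push_back(0); outK.push_back(0);
      inL.push_back(0);  inK.push_back(0);
    }
    int b = chosen;
    for (int j = 0; j < st.g; ++j) {
      st.L[b][j] += outL[j]; st.K[b][j] += outK[j];
      st.L[j][b] += inL[j];  st.K[j][b] += inK[j];
    }
    st.L[b][b] += selfNZ; st.K[b][b] += selfPos;
    st.sizes[b]++;
    st.assign[s] = b;
    if (st.sizes[a] == 0) st.dropEmptyGroup(a);
  }
  st.rebuild(signs);  // canonical labels once per sweep
}

} // namespace

// [[Rcpp::export(name = ".gibbs_sweep_engine")]]
IntegerVector gibbs_sweep_engine(IntegerMatrix signs, IntegerVector assign,
                                 double exponent, int maxGroups) {
  int S = signs.nrow();
  LgTable tab(S * S + S + 2);
  ChainState st;
  st.assign.resize(S);
  for (int s = 0; s < S; ++s) st.assign[s] = assign[s] - 1;
  st.rebuild(signs);
  gibbsSweep(signs, st, exponent, maxGroups, tab);
  IntegerVector out(S);
  for (int s = 0; s < S; ++s) out[s] = st.assign[s] + 1;
  return out;
}

// [[Rcpp::export(name = ".mc3_engine")]]
List mc3_engine(IntegerMatrix signs, IntegerMatrix initAssign,
                NumericVector exponents, int nSweeps, int maxGroups,
                int recordEvery) {
  int S = signs.nrow();
  int nChains = initAssign.nrow();
  LgTable tab(S * S + S + 2);

  std::vector<ChainState> chains(nChains);
  std::vector<double> curScore(nChains);
  std::vector<int> bestAssign;
  double bestScore = -std::numeric_limits<double>::infinity();
  for (int c = 0; c < nChains; ++c) {
    chains[c].assign.resize(S);
    for (int s = 0; s < S; ++s) chains[c].assign[s] = initAssign(c, s) - 1;
    chains[c].rebuild(signs);
    curScore[c] = chains[c].logMarginal(tab);
    if (curScore[c] > bestScore) {
      bestScore = curScore[c];
      bestAssign = chains[c].assign;
    }
  }

  int nRec = nSweeps / recordEvery;
  NumericMatrix traceScore(nRec, nChains);
  IntegerVector traceSweep(nRec);
  int rec = 0;
  int nSwapProp = 0, nSwapAcc = 0;

  for (int sweep = 1; sweep <= nSweeps; ++sweep) {
    for (int c = 0; c < nChains; ++c) {
      gibbsSweep(signs, chains[c], exponents[c], maxGroups, tab);
      curScore[c] = chains[c].logMarginal(tab);
      if (curScore[c] > bestScore) {
        bestScore = curScore[c];
        bestAssign = chains[c].assign;
      }
    }
    if (nChains > 1) {  // one adjacent-pair exchange proposal per sweep
      int k = (int)std::floor(unif_rand() * (nChains - 1));
      if (k > nChains - 2) k = nChains - 2;
      double logRatio = (exponents[k] - exponents[k + 1]) *
                        (curScore[k + 1] - curScore[k]);
      nSwapProp++;
      if (logRatio >= 0 || unif_rand() < std::exp(logRatio)) {
        std::swap(chains[k], chains[k + 1]);
        std::swap(curScore[k], curScore[k + 1]);
        nSwapAcc++;
      }
    }
    if (recordEvery > 0 && sweep % recordEvery == 0 && rec < nRec) {
      traceSweep[rec] = sweep;
      for (int c = 0; c < nChains; ++c) traceScore(rec, c) = curScore[c];
      rec++;
    }
  }

  IntegerVector bestOut(S);
  for (int s = 0; s < S; ++s) bestOut[s] = bestAssign[s] + 1;
  return List::create(
    _["best_assign"] = bestOut,
    _["best_score"] = bestScore,
    _["trace_sweep"] = traceSweep,
    _["trace_score"] = traceScore,
    _["n_recorded"] = rec,
    _["swap_proposed"] = nSwapProp,
    _["swap_accepted"] = nSwapAcc);
}

// [[Rcpp::export(name = ".exhaustive_engine")]]
List exhaustive_engine(IntegerMatrix signs) {
  int S = signs.nrow();
  LgTable tab(S * S + S + 2);
  // enumerate restricted growth strings in lexicographic order; the first
  // maximizer encountered is the canonically smallest, fixing ties
  std::vector<int> a(S, 0), m(S, 0);
  std::vector<int> bestA = a;
  double bestScore = -std::numeric_limits<double>::infinity();
  double count = 0;
  ChainState st;
  st.assign.resize(S);
  while (true) {
    ++count;
    st.assign = a;
    st.rebuild(signs);
    double sc = st.logMarginal(tab);
    if (sc > bestScore) { bestScore = sc; bestA = a; }
    int i = S - 1;
    while (i > 0 && a[i] == m[i - 1] + 1) --i;
    if (i == 0) break;
    a[i]++;
    m[i] = std::max(m[i - 1], a[i]);
    for (int j = i + 1; j < S; ++j) { a[j] = 0; m[j] = m[i]; }
    Rcpp::checkUserInterrupt();
  }
  IntegerVector bestOut(S);
  for (int s = 0; s < S; ++s) bestOut[s] = bestA[s] + 1;
  return List::create(_["best_assign"] = bestOut,
                      _["best_score"] = bestScore,
                      _["n_partitions"] = count);
}
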