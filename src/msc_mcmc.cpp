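// Bayesian MCMC sampler for species-tree divergence times and population
// sizes under the multispecies coalescent, with per-locus gene-tree
// sampling, JC69 sequence likelihoods (pruning on compressed site
// patterns), optional per-locus rate/heredity multipliers, and optional
// species-tree topology (NNI) moves for small trees.
//
// Conventions: all indices 0-based; node ages and tau/theta on the
// nuclear-mean substitutions/site scale; locus branch lengths for the
// likelihood are age differences times the locus rate multiplier; the
// effective coalescent parameter of a population for a locus is
// theta_pop * heredity_multiplier.  Uses R's RNG so set.seed() in R
// makes runs reproducible.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <string>
#include <sstream>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------- species

struct SpeciesTree {
  int S = 0, nn = 0, root = -1;
  std::vector<int> parent, left, right;   // left/right = -1 for tips
  std::vector<double> tau, theta;
  std::vector<int> cladeMask;             // species bitmask of each node
  std::vector<int> mrcaOf;                // size 1<<S: MRCA node of mask

  void rebuild() {
    left.assign(nn, -1); right.assign(nn, -1);
    for (int v = 0; v < nn; ++v) {
      int p = parent[v];
      if (p < 0) { root = v; continue; }
      if (left[p] < 0) left[p] = v; else right[p] = v;
    }
    cladeMask.assign(nn, 0);
    // postorder by recursion
    std::vector<int> stack{root}, order;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      order.push_back(v);
      if (left[v] >= 0) { stack.push_back(left[v]); stack.push_back(right[v]); }
    }
    for (auto it = order.rbegin(); it != order.rend(); ++it) {
      int v = *it;
      cladeMask[v] = (left[v] < 0) ? (1 << v) :
        (cladeMask[left[v]] | cladeMask[right[v]]);
    }
    mrcaOf.assign(1 << S, -1);
    for (int m = 1; m < (1 << S); ++m) {
      int best = -1;
      for (int v = 0; v < nn; ++v)
        if ((cladeMask[v] & m) == m)
          if (best < 0 || tau[v] < tau[best]) best = v;
      mrcaOf[m] = best;
    }
  }

  // population (branch) holding a lineage of species-content `mask` at `age`
  inline int popOf(int mask, double age) const {
    int p = mrcaOf[mask];
    while (parent[p] >= 0 && age >= tau[parent[p]]) p = parent[p];
    return p;
  }
};

// ----------------------------------------------------------------- locus

struct Locus {
  int ntip = 0, nn = 0, root = -1;
  std::vector<int> parent, left, right;
  std::vector<double> age;
  std::vector<int> tipsp, mask;
  double rate = 1.0, hered = 1.0, heredPriorMean = 1.0;
  double kappa = 1.0;            // 1 = JC69; >1 = K80 (HKY, equal freqs)
  // sequence data (JC69, compressed patterns)
  bool hasData = false;
  int npat = 0;
  std::vector<int> tipstate;      // ntip x npat, column-major by pattern
  std::vector<double> wt;
  std::vector<double> clv;        // nn x npat x 4 (internal rows used)
  std::vector<double> clv2;       // proposal buffer (swapped on accept)
  std::vector<int> postorder;     // internal nodes, children first
  double loglik = 0.0, logmsc = 0.0;

  void rebuildTopology() {
    left.assign(nn, -1); right.assign(nn, -1);
    for (int v = 0; v < nn; ++v) {
      int p = parent[v];
      if (p < 0) { root = v; continue; }
      if (left[p] < 0) left[p] = v; else right[p] = v;
    }
    postorder.clear();
    std::vector<int> stack{root}, order;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (left[v] < 0) continue;
      order.push_back(v);
      stack.push_back(left[v]); stack.push_back(right[v]);
    }
    postorder.assign(order.rbegin(), order.rend());
  }

  void rebuildMasks(const SpeciesTree& sp) {
    mask.assign(nn, 0);
    for (int i = 0; i < ntip; ++i) mask[i] = 1 << tipsp[i];
    for (int v : postorder) mask[v] = mask[left[v]] | mask[right[v]];
  }
};

// JC69 / K80 pruning ----------------------------------------------------

static inline void jcP(double b, double& p0, double& p1) {
  double e = std::exp(-4.0 * b / 3.0);
  p0 = 0.25 + 0.75 * e;
  p1 = 0.25 - 0.25 * e;
}

// K80 transition probabilities (kappa = alpha/beta); states are ordered
// A,G,C,T so the transition partner of state x is x^1
static inline void k80P(double b, double kappa,
                        double& p0, double& pts, double& ptv) {
  double e1 = std::exp(-4.0 * b / (kappa + 2.0));
  double e2 = std::exp(-2.0 * b * (kappa + 1.0) / (kappa + 2.0));
  p0 = 0.25 + 0.25 * e1 + 0.5 * e2;
  pts = 0.25 + 0.25 * e1 - 0.5 * e2;
  ptv = 0.25 - 0.25 * e1;
}

// conditional likelihood of internal node v from its children: one pass
// over patterns, with per-branch tip lookup tables (JC69 has only two
// distinct transition probabilities per branch)
static void clvNode(Locus& L, int v, std::vector<double>& buf) {
  double* out = &buf[(size_t)v * L.npat * 4];
  const int c1 = L.left[v], c2 = L.right[v];
  // per-branch probabilities: p0 same, pts transition, ptv transversion
  // (JC69 is the kappa = 1 special case with pts = ptv)
  double p0a, ptsa, ptva, p0b, ptsb, ptvb;
  if (L.kappa == 1.0) {
    jcP((L.age[v] - L.age[c1]) * L.rate, p0a, ptva); ptsa = ptva;
    jcP((L.age[v] - L.age[c2]) * L.rate, p0b, ptvb); ptsb = ptvb;
  } else {
    k80P((L.age[v] - L.age[c1]) * L.rate, L.kappa, p0a, ptsa, ptva);
    k80P((L.age[v] - L.age[c2]) * L.rate, L.kappa, p0b, ptsb, ptvb);
  }
  const double da = p0a - ptva, ea = ptsa - ptva;
  const double db = p0b - ptvb, eb = ptsb - ptvb;
  const bool tip1 = c1 < L.ntip, tip2 = c2 < L.ntip;
  double ta[5][4], tb[5][4];     // tip state 0..3 plus missing (4)
  if (tip1) {
    for (int x = 0; x < 4; ++x) {
      for (int y = 0; y < 4; ++y) ta[x][y] = ptva;
      ta[x][x] = p0a; ta[x][x ^ 1] = ptsa; ta[4][x] = 1.0;
    }
  }
  if (tip2) {
    for (int x = 0; x < 4; ++x) {
      for (int y = 0; y < 4; ++y) tb[x][y] = ptvb;
      tb[x][x] = p0b; tb[x][x ^ 1] = ptsb; tb[4][x] = 1.0;
    }
  }
  const int* s1 = tip1 ? &L.tipstate[(size_t)c1 * L.npat] : nullptr;
  const int* s2 = tip2 ? &L.tipstate[(size_t)c2 * L.npat] : nullptr;
  const double* cl1 = tip1 ? nullptr : &buf[(size_t)c1 * L.npat * 4];
  const double* cl2 = tip2 ? nullptr : &buf[(size_t)c2 * L.npat * 4];
  for (int s = 0; s < L.npat; ++s) {
    double a0, a1, a2, a3, b0, b1, b2, b3;
    if (tip1) {
      int x = s1[s]; const double* r = ta[x < 0 ? 4 : x];
      a0 = r[0]; a1 = r[1]; a2 = r[2]; a3 = r[3];
    } else {
      const double* ci = cl1 + 4 * s;
      double base = ptva * (ci[0] + ci[1] + ci[2] + ci[3]);
      a0 = base + da * ci[0] + ea * ci[1];
      a1 = base + da * ci[1] + ea * ci[0];
      a2 = base + da * ci[2] + ea * ci[3];
      a3 = base + da * ci[3] + ea * ci[2];
    }
    if (tip2) {
      int x = s2[s]; const double* r = tb[x < 0 ? 4 : x];
      b0 = r[0]; b1 = r[1]; b2 = r[2]; b3 = r[3];
    } else {
      const double* ci = cl2 + 4 * s;
      double base = ptvb * (ci[0] + ci[1] + ci[2] + ci[3]);
      b0 = base + db * ci[0] + eb * ci[1];
      b1 = base + db * ci[1] + eb * ci[0];
      b2 = base + db * ci[2] + eb * ci[3];
      b3 = base + db * ci[3] + eb * ci[2];
    }
    double* o = out + 4 * s;
    o[0] = a0 * b0; o[1] = a1 * b1; o[2] = a2 * b2; o[3] = a3 * b3;
  }
}

static double rootLoglik(const Locus& L, const std::vector<double>& buf) {
  const double* cl = &buf[(size_t)L.root * L.npat * 4];
  double ll = 0.0;
  for (int s = 0; s < L.npat; ++s) {
    const double* ci = cl + 4 * s;
    double site = 0.25 * (ci[0] + ci[1] + ci[2] + ci[3]);
    ll += L.wt[s] * std::log(std::max(site, 1e-300));
  }
  return ll;
}

static double logLikFull(Locus& L) {
  if (!L.hasData) return 0.0;
  for (int v : L.postorder) clvNode(L, v, L.clv);
  return rootLoglik(L, L.clv);
}

// full recompute into the proposal buffer; commitAlt() swaps it in
static double logLikFullAlt(Locus& L) {
  if (!L.hasData) return 0.0;
  if (L.clv2.size() != L.clv.size()) L.clv2.assign(L.clv.size(), 0.0);
  for (int v : L.postorder) clvNode(L, v, L.clv2);
  return rootLoglik(L, L.clv2);
}

static inline void commitAlt(Locus& L) { if (L.hasData) L.clv.swap(L.clv2); }

// Recompute only the clv rows invalidated by age/topology changes at the
// nodes flagged `dirty`, saving the overwritten rows so that a rejected
// proposal can be reverted cheaply.  Returns the root log likelihood.
struct PartialUpdate {
  std::vector<int> rows;
  std::vector<double> saved;
  double apply(Locus& L, const std::vector<char>& dirty) {
    rows.clear(); saved.clear();
    if (!L.hasData) return 0.0;
    static thread_local std::vector<char> redo;
    redo.assign(L.nn, 0);
    for (int v : L.postorder) {
      int a = L.left[v], b = L.right[v];
      if (dirty[v] || dirty[a] || dirty[b] || redo[a] || redo[b])
        redo[v] = 1;
    }
    size_t rowlen = (size_t)L.npat * 4;
    for (int v : L.postorder) {
      if (!redo[v]) continue;
      rows.push_back(v);
      const double* r = &L.clv[(size_t)v * rowlen];
      saved.insert(saved.end(), r, r + rowlen);
      clvNode(L, v, L.clv);
    }
    return rootLoglik(L, L.clv);
  }
  void revert(Locus& L) {
    size_t rowlen = (size_t)L.npat * 4;
    for (size_t k = 0; k < rows.size(); ++k)
      std::copy(saved.begin() + k * rowlen, saved.begin() + (k + 1) * rowlen,
                L.clv.begin() + (size_t)rows[k] * rowlen);
  }
};

// recompute v (if internal) and its ancestors; children assumed valid
static double logLikPath(Locus& L, int v) {
  if (!L.hasData) return 0.0;
  if (v < L.ntip) v = L.parent[v];
  while (v >= 0) { clvNode(L, v, L.clv); v = L.parent[v]; }
  return rootLoglik(L, L.clv);
}

// MSC log density -------------------------------------------------------

static double mscLogDensity(const Locus& L, const SpeciesTree& sp) {
  // fixed-size scratch: at most 15 populations, 63 events per locus
  static thread_local double ev[16][64];
  static thread_local int nev[16], entering[16], order[16];
  for (int v = 0; v < sp.nn; ++v) { nev[v] = 0; entering[v] = 0; }
  for (int v = L.ntip; v < L.nn; ++v) {
    int base = sp.mrcaOf[L.mask[v]];
    if (L.age[v] < sp.tau[base] - 1e-300) return NEG_INF;
    int p = base;
    while (sp.parent[p] >= 0 && L.age[v] >= sp.tau[sp.parent[p]])
      p = sp.parent[p];
    ev[p][nev[p]++] = L.age[v];
  }
  for (int i = 0; i < L.ntip; ++i) entering[L.tipsp[i]]++;
  // process populations in age order (tips first)
  for (int i = 0; i < sp.nn; ++i) order[i] = i;
  std::sort(order, order + sp.nn, [&](int a, int b) {
    return sp.tau[a] < sp.tau[b];
  });
  double logd = 0.0;
  for (int oi = 0; oi < sp.nn; ++oi) {
    int v = order[oi];
    int j = entering[v];
    double th = sp.theta[v] * L.hered;
    double t = sp.tau[v];
    double tEnd = sp.parent[v] < 0 ? R_PosInf : sp.tau[sp.parent[v]];
    std::sort(ev[v], ev[v] + nev[v]);
    double log2th = std::log(2.0 / th);
    for (int e = 0; e < nev[v]; ++e) {
      double a = ev[v][e];
      if (j < 2) return NEG_INF;
      logd += log2th - j * (j - 1) / th * (a - t);
      --j; t = a;
    }
    if (R_FINITE(tEnd)) {
      if (j >= 2) logd -= j * (j - 1) / th * (tEnd - t);
      entering[sp.parent[v]] += j;
    }
  }
  return logd;
}

// priors ----------------------------------------------------------------

struct Priors {
  double thetaShape = 2.0, thetaScale = 0.0125;
  double tauMean = 0.01;          // ladder increments (fixed topology)
  double rootMean = 0.03;         // polytope mode root age
  int tauMode = 0;                // 0 ladder, 1 polytope
  double rateDirAlpha = 2.0;      // Dirichlet concentration for rates
  double heredShape = 4.0;
};

static double logPriorTheta(const SpeciesTree& sp, const Priors& pr) {
  double s = 0.0;
  for (int v = 0; v < sp.nn; ++v)
    s += R::dgamma(sp.theta[v], pr.thetaShape, pr.thetaScale, 1);
  return s;
}

// number of linear extensions of the internal-node partial order
// (non-root internal nodes ranked by age ascending; descendants younger)
static int linearExtensions(const SpeciesTree& sp) {
  std::vector<int> nodes;
  for (int v = 0; v < sp.nn; ++v)
    if (sp.left[v] >= 0 && v != sp.root) nodes.push_back(v);
  int k = nodes.size();
  if (k <= 1) return 1;
  std::vector<int> idx(k);
  for (int i = 0; i < k; ++i) idx[i] = i;
  // ancestor matrix
  std::vector<std::vector<bool>> anc(k, std::vector<bool>(k, false));
  for (int i = 0; i < k; ++i) {
    int p = sp.parent[nodes[i]];
    while (p >= 0) {
      for (int j = 0; j < k; ++j) if (nodes[j] == p) anc[i][j] = true;
      p = sp.parent[p];
    }
  }
  int count = 0;
  std::sort(idx.begin(), idx.end());
  do {
    bool ok = true;
    // idx gives age-ascending order: if j is an ancestor of i, j must
    // come after i
    std::vector<int> pos(k);
    for (int r = 0; r < k; ++r) pos[idx[r]] = r;
    for (int i = 0; i < k && ok; ++i)
      for (int j = 0; j < k && ok; ++j)
        if (anc[i][j] && pos[j] < pos[i]) ok = false;
    if (ok) ++count;
  } while (std::next_permutation(idx.begin(), idx.end()));
  return count;
}

static double logPriorTau(const SpeciesTree& sp, const Priors& pr) {
  if (sp.nn <= 1) return 0.0;
  std::vector<double> taus;
  for (int v = 0; v < sp.nn; ++v) if (sp.left[v] >= 0) taus.push_back(sp.tau[v]);
  if (pr.tauMode == 0) {
    std::sort(taus.begin(), taus.end());
    double s = 0.0, prev = 0.0;
    for (double t : taus) {
      s += R::dexp(t - prev, pr.tauMean, 1);
      prev = t;
    }
    return s;
  }
  // polytope: root ~ Exp(rootMean), others uniform in the order polytope
  double tr = sp.tau[sp.root];
  int k = taus.size() - 1;
  double s = R::dexp(tr, pr.rootMean, 1);
  if (k > 0) {
    double lfact = std::lgamma(k + 1.0);
    s += lfact - std::log((double)linearExtensions(sp)) - k * std::log(tr);
  }
  return s;
}

static double logPriorRates(const std::vector<Locus>& loci, const Priors& pr,
                            bool estimated) {
  if (!estimated) return 0.0;
  double s = 0.0;
  for (const Locus& L : loci) {
    if (L.rate <= 0) return NEG_INF;
    s += (pr.rateDirAlpha - 1.0) * std::log(L.rate);
  }
  return s;
}

static double logPriorHered(const std::vector<Locus>& loci, const Priors& pr,
                            bool estimated) {
  if (!estimated) return 0.0;
  double s = 0.0;
  for (const Locus& L : loci)
    s += R::dgamma(L.hered, pr.heredShape, L.heredPriorMean / pr.heredShape, 1);
  return s;
}

// ---------------------------------------------------------------- sampler

struct StepSizes {
  double age = 0.5;      // multiplier window (log scale factor-ish)
  double sprAge = 0.8;
  double tau = 0.3;      // relative window
  double theta = 0.5;
  double mix = 0.15;
  double rate = 0.3;
  double hered = 0.5;
};

struct AccCount { long prop = 0, acc = 0; };

class Sampler {
public:
  SpeciesTree sp;
  std::vector<Locus> loci;
  Priors pr;
  bool likeOn = true, estRates = false, estHered = false, topoMoves = false;
  StepSizes st;
  AccCount accAge, accSpr, accTau, accTheta, accMix, accRate, accHered, accNni;

  double totalLogLik() const {
    double s = 0; for (const Locus& L : loci) s += L.loglik; return s;
  }
  double totalLogMsc() const {
    double s = 0; for (const Locus& L : loci) s += L.logmsc; return s;
  }

  void refreshAll() {
    sp.rebuild();
    for (Locus& L : loci) {
      L.rebuildTopology();
      L.rebuildMasks(sp);
      if (L.hasData) L.clv.assign((size_t)L.nn * L.npat * 4, 0.0);
      L.loglik = likeOn ? logLikFull(L) : 0.0;
      L.logmsc = mscLogDensity(L, sp);
    }
  }

  // --- gene-tree node age move (one node of one locus)
  void moveAge(Locus& L, int v) {
    accAge.prop++;
    double lo = std::max(L.age[L.left[v]], L.age[L.right[v]]);
    lo = std::max(lo, sp.tau[sp.mrcaOf[L.mask[v]]]);
    double old = L.age[v], prop, lhast = 0.0;
    if (L.parent[v] >= 0) {
      double hi = L.age[L.parent[v]];
      if (hi <= lo) return;
      double w = st.age * (hi - lo);
      prop = old + w * (unif_rand() - 0.5);
      while (prop < lo || prop > hi) {     // reflect
        if (prop < lo) prop = 2 * lo - prop;
        if (prop > hi) prop = 2 * hi - prop;
      }
    } else {
      double span = old - lo;
      if (span <= 0) span = 1e-12;
      prop = lo + span * std::exp(st.age * (unif_rand() - 0.5));
      lhast = std::log((prop - lo) / span);
    }
    // save path clvs
    double oldLik = L.loglik, oldMsc = L.logmsc;
    std::vector<double> saved;
    if (L.hasData && likeOn) {
      int u = v;
      while (u >= 0) {
        const double* c = &L.clv[(size_t)u * L.npat * 4];
        saved.insert(saved.end(), c, c + L.npat * 4);
        u = L.parent[u];
      }
    }
    L.age[v] = prop;
    double newMsc = mscLogDensity(L, sp);
    double newLik = likeOn ? logLikPath(L, v) : 0.0;
    double lr = newLik - oldLik + newMsc - oldMsc + lhast;
    if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
      L.loglik = newLik; L.logmsc = newMsc; accAge.acc++;
    } else {
      L.age[v] = old;
      if (L.hasData && likeOn) {
        size_t off = 0; int u = v;
        while (u >= 0) {
          std::copy(saved.begin() + off, saved.begin() + off + L.npat * 4,
                    L.clv.begin() + (size_t)u * L.npat * 4);
          off += L.npat * 4;
          u = L.parent[u];
        }
      }
    }
  }

  // --- constrained Wilson-Balding subtree re-attachment
  void moveSpr(Locus& L) {
    if (L.ntip < 3) return;
    accSpr.prop++;
    int i = (int)(unif_rand() * L.nn);
    while (i == L.root || i >= L.nn) i = (int)(unif_rand() * L.nn);
    int p = L.parent[i];
    int s = (L.left[p] == i) ? L.right[p] : L.left[p];
    int g = L.parent[p];
    double tOld = L.age[p];

    // Detached view: node p removed, s inherits p's parent.  Masks only
    // change for the ancestors of p (they lose i's species content).
    int rootD = (p == L.root) ? s : L.root;
    std::vector<int> maskD = L.mask;
    for (int u = g; u >= 0; u = L.parent[u]) {
      int l = L.left[u], r = L.right[u];
      int ml = (l == p) ? L.mask[s] : maskD[l];
      int mr = (r == p) ? L.mask[s] : maskD[r];
      maskD[u] = ml | mr;
    }
    auto detParent = [&](int u) {
      if (u == s) return (p == L.root) ? -1 : g;
      return L.parent[u];
    };
    // lineages (edges) crossing time t in population popI, excluding the
    // pruned subtree's stem; the detached root's stem extends to +inf
    auto candidates = [&](double t, int popI, std::array<int, 64>& out) {
      int k = 0;
      for (int u = 0; u < L.nn; ++u) {
        if (u == i || u == p) continue;
        int pu = detParent(u);
        double top = (pu < 0) ? R_PosInf : L.age[pu];
        if (L.age[u] < t && t < top && sp.popOf(maskD[u], t) == popI)
          out[k++] = u;
      }
      return k;
    };

    double tNew = tOld * std::exp(st.sprAge * (unif_rand() - 0.5));
    if (tNew <= L.age[i] || tNew < sp.tau[sp.mrcaOf[L.mask[i]]]) return;
    std::array<int, 64> cand;
    int popNew = sp.popOf(L.mask[i], tNew);
    int kNew = candidates(tNew, popNew, cand);
    if (kNew == 0) return;
    int j = cand[(int)(unif_rand() * kNew)];
    int popOld = sp.popOf(L.mask[i], tOld);
    std::array<int, 64> dummy;
    int kOld = candidates(tOld, popOld, dummy);  // includes s: reverse target

    // save the cheap state only; clvs go through the proposal buffer
    std::vector<int> savedParent = L.parent;
    std::vector<double> savedAge = L.age;
    std::vector<int> savedMask = L.mask, savedPost = L.postorder;
    int savedRoot = L.root;
    double savedLoglik = L.loglik, savedMsc = L.logmsc;
    int pj = detParent(j);
    L.parent[s] = (p == savedRoot) ? -1 : g;     // detach
    L.parent[p] = pj;                            // re-insert above j
    L.parent[j] = p;
    L.age[p] = tNew;
    L.rebuildTopology();
    L.rebuildMasks(sp);
    double newMsc = mscLogDensity(L, sp);
    static thread_local PartialUpdate pu;
    double newLik = 0.0;
    if (likeOn && L.hasData) {
      static thread_local std::vector<char> dirty;
      dirty.assign(L.nn, 0);
      dirty[p] = 1;
      if (g >= 0) dirty[g] = 1;
      if (pj >= 0) dirty[pj] = 1;
      newLik = pu.apply(L, dirty);
    }
    // q(x|x')/q(x'|x) = [q(t|t')/kOld] / [q(t'|t)/kNew]
    //                 = (tNew/tOld) * kNew / kOld
    double lhast = std::log(tNew / tOld) + std::log((double)kNew) -
      std::log((double)kOld);
    double lr = newLik - savedLoglik + newMsc - savedMsc + lhast;
    if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
      L.loglik = newLik; L.logmsc = newMsc; accSpr.acc++;
    } else {
      if (likeOn && L.hasData) pu.revert(L);
      L.parent = savedParent; L.age = savedAge;
      L.mask = savedMask; L.loglik = savedLoglik; L.logmsc = savedMsc;
      L.rebuildTopology();           // restores left/right/root/postorder
    }
  }

  // --- species-tree node age (rubber band)
  void moveTau(int J) {
    accTau.prop++;
    double tL = std::max(sp.tau[sp.left[J]], sp.tau[sp.right[J]]);
    double tOld = sp.tau[J], tNew, lhast = 0.0;
    bool isRoot = (sp.parent[J] < 0);
    double tU = isRoot ? R_PosInf : sp.tau[sp.parent[J]];
    if (isRoot) {
      double span = tOld - tL;
      if (span <= 0) span = 1e-12;
      tNew = tL + span * std::exp(st.tau * (unif_rand() - 0.5));
      lhast = std::log((tNew - tL) / span);
    } else {
      if (tU <= tL) return;
      double w = st.tau * (tU - tL);
      tNew = tOld + w * (unif_rand() - 0.5);
      while (tNew < tL || tNew > tU) {
        if (tNew < tL) tNew = 2 * tL - tNew;
        if (tNew > tU) tNew = 2 * tU - tNew;
      }
    }
    // rubber-band remap of gene-node ages in the three adjacent pops
    double oldPriorTau = logPriorTau(sp, pr);
    double oldLik = totalLogLik(), oldMsc = totalLogMsc();
    std::vector<std::vector<double>> savedAges(loci.size());
    double ljac = 0.0;
    int c1 = sp.left[J], c2 = sp.right[J];
    std::vector<bool> changed(loci.size(), false);
    std::vector<std::vector<char>> dirtyAll(loci.size());
    for (size_t li = 0; li < loci.size(); ++li) {
      Locus& L = loci[li];
      savedAges[li] = L.age;
      dirtyAll[li].assign(L.nn, 0);
      for (int v = L.ntip; v < L.nn; ++v) {
        int pop = sp.popOf(L.mask[v], L.age[v]);
        if (pop == c1 || pop == c2) {
          double base = sp.tau[pop];
          double f = (tNew - base) / (tOld - base);
          L.age[v] = base + (L.age[v] - base) * f;
          ljac += std::log(f);
          changed[li] = true; dirtyAll[li][v] = 1;
        } else if (pop == J) {
          if (isRoot) {
            L.age[v] += (tNew - tOld);
          } else {
            double f = (tU - tNew) / (tU - tOld);
            L.age[v] = tU - (tU - L.age[v]) * f;
            ljac += std::log(f);
          }
          changed[li] = true; dirtyAll[li][v] = 1;
        }
      }
    }
    sp.tau[J] = tNew;
    sp.rebuild();
    double newPriorTau = logPriorTau(sp, pr);
    double newLik = 0.0, newMsc = 0.0;
    std::vector<double> savedLik(loci.size()), savedMsc(loci.size());
    std::vector<PartialUpdate> pus(loci.size());
    for (size_t li = 0; li < loci.size(); ++li) {
      Locus& L = loci[li];
      savedLik[li] = L.loglik; savedMsc[li] = L.logmsc;
      L.logmsc = mscLogDensity(L, sp);
      if (changed[li] && likeOn && L.hasData)
        L.loglik = pus[li].apply(L, dirtyAll[li]);
      newLik += L.loglik; newMsc += L.logmsc;
    }
    double lr = newLik - oldLik + newMsc - oldMsc +
      newPriorTau - oldPriorTau + lhast + ljac;
    if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
      accTau.acc++;
    } else {
      sp.tau[J] = tOld;
      sp.rebuild();
      for (size_t li = 0; li < loci.size(); ++li) {
        Locus& L = loci[li];
        if (changed[li] && likeOn && L.hasData) pus[li].revert(L);
        L.age = savedAges[li];
        L.loglik = savedLik[li];
        L.logmsc = savedMsc[li];
      }
    }
  }

  // --- theta multiplier move
  void moveTheta(int v) {
    accTheta.prop++;
    double old = sp.theta[v];
    double prop = old * std::exp(st.theta * (unif_rand() - 0.5));
    double lhast = std::log(prop / old);
    double oldPrior = R::dgamma(old, pr.thetaShape, pr.thetaScale, 1);
    double newPrior = R::dgamma(prop, pr.thetaShape, pr.thetaScale, 1);
    double oldMsc = totalLogMsc();
    sp.theta[v] = prop;
    double newMsc = 0.0;
    std::vector<double> savedMsc(loci.size());
    for (size_t li = 0; li < loci.size(); ++li) {
      savedMsc[li] = loci[li].logmsc;
      loci[li].logmsc = mscLogDensity(loci[li], sp);
      newMsc += loci[li].logmsc;
    }
    double lr = newMsc - oldMsc + newPrior - oldPrior + lhast;
    if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
      accTheta.acc++;
    } else {
      sp.theta[v] = old;
      for (size_t li = 0; li < loci.size(); ++li)
        loci[li].logmsc = savedMsc[li];
    }
  }

  // --- whole-state scale (mixing) move
  void moveMix() {
    accMix.prop++;
    double c = std::exp(st.mix * (unif_rand() - 0.5));
    int nScaled = 0;
    double oldPrior = logPriorTau(sp, pr) + logPriorTheta(sp, pr);
    double oldLik = totalLogLik(), oldMsc = totalLogMsc();
    std::vector<double> savedTau = sp.tau, savedTheta = sp.theta;
    std::vector<std::vector<double>> savedAges(loci.size());
    std::vector<double> savedLik(loci.size()), savedMsc(loci.size());
    for (int v = 0; v < sp.nn; ++v) {
      if (sp.left[v] >= 0) { sp.tau[v] *= c; ++nScaled; }
      sp.theta[v] *= c; ++nScaled;
    }
    for (size_t li = 0; li < loci.size(); ++li) {
      Locus& L = loci[li];
      savedAges[li] = L.age;
      savedLik[li] = L.loglik; savedMsc[li] = L.logmsc;
      for (int v = L.ntip; v < L.nn; ++v) { L.age[v] *= c; ++nScaled; }
    }
    sp.rebuild();
    double newLik = 0.0, newMsc = 0.0;
    for (Locus& L : loci) {
      L.logmsc = mscLogDensity(L, sp);
      if (likeOn) L.loglik = logLikFullAlt(L);
      newLik += L.loglik; newMsc += L.logmsc;
    }
    double newPrior = logPriorTau(sp, pr) + logPriorTheta(sp, pr);
    double lr = newLik - oldLik + newMsc - oldMsc + newPrior - oldPrior +
      nScaled * std::log(c);
    if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
      if (likeOn) for (Locus& L : loci) commitAlt(L);
      accMix.acc++;
    } else {
      sp.tau = savedTau; sp.theta = savedTheta;
      sp.rebuild();
      for (size_t li = 0; li < loci.size(); ++li) {
        loci[li].age = savedAges[li];
        loci[li].loglik = savedLik[li];
        loci[li].logmsc = savedMsc[li];
      }
    }
  }

  // --- rate exchange (Dirichlet-constrained, sum fixed)
  void moveRate() {
    if (loci.size() < 2) return;
    accRate.prop++;
    int i = (int)(unif_rand() * loci.size());
    int j = (int)(unif_rand() * loci.size());
    while (j == i) j = (int)(unif_rand() * loci.size());
    double d = st.rate * (unif_rand() - 0.5);
    double ri = loci[i].rate + d, rj = loci[j].rate - d;
    if (ri <= 0 || rj <= 0) return;
    double oldPrior = (pr.rateDirAlpha - 1.0) *
      (std::log(loci[i].rate) + std::log(loci[j].rate));
    double newPrior = (pr.rateDirAlpha - 1.0) * (std::log(ri) + std::log(rj));
    double oldLik = loci[i].loglik + loci[j].loglik;
    double si = loci[i].rate, sj = loci[j].rate;
    loci[i].rate = ri; loci[j].rate = rj;
    double li2 = likeOn ? logLikFull(loci[i]) : 0.0;
    double lj2 = likeOn ? logLikFull(loci[j]) : 0.0;
    double lr = li2 + lj2 - oldLik + newPrior - oldPrior;
    if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
      loci[i].loglik = li2; loci[j].loglik = lj2; accRate.acc++;
    } else {
      loci[i].rate = si; loci[j].rate = sj;
      if (likeOn) { logLikFull(loci[i]); logLikFull(loci[j]); }
    }
  }

  // --- heredity multiplier move
  void moveHered(Locus& L) {
    accHered.prop++;
    double old = L.hered;
    double prop = old * std::exp(st.hered * (unif_rand() - 0.5));
    double lhast = std::log(prop / old);
    double oldPrior = R::dgamma(old, pr.heredShape,
                                L.heredPriorMean / pr.heredShape, 1);
    double newPrior = R::dgamma(prop, pr.heredShape,
                                L.heredPriorMean / pr.heredShape, 1);
    double oldMsc = L.logmsc;
    L.hered = prop;
    double newMsc = mscLogDensity(L, sp);
    double lr = newMsc - oldMsc + newPrior - oldPrior + lhast;
    if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
      L.logmsc = newMsc; accHered.acc++;
    } else {
      L.hered = old;
    }
  }

  // --- species-tree NNI with tau re-draw (gene trees retained)
  void moveNni() {
    accNni.prop++;
    // pick an internal non-root node C
    std::vector<int> cands;
    for (int v = 0; v < sp.nn; ++v)
      if (sp.left[v] >= 0 && v != sp.root) cands.push_back(v);
    if (cands.empty()) return;
    int C = cands[(int)(unif_rand() * cands.size())];
    int J = sp.parent[C];
    int B = (sp.left[J] == C) ? sp.right[J] : sp.left[J];
    int X = (unif_rand() < 0.5) ? sp.left[C] : sp.right[C];
    double oldTauC = sp.tau[C];
    double oldPrior = logPriorTau(sp, pr);
    double oldMsc = totalLogMsc();
    int Y = (X == sp.left[C]) ? sp.right[C] : sp.left[C];
    // swap B and X: B becomes child of C, X child of J
    std::vector<int> savedParent = sp.parent;
    sp.parent[B] = C;
    sp.parent[X] = J;
    // re-draw tau[C] uniformly in its new valid interval
    double loNew = std::max(sp.tau[B], sp.tau[Y]);
    double hi = sp.tau[J];
    if (hi <= loNew) { sp.parent = savedParent; return; }
    double tauNew = loNew + unif_rand() * (hi - loNew);
    double loOld = std::max(sp.tau[X], sp.tau[Y]);
    double lhast = std::log(hi - loNew) - std::log(hi - loOld);
    sp.tau[C] = tauNew;
    sp.rebuild();
    double newMsc = 0.0;
    std::vector<double> savedMsc(loci.size());
    for (size_t li = 0; li < loci.size(); ++li) {
      savedMsc[li] = loci[li].logmsc;
      loci[li].logmsc = mscLogDensity(loci[li], sp);
      newMsc += loci[li].logmsc;
    }
    double newPrior = logPriorTau(sp, pr);
    double lr = newMsc - oldMsc + newPrior - oldPrior + lhast;
    if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
      accNni.acc++;
    } else {
      sp.parent = savedParent;
      sp.tau[C] = oldTauC;
      sp.rebuild();
      for (size_t li = 0; li < loci.size(); ++li)
        loci[li].logmsc = savedMsc[li];
    }
  }

  // move-class switches (all on by default; used by correctness tests)
  bool onAge = true, onSpr = true, onTau = true, onTheta = true,
       onMix = true;

  void sweep() {
    for (Locus& L : loci) {
      if (onAge) for (int v = L.ntip; v < L.nn; ++v) moveAge(L, v);
      int nspr = std::max(2, L.ntip / 4);
      if (onSpr) for (int k = 0; k < nspr; ++k) moveSpr(L);
      if (estHered) moveHered(L);
    }
    if (onTau && sp.nn > 1)
      for (int v = 0; v < sp.nn; ++v)
        if (sp.left[v] >= 0) moveTau(v);
    if (onTheta) for (int v = 0; v < sp.nn; ++v) moveTheta(v);
    if (onMix) moveMix();
    if (estRates) { moveRate(); moveRate(); }
    if (topoMoves) { moveNni(); moveNni(); }
  }

  void adapt() {
    auto tune = [](AccCount& a, double& s, double lo = 0.2, double hi = 0.5) {
      if (a.prop < 20) return;
      double r = (double)a.acc / a.prop;
      if (r < lo) s /= 1.3;
      if (r > hi) s *= 1.3;
      s = std::min(std::max(s, 1e-4), 20.0);
      a.prop = a.acc = 0;
    };
    tune(accAge, st.age); tune(accSpr, st.sprAge); tune(accTau, st.tau);
    tune(accTheta, st.theta); tune(accMix, st.mix); tune(accRate, st.rate);
    tune(accHered, st.hered);
  }
};

// canonical newick of the species-tree topology (no branch lengths)
static std::string topoNewick(const SpeciesTree& sp, int v,
                              const std::vector<std::string>& labels) {
  if (sp.left[v] < 0) return labels[v];
  std::string a = topoNewick(sp, sp.left[v], labels);
  std::string b = topoNewick(sp, sp.right[v], labels);
  if (b < a) std::swap(a, b);
  return "(" + a + "," + b + ")";
}

// --------------------------------------------------------------- bridge

static SpeciesTree speciesFromR(const List& spec) {
  SpeciesTree sp;
  IntegerVector par = spec["parent"];
  NumericVector tau = spec["tau"], theta = spec["theta"];
  sp.nn = par.size();
  sp.S = (sp.nn + 1) / 2;
  sp.parent.assign(par.begin(), par.end());
  sp.tau.assign(tau.begin(), tau.end());
  sp.theta.assign(theta.begin(), theta.end());
  sp.rebuild();
  return sp;
}

static Locus locusFromR(const List& lr) {
  Locus L;
  IntegerVector par = lr["parent"];
  NumericVector age = lr["age"];
  IntegerVector tipsp = lr["tipsp"];
  L.nn = par.size();
  L.ntip = tipsp.size();
  L.parent.assign(par.begin(), par.end());
  L.age.assign(age.begin(), age.end());
  L.tipsp.assign(tipsp.begin(), tipsp.end());
  L.rate = as<double>(lr["rate"]);
  L.hered = as<double>(lr["hered"]);
  if (lr.containsElementNamed("kappa")) L.kappa = as<double>(lr["kappa"]);
  L.heredPriorMean = as<double>(lr["hered_prior_mean"]);
  if (lr.containsElementNamed("patterns") &&
      !Rf_isNull(lr["patterns"])) {
    IntegerMatrix pat = lr["patterns"];     // ntip x npat
    NumericVector wt = lr["wt"];
    L.npat = pat.ncol();
    L.hasData = L.npat > 0;
    L.tipstate.resize((size_t)L.ntip * L.npat);
    for (int i = 0; i < L.ntip; ++i)
      for (int s = 0; s < L.npat; ++s)
        L.tipstate[(size_t)i * L.npat + s] = pat(i, s);
    L.wt.assign(wt.begin(), wt.end());
  }
  L.rebuildTopology();
  return L;
}

// [[Rcpp::export]]
List msc_mcmc_cpp(List species, List loci_in, List opts) {
  Sampler S;
  S.sp = speciesFromR(species);
  int nloc = loci_in.size();
  for (int l = 0; l < nloc; ++l)
    S.loci.push_back(locusFromR(loci_in[l]));

  List priors = opts["priors"];
  S.pr.thetaShape = as<double>(priors["theta_shape"]);
  S.pr.thetaScale = as<double>(priors["theta_scale"]);
  S.pr.tauMean = as<double>(priors["tau_mean"]);
  S.pr.rootMean = as<double>(priors["root_mean"]);
  S.pr.tauMode = as<int>(priors["tau_mode"]);
  S.pr.rateDirAlpha = as<double>(priors["rate_dir_alpha"]);
  S.pr.heredShape = as<double>(priors["hered_shape"]);
  S.likeOn = as<bool>(opts["likelihood_on"]);
  S.estRates = as<bool>(opts["estimate_rates"]);
  S.estHered = as<bool>(opts["estimate_heredity"]);
  S.topoMoves = as<bool>(opts["topology_moves"]);
  int nGen = as<int>(opts["n_gen"]);
  int burnin = as<int>(opts["burnin"]);
  int thin = as<int>(opts["sample_every"]);
  bool adaptOn = as<bool>(opts["adapt"]);
  if (opts.containsElementNamed("moves_on")) {
    LogicalVector mv = opts["moves_on"];   // age, spr, tau, theta, mix
    S.onAge = mv[0]; S.onSpr = mv[1]; S.onTau = mv[2];
    S.onTheta = mv[3]; S.onMix = mv[4];
  }

  std::vector<std::string> labels(S.sp.S);
  CharacterVector labs = species["labels"];
  for (int i = 0; i < S.sp.S; ++i) labels[i] = as<std::string>(labs[i]);

  GetRNGstate();
  S.refreshAll();

  int nTauCols = 0;
  std::vector<int> tauNodes;
  for (int v = 0; v < S.sp.nn; ++v)
    if (S.sp.left[v] >= 0) { tauNodes.push_back(v); ++nTauCols; }

  int nsamp = (nGen > burnin) ? (nGen - burnin) / thin : 0;
  NumericMatrix tauTrace(nsamp, nTauCols);
  NumericMatrix thetaTrace(nsamp, S.sp.nn);
  NumericMatrix rateTrace(nsamp, nloc);
  NumericMatrix heredTrace(nsamp, nloc);
  NumericVector likTrace(nsamp), mscTrace(nsamp);
  CharacterVector topoTrace(nsamp);

  int si = 0;
  for (int g = 1; g <= nGen; ++g) {
    S.sweep();
    if (adaptOn && g <= burnin && g % 50 == 0) S.adapt();
    if (g > burnin && (g - burnin) % thin == 0 && si < nsamp) {
      for (int k = 0; k < nTauCols; ++k)
        tauTrace(si, k) = S.sp.tau[tauNodes[k]];
      for (int v = 0; v < S.sp.nn; ++v) thetaTrace(si, v) = S.sp.theta[v];
      for (int l = 0; l < nloc; ++l) {
        rateTrace(si, l) = S.loci[l].rate;
        heredTrace(si, l) = S.loci[l].hered;
      }
      likTrace[si] = S.totalLogLik();
      mscTrace[si] = S.totalLogMsc();
      if (S.topoMoves)
        topoTrace[si] = topoNewick(S.sp, S.sp.root, labels);
      ++si;
    }
    if (g % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();

  // final state (for Geweke-style successive-conditional cycling)
  List lociState(nloc);
  for (int l = 0; l < nloc; ++l) {
    const Locus& L = S.loci[l];
    lociState[l] = List::create(
      _["parent"] = IntegerVector(L.parent.begin(), L.parent.end()),
      _["age"] = NumericVector(L.age.begin(), L.age.end()),
      _["rate"] = L.rate, _["hered"] = L.hered);
  }
  List state = List::create(
    _["tau"] = NumericVector(S.sp.tau.begin(), S.sp.tau.end()),
    _["theta"] = NumericVector(S.sp.theta.begin(), S.sp.theta.end()),
    _["sp_parent"] = IntegerVector(S.sp.parent.begin(), S.sp.parent.end()),
    _["loci"] = lociState);

  CharacterVector tauNames(nTauCols);
  for (int k = 0; k < nTauCols; ++k) {
    std::ostringstream nm;
    nm << "tau_" << topoNewick(S.sp, tauNodes[k], labels);
    tauNames[k] = nm.str();
  }
  colnames(tauTrace) = tauNames;

  IntegerVector acc = IntegerVector::create(
    _["age"] = (int)S.accAge.acc, _["spr"] = (int)S.accSpr.acc,
    _["tau"] = (int)S.accTau.acc, _["theta"] = (int)S.accTheta.acc,
    _["mix"] = (int)S.accMix.acc, _["rate"] = (int)S.accRate.acc,
    _["hered"] = (int)S.accHered.acc, _["nni"] = (int)S.accNni.acc);
  IntegerVector prop = IntegerVector::create(
    _["age"] = (int)S.accAge.prop, _["spr"] = (int)S.accSpr.prop,
    _["tau"] = (int)S.accTau.prop, _["theta"] = (int)S.accTheta.prop,
    _["mix"] = (int)S.accMix.prop, _["rate"] = (int)S.accRate.prop,
    _["hered"] = (int)S.accHered.prop, _["nni"] = (int)S.accNni.prop);

  return List::create(
    _["tau"] = tauTrace, _["theta"] = thetaTrace,
    _["rate"] = rateTrace, _["hered"] = heredTrace,
    _["loglik"] = likTrace, _["logmsc"] = mscTrace,
    _["topology"] = topoTrace,
    _["state"] = state, _["accept"] = acc, _["propose"] = prop);
}

// standalone MSC log density (cross-check against the R implementation)
// [[Rcpp::export]]
double msc_logdensity_cpp(List species, List locus) {
  SpeciesTree sp = speciesFromR(species);
  Locus L = locusFromR(locus);
  L.rebuildMasks(sp);
  return mscLogDensity(L, sp);
}

// standalone JC69 log likelihood (cross-check against phangorn)
// [[Rcpp::export]]
double jc_loglik_cpp(List locus) {
  Locus L = locusFromR(locus);
  if (!L.hasData) return 0.0;
  L.clv.assign((size_t)L.nn * L.npat * 4, 0.0);
  return logLikFull(L);
}
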