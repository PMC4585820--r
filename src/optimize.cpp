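// Louvain optimizer with recursive refinement for signed-graph objectives:
//   obj 0: signed CPM        H = a*sum_c(w+_c - l*Nc(Nc-1)) - (1-a)*sum_c(w-_c - l'*Nc(Nc-1))
//   obj 1: signed modularity Q = a*Q+(G+) - (1-a)*Q-(G-)
//   obj 2: unsigned two-level map equation (positive subgraph, closed-form
//          flows p_i = s_i/omega, exits q_c = boundary_c/omega), maximizing
//          the negated partition-dependent part of the description length.
// All internal weights are "directed" sums (each undirected edge counted
// twice); node-set moves use exact deltas so the objective never decreases.

#include <Rcpp.h>
#include <vector>
#include <random>
#include <algorithm>
#include <unordered_map>
#include <cmath>

using namespace Rcpp;

static inline double plogp(double x) { return x > 0 ? x * std::log2(x) : 0.0; }

struct Params {
  int obj;                  // 0 CPM, 1 modularity, 2 map
  double lambda, lambdaNeg, alpha;
  double omegaP, omegaN;    // leaf directed totals (modularity, map)
  double eps;
};

struct Graph {
  int n;
  std::vector<std::vector<std::pair<int, double>>> pos, neg;
  std::vector<double> selfP, selfN;  // internal directed weight of super-node
  std::vector<double> sP, sN;        // strengths incl. self weight
  std::vector<double> pmass;         // leaf visit mass (map objective)
  std::vector<int> size;             // leaf node count

  void init(int n_) {
    n = n_;
    pos.assign(n, {}); neg.assign(n, {});
    selfP.assign(n, 0.0); selfN.assign(n, 0.0);
    sP.assign(n, 0.0); sN.assign(n, 0.0);
    pmass.assign(n, 0.0); size.assign(n, 1);
  }
  void finalizeStrengths() {
    for (int v = 0; v < n; ++v) {
      double a = selfP[v], b = selfN[v];
      for (auto& e : pos[v]) a += e.second;
      for (auto& e : neg[v]) b += e.second;
      sP[v] = a; sN[v] = b;
    }
  }
};

static Graph buildLeafGraph(int n, const NumericMatrix& posE,
                            const NumericMatrix& negE) {
  Graph G; G.init(n);
  for (int r = 0; r < posE.nrow(); ++r) {
    int i = (int)posE(r, 0) - 1, j = (int)posE(r, 1) - 1;
    double w = posE(r, 2);
    G.pos[i].push_back({j, w}); G.pos[j].push_back({i, w});
  }
  for (int r = 0; r < negE.nrow(); ++r) {
    int i = (int)negE(r, 0) - 1, j = (int)negE(r, 1) - 1;
    double w = negE(r, 2);
    G.neg[i].push_back({j, w}); G.neg[j].push_back({i, w});
  }
  G.finalizeStrengths();
  double omega = 0;
  for (int v = 0; v < n; ++v) omega += G.sP[v];
  for (int v = 0; v < n; ++v) G.pmass[v] = omega > 0 ? G.sP[v] / omega : 0.0;
  return G;
}

// Per-module aggregates for the current level.
struct Aggregates {
  std::vector<int> N;                 // leaf counts
  std::vector<double> WinP, WinN;     // internal directed weights
  std::vector<double> SP, SN, P;      // strengths, map mass
  std::vector<int> freeIds;
  double qt = 0;                      // map: sum of module exits

  void build(const Graph& G, const std::vector<int>& memb, int K,
             const Params& par) {
    N.assign(K, 0); WinP.assign(K, 0.0); WinN.assign(K, 0.0);
    SP.assign(K, 0.0); SN.assign(K, 0.0); P.assign(K, 0.0);
    freeIds.clear();
    for (int v = 0; v < G.n; ++v) {
      int c = memb[v];
      N[c] += G.size[v]; SP[c] += G.sP[v]; SN[c] += G.sN[v];
      P[c] += G.pmass[v];
      WinP[c] += G.selfP[v]; WinN[c] += G.selfN[v];
      for (auto& e : G.pos[v]) if (memb[e.first] == c) WinP[c] += e.second;
      for (auto& e : G.neg[v]) if (memb[e.first] == c) WinN[c] += e.second;
    }
    qt = 0;
    if (par.obj == 2 && par.omegaP > 0)
      for (int c = 0; c < K; ++c) qt += (SP[c] - WinP[c]) / par.omegaP;
  }
  double q(int c, const Params& par) const {
    return par.omegaP > 0 ? (SP[c] - WinP[c]) / par.omegaP : 0.0;
  }
  int grow() {
    int c;
    if (!freeIds.empty()) { c = freeIds.back(); freeIds.pop_back(); }
    else {
      c = (int)N.size();
      N.push_back(0); WinP.push_back(0); WinN.push_back(0);
      SP.push_back(0); SN.push_back(0); P.push_back(0);
    }
    return c;
  }
};

// Objective value from scratch (map: negated partition-dependent part).
static double objectiveValue(const Graph& G, const std::vector<int>& memb,
                             int K, const Params& par) {
  Aggregates A; A.build(G, memb, K, par);
  double val = 0;
  if (par.obj == 0) {
    for (int c = 0; c < K; ++c) {
      double pairs = (double)A.N[c] * (A.N[c] - 1);
      val += par.alpha * (A.WinP[c] - par.lambda * pairs)
           - (1 - par.alpha) * (A.WinN[c] - par.lambdaNeg * pairs);
    }
  } else if (par.obj == 1) {
    double qp = 0, qn = 0;
    if (par.omegaP > 0)
      for (int c = 0; c < K; ++c)
        qp += A.WinP[c] / par.omegaP
            - (A.SP[c] / par.omegaP) * (A.SP[c] / par.omegaP);
    if (par.omegaN > 0)
      for (int c = 0; c < K; ++c)
        qn += A.WinN[c] / par.omegaN
            - (A.SN[c] / par.omegaN) * (A.SN[c] / par.omegaN);
    val = par.omegaN > 0 ? par.alpha * qp - (1 - par.alpha) * qn : qp;
  } else {
    double F = plogp(A.qt);
    for (int c = 0; c < K; ++c) {
      double qc = A.q(c, par);
      F += -2 * plogp(qc) + plogp(qc + A.P[c]);
    }
    val = -F;
  }
  return val;
}

// Gain of inserting super-node v into module d, relative to leaving v
// isolated in a fresh module; aggregates must exclude v.
static double insertGain(const Graph& G, const Aggregates& A, int v, int d,
                         double wpD, double wnD, const Params& par) {
  if (par.obj == 0) {
    double pairs = 2.0 * A.N[d] * G.size[v];
    return par.alpha * (2 * wpD - par.lambda * pairs)
         - (1 - par.alpha) * (2 * wnD - par.lambdaNeg * pairs);
  }
  if (par.obj == 1) {
    double gp = 0, gn = 0;
    if (par.omegaP > 0)
      gp = 2 * wpD / par.omegaP
         - 2 * G.sP[v] * A.SP[d] / (par.omegaP * par.omegaP);
    if (par.omegaN > 0)
      gn = 2 * wnD / par.omegaN
         - 2 * G.sN[v] * A.SN[d] / (par.omegaN * par.omegaN);
    return par.omegaN > 0 ? par.alpha * gp - (1 - par.alpha) * gn : gp;
  }
  // map
  double om = par.omegaP;
  if (om <= 0) return 0.0;
  double b0 = (G.sP[v] - G.selfP[v]) / om;
  double bd = (G.sP[v] - G.selfP[v] - 2 * wpD) / om;
  double qd = A.q(d, par);
  double qtrm = A.qt;  // aggregates exclude v entirely
  return -(plogp(qtrm + bd) - plogp(qtrm + b0))
       + 2 * (plogp(qd + bd) - plogp(qd) - plogp(b0))
       - (plogp(qd + bd + A.P[d] + G.pmass[v])
          - plogp(qd + A.P[d]) - plogp(b0 + G.pmass[v]));
}

static void removeNode(const Graph& G, Aggregates& A, int v, int c,
                       double wpC, double wnC, const Params& par) {
  if (par.obj == 2 && par.omegaP > 0)
    A.qt -= (G.sP[v] - G.selfP[v] - 2 * wpC) / par.omegaP;
  A.N[c] -= G.size[v]; A.SP[c] -= G.sP[v]; A.SN[c] -= G.sN[v];
  A.P[c] -= G.pmass[v];
  A.WinP[c] -= G.selfP[v] + 2 * wpC;
  A.WinN[c] -= G.selfN[v] + 2 * wnC;
  if (A.N[c] == 0) A.freeIds.push_back(c);
}

static void insertNode(const Graph& G, Aggregates& A, int v, int d,
                       double wpD, double wnD, const Params& par) {
  if (A.N[d] == 0) {
    auto it = std::find(A.freeIds.begin(), A.freeIds.end(), d);
    if (it != A.freeIds.end()) A.freeIds.erase(it);
  }
  if (par.obj == 2 && par.omegaP > 0)
    A.qt += (G.sP[v] - G.selfP[v] - 2 * wpD) / par.omegaP;
  A.N[d] += G.size[v]; A.SP[d] += G.sP[v]; A.SN[d] += G.sN[v];
  A.P[d] += G.pmass[v];
  A.WinP[d] += G.selfP[v] + 2 * wpD;
  A.WinN[d] += G.selfN[v] + 2 * wnD;
}

// Repeated single-(super-)node move sweeps; returns true if anything moved.
static bool sweeps(const Graph& G, std::vector<int>& memb, Aggregates& A,
                   const Params& par, std::mt19937& rng,
                   int maxPasses = 1000) {
  int n = G.n;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  size_t cap = A.N.size() + n + 1;
  std::vector<double> wpTo(cap, 0.0), wnTo(cap, 0.0);
  std::vector<char> touched(cap, 0);
  std::vector<int> touchList;
  bool any = false;

  for (int pass = 0; pass < maxPasses; ++pass) {
    std::shuffle(order.begin(), order.end(), rng);
    bool moved = false;
    for (int oi = 0; oi < n; ++oi) {
      int v = order[oi];
      int c = memb[v];
      touchList.clear();
      auto touch = [&](int mod) {
        if ((size_t)mod >= cap) {
          cap = mod + n + 1;
          wpTo.resize(cap, 0.0); wnTo.resize(cap, 0.0); touched.resize(cap, 0);
        }
        if (!touched[mod]) { touched[mod] = 1; touchList.push_back(mod); }
      };
      touch(c);
      for (auto& e : G.pos[v]) { int m = memb[e.first]; touch(m); wpTo[m] += e.second; }
      for (auto& e : G.neg[v]) { int m = memb[e.first]; touch(m); wnTo[m] += e.second; }

      removeNode(G, A, v, c, wpTo[c], wnTo[c], par);

      double stayGain = insertGain(G, A, v, c, wpTo[c], wnTo[c], par);
      std::sort(touchList.begin(), touchList.end());
      int bestD = -1; double bestGain = 0;
      for (int d : touchList) {
        if (d == c) continue;
        double gn = insertGain(G, A, v, d, wpTo[d], wnTo[d], par);
        if (bestD < 0 || gn > bestGain + 1e-15) { bestD = d; bestGain = gn; }
      }
      // candidates: stay, best neighboring module, fresh empty module
      // (gain 0 by construction); strict improvement required to move,
      // ties among equal-gain targets go to the lowest module id.
      int target = c; double targetGain = stayGain;
      if (bestD >= 0 && bestGain > targetGain + par.eps) {
        target = bestD; targetGain = bestGain;
      }
      bool fresh = (A.N[c] > 0 || target != c) && 0.0 > targetGain + par.eps;
      if (fresh) {
        int d = A.grow();
        touch(d);
        insertNode(G, A, v, d, 0.0, 0.0, par);
        memb[v] = d;
        moved = true; any = true;
      } else if (target != c) {
        insertNode(G, A, v, target, wpTo[target], wnTo[target], par);
        memb[v] = target;
        moved = true; any = true;
      } else {
        insertNode(G, A, v, c, wpTo[c], wnTo[c], par);
      }
      for (int t : touchList) { wpTo[t] = 0; wnTo[t] = 0; touched[t] = 0; }
    }
    if (!moved) break;
  }
  return any;
}

static int compact(std::vector<int>& memb) {
  std::unordered_map<int, int> re;
  int k = 0;
  for (auto& c : memb) {
    auto it = re.find(c);
    if (it == re.end()) { re[c] = k; c = k; ++k; }
    else c = it->second;
  }
  return k;
}

static Graph contract(const Graph& G, const std::vector<int>& memb, int K) {
  Graph H; H.init(K);
  for (int c = 0; c < K; ++c) H.size[c] = 0;
  for (int v = 0; v < G.n; ++v) {
    int c = memb[v];
    H.size[c] += G.size[v]; H.pmass[c] += G.pmass[v];
    H.selfP[c] += G.selfP[v]; H.selfN[c] += G.selfN[v];
  }
  std::unordered_map<long long, double> accP, accN;
  for (int v = 0; v < G.n; ++v) {
    for (auto& e : G.pos[v]) {
      if (e.first < v) continue;  // each undirected edge once
      int cu = memb[v], cv = memb[e.first];
      if (cu == cv) H.selfP[cu] += 2 * e.second;
      else {
        long long key = (long long)std::min(cu, cv) * K + std::max(cu, cv);
        accP[key] += e.second;
      }
    }
    for (auto& e : G.neg[v]) {
      if (e.first < v) continue;
      int cu = memb[v], cv = memb[e.first];
      if (cu == cv) H.selfN[cu] += 2 * e.second;
      else {
        long long key = (long long)std::min(cu, cv) * K + std::max(cu, cv);
        accN[key] += e.second;
      }
    }
  }
  for (auto& kv : accP) {
    int a = (int)(kv.first / K), b = (int)(kv.first % K);
    H.pos[a].push_back({b, kv.second}); H.pos[b].push_back({a, kv.second});
  }
  for (auto& kv : accN) {
    int a = (int)(kv.first / K), b = (int)(kv.first % K);
    H.neg[a].push_back({b, kv.second}); H.neg[b].push_back({a, kv.second});
  }
  H.finalizeStrengths();
  return H;
}

// Multi-level Louvain from singletons; returns leaf membership (compact).
static std::vector<int> louvainRun(const Graph& G0, const Params& par,
                                   std::mt19937& rng) {
  std::vector<int> leafMemb(G0.n);
  for (int i = 0; i < G0.n; ++i) leafMemb[i] = i;
  Graph G = G0;
  while (true) {
    std::vector<int> memb(G.n);
    for (int i = 0; i < G.n; ++i) memb[i] = i;
    Aggregates A; A.build(G, memb, G.n, par);
    sweeps(G, memb, A, par, rng);
    int K = compact(memb);
    if (K == G.n) break;
    for (auto& c : leafMemb) c = memb[c];
    G = contract(G, memb, K);
  }
  compact(leafMemb);
  return leafMemb;
}

// Exact global delta for moving node set kappa from its module c to d
// (d == -1 means a fresh module). Aggregates must be current (kappa in c).
static double setMoveDelta(const Graph& G, const std::vector<int>& memb,
                           const Aggregates& A, const std::vector<int>& kappa,
                           int d, const Params& par) {
  int c = memb[kappa[0]];
  std::vector<char> inK(G.n, 0);
  for (int v : kappa) inK[v] = 1;
  double wpC = 0, wnC = 0, wpD = 0, wnD = 0, selfPK = 0, selfNK = 0;
  double spK = 0, snK = 0, pK = 0;
  int nK = 0;
  for (int v : kappa) {
    spK += G.sP[v]; snK += G.sN[v]; pK += G.pmass[v]; nK += G.size[v];
    selfPK += G.selfP[v]; selfNK += G.selfN[v];
    for (auto& e : G.pos[v]) {
      if (inK[e.first]) { selfPK += e.second; continue; }  // counted twice
      if (memb[e.first] == c) wpC += e.second;
      if (d >= 0 && memb[e.first] == d) wpD += e.second;
    }
    for (auto& e : G.neg[v]) {
      if (inK[e.first]) { selfNK += e.second; continue; }
      if (memb[e.first] == c) wnC += e.second;
      if (d >= 0 && memb[e.first] == d) wnD += e.second;
    }
  }
  int Nc = A.N[c], Nd = d >= 0 ? A.N[d] : 0;
  if (par.obj == 0) {
    double pairs = 2.0 * nK * (Nd - Nc + nK);
    return par.alpha * ((2 * wpD - 2 * wpC) - par.lambda * pairs)
         - (1 - par.alpha) * ((2 * wnD - 2 * wnC) - par.lambdaNeg * pairs);
  }
  if (par.obj == 1) {
    double SpC = A.SP[c], SpD = d >= 0 ? A.SP[d] : 0;
    double SnC = A.SN[c], SnD = d >= 0 ? A.SN[d] : 0;
    double gp = 0, gn = 0;
    if (par.omegaP > 0)
      gp = (2 * wpD - 2 * wpC) / par.omegaP
         - 2 * spK * (SpD - SpC + spK) / (par.omegaP * par.omegaP);
    if (par.omegaN > 0)
      gn = (2 * wnD - 2 * wnC) / par.omegaN
         - 2 * snK * (SnD - SnC + snK) / (par.omegaN * par.omegaN);
    return par.omegaN > 0 ? par.alpha * gp - (1 - par.alpha) * gn : gp;
  }
  // map
  double om = par.omegaP;
  if (om <= 0) return 0.0;
  double qc = A.q(c, par), qd = d >= 0 ? A.q(d, par) : 0.0;
  double Pc = A.P[c], Pd = d >= 0 ? A.P[d] : 0.0;
  double qcNew = qc - (spK - selfPK - 2 * wpC) / om;
  double qdNew = qd + (spK - selfPK - 2 * wpD) / om;
  double qtNew = A.qt + (qcNew - qc) + (qdNew - qd);
  double dF = plogp(qtNew) - plogp(A.qt)
            - 2 * (plogp(qcNew) + plogp(qdNew) - plogp(qc) - plogp(qd))
            + (plogp(qcNew + Pc - pK) + plogp(qdNew + Pd + pK)
               - plogp(qc + Pc) - plogp(qd + Pd));
  return -dF;
}

// One refinement pass: leaf-level node sweeps, then submodule proposals
// (Louvain inside each module; submodules moved as units under exact global
// deltas). Returns true if the partition changed.
static bool refineOnce(const Graph& G0, std::vector<int>& memb,
                       const Params& par, std::mt19937& rng) {
  int K = compact(memb);
  Aggregates A; A.build(G0, memb, K, par);
  bool any = sweeps(G0, memb, A, par, rng);
  K = compact(memb);
  A.build(G0, memb, K, par);  // module ids changed; refresh aggregates

  // submodule proposals
  std::vector<std::vector<int>> members(K);
  for (int v = 0; v < G0.n; ++v) members[memb[v]].push_back(v);
  for (int c = 0; c < K; ++c) {
    if ((int)members[c].size() < 3) continue;
    // induced subgraph
    std::vector<int> idx(G0.n, -1);
    int ns = (int)members[c].size();
    for (int t = 0; t < ns; ++t) idx[members[c][t]] = t;
    Graph Gs; Gs.init(ns);
    for (int t = 0; t < ns; ++t) {
      int v = members[c][t];
      Gs.size[t] = G0.size[v]; Gs.selfP[t] = G0.selfP[v];
      Gs.selfN[t] = G0.selfN[v];
      for (auto& e : G0.pos[v])
        if (idx[e.first] >= 0) Gs.pos[t].push_back({idx[e.first], e.second});
      for (auto& e : G0.neg[v])
        if (idx[e.first] >= 0) Gs.neg[t].push_back({idx[e.first], e.second});
    }
    Gs.finalizeStrengths();
    Params parS = par;
    if (par.obj == 1 || par.obj == 2) {
      double op = 0, on = 0;
      for (int t = 0; t < ns; ++t) { op += Gs.sP[t]; on += Gs.sN[t]; }
      parS.omegaP = op; parS.omegaN = on;
    }
    for (int t = 0; t < ns; ++t)
      Gs.pmass[t] = parS.omegaP > 0 ? Gs.sP[t] / parS.omegaP : 0.0;
    std::vector<int> sub = louvainRun(Gs, parS, rng);
    int kSub = 0;
    for (int t = 0; t < ns; ++t) kSub = std::max(kSub, sub[t] + 1);
    if (kSub < 2) continue;
    // propose moving each submodule as a unit
    std::vector<std::vector<int>> subsets(kSub);
    for (int t = 0; t < ns; ++t) subsets[sub[t]].push_back(members[c][t]);
    for (auto& kappa : subsets) {
      if ((int)kappa.size() == (int)members[c].size()) continue;
      // candidate targets: modules adjacent to kappa
      std::vector<int> cands;
      std::vector<char> seen(A.N.size(), 0);
      for (int v : kappa) {
        for (auto& e : G0.pos[v]) {
          int mcur = memb[e.first];
          if (mcur != c && !seen[mcur]) { seen[mcur] = 1; cands.push_back(mcur); }
        }
        for (auto& e : G0.neg[v]) {
          int mcur = memb[e.first];
          if (mcur != c && !seen[mcur]) { seen[mcur] = 1; cands.push_back(mcur); }
        }
      }
      int bestD = -2; double bestDelta = par.eps;
      double dNew = setMoveDelta(G0, memb, A, kappa, -1, par);
      if (dNew > bestDelta) { bestDelta = dNew; bestD = -1; }
      std::sort(cands.begin(), cands.end());
      for (int dmod : cands) {
        double dd = setMoveDelta(G0, memb, A, kappa, dmod, par);
        if (dd > bestDelta + 1e-15) { bestDelta = dd; bestD = dmod; }
      }
      if (bestD != -2) {
        int target = bestD;
        if (target == -1) target = A.grow();
        for (int v : kappa) memb[v] = target;
        any = true;
        A.build(G0, memb, (int)A.N.size(), par);  // refresh after set move
        // membership of module c changed; stop proposing from stale subsets
        break;
      }
    }
  }
  return any;
}

static Params makeParams(int obj, double lambda, double lambdaNeg,
                         double alpha, const Graph& G, double eps) {
  Params par;
  par.obj = obj; par.lambda = lambda; par.lambdaNeg = lambdaNeg;
  par.alpha = alpha; par.eps = eps;
  double op = 0, on = 0;
  for (int v = 0; v < G.n; ++v) { op += G.sP[v]; on += G.sN[v]; }
  par.omegaP = op; par.omegaN = on;
  return par;
}

// [[Rcpp::export]]
List cpp_optimize(int n, NumericMatrix posE, NumericMatrix negE,
                  int objective, double lambda, double lambdaNeg,
                  double alpha, int seed, int refineRounds, double eps,
                  IntegerVector init, bool runLouvain) {
  Graph G = buildLeafGraph(n, posE, negE);
  Params par = makeParams(objective, lambda, lambdaNeg, alpha, G, eps);
  std::mt19937 rng((unsigned)seed);
  std::vector<int> memb(n);
  if (init.size() == n) {
    for (int i = 0; i < n; ++i) memb[i] = init[i] - 1;
    compact(memb);
  } else {
    for (int i = 0; i < n; ++i) memb[i] = i;
  }
  if (runLouvain) memb = louvainRun(G, par, rng);
  for (int r = 0; r < refineRounds; ++r)
    if (!refineOnce(G, memb, par, rng)) break;
  int K = compact(memb);
  double val = objectiveValue(G, memb, K, par);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = memb[i] + 1;
  return List::create(_["membership"] = out, _["value"] = val);
}

// [[Rcpp::export]]
double cpp_set_move_delta(int n, NumericMatrix posE, NumericMatrix negE,
                          int objective, double lambda, double lambdaNeg,
                          double alpha, IntegerVector memb1,
                          IntegerVector kappa1, int target1) {
  Graph G = buildLeafGraph(n, posE, negE);
  Params par = makeParams(objective, lambda, lambdaNeg, alpha, G, 1e-12);
  std::vector<int> memb(n);
  int K = 0;
  for (int i = 0; i < n; ++i) { memb[i] = memb1[i] - 1; K = std::max(K, memb[i] + 1); }
  Aggregates A; A.build(G, memb, K, par);
  std::vector<int> kappa(kappa1.size());
  for (int i = 0; i < kappa1.size(); ++i) kappa[i] = kappa1[i] - 1;
  return setMoveDelta(G, memb, A, kappa, target1 - 1, par);
}

// [[Rcpp::export]]
double cpp_objective_value(int n, NumericMatrix posE, NumericMatrix negE,
                           int objective, double lambda, double lambdaNeg,
                           double alpha, IntegerVector memb1) {
  Graph G = buildLeafGraph(n, posE, negE);
  Params par = makeParams(objective, lambda, lambdaNeg, alpha, G, 1e-12);
  std::vector<int> memb(n);
  int K = 0;
  for (int i = 0; i < n; ++i) { memb[i] = memb1[i] - 1; K = std::max(K, memb[i] + 1); }
  return objectiveValue(G, memb, K, par);
}
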