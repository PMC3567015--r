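// Structured-coalescent simulator for a two-population
// isolation-with-migration model, finite-sites HKY mutation sprinkling,
// and summary-statistic counting. Time unit: one "coalescent unit" in
// which a pair of lineages in a population with theta == theta_ref
// coalesces at rate 1; per-site mutation rate per lineage per unit is
// (theta_ref / 2) * rate_multiplier, so E[pi] = theta for a panmictic
// sample at rate_multiplier 1. tau is expressed in the same unit.
//
// All randomness comes from R's RNG (unif_rand / exp_rand / rpois), so
// set.seed() in R makes every routine reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Genealogy {
  int n_tip;
  std::vector<int> parent;        // size 2n-1; -1 at root
  std::vector<double> node_time;  // tips at 0, root largest
  std::vector<int> tip_pop;       // 1 or 2 per tip
  std::vector<double> mig_time;   // migration events (backward in time)
  std::vector<int> mig_node;      // lineage (node id below the event)
  std::vector<int> mig_from, mig_to;
};

inline int pick_k(double u, int k) {
  int i = static_cast<int>(u * k);
  return i >= k ? k - 1 : i;
}

// Structured coalescent with two demes until tau, then one ancestral deme.
// Coalescence rate per lineage pair in deme i is theta_ref / theta_i;
// migration moves a lineage between demes at per-lineage rate m_i
// (backward in time, from its current deme to the other).
Genealogy sim_genealogy(int n1, int n2, double theta1, double theta2,
                        double thetaA, double tau, double m1, double m2,
                        double theta_ref, long max_events) {
  const int n = n1 + n2;
  Genealogy g;
  g.n_tip = n;
  g.parent.assign(2 * n - 1, -1);
  g.node_time.assign(2 * n - 1, 0.0);
  g.tip_pop.resize(n);
  for (int i = 0; i < n; ++i) g.tip_pop[i] = (i < n1) ? 1 : 2;

  std::vector<int> act1, act2;  // active lineage node ids per deme
  act1.reserve(n); act2.reserve(n);
  for (int i = 0; i < n1; ++i) act1.push_back(i);
  for (int i = 0; i < n2; ++i) act2.push_back(n1 + i);

  double t = 0.0;
  int next_node = n;
  long events = 0;
  bool ancestral = false;

  const double c1 = theta_ref / theta1;
  const double c2 = theta_ref / theta2;
  const double cA = theta_ref / thetaA;

  auto coalesce = [&](std::vector<int>& act, double when) {
    int k = static_cast<int>(act.size());
    int i = pick_k(unif_rand(), k);
    int j = pick_k(unif_rand(), k - 1);
    if (j >= i) ++j;
    int a = act[i], b = act[j];
    int p = next_node++;
    g.parent[a] = p; g.parent[b] = p;
    g.node_time[p] = when;
    // drop the higher index by back-swap first, then overwrite the
    // lower one with the new node (order matters when i or j is last)
    if (i > j) std::swap(i, j);
    act[j] = act.back();
    act.pop_back();
    act[i] = p;
  };

  while (static_cast<int>(act1.size() + act2.size()) > 1) {
    if (++events > max_events)
      stop("genealogy simulation exceeded the event cap (%d); "
           "check the parameter draw", max_events);
    if (!ancestral) {
      int k1 = act1.size(), k2 = act2.size();
      double rc1 = 0.5 * k1 * (k1 - 1) * c1;
      double rc2 = 0.5 * k2 * (k2 - 1) * c2;
      double rm1 = k1 * m1;
      double rm2 = k2 * m2;
      double R = rc1 + rc2 + rm1 + rm2;
      double dt = (R > 0.0) ? exp_rand() / R : R_PosInf;
      if (t + dt >= tau) {
        // merge demes into the ancestral population
        t = tau;
        ancestral = true;
        for (int id : act2) act1.push_back(id);
        act2.clear();
        continue;
      }
      t += dt;
      double u = unif_rand() * R;
      if (u < rc1) {
        coalesce(act1, t);
      } else if (u < rc1 + rc2) {
        coalesce(act2, t);
      } else if (u < rc1 + rc2 + rm1) {
        int i = pick_k(unif_rand(), k1);
        int id = act1[i];
        act1[i] = act1.back(); act1.pop_back();
        act2.push_back(id);
        g.mig_time.push_back(t); g.mig_node.push_back(id);
        g.mig_from.push_back(1); g.mig_to.push_back(2);
      } else {
        int i = pick_k(unif_rand(), k2);
        int id = act2[i];
        act2[i] = act2.back(); act2.pop_back();
        act1.push_back(id);
        g.mig_time.push_back(t); g.mig_node.push_back(id);
        g.mig_from.push_back(2); g.mig_to.push_back(1);
      }
    } else {
      int k = act1.size();
      double R = 0.5 * k * (k - 1) * cA;
      t += exp_rand() / R;
      coalesce(act1, t);
    }
  }
  return g;
}

// children lists from the parent vector
void build_children(const Genealogy& g, std::vector<int>& child1,
                    std::vector<int>& child2, int& root) {
  int m = 2 * g.n_tip - 1;
  child1.assign(m, -1);
  child2.assign(m, -1);
  root = -1;
  for (int v = 0; v < m; ++v) {
    int p = g.parent[v];
    if (p < 0) { root = v; continue; }
    if (child1[p] < 0) child1[p] = v; else child2[p] = v;
  }
}

// HKY conditional substitution kernel with uniform base frequencies:
// given a mutation occurs on base b (0=A,1=C,2=G,3=T), it is a
// transition with probability kappa/(kappa+2), else one of the two
// transversions uniformly.
inline int hky_substitute(int b, double kappa) {
  static const int ts_partner[4] = {2, 3, 0, 1};
  static const int tv1[4] = {1, 0, 1, 0};
  static const int tv2[4] = {3, 2, 3, 2};
  double u = unif_rand() * (kappa + 2.0);
  if (u < kappa) return ts_partner[b];
  return (u < kappa + 1.0) ? tv1[b] : tv2[b];
}

// Summary statistics from per-tip states at variant columns.
// `states` is n x ncol (column-major std::vector), codes 0..3.
// Monomorphic (unrepresented) sites contribute nothing to any
// statistic, so only mutated columns need be present; L scales
// per-site quantities.
void stats_from_columns(const std::vector<signed char>& states, int n,
                        int ncol, int n1, int n2, int L, double* out) {
  double diff1 = 0.0, diff2 = 0.0, diffb = 0.0;
  int S1 = 0, S2 = 0;
  const double npairs1 = 0.5 * n1 * (n1 - 1);
  const double npairs2 = 0.5 * n2 * (n2 - 1);
  const double npairsb = static_cast<double>(n1) * n2;

  for (int c = 0; c < ncol; ++c) {
    const signed char* col = &states[static_cast<size_t>(c) * n];
    int c1[4] = {0, 0, 0, 0}, c2[4] = {0, 0, 0, 0};
    for (int i = 0; i < n1; ++i) ++c1[static_cast<int>(col[i])];
    for (int i = n1; i < n; ++i) ++c2[static_cast<int>(col[i])];
    double same1 = 0.0, same2 = 0.0, sameb = 0.0;
    int alle1 = 0, alle2 = 0;
    for (int a = 0; a < 4; ++a) {
      same1 += 0.5 * c1[a] * (c1[a] - 1);
      same2 += 0.5 * c2[a] * (c2[a] - 1);
      sameb += static_cast<double>(c1[a]) * c2[a];
      if (c1[a] > 0) ++alle1;
      if (c2[a] > 0) ++alle2;
    }
    if (n1 >= 2) { diff1 += npairs1 - same1; if (alle1 > 1) ++S1; }
    if (n2 >= 2) { diff2 += npairs2 - same2; if (alle2 > 1) ++S2; }
    if (n1 >= 1 && n2 >= 1) diffb += npairsb - sameb;
  }

  auto harmonic = [](int k) {
    double a = 0.0;
    for (int i = 1; i < k; ++i) a += 1.0 / i;
    return a;
  };
  auto tajd = [&](int nn, double khat, int S) -> double {
    if (nn < 3 || S < 1) return NA_REAL;
    double a1 = harmonic(nn), a2 = 0.0;
    for (int i = 1; i < nn; ++i) a2 += 1.0 / (static_cast<double>(i) * i);
    double b1 = (nn + 1.0) / (3.0 * (nn - 1.0));
    double b2 = 2.0 * (nn * nn + nn + 3.0) / (9.0 * nn * (nn - 1.0));
    double cc1 = b1 - 1.0 / a1;
    double cc2 = b2 - (nn + 2.0) / (a1 * nn) + a2 / (a1 * a1);
    double e1 = cc1 / a1;
    double e2 = cc2 / (a1 * a1 + a2);
    double denom = std::sqrt(e1 * S + e2 * S * (S - 1.0));
    if (denom <= 0.0) return NA_REAL;
    return (khat - S / a1) / denom;
  };

  double pi1 = (n1 >= 2) ? diff1 / (npairs1 * L) : NA_REAL;
  double pi2 = (n2 >= 2) ? diff2 / (npairs2 * L) : NA_REAL;
  double pib = (n1 >= 1 && n2 >= 1) ? diffb / (npairsb * L) : NA_REAL;
  double pinet = pib - (pi1 + pi2) / 2.0;
  double tw1 = (n1 >= 2) ? S1 / (harmonic(n1) * L) : NA_REAL;
  double tw2 = (n2 >= 2) ? S2 / (harmonic(n2) * L) : NA_REAL;
  out[0] = pi1; out[1] = pi2; out[2] = pib; out[3] = pinet;
  out[4] = tw1; out[5] = tw2;
  out[6] = (n1 >= 2) ? tajd(n1, (npairs1 > 0 ? diff1 / npairs1 : 0.0), S1)
                     : NA_REAL;
  out[7] = (n2 >= 2) ? tajd(n2, (npairs2 > 0 ? diff2 / npairs2 : 0.0), S2)
                     : NA_REAL;
}

// Fused path: genealogy -> sparse mutation columns -> statistics.
// Ancestral bases are drawn only for mutated sites (a monomorphic site
// contributes nothing); multiple hits at one site are handled by
// applying mutations in root-to-tip order along each path.
void sim_pair_stats_one(int n1, int n2, int L, double theta1, double theta2,
                        double thetaA, double tau, double m1, double m2,
                        double mult, double theta_ref, double kappa,
                        long max_events, double* out) {
  Genealogy g = sim_genealogy(n1, n2, theta1, theta2, thetaA, tau, m1, m2,
                              theta_ref, max_events);
  const int n = g.n_tip;
  const int nnode = 2 * n - 1;
  const double mu_site = 0.5 * theta_ref * mult;

  // per-branch mutated columns; column = index into the set of distinct
  // mutated sites, in order of first appearance (deterministic)
  std::vector<std::vector<int> > branch_mut(nnode);
  std::vector<int> site_of_col;
  std::vector<signed char> root_state;
  // site -> column lookup; L can be large so use a flat map
  std::vector<int> col_of_site(L, -1);

  for (int v = 0; v < nnode; ++v) {
    if (g.parent[v] < 0) continue;
    double len = g.node_time[g.parent[v]] - g.node_time[v];
    double lambda = len * mu_site * L;
    int nm = static_cast<int>(R::rpois(lambda));
    for (int k = 0; k < nm; ++k) {
      int site = pick_k(unif_rand(), L);
      int col = col_of_site[site];
      if (col < 0) {
        col = site_of_col.size();
        col_of_site[site] = col;
        site_of_col.push_back(site);
        root_state.push_back(static_cast<signed char>(pick_k(unif_rand(), 4)));
      }
      branch_mut[v].push_back(col);
    }
  }

  const int ncol = site_of_col.size();
  std::vector<signed char> state(root_state);
  std::vector<signed char> tips(static_cast<size_t>(n) * ncol);

  std::vector<int> child1, child2;
  int root;
  build_children(g, child1, child2, root);

  // iterative DFS with undo log (explicit stack; trees can be deep)
  struct Frame { int node; int stage; size_t undo_mark; };
  std::vector<std::pair<int, signed char> > undo;
  std::vector<Frame> stack;
  stack.push_back({root, 0, 0});
  while (!stack.empty()) {
    Frame& f = stack.back();
    if (f.stage == 0) {
      f.undo_mark = undo.size();
      if (g.parent[f.node] >= 0) {
        for (int col : branch_mut[f.node]) {
          undo.push_back(std::make_pair(col, state[col]));
          state[col] = static_cast<signed char>(
              hky_substitute(state[col], kappa));
        }
      }
      if (f.node < n) {  // tip: record states column-major
        for (int c = 0; c < ncol; ++c)
          tips[static_cast<size_t>(c) * n + f.node] = state[c];
      }
      f.stage = 1;
      if (child1[f.node] >= 0) stack.push_back({child1[f.node], 0, 0});
    } else if (f.stage == 1) {
      f.stage = 2;
      if (child2[f.node] >= 0) stack.push_back({child2[f.node], 0, 0});
    } else {
      while (undo.size() > f.undo_mark) {
        state[undo.back().first] = undo.back().second;
        undo.pop_back();
      }
      stack.pop_back();
    }
  }

  stats_from_columns(tips, n, ncol, n1, n2, L, out);
}

}  // namespace

// [[Rcpp::export]]
List cpp_sim_genealogy(int n1, int n2, double theta1, double theta2,
                       double thetaA, double tau, double m1, double m2,
                       double theta_ref, double max_events) {
  Genealogy g = sim_genealogy(n1, n2, theta1, theta2, thetaA, tau, m1, m2,
                              theta_ref, static_cast<long>(max_events));
  int nm = g.mig_time.size();
  NumericMatrix mig(nm, 4);
  for (int i = 0; i < nm; ++i) {
    mig(i, 0) = g.mig_time[i];
    mig(i, 1) = g.mig_node[i] + 1;  // 1-based for R
    mig(i, 2) = g.mig_from[i];
    mig(i, 3) = g.mig_to[i];
  }
  colnames(mig) = CharacterVector::create("time", "node", "from", "to");
  return List::create(
      _["n_tip"] = g.n_tip,
      _["parent"] = IntegerVector(g.parent.begin(), g.parent.end()),
      _["node_time"] = NumericVector(g.node_time.begin(), g.node_time.end()),
      _["tip_pop"] = IntegerVector(g.tip_pop.begin(), g.tip_pop.end()),
      _["migrations"] = mig,
      _["tmrca"] = g.node_time[2 * g.n_tip - 2]);
}

// [[Rcpp::export]]
IntegerMatrix cpp_mutate_on_tree(IntegerVector parent, NumericVector node_time,
                                 int n_tip, int L, double mu_site,
                                 double kappa) {
  const int nnode = parent.size();
  Genealogy g;
  g.n_tip = n_tip;
  g.parent.assign(parent.begin(), parent.end());
  g.node_time.assign(node_time.begin(), node_time.end());

  // full ancestral sequence, uniform bases
  std::vector<signed char> state(L);
  for (int s = 0; s < L; ++s)
    state[s] = static_cast<signed char>(pick_k(unif_rand(), 4));

  std::vector<std::vector<int> > branch_mut(nnode);
  for (int v = 0; v < nnode; ++v) {
    if (g.parent[v] < 0) continue;
    double len = g.node_time[g.parent[v]] - g.node_time[v];
    if (len < 0) stop("node times are not consistent with the parent vector");
    int nm = static_cast<int>(R::rpois(len * mu_site * L));
    for (int k = 0; k < nm; ++k)
      branch_mut[v].push_back(pick_k(unif_rand(), L));
  }

  std::vector<int> child1, child2;
  int root;
  build_children(g, child1, child2, root);

  IntegerMatrix aln(n_tip, L);
  struct Frame { int node; int stage; size_t undo_mark; };
  std::vector<std::pair<int, signed char> > undo;
  std::vector<Frame> stack;
  stack.push_back({root, 0, 0});
  while (!stack.empty()) {
    Frame& f = stack.back();
    if (f.stage == 0) {
      f.undo_mark = undo.size();
      if (g.parent[f.node] >= 0) {
        for (int site : branch_mut[f.node]) {
          undo.push_back(std::make_pair(site, state[site]));
          state[site] = static_cast<signed char>(
              hky_substitute(state[site], kappa));
        }
      }
      if (f.node < n_tip)
        for (int s = 0; s < L; ++s) aln(f.node, s) = state[s] + 1;
      f.stage = 1;
      if (child1[f.node] >= 0) stack.push_back({child1[f.node], 0, 0});
    } else if (f.stage == 1) {
      f.stage = 2;
      if (child2[f.node] >= 0) stack.push_back({child2[f.node], 0, 0});
    } else {
      while (undo.size() > f.undo_mark) {
        state[undo.back().first] = undo.back().second;
        undo.pop_back();
      }
      stack.pop_back();
    }
  }
  return aln;
}

// [[Rcpp::export]]
NumericVector cpp_sim_pair_stats(int n1, int n2, int L, double theta1,
                                 double theta2, double thetaA, double tau,
                                 double m1, double m2, double mult,
                                 double theta_ref, double kappa,
                                 double max_events) {
  NumericVector out(8);
  sim_pair_stats_one(n1, n2, L, theta1, theta2, thetaA, tau, m1, m2, mult,
                     theta_ref, kappa, static_cast<long>(max_events),
                     out.begin());
  return out;
}

// Reference table inner loop: `par` holds one row per simulated dataset
// with 6 columns per pair (theta1, theta2, thetaA, tau, m1, m2); returns
// 8 statistics per pair per row.
// [[Rcpp::export]]
NumericMatrix cpp_study_stats(NumericMatrix par, IntegerVector n1,
                              IntegerVector n2, IntegerVector L,
                              NumericVector mult, double theta_ref,
                              double kappa, double max_events) {
  const int nsim = par.nrow();
  const int Y = n1.size();
  if (par.ncol() != 6 * Y) stop("parameter matrix has wrong width");
  NumericMatrix out(nsim, 8 * Y);
  std::vector<double> buf(8);
  for (int s = 0; s < nsim; ++s) {
    for (int p = 0; p < Y; ++p) {
      const int o = 6 * p;
      sim_pair_stats_one(n1[p], n2[p], L[p], par(s, o), par(s, o + 1),
                         par(s, o + 2), par(s, o + 3), par(s, o + 4),
                         par(s, o + 5), mult[p], theta_ref, kappa,
                         static_cast<long>(max_events), &buf[0]);
      for (int j = 0; j < 8; ++j) out(s, 8 * p + j) = buf[j];
    }
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Statistics straight from an integer alignment (codes 1..4, no missing
// data) — used to cross-check the R implementations on materialised
// simulated alignments.
// [[Rcpp::export]]
NumericVector cpp_aln_stats(IntegerMatrix aln, int n1, int n2) {
  const int n = aln.nrow();
  const int L = aln.ncol();
  if (n1 + n2 != n) stop("n1 + n2 must equal the number of sequences");
  std::vector<signed char> states(static_cast<size_t>(n) * L);
  for (int c = 0; c < L; ++c)
    for (int i = 0; i < n; ++i)
      states[static_cast<size_t>(c) * n + i] =
          static_cast<signed char>(aln(i, c) - 1);
  NumericVector out(8);
  stats_from_columns(states, n, L, n1, n2, L, out.begin());
  return out;
}
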