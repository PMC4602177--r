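// Numerical kernels: two-type birth-death tables along the discretized
// species tree, the gene-tree prior dynamic program, and the forward
// Monte-Carlo oracle for the two-type process.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// derivative of (Eg, Ep, Ig, Ip): extinction probabilities of a gene and a
// pseudogene lineage and their running time-integrals.  Time runs towards
// the root; a gene lineage duplicates/dies/converts at delta/mu/psi, a
// pseudogene lineage duplicates/dies at delta/mu.
static inline void bd_deriv(const double *y, double *dy,
                            double delta, double mu, double psi) {
  double Eg = y[0], Ep = y[1];
  dy[0] = mu - (delta + mu + psi) * Eg + delta * Eg * Eg + psi * Ep;
  dy[1] = mu - (delta + mu) * Ep + delta * Ep * Ep;
  dy[2] = Eg;
  dy[3] = Ep;
}

// RK4 over one slice of duration dt starting from (Eg0, Ep0); integrals
// start at zero.  nsub fixed substeps.
static void bd_slice(double Eg0, double Ep0, double dt, int nsub,
                     double delta, double mu, double psi, double *out) {
  double y[4] = {Eg0, Ep0, 0.0, 0.0};
  double h = dt / nsub;
  double k1[4], k2[4], k3[4], k4[4], tmp[4];
  for (int s = 0; s < nsub; s++) {
    bd_deriv(y, k1, delta, mu, psi);
    for (int i = 0; i < 4; i++) tmp[i] = y[i] + 0.5 * h * k1[i];
    bd_deriv(tmp, k2, delta, mu, psi);
    for (int i = 0; i < 4; i++) tmp[i] = y[i] + 0.5 * h * k2[i];
    bd_deriv(tmp, k3, delta, mu, psi);
    for (int i = 0; i < 4; i++) tmp[i] = y[i] + h * k3[i];
    bd_deriv(tmp, k4, delta, mu, psi);
    for (int i = 0; i < 4; i++)
      y[i] += h / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
    if (y[0] < 0) y[0] = 0; if (y[0] > 1) y[0] = 1;
    if (y[1] < 0) y[1] = 0; if (y[1] > 1) y[1] = 1;
  }
  out[0] = y[0]; out[1] = y[1]; out[2] = y[2]; out[3] = y[3];
}

// [[Rcpp::export]]
List bd_tables_cpp(IntegerVector pt_parent, NumericVector pt_time,
                   IntegerVector order, double delta, double mu, double psi,
                   int nsub) {
  int n = pt_parent.size();
  std::vector< std::vector<int> > kids(n);
  for (int i = 0; i < n; i++)
    if (pt_parent[i] >= 0) kids[pt_parent[i]].push_back(i);
  NumericVector eps_g(n), eps_p(n), arc_g(n), arc_p(n),
                p11_g(n, 1.0), p11_p(n, 1.0);
  for (int oi = 0; oi < n; oi++) {
    int x = order[oi];
    if (kids[x].empty()) { eps_g[x] = 0.0; eps_p[x] = 0.0; continue; }
    double pg = 1.0, pp = 1.0, out[4];
    for (size_t c = 0; c < kids[x].size(); c++) {
      int z = kids[x][c];
      double dt = pt_time[x] - pt_time[z];
      bd_slice(eps_g[z], eps_p[z], dt, nsub, delta, mu, psi, out);
      arc_g[z] = out[0]; arc_p[z] = out[1];
      p11_g[z] = std::exp(2.0 * delta * out[2] - (delta + mu + psi) * dt);
      p11_p[z] = std::exp(2.0 * delta * out[3] - (delta + mu) * dt);
      pg *= out[0]; pp *= out[1];
    }
    eps_g[x] = pg; eps_p[x] = pp;
  }
  return List::create(_["eps_g"] = eps_g, _["eps_p"] = eps_p,
                      _["eps_arc_g"] = arc_g, _["eps_arc_p"] = arc_p,
                      _["p11_g"] = p11_g, _["p11_p"] = p11_p);
}

// induced density of an edge length l over a time span t under the
// gamma rate density: g(l, t) = dgamma(l / t; shape, scale) / t
static inline double glen(double l, double t, double shape, double scale) {
  if (t <= 0) return 0.0;
  return R::dgamma(l / t, shape, scale, 0) / t;
}

// Gene-tree prior dynamic program over the discretized species tree.
// Point arrays are 0-based; pt_kind: 0 interior, 1 speciation vertex,
// 2 leaf vertex, 3 degree-one root.  Gene-tree arrays are 0-based over all
// vertices except that the degree-one gene-tree root is excluded from
// `post` (its single child carries the stem edge).
// [[Rcpp::export]]
List dp_stable_cpp(IntegerVector pt_parent, NumericVector pt_time,
                   IntegerVector pt_kind, NumericVector wt,
                   IntegerVector sibling, IntegerVector side,
                   NumericVector eps_arc_g, NumericVector eps_arc_p,
                   NumericVector p11_g, NumericVector p11_p,
                   IntegerVector post, IntegerVector child1,
                   IntegerVector child2, LogicalVector is_leaf,
                   LogicalVector is_psi, IntegerVector edge_mode,
                   NumericVector elen, IntegerVector sigma_pt,
                   int root_child, int root_point,
                   double delta, double psi_rate,
                   double shape, double scale, bool return_tables) {
  int npts = pt_parent.size();
  int nall = child1.size();
  std::vector< std::vector<double> > Rsum(nall), S0(nall), S1(nall);
  std::vector<double> ls(nall, 0.0);
  List tables(return_tables ? nall : 0);
  std::vector< std::vector<double> > Mstore; // kept only when returning
  bool dead = false;
  for (int pi = 0; pi < post.size() && !dead; pi++) {
    int u = post[pi];
    int v = child1[u], w = child2[u];
    double l_u = elen[u];
    int mode = edge_mode[u];
    std::vector<double> M;
    if (return_tables) M.assign((size_t)npts * npts, 0.0);
    std::vector<double> Ru(npts, 0.0), S0u(npts, 0.0), S1u(npts, 0.0);
    double lsu = 0.0;
    if (is_leaf[u]) lsu = 0.0;
    else if (is_psi[u]) lsu = ls[v];
    else lsu = ls[v] + ls[w];
    double mx = 0.0;
    for (int y = 0; y < npts; y++) {
      double d;
      if (is_leaf[u]) {
        d = (y == sigma_pt[u]) ? 1.0 : 0.0;
      } else if (is_psi[u]) {
        d = (pt_kind[y] == 0) ? psi_rate * wt[y] * Rsum[v][y] : 0.0;
      } else if (pt_kind[y] == 0) {
        d = 2.0 * delta * wt[y] * Rsum[v][y] * Rsum[w][y];
      } else if (pt_kind[y] == 1 && y == sigma_pt[u]) {
        d = S0[v][y] * S1[w][y] + S0[w][y] * S1[v][y];
      } else {
        d = 0.0;
      }
      if (d <= 0.0) continue;
      if (return_tables) M[(size_t)y * npts + y] = d;
      if (d > mx) mx = d;
      double base = d, ty = pt_time[y];
      int z = y, x = pt_parent[z];
      while (x >= 0) {
        base *= (mode == 1) ? p11_p[z] : p11_g[z];
        double gl = glen(l_u, pt_time[x] - ty, shape, scale);
        if (pt_kind[x] == 1) {
          // side sums feed the speciation case, where the sibling side is
          // taken by the other child: no off-path extinction there.  The
          // factor applies only when the lineage continues past x.
          double val_side = base * gl;
          if (side[z] == 0) S0u[x] += val_side; else S1u[x] += val_side;
          if (val_side > mx) mx = val_side;
          int sib = sibling[z];
          base *= (mode == 1) ? eps_arc_p[sib] : eps_arc_g[sib];
        }
        double val = base * gl;
        if (return_tables) M[(size_t)x * npts + y] = val;
        Ru[x] += val;
        if (val > mx) mx = val;
        z = x; x = pt_parent[z];
      }
    }
    if (mx <= 0.0) { dead = true; break; }
    // rescale to guard against under/overflow across vertices
    for (int y = 0; y < npts; y++) {
      Ru[y] /= mx; S0u[y] /= mx; S1u[y] /= mx;
    }
    if (return_tables) {
      for (size_t k = 0; k < M.size(); k++) M[k] /= mx;
      NumericMatrix Mm(npts, npts);
      for (int x = 0; x < npts; x++)
        for (int y = 0; y < npts; y++) Mm(x, y) = M[(size_t)x * npts + y];
      tables[u] = Mm;
    }
    ls[u] = lsu + std::log(mx);
    Rsum[u] = Ru; S0[u] = S0u; S1[u] = S1u;
  }
  double logp;
  if (dead) {
    logp = R_NegInf;
  } else {
    double tot = Rsum[root_child][root_point];
    logp = (tot > 0) ? std::log(tot) + ls[root_child] : R_NegInf;
  }
  List out = List::create(_["log_prior"] = logp,
                          _["logscale"] = NumericVector(ls.begin(), ls.end()));
  if (return_tables) out["tables"] = tables;
  return out;
}

// ---- forward Monte-Carlo oracle for the two-type process ----------------

struct McCtx {
  const int *vkid1, *vkid2;      // species-tree children (-1 at leaves)
  const double *vtime;
  double delta, mu, psi;
  bool has_target;
  int target_edge;               // edge identified by its child vertex
  double t1;                     // target time on that edge
  std::vector<int> cross_type;
  std::vector<int> cross_surv;
};

// simulate one lineage entering edge above vertex cv at time t with the
// given type (0 gene, 1 pseudogene); returns 1 if any extant descendant
static int mc_sim(McCtx &C, int cv, double t, int type) {
  for (;;) {
    double rate = C.delta + C.mu + (type == 0 ? C.psi : 0.0);
    double tn = (rate > 0) ? t - R::exp_rand() / rate : -1e300;
    if (C.has_target && cv == C.target_edge && t > C.t1 && tn <= C.t1) {
      // reaches the registration point uneventfully; restart below it
      int surv = mc_sim(C, cv, C.t1, type);
      C.cross_type.push_back(type);
      C.cross_surv.push_back(surv);
      return surv;
    }
    double bottom = C.vtime[cv];
    if (tn <= bottom) {
      if (C.vkid1[cv] < 0) return 1;               // extant leaf
      int s1 = mc_sim(C, C.vkid1[cv], bottom, type);
      int s2 = mc_sim(C, C.vkid2[cv], bottom, type);
      return s1 || s2;
    }
    double e = R::unif_rand() * rate;
    if (e < C.delta) {                             // duplication
      int s1 = mc_sim(C, cv, tn, type);
      int s2 = mc_sim(C, cv, tn, type);
      return s1 || s2;
    } else if (e < C.delta + C.mu) {
      return 0;                                    // loss
    } else {
      type = 1; t = tn;                            // pseudogenization
    }
  }
}

// [[Rcpp::export]]
List mc_twotype_cpp(IntegerVector vkid1, IntegerVector vkid2,
                    NumericVector vtime, int start_edge, double start_time,
                    int start_type, double delta, double mu, double psi,
                    int n_reps, bool has_target, int target_edge,
                    double target_time, int target_type) {
  McCtx C;
  C.vkid1 = vkid1.begin(); C.vkid2 = vkid2.begin(); C.vtime = vtime.begin();
  C.delta = delta; C.mu = mu; C.psi = psi;
  C.has_target = has_target; C.target_edge = target_edge;
  C.t1 = target_time;
  IntegerVector extinct(n_reps);
  NumericVector oneone(n_reps);
  for (int r = 0; r < n_reps; r++) {
    C.cross_type.clear(); C.cross_surv.clear();
    int surv = mc_sim(C, start_edge, start_time, start_type);
    extinct[r] = surv ? 0 : 1;
    if (has_target) {
      int nsurv = 0, surv_idx = -1;
      for (size_t k = 0; k < C.cross_surv.size(); k++)
        if (C.cross_surv[k]) { nsurv++; surv_idx = (int)k; }
      double N = 0.0;
      if (nsurv == 0) {
        for (size_t k = 0; k < C.cross_type.size(); k++)
          if (C.cross_type[k] == target_type) N += 1.0;
      } else if (nsurv == 1 && C.cross_type[surv_idx] == target_type) {
        N = 1.0;
      }
      oneone[r] = N;
    }
  }
  return List::create(_["extinct"] = extinct, _["one_to_one"] = oneone);
}
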