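#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Felsenstein pruning log-likelihood under a reversible 4-state model.
//
// edge: 2-column integer matrix (parent, child), 1-based node ids, ordered
//   so that every child's own subtree is complete before its edge is used
//   (callers sort edges by parent node time, ascending).
// edge_len: branch lengths in expected substitutions per site.
// tip_pat: n_tips x n_pat integer matrix of base codes 0..3, -1 = missing.
// weights: pattern weights (site counts).
// U, Uinv, eval: eigendecomposition of the rate matrix, P(t) = U e^{Dt} Uinv.
// pi: equilibrium base frequencies. root: 1-based root node id.
// [[Rcpp::export]]
double prune_loglik_cpp(IntegerMatrix edge, NumericVector edge_len,
                        IntegerMatrix tip_pat, NumericVector weights,
                        NumericMatrix U, NumericMatrix Uinv,
                        NumericVector eval, NumericVector pi,
                        int n_nodes, int root) {
  const int n_tips = tip_pat.nrow();
  const int n_pat = tip_pat.ncol();
  const int n_edge = edge.nrow();
  if (n_pat == 0) return 0.0;

  // partials stored for internal nodes only; tip edges are folded into
  // their parent directly through a P-column lookup
  const int n_int = n_nodes - n_tips;
  std::vector<double> part((size_t)n_int * 4 * n_pat, 1.0);
  std::vector<double> logsc((size_t)n_int * n_pat, 0.0);

  double P[4][4];
  for (int e = 0; e < n_edge; ++e) {
    const int par = edge(e, 0) - 1 - n_tips, ch = edge(e, 1) - 1;
    const double t = edge_len[e];
    // P = U diag(exp(eval*t)) Uinv
    double ex[4];
    for (int s = 0; s < 4; ++s) ex[s] = std::exp(eval[s] * t);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        double acc = 0.0;
        for (int s = 0; s < 4; ++s) acc += U(i, s) * ex[s] * Uinv(s, j);
        P[i][j] = acc < 0.0 ? 0.0 : acc;
      }
    if (ch < n_tips) {
      for (int p = 0; p < n_pat; ++p) {
        const int code = tip_pat(ch, p);
        if (code < 0) continue;  // missing base: flat contribution
        double *pp = &part[((size_t)par * n_pat + p) * 4];
        for (int i = 0; i < 4; ++i) pp[i] *= P[i][code];
      }
      continue;
    }
    const int chi = ch - n_tips;
    for (int p = 0; p < n_pat; ++p) {
      const double *pc = &part[((size_t)chi * n_pat + p) * 4];
      double *pp = &part[((size_t)par * n_pat + p) * 4];
      double mx = 0.0;
      for (int i = 0; i < 4; ++i) {
        double acc = 0.0;
        for (int j = 0; j < 4; ++j) acc += P[i][j] * pc[j];
        pp[i] *= acc;
        if (pp[i] > mx) mx = pp[i];
      }
      double &ls = logsc[(size_t)par * n_pat + p];
      ls += logsc[(size_t)chi * n_pat + p];
      if (mx > 0.0 && mx < 1e-100) {  // rescale to avoid underflow
        for (int i = 0; i < 4; ++i) pp[i] /= mx;
        ls += std::log(mx);
      }
    }
  }

  double ll = 0.0;
  const int r = root - 1 - n_tips;
  for (int p = 0; p < n_pat; ++p) {
    const double *pr = &part[((size_t)r * n_pat + p) * 4];
    double acc = 0.0;
    for (int s = 0; s < 4; ++s) acc += pi[s] * pr[s];
    if (acc <= 0.0) return R_NegInf;
    ll += weights[p] * (std::log(acc) + logsc[(size_t)r * n_pat + p]);
  }
  return ll;
}

// Log-density of a structured-coalescent history.
//
// Events sorted by time (mutational units, increasing into the past).
// ev_type: 1 = coalescence (in deme ev_d1), 2 = migration (lineage moves
// backward from deme ev_d1 to deme ev_d2); demes 1-based. k0: lineage
// counts per deme at time 0. theta: per-deme Theta. M: K x K backward
// migration rate matrix (mutational scale). Interval rates are
// sum_i k_i (k_i - 1) / theta_i + sum_i k_i sum_j M[i, j]; each
// coalescence contributes 2/theta_i, each migration M[i, j].
// [[Rcpp::export]]
double struct_coal_loglik_cpp(NumericVector ev_time, IntegerVector ev_type,
                              IntegerVector ev_d1, IntegerVector ev_d2,
                              IntegerVector k0, NumericVector theta,
                              NumericMatrix M) {
  const int K = k0.size();
  const int n_ev = ev_time.size();
  std::vector<double> k(K), mout(K);
  for (int i = 0; i < K; ++i) {
    k[i] = k0[i];
    double acc = 0.0;
    for (int j = 0; j < K; ++j) acc += M(i, j);
    mout[i] = acc;
  }
  double t = 0.0, ll = 0.0;
  for (int e = 0; e < n_ev; ++e) {
    const double dt = ev_time[e] - t;
    if (dt < 0) return R_NegInf;
    double rate = 0.0;
    for (int i = 0; i < K; ++i)
      rate += k[i] * (k[i] - 1.0) / theta[i] + k[i] * mout[i];
    ll -= rate * dt;
    t = ev_time[e];
    const int d1 = ev_d1[e] - 1;
    if (ev_type[e] == 1) {
      if (k[d1] < 2.0) return R_NegInf;
      ll += std::log(2.0 / theta[d1]);
      k[d1] -= 1.0;
    } else {
      const int d2 = ev_d2[e] - 1;
      if (k[d1] < 1.0) return R_NegInf;
      const double r = M(d1, d2);
      if (r <= 0.0) return R_NegInf;
      ll += std::log(r);
      k[d1] -= 1.0;
      k[d2] += 1.0;
    }
  }
  return ll;
}

// Structured-coalescent genealogy simulation on a 1-D lattice with an
// instantaneous size change at t_expansion (backward time, generations).
// Returns time, parent (0 = root) and deme for the 2n-1 nodes; tips are
// nodes 1..n in deme-block order. Uses R's RNG for reproducibility.
// [[Rcpp::export]]
List sim_genealogy_cpp(int D, int per_deme, double N_recent,
                       double N_ancient, double t_expansion, double m) {
  const int n_tips = D * per_deme;
  const int n_nodes = 2 * n_tips - 1;
  NumericVector time(n_nodes);
  IntegerVector parent(n_nodes);
  IntegerVector deme(n_nodes);
  std::vector<std::vector<int> > by_deme(D);  // active lineages per deme
  for (int d = 0; d < D; ++d) {
    by_deme[d].reserve(n_tips);
    for (int i = 0; i < per_deme; ++i) {
      int id = d * per_deme + i;
      by_deme[d].push_back(id);
      deme[id] = d + 1;
    }
  }
  int n_active = n_tips, nxt = n_tips;
  double t = 0.0;
  std::vector<double> coal(D), mig(D);
  while (n_active > 1) {
    const double N_now = (t < t_expansion) ? N_recent : N_ancient;
    double R = 0.0;
    for (int d = 0; d < D; ++d) {
      const double k = (double)by_deme[d].size();
      const int nb = (D == 1) ? 0 : ((d == 0 || d == D - 1) ? 1 : 2);
      coal[d] = k * (k - 1.0) / 2.0 / N_now;
      mig[d] = k * nb * m;
      R += coal[d] + mig[d];
    }
    if (R <= 0.0) stop("no events possible: isolated lineages with m = 0");
    const double dt = R::exp_rand() / R;
    if (t < t_expansion && t + dt >= t_expansion) {
      t = t_expansion;
      continue;
    }
    t += dt;
    double u = unif_rand() * R;
    int d = 0;
    bool is_coal = true;
    for (d = 0; d < D; ++d) {
      if (u < coal[d]) { is_coal = true; break; }
      u -= coal[d];
      if (u < mig[d]) { is_coal = false; break; }
      u -= mig[d];
    }
    if (d >= D) d = D - 1;  // numerical edge: force last deme
    std::vector<int> &pool = by_deme[d];
    if (is_coal && pool.size() >= 2) {
      int i1 = (int)(unif_rand() * pool.size());
      int a = pool[i1];
      pool[i1] = pool.back(); pool.pop_back();
      int i2 = (int)(unif_rand() * pool.size());
      int b = pool[i2];
      pool[i2] = pool.back(); pool.pop_back();
      time[nxt] = t;
      deme[nxt] = d + 1;
      parent[a] = nxt + 1;
      parent[b] = nxt + 1;
      pool.push_back(nxt);
      ++nxt;
      --n_active;
    } else if (!is_coal && !pool.empty()) {
      int i1 = (int)(unif_rand() * pool.size());
      int id = pool[i1];
      pool[i1] = pool.back(); pool.pop_back();
      int to = (d == 0) ? 1 : (d == D - 1 ? D - 2 :
                               (unif_rand() < 0.5 ? d - 1 : d + 1));
      by_deme[to].push_back(id);
    }
  }
  return List::create(_["time"] = time, _["parent"] = parent,
                      _["deme"] = deme);
}

// Structured-coalescent log-density computed directly from a genealogy
// state: assembles coalescence times and per-branch migration events,
// sorts them, and runs the interval sweep of struct_coal_loglik_cpp.
// events: list of 3-column matrices (time, from, to), one per node.
// [[Rcpp::export]]
double state_coal_loglik_cpp(NumericVector time, IntegerVector node_deme,
                             List events, int n_tips, IntegerVector k0,
                             NumericVector theta, NumericMatrix M) {
  const int n_nodes = time.size();
  struct Ev { double t; int type, d1, d2; };
  std::vector<Ev> ev;
  ev.reserve(2 * n_nodes);
  for (int v = n_tips; v < n_nodes; ++v)
    ev.push_back(Ev{time[v], 1, node_deme[v], 0});
  for (int v = 0; v < n_nodes; ++v) {
    SEXP em = events[v];          // 3-column numeric matrix (time, from, to)
    const int nr = Rf_nrows(em);
    if (nr == 0) continue;
    const double *pe = REAL(em);
    for (int r = 0; r < nr; ++r)
      ev.push_back(Ev{pe[r], 2, (int)pe[r + nr], (int)pe[r + 2 * nr]});
  }
  std::sort(ev.begin(), ev.end(),
            [](const Ev &a, const Ev &b) { return a.t < b.t; });

  const int K = k0.size();
  std::vector<double> k(K), mout(K);
  for (int i = 0; i < K; ++i) {
    k[i] = k0[i];
    double acc = 0.0;
    for (int j = 0; j < K; ++j) acc += M(i, j);
    mout[i] = acc;
  }
  double t = 0.0, ll = 0.0;
  for (size_t e = 0; e < ev.size(); ++e) {
    const double dt = ev[e].t - t;
    if (dt < 0) return R_NegInf;
    double rate = 0.0;
    for (int i = 0; i < K; ++i)
      rate += k[i] * (k[i] - 1.0) / theta[i] + k[i] * mout[i];
    ll -= rate * dt;
    t = ev[e].t;
    const int d1 = ev[e].d1 - 1;
    if (ev[e].type == 1) {
      if (k[d1] < 2.0) return R_NegInf;
      ll += std::log(2.0 / theta[d1]);
      k[d1] -= 1.0;
    } else {
      const int d2 = ev[e].d2 - 1;
      if (k[d1] < 1.0) return R_NegInf;
      const double r = M(d1, d2);
      if (r <= 0.0) return R_NegInf;
      ll += std::log(r);
      k[d1] -= 1.0;
      k[d2] += 1.0;
    }
  }
  return ll;
}
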