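// Bond-switching Monte Carlo engine for 2D planar networks.
//
// State lives in C++ behind an external pointer so that schedule drivers can
// run many thousands of attempted switches without crossing the R boundary.
// Node indices are 0-based internally, 1-based at the R interface.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static const double TWOPI = 6.283185307179586476925286766559;

struct CellGeom {
  double W, H, shear;  // shear: x-offset applied on a vertical wrap
  bool periodic;
};

struct Potential {
  double kr, Kth, req;
  bool fixed_theta;
  double theta_fixed;
};

struct Engine {
  CellGeom cell;
  int V, E;
  std::vector<double> px, py;
  std::vector< std::vector<int> > adj;
  std::vector< std::vector<int> > rings;
  std::vector< std::vector<int> > nodeRings;
  Potential pot;
  int kmin, kmax, nmax;
  int radius, max_iter;
  double ftol;
  double Ecur;
  // counters
  long long n_att, n_acc, rej_k, rej_n, rej_topo, rej_metro;
  // scratch
  std::vector<char> mark;
};

// ---------------------------------------------------------------------------
// geometry

static inline void disp(const Engine& e, int i, int j, double& dx, double& dy) {
  dx = e.px[j] - e.px[i];
  dy = e.py[j] - e.py[i];
  if (e.cell.periodic) {
    double m = std::nearbyint(dy / e.cell.H);
    dy -= m * e.cell.H;
    dx -= m * e.cell.shear;
    dx -= std::nearbyint(dx / e.cell.W) * e.cell.W;
  }
}

static inline void wrap_xy(const Engine& e, double& x, double& y) {
  if (!e.cell.periodic) return;
  while (y < 0)         { y += e.cell.H; x += e.cell.shear; }
  while (y >= e.cell.H) { y -= e.cell.H; x -= e.cell.shear; }
  x -= std::floor(x / e.cell.W) * e.cell.W;
}

static inline double theta_eqm_of(const Potential& p, int k) {
  return p.fixed_theta ? p.theta_fixed : TWOPI / (double)k;
}

// ---------------------------------------------------------------------------
// energy and gradient over explicit term sets

struct TermSet {
  std::vector< std::pair<int,int> > bonds;
  std::vector<int> centers;
};

static void full_terms(const Engine& e, TermSet& t) {
  t.bonds.clear(); t.centers.clear();
  for (int i = 0; i < e.V; ++i) {
    for (size_t q = 0; q < e.adj[i].size(); ++q)
      if (i < e.adj[i][q]) t.bonds.push_back(std::make_pair(i, e.adj[i][q]));
    t.centers.push_back(i);
  }
}

// angular gaps around node c; neighbours sorted by angle (ties by node id)
static inline double angle_energy_at(const Engine& e, int c) {
  int k = (int)e.adj[c].size();
  if (e.pot.Kth == 0.0) return 0.0;  // angle terms disabled
  if (k < 2) stop("angle term at a node of degree < 2 (node %d)", c + 1);
  std::pair<double,int> ang[16];
  if (k > 16) stop("degree exceeds engine limit");
  for (int q = 0; q < k; ++q) {
    double dx, dy; disp(e, c, e.adj[c][q], dx, dy);
    ang[q] = std::make_pair(std::atan2(dy, dx), e.adj[c][q]);
  }
  std::sort(ang, ang + k);
  double th0 = theta_eqm_of(e.pot, k), acc = 0.0;
  for (int q = 0; q < k; ++q) {
    double a1 = ang[q].first;
    double a2 = ang[(q + 1) % k].first;
    double th = a2 - a1;
    if (q == k - 1) th += TWOPI;
    double d = th - th0;
    acc += 0.5 * e.pot.Kth * d * d;
  }
  return acc;
}

static double energy_terms(const Engine& e, const TermSet& t) {
  double acc = 0.0;
  for (size_t b = 0; b < t.bonds.size(); ++b) {
    double dx, dy; disp(e, t.bonds[b].first, t.bonds[b].second, dx, dy);
    double r = std::sqrt(dx * dx + dy * dy) - e.pot.req;
    acc += 0.5 * e.pot.kr * r * r;
  }
  for (size_t q = 0; q < t.centers.size(); ++q)
    acc += angle_energy_at(e, t.centers[q]);
  return acc;
}

static double energy_full(const Engine& e) {
  TermSet t; full_terms(const_cast<Engine&>(e), t);
  return energy_terms(e, t);
}

// gradient accumulated into gx, gy (full-length vectors)
static void grad_terms(const Engine& e, const TermSet& t,
                       std::vector<double>& gx, std::vector<double>& gy) {
  for (size_t b = 0; b < t.bonds.size(); ++b) {
    int i = t.bonds[b].first, j = t.bonds[b].second;
    double dx, dy; disp(e, i, j, dx, dy);
    double r = std::sqrt(dx * dx + dy * dy);
    if (r < 1e-12) continue;
    double f = e.pot.kr * (r - e.pot.req) / r;
    gx[i] -= f * dx; gy[i] -= f * dy;
    gx[j] += f * dx; gy[j] += f * dy;
  }
  for (size_t q = 0; q < t.centers.size(); ++q) {
    if (e.pot.Kth == 0.0) break;  // angle terms disabled
    int c = t.centers[q];
    int k = (int)e.adj[c].size();
    if (k < 2) stop("angle term at a node of degree < 2");
    std::pair<double,int> ang[16];
    double ux[16], uy[16], r2[16];
    for (int w = 0; w < k; ++w) {
      double dx, dy; disp(e, c, e.adj[c][w], dx, dy);
      ang[w] = std::make_pair(std::atan2(dy, dx), w);
      ux[w] = dx; uy[w] = dy; r2[w] = dx * dx + dy * dy;
    }
    std::sort(ang, ang + k);
    double th0 = theta_eqm_of(e.pot, k);
    for (int w = 0; w < k; ++w) {
      int ia = ang[w].second, ib = ang[(w + 1) % k].second;
      double th = ang[(w + 1) % k].first - ang[w].first;
      if (w == k - 1) th += TWOPI;
      double f = e.pot.Kth * (th - th0);
      // d theta / d pos_a = ( uy_a, -ux_a) / |u_a|^2  (a = first neighbour)
      // d theta / d pos_b = (-uy_b,  ux_b) / |u_b|^2
      double dax =  uy[ia] / r2[ia], day = -ux[ia] / r2[ia];
      double dbx = -uy[ib] / r2[ib], dby =  ux[ib] / r2[ib];
      int na = e.adj[c][ia], nb = e.adj[c][ib];
      gx[na] += f * dax; gy[na] += f * day;
      gx[nb] += f * dbx; gy[nb] += f * dby;
      gx[c]  -= f * (dax + dbx); gy[c] -= f * (day + dby);
    }
  }
}

// ---------------------------------------------------------------------------
// local relaxation: damped gradient descent with backtracking line search

static int relax_mobile(Engine& e, const std::vector<int>& mobile) {
  if (mobile.empty()) return 0;
  std::vector<char> is_mob(e.V, 0);
  for (size_t i = 0; i < mobile.size(); ++i) is_mob[mobile[i]] = 1;

  TermSet t;
  std::vector<char> cen(e.V, 0);
  for (size_t i = 0; i < mobile.size(); ++i) {
    int m = mobile[i];
    if (!cen[m]) { cen[m] = 1; t.centers.push_back(m); }
    for (size_t q = 0; q < e.adj[m].size(); ++q) {
      int nb = e.adj[m][q];
      if (!is_mob[nb] || m < nb) t.bonds.push_back(std::make_pair(m, nb));
      if (!cen[nb]) { cen[nb] = 1; t.centers.push_back(nb); }
    }
  }

  // Polak-Ribiere nonlinear conjugate gradient with Armijo backtracking;
  // energy is piecewise smooth (angular-order swaps), so restart to steepest
  // descent whenever the CG direction stops being a descent direction.
  int nm = (int)mobile.size();
  std::vector<double> gx(e.V, 0.0), gy(e.V, 0.0);
  std::vector<double> mgx(nm), mgy(nm), ogx(nm), ogy(nm), dx(nm), dy(nm),
                      sx(nm), sy(nm);
  double Eloc = energy_terms(e, t);
  grad_terms(e, t, gx, gy);
  double gn2 = 0.0;
  for (int i = 0; i < nm; ++i) {
    mgx[i] = gx[mobile[i]]; mgy[i] = gy[mobile[i]];
    gn2 += mgx[i] * mgx[i] + mgy[i] * mgy[i];
  }
  for (int i = 0; i < nm; ++i) { dx[i] = -mgx[i]; dy[i] = -mgy[i]; }
  double slope = -gn2;
  double step = 0.1;
  int it = 0;
  for (; it < e.max_iter; ++it) {
    if (std::sqrt(gn2) <= e.ftol) break;
    if (slope >= 0) {  // restart
      for (int i = 0; i < nm; ++i) { dx[i] = -mgx[i]; dy[i] = -mgy[i]; }
      slope = -gn2;
    }
    for (int i = 0; i < nm; ++i) { sx[i] = e.px[mobile[i]]; sy[i] = e.py[mobile[i]]; }
    bool moved = false;
    while (step > 1e-14) {
      for (int i = 0; i < nm; ++i) {
        int m = mobile[i];
        double x = sx[i] + step * dx[i], y = sy[i] + step * dy[i];
        wrap_xy(e, x, y);
        e.px[m] = x; e.py[m] = y;
      }
      double Et = energy_terms(e, t);
      if (Et <= Eloc + 1e-4 * step * slope) {
        Eloc = Et; moved = true;
        step = std::min(step * 2.0, 4.0);
        break;
      }
      for (int i = 0; i < nm; ++i) { e.px[mobile[i]] = sx[i]; e.py[mobile[i]] = sy[i]; }
      step *= 0.5;
    }
    if (!moved) break;
    std::fill(gx.begin(), gx.end(), 0.0);
    std::fill(gy.begin(), gy.end(), 0.0);
    grad_terms(e, t, gx, gy);
    double gn2_new = 0.0, gdot = 0.0;
    for (int i = 0; i < nm; ++i) {
      ogx[i] = mgx[i]; ogy[i] = mgy[i];
      mgx[i] = gx[mobile[i]]; mgy[i] = gy[mobile[i]];
      gn2_new += mgx[i] * mgx[i] + mgy[i] * mgy[i];
      gdot += mgx[i] * (mgx[i] - ogx[i]) + mgy[i] * (mgy[i] - ogy[i]);
    }
    double beta = gn2 > 0 ? std::max(0.0, gdot / gn2) : 0.0;
    slope = 0.0;
    for (int i = 0; i < nm; ++i) {
      dx[i] = -mgx[i] + beta * dx[i];
      dy[i] = -mgy[i] + beta * dy[i];
      slope += dx[i] * mgx[i] + dy[i] * mgy[i];
    }
    gn2 = gn2_new;
  }
  return it;
}

static std::vector<int> bfs_ball(const Engine& e, const std::vector<int>& centers, int radius) {
  std::vector<int> dist(e.V, -1), out;
  std::vector<int> queue;
  for (size_t i = 0; i < centers.size(); ++i)
    if (dist[centers[i]] < 0) { dist[centers[i]] = 0; queue.push_back(centers[i]); }
  for (size_t h = 0; h < queue.size(); ++h) {
    int u = queue[h];
    out.push_back(u);
    if (dist[u] == radius) continue;
    for (size_t q = 0; q < e.adj[u].size(); ++q) {
      int w = e.adj[u][q];
      if (dist[w] < 0) { dist[w] = dist[u] + 1; queue.push_back(w); }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// ring bookkeeping

// rotate ring so out[0] == A and out[1] == B (either orientation)
static bool rot_pair(const std::vector<int>& ring, int A, int B, std::vector<int>& out) {
  int n = (int)ring.size();
  for (int i = 0; i < n; ++i) {
    if (ring[i] == A && ring[(i + 1) % n] == B) {
      out.resize(n);
      for (int j = 0; j < n; ++j) out[j] = ring[(i + j) % n];
      return true;
    }
    if (ring[i] == A && ring[(i - 1 + n) % n] == B) {
      out.resize(n);
      for (int j = 0; j < n; ++j) out[j] = ring[(i - j + n) % n];
      return true;
    }
  }
  return false;
}

// rings bordering edge a-b (consecutive occurrence); returns number found (<= 2)
static int edge_rings(const Engine& e, int a, int b, int& r1, int& r2) {
  int found = 0;
  const std::vector<int>& cand = e.nodeRings[a];
  for (size_t q = 0; q < cand.size(); ++q) {
    const std::vector<int>& rg = e.rings[cand[q]];
    int n = (int)rg.size();
    for (int i = 0; i < n; ++i) {
      if (rg[i] == a && (rg[(i + 1) % n] == b || rg[(i - 1 + n) % n] == b)) {
        if (found == 0) r1 = cand[q];
        else if ((int)cand[q] != r1) r2 = cand[q];
        else break;           // same ring twice: degenerate
        ++found;
        break;
      }
    }
    if (found == 2) break;
  }
  return found;
}

static void nr_remove(std::vector<int>& v, int rid) {
  for (size_t i = 0; i < v.size(); ++i)
    if (v[i] == rid) { v[i] = v.back(); v.pop_back(); return; }
}

static void adj_remove(std::vector<int>& v, int node) {
  for (size_t i = 0; i < v.size(); ++i)
    if (v[i] == node) { v[i] = v.back(); v.pop_back(); return; }
}

static bool has_neigh(const std::vector<int>& v, int node) {
  return std::find(v.begin(), v.end(), node) != v.end();
}

// ---------------------------------------------------------------------------
// proposal

struct Proposal {
  int reason;           // 0 ok, 1 constraint_k, 2 constraint_n, 3 topology
  int A, B, C;
  int r1, r2;
  std::vector<int> M;   // merged ring, M[0] = B, M[idxA] = A
  int idxA, idxC;
};

// reason codes: 0 none, 1 constraint_k, 2 constraint_n, 3 topology, 4 metropolis
static void propose(Engine& e, Proposal& p) {
  p.reason = 3;
  if (e.E == 0) stop("network has no edges");
  // uniform directed edge
  long r = (long)std::floor(unif_rand() * (2.0 * e.E));
  if (r >= 2L * e.E) r = 2L * e.E - 1;
  int A = -1, B = -1;
  long cum = 0;
  for (int i = 0; i < e.V; ++i) {
    long k = (long)e.adj[i].size();
    if (r < cum + k) { A = i; B = e.adj[i][(int)(r - cum)]; break; }
    cum += k;
  }
  p.A = A; p.B = B;

  if ((int)e.adj[B].size() - 1 < e.kmin) { p.reason = 1; return; }

  int r1 = -1, r2 = -1;
  if (edge_rings(e, A, B, r1, r2) != 2) { p.reason = 3; return; }
  p.r1 = r1; p.r2 = r2;

  std::vector<int> R1p, R2p;
  if (!rot_pair(e.rings[r1], A, B, R1p) || !rot_pair(e.rings[r2], B, A, R2p)) {
    p.reason = 3; return;
  }
  int n1 = (int)R1p.size(), n2 = (int)R2p.size();
  // merged cycle: B, x2..x_{n1-1}, A, y2..y_{n2-1}
  std::vector<int>& M = p.M;
  M.clear(); M.reserve(n1 + n2 - 2);
  for (int j = 1; j < n1; ++j) M.push_back(R1p[j]);   // B .. x_{n1-1}
  M.push_back(A);
  for (int j = 2; j < n2; ++j) M.push_back(R2p[j]);
  // simplicity of merged cycle
  for (size_t i = 0; i < M.size(); ++i) e.mark[M[i]]++;
  bool dup = false;
  for (size_t i = 0; i < M.size(); ++i) { if (e.mark[M[i]] > 1) dup = true; e.mark[M[i]] = 0; }
  if (dup) { p.reason = 3; return; }
  p.idxA = n1 - 1;

  int nM = (int)M.size();
  // only the post-split rings are screened against n_max: the merged ring is
  // a transient construction, not a configuration
  bool any_onM = false, any_k_ok = false;
  std::vector<int> valid;
  for (size_t q = 0; q < e.adj[B].size(); ++q) {
    int w = e.adj[B][q];
    if (w == A) continue;
    if (has_neigh(e.adj[A], w)) continue;
    int idx = -1;
    for (int i = 0; i < nM; ++i) if (M[i] == w) { idx = i; break; }
    if (idx < 0) continue;
    any_onM = true;
    if ((int)e.adj[w].size() + 1 > e.kmax) continue;
    any_k_ok = true;
    int d = (idx - p.idxA + nM) % nM;
    int s1 = d + 1, s2 = nM - d + 1;
    if (s1 < 3 || s2 < 3 || s1 > e.nmax || s2 > e.nmax) continue;
    valid.push_back(idx);
  }
  if (valid.empty()) {
    p.reason = !any_onM ? 3 : (!any_k_ok ? 1 : 2);
    return;
  }
  int pick = (int)std::floor(unif_rand() * valid.size());
  if (pick >= (int)valid.size()) pick = (int)valid.size() - 1;
  p.idxC = valid[pick];
  p.C = M[p.idxC];
  p.reason = 0;
}

// ---------------------------------------------------------------------------
// apply / revert

struct Snapshot {
  std::vector<int> oldR1, oldR2, S1, S2;
  int A, B, C, r1, r2;
  std::vector<int> mobile;
  std::vector<double> mx, my;
};

static void apply_proposal(Engine& e, const Proposal& p, Snapshot& s) {
  s.A = p.A; s.B = p.B; s.C = p.C; s.r1 = p.r1; s.r2 = p.r2;
  s.oldR1 = e.rings[p.r1]; s.oldR2 = e.rings[p.r2];
  // adjacency
  adj_remove(e.adj[p.A], p.B);
  adj_remove(e.adj[p.B], p.A);
  e.adj[p.A].push_back(p.C);
  e.adj[p.C].push_back(p.A);
  // split rings
  int nM = (int)p.M.size();
  int d = (p.idxC - p.idxA + nM) % nM;
  s.S1.clear(); s.S2.clear();
  for (int j = 0; j <= d; ++j) s.S1.push_back(p.M[(p.idxA + j) % nM]);
  for (int j = 0; j <= nM - d; ++j) s.S2.push_back(p.M[(p.idxC + j) % nM]);
  // node-ring incidence
  for (size_t i = 0; i < s.oldR1.size(); ++i) nr_remove(e.nodeRings[s.oldR1[i]], p.r1);
  for (size_t i = 0; i < s.oldR2.size(); ++i) nr_remove(e.nodeRings[s.oldR2[i]], p.r2);
  e.rings[p.r1] = s.S1;
  e.rings[p.r2] = s.S2;
  for (size_t i = 0; i < s.S1.size(); ++i) e.nodeRings[s.S1[i]].push_back(p.r1);
  for (size_t i = 0; i < s.S2.size(); ++i) e.nodeRings[s.S2[i]].push_back(p.r2);
}

static void revert(Engine& e, const Snapshot& s) {
  adj_remove(e.adj[s.A], s.C);
  adj_remove(e.adj[s.C], s.A);
  e.adj[s.A].push_back(s.B);
  e.adj[s.B].push_back(s.A);
  for (size_t i = 0; i < s.S1.size(); ++i) nr_remove(e.nodeRings[s.S1[i]], s.r1);
  for (size_t i = 0; i < s.S2.size(); ++i) nr_remove(e.nodeRings[s.S2[i]], s.r2);
  e.rings[s.r1] = s.oldR1;
  e.rings[s.r2] = s.oldR2;
  for (size_t i = 0; i < s.oldR1.size(); ++i) e.nodeRings[s.oldR1[i]].push_back(s.r1);
  for (size_t i = 0; i < s.oldR2.size(); ++i) e.nodeRings[s.oldR2[i]].push_back(s.r2);
  for (size_t i = 0; i < s.mobile.size(); ++i) {
    e.px[s.mobile[i]] = s.mx[i];
    e.py[s.mobile[i]] = s.my[i];
  }
}

static void check_state(const Engine& e) {
  long sumn = 0;
  for (size_t r = 0; r < e.rings.size(); ++r) {
    int n = (int)e.rings[r].size();
    if (n < 3 || n > e.nmax) stop("ring size %d outside [3, n_max]", n);
    sumn += n;
    for (int i = 0; i < n; ++i)
      if (!has_neigh(e.adj[e.rings[r][i]], e.rings[r][(i + 1) % n]))
        stop("ring traversal inconsistent with adjacency");
  }
  long sumk = 0;
  for (int i = 0; i < e.V; ++i) {
    int k = (int)e.adj[i].size();
    if (k < e.kmin || k > e.kmax) stop("degree %d outside [k_min, k_max]", k);
    sumk += k;
  }
  if (sumk != 2L * e.E) stop("edge count changed");
  if (sumn != 2L * e.E) stop("sum of ring sizes != 2E");
  if (e.V - e.E + (long)e.rings.size() != 0) stop("torus Euler relation violated");
}

// result: accepted, reason, dE
static void mc_step_internal(Engine& e, double T, bool check,
                             int& accepted, int& reason, double& dE) {
  if (T <= 0) stop("temperature must be positive");
  e.n_att++;
  accepted = 0; dE = NA_REAL;
  Proposal p;
  propose(e, p);
  if (p.reason != 0) {
    reason = p.reason;
    if (p.reason == 1) e.rej_k++;
    else if (p.reason == 2) e.rej_n++;
    else e.rej_topo++;
    return;
  }
  Snapshot s;
  apply_proposal(e, p, s);
  std::vector<int> centers;
  centers.push_back(p.A); centers.push_back(p.B); centers.push_back(p.C);
  s.mobile = bfs_ball(e, centers, e.radius);
  s.mx.resize(s.mobile.size()); s.my.resize(s.mobile.size());
  for (size_t i = 0; i < s.mobile.size(); ++i) {
    s.mx[i] = e.px[s.mobile[i]];
    s.my[i] = e.py[s.mobile[i]];
  }
  relax_mobile(e, s.mobile);
  double Enew = energy_full(e);
  dE = Enew - e.Ecur;
  bool acc = (dE <= 0) || (unif_rand() < std::exp(-dE / T));
  if (acc) {
    e.Ecur = Enew;
    e.n_acc++;
    accepted = 1; reason = 0;
    if (check) check_state(e);
  } else {
    revert(e, s);
    e.rej_metro++;
    reason = 4;
  }
}

// ---------------------------------------------------------------------------
// R interface

static Engine* get(SEXP xp) {
  XPtr<Engine> p(xp);
  return p.get();
}

// [[Rcpp::export]]
SEXP eng_create(NumericMatrix pos, List adj, List rings,
                double width, double height, double shear, bool periodic,
                List params, List constraints, List relax) {
  Engine* e = new Engine();
  e->cell.W = width; e->cell.H = height; e->cell.shear = shear;
  e->cell.periodic = periodic;
  e->V = pos.nrow();
  e->px.resize(e->V); e->py.resize(e->V);
  for (int i = 0; i < e->V; ++i) { e->px[i] = pos(i, 0); e->py[i] = pos(i, 1); }
  e->adj.resize(e->V);
  long sumk = 0;
  for (int i = 0; i < e->V; ++i) {
    IntegerVector nb = adj[i];
    for (int q = 0; q < nb.size(); ++q) e->adj[i].push_back(nb[q] - 1);
    sumk += nb.size();
  }
  e->E = (int)(sumk / 2);
  e->rings.resize(rings.size());
  e->nodeRings.resize(e->V);
  for (int r = 0; r < rings.size(); ++r) {
    IntegerVector rg = rings[r];
    for (int i = 0; i < rg.size(); ++i) {
      e->rings[r].push_back(rg[i] - 1);
      e->nodeRings[rg[i] - 1].push_back(r);
    }
  }
  e->pot.kr  = as<double>(params["k_r"]);
  e->pot.Kth = as<double>(params["K_theta"]);
  e->pot.req = as<double>(params["r_eqm"]);
  e->pot.fixed_theta = as<bool>(params["fixed_theta"]);
  e->pot.theta_fixed = as<double>(params["theta_fixed"]);
  e->kmin = as<int>(constraints["k_min"]);
  e->kmax = as<int>(constraints["k_max"]);
  e->nmax = as<int>(constraints["n_max"]);
  e->radius   = as<int>(relax["radius"]);
  e->ftol     = as<double>(relax["force_tol"]);
  e->max_iter = as<int>(relax["max_iter"]);
  e->n_att = e->n_acc = e->rej_k = e->rej_n = e->rej_topo = e->rej_metro = 0;
  e->mark.assign(e->V, 0);
  e->Ecur = energy_full(*e);
  XPtr<Engine> xp(e, true);
  return xp;
}

// [[Rcpp::export]]
NumericMatrix eng_positions(SEXP xp) {
  Engine* e = get(xp);
  NumericMatrix out(e->V, 2);
  for (int i = 0; i < e->V; ++i) { out(i, 0) = e->px[i]; out(i, 1) = e->py[i]; }
  return out;
}

// [[Rcpp::export]]
List eng_adjacency(SEXP xp) {
  Engine* e = get(xp);
  List out(e->V);
  for (int i = 0; i < e->V; ++i) {
    IntegerVector nb(e->adj[i].size());
    for (size_t q = 0; q < e->adj[i].size(); ++q) nb[q] = e->adj[i][q] + 1;
    std::sort(nb.begin(), nb.end());
    out[i] = nb;
  }
  return out;
}

// [[Rcpp::export]]
List eng_rings(SEXP xp) {
  Engine* e = get(xp);
  List out(e->rings.size());
  for (size_t r = 0; r < e->rings.size(); ++r) {
    IntegerVector rg(e->rings[r].size());
    for (size_t i = 0; i < e->rings[r].size(); ++i) rg[i] = e->rings[r][i] + 1;
    out[r] = rg;
  }
  return out;
}

// [[Rcpp::export]]
double eng_energy(SEXP xp) { return get(xp)->Ecur; }

// [[Rcpp::export]]
List eng_counters(SEXP xp) {
  Engine* e = get(xp);
  return List::create(
    _["attempts"] = (double)e->n_att,
    _["accepted"] = (double)e->n_acc,
    _["rejected_constraint_k"] = (double)e->rej_k,
    _["rejected_constraint_n"] = (double)e->rej_n,
    _["rejected_topology"] = (double)e->rej_topo,
    _["rejected_metropolis"] = (double)e->rej_metro);
}

// [[Rcpp::export]]
List eng_step(SEXP xp, double T, bool check = false) {
  Engine* e = get(xp);
  int acc, reason; double dE;
  mc_step_internal(*e, T, check, acc, reason, dE);
  return List::create(_["accepted"] = (acc == 1), _["reason"] = reason,
                      _["delta_E"] = dE, _["energy"] = e->Ecur);
}

// [[Rcpp::export]]
DataFrame eng_run(SEXP xp, NumericVector Ts, int max_accepts = -1, bool check = false) {
  Engine* e = get(xp);
  int n = Ts.size();
  std::vector<double> lT, lE, lmu2, ldE;
  std::vector<int> lacc, lreason;
  lT.reserve(n);
  int done = 0;
  for (int i = 0; i < n; ++i) {
    int acc, reason; double dE;
    mc_step_internal(*e, Ts[i], check, acc, reason, dE);
    double sumk = 0, sumk2 = 0;
    for (int v = 0; v < e->V; ++v) {
      double k = (double)e->adj[v].size();
      sumk += k; sumk2 += k * k;
    }
    double mk = sumk / e->V;
    lT.push_back(Ts[i]); lacc.push_back(acc); lreason.push_back(reason);
    lE.push_back(e->Ecur); ldE.push_back(dE);
    lmu2.push_back(sumk2 / e->V - mk * mk);
    ++done;
    if (max_accepts > 0 && acc) {
      if (--max_accepts == 0) break;
    }
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  IntegerVector step(done);
  for (int i = 0; i < done; ++i) step[i] = i + 1;
  NumericVector meank(done);
  for (int i = 0; i < done; ++i) meank[i] = 2.0 * e->E / e->V;
  return DataFrame::create(
    _["step"] = step,
    _["T"] = NumericVector(lT.begin(), lT.end()),
    _["accepted"] = IntegerVector(lacc.begin(), lacc.end()),
    _["reason"] = IntegerVector(lreason.begin(), lreason.end()),
    _["delta_E"] = NumericVector(ldE.begin(), ldE.end()),
    _["energy"] = NumericVector(lE.begin(), lE.end()),
    _["mean_k"] = meank,
    _["mu2_k"] = NumericVector(lmu2.begin(), lmu2.end()));
}

// [[Rcpp::export]]
void eng_validate(SEXP xp) { check_state(*get(xp)); }

// ---------------------------------------------------------------------------
// standalone evaluators used by the R-level potential interface

static Engine make_static(NumericMatrix pos, List adj,
                          double width, double height, double shear, bool periodic,
                          List params) {
  Engine e;
  e.cell.W = width; e.cell.H = height; e.cell.shear = shear; e.cell.periodic = periodic;
  e.V = pos.nrow();
  e.px.resize(e.V); e.py.resize(e.V);
  for (int i = 0; i < e.V; ++i) { e.px[i] = pos(i, 0); e.py[i] = pos(i, 1); }
  e.adj.resize(e.V);
  long sumk = 0;
  for (int i = 0; i < e.V; ++i) {
    IntegerVector nb = adj[i];
    for (int q = 0; q < nb.size(); ++q) e.adj[i].push_back(nb[q] - 1);
    sumk += nb.size();
  }
  e.E = (int)(sumk / 2);
  e.pot.kr  = as<double>(params["k_r"]);
  e.pot.Kth = as<double>(params["K_theta"]);
  e.pot.req = as<double>(params["r_eqm"]);
  e.pot.fixed_theta = as<bool>(params["fixed_theta"]);
  e.pot.theta_fixed = as<double>(params["theta_fixed"]);
  e.kmin = 2; e.kmax = 16; e.nmax = 1000000;
  e.radius = 2; e.ftol = 1e-6; e.max_iter = 200;
  return e;
}

// subset: 1-based node ids or empty for the full network; a term is included
// exactly once when any node it involves is in the subset
// [[Rcpp::export]]
double cpp_energy(NumericMatrix pos, List adj,
                  double width, double height, double shear, bool periodic,
                  List params, IntegerVector subset) {
  Engine e = make_static(pos, adj, width, height, shear, periodic, params);
  TermSet t;
  if (subset.size() == 0) {
    full_terms(e, t);
  } else {
    std::vector<char> in(e.V, 0);
    for (int i = 0; i < subset.size(); ++i) in[subset[i] - 1] = 1;
    std::vector<char> cen(e.V, 0);
    for (int i = 0; i < e.V; ++i) {
      bool touch = in[i] != 0;
      for (size_t q = 0; q < e.adj[i].size(); ++q) {
        int j = e.adj[i][q];
        if ((in[i] || in[j]) && i < j) t.bonds.push_back(std::make_pair(i, j));
        if (in[j]) touch = true;
      }
      if (touch && !cen[i]) { cen[i] = 1; t.centers.push_back(i); }
    }
  }
  return energy_terms(e, t);
}

// [[Rcpp::export]]
NumericMatrix cpp_gradient(NumericMatrix pos, List adj,
                           double width, double height, double shear, bool periodic,
                           List params) {
  Engine e = make_static(pos, adj, width, height, shear, periodic, params);
  TermSet t; full_terms(e, t);
  std::vector<double> gx(e.V, 0.0), gy(e.V, 0.0);
  grad_terms(e, t, gx, gy);
  NumericMatrix out(e.V, 2);
  for (int i = 0; i < e.V; ++i) { out(i, 0) = gx[i]; out(i, 1) = gy[i]; }
  return out;
}

// [[Rcpp::export]]
List cpp_relax(NumericMatrix pos, List adj,
               double width, double height, double shear, bool periodic,
               List params, IntegerVector mobile,
               double force_tol, int max_iter) {
  Engine e = make_static(pos, adj, width, height, shear, periodic, params);
  e.ftol = force_tol; e.max_iter = max_iter;
  std::vector<int> mob;
  for (int i = 0; i < mobile.size(); ++i) mob.push_back(mobile[i] - 1);
  int iters = relax_mobile(e, mob);
  NumericMatrix out(e.V, 2);
  for (int i = 0; i < e.V; ++i) { out(i, 0) = e.px[i]; out(i, 1) = e.py[i]; }
  return List::create(_["positions"] = out, _["iterations"] = iters,
                      _["energy"] = energy_full(e));
}
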