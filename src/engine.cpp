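// Core numerical engine for the vertex-dynamics model.
//
// Geometry/topology surgery (cell division) happens on the R side; this file
// only moves vertices and integrates the per-cell chemical state between
// topology changes, so all arrays are flat and rebuilt from R after each
// division.  Vertex indices and cell indices arriving here are 0-based.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Topo {
  int nv, nc, ne;
  std::vector<int> cell_ptr;   // nc+1 offsets into cell_vert
  std::vector<int> cell_vert;  // concatenated CCW vertex cycles
  std::vector<int> edge_a, edge_b;
  std::vector<char> edge_outer;
  std::vector<int> adj_i, adj_j;        // interior-edge cell pairs
  std::vector<char> epidermal;          // L1 flag per cell
  std::vector<char> src_u, src_v, src_w;
  std::vector<double> s_target;         // N-dependent target area per cell
};

Topo unpack_topo(const List& tl) {
  Topo t;
  IntegerVector cp = tl["cell_ptr"], cv = tl["cell_vert"];
  IntegerVector ea = tl["edge_a"], eb = tl["edge_b"];
  IntegerVector eo = tl["edge_outer"];
  IntegerVector ai = tl["adj_i"], aj = tl["adj_j"];
  IntegerVector ep = tl["epidermal"];
  IntegerVector su = tl["src_u"], sv = tl["src_v"], sw = tl["src_w"];
  NumericVector st = tl["s_target"];
  t.nv = as<int>(tl["nv"]);
  t.nc = cp.size() - 1;
  t.ne = ea.size();
  t.cell_ptr.assign(cp.begin(), cp.end());
  t.cell_vert.assign(cv.begin(), cv.end());
  t.edge_a.assign(ea.begin(), ea.end());
  t.edge_b.assign(eb.begin(), eb.end());
  t.edge_outer.assign(eo.begin(), eo.end());
  t.adj_i.assign(ai.begin(), ai.end());
  t.adj_j.assign(aj.begin(), aj.end());
  t.epidermal.assign(ep.begin(), ep.end());
  t.src_u.assign(su.begin(), su.end());
  t.src_v.assign(sv.begin(), sv.end());
  t.src_w.assign(sw.begin(), sw.end());
  t.s_target.assign(st.begin(), st.end());
  return t;
}

struct Params {
  double eta, K_S, K_B, K_R, K_E, L_E, dt;
  double A_u, B_u, D_u, A_v, B_v, D_v, A_w, B_w, D_w;
  double P0, P, u0, S0, n, m;
};

Params unpack_params(const List& pl) {
  Params p;
  p.eta = pl["eta"]; p.K_S = pl["K_S"]; p.K_B = pl["K_B"]; p.K_R = pl["K_R"];
  p.K_E = pl["K_E"]; p.L_E = pl["L_E"]; p.dt = pl["dt"];
  p.A_u = pl["A_u"]; p.B_u = pl["B_u"]; p.D_u = pl["D_u"];
  p.A_v = pl["A_v"]; p.B_v = pl["B_v"]; p.D_v = pl["D_v"];
  p.A_w = pl["A_w"]; p.B_w = pl["B_w"]; p.D_w = pl["D_w"];
  p.P0 = pl["P0"]; p.P = pl["P"]; p.u0 = pl["u0"]; p.S0 = pl["S0"];
  p.n = pl["n"]; p.m = pl["m"];
  return p;
}

// shoelace area of cell c (CCW positive)
inline double cell_area(const Topo& t, const double* x, const double* y, int c) {
  double a = 0.0;
  int lo = t.cell_ptr[c], hi = t.cell_ptr[c + 1];
  int prev = t.cell_vert[hi - 1];
  for (int k = lo; k < hi; ++k) {
    int cur = t.cell_vert[k];
    a += x[prev] * y[cur] - x[cur] * y[prev];
    prev = cur;
  }
  return 0.5 * a;
}

void all_areas(const Topo& t, const double* x, const double* y, double* S) {
  for (int c = 0; c < t.nc; ++c) S[c] = cell_area(t, x, y, c);
}

// F = -dU/dx assembled analytically from the three potential terms
void forces(const Topo& t, const Params& p, const double* x, const double* y,
            double* fx, double* fy, double* Sbuf) {
  for (int j = 0; j < t.nv; ++j) { fx[j] = 0.0; fy[j] = 0.0; }
  // area elasticity (K_S/2)(S_i - s_i)^2 ; dS/dx_j = (y_next - y_prev)/2
  for (int c = 0; c < t.nc; ++c) {
    double S = cell_area(t, x, y, c);
    Sbuf[c] = S;
    double coef = -p.K_S * (S - t.s_target[c]);
    int lo = t.cell_ptr[c], hi = t.cell_ptr[c + 1], n = hi - lo;
    for (int k = 0; k < n; ++k) {
      int j = t.cell_vert[lo + k];
      int jp = t.cell_vert[k == 0 ? hi - 1 : lo + k - 1];
      int jn = t.cell_vert[k == n - 1 ? lo : lo + k + 1];
      fx[j] += coef * 0.5 * (y[jn] - y[jp]);
      fy[j] += coef * 0.5 * (x[jp] - x[jn]);
    }
  }
  // edge terms: K_B L + K_R / L on every edge; (K_E/2)(L - L_E)^2 on outer edges
  for (int e = 0; e < t.ne; ++e) {
    int a = t.edge_a[e], b = t.edge_b[e];
    double dx = x[a] - x[b], dy = y[a] - y[b];
    double L = std::sqrt(dx * dx + dy * dy);
    if (L <= 0.0) stop("zero-length edge: repulsive term undefined");
    double dUdL = p.K_B - p.K_R / (L * L);
    if (t.edge_outer[e]) dUdL += p.K_E * (L - p.L_E);
    double s = -dUdL / L;
    fx[a] += s * dx; fy[a] += s * dy;
    fx[b] -= s * dx; fy[b] -= s * dy;
  }
}

double energy(const Topo& t, const Params& p, const double* x, const double* y) {
  double U = 0.0;
  for (int c = 0; c < t.nc; ++c) {
    double d = cell_area(t, x, y, c) - t.s_target[c];
    U += 0.5 * p.K_S * d * d;
  }
  for (int e = 0; e < t.ne; ++e) {
    int a = t.edge_a[e], b = t.edge_b[e];
    double dx = x[a] - x[b], dy = y[a] - y[b];
    double L = std::sqrt(dx * dx + dy * dy);
    if (L <= 0.0) stop("zero-length edge: repulsive term undefined");
    U += p.K_B * L + p.K_R / L;
    if (t.edge_outer[e]) U += 0.5 * p.K_E * (L - p.L_E) * (L - p.L_E);
  }
  return U;
}

bool areas_ok(const Topo& t, const double* x, const double* y) {
  for (int c = 0; c < t.nc; ++c) {
    double a = cell_area(t, x, y, c);
    if (!std::isfinite(a) || a <= 0.0) return false;
  }
  return true;
}

struct Work {
  std::vector<double> k1x, k1y, k2x, k2y, k3x, k3y, k4x, k4y, tx, ty, S;
  void resize(int nv, int nc) {
    k1x.resize(nv); k1y.resize(nv); k2x.resize(nv); k2y.resize(nv);
    k3x.resize(nv); k3y.resize(nv); k4x.resize(nv); k4y.resize(nv);
    tx.resize(nv); ty.resize(nv); S.resize(nc);
  }
};

// One RK4 step of eta dx/dt = F with step dt; halves dt on post-step area
// collapse (up to max_halve attempts).  Returns max |displacement| component,
// or -1 if even the smallest step failed.
double rk4_step(const Topo& t, const Params& p, double dt, double* x, double* y,
                Work& w, int max_halve = 5) {
  int nv = t.nv;
  for (int attempt = 0; attempt <= max_halve; ++attempt, dt *= 0.5) {
    double h = dt / p.eta;
    forces(t, p, x, y, w.k1x.data(), w.k1y.data(), w.S.data());
    for (int j = 0; j < nv; ++j) { w.tx[j] = x[j] + 0.5 * h * w.k1x[j]; w.ty[j] = y[j] + 0.5 * h * w.k1y[j]; }
    forces(t, p, w.tx.data(), w.ty.data(), w.k2x.data(), w.k2y.data(), w.S.data());
    for (int j = 0; j < nv; ++j) { w.tx[j] = x[j] + 0.5 * h * w.k2x[j]; w.ty[j] = y[j] + 0.5 * h * w.k2y[j]; }
    forces(t, p, w.tx.data(), w.ty.data(), w.k3x.data(), w.k3y.data(), w.S.data());
    for (int j = 0; j < nv; ++j) { w.tx[j] = x[j] + h * w.k3x[j]; w.ty[j] = y[j] + h * w.k3y[j]; }
    forces(t, p, w.tx.data(), w.ty.data(), w.k4x.data(), w.k4y.data(), w.S.data());
    double maxd = 0.0;
    for (int j = 0; j < nv; ++j) {
      double ddx = (h / 6.0) * (w.k1x[j] + 2.0 * w.k2x[j] + 2.0 * w.k3x[j] + w.k4x[j]);
      double ddy = (h / 6.0) * (w.k1y[j] + 2.0 * w.k2y[j] + 2.0 * w.k3y[j] + w.k4y[j]);
      w.tx[j] = x[j] + ddx; w.ty[j] = y[j] + ddy;
      double ad = std::max(std::fabs(ddx), std::fabs(ddy));
      if (ad > maxd) maxd = ad;
    }
    if (areas_ok(t, w.tx.data(), w.ty.data())) {
      for (int j = 0; j < nv; ++j) { x[j] = w.tx[j]; y[j] = w.ty[j]; }
      return maxd;
    }
  }
  return -1.0;
}

// x^e for integer e >= 0 (exponents n, m are small integers in practice;
// std::pow with a runtime double exponent dominates the clock step cost)
inline double powi(double x, int e) {
  double r = 1.0;
  while (e) {
    if (e & 1) r *= x;
    x *= x;
    e >>= 1;
  }
  return r;
}

inline double powf_any(double x, double e) {
  int ei = static_cast<int>(e);
  if (e == ei && ei >= 0) return powi(x, ei);
  return std::pow(x, e);
}

// Hill term z^n / (z0n + z^n) with z0n = z0^n precomputed
inline double hill_pre(double z, double z0n, double n) {
  if (z <= 0.0) return 0.0;
  double a = powf_any(z, n);
  return a / (z0n + a);
}

} // namespace

// [[Rcpp::export]]
double cpp_energy(NumericMatrix V, List topo, List params) {
  Topo t = unpack_topo(topo);
  Params p = unpack_params(params);
  std::vector<double> x(t.nv), y(t.nv);
  for (int j = 0; j < t.nv; ++j) { x[j] = V(j, 0); y[j] = V(j, 1); }
  return energy(t, p, x.data(), y.data());
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix V, List topo, List params) {
  Topo t = unpack_topo(topo);
  Params p = unpack_params(params);
  std::vector<double> x(t.nv), y(t.nv), fx(t.nv), fy(t.nv), S(t.nc);
  for (int j = 0; j < t.nv; ++j) { x[j] = V(j, 0); y[j] = V(j, 1); }
  forces(t, p, x.data(), y.data(), fx.data(), fy.data(), S.data());
  NumericMatrix F(t.nv, 2);
  for (int j = 0; j < t.nv; ++j) { F(j, 0) = fx[j]; F(j, 1) = fy[j]; }
  return F;
}

// [[Rcpp::export]]
NumericVector cpp_areas(NumericMatrix V, List topo) {
  Topo t = unpack_topo(topo);
  std::vector<double> x(t.nv), y(t.nv);
  for (int j = 0; j < t.nv; ++j) { x[j] = V(j, 0); y[j] = V(j, 1); }
  NumericVector S(t.nc);
  for (int c = 0; c < t.nc; ++c) S[c] = cell_area(t, x.data(), y.data(), c);
  return S;
}

// Pure mechanical relaxation: nsteps RK4 steps (optionally recording energy),
// with optional early exit once the per-step displacement falls below tol.
// [[Rcpp::export]]
List cpp_mech_steps(NumericMatrix V, List topo, List params, int nsteps,
                    bool record_energy = false, double tol = 0.0) {
  Topo t = unpack_topo(topo);
  Params p = unpack_params(params);
  std::vector<double> x(t.nv), y(t.nv);
  for (int j = 0; j < t.nv; ++j) { x[j] = V(j, 0); y[j] = V(j, 1); }
  Work w; w.resize(t.nv, t.nc);
  std::vector<double> etrace;
  if (record_energy) etrace.push_back(energy(t, p, x.data(), y.data()));
  int done = 0;
  double maxd = NA_REAL;
  for (int s = 0; s < nsteps; ++s) {
    maxd = rk4_step(t, p, p.dt, x.data(), y.data(), w);
    if (maxd < 0.0) stop("mechanics step failed after 5 dt halvings");
    ++done;
    if (record_energy) etrace.push_back(energy(t, p, x.data(), y.data()));
    if (tol > 0.0 && maxd < tol) break;
  }
  NumericMatrix Vout(t.nv, 2);
  for (int j = 0; j < t.nv; ++j) { Vout(j, 0) = x[j]; Vout(j, 1) = y[j]; }
  return List::create(_["V"] = Vout, _["steps"] = done, _["max_disp"] = maxd,
                      _["energy"] = wrap(etrace));
}

// Fused inner loop: per dt step, in this fixed order,
//   1. Euler step of the three morphogen fields on the adjacency graph
//   2. Euler step of the division clock (non-epidermal cells only)
//   3. division-trigger check (returns control to R *before* mechanics so the
//      division executes within the same dt step, mechanics following it)
//   4. one RK4 mechanics step
// Early return when quiescent (per-step displacement and concentration changes
// below tolerance) so the R driver can advance the clocks analytically.
// status: 0 = max_steps done, 1 = clock trigger, 3 = quiescent.
// [[Rcpp::export]]
List cpp_run_chunk(NumericMatrix V, List topo, List params,
                   NumericVector u, NumericVector v, NumericVector w,
                   NumericVector clock, NumericVector thresh,
                   int max_steps, bool check_divisions = true,
                   bool clocks_on = true, bool quiesce = false,
                   double tol_v = 1e-9, double tol_z = 1e-12,
                   bool skip_first_chem = false) {
  Topo t = unpack_topo(topo);
  Params p = unpack_params(params);
  int nc = t.nc;
  std::vector<double> x(t.nv), y(t.nv);
  for (int j = 0; j < t.nv; ++j) { x[j] = V(j, 0); y[j] = V(j, 1); }
  std::vector<double> U(u.begin(), u.end()), Vv(v.begin(), v.end()),
      W(w.begin(), w.end()), CK(clock.begin(), clock.end());
  std::vector<double> lu(nc), lv(nc), lw(nc), S(nc), rate(nc, 0.0);
  Work wk; wk.resize(t.nv, nc);
  int status = 0, steps = 0;
  double maxdz = NA_REAL, maxd = NA_REAL;
  IntegerVector triggered;

  for (int s = 0; s < max_steps; ++s) {
    if (!(skip_first_chem && s == 0)) {
      // 1. morphogens (unweighted graph Laplacian coupling)
      std::fill(lu.begin(), lu.end(), 0.0);
      std::fill(lv.begin(), lv.end(), 0.0);
      std::fill(lw.begin(), lw.end(), 0.0);
      for (size_t e = 0; e < t.adj_i.size(); ++e) {
        int i = t.adj_i[e], j = t.adj_j[e];
        double du = U[j] - U[i]; lu[i] += du; lu[j] -= du;
        double dv = Vv[j] - Vv[i]; lv[i] += dv; lv[j] -= dv;
        double dw = W[j] - W[i]; lw[i] += dw; lw[j] -= dw;
      }
      maxdz = 0.0;
      for (int c = 0; c < nc; ++c) {
        double du = p.dt * (p.A_u * t.src_u[c] - p.B_u * U[c] + p.D_u * lu[c]);
        double dv = p.dt * (p.A_v * t.src_v[c] - p.B_v * Vv[c] + p.D_v * lv[c]);
        double dw = p.dt * (p.A_w * t.src_w[c] - p.B_w * W[c] + p.D_w * lw[c]);
        U[c] += du; Vv[c] += dv; W[c] += dw;
        double m3 = std::max(std::fabs(du), std::max(std::fabs(dv), std::fabs(dw)));
        if (m3 > maxdz) maxdz = m3;
        if (U[c] < 0.0 || Vv[c] < 0.0 || W[c] < 0.0 ||
            !std::isfinite(U[c]) || !std::isfinite(Vv[c]) || !std::isfinite(W[c]))
          stop("morphogen Euler instability at dt=%f (cell %d)", p.dt, c + 1);
      }
      // 2. clock
      if (clocks_on) {
        const double u0n = powf_any(p.u0, p.n), S0m = powf_any(p.S0, p.m);
        all_areas(t, x.data(), y.data(), S.data());
        for (int c = 0; c < nc; ++c) {
          if (t.epidermal[c]) continue;
          if (U[c] < 0.0 || S[c] < 0.0) stop("negative u or S in clock step");
          rate[c] = p.P0 + p.P * hill_pre(U[c], u0n, p.n) *
                    hill_pre(S[c], S0m, p.m);
          CK[c] += p.dt * rate[c];
        }
        // 3. trigger check (strict inequality)
        if (check_divisions) {
          std::vector<int> hit;
          for (int c = 0; c < nc; ++c)
            if (!t.epidermal[c] && CK[c] > thresh[c]) hit.push_back(c + 1);
          if (!hit.empty()) {
            triggered = wrap(hit);
            status = 1;
            ++steps;  // morphogen+clock advanced; mechanics for this dt runs
                      // in R after the division executes
            break;
          }
        }
      }
    }
    // 4. mechanics
    maxd = rk4_step(t, p, p.dt, x.data(), y.data(), wk);
    if (maxd < 0.0) stop("mechanics step failed after 5 dt halvings");
    ++steps;
    if (quiesce && s > 0 && maxd < tol_v &&
        (!std::isfinite(maxdz) || maxdz < tol_z || !clocks_on)) {
      status = 3;
      break;
    }
  }

  NumericMatrix Vout(t.nv, 2);
  for (int j = 0; j < t.nv; ++j) { Vout(j, 0) = x[j]; Vout(j, 1) = y[j]; }
  return List::create(
      _["V"] = Vout, _["u"] = wrap(U), _["v"] = wrap(Vv), _["w"] = wrap(W),
      _["clock"] = wrap(CK), _["rate"] = wrap(rate), _["steps"] = steps,
      _["status"] = status, _["triggered"] = triggered,
      _["max_disp"] = maxd, _["max_dz"] = maxdz);
}
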