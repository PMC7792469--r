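// Compiled kernels: distance transform, connected components, geodesic
// centerline tracing, tube rasterization, and the 1D elastic-tube solver.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher), 3D,
// anisotropic spacing.  Returns, for every foreground voxel, the distance in
// mm to the nearest background voxel (0 on background).
// ---------------------------------------------------------------------------

// "infinite" squared distance that stays finite in parabola arithmetic
static const double DT_BIG = 1e20;

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double fq = f[q], fv = f[v[k]];
      s = ((fq + h2 * q * q) - (fv + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k]) {  // k == 0 and still dominated: replace the root
      v[0] = q;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = "cf_edt")]]
NumericVector cf_edt(LogicalVector mask, IntegerVector dims,
                     NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? DT_BIG : 0.0;
  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = 0; i < nx; ++i) f[i] = out[base + i];
        dt1d(f, d, nx, spacing[0]);
        for (int i = 0; i < nx; ++i) out[base + i] = d[i];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j)
          f[j] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        dt1d(f, d, ny, spacing[1]);
        for (int j = 0; j < ny; ++j)
          out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[j];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k)
          f[k] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        dt1d(f, d, nz, spacing[2]);
        for (int k = 0; k < nz; ++k)
          out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = std::sqrt(d[k]);
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (6- or 26-connectivity).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = "cf_label")]]
IntegerVector cf_label(LogicalVector mask, IntegerVector dims,
                       int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) > 1)
              continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[w] && !lab[w]) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Dijkstra geodesic distance inside a mask, 26-connectivity, physical step
// lengths, optional per-voxel multiplicative cost weight.  Seeds are 0-based
// linear indices.  Returns dist (Inf where unreached) and parent (-1 at
// seeds / unreached).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = "cf_geodesic")]]
List cf_geodesic(LogicalVector mask, IntegerVector dims, NumericVector spacing,
                 IntegerVector seeds, NumericVector weight) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  bool haveW = weight.size() == n;
  NumericVector dist(n, INF);
  IntegerVector parent(n, -1);
  IntegerVector label(n, -1);   // index of the seed each voxel drains to
  // neighbour offsets + physical lengths
  int off[26][3];
  double len[26];
  int m = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (!di && !dj && !dk) continue;
        off[m][0] = di; off[m][1] = dj; off[m][2] = dk;
        double lx = di * spacing[0], ly = dj * spacing[1], lz = dk * spacing[2];
        len[m] = std::sqrt(lx * lx + ly * ly + lz * lz);
        ++m;
      }
  typedef std::pair<double, R_xlen_t> PQE;
  std::priority_queue<PQE, std::vector<PQE>, std::greater<PQE> > pq;
  for (int s = 0; s < seeds.size(); ++s) {
    R_xlen_t v = seeds[s];
    if (v < 0 || v >= n || !mask[v]) continue;
    dist[v] = 0.0;
    label[v] = s;
    pq.push(PQE(0.0, v));
  }
  while (!pq.empty()) {
    PQE top = pq.top();
    pq.pop();
    R_xlen_t v = top.second;
    if (top.first > dist[v]) continue;
    int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
    double wv = haveW ? weight[v] : 1.0;
    for (int e = 0; e < 26; ++e) {
      int ii = i + off[e][0], jj = j + off[e][1], kk = k + off[e][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (!mask[w]) continue;
      double ww = haveW ? weight[w] : 1.0;
      double nd = dist[v] + len[e] * 0.5 * (wv + ww);
      if (nd < dist[w]) {
        dist[w] = nd;
        parent[w] = (int)v;
        label[w] = label[v];
        pq.push(PQE(nd, w));
      }
    }
  }
  return List::create(_["dist"] = dist, _["parent"] = parent,
                      _["label"] = label);
}

// ---------------------------------------------------------------------------
// Rasterize a capsule (cylinder with spherical caps) into an intensity
// array: voxels whose centre lies within `radius` mm of the segment
// p0-p1 (world mm) are set to max(current, value).  Modifies `vol` in
// place; the R wrapper owns the array.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = "cf_add_capsule")]]
void cf_add_capsule(NumericVector vol, IntegerVector dims,
                    NumericVector spacing, NumericVector origin,
                    NumericVector p0, NumericVector p1, double radius,
                    double value) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = std::min(p0[a], p1[a]) - radius;
    hi[a] = std::max(p0[a], p1[a]) + radius;
  }
  int i0 = std::max(0, (int)std::floor((lo[0] - origin[0]) / spacing[0]));
  int j0 = std::max(0, (int)std::floor((lo[1] - origin[1]) / spacing[1]));
  int k0 = std::max(0, (int)std::floor((lo[2] - origin[2]) / spacing[2]));
  int i1 = std::min(nx - 1, (int)std::ceil((hi[0] - origin[0]) / spacing[0]));
  int j1 = std::min(ny - 1, (int)std::ceil((hi[1] - origin[1]) / spacing[1]));
  int k1 = std::min(nz - 1, (int)std::ceil((hi[2] - origin[2]) / spacing[2]));
  double d[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double L2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
  double r2 = radius * radius;
  for (int k = k0; k <= k1; ++k)
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        double x = origin[0] + i * spacing[0] - p0[0];
        double y = origin[1] + j * spacing[1] - p0[1];
        double z = origin[2] + k * spacing[2] - p0[2];
        double t = L2 > 0 ? (x * d[0] + y * d[1] + z * d[2]) / L2 : 0.0;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
        double qx = x - t * d[0], qy = y - t * d[1], qz = z - t * d[2];
        if (qx * qx + qy * qy + qz * qz <= r2) {
          R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          if (vol[v] < value) vol[v] = value;
        }
      }
}

// ---------------------------------------------------------------------------
// 1D unsteady elastic-tube network solver.
//
// Governing equations per segment (conservative area / velocity head form):
//   dA/dt + d(Au)/dx = 0
//   du/dt + d(u^2/2 + p/rho)/dx = -8 pi mu u / (rho A)
// Tube law: p = p_ext + rho c0^2 (A/A0 - 1)  =>  c(A) = c0 sqrt(A/A0),
// Riemann invariants W+- = u +- 2 (c - c0).
// Interior: MacCormack predictor-corrector.  Boundaries: characteristic
// extrapolation + algebraic closures (prescribed inlet pressure, resistive
// terminals, junctions with mass conservation and total-pressure
// continuity solved by Newton).
// ---------------------------------------------------------------------------

struct Seg1D {
  int from, to, nx;
  double L, dx, A0, c0;
  std::vector<double> A, u, An, un, As, us;
};

// periodic reduction without libm fmod (keeps the binary portable)
static inline double pmod(double a, double b) {
  double r = a - b * std::floor(a / b);
  if (r < 0) r += b;
  if (r >= b) r -= b;
  return r;
}

static inline double tl_p(const Seg1D& s, double A, double rho, double pext) {
  return pext + rho * s.c0 * s.c0 * (A / s.A0 - 1.0);
}
static inline double tl_c(const Seg1D& s, double A) {
  return s.c0 * std::sqrt(A / s.A0);
}

// dense Gaussian elimination with partial pivoting
static bool gauss_solve(std::vector<double>& M, std::vector<double>& b, int n) {
  for (int col = 0; col < n; ++col) {
    int piv = col;
    for (int r = col + 1; r < n; ++r)
      if (std::fabs(M[r * n + col]) > std::fabs(M[piv * n + col])) piv = r;
    if (std::fabs(M[piv * n + col]) < 1e-300) return false;
    if (piv != col) {
      for (int c = 0; c < n; ++c) std::swap(M[col * n + c], M[piv * n + c]);
      std::swap(b[col], b[piv]);
    }
    for (int r = col + 1; r < n; ++r) {
      double f = M[r * n + col] / M[col * n + col];
      for (int c = col; c < n; ++c) M[r * n + c] -= f * M[col * n + c];
      b[r] -= f * b[col];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = b[r];
    for (int c = r + 1; c < n; ++c) s -= M[r * n + c] * b[c];
    b[r] = s / M[r * n + r];
  }
  return true;
}

// [[Rcpp::export(name = "cf_solve1d")]]
List cf_solve1d(IntegerVector seg_from, IntegerVector seg_to,
                NumericVector seg_L, NumericVector seg_A0,
                NumericVector seg_c0, IntegerVector seg_nx,
                IntegerVector node_type,  // 0 inlet, 1 junction, 2 terminal
                NumericVector term_R, NumericVector term_Pout,
                NumericVector inflow, double period, double rho, double mu,
                double pext, double cfl, int n_cycles, double conv_tol,
                int n_out) {
  int ns = seg_from.size();
  int nn = node_type.size();
  std::vector<Seg1D> S(ns);
  for (int s = 0; s < ns; ++s) {
    S[s].from = seg_from[s];
    S[s].to = seg_to[s];
    S[s].nx = seg_nx[s];
    S[s].L = seg_L[s];
    S[s].dx = seg_L[s] / (seg_nx[s] - 1);
    S[s].A0 = seg_A0[s];
    S[s].c0 = seg_c0[s];
    S[s].A.assign(S[s].nx, S[s].A0);
    S[s].u.assign(S[s].nx, 0.0);
    S[s].An = S[s].A;
    S[s].un = S[s].u;
    S[s].As = S[s].A;
    S[s].us = S[s].u;
  }
  // node -> attached segment ends: (seg index, end: 0 proximal / 1 distal)
  std::vector<std::vector<std::pair<int, int> > > ends(nn);
  for (int s = 0; s < ns; ++s) {
    ends[S[s].from].push_back(std::make_pair(s, 0));
    ends[S[s].to].push_back(std::make_pair(s, 1));
  }
  int nwf = inflow.size();
  // cycle accumulators for pressure means at every grid point
  std::vector<std::vector<double> > accP(ns), accU(ns), accA(ns), meanP(ns),
      meanU(ns), meanA(ns), prevP(ns);
  for (int s = 0; s < ns; ++s) {
    accP[s].assign(S[s].nx, 0.0);
    accU[s].assign(S[s].nx, 0.0);
    accA[s].assign(S[s].nx, 0.0);
    meanP[s].assign(S[s].nx, NA_REAL);
    prevP[s].assign(S[s].nx, NA_REAL);
  }
  double accT = 0.0;
  // snapshots at n_out phases of the running cycle
  std::vector<NumericMatrix> snapP(ns), snapU(ns), snapA(ns);
  for (int s = 0; s < ns; ++s) {
    snapP[s] = NumericMatrix(n_out, S[s].nx);
    snapU[s] = NumericMatrix(n_out, S[s].nx);
    snapA[s] = NumericMatrix(n_out, S[s].nx);
  }
  int next_snap = 0;

  double t = 0.0;
  int cycle = 0, cycles_done = 0;
  bool converged = false, have_mean = false;
  double max_mass_res = 0.0, dt_min = INF, last_maxdiff = NA_REAL;
  long n_static_fallback = 0;
  const double PI = 3.14159265358979323846;
  long max_steps = 50000000L;  // hard safety stop
  long step = 0;

  // inflow interpolation (periodic, linear)
  auto p_in = [&](double tt) {
    if (nwf == 1) return inflow[0];
    double ph = pmod(tt, period) / period * nwf;
    int i0 = (int)std::floor(ph) % nwf;
    int i1 = (i0 + 1) % nwf;
    double f = ph - std::floor(ph);
    return inflow[i0] * (1.0 - f) + inflow[i1] * f;
  };
  auto fric = [&](const Seg1D& sg, double A, double u) {
    return mu > 0 ? -8.0 * PI * mu * u / (rho * A) : 0.0;
  };

  while (step < max_steps) {
    ++step;
    // time step from CFL
    double dt = INF;
    for (int s = 0; s < ns; ++s) {
      double smax = 1e-12;
      for (int i = 0; i < S[s].nx; ++i) {
        double sp = std::fabs(S[s].u[i]) + tl_c(S[s], S[s].A[i]);
        if (sp > smax) smax = sp;
      }
      double d = cfl * S[s].dx / smax;
      if (d < dt) dt = d;
    }
    if (period > 0 && dt > period / 200.0) dt = period / 200.0;
    if (dt < dt_min) dt_min = dt;
    double tn = t + dt;

    // MacCormack interior update
    for (int s = 0; s < ns; ++s) {
      Seg1D& sg = S[s];
      int nx = sg.nx;
      double lam = dt / sg.dx;
      // predictor (forward differences), defined for i = 0..nx-2
      for (int i = 0; i < nx; ++i) {
        if (i < nx - 1) {
          double F1a = sg.A[i] * sg.u[i];
          double F1b = sg.A[i + 1] * sg.u[i + 1];
          double F2a = 0.5 * sg.u[i] * sg.u[i] + tl_p(sg, sg.A[i], rho, pext) / rho;
          double F2b = 0.5 * sg.u[i + 1] * sg.u[i + 1] +
                       tl_p(sg, sg.A[i + 1], rho, pext) / rho;
          sg.As[i] = sg.A[i] - lam * (F1b - F1a);
          sg.us[i] = sg.u[i] - lam * (F2b - F2a) + dt * fric(sg, sg.A[i], sg.u[i]);
        } else {
          sg.As[i] = sg.A[i];
          sg.us[i] = sg.u[i];
        }
        if (sg.As[i] < 1e-3 * sg.A0) sg.As[i] = 1e-3 * sg.A0;
      }
      // corrector (backward differences), interior i = 1..nx-2
      for (int i = 1; i < nx - 1; ++i) {
        double F1a = sg.As[i - 1] * sg.us[i - 1];
        double F1b = sg.As[i] * sg.us[i];
        double F2a = 0.5 * sg.us[i - 1] * sg.us[i - 1] +
                     tl_p(sg, sg.As[i - 1], rho, pext) / rho;
        double F2b = 0.5 * sg.us[i] * sg.us[i] +
                     tl_p(sg, sg.As[i], rho, pext) / rho;
        sg.An[i] = 0.5 * (sg.A[i] + sg.As[i]) - 0.5 * lam * (F1b - F1a);
        sg.un[i] = 0.5 * (sg.u[i] + sg.us[i]) - 0.5 * lam * (F2b - F2a) +
                   0.5 * dt * fric(sg, sg.As[i], sg.us[i]);
        if (sg.An[i] < 1e-3 * sg.A0) sg.An[i] = 1e-3 * sg.A0;
      }
    }

    // outgoing characteristic invariants at each segment end (old time foot)
    std::vector<double> Wprox(ns), Wdist(ns);
    for (int s = 0; s < ns; ++s) {
      Seg1D& sg = S[s];
      int nx = sg.nx;
      {  // proximal end: outgoing speed c - u toward x=0
        double c0p = tl_c(sg, sg.A[0]);
        double sp = std::max(0.0, c0p - sg.u[0]);
        double f = std::min(1.0, sp * dt / sg.dx);
        double Af = (1 - f) * sg.A[0] + f * sg.A[1];
        double uf = (1 - f) * sg.u[0] + f * sg.u[1];
        Wprox[s] = uf - 2.0 * (tl_c(sg, Af) - sg.c0) + dt * fric(sg, Af, uf);
      }
      {  // distal end: outgoing speed u + c toward x=L
        double cNp = tl_c(sg, sg.A[nx - 1]);
        double sp = std::max(0.0, sg.u[nx - 1] + cNp);
        double f = std::min(1.0, sp * dt / sg.dx);
        double Af = (1 - f) * sg.A[nx - 1] + f * sg.A[nx - 2];
        double uf = (1 - f) * sg.u[nx - 1] + f * sg.u[nx - 2];
        Wdist[s] = uf + 2.0 * (tl_c(sg, Af) - sg.c0) + dt * fric(sg, Af, uf);
      }
    }

    // boundary closures per node
    for (int v = 0; v < nn; ++v) {
      const std::vector<std::pair<int, int> >& E = ends[v];
      if (E.empty()) continue;
      if (node_type[v] == 0) {
        // prescribed-pressure inlet; must be a proximal end
        for (size_t e = 0; e < E.size(); ++e) {
          Seg1D& sg = S[E[e].first];
          double pt = p_in(tn);
          double A = sg.A0 * ((pt - pext) / (rho * sg.c0 * sg.c0) + 1.0);
          if (A < 1e-3 * sg.A0) A = 1e-3 * sg.A0;
          double W = Wprox[E[e].first];
          double u = W + 2.0 * (tl_c(sg, A) - sg.c0);
          sg.An[0] = A;
          sg.un[0] = u;
        }
      } else if (node_type[v] == 2) {
        // resistive terminal at a distal end: A u = (p(A) - Pout)/R
        Seg1D& sg = S[E[0].first];
        int nx = sg.nx;
        double W = Wdist[E[0].first];
        double R = term_R[v], Pout = term_Pout[v];
        double A = sg.A[nx - 1];
        for (int it = 0; it < 50; ++it) {
          double c = tl_c(sg, A);
          double u = W - 2.0 * (c - sg.c0);
          double g = A * u - (tl_p(sg, A, rho, pext) - Pout) / R;
          double dg = u - c - rho * sg.c0 * sg.c0 / (sg.A0 * R);
          double dA = -g / dg;
          // damped Newton
          if (dA > 0.25 * A) dA = 0.25 * A;
          if (dA < -0.25 * A) dA = -0.25 * A;
          A += dA;
          if (A < 1e-3 * sg.A0) A = 1e-3 * sg.A0;
          if (std::fabs(dA) < 1e-14 * sg.A0) break;
        }
        sg.An[nx - 1] = A;
        sg.un[nx - 1] = W - 2.0 * (tl_c(sg, A) - sg.c0);
      } else {
        // junction: unknowns (A_e, u_e) per attached end
        int k = E.size();
        int nunk = 2 * k;
        std::vector<double> X(nunk);
        std::vector<double> Wv(k);
        std::vector<int> dir(k);  // +1 distal end (flow into node), -1 proximal
        for (int e = 0; e < k; ++e) {
          Seg1D& sg = S[E[e].first];
          if (E[e].second == 1) {
            dir[e] = 1;
            Wv[e] = Wdist[E[e].first];
            X[2 * e] = sg.A[sg.nx - 1];
            X[2 * e + 1] = sg.u[sg.nx - 1];
          } else {
            dir[e] = -1;
            Wv[e] = Wprox[E[e].first];
            X[2 * e] = sg.A[0];
            X[2 * e + 1] = sg.u[0];
          }
        }
        std::vector<double> Rv(nunk), M(nunk * nunk);
        std::vector<double> X0(X);
        bool ok = false;
        // mode 0: total-pressure continuity (p + rho u^2/2).  If the throat
        // flow turns supercritical the Newton system loses its subcritical
        // root; mode 1 retries with static-pressure continuity (the
        // dynamic-pressure term dropped), which always has one.
        for (int mode = 0; mode < 2 && !ok; ++mode) {
        if (mode == 1) { X = X0; ++n_static_fallback; }
        for (int it = 0; it < 120; ++it) {
          std::fill(M.begin(), M.end(), 0.0);
          double rn = 0.0;
          // rows 0..k-1: characteristic compatibility
          for (int e = 0; e < k; ++e) {
            Seg1D& sg = S[E[e].first];
            double A = X[2 * e], u = X[2 * e + 1];
            double c = tl_c(sg, A);
            Rv[e] = u + dir[e] * 2.0 * (c - sg.c0) - Wv[e];
            M[e * nunk + 2 * e] = dir[e] * c / A;
            M[e * nunk + 2 * e + 1] = 1.0;
            rn = std::max(rn, std::fabs(Rv[e]) / sg.c0);
          }
          // row k: mass balance
          {
            double q = 0.0;
            double qs = 1e-12;
            for (int e = 0; e < k; ++e) {
              double A = X[2 * e], u = X[2 * e + 1];
              q += dir[e] * A * u;
              qs += std::fabs(A * u);
              M[k * nunk + 2 * e] = dir[e] * u;
              M[k * nunk + 2 * e + 1] = dir[e] * A;
            }
            Rv[k] = q;
            rn = std::max(rn, std::fabs(q) / qs);
          }
          // rows k+1 .. 2k-1: (total) pressure continuity vs end 0
          for (int e = 1; e < k; ++e) {
            Seg1D& s0 = S[E[0].first];
            Seg1D& se = S[E[e].first];
            double A0v = X[0], u0v = X[1], Ae = X[2 * e], ue = X[2 * e + 1];
            double kin0 = mode == 0 ? 0.5 * rho * u0v * u0v : 0.0;
            double kine = mode == 0 ? 0.5 * rho * ue * ue : 0.0;
            double pt0 = tl_p(s0, A0v, rho, pext) + kin0;
            double pte = tl_p(se, Ae, rho, pext) + kine;
            int row = k + e;
            Rv[row] = pt0 - pte;
            M[row * nunk + 0] = rho * s0.c0 * s0.c0 / s0.A0;
            M[row * nunk + 1] = mode == 0 ? rho * u0v : 0.0;
            M[row * nunk + 2 * e] = -rho * se.c0 * se.c0 / se.A0;
            M[row * nunk + 2 * e + 1] = mode == 0 ? -rho * ue : 0.0;
            rn = std::max(rn, std::fabs(Rv[row]) /
                                  (rho * s0.c0 * s0.c0));
          }
          if (rn < 1e-11) { ok = true; break; }
          std::vector<double> b(Rv);
          if (!gauss_solve(M, b, nunk)) break;
          for (int e = 0; e < k; ++e) {
            Seg1D& sg = S[E[e].first];
            // damped update keeps the iterates physical
            double dA = b[2 * e], du = b[2 * e + 1];
            double capA = 0.25 * X[2 * e], capU = 0.5 * sg.c0;
            if (dA > capA) dA = capA;
            if (dA < -capA) dA = -capA;
            if (du > capU) du = capU;
            if (du < -capU) du = -capU;
            X[2 * e] -= dA;
            X[2 * e + 1] -= du;
            if (X[2 * e] < 1e-3 * sg.A0) X[2 * e] = 1e-3 * sg.A0;
          }
        }
        }
        if (!ok) stop("junction Newton failed to converge at node %d", v + 1);
        double q = 0.0, qs = 1e-30;
        for (int e = 0; e < k; ++e) {
          Seg1D& sg = S[E[e].first];
          double A = X[2 * e], u = X[2 * e + 1];
          q += dir[e] * A * u;
          qs += std::fabs(A * u);
          if (dir[e] == 1) {
            sg.An[sg.nx - 1] = A;
            sg.un[sg.nx - 1] = u;
          } else {
            sg.An[0] = A;
            sg.un[0] = u;
          }
        }
        double res = std::fabs(q) / qs;
        if (res > max_mass_res) max_mass_res = res;
      }
    }

    // commit
    for (int s = 0; s < ns; ++s) {
      S[s].A.swap(S[s].An);
      S[s].u.swap(S[s].un);
      for (int i = 0; i < S[s].nx; ++i)
        if (!std::isfinite(S[s].A[i]) || !std::isfinite(S[s].u[i]))
          stop("1D solver diverged (non-finite state)");
    }

    // accumulate means, snapshots
    for (int s = 0; s < ns; ++s)
      for (int i = 0; i < S[s].nx; ++i) {
        accP[s][i] += dt * tl_p(S[s], S[s].A[i], rho, pext);
        accU[s][i] += dt * S[s].u[i];
        accA[s][i] += dt * S[s].A[i];
      }
    accT += dt;
    double phase_new = pmod(tn, period);
    while (next_snap < n_out && phase_new >= period * next_snap / n_out &&
           pmod(t, period) <= phase_new) {
      for (int s = 0; s < ns; ++s)
        for (int i = 0; i < S[s].nx; ++i) {
          snapP[s](next_snap, i) = tl_p(S[s], S[s].A[i], rho, pext);
          snapU[s](next_snap, i) = S[s].u[i];
          snapA[s](next_snap, i) = S[s].A[i];
        }
      ++next_snap;
    }

    t = tn;
    int new_cycle = (int)std::floor(t / period + 1e-12);
    if (new_cycle > cycle) {
      // cycle boundary: finalize means, test periodic convergence
      ++cycles_done;
      double maxdiff = 0.0;
      for (int s = 0; s < ns; ++s) {
        meanU[s].assign(S[s].nx, 0.0);
        meanA[s].assign(S[s].nx, 0.0);
        for (int i = 0; i < S[s].nx; ++i) {
          double mp = accP[s][i] / accT;
          if (have_mean) {
            double d = std::fabs(mp - prevP[s][i]);
            if (d > maxdiff) maxdiff = d;
          }
          prevP[s][i] = mp;
          meanP[s][i] = mp;
          meanU[s][i] = accU[s][i] / accT;
          meanA[s][i] = accA[s][i] / accT;
          accP[s][i] = accU[s][i] = accA[s][i] = 0.0;
        }
      }
      accT = 0.0;
      next_snap = 0;
      last_maxdiff = have_mean ? maxdiff : NA_REAL;
      if (have_mean && maxdiff < conv_tol) {
        converged = true;
        break;
      }
      have_mean = true;
      cycle = new_cycle;
      if (cycles_done >= n_cycles) break;
    }
  }

  // node-level cycle-mean pressures.  Static pressure differs between the
  // segment ends meeting at a junction (total pressure is what is
  // continuous); report the value in the largest-calibre attached segment,
  // which is where a pressure wire sits - never inside a stenotic throat.
  NumericVector nodeP(nn, NA_REAL);
  for (int v = 0; v < nn; ++v) {
    if (ends[v].empty()) continue;
    int best = 0;
    for (size_t e = 1; e < ends[v].size(); ++e)
      if (S[ends[v][e].first].A0 > S[ends[v][best].first].A0) best = e;
    int s = ends[v][best].first;
    int i = ends[v][best].second == 1 ? S[s].nx - 1 : 0;
    nodeP[v] = meanP[s][i];
  }
  List segP(ns), segU(ns), segA(ns), spP(ns), spU(ns), spA(ns);
  for (int s = 0; s < ns; ++s) {
    segP[s] = wrap(meanP[s]);
    segU[s] = wrap(meanU[s]);
    segA[s] = wrap(meanA[s]);
    spP[s] = snapP[s];
    spU[s] = snapU[s];
    spA[s] = snapA[s];
  }
  return List::create(
      _["node_p_mean"] = nodeP, _["seg_p_mean"] = segP,
      _["seg_u_mean"] = segU, _["seg_A_mean"] = segA, _["snap_p"] = spP,
      _["snap_u"] = spU, _["snap_A"] = spA, _["converged"] = converged,
      _["cycles_run"] = cycles_done, _["mass_residual"] = max_mass_res,
      _["dt_min"] = dt_min, _["cycle_delta_p"] = last_maxdiff,
      _["n_static_fallback"] = (double)n_static_fallback,
      _["n_steps"] = (double)step);
}
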