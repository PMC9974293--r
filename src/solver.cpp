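// Explicit 1D pulse-wave solver on an arterial tree.
//
// Per vessel: mass and momentum balance on (A, Q),
//   A_t + Q_x = 0
//   Q_t + (alpha Q^2/A + beta A^{3/2} / (3 rho A0))_x =
//       -K_R Q/A + A g sin(tilt) sin(phi) + taper source,
// with the elastic beta tube law P = beta/A0 (sqrt(A) - sqrt(A0)) and
// wave speed c = sqrt(beta / (2 rho A0)) A^{1/4}.  Interior nodes are
// advanced with the two-step (Richtmyer) Lax-Wendroff scheme; vessel
// ends are coupled by Riemann characteristics (W+- = U +- 4c) to the
// prescribed inflow, to junction matching (mass + total pressure via
// Newton), and to RCR Windkessel terminals.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Vessel {
  int n;                 // cells; nodes are 0..n
  double L, dx, beta, Gamma, sinphi, z_prox, dA0dx;
  std::vector<double> A0;        // at nodes
  std::vector<double> A0h;       // at interfaces i+1/2
  std::vector<double> A, Q;      // state at nodes
  std::vector<double> Ah, Qh;    // half-step interface states
  // time-n boundary-adjacent states kept for characteristic extrapolation
  double bA0n, bQ0n, bA1n, bQ1n, bAm1n, bQm1n, bAmn, bQmn;
};

struct Terminal {
  int vessel;
  double R1, R2, C, Pout, Pc;
};

struct Junction {
  int parent;
  std::vector<int> daughters;
};

static inline double pressure(const Vessel& v, int i, double A) {
  return v.beta / v.A0[i] * (std::sqrt(A) - std::sqrt(v.A0[i]));
}
static inline double wavespeed(const Vessel& v, double A0, double A,
                               double rho) {
  return std::sqrt(v.beta / (2.0 * rho * A0)) * std::pow(A, 0.25);
}
static inline double flux2(double Q, double A, double A0, double beta,
                           double alpha, double rho) {
  return alpha * Q * Q / A + beta * std::pow(A, 1.5) / (3.0 * rho * A0);
}
static inline double source2(const Vessel& v, double Q, double A,
                             double A0, double Kr, double geff,
                             double rho) {
  double taper = v.dA0dx * (2.0 / 3.0 * v.beta * std::pow(A, 1.5) /
                              (rho * A0 * A0) -
                            v.beta * A / (2.0 * rho * std::pow(A0, 1.5)));
  return -Kr * Q / A + A * geff * v.sinphi + taper;
}

// source term of the characteristic variable W+- = U +- 4c along its
// path (gravity, friction, and the explicit x-dependence of the tube
// law through A0(x)); needed so boundary extrapolation preserves
// steady and hydrostatic states
static inline double char_source(const Vessel& v, int i, double A,
                                 double Q, int sgn, double Kr,
                                 double geff, double rho) {
  double U = Q / A;
  double A0 = v.A0[i];
  double c = wavespeed(v, A0, A, rho);
  return geff * v.sinphi - Kr * U / A -
         (v.beta * v.dA0dx / rho) *
             (-std::sqrt(A) / (A0 * A0) + 0.5 * std::pow(A0, -1.5)) -
         sgn * 2.0 * c * (v.dA0dx / A0) * (U + sgn * c);
}

// solve m x m linear system in place (partial pivoting); returns false if singular
static bool solve_lin(std::vector<double>& J, std::vector<double>& r, int m) {
  for (int k = 0; k < m; ++k) {
    int piv = k;
    for (int i = k + 1; i < m; ++i)
      if (std::fabs(J[i * m + k]) > std::fabs(J[piv * m + k])) piv = i;
    if (std::fabs(J[piv * m + k]) < 1e-300) return false;
    if (piv != k) {
      for (int j = 0; j < m; ++j) std::swap(J[k * m + j], J[piv * m + j]);
      std::swap(r[k], r[piv]);
    }
    for (int i = k + 1; i < m; ++i) {
      double f = J[i * m + k] / J[k * m + k];
      for (int j = k; j < m; ++j) J[i * m + j] -= f * J[k * m + j];
      r[i] -= f * r[k];
    }
  }
  for (int i = m - 1; i >= 0; --i) {
    double s = r[i];
    for (int j = i + 1; j < m; ++j) s -= J[i * m + j] * r[j];
    r[i] = s / J[i * m + i];
  }
  return true;
}

// junction residuals: x = areas (parent, daughters...);
// parent outlet uses W+ = U + 4c, daughter inlets W- = U - 4c
static void junction_residual(const std::vector<double>& x,
                              const Vessel& vp,
                              const std::vector<const Vessel*>& vd,
                              double Wp, const std::vector<double>& Wd,
                              double rho, std::vector<double>& res) {
  int nd = vd.size();
  double Ap = x[0];
  double cp = wavespeed(vp, vp.A0[vp.n], Ap, rho);
  double Up = Wp - 4.0 * cp;
  double Pp = vp.beta / vp.A0[vp.n] *
              (std::sqrt(Ap) - std::sqrt(vp.A0[vp.n]));
  double mass = Ap * Up;
  for (int k = 0; k < nd; ++k) {
    double Ad = x[1 + k];
    double cd = wavespeed(*vd[k], vd[k]->A0[0], Ad, rho);
    double Ud = Wd[k] + 4.0 * cd;
    double Pd = vd[k]->beta / vd[k]->A0[0] *
                (std::sqrt(Ad) - std::sqrt(vd[k]->A0[0]));
    mass -= Ad * Ud;
    res[1 + k] = Pp + 0.5 * rho * Up * Up - Pd - 0.5 * rho * Ud * Ud;
  }
  res[0] = mass;
}

// Newton solve of a junction; returns achieved |sum Q| / max|Q|
static double solve_junction(Vessel& vp, std::vector<Vessel*>& vd,
                             double Wp, const std::vector<double>& Wd,
                             double rho, int jid) {
  int nd = vd.size();
  int m = 1 + nd;
  std::vector<double> x(m), res(m), res2(m), J(m * m), step(m);
  std::vector<const Vessel*> vdc(vd.begin(), vd.end());
  x[0] = vp.A[vp.n];
  for (int k = 0; k < nd; ++k) x[1 + k] = vd[k]->A[0];

  double pscale = 0.0;
  for (int k = 0; k < m; ++k) pscale = std::max(pscale, x[k]);

  bool ok = false;
  for (int it = 0; it < 50; ++it) {
    junction_residual(x, vp, vdc, Wp, Wd, rho, res);
    double rmax = 0.0;
    // scales: mass ~ A*c, pressure ~ rho c^2
    double c0 = wavespeed(vp, vp.A0[vp.n], x[0], rho);
    double ms = x[0] * c0, ps = rho * c0 * c0;
    rmax = std::fabs(res[0]) / ms;
    for (int k = 1; k < m; ++k)
      rmax = std::max(rmax, std::fabs(res[k]) / ps);
    if (rmax < 1e-13) { ok = true; break; }
    // numeric Jacobian
    for (int j = 0; j < m; ++j) {
      double h = 1e-7 * x[j];
      std::vector<double> xp = x; xp[j] += h;
      junction_residual(xp, vp, vdc, Wp, Wd, rho, res2);
      for (int i = 0; i < m; ++i) J[i * m + j] = (res2[i] - res[i]) / h;
    }
    step = res;
    if (!solve_lin(J, step, m)) break;
    for (int j = 0; j < m; ++j) {
      x[j] -= step[j];
      if (x[j] <= 0.0) x[j] = 0.1 * (x[j] + step[j]);  // keep positive
    }
  }
  if (!ok)
    stop("junction solver did not converge at junction of vessel index %d", jid);

  // write back states
  double cp = wavespeed(vp, vp.A0[vp.n], x[0], rho);
  double Up = Wp - 4.0 * cp;
  vp.A[vp.n] = x[0];
  vp.Q[vp.n] = x[0] * Up;
  double qmax = std::fabs(vp.Q[vp.n]), qsum = vp.Q[vp.n];
  for (int k = 0; k < nd; ++k) {
    double cd = wavespeed(*vd[k], vd[k]->A0[0], x[1 + k], rho);
    double Ud = Wd[k] + 4.0 * cd;
    vd[k]->A[0] = x[1 + k];
    vd[k]->Q[0] = x[1 + k] * Ud;
    qsum -= vd[k]->Q[0];
    qmax = std::max(qmax, std::fabs(vd[k]->Q[0]));
  }
  // relative residual; floor the scale so rest states (Q ~ 0) do not
  // inflate the ratio
  double qscale = std::max(qmax, 1e-3 * x[0] * cp);
  return std::fabs(qsum) / qscale;
}

// periodic linear interpolation of the inflow table
static inline double inflow_at(const NumericVector& tq,
                               const NumericVector& Qq, double RR,
                               double t) {
  double tt = t - RR * std::floor(t / RR);
  double dtq = tq[1] - tq[0];
  int i = (int)std::floor(tt / dtq);
  int n = tq.size();
  if (i >= n - 1) return Qq[n - 1];
  double w = (tt - tq[i]) / dtq;
  return (1.0 - w) * Qq[i] + w * Qq[i + 1];
}

// [[Rcpp::export(name = ".pw_solve")]]
List pw_solve(List vessels_in, IntegerVector junc_parent, List junc_daughters,
              List terminals_in, int root, NumericVector inflow_t,
              NumericVector inflow_Q, double RR, List sim,
              IntegerMatrix monitors, double P_init) {
  const double rho = as<double>(sim["blood_density"]);
  const double g = as<double>(sim["gravity"]);
  const double alpha = as<double>(sim["momentum_correction"]);
  const double Kr = as<double>(sim["friction_coefficient"]);
  const double cfl = as<double>(sim["cfl"]);
  const int max_beats = as<int>(sim["max_beats"]);
  const double tol = as<double>(sim["convergence_tol"]);
  const double rate = as<double>(sim["sample_rate"]);
  const double tilt = as<double>(sim["tilt_deg"]);
  const double geff = g * std::sin(tilt * M_PI / 180.0);

  int nv = vessels_in.size();
  std::vector<Vessel> V(nv);
  for (int v = 0; v < nv; ++v) {
    List vi = vessels_in[v];
    Vessel& w = V[v];
    w.n = as<int>(vi["n_cells"]);
    w.L = as<double>(vi["length"]);
    w.dx = w.L / w.n;
    w.beta = as<double>(vi["beta"]);
    w.Gamma = as<double>(vi["Gamma"]);
    w.sinphi = std::sin(as<double>(vi["phi"]) * M_PI / 180.0);
    w.z_prox = as<double>(vi["z_prox"]);
    double A0p = as<double>(vi["A0_prox"]), A0d = as<double>(vi["A0_dist"]);
    w.dA0dx = (A0d - A0p) / w.L;
    w.A0.resize(w.n + 1);
    w.A0h.resize(w.n);
    for (int i = 0; i <= w.n; ++i)
      w.A0[i] = A0p + (A0d - A0p) * (double)i / w.n;
    for (int i = 0; i < w.n; ++i)
      w.A0h[i] = A0p + (A0d - A0p) * (i + 0.5) / w.n;
    w.A.resize(w.n + 1);
    w.Q.assign(w.n + 1, 0.0);
    w.Ah.resize(w.n);
    w.Qh.resize(w.n);
    for (int i = 0; i <= w.n; ++i) {
      double z = w.z_prox + (w.L * i / w.n) * w.sinphi;
      double Ploc = P_init + rho * geff * z;
      double sa = std::sqrt(w.A0[i]) + Ploc * w.A0[i] / w.beta;
      if (sa <= 0) stop("initial pressure collapses vessel %d", v + 1);
      w.A[i] = sa * sa;
    }
  }

  int nj = junc_parent.size();
  std::vector<Junction> J(nj);
  for (int j = 0; j < nj; ++j) {
    J[j].parent = junc_parent[j] - 1;
    IntegerVector ds = junc_daughters[j];
    for (int k = 0; k < ds.size(); ++k)
      J[j].daughters.push_back(ds[k] - 1);
  }

  int nt = terminals_in.size();
  std::vector<Terminal> T(nt);
  for (int k = 0; k < nt; ++k) {
    List ti = terminals_in[k];
    T[k].vessel = as<int>(ti["vessel"]) - 1;
    T[k].R1 = as<double>(ti["R1"]);
    T[k].R2 = as<double>(ti["R2"]);
    T[k].C = as<double>(ti["C"]);
    T[k].Pout = as<double>(ti["Pout"]);
    Vessel& w = V[T[k].vessel];
    double zd = w.z_prox + w.L * w.sinphi;
    // initialize the Windkessel node at the local initial pressure
    T[k].Pc = P_init + rho * geff * zd;
  }

  int rooti = root - 1;
  int n_samp = (int)std::lround(RR * rate);
  if (n_samp < 64) stop("sample grid under 64 points per beat; raise sample_rate");

  // sample storage: per vessel, cells x samples, for P, Q, A
  std::vector<NumericMatrix> Ps(nv), Qs(nv), As(nv);
  std::vector<std::vector<double>> Pprev; // monitored cell series, previous beat
  for (int v = 0; v < nv; ++v) {
    Ps[v] = NumericMatrix(V[v].n, n_samp);
    Qs[v] = NumericMatrix(V[v].n, n_samp);
    As[v] = NumericMatrix(V[v].n, n_samp);
  }
  int nmon = monitors.nrow();
  Pprev.assign(nmon, std::vector<double>(n_samp, 0.0));
  NumericVector beat_change(max_beats, NA_REAL);

  double max_jres = 0.0;
  int beats_run = 0;
  bool converged = false;

  for (int beat = 0; beat < max_beats && !converged; ++beat) {
    double t = 0.0;
    int ksamp = 0;
    // record a sample (cell midpoints) at current state
    auto record = [&](int k) {
      for (int v = 0; v < nv; ++v) {
        Vessel& w = V[v];
        for (int e = 0; e < w.n; ++e) {
          double Am = 0.5 * (w.A[e] + w.A[e + 1]);
          double Qm = 0.5 * (w.Q[e] + w.Q[e + 1]);
          double Pm = 0.5 * (pressure(w, e, w.A[e]) +
                             pressure(w, e + 1, w.A[e + 1]));
          if (w.Gamma > 0) {
            // Voigt contribution via dA/dt = -dQ/dx at the midpoint
            double dQdx = (w.Q[e + 1] - w.Q[e]) / w.dx;
            Pm += w.Gamma / (w.A0h[e] * std::sqrt(Am)) * (-dQdx);
          }
          Ps[v](e, k) = Pm;
          Qs[v](e, k) = Qm;
          As[v](e, k) = Am;
        }
      }
    };
    record(ksamp++);

    while (ksamp <= n_samp) {
      // advective CFL limit plus, for visco-elastic walls, the explicit
      // diffusion limit of the Voigt source
      double dtc = 1e9, dtd = 1e9;
      for (int v = 0; v < nv; ++v) {
        Vessel& w = V[v];
        for (int i = 0; i <= w.n; ++i) {
          double c = wavespeed(w, w.A0[i], w.A[i], rho);
          double u = std::fabs(w.Q[i] / w.A[i]);
          dtc = std::min(dtc, w.dx / (u + c));
          if (w.Gamma > 0) {
            double D = w.Gamma * std::sqrt(w.A[i]) / (rho * w.A0[i]);
            dtd = std::min(dtd, 0.4 * w.dx * w.dx / D);
          }
        }
      }
      double dt = std::min(cfl * dtc, dtd);
      double t_target = (ksamp < n_samp) ? ksamp / rate : RR;
      if (t + dt >= t_target - 1e-12) dt = t_target - t;
      if (dt <= 0) stop("non-positive time step (CFL breakdown)");

      // half then full Lax-Wendroff step per vessel (interior nodes)
      for (int v = 0; v < nv; ++v) {
        Vessel& w = V[v];
        int n = w.n;
        for (int i = 0; i < n; ++i) {
          double F2l = flux2(w.Q[i], w.A[i], w.A0[i], w.beta, alpha, rho);
          double F2r = flux2(w.Q[i + 1], w.A[i + 1], w.A0[i + 1], w.beta,
                             alpha, rho);
          double S2l = source2(w, w.Q[i], w.A[i], w.A0[i], Kr, geff, rho);
          double S2r = source2(w, w.Q[i + 1], w.A[i + 1], w.A0[i + 1], Kr,
                               geff, rho);
          w.Ah[i] = 0.5 * (w.A[i] + w.A[i + 1]) -
                    dt / (2.0 * w.dx) * (w.Q[i + 1] - w.Q[i]);
          w.Qh[i] = 0.5 * (w.Q[i] + w.Q[i + 1]) -
                    dt / (2.0 * w.dx) * (F2r - F2l) +
                    0.25 * dt * (S2l + S2r);
          if (w.Ah[i] <= 0)
            stop("numerical-state error: A <= 0 in vessel %d (half step, beat %d, t=%g)",
                 v + 1, beat + 1, t);
        }
      }
      for (int v = 0; v < nv; ++v) {
        Vessel& w = V[v];
        int n = w.n;
        std::vector<double> Anew(w.A), Qnew(w.Q);
        for (int i = 1; i < n; ++i) {
          double F2l = flux2(w.Qh[i - 1], w.Ah[i - 1], w.A0h[i - 1], w.beta,
                             alpha, rho);
          double F2r = flux2(w.Qh[i], w.Ah[i], w.A0h[i], w.beta, alpha, rho);
          double S2l = source2(w, w.Qh[i - 1], w.Ah[i - 1], w.A0h[i - 1], Kr,
                               geff, rho);
          double S2r = source2(w, w.Qh[i], w.Ah[i], w.A0h[i], Kr, geff, rho);
          Anew[i] = w.A[i] - dt / w.dx * (w.Qh[i] - w.Qh[i - 1]);
          Qnew[i] = w.Q[i] - dt / w.dx * (F2r - F2l) +
                    0.5 * dt * (S2l + S2r);
          if (w.Gamma > 0 && i >= 1 && i <= n - 1) {
            // explicit Voigt diffusion source on momentum
            double gl = w.Gamma / (w.A0h[i - 1] * std::sqrt(w.Ah[i - 1])) *
                        (w.Q[i] - w.Q[i - 1]) / w.dx;
            double gr = w.Gamma / (w.A0h[i] * std::sqrt(w.Ah[i])) *
                        (w.Q[i + 1] - w.Q[i]) / w.dx;
            Qnew[i] += dt * (w.A[i] / rho) * (gr - gl) / w.dx;
          }
          if (Anew[i] <= 0)
            stop("numerical-state error: A <= 0 in vessel %d node %d (beat %d, t=%g)",
                 v + 1, i, beat + 1, t);
        }
        w.A.swap(Anew);
        w.Q.swap(Qnew);
        // after the swap Anew/Qnew hold the complete time-n state; keep
        // the boundary-adjacent values for the characteristic solves
        w.bA0n = Anew[0]; w.bQ0n = Qnew[0];
        w.bA1n = Anew[1]; w.bQ1n = Qnew[1];
        w.bAm1n = Anew[n - 1]; w.bQm1n = Qnew[n - 1];
        w.bAmn = Anew[n]; w.bQmn = Qnew[n];
      }

      double tnew = t + dt;

      // inlet boundary of root: prescribed flow + backward characteristic
      {
        Vessel& w = V[rooti];
        double Qin = inflow_at(inflow_t, inflow_Q, RR, tnew);
        double c0 = wavespeed(w, w.A0[0], w.bA0n, rho);
        double u0 = w.bQ0n / w.bA0n;
        double lam = u0 - c0; // negative
        double xi = std::min(1.0, std::fabs(lam) * dt / w.dx);
        double Wm0 = u0 - 4.0 * c0;
        double c1 = wavespeed(w, w.A0[1], w.bA1n, rho);
        double Wm1 = w.bQ1n / w.bA1n - 4.0 * c1;
        double Wm = (1.0 - xi) * Wm0 + xi * Wm1 +
                    dt * char_source(w, 0, w.bA0n, w.bQ0n, -1, Kr, geff, rho);
        double A = w.A[0];
        for (int it = 0; it < 60; ++it) {
          double c = wavespeed(w, w.A0[0], A, rho);
          double f = Qin / A - 4.0 * c - Wm;
          double fp = -Qin / (A * A) - c / A;
          double dA = f / fp;
          A -= dA;
          if (A <= 0) A = 0.5 * (A + dA);
          if (std::fabs(dA) < 1e-14 * A) break;
        }
        if (!(A > 0)) stop("inlet boundary produced non-positive area");
        w.A[0] = A;
        w.Q[0] = Qin;
      }

      // terminals
      for (int k = 0; k < nt; ++k) {
        Terminal& tm = T[k];
        Vessel& w = V[tm.vessel];
        int n = w.n;
        double zd = w.z_prox + w.L * w.sinphi;
        double Pout_eff = tm.Pout + rho * geff * zd;
        double cn = wavespeed(w, w.A0[n], w.bAmn, rho);
        double un = w.bQmn / w.bAmn;
        double lam = un + cn;
        double xi = std::min(1.0, std::max(0.0, lam) * dt / w.dx);
        double Wpn = un + 4.0 * cn;
        double cm = wavespeed(w, w.A0[n - 1], w.bAm1n, rho);
        double Wpm = w.bQm1n / w.bAm1n + 4.0 * cm;
        double Wp = (1.0 - xi) * Wpn + xi * Wpm +
                    dt * char_source(w, n, w.bAmn, w.bQmn, +1, Kr, geff, rho);

        double denom = (tm.C > 0) ? 1.0 + dt / (tm.R2 * tm.C) : 1.0;
        auto resid = [&](double A) {
          double c = wavespeed(w, w.A0[n], A, rho);
          double U = Wp - 4.0 * c;
          double Qb = U * A;
          double P = pressure(w, n, A);
          double Pc_new;
          if (tm.C > 0)
            Pc_new = (tm.Pc + dt / tm.C * (Qb + Pout_eff / tm.R2)) / denom;
          else
            Pc_new = Pout_eff + Qb * tm.R2;
          return P - Pc_new - Qb * tm.R1;
        };
        double A = w.A[n];
        for (int it = 0; it < 80; ++it) {
          double f = resid(A);
          double h = 1e-7 * A;
          double fp = (resid(A + h) - f) / h;
          double dA = f / fp;
          A -= dA;
          if (A <= 0) A = 0.5 * (A + dA);
          if (std::fabs(dA) < 1e-14 * A) break;
        }
        if (!(A > 0)) stop("terminal boundary produced non-positive area");
        double c = wavespeed(w, w.A0[n], A, rho);
        double U = Wp - 4.0 * c;
        w.A[n] = A;
        w.Q[n] = U * A;
        if (tm.C > 0)
          tm.Pc = (tm.Pc + dt / tm.C * (w.Q[n] + Pout_eff / tm.R2)) / denom;
        else
          tm.Pc = Pout_eff + w.Q[n] * tm.R2;
      }

      // junctions
      for (int j = 0; j < nj; ++j) {
        Vessel& vp = V[J[j].parent];
        int n = vp.n;
        double cn = wavespeed(vp, vp.A0[n], vp.bAmn, rho);
        double un = vp.bQmn / vp.bAmn;
        double xi = std::min(1.0, std::max(0.0, un + cn) * dt / vp.dx);
        double Wpn = un + 4.0 * cn;
        double cm = wavespeed(vp, vp.A0[n - 1], vp.bAm1n, rho);
        double Wpm = vp.bQm1n / vp.bAm1n + 4.0 * cm;
        double Wp = (1.0 - xi) * Wpn + xi * Wpm +
                    dt * char_source(vp, n, vp.bAmn, vp.bQmn, +1, Kr, geff, rho);

        std::vector<Vessel*> vd;
        std::vector<double> Wd;
        for (size_t k = 0; k < J[j].daughters.size(); ++k) {
          Vessel& w = V[J[j].daughters[k]];
          double c0 = wavespeed(w, w.A0[0], w.bA0n, rho);
          double u0 = w.bQ0n / w.bA0n;
          double xid = std::min(1.0, std::fabs(std::min(0.0, u0 - c0)) * dt / w.dx);
          double Wm0 = u0 - 4.0 * c0;
          double c1 = wavespeed(w, w.A0[1], w.bA1n, rho);
          double Wm1 = w.bQ1n / w.bA1n - 4.0 * c1;
          Wd.push_back((1.0 - xid) * Wm0 + xid * Wm1 +
                       dt * char_source(w, 0, w.bA0n, w.bQ0n, -1, Kr, geff, rho));
          vd.push_back(&w);
        }
        double r = solve_junction(vp, vd, Wp, Wd, rho, J[j].parent + 1);
        max_jres = std::max(max_jres, r);
      }

      t = tnew;
      if (std::fabs(t - t_target) < 1e-12 && ksamp < n_samp) {
        record(ksamp++);
      } else if (std::fabs(t - RR) < 1e-12 && ksamp == n_samp) {
        break; // beat complete (sample n_samp would alias sample 0 of next)
      }
      if (t >= RR - 1e-12) break;
    }

    // convergence on monitored cells
    double chg = 0.0;
    for (int m = 0; m < nmon; ++m) {
      int v = monitors(m, 0) - 1, e = monitors(m, 1) - 1;
      double num = 0.0, den = 0.0;
      for (int k = 0; k < n_samp; ++k) {
        double d = Ps[v](e, k) - Pprev[m][k];
        num += d * d;
        den += Pprev[m][k] * Pprev[m][k];
      }
      double rel = (beat == 0 || den == 0) ? 1.0 : std::sqrt(num / den);
      chg = std::max(chg, rel);
      for (int k = 0; k < n_samp; ++k) Pprev[m][k] = Ps[v](e, k);
    }
    beat_change[beat] = chg;
    beats_run = beat + 1;
    if (beat > 0 && chg < tol) converged = true;
    Rcpp::checkUserInterrupt();
  }

  NumericVector tgrid(n_samp);
  for (int k = 0; k < n_samp; ++k) tgrid[k] = k / rate;

  List PV(nv), QV(nv), AV(nv);
  for (int v = 0; v < nv; ++v) {
    PV[v] = Ps[v]; QV[v] = Qs[v]; AV[v] = As[v];
  }
  return List::create(
    _["t"] = tgrid, _["P"] = PV, _["Q"] = QV, _["A"] = AV,
    _["beats_run"] = beats_run,
    _["beat_change"] = beat_change[Range(0, beats_run - 1)],
    _["converged"] = converged,
    _["max_junction_residual"] = max_jres);
}

// Standalone junction matching for testing: given parent/daughter tube
// parameters and incoming characteristic information, return the coupled
// boundary state.
// [[Rcpp::export(name = ".pw_junction_match")]]
List pw_junction_match(List parent, List daughters, double rho) {
  // parent: list(beta, A0, W) with W = U + 4c (outgoing at outlet)
  // daughters: list of list(beta, A0, W) with W = U - 4c (outgoing at inlet)
  Vessel vp;
  vp.n = 1;
  vp.beta = as<double>(parent["beta"]);
  vp.A0.assign(2, as<double>(parent["A0"]));
  vp.A.assign(2, as<double>(parent["A0"]));
  vp.Q.assign(2, 0.0);
  vp.dA0dx = 0; vp.sinphi = 0; vp.z_prox = 0; vp.Gamma = 0;
  vp.L = 1; vp.dx = 1;
  double Wp = as<double>(parent["W"]);

  int nd = daughters.size();
  std::vector<Vessel> vds(nd);
  std::vector<Vessel*> vd(nd);
  std::vector<double> Wd(nd);
  for (int k = 0; k < nd; ++k) {
    List dk = daughters[k];
    vds[k].n = 1;
    vds[k].beta = as<double>(dk["beta"]);
    vds[k].A0.assign(2, as<double>(dk["A0"]));
    vds[k].A.assign(2, as<double>(dk["A0"]));
    vds[k].Q.assign(2, 0.0);
    vds[k].dA0dx = 0; vds[k].sinphi = 0; vds[k].z_prox = 0; vds[k].Gamma = 0;
    vds[k].L = 1; vds[k].dx = 1;
    Wd[k] = as<double>(dk["W"]);
    vd[k] = &vds[k];
  }
  double r = solve_junction(vp, vd, Wp, Wd, rho, 0);
  NumericVector Ad(nd), Qd(nd), Pd(nd);
  for (int k = 0; k < nd; ++k) {
    Ad[k] = vds[k].A[0];
    Qd[k] = vds[k].Q[0];
    Pd[k] = vds[k].beta / vds[k].A0[0] *
            (std::sqrt(Ad[k]) - std::sqrt(vds[k].A0[0]));
  }
  return List::create(
    _["A_parent"] = vp.A[vp.n], _["Q_parent"] = vp.Q[vp.n],
    _["P_parent"] = vp.beta / vp.A0[1] *
                    (std::sqrt(vp.A[vp.n]) - std::sqrt(vp.A0[1])),
    _["A_daughters"] = Ad, _["Q_daughters"] = Qd, _["P_daughters"] = Pd,
    _["mass_residual"] = r);
}
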