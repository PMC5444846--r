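// Fully implicit moving-mesh finite-difference integrator for the radially
// symmetric free-boundary tumor model (9 species on 0 <= r <= R(t)).
//
// Species order (fixed, mirrored by .species_names() on the R side):
//   0 D, 1 T1, 2 T8, 3 C, 4 G, 5 I12, 6 I2, 7 P, 8 A
// D, T1, T8, C, P are advected with the common cell velocity u and diffuse;
// G, I12, I2, A diffuse only.  The velocity closure is
//   theta_tot * div(u) = sum of the four cell-species reaction terms,
// so u(r) = (1/(theta_tot r^2)) * int_0^r s^2 S(s) ds, u(0) = 0.
//
// Each time step runs a Picard loop: reaction coefficients, velocity and mesh
// iterate are refreshed from the current iterate, one tridiagonal solve per
// species (reaction split as  a - b*X  with a from the lagged iterate and the
// X-proportional part implicit).  Nodes then move by r <- r + u*tau and the
// boundary by R' = u(R).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

static const int NSP = 9;
enum Sp { iD = 0, iT1, iT8, iC, iG, iI12, iI2, iP, iA };

struct Par {
  double delta[NSP];          // diffusion coefficients per species
  double sigma0;
  double lamDC, lamDG, lamT1I12, lamT1I2, lamT8I12, lamT8I2, lamC;
  double lamG, lamI12D, lamI2T1;
  double eta1, eta8, muPA;
  double rhoL, eps;
  double dD, dT1, dT8, dC, dG, dI12, dI2, dA;
  double KG, KC, KI12, KI2, KpTQ;
  double D0, T10, T80, CM;
  double That1, That8, theta;
  double tcell_floor;
};

static Par parse_par(const List& p) {
  Par q;
  q.delta[iD]   = as<double>(p["delta_D"]);
  q.delta[iT1]  = as<double>(p["delta_T"]);
  q.delta[iT8]  = as<double>(p["delta_T"]);
  q.delta[iC]   = as<double>(p["delta_C"]);
  q.delta[iG]   = as<double>(p["delta_G"]);
  q.delta[iI12] = as<double>(p["delta_I12"]);
  q.delta[iI2]  = as<double>(p["delta_I2"]);
  q.delta[iP]   = as<double>(p["delta_T"]);   // PD-1 rides on T cells
  q.delta[iA]   = as<double>(p["delta_A"]);
  q.sigma0   = as<double>(p["sigma0"]);
  q.lamDC    = as<double>(p["lambda_DC"]);
  q.lamDG    = as<double>(p["lambda_DG"]);
  q.lamT1I12 = as<double>(p["lambda_T1I12"]);
  q.lamT1I2  = as<double>(p["lambda_T1I2"]);
  q.lamT8I12 = as<double>(p["lambda_T8I12"]);
  q.lamT8I2  = as<double>(p["lambda_T8I2"]);
  q.lamC     = as<double>(p["lambda_C"]);
  q.lamG     = as<double>(p["lambda_G"]);
  q.lamI12D  = as<double>(p["lambda_I12D"]);
  q.lamI2T1  = as<double>(p["lambda_I2T1"]);
  q.eta1     = as<double>(p["eta1"]);
  q.eta8     = as<double>(p["eta8"]);
  q.muPA     = as<double>(p["mu_PA"]);
  q.rhoL     = as<double>(p["rho_L"]);
  q.eps      = as<double>(p["epsilon"]);
  q.dD   = as<double>(p["d_D"]);
  q.dT1  = as<double>(p["d_T1"]);
  q.dT8  = as<double>(p["d_T8"]);
  q.dC   = as<double>(p["d_C"]);
  q.dG   = as<double>(p["d_G"]);
  q.dI12 = as<double>(p["d_I12"]);
  q.dI2  = as<double>(p["d_I2"]);
  q.dA   = as<double>(p["d_A"]);
  q.KG   = as<double>(p["K_G"]);
  q.KC   = as<double>(p["K_C"]);
  q.KI12 = as<double>(p["K_I12"]);
  q.KI2  = as<double>(p["K_I2"]);
  q.KpTQ = as<double>(p["Kp_TQ"]);
  q.D0   = as<double>(p["D_0"]);
  q.T10  = as<double>(p["T_10"]);
  q.T80  = as<double>(p["T_80"]);
  q.CM   = as<double>(p["C_M"]);
  q.That1 = as<double>(p["That_1"]);
  q.That8 = as<double>(p["That_8"]);
  q.theta = as<double>(p["theta_tot"]);
  q.tcell_floor = as<double>(p["tcell_floor"]);
  return q;
}

// piecewise dosing source: gamma on [0, t_stop], linear ramp to 0 on
// (t_stop, t_zero], 0 afterwards
static double dose_source(double t, double gamma, double t_stop, double t_zero) {
  if (t <= t_stop) return gamma;
  if (t <= t_zero) return gamma * (t_zero - t) / (t_zero - t_stop);
  return 0.0;
}

typedef std::vector<double> dvec;

// reaction split X' = a - b*X per species, plus the cell-rate sum S used by
// the velocity closure; everything evaluated at the supplied (Picard) iterate
static void reaction_ab(const std::vector<dvec>& X, double t, const Par& q,
                        double gG, double gA, double t_stop, double t_zero,
                        std::vector<dvec>& a, std::vector<dvec>& b, dvec& S) {
  const size_t n = X[0].size();
  const double Ghat = dose_source(t, gG, t_stop, t_zero);
  const double Ahat = dose_source(t, gA, t_stop, t_zero);
  for (size_t i = 0; i < n; ++i) {
    const double D = X[iD][i], T1 = X[iT1][i], T8 = X[iT8][i], C = X[iC][i];
    const double G = X[iG][i], I12 = X[iI12][i], I2 = X[iI2][i];
    const double P = X[iP][i], A = X[iA][i];
    const double fG  = G / (q.KG + G);
    const double fC  = C / (q.KC + C);
    const double f12 = I12 / (q.KI12 + I12);
    const double f2  = I2 / (q.KI2 + I2);
    const double L   = q.rhoL * (T1 + T8 + q.eps * C);
    const double inhib = 1.0 / (1.0 + P * L / q.KpTQ);

    a[iD][i] = q.lamDC * q.D0 * fC + q.lamDG * q.D0 * fG;
    b[iD][i] = q.dD;
    a[iT1][i] = q.lamT1I12 * q.T10 * f12 * inhib;
    b[iT1][i] = q.dT1 - q.lamT1I2 * f2 * inhib;
    a[iT8][i] = q.lamT8I12 * q.T80 * f12 * inhib;
    b[iT8][i] = q.dT8 - q.lamT8I2 * f2 * inhib;
    a[iC][i] = 0.0;
    b[iC][i] = q.dC + q.eta1 * T1 + q.eta8 * T8 - q.lamC * (1.0 - C / q.CM);
    a[iG][i] = q.lamG + Ghat;
    b[iG][i] = q.dG;
    a[iI12][i] = q.lamI12D * D;
    b[iI12][i] = q.dI12;
    a[iI2][i] = q.lamI2T1 * T1;
    b[iI2][i] = q.dI2;
    const double Tsum = T1 + T8;
    a[iP][i] = 0.0;
    if (Tsum > q.tcell_floor) {
      const double prodT = ((q.lamT1I12 * q.T10 + q.lamT8I12 * q.T80) * f12 +
                            (q.lamT1I2 * T1 + q.lamT8I2 * T8) * f2) * inhib;
      b[iP][i] = (q.dT1 * T1 + q.dT8 * T8 - prodT) / Tsum + q.muPA * A;
    } else {
      // PD-1 lives on T cells: no T cells, no production, bounded decay
      b[iP][i] = q.muPA * A + std::max(q.dT1, q.dT8);
    }
    a[iA][i] = Ahat;
    b[iA][i] = q.muPA * P + q.dA;

    S[i] = (a[iD][i] - b[iD][i] * D) + (a[iT1][i] - b[iT1][i] * T1) +
           (a[iT8][i] - b[iT8][i] * T8) + (a[iC][i] - b[iC][i] * C);
  }
}

// u(r_i) from the cumulative integral of s^2 S(s), with S piecewise linear
// integrated exactly (plain trapezoid on s^2 S misses the s^2 curvature near
// the origin and over-drives the dilution there); u(0) = 0
static void velocity_from_S(const dvec& r, const dvec& S, double theta, dvec& u) {
  const size_t n = r.size();
  u[0] = 0.0;
  double acc = 0.0;
  for (size_t i = 1; i < n; ++i) {
    const double ra = r[i - 1], rb = r[i], h = rb - ra;
    const double i3 = (rb * rb * rb - ra * ra * ra) / 3.0;
    const double i4 = (rb * rb * rb * rb - ra * ra * ra * ra) / 4.0;
    acc += S[i - 1] * i3 + (S[i] - S[i - 1]) / h * (i4 - ra * i3);
    u[i] = acc / (theta * r[i] * r[i]);
  }
}

// Thomas algorithm, overwrites rhs with the solution
static void thomas(dvec& sub, dvec& diag, dvec& sup, dvec& rhs) {
  const size_t n = diag.size();
  for (size_t i = 1; i < n; ++i) {
    const double w = sub[i] / diag[i - 1];
    diag[i] -= w * sup[i - 1];
    rhs[i] -= w * rhs[i - 1];
  }
  rhs[n - 1] /= diag[n - 1];
  for (size_t i = n - 1; i-- > 0;)
    rhs[i] = (rhs[i] - sup[i] * rhs[i + 1]) / diag[i];
}

// Fritsch-Carlson monotone cubic interpolation (used when remeshing)
static void pchip(const dvec& x, const dvec& y, const dvec& xo, dvec& yo) {
  const size_t n = x.size();
  dvec h(n - 1), d(n - 1), m(n);
  for (size_t i = 0; i + 1 < n; ++i) {
    h[i] = x[i + 1] - x[i];
    d[i] = (y[i + 1] - y[i]) / h[i];
  }
  m[0] = d[0];
  m[n - 1] = d[n - 2];
  for (size_t i = 1; i + 1 < n; ++i) {
    if (d[i - 1] * d[i] <= 0.0) {
      m[i] = 0.0;
    } else {
      const double w1 = 2.0 * h[i] + h[i - 1];
      const double w2 = h[i] + 2.0 * h[i - 1];
      m[i] = (w1 + w2) / (w1 / d[i - 1] + w2 / d[i]);
    }
  }
  size_t k = 0;
  for (size_t j = 0; j < xo.size(); ++j) {
    const double xx = std::min(std::max(xo[j], x[0]), x[n - 1]);
    while (k + 2 < n && x[k + 1] < xx) ++k;
    const double tt = (xx - x[k]) / h[k];
    const double t2 = tt * tt, t3 = t2 * tt;
    yo[j] = (2 * t3 - 3 * t2 + 1) * y[k] + (t3 - 2 * t2 + tt) * h[k] * m[k] +
            (-2 * t3 + 3 * t2) * y[k + 1] + (t3 - t2) * h[k] * m[k + 1];
  }
}

struct StepStats {
  long picard_iters = 0;
  long steps = 0;
  long clips = 0;
  long remeshes = 0;
  long halvings = 0;
};

// one implicit step of size tau starting at time t; returns false on Picard
// failure or severe negativity (caller halves tau)
static bool picard_step(std::vector<dvec>& X, dvec& r, double t, double tau,
                        const Par& q, double gG, double gA, double t_stop,
                        double t_zero, double tol, int maxit, StepStats& st) {
  const size_t n = r.size();
  std::vector<dvec> Xit = X, Xnew(NSP, dvec(n));
  std::vector<dvec> a(NSP, dvec(n)), b(NSP, dvec(n));
  dvec S(n), u(n), ur(n), rit(n);
  dvec sub(n), diag(n), sup(n), rhs(n);
  const double tnew = t + tau;
  bool converged = false;

  for (int m = 0; m < maxit; ++m) {
    st.picard_iters++;
    reaction_ab(Xit, tnew, q, gG, gA, t_stop, t_zero, a, b, S);
    velocity_from_S(r, S, q.theta, u);
    for (size_t i = 0; i < n; ++i) rit[i] = r[i] + u[i] * tau;
    // du/dr on the iterate mesh (nonuniform central; one-sided at ends)
    ur[0] = u[1] / rit[1];
    for (size_t i = 1; i + 1 < n; ++i) {
      const double hm = rit[i] - rit[i - 1], hp = rit[i + 1] - rit[i];
      const double den = hp * hm * (hp + hm);
      ur[i] = (hm * hm * u[i + 1] - hp * hp * u[i - 1] +
               (hp * hp - hm * hm) * u[i]) / den;
    }
    ur[n - 1] = (u[n - 1] - u[n - 2]) / (rit[n - 1] - rit[n - 2]);
    // boundary flux coefficient for the T-cell Robin condition
    const double I12b = Xit[iI12][n - 1];
    const double sigT = q.sigma0 * I12b / (I12b + q.KI12);

    for (int s = 0; s < NSP; ++s) {
      const bool adv = (s == iD || s == iT1 || s == iT8 || s == iC || s == iP);
      const double del = q.delta[s];
      // r = 0: symmetry, laplacian -> 3 * X_rr with ghost mirror node
      {
        const double h1 = rit[1] - rit[0];
        const double adv0 = adv ? 3.0 * ur[0] : 0.0;
        diag[0] = 1.0 / tau + b[s][0] + adv0 + 6.0 * del / (h1 * h1);
        sup[0] = -6.0 * del / (h1 * h1);
        sub[0] = 0.0;
        rhs[0] = X[s][0] / tau + a[s][0];
      }
      for (size_t i = 1; i + 1 < n; ++i) {
        const double hm = rit[i] - rit[i - 1], hp = rit[i + 1] - rit[i];
        const double den = hp * hm * (hp + hm);
        const double dr_m = -hp * hp / den, dr_p = hm * hm / den;
        const double dr_0 = (hp * hp - hm * hm) / den;
        const double drr_m = 2.0 * hp / den, drr_p = 2.0 * hm / den;
        const double drr_0 = -2.0 * (hp + hm) / den;
        const double ri = rit[i];
        sub[i]  = -del * (drr_m + (2.0 / ri) * dr_m);
        diag[i] = 1.0 / tau + b[s][i] - del * (drr_0 + (2.0 / ri) * dr_0);
        sup[i]  = -del * (drr_p + (2.0 / ri) * dr_p);
        if (adv) {
          sub[i]  += u[i] * dr_m;
          diag[i] += (2.0 * u[i] / ri + ur[i]) + u[i] * dr_0;
          sup[i]  += u[i] * dr_p;
        }
        rhs[i] = X[s][i] / tau + a[s][i];
      }
      // r = R: ghost node, second-order one-sided via centered stencil
      {
        const size_t N = n - 1;
        const double h = rit[N] - rit[N - 1];
        const double rb = rit[N];
        const double advN = adv ? (2.0 * u[N] / rb + ur[N]) : 0.0;
        sub[N] = -2.0 * del / (h * h);
        diag[N] = 1.0 / tau + b[s][N] + advN + 2.0 * del / (h * h);
        sup[N] = 0.0;
        rhs[N] = X[s][N] / tau + a[s][N];
        if (s == iT1 || s == iT8) {
          // Robin influx of naive T cells: dX/dr = -sigT (X - That)
          const double That = (s == iT1) ? q.That1 : q.That8;
          diag[N] += 2.0 * del * sigT / h + 2.0 * del * sigT / rb;
          rhs[N]  += (2.0 * del * sigT / h + 2.0 * del * sigT / rb) * That;
          if (adv) {
            diag[N] += -u[N] * sigT;
            rhs[N]  += -u[N] * sigT * That;
          }
        }
      }
      thomas(sub, diag, sup, rhs);
      for (size_t i = 0; i < n; ++i) Xnew[s][i] = rhs[i];
    }
    // positivity: clip round-off negatives, fail on anything worse
    for (int s = 0; s < NSP; ++s) {
      for (size_t i = 0; i < n; ++i) {
        if (Xnew[s][i] < 0.0) {
          if (Xnew[s][i] < -1e-12) return false;
          Xnew[s][i] = 0.0;
          st.clips++;
        }
      }
    }
    double relchg = 0.0;
    for (int s = 0; s < NSP; ++s) {
      double scale = 0.0;
      for (size_t i = 0; i < n; ++i) scale = std::max(scale, std::fabs(Xnew[s][i]));
      if (scale <= 0.0) continue;
      for (size_t i = 0; i < n; ++i)
        relchg = std::max(relchg, std::fabs(Xnew[s][i] - Xit[s][i]) / scale);
    }
    Xit = Xnew;
    if (relchg < tol) { converged = true; break; }
  }
  if (!converged) return false;
  // mesh must stay strictly increasing after the move
  for (size_t i = 1; i < n; ++i)
    if (rit[i] <= rit[i - 1]) return false;
  X = Xit;
  r = rit;
  return true;
}

// advance by tau with up to `depth` recursive halvings on failure
static bool advance(std::vector<dvec>& X, dvec& r, double t, double tau,
                    const Par& q, double gG, double gA, double t_stop,
                    double t_zero, double tol, int maxit, int depth,
                    StepStats& st) {
  if (picard_step(X, r, t, tau, q, gG, gA, t_stop, t_zero, tol, maxit, st)) {
    st.steps++;
    return true;
  }
  if (depth <= 0) return false;
  st.halvings++;
  return advance(X, r, t, tau / 2, q, gG, gA, t_stop, t_zero, tol, maxit,
                 depth - 1, st) &&
         advance(X, r, t + tau / 2, tau / 2, q, gG, gA, t_stop, t_zero, tol,
                 maxit, depth - 1, st);
}

static void remesh_uniform(std::vector<dvec>& X, dvec& r, StepStats& st) {
  const size_t n = r.size();
  dvec rn(n);
  const double R = r[n - 1];
  for (size_t i = 0; i < n; ++i) rn[i] = R * double(i) / double(n - 1);
  dvec yo(n);
  for (int s = 0; s < NSP; ++s) {
    pchip(r, X[s], rn, yo);
    X[s] = yo;
  }
  r = rn;
  st.remeshes++;
}

static double trapz_avg(const dvec& r, const dvec& x) {
  double num = 0.0, den = 0.0;
  for (size_t i = 1; i < r.size(); ++i) {
    const double dr = r[i] - r[i - 1];
    num += 0.5 * (x[i] * r[i] * r[i] + x[i - 1] * r[i - 1] * r[i - 1]) * dr;
    den += 0.5 * (r[i] * r[i] + r[i - 1] * r[i - 1]) * dr;
  }
  return num / den;
}

// [[Rcpp::export(name = ".run_sim_cpp")]]
List run_sim_cpp(List par, double gamma_G, double gamma_A, double t_stop,
                 double t_zero, NumericVector r0, NumericMatrix X0, double t0,
                 double t_end, double tau, double out_every, double picard_tol,
                 int picard_max, double remesh_ratio, int max_halvings,
                 double r_elim) {
  const Par q = parse_par(par);
  const size_t n = r0.size();
  if ((size_t)X0.nrow() != n || X0.ncol() != NSP)
    stop("initial state must be length(r0) x 9");
  std::vector<dvec> X(NSP, dvec(n));
  dvec r(n);
  for (size_t i = 0; i < n; ++i) {
    r[i] = r0[i];
    for (int s = 0; s < NSP; ++s) X[s][i] = X0(i, s);
  }
  const long nsteps = (long)std::llround((t_end - t0) / tau);
  if (nsteps < 0) stop("t_end must be >= t0");
  const long stride = std::max(1L, (long)std::llround(out_every / tau));
  StepStats st;

  std::vector<double> otime, orad, ocons;
  std::vector<std::array<double, NSP> > oavg;
  double max_cons = 0.0;
  auto record = [&](double t) {
    otime.push_back(t);
    orad.push_back(r[n - 1]);
    std::array<double, NSP> av;
    for (int s = 0; s < NSP; ++s) av[s] = trapz_avg(r, X[s]);
    oavg.push_back(av);
    double cd = 0.0;
    for (size_t i = 0; i < n; ++i) {
      const double sum = X[iD][i] + X[iT1][i] + X[iT8][i] + X[iC][i];
      cd = std::max(cd, std::fabs(sum - q.theta) / q.theta);
    }
    ocons.push_back(cd);
    max_cons = std::max(max_cons, cd);
  };
  record(t0);

  // once the free boundary falls below r_elim the tumor is treated as
  // eliminated: the state is frozen and only the output schedule continues
  bool eliminated = (r[n - 1] <= r_elim);
  for (long k = 0; k < nsteps; ++k) {
    const double t = t0 + k * tau;
    if (!eliminated) {
      if (!advance(X, r, t, tau, q, gamma_G, gamma_A, t_stop, t_zero,
                   picard_tol, picard_max, max_halvings, st)) {
        // non-convergence during terminal collapse of the free boundary is
        // the elimination endgame; anywhere else it is a hard failure
        if (r_elim > 0 && r[n - 1] <= 2.0 * r_elim) {
          eliminated = true;
        } else {
          stop("solver failed at t = %g (Picard non-convergence or negative "
               "state after %d step halvings)", t, max_halvings);
        }
      }
      // guard against node crowding from the mesh motion
      double hmin = 1e300, hmax = 0.0;
      for (size_t i = 1; i < n; ++i) {
        const double h = r[i] - r[i - 1];
        hmin = std::min(hmin, h);
        hmax = std::max(hmax, h);
      }
      if (hmax / hmin > remesh_ratio) remesh_uniform(X, r, st);
      if (r[n - 1] <= r_elim) eliminated = true;
    }
    if ((k + 1) % stride == 0 || k + 1 == nsteps) record(t0 + (k + 1) * tau);
  }

  const size_t nt = otime.size();
  NumericMatrix avg(nt, NSP);
  NumericVector tv(nt), Rv(nt), cons(nt);
  for (size_t j = 0; j < nt; ++j) {
    tv[j] = otime[j];
    Rv[j] = orad[j];
    cons[j] = ocons[j];
    for (int s = 0; s < NSP; ++s) avg(j, s) = oavg[j][s];
  }
  NumericMatrix Xf(n, NSP);
  NumericVector rf(n);
  for (size_t i = 0; i < n; ++i) {
    rf[i] = r[i];
    for (int s = 0; s < NSP; ++s) Xf(i, s) = X[s][i];
  }
  return List::create(
      _["time"] = tv, _["radius"] = Rv, _["avg"] = avg, _["cons_dev"] = cons,
      _["r_final"] = rf, _["X_final"] = Xf, _["max_cons_dev"] = max_cons,
      _["picard_iters"] = (double)st.picard_iters,
      _["steps"] = (double)st.steps, _["clips"] = (double)st.clips,
      _["remeshes"] = (double)st.remeshes,
      _["halvings"] = (double)st.halvings, _["eliminated"] = eliminated);
}

// reaction terms alone, for cross-checking against the R-level reaction_rhs
// [[Rcpp::export(name = ".reaction_cpp")]]
NumericMatrix reaction_cpp(List par, NumericMatrix X0, double t, double gamma_G,
                           double gamma_A, double t_stop, double t_zero) {
  const Par q = parse_par(par);
  const size_t n = X0.nrow();
  std::vector<dvec> X(NSP, dvec(n));
  for (size_t i = 0; i < n; ++i)
    for (int s = 0; s < NSP; ++s) X[s][i] = X0(i, s);
  std::vector<dvec> a(NSP, dvec(n)), b(NSP, dvec(n));
  dvec S(n);
  reaction_ab(X, t, q, gamma_G, gamma_A, t_stop, t_zero, a, b, S);
  NumericMatrix out(n, NSP);
  for (size_t i = 0; i < n; ++i)
    for (int s = 0; s < NSP; ++s) out(i, s) = a[s][i] - b[s][i] * X[s][i];
  return out;
}
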