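// Implicit finite-volume time steppers for the 1-D spherical bioheat and
// drug-transport problems. All geometry/coefficient bookkeeping happens on
// the R side; these routines march the (tri)diagonal systems.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Solve a tridiagonal system in place (Thomas algorithm).
// lower[i] couples row i to i-1 (i = 1..n-1), upper[i] couples row i to i+1.
static void thomas(std::vector<double>& lower, std::vector<double>& diag,
                   std::vector<double>& upper, std::vector<double>& rhs,
                   std::vector<double>& x) {
  const int n = diag.size();
  std::vector<double> cp(n), dp(n);
  cp[0] = upper[0] / diag[0];
  dp[0] = rhs[0] / diag[0];
  for (int i = 1; i < n; ++i) {
    const double m = diag[i] - lower[i] * cp[i - 1];
    cp[i] = upper[i] / m;
    dp[i] = (rhs[i] - lower[i] * dp[i - 1]) / m;
  }
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
}

// [[Rcpp::export(name = ".cpp_thomas")]]
NumericVector cpp_thomas(NumericVector lower, NumericVector diag,
                         NumericVector upper, NumericVector rhs) {
  const int n = diag.size();
  std::vector<double> a(lower.begin(), lower.end()),
      b(diag.begin(), diag.end()), c(upper.begin(), upper.end()),
      d(rhs.begin(), rhs.end()), x(n);
  thomas(a, b, c, d, x);
  return NumericVector(x.begin(), x.end());
}

// Backward-Euler march of the Pennes bioheat equation.
//   rhoC_i V_i dT/dt = sum_f G_f (T_nb - T_i) + beta_i V_i (Tb - T_i) + q_i V_i
// with zero flux at r = 0 and Dirichlet T = t_boundary at the outer node.
// G (length N-1) are face conductances A_f k_f / dr_f.
// Returns temperatures recorded every `record_every` steps (including the
// initial state as the first row).
// [[Rcpp::export(name = ".cpp_bioheat_march")]]
NumericMatrix cpp_bioheat_march(NumericVector T0, NumericVector G,
                                NumericVector rhoC_V, NumericVector beta_V,
                                NumericVector q_V, double Tb,
                                double t_boundary, double dt, int nsteps,
                                int record_every) {
  const int n = T0.size();
  std::vector<double> lower(n), diag(n), upper(n), rhs(n), T(T0.begin(), T0.end()), x(n);
  // constant matrix
  for (int i = 0; i < n; ++i) {
    lower[i] = 0.0; upper[i] = 0.0;
    diag[i] = rhoC_V[i] / dt + beta_V[i];
    if (i > 0)     { lower[i] = -G[i - 1]; diag[i] += G[i - 1]; }
    if (i < n - 1) { upper[i] = -G[i];     diag[i] += G[i]; }
  }
  // Dirichlet outer node
  lower[n - 1] = 0.0; upper[n - 1] = 0.0; diag[n - 1] = 1.0;

  const int nrec = nsteps / record_every + 1;
  NumericMatrix out(nrec, n);
  for (int j = 0; j < n; ++j) out(0, j) = T[j];
  int rec = 1;
  for (int s = 1; s <= nsteps; ++s) {
    for (int i = 0; i < n - 1; ++i)
      rhs[i] = rhoC_V[i] / dt * T[i] + beta_V[i] * Tb + q_V[i];
    rhs[n - 1] = t_boundary;
    thomas(lower, diag, upper, rhs, x);
    T = x;
    if (s % record_every == 0 && rec < nrec) {
      for (int j = 0; j < n; ++j) out(rec, j) = T[j];
      ++rec;
    }
  }
  return out;
}

// Steady Pennes solution: solve the same system without the mass term.
// [[Rcpp::export(name = ".cpp_bioheat_steady")]]
NumericVector cpp_bioheat_steady(NumericVector G, NumericVector beta_V,
                                 NumericVector q_V, double Tb,
                                 double t_boundary) {
  const int n = beta_V.size();
  std::vector<double> lower(n), diag(n), upper(n), rhs(n), x(n);
  for (int i = 0; i < n; ++i) {
    lower[i] = 0.0; upper[i] = 0.0;
    diag[i] = beta_V[i];
    if (i > 0)     { lower[i] = -G[i - 1]; diag[i] += G[i - 1]; }
    if (i < n - 1) { upper[i] = -G[i];     diag[i] += G[i]; }
    rhs[i] = beta_V[i] * Tb + q_V[i];
  }
  lower[n - 1] = 0.0; upper[n - 1] = 0.0; diag[n - 1] = 1.0;
  rhs[n - 1] = t_boundary;
  thomas(lower, diag, upper, rhs, x);
  return NumericVector(x.begin(), x.end());
}

struct ReactionRates {
  // per-node constant coefficients
  const double *kon, *koff, *kint;      // binding/internalization (1/s)
  const double *exLa, *exLl;            // carrier exchange: + exLa*Cp - exLl*CL
  const double *exFa, *exFl;            // free-drug exchange
};

// Local kinetics RHS at one node. KEL and Cp are time-interpolated outside.
static inline void local_rhs(double CL, double CF, double CB,
                             double kel, double cp,
                             const ReactionRates& rr, int i,
                             double& dCL, double& dCF, double& dCB,
                             double& dCI) {
  const double release = kel * CL;
  const double bind = rr.kon[i] * CF - rr.koff[i] * CB;
  dCL = -release + rr.exLa[i] * cp - rr.exLl[i] * CL;
  dCF = release + rr.exFa[i] * cp - rr.exFl[i] * CF - bind;
  dCB = bind - rr.kint[i] * CB;
  dCI = rr.kint[i] * CB;
}

// Coupled carrier/free/bound/internalized transport march.
// Operator splitting per step: (1) local kinetics + transvascular exchange,
// integrated with RK4 substeps and exact time dependence of the plasma
// forcing and the release-rate field; (2) implicit upwind
// convection-diffusion for the mobile species (CL, CF).
//
// args (List):
//  dt, nsteps, nsub, t0
//  volume (N), G_L, G_F (face conductances for each mobile species, N-1)
//  conv (face convective coefficient A_f * u_f, N-1)
//  mobileL (bool: carrier present/mobile)
//  kon, koff, kint, exLa, exLl, exFa, exFl (N)
//  cp0, kd  (plasma forcing of the exchanging species)
//  kel_times (nt), kel_mat (nt x N)  release rate field vs time (0 outside)
//  w_tumor (N) volume weights for the recorded tumor averages
//  record_every, snapshot_steps (integer vector of step indices)
// [[Rcpp::export(name = ".cpp_transport_march")]]
List cpp_transport_march(List args) {
  const double dt = as<double>(args["dt"]);
  const int nsteps = as<int>(args["nsteps"]);
  const int nsub = as<int>(args["nsub"]);
  const double t0 = as<double>(args["t0"]);
  NumericVector volume = args["volume"];
  NumericVector G_L = args["G_L"], G_F = args["G_F"], conv = args["conv"];
  const bool mobileL = as<bool>(args["mobileL"]);
  NumericVector kon = args["kon"], koff = args["koff"], kint = args["kint"];
  NumericVector exLa = args["exLa"], exLl = args["exLl"];
  NumericVector exFa = args["exFa"], exFl = args["exFl"];
  const double cp0 = as<double>(args["cp0"]);
  const double kd = as<double>(args["kd"]);
  NumericVector kel_times = args["kel_times"];
  NumericMatrix kel_mat = args["kel_mat"];
  NumericVector w_tumor = args["w_tumor"];
  const double omega = as<double>(args["omega"]);
  const int record_every = as<int>(args["record_every"]);
  IntegerVector snapshot_steps = args["snapshot_steps"];

  const int n = volume.size();
  const int nt = kel_times.size();
  ReactionRates rr{kon.begin(), koff.begin(), kint.begin(),
                   exLa.begin(), exLl.begin(), exFa.begin(), exFl.begin()};

  NumericVector CL0 = args["CL0"], CF0 = args["CF0"],
      CB0 = args["CB0"], CI0 = args["CI0"];
  std::vector<double> CL(CL0.begin(), CL0.end()), CF(CF0.begin(), CF0.end()),
      CB(CB0.begin(), CB0.end()), CI(CI0.begin(), CI0.end());
  double mass0 = 0.0;
  for (int i = 0; i < n - 1; ++i)
    mass0 += (CL[i] + CF[i] + CB[i] + CI[i]) * volume[i];
  std::vector<double> lower(n), diag(n), upper(n), rhs(n), x(n);

  // assemble the implicit convection-diffusion matrix for a mobile species
  auto assemble = [&](const NumericVector& G) {
    for (int i = 0; i < n; ++i) {
      lower[i] = 0.0; upper[i] = 0.0;
      diag[i] = volume[i] / dt;
      if (i > 0) {
        const double c = conv[i - 1];
        lower[i] = -G[i - 1] - (c > 0 ? c : 0.0);
        diag[i] += G[i - 1] - (c > 0 ? 0.0 : c);
      }
      if (i < n - 1) {
        const double c = conv[i];
        upper[i] = -G[i] + (c > 0 ? 0.0 : c);
        diag[i] += G[i] + (c > 0 ? c : 0.0);
      }
    }
    // outer node: Dirichlet zero concentration
    lower[n - 1] = 0.0; upper[n - 1] = 0.0; diag[n - 1] = 1.0;
  };

  // interpolate the release-rate field at time t into kel_now
  std::vector<double> kel_now(n, 0.0);
  auto kel_at = [&](double t) {
    if (nt == 0 || t <= kel_times[0] || t >= kel_times[nt - 1]) {
      std::fill(kel_now.begin(), kel_now.end(), 0.0);
      return;
    }
    int lo = 0, hi = nt - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2;
      if (kel_times[mid] <= t) lo = mid; else hi = mid; }
    const double w = (t - kel_times[lo]) / (kel_times[hi] - kel_times[lo]);
    for (int i = 0; i < n; ++i)
      kel_now[i] = (1.0 - w) * kel_mat(lo, i) + w * kel_mat(hi, i);
  };

  const int nrec = nsteps / record_every + 1;
  NumericVector rec_t(nrec), rec_CL(nrec), rec_CF(nrec), rec_CB(nrec),
      rec_CI(nrec), rec_S(nrec);
  double w_sum = 0.0; for (int i = 0; i < n; ++i) w_sum += w_tumor[i];
  auto record = [&](int rec, double t) {
    double sL = 0, sF = 0, sB = 0, sI = 0, sS = 0;
    for (int i = 0; i < n; ++i) {
      sL += CL[i] * w_tumor[i]; sF += CF[i] * w_tumor[i];
      sB += CB[i] * w_tumor[i]; sI += CI[i] * w_tumor[i];
      sS += std::exp(-omega * CI[i]) * w_tumor[i];
    }
    rec_t[rec] = t; rec_CL[rec] = sL / w_sum; rec_CF[rec] = sF / w_sum;
    rec_CB[rec] = sB / w_sum; rec_CI[rec] = sI / w_sum;
    rec_S[rec] = sS / w_sum;
  };
  record(0, t0);

  const int nsnap = snapshot_steps.size();
  NumericMatrix snapCL(nsnap, n), snapCF(nsnap, n), snapCB(nsnap, n), snapCI(nsnap, n);
  NumericVector snap_t(nsnap);
  int isnap = 0;

  double influx = 0.0, outflux = 0.0;
  std::vector<double> k1(4), k2(4), k3(4), k4(4);
  std::vector<double> kel_a(n), kel_b(n), kel_m(n);

  int rec = 1;
  for (int s = 1; s <= nsteps; ++s) {
    const double t_start = t0 + (s - 1) * dt;

    // --- (1) local kinetics + exchange, RK4 with nsub substeps ---
    const double h = dt / nsub;
    for (int sub = 0; sub < nsub; ++sub) {
      const double ta = t_start + sub * h;
      const double tm = ta + h / 2.0, tb = ta + h;
      const double cpa = cp0 * std::exp(-ta / kd);
      const double cpm = cp0 * std::exp(-tm / kd);
      const double cpb = cp0 * std::exp(-tb / kd);
      kel_at(ta); kel_a = kel_now;
      kel_at(tm); kel_m = kel_now;
      kel_at(tb); kel_b = kel_now;
      for (int i = 0; i < n - 1; ++i) {  // outer Dirichlet node stays 0
        double cL = CL[i], cF = CF[i], cB = CB[i];
        double d1L, d1F, d1B, d1I, d2L, d2F, d2B, d2I;
        double d3L, d3F, d3B, d3I, d4L, d4F, d4B, d4I;
        local_rhs(cL, cF, cB, kel_a[i], cpa, rr, i, d1L, d1F, d1B, d1I);
        local_rhs(cL + h / 2 * d1L, cF + h / 2 * d1F, cB + h / 2 * d1B,
                  kel_m[i], cpm, rr, i, d2L, d2F, d2B, d2I);
        local_rhs(cL + h / 2 * d2L, cF + h / 2 * d2F, cB + h / 2 * d2B,
                  kel_m[i], cpm, rr, i, d3L, d3F, d3B, d3I);
        local_rhs(cL + h * d3L, cF + h * d3F, cB + h * d3B,
                  kel_b[i], cpb, rr, i, d4L, d4F, d4B, d4I);
        const double nCL = cL + h / 6 * (d1L + 2 * d2L + 2 * d3L + d4L);
        const double nCF = cF + h / 6 * (d1F + 2 * d2F + 2 * d3F + d4F);
        const double nCB = cB + h / 6 * (d1B + 2 * d2B + 2 * d3B + d4B);
        const double nCI = CI[i] + h / 6 * (d1I + 2 * d2I + 2 * d3I + d4I);
        influx += ((nCL - cL) + (nCF - cF) + (nCB - cB) + (nCI - CI[i])) * volume[i];
        CL[i] = nCL; CF[i] = nCF; CB[i] = nCB; CI[i] = nCI;
      }
    }

    // --- (2) implicit convection-diffusion for mobile species ---
    if (mobileL) {
      assemble(G_L);
      for (int i = 0; i < n - 1; ++i) rhs[i] = volume[i] / dt * CL[i];
      rhs[n - 1] = 0.0;
      thomas(lower, diag, upper, rhs, x);
      // boundary outflux through the outermost interior face
      {
        const double c = conv[n - 2];
        const double up = c > 0 ? x[n - 2] : x[n - 1];
        outflux += dt * (c * up - G_L[n - 2] * (x[n - 1] - x[n - 2]));
      }
      CL = x;
    }
    assemble(G_F);
    for (int i = 0; i < n - 1; ++i) rhs[i] = volume[i] / dt * CF[i];
    rhs[n - 1] = 0.0;
    thomas(lower, diag, upper, rhs, x);
    {
      const double c = conv[n - 2];
      const double up = c > 0 ? x[n - 2] : x[n - 1];
      outflux += dt * (c * up - G_F[n - 2] * (x[n - 1] - x[n - 2]));
    }
    CF = x;

    // guard: concentrations must remain (numerically) non-negative
    for (int i = 0; i < n; ++i) {
      if (CL[i] < -1e-9 || CF[i] < -1e-9 || CB[i] < -1e-9)
        stop("negative concentration beyond tolerance at step %d", s);
      if (CL[i] < 0) CL[i] = 0; if (CF[i] < 0) CF[i] = 0;
      if (CB[i] < 0) CB[i] = 0;
    }

    if (s % record_every == 0 && rec < nrec) { record(rec, t0 + s * dt); ++rec; }
    while (isnap < nsnap && snapshot_steps[isnap] == s) {
      for (int j = 0; j < n; ++j) {
        snapCL(isnap, j) = CL[j]; snapCF(isnap, j) = CF[j];
        snapCB(isnap, j) = CB[j]; snapCI(isnap, j) = CI[j];
      }
      snap_t[isnap] = t0 + s * dt;
      ++isnap;
    }
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  double mass = 0.0;
  for (int i = 0; i < n - 1; ++i)
    mass += (CL[i] + CF[i] + CB[i] + CI[i]) * volume[i];

  return List::create(
    _["times"] = rec_t, _["CL_mean"] = rec_CL, _["CF_mean"] = rec_CF,
    _["CB_mean"] = rec_CB, _["CI_mean"] = rec_CI,
    _["drug_survival_mean"] = rec_S,
    _["CL"] = NumericVector(CL.begin(), CL.end()),
    _["CF"] = NumericVector(CF.begin(), CF.end()),
    _["CB"] = NumericVector(CB.begin(), CB.end()),
    _["CI"] = NumericVector(CI.begin(), CI.end()),
    _["snap_t"] = snap_t, _["snapCL"] = snapCL, _["snapCF"] = snapCF,
    _["snapCB"] = snapCB, _["snapCI"] = snapCI,
    _["mass_total"] = mass, _["mass_initial"] = mass0,
    _["influx"] = influx, _["outflux"] = outflux);
}
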