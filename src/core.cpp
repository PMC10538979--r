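// Closed-loop heart-coronary simulator core.
//
// State is a DAE: differential states (cavity, vascular and coronary
// compartment volumes, valve and coronary inlet flows, contractile-element
// lengths) plus algebraic states (septal cap volume Vs, junction radius Ys,
// and the midwall area of every wall patch, which enforces equal tension
// across the patches of a wall and ties their summed area to the wall cap
// geometry). Integration is BDF2 (implicit Euler on the first step) with a
// modified Newton iteration on a finite-difference Jacobian that is
// refactorized adaptively.
//
// Units: kPa, mL, mL/s, s, cm^2, um.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double sq(double x) { return x * x; }

struct Model {
  // dims
  int P;           // number of wall patches (LV first, then SEP, then RV)
  int S;           // number of perfused segments
  int ND, N;       // differential and total state counts

  // patches
  std::vector<int> patch_wall;       // 0 LV, 1 SEP, 2 RV
  std::vector<double> patch_Vw, patch_Am_ref, patch_t_act;
  double wall_Vw[3];
  double wall_Am_ref[3];
  int wall_first[3];                 // first patch index per wall

  // sarcomere
  double sig_act_max, TR, TD, Ls_ref, Ls0, Lsc0, Lse_iso, v_max;
  double sig_pas0, k_pas, k_lin, k_comp, eps0;

  // atria
  double at_V0, at_Vref, at_Epas, at_Eact, at_kexp, at_sigexp, at_TR, at_TD;

  // valves: order mv, av, tv, pv
  double v_Aopen[4], v_Aleak, v_len, v_rho, v_psw, v_tau;
  double v_L[4], v_B; // inertance per valve; bernoulli coeff 5.25e-5

  // systemic / pulmonary
  double Rsys, C_sa, V0_sa, C_sv, V0_sv, R_vr, Rpulm, C_pa, V0_pa, C_pv, V0_pv, R_pl;

  // pericardium
  double pc_k1, pc_k2, pc_Vref, pc_Vwall;

  // coronary epicardial vessels: 0 LM, 1 LAD, 2 LCx, 3 RCA (2 nodes each)
  double ves_E, ves_V0[4], ves_Rint, ves_Rin, ves_Lin, ves_Rjunc;
  std::vector<int> seg_parent;   // 0 LAD, 1 LCx, 2 RCA
  std::vector<int> seg_patch;
  std::vector<double> seg_Rsub_art, seg_Rsub_ven;
  double vein_E, vein_V0[3], vein_Rcs, cs_E, cs_V0, R_csra;
  double layer_w[3];             // resting flow weights (sum 1)
  double layer_r[3];             // radial positions: 5/6, 3/6, 1/6
  double gamma;

  // micro compartments, length S*15, order [seg][layer][class]
  std::vector<double> mc_V0, mc_Vw, mc_p0, mc_k, mc_dp0, mc_q0, mc_fDil;
  std::vector<double> mc_wfac, mc_v0d, mc_gref;  // precomputed per call

  double tcycle, dt;
  double newton_tol; int newton_maxit, jac_refresh;

  // index helpers
  int iVLA, iVRA, iVLV, iVRV, iQ0, iVsa, iVsv, iVpa, iVpv;
  int iQlm, iQrca, iVves, iVvein, iVcs, iSv, iLsc, iMC, iVs, iYs, iAm;

  int mci(int s, int l, int c) const { return iMC + (s * 3 + l) * 5 + c; }

  explicit Model(const List& par) {
    P = as<int>(par["P"]); S = as<int>(par["S"]);
    patch_wall = as<std::vector<int>>(par["patch_wall"]);
    patch_Vw = as<std::vector<double>>(par["patch_Vw"]);
    patch_Am_ref = as<std::vector<double>>(par["patch_Am_ref"]);
    patch_t_act = as<std::vector<double>>(par["patch_t_act"]);
    NumericVector wv = par["wall_Vw"], wa = par["wall_Am_ref"];
    for (int i = 0; i < 3; ++i) { wall_Vw[i] = wv[i]; wall_Am_ref[i] = wa[i]; }
    wall_first[0] = 0; wall_first[1] = -1; wall_first[2] = -1;
    for (int p = 0; p < P; ++p) {
      if (patch_wall[p] == 1 && wall_first[1] < 0) wall_first[1] = p;
      if (patch_wall[p] == 2 && wall_first[2] < 0) wall_first[2] = p;
    }
    NumericVector sc = par["sarc"];
    sig_act_max = sc[0]; TR = sc[1]; TD = sc[2]; Ls_ref = sc[3]; Ls0 = sc[4];
    Lsc0 = sc[5]; Lse_iso = sc[6]; v_max = sc[7]; sig_pas0 = sc[8];
    k_pas = sc[9]; k_lin = sc[10]; k_comp = sc[11];
    eps0 = std::log(Ls0 / Ls_ref);
    NumericVector at = par["atria"];
    at_V0 = at[0]; at_Vref = at[1]; at_Epas = at[2]; at_Eact = at[3];
    at_kexp = at[4]; at_sigexp = at[5]; at_TR = at[6]; at_TD = at[7];
    NumericVector va = par["valve_Aopen"];
    for (int i = 0; i < 4; ++i) v_Aopen[i] = va[i];
    v_Aleak = as<double>(par["valve_Aleak"]);
    v_len = as<double>(par["valve_len"]);
    v_rho = as<double>(par["valve_rho"]);
    v_psw = as<double>(par["valve_psw"]);
    v_tau = as<double>(par["valve_tau"]);
    for (int i = 0; i < 4; ++i)
      v_L[i] = v_rho * (v_len * 1e-2) / (v_Aopen[i] * 1e-4) * 1e-9;
    v_B = 0.5 * v_rho * 1e-4 * 1e-3; // 0.5*rho*(1e-2 q/A)^2 Pa -> kPa

    NumericVector sy = par["systemic"];
    Rsys = sy[0]; C_sa = sy[1]; V0_sa = sy[2]; C_sv = sy[3]; V0_sv = sy[4];
    R_vr = sy[5]; Rpulm = sy[6]; C_pa = sy[7]; V0_pa = sy[8]; C_pv = sy[9];
    V0_pv = sy[10]; R_pl = sy[11];
    NumericVector pc = par["pericardium"];
    pc_k1 = pc[0]; pc_k2 = pc[1]; pc_Vref = pc[2]; pc_Vwall = pc[3];

    ves_E = as<double>(par["ves_E"]);
    NumericVector vv0 = par["ves_V0"];
    for (int i = 0; i < 4; ++i) ves_V0[i] = vv0[i];
    ves_Rint = as<double>(par["ves_Rint"]);
    ves_Rin = as<double>(par["ves_Rin"]);
    ves_Lin = as<double>(par["ves_Lin"]);
    ves_Rjunc = as<double>(par["ves_Rjunc"]);
    seg_parent = as<std::vector<int>>(par["seg_parent"]);
    seg_patch = as<std::vector<int>>(par["seg_patch"]);
    seg_Rsub_art = as<std::vector<double>>(par["seg_Rsub_art"]);
    seg_Rsub_ven = as<std::vector<double>>(par["seg_Rsub_ven"]);
    vein_E = as<double>(par["vein_E"]);
    NumericVector vnv = par["vein_V0"];
    for (int i = 0; i < 3; ++i) vein_V0[i] = vnv[i];
    vein_Rcs = as<double>(par["vein_Rcs"]);
    cs_E = as<double>(par["cs_E"]); cs_V0 = as<double>(par["cs_V0"]);
    R_csra = as<double>(par["R_csra"]);
    NumericVector lw = par["layer_w"], lr = par["layer_r"];
    for (int i = 0; i < 3; ++i) { layer_w[i] = lw[i]; layer_r[i] = lr[i]; }
    gamma = as<double>(par["gamma"]);
    mc_V0 = as<std::vector<double>>(par["mc_V0"]);
    mc_Vw = as<std::vector<double>>(par["mc_Vw"]);
    mc_p0 = as<std::vector<double>>(par["mc_p0"]);
    mc_k = as<std::vector<double>>(par["mc_k"]);
    mc_dp0 = as<std::vector<double>>(par["mc_dp0"]);
    mc_q0 = as<std::vector<double>>(par["mc_q0"]);
    mc_fDil = as<std::vector<double>>(par["mc_fDil"]);

    int nmc = (int)mc_V0.size();
    mc_wfac.resize(nmc); mc_v0d.resize(nmc); mc_gref.resize(nmc);
    for (int i = 0; i < nmc; ++i) {
      mc_v0d[i] = mc_fDil[i] * mc_V0[i];
      mc_wfac[i] = std::pow(mc_Vw[i] / mc_v0d[i], -0.4);
      mc_gref[i] = mc_q0[i] / mc_dp0[i];
    }
    tcycle = as<double>(par["tcycle"]); dt = as<double>(par["dt"]);
    newton_tol = as<double>(par["newton_tol"]);
    newton_maxit = as<int>(par["newton_maxit"]);
    jac_refresh = std::abs(as<int>(par["jac_refresh"]));

    iVLA = 0; iVRA = 1; iVLV = 2; iVRV = 3; iQ0 = 4;
    iVsa = 8; iVsv = 9; iVpa = 10; iVpv = 11;
    iQlm = 12; iQrca = 13; iVves = 14; iVvein = 22; iVcs = 25;
    iSv = 26; iLsc = 30; iMC = iLsc + P;
    ND = iMC + S * 15;
    iVs = ND; iYs = ND + 1; iAm = ND + 2;
    N = ND + 2 + P;
  }

  // smooth twitch with a small resting tone: the floor keeps ventricular
  // wall tension from vanishing entirely in late relaxation, where the
  // junction force balance would otherwise degenerate
  double twitch(double trel, double tr, double td, double floor_ = 0.0) const {
    double c = 0.0;
    if (trel > 0 && trel < tr) c = 0.5 * (1.0 - std::cos(M_PI * trel / tr));
    else if (trel >= tr && trel < tr + td)
      c = 0.5 * (1.0 + std::cos(M_PI * (trel - tr) / td));
    return std::max(c, floor_);
  }

  // unique real root of (pi/6) x (x^2 + 3 y^2) = Vm
  static double capHeight(double Vm, double Ys) {
    double p = 3.0 * Ys * Ys, qh = 6.0 * Vm / M_PI;
    double s = std::sqrt(0.25 * qh * qh + p * p * p / 27.0);
    return std::cbrt(0.5 * qh + s) + std::cbrt(0.5 * qh - s);
  }

  double tubeLaw(double V, int idx) const {
    double Vw = mc_Vw[idx], k = mc_k[idx], p0 = mc_p0[idx];
    double v0d = mc_v0d[idx];
    double Vr = std::max(V, 1e-9);
    double t1 = std::pow((Vr + 0.5 * Vw) / (v0d + 0.5 * Vw), k / 3.0);
    double u = std::pow(Vr / v0d, 0.7) * mc_wfac[idx];
    double coll = u > 1.0 ? sq(u - 1.0) : 0.0;
    double pt = p0 * (t1 - 1.0 - coll);
    // residual-lumen barrier: the printed law's suction pressure is
    // bounded (~ -p0), so strong extravascular compression would drive
    // the volume to zero; a collapsed vessel retains a residual lumen,
    // modeled as a steep smooth stiffening below 8% of reference volume
    double Vb = 0.08 * v0d;
    if (Vr < Vb) pt -= 8.0 * p0 * sq(Vb / Vr - 1.0);
    return pt;
  }
};

struct Aux {
  double pLV, pRV, pLA, pRA, psa, psv, ppa, ppv, Pperi, Vtot;
  double Vs_x[3];       // cap heights xm per wall
  double TmW[3];
  std::vector<double> eps, sig, sigact; // per patch
  double qv[4];
  double qcor[4];       // lm inlet, lad inlet, lcx inlet, rca inlet
  std::vector<double> qsub;             // per segment arterial sub-branch inflow
  std::vector<double> imp;              // per seg*3
  std::vector<double> qmid;             // per compartment: 0.5*(qin+qout)
  Aux(int P, int S) : eps(P), sig(P), sigact(P), qsub(S), imp(S * 3), qmid(S * 15) {}
};

static void rhs(const Model& M, double t, const double* y, double* f,
                double* g, Aux& ax) {
  const int P = M.P, S = M.S;
  // ---- pericardium
  double Vves_sum = 0;
  for (int i = 0; i < 8; ++i) Vves_sum += y[M.iVves + i];
  double Vvein_sum = y[M.iVvein] + y[M.iVvein + 1] + y[M.iVvein + 2] + y[M.iVcs];
  double Venc = y[M.iVLA] + y[M.iVRA] + y[M.iVLV] + y[M.iVRV] + M.pc_Vwall +
                Vves_sum + Vvein_sum;
  double Pperi = M.pc_k1 * std::expm1(M.pc_k2 * (Venc / M.pc_Vref - 1.0));
  ax.Pperi = Pperi;

  // ---- patch mechanics
  double tc = t - M.tcycle * std::floor(t / M.tcycle);
  double TmWnum[3] = {0, 0, 0}, TmWden[3] = {0, 0, 0};
  std::vector<double> Tm(P);
  for (int p = 0; p < P; ++p) {
    double Am = y[M.iAm + p];
    double Amr = M.patch_Am_ref[p];
    double eps = 0.5 * std::log(std::max(Am, 1e-6) / Amr);
    double Ls = M.Ls_ref * std::exp(eps);
    double Lsc = y[M.iLsc + p];
    double trel = tc - M.patch_t_act[p];
    double C = M.twitch(trel, M.TR, M.TD, 0.006);
    double gl = std::max(0.0, (Lsc - M.Lsc0) / (M.Ls_ref - M.Lse_iso - M.Lsc0));
    double se = std::max(0.0, (Ls - Lsc) / M.Lse_iso);
    double sa = M.sig_act_max * C * gl * se;
    double d = eps - M.eps0;
    // tension branch: exponential strain stiffening; compression branch:
    // exponential stiffening of opposite sign (tissue resists crumpling),
    // slope-matched at the zero-stress strain
    double sig_comp = M.sig_pas0 * M.k_pas / M.k_comp;
    double sp = M.k_lin * d + (d > 0 ? M.sig_pas0 * std::expm1(M.k_pas * d)
                                     : -sig_comp * std::expm1(-M.k_comp * d));
    double sig = sa + sp;
    ax.eps[p] = eps; ax.sig[p] = sig; ax.sigact[p] = sa;
    Tm[p] = sig * M.patch_Vw[p] / (2.0 * Am);
    f[M.iLsc + p] = ((Ls - Lsc) / M.Lse_iso - 1.0) * M.v_max;
    int w = M.patch_wall[p];
    TmWnum[w] += Am * Tm[p]; TmWden[w] += Am;
  }
  for (int w = 0; w < 3; ++w) ax.TmW[w] = TmWnum[w] / std::max(TmWden[w], 1e-9);

  // ---- TriSeg geometry
  double Vs = y[M.iVs], Ys = y[M.iYs];
  double VLV = y[M.iVLV], VRV = y[M.iVRV];
  double Vm[3];
  Vm[0] = Vs - (VLV + 0.5 * (M.wall_Vw[0] + M.wall_Vw[1]));
  Vm[1] = Vs;
  Vm[2] = Vs + VRV + 0.5 * (M.wall_Vw[1] + M.wall_Vw[2]);
  double xm[3], AmW[3], CmW[3];
  for (int w = 0; w < 3; ++w) {
    xm[w] = Model::capHeight(Vm[w], Ys);
    AmW[w] = M_PI * (xm[w] * xm[w] + Ys * Ys);
    CmW[w] = 2.0 * xm[w] / (xm[w] * xm[w] + Ys * Ys);
    ax.Vs_x[w] = xm[w];
  }
  // algebraic residuals, scaled by the instantaneous tension magnitude so
  // the junction equilibrium stays well-conditioned through diastole
  double Tscale = 0.0;
  for (int w = 0; w < 3; ++w) Tscale += std::fabs(ax.TmW[w]);
  Tscale = std::max(Tscale / 3.0, 0.05);
  double gx = 0, gy = 0;
  for (int w = 0; w < 3; ++w) {
    double d2 = xm[w] * xm[w] + Ys * Ys;
    gx += ax.TmW[w] * 2.0 * xm[w] * Ys / d2;
    gy += ax.TmW[w] * (Ys * Ys - xm[w] * xm[w]) / d2;
  }
  g[0] = gx / Tscale;
  g[1] = gy / Tscale;
  double AmSum[3] = {0, 0, 0};
  for (int p = 0; p < P; ++p) AmSum[M.patch_wall[p]] += y[M.iAm + p];
  for (int p = 0; p < P; ++p) {
    int w = M.patch_wall[p];
    if (p == M.wall_first[w])
      g[2 + p] = (AmSum[w] - AmW[w]) / M.wall_Am_ref[w];
    else
      g[2 + p] = (Tm[p] - Tm[M.wall_first[w]]) / Tscale;
  }

  // ---- cavity pressures
  double pLV = Pperi - 2.0 * ax.TmW[0] * CmW[0];
  double pRV = Pperi + 2.0 * ax.TmW[2] * CmW[2];
  ax.pLV = pLV; ax.pRV = pRV;

  // ---- atria
  double actA = M.twitch(tc, M.at_TR, M.at_TD);
  double VLA = y[M.iVLA], VRA = y[M.iVRA];
  double pLA = Pperi + M.at_Epas * (VLA - M.at_V0) + actA * M.at_Eact * (VLA - M.at_V0) +
               M.at_sigexp * std::expm1(M.at_kexp * (VLA / M.at_Vref - 1.0));
  double pRA = Pperi + M.at_Epas * (VRA - M.at_V0) + actA * M.at_Eact * (VRA - M.at_V0) +
               M.at_sigexp * std::expm1(M.at_kexp * (VRA / M.at_Vref - 1.0));
  ax.pLA = pLA; ax.pRA = pRA;

  // ---- systemic / pulmonary
  double psa = (y[M.iVsa] - M.V0_sa) / M.C_sa;
  double psv = (y[M.iVsv] - M.V0_sv) / M.C_sv;
  double ppa = (y[M.iVpa] - M.V0_pa) / M.C_pa;
  double ppv = (y[M.iVpv] - M.V0_pv) / M.C_pv;
  ax.psa = psa; ax.psv = psv; ax.ppa = ppa; ax.ppv = ppv;
  double qsys = (psa - psv) / M.Rsys;
  double qvr = (psv - pRA) / M.R_vr;
  double qpul = (ppa - ppv) / M.Rpulm;
  double qpl = (ppv - pLA) / M.R_pl;

  // ---- valves (mv, av, tv, pv)
  double dpv[4] = {pLA - pLV, pLV - psa, pRA - pRV, pRV - ppa};
  for (int v = 0; v < 4; ++v) {
    double q = y[M.iQ0 + v];
    // leaflet opening state: relaxes toward a target set by the pressure
    // gradient plus a softplus of forward flow (an ejecting valve stays
    // open under a decelerating gradient; a closed valve at q ~ 0 under
    // negative dp reads fully closed). Making the opening a state with
    // its own time constant removes the algebraic flow-area feedback.
    double a = q / 20.0;
    double sp = a > 30.0 ? a : std::log1p(std::exp(a));
    double m = dpv[v] / M.v_psw + sp;
    double st = m > 0 ? 1.0 / (1.0 + std::exp(-m)) : std::exp(m) / (1.0 + std::exp(m));
    double s = std::min(1.0, std::max(0.0, y[M.iSv + v]));
    f[M.iSv + v] = (st - y[M.iSv + v]) / M.v_tau;
    double Aeff = M.v_Aleak + (M.v_Aopen[v] - M.v_Aleak) * s;
    // regularized quadratic drag: nonzero slope at q = 0 so the closed
    // valve is a stiff linear resistor rather than a Newton-degenerate
    // quadratic
    double bern = M.v_B * q * std::sqrt(q * q + 0.25) / (Aeff * Aeff);
    f[M.iQ0 + v] = (dpv[v] - bern) / M.v_L[v];
    ax.qv[v] = q;
  }
  double qmv = y[M.iQ0], qav = y[M.iQ0 + 1], qtv = y[M.iQ0 + 2], qpv = y[M.iQ0 + 3];

  // ---- coronary epicardial vessels
  double pn[8];
  for (int i = 0; i < 8; ++i) {
    int vsl = i / 2;
    pn[i] = Pperi + M.ves_E * (y[M.iVves + i] / (0.5 * M.ves_V0[vsl]) - 1.0);
  }
  double qlm = y[M.iQlm], qrca = y[M.iQrca];
  f[M.iQlm] = (psa - pn[0] - M.ves_Rin * qlm) / M.ves_Lin;
  f[M.iQrca] = (psa - pn[6] - M.ves_Rin * qrca) / M.ves_Lin;
  double qlm12 = (pn[0] - pn[1]) / M.ves_Rint;
  double qladin = (pn[1] - pn[2]) / M.ves_Rjunc;
  double qlcxin = (pn[1] - pn[4]) / M.ves_Rjunc;
  double qlad12 = (pn[2] - pn[3]) / M.ves_Rint;
  double qlcx12 = (pn[4] - pn[5]) / M.ves_Rint;
  double qrca12 = (pn[6] - pn[7]) / M.ves_Rint;
  ax.qcor[0] = qlm; ax.qcor[1] = qladin; ax.qcor[2] = qlcxin; ax.qcor[3] = qrca;

  double pvein[3], subout[3] = {0, 0, 0}, subin[3] = {0, 0, 0};
  // logarithmic pressure-volume law: stiffens steeply toward collapse so
  // vein nodes cannot be sucked to negative volumes
  for (int b = 0; b < 3; ++b)
    pvein[b] = Pperi + M.vein_E * std::log(std::max(y[M.iVvein + b], 1e-3) / M.vein_V0[b]);
  double pcs = Pperi + M.cs_E * std::log(std::max(y[M.iVcs], 1e-3) / M.cs_V0);

  // ---- micro circulation
  for (int s = 0; s < S; ++s) {
    int pat = M.seg_patch[s];
    int w = M.patch_wall[pat];
    double P1, P2;
    if (w == 0) { P1 = pLV; P2 = Pperi; }
    else if (w == 1) { P1 = pLV; P2 = pRV; }
    else { P1 = pRV; P2 = Pperi; }
    int parent = M.seg_parent[s];
    double pfeed = pn[parent == 0 ? 3 : (parent == 1 ? 5 : 7)];
    double qseg = 0;
    for (int l = 0; l < 3; ++l) {
      double IMP = M.layer_r[l] * P1 + (1.0 - M.layer_r[l]) * P2 +
                   M.gamma * ax.sig[pat];
      ax.imp[s * 3 + l] = IMP;
      double p[5], R[5];
      for (int c = 0; c < 5; ++c) {
        int idx = M.mci(s, l, c);
        double V = std::max(y[idx], 1e-9);
        int im = idx - M.iMC;
        p[c] = M.tubeLaw(V, im) + IMP;
        // volume-dependent Poiseuille resistance, floored so a squeezed
        // compartment impedes but never fully seals the chain
        double vr = M.mc_V0[im] / std::max(V, 0.08 * M.mc_V0[im]);
        R[c] = vr * vr / M.mc_gref[im];
      }
      double Rsub_a = M.seg_Rsub_art[s] / M.layer_w[l];
      double Rsub_v = M.seg_Rsub_ven[s] / M.layer_w[l];
      double qin = (pfeed - p[0]) / (Rsub_a + 0.5 * R[0]);
      double qq[6];
      qq[0] = qin;
      for (int c = 0; c < 4; ++c)
        qq[c + 1] = (p[c] - p[c + 1]) / (0.5 * R[c] + 0.5 * R[c + 1]);
      int b = M.seg_parent[s];
      qq[5] = (p[4] - pvein[b]) / (0.5 * R[4] + Rsub_v);
      for (int c = 0; c < 5; ++c) {
        int idx = M.mci(s, l, c);
        f[idx] = qq[c] - qq[c + 1];
        ax.qmid[idx - M.iMC] = 0.5 * (qq[c] + qq[c + 1]);
      }
      subin[b] += qin;
      subout[b] += qq[5];
      qseg += qin;
    }
    ax.qsub[s] = qseg;
  }

  // ---- vessel node volume ODEs
  f[M.iVves + 0] = qlm - qlm12;
  f[M.iVves + 1] = qlm12 - qladin - qlcxin;
  f[M.iVves + 2] = qladin - qlad12;
  f[M.iVves + 3] = qlad12 - subin[0];
  f[M.iVves + 4] = qlcxin - qlcx12;
  f[M.iVves + 5] = qlcx12 - subin[1];
  f[M.iVves + 6] = qrca - qrca12;
  f[M.iVves + 7] = qrca12 - subin[2];
  double qcs_in = 0;
  for (int b = 0; b < 3; ++b) {
    double qb = (pvein[b] - pcs) / M.vein_Rcs;
    f[M.iVvein + b] = subout[b] - qb;
    qcs_in += qb;
  }
  double qcsra = (pcs - pRA) / M.R_csra;
  f[M.iVcs] = qcs_in - qcsra;

  // ---- chambers and vascular beds
  f[M.iVLA] = qpl - qmv;
  f[M.iVLV] = qmv - qav;
  f[M.iVRA] = qvr + qcsra - qtv;
  f[M.iVRV] = qtv - qpv;
  f[M.iVsa] = qav - qsys - qlm - qrca;
  f[M.iVsv] = qsys - qvr;
  f[M.iVpa] = qpv - qpul;
  f[M.iVpv] = qpul - qpl;

  // total blood volume (diagnostic)
  double Vtot = VLA + VRA + VLV + VRV + y[M.iVsa] + y[M.iVsv] + y[M.iVpa] +
                y[M.iVpv] + Vves_sum + Vvein_sum;
  for (int i = M.iMC; i < M.ND; ++i) Vtot += y[i];
  ax.Vtot = Vtot;
}

// residual of the implicit step: diff rows y - a1*y1 - a2*y2 - bh*f(y),
// algebraic rows g(y)
static void stepResidual(const Model& M, double t, const double* y,
                         const double* y1, const double* y2, double a1,
                         double a2, double bh, double* res, Aux& ax) {
  std::vector<double> f(M.ND, 0.0);
  std::vector<double> g(2 + M.P, 0.0);
  rhs(M, t, y, f.data(), g.data(), ax);
  for (int i = 0; i < M.ND; ++i)
    res[i] = y[i] - a1 * y1[i] - (a2 != 0 ? a2 * y2[i] : 0.0) - bh * f[i];
  // weak temporal damping on the algebraic (geometry) rows: when all wall
  // tensions pass through zero together (end of relaxation) the junction
  // equilibrium degenerates to 0 = 0 and any geometry satisfies it; the
  // damping term then pins the geometry to its previous-step value, while
  // under normal tension its contribution is negligible
  // damping strength fades quadratically with the tension scale, so the
  // equilibrium is exact to solver tolerance whenever the junction forces
  // meaningfully constrain the geometry
  double tmean = (std::fabs(ax.TmW[0]) + std::fabs(ax.TmW[1]) +
                  std::fabs(ax.TmW[2])) / 3.0;
  const double lam = 0.35 * sq(0.15 / (0.15 + tmean));
  for (int i = 0; i < 2 + M.P; ++i) {
    int idx = M.ND + i;
    bool is_area_sum = i >= 2 && (i - 2) == M.wall_first[M.patch_wall[i - 2]];
    double d = 0.0;
    if (!is_area_sum) {   // keep the exact area-sum constraints exact
      double asc = (i == 0) ? 20.0
                 : (i == 1) ? 0.5
                            : 0.05 * M.patch_Am_ref[i - 2];
      d = lam * (y[idx] - y1[idx]) / asc;
    }
    res[idx] = g[i] + d;
  }
}

struct Solver {
  const Model& M;
  bool debug_trace = false;
  long n_builds = 0, n_iters = 0;
  arma::mat L, U;
  arma::uvec piv;
  bool haveJ = false;
  std::vector<double> ysc;

  explicit Solver(const Model& Mm) : M(Mm), ysc(Mm.N, 1.0) {}

  // keep Newton iterates away from unphysical regions where the model
  // equations lose meaning (non-positive areas, radii, volumes)
  void sanitize(double* y) {
    if (y[M.iYs] < 0.2) y[M.iYs] = 0.2;
    for (int p = 0; p < M.P; ++p)
      if (y[M.iAm + p] < 0.02 * M.patch_Am_ref[p])
        y[M.iAm + p] = 0.02 * M.patch_Am_ref[p];
    for (int i = M.iMC; i < M.ND; ++i)
      if (y[i] < 1e-3 * M.mc_V0[i - M.iMC]) y[i] = 1e-3 * M.mc_V0[i - M.iMC];
    for (int v = 0; v < 4; ++v) {
      if (y[M.iSv + v] < -0.2) y[M.iSv + v] = -0.2;
      if (y[M.iSv + v] > 1.2) y[M.iSv + v] = 1.2;
    }
  }

  void setScales(const double* y) {
    for (int i = 0; i < M.N; ++i) ysc[i] = std::max(std::fabs(y[i]), 1e-3);
    ysc[M.iYs] = std::max(std::fabs(y[M.iYs]), 0.5);
    for (int p = 0; p < M.P; ++p) {
      ysc[M.iLsc + p] = 2.0;
      ysc[M.iAm + p] = std::max(M.patch_Am_ref[p], 1.0);
    }
    for (int i = M.iMC; i < M.ND; ++i)
      ysc[i] = std::max(M.mc_V0[i - M.iMC], 1e-4);
    for (int v = 0; v < 4; ++v) ysc[M.iQ0 + v] = 200.0;
    for (int v = 0; v < 4; ++v) ysc[M.iSv + v] = 1.0;
    ysc[M.iQlm] = 10.0; ysc[M.iQrca] = 10.0;
  }

  void buildJacobian(double t, const double* y, const double* y1,
                     const double* y2, double a1, double a2, double bh,
                     Aux& ax) {
    int N = M.N;
    arma::mat J(N, N);
    std::vector<double> r0(N), rp(N), rm(N), yp(y, y + N);
    stepResidual(M, t, y, y1, y2, a1, a2, bh, r0.data(), ax);
    for (int j = 0; j < N; ++j) {
      // central differences for the algebraic (TriSeg geometry) and valve
      // columns, where forward-difference truncation error is enough to
      // destabilize the iteration in nearly-flat directions
      bool cent = j >= M.ND || (j >= M.iQ0 && j < M.iQ0 + 4) ||
                  (j >= M.iSv && j < M.iSv + 4);
      double e = (cent ? 1e-5 : 1e-7) * ysc[j];
      yp[j] = y[j] + e;
      stepResidual(M, t, yp.data(), y1, y2, a1, a2, bh, rp.data(), ax);
      if (cent) {
        yp[j] = y[j] - e;
        stepResidual(M, t, yp.data(), y1, y2, a1, a2, bh, rm.data(), ax);
        yp[j] = y[j];
        for (int i = 0; i < N; ++i)
          J(i, j) = (rp[i] - rm[i]) / (2 * e) * ysc[j] / ysc[i];
      } else {
        yp[j] = y[j];
        // row/column equilibration by the state scales: entries are O(1),
        // so pivot magnitudes are meaningful across mixed physical units
        for (int i = 0; i < N; ++i)
          J(i, j) = (rp[i] - r0[i]) / e * ysc[j] / ysc[i];
      }
    }
    ++n_builds;
    // factorize with escalating diagonal (Levenberg-style) regularization
    // if a pivot vanishes: kink crossings in the finite-difference
    // Jacobian can make it numerically singular for one step
    double lam = 0.0;
    for (int attempt = 0; attempt < 6; ++attempt) {
      arma::mat Jr = J;
      if (lam > 0) Jr.diag() += lam;
      arma::mat Pm;
      bool ok = arma::lu(L, U, Pm, Jr);
      if (ok) {
        double umax = arma::abs(U.diag()).max();
        double umin = arma::abs(U.diag()).min();
        if (umin > 1e-12 * std::max(umax, 1.0)) {
          piv.set_size(N);
          for (int i = 0; i < N; ++i) {
            arma::uvec nz = arma::find(Pm.row(i) > 0.5);
            piv[i] = nz[0];
          }
          haveJ = true;
          return;
        }
      }
      lam = (lam == 0.0) ? 1e-8 : lam * 100.0;
      Rcpp::Rcout << "[jac] regularizing lam=" << lam << "\n";
    }
    stop("Jacobian factorization failed");
  }

  // one implicit step with a modified Newton iteration that rebuilds the
  // Jacobian when convergence stalls; returns iterations used (negated
  // rebuild count folded into the hundreds digit), or -1 on failure
  int solveStep(double t, double* y, const double* y1, const double* y2,
                double a1, double a2, double bh, Aux& ax) {
    int N = M.N;
    std::vector<double> res(N), ybak(y, y + N);
    arma::vec r(N), z;
    double preverr = 1e100;
    int rebuilds = 0;
    for (int it = 0; it < M.newton_maxit; ++it) {
      ++n_iters;
      stepResidual(M, t, y, y1, y2, a1, a2, bh, res.data(), ax);
      bool resbad = false;
      for (int i = 0; i < N; ++i)
        if (!std::isfinite(res[i])) { resbad = true; break; }
      if (resbad) {
        if (rebuilds >= 8) return -1;
        std::copy(ybak.begin(), ybak.end(), y);
        stepResidual(M, t, y, y1, y2, a1, a2, bh, res.data(), ax);
        for (int i = 0; i < N; ++i)
          if (!std::isfinite(res[i])) return -1;
        buildJacobian(t, y, y1, y2, a1, a2, bh, ax);
        ++rebuilds; preverr = 1e100;
      }
      for (int i = 0; i < N; ++i) r[i] = res[piv[i]] / ysc[piv[i]];
      z = arma::solve(arma::trimatl(L), r);
      arma::vec du = arma::solve(arma::trimatu(U), z);
      arma::vec dy(N);
      double err = 0;
      bool bad = false;
      for (int i = 0; i < N; ++i) {
        if (!std::isfinite(du[i])) { bad = true; break; }
        dy[i] = du[i] * ysc[i];
        err += sq(du[i]);
      }
      err = std::sqrt(err / N);
      if (bad || !std::isfinite(err)) {
        if (rebuilds >= 8) return -1;
        std::copy(ybak.begin(), ybak.end(), y);
        buildJacobian(t, y, y1, y2, a1, a2, bh, ax);
        ++rebuilds; preverr = 1e100;
        continue;
      }
      std::copy(y, y + N, ybak.begin());
      // per-component trust region: algebraic (geometry) states move at
      // most 5% of scale per iteration, differential states at most one
      // scale unit; keeps the iteration inside the local TriSeg basin
      for (int i = 0; i < N; ++i) {
        double cap = (i >= M.ND ? 0.05 : 1.0) * ysc[i];
        double d = dy[i];
        if (d > cap) d = cap;
        if (d < -cap) d = -cap;
        y[i] -= d;
      }
      sanitize(y);
      if (err < M.newton_tol) return it + 1 + 100 * rebuilds;
      if (debug_trace) {
        int imax = 0; double vmax = 0;
        for (int i = 0; i < N; ++i)
          if (std::fabs(du[i]) > vmax) { vmax = std::fabs(du[i]); imax = i; }
        int rmax = 0; double rv = 0;
        for (int i = 0; i < N; ++i)
          if (std::fabs(res[i] / ysc[i]) > rv) { rv = std::fabs(res[i] / ysc[i]); rmax = i; }
        Rcpp::Rcout << "[nwt] it=" << it << " err=" << err
                    << " imax=" << imax << " du=" << du[imax]
                    << " y=" << y[imax] << " rmax=" << rmax << " r=" << rv
                    << " rb=" << rebuilds << "\n";
      }
      // slow or diverging contraction: refresh the Jacobian at the
      // current iterate and keep going
      if (err > 0.9 * preverr && it >= 2) {
        if (rebuilds >= 8) return -1;
        buildJacobian(t, y, y1, y2, a1, a2, bh, ax);
        ++rebuilds; preverr = 1e100;
        continue;
      }
      preverr = err;
    }
    return -1;
  }
};

// Solve the algebraic (TriSeg + patch-area) subsystem for a given set of
// differential states, by damped Newton on (Vs, Ys, Am_p).
// [[Rcpp::export]]
NumericVector cf_init_geometry(List par, NumericVector y0) {
  Model M(par);
  std::vector<double> y(y0.begin(), y0.end());
  int na = 2 + M.P;
  Aux ax(M.P, M.S);
  std::vector<double> f(M.ND), g(na), gp(na);
  arma::mat J(na, na);
  arma::vec r(na);
  for (int iter = 0; iter < 200; ++iter) {
    rhs(M, 0.0, y.data(), f.data(), g.data(), ax);
    double nrm = 0;
    for (int i = 0; i < na; ++i) nrm = std::max(nrm, std::fabs(g[i]));
    if (nrm < 1e-10) break;
    for (int j = 0; j < na; ++j) {
      int idx = M.ND + j;
      double sc = (j == 0) ? 10.0 : (j == 1 ? 0.5 : std::max(1.0, y[idx] * 0.1));
      double e = 1e-6 * sc;
      double sav = y[idx];
      y[idx] += e;
      rhs(M, 0.0, y.data(), f.data(), gp.data(), ax);
      y[idx] = sav;
      for (int i = 0; i < na; ++i) J(i, j) = (gp[i] - g[i]) / e;
    }
    for (int i = 0; i < na; ++i) r[i] = g[i];
    arma::vec dy;
    if (!arma::solve(dy, J, r)) stop("geometry initialization failed");
    // damped update with per-component step limiting
    for (int j = 0; j < na; ++j) {
      int idx = M.ND + j;
      double lim = (j == 0) ? 20.0 : (j == 1 ? 0.4 : 0.25 * std::max(1.0, y[idx]));
      double d = -dy[j];
      if (d > lim) d = lim;
      if (d < -lim) d = -lim;
      y[idx] += d;
      if (j >= 2 && y[idx] < 0.05) y[idx] = 0.05;
    }
    if (y[M.iYs] < 0.3) y[M.iYs] = 0.3;
    if (iter == 199) stop("geometry initialization did not converge");
  }
  return NumericVector(y.begin(), y.end());
}

// [[Rcpp::export]]
List cf_simulate(List par, NumericVector y0, Nullable<NumericVector> yprev,
                 int nsteps, double t0, int record_level) {
  Model M(par);
  if ((int)y0.size() != M.N) stop("state length mismatch");
  Solver Sv(M);
  Sv.debug_trace = as<int>(par["jac_refresh"]) < 0;
  Aux ax(M.P, M.S);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> y1(y.begin(), y.end()), y2(M.N, 0.0), y3(M.N, 0.0);
  bool have2 = false, have3 = false;
  if (yprev.isNotNull()) {
    NumericVector yp(yprev);
    if ((int)yp.size() == M.N) {
      std::copy(yp.begin(), yp.end(), y2.begin());
      have2 = true;
    }
  }
  double h = M.dt;
  int P = M.P, S = M.S;

  // records
  NumericVector rt(nsteps);
  NumericMatrix hemo(nsteps, 13), valveQ(nsteps, 4), corQ(nsteps, 4);
  NumericMatrix peps(nsteps, P), psig(nsteps, P), psigact(nsteps, P);
  NumericMatrix qsub(nsteps, S);
  NumericMatrix impRec((record_level >= 2) ? nsteps : 1,
                       (record_level >= 2) ? S * 3 : 1);
  std::vector<double> meanQ(S * 15, 0.0), meanIMP(S * 3, 0.0), meanQsub(S, 0.0);
  double sumQav = 0, sumQpv = 0, sumPsa = 0, peakPLV = -1e9;
  std::vector<double> peakSig(P, -1e9);
  double Vtot0 = -1, VtotMin = 1e18, VtotMax = -1e18;

  Sv.setScales(y.data());
  int sinceJ = 1 << 30;

  for (int k = 0; k < nsteps; ++k) {
    double t = t0 + (k + 1) * h;
    double a1, a2, bh;
    if (have2) { a1 = 4.0 / 3.0; a2 = -1.0 / 3.0; bh = 2.0 / 3.0 * h; }
    else { a1 = 1.0; a2 = 0.0; bh = h; }
    // predictor: quadratic extrapolation when three history points are
    // available, else linear, else constant
    std::vector<double> yn(y.begin(), y.end());
    for (int i = 0; i < M.N; ++i) {
      if (have3) y[i] = 3.0 * yn[i] - 3.0 * y2[i] + y3[i];
      else if (have2) y[i] = 2.0 * yn[i] - y2[i];
    }
    Sv.sanitize(y.data());

    if (!Sv.haveJ || sinceJ >= M.jac_refresh) {
      Sv.setScales(yn.data());
      Sv.buildJacobian(t, y.data(), yn.data(), y2.data(), a1, a2, bh, ax);
      sinceJ = 0;
    }
    int its = Sv.solveStep(t, y.data(), yn.data(), y2.data(), a1, a2, bh, ax);
    if (its < 0) {
      // refresh Jacobian at the predictor and retry
      std::copy(yn.begin(), yn.end(), y.begin());
      Sv.setScales(yn.data());
      Sv.buildJacobian(t, y.data(), yn.data(), y2.data(), a1, a2, bh, ax);
      sinceJ = 0;
      its = Sv.solveStep(t, y.data(), yn.data(), y2.data(), a1, a2, bh, ax);
      if (its < 0) {
        // last resort: adaptive bisection of the step with implicit
        // Euler, each sub-step with its own fresh Jacobian
        std::copy(yn.begin(), yn.end(), y.begin());
        double t_cur = t - h, t_goal = t;
        double hs = h / 2.0;
        int guard = 0;
        while (t_cur < t_goal - 1e-12 && ++guard < 400) {
          double ts = std::min(t_cur + hs, t_goal);
          double hcur = ts - t_cur;
          std::vector<double> ys(y.begin(), y.end());
          Sv.setScales(ys.data());
          Sv.buildJacobian(ts, y.data(), ys.data(), y2.data(), 1.0, 0.0,
                           hcur, ax);
          int it2 = Sv.solveStep(ts, y.data(), ys.data(), y2.data(), 1.0,
                                 0.0, hcur, ax);
          if (it2 < 0) {
            std::copy(ys.begin(), ys.end(), y.begin());
            hs /= 2.0;
            if (hs < h / 256.0)
              stop("implicit step failed at t=%f (Newton non-convergence)", ts);
          } else {
            t_cur = ts;
            if (it2 % 100 < 4 && hs < h / 2.0) hs *= 2.0;
          }
        }
        have2 = false; have3 = false;  // restart BDF2 history
        sinceJ = M.jac_refresh;        // force a fresh Jacobian next step
      }
    }
    int rbs = its > 0 ? its / 100 : 0;
    int iters = its > 0 ? its % 100 : 0;
    if (rbs > 0) sinceJ = 0;                  // J was just rebuilt in-solve
    else if (iters > 5) sinceJ = M.jac_refresh; // force refresh next step
    else ++sinceJ;

    y3 = y2;
    have3 = have2;
    y2 = yn;
    have2 = true;

    // evaluate auxiliaries at the accepted state for recording
    {
      std::vector<double> f(M.ND), g(2 + P);
      rhs(M, t, y.data(), f.data(), g.data(), ax);
    }
    rt[k] = t;
    hemo(k, 0) = ax.pLV; hemo(k, 1) = ax.pRV; hemo(k, 2) = ax.pLA;
    hemo(k, 3) = ax.pRA; hemo(k, 4) = ax.psa; hemo(k, 5) = ax.ppa;
    hemo(k, 6) = ax.ppv; hemo(k, 7) = ax.psv; hemo(k, 8) = ax.Pperi;
    hemo(k, 9) = y[M.iVLV]; hemo(k, 10) = y[M.iVRV]; hemo(k, 11) = ax.Vtot;
    hemo(k, 12) = y[M.iVs];
    for (int v = 0; v < 4; ++v) valveQ(k, v) = ax.qv[v];
    for (int v = 0; v < 4; ++v) corQ(k, v) = ax.qcor[v];
    for (int p = 0; p < P; ++p) {
      peps(k, p) = ax.eps[p]; psig(k, p) = ax.sig[p];
      psigact(k, p) = ax.sigact[p];
      if (ax.sig[p] > peakSig[p]) peakSig[p] = ax.sig[p];
    }
    for (int s = 0; s < S; ++s) { qsub(k, s) = ax.qsub[s]; meanQsub[s] += ax.qsub[s]; }
    if (record_level >= 2)
      for (int i = 0; i < S * 3; ++i) impRec(k, i) = ax.imp[i];
    for (int i = 0; i < S * 15; ++i) meanQ[i] += ax.qmid[i];
    for (int i = 0; i < S * 3; ++i) meanIMP[i] += ax.imp[i];
    sumQav += ax.qv[1]; sumQpv += ax.qv[3]; sumPsa += ax.psa;
    if (ax.pLV > peakPLV) peakPLV = ax.pLV;
    if (Vtot0 < 0) Vtot0 = ax.Vtot;
    VtotMin = std::min(VtotMin, ax.Vtot);
    VtotMax = std::max(VtotMax, ax.Vtot);
  }

  double inv = 1.0 / nsteps;
  for (auto& v : meanQ) v *= inv;
  for (auto& v : meanIMP) v *= inv;
  for (auto& v : meanQsub) v *= inv;

  List summary = List::create(
      _["CO"] = sumQav * inv, _["CO_rv"] = sumQpv * inv,
      _["MAP"] = sumPsa * inv, _["SV_LV"] = sumQav * inv * nsteps * h,
      _["SV_RV"] = sumQpv * inv * nsteps * h, _["peak_pLV"] = peakPLV,
      _["peak_sig"] = NumericVector(peakSig.begin(), peakSig.end()),
      _["meanQ"] = NumericVector(meanQ.begin(), meanQ.end()),
      _["meanIMP"] = NumericVector(meanIMP.begin(), meanIMP.end()),
      _["meanQsub"] = NumericVector(meanQsub.begin(), meanQsub.end()),
      _["Vtot_drift"] = (VtotMax - VtotMin) / Vtot0,
      _["n_jac"] = (double)Sv.n_builds, _["n_newton"] = (double)Sv.n_iters);

  List out = List::create(
      _["y"] = NumericVector(y.begin(), y.end()),
      _["yprev"] = NumericVector(y2.begin(), y2.end()),
      _["t_end"] = t0 + nsteps * h, _["summary"] = summary, _["t"] = rt,
      _["hemo"] = hemo, _["valveQ"] = valveQ, _["corQ"] = corQ,
      _["eps"] = peps, _["sig"] = psig, _["sigact"] = psigact,
      _["qsub"] = qsub);
  if (record_level >= 2) out["imp"] = impRec;
  return out;
}

// Evaluate the model equations at one state: time derivatives of the
// differential states, algebraic residuals, and the main auxiliary
// quantities. Used by tests as an independent residual/consistency oracle.
// [[Rcpp::export]]
List cf_eval(List par, NumericVector y0, double t) {
  Model M(par);
  if ((int)y0.size() != M.N) stop("state length mismatch");
  Aux ax(M.P, M.S);
  std::vector<double> f(M.ND, 0.0), g(2 + M.P, 0.0);
  rhs(M, t, &y0[0], f.data(), g.data(), ax);
  return List::create(
      _["f"] = NumericVector(f.begin(), f.end()),
      _["g"] = NumericVector(g.begin(), g.end()),
      _["pLV"] = ax.pLV, _["pRV"] = ax.pRV, _["pLA"] = ax.pLA,
      _["pRA"] = ax.pRA, _["psa"] = ax.psa, _["psv"] = ax.psv,
      _["ppa"] = ax.ppa, _["ppv"] = ax.ppv, _["Pperi"] = ax.Pperi,
      _["Vtot"] = ax.Vtot, _["xm"] = NumericVector(ax.Vs_x, ax.Vs_x + 3),
      _["TmW"] = NumericVector(ax.TmW, ax.TmW + 3),
      _["eps"] = NumericVector(ax.eps.begin(), ax.eps.end()),
      _["sig"] = NumericVector(ax.sig.begin(), ax.sig.end()),
      _["sigact"] = NumericVector(ax.sigact.begin(), ax.sigact.end()),
      _["qv"] = NumericVector(ax.qv, ax.qv + 4),
      _["qsub"] = NumericVector(ax.qsub.begin(), ax.qsub.end()),
      _["imp"] = NumericVector(ax.imp.begin(), ax.imp.end()));
}

// Direct evaluation of the compartment tube law (for tests/diagnostics).
// [[Rcpp::export]]
NumericVector cf_tube_law(NumericVector V, double V0, double Vw, double k,
                          double p0, double fDil) {
  NumericVector out(V.size());
  for (int i = 0; i < (int)V.size(); ++i) {
    double t1 = std::pow((V[i] + 0.5 * Vw) / (fDil * V0 + 0.5 * Vw), k / 3.0);
    double u = std::pow(V[i] / (fDil * V0), 0.7) * std::pow(Vw / (fDil * V0), -0.4);
    double coll = u > 1.0 ? sq(u - 1.0) : 0.0;
    out[i] = p0 * (t1 - 1.0 - coll);
  }
  return out;
}
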