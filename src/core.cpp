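// Conductance-based DG-CA3 micro-network: cell right-hand sides, kinetic
// synapses and the fixed-step RK4 integrator.  All voltages in mV, time in
// ms, currents in uA/cm2, conductances in mS/cm2, capacitance in uF/cm2.
//
// Cell roster (fixed order): G (granule), DI (DG interneuron), mossy
// (Pinsky-Rinzel soma MS + dendrite MD), P (pyramidal), I (CA3 interneuron),
// O (O-LM).  Trace columns: 0=G 1=DI 2=MS 3=MD 4=P 5=I 6=O.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// x/(exp(x)-1) with the removable singularity at x=0 handled by its series.
static inline double f1(double x) {
  if (std::fabs(x) < 1e-4) return 1.0 - 0.5 * x + x * x / 12.0;
  return x / (std::exp(x) - 1.0);
}
static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// ---------------------------------------------------------------------------
// presynaptic transmitter drive and NMDA magnesium block
// ---------------------------------------------------------------------------
static const double DRIVE_VMID = 2.0;  // mV, sigmoid midpoint
static const double DRIVE_K    = 5.0;  // mV, sigmoid slope

// [[Rcpp::export]]
double drive_cpp(double v_pre) { return sigm((v_pre - DRIVE_VMID) / DRIVE_K); }

// [[Rcpp::export]]
double mg_block_cpp(double v, double mg) {
  if (mg < 0.0) stop("negative Mg concentration");
  return 1.0 / (1.0 + std::exp(-0.062 * v) * mg / 3.57);
}

// ---------------------------------------------------------------------------
// gating-rate functions
// ---------------------------------------------------------------------------
// Traub-Miles kinetics (granule, pyramidal, O-LM backbone)
static inline double tm_am(double V) { return 1.28 * f1(-(V + 54.0) / 4.0); }
static inline double tm_bm(double V) { return 1.40 * f1((V + 27.0) / 5.0); }
static inline double tm_ah(double V) { return 0.128 * std::exp(-(V + 50.0) / 18.0); }
static inline double tm_bh(double V) { return 4.0 * sigm((V + 27.0) / 5.0); }
static inline double tm_an(double V) { return 0.16 * f1(-(V + 52.0) / 5.0); }
static inline double tm_bn(double V) { return 0.5 * std::exp(-(V + 57.0) / 40.0); }
// muscarinic K (M-type) adaptation current of the pyramidal cell
static inline double m_winf(double V) { return sigm((V + 35.0) / 10.0); }
static inline double m_tauw(double V) {
  return 400.0 / (3.3 * std::exp((V + 35.0) / 20.0) + std::exp(-(V + 35.0) / 20.0));
}
// pyramidal-cell kinetics: reduced CA1 model with instantaneous Na
// activation, inactivating Na, delayed rectifier, A-current, persistent Na
// and a slow M-like K current (the burst/block switch of the cell)
static inline double py_minf(double V) { return sigm((V + 30.0) / 9.5); }
static inline double py_hinf(double V) { return sigm(-(V + 45.0) / 7.0); }
static inline double py_tauh(double V) { return 0.1 + 0.75 * sigm(-(V + 40.5) / 6.0); }
static inline double py_ninf(double V) { return sigm((V + 35.0) / 10.0); }
static inline double py_taun(double V) { return 0.1 + 0.5 * sigm(-(V + 27.0) / 15.0); }
static inline double py_pinf(double V) { return sigm((V + 41.0) / 3.0); }
static inline double py_ainf(double V) { return sigm((V + 50.0) / 20.0); }
static inline double py_binf(double V) { return sigm(-(V + 80.0) / 6.0); }
static const double PY_TAUB = 15.0;
static inline double py_zinf(double V) { return sigm((V + 39.0) / 5.0); }
static const double PY_TAUZ = 75.0;
// hyperpolarization-activated (h) current of the O-LM cell
static inline double o_rinf(double V) { return sigm(-(V + 84.0) / 10.2); }
static inline double o_taur(double V) {
  return 1.0 / (std::exp(-14.59 - 0.086 * V) + std::exp(-1.87 + 0.0701 * V));
}
// Wang-Buzsaki fast-spiking kinetics (DG and CA3 interneurons)
static inline double wb_am(double V) { return 1.0 * f1(-(V + 35.0) / 10.0); }
static inline double wb_bm(double V) { return 4.0 * std::exp(-(V + 60.0) / 18.0); }
static inline double wb_ah(double V) { return 0.07 * std::exp(-(V + 58.0) / 20.0); }
static inline double wb_bh(double V) { return sigm((V + 28.0) / 10.0); }
static inline double wb_an(double V) { return 0.1 * f1(-(V + 34.0) / 10.0); }
static inline double wb_bn(double V) { return 0.125 * std::exp(-(V + 44.0) / 80.0); }
// Pinsky-Rinzel kinetics on the shifted voltage u = V + 60 (rest near u = 0)
static inline double pr_am(double u) { return 1.28 * f1((13.1 - u) / 4.0); }
static inline double pr_bm(double u) { return 1.40 * f1((u - 40.1) / 5.0); }
static inline double pr_an(double u) { return 0.08 * f1((35.1 - u) / 5.0); }
static inline double pr_bn(double u) { return 0.25 * std::exp(0.5 - 0.025 * u); }
static inline double pr_ah(double u) { return 0.128 * std::exp((17.0 - u) / 18.0); }
static inline double pr_bh(double u) { return 4.0 * sigm((u - 40.0) / 5.0); }
static inline double pr_as(double u) { return 1.6 * sigm(0.072 * (u - 65.0)); }
static inline double pr_bs(double u) { return 0.1 * f1((u - 51.1) / 5.0); }
static inline double pr_ac(double u) {
  if (u <= 50.0) return std::exp((u - 10.0) / 11.0 - (u - 6.5) / 27.0) / 18.975;
  return 2.0 * std::exp((6.5 - u) / 27.0);
}
static inline double pr_bc(double u) {
  // the two branches meet at u = 50; guard the floating-point crossing
  if (u <= 50.0) return std::max(0.0, 2.0 * std::exp((6.5 - u) / 27.0) - pr_ac(u));
  return 0.0;
}
static inline double pr_aq(double ca) { return std::min(0.00002 * ca, 0.01); }
static inline double pr_bq(double) { return 0.001; }
static inline double pr_chi(double ca) { return std::min(ca / 250.0, 1.0); }

// [[Rcpp::export]]
NumericVector gate_rates_cpp(std::string kind, std::string gate, double v) {
  double a = NA_REAL, b = NA_REAL;
  bool tm = (kind == "G" || kind == "O");
  bool wb = (kind == "DI" || kind == "I");
  if (kind == "P") {
    double xi = NA_REAL, tx = NA_REAL;
    if (gate == "h") { xi = py_hinf(v); tx = py_tauh(v); }
    else if (gate == "n") { xi = py_ninf(v); tx = py_taun(v); }
    else if (gate == "b") { xi = py_binf(v); tx = PY_TAUB; }
    else if (gate == "z") { xi = py_zinf(v); tx = PY_TAUZ; }
    else if (gate == "m") { xi = py_minf(v); tx = 0.05; }  // instantaneous
    else if (gate == "p") { xi = py_pinf(v); tx = 0.05; }
    else if (gate == "a") { xi = py_ainf(v); tx = 0.05; }
    if (!NumericVector::is_na(xi)) { a = xi / tx; b = (1.0 - xi) / tx; }
  } else if (tm) {
    if (gate == "m") { a = tm_am(v); b = tm_bm(v); }
    else if (gate == "h") { a = tm_ah(v); b = tm_bh(v); }
    else if (gate == "n") { a = tm_an(v); b = tm_bn(v); }
    else if (gate == "r" && kind == "O") {
      double ri = o_rinf(v), tr = o_taur(v); a = ri / tr; b = (1.0 - ri) / tr;
    } else if (gate == "w" && kind == "O") {
      double wi = m_winf(v), tw = m_tauw(v); a = wi / tw; b = (1.0 - wi) / tw;
    }
  } else if (wb) {
    if (gate == "m") { a = wb_am(v); b = wb_bm(v); }
    else if (gate == "h") { a = wb_ah(v); b = wb_bh(v); }
    else if (gate == "n") { a = wb_an(v); b = wb_bn(v); }
  } else if (kind == "MS" || kind == "MD") {
    double u = v + 60.0;
    if (gate == "m") { a = pr_am(u); b = pr_bm(u); }
    else if (gate == "h") { a = pr_ah(u); b = pr_bh(u); }
    else if (gate == "n") { a = pr_an(u); b = pr_bn(u); }
    else if (gate == "s") { a = pr_as(u); b = pr_bs(u); }
    else if (gate == "c") { a = pr_ac(u); b = pr_bc(u); }
    else if (gate == "q") { a = pr_aq(v); b = pr_bq(v); }  // v is [Ca] here
  } else {
    stop("unknown cell kind '%s'", kind.c_str());
  }
  if (NumericVector::is_na(a))
    stop("unknown gate '%s' for cell kind '%s'", gate.c_str(), kind.c_str());
  return NumericVector::create(_["alpha"] = a, _["beta"] = b);
}

// ---------------------------------------------------------------------------
// per-cell right-hand sides
// ---------------------------------------------------------------------------
// param layouts (fixed order, mirrored in R/cells.R):
//   G : Cm gNa gK gL ENa EK EL Iext
//   P : Cm gNa gKdr gL ENa EK EL Iext gM gNaP gA
//   O : Cm gNa gK gL ENa EK EL Iext gh Eh gM
//   DI/I : Cm gNa gK gL ENa EK EL Iext phi
//   mossy : Cm gNa gKdr gCa gKC gKahp gLs gLd gc p ENa EK ECa EL Is Id

static void rhs_g(const double* y, double* dy, const double* p, double Isyn) {
  double V = y[0], m = y[1], h = y[2], n = y[3];
  double ion = p[1] * m * m * m * h * (V - p[4]) + p[2] * n * n * n * n * (V - p[5]) +
               p[3] * (V - p[6]);
  dy[0] = (-ion + p[7] - Isyn) / p[0];
  dy[1] = tm_am(V) * (1.0 - m) - tm_bm(V) * m;
  dy[2] = tm_ah(V) * (1.0 - h) - tm_bh(V) * h;
  dy[3] = tm_an(V) * (1.0 - n) - tm_bn(V) * n;
}

// state: V h n b z   (m, p, a gates instantaneous)
static void rhs_p(const double* y, double* dy, const double* p, double Isyn) {
  double V = y[0], h = y[1], n = y[2], b = y[3], z = y[4];
  double mi = py_minf(V);
  double n2 = n * n;
  double ai = py_ainf(V);
  double ion = p[1] * mi * mi * mi * h * (V - p[4]) +
               p[9] * py_pinf(V) * (V - p[4]) +
               p[2] * n2 * n2 * (V - p[5]) +
               p[10] * ai * ai * ai * b * (V - p[5]) +
               p[8] * z * (V - p[5]) + p[3] * (V - p[6]);
  dy[0] = (-ion + p[7] - Isyn) / p[0];
  dy[1] = (py_hinf(V) - h) / py_tauh(V);
  dy[2] = (py_ninf(V) - n) / py_taun(V);
  dy[3] = (py_binf(V) - b) / PY_TAUB;
  dy[4] = (py_zinf(V) - z) / PY_TAUZ;
}

static void rhs_o(const double* y, double* dy, const double* p, double Isyn) {
  double V = y[0], m = y[1], h = y[2], n = y[3], r = y[4], w = y[5];
  double ion = p[1] * m * m * m * h * (V - p[4]) + p[2] * n * n * n * n * (V - p[5]) +
               p[3] * (V - p[6]) + p[8] * r * (V - p[9]) + p[10] * w * (V - p[5]);
  dy[0] = (-ion + p[7] - Isyn) / p[0];
  dy[1] = tm_am(V) * (1.0 - m) - tm_bm(V) * m;
  dy[2] = tm_ah(V) * (1.0 - h) - tm_bh(V) * h;
  dy[3] = tm_an(V) * (1.0 - n) - tm_bn(V) * n;
  dy[4] = (o_rinf(V) - r) / o_taur(V);
  dy[5] = (m_winf(V) - w) / m_tauw(V);
}

static void rhs_wb(const double* y, double* dy, const double* p, double Isyn) {
  double V = y[0], h = y[1], n = y[2];
  double am = wb_am(V), bm = wb_bm(V);
  double minf = am / (am + bm);
  double ion = p[1] * minf * minf * minf * h * (V - p[4]) +
               p[2] * n * n * n * n * (V - p[5]) + p[3] * (V - p[6]);
  dy[0] = (-ion + p[7] - Isyn) / p[0];
  dy[1] = p[8] * (wb_ah(V) * (1.0 - h) - wb_bh(V) * h);
  dy[2] = p[8] * (wb_an(V) * (1.0 - n) - wb_bn(V) * n);
}

// two-compartment Pinsky-Rinzel mossy cell; y = Vs Vd h n s c q Ca
static void rhs_pr(const double* y, double* dy, const double* p,
                   double Isyn_s, double Isyn_d) {
  double Cm = p[0], gNa = p[1], gKdr = p[2], gCa = p[3], gKC = p[4], gKahp = p[5];
  double gLs = p[6], gLd = p[7], gc = p[8], pa = p[9];
  double ENa = p[10], EK = p[11], ECa = p[12], EL = p[13], Is = p[14], Id = p[15];
  double Vs = y[0], Vd = y[1], h = y[2], n = y[3], s = y[4], c = y[5], q = y[6],
         Ca = y[7];
  double us = Vs + 60.0, ud = Vd + 60.0;
  double am = pr_am(us), bm = pr_bm(us);
  double minf = am / (am + bm);
  double INa = gNa * minf * minf * h * (Vs - ENa);
  double IKdr = gKdr * n * (Vs - EK);
  double ICa = gCa * s * s * (Vd - ECa);
  double IKC = gKC * c * pr_chi(Ca) * (Vd - EK);
  double IKahp = gKahp * q * (Vd - EK);
  dy[0] = (-gLs * (Vs - EL) - INa - IKdr + (gc * (Vd - Vs) + Is - Isyn_s) / pa) / Cm;
  dy[1] = (-gLd * (Vd - EL) - ICa - IKC - IKahp +
           (gc * (Vs - Vd) + Id - Isyn_d) / (1.0 - pa)) / Cm;
  dy[2] = pr_ah(us) * (1.0 - h) - pr_bh(us) * h;
  dy[3] = pr_an(us) * (1.0 - n) - pr_bn(us) * n;
  dy[4] = pr_as(ud) * (1.0 - s) - pr_bs(ud) * s;
  dy[5] = pr_ac(ud) * (1.0 - c) - pr_bc(ud) * c;
  dy[6] = pr_aq(Ca) * (1.0 - q) - pr_bq(Ca) * q;
  dy[7] = -0.13 * ICa - 0.075 * Ca;
}

// Single-cell derivative, exposed for unit tests and step-refinement oracles.
// [[Rcpp::export]]
NumericVector cell_rhs_cpp(std::string kind, NumericVector state,
                           NumericVector params, double i_syn = 0.0,
                           double i_syn_dend = 0.0) {
  NumericVector out(state.size());
  if (kind == "G") rhs_g(state.begin(), out.begin(), params.begin(), i_syn);
  else if (kind == "P") rhs_p(state.begin(), out.begin(), params.begin(), i_syn);
  else if (kind == "O") rhs_o(state.begin(), out.begin(), params.begin(), i_syn);
  else if (kind == "DI" || kind == "I")
    rhs_wb(state.begin(), out.begin(), params.begin(), i_syn);
  else if (kind == "MS" || kind == "mossy")
    rhs_pr(state.begin(), out.begin(), params.begin(), i_syn, i_syn_dend);
  else stop("unknown cell kind '%s'", kind.c_str());
  out.names() = state.names();
  return out;
}

// ---------------------------------------------------------------------------
// network assembly and integration
// ---------------------------------------------------------------------------
static const int OFF_G = 0, OFF_DI = 4, OFF_M = 7, OFF_P = 15, OFF_I = 20,
                 OFF_O = 23, NCELL_STATE = 29;
static const int CELL_OFF[6] = {OFF_G, OFF_DI, OFF_M, OFF_P, OFF_I, OFF_O};

static inline double col_voltage(const double* y, int col) {
  switch (col) {
    case 0: return y[OFF_G];
    case 1: return y[OFF_DI];
    case 2: return y[OFF_M];
    case 3: return y[OFF_M + 1];
    case 4: return y[OFF_P];
    case 5: return y[OFF_I];
    default: return y[OFF_O];
  }
}

struct NetSpec {
  std::vector<std::vector<double>> pp;  // params: G DI mossy P I O
  std::vector<double> ed;               // edges, 9 doubles each
  int ne;
};

// edge layout: pre_col post_cell post_comp receptor g E alpha beta mg
static void net_deriv(const double* y, double* dy, const NetSpec& net) {
  double Isyn[6][2] = {{0.0, 0.0}, {0.0, 0.0}, {0.0, 0.0},
                       {0.0, 0.0}, {0.0, 0.0}, {0.0, 0.0}};
  for (int e = 0; e < net.ne; ++e) {
    const double* E = &net.ed[9 * e];
    double s = y[NCELL_STATE + e];
    double vpre = col_voltage(y, (int)E[0]);
    int post = (int)E[1], comp = (int)E[2], rec = (int)E[3];
    double vpost = (comp == 1) ? y[OFF_M + 1] : y[CELL_OFF[post]];
    double I = E[4] * s * (vpost - E[5]);
    if (rec == 1) I /= 1.0 + std::exp(-0.062 * vpost) * E[8] / 3.57;
    Isyn[post][comp] += I;
    double T = sigm((vpre - DRIVE_VMID) / DRIVE_K);
    dy[NCELL_STATE + e] = E[6] * T * (1.0 - s) - E[7] * s;
  }
  rhs_g(y + OFF_G, dy + OFF_G, net.pp[0].data(), Isyn[0][0]);
  rhs_wb(y + OFF_DI, dy + OFF_DI, net.pp[1].data(), Isyn[1][0]);
  rhs_pr(y + OFF_M, dy + OFF_M, net.pp[2].data(), Isyn[2][0], Isyn[2][1]);
  rhs_p(y + OFF_P, dy + OFF_P, net.pp[3].data(), Isyn[3][0]);
  rhs_wb(y + OFF_I, dy + OFF_I, net.pp[4].data(), Isyn[4][0]);
  rhs_o(y + OFF_O, dy + OFF_O, net.pp[5].data(), Isyn[5][0]);
}

// Fixed-step RK4 over the coupled cell+synapse system.  Records decimated
// traces, optional synaptic gating, and spike times (upward threshold
// crossing with a 2-ms refractory guard) at full step resolution.
// [[Rcpp::export]]
List integrate_network_cpp(List cell_params, NumericMatrix edges,
                           NumericVector y0, double dt, double duration_ms,
                           int record_every, bool record_syn,
                           double v_thresh, double refractory_ms) {
  NetSpec net;
  net.pp.resize(6);
  for (int i = 0; i < 6; ++i) {
    NumericVector p = cell_params[i];
    net.pp[i].assign(p.begin(), p.end());
  }
  net.ne = edges.nrow();
  net.ed.resize(9 * net.ne);
  for (int e = 0; e < net.ne; ++e)
    for (int j = 0; j < 9; ++j) net.ed[9 * e + j] = edges(e, j);

  const int nstate = NCELL_STATE + net.ne;
  if (y0.size() != nstate) stop("initial state has wrong length");
  long nstep = (long)std::ceil(duration_ms / dt - 1e-9);
  long nrec = nstep / record_every + 1;

  std::vector<double> y(y0.begin(), y0.end()), yt(nstate), k1(nstate), k2(nstate),
      k3(nstate), k4(nstate);
  // indices clamped to [0,1] after each step (gates and synaptic fractions)
  std::vector<int> gate_idx = {1, 2, 3, 5, 6, 9, 10, 11, 12, 13,
                               16, 17, 18, 19, 21, 22, 24, 25, 26, 27, 28};
  for (int e = 0; e < net.ne; ++e) gate_idx.push_back(NCELL_STATE + e);

  NumericMatrix traces(nrec, 7);
  NumericMatrix syn;
  if (record_syn) syn = NumericMatrix(nrec, net.ne);
  NumericVector time(nrec);
  std::vector<std::vector<double>> spikes(7);
  double vprev[7], last_spike[7];
  for (int c = 0; c < 7; ++c) {
    vprev[c] = col_voltage(y.data(), c);
    last_spike[c] = -1e9;
    traces(0, c) = vprev[c];
  }
  if (record_syn)
    for (int e = 0; e < net.ne; ++e) syn(0, e) = y[NCELL_STATE + e];
  time[0] = 0.0;

  bool ok = true;
  double err_time = NA_REAL;
  int err_cell = -1;
  long irec = 1;
  for (long step = 1; step <= nstep; ++step) {
    net_deriv(y.data(), k1.data(), net);
    for (int i = 0; i < nstate; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    net_deriv(yt.data(), k2.data(), net);
    for (int i = 0; i < nstate; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    net_deriv(yt.data(), k3.data(), net);
    for (int i = 0; i < nstate; ++i) yt[i] = y[i] + dt * k3[i];
    net_deriv(yt.data(), k4.data(), net);
    for (int i = 0; i < nstate; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    for (size_t gi = 0; gi < gate_idx.size(); ++gi) {
      double& v = y[gate_idx[gi]];
      if (v < 0.0) v = 0.0; else if (v > 1.0) v = 1.0;
    }
    if (y[OFF_M + 7] < 0.0) y[OFF_M + 7] = 0.0;  // calcium

    double t = step * dt;
    for (int c = 0; c < 7; ++c) {
      double v = col_voltage(y.data(), c);
      if (!std::isfinite(v) || std::fabs(v) > 200.0) {
        ok = false; err_time = t; err_cell = c;
        break;
      }
      if (vprev[c] < v_thresh && v >= v_thresh && t - last_spike[c] >= refractory_ms) {
        spikes[c].push_back(t);
        last_spike[c] = t;
      }
      vprev[c] = v;
    }
    if (!ok) break;
    if (step % record_every == 0) {
      time[irec] = t;
      for (int c = 0; c < 7; ++c) traces(irec, c) = col_voltage(y.data(), c);
      if (record_syn)
        for (int e = 0; e < net.ne; ++e) syn(irec, e) = y[NCELL_STATE + e];
      ++irec;
    }
  }
  if (irec < nrec) {  // aborted run: trim
    time = time[Range(0, std::max(irec - 1, 1L))];
    traces = traces(Range(0, std::max(irec - 1, 1L)), _);
    if (record_syn) syn = syn(Range(0, std::max(irec - 1, 1L)), _);
  }
  List sp(7);
  for (int c = 0; c < 7; ++c) sp[c] = NumericVector(spikes[c].begin(), spikes[c].end());
  List out = List::create(_["time"] = time, _["traces"] = traces, _["spikes"] = sp,
                          _["ok"] = ok, _["err_time"] = err_time,
                          _["err_cell"] = err_cell,
                          _["final_state"] = NumericVector(y.begin(), y.end()));
  if (record_syn) out["syn"] = syn;
  return out;
}
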