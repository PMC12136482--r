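#include <Rcpp.h>
#include "cell_core.h"
using namespace Rcpp;

static CellP as_cellp(const NumericVector& p) {
  CellP q;
  q.Cm = p["cm"]; q.tau_n = p["tau_n"];
  q.gCl = p["g0_Cl"]; q.gNa = p["g0_Na"]; q.gK = p["g0_K"];
  q.gNaL = p["gl_Na"]; q.gKL = p["gl_K"];
  q.rho = p["rho"]; q.gamma = p["gamma_ion"]; q.eps = p["epsilon"];
  q.beta = p["beta_vol"];
  q.Ki0 = p["K0_i"]; q.Ko0 = p["K0_o"]; q.Nai0 = p["Na0_i"]; q.Nao0 = p["Na0_o"];
  q.Cli0 = p["Cl0_i"]; q.Clo0 = p["Cl0_o"];
  q.C = p["C_nernst"]; q.K_bath = p["K_bath"];
  q.vm = p["v_m"]; q.sm = p["s_m"]; q.f_pump = p["f_pump"];
  return q;
}

// [[Rcpp::export(name = ".cell_currents_cpp")]]
NumericVector cell_currents_cpp(NumericVector state, NumericVector params) {
  CellP p = as_cellp(params);
  CellS s{state["V"], state["n"], state["dKi"], state["Kg"]};
  if (ISNAN(s.V) || ISNAN(s.n) || ISNAN(s.dKi) || ISNAN(s.Kg))
    stop("NaN in cell state");
  CellCur c;
  if (!cell_currents(s, p, c))
    stop("derived ion concentration is non-positive");
  return NumericVector::create(
      _["i_K"] = c.iK, _["i_Na"] = c.iNa, _["i_Cl"] = c.iCl, _["i_pump"] = c.ipump,
      _["E_K"] = c.EK, _["E_Na"] = c.ENa, _["E_Cl"] = c.ECl,
      _["K_i"] = c.Ki, _["K_o"] = c.Ko, _["Na_i"] = c.Nai, _["Na_o"] = c.Nao);
}

// [[Rcpp::export(name = ".cell_rhs_cpp")]]
NumericVector cell_rhs_cpp(NumericVector state, NumericVector params, double i_syn) {
  CellP p = as_cellp(params);
  CellS s{state["V"], state["n"], state["dKi"], state["Kg"]};
  CellCur c;
  if (!cell_currents(s, p, c))
    stop("derived ion concentration is non-positive");
  const double dV = (-(c.iK + c.iNa + c.iCl + c.ipump) + i_syn) / p.Cm;
  const double dn = (ninf_of(s.V) - s.n) / p.tau_n;
  const double dDK = -p.gamma * (c.iK - p.f_pump * c.ipump);
  const double dKg = p.eps * (p.K_bath - c.Ko);
  return NumericVector::create(_["V"] = dV, _["n"] = dn, _["dKi"] = dDK, _["Kg"] = dKg);
}

// Fixed-step trajectory.  i_syn may be empty (no drive) or one value per step.
// record_stride: keep every k-th sample (k >= 1); sample 0 is always kept.
// [[Rcpp::export(name = ".simulate_cell_cpp")]]
List simulate_cell_cpp(NumericVector params, double T, double dt,
                       NumericVector init, NumericVector i_syn,
                       int record_stride) {
  CellP p = as_cellp(params);
  CellS s{init[0], init[1], init[2], init[3]};
  const R_xlen_t n_steps = (R_xlen_t)std::llround(T / dt);
  const bool drive = i_syn.size() > 0;
  if (drive && i_syn.size() < n_steps)
    stop("i_syn must supply one value per step");
  const R_xlen_t n_rec = n_steps / record_stride + 1;
  NumericVector tv(n_rec), Vv(n_rec), nv(n_rec), dkv(n_rec), kgv(n_rec);
  R_xlen_t k = 0;
  for (R_xlen_t i = 0; i <= n_steps; ++i) {
    if (!(std::abs(s.V) <= 500.0) || ISNAN(s.n)) {
      stop("integration diverged at t = %f ms", (double)i * dt);
    }
    if (i % record_stride == 0) {
      tv[k] = (double)i * dt; Vv[k] = s.V; nv[k] = s.n; dkv[k] = s.dKi; kgv[k] = s.Kg;
      ++k;
    }
    if (i == n_steps) break;
    const double isyn_i = drive ? i_syn[i] : 0.0;
    if (!cell_step(s, p, isyn_i, dt))
      stop("ion concentration became non-positive at t = %f ms", (double)i * dt);
  }
  return List::create(_["t_ms"] = tv, _["V_mV"] = Vv, _["n"] = nv,
                      _["dKi_mM"] = dkv, _["Kg_mM"] = kgv);
}

// Upward threshold crossings with re-arm below threshold.
// [[Rcpp::export(name = ".detect_spikes_cpp")]]
NumericVector detect_spikes_cpp(NumericVector t, NumericVector V, double threshold) {
  std::vector<double> out;
  for (R_xlen_t i = 1; i < V.size(); ++i) {
    if (V[i] >= threshold && V[i - 1] < threshold) out.push_back(t[i]);
  }
  return wrap(out);
}
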