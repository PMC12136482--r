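#ifndef BRAINCOSIM_CELL_CORE_H
#define BRAINCOSIM_CELL_CORE_H

#include <cmath>

// Potassium-bath neuron: fast membrane (V, n) plus slow ion bookkeeping
// (dKi = internal K+ deviation, Kg = bath-buffer variable).
// Units package-wide: ms, mV, mM, uA/cm2, mS/cm2, uF/cm2.
struct CellP {
  double Cm;      // membrane capacitance (uF/cm2)
  double tau_n;   // K gating time constant (ms)
  double gCl;     // Cl conductance (mS/cm2)
  double gNa;     // max Na conductance (mS/cm2)
  double gK;      // max K conductance (mS/cm2)
  double gNaL;    // Na leak (mS/cm2)
  double gKL;     // K leak (mS/cm2)
  double rho;     // pump strength (uA/cm2)
  double gamma;   // current-to-flux conversion (mM cm2 / uC)
  double eps;     // bath exchange rate (1/ms)
  double beta;    // ICS/ECS volume ratio
  double Ki0, Ko0, Nai0, Nao0, Cli0, Clo0; // baseline concentrations (mM)
  double C;       // Nernst prefactor (mV)
  double K_bath;  // bath potassium (mM)
  double vm, sm;  // Na activation midpoint/slope (mV)
  double f_pump;  // K flux stoichiometry factor on the pump term
};

struct CellS {
  double V, n, dKi, Kg;
};

inline double ninf_of(double V) { return 1.0 / (1.0 + std::exp(-(19.0 + V) / 18.0)); }

struct CellCur {
  double iK, iNa, iCl, ipump;
  double Ki, Ko, Nai, Nao;
  double EK, ENa, ECl;
};

// Instantaneous current densities and derived concentrations.
inline bool cell_currents(const CellS& s, const CellP& p, CellCur& c) {
  c.Ki = p.Ki0 + s.dKi;
  c.Nai = p.Nai0 - s.dKi;
  c.Ko = p.Ko0 - p.beta * s.dKi + s.Kg;
  c.Nao = p.Nao0 + p.beta * s.dKi;
  if (c.Ki <= 0.0 || c.Ko <= 0.0 || c.Nai <= 0.0 || c.Nao <= 0.0) return false;
  c.EK = p.C * std::log(c.Ko / c.Ki);
  c.ENa = p.C * std::log(c.Nao / c.Nai);
  // chloride carries negative charge: reversal uses the inverted ratio
  c.ECl = p.C * std::log(p.Cli0 / p.Clo0);
  const double minf = 1.0 / (1.0 + std::exp(-(p.vm + s.V) / p.sm));
  const double h = 1.1 - 1.0 / (1.0 + std::exp(3.2 - 8.0 * s.n));
  c.iK = (p.gK * s.n + p.gKL) * (s.V - c.EK);
  c.iNa = (p.gNa * minf * h + p.gNaL) * (s.V - c.ENa);
  c.iCl = p.gCl * (s.V - c.ECl);
  c.ipump = p.rho / ((1.0 + std::exp(10.5 - 0.5 * c.Nai)) * (1.0 + std::exp(5.5 - c.Ko)));
  return true;
}

// One fixed step: forward Euler on V and the slow pair, exact exponential
// relaxation for the gating variable (first-order splitting).
// i_syn is the synaptic current density (positive = depolarizing), added to
// dV/dt as +i_syn/Cm.  Returns false if concentrations left the positive cone.
inline bool cell_step(CellS& s, const CellP& p, double i_syn, double dt) {
  CellCur c;
  if (!cell_currents(s, p, c)) return false;
  const double dV = (-(c.iK + c.iNa + c.iCl + c.ipump) + i_syn) / p.Cm;
  const double nf = ninf_of(s.V);
  const double dDK = -p.gamma * (c.iK - p.f_pump * c.ipump);
  const double dKg = p.eps * (p.K_bath - c.Ko);
  s.V += dt * dV;
  s.n = nf + (s.n - nf) * std::exp(-dt / p.tau_n);
  s.dKi += dt * dDK;
  s.Kg += dt * dKg;
  return true;
}

#endif
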