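#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sigmoidal firing-rate transfer H(x) = (a x - b) / (1 - exp(-d (a x - b)))
// with the removable singularity at a x = b evaluated as the limit 1/d.
inline double rate_H(double x, double a, double b, double d) {
  const double u = a * x - b;
  const double du = d * u;
  if (std::abs(du) < 1e-8) {
    // series: u / (1 - exp(-du)) = 1/d * 1 / (1 - du/2 + du^2/6 - ...)
    return 1.0 / (d * (1.0 - du / 2.0 + du * du / 6.0));
  }
  return u / (1.0 - std::exp(-du));
}

// [[Rcpp::export(name = ".rate_H_cpp")]]
NumericVector rate_H_cpp(NumericVector x, double a, double b, double d) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = rate_H(x[i], a, b, d);
  return out;
}

// Reduced Wong-Wang network on a delayed connectome, explicit Euler with a
// ring-buffer delay history.  State continuation: (S, hist, step) round-trips
// so an epoch-chunked run is bit-identical to a monolithic one.
//
// W:        weights matrix, W(I,K) = c_IK (row I receives from K)
// dsteps:   integer delay matrix in units of dt (>= 1 off-diagonal)
// hist:     H x N ring buffer of (substituted) S, row (step %% H) = S at step
// proxy_idx: 0-based region replaced by external activity, or -1
// proxy_vals: substituted activity (G_A * nu_P), one value per local step
//             0..n_steps (length n_steps + 1); ignored when proxy_idx < 0
// [[Rcpp::export(name = ".simulate_rww_cpp")]]
List simulate_rww_cpp(NumericMatrix W, IntegerMatrix dsteps,
                      NumericVector params, NumericVector S0,
                      NumericMatrix hist, double step0,
                      double T, double dt, int proxy_idx,
                      NumericVector proxy_vals, int record_stride,
                      bool clamp) {
  const int N = W.nrow();
  const int H = hist.nrow();
  const double a = params["a"], b = params["b"], d = params["d"];
  const double gamma_kin = params["gamma_kin"], tau_s = params["tau_s"];
  const double J_N = params["J_N"], I_0 = params["I_0"];
  const double omega = params["omega"], G = params["G"];

  const long long s0 = (long long)std::llround(step0);
  const long long n_steps = (long long)std::llround(T / dt);
  if (proxy_idx >= 0 && proxy_vals.size() < n_steps + 1)
    stop("proxy_vals must have one value per step (n_steps + 1)");

  NumericVector S = clone(S0);
  NumericMatrix Hst = clone(hist);
  const long long n_rec = n_steps / record_stride + 1;
  NumericMatrix Sout((int)n_rec, N), NUout((int)n_rec, N);
  NumericVector tout((int)n_rec);
  NumericVector nu_sum(N);

  // sparse edge list: iterate only existing connections
  struct Edge { int I, K, lag; double w; };
  std::vector<Edge> edges;
  for (int I = 0; I < N; ++I)
    for (int K = 0; K < N; ++K)
      if (K != I && W(I, K) != 0.0)
        edges.push_back(Edge{I, K, dsteps(I, K), W(I, K)});
  const double* hp = &Hst(0, 0);  // column-major, column K at hp + K*H

  long long k = 0;
  std::vector<double> x(N), nu(N), coupl(N);
  for (long long i = 0; i <= n_steps; ++i) {
    const long long s = s0 + i;
    const int cur = (int)(s % H);
    if (proxy_idx >= 0) {
      const double pv = proxy_vals[(R_xlen_t)i];
      Hst(cur, proxy_idx) = pv;
      S[proxy_idx] = pv;
    }
    std::fill(coupl.begin(), coupl.end(), 0.0);
    for (const Edge& e : edges) {
      const long long back = s - e.lag;
      const int row = (int)(back >= 0 ? back % H : ((back % H) + H) % H);
      coupl[e.I] += e.w * hp[(size_t)e.K * H + row];
    }
    for (int I = 0; I < N; ++I) {
      x[I] = omega * J_N * S[I] + G * J_N * coupl[I] + I_0;
      nu[I] = rate_H(x[I], a, b, d);
    }
    if (i % record_stride == 0) {
      tout[(int)k] = (double)s * dt;
      for (int I = 0; I < N; ++I) { Sout((int)k, I) = S[I]; NUout((int)k, I) = nu[I]; }
      ++k;
    }
    if (i < n_steps)
      for (int I = 0; I < N; ++I) nu_sum[I] += nu[I];
    if (i == n_steps) break;
    const int nxt = (int)((s + 1) % H);
    for (int I = 0; I < N; ++I) {
      double Snew = S[I] + dt * (-S[I] / tau_s + (1.0 - S[I]) * gamma_kin * nu[I]);
      if (clamp) {
        if (Snew < 0.0) Snew = 0.0;
        if (Snew > 1.0) Snew = 1.0;
      }
      S[I] = Snew;
      Hst(nxt, I) = Snew;
    }
  }
  return List::create(_["t_ms"] = tout, _["S"] = Sout, _["nu"] = NUout,
                      _["S_end"] = S, _["hist"] = Hst, _["step"] = (double)(s0 + n_steps),
                      _["nu_mean"] = nu_sum / (double)n_steps);
}

// Calcium-like per-cell activity filter: dC/dt = -C/tau + beta * sum delta(t - t_spike).
// Exact exponential decay between events; population mean returned per step.
// spk_cell 1-based; samples at t0 + j*dt for j = 0..n_steps.
// [[Rcpp::export(name = ".ca_filter_cpp")]]
List ca_filter_cpp(IntegerVector spk_cell, NumericVector spk_time, int N,
                   double tau, double beta, double t0, double dt,
                   double n_steps_d, NumericVector C0) {
  const long long n_steps = (long long)std::llround(n_steps_d);
  std::vector<double> C(C0.begin(), C0.end());
  if ((int)C.size() != N) stop("C0 must have length N");
  // order spikes by time
  std::vector<size_t> ord(spk_time.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a2, size_t b2) {
    return spk_time[a2] < spk_time[b2];
  });
  NumericVector trace(n_steps + 1), tout(n_steps + 1);
  size_t sp = 0;
  for (long long j = 0; j <= n_steps; ++j) {
    const double t_lo = t0 + (double)(j - 1) * dt;
    const double t_hi = t0 + (double)j * dt;
    if (j > 0) {
      const double dec = std::exp(-dt / tau);
      for (int c = 0; c < N; ++c) C[c] *= dec;
      while (sp < ord.size() && spk_time[ord[sp]] <= t_hi) {
        const double ts = spk_time[ord[sp]];
        if (ts > t_lo) {
          const int c = spk_cell[ord[sp]] - 1;
          if (c >= 0 && c < N) C[c] += beta * std::exp(-(t_hi - ts) / tau);
        }
        ++sp;
      }
    } else {
      // spikes exactly at the window start
      while (sp < ord.size() && spk_time[ord[sp]] <= t_hi) {
        const int c = spk_cell[ord[sp]] - 1;
        if (spk_time[ord[sp]] == t_hi && c >= 0 && c < N) C[c] += beta;
        ++sp;
      }
    }
    double m = 0.0;
    for (int c = 0; c < N; ++c) m += C[c];
    trace[(R_xlen_t)j] = m / (double)N;
    tout[(R_xlen_t)j] = t_hi;
  }
  return List::create(_["t_ms"] = tout, _["nu"] = trace, _["C_end"] = wrap(C));
}
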