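#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include "cell_core.h"
using namespace Rcpp;

// Spiking network of potassium-bath neurons with conductance-based
// single-exponential synapses.  Supports state continuation so the
// co-simulation loop can advance the network epoch by epoch; a run started
// from the initial state and chunked over epochs is bit-identical to a
// monolithic run.
//
// Internal spike deliveries use a ring of per-step buckets (broadcast +
// per-cell corrections for the all-to-all mode), so cost per step is O(N)
// plus O(targets) per spike for explicit adjacency.
//
// params_mat: one row per cell, columns in the fixed order produced by
//             R-side .cell_param_vector().
// events:     matrix (cell 1-based, time ms, g increment mS/cm2), absolute
//             times; gid 0 broadcasts to every cell.
// pending:    matrix (global step, cell 1-based or 0 = broadcast, g
//             increment) carried between calls.
// switch_t / switch_mode: connectivity changes at absolute times
//             (mode 0 = none, 1 = all-to-all, 2 = explicit adjacency).
// adj_ptr/adj_idx: CSR adjacency (0-based) used for mode 2.
// [[Rcpp::export(name = ".simulate_network_cpp")]]
List simulate_network_cpp(NumericMatrix params_mat, double T, double dt,
                          NumericMatrix state0, NumericVector gsyn0,
                          LogicalVector armed0, double step0,
                          NumericMatrix events, NumericMatrix pending,
                          double weight_scale, double tau_syn, double e_rev,
                          double syn_delay, double spike_threshold,
                          int conn_mode0,
                          NumericVector switch_t, IntegerVector switch_mode,
                          IntegerVector adj_ptr, IntegerVector adj_idx,
                          int record_stride) {
  const int N = params_mat.nrow();
  std::vector<CellP> P(N);
  for (int c = 0; c < N; ++c) {
    NumericMatrix::Row row = params_mat(c, _);
    CellP q;
    q.Cm = row[0]; q.tau_n = row[1]; q.gCl = row[2]; q.gNa = row[3]; q.gK = row[4];
    q.gNaL = row[5]; q.gKL = row[6]; q.rho = row[7]; q.gamma = row[8]; q.eps = row[9];
    q.beta = row[10]; q.Ki0 = row[11]; q.Ko0 = row[12]; q.Nai0 = row[13];
    q.Nao0 = row[14]; q.Cli0 = row[15]; q.Clo0 = row[16]; q.C = row[17];
    q.K_bath = row[18]; q.vm = row[19]; q.sm = row[20]; q.f_pump = row[21];
    P[c] = q;
  }
  std::vector<CellS> S(N);
  for (int c = 0; c < N; ++c)
    S[c] = CellS{state0(c, 0), state0(c, 1), state0(c, 2), state0(c, 3)};
  std::vector<double> g(gsyn0.begin(), gsyn0.end());
  std::vector<char> armed(N);
  for (int c = 0; c < N; ++c) armed[c] = armed0[c] ? 1 : 0;

  const long long s0 = (long long)std::llround(step0);
  const long long n_steps = (long long)std::llround(T / dt);
  const long long s_end = s0 + n_steps;
  const long long delay_steps = std::max<long long>(1, (long long)std::llround(syn_delay / dt));
  const double decay = std::exp(-dt / tau_syn);

  // ring of delivery buckets for steps [i, i + ring_size)
  const int ring_size = (int)delay_steps + 2;
  std::vector<std::vector<double> > ring((size_t)ring_size,
                                         std::vector<double>((size_t)N, 0.0));
  std::vector<double> ring_bcast((size_t)ring_size, 0.0);

  // carried-over deliveries and external events, sorted by step; entries
  // beyond the ring horizon stay in this list until reachable
  struct Ev { long long step; int cell; double inc; };
  std::vector<Ev> far;
  far.reserve((size_t)(pending.nrow() + events.nrow()));
  for (int i = 0; i < pending.nrow(); ++i)
    far.push_back(Ev{(long long)std::llround(pending(i, 0)),
                     (int)pending(i, 1), pending(i, 2)});
  for (int i = 0; i < events.nrow(); ++i) {
    long long st = (long long)std::llround(events(i, 1) / dt);
    if (st < s0) st = s0;
    far.push_back(Ev{st, (int)events(i, 0), events(i, 2)});
  }
  std::sort(far.begin(), far.end(),
            [](const Ev& a, const Ev& b) { return a.step < b.step; });
  size_t far_head = 0;

  int conn_mode = conn_mode0;
  std::vector<std::pair<long long, int> > switches;
  for (int i = 0; i < switch_t.size(); ++i)
    switches.push_back(std::make_pair((long long)std::llround(switch_t[i] / dt),
                                      switch_mode[i]));
  std::sort(switches.begin(), switches.end());
  size_t whead = 0;

  const long long n_rec = n_steps / record_stride + 1;
  NumericMatrix Vout((int)n_rec, N);
  NumericVector tout((int)n_rec);
  std::vector<int> sp_cell;
  std::vector<double> sp_time;

  long long k = 0;
  for (long long i = s0; i <= s_end; ++i) {
    while (whead < switches.size() && switches[whead].first <= i) {
      conn_mode = switches[whead].second; ++whead;
    }
    // move reachable far events into the ring
    while (far_head < far.size() && far[far_head].step < i + ring_size) {
      const Ev& e = far[far_head];
      if (e.step >= i) {
        const int slot = (int)(e.step % ring_size);
        if (e.cell == 0) ring_bcast[(size_t)slot] += e.inc;
        else ring[(size_t)slot][(size_t)(e.cell - 1)] += e.inc;
      }
      ++far_head;
    }
    // deliver this step's bucket
    const int cur = (int)(i % ring_size);
    if (ring_bcast[(size_t)cur] != 0.0) {
      const double b = ring_bcast[(size_t)cur];
      for (int c = 0; c < N; ++c) g[c] += b + ring[(size_t)cur][(size_t)c];
    } else {
      for (int c = 0; c < N; ++c)
        if (ring[(size_t)cur][(size_t)c] != 0.0) {
          g[c] += ring[(size_t)cur][(size_t)c];
        }
    }
    ring_bcast[(size_t)cur] = 0.0;
    std::fill(ring[(size_t)cur].begin(), ring[(size_t)cur].end(), 0.0);

    if ((i - s0) % record_stride == 0) {
      tout[(int)k] = (double)i * dt;
      for (int c = 0; c < N; ++c) Vout((int)k, c) = S[c].V;
      ++k;
    }
    if (i == s_end) break;
    for (int c = 0; c < N; ++c) {
      const double i_syn = g[c] * (e_rev - S[c].V);
      if (!(std::abs(S[c].V) <= 500.0))
        stop("cell %d diverged at t = %f ms", c + 1, (double)i * dt);
      if (!cell_step(S[c], P[c], i_syn, dt))
        stop("cell %d: ion concentration became non-positive at t = %f ms",
             c + 1, (double)i * dt);
      g[c] *= decay;
    }
    const long long dstep = i + 1 + delay_steps;
    const int dslot = (int)(dstep % ring_size);
    for (int c = 0; c < N; ++c) {
      if (armed[c] && S[c].V >= spike_threshold) {
        armed[c] = 0;
        sp_cell.push_back(c + 1);
        sp_time.push_back((double)(i + 1) * dt);
        if (conn_mode == 1) {
          ring_bcast[(size_t)dslot] += weight_scale;
          ring[(size_t)dslot][(size_t)c] -= weight_scale;  // no self-connection
        } else if (conn_mode == 2) {
          for (int j = adj_ptr[c]; j < adj_ptr[c + 1]; ++j)
            ring[(size_t)dslot][(size_t)adj_idx[j]] += weight_scale;
        }
      } else if (!armed[c] && S[c].V < spike_threshold) {
        armed[c] = 1;
      }
    }
  }

  // export leftover state: ring contents + unreached far events
  std::vector<Ev> left;
  for (int off = 0; off < ring_size; ++off) {
    const long long st = s_end + off;
    const int slot = (int)(st % ring_size);
    if (ring_bcast[(size_t)slot] != 0.0)
      left.push_back(Ev{st, 0, ring_bcast[(size_t)slot]});
    for (int c = 0; c < N; ++c)
      if (ring[(size_t)slot][(size_t)c] != 0.0)
        left.push_back(Ev{st, c + 1, ring[(size_t)slot][(size_t)c]});
    ring_bcast[(size_t)slot] = 0.0;  // each slot visited once
  }
  for (size_t j = far_head; j < far.size(); ++j) left.push_back(far[j]);
  NumericMatrix leftm((int)left.size(), 3);
  for (size_t j = 0; j < left.size(); ++j) {
    leftm((int)j, 0) = (double)left[j].step;
    leftm((int)j, 1) = left[j].cell;
    leftm((int)j, 2) = left[j].inc;
  }
  NumericMatrix stateN(N, 4);
  for (int c = 0; c < N; ++c) {
    stateN(c, 0) = S[c].V; stateN(c, 1) = S[c].n;
    stateN(c, 2) = S[c].dKi; stateN(c, 3) = S[c].Kg;
  }
  LogicalVector armedN(N);
  for (int c = 0; c < N; ++c) armedN[c] = armed[c] != 0;
  return List::create(
      _["t_ms"] = tout, _["V"] = Vout,
      _["spike_cell"] = wrap(sp_cell), _["spike_time"] = wrap(sp_time),
      _["state"] = stateN, _["gsyn"] = wrap(g), _["armed"] = armedN,
      _["step"] = (double)s_end, _["pending"] = leftm,
      _["conn_mode"] = conn_mode);
}
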