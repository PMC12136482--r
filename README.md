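# braincosim

Multi-scale co-simulation of seizure generation and whole-brain
propagation, self-contained in one R package.

## What it is for

Seizures start with cell-level biophysics — potassium accumulating around
neurons, pumps failing to keep up — and end as abnormal activity sweeping
across the whole brain.  `braincosim` is for modellers who want both ends
of that chain in one reproducible simulation:

* a **biophysical neuron** whose firing regime is set by the potassium
  concentration `K_bath` of the bath around it: resting state → spike
  train → tonic spiking → bursting → seizure-like events (SLE) →
  sustained ictal activity → depolarization block, as `K_bath` rises;
* **networks** of such neurons (healthy/pathological mixtures, exponential
  synapses);
* a **reduced Wong-Wang whole-brain model** on a weighted structural
  connectome with axonal delays;
* a **co-simulation loop** that replaces one brain region by the spiking
  network (a *proxy node*) and exchanges activity between the scales every
  epoch — the epoch being the smallest inter-region delay, so no causality
  is violated;
* **seizure analysis**: region-specific 55%-over-baseline recruitment,
  first-peak onsets, propagation-latency maps.

## The models in brief

Single cell (fast membrane + slow ion bookkeeping; units ms, mV, mM,
µA/cm², mS/cm²):

    cm dV/dt   = -(iK + iNa + iCl + ipump) + isyn
    dn/dt      = (n_inf(V) - n) / tau_n
    d dKi/dt   = -gamma (iK - 2 ipump)
    d Kg/dt    = epsilon (K_bath - Ko)

with `iX = gX (V - EX)`, `EX = C log(Xo/Xi)`, `gK = g0K n + glK`,
`gNa = g0Na m_inf(V) h(n) + glNa`, and the pump
`ipump = rho / ((1 + exp(10.5 - Nai/2)) (1 + exp(5.5 - Ko)))`.

Whole brain (one gating variable per region):

    dS_I/dt = -S_I/tau_s + (1 - S_I) gamma H(x_I)
    H(x)    = (a x - b) / (1 - exp(-d (a x - b)))
    x_I     = omega J_N S_I + G J_N sum_K c_IK S_K(t - tau_IK) + I_0

Coupling: spikes → rate through a calcium-like filter
(`dC/dt = -C/tau + beta sum delta(t - t_spike)`, population mean), scaled
by `G_A` into the proxy's gating slot; rate → spikes by Poisson event
counts with uniform timing per epoch.

## Worked example

Sweep the bath concentration and classify the firing regimes:

```r
library(braincosim)
sw <- regime_sweep(c(4, 7.5, 9.5, 12.5, 17, 17.5, 22.5))
sw
#>   K_bath   regime n_spikes
#> 1    4.0       RS        0
#> 2    7.5       RS        0
#> 3    9.5       TS       80
#> 4   12.5 BURSTING      234
#> 5   17.0      SLE      295
#> 6   17.5      SLE      295
#> 7   22.5       DB       38
```

Each row is a 10-s single-cell simulation: at 4 and 7.5 mM the cell stays
at rest; at 9.5 mM it spikes tonically through the end of the trace; at
12.5 mM spikes come in short clusters; at 17 and 17.5 mM it produces
recurrent multi-second seizure-like discharges separated by quiescence; at
22.5 mM the membrane locks at a depolarized plateau after an initial
discharge (depolarization block), and on a 0.5 mM grid the block first
appears at 22.5 mM, not at 20 mM.

Embed a pathological population into a synthetic whole-brain network and
map seizure propagation:

```r
cn  <- synthetic_connectome(n_regions = 98, seed = 1)
cfg <- cosim_config(
  proxy_region = "L1",
  network = network_config(N = 100, f = 0, K_bath_path = 17),  # all-SLE proxy
  T = 20000, seed = 1)
run <- run_cosim(cfg, cn, record_every_macro = 10L)

onsets <- seizure_onsets(run, baseline_window = c(6000, 10000),
                         search_window = c(10000, 20000),
                         exclude = run$proxy_region)
map <- propagation_map(onsets, source = names(which.min(onsets)))
head(map[map$recruited, ])
```

The proxy's recurrent seizure-like surges perturb every connected region;
regions whose activity rises at least 55% over their own baseline are
recruited, and `propagation_map()` reports their onset latencies relative
to the first recruited region.

## Layout

* `R/`, `src/` — implementation (cell, network, mass model, coupling,
  co-simulation, analysis, I/O); C++ kernels behind every integrator.
* `vignettes/multiscale-seizure-cosimulation.Rmd` — the methods vignette:
  model equations, parameter provenance and calibration, design choices,
  limitations.
* `inst/cli/braincosim.R` — command-line wrapper
  (`cell-sweep`, `cosim-run`, `analyze`).
* `tests/testthat/` — unit, property and acceptance tests.
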