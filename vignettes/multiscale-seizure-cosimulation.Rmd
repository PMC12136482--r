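---
title: "Multi-scale co-simulation of seizure generation and propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale co-simulation of seizure generation and propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braincosim)
```

## The modelling problem

Epileptic seizures are generated by biophysical processes at the scale of
single neurons — ion-channel gating, ion-concentration homeostasis, pump
failure — but are experienced and measured at the scale of the whole brain,
as abnormal activity that spreads along anatomical connections.  No single
model resolves both scales at once at acceptable cost.  `braincosim`
couples two well-understood models across that gap:

* a **microscopic scale**: a biophysical single-compartment neuron whose
  firing regime is controlled by the potassium concentration of the bath
  surrounding it, and networks of such neurons; and
* a **macroscopic scale**: a reduced Wong-Wang mean-field model, one
  synaptic gating variable per brain region, coupled through a weighted
  structural connectome with axonal transmission delays.

One connectome region (a *proxy*) is replaced by the spiking population;
spikes and region activity are translated across the boundary in both
directions, on a schedule that respects the smallest inter-region delay.
The package also ships the analysis layer (seizure detection and
propagation-latency mapping) and a synthetic connectome generator so the
entire pipeline runs self-contained.

## The potassium-bath neuron

The cell model couples fast Hodgkin-Huxley membrane dynamics to slow ion
bookkeeping.  The membrane equation is

$$ c_m \dot V = -(i_K + i_{Na} + i_{Cl} + i_{pump}) + i_{syn}, $$

with channel currents $i_X = g_X (V - E_X)$, Nernst potentials
$E_X = C \log(X_o / X_i)$ (chloride, carrying negative charge, uses the
inverted concentration ratio), conductances

$$ g_K = g_{0,K}\, n + g_{l,K}, \qquad
   g_{Na} = g_{0,Na}\, m_\infty(V)\, h(n) + g_{l,Na}, \qquad
   g_{Cl} = g_{0,Cl}, $$

and a Na/K exchange pump

$$ i_{pump} = \frac{\rho}{\bigl(1 + e^{10.5 - Na_i/2}\bigr)\bigl(1 + e^{5.5 - K_o}\bigr)}. $$

Sodium activation is treated as instantaneous, $m = m_\infty(V)$, and
inactivation is slaved to the potassium gate through
$h(n) = 1.1 - 1/(1 + e^{3.2 - 8n})$ — an expression of the empirical
observation that $h + n$ is approximately conserved.  The single gating
variable relaxes as $\dot n = (n_\infty(V) - n)/\tau_n$ with
$n_\infty(V) = 1/(1 + e^{-(19 + V)/18})$.

The slow subsystem tracks two variables: the internal potassium deviation
$\Delta K_i$ and a bath-buffer variable $K_g$,

$$ \dot{\Delta K_i} = -\gamma\,(i_K - 2\, i_{pump}), \qquad
   \dot K_g = \varepsilon\,(K_{bath} - K_o), $$

with all six concentrations derived by bookkeeping
($K_i = K_{0,i} + \Delta K_i$, $Na_i = Na_{0,i} - \Delta K_i$,
$K_o = K_{0,o} - \beta \Delta K_i + K_g$, $Na_o = Na_{0,o} + \beta
\Delta K_i$; chloride is held at baseline).  The factor 2 on the pump term
is its K$^+$ stoichiometry (2 K$^+$ in per cycle); it is exposed as
`f_pump` in `cell_params()`.  Because the bookkeeping is algebraic,
$Na_i + \Delta K_i$ and $K_i - \Delta K_i$ are conserved exactly — the
tests assert this to machine precision.

### The control parameter and the regime sequence

The bath concentration `K_bath` is the single dial.  The canonical
progression under increasing bath potassium is: resting state (RS) →
transient spike train (ST) → tonic spiking (TS) → bursting → seizure-like
events (SLE) → sustained ictal activity (SIA) → depolarization block (DB),
with the block first appearing near 22.5 mM (not 20 mM) on a 0.5 mM grid.
With the calibrated defaults a 10-s sweep over the reference values gives

| `K_bath` (mM) | regime with default parameters |
|---|---|
| 4.0 | resting state |
| 7.5 | resting state |
| 9.5 | tonic spiking |
| 12.5 | bursting |
| 17.0 | seizure-like events |
| 17.5 | seizure-like events |
| 22.5 | depolarization block (first on the 0.5 mM grid) |

The two narrow border regimes — the transient spike train between rest and
tonic firing, and sustained ictal activity between seizure-like events and
block — are not expressed by this parameter set: its rest band extends to
7.5 mM and its seizure-like band covers 17.5 mM.  The classifier
recognizes all seven patterns (exercised on constructed traces in the
tests); reproducing the two border regimes at exactly the reference bath
values is a known limitation of the calibration, recorded below.

### Choice of the numeric constants

The published form of this model prints its equations but not its full
parameter table, and the reference implementation it points to was not
available when this package was written.  The defaults in `cell_params()`
were therefore **calibrated against the regime sequence itself**, which is
the behaviour the model exists to produce, in two stages:

1. *Structure.* At the slow-subsystem equilibrium the bath equation forces
   $K_o = K_{bath}$ and the flux balance forces $i_K = 2 i_{pump}$; the
   equilibrium is therefore independent of the rate constants $\gamma$ and
   $\varepsilon$.  Conductances, pump strength and baseline concentrations
   were selected so that the full system's equilibrium is stable and
   hyperpolarized at 4 mM (rest), unstable between ~9 and ~22 mM
   (sustained activity), and stable-depolarized first at 22.5 mM on a
   0.5 mM grid (depolarization block) — established by eigenvalue analysis
   of the 4-D Jacobian along the equilibrium branch.
2. *Dynamics.* $\gamma$ and $\varepsilon$ (with small adjustments of the
   remaining constants inside the structural constraints) were then tuned
   so that simulated 10-s traces, classified by the package's own
   `classify_regime()` rules, reproduce the full sequence above.

This is a deliberate design choice: the parameter set is *defined* by the
phenomenology, not copied from a table, and the regime sweep is its
acceptance test.  Anyone replacing the defaults with the original
published values should expect the same qualitative sequence.

### Integration and initial conditions

A fixed-step first-order split is used, mirroring the cable-equation
solvers this model family is usually run under: explicit Euler for the
membrane potential and the two slow variables, an exact exponential
relaxation step for the gating variable (which is the stiffest state).
The default step is 0.025 ms; halving it changes the membrane trajectory
at 1 s by well under a millivolt (asserted in the tests).  Initial
conditions are the resting point of the fast subsystem at baseline
concentrations ($\Delta K_i = K_g = 0$, $n = n_\infty(V)$), found by
bisection on the total membrane current.

### Regime classification

`classify_regime()` applies a fixed decision tree to the spike pattern
(threshold crossings at −25 mV, re-armed below threshold) after discarding
the first second: resting and depolarization block are separated by the
trailing mean potential (below −50 mV vs above −40 mV) and the absence of
spikes (entirely, vs in the final half); a transient spike train is
spiking confined to the leading 30%; seizure-like events are spike
clusters of at least 1 s separated by at least 1 s of quiescence; bursting
is a bimodal inter-spike-interval distribution (clusters split at three
times the median intra-cluster interval, all clusters shorter than 1 s);
tonic spiking persists to the end with an ISI coefficient of variation
below 0.3; sustained ictal activity persists without 1-s quiescence at an
elevated potential.  All thresholds are exposed in `regime_criteria()`.
Traces shorter than 10 s are refused rather than misclassified.

## The spiking network

`build_network()` assembles $N$ cells, the first $\mathrm{round}(fN)$
"healthy" (default bath 9.5 mM, tonic) and the rest "pathological"
(default 17 mM, seizure-like).  Synapses are conductance-based with a
single-exponential decay: each delivered spike increments the target's
synaptic conductance by `weight * weight_scale` (mS/cm²), which then
decays with `tau_syn` (default 2 ms, a common default for exponential
synapses in spiking simulators); the synaptic current is
$g_{syn}(E_{rev} - V)$ with $E_{rev} = 0$ mV (excitatory).  The published
network prints only the weight $w = 0.5$; whether its synapses were
current- or conductance-based is unstated, and we chose conductance-based
(the saturating, voltage-dependent variant) — the choice is flagged here
because at strongly depolarized potentials the two differ.  The absolute
conductance scale `weight_scale` is calibrated so that the mixed
80%/20% population, connected all-to-all at $t = 5$ s after 5 s of
disconnected evolution, locks onto the pathological slow rhythm with
clearly increased pairwise spike-train synchrony — the entrainment
experiment reproduced in the acceptance suite.  The internal transmission
delay (1 ms) is likewise unprinted and config-exposed.

## The mass model

Each region carries one synaptic gating variable $S_I \in [0,1]$:

$$ \dot S_I = -\frac{S_I}{\tau_s} + (1 - S_I)\, \gamma\, H(x_I), \qquad
   H(x) = \frac{a x - b}{1 - e^{-d(ax - b)}}, $$

$$ x_I = \omega J_N S_I + G J_N \sum_K c_{IK}\, S_K(t - \tau_{IK}) + I_0, $$

with the canonical constants ($a = 0.27$ nC⁻¹, $b = 0.108$ kHz, $d = 154$
ms, $\gamma = 0.641$, $\tau_s = 100$ ms, $J_N = 0.2609$ nA, $I_0 = 0.33$
nA, $\omega = 1$, $G = 0.096$).  The removable singularity of $H$ at
$ax = b$ is evaluated by series expansion (limit $1/d$); the tests pin it
to $10^{-9}$ relative accuracy.  Delays are tract lengths divided by a
conduction speed (default 3 mm/ms); they are discretized to the nearest
integration step, zero delays are replaced by one step, and the
integration step must evenly divide the smallest inter-region delay
$\tau_{min}$ — a hard error otherwise, because the co-simulation epoch
equals $\tau_{min}$.  Integration is explicit Euler (0.1 ms by default)
over a ring-buffer delay history, with $S$ clamped to $[0,1]$ after each
step to guard against Euler overshoot.  The model is deterministic: the
printed equations carry no noise term, and none is added.  Rates are kHz
and times ms throughout; any Hz conversion happens at I/O boundaries
only.

## Crossing the scales

**Spikes to rates.** Two converters are provided.  Binning counts spikes
in windows of `bin_width` and normalizes by cell count and width,
giving a per-cell rate in kHz; it is exact but rough for small
populations.  The calcium-filter converter integrates, per cell,
$\dot C_p = -C_p/\tau + \beta \sum \delta(t - t_{spike})$ (defaults
$\tau = 100$ ms, $\beta = 0.1$) and averages over the population —
a smooth trace, and the default.  With a per-spike increment of $\beta$
*per cell* and a population mean, both converters are invariant under
population size for per-cell-identical activity; the printed form
"$\beta = 0.1 N$" would cancel against the population mean and break that
stated invariance, so the per-cell reading is implemented ($\beta$ is
config-exposed).

**Rates into the mass model.** The proxy's activity enters every other
region's coupling sum in place of its gating variable, scaled by a local
factor $G_A$ (default 100): the substituted slot value is $G_A \nu_P(t)$.
Substitution into the $S$-slot (rather than through $H$ first) was chosen
because the coupling sum consumes gating variables, not rates.

**Rates to spikes.** For each region $I$ with inbound weight $c_{PI} > 0$
onto the proxy, the event count in an epoch is drawn Poisson with mean
$\mathrm{gain} \cdot c_{PI} \cdot \nu_I \cdot \Delta t_{epoch}$, event
times i.i.d. uniform over the epoch, each event dispatched to every proxy
cell after the per-connection delay.  The functional form linking rates
to event counts is genuinely underdetermined (it depends on the region
model); Poisson-with-uniform-timing is this package's default, exposed as
a seam, not a claim.

## The epoch schedule

Every inter-region influence is delayed by at least $\tau_{min}$, so both
simulators can advance one epoch of length $\tau_{min}$ independently;
data crosses the boundary only at epoch ends.  `validate_schedule()`
rejects epochs longer than $\tau_{min}$ and steps that do not divide the
epoch.  Event generation for epoch $k$ uses the previous epoch's mean
rate per region; each (source region, epoch) pair draws from its own
deterministically derived RNG stream, so results are independent of
evaluation order and bit-reproducible from the base seed.  The orchestrator
runs single-process; the exchange contract (what crosses, and when) is the
part a distributed backend would have to preserve.

Three decoupling identities anchor the implementation, all asserted
bitwise in the tests: an unconnected network equals isolated cells; an
epoch-chunked mass-model run equals a monolithic one; a co-simulation
whose proxy has zero in/out weights equals the two standalone runs.
They hold because the network and single-cell integrators share one
C++ step kernel, and the mass-model state (gating, ring buffer, step
counter) round-trips exactly across epoch boundaries.

## Seizure detection and propagation

A region is *recruited* when its activity exceeds its own baseline
(mean over a configured post-transient window) by at least 55%
(`rel_threshold = 0.55`); the onset is the first local maximum above that
level, by three-point comparison on the sampled trace — the first peak,
not the largest.  Detection is scale-invariant, and raising the threshold
can only shrink the recruited set (both property-tested).  Region-specific
sensitivity comes from per-region baselines under a shared relative
threshold; per-region overrides are possible.  No smoothing is applied by
default; an optional moving average is exposed.  `propagation_map()`
reports each region's onset latency relative to a source region, with
non-recruited regions flagged.

## The synthetic connectome

`synthetic_connectome()` emulates the gross statistics of a ~100-region
mammalian structural connectome: 98 regions by default, log-normal
weights, uniform positive tract lengths (3–60 mm), ~30% density, and
mirrored left/right hemisphere blocks (the real atlas this stands in for
has symmetric inter-hemispheric connections).  Tract lengths are drawn on
a 0.3 mm grid so that delays are exact multiples of the conventional
0.1 ms step.  What it does **not** emulate: spatial embedding (no
distance-dependent weight decay), hub structure, or the true weight-delay
correlations of a measured connectome.  Passing tests on this surrogate
demonstrates that the machinery — exchange, recruitment, latency ordering
— behaves correctly, not that any particular biological propagation
pattern is predicted; runs on a real connectome remain the scientific
use case, and the reader format (`read_connectome()`) accepts the usual
weights/tract-lengths text layout directly.

## Problem sizes and determinism

The shipped experiments use a 100-cell proxy on a 98-region synthetic
connectome over 20 s of biological time, and 10-s single-cell sweeps —
sizes chosen so the full acceptance suite recomputes everything from
scratch in minutes on a single core while exercising every code path at
meaningful scale.  The published experiment this emulates used a 10⁴-cell
proxy on a measured atlas connectome; nothing in the code limits those
sizes, only wall-clock time.  All stochastic steps (synthetic connectome,
event generation) consume named seeds recorded in the run manifest, and
every simulation is otherwise deterministic, so any run is reproducible
bitwise from its manifest.

## Known limitations

* The cell parameter set is a calibrated reconstruction (see above); it
  reproduces the regime phenomenology but individual constants should not
  be quoted as measurements.
* The transient-spike-train and sustained-ictal-activity border regimes are
  not expressed at the reference bath values by the default set (see the
  table above); the classifier supports them, and a parameter set that
  shows all seven bands at once was not found within the structural
  constraints (rest at 4 mM, block first at 22.5 mM, tonic/bursting/SLE at
  their reference values) during calibration.
* Synapse kinetics (conductance-based, 2 ms decay) and the rate-to-event
  law are stated defaults for underdetermined components.
* Single proxy region per run; compound multi-simulator configurations
  are out of scope.
* No inhibitory subpopulations, plasticity, multi-compartment morphology,
  or BOLD forward model.
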