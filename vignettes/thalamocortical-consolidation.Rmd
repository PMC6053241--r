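---
title: "Sleep-stage dynamics and sequence consolidation in a thalamocortical network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep-stage dynamics and sequence consolidation in a thalamocortical network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tcsleep)
```

## The model

`tcsleep` simulates a one-dimensional thalamocortical network of four
populations: 500 cortical pyramidal cells (PY), 100 cortical inhibitory
interneurons (IN), 100 thalamic relay cells (TC) and 100 reticular
thalamic cells (RE). Cortical cells are two-compartment
conductance-based models (a large dendrite carrying leak, potassium
leak, persistent sodium, slow potassium, calcium-activated potassium
and high-threshold calcium currents, and a tiny axosomatic compartment
with high-density fast sodium/potassium currents). Because the
axosomatic conductances are two orders of magnitude larger than the
dendritic ones, the somatic membrane equation degenerates to an
algebraic current balance: the soma voltage is the root of
`0 = -g(V_S - V_D) - I_Na - I_K - I_Na(p)`, which is solved in closed
form at every evaluation (all axosomatic currents are ohmic in `V_S`
once the gating variables are carried as state). Thalamic cells are
single-compartment models with fast spike currents, the low-threshold
calcium current `I_T` (the burst generator), and — in TC cells only —
the hyperpolarization-activated cation current `I_h`.

Synapses are transmitter-gated first-order kinetic schemes (AMPA, NMDA
with a sigmoidal magnesium block, GABA-A) plus the G-protein cascade
for GABA-B. Connectivity is local and flat: each target receives from
all sources within a fixed radius on the chain, with the printed total
conductance divided equally among afferents, so boundary neurons keep
the same total synaptic input. Spontaneous miniature PSPs (minis) on
the cortical projections follow a time-dependent Poisson process whose
rate recovers after each presynaptic spike as
`mu(t) = (2/(1+exp(-(t-t0)/30)) - 1)/250` per ms and saturates at
4 Hz per synapse.

### Vigilance stages

The three simulated stages — awake, N2 and N3 — differ only through
neuromodulator scaling: acetylcholine sets the potassium-leak factor
per cell kind (PY/IN 0.133/0.228/0.38; TC 0.4/0.96/1.6; RE
0.9/0.81/0.45 for awake/N2/N3) and the AMPA strength of cortical and
thalamocortical projections (PY source: 0.133/0.1938/0.4332; TC
source: 0.6/0.72/1.2); GABA level scales the GABA-A strength of IN and
RE projections; histamine shifts the `I_h` activation midpoint
(-24/-2/-1 mV). Stage switches are instantaneous parameter swaps.
These factors move the thalamus through its classic functional
regimes: TC cells rest near -60 mV awake (relay mode), near -67 mV in
N2 (the spindle-generating zone of partially de-inactivated `I_T`) and
near -78 mV in N3.

### Plasticity

Cortical PY-to-PY AMPA synapses (and their mini amplitudes, at the
slow factor f = 0.01) are plastic under a symmetric STDP rule:
`F(dt) = A+ exp(-|dt|/20)` for pre-before-post and `-A- exp(-|dt|/20)`
otherwise, with `A+ = A- = 0.002` in awake and N2, halved to 0.001 in
N3. Updates use nearest-neighbour pairing at spike time,
`g <- g + g_max F(dt)` with `g_max` the unnormalized projection
conductance (0.24 uS), and weights are clipped to [0, 200%] of their
initial value — both the clip and the symmetric window prevent runaway
dynamics while letting ordered firing imprint a direction.

## Numerical scheme

The network is integrated with fixed-step RK4 at dt = 0.02 ms. Rate
functions are tabulated on a 0.05 mV grid with linear interpolation;
the exported single-cell operations evaluate the same kinetics
directly. Spikes are registered on upward zero crossings of the
axosomatic (cortical) or membrane (thalamic) voltage with a 2 ms
refractory. Minis and the background process are sampled by thinning
against their constant-rate envelopes and deposited as instantaneous
increments on per-target decaying conductances; stimuli enter as
step-constant current densities. Gating variables are clamped to
[0, 1] after each step (roundoff protection); the integration aborts
with a diagnostic if any voltage exceeds 500 mV in magnitude.

## Adopted kinetics and their free placements

The per-current rate functions are not part of the printed parameter
set; the package adopts the canonical kinetics of the model lineage
(Mainen-style cortical channels, Traub-style thalamic spike currents,
the classical relay/reticular low-threshold calcium currents, the
McCormick-style h-current) and records every formula in
`src/kinetics.h`. Four placements are genuinely free and were fixed by
the package after a stability analysis of the instantaneous-soma
reduction; they are exposed as cell parameters:

* the cortical delayed rectifier half-activation sits at +5 mV
  (`kv_mid`): much lower and its subthreshold tail loads the resting
  cell; much higher and the sodium window current stabilizes a
  spurious depolarized equilibrium near -30 mV;
* steady-state sodium inactivation uses a 5 mV slope so the window
  current stays small above -40 mV;
* the persistent-sodium maximal open fraction (`nap_max`, 0.012)
  keeps the dendritic current balance monotonic (no intrinsic
  latch-up) while still amplifying depolarizations;
* thalamic spike kinetics are threshold-shifted (`V_tr = -55`) with
  the delayed rectifier activated 15 mV earlier (`V_trK = -70`);
  without the separate potassium placement, the printed 7.5:1
  gNa:gK ratio leaves a stable sodium-window block state ~18 mV above
  threshold that silences bursting thalamic cells.

The TC h-current additionally carries the canonical calcium-regulated
open/locked-open scheme (a calcium-bound messenger locks open channels
at double conductance). This slow positive-then-negative feedback is
what groups spindle-band activity into discrete waxing-waning events
with a seconds-scale refractory period instead of a continuous
oscillation.

## Background drive

Two noise sources drive spontaneous activity. The printed miniature
PSP process perturbs cortical synapses: amplitudes (0.2 mV at the
awake baseline) are converted to conductance increments through the
local input resistance of the dendritic compartment using a
charge-based conversion (`dg = A C_m / (drive tau_syn)`), and are
scaled across stages by the AMPA/GABA factor of their projection
relative to the awake factor. With the adopted kinetics the pyramidal
rest-to-threshold gap is close to 20 mV, which subthreshold mini
summation cannot bridge at a realistic rate; spontaneous firing and
Down-to-Up ignition therefore additionally require sparse
suprathreshold background inputs (`background_hz`, default 0.4 Hz per
PY cell; amplitude equivalent to a 30 mV PSP) modelling afferents from
cortex outside the simulated patch. This is the package's own
background-activity model: it fixes the rate of candidate ignition
events, while the stage-dependent synaptic factors decide whether an
ignition stays local (awake, N2) or recruits a travelling network wave
(N3, where AMPA is 3.3 times the awake strength).

## What the synthetic raster generator emulates

`generate_fixture()` produces spike rasters with planted ordered group
activations (configurable inter-group lag, per-spike jitter,
activation times) over homogeneous Poisson background. This is the
minimal structure the analysis chain assumes — it lets the string
match, recall detection, replay chaining, spatial correlation and
cluster analyses be tested against known ground truth without running
the simulator. It does not emulate oscillatory structure, refractory
periods, spatially graded correlations or rate inhomogeneity, so
passing fixture tests demonstrates correctness of the measurement
algorithms, not realism of the simulated dynamics; the regime-level
assertions run on simulated records instead.

## Analysis conventions

* String match: duplicates are collapsed to the first occurrence and
  labels outside the ideal alphabet dropped before scoring;
  normalization divides by twice the ideal-sequence length.
* Recall detection smooths each group's mean rate with a Gaussian
  kernel of 50 ms window (sd = 12.5 ms) on a 1 ms grid and orders
  groups by peak time.
* Replay chaining rejects links with |dt| > 50 ms and carries the
  previous anchor forward; group times average the accepted spikes;
  both the per-leading-spike and the per-detected denominators are
  reported.
* Spatial correlation convolves each train with a Gaussian kernel
  (1000 ms window, sd = 5 ms), computes the Pearson correlation
  maximized over lags up to 100 ms within each event epoch (so
  identical trains score 1 and the measure is symmetric and
  shift-invariant), samples up to 30 evenly spaced pairs per distance,
  and averages over pairs and epochs. The large-distance plateau is
  the mean over distances >= 50.
* Cluster analysis smooths the (neuron x time) activity with a
  separable 2-D Gaussian kernel (sd = 2 neurons x 10 ms, 2 ms bins),
  binarizes at 50% of the segment maximum, labels 8-connected
  components, and optionally merges co-occurring clusters separated by
  fewer than 5 neurons (the monosynaptic radius). Kernel widths and
  threshold are exposed as arguments.
* Spindle epochs: 7-14 Hz envelope (100 ms RMS) above mean + 2 sd
  with hysteresis, 0.3-3.5 s duration, gaps under 250 ms merged (the
  strict threshold keeps only genuine waxing-waning bursts, at the
  physiological few-per-minute density). Up states: smoothed
  population rate above 50% of its 95th percentile for >= 100 ms —
  an Up state of the slow oscillation engages a large part of the
  population, so only strong network-wide excursions qualify.
* Cross-correlation normalization: unit-energy without mean removal
  (the classic signal-processing convention; identical trains score
  1, an active/silent pair 0); a Pearson variant (mean-removed, so
  independent trains decay to 0) is available via `normalize`.
* Consolidation probability: fraction of replicates whose mask-mean
  relative weight change has a positive linear trend over the final
  100 s of sleep.

## Problem sizes and run times

Full-design runs (500 PY, hundreds of seconds of biological time,
10 seeds) are hours-scale on one core. The package's own tests and the
acceptance script therefore run the generator-defined conditions at
reduced scale — populations scaled to 12-30% (the trained span and the
analysis distances scale with the network), segments of 12-30 s, and
single seeds — which preserves the sign and ordering of every headline
contrast while shrinking magnitudes and raising seed-to-seed variance;
the reported problem size accompanies every computed number. The
`scale` knob of `experiment_preset()` makes the same trade explicit for
user experiments. One property is known to shrink more than
proportionally: the large-distance coordination during slow-oscillation
Up states, whose wave recruitment is less complete in small networks
than at full scale.

## A worked experiment

```{r}
preset <- experiment_preset("fig3_n3_only", scale = 0.1,
                            populations = c(PY = 200, IN = 40,
                                            TC = 40, RE = 40))
res <- run_preset(preset, seeds = 1:2, snapshot_ms = 5000)
print(res)
```

The result bundles per-seed recall performance at the three test
sessions (baseline, after training, after sleep), replay counts inside
the sleep block and the trajectory of the trained-direction mean
synaptic weight.

## Known limitations

* Trace-level voltage identity with the original implementation of
  this model family is out of scope; the acceptance surface is
  regime-level statistics (rates, spindle density, slow-oscillation
  frequency, correlation structure, recall contrasts).
* The background-input process is exogenous; consequently the
  dependence of the awake rate on the mini amplitude is weaker than in
  a fully mini-driven cortex.
* Short-term synaptic depression, gap junctions and non-flat
  connectivity profiles are not modelled.
* Stage transitions are instantaneous parameter swaps; no N1 or REM.
```
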