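# tcsleep

Conductance-based simulation of sleep-dependent memory consolidation in
a thalamocortical network, with the complete measurement toolkit for
sequence-recall experiments.

## The scientific problem

During non-REM sleep the cortex expresses two hallmark rhythms: sleep
spindles (7–14 Hz waxing–waning bursts, stage N2) and the slow
oscillation (< 1 Hz alternation of active Up and silent Down states,
stage N3). Both are candidate substrates for consolidating memories
acquired in the awake state: spike sequences trained during waking are
replayed spontaneously during these rhythms, and spike-timing-dependent
plasticity (STDP) converts replay into directed synaptic change.
`tcsleep` implements the standard modelling framework for this
question: a one-dimensional thalamocortical network (pyramidal PY and
inhibitory IN cortical cells, thalamic relay TC and reticular RE
cells; 500/100/100/100 by default) in which the awake, N2 and N3
stages arise from neuromodulator scaling of potassium-leak, AMPA and
GABA-A conductances and of the h-current activation curve.

Cortical cells are two-compartment models whose axosomatic voltage is
held at its equilibrium, `0 = -g(V_S - V_D) - I_Na - I_K - I_Na(p)`;
cortical PY→PY AMPA synapses follow the symmetric STDP rule

```
F(Δt) =  A+ exp(-|Δt|/τ+)   Δt > 0
        -A- exp(-|Δt|/τ-)   Δt < 0
```

with A± = 0.002 (0.001 in N3), τ± = 20 ms, weights bounded to
[0, 200 %] of their initial values. Sequence memories are trained by
stimulating five groups of five neurons in order (10 ms pulses, 5 ms
gaps) and tested by "pattern completion": only the first group is
stimulated and the recalled order is read from the population response
within 350 ms. Similarity to the trained order is scored with the
string match (SM) measure,

```
SM = 2N - Σ_i |L(S1, S2[i]) - i|,   normalized by 2·len(S),
```

and recall performance is the percentage of test trials with SM ≥ 0.8.
The analysis toolkit further provides replay counting by spike
chaining, spatial cross-correlation of Gaussian-convolved spike
trains, spatiotemporal cluster detection, synaptic-weight trajectory
statistics, and a synthetic raster generator for testing the analysis
chain in isolation.

## A worked example

```r
library(tcsleep)

# score a recalled sequence against the trained ideal
string_match("ACDB", "ABCDE")
#> [1] 0.4
string_match("ABCDE", "ABCDE")
#> [1] 1

# a reduced network, one N3 minute, no plasticity: slow-oscillation
# statistics
net <- tc_network(c(PY = 200, IN = 40, TC = 40, RE = 40))
rec <- simulate_network(net, data.frame(stage = "n3", duration = 30000),
                        seed = 1, plastic = FALSE, snapshot_ms = 0)
up <- detect_upstates(rec$raster)
nrow(up) / 30                      # Up states per second (SO frequency)
sc <- spatial_correlation(rec$raster, up)
correlation_plateau(sc)            # large-distance coherence during Up states
```

`nrow(up)/30` is the slow-oscillation frequency in Hz;
`correlation_plateau()` is the large-distance asymptote of the peak
pairwise cross-correlation — high during the globally coordinated slow
oscillation, low during spatially local spindle activity (compare with
an `"n2"` run and `detect_spindles()`).

A full training experiment (test – train – test – sleep – test) is one
call:

```r
preset <- experiment_preset("fig3_n3_only", scale = 0.1,
                            populations = c(PY = 200, IN = 40,
                                            TC = 40, RE = 40))
res <- run_preset(preset, seeds = 1:2)
res$summary      # recall performance per session, mean ± SEM
```

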