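---
title: "Connectome-constrained dynamics and in silico circuit dissection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-constrained dynamics and in silico circuit dissection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormcircuit)
```

## The problem

Chemosensory information in *C. elegans* must travel from sensory neurons
through interneurons to the motor neurons that execute avoidance
locomotion. The wiring diagram alone does not say which interneurons
functionally complete a given sensorimotor pathway: many neurons bridge a
sensor and the motor periphery anatomically, yet only some of them carry
the signal that matters. `wormcircuit` addresses this with simulation:
drive the sensory neurons (and, where needed, the AVA/AVD/AVE command
interneurons) with injected current, read out whether the
backward-locomotion motor classes — VA, DA, AS (cholinergic, excitatory)
and VD, DD (GABAergic) — oscillate, and then ablate candidate interneurons
one at a time. A candidate whose removal abolishes the motor-neuron
oscillation is called a circuit member; one whose removal leaves it intact
is not.

## The model

Each neuron is a single-compartment leaky unit. Voltage $V_i$ (mV) and a
graded synaptic activation $s_i \in [0,1]$ evolve as

$$
C \frac{dV_i}{dt} = -G_c\,(V_i - E_{cell})
 - \sum_j g^{gap}\,G^{gap}_{ij}\,(V_i - V_j)
 - \sum_j g^{syn}\,G^{syn}_{ji}\,s_j\,(V_i - E_j) + I^{ext}_i(t),
$$
$$
\frac{ds_i}{dt} = a_r\,\phi(V_i)\,(1 - s_i) - a_d\,s_i,
\qquad
\phi(V) = \frac{1}{1 + e^{-\beta (V - V_{th,i})}},
$$

where $G^{gap}$ (symmetric) and $G^{syn}$ (directed, pre in rows) are
contact-count matrices from the connectome, and $E_j$ is the excitatory or
inhibitory reversal potential according to the *presynaptic* neuron's
transmitter sign. Gap junctions are ohmic and bidirectional; chemical
synapses release transmitter as a continuous sigmoidal function of
presynaptic voltage, the non-spiking transmission mode of the worm's
neurons.

### Units

Currents are stated in nA, conductances in pS, capacitance in pF,
voltages in mV, time in s. These are mutually consistent once a current
of $I$ nA enters the voltage equation as $I \times 10^6$ pS·mV
(1 nA = 10⁻⁹ A = 10⁶ pS·mV). The single-neuron closed form
$V_{ss} = E_{cell} + I/G_c$, with time constant $C/G_c = 0.1$ s at the
defaults, is asserted in the test suite in exactly these units.

### Default constants

None of the biophysical constants are measured quantities for individual
worm neurons; the defaults are the conventional values for this model
family and every one of them is a plain config value (YAML/JSON file or
`--param key=value` on the CLI):

| parameter | default | unit | meaning |
|---|---|---|---|
| `capacitance` | 1 | pF | membrane capacitance |
| `leak_conductance` | 10 | pS | leak ($G_c$) |
| `leak_reversal` | −35 | mV | $E_{cell}$ |
| `gap_unit_conductance` | 100 | pS | per gap contact |
| `syn_unit_conductance` | 100 | pS | per chemical contact |
| `syn_reversal_exc` | 0 | mV | excitatory $E_j$ |
| `syn_reversal_inh` | −45 | mV | inhibitory $E_j$ |
| `sigmoid_gain` | 0.125 | mV⁻¹ | $\beta$ |
| `syn_rise` / `syn_decay` | 1 / 5 | s⁻¹ | $a_r$, $a_d$ |
| `dt` | 0.001 | s | integration step |
| `duration` | 12 | s | run length |

Reproducing the *numerical* voltages printed for the full worm connectome
(e.g. a VA01 maximum of 39.2 mV under sensor-plus-command stimulation)
additionally requires the reference wiring dataset and constants
calibrated against the published simulator; those runs are supported
(`awb_only`, `awb_ci`, …) but need that dataset as input.

## Resting state and threshold anchoring

The half-activation thresholds $V_{th,i}$ are not free parameters: they
are anchored so that every release sigmoid sits at $\phi = 1/2$ at the
network equilibrium *under the protocol's injected currents*. With
$\phi = 1/2$, the activation equilibrium is uniform,
$s_{eq} = a_r/(a_r + 2 a_d)$, and the voltage equilibrium becomes one
linear solve.

Anchoring at the stimulated equilibrium (rather than the zero-input one)
is a deliberate design choice, and the one that makes stimulation able to
ignite oscillations at all. Linear-response analysis of this model shows
that every chemical stage's modulation gain is proportional to
$\beta\,\phi'(\cdot)$ at the presynaptic neuron times the postsynaptic
driving force $|V - E_j|$, divided by the postsynaptic total conductance.
If thresholds were anchored at rest, the sigmoid slope would be maximal
exactly at rest and any injected current would push operating points into
lower-gain regions; one can bound the per-stage gain below ~0.4 whenever
the rest state is stable, so no stimulus could destabilize a loop and no
amount of tuning would produce stimulus-gated oscillations. With
input-anchored thresholds, an injected neuron's equilibrium voltage sits
far from the synaptic reversal potentials — a large driving force — while
its sigmoid still operates at full gain, and sufficiently strong
stimulation pushes network feedback loops across a Hopf bifurcation. This
matches the behavior of the simulator family this package follows, which
recomputes thresholds whenever the stimulus configuration changes.

Unstimulated runs anchor at the zero-input equilibrium, which is then an
exact fixed point: a 12-s zero-input simulation of the shipped fixture
drifts by 0 mV. Every simulation starts from the resting state of the
*ablated* network, so ablation screens carry no transient from a stale
equilibrium.

## Integration

A fixed-step classical 4th-order Runge–Kutta scheme (via `deSolve`) on a
uniform grid, default `dt` = 1 ms. The system is non-stiff at these
parameter scales and millisecond steps; a fixed step yields deterministic,
bit-reproducible, uniformly sampled traces, which the screening layer
treats as part of its contract. A pre-flight heuristic compares `dt`
against the fastest resting-load membrane time scale
$C/\max_i G^{eff}_i$ and refuses to run with a step outside the scheme's
stability region; non-finite states abort with the offending time and
neuron. The integrator is cross-checked in the test suite against the RC
closed form (single neuron, 0.1%), against matrix-exponential solutions of
the activation-frozen linear mode (`linearized_simulate`, ≤ 4-neuron
networks, absolute error below 10⁻⁶ mV), and for 4th-order grid
convergence. A stimulus held to the end of the run stays on through the
final integration step, so the last sample is not contaminated by a
mid-step switch-off.

## Oscillation analytics

All readouts work on the post-transient window, by default
**[3 s, end]** — the motor response to strong stimulation begins with a
large onset excursion and a dip before settling into its rhythm — except
`max_voltage`, which deliberately uses the full run because the headline
maxima occur at onset.

* **Oscillating**: windowed peak-to-trough amplitude ≥ 0.5 mV *and* at
  least two prominence-filtered peaks. The 0.5 mV floor sits orders of
  magnitude above the ~10⁻² mV tapering responses seen under
  sensor-only stimulation and far below the multi-mV oscillatory regime,
  so the call is insensitive to its exact value; it is configurable.
* **Period**: detrend (subtract windowed mean), smooth with a centered
  moving average (`smooth_s` = 0.15 s) so sample noise cannot spawn
  spurious peaks, detect peaks with topographic prominence at least 10%
  of the windowed range (ties resolve to the earliest sample), refine
  each crest by a least-squares parabola over ±20% of the raw inter-peak
  spacing, and report the mean inter-peak interval; fewer than two
  surviving peaks means no period. The estimator is invariant to offsets
  and positive rescaling. On seeded sinusoids with 10% noise the
  worst-case error over 100 trials is below 0.5% (the suite asserts 2%).
* **Phase**: zero-lag Pearson correlation of the detrended windowed
  traces; ≥ +0.5 is in-phase, ≤ −0.5 anti-phase, otherwise undetermined
  (quadrature lands here by construction). Degenerate or non-oscillating
  traces are undetermined with correlation 0. The call is symmetric.
* **Verdict**: `oscillatory` if at least half (configurable) of the
  readout motor neurons oscillate; `silent` if none reaches the amplitude
  floor; `weak` otherwise. The ablation screen flips on this verdict —
  the binary present/lost reading of the motor heatmaps — while median
  amplitudes are reported alongside for inspection.

## Protocols and the screen

Protocols live in a YAML registry (shipped as data, user-extendable
without code changes): stimulated groups with per-member currents in nA,
ablations, duration (≥ 12 s by convention), readout classes. Group names
are class labels (`AWB`), aliases (`CI` = AVA+AVD+AVE;
`backward_motor` = VA+DA+VD+DD+AS), or explicit neuron names, resolved
against the concrete connectome at run time; each member of a stimulated
class receives the full stated current. Ablation is structural — all gap
and chemical connections of the neuron are zeroed while it remains in the
state vector at its leak equilibrium — which keeps matrix indices and
trace columns stable across a screen.

`ablation_screen()` runs the base protocol once, then once per candidate
group; candidates whose removal makes the verdict non-oscillatory are the
inferred circuit members. Cost is linear in candidates and every run's
traces and report can be persisted and reloaded independently.

## The synthetic fixtures

`make_toy_connectome()` emulates the four-layer topology of the
sensorimotor pathway: a sensor pair gap-coupled to an interneuron pair,
chemical projections onto a command set, and chemical projections onto
motor classes with mixed excitatory/inhibitory members — plus an optional
bystander pair that touches the sensors but has no path to the motors,
the structural analogue of anatomically adjacent neurons that are not
circuit members.

The shipped oscillator fixture (`toy_oscillator()`, 14 neurons, frozen as
CSV under `inst/extdata`) adds the one ingredient a purely feedforward
toy cannot have: a feedback loop. The loop IN → CM1 (excitatory),
CM1 → CM2, CM2 → IN (inhibitory) is deliberately routed *through* the
interneuron layer, so ablating that layer cuts the cycle structurally and
the loss of oscillation under ablation is guaranteed by graph topology,
not by delicate tuning. At the co-stimulation operating point all three
links are effectively sign-inverting (the commands sit above the
excitatory reversal), giving a net-negative three-stage loop that crosses
a Hopf bifurcation when the sensors (0.05 nA each) and commands
(0.02 nA each) are driven together; either input alone leaves the loop
subcritical. The inhibitory motor class MD is driven by CM3, an
excitatory twin of CM1 with identical inputs, so the excitatory classes
(driven, inverted, by CM1) and the inhibitory class oscillate in exact
anti-phase — the alternation characteristic of backward locomotion. The
toy's currents are smaller than the worm-protocol currents because its
synaptic load is a dozen contacts rather than thousands; its weights were
tuned once against the screen criteria and then frozen. The screen
outcome is stable across `dt` ∈ {0.0005, 0.001} s.

What the toy does **not** emulate: the scale and heterogeneity of the
real connectome, its left/right wiring asymmetries (which in the full
network seed the symmetry breaking behind motor rhythms), extrasynaptic
signaling, and the specific oscillation period of the worm's backward
rhythm (the toy's cycle is ~0.74 s). Passing the fixture screen therefore
demonstrates that the simulation, analytics and screening machinery
compose correctly and that the verdict logic separates loop members from
bystanders — not that the package reproduces the worm's printed voltages,
which requires the reference wiring dataset as input.

`make_surrogate_traces()` generates sinusoids with known period, phase
map (0 or π) and seeded Gaussian noise for validating the analytics in
isolation; generators are deterministic under a fixed seed and leave the
session RNG untouched.

## Behavioral indices

`response_index(n_responses, n_drops)` and
`occupancy_index(n_on_lawn, n_total)` are the exact defining ratios of
the dry-drop and lawn-occupancy assays, kept here so simulation
predictions and behavioral data share one reporting layer. No
significance testing is included by design.

## Problem sizes

The test suite and the acceptance script run on the 14-neuron fixture
(12-s runs at 1-ms steps), ≤ 4-neuron oracle networks at 0.1-ms steps,
and 100 surrogate trials of 1201 samples — sizes chosen so the whole
battery completes in well under a minute while still exercising every
code path end to end.

## Known limitations

* Single-compartment, non-spiking units: no channel noise, no
  morphology, no plasticity; the "learning" of learned aversion is
  behavioral context, not modeled dynamics.
* Thresholds are recomputed per protocol, not continuously; a stimulus
  that switches off mid-run relaxes toward a nearby (not identical)
  equilibrium.
* Phase relations are sign calls at zero lag, not phase lags in radians.
* Quantitative agreement with published full-connectome voltages is
  conditional on the reference wiring dataset and calibrated constants,
  which are inputs, not package contents.
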