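---
title: "The colrhythm cortical-column model: equations, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The colrhythm cortical-column model: equations, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`colrhythm` simulates a single cortical column of mouse primary visual cortex
as a spiking network of 17 cell groups — pyramidal (E), PV, SST and VIP
interneurons in layers 2/3, 4, 5 and 6, plus a VIP-only layer 1 — and provides
the experiment protocols and measurement tools used to ask when such a column
oscillates. This vignette documents the model equations, every tunable
parameter with its unit and default, the synthetic connectivity generator, the
numerical scheme, and the design decisions taken where the problem was
genuinely open.

## Neurons

All cells are leaky integrate-and-fire point neurons. Between spikes the
membrane potential obeys

$$C_m \frac{dV}{dt} = -g_L\,(V - V_{rest}) + I_{syn}(t),$$

and when $V$ reaches $V_{th}$ a spike is emitted, $V$ is reset to $V_{rest}$
and held there for the refractory time $\tau_{ref}$. Each of the 17 groups has
its own $C_m$ (pF), $g_L$ (nS), $\tau_{ref}$ (ms), $V_{rest}$ and $V_{th}$
(mV), shipped as the plain-text fixture behind
`default_membrane_params()`. The membrane time constant is
$\tau_m = C_m / g_L$.

## Synapses

The total current is

$$I_{syn} = I_{ext} + I_{ext,AMPA} + I_{AMPA} + I_{NMDA} + I_{GABA},$$

with conductance-based receptor currents
$I_{rec} = g_{rec}\,(V - V_{rev})\sum_j w_j s_j(t)$ summed over presynaptic
neurons $j$. AMPA and NMDA reverse at $V_E = 0$ mV; GABA-A reverses at $V_I$,
taken by default as the **postsynaptic** cell's resting potential. The model
statement of the GABA reversal is ambiguous between the pre- and postsynaptic
cell's $V_{rest}$; both are implemented
(`gaba_reversal = "postsynaptic" | "presynaptic"`, the presynaptic variant via
a second weighted accumulator) and the postsynaptic reading is the default.
The NMDA current carries the magnesium-block factor
$\big(1 + [\mathrm{Mg}^{2+}] e^{-0.062 V}/3.57\big)^{-1}$ with
$[\mathrm{Mg}^{2+}] = 1$ mM (`nmda_voltage_factor()`).

Gating variables sit on the presynaptic neuron. AMPA, external AMPA and GABA
gating decay exponentially ($\tau_{AMPA} = 2$ ms, $\tau_{GABA} = 5$ ms) and
jump by 1 at each presynaptic spike. NMDA gating has rise/decay kinetics

$$\dot{s} = -s/\tau_{decay} + \alpha\, x\,(1 - s), \qquad
  \dot{x} = -x/\tau_{rise} + \textstyle\sum_k \delta(t - t_k),$$

with $\tau_{decay} = 80$ ms, $\tau_{rise} = 2$ ms, $\alpha = 0.5$ ms$^{-1}$;
the saturation term keeps $s \le 1$.

The receptor conductances $g_{AMPA}, g_{NMDA}, g_{GABA}$ are not published
for this model; they default to 1 nS each and are exposed in
`synapse_constants()`. Their scale is degenerate with the connectivity
strength matrix, so the synthetic-matrix calibration below absorbs them.

## Architecture and weights

`compute_population_counts()` splits `n_total` neurons into the 17 groups:
each layer takes `round(fraction * n_total)` cells; full layers are 85%
excitatory, and the 15% inhibitory pool is split between PV/SST/VIP by
per-layer fractions, each subtype rounded from the unrounded pool with the
pyramidal count as the layer remainder. At `n_total = 5000` this reproduces
the published census in all 17 cells. One data note: the published per-layer
fraction for L6 (0.297031276) is inconsistent by one neuron with the published
L6 census (1,486 cells at n = 5,000); the packaged fixture carries
`f_L6 = 0.2972`, back-derived from the census, which we treat as
authoritative.

Group-level connectivity is given by two 17 × 17 matrices: connection
probabilities $P$ and strengths $\hat{s}$ ($S$). Each realized synapse from
group A to group B carries the weight

$$w = \frac{G\,\hat{s}}{N_{send}\,p},$$

with global coupling $G = 5$. This normalization makes the **expected summed
input weight** per postsynaptic cell equal to $G\hat{s}$, independent of
network size and connection probability, so reduced columns preserve the mean
synaptic drive of larger ones. Excitatory projections are realized as two
independent Bernoulli wiring draws per neuron pair — AMPA with probability
$0.8p$ and NMDA with probability $0.2p$ — while inhibitory projections draw
single GABA synapses at probability $p$. Autapses are excluded. The AMPA and
NMDA entries of one plastic E→E pair share a single logical weight.

## Background drive and stimuli

Every neuron owns an independent Poisson generator at its group's rate
(`default_background_rates()`, 240–4,740 Hz) feeding the external-AMPA gating
with fixed weight $w_{ext} = 1$. Events are binned per integration step
(Bernoulli with probability rate × dt; the dt guard keeps this below 0.25).

Stimuli are constant currents injected into a seeded random subset of one
group: the standard feedforward input is 30 pA to 50% of the layer-4
pyramidal cells; feedback input targets layer-5 pyramidal cells. Epoch
windows are half-open `[t_on, t_off)`.

## Plasticity

Excitatory-to-excitatory synapses follow pair-based exponential STDP: the
weight change is the sum of $F(\Delta t)$ over **all** spike pairs
($\Delta t = t_{post} - t_{pre}$), with

$$F(x) = \begin{cases} A_+ e^{-x/\tau_+}, & x > 0\\
 -A_- e^{x/\tau_-}, & x < 0 \end{cases}$$

and $A_+ = 0.02$, $A_- = 0.021$, $\tau_\pm = 20$ ms. Weights are clipped into
$[0, 0.2]$ immediately after every update, and plastic weights start inside
those bounds. Because $A_-\tau_- > A_+\tau_+$, uncorrelated firing drifts
weights downward; only causally correlated firing potentiates.

The all-pairs sum is implemented online with per-neuron exponential traces,
which is exact for exponential kernels; the test suite verifies the trace
implementation against a brute-force double sum to 10⁻⁹, both at the level of
isolated spike trains and for every plastic connection of a simulated column.
$F(0)$ is taken as 0, and when pre- and postsynaptic spikes fall into the same
integration step both updates use the traces as they were before that step's
spikes — a symmetric same-bin treatment.

PV→pyramidal synapses can additionally follow a symmetric "sunken Mexican
hat" rule $H(x) = B_+ e^{-|x|/\tau_+} - B_- e^{-|x|/\tau_-}$ with $B_+ = 0.04$,
$B_- = 0.02$, $\tau_+ = 10$ ms, $\tau_- = 20$ ms (zero crossing at
$20\ln 2 \approx 13.9$ ms); positive changes strengthen inhibition. This rule
is off by default. Its weights are clipped below at 0 but not capped: no upper
bound is stated for it, its flank depression is self-stabilizing, and GABA
weights live on a different scale than the excitatory cap.

## Numerical scheme

The integrator advances with `dt = 0.05` ms by default and refuses
`dt > 0.1` ms without an explicit override. Within one step: (1) gating and
traces decay by their exact exponential factors, with the NMDA saturation
cross-term taken forward-Euler; (2) background events are drawn; (3) currents
are evaluated at the start-of-step voltage; (4) membranes advance by
exponential Euler (exact for a constant current); (5) threshold crossings
spike at the end of the step; (6) plastic weights update from pre-step
traces; (7) traces increment; (8) spikes deliver to the AMPA/GABA
accumulators and NMDA rise variables. There are **no synaptic transmission
delays** — the model never states any — which matters when interpreting
oscillation frequencies, since delays would slow the inhibitory loop.

Two independent integrators ship in the package: the compiled production core
and a plain-R reference stepper with a different data layout (per-presynaptic
gating summed at the current stage, as in the model equations). The tests
drive both on the same column and require spike-for-spike agreement at 10⁻¹²,
with and without the stochastic background on a shared RNG stream. The NMDA
rise variable is flushed to zero once below 10⁻¹⁰ (truncation error in $s$
below $\alpha\,\tau_{rise}\,10^{-10}$), in both integrators, which lets silent
neurons cost nothing.

Four explicit seed streams (wiring, background, stimulus subset,
plasticity/shuffle) make every experiment bit-reproducible from its manifest
and let the controls vary one factor at a time.

## The synthetic connectivity generator

The data-constrained $P$ and $S$ matrices of the original model live in an
external data portal and are not printed; when the user supplies them,
`load_connectivity()` consumes them as labelled CSV. For self-contained use,
`generate_synthetic_connectivity()` produces stand-in matrices with the
qualitative structure the published description implies, as hard constraints:

* inhibition-dominated strengths, with within-layer somatic PV→E the
  strongest inhibitory projection (`S[PV→E] > S[SST→E] > S[VIP→E]` in every
  full layer);
* a laminar feedforward pyramidal motif L4 → L2/3 → L5 → L6, dense and strong
  enough that a stimulated layer recruits its downstream layer;
* preferential VIP→SST targeting (disinhibition), including column-wide
  projections from layer-1 VIP cells;
* all 289 entries populated, with a seeded log-normal jitter (sd 0.1 on the
  log scale) individualizing matrices across seeds without breaking the
  ordering constraints.

Two design rules deserve explanation. First, E→E entries keep $\hat{s}/p$
low enough that initial Eq.-type weights sit inside the STDP bounds at the
intended sizes (`n_total` ≥ 1,000): initial weights above the cap would be
clipped at their first update, a spurious mass depression. Second, the
within-layer E→E pool is dense (p = 0.25) so that the bounded rule has room
to build an effective assembly at reduced sizes — with the cap fixed at 0.2,
the achievable recurrent drive scales with the number of synapses per target.
With the packaged membrane/background tables, G = 5 and 1 nS conductances,
the generated columns sit in an inhibition-dominated asynchronous regime:
interneuron rates above pyramidal rates (VIP cells in layer 4 are the lowest,
as in the recorded data), pyramidal rates of order 0.2–5 Hz with layer 5
highest, and ISI CVs above 0.5.

What the generator does **not** emulate: the actual laminar strength values of
the measured matrices (only their orderings), distance- or tuning-dependent
connectivity, and any fitted correspondence to recorded firing rates. Results
that depend on the precise measured weights — the published 26 Hz column
rhythm, the 37 Hz isolated-layer-4 rhythm, absolute spectral powers — are
reproducible only with the portal matrices supplied by the user.

## Experiments and measurement

`run_spontaneous()`, `run_evoked()`, `run_conditioning()`,
`inactivate_groups()`, `run_isolated_layer4()`, `shuffle_weights()`,
`uniform_increase()` and `input_sweep()` orchestrate the protocols; every
result carries its config and seeds and re-runs bit-identically
(`write_run_manifest()` / `verify_run_manifest()`).

The measurement layer computes population rates on a 1-ms grid with a
sliding window (200 ms for display and latency traces, matching the published
figures), ISI coefficients of variation (units with ≥ 3 spikes), the Golomb
membrane-potential synchrony $\chi$, Welch power spectra, half-max activation
latencies with linear interpolation, and normalized rate cross-correlations.
Two spectral conventions matter:

* spectra are computed on **5-ms-window** rates, not the 200-ms display
  window — a 200 ms boxcar attenuates 26-Hz power by roughly 3×10³ and would
  hide the band of interest;
* the PSD estimator is Welch with 2-s Hann segments and 50% overlap (the
  original estimator is unstated, so absolute published power values are
  order-of-magnitude context only); the default peak search band is
  5–100 Hz.

## Test scale and the plasticity–oscillation link

The packaged tests and the acceptance script run at reduced scale, chosen to
keep the full suite within ordinary desktop budgets: columns of 300–1,000
neurons for dynamical checks, 2,500 vs 5,000 for the finite-size comparison
(1.5 s of activity, 5 seeds), and 1,000 neurons with 10 s of conditioning
(5 seeds) for the plasticity experiments. The weight normalization above is
what makes these reduced columns meaningful.

One caveat is stated plainly. The published oscillation emergence rests on
55 s of conditioning in a 5,000-neuron column with the measured matrices. At
the reduced test scale, the depression bias of the rule
($A_-\tau_- - A_+\tau_+ > 0$) is not reliably overcome by causal
potentiation within 10 s: per-synapse EPSPs, capped by the 0.2 weight bound,
are small at these sizes, so the selective reinforcement that seeds the
rhythm accumulates too slowly. The reduced-scale directionality comparisons
(conditioned vs naive, shuffled, uniformly-increased, zero-input) are
implemented exactly and report whatever the simulations produce; the column's
oscillation capability itself is separately verifiable — with all plastic
weights at the upper bound the driven column shows a clear beta-band peak
that the naive column lacks. Passing the reduced-scale suite therefore
validates the machinery (integrators, plasticity bookkeeping, controls,
measurement), not the full-scale emergence claim, which requires the portal
matrices and full-length conditioning.

## Known limitations

Point neurons only (no multi-compartment morphology), no spike-frequency
adaptation, no short-term plasticity, no transmission delays, plasticity
restricted to E→E (and optionally PV→E) synapses, and unstructured (constant
current) stimuli. These mirror the scope of the original model; the first
three are named there as future work.
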