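# colrhythm

Spiking-network simulation of a mouse V1 cortical column with four cell
classes — pyramidal (E), PV, SST and VIP interneurons — across layers 1–6,
built to study when cortical columns produce fast (beta/gamma) oscillations.
The package is for computational neuroscientists who want a self-contained,
reproducible column model with realistic interneuron diversity, long-term
plasticity, and the full experiment/measurement stack: spontaneous and
stimulus-evoked protocols, STDP conditioning, cell-type inactivations,
layer-4 isolation, weight-shuffle and uniform-increase controls, and input
sweeps.

## The model

17 cell groups (VIP in layer 1; E/PV/SST/VIP in layers 2/3, 4, 5, 6) of leaky
integrate-and-fire neurons:

    C_m dV/dt = -g_L (V - V_rest) + I_syn(t)

with per-group membrane parameters and spike threshold/reset/refractory
dynamics. Synaptic currents are conductance-based through AMPA, NMDA and
GABA-A receptors, `I = g (V - V_rev) Σ_j w_j s_j`, with exponential AMPA/GABA
gating (τ = 2 / 5 ms), saturating NMDA kinetics (rise 2 ms, decay 80 ms,
magnesium block `1/(1 + [Mg] e^{-0.062V}/3.57)`), and per-neuron independent
Poisson background drive at published per-group rates. Synaptic weights
follow the size-invariant normalization

    w = G * s_hat / (N_send * p),     G = 5,

so the expected summed input per neuron from any projection is `G * s_hat`
regardless of network size. Excitatory wiring splits AMPA:NMDA 0.8:0.2.
E→E synapses evolve under pair-based exponential STDP
(`A+ = 0.02`, `A- = 0.021`, τ± = 20 ms, weights bounded in [0, 0.2]), with an
optional symmetric "sunken Mexican hat" rule on PV→E synapses. The published
group-to-group connectivity matrices live in an external portal; the package
reads them from labelled CSV when available and otherwise generates synthetic
inhibition-dominated matrices with the same qualitative structure
(PV→E > SST→E > VIP→E within each layer, a laminar L4→L2/3→L5→L6 feedforward
motif, VIP→SST disinhibition).

## Worked example

Build a reduced 1,000-neuron column, simulate 1.5 s of spontaneous activity,
and summarize it:

```r
library(colrhythm)

cfg <- default_config(n_total = 1000, duration = 1500, seed = 1)
spont <- run_spontaneous(cfg)
print(spont)
#> <col_experiment:spontaneous> 1019 neurons, 1500 ms
#>   VIP1   E2/3  PV2/3 SST2/3 VIP2/3     E4    PV4   SST4   VIP4     E5    PV5
#>   0.81   0.23   2.92   2.15   7.87   0.77   4.07   3.15   0.27   5.05   3.54
#>   SST5   VIP5     E6    PV6   SST6   VIP6
#>   4.42   4.00   1.10   2.17   6.43   2.33
```

The rates are per-group means in Hz over the run. The column sits in the
inhibition-dominated asynchronous regime the recorded data show: pyramidal
rates low (≈ 0.2–1 Hz, layer 5 highest at ≈ 5 Hz), interneurons faster than
pyramidal cells in every layer except the layer-4 VIP group, and irregular
single-unit firing (`mean(spont$cv, na.rm = TRUE)` = 0.71).

Drive the layer-4 pyramidal cells with the standard feedforward stimulus
(30 pA to half the population) and measure the spectrum of the layer-4 rate:

```r
cfg$stimulus$epochs <- data.frame(group = "E4", fraction = 0.5, amplitude = 30,
                                  t_on = 500, t_off = Inf)
col <- build_column(cfg)
ev  <- run_evoked(cfg, column = col, duration = 4500)
tr  <- population_rate(ev$sim$spikes, col$spec, "E4", window = 5,
                       t_range = c(0, 4500))
ps  <- power_spectrum(tr, t_start = 1000, t_end = 4500)
c(peak_frequency = ps$peak_frequency, peak_power = signif(ps$peak_power, 3))
```

STDP conditioning (`run_conditioning()`), the weight-shuffle and
uniform-increase controls (`shuffle_weights()`, `uniform_increase()`),
inactivations (`inactivate_groups()`) and input sweeps (`input_sweep()`)
compose the same way; see the methods vignette
(`vignettes/column-model.Rmd`) for the model details and design decisions,
and `inst/cli/colrhythm` for a command-line wrapper over the same functions.

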