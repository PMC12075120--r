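# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force all-pairs STDP sum: kernel evaluated at every (pre, post) spike
# pair lag, excluding exactly simultaneous pairs
pair_sum_stdp <- function(t_pre, t_post, cfg) {
  if (!length(t_pre) || !length(t_post)) return(0)
  lags <- as.vector(outer(t_post, t_pre, "-"))   # t_post - t_pre
  pos <- lags[lags > 0]
  neg <- lags[lags < 0]
  if (inherits(cfg, "inh_stdp_config")) {
    a <- abs(c(pos, neg))
    sum(cfg$B_plus * exp(-a / cfg$tau_plus)) -
      sum(cfg$B_minus * exp(-a / cfg$tau_minus))
  } else {
    sum(cfg$A_plus * exp(-pos / cfg$tau_plus)) -
      sum(cfg$A_minus * exp(neg / cfg$tau_minus))
  }
}

# fine-step single-neuron LIF under Poisson AMPA drive; independent of the
# package's integrator (plain forward loop, 0.01 ms step)
single_neuron_rate <- function(C_m, g_L, tau_ref, V_rest, V_th, rate_hz,
                               duration_ms, dt = 0.01, g_AMPA = 1, w_ext = 1) {
  n_steps <- round(duration_ms / dt)
  tau_AMPA <- 2
  p <- rate_hz * dt / 1000
  V <- V_rest
  s <- 0
  refr <- -Inf
  spikes <- 0L
  t <- 0
  dec <- exp(-dt / tau_AMPA)
  events <- stats::runif(n_steps) < p
  for (k in seq_len(n_steps)) {
    s <- s * dec
    if (events[k]) s <- s + 1
    t <- t + dt
    if (t - dt < refr) { V <- V_rest; next }
    I <- -g_AMPA * (V - 0) * w_ext * s
    V <- V + dt * (-g_L * (V - V_rest) + I) / C_m
    if (V >= V_th) {
      spikes <- spikes + 1L
      V <- V_rest
      refr <- t + tau_ref
    }
  }
  1000 * spikes / duration_ms
}

# closed-form mean firing rate of a LIF neuron under constant current
lif_analytic_rate <- function(I, C_m, g_L, tau_ref, V_rest, V_th) {
  drive <- g_L * (V_th - V_rest)
  if (I <= drive) return(0)
  tau_m <- C_m / g_L
  T_isi <- tau_m * log(I / (I - drive)) + tau_ref
  1000 / T_isi
}

# small shared fixtures -------------------------------------------------------

small_column <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- column_spec(300)
      conn <- generate_synthetic_connectivity(seed = 42)
      syn <- build_synapse_table(spec, conn, seed = 43)
      cache <<- list(spec = spec, conn = conn, synapses = syn)
    }
    cache
  }
})

# published census at n_total = 5000
table3_counts <- c(
  VIP1 = 96,
  `E2/3` = 1236, `PV2/3` = 65, `SST2/3` = 47, `VIP2/3` = 107,
  E4 = 1010, PV4 = 98, SST4 = 53, VIP4 = 27,
  E5 = 741, PV5 = 63, SST5 = 56, VIP5 = 11,
  E6 = 1263, PV6 = 102, SST6 = 102, VIP6 = 19
)
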