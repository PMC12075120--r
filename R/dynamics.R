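#' NMDA receptor voltage dependence
#'
#' Magnesium-block factor of the NMDA current,
#' `1 / (1 + Mg * exp(-0.062 * V) / 3.57)`, strictly increasing in `V`;
#' equals 1 in the magnesium-free limit.
#'
#' @param V membrane potential (mV), vectorized.
#' @param Mg extracellular magnesium concentration (mM).
#' @return Dimensionless multiplier in (0, 1].
#' @examples
#' nmda_voltage_factor(0)    # ~0.781
#' nmda_voltage_factor(-65)  # ~0.060
#' @export
nmda_voltage_factor <- function(V, Mg = 1) {
  1 / (1 + Mg * exp(-0.062 * V) / 3.57)
}

#' Initialize the per-neuron state of the reference integrator
#'
#' The package carries two integrators: the compiled production core used by
#' [run_simulation()], and a plain-R reference stepper built from
#' [update_gating()], [total_synaptic_current()] and [step_membrane()] with an
#' independent data layout (per-presynaptic gating summed at the current
#' stage, as in the model equations). The two are cross-validated against each
#' other in the test suite; the reference is only practical for small
#' networks.
#'
#' @param n number of neurons.
#' @param V_rest per-neuron resting potentials (mV).
#' @return A `network_state` list: time `t`, membrane `V`, refractory gates
#'   `refr_until`, and gating vectors `s_ext`, `s_ampa`, `s_gaba`, `s_nmda`,
#'   `x_nmda` (per presynaptic neuron).
#' @export
network_state <- function(n, V_rest) {
  stopifnot(length(V_rest) == n)
  list(t = 0, V = V_rest, refr_until = rep(-Inf, n),
       s_ext = numeric(n), s_ampa = numeric(n), s_gaba = numeric(n),
       s_nmda = numeric(n), x_nmda = numeric(n))
}

#' Advance the synaptic gating variables by one step
#'
#' Between spikes, AMPA, GABA and external-AMPA gating and the NMDA auxiliary
#' variable `x` decay by their exact exponential factors; the NMDA gating
#' follows its saturating kinetics (`alpha * x * (1 - s)` rise term, forward
#' Euler), which keeps `s_nmda <= 1`. A spike of presynaptic neuron `j`
#' increments `s_ampa[j]` and `x_nmda[j]` (excitatory cells) or `s_gaba[j]`
#' (inhibitory cells) by 1.
#'
#' @param state a [network_state()].
#' @param spikes integer ids of neurons spiking at the end of the step.
#' @param dt time step (ms).
#' @param is_exc logical per neuron.
#' @param consts [synapse_constants()].
#' @return Updated state.
#' @export
update_gating <- function(state, spikes, dt, is_exc,
                          consts = synapse_constants()) {
  stopifnot(dt > 0)
  state <- decay_gating(state, dt, consts)
  apply_spike_increments(state, spikes, is_exc)
}

decay_gating <- function(state, dt, consts) {
  state$s_ext <- state$s_ext * exp(-dt / consts$tau_AMPA)
  state$s_ampa <- state$s_ampa * exp(-dt / consts$tau_AMPA)
  state$s_gaba <- state$s_gaba * exp(-dt / consts$tau_GABA)
  s <- state$s_nmda
  x <- state$x_nmda
  # the rise variable is cut once negligible (matches the compiled core; the
  # truncation error in s is below alpha * tau_rise * 1e-10)
  dead <- x <= 1e-10
  rise <- consts$alpha * dt * x * (1 - s)
  rise[dead] <- 0
  state$s_nmda <- s * exp(-dt / consts$tau_NMDA_decay) + rise
  x <- x * exp(-dt / consts$tau_NMDA_rise)
  x[dead] <- 0
  state$x_nmda <- x
  state
}

apply_spike_increments <- function(state, spikes, is_exc) {
  if (length(spikes)) {
    e <- spikes[is_exc[spikes]]
    i <- spikes[!is_exc[spikes]]
    state$s_ampa[e] <- state$s_ampa[e] + 1
    state$x_nmda[e] <- state$x_nmda[e] + 1
    state$s_gaba[i] <- state$s_gaba[i] + 1
  }
  state
}

#' Total synaptic current per neuron (reference implementation)
#'
#' Evaluates the receptor currents from the per-presynaptic gating variables
#' and the synapse table: AMPA/NMDA use driving force `(V - V_E)`, GABA uses
#' `(V - V_I)`; the NMDA term is scaled by [nmda_voltage_factor()]. The sign
#' convention makes excitatory input depolarizing and GABA input (above its
#' reversal) hyperpolarizing.
#'
#' @param state a [network_state()].
#' @param synapses a synapse table.
#' @param V_I per-neuron GABA reversal potentials (mV), or per-presynaptic
#'   resting potentials when `gaba_reversal = "presynaptic"`.
#' @param I_ext per-neuron external current (pA).
#' @param consts [synapse_constants()].
#' @param gaba_reversal whether `V_I` applies per postsynaptic cell
#'   (`"postsynaptic"`, default) or per presynaptic cell (`"presynaptic"`).
#' @return Per-neuron current (pA) entering the membrane equation.
#' @export
total_synaptic_current <- function(state, synapses, V_I, I_ext = 0,
                                   consts = synapse_constants(),
                                   gaba_reversal = c("postsynaptic",
                                                     "presynaptic")) {
  gaba_reversal <- match.arg(gaba_reversal)
  n <- length(state$V)
  V <- state$V
  sum_by_post <- function(rows, vals) {
    out <- numeric(n)
    if (length(rows)) {
      agg <- rowsum(vals, synapses$post[rows])
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
  }
  ra <- which(synapses$receptor == "AMPA")
  rn <- which(synapses$receptor == "NMDA")
  rg <- which(synapses$receptor == "GABA")
  a_ampa <- sum_by_post(ra, synapses$weight[ra] * state$s_ampa[synapses$pre[ra]])
  a_nmda <- sum_by_post(rn, synapses$weight[rn] * state$s_nmda[synapses$pre[rn]])
  a_gaba <- sum_by_post(rg, synapses$weight[rg] * state$s_gaba[synapses$pre[rg]])
  I_gaba <- if (gaba_reversal == "postsynaptic") {
    consts$g_GABA * (V - V_I) * a_gaba
  } else {
    b_gaba <- sum_by_post(rg, synapses$weight[rg] * state$s_gaba[synapses$pre[rg]] *
                            V_I[synapses$pre[rg]])
    consts$g_GABA * (V * a_gaba - b_gaba)
  }
  I_ext -
    consts$g_AMPA * (V - consts$V_E) * (consts$w_ext * state$s_ext + a_ampa) -
    consts$g_NMDA * (V - consts$V_E) * nmda_voltage_factor(V, consts$Mg) * a_nmda -
    I_gaba
}

#' Integrate the membrane equation by one step (reference implementation)
#'
#' Exponential-Euler update of the leaky integrate-and-fire membranes with the
#' synaptic current held constant over the step: neurons at or above threshold
#' after the update spike at `t + dt`, are reset to `V_rest` and clamped there
#' for their refractory period.
#'
#' @param state a [network_state()].
#' @param I_syn per-neuron current (pA).
#' @param C_m,g_L,tau_ref,V_rest,V_th per-neuron membrane parameters.
#' @param dt time step (ms); must be <= 0.1 unless `allow_large_dt`.
#' @param allow_large_dt override the stability guard.
#' @return A list `(state, spikes)`; `spikes` holds the ids of neurons that
#'   fired at the new time `state$t`.
#' @export
step_membrane <- function(state, I_syn, C_m, g_L, tau_ref, V_rest, V_th, dt,
                          allow_large_dt = FALSE) {
  if (dt > 0.1 && !allow_large_dt) {
    stop("dt = ", dt, " ms exceeds the 0.1 ms stability guard", call. = FALSE)
  }
  t_next <- state$t + dt
  refr <- state$t < state$refr_until
  V <- state$V
  V_inf <- V_rest + I_syn / g_L
  V_new <- V_inf + (V - V_inf) * exp(-dt * g_L / C_m)
  V_new[refr] <- V_rest[refr]
  if (any(!is.finite(V_new))) {
    stop("integration fault: non-finite membrane potential for neuron ",
         which(!is.finite(V_new))[1], " at t = ", t_next, " ms", call. = FALSE)
  }
  spikes <- which(!refr & V_new >= V_th)
  V_new[spikes] <- V_rest[spikes]
  state$refr_until[spikes] <- t_next + tau_ref[spikes]
  state$V <- V_new
  state$t <- t_next
  list(state = state, spikes = spikes)
}

# plain-R reference simulation loop; mirrors the compiled core step for step
# (no plasticity, no inactivation — used for cross-validation on tiny nets)
simulate_reference <- function(spec, synapses, duration, dt = 0.05,
                               consts = synapse_constants(),
                               protocol_epochs = NULL,
                               background = TRUE,
                               gaba_reversal = "postsynaptic",
                               record_V = integer(0)) {
  pp <- per_neuron_params(spec)
  n <- spec$n_total
  state <- network_state(n, pp$V_rest)
  V_I <- if (gaba_reversal == "postsynaptic") pp$V_rest else pp$V_rest
  bkg_p <- if (isTRUE(background)) pp$bkg_rate * dt / 1000 else numeric(n)
  has_bkg <- which(bkg_p > 0)
  n_steps <- round(duration / dt)
  sp_id <- integer(0)
  sp_t <- numeric(0)
  V_rec <- if (length(record_V)) {
    matrix(NA_real_, n_steps, length(record_V))
  } else NULL
  for (step in seq_len(n_steps)) {
    state <- decay_gating(state, dt, consts)
    if (length(has_bkg)) {
      hits <- has_bkg[stats::runif(length(has_bkg)) < bkg_p[has_bkg]]
      state$s_ext[hits] <- state$s_ext[hits] + 1
    }
    I_ext <- numeric(n)
    if (!is.null(protocol_epochs)) {
      for (e in protocol_epochs) {
        if (state$t >= e$t_on && state$t < e$t_off) {
          I_ext[e$targets] <- I_ext[e$targets] + e$amplitude
        }
      }
    }
    I <- total_synaptic_current(state, synapses, V_I, I_ext, consts,
                                gaba_reversal)
    res <- step_membrane(state, I, pp$C_m, pp$g_L, pp$tau_ref, pp$V_rest,
                         pp$V_th, dt)
    state <- res$state
    state <- apply_spike_increments(state, res$spikes, pp$is_exc)
    if (length(res$spikes)) {
      sp_id <- c(sp_id, res$spikes)
      sp_t <- c(sp_t, rep(state$t, length(res$spikes)))
    }
    if (!is.null(V_rec)) V_rec[step, ] <- state$V[record_V]
  }
  list(spikes = data.frame(neuron = sp_id, time = sp_t), V = V_rec,
       state = state)
}

# expand group-level parameters to per-neuron vectors
per_neuron_params <- function(spec) {
  g <- neuron_groups(spec)
  mp <- spec$membrane
  list(
    group = g,
    C_m = mp$C_m[g], g_L = mp$g_L[g], tau_ref = mp$tau_ref[g],
    V_rest = mp$V_rest[g], V_th = mp$V_th[g],
    is_exc = mp$cell_type[g] == "E",
    bkg_rate = unname(spec$bkgnd_rate[g])
  )
}
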