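test_that("NMDA voltage factor matches its closed form", {
  expect_equal(nmda_voltage_factor(0, Mg = 1), 1 / (1 + 1 / 3.57))
  expect_equal(nmda_voltage_factor(-65, Mg = 1),
               1 / (1 + exp(0.062 * 65) / 3.57))
  expect_equal(nmda_voltage_factor(c(-120, 40), Mg = 0), c(1, 1))
  # strictly increasing in V
  v <- seq(-100, 20, by = 1)
  expect_true(all(diff(nmda_voltage_factor(v)) > 0))
})

test_that("gating variables decay by exact exponential factors", {
  st <- network_state(2, c(-70, -70))
  st$s_ampa[1] <- 1
  st$s_gaba[2] <- 1
  st$s_ext[1] <- 1
  out <- update_gating(st, integer(0), dt = 2, is_exc = c(TRUE, FALSE))
  expect_equal(out$s_ampa[1], exp(-1))        # tau_AMPA = 2 ms
  expect_equal(out$s_ext[1], exp(-1))
  expect_equal(out$s_gaba[2], exp(-2 / 5))    # tau_GABA = 5 ms
  # spikes increment the class-appropriate gating
  out2 <- update_gating(out, c(1L, 2L), dt = 2, is_exc = c(TRUE, FALSE))
  expect_equal(out2$s_ampa[1], exp(-2) + 1)
  expect_equal(out2$x_nmda[1], 1)
  expect_equal(out2$s_gaba[2], exp(-4 / 5) + 1)
  expect_equal(out2$s_ampa[2], 0)
})

test_that("gating decays to the zero fixed point without spikes", {
  st <- network_state(1, -70)
  st$s_ampa[1] <- 1; st$x_nmda[1] <- 1; st$s_nmda[1] <- 0.5; st$s_gaba[1] <- 1
  for (k in 1:20000) st <- colrhythm:::decay_gating(st, 0.5, synapse_constants())
  expect_true(all(abs(c(st$s_ampa, st$s_gaba, st$s_nmda, st$x_nmda)) < 1e-10))
})

test_that("NMDA gating saturates below 1 under sustained firing", {
  st <- network_state(1, -70)
  dt <- 0.05
  set.seed(1)
  s_max <- 0
  for (k in 1:20000) {   # 1 s of 200 Hz presynaptic bombardment
    st <- colrhythm:::decay_gating(st, dt, synapse_constants())
    if (stats::runif(1) < 200 * dt / 1000) {
      st <- colrhythm:::apply_spike_increments(st, 1L, TRUE)
    }
    s_max <- max(s_max, st$s_nmda[1])
  }
  expect_gt(s_max, 0.5)    # approaches saturation
  expect_lte(s_max, 1)     # never exceeds it
})

test_that("synaptic currents match direct evaluation of the receptor sums", {
  # two neurons, one AMPA synapse 1 -> 2 with weight 0.5
  syn <- data.frame(pre = 1L, post = 2L, receptor = "AMPA",
                    weight = 0.5, plastic = 0L)
  st <- network_state(2, c(-70, -70))
  st$s_ampa[1] <- 1
  I <- total_synaptic_current(st, syn, V_I = c(-70, -70))
  expect_equal(I[2], -1 * (-70 - 0) * 0.5)   # 35 pA depolarizing
  expect_equal(I[1], 0)

  # GABA at its reversal potential carries no current
  syn$receptor <- "GABA"
  st2 <- network_state(2, c(-70, -70))
  st2$s_gaba[1] <- 1
  expect_equal(total_synaptic_current(st2, syn, V_I = c(-70, -70))[2], 0)
  # below reversal the GABA term hyperpolarizes
  st2$V[2] <- -60
  expect_lt(total_synaptic_current(st2, syn, V_I = c(-70, -70))[2], 0)

  # all gating zero, no external input: zero current
  st3 <- network_state(2, c(-70, -70))
  expect_equal(total_synaptic_current(st3, syn, V_I = c(-70, -70)), c(0, 0))
})

test_that("resting potential is a fixed point of the membrane update", {
  st <- network_state(1, -70)
  for (k in 1:100) {
    st <- step_membrane(st, 0, C_m = 100, g_L = 5, tau_ref = 2,
                        V_rest = -70, V_th = -40, dt = 0.05)$state
  }
  expect_equal(st$V, -70)
})

test_that("constant-current firing matches the analytic LIF rate within 2%", {
  # one neuron per membrane-parameter set, rheobase and rate from closed form
  mp <- default_membrane_params()[c(2, 6, 10), ]   # E2/3, E4, E5
  for (i in seq_len(nrow(mp))) {
    rheo <- mp$g_L[i] * (mp$V_th[i] - mp$V_rest[i])
    I <- 1.6 * rheo
    st <- network_state(1, mp$V_rest[i])
    n_steps <- round(2000 / 0.05)
    spikes <- 0
    for (k in seq_len(n_steps)) {
      out <- step_membrane(st, I, mp$C_m[i], mp$g_L[i], mp$tau_ref[i],
                           mp$V_rest[i], mp$V_th[i], dt = 0.05)
      st <- out$state
      spikes <- spikes + length(out$spikes)
    }
    expect_equal(1000 * spikes / 2000,
                 lif_analytic_rate(I, mp$C_m[i], mp$g_L[i], mp$tau_ref[i],
                                   mp$V_rest[i], mp$V_th[i]),
                 tolerance = 0.02)
    # below rheobase: silent
    st <- network_state(1, mp$V_rest[i])
    out <- step_membrane(st, 0.9 * rheo, mp$C_m[i], mp$g_L[i], mp$tau_ref[i],
                         mp$V_rest[i], mp$V_th[i], dt = 0.05)
    for (k in 1:20000) {
      out <- step_membrane(out$state, 0.9 * rheo, mp$C_m[i], mp$g_L[i],
                           mp$tau_ref[i], mp$V_rest[i], mp$V_th[i], dt = 0.05)
      if (length(out$spikes)) break
    }
    expect_identical(length(out$spikes), 0L)
  }
})

test_that("compiled core and R reference stepper agree to machine precision", {
  col <- small_column()
  prot <- stimulus_protocol(
    data.frame(group = c("E4", "PV4"), fraction = 1, amplitude = c(300, 200),
               t_on = 0, t_off = 120), seed = 5)
  sim <- run_simulation(col$spec, col$synapses, protocol = prot,
                        duration = 120, dt = 0.05, seed = 7,
                        background = FALSE, record_V = 1:5,
                        record_V_every = 0.05)
  eps <- make_stimulus(prot, col$spec)
  ref <- colrhythm:::simulate_reference(col$spec, col$synapses, duration = 120,
                                        dt = 0.05, protocol_epochs = eps,
                                        background = FALSE, record_V = 1:5)
  o1 <- with(sim$spikes, order(time, neuron))
  o2 <- with(ref$spikes, order(time, neuron))
  expect_gt(nrow(sim$spikes), 50)   # the check exercises real activity
  expect_equal(sim$spikes[o1, ], ref$spikes[o2, ], ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_lt(max(abs(sim$V - ref$V)), 1e-10)

  # and with the stochastic background drive on the same RNG stream
  sim_b <- run_simulation(col$spec, col$synapses, duration = 100, dt = 0.05,
                          seed = 11)
  set.seed(11)
  ref_b <- colrhythm:::simulate_reference(col$spec, col$synapses,
                                          duration = 100, dt = 0.05)
  o1 <- with(sim_b$spikes, order(time, neuron))
  o2 <- with(ref_b$spikes, order(time, neuron))
  expect_equal(sim_b$spikes[o1, ], ref_b$spikes[o2, ], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("simulation is deterministic for a fixed seed and silent without input", {
  col <- small_column()
  a <- run_simulation(col$spec, col$synapses, duration = 100, seed = 3)
  b <- run_simulation(col$spec, col$synapses, duration = 100, seed = 3)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$synapses$weight, b$synapses$weight)

  silent <- run_simulation(col$spec, col$synapses, duration = 100, seed = 3,
                           background = FALSE)
  expect_identical(nrow(silent$spikes), 0L)
})

test_that("refractory contract: inter-spike intervals never undercut tau_ref", {
  col <- small_column()
  prot <- stimulus_protocol(
    data.frame(group = "PV4", fraction = 1, amplitude = 600,
               t_on = 0, t_off = 300), seed = 1)
  sim <- run_simulation(col$spec, col$synapses, protocol = prot,
                        duration = 300, seed = 5)
  pp <- colrhythm:::per_neuron_params(col$spec)
  by_unit <- split(sim$spikes$time, sim$spikes$neuron)
  for (id in names(by_unit)) {
    isi <- diff(sort(by_unit[[id]]))
    if (length(isi)) {
      expect_gte(min(isi), pp$tau_ref[as.integer(id)] - 1e-9)
    }
  }
})

test_that("membrane potentials stay within physical bounds", {
  col <- small_column()
  prot <- stimulus_protocol(
    data.frame(group = "E4", fraction = 1, amplitude = 200,
               t_on = 0, t_off = 200), seed = 1)
  ids <- seq_len(col$spec$n_total)
  sim <- run_simulation(col$spec, col$synapses, protocol = prot,
                        duration = 200, seed = 2, record_V = ids)
  pp <- colrhythm:::per_neuron_params(col$spec)
  lo <- min(pp$V_rest) - 50
  expect_true(all(is.finite(sim$V)))
  expect_true(all(t(sim$V) >= lo - 1e-9))
  expect_true(all(t(sim$V) <= pp$V_th + 1e-9))
})

test_that("time steps above the stability guard are refused unless overridden", {
  col <- small_column()
  expect_error(run_simulation(col$spec, col$synapses, duration = 10, dt = 0.2),
               "stability guard")
  sim <- run_simulation(col$spec, col$synapses, duration = 10, dt = 0.2,
                        seed = 1, allow_large_dt = TRUE, background = FALSE)
  expect_identical(nrow(sim$spikes), 0L)
})

test_that("decoupled column rates rise monotonically with background rate", {
  # G = 0: each group is an isolated population driven only by its Poisson
  # background (monotonic input-output relationship)
  spec0 <- column_spec(300, G = 0)
  conn <- generate_synthetic_connectivity(1)
  rates <- vapply(c(0.7, 0.85, 1.0), function(f) {
    rt <- default_background_rates()
    rt$rate_hz <- rt$rate_hz * f
    spec_f <- column_spec(300, G = 0, bkgnd_rates = rt)
    syn <- build_synapse_table(spec_f, conn, seed = 1)
    sim <- run_simulation(spec_f, syn, duration = 800, seed = 4)
    nrow(sim$spikes)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("decoupled group rates match an independent single-neuron oracle", {
  spec0 <- column_spec(300, G = 0)
  conn <- generate_synthetic_connectivity(1)
  syn <- build_synapse_table(spec0, conn, seed = 1)
  sim <- run_simulation(spec0, syn, duration = 2000, seed = 9)
  mp <- default_membrane_params()
  for (grp in c("E5", "PV4", "SST4")) {
    ids <- colrhythm:::neurons_of_group(spec0, grp)
    n_spk <- sum(sim$spikes$neuron %in% ids & sim$spikes$time > 200)
    rate_net <- 1000 * n_spk / (length(ids) * 1800)
    i <- match(grp, mp$group)
    set.seed(100 + i)
    oracle <- vapply(1:20, function(k) {
      single_neuron_rate(mp$C_m[i], mp$g_L[i], mp$tau_ref[i], mp$V_rest[i],
                         mp$V_th[i],
                         default_background_rates()$rate_hz[
                           default_background_rates()$group == grp],
                         duration_ms = 1500)
    }, numeric(1))
    se <- stats::sd(oracle) / sqrt(length(oracle)) +
      sqrt(rate_net / (length(ids) * 1.8)) / sqrt(length(ids))
    expect_lt(abs(rate_net - mean(oracle)), 3 * se + 0.2)
  }
})
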