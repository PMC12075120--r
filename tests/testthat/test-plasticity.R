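test_that("excitatory STDP kernel matches its closed form at quoted values", {
  cfg <- stdp_config()
  expect_equal(stdp_kernel(1e-9, cfg), 0.02, tolerance = 1e-6)   # x -> 0+
  expect_equal(stdp_kernel(20, cfg), 0.02 * exp(-1))
  expect_equal(stdp_kernel(-20, cfg), -0.021 * exp(-1))
  expect_identical(stdp_kernel(0, cfg), 0)    # simultaneous pairs contribute 0
  x <- seq(1, 100, by = 1)
  expect_true(all(stdp_kernel(x, cfg) > 0))
  expect_true(all(stdp_kernel(-x, cfg) < 0))
})

test_that("inhibitory kernel is a symmetric sunken Mexican hat", {
  cfg <- inh_stdp_config()
  expect_equal(inh_kernel(0, cfg), 0.04 - 0.02)
  expect_equal(inh_kernel(20 * log(2), cfg), 0, tolerance = 1e-12)
  x <- seq(-80, 80, by = 0.5)
  expect_equal(inh_kernel(x, cfg), inh_kernel(-x, cfg))
  expect_true(all(inh_kernel(x[abs(x) < 13.8], cfg) > 0))
  expect_true(all(inh_kernel(x[abs(x) > 13.9], cfg) < 0))
  expect_lt(abs(inh_kernel(500, cfg)), 1e-10)
})

test_that("trace-based train change equals the brute-force pair sum", {
  cfgs <- list(stdp_config(), inh_stdp_config())
  set.seed(99)
  for (cfg in cfgs) {
    for (rep in 1:25) {
      n_pre <- sample(0:20, 1)
      n_post <- sample(0:20, 1)
      t_pre <- sort(stats::runif(n_pre, 0, 300))
      t_post <- sort(stats::runif(n_post, 0, 300))
      expect_equal(stdp_train_change(t_pre, t_post, cfg),
                   pair_sum_stdp(t_pre, t_post, cfg), tolerance = 1e-9)
    }
  }
})

test_that("simulated plasticity equals the pair-sum oracle on recorded trains", {
  # run the column with plasticity and unreachable bounds, then check every
  # plastic connection against the brute-force sum over its recorded spikes
  col <- small_column()
  wide <- stdp_config(w_min = -1e6, w_max = 1e6)
  prot <- stimulus_protocol(
    data.frame(group = c("E4", "E2/3"), fraction = 1, amplitude = c(260, 240),
               t_on = 0, t_off = 400), seed = 2)
  sim <- run_simulation(col$spec, col$synapses, protocol = prot,
                        duration = 400, seed = 21, stdp = wide)
  expect_gt(nrow(sim$spikes), 100)
  trains <- split(sim$spikes$time, sim$spikes$neuron)
  pl0 <- col$synapses[col$synapses$plastic == 1L, ]
  pl1 <- sim$synapses[sim$synapses$plastic == 1L, ]
  key <- paste(pl0$pre, pl0$post)
  pick <- which(!duplicated(key))
  set.seed(31)
  pick <- sample(pick, min(500, length(pick)))
  pre_u <- pl0$pre[pick]; post_u <- pl0$post[pick]
  dw_sim <- (pl1$weight - pl0$weight)[pick]
  dw_oracle <- vapply(seq_along(pick), function(k) {
    pair_sum_stdp(trains[[as.character(pre_u[k])]] %||% numeric(0),
                  trains[[as.character(post_u[k])]] %||% numeric(0),
                  stdp_config())
  }, numeric(1))
  expect_gt(sum(dw_oracle != 0), 50)   # the check exercises real pairings
  expect_lt(max(abs(dw_sim - dw_oracle)), 1e-9)
  # AMPA and NMDA rows of one logical pair carry identical weights
  agg <- tapply(pl1$weight, paste(pl1$pre, pl1$post),
                function(w) diff(range(w)))
  expect_true(all(agg == 0))
})

test_that("weights never leave the configured bounds during conditioning", {
  col <- small_column()
  prot <- stimulus_protocol(
    data.frame(group = "E4", fraction = 1, amplitude = 300,
               t_on = 0, t_off = 600), seed = 2)
  sim <- run_simulation(col$spec, col$synapses, protocol = prot,
                        duration = 600, seed = 22, stdp = stdp_config(),
                        snapshot_times = c(150, 300, 450, 600))
  for (sn in sim$snapshots) {
    expect_true(all(sn$weight >= 0 & sn$weight <= 0.2))
  }
  w1 <- sim$synapses$weight[sim$synapses$plastic == 1L]
  expect_true(all(w1 >= 0 & w1 <= 0.2))
  expect_false(identical(w1, col$synapses$weight[col$synapses$plastic == 1L]))
})

test_that("uncorrelated equal-rate trains drift toward depression", {
  # expected drift per pair is proportional to A+tau+ - A-tau- < 0
  set.seed(7)
  dws <- vapply(1:100, function(k) {
    t_pre <- cumsum(stats::rexp(200, rate = 20 / 1000))   # 20 Hz Poisson
    t_post <- cumsum(stats::rexp(200, rate = 20 / 1000))
    stdp_train_change(t_pre, t_post, stdp_config())
  }, numeric(1))
  expect_lt(mean(dws), 0)
  expect_lt(stats::t.test(dws, alternative = "less")$p.value, 0.01)
})

test_that("disabling plasticity after conditioning freezes weights exactly", {
  col <- small_column()
  prot <- stimulus_protocol(
    data.frame(group = "E4", fraction = 1, amplitude = 280,
               t_on = 0, t_off = 300), seed = 2)
  cond <- run_simulation(col$spec, col$synapses, protocol = prot,
                         duration = 300, seed = 23, stdp = stdp_config())
  after <- run_simulation(col$spec, cond$synapses, protocol = prot,
                          duration = 300, seed = 24, stdp = NULL)
  expect_identical(after$synapses$weight, cond$synapses$weight)
})

test_that("inhibitory plasticity acts on PV->E weights only, within bounds", {
  col <- small_column()
  prot <- stimulus_protocol(
    data.frame(group = c("E4", "PV4"), fraction = 1, amplitude = c(280, 150),
               t_on = 0, t_off = 400), seed = 2)
  sim <- run_simulation(col$spec, col$synapses, protocol = prot,
                        duration = 400, seed = 25,
                        inh_stdp = inh_stdp_config())
  g <- colrhythm:::neuron_groups(col$spec)
  ct <- column_groups()$cell_type
  pv_e <- ct[g[sim$synapses$pre]] == "PV" & ct[g[sim$synapses$post]] == "E"
  changed <- sim$synapses$weight != col$synapses$weight
  expect_true(any(changed[pv_e]))
  expect_false(any(changed[!pv_e]))
  expect_true(all(sim$synapses$weight[pv_e] >= 0))
})

test_that("plasticity summaries report changes and bound fractions", {
  col <- small_column()
  syn0 <- col$synapses
  syn1 <- syn0
  expect_equal(plasticity_summary(syn0, syn1, col$spec)$mean_change, 0)

  syn1$weight[syn1$plastic == 1L] <- 0.2
  s <- plasticity_summary(syn0, syn1, col$spec)
  expect_equal(s$fraction_at_upper, 1)
  expect_equal(s$fraction_at_lower, 0)

  set.seed(4)
  delta <- stats::rnorm(sum(syn0$plastic == 1L), mean = 0.003, sd = 1e-4)
  syn2 <- syn0
  syn2$weight[syn2$plastic == 1L] <- syn0$weight[syn0$plastic == 1L] + delta
  s2 <- plasticity_summary(syn0, syn2, col$spec)
  expect_equal(s2$mean_change, mean(delta), tolerance = 1e-12)

  syn_bad <- syn1[sample(nrow(syn1)), ]
  expect_error(plasticity_summary(syn0, syn_bad, col$spec), "not matched")
})
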