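# shared reduced column for the experiment-level tests
exp_config <- function(seed = 1, n = 500, duration = 800) {
  default_config(n_total = n, duration = duration, seed = seed)
}

test_that("weight shuffling preserves topology, receptors and the weight multiset", {
  col <- small_column()
  syn <- col$synapses
  # give the plastic weights distinguishable values
  set.seed(8)
  syn$weight[syn$plastic == 1L] <- stats::runif(sum(syn$plastic == 1L))
  key <- paste(syn$pre, syn$post)
  pl <- syn$plastic == 1L
  w_pairs <- syn$weight[pl][!duplicated(key[pl])]

  sh <- shuffle_weights(syn, seed = 4)
  expect_identical(sh[, c("pre", "post", "receptor", "plastic")],
                   syn[, c("pre", "post", "receptor", "plastic")])
  expect_identical(sh$weight[!pl], syn$weight[!pl])
  w_pairs_sh <- sh$weight[pl][!duplicated(key[pl])]
  expect_equal(sort(w_pairs_sh), sort(w_pairs))
  expect_equal(mean(w_pairs_sh), mean(w_pairs))
  expect_false(identical(w_pairs_sh, w_pairs))

  # all-equal weights: shuffling is the identity in effect
  syn2 <- col$synapses
  syn2$weight[pl] <- 0.1
  expect_equal(shuffle_weights(syn2, seed = 9)$weight, syn2$weight)
})

test_that("uniformly-increased control matches the conditioned mean exactly", {
  col <- small_column()
  naive <- col$synapses
  conditioned <- naive
  set.seed(10)
  pl <- naive$plastic == 1L
  conditioned$weight[pl] <- pmin(pmax(
    naive$weight[pl] * stats::runif(sum(pl), 0.5, 3), 0), 0.2)
  ui <- uniform_increase(naive, conditioned)
  expect_equal(mean(ui$weight[pl]), mean(conditioned$weight[pl]),
               tolerance = 1e-14)
  # scaling is uniform: weight ratios within scope are preserved
  expect_equal(ui$weight[pl] / naive$weight[pl],
               rep(mean(conditioned$weight[pl]) / mean(naive$weight[pl]),
                   sum(pl)))
  expect_identical(ui$weight[!pl], naive$weight[!pl])

  # identical means: identity
  expect_equal(uniform_increase(naive, naive)$weight, naive$weight)

  zero <- naive; zero$weight[pl] <- 0
  expect_error(uniform_increase(zero, conditioned), "zero")
})

test_that("layer-4 isolation keeps exactly the intra-L4 synapses, reversibly", {
  col <- small_column()
  iso <- isolate_layer4_table(col$synapses, col$spec)
  layer <- column_groups()$layer[colrhythm:::neuron_groups(col$spec)]
  expect_true(all(layer[iso$pre] == "L4" & layer[iso$post] == "L4"))
  in_l4 <- layer[col$synapses$pre] == "L4" & layer[col$synapses$post] == "L4"
  expect_identical(nrow(iso), sum(in_l4))
  # isolation is pure bookkeeping: the kept rows are bit-identical, so
  # restoring the dropped rows reproduces the original table
  expect_equal(iso, col$synapses[in_l4, ], ignore_attr = TRUE)
})

test_that("inactivation is absorbing and silencing inhibition raises E rates", {
  cfg <- exp_config(seed = 2, n = 500, duration = 900)
  col <- build_column(cfg)
  inh_groups <- grep("^(PV|SST|VIP)", group_labels(), value = TRUE)
  ex <- inactivate_groups(cfg, groups = inh_groups, t_off = 450, column = col)
  silenced <- unlist(lapply(inh_groups, colrhythm:::neurons_of_group,
                            spec = col$spec))
  late <- ex$sim$spikes$time > 450
  expect_identical(sum(ex$sim$spikes$neuron[late] %in% silenced), 0L)
  e_groups <- grep("^E", group_labels(), value = TRUE)
  expect_true(all(ex$rates_after[e_groups] > ex$rates_before[e_groups]))

  # inactivating every group silences the whole column
  ex_all <- inactivate_groups(cfg, groups = group_labels(), t_off = 300,
                              column = col, duration = 500)
  expect_identical(sum(ex_all$sim$spikes$time > 300), 0L)

  # PV-subset inactivation: only the requested number of cells is silenced
  ex_sub <- inactivate_groups(cfg, groups = "PV4", t_off = 200, column = col,
                              duration = 400, pv_subset = 3)
  pv_ids <- colrhythm:::neurons_of_group(col$spec, "PV4")
  off <- pv_ids[1:3]
  late <- ex_sub$sim$spikes$time > 200
  expect_identical(sum(ex_sub$sim$spikes$neuron[late] %in% off), 0L)
  expect_gt(sum(ex_sub$sim$spikes$neuron[late] %in% pv_ids[-(1:3)]), 0L)

  expect_warning(inactivate_groups(cfg, groups = character(0), t_off = 100,
                                   column = col, duration = 200),
                 "no groups")
})

test_that("spontaneous experiment summarizes rates, CV and synchrony", {
  cfg <- exp_config(seed = 3, n = 500, duration = 800)
  col <- build_column(cfg)
  ids <- colrhythm:::neurons_of_group(col$spec, "E5")[1:10]
  ex <- run_spontaneous(cfg, column = col, record_V = ids)
  expect_named(ex$rates, group_labels())
  expect_true(all(ex$rates >= 0))
  expect_true(is.finite(ex$chi) && ex$chi >= 0 && ex$chi <= 1)

  # silent column when all background rates are zero
  rt <- default_background_rates(); rt$rate_hz[] <- 0
  spec0 <- column_spec(500, bkgnd_rates = rt)
  col0 <- list(spec = spec0, conn = col$conn,
               synapses = build_synapse_table(spec0, col$conn, seed = 1))
  ex0 <- run_spontaneous(cfg, column = col0, duration = 300)
  expect_true(all(ex0$rates == 0))
})

test_that("zero-amplitude stimulation reproduces spontaneous statistics", {
  cfg <- exp_config(seed = 4, n = 500, duration = 1200)
  col <- build_column(cfg)
  prot <- stimulus_protocol(
    data.frame(group = "E4", fraction = 0.5, amplitude = 0,
               t_on = 600, t_off = 1200), seed = cfg$seeds$stimulus)
  ev <- run_evoked(cfg, column = col, protocol = prot)
  sp <- run_spontaneous(cfg, column = col)
  expect_identical(ev$sim$spikes, sp$sim$spikes)
})

test_that("the stimulated layer responds first (activation latency)", {
  lat <- sapply(5:7, function(seed) {
    cfg <- default_config(n_total = 1000, seed = seed, duration = 1400)
    cfg$stimulus$epochs <- data.frame(group = "E4", fraction = 1,
                                      amplitude = 30, t_on = 700, t_off = 1400)
    run_evoked(cfg)$latency[c("E4", "E2/3", "E5", "E6")]
  })
  m <- rowMeans(lat, na.rm = TRUE)
  expect_true(all(m["E4"] < m[c("E2/3", "E5", "E6")], na.rm = TRUE))
  # the stimulated layer shows a crisp early response
  expect_lt(m["E4"], 100)
})

test_that("restricting the plasticity scope restricts the changed weights", {
  cfg <- exp_config(seed = 5, n = 500)
  col <- build_column(cfg)
  cond <- run_conditioning(cfg, column = col, duration = 1500,
                           scope = "from_L4")
  changed <- cond$synapses_conditioned$weight != cond$synapses_naive$weight
  g <- colrhythm:::neuron_groups(col$spec)
  expect_true(any(changed))
  expect_true(all(g[cond$synapses_naive$pre[changed]] ==
                    colrhythm:::group_index("E4")))

  # empty scope: conditioning changes nothing
  syn_off <- col$synapses
  syn_off$plastic <- 0L
  col_off <- col; col_off$synapses <- syn_off
  cond0 <- run_conditioning(cfg, column = col_off, duration = 600)
  expect_identical(cond0$synapses_conditioned$weight,
                   cond0$synapses_naive$weight)
})

test_that("experiments re-run bit-identically from their provenance", {
  cfg <- exp_config(seed = 6, n = 500, duration = 500)
  a <- run_spontaneous(cfg)
  b <- run_spontaneous(a$config)
  expect_identical(a$sim$spikes, b$sim$spikes)
  expect_identical(a$rates, b$rates)
})

test_that("run manifests verify and detect tampering", {
  cfg <- exp_config(seed = 7, n = 500, duration = 400)
  ex <- run_spontaneous(cfg)
  dir <- file.path(tempdir(), "colrhythm-run")
  write_run_manifest(ex, dir)
  expect_true(verify_run_manifest(dir))
  # tamper with an output file
  cat("tamper\n", file = file.path(dir, "spikes.csv"), append = TRUE)
  expect_error(verify_run_manifest(dir), "checksum mismatch")
  unlink(dir, recursive = TRUE)
})

test_that("configurations round-trip through YAML with defaults applied", {
  empty <- tempfile(fileext = ".yaml")
  writeLines("", empty)
  cfg <- load_config(empty)
  ref <- default_config()
  expect_equal(cfg$network$n_total, ref$network$n_total)
  expect_equal(cfg$plasticity$A_minus, 0.021)
  expect_equal(cfg$dynamics$dt, 0.05)

  p2 <- tempfile(fileext = ".yaml")
  save_config(cfg, p2)
  expect_equal(load_config(p2), cfg)

  bad <- tempfile(fileext = ".yaml")
  writeLines("dynamics:\n  dt: 0.2\n", bad)
  expect_error(load_config(bad), "stability guard")
  writeLines("network:\n  matrices: files\n", bad)
  expect_error(load_config(bad), "path_P")
  unlink(c(empty, p2, bad))
})
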