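#' Build the column described by a run configuration
#'
#' Materializes the network of a [default_config()]-style configuration:
#' the [column_spec()], the connectivity (synthetic or loaded from files,
#' per `network$matrices`) and the realized synapse table (wiring seed).
#'
#' @param config a run configuration list (see [default_config()]).
#' @return A list `(spec, conn, synapses)`.
#' @export
build_column <- function(config) {
  spec <- column_spec(n_total = config$network$n_total, G = config$network$G)
  conn <- if (identical(config$network$matrices, "files")) {
    load_connectivity(config$network$path_P, config$network$path_S)
  } else {
    generate_synthetic_connectivity(seed = config$seeds$wiring,
                                    style = config$network$style)
  }
  synapses <- build_synapse_table(spec, conn, seed = config$seeds$wiring)
  list(spec = spec, conn = conn, synapses = synapses)
}

# shared driver: run one simulation under a config, with optional overrides
run_column <- function(config, column = NULL, synapses = NULL,
                       protocol = NULL, stdp = NULL, inh_stdp = NULL,
                       inactivate_from = NULL, record_V = integer(0),
                       snapshot_times = numeric(0), duration = NULL,
                       background = TRUE) {
  if (is.null(column)) column <- build_column(config)
  if (is.null(synapses)) synapses <- column$synapses
  dyn <- config$dynamics
  consts <- synapse_constants(g_AMPA = dyn$g_AMPA, g_NMDA = dyn$g_NMDA,
                              g_GABA = dyn$g_GABA, Mg = dyn$Mg)
  run_simulation(
    spec = column$spec, synapses = synapses, protocol = protocol,
    duration = if (is.null(duration)) dyn$duration else duration,
    dt = dyn$dt, seed = config$seeds$background,
    stdp = stdp, inh_stdp = inh_stdp, consts = consts,
    gaba_reversal = dyn$gaba_reversal, background = background,
    record_V = record_V, record_V_every = config$output$record_V_every,
    snapshot_times = snapshot_times, inactivate_from = inactivate_from)
}

# spikes -> mean rate (Hz) per group over [t_from, t_to]
group_rates <- function(sim, t_from = 0, t_to = sim$duration) {
  spec <- sim$spec
  sel <- sim$spikes$time > t_from & sim$spikes$time <= t_to
  g <- neuron_groups(spec)[sim$spikes$neuron[sel]]
  counts <- tabulate(g, 17L)
  rate <- 1000 * counts / (spec$counts * (t_to - t_from))
  stats::setNames(rate, group_labels())
}

new_experiment <- function(type, sim, config, extra = list()) {
  structure(c(list(type = type, sim = sim, config = config,
                   rates = group_rates(sim)), extra),
            class = "col_experiment")
}

#' @export
print.col_experiment <- function(x, ...) {
  cat("<col_experiment:", x$type, "> ", x$sim$spec$n_total, " neurons, ",
      x$sim$duration, " ms\n", sep = "")
  print(round(x$rates, 2))
  invisible(x)
}

#' Spontaneous activity of the column
#'
#' Simulates the column under background drive only (default display window
#' 1,500 ms) and summarizes per-group mean firing rates, inter-spike-interval
#' irregularity (CV) and, if membrane traces are recorded, population
#' synchrony.
#'
#' @param config a run configuration ([default_config()]).
#' @param column optional pre-built column ([build_column()]) to reuse.
#' @param synapses optional synapse-table override (e.g. conditioned weights).
#' @param duration optional duration override (ms).
#' @param record_V neuron ids whose membrane potential to record (for the
#'   synchrony measure).
#' @return A `col_experiment` with `rates` (Hz per group), `cv` (mean ISI CV
#'   per group) and `chi` (synchrony; `NA` unless `record_V` given).
#' @export
run_spontaneous <- function(config = default_config(), column = NULL,
                            synapses = NULL, duration = NULL,
                            record_V = integer(0)) {
  sim <- run_column(config, column = column, synapses = synapses,
                    duration = duration, record_V = record_V)
  cv <- vapply(group_labels(), function(g) {
    isi_cv(sim$spikes, sim$spec, g)$mean_cv
  }, numeric(1))
  chi <- if (length(record_V) >= 2 && any(apply(sim$V, 2, stats::var) > 0)) {
    synchrony_chi(sim$V)
  } else NA_real_
  new_experiment("spontaneous", sim, config, list(cv = cv, chi = chi))
}

#' Stimulus-evoked activity and activation latencies
#'
#' Applies the configured stimulus (default: 30 pA to a fraction of the
#' layer-4 pyramidal cells at `t_on = 700` ms) and reports per-group
#' activation latencies — the time for each population's rate (200-ms sliding
#' window) to reach half of its maximum evoked increase.
#'
#' @inheritParams run_spontaneous
#' @param protocol optional [stimulus_protocol()] override; defaults to the
#'   config's `stimulus$epochs`.
#' @return A `col_experiment` with `latency` (ms per group; `NA` where no
#'   evoked increase was detected), `evoked_rates` and `spont_rates`.
#' @export
run_evoked <- function(config = default_config(), column = NULL,
                       synapses = NULL, protocol = NULL, duration = NULL) {
  if (is.null(protocol)) protocol <- config_protocol(config)
  if (is.null(protocol)) {
    stop("run_evoked() needs a stimulus protocol", call. = FALSE)
  }
  sim <- run_column(config, column = column, synapses = synapses,
                    protocol = protocol, duration = duration)
  onset <- min(protocol$epochs$t_on)
  lat <- vapply(group_labels(), function(g) {
    tr <- population_rate(sim$spikes, sim$spec, g,
                          window = config$analysis$rate_window,
                          t_range = c(0, sim$duration))
    tryCatch(activation_latency(tr, stim_onset = onset),
             error = function(e) NA_real_)
  }, numeric(1))
  new_experiment("evoked", sim, config, list(
    latency = lat,
    spont_rates = group_rates(sim, 0, onset),
    evoked_rates = group_rates(sim, onset, sim$duration),
    stim_onset = onset))
}

#' STDP conditioning of the column
#'
#' Enables plasticity and applies sustained feedforward input (default 30 pA
#' to half of the layer-4 pyramidal cells from 500 ms on). All E -> E
#' connections flagged plastic in the synapse table evolve under the STDP
#' rule; the scope can be restricted to efferents of layer-4 pyramidal cells
#' (`"from_L4"`) or to everything except layer-4 efferents (`"except_from_L4"`).
#' Returns the naive and conditioned tables plus optional checkpoints.
#'
#' @inheritParams run_spontaneous
#' @param duration conditioning time (ms); the published runs use 55,000.
#' @param scope plasticity scope: `"all"`, `"from_L4"`, `"except_from_L4"`.
#' @param snapshot_times checkpoint times (ms) for plastic-weight snapshots.
#' @param record_V optional membrane recording ids.
#' @return A `col_experiment` with `synapses_naive`, `synapses_conditioned`,
#'   `snapshots`, and the STDP settings used.
#' @export
run_conditioning <- function(config = default_config(), column = NULL,
                             duration = 55000,
                             scope = c("all", "from_L4", "except_from_L4"),
                             snapshot_times = numeric(0),
                             record_V = integer(0)) {
  scope <- match.arg(scope)
  if (is.null(column)) column <- build_column(config)
  syn <- set_plasticity_scope(column$synapses, column$spec, scope)
  stdp <- config_stdp(config)
  inh <- if (isTRUE(config$plasticity$inh_enabled)) config_inh_stdp(config)
  protocol <- config_protocol(config)
  if (is.null(protocol)) {
    protocol <- stimulus_protocol(
      data.frame(group = "E4", fraction = 0.5, amplitude = 30,
                 t_on = 500, t_off = Inf),
      seed = config$seeds$stimulus)
  }
  sim <- run_column(config, column = column, synapses = syn,
                    protocol = protocol, stdp = stdp, inh_stdp = inh,
                    duration = duration, snapshot_times = snapshot_times,
                    record_V = record_V)
  new_experiment("conditioning", sim, config, list(
    synapses_naive = syn,
    synapses_conditioned = sim$synapses,
    snapshots = sim$snapshots,
    scope = scope, stdp = stdp, protocol = protocol))
}

# restrict the plastic flag of an E->E table to a laminar scope
set_plasticity_scope <- function(synapses, spec, scope) {
  if (scope == "all") return(synapses)
  g <- neuron_groups(spec)
  pre_l4e <- g[synapses$pre] == group_index("E4")
  post_l4 <- column_groups()$layer[g[synapses$post]] == "L4"
  pre_l4 <- column_groups()$layer[g[synapses$pre]] == "L4"
  keep <- switch(scope,
    from_L4 = pre_l4e,
    except_from_L4 = !(pre_l4 | post_l4))
  synapses$plastic <- as.integer(synapses$plastic == 1L & keep)
  synapses
}

#' Inactivate cell groups during a run
#'
#' From `t_off` on, all neurons of the given groups are clamped at their
#' resting potential and emit no spikes (their synaptic gating decays
#' naturally). `pv_subset` optionally silences only the first `pv_subset`
#' PV cells of each targeted PV group (used to match the size of another
#' population, e.g. the layer-4 SST count).
#'
#' @inheritParams run_spontaneous
#' @param groups character vector of group labels to silence.
#' @param t_off inactivation time (ms).
#' @param protocol optional stimulus protocol (e.g. the conditioning input).
#' @param pv_subset optional number of cells to silence per group instead of
#'   the whole group.
#' @return A `col_experiment` with `rates_before`/`rates_after` (per group,
#'   relative to `t_off`) and the inactivation metadata.
#' @export
inactivate_groups <- function(config = default_config(), groups, t_off,
                              column = NULL, synapses = NULL, protocol = NULL,
                              duration = NULL, pv_subset = NULL) {
  if (length(groups) == 0) {
    warning("no groups to inactivate; running unchanged")
  }
  if (is.null(column)) column <- build_column(config)
  spec <- column$spec
  inact <- rep(Inf, spec$n_total)
  for (g in groups) {
    ids <- neurons_of_group(spec, g)
    if (!is.null(pv_subset)) ids <- ids[seq_len(min(pv_subset, length(ids)))]
    inact[ids] <- t_off
  }
  sim <- run_column(config, column = column, synapses = synapses,
                    protocol = protocol, inactivate_from = inact,
                    duration = duration)
  new_experiment("inactivation", sim, config, list(
    groups = groups, t_off = t_off,
    rates_before = group_rates(sim, 0, t_off),
    rates_after = group_rates(sim, t_off, sim$duration)))
}

#' Isolate the layer-4 subcircuit
#'
#' `isolate_layer4_table()` removes every synapse with an endpoint outside
#' layer 4, keeping the L4 <-> L4 connections (weights untouched, so a
#' conditioned table stays conditioned). `run_isolated_layer4()` simulates the
#' column with the filtered table; background and stimulus are unchanged.
#'
#' @param synapses a synapse table (typically conditioned weights).
#' @param spec the [column_spec()].
#' @return The filtered synapse table.
#' @export
isolate_layer4_table <- function(synapses, spec) {
  layer <- column_groups()$layer[neuron_groups(spec)]
  keep <- layer[synapses$pre] == "L4" & layer[synapses$post] == "L4"
  out <- synapses[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname isolate_layer4_table
#' @inheritParams inactivate_groups
#' @export
run_isolated_layer4 <- function(config = default_config(), synapses,
                                column = NULL, protocol = NULL,
                                duration = NULL) {
  if (is.null(column)) column <- build_column(config)
  iso <- isolate_layer4_table(synapses, column$spec)
  sim <- run_column(config, column = column, synapses = iso,
                    protocol = protocol, duration = duration)
  new_experiment("isolated_L4", sim, config, list(synapses_isolated = iso))
}

#' Shuffle conditioned weights between cell pairs
#'
#' Control for the role of weight structure: permutes the logical weights of
#' the in-scope connections between (pre, post) pairs, preserving the graph
#' topology, receptor labels and the multiset of pair weights exactly (and
#' hence any overall increase in coupling). The AMPA and NMDA rows of one
#' pair stay equal to each other.
#'
#' @param synapses a synapse table.
#' @param seed permutation seed.
#' @param scope `"plastic"` (default: the plastic E -> E pairs) or `"all"`.
#' @return The table with permuted weights.
#' @export
shuffle_weights <- function(synapses, seed, scope = c("plastic", "all")) {
  scope <- match.arg(scope)
  rows <- if (scope == "plastic") which(synapses$plastic == 1L) else
    seq_len(nrow(synapses))
  if (!length(rows)) return(synapses)
  key <- paste(synapses$pre[rows], synapses$post[rows])
  pair_of_row <- match(key, unique(key))
  pair_w <- synapses$weight[rows][!duplicated(pair_of_row)]
  set.seed(as.integer(seed))
  perm <- sample.int(length(pair_w))
  synapses$weight[rows] <- pair_w[perm][pair_of_row]
  synapses
}

#' Uniformly-increased control
#'
#' Scales every in-scope naive weight by the ratio of conditioned to naive
#' mean weight, so the mean matches the conditioned table exactly while the
#' plasticity-sculpted weight structure is absent.
#'
#' @param table_naive,table_conditioned matched synapse tables.
#' @param scope `"plastic"` or `"all"`.
#' @return The uniformly-increased table.
#' @export
uniform_increase <- function(table_naive, table_conditioned,
                             scope = c("plastic", "all")) {
  scope <- match.arg(scope)
  if (nrow(table_naive) != nrow(table_conditioned)) {
    stop("tables are not matched", call. = FALSE)
  }
  rows <- if (scope == "plastic") which(table_naive$plastic == 1L) else
    seq_len(nrow(table_naive))
  m0 <- mean(table_naive$weight[rows])
  if (m0 == 0) stop("naive mean weight is zero; cannot scale", call. = FALSE)
  m1 <- mean(table_conditioned$weight[rows])
  out <- table_naive
  out$weight[rows] <- out$weight[rows] * (m1 / m0)
  out
}

#' Sweep feedforward or feedback input strength
#'
#' Runs the column (typically with frozen conditioned weights) over a grid of
#' input amplitudes and reports, per amplitude, the peak frequency and peak
#' power of each layer's pyramidal rate spectrum. `FF_L4` sweeps the
#' layer-4 input amplitude; `FB_L5` sweeps a layer-5 input while layer 4 is
#' held at `ff_hold` (30 pA).
#'
#' @inheritParams run_spontaneous
#' @param axis `"FF_L4"` or `"FB_L5"`.
#' @param amplitudes input grid (pA); the default mirrors the published range.
#' @param t_on stimulus onset (ms); spectra are computed from `t_on + 200` on.
#' @param ff_hold layer-4 amplitude held constant during the FB sweep (pA).
#' @param groups E groups to analyze.
#' @return A data.frame: `amplitude`, `group`, `peak_frequency`, `peak_power`.
#' @export
input_sweep <- function(config = default_config(), synapses = NULL,
                        column = NULL,
                        axis = c("FF_L4", "FB_L5"),
                        amplitudes = c(0, 10, 20, 30, 40, 50, 60),
                        duration = NULL, t_on = 500, ff_hold = 30,
                        groups = c("E2/3", "E4", "E5", "E6")) {
  axis <- match.arg(axis)
  if (is.null(column)) column <- build_column(config)
  if (is.null(duration)) duration <- config$dynamics$duration
  res <- vector("list", length(amplitudes))
  for (i in seq_along(amplitudes)) {
    amp <- amplitudes[i]
    ep <- if (axis == "FF_L4") {
      data.frame(group = "E4", fraction = 0.5, amplitude = amp,
                 t_on = t_on, t_off = Inf)
    } else {
      rbind(
        data.frame(group = "E4", fraction = 0.5, amplitude = ff_hold,
                   t_on = t_on, t_off = Inf),
        data.frame(group = "E5", fraction = 0.5, amplitude = amp,
                   t_on = t_on, t_off = Inf))
    }
    ep <- ep[ep$amplitude != 0, , drop = FALSE]
    protocol <- if (nrow(ep)) stimulus_protocol(ep, seed = config$seeds$stimulus)
    sim <- run_column(config, column = column, synapses = synapses,
                      protocol = protocol, duration = duration)
    res[[i]] <- do.call(rbind, lapply(groups, function(g) {
      # short rate window: a 200-ms display window would low-pass away the
      # beta/gamma band this sweep is about
      tr <- population_rate(sim$spikes, sim$spec, g,
                            window = config$analysis$psd_rate_window,
                            t_range = c(0, duration))
      ps <- power_spectrum(tr, t_start = t_on + 200, t_end = duration,
                           segment_ms = config$analysis$psd_segment_ms,
                           band = config$analysis$band)
      data.frame(amplitude = amp, group = g,
                 peak_frequency = ps$peak_frequency,
                 peak_power = ps$peak_power)
    }))
  }
  do.call(rbind, res)
}
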