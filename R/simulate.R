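#' Simulate the column
#'
#' Integrates the full network (LIF membranes, AMPA/NMDA/GABA gating,
#' per-neuron Poisson background, optional stimulus epochs, optional online
#' plasticity) with the compiled core. Deterministic for a fixed
#' `seed`/`dt`/inputs.
#'
#' @param spec a [column_spec()].
#' @param synapses a synapse table from [build_synapse_table()] (or read from
#'   file). When STDP is enabled, rows flagged `plastic == 1` define the
#'   plasticity scope; the AMPA and NMDA rows of one (pre, post) pair evolve
#'   as a single logical weight.
#' @param protocol a [stimulus_protocol()] or `NULL` for no external input.
#' @param duration simulated time (ms).
#' @param dt integration step (ms); refused above 0.1 unless
#'   `allow_large_dt = TRUE`. Background binning additionally requires
#'   `max rate * dt < 0.25`.
#' @param seed integer seed for the background generators (one independent
#'   Bernoulli stream per neuron per step, probability `rate * dt`).
#' @param stdp `NULL` (plasticity off) or a [stdp_config()].
#' @param inh_stdp `NULL` or an [inh_stdp_config()] applied to PV -> E GABA
#'   synapses.
#' @param consts [synapse_constants()].
#' @param gaba_reversal `"postsynaptic"` (default; GABA reverses at the
#'   postsynaptic cell's resting potential) or `"presynaptic"`.
#' @param background `TRUE` to use the spec's rates, `FALSE` to silence the
#'   background drive.
#' @param record_V integer neuron ids whose membrane potential is sampled.
#' @param record_V_every sampling interval (ms) for membrane traces.
#' @param snapshot_times times (ms) at which plastic weights are snapshotted.
#' @param inactivate_from per-neuron times (ms) after which a neuron is
#'   clamped at rest and emits no spikes (`Inf` = never), or `NULL`.
#' @param allow_large_dt override the `dt` stability guard.
#' @return A list of class `col_sim`: `spikes` (data.frame `neuron`, `time`),
#'   `synapses` (input table with final weights), `V` (matrix, one column per
#'   recorded neuron; attribute `"time"`), `snapshots` (list of data.frames
#'   `pre`, `post`, `weight` of the plastic pairs), `duration`, `dt`, `seed`,
#'   `spec`.
#' @export
run_simulation <- function(spec, synapses, protocol = NULL, duration = 1000,
                           dt = 0.05, seed = 1, stdp = NULL, inh_stdp = NULL,
                           consts = synapse_constants(),
                           gaba_reversal = c("postsynaptic", "presynaptic"),
                           background = TRUE,
                           record_V = integer(0), record_V_every = 1,
                           snapshot_times = numeric(0),
                           inactivate_from = NULL,
                           allow_large_dt = FALSE) {
  gaba_reversal <- match.arg(gaba_reversal)
  if (dt > 0.1 && !allow_large_dt) {
    stop("dt = ", dt, " ms exceeds the 0.1 ms stability guard ",
         "(pass allow_large_dt = TRUE to override)", call. = FALSE)
  }
  pp <- per_neuron_params(spec)
  n <- spec$n_total
  if (isTRUE(background) && max(pp$bkg_rate) * dt / 1000 >= 0.25) {
    stop("background binning requires rate * dt < 0.25; reduce dt",
         call. = FALSE)
  }
  stopifnot(all(synapses$pre >= 1), all(synapses$post <= n))

  cs <- build_core_structures(synapses, n, pp,
                              stdp_on = !is.null(stdp),
                              inh_stdp_on = !is.null(inh_stdp))
  if (!is.null(stdp) && length(cs$pl_w)) {
    # the rule bounds the weights as a whole: plastic weights start inside
    # [w_min, w_max] (relevant when Eq.-11 initial values exceed the cap at
    # small network sizes)
    cs$pl_w <- pmin(pmax(cs$pl_w, stdp$w_min), stdp$w_max)
    for (idx in list(cs$pl_ampa, cs$pl_nmda)) {
      has <- idx >= 0L
      cs$syn_w[idx[has] + 1L] <- cs$pl_w[has]
    }
  }
  epochs <- resolve_protocol(protocol, spec)
  ep_ptr <- c(0L, cumsum(vapply(epochs, function(e) length(e$targets),
                                integer(1))))
  ep_targets <- as.integer(unlist(lapply(epochs, function(e) e$targets),
                                  use.names = FALSE)) - 1L
  num <- function(f) vapply(epochs, function(e) as.numeric(e[[f]]), numeric(1))

  if (is.null(inactivate_from)) inactivate_from <- rep(Inf, n)
  stopifnot(length(inactivate_from) == n)

  stdp_pars <- if (is.null(stdp)) stdp_config() else stdp
  inh_pars <- if (is.null(inh_stdp)) inh_stdp_config() else inh_stdp

  set.seed(as.integer(seed))
  out <- .simulate_core(
    n = n, C_m = pp$C_m, g_L = pp$g_L, tau_ref = pp$tau_ref,
    V_rest = pp$V_rest, V_th = pp$V_th, V_I = pp$V_rest,
    is_exc = pp$is_exc,
    bkg_prob = if (isTRUE(background)) pp$bkg_rate * dt / 1000 else numeric(n),
    syn_ptr = cs$syn_ptr, syn_post = cs$syn_post, syn_rec = cs$syn_rec,
    syn_w_in = cs$syn_w,
    nmda_ptr = cs$nmda_ptr, nmda_idx = cs$nmda_idx,
    pl_pre = cs$pl_pre, pl_post = cs$pl_post, pl_w_in = cs$pl_w,
    pl_ampa = cs$pl_ampa, pl_nmda = cs$pl_nmda,
    pl_by_pre_ptr = cs$pl_by_pre_ptr, pl_by_pre = cs$pl_by_pre,
    pl_by_post_ptr = cs$pl_by_post_ptr, pl_by_post = cs$pl_by_post,
    ipl_pre = cs$ipl_pre, ipl_post = cs$ipl_post, ipl_syn = cs$ipl_syn,
    ipl_by_pre_ptr = cs$ipl_by_pre_ptr, ipl_by_pre = cs$ipl_by_pre,
    ipl_by_post_ptr = cs$ipl_by_post_ptr, ipl_by_post = cs$ipl_by_post,
    consts = consts, stdp = unclass(stdp_pars), inh_stdp = unclass(inh_pars),
    stdp_on = !is.null(stdp), inh_stdp_on = !is.null(inh_stdp),
    gaba_pre_reversal = (gaba_reversal == "presynaptic"),
    ep_on = num("t_on"), ep_off = num("t_off"), ep_amp = num("amplitude"),
    ep_ptr = ep_ptr, ep_targets = ep_targets,
    inact_from = as.numeric(inactivate_from),
    dt = dt, duration = duration,
    rec_ids = as.integer(record_V) - 1L, rec_every = record_V_every,
    snap_times = as.numeric(snapshot_times))

  syn_out <- synapses
  syn_out$weight <- out$syn_w[cs$order_back]
  V <- out$V_rec
  if (length(record_V)) {
    colnames(V) <- as.character(record_V)
    attr(V, "time") <- out$V_rec_time
  }
  snaps <- lapply(out$snapshots, function(w) {
    data.frame(pre = cs$pl_pre + 1L, post = cs$pl_post + 1L, weight = w)
  })
  structure(
    list(spikes = data.frame(neuron = out$spike_neuron, time = out$spike_time),
         synapses = syn_out, V = V,
         snapshots = snaps, snapshot_times = snapshot_times,
         duration = duration, dt = dt, seed = seed, spec = spec,
         gaba_reversal = gaba_reversal),
    class = "col_sim"
  )
}

#' @export
print.col_sim <- function(x, ...) {
  cat("<col_sim> ", x$spec$n_total, " neurons, ", x$duration, " ms, ",
      nrow(x$spikes), " spikes\n", sep = "")
  invisible(x)
}

# Pack a synapse table into the flat 0-based CSR structures the compiled core
# consumes. Returns also `order_back` mapping core order back to input rows.
build_core_structures <- function(synapses, n, pp, stdp_on, inh_stdp_on) {
  dt_syn <- data.table::as.data.table(synapses)
  dt_syn[, row0 := .I]
  data.table::setorder(dt_syn, pre, post, receptor)
  m <- nrow(dt_syn)
  rec_code <- match(dt_syn$receptor, c("AMPA", "NMDA", "GABA")) - 1L
  if (anyNA(rec_code)) stop("unknown receptor label in synapse table",
                            call. = FALSE)
  ptr <- function(idx, nbins) c(0L, cumsum(tabulate(idx, nbins)))
  syn_ptr <- ptr(dt_syn$pre, n)

  nm <- which(rec_code == 1L)
  nmda_ptr <- ptr(dt_syn$pre[nm], n)
  nmda_idx <- nm - 1L

  # plastic logical connections: merge AMPA+NMDA rows of one (pre, post) pair
  pl_rows <- which(dt_syn$plastic == 1L & stdp_on)
  if (length(pl_rows)) {
    pl <- data.table::data.table(pre = dt_syn$pre[pl_rows],
                                 post = dt_syn$post[pl_rows],
                                 rec = rec_code[pl_rows],
                                 w = dt_syn$weight[pl_rows],
                                 idx = pl_rows - 1L)
    conn <- pl[, .(w = w[1],
                   ampa = if (any(rec == 0L)) idx[rec == 0L][1] else -1L,
                   nmda = if (any(rec == 1L)) idx[rec == 1L][1] else -1L),
               by = .(pre, post)]
    pl_pre <- conn$pre - 1L
    pl_post <- conn$post - 1L
    pl_w <- conn$w
    pl_ampa <- conn$ampa
    pl_nmda <- conn$nmda
  } else {
    pl_pre <- pl_post <- pl_ampa <- pl_nmda <- integer(0)
    pl_w <- numeric(0)
  }
  adj <- function(keys) {
    o <- order(keys)
    list(ptr = ptr(keys[o], n), idx = as.integer(o - 1L))
  }
  bp <- adj(pl_pre + 1L)
  bq <- adj(pl_post + 1L)

  # inhibitory plastic connections: PV -> E GABA synapses
  if (inh_stdp_on) {
    glab <- column_groups()
    irows <- which(rec_code == 2L &
                     glab$cell_type[pp$group[dt_syn$pre]] == "PV" &
                     pp$is_exc[dt_syn$post])
  } else {
    irows <- integer(0)
  }
  ipl_pre <- dt_syn$pre[irows] - 1L
  ipl_post <- dt_syn$post[irows] - 1L
  ipl_syn <- irows - 1L
  ip <- adj(ipl_pre + 1L)
  iq <- adj(ipl_post + 1L)

  list(
    syn_ptr = as.integer(syn_ptr), syn_post = dt_syn$post - 1L,
    syn_rec = rec_code, syn_w = dt_syn$weight,
    nmda_ptr = as.integer(nmda_ptr), nmda_idx = as.integer(nmda_idx),
    pl_pre = as.integer(pl_pre), pl_post = as.integer(pl_post), pl_w = pl_w,
    pl_ampa = as.integer(pl_ampa), pl_nmda = as.integer(pl_nmda),
    pl_by_pre_ptr = as.integer(bp$ptr), pl_by_pre = bp$idx,
    pl_by_post_ptr = as.integer(bq$ptr), pl_by_post = bq$idx,
    ipl_pre = as.integer(ipl_pre), ipl_post = as.integer(ipl_post),
    ipl_syn = as.integer(ipl_syn),
    ipl_by_pre_ptr = as.integer(ip$ptr), ipl_by_pre = ip$idx,
    ipl_by_post_ptr = as.integer(iq$ptr), ipl_by_post = iq$idx,
    order_back = order(dt_syn$row0)
  )
}
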