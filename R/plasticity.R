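#' Configuration of the excitatory pair-based STDP rule
#'
#' Exponential spike-timing-dependent plasticity on excitatory-to-excitatory
#' synapses: a pre-before-post pair at lag `x = t_post - t_pre > 0`
#' potentiates by `A_plus * exp(-x / tau_plus)`, a post-before-pre pair
#' depresses by `A_minus * exp(x / tau_minus)` (`x < 0`). The weight change of
#' a synapse is the sum over all spike pairs; exactly simultaneous spikes
#' contribute nothing. Weights are clipped into `[w_min, w_max]` after every
#' update. Published values: `A_plus = 0.02`, `A_minus = 0.021`, both time
#' constants 20 ms, bounds `[0, 0.2]`. Slight depression dominance
#' (`A_minus * tau_minus > A_plus * tau_plus`) makes weights drift down under
#' uncorrelated firing.
#'
#' @param A_plus,A_minus potentiation/depression amplitudes (> 0).
#' @param tau_plus,tau_minus kernel time constants (ms).
#' @param w_min,w_max weight bounds.
#' @return An object of class `stdp_config`.
#' @export
stdp_config <- function(A_plus = 0.02, A_minus = 0.021,
                        tau_plus = 20, tau_minus = 20,
                        w_min = 0, w_max = 0.2) {
  stopifnot(A_plus > 0, A_minus > 0, tau_plus > 0, tau_minus > 0,
            w_min < w_max)
  structure(list(A_plus = A_plus, A_minus = A_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, w_min = w_min, w_max = w_max),
            class = "stdp_config")
}

#' Configuration of the inhibitory "sunken Mexican hat" plasticity rule
#'
#' Symmetric rule for PV -> pyramidal synapses: a spike pair at lag `x`
#' changes the inhibitory weight by
#' `H(x) = B_plus * exp(-|x|/tau_plus) - B_minus * exp(-|x|/tau_minus)` —
#' potentiation of inhibition for near-coincident spikes, depression in the
#' flanks. Published values: `B_plus = 0.04`, `B_minus = 0.02`,
#' `tau_plus = 10` ms, `tau_minus = 20` ms (zero crossing at `20*log(2)` ~
#' 13.9 ms). A positive change strengthens inhibition (larger GABA weight).
#'
#' @param B_plus,B_minus potentiation/depression magnitudes (`B_plus > B_minus`).
#' @param tau_plus,tau_minus time constants (ms, `tau_plus < tau_minus`).
#' @param w_min,w_max bounds applied to plastic GABA weights. The default
#'   only forbids negative weights: unlike the excitatory rule, no upper
#'   bound is stated for the inhibitory rule, whose flank depression is
#'   self-stabilizing, and GABA weights are on a different scale than the
#'   excitatory cap.
#' @return An object of class `inh_stdp_config`.
#' @export
inh_stdp_config <- function(B_plus = 0.04, B_minus = 0.02,
                            tau_plus = 10, tau_minus = 20,
                            w_min = 0, w_max = Inf) {
  stopifnot(B_plus > B_minus, B_minus > 0, tau_plus < tau_minus,
            tau_plus > 0, w_min < w_max)
  structure(list(B_plus = B_plus, B_minus = B_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, w_min = w_min, w_max = w_max),
            class = "inh_stdp_config")
}

#' STDP kernels
#'
#' `stdp_kernel()` evaluates the asymmetric excitatory kernel `F(x)` and
#' `inh_kernel()` the symmetric inhibitory kernel `H(x)` at spike-time lags
#' `delta_t = t_post - t_pre` (ms). `F(0)` is defined as 0 (the rule is stated
#' for `x > 0` and `x < 0` only); `H` is defined for all lags.
#'
#' @param delta_t numeric vector of lags (ms).
#' @param cfg a [stdp_config()] or [inh_stdp_config()].
#' @return Numeric vector of weight changes.
#' @examples
#' stdp_kernel(20)            # A_plus * exp(-1)
#' inh_kernel(20 * log(2))    # zero crossing
#' @export
stdp_kernel <- function(delta_t, cfg = stdp_config()) {
  stopifnot(inherits(cfg, "stdp_config"))
  out <- numeric(length(delta_t))
  pos <- delta_t > 0
  neg <- delta_t < 0
  out[pos] <- cfg$A_plus * exp(-delta_t[pos] / cfg$tau_plus)
  out[neg] <- -cfg$A_minus * exp(delta_t[neg] / cfg$tau_minus)
  out
}

#' @rdname stdp_kernel
#' @export
inh_kernel <- function(delta_t, cfg = inh_stdp_config()) {
  stopifnot(inherits(cfg, "inh_stdp_config"))
  cfg$B_plus * exp(-abs(delta_t) / cfg$tau_plus) -
    cfg$B_minus * exp(-abs(delta_t) / cfg$tau_minus)
}

#' Total weight change of one synapse from two spike trains
#'
#' Online, trace-based evaluation of the all-to-all pair sum over one pre- and
#' one postsynaptic spike train, exactly equivalent (for exponential kernels)
#' to summing the kernel over all spike pairs. Spikes falling into the same
#' time bin (lag exactly 0) are excluded, matching the simulator's same-step
#' policy. No clipping is applied; this is the raw pair-sum increment.
#'
#' @param t_pre,t_post numeric vectors of spike times (ms).
#' @param cfg a [stdp_config()] or [inh_stdp_config()].
#' @return Total weight change (scalar).
#' @export
stdp_train_change <- function(t_pre, t_post, cfg = stdp_config()) {
  events <- rbind(
    data.frame(t = as.numeric(t_pre), pre = rep(TRUE, length(t_pre))),
    data.frame(t = as.numeric(t_post), pre = rep(FALSE, length(t_post)))
  )
  events <- events[order(events$t), , drop = FALSE]
  inh <- inherits(cfg, "inh_stdp_config")
  dw <- 0
  # trace seen by an event: contributions of strictly earlier opposite spikes
  trace_at <- function(times, tau, t) sum(exp(-(t - times[times < t]) / tau))
  for (i in seq_len(nrow(events))) {
    t <- events$t[i]
    if (events$pre[i]) {
      post_p <- trace_at(t_post, cfg$tau_plus, t)
      post_m <- trace_at(t_post, cfg$tau_minus, t)
      dw <- dw + if (inh) cfg$B_plus * post_p - cfg$B_minus * post_m else
        -cfg$A_minus * post_m
    } else {
      pre_p <- trace_at(t_pre, cfg$tau_plus, t)
      pre_m <- trace_at(t_pre, cfg$tau_minus, t)
      dw <- dw + if (inh) cfg$B_plus * pre_p - cfg$B_minus * pre_m else
        cfg$A_plus * pre_p
    }
  }
  dw
}

#' Summarize weight changes between two snapshots
#'
#' Compares two matched synapse tables (same rows, e.g. before and after a
#' conditioning run) and reports, per projection (pre-group -> post-group,
#' plastic synapses only unless `scope = "all"`): mean initial and final
#' weight, mean change, and the fraction of weights at the lower/upper bound.
#'
#' @param syn0,syn1 matched synapse tables (identical `pre`, `post`,
#'   `receptor` columns).
#' @param spec the [column_spec()] the tables belong to.
#' @param cfg bounds used for the at-bound fractions.
#' @param scope `"plastic"` (default) or `"all"`.
#' @return A list with elements `by_projection` (data.frame), `mean_change`,
#'   `fraction_at_upper`, `fraction_at_lower`, and `breaks`/`hist0`/`hist1`
#'   (shared weight histograms).
#' @export
plasticity_summary <- function(syn0, syn1, spec, cfg = stdp_config(),
                               scope = c("plastic", "all")) {
  scope <- match.arg(scope)
  if (nrow(syn0) != nrow(syn1) ||
      !all(syn0$pre == syn1$pre & syn0$post == syn1$post &
             syn0$receptor == syn1$receptor)) {
    stop("synapse tables are not matched row-for-row", call. = FALSE)
  }
  keep <- if (scope == "plastic") syn0$plastic == 1L else rep(TRUE, nrow(syn0))
  w0 <- syn0$weight[keep]
  w1 <- syn1$weight[keep]
  glab <- group_labels()
  g <- neuron_groups(spec)
  proj <- paste(glab[g[syn0$pre[keep]]], "->", glab[g[syn0$post[keep]]])
  by_proj <- do.call(rbind, lapply(split(seq_along(w0), proj), function(i) {
    data.frame(projection = proj[i[1]], n = length(i),
               mean_w0 = mean(w0[i]), mean_w1 = mean(w1[i]),
               mean_change = mean(w1[i] - w0[i]))
  }))
  rownames(by_proj) <- NULL
  eps <- 1e-12
  breaks <- seq(cfg$w_min, cfg$w_max, length.out = 41)
  clip <- function(w) pmin(pmax(w, cfg$w_min), cfg$w_max)
  list(
    by_projection = by_proj,
    mean_change = mean(w1 - w0),
    fraction_at_upper = mean(w1 >= cfg$w_max - eps),
    fraction_at_lower = mean(w1 <= cfg$w_min + eps),
    breaks = breaks,
    hist0 = graphics::hist(clip(w0), breaks = breaks, plot = FALSE)$counts,
    hist1 = graphics::hist(clip(w1), breaks = breaks, plot = FALSE)$counts
  )
}
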