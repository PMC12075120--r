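#' Declare a stimulus protocol
#'
#' A protocol is a time-ordered list of current-injection epochs. Each epoch
#' targets a fixed random subset of one cell group: `fraction` of the group's
#' neurons (the first `ceiling(fraction * N)` under a seeded permutation, so
#' the subset is reproducible) receive a constant `amplitude` (pA) during
#' `[t_on, t_off)`. The published feedforward stimulus is 30 pA to 50% of the
#' layer-4 pyramidal cells; feedback input targets layer-5 pyramidal cells.
#'
#' @param epochs data.frame with columns `group`, `fraction` (in (0, 1\]),
#'   `amplitude` (pA), `t_on`, `t_off` (ms).
#' @param seed integer seed for the target-subset permutation.
#' @return An object of class `stimulus_protocol`.
#' @examples
#' ff <- stimulus_protocol(data.frame(group = "E4", fraction = 0.5,
#'                                    amplitude = 30, t_on = 700, t_off = 1500))
#' @export
stimulus_protocol <- function(epochs, seed = 1) {
  needed <- c("group", "fraction", "amplitude", "t_on", "t_off")
  if (!all(needed %in% names(epochs))) {
    stop("epochs must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  group_index(epochs$group)   # validates labels
  stopifnot(all(epochs$fraction > 0), all(epochs$fraction <= 1),
            all(epochs$t_off > epochs$t_on))
  epochs <- epochs[order(epochs$t_on), , drop = FALSE]
  rownames(epochs) <- NULL
  structure(list(epochs = epochs, seed = as.integer(seed)),
            class = "stimulus_protocol")
}

#' Resolve a protocol against a column: per-epoch target neurons
#'
#' Materializes the per-neuron current time course implied by a protocol:
#' for each epoch, the targeted neuron ids (deterministic for the protocol's
#' seed) and the epoch window. The returned object can be evaluated at any
#' time with `stimulus_current()`.
#'
#' @param protocol a [stimulus_protocol()] (or `NULL`, yielding no epochs).
#' @param spec a [column_spec()].
#' @return A list of epochs, each `(targets, amplitude, t_on, t_off)`.
#' @export
make_stimulus <- function(protocol, spec) {
  resolve_protocol(protocol, spec)
}

resolve_protocol <- function(protocol, spec) {
  if (is.null(protocol)) return(list())
  stopifnot(inherits(protocol, "stimulus_protocol"))
  ep <- protocol$epochs
  out <- vector("list", nrow(ep))
  for (i in seq_len(nrow(ep))) {
    ids <- neurons_of_group(spec, ep$group[i])
    n_target <- ceiling(ep$fraction[i] * length(ids))
    if (n_target < 1) {
      stop("epoch ", i, " targets no neurons (fraction * count < 1)",
           call. = FALSE)
    }
    # distinct seed per epoch so epochs draw independent subsets
    set.seed(protocol$seed + (i - 1L))
    targets <- sort(sample(ids)[seq_len(n_target)])
    out[[i]] <- list(targets = targets, amplitude = ep$amplitude[i],
                     t_on = ep$t_on[i], t_off = ep$t_off[i],
                     group = ep$group[i])
  }
  out
}

#' Evaluate the external current of resolved epochs at one time
#'
#' @param epochs result of [make_stimulus()].
#' @param t time (ms).
#' @param n number of neurons.
#' @return Per-neuron current (pA) at time `t`.
#' @export
stimulus_current <- function(epochs, t, n) {
  I <- numeric(n)
  for (e in epochs) {
    if (t >= e$t_on && t < e$t_off) I[e$targets] <- I[e$targets] + e$amplitude
  }
  I
}

#' Generate background Poisson event trains
#'
#' Every neuron owns an independent background Poisson generator at its
#' group's rate; events are binned per integration step (one Bernoulli draw
#' per step with probability `rate * dt`, unbiased in rate for
#' `rate * dt < 0.25`). The compiled core draws statistically identical
#' streams inline during simulation; this function is the testing and
#' measurement surface for the background drive.
#'
#' @param spec a [column_spec()].
#' @param duration length of the streams (ms).
#' @param dt bin width (ms).
#' @param seed integer seed.
#' @param neurons integer ids to generate for (default: all; keep small — the
#'   full column over long durations is large).
#' @return A list of numeric vectors of event times (ms), one per requested
#'   neuron, named by neuron id.
#' @export
make_background <- function(spec, duration, dt = 0.05, seed = 1,
                            neurons = seq_len(spec$n_total)) {
  pp <- per_neuron_params(spec)
  rate <- pp$bkg_rate[neurons]
  if (any(rate < 0)) stop("negative background rate", call. = FALSE)
  p <- rate * dt / 1000
  if (any(p >= 0.25)) {
    stop("background binning requires rate * dt < 0.25", call. = FALSE)
  }
  n_steps <- round(duration / dt)
  set.seed(as.integer(seed))
  out <- lapply(seq_along(neurons), function(k) {
    if (p[k] == 0) return(numeric(0))
    hits <- which(stats::runif(n_steps) < p[k])
    hits * dt
  })
  names(out) <- as.character(neurons)
  out
}
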