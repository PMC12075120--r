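# round half away from zero; base round() is half-to-even, which would make
# counts depend on floating-point parity of intermediate products
round_half_up <- function(x) floor(x + 0.5)

#' Per-group neuron counts for a column of a given size
#'
#' Splits `n_total` neurons over the 17 cell groups. Each layer receives
#' `round(fraction * n_total)` neurons; in the four full layers 15% of the
#' layer is inhibitory, split between PV/SST/VIP by the per-layer inhibitory
#' fractions (each subtype count rounded from the unrounded inhibitory pool),
#' and the excitatory count is the layer remainder. At `n_total = 5000` with
#' the packaged tables this reproduces the published census exactly.
#'
#' @param n_total total number of neurons (>= 17).
#' @param layer_fractions data.frame with columns `layer`, `fraction`
#'   (defaults to the packaged table).
#' @param inh_fractions data.frame with columns `layer`, `PV`, `SST`, `VIP`
#'   (defaults to the packaged table).
#' @return Named integer vector of counts over the 17 groups, canonical order.
#' @examples
#' counts <- compute_population_counts(5000)
#' counts[c("E2/3", "PV2/3", "SST2/3", "VIP2/3")]
#' @export
compute_population_counts <- function(n_total,
                                      layer_fractions = default_layer_fractions(),
                                      inh_fractions = default_inh_fractions()) {
  stopifnot(is.numeric(n_total), length(n_total) == 1, n_total >= 17)
  groups <- column_groups()
  counts <- integer(nrow(groups))
  names(counts) <- groups$group

  for (ly in column_layers()) {
    f <- layer_fractions$fraction[layer_fractions$layer == ly]
    if (length(f) != 1 || is.na(f)) {
      stop("layer_fractions must provide one fraction for layer ", ly,
           call. = FALSE)
    }
    layer_n <- round_half_up(f * n_total)
    if (ly == "L1") {
      counts["VIP1"] <- layer_n
      next
    }
    inh <- inh_fractions[inh_fractions$layer == ly, , drop = FALSE]
    if (nrow(inh) != 1) {
      stop("inh_fractions must provide one row for layer ", ly, call. = FALSE)
    }
    pool <- 0.15 * layer_n
    suffix <- sub("^L", "", ly)
    sub_counts <- integer(0)
    for (tp in c("PV", "SST", "VIP")) {
      sub_counts[tp] <- round_half_up(inh[[tp]] * pool)
      if (sub_counts[tp] <= 0 && inh[[tp]] > 0) {
        stop("n_total = ", n_total, " is too small: group ",
             paste0(tp, suffix), " would be empty", call. = FALSE)
      }
      counts[paste0(tp, suffix)] <- sub_counts[tp]
    }
    e_count <- layer_n - sum(sub_counts)
    if (e_count <= 0) {
      stop("n_total = ", n_total, " is too small: group ",
           paste0("E", suffix), " would be empty", call. = FALSE)
    }
    counts[paste0("E", suffix)] <- e_count
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Construct a column specification
#'
#' Bundles the architecture of one column: per-group neuron counts, membrane
#' parameters, background Poisson rates and the global coupling factor `G`
#' that scales all recurrent synaptic weights (published value: 5).
#'
#' @param n_total total number of neurons requested (counts are derived by
#'   [compute_population_counts()]; their sum may differ slightly from
#'   `n_total` because per-layer fractions are rounded independently).
#' @param G global coupling factor (dimensionless).
#' @param membrane data.frame of membrane parameters (packaged default).
#' @param bkgnd_rates data.frame of background rates (packaged default).
#' @param layer_fractions,inh_fractions passed to
#'   [compute_population_counts()].
#' @return An object of class `column_spec`: a list with `n_total`, `counts`,
#'   `membrane`, `bkgnd_rate` (named numeric, Hz) and `G`.
#' @examples
#' spec <- column_spec(1000)
#' sum(spec$counts)
#' @export
column_spec <- function(n_total = 5000, G = 5,
                        membrane = default_membrane_params(),
                        bkgnd_rates = default_background_rates(),
                        layer_fractions = default_layer_fractions(),
                        inh_fractions = default_inh_fractions()) {
  stopifnot(is.numeric(G), length(G) == 1, G >= 0)
  counts <- compute_population_counts(n_total, layer_fractions, inh_fractions)
  validate_membrane_params(membrane)
  membrane <- membrane[order(group_index(membrane$group)), , drop = FALSE]
  rownames(membrane) <- NULL
  if (!setequal(bkgnd_rates$group, group_labels())) {
    stop("background rates must cover all 17 groups", call. = FALSE)
  }
  if (any(bkgnd_rates$rate_hz < 0)) {
    stop("background rates must be >= 0", call. = FALSE)
  }
  rate <- stats::setNames(bkgnd_rates$rate_hz, bkgnd_rates$group)[group_labels()]
  structure(
    list(n_total = sum(counts), counts = counts, membrane = membrane,
         bkgnd_rate = rate, G = G),
    class = "column_spec"
  )
}

#' @export
print.column_spec <- function(x, ...) {
  cat("<column_spec> ", x$n_total, " neurons, G = ", x$G, "\n", sep = "")
  print(x$counts)
  invisible(x)
}

# per-neuron expansion helpers ------------------------------------------------

# assign neuron ids 1..n_total to groups, contiguous blocks in canonical order
neuron_groups <- function(spec) {
  rep.int(seq_along(spec$counts), spec$counts)
}

# ids of neurons belonging to one group label
neurons_of_group <- function(spec, group) {
  gi <- group_index(group)
  offs <- cumsum(c(0L, spec$counts))
  seq.int(offs[gi] + 1L, offs[gi + 1L])
}
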