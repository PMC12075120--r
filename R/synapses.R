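#' Realize the synapse table of a column
#'
#' Draws the individual synapses implied by the group-level connectivity.
#' For every ordered group pair (A -> B) with connection probability `p > 0`:
#' \itemize{
#'   \item if A is excitatory, every (pre, post) neuron pair receives two
#'     independent Bernoulli wiring draws — an AMPA synapse with probability
#'     `0.8 * p` and an NMDA synapse with probability `0.2 * p`;
#'   \item if A is inhibitory, every pair receives one GABA synapse draw with
#'     probability `p`.
#' }
#' Every realized synapse carries the weight `w = G * s_hat / (N_send * p)`,
#' where `s_hat = S[A, B]` and `N_send` is the size of A. This normalization
#' keeps the expected summed input weight per postsynaptic neuron from any
#' group equal to `G * s_hat`, independent of network size and `p`, so the
#' dynamics scale with `n_total`. Self-connections are excluded. E -> E
#' synapses are flagged plastic; the AMPA and NMDA entries of one plastic
#' (pre, post) pair share a single logical weight under STDP.
#'
#' @param spec a [column_spec()].
#' @param conn a [connectivity_data()] object.
#' @param seed integer wiring seed; the realized table is reproducible.
#' @return A data.frame of class `synapse_table` with columns `pre`, `post`
#'   (integer neuron ids), `receptor` (`"AMPA"`, `"NMDA"` or `"GABA"`),
#'   `weight` (>= 0) and `plastic` (0/1), ordered by (`pre`, `post`,
#'   `receptor`).
#' @examples
#' spec <- column_spec(500)
#' conn <- generate_synthetic_connectivity(seed = 1)
#' syn <- build_synapse_table(spec, conn, seed = 1)
#' head(syn)
#' @export
build_synapse_table <- function(spec, conn, seed) {
  stopifnot(inherits(spec, "column_spec"), inherits(conn, "connectivity_data"))
  labs <- group_labels()
  counts <- spec$counts
  offs <- cumsum(c(0L, counts))
  exc <- is_excitatory_group(labs)
  set.seed(as.integer(seed))

  pieces <- vector("list", 17L * 17L * 2L)
  k <- 0L
  for (a in seq_len(17L)) {
    n_send <- counts[a]
    for (b in seq_len(17L)) {
      p <- conn$P[a, b]
      s_hat <- conn$S[a, b]
      if (p <= 0 || counts[b] == 0L) next
      if (n_send == 0L) {
        stop("group pair ", labs[a], " -> ", labs[b],
             " has p > 0 but the sending population is empty", call. = FALSE)
      }
      w <- spec$G * s_hat / (n_send * p)
      draws <- if (exc[a]) {
        list(AMPA = 0.8 * p, NMDA = 0.2 * p)
      } else {
        list(GABA = p)
      }
      for (rec in names(draws)) {
        k <- k + 1L
        pieces[[k]] <- draw_pairs(offs[a], n_send, offs[b], counts[b],
                                  draws[[rec]], rec, w,
                                  plastic = exc[a] && exc[b])
      }
    }
  }
  if (k == 0L) {
    pieces <- list(data.table::data.table(
      pre = integer(0), post = integer(0), receptor = character(0),
      weight = numeric(0), plastic = integer(0)))
    k <- 1L
  }
  syn <- data.table::rbindlist(pieces[seq_len(k)])
  data.table::setorder(syn, pre, post, receptor)
  syn <- as.data.frame(syn)
  syn$receptor <- as.character(syn$receptor)
  class(syn) <- c("synapse_table", "data.frame")
  syn
}

# Bernoulli wiring for one (group pair, receptor): all ordered neuron pairs
# except autapses
draw_pairs <- function(off_pre, n_pre, off_post, n_post, p, receptor, w,
                       plastic) {
  n_pairs <- n_pre * n_post
  hit <- which(stats::runif(n_pairs) < p)
  if (length(hit)) {
    pre <- off_pre + ((hit - 1L) %% n_pre) + 1L
    post <- off_post + ((hit - 1L) %/% n_pre) + 1L
    keep <- pre != post
    pre <- pre[keep]
    post <- post[keep]
  } else {
    pre <- post <- integer(0)
  }
  data.table::data.table(
    pre = pre, post = post, receptor = rep(receptor, length(pre)),
    weight = rep(w, length(pre)), plastic = rep(as.integer(plastic), length(pre))
  )
}

#' Write or read a synapse table as columnar text
#'
#' Columns: `pre`, `post`, `receptor`, `weight`, `plastic`.
#'
#' @param syn a synapse table.
#' @param path file path (CSV).
#' @return `read_synapse_table()` returns the table; `write_synapse_table()`
#'   returns it invisibly.
#' @export
write_synapse_table <- function(syn, path) {
  data.table::fwrite(as.data.frame(syn), path)
  invisible(syn)
}

#' @rdname write_synapse_table
#' @export
read_synapse_table <- function(path) {
  syn <- as.data.frame(data.table::fread(path,
    colClasses = list(integer = c("pre", "post", "plastic"),
                      character = "receptor", numeric = "weight")))
  needed <- c("pre", "post", "receptor", "weight", "plastic")
  if (!all(needed %in% names(syn))) {
    stop("synapse table file lacks column(s): ",
         paste(setdiff(needed, names(syn)), collapse = ", "), call. = FALSE)
  }
  if (any(syn$weight < 0)) stop("negative synaptic weight in file", call. = FALSE)
  class(syn) <- c("synapse_table", "data.frame")
  syn
}
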