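#' Connectivity data: probability and strength matrices
#'
#' A `connectivity_data` object holds the two 17 x 17 group-level matrices of
#' the column: `P`, connection probabilities in \[0, 1\], and `S`, group-level
#' synaptic strengths (non-negative magnitudes; the sign of a connection is
#' carried by its receptor type, not by `S`). Rows index the presynaptic
#' group, columns the postsynaptic group, both in canonical order.
#'
#' @param P,S 17 x 17 numeric matrices with dimnames equal to
#'   [group_labels()] (any row/column order; they are realigned).
#' @return A `connectivity_data` object.
#' @export
connectivity_data <- function(P, S) {
  P <- align_conn_matrix(P, "P")
  S <- align_conn_matrix(S, "S")
  if (any(P < 0 | P > 1)) {
    bad <- which(P < 0 | P > 1, arr.ind = TRUE)[1, ]
    stop("P[", rownames(P)[bad[1]], ", ", colnames(P)[bad[2]],
         "] is outside [0, 1]", call. = FALSE)
  }
  if (any(S < 0)) {
    bad <- which(S < 0, arr.ind = TRUE)[1, ]
    stop("S[", rownames(S)[bad[1]], ", ", colnames(S)[bad[2]],
         "] is negative; strengths are magnitudes", call. = FALSE)
  }
  structure(list(P = P, S = S), class = "connectivity_data")
}

align_conn_matrix <- function(M, what) {
  labs <- group_labels()
  if (!is.matrix(M) || nrow(M) != 17 || ncol(M) != 17) {
    stop(what, " must be a 17 x 17 matrix", call. = FALSE)
  }
  if (is.null(rownames(M)) || is.null(colnames(M))) {
    stop(what, " must carry group labels as dimnames", call. = FALSE)
  }
  if (!setequal(rownames(M), labs) || !setequal(colnames(M), labs)) {
    unknown <- setdiff(unique(c(rownames(M), colnames(M))), labs)
    if (length(unknown)) {
      stop(what, ": unknown group label(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    stop(what, ": missing group label(s): ",
         paste(setdiff(labs, c(rownames(M), colnames(M))), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(M))) stop(what, " contains missing values", call. = FALSE)
  M[labs, labs, drop = FALSE]
}

#' @export
print.connectivity_data <- function(x, ...) {
  cat("<connectivity_data> 17 x 17; mean P =", signif(mean(x$P), 3),
      "; mean S =", signif(mean(x$S), 3), "\n")
  invisible(x)
}

#' Read connectivity matrices from labelled CSV files
#'
#' Each file is comma-separated with a header row and a first column holding
#' the 17 group labels (e.g. `"E2/3"`, `"PV4"`, `"VIP1"`); rows are
#' presynaptic groups. Row/column order in the file is irrelevant: matrices
#' are realigned to the canonical group order.
#'
#' @param path_P path to the probability matrix file.
#' @param path_S path to the strength matrix file.
#' @return A [connectivity_data()] object.
#' @export
load_connectivity <- function(path_P, path_S) {
  connectivity_data(read_conn_matrix(path_P, "P"),
                    read_conn_matrix(path_S, "S"))
}

read_conn_matrix <- function(path, what) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = 1),
    error = function(e) {
      stop("failed to parse ", what, " matrix file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  M <- as.matrix(df)
  if (!is.numeric(M)) {
    stop(what, " matrix file '", path, "' contains non-numeric cells",
         call. = FALSE)
  }
  M
}

#' Write connectivity matrices to labelled CSV files
#'
#' @param conn a [connectivity_data()] object.
#' @param path_P,path_S output file paths.
#' @return Invisibly, `conn`.
#' @export
write_connectivity <- function(conn, path_P, path_S) {
  stopifnot(inherits(conn, "connectivity_data"))
  utils::write.csv(conn$P, path_P)
  utils::write.csv(conn$S, path_S)
  invisible(conn)
}

#' Generate synthetic connectivity matrices
#'
#' The published group-level matrices of the column live in an external data
#' portal and are not printed; this generator produces stand-in matrices that
#' emulate their qualitative structure. The `"inhibition_dominated"` style
#' enforces, by construction: within every full layer, PV->E strength >
#' SST->E strength > VIP->E strength (somatic PV inhibition is the strongest);
#' a feedforward excitatory motif L4 -> L2/3 -> L5 -> L6 with nonzero
#' probability; and preferential VIP -> SST targeting (disinhibition). All 289
#' entries are populated. A seeded log-normal jitter (sd 0.1 on the log scale)
#' individualises matrices across seeds without breaking the ordering
#' constraints. The `"uniform"` style sets every probability to 0.1 and every
#' strength to 1.
#'
#' @param seed integer seed; the same seed always yields the same matrices.
#' @param style `"inhibition_dominated"` (default) or `"uniform"`.
#' @return A [connectivity_data()] object.
#' @examples
#' conn <- generate_synthetic_connectivity(seed = 1)
#' conn$S["PV4", "E4"] > conn$S["SST4", "E4"]
#' @export
generate_synthetic_connectivity <- function(seed,
                                            style = c("inhibition_dominated",
                                                      "uniform")) {
  style <- match.arg(style)
  labs <- group_labels()
  if (style == "uniform") {
    P <- matrix(0.1, 17, 17, dimnames = list(labs, labs))
    S <- matrix(1, 17, 17, dimnames = list(labs, labs))
    return(connectivity_data(P, S))
  }
  base <- synthetic_template()
  set.seed(as.integer(seed))
  jit_P <- matrix(exp(stats::rnorm(289, 0, 0.1)), 17, 17)
  jit_S <- matrix(exp(stats::rnorm(289, 0, 0.1)), 17, 17)
  P <- pmin(base$P * jit_P, 1)
  S <- base$S * jit_S
  dimnames(P) <- dimnames(S) <- list(labs, labs)
  # hard constraint: within every full layer, PV->E > SST->E > VIP->E strength
  # (jitter is far too small to flip the 2x template gaps, but the ordering is
  # contractual, so enforce it rather than rely on tail probabilities)
  for (suf in c("2/3", "4", "5", "6")) {
    pre <- paste0(c("PV", "SST", "VIP"), suf)
    e <- paste0("E", suf)
    S[pre, e] <- sort(S[pre, e], decreasing = TRUE)
  }
  connectivity_data(P, S)
}

# Qualitative template for the inhibition-dominated style. Values are chosen
# so that, with the packaged membrane/background tables and G = 5, the column
# sits in an inhibition-dominated asynchronous regime (interneuron rates above
# pyramidal rates, E rates of order 1-10 Hz) and feedforward L4 input
# propagates through the canonical L4 -> L2/3 -> L5 -> L6 excitatory pathway.
synthetic_template <- function() {
  labs <- group_labels()
  groups <- column_groups()
  layer <- groups$layer
  type <- groups$cell_type
  n <- 17
  P <- matrix(0.02, n, n)   # weak baseline so all entries are populated
  S <- matrix(0.1, n, n)
  full <- c("L2/3", "L4", "L5", "L6")
  # E->E entries keep s_hat/p low enough that initial per-synapse weights
  # G*s_hat/(N*p) sit inside the STDP bounds [0, 0.2] at the network sizes
  # the column is intended for (n_total >= 1000)
  ee <- which(type == "E")
  S[ee, ee] <- 0.04

  set_PS <- function(pre_type, pre_layer, post_type, post_layer, p, s) {
    i <- which(type == pre_type & layer == pre_layer)
    j <- which(post_type == type & layer == post_layer)
    P[i, j] <<- p
    S[i, j] <<- s
  }

  for (ly in full) {
    # within-layer recurrence; the dense E->E pool is what gives bounded
    # STDP room to build an effective assembly at reduced network sizes
    set_PS("E", ly, "E", ly, 0.25, 0.60)
    set_PS("E", ly, "PV", ly, 0.40, 1.20)
    set_PS("E", ly, "SST", ly, 0.25, 0.60)
    set_PS("E", ly, "VIP", ly, 0.15, 0.50)
    set_PS("PV", ly, "E", ly, 0.40, 3.00)   # strong somatic inhibition
    set_PS("PV", ly, "PV", ly, 0.35, 2.00)
    set_PS("SST", ly, "E", ly, 0.30, 1.50)  # dendritic, intermediate
    set_PS("SST", ly, "PV", ly, 0.20, 0.90)
    set_PS("SST", ly, "VIP", ly, 0.20, 0.90)
    set_PS("VIP", ly, "SST", ly, 0.35, 2.00) # disinhibitory motif
    set_PS("VIP", ly, "E", ly, 0.05, 0.40)
    set_PS("VIP", ly, "PV", ly, 0.05, 0.40)
  }

  # laminar feedforward excitatory motif (L4 -> L2/3 -> L5 -> L6); dense and
  # strong enough that a stimulated layer recruits its target layer within
  # tens of ms, with s_hat/p capped (ratio 5) so per-synapse weights stay
  # inside the STDP bounds at the intended network sizes
  ff <- list(c("L4", "L2/3", 0.50, 3.00), c("L2/3", "L5", 0.40, 2.00),
             c("L5", "L6", 0.35, 1.75), c("L4", "L5", 0.10, 0.50),
             c("L2/3", "L6", 0.08, 0.40))
  for (e in ff) {
    set_PS("E", e[1], "E", e[2], as.numeric(e[3]), as.numeric(e[4]))
  }
  # weaker feedback excitation (ratio 2)
  fb <- list(c("L2/3", "L4", 0.03), c("L5", "L2/3", 0.05),
             c("L6", "L5", 0.04), c("L5", "L4", 0.02), c("L6", "L4", 0.02))
  for (e in fb) {
    p <- as.numeric(e[3])
    set_PS("E", e[1], "E", e[2], p, 2 * p)
  }
  # excitation of interneurons in neighbouring layers
  adj <- list(c("L4", "L2/3"), c("L2/3", "L4"), c("L4", "L5"), c("L5", "L4"),
              c("L2/3", "L5"), c("L5", "L2/3"), c("L5", "L6"), c("L6", "L5"))
  for (e in adj) {
    set_PS("E", e[1], "PV", e[2], 0.06, 0.50)
    set_PS("E", e[1], "SST", e[2], 0.05, 0.40)
  }
  # translaminar SST inhibition (dendrite-targeting cells project broadly)
  for (pre in full) for (post in setdiff(full, pre)) {
    set_PS("SST", pre, "E", post, 0.05, 0.70)
  }
  # layer 1 VIP cells: column-wide disinhibition of SST
  for (post in full) {
    set_PS("VIP", "L1", "SST", post, 0.25, 2.00)
    set_PS("VIP", "L1", "E", post, 0.03, 0.30)
    set_PS("E", post, "VIP", "L1", 0.08, 0.40)
  }
  list(P = P, S = S)
}
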