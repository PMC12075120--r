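#' Canonical cell groups of the cortical column
#'
#' The column model distinguishes 17 cell groups: layer 1 contains only VIP
#' interneurons, while layers 2/3, 4, 5 and 6 each contain excitatory (E)
#' pyramidal cells plus PV, SST and VIP interneurons. All matrices and tables
#' in the package are indexed in one canonical order: `VIP1` first, then for
#' each full layer (2/3, 4, 5, 6) the types E, PV, SST, VIP.
#'
#' @return `column_groups()` returns a data.frame with columns `group`,
#'   `layer` and `cell_type`, one row per group, in canonical order.
#' @examples
#' column_groups()
#' group_labels()
#' @export
column_groups <- function() {
  layers <- c("L2/3", "L4", "L5", "L6")
  types <- c("E", "PV", "SST", "VIP")
  full <- expand.grid(cell_type = types, layer = layers,
                      stringsAsFactors = FALSE)[, c("layer", "cell_type")]
  df <- rbind(data.frame(layer = "L1", cell_type = "VIP",
                         stringsAsFactors = FALSE), full)
  df$group <- paste0(df$cell_type, sub("^L", "", df$layer))
  df[, c("group", "layer", "cell_type")]
}

#' @rdname column_groups
#' @return `group_labels()` returns the 17 group labels as a character vector.
#' @export
group_labels <- function() column_groups()$group

#' @rdname column_groups
#' @return `column_layers()` returns the five layer labels.
#' @export
column_layers <- function() c("L1", "L2/3", "L4", "L5", "L6")

# index of a group label in canonical order, with validation
group_index <- function(labels) {
  idx <- match(labels, group_labels())
  if (anyNA(idx)) {
    stop("unknown group label(s): ",
         paste(unique(labels[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

is_excitatory_group <- function(labels) {
  column_groups()$cell_type[group_index(labels)] == "E"
}
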