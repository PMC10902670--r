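#' Construct a gating-tree decision node
#'
#' @param marker Marker name the node thresholds on (arcsinh scale).
#' @param threshold Finite numeric gate position.
#' @param above,below Child nodes: either another `gate_node()` or a
#'   `gate_leaf()`. Events with intensity strictly greater than `threshold`
#'   descend into `above`, the rest into `below`.
#' @return A gating-tree node (list).
#' @seealso [gate_leaf()], [default_gating_tree()], [gate_events()]
#' @export
gate_node <- function(marker, threshold, above, below) {
  stopifnot(is.character(marker), length(marker) == 1L,
            is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  structure(list(marker = marker, threshold = threshold,
                 above = above, below = below),
            class = "gate_node")
}

#' Construct a gating-tree leaf
#'
#' @param subset Subset label carried by the leaf. Use `"ungated"` for
#'   events that should be excluded from all features.
#' @return A gating-tree leaf (list).
#' @export
gate_leaf <- function(subset) {
  stopifnot(is.character(subset), length(subset) == 1L)
  structure(list(leaf = subset), class = "gate_leaf")
}

#' Default manual gating hierarchy
#'
#' A decision tree over arcsinh-transformed lineage markers that assigns
#' every event to exactly one of 17 leaf subsets (or `"ungated"`). The
#' topology follows standard PBMC phenotyping: CD3 splits T from non-T;
#' T cells branch by TCRgd, CD56 (NKT), TCRVa7.2 (MAIT), CD4/CD8, FoxP3
#' (Treg) and CCR7(CD197)/CD45RA memory stages; non-T branch by CD56
#' (NK, with a second, higher CD56 gate separating CD56bright from
#' CD56dim and CD57 splitting the dim subsets), then CD14/CD16
#' (monocyte subsets) and CD123 (plasmacytoid DC).
#'
#' Thresholds sit at the valley between the negative and positive
#' intensity modes on the arcsinh scale; the figure-style gating logic
#' fixes the marker order while thresholds remain configurable.
#'
#' @param threshold Valley position between negative and positive marker
#'   modes (arcsinh scale); default 2.2.
#' @param cd56_positive CD56 gate separating NK/NKT from CD56- cells.
#' @param cd56_bright Higher CD56 gate separating CD56bright from CD56dim.
#' @return A gating tree rooted at a `gate_node`.
#' @export
default_gating_tree <- function(threshold = 2.2, cd56_positive = 1.6,
                                cd56_bright = 3.8) {
  t <- threshold
  cd4_memory <- gate_node("FoxP3", t,
    above = gate_leaf("Treg"),
    below = gate_node("CD197", t,
      above = gate_node("CD45RA", t,
        above = gate_leaf("naive CD4T"),
        below = gate_leaf("central memory CD4T")),
      below = gate_leaf("effector memory CD4T")))
  cd8_memory <- gate_node("CD197", t,
    above = gate_leaf("central memory CD8T"),
    below = gate_node("CD45RA", t,
      above = gate_leaf("TEMRA CD8T"),
      below = gate_leaf("effector memory CD8T")))
  t_branch <- gate_node("TCRgd", t,
    above = gate_leaf("gdT"),
    below = gate_node("CD56", cd56_positive,
      above = gate_leaf("NKT"),
      below = gate_node("TCRVa7.2", t,
        above = gate_leaf("MAIT"),
        below = gate_node("CD4", t,
          above = cd4_memory,
          below = gate_node("CD8", t,
            above = cd8_memory,
            below = gate_leaf(UNGATED))))))
  nk_branch <- gate_node("CD56", cd56_bright,
    above = gate_leaf("NK(CD56bright)"),
    below = gate_node("CD57", t,
      above = gate_leaf("NK(CD56dimCD57+)"),
      below = gate_leaf("NK(CD56dimCD57-)")))
  myeloid <- gate_node("CD14", t,
    above = gate_node("CD16", t,
      above = gate_leaf("intermediate monocytes"),
      below = gate_leaf("classical monocytes")),
    below = gate_node("CD16", t,
      above = gate_leaf("non-classical monocytes"),
      below = gate_node("CD123", t,
        above = gate_leaf("plasmacytoid DC"),
        below = gate_leaf(UNGATED))))
  gate_node("CD3", t,
    above = t_branch,
    below = gate_node("CD56", cd56_positive,
      above = nk_branch,
      below = myeloid))
}

#' Build a gating tree from a nested list (e.g. parsed YAML/JSON config)
#'
#' Nodes are lists with fields `marker`, `threshold` and children `above`
#' and `below`; leaves are lists with a single field `leaf`.
#'
#' @param x Nested list description of the tree.
#' @return A gating tree of `gate_node`/`gate_leaf` objects.
#' @export
gating_tree_from_list <- function(x) {
  if (!is.list(x)) stop("gating config must be a nested list")
  if (!is.null(x$leaf)) return(gate_leaf(x$leaf))
  if (is.null(x$marker) || is.null(x$threshold) ||
      is.null(x$above) || is.null(x$below)) {
    stop("gating node needs fields marker, threshold, above, below")
  }
  gate_node(x$marker, as.numeric(x$threshold),
            gating_tree_from_list(x$above),
            gating_tree_from_list(x$below))
}

gating_tree_markers <- function(tree) {
  if (inherits(tree, "gate_leaf")) return(character())
  unique(c(tree$marker,
           gating_tree_markers(tree$above),
           gating_tree_markers(tree$below)))
}

gating_tree_leaves <- function(tree) {
  if (inherits(tree, "gate_leaf")) return(tree$leaf)
  c(gating_tree_leaves(tree$above), gating_tree_leaves(tree$below))
}

#' Assign events to gated subsets
#'
#' Pushes every event down the gating tree; each event lands in exactly
#' one leaf (or `"ungated"`). Assignment is a deterministic function of
#' the event's intensities and the tree, so it is invariant to event
#' order.
#'
#' @param events Data frame with one row per cell and one column per
#'   marker on the arcsinh scale (see [arcsinh_transform()]).
#' @param tree Gating tree from [default_gating_tree()] or
#'   [gating_tree_from_list()].
#' @return `events` with a `subset_label` column of leaf assignments.
#' @export
gate_events <- function(events, tree) {
  markers <- gating_tree_markers(tree)
  missing <- setdiff(markers, names(events))
  if (length(missing)) {
    stop("marker column(s) missing from events: ",
         paste(missing, collapse = ", "))
  }
  leaves <- gating_tree_leaves(tree)
  dup <- leaves[duplicated(leaves) & leaves != UNGATED]
  if (length(dup)) stop("duplicate leaf subset name(s): ",
                        paste(unique(dup), collapse = ", "))
  labels <- character(nrow(events))
  assign_rec <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (inherits(node, "gate_leaf")) {
      labels[idx] <<- node$leaf
      return(invisible())
    }
    up <- events[[node$marker]][idx] > node$threshold
    assign_rec(node$above, idx[up])
    assign_rec(node$below, idx[!up])
  }
  assign_rec(tree, seq_len(nrow(events)))
  events$subset_label <- labels
  events
}
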