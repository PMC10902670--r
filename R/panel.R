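#' Default CyTOF marker panel
#'
#' The default antibody panel: 26 immune-lineage markers and 16 metabolic
#' regulator proteins measured per cell. Lineage markers drive the gating
#' hierarchy; metabolic regulators are summarised per subset into patient
#' features.
#'
#' @return A list with character vectors `lineage` (26 names) and
#'   `metabolic` (16 names).
#' @export
default_panel <- function() {
  list(
    lineage = c(
      "CD1c", "CD3", "CD4", "CD8", "CD11c", "CD14", "CD16", "CD19",
      "CD38", "CD39", "CD45", "CD45RA", "CD56", "CD57", "CD66b", "CD86",
      "CD123", "CD141", "CD161", "CD197", "CCR2", "FoxP3", "HLA-DR",
      "PD1", "TCRVa7.2", "TCRgd"
    ),
    metabolic = c(
      "ATP5a", "ACADM", "CPT1a", "CS", "CytC", "DRP1", "GAPDH", "GLUT1",
      "HADHA", "HK2", "LDH", "NRF1", "OGDH", "OPA1", "PGC1a", "VDAC"
    )
  )
}

#' Default immune subset catalogue
#'
#' Twenty-one peripheral-blood immune subsets are reported per patient:
#' seventeen disjoint leaf subsets produced by the gating tree, plus four
#' aggregate (parent) populations assembled from leaves. Aggregates let the
#' feature table carry both fine NK subsets (CD56bright, CD56dim CD57+/-)
#' and the pooled NK / CD56dim populations that clinical reports quote.
#'
#' @return A list with `leaves` (17 leaf subset names), `aggregates` (named
#'   list mapping each aggregate subset to its member leaves) and `subsets`
#'   (all 21 reporting subset names, leaves first).
#' @export
default_subsets <- function() {
  leaves <- c(
    "naive CD4T", "central memory CD4T", "effector memory CD4T", "Treg",
    "central memory CD8T", "effector memory CD8T", "TEMRA CD8T",
    "gdT", "MAIT", "NKT",
    "NK(CD56bright)", "NK(CD56dimCD57-)", "NK(CD56dimCD57+)",
    "classical monocytes", "intermediate monocytes",
    "non-classical monocytes", "plasmacytoid DC"
  )
  aggregates <- list(
    "CD4T" = c("naive CD4T", "central memory CD4T",
               "effector memory CD4T", "Treg"),
    "CD8T" = c("central memory CD8T", "effector memory CD8T", "TEMRA CD8T"),
    "NK(CD56dim)" = c("NK(CD56dimCD57-)", "NK(CD56dimCD57+)"),
    "NK" = c("NK(CD56bright)", "NK(CD56dimCD57-)", "NK(CD56dimCD57+)")
  )
  list(leaves = leaves, aggregates = aggregates,
       subsets = c(leaves, names(aggregates)))
}

#' Default cytokine panel
#'
#' Plasma cytokines measured per patient, in pg/mL.
#'
#' @return Character vector of the five cytokine names.
#' @export
default_cytokines <- function() {
  c("IL-6", "IL-8", "IL-10", "IL-15", "TNF-a")
}

# Label used for events that fall outside every leaf gate.
UNGATED <- "ungated"
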