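#' Default planted immunometabolic effects
#'
#' The default effect map encodes the study's headline finding as the
#' generative truth: in patients who develop a nosocomial infection, NRF1
#' (mitochondrial biogenesis) is shifted down and CPT1a (fatty-acid
#' import) up in all NK-cell leaf subsets, by half a within-cell standard
#' deviation on the arcsinh scale. Magnitudes are configurable: the
#' qualitative direction is established biology here, the size is a
#' simulation choice.
#'
#' @param shift_sd Absolute planted shift in within-cell SD units.
#' @return Data frame with columns `subset`, `marker`, `shift`.
#' @export
default_effect_map <- function(shift_sd = 0.5) {
  nk <- c("NK(CD56bright)", "NK(CD56dimCD57-)", "NK(CD56dimCD57+)")
  rbind(
    data.frame(subset = nk, marker = "NRF1",  shift = -shift_sd),
    data.frame(subset = nk, marker = "CPT1a", shift = +shift_sd)
  )
}

#' Default cytokine generative parameters
#'
#' Log-normal plasma cytokine levels (pg/mL) per outcome group, with a
#' detection limit below which measurements are reported as 0 pg/mL.
#' IL-10 and IL-15 are elevated in the infected group; IL-6, IL-8 and
#' TNF-a are shared between groups.
#'
#' @return Data frame with columns `cytokine`, `meanlog_uninfected`,
#'   `meanlog_infected`, `sdlog`, `detection_limit`.
#' @export
default_cytokine_params <- function() {
  data.frame(
    cytokine = default_cytokines(),
    meanlog_uninfected = log(c(20, 15, 3, 2, 15)),
    meanlog_infected   = log(c(25, 18, 8, 4.5, 18)),
    sdlog = c(0.8, 0.8, 0.7, 0.6, 0.7),
    detection_limit = 1
  )
}

default_subset_proportions <- function() {
  c("naive CD4T" = 0.10, "central memory CD4T" = 0.09,
    "effector memory CD4T" = 0.07, "Treg" = 0.03,
    "central memory CD8T" = 0.05, "effector memory CD8T" = 0.06,
    "TEMRA CD8T" = 0.05, "gdT" = 0.03, "MAIT" = 0.03, "NKT" = 0.02,
    "NK(CD56bright)" = 0.015, "NK(CD56dimCD57-)" = 0.06,
    "NK(CD56dimCD57+)" = 0.045, "classical monocytes" = 0.24,
    "intermediate monocytes" = 0.05, "non-classical monocytes" = 0.05,
    "plasmacytoid DC" = 0.01)
}

# Arcsinh-scale intensity modes for bimodal lineage markers.
lineage_levels <- function() {
  list(neg    = c(mean = 0.4, sd = 0.30),
       pos    = c(mean = 4.0, sd = 0.35),
       dim    = c(mean = 2.8, sd = 0.30),
       bright = c(mean = 4.8, sd = 0.30))
}

# Which lineage markers are non-negative in each leaf subset.
default_lineage_profiles <- function() {
  pos <- list(
    "naive CD4T" = c("CD3", "CD4", "CD45RA", "CD197"),
    "central memory CD4T" = c("CD3", "CD4", "CD197"),
    "effector memory CD4T" = c("CD3", "CD4"),
    "Treg" = c("CD3", "CD4", "FoxP3", "CD39"),
    "central memory CD8T" = c("CD3", "CD8", "CD197"),
    "effector memory CD8T" = c("CD3", "CD8"),
    "TEMRA CD8T" = c("CD3", "CD8", "CD45RA"),
    "gdT" = c("CD3", "TCRgd"),
    "MAIT" = c("CD3", "TCRVa7.2", "CD161"),
    "NKT" = c("CD3"),
    "NK(CD56bright)" = character(),
    "NK(CD56dimCD57-)" = c("CD16"),
    "NK(CD56dimCD57+)" = c("CD57", "CD16"),
    "classical monocytes" = c("CD14", "CD11c", "HLA-DR", "CCR2"),
    "intermediate monocytes" = c("CD14", "CD16", "CD11c", "HLA-DR"),
    "non-classical monocytes" = c("CD16", "CD11c", "HLA-DR"),
    "plasmacytoid DC" = c("CD123", "HLA-DR")
  )
  cd56 <- c("NKT" = "dim", "NK(CD56bright)" = "bright",
            "NK(CD56dimCD57-)" = "dim", "NK(CD56dimCD57+)" = "dim")
  list(positive = pos, cd56_level = cd56)
}

#' Specify a synthetic cohort
#'
#' Collects every generative parameter of the synthetic mass-cytometry
#' cohort: cohort size and infection prevalence, per-patient cell counts,
#' leaf-subset composition, planted (subset, metabolic marker) effects in
#' SD units, cytokine distributions with a detection floor, and the
#' variance components of the intensity model. Raw intensities are
#' constructed as `cofactor * sinh(y)` with `y` normal on the arcsinh
#' scale, so planted shifts are exact on the scale the analysis uses.
#'
#' @param n_patients Number of patients (default 37).
#' @param infection_rate Fraction of infected patients, strictly in (0,1);
#'   default 16/37. The realised count is `round(n_patients * rate)`.
#' @param cells_per_patient Cells generated per patient.
#' @param subset_proportions Named fractions over the 17 disjoint leaf
#'   subsets, summing to 1 (aggregate subsets are derived, so proportions
#'   are defined on the leaves).
#' @param effect_map Data frame (`subset`, `marker`, `shift`) of planted
#'   arcsinh-scale shifts, in within-cell SD units, applied to infected
#'   patients' metabolic markers; defaults to [default_effect_map()].
#' @param cytokine_params Data frame as [default_cytokine_params()].
#' @param metabolic_mean Baseline arcsinh-scale level of metabolic markers.
#' @param cell_sd Within-cell arcsinh-scale SD of metabolic markers (the
#'   unit of `effect_map$shift`).
#' @param patient_sd SD of patient-level random intercepts, drawn
#'   independently per (subset, metabolic marker): subset-specific
#'   between-patient biological variability.
#' @param staining_sd SD of a single per-patient intercept shared by all
#'   metabolic markers, emulating global staining-efficiency variation.
#'   This shared component creates the outcome-unrelated leading
#'   structure typical of patient embeddings, so infection signal need
#'   not surface on the first coordinate.
#' @param cofactor Arcsinh cofactor used to map to the raw ion-count scale.
#' @param seed Integer seed; all generation is reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 37,
                        infection_rate = 16 / 37,
                        cells_per_patient = 10000,
                        subset_proportions = default_subset_proportions(),
                        effect_map = default_effect_map(),
                        cytokine_params = default_cytokine_params(),
                        metabolic_mean = 2.5,
                        cell_sd = 0.5,
                        patient_sd = 0.10,
                        staining_sd = 0.1,
                        cofactor = 5,
                        seed = 1L) {
  stopifnot(n_patients >= 1, cells_per_patient >= 1)
  if (!(infection_rate > 0 && infection_rate < 1)) {
    stop("`infection_rate` must be strictly between 0 and 1")
  }
  if (abs(sum(subset_proportions) - 1) > 1e-9) {
    stop("`subset_proportions` must sum to 1")
  }
  leaves <- default_subsets()$leaves
  if (!setequal(names(subset_proportions), leaves)) {
    stop("`subset_proportions` must be named by the leaf subsets")
  }
  if (any(subset_proportions < 0)) stop("proportions must be nonnegative")
  if (cell_sd <= 0 || patient_sd < 0 || staining_sd < 0 || cofactor <= 0) {
    stop("scales must be positive")
  }
  if (nrow(effect_map)) {
    bad_s <- setdiff(effect_map$subset, leaves)
    bad_m <- setdiff(effect_map$marker, default_panel()$metabolic)
    if (length(bad_s)) stop("effect_map subset(s) not in leaf list: ",
                            paste(bad_s, collapse = ", "))
    if (length(bad_m)) stop("effect_map marker(s) not in metabolic panel: ",
                            paste(bad_m, collapse = ", "))
  }
  if (any(cytokine_params$sdlog <= 0)) stop("cytokine sdlog must be > 0")
  structure(list(
    n_patients = as.integer(n_patients), infection_rate = infection_rate,
    cells_per_patient = as.integer(cells_per_patient),
    subset_proportions = subset_proportions[leaves],
    effect_map = effect_map, cytokine_params = cytokine_params,
    metabolic_mean = metabolic_mean, cell_sd = cell_sd,
    patient_sd = patient_sd, staining_sd = staining_sd,
    cofactor = cofactor,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' Generate a synthetic mass-cytometry cohort
#'
#' Draws, per patient: a multinomial split of cells over the leaf subsets;
#' bimodal log-normal-type lineage intensities that make each subset
#' separable by the default gating tree; metabolic-marker intensities that
#' are normal on the arcsinh scale with patient-level random intercepts
#' and the planted infected-group shifts from the effect map; and plasma
#' cytokines with values below the detection limit designated 0 pg/mL.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort_data` with elements `events` (one row
#'   per cell: `patient_id`, ground-truth `subset_label`, 42 raw marker
#'   intensities), `cytokines` (patients x cytokine pg/mL), `outcomes`
#'   (`patient_id`, binary `infected`) and the `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  panel <- default_panel()
  leaves <- names(spec$subset_proportions)
  prof <- default_lineage_profiles()
  lv <- lineage_levels()
  n <- spec$n_patients
  ids <- sprintf("P%02d", seq_len(n))
  n_inf <- round(n * spec$infection_rate)
  infected <- integer(n)
  infected[sample.int(n, n_inf)] <- 1L
  outcomes <- data.frame(patient_id = ids, infected = infected)

  # planted shift lookup: subset x metabolic marker, arcsinh units
  shift <- matrix(0, length(leaves), length(panel$metabolic),
                  dimnames = list(leaves, panel$metabolic))
  if (nrow(spec$effect_map)) {
    for (r in seq_len(nrow(spec$effect_map))) {
      shift[spec$effect_map$subset[r], spec$effect_map$marker[r]] <-
        spec$effect_map$shift[r] * spec$cell_sd
    }
  }

  # per-marker intensity mode for each (leaf, lineage marker)
  level_of <- matrix("neg", length(leaves), length(panel$lineage),
                     dimnames = list(leaves, panel$lineage))
  level_of[, "CD45"] <- "pos"
  for (s in leaves) level_of[s, prof$positive[[s]]] <- "pos"
  for (s in names(prof$cd56_level)) level_of[s, "CD56"] <- prof$cd56_level[s]

  lvl_mean <- vapply(lv, `[[`, numeric(1), "mean")
  lvl_sd <- vapply(lv, `[[`, numeric(1), "sd")
  per_patient <- vector("list", n)
  for (p in seq_len(n)) {
    counts <- as.vector(stats::rmultinom(1, spec$cells_per_patient,
                                         spec$subset_proportions))
    lab <- rep(leaves, counts)
    m <- length(lab)
    cols <- list(patient_id = rep(ids[p], m), subset_label = lab)
    for (mk in panel$lineage) {
      lvl <- level_of[lab, mk]
      y <- stats::rnorm(m, lvl_mean[lvl], lvl_sd[lvl])
      cols[[mk]] <- spec$cofactor * sinh(pmax(y, 0))
    }
    g_p <- stats::rnorm(1, 0, spec$staining_sd)
    b <- matrix(stats::rnorm(length(leaves) * length(panel$metabolic),
                             0, spec$patient_sd),
                length(leaves), length(panel$metabolic),
                dimnames = list(leaves, panel$metabolic))
    for (mk in panel$metabolic) {
      mu <- spec$metabolic_mean + g_p + b[lab, mk] +
        if (infected[p]) shift[lab, mk] else 0
      y <- stats::rnorm(m, mu, spec$cell_sd)
      cols[[mk]] <- spec$cofactor * sinh(pmax(y, 0))
    }
    per_patient[[p]] <- data.frame(cols, check.names = FALSE,
                                   stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, per_patient)
  rownames(events) <- NULL

  cyt <- spec$cytokine_params
  cytokines <- data.frame(patient_id = ids)
  for (r in seq_len(nrow(cyt))) {
    ml <- ifelse(infected == 1L, cyt$meanlog_infected[r],
                 cyt$meanlog_uninfected[r])
    v <- stats::rlnorm(n, ml, cyt$sdlog[r])
    v[v < cyt$detection_limit[r]] <- 0  # below detection: 0 pg/mL
    cytokines[[cyt$cytokine[r]]] <- v
  }
  structure(list(events = events, cytokines = cytokines,
                 outcomes = outcomes, spec = spec),
            class = "cohort_data")
}

#' Generate a synthetic labelled expression matrix
#'
#' Negative-binomial counts for NK-like cells in several clinical groups,
#' with the signature genes' means multiplied by `exp(planted_shift)` per
#' group. Used to exercise the gene-signature scoring stage.
#'
#' @param n_cells_per_group Cells per group.
#' @param groups Character vector of at least two group labels.
#' @param signature_genes Genes whose means are shifted; must be contained
#'   in the gene universe.
#' @param planted_shift Numeric log-scale shift per group (recycled names
#'   must match `groups` if named); 0 means no effect.
#' @param seed Integer seed.
#' @param genes Gene universe (default 200 genes `G001`... padded to
#'   include `signature_genes`).
#' @param dispersion Negative-binomial size parameter.
#' @return List of class `expression_data`: `counts` (cells x genes
#'   matrix), `meta` (`cell`, `group`, `cell_type`).
#' @export
generate_expression <- function(n_cells_per_group, groups, signature_genes,
                                planted_shift, seed = 1L, genes = NULL,
                                dispersion = 2) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (!length(signature_genes)) stop("empty gene set")
  if (anyDuplicated(signature_genes)) stop("duplicate gene names in set")
  if (is.null(genes)) {
    genes <- union(sprintf("G%03d", seq_len(200)), signature_genes)
  }
  if (anyDuplicated(genes)) stop("duplicate gene names in universe")
  if (!all(signature_genes %in% genes)) {
    stop("signature genes must be contained in the gene universe")
  }
  if (length(planted_shift) == 1) {
    planted_shift <- rep(planted_shift, length(groups))
  }
  stopifnot(length(planted_shift) == length(groups))
  set.seed(seed)
  g <- length(genes)
  base_mu <- stats::rlnorm(g, log(2), 1)
  names(base_mu) <- genes
  in_set <- genes %in% signature_genes
  counts <- NULL
  meta <- NULL
  for (k in seq_along(groups)) {
    mu <- base_mu
    mu[in_set] <- mu[in_set] * exp(planted_shift[k])
    block <- matrix(stats::rnbinom(n_cells_per_group * g,
                                   mu = rep(mu, each = n_cells_per_group),
                                   size = dispersion),
                    nrow = n_cells_per_group, ncol = g)
    counts <- rbind(counts, block)
    meta <- rbind(meta, data.frame(
      cell = sprintf("%s_c%04d", groups[k], seq_len(n_cells_per_group)),
      group = groups[k], cell_type = "NK"))
  }
  colnames(counts) <- genes
  rownames(counts) <- meta$cell
  structure(list(counts = counts, meta = meta), class = "expression_data")
}
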