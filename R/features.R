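#' Arcsinh-transform the marker columns of an event table
#'
#' @param events Data frame of events with raw marker intensities.
#' @param markers Marker columns to transform (default: all panel markers
#'   present in the table).
#' @param cofactor Arcsinh cofactor (default 5).
#' @return The event table with marker columns on the arcsinh scale.
#' @export
transform_events <- function(events, markers = NULL, cofactor = 5) {
  if (is.null(markers)) {
    markers <- intersect(unlist(default_panel()), names(events))
  }
  for (mk in markers) events[[mk]] <- arcsinh_transform(events[[mk]], cofactor)
  events
}

#' Assemble the per-patient feature table
#'
#' For each patient, computes the abundance of each reporting subset (as a
#' fraction of that patient's gated cells) and, for each (subset,
#' metabolic regulator) pair, the arcsinh mean: the mean over the subset's
#' cells of the per-cell arcsinh intensity. Aggregate subsets pool the
#' cells of their member leaves. Cytokine levels (already floored at the
#' detection limit) and the binary outcome are appended. With 21 subsets
#' and 16 regulators this yields exactly 21 + 21*16 = 357 cytometry
#' features per patient, plus the cytokines.
#'
#' Ungated events are excluded from every feature (both numerators and the
#' abundance denominator). A subset with no cells for a patient produces
#' `NA` marker means and zero abundance.
#'
#' @param events Gated, arcsinh-transformed event table with `patient_id`
#'   and `subset_label` columns (see [gate_events()]).
#' @param cytokines Data frame: `patient_id` plus one column per cytokine.
#' @param outcomes Data frame: `patient_id`, binary `infected`.
#' @param subsets Subset catalogue as [default_subsets()].
#' @param markers Metabolic regulator names (default panel).
#' @return Data frame of class `feature_table`: `patient_id`, `infected`,
#'   then `abundance_*` columns, then `<marker>_<subset>` columns in
#'   subset-major order, then cytokines.
#' @export
build_feature_table <- function(events, cytokines, outcomes,
                                subsets = default_subsets(),
                                markers = default_panel()$metabolic) {
  stopifnot(all(c("patient_id", "subset_label") %in% names(events)))
  miss <- setdiff(unique(events$patient_id), outcomes$patient_id)
  if (length(miss)) {
    stop("patient(s) in events but absent from outcome table: ",
         paste(miss, collapse = ", "))
  }
  ids <- outcomes$patient_id
  members <- c(stats::setNames(as.list(subsets$leaves), subsets$leaves),
               subsets$aggregates)
  gated <- events[events$subset_label != UNGATED, , drop = FALSE]
  ft <- data.frame(patient_id = ids,
                   infected = outcomes$infected[match(ids, outcomes$patient_id)],
                   check.names = FALSE)
  pid <- factor(gated$patient_id, levels = ids)
  total <- as.vector(table(pid))
  for (s in subsets$subsets) {
    in_s <- gated$subset_label %in% members[[s]]
    ft[[paste0("abundance_", s)]] <-
      as.vector(table(pid[in_s])) / pmax(total, 1L)
  }
  for (s in subsets$subsets) {
    in_s <- gated$subset_label %in% members[[s]]
    pid_s <- pid[in_s]
    for (mk in markers) {
      v <- tapply(gated[[mk]][in_s], pid_s, mean)
      ft[[paste0(mk, "_", s)]] <- as.vector(v)[match(ids, names(v))]
    }
  }
  cyt_cols <- setdiff(names(cytokines), "patient_id")
  for (cc in cyt_cols) {
    ft[[cc]] <- cytokines[[cc]][match(ids, cytokines$patient_id)]
  }
  attr(ft, "n_cytometry_features") <-
    length(subsets$subsets) * (1 + length(markers))
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Feature column names of a feature table
#'
#' @param table A feature table.
#' @return Character vector of feature columns (everything except
#'   `patient_id` and `infected`).
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("patient_id", "infected"))
}

#' Z-transform the features of a feature table
#'
#' Standardises every feature column to mean 0 and sample SD 1 (n - 1
#' denominator), using the feature's own mean and SD across patients.
#' Constant features carry no ranking information and cannot be
#' standardised; they are dropped with a warning.
#'
#' @param table A [build_feature_table()] result (or any data frame with
#'   `patient_id`/`infected` plus numeric feature columns).
#' @return The standardised table, with attributes `center` and `scale`
#'   holding the per-feature means and SDs used.
#' @export
z_normalize <- function(table) {
  if (nrow(table) < 2) stop("need at least 2 patients to standardise")
  cols <- feature_columns(table)
  ctr <- vapply(table[cols], function(v) mean(v, na.rm = TRUE), numeric(1))
  scl <- vapply(table[cols], function(v) stats::sd(v, na.rm = TRUE), numeric(1))
  const <- !is.na(scl) & scl == 0
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(cols[const], collapse = ", "))
    table[cols[const]] <- NULL
    cols <- cols[!const]
    ctr <- ctr[!const]
    scl <- scl[!const]
  }
  for (i in seq_along(cols)) {
    table[[cols[i]]] <- (table[[cols[i]]] - ctr[i]) / scl[i]
  }
  attr(table, "center") <- ctr
  attr(table, "scale") <- scl
  table
}
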