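#' Default candidate-feature filter for the risk score
#'
#' The elastic-net candidate set mirrors the biology-driven narrowing of
#' the screen: NK-cell-related cytometry features plus plasma cytokines.
#'
#' @param features Character vector of feature names.
#' @return Logical vector marking NK-related features and cytokines.
#' @export
nk_candidate_filter <- function(features) {
  grepl("_NK", features, fixed = TRUE) | features %in% default_cytokines()
}

#' Run the full immunometabolic risk-stratification pipeline
#'
#' From raw events to the predicted score: arcsinh transform, gating,
#' feature assembly, Z-standardisation, squared-rank-difference distance,
#' stress curve with elbow dimensionality choice, coordinate screening by
#' bootstrap AUROC, feature correlation with the selected coordinate
#' (Spearman + Storey q-values), elastic-net variable selection over the
#' significant candidate features, and evaluation of the predicted score.
#'
#' @param cohort A `cohort_data` object (events with raw intensities,
#'   cytokines, outcomes), e.g. from [generate_cohort()].
#' @param tree Gating tree (default [default_gating_tree()]).
#' @param dims_range Dimensionalities for the stress curve (default 2:8;
#'   the sweep starts at two dimensions because the least-squares stress
#'   drop from one to two dimensions is dominated by uniform distance
#'   rescaling after projection and would mask any real elbow).
#' @param reps Bootstrap replications for AUROC intervals (default 1000).
#' @param seed Integer seed for bootstrap and fold randomness.
#' @param q_threshold Feature-significance cut-off on q-values.
#' @param candidate_filter Function mapping feature names to a logical
#'   mask of score candidates (default [nk_candidate_filter()]).
#' @param mixing Elastic-net mixing weight (default 0.5).
#' @param cofactor Arcsinh cofactor (default 5).
#' @return List of class `risk_pipeline`: `features` (raw feature table),
#'   `features_std`, `curve`, `chosen_dim`, `embedding`, `screen`,
#'   `correlations`, `candidates`, `model`, `scores`, `evaluation`.
#' @export
run_risk_pipeline <- function(cohort, tree = default_gating_tree(),
                              dims_range = 2:8, reps = 1000, seed = 1L,
                              q_threshold = 0.05,
                              candidate_filter = nk_candidate_filter,
                              mixing = 0.5, cofactor = 5) {
  stopifnot(inherits(cohort, "cohort_data"))
  events <- transform_events(cohort$events, cofactor = cofactor)
  events$subset_label <- NULL  # ignore ground-truth labels: re-gate
  events <- gate_events(events, tree)
  ft <- build_feature_table(events, cohort$cytokines, cohort$outcomes)
  ft_std <- z_normalize(ft)
  rd <- rank_distance(ft_std)
  curve <- stress_curve(rd, dims_range)
  chosen <- choose_dimension(curve)
  emb <- attr(curve, "fits")[[as.character(chosen)]]
  emb <- align_embedding(emb, ft_std$infected)
  screen <- screen_coordinates(emb, ft_std$infected, reps = reps,
                               seed = seed)
  coord <- emb$points[, screen$selected]
  corr <- correlate_features(ft_std, coord, q_threshold = q_threshold)
  cand <- corr$feature[corr$significant & candidate_filter(corr$feature)]
  if (length(cand) < 2) {
    message("fewer than 2 significant candidate features; ",
            "using the top candidate-filter features by |rho|")
    pool <- corr$feature[candidate_filter(corr$feature)]
    cand <- utils::head(pool, 11)
  }
  model <- fit_elastic_net(ft_std[cand], ft_std$infected, mixing = mixing,
                           seed = seed)
  scores <- predicted_score(model, ft_std[cand])
  evaluation <- evaluate_score(scores, ft_std$infected, reps = reps,
                               seed = seed)
  structure(list(features = ft, features_std = ft_std, curve = curve,
                 chosen_dim = chosen, embedding = emb, screen = screen,
                 correlations = corr, candidates = cand, model = model,
                 scores = scores, evaluation = evaluation),
            class = "risk_pipeline")
}
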