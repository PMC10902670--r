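#' Screen MDS coordinates against the outcome
#'
#' Computes the AUROC of each embedding coordinate for the binary outcome
#' with a stratified bootstrap percentile confidence interval, and selects
#' the coordinate with the largest AUROC (ties broken toward the lower
#' index, with a message).
#'
#' @param embedding An `mds_embedding` or a numeric coordinate matrix
#'   (patients x dims).
#' @param outcome Binary outcome vector aligned with the rows.
#' @param reps Bootstrap replications (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return List of class `screen_result`: `table` (data frame with
#'   `coordinate`, `auroc`, `lower`, `upper`), `selected` (index of the
#'   chosen coordinate), `reps`, `level`, `seed`.
#' @export
screen_coordinates <- function(embedding, outcome, reps = 1000,
                               level = 0.95, seed = 1L) {
  pts <- if (inherits(embedding, "mds_embedding")) embedding$points
         else as.matrix(embedding)
  stopifnot(nrow(pts) == length(outcome))
  rows <- lapply(seq_len(ncol(pts)), function(j) {
    ci <- bootstrap_auroc_ci(pts[, j], outcome, reps = reps, level = level,
                             seed = seed + j - 1L)
    data.frame(coordinate = j, auroc = ci$auroc,
               lower = ci$lower, upper = ci$upper)
  })
  tab <- do.call(rbind, rows)
  best <- max(tab$auroc)
  cand <- which(tab$auroc == best)
  if (length(cand) > 1) {
    message("AUROC tie among coordinates ",
            paste(cand, collapse = ", "), "; selecting the lowest index")
  }
  structure(list(table = tab, selected = min(cand), reps = reps,
                 level = level, seed = seed), class = "screen_result")
}

#' Correlate features with a selected coordinate
#'
#' Spearman correlation of every feature with the selected embedding
#' coordinate, with Storey q-value multiplicity control and a
#' significance flag at `q < q_threshold`. Features that are constant (no
#' rank information) are reported with `NA` and excluded from the
#' multiplicity adjustment.
#'
#' @param table Feature table (standardised or not; ranks are invariant).
#' @param coordinate Numeric vector of the selected coordinate's values.
#' @param features Feature columns to test (default [feature_columns()]).
#' @param q_threshold Significance cut-off on the q-value (default 0.05).
#' @return Data frame of class `feature_correlation`: `feature`, `rho`,
#'   `p`, `q`, `significant`, ordered by decreasing `|rho|`; the pi0
#'   estimate is attached as attribute `pi0`.
#' @export
correlate_features <- function(table, coordinate,
                               features = feature_columns(table),
                               q_threshold = 0.05) {
  stopifnot(length(coordinate) == nrow(table))
  rho <- p <- rep(NA_real_, length(features))
  for (i in seq_along(features)) {
    v <- table[[features[i]]]
    ok <- !is.na(v) & !is.na(coordinate)
    if (sum(ok) >= 3 && stats::sd(v[ok]) > 0 &&
        stats::sd(coordinate[ok]) > 0) {
      sc <- spearman_cor(v[ok], coordinate[ok])
      rho[i] <- sc$rho
      p[i] <- sc$p
    }
  }
  q <- rep(NA_real_, length(features))
  tested <- !is.na(p)
  if (any(tested)) {
    qv <- storey_qvalues(p[tested])
    q[tested] <- qv
    pi0 <- attr(qv, "pi0")
  } else {
    pi0 <- NA_real_
  }
  out <- data.frame(feature = features, rho = rho, p = p, q = q,
                    significant = !is.na(q) & q < q_threshold)
  out <- out[order(-abs(out$rho), na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "pi0") <- pi0
  class(out) <- c("feature_correlation", "data.frame")
  out
}
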