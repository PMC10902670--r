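#' Squared-rank-difference distance between patients
#'
#' For each feature, patients are ranked across the cohort (average ranks
#' for ties); the distance between patients i and j is the sum over
#' features of the squared difference of their ranks,
#' \eqn{d_{ij} = \sum_k (r_k(i) - r_k(j))^2}. Ranks are invariant to any
#' strictly monotone per-feature transform, so the preceding
#' Z-standardisation leaves this distance unchanged (it is retained in
#' the workflow for fidelity, and because other consumers of the
#' standardised table need it). Missing values are excluded pairwise:
#' a feature contributes to d_ij only when both patients are observed;
#' the number of skipped pairs is reported via `message()`.
#'
#' @param table Feature table (standardised or not) with `patient_id`.
#' @param features Feature columns to use (default [feature_columns()]).
#' @return List of class `rank_distance`: `d` (n x n symmetric matrix with
#'   zero diagonal, patient ids as dimnames) and `ranks` (patients x
#'   features matrix of within-feature ranks).
#' @export
rank_distance <- function(table, features = feature_columns(table)) {
  n <- nrow(table)
  if (n < 2) stop("need at least 2 patients")
  ranks <- vapply(features, function(f) {
    v <- table[[f]]
    if (all(is.na(v))) stop("feature has no observed values: ", f)
    rank(v, na.last = "keep", ties.method = "average")
  }, numeric(n))
  d <- matrix(0, n, n)
  n_skipped <- 0L
  for (k in seq_along(features)) {
    r <- ranks[, k]
    dk <- outer(r, r, `-`)^2
    na <- is.na(dk)
    if (any(na)) {
      n_skipped <- n_skipped + (sum(na) - sum(is.na(r))) / 2L
      dk[na] <- 0
    }
    d <- d + dk
  }
  if (n_skipped > 0) {
    message("rank_distance: ", n_skipped,
            " patient-pair feature values excluded for missingness")
  }
  dimnames(d) <- list(table$patient_id, table$patient_id)
  structure(list(d = d, ranks = ranks), class = "rank_distance")
}

as_distance_matrix <- function(d) {
  if (inherits(d, "rank_distance")) d <- d$d
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be nonnegative")
  d
}

mds_stress <- function(delta, dhat) {
  sum((delta - dhat)^2) / sum(delta^2)  # full-matrix sums; ratio identical
}

#' Metric MDS by majorization (SMACOF)
#'
#' Embeds patients in `dims` dimensions by least-squares metric MDS on the
#' supplied dissimilarities, minimising
#' \deqn{Stress = \sum_{i<j} (d_{ij} - \hat d_{ij})^2 / \sum_{i<j} d_{ij}^2,}
#' where \eqn{\hat d_{ij}} are the Euclidean distances of the embedded
#' points. Optimisation is iterative majorization (the Guttman transform)
#' from a classical-scaling start, so the stress sequence is
#' non-increasing. The reported stress is recomputed from the returned
#' coordinates with exactly the formula above.
#'
#' @param d Distance matrix, `rank_distance` object, or `dist`.
#' @param dims Embedding dimensionality, `1 <= dims < n`.
#' @param init Optional n x dims starting configuration (warm start);
#'   default is classical scaling (`stats::cmdscale`).
#' @param max_iter Maximum majorization iterations (default 1000).
#' @param tol Relative stress-change convergence threshold (default 1e-8).
#' @return List of class `mds_embedding`: `points` (n x dims, centred),
#'   `stress`, `dhat` (fitted distances), `trace` (stress per iteration),
#'   `dims`, `converged`.
#' @export
mds_embed <- function(d, dims, init = NULL, max_iter = 1000, tol = 1e-8) {
  delta <- as_distance_matrix(d)
  n <- nrow(delta)
  if (dims >= n || dims < 1) stop("`dims` must satisfy 1 <= dims < n")
  if (is.null(init)) {
    x <- suppressWarnings(stats::cmdscale(delta, k = dims))
    if (ncol(x) < dims) {  # degenerate spectrum: pad with zero coordinates
      x <- cbind(x, matrix(0, n, dims - ncol(x)))
    }
  } else {
    x <- as.matrix(init)
    stopifnot(nrow(x) == n, ncol(x) == dims)
  }
  dhat <- as.matrix(stats::dist(x))
  s <- mds_stress(delta, dhat)
  trace <- s
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # Guttman transform: X <- (1/n) B(X) X with unit weights
    b <- ifelse(dhat > 0, -delta / dhat, 0)
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x <- (b %*% x) / n
    dhat <- as.matrix(stats::dist(x))
    s_new <- mds_stress(delta, dhat)
    trace <- c(trace, s_new)
    if (s - s_new < tol * max(s, .Machine$double.eps)) {
      s <- s_new
      converged <- TRUE
      break
    }
    s <- s_new
  }
  x <- scale(x, center = TRUE, scale = FALSE)  # centre columns
  dimnames(x) <- list(rownames(delta), paste0("coord", seq_len(dims)))
  structure(list(points = x, stress = s, dhat = as.matrix(stats::dist(x)),
                 trace = trace, dims = dims, converged = converged),
            class = "mds_embedding")
}

#' Stress-versus-dimension curve
#'
#' Fits the embedding for each dimensionality in `dims_range`. Each fit at
#' D+1 is additionally warm-started from the D-dimensional solution padded
#' with a zero coordinate, and the better of warm and classical-scaling
#' starts is kept, which enforces a monotone non-increasing curve.
#'
#' @param d Distance matrix or `rank_distance`.
#' @param dims_range Increasing integer vector of dimensionalities
#'   (default 2:8). Sweeps conventionally start at two dimensions: the
#'   stress drop from one to two is dominated by the uniform rescaling
#'   that least-squares fits apply after projection and carries no
#'   information about intrinsic dimensionality.
#' @param ... Passed to [mds_embed()].
#' @return Data frame with columns `dims` and `stress`; the fitted
#'   embeddings are attached as attribute `fits` (a list keyed by dims).
#' @export
stress_curve <- function(d, dims_range = 2:8, ...) {
  delta <- as_distance_matrix(d)
  if (!length(dims_range)) stop("empty dims_range")
  dims_range <- sort(unique(as.integer(dims_range)))
  fits <- list()
  prev <- NULL
  out <- data.frame(dims = dims_range, stress = NA_real_)
  for (i in seq_along(dims_range)) {
    dd <- dims_range[i]
    fit <- mds_embed(delta, dd, ...)
    if (!is.null(prev)) {
      warm_init <- cbind(prev$points,
                         matrix(0, nrow(delta), dd - ncol(prev$points)))
      warm <- mds_embed(delta, dd, init = warm_init, ...)
      if (warm$stress < fit$stress) fit <- warm
    }
    fits[[as.character(dd)]] <- fit
    out$stress[i] <- fit$stress
    prev <- fit
  }
  attr(out, "fits") <- fits
  out
}

#' Choose embedding dimensionality by the elbow rule
#'
#' Picks the dimension with the largest discrete second difference of the
#' stress curve (greatest curvature). A flat or strictly linear curve has
#' no elbow: the smallest dimension is returned with a warning.
#'
#' @param curve Data frame with `dims` and `stress` (see [stress_curve()]),
#'   at least 3 rows.
#' @param tol Curvature below this is treated as no elbow (default 1e-10).
#' @return The chosen dimensionality (integer).
#' @export
choose_dimension <- function(curve, tol = 1e-10) {
  if (nrow(curve) < 3) stop("curve must have at least 3 points")
  s <- curve$stress
  k <- nrow(curve)
  curvature <- s[1:(k - 2)] - 2 * s[2:(k - 1)] + s[3:k]
  if (max(curvature) <= tol) {
    warning("stress curve has no elbow; returning smallest dimension")
    return(curve$dims[1])
  }
  curve$dims[which.max(curvature) + 1L]
}

#' Orient embedding axes against the outcome
#'
#' Flips the sign of each coordinate so that its Spearman correlation with
#' the binary outcome indicator is nonnegative, making downstream reports
#' reproducible (MDS solutions are only defined up to rotation/reflection).
#'
#' @param embedding An `mds_embedding`.
#' @param outcome Binary vector aligned with the embedding's rows.
#' @return The embedding with reoriented `points`.
#' @export
align_embedding <- function(embedding, outcome) {
  for (j in seq_len(ncol(embedding$points))) {
    rho <- suppressWarnings(
      stats::cor(embedding$points[, j], outcome, method = "spearman"))
    if (!is.na(rho) && rho < 0) {
      embedding$points[, j] <- -embedding$points[, j]
    }
  }
  embedding
}
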