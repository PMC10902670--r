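#' Per-cell gene-signature module score
#'
#' Scores a gene set in each cell as the mean expression of the set's
#' genes minus the mean expression of control genes drawn from
#' expression-matched bins: genes are binned by their cross-cell average
#' expression into `n_bins` equal-count bins, and for every set gene
#' `n_ctrl` controls are sampled (without replacement, capped at the bin
#' size) from its bin; the union of sampled controls forms the control
#' set. Genes absent from the matrix are dropped with a warning.
#'
#' @param x An `expression_data` object (see [generate_expression()]) or a
#'   cells x genes numeric matrix with gene column names.
#' @param gene_set Character vector of signature gene names.
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Control genes sampled per set gene (default 100).
#' @param seed Integer seed for the control sampling.
#' @return List of class `signature_score`: `score` (named per-cell
#'   vector), `genes_used`, `control_genes`.
#' @export
module_score <- function(x, gene_set, n_bins = 24, n_ctrl = 100, seed = 1L) {
  if (inherits(x, "expression_data")) x <- x$counts
  x <- as.matrix(x)
  if (anyDuplicated(colnames(x))) stop("duplicate gene names in matrix")
  # genes absent from every cell carry no signal and would only perturb
  # the expression bins, so scores stay invariant to appending them
  x <- x[, colSums(abs(x)) > 0, drop = FALSE]
  present <- intersect(gene_set, colnames(x))
  absent <- setdiff(gene_set, colnames(x))
  if (length(absent)) {
    warning(length(absent), " signature gene(s) absent from the matrix")
  }
  if (!length(present)) stop("no signature gene present in the matrix")
  set.seed(seed)
  g <- ncol(x)
  n_bins <- min(n_bins, g)
  gene_avg <- colMeans(x)
  bin <- ceiling(rank(gene_avg, ties.method = "first") * n_bins / g)
  names(bin) <- colnames(x)
  ctrl <- character(0)
  for (gene in present) {
    pool <- names(bin)[bin == bin[gene]]
    ctrl <- c(ctrl, sample(pool, min(n_ctrl, length(pool))))
  }
  ctrl <- unique(ctrl)
  score <- rowMeans(x[, present, drop = FALSE]) -
    rowMeans(x[, ctrl, drop = FALSE])
  structure(list(score = score, genes_used = present,
                 control_genes = ctrl),
            class = "signature_score")
}

#' Kruskal-Wallis omnibus test with Dunn post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with its chi-squared p-value, followed
#' by Dunn's pairwise z tests on average ranks with multiplicity
#' adjustment over the pairwise family (Bonferroni by default, Holm
#' optionally). With fewer than three groups the omnibus question
#' degenerates; a Mann-Whitney comparison is run instead with a warning.
#'
#' @param scores Numeric vector of per-cell scores.
#' @param groups Group labels aligned with `scores` (>= 2 per group).
#' @param adjust Pairwise adjustment: `"bonferroni"` (default) or
#'   `"holm"`.
#' @return List of class `kruskal_dunn`: `H`, `p`, `pairwise` (data frame
#'   `group1`, `group2`, `z`, `p`, `p_adj`), `mean_ranks`.
#' @export
kruskal_dunn <- function(scores, groups, adjust = c("bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop("need at least 2 observations per group")
  if (nlevels(groups) < 3) {
    warning("fewer than 3 groups; falling back to Mann-Whitney")
    mw <- group_compare(scores, as.integer(groups == levels(groups)[2]))
    return(structure(list(H = NA_real_, p = mw$p, pairwise = NULL,
                          mean_ranks = tapply(rank(scores), groups, mean)),
                     class = "kruskal_dunn"))
  }
  kw <- stats::kruskal.test(scores, groups)
  n <- length(scores)
  r <- rank(scores)
  rbar <- tapply(r, groups, mean)
  sizes <- table(groups)
  ties <- table(scores)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / sizes[[a]] + 1 / sizes[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  structure(list(
    H = unname(kw$statistic), p = kw$p.value,
    pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                          z = z, p = p,
                          p_adj = stats::p.adjust(p, method = adjust)),
    mean_ranks = rbar), class = "kruskal_dunn")
}
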