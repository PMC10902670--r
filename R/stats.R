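#' Rank-based AUROC
#'
#' Area under the ROC curve via the Mann-Whitney identity: the probability
#' that a random positive outscores a random negative, counting ties 1/2.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap percentile confidence interval for the AUROC
#'
#' Resamples patients with replacement, stratified by class so that every
#' resample retains both outcomes and the cohort prevalence, and returns
#' the percentile interval of the bootstrap AUROC distribution.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector.
#' @param reps Bootstrap replications (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling.
#' @param stratified Resample within class (default TRUE). If FALSE,
#'   plain resampling is used and single-class resamples are redrawn;
#'   the redraw count is attached as attribute `n_redrawn`.
#' @return List: `lower`, `upper`, `level`, `reps`, `auroc` (point
#'   estimate), and `boot` (the bootstrap AUROC draws).
#' @export
bootstrap_auroc_ci <- function(scores, labels, reps = 1000, level = 0.95,
                               seed = 1L, stratified = TRUE) {
  if (reps < 2) stop("`reps` must be at least 2")
  labels <- as.integer(labels)
  set.seed(seed)
  ip <- which(labels == 1L)
  im <- which(labels == 0L)
  if (!length(ip) || !length(im)) stop("both classes must be present")
  n <- length(labels)
  boot <- numeric(reps)
  n_redrawn <- 0L
  for (b in seq_len(reps)) {
    if (stratified) {
      idx <- c(sample(ip, length(ip), replace = TRUE),
               sample(im, length(im), replace = TRUE))
    } else {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
        n_redrawn <- n_redrawn + 1L
      }
    }
    boot[b] <- auroc(scores[idx], labels[idx])
  }
  alpha <- (1 - level) / 2
  # type-6 quantiles: the (R+1)-based order statistics conventional for
  # bootstrap percentile intervals
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 6))
  out <- list(lower = ci[1], upper = ci[2], level = level, reps = reps,
              auroc = auroc(scores, labels), boot = boot)
  if (!stratified) attr(out, "n_redrawn") <- n_redrawn
  out
}

# All permutations of 1..n as an integer matrix (n! rows), built by
# inserting n into every position of each permutation of 1..(n-1).
permutation_matrix <- function(n) {
  m <- matrix(1L, 1, 1)
  for (k in seq_len(n)[-1]) {
    old <- m
    r <- nrow(old)
    m <- matrix(0L, r * k, k)
    for (pos in seq_len(k)) {
      left <- if (pos > 1) old[, 1:(pos - 1), drop = FALSE] else NULL
      right <- if (pos < k) old[, pos:(k - 1), drop = FALSE] else NULL
      m[((pos - 1) * r + 1):(pos * r), ] <-
        cbind(left, rep(k, r), right)
    }
  }
  m
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' The coefficient is the Pearson correlation of average ranks. For
#' n <= 9 the two-sided p-value is computed by full permutation
#' enumeration of one margin (valid under ties); for larger n the
#' t-distribution approximation is used.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List: `rho`, `p`, `method` ("exact" or "t-approximation").
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need vectors of equal length, n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector supplied to spearman_cor")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- permutation_matrix(n)
    rx_perm <- matrix(rx[perms], nrow(perms), n)
    rho_perm <- as.vector(stats::cor(t(rx_perm), ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = min(p, 1), method = method)
}

#' Storey q-values
#'
#' Positive-FDR multiplicity adjustment: the null proportion
#' \eqn{\hat\pi_0} is estimated on the lambda grid by
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m (1 - \lambda))}
#' smoothed with a cubic spline and evaluated at the largest lambda, and
#' q-values are the step-up minima
#' \eqn{q_{(i)} = \min_{j \ge i} \hat\pi_0 m p_{(j)} / j}, clipped to
#' [0, 1]. Forcing `pi0 = 1` reproduces Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param p Vector of p-values in [0, 1] (no NaN).
#' @param lambda Grid for the pi0 estimate (default 0.05..0.95 by 0.05).
#' @param pi0 Optional fixed null proportion overriding estimation.
#' @return Numeric vector of q-values; the estimate used is attached as
#'   attribute `pi0`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  if (any(is.na(p))) stop("NaN/NA p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l),
                         numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(pi0, 1)
    if (pi0 <= 0) {
      warning("estimated pi0 <= 0; falling back to pi0 = 1")
      pi0 <- 1
    }
  }
  ord <- order(p)
  q <- numeric(m)
  q[ord[m]] <- min(pi0 * p[ord[m]], 1)
  if (m > 1) {
    for (i in (m - 1):1) {
      q[ord[i]] <- min(pi0 * m * p[ord[i]] / i, q[ord[i + 1]])
    }
  }
  attr(q, "pi0") <- pi0
  q
}

#' Two-group comparison by the Mann-Whitney U test
#'
#' Exact two-sided p for combined n <= 20 without ties; otherwise the
#' normal approximation with tie correction.
#'
#' @param values Numeric vector.
#' @param labels Binary group labels aligned with `values`.
#' @return List: `U` (statistic for the label-1 group), `p`.
#' @export
group_compare <- function(values, labels) {
  labels <- as.integer(labels)
  x <- values[labels == 1L]
  y <- values[labels == 0L]
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  n <- length(values)
  exact <- n <= 20 && !anyDuplicated(values)
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing all hypergeometric probabilities not larger
#' than the observed table's.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  stats::fisher.test(table)$p.value
}

#' Per-feature univariate logistic odds ratios
#'
#' Fits `outcome ~ feature` by logistic regression for each feature and
#' reports the odds ratio per unit of the (typically standardised)
#' feature, with Wald confidence interval and p-value. Perfect separation
#' is detected (diverging coefficient / degenerate fitted probabilities)
#' and reported as an infinite odds ratio with a warning rather than a
#' spurious finite estimate.
#'
#' @param features Data frame or matrix (patients x features).
#' @param labels Binary outcome vector.
#' @param level Confidence level (default 0.95).
#' @return Data frame: `feature`, `or`, `lower`, `upper`, `p`,
#'   `separated`.
#' @export
feature_odds_ratios <- function(features, labels, level = 0.95) {
  features <- as.data.frame(features)
  labels <- as.integer(labels)
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(names(features), function(f) {
    x <- features[[f]]
    fit <- suppressWarnings(stats::glm(labels ~ x, family = stats::binomial()))
    beta <- stats::coef(fit)[["x"]]
    pr <- stats::fitted(fit)
    separated <- !fit$converged || abs(beta) > 20 ||
      all(pr[labels == 1L] > 1 - 1e-8) && all(pr[labels == 0L] < 1e-8)
    if (separated) {
      warning("perfect separation for feature ", f,
              "; odds ratio reported as infinite")
      return(data.frame(feature = f, or = Inf * sign(beta), lower = NA,
                        upper = NA, p = NA, separated = TRUE))
    }
    se <- sqrt(diag(stats::vcov(fit)))[["x"]]
    data.frame(feature = f, or = exp(beta),
               lower = exp(beta - z * se), upper = exp(beta + z * se),
               p = 2 * stats::pnorm(-abs(beta / se)), separated = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
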