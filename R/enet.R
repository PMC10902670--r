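# Penalised logistic fit for one lambda (IRLS + cyclic coordinate
# descent; compiled kernel). X must be standardised; the intercept is
# never penalised.
enet_logistic_fit <- function(x, y, mix, lambda, beta0 = NULL, b0 = NULL,
                              maxit_outer = 100, maxit_inner = 500,
                              tol = 1e-11) {
  p <- ncol(x)
  beta <- if (is.null(beta0)) numeric(p) else beta0
  b <- if (is.null(b0)) stats::qlogis(max(min(mean(y), 1 - 1e-6), 1e-6))
       else b0
  enet_fit_cpp(x, as.integer(y), mix, lambda, beta, b,
               as.integer(maxit_outer), as.integer(maxit_inner), tol)
}

enet_lambda_grid <- function(x, y, mix, nlambda = 100,
                             ratio = if (nrow(x) < ncol(x)) 1e-2 else 1e-4) {
  n <- nrow(x)
  a <- max(mix, 1e-3)  # ridge limit still needs a finite entry point
  lambda_max <- max(abs(crossprod(x, y - mean(y)))) / (n * a)
  exp(seq(log(lambda_max), log(lambda_max * ratio), length.out = nlambda))
}

binomial_deviance <- function(y, pr) {
  pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
  -2 * (y * log(pr) + (1 - y) * log(1 - pr))
}

#' Elastic-net logistic regression with cross-validated penalty choice
#'
#' Fits the L1/L2-penalised logistic model over a decreasing lambda path
#' by cyclic coordinate descent on the iteratively reweighted quadratic
#' approximation, with warm starts along the path. Features are
#' standardised internally (population SD, matching the common penalised
#' regression convention); coefficients are reported on both the
#' standardised and the original feature scale, and predictions are
#' identical either way. The penalty is chosen by cross-validated
#' binomial deviance, leave-one-out by default (appropriate for cohorts
#' of a few dozen patients, where k-fold assignments are unstable), with
#' the one-standard-error rule.
#'
#' @param x Data frame or matrix of candidate features (patients x
#'   features), at least 2 columns.
#' @param y Binary outcome vector.
#' @param mixing Elastic-net mixing weight in [0, 1]: 1 = lasso,
#'   0 = ridge. Default 0.5.
#' @param lambda_grid Optional decreasing penalty grid; default is the
#'   standard geometric path from the smallest all-zero lambda.
#' @param cv_folds Number of folds; `NULL` (default) means leave-one-out.
#' @param rule `"1se"` (default) or `"min"` lambda selection.
#' @param seed Integer seed controlling fold assignment.
#' @return List of class `elastic_net_model`: `alpha` (intercept, original
#'   scale), `beta` (named coefficients, original scale), `beta_std`,
#'   `alpha_std` (standardised scale), `center`/`scale` (standardisation
#'   parameters), `lambda` (chosen), `mixing`, `cv` (data frame lambda x
#'   deviance x se), `selected` (features with nonzero coefficients),
#'   `seed`, `foldid`.
#' @export
fit_elastic_net <- function(x, y, mixing = 0.5, lambda_grid = NULL,
                            cv_folds = NULL, rule = c("1se", "min"),
                            seed = 1L) {
  rule <- match.arg(rule)
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("outcome has a single class")
  if (ncol(x) < 2) stop("need at least 2 candidate features")
  if (mixing < 0 || mixing > 1) stop("`mixing` must be in [0, 1]")
  n <- nrow(x)
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  if (any(scl == 0)) stop("constant candidate feature(s): ",
                          paste(colnames(x)[scl == 0], collapse = ", "))
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  if (is.null(lambda_grid)) lambda_grid <- enet_lambda_grid(xs, y, mixing)
  if (!length(lambda_grid)) stop("empty lambda grid")
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  fit_path <- function(xtr, ytr) {
    beta <- NULL; b0 <- NULL; frozen <- NULL
    lapply(lambda_grid, function(l) {
      # once a fit diverges (separation), smaller penalties diverge too
      if (!is.null(frozen)) return(frozen)
      f <- enet_logistic_fit(xtr, ytr, mixing, l, beta0 = beta, b0 = b0)
      beta <<- f$beta; b0 <<- f$intercept
      if (isTRUE(f$diverged)) frozen <<- f
      f
    })
  }

  set.seed(seed)
  k <- if (is.null(cv_folds)) n else min(cv_folds, n)
  foldid <- sample(rep(seq_len(k), length.out = n))
  dev <- matrix(NA_real_, n, length(lambda_grid))
  for (fold in seq_len(k)) {
    hold <- foldid == fold
    path <- fit_path(xs[!hold, , drop = FALSE], y[!hold])
    for (li in seq_along(lambda_grid)) {
      eta <- drop(xs[hold, , drop = FALSE] %*% path[[li]]$beta) +
        path[[li]]$intercept
      dev[hold, li] <- binomial_deviance(y[hold], stats::plogis(eta))
    }
  }
  cvm <- colMeans(dev)
  cvse <- apply(dev, 2, stats::sd) / sqrt(n)
  i_min <- which.min(cvm)
  i_sel <- if (rule == "min") i_min else
    min(which(cvm <= cvm[i_min] + cvse[i_min]))
  lambda <- lambda_grid[i_sel]

  full <- fit_path(xs, y)[[i_sel]]
  beta_std <- full$beta
  names(beta_std) <- colnames(x)
  beta <- beta_std / scl
  alpha <- full$intercept - sum(beta_std * ctr / scl)
  structure(list(
    alpha = alpha, beta = beta,
    alpha_std = full$intercept, beta_std = beta_std,
    center = ctr, scale = scl, lambda = lambda, mixing = mixing,
    lambda_grid = lambda_grid,
    cv = data.frame(lambda = lambda_grid, deviance = cvm, se = cvse),
    selected = names(beta_std)[beta_std != 0],
    rule = rule, seed = seed, foldid = foldid),
    class = "elastic_net_model")
}

#' KKT residuals of an elastic-net logistic solution
#'
#' Measures how far the fitted coefficients are from satisfying the
#' Karush-Kuhn-Tucker optimality conditions of the penalised objective on
#' the standardised scale: for active coordinates the penalised gradient
#' must vanish; for zero coordinates the bare gradient must lie within
#' the L1 threshold.
#'
#' @param model An `elastic_net_model`.
#' @param x,y The fitting data (original feature scale).
#' @return Numeric vector of per-coordinate KKT violations (0 = exact).
#' @export
enet_kkt_residuals <- function(model, x, y) {
  x <- as.matrix(as.data.frame(x))
  y <- as.integer(y)
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  n <- nrow(xs)
  eta <- drop(xs %*% model$beta_std) + model$alpha_std
  pr <- stats::plogis(eta)
  g <- -drop(crossprod(xs, y - pr)) / n
  l <- model$lambda
  mix <- model$mixing
  viol <- numeric(length(g))
  active <- model$beta_std != 0
  viol[active] <- abs(g[active] + l * (1 - mix) * model$beta_std[active] +
                        l * mix * sign(model$beta_std[active]))
  viol[!active] <- pmax(abs(g[!active]) - l * mix, 0)
  viol
}

#' Predicted score from an elastic-net model
#'
#' The logistic transform of the linear predictor,
#' \deqn{e^{\alpha + \sum_k \beta_k V_k} / (1 + e^{\alpha + \sum_k \beta_k V_k}),}
#' evaluated with numerically stable code for large linear predictors.
#'
#' @param model An `elastic_net_model`, or a list with `alpha` and a named
#'   `beta` vector.
#' @param features Named numeric vector, or data frame / matrix with one
#'   row per patient, containing every model feature.
#' @return Predicted score(s) in (0, 1).
#' @export
predicted_score <- function(model, features) {
  beta <- model$beta
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  }
  features <- as.matrix(as.data.frame(features))
  miss <- setdiff(names(beta), colnames(features))
  if (length(miss)) stop("missing model feature(s): ",
                         paste(miss, collapse = ", "))
  eta <- drop(features[, names(beta), drop = FALSE] %*% beta) + model$alpha
  stats::plogis(eta)
}

#' Evaluate predicted scores against the outcome
#'
#' Mann-Whitney comparison of scores between outcome groups and AUROC
#' with a stratified bootstrap percentile confidence interval.
#'
#' @param scores Numeric predicted scores.
#' @param labels Binary outcome.
#' @param reps Bootstrap replications (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return List: `p` (Mann-Whitney two-sided), `auroc`, `lower`, `upper`.
#' @export
evaluate_score <- function(scores, labels, reps = 1000, seed = 1L,
                           level = 0.95) {
  mw <- group_compare(scores, labels)
  ci <- bootstrap_auroc_ci(scores, labels, reps = reps, level = level,
                           seed = seed)
  list(p = mw$p, auroc = ci$auroc, lower = ci$lower, upper = ci$upper)
}
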