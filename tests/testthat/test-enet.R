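test_that("a saturating penalty zeroes all coefficients", {
  set.seed(20)
  x <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c(0L, 1L), c(18, 12))
  m <- fit_elastic_net(x, y, lambda_grid = c(100), cv_folds = 3, seed = 1)
  expect_true(all(m$beta == 0))
  expect_equal(m$alpha, qlogis(mean(y)), tolerance = 1e-6)
})

test_that("near-unpenalised ridge matches a maximum-likelihood oracle", {
  set.seed(21)
  n <- 60
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(0.5 * x[, 1] - 0.7 * x[, 2]))
  lam <- 1e-4
  m <- fit_elastic_net(x, y, mixing = 0, lambda_grid = c(lam),
                       cv_folds = 3, seed = 1)
  xs <- scale(x, scale = apply(x, 2, function(v)
    sqrt(mean((v - mean(v))^2))))
  opt <- optim(rep(0, 4), oracle_enet_objective, x = xs, y = y,
               lambda = lam, mix = 0, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(c(m$alpha_std, m$beta_std)), opt$par,
               tolerance = 1e-5)
})

test_that("solutions satisfy the KKT conditions and match glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(22)
  x <- matrix(rnorm(37 * 8), 37, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c(0L, 1L), c(21, 16))
  x[, 1] <- x[, 1] + y
  m <- fit_elastic_net(x, y, seed = 2)
  expect_lt(max(enet_kkt_residuals(m, x, y)), 1e-6)
  g <- glmnet::glmnet(x, y, family = "binomial", alpha = 0.5,
                      lambda = m$lambda, thresh = 1e-14)
  expect_equal(c(m$alpha, unname(m$beta)), as.numeric(coef(g)),
               tolerance = 1e-6)
})

test_that("standardise-then-fit and internal standardisation agree", {
  set.seed(23)
  x <- matrix(rnorm(40 * 4) * rep(c(1, 10, 0.2, 3), each = 40), 40, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(40, 1, plogis(x[, 1]))
  lam <- 0.05
  m_raw <- fit_elastic_net(x, y, lambda_grid = c(lam), cv_folds = 3,
                           seed = 1)
  xs <- sweep(sweep(x, 2, m_raw$center), 2, m_raw$scale, "/")
  m_std <- fit_elastic_net(xs, y, lambda_grid = c(lam), cv_folds = 3,
                           seed = 1)
  expect_equal(predicted_score(m_raw, x), predicted_score(m_std, xs),
               tolerance = 1e-8)
})

test_that("the predicted score is exactly the printed logistic transform", {
  m0 <- list(alpha = 0, beta = c(v = 0))
  expect_equal(unname(predicted_score(m0, c(v = 3))), 0.5)
  m1 <- list(alpha = 1, beta = c(v = 2))
  expect_equal(unname(predicted_score(m1, c(v = 1))),
               exp(3) / (1 + exp(3)), tolerance = 1e-15)

  set.seed(24)
  for (i in 1:30) {
    k <- sample(1:5, 1)
    beta <- rnorm(k); names(beta) <- paste0("v", 1:k)
    alpha <- rnorm(1)
    v <- rnorm(k); names(v) <- names(beta)
    lp <- alpha + sum(beta * v)
    m <- list(alpha = alpha, beta = beta)
    expect_equal(unname(predicted_score(m, v)),
                 exp(lp) / (1 + exp(lp)), tolerance = 1e-12)
    m_neg <- list(alpha = -alpha, beta = -beta)
    expect_equal(unname(predicted_score(m_neg, v)),
                 1 - unname(predicted_score(m, v)), tolerance = 1e-12)
  }
  # numerically stable in the saturated tails
  big <- list(alpha = 800, beta = c(v = 1))
  expect_equal(unname(predicted_score(big, c(v = 0))), 1)
  expect_error(predicted_score(m1, c(w = 1)), "missing model feature")
})

test_that("the score is monotone in each feature with the sign of its beta", {
  m <- list(alpha = 0.2, beta = c(up = 1.5, down = -2))
  grid <- seq(-2, 2, length.out = 9)
  s_up <- predicted_score(m, data.frame(up = grid, down = 0))
  s_down <- predicted_score(m, data.frame(up = 0, down = grid))
  expect_true(all(diff(s_up) > 0))
  expect_true(all(diff(s_down) < 0))
})

test_that("planted informative features are selected among candidates", {
  hits <- sapply(1:10, function(s) {
    set.seed(s)
    n <- 37
    y <- rep(c(0L, 1L), c(21, 16))[sample.int(n)]
    x <- matrix(rnorm(n * 11), n, 11,
                dimnames = list(NULL, paste0("f", 1:11)))
    x[, 1:3] <- x[, 1:3] + y
    m <- fit_elastic_net(x, y, seed = s)
    length(intersect(m$selected, c("f1", "f2", "f3"))) >= 1
  })
  expect_gte(mean(hits), 0.8)
})

test_that("score evaluation is seeded and behaves under the null", {
  set.seed(25)
  sc <- runif(30)
  lb <- rep(c(0L, 1L), 15)
  e1 <- evaluate_score(sc, lb, reps = 100, seed = 3)
  e2 <- evaluate_score(sc, lb, reps = 100, seed = 3)
  expect_identical(e1, e2)

  # shuffled labels: AUROC distribution centred at 1/2
  aucs <- replicate(200, auroc(sc, sample(lb)))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("degenerate elastic-net inputs error cleanly", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_elastic_net(x, rep(1L, 10)), "single class")
  expect_error(fit_elastic_net(x[, 1, drop = FALSE], rep(c(0L, 1L), 5)),
               "at least 2")
  expect_error(fit_elastic_net(x, rep(c(0L, 1L), 5),
                               lambda_grid = numeric()), "empty lambda")
})
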