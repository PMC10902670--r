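test_that("AUROC follows the Mann-Whitney identity with half-weighted ties", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  # 3 of 4 concordant pairs
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")

  # complement symmetry over random inputs
  set.seed(10)
  for (i in 1:20) {
    sc <- rnorm(15)
    lb <- rbinom(15, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(auroc(sc, lb) + auroc(-sc, lb), 1)
  }
})

test_that("bootstrap AUROC interval is percentile-based and seeded", {
  set.seed(2)
  sc <- c(rnorm(15), rnorm(15, 3))
  lb <- rep(c(0, 1), each = 15)
  ci1 <- bootstrap_auroc_ci(sc, lb, reps = 200, seed = 9)
  ci2 <- bootstrap_auroc_ci(sc, lb, reps = 200, seed = 9)
  expect_identical(ci1$boot, ci2$boot)
  expect_lte(ci1$lower, ci1$auroc)
  expect_gte(ci1$upper, ci1$auroc)

  # perfectly separated, well-sized data: interval pinned at 1
  sep <- c(rep(0, 12), rep(1, 12))
  ci3 <- bootstrap_auroc_ci(seq_along(sep), sep, reps = 100, seed = 1)
  expect_equal(ci3$lower, 1)
  expect_equal(ci3$upper, 1)
  expect_error(bootstrap_auroc_ci(sc, lb, reps = 1), "at least 2")
})

test_that("Spearman correlation matches the rank-Pearson oracle", {
  s <- spearman_cor(1:6, c(2, 4, 5, 7, 8, 12))
  expect_equal(s$rho, 1)
  s2 <- spearman_cor(c(1, 2, 3), c(3, 1, 2))
  expect_equal(s2$rho, -0.5)  # 1 - 6*6/(3*8)

  set.seed(11)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    x <- rnorm(n)
    y <- sample(c(rnorm(n - 1), x[1]))  # occasional ties across vectors
    expect_equal(spearman_cor(x, y)$rho, oracle_spearman_rho(x, y),
                 tolerance = 1e-12)
  }
  expect_error(spearman_cor(rep(1, 5), rnorm(5)), "constant")
})

test_that("small-sample Spearman p agrees with the exact distribution", {
  set.seed(12)
  for (i in 1:5) {
    n <- 7
    x <- rnorm(n)
    y <- rnorm(n)
    ours <- spearman_cor(x, y)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
  # t approximation beyond the enumeration limit
  x <- rnorm(30); y <- rnorm(30)
  ours <- spearman_cor(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
})

test_that("Storey q-values reduce to Benjamini-Hochberg when pi0 is 1", {
  set.seed(13)
  p <- c(runif(40), runif(10, 0, 1e-3))
  q <- storey_qvalues(p, pi0 = 1)
  expect_equal(as.numeric(q), p.adjust(p, method = "BH"), tolerance = 1e-12)

  q_est <- storey_qvalues(p)
  expect_true(all(q_est >= 0 & q_est <= 1))
  expect_lte(attr(q_est, "pi0"), 1)
  # q-values are monotone in sorted p
  ord <- order(p)
  expect_true(all(diff(q_est[ord]) >= -1e-12))

  expect_equal(as.numeric(storey_qvalues(rep(1, 5), pi0 = 1)), rep(1, 5))
  expect_error(storey_qvalues(c(0.1, NA)), "NaN/NA")
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Mann-Whitney matches enumeration for small samples", {
  gc <- group_compare(c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_equal(gc$U, 0)
  expect_equal(gc$p, 1 / 3)  # enumeration over C(4,2) assignments

  set.seed(14)
  for (i in 1:15) {
    n1 <- sample(2:4, 1); n0 <- sample(2:4, 1)
    x <- rnorm(n1); y <- rnorm(n0)
    ours <- group_compare(c(x, y), rep(c(1, 0), c(n1, n0)))
    expect_equal(ours$p, oracle_mw_p(x, y), tolerance = 1e-9)
  }
  expect_error(group_compare(1:3, c(1, 1, 1)), "nonempty")
})

test_that("Fisher's exact test matches the hypergeometric oracle", {
  set.seed(15)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2, 2)
    expect_equal(fisher_exact(tab), oracle_fisher_p(tab), tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
  expect_error(fisher_exact(matrix(1:6, 2)), "2x2")
})

test_that("per-feature logistic odds ratios match a maximum-likelihood oracle", {
  set.seed(16)
  for (i in 1:10) {
    n <- 40
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.3 + 0.8 * x))
    if (length(unique(y)) < 2) next
    res <- feature_odds_ratios(data.frame(f = x), y)
    nll <- function(par) {
      eta <- par[1] + par[2] * x
      -sum(y * eta - log1p(exp(eta)))
    }
    gr <- function(par) {
      pr <- plogis(par[1] + par[2] * x)
      -c(sum(y - pr), sum((y - pr) * x))
    }
    opt <- optim(c(0, 0), nll, gr, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 1000))
    expect_equal(log(res$or), opt$par[2], tolerance = 1e-6)
  }

  # separation is flagged, not reported as a finite estimate
  xs <- c(rnorm(10, -3), rnorm(10, 3))
  ys <- rep(c(0, 1), each = 10)
  expect_warning(sep <- feature_odds_ratios(data.frame(f = xs), ys),
                 "separation")
  expect_true(sep$separated[1])
  expect_true(is.infinite(sep$or[1]))

  # null simulation: type-I error near nominal
  set.seed(17)
  rej <- replicate(400, {
    x <- rnorm(40); y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) return(NA)
    suppressWarnings(feature_odds_ratios(data.frame(f = x), y)$p[1]) < 0.05
  })
  expect_lt(abs(mean(rej, na.rm = TRUE) - 0.05), 0.035)
})

test_that("coordinate screening selects the most discriminative axis", {
  set.seed(18)
  n <- 30
  outcome <- rep(c(0L, 1L), each = 15)
  pts <- cbind(rnorm(n), rnorm(n), outcome * 2 + rnorm(n, sd = 0.6))
  sc <- screen_coordinates(pts, outcome, reps = 100, seed = 1)
  expect_equal(sc$selected, 3)
  expect_true(all(sc$table$lower <= sc$table$auroc + 1e-9))
  expect_true(all(sc$table$upper >= sc$table$auroc - 1e-9))
})

test_that("feature correlation flags planted associations via q-values", {
  set.seed(19)
  n <- 30
  coord <- rnorm(n)
  tb <- data.frame(patient_id = seq_len(n), infected = 0L,
                   as.data.frame(matrix(rnorm(n * 40), n, 40)),
                   check.names = FALSE)
  tb$hit1 <- coord + rnorm(n, sd = 0.2)
  tb$hit2 <- -coord + rnorm(n, sd = 0.2)
  cr <- correlate_features(tb, coord)
  expect_setequal(cr$feature[1:2], c("hit1", "hit2"))
  expect_true(all(cr$significant[1:2]))
  expect_true(all(abs(cr$rho) <= 1, na.rm = TRUE))
})
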