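test_that("rank distance matches hand-computed squared rank differences", {
  # two patients, one feature: ranks 1, 2 -> d = 1
  tb2 <- data.frame(patient_id = c("a", "b"), infected = c(0L, 1L),
                    f1 = c(10, 20))
  expect_equal(unname(rank_distance(tb2)$d[1, 2]), 1)

  # tie case: values (5, 5, 9) -> average ranks (1.5, 1.5, 3)
  tb3 <- data.frame(patient_id = c("a", "b", "c"), infected = 0L,
                    f1 = c(5, 5, 9))
  d3 <- rank_distance(tb3)$d
  expect_equal(unname(d3[1, 2]), 0)
  expect_equal(unname(d3[1, 3]), 2.25)
  expect_equal(unname(d3[2, 3]), 2.25)

  # identical patients are at distance zero; symmetry; zero diagonal
  tb4 <- data.frame(patient_id = c("a", "b", "c"), infected = 0L,
                    f1 = c(1, 1, 2), f2 = c(4, 4, 9))
  d4 <- rank_distance(tb4)$d
  expect_equal(unname(d4[1, 2]), 0)
  expect_identical(d4, t(d4))
  expect_true(all(diag(d4) == 0))

  # ranks are invariant to standardisation, hence so is the distance
  z4 <- z_normalize(tb4)
  expect_equal(rank_distance(z4)$d, d4)

  expect_error(rank_distance(data.frame(patient_id = "a", infected = 0L,
                                        f1 = NA_real_)),
               "at least 2 patients")
})

test_that("SMACOF embeds exactly embeddable distances at ~zero stress", {
  set.seed(4)
  x0 <- matrix(rnorm(24), 8, 3)
  fit <- mds_embed(as.matrix(dist(x0)), 3)
  expect_lt(fit$stress, 1e-6)
  expect_true(all(diff(fit$trace) <= 1e-12))  # majorization: non-increasing
  expect_equal(unname(colMeans(fit$points)), rep(0, 3), tolerance = 1e-8)

  # D = n - 1 always suffices for Euclidean input
  fit2 <- mds_embed(as.matrix(dist(matrix(rnorm(10), 5, 2))), 4)
  expect_lt(fit2$stress, 1e-8)
})

test_that("reported stress equals the printed formula on returned coordinates", {
  set.seed(5)
  co <- tiny_cohort(seed = 5, n_patients = 8, cells = 300)
  d <- rank_distance(z_normalize(cohort_features(co)))$d
  fit <- mds_embed(d, 2)
  dhat <- as.matrix(dist(fit$points))
  recomputed <- sum((d - dhat)^2) / sum(d^2)
  expect_equal(fit$stress, recomputed, tolerance = 1e-8)
  # stress is invariant to patient relabeling and rigid rotation
  perm <- sample(nrow(d))
  fitp <- mds_embed(d[perm, perm], 2)
  expect_equal(fitp$stress, fit$stress, tolerance = 1e-5)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  dhat_rot <- as.matrix(dist(fit$points %*% rot))
  expect_equal(sum((d - dhat_rot)^2) / sum(d^2), fit$stress,
               tolerance = 1e-10)
})

test_that("1-D embedding of three equidistant points attains the grid-search optimum", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  fit <- mds_embed(d, 1)
  # dense grid over centred 1-D configurations (x1 <= x2 <= x3, sum 0)
  grid <- seq(-1.2, 1.2, by = 0.005)
  best <- Inf
  for (x1 in grid) for (x3 in grid[grid >= 0]) {
    x2 <- -(x1 + x3)
    dh <- abs(c(x1 - x2, x1 - x3, x2 - x3))
    s <- sum((c(1, 1, 1) - dh)^2) / 3
    if (s < best) best <- s
  }
  expect_equal(fit$stress, best, tolerance = 1e-3)
})

test_that("stress curves decrease monotonically and are reproducible", {
  co <- tiny_cohort(seed = 12, n_patients = 10, cells = 300)
  d <- rank_distance(z_normalize(cohort_features(co)))
  cv <- stress_curve(d, 2:6)
  expect_true(all(diff(cv$stress) <= 1e-12))
  cv2 <- stress_curve(d, 2:6)
  expect_identical(cv$stress, cv2$stress)
  expect_error(stress_curve(d, integer()), "empty")
})

test_that("elbow choice maximises the second difference and flags flat curves", {
  curve <- data.frame(dims = 1:4, stress = c(0.5, 0.2, 0.19, 0.185))
  expect_equal(choose_dimension(curve), 2)
  lin <- data.frame(dims = 1:5, stress = seq(0.5, 0.1, length.out = 5))
  expect_warning(dd <- choose_dimension(lin), "no elbow")
  expect_equal(dd, 1)
  expect_error(choose_dimension(curve[1:2, ]), "at least 3")
})

test_that("the elbow recovers a planted latent dimension of three", {
  hits <- sapply(1:10, function(s) {
    set.seed(s)
    L <- matrix(rnorm(40 * 3), 40, 3)
    W <- matrix(rnorm(3 * 40), 3, 40)
    X <- L %*% W + matrix(rnorm(40 * 40, sd = 0.05), 40, 40)
    tb <- data.frame(patient_id = 1:40, infected = 0L, X,
                     check.names = FALSE)
    cv <- stress_curve(rank_distance(tb), 2:8)
    suppressWarnings(choose_dimension(cv))
  })
  expect_gte(mean(hits == 3), 0.8)
})

test_that("axis orientation aligns coordinates with the outcome", {
  set.seed(6)
  x0 <- matrix(rnorm(40), 20, 2)
  outcome <- as.integer(x0[, 1] > 0)
  fit <- mds_embed(as.matrix(dist(x0)), 2)
  ali <- align_embedding(fit, outcome)
  for (j in 1:2) {
    rho <- suppressWarnings(cor(ali$points[, j], outcome,
                                method = "spearman"))
    expect_gte(rho, 0)
  }
})
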