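# Independent brute-force oracles used to pin expected values.

# All permutations of 1..n (rows), recursion independent of the package's
# generator.
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Spearman rho as Pearson on average ranks, from first principles.
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exact two-sided Mann-Whitney p by enumerating group assignments.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * (length(y)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Two-sided Fisher p: sum of hypergeometric probabilities <= observed.
oracle_fisher_p <- function(tab) {
  m <- tab[1, 1] + tab[2, 1]
  nn <- tab[1, 2] + tab[2, 2]
  k <- tab[1, 1] + tab[1, 2]
  support <- max(0, k - nn):min(k, m)
  probs <- dhyper(support, m, nn, k)
  p_obs <- dhyper(tab[1, 1], m, nn, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Tie-corrected Kruskal-Wallis H from first principles.
oracle_kw_h <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exact permutation p for Kruskal-Wallis by enumerating all group-label
# arrangements (small n only).
oracle_kw_perm_p <- function(values, groups) {
  h_obs <- oracle_kw_h(values, groups)
  perms <- oracle_perms(length(values))
  hs <- apply(perms, 1, function(ix) oracle_kw_h(values[ix], groups))
  mean(hs >= h_obs - 1e-9)
}

# Penalised logistic negative objective for optim-based oracles
# (glmnet-style scaling).
oracle_enet_objective <- function(par, x, y, lambda, mix) {
  b0 <- par[1]; b <- par[-1]
  eta <- drop(x %*% b) + b0
  -mean(y * eta - log1p(exp(eta))) +
    lambda * (mix * sum(abs(b)) + (1 - mix) / 2 * sum(b^2))
}

# Small synthetic cohort for unit tests (kept light).
tiny_cohort <- function(seed = 1L, n_patients = 8, cells = 1500, ...) {
  generate_cohort(cohort_spec(n_patients = n_patients,
                              cells_per_patient = cells,
                              seed = seed, ...))
}

# Gated, standardised feature table from a cohort.
cohort_features <- function(co) {
  ev <- transform_events(co$events)
  ev$subset_label <- NULL
  ev <- gate_events(ev, default_gating_tree())
  build_feature_table(ev, co$cytokines, co$outcomes)
}

# Names of the ten NK-related planted features (leaves + aggregates).
nk_planted_features <- function() {
  as.vector(outer(c("NRF1_", "CPT1a_"),
                  c("NK", "NK(CD56bright)", "NK(CD56dim)",
                    "NK(CD56dimCD57-)", "NK(CD56dimCD57+)"), paste0))
}
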