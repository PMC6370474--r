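test_that("antipodal groups separate perfectly and pure clusters have zero distance", {
  v <- rnorm(30)
  x <- rbind(
    matrix(rep(v, 5), 5, byrow = TRUE),
    matrix(rep(-v, 5), 5, byrow = TRUE)
  )
  fit <- cosine_kmeans(x, 2, seed = 1, n_restarts = 5)
  expect_equal(ari(fit$assignments, rep(1:2, each = 5)), 1)
  expect_equal(fit$mean_distance, 0, tolerance = 1e-12)

  # k = 1 on identical vectors: centroid equals the vector
  x1 <- matrix(rep(v, 4), 4, byrow = TRUE)
  fit1 <- cosine_kmeans(x1, 1, seed = 1, n_restarts = 1)
  expect_equal(as.numeric(fit1$centroids), v)
  expect_equal(fit1$mean_distance, 0, tolerance = 1e-12)

  expect_error(cosine_kmeans(rbind(v, 0 * v), 2), "all-zero")
})

test_that("planted subtypes are recovered with high adjusted Rand index", {
  # two angular clusters in connectivity space: a shared baseline plus a
  # within/between-network contrast for half the subjects; recovery under
  # the full generator at standard conditions is checked in the acceptance
  # suite
  set.seed(2)
  p <- 190
  base <- c(rep(0.35, 19), rep(0.08, 171))
  offset <- c(rep(0.3, 19), rep(-0.3, 171))
  lab <- rep(1:2, each = 30)
  m <- t(sapply(lab, function(l) {
    base + (l == 2) * offset + rnorm(p, 0, 0.1)
  }))
  fit <- cosine_kmeans(m, 2, seed = 1, n_restarts = 10)
  expect_gte(ari(fit$assignments, lab), 0.9)
})

test_that("elbow criterion maximizes the second difference, ties to smaller k", {
  d <- tibble::tibble(
    k = 1:8,
    mean_distance = c(10, 4, 3.5, 3.2, 3.0, 2.9, 2.85, 2.8)
  )
  expect_equal(elbow_select(d), 2) # slope_change(2) = 6 - 0.5 dominates
  lin <- tibble::tibble(k = 1:6, mean_distance = seq(6, 1))
  expect_equal(elbow_select(lin), 2) # all second differences 0: tie rule
  expect_error(elbow_select(d[1:2, ]), "3")
})

test_that("three well-separated planted clusters give an elbow at k = 3", {
  set.seed(3)
  centers <- 5 * rbind(
    c(rep(1, 14), rep(0, 28)),
    c(rep(0, 14), rep(1, 14), rep(0, 14)),
    c(rep(0, 28), rep(1, 14))
  )
  x <- centers[rep(1:3, each = 20), ] + matrix(rnorm(60 * 42, 0, 0.3), 60)
  curve <- elbow_curve(x, k_max = 6, seed = 1, n_restarts = 10)
  expect_equal(elbow_select(curve), 3)
})

test_that("best-of-restarts matches the exhaustive 2-partition oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(rnorm(7 * 9), 7)
    fit <- cosine_kmeans(m, 2, seed = seed, n_restarts = 20)
    expect_equal(fit$mean_distance, brute_force_k2(m), tolerance = 1e-12)
  }
})

test_that("mean cosine distance is non-increasing across Lloyd iterations", {
  set.seed(4)
  m <- matrix(rnorm(40 * 15), 40)
  m <- m / sqrt(rowSums(m^2)) # unit rows: mean update is exactly optimal
  prev <- Inf
  for (cap in 1:8) {
    fit <- suppressWarnings(
      cosine_kmeans(m, 3, seed = 9, n_restarts = 1, max_iter = cap)
    )
    expect_lte(fit$mean_distance, prev + 1e-12)
    prev <- fit$mean_distance
  }
})

test_that("assignments are scale invariant and reruns are deterministic", {
  set.seed(5)
  m <- matrix(rnorm(30 * 12), 30)
  f1 <- cosine_kmeans(m, 3, seed = 2, n_restarts = 5)
  f2 <- cosine_kmeans(3.7 * m, 3, seed = 2, n_restarts = 5)
  expect_identical(f1$assignments, f2$assignments)
  f3 <- cosine_kmeans(m, 3, seed = 2, n_restarts = 5)
  expect_identical(f1$assignments, f3$assignments)
  expect_identical(f1$mean_distance, f3$mean_distance)
})

test_that("half-sample reliability is deterministic and handles edge cases", {
  cc <- sim_fc_cohort(n_subjects = 30, n_rois = 12, seed = 6)
  r1 <- bootstrap_k(cc$m, k_max = 4, n_resamples = 8, seed = 3)
  r2 <- bootstrap_k(cc$m, k_max = 4, n_resamples = 8, seed = 3)
  expect_identical(r1$chosen_k_counts, r2$chosen_k_counts)
  expect_equal(sum(r1$chosen_k_counts), 8)
  r0 <- bootstrap_k(cc$m, k_max = 4, n_resamples = 0, seed = 3)
  expect_equal(sum(r0$chosen_k_counts), 0)
  expect_error(bootstrap_k(cc$m, k_max = 4, fraction = 1.5), "fraction")
  expect_error(bootstrap_k(cc$m[1:6, ], k_max = 4, fraction = 0.5), "smaller")
})

test_that("subtype phenotype comparison computes t and chi-square per variable", {
  # identical continuous distributions in both subtypes: t = 0
  pheno <- tibble::tibble(
    age = rep(c(10, 12, 14, 16), 2),
    site = rep(c("s1", "s2"), each = 4),
    srs = c(50, 60, NA, 70, 50, 60, 70, NA)
  )
  g <- rep(1:2, each = 4)
  rep_tab <- compare_subtype_phenotypes(g, pheno,
    continuous = c("age", "srs"), categorical = "site"
  )
  expect_equal(rep_tab$statistic[rep_tab$variable == "age"], 0)
  # NA handled pairwise: n reported excludes them
  expect_equal(rep_tab$n1[rep_tab$variable == "srs"], 3)
  expect_equal(rep_tab$n2[rep_tab$variable == "srs"], 3)
  # site perfectly confounded with subtype: chi-square = N
  expect_equal(rep_tab$statistic[rep_tab$variable == "site"], 8)
  pheno2 <- tibble::tibble(site = rep(c("a", "b"), each = 50))
  out2 <- compare_subtype_phenotypes(rep(1:2, each = 50), pheno2,
    continuous = character(), categorical = "site"
  )
  expect_equal(out2$statistic, 100)
  expect_equal(out2$df, 1)
})
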