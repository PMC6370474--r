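test_that("mean-centering PLS matches a directly constructed SVD", {
  set.seed(1)
  n <- 40
  x <- matrix(rnorm(n * 6), n)
  g <- factor(rep(c("a", "b", "c", "d"), each = 10))
  fit <- mean_centering_pls(x, g)
  # independent construction: group means, unweighted grand mean, dense SVD
  gm <- t(sapply(levels(g), function(lv) colMeans(x[g == lv, ])))
  mc <- sweep(gm, 2, colMeans(gm))
  s <- svd(mc)
  expect_equal(fit$singular_values, s$d[1:3], tolerance = 1e-10)
  # energy conservation
  expect_equal(sum(fit$singular_values^2), sum(mc^2), tolerance = 1e-10)
  # orthonormal brain saliences
  expect_equal(crossprod(fit$brain_salience), diag(3), tolerance = 1e-10)
  # brain scores are projections of the data
  expect_equal(fit$brain_scores, x %*% fit$brain_salience)
})

test_that("a pure two-group mean shift is a rank-1 pattern along the shift", {
  d <- c(1, -2, 0.5, 3, -1, 0, 2, 1)
  base <- rnorm(8)
  x <- rbind(
    matrix(rep(base, 5), 5, byrow = TRUE),
    matrix(rep(base + d, 5), 5, byrow = TRUE)
  )
  fit <- mean_centering_pls(x, rep(c("g1", "g2"), each = 5))
  expect_equal(fit$patterns$covariance_fraction[1], 1, tolerance = 1e-10)
  sal <- fit$brain_salience[, 1]
  expect_equal(abs(sum(sal * d / sqrt(sum(d^2)))), 1, tolerance = 1e-10)
})

test_that("additive group structure yields subtype, diagnosis, and null
           interaction patterns", {
  # exact additive means, balanced groups, no noise: the interaction
  # singular value must vanish
  p <- 30
  set.seed(2)
  mu <- rnorm(p)
  s_eff <- rnorm(p)
  d_eff <- rnorm(p)
  means <- list(
    asd_st1 = mu + d_eff, td_st1 = mu,
    asd_st2 = mu + d_eff + 4 * s_eff, td_st2 = mu + 4 * s_eff
  )
  x <- do.call(rbind, lapply(means, function(m) {
    matrix(rep(m, 6), 6, byrow = TRUE)
  }))
  g <- factor(rep(names(means), each = 6), levels = names(means))
  fit <- mean_centering_pls(x, g)
  expect_lt(fit$singular_values[3], 1e-10)
  # pattern 1 contrasts subtypes, pattern 2 diagnoses
  u <- fit$design_salience
  st <- c(1, 1, -1, -1)
  dx <- c(1, -1, 1, -1)
  expect_gt(abs(cor(u[, 1], st)), 0.99)
  expect_gt(abs(cor(u[, 2], dx)), 0.99)
})

test_that("patterns are invariant to subject order", {
  set.seed(3)
  x <- matrix(rnorm(30 * 10), 30)
  g <- factor(rep(1:3, each = 10))
  perm <- sample(30)
  f1 <- mean_centering_pls(x, g)
  f2 <- mean_centering_pls(x[perm, ], g[perm])
  expect_equal(f1$singular_values, f2$singular_values, tolerance = 1e-12)
  expect_equal(f1$brain_salience, f2$brain_salience, tolerance = 1e-10)
})

test_that("behavior PLS reduces to the Pearson correlation in the 1x1x1 case", {
  set.seed(4)
  brain <- matrix(rnorm(25), 25, 1)
  beh <- 0.6 * brain[, 1] + rnorm(25)
  r <- cor(beh, brain[, 1])
  fit <- behavior_pls(brain, data.frame(b = beh), rep("all", 25))
  expect_equal(fit$singular_values[1], abs(r), tolerance = 1e-12)
  expect_equal(
    unname(sign(fit$design_salience[1, 1] * fit$brain_salience[1, 1])),
    sign(r)
  )
})

test_that("behavior PLS recovers the planted brain-behavior pattern", {
  cc <- sim_fc_cohort(n_subjects = 120, n_rois = 20, seed = 5)
  beh <- cc$phenotypes[c("iq", "ados_comm", "ados_social", "ados_rrb", "srs")]
  fit <- behavior_pls(cc$m, beh, rep("all", nrow(cc$m)))
  expect_gt(
    abs(cor(fit$brain_salience[, 1], cc$truth$planted_subtype_salience)),
    0.9
  )
  expect_gt(
    abs(cor(fit$design_salience[, 1], cc$truth$planted_behavior_salience)),
    0.9
  )
  # complete-case rule: rows with missing behavior are dropped
  beh2 <- beh
  beh2$srs[1:5] <- NA
  fit2 <- behavior_pls(cc$m, beh2, rep("all", nrow(cc$m)))
  expect_equal(nrow(fit2$fc), 115)
  # zero-variance behavior within a group is a named error
  beh3 <- beh
  beh3$iq <- 100
  expect_error(behavior_pls(cc$m, beh3, rep("all", nrow(cc$m))), "iq")
})

test_that("permutation p-values are deterministic and detect strong effects", {
  cc <- sim_fc_cohort(
    n_subjects = 60, n_rois = 16, seed = 6,
    subtype_effect = 0.5
  )
  fit <- mean_centering_pls(cc$m, factor(cc$truth$subtype_labels))
  f1 <- pls_permutation(fit, n_perm = 100, seed = 7)
  expect_lt(f1$patterns$perm_p[1], 0.01)
  expect_true(f1$patterns$p_floor[1])
  f2 <- pls_permutation(fit, n_perm = 100, seed = 7)
  expect_identical(f1$patterns$perm_p, f2$patterns$perm_p)
  expect_error(pls_permutation(fit, n_perm = 0), "n_perm")
})

test_that("the covariance-fraction statistic leaves a truly additive
           interaction pattern non-significant while raw singular values
           do not", {
  cc <- sim_fc_cohort(n_subjects = 120, n_rois = 24, seed = 8)
  g4 <- interaction(cc$truth$dx_labels, cc$truth$subtype_labels)
  fit <- mean_centering_pls(cc$m, g4)
  raw <- pls_permutation(fit, n_perm = 100, seed = 1)
  frac <- pls_permutation(fit,
    n_perm = 100, seed = 1,
    statistic = "covariance_fraction"
  )
  # both find the dominant subtype pattern
  expect_lt(raw$patterns$perm_p[1], 0.05)
  expect_lt(frac$patterns$perm_p[1], 0.05)
  # the raw comparison is structurally anticonservative for the (absent)
  # interaction; the normalized statistic is not
  expect_gt(frac$patterns$perm_p[3], 0.05)
})

test_that("bootstrap ratios are deterministic and flag degenerate resamples", {
  # noiseless two-group data: every bootstrap reproduces the same salience,
  # so SEs collapse to zero and BSRs are flagged
  base <- rnorm(12)
  d <- rnorm(12)
  x <- rbind(
    matrix(rep(base, 6), 6, byrow = TRUE),
    matrix(rep(base + d, 6), 6, byrow = TRUE)
  )
  fit <- mean_centering_pls(x, rep(c("a", "b"), each = 6))
  expect_warning(
    fitb <- pls_bootstrap(fit, n_boot = 20, seed = 1),
    "zero bootstrap SE"
  )
  expect_true(all(is.na(fitb$bsr[, 1])))
  expect_false(any(fitb$stable_mask))

  cc <- sim_fc_cohort(n_subjects = 40, n_rois = 12, seed = 9)
  f <- mean_centering_pls(cc$m, factor(cc$truth$subtype_labels))
  b1 <- pls_bootstrap(f, n_boot = 30, seed = 2)
  b2 <- pls_bootstrap(f, n_boot = 30, seed = 2)
  expect_identical(b1$bsr, b2$bsr)
  expect_identical(b1$design_salience_ci, b2$design_salience_ci)
})

test_that("BSR-thresholded connections recover a sparse planted contrast", {
  # two diagnostic groups differing on a known 10% connection subset
  cc <- sim_fc_cohort(
    n_subjects = 200, n_rois = 20, seed = 10,
    subtype_effect = 0, dx_effect = 0.5
  )
  fit <- mean_centering_pls(cc$m, factor(cc$truth$dx_labels))
  fit <- pls_bootstrap(fit, n_boot = 100, seed = 3)
  planted <- cc$truth$planted_dx_salience != 0
  stable <- fit$stable_mask[, 1]
  expect_gte(mean(stable[planted]), 0.8) # sensitivity
  expect_lte(mean(stable[!planted]), 0.1) # false-positive rate
})

test_that("contrast expressions average the right connection sets per group", {
  # group 1 positive on set A and negative on set B, group 2 reversed
  p <- 20
  a_set <- 1:5
  b_set <- 6:10
  x <- matrix(0, 10, p)
  x[1:5, a_set] <- 0.5
  x[1:5, b_set] <- -0.5
  x[6:10, a_set] <- -0.5
  x[6:10, b_set] <- 0.5
  g <- rep(c("g1", "g2"), each = 5)
  bsr <- matrix(0, p, 1)
  bsr[a_set, 1] <- 3
  bsr[b_set, 1] <- -3
  fake <- structure(list(bsr = bsr, bsr_threshold = 2), class = "fc_pls")
  ce <- contrast_expression(x, g, fake)
  bg <- ce$by_group
  expect_equal(bg$mean_fc[bg$group == "g1" & bg$sign == "positive"], 0.5)
  expect_equal(bg$mean_fc[bg$group == "g2" & bg$sign == "positive"], -0.5)
  expect_equal(bg$mean_fc[bg$group == "g1" & bg$sign == "negative"], -0.5)
  # all-zero FC gives zero expressions
  ce0 <- contrast_expression(0 * x, g, fake)
  expect_true(all(ce0$by_group$mean_fc == 0))
  # a threshold nothing passes reports absent expressions
  ce_hi <- contrast_expression(x, g, fake, threshold = 99)
  expect_true(all(is.na(ce_hi$by_group$mean_fc)))
})

test_that("salience correlation handles exact, null, and degenerate cases", {
  set.seed(11)
  v <- rnorm(500)
  expect_equal(salience_correlation(v, v, n_perm = 50, seed = 1)$r, 1)
  expect_equal(salience_correlation(v, -v, n_perm = 50, seed = 1)$r, -1)
  w <- rnorm(500)
  out <- salience_correlation(v, w, n_perm = 100, seed = 2)
  expect_lt(abs(out$r), 0.1)
  expect_gt(out$p, 0.05)
  expect_error(salience_correlation(v, w[1:10]), "length")
  expect_error(salience_correlation(v, rep(1, 500)), "constant")
})
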