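test_that("series are truncated to the cohort minimum, from the start", {
  set.seed(1)
  s <- list(
    a = matrix(rnorm(150 * 4), 150),
    b = matrix(rnorm(147 * 4), 147),
    c = matrix(rnorm(145 * 4), 145)
  )
  out <- truncate_to_common_length(s)
  expect_equal(unname(vapply(out, nrow, integer(1))), c(145, 145, 145))
  expect_equal(out$a, s$a[1:145, ])
  # already-equal lengths: identity
  expect_identical(truncate_to_common_length(out), out)
  # a short series is a named error
  s$d <- matrix(rnorm(100 * 4), 100)
  expect_error(truncate_to_common_length(s, 145), "d")
})

test_that("FC is the Fisher z of Pearson correlations in fixed order", {
  # construct two columns with exact correlation 0.5 by Gram-Schmidt
  set.seed(2)
  x <- as.numeric(scale(rnorm(50)))
  e <- as.numeric(scale(stats::resid(lm(rnorm(50) ~ x))))
  y <- 0.5 * x + sqrt(0.75) * e # unit-variance parts, exactly orthogonal
  series <- cbind(x, y)
  expect_equal(cor(series)[2, 1], 0.5, tolerance = 1e-12)
  z <- compute_fc(series)
  expect_equal(unname(z), atanh(0.5), tolerance = 1e-12)
  expect_equal(round(unname(z), 4), 0.5493)

  # identical columns: r = 1 clipped, finite large z
  dup <- cbind(x, x)
  zdup <- compute_fc(dup)
  expect_true(is.finite(zdup))
  expect_equal(unname(zdup), atanh(1 - 1e-12))

  # zero-variance column is a named error
  expect_error(compute_fc(cbind(x, rep(1, 50))), "2")
})

test_that("FC vectorization is equivariant to ROI permutation", {
  set.seed(3)
  series <- matrix(rnorm(60 * 6), 60)
  perm <- c(3, 1, 6, 2, 5, 4)
  z1 <- compute_fc(series)
  z2 <- compute_fc(series[, perm])
  idx <- connection_index(6)
  # map each permuted connection back to the original pair
  orig_pair <- function(i, j) {
    a <- perm[i]
    b <- perm[j]
    paste(max(a, b), min(a, b))
  }
  key1 <- paste(idx$roi_i, idx$roi_j)
  key2 <- mapply(orig_pair, idx$roi_i, idx$roi_j)
  expect_equal(unname(z2), unname(z1[match(key2, key1)]))
})

test_that("Helmert basis columns are zero-sum and orthogonal", {
  h2 <- helmert_basis(2)
  expect_equal(ncol(h2), 1)
  expect_equal(unname(h2[, 1] / max(abs(h2[, 1]))), c(-1, 1))
  h5 <- helmert_basis(5)
  expect_equal(dim(h5), c(5, 4))
  expect_equal(colSums(h5), rep(0, 4), ignore_attr = TRUE)
  g <- crossprod(h5)
  expect_equal(g[upper.tri(g)], rep(0, 6))
  expect_error(helmert_basis(1))
})

test_that("residualization removes site and age effects exactly", {
  cc <- sim_fc_cohort(
    n_subjects = 40, n_rois = 10, seed = 4,
    site_offsets = c(-0.2, -0.1, 0, 0.1, 0.2), age_slope = 0.02
  )
  res <- cc$m
  site <- cc$phenotypes$site
  # per-site means of every connection agree to numerical precision
  site_means <- rowsum(res, site) / as.vector(table(site))
  expect_lt(max(apply(site_means, 2, function(x) diff(range(x)))), 1e-10)
  # residual FC is uncorrelated with age
  age_cor <- suppressWarnings(cor(cc$phenotypes$age, res))
  expect_lt(max(abs(age_cor)), 1e-10)
})

test_that("residualization retains the grand mean, is idempotent, and is
           invariant to the Helmert variant", {
  cc <- sim_fc_cohort(n_subjects = 24, n_rois = 8, seed = 5)
  fc <- cc$fc
  design <- confound_design(cc$phenotypes$age, cc$phenotypes$site)
  r1 <- residualize(fc, design)
  # intercept-only design: output equals input
  d0 <- structure(
    list(x = matrix(1, nrow(fc), 1, dimnames = list(NULL, "intercept"))),
    class = "confound_design"
  )
  expect_equal(as.matrix(residualize(fc, d0)[-1]), as.matrix(fc[-1]),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  # idempotence
  r2 <- residualize(r1, design)
  expect_equal(as.matrix(r2[-1]), as.matrix(r1[-1]), tolerance = 1e-10)
  # reversing the site level order spans the same space: identical residuals
  design_rev <- confound_design(
    cc$phenotypes$age,
    factor(cc$phenotypes$site, levels = rev(sort(unique(cc$phenotypes$site))))
  )
  r3 <- residualize(fc, design_rev)
  expect_equal(as.matrix(r3[-1]), as.matrix(r1[-1]), tolerance = 1e-10)
  # mean-zero mode removes the grand mean
  r4 <- residualize(fc, design, mode = "residual")
  expect_lt(max(abs(colMeans(as.matrix(r4[-1])))), 1e-10)
  # rank-deficient design errors
  expect_error(confound_design(rep(5, 24), cc$phenotypes$site), "rank")
})

test_that("motion screen flags planted motion-FC coupling and validates input", {
  set.seed(6)
  n <- 100
  fc <- matrix(rnorm(n * 50), n)
  motion <- tibble::tibble(
    mean_fd = runif(n, 0.02, 0.2),
    pct_fd_gt_0p2 = runif(n, 0, 20)
  )
  # plant the motion metric as an FC column
  fc[, 1] <- motion$mean_fd
  chk <- motion_association_check(fc, motion, n_perm = 100, seed = 1)
  expect_lte(chk$p, 0.01)
  expect_error(
    motion_association_check(fc, motion[, 1, drop = FALSE], n_perm = 10),
    "pct_fd"
  )
  expect_error(
    motion_association_check(fc, dplyr::mutate(motion, mean_fd = 0.1), n_perm = 10),
    "constant"
  )
  expect_error(motion_association_check(fc, motion, n_perm = 0), "n_perm")
})
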