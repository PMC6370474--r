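test_that("identical spec and seed reproduce the cohort exactly", {
  spec <- cohort_spec(n_subjects = 8, n_rois = 12, seed = 7)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$subtype_labels, b$truth$subtype_labels)
})

test_that("zero effects and zero baseline give the identity covariance", {
  spec <- cohort_spec(
    n_subjects = 3, n_rois = 10, seed = 2,
    subtype_effect = 0, dx_effect = 0, site_offsets = rep(0, 5),
    age_slope = 0, noise_sd = 0, base_z_within = 0, base_z_between = 0
  )
  truth <- make_ground_truth(spec)
  expect_equal(build_target_covariance(spec, truth, 1), diag(10))
})

test_that("subtype-2 within-network entries follow tanh of the planted z offset", {
  spec <- cohort_spec(
    n_subjects = 30, n_rois = 12, seed = 3,
    subtype_effect = 0.3, dx_effect = 0, site_offsets = rep(0, 5),
    age_slope = 0, noise_sd = 0
  )
  # two equal networks keep the planted block matrix positive definite, so
  # the PD repair is the identity and entries match the direct tanh exactly
  truth <- make_ground_truth(spec, atlas = default_atlas(c(A = 6, B = 6)))
  s1 <- which(truth$subtype_labels == 1)[1]
  s2 <- which(truth$subtype_labels == 2)[1]
  c1 <- build_target_covariance(spec, truth, s1)
  c2 <- build_target_covariance(spec, truth, s2)
  within <- truth$within_network
  v1 <- c1[lower.tri(c1)]
  v2 <- c2[lower.tri(c2)]
  # direct tanh computation, independent of the builder
  expect_equal(v1[within], rep(tanh(spec$base_z_within), sum(within)),
    tolerance = 1e-8
  )
  expect_equal(v2[within], rep(tanh(spec$base_z_within + 0.3), sum(within)),
    tolerance = 1e-8
  )
  expect_equal(v2[!within], rep(tanh(spec$base_z_between - 0.3), sum(!within)),
    tolerance = 1e-8
  )
})

test_that("target covariances are positive definite even with noise", {
  spec <- cohort_spec(n_subjects = 5, n_rois = 20, noise_sd = 0.5, seed = 4)
  truth <- make_ground_truth(spec)
  for (i in 1:5) {
    ev <- eigen(build_target_covariance(spec, truth, i),
      symmetric = TRUE, only.values = TRUE
    )$values
    expect_gt(min(ev), 0)
  }
})

test_that("long series reproduce the target correlations (Monte Carlo)", {
  spec <- cohort_spec(
    n_subjects = 1, n_rois = 10, seed = 5,
    subtype_effect = 0, dx_effect = 0, site_offsets = rep(0, 5),
    age_slope = 0, noise_sd = 0
  )
  truth <- make_ground_truth(spec)
  target <- build_target_covariance(spec, truth, 1)
  set.seed(99)
  ts1 <- matrix(rnorm(10000 * 10), 10000) %*% chol(target)
  expect_lt(max(abs(cor(ts1) - target)), 0.05)
})

test_that("an empty cohort is valid", {
  spec <- cohort_spec(n_subjects = 0, n_rois = 10, seed = 1)
  co <- simulate_cohort(spec)
  expect_length(co$timeseries, 0)
  expect_equal(nrow(co$phenotypes), 0)
  d <- withr::local_tempdir()
  expect_no_error(write_cohort(co, d))
})

test_that("behavior coupling follows the loading and is reproducible", {
  # loading 0: behaviors decoupled from the latent brain score
  spec0 <- cohort_spec(
    n_subjects = 500, n_rois = 10, seed = 6,
    behavior_loading = 0
  )
  truth0 <- make_ground_truth(spec0)
  beh0 <- simulate_behaviors(truth0, spec0)
  latent <- fcsubtype:::latent_brain_scores(spec0, truth0)
  for (v in names(beh0)) {
    expect_lt(abs(cor(beh0[[v]], latent)), 0.1)
  }
  # noiseless limit: columns exactly proportional to latent * weight
  spec1 <- cohort_spec(
    n_subjects = 20, n_rois = 10, seed = 6,
    behavior_loading = 1, noise_sd = 0
  )
  truth1 <- make_ground_truth(spec1)
  beh1 <- simulate_behaviors(truth1, spec1)
  latent1 <- fcsubtype:::latent_brain_scores(spec1, truth1)
  w <- truth1$planted_behavior_salience
  # after the affine map to clinical units, correlation with latent*weight
  # is exactly +/-1 (up to the 2-decimal rounding of the printed scores)
  expect_gt(abs(cor(beh1$srs, latent1 * w["srs"])), 0.9999)
  expect_gt(abs(cor(beh1$iq, latent1 * w["iq"])), 0.9999)
  # determinism
  expect_identical(beh1, simulate_behaviors(truth1, spec1))
  # optional missingness masks the ADOS columns only
  behm <- simulate_behaviors(truth1, spec1, missing_fraction = 0.5)
  expect_true(anyNA(behm$ados_comm))
  expect_false(anyNA(behm$iq))
})

test_that("cohorts round-trip through disk", {
  spec <- cohort_spec(n_subjects = 4, n_rois = 8, seed = 11)
  co <- simulate_cohort(spec)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(length(back$timeseries), 4)
  expect_equal(unname(dim(back$timeseries[[1]])), dim(co$timeseries[[1]]))
  expect_equal(
    unname(as.matrix(back$timeseries[[2]])),
    unname(co$timeseries[[2]]),
    tolerance = 1e-12
  )
  expect_equal(back$phenotypes$dx, co$phenotypes$dx)
  expect_equal(as.character(back$atlas$network), as.character(co$atlas$network))
})
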