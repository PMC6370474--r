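# Shared fixture builders. Everything is generated in code at fixed seeds;
# sizes are kept small so the default run stays fast.

# Simulate a cohort and return its residualized FC matrix plus components.
sim_fc_cohort <- function(n_subjects = 40, n_rois = 20, seed = 1, ...) {
  spec <- cohort_spec(n_subjects = n_subjects, n_rois = n_rois, seed = seed, ...)
  co <- simulate_cohort(spec)
  fc <- cohort_fc(co$timeseries)
  design <- confound_design(co$phenotypes$age, co$phenotypes$site)
  list(
    spec = spec, cohort = co, fc = fc,
    fc_res = residualize(fc, design),
    m = as.matrix(residualize(fc, design)[-1]),
    truth = co$truth, phenotypes = co$phenotypes, atlas = co$atlas
  )
}

# Plain iid-normal FC matrix (no structure at all).
null_fc <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n)
}

# Adjusted Rand index between two labelings (mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Exhaustive best 2-partition by mean cosine distance (oracle for k-means).
# Centroids are arithmetic means of raw rows, as in the implementation's
# update rule; all 2^(n-1)-1 bipartitions are scanned.
brute_force_k2 <- function(m) {
  n <- nrow(m)
  cosdist <- function(x, c) 1 - sum(x * c) / sqrt(sum(x^2) * sum(c^2))
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    lab <- c(1L, as.integer(intToBits(code)[1:(n - 1)]) + 1L)
    if (length(unique(lab)) < 2) next
    c1 <- colMeans(m[lab == 1, , drop = FALSE])
    c2 <- colMeans(m[lab == 2, , drop = FALSE])
    d <- mean(vapply(seq_len(n), function(i) {
      cosdist(m[i, ], if (lab[i] == 1) c1 else c2)
    }, numeric(1)))
    if (d < best) best <- d
  }
  best
}
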