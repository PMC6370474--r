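# The standard validation cohort (full 160-ROI scale, n = 200, subtype
# effect 0.3 z, noise 0.2 z) is expensive enough to build once and share
# across the acceptance checks.
std_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(seed = 101)
      co <- simulate_cohort(spec)
      fc <- cohort_fc(co$timeseries)
      design <- confound_design(co$phenotypes$age, co$phenotypes$site)
      fc_res <- residualize(fc, design)
      cache <<- list(
        spec = spec, cohort = co, truth = co$truth,
        phenotypes = co$phenotypes, atlas = co$atlas,
        m = as.matrix(fc_res[-1])
      )
    }
    cache
  }
})
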