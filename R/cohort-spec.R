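#' Specification of a synthetic multi-site cohort
#'
#' Bundles every parameter of the synthetic cohort generator. The generator
#' plants, in Fisher-z space: (a) per-site additive FC offsets, (b) a linear
#' age effect on every connection, (c) two FC subtypes that differ in
#' within- versus between-network connectivity, (d) an additive diagnosis
#' effect on a fixed random subset of connections (no subtype-by-diagnosis
#' interaction), and (e) behavioral scores coupled to each subject's
#' expression of the planted subtype pattern. Defaults define the package's
#' standard validation cohort: 200 subjects, 5 sites, a 0.3 z-unit subtype
#' effect and 0.2 z-units of residual connection noise.
#'
#' @param n_subjects Number of subjects.
#' @param n_rois Number of ROIs (default 160).
#' @param n_timepoints Maximum time-series length; per-subject lengths vary
#'   uniformly in `[145, n_timepoints]` so truncation to a common length is
#'   exercised. Must be at least 145.
#' @param n_sites Number of acquisition sites.
#' @param subtype_fraction Fraction of subjects in subtype 2.
#' @param asd_fraction Fraction of subjects with an ASD diagnosis (default
#'   145/266, the case fraction of the cohort the generator emulates).
#' @param subtype_effect z-units added to within-network connections and
#'   subtracted from between-network connections for subtype-2 subjects.
#' @param dx_effect z-units added, for ASD subjects, to a fixed random 10%
#'   subset of connections drawn once per cohort.
#' @param site_offsets Numeric vector (length `n_sites`) of additive z-space
#'   FC shifts applied uniformly to all connections of a site's subjects.
#' @param age_slope z-units of FC change per year of age, applied uniformly.
#' @param behavior_loading Coupling strength between the latent brain score
#'   (projection of a subject's planted z-deviation on the subtype salience)
#'   and the behavior battery; 0 decouples behavior from FC.
#' @param noise_sd SD of iid Gaussian z-noise added per subject and
#'   connection before mapping to correlation space.
#' @param base_z_within,base_z_between Baseline Fisher-z connectivity of
#'   within- and between-network connections.
#' @param seed RNG seed; identical spec + seed reproduces the cohort exactly.
#' @return An object of class `cohort_spec` (a validated list).
#' @examples
#' spec <- cohort_spec(n_subjects = 20, seed = 1)
#' spec$subtype_effect
#' @export
cohort_spec <- function(n_subjects = 200,
                        n_rois = 160,
                        n_timepoints = 180,
                        n_sites = 5,
                        subtype_fraction = 0.5,
                        asd_fraction = 145 / 266,
                        subtype_effect = 0.3,
                        dx_effect = 0.2,
                        site_offsets = seq(-0.06, 0.06, length.out = n_sites),
                        age_slope = 0.005,
                        behavior_loading = 1,
                        noise_sd = 0.2,
                        base_z_within = 0.35,
                        base_z_between = 0.08,
                        seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 0)
  n_rois <- check_count(n_rois, "n_rois", min = 2)
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 145)
  n_sites <- check_count(n_sites, "n_sites", min = 1)
  check_fraction(subtype_fraction, "subtype_fraction")
  check_fraction(asd_fraction, "asd_fraction")
  if (length(site_offsets) != n_sites) {
    abort("`site_offsets` must have one entry per site")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  structure(
    list(
      n_subjects = n_subjects, n_rois = n_rois,
      n_timepoints = n_timepoints, n_sites = n_sites,
      subtype_fraction = subtype_fraction, asd_fraction = asd_fraction,
      subtype_effect = subtype_effect, dx_effect = dx_effect,
      site_offsets = as.numeric(site_offsets), age_slope = age_slope,
      behavior_loading = behavior_loading, noise_sd = noise_sd,
      base_z_within = base_z_within, base_z_between = base_z_between,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf(
    "  %d subjects, %d ROIs, %d sites, T in [145, %d]\n",
    x$n_subjects, x$n_rois, x$n_sites, x$n_timepoints
  ))
  cat(sprintf(
    "  subtype effect %.3g z, dx effect %.3g z, noise sd %.3g z, seed %d\n",
    x$subtype_effect, x$dx_effect, x$noise_sd, x$seed
  ))
  invisible(x)
}
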