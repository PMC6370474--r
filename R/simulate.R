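#' Ground truth of a synthetic cohort
#'
#' Draws the planted per-subject labels and the planted spatial patterns for
#' a cohort specification. Everything downstream of the generator can be
#' scored against this object: subtype recovery against `subtype_labels`,
#' recovered PLS brain saliences against the unit-norm planted salience
#' vectors, behavior saliences against `planted_behavior_salience`.
#'
#' @param spec A [cohort_spec()].
#' @param atlas Atlas partition tibble; defaults to [default_atlas()] resized
#'   to `spec$n_rois` only when `n_rois` is 160, otherwise a single-network
#'   stand-in must be supplied.
#' @return An object of class `cohort_truth`: a list with per-subject
#'   `subtype_labels` (1/2), `dx_labels` ("ASD"/"TD"), `site_assignment`,
#'   `age`, the planted unit-norm salience vectors, the fixed diagnosis
#'   connection subset, and per-behavior weights.
#' @examples
#' truth <- make_ground_truth(cohort_spec(n_subjects = 10, seed = 3))
#' table(truth$subtype_labels)
#' @export
make_ground_truth <- function(spec, atlas = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  atlas <- atlas %||% default_atlas_for(spec$n_rois)
  validate_atlas(atlas, spec$n_rois)
  n <- spec$n_subjects
  p <- n_connections(spec$n_rois)

  cn <- connection_networks(atlas)
  within <- cn$net_a == cn$net_b
  sign_vec <- ifelse(within, 1, -1)
  subtype_sal <- sign_vec / sqrt(sum(sign_vec^2))

  dx_conn <- with_seed(derive_seed(spec$seed, "dx_connections"), {
    sort(sample.int(p, size = max(1L, round(0.10 * p))))
  })
  dx_sal <- numeric(p)
  dx_sal[dx_conn] <- 1 / sqrt(length(dx_conn))

  beh_w <- c(
    iq = -0.5, ados_comm = 0.45, ados_social = 0.5,
    ados_rrb = 0.4, srs = 0.55
  )
  beh_sal <- beh_w / sqrt(sum(beh_w^2))

  n2 <- round(n * spec$subtype_fraction)
  n_asd <- round(n * spec$asd_fraction)
  labels <- with_seed(derive_seed(spec$seed, "labels"), {
    subtype <- rep(1L, n)
    if (n > 0) subtype[sample.int(n, n2)] <- 2L
    dx <- rep("TD", n)
    if (n > 0) dx[sample.int(n, n_asd)] <- "ASD"
    site <- if (n > 0) sample(rep_len(seq_len(spec$n_sites), n)) else integer()
    age <- round(runif(n, 8, 35), 2)
    list(subtype = subtype, dx = dx, site = site, age = age)
  })

  structure(
    list(
      n_subjects = n, n_rois = spec$n_rois,
      subtype_labels = labels$subtype,
      dx_labels = labels$dx,
      site_assignment = labels$site,
      age = labels$age,
      planted_subtype_salience = subtype_sal,
      planted_dx_salience = dx_sal,
      planted_behavior_salience = beh_sal,
      dx_connections = dx_conn,
      within_network = within
    ),
    class = "cohort_truth"
  )
}

default_atlas_for <- function(n_rois) {
  if (n_rois == 160) {
    return(default_atlas())
  }
  # proportionally shrunk six-network partition for reduced-size cohorts
  base <- c(DMN = 34, FPN = 21, CON = 32, ON = 22, SMN = 33, CN = 18)
  sizes <- round(base * n_rois / 160)
  sizes[sizes < 1] <- 1
  while (sum(sizes) != n_rois) {
    i <- which.max(sizes)
    sizes[i] <- sizes[i] + sign(n_rois - sum(sizes))
  }
  default_atlas(sizes)
}

# Planted Fisher-z connectivity vector (lower triangle) for one subject:
# base block structure + subtype, diagnosis, site and age contributions plus
# subject-specific z-noise. Deterministic in (spec, subject_index).
subject_z_vector <- function(spec, truth, subject_index) {
  p <- n_connections(spec$n_rois)
  z <- ifelse(truth$within_network, spec$base_z_within, spec$base_z_between)
  if (truth$subtype_labels[subject_index] == 2L) {
    z <- z + spec$subtype_effect * ifelse(truth$within_network, 1, -1)
  }
  if (truth$dx_labels[subject_index] == "ASD") {
    z[truth$dx_connections] <- z[truth$dx_connections] + spec$dx_effect
  }
  z <- z + spec$site_offsets[truth$site_assignment[subject_index]]
  z <- z + spec$age_slope * (truth$age[subject_index] - 21.5)
  if (spec$noise_sd > 0) {
    z <- z + with_seed(
      derive_seed(spec$seed, paste0("znoise_", subject_index)),
      rnorm(p, 0, spec$noise_sd)
    )
  }
  z
}

#' Target ROI covariance matrix for one synthetic subject
#'
#' Assembles the subject's planted Fisher-z connectivity (base network-block
#' structure plus subtype, diagnosis, site and age contributions and
#' subject z-noise), maps it to correlation space through `tanh`, and repairs
#' the result to the nearest positive-definite matrix by clipping eigenvalues
#' at `1e-6` and re-symmetrizing.
#'
#' @inheritParams make_ground_truth
#' @param truth A [make_ground_truth()] object for the same spec.
#' @param subject_index Subject position in 1..n_subjects.
#' @return A symmetric positive-definite `n_rois` x `n_rois` matrix.
#' @examples
#' spec <- cohort_spec(n_subjects = 4, n_rois = 20, seed = 1)
#' sigma <- build_target_covariance(spec, make_ground_truth(spec), 1)
#' min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) > 0
#' @export
build_target_covariance <- function(spec, truth, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "cohort_truth"))
  subject_index <- check_count(subject_index, "subject_index")
  if (subject_index > spec$n_subjects) {
    abort(sprintf("subject_index %d exceeds n_subjects", subject_index))
  }
  z <- subject_z_vector(spec, truth, subject_index)
  r <- tanh(z)
  m <- matrix(0, spec$n_rois, spec$n_rois)
  m[lower.tri(m)] <- r
  m <- m + t(m)
  diag(m) <- 1
  repair_pd(m, subject_index)
}

# Eigenvalue clip at 1e-6 + re-symmetrization; hard error if the repaired
# matrix still fails a Cholesky factorization.
repair_pd <- function(m, subject_index) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < 1e-6) {
    v <- pmax(e$values, 1e-6)
    m <- e$vectors %*% (v * t(e$vectors))
    m <- (m + t(m)) / 2
  }
  ok <- tryCatch(
    {
      chol(m)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) {
    abort(sprintf(
      "covariance for subject %d not positive definite after repair",
      subject_index
    ))
  }
  m
}

#' Simulate a synthetic multi-site cohort
#'
#' Draws per-subject ROI time series from zero-mean multivariate normals with
#' subject-specific target covariances (see [build_target_covariance()]),
#' together with a phenotype table and behavior battery. Per-subject series
#' lengths vary uniformly in `[145, n_timepoints]` so that truncation to a
#' common length is a meaningful downstream step. Identical `(spec, seed)`
#' reproduce the cohort exactly.
#'
#' @inheritParams make_ground_truth
#' @return An object of class `fc_cohort`: a list with `timeseries` (list of
#'   T_i x n_rois matrices), `phenotypes` (tibble, one row per subject, with
#'   behavior columns), `truth` ([make_ground_truth()]), `atlas`, `spec`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_subjects = 6, n_rois = 20, seed = 2))
#' sapply(cohort$timeseries, nrow)
#' @export
simulate_cohort <- function(spec, atlas = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  atlas <- atlas %||% default_atlas_for(spec$n_rois)
  truth <- make_ground_truth(spec, atlas)
  n <- spec$n_subjects

  lengths <- with_seed(
    derive_seed(spec$seed, "series_lengths"),
    if (n > 0) {
      144L + sample.int(spec$n_timepoints - 144L, n, replace = TRUE)
    } else {
      integer()
    }
  )

  series <- vector("list", n)
  for (i in seq_len(n)) {
    sigma <- build_target_covariance(spec, truth, i)
    cl <- chol(sigma)
    series[[i]] <- with_seed(derive_seed(spec$seed, paste0("series_", i)), {
      matrix(rnorm(lengths[i] * spec$n_rois), lengths[i]) %*% cl
    })
  }
  ids <- sprintf("S%04d", seq_len(n))
  names(series) <- ids

  behaviors <- simulate_behaviors(truth, spec)

  pheno <- with_seed(derive_seed(spec$seed, "phenotypes"), {
    mean_fd <- pmin(pmax(round(rnorm(n, 0.07, 0.035), 3), 0.02), 0.19)
    tibble::tibble(
      subject_id = ids,
      dx = truth$dx_labels,
      site = sprintf("site%d", truth$site_assignment),
      age = truth$age,
      mean_fd = mean_fd,
      pct_fd_gt_0p2 = round(pmin(
        pmax(mean_fd * 50 + rnorm(n, 0, 2), 0), 19.3
      ), 2),
      eye_status = sample(c("open", "closed"), n, TRUE, c(0.8, 0.2)),
      handedness = sample(c("R", "L"), n, TRUE, c(0.88, 0.12)),
      n_timepoints = lengths
    )
  })
  pheno <- dplyr::bind_cols(pheno, behaviors)

  structure(
    list(
      timeseries = series, phenotypes = pheno,
      truth = truth, atlas = atlas, spec = spec
    ),
    class = "fc_cohort"
  )
}

#' Simulate the behavior battery for a cohort
#'
#' Five behavior columns (IQ, ADOS communication, ADOS social affect, ADOS
#' RRB, SRS) are generated as
#' `loading * latent_i * weight_j + N(0, 5 * noise_sd)` on a standardized
#' scale and then mapped to realistic clinical units (unit-SD noise at the
#' default `noise_sd` of 0.2; the noiseless limit is exact). The latent
#' score `latent_i` is the subject's planted z-deviation projected on the
#' planted subtype salience, standardized across the cohort, so a positive
#' `behavior_loading` couples the battery to the planted FC pattern.
#'
#' @param truth A [make_ground_truth()] object.
#' @param spec The matching [cohort_spec()].
#' @param missing_fraction Fraction of subjects whose ADOS columns are set to
#'   `NA`, mimicking partial instrument availability. Default 0.
#' @return A tibble with columns `iq`, `ados_comm`, `ados_social`,
#'   `ados_rrb`, `srs`.
#' @export
simulate_behaviors <- function(truth, spec, missing_fraction = 0) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "cohort_truth"))
  n <- spec$n_subjects
  if (n == 0) {
    return(tibble::tibble(
      iq = numeric(), ados_comm = numeric(), ados_social = numeric(),
      ados_rrb = numeric(), srs = numeric()
    ))
  }
  latent <- latent_brain_scores(spec, truth)
  w <- truth$planted_behavior_salience
  scales <- list(
    iq = c(108, 14), ados_comm = c(3, 1.6), ados_social = c(5, 3),
    ados_rrb = c(1.6, 1.4), srs = c(55, 35)
  )
  noise <- with_seed(
    derive_seed(spec$seed, "behavior_noise"),
    matrix(rnorm(n * length(w), sd = 5 * spec$noise_sd), n)
  )
  std <- outer(spec$behavior_loading * latent, w) + noise
  out <- purrr::imap(scales, function(ms, nm) {
    round(ms[1] + ms[2] * std[, match(nm, names(w))], 2)
  })
  out <- tibble::as_tibble(out)
  if (missing_fraction > 0) {
    miss <- with_seed(
      derive_seed(spec$seed, "behavior_missing"),
      runif(n) < missing_fraction
    )
    out$ados_comm[miss] <- NA_real_
    out$ados_social[miss] <- NA_real_
    out$ados_rrb[miss] <- NA_real_
  }
  out
}

# Projection of each subject's planted z-deviation (from the cohort base) on
# the planted subtype salience, standardized across the cohort.
latent_brain_scores <- function(spec, truth) {
  base <- ifelse(truth$within_network, spec$base_z_within, spec$base_z_between)
  sal <- truth$planted_subtype_salience
  latent <- vapply(seq_len(spec$n_subjects), function(i) {
    sum((subject_z_vector(spec, truth, i) - base) * sal)
  }, numeric(1))
  if (length(latent) > 1 && sd(latent) > 0) {
    latent <- (latent - mean(latent)) / sd(latent)
  }
  latent
}

#' Write a synthetic cohort to disk
#'
#' Writes one headerless TSV time-series file per subject, a phenotype
#' manifest CSV (with a `timeseries_path` column), the atlas partition TSV,
#' and the ground truth as JSON.
#'
#' @param cohort An [simulate_cohort()] object.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fc_cohort"))
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(cohort$timeseries))
  for (i in seq_along(cohort$timeseries)) {
    paths[i] <- file.path("timeseries", paste0(names(cohort$timeseries)[i], ".tsv"))
    utils::write.table(cohort$timeseries[[i]], file.path(dir, paths[i]),
      sep = "\t", row.names = FALSE, col.names = FALSE
    )
  }
  pheno <- cohort$phenotypes
  pheno$timeseries_path <- paths
  readr::write_csv(pheno, file.path(dir, "phenotypes.csv"))
  readr::write_tsv(cohort$atlas, file.path(dir, "atlas.tsv"))
  truth <- cohort$truth
  truth$within_network <- NULL
  jsonlite::write_json(unclass(truth), file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `phenotypes.csv`, `atlas.tsv` and the
#'   per-subject time-series TSVs.
#' @return A list with `timeseries`, `phenotypes` and `atlas` (no ground
#'   truth: the reader treats the cohort as observed data).
#' @export
read_cohort <- function(dir) {
  pheno <- readr::read_csv(file.path(dir, "phenotypes.csv"),
    show_col_types = FALSE
  )
  atlas <- readr::read_tsv(file.path(dir, "atlas.tsv"), show_col_types = FALSE)
  atlas$network <- factor(atlas$network, levels = unique(atlas$network))
  series <- lapply(pheno$timeseries_path, function(p) {
    as.matrix(readr::read_tsv(file.path(dir, p),
      col_names = FALSE,
      show_col_types = FALSE
    ))
  })
  names(series) <- pheno$subject_id
  list(timeseries = series, phenotypes = pheno, atlas = atlas)
}
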