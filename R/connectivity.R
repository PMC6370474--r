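#' Truncate a set of ROI time series to a common length
#'
#' Resting-state scans differ in length across subjects and sites; all
#' downstream correlation estimates use the same number of timepoints, taken
#' from the start of each series. The default target is the minimum length
#' across the cohort (145 for the reference cohort).
#'
#' @param series_set Named list of T_i x R numeric matrices.
#' @param target_length Common length; defaults to the cohort minimum.
#' @return A list of matrices, each with exactly `target_length` rows.
#' @examples
#' s <- list(a = matrix(rnorm(300), 150), b = matrix(rnorm(290), 145))
#' sapply(truncate_to_common_length(s), nrow)
#' @export
truncate_to_common_length <- function(series_set, target_length = NULL) {
  stopifnot(is.list(series_set))
  lens <- vapply(series_set, nrow, integer(1))
  target_length <- target_length %||% min(lens)
  target_length <- check_count(target_length, "target_length", min = 2)
  short <- lens < target_length
  if (any(short)) {
    abort(sprintf(
      "series shorter than target length %d: %s",
      target_length,
      paste(names(series_set)[short] %||% which(short), collapse = ", ")
    ))
  }
  lapply(series_set, function(m) m[seq_len(target_length), , drop = FALSE])
}

#' Fisher-z functional connectivity vector of one subject
#'
#' Pearson correlation of every ROI pair across timepoints, Fisher
#' z-transformed (`atanh`), vectorized in the fixed lower-triangle order of
#' [connection_index()]. Correlations are clipped to `±(1 - 1e-12)` before
#' the transform so perfectly correlated pairs stay finite.
#'
#' @param series A T x R numeric matrix (timepoints by ROIs).
#' @return Numeric vector of length `R(R-1)/2` (12,720 for R = 160), named by
#'   connection label.
#' @examples
#' z <- compute_fc(matrix(rnorm(500), 100))
#' length(z) # choose(5, 2)
#' @export
compute_fc <- function(series) {
  series <- as.matrix(series)
  if (nrow(series) < 2) abort("need at least 2 timepoints")
  v <- apply(series, 2, sd)
  if (any(v == 0)) {
    abort(sprintf(
      "zero-variance ROI column(s): %s",
      paste(which(v == 0), collapse = ", ")
    ))
  }
  r <- cor(series)
  r <- pmin(pmax(r[lower.tri(r)], -(1 - 1e-12)), 1 - 1e-12)
  z <- atanh(r)
  names(z) <- connection_index(ncol(series))$label
  z
}

#' Cohort FC table
#'
#' Applies [truncate_to_common_length()] and [compute_fc()] to every subject
#' and stacks the results.
#'
#' @inheritParams truncate_to_common_length
#' @return A tibble with `subject_id` plus one column per connection.
#' @export
cohort_fc <- function(series_set, target_length = NULL) {
  series_set <- truncate_to_common_length(series_set, target_length)
  m <- t(vapply(
    series_set, compute_fc,
    numeric(n_connections(ncol(series_set[[1]])))
  ))
  tibble::as_tibble(m) |>
    dplyr::mutate(
      subject_id = names(series_set) %||% sprintf("S%04d", seq_len(nrow(m))),
      .before = 1
    )
}

#' Helmert contrast basis for a categorical factor
#'
#' Column j contrasts level j+1 against the mean of levels 1..j. Columns sum
#' to zero and are mutually orthogonal; together with an intercept they span
#' the same space as the level indicators, which is what confound regression
#' relies on (residuals are invariant to the Helmert variant chosen).
#'
#' @param n_levels Number of factor levels (>= 2).
#' @return An `n_levels` x `n_levels - 1` matrix.
#' @examples
#' helmert_basis(3)
#' @export
helmert_basis <- function(n_levels) {
  n_levels <- check_count(n_levels, "n_levels", min = 2)
  stats::contr.helmert(n_levels)
}

#' Confound design matrix for age and acquisition site
#'
#' Builds the `[intercept, centered age, Helmert site columns]` design used
#' by [residualize()].
#'
#' @param age Numeric vector of ages (years).
#' @param site Per-subject site labels (factor or character).
#' @return A list of class `confound_design` with the design matrix `x`
#'   (first column the intercept), `age`, and `site`.
#' @export
confound_design <- function(age, site) {
  if (length(age) != length(site)) abort("age and site lengths differ")
  site <- factor(site)
  x <- cbind(intercept = 1, age = age - mean(age))
  if (nlevels(site) > 1) {
    h <- helmert_basis(nlevels(site))[as.integer(site), , drop = FALSE]
    colnames(h) <- paste0("site_h", seq_len(ncol(h)))
    x <- cbind(x, h)
  }
  if (qr(x)$rank < ncol(x)) {
    abort("confound design is rank deficient (collinear age/site columns)")
  }
  structure(list(x = x, age = age, site = site), class = "confound_design")
}

#' Regress age and site out of a cohort FC table
#'
#' Per connection, ordinary least squares of the Fisher-z values on the
#' intercept, centered age and the Helmert site basis. By default the
#' returned values are the OLS residuals plus the intercept estimate:
#' covariate contributions are removed but the grand mean of each connection
#' is retained (cosine-distance clustering and the contrast expressions are
#' sign-sensitive, so mean structure must survive). `mode = "residual"`
#' returns mean-zero raw residuals instead.
#'
#' @param fc A subjects x connections data frame (with optional
#'   `subject_id`) or matrix.
#' @param design A [confound_design()] whose rows align with `fc`.
#' @param mode `"keep_mean"` (default) or `"residual"`.
#' @return A tibble of the same shape as `fc` (with `subject_id` if present).
#' @export
residualize <- function(fc, design, mode = c("keep_mean", "residual")) {
  mode <- match.arg(mode)
  m <- as_fc_matrix(fc)
  stopifnot(inherits(design, "confound_design"))
  x <- design$x
  if (nrow(x) != nrow(m)) abort("design rows do not match FC rows")
  qr_x <- qr(x)
  beta <- qr.coef(qr_x, m)
  res <- m - x %*% beta
  if (mode == "keep_mean") res <- res + rep(beta[1, ], each = nrow(m))
  if (is.null(colnames(res))) colnames(res) <- paste0("c", seq_len(ncol(res)))
  out <- tibble::as_tibble(res)
  if (is.data.frame(fc) && "subject_id" %in% names(fc)) {
    out <- dplyr::mutate(out, subject_id = fc$subject_id, .before = 1)
  }
  out
}

#' Screen residualized FC for residual head-motion association
#'
#' Runs a single-group behavior PLS of the FC table against the two motion
#' summaries (mean framewise displacement and percentage of frames above
#' 0.2 mm) and returns the permutation p of the first pattern. A
#' non-significant p indicates no detectable multivariate FC-motion
#' relationship; the check is report-only and never modifies the data.
#'
#' @inheritParams residualize
#' @param motion A data frame with columns `mean_fd` and `pct_fd_gt_0p2`
#'   aligned with the FC rows.
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed for the permutation test.
#' @return A list with `p` (first-pattern permutation p), `r` the pattern
#'   singular value, and the full `pls` fit.
#' @export
motion_association_check <- function(fc, motion, n_perm = 1000, seed = 1) {
  n_perm <- check_count(n_perm, "n_perm")
  if (!all(c("mean_fd", "pct_fd_gt_0p2") %in% names(motion))) {
    abort("motion table needs columns mean_fd and pct_fd_gt_0p2")
  }
  mm <- as.matrix(motion[, c("mean_fd", "pct_fd_gt_0p2")])
  if (any(apply(mm, 2, sd) == 0)) abort("constant motion column")
  m <- as_fc_matrix(fc)
  fit <- behavior_pls(m, mm, groups = rep("all", nrow(m)))
  fit <- pls_permutation(fit, n_perm = n_perm, seed = seed)
  list(p = fit$patterns$perm_p[1], singular_value = fit$patterns$singular_value[1], pls = fit)
}
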