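#' K-means clustering with the cosine distance
#'
#' Lloyd iterations on subjects x connections FC vectors: each subject is
#' assigned to the nearest centroid under the cosine distance (one minus the
#' cosine of the included angle), and centroids are updated as the
#' arithmetic mean of their assigned rows, until assignments no longer
#' change. Initial centroids are `k` distinct random subjects; the best of
#' `n_restarts` runs by mean cosine distance is returned. An empty cluster
#' is reseeded with the point farthest (cosine) from its current centroid.
#'
#' @param fc Subjects x connections matrix or data frame (optional
#'   `subject_id` column).
#' @param k Number of clusters.
#' @param seed RNG seed (controls initialization only).
#' @param n_restarts Number of random restarts (default 20).
#' @param max_iter Iteration cap per run (default 300, with a warning when
#'   hit).
#' @return An object of class `cosine_kmeans`: list with `k`, `centroids`
#'   (k x p), `assignments` (integer per subject), `mean_distance`, `n_iter`,
#'   `seed`, `subject_id`.
#' @examples
#' x <- rbind(
#'   matrix(rnorm(50, 5), 5),
#'   matrix(rnorm(50, -5), 5)
#' )
#' fit <- cosine_kmeans(x, k = 2, seed = 1)
#' fit$assignments
#' @export
cosine_kmeans <- function(fc, k, seed = 1, n_restarts = 20, max_iter = 300) {
  m <- as_fc_matrix(fc)
  k <- check_count(k, "k")
  n_restarts <- check_count(n_restarts, "n_restarts")
  n <- nrow(m)
  if (n < k) abort("fewer subjects than clusters")
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) {
    abort(sprintf(
      "all-zero FC vector (cosine undefined) for subject(s): %s",
      paste(which(norms == 0), collapse = ", ")
    ))
  }
  xh <- m / norms # unit rows: cosine similarity is a plain inner product
  fit <- cosine_kmeans_impl(m, xh, k, seed, n_restarts, max_iter)
  fit$subject_id <- rownames(m) %||%
    (if (is.data.frame(fc) && "subject_id" %in% names(fc)) {
      as.character(fc$subject_id)
    } else {
      sprintf("S%04d", seq_len(n))
    })
  fit
}

# Core restart loop on pre-validated, pre-normalized data.
cosine_kmeans_impl <- function(m, xh, k, seed, n_restarts, max_iter = 300) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- with_seed(
      derive_seed(seed, paste0("km_init_", r)),
      sample.int(nrow(m), k)
    )
    run <- lloyd_cosine(m, xh, m[init, , drop = FALSE], max_iter)
    if (is.null(best) || run$mean_distance < best$mean_distance) best <- run
  }
  structure(
    list(
      k = k, centroids = best$centroids, assignments = best$assignments,
      mean_distance = best$mean_distance, n_iter = best$n_iter, seed = seed
    ),
    class = "cosine_kmeans"
  )
}

lloyd_cosine <- function(m, xh, centroids, max_iter) {
  n <- nrow(m)
  assign_prev <- rep(0L, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cn <- sqrt(rowSums(centroids^2))
    cn[cn == 0] <- 1
    sim <- xh %*% t(centroids / cn) # n x k cosine similarities
    assign_new <- max.col(sim, ties.method = "first")
    # reseed empty clusters with the point farthest from its own centroid
    for (cl in seq_len(nrow(centroids))) {
      if (!any(assign_new == cl)) {
        d_own <- 1 - sim[cbind(seq_len(n), assign_new)]
        far <- which.max(d_own)
        assign_new[far] <- cl
        sim[far, ] <- -Inf
        sim[far, cl] <- Inf
      }
    }
    if (all(assign_new == assign_prev)) break
    assign_prev <- assign_new
    centroids <- rowsum(m, assign_new) /
      as.vector(table(factor(assign_new, levels = seq_len(nrow(centroids)))))
    if (iter >= max_iter) {
      warn(sprintf("cosine k-means hit the %d-iteration cap", max_iter))
      break
    }
  }
  cn <- sqrt(rowSums(centroids^2))
  cn[cn == 0] <- 1
  sim <- xh %*% t(centroids / cn)
  d <- 1 - sim[cbind(seq_len(n), assign_prev)]
  list(
    centroids = centroids, assignments = assign_prev,
    mean_distance = mean(d), n_iter = iter
  )
}

#' Mean cosine distance as a function of k (elbow curve)
#'
#' Runs [cosine_kmeans()] for k = 1..`k_max` and records the mean cosine
#' distance of subjects to their assigned centroid. k = 1 is included as the
#' reference point for the elbow criterion.
#'
#' @inheritParams cosine_kmeans
#' @param k_max Largest k (default 8).
#' @return An object of class `elbow_curve`: tibble with columns `k`,
#'   `mean_distance`, `slope_change` (second difference, defined for
#'   2 <= k <= k_max - 1), plus attribute `models` (the fitted models).
#' @export
elbow_curve <- function(fc, k_max = 8, seed = 1, n_restarts = 20) {
  k_max <- check_count(k_max, "k_max", min = 3)
  m <- as_fc_matrix(fc)
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) abort("all-zero FC vector (cosine undefined)")
  xh <- m / norms
  models <- lapply(seq_len(k_max), function(k) {
    cosine_kmeans_impl(m, xh, k,
      seed = derive_seed(seed, paste0("elbow_k", k)),
      n_restarts = if (k == 1) 1 else n_restarts
    )
  })
  d <- vapply(models, `[[`, numeric(1), "mean_distance")
  out <- tibble::tibble(
    k = seq_len(k_max),
    mean_distance = d,
    slope_change = c(NA_real_, diff(diff(d)), NA_real_)
  )
  structure(out, models = models, class = c("elbow_curve", class(out)))
}

#' Elbow criterion for the number of clusters
#'
#' The elbow is the k where the rate of decrease in mean cosine distance
#' changes most sharply: `slope_change(k) = (D(k-1) - D(k)) - (D(k) - D(k+1))`
#' maximized over 2 <= k <= k_max - 1, ties broken toward smaller k.
#'
#' @param curve An [elbow_curve()] or a data frame with columns `k` and
#'   `mean_distance` for k = 1..k_max (k_max >= 3).
#' @return The chosen k (integer).
#' @examples
#' d <- tibble::tibble(k = 1:8, mean_distance = c(10, 4, 3.5, 3.2, 3, 2.9, 2.85, 2.8))
#' elbow_select(d) # 2
#' @export
elbow_select <- function(curve) {
  if (!all(c("k", "mean_distance") %in% names(curve))) {
    abort("curve needs columns k and mean_distance")
  }
  curve <- curve[order(curve$k), ]
  if (nrow(curve) < 3) abort("need distances for at least 3 values of k")
  d <- curve$mean_distance
  sc <- diff(diff(d)) # (D(k-1)-D(k)) - (D(k)-D(k+1)) for interior k
  curve$k[1 + which.max(sc)] # which.max breaks ties toward smaller k
}

#' Reliability of the chosen number of clusters by half-sample resampling
#'
#' Draws `n_resamples` random half samples (a `fraction` of subjects,
#' without replacement), reruns the elbow procedure (k = 1..`k_max`) on
#' each, and accumulates the histogram of chosen k plus per-k 95% intervals
#' of the slope-change statistic across resamples.
#'
#' @inheritParams elbow_curve
#' @param n_resamples Number of resamples (default 500).
#' @param fraction Fraction of subjects per resample, in (0, 1] (default 0.5).
#' @param n_restarts Restarts per k-means run within each resample; default 3
#'   keeps the 500-resample sweep tractable.
#' @return An object of class `k_reliability`: list with `chosen_k_counts`
#'   (named integer histogram over 2..k_max-1), `slope_change_intervals`
#'   (tibble: k, lo, hi, median), `n_resamples`, `fraction`, `seed`.
#' @export
bootstrap_k <- function(fc, k_max = 8, n_resamples = 500, fraction = 0.5,
                        seed = 1, n_restarts = 3) {
  m <- as_fc_matrix(fc)
  k_max <- check_count(k_max, "k_max", min = 3)
  n_resamples <- check_count(n_resamples, "n_resamples", min = 0)
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1]")
  n_sub <- floor(fraction * nrow(m))
  if (n_sub < k_max) abort("resample size smaller than k_max")

  ks <- seq_len(k_max)
  counts <- setNames(integer(k_max), as.character(ks))
  sc_all <- matrix(NA_real_, n_resamples, k_max)
  chosen <- integer(n_resamples)
  for (b in seq_len(n_resamples)) {
    idx <- with_seed(
      derive_seed(seed, paste0("halfsample_", b)),
      sample.int(nrow(m), n_sub)
    )
    cur <- elbow_curve(m[idx, , drop = FALSE],
      k_max = k_max,
      seed = derive_seed(seed, paste0("resample_fit_", b)),
      n_restarts = n_restarts
    )
    kc <- elbow_select(cur)
    chosen[b] <- kc
    counts[as.character(kc)] <- counts[as.character(kc)] + 1L
    sc_all[b, ] <- cur$slope_change
  }
  interior <- 2:(k_max - 1)
  intervals <- tibble::tibble(
    k = interior,
    lo = apply(sc_all[, interior, drop = FALSE], 2, quantile,
      probs = 0.025, na.rm = TRUE
    ),
    median = apply(sc_all[, interior, drop = FALSE], 2, quantile,
      probs = 0.5, na.rm = TRUE
    ),
    hi = apply(sc_all[, interior, drop = FALSE], 2, quantile,
      probs = 0.975, na.rm = TRUE
    )
  )
  if (n_resamples == 0) {
    intervals <- intervals[0, ]
  }
  structure(
    list(
      chosen_k_counts = counts, chosen_k = chosen,
      slope_change_intervals = intervals,
      n_resamples = n_resamples, fraction = fraction,
      k_max = k_max, seed = seed
    ),
    class = "k_reliability"
  )
}

#' Compare phenotypes across FC subtypes
#'
#' Two-sample pooled-variance t tests for continuous phenotypes and Pearson
#' chi-square tests for categorical ones (site, eye status, handedness,
#' diagnosis), between the two subtypes. Missing values are excluded
#' pairwise with the retained n reported; a phenotype with fewer than 2
#' observations in either subtype is skipped with a warning.
#'
#' @param assignments Integer/factor subtype labels, or a `cosine_kmeans`
#'   fit.
#' @param phenotypes Tibble aligned with the assignments.
#' @param continuous,categorical Character vectors of column names; defaults
#'   cover the standard phenotype manifest.
#' @return A tibble: `variable`, `type`, `statistic`, `df`, `p`, `n1`, `n2`.
#' @export
compare_subtype_phenotypes <- function(assignments, phenotypes,
                                       continuous = intersect(
                                         c(
                                           "age", "iq", "mean_fd",
                                           "pct_fd_gt_0p2", "ados_comm",
                                           "ados_social", "ados_rrb", "srs"
                                         ),
                                         names(phenotypes)
                                       ),
                                       categorical = intersect(
                                         c("site", "eye_status", "handedness", "dx"),
                                         names(phenotypes)
                                       )) {
  if (inherits(assignments, "cosine_kmeans")) {
    assignments <- assignments$assignments
  }
  g <- factor(assignments)
  if (nlevels(g) != 2) abort("expected exactly 2 subtypes")
  if (length(g) != nrow(phenotypes)) {
    abort("assignments and phenotype rows differ")
  }
  rows <- list()
  for (v in continuous) {
    x1 <- phenotypes[[v]][g == levels(g)[1]]
    x2 <- phenotypes[[v]][g == levels(g)[2]]
    x1 <- x1[!is.na(x1)]
    x2 <- x2[!is.na(x2)]
    if (length(x1) < 2 || length(x2) < 2) {
      warn(sprintf("phenotype %s skipped: < 2 observations in a subtype", v))
      next
    }
    tt <- pooled_t_from_summary(
      mean(x1), sd(x1), length(x1),
      mean(x2), sd(x2), length(x2)
    )
    rows[[v]] <- tibble::tibble(
      variable = v, type = "continuous",
      statistic = tt$t, df = tt$df, p = tt$p,
      n1 = length(x1), n2 = length(x2)
    )
  }
  for (v in categorical) {
    tab <- table(g, phenotypes[[v]])
    if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warn(sprintf("phenotype %s skipped: degenerate contingency table", v))
      next
    }
    cs <- chi_square_contingency(tab)
    rows[[v]] <- tibble::tibble(
      variable = v, type = "categorical",
      statistic = cs$statistic, df = cs$df, p = cs$p,
      n1 = sum(tab[1, ]), n2 = sum(tab[2, ])
    )
  }
  dplyr::bind_rows(rows)
}
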