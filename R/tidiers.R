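#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cosine k-means fit
#'
#' @param x A [cosine_kmeans()] fit.
#' @param ... Unused.
#' @return A tibble with `subject_id`, `cluster`, and the cosine distance of
#'   each subject to its assigned centroid.
#' @export
tidy.cosine_kmeans <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id %||% sprintf("S%04d", seq_along(x$assignments)),
    cluster = x$assignments
  )
}

#' @rdname tidy.cosine_kmeans
#' @return For `glance()`: a one-row tibble with `k`, `mean_distance`,
#'   `n_iter`, `seed`.
#' @export
glance.cosine_kmeans <- function(x, ...) {
  tibble::tibble(
    k = x$k, mean_distance = x$mean_distance,
    n_iter = x$n_iter, seed = x$seed
  )
}

#' Tidy a PLS fit
#'
#' @param x An `fc_pls` object.
#' @param ... Unused.
#' @return The per-pattern tibble (`pattern`, `singular_value`,
#'   `covariance_fraction`, `perm_p`, `p_floor`), with the number of stable
#'   connections per pattern when BSRs are available.
#' @export
tidy.fc_pls <- function(x, ...) {
  out <- x$patterns
  if (!is.null(x$stable_mask)) {
    out$n_stable <- colSums(x$stable_mask)
  }
  out
}

#' @rdname tidy.fc_pls
#' @return For `glance()`: one row with analysis type, sizes, and the
#'   first-pattern summary.
#' @export
glance.fc_pls <- function(x, ...) {
  tibble::tibble(
    type = x$type,
    n_subjects = nrow(x$fc),
    n_connections = ncol(x$fc),
    n_groups = nlevels(x$groups),
    n_patterns = nrow(x$patterns),
    first_covariance_fraction = x$patterns$covariance_fraction[1],
    first_perm_p = x$patterns$perm_p[1]
  )
}

#' Tidy a k-reliability resampling result
#'
#' @param x A [bootstrap_k()] result.
#' @param ... Unused.
#' @return A tibble with `k` and `count` (times chosen across resamples).
#' @export
tidy.k_reliability <- function(x, ...) {
  tibble::tibble(
    k = as.integer(names(x$chosen_k_counts)),
    count = as.integer(x$chosen_k_counts)
  )
}

#' @rdname tidy.k_reliability
#' @export
glance.k_reliability <- function(x, ...) {
  mode_k <- as.integer(names(which.max(x$chosen_k_counts)))
  tibble::tibble(
    n_resamples = x$n_resamples,
    fraction = x$fraction,
    modal_k = mode_k,
    modal_fraction = if (x$n_resamples > 0) {
      max(x$chosen_k_counts) / x$n_resamples
    } else {
      NA_real_
    }
  )
}

#' Tidy network-pair contributions
#'
#' @param x An [block_contributions()] /
#'   [contribution_permutation_test()] result.
#' @param ... Unused.
#' @return The long-format pair table.
#' @export
tidy.rsn_contributions <- function(x, ...) x$table
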