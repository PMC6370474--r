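#' Default 160-ROI, six-network atlas partition
#'
#' Returns the partition of 160 spherical regions of interest into the six
#' canonical resting-state networks (RSNs) used throughout the package:
#' default mode (DMN), fronto-parietal (FPN), cingulo-opercular (CON),
#' occipital (ON), sensorimotor (SMN) and cerebellar (CN). Network sizes are
#' configurable; the defaults (34, 21, 32, 22, 33, 18) are a fixture summing
#' to 160, not a claim about any published parcellation.
#'
#' @param network_sizes Named integer vector of ROIs per network. Must sum to
#'   the total number of ROIs.
#' @return A tibble with columns `roi_index` (1-based), `roi_name`, `network`
#'   (factor with the six RSN levels in canonical order).
#' @examples
#' atlas <- default_atlas()
#' dplyr::count(atlas, network)
#' @export
default_atlas <- function(network_sizes = c(
                            DMN = 34, FPN = 21, CON = 32,
                            ON = 22, SMN = 33, CN = 18
                          )) {
  if (is.null(names(network_sizes)) || any(!nzchar(names(network_sizes)))) {
    abort("`network_sizes` must be a named vector")
  }
  sizes <- as.integer(network_sizes)
  if (any(sizes < 1)) abort("every network needs at least one ROI")
  n_roi <- sum(sizes)
  network <- factor(rep(names(network_sizes), sizes),
    levels = names(network_sizes)
  )
  tibble::tibble(
    roi_index = seq_len(n_roi),
    roi_name = sprintf("ROI%03d", seq_len(n_roi)),
    network = network
  )
}

validate_atlas <- function(atlas, n_rois = NULL) {
  req <- c("roi_index", "network")
  if (!all(req %in% names(atlas))) {
    abort("atlas needs columns roi_index and network")
  }
  if (!is.null(n_rois) && nrow(atlas) != n_rois) {
    abort(sprintf("atlas covers %d ROIs, expected %d", nrow(atlas), n_rois))
  }
  if (anyDuplicated(atlas$roi_index) || !setequal(atlas$roi_index, seq_len(nrow(atlas)))) {
    abort("atlas roi_index must be exactly 1..n with no duplicates")
  }
  invisible(atlas)
}

#' Fixed connection ordering for the lower-triangle FC vectorization
#'
#' Every FC vector in the package uses one fixed ordering of the R(R-1)/2
#' distinct ROI pairs: for j = 1..R-1, for i = j+1..R, append (i, j). This is
#' the column-major order of the strict lower triangle, i.e. the order
#' `lower.tri()` extracts. For R = 160 the vector has 12,720 entries.
#'
#' @param n_rois Number of ROIs.
#' @return A tibble with columns `connection` (1-based position), `roi_i`,
#'   `roi_j` (1-based ROI indices, `roi_i > roi_j`), and `label`
#'   (`"ROI<i>-ROI<j>"`).
#' @examples
#' head(connection_index(5))
#' nrow(connection_index(160)) # 12720
#' @export
connection_index <- function(n_rois = 160) {
  n_rois <- check_count(n_rois, "n_rois", min = 2)
  j <- rep(seq_len(n_rois - 1), times = (n_rois - 1):1)
  i <- sequence((n_rois - 1):1, from = 2:n_rois)
  tibble::tibble(
    connection = seq_along(i),
    roi_i = i,
    roi_j = j,
    label = sprintf("ROI%d-ROI%d", i, j)
  )
}

#' Number of distinct ROI pairs
#'
#' @param n_rois Number of ROIs.
#' @return `n_rois * (n_rois - 1) / 2`.
#' @examples
#' n_connections(160)
#' @export
n_connections <- function(n_rois = 160) {
  n_rois <- check_count(n_rois, "n_rois", min = 1)
  n_rois * (n_rois - 1L) / 2L
}

# Network label per connection (pair of networks, unordered), as a character
# vector "A|B" with A <= B in atlas level order, plus the per-pair block sizes.
connection_networks <- function(atlas) {
  validate_atlas(atlas)
  atlas <- atlas[order(atlas$roi_index), ]
  idx <- connection_index(nrow(atlas))
  net <- as.character(atlas$network)
  lv <- levels(factor(atlas$network))
  a <- net[idx$roi_i]
  b <- net[idx$roi_j]
  ka <- match(a, lv)
  kb <- match(b, lv)
  lo <- pmin(ka, kb)
  hi <- pmax(ka, kb)
  tibble::tibble(
    connection = idx$connection,
    net_a = lv[lo], net_b = lv[hi],
    pair = paste(lv[lo], lv[hi], sep = "|")
  )
}
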