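#' Sign-threshold a BSR map
#'
#' Connections with BSR strictly greater than `threshold` map to +1, those
#' strictly below `-threshold` to -1, everything else (including BSRs of
#' exactly +/-threshold) to 0. Non-finite BSRs are treated as 0 with a
#' warning.
#'
#' @param bsr Numeric BSR vector (one value per connection), or an `fc_pls`
#'   fit with BSRs, in which case `pattern` selects the column.
#' @param threshold Threshold (default 2).
#' @param pattern Pattern number when `bsr` is a fit.
#' @return Integer vector in \{-1, 0, 1\}.
#' @examples
#' threshold_bsr_to_signs(c(2.5, -2.5, 1.9, -1.9, 2))
#' @export
threshold_bsr_to_signs <- function(bsr, threshold = 2, pattern = 1) {
  if (inherits(bsr, "fc_pls")) {
    if (is.null(bsr$bsr)) abort("fit has no BSRs; run pls_bootstrap() first")
    bsr <- bsr$bsr[, pattern]
  }
  bad <- !is.finite(bsr)
  if (any(bad)) {
    warn(sprintf("%d non-finite BSR value(s) treated as 0", sum(bad)))
    bsr[bad] <- 0
  }
  as.integer((bsr > threshold) - (bsr < -threshold))
}

#' Average network-pair contributions of a thresholded pattern
#'
#' For each unordered pair of resting-state networks, the positive
#' contribution is the fraction of the pair's connections carrying +1 and
#' the negative contribution is minus the fraction carrying -1. Block sizes
#' are `n_a * n_b` for distinct networks and `n_a (n_a - 1) / 2` within a
#' network (no self-connections).
#'
#' @param signs Thresholded sign vector ([threshold_bsr_to_signs()]), one
#'   entry per connection.
#' @param atlas Atlas partition tibble covering all ROIs.
#' @return An object of class `rsn_contributions`: list with `positive` and
#'   `negative` (symmetric network x network matrices), `block_sizes`, and a
#'   long-format `table` tibble.
#' @export
block_contributions <- function(signs, atlas) {
  validate_atlas(atlas)
  p <- n_connections(nrow(atlas))
  if (length(signs) != p) {
    abort(sprintf("signs length %d, expected %d", length(signs), p))
  }
  cn <- connection_networks(atlas)
  lv <- levels(factor(atlas$network))
  pair <- factor(cn$pair, levels = unique_pairs(lv))
  size <- as.vector(table(pair))
  pos <- block_rate(signs == 1, pair, size)
  neg <- -block_rate(signs == -1, pair, size)
  k <- length(lv)
  to_mat <- function(v) {
    m <- matrix(0, k, k, dimnames = list(lv, lv))
    for (nm in names(v)) {
      ab <- strsplit(nm, "|", fixed = TRUE)[[1]]
      m[ab[1], ab[2]] <- v[[nm]]
      m[ab[2], ab[1]] <- v[[nm]]
    }
    m
  }
  structure(
    list(
      positive = to_mat(pos), negative = to_mat(neg),
      block_sizes = setNames(size, levels(pair)),
      table = tibble::tibble(
        pair = levels(pair),
        block_size = size,
        positive = as.vector(pos),
        negative = as.vector(neg)
      )
    ),
    class = "rsn_contributions"
  )
}

# Count-per-block divided by block size; empty blocks (e.g. a single-ROI
# network's diagonal) contribute 0.
block_rate <- function(hits, pair, size) {
  counts <- tapply(hits, pair, sum, default = 0)
  out <- ifelse(size > 0, counts / pmax(size, 1), 0)
  setNames(as.vector(out), levels(pair))
}

unique_pairs <- function(lv) {
  out <- character(0)
  for (a in seq_along(lv)) {
    for (b in a:length(lv)) {
      out <- c(out, paste(lv[a], lv[b], sep = "|"))
    }
  }
  out
}

#' Permutation test for network-pair contributions
#'
#' Permutes the thresholded sign vector over connection positions (keeping
#' the network labels of the positions fixed), recomputes the block
#' contributions for each permutation, and reports per-pair p-values:
#' for positive entries the proportion of permuted contributions greater
#' than or equal to the observed one; for negative entries the proportion
#' less than or equal (more extreme in the negative direction). Zero
#' exceedances are reported as `p = 0` with a floor flag (read p <
#' 1/`n_perm`).
#'
#' @inheritParams block_contributions
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @return An `rsn_contributions` object additionally carrying `p_positive`,
#'   `p_negative` matrices, floor flags, and `n_perm`; the long `table`
#'   gains p-value columns.
#' @export
contribution_permutation_test <- function(signs, atlas, n_perm = 1000,
                                          seed = 1) {
  n_perm <- check_count(n_perm, "n_perm")
  obs <- block_contributions(signs, atlas)
  cn <- connection_networks(atlas)
  pair <- factor(cn$pair, levels = names(obs$block_sizes))
  size <- obs$block_sizes
  npair <- length(size)
  ge_pos <- integer(npair)
  le_neg <- integer(npair)
  obs_pos <- obs$table$positive
  obs_neg <- obs$table$negative
  for (i in seq_len(n_perm)) {
    sp <- with_seed(
      derive_seed(seed, paste0("contrib_perm_", i)),
      sample(signs)
    )
    pp <- block_rate(sp == 1, pair, size)
    nn <- -block_rate(sp == -1, pair, size)
    ge_pos <- ge_pos + (pp >= obs_pos)
    le_neg <- le_neg + (nn <= obs_neg)
  }
  obs$table$p_positive <- as.vector(ge_pos / n_perm)
  obs$table$p_negative <- as.vector(le_neg / n_perm)
  obs$table$p_positive_floor <- ge_pos == 0
  obs$table$p_negative_floor <- le_neg == 0
  lv <- rownames(obs$positive)
  pm <- nm <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (j in seq_len(nrow(obs$table))) {
    ab <- strsplit(obs$table$pair[j], "|", fixed = TRUE)[[1]]
    pm[ab[1], ab[2]] <- pm[ab[2], ab[1]] <- obs$table$p_positive[j]
    nm[ab[1], ab[2]] <- nm[ab[2], ab[1]] <- obs$table$p_negative[j]
  }
  obs$p_positive <- pm
  obs$p_negative <- nm
  obs$n_perm <- n_perm
  obs
}
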