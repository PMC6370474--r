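#' @importFrom rlang abort warn %||% .data
#' @importFrom stats cor rnorm runif sd setNames quantile
NULL

# Deterministic sub-seed derivation: one master seed fans out to independent
# per-stage streams so stages can be rerun in isolation. Kept < 2^31 - 1.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483629
  as.integer((abs(seed) * 48271 + h) %% 2147483629 + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a number in [%s, %s]", name, lo, hi))
  }
  as.numeric(x)
}

# Coerce a subjects x connections input (matrix or data frame with optional
# subject_id column) to a plain numeric matrix with subject ids as rownames.
as_fc_matrix <- function(fc) {
  if (is.data.frame(fc)) {
    ids <- NULL
    if ("subject_id" %in% names(fc)) {
      ids <- as.character(fc$subject_id)
      fc <- fc[setdiff(names(fc), "subject_id")]
    }
    fc <- as.matrix(fc)
    if (!is.null(ids)) rownames(fc) <- ids
  }
  if (!is.numeric(fc)) abort("FC input must be numeric")
  if (anyNA(fc)) abort("FC matrix contains missing values")
  fc
}
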