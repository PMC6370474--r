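#' Participant exclusion rules
#'
#' Standard quality thresholds for a multi-site resting-state cohort:
#' subjects are retained iff age <= `max_age`, IQ >= `min_iq`, mean
#' framewise displacement <= `max_mean_fd` and percentage of frames above
#' 0.2 mm <= `max_pct_fd`. The boundaries are strict on the exclusion side
#' (a subject aged exactly 40 or with IQ exactly 75 is retained).
#'
#' @param max_age Maximum age in years (default 40).
#' @param min_iq Minimum full-scale IQ (default 75).
#' @param max_mean_fd Maximum mean FD in mm (default 0.20).
#' @param max_pct_fd Maximum percentage of frames with FD > 0.2 mm
#'   (default 20).
#' @return A list of class `exclusion_rules`.
#' @export
exclusion_rules <- function(max_age = 40, min_iq = 75, max_mean_fd = 0.20,
                            max_pct_fd = 20) {
  if (any(c(max_age, min_iq, max_mean_fd, max_pct_fd) <= 0)) {
    abort("all thresholds must be positive")
  }
  structure(
    list(
      max_age = max_age, min_iq = min_iq,
      max_mean_fd = max_mean_fd, max_pct_fd = max_pct_fd
    ),
    class = "exclusion_rules"
  )
}

#' Apply participant exclusion rules to a phenotype table
#'
#' @param phenotypes Tibble with columns `age`, `iq`, `mean_fd`,
#'   `pct_fd_gt_0p2` (plus anything else, carried through).
#' @param rules An [exclusion_rules()] object.
#' @return A list with `retained` (the filtered tibble) and `log` (tibble:
#'   one row per excluded subject and failed rule; a subject failing two
#'   rules appears twice).
#' @export
apply_exclusions <- function(phenotypes, rules = exclusion_rules()) {
  req <- c("age", "iq", "mean_fd", "pct_fd_gt_0p2")
  miss <- setdiff(req, names(phenotypes))
  if (length(miss)) {
    abort(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  }
  checks <- list(
    age_gt_max = phenotypes$age > rules$max_age,
    iq_lt_min = phenotypes$iq < rules$min_iq,
    mean_fd_gt_max = phenotypes$mean_fd > rules$max_mean_fd,
    pct_fd_gt_max = phenotypes$pct_fd_gt_0p2 > rules$max_pct_fd
  )
  fails <- purrr::imap(checks, function(bad, rule) {
    bad[is.na(bad)] <- FALSE
    if (!any(bad)) {
      return(NULL)
    }
    tibble::tibble(
      subject_id = if ("subject_id" %in% names(phenotypes)) {
        phenotypes$subject_id[bad]
      } else {
        which(bad)
      },
      rule = rule
    )
  })
  log <- dplyr::bind_rows(fails)
  any_fail <- Reduce(`|`, lapply(checks, function(b) {
    b[is.na(b)] <- FALSE
    b
  }))
  list(retained = phenotypes[!any_fail, , drop = FALSE], log = log)
}

#' Pooled-variance two-sample t from summary statistics
#'
#' `t = (m1 - m2) / (sp * sqrt(1/n1 + 1/n2))` with the pooled SD
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` and
#' `df = n1 + n2 - 2` — the form implied whenever a report prints
#' `t(n1 + n2 - 2)`. Equals `t.test(..., var.equal = TRUE)` on raw data.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return A list with `t`, `df`, `p` (two-sided).
#' @examples
#' pooled_t_from_summary(16.47, 6.46, 145, 16.03, 5.70, 121) # t ~ 0.58
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  n1 <- check_count(n1, "n1", min = 2)
  n2 <- check_count(n2, "n2", min = 2)
  if (s1 < 0 || s2 < 0) abort("standard deviations must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 == 0) {
    if (m1 == m2) {
      return(list(t = 0, df = df, p = 1))
    }
    abort("both variances zero with unequal means: t undefined")
  }
  t <- (m1 - m2) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson X^2 with expected counts from the margins and
#' `df = (r - 1)(c - 1)`; no continuity correction.
#'
#' @param table An r x c matrix of counts.
#' @return A list with `statistic`, `df`, `p`.
#' @examples
#' chi_square_contingency(rbind(c(59, 11, 18, 26, 31), c(52, 10, 16, 29, 14)))
#' @export
chi_square_contingency <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) abort("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero row or column margin")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p = unname(res$p.value)
  )
}

#' Table-1-style group comparison report
#'
#' Per-variable group summaries (mean +/- SD, n) and between-group tests:
#' pooled-variance t for continuous variables, Pearson chi-square for
#' categorical ones. Missing values are dropped per variable.
#'
#' @param phenotypes Phenotype tibble.
#' @param group Name of the two-level grouping column (default `"dx"`).
#' @param continuous,categorical Character vectors of variable names.
#' @return A tibble: `variable`, `type`, per-group `mean`/`sd`/`n` (or
#'   counts), `statistic`, `df`, `p`.
#' @export
table1_report <- function(phenotypes, group = "dx",
                          continuous = intersect(
                            c(
                              "age", "iq", "mean_fd", "pct_fd_gt_0p2",
                              "ados_comm", "ados_social", "ados_rrb", "srs"
                            ),
                            names(phenotypes)
                          ),
                          categorical = intersect(
                            c("site", "eye_status", "handedness"),
                            names(phenotypes)
                          )) {
  g <- factor(phenotypes[[group]])
  if (nlevels(g) != 2) abort("grouping column must have exactly 2 levels")
  rows <- list()
  for (v in continuous) {
    x1 <- phenotypes[[v]][g == levels(g)[1]]
    x2 <- phenotypes[[v]][g == levels(g)[2]]
    x1 <- x1[!is.na(x1)]
    x2 <- x2[!is.na(x2)]
    if (length(x1) < 2 || length(x2) < 2) next
    tt <- pooled_t_from_summary(
      mean(x1), sd(x1), length(x1),
      mean(x2), sd(x2), length(x2)
    )
    rows[[v]] <- tibble::tibble(
      variable = v, type = "continuous",
      mean1 = mean(x1), sd1 = sd(x1), n1 = length(x1),
      mean2 = mean(x2), sd2 = sd(x2), n2 = length(x2),
      statistic = tt$t, df = tt$df, p = tt$p
    )
  }
  for (v in categorical) {
    tab <- table(g, phenotypes[[v]])
    if (any(dim(tab) < 2)) next
    cs <- chi_square_contingency(tab)
    rows[[v]] <- tibble::tibble(
      variable = v, type = "categorical",
      mean1 = NA_real_, sd1 = NA_real_, n1 = sum(tab[1, ]),
      mean2 = NA_real_, sd2 = NA_real_, n2 = sum(tab[2, ]),
      statistic = cs$statistic, df = cs$df, p = cs$p
    )
  }
  dplyr::bind_rows(rows)
}
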