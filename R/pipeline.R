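#' Configuration for a full pipeline run
#'
#' Collects paths, analysis parameters and stage toggles for
#' [run_full_pipeline()]. Either pass parameters directly or a path to a
#' YAML file with the same field names. A serialized copy of the resolved
#' configuration is written to the output directory for provenance.
#'
#' @param output_dir Output directory.
#' @param input_dir Optional directory of an existing cohort (written by
#'   [write_cohort()]); when `NULL` the `cohort` parameters are used to
#'   simulate one.
#' @param cohort Named list of [cohort_spec()] arguments for the simulate
#'   stage.
#' @param k_max,n_resamples,fraction,n_restarts Clustering parameters.
#' @param n_perm,n_boot,bsr_threshold PLS inference parameters.
#' @param truncation_length Common series length (`NULL` = cohort minimum).
#' @param residualization_mode `"keep_mean"` or `"residual"`.
#' @param stages Character vector of stages to run, in order, among
#'   `simulate`, `fc`, `cluster`, `pls_group`, `pls_behavior`,
#'   `network_contrib`, `table1`, `report`.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            input_dir = NULL,
                            cohort = list(),
                            k_max = 8, n_resamples = 500, fraction = 0.5,
                            n_restarts = 20,
                            n_perm = 1000, n_boot = 500, bsr_threshold = 2,
                            truncation_length = NULL,
                            residualization_mode = c("keep_mean", "residual"),
                            stages = c(
                              "simulate", "fc", "cluster", "pls_group",
                              "pls_behavior", "network_contrib", "table1",
                              "report"
                            ),
                            seed = 1L) {
  residualization_mode <- match.arg(residualization_mode)
  known <- c(
    "simulate", "fc", "cluster", "pls_group", "pls_behavior",
    "network_contrib", "table1", "report"
  )
  bad <- setdiff(stages, known)
  if (length(bad)) abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  structure(
    list(
      output_dir = output_dir, input_dir = input_dir, cohort = cohort,
      k_max = check_count(k_max, "k_max", 3),
      n_resamples = check_count(n_resamples, "n_resamples", 0),
      fraction = check_fraction(fraction, "fraction", 1e-9, 1),
      n_restarts = check_count(n_restarts, "n_restarts"),
      n_perm = check_count(n_perm, "n_perm"),
      n_boot = check_count(n_boot, "n_boot"),
      bsr_threshold = bsr_threshold,
      truncation_length = truncation_length,
      residualization_mode = residualization_mode,
      stages = stages, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full subtyping and PLS pipeline
#'
#' Executes the enabled stages in order — simulate (or load) a cohort,
#' build and residualize FC, cluster into subtypes with elbow + half-sample
#' reliability, mean-centering PLS on subtype x diagnosis groups, behavior
#' PLS within subtypes, network-pair contribution tests, Table-1-style
#' cohort statistics, and a report — each stage consuming the previous
#' stage's files under `output_dir`. A manifest JSON records per-stage
#' outputs, parameters, derived seeds and wall time. Reruns with an
#' identical configuration reproduce identical numbers.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @return The manifest, invisibly (a list; also written to
#'   `manifest.json`).
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- config
  cfg_json$stages <- as.list(cfg_json$stages)
  jsonlite::write_json(unclass(cfg_json), file.path(out, "config.json"),
    auto_unbox = TRUE, null = "null", digits = NA
  )

  need <- function(stage, file) {
    if (!file.exists(file.path(out, file))) {
      abort(sprintf(
        "stage '%s' needs %s from an earlier stage; enable it or provide the file",
        stage, file
      ))
    }
  }
  manifest <- list(stages = list(), seed = config$seed)
  env <- new.env()
  # file-based fallbacks keep stages runnable in isolation: every stage's
  # inputs are readable from the previous stage's documented files
  get_fc <- function() {
    env$fc <- env$fc %||% readr::read_csv(
      file.path(out, "fc_residualized.csv"),
      show_col_types = FALSE
    )
    env$fc
  }
  get_pheno <- function(stage) {
    if (is.null(env$phenotypes)) {
      src <- config$input_dir %||% file.path(out, "cohort")
      need_file <- file.path(src, "phenotypes.csv")
      if (!file.exists(need_file)) {
        abort(sprintf("stage '%s' needs a cohort phenotype table", stage))
      }
      env$phenotypes <- readr::read_csv(need_file, show_col_types = FALSE)
    }
    env$phenotypes
  }
  get_atlas <- function(stage) {
    if (is.null(env$atlas)) {
      src <- config$input_dir %||% file.path(out, "cohort")
      f <- file.path(src, "atlas.tsv")
      if (!file.exists(f)) abort(sprintf("stage '%s' needs the atlas", stage))
      a <- readr::read_tsv(f, show_col_types = FALSE)
      a$network <- factor(a$network, levels = unique(a$network))
      env$atlas <- a
    }
    env$atlas
  }
  get_assignments <- function(stage) {
    if (is.null(env$assignments)) {
      need(stage, "assignments.csv")
      env$assignments <- readr::read_csv(
        file.path(out, "assignments.csv"),
        show_col_types = FALSE
      )$cluster
    }
    env$assignments
  }

  for (stage in config$stages) {
    t0 <- Sys.time()
    stage_seed <- derive_seed(config$seed, paste0("stage_", stage))
    outputs <- switch(stage,
      simulate = {
        if (!is.null(config$input_dir)) {
          abort("stage 'simulate' conflicts with input_dir; drop one")
        }
        spec <- do.call(cohort_spec, c(config$cohort, list(seed = stage_seed)))
        cohort <- simulate_cohort(spec)
        write_cohort(cohort, file.path(out, "cohort"))
        "cohort"
      },
      fc = {
        src <- config$input_dir %||% file.path(out, "cohort")
        if (!file.exists(file.path(src, "phenotypes.csv"))) {
          abort("stage 'fc': no cohort found; run 'simulate' or set input_dir")
        }
        data <- read_cohort(src)
        fc <- cohort_fc(data$timeseries, config$truncation_length)
        design <- confound_design(data$phenotypes$age, data$phenotypes$site)
        fc_res <- residualize(fc, design, mode = config$residualization_mode)
        readr::write_csv(fc_res, file.path(out, "fc_residualized.csv"))
        env$fc <- fc_res
        env$phenotypes <- data$phenotypes
        env$atlas <- data$atlas
        "fc_residualized.csv"
      },
      cluster = {
        need("cluster", "fc_residualized.csv")
        fc <- env$fc %||% readr::read_csv(
          file.path(out, "fc_residualized.csv"),
          show_col_types = FALSE
        )
        curve <- elbow_curve(fc,
          k_max = config$k_max, seed = stage_seed,
          n_restarts = config$n_restarts
        )
        k_star <- elbow_select(curve)
        fit <- attr(curve, "models")[[k_star]]
        rel <- bootstrap_k(fc,
          k_max = config$k_max,
          n_resamples = config$n_resamples,
          fraction = config$fraction, seed = stage_seed
        )
        readr::write_csv(
          tibble::as_tibble(curve),
          file.path(out, "elbow_curve.csv")
        )
        readr::write_csv(tidy(fit), file.path(out, "assignments.csv"))
        readr::write_csv(
          tibble::as_tibble(fit$centroids, .name_repair = "minimal"),
          file.path(out, "centroids.csv")
        )
        jsonlite::write_json(
          list(
            chosen_k = k_star,
            counts = as.list(rel$chosen_k_counts),
            n_resamples = rel$n_resamples
          ),
          file.path(out, "k_reliability.json"),
          auto_unbox = TRUE, digits = NA
        )
        env$assignments <- fit$assignments
        env$fit_k <- fit
        c(
          "elbow_curve.csv", "assignments.csv", "centroids.csv",
          "k_reliability.json"
        )
      },
      pls_group = {
        fc <- get_fc()
        pheno <- get_pheno("pls_group")
        groups <- interaction(
          pheno$dx,
          paste0("subtype", get_assignments("pls_group")),
          sep = "_"
        )
        fit <- mean_centering_pls(fc, groups)
        fit <- pls_permutation(fit, n_perm = config$n_perm, seed = stage_seed)
        fit <- pls_bootstrap(fit,
          n_boot = config$n_boot, seed = stage_seed,
          threshold = config$bsr_threshold
        )
        write_pls(fit, out, "group")
        env$pls_group <- fit
        c("pls_group_patterns.json", "pls_group_salience.csv")
      },
      pls_behavior = {
        pheno <- get_pheno("pls_behavior")
        beh_cols <- c("iq", "ados_comm", "ados_social", "ados_rrb", "srs")
        fit <- behavior_pls(
          get_fc(), pheno[beh_cols],
          paste0("subtype", get_assignments("pls_behavior"))
        )
        fit <- pls_permutation(fit, n_perm = config$n_perm, seed = stage_seed)
        fit <- pls_bootstrap(fit,
          n_boot = config$n_boot, seed = stage_seed,
          threshold = config$bsr_threshold
        )
        write_pls(fit, out, "behavior")
        env$pls_behavior <- fit
        c("pls_behavior_patterns.json", "pls_behavior_salience.csv")
      },
      network_contrib = {
        need("network_contrib", "pls_group_salience.csv")
        bsr1 <- if (!is.null(env$pls_group)) {
          env$pls_group$bsr[, 1]
        } else {
          readr::read_csv(file.path(out, "pls_group_salience.csv"),
            show_col_types = FALSE
          )$bsr_pattern1
        }
        signs <- threshold_bsr_to_signs(bsr1,
          threshold = config$bsr_threshold
        )
        contrib <- contribution_permutation_test(
          signs, get_atlas("network_contrib"),
          n_perm = config$n_perm, seed = stage_seed
        )
        readr::write_csv(tidy(contrib), file.path(out, "rsn_contributions.csv"))
        jsonlite::write_json(
          list(
            positive = contrib$positive, negative = contrib$negative,
            p_positive = contrib$p_positive, p_negative = contrib$p_negative,
            n_perm = contrib$n_perm
          ),
          file.path(out, "rsn_contributions.json"),
          digits = NA, matrix = "rowmajor"
        )
        "rsn_contributions.csv"
      },
      table1 = {
        readr::write_csv(
          table1_report(get_pheno("table1")),
          file.path(out, "table1.csv")
        )
        "table1.csv"
      },
      report = {
        make_report(out)
        "report"
      },
      abort(sprintf("unknown stage %s", stage))
    )
    manifest$stages[[stage]] <- list(
      outputs = outputs,
      seed = stage_seed,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

write_pls <- function(fit, out, tag) {
  jsonlite::write_json(
    list(
      type = fit$type,
      patterns = tidy(fit),
      design_salience = as.data.frame(fit$design_salience),
      design_salience_ci = fit$design_salience_ci
    ),
    file.path(out, sprintf("pls_%s_patterns.json", tag)),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  sal <- tibble::as_tibble(fit$brain_salience, .name_repair = "minimal")
  names(sal) <- paste0("pattern", seq_len(ncol(sal)))
  sal <- dplyr::mutate(sal, connection = dplyr::row_number(), .before = 1)
  if (!is.null(fit$bsr)) {
    bsr <- tibble::as_tibble(fit$bsr, .name_repair = "minimal")
    names(bsr) <- paste0("bsr_pattern", seq_len(ncol(bsr)))
    sal <- dplyr::bind_cols(sal, bsr)
  }
  readr::write_csv(sal, file.path(out, sprintf("pls_%s_salience.csv", tag)))
  readr::write_csv(
    tibble::as_tibble(fit$brain_scores, .name_repair = "minimal") |>
      rlang::set_names(paste0("pattern", seq_len(ncol(fit$brain_scores)))),
    file.path(out, sprintf("pls_%s_brain_scores.csv", tag))
  )
  invisible(NULL)
}

#' Render a human-readable report from pipeline outputs
#'
#' Reads whatever stage outputs are present under `dir` and writes elbow and
#' reliability plots, pattern summaries and contribution heatmaps as PNG
#' files plus a `summary.txt`. Missing stages are skipped with a notice; an
#' empty directory yields an empty report.
#'
#' @param dir Pipeline output directory.
#' @return Invisibly, the paths written.
#' @export
make_report <- function(dir) {
  written <- character()
  lines <- character()
  note <- function(...) lines <<- c(lines, sprintf(...))

  f <- file.path(dir, "elbow_curve.csv")
  if (file.exists(f)) {
    curve <- readr::read_csv(f, show_col_types = FALSE)
    class(curve) <- c("elbow_curve", class(curve))
    p <- autoplot(curve)
    ggplot2::ggsave(file.path(dir, "elbow_curve.png"), p,
      width = 5, height = 4, dpi = 120
    )
    written <- c(written, "elbow_curve.png")
    note("Elbow criterion chose k = %d", elbow_select(curve))
  } else {
    note("clustering outputs absent; skipped")
  }

  f <- file.path(dir, "k_reliability.json")
  if (file.exists(f)) {
    rel <- jsonlite::read_json(f)
    counts <- unlist(rel$counts)
    note(
      "k histogram over %s resamples: %s", rel$n_resamples,
      paste(sprintf("k=%s:%s", names(counts), counts), collapse = " ")
    )
  }

  for (tag in c("group", "behavior")) {
    f <- file.path(dir, sprintf("pls_%s_patterns.json", tag))
    if (!file.exists(f)) {
      note("%s PLS outputs absent; skipped", tag)
      next
    }
    pat <- tryCatch(jsonlite::read_json(f, simplifyVector = TRUE),
      error = function(e) {
        abort(sprintf("could not parse %s: %s", f, conditionMessage(e)))
      }
    )
    pt <- pat$patterns
    sig <- which(pt$perm_p < 0.05 | pt$p_floor)
    note(
      "%s PLS: %d patterns; significant at 0.05: %s", tag, nrow(pt),
      if (length(sig)) {
        paste(sprintf(
          "#%d (p=%.3g, %.1f%% cov)", sig, pt$perm_p[sig],
          100 * pt$covariance_fraction[sig]
        ), collapse = "; ")
      } else {
        "none"
      }
    )
  }

  f <- file.path(dir, "rsn_contributions.csv")
  if (file.exists(f)) {
    tab <- readr::read_csv(f, show_col_types = FALSE)
    obj <- structure(list(table = tab), class = "rsn_contributions")
    ggplot2::ggsave(file.path(dir, "rsn_contributions.png"), autoplot(obj),
      width = 7, height = 4, dpi = 120
    )
    written <- c(written, "rsn_contributions.png")
  }

  f <- file.path(dir, "table1.csv")
  if (file.exists(f)) {
    note("Table-1 report written with %d rows", nrow(readr::read_csv(f, show_col_types = FALSE)))
  }

  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(c(written, "summary.txt"))
}
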