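#' @title Config-driven pipeline orchestration
#' @description Runs simulate -> extract -> group stats -> balanced MLR
#'   -> RSN localization over every (measure, parcellation) cohort in
#'   the configuration, with a single global seed and a
#'   machine-readable report.
#' @name pipeline
NULL

#' Build a pipeline configuration
#'
#' @param cohorts List of cohort sources. Each element is either a
#'   [sim_config()] (the cohort is simulated) or a list with `dir`
#'   naming a directory written by [write_cohort_dir()].
#' @param extraction [extraction_params()].
#' @param q_threshold FDR level for the presence tests and the MLR
#'   family.
#' @param stats_family `"pooled"` or `"per_combo"` (see
#'   [presence_test_family()]).
#' @param mlr_n_runs,mlr_alpha,mlr_max_attempts Balanced-sampler
#'   settings.
#' @param z_thresh,denominator_mode RSN subtrait settings.
#' @param seed Global pipeline seed; every random draw derives from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohorts, extraction = extraction_params(),
                            q_threshold = 0.05, stats_family = "pooled",
                            mlr_n_runs = 100, mlr_alpha = 0.05,
                            mlr_max_attempts = 100000,
                            z_thresh = 2, denominator_mode = "retained_edges",
                            seed = 1L) {
  if (length(cohorts) == 0) {
    rlang::abort("`cohorts` is empty: no cohort inputs to run on.")
  }
  structure(list(cohorts = cohorts, extraction = extraction,
                 q_threshold = q_threshold, stats_family = stats_family,
                 mlr_n_runs = mlr_n_runs, mlr_alpha = mlr_alpha,
                 mlr_max_attempts = mlr_max_attempts,
                 z_thresh = z_thresh, denominator_mode = denominator_mode,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()]; each entry of
#' `cohorts:` either carries `dir:` or the fields of [sim_config()]
#' (with `block_spec` as a list of `{network_a, network_b, sign,
#' amplitude}` blocks per trait).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohorts <- lapply(y$cohorts, function(cs) {
    if (!is.null(cs$dir)) return(list(dir = cs$dir))
    args <- cs
    if (!is.null(args$block_spec)) {
      args$block_spec <- lapply(args$block_spec, function(tr) {
        lapply(tr, function(b) {
          trait_block(b$network_a, b$network_b %||% b$network_a,
                      sign = b$sign %||% 1, amplitude = b$amplitude %||% 3)
        })
      })
    }
    do.call(sim_config, args)
  })
  extraction <- do.call(extraction_params, y$extraction %||% list())
  pipeline_config(
    cohorts = cohorts, extraction = extraction,
    q_threshold = y$q_threshold %||% 0.05,
    stats_family = y$stats_family %||% "pooled",
    mlr_n_runs = y$mlr_n_runs %||% 100,
    mlr_alpha = y$mlr_alpha %||% 0.05,
    mlr_max_attempts = y$mlr_max_attempts %||% 100000,
    z_thresh = y$z_thresh %||% 2,
    denominator_mode = y$denominator_mode %||% "retained_edges",
    seed = y$seed %||% 1L)
}

read_cohort_dir <- function(dir) {
  cov_path <- file.path(dir, "covariates.tsv")
  part_path <- file.path(dir, "partition.tsv")
  files <- sort(list.files(dir, pattern = "^sub.*\\.tsv$", full.names = TRUE))
  files <- setdiff(files, c(cov_path, part_path))
  if (!file.exists(cov_path) || !file.exists(part_path) ||
      length(files) == 0) {
    rlang::abort(sprintf(
      "Cohort directory '%s' must contain per-subject connectome TSVs, covariates.tsv and partition.tsv.",
      dir))
  }
  covariates <- read_covariates(cov_path)
  partition <- read_partition(part_path)
  meta <- list(measure = NA_character_, parcellation_id = NA_character_)
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gj <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    meta$measure <- gj$measure %||% NA_character_
    meta$parcellation_id <- gj$parcellation_id %||% NA_character_
  }
  mats <- lapply(files, read_connectome)
  ids <- sub("\\.tsv$", "", basename(files))
  cohort <- assemble_cohort(mats, subject_ids = ids,
                            measure = meta$measure,
                            parcellation_id = meta$parcellation_id)
  list(cohort = cohort, covariates = covariates, partition = partition,
       ground_truth = NULL)
}

#' Run the full trait-discovery pipeline
#'
#' For every cohort: extraction of robust traits; then one pooled
#' family of group t-tests over all traits of all cohorts; for every
#' FDR-significant trait, the balanced-sampling MLR (with the
#' analysis-wide predictor FDR family re-pooled across traits) and the
#' RSN block localization. The report contains the robust-count grid,
#' the presence tests, tidied MLR summaries and RSN flags, and is
#' reproducible bit-for-bit given the same config.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @return A `conn_report` list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  cohorts <- vector("list", length(config$cohorts))
  for (ci in seq_along(config$cohorts)) {
    src <- config$cohorts[[ci]]
    cohorts[[ci]] <- withCallingHandlers({
      if (inherits(src, "sim_config")) {
        sim <- generate_cohort(src, seed = config$seed + 1000L * ci)
        list(cohort = sim$cohort, covariates = sim$covariates,
             partition = sim$partition, ground_truth = sim$ground_truth)
      } else {
        read_cohort_dir(src$dir)
      }
    }, error = function(e) {
      rlang::abort(sprintf("Pipeline stage 'load/simulate' failed for cohort %d: %s",
                           ci, conditionMessage(e)), parent = e)
    })
  }

  extractions <- vector("list", length(cohorts))
  weights_all <- list()
  for (ci in seq_along(cohorts)) {
    params <- config$extraction
    params$base_seed <- params$base_seed + 10000L * ci
    extractions[[ci]] <- tryCatch(
      extract_robust_traits(cohorts[[ci]]$cohort, params),
      error = function(e) {
        rlang::abort(sprintf("Pipeline stage 'extract' failed for cohort %d: %s",
                             ci, conditionMessage(e)), parent = e)
      })
    w <- trait_weights(extractions[[ci]])
    if (nrow(w) > 0) w$cohort_index <- ci
    weights_all[[ci]] <- w
  }
  robust_counts <- summarize_robust_counts(extractions)

  weights <- dplyr::bind_rows(weights_all)
  presence <- if (nrow(weights) == 0) {
    presence_test_family(weights[0, setdiff(names(weights), "cohort_index")],
                         cohorts[[1]]$covariates, config$q_threshold)
  } else {
    keymap <- dplyr::distinct(weights, .data$measure, .data$parcellation_id,
                              .data$trait_id, .data$cohort_index)
    res <- presence_test_family(
      dplyr::select(weights, -"cohort_index"),
      cohorts[[1]]$covariates, q_threshold = config$q_threshold,
      family = config$stats_family)
    dplyr::left_join(res, keymap,
                     by = c("measure", "parcellation_id", "trait_id"))
  }

  mlr_results <- list()
  rsn_results <- list()
  sig <- if (nrow(presence) > 0) {
    dplyr::filter(presence, .data$significant)
  } else presence
  if (nrow(sig) > 0) {
    sampler_cache <- list()
    for (r in seq_len(nrow(sig))) {
      ci <- sig$cohort_index[r]
      key <- as.character(ci)
      covs <- cohorts[[ci]]$covariates
      if (is.null(sampler_cache[[key]])) {
        sampler_cache[[key]] <- tryCatch(
          collect_samplings(covs, n_runs = config$mlr_n_runs,
                            alpha = config$mlr_alpha,
                            max_attempts = config$mlr_max_attempts,
                            seed = config$seed + 500L + ci),
          error = function(e) {
            rlang::abort(sprintf("Pipeline stage 'mlr sampling' failed for cohort %d: %s",
                                 ci, conditionMessage(e)), parent = e)
          })
      }
      ext <- extractions[[ci]]
      tid <- sig$trait_id[r]
      resp <- setNames(ext$weights[, tid], rownames(ext$weights))
      label <- sprintf("%s/%s/%s", sig$measure[r], sig$parcellation_id[r], tid)
      mlr_results[[label]] <- averaged_mlr(resp, covs, sampler_cache[[key]],
                                           q_threshold = config$q_threshold)
      tr_vec <- ext$traits[match(tid, ext$info$trait_id), ]
      rsn_results[[label]] <- rsn_block_analysis(
        tr_vec, resp, covs$family_history[match(names(resp), covs$subject_id)],
        cohorts[[ci]]$partition, z_thresh = config$z_thresh,
        denominator_mode = config$denominator_mode)
    }
    mlr_results <- mlr_family_fdr(mlr_results, config$q_threshold)
  }

  structure(list(robust_counts = robust_counts, presence_tests = presence,
                 mlr = mlr_results, rsn = rsn_results,
                 extractions = extractions,
                 seed = config$seed, config = config,
                 version = as.character(utils::packageVersion("conntrait"))),
            class = "conn_report")
}

#' Robust-trait counts per (measure, parcellation)
#'
#' Combinations with zero robust traits are marked `excluded` and take
#' no part in the downstream statistics.
#'
#' @param extractions List of `conn_traits` objects.
#' @return Tibble with `measure`, `parcellation_id`, `n_robust`,
#'   `excluded`.
#' @export
summarize_robust_counts <- function(extractions) {
  purrr::map_dfr(extractions, function(e) {
    tibble::tibble(measure = e$measure, parcellation_id = e$parcellation_id,
                   n_robust = nrow(e$info))
  }) |>
    dplyr::mutate(excluded = .data$n_robust == 0)
}

#' @export
print.conn_report <- function(x, ...) {
  cat("<conn_report>\nRobust traits per cohort:\n")
  print(x$robust_counts)
  nsig <- sum(x$presence_tests$significant %||% logical(0))
  cat(sprintf("Significant traits after FDR: %d\n", nsig))
  invisible(x)
}

#' Write a pipeline report to disk (JSON + TSVs)
#'
#' @param report A `conn_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$robust_counts, file.path(dir, "robust_counts.tsv"))
  readr::write_tsv(report$presence_tests, file.path(dir, "presence_tests.tsv"))
  mlr <- lapply(report$mlr, function(m) {
    list(terms = tidy(m), model = glance(m))
  })
  rsn <- lapply(report$rsn, function(r) {
    list(threshold = r$overrep$threshold,
         validation = r$overrep$validation,
         blocks = r$overrep$blocks)
  })
  jsonlite::write_json(
    list(seed = report$seed, version = report$version,
         robust_counts = report$robust_counts,
         presence_tests = report$presence_tests,
         mlr = mlr, rsn = rsn),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Tidy per-trait summary of an extraction
#' @param x A `conn_traits` object.
#' @param ... Unused.
#' @return The `info` tibble with measure/parcellation columns.
#' @method tidy conn_traits
#' @export
tidy.conn_traits <- function(x, ...) {
  dplyr::mutate(x$info, measure = x$measure,
                parcellation_id = x$parcellation_id)
}

#' One-row summary of an extraction
#' @param x A `conn_traits` object.
#' @param ... Unused.
#' @method glance conn_traits
#' @export
glance.conn_traits <- function(x, ...) {
  tibble::tibble(n_robust = nrow(x$info), n_runs = x$n_runs,
                 k_pca = x$k_pca, measure = x$measure,
                 parcellation_id = x$parcellation_id)
}
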