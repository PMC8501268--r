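#' @title Connectome, partition and covariate I/O
#' @description Plain-text readers/writers for the objects the pipeline
#'   consumes. Connectomes are square numeric TSV/CSV files; partitions
#'   are two-column TSVs (node index, network label); covariates are
#'   headered TSVs. Imaging formats are deliberately out of scope: the
#'   pipeline begins after connectome estimation.
#' @name connectome-io
NULL

STRUCT_MEASURES <- c("NoS", "FA", "ADiff", "MDiff", "RDiff")

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a connectome matrix from a delimited text file
#'
#' @param path TSV (default) or CSV file holding a square numeric
#'   matrix; an optional header row of node names is detected and
#'   dropped.
#' @param measure Structural measure label, one of NoS, FA, ADiff,
#'   MDiff, RDiff (optional; stored as an attribute).
#' @param parcellation_id Parcellation label (optional attribute).
#' @param tol Symmetry tolerance (see [vectorize_upper()]).
#' @return Symmetric numeric matrix with attributes `measure` and
#'   `parcellation_id`.
#' @export
read_connectome <- function(path, measure = NULL, parcellation_id = NULL,
                            tol = 1e-8) {
  delim <- delim_for(path)
  first <- readLines(path, n = 1L)
  toks <- strsplit(first, delim, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(toks)))
  df <- utils::read.table(path, sep = delim, header = has_header,
                          check.names = FALSE)
  mat <- as.matrix(df)
  if (!is.numeric(mat)) {
    rlang::abort(sprintf("Non-numeric entries in connectome file '%s'.", path))
  }
  if (anyNA(mat)) {
    rlang::abort(sprintf("NA/NaN entries in connectome file '%s'.", path))
  }
  if (nrow(mat) != ncol(mat)) {
    rlang::abort(sprintf(
      "Connectome file '%s' is not square: %d rows x %d columns.",
      path, nrow(mat), ncol(mat)))
  }
  dimnames(mat) <- NULL
  asym <- max(abs(mat - t(mat)))
  if (asym > tol) {
    rlang::abort(sprintf(
      "Connectome file '%s' is not symmetric: max asymmetry %.3g.", path, asym))
  }
  if (max(abs(diag(mat))) > tol) {
    rlang::abort(sprintf("Connectome file '%s' has a nonzero diagonal.", path))
  }
  validate_measure(mat, measure)
  attr(mat, "measure") <- measure
  attr(mat, "parcellation_id") <- parcellation_id
  mat
}

validate_measure <- function(mat, measure) {
  if (identical(measure, "FA") &&
      (min(mat) < -1e-12 || max(mat) > 1 + 1e-12)) {
    rlang::abort("FA connectome values must lie in [0, 1].")
  }
  invisible(TRUE)
}

#' Write a connectome matrix (with a JSON sidecar)
#'
#' Writes the full square matrix as delimited text and a `<path>.json`
#' sidecar recording the measure, parcellation, edge-ordering
#' convention and package version.
#'
#' @param mat Symmetric numeric matrix.
#' @param path Output file; `.csv` selects comma delimiting, anything
#'   else is tab-delimited.
#' @param measure,parcellation_id Metadata for the sidecar; default to
#'   the matrix attributes.
#' @param sidecar Write the JSON sidecar? Default TRUE.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(mat, path, measure = attr(mat, "measure"),
                             parcellation_id = attr(mat, "parcellation_id"),
                             sidecar = TRUE) {
  delim <- delim_for(path)
  utils::write.table(format(mat, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = delim, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  if (sidecar) {
    meta <- list(
      measure = measure, parcellation_id = parcellation_id,
      n_nodes = nrow(mat),
      edge_ordering = "upper triangle, row-major, pairs (i, j) with i < j",
      software = paste0("conntrait ",
                        as.character(utils::packageVersion("conntrait"))))
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' Stack connectomes of one (measure, parcellation) into a cohort matrix
#'
#' @param connectomes List of symmetric matrices sharing node count,
#'   measure and parcellation.
#' @param subject_ids Optional character vector of subject identifiers
#'   (defaults to `sub001`, ...); becomes the rownames.
#' @param measure,parcellation_id Metadata; default to the first
#'   connectome's attributes.
#' @return A subjects-by-edges numeric matrix of class `cohort_matrix`
#'   with attributes `n_nodes`, `measure`, `parcellation_id`.
#' @export
assemble_cohort <- function(connectomes, subject_ids = NULL,
                            measure = NULL, parcellation_id = NULL) {
  if (length(connectomes) == 0) {
    rlang::abort("`connectomes` is empty.")
  }
  ns <- vapply(connectomes, nrow, integer(1))
  if (length(unique(ns)) > 1) {
    bad <- which(ns != ns[1])
    rlang::abort(sprintf(
      "Connectomes disagree on node count: first has %d nodes, offenders: %s.",
      ns[1], paste0("#", bad, " (n=", ns[bad], ")", collapse = ", ")))
  }
  meas <- vapply(connectomes,
                 function(x) attr(x, "measure") %||% NA_character_,
                 character(1))
  if (length(unique(meas[!is.na(meas)])) > 1) {
    rlang::abort(sprintf("Connectomes mix measures: %s.",
                         paste(unique(meas[!is.na(meas)]), collapse = ", ")))
  }
  measure <- measure %||% meas[!is.na(meas)][1]
  parcellation_id <- parcellation_id %||%
    attr(connectomes[[1]], "parcellation_id")
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("sub%03d", seq_along(connectomes))
  }
  if (length(subject_ids) != length(connectomes)) {
    rlang::abort("`subject_ids` must match the number of connectomes.")
  }
  data <- do.call(rbind, lapply(connectomes, vectorize_upper))
  rownames(data) <- subject_ids
  new_cohort_matrix(data, n_nodes = ns[1], measure = measure,
                    parcellation_id = parcellation_id)
}

new_cohort_matrix <- function(data, n_nodes, measure = NULL,
                              parcellation_id = NULL) {
  stopifnot(ncol(data) == n_edges(n_nodes))
  structure(data, n_nodes = as.integer(n_nodes),
            measure = if (is.null(measure)) NA_character_ else measure,
            parcellation_id = if (is.null(parcellation_id)) NA_character_
                              else parcellation_id,
            class = c("cohort_matrix", "matrix", "array"))
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf(
    "<cohort_matrix> %d subjects x %d edges (%d nodes), measure=%s, parcellation=%s\n",
    nrow(x), ncol(x), attr(x, "n_nodes"), attr(x, "measure"),
    attr(x, "parcellation_id")))
  invisible(x)
}

#' Read a node-to-network partition
#'
#' @param path Two-column TSV `(node_index, network_label)`; node
#'   indices may be 0- or 1-based and are normalized to 1-based. A
#'   header row is detected and dropped.
#' @return A tibble with columns `node` (integer) and `network`
#'   (factor; level order = order of first appearance).
#' @export
read_partition <- function(path) {
  first <- readLines(path, n = 1L)
  toks <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(toks[1])))
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          colClasses = c("integer", "character"))
  names(df) <- c("node", "network")
  as_partition(df$network, node = df$node)
}

#' Build a partition object from a label vector
#'
#' @param labels Character vector of network labels, one per node.
#' @param node Optional node indices (0- or 1-based, consecutive).
#' @param networks Optional explicit network level order.
#' @return Partition tibble (`node`, `network`).
#' @export
as_partition <- function(labels, node = seq_along(labels), networks = NULL) {
  if (anyDuplicated(node)) {
    rlang::abort(sprintf("Duplicated node ids in partition: %s.",
                         paste(unique(node[duplicated(node)]), collapse = ", ")))
  }
  node <- as.integer(node)
  if (min(node) == 0L) node <- node + 1L
  o <- order(node)
  node <- node[o]; labels <- labels[o]
  if (!identical(node, seq_along(node))) {
    rlang::abort("Partition node ids must be consecutive (0- or 1-based).")
  }
  networks <- networks %||% unique(labels)
  if (!all(labels %in% networks)) {
    rlang::abort(sprintf("Unknown network labels: %s.",
                         paste(setdiff(labels, networks), collapse = ", ")))
  }
  tibble::tibble(node = node, network = factor(labels, levels = networks))
}

#' Write a partition to TSV
#' @param partition Partition tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  readr::write_tsv(
    dplyr::mutate(partition, network = as.character(.data$network)), path)
  invisible(path)
}

COVARIATE_COLUMNS <- c("age", "sex", "apoe_e4", "education", "moca", "tpa",
                       "cortical_thickness", "hippocampi_volume",
                       "family_history")

#' Read the per-subject covariate table
#'
#' Expects a headered TSV with one row per subject and the nine
#' predictor columns: `age` (years), `sex` (M/F), `apoe_e4`
#' (carrier/noncarrier), `education` (years), `moca`, `tpa`,
#' `cortical_thickness` (mm), `hippocampi_volume` (mm^3) and
#' `family_history` (relative/control). A `subject_id` column is
#' optional and generated when absent. Subject order is preserved.
#'
#' @param path TSV file path.
#' @return A validated covariate tibble.
#' @export
read_covariates <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_covariates(df)
}

#' Validate a covariate table
#' @param df Data frame of covariates.
#' @return The tibble, with categorical columns checked and a
#'   `subject_id` column guaranteed.
#' @export
validate_covariates <- function(df) {
  missing_cols <- setdiff(COVARIATE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("Covariate table is missing required column(s): %s.",
                         paste(missing_cols, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)
  if (!"subject_id" %in% names(df)) {
    df$subject_id <- sprintf("sub%03d", seq_len(nrow(df)))
  }
  if (anyNA(df[COVARIATE_COLUMNS])) {
    bad <- COVARIATE_COLUMNS[colSums(is.na(df[COVARIATE_COLUMNS])) > 0]
    rlang::abort(sprintf("Missing values in covariate column(s): %s.",
                         paste(bad, collapse = ", ")))
  }
  check_levels <- function(col, levels) {
    vals <- unique(df[[col]])
    if (!all(vals %in% levels)) {
      rlang::abort(sprintf("Column '%s' has values outside {%s}: %s.",
                           col, paste(levels, collapse = ", "),
                           paste(setdiff(vals, levels), collapse = ", ")))
    }
  }
  check_levels("sex", c("M", "F"))
  check_levels("apoe_e4", c("carrier", "noncarrier"))
  check_levels("family_history", c("relative", "control"))
  grp <- table(df$family_history)
  if (any(grp < 2)) {
    rlang::abort("Each family-history group must have more than one subject.")
  }
  dplyr::relocate(df, "subject_id")
}

#' Write a covariate table to TSV
#' @param covariates Covariate tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  readr::write_tsv(covariates, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
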