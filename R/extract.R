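#' @title Robust trait extraction (the connICA core)
#' @description PCA denoising at a fixed explained-variance level,
#'   repeated seeded FastICA decompositions of the reconstructed cohort
#'   matrix, and a greedy consensus that keeps only the components
#'   recurring across runs ("robust traits").
#' @name trait-extraction
NULL

#' Extraction parameters
#'
#' Defaults follow the published analysis settings: PCA reconstruction
#' at 95% explained variance, 20 independent components, 500 FastICA
#' runs, a component "present" in another run when some component there
#' matches it at |Pearson r| >= 0.7, and robustness requiring presence
#' in at least 75% of runs.
#'
#' @param var_explained Fraction of variance the PCA reconstruction
#'   must explain, in (0, 1].
#' @param n_components Number of independent components per run.
#' @param n_runs Number of FastICA runs.
#' @param match_rho Absolute-correlation threshold for matching
#'   components across runs.
#' @param presence_min Minimal fraction of (converged) runs a component
#'   must recur in to count as robust.
#' @param base_seed Base seed; run r uses seed `base_seed + r`.
#' @param tol,max_iter FastICA convergence tolerance and iteration cap.
#' @param drop_nonconverged Drop runs that did not meet `tol` from the
#'   consensus (and its presence denominator)? Default `FALSE`: when
#'   part of the whitened space is essentially Gaussian, the symmetric
#'   fixed-point rotation cannot stabilize there to any tolerance even
#'   though the informative components have, so completed runs
#'   participate flagged, and the run-to-run instability is exactly
#'   what the robustness consensus filters.
#' @return An `extraction_params` list.
#' @export
extraction_params <- function(var_explained = 0.95, n_components = 20,
                              n_runs = 500, match_rho = 0.7,
                              presence_min = 0.75, base_seed = 1L,
                              tol = 1e-4, max_iter = 200,
                              drop_nonconverged = FALSE) {
  if (!(var_explained > 0 && var_explained <= 1)) {
    rlang::abort("`var_explained` must lie in (0, 1].")
  }
  if (!(match_rho > 0 && match_rho < 1)) {
    rlang::abort("`match_rho` must lie in (0, 1).")
  }
  if (!(presence_min > 0 && presence_min <= 1)) {
    rlang::abort("`presence_min` must lie in (0, 1].")
  }
  structure(list(var_explained = var_explained,
                 n_components = as.integer(n_components),
                 n_runs = as.integer(n_runs), match_rho = match_rho,
                 presence_min = presence_min, base_seed = as.integer(base_seed),
                 tol = tol, max_iter = as.integer(max_iter),
                 drop_nonconverged = isTRUE(drop_nonconverged)),
            class = "extraction_params")
}

#' PCA denoising of a cohort matrix
#'
#' Centers each edge across subjects, finds the smallest number of
#' principal components whose cumulative explained variance reaches
#' `var_explained`, and reconstructs the matrix from those components
#' with the edge means added back.
#'
#' @param cohort Subjects-by-edges matrix (e.g. a `cohort_matrix`).
#' @param var_explained Target cumulative explained-variance fraction.
#' @return List with `denoised` (S x m matrix), `k` (components used)
#'   and `explained_curve` (cumulative fractions, nondecreasing to 1).
#' @export
pca_denoise <- function(cohort, var_explained = 0.95) {
  if (!(var_explained > 0 && var_explained <= 1)) {
    rlang::abort("`var_explained` must lie in (0, 1].")
  }
  X <- unclass(cohort)
  if (nrow(X) < 3) rlang::abort("Need at least 3 subjects for PCA denoising.")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = nrow(X), nv = 0)
  lam <- sv$d^2
  tot <- sum(lam)
  if (tot <= 0) rlang::abort("Cohort matrix has zero variance.")
  curve <- cumsum(lam) / tot
  k <- which(curve >= var_explained - 1e-12)[1]
  U <- sv$u[, seq_len(k), drop = FALSE]
  # project the centered data on the top-k left singular vectors
  denoised <- U %*% (t(U) %*% Xc)
  denoised <- sweep(denoised, 2, ctr, `+`)
  dimnames(denoised) <- dimnames(X)
  list(denoised = denoised, k = k, explained_curve = curve)
}

#' One FastICA decomposition of the denoised cohort matrix
#'
#' Factorizes `denoised (S x m) ~ weights (S x C) %*% traits (C x m)`
#' where trait rows are independent edge-space patterns. Trait rows are
#' normalized to unit variance with the scale absorbed into the
#' weights. Deterministic given `seed`.
#'
#' @param denoised S x m matrix from [pca_denoise()].
#' @param n_components Number of components C.
#' @param seed Integer seed for the random orthogonal initialization.
#' @param tol,max_iter FastICA stopping parameters.
#' @return List of class `ica_run`: `traits` (C x m), `weights`
#'   (S x C), `run_seed`, `converged`, `n_iter`.
#' @export
run_ica_once <- function(denoised, n_components, seed, tol = 1e-4,
                         max_iter = 200) {
  S <- nrow(denoised); m <- ncol(denoised)
  if (n_components > min(S, m)) {
    rlang::abort(sprintf(
      "n_components = %d exceeds min(S, m) = %d.", n_components, min(S, m)))
  }
  fit <- fastica_symm(unclass(denoised), n_components, seed = seed,
                      tol = tol, max_iter = max_iter)
  sds <- apply(fit$sources, 1, sd)
  traits <- fit$sources / sds
  weights <- sweep(fit$mixing, 2, sds, `*`)
  rownames(weights) <- rownames(denoised)
  structure(list(traits = traits, weights = weights,
                 run_seed = as.integer(seed), converged = fit$converged,
                 n_iter = fit$n_iter),
            class = "ica_run")
}

# canonical sign: the entry of maximal |value| is positive
canonical_sign <- function(v) if (v[which.max(abs(v))] < 0) -1 else 1

#' Consensus of components across ICA runs
#'
#' Greedy clustering over all components of all converged runs, in
#' deterministic order (run index, then component index): an unassigned
#' component seeds a cluster; from every other run the best-matching
#' unassigned component with |Pearson r| >= `match_rho` (against the
#' seed) joins, at most one per run. A cluster is robust iff its
#' distinct contributing runs reach `presence_min` of the converged
#' runs. The consensus trait is the mean of the member traits
#' sign-aligned to the seed, re-standardized to unit variance, with the
#' canonical sign (entry of maximal magnitude positive) applied; the
#' weights are averaged under the same alignment.
#'
#' @param runs List of `ica_run` objects.
#' @param match_rho Absolute-correlation matching threshold.
#' @param presence_min Minimal presence fraction for robustness.
#' @param drop_nonconverged See [extraction_params()].
#' @return A `conn_traits` object: `traits` (R x m matrix), `weights`
#'   (S x R), and `info` tibble (`trait_id`, `presence_fraction`,
#'   `n_member_runs`, `member_corr_mean`), sorted by presence
#'   descending.
#' @export
consensus_robust_traits <- function(runs, match_rho = 0.7,
                                    presence_min = 0.75,
                                    drop_nonconverged = FALSE) {
  conv <- if (drop_nonconverged) {
    Filter(function(r) isTRUE(r$converged), runs)
  } else {
    runs
  }
  if (length(conv) == 0) rlang::abort("No converged ICA runs.")
  if (length(conv) < 2) {
    rlang::abort("Consensus requires at least 2 converged ICA runs.")
  }
  n_runs_conv <- length(conv)
  comp_run <- integer(0); comp_idx <- integer(0)
  for (r in seq_along(conv)) {
    C <- nrow(conv[[r]]$traits)
    comp_run <- c(comp_run, rep.int(r, C))
    comp_idx <- c(comp_idx, seq_len(C))
  }
  total <- length(comp_run)
  m <- ncol(conv[[1]]$traits)
  Tmat <- matrix(0, total, m)
  pos <- 1L
  for (r in seq_along(conv)) {
    C <- nrow(conv[[r]]$traits)
    Tmat[pos:(pos + C - 1L), ] <- conv[[r]]$traits
    pos <- pos + C
  }
  # row-normalize so correlations are inner products
  Rn <- Tmat - rowMeans(Tmat)
  Rn <- Rn / sqrt(rowSums(Rn^2))

  assigned <- logical(total)
  clusters <- list()
  for (idx in seq_len(total)) {
    if (assigned[idx]) next
    assigned[idx] <- TRUE
    cors_all <- as.numeric(Rn %*% Rn[idx, ])
    members <- idx
    signs <- 1
    for (r in seq_len(n_runs_conv)) {
      if (r == comp_run[idx]) next
      cand <- which(comp_run == r & !assigned)
      if (length(cand) == 0) next
      best <- cand[which.max(abs(cors_all[cand]))]
      if (abs(cors_all[best]) >= match_rho) {
        assigned[best] <- TRUE
        members <- c(members, best)
        signs <- c(signs, sign(cors_all[best]))
      }
    }
    clusters[[length(clusters) + 1L]] <-
      list(members = members, signs = signs,
           member_corr_mean = mean(abs(cors_all[members])))
  }

  robust <- Filter(function(cl) {
    length(cl$members) / n_runs_conv >= cl_presence_eps(presence_min)
  }, clusters)
  S <- nrow(conv[[1]]$weights)
  if (length(robust) == 0) {
    return(new_conn_traits(matrix(0, 0, m),
                           matrix(0, S, 0,
                                  dimnames = list(rownames(conv[[1]]$weights),
                                                  NULL)),
                           tibble::tibble(trait_id = character(0),
                                          presence_fraction = numeric(0),
                                          n_member_runs = integer(0),
                                          member_corr_mean = numeric(0)),
                           n_runs = n_runs_conv))
  }
  traits <- matrix(0, length(robust), m)
  weights <- matrix(0, S, length(robust))
  info <- vector("list", length(robust))
  for (ci in seq_along(robust)) {
    cl <- robust[[ci]]
    tm <- Tmat[cl$members, , drop = FALSE] * cl$signs
    cons <- colMeans(tm)
    cons <- (cons - mean(cons)) / sd(cons)
    csign <- canonical_sign(cons)
    cons <- cons * csign
    wm <- vapply(seq_along(cl$members), function(k) {
      j <- cl$members[k]
      conv[[comp_run[j]]]$weights[, comp_idx[j]] * cl$signs[k]
    }, numeric(S))
    traits[ci, ] <- cons
    weights[, ci] <- rowMeans(wm) * csign
    info[[ci]] <- tibble::tibble(
      presence_fraction = length(cl$members) / n_runs_conv,
      n_member_runs = length(cl$members),
      member_corr_mean = cl$member_corr_mean)
  }
  info <- dplyr::bind_rows(info)
  ord <- order(info$presence_fraction, decreasing = TRUE)
  info <- info[ord, ]
  traits <- traits[ord, , drop = FALSE]
  weights <- weights[, ord, drop = FALSE]
  info <- dplyr::mutate(info,
                        trait_id = sprintf("trait%02d", dplyr::row_number()),
                        .before = 1)
  colnames(weights) <- info$trait_id
  rownames(weights) <- rownames(conv[[1]]$weights)
  new_conn_traits(traits, weights, info, n_runs = n_runs_conv)
}

# guard against 74.999...% floating artifacts when presence_min * n is
# an exact integer (ceil semantics on run counts)
cl_presence_eps <- function(presence_min) presence_min - 1e-12

new_conn_traits <- function(traits, weights, info, n_runs, k_pca = NA_integer_,
                            params = NULL, measure = NA_character_,
                            parcellation_id = NA_character_) {
  structure(list(traits = traits, weights = weights, info = info,
                 n_runs = n_runs, k_pca = k_pca, params = params,
                 measure = measure, parcellation_id = parcellation_id),
            class = "conn_traits")
}

#' @export
print.conn_traits <- function(x, ...) {
  cat(sprintf("<conn_traits> %d robust trait(s) over %d edges (%d converged runs",
              nrow(x$traits), ncol(x$traits), x$n_runs))
  if (!is.na(x$k_pca)) cat(sprintf(", PCA rank %d", x$k_pca))
  cat(")\n")
  if (nrow(x$info) > 0) print(x$info)
  invisible(x)
}

#' Extract robust traits from a cohort matrix
#'
#' Orchestrates [pca_denoise()], `n_runs` seeded [run_ica_once()] calls
#' (run r uses `base_seed + r`), and [consensus_robust_traits()].
#' Strict-convergence counts are recorded in the result; see
#' [extraction_params()] for how non-converged runs are handled. If the
#' PCA rank is below `n_components` the component count is reduced to
#' the rank with a warning.
#'
#' @param cohort Subjects-by-edges matrix.
#' @param params An [extraction_params()] list.
#' @return A `conn_traits` object; `info` holds per-trait presence and
#'   `report` (attribute-like list entries `k_pca`, `n_runs`,
#'   `n_converged`, `params`) carries provenance.
#' @export
extract_robust_traits <- function(cohort, params = extraction_params()) {
  stopifnot(inherits(params, "extraction_params"))
  den <- pca_denoise(cohort, params$var_explained)
  C <- params$n_components
  if (den$k < C) {
    rlang::warn(sprintf(
      "PCA rank %d is below the requested %d components; extracting %d.",
      den$k, C, den$k))
    C <- den$k
  }
  runs <- lapply(seq_len(params$n_runs), function(r) {
    run_ica_once(den$denoised, C, seed = params$base_seed + r,
                 tol = params$tol, max_iter = params$max_iter)
  })
  n_conv <- sum(vapply(runs, function(r) isTRUE(r$converged), logical(1)))
  if (params$drop_nonconverged && n_conv < params$n_runs) {
    rlang::warn(sprintf("%d of %d ICA runs did not converge and were dropped.",
                        params$n_runs - n_conv, params$n_runs))
  }
  res <- consensus_robust_traits(runs, params$match_rho, params$presence_min,
                                 drop_nonconverged = params$drop_nonconverged)
  res$n_strict_converged <- n_conv
  res$k_pca <- den$k
  res$params <- params
  res$measure <- attr(cohort, "measure") %||% NA_character_
  res$parcellation_id <- attr(cohort, "parcellation_id") %||% NA_character_
  res
}

#' Tidy per-subject trait weights into long format
#'
#' @param traits A `conn_traits` object.
#' @return Tibble with `subject_id`, `trait_id`, `weight`, `measure`,
#'   `parcellation_id`.
#' @export
trait_weights <- function(traits) {
  stopifnot(inherits(traits, "conn_traits"))
  w <- traits$weights
  if (ncol(w) == 0) {
    return(tibble::tibble(subject_id = character(0), trait_id = character(0),
                          weight = numeric(0), measure = character(0),
                          parcellation_id = character(0)))
  }
  tibble::as_tibble(w, rownames = "subject_id") |>
    tidyr::pivot_longer(-"subject_id", names_to = "trait_id",
                        values_to = "weight") |>
    dplyr::mutate(measure = traits$measure,
                  parcellation_id = traits$parcellation_id) |>
    dplyr::arrange(.data$trait_id, .data$subject_id)
}

#' Match robust traits to reference patterns
#'
#' For each reference pattern (e.g. a planted ground-truth trait) finds
#' the robust trait with maximal |Pearson r| over edges.
#'
#' @param traits A `conn_traits` object.
#' @param reference K x m matrix of reference edge patterns.
#' @return Tibble with `reference` (row index), `trait_id`,
#'   `abs_corr`, and `sign` of the best match.
#' @export
match_traits <- function(traits, reference) {
  stopifnot(inherits(traits, "conn_traits"))
  if (nrow(traits$traits) == 0) {
    return(tibble::tibble(reference = seq_len(nrow(reference)),
                          trait_id = NA_character_, abs_corr = NA_real_,
                          sign = NA_real_))
  }
  cc <- cor(t(reference), t(traits$traits))
  purrr::map_dfr(seq_len(nrow(reference)), function(k) {
    j <- which.max(abs(cc[k, ]))
    tibble::tibble(reference = k, trait_id = traits$info$trait_id[j],
                   abs_corr = abs(cc[k, j]), sign = sign(cc[k, j]))
  })
}
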