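#' @title Group comparison of trait weights with FDR control
#' @name group-presence-stats
NULL

#' Two-sample t-test on trait weights
#'
#' @param x Numeric vector of weights.
#' @param groups Two-level grouping vector aligned with `x`.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return Tibble with `t_stat`, `p_value`, group means and SDs (two
#'   columns each, suffixed by group level).
#' @export
two_sample_ttest <- function(x, groups, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) {
    rlang::abort("`groups` must have exactly two levels.")
  }
  groups <- droplevels(groups)
  g1 <- x[groups == levels(groups)[1]]
  g2 <- x[groups == levels(groups)[2]]
  if (length(g1) < 2 || length(g2) < 2) {
    rlang::abort("Both groups must contain at least 2 observations.")
  }
  if (sd(g1) == 0 && sd(g2) == 0) {
    rlang::abort("Weights are constant within both groups; t is undefined.")
  }
  ht <- stats::t.test(g1, g2, var.equal = (variant == "student"))
  tibble::tibble(t_stat = unname(ht$statistic),
                 p_value = ht$p.value,
                 df = unname(ht$parameter),
                 mean_1 = mean(g1), mean_2 = mean(g2),
                 sd_1 = sd(g1), sd_2 = sd(g2))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjustment with monotonicity enforcement (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param q_threshold Significance level on the adjusted values.
#' @return Tibble with `p_value`, `q_value` and `significant`
#'   (`q_value < q_threshold`); empty input gives an empty tibble.
#' @export
bh_fdr <- function(p_values, q_threshold = 0.05) {
  if (length(p_values) == 0) {
    return(tibble::tibble(p_value = numeric(0), q_value = numeric(0),
                          significant = logical(0)))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    rlang::abort("All p-values must lie in [0, 1].")
  }
  q <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(p_value = p_values, q_value = q,
                 significant = q < q_threshold)
}

#' Group t-tests over a family of robust traits with pooled FDR
#'
#' Runs one two-sample t-test per robust trait (weights vs group
#' membership) and corrects the whole family — by default every trait
#' of every (measure, parcellation) combination pooled into a single
#' Benjamini-Hochberg call, the analysis-wide family; `family =
#' "per_combo"` corrects within each combination instead.
#'
#' @param weights Long tibble from [trait_weights()] (columns
#'   `subject_id`, `trait_id`, `weight`, `measure`, `parcellation_id`),
#'   possibly row-bound across combinations.
#' @param covariates Covariate tibble with `subject_id` and
#'   `family_history`.
#' @param q_threshold FDR significance level (default 0.05).
#' @param variant t-test variant, see [two_sample_ttest()].
#' @param family `"pooled"` (default) or `"per_combo"`.
#' @return Tibble with one row per trait: test statistics, group means
#'   and SDs, `q_value`, `significant`.
#' @export
presence_test_family <- function(weights, covariates, q_threshold = 0.05,
                                 variant = "student",
                                 family = c("pooled", "per_combo")) {
  family <- match.arg(family)
  if (nrow(weights) == 0) {
    return(tibble::tibble(measure = character(0),
                          parcellation_id = character(0),
                          trait_id = character(0), t_stat = numeric(0),
                          p_value = numeric(0), q_value = numeric(0),
                          significant = logical(0)))
  }
  dat <- dplyr::inner_join(weights,
                           dplyr::select(covariates, "subject_id",
                                         "family_history"),
                           by = "subject_id")
  n_w <- dplyr::n_distinct(weights$subject_id)
  n_c <- dplyr::n_distinct(dat$subject_id)
  if (n_c != n_w) {
    rlang::abort(sprintf(
      "Subject sets mismatch: %d subjects in weights, %d matched in covariates.",
      n_w, n_c))
  }
  res <- dat |>
    dplyr::group_by(.data$measure, .data$parcellation_id, .data$trait_id) |>
    dplyr::group_modify(function(d, key) {
      tt <- two_sample_ttest(d$weight,
                             factor(d$family_history,
                                    levels = c("relative", "control")),
                             variant = variant)
      dplyr::rename(tt, mean_relative = "mean_1", mean_control = "mean_2",
                    sd_relative = "sd_1", sd_control = "sd_2")
    }) |>
    dplyr::ungroup()
  if (family == "pooled") {
    adj <- bh_fdr(res$p_value, q_threshold)
    res$q_value <- adj$q_value
    res$significant <- adj$significant
  } else {
    res <- res |>
      dplyr::group_by(.data$measure, .data$parcellation_id) |>
      dplyr::group_modify(function(d, key) {
        adj <- bh_fdr(d$p_value, q_threshold)
        dplyr::mutate(d, q_value = adj$q_value, significant = adj$significant)
      }) |>
      dplyr::ungroup()
  }
  res
}
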