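#' @title Balanced subsampling multiple linear regression
#' @description The cohort is unbalanced (123 relatives vs 61
#'   controls). To keep the family-history effect free of covariate
#'   confounding, the MLR is fitted on repeated balanced subsamples:
#'   each draw selects `target_n` relatives without replacement,
#'   accepts the draw only if the selection shows no significant
#'   difference from the controls on any of the 8 nuisance predictors,
#'   fits the 9-predictor regression on trait weights, and the
#'   statistics are averaged over the accepted samplings.
#' @name balanced-mlr
NULL

#' Predictor specification for the MLR
#'
#' @param predictors Ordered predictor names; `family_history` must be
#'   present and is last by default so its incremental contribution is
#'   the one on top of all nuisance predictors.
#' @return A `predictor_spec` list with the fixed categorical
#'   encodings: `sex` F=1/M=0, `apoe_e4` carrier=1, `family_history`
#'   relative=1. Sign conventions affect beta signs only.
#' @export
predictor_spec <- function(predictors = c("age", "apoe_e4", "sex",
                                          "education", "moca", "tpa",
                                          "cortical_thickness",
                                          "hippocampi_volume",
                                          "family_history")) {
  if (!"family_history" %in% predictors) {
    rlang::abort("`predictors` must include family_history.")
  }
  structure(list(predictors = predictors,
                 encodings = list(sex = c(F = 1, M = 0),
                                  apoe_e4 = c(carrier = 1, noncarrier = 0),
                                  family_history = c(relative = 1, control = 0))),
            class = "predictor_spec")
}

# numeric design tibble in spec order (unstandardized)
encode_predictors <- function(covariates, spec = predictor_spec()) {
  cols <- lapply(spec$predictors, function(p) {
    v <- covariates[[p]]
    if (p %in% names(spec$encodings)) {
      unname(spec$encodings[[p]][as.character(v)])
    } else {
      as.numeric(v)
    }
  })
  names(cols) <- spec$predictors
  tibble::as_tibble(cols)
}

cohens_d <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Covariate balance tests between selected relatives and controls
#'
#' Continuous predictors: pooled-variance two-sample t-test with
#' Cohen's d. Categorical predictors (sex, APOE-e4): Pearson chi-square
#' (no continuity correction) with the phi coefficient; if a category
#' is degenerate (a level absent in a group) Fisher's exact test is
#' used instead and noted in the `test` column. The draw passes when
#' every nuisance p-value is >= `alpha`.
#'
#' @param covariates Covariate tibble.
#' @param selected_ids Subject ids of the selected relatives.
#' @param control_ids Subject ids of the controls (default: all
#'   controls in `covariates`).
#' @param alpha Balance significance level (default 0.05).
#' @param spec [predictor_spec()]; every predictor except
#'   `family_history` is tested.
#' @return Tibble with `predictor`, `p_value`, `effect_size`, `test`,
#'   plus an attribute `pass` (all p >= alpha).
#' @export
balance_tests <- function(covariates, selected_ids, control_ids = NULL,
                          alpha = 0.05, spec = predictor_spec()) {
  control_ids <- control_ids %||%
    covariates$subject_id[covariates$family_history == "control"]
  sel <- covariates[match(selected_ids, covariates$subject_id), ]
  ctl <- covariates[match(control_ids, covariates$subject_id), ]
  nuisance <- setdiff(spec$predictors, "family_history")
  categorical <- intersect(nuisance, names(spec$encodings))
  rows <- lapply(nuisance, function(p) {
    if (p %in% categorical) {
      xs <- factor(sel[[p]], levels = names(spec$encodings[[p]]))
      xc <- factor(ctl[[p]], levels = names(spec$encodings[[p]]))
      tab <- rbind(table(xs), table(xc))
      # a zero cell means a level is absent in one group: the chi-square
      # approximation is degenerate there, use Fisher's exact test
      if (any(tab == 0)) {
        ht <- stats::fisher.test(tab)
        p_val <- ht$p.value
        test <- "fisher"
      } else {
        ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        p_val <- ht$p.value
        test <- "chisq"
      }
      phi <- sqrt(suppressWarnings(
        stats::chisq.test(tab, correct = FALSE))$statistic / sum(tab))
      if (!is.finite(phi)) phi <- 0  # a level absent in both groups
      tibble::tibble(predictor = p, p_value = p_val,
                     effect_size = unname(phi), test = test)
    } else {
      ht <- stats::t.test(sel[[p]], ctl[[p]], var.equal = TRUE)
      tibble::tibble(predictor = p, p_value = ht$p.value,
                     effect_size = abs(cohens_d(sel[[p]], ctl[[p]])),
                     test = "t")
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "pass") <- all(out$p_value >= alpha)
  out
}

#' Collect balanced samplings of the relatives group
#'
#' Rejection sampling: repeatedly draw `target_n` relatives without
#' replacement and keep the draw iff it passes [balance_tests()]
#' against the controls on all 8 nuisance predictors, until `n_runs`
#' accepted samplings are collected. Deterministic given `seed`.
#'
#' @param covariates Covariate tibble.
#' @param n_runs Number of accepted samplings to collect (default 100).
#' @param target_n Relatives per sampling (default: the control group
#'   size).
#' @param alpha Balance significance level.
#' @param max_attempts Attempt cap; exhausting it is an error reporting
#'   the acceptance rate and the most-often-failing predictor.
#' @param seed Integer seed.
#' @param spec [predictor_spec()].
#' @return A `balanced_samplings` object: list of samplings (each with
#'   `selected_ids`, `balance` tibble, `attempt_index`) with attributes
#'   `n_attempts`, `acceptance_rate`, `alpha`, `target_n`.
#' @export
collect_samplings <- function(covariates, n_runs = 100, target_n = NULL,
                              alpha = 0.05, max_attempts = 100000,
                              seed = 1L, spec = predictor_spec()) {
  rel_ids <- covariates$subject_id[covariates$family_history == "relative"]
  ctl_ids <- covariates$subject_id[covariates$family_history == "control"]
  target_n <- target_n %||% length(ctl_ids)
  if (length(rel_ids) < target_n) {
    rlang::abort(sprintf(
      "Cannot sample %d relatives without replacement from %d.",
      target_n, length(rel_ids)))
  }
  screen <- balance_screen_setup(covariates, rel_ids, ctl_ids, spec)
  accepted <- vector("list", n_runs)
  n_acc <- 0L
  fail_counts <- setNames(numeric(length(screen$predictors)),
                          screen$predictors)
  attempts <- 0L
  withr::with_seed(seed, {
    while (n_acc < n_runs) {
      if (attempts >= max_attempts) {
        worst <- names(fail_counts)[which.max(fail_counts)]
        rlang::abort(sprintf(
          paste0("collect_samplings: %d attempts yielded only %d/%d accepted ",
                 "samplings (acceptance rate %.2g); worst predictor: %s."),
          attempts, n_acc, n_runs, n_acc / attempts, worst))
      }
      attempts <- attempts + 1L
      idx <- sample.int(length(rel_ids), target_n)
      p_vals <- balance_screen(screen, idx)
      if (all(p_vals >= alpha)) {
        sel <- rel_ids[idx]
        # full record, incl. effect sizes, for the accepted draw; the
        # screen computes the identical test statistics in closed form
        bal <- balance_tests(covariates, sel, ctl_ids, alpha = alpha,
                             spec = spec)
        n_acc <- n_acc + 1L
        accepted[[n_acc]] <- list(selected_ids = sort(sel), balance = bal,
                                  attempt_index = attempts)
      } else {
        bad <- screen$predictors[p_vals < alpha]
        fail_counts[bad] <- fail_counts[bad] + 1
      }
    }
  })
  structure(accepted, class = "balanced_samplings",
            n_attempts = attempts, acceptance_rate = n_runs / attempts,
            alpha = alpha, target_n = target_n,
            control_ids = sort(ctl_ids))
}

# Precomputed closed-form versions of the balance tests, so the
# rejection sampler can screen millions of draws: pooled-variance t
# for continuous predictors, Pearson chi-square (df = 1, no
# correction) for categoricals, Fisher's exact when a cell is empty.
# The p-values are algebraically identical to balance_tests().
balance_screen_setup <- function(covariates, rel_ids, ctl_ids, spec) {
  nuisance <- setdiff(spec$predictors, "family_history")
  categorical <- intersect(nuisance, names(spec$encodings))
  continuous <- setdiff(nuisance, categorical)
  rel <- covariates[match(rel_ids, covariates$subject_id), ]
  ctl <- covariates[match(ctl_ids, covariates$subject_id), ]
  Rc <- as.matrix(rel[continuous])
  list(
    predictors = nuisance, continuous = continuous,
    categorical = categorical,
    Rc = Rc, Rc2 = Rc^2,
    ctl_n = nrow(ctl),
    ctl_mean = colMeans(as.matrix(ctl[continuous])),
    ctl_ss = colSums(scale(as.matrix(ctl[continuous]), scale = FALSE)^2),
    rel_cat = lapply(categorical, function(p) {
      as.numeric(rel[[p]] == names(spec$encodings[[p]])[1])
    }) |> setNames(categorical),
    ctl_cat_count = vapply(categorical, function(p) {
      sum(ctl[[p]] == names(spec$encodings[[p]])[1])
    }, numeric(1)))
}

balance_screen <- function(sc, idx) {
  n_s <- length(idx)
  n_c <- sc$ctl_n
  df <- n_s + n_c - 2
  sums <- colSums(sc$Rc[idx, , drop = FALSE])
  sums2 <- colSums(sc$Rc2[idx, , drop = FALSE])
  m_s <- sums / n_s
  ss_s <- sums2 - n_s * m_s^2
  vp <- (ss_s + sc$ctl_ss) / df
  t_stat <- (m_s - sc$ctl_mean) / sqrt(vp * (1 / n_s + 1 / n_c))
  p <- 2 * pt(-abs(t_stat), df)
  p_cat <- vapply(sc$categorical, function(pn) {
    a <- sum(sc$rel_cat[[pn]][idx]); b <- n_s - a
    cc <- sc$ctl_cat_count[[pn]]; dd <- n_c - cc
    tab <- matrix(c(a, cc, b, dd), 2, 2)
    if (any(tab == 0)) return(stats::fisher.test(tab)$p.value)
    n <- n_s + n_c
    x2 <- n * (a * dd - b * cc)^2 /
      ((a + b) * (cc + dd) * (a + cc) * (b + dd))
    stats::pchisq(x2, df = 1, lower.tail = FALSE)
  }, numeric(1))
  out <- c(p, p_cat)
  out[match(sc$predictors, c(sc$continuous, sc$categorical))]
}

#' @export
print.balanced_samplings <- function(x, ...) {
  cat(sprintf(
    "<balanced_samplings> %d accepted samplings of %d relatives (acceptance rate %.3f over %d attempts, alpha = %g)\n",
    length(x), attr(x, "target_n"), attr(x, "acceptance_rate"),
    attr(x, "n_attempts"), attr(x, "alpha")))
  invisible(x)
}

#' @rdname print.balanced_samplings
#' @description `tidy()` summarizes the per-predictor balance p-values
#'   and effect sizes across samplings (min/max), mirroring the
#'   bootstrap columns of a demographics table.
#' @param x A `balanced_samplings` object.
#' @param ... Unused.
#' @method tidy balanced_samplings
#' @export
tidy.balanced_samplings <- function(x, ...) {
  purrr::map_dfr(x, function(s) s$balance) |>
    dplyr::group_by(.data$predictor) |>
    dplyr::summarise(p_min = min(.data$p_value), p_max = max(.data$p_value),
                     effect_min = min(.data$effect_size),
                     effect_max = max(.data$effect_size),
                     .groups = "drop")
}

# z-scored response + design for one sampling; subjects = controls +
# selected relatives, in covariate-table order
mlr_frame <- function(response, covariates, selected_ids, control_ids,
                      spec) {
  ids <- covariates$subject_id[covariates$subject_id %in%
                                 c(selected_ids, control_ids)]
  cov_sub <- covariates[match(ids, covariates$subject_id), ]
  y <- response[ids]
  if (anyNA(y)) {
    rlang::abort("Response is missing for some sampled subjects.")
  }
  X <- as.matrix(encode_predictors(cov_sub, spec))
  Xz <- scale(X)
  if (any(!is.finite(Xz))) {
    rlang::abort("A predictor is constant within the sampling; cannot z-score.")
  }
  yz <- as.numeric(scale(y))
  kp <- kappa(Xz, exact = TRUE)
  if (kp > 1e10) {
    cc <- cor(X)
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "Collinear predictors (condition number %.3g): %s and %s.",
      kp, colnames(X)[worst[1]], colnames(X)[worst[2]]))
  }
  list(ids = ids, y = yz, X = Xz)
}

#' Fit the MLR on one balanced sampling
#'
#' Response (trait weights) and all predictors are z-scored within the
#' sampling, so the coefficients are standardized betas; ordinary least
#' squares with intercept; residual df = n - 9 - 1 for the default
#' 9-predictor model.
#'
#' @param response Named numeric vector of trait weights (names =
#'   subject ids).
#' @param covariates Covariate tibble.
#' @param sampling One element of a `balanced_samplings` object (or any
#'   list with `selected_ids`).
#' @param control_ids Control subject ids (default: all controls).
#' @param spec [predictor_spec()].
#' @return List with `coefficients` tibble (`predictor`, `beta`,
#'   `t_stat`), `r_squared`, `df`, `predicted` and
#'   `std_residuals` (named by subject), `incremental` tibble.
#' @export
fit_mlr_once <- function(response, covariates, sampling,
                         control_ids = NULL, spec = predictor_spec()) {
  control_ids <- control_ids %||%
    covariates$subject_id[covariates$family_history == "control"]
  fr <- mlr_frame(response, covariates, sampling$selected_ids, control_ids,
                  spec)
  n <- length(fr$y); p <- ncol(fr$X)
  fit <- lm(fr$y ~ fr$X)
  sm <- summary(fit)
  coefs <- tibble::tibble(predictor = spec$predictors,
                          beta = unname(coef(fit)[-1]),
                          t_stat = unname(sm$coefficients[-1, "t value"]))
  pred <- fitted(fit)
  res <- residuals(fit)
  sigma <- sqrt(sum(res^2) / (n - p - 1))
  if (sigma < 1e-10) {  # perfect fit (y is z-scored, so scale is 1)
    res[] <- 0
    sigma <- 1
  }
  incr <- incremental_r2_frame(fr$y, fr$X)
  list(coefficients = coefs, r_squared = sm$r.squared,
       df = n - p - 1,
       predicted = setNames(as.numeric(pred), fr$ids),
       std_residuals = setNames(as.numeric(res / sigma), fr$ids),
       incremental = incr, n_sub = n)
}

# sequential R^2 contributions over the columns of X (already z-scored)
incremental_r2_frame <- function(y, X) {
  p <- ncol(X)
  r2 <- numeric(p)
  prev <- 0
  tss <- sum((y - mean(y))^2)
  for (j in seq_len(p)) {
    f <- stats::lm.fit(cbind(1, X[, seq_len(j), drop = FALSE]), y)
    cur <- 1 - sum(f$residuals^2) / tss
    r2[j] <- cur - prev
    prev <- cur
  }
  tibble::tibble(predictor = colnames(X), incremental_r2 = r2)
}

#' Sequential (incremental) R-squared contributions for one sampling
#'
#' Adds the predictors to the model in the specification order;
#' contribution j is `R2(1..j) - R2(1..j-1)`. The contributions
#' telescope, so they sum exactly to the full-model R-squared. With
#' `family_history` last, its contribution is the variance it explains
#' on top of all 8 nuisance predictors.
#'
#' @inheritParams fit_mlr_once
#' @return Tibble with `predictor` and `incremental_r2` in model order.
#' @export
incremental_r2 <- function(response, covariates, sampling,
                           control_ids = NULL, spec = predictor_spec()) {
  control_ids <- control_ids %||%
    covariates$subject_id[covariates$family_history == "control"]
  fr <- mlr_frame(response, covariates, sampling$selected_ids, control_ids,
                  spec)
  incremental_r2_frame(fr$y, fr$X)
}

#' Average the MLR over all balanced samplings
#'
#' Fits [fit_mlr_once()] on every accepted sampling and averages the
#' statistics across runs: R-squared, standardized betas (mean and SD),
#' t-statistics and incremental contributions. The per-predictor
#' p-value is the two-tailed tail probability of the *averaged* t at
#' the common residual df; q-values are BH-adjusted within the object
#' (re-pool across traits with [mlr_family_fdr()] for the
#' analysis-wide family). Predicted values and standardized residuals
#' are averaged per subject over the samplings containing that subject
#' (controls appear in every sampling; each relative only in the
#' samplings that selected them).
#'
#' @param response Named numeric vector of trait weights.
#' @param covariates Covariate tibble.
#' @param samplings A `balanced_samplings` object.
#' @param spec [predictor_spec()].
#' @param q_threshold FDR level for the within-object adjustment.
#' @return A `conn_mlr` object; see [tidy.conn_mlr()],
#'   [glance.conn_mlr()], [augment.conn_mlr()].
#' @export
averaged_mlr <- function(response, covariates, samplings,
                         spec = predictor_spec(), q_threshold = 0.05) {
  if (length(samplings) == 0) rlang::abort("Need at least one sampling.")
  control_ids <- attr(samplings, "control_ids") %||%
    covariates$subject_id[covariates$family_history == "control"]
  fits <- lapply(samplings, function(s) {
    fit_mlr_once(response, covariates, s, control_ids, spec)
  })
  dfres <- fits[[1]]$df
  betas <- vapply(fits, function(f) f$coefficients$beta,
                  numeric(length(spec$predictors)))
  ts <- vapply(fits, function(f) f$coefficients$t_stat,
               numeric(length(spec$predictors)))
  incr <- vapply(fits, function(f) f$incremental$incremental_r2,
                 numeric(length(spec$predictors)))
  if (length(fits) == 1) {
    betas <- matrix(betas, ncol = 1); ts <- matrix(ts, ncol = 1)
    incr <- matrix(incr, ncol = 1)
  }
  t_mean <- rowMeans(ts)
  p_val <- 2 * pt(-abs(t_mean), df = dfres)
  adj <- bh_fdr(p_val, q_threshold)
  terms <- tibble::tibble(
    predictor = spec$predictors,
    beta_mean = rowMeans(betas),
    beta_sd = apply(betas, 1, sd),
    t_mean = t_mean,
    p_value = p_val,
    q_value = adj$q_value,
    significant = adj$significant,
    incremental_r2 = rowMeans(incr))
  all_ids <- covariates$subject_id
  acc_pred <- setNames(numeric(length(all_ids)), all_ids)
  acc_res <- acc_pred
  cnt <- setNames(integer(length(all_ids)), all_ids)
  for (f in fits) {
    ids <- names(f$predicted)
    acc_pred[ids] <- acc_pred[ids] + f$predicted
    acc_res[ids] <- acc_res[ids] + f$std_residuals
    cnt[ids] <- cnt[ids] + 1L
  }
  seen <- cnt > 0
  subjects <- tibble::tibble(
    subject_id = all_ids[seen],
    n_samplings = unname(cnt[seen]),
    predicted_mean = unname(acc_pred[seen] / cnt[seen]),
    std_residual_mean = unname(acc_res[seen] / cnt[seen]),
    weight = unname(response[all_ids[seen]]))
  structure(list(terms = terms,
                 r_squared = mean(vapply(fits, `[[`, numeric(1), "r_squared")),
                 df = dfres, n_sub = fits[[1]]$n_sub,
                 n_samplings = length(fits),
                 subjects = subjects, spec = spec,
                 acceptance_rate = attr(samplings, "acceptance_rate")),
            class = "conn_mlr")
}

#' @export
print.conn_mlr <- function(x, ...) {
  cat(sprintf(
    "<conn_mlr> averaged over %d balanced samplings: R^2 = %.4f, df = %d\n",
    x$n_samplings, x$r_squared, x$df))
  print(x$terms)
  invisible(x)
}

#' Broom-style tidiers for averaged MLR results
#'
#' `tidy()` returns the per-predictor table (standardized beta mean and
#' SD, averaged t, p from the averaged t, BH q, incremental R-squared);
#' `glance()` the one-row model summary; `augment()` the per-subject
#' averaged predicted values and standardized residuals.
#'
#' @param x A `conn_mlr` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy conn_mlr
#' @export
tidy.conn_mlr <- function(x, ...) x$terms

#' @rdname tidy.conn_mlr
#' @method glance conn_mlr
#' @export
glance.conn_mlr <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, df = x$df, n_sub = x$n_sub,
                 n_samplings = x$n_samplings,
                 acceptance_rate = x$acceptance_rate %||% NA_real_)
}

#' @rdname tidy.conn_mlr
#' @method augment conn_mlr
#' @export
augment.conn_mlr <- function(x, ...) x$subjects

#' Re-pool the predictor FDR family across several MLR results
#'
#' The analysis-wide family spans traits x predictors x measures x
#' parcellations: all per-predictor p-values of all supplied `conn_mlr`
#' objects enter one BH call and the q-values are written back.
#'
#' @param results Named list of `conn_mlr` objects (names = trait ids).
#' @param q_threshold FDR level.
#' @return The list, with `terms$q_value`/`significant` updated.
#' @export
mlr_family_fdr <- function(results, q_threshold = 0.05) {
  if (length(results) == 0) return(results)
  ps <- unlist(lapply(results, function(r) r$terms$p_value))
  adj <- bh_fdr(ps, q_threshold)
  i <- 0L
  for (k in seq_along(results)) {
    nk <- nrow(results[[k]]$terms)
    results[[k]]$terms$q_value <- adj$q_value[i + seq_len(nk)]
    results[[k]]$terms$significant <- adj$significant[i + seq_len(nk)]
    i <- i + nk
  }
  results
}
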