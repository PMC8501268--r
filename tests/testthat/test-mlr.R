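test_that("balance tests pass on identical distributions and fail on shifts", {
  cov <- tiny_covariates(n_rel = 24, n_ctl = 12, seed = 12)
  ctl_ids <- cov$subject_id[cov$family_history == "control"]

  # selection whose continuous covariates copy the controls exactly
  mirror <- cov
  rel_rows <- which(mirror$family_history == "relative")[1:12]
  cont <- c("age", "education", "moca", "tpa", "cortical_thickness",
            "hippocampi_volume")
  for (cc in cont) mirror[[cc]][rel_rows] <- mirror[[cc]][mirror$family_history == "control"]
  mirror$sex[rel_rows] <- mirror$sex[mirror$family_history == "control"]
  mirror$apoe_e4[rel_rows] <- mirror$apoe_e4[mirror$family_history == "control"]
  bal <- balance_tests(mirror, mirror$subject_id[rel_rows], ctl_ids)
  expect_true(attr(bal, "pass"))
  expect_equal(nrow(bal), 8)
  expect_true(all(bal$p_value[bal$test == "t"] == 1))
  expect_true(all(bal$effect_size[bal$test == "t"] == 0))

  # a 3-SD age shift in the selection must fail on age
  shifted <- cov
  shifted$age[rel_rows] <- shifted$age[rel_rows] + 3 * sd(shifted$age)
  bal2 <- balance_tests(shifted, shifted$subject_id[rel_rows], ctl_ids)
  expect_false(attr(bal2, "pass"))
  expect_lt(bal2$p_value[bal2$predictor == "age"], 0.05)
  expect_gt(bal2$effect_size[bal2$predictor == "age"], 2)
})

test_that("degenerate categorical levels fall back to Fisher's exact test", {
  cov <- tiny_covariates(n_rel = 20, n_ctl = 10, seed = 3)
  rel_ids <- cov$subject_id[cov$family_history == "relative"][1:10]
  cov$apoe_e4[cov$subject_id %in% rel_ids] <- "carrier"
  cov$apoe_e4[cov$family_history == "control"] <- "noncarrier"
  bal <- balance_tests(cov, rel_ids)
  expect_equal(bal$test[bal$predictor == "apoe_e4"], "fisher")
  expect_lt(bal$p_value[bal$predictor == "apoe_e4"], 0.05)
})

test_that("collect_samplings returns exactly n_runs valid, seeded samplings", {
  cov <- withr::with_seed(2, conntrait:::generate_covariates(
    default_covariate_spec(), c(rep("relative", 60), rep("control", 30)),
    seed = 5))
  s <- collect_samplings(cov, n_runs = 25, seed = 9)
  expect_length(s, 25)
  expect_equal(attr(s, "target_n"), 30)
  rel_ids <- cov$subject_id[cov$family_history == "relative"]
  for (smp in s) {
    expect_length(smp$selected_ids, 30)
    expect_equal(anyDuplicated(smp$selected_ids), 0L)
    expect_true(all(smp$selected_ids %in% rel_ids))
    expect_true(all(smp$balance$p_value >= 0.05))
  }
  expect_true(all(diff(vapply(s, `[[`, numeric(1), "attempt_index")) > 0))

  # determinism
  s2 <- collect_samplings(cov, n_runs = 25, seed = 9)
  expect_identical(lapply(s, `[[`, "selected_ids"),
                   lapply(s2, `[[`, "selected_ids"))

  # tidy() summarises the balance envelope like a demographics table
  td <- tidy(s)
  expect_equal(nrow(td), 8)
  expect_true(all(td$p_min >= 0.05))

  # exhaustion case: target_n == all relatives leaves one possible draw,
  # accepted iff it is balanced (here relatives duplicate the controls'
  # covariates, so every balance test passes by construction)
  ctl <- cov[cov$family_history == "control", ]
  mirror <- dplyr::bind_rows(ctl, ctl, ctl)
  mirror$family_history <- rep(c("relative", "relative", "control"),
                               each = nrow(ctl))
  mirror$subject_id <- sprintf("sub%03d", seq_len(nrow(mirror)))
  s3 <- collect_samplings(mirror, n_runs = 3, target_n = 2 * nrow(ctl),
                          seed = 1)
  expect_identical(s3[[1]]$selected_ids, s3[[2]]$selected_ids)
  expect_identical(s3[[2]]$selected_ids, s3[[3]]$selected_ids)

  expect_error(collect_samplings(cov, n_runs = 1, target_n = 61),
               "without replacement")
})

test_that("an impossible balance requirement fails loudly with diagnostics", {
  cov <- tiny_covariates(n_rel = 30, n_ctl = 15, seed = 8)
  cov$age[cov$family_history == "relative"] <-
    cov$age[cov$family_history == "relative"] + 40
  expect_error(collect_samplings(cov, n_runs = 5, max_attempts = 50, seed = 2),
               "acceptance rate.*age")
})

test_that("fit_mlr_once matches the normal-equations oracle", {
  # 50 random small fixtures; z-scored response and predictors
  withr::with_seed(41, {
    for (r in 1:50) {
      n_rel <- sample(12:20, 1); n_ctl <- sample(8:14, 1)
      cov <- tiny_covariates(n_rel, n_ctl, seed = 500 + r)
      resp <- setNames(rnorm(n_rel + n_ctl), cov$subject_id)
      sampling <- list(selected_ids =
                         cov$subject_id[cov$family_history == "relative"])
      fit <- fit_mlr_once(resp, cov, sampling)
      Xz <- scale(as.matrix(conntrait:::encode_predictors(cov)))
      yz <- as.numeric(scale(resp[cov$subject_id]))
      orc <- ols_oracle(yz, Xz)
      expect_equal(fit$coefficients$beta, unname(orc$beta[-1]),
                   tolerance = 1e-8)
      expect_equal(fit$coefficients$t_stat, unname(orc$t[-1]),
                   tolerance = 1e-8)
      expect_equal(fit$r_squared, orc$r_squared, tolerance = 1e-10)
      expect_equal(fit$df, orc$df)
    }
  })
})

test_that("df is n_sub - p - 1; 122 subjects with 9 predictors give df 112", {
  cov <- withr::with_seed(3, conntrait:::generate_covariates(
    default_covariate_spec(), c(rep("relative", 123), rep("control", 61)),
    seed = 77))
  sel <- cov$subject_id[cov$family_history == "relative"][1:61]
  resp <- withr::with_seed(4, setNames(rnorm(184), cov$subject_id))
  fit <- fit_mlr_once(resp, cov, list(selected_ids = sel))
  expect_equal(fit$n_sub, 122)
  expect_equal(fit$df, 112)
})

test_that("an exact linear response gives R^2 = 1 and zero residuals", {
  cov <- tiny_covariates(n_rel = 16, n_ctl = 10, seed = 6)
  X <- conntrait:::encode_predictors(cov)
  resp <- setNames(2 * X$age - 3 * X$moca + 0.5 * X$family_history,
                   cov$subject_id)
  fit <- suppressWarnings(  # summary.lm flags the perfect fit
    fit_mlr_once(resp, cov,
                 list(selected_ids =
                        cov$subject_id[cov$family_history == "relative"])))
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$std_residuals), na.rm = TRUE), 1e-6)
})

test_that("collinear predictors are rejected naming the offending pair", {
  cov <- tiny_covariates(n_rel = 16, n_ctl = 10, seed = 6)
  cov$education <- 2 * cov$age + 1
  resp <- setNames(rnorm(26), cov$subject_id)
  expect_error(
    fit_mlr_once(resp, cov,
                 list(selected_ids =
                        cov$subject_id[cov$family_history == "relative"])),
    "Collinear")
})

test_that("incremental R^2 telescopes to the full model and handles orthogonality", {
  cov <- tiny_covariates(n_rel = 30, n_ctl = 20, seed = 10)
  resp <- withr::with_seed(11, setNames(rnorm(50), cov$subject_id))
  sampling <- list(selected_ids =
                     cov$subject_id[cov$family_history == "relative"])
  fit <- fit_mlr_once(resp, cov, sampling)
  expect_equal(sum(fit$incremental$incremental_r2), fit$r_squared,
               tolerance = 1e-10)
  incr <- incremental_r2(resp, cov, sampling)
  expect_identical(incr, fit$incremental)
  # the family-history contribution equals R2(full) - R2(8 nuisance)
  Xz <- scale(as.matrix(conntrait:::encode_predictors(cov)))
  yz <- as.numeric(scale(resp[cov$subject_id]))
  r2_full <- ols_oracle(yz, Xz)$r_squared
  r2_nuis <- ols_oracle(yz, Xz[, 1:8])$r_squared
  expect_equal(incr$incremental_r2[9], r2_full - r2_nuis, tolerance = 1e-10)

  # orthogonalized predictors: contribution == squared correlation
  withr::with_seed(12, {
    n <- 40
    M <- scale(matrix(rnorm(n * 4), n, 4), center = TRUE, scale = FALSE)
    Q <- qr.Q(qr(M))          # centered orthonormal columns
    Qz <- scale(Q)            # z-scoring keeps them sample-orthogonal
    colnames(Qz) <- paste0("x", 1:4)
    y <- rnorm(n)
    yz2 <- as.numeric(scale(y))
    contrib <- conntrait:::incremental_r2_frame(yz2, Qz)
    r2_direct <- vapply(1:4, function(j) cor(yz2, Qz[, j])^2, numeric(1))
    expect_equal(contrib$incremental_r2, r2_direct, tolerance = 1e-8)
  })

  # single predictor: contribution equals the full R^2
  one <- conntrait:::incremental_r2_frame(yz, Xz[, 1, drop = FALSE])
  expect_equal(one$incremental_r2, ols_oracle(yz, Xz[, 1])$r_squared,
               tolerance = 1e-10)
})

test_that("averaged_mlr averages statistics and augments per subject", {
  cov <- withr::with_seed(13, conntrait:::generate_covariates(
    default_covariate_spec(), c(rep("relative", 50), rep("control", 25)),
    seed = 19))
  X <- conntrait:::encode_predictors(cov)
  resp <- withr::with_seed(14, setNames(
    0.8 * as.numeric(scale(X$family_history)) + rnorm(75),
    cov$subject_id))
  s <- collect_samplings(cov, n_runs = 20, seed = 3)
  avg <- averaged_mlr(resp, cov, s)

  # a single sampling averages to that run's statistics
  one <- averaged_mlr(resp, cov, s[1])
  fit1 <- fit_mlr_once(resp, cov, s[[1]])
  expect_equal(one$terms$beta_mean, fit1$coefficients$beta)
  expect_equal(one$terms$t_mean, fit1$coefficients$t_stat)
  expect_equal(one$r_squared, fit1$r_squared)

  # p from the averaged t at the common df
  expect_equal(avg$terms$p_value,
               2 * pt(-abs(avg$terms$t_mean), avg$df), tolerance = 1e-12)
  # incremental contributions still sum to the averaged R^2
  expect_equal(sum(avg$terms$incremental_r2), avg$r_squared,
               tolerance = 1e-10)

  aug <- augment(avg)
  # controls enter every sampling; relatives only some
  ctl <- dplyr::filter(aug, .data$subject_id %in%
                         cov$subject_id[cov$family_history == "control"])
  expect_true(all(ctl$n_samplings == 20))
  rel <- dplyr::filter(aug, !.data$subject_id %in% ctl$subject_id)
  expect_true(all(rel$n_samplings <= 20))
  gl <- glance(avg)
  expect_equal(gl$n_samplings, 20)
  expect_equal(gl$df, avg$df)
})

test_that("a planted family-history effect is detected and a null is not", {
  reps <- 10
  detected <- logical(reps)
  null_hit <- logical(reps)
  for (r in seq_len(reps)) {
    cov <- conntrait:::generate_covariates(
      default_covariate_spec(),
      c(rep("relative", 123), rep("control", 61)), seed = 900 + r)
    fh <- as.numeric(cov$family_history == "relative")
    resp_alt <- withr::with_seed(300 + r, setNames(0.8 * fh + rnorm(184),
                                                   cov$subject_id))
    resp_null <- withr::with_seed(600 + r, setNames(rnorm(184),
                                                    cov$subject_id))
    s <- collect_samplings(cov, n_runs = 30, seed = 40 + r)
    alt <- averaged_mlr(resp_alt, cov, s)
    fh_row <- dplyr::filter(alt$terms, .data$predictor == "family_history")
    detected[r] <- fh_row$significant &&
      alt$terms$predictor[which.max(abs(alt$terms$t_mean))] == "family_history"
    nul <- averaged_mlr(resp_null, cov, s)
    null_hit[r] <- dplyr::filter(nul$terms,
                                 .data$predictor == "family_history")$significant
  }
  expect_gte(mean(detected), 0.9)
  expect_lte(mean(null_hit), 0.2)
})

test_that("mlr_family_fdr pools q-values across traits", {
  cov <- tiny_covariates(n_rel = 30, n_ctl = 20, seed = 22)
  s <- collect_samplings(cov, n_runs = 5, seed = 4)
  withr::with_seed(23, {
    r1 <- averaged_mlr(setNames(rnorm(50), cov$subject_id), cov, s)
    r2 <- averaged_mlr(setNames(rnorm(50), cov$subject_id), cov, s)
  })
  pooled <- mlr_family_fdr(list(a = r1, b = r2))
  all_p <- c(r1$terms$p_value, r2$terms$p_value)
  expect_equal(unname(c(pooled$a$terms$q_value, pooled$b$terms$q_value)),
               bh_oracle(all_p), tolerance = 1e-12)
})

test_that("the sampler's closed-form screen equals balance_tests exactly", {
  cov <- withr::with_seed(71, conntrait:::generate_covariates(
    default_covariate_spec(confounded = TRUE),
    c(rep("relative", 40), rep("control", 25)), seed = 72))
  sc <- conntrait:::balance_screen_setup(
    cov, cov$subject_id[cov$family_history == "relative"],
    cov$subject_id[cov$family_history == "control"], predictor_spec())
  withr::with_seed(73, {
    for (r in 1:30) {
      idx <- sample.int(40, 25)
      p_screen <- conntrait:::balance_screen(sc, idx)
      bal <- balance_tests(
        cov, cov$subject_id[cov$family_history == "relative"][idx])
      expect_equal(unname(p_screen), bal$p_value, tolerance = 1e-12)
    }
  })
})
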