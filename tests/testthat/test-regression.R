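small_cohort <- function(n = 12, seed = 2) {
  apply_exclusions(generate_cohort(cohort_config(n_per_group = n,
                                                 seed = seed)))$table
}

test_that("raw regressors have the documented semantics", {
  tab <- small_cohort(3)
  raw <- riskforage:::raw_regressors(tab)
  one <- raw[raw$participant_id == raw$participant_id[1], ]
  one <- one[order(one$trial_index), ]
  expect_equal(one$ev, one$magnitude * one$probability)
  expect_equal(one$risk,
               one$magnitude^2 * one$probability * (1 - one$probability))
  # dpc: deviation from the current environment's mean probability
  pcm <- ifelse(one$environment == "poor", 0.4, 0.6)
  expect_equal(one$dpc, one$probability - pcm)
  # dpp: 0 in the first block, current minus previous mean in the second
  expect_true(all(one$dpp[one$block_index == 1] == 0))
  grp <- one$group[1]  # PR sees poor then rich: dpp = 0.6 - 0.4 in block 2
  expect_equal(unique(one$dpp[one$block_index == 2]),
               if (grp == "PR") 0.6 - 0.4 else 0.4 - 0.6)
  # history lags shift by one presented trial
  accepted <- as.numeric(one$choice == "accept")
  expect_equal(one$prev_choice, c(0, accepted[-nrow(one)]))
  rew <- ifelse(is.na(one$outcome), 0, one$outcome)
  expect_equal(one$prev_reward, c(0, rew[-nrow(one)]))
  expect_equal(one$acc_raw, cumsum(rew) - rew)
})

test_that("the regressor matrix is z-scored per experiment", {
  tab <- small_cohort(8)
  mat <- build_regressors(tab)
  expect_s3_class(mat, "regressor_matrix")
  expect_true(all(regressor_names() %in% names(mat)))
  for (r in c("ev", "risk", "dpc", "prev_choice")) {
    expect_equal(mean(mat[[r]]), 0, tolerance = 1e-10)
    expect_equal(sd(mat[[r]]), 1, tolerance = 1e-10)
  }
  # only analyzed, responded trials remain (seq() floating-point tolerant)
  expect_true(all(vapply(mat$probability, function(x)
    min(abs(x - c(0.4, 0.5, 0.6))) < 1e-9, logical(1))))
  expect_true(all(mat$magnitude > 10))
  sc <- attr(mat, "scaling")
  expect_equal(sc$pooled[["1"]]$ev[["mean"]],
               mean(riskforage:::raw_regressors(tab)$ev[
                 tab$analyzed & tab$choice != "missing"]))
})

test_that("fit_logistic agrees with glm and reports BIC and errors", {
  tab <- small_cohort(8)
  mat <- build_regressors(tab)
  fit <- fit_logistic(mat, subset = c("ev", "risk", "prev_choice"))
  ref <- glm(response ~ ev + risk + prev_choice, binomial(), data = mat)
  expect_equal(setNames(fit$coefficients$estimate, fit$coefficients$term),
               coef(ref), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(fit$bic, -2 * fit$loglik + 4 * log(nrow(mat)))
  expect_false(fit$separation)
  # singular design: a duplicated regressor
  mat2 <- mat
  mat2$ev2 <- mat2$ev
  class(mat2) <- class(mat)
  attr(mat2, "lags") <- 1L
  expect_error(fit_logistic(mat2, subset = c("ev", "ev2")), "singular")
  mat3 <- mat
  mat3$response <- 1
  expect_error(fit_logistic(mat3, subset = "ev"), "constant")
})

test_that("VIFs are near one for clean designs and capped when collinear", {
  tab <- small_cohort(8)
  mat <- build_regressors(tab)
  v <- vif(mat)
  expect_setequal(v$term, regressor_names())
  # EV/Risk and prev_reward/prev_success share structure by design, so
  # moderate inflation (~10) is expected; nothing should be near-singular
  expect_true(all(v$vif < 15))
  expect_false(any(v$capped))
  mat$ev2 <- mat$ev
  expect_true(vif(mat, subset = c("ev", "ev2"))$capped[1])
})

test_that("the L1 path and bootstrap inference run end to end", {
  tab <- small_cohort(10)
  mat <- build_regressors(tab)
  l1 <- fit_logistic(mat, penalty = "L1", seed = 4)
  expect_equal(l1$penalty, "L1")
  expect_equal(nrow(l1$coefficients), 9)
  bs <- fit_logistic(mat, subset = c("ev", "risk"), B = 49, seed = 3)
  expect_true(all(c("ci_low", "ci_high", "p_value") %in%
                    names(bs$coefficients)))
  expect_true(all(bs$coefficients$ci_low <= bs$coefficients$estimate &
                    bs$coefficients$estimate <= bs$coefficients$ci_high))
  expect_true(all(bs$coefficients$p_value >= 0 &
                    bs$coefficients$p_value <= 1))
})

test_that("the regression recovers the generator's coefficient signs", {
  tab <- small_cohort(30, seed = 2)
  fit <- fit_logistic(build_regressors(tab))
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  # the cohort generator makes acceptance rise with EV and dpc/dpp (lower
  # effective alpha), fall with Risk, and perseverate on the previous choice
  expect_gt(co[["ev"]], 0)
  expect_lt(co[["risk"]], 0)
  expect_gt(co[["dpc"]], 0)
  expect_gt(co[["dpp"]], 0)
  expect_gt(co[["prev_choice"]], 0)
})

test_that("simulations and ablations produce valid variants", {
  tab <- small_cohort(8)
  mat <- build_regressors(tab)
  fit <- fit_logistic(mat)
  sim <- simulate_from_fit(fit, n_per_group = 2, seed = 5)
  expect_equal(nrow(sim), 4 * 132)
  expect_true(all(sim$choice %in% c("accept", "reject")))
  expect_identical(sim, simulate_from_fit(fit, n_per_group = 2, seed = 5))
  # zeroing all non-intercept terms gives a flat acceptance probability
  sim0 <- simulate_from_fit(fit, n_per_group = 12, use_terms = character(0),
                            seed = 5)
  co0 <- fit_logistic(build_regressors(sim0))$coefficients
  expect_lt(max(abs(co0$estimate[co0$term %in% c("dpc", "dpp")])), 0.15)
  ab <- ablation_suite(mat, table = tab, drop = c("dpc", "dpp"),
                       add_lags = 2, simulate = FALSE)
  expect_setequal(names(ab), c("drop_dpc", "drop_dpp", "lags_2"))
  expect_false("dpc" %in% ab$drop_dpc$fit$subset)
  expect_true("prev_choice2" %in% ab$lags_2$fit$subset)
  expect_error(ablation_suite(mat, drop = "dpc", add_lags = 2,
                              simulate = FALSE))
})
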