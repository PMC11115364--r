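test_that("the core filter matches a Kalman filter on a linear model", {
  set.seed(10)
  n <- 40; sd_q <- 0.3; sd_r <- 0.5
  x <- cumsum(rnorm(n, 0, sd_q))
  y <- x + rnorm(n, 0, sd_r)
  pf <- particle_filter_core(
    n_steps = n,
    init = function(k) rnorm(k, 0, 1),
    transition = function(z, t) z + rnorm(length(z), 0, sd_q),
    obs_loglik = function(z, t) dnorm(y[t], z, sd_r, log = TRUE),
    n_particles = 20000, lag = 0, seed = 3
  )
  # exact Kalman recursion with matching prior N(0, 1) before the first
  # transition
  m <- 0; P <- 1
  km <- ll <- numeric(n)
  for (t in 1:n) {
    Pp <- P + sd_q^2
    ll[t] <- dnorm(y[t], m, sqrt(Pp + sd_r^2), log = TRUE)
    K <- Pp / (Pp + sd_r^2)
    m <- m + K * (y[t] - m)
    P <- (1 - K) * Pp
    km[t] <- m
  }
  expect_lt(max(abs(pf$filtered[, 2] - km)), 0.08)
  expect_lt(abs(pf$total_loglik - sum(ll)), 0.2)
})

test_that("systematic resampling of equal weights is the identity", {
  set.seed(2)
  expect_equal(riskforage:::systematic_resample(rep(-3.7, 100)), 1:100)
})

test_that("lag-0 smoothing returns the filtering distribution exactly", {
  spec <- model_spec("risk_return")
  ps <- replicate(5, utility_params(alpha = 0.015, beta = 0.3),
                  simplify = FALSE)
  tab <- simulate_choices(spec, ps, "PR", seed = 4)
  cfg <- pf_config(n_particles = 500, seed = 6)
  tr <- fixed_lag_smooth(tab, cfg, lag = 0)$trajectory
  expect_equal(tr$median, tr$filtered_median)
  expect_equal(tr$lo90, tr$filtered_lo90)
  expect_equal(tr$hi90, tr$filtered_hi90)
  # and a positive lag must differ somewhere while staying aligned
  tr20 <- fixed_lag_smooth(tab, cfg, lag = 20)$trajectory
  expect_false(isTRUE(all.equal(tr20$median, tr20$filtered_median)))
  expect_equal(tr20$filtered_median, tr$filtered_median)
})

test_that("alignment masks catch, unanalyzed, and missing trials", {
  spec <- model_spec("risk_return")
  tab <- simulate_choices(spec, list(utility_params(alpha = 0, beta = 0.3),
                                     utility_params(alpha = 0, beta = 0.3)),
                          "PR", seed = 1)
  tab$choice[tab$trial_index == 5] <- "missing"
  al <- riskforage:::align_group_table(tab)
  expect_equal(dim(al$Y), c(132, 2))
  masked <- !tab$analyzed[tab$participant_id == al$ids[1]]
  expect_true(all(is.na(al$Y[masked, 1])))
  expect_true(all(is.na(al$Y[5, ])))
  expect_false(anyNA(al$M))
  # ragged tables are rejected
  expect_error(riskforage:::align_group_table(tab[-1, ]), "design length")
})

test_that("the filter brackets a constant latent risk-aversiveness", {
  spec <- model_spec("risk_return")
  ps <- replicate(40, utility_params(alpha = 0.015, beta = 0.3),
                  simplify = FALSE)
  tab <- simulate_choices(spec, ps, "PR", seed = 9)
  fit <- run_filter(tab, pf_config(sigma = 1e-3, beta = 0.3,
                                   n_particles = 2000, seed = 4))
  tr <- fit$trajectory
  expect_equal(nrow(tr), 132)
  expect_true(all(tr$lo90 <= tr$median & tr$median <= tr$hi90))
  expect_gt(mean(0.015 >= tr$lo90 & 0.015 <= tr$hi90), 0.8)
  expect_lt(abs(mean(tr$median) - 0.015), 0.005)
  expect_true(is.finite(fit$total_loglik))
})

test_that("simulate_from_trajectory produces a valid, reproducible table", {
  spec <- model_spec("risk_return")
  ps <- replicate(5, utility_params(alpha = 0.015, beta = 0.3),
                  simplify = FALSE)
  tab <- simulate_choices(spec, ps, "PR", seed = 4)
  fit <- run_filter(tab, pf_config(beta = 0.3, n_particles = 500, seed = 2))
  sim <- simulate_from_trajectory(fit, tab, seed = 8)
  expect_equal(nrow(sim), nrow(tab))
  expect_true(all(sim$choice %in% c("accept", "reject")))
  expect_true(all(sim$outcome[sim$choice == "reject"] == 10))
  acc <- sim[sim$choice == "accept", ]
  expect_true(all(acc$outcome == 0 | acc$outcome == acc$magnitude))
  expect_identical(sim, simulate_from_trajectory(fit, tab, seed = 8))
})
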