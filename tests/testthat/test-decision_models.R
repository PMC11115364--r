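test_that("risk-return utility matches the mean-variance formula", {
  s <- model_spec("risk_return")
  pp <- utility_params(alpha = 0.01, beta = 1)
  # U = mp - alpha m^2 p (1 - p): 20*0.5 - 0.01*400*0.25 = 9
  expect_equal(utility(s, pp, 20, 0.5), 9)
  # vectorized, and the sure option has no variance term
  m <- c(15, 65); p <- c(0.4, 0.6)
  expect_equal(utility(s, pp, m, p), m * p - 0.01 * m^2 * p * (1 - p))
  expect_equal(delta_utility(s, pp, m, p),
               (m * p - 10) - 0.01 * m^2 * p * (1 - p))
})

test_that("Prelec weighting has the right limits and identity case", {
  pr <- riskforage:::prelec
  expect_equal(pr(1, 2), 1)
  expect_equal(pr(0, 2), 0)
  expect_equal(pr(0.37, 1), 0.37)  # gamma = 1 is the identity
  p <- seq(0.05, 0.95, by = 0.1)
  expect_equal(pr(p, 1), p)
  expect_true(all(diff(pr(p, 0.6)) > 0))  # strictly increasing
})

test_that("multiplicative and additive utilities follow Eqs 7-8", {
  pp <- utility_params(beta = 1, gamma = 0.8, lambda = 1.2, w_p = 0.3)
  mult <- model_spec("multiplicative")
  expect_equal(utility(mult, pp, 40, 0.5),
               40^1.2 * exp(-((-log(0.5))^0.8)))
  add <- model_spec("additive")
  expect_equal(utility(add, pp, 40, 0.5),
               0.7 * (40^1.2 / 65^1.2) + 0.3 * exp(-((-log(0.5))^0.8)))
  # additive components are normalized into (0, 1]
  grid <- expand.grid(m = seq(15, 65, 5), p = seq(0.2, 0.8, 0.1))
  u <- utility(add, pp, grid$m, grid$p)
  expect_true(all(u > 0 & u <= 1))
  expect_equal(utility(add, utility_params(w_p = 0), 65, 0.5), 1)
})

test_that("excluded exponents are fixed at one", {
  pp <- utility_params(beta = 1, gamma = 3, lambda = 3)
  s0 <- model_spec("multiplicative", include_lambda = FALSE,
                   include_gamma = FALSE)
  expect_equal(utility(s0, pp, 40, 0.5), 40 * 0.5)
  expect_equal(model_parameters(s0), "beta")
  expect_equal(model_parameters(model_spec("risk_return")),
               c("alpha", "beta"))
  expect_equal(model_parameters(model_spec("additive",
                                           rule = "approach_avoidance")),
               c("beta", "lambda", "gamma", "w_p", "eta"))
})

test_that("the sigmoid rule is Eq 9 and approach-avoidance shifts its range", {
  s <- model_spec("risk_return")
  pp <- utility_params(alpha = 0.01, beta = 0.3)
  du <- delta_utility(s, pp, c(20, 50), c(0.4, 0.6))
  expect_equal(choice_probability(s, pp, c(20, 50), c(0.4, 0.6)),
               1 / (1 + exp(-0.3 * du)))

  aa <- model_spec("risk_return", rule = "approach_avoidance")
  # eta = 0 reduces to the sigmoid
  expect_equal(choice_probability(aa, utility_params(alpha = 0.01, beta = 0.3,
                                                     eta = 0), 20, 0.4),
               choice_probability(s, pp, 20, 0.4))
  # eta = 1 always gambles; eta = -1 never gambles
  expect_equal(choice_probability(aa, utility_params(beta = 1, eta = 1),
                                  20, 0.4), 1)
  expect_equal(choice_probability(aa, utility_params(beta = 1, eta = -1),
                                  20, 0.4), 0)
  # intermediate biases stay inside [0, 1] and order correctly
  lo <- choice_probability(aa, utility_params(alpha = 0.01, beta = 0.3,
                                              eta = -0.5), c(20, 50), 0.5)
  hi <- choice_probability(aa, utility_params(alpha = 0.01, beta = 0.3,
                                              eta = 0.5), c(20, 50), 0.5)
  expect_true(all(lo >= 0 & hi <= 1 & lo < hi))
})

test_that("utility_params enforces its ranges", {
  expect_error(utility_params(beta = -1))
  expect_error(utility_params(beta = 1, gamma = 0))
  expect_error(utility_params(beta = 1, w_p = 1.2))
  expect_error(utility_params(beta = 1, eta = -2))
})

test_that("simulate_choices is deterministic and pays out consistently", {
  s <- model_spec("risk_return")
  ps <- lapply(1:4, function(i) utility_params(alpha = 0.015, beta = 0.3))
  a <- simulate_choices(s, ps, "PR", seed = 6)
  b <- simulate_choices(s, ps, "PR", seed = 6)
  expect_identical(a, b)
  expect_true(all(a$outcome[a$choice == "reject"] == 10))
  acc <- a[a$choice == "accept", ]
  expect_true(all(acc$outcome == 0 | acc$outcome == acc$magnitude))
  expect_equal(nrow(a), 4 * 132)
  # near-deterministic choices at very large beta follow the utility sign
  d <- simulate_choices(s, list(utility_params(alpha = 0, beta = 100)),
                        "PR", seed = 2)
  an <- analyzed_choices(d)
  an <- an[an$magnitude * an$probability != 10, ]  # du = 0 gambles are coin flips
  expect_true(all((an$choice == "accept") ==
                    (an$magnitude * an$probability > 10)))
})
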