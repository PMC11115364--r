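# Bounds of each parameter's natural space (MAP optimization is box
# constrained; open boundaries are clipped by eps).
param_bounds <- function(par) {
  switch(par,
    alpha  = c(-Inf, Inf),
    beta   = c(1e-6, Inf),
    gamma  = c(1e-6, Inf),
    lambda = c(1e-6, Inf),
    w_p    = c(1e-6, 1 - 1e-6),
    eta    = c(-1 + 1e-6, 1 - 1e-6)
  )
}

#' Initial (broad) group-level prior
#'
#' Gamma-distributed parameters (beta, gamma, lambda) start at gamma(1, 0.1)
#' (mean 10), alpha at normal(0, 10), and the bounded parameters (w_p, and
#' eta mapped affinely to [-1, 1]) at uniform beta(1, 1).
#'
#' @param spec A `model_spec`.
#' @return Named list of per-parameter prior descriptors
#'   (`list(family, hyper)`).
#' @export
initial_prior <- function(spec) {
  pr <- lapply(model_parameters(spec), function(par) {
    switch(par,
      alpha = list(family = "normal", hyper = c(mean = 0, sd = 10)),
      beta = , gamma = , lambda =
        list(family = "gamma", hyper = c(shape = 1, rate = 0.1)),
      w_p = , eta = list(family = "beta", hyper = c(a = 1, b = 1))
    )
  })
  names(pr) <- model_parameters(spec)
  pr
}

prior_mean <- function(par, prior) {
  h <- prior$hyper
  switch(prior$family,
    normal = h[["mean"]],
    gamma  = h[["shape"]] / h[["rate"]],
    beta   = {
      m <- h[["a"]] / (h[["a"]] + h[["b"]])
      if (par == "eta") 2 * m - 1 else m
    }
  )
}

log_prior_density <- function(par, x, prior) {
  h <- prior$hyper
  switch(prior$family,
    normal = dnorm(x, h[["mean"]], h[["sd"]], log = TRUE),
    gamma  = dgamma(x, shape = h[["shape"]], rate = h[["rate"]], log = TRUE),
    beta   = {
      u <- if (par == "eta") (x + 1) / 2 else x
      dbeta(u, h[["a"]], h[["b"]], log = TRUE) +
        if (par == "eta") log(0.5) else 0
    }
  )
}

sample_prior <- function(par, n, prior) {
  h <- prior$hyper
  switch(prior$family,
    normal = rnorm(n, h[["mean"]], h[["sd"]]),
    gamma  = rgamma(n, shape = h[["shape"]], rate = h[["rate"]]),
    beta   = {
      u <- rbeta(n, h[["a"]], h[["b"]])
      if (par == "eta") 2 * u - 1 else u
    }
  )
}

# Parameter list without range validation, for optimizer hot paths where
# box constraints already hold (finite-difference probes may graze bounds).
theta_to_params <- function(theta) {
  defaults <- list(alpha = 0, beta = 1, gamma = 1, lambda = 1, w_p = 0.5,
                   eta = 0)
  defaults[names(theta)] <- as.list(theta)
  class(defaults) <- "utility_params"
  defaults
}

# Bernoulli log-likelihood of one participant's accept/reject sequence.
choice_loglik <- function(spec, theta, m, p, y) {
  mu <- choice_probability(spec, theta_to_params(theta), m, p)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

# Central-difference Hessian with steps shrunk near box bounds so the
# objective is only evaluated inside the constraint region.
num_hessian <- function(f, x, lower, upper, h) {
  k <- length(x)
  h <- pmin(h, (upper - x) / 2.5, (x - lower) / 2.5)
  h <- pmax(h, 1e-10)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  pert <- function(i, di, j = NULL, dj = 0) {
    z <- x
    z[i] <- z[i] + di * h[i]
    if (!is.null(j)) z[j] <- z[j] + dj * h[j]
    f(z)
  }
  for (i in seq_len(k)) {
    H[i, i] <- (pert(i, 1) - 2 * f0 + pert(i, -1)) / h[i]^2
    if (i < k) for (j in (i + 1):k) {
      H[i, j] <- H[j, i] <-
        (pert(i, 1, j, 1) - pert(i, 1, j, -1) -
           pert(i, -1, j, 1) + pert(i, -1, j, -1)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' EM fitting configuration
#'
#' @param tol Relative change of the summed MAP objective declaring
#'   convergence.
#' @param max_iter Maximum EM iterations.
#' @param min_var Variance floor used in the moment-matched M-step.
#' @return List of settings.
#' @export
em_config <- function(tol = 1e-4, max_iter = 200L, min_var = 1e-12) {
  list(tol = tol, max_iter = max_iter, min_var = min_var)
}

# Per-participant MAP + Laplace variance under the current prior.
map_one <- function(spec, pars, prior, m, p, y, start) {
  lower <- vapply(pars, function(q) param_bounds(q)[1], numeric(1))
  upper <- vapply(pars, function(q) param_bounds(q)[2], numeric(1))
  scale <- vapply(pars, function(q)
    switch(q, alpha = 1e-2, beta = 0.1, 0.25), numeric(1))
  neg_post <- function(th) {
    names(th) <- pars
    lp <- sum(vapply(pars, function(q)
      log_prior_density(q, th[[q]], prior[[q]]), numeric(1)))
    val <- -(choice_loglik(spec, th, m, p, y) + lp)
    if (!is.finite(val)) val <- 1e10
    val
  }
  # two starts guard against the local optima of the joint likelihood
  # (e.g. beta -> 0 with alpha unidentified): the caller's warm start and a
  # neutral weak-response start (the zero-coefficient convention of logistic
  # models: alpha 0, small beta, exponents 1, wp 1/2, eta 0)
  neutral <- vapply(pars, function(q)
    switch(q, alpha = 0, beta = 0.1, w_p = 0.5, eta = 0, 1), numeric(1))
  starts <- list(pmin(pmax(start, lower + 1e-8), upper - 1e-8),
                 pmin(pmax(neutral, lower + 1e-8), upper - 1e-8))
  # L-BFGS-B's internal line search can go NaN when the optimum sits on a
  # bound (optim() then errors before evaluating the objective), so failed
  # starts are tolerated; if every start fails, fall back to Nelder-Mead on
  # the guarded objective (out-of-bound points already score 1e10) and clamp.
  opts <- lapply(starts, function(s)
    try(optim(s, neg_post, method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(parscale = scale, maxit = 500)), silent = TRUE))
  opts <- opts[!vapply(opts, inherits, logical(1), "try-error")]
  if (length(opts) == 0) {
    nm <- optim(starts[[1]], neg_post, method = "Nelder-Mead",
                control = list(parscale = scale, maxit = 2000))
    nm$par <- pmin(pmax(nm$par, lower + 1e-8), upper - 1e-8)
    nm$value <- neg_post(nm$par)
    opts <- list(nm)
  }
  opt <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
  hess <- num_hessian(neg_post, opt$par, lower, upper, h = 1e-3 * scale)
  var <- rep(NA_real_, length(pars))
  cv <- try(solve(hess), silent = TRUE)
  if (!inherits(cv, "try-error")) var <- diag(cv)
  bad <- !is.finite(var) | var <= 0
  if (any(bad)) var[bad] <- (scale[bad] * 1e-2)^2  # conservative fallback
  names(var) <- pars
  th <- opt$par
  names(th) <- pars
  list(theta = th, var = var, objective = -opt$value,
       covariance = if (inherits(cv, "try-error")) NULL else cv)
}

moment_match <- function(par, m1, v, prior, min_var) {
  v <- max(v, min_var)
  switch(prior$family,
    normal = list(family = "normal", hyper = c(mean = m1, sd = sqrt(v))),
    gamma = {
      m1 <- max(m1, 1e-8)
      # keep the group prior log-concave (shape >= 1, mean preserved): a
      # shape-below-1 gamma has infinite density at 0, which drags weakly
      # identified participants' MAPs to the boundary and makes EM collapse
      shape <- max(m1^2 / v, 1)
      list(family = "gamma", hyper = c(shape = shape, rate = shape / m1))
    },
    beta = {
      u <- if (par == "eta") (m1 + 1) / 2 else m1
      vu <- if (par == "eta") v / 4 else v
      u <- min(max(u, 1e-6), 1 - 1e-6)
      nu <- u * (1 - u) / vu - 1
      if (!is.finite(nu) || nu <= 0) return(prior)  # keep previous prior
      a <- u * nu; b <- (1 - u) * nu
      # same log-concavity floor: rescale (a, b) so both exceed 1,
      # preserving the mean
      if (min(a, b) < 1) {
        f <- 1 / min(a, b)
        a <- a * f; b <- b * f
      }
      list(family = "beta", hyper = c(a = a, b = b))
    }
  )
}

#' Hierarchical expectation-maximization fit of a decision model
#'
#' Fits a decision model to each participant's analyzed choices under a
#' group-level prior, alternating (E) per-participant MAP estimation with a
#' Laplace approximation of the posterior and (M) moment-matched updates of
#' the prior hyperparameters: with E\[theta\] taken as the MAP and
#' E\[theta^2\] as MAP^2 plus the Laplace variance, moments are converted
#' back to each prior family. Iterations stop when the summed MAP objective
#' changes by less than `config$tol` (relative) or `config$max_iter` is
#' reached (flagged via `converged`).
#'
#' @param spec A `model_spec`.
#' @param table Trial table; only analyzed, responded trials are used.
#' @param environment Optional environment name to restrict fitting to.
#' @param config An [em_config()].
#' @param prior Optional starting prior (default [initial_prior()]).
#' @return A `hier_fit` object: `estimates` (data.frame participant x
#'   parameter with `estimate` and `sd`), `prior`, `n_obs`,
#'   `n_hyperparameters`, `objective` trace, `converged`, `spec`, and the
#'   per-participant data needed by [ibic()].
#' @export
fit_hierarchical <- function(spec, table, environment = NULL,
                             config = em_config(), prior = NULL) {
  tt <- analyzed_choices(table)
  if (!is.null(environment))
    tt <- tt[tt$environment == environment, , drop = FALSE]
  ids <- unique(tt$participant_id)
  if (length(ids) < 2) stop("need at least 2 participants")
  dat <- lapply(split(tt, tt$participant_id)[ids], function(d)
    list(m = d$magnitude, p = d$probability,
         y = as.numeric(d$choice == "accept")))
  pars <- model_parameters(spec)
  if (is.null(prior)) prior <- initial_prior(spec)

  starts <- NULL
  trace <- numeric(0)
  maps <- NULL
  for (iter in seq_len(config$max_iter)) {
    start0 <- vapply(pars, function(q) prior_mean(q, prior[[q]]), numeric(1))
    maps <- lapply(seq_along(ids), function(i) {
      st <- if (is.null(starts)) start0 else starts[[i]]
      map_one(spec, pars, prior, dat[[i]]$m, dat[[i]]$p, dat[[i]]$y, st)
    })
    starts <- lapply(maps, `[[`, "theta")
    obj <- sum(vapply(maps, `[[`, numeric(1), "objective"))
    trace <- c(trace, obj)
    th <- do.call(rbind, starts)
    vv <- do.call(rbind, lapply(maps, `[[`, "var"))
    for (q in pars) {
      m1 <- mean(th[, q])
      m2 <- mean(th[, q]^2 + vv[, q])
      prior[[q]] <- moment_match(q, m1, m2 - m1^2, prior[[q]], config$min_var)
    }
    if (iter > 1 &&
        abs(trace[iter] - trace[iter - 1]) <
          config$tol * (abs(trace[iter - 1]) + 1e-8)) break
  }
  est <- do.call(rbind, lapply(seq_along(ids), function(i)
    data.frame(participant_id = ids[i], parameter = pars,
               estimate = unname(maps[[i]]$theta),
               sd = sqrt(unname(maps[[i]]$var)),
               stringsAsFactors = FALSE)))
  rownames(est) <- NULL
  structure(
    list(spec = spec, estimates = est, prior = prior,
         n_obs = sum(vapply(dat, function(d) length(d$y), numeric(1))),
         n_hyperparameters = 2L * length(pars),
         objective = trace,
         converged = length(trace) < config$max_iter,
         data = dat, participants = ids, environment = environment),
    class = "hier_fit"
  )
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf("<hier_fit> %s: %d participants, %d observations, %s after %d EM iterations\n",
              model_label(x$spec), length(x$participants), x$n_obs,
              if (x$converged) "converged" else "NOT converged",
              length(x$objective)))
  for (q in names(x$prior))
    cat(sprintf("  %-6s ~ %s(%s)\n", q, x$prior[[q]]$family,
                paste(sprintf("%s=%.4g", names(x$prior[[q]]$hyper),
                              x$prior[[q]]$hyper), collapse = ", ")))
  invisible(x)
}

#' Integrated BIC of a hierarchical fit
#'
#' Estimates each participant's marginal likelihood by Monte-Carlo averaging
#' the data likelihood over draws from the fitted group prior (log-sum-exp
#' guarded), and returns
#' iBIC = -2 * sum(log marginal likelihood) + n_hyperparameters * log(n_obs).
#'
#' @param fit A `hier_fit`.
#' @param n_prior_samples Prior draws per participant (default 2,000).
#' @param seed Integer seed for the draws.
#' @return The `fit` with elements `ibic`, `log_marginal` (per participant)
#'   added; access the value as `fit$ibic`.
#' @export
ibic <- function(fit, n_prior_samples = 2000L, seed = 1L) {
  pars <- model_parameters(fit$spec)
  local_rng(seed)
  samp <- vapply(pars, function(q)
    sample_prior(q, n_prior_samples, fit$prior[[q]]),
    numeric(n_prior_samples))
  colnames(samp) <- pars
  logmarg <- vapply(fit$data, function(d) {
    ll <- vapply(seq_len(n_prior_samples), function(k) {
      choice_loglik(fit$spec, samp[k, ], d$m, d$p, d$y)
    }, numeric(1))
    mx <- max(ll)
    mx + log(mean(exp(ll - mx)))
  }, numeric(1))
  fit$log_marginal <- logmarg
  fit$ibic <- -2 * sum(logmarg) + fit$n_hyperparameters * log(fit$n_obs)
  fit
}

#' The candidate model set
#'
#' The 9 utility models (risk-return, and the multiplicative and additive
#' families with each combination of including/excluding lambda and gamma)
#' crossed with the requested choice rules: 18 models with both rules.
#'
#' @param rules Choice rules to include.
#' @return List of `model_spec`s.
#' @export
candidate_models <- function(rules = c("sigmoid", "approach_avoidance")) {
  out <- list()
  for (rule in rules) {
    out <- c(out, list(model_spec("risk_return", rule = rule)))
    for (fam in c("multiplicative", "additive"))
      for (il in c(TRUE, FALSE))
        for (ig in c(TRUE, FALSE))
          out <- c(out, list(model_spec(fam, il, ig, rule = rule)))
  }
  out
}

#' Rank fitted models by iBIC
#'
#' @param fits List of `hier_fit` objects that have been passed through
#'   [ibic()].
#' @return Data.frame sorted ascending by iBIC (ties broken toward fewer
#'   hyperparameters) with `delta_ibic` relative to the best model.
#' @export
compare_models <- function(fits) {
  tab <- do.call(rbind, lapply(fits, function(f) {
    if (is.null(f$ibic)) stop("run ibic() on each fit first")
    data.frame(model = model_label(f$spec),
               n_hyperparameters = f$n_hyperparameters, ibic = f$ibic,
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$ibic, tab$n_hyperparameters), , drop = FALSE]
  tab$delta_ibic <- tab$ibic - tab$ibic[1]
  rownames(tab) <- NULL
  tab
}

#' One-tailed t-tests on per-participant parameter estimates
#'
#' Unpaired t-tests between two fits (e.g. two environments or two groups) on
#' the per-participant MAP estimates of the named parameters, one-tailed in
#' the predicted direction, Bonferroni-multiplied by `m_tests` (default: the
#' number of parameters tested).
#'
#' @param fit_a,fit_b `hier_fit` objects.
#' @param parameters Parameter names to test (default: all shared).
#' @param alternative `"greater"` tests mean(a) > mean(b).
#' @param m_tests Bonferroni factor.
#' @return Data.frame (parameter, mean_a, mean_b, t, df, p_raw,
#'   p_bonferroni).
#' @export
parameter_hypothesis_tests <- function(fit_a, fit_b, parameters = NULL,
                                       alternative = c("greater", "less"),
                                       m_tests = NULL) {
  alternative <- match.arg(alternative)
  if (is.null(parameters))
    parameters <- intersect(unique(fit_a$estimates$parameter),
                            unique(fit_b$estimates$parameter))
  if (is.null(m_tests)) m_tests <- length(parameters)
  out <- do.call(rbind, lapply(parameters, function(q) {
    xa <- fit_a$estimates$estimate[fit_a$estimates$parameter == q]
    xb <- fit_b$estimates$estimate[fit_b$estimates$parameter == q]
    tt <- t.test(xa, xb, alternative = alternative)
    data.frame(parameter = q, mean_a = mean(xa), mean_b = mean(xb),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               p_bonferroni = min(1, m_tests * tt$p.value),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
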