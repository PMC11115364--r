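#' Specify a decision model
#'
#' A decision model is a utility family combined with a choice rule. Three
#' utility families are supported:
#' \describe{
#'   \item{risk_return}{mean-variance utility \eqn{U = mp - \alpha m^2 p(1-p)},
#'     where \eqn{\alpha} is the risk-aversiveness (positive = risk-averse).}
#'   \item{multiplicative}{prospect-theory form \eqn{U = v(m)\pi(p)} with value
#'     function \eqn{v(m) = m^\lambda} and Prelec probability weighting
#'     \eqn{\pi(p) = \exp(-(-\log p)^\gamma)}.}
#'   \item{additive}{\eqn{U = (1-w_p)\tilde v(m) + w_p \pi(p)} with both
#'     components normalized to (0, 1]: \eqn{\tilde v(m) = m^\lambda/65^\lambda}
#'     (65 is the largest magnitude in the design) and \eqn{\pi(1) = 1}.}
#' }
#' `lambda` and `gamma` can each be excluded, in which case they are fixed at
#' 1 (the risk-return family ignores both flags). Choice rules are the
#' standard sigmoid \eqn{1/(1+e^{-\beta\Delta U})} or the approach-avoidance
#' rule, which shifts the sigmoid's floor (\eqn{\eta \ge 0}) or ceiling
#' (\eqn{\eta < 0}) by a gambling bias \eqn{\eta \in [-1, 1]}.
#'
#' @param family `"risk_return"`, `"multiplicative"` or `"additive"`.
#' @param include_lambda,include_gamma Fit the value-function exponent
#'   \eqn{\lambda} / weighting exponent \eqn{\gamma}? Fixed at 1 when `FALSE`.
#' @param rule `"sigmoid"` or `"approach_avoidance"`.
#' @return A `model_spec` object.
#' @seealso [utility_params()], [choice_probability()]
#' @export
model_spec <- function(family = c("risk_return", "multiplicative", "additive"),
                       include_lambda = TRUE, include_gamma = TRUE,
                       rule = c("sigmoid", "approach_avoidance")) {
  family <- match.arg(family)
  rule <- match.arg(rule)
  if (family == "risk_return") include_lambda <- include_gamma <- FALSE
  structure(
    list(family = family, include_lambda = include_lambda,
         include_gamma = include_gamma, rule = rule),
    class = "model_spec"
  )
}

#' Names of the free parameters of a model
#' @param spec A `model_spec`.
#' @return Character vector of parameter names in canonical order.
#' @export
model_parameters <- function(spec) {
  pars <- "beta"
  if (spec$family == "risk_return") pars <- c("alpha", pars)
  if (spec$family %in% c("multiplicative", "additive")) {
    if (spec$include_lambda) pars <- c(pars, "lambda")
    if (spec$include_gamma) pars <- c(pars, "gamma")
  }
  if (spec$family == "additive") pars <- c(pars, "w_p")
  if (spec$rule == "approach_avoidance") pars <- c(pars, "eta")
  pars
}

#' Model identifier string
#' @param spec A `model_spec`.
#' @return A short label such as `"additive(lambda,gamma)+sigmoid"`.
#' @export
model_label <- function(spec) {
  inc <- c(if (spec$include_lambda) "lambda", if (spec$include_gamma) "gamma")
  fam <- if (spec$family == "risk_return") "risk_return" else
    sprintf("%s(%s)", spec$family, paste(inc, collapse = ","))
  paste0(fam, "+", spec$rule)
}

#' Construct and validate a parameter vector
#'
#' Range constraints are enforced here, not at evaluation time: `beta`,
#' `gamma`, `lambda` must be positive, `w_p` lies in [0, 1] and `eta` in
#' [-1, 1]. Parameters a model excludes default to 1 (`eta` to 0, `alpha`
#' unused outside risk-return).
#'
#' @param alpha Risk-aversiveness (risk-return family only; any real).
#' @param beta Inverse temperature, > 0.
#' @param gamma Prelec weighting exponent, > 0.
#' @param lambda Value-function exponent, > 0.
#' @param w_p Probability weight of the additive family, in [0, 1].
#' @param eta Approach-avoidance gambling bias, in [-1, 1].
#' @return A `utility_params` object (named list).
#' @export
utility_params <- function(alpha = 0, beta = 1, gamma = 1, lambda = 1,
                           w_p = 0.5, eta = 0) {
  stopifnot(is.finite(alpha), is.finite(beta), beta > 0, gamma > 0, lambda > 0,
            w_p >= 0, w_p <= 1, eta >= -1, eta <= 1)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda,
                 w_p = w_p, eta = eta),
            class = "utility_params")
}

#' Sure option common to all trials
#'
#' Rejecting any gamble yields a guaranteed 10 points; under the
#' prospect-theory families its utility is computed with the same value and
#' weighting functions applied to (m = 10, p = 1).
#' @return List with `magnitude = 10`, `probability = 1`.
#' @export
sure_option <- function() list(magnitude = 10, probability = 1)

prelec <- function(p, gamma) {
  # continuous limit pi(0) = 0 avoids log(0)
  out <- ifelse(p <= 0, 0, exp(-((-log(pmax(p, 1e-300)))^gamma)))
  ifelse(p >= 1, 1, out)
}

#' Utility of a gamble under a model
#'
#' @param spec A `model_spec`.
#' @param params A `utility_params`.
#' @param m Reward magnitude(s), points.
#' @param p Reward probability(ies) in [0, 1].
#' @return Numeric utility, vectorized over `m`/`p`.
#' @examples
#' s <- model_spec("risk_return")
#' utility(s, utility_params(alpha = 0.01, beta = 1), 20, 0.5)  # 9
#' @export
utility <- function(spec, params, m, p) {
  switch(spec$family,
    risk_return = m * p - params$alpha * m^2 * p * (1 - p),
    multiplicative = {
      lam <- if (spec$include_lambda) params$lambda else 1
      gam <- if (spec$include_gamma) params$gamma else 1
      m^lam * prelec(p, gam)
    },
    additive = {
      lam <- if (spec$include_lambda) params$lambda else 1
      gam <- if (spec$include_gamma) params$gamma else 1
      (1 - params$w_p) * (m^lam / 65^lam) + params$w_p * prelec(p, gam)
    }
  )
}

#' Excess utility of accepting a gamble over the sure 10 points
#'
#' For the risk-return family this is \eqn{(mp - 10) - \alpha m^2 p (1-p)}
#' since the sure option carries no variance.
#'
#' @inheritParams utility
#' @return Numeric, vectorized.
#' @export
delta_utility <- function(spec, params, m, p) {
  s <- sure_option()
  utility(spec, params, m, p) - utility(spec, params, s$magnitude, s$probability)
}

#' Probability of accepting a gamble
#'
#' Sigmoid rule: \eqn{1/(1+e^{-\beta\Delta U})}. Approach-avoidance rule:
#' the sigmoid is compressed toward 1 when \eqn{\eta \ge 0}
#' (\eqn{(1-\eta)\,\mathrm{sig} + \eta}) and toward 0 when \eqn{\eta < 0}
#' (\eqn{(1+\eta)\,\mathrm{sig}}); the result always lies in [0, 1].
#'
#' @inheritParams utility
#' @return Acceptance probability, vectorized.
#' @export
choice_probability <- function(spec, params, m, p) {
  du <- delta_utility(spec, params, m, p)
  sig <- plogis(params$beta * du)
  if (spec$rule == "approach_avoidance") {
    if (params$eta >= 0) (1 - params$eta) * sig + params$eta
    else (1 + params$eta) * sig
  } else {
    sig
  }
}

#' Simulate choices and outcomes on a schedule
#'
#' Generative counterpart of the decision models: each trial is accepted with
#' [choice_probability()]; accepted gambles pay the magnitude with the stated
#' probability and 0 otherwise; rejected trials pay the sure 10 points.
#'
#' @param spec A `model_spec`.
#' @param params_list List of `utility_params`, one per simulated participant.
#' @param group Group name passed to [generate_experiment_schedule()], or a
#'   precomputed schedule data.frame applied to every participant.
#' @param seed Integer seed.
#' @param participant_prefix Prefix for generated participant ids.
#' @return A long-format trial table (one row per participant x trial) with
#'   `choice` (`"accept"`/`"reject"`) and `outcome` columns appended.
#' @export
simulate_choices <- function(spec, params_list, group, seed,
                             participant_prefix = "sim") {
  shared_schedule <- is.data.frame(group)
  tables <- lapply(seq_along(params_list), function(i) {
    sched <- if (shared_schedule) group else
      generate_experiment_schedule(group, seed = derive_seed(seed, i))
    local_rng(derive_seed(seed, 100000L + i))
    pr <- choice_probability(spec, params_list[[i]], sched$magnitude,
                             sched$probability)
    accept <- runif(nrow(sched)) < pr
    win <- runif(nrow(sched)) < sched$probability
    sched$choice <- ifelse(accept, "accept", "reject")
    sched$outcome <- ifelse(accept, ifelse(win, sched$magnitude, 0), 10)
    cbind(participant_id = sprintf("%s%03d", participant_prefix, i), sched,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  out
}
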