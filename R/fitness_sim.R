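#' Need conditions for the fitness simulation
#'
#' "Need" is the minimum number of points an agent must accumulate over the
#' 60-trial horizon to survive: 850 (high need), 1000 (moderate) and 1150
#' (low). Note the labels follow the framing that a higher survival threshold
#' relative to what the environment affords corresponds to *lower* slack.
#'
#' @param label `"high"`, `"moderate"` or `"low"`.
#' @param threshold Override the survival threshold (points).
#' @param horizon Number of trials (default 60).
#' @return A `need_condition` list.
#' @export
need_condition <- function(label = c("high", "moderate", "low"),
                           threshold = NULL, horizon = 60L) {
  label <- match.arg(label)
  if (is.null(threshold))
    threshold <- c(high = 850, moderate = 1000, low = 1150)[[label]]
  structure(list(label = label, threshold = threshold,
                 horizon = as.integer(horizon)),
            class = "need_condition")
}

# Expected points from one uniform draw off the environment's non-catch grid
# under the risk-return utility with deterministic accept-iff-better choices.
expected_trial_reward <- function(env, alpha) {
  grid <- expand.grid(m = env$magnitudes, p = env$probabilities)
  u <- grid$m * grid$p - alpha * grid$m^2 * grid$p * (1 - grid$p)
  mean(ifelse(u > 10, grid$m * grid$p, 10))
}

#' Analytic expected accumulated reward in the deterministic choice limit
#'
#' With trials drawn uniformly (with replacement) from the environment's
#' non-catch grid and choices made by strict utility maximization under the
#' risk-return model, the expected total over the horizon is simply
#' `horizon` times the per-trial expectation of `max(EV, 10)` restricted to
#' the chosen option.
#'
#' @param env An `environment_spec`.
#' @param alpha Risk-aversiveness.
#' @param horizon Number of trials.
#' @return Expected accumulated points.
#' @export
expected_accumulated_reward <- function(env, alpha, horizon = 60L) {
  horizon * expected_trial_reward(env, alpha)
}

#' Simulate survival probability and mean reward at one grid point
#'
#' Each of `n_agents` agents faces `need$horizon` gambles drawn uniformly with
#' replacement from the environment's non-catch grid, choosing via the
#' risk-return model: stochastically through the sigmoid rule with inverse
#' temperature `beta`, or by strict utility maximization when
#' `deterministic = TRUE`.
#'
#' @param env An `environment_spec`.
#' @param alpha Risk-aversiveness.
#' @param need A `need_condition`.
#' @param n_agents Number of simulated agents.
#' @param beta Inverse temperature for the sigmoid rule.
#' @param deterministic Use the utility-maximizing choice limit?
#' @param seed Integer seed.
#' @return List with `survival_prob` (fraction of agents reaching the
#'   threshold) and `mean_reward` (mean total points).
#' @export
simulate_fitness_point <- function(env, alpha, need, n_agents = 10000L,
                                   beta = 0.1, deterministic = FALSE,
                                   seed = 1L) {
  grid <- expand.grid(m = env$magnitudes, p = env$probabilities)
  if (nrow(grid) == 0) stop("empty gamble grid")
  local_rng(seed)
  n <- n_agents * need$horizon
  idx <- sample.int(nrow(grid), n, replace = TRUE)
  m <- grid$m[idx]; p <- grid$p[idx]
  du <- (m * p - 10) - alpha * m^2 * p * (1 - p)
  accept <- if (deterministic) du > 0 else runif(n) < plogis(beta * du)
  gain <- ifelse(accept, ifelse(runif(n) < p, m, 0), 10)
  totals <- rowSums(matrix(gain, nrow = n_agents))
  list(survival_prob = mean(totals >= need$threshold),
       mean_reward = mean(totals))
}

#' Sweep fitness curves over a risk-aversiveness grid
#'
#' @param env An `environment_spec`.
#' @param alpha_grid Numeric grid of risk-aversiveness values; the default 41
#'   equally spaced points in [-0.02, 0.02] matches the magnitude of the
#'   particle-filter estimates.
#' @param needs List of `need_condition`s (default all three).
#' @inheritParams simulate_fitness_point
#' @return A tidy data.frame (environment, need, threshold, alpha,
#'   survival_prob, mean_reward), one row per grid point and need.
#' @export
fitness_curves <- function(env, alpha_grid = seq(-0.02, 0.02, length.out = 41),
                           needs = lapply(c("high", "moderate", "low"),
                                          need_condition),
                           n_agents = 10000L, beta = 0.1,
                           deterministic = FALSE, seed = 1L) {
  rows <- list()
  for (nd in needs) {
    for (k in seq_along(alpha_grid)) {
      pt <- simulate_fitness_point(env, alpha_grid[k], nd, n_agents, beta,
                                   deterministic,
                                   seed = derive_seed(seed, k))
      rows[[length(rows) + 1L]] <- data.frame(
        environment = env$name, need = nd$label, threshold = nd$threshold,
        alpha = alpha_grid[k], survival_prob = pt$survival_prob,
        mean_reward = pt$mean_reward
      )
    }
  }
  do.call(rbind, rows)
}

#' Grid optimum of a fitness curve
#'
#' Returns the grid alpha maximizing the chosen criterion. Ties (within
#' `tol`) are broken toward the smallest absolute alpha, then toward the more
#' negative value.
#'
#' @param curve A data.frame with columns `alpha` and the criterion column
#'   (`survival_prob` or `mean_reward`), e.g. one need-slice of
#'   [fitness_curves()].
#' @param criterion `"survival"` or `"mean_reward"`.
#' @param tol Values within `tol` of the maximum count as tied.
#' @return The optimal alpha.
#' @export
optimal_alpha <- function(curve, criterion = c("survival", "mean_reward"),
                          tol = 1e-12) {
  criterion <- match.arg(criterion)
  y <- if (criterion == "survival") curve$survival_prob else curve$mean_reward
  stopifnot(length(y) > 0)
  cand <- curve$alpha[y >= max(y) - tol]
  cand <- cand[order(abs(cand), cand)]
  cand[1]
}
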