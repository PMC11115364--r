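#' Particle filter configuration
#'
#' @param sigma Scale of the Cauchy random-walk transition of the latent
#'   risk-aversiveness.
#' @param beta Inverse temperature of the observation (choice) model.
#' @param n_particles Number of particles (10,000 by default; analyses of
#'   moderate size reproduce these results with a few thousand).
#' @param lag Fixed-lag smoothing lag L (Kitagawa's recommendation L = 20).
#' @param init_sd SD of the normal draw initializing the latent state.
#' @param seed Integer seed.
#' @return A `pf_config` list.
#' @export
pf_config <- function(sigma = 1e-3, beta = 0.5, n_particles = 10000L,
                      lag = 20L, init_sd = 1, seed = 1L) {
  stopifnot(sigma > 0, beta > 0, n_particles >= 100, lag >= 0)
  list(sigma = sigma, beta = beta, n_particles = as.integer(n_particles),
       lag = as.integer(lag), init_sd = init_sd, seed = seed)
}

# Reshape a group trial table into trial-by-participant matrices. All
# participants must share the design length; non-analyzed and missing trials
# are masked (contribute no likelihood).
align_group_table <- function(table) {
  ids <- unique(table$participant_id)
  tmax <- max(table$trial_index)
  M <- P <- Y <- matrix(NA_real_, nrow = tmax, ncol = length(ids))
  for (j in seq_along(ids)) {
    tt <- table[table$participant_id == ids[j], , drop = FALSE]
    if (nrow(tt) != tmax)
      stop("participants do not share the design length")
    o <- order(tt$trial_index)
    tt <- tt[o, ]
    M[, j] <- tt$magnitude
    P[, j] <- tt$probability
    use <- tt$analyzed & tt$choice != "missing"
    Y[use, j] <- as.numeric(tt$choice[use] == "accept")
  }
  list(M = M, P = P, Y = Y, ids = ids, n_trials = tmax)
}

log1pexp <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

# Bernoulli observation log-likelihood of all unmasked choices at trial t,
# evaluated at each particle's alpha.
pf_obs_loglik_factory <- function(aligned, beta) {
  ev <- aligned$M * aligned$P - 10
  rk <- aligned$M^2 * aligned$P * (1 - aligned$P)
  function(x, t) {
    use <- which(!is.na(aligned$Y[t, ]))
    if (length(use) == 0) return(NULL)
    z <- beta * (matrix(ev[t, use], nrow = length(x), ncol = length(use),
                        byrow = TRUE) - outer(x, rk[t, use]))
    y <- aligned$Y[t, use]
    ll <- sweep(z, 2, y, `*`) - log1pexp(z)
    rowSums(ll)
  }
}

systematic_resample <- function(logw) {
  n <- length(logw)
  w <- exp(logw - max(logw))
  cw <- cumsum(w) / sum(w)
  u <- (runif(1) + 0:(n - 1)) / n
  findInterval(u, cw) + 1L
}

#' Generic bootstrap particle filter with fixed-lag smoothing
#'
#' The workhorse behind [run_filter()], exposed so alternative transition and
#' observation models can be filtered with the identical algorithm (systematic
#' resampling at every informative step, fixed-lag smoothing by genealogy over
#' a rolling lag buffer; the final `lag` steps fall back to the terminal
#' filtering distribution).
#'
#' @param n_steps Number of time steps.
#' @param init Function(n) returning n initial particle states.
#' @param transition Function(x, t) propagating the particle vector.
#' @param obs_loglik Function(x, t) returning per-particle observation
#'   log-likelihoods, or NULL for steps without observations.
#' @param n_particles Number of particles.
#' @param lag Fixed smoothing lag.
#' @param seed Integer seed.
#' @param probs Quantiles reported per step (median and 90% band).
#' @return List with `smoothed` and `filtered` (matrices n_steps x
#'   length(probs)), `loglik_increments` and `total_loglik`.
#' @export
particle_filter_core <- function(n_steps, init, transition, obs_loglik,
                                 n_particles, lag, seed = 1L,
                                 probs = c(0.05, 0.5, 0.95)) {
  local_rng(seed)
  x <- init(n_particles)
  buf <- matrix(numeric(0), nrow = n_particles, ncol = 0)
  smoothed <- filtered <- matrix(NA_real_, nrow = n_steps,
                                 ncol = length(probs))
  incr <- numeric(n_steps)
  for (t in seq_len(n_steps)) {
    x <- transition(x, t)
    buf <- cbind(buf, x)
    lw <- obs_loglik(x, t)
    if (!is.null(lw)) {
      mx <- max(lw)
      incr[t] <- mx + log(mean(exp(lw - mx)))
      idx <- systematic_resample(lw)
      buf <- buf[idx, , drop = FALSE]
      x <- buf[, ncol(buf)]
    }
    filtered[t, ] <- quantile(x, probs)
    if (ncol(buf) == lag + 1L) {
      smoothed[t - lag, ] <- quantile(buf[, 1], probs)
      buf <- buf[, -1, drop = FALSE]
    }
  }
  done <- n_steps - ncol(buf)
  if (ncol(buf) > 0)
    for (k in seq_len(ncol(buf)))
      smoothed[done + k, ] <- quantile(buf[, k], probs)
  list(smoothed = smoothed, filtered = filtered, loglik_increments = incr,
       total_loglik = sum(incr))
}

#' Filter the latent group-level risk-aversiveness trajectory
#'
#' Estimates the trial-by-trial risk-aversiveness alpha_t shared by a group
#' from its pooled choices. Each participant's accept/reject on trial t is a
#' Bernoulli draw with probability sigmoid(beta * dU), where
#' dU = (mp - 10) - alpha_t m^2 p (1 - p), and alpha_t follows a Cauchy
#' random walk with scale sigma. Non-analyzed and missing trials contribute
#' no likelihood; an all-masked trial propagates the state without an update.
#'
#' @param table Trial table of one group (shared design length).
#' @param config A [pf_config()].
#' @return A `latent_trajectory` object: data.frame `trajectory`
#'   (`trial_index`, `median`, `lo90`, `hi90` from the fixed-lag smoother,
#'   filtered counterparts, `loglik_increment`), plus `total_loglik` and the
#'   `config`.
#' @export
run_filter <- function(table, config = pf_config()) {
  aligned <- align_group_table(table)
  obs <- pf_obs_loglik_factory(aligned, config$beta)
  res <- particle_filter_core(
    n_steps = aligned$n_trials,
    init = function(n) rnorm(n, 0, config$init_sd),
    transition = function(x, t) x + config$sigma * rcauchy(length(x)),
    obs_loglik = obs,
    n_particles = config$n_particles, lag = config$lag, seed = config$seed
  )
  traj <- data.frame(
    trial_index = seq_len(aligned$n_trials),
    median = res$smoothed[, 2], lo90 = res$smoothed[, 1],
    hi90 = res$smoothed[, 3],
    filtered_median = res$filtered[, 2], filtered_lo90 = res$filtered[, 1],
    filtered_hi90 = res$filtered[, 3],
    loglik_increment = res$loglik_increments
  )
  structure(list(trajectory = traj, total_loglik = res$total_loglik,
                 config = config),
            class = "latent_trajectory")
}

#' @export
print.latent_trajectory <- function(x, ...) {
  cat(sprintf("<latent_trajectory> %d trials, log marginal likelihood %.2f (sigma = %g, beta = %g, %d particles, lag %d)\n",
              nrow(x$trajectory), x$total_loglik, x$config$sigma,
              x$config$beta, x$config$n_particles, x$config$lag))
  invisible(x)
}

#' Fixed-lag smoothed trajectory at a given lag
#'
#' Convenience wrapper re-running the filter with the requested lag (the
#' smoother is computed on-line from the particle genealogy); `lag = 0`
#' returns the filtered trajectory.
#'
#' @param table Trial table of one group.
#' @param config A [pf_config()]; its `lag` is overridden.
#' @param lag Smoothing lag.
#' @return A `latent_trajectory`.
#' @export
fixed_lag_smooth <- function(table, config = pf_config(), lag = 20L) {
  config$lag <- as.integer(lag)
  run_filter(table, config)
}

#' Grid search over the transition scale and inverse temperature
#'
#' Maximizes the total log marginal likelihood over a grid of (sigma, beta):
#' by default 50 log-spaced sigma in [1e-5, 1e-1] by 50 equally spaced beta
#' in [0.1, 1]. A reduced particle count can be used for scoring the grid
#' (`n_particles_search`); the filter and smoother are re-run at the argmax
#' with the full configuration. Common random numbers (one seed for every
#' grid point) keep the surface comparable across points.
#'
#' @param table Trial table of one group.
#' @param sigma_grid,beta_grid Numeric grids.
#' @param config A [pf_config()] used for the final run.
#' @param n_particles_search Particles used while scoring the grid.
#' @return List with `sigma`, `beta`, `trajectory` (final
#'   `latent_trajectory`) and `surface` (data.frame sigma, beta, loglik).
#' @export
grid_search <- function(table,
                        sigma_grid = exp(seq(log(1e-5), log(1e-1),
                                             length.out = 50)),
                        beta_grid = seq(0.1, 1, length.out = 50),
                        config = pf_config(),
                        n_particles_search = config$n_particles) {
  aligned <- align_group_table(table)
  grid <- expand.grid(sigma = sigma_grid, beta = beta_grid)
  ll <- vapply(seq_len(nrow(grid)), function(i) {
    obs <- pf_obs_loglik_factory(aligned, grid$beta[i])
    res <- particle_filter_core(
      n_steps = aligned$n_trials,
      init = function(n) rnorm(n, 0, config$init_sd),
      transition = function(x, t) x + grid$sigma[i] * rcauchy(length(x)),
      obs_loglik = obs, n_particles = n_particles_search,
      lag = 0L, seed = config$seed
    )
    res$total_loglik
  }, numeric(1))
  best <- which.max(ll)
  cfg <- config
  cfg$sigma <- grid$sigma[best]
  cfg$beta <- grid$beta[best]
  traj <- run_filter(table, cfg)
  list(sigma = cfg$sigma, beta = cfg$beta, trajectory = traj,
       surface = cbind(grid, loglik = ll))
}

#' Step-change recovery experiment for the particle filter
#'
#' Simulates a group of participants whose shared risk-aversiveness follows a
#' step profile (alpha_start in the first block, alpha_start + delta_alpha in
#' the second), generates choices on per-participant poor-then-rich task
#' schedules, estimates the trajectory by grid search plus fixed-lag
#' smoothing, and reports how well the step is recovered.
#'
#' @param n_participants Simulated participants (120 matches the study's
#'   simulation scale).
#' @param delta_alpha Size of the step (default 0.2e-2).
#' @param alpha_start Pre-step risk-aversiveness.
#' @param beta_true Inverse temperature generating the choices.
#' @param config A [pf_config()] for the final run.
#' @param sigma_grid,beta_grid Grids for [grid_search()].
#' @param n_particles_search Particles for grid scoring.
#' @param settle Trials dropped after the step (and at the start of the
#'   experiment) when measuring plateau levels.
#' @param seed Integer seed.
#' @return List with `trajectory`, the selected `sigma` and `beta`, the
#'   `true_alpha` path, `plateau_estimate` (estimated step size),
#'   `delta_alpha`, and `coverage` (fraction of trials with the true path
#'   inside the 90% band).
#' @export
recovery_experiment <- function(n_participants = 120L, delta_alpha = 0.2e-2,
                                alpha_start = 1.6e-2, beta_true = 0.3,
                                config = pf_config(n_particles = 2000L),
                                sigma_grid = exp(seq(log(1e-5), log(1e-2),
                                                     length.out = 12)),
                                beta_grid = seq(0.1, 0.7, by = 0.05),
                                n_particles_search = 500L,
                                settle = 10L, seed = 1L) {
  tables <- lapply(seq_len(n_participants), function(i) {
    sched <- generate_experiment_schedule("PR", seed = derive_seed(seed, i))
    sched$participant_id <- sprintf("rec%03d", i)
    sched
  })
  tab <- do.call(rbind, tables)
  tmax <- max(tab$trial_index)
  step_at <- block_length(build_environment("poor")) + 1L
  true_alpha <- ifelse(seq_len(tmax) < step_at, alpha_start,
                       alpha_start + delta_alpha)
  local_rng(derive_seed(seed, 999983L))
  a <- true_alpha[tab$trial_index]
  du <- (tab$magnitude * tab$probability - 10) -
    a * tab$magnitude^2 * tab$probability * (1 - tab$probability)
  accept <- runif(nrow(tab)) < plogis(beta_true * du)
  tab$choice <- ifelse(accept, "accept", "reject")
  tab$outcome <- ifelse(accept,
                        ifelse(runif(nrow(tab)) < tab$probability,
                               tab$magnitude, 0), 10)

  gs <- grid_search(tab, sigma_grid, beta_grid, config, n_particles_search)
  traj <- gs$trajectory$trajectory
  w1 <- seq.int(settle + 1L, step_at - 1L)
  w2 <- seq.int(step_at + settle, tmax)
  plateau <- mean(traj$median[w2]) - mean(traj$median[w1])
  coverage <- mean(true_alpha >= traj$lo90 & true_alpha <= traj$hi90)
  list(trajectory = gs$trajectory, sigma = gs$sigma, beta = gs$beta,
       true_alpha = true_alpha, plateau_estimate = plateau,
       delta_alpha = delta_alpha, coverage = coverage, table = tab)
}

#' Simulate choices from an estimated risk-aversiveness trajectory
#'
#' Draws each trial's choice from the sigmoid risk-return rule evaluated at
#' the trajectory's median alpha for that trial index, on the gamble
#' parameters of the supplied schedules.
#'
#' @param trajectory A `latent_trajectory` (or its `trajectory` data.frame).
#' @param table Trial table providing per-participant (m, p) and trial
#'   indices (choices/outcomes in it are ignored).
#' @param beta Inverse temperature (defaults to the trajectory's config).
#' @param seed Integer seed.
#' @return The table with simulated `choice` and `outcome` columns.
#' @export
simulate_from_trajectory <- function(trajectory, table, beta = NULL,
                                     seed = 1L) {
  if (inherits(trajectory, "latent_trajectory")) {
    if (is.null(beta)) beta <- trajectory$config$beta
    trajectory <- trajectory$trajectory
  }
  stopifnot(!is.null(beta))
  alpha <- trajectory$median[match(table$trial_index,
                                   trajectory$trial_index)]
  local_rng(seed)
  du <- (table$magnitude * table$probability - 10) -
    alpha * table$magnitude^2 * table$probability * (1 - table$probability)
  accept <- runif(nrow(table)) < plogis(beta * du)
  table$choice <- ifelse(accept, "accept", "reject")
  table$outcome <- ifelse(accept,
                          ifelse(runif(nrow(table)) < table$probability,
                                 table$magnitude, 0), 10)
  table
}
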