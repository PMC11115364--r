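#' Configuration of the synthetic cohort generator
#'
#' The generator produces trial tables with the statistical structure the
#' downstream analyses assume: participants choose via the risk-return model
#' with a sigmoid rule, and each participant's effective risk-aversiveness on
#' trial t is
#' \deqn{\alpha_t = \alpha_0 - w_{env}\,\Delta p_c - w_{past}\,\Delta p_p +
#'   w_{acc}\, z(\mathrm{acc.\ reward}),}
#' where \eqn{\Delta p_c} is the option's reward-probability deviation from
#' the current environment's mean, \eqn{\Delta p_p} the current-minus-previous
#' environment mean difference (0 in the first block), and the accumulated
#' reward is detrended by a typical per-trial gain and scaled before entering
#' (see `acc_center_rate`, `acc_scale`). A perseveration bias (+/-
#' `perseveration` utility points depending on the previous choice) is added
#' to the utility difference. Non-responses are injected at
#' `nonresponse_rate`. Catch trials present dominated options whose correct
#' answer is self-evident, so attentive participants answer them correctly up
#' to a small lapse rate (`catch_lapse`); a configurable fraction of
#' inattentive participants instead answers them at chance, tripping the
#' catch-error exclusion criterion.
#'
#' Defaults place the population mean risk-aversiveness at 1.8e-2 with SD
#' 0.4e-2 and inverse temperature around 0.2, the scale of the group-level
#' estimates the task elicits, and the current-environment weight at 2e-2 so
#' that the poor-versus-rich contrast in effective alpha is about 0.4e-2.
#'
#' @param n_per_group Participants per group.
#' @param alpha0_mean,alpha0_sd Population distribution of baseline
#'   risk-aversiveness (normal).
#' @param beta_shape,beta_rate Population distribution of inverse temperature
#'   (gamma; defaults give mean 0.2).
#' @param env_effect Weight of the current-environment deviation on alpha.
#' @param past_effect Weight of the past-environment difference on alpha.
#' @param acc_effect Weight of the scaled accumulated reward on alpha.
#' @param acc_center_rate,acc_scale Accumulated reward enters as
#'   `(acc - acc_center_rate * (t-1)) / acc_scale`.
#' @param perseveration Utility bonus (+) for repeating an accept, penalty
#'   (-) after a reject.
#' @param nonresponse_rate Per-trial probability of a missing response.
#' @param catch_lapse Error probability of attentive participants on catch
#'   trials.
#' @param inattentive_fraction Fraction of participants answering catch
#'   trials at chance.
#' @param seed Master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 120L,
                          alpha0_mean = 1.8e-2, alpha0_sd = 0.4e-2,
                          beta_shape = 16, beta_rate = 80,
                          env_effect = 2e-2, past_effect = 1e-2,
                          acc_effect = 0.2e-2,
                          acc_center_rate = 15, acc_scale = 200,
                          perseveration = 2,
                          nonresponse_rate = 0.003,
                          catch_lapse = 0.02,
                          inattentive_fraction = 0,
                          seed = 1L) {
  stopifnot(n_per_group >= 1, nonresponse_rate >= 0, nonresponse_rate <= 1,
            inattentive_fraction >= 0, inattentive_fraction <= 1,
            catch_lapse >= 0, catch_lapse <= 0.5,
            alpha0_sd >= 0, beta_shape > 0, beta_rate > 0, acc_scale > 0)
  structure(as.list(environment()), class = "cohort_config")
}

env_mean_probability <- function(environment) {
  vapply(environment, function(e) build_environment(e)$mean_probability,
         numeric(1))
}

# Previous-block mean reward probability per block index, given the group's
# block order; the first block has no past environment.
past_mean_probability <- function(group) {
  envs <- group_block_order(group)
  means <- env_mean_probability(envs)
  c(NA_real_, means[-length(means)])
}

simulate_participant <- function(cfg, group, pid, alpha0, beta, inattentive,
                                 seed) {
  sched <- generate_experiment_schedule(group, seed = derive_seed(seed, 1))
  local_rng(derive_seed(seed, 2))
  n <- nrow(sched)
  p_cur_mean <- env_mean_probability(sched$environment)
  p_past <- past_mean_probability(group)[sched$block_index]
  dpp <- ifelse(is.na(p_past), 0, p_cur_mean - p_past)

  choice <- character(n)
  outcome <- rep(NA_real_, n)
  acc <- 0
  prev_accept <- NA
  nonresp <- runif(n) < cfg$nonresponse_rate
  u_choice <- runif(n)
  u_win <- runif(n)
  u_catch <- runif(n)
  for (t in seq_len(n)) {
    if (nonresp[t]) {
      choice[t] <- "missing"
      prev_accept <- NA
      next
    }
    m <- sched$magnitude[t]; p <- sched$probability[t]
    if (sched$catch_type[t] != "none") {
      # dominated options: attentive participants err only by lapses,
      # inattentive participants answer at chance
      correct <- sched$catch_type[t] == "always_accept"
      p_accept <- if (inattentive) 0.5 else
        if (correct) 1 - cfg$catch_lapse else cfg$catch_lapse
      accept <- u_catch[t] < p_accept
    } else {
      dpc <- p - p_cur_mean[t]
      z_acc <- (acc - cfg$acc_center_rate * (t - 1)) / cfg$acc_scale
      alpha_t <- alpha0 - cfg$env_effect * dpc - cfg$past_effect * dpp[t] +
        cfg$acc_effect * z_acc
      du <- (m * p - 10) - alpha_t * m^2 * p * (1 - p)
      if (!is.na(prev_accept))
        du <- du + cfg$perseveration * (if (prev_accept) 1 else -1)
      accept <- u_choice[t] < plogis(beta * du)
    }
    if (accept) {
      outcome[t] <- if (u_win[t] < p) m else 0
      choice[t] <- "accept"
    } else {
      outcome[t] <- 10
      choice[t] <- "reject"
    }
    acc <- acc + outcome[t]
    prev_accept <- accept
  }
  cbind(data.frame(participant_id = pid, stringsAsFactors = FALSE),
        sched, choice = choice, outcome = outcome)
}

#' Generate a synthetic cohort
#'
#' @param config A [cohort_config()].
#' @param groups Character vector of groups to generate (defaults to both
#'   Experiment 1 groups; use `c("IPI", "IRI")` for Experiment 2 or all four).
#' @return A long-format trial table with one row per participant and trial
#'   (columns as in [read_trial_table()]); the per-participant ground-truth
#'   parameters are attached as the `"ground_truth"` attribute.
#' @export
generate_cohort <- function(config, groups = c("PR", "RP")) {
  stopifnot(inherits(config, "cohort_config"))
  tables <- list()
  truths <- list()
  for (g in seq_along(groups)) {
    group <- groups[g]
    gseed <- derive_seed(config$seed, 1000L * g)
    local_rng(gseed)
    n <- config$n_per_group
    alpha0 <- rnorm(n, config$alpha0_mean, config$alpha0_sd)
    beta <- rgamma(n, config$beta_shape, config$beta_rate)
    inattentive <- runif(n) < config$inattentive_fraction
    for (i in seq_len(n)) {
      pid <- sprintf("%s_%03d", group, i)
      tables[[length(tables) + 1L]] <- simulate_participant(
        config, group, pid, alpha0[i], beta[i], inattentive[i],
        seed = derive_seed(gseed, i)
      )
      truths[[length(truths) + 1L]] <- data.frame(
        participant_id = pid, group = group, alpha0 = alpha0[i],
        beta = beta[i], inattentive = inattentive[i],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  truth <- do.call(rbind, truths)
  truth$env_effect <- config$env_effect
  truth$past_effect <- config$past_effect
  truth$acc_effect <- config$acc_effect
  truth$perseveration <- config$perseveration
  attr(out, "ground_truth") <- truth
  out
}
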