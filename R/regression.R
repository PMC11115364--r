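history_regressor_names <- function(lags = 1L) {
  c("prev_choice", if (lags >= 2) paste0("prev_choice", 2:lags),
    "prev_reward", "prev_success", "acc_reward")
}

#' Names of the choice-regression regressors
#'
#' `ev` (expected value m*p), `risk` (outcome variance m^2 p (1-p)), `dpc`
#' (probability minus current-environment mean), `dpp` (current minus
#' previous environment mean), and the trial-history set `prev_choice`
#' (plus `prev_choice2`, ... when `lags > 1`), `prev_reward`,
#' `prev_success`, `acc_reward`.
#'
#' @param lags Number of previous-choice lags included.
#' @return Character vector, useful for the `subset` argument of
#'   [fit_logistic()].
#' @export
regressor_names <- function(lags = 1L) {
  c("ev", "risk", "dpc", "dpp", history_regressor_names(lags))
}

# Raw (pre-standardization) regressor values for every presented trial of
# every participant. History regressors reference previous *presented*
# trials, catch trials included, since that history was experienced whether
# or not the trial enters the analysis; a missing previous response
# contributes prev_choice = prev_reward = prev_success = 0.
raw_regressors <- function(table, lags = 1L) {
  parts <- split(table, table$participant_id)
  out <- do.call(rbind, lapply(parts, function(tt) {
    tt <- tt[order(tt$trial_index), , drop = FALSE]
    m <- tt$magnitude; p <- tt$probability
    pcm <- env_mean_probability(tt$environment)
    ppast <- past_mean_probability(tt$group[1])[tt$block_index]
    accepted <- tt$choice == "accept"
    rewarded <- ifelse(is.na(tt$outcome), 0, tt$outcome)
    lagged <- function(x, k) c(rep(0, k), x[seq_len(length(x) - k)])
    tt$ev <- m * p
    tt$risk <- m^2 * p * (1 - p)
    tt$dpc <- p - pcm
    tt$dpp <- ifelse(is.na(ppast), 0, pcm - ppast)
    tt$prev_choice <- lagged(as.numeric(accepted), 1)
    if (lags >= 2)
      for (k in 2:lags)
        tt[[paste0("prev_choice", k)]] <- lagged(as.numeric(accepted), k)
    tt$prev_reward <- lagged(rewarded, 1)
    tt$prev_success <- lagged(as.numeric(accepted & rewarded > 0), 1)
    tt$acc_raw <- cumsum(rewarded) - rewarded  # points before this trial
    # within-participant z-scoring of the accumulated reward
    s <- sd(tt$acc_raw)
    tt$acc_reward <- if (s > 0) (tt$acc_raw - mean(tt$acc_raw)) / s else 0
    tt
  }))
  rownames(out) <- NULL
  out
}

#' Build the z-scored trial-level regressor matrix
#'
#' Constructs the eight regressors of the choice regression for every
#' presented trial -- expected value (EV = mp), Risk (m^2 p(1-p)), the
#' current-environment probability deviation (dpc = p minus the environment's
#' mean reward probability), the past-environment difference (dpp = current
#' minus previous environment mean, 0 in the first block), previous choice,
#' previous reward, previous success, and the accumulated reward before the
#' trial (z-scored within participant) -- then restricts to analyzed,
#' responded trials, pools per experiment and z-scores every column. With
#' `lags > 1`, indicator regressors for the choices made 2..lags trials ago
#' are added.
#'
#' @param table Trial table with exclusions applied (full sequences: history
#'   regressors use all presented trials).
#' @param lags Number of previous-choice lags (default 1).
#' @return A `regressor_matrix`: a data.frame with key columns, `response`
#'   (1 = accept) and the z-scored regressors; standardization statistics are
#'   attached as the `"scaling"` attribute (pooled per experiment, and per
#'   group for the history regressors, as used by [simulate_from_fit()]).
#' @export
build_regressors <- function(table, lags = 1L) {
  raw <- raw_regressors(table, lags)
  regs <- regressor_names(lags)
  keep <- raw$analyzed & raw$choice != "missing"
  dat <- raw[keep, , drop = FALSE]
  dat$response <- as.numeric(dat$choice == "accept")

  scaling <- list(pooled = list(), group = list())
  for (ex in unique(dat$experiment)) {
    rows <- dat$experiment == ex
    st <- lapply(regs, function(r) {
      mu <- mean(dat[[r]][rows]); sdev <- sd(dat[[r]][rows])
      if (!is.finite(sdev) || sdev == 0) sdev <- 1
      dat[[r]][rows] <<- (dat[[r]][rows] - mu) / sdev
      c(mean = mu, sd = sdev)
    })
    names(st) <- regs
    scaling$pooled[[as.character(ex)]] <- st
  }
  # per-group statistics of the *raw* history quantities, used to
  # pseudo-standardize history regressors in forward simulation
  hist_regs <- history_regressor_names(lags)
  for (g in unique(dat$group)) {
    rows <- which(raw$analyzed & raw$choice != "missing" & raw$group == g)
    st <- lapply(hist_regs, function(r) {
      x <- if (r == "acc_reward") raw$acc_raw[rows] else raw[[r]][rows]
      sdev <- sd(x)
      c(mean = mean(x), sd = if (is.finite(sdev) && sdev > 0) sdev else 1)
    })
    names(st) <- hist_regs
    scaling$group[[g]] <- st
  }
  cols <- c("participant_id", "group", "experiment", "block_index",
            "trial_index", "environment", "magnitude", "probability",
            "response", regs)
  out <- dat[, cols]
  rownames(out) <- NULL
  attr(out, "scaling") <- scaling
  attr(out, "lags") <- lags
  class(out) <- c("regressor_matrix", class(out))
  out
}

logistic_loglik <- function(y, eta) {
  sum(y * eta - log1pexp(eta))
}

#' Pooled logistic regression of gambling choices
#'
#' Maximum-likelihood (or L1-penalized) logistic regression of accept/reject
#' on a subset of the z-scored regressors, with the intercept always
#' included. BIC = -2 loglik + k log(n) with k counting all fitted
#' coefficients. When `B > 0`, coefficient confidence bounds and two-tailed
#' one-sample bootstrap p-values against zero (Bonferroni-corrected by the
#' subset size) are computed from participant-resampled refits. For the L1
#' penalty the regularization strength is chosen by 5-fold cross-validated
#' deviance.
#'
#' @param matrix A `regressor_matrix` (one experiment).
#' @param subset Regressor names to fit (default: all in the matrix).
#' @param penalty `"none"` or `"L1"`.
#' @param B Bootstrap refits for coefficient inference (0 skips).
#' @param seed Integer seed.
#' @return A `regression_fit`: `coefficients` data.frame (term, estimate,
#'   optional ci_low/ci_high/p_value), `loglik`, `bic`, `n`, `subset`,
#'   `penalty`, `separation` flag and the scaling metadata.
#' @export
fit_logistic <- function(matrix, subset = NULL, penalty = c("none", "L1"),
                         B = 0L, seed = 1L) {
  penalty <- match.arg(penalty)
  lags <- attr(matrix, "lags") %||% 1L
  if (is.null(subset)) subset <- regressor_names(lags)
  stopifnot(all(subset %in% names(matrix)))
  y <- matrix$response
  if (length(unique(y)) < 2) stop("responses are constant")
  X <- as.matrix(matrix[, subset, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("singular design: regressors are linearly dependent")

  fit_coefs <- function(X, y) {
    if (penalty == "none") {
      sep <- FALSE
      fit <- withCallingHandlers(
        glm.fit(cbind(`(Intercept)` = 1, X), y, family = binomial()),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1",
                    conditionMessage(w))) sep <<- TRUE
          invokeRestart("muffleWarning")
        })
      list(coef = fit$coefficients, separation = sep)
    } else {
      cv <- glmnet::cv.glmnet(X, y, family = "binomial", nfolds = 5,
                              alpha = 1)
      co <- as.numeric(coef(cv, s = "lambda.min"))
      names(co) <- c("(Intercept)", colnames(X))
      list(coef = co, separation = FALSE)
    }
  }

  local_rng(seed)
  main <- fit_coefs(X, y)
  eta <- cbind(1, X) %*% main$coef
  ll <- logistic_loglik(y, eta)
  k <- length(main$coef)
  n <- length(y)
  coefs <- data.frame(term = names(main$coef),
                      estimate = unname(main$coef),
                      stringsAsFactors = FALSE)
  if (B > 0) {
    ids <- unique(matrix$participant_id)
    rows_by_id <- split(seq_len(nrow(matrix)), matrix$participant_id)[ids]
    draws <- matrix(NA_real_, nrow = B, ncol = k)
    for (b in seq_len(B)) {
      take <- unlist(rows_by_id[sample.int(length(ids), replace = TRUE)],
                     use.names = FALSE)
      draws[b, ] <- fit_coefs(X[take, , drop = FALSE], y[take])$coef
    }
    cis <- apply(draws, 2, percentile_ci)
    coefs$ci_low <- cis[1, ]
    coefs$ci_high <- cis[2, ]
    coefs$p_value <- vapply(seq_len(k), function(j)
      two_tailed_onesample_test(draws[, j], main$coef[j],
                                m_tests = length(subset)), numeric(1))
  }
  structure(
    list(coefficients = coefs, loglik = ll, bic = -2 * ll + k * log(n),
         n = n, subset = subset, penalty = penalty,
         separation = main$separation,
         scaling = attr(matrix, "scaling"), lags = lags),
    class = "regression_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> %s penalty, n = %d, loglik = %.1f, BIC = %.1f%s\n",
              x$penalty, x$n, x$loglik, x$bic,
              if (x$separation) " [separation]" else ""))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing each regressor on the others.
#' Numerically collinear columns are reported capped at `cap` with a flag.
#'
#' @param matrix A `regressor_matrix`.
#' @param subset Regressors to include (default all).
#' @param cap Cap for (near-)infinite VIFs.
#' @return Data.frame (term, vif, capped).
#' @export
vif <- function(matrix, subset = NULL, cap = 1e6) {
  lags <- attr(matrix, "lags") %||% 1L
  if (is.null(subset)) subset <- regressor_names(lags)
  stopifnot(length(subset) >= 2)
  X <- as.matrix(matrix[, subset, drop = FALSE])
  out <- do.call(rbind, lapply(seq_along(subset), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    v <- if (r2 >= 1 - 1 / cap) cap else 1 / (1 - r2)
    data.frame(term = subset[j], vif = v, capped = r2 >= 1 - 1 / cap)
  }))
  rownames(out) <- NULL
  out
}

#' Forward-simulate choices from a fitted regression
#'
#' Simulates fresh participants over new task schedules using the fitted
#' coefficients. Static regressors (EV, Risk, dpc, dpp) are standardized with
#' the pooled statistics stored at fitting time; history regressors are
#' updated on-line from the simulated history and pseudo-standardized with
#' the corresponding experimental group's stored raw mean and SD. Choices are
#' drawn from the logistic probability on every presented trial and outcomes
#' sampled.
#'
#' @param fit A `regression_fit`.
#' @param groups Groups to simulate.
#' @param n_per_group Simulated participants per group (120 by default).
#' @param use_terms Optional subset of the fitted regressors to retain in the
#'   linear predictor (others contribute 0), e.g. only the consistently
#'   significant ones.
#' @param seed Integer seed.
#' @return A long-format simulated trial table.
#' @export
simulate_from_fit <- function(fit, groups = c("PR", "RP"), n_per_group = 120L,
                              use_terms = NULL, seed = 1L) {
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  if (!is.null(use_terms)) {
    drop <- setdiff(names(co), c("(Intercept)", use_terms))
    co[drop] <- 0
  }
  lags <- fit$lags %||% 1L
  hist_regs <- history_regressor_names(lags)
  tables <- list()
  for (g in seq_along(groups)) {
    group <- groups[g]
    ex <- as.character(group_experiment(group))
    pooled <- fit$scaling$pooled[[ex]] %||% fit$scaling$pooled[[1]]
    gstats <- fit$scaling$group[[group]] %||% fit$scaling$group[[1]]
    zs <- function(r, x) (x - pooled[[r]][["mean"]]) / pooled[[r]][["sd"]]
    zg <- function(r, x) (x - gstats[[r]][["mean"]]) / gstats[[r]][["sd"]]
    for (i in seq_len(n_per_group)) {
      sseed <- derive_seed(seed, g * 100000L + i)
      sched <- generate_experiment_schedule(group, seed = sseed)
      local_rng(derive_seed(sseed, 7L))
      n <- nrow(sched)
      pcm <- env_mean_probability(sched$environment)
      ppast <- past_mean_probability(group)[sched$block_index]
      dpp <- ifelse(is.na(ppast), 0, pcm - ppast)
      u_choice <- runif(n); u_win <- runif(n)
      choice <- character(n); outcome <- numeric(n)
      prev <- rep(0, lags); prev_rew <- 0; prev_suc <- 0; acc <- 0
      for (t in seq_len(n)) {
        m <- sched$magnitude[t]; p <- sched$probability[t]
        z <- c(
          ev = zs("ev", m * p),
          risk = zs("risk", m^2 * p * (1 - p)),
          dpc = zs("dpc", p - pcm[[t]]),
          dpp = zs("dpp", dpp[[t]]),
          prev_choice = zg("prev_choice", prev[1]),
          if (lags >= 2)
            setNames(vapply(2:lags, function(k)
              zg(paste0("prev_choice", k), prev[k]), numeric(1)),
              paste0("prev_choice", 2:lags)),
          prev_reward = zg("prev_reward", prev_rew),
          prev_success = zg("prev_success", prev_suc),
          acc_reward = zg("acc_reward", acc)
        )
        regs <- setdiff(names(co), "(Intercept)")
        if (anyNA(z[regs]))
          stop("regressor/coefficient name mismatch in simulate_from_fit")
        eta <- co[["(Intercept)"]] + sum(co[regs] * z[regs])
        accept <- u_choice[t] < plogis(eta)
        if (accept) {
          outcome[t] <- if (u_win[t] < p) m else 0
          choice[t] <- "accept"
        } else {
          outcome[t] <- 10
          choice[t] <- "reject"
        }
        prev <- c(as.numeric(accept), prev[-length(prev)])
        prev_rew <- outcome[t]
        prev_suc <- as.numeric(accept && outcome[t] > 0)
        acc <- acc + outcome[t]
      }
      sched$choice <- choice
      sched$outcome <- outcome
      tables[[length(tables) + 1L]] <- cbind(
        participant_id = sprintf("%s_sim%03d", group, i), sched,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  out
}

#' Refit and simulate with regressors dropped or lags added
#'
#' Systematically refits the regression with each named regressor excluded
#' (and, optionally, with extra previous-choice lags added), feeding each
#' refit to [simulate_from_fit()].
#'
#' @param matrix A `regressor_matrix`.
#' @param table The trial table the matrix was built from (needed to rebuild
#'   the matrix when lags are added).
#' @param drop Regressors to drop, one variant each.
#' @param add_lags If > 1, adds a variant with previous-choice regressors up
#'   to this lag.
#' @param groups,n_per_group,seed Passed to [simulate_from_fit()].
#' @param simulate Run the forward simulations?
#' @return Named list of variants, each with `fit` and (optionally)
#'   `simulation`.
#' @export
ablation_suite <- function(matrix, table = NULL,
                           drop = c("dpc", "dpp", "prev_choice", "acc_reward"),
                           add_lags = 0L, groups = c("PR", "RP"),
                           n_per_group = 120L, seed = 1L, simulate = TRUE) {
  lags <- attr(matrix, "lags") %||% 1L
  full <- regressor_names(lags)
  variants <- list()
  for (d in drop) {
    fit <- fit_logistic(matrix, subset = setdiff(full, d))
    variants[[paste0("drop_", d)]] <- list(fit = fit)
  }
  if (add_lags > 1) {
    stopifnot(!is.null(table))
    mat2 <- build_regressors(table, lags = add_lags)
    variants[[paste0("lags_", add_lags)]] <-
      list(fit = fit_logistic(mat2))
  }
  if (simulate)
    for (v in names(variants))
      variants[[v]]$simulation <- simulate_from_fit(
        variants[[v]]$fit, groups = groups, n_per_group = n_per_group,
        seed = derive_seed(seed, match(v, names(variants))))
  variants
}
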