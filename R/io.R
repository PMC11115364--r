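trial_table_columns <- c("participant_id", "group", "experiment",
                         "block_index", "trial_index", "environment",
                         "magnitude", "probability", "catch_type", "analyzed",
                         "choice", "outcome")

#' Validate a trial table
#'
#' Checks the long-format schema: required columns, known enum values,
#' 1-based contiguous trial indices per participant, and the
#' choice/outcome consistency rules (rejects pay 10; accepts pay 0 or the
#' magnitude; missing choices have missing outcomes). The first offending
#' row/column is named in the error.
#'
#' @param table A data.frame.
#' @return The table, invisibly, if valid.
#' @export
validate_trial_table <- function(table) {
  if (nrow(table) == 0) stop("empty trial table")
  missing_cols <- setdiff(trial_table_columns, names(table))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  check_enum <- function(col, allowed) {
    bad <- which(!table[[col]] %in% allowed)
    if (length(bad))
      stop(sprintf("column '%s', row %d: invalid value '%s'", col, bad[1],
                   table[[col]][bad[1]]))
  }
  check_enum("choice", c("accept", "reject", "missing"))
  check_enum("catch_type", c("none", "always_reject", "always_accept"))
  check_enum("group", c("PR", "RP", "IPI", "IRI"))
  for (id in unique(table$participant_id)) {
    ti <- sort(table$trial_index[table$participant_id == id])
    if (!identical(as.integer(ti), seq_len(length(ti))))
      stop("participant ", id, ": trial_index not 1-based contiguous")
  }
  rej <- table$choice == "reject"
  if (any(bad <- rej & (is.na(table$outcome) | table$outcome != 10)))
    stop("row ", which(bad)[1], ": rejected trial must have outcome 10")
  accp <- table$choice == "accept"
  ok_acc <- !is.na(table$outcome) &
    (table$outcome == 0 | table$outcome == table$magnitude)
  if (any(bad <- accp & !ok_acc))
    stop("row ", which(bad)[1],
         ": accepted trial outcome must be 0 or the magnitude")
  if (any(bad <- table$choice == "missing" & !is.na(table$outcome)))
    stop("row ", which(bad)[1], ": missing choice must have missing outcome")
  invisible(table)
}

#' Read a trial table from CSV
#'
#' @param path CSV path with the long-format header (see
#'   [write_trial_table()]).
#' @return A validated trial table data.frame.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  table <- utils::read.csv(path, stringsAsFactors = FALSE)
  table$analyzed <- as.logical(table$analyzed)
  validate_trial_table(table)
  table
}

#' Write a trial table to CSV
#'
#' @param table Trial table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  validate_trial_table(table[, trial_table_columns])
  utils::write.csv(table[, trial_table_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates cohorts for both experiments, applies exclusions, computes
#' pooled and time-resolved acceptance, runs the bootstrap group tests, the
#' hierarchical risk-return fit per environment, the particle filter, the
#' choice regression with its two forward simulations (full model, and with
#' the environment regressors dropped), and the fitness curves, writing tidy
#' CSV outputs and a run log to `out_dir`.
#'
#' The default `scale = "smoke"` uses reduced sizes (participants, bootstrap
#' draws, particles) suitable for a desk check; `scale = "full"` uses the
#' study-scale settings.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; refusing a run without one keeps every stage
#'   reproducible.
#' @param scale `"smoke"` or `"full"`.
#' @return Invisibly, a named list of the main result objects.
#' @export
reproduce_all <- function(out_dir, seed, scale = c("smoke", "full")) {
  scale <- match.arg(scale)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  smoke <- scale == "smoke"
  n_per_group <- if (smoke) 40L else 120L
  B <- if (smoke) 999L else 9999L
  n_particles <- if (smoke) 1000L else 10000L
  logf <- file.path(out_dir, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  cat(sprintf("riskforage reproduce_all  seed=%d scale=%s  R %s\n",
              seed, scale, getRversion()), file = logf)

  stage <- function(name, expr) {
    logline("[%s] start %s", format(Sys.time(), "%H:%M:%S"), name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e)))
  }

  cfg <- cohort_config(n_per_group = n_per_group,
                       inattentive_fraction = 0.1,
                       seed = derive_seed(seed, 1))
  cohort <- stage("simulate-cohort",
                  generate_cohort(cfg, groups = c("PR", "RP", "IPI", "IRI")))
  write_trial_table(cohort, file.path(out_dir, "cohort.csv"))
  jsonlite::write_json(
    list(config = unclass(cfg), seed = seed, scale = scale),
    file.path(out_dir, "cohort_ground_truth.json"), auto_unbox = TRUE,
    digits = NA)

  excl <- stage("exclusions", apply_exclusions(cohort))
  utils::write.csv(excl$report, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  kept <- excl$table

  desc <- stage("descriptives",
                pooled_acceptance(kept, by = c("group", "block_index",
                                               "environment")))
  utils::write.csv(desc, file.path(out_dir, "acceptance_by_block.csv"),
                   row.names = FALSE)
  ma <- do.call(rbind, lapply(split(kept, kept$group), function(g)
    cbind(group = g$group[1], moving_average_acceptance(g))))
  utils::write.csv(ma, file.path(out_dir, "acceptance_moving_average.csv"),
                   row.names = FALSE)

  b1 <- function(ga, gb, blocks_a, blocks_b, k) {
    ta <- kept[kept$group == ga & kept$block_index %in% blocks_a, ]
    tb <- kept[kept$group == gb & kept$block_index %in% blocks_b, ]
    r <- one_tailed_diff_test(ta, tb, B = B, seed = derive_seed(seed, k))
    data.frame(comparison = sprintf("%s>%s", ga, gb), D = r$observed,
               p = r$p_value, ci_low = r$ci[1], ci_high = r$ci[2], B = B)
  }
  boot <- stage("bootstrap-test", rbind(
    b1("PR", "RP", 1, 1, 11),   # current env: poor vs rich first block
    b1("PR", "RP", 1:2, 1:2, 12),
    b1("IPI", "IRI", 2, 2, 13),
    b1("IPI", "IRI", 3, 3, 14)
  ))
  utils::write.csv(boot, file.path(out_dir, "bootstrap_tests.csv"),
                   row.names = FALSE)

  exp1 <- kept[kept$experiment == 1, ]
  fits <- stage("fit-hier", lapply(c("poor", "rich"), function(e)
    ibic(fit_hierarchical(model_spec("risk_return"), exp1, environment = e),
         n_prior_samples = if (smoke) 500L else 2000L,
         seed = derive_seed(seed, 21))))
  est <- do.call(rbind, lapply(seq_along(fits), function(i)
    cbind(environment = c("poor", "rich")[i], fits[[i]]$estimates)))
  utils::write.csv(est, file.path(out_dir, "hier_estimates.csv"),
                   row.names = FALSE)

  pfres <- stage("fit-pf", {
    pr <- kept[kept$group == "PR", ]
    grid_search(pr,
                sigma_grid = exp(seq(log(1e-5), log(1e-2),
                                     length.out = if (smoke) 5 else 50)),
                beta_grid = seq(0.1, 1, length.out = if (smoke) 4 else 50),
                config = pf_config(n_particles = n_particles,
                                   seed = derive_seed(seed, 31)),
                n_particles_search = if (smoke) 500L else n_particles)
  })
  utils::write.csv(pfres$trajectory$trajectory,
                   file.path(out_dir, "pf_trajectory_PR.csv"),
                   row.names = FALSE)

  regres <- stage("regress", {
    mat <- build_regressors(exp1)
    full <- fit_logistic(mat, B = if (smoke) 199L else 999L,
                         seed = derive_seed(seed, 41))
    reduced <- fit_logistic(mat, subset = setdiff(regressor_names(),
                                                  c("dpc", "dpp")))
    list(matrix = mat, full = full, reduced = reduced,
         vif = vif(mat))
  })
  utils::write.csv(regres$full$coefficients,
                   file.path(out_dir, "regression_full.csv"),
                   row.names = FALSE)
  utils::write.csv(regres$vif, file.path(out_dir, "regression_vif.csv"),
                   row.names = FALSE)

  sims <- stage("simulate-from-fit", {
    s1 <- simulate_from_fit(regres$full, n_per_group = n_per_group,
                            seed = derive_seed(seed, 51))
    s2 <- simulate_from_fit(regres$reduced, n_per_group = n_per_group,
                            seed = derive_seed(seed, 52))
    list(sim1 = s1, sim2 = s2)
  })
  write_trial_table(sims$sim1, file.path(out_dir, "simulation1.csv"))
  write_trial_table(sims$sim2, file.path(out_dir, "simulation2.csv"))

  fitc <- stage("fitness", {
    rows <- lapply(c("poor", "rich"), function(e)
      fitness_curves(build_environment(e),
                     alpha_grid = seq(-0.02, 0.02,
                                      length.out = if (smoke) 11 else 41),
                     n_agents = if (smoke) 2000L else 10000L,
                     seed = derive_seed(seed, 61)))
    do.call(rbind, rows)
  })
  utils::write.csv(fitc, file.path(out_dir, "fitness_curves.csv"),
                   row.names = FALSE)

  logline("[%s] done", format(Sys.time(), "%H:%M:%S"))
  invisible(list(cohort = cohort, exclusions = excl, descriptives = desc,
                 bootstrap = boot, hier_fits = fits, pf = pfres,
                 regression = regres, simulations = sims, fitness = fitc))
}
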