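expected_trials <- function(group) {
  sum(vapply(group_block_order(group),
             function(e) block_length(build_environment(e)), numeric(1)))
}

#' Apply the a priori exclusion criteria
#'
#' Participants are excluded if they (1) did not finish the task (fewer
#' trials than their group's design length), (2) failed to respond on at
#' least 5% of presented trials, (3) made one identical response on every
#' trial, or (4) erred on more than 10% of catch trials (accepting an
#' always-reject gamble or rejecting an always-accept gamble).
#'
#' @param table Full unfiltered trial table including catch trials.
#' @return List with `table` (rows of kept participants) and `report`, a
#'   data.frame with one row per participant: `kept` plus one logical column
#'   per criterion and a collapsed `reasons` string.
#' @export
apply_exclusions <- function(table) {
  if (!"catch_type" %in% names(table)) stop("table lacks catch-trial flags")
  ids <- unique(table$participant_id)
  report <- do.call(rbind, lapply(ids, function(id) {
    tt <- table[table$participant_id == id, , drop = FALSE]
    incomplete <- nrow(tt) < expected_trials(tt$group[1])
    nonresp <- mean(tt$choice == "missing") >= 0.05
    resp <- tt$choice[tt$choice != "missing"]
    constant <- length(resp) > 0 && length(unique(resp)) == 1
    is_catch <- tt$catch_type != "none"
    err <- (tt$catch_type == "always_reject" & tt$choice == "accept") |
      (tt$catch_type == "always_accept" & tt$choice == "reject")
    catch_err <- sum(is_catch) > 0 && sum(err[is_catch]) / sum(is_catch) > 0.10
    reasons <- c(incomplete = incomplete, nonresponse_ge_5pct = nonresp,
                 constant_response = constant,
                 catch_error_gt_10pct = catch_err)
    data.frame(participant_id = id, kept = !any(reasons),
               incomplete = incomplete, nonresponse_ge_5pct = nonresp,
               constant_response = constant, catch_error_gt_10pct = catch_err,
               reasons = paste(names(reasons)[reasons], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  kept <- report$participant_id[report$kept]
  list(table = table[table$participant_id %in% kept, , drop = FALSE],
       report = report)
}

#' Analyzed trials with a recorded response
#'
#' Subsets a trial table to the rows entering every acceptance statistic:
#' non-catch trials with probability in \{0.4, 0.5, 0.6\}, magnitude above
#' the sure option, and a non-missing choice.
#'
#' @param table Trial table.
#' @return The subset of `table`.
#' @export
analyzed_choices <- function(table) {
  table[table$analyzed & table$choice != "missing", , drop = FALSE]
}

#' Pooled proportion of gambles accepted
#'
#' The group-level acceptance proportion pools all choices of all
#' participants: q = (total accepts) / (total choices), computed on analyzed
#' trials with non-missing responses.
#'
#' @param table Trial table (exclusions applied).
#' @param by Optional character vector of grouping columns (e.g.
#'   `c("group", "block_index")`); `NULL` pools everything.
#' @return A data.frame with the grouping keys, `n_accept`, `n_choices`, `q`.
#' @export
pooled_acceptance <- function(table, by = NULL) {
  tt <- analyzed_choices(table)
  if (nrow(tt) == 0) stop("no analyzed choices to pool")
  acc <- as.numeric(tt$choice == "accept")
  if (is.null(by)) {
    return(data.frame(n_accept = sum(acc), n_choices = length(acc),
                      q = mean(acc)))
  }
  key <- interaction(tt[by], drop = TRUE, lex.order = TRUE)
  n_acc <- tapply(acc, key, sum)
  n_cho <- tapply(acc, key, length)
  keys <- unique(tt[by])
  keys <- keys[order(interaction(keys, lex.order = TRUE)), , drop = FALSE]
  out <- cbind(keys, n_accept = as.numeric(n_acc),
               n_choices = as.numeric(n_cho),
               q = as.numeric(n_acc / n_cho))
  rownames(out) <- NULL
  out
}

#' Per-participant proportion of gambles accepted
#'
#' @param table Trial table.
#' @param by Optional additional grouping columns beside `participant_id`.
#' @return A data.frame keyed by participant (and `by`) with `q`.
#' @export
participant_acceptance <- function(table, by = NULL) {
  pooled_acceptance(table, by = c("participant_id", by))
}

#' Moving-average acceptance across aligned trial indices
#'
#' For each trial index i of a group's (shared) design, sums accepted (N) and
#' responded (M) analyzed choices over the window i-k..i+k and reports
#' sum(N)/sum(M). Indices within k of either end of the experiment are
#' omitted; windows without any analyzed response give NA.
#'
#' @param table Trial table of one group (all participants share the design
#'   length).
#' @param k Half-window; k = 2 forms the 5-trial window.
#' @return A data.frame (`trial_index`, `n_accept`, `n_choices`, `q`).
#' @export
moving_average_acceptance <- function(table, k = 2L) {
  tmax <- max(table$trial_index)
  tt <- analyzed_choices(table)
  N <- M <- numeric(tmax)
  acc <- tapply(as.numeric(tt$choice == "accept"), tt$trial_index, sum)
  cho <- tapply(rep(1, nrow(tt)), tt$trial_index, sum)
  N[as.integer(names(acc))] <- acc
  M[as.integer(names(cho))] <- cho
  idx <- seq.int(k + 1L, tmax - k)
  win <- function(x, i) sum(x[(i - k):(i + k)])
  n_acc <- vapply(idx, function(i) win(N, i), numeric(1))
  n_cho <- vapply(idx, function(i) win(M, i), numeric(1))
  data.frame(trial_index = idx, n_accept = n_acc, n_choices = n_cho,
             q = ifelse(n_cho > 0, n_acc / n_cho, NA_real_))
}

#' Binomial-logit acceptance curve
#'
#' Fits a maximum-likelihood logistic (binomial) regression of acceptance on
#' reward magnitude or reward probability over the pooled analyzed choices,
#' optionally split by reward probability when magnitude is the predictor.
#' Perfect separation is reported via the `separation` flag rather than an
#' error. A participant-level bootstrap confidence interval for the slope is
#' attached when `B > 0`.
#'
#' @param table Trial table (exclusions applied).
#' @param predictor `"magnitude"` or `"probability"`.
#' @param per_probability Fit a separate magnitude curve per reward
#'   probability?
#' @param B Bootstrap draws for the slope CI (0 skips the bootstrap).
#' @param seed Seed for the bootstrap.
#' @return A data.frame with one row per fit: optional `probability`,
#'   `intercept`, `slope`, `separation`, and `ci_low`/`ci_high` when `B > 0`.
#' @export
fit_acceptance_curve <- function(table, predictor = c("magnitude", "probability"),
                                 per_probability = FALSE, B = 0L, seed = 1L) {
  predictor <- match.arg(predictor)
  tt <- analyzed_choices(table)
  if (length(unique(tt[[predictor]])) < 2)
    stop("need at least two levels of ", predictor)
  fit_one <- function(dat) {
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(I(choice == "accept") ~ x, family = binomial(),
          data = data.frame(choice = dat$choice, x = dat[[predictor]])),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
      separation = sep)
  }
  slices <- if (per_probability && predictor == "magnitude")
    split(tt, tt$probability) else list(all = tt)
  out <- do.call(rbind, lapply(names(slices), function(nm) {
    est <- fit_one(slices[[nm]])
    row <- data.frame(intercept = est[["intercept"]], slope = est[["slope"]],
                      separation = as.logical(est[["separation"]]))
    if (nm != "all") row <- cbind(probability = as.numeric(nm), row)
    if (B > 0) {
      bd <- bootstrap_distribution(
        slices[[nm]], function(d) fit_one(d)[["slope"]], B = B, seed = seed)
      ci <- percentile_ci(bd$draws)
      row$ci_low <- ci[1]; row$ci_high <- ci[2]
    }
    row
  }))
  rownames(out) <- NULL
  out
}
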