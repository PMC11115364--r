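# Per-participant accept/choice counts on analyzed trials; the sufficient
# statistics for the pooled proportion and its participant-level bootstrap.
participant_counts <- function(table) {
  tt <- analyzed_choices(table)
  if (nrow(tt) == 0) stop("no analyzed choices in table")
  ids <- unique(table$participant_id)
  acc <- tapply(as.numeric(tt$choice == "accept"), tt$participant_id, sum)
  cho <- tapply(rep(1, nrow(tt)), tt$participant_id, length)
  n_acc <- n_cho <- setNames(numeric(length(ids)), ids)
  n_acc[names(acc)] <- acc
  n_cho[names(cho)] <- cho
  data.frame(participant_id = ids, n_accept = as.numeric(n_acc[ids]),
             n_choices = as.numeric(n_cho[ids]), stringsAsFactors = FALSE)
}

#' Participant-level bootstrap distribution of a pooled statistic
#'
#' Resamples participants with replacement `B` times and recomputes the
#' statistic on the pooled resampled data. The statistic is either the string
#' `"pooled_q"` (the pooled proportion of gambles accepted, computed via a
#' fast count-based path) or any function mapping a trial table to a scalar.
#'
#' @param table Trial table of one group.
#' @param statistic `"pooled_q"` or a function(table) -> scalar.
#' @param B Number of bootstrap draws (9,999 by default).
#' @param seed Integer seed.
#' @return List with `observed` (statistic on the original table) and
#'   `draws` (length-`B` numeric vector).
#' @export
bootstrap_distribution <- function(table, statistic = "pooled_q", B = 9999L,
                                   seed = 1L) {
  ids <- unique(table$participant_id)
  if (length(ids) == 0) stop("empty group")
  local_rng(seed)
  if (identical(statistic, "pooled_q")) {
    cnt <- participant_counts(table)
    n <- nrow(cnt)
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    draws <- rowSums(matrix(cnt$n_accept[idx], nrow = B)) /
      rowSums(matrix(cnt$n_choices[idx], nrow = B))
    observed <- sum(cnt$n_accept) / sum(cnt$n_choices)
  } else {
    stopifnot(is.function(statistic))
    observed <- statistic(table)
    rows_by_id <- split(seq_len(nrow(table)), table$participant_id)[ids]
    n <- length(ids)
    draws <- vapply(seq_len(B), function(b) {
      take <- sample.int(n, n, replace = TRUE)
      res <- table[unlist(rows_by_id[take], use.names = FALSE), , drop = FALSE]
      # relabel so duplicated participants count as distinct draws
      res$participant_id <- rep(
        sprintf("bs%04d", seq_len(n)),
        vapply(rows_by_id[take], length, integer(1)))
      statistic(res)
    }, numeric(1))
  }
  list(observed = observed, draws = draws, B = B)
}

#' One-tailed bootstrap difference test between two groups
#'
#' Tests H0: D <= 0 for D = q_A - q_B. The null distribution recenters each
#' group's bootstrap draws at its observed statistic,
#' D_null(b) = (q_A(b) - q_A) - (q_B(b) - q_B), and
#' p = (1 + #\{D_null(b) > D\}) / (1 + B).
#'
#' @param table_a,table_b Trial tables of the two (disjoint) groups.
#' @param statistic As in [bootstrap_distribution()].
#' @param B Bootstrap draws.
#' @param seed Integer seed (independent sub-seeds per group).
#' @param ci_level Level of the percentile CI reported for the difference.
#' @return A `bootstrap_result` list: `observed` (D), `null_draws`,
#'   `p_value`, `ci` (percentile CI of q_A(b) - q_B(b)), `B`.
#' @export
one_tailed_diff_test <- function(table_a, table_b, statistic = "pooled_q",
                                 B = 9999L, seed = 1L, ci_level = 0.95) {
  ba <- bootstrap_distribution(table_a, statistic, B, derive_seed(seed, 1))
  bb <- bootstrap_distribution(table_b, statistic, B, derive_seed(seed, 2))
  D <- ba$observed - bb$observed
  null_draws <- (ba$draws - ba$observed) - (bb$draws - bb$observed)
  p <- (1 + sum(null_draws - D > 0)) / (1 + B)
  structure(
    list(observed = D, null_draws = null_draws, p_value = p,
         ci = percentile_ci(ba$draws - bb$draws, ci_level), B = B),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> D = %.4f, p = %.4g (B = %d), 95%% CI [%.4f, %.4f]\n",
              x$observed, x$p_value, x$B, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Two-tailed one-sample bootstrap test
#'
#' Tests whether a statistic differs from `null_value` using its bootstrap
#' distribution: the draws are recentered at the observed statistic, the
#' smaller of the two tail probabilities (with the +1 smoothing of the
#' difference test) is doubled, multiplied by the Bonferroni factor
#' `m_tests`, and capped at 1.
#'
#' @param draws Bootstrap draws of the statistic.
#' @param observed Observed statistic.
#' @param null_value Hypothesized value (default 0).
#' @param m_tests Bonferroni correction factor.
#' @return The corrected p-value.
#' @export
two_tailed_onesample_test <- function(draws, observed, null_value = 0,
                                      m_tests = 1L) {
  B <- length(draws)
  centered <- draws - observed
  d <- observed - null_value
  upper <- (1 + sum(centered - d > 0)) / (1 + B)
  lower <- (1 + sum(d - centered > 0)) / (1 + B)
  min(1, m_tests * 2 * min(upper, lower))
}

#' Percentile bootstrap confidence interval
#'
#' @param draws Bootstrap draws.
#' @param level Confidence level; 0 collapses to the median.
#' @return Numeric vector `c(low, high)`.
#' @export
percentile_ci <- function(draws, level = 0.95) {
  unname(quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                  na.rm = TRUE))
}
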