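#' Construct an environment specification
#'
#' An environment is a named distribution of gamble parameters. Reward
#' probabilities are uniform over an environment-specific set (poor
#' \{0.2,...,0.6\}, intermediate \{0.4,0.5,0.6\}, rich \{0.4,...,0.8\}) and
#' reward magnitudes are uniform over \{15, 20, ..., 65\} points for every
#' environment. Each environment also carries a catch-trial composition:
#' always-reject catch trials offer magnitude 10 (never better than the sure
#' 10 points) and always-accept catch trials offer probability 1 with a
#' magnitude above 10.
#'
#' @param name One of `"poor"`, `"intermediate"`, `"rich"`.
#' @return An object of class `environment_spec` with fields `name`,
#'   `probabilities`, `magnitudes`, `n_catch_reject`, `n_catch_accept` and
#'   `mean_probability`.
#' @examples
#' build_environment("poor")$mean_probability  # 0.4
#' @export
build_environment <- function(name) {
  name <- match.arg(name, c("poor", "intermediate", "rich"))
  probabilities <- switch(name,
    poor         = seq(0.2, 0.6, by = 0.1),
    intermediate = seq(0.4, 0.6, by = 0.1),
    rich         = seq(0.4, 0.8, by = 0.1)
  )
  n_catch_reject <- if (name == "intermediate") 3L else 8L
  structure(
    list(
      name             = name,
      probabilities    = probabilities,
      magnitudes       = seq(15, 65, by = 5),
      n_catch_reject   = n_catch_reject,
      n_catch_accept   = 3L,
      mean_probability = mean(probabilities)
    ),
    class = "environment_spec"
  )
}

#' @export
print.environment_spec <- function(x, ...) {
  cat(sprintf(
    "<environment_spec> %s: p in {%s} (mean %.2f), m in {%d..%d}, catch %d reject + %d accept\n",
    x$name, paste(x$probabilities, collapse = ","), x$mean_probability,
    min(x$magnitudes), max(x$magnitudes), x$n_catch_reject, x$n_catch_accept
  ))
  invisible(x)
}

block_length <- function(env) {
  length(env$probabilities) * length(env$magnitudes) +
    env$n_catch_reject + env$n_catch_accept
}

#' Generate one block of trials for an environment
#'
#' Every (probability, magnitude) pair of the environment grid appears exactly
#' once among non-catch trials; always-reject catch trials (magnitude 10) draw
#' their probability uniformly from the environment's probability set, and
#' always-accept catch trials (probability 1) draw their magnitude uniformly
#' from the magnitude set. All trials are interleaved by a uniform shuffle.
#' The result is deterministic given `seed`.
#'
#' @param env An `environment_spec`.
#' @param seed Integer seed for the shuffle.
#' @return A data.frame with columns `magnitude`, `probability`, `catch_type`
#'   (`"none"`, `"always_reject"`, `"always_accept"`) and `analyzed`.
#' @export
generate_block <- function(env, seed) {
  stopifnot(inherits(env, "environment_spec"))
  grid <- expand.grid(magnitude = env$magnitudes, probability = env$probabilities)
  rng <- local_rng(seed)
  catch_reject <- data.frame(
    magnitude   = rep(10, env$n_catch_reject),
    probability = sample(env$probabilities, env$n_catch_reject, replace = TRUE)
  )
  catch_accept <- data.frame(
    magnitude   = sample(env$magnitudes, env$n_catch_accept, replace = TRUE),
    probability = rep(1, env$n_catch_accept)
  )
  trials <- rbind(
    cbind(grid, catch_type = "none"),
    cbind(catch_reject, catch_type = "always_reject"),
    cbind(catch_accept, catch_type = "always_accept")
  )
  trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  rownames(trials) <- NULL
  trials$analyzed <- is_analyzed_trial(trials)
  trials
}

group_block_order <- function(group) {
  switch(group,
    PR  = c("poor", "rich"),
    RP  = c("rich", "poor"),
    IPI = c("intermediate", "poor", "intermediate"),
    IRI = c("intermediate", "rich", "intermediate"),
    stop("unknown group: ", group, " (expected PR, RP, IPI or IRI)")
  )
}

group_experiment <- function(group) {
  if (group %in% c("PR", "RP")) 1L else 2L
}

#' Generate the full trial schedule for one participant
#'
#' Blocks are ordered by group (PR = poor then rich, RP the reverse; IPI and
#' IRI sandwich the poor or rich environment between two intermediate blocks)
#' and each block is shuffled independently.
#'
#' @param group One of `"PR"`, `"RP"`, `"IPI"`, `"IRI"`.
#' @param seed Integer seed; per-block seeds are derived from it.
#' @return A data.frame with columns `experiment`, `group`, `block_index`,
#'   `trial_index`, `environment`, `magnitude`, `probability`, `catch_type`,
#'   `analyzed`.
#' @export
generate_experiment_schedule <- function(group, seed) {
  envs <- group_block_order(group)
  blocks <- lapply(seq_along(envs), function(b) {
    env <- build_environment(envs[b])
    tr <- generate_block(env, seed = derive_seed(seed, b))
    cbind(
      data.frame(
        experiment  = group_experiment(group),
        group       = group,
        block_index = b,
        environment = envs[b],
        stringsAsFactors = FALSE
      ),
      tr
    )
  })
  out <- do.call(rbind, blocks)
  out$trial_index <- seq_len(nrow(out))
  out[, c("experiment", "group", "block_index", "trial_index", "environment",
          "magnitude", "probability", "catch_type", "analyzed")]
}

#' Flag trials entering the behavioral analyses
#'
#' Analyzed trials are the non-catch gambles whose parameters occur in every
#' environment: reward probability in \{0.4, 0.5, 0.6\} and magnitude above
#' 10. Catch trials and the environment-specific probabilities (0.2/0.3 in
#' poor, 0.7/0.8 in rich) are excluded.
#'
#' @param trials A data.frame with columns `magnitude`, `probability`,
#'   `catch_type` (a single trial-row also works).
#' @return Logical vector.
#' @export
is_analyzed_trial <- function(trials) {
  trials$catch_type == "none" &
    trials$magnitude > 10 &
    vapply(trials$probability, function(p) {
      any(abs(p - c(0.4, 0.5, 0.6)) < 1e-9)
    }, logical(1))
}
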