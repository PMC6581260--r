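#' Generate a task (latent reward schedule)
#'
#' Latent reward probabilities follow a Gaussian random walk (step sd
#' `walk_sd`) reflected at `bounds`; per-trial outcomes are later realized as
#' Bernoulli draws from these probabilities ("binarized Gaussian random
#' walk"). Kinds:
#' * `bandit2`: two options, one walk each.
#' * `gonogo`: two interleaved stimuli (0 aversive, 1 appetitive, randomized
#'   order) with independent walks per stimulus x action; outcome value is
#'   independent of the stimulus label.
#' * `twostep`: two first-stage actions lead to two second-stage states via
#'   fixed 0.7/0.3 common/rare transitions; one walk per second-stage
#'   state x action.
#'
#' @param kind One of `"bandit2"`, `"gonogo"`, `"twostep"`.
#' @param n_trials Number of trials (> 0).
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param walk_sd Random-walk step standard deviation.
#' @param bounds Reflection bounds for the latent probability, within `[0, 1]`.
#' @return An `hbi_task` list with `kind`, `n_trials`, `outcome_prob`
#'   (trials x options matrix) and, for go/no-go, `stimulus`.
#' @export
generate_task <- function(kind = c("bandit2", "gonogo", "twostep"),
                          n_trials = 100, seed = NULL,
                          walk_sd = 0.1, bounds = c(0.2, 0.8)) {
  kind <- match.arg(kind)
  stopifnot(n_trials > 0, walk_sd > 0,
            length(bounds) == 2, bounds[1] < bounds[2],
            bounds[1] >= 0, bounds[2] <= 1)
  n_walks <- if (kind == "bandit2") 2L else 4L
  task <- with_seed(seed, {
    prob <- vapply(seq_len(n_walks),
                   function(i) reflect_walk(n_trials, walk_sd, bounds),
                   numeric(n_trials))
    t <- list(kind = kind, n_trials = as.integer(n_trials),
              outcome_prob = prob, walk_sd = walk_sd, bounds = bounds,
              seed = seed)
    if (kind == "gonogo") {
      t$stimulus <- sample(0:1, n_trials, replace = TRUE)
    }
    if (kind == "twostep") {
      t$transition_prob <- 0.7
    }
    t
  })
  structure(task, class = "hbi_task")
}

# Gaussian random walk reflected into [lo, hi], uniform start.
reflect_walk <- function(n, sd, bounds) {
  lo <- bounds[1]; hi <- bounds[2]
  x <- numeric(n)
  x[1] <- stats::runif(1, lo, hi)
  steps <- stats::rnorm(n - 1, 0, sd)
  for (t in seq_len(n - 1)) x[t + 1] <- reflect_into(x[t] + steps[t], lo, hi)
  x
}

reflect_into <- function(x, lo, hi) {
  rng <- hi - lo
  y <- (x - lo) %% (2 * rng)
  lo + min(y, 2 * rng - y)
}

#' @export
print.hbi_task <- function(x, ...) {
  cat("<hbi_task> ", x$kind, ", ", x$n_trials, " trials, walk sd ",
      x$walk_sd, ", bounds [", x$bounds[1], ", ", x$bounds[2], "]\n", sep = "")
  invisible(x)
}
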