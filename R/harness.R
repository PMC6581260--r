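#' Moment-specified skewed random numbers
#'
#' Draws from a distribution with the requested mean, variance, skewness and
#' kurtosis, realized as a shifted and scaled Beta (the Pearson Type I
#' family covers the target region, e.g. skewness -0.5 with normal kurtosis
#' 3). With zero skewness and kurtosis 3 this reduces to a Gaussian.
#'
#' @param n Number of draws.
#' @param mean,variance,skewness,kurtosis Target moments (kurtosis is the
#'   raw fourth standardized moment; 3 for a Gaussian).
#' @return Numeric vector of length `n`.
#' @export
rskewed <- function(n, mean = 0, variance = 1, skewness = 0, kurtosis = 3) {
  stopifnot(variance > 0)
  if (abs(skewness) < 1e-10 && abs(kurtosis - 3) < 1e-10) {
    return(stats::rnorm(n, mean, sqrt(variance)))
  }
  ab <- solve_beta_moments(skewness, kurtosis - 3)
  a <- ab[1]; b <- ab[2]
  m_b <- a / (a + b)
  sd_b <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  (stats::rbeta(n, a, b) - m_b) / sd_b * sqrt(variance) + mean
}

.beta_moment_cache <- new.env(parent = emptyenv())

# Beta shape parameters matching a target skewness and excess kurtosis.
solve_beta_moments <- function(skew, exkurt) {
  key <- paste(format(skew, digits = 12), format(exkurt, digits = 12))
  hit <- .beta_moment_cache[[key]]
  if (!is.null(hit)) return(hit)
  on.exit(if (exists("out", inherits = FALSE))
    assign(key, out, envir = .beta_moment_cache))
  out <- solve_beta_moments_impl(skew, exkurt)
  out
}

solve_beta_moments_impl <- function(skew, exkurt) {
  moments <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    g1 <- 2 * (b - a) * sqrt(a + b + 1) / ((a + b + 2) * sqrt(a * b))
    g2 <- 6 * ((a - b)^2 * (a + b + 1) - a * b * (a + b + 2)) /
      (a * b * (a + b + 2) * (a + b + 3))
    c(g1, g2)
  }
  obj <- function(p) sum((moments(p) - c(skew, exkurt))^2)
  best <- NULL
  for (st in list(c(1, 1), c(2, 0.5), c(0.5, 2), c(3, 1.5))) {
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (best$value > 1e-8) {
    stop("no Beta-family distribution matches skewness ", skew,
         " with excess kurtosis ", exkurt)
  }
  exp(best$par)
}

#' Scenario configuration for simulation studies
#'
#' `agent_group()` describes one sub-population: a generating model, how many
#' subjects express it, and the per-parameter generating distribution on the
#' unconstrained scale (normal by default; a moment-matched skewed family if
#' `skewness`/`kurtosis` are supplied per parameter).
#'
#' @param model A [cog_models] object.
#' @param n Number of subjects in the group.
#' @param mean,sd Unconstrained-scale generating mean and sd per parameter.
#' @param skewness,kurtosis Optional per-parameter moments (0 / 3 keeps the
#'   normal).
#' @return An `agent_group` list.
#' @export
agent_group <- function(model, n, mean, sd, skewness = NULL, kurtosis = NULL) {
  stopifnot(inherits(model, "cog_model"), n >= 0,
            length(mean) == model$n_params, length(sd) == model$n_params,
            all(sd > 0))
  structure(list(model = model, n = as.integer(n), mean = mean, sd = sd,
                 skewness = skewness %||% rep(0, model$n_params),
                 kurtosis = kurtosis %||% rep(3, model$n_params)),
            class = "agent_group")
}

#' @rdname agent_group
#' @param groups List of `agent_group`s (the generating mixture).
#' @param task Task settings: `kind`, `n_trials`, `walk_sd`, `bounds`.
#' @param n_replications Number of independent replications.
#' @param methods Which procedures [run_scenario()] applies: any of
#'   `"hbi"`, `"nhi"`, `"hpe"`.
#' @param seed Master seed.
#' @param outliers Optional evidence-outlier spec
#'   `list(subject = <id>, times = <copies>)` applied after generation.
#' @export
scenario_config <- function(groups, task = list(kind = "bandit2", n_trials = 100,
                                                walk_sd = 0.1, bounds = c(0.2, 0.8)),
                            n_replications = 10, methods = "hbi", seed = 1,
                            outliers = NULL) {
  stopifnot(length(groups) >= 1,
            all(vapply(groups, inherits, logical(1), "agent_group")),
            n_replications >= 1, all(methods %in% c("hbi", "nhi", "hpe")))
  task <- utils::modifyList(list(kind = "bandit2", n_trials = 100,
                                 walk_sd = 0.1, bounds = c(0.2, 0.8)), task)
  structure(list(groups = groups, task = task,
                 n_replications = as.integer(n_replications),
                 methods = methods, seed = seed, outliers = outliers),
            class = "scenario_config")
}

#' Generate one synthetic group dataset
#'
#' Draws each subject's unconstrained parameters from its group's generating
#' distribution, generates a fresh task per subject and simulates the agent.
#' Identical `(config, replication)` give byte-identical datasets.
#'
#' @param config A [scenario_config()].
#' @param replication Replication index (drives the seed stream).
#' @return List with `data` (trials tibble) and `truth` (tibble: `subject`,
#'   `model`, list-column `params` of unconstrained generating values).
#' @export
generate_group_dataset <- function(config, replication = 1) {
  seed_rep <- derive_seed(config$seed, "rep", replication)
  res <- with_seed(seed_rep, {
    rows <- list(); truth <- list(); idx <- 0L
    for (g in config$groups) {
      for (j in seq_len(g$n)) {
        idx <- idx + 1L
        id <- sprintf("s%03d", idx)
        raw <- vapply(seq_len(g$model$n_params), function(i) {
          rskewed(1, g$mean[i], g$sd[i]^2, g$skewness[i], g$kurtosis[i])
        }, numeric(1))
        names(raw) <- g$model$param_names
        task <- generate_task(config$task$kind, config$task$n_trials,
                              walk_sd = config$task$walk_sd,
                              bounds = config$task$bounds)
        trials <- simulate_agent(g$model, raw, task)
        trials$subject <- id
        rows[[idx]] <- trials
        truth[[idx]] <- tibble::tibble(subject = id, model = g$model$name,
                                       params = list(raw))
      }
    }
    list(data = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth))
  })
  if (!is.null(config$outliers)) {
    res <- add_evidence_outliers(res$data, res$truth,
                                 config$outliers$subject,
                                 config$outliers$times)
  }
  res
}

#' Duplicate a subject to create evidence-space outliers
#'
#' Copies one subject's data `times` times (fresh subject ids), the mechanism
#' by which a single extreme-evidence subject can flip a fixed-effects model
#' comparison.
#'
#' @param data,truth As returned by [generate_group_dataset()].
#' @param subject Subject id to copy.
#' @param times Number of copies to append.
#' @export
add_evidence_outliers <- function(data, truth, subject, times = 1) {
  stopifnot(subject %in% data$subject, times >= 1)
  src <- data[data$subject == subject, ]
  tsrc <- truth[truth$subject == subject, ]
  for (i in seq_len(times)) {
    id <- paste0(subject, "_dup", i)
    cp <- src; cp$subject <- id
    data <- dplyr::bind_rows(data, cp)
    tcp <- tsrc; tcp$subject <- id
    truth <- dplyr::bind_rows(truth, tcp)
  }
  list(data = data, truth = truth)
}

#' Run a simulation scenario end to end
#'
#' For each replication: generate a synthetic group, fit the requested
#' procedures, and score model selection (against the most frequent
#' generating model), per-subject attribution and unconstrained-scale
#' parameter recovery.
#'
#' @param config A [scenario_config()].
#' @param verbose Print per-replication progress?
#' @return A tibble with one row per replication x method: `selected`,
#'   `correct_selection`, `pxp_selected`, `attribution_accuracy`,
#'   `mean_abs_error`, plus a `frequency` list-column.
#' @export
run_scenario <- function(config, verbose = FALSE) {
  models <- lapply(config$groups, `[[`, "model")
  model_names <- vapply(models, `[[`, character(1), "name")
  keep <- !duplicated(model_names)
  models <- models[keep]; model_names <- model_names[keep]
  counts <- vapply(model_names, function(nm) {
    sum(vapply(config$groups,
               function(g) if (g$model$name == nm) g$n else 0L, numeric(1)))
  }, numeric(1))
  majority <- model_names[which.max(counts)]

  out <- list()
  for (rep in seq_len(config$n_replications)) {
    gen <- generate_group_dataset(config, rep)
    seed_rep <- derive_seed(config$seed, "fit", rep)
    truth_model <- gen$truth$model[match(unique(gen$data$subject),
                                         gen$truth$subject)]
    for (method in config$methods) {
      row <- score_method(method, gen, models, model_names, majority,
                          truth_model, seed_rep)
      row$replication <- rep
      out[[length(out) + 1L]] <- row
      if (verbose) {
        message(sprintf("rep %d %s: selected %s (majority %s)",
                        rep, method, row$selected, majority))
      }
    }
  }
  dplyr::bind_rows(out)
}

score_method <- function(method, gen, models, model_names, majority,
                         truth_model, seed_rep) {
  truth_idx <- match(truth_model, model_names)
  if (method == "hbi") {
    fit <- hbi(gen$data, models, seed = seed_rep, pxp = TRUE)
    sel <- which.max(fit$pxp)
    assigned <- apply(fit$responsibility, 2, which.max)
    err <- recovery_error(fit$theta, gen$truth, model_names)
    tibble::tibble(method = method, selected = model_names[sel],
                   correct_selection = model_names[sel] == majority,
                   pxp_selected = fit$pxp[sel],
                   attribution_accuracy = mean(assigned == truth_idx),
                   mean_abs_error = err,
                   frequency = list(stats::setNames(fit$model_frequency,
                                                    model_names)))
  } else if (method == "nhi") {
    fit <- nhi(gen$data, models, seed = seed_rep)
    sel <- which.max(fit$bms$pxp)
    assigned <- apply(fit$bms$u, 1, which.max)
    err <- recovery_error(fit$theta, gen$truth, model_names)
    tibble::tibble(method = method, selected = model_names[sel],
                   correct_selection = model_names[sel] == majority,
                   pxp_selected = fit$bms$pxp[sel],
                   attribution_accuracy = mean(assigned == truth_idx),
                   mean_abs_error = err,
                   frequency = list(stats::setNames(fit$bms$frequency,
                                                    model_names)))
  } else {
    fits <- lapply(models, function(m) hpe(gen$data, m, seed = seed_rep))
    cmp <- fixed_effects_comparison(fits)
    sel <- which(cmp$selected)[1]
    err <- recovery_error(lapply(fits, `[[`, "theta"), gen$truth, model_names)
    tibble::tibble(method = method, selected = model_names[sel],
                   correct_selection = model_names[sel] == majority &&
                     !cmp$tie[1],
                   pxp_selected = NA_real_,
                   attribution_accuracy = NA_real_,
                   mean_abs_error = err,
                   frequency = list(NULL))
  }
}

# Mean absolute unconstrained-scale error of each subject's estimates under
# its true generating model.
recovery_error <- function(theta, truth, model_names) {
  errs <- vapply(seq_len(nrow(truth)), function(n) {
    k <- match(truth$model[n], model_names)
    mean(abs(theta[[k]][, n] - truth$params[[n]]))
  }, numeric(1))
  mean(errs)
}

#' Per-parameter absolute estimation error
#'
#' `|estimate - truth|` element-wise, on the unconstrained ("normally
#' distributed") scale by default or on the constrained scale after applying
#' the model transforms.
#'
#' @param estimates,truth `D x N` matrices of unconstrained parameters
#'   (aligned columns).
#' @param model The [cog_models] object (needed for `space = "constrained"`).
#' @param space `"unconstrained"` or `"constrained"`.
#' @return Tibble: `subject` (column index), `parameter`, `error`.
#' @export
compute_estimation_error <- function(estimates, truth, model = NULL,
                                     space = c("unconstrained", "constrained")) {
  space <- match.arg(space)
  estimates <- as.matrix(estimates); truth <- as.matrix(truth)
  if (!all(dim(estimates) == dim(truth))) {
    stop("estimates and truth are misaligned")
  }
  if (space == "constrained") {
    stopifnot(!is.null(model))
    estimates <- apply(estimates, 2, transform_parameters, model = model)
    truth <- apply(truth, 2, transform_parameters, model = model)
  }
  err <- abs(estimates - truth)
  pn <- if (!is.null(model)) model$param_names else
    paste0("p", seq_len(nrow(err)))
  tibble::tibble(subject = rep(seq_len(ncol(err)), each = nrow(err)),
                 parameter = rep(pn, ncol(err)),
                 error = as.double(err))
}

#' Attribution ROC curve and AUC
#'
#' True-attribution rate against false-attribution rate of a designated
#' model's responsibilities across thresholds; AUC by the trapezoid rule
#' (equivalently the Mann-Whitney statistic).
#'
#' @param responsibility Responsibilities in `[0, 1]` for the designated model.
#' @param truth Logical (or 0/1) vector: does the subject truly express it?
#' @return List with `curve` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
attribution_roc <- function(responsibility, truth) {
  truth <- as.logical(truth)
  stopifnot(length(responsibility) == length(truth),
            all(responsibility >= 0 & responsibility <= 1))
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: single-class truth")
  thr <- c(Inf, sort(unique(responsibility), decreasing = TRUE), -Inf)
  curve <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(responsibility[truth] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(responsibility[!truth] >= t), numeric(1)))
  rk <- rank(responsibility)
  auc <- (sum(rk[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(curve = curve, auc = auc)
}

#' Bootstrap confidence interval for a mean
#'
#' @param x Numeric vector.
#' @param n_boot Number of resamples.
#' @param level Interval level.
#' @param seed Seed.
#' @return Named vector `mean`, `lower`, `upper`.
#' @export
bootstrap_mean_ci <- function(x, n_boot = 1000, level = 0.95, seed = 1) {
  with_seed(seed, {
    means <- vapply(seq_len(n_boot),
                    function(i) mean(sample(x, replace = TRUE)), numeric(1))
    qs <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2))
    c(mean = mean(x), lower = unname(qs[1]), upper = unname(qs[2]))
  })
}

# ------------------------------------------------------------ presets -------

#' Preset simulation scenarios
#'
#' Study designs used throughout the recovery experiments, with generating
#' distributions on the unconstrained scale (see the methods vignette for
#' the rationale behind the defaults):
#' * `scenario_rl_kalman()`: two same-complexity learners, a constant-rate
#'   learner (minority) vs. a Kalman filter (majority) on a two-armed bandit.
#' * `scenario_rl_dual()`: nested pair; the single learning rate (mean 0.1 on
#'   the constrained scale) is below both dual rates (0.8 / 0.4).
#' * `scenario_bias()`: go/no-go groups with a Pavlovian bias parameter drawn
#'   with group mean `effect` and variance 1 (optionally from the skewed
#'   family), for group-level inference studies.
#'
#' @param n_rl,n_kalman,n_dual,n Group sizes.
#' @param n_trials Trials per subject.
#' @param n_replications,seed,methods Passed to [scenario_config()].
#' @param effect Generating mean of the bias parameter.
#' @param skewness,kurtosis Moments of the bias-generating distribution.
#' @return A [scenario_config()].
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_rl_kalman <- function(n_rl = 10, n_kalman = 30, n_trials = 100,
                               n_replications = 10, seed = 1,
                               methods = "hbi") {
  scenario_config(
    groups = list(
      agent_group(model_rl(), n_rl,
                  mean = c(log(3), stats::qlogis(0.3)), sd = c(0.5, 0.5)),
      agent_group(model_kalman(), n_kalman,
                  mean = c(log(3), 0), sd = c(0.5, 0.5))),
    task = list(kind = "bandit2", n_trials = n_trials),
    n_replications = n_replications, methods = methods, seed = seed)
}

#' @rdname scenarios
#' @export
scenario_rl_dual <- function(n_rl = 10, n_dual = 30, n_trials = 100,
                             n_replications = 10, seed = 1,
                             methods = "hbi") {
  scenario_config(
    groups = list(
      agent_group(model_rl(), n_rl,
                  mean = c(log(3), stats::qlogis(0.1)), sd = c(0.5, 0.5)),
      agent_group(model_dual_alpha(), n_dual,
                  mean = c(log(3), stats::qlogis(0.8), stats::qlogis(0.4)),
                  sd = c(0.5, 0.5, 0.5))),
    task = list(kind = "bandit2", n_trials = n_trials),
    n_replications = n_replications, methods = methods, seed = seed)
}

#' @rdname scenarios
#' @export
scenario_bias <- function(n = 20, effect = 0, skewness = 0, kurtosis = 3,
                          n_trials = 100, n_replications = 10, seed = 1,
                          methods = "hbi") {
  scenario_config(
    groups = list(
      agent_group(model_biased_rl(), n,
                  mean = c(log(3), stats::qlogis(0.3), effect),
                  sd = c(0.5, 0.5, 1),
                  skewness = c(0, 0, skewness),
                  kurtosis = c(3, 3, kurtosis))),
    task = list(kind = "gonogo", n_trials = n_trials),
    n_replications = n_replications, methods = methods, seed = seed)
}

#' Load a scenario from a YAML configuration
#'
#' The YAML mirrors [scenario_config()]: a `task` block, a list of `groups`
#' (each with `model`, `n_subjects`, `mean`, `sd`, optional
#' `skewness`/`kurtosis`),
#' `n_replications`, `methods`, `seed`. Model names map to the built-in
#' constructors.
#'
#' @param path YAML file path.
#' @param name Scenario name when the file holds a named collection (see
#'   `system.file("extdata", "scenarios.yaml", package = "hbifit")`).
#' @return A [scenario_config()].
#' @export
read_scenario_yaml <- function(path, name = NULL) {
  y <- yaml::read_yaml(path)
  if (is.null(y$groups)) {
    if (is.null(name)) {
      stop("file holds scenarios ", paste(names(y), collapse = ", "),
           "; pick one with `name`")
    }
    y <- y[[name]]
    if (is.null(y)) stop("no scenario named '", name, "'")
  }
  ctors <- list(rl = model_rl, dual_alpha = model_dual_alpha,
                kalman = model_kalman, actor_critic = model_actor_critic,
                last_outcome = model_last_outcome, biased_rl = model_biased_rl,
                rl_persev = model_rl_persev,
                dual_alpha_persev = model_dual_alpha_persev,
                mf = model_mf, mb = model_mb, hybrid = model_hybrid)
  groups <- lapply(y$groups, function(g) {
    ctor <- ctors[[g$model]]
    if (is.null(ctor)) stop("unknown model '", g$model, "' in ", path)
    agent_group(ctor(), g$n_subjects, mean = unlist(g$mean), sd = unlist(g$sd),
                skewness = if (!is.null(g$skewness)) unlist(g$skewness),
                kurtosis = if (!is.null(g$kurtosis)) unlist(g$kurtosis))
  })
  scenario_config(groups = groups,
                  task = y$task %||% list(),
                  n_replications = y$n_replications %||% 10,
                  methods = y$methods %||% "hbi",
                  seed = y$seed %||% 1)
}
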