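#' Non-hierarchical inference (NHI)
#'
#' Fits every model to every subject independently under a fixed Gaussian
#' prior (default mean 0, variance 6.25 per dimension, wide enough to exert
#' little pull on the estimates), computes the per-cell Laplace log evidence
#' and, optionally, feeds the evidence matrix to random-effects Bayesian
#' model selection.
#'
#' @inheritParams hbi
#' @param prior_mean,prior_variance Fixed Gaussian prior.
#' @param bms Run [bms_random_effects()] on the evidence matrix?
#' @return An `nhi_fit`: per-model `theta` matrices, `log_evidence` (N x K),
#'   per-cell Laplace fits and the `bms` summary.
#' @export
nhi <- function(data, models, prior_mean = 0, prior_variance = 6.25,
                n_restarts = 5, seed = 1, bms = TRUE) {
  if (inherits(models, "cog_model")) models <- list(models)
  stopifnot(prior_variance > 0)
  subjects <- split_subjects(data)
  N <- length(subjects)
  K <- length(models)
  model_names <- make.unique(vapply(models, `[[`, character(1), "name"))
  D <- vapply(models, `[[`, numeric(1), "n_params")
  cells <- fit_all_cells(subjects, models,
                         lapply(D, function(d) rep(prior_mean, d)),
                         lapply(D, function(d) rep(1 / prior_variance, d)),
                         n_restarts, seed, stage = 0L)
  logev <- vapply(seq_len(K), function(k) {
    cells[[k]]$log_f + D[k] / 2 * log(2 * pi) - cells[[k]]$logdet / 2
  }, numeric(N))
  logev <- matrix(logev, nrow = N,
                  dimnames = list(names(subjects), model_names))
  out <- structure(list(models = models, model_names = model_names,
                        subject_ids = names(subjects),
                        theta = lapply(cells, `[[`, "theta"),
                        A = lapply(cells, `[[`, "A"),
                        log_evidence = logev, n_subjects = N,
                        bms = NULL), class = "nhi_fit")
  if (bms && K > 1) out$bms <- bms_random_effects(logev, seed = seed)
  out
}

#' Random-effects Bayesian model selection
#'
#' Variational inference on the Dirichlet-multinomial model over model
#' identity given per-subject log evidences: iterate
#' `u_nk ~ exp(logev_nk + psi(alpha_k) - psi(sum alpha))` (normalized per
#' subject) and `alpha_k = alpha0 + sum_n u_nk` to convergence. Exceedance
#' probabilities come from the Dirichlet posterior; protected exceedance
#' probabilities compare the model's free energy against the
#' uniform-frequency null free energy `F0 = sum_n log mean_k exp(logev_nk)`.
#'
#' @param log_evidence N x K matrix of per-subject log model evidence.
#' @param alpha0 Dirichlet prior concentration.
#' @param max_iter,tol Fixed-point iteration controls.
#' @param n_samples,seed Monte-Carlo settings for exceedance probabilities.
#' @return List: `alpha`, `u` (posterior assignments), `frequency`, `xp`,
#'   `pxp`, `P0`, `converged`.
#' @export
bms_random_effects <- function(log_evidence, alpha0 = 1, max_iter = 200,
                               tol = 1e-6, n_samples = 1e6, seed = 1) {
  stopifnot(all(is.finite(log_evidence)))
  lev <- as.matrix(log_evidence)
  N <- nrow(lev); K <- ncol(lev)
  alpha <- rep(alpha0, K)
  u <- matrix(1 / K, N, K)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- sweep(lev, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    u <- t(apply(w, 1, softmax_log))
    if (K == 1) u <- matrix(u, ncol = 1)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new; converged <- TRUE; break
    }
    alpha <- alpha_new
  }
  xp <- exceedance_probabilities(alpha, n_samples = n_samples, seed = seed)
  # free energies of the random-effects model and the uniform-frequency null
  elogm <- digamma(alpha) - digamma(sum(alpha))
  F1 <- sum(apply(sweep(lev, 2, elogm, `+`), 1, logsumexp)) +
    lgamma(K * alpha0) - K * lgamma(alpha0) -
    lgamma(sum(alpha)) + sum(lgamma(alpha)) +
    sum((alpha0 - alpha) * elogm)
  F0 <- sum(apply(lev - log(K), 1, logsumexp))
  pe <- protected_exceedance(xp, F1, F0)
  list(alpha = alpha, u = u, frequency = alpha / sum(alpha), xp = xp,
       pxp = pe$pxp, P0 = pe$P0, converged = converged)
}

#' Hierarchical parameter estimation (HPE) by expectation-maximization
#'
#' Empirical-Bayes fit of a single model to all subjects under the
#' fixed-effects assumption that every subject expresses it. Alternates
#' Laplace fits of each subject under the current group Gaussian
#' `N(mu, diag(V))` (E-step) with moment updates `mu = mean(theta)`,
#' `V = diag((1/N) sum(theta theta' - mu mu' + A^-1))` (M-step) until the
#' relative change in `(mu, V)` drops below `tol`. The group-level log
#' evidence is the sum of per-subject Laplace evidences under the fitted
#' group prior minus an iBIC-style penalty `(1/2) (2 D) log(total trials)`
#' for the mean and variance hyperparameters.
#'
#' @inheritParams hbi
#' @param model A single [cog_models] object.
#' @param init_mean,init_variance Initial group Gaussian.
#' @param tol Relative-change convergence threshold.
#' @return An `hpe_fit`: `mu`, `V` (diagonal), per-subject `theta`/`A`,
#'   `log_evidence` (per subject), `group_evidence`, `iterations`,
#'   `converged`.
#' @export
hpe <- function(data, model, init_mean = 0, init_variance = 6.25,
                tol = 1e-4, max_iter = 50, n_restarts = 5, iter_restarts = 1,
                seed = 1) {
  stopifnot(inherits(model, "cog_model"))
  subjects <- split_subjects(data)
  N <- length(subjects)
  D <- model$n_params
  mu <- rep(init_mean, D)
  V <- rep(init_variance, D)
  cells <- NULL
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    cells <- fit_all_cells(subjects, list(model), list(mu), list(1 / V),
                           if (it == 1) n_restarts else iter_restarts,
                           seed, stage = it,
                           warm = if (is.null(cells)) NULL
                                  else list(cells$theta))[[1]]
    th <- cells$theta
    mu_new <- rowMeans(th)
    second <- rowMeans(th^2) +
      rowMeans(matrix(vapply(cells$Ainv, diag, numeric(D)), nrow = D))
    V_new <- second - mu_new^2
    if (any(V_new < 1e-6)) {
      warning("group variance collapsed; floored at 1e-6")
      V_new <- pmax(V_new, 1e-6)
    }
    delta <- max(abs(mu_new - mu) / (1 + abs(mu)),
                 abs(V_new - V) / (1 + abs(V)))
    mu <- mu_new; V <- V_new
    if (delta < tol) { converged <- TRUE; break }
  }
  # E-step once more so theta/A/evidence reflect the final (mu, V)
  cells <- fit_all_cells(subjects, list(model), list(mu), list(1 / V),
                         iter_restarts, seed, stage = iterations + 1L,
                         warm = list(cells$theta))[[1]]
  logev <- cells$log_f + D / 2 * log(2 * pi) - cells$logdet / 2
  total_obs <- sum(vapply(subjects, function(s) {
    if (!is.null(s$choice)) length(s$choice) else length(s[[1]])
  }, numeric(1)))
  structure(list(model = model, mu = mu, V = V,
                 theta = cells$theta, A = cells$A,
                 log_evidence = stats::setNames(logev, names(subjects)),
                 group_evidence = sum(logev) - D * log(total_obs),
                 total_observations = total_obs,
                 iterations = iterations, converged = converged,
                 n_subjects = N, subject_ids = names(subjects)),
            class = "hpe_fit")
}

#' Fixed-effects model comparison of HPE fits
#'
#' Compares models by their penalized group-level evidences (each the sum of
#' individual subject evidences, i.e. model identity treated as a fixed
#' effect) and selects the argmax; exact ties are reported as such.
#'
#' @param fits List of [hpe()] results fitted on identical data.
#' @return A tibble with one row per model: `model`, `log_evidence`,
#'   `selected`, `tie`.
#' @export
fixed_effects_comparison <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "hpe_fit")))
  ids <- lapply(fits, `[[`, "subject_ids")
  if (length(unique(lapply(ids, sort))) != 1) {
    stop("HPE fits cover different subject sets")
  }
  ev <- vapply(fits, `[[`, numeric(1), "group_evidence")
  best <- max(ev)
  sel <- abs(ev - best) < 1e-9
  tibble::tibble(model = vapply(fits, function(f) f$model$name, character(1)),
                 log_evidence = ev, selected = sel, tie = sum(sel) > 1)
}

#' @export
print.nhi_fit <- function(x, ...) {
  cat("Non-hierarchical inference fit:", x$n_subjects, "subjects,",
      length(x$models), "models\n")
  if (!is.null(x$bms)) {
    df <- data.frame(model = x$model_names,
                     frequency = round(x$bms$frequency, 3),
                     xp = round(x$bms$xp, 3), pxp = round(x$bms$pxp, 3))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.hpe_fit <- function(x, ...) {
  cat("HPE fit of '", x$model$name, "': ", x$n_subjects, " subjects, ",
      x$iterations, " EM iterations",
      if (x$converged) " (converged)" else " (max iterations)", "\n", sep = "")
  cat("  group mean:", paste(round(x$mu, 3), collapse = ", "), "\n")
  cat("  group variance:", paste(round(x$V, 3), collapse = ", "), "\n")
  cat("  penalized group evidence:", format(x$group_evidence, digits = 6), "\n")
  invisible(x)
}
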