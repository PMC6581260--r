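#' Prior configuration for the hierarchical model
#'
#' Group means carry a Gaussian-Gamma prior `N(mu_k | a0, diag(b tau_k)^-1)
#' G(tau_k | v, s)` and model frequencies a symmetric Dirichlet `Dir(alpha0)`.
#' The defaults make the priors account for one effective prior sample
#' (`b = 1`, `v = 1/2`), center group means at zero on the unconstrained
#' scale, keep the Gamma inverse-scale seed `s` small so the posterior scale
#' is driven by data, and place a uniform prior on model frequencies.
#'
#' @param a0 Prior mean of the group means (scalar, broadcast per dimension).
#' @param b Effective number of prior samples for the means (> 0).
#' @param v Half the effective number of prior samples for the precisions (> 0).
#' @param s Gamma inverse-scale seed (> 0, small).
#' @param alpha0 Dirichlet concentration (> 0).
#' @return An `hbi_prior` list.
#' @export
hbi_prior <- function(a0 = 0, b = 1, v = 0.5, s = 0.01, alpha0 = 1) {
  stopifnot(b > 0, v > 0, s > 0, alpha0 > 0)
  structure(list(a0 = a0, b = b, v = v, s = s, alpha0 = alpha0),
            class = "hbi_prior")
}

#' Responsibility-weighted summary statistics
#'
#' For each model `k`: the expected subject count `Nbar_k = sum_n r_kn`, the
#' weighted mean `theta_bar_k` of the subject-level posterior modes and the
#' weighted second-moment matrix
#' `V_bar_k = (1/Nbar_k) sum_n r_kn (theta theta' - theta_bar theta_bar' +
#' A_kn^-1)`. When `Nbar_k` falls below `1e-6` the division is undefined and
#' the statistics revert to the prior mean with unit spread.
#'
#' @param theta List (per model) of `D_k x N` matrices of posterior modes.
#' @param Ainv List (per model) of per-subject posterior covariance matrices.
#' @param r `K x N` responsibility matrix with unit column sums.
#' @param a0 Prior mean used for the degenerate reversion.
#' @return List per model with `Nbar`, `theta_bar`, `V_bar`.
#' @export
compute_summary_stats <- function(theta, Ainv, r, a0 = 0) {
  K <- nrow(r)
  stopifnot(length(theta) == K, length(Ainv) == K,
            max(abs(colSums(r) - 1)) < 1e-9)
  lapply(seq_len(K), function(k) {
    M <- theta[[k]]
    D <- nrow(M)
    w <- r[k, ]
    Nbar <- sum(w)
    if (Nbar < 1e-6) {
      return(list(Nbar = Nbar, theta_bar = rep(a0, D), V_bar = diag(D)))
    }
    tb <- as.double(M %*% w) / Nbar
    S <- M %*% (w * t(M))
    for (n in seq_along(w)) S <- S + w[n] * Ainv[[k]][[n]]
    V <- S / Nbar - tcrossprod(tb)
    V <- (V + t(V)) / 2
    diag(V) <- pmax(diag(V), 1e-10)
    list(Nbar = Nbar, theta_bar = tb, V_bar = V)
  })
}

#' Group-level posterior update
#'
#' Conjugate update of the Gaussian-Gamma posterior `q(mu_k, tau_k) =
#' N(mu_k | a_k, diag(beta_k tau_k)^-1) G(tau_k | nu_k, sigma_k)` and of the
#' Dirichlet concentration, from the current summary statistics:
#' `a_k = (Nbar theta_bar + b a0) / (Nbar + b)`, `beta_k = b + Nbar`,
#' `sigma_k = s + (1/2) diag(Nbar V_bar + (b Nbar / (b + Nbar))
#' (theta_bar - a0)(theta_bar - a0)')`, `nu_k = v + Nbar / 2`,
#' `alpha_k = alpha0 + Nbar`.
#'
#' @param stats Output of [compute_summary_stats()].
#' @param prior An [hbi_prior()].
#' @return List per model with `a`, `beta`, `sigma`, `nu`, `alpha`, `Nbar`.
#' @export
update_group_posterior <- function(stats, prior) {
  lapply(stats, function(st) {
    D <- length(st$theta_bar)
    a0 <- rep_len(prior$a0, D)
    Nbar <- st$Nbar
    dev <- st$theta_bar - a0
    a <- (Nbar * st$theta_bar + prior$b * a0) / (Nbar + prior$b)
    sigma <- prior$s + 0.5 * (Nbar * diag(st$V_bar) +
                                (prior$b * Nbar / (prior$b + Nbar)) * dev^2)
    list(a = a, beta = prior$b + Nbar, sigma = sigma,
         nu = prior$v + Nbar / 2, alpha = prior$alpha0 + Nbar, Nbar = Nbar)
  })
}

#' Responsibility update
#'
#' `log rho_kn = log f_kn + (D_k/2) log 2 pi - (1/2) log|A_kn| + lambda_k +
#' E[log m_k]` with `lambda_k = (D_k/2)(psi(nu_k) - log nu_k - 1/beta_k)` and
#' `E[log m_k] = psi(alpha_k) - psi(sum_j alpha_j)`; responsibilities are the
#' column-wise softmax of `log rho`. Under the frequency-null model
#' (`null = TRUE`, the `alpha0 -> Inf` limit used for protected exceedance
#' probabilities) `E[log m_k]` is pinned at `-log K`.
#'
#' @param log_f `K x N` matrix of Laplace maximum log values.
#' @param logdet_A `K x N` matrix of log-determinants of the precisions.
#' @param D Integer vector of model dimensions.
#' @param group Output of [update_group_posterior()].
#' @param null Pin the frequency prior at uniform?
#' @return List with `r` (K x N, unit column sums) and `log_rho`.
#' @export
update_responsibilities <- function(log_f, logdet_A, D, group, null = FALSE) {
  K <- nrow(log_f)
  alpha <- vapply(group, `[[`, numeric(1), "alpha")
  elogm <- if (null) rep(-log(K), K) else digamma(alpha) - digamma(sum(alpha))
  lambda <- vapply(seq_len(K), function(k) {
    g <- group[[k]]
    D[k] / 2 * (digamma(g$nu) - log(g$nu) - 1 / g$beta)
  }, numeric(1))
  log_rho <- log_f + D / 2 * log(2 * pi) - logdet_A / 2 + lambda + elogm
  r <- apply(log_rho, 2, function(col) {
    if (all(!is.finite(col))) stop("degenerate subject: all models have -Inf evidence")
    softmax_log(col)
  })
  r <- matrix(r, nrow = K)
  list(r = r, log_rho = log_rho)
}

#' Convergence statistic
#'
#' The normalized parameter change `dhat = (1/K) sum_k (1/D_k) sum_i
#' (thetahat_ki^j - thetahat_ki^(j-1))^2`, with `thetahat_ki =
#' theta_bar_ki / sqrt(V_bar_kii)`. The algorithm stops when `dhat < tol`
#' (strict) or the iteration cap is reached (flagged distinctly).
#'
#' @param stats,prev_stats Summary statistics of consecutive iterations.
#' @return Scalar `dhat`.
#' @export
dhat_statistic <- function(stats, prev_stats) {
  K <- length(stats)
  mean(vapply(seq_len(K), function(k) {
    th1 <- stats[[k]]$theta_bar / sqrt(diag(stats[[k]]$V_bar))
    th0 <- prev_stats[[k]]$theta_bar / sqrt(diag(prev_stats[[k]]$V_bar))
    mean((th1 - th0)^2)
  }, numeric(1)))
}

#' @rdname dhat_statistic
#' @param dhat Current statistic.
#' @param iteration Current iteration number.
#' @param tol Convergence threshold (strict inequality).
#' @param max_iter Iteration cap.
#' @return `check_convergence()`: list with `stop` and `reason`
#'   (`"converged"`, `"max_iter"` or `"continue"`).
#' @export
check_convergence <- function(dhat, iteration, tol = 0.01, max_iter = 50) {
  if (is.finite(dhat) && dhat < tol) {
    list(stop = TRUE, reason = "converged")
  } else if (iteration >= max_iter) {
    list(stop = TRUE, reason = "max_iter")
  } else {
    list(stop = FALSE, reason = "continue")
  }
}

#' Variational lower bound
#'
#' Assembles `L = E_q[log p(X, H, Z, mu, tau, m)] - E_q[log q]` from the
#' Laplace-approximated per-subject terms and the conjugate group-level
#' terms. Under the Laplace approximation the expected data-plus-parameter
#' term for one subject and model collapses to `log f_kn - D_k/2 + lambda_k`,
#' which together with the Gaussian entropy of `q(h)`, the `z` terms and the
#' responsibility entropy yields `sum_n log sum_k rho_kn`; the remaining
#' terms are the negative Kullback-Leibler divergences of the Gaussian-Gamma
#' and Dirichlet posteriors from their priors (the Dirichlet term vanishes in
#' the symmetric `alpha0 -> Inf` null limit).
#'
#' @param log_rho `K x N` matrix from [update_responsibilities()].
#' @param group Output of [update_group_posterior()].
#' @param prior An [hbi_prior()].
#' @param null Frequency-null variant?
#' @return Scalar lower bound.
#' @export
compute_lower_bound <- function(log_rho, group, prior, null = FALSE) {
  subj <- sum(apply(log_rho, 2, logsumexp))

  ng <- sum(vapply(group, function(g) {
    D <- length(g$a)
    a0 <- rep_len(prior$a0, D)
    e_tau <- g$nu / g$sigma
    e_logtau <- digamma(g$nu) - log(g$sigma)
    sum(0.5 * log(prior$b / g$beta) -
          (prior$b / 2) * (e_tau * (g$a - a0)^2 + 1 / g$beta) + 0.5 +
          prior$v * log(prior$s) - g$nu * log(g$sigma) -
          lgamma(prior$v) + lgamma(g$nu) +
          (prior$v - g$nu) * e_logtau - prior$s * e_tau + g$nu)
  }, numeric(1)))

  dir_term <- 0
  if (!null) {
    alpha <- vapply(group, `[[`, numeric(1), "alpha")
    K <- length(alpha)
    a0 <- prior$alpha0
    dir_term <- lgamma(K * a0) - K * lgamma(a0) -
      lgamma(sum(alpha)) + sum(lgamma(alpha)) +
      sum((a0 - alpha) * (digamma(alpha) - digamma(sum(alpha))))
  }
  val <- subj + ng + dir_term
  if (!is.finite(val)) {
    stop("non-finite lower bound (subject term ", subj, ", group term ", ng,
         ", Dirichlet term ", dir_term, ")")
  }
  val
}

# Laplace-fit every subject x model cell. `warm` is an optional list (per
# model) of D x N matrices of previous modes used as first starts.
fit_all_cells <- function(subjects, models, prior_means, prior_precisions,
                          n_restarts, seed, stage, warm = NULL) {
  ids <- names(subjects)
  lapply(seq_along(models), function(k) {
    model <- models[[k]]
    D <- model$n_params
    theta <- matrix(NA_real_, D, length(subjects))
    log_f <- logdet <- numeric(length(subjects))
    A <- Ainv <- vector("list", length(subjects))
    conv <- logical(length(subjects))
    for (n in seq_along(subjects)) {
      subj <- subjects[[n]]
      lt <- function(h) evaluate_loglik(model, h, subj)
      fit <- fit_map_laplace(
        lt, prior_means[[k]], prior_precisions[[k]],
        n_restarts = n_restarts,
        init = if (!is.null(warm)) warm[[k]][, n] else NULL,
        seed = derive_seed(seed, model$name, k, ids[n], stage))
      theta[, n] <- fit$theta
      A[[n]] <- fit$A
      Ainv[[n]] <- chol2inv(chol(fit$A))
      logdet[n] <- as.double(determinant(fit$A, logarithm = TRUE)$modulus)
      log_f[n] <- fit$log_f
      conv[n] <- fit$converged
    }
    list(theta = theta, A = A, Ainv = Ainv, log_f = log_f,
         logdet = logdet, converged = conv)
  })
}

#' Hierarchical Bayesian inference over a model space
#'
#' Fits every candidate model to every subject while inferring, per subject,
#' which model generated the data. Iterates the four variational steps --
#' summary statistics, group-posterior update, subject-level Laplace fits
#' under the current group prior, responsibility update -- until the
#' normalized parameter change `dhat` falls below `tol` or `max_iter` is
#' reached. Model frequencies, exceedance probabilities and (optionally, via
#' an additional run under the uniform-frequency null) protected exceedance
#' probabilities are attached to the result.
#'
#' @param data Trial-level data: a data frame with a `subject` column plus
#'   `choice`, `outcome` (and `stimulus` / `state2`, `choice2` where the task
#'   requires them), or a named list of per-subject data.
#' @param models A [cog_models] object or list of them.
#' @param prior An [hbi_prior()].
#' @param tol,max_iter Convergence threshold on `dhat` and iteration cap.
#' @param seed Master seed controlling all restart draws.
#' @param n_restarts Optimization restarts for the initial subject fits.
#' @param iter_restarts Restarts during iterations (warm-started at the
#'   previous mode).
#' @param init_prior_variance Variance of the zero-mean Gaussian prior used
#'   for the initial independent subject fits.
#' @param pxp Also run the frequency-null fit and attach protected exceedance
#'   probabilities?
#' @param null Run the algorithm under the uniform-frequency null itself
#'   (used internally for `pxp`; see [run_null_hbi()]).
#' @param verbose Print per-iteration progress?
#' @return An `hbi_fit` object; see [tidy.hbi_fit()].
#' @export
hbi <- function(data, models, prior = hbi_prior(), tol = 0.01, max_iter = 50,
                seed = 1, n_restarts = 5, iter_restarts = 2,
                init_prior_variance = 6.25, pxp = TRUE, null = FALSE,
                verbose = FALSE) {
  if (inherits(models, "cog_model")) models <- list(models)
  stopifnot(length(models) >= 1)
  subjects <- split_subjects(data)
  N <- length(subjects)
  K <- length(models)
  D <- vapply(models, `[[`, numeric(1), "n_params")
  model_names <- make.unique(vapply(models, `[[`, character(1), "name"))

  # initialization: independent fits under a fixed Gaussian prior
  init_means <- lapply(D, function(d) rep(0, d))
  init_prec <- lapply(D, function(d) rep(1 / init_prior_variance, d))
  cells <- fit_all_cells(subjects, models, init_means, init_prec,
                         n_restarts, seed, stage = 0L)
  r <- matrix(1 / K, K, N)

  trace <- list()
  prev_stats <- NULL
  reason <- "max_iter"
  group <- NULL
  log_rho <- NULL
  L <- NA_real_

  for (iter in seq_len(max_iter)) {
    stats <- compute_summary_stats(lapply(cells, `[[`, "theta"),
                                   lapply(cells, `[[`, "Ainv"), r,
                                   a0 = prior$a0)
    group <- update_group_posterior(stats, prior)
    prior_means <- lapply(group, `[[`, "a")
    prior_precs <- lapply(group, function(g) g$nu / g$sigma)
    cells <- fit_all_cells(subjects, models, prior_means, prior_precs,
                           iter_restarts, seed, stage = iter,
                           warm = lapply(cells, `[[`, "theta"))
    resp <- update_responsibilities(
      do.call(rbind, lapply(cells, `[[`, "log_f")),
      do.call(rbind, lapply(cells, `[[`, "logdet")),
      D, group, null = null)
    r <- resp$r
    log_rho <- resp$log_rho
    L <- compute_lower_bound(log_rho, group, prior, null = null)

    dhat <- if (is.null(prev_stats)) Inf else dhat_statistic(stats, prev_stats)
    prev_stats <- stats
    trace[[iter]] <- c(iteration = iter, dhat = dhat, lower_bound = L)
    if (verbose) {
      message(sprintf("iter %2d  dhat %.5f  L %.3f", iter, dhat, L))
    }
    st <- check_convergence(dhat, iter, tol = tol, max_iter = max_iter)
    if (st$stop) { reason <- st$reason; break }
  }

  Nbar <- vapply(group, `[[`, numeric(1), "Nbar")
  alpha <- vapply(group, `[[`, numeric(1), "alpha")
  xp <- exceedance_probabilities(alpha, seed = derive_seed(seed, "xp"))

  fit <- structure(list(
    models = models, model_names = model_names, prior = prior,
    subject_ids = names(subjects),
    group = group, stats = prev_stats,
    theta = lapply(cells, `[[`, "theta"),
    A = lapply(cells, `[[`, "A"),
    Ainv = lapply(cells, `[[`, "Ainv"),
    log_f = do.call(rbind, lapply(cells, `[[`, "log_f")),
    responsibility = r, Nbar = Nbar,
    model_frequency = Nbar / N, alpha = alpha,
    lower_bound = L, xp = xp, pxp = NULL, P0 = NA_real_, L0 = NA_real_,
    trace = dplyr::bind_rows(lapply(trace, as.list)),
    convergence = reason, null = null, seed = seed,
    n_subjects = N), class = "hbi_fit")

  if (pxp && !null) {
    fit0 <- hbi(data, models, prior = prior, tol = tol, max_iter = max_iter,
                seed = seed, n_restarts = n_restarts,
                iter_restarts = iter_restarts,
                init_prior_variance = init_prior_variance,
                pxp = FALSE, null = TRUE)
    fit$L0 <- fit0$lower_bound
    pe <- protected_exceedance(xp, L, fit$L0)
    fit$pxp <- pe$pxp
    fit$P0 <- pe$P0
  }
  fit
}

#' Frequency-null companion fit
#'
#' Runs the same variational algorithm under the prior null hypothesis that
#' all models are equally frequent (`alpha0 -> Inf`), realized by pinning
#' `E[log m_k] = -log K` and evaluating the Dirichlet bound terms at their
#' symmetric limit. Its lower bound `L0` feeds the protected exceedance
#' probabilities.
#'
#' @inheritParams hbi
#' @return An `hbi_fit` with `null = TRUE`.
#' @export
run_null_hbi <- function(data, models, prior = hbi_prior(), ...) {
  hbi(data, models, prior = prior, ..., pxp = FALSE, null = TRUE)
}

#' @export
print.hbi_fit <- function(x, ...) {
  cat("Hierarchical Bayesian inference fit",
      if (x$null) "(frequency-null run)" else "", "\n")
  cat("  subjects:", x$n_subjects, " models:",
      paste(x$model_names, collapse = ", "), "\n")
  cat("  iterations:", nrow(x$trace), " stop:", x$convergence,
      " lower bound:", format(x$lower_bound, digits = 6), "\n")
  df <- data.frame(model = x$model_names,
                   Nbar = round(x$Nbar, 2),
                   frequency = round(x$model_frequency, 3),
                   xp = round(x$xp, 3))
  if (!is.null(x$pxp)) df$pxp <- round(x$pxp, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
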