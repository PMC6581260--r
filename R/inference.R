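#' HBI t-test on a group-level parameter
#'
#' The marginal posterior of the group mean `mu_ki` is a Student distribution
#' centered at `a_ki` with `n_k = 2 nu_k` degrees of freedom and scale
#' `s_ki / sqrt(n_k)` ("hierarchical error"), where `s_ki^2 = 2 sigma_ki /
#' beta_k` is the empirical deviance statistic. Degrees of freedom track the
#' responsibility-weighted subject count (`n_k = 1 + Nbar_k` under the
#' default `v = 1/2`), not the total number of subjects. The reported
#' (Bayesian) p-value is the posterior tail probability of the null value.
#'
#' @param fit An `hbi_fit`.
#' @param model Model name or index.
#' @param parameter Parameter name or index within the model.
#' @param null_value Value tested against (default 0).
#' @param level Credible-interval level.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return A one-row tibble: estimate, hierarchical error, dof, statistic,
#'   p.value, credible interval bounds.
#' @export
hbi_ttest <- function(fit, model = 1, parameter = 1, null_value = 0,
                      level = 0.95, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  k <- if (is.character(model)) match(model, fit$model_names) else model
  if (is.na(k) || k < 1 || k > length(fit$models)) stop("unknown model")
  g <- fit$group[[k]]
  i <- if (is.character(parameter)) {
    match(parameter, fit$models[[k]]$param_names)
  } else parameter
  if (is.na(i) || i < 1 || i > length(g$a)) stop("unknown parameter")
  if (g$Nbar < 1e-3) {
    warning("model '", fit$model_names[k],
            "' has near-zero responsibility; the test reflects the prior")
  }
  n <- 2 * g$nu
  s <- sqrt(2 * g$sigma[i] / g$beta)
  he <- s / sqrt(n)
  t <- (g$a[i] - null_value) / he
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df = n),
              greater = stats::pt(t, df = n, lower.tail = FALSE),
              less = stats::pt(t, df = n))
  q <- stats::qt(1 - (1 - level) / 2, df = n)
  tibble::tibble(model = fit$model_names[k],
                 parameter = fit$models[[k]]$param_names[i],
                 estimate = g$a[i], hierarchical_error = he, dof = n,
                 statistic = t, p.value = p,
                 conf.low = g$a[i] - q * he, conf.high = g$a[i] + q * he)
}

#' Fit a new subject through the predictive distribution
#'
#' Marginalizing the group posterior gives a Student predictive prior for a
#' previously unseen subject's parameters: center `a_k`, per-dimension scale
#' `s_k` (with `s_ki^2 = 2 sigma_ki / beta_k`, using the `b = 2v` convention
#' that holds at the defaults) and `n_k = 2 nu_k` degrees of freedom. The
#' returned `theta_star` maximizes `log p(x* | h, M_k) + log St(diag(s_k)^-1
#' (h - a_k) | n_k)`.
#'
#' @param fit An `hbi_fit`.
#' @param model Model name or index.
#' @param new_data One subject's trial data.
#' @param n_restarts,seed Multi-start optimization settings.
#' @return List with `theta_star`, `center`, `scale`, `dof`, `converged`.
#' @export
fit_new_subject <- function(fit, model = 1, new_data, n_restarts = 5, seed = 1) {
  k <- if (is.character(model)) match(model, fit$model_names) else model
  g <- fit$group[[k]]
  m <- fit$models[[k]]
  subj <- as_subject(new_data)
  if (!is.null(m$model_id)) check_task_match(m, subj)
  D <- m$n_params
  n <- 2 * g$nu
  s <- sqrt(2 * g$sigma / g$beta)

  log_st_prior <- function(h) {
    z2 <- sum(((h - g$a) / s)^2)
    lgamma((n + D) / 2) - lgamma(n / 2) - (D / 2) * log(n * pi) -
      sum(log(s)) - (n + D) / 2 * log1p(z2 / n)
  }
  negobj <- function(h) {
    v <- evaluate_loglik(m, h, subj) + log_st_prior(h)
    if (!is.finite(v)) return(1e12)
    -v
  }
  starts <- with_seed(seed, {
    c(list(g$a),
      lapply(seq_len(max(0, n_restarts - 1)),
             function(i) g$a + stats::rnorm(D) * s))
  })
  best <- NULL
  for (st in starts) {
    o <- tryCatch(stats::optim(st, negobj, method = "BFGS",
                               control = list(maxit = 500, reltol = 1e-10)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("optimizer failed on all restarts")
  list(theta_star = stats::setNames(best$par, m$param_names),
       center = g$a, scale = s, dof = n,
       converged = best$convergence == 0L)
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' `phi_k = Prob(m_k > m_j for all j != k)` under `Dir(alpha)`: exact via the
#' regularized incomplete beta function for two models, Monte-Carlo over
#' Dirichlet draws otherwise.
#'
#' @param alpha Positive Dirichlet concentrations.
#' @param n_samples Monte-Carlo draws (K > 2).
#' @param seed Seed for the draws.
#' @return Probability vector summing to one.
#' @export
exceedance_probabilities <- function(alpha, n_samples = 1e6, seed = 1) {
  if (any(alpha <= 0)) stop("Dirichlet concentrations must be positive")
  K <- length(alpha)
  if (K == 1) return(1)
  if (K == 2) {
    phi1 <- stats::pbeta(0.5, alpha[1], alpha[2], lower.tail = FALSE)
    return(c(phi1, 1 - phi1))
  }
  with_seed(seed, {
    g <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                nrow = n_samples)
    tabulate(max.col(g, ties.method = "first"), nbins = K) / n_samples
  })
}

#' Protected exceedance probabilities
#'
#' Shrinks the exceedance probabilities toward uniform by the posterior
#' probability `P0 = 1 / (1 + exp(L - L0))` that frequency differences are
#' due to chance, where `L` and `L0` are the lower bounds of the full fit and
#' of the uniform-frequency null fit:
#' `pxp_k = phi_k (1 - P0) + P0 / K`.
#'
#' @param phi Exceedance probabilities (normalized).
#' @param L,L0 Lower bounds of the alternative and null fits.
#' @return List with `pxp` and `P0`.
#' @export
protected_exceedance <- function(phi, L, L0) {
  P0 <- stats::plogis(L0 - L)
  list(pxp = phi * (1 - P0) + P0 / length(phi), P0 = P0)
}
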