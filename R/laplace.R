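#' Subject-level MAP fit with Laplace approximation
#'
#' Maximizes `log l(h) = log_target(h) + log N(h | prior_mean,
#' diag(prior_precision)^-1)` by quasi-Newton optimization with multiple
#' restarts drawn from the prior, and returns the quadratic (Laplace)
#' approximation at the mode: the mode `theta`, the negative Hessian `A`
#' (repaired to be symmetric positive-definite by eigenvalue flooring when
#' needed) and the maximum log value `log_f`. This single primitive underlies
#' the non-hierarchical, hierarchical-EM and variational procedures alike.
#'
#' @param log_target Function mapping a real vector to the data log-likelihood
#'   (the Gaussian prior is added internally).
#' @param prior_mean Prior mean vector.
#' @param prior_precision Diagonal of the prior precision matrix (positive),
#'   recycled to `length(prior_mean)`.
#' @param n_restarts Number of optimization starts: the prior mean (or `init`
#'   when given) plus prior draws.
#' @param init Optional warm-start vector used as the first start.
#' @param seed Integer seed for the restart draws.
#' @param control Passed to [stats::optim()] (method BFGS) after defaults
#'   `maxit = 500`, `reltol = 1e-10`.
#' @return A `laplace_fit` list: `theta`, `A`, `log_f`, `converged`,
#'   `n_restarts_used`, `repaired`.
#' @export
fit_map_laplace <- function(log_target, prior_mean, prior_precision,
                            n_restarts = 5, init = NULL, seed = NULL,
                            control = list()) {
  d <- length(prior_mean)
  prec <- rep_len(as.double(prior_precision), d)
  stopifnot(all(prec > 0), n_restarts >= 1)
  prior_sd <- 1 / sqrt(prec)

  negobj <- function(h) {
    v <- log_target(h) + sum(stats::dnorm(h, prior_mean, prior_sd, log = TRUE))
    if (!is.finite(v)) return(1e12)
    -v
  }

  starts <- with_seed(seed, {
    extra <- max(0L, n_restarts - 1L)
    s <- lapply(seq_len(extra),
                function(i) prior_mean + stats::rnorm(d) * prior_sd)
    c(list(if (is.null(init)) prior_mean else init), s)
  })

  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)
  best <- NULL
  any_ok <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, negobj, method = "BFGS", control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_ok <- any_ok || fit$convergence == 0L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    # total optimizer failure: fall back to the prior mode
    best <- list(par = prior_mean, value = negobj(prior_mean), convergence = 1L)
  }

  H <- tryCatch(stats::optimHess(best$par, negobj, control = ctrl),
                error = function(e) diag(prec, d))
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE)
  repaired <- any(ev$values < 1e-6)
  if (repaired) {
    vals <- pmax(ev$values, 1e-6)
    H <- ev$vectors %*% (vals * t(ev$vectors))
    H <- (H + t(H)) / 2
  }

  structure(list(theta = as.double(best$par), A = H, log_f = -best$value,
                 converged = any_ok && best$convergence == 0L,
                 n_restarts_used = length(starts), repaired = repaired),
            class = "laplace_fit")
}

#' Laplace approximation to the log model evidence
#'
#' `log_f + (D/2) log(2 pi) - (1/2) log|A|`, the Gaussian-integral
#' approximation to the log marginal likelihood under the prior supplied to
#' [fit_map_laplace()].
#'
#' @param fit A `laplace_fit`.
#' @param D Parameter count (defaults to `length(fit$theta)`).
#' @return Scalar log evidence.
#' @export
log_evidence_laplace <- function(fit, D = length(fit$theta)) {
  ld <- determinant(fit$A, logarithm = TRUE)
  if (ld$sign <= 0) stop("precision matrix is not positive definite")
  fit$log_f + 0.5 * D * log(2 * pi) - 0.5 * as.double(ld$modulus)
}
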