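#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an HBI fit
#'
#' `type = "parameters"` (default) returns one row per model x parameter with
#' the posterior group mean, the empirical deviance statistic, the
#' hierarchical error and the Student degrees of freedom; `type =
#' "frequency"` one row per model with `Nbar`, model frequency, exceedance
#' and protected exceedance probabilities; `type = "responsibility"` one row
#' per subject x model; `type = "subjects"` one row per subject x model x
#' parameter with the subject-level posterior mode.
#'
#' @param x An `hbi_fit`.
#' @param type What to tidy.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy hbi_fit
#' @export
tidy.hbi_fit <- function(x, type = c("parameters", "frequency",
                                     "responsibility", "subjects"), ...) {
  type <- match.arg(type)
  if (type == "parameters") {
    purrr::map2_dfr(x$group, seq_along(x$group), function(g, k) {
      n <- 2 * g$nu
      s <- sqrt(2 * g$sigma / g$beta)
      tibble::tibble(model = x$model_names[k],
                     parameter = x$models[[k]]$param_names,
                     estimate = g$a, deviance = s,
                     hierarchical_error = s / sqrt(n), dof = n)
    })
  } else if (type == "frequency") {
    tibble::tibble(model = x$model_names, Nbar = x$Nbar,
                   frequency = x$model_frequency, alpha = x$alpha,
                   xp = x$xp,
                   pxp = if (is.null(x$pxp)) NA_real_ else x$pxp)
  } else if (type == "responsibility") {
    tidyr::expand_grid(model = x$model_names, subject = x$subject_ids) |>
      dplyr::mutate(responsibility = as.double(t(x$responsibility)))
  } else {
    purrr::map2_dfr(seq_along(x$models), x$models, function(k, m) {
      th <- x$theta[[k]]
      tibble::tibble(model = x$model_names[k],
                     subject = rep(x$subject_ids, each = m$n_params),
                     parameter = rep(m$param_names, length(x$subject_ids)),
                     estimate = as.double(th))
    })
  }
}

#' @rdname tidy.hbi_fit
#' @method glance hbi_fit
#' @export
glance.hbi_fit <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_models = length(x$models),
                 iterations = nrow(x$trace), convergence = x$convergence,
                 lower_bound = x$lower_bound, null_bound = x$L0, P0 = x$P0)
}

#' Tidy baseline fits
#'
#' @param x An `nhi_fit` or `hpe_fit`.
#' @param ... Unused.
#' @return A tibble (per-model comparison summary for NHI; per-parameter
#'   group estimates for HPE).
#' @method tidy nhi_fit
#' @export
tidy.nhi_fit <- function(x, ...) {
  if (is.null(x$bms)) {
    return(tibble::tibble(model = x$model_names,
                          total_log_evidence = colSums(x$log_evidence)))
  }
  tibble::tibble(model = x$model_names,
                 total_log_evidence = colSums(x$log_evidence),
                 alpha = x$bms$alpha, frequency = x$bms$frequency,
                 xp = x$bms$xp, pxp = x$bms$pxp)
}

#' @rdname tidy.nhi_fit
#' @method tidy hpe_fit
#' @export
tidy.hpe_fit <- function(x, ...) {
  tibble::tibble(model = x$model$name, parameter = x$model$param_names,
                 estimate = x$mu, variance = x$V)
}

#' @rdname tidy.nhi_fit
#' @method glance hpe_fit
#' @export
glance.hpe_fit <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, iterations = x$iterations,
                 converged = x$converged, group_evidence = x$group_evidence)
}
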