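#' Candidate cognitive models
#'
#' A `cog_model` bundles everything the inference machinery needs to know
#' about one candidate model: its free parameters, the transforms mapping the
#' unconstrained ("normally distributed") scale on which group-level Gaussian
#' priors live to the constrained scale the model operates on, a
#' log-likelihood evaluator and an agent simulator. All built-in models use a
#' softmax choice rule with inverse temperature `beta = exp(raw)`.
#'
#' Built-in constructors:
#' * `model_rl()` - delta-rule learner with constant learning rate `alpha`
#'   (sigmoid) and inverse temperature `beta` (exponential); 2-armed bandit.
#' * `model_dual_alpha()` - separate learning rates for positive
#'   (`alpha_plus`) and negative (`alpha_minus`) prediction errors.
#' * `model_kalman()` - Kalman filter whose per-option learning rate (the
#'   Kalman gain) decays over trials; free observation noise `omega`
#'   (exponential), initial value mean 0 and prior variance 1, no drift term.
#' * `model_actor_critic()` - TD critic (state value) plus actor preference
#'   update with a shared learning rate.
#' * `model_last_outcome()` - non-learning strategy whose option value equals
#'   the most recent outcome; a single decision-noise parameter.
#' * `model_rl_persev()`, `model_dual_alpha_persev()` - as above plus a
#'   perseveration bonus `persev` (identity scale) added to the utility of
#'   repeating the previous action.
#' * `model_biased_rl()` - go/no-go learner with a Pavlovian bias `bias`
#'   (identity scale): `+bias` toward "go" after an appetitive stimulus and
#'   `-bias` after an aversive one.
#' * `model_mf()`, `model_mb()`, `model_hybrid()` - two-step task agents:
#'   SARSA(lambda) model-free learner, transition-model planner using the
#'   fixed 0.7/0.3 common/rare structure, and their mixture with weight `w`
#'   (sigmoid; `w = 0` reduces to model-free, `w = 1` to model-based).
#'
#' @param q0 Initial action value (midpoint 0.5 for 0/1 outcomes).
#' @param m0,v0 Initial Kalman posterior mean and variance.
#' @param lambda Eligibility mixing for the two-step model-free/hybrid stage-1
#'   backup (fixed, not fitted).
#' @param name Model name.
#' @return An object of class `cog_model`.
#' @name cog_models
NULL

#' Define a custom model
#'
#' Builds a `cog_model` from scratch for likelihoods not covered by the
#' built-ins. `loglik(raw, data)` must accept unconstrained parameters and
#' return a finite log-likelihood for finite parameters and valid data (0 for
#' an empty trial sequence); `simulate(raw, task)`, if supplied, must return
#' a list of per-trial vectors.
#'
#' @param name Model name.
#' @param param_names Character vector of parameter names.
#' @param transforms Per-parameter transform: `"identity"`, `"sigmoid"` or
#'   `"exponential"` (informational for custom models, whose `loglik`
#'   receives unconstrained values and applies transforms itself).
#' @param task_kind Task label (`"bandit2"`, `"gonogo"`, `"twostep"` or a
#'   custom tag).
#' @param model_id Internal id of a compiled likelihood (custom models leave
#'   this `NULL`).
#' @param fixed Fixed configuration constants for compiled likelihoods.
#' @param loglik,simulate Functions for custom models.
#' @return A `cog_model`.
#' @export
new_cog_model <- function(name, param_names, transforms, task_kind,
                          model_id = NULL, fixed = numeric(0),
                          loglik = NULL, simulate = NULL) {
  stopifnot(length(param_names) >= 1, length(transforms) == length(param_names),
            all(transforms %in% c("identity", "sigmoid", "exponential")))
  structure(
    list(name = name, n_params = length(param_names),
         param_names = param_names, transforms = transforms,
         task_kind = task_kind, model_id = model_id, fixed = fixed,
         loglik = loglik, simulate = simulate),
    class = "cog_model")
}

#' @export
print.cog_model <- function(x, ...) {
  cat("<cog_model> ", x$name, " (", x$task_kind, "): ",
      paste0(x$param_names, " [", x$transforms, "]", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname cog_models
#' @export
model_rl <- function(q0 = 0.5, name = "rl") {
  new_cog_model(name, c("beta", "alpha"), c("exponential", "sigmoid"),
                "bandit2", model_id = 1L, fixed = q0)
}

#' @rdname cog_models
#' @export
model_dual_alpha <- function(q0 = 0.5, name = "dual_alpha") {
  new_cog_model(name, c("beta", "alpha_plus", "alpha_minus"),
                c("exponential", "sigmoid", "sigmoid"),
                "bandit2", model_id = 2L, fixed = q0)
}

#' @rdname cog_models
#' @export
model_kalman <- function(m0 = 0, v0 = 1, name = "kalman") {
  new_cog_model(name, c("beta", "omega"), c("exponential", "exponential"),
                "bandit2", model_id = 3L, fixed = c(m0, v0))
}

#' @rdname cog_models
#' @export
model_actor_critic <- function(v0 = 0.5, name = "actor_critic") {
  new_cog_model(name, c("beta", "alpha"), c("exponential", "sigmoid"),
                "bandit2", model_id = 4L, fixed = v0)
}

#' @rdname cog_models
#' @export
model_last_outcome <- function(v0 = 0.5, name = "last_outcome") {
  new_cog_model(name, "beta", "exponential",
                "bandit2", model_id = 5L, fixed = v0)
}

#' @rdname cog_models
#' @export
model_rl_persev <- function(q0 = 0.5, name = "rl_persev") {
  new_cog_model(name, c("beta", "alpha", "persev"),
                c("exponential", "sigmoid", "identity"),
                "bandit2", model_id = 6L, fixed = q0)
}

#' @rdname cog_models
#' @export
model_dual_alpha_persev <- function(q0 = 0.5, name = "dual_alpha_persev") {
  new_cog_model(name, c("beta", "alpha_plus", "alpha_minus", "persev"),
                c("exponential", "sigmoid", "sigmoid", "identity"),
                "bandit2", model_id = 7L, fixed = q0)
}

#' @rdname cog_models
#' @export
model_biased_rl <- function(q0 = 0.5, name = "biased_rl") {
  new_cog_model(name, c("beta", "alpha", "bias"),
                c("exponential", "sigmoid", "identity"),
                "gonogo", model_id = 8L, fixed = q0)
}

#' @rdname cog_models
#' @export
model_mf <- function(q0 = 0.5, lambda = 1, name = "mf") {
  new_cog_model(name, c("beta", "alpha"), c("exponential", "sigmoid"),
                "twostep", model_id = 9L, fixed = c(q0, lambda))
}

#' @rdname cog_models
#' @export
model_mb <- function(q0 = 0.5, name = "mb") {
  new_cog_model(name, c("beta", "alpha"), c("exponential", "sigmoid"),
                "twostep", model_id = 10L, fixed = q0)
}

#' @rdname cog_models
#' @export
model_hybrid <- function(q0 = 0.5, lambda = 1, name = "hybrid") {
  new_cog_model(name, c("beta", "alpha", "w"),
                c("exponential", "sigmoid", "sigmoid"),
                "twostep", model_id = 11L, fixed = c(q0, lambda))
}

#' Map parameters between unconstrained and constrained scales
#'
#' Group-level Gaussian priors are placed on the unconstrained real scale;
#' each parameter is mapped to its constrained range by its transform:
#' `sigmoid` onto (0, 1), `exponential` onto (0, Inf), `identity` unchanged.
#' `inverse_transform_parameters()` is the exact inverse.
#'
#' @param raw Unconstrained parameter vector of length `model$n_params`.
#' @param model A [cog_models] object.
#' @return Numeric vector on the constrained (respectively unconstrained) scale.
#' @export
transform_parameters <- function(raw, model) {
  tr <- model$transforms
  if (length(raw) != length(tr)) {
    stop("expected ", length(tr), " parameters for model '", model$name,
         "', got ", length(raw))
  }
  raw <- pmin(pmax(raw, -700), 700)  # keep exp() finite
  out <- raw
  out[tr == "sigmoid"] <- stats::plogis(raw[tr == "sigmoid"])
  out[tr == "exponential"] <- exp(raw[tr == "exponential"])
  names(out) <- model$param_names
  out
}

#' @rdname transform_parameters
#' @param constrained Constrained parameter vector.
#' @export
inverse_transform_parameters <- function(constrained, model) {
  tr <- model$transforms
  if (length(constrained) != length(tr)) {
    stop("expected ", length(tr), " parameters for model '", model$name, "'")
  }
  out <- constrained
  out[tr == "sigmoid"] <- stats::qlogis(constrained[tr == "sigmoid"])
  out[tr == "exponential"] <- log(constrained[tr == "exponential"])
  names(out) <- model$param_names
  out
}

# Coerce one subject's data (list or single-subject trials tibble) to the
# internal list the compiled likelihoods consume.
as_subject <- function(data) {
  if (is.data.frame(data)) {
    sd <- list(choice = as.integer(data[["choice"]]),
               outcome = as.double(data[["outcome"]]))
    if (!is.null(data[["stimulus"]])) sd$stimulus <- as.integer(data[["stimulus"]])
    if (!is.null(data[["state2"]])) sd$state2 <- as.integer(data[["state2"]])
    if (!is.null(data[["choice2"]])) sd$choice2 <- as.integer(data[["choice2"]])
    return(sd)
  }
  stopifnot(is.list(data))
  data
}

check_task_match <- function(model, data) {
  if (is.null(data$choice) || is.null(data$outcome)) {
    stop("model '", model$name, "' needs `choice` and `outcome` fields")
  }
  if (model$task_kind == "gonogo" && is.null(data$stimulus)) {
    stop("model '", model$name, "' needs go/no-go data with a stimulus column")
  }
  if (model$task_kind == "twostep" &&
      (is.null(data$state2) || is.null(data$choice2))) {
    stop("model '", model$name, "' needs two-step data (state2, choice2)")
  }
  invisible(TRUE)
}

#' Evaluate a model log-likelihood
#'
#' Returns `sum_t log P(choice_t)` for one subject under the model, with
#' parameters given on the unconstrained scale by default (the scale the
#' hierarchical machinery works on). Set `constrained = TRUE` to pass
#' parameters on their natural scale directly, e.g. `beta = 0` for a
#' uniform-choice limit that has no finite unconstrained preimage.
#'
#' @param model A [cog_models] object.
#' @param params Parameter vector.
#' @param data One subject's data: a trials data frame (columns `choice`,
#'   `outcome`, optionally `stimulus`, `state2`, `choice2`) or an equivalent
#'   list.
#' @param constrained Are `params` already on the constrained scale?
#' @return Log-likelihood (scalar; 0 for an empty trial sequence).
#' @export
evaluate_loglik <- function(model, params, data, constrained = FALSE) {
  if (any(!is.finite(params))) stop("non-finite model parameters")
  data <- as_subject(data)
  if (!is.null(model$model_id)) {
    check_task_match(model, data)
    h <- if (constrained) params else transform_parameters(params, model)
    cpp_loglik(model$model_id, as.double(h), data, as.double(model$fixed))
  } else {
    if (constrained) stop("custom models take unconstrained parameters")
    model$loglik(params, data)
  }
}

#' Simulate an artificial subject
#'
#' Plays the model through a generated task, sampling choices from its
#' softmax probabilities and outcomes from the task's latent reward
#' probabilities. Identical `(params, task, seed)` give identical data.
#'
#' @inheritParams evaluate_loglik
#' @param task A task from [generate_task()] whose kind matches the model.
#' @param seed Integer seed.
#' @return A one-subject trials [tibble::tibble()].
#' @export
simulate_agent <- function(model, params, task, seed = NULL,
                           constrained = FALSE) {
  if (any(!is.finite(params))) stop("non-finite model parameters")
  if (!inherits(task, "hbi_task")) stop("`task` must come from generate_task()")
  gonogo_as_bandit <- model$task_kind == "bandit2" && task$kind == "gonogo"
  if (task$kind != model$task_kind && !gonogo_as_bandit) {
    stop("model '", model$name, "' plays a ", model$task_kind,
         " task, not ", task$kind)
  }
  if (gonogo_as_bandit) {
    # a stimulus-blind learner can play the go/no-go schedule: its two
    # actions draw from the (stimulus, action) column shown on each trial
    prob <- t(vapply(seq_len(task$n_trials), function(t) {
      task$outcome_prob[t, 2 * task$stimulus[t] + 1:2]
    }, numeric(2)))
    reduced <- task
    reduced$outcome_prob <- prob
    task_arg <- reduced
  } else {
    task_arg <- task
  }
  h <- if (constrained || is.null(model$model_id)) params
       else transform_parameters(params, model)
  sim <- with_seed(seed, {
    if (!is.null(model$model_id)) {
      cpp_simulate(model$model_id, as.double(h), task_arg,
                   as.double(model$fixed))
    } else {
      model$simulate(params, task_arg)
    }
  })
  if (gonogo_as_bandit) sim$stimulus <- task$stimulus
  out <- tibble::tibble(trial = seq_len(task$n_trials),
                        choice = as.integer(sim$choice),
                        outcome = as.double(sim$outcome))
  if (!is.null(sim$stimulus)) out$stimulus <- as.integer(sim$stimulus)
  if (!is.null(sim$state2)) {
    out$state2 <- as.integer(sim$state2)
    out$choice2 <- as.integer(sim$choice2)
  }
  out
}
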