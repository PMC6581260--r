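# Shared fixtures, all built in code.

# A model with an exactly quadratic log-likelihood: y_t ~ N(h, sd^2) with a
# single unconstrained mean parameter. Laplace is exact for it, so it serves
# as the conjugate oracle throughout.
gaussian_toy_model <- function(sd = 1, name = "gauss_toy") {
  new_cog_model(
    name, param_names = "mu", transforms = "identity", task_kind = "custom",
    loglik = function(raw, data) sum(dnorm(data$y, raw[1], sd, log = TRUE)))
}

gaussian_toy_subjects <- function(n_subjects, mu, sd_subject = 1, sd_obs = 1,
                                  n_obs = 20, seed = 1) {
  set.seed(seed)
  out <- lapply(seq_len(n_subjects), function(i) {
    list(y = rnorm(n_obs, rnorm(1, mu, sd_subject), sd_obs))
  })
  names(out) <- sprintf("s%02d", seq_len(n_subjects))
  out
}

# Exact log marginal likelihood for y ~ N(h, sd^2), h ~ N(m0, v0).
gaussian_log_marginal <- function(y, sd, m0, v0) {
  n <- length(y)
  prec_post <- 1 / v0 + n / sd^2
  # complete the square in h and integrate
  -n / 2 * log(2 * pi * sd^2) - 0.5 * log(v0 * prec_post) -
    0.5 * (sum(y^2) / sd^2 + m0^2 / v0) +
    0.5 * (sum(y) / sd^2 + m0 / v0)^2 / prec_post
}

# quick two-armed bandit dataset from an RL agent
rl_bandit_data <- function(n_trials = 100, raw = c(log(3), qlogis(0.3)),
                           seed = 1) {
  task <- generate_task("bandit2", n_trials, seed = seed)
  simulate_agent(model_rl(), raw, task, seed = seed + 1)
}
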