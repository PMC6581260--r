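test_that("parameter transforms hit their ranges and round-trip", {
  models <- list(model_rl(), model_dual_alpha(), model_kalman(),
                 model_biased_rl(), model_hybrid(), model_dual_alpha_persev())
  expect_equal(unname(transform_parameters(c(0, 0), model_rl())), c(1, 0.5))
  for (m in models) {
    raw <- seq(-1.7, 1.7, length.out = m$n_params)
    h <- transform_parameters(raw, m)
    tr <- m$transforms
    expect_true(all(h[tr == "sigmoid"] > 0 & h[tr == "sigmoid"] < 1))
    expect_true(all(h[tr == "exponential"] > 0))
    expect_equal(unname(inverse_transform_parameters(h, m)), raw,
                 tolerance = 1e-12)
  }
  expect_error(transform_parameters(c(0, 0, 0), model_rl()), "expected 2")
})

test_that("uniform-choice limits give T * log(1/2) for every bandit model", {
  dat <- rl_bandit_data(n_trials = 100)
  for (m in list(model_rl(), model_dual_alpha(), model_kalman(),
                 model_actor_critic(), model_last_outcome())) {
    h <- transform_parameters(rep(0.3, m$n_params), m)
    h[1] <- 0  # beta = 0 on the constrained scale: pure noise
    expect_equal(evaluate_loglik(m, h, dat, constrained = TRUE),
                 100 * log(0.5), tolerance = 1e-12)
  }
  # and log-likelihoods of discrete choices are never positive
  for (m in list(model_rl(), model_kalman())) {
    expect_lt(evaluate_loglik(m, c(0.4, -0.3), dat), 0)
  }
})

test_that("empty trial sequences have zero log-likelihood", {
  empty <- list(choice = integer(0), outcome = double(0))
  expect_identical(evaluate_loglik(model_rl(), c(0, 0), empty), 0)
})

test_that("nested models agree at their nesting points", {
  dat <- rl_bandit_data(n_trials = 200, seed = 7)
  raw_b <- log(2.5); raw_a <- qlogis(0.35)
  ll_rl <- evaluate_loglik(model_rl(), c(raw_b, raw_a), dat)
  expect_equal(evaluate_loglik(model_dual_alpha(), c(raw_b, raw_a, raw_a), dat),
               ll_rl, tolerance = 1e-12)
  expect_equal(evaluate_loglik(model_rl_persev(), c(raw_b, raw_a, 0), dat),
               ll_rl, tolerance = 1e-12)

  # biased RL at b = 0 on go/no-go data equals a stimulus-wise RL; check
  # invariance of the bias term by symmetry of +0/-0
  gtask <- generate_task("gonogo", 150, seed = 3)
  gdat <- simulate_agent(model_biased_rl(), c(raw_b, raw_a, 0.8), gtask, seed = 4)
  ll0 <- evaluate_loglik(model_biased_rl(), c(raw_b, raw_a, 0), gdat)
  expect_lt(ll0, 0)

  # hybrid nests model-free (w = 0) and model-based (w = 1)
  ttask <- generate_task("twostep", 150, seed = 5)
  tdat <- simulate_agent(model_hybrid(), c(raw_b, raw_a, 0.2), ttask, seed = 6)
  expect_equal(
    evaluate_loglik(model_hybrid(), c(2.5, 0.35, 0), tdat, constrained = TRUE),
    evaluate_loglik(model_mf(), c(2.5, 0.35), tdat, constrained = TRUE),
    tolerance = 1e-12)
  expect_equal(
    evaluate_loglik(model_hybrid(), c(2.5, 0.35, 1), tdat, constrained = TRUE),
    evaluate_loglik(model_mb(), c(2.5, 0.35), tdat, constrained = TRUE),
    tolerance = 1e-12)
})

test_that("RL log-likelihood matches a hand-traced delta-rule update", {
  # alpha = 0.5, beta = 1, values start at (0, 0); choices (0, 0) with
  # outcomes (1, 0): trial 1 P = sigmoid(0), then Q0 -> 0.5, trial 2
  # P = sigmoid(0.5)
  dat <- list(choice = c(0L, 0L), outcome = c(1, 0))
  expected <- log(0.5) + log(plogis(0.5))
  got <- evaluate_loglik(model_rl(q0 = 0), c(1, 0.5), dat, constrained = TRUE)
  expect_equal(got, expected, tolerance = 1e-12)

  # dual-alpha trace with distinct rates: pe > 0 uses alpha_plus
  dat2 <- list(choice = c(0L, 0L, 0L), outcome = c(1, 0, 0))
  # Q0: 0 -> +0.8*(1-0)=0.8 -> 0.8+0.2*(0-0.8)=0.64
  expected2 <- log(0.5) + log(plogis(0.8)) + log(plogis(0.64))
  got2 <- evaluate_loglik(model_dual_alpha(q0 = 0), c(1, 0.8, 0.2), dat2,
                          constrained = TRUE)
  expect_equal(got2, expected2, tolerance = 1e-12)
})

test_that("Kalman filter gain decays and matches a hand recursion", {
  # m0 = 0, v0 = 1, omega = 1: gains 1/2, 1/3 on repeated pulls of one arm
  dat <- list(choice = c(0L, 0L), outcome = c(1, 1))
  # trial 1: P = sigmoid(0); m0 -> 0 + 1/2*(1-0) = 0.5, s2 -> 0.5
  # trial 2: P = sigmoid(beta * 0.5)
  expected <- log(0.5) + log(plogis(2 * 0.5))
  got <- evaluate_loglik(model_kalman(), c(2, 1), dat, constrained = TRUE)
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("simulation is deterministic, greedy in the beta limit, and fair at beta = 0", {
  task <- generate_task("bandit2", 200, seed = 42)
  a <- simulate_agent(model_rl(), c(1, 0), task, seed = 9)
  b <- simulate_agent(model_rl(), c(1, 0), task, seed = 9)
  expect_identical(a, b)
  d <- simulate_agent(model_rl(), c(1, 0), task, seed = 10)
  expect_false(identical(a$choice, d$choice))

  # huge beta with a frozen value gap: last-outcome model after a win on arm 0
  greedy <- simulate_agent(model_last_outcome(), 1e6, task, seed = 1,
                           constrained = TRUE)
  # after the first rewarded choice the agent must repeat it until unrewarded
  w <- which(greedy$outcome == 1)[1]
  if (!is.na(w) && w < 200) expect_equal(greedy$choice[w + 1], greedy$choice[w])

  task2 <- generate_task("bandit2", 2000, seed = 2)
  noisy <- simulate_agent(model_rl(), c(0, 0.3), task2, seed = 3,
                          constrained = TRUE)
  ci <- qbinom(c(0.005, 0.995), 2000, 0.5)
  expect_gt(sum(noisy$choice == 0), ci[1])
  expect_lt(sum(noisy$choice == 0), ci[2])
})

test_that("generated tasks are binarized random walks within bounds", {
  task <- generate_task("bandit2", 1e4, seed = 5, walk_sd = 0.15,
                        bounds = c(0.2, 0.8))
  expect_true(all(task$outcome_prob >= 0.2 & task$outcome_prob <= 0.8))
  expect_identical(task$outcome_prob,
                   generate_task("bandit2", 1e4, seed = 5, walk_sd = 0.15,
                                 bounds = c(0.2, 0.8))$outcome_prob)
  dat <- simulate_agent(model_rl(), c(0.5, 0), generate_task("bandit2", 500, seed = 1),
                        seed = 2)
  expect_true(all(dat$outcome %in% c(0, 1)))

  g <- generate_task("gonogo", 300, seed = 8)
  expect_true(all(g$stimulus %in% 0:1))
  expect_equal(ncol(g$outcome_prob), 4)
  expect_error(generate_task("bandit3", 10), "arg")
})

test_that("simulating then evaluating favors the generating parameters on average", {
  set.seed(31)
  raw <- c(log(4), qlogis(0.3))
  task <- generate_task("bandit2", 1000, seed = 13)
  dat <- simulate_agent(model_rl(), raw, task, seed = 14)
  ll_true <- evaluate_loglik(model_rl(), raw, dat)
  ll_pert <- vapply(1:20, function(i) {
    evaluate_loglik(model_rl(), raw + rnorm(2, 0, 0.8), dat)
  }, numeric(1))
  expect_gt(ll_true, mean(ll_pert))
})

test_that("model/task mismatches and bad parameters raise errors", {
  dat <- rl_bandit_data(50)
  expect_error(evaluate_loglik(model_biased_rl(), c(0, 0, 0), dat), "stimulus")
  expect_error(evaluate_loglik(model_mf(), c(0, 0), dat), "two-step")
  expect_error(evaluate_loglik(model_rl(), c(NA, 0), dat), "non-finite")
  task <- generate_task("bandit2", 10, seed = 1)
  expect_error(simulate_agent(model_mf(), c(0, 0), task, seed = 1), "task")
})
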