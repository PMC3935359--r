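bp_std <- bayes_params(mu = c(1, -1), mu_hat = c(1, -1), sigma = 1,
                       sigma_hat = 1, lambda = 0.7, dt = 1)

test_that("observation_sample has mean mu_i and variance dt * sigma^2", {
  bp0 <- bayes_params(mu = c(2, -2), mu_hat = c(2, -2), sigma = 0,
                      sigma_hat = 1, lambda = 0.7, dt = 0.5)
  expect_equal(observation_sample(bp0, 1, epsilon = 3.7), 2)
  expect_equal(observation_sample(bp0, 2, epsilon = -1), -2)

  bp <- bayes_params(mu = c(1.5, -1.5), mu_hat = c(1.5, -1.5), sigma = 2,
                     sigma_hat = 1, lambda = 0.7, dt = 0.1)
  set.seed(4)
  eps <- rnorm(1e5)
  x <- vapply(eps, function(e) observation_sample(bp, 1, e), numeric(1))
  se_mean <- sqrt(bp$dt) * bp$sigma / sqrt(length(x))
  expect_lt(abs(mean(x) - 1.5), 4 * se_mean)
  v_target <- bp$dt * bp$sigma^2
  se_var <- v_target * sqrt(2 / (length(x) - 1))
  expect_lt(abs(var(x) - v_target), 4 * se_var)
  # halving dt halves the observation variance, not the mean
  bp_half <- bayes_params(mu = bp$mu, mu_hat = bp$mu_hat, sigma = bp$sigma,
                          sigma_hat = 1, lambda = 0.7, dt = bp$dt / 2)
  x2 <- vapply(eps, function(e) observation_sample(bp_half, 1, e), numeric(1))
  expect_equal(var(x2) / var(x), 0.5, tolerance = 1e-12)
  expect_equal(mean(x2) - 1.5, (mean(x) - 1.5) / sqrt(2), tolerance = 1e-12)
})

test_that("log_likelihood is a Gaussian log density with the stated symmetries", {
  # maximized at x = mu_hat_i
  xs <- seq(-3, 3, by = 0.25)
  ll <- log_likelihood(xs, 1, bp_std)
  expect_equal(xs[which.max(ll)], 1)
  # symmetric generative means give equal likelihood at x = 0
  expect_equal(log_likelihood(0, 1, bp_std), log_likelihood(0, 2, bp_std))
  # log-likelihood ratio antisymmetry under swapping the alternatives
  for (x in c(-1.7, 0.2, 2.5)) {
    d12 <- log_likelihood(x, 1, bp_std) - log_likelihood(x, 2, bp_std)
    d21 <- log_likelihood(x, 2, bp_std) - log_likelihood(x, 1, bp_std)
    expect_equal(d12, -d21)
  }
})

test_that("update_posterior matches hand values and the batch-Bayes oracle", {
  expect_equal(update_posterior(c(0.5, 0.5), 0, bp_std), c(0.5, 0.5))
  # x = 1: log-odds increment q = s_hat * x = 2, posterior e^2/(1+e^2)
  post <- update_posterior(c(0.5, 0.5), 1, bp_std)
  expect_equal(post[1], exp(2) / (1 + exp(2)), tolerance = 1e-12)

  # sequential updating equals one-shot normalized product (3 alternatives)
  set.seed(10)
  bp3 <- bayes_params(mu = c(1, 0, -1), mu_hat = c(0.8, 0.1, -1.2),
                      sigma = 1, sigma_hat = 0.9, lambda = 0.6,
                      prior = c(0.5, 0.3, 0.2), dt = 0.2)
  xs <- rnorm(20, 0.3, 0.5)
  seq_post <- bp3$prior
  for (x in xs) seq_post <- update_posterior(seq_post, x, bp3)
  batch <- log(bp3$prior)
  for (i in 1:3) batch[i] <- batch[i] + sum(log_likelihood(xs, i, bp3))
  batch <- exp(batch - max(batch))
  batch <- batch / sum(batch)
  expect_equal(seq_post, batch, tolerance = 1e-10)
})

test_that("posterior rows stay normalized along whole trajectories", {
  set.seed(17)
  for (r in 1:20) {
    bp <- random_bayes_params()
    out <- simulate_bayes_trial(bp, true_alternative = sample(1:2, 1),
                                deadline = 60 * bp$dt, record = TRUE,
                                stop_at_bound = FALSE)
    sums <- rowSums(out$trajectory$posterior)
    expect_true(all(abs(sums - 1) < 1e-10))
    # q_t = log z1 - log z2 by construction
    expect_equal(out$trajectory$log_odds,
                 out$trajectory$log_posterior[, 1] -
                   out$trajectory$log_posterior[, 2])
  }
})

test_that("with a uniform prior the log odds equal accumulated log-likelihood ratios", {
  set.seed(23)
  bp <- random_bayes_params(uniform_prior = TRUE)
  out <- simulate_bayes_trial(bp, true_alternative = 1,
                              deadline = 80 * bp$dt, record = TRUE,
                              stop_at_bound = FALSE)
  x <- out$trajectory$observations
  llr <- cumsum(log_likelihood(x, 1, bp) - log_likelihood(x, 2, bp))
  expect_equal(out$trajectory$log_odds, llr, tolerance = 1e-10)
})

test_that("decide uses inclusive bounds and the linked transforms", {
  pol <- decision_policy("posterior", 0.7)
  expect_identical(decide(c(0.71, 0.29), pol), 1L)
  expect_identical(decide(c(0.70, 0.30), pol), 1L)  # inclusive
  expect_identical(decide(c(0.69, 0.31), pol), NA_integer_)
  expect_identical(decide(c(0.29, 0.71), pol), 2L)
  expect_identical(decide(c(0.2, 0.75, 0.05), decision_policy("posterior", 0.7)),
                   2L)
  expect_error(decide(c(0.2, 0.7, 0.1), decision_policy("log_odds", 0.7)),
               "two alternatives")
  lp <- decision_policy("log_posterior", 0.7)
  expect_identical(decide(c(0.70, 0.30), lp), 1L)
  lo <- decision_policy("log_odds", 0.7)
  expect_identical(decide(c(0.70, 0.30), lo), 1L)
  expect_identical(decide(c(0.31, 0.69), lo), NA_integer_)
})

test_that("noise-free observer decides after ceil(bound / increment) steps", {
  # sigma = 0: every step adds the constant q-increment v_hat + s_hat * mu_1
  bp <- bayes_params(mu = c(1, -1), mu_hat = c(1, -1), sigma = 0,
                     sigma_hat = 1.3, lambda = 0.8, dt = 0.25)
  s_hat <- (bp$mu_hat[1] - bp$mu_hat[2]) / (bp$dt * bp$sigma_hat^2)
  v_hat <- (bp$mu_hat[2]^2 - bp$mu_hat[1]^2) / (2 * bp$dt * bp$sigma_hat^2)
  inc <- v_hat + s_hat * bp$mu[1]
  lam_star <- log(bp$lambda / (1 - bp$lambda))
  out <- simulate_bayes_trial(bp, true_alternative = 1, deadline = 100 * bp$dt)
  expect_identical(out$choice, 1L)
  expect_identical(out$n_steps, as.integer(ceiling(lam_star / inc - 1e-12)))
})

test_that("trajectory averaging obeys the minimum-contributor rule", {
  # synthetic trajectories with controlled lengths: posterior drifts to 1
  make_traj <- function(n, dt = 0.1) {
    p1 <- seq(0.5, 0.95, length.out = n)
    lp <- cbind(log(p1), log(1 - p1))
    structure(list(times = dt * seq_len(n), epsilons = rnorm(n),
                   observations = rnorm(n), posterior = cbind(p1, 1 - p1),
                   log_posterior = lp, log_odds = lp[, 1] - lp[, 2],
                   ddm_state = lp[, 1] - lp[, 2],
                   start_posterior = c(0.5, 0.5), true_alternative = 1L,
                   dt = dt), class = "bayes_trajectory")
  }
  set.seed(5)
  # 15 long trials and 4 short ones: contributors drop from 19 to 15 at step 6
  trajs <- c(replicate(15, make_traj(30), simplify = FALSE),
             replicate(4, make_traj(5), simplify = FALSE))
  avg <- average_trajectories(trajs, "posterior", min_trials = 16)
  # at time index 7 (step 6) only 15 contribute -> curve ends at step 5
  expect_equal(nrow(avg), 6)  # time 0 plus steps 1..5
  expect_equal(avg$n[1], 19)
  avg_all <- average_trajectories(trajs, "posterior", min_trials = 1)
  expect_equal(nrow(avg_all), 31)
  expect_equal(avg_all$n[31], 15)
})

test_that("rescaled averages start at 0 and reach 1 at the bound", {
  set.seed(6)
  bp <- bayes_params(mu = c(1, -1), mu_hat = c(1, -1), sigma = 1,
                     sigma_hat = 1, lambda = 0.7, dt = 0.05)
  pol <- decision_policy("posterior", bp$lambda)
  trajs <- lapply(1:30, function(i)
    simulate_bayes_trial(bp, pol, true_alternative = 1, deadline = 10,
                         record = TRUE, stop_at_bound = FALSE)$trajectory)
  for (variable in c("posterior", "log_posterior", "log_odds")) {
    avg <- average_trajectories(trajs, variable, min_trials = 1,
                                rescale = TRUE, policy = pol)
    expect_equal(avg$mean[1], 0, tolerance = 1e-12)  # start maps to 0
    # the bound value maps to 1: check via a degenerate one-point average
    sc_bound <- switch(variable, posterior = bp$lambda,
                       log_posterior = log(bp$lambda),
                       log_odds = log(bp$lambda / (1 - bp$lambda)))
    one <- trajs[[1]]
    one$posterior[1, ] <- c(sc_bound, 1 - sc_bound)
    if (variable == "posterior") {
      a1 <- average_trajectories(list(one), "posterior", min_trials = 1,
                                 rescale = TRUE, policy = pol)
      expect_equal(a1$mean[2], 1, tolerance = 1e-12)
    }
  }
})

test_that("unbounded posterior averages converge toward 1 for the correct alternative", {
  set.seed(7)
  bp <- bayes_params(mu = c(1, -1), mu_hat = c(1, -1), sigma = 0.8,
                     sigma_hat = 0.8, lambda = 0.7, dt = 0.05)
  trajs <- lapply(1:60, function(i)
    simulate_bayes_trial(bp, true_alternative = 1, deadline = 15,
                         record = TRUE, stop_at_bound = FALSE)$trajectory)
  avg <- average_trajectories(trajs, "posterior", alternative = 1,
                              min_trials = 1)
  expect_gt(tail(avg$mean, 1), 0.99)
  avg2 <- average_trajectories(trajs, "posterior", alternative = 2,
                               min_trials = 1)
  expect_lt(tail(avg2$mean, 1), 0.01)
})

test_that("stop_at_bound averaging only uses pre-crossing data", {
  set.seed(8)
  bp <- bayes_params(mu = c(1, -1), mu_hat = c(1, -1), sigma = 1,
                     sigma_hat = 1, lambda = 0.7, dt = 0.05)
  pol <- decision_policy("posterior", bp$lambda)
  trajs <- lapply(1:40, function(i)
    simulate_bayes_trial(bp, pol, true_alternative = 1, deadline = 10,
                         record = TRUE, stop_at_bound = FALSE)$trajectory)
  avg <- average_trajectories(trajs, "posterior", stop_at_bound = TRUE,
                              policy = pol, min_trials = 1)
  # no averaged point may lie at or beyond the bound for alternative 1
  expect_true(all(avg$mean < bp$lambda))
  # contributor counts are non-increasing
  expect_true(all(diff(avg$n) <= 0))
})

test_that("trajectories export to a tidy table", {
  set.seed(9)
  bp <- bayes_params(mu = c(1, -1), mu_hat = c(1, -1), sigma = 1,
                     sigma_hat = 1, lambda = 0.7, dt = 0.1)
  trs <- lapply(1:2, function(i)
    simulate_bayes_trial(bp, true_alternative = 1, deadline = 1,
                         record = TRUE, stop_at_bound = FALSE)$trajectory)
  df <- trajectories_to_df(trs)
  expect_named(df, c("trial", "step", "time", "variable", "alternative",
                     "value"))
  expect_setequal(unique(df$variable),
                  c("posterior", "log_posterior", "log_odds"))
  n_steps <- length(trs[[1]]$times)
  expect_equal(sum(df$trial == 1 & df$variable == "posterior"), 2 * n_steps)
})
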