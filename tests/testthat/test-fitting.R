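make_trials <- function(rt_correct, rt_error = numeric(0), rt_outlier = numeric(0),
                        n_undecided = 0) {
  n <- length(rt_correct) + length(rt_error) + length(rt_outlier) + n_undecided
  data.frame(
    choice = c(rep(1L, length(rt_correct)), rep(2L, length(rt_error)),
               rep(1L, length(rt_outlier)), rep(NA_integer_, n_undecided)),
    correct = c(rep(TRUE, length(rt_correct)), rep(FALSE, length(rt_error)),
                rep(TRUE, length(rt_outlier)), rep(NA, n_undecided)),
    rt = c(rt_correct, rt_error, rt_outlier, rep(NA_real_, n_undecided)))
}

test_that("summarize_behavior counts outliers and classes correctly", {
  set.seed(1)
  tr <- make_trials(rt_correct = runif(80, 0.4, 1.0),
                    rt_error = runif(17, 0.4, 1.2),
                    rt_outlier = runif(2, 1.3, 1.6),
                    n_undecided = 1)
  sm <- summarize_behavior(tr, deadline = 1.25)
  expect_equal(sm$n_trials, 97)
  expect_equal(sm$n_outliers, 3)
  expect_equal(sm$n_correct, 80)
  expect_equal(sm$n_error, 17)
  expect_equal(sm$acc, 80 / 97)
  # retaining decided outliers changes the counts
  sm2 <- summarize_behavior(tr, deadline = 1.25, drop_outliers = FALSE)
  expect_equal(sm2$n_trials, 99)
})

test_that("all-correct input flags error quantiles unavailable", {
  tr <- make_trials(rt_correct = seq(0.4, 1.0, length.out = 30))
  sm <- summarize_behavior(tr)
  expect_true(all(is.na(sm$q_error)))
  expect_false(anyNA(sm$q_correct))
  expect_equal(sm$acc, 1)
})

test_that("RT quantiles match an independent order-statistic oracle", {
  set.seed(2)
  probs <- c(0.02, 0.05, 0.1, 0.3, 0.5, 0.7, 0.9)
  rt_c <- runif(137, 0.3, 1.2)
  rt_e <- runif(23, 0.3, 1.2)
  sm <- summarize_behavior(make_trials(rt_c, rt_e), deadline = 1.25)
  expect_equal(sm$q_correct, quantile_type7_oracle(rt_c, probs),
               tolerance = 1e-12)
  expect_equal(sm$q_error, quantile_type7_oracle(rt_e, probs),
               tolerance = 1e-12)
  expect_true(all(diff(sm$q_correct) >= 0))
})

test_that("estimate_weights is deterministic in the seed and inverse-variance", {
  theta <- c(sigma = 18.1, sigma_hat = 28.6, t_nd = 0.42)
  w1 <- estimate_weights(theta, n_reps = 6, n_trials = 150, seed = 42)
  w2 <- estimate_weights(theta, n_reps = 6, n_trials = 150, seed = 42)
  expect_identical(w1, w2)
  expect_true(is.finite(w1$w_acc) && w1$w_acc > 0)
  expect_true(all(is.finite(w1$w_q_correct) & w1$w_q_correct > 0))
})

test_that("pseudo_log_likelihood matches a hand-computed weighted sum", {
  probs <- c(0.02, 0.05, 0.1, 0.3, 0.5, 0.7, 0.9)
  obs <- structure(list(acc = 0.8, quantile_probs = probs,
                        q_correct = seq(0.4, 1.0, length.out = 7),
                        q_error = seq(0.45, 1.05, length.out = 7),
                        n_trials = 100, n_correct = 80, n_error = 20,
                        n_outliers = 0), class = "behavior_summary")
  pred <- obs
  pred$acc <- 0.75
  pred$q_correct <- obs$q_correct + 0.02
  pred$q_error <- obs$q_error - 0.03
  w <- structure(list(w_acc = 4246, w_q_correct = rep(3.5, 7),
                      w_q_error = rep(4.2, 7), quantile_probs = probs,
                      n_reps = 30, n_trials = 1100),
                 class = "objective_weights")
  expected <- -4246 * 0.05^2 - sum(3.5 * rep(0.02^2, 7)) -
    sum(4.2 * rep(0.03^2, 7))
  expect_equal(pseudo_log_likelihood(obs, weights = w, prediction = pred),
               expected, tolerance = 1e-12)
  # perfect agreement attains the maximum, 0
  expect_equal(pseudo_log_likelihood(obs, weights = w, prediction = obs), 0)
  # increasing the accuracy residual strictly decreases the value
  worse <- pred
  worse$acc <- 0.7
  expect_lt(pseudo_log_likelihood(obs, weights = w, prediction = worse),
            pseudo_log_likelihood(obs, weights = w, prediction = pred))
})

test_that("the objective depends on the data only through its summary", {
  set.seed(3)
  rt_c <- runif(60, 0.4, 1.0)
  rt_e <- runif(15, 0.4, 1.0)
  tr <- make_trials(rt_c, rt_e)
  perm <- tr[sample(nrow(tr)), ]
  s1 <- summarize_behavior(tr)
  s2 <- summarize_behavior(perm)
  w <- estimate_weights(c(sigma = 18.1, sigma_hat = 28.6, t_nd = 0.42),
                        n_reps = 4, n_trials = 100, seed = 9)
  pred <- predict_summary(c(sigma = 18.1, sigma_hat = 28.6, t_nd = 0.42),
                          n_trials = 100, n_reps = 2, seed = 10)
  expect_equal(pseudo_log_likelihood(s1, weights = w, prediction = pred),
               pseudo_log_likelihood(s2, weights = w, prediction = pred))
})

test_that("sparse error responses drop the error terms with a warning", {
  tr <- make_trials(rt_correct = runif(95, 0.4, 1.0),
                    rt_error = runif(5, 0.4, 1.0))
  obs <- summarize_behavior(tr)
  w <- estimate_weights(c(sigma = 18.1, sigma_hat = 28.6, t_nd = 0.42),
                        n_reps = 4, n_trials = 100, seed = 9)
  pred <- predict_summary(c(sigma = 18.1, sigma_hat = 28.6, t_nd = 0.42),
                          n_trials = 100, n_reps = 2, seed = 10)
  expect_warning(
    ll <- pseudo_log_likelihood(obs, weights = w, prediction = pred,
                                min_error_count = 10),
    "dropped")
  ll_manual <- -w$w_acc * (obs$acc - pred$acc)^2 -
    sum(w$w_q_correct * (obs$q_correct - pred$q_correct)^2)
  expect_equal(ll, ll_manual)
})

test_that("predict_summary responds to its parameters as the model dictates", {
  theta <- c(sigma = 18.1, sigma_hat = 28.6, t_nd = 0.42)
  # near-noiseless input drives accuracy toward 1
  hi <- predict_summary(c(sigma = 0.05, sigma_hat = 28.6, t_nd = 0.42),
                        n_trials = 400, n_reps = 3, seed = 4)
  expect_gt(hi$acc, 0.99)
  # a higher bound stochastically lengthens RTs
  lo_b <- predict_summary(theta, fixed = list(lambda = 0.6),
                          n_trials = 600, n_reps = 5, seed = 5)
  hi_b <- predict_summary(theta, fixed = list(lambda = 0.9),
                          n_trials = 600, n_reps = 5, seed = 5)
  expect_gt(hi_b$q_correct[4], lo_b$q_correct[4])
  # the default grid uses at most 45 accumulation steps before the deadline
  expect_identical(steps_to_deadline(0.0283, 1.25), 45L)
  pr <- predict_summary(theta, n_trials = 200, n_reps = 2, seed = 6)
  expect_lte(max(pr$q_correct, na.rm = TRUE), 45 * 0.0283 + theta[["t_nd"]])
})

test_that("chain bookkeeping retains floor((n - burn_in)/thin) samples", {
  set.seed(12)
  theta <- c(sigma = 18.1, sigma_hat = 28.6, t_nd = 0.42)
  bp <- bayes_params(mu = c(1, -1), mu_hat = c(1, -1), sigma = theta[1],
                     sigma_hat = theta[2], lambda = 0.7, dt = 0.0283,
                     t_nd = theta[3])
  tr <- simulate_bayes_experiment(bp, 400, deadline = 1.25)
  obs <- summarize_behavior(tr)
  w <- estimate_weights(theta, n_reps = 4, n_trials = 200, seed = 13)
  fit <- fit_mcmc(obs, w, n_samples = 60, burn_in = 20, thin = 7,
                  n_trials = 120, n_reps = 2, seed = 14)
  expect_equal(nrow(fit$retained), floor((60 - 20) / 7))
  expect_true(all(fit$retained > 0))  # positivity restriction
  expect_equal(ncol(fit$chain), 3)
  expect_equal(fit$theta_names, c("sigma", "sigma_hat", "t_nd"))
  expect_true(is.finite(fit$acceptance_rate))
  expect_error(fit_mcmc(obs, w, n_samples = 50, burn_in = 50),
               "burn_in")
})

test_that("fit_ez inverts the closed-form forward statistics to < 1e-6", {
  for (pars in list(c(v = 0.2, B = 0.08, t_nd = 0.3),
                    c(v = 0.35, B = 0.05, t_nd = 0.25),
                    c(v = 0.1, B = 0.12, t_nd = 0.4))) {
    p <- ddm_params(v = pars[["v"]], s = 0.1, B = pars[["B"]], dt = 0.0283,
                    t_nd = pars[["t_nd"]])
    sm <- ddm_summary_closed_form(p)
    fit <- fit_ez(sm$acc, sm$mrt, sm$vrt)
    expect_equal(fit$ddm$v, p$v, tolerance = 1e-10)
    expect_equal(fit$ddm$B, p$B, tolerance = 1e-10)
    expect_equal(fit$t_nd, p$t_nd, tolerance = 1e-10)
    expect_equal(fit$a, 2 * p$B, tolerance = 1e-10)
  }
})

test_that("fit_ez edge cases follow the documented contract", {
  expect_error(fit_ez(0.5, 0.5, 0.04), "edge_correction")
  expect_error(fit_ez(1, 0.5, 0.04), "edge_correction")
  corrected <- fit_ez(1, 0.5, 0.04, edge_correction = TRUE, n_trials = 100)
  expect_true(is.finite(corrected$ddm$v))
  # chance-level accuracy maps to near-zero drift after correction
  near0 <- fit_ez(0.5, 0.5, 0.04, edge_correction = TRUE, n_trials = 1e5)
  expect_lt(abs(near0$ddm$v), 0.02)
})

test_that("fit_ez optionally rescales to a posterior bound and translates", {
  p <- ddm_params(v = 0.2, s = 0.1, B = 0.08, dt = 0.0283, t_nd = 0.3)
  sm <- ddm_summary_closed_form(p)
  fit <- fit_ez(sm$acc, sm$mrt, sm$vrt, lambda = 0.7)
  expect_equal(fit$scaled$B, log(0.7 / 0.3), tolerance = 1e-10)
  expect_s3_class(fit$bayes, "bayes_params")
  expect_true(fit$bayes$sigma > 0 && fit$bayes$sigma_hat > 0)
  expect_equal(fit$bayes$lambda, 0.7, tolerance = 1e-10)
})

test_that("posterior_density_at agrees with a reference Gaussian density", {
  skip_if_not_installed("mclust")
  set.seed(20)
  X <- cbind(sigma = rnorm(80, 18, 2), sigma_hat = rnorm(80, 28, 3),
             t_nd = rnorm(80, 0.4, 0.05))
  samples <- structure(list(retained = X, theta_names = colnames(X)),
                       class = "posterior_samples")
  mu <- colMeans(X)
  S <- cov(X)
  for (pt in list(mu, mu + c(1, -2, 0.02), mu - c(3, 1, 0.1))) {
    expect_equal(posterior_density_at(samples, pt),
                 mclust::dmvnorm(rbind(pt), mu, S)[1], tolerance = 1e-10)
  }
  # at the mean the density is the Gaussian peak 1/((2*pi)^{3/2} |S|^{1/2})
  expect_equal(posterior_density_at(samples, mu),
               1 / ((2 * pi)^(3 / 2) * sqrt(det(S))), tolerance = 1e-10)
  # symmetry under reflection about the mean
  d <- c(1.2, -0.7, 0.03)
  expect_equal(posterior_density_at(samples, mu + d),
               posterior_density_at(samples, mu - d), tolerance = 1e-12)
})

test_that("split_rhat and ess behave sensibly on known chains", {
  set.seed(30)
  iid <- rnorm(2000)
  expect_lt(abs(split_rhat(iid) - 1), 0.05)
  expect_gt(ess(iid), 1000)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.95), 2000))
  expect_lt(ess(ar), ess(iid))
  trending <- cumsum(rnorm(2000)) + seq(0, 50, length.out = 2000)
  expect_gt(split_rhat(trending), 1.1)
})
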