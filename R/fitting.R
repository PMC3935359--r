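#' Summarize a trial table into accuracy and RT quantiles
#'
#' Removes outliers (undecided trials and trials with `rt > deadline`),
#' then computes the proportion correct over the retained trials and reaction
#' time quantiles separately for correct and error responses. The quantile
#' estimator is linear interpolation of order statistics
#' (`stats::quantile()` type 7).
#'
#' @param trials data frame with at least `choice`, `correct` and `rt`
#'   columns (as produced by [simulate_bayes_experiment()],
#'   [simulate_ddm_experiment()] or [generate_experiment()]).
#' @param quantile_probs quantile levels; the default is the seven levels
#'   0.02, 0.05, 0.1, 0.3, 0.5, 0.7, 0.9.
#' @param deadline outlier threshold on the reaction time, in seconds.
#' @param drop_outliers if `FALSE`, decided trials beyond the deadline are
#'   retained in the summary (undecided trials never contribute).
#' @return An object of class `behavior_summary`: `acc`, `quantile_probs`,
#'   `q_correct`, `q_error` (a vector of `NA`s when no error responses are
#'   available — never fabricated), `n_trials` (retained), `n_correct`,
#'   `n_error`, `n_outliers`.
#' @export
summarize_behavior <- function(trials,
                               quantile_probs = c(0.02, 0.05, 0.1, 0.3,
                                                  0.5, 0.7, 0.9),
                               deadline = 1.25, drop_outliers = TRUE) {
  need <- c("choice", "correct", "rt")
  if (!all(need %in% names(trials)))
    stop("'trials' must contain columns: ", paste(need, collapse = ", "))
  decided <- !is.na(trials$choice)
  late <- decided & trials$rt > deadline
  keep <- if (drop_outliers) decided & !late else decided
  n_out <- sum(!decided | late)
  if (!any(keep)) stop("no trials retained after outlier removal")
  tt <- trials[keep, , drop = FALSE]
  correct <- as.logical(tt$correct)
  qc <- if (any(correct))
    stats::quantile(tt$rt[correct], probs = quantile_probs, type = 7,
                    names = FALSE)
  else rep(NA_real_, length(quantile_probs))
  qe <- if (any(!correct))
    stats::quantile(tt$rt[!correct], probs = quantile_probs, type = 7,
                    names = FALSE)
  else rep(NA_real_, length(quantile_probs))
  structure(list(acc = mean(correct),
                 quantile_probs = quantile_probs,
                 q_correct = qc,
                 q_error = qe,
                 n_trials = nrow(tt),
                 n_correct = sum(correct),
                 n_error = sum(!correct),
                 n_outliers = n_out),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf("Behavioral summary: %d trials retained (%d outliers), accuracy %.3f\n",
              x$n_trials, x$n_outliers, x$acc))
  cat("  RT quantiles (s) at", paste(x$quantile_probs, collapse = ", "), "\n")
  cat("  correct:", paste(sprintf("%.3f", x$q_correct), collapse = " "), "\n")
  if (all(is.na(x$q_error))) {
    cat("  error:   unavailable (no error responses)\n")
  } else {
    cat("  error:  ", paste(sprintf("%.3f", x$q_error), collapse = " "), "\n")
  }
  invisible(x)
}

# Build the equal-means observer implied by theta = (sigma, sigma_hat, t_nd)
# under the fixed settings (posterior bound, feature amplitude, time step).
.theta_to_params <- function(theta, fixed) {
  bayes_params(mu = c(fixed$mu, -fixed$mu), mu_hat = c(fixed$mu, -fixed$mu),
               sigma = theta[["sigma"]], sigma_hat = theta[["sigma_hat"]],
               lambda = fixed$lambda, dt = fixed$dt, t_nd = theta[["t_nd"]])
}

.default_fixed <- function(fixed = list()) {
  utils::modifyList(list(lambda = 0.7, mu = 1, dt = 0.0283, deadline = 1.25),
                    fixed)
}

#' Model-predicted behavioral summary for a parameter set
#'
#' Simulates `n_reps` independent synthetic experiments of `n_trials`
#' two-alternative trials at `theta = (sigma, sigma_hat, t_nd)` under the
#' equal-means constraints (posterior bound, feature amplitude and time step
#' given in `fixed`) and averages accuracy and the RT quantiles across
#' repetitions. Deadline truncation matches [summarize_behavior()].
#'
#' @param theta named vector with `sigma`, `sigma_hat`, `t_nd` (all `> 0`).
#' @param fixed list overriding the fixed settings `lambda` (0.7), `mu` (1),
#'   `dt` (0.0283 s), `deadline` (1.25 s).
#' @param n_trials trials per simulated experiment (default 1100).
#' @param n_reps number of simulated experiments averaged (default 30).
#' @param quantile_probs quantile levels (default: the seven standard levels).
#' @param seed optional integer seed.
#' @return A `behavior_summary` of averaged predictions; `q_error` entries
#'   are averages over the repetitions that produced error responses and are
#'   `NA` when none did. Attribute `"n_reps_error"` counts contributing reps.
#' @export
predict_summary <- function(theta, fixed = list(), n_trials = 1100L,
                            n_reps = 30L,
                            quantile_probs = c(0.02, 0.05, 0.1, 0.3,
                                               0.5, 0.7, 0.9),
                            seed = NULL) {
  if (any(theta <= 0)) stop("all components of 'theta' must be positive")
  fixed <- .default_fixed(fixed)
  if (!is.null(seed)) set.seed(seed)
  bp <- .theta_to_params(theta, fixed)
  nq <- length(quantile_probs)
  acc <- numeric(n_reps)
  qc <- matrix(NA_real_, n_reps, nq)
  qe <- matrix(NA_real_, n_reps, nq)
  n_out <- n_err <- 0L
  for (r in seq_len(n_reps)) {
    tr <- simulate_bayes_experiment(bp, n_trials, deadline = fixed$deadline)
    sm <- summarize_behavior(tr, quantile_probs, deadline = fixed$deadline)
    acc[r] <- sm$acc
    qc[r, ] <- sm$q_correct
    qe[r, ] <- sm$q_error
    n_out <- n_out + sm$n_outliers
    n_err <- n_err + sm$n_error
  }
  n_reps_error <- sum(stats::complete.cases(qe))
  q_error <- if (n_reps_error > 0) colMeans(qe, na.rm = TRUE)
  else rep(NA_real_, nq)
  structure(list(acc = mean(acc),
                 quantile_probs = quantile_probs,
                 q_correct = colMeans(qc, na.rm = TRUE),
                 q_error = q_error,
                 n_trials = n_trials,
                 n_correct = NA_integer_,
                 n_error = as.integer(round(n_err / n_reps)),
                 n_outliers = as.integer(round(n_out / n_reps))),
            class = "behavior_summary",
            n_reps_error = n_reps_error)
}

#' Precision weights for the quantile-based objective
#'
#' Simulates `n_reps` independent experiments at a reference parameter set
#' and sets the weight of each summary statistic (accuracy and the 14 RT
#' quantiles) to the inverse of its variance across repetitions. The
#' reference set should be chosen to exhibit a generously large spread of the
#' statistics, so the weights act as an upper bound on the expected
#' observation variability; the default reference produces accuracy around
#' 0.8 with a broad RT distribution under the default settings. Weights are
#' not updated during fitting: they describe the precision of the
#' experimental observations, not of model predictions.
#'
#' @param reference_theta named vector (`sigma`, `sigma_hat`, `t_nd`) at
#'   which the spread is measured.
#' @param n_reps repetitions (default 30).
#' @param n_trials trials per repetition (default 1100).
#' @param fixed fixed settings, see [predict_summary()].
#' @param quantile_probs quantile levels.
#' @param seed optional integer seed (same seed, same weights).
#' @param var_floor lower floor on each variance before inversion, guarding
#'   degenerate zero-variance statistics. Simulated reaction times live on
#'   the lattice `t_nd + k * dt`, so extreme quantiles can be identical
#'   across repetitions; the default floor `(dt / 2)^2` caps any quantile
#'   weight at the precision of the time grid itself.
#' @param acc_floor variance floor for the (dimensionless) accuracy term.
#' @return An object of class `objective_weights`: `w_acc`, `w_q_correct`,
#'   `w_q_error` (each `NA` when the statistic was never observed),
#'   `quantile_probs`, and the generating settings.
#' @export
estimate_weights <- function(reference_theta = c(sigma = 18.1,
                                                 sigma_hat = 28.6,
                                                 t_nd = 0.42),
                             n_reps = 30L, n_trials = 1100L, fixed = list(),
                             quantile_probs = c(0.02, 0.05, 0.1, 0.3,
                                                0.5, 0.7, 0.9),
                             seed = NULL, var_floor = NULL,
                             acc_floor = 1e-10) {
  fixed <- .default_fixed(fixed)
  if (is.null(var_floor)) var_floor <- (fixed$dt / 2)^2
  if (!is.null(seed)) set.seed(seed)
  bp <- .theta_to_params(reference_theta, fixed)
  nq <- length(quantile_probs)
  acc <- numeric(n_reps)
  qc <- matrix(NA_real_, n_reps, nq)
  qe <- matrix(NA_real_, n_reps, nq)
  for (r in seq_len(n_reps)) {
    tr <- simulate_bayes_experiment(bp, n_trials, deadline = fixed$deadline)
    sm <- summarize_behavior(tr, quantile_probs, deadline = fixed$deadline)
    acc[r] <- sm$acc
    qc[r, ] <- sm$q_correct
    qe[r, ] <- sm$q_error
  }
  inv_var <- function(m) {
    v <- apply(m, 2L, function(col) {
      col <- col[!is.na(col)]
      if (length(col) < 2L) return(NA_real_)
      stats::var(col)
    })
    1 / pmax(v, var_floor)
  }
  structure(list(w_acc = 1 / max(stats::var(acc), acc_floor),
                 w_q_correct = inv_var(qc),
                 w_q_error = inv_var(qe),
                 quantile_probs = quantile_probs,
                 reference_theta = reference_theta,
                 n_reps = n_reps, n_trials = n_trials),
            class = "objective_weights")
}

#' @export
print.objective_weights <- function(x, ...) {
  cat("Objective precision weights (inverse variance over",
      x$n_reps, "repetitions)\n")
  cat("  w_acc =", signif(x$w_acc, 5), "\n")
  cat("  mean correct-quantile weight:",
      signif(mean(x$w_q_correct, na.rm = TRUE), 5), "\n")
  cat("  mean error-quantile weight:  ",
      signif(mean(x$w_q_error, na.rm = TRUE), 5), "\n")
  invisible(x)
}

#' Quantile-weighted Gaussian pseudo-log-likelihood
#'
#' The objective used for fitting: up to an additive constant,
#' \deqn{L(\theta) = -w_{Acc}(Acc - Acc(\theta))^2
#'   - \sum_{e \in \{0,1\}} \sum_i w_{q_{e,i}} (q_{e,i} - q_{e,i}(\theta))^2,}
#' where the predictions come from [predict_summary()] (fresh simulation
#' noise on every call unless a `prediction` is supplied). Error-response
#' terms are dropped, with a warning, when the observed error count falls
#' below `min_error_count` or when predictions or weights for the error
#' class are unavailable.
#'
#' @param observed a `behavior_summary` of the data.
#' @param theta parameter vector at which to predict (ignored when
#'   `prediction` is given).
#' @param weights an `objective_weights` object on the same quantile grid.
#' @param fixed,n_trials,n_reps,seed prediction settings, see
#'   [predict_summary()].
#' @param prediction optional precomputed `behavior_summary` of predictions.
#' @param min_error_count minimum observed error responses required to use
#'   the error-quantile terms (default 10).
#' @param warn emit the dropped-error-terms warning (default `TRUE`).
#' @return The scalar pseudo-log-likelihood (0 is the maximum, attained when
#'   observation and prediction coincide).
#' @export
pseudo_log_likelihood <- function(observed, theta = NULL, weights,
                                  fixed = list(), n_trials = 1100L,
                                  n_reps = 30L, seed = NULL,
                                  prediction = NULL, min_error_count = 10L,
                                  warn = TRUE) {
  stopifnot(inherits(observed, "behavior_summary"),
            inherits(weights, "objective_weights"))
  if (is.null(prediction)) {
    if (is.null(theta)) stop("supply either 'theta' or 'prediction'")
    prediction <- predict_summary(theta, fixed = fixed, n_trials = n_trials,
                                  n_reps = n_reps,
                                  quantile_probs = observed$quantile_probs,
                                  seed = seed)
  }
  if (!isTRUE(all.equal(observed$quantile_probs, prediction$quantile_probs)) ||
      !isTRUE(all.equal(observed$quantile_probs, weights$quantile_probs)))
    stop("observed, predicted and weight quantile grids must match")
  ll <- -weights$w_acc * (observed$acc - prediction$acc)^2 -
    sum(weights$w_q_correct * (observed$q_correct - prediction$q_correct)^2)
  use_error <- observed$n_error >= min_error_count &&
    all(is.finite(observed$q_error)) &&
    all(is.finite(prediction$q_error)) &&
    all(is.finite(weights$w_q_error))
  if (use_error) {
    ll <- ll - sum(weights$w_q_error *
                     (observed$q_error - prediction$q_error)^2)
  } else if (warn) {
    warning("error-response quantile terms dropped (too few error responses ",
            "or unavailable predictions/weights)", call. = FALSE)
  }
  ll
}

# log density of a multivariate normal with covariance factor R (upper chol)
.dmvnorm_log <- function(x, mean, chol_upper) {
  d <- length(mean)
  z <- backsolve(chol_upper, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(chol_upper))) - 0.5 * sum(z^2)
}

#' Split-half potential scale reduction of a single chain
#'
#' Splits the (post-burn-in) draws of each parameter into two halves and
#' computes the potential scale reduction factor between them — a basic
#' stationarity diagnostic for a single-chain run.
#'
#' @param x numeric vector of draws.
#' @return The split R-hat value.
#' @export
split_rhat <- function(x) {
  n <- floor(length(x) / 2) * 2
  if (n < 4) return(NA_real_)
  m <- matrix(x[seq_len(n)], ncol = 2)
  nh <- n / 2
  W <- mean(apply(m, 2, stats::var))
  Bv <- nh * stats::var(colMeans(m))
  sqrt(((nh - 1) / nh * W + Bv / nh) / W)
}

#' Effective sample size of a chain
#'
#' Autocorrelation-based effective sample size using the initial positive
#' sequence of sample autocorrelations.
#'
#' @param x numeric vector of draws.
#' @return Effective number of independent draws.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4 || stats::var(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos) > 0) rho <- rho[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(rho))
}

#' Fit the Bayesian observer by adaptive Metropolis MCMC
#'
#' Samples the parameters `theta = (sigma, sigma_hat, t_nd)` from the
#' pseudo-posterior defined by the quantile-weighted objective
#' ([pseudo_log_likelihood()]) and wide zero-mean Gaussian priors, using an
#' adaptive Metropolis sampler with optional delayed rejection (DRAM style).
#' Proposals with any non-positive component are rejected, restricting the
#' chain to the positive orthant. The objective is stochastic (fresh
#' simulation noise at every evaluation); by default the current state's
#' log-posterior is also re-evaluated every iteration, so a single lucky
#' evaluation cannot freeze the chain and the retained samples reflect the
#' objective noise honestly (set `reevaluate = FALSE` to keep the stored
#' value instead).
#'
#' @param observed a `behavior_summary` of the data to fit.
#' @param weights precomputed `objective_weights` (they are not updated
#'   during fitting).
#' @param fixed fixed settings, see [predict_summary()].
#' @param priors list of prior standard deviations: `sigma` (400),
#'   `sigma_hat` (400), `t_nd` (10.2); priors are zero-mean Gaussians
#'   truncated to positive values by proposal rejection.
#' @param init named start values (default `sigma = 2`, `sigma_hat = 2`,
#'   `t_nd = 0.42`).
#' @param n_samples chain length (default 3000).
#' @param burn_in discarded initial samples (default 1000).
#' @param thin keep every `thin`-th post-burn-in sample (default 10); the
#'   retained count is `floor((n_samples - burn_in) / thin)`.
#' @param n_trials,n_reps simulation effort per objective evaluation.
#' @param proposal_sd initial (diagonal) proposal standard deviations.
#' @param adapt_start iteration at which covariance adaptation begins.
#' @param adapt_interval iterations between adaptation updates; each update
#'   also rescales the proposal toward the 0.234 random-walk acceptance
#'   target.
#' @param reevaluate refresh the current state's (stochastic) log-posterior
#'   every iteration (default `TRUE`).
#' @param dr use a delayed-rejection second stage with a shrunk proposal.
#' @param dr_scale scale factor of the second-stage proposal.
#' @param min_error_count see [pseudo_log_likelihood()].
#' @param common_random_numbers if `TRUE`, every objective evaluation reuses
#'   the same simulation seed, removing objective noise (useful for testing;
#'   the default matches the fresh-noise behavior of stochastic fitting).
#' @param seed optional integer seed for the whole run.
#' @param verbose print progress every 500 iterations.
#' @return An object of class `posterior_samples`: `theta_names`, `chain`
#'   (`n_samples` x 3), `lp`, `retained` (thinned post-burn-in draws),
#'   `means`, `sds`, `acceptance_rate`, `rhat` and `ess` per parameter, and
#'   the bookkeeping fields `n_samples`, `burn_in`, `thin`.
#' @export
fit_mcmc <- function(observed, weights, fixed = list(),
                     priors = list(sigma = 400, sigma_hat = 400, t_nd = 10.2),
                     init = c(sigma = 2, sigma_hat = 2, t_nd = 0.42),
                     n_samples = 3000L, burn_in = 1000L, thin = 10L,
                     n_trials = 1100L, n_reps = 30L,
                     proposal_sd = c(1, 1, 0.02),
                     adapt_start = 100L, adapt_interval = 25L,
                     reevaluate = TRUE,
                     dr = TRUE, dr_scale = 0.25,
                     min_error_count = 10L,
                     common_random_numbers = FALSE,
                     seed = NULL, verbose = FALSE) {
  stopifnot(inherits(observed, "behavior_summary"),
            inherits(weights, "objective_weights"))
  if (burn_in >= n_samples) stop("'burn_in' must be smaller than 'n_samples'")
  if (thin < 1L) stop("'thin' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  theta_names <- c("sigma", "sigma_hat", "t_nd")
  theta <- init[theta_names]
  if (any(theta <= 0)) stop("'init' must be positive")
  prior_sd <- c(priors$sigma, priors$sigma_hat, priors$t_nd)
  crn_seed <- if (common_random_numbers)
    sample.int(.Machine$integer.max, 1L) else NULL
  # decide once whether error terms participate; avoids a warning per step
  use_error <- observed$n_error >= min_error_count &&
    all(is.finite(observed$q_error)) &&
    all(is.finite(weights$w_q_error))
  if (!use_error)
    warning("error-response quantile terms are dropped from the objective",
            call. = FALSE)
  log_post <- function(th) {
    if (any(th <= 0)) return(-Inf)
    ll <- pseudo_log_likelihood(observed, theta = th, weights = weights,
                                fixed = fixed, n_trials = n_trials,
                                n_reps = n_reps, seed = crn_seed,
                                min_error_count = if (use_error)
                                  min_error_count else .Machine$integer.max,
                                warn = FALSE)
    ll + sum(stats::dnorm(th, 0, prior_sd, log = TRUE))
  }
  lp_cur <- log_post(theta)
  if (!is.finite(lp_cur))
    stop("the objective is not finite at the initial values")
  d <- 3L
  chain <- matrix(NA_real_, n_samples, d,
                  dimnames = list(NULL, theta_names))
  lp_trace <- numeric(n_samples)
  R <- diag(proposal_sd, d)  # upper-triangular factor of proposal covariance
  g_scale <- 1  # global proposal scale, adapted toward 0.234 acceptance
  accepted <- logical(n_samples)
  sd_adapt <- 2.38^2 / d
  for (i in seq_len(n_samples)) {
    if (reevaluate) lp_cur <- log_post(theta)
    prop1 <- theta + g_scale * as.numeric(crossprod(R, stats::rnorm(d)))
    lp1 <- log_post(prop1)
    a1 <- min(1, exp(lp1 - lp_cur))
    if (is.finite(lp1) && stats::runif(1) < a1) {
      theta <- prop1
      lp_cur <- lp1
      accepted[i] <- TRUE
    } else if (dr) {
      # delayed-rejection second stage with a shrunk proposal
      prop2 <- theta + dr_scale * g_scale *
        as.numeric(crossprod(R, stats::rnorm(d)))
      lp2 <- log_post(prop2)
      if (is.finite(lp2)) {
        a_21 <- min(1, exp(lp1 - lp2))
        num_q <- .dmvnorm_log(prop1, prop2, g_scale * R)
        den_q <- .dmvnorm_log(prop1, theta, g_scale * R)
        log_a2 <- (lp2 - lp_cur) + (num_q - den_q) +
          log1p(-a_21) - log1p(-a1)
        if (is.finite(log_a2) && stats::runif(1) < exp(min(0, log_a2))) {
          theta <- prop2
          lp_cur <- lp2
          accepted[i] <- TRUE
        }
      }
    }
    chain[i, ] <- theta
    lp_trace[i] <- lp_cur
    if (i >= adapt_start && i %% adapt_interval == 0L) {
      S <- sd_adapt * stats::cov(chain[seq_len(i), , drop = FALSE]) +
        diag(1e-10, d)
      Rnew <- tryCatch(chol(S), error = function(e) NULL)
      if (!is.null(Rnew)) R <- Rnew
      acc_win <- mean(accepted[(i - adapt_interval + 1L):i])
      g_scale <- g_scale * exp(acc_win - 0.234)
    }
    if (i >= 200L && i %% 200L == 0L &&
        !any(accepted[(i - 199L):i]))
      warning(sprintf("no accepted proposal in iterations %d-%d", i - 199L, i),
              call. = FALSE)
    if (verbose && i %% 500L == 0L)
      message(sprintf("iteration %d / %d (acceptance %.2f)", i, n_samples,
                      mean(accepted[seq_len(i)])))
  }
  keep_idx <- seq.int(burn_in + thin, n_samples, by = thin)
  retained <- chain[keep_idx, , drop = FALSE]
  structure(list(theta_names = theta_names,
                 chain = chain,
                 lp = lp_trace,
                 n_samples = n_samples,
                 burn_in = burn_in,
                 thin = thin,
                 retained = retained,
                 means = colMeans(retained),
                 sds = apply(retained, 2L, stats::sd),
                 acceptance_rate = mean(accepted),
                 rhat = apply(retained, 2L, split_rhat),
                 ess = apply(retained, 2L, ess),
                 fixed = .default_fixed(fixed)),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("MCMC posterior: %d samples, burn-in %d, thin %d -> %d retained\n",
              x$n_samples, x$burn_in, x$thin, nrow(x$retained)))
  cat(sprintf("  acceptance rate %.2f\n", x$acceptance_rate))
  tab <- data.frame(mean = x$means, sd = x$sds, rhat = x$rhat, ess = x$ess)
  print(round(tab, 4))
  invisible(x)
}

#' Closed-form EZ fit of the pDDM
#'
#' Inverts the proportion of correct responses, the mean and the variance of
#' correct-response reaction times into drift `v`, boundary separation `a`
#' (with bound `B = a/2`; the process starts midway between the bounds) and
#' non-decision time, under the conventional fixed diffusion scale
#' `s = 0.1`. With `L = qlogis(acc)` the solution is
#' \deqn{v = \mathrm{sign}(acc - 0.5)\, s
#'         \left[\frac{L (L\,acc^2 - L\,acc + acc - 0.5)}{vrt}\right]^{1/4},
#'       \quad a = \frac{s^2 L}{v},}
#' with mean decision time `(a / 2v) (1 - e^{-va/s^2}) / (1 + e^{-va/s^2})`
#' subtracted from `mrt` to give the non-decision time. The closed forms
#' assume the continuum limit and no deadline truncation.
#'
#' @param acc proportion correct, strictly in (0, 1) and not 0.5 (see
#'   `edge_correction`).
#' @param mrt mean correct-response RT in seconds.
#' @param vrt variance of correct-response RTs, `> 0`.
#' @param s diffusion-scale convention (default 0.1).
#' @param dt time step recorded on the returned parameter object (the EZ
#'   solution itself is a continuum-limit result).
#' @param edge_correction apply the standard edge corrections for `acc` of 0,
#'   0.5 or 1 (requires `n_trials`); otherwise those values are an error.
#' @param n_trials trial count used by the edge correction.
#' @param lambda optional posterior bound: when supplied, the fit is also
#'   rescaled to this bound ([rescale_to_bound()]) and translated to the
#'   observer ([ddm_to_bayes_equal_means()]).
#' @return An object of class `ez_fit`: `ddm` (a [ddm_params()] with
#'   `B = a/2` and the fitted `t_nd`), `a`, `mdt`, `t_nd`, and — when
#'   `lambda` is given — `scaled` (rescaled [ddm_params()]), `bayes` (the
#'   translated observer) and `c` (the scaling constant).
#' @examples
#' p <- ddm_params(v = 0.2, s = 0.1, B = 0.08, dt = 0.0283, t_nd = 0.3)
#' sm <- ddm_summary_closed_form(p)
#' fit_ez(sm$acc, sm$mrt, sm$vrt)$ddm  # recovers v, B, t_nd
#' @export
fit_ez <- function(acc, mrt, vrt, s = 0.1, dt = 0.0283,
                   edge_correction = FALSE, n_trials = NULL, lambda = NULL) {
  if (!all(is.finite(c(acc, mrt, vrt))) || vrt <= 0)
    stop("'acc', 'mrt', 'vrt' must be finite with vrt > 0")
  if (acc <= 0 || acc >= 1 || acc == 0.5) {
    if (!edge_correction || is.null(n_trials))
      stop("'acc' of 0, 0.5 or 1 requires edge_correction = TRUE with n_trials")
    if (acc >= 1) acc <- 1 - 1 / (2 * n_trials)
    else if (acc <= 0) acc <- 1 / (2 * n_trials)
    else acc <- 0.5 + 1 / (2 * n_trials)
  }
  L <- stats::qlogis(acc)
  x <- L * (L * acc^2 - L * acc + acc - 0.5) / vrt
  v <- sign(acc - 0.5) * s * x^0.25
  a <- s^2 * L / v
  y <- exp(-v * a / s^2)
  mdt <- (a / (2 * v)) * (1 - y) / (1 + y)
  t_nd <- mrt - mdt
  if (t_nd < 0)
    warning("fitted non-decision time is negative; clamped to 0 on the ",
            "returned parameter object", call. = FALSE)
  out <- list(ddm = ddm_params(v = v, s = s, B = a / 2, y0 = 0, dt = dt,
                               t_nd = max(t_nd, 0)),
              a = a, mdt = mdt, t_nd = t_nd)
  if (!is.null(lambda)) {
    rs <- rescale_to_bound(out$ddm, lambda)
    out$scaled <- rs$params
    out$c <- rs$c
    out$bayes <- ddm_to_bayes_equal_means(rs$params)
  }
  class(out) <- "ez_fit"
  out
}

#' @export
print.ez_fit <- function(x, ...) {
  cat("EZ closed-form fit\n")
  cat(sprintf("  v = %.5g, a = %.5g (B = %.5g), t_nd = %.4g s\n",
              x$ddm$v, x$a, x$ddm$B, x$t_nd))
  if (!is.null(x$bayes))
    cat(sprintf("  rescaled to lambda = %.3g (c = %.4g): sigma = %.5g, sigma_hat = %.5g\n",
                x$bayes$lambda, x$c, x$bayes$sigma, x$bayes$sigma_hat))
  invisible(x)
}

#' Gaussian posterior density at a parameter point
#'
#' Models the retained MCMC samples with a multivariate Gaussian (sample mean
#' and covariance) and evaluates its density at a parameter triple — used to
#' judge how plausible an externally fitted parameter set is under the MCMC
#' posterior.
#'
#' @param samples a `posterior_samples` object with at least `d + 1`
#'   retained draws.
#' @param point numeric vector (`sigma`, `sigma_hat`, `t_nd`).
#' @return The Gaussian density value at `point`.
#' @export
posterior_density_at <- function(samples, point) {
  stopifnot(inherits(samples, "posterior_samples"))
  X <- samples$retained
  d <- ncol(X)
  if (nrow(X) < d + 1L) stop("need at least d + 1 retained samples")
  if (length(point) != d) stop("'point' must have one value per parameter")
  mu <- colMeans(X)
  S <- stats::cov(X)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    warning("singular sample covariance; falling back to its diagonal",
            call. = FALSE)
    R <- chol(diag(diag(S), d))
  }
  exp(.dmvnorm_log(as.numeric(point), mu, R))
}
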