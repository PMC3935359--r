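.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Draw one observation from the input process
#'
#' While alternative `i` is presented, the sensory stages are modeled as
#' delivering a noisy scalar feature `x_t = mu[i] + sqrt(dt) * sigma * eps`
#' with `eps ~ N(0, 1)`: the observation mean does not scale with `dt`, the
#' variance is `dt * sigma^2`.
#'
#' @param params a [bayes_params()] object.
#' @param true_alternative index of the presented alternative.
#' @param epsilon a standard-normal draw (supply to match noise across
#'   simulators); drawn internally when omitted.
#' @return The observation `x_t`.
#' @export
observation_sample <- function(params, true_alternative = 1L, epsilon = NULL) {
  stopifnot(inherits(params, "bayes_params"))
  if (true_alternative < 1L || true_alternative > params$M)
    stop("'true_alternative' out of range")
  if (is.null(epsilon)) epsilon <- stats::rnorm(1L)
  params$mu[true_alternative] + sqrt(params$dt) * params$sigma * epsilon
}

#' Log-likelihood of an observation under a generative model
#'
#' Log density of `x` under the observer's generative model for alternative
#' `i`: a Gaussian with mean `mu_hat[i]` and variance `dt * sigma_hat^2`.
#'
#' @param x observation value (vectorized).
#' @param alternative generative-model index.
#' @param params a [bayes_params()] object.
#' @return Log density value(s).
#' @export
log_likelihood <- function(x, alternative, params) {
  stopifnot(inherits(params, "bayes_params"))
  if (alternative < 1L || alternative > params$M)
    stop("'alternative' out of range")
  stats::dnorm(x, mean = params$mu_hat[alternative],
               sd = sqrt(params$dt) * params$sigma_hat, log = TRUE)
}

#' One recursive Bayesian posterior update
#'
#' Updates a posterior belief vector with one observation:
#' `post_i = p(x | A_i) prev_i / sum_j p(x | A_j) prev_j`. The computation is
#' carried out in log space with the log-sum-exp construction; the
#' unnormalized posterior and its normalization constant are internal to this
#' function.
#'
#' @param prev previous posterior (probability vector over alternatives).
#' @param x observation value.
#' @param params a [bayes_params()] object.
#' @return Updated probability vector.
#' @examples
#' bp <- bayes_params(mu = c(1, -1), mu_hat = c(1, -1), sigma = 1,
#'                    sigma_hat = 1, lambda = 0.7, dt = 1)
#' update_posterior(c(0.5, 0.5), 1, bp)  # ~ (0.8808, 0.1192)
#' @export
update_posterior <- function(prev, x, params) {
  stopifnot(inherits(params, "bayes_params"))
  if (length(prev) != params$M || any(prev < 0) || abs(sum(prev) - 1) > 1e-8)
    stop("'prev' must be a probability vector over the alternatives")
  logw <- log(prev) + vapply(seq_len(params$M),
                             function(i) log_likelihood(x, i, params),
                             numeric(1L))
  if (all(!is.finite(logw)))
    stop("all posterior weights vanished; observation incompatible with every model")
  logz <- logw - .logsumexp(logw)
  exp(logz)
}

#' Apply a decision policy to a single posterior belief
#'
#' Thresholds the decision variable selected by `policy`: the posterior
#' (`max_i z_i >= lambda`), the log posterior (`max_i log z_i >= log lambda`),
#' or, for two alternatives, the log posterior odds
#' (`|log(z_1 / z_2)| >= log(lambda / (1 - lambda))`). Crossings are
#' inclusive (`>=`).
#'
#' @param posterior probability vector over alternatives.
#' @param policy a [decision_policy()] object.
#' @return The chosen alternative index, or `NA` if no bound is reached.
#' @examples
#' decide(c(0.70, 0.30), decision_policy("posterior", 0.7))  # 1 (inclusive)
#' decide(c(0.69, 0.31), decision_policy("posterior", 0.7))  # NA
#' @export
decide <- function(posterior, policy) {
  stopifnot(inherits(policy, "decision_policy"))
  M <- length(posterior)
  if (policy$variant == "log_odds" && M != 2L)
    stop("the log-odds policy is defined for two alternatives only")
  switch(policy$variant,
         posterior = if (max(posterior) >= policy$bound)
           which.max(posterior) else NA_integer_,
         log_posterior = if (max(log(posterior)) >= policy$bound)
           which.max(posterior) else NA_integer_,
         log_odds = {
           q <- log(posterior[1L]) - log(posterior[2L])
           if (abs(q) >= policy$bound) (if (q > 0) 1L else 2L)
           else NA_integer_
         })
}

# First decision step of a recorded trajectory under a policy (vectorized
# over steps). Returns list(choice, n_steps); NA choice if no crossing.
.first_decision <- function(logpost, policy) {
  n <- nrow(logpost)
  mx <- apply(logpost, 1L, max)
  cond <- switch(policy$variant,
                 posterior = exp(mx) >= policy$bound,
                 log_posterior = mx >= policy$bound,
                 log_odds = abs(logpost[, 1L] - logpost[, 2L]) >= policy$bound)
  k <- which(cond)
  if (length(k) == 0L) return(list(choice = NA_integer_, n_steps = NA_integer_))
  k <- k[1L]
  choice <- if (policy$variant == "log_odds") {
    if (logpost[k, 1L] > logpost[k, 2L]) 1L else 2L
  } else {
    which.max(logpost[k, ])
  }
  list(choice = choice, n_steps = as.integer(k))
}

#' Decision implied by a recorded trajectory under a policy
#'
#' Scans a [simulate_bayes_trial()] trajectory and returns the first step at
#' which the given policy triggers. Because the three policy variants carry
#' exactly transformed bounds, they agree in choice and decision step on
#' every trajectory.
#'
#' @param trajectory a `bayes_trajectory` object.
#' @param policy a [decision_policy()] object.
#' @return List with `choice` (`NA` if no crossing) and `n_steps`.
#' @export
apply_policy <- function(trajectory, policy) {
  stopifnot(inherits(trajectory, "bayes_trajectory"))
  .first_decision(trajectory$log_posterior, policy)
}

#' Simulate a single trial of the Bayesian observer
#'
#' Draws observations from the input process, updates the posterior belief
#' recursively in log space, and applies the decision policy after every
#' update (inclusive bound). Deadline handling matches
#' [simulate_ddm_trial()]: at most `steps_to_deadline(dt, deadline)` updates
#' are run, an undecided trial is an outlier, and a decided trial with
#' `rt > deadline` is flagged as well.
#'
#' @param params a [bayes_params()] object.
#' @param policy a [decision_policy()]; defaults to the posterior policy at
#'   `params$lambda`.
#' @param true_alternative index of the presented alternative.
#' @param noise optional vector of standard-normal draws (one per step) for
#'   matched-noise comparisons; must cover all steps to the deadline.
#' @param seed optional integer seed used when `noise` is not supplied.
#' @param deadline response deadline in seconds (total RT).
#' @param record if `TRUE`, attach the full `bayes_trajectory` to the outcome.
#' @param stop_at_bound if `FALSE`, accumulation continues to the deadline
#'   regardless of the bound (useful to inspect asymptotic trajectories or to
#'   apply several policies post hoc via [apply_policy()]); the returned
#'   outcome is then determined post hoc with the supplied policy.
#'
#' @return A `trial_outcome`; with `record = TRUE` it carries a `trajectory`
#'   element with fields `times`, `epsilons`, `observations`, `posterior`
#'   (steps x alternatives), `log_posterior`, `log_odds` (two alternatives;
#'   `q_t = log z_1 - log z_2`), `ddm_state` (identical to `log_odds`: the
#'   equivalent diffusion state), and `start_posterior` (the prior, the value
#'   at time 0).
#' @examples
#' bp <- bayes_params(mu = c(1, -1), mu_hat = c(1, -1), sigma = 2,
#'                    sigma_hat = 2, lambda = 0.7, dt = 0.1)
#' simulate_bayes_trial(bp, true_alternative = 1, seed = 1, deadline = 30)
#' @export
simulate_bayes_trial <- function(params, policy = NULL, true_alternative = 1L,
                                 noise = NULL, seed = NULL, deadline,
                                 record = FALSE, stop_at_bound = TRUE) {
  stopifnot(inherits(params, "bayes_params"))
  if (is.null(policy)) policy <- decision_policy("posterior", params$lambda)
  if (policy$variant == "log_odds" && params$M != 2L)
    stop("the log-odds policy is defined for two alternatives only")
  if (deadline <= params$t_nd)
    stop("'deadline' must exceed the non-decision time")
  n_max <- steps_to_deadline(params$dt, deadline)
  if (is.null(noise)) {
    if (!is.null(seed)) set.seed(seed)
    noise <- stats::rnorm(n_max)
  } else {
    if (length(noise) == 0L) stop("'noise' must not be empty")
    if (length(noise) < n_max)
      stop(sprintf("'noise' has %d draws but %d steps are needed to reach the deadline",
                   length(noise), n_max))
    noise <- noise[seq_len(n_max)]
  }
  M <- params$M
  sd_obs <- sqrt(params$dt) * params$sigma_hat
  x_all <- params$mu[true_alternative] + sqrt(params$dt) * params$sigma * noise
  logz <- log(params$prior)
  logpost <- matrix(NA_real_, n_max, M)
  n_run <- 0L
  choice <- NA_integer_
  n_steps <- NA_integer_
  for (t in seq_len(n_max)) {
    loglik <- stats::dnorm(x_all[t], mean = params$mu_hat, sd = sd_obs,
                           log = TRUE)
    logz <- logz + loglik
    logz <- logz - .logsumexp(logz)
    logpost[t, ] <- logz
    n_run <- t
    if (stop_at_bound) {
      hit <- switch(policy$variant,
                    posterior = exp(max(logz)) >= policy$bound,
                    log_posterior = max(logz) >= policy$bound,
                    log_odds = abs(logz[1L] - logz[2L]) >= policy$bound)
      if (hit) {
        choice <- if (policy$variant == "log_odds") {
          if (logz[1L] > logz[2L]) 1L else 2L
        } else which.max(logz)
        n_steps <- t
        break
      }
    }
  }
  if (!stop_at_bound) {
    d <- .first_decision(logpost[seq_len(n_run), , drop = FALSE], policy)
    choice <- d$choice
    n_steps <- d$n_steps
  }
  out <- .trial_outcome(choice, n_steps, params$dt, params$t_nd,
                        true_alternative, deadline)
  if (record) {
    lp <- logpost[seq_len(n_run), , drop = FALSE]
    q <- if (M == 2L) lp[, 1L] - lp[, 2L] else NULL
    out$trajectory <- structure(
      list(times = params$dt * seq_len(n_run),
           epsilons = noise[seq_len(n_run)],
           observations = x_all[seq_len(n_run)],
           posterior = exp(lp),
           log_posterior = lp,
           log_odds = q,
           ddm_state = q,
           start_posterior = params$prior,
           true_alternative = true_alternative,
           dt = params$dt),
      class = "bayes_trajectory")
  }
  out
}

# Per-trial series of one decision variable, including the time-0 value
# implied by the prior. alternative is ignored for log_odds.
.traj_series <- function(traj, variable, alternative) {
  switch(variable,
         posterior = c(traj$start_posterior[alternative],
                       traj$posterior[, alternative]),
         log_posterior = c(log(traj$start_posterior[alternative]),
                           traj$log_posterior[, alternative]),
         log_odds = {
           if (is.null(traj$log_odds))
             stop("log-odds series requires two alternatives")
           q0 <- log(traj$start_posterior[1L]) - log(traj$start_posterior[2L])
           c(q0, traj$log_odds)
         })
}

.policy_scale <- function(variable, policy, prior, alternative) {
  start <- switch(variable,
                  posterior = prior[alternative],
                  log_posterior = log(prior[alternative]),
                  log_odds = log(prior[1L]) - log(prior[2L]))
  bound <- switch(variable,
                  posterior = policy$lambda,
                  log_posterior = log(policy$lambda),
                  log_odds = log(policy$lambda / (1 - policy$lambda)))
  c(start = start, bound = bound)
}

#' Average decision-variable trajectories across trials
#'
#' Computes, per time point, the mean and standard error of a decision
#' variable over the trials still contributing data, in the style of
#' trajectory-averaging analyses of neural accumulation signals. With
#' `stop_at_bound = TRUE` a trial contributes only the points strictly before
#' its bound crossing (determined by `policy`), so that contributor counts
#' shrink over time; the curve is truncated at the last time point with at
#' least `min_trials` contributors. With `rescale = TRUE` the variable is
#' mapped affinely so that its starting value (from the prior) becomes 0 and
#' its bound value becomes 1, removing the unknown scaling a neural correlate
#' of the variable would carry.
#'
#' @param trajectories list of `bayes_trajectory` objects (same `dt`).
#' @param variable `"posterior"`, `"log_posterior"` or `"log_odds"`.
#' @param alternative which alternative's belief to average (ignored for
#'   `"log_odds"`).
#' @param stop_at_bound drop data points at and after the bound crossing.
#' @param policy a [decision_policy()]; required when `stop_at_bound` or
#'   `rescale` is used.
#' @param min_trials minimum number of contributing trials per time point
#'   (default 12); the curve stops when fewer trials contribute.
#' @param rescale apply the start-to-0, bound-to-1 affine map.
#' @return Data frame with `time`, `mean`, `se` (standard error of the mean)
#'   and `n` (contributing trials), starting at time 0.
#' @export
average_trajectories <- function(trajectories,
                                 variable = c("posterior", "log_posterior",
                                              "log_odds"),
                                 alternative = 1L, stop_at_bound = FALSE,
                                 policy = NULL, min_trials = 12L,
                                 rescale = FALSE) {
  variable <- match.arg(variable)
  if (length(trajectories) == 0L) stop("no trajectories supplied")
  if ((stop_at_bound || rescale) && is.null(policy))
    stop("'policy' is required for stop_at_bound or rescale")
  series <- lapply(trajectories, function(tr) {
    s <- .traj_series(tr, variable, alternative)
    if (stop_at_bound) {
      d <- .first_decision(tr$log_posterior, policy)
      if (!is.na(d$n_steps)) s <- s[seq_len(d$n_steps)]  # keeps pre-crossing
    }
    s
  })
  if (rescale) {
    series <- lapply(seq_along(series), function(j) {
      sc <- .policy_scale(variable, policy,
                          trajectories[[j]]$start_posterior, alternative)
      (series[[j]] - sc["start"]) / (sc["bound"] - sc["start"])
    })
  }
  len <- vapply(series, length, integer(1L))
  n_t <- max(len)
  mat <- matrix(NA_real_, n_t, length(series))
  for (j in seq_along(series)) mat[seq_len(len[j]), j] <- series[[j]]
  n_contrib <- rowSums(!is.na(mat))
  keep <- n_contrib >= min_trials
  last <- if (any(keep)) max(which(keep)) else 0L
  if (last == 0L)
    return(data.frame(time = numeric(0), mean = numeric(0),
                      se = numeric(0), n = integer(0)))
  mat <- mat[seq_len(last), , drop = FALSE]
  dt <- trajectories[[1L]]$dt
  mean_v <- rowMeans(mat, na.rm = TRUE)
  sd_v <- apply(mat, 1L, stats::sd, na.rm = TRUE)
  n_v <- rowSums(!is.na(mat))
  data.frame(time = dt * (seq_len(last) - 1L),
             mean = mean_v,
             se = sd_v / sqrt(n_v),
             n = as.integer(n_v))
}

#' Export trajectories to a tidy table
#'
#' Flattens recorded trajectories into one row per (trial, step, variable,
#' alternative) for plotting or CSV export.
#'
#' @param trajectories list of `bayes_trajectory` objects.
#' @return Data frame with columns `trial`, `step`, `time`, `variable`,
#'   `alternative`, `value`.
#' @export
trajectories_to_df <- function(trajectories) {
  rows <- lapply(seq_along(trajectories), function(j) {
    tr <- trajectories[[j]]
    n <- length(tr$times)
    M <- ncol(tr$posterior)
    parts <- lapply(seq_len(M), function(i) {
      rbind(data.frame(trial = j, step = seq_len(n), time = tr$times,
                       variable = "posterior", alternative = i,
                       value = tr$posterior[, i]),
            data.frame(trial = j, step = seq_len(n), time = tr$times,
                       variable = "log_posterior", alternative = i,
                       value = tr$log_posterior[, i]))
    })
    out <- do.call(rbind, parts)
    if (!is.null(tr$log_odds))
      out <- rbind(out,
                   data.frame(trial = j, step = seq_len(n), time = tr$times,
                              variable = "log_odds", alternative = NA_integer_,
                              value = tr$log_odds))
    out
  })
  do.call(rbind, rows)
}

#' Simulate a whole experiment of Bayesian-observer trials (two alternatives)
#'
#' Vectorized simulation of many independent trials of the two-alternative
#' observer, carried out on its log-posterior-odds decision variable: by the
#' exact accumulation identity, each update adds
#' `v_hat + s_hat * x_t` to the log odds `q_t`, where
#' `v_hat = (mu_hat[2]^2 - mu_hat[1]^2) / (2 dt sigma_hat^2)` and
#' `s_hat = (mu_hat[1] - mu_hat[2]) / (dt sigma_hat^2)`, and a decision is
#' made when `|q_t| >= log(lambda / (1 - lambda))`. This is the same
#' inference as [simulate_bayes_trial()] (all three policies decide at the
#' same step), computed without materializing per-trial posteriors.
#'
#' @param params a [bayes_params()] object with two alternatives.
#' @param n_trials number of trials.
#' @param true_alternatives per-trial presented alternative, recycled;
#'   defaults to a balanced alternating schedule.
#' @param deadline response deadline in seconds (total RT).
#' @param seed optional integer seed.
#' @return Data frame as in [simulate_ddm_experiment()].
#' @export
simulate_bayes_experiment <- function(params, n_trials,
                                      true_alternatives = NULL,
                                      deadline, seed = NULL) {
  stopifnot(inherits(params, "bayes_params"))
  if (params$M != 2L)
    stop("vectorized experiment simulation supports two alternatives")
  if (deadline <= params$t_nd)
    stop("'deadline' must exceed the non-decision time")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(true_alternatives))
    true_alternatives <- rep_len(c(1L, 2L), n_trials)
  alt <- rep_len(as.integer(true_alternatives), n_trials)
  if (!all(alt %in% c(1L, 2L))) stop("'true_alternatives' must be 1 or 2")
  dt <- params$dt
  s_hat <- (params$mu_hat[1L] - params$mu_hat[2L]) / (dt * params$sigma_hat^2)
  v_hat <- (params$mu_hat[2L]^2 - params$mu_hat[1L]^2) /
    (2 * dt * params$sigma_hat^2)
  # per-step log-odds increment: v_hat + s_hat * (mu_i + sqrt(dt) sigma eps)
  # = v_i * dt + sqrt(dt) * s * eps with the translated drift/diffusion
  v_trial <- (v_hat + s_hat * params$mu[alt]) / dt
  # eps is symmetric, so |s_hat| gives the same law as a signed s_hat
  s_eq <- abs(s_hat) * params$sigma
  q_bound <- log(params$lambda / (1 - params$lambda))
  y0 <- log(params$prior[1L]) - log(params$prior[2L])
  n_max <- steps_to_deadline(dt, deadline)
  fp <- .ddm_first_passage(v_trial, s_eq, q_bound, y0, dt, n_max, n_trials)
  choice <- ifelse(is.na(fp$sign), NA_integer_, ifelse(fp$sign > 0, 1L, 2L))
  decision_time <- fp$n_steps * dt
  rt <- decision_time + params$t_nd
  data.frame(true_alternative = alt,
             choice = choice,
             n_steps = fp$n_steps,
             decision_time = decision_time,
             rt = rt,
             correct = ifelse(is.na(choice), NA, choice == alt),
             outlier = is.na(choice) | rt > deadline)
}
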