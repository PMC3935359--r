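#' Parameters of the Bayesian observer
#'
#' Bundles the description of a Bayesian sequential-inference observer for an
#' M-alternative forced-choice task: the input process draws a noisy feature
#' value `x_t ~ N(mu[i], dt * sigma^2)` while stimulus `i` is presented, the
#' observer scores each alternative with its internal generative density
#' `N(mu_hat[i], dt * sigma_hat^2)`, and posterior beliefs are updated
#' recursively from independent observations. A decision is triggered when the
#' largest posterior belief reaches the bound `lambda` (or an equivalent
#' transformed bound, see [decision_policy()]).
#'
#' Note that the mean of an observation does not scale with `dt` while its
#' variance is `dt * sigma^2`; halving the time step therefore halves the
#' observation variance but leaves the mean untouched.
#'
#' @param mu numeric vector of true feature means, one per alternative.
#' @param mu_hat numeric vector of generative-model means, one per
#'   alternative. The generative variance is shared across alternatives
#'   (`sigma_hat` is a scalar); alternative-specific generative variances
#'   break the drift-diffusion equivalence and are not supported.
#' @param sigma input (stimulus plus sensory) noise standard deviation,
#'   `>= 0`, in feature units per sqrt(second).
#' @param sigma_hat internal uncertainty: the observer's assumed observation
#'   standard deviation, `> 0`. Acts as a gain on the evidence, not as an
#'   extra noise source.
#' @param lambda bound on the posterior belief, strictly between `1/M` and 1.
#'   Values `<= 1/M` would trigger a decision before any evidence arrives and
#'   are rejected.
#' @param prior prior probability vector over the alternatives; defaults to
#'   uniform. Must sum to 1 (tolerance 1e-12).
#' @param dt time step in seconds, `> 0`.
#' @param t_nd non-decision time in seconds, `>= 0`: latency added to the
#'   decision time to account for transduction and motor preparation.
#'
#' @return An object of class `bayes_params`.
#' @seealso [ddm_params()], [bayes_to_ddm()], [simulate_bayes_trial()]
#' @examples
#' bp <- bayes_params(mu = c(1, -1), mu_hat = c(1, -1),
#'                    sigma = 2, sigma_hat = 2, lambda = 0.7, dt = 1)
#' bp
#' @export
bayes_params <- function(mu, mu_hat, sigma, sigma_hat, lambda = 0.7,
                         prior = NULL, dt, t_nd = 0) {
  mu <- as.numeric(mu)
  mu_hat <- as.numeric(mu_hat)
  M <- length(mu)
  if (M < 2L) stop("at least two alternatives are required")
  if (length(mu_hat) != M)
    stop("'mu' and 'mu_hat' must have the same length (one mean per alternative)")
  if (length(sigma_hat) != 1L)
    stop("'sigma_hat' must be a single value: alternative-specific generative ",
         "variances break the exact drift-diffusion equivalence and are not supported")
  if (is.null(prior)) prior <- rep(1 / M, M)
  prior <- as.numeric(prior)
  if (length(prior) != M) stop("'prior' must have one entry per alternative")
  vals <- c(mu, mu_hat, sigma, sigma_hat, lambda, prior, dt, t_nd)
  if (!all(is.finite(vals))) stop("all parameters must be finite")
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (sigma_hat <= 0) stop("'sigma_hat' must be > 0")
  if (any(prior < 0) || abs(sum(prior) - 1) > 1e-12)
    stop("'prior' must be a probability vector summing to 1 (tolerance 1e-12)")
  if (lambda <= 1 / M || lambda >= 1)
    stop(sprintf(paste0("'lambda' must lie strictly between 1/M = %.4g and 1; ",
                        "a bound <= 1/M would be crossed at t = 0, before any ",
                        "observation is made"), 1 / M))
  if (dt <= 0) stop("'dt' must be > 0")
  if (t_nd < 0) stop("'t_nd' must be >= 0")
  structure(list(mu = mu, mu_hat = mu_hat, sigma = unname(sigma),
                 sigma_hat = unname(sigma_hat), lambda = unname(lambda),
                 prior = prior / sum(prior), dt = unname(dt),
                 t_nd = unname(t_nd), M = M),
            class = "bayes_params")
}

#' @export
print.bayes_params <- function(x, ...) {
  cat("Bayesian observer parameters (", x$M, " alternatives)\n", sep = "")
  cat("  feature means      mu     =", paste(signif(x$mu, 5), collapse = ", "), "\n")
  cat("  generative means   mu_hat =", paste(signif(x$mu_hat, 5), collapse = ", "), "\n")
  cat("  input noise        sigma     =", signif(x$sigma, 5), "\n")
  cat("  internal uncert.   sigma_hat =", signif(x$sigma_hat, 5), "\n")
  cat("  posterior bound    lambda    =", signif(x$lambda, 5), "\n")
  cat("  prior              =", paste(signif(x$prior, 5), collapse = ", "), "\n")
  cat("  dt =", x$dt, "s,  t_nd =", x$t_nd, "s\n")
  invisible(x)
}

#' Parameters of the pure drift-diffusion model
#'
#' The pure drift-diffusion model (pDDM) accumulates evidence
#' `y_t = y_{t-dt} + v*dt + sqrt(dt)*s*eps_t` from the starting state `y0`
#' between absorbing bounds at `+B` and `-B`; the first bound crossed selects
#' the alternative (upper bound = alternative 1 by convention).
#'
#' The drift `v` is stored signed, relative to the fixed convention that
#' alternative 1 maps to positive drift and the upper bound. Simulators for
#' whole experiments flip the drift sign on trials where alternative 2 is
#' presented (the usual symmetric-drift assumption); [simulate_ddm_trial()]
#' itself uses `v` exactly as given, so that stimulus-specific parameter sets
#' produced by [bayes_to_ddm()] keep their signed drift.
#'
#' @param v drift, in evidence units per second (may be negative; see Details).
#' @param s diffusion scale, evidence units per sqrt(second), `>= 0`.
#' @param B bound, evidence units, `> 0` (bounds are symmetric at `+B`, `-B`).
#' @param y0 starting state (bias), `|y0| < B`. Equals the log prior odds of
#'   the equivalent Bayesian observer, see [prior_to_bias()].
#' @param dt time step in seconds, `> 0`.
#' @param t_nd non-decision time in seconds, `>= 0`.
#'
#' @return An object of class `ddm_params`.
#' @seealso [bayes_params()], [simulate_ddm_trial()], [ddm_to_bayes_equal_means()]
#' @examples
#' dp <- ddm_params(v = 0.5, s = 1, B = log(7 / 3), dt = 1)
#' dp
#' @export
ddm_params <- function(v, s, B, y0 = 0, dt, t_nd = 0) {
  vals <- c(v, s, B, y0, dt, t_nd)
  if (length(vals) != 6L || !all(is.finite(vals)))
    stop("all parameters must be finite scalars")
  if (s < 0) stop("'s' must be >= 0")
  if (B <= 0) stop("'B' must be > 0")
  if (abs(y0) >= B) stop("the starting state must satisfy |y0| < B")
  if (dt <= 0) stop("'dt' must be > 0")
  if (t_nd < 0) stop("'t_nd' must be >= 0")
  structure(list(v = unname(v), s = unname(s), B = unname(B),
                 y0 = unname(y0), dt = unname(dt), t_nd = unname(t_nd)),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Pure drift-diffusion parameters\n")
  cat("  drift     v  =", signif(x$v, 6), "\n")
  cat("  diffusion s  =", signif(x$s, 6), "\n")
  cat("  bound     B  =", signif(x$B, 6), "\n")
  cat("  bias      y0 =", signif(x$y0, 6), "\n")
  cat("  dt =", x$dt, "s,  t_nd =", x$t_nd, "s\n")
  invisible(x)
}

#' Decision policies on the posterior belief
#'
#' The observer can threshold three different decision variables: the
#' posterior belief itself (bound `lambda`), the log posterior (bound
#' `log(lambda)`), or, for two alternatives, the log posterior odds (bound
#' `log(lambda / (1 - lambda))`). With the bounds linked by these transforms
#' the three policies produce identical choices and identical decision steps
#' on every trial; they differ only in the quantity that would have to be
#' represented neurally.
#'
#' @param variant one of `"posterior"`, `"log_posterior"`, `"log_odds"`.
#' @param lambda the bound on the posterior belief scale, in `(1/M, 1)`; it is
#'   transformed internally to the scale of the chosen decision variable.
#'
#' @return An object of class `decision_policy` with elements `variant`,
#'   `lambda` and `bound` (the bound on the variant's own scale).
#' @seealso [decide()], [simulate_bayes_trial()]
#' @examples
#' decision_policy("log_odds", 0.7)$bound  # log(0.7/0.3)
#' @export
decision_policy <- function(variant = c("posterior", "log_posterior", "log_odds"),
                            lambda) {
  variant <- match.arg(variant)
  if (!is.finite(lambda) || lambda <= 0 || lambda >= 1)
    stop("'lambda' must lie in (0, 1)")
  bound <- switch(variant,
                  posterior = lambda,
                  log_posterior = log(lambda),
                  log_odds = log(lambda / (1 - lambda)))
  structure(list(variant = variant, lambda = lambda, bound = bound),
            class = "decision_policy")
}

#' @export
print.decision_policy <- function(x, ...) {
  cat("Decision policy: ", x$variant, " (lambda = ", signif(x$lambda, 5),
      ", bound = ", signif(x$bound, 6), ")\n", sep = "")
  invisible(x)
}
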