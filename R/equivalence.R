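#' Translate Bayesian-observer parameters to the equivalent pDDM
#'
#' For a two-alternative observer with equal generative variances the
#' log-posterior-odds update is exactly a discretized drift-diffusion step,
#' which fixes the pDDM parameters:
#' \deqn{v = \frac{\hat\mu_2^2 - \hat\mu_1^2}{2\,\Delta t^2\,\hat\sigma^2}
#'        + \mu_i \frac{\hat\mu_1 - \hat\mu_2}{\Delta t^2\,\hat\sigma^2},\quad
#'       s = \sigma \frac{\hat\mu_1 - \hat\mu_2}{\Delta t\,\hat\sigma^2},\quad
#'       B = \log\frac{\lambda}{1-\lambda},\quad
#'       y_0 = \log\frac{p(A_1)}{p(A_2)}.}
#' The drift depends on the presented stimulus through its feature mean
#' `mu[i]`, so the translation is stimulus-specific: the returned `v` is the
#' signed drift on trials where alternative `true_alternative` is shown
#' (positive values drive the state toward the upper bound = alternative 1).
#' Feeding the same standard-normal sequence to [simulate_bayes_trial()] and
#' to [simulate_ddm_trial()] with the translated parameters yields identical
#' trajectories, choices and decision steps.
#'
#' @param params a [bayes_params()] object with two alternatives and
#'   `mu_hat[1] > mu_hat[2]` (the alternative-1-positive sign convention).
#' @param true_alternative the presented stimulus the drift refers to.
#' @return A [ddm_params()] object (class additionally records the applied
#'   convention in attribute `"fixed_values"`).
#' @examples
#' bp <- bayes_params(mu = c(1, -1), mu_hat = c(1, -1), sigma = 2,
#'                    sigma_hat = 2, lambda = 0.7, dt = 1)
#' bayes_to_ddm(bp)  # v = 0.5, s = 1, B = log(7/3)
#' @export
bayes_to_ddm <- function(params, true_alternative = 1L) {
  stopifnot(inherits(params, "bayes_params"))
  if (params$M != 2L)
    stop("the pDDM translation is defined for two alternatives")
  dmu <- params$mu_hat[1L] - params$mu_hat[2L]
  if (dmu == 0)
    stop("'mu_hat' means coincide: the generative models are degenerate and ",
         "no drift-diffusion equivalent exists")
  if (dmu < 0)
    stop("sign convention violated: alternative 1 must carry the larger ",
         "generative mean (mu_hat[1] > mu_hat[2]) so that it maps to ",
         "positive drift and the upper bound")
  dt <- params$dt
  sh2 <- params$sigma_hat^2
  v <- (params$mu_hat[2L]^2 - params$mu_hat[1L]^2) / (2 * dt^2 * sh2) +
    params$mu[true_alternative] * dmu / (dt^2 * sh2)
  s <- params$sigma * dmu / (dt * sh2)
  B <- log(params$lambda / (1 - params$lambda))
  y0 <- log(params$prior[1L]) - log(params$prior[2L])
  out <- ddm_params(v = v, s = s, B = B, y0 = y0, dt = dt, t_nd = params$t_nd)
  attr(out, "fixed_values") <- list(true_alternative = true_alternative,
                                    lambda = params$lambda)
  out
}

#' Translate pDDM parameters to the observer, equal-means constraint
#'
#' Resolves the observer's over-parameterization by assuming the observer has
#' internalized the stimulus feature means perfectly (`mu_hat = mu`), centers
#' the means at `+-mu` and fixes the amplitude (default `mu = 1`). The
#' remaining observer parameters follow uniquely from the pDDM:
#' \deqn{\hat\sigma^2 = \frac{2\mu^2}{\Delta t^2 |v|},\quad
#'       \sigma = \frac{\mu\,s}{\Delta t\,|v|},\quad
#'       \lambda = \frac{e^B}{1+e^B},}
#' and the bias maps to the prior via [bias_to_prior()]. Under this
#' constraint set, behavior is explained by the interplay of input noise and
#' internal uncertainty at fixed feature values. Only the magnitude of `v`
#' enters (its sign encodes which stimulus was presented).
#'
#' @param params a [ddm_params()] object with `v != 0`, `s > 0`.
#' @param mu fixed feature-mean amplitude (default 1).
#' @return A [bayes_params()] object; attribute `"fixed_values"` records the
#'   constraint set and the fixed amplitude.
#' @examples
#' dp <- ddm_params(v = 0.5, s = 1, B = log(7 / 3), dt = 1)
#' ddm_to_bayes_equal_means(dp)  # sigma = 2, sigma_hat = 2, lambda = 0.7
#' @export
ddm_to_bayes_equal_means <- function(params, mu = 1) {
  stopifnot(inherits(params, "ddm_params"))
  if (params$v == 0)
    stop("'v' must be nonzero: the internal uncertainty is undefined at v = 0")
  if (params$s <= 0) stop("'s' must be > 0")
  if (mu <= 0) stop("'mu' must be > 0")
  dt <- params$dt
  av <- abs(params$v)
  sigma_hat <- sqrt(2 * mu^2 / (dt^2 * av))
  sigma <- mu * params$s / (dt * av)
  lambda <- stats::plogis(params$B)
  prior1 <- stats::plogis(params$y0)
  out <- bayes_params(mu = c(mu, -mu), mu_hat = c(mu, -mu), sigma = sigma,
                      sigma_hat = sigma_hat, lambda = lambda,
                      prior = c(prior1, 1 - prior1), dt = dt,
                      t_nd = params$t_nd)
  attr(out, "fixed_values") <- list(constraint_set = "equal_means", mu = mu)
  out
}

#' Translate pDDM parameters to the observer, symmetric-means constraint
#'
#' Resolves the observer's over-parameterization by centering both the input
#' process and generative means symmetrically at `+-mu` and `+-mu_hat` and
#' fixing the two uncertainties to a common value `sigma = sigma_hat = a`.
#' Then
#' \deqn{\mu = \frac{v\,\Delta t\,\sigma}{s},\qquad
#'       \hat\mu = \frac{s\,\Delta t\,\hat\sigma^2}{2\sigma},}
#' which enforces the signal-to-noise identity `v * dt / s = mu / sigma`
#' between the pDDM and the input process. Under this constraint set,
#' behavior is explained by the feature amplitudes assumed in the input
#' process and the generative models.
#'
#' @param params a [ddm_params()] object with `s > 0`.
#' @param a common uncertainty value for `sigma` and `sigma_hat` (default 1).
#' @return A [bayes_params()] object; attribute `"fixed_values"` records the
#'   constraint set and `a`.
#' @examples
#' dp <- ddm_params(v = 1, s = 1, B = 0.8, dt = 1)
#' ddm_to_bayes_symmetric_means(dp)  # mu = 1, mu_hat = 0.5
#' @export
ddm_to_bayes_symmetric_means <- function(params, a = 1) {
  stopifnot(inherits(params, "ddm_params"))
  if (params$s <= 0) stop("'s' must be > 0")
  if (a <= 0) stop("'a' must be > 0")
  dt <- params$dt
  mu <- params$v * dt * a / params$s
  mu_hat <- params$s * dt * a / 2
  lambda <- stats::plogis(params$B)
  prior1 <- stats::plogis(params$y0)
  out <- bayes_params(mu = c(mu, -mu), mu_hat = c(mu_hat, -mu_hat),
                      sigma = a, sigma_hat = a, lambda = lambda,
                      prior = c(prior1, 1 - prior1), dt = dt,
                      t_nd = params$t_nd)
  attr(out, "fixed_values") <- list(constraint_set = "symmetric_means", a = a)
  out
}

#' Rescale a parameter set to a different posterior bound
#'
#' Accuracy and reaction times determine the pDDM only up to a common scaling
#' of `(v, s, B)` (and `y0`); on the Bayesian side the same freedom lives in
#' the pair (internal uncertainty, posterior bound) while the input noise
#' `sigma` is untouched (it is a ratio of diffusion to drift). This function
#' applies the scaling constant
#' `c = log(new_lambda / (1 - new_lambda)) / B` that moves a fit made at one
#' posterior bound to the equivalent parameterization at `new_lambda`. For a
#' [bayes_params()] input under the equal-means constraints this leaves
#' `sigma` invariant and scales the internal uncertainty to
#' `sigma_hat / sqrt(c)`. All simulated decisions and decision times are
#' unchanged (bit-identical under matched noise).
#'
#' @param params a [ddm_params()] or equal-means [bayes_params()] object.
#' @param new_lambda target posterior bound in (0.5, 1).
#' @param mu fixed feature amplitude used when re-translating a
#'   [bayes_params()] input (default 1).
#' @return List with `params` (same class as the input) and the scaling
#'   constant `c`.
#' @examples
#' bp <- bayes_params(mu = c(1, -1), mu_hat = c(1, -1), sigma = 18.1,
#'                    sigma_hat = 28.6, lambda = 0.7, dt = 0.0283)
#' rescale_to_bound(bp, 0.99)$params$sigma_hat  # ~ 12.3
#' @export
rescale_to_bound <- function(params, new_lambda, mu = 1) {
  if (!is.finite(new_lambda) || new_lambda <= 0.5 || new_lambda >= 1)
    stop("'new_lambda' must lie in (0.5, 1)")
  new_B <- log(new_lambda / (1 - new_lambda))
  if (inherits(params, "ddm_params")) {
    c_scale <- new_B / params$B
    out <- ddm_params(v = c_scale * params$v, s = c_scale * params$s,
                      B = c_scale * params$B, y0 = c_scale * params$y0,
                      dt = params$dt, t_nd = params$t_nd)
    return(list(params = out, c = c_scale))
  }
  if (inherits(params, "bayes_params")) {
    dp <- bayes_to_ddm(params)
    c_scale <- new_B / dp$B
    dp2 <- ddm_params(v = c_scale * dp$v, s = c_scale * dp$s,
                      B = c_scale * dp$B, y0 = c_scale * dp$y0,
                      dt = dp$dt, t_nd = dp$t_nd)
    out <- ddm_to_bayes_equal_means(dp2, mu = mu)
    return(list(params = out, c = c_scale))
  }
  stop("'params' must be a ddm_params or bayes_params object")
}

#' Map a prior probability to the equivalent diffusion bias, and back
#'
#' A non-uniform prior `p0 = p(A_1)` of the observer corresponds exactly to a
#' shifted starting state of the equivalent diffusion:
#' `y0 = log(p0 / (1 - p0))`, with inverse `p0 = exp(y0) / (1 + exp(y0))`.
#'
#' @param p0 prior probability of alternative 1, strictly in (0, 1).
#' @return `prior_to_bias()`: the bias `y0`; `bias_to_prior()`: the prior.
#' @examples
#' prior_to_bias(0.5)        # 0
#' bias_to_prior(1)          # e / (1 + e) ~ 0.7311
#' @export
prior_to_bias <- function(p0) {
  if (any(!is.finite(p0)) || any(p0 <= 0) || any(p0 >= 1))
    stop("'p0' must lie strictly in (0, 1)")
  log(p0 / (1 - p0))
}

#' @rdname prior_to_bias
#' @param y0 diffusion starting state (log prior odds).
#' @export
bias_to_prior <- function(y0) {
  if (any(!is.finite(y0))) stop("'y0' must be finite")
  stats::plogis(y0)
}
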