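#' Number of accumulation steps until a deadline
#'
#' Smallest integer `n` such that `n * dt >= deadline`. With `dt = 0.0283` s
#' and the 1.25 s response deadline this gives the 45 accumulation steps used
#' throughout the package defaults.
#'
#' @param dt time step in seconds, `> 0`.
#' @param deadline deadline in seconds, `> 0`.
#' @return Integer step count.
#' @examples
#' steps_to_deadline(0.0283, 1.25)  # 45
#' @export
steps_to_deadline <- function(dt, deadline) {
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0")
  if (!is.finite(deadline) || deadline <= 0) stop("'deadline' must be > 0")
  # small slack so that exact multiples are not pushed up by rounding noise
  as.integer(ceiling(deadline / dt - 1e-9))
}

.trial_outcome <- function(choice, n_steps, dt, t_nd, true_alternative, deadline,
                           path = NULL) {
  undecided <- is.na(choice)
  decision_time <- if (undecided) NA_real_ else n_steps * dt
  rt <- if (undecided) NA_real_ else decision_time + t_nd
  out <- list(choice = choice,
              n_steps = if (undecided) NA_integer_ else as.integer(n_steps),
              decision_time = decision_time,
              rt = rt,
              correct = if (undecided) NA else choice == true_alternative,
              outlier = undecided || rt > deadline)
  if (!is.null(path)) out$path <- path
  class(out) <- "trial_outcome"
  out
}

#' @export
print.trial_outcome <- function(x, ...) {
  if (is.na(x$choice)) {
    cat("Trial outcome: undecided at deadline (outlier)\n")
  } else {
    cat(sprintf("Trial outcome: chose alternative %d after %d steps (DT = %.4g s, RT = %.4g s)%s\n",
                x$choice, x$n_steps, x$decision_time, x$rt,
                if (isTRUE(x$outlier)) " [outlier]" else ""))
  }
  invisible(x)
}

#' Simulate a single pDDM trial
#'
#' Iterates the discretized pure drift-diffusion process
#' `y_t = y_{t-dt} + v*dt + sqrt(dt)*s*eps_t` from `y0` and declares a
#' decision at the first step with `|y_t| >= B` (inclusive crossing, no
#' within-step interpolation); the sign of `y_t` selects the alternative
#' (positive = alternative 1). If no bound is crossed within
#' `steps_to_deadline(dt, deadline)` updates the trial is undecided and
#' flagged as an outlier. The deadline applies to the total reaction time, so
#' a decided trial with `rt > deadline` is also flagged.
#'
#' The drift in `params` is used exactly as given (see [ddm_params()] for the
#' sign convention); `true_alternative` only determines the `correct` flag.
#'
#' @param params a [ddm_params()] object.
#' @param true_alternative index of the presented alternative (for the
#'   `correct` flag).
#' @param noise optional numeric vector of standard-normal draws, used one per
#'   step; supplying the identical sequence to [simulate_bayes_trial()] with
#'   translated parameters reproduces the identical trajectory and decision.
#'   Must contain at least `steps_to_deadline(dt, deadline)` values.
#' @param seed optional integer seed used when `noise` is not supplied.
#' @param deadline response deadline in seconds (total RT).
#' @param return_path if `TRUE`, the outcome carries the visited states `y_t`
#'   (up to and including the crossing step).
#'
#' @return A `trial_outcome`: `choice` (1, 2 or `NA`), `n_steps`,
#'   `decision_time = n_steps * dt`, `rt = decision_time + t_nd`, `correct`,
#'   `outlier`, and optionally `path`.
#' @seealso [simulate_ddm_experiment()], [ddm_accuracy_closed_form()]
#' @examples
#' # noise-free: with s = 0 and v = 1 the bound B = 1 is hit at step 10
#' p <- ddm_params(v = 1, s = 0, B = 1, dt = 0.1)
#' simulate_ddm_trial(p, deadline = 5)
#' @export
simulate_ddm_trial <- function(params, true_alternative = 1L, noise = NULL,
                               seed = NULL, deadline, return_path = FALSE) {
  stopifnot(inherits(params, "ddm_params"))
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
  y <- params$y0 + cumsum(params$v * params$dt +
                            sqrt(params$dt) * params$s * noise)
  hit <- which(abs(y) >= params$B)
  if (length(hit) == 0L) {
    .trial_outcome(NA_integer_, NA_integer_, params$dt, params$t_nd,
                   true_alternative, deadline,
                   path = if (return_path) y else NULL)
  } else {
    k <- hit[1L]
    choice <- if (y[k] > 0) 1L else 2L
    .trial_outcome(choice, k, params$dt, params$t_nd, true_alternative,
                   deadline, path = if (return_path) y[seq_len(k)] else NULL)
  }
}

# Vectorized first-passage simulation of many independent discretized
# diffusion trials. `v` may be a per-trial vector (signed drift). Works in
# step chunks so that very fine time grids (dt = 1e-4) stay within memory.
# Returns integer crossing step (NA if none within n_max) and sign at
# crossing (+1 upper / -1 lower).
.ddm_first_passage <- function(v, s, B, y0, dt, n_max, n_trials,
                               chunk = 256L) {
  v <- rep_len(v, n_trials)
  step_mu <- v * dt
  step_sd <- sqrt(dt) * s
  n_steps <- rep(NA_integer_, n_trials)
  sign_hit <- rep(NA_real_, n_trials)
  y <- rep(y0, n_trials)
  active <- seq_len(n_trials)
  done_steps <- 0L
  while (length(active) > 0L && done_steps < n_max) {
    k <- min(chunk, n_max - done_steps)
    m <- length(active)
    inc <- rep(step_mu[active], each = k) + step_sd * stats::rnorm(k * m)
    # column-wise cumulative sums without apply(): cumsum the whole vector,
    # then remove the carry-over between columns
    cs <- matrix(cumsum(inc), nrow = k, ncol = m)
    if (m > 1L) cs <- cs - rep(c(0, cs[k, -m]), each = k)
    path <- cs + rep(y[active], each = k)
    crossed <- abs(path) >= B
    any_cross <- colSums(crossed) > 0L
    if (any(any_cross)) {
      first <- max.col(t(crossed[, any_cross, drop = FALSE]),
                       ties.method = "first")
      idx <- active[any_cross]
      n_steps[idx] <- done_steps + first
      sign_hit[idx] <- sign(path[cbind(first, which(any_cross))])
    }
    y[active[!any_cross]] <- path[k, !any_cross]
    active <- active[!any_cross]
    done_steps <- done_steps + k
  }
  list(n_steps = n_steps, sign = sign_hit)
}

#' Simulate many pDDM trials at once
#'
#' Vectorized counterpart of [simulate_ddm_trial()] for whole experiments.
#' Trials on which alternative 2 is presented use drift `-v` (symmetric-drift
#' convention); all trials share `s`, `B`, `y0`.
#'
#' @param params a [ddm_params()] object.
#' @param n_trials number of trials.
#' @param true_alternatives per-trial presented alternative (1 or 2), recycled
#'   to `n_trials`; defaults to all 1.
#' @param deadline response deadline in seconds (total RT).
#' @param seed optional integer seed.
#' @param chunk internal step-chunk size (memory/speed trade-off on fine grids).
#' @return A data frame with one row per trial: `true_alternative`, `choice`,
#'   `n_steps`, `decision_time`, `rt`, `correct`, `outlier`.
#' @examples
#' p <- ddm_params(v = 1, s = 1, B = 1, dt = 0.001)
#' head(simulate_ddm_experiment(p, 5, deadline = 10, seed = 1))
#' @export
simulate_ddm_experiment <- function(params, n_trials, true_alternatives = 1L,
                                    deadline, seed = NULL, chunk = 256L) {
  stopifnot(inherits(params, "ddm_params"))
  if (deadline <= params$t_nd)
    stop("'deadline' must exceed the non-decision time")
  if (!is.null(seed)) set.seed(seed)
  alt <- rep_len(as.integer(true_alternatives), n_trials)
  if (!all(alt %in% c(1L, 2L))) stop("'true_alternatives' must be 1 or 2")
  v_trial <- ifelse(alt == 1L, params$v, -params$v)
  n_max <- steps_to_deadline(params$dt, deadline)
  fp <- .ddm_first_passage(v_trial, params$s, params$B, params$y0,
                           params$dt, n_max, n_trials, chunk = chunk)
  choice <- ifelse(is.na(fp$sign), NA_integer_, ifelse(fp$sign > 0, 1L, 2L))
  decision_time <- fp$n_steps * params$dt
  rt <- decision_time + params$t_nd
  data.frame(true_alternative = alt,
             choice = choice,
             n_steps = fp$n_steps,
             decision_time = decision_time,
             rt = rt,
             correct = ifelse(is.na(choice), NA, choice == alt),
             outlier = is.na(choice) | rt > deadline)
}

#' Closed-form pDDM accuracy in the continuum limit
#'
#' Probability that the diffusion `dy = v dt + s dW`, started at `y0` between
#' absorbing bounds at `-B` and `+B`, is absorbed at the upper bound:
#' `(1 - exp(-2 v (y0 + B) / s^2)) / (1 - exp(-4 v B / s^2))`, with the
#' drift-free limit `(y0 + B) / (2 B)`. Used as a validation oracle for the
#' discretized simulators.
#'
#' @param v drift; @param s diffusion scale, `> 0`; @param B bound, `> 0`;
#' @param y0 starting state, `|y0| < B`.
#' @return Upper-bound absorption probability.
#' @examples
#' ddm_accuracy_closed_form(1, 1, 1)  # 1 / (1 + exp(-2)) ~ 0.8808
#' @export
ddm_accuracy_closed_form <- function(v, s, B, y0 = 0) {
  if (!all(is.finite(c(v, s, B, y0)))) stop("inputs must be finite")
  if (s <= 0 || B <= 0 || abs(y0) >= B) stop("need s > 0, B > 0, |y0| < B")
  z <- 2 * v * B / s^2
  if (abs(z) < 1e-10) return((y0 + B) / (2 * B))
  # expm1 keeps the ratio stable near v = 0
  expm1(-2 * v * (y0 + B) / s^2) / expm1(-4 * v * B / s^2)
}

#' Closed-form mean decision time of the pDDM (unbiased start)
#'
#' Expected first-passage time of the continuum-limit diffusion started at 0
#' between symmetric bounds: `(B / v) * tanh(v B / s^2)`, with drift-free
#' limit `B^2 / s^2`. For the unbiased symmetric process the decision-time
#' distribution is the same for correct and error responses, so this is also
#' the mean correct decision time.
#'
#' @param v drift; @param s diffusion scale, `> 0`; @param B bound, `> 0`.
#' @return Mean decision time in seconds.
#' @examples
#' ddm_mean_dt_closed_form(1, 1, 1)  # tanh(1) ~ 0.7616
#' @export
ddm_mean_dt_closed_form <- function(v, s, B) {
  if (!all(is.finite(c(v, s, B)))) stop("inputs must be finite")
  if (s <= 0 || B <= 0) stop("need s > 0, B > 0")
  z <- v * B / s^2
  if (abs(z) < 1e-10) return(B^2 / s^2)
  (B / v) * tanh(z)
}

#' Closed-form decision-time variance of the pDDM (unbiased start)
#'
#' Variance of the first-passage time of the continuum-limit diffusion
#' started at 0 between symmetric bounds `+-B`. With `a = 2B`,
#' `L = a v / s^2` and `Pc = 1 / (1 + exp(-L))` the variance is
#' `s^4 L (L Pc^2 - L Pc + Pc - 1/2) / v^4`. This expression solves the
#' first-passage moment boundary-value problem and serves as the forward
#' oracle for the EZ closed-form fit ([fit_ez()]).
#'
#' @param v drift, nonzero; @param s diffusion scale, `> 0`;
#' @param B bound, `> 0`.
#' @return Decision-time variance in seconds squared.
#' @examples
#' ddm_var_dt_closed_form(1, 1, 1)  # ~ 0.3416
#' @export
ddm_var_dt_closed_form <- function(v, s, B) {
  if (!all(is.finite(c(v, s, B)))) stop("inputs must be finite")
  if (s <= 0 || B <= 0) stop("need s > 0, B > 0")
  L <- 2 * B * v / s^2
  if (abs(L) < 1e-6)
    stop("'v' too close to zero for the closed-form variance")
  Pc <- stats::plogis(L)
  s^4 * L * (L * Pc^2 - L * Pc + Pc - 0.5) / v^4
}

#' Closed-form behavioral summary of a pDDM
#'
#' Convenience wrapper collecting the continuum-limit accuracy, mean and
#' variance of the decision time, and the mean correct reaction time
#' (`mrt = mean decision time + t_nd`) of an unbiased pDDM. These are the
#' noiseless statistics the EZ inversion consumes.
#'
#' @param params a [ddm_params()] object with `y0 = 0`.
#' @return List with `acc`, `mdt`, `mrt`, `vrt`.
#' @seealso [fit_ez()]
#' @export
ddm_summary_closed_form <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  if (params$y0 != 0)
    stop("closed-form summaries are implemented for the unbiased case y0 = 0")
  mdt <- ddm_mean_dt_closed_form(params$v, params$s, params$B)
  list(acc = ddm_accuracy_closed_form(params$v, params$s, params$B),
       mdt = mdt,
       mrt = mdt + params$t_nd,
       vrt = ddm_var_dt_closed_form(params$v, params$s, params$B))
}
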