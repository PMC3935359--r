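# Random-but-valid parameter sets used by the property-style tests.
# Alternative 1 carries the larger generative mean (the package sign
# convention), priors stay away from the boundaries of (0, 1).

random_bayes_params <- function(uniform_prior = FALSE, symmetric = FALSE,
                                t_nd = 0) {
  mu1 <- runif(1, 0.3, 2)
  mu2 <- -runif(1, 0.3, 2)
  mh1 <- runif(1, 0.3, 2)
  mh2 <- -runif(1, 0.3, 2)
  if (symmetric) {
    mu2 <- -mu1
    mh2 <- -mh1
  }
  lambda <- runif(1, 0.6, 0.95)
  # keep the prior's log odds strictly inside the log-odds bound, so the
  # equivalent diffusion starts strictly between its bounds
  p_hi <- plogis(0.8 * log(lambda / (1 - lambda)))
  prior1 <- if (uniform_prior) 0.5 else runif(1, 1 - p_hi, p_hi)
  bayes_params(mu = c(mu1, mu2), mu_hat = c(mh1, mh2),
               sigma = runif(1, 0.2, 2), sigma_hat = runif(1, 0.4, 2),
               lambda = lambda,
               prior = c(prior1, 1 - prior1),
               dt = runif(1, 0.02, 0.2), t_nd = t_nd)
}

random_ddm_params <- function(t_nd = 0) {
  B <- runif(1, 0.4, 2)
  ddm_params(v = runif(1, 0.1, 2), s = runif(1, 0.2, 2), B = B,
             y0 = runif(1, -0.8, 0.8) * B, dt = runif(1, 0.02, 0.2),
             t_nd = t_nd)
}

# Independent type-7 quantile oracle: linear interpolation of order
# statistics at h = (n - 1) p + 1.
quantile_type7_oracle <- function(x, probs) {
  x <- sort(x)
  n <- length(x)
  vapply(probs, function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}
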