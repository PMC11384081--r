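# Shared fixtures and independent oracles.

# random valid parameter draws for a candidate function (natural scale)
draw_params <- function(fn) {
  fn <- soe_function(fn)
  p <- numeric(fn$n_shape)
  for (k in seq_len(fn$n_shape)) {
    nm <- fn$params[k]
    p[k] <- if (fn$type[k] == "frac") runif(1, 0.05, 0.95)
    else if (startsWith(nm, "A")) runif(1, 0.001, 0.1)
    else exp(runif(1, log(1e-5), log(5e-3)))  # rates per minute
  }
  names(p) <- fn$params
  p
}

# independent quadrature oracle for the time integral of the activity curve
tia_quadrature <- function(fn, params, decay, t_end) {
  stats::integrate(function(t) soe_eval(fn, params, t, decay, check = FALSE),
                   lower = 0, upper = t_end, rel.tol = 1e-9,
                   subdivisions = 1000L)$value
}

# tiny hand-built cohort (3 patients, 3 points each)
toy_cohort <- function() {
  ta_cohort(data.frame(
    patient_id = rep(c("A", "B", "C"), each = 3),
    time = rep(c(60, 1200, 9800), 3),
    activity = c(0.040, 0.027, 0.0060,
                 0.052, 0.031, 0.0071,
                 0.035, 0.024, 0.0049)), time_unit = "min")
}

# Independent Gauss-Hermite oracle for the marginal -2 log likelihood of a
# one-random-effect f2a model (random effect on A1 only), on the log-data
# scale used throughout the package.
gh_neg2ll_f2a_A1 <- function(cohort, A1, lambda1, omega, sigma,
                             decay = decay_constants(), n_nodes = 40) {
  gh <- pracma::gaussHermite(n_nodes)
  total <- 0
  for (id in unique(cohort$patient_id)) {
    sub <- cohort[cohort$patient_id == id, ]
    ll <- vapply(gh$x, function(x) {
      a1 <- A1 * exp(sqrt(2) * omega * x)
      f <- soe_eval("f2a", c(A1 = a1, lambda1 = lambda1), sub$time, decay,
                    check = FALSE)
      sum(stats::dnorm(log(sub$activity), log(f), sigma, log = TRUE))
    }, 0)
    lw <- log(gh$w) - 0.5 * log(pi) + ll
    m <- max(lw)
    total <- total - 2 * (m + log(sum(exp(lw - m))))
  }
  total
}
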