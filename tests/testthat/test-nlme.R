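# Population (NLME) fitting engine: Laplace marginal likelihood,
# empirical-Bayes individualisation, CV of the fixed effects.

test_that("Laplace marginal matches Gauss-Hermite quadrature on a one-random-effect toy", {
  coh <- toy_cohort()
  for (pars in list(c(A1 = 0.045, l1 = 2.5e-4, om = 0.3, sg = 0.2),
                    c(A1 = 0.04, l1 = 3e-4, om = 0.5, sg = 0.25),
                    c(A1 = 0.05, l1 = 2e-4, om = 0.15, sg = 0.3))) {
    lap <- soe_nlme_neg2ll(coh, "f2a",
                           fixef = c(A1 = pars[["A1"]], lambda1 = pars[["l1"]]),
                           omega = pars[["om"]], sigma = pars[["sg"]],
                           random = "A1")
    gh <- gh_neg2ll_f2a_A1(coh, pars[["A1"]], pars[["l1"]], pars[["om"]],
                           pars[["sg"]], n_nodes = 64)
    expect_lt(abs(lap - gh), 1e-3)
  }
  # for this log-linear random effect the marginal is exactly
  # linear-Gaussian; verify against the closed form too
  dk <- decay_constants()
  mu <- 2.5e-4 + dk$lambda_phys
  closed <- 0
  for (id in unique(coh$patient_id)) {
    sub <- coh[coh$patient_id == id, ]
    m <- log(0.045) - mu * sub$time
    S <- diag(0.2^2, 3) + 0.3^2
    r <- log(sub$activity) - m
    closed <- closed + as.numeric(determinant(S)$modulus) +
      drop(t(r) %*% solve(S) %*% r) + 3 * log(2 * pi)
  }
  lap1 <- soe_nlme_neg2ll(coh, "f2a", c(A1 = 0.045, lambda1 = 2.5e-4),
                          omega = 0.3, sigma = 0.2, random = "A1")
  expect_equal(lap1, closed, tolerance = 1e-9)
})

test_that("noise-free cohort recovers generating values to 0.1 percent", {
  d0 <- cohort_design(truth_fn = "f2a",
                      truth_tvp = c(A1 = 0.05, lambda1 = 4e-4),
                      omega = 1e-9, sigma_res = 1e-9)
  coh <- simulate_cohort(d0, seed = 8)
  fit <- soe_nlme(coh, "f2a",
                  control = nlme_control(n_starts = 2, omega_fixed = 1e-4,
                                         sigma_fixed = 0.01))
  expect_equal(unname(coef(fit)), c(0.05, 4e-4), tolerance = 1e-3)
  # per-patient empirical-Bayes parameters equal the truth too
  for (id in c("P01", "P07"))
    expect_equal(unname(individual_params(fit, id)), c(0.05, 4e-4),
                 tolerance = 1e-3)
})

test_that("fit is invariant under patient relabelling and observation reordering", {
  coh <- simulate_cohort(seed = 21)
  fit1 <- soe_nlme(coh, "f2a", control = nlme_control(n_starts = 2))
  df <- as.data.frame(coh)
  perm <- sample(seq_len(nrow(df)))
  df2 <- df[perm, ]
  df2$patient_id <- paste0("X", df2$patient_id)
  coh2 <- ta_cohort(df2, time_unit = "min")
  fit2 <- soe_nlme(coh2, "f2a", control = nlme_control(n_starts = 2))
  expect_equal(fit1$neg2ll, fit2$neg2ll, tolerance = 1e-6)
  expect_equal(unname(coef(fit1)), unname(coef(fit2)), tolerance = 1e-6)
})

test_that("adding a random effect never increases the minimised objective", {
  coh <- simulate_cohort(seed = 31)
  ctl <- nlme_control(n_starts = 3)
  f_a1 <- soe_nlme(coh, "f2a", random = "A1", control = ctl)
  f_all <- soe_nlme(coh, "f2a", random = "all", control = ctl)
  expect_lte(f_all$neg2ll, f_a1$neg2ll + 1e-4)
  expect_identical(f_a1$K, 4L)   # 2 fixed + 1 variance + residual
  expect_identical(f_all$K, 5L)  # 2 fixed + 2 variances + residual
})

test_that("omega to zero with fixed sigma reduces to pooled log-scale least squares", {
  coh <- simulate_cohort(seed = 5)
  fit <- soe_nlme(coh, "f2a",
                  control = nlme_control(n_starts = 3, omega_fixed = 1e-6,
                                         sigma_fixed = 0.15))
  # independent pooled fit on log observations
  pooled <- stats::nlminb(
    log(c(0.04, 3e-4)),
    function(v) {
      f <- soe_eval("f2a", exp(v), coh$time, check = FALSE)
      sum((log(coh$activity) - log(f))^2)
    })
  expect_equal(unname(coef(fit)), unname(exp(pooled$par)), tolerance = 1e-4)
})

test_that("single-patient cohorts fit with a warning about unidentifiable variances", {
  coh <- simulate_cohort(seed = 2)
  one <- coh[coh$patient_id == "P01", ]
  class(one) <- class(coh)
  expect_warning(
    fit <- soe_nlme(one, "f2a", control = nlme_control(n_starts = 2)),
    "identifiab")
  expect_s3_class(fit, "soe_nlme")
})

test_that("CV of the fixed effects follows sqrt(exp(se^2) - 1)", {
  coh <- simulate_cohort(seed = 13)
  fit <- soe_nlme(coh, "f2a", control = nlme_control(n_starts = 2))
  # direct functional check on the stored standard errors
  expect_equal(unname(fit$cv), unname(sqrt(exp(fit$se_t^2) - 1)))
  # boundary: se^2 = ln(1.25) sits exactly at the 0.5 gate
  expect_equal(sqrt(exp(log(1.25)) - 1), 0.5)
  # degenerate fit: infinite SEs give infinite CV and a failed gate
  broken <- fit
  broken$cv[] <- Inf
  expect_identical(cv_fixed_effects(broken)$max_cv, Inf)
  g <- goodness_gate(list(f = broken))
  expect_false(g[["f"]])
})

test_that("individual parameters are TVP times exp(eta) and unknown patients error", {
  coh <- simulate_cohort(seed = 17)
  fit <- soe_nlme(coh, "f3a", control = nlme_control(n_starts = 2))
  p1 <- individual_params(fit, "P01")
  manual <- exp(fit$fixef_t + fit$eta["P01", ])
  expect_equal(unname(p1), unname(manual), tolerance = 1e-12)
  # eta = 0 returns the typical values exactly
  zero <- fit
  zero$eta[] <- 0
  expect_equal(unname(individual_params(zero, "P01")),
               unname(coef(fit)), tolerance = 1e-12)
  expect_error(individual_params(fit, "nobody"), "unknown patient")
})

test_that("S3 surface behaves: print, summary, coef, logLik, predict, residuals, simulate", {
  coh <- simulate_cohort(seed = 19)
  fit <- soe_nlme(coh, "f2a", control = nlme_control(n_starts = 2))
  expect_output(print(fit), "Population SOE fit: f2a")
  expect_output(print(summary(fit)), "max CV")
  expect_named(coef(fit), c("A1", "lambda1"))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), -fit$neg2ll / 2)
  expect_identical(attr(ll, "df"), fit$K)
  pred <- predict(fit)
  expect_length(pred, nrow(coh))
  expect_equal(predict(fit, data.frame(time = 0), level = "population"),
               sum(coef(fit)[1]), tolerance = 1e-12)
  r <- residuals(fit)
  expect_equal(r, log(coh$activity) - log(fitted(fit)),
               ignore_attr = TRUE)
  sim <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sim, 2L)
  expect_s3_class(sim[[1]], "ta_cohort")
  expect_equal(nrow(sim[[1]]), nrow(coh))
})
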