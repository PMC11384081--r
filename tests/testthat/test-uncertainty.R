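# Log-normal moment matching and frequency-based uncertainty propagation.

test_that("log-normal moments reproduce the requested natural-scale moments", {
  lm0 <- normal_to_lognormal(1, 0)
  expect_equal(lm0$mu_log, 0)
  expect_equal(lm0$sigma_log, 0)
  lm <- normal_to_lognormal(2, 1)
  expect_equal(lm$mu_log, 2 * log(2) - 0.5 * log(5), tolerance = 1e-12)
  expect_equal(lm$mu_log, 0.5816, tolerance = 1e-4)
  expect_equal(lm$sigma_log, sqrt(log(5) - 2 * log(2)), tolerance = 1e-12)
  expect_equal(lm$sigma_log, 0.4724, tolerance = 1e-4)
  # round trip: analytic moments of LogNormal(mu, sigma) match to 1e-9
  set.seed(8)
  for (r in 1:25) {
    m <- runif(1, 0.01, 50)
    s <- runif(1, 0, m)
    lm <- normal_to_lognormal(m, s)
    expect_equal(exp(lm$mu_log + lm$sigma_log^2 / 2), m, tolerance = 1e-9)
    v <- (exp(lm$sigma_log^2) - 1) * exp(2 * lm$mu_log + lm$sigma_log^2)
    expect_equal(sqrt(v), s, tolerance = 1e-9)
  }
  expect_error(normal_to_lognormal(-1, 1), "positive")
})

test_that("frequency sampler has the documented shape, range and determinism", {
  smp <- frequency_sampler()  # omega = 1028, n_evals = 8193
  expect_identical(smp$omega, 1028L)
  expect_identical(smp$n_evals, 8193L)
  U <- frequency_sample(smp, 3)
  expect_identical(dim(U), c(8193L, 3L))
  expect_true(all(U >= 0 & U <= 1))
  # triangle-wave sampling is near-uniform: column means close to 1/2
  expect_true(all(abs(colMeans(U) - 0.5) < 0.02))
  # identical settings reproduce bit-identical samples
  expect_identical(U, frequency_sample(frequency_sampler(), 3))
  expect_false(identical(U, frequency_sample(frequency_sampler(seed = 2), 3)))
  # s = 0 with zero phase maps to exactly 1/2
  expect_equal(0.5 + asin(sin(1028 * 0)) / pi, 0.5)
  # the odd default grid contains s = 0, where a zero-phase column gives 1/2
  n <- 8193L
  s <- -pi / 2 + pi * (seq_len(n) - 0.5) / n
  expect_true(any(abs(s) < 1e-12))
})

test_that("TIA uncertainty propagation matches the delta method on a one-parameter model", {
  # patient with an effectively one-parameter TIA: A / mu, 10 percent CV on A
  coh <- simulate_cohort(cohort_design(truth_fn = "f2a",
                                       truth_tvp = c(A1 = 0.05,
                                                     lambda1 = 4e-4),
                                       omega = 1e-9, sigma_res = 1e-9),
                         seed = 23)
  ib <- fit_ibms(coh, "f2a")
  ib$fits <- ib$fits["P01"]
  ib$fits$P01$param_sd <- c(A1 = 0.1 * ib$fits$P01$params[["A1"]],
                            lambda1 = 0)
  out <- tia_sd(ib, frequency_sampler(seed = 3))
  # TIA linear in A: CV of TIA equals CV of A
  expect_equal(out$tia_sd / out$tia_mean, 0.1, tolerance = 0.01)
  expect_equal(out$tia_mean, out$tia, tolerance = 0.01)
  # all-zero parameter SDs collapse to the point estimate
  ib$fits$P01$param_sd[] <- 0
  out0 <- tia_sd(ib, frequency_sampler(seed = 3))
  expect_equal(out0$tia_sd, 0)
  expect_equal(out0$tia_mean, out0$tia)
})

test_that("quantile-pushed samples reproduce the requested moments at the default size", {
  U <- frequency_sample(frequency_sampler(seed = 5), 1)
  m <- 3; s <- 0.6
  lm <- normal_to_lognormal(m, s)
  draws <- qlnorm(U[, 1], lm$mu_log, lm$sigma_log)
  expect_equal(mean(draws), m, tolerance = 0.02)
  expect_equal(sd(draws), s, tolerance = 0.02)
})
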