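# Candidate sum-of-exponential functions: evaluation, constraints and
# closed-form time integration.

test_that("registry exposes the eleven candidate functions with the expected shape-parameter counts", {
  expect_length(soe_functions(), 11L)
  counts <- c(f2a = 2L, f3a = 3L, f3b = 3L, f3c = 3L, f4a = 4L, f4b = 4L,
              f5a = 5L, f5b = 5L, f5c = 5L, f6a = 6L, f6b = 6L)
  for (nm in names(counts))
    expect_identical(soe_function(nm)$n_shape, unname(counts[[nm]]),
                     info = nm)
  expect_error(soe_function("f9z"), "unknown function")
})

test_that("physical decay constant follows ln2 over the half-life in minutes", {
  dk <- decay_constants(6.6443)
  expect_equal(dk$lambda_phys, log(2) / (6.6443 * 1440), tolerance = 1e-12)
  expect_equal(decay_constants(1)$lambda_phys, log(2) / 1440)
  expect_error(decay_constants(-1), "positive")
})

test_that("evaluation at t = 0 equals the algebraic sum of pre-factors", {
  dk <- decay_constants()
  set.seed(41)
  expect_equal(soe_eval("f3a", c(A1 = 0.3, A2 = 0.2, lambda1 = 0.01), 0, dk),
               0.5)
  # structural cancellation: f5b is exactly zero at t = 0
  p5b <- c(A1 = 0.4, A2 = 0.3, lambda1 = 0.01, lambda2 = 0.001,
           lambda3 = 0.05)
  expect_equal(soe_eval("f5b", p5b, 0, dk), 0)
  for (nm in soe_functions()) {
    p <- draw_params(nm)
    tm <- soe_terms(nm, p, dk)
    expect_equal(soe_eval(nm, p, 0, dk), sum(tm$coef), info = nm)
  }
})

test_that("f2a evaluation matches direct scalar arithmetic", {
  dk <- decay_constants()
  got <- soe_eval("f2a", c(A1 = 1, lambda1 = 0.001), t = 1000, decay = dk)
  expect_equal(got, exp(-(0.001 + dk$lambda_phys) * 1000), tolerance = 1e-12)
  expect_equal(got, 0.3422, tolerance = 1e-4)
})

test_that("f3b at alpha is pointwise identical to f3c at 1 - alpha, with equal TIAs", {
  dk <- decay_constants()
  tt <- c(0, 10, 100, 1000, 10000)
  for (a in c(0.1, 0.5, 0.9632)) {
    pb <- c(A1 = 0.05, alpha = a, lambda1 = 4e-4)
    pc <- c(A1 = 0.05, alpha = 1 - a, lambda1 = 4e-4)
    expect_equal(soe_eval("f3b", pb, tt, dk), soe_eval("f3c", pc, tt, dk),
                 tolerance = 1e-12)
    expect_equal(soe_tia("f3b", pb, dk), soe_tia("f3c", pc, dk),
                 tolerance = 1e-12)
  }
})

test_that("functions with all-positive pre-factors are non-increasing in time", {
  dk <- decay_constants()
  tt <- seq(0, 5e4, length.out = 200)
  set.seed(7)
  for (nm in c("f2a", "f3a", "f3b", "f3c", "f4a", "f4b", "f5c", "f6b")) {
    for (r in 1:5) {
      v <- soe_eval(nm, draw_params(nm), tt, dk)
      expect_true(all(diff(v) <= 1e-12), info = nm)
    }
  }
})

test_that("closed-form TIA matches scalar arithmetic and handles limits", {
  dk <- decay_constants()
  # infinite horizon of a single-term function is A / mu
  expect_equal(soe_tia("f2a", c(A1 = 1, lambda1 = 0.001), dk, t_end = Inf),
               1 / (0.001 + dk$lambda_phys), tolerance = 1e-12)
  mu <- 0.001 + dk$lambda_phys
  expect_equal(soe_tia("f2a", c(A1 = 1, lambda1 = 0.001), dk, t_end = 1e5),
               (1 - exp(-mu * 1e5)) / mu, tolerance = 1e-12)
  expect_equal(soe_tia("f2a", c(A1 = 1, lambda1 = 0.001), dk, t_end = 1e5),
               932.45, tolerance = 1e-4)
  # zero total rate integrates as A * t_end (limit, not a crash)
  dk0 <- structure(list(half_life_days = Inf, lambda_phys = 0),
                   class = "decay_constants")
  expect_equal(soe_tia("f2a", c(A1 = 0.5, lambda1 = 0), dk0, t_end = 100),
               0.5 * 100, tolerance = 1e-12)
  expect_error(soe_tia("f2a", c(A1 = 1, lambda1 = 0), dk0, t_end = Inf),
               "zero-rate")
  # near-zero rates stay cancellation-free
  dk1 <- decay_constants(1e12)
  expect_equal(soe_tia("f2a", c(A1 = 0.5, lambda1 = 0), dk1, t_end = 100),
               50, tolerance = 1e-9)
})

test_that("closed-form TIA agrees with adaptive quadrature across all functions and random draws", {
  dk <- decay_constants()
  set.seed(2024)
  for (nm in soe_functions()) {
    for (r in 1:20) {
      p <- draw_params(nm)
      a <- soe_tia(nm, p, dk, t_end = 1e5)
      b <- tia_quadrature(nm, p, dk, t_end = 1e5)
      expect_equal(a, b, tolerance = 1e-6, info = sprintf("%s draw %d", nm, r))
    }
  }
  # f5b with equal-and-opposite terms at t = 0 still integrates positively
  p <- c(A1 = 0.03, A2 = 0.02, lambda1 = 2e-3, lambda2 = 2e-4, lambda3 = 0.05)
  a <- soe_tia("f5b", p, dk, t_end = 1e5)
  expect_gt(a, 0)
  expect_equal(a, tia_quadrature("f5b", p, dk, 1e5), tolerance = 1e-6)
})

test_that("parameter validation names the offending parameter", {
  expect_match(soe_validate("f3a", c(A1 = 1, A2 = 1, lambda1 = -0.1)),
               "lambda1")
  expect_length(soe_validate("f3b", c(A1 = 1, alpha = 0.5, lambda1 = 0.01)),
                0L)
  expect_match(soe_validate("f6b", c(A1 = 1, A2 = 1, A3 = -1, lambda1 = 1,
                                     lambda2 = 1, lambda3 = 1)), "A3")
  expect_match(soe_validate("f3b", c(A1 = 1, alpha = 1.2, lambda1 = 0.01)),
               "alpha")
  expect_error(soe_eval("f3a", c(A1 = -1, A2 = 1, lambda1 = 0.1), 0), "A1")
})

test_that("C++ term expansion agrees with the R registry", {
  dk <- decay_constants()
  set.seed(99)
  for (nm in soe_functions()) {
    p <- draw_params(nm)
    r <- soe_terms(nm, p, dk)
    cc <- tiapbms:::cpp_soe_terms(soe_function(nm)$id, unname(p),
                                  dk$lambda_phys)
    expect_equal(unname(r$coef), cc$coef, tolerance = 1e-14, info = nm)
    expect_equal(unname(r$rate), cc$rate, tolerance = 1e-14, info = nm)
  }
})
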