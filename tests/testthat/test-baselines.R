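# IBMS (per-patient WLS) and SP-PBMS (shared-parameter population WLS).

test_that("noise-free individual data recover f2a parameters essentially exactly", {
  d0 <- cohort_design(truth_fn = "f2a",
                      truth_tvp = c(A1 = 0.05, lambda1 = 4e-4),
                      omega = 1e-9, sigma_res = 1e-9)
  coh <- simulate_cohort(d0, seed = 14)
  ib <- fit_ibms(coh, "f2a")
  for (id in names(ib$fits)) {
    expect_equal(unname(ib$fits[[id]]$params), c(0.05, 4e-4),
                 tolerance = 1e-5, info = id)
    expect_true(ib$fits[[id]]$converged)
  }
  # per-patient TIA equals the closed form at the fitted parameters
  dk <- decay_constants()
  tt <- tia(ib)
  for (id in names(ib$fits)) {
    p <- ib$fits[[id]]$params
    mu <- p[["lambda1"]] + dk$lambda_phys
    expect_equal(unname(tt[id]), p[["A1"]] / mu * (1 - exp(-mu * 1e5)),
                 tolerance = 1e-10)
  }
})

test_that("patients without enough observations for the function are skipped", {
  coh <- simulate_cohort(seed = 3)
  ib <- fit_ibms(coh, "f3a")  # 3 parameters; 3-point patients have df = 0
  npts <- table(coh$patient_id)
  expect_setequal(names(ib$skipped), names(npts)[npts <= 3])
  expect_match(ib$skipped[[1]], "df")
  expect_setequal(names(ib$fits), names(npts)[npts > 3])
})

test_that("IBMS f2a over 13 patients totals K = 26 and SP-PBMS f3b totals K = 27", {
  coh <- simulate_cohort(seed = 7)
  ib <- fit_ibms(coh, "f2a")
  expect_identical(ib$K, 26L)
  sp <- fit_sp_pbms(coh, "f3b", shared = "alpha")
  expect_identical(sp$K, 27L)
  expect_true(sp$shared_estimated)
  # fixed-alpha evaluation mode: 2 free parameters per patient
  spf <- fit_sp_pbms(coh, "f3b", shared = "alpha", shared_value = 0.9632)
  expect_identical(spf$n_free_per_patient, 2L)
  expect_equal(spf$shared_value, 0.9632, tolerance = 1e-9)
  expect_identical(spf$K, 26L)
  for (f in spf$fits) expect_equal(f$params[["alpha"]], 0.9632,
                                   tolerance = 1e-9)
})

test_that("two identical patients double the individual objective under a shared fit", {
  d0 <- cohort_design(truth_fn = "f3b",
                      truth_tvp = c(A1 = 0.05, alpha = 0.9, lambda1 = 4e-4),
                      omega = 1e-9, sigma_res = 1e-9)
  base <- simulate_cohort(d0, seed = 10)
  sub <- as.data.frame(base[base$patient_id == "P02", ])  # 5 observations
  sub$activity <- sub$activity * exp(c(0.1, -0.05, 0.02, 0.04, -0.08))
  df <- rbind(transform(sub, patient_id = "A"),
              transform(sub, patient_id = "B"))
  coh <- ta_cohort(df, time_unit = "min")
  sp <- fit_sp_pbms(coh, "f3b", shared = "alpha")
  one <- fit_ibms(ta_cohort(transform(sub, patient_id = "A"), "min"), "f3b")
  expect_equal(sp$objective, 2 * one$fits[["A"]]$objective, tolerance = 1e-4)
})

test_that("shared alpha is recovered from an f3b-truth cohort", {
  # clearly two-phase truth (fast phase gone by the second scan) so the
  # plateau fraction 1 - alpha is expressed in the sampled window
  d0 <- cohort_design(truth_fn = "f3b",
                      truth_tvp = c(A1 = 0.05, alpha = 0.9, lambda1 = 2e-3),
                      omega = c(0.2, 1e-9, 0.2), sigma_res = 0.1)
  est <- vapply(1:5, function(s)
    fit_sp_pbms(simulate_cohort(d0, seed = s), "f3b",
                shared = "alpha")$shared_value, 0)
  expect_lt(abs(median(est) - 0.9), 0.05)
})

test_that("freeing the shared parameter can only lower the summed objective", {
  coh <- simulate_cohort(seed = 16)
  sp <- fit_sp_pbms(coh, "f3b", shared = "alpha")
  free <- fit_ibms(coh, "f3b")  # alpha free per patient (where df allows)
  ids <- names(free$fits)
  sp_sub <- sum(vapply(sp$fits[ids], `[[`, 0, "objective"))
  free_sum <- sum(vapply(free$fits, `[[`, 0, "objective"))
  expect_lte(free_sum, sp_sub + 1e-6)
})
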