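# AICc, Akaike weights, goodness gate, model averaging, Jackknife.

test_that("AICc penalty reproduces the published small-sample arithmetic", {
  expect_equal(aicc_penalty(7, 46), 2 * 7 + 2 * 7 * 8 / 38, tolerance = 1e-12)
  expect_equal(round(aicc_penalty(7, 46)), 17)
  expect_equal(round(aicc_penalty(26, 46)), 126)
  expect_equal(aicc_penalty(27, 46), 138)
  expect_equal(aicc(10, 7, 46), 10 + aicc_penalty(7, 46))
  expect_error(aicc(0, 45, 46), "N - K - 1")
  expect_error(aicc_penalty(46, 46))
})

test_that("AICc penalty tends to the plain AIC penalty for large N", {
  K <- 7
  expect_equal(aicc_penalty(K, 1e8), 2 * K, tolerance = 1e-5)
  expect_true(all(diff(sapply(c(50, 100, 1000, 1e6), aicc_penalty,
                              K = K)) < 0))
})

test_that("Akaike weights normalise, order and survive huge deltas", {
  expect_equal(akaike_weights(42), 1)
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  # the published worked example: equal -2lnP, K = 7 / 26 / 27 at N = 46
  d <- c(0, aicc_penalty(26, 46) - aicc_penalty(7, 46),
         aicc_penalty(27, 46) - aicc_penalty(7, 46))
  expect_equal(d[2], 108.947, tolerance = 1e-3)
  expect_equal(d[3], 121.053, tolerance = 1e-3)
  w <- akaike_weights(d)
  expect_equal(w[1], 1, tolerance = 1e-10)
  expect_equal(w[3], 5.17e-27, tolerance = 1e-2)    # i.e. 5.2e-25 percent
  expect_equal(w[3] * 100, 5.2e-25, tolerance = 5e-2)
  expect_equal(sum(w), 1)
  # shift invariance and monotonicity
  set.seed(3)
  for (r in 1:20) {
    a <- runif(6, 0, 300)
    expect_equal(akaike_weights(a), akaike_weights(a + 123.4),
                 tolerance = 1e-12)
    expect_true(all(diff(akaike_weights(sort(a))) <= 1e-15))
  }
  expect_error(akaike_weights(c(1, Inf)), "non-finite")
  expect_error(akaike_weights(numeric(0)), "empty")
})

test_that("BIC takes the standard form and is monotone in K", {
  expect_equal(bic(0, 1, exp(1)), 1)
  expect_equal(bic(5, 0, 100), 5)
  expect_equal(bic(10, 3, 46), 10 + 3 * log(46))
})

test_that("goodness gate fails non-convergence, large CV and non-finite CV", {
  mk <- function(cv, conv = TRUE) {
    structure(list(cv = c(A1 = cv), converged = conv), class = "soe_nlme")
  }
  g <- goodness_gate(list(a = mk(0.20), b = mk(0.78), c = mk(Inf),
                          d = mk(0.10, conv = FALSE), e = mk(0.499)))
  expect_equal(as.logical(g), c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_match(attr(g, "reason")[2], "0.78")
  expect_match(attr(g, "reason")[3], "singular|finite")
  expect_match(attr(g, "reason")[4], "converge")
})

test_that("model averaging is the weighted dot product of per-patient TIAs", {
  tias <- matrix(c(100, 200), 1, 2, dimnames = list("P1", c("a", "b")))
  expect_equal(model_average_tia(c(a = 1, b = 0), tias)$tia_ma, c(P1 = 100))
  expect_equal(model_average_tia(c(a = 0.5, b = 0.5), tias)$tia_ma,
               c(P1 = 150))
  set.seed(12)
  M <- matrix(runif(13 * 5, 50, 400), 13, 5,
              dimnames = list(sprintf("P%02d", 1:13), paste0("f", 1:5)))
  w <- runif(5)
  w <- w / sum(w)
  names(w) <- paste0("f", 1:5)
  got <- model_average_tia(w, M)$tia_ma
  # independent elementwise oracle
  for (i in 1:13)
    expect_equal(unname(got[i]), sum(w * M[i, names(w)]), tolerance = 1e-12)
  expect_error(model_average_tia(c(a = 0.7, b = 0.7), tias), "sum to 1")
  expect_error(model_average_tia(c(a = 0.5, z = 0.5), tias),
               "different function sets")
})

test_that("selection table weights live on the gate-passing set only", {
  coh <- simulate_cohort(seed = 6)
  sel <- pbms_select(coh, c("f2a", "f3a", "f3c"),
                     control = nlme_control(n_starts = 2))
  tab <- sel$table
  expect_equal(sum(tab$weight[tab$passed]), 1, tolerance = 1e-9)
  expect_true(all(tab$weight[!tab$passed] == 0))
  expect_true(all(tab$delta[tab$passed] >= 0))
  expect_equal(min(tab$delta[tab$passed]), 0)
  expect_true(all(tab$K[tab$passed] < tab$N[tab$passed] - 1))
  expect_s3_class(model_average(sel), "ma_result")
  expect_output(print(sel), "Best supported function")
  # the BIC convenience criterion ranks the same candidates in the same
  # order as AICc on this fixture
  sc <- tab[!is.na(tab$aicc), ]
  bics <- bic(sc$neg2ll, sc$K, sc$N)
  expect_identical(order(bics), order(sc$aicc))
})

test_that("best-function ties break by smaller K then name", {
  sel <- structure(list(table = data.frame(
    fn = c("x2", "a3", "b3"), K = c(5L, 7L, 7L), weight = c(0.2, 0.4, 0.4),
    passed = TRUE)), class = "pbms_selection")
  expect_identical(best_function(sel), "a3")
  sel$table$K <- c(5L, 7L, 5L)
  expect_identical(best_function(sel), "b3")
})

test_that("jackknife runs one replicate per patient at size n - 1", {
  coh <- simulate_cohort(seed = 9)
  jk <- pbms_jackknife(coh, c("f2a", "f3a"),
                       control = nlme_control(n_starts = 2))
  expect_identical(jk$n_replicates, 13L)
  expect_identical(dim(jk$weights), c(13L, 2L))
  expect_equal(sum(jk$summary$n_first), 13L)
  expect_output(print(jk), "13 leave-one-out replicates")
  two <- coh[coh$patient_id %in% c("P01", "P02"), ]
  class(two) <- class(coh)
  expect_error(pbms_jackknife(two, "f2a"), "at least 3 patients")
})

test_that("identical patients give zero jackknife weight spread", {
  one <- simulate_cohort(cohort_design(omega = 1e-9, sigma_res = 0.1),
                         seed = 4)
  sub <- one[one$patient_id == "P02", ]  # 5 observations
  df <- do.call(rbind, lapply(sprintf("Q%d", 1:5), function(id) {
    out <- as.data.frame(sub)
    out$patient_id <- id
    out
  }))
  coh <- ta_cohort(df, time_unit = "min")
  # variances fixed (and the CV screen disabled) so the fits are well-posed
  # on literally identical patients; every leave-one-out subset is then the
  # same data set and the weights cannot vary
  jk <- pbms_jackknife(coh, c("f2a", "f3a"), cv_threshold = Inf,
                       control = nlme_control(n_starts = 2,
                                              omega_fixed = 0.1,
                                              sigma_fixed = 0.1))
  expect_length(jk$failed, 0L)
  expect_true(all(is.finite(jk$summary$sd)))
  expect_lt(max(jk$summary$sd), 1e-8)
})
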