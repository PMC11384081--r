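# Synthetic cohorts emulating the study design: 13 patients imaged at
# roughly 1.1 h, 20.7 h and 163.8 h after injection, one patient with one
# extra point (66.1 h) and three patients with two extra points each
# (about 45.9 h and 68.7 h), for 46 observations in total. Kinetics follow
# a known truth function with log-normal inter-individual variability and
# multiplicative residual error, so parameter- and selection-recovery are
# testable against exact reference values.

#' Synthetic cohort design
#'
#' @param n_patients number of patients (default 13).
#' @param schedule_h means of the nominal imaging times (hours).
#' @param schedule_sd_h SDs of the imaging times (hours).
#' @param extra_single_h one additional time point (hours) given to the
#'   first patient.
#' @param extra_pair_h,extra_pair_sd_h mean and SD (hours) of the two
#'   additional points given to each of \code{n_extra_pair} patients.
#' @param n_extra_pair number of patients receiving the extra pair.
#' @param truth_fn truth function name.
#' @param truth_tvp named natural-scale typical values of the truth
#'   function. The defaults (A1 = 0.04, A2 = 0.005 as fractions of injected
#'   activity, lambda1 = 0.02/h) are fixture choices of physiologically
#'   plausible magnitude, not literature estimates.
#' @param omega inter-individual SD of each parameter (log/logit scale).
#' @param sigma_res residual SD (log scale).
#' @param half_life_days physical half-life (days).
#' @return List of class \code{"cohort_design"}.
#' @export
cohort_design <- function(n_patients = 13L,
                          schedule_h = c(1.1, 20.7, 163.8),
                          schedule_sd_h = c(0.7, 2.3, 2.0),
                          extra_single_h = 66.1,
                          extra_pair_h = c(45.9, 68.7),
                          extra_pair_sd_h = c(1.6, 1.7),
                          n_extra_pair = 3L,
                          truth_fn = "f3a",
                          truth_tvp = c(A1 = 0.04, A2 = 0.005,
                                        lambda1 = 0.02 / 60),
                          omega = 0.3, sigma_res = 0.15,
                          half_life_days = 6.6443) {
  stopifnot(n_patients >= 1, length(schedule_h) == length(schedule_sd_h),
            length(extra_pair_h) == length(extra_pair_sd_h),
            n_extra_pair + 1L <= n_patients)
  fn <- soe_function(truth_fn)
  tvp <- .as_param_vector(fn, truth_tvp)
  .soe_check(fn, tvp)
  structure(list(n_patients = as.integer(n_patients),
                 schedule_h = schedule_h, schedule_sd_h = schedule_sd_h,
                 extra_single_h = extra_single_h,
                 extra_pair_h = extra_pair_h,
                 extra_pair_sd_h = extra_pair_sd_h,
                 n_extra_pair = as.integer(n_extra_pair),
                 truth_fn = fn, truth_tvp = tvp,
                 omega = omega, sigma_res = sigma_res,
                 half_life_days = half_life_days),
            class = "cohort_design")
}

.rtruncnorm_pos <- function(n, mean, sd) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:100) {
      v <- stats::rnorm(1, mean, sd)
      if (v > 0) break
      v <- NA_real_
    }
    if (is.na(v)) stop("could not sample a positive time after 100 tries ",
                       "(pathological design: mean ", mean, ", sd ", sd, ")")
    out[i] <- v
  }
  out
}

#' Simulate a study-design cohort with known truth
#'
#' Per patient, individual parameters are drawn as \code{TVP * exp(eta)}
#' (logit-shifted for fraction parameters) with \code{eta ~ N(0, omega^2)};
#' observation times come from truncated normals around the nominal
#' schedule; observations are \code{f(t; P_i) * exp(eps)} with
#' \code{eps ~ N(0, sigma_res^2)}.
#'
#' @param design a \code{\link{cohort_design}}.
#' @param seed integer seed; the cohort is bit-identical given it.
#' @return A \code{\link{ta_cohort}} carrying a \code{"truth"} attribute:
#'   the design, per-patient natural-scale parameters, eta draws and exact
#'   per-patient TIAs (horizon 1e5 min).
#' @examples
#' coh <- simulate_cohort(seed = 1)
#' nrow(coh)  # 46
#' @export
simulate_cohort <- function(design = cohort_design(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  fn <- design$truth_fn
  decay <- decay_constants(design$half_life_days)
  tvp_t <- .transform_params(fn, design$truth_tvp)
  n <- design$n_patients
  ids <- sprintf("P%02d", seq_len(n))
  om <- rep_len(design$omega, fn$n_shape)  # per-parameter SD, recycled
  eta <- matrix(stats::rnorm(n * fn$n_shape), n, fn$n_shape,
                dimnames = list(ids, fn$params)) *
    rep(om, each = n)
  pmat <- t(apply(eta, 1L, function(e) .untransform_params(fn, tvp_t + e)))
  colnames(pmat) <- fn$params
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t_h <- .rtruncnorm_pos(length(design$schedule_h), design$schedule_h,
                           design$schedule_sd_h)
    if (i == 1L && length(design$extra_single_h))
      t_h <- c(t_h, design$extra_single_h)
    if (i >= 2L && i <= 1L + design$n_extra_pair)
      t_h <- c(t_h, .rtruncnorm_pos(length(design$extra_pair_h),
                                    design$extra_pair_h,
                                    design$extra_pair_sd_h))
    t_min <- sort(t_h) * 60
    f <- soe_eval(fn, pmat[i, ], t_min, decay, check = FALSE)
    y <- f * exp(stats::rnorm(length(t_min), 0, design$sigma_res))
    rows[[i]] <- data.frame(patient_id = ids[i], time = t_min, activity = y)
  }
  coh <- ta_cohort(do.call(rbind, rows), time_unit = "min")
  tia_true <- vapply(seq_len(n), function(i)
    soe_tia(fn, pmat[i, ], decay, 1e5, check = FALSE), 0)
  names(tia_true) <- ids
  attr(coh, "truth") <- list(design = design, fn = fn,
                             tvp = design$truth_tvp, eta = eta,
                             params = pmat, tia = tia_true, seed = seed,
                             decay = decay)
  coh
}

#' Exact per-patient TIA of the simulated truth
#'
#' @param truth the \code{"truth"} attribute of a
#'   \code{\link{simulate_cohort}} cohort (or the cohort itself).
#' @param t_end integration horizon in minutes.
#' @return Named per-patient TIA vector at the true individual parameters.
#' @export
truth_tia <- function(truth, t_end = 1e5) {
  if (inherits(truth, "ta_cohort")) truth <- attr(truth, "truth")
  if (is.null(truth)) stop("no truth record: not a simulated cohort")
  vapply(stats::setNames(rownames(truth$params), rownames(truth$params)),
         function(id) soe_tia(truth$fn, truth$params[id, ], truth$decay,
                              t_end, check = FALSE), 0)
}
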