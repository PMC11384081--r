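# Frequency-based (Saltelli-style) parameter sampling through log-normal
# marginals, used to attach standard deviations to the IBMS and SP-PBMS
# per-patient TIAs.

#' Log-normal moments from natural-scale mean and SD
#'
#' Moment matching: \code{mu_log = 2 ln m - 0.5 ln(m^2 + s^2)} and
#' \code{sigma_log = sqrt(ln(m^2 + s^2) - 2 ln m)}, so that
#' LogNormal(mu_log, sigma_log) has mean \code{m} and SD \code{s}.
#'
#' @param mean_normal natural-scale mean (> 0).
#' @param sd_normal natural-scale SD (>= 0).
#' @return List of class \code{"lognormal_moments"} with \code{mu_log} and
#'   \code{sigma_log}.
#' @examples
#' normal_to_lognormal(2, 1)
#' @export
normal_to_lognormal <- function(mean_normal, sd_normal) {
  if (!is.finite(mean_normal) || mean_normal <= 0)
    stop("'mean_normal' must be a positive finite number")
  if (!is.finite(sd_normal) || sd_normal < 0)
    stop("'sd_normal' must be a non-negative finite number")
  m2 <- mean_normal^2
  mu <- 2 * log(mean_normal) - 0.5 * log(m2 + sd_normal^2)
  s2 <- log(m2 + sd_normal^2) - 2 * log(mean_normal)
  structure(list(mu_log = mu, sigma_log = sqrt(max(s2, 0))),
            class = "lognormal_moments")
}

#' Frequency-based sampler settings
#'
#' The deterministic sinusoidal sampler
#' \code{X(s) = 1/2 + arcsin(sin(omega s + phi)) / pi} evaluated on an even
#' grid of \code{n_evals} points over \code{s} in (-pi/2, pi/2), with one
#' random phase \code{phi} per parameter. Defaults are frequency 1028 and
#' 8193 evaluations.
#'
#' @param omega integer frequency shared by all parameters.
#' @param n_evals number of model evaluations (grid points).
#' @param seed seed for the uniform phase draws.
#' @return List of class \code{"frequency_sampler"}.
#' @export
frequency_sampler <- function(omega = 1028L, n_evals = 8193L, seed = 1L) {
  stopifnot(omega >= 1, n_evals >= 1)
  structure(list(omega = as.integer(omega), n_evals = as.integer(n_evals),
                 seed = as.integer(seed)),
            class = "frequency_sampler")
}

#' Draw frequency-based samples in [0, 1]
#'
#' @param sampler a \code{\link{frequency_sampler}}.
#' @param n_params number of parameters (columns).
#' @return \code{n_evals x n_params} matrix of values in [0, 1];
#'   deterministic given the sampler's seed.
#' @examples
#' x <- frequency_sample(frequency_sampler(seed = 2), 3)
#' dim(x); range(x)
#' @export
frequency_sample <- function(sampler, n_params) {
  stopifnot(inherits(sampler, "frequency_sampler"), n_params >= 1)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(sampler$seed)
  phi <- stats::runif(n_params, 0, 2 * pi)
  n <- sampler$n_evals
  # midpoint grid: n points strictly inside (-pi/2, pi/2); includes s = 0
  # when n is odd
  s <- -pi / 2 + pi * (seq_len(n) - 0.5) / n
  X <- matrix(0, n, n_params)
  for (k in seq_len(n_params))
    X[, k] <- 0.5 + asin(sin(sampler$omega * s + phi[k])) / pi
  X
}

#' Frequency-sampled mean and SD of per-patient TIAs
#'
#' For each patient of an IBMS or SP-PBMS fit, pushes the [0, 1] frequency
#' samples through log-normal quantile functions whose moments match each
#' fitted parameter's estimate and SD (from the WLS covariance), evaluates
#' the closed-form TIA per sample, and reports the sample mean and SD.
#' Parameters with zero/non-finite estimate or SD are held fixed (with a
#' warning for non-positive means); fraction parameters are clipped into
#' [0, 1].
#'
#' @param fit an \code{\link{fit_ibms}} or \code{\link{fit_sp_pbms}} result.
#' @param sampler a \code{\link{frequency_sampler}}.
#' @param t_end integration horizon in minutes.
#' @return data.frame with one row per patient: \code{patient_id},
#'   \code{tia} (point estimate), \code{tia_mean}, \code{tia_sd}.
#' @export
tia_sd <- function(fit, sampler = frequency_sampler(), t_end = 1e5) {
  if (!inherits(fit, c("ibms_fit", "sp_pbms_fit")))
    stop("'fit' must be an IBMS or SP-PBMS fit")
  fn <- fit$fn
  ids <- names(fit$fits)
  U <- frequency_sample(sampler, fn$n_shape)
  out <- data.frame(patient_id = ids, tia = NA_real_, tia_mean = NA_real_,
                    tia_sd = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    f <- fit$fits[[ids[i]]]
    pmat <- matrix(rep(f$params, each = nrow(U)), nrow(U), fn$n_shape,
                   dimnames = list(NULL, fn$params))
    for (k in seq_len(fn$n_shape)) {
      m <- f$params[k]
      s <- f$param_sd[k]
      if (!is.finite(s) || s == 0) next
      if (!is.finite(m) || m <= 0) {
        warning("parameter ", fn$params[k], " of patient ", ids[i],
                " has non-positive mean; held fixed in sampling")
        next
      }
      lm <- normal_to_lognormal(m, s)
      draws <- stats::qlnorm(pmin(pmax(U[, k], 1e-12), 1 - 1e-12),
                             lm$mu_log, lm$sigma_log)
      if (fn$type[k] == "frac") draws <- pmin(draws, 1 - 1e-9)
      pmat[, k] <- draws
    }
    tias <- .soe_tia_matrix(fn, pmat, fit$decay, t_end)
    out$tia[i] <- soe_tia(fn, f$params, fit$decay, t_end, check = FALSE)
    out$tia_mean[i] <- mean(tias)
    out$tia_sd[i] <- stats::sd(tias)
  }
  out
}
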