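#' Physical decay constants for the radionuclide
#'
#' Builds the physical-decay description used throughout the package. All
#' internal kinetics are expressed in minutes; the physical decay constant is
#' \code{ln(2)/T1/2} converted from days. The default half-life is that of
#' Lu-177 (6.6443 d).
#'
#' @param half_life_days physical half-life in days (> 0).
#' @return An object of class \code{"decay_constants"} with elements
#'   \code{half_life_days} and \code{lambda_phys} (per minute).
#' @examples
#' dk <- decay_constants()
#' dk$lambda_phys  # about 7.245e-5 / min
#' @export
decay_constants <- function(half_life_days = 6.6443) {
  if (!is.numeric(half_life_days) || length(half_life_days) != 1L ||
      !is.finite(half_life_days) || half_life_days <= 0)
    stop("'half_life_days' must be a single positive number")
  structure(list(half_life_days = half_life_days,
                 lambda_phys = log(2) / (half_life_days * 1440)),
            class = "decay_constants")
}

#' @export
print.decay_constants <- function(x, ...) {
  cat(sprintf("Physical decay: T1/2 = %.4f d, lambda_phys = %.6e /min\n",
              x$half_life_days, x$lambda_phys))
  invisible(x)
}

# Registry of the eleven candidate sum-of-exponential functions.
# 'params' gives the shape-parameter order used everywhere (C++ included);
# 'type' is "pos" (A's and lambdas, >= 0) or "frac" (alpha in [0, 1]).
.soe_registry <- local({
  def <- function(params, type) list(params = params, type = type)
  list(
    f2a = def(c("A1", "lambda1"), c("pos", "pos")),
    f3a = def(c("A1", "A2", "lambda1"), c("pos", "pos", "pos")),
    f3b = def(c("A1", "alpha", "lambda1"), c("pos", "frac", "pos")),
    f3c = def(c("A1", "alpha", "lambda1"), c("pos", "frac", "pos")),
    f4a = def(c("A1", "A2", "lambda1", "lambda2"), c("pos", "pos", "pos", "pos")),
    f4b = def(c("A1", "alpha", "lambda1", "lambda2"),
              c("pos", "frac", "pos", "pos")),
    f5a = def(c("A1", "A2", "A3", "lambda1", "lambda2"),
              c("pos", "pos", "pos", "pos", "pos")),
    f5b = def(c("A1", "A2", "lambda1", "lambda2", "lambda3"),
              c("pos", "pos", "pos", "pos", "pos")),
    f5c = def(c("A1", "A2", "A3", "lambda1", "lambda2"),
              c("pos", "pos", "pos", "pos", "pos")),
    f6a = def(c("A1", "A2", "A3", "lambda1", "lambda2", "lambda3"),
              c("pos", "pos", "pos", "pos", "pos", "pos")),
    f6b = def(c("A1", "A2", "A3", "lambda1", "lambda2", "lambda3"),
              c("pos", "pos", "pos", "pos", "pos", "pos"))
  )
})

#' Names of the candidate sum-of-exponential functions
#'
#' @return Character vector of the eleven registered function names.
#' @export
soe_functions <- function() names(.soe_registry)

#' A candidate sum-of-exponential kinetic function
#'
#' The candidate set comprises mono-, bi- and tri-exponential
#' parameterisations of the activity-time curve. Every biological rate
#' carries the physical decay constant additively, and some functions have
#' terms decaying with the physical rate alone. The digit in a function name
#' is its number of adjustable shape parameters (e.g. \code{f3a}: A1, A2,
#' lambda1).
#'
#' @param name one of the names returned by \code{\link{soe_functions}}.
#' @return An object of class \code{"soe_function"}: name, shape-parameter
#'   names, parameter types and count.
#' @examples
#' fn <- soe_function("f3a")
#' fn$params
#' @export
soe_function <- function(name) {
  if (inherits(name, "soe_function")) return(name)
  if (!is.character(name) || length(name) != 1L || is.na(name))
    stop("'name' must be a single function name")
  entry <- .soe_registry[[name]]
  if (is.null(entry))
    stop(sprintf("unknown function '%s'; known: %s", name,
                 paste(soe_functions(), collapse = ", ")))
  structure(list(name = name, params = entry$params, type = entry$type,
                 n_shape = length(entry$params),
                 id = match(name, soe_functions()) - 1L),
            class = "soe_function")
}

#' @export
print.soe_function <- function(x, ...) {
  cat(sprintf("SOE function %s: %d shape parameters (%s)\n",
              x$name, x$n_shape, paste(x$params, collapse = ", ")))
  invisible(x)
}

.as_param_vector <- function(fn, params) {
  fn <- soe_function(fn)
  p <- unlist(params, use.names = TRUE)
  if (!is.null(names(p)) && all(nzchar(names(p)))) {
    miss <- setdiff(fn$params, names(p))
    if (length(miss))
      stop(sprintf("missing parameter(s) for %s: %s", fn$name,
                   paste(miss, collapse = ", ")))
    p <- p[fn$params]
  } else if (length(p) == fn$n_shape) {
    names(p) <- fn$params
  } else {
    stop(sprintf("%s expects %d parameters (%s), got %d", fn$name,
                 fn$n_shape, paste(fn$params, collapse = ", "), length(p)))
  }
  storage.mode(p) <- "double"
  p
}

#' Validate shape parameters against a function's constraints
#'
#' Pre-factors and biological decay constants must be non-negative; fraction
#' parameters (alpha) must lie in [0, 1].
#'
#' @param fn function name or \code{\link{soe_function}} object.
#' @param params named (or correctly ordered) numeric parameter vector.
#' @return Character vector of violation messages; empty when all constraints
#'   hold.
#' @examples
#' soe_validate(soe_function("f3a"), c(A1 = 1, A2 = 1, lambda1 = -0.1))
#' @export
soe_validate <- function(fn, params) {
  fn <- soe_function(fn)
  p <- .as_param_vector(fn, params)
  bad <- character(0)
  for (k in seq_len(fn$n_shape)) {
    nm <- fn$params[k]
    v <- p[[k]]
    if (!is.finite(v)) {
      bad <- c(bad, sprintf("%s is not finite", nm))
    } else if (fn$type[k] == "pos" && v < 0) {
      bad <- c(bad, sprintf("%s = %g violates %s >= 0", nm, v, nm))
    } else if (fn$type[k] == "frac" && (v < 0 || v > 1)) {
      bad <- c(bad, sprintf("%s = %g violates 0 <= %s <= 1", nm, v, nm))
    }
  }
  bad
}

.soe_check <- function(fn, params) {
  bad <- soe_validate(fn, params)
  if (length(bad)) stop(paste(bad, collapse = "; "))
  invisible(TRUE)
}

#' Term expansion of a sum-of-exponential function
#'
#' Expands a candidate function at given shape parameters into signed
#' exponential terms \code{sum(coef * exp(-rate * t))}, with the physical
#' decay constant folded into every rate.
#'
#' @inheritParams soe_validate
#' @param decay a \code{\link{decay_constants}} object.
#' @return List with numeric vectors \code{coef} and \code{rate} (per minute).
#' @export
soe_terms <- function(fn, params, decay = decay_constants()) {
  fn <- soe_function(fn)
  p <- .as_param_vector(fn, params)
  lp <- decay$lambda_phys
  a <- function(i) p[[i]]
  switch(fn$name,
    f2a = list(coef = a(1), rate = a(2) + lp),
    f3a = list(coef = c(a(1), a(2)), rate = c(a(3) + lp, lp)),
    f3b = list(coef = c(a(1) * a(2), a(1) * (1 - a(2))),
               rate = c(a(3) + lp, lp)),
    f3c = list(coef = c(a(1) * (1 - a(2)), a(1) * a(2)),
               rate = c(a(3) + lp, lp)),
    f4a = list(coef = c(a(1), a(2)), rate = c(a(3) + lp, a(4) + lp)),
    f4b = list(coef = c(a(1) * a(2), a(1) * (1 - a(2))),
               rate = c(a(3) + lp, a(4) + lp)),
    f5a = list(coef = c(a(1), a(2), -a(3)),
               rate = c(a(4) + lp, a(5) + lp, lp)),
    f5b = list(coef = c(a(1), a(2), -(a(1) + a(2))),
               rate = c(a(3) + lp, a(4) + lp, a(5) + lp)),
    f5c = list(coef = c(a(1), a(2), a(3)),
               rate = c(a(4) + lp, a(5) + lp, lp)),
    f6a = list(coef = c(a(1), a(2), -a(3)),
               rate = c(a(4) + lp, a(5) + lp, a(6) + lp)),
    f6b = list(coef = c(a(1), a(2), a(3)),
               rate = c(a(4) + lp, a(5) + lp, a(6) + lp)))
}

#' Evaluate a sum-of-exponential function
#'
#' @inheritParams soe_terms
#' @param t numeric vector of times in minutes, all >= 0.
#' @param check validate parameter constraints first (default TRUE).
#' @return Numeric vector of activity fractions, same length as \code{t}.
#' @examples
#' dk <- decay_constants()
#' soe_eval("f2a", c(A1 = 1, lambda1 = 0.001), t = 1000, decay = dk)
#' @export
soe_eval <- function(fn, params, t, decay = decay_constants(), check = TRUE) {
  if (check) .soe_check(fn, params)
  if (any(t < 0)) stop("all times must be >= 0")
  tm <- soe_terms(fn, params, decay)
  drop(exp(outer(t, tm$rate, function(tt, mu) -mu * tt)) %*% tm$coef)
}

#' Closed-form time-integrated activity of a candidate function
#'
#' Integrates the activity curve termwise from 0 to \code{t_end}:
#' \code{sum(coef * (1 - exp(-rate * t_end)) / rate)}, with a term of zero
#' total rate contributing \code{coef * t_end}. \code{t_end = Inf} gives the
#' infinite-horizon integral \code{sum(coef / rate)}.
#'
#' @inheritParams soe_eval
#' @param t_end upper integration limit in minutes (default 1e5 min).
#' @return Time-integrated activity in minutes (activity is a fraction of the
#'   injected activity, so this is the TIA per unit injected activity).
#' @examples
#' soe_tia("f2a", c(A1 = 1, lambda1 = 0.001))
#' @export
soe_tia <- function(fn, params, decay = decay_constants(), t_end = 1e5,
                    check = TRUE) {
  if (check) .soe_check(fn, params)
  if (length(t_end) != 1L || is.na(t_end) || t_end <= 0)
    stop("'t_end' must be a single positive time (minutes), possibly Inf")
  tm <- soe_terms(fn, params, decay)
  zero <- tm$rate == 0
  out <- numeric(length(tm$rate))
  if (is.infinite(t_end)) {
    if (any(zero)) stop("infinite-horizon TIA undefined for a zero-rate term")
    out <- tm$coef / tm$rate
  } else {
    # -expm1 avoids cancellation when rate * t_end is tiny
    out[!zero] <- tm$coef[!zero] *
      (-expm1(-tm$rate[!zero] * t_end)) / tm$rate[!zero]
    out[zero] <- tm$coef[zero] * t_end
  }
  sum(out)
}

# TIA for a matrix of parameter draws (rows = draws, columns = shape params);
# vectorised for the frequency-sampling uncertainty propagation.
.soe_tia_matrix <- function(fn, pmat, decay = decay_constants(), t_end = 1e5) {
  fn <- soe_function(fn)
  apply(pmat, 1L, function(p) soe_tia(fn, p, decay, t_end, check = FALSE))
}
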