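# Population-based model selection: goodness gate, small-sample AIC,
# Akaike weights, model averaging and leave-one-out stability.

#' Small-sample corrected AIC
#'
#' \code{AICc = -2 log P + 2K + 2K(K+1)/(N-K-1)}, the AIC with the
#' correction recommended when \code{N/K < 40}.
#'
#' @param neg2lnP minimised -2 log likelihood.
#' @param K total number of estimated parameters.
#' @param N total number of observations.
#' @return The AICc value.
#' @seealso \code{\link{aicc_penalty}}, \code{\link{akaike_weights}}
#' @export
aicc <- function(neg2lnP, K, N) {
  if (any(N - K - 1 <= 0))
    stop("AICc undefined for N - K - 1 <= 0 (K = ", K, ", N = ", N,
         "); such a function must be excluded from scoring")
  neg2lnP + aicc_penalty(K, N)
}

#' AICc penalty term
#'
#' The parameter-count part of the AICc: \code{2K + 2K(K+1)/(N-K-1)}.
#'
#' @inheritParams aicc
#' @return The penalty value.
#' @examples
#' aicc_penalty(7, 46)   # about 16.95
#' aicc_penalty(27, 46)  # exactly 138
#' @export
aicc_penalty <- function(K, N) {
  if (any(N - K - 1 <= 0)) stop("penalty undefined for N - K - 1 <= 0")
  2 * K + 2 * K * (K + 1) / (N - K - 1)
}

#' Bayesian Information Criterion
#'
#' Standard form \code{-2 log P + K log N}; provided as a convenience
#' cross-check on the AICc ranking.
#'
#' @inheritParams aicc
#' @return The BIC value.
#' @export
bic <- function(neg2lnP, K, N) {
  stopifnot(N >= 1)
  neg2lnP + K * log(N)
}

#' Akaike weights
#'
#' Evidence weights \code{w_i = exp(-Delta_i/2) / sum(exp(-Delta_j/2))} with
#' \code{Delta_i = AICc_i - min(AICc)}; computed through log-sum-exp so that
#' differences of hundreds of AICc units do not underflow.
#'
#' @param aicc_values numeric vector of AICc values (all finite).
#' @return Numeric vector of weights in [0, 1] summing to 1.
#' @examples
#' akaike_weights(c(100, 100))        # 0.5, 0.5
#' akaike_weights(c(0, 108.947, 121.053))
#' @export
akaike_weights <- function(aicc_values) {
  if (!length(aicc_values)) stop("empty AICc vector")
  if (any(!is.finite(aicc_values)))
    stop("non-finite AICc; exclude such functions before weighting")
  d <- aicc_values - min(aicc_values)
  lw <- -d / 2
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Goodness-of-fit gate
#'
#' A candidate passes when its fit converged and the maximum CV of its fixed
#' effects is finite and below the threshold (default 0.5). Non-finite CVs
#' (singular information matrix) fail.
#'
#' @param fits list of \code{\link{soe_nlme}} fits.
#' @param cv_threshold gate threshold on the maximum CV.
#' @return Logical vector (named by function when fits are named) with a
#'   \code{"reason"} attribute describing each failure.
#' @export
goodness_gate <- function(fits, cv_threshold = 0.5) {
  pass <- logical(length(fits))
  reason <- character(length(fits))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    mx <- cv_fixed_effects(f)$max_cv
    if (!isTRUE(f$converged)) {
      reason[i] <- "fit did not converge"
    } else if (!is.finite(mx)) {
      reason[i] <- "CV not finite (singular information matrix)"
    } else if (mx >= cv_threshold) {
      reason[i] <- sprintf("max CV %.2f >= %.2f", mx, cv_threshold)
    } else {
      pass[i] <- TRUE
      reason[i] <- ""
    }
  }
  names(pass) <- names(fits)
  attr(pass, "reason") <- reason
  pass
}

#' Population-based model selection across candidate functions
#'
#' Fits every candidate function to the cohort with \code{\link{soe_nlme}},
#' applies the goodness-of-fit gate (convergence, max CV < threshold, and
#' the scoring requirement \code{K < N - 1}), computes AICc values, AICc
#' differences and Akaike weights over the gate-passing set, and per-patient
#' TIAs per function.
#'
#' @param cohort a \code{\link{ta_cohort}}.
#' @param functions character vector of candidate names (default all 11).
#' @param cv_threshold goodness gate threshold (default 0.5).
#' @param t_end TIA integration horizon in minutes.
#' @param random,decay,control passed to \code{\link{soe_nlme}}.
#' @return Object of class \code{"pbms_selection"}: \code{table} (one row
#'   per candidate: K, N, neg2ll, AICc, delta, weight, max_cv, passed,
#'   reason), \code{fits}, \code{tia} (patients x functions matrix) and the
#'   settings used.
#' @examples
#' coh <- simulate_cohort(seed = 11)
#' sel <- pbms_select(coh, c("f2a", "f3a"),
#'                    control = nlme_control(n_starts = 2))
#' sel$table
#' @export
pbms_select <- function(cohort, functions = soe_functions(),
                        cv_threshold = 0.5, t_end = 1e5, random = "all",
                        decay = decay_constants(),
                        control = nlme_control()) {
  stopifnot(inherits(cohort, "ta_cohort"))
  functions <- match.arg(functions, soe_functions(), several.ok = TRUE)
  fits <- vector("list", length(functions))
  names(fits) <- functions
  for (nm in functions) {
    fits[[nm]] <- tryCatch(
      soe_nlme(cohort, nm, random = random, decay = decay, control = control),
      error = function(e) e)
  }
  failed <- vapply(fits, inherits, TRUE, "condition")
  err_msg <- rep("", length(functions))
  err_msg[failed] <- vapply(fits[failed], conditionMessage, "")

  N <- nrow(cohort)
  K <- vapply(seq_along(fits), function(i)
    if (failed[i]) NA_integer_ else fits[[i]]$K, 0L)
  neg2ll <- vapply(seq_along(fits), function(i)
    if (failed[i]) NA_real_ else fits[[i]]$neg2ll, 0)
  max_cv <- vapply(seq_along(fits), function(i)
    if (failed[i]) NA_real_ else cv_fixed_effects(fits[[i]])$max_cv, 0)

  pass <- rep(FALSE, length(functions))
  reason <- err_msg
  ok <- !failed
  scoreable <- ok & !is.na(K) & (N - K - 1 > 0)
  reason[ok & !scoreable] <- sprintf("K = %d >= N - 1 = %d: not scoreable",
                                     K[ok & !scoreable], N - 1)
  if (any(scoreable)) {
    g <- goodness_gate(fits[scoreable], cv_threshold)
    pass[scoreable] <- g
    reason[scoreable] <- attr(g, "reason")
  }

  aicc_v <- rep(NA_real_, length(functions))
  aicc_v[scoreable] <- aicc(neg2ll[scoreable], K[scoreable], N)
  weight <- rep(0, length(functions))
  delta <- rep(NA_real_, length(functions))
  if (any(pass)) {
    delta[pass] <- aicc_v[pass] - min(aicc_v[pass])
    weight[pass] <- akaike_weights(aicc_v[pass])
  }

  tia_mat <- matrix(NA_real_, length(unique(cohort$patient_id)),
                    length(functions),
                    dimnames = list(unique(cohort$patient_id), functions))
  for (i in seq_along(fits)) if (!failed[i])
    tia_mat[, i] <- tia(fits[[i]], t_end = t_end)

  tab <- data.frame(fn = functions, K = K, N = N, neg2ll = neg2ll,
                    aicc = aicc_v, delta = delta, weight = weight,
                    max_cv = max_cv, passed = pass, reason = reason,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, tia = tia_mat,
                 cv_threshold = cv_threshold, t_end = t_end,
                 decay = decay, cohort = cohort),
            class = "pbms_selection")
}

#' Best candidate of a selection
#'
#' Highest Akaike weight among gate-passing functions; ties are broken by
#' smaller K, then by name.
#'
#' @param sel a \code{\link{pbms_select}} result.
#' @return The winning function name, or \code{NA} if nothing passed.
#' @export
best_function <- function(sel) {
  stopifnot(inherits(sel, "pbms_selection"))
  tab <- sel$table[sel$table$passed, , drop = FALSE]
  if (!nrow(tab)) return(NA_character_)
  tab <- tab[order(-tab$weight, tab$K, tab$fn), , drop = FALSE]
  tab$fn[1L]
}

#' Model-averaged per-patient TIA
#'
#' Weight-sum of per-patient TIAs over the gate-passing candidates:
#' \code{TIA_MA = sum_i w_i TIA_i} with the Akaike weights renormalised over
#' the contributing set.
#'
#' @param weights named per-function weights summing to 1 (within 1e-9).
#' @param tias patients x functions matrix of per-patient TIAs covering
#'   exactly the weighted functions.
#' @return Object of class \code{"ma_result"}: \code{tia_ma} (per patient),
#'   \code{weights}, \code{functions}.
#' @examples
#' model_average_tia(c(a = 0.5, b = 0.5),
#'                   matrix(c(100, 200), 1, 2,
#'                          dimnames = list("P1", c("a", "b"))))
#' @export
model_average_tia <- function(weights, tias) {
  if (is.null(names(weights)) || is.null(colnames(tias)))
    stop("weights and TIA columns must be named by function")
  if (!setequal(names(weights), colnames(tias)))
    stop("weights and TIA table cover different function sets")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", format(sum(weights)), ")")
  tias <- tias[, names(weights), drop = FALSE]
  tia_ma <- drop(tias %*% weights)
  structure(list(tia_ma = tia_ma, weights = weights,
                 functions = names(weights)), class = "ma_result")
}

#' @rdname model_average_tia
#' @param sel a \code{\link{pbms_select}} result (method dispatch helper).
#' @export
model_average <- function(sel) {
  stopifnot(inherits(sel, "pbms_selection"))
  tab <- sel$table
  use <- tab$passed
  if (!any(use)) stop("no gate-passing function: model averaging impossible")
  w <- stats::setNames(tab$weight[use], tab$fn[use])
  model_average_tia(w / sum(w), sel$tia[, tab$fn[use], drop = FALSE])
}

#' @export
print.ma_result <- function(x, digits = 4, ...) {
  cat("Model-averaged TIA over", length(x$functions), "functions (",
      paste(sprintf("%s:%.3f", x$functions, x$weights), collapse = " "),
      ")\n")
  print(signif(x$tia_ma, digits))
  invisible(x)
}

#' Leave-one-patient-out selection stability (Jackknife)
#'
#' Repeats the fit + gate + Akaike-weight pipeline once per left-out
#' patient and summarises each candidate's weight across the replicates,
#' plus how often each candidate ranked first.
#'
#' @inheritParams pbms_select
#' @return Object of class \code{"pbms_jackknife"}: \code{weights}
#'   (replicates x functions matrix), \code{summary} (per function: mean,
#'   sd, median, min, max weight and first-rank count), \code{n_replicates},
#'   \code{failed} (labels of replicates whose pipeline failed, excluded
#'   with a warning).
#' @export
pbms_jackknife <- function(cohort, functions = soe_functions(),
                           cv_threshold = 0.5, t_end = 1e5, random = "all",
                           decay = decay_constants(),
                           control = nlme_control()) {
  stopifnot(inherits(cohort, "ta_cohort"))
  ids <- unique(cohort$patient_id)
  if (length(ids) < 3L) stop("Jackknife needs at least 3 patients")
  wmat <- matrix(NA_real_, length(ids), length(functions),
                 dimnames = list(ids, functions))
  firsts <- stats::setNames(integer(length(functions)), functions)
  failed <- character(0)
  for (i in seq_along(ids)) {
    sub <- cohort[cohort$patient_id != ids[i], , drop = FALSE]
    class(sub) <- class(cohort)
    sel <- tryCatch(
      pbms_select(sub, functions, cv_threshold, t_end, random, decay,
                  control),
      error = function(e) e)
    if (inherits(sel, "condition") || !any(sel$table$passed)) {
      failed <- c(failed, ids[i])
      next
    }
    wmat[i, sel$table$fn] <- sel$table$weight
    bf <- best_function(sel)
    firsts[bf] <- firsts[bf] + 1L
  }
  if (length(failed))
    warning("Jackknife replicate(s) excluded (pipeline failure): ",
            paste(failed, collapse = ", "))
  keep <- !(rownames(wmat) %in% failed)
  ws <- wmat[keep, , drop = FALSE]
  smry <- data.frame(
    fn = functions,
    mean = colMeans(ws), sd = apply(ws, 2, stats::sd),
    median = apply(ws, 2, stats::median),
    min = apply(ws, 2, min), max = apply(ws, 2, max),
    n_first = as.integer(firsts[functions]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(weights = wmat, summary = smry,
                 n_replicates = sum(keep), failed = failed),
            class = "pbms_jackknife")
}

#' @export
print.pbms_jackknife <- function(x, digits = 3, ...) {
  cat(sprintf("Jackknife over %d leave-one-out replicates\n",
              x$n_replicates))
  tab <- x$summary
  tab[-1] <- lapply(tab[-1], function(v)
    if (is.double(v)) signif(v, digits) else v)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
print.pbms_selection <- function(x, digits = 4, ...) {
  tab <- x$table
  cat(sprintf("Population-based model selection: N = %d, gate CV < %.2f\n",
              tab$N[1L], x$cv_threshold))
  show <- data.frame(fn = tab$fn, K = tab$K,
                     neg2ll = round(tab$neg2ll, 2),
                     AICc = round(tab$aicc, 2),
                     delta = round(tab$delta, 2),
                     weight_pct = round(100 * tab$weight, 2),
                     max_CV = signif(tab$max_cv, 3),
                     passed = ifelse(tab$passed, "yes", "-"))
  print(show, row.names = FALSE)
  bf <- best_function(x)
  if (!is.na(bf)) cat("Best supported function:", bf, "\n")
  invisible(x)
}

#' @export
summary.pbms_selection <- function(object, ...) {
  print(object, ...)
  invisible(object$table)
}

#' @export
plot.pbms_selection <- function(x, ...) {
  tab <- x$table[x$table$passed, , drop = FALSE]
  if (!nrow(tab)) {
    warning("nothing passed the gate; no weights to plot")
    return(invisible(x))
  }
  graphics::barplot(100 * tab$weight, names.arg = tab$fn,
                    ylab = "Akaike weight (%)",
                    main = "Gate-passing candidate functions", ...)
  invisible(x)
}
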