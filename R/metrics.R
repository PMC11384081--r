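# Accuracy metrics: relative deviations against the model-averaged
# reference TIAs and their root-mean-square error over patients.

#' Per-patient relative deviation from the reference TIA
#'
#' \code{RD = (TIA_j - TIA_MA) / TIA_MA}, in percent.
#'
#' @param tia_j per-patient TIAs of the method under comparison (named).
#' @param tia_ma per-patient reference (model-averaged) TIAs, same patients.
#' @return Numeric vector of RDs in percent.
#' @examples
#' relative_deviation(c(P1 = 110), c(P1 = 100))  # +10
#' @export
relative_deviation <- function(tia_j, tia_ma) {
  if (length(tia_j) != length(tia_ma))
    stop("TIA vectors must cover the same patients")
  if (!is.null(names(tia_j)) && !is.null(names(tia_ma))) {
    if (!setequal(names(tia_j), names(tia_ma)))
      stop("TIA vectors must cover the same patients")
    tia_j <- tia_j[names(tia_ma)]
  }
  if (any(tia_ma == 0)) stop("reference TIA of 0: RD undefined")
  100 * (tia_j - tia_ma) / tia_ma
}

#' Root-mean-square error of relative deviations
#'
#' \code{RMSE = sqrt(SD(RD)^2 + mean(RD)^2)}. With the sample SD (n-1
#' denominator, the default) this slightly exceeds \code{sqrt(mean(RD^2))};
#' with the population (n) denominator the two coincide exactly.
#'
#' @param rd numeric vector of per-patient RDs (>= 2 values).
#' @param denominator \code{"sample"} (n-1, default) or \code{"population"}
#'   (n).
#' @return The RMSE (same units as \code{rd}, conventionally percent).
#' @examples
#' rmse_rd(c(3, 4))  # 3.5707
#' @export
rmse_rd <- function(rd, denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  n <- length(rd)
  if (n < 2L) stop("RMSE needs at least 2 values")
  m <- mean(rd)
  v <- stats::var(rd)
  if (denominator == "population") v <- v * (n - 1) / n
  sqrt(v + m^2)
}

#' Method-comparison TIA report
#'
#' Assembles the per-patient TIAs of several methods against the
#' model-averaged reference: RD per patient and method, and per-method
#' summaries (mean (SD), median [min, max] of the RDs, and their RMSE).
#'
#' @param tias named list of per-patient TIA vectors, one entry per method.
#' @param tia_ma per-patient reference (model-averaged) TIAs.
#' @param denominator passed to \code{\link{rmse_rd}}.
#' @return Object of class \code{"tia_report"}: \code{tia} (patients x
#'   methods, reference included as \code{"MA"}), \code{rd} (percent),
#'   \code{summary} (per method: mean_rd, sd_rd, median_rd, min_rd, max_rd,
#'   rmse), \code{denominator}.
#' @export
tia_report <- function(tias, tia_ma, denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  stopifnot(is.list(tias), length(tias) >= 1, !is.null(names(tias)))
  ids <- names(tia_ma)
  rd <- vapply(tias, relative_deviation, numeric(length(tia_ma)),
               tia_ma = tia_ma)
  if (is.matrix(rd)) rownames(rd) <- ids
  smry <- data.frame(
    method = names(tias),
    mean_rd = apply(rd, 2, mean),
    sd_rd = apply(rd, 2, stats::sd),
    median_rd = apply(rd, 2, stats::median),
    min_rd = apply(rd, 2, min),
    max_rd = apply(rd, 2, max),
    rmse = apply(rd, 2, rmse_rd, denominator = denominator),
    row.names = NULL, stringsAsFactors = FALSE)
  tia_tab <- cbind(do.call(cbind, tias), MA = tia_ma)
  structure(list(tia = tia_tab, rd = rd, summary = smry,
                 denominator = denominator),
            class = "tia_report")
}

#' @export
print.tia_report <- function(x, digits = 3, ...) {
  cat("TIA comparison against the model-averaged reference",
      sprintf("(RD in %%, %s-SD RMSE)\n", x$denominator))
  tab <- x$summary
  show <- data.frame(method = tab$method,
                     `mean (SD)` = sprintf("%.1f (%.1f)", tab$mean_rd,
                                           tab$sd_rd),
                     `median [min, max]` = sprintf("%.1f [%.1f, %.1f]",
                                                   tab$median_rd, tab$min_rd,
                                                   tab$max_rd),
                     RMSE = round(tab$rmse, 1), check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}
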