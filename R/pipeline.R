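# End-to-end orchestration: simulate or load a cohort, fit the candidate
# set, gate + select + model-average, run the baseline methods, propagate
# uncertainties and emit delimited reports plus a machine-readable summary.

#' Run configuration
#'
#' Builds (and validates) the configuration consumed by
#' \code{\link{run_pipeline}}. Every entry has a default; \code{input} may
#' be a cohort file path or NULL to simulate the default study design.
#'
#' @param input cohort file path (delimited text) or NULL to simulate.
#' @param time_unit unit of the input time column.
#' @param functions candidate function names, or \code{"all"}.
#' @param half_life_days physical half-life in days.
#' @param t_end TIA integration horizon (minutes).
#' @param cv_threshold goodness-gate threshold.
#' @param seed master seed (simulation, multi-start jitter, sampler phases).
#' @param n_starts multi-start count for the population fits.
#' @param methods character subset of
#'   \code{c("nlme-pbms", "ibms", "sp-pbms", "ma", "tia-sd", "jackknife")}.
#' @param ibms_fn,sp_fn,sp_shared,sp_shared_value baseline settings; the
#'   default SP-PBMS evaluation fixes alpha = 0.9632.
#' @param out_dir output directory for the report files.
#' @return List of class \code{"run_config"}.
#' @export
run_config <- function(input = NULL, time_unit = "min",
                       functions = c("f2a", "f3a", "f3b", "f3c", "f4a"),
                       half_life_days = 6.6443, t_end = 1e5,
                       cv_threshold = 0.5, seed = 1L, n_starts = 5L,
                       methods = c("nlme-pbms", "ibms", "sp-pbms", "ma"),
                       ibms_fn = "f2a", sp_fn = "f3b", sp_shared = "alpha",
                       sp_shared_value = 0.9632, out_dir = tempdir()) {
  if (identical(functions, "all")) functions <- soe_functions()
  stopifnot(all(functions %in% soe_functions()),
            half_life_days > 0, t_end > 0)
  known <- c("nlme-pbms", "ibms", "sp-pbms", "ma", "tia-sd", "jackknife")
  if (!all(methods %in% known))
    stop("unknown method(s): ", paste(setdiff(methods, known),
                                      collapse = ", "))
  structure(list(input = input, time_unit = time_unit,
                 functions = functions, half_life_days = half_life_days,
                 t_end = t_end, cv_threshold = cv_threshold,
                 seed = as.integer(seed), n_starts = as.integer(n_starts),
                 methods = methods, ibms_fn = ibms_fn, sp_fn = sp_fn,
                 sp_shared = sp_shared, sp_shared_value = sp_shared_value,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the
#' \code{\link{run_config}} defaults.
#'
#' @param path YAML file path.
#' @return A \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  extra <- setdiff(names(cfg), allowed)
  if (length(extra)) stop("unknown config key(s): ",
                          paste(extra, collapse = ", "))
  do.call(run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order: cohort (load or simulate),
#' population fits + selection, model averaging, baselines, TIA
#' uncertainty, Jackknife, method comparison. Writes \code{selection.tsv},
#' \code{tia.tsv}, \code{jackknife.tsv} (when enabled), a structured
#' \code{summary.json} and a \code{run.log} recording seeds and settings to
#' \code{config$out_dir}.
#'
#' @param config a \code{\link{run_config}}.
#' @return Invisibly, a list with the stage results (\code{cohort},
#'   \code{selection}, \code{ma}, \code{ibms}, \code{sp}, \code{report},
#'   \code{jackknife}, \code{files}).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out_dir, "run.log")
  logmsg <- function(...) cat(sprintf("[%s] %s\n",
                                      format(Sys.time(), "%H:%M:%S"),
                                      sprintf(...)),
                              file = logfile, append = TRUE)
  cat("", file = logfile)
  fingerprint <- substr(paste(
    vapply(config[setdiff(names(config), "out_dir")],
           function(v) paste(format(v), collapse = ","), "")
    , collapse = "|"), 1, 400)
  logmsg("config: %s", fingerprint)
  decay <- decay_constants(config$half_life_days)
  ctl <- nlme_control(n_starts = config$n_starts, seed = config$seed)

  cohort <- if (is.null(config$input)) {
    logmsg("stage simulate: default study design, seed %d", config$seed)
    simulate_cohort(seed = config$seed)
  } else {
    logmsg("stage load: %s (unit %s)", config$input, config$time_unit)
    read_cohort(config$input, config$time_unit)
  }
  files <- character(0)
  sel <- ma <- ib <- sp <- jk <- report <- NULL

  if ("nlme-pbms" %in% config$methods) {
    logmsg("stage select: %d candidates, %d starts each",
           length(config$functions), config$n_starts)
    sel <- pbms_select(cohort, config$functions, config$cv_threshold,
                       config$t_end, decay = decay, control = ctl)
    f <- file.path(config$out_dir, "selection.tsv")
    utils::write.table(sel$table, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
    if (!any(sel$table$passed))
      stop("selection stage: no candidate passed the goodness gate; ",
           "cannot model-average or compare")
    if ("ma" %in% config$methods) ma <- model_average(sel)
  }
  if ("ibms" %in% config$methods) {
    logmsg("stage ibms: %s", config$ibms_fn)
    ib <- fit_ibms(cohort, config$ibms_fn, decay = decay,
                   seed = config$seed)
  }
  if ("sp-pbms" %in% config$methods) {
    logmsg("stage sp-pbms: %s shared %s = %s", config$sp_fn,
           config$sp_shared, format(config$sp_shared_value))
    sp <- fit_sp_pbms(cohort, config$sp_fn, config$sp_shared,
                      config$sp_shared_value, decay = decay,
                      seed = config$seed)
  }

  tia_tab <- NULL
  if (!is.null(ma)) {
    methods_tia <- list()
    if (!is.null(sel)) {
      bf <- best_function(sel)
      methods_tia[[paste0("NLME-PBMS (", bf, ")")]] <-
        sel$tia[names(ma$tia_ma), bf]
    }
    if (!is.null(ib) && length(ib$fits) == length(ma$tia_ma))
      methods_tia[["IBMS"]] <- tia(ib, config$t_end)[names(ma$tia_ma)]
    if (!is.null(sp))
      methods_tia[["SP-PBMS"]] <- tia(sp, config$t_end)[names(ma$tia_ma)]
    if (length(methods_tia)) {
      report <- tia_report(methods_tia, ma$tia_ma)
      tia_tab <- data.frame(patient_id = rownames(report$tia),
                            report$tia, check.names = FALSE)
      f <- file.path(config$out_dir, "tia.tsv")
      utils::write.table(tia_tab, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f)
    }
  }

  sd_tabs <- list()
  if ("tia-sd" %in% config$methods) {
    logmsg("stage tia-sd: frequency sampler omega=1028 n=8193 seed %d",
           config$seed)
    smp <- frequency_sampler(seed = config$seed)
    if (!is.null(ib)) sd_tabs$ibms <- tia_sd(ib, smp, config$t_end)
    if (!is.null(sp)) sd_tabs$sp_pbms <- tia_sd(sp, smp, config$t_end)
  }
  if ("jackknife" %in% config$methods) {
    logmsg("stage jackknife: %d replicates",
           length(unique(cohort$patient_id)))
    jk <- pbms_jackknife(cohort, config$functions, config$cv_threshold,
                         config$t_end, decay = decay, control = ctl)
    f <- file.path(config$out_dir, "jackknife.tsv")
    utils::write.table(jk$summary, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }

  summ <- list(fingerprint = fingerprint, seed = config$seed,
               n_patients = length(unique(cohort$patient_id)),
               n_obs = nrow(cohort))
  if (!is.null(sel)) {
    summ$selection <- sel$table[, c("fn", "K", "aicc", "weight", "max_cv",
                                    "passed")]
    summ$best_function <- best_function(sel)
  }
  if (!is.null(report)) summ$rmse <-
    stats::setNames(as.list(report$summary$rmse), report$summary$method)
  if (!is.null(jk)) summ$jackknife <- jk$summary
  if (length(sd_tabs)) summ$tia_sd <- sd_tabs
  f <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summ, f, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  files <- c(files, f)
  logmsg("done: %s", paste(basename(files), collapse = ", "))

  invisible(list(cohort = cohort, selection = sel, ma = ma, ibms = ib,
                 sp = sp, report = report, jackknife = jk,
                 tia_sd = sd_tabs, files = files, log = logfile))
}
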