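# Run the full estimator suite on one harmonized pair set.
estimate_suite <- function(pairs, model = "random", n_boot = 1000,
                           n_sim = 1000, seed = NULL, outlier_alpha = 0.05) {
  J <- nrow(pairs)
  ests <- list(ivw = mr_ivw(pairs, model))
  if (J >= 3L) {
    ests$weighted_median <- mr_weighted_median(pairs, n_boot = n_boot, seed = seed)
    ests$egger <- mr_egger(pairs)
  }
  presso <- if (J >= 4L) {
    mr_presso(pairs, n_sim = n_sim, seed = seed, outlier_alpha = outlier_alpha)
  }
  heterogeneity <- if (J >= 2L) cochran_q(pairs, ests$ivw)
  loo <- if (J >= 3L) leave_one_out(pairs, model)
  list(estimates = ests, presso = presso, heterogeneity = heterogeneity,
       leave_one_out = loo)
}

suite_forest_rows <- function(suite, outcome) {
  ests <- suite$estimates
  if (!is.null(suite$presso) && length(suite$presso$outlier_ids)) {
    corrected <- suite$presso$corrected_estimate
    corrected$method <- "MR-PRESSO (outlier-corrected)"
    ests$presso <- corrected
  }
  forest_table(ests, outcome = outcome)
}

#' Run positive-control analyses
#'
#' Validates an instrument set by estimating its effect on outcomes whose
#' direction is known a priori (for a drug-target study, the drug's
#' indications). A control PASSes when the IVW 95% CI excludes the null in
#' the expected direction.
#'
#' @param instruments Selected exposure `sumstats` table.
#' @param controls Named list of outcome `sumstats` tables.
#' @param expected_direction `-1` for protective effects (default), `+1`
#'   for risk-increasing.
#' @param model IVW model.
#' @param n_boot,seed Passed to the weighted median.
#' @return Data frame of forest rows for every control and method, with a
#'   `pass` flag on the IVW rows.
#' @export
run_positive_controls <- function(instruments, controls,
                                  expected_direction = -1,
                                  model = "random", n_boot = 1000,
                                  seed = NULL) {
  if (!length(controls)) stop("no positive-control outcome tables configured", call. = FALSE)
  rows <- lapply(names(controls), function(nm) {
    pairs <- harmonize(instruments, controls[[nm]])
    suite <- estimate_suite(pairs, model = model, n_boot = n_boot,
                            n_sim = 1000, seed = seed)
    tab <- suite_forest_rows(suite, outcome = nm)
    ivw <- suite$estimates$ivw
    pass <- if (expected_direction < 0) ivw$ci_high < 0 else ivw$ci_low > 0
    tab$pass <- ifelse(tab$method == "IVW", pass, NA)
    tab
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full drug-target MR study
#'
#' Orchestrates the study stages in order: instrument selection, positive
#' controls, the main MR analysis with its sensitivity diagnostics
#' (heterogeneity, Egger intercept, leave-one-out, MR-PRESSO), two-step
#' mediation for each configured mediator (with the difference-in-
#' coefficients sensitivity method when mediator associations at the
#' exposure instruments are available), and two-step cis-MR confounder
#' adjustment. Everything downstream of the seed is deterministic.
#'
#' @param config A list with components:
#'   \describe{
#'     \item{exposure}{candidate exposure `sumstats` table (e.g. cis-eQTLs).}
#'     \item{outcome}{main outcome `sumstats` table.}
#'     \item{selection}{a [selection_config()], or `NULL` to use the
#'       exposure table as-is.}
#'     \item{exclusion,ld}{optional exclusion list and LD matrix for
#'       selection.}
#'     \item{controls}{optional named list of positive-control outcome
#'       tables.}
#'     \item{expected_control_direction}{sign expected for controls
#'       (default -1).}
#'     \item{mediators}{optional named list; each element has
#'       `step1_outcome` (mediator associations at the exposure
#'       instruments) and `step2` (list of `exposure` and `outcome` tables
#'       for the mediator's own instruments).}
#'     \item{confounders}{optional list of [confounder_triple()] objects.}
#'     \item{estimator}{optional list overriding `model`, `n_boot`,
#'       `n_sim`, `outlier_alpha`.}
#'     \item{seed}{mandatory integer seed.}
#'   }
#' @param verbose Log stage progress via `message()`.
#' @return A `study_report` list: `selection`, `harmonization`, `forest`,
#'   `controls`, `sensitivity`, `leave_one_out`, `presso`, `mediation`,
#'   `tscmr`, `meta` (seed, config hash, package version), and the
#'   underlying `estimates`.
#' @export
run_full_study <- function(config, verbose = TRUE) {
  if (is.null(config$seed)) stop("config$seed is mandatory", call. = FALSE)
  if (is.null(config$exposure) || is.null(config$outcome)) {
    stop("config must provide exposure and outcome tables", call. = FALSE)
  }
  est_cfg <- config$estimator %||% list()
  model <- est_cfg$model %||% "random"
  n_boot <- est_cfg$n_boot %||% 1000
  n_sim <- est_cfg$n_sim %||% 1000
  outlier_alpha <- est_cfg$outlier_alpha %||% 0.05
  say <- function(...) if (verbose) message("[cismr] ", ...)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # 1. instrument selection
  say("selecting instruments")
  selection <- NULL
  instruments <- config$exposure
  if (!is.null(config$selection)) {
    sel <- stage("selection", select_instruments(config$exposure, config$selection,
                                                 excl = config$exclusion,
                                                 ld = config$ld))
    instruments <- sel$table
    selection <- sel$report
  }

  # 2. positive controls
  controls <- NULL
  if (length(config$controls)) {
    say("running positive controls")
    controls <- stage("positive-controls", run_positive_controls(
      instruments, config$controls,
      expected_direction = config$expected_control_direction %||% -1,
      model = model, n_boot = n_boot, seed = config$seed + 1L))
  }

  # 3. main MR analysis
  say("main MR analysis")
  pairs <- stage("harmonization", harmonize(instruments, config$outcome))
  suite <- stage("mr-estimation", estimate_suite(
    pairs, model = model, n_boot = n_boot, n_sim = n_sim,
    seed = config$seed + 2L, outlier_alpha = outlier_alpha))
  forest <- suite_forest_rows(suite, outcome = attr(config$outcome, "trait_id") %||% "outcome")
  sensitivity <- data.frame(
    q = suite$heterogeneity$Q,
    q_df = suite$heterogeneity$df,
    p_heterogeneity = suite$heterogeneity$pval,
    egger_intercept = suite$estimates$egger$intercept %||% NA_real_,
    p_pleiotropy = suite$estimates$egger$intercept_pval %||% NA_real_,
    presso_global_p = if (!is.null(suite$presso)) suite$presso$global_pval else NA_real_,
    n_presso_outliers = if (!is.null(suite$presso)) length(suite$presso$outlier_ids) else NA_integer_
  )

  # 4. mediation
  mediation <- NULL
  if (length(config$mediators)) {
    say("two-step mediation")
    total <- suite$estimates$ivw
    results <- list()
    for (nm in names(config$mediators)) {
      med <- config$mediators[[nm]]
      p1 <- harmonize(instruments, med$step1_outcome)
      step1 <- mr_ivw(p1, model)
      p2 <- harmonize(med$step2$exposure, med$step2$outcome)
      step2 <- mr_ivw(p2, model)
      results[[nm]] <- two_step_mediation(step1, step2, total, mediator_id = nm)
      # difference-in-coefficients sensitivity via multivariable IVW on the
      # union of exposure and mediator instruments (when an exposure lookup
      # at the mediator's instruments is configured)
      eam <- if (!is.null(med$exposure_at_mediator)) {
        harmonize(med$step2$exposure, med$exposure_at_mediator)
      }
      direct <- tryCatch(
        mvmr_direct_effect(pairs, p1, p2, exposure_at_mediator_pairs = eam),
        error = function(e) NULL)
      if (!is.null(direct)) {
        results[[paste0(nm, "_difference")]] <-
          difference_in_coefficients(total, direct, mediator_id = nm)
      }
    }
    mediation <- list(results = results, table = mediation_table(results))
  }

  # 5. confounder adjustment
  tscmr <- NULL
  if (length(config$confounders)) {
    say("two-step cis-MR confounder adjustment")
    tscmr <- stage("tscmr", tscmr_pipeline(pairs, config$confounders, model))
  }

  meta <- list(seed = config$seed,
               config_hash = config_hash(config),
               package_version = as.character(utils::packageVersion("cismr")))
  structure(list(
    selection = selection, harmonization = harmonization_report(pairs),
    forest = forest, controls = controls, sensitivity = sensitivity,
    leave_one_out = if (!is.null(suite$leave_one_out)) suite$leave_one_out$table,
    presso = suite$presso, mediation = mediation, tscmr = tscmr,
    estimates = suite$estimates, pairs = pairs, meta = meta
  ), class = "study_report")
}

# md5 of the serialized config; ties every report to its inputs.
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' @export
print.study_report <- function(x, ...) {
  cat("Drug-target MR study report (seed ", x$meta$seed, ")\n\n", sep = "")
  if (!is.null(x$selection)) print(x$selection)
  cat("\nForest table:\n")
  print(x$forest, digits = 4)
  cat("\nSensitivity:\n")
  print(x$sensitivity, digits = 4)
  if (!is.null(x$mediation)) {
    cat("\nMediation:\n")
    print(x$mediation$table, digits = 4)
  }
  if (!is.null(x$tscmr)) {
    cat("\n")
    print(x$tscmr)
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes every tabular component as TSV plus a single JSON bundle of the
#' whole report.
#'
#' @param report A `study_report` from [run_full_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(tab, name) {
    if (is.null(tab)) return()
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$forest, "forest")
  wr(report$controls, "controls")
  wr(report$sensitivity, "sensitivity")
  wr(report$leave_one_out, "leave_one_out")
  if (!is.null(report$mediation)) wr(report$mediation$table, "mediation")
  if (!is.null(report$tscmr)) wr(report$tscmr$table, "tscmr")

  bundle <- list(
    meta = report$meta,
    selection = if (!is.null(report$selection)) unclass(report$selection),
    harmonization = report$harmonization,
    forest = report$forest,
    controls = report$controls,
    sensitivity = report$sensitivity,
    leave_one_out = report$leave_one_out,
    mediation = if (!is.null(report$mediation)) report$mediation$table,
    tscmr = if (!is.null(report$tscmr)) report$tscmr$table
  )
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(bundle, jp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, jp))
}
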