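#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: either a synthetic cohort
#' configuration or a path to an existing cohort CSV (exactly one of the
#' two), the scale and scoring configuration, the ordinal variable coding,
#' which treatment arm to analyse, the survival horizons, output directory
#' and seed.
#'
#' @param synthetic a [synthetic_config()], or `NULL` when reading a cohort.
#' @param input path to a cohort CSV, or `NULL` when simulating.
#' @param scale_cfg a [scale_config()].
#' @param scale a [sensitivity_scale()].
#' @param coding a [variable_coding()].
#' @param cohort_filter `"all"` (analyse the intensive and non-intensive
#'   arms separately, as the study design prescribes), `"intensive"` or
#'   `"non_intensive"`.
#' @param horizons survival horizons in days for the KM summary.
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed governing every random stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, input = NULL,
                            scale_cfg = scale_config(),
                            scale = sensitivity_scale(),
                            coding = variable_coding(),
                            cohort_filter = c("all", "intensive",
                                              "non_intensive"),
                            horizons = c(180, 365, 1095),
                            out_dir = NULL, seed = 1) {
  cohort_filter <- match.arg(cohort_filter)
  if (is.null(synthetic) == is.null(input)) {
    stop("supply exactly one of `synthetic` / `input`", call. = FALSE)
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config")) {
    stop_field("synthetic", "must be a synthetic_config()")
  }
  if (!is.null(input) && !file.exists(input)) {
    stop_field("input", sprintf("file not found: %s", input))
  }
  if (is.null(out_dir)) stop_field("out_dir", "must be supplied")
  structure(list(synthetic = synthetic, input = input,
                 scale_cfg = scale_cfg, scale = scale, coding = coding,
                 cohort_filter = cohort_filter, horizons = horizons,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# variables correlated in the report (the report-table row set)
default_correlation_variables <- function() {
  c("therapy_response", "sens_daunorubicin", "sens_cytarabine",
    "total_sensitivity", "mdr1_category", "pgp_category",
    "n_aberrant_markers", "age_years", "n_unfavorable_mutations", "origin",
    "karyotype_risk", "standard_prognosis", "risk_group", "cd34_positive",
    "hla_dr_positive", "leukocytes", "hemoglobin", "platelets", "ldh",
    "syndrome_hemorrhagic", "syndrome_infectious", "syndrome_intoxication",
    "syndrome_hyperplastic", "neuroleukemia")
}

default_cox_candidates <- function() {
  c("risk_group", "karyotype_risk", "origin", "sens_daunorubicin",
    "sens_cytarabine", "mdr1_category", "n_aberrant_markers", "age_years")
}

# derived per-patient columns used by the evaluation battery
add_derived_columns <- function(scored, scale) {
  for (drug in names(scale$breakpoints)) {
    col <- paste0("ic50_", drug)
    ccol <- paste0(col, "_censored")
    cens <- if (ccol %in% names(scored)) scored[[ccol]] %in% TRUE else FALSE
    scored[[paste0("sens_", drug)]] <-
      classify_drug_sensitivity(scored[[col]], drug, scale, censored = cens)
  }
  sens_cols <- paste0("sens_", names(scale$breakpoints))
  scored$total_sensitivity <-
    rowMeans(as.matrix(scored[, sens_cols, drop = FALSE]), na.rm = TRUE)
  scored
}

evaluate_arm <- function(dat, label, cfg, log) {
  log(sprintf("evaluating %s arm: n = %d, events = %d", label, nrow(dat),
              sum(dat$death_event)))
  vars <- intersect(default_correlation_variables(), names(dat))
  cm <- correlation_matrix(dat, vars, cfg$coding)

  km_groups <- lapply(split(dat, dat$risk_group), function(g) {
    if (nrow(g) == 0L) return(NULL)
    km_estimate(g$os_days, g$death_event, horizons = cfg$horizons)
  })
  km_rows <- do.call(rbind, lapply(names(km_groups), function(gname) {
    km <- km_groups[[gname]]
    if (is.null(km)) return(NULL)
    data.frame(cohort = label, risk_group = gname, n = km$n,
               events = km$n_events, median_days = km$median,
               t(km$horizon_surv), stringsAsFactors = FALSE)
  }))
  present <- table(dat$risk_group) > 0
  lr <- if (sum(present) >= 2L) {
    log_rank(dat$os_days, dat$death_event, droplevels(dat$risk_group))
  } else NULL

  # a small arm can be single-class (e.g. every patient deceased); the ROC
  # is then undefined and reported as unavailable rather than fabricated
  roc_response <- tryCatch(
    roc_analysis(dat$total_score, dat$therapy_response != "remission"),
    error = function(e) { log(paste("ROC (response):",
                                    conditionMessage(e))); NULL })
  roc_survival <- tryCatch(
    roc_analysis(dat$total_score, dat$death_event),
    error = function(e) { log(paste("ROC (survival):",
                                    conditionMessage(e))); NULL })

  uni <- lapply(intersect(default_cox_candidates(), names(dat)),
                function(v) {
    tryCatch(cox_univariate(dat, v, coding = cfg$coding),
             error = function(e) NULL)
  })
  uni <- uni[!vapply(uni, is.null, logical(1L))]
  uni_tab <- do.call(rbind, lapply(uni, function(f) {
    cbind(f$coefficients, model_p = f$model_p, flagged = f$flagged)
  }))
  multi <- tryCatch(
    cox_multivariate(dat, intersect(default_cox_candidates(), names(dat)),
                     coding = cfg$coding),
    error = function(e) NULL)

  list(label = label, n = nrow(dat), correlations = cm, km = km_rows,
       log_rank = lr, roc_response = roc_response,
       roc_survival = roc_survival, cox_univariate = uni_tab,
       cox_multivariate = multi)
}

roc_record <- function(r) {
  if (is.null(r)) return(list(available = FALSE))
  list(auc = r$auc, se = r$se, ci95 = r$ci95, p = r$p, cutoff = r$cutoff,
       youden_j = r$youden_j, sensitivity = r$sensitivity,
       specificity = r$specificity, quality_band = r$quality_band,
       valid = r$valid, n_pos = r$n_pos, n_neg = r$n_neg)
}

cox_record <- function(f) {
  if (is.null(f)) return(NULL)
  list(coefficients = f$coefficients, model_p = f$model_p, n = f$n,
       n_events = f$n_events, policy = f$policy %||% "univariate",
       retained = f$retained %||% f$coefficients$variable,
       flagged = f$flagged)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> score -> evaluate and writes a report
#' bundle to the output directory: the scored cohort CSV, per-arm Spearman
#' correlation matrices, a per-risk-group Kaplan-Meier summary with log-rank
#' tests, ROC results for therapy response and overall survival, univariate
#' and multivariate Cox tables, a run log, and a manifest (config + seed +
#' package version) sufficient to regenerate the bundle byte-identically.
#' When `cohort_filter = "all"` the intensive and non-intensive arms are
#' analysed separately, mirroring the two-cohort study design.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) object of class `report_bundle`: list with the scored
#'   cohort, per-arm evaluation results and the paths written.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be created by pipeline_config()", call. = FALSE)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  log <- function(msg) log_lines[[length(log_lines) + 1L]] <<- msg
  written <- character()
  cleanup_on_error <- function() unlink(file.path(out_dir, written))

  result <- tryCatch({
    # ---- stage: cohort ----
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      syn$seed <- config$seed
      log(sprintf("stage simulate: n = %d, seed = %d", syn$n_patients,
                  syn$seed))
      cohort <- generate_cohort(syn)
    } else {
      log(sprintf("stage load: %s", config$input))
      cohort <- read_cohort(config$input)
    }

    # ---- stage: score ----
    log("stage score")
    scored <- score_cohort(cohort, config$scale_cfg, config$scale)
    errs <- attr(scored, "scoring_errors")
    if (length(errs)) for (e in errs) log(paste("scoring:", e))
    n_imp <- sum(nzchar(scored$imputed_parameters), na.rm = TRUE)
    if (n_imp) log(sprintf("scoring: %d record(s) with imputed parameters",
                           n_imp))
    scored <- add_derived_columns(scored, config$scale)
    cohort_csv <- file.path(out_dir, "scored_cohort.csv")
    written <- c(written, "scored_cohort.csv")
    write_cohort(scored, cohort_csv)

    # ---- stage: evaluate ----
    arms <- switch(config$cohort_filter,
                   all = c("intensive", "non_intensive"),
                   config$cohort_filter)
    evals <- list()
    for (arm in arms) {
      dat <- scored[scored$treatment_cohort == arm, , drop = FALSE]
      if (nrow(dat) == 0L) {
        stop(sprintf("stage evaluate: no patients in the %s arm", arm),
             call. = FALSE)
      }
      evals[[arm]] <- evaluate_arm(dat, arm, config, log)
    }

    for (arm in names(evals)) {
      ev <- evals[[arm]]
      fn <- sprintf("correlations_%s.csv", arm)
      written <- c(written, fn)
      write.csv(correlation_matrix_long(ev$correlations),
                file.path(out_dir, fn), row.names = FALSE, eol = "\n")
    }
    km_all <- do.call(rbind, lapply(evals, `[[`, "km"))
    written <- c(written, "km_summary.csv")
    write.csv(km_all, file.path(out_dir, "km_summary.csv"),
              row.names = FALSE, eol = "\n")

    roc_out <- lapply(evals, function(ev) {
      list(n = ev$n, therapy_response = roc_record(ev$roc_response),
           overall_survival = roc_record(ev$roc_survival),
           log_rank = if (!is.null(ev$log_rank))
             list(chisq = ev$log_rank$chisq, df = ev$log_rank$df,
                  p = ev$log_rank$p) else NULL)
    })
    written <- c(written, "roc_results.json")
    jsonlite::write_json(roc_out, file.path(out_dir, "roc_results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    cox_out <- lapply(evals, function(ev) {
      list(n = ev$n,
           univariate = ev$cox_univariate,
           multivariate = cox_record(ev$cox_multivariate))
    })
    written <- c(written, "cox_results.json")
    jsonlite::write_json(cox_out, file.path(out_dir, "cox_results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")

    manifest <- list(
      package = "amlrisk",
      version = as.character(packageVersion("amlrisk")),
      seed = config$seed,
      cohort_filter = config$cohort_filter,
      horizons = config$horizons,
      input = config$input,
      synthetic = if (!is.null(config$synthetic))
        unclass(config$synthetic) else NULL,
      scale_config = unclass(config$scale_cfg),
      sensitivity_scale = config$scale$breakpoints,
      coding = lapply(unclass(config$coding), as.list),
      outputs = written)
    written <- c(written, "manifest.json")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    log("pipeline complete")
    writeLines(log_lines, log_path)
    structure(list(scored = scored, evaluations = evals,
                   out_dir = out_dir,
                   files = c(written, "run.log")),
              class = "report_bundle")
  }, error = function(e) {
    cleanup_on_error()
    stop(e)
  })
  invisible(result)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Report bundle in", x$out_dir, "\n")
  cat("  files:", paste(x$files, collapse = ", "), "\n")
  for (arm in names(x$evaluations)) {
    ev <- x$evaluations[[arm]]
    fmt_auc <- function(r) if (is.null(r)) "n/a" else sprintf("%.3f", r$auc)
    cat(sprintf("  %s arm (n = %d): response AUC %s, survival AUC %s\n",
                arm, ev$n, fmt_auc(ev$roc_response),
                fmt_auc(ev$roc_survival)))
  }
  invisible(x)
}
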