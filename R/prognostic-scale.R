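#' Drug-sensitivity scale (IC50 breakpoints)
#'
#' Ordered IC50 breakpoints defining the three sensitivity categories for
#' each assayed drug: category 1 (high sensitivity) for IC50 in `[0, b1]`,
#' category 2 (moderate) in `(b1, b2]`, category 3 (low) above `b2` or when
#' the IC50 is right-censored at the maximum tested dose. Defaults are the
#' published breakpoints: daunorubicin 0.25/0.5 uM, cytarabine 1.5/8 uM. The
#' printed intervals overlap at the breakpoints, so boundary values are
#' assigned to the more-sensitive category (right-closed on the sensitive
#' side); this convention is configurable by moving the breakpoints.
#'
#' @param breakpoints named list; each element an ordered pair `c(b1, b2)`
#'   with `0 < b1 < b2`, named by drug.
#' @return object of class `sensitivity_scale`.
#' @examples
#' sensitivity_scale()
#' @export
sensitivity_scale <- function(breakpoints = list(daunorubicin = c(0.25, 0.5),
                                                 cytarabine = c(1.5, 8))) {
  if (!is.list(breakpoints) || is.null(names(breakpoints)) ||
      any(names(breakpoints) == "")) {
    stop_field("breakpoints", "must be a named list of per-drug pairs")
  }
  for (drug in names(breakpoints)) {
    b <- breakpoints[[drug]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1L] <= 0 || b[1L] >= b[2L]) {
      stop_field(drug, "breakpoints must satisfy 0 < b1 < b2")
    }
  }
  structure(list(breakpoints = breakpoints), class = "sensitivity_scale")
}

#' @export
print.sensitivity_scale <- function(x, ...) {
  cat("Drug-sensitivity scale (IC50 breakpoints, uM):\n")
  for (drug in names(x$breakpoints)) {
    b <- x$breakpoints[[drug]]
    cat(sprintf("  %-14s high [0, %g], moderate (%g, %g], low > %g\n",
                drug, b[1L], b[1L], b[2L], b[2L]))
  }
  invisible(x)
}

#' Classify an IC50 into a sensitivity category
#'
#' @param ic50 numeric IC50 in uM, or a string like `">2"` for an estimate
#'   right-censored at the maximum tested dose.
#' @param drug drug name present in `scale`.
#' @param scale a [sensitivity_scale()].
#' @param censored logical, vectorised; `TRUE` marks right-censored values
#'   (alternative to the `">"` string encoding).
#' @return integer category: 1 = high, 2 = moderate, 3 = low sensitivity.
#' @examples
#' classify_drug_sensitivity(0.6, "daunorubicin")   # 3
#' classify_drug_sensitivity(0.25, "daunorubicin")  # boundary -> 1
#' classify_drug_sensitivity(">2", "daunorubicin")  # censored -> 3
#' @export
classify_drug_sensitivity <- function(ic50, drug,
                                      scale = sensitivity_scale(),
                                      censored = FALSE) {
  if (!drug %in% names(scale$breakpoints)) {
    stop(sprintf("unknown drug '%s'; configured drugs: %s", drug,
                 paste(names(scale$breakpoints), collapse = ", ")),
         call. = FALSE)
  }
  if (is.character(ic50)) {
    p <- parse_ic50(ic50)
    ic50 <- p$value
    censored <- censored | p$censored
  }
  censored <- rep_len(censored, length(ic50))
  if (any(!censored & !is.na(ic50) & ic50 <= 0)) {
    stop_field("ic50", "must be > 0 when uncensored")
  }
  b <- scale$breakpoints[[drug]]
  out <- ifelse(censored, 3L,
                ifelse(ic50 <= b[1L], 1L, ifelse(ic50 <= b[2L], 2L, 3L)))
  out[is.na(ic50) & !censored] <- NA_integer_
  as.integer(out)
}

#' Drug-sensitivity parameter subscore
#'
#' Maps per-drug sensitivity categories to scale points (high = 0,
#' moderate = 1, low = 2) and averages them over the assayed drugs, so the
#' sensitivity parameter contributes at most 2 points regardless of how many
#' drugs were tested. With two drugs the mean can be fractional (0.5, 1.5);
#' by default it is rounded half-up to keep totals on the integer band scale,
#' or kept fractional with `rounding = "keep_fraction"`.
#'
#' @param categories integer vector of categories in `{1, 2, 3}`, one per
#'   assayed drug; `NA`s are dropped.
#' @param rounding `"round_half_up"` (default) or `"keep_fraction"`.
#' @return subscore in `[0, 2]`.
#' @examples
#' sensitivity_subscore(c(3, 1))  # mean(2, 0) = 1
#' @export
sensitivity_subscore <- function(categories, rounding = "round_half_up") {
  categories <- categories[!is.na(categories)]
  if (length(categories) < 1L) {
    stop("need at least one sensitivity category", call. = FALSE)
  }
  if (!all(categories %in% 1:3)) {
    stop_field("categories", "must be in {1, 2, 3}")
  }
  s <- mean(categories - 1)
  if (rounding == "round_half_up") s <- floor(s + 0.5)
  s
}

#' Scoring configuration for the prognostic scale
#'
#' @param missing_policy how to score parameters that cannot be determined
#'   (e.g. failed cytogenetics): `"score_zero_and_flag"` (default) scores the
#'   parameter 0 and records it as imputed; `"exclude_and_rescale"` drops the
#'   parameter and rescales the total to the full 0-12 range
#'   (`total * 12 / attainable maximum`).
#' @param subscore_rounding passed to [sensitivity_subscore()];
#'   `"round_half_up"` or `"keep_fraction"`.
#' @param fractional_group_cuts band cuts used for fractional totals under
#'   `keep_fraction` (and for rescaled totals): below the first cut is low
#'   risk, below the second intermediate, else high. Defaults to the
#'   midpoints (2.5, 5.5) of the integer bands.
#' @param mdr1_thresholds fold-change thresholds for
#'   [categorize_expression()] when only `mdr1_fold` is available.
#' @return object of class `scale_config`.
#' @export
scale_config <- function(missing_policy = c("score_zero_and_flag",
                                            "exclude_and_rescale"),
                         subscore_rounding = c("round_half_up",
                                               "keep_fraction"),
                         fractional_group_cuts = c(2.5, 5.5),
                         mdr1_thresholds = c(2, 10)) {
  missing_policy <- match.arg(missing_policy)
  subscore_rounding <- match.arg(subscore_rounding)
  if (length(fractional_group_cuts) != 2L ||
      !all(is.finite(fractional_group_cuts)) ||
      fractional_group_cuts[1L] >= fractional_group_cuts[2L] ||
      fractional_group_cuts[1L] <= 0 || fractional_group_cuts[2L] >= 12) {
    stop_field("fractional_group_cuts",
               "must be strictly increasing and inside (0, 12)")
  }
  structure(list(missing_policy = missing_policy,
                 subscore_rounding = subscore_rounding,
                 fractional_group_cuts = fractional_group_cuts,
                 mdr1_thresholds = mdr1_thresholds),
            class = "scale_config")
}

#' Assign a risk group from a total score
#'
#' Integer totals follow the published bands: 0-2 low, 3-5 intermediate,
#' 6-12 high risk. Fractional totals (possible under
#' `subscore_rounding = "keep_fraction"` or the rescaling missing policy)
#' use the configured fractional cuts, by default the band midpoints 2.5 and
#' 5.5.
#'
#' @param total numeric total score in `[0, 12]` (vectorised).
#' @param config a [scale_config()].
#' @return factor with levels `low`, `intermediate`, `high`.
#' @examples
#' assign_risk_group(c(0, 2, 3, 5, 6, 12))
#' @export
assign_risk_group <- function(total, config = scale_config()) {
  if (any(!is.na(total) & (total < 0 | total > 12))) {
    stop_field("total", "must lie in [0, 12]")
  }
  cuts <- config$fractional_group_cuts
  grp <- ifelse(
    is.na(total), NA_character_,
    ifelse(abs(total - round(total)) < 1e-9,
           ifelse(total <= 2, "low", ifelse(total <= 5, "intermediate", "high")),
           ifelse(total < cuts[1L], "low",
                  ifelse(total < cuts[2L], "intermediate", "high")))
  )
  factor(grp, levels = c("low", "intermediate", "high"))
}

# ordinal mdr1 category -> points
mdr1_points <- function(category) {
  unname(c(weak = 0, moderate = 1, strong = 2)[as.character(category)])
}

age_points <- function(age) {
  ifelse(age < 40, 0L, ifelse(age <= 60, 1L, 2L))
}

#' Score one patient on the six-parameter prognostic scale
#'
#' Computes the per-parameter scores, the total (0-12) and the risk group
#' for a single patient record. The six parameters and their points:
#' \itemize{
#'   \item drug sensitivity: per-drug category high/moderate/low -> 0/1/2,
#'     averaged over assayed drugs ([sensitivity_subscore()]);
#'   \item MDR1 mRNA expression: weak/moderate/strong -> 0/1/2 (from
#'     `mdr1_category`, or from `mdr1_fold` via the configured thresholds);
#'   \item tumor origin: primary 0, secondary 2;
#'   \item cytogenetics: no unfavorable mutations 0, one 1, more than one 2;
#'   \item age: under 40 years 0, 40-60 years 1, over 60 years 2;
#'   \item aberrant immunophenotype: no aberrant markers 0, one 1, more than
#'     one 2.
#' }
#' Parameters that cannot be determined are handled by the configured missing
#' policy and recorded in `imputed_parameters`.
#'
#' @param record one-row data frame or named list with fields as produced by
#'   [generate_cohort()]; at minimum IC50 information for one drug plus the
#'   remaining parameters (or their absence).
#' @param config a [scale_config()].
#' @param scale a [sensitivity_scale()].
#' @return object of class `scale_score`: list with `s_sens`, `s_mdr1`,
#'   `s_origin`, `s_cyto`, `s_age`, `s_immuno`, `total`, `risk_group`,
#'   `imputed_parameters`.
#' @examples
#' rec <- list(age_years = 50, origin = "primary",
#'             n_unfavorable_mutations = 1, mdr1_category = "moderate",
#'             n_aberrant_markers = 1,
#'             ic50_daunorubicin = 0.4, ic50_cytarabine = 4)
#' score_patient(rec)  # total 5, intermediate risk
#' @export
score_patient <- function(record, config = scale_config(),
                          scale = sensitivity_scale()) {
  df <- as.data.frame(record, stringsAsFactors = FALSE)
  if (nrow(df) != 1L) stop("record must describe exactly one patient",
                           call. = FALSE)
  scored <- score_components(df, config, scale)
  out <- as.list(scored[1L, c("s_sens", "s_mdr1", "s_origin", "s_cyto",
                              "s_age", "s_immuno", "total_score")])
  names(out)[names(out) == "total_score"] <- "total"
  out$risk_group <- scored$risk_group[1L]
  out$imputed_parameters <-
    if (nzchar(scored$imputed_parameters[1L]))
      strsplit(scored$imputed_parameters[1L], ";")[[1L]] else character()
  structure(out, class = "scale_score")
}

#' @export
print.scale_score <- function(x, ...) {
  cat(sprintf(paste0("Prognostic scale score: total %g (%s risk)\n",
                     "  sensitivity %g | MDR1 %g | origin %g | cytogenetics",
                     " %g | age %g | immunophenotype %g\n"),
              x$total, as.character(x$risk_group), x$s_sens, x$s_mdr1,
              x$s_origin, x$s_cyto, x$s_age, x$s_immuno))
  if (length(x$imputed_parameters)) {
    cat("  imputed:", paste(x$imputed_parameters, collapse = ", "), "\n")
  }
  invisible(x)
}

# vectorised scoring core shared by score_patient/score_cohort and the
# synthetic generator (which scores the pre-masking truth)
score_components <- function(df, config, scale) {
  n <- nrow(df)
  get <- function(nm) if (nm %in% names(df)) df[[nm]] else rep(NA, n)

  # --- drug sensitivity ---
  drugs <- names(scale$breakpoints)
  cat_mat <- matrix(NA_integer_, n, length(drugs),
                    dimnames = list(NULL, drugs))
  for (drug in drugs) {
    col <- paste0("ic50_", drug)
    ccol <- paste0(col, "_censored")
    if (col %in% names(df)) {
      cens <- if (ccol %in% names(df)) df[[ccol]] %in% TRUE else FALSE
      cat_mat[, drug] <- classify_drug_sensitivity(df[[col]], drug, scale,
                                                   censored = cens)
    }
    scat <- paste0("sens_", drug)  # pre-classified category column
    if (scat %in% names(df)) {
      have <- !is.na(df[[scat]])
      cat_mat[have, drug] <- as.integer(df[[scat]][have])
    }
  }
  s_sens <- apply(cat_mat, 1L, function(ct) {
    ct <- ct[!is.na(ct)]
    if (!length(ct)) return(NA_real_)
    sensitivity_subscore(ct, rounding = config$subscore_rounding)
  })

  # --- MDR1 ---
  mdr_cat <- as.character(get("mdr1_category"))
  fold <- suppressWarnings(as.numeric(get("mdr1_fold")))
  need <- is.na(mdr_cat) & !is.na(fold)
  if (any(need)) {
    mdr_cat[need] <- categorize_expression(fold[need],
                                           config$mdr1_thresholds)
  }
  s_mdr1 <- mdr1_points(mdr_cat)

  # --- origin ---
  origin <- as.character(get("origin"))
  bad_origin <- !is.na(origin) & !origin %in% c("primary", "secondary")
  if (any(bad_origin)) stop_field("origin", "must be primary or secondary")
  s_origin <- ifelse(origin == "secondary", 2, 0)

  # --- cytogenetics ---
  mut <- get("n_unfavorable_mutations")
  mut_num <- suppressWarnings(as.numeric(ifelse(mut %in% "unknown", NA, mut)))
  s_cyto <- pmin(mut_num, 2)

  # --- age ---
  age <- suppressWarnings(as.numeric(get("age_years")))
  s_age <- age_points(age)

  # --- immunophenotype ---
  mk <- suppressWarnings(as.numeric(get("n_aberrant_markers")))
  s_immuno <- pmin(mk, 2)

  parts <- cbind(s_sens = s_sens, s_mdr1 = s_mdr1, s_origin = s_origin,
                 s_cyto = s_cyto, s_age = s_age, s_immuno = s_immuno)
  all_missing <- rowSums(!is.na(parts)) == 0L
  if (any(all_missing)) {
    stop(sprintf("all six scale parameters missing for row(s) %s",
                 paste(which(all_missing), collapse = ", ")), call. = FALSE)
  }

  imput <- apply(parts, 1L, function(p) {
    paste(colnames(parts)[is.na(p)], collapse = ";")
  })
  max_attain <- rowSums(!is.na(parts)) * 2
  if (config$missing_policy == "score_zero_and_flag") {
    parts[is.na(parts)] <- 0
    total <- rowSums(parts)
  } else {
    total <- rowSums(parts, na.rm = TRUE) * 12 / max_attain
    parts[is.na(parts)] <- NA
  }
  data.frame(parts, total_score = total,
             risk_group = assign_risk_group(total, config),
             imputed_parameters = imput,
             stringsAsFactors = FALSE)
}

#' Score every patient in a cohort
#'
#' Applies [score_patient()] row-wise and appends the per-parameter scores,
#' total, risk group and imputation flags as columns. Rows that cannot be
#' scored are kept with `NA` scores and the failure message collected in the
#' `"scoring_errors"` attribute rather than aborting the batch.
#'
#' @param table cohort data frame (e.g. from [generate_cohort()] or
#'   [read_cohort()]).
#' @inheritParams score_patient
#' @return the input with columns `s_sens`, `s_mdr1`, `s_origin`, `s_cyto`,
#'   `s_age`, `s_immuno`, `total_score`, `risk_group`,
#'   `imputed_parameters` appended (replaced if already present, so
#'   re-scoring is idempotent).
#' @export
score_cohort <- function(table, config = scale_config(),
                         scale = sensitivity_scale()) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("cohort table must be a non-empty data frame", call. = FALSE)
  }
  score_cols <- c("s_sens", "s_mdr1", "s_origin", "s_cyto", "s_age",
                  "s_immuno", "total_score", "risk_group",
                  "imputed_parameters")
  base <- table[, setdiff(names(table), score_cols), drop = FALSE]
  errors <- character()
  scored <- tryCatch(score_components(base, config, scale),
                     error = function(e) NULL)
  if (is.null(scored)) {  # retry row-wise, collecting per-row failures
    rows <- lapply(seq_len(nrow(base)), function(i) {
      tryCatch(score_components(base[i, , drop = FALSE], config, scale),
               error = function(e) {
                 errors[[length(errors) + 1L]] <<-
                   sprintf("row %d: %s", i, conditionMessage(e))
                 data.frame(s_sens = NA_real_, s_mdr1 = NA_real_,
                            s_origin = NA_real_, s_cyto = NA_real_,
                            s_age = NA_real_, s_immuno = NA_real_,
                            total_score = NA_real_,
                            risk_group = factor(NA, levels =
                              c("low", "intermediate", "high")),
                            imputed_parameters = NA_character_,
                            stringsAsFactors = FALSE)
               })
    })
    scored <- do.call(rbind, rows)
  }
  out <- cbind(base, scored)
  attr(out, "scoring_errors") <- errors
  attr(out, "provenance") <- attr(table, "provenance")
  out
}
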