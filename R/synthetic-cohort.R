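# fixed column vocabulary of a cohort table (CSV schema order)
cohort_schema <- function() {
  c("patient_id", "age_years", "treatment_cohort", "origin",
    "n_unfavorable_mutations", "n_aberrant_markers",
    "ic50_daunorubicin", "ic50_cytarabine",
    "mdr1_fold", "mdr1_category", "pgp_category",
    "karyotype_risk", "standard_prognosis", "therapy_response",
    "os_days", "death_event",
    "leukocytes", "hemoglobin", "platelets", "ldh",
    "syndrome_hemorrhagic", "syndrome_anemic", "syndrome_infectious",
    "syndrome_hyperplastic", "syndrome_intoxication", "neuroleukemia",
    "cd34_positive", "hla_dr_positive")
}

cohort_vocab <- list(
  treatment_cohort = c("intensive", "non_intensive"),
  origin = c("primary", "secondary"),
  n_unfavorable_mutations = c("0", "1", "2", "unknown"),
  mdr1_category = c("weak", "moderate", "strong"),
  karyotype_risk = c("favorable", "intermediate", "adverse", "unknown"),
  standard_prognosis = c("favorable", "unfavorable"),
  therapy_response = c("remission", "relapse", "refractory")
)

#' Configuration of the synthetic AML cohort generator
#'
#' Defines the study conditions the generator emulates: a cohort of newly
#' diagnosed AML patients split into an intensive (anthracycline-based) and a
#' non-intensive (low-dose cytarabine) treatment arm, with a single latent
#' per-patient resistance burden driving the positive inter-correlations
#' among the multidrug-resistance covariates, an ordinal therapy-response
#' outcome driven by the true scale total, and exponential
#' proportional-hazards survival with administrative censoring.
#'
#' @param n_patients cohort size (default 53).
#' @param seed integer RNG seed; identical configs give byte-identical
#'   cohorts.
#' @param p_intensive probability of assignment to the intensive arm.
#' @param latent_sd standard deviation of the latent resistance burden.
#' @param covariate_loadings named numeric vector of per-covariate effects of
#'   the latent burden: `ic50` (log-IC50 shift per unit burden), and
#'   log-odds shifts for the ordinal covariates `mdr1`, `mutations`,
#'   `markers`, `pgp`, `origin`, `karyotype`, `prognosis`. Setting all to 0
#'   makes the covariates mutually independent.
#' @param response_coefficients list with `slope` (log-odds of a worse
#'   response per scale point) and `intercepts` (two ordered cumulative-logit
#'   thresholds) for the ordinal therapy-response model on the true total
#'   score.
#' @param baseline_hazard events/day in the low-risk group (default
#'   `log(2)/452`, i.e. a 452-day median).
#' @param log_hr_per_risk_step log hazard ratio per one-step increase in risk
#'   group (default `log(452/79)/2`, spanning a 452- to 79-day median across
#'   the three groups).
#' @param admin_censor_day administrative censoring horizon in days.
#' @param missing_karyotype_fraction probability a record lacks cytogenetics
#'   (default 0.19, i.e. about 10 of 53).
#' @param concentration_grids per-drug assay concentration grids (uM),
#'   strictly increasing and starting at the zero-dose well.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 53,
                             seed = 1,
                             p_intensive = 0.6,
                             latent_sd = 1,
                             covariate_loadings = c(
                               ic50 = 0.9, mdr1 = 1.0, mutations = 0.8,
                               markers = 0.8, pgp = 0.8, origin = 0.5,
                               karyotype = 0.8, prognosis = 0.8),
                             response_coefficients = list(
                               slope = 0.6, intercepts = c(2.16, 2.58)),
                             baseline_hazard = log(2) / 452,
                             log_hr_per_risk_step = log(452 / 79) / 2,
                             admin_censor_day = 1095,
                             missing_karyotype_fraction = 0.19,
                             concentration_grids = list(
                               daunorubicin = c(0, 0.05, 0.1, 0.2, 0.4,
                                                0.6, 1, 2),
                               cytarabine = c(0, 0.001, 0.01, 0.2, 0.8,
                                              4, 40, 82))) {
  if (!is_count(n_patients)) stop_field("n_patients", "must be a count >= 1")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_field("seed", "must be a single integer")
  }
  if (!is_prob(p_intensive)) stop_field("p_intensive", "must be in [0, 1]")
  if (!is.numeric(latent_sd) || latent_sd < 0) {
    stop_field("latent_sd", "must be >= 0")
  }
  need <- c("ic50", "mdr1", "mutations", "markers", "pgp", "origin",
            "karyotype", "prognosis")
  if (!is.numeric(covariate_loadings) ||
      !all(need %in% names(covariate_loadings))) {
    stop_field("covariate_loadings",
               paste("must be a named numeric vector with entries",
                     paste(need, collapse = ", ")))
  }
  if (!is.list(response_coefficients) ||
      !is.numeric(response_coefficients$slope) ||
      length(response_coefficients$intercepts) != 2L ||
      diff(response_coefficients$intercepts) < 0) {
    stop_field("response_coefficients",
               "must be list(slope=, intercepts=c(t1, t2)) with t1 <= t2")
  }
  if (!is_pos_scalar(baseline_hazard)) {
    stop_field("baseline_hazard", "must be > 0")
  }
  if (!is.numeric(log_hr_per_risk_step) || length(log_hr_per_risk_step) != 1L ||
      !is.finite(log_hr_per_risk_step)) {
    stop_field("log_hr_per_risk_step", "must be a finite number")
  }
  if (!is_pos_scalar(admin_censor_day)) {
    stop_field("admin_censor_day", "must be > 0")
  }
  if (!is_prob(missing_karyotype_fraction)) {
    stop_field("missing_karyotype_fraction", "must be in [0, 1]")
  }
  for (drug in names(concentration_grids)) {
    g <- concentration_grids[[drug]]
    if (g[1L] != 0 || any(diff(g) <= 0)) {
      stop_field("concentration_grids",
                 sprintf("%s grid must start at 0 and be strictly increasing",
                         drug))
    }
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 p_intensive = p_intensive, latent_sd = latent_sd,
                 covariate_loadings = covariate_loadings,
                 response_coefficients = response_coefficients,
                 baseline_hazard = baseline_hazard,
                 log_hr_per_risk_step = log_hr_per_risk_step,
                 admin_censor_day = admin_censor_day,
                 missing_karyotype_fraction = missing_karyotype_fraction,
                 concentration_grids = concentration_grids),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic AML cohort config: n = %d, seed = %d\n",
                     "  P(intensive arm) = %g, latent burden sd = %g\n",
                     "  baseline hazard = %.3g/day, log HR per risk step =",
                     " %.3g, censor at %g d\n"),
              x$n_patients, x$seed, x$p_intensive, x$latent_sd,
              x$baseline_hazard, x$log_hr_per_risk_step, x$admin_censor_day))
  invisible(x)
}

# ordinal draw from cumulative-logit thresholds shifted by load * z
ordinal_draw <- function(z, load, base_cum, levels_out) {
  # base_cum: baseline probabilities of being at or above each higher level
  n <- length(z)
  k <- length(base_cum)
  p_ge <- vapply(seq_len(k), function(j) {
    plogis(qlogis(base_cum[j]) + load * z)
  }, numeric(n))
  if (n == 1L) p_ge <- matrix(p_ge, nrow = 1L)
  u <- runif(n)
  idx <- 1L + rowSums(u < p_ge)
  levels_out[idx]
}

#' Generate a synthetic AML cohort
#'
#' Draws `n_patients` records under the model described in
#' [synthetic_config()]: a standard-normal latent resistance burden per
#' patient shifts log-IC50s (log-normal), the MDR1, P-gp, mutation-count,
#' marker-count, origin, karyotype-risk and prognosis categories (ordered
#' logit); therapy response is drawn from a cumulative-logit model on the
#' patient's true scale total; overall survival is exponential with a
#' proportional hazard on the true risk-group index and administrative
#' censoring at the follow-up horizon. Cytogenetics are masked to
#' `"unknown"` with the configured probability after the truth is scored.
#'
#' @param config a [synthetic_config()].
#' @return data frame of class `cohort_table` with one row per patient and
#'   the fixed cohort schema; carries the generating config in the
#'   `"provenance"` attribute and the pre-masking truth (`true_total`,
#'   `true_risk_index`) in the `"truth"` attribute.
#' @examples
#' coh <- generate_cohort(synthetic_config(n_patients = 10, seed = 42))
#' head(coh[, 1:8])
#' @export
generate_cohort <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    stop("config must be created by synthetic_config()", call. = FALSE)
  }
  n <- config$n_patients
  ld <- config$covariate_loadings
  with_seed(config$seed, {
    z <- rnorm(n, 0, config$latent_sd)

    arm <- ifelse(runif(n) < config$p_intensive, "intensive", "non_intensive")
    age <- round(pmin(pmax(rnorm(n, 51.2, 14.5), 18), 90), 1)

    # log-normal IC50s, right-censored at the top of the tested grid
    grids <- config$concentration_grids
    ic50_d <- exp(log(0.35) + ld[["ic50"]] * z + rnorm(n, 0, 0.6))
    ic50_c <- exp(log(3) + ld[["ic50"]] * z + rnorm(n, 0, 0.8))
    cmax_d <- max(grids$daunorubicin)
    cmax_c <- max(grids$cytarabine)
    cens_d <- ic50_d > cmax_d
    cens_c <- ic50_c > cmax_c
    ic50_d <- signif(pmin(ic50_d, cmax_d), 4)
    ic50_c <- signif(pmin(ic50_c, cmax_c), 4)

    mdr1_fold <- signif(exp(log(3) + ld[["mdr1"]] * z + rnorm(n, 0, 0.7)), 4)
    mdr1_category <- categorize_expression(mdr1_fold)

    pgp <- as.integer(ordinal_draw(z, ld[["pgp"]], c(0.5, 0.2), 1:3))
    muts <- as.integer(ordinal_draw(z, ld[["mutations"]], c(0.45, 0.18), 0:2))
    marks <- as.integer(ordinal_draw(z, ld[["markers"]], c(0.55, 0.25), 0:2))
    origin <- ordinal_draw(z, ld[["origin"]], 0.2,
                           c("primary", "secondary"))
    karyo <- ordinal_draw(z, ld[["karyotype"]], c(0.465, 0.349),
                          c("favorable", "intermediate", "adverse"))
    progn <- ordinal_draw(z, ld[["prognosis"]], 0.811,
                          c("favorable", "unfavorable"))

    # blood counts / labs, loosely matching the reported marginals
    leuko <- signif(exp(rnorm(n, log(20), 1.3)), 3)
    hb <- round(pmin(pmax(rnorm(n, 85, 25), 40), 165), 1)
    plt <- signif(exp(rnorm(n, log(60), 0.9)), 3)
    ldh <- round(exp(rnorm(n, log(500), 0.7)))

    syn <- function(p) rbinom(n, 1L, p)
    s_hem <- syn(0.792); s_ane <- syn(0.943); s_inf <- syn(0.509)
    s_hyp <- syn(0.66); s_int <- syn(0.868); s_neu <- syn(0.08)
    cd34 <- syn(0.6); hladr <- syn(0.65)

    # score the pre-masking truth to drive outcome and survival
    truth <- data.frame(
      age_years = age, origin = origin,
      n_unfavorable_mutations = muts, n_aberrant_markers = marks,
      mdr1_category = mdr1_category,
      ic50_daunorubicin = ic50_d, ic50_daunorubicin_censored = cens_d,
      ic50_cytarabine = ic50_c, ic50_cytarabine_censored = cens_c,
      stringsAsFactors = FALSE)
    sc <- score_components(truth, scale_config(), sensitivity_scale())
    total <- sc$total_score
    g <- as.integer(sc$risk_group) - 1L  # 0 = low, 1 = intermediate, 2 = high

    # ordinal therapy response on the true total
    rc <- config$response_coefficients
    eta <- rc$slope * total
    p_rem <- plogis(rc$intercepts[1L] - eta)
    p_rel <- plogis(rc$intercepts[2L] - eta) - p_rem
    u <- runif(n)
    response <- ifelse(u < p_rem, "remission",
                       ifelse(u < p_rem + p_rel, "relapse", "refractory"))

    # exponential PH survival with administrative censoring
    rate <- config$baseline_hazard * exp(config$log_hr_per_risk_step * g)
    t_event <- rexp(n, rate)
    death <- as.integer(t_event < config$admin_censor_day)
    os <- ifelse(death == 1L, ceiling(t_event), config$admin_censor_day)

    # mask cytogenetics after the truth is fixed
    miss <- runif(n) < config$missing_karyotype_fraction
    mut_col <- as.character(muts)
    mut_col[miss] <- "unknown"
    karyo[miss] <- "unknown"

    out <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      age_years = age, treatment_cohort = arm, origin = origin,
      n_unfavorable_mutations = mut_col, n_aberrant_markers = marks,
      ic50_daunorubicin = ic50_d, ic50_cytarabine = ic50_c,
      mdr1_fold = mdr1_fold, mdr1_category = mdr1_category,
      pgp_category = pgp, karyotype_risk = karyo,
      standard_prognosis = progn, therapy_response = response,
      os_days = os, death_event = death,
      leukocytes = leuko, hemoglobin = hb, platelets = plt, ldh = ldh,
      syndrome_hemorrhagic = s_hem, syndrome_anemic = s_ane,
      syndrome_infectious = s_inf, syndrome_hyperplastic = s_hyp,
      syndrome_intoxication = s_int, neuroleukemia = s_neu,
      cd34_positive = cd34, hla_dr_positive = hladr,
      stringsAsFactors = FALSE)
    out$ic50_daunorubicin_censored <- cens_d
    out$ic50_cytarabine_censored <- cens_c
    attr(out, "provenance") <- config
    attr(out, "truth") <- data.frame(true_total = total,
                                     true_risk_index = g)
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Generate a synthetic WST-1 dose-response plate
#'
#' Simulates paired 450/620 nm absorbances for one drug on its concentration
#' grid: mean viability follows the two-parameter log-logistic
#' \eqn{v(c) = 1/(1 + (c/IC50_{true})^{hill})}, mapped to absorbance as
#' blank offset + viability x signal span, plus Gaussian read noise. The
#' plate includes zero-dose (untreated) wells and cell-free blanks, so with
#' `noise_sd = 0` the computed viability at `c = ic50_true` is exactly 0.5.
#'
#' @param drug drug name; supplies the default grid for
#'   `"daunorubicin"` / `"cytarabine"`.
#' @param ic50_true true IC50 in uM (> 0).
#' @param hill Hill slope (> 0).
#' @param noise_sd Gaussian noise sd in absorbance units.
#' @param grid concentration grid starting at 0; default per drug.
#' @param replicates wells per condition (default 3).
#' @param seed RNG seed.
#' @return plate data frame in long format (`drug`, `concentration_uM`,
#'   `replicate`, `a450`, `a620`, `well_type`).
#' @export
generate_plate <- function(drug, ic50_true, hill = 1, noise_sd = 0.02,
                           grid = NULL, replicates = 3, seed = 1) {
  if (!is_pos_scalar(ic50_true)) stop_field("ic50_true", "must be > 0")
  if (!is_pos_scalar(hill)) stop_field("hill", "must be > 0")
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_field("noise_sd", "must be >= 0")
  }
  if (is.null(grid)) {
    grid <- synthetic_config()$concentration_grids[[drug]]
    if (is.null(grid)) {
      stop_field("grid", sprintf("no default grid for drug '%s'", drug))
    }
  }
  if (grid[1L] != 0 || any(diff(grid) <= 0)) {
    stop_field("grid", "must start at 0 and be strictly increasing")
  }
  blank_abs <- 0.08
  span <- 1.0
  ref <- 0.04
  with_seed(seed, {
    conc <- grid[grid > 0]
    rows <- expand.grid(replicate = seq_len(replicates),
                        concentration_uM = conc)
    v <- hill_viability(rows$concentration_uM, ic50_true, hill)
    treated <- data.frame(drug = drug,
                          concentration_uM = rows$concentration_uM,
                          replicate = rows$replicate,
                          a450 = blank_abs + v * span +
                            rnorm(nrow(rows), 0, noise_sd),
                          a620 = ref, well_type = "treated",
                          stringsAsFactors = FALSE)
    untreated <- data.frame(drug = drug, concentration_uM = 0,
                            replicate = seq_len(replicates),
                            a450 = blank_abs + span +
                              rnorm(replicates, 0, noise_sd),
                            a620 = ref, well_type = "untreated",
                            stringsAsFactors = FALSE)
    blank <- data.frame(drug = drug, concentration_uM = 0,
                        replicate = seq_len(replicates),
                        a450 = blank_abs + rnorm(replicates, 0, noise_sd),
                        a620 = ref, well_type = "blank",
                        stringsAsFactors = FALSE)
    rbind(untreated, treated, blank)
  })
}

#' Write / read a cohort CSV
#'
#' The cohort CSV has one row per patient with the fixed schema; missing
#' values are the token `NA` and IC50 estimates right-censored at the top
#' tested dose are encoded as `">"` + dose (e.g. `">2"`). `read_cohort()`
#' validates the header, the categorical vocabularies and the survival
#' fields, reporting the offending rows and columns.
#'
#' @param table a cohort table (from [generate_cohort()] or compatible).
#' @param path file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   a `cohort_table` data frame.
#' @export
write_cohort <- function(table, path) {
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  for (drug in c("daunorubicin", "cytarabine")) {
    col <- paste0("ic50_", drug)
    ccol <- paste0(col, "_censored")
    if (col %in% names(df)) {
      cens <- if (ccol %in% names(df)) df[[ccol]] %in% TRUE else FALSE
      df[[col]] <- format_ic50(df[[col]], cens)
      df[[ccol]] <- NULL
    }
  }
  keep <- intersect(c(cohort_schema(),
                      c("s_sens", "s_mdr1", "s_origin", "s_cyto", "s_age",
                        "s_immuno", "total_score", "risk_group",
                        "imputed_parameters")),
                    names(df))
  write.csv(df[, keep, drop = FALSE], path, row.names = FALSE, quote = TRUE,
            na = "NA", eol = "\n")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 na.strings = "NA", check.names = FALSE)
  extra <- setdiff(names(df),
                   c(cohort_schema(),
                     c("s_sens", "s_mdr1", "s_origin", "s_cyto", "s_age",
                       "s_immuno", "total_score", "risk_group",
                       "imputed_parameters")))
  if (length(extra)) {
    stop("unknown cohort column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(cohort_schema(), names(df))
  if (length(miss)) {
    stop("missing cohort column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in names(cohort_vocab)) {
    vals <- df[[col]]
    bad <- !is.na(vals) & !vals %in% cohort_vocab[[col]]
    if (any(bad)) {
      stop(sprintf(
        "column `%s`: value(s) %s outside vocabulary {%s} (row %s)",
        col, paste(unique(vals[bad]), collapse = ", "),
        paste(cohort_vocab[[col]], collapse = ", "),
        paste(which(bad), collapse = ", ")), call. = FALSE)
    }
  }
  num_cols <- c("age_years", "mdr1_fold", "pgp_category", "os_days",
                "death_event", "n_aberrant_markers", "leukocytes",
                "hemoglobin", "platelets", "ldh", "syndrome_hemorrhagic",
                "syndrome_anemic", "syndrome_infectious",
                "syndrome_hyperplastic", "syndrome_intoxication",
                "neuroleukemia", "cd34_positive", "hla_dr_positive")
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  int_cols <- c("pgp_category", "death_event", "n_aberrant_markers",
                "os_days", "syndrome_hemorrhagic", "syndrome_anemic",
                "syndrome_infectious", "syndrome_hyperplastic",
                "syndrome_intoxication", "neuroleukemia", "cd34_positive",
                "hla_dr_positive")
  for (col in int_cols) df[[col]] <- as.integer(df[[col]])
  bad_os <- !is.na(df$os_days) & df$os_days < 0
  if (any(bad_os)) {
    stop("negative os_days at row(s): ",
         paste(which(bad_os), collapse = ", "), call. = FALSE)
  }
  flags <- c("syndrome_hemorrhagic", "syndrome_anemic",
             "syndrome_infectious", "syndrome_hyperplastic",
             "syndrome_intoxication", "neuroleukemia", "cd34_positive",
             "hla_dr_positive", "death_event")
  for (col in flags) {
    bad <- !is.na(df[[col]]) & !df[[col]] %in% c(0L, 1L)
    if (any(bad)) {
      stop(sprintf("column `%s` must be 0/1 (row %s)", col,
                   paste(which(bad), collapse = ", ")), call. = FALSE)
    }
  }
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id values", call. = FALSE)
  }
  for (drug in c("daunorubicin", "cytarabine")) {
    col <- paste0("ic50_", drug)
    p <- parse_ic50(df[[col]])
    if (any(!p$censored & !is.na(p$value) & p$value <= 0)) {
      stop(sprintf("column `%s`: uncensored IC50 must be > 0", col),
           call. = FALSE)
    }
    df[[col]] <- p$value
    df[[paste0(col, "_censored")]] <- p$censored
  }
  for (col in intersect(c("s_sens", "s_mdr1", "s_origin", "s_cyto", "s_age",
                          "s_immuno", "total_score"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("AML cohort table: %d patients (%d intensive, %d non-intensive)\n",
              nrow(x), sum(x$treatment_cohort == "intensive"),
              sum(x$treatment_cohort == "non_intensive")))
  NextMethod()
}
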