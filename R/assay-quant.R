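#' Dose-response viability from a WST-1 plate
#'
#' Converts raw paired-wavelength absorbances into a viability curve. The
#' per-well signal is the 450 nm reading minus the 620 nm reference reading;
#' the mean blank signal (wells without cells) is subtracted, and viability at
#' each concentration is the blank-corrected treated signal divided by the
#' blank-corrected zero-dose (untreated) signal. Viability of the zero-dose
#' condition is therefore exactly 1 by construction.
#'
#' @param plate data frame in long plate format with columns `drug`,
#'   `concentration_uM`, `replicate`, `a450`, `a620` and
#'   `well_type` (one of `"treated"`, `"untreated"`, `"blank"`).
#' @param cap upper cap applied to viability fractions; noisy wells slightly
#'   above the untreated signal are tolerated up to this value (default 1.5).
#' @return object of class `viability_curve`: a list with `drug`,
#'   `points` (data frame `concentration`, `viability`, `sd`, `n`) where the
#'   first row is the zero-dose condition with viability 1.
#' @examples
#' pl <- generate_plate("daunorubicin", ic50_true = 0.4, hill = 1,
#'                      noise_sd = 0, seed = 1)
#' cv <- compute_viability(pl)
#' cv$points
#' @export
compute_viability <- function(plate, cap = 1.5) {
  req <- c("drug", "concentration_uM", "replicate", "a450", "a620", "well_type")
  miss <- setdiff(req, names(plate))
  if (length(miss)) {
    stop("plate is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(plate$a450)) || !all(is.finite(plate$a620))) {
    stop("non-finite absorbance values in plate", call. = FALSE)
  }
  signal <- plate$a450 - plate$a620
  blank <- signal[plate$well_type == "blank"]
  zero <- signal[plate$well_type == "untreated"]
  if (length(blank) < 1L) stop("plate has no blank wells", call. = FALSE)
  if (length(zero) < 1L) stop("plate has no zero-dose wells", call. = FALSE)
  denom <- mean(zero) - mean(blank)
  if (denom <= 0) {
    stop("degenerate plate: zero-dose signal does not exceed blank signal",
         call. = FALSE)
  }
  treated <- plate[plate$well_type == "treated", , drop = FALSE]
  conc <- sort(unique(treated$concentration_uM))
  if (length(conc) < 4L) {
    stop("plate must contain at least 4 distinct non-zero concentrations",
         call. = FALSE)
  }
  pts <- lapply(conc, function(cc) {
    v <- (signal[plate$well_type == "treated" &
                   plate$concentration_uM == cc] - mean(blank)) / denom
    v <- pmin(v, cap)
    data.frame(concentration = cc, viability = mean(v),
               sd = if (length(v) > 1L) sd(v) else NA_real_, n = length(v))
  })
  vz <- (zero - mean(blank)) / denom
  pts <- rbind(
    data.frame(concentration = 0, viability = 1,
               sd = if (length(vz) > 1L) sd(vz) else NA_real_,
               n = length(vz)),
    do.call(rbind, pts)
  )
  structure(list(drug = plate$drug[1L], points = pts),
            class = "viability_curve")
}

#' @export
print.viability_curve <- function(x, ...) {
  cat("Viability curve:", x$drug, "—", nrow(x$points) - 1L,
      "non-zero concentrations\n")
  print(x$points, row.names = FALSE)
  invisible(x)
}

hill_viability <- function(conc, ic50, hill) {
  v <- 1 / (1 + (conc / ic50)^hill)
  v[conc == 0] <- 1
  v
}

#' Half-maximal inhibitory concentration from a viability curve
#'
#' Estimates the IC50 as the concentration at which the fitted viability
#' falls to 50%. The primary method is a least-squares fit of the
#' two-parameter log-logistic model \eqn{v(c) = 1 / (1 + (c/IC50)^h)} with the
#' upper asymptote fixed at the zero-dose viability (1) and the lower at 0,
#' started from a log-spaced grid of IC50 candidates to avoid local minima.
#' When the fit does not converge, the 50% crossing is linearly interpolated
#' in log-concentration between the bracketing doses. When every mean
#' viability stays above 0.5 the estimate is right-censored at the maximum
#' tested dose (`method = "censored"`), the convention under which such a
#' sample is later classified low-sensitivity.
#'
#' @param curve a `viability_curve` from [compute_viability()], or a data
#'   frame with columns `concentration` and `viability`.
#' @return object of class `ic50_estimate`: list with `value` (uM), `censored`
#'   (logical), `method` (`"loglogistic_fit"`, `"interpolation"` or
#'   `"censored"`), `hill` and `rss` (NA unless fitted).
#' @examples
#' pts <- data.frame(concentration = c(0, 0.05, 0.1, 0.2, 0.4, 0.6, 1, 2))
#' pts$viability <- 1 / (1 + pts$concentration / 0.4)
#' estimate_ic50(pts)
#' @export
estimate_ic50 <- function(curve) {
  pts <- if (inherits(curve, "viability_curve")) curve$points else
    as.data.frame(curve)
  if (!all(c("concentration", "viability") %in% names(pts))) {
    stop("curve must have columns `concentration` and `viability`",
         call. = FALSE)
  }
  pts <- pts[order(pts$concentration), , drop = FALSE]
  nz <- pts[pts$concentration > 0 & is.finite(pts$viability), , drop = FALSE]
  if (nrow(nz) < 4L) {
    stop("insufficient data: need at least 4 non-zero concentrations",
         call. = FALSE)
  }
  cmax <- max(nz$concentration)
  if (min(nz$viability) > 0.5) {
    return(structure(list(value = cmax, censored = TRUE, method = "censored",
                          hill = NA_real_, rss = NA_real_),
                     class = "ic50_estimate"))
  }
  fit <- fit_loglogistic(nz$concentration, nz$viability)
  if (!is.null(fit)) {
    return(structure(list(value = fit$ic50, censored = FALSE,
                          method = "loglogistic_fit", hill = fit$hill,
                          rss = fit$rss),
                     class = "ic50_estimate"))
  }
  ic50 <- interpolate_ic50(nz$concentration, nz$viability)
  structure(list(value = ic50, censored = FALSE, method = "interpolation",
                 hill = NA_real_, rss = NA_real_),
            class = "ic50_estimate")
}

# multi-start least squares on (log IC50, log hill); returns NULL on failure
fit_loglogistic <- function(conc, viab) {
  obj <- function(par) {
    pred <- 1 / (1 + (conc / exp(par[1L]))^exp(par[2L]))
    sum((viab - pred)^2)
  }
  starts <- expand.grid(
    le = log(exp(seq(log(min(conc)), log(max(conc)), length.out = 7L))),
    lh = log(c(0.5, 1, 2))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(c(starts$le[i], starts$lh[i]), obj, method = "Nelder-Mead",
            control = list(maxit = 500L, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) return(NULL)
  ic50 <- exp(best$par[1L])
  # reject fits that run off the tested range by more than a decade
  if (!is.finite(ic50) || ic50 <= 0 || ic50 > max(conc) * 10 ||
      ic50 < min(conc) / 10) {
    return(NULL)
  }
  list(ic50 = ic50, hill = exp(best$par[2L]), rss = best$value)
}

# linear interpolation of the 50% crossing in log-concentration
interpolate_ic50 <- function(conc, viab) {
  idx <- which(viab <= 0.5)[1L]
  if (is.na(idx)) stop("no 50% crossing to interpolate", call. = FALSE)
  if (idx == 1L) return(conc[1L])
  c1 <- conc[idx - 1L]; c2 <- conc[idx]
  v1 <- viab[idx - 1L]; v2 <- viab[idx]
  if (v1 == v2) return(exp((log(c1) + log(c2)) / 2))
  exp(log(c1) + (0.5 - v1) / (v2 - v1) * (log(c2) - log(c1)))
}

#' @export
print.ic50_estimate <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("IC50: right-censored at >%g uM\n", x$value))
  } else {
    cat(sprintf("IC50: %.4g uM (%s)\n", x$value, x$method))
    if (is.finite(x$hill)) cat(sprintf("  hill = %.3g, rss = %.3g\n",
                                       x$hill, x$rss))
  }
  invisible(x)
}

#' Relative gene expression by the delta-delta-Ct method
#'
#' Quantifies target-gene expression relative to a reference gene (GAPDH in
#' the assay this models) and a calibrator sample. Per condition,
#' \eqn{\Delta Ct} is the mean target Ct minus the mean reference Ct;
#' \eqn{\Delta\Delta Ct = \Delta Ct_{sample} - \Delta Ct_{calibrator}}; fold
#' change is \eqn{2^{-\Delta\Delta Ct}}.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_calibrator,ct_ref_calibrator
#'   numeric vectors of cycle-threshold replicates (triplicates in the assay
#'   modelled here; any length >= 1 accepted), all finite and positive.
#' @param thresholds optional ordered pair passed to
#'   [categorize_expression()]; when supplied the result carries a
#'   `category`.
#' @return object of class `relative_expression`: list with `fold`,
#'   `delta_delta_ct`, `delta_ct_sample`, `delta_ct_calibrator` and
#'   optionally `category`.
#' @examples
#' relative_expression(c(25, 25.2, 24.8), c(20, 20, 20),
#'                     c(27, 27, 27), c(20, 20, 20))
#' @export
relative_expression <- function(ct_target_sample, ct_ref_sample,
                                ct_target_calibrator, ct_ref_calibrator,
                                thresholds = NULL) {
  tris <- list(ct_target_sample = ct_target_sample,
               ct_ref_sample = ct_ref_sample,
               ct_target_calibrator = ct_target_calibrator,
               ct_ref_calibrator = ct_ref_calibrator)
  for (nm in names(tris)) {
    x <- tris[[nm]]
    if (length(x) < 1L) stop_field(nm, "empty Ct replicate set")
    if (!all(is.finite(x)) || any(x <= 0)) {
      stop_field(nm, "Ct values must be finite and > 0")
    }
  }
  dct_s <- mean(ct_target_sample) - mean(ct_ref_sample)
  dct_c <- mean(ct_target_calibrator) - mean(ct_ref_calibrator)
  ddct <- dct_s - dct_c
  out <- list(fold = 2^(-ddct), delta_delta_ct = ddct,
              delta_ct_sample = dct_s, delta_ct_calibrator = dct_c)
  if (!is.null(thresholds)) {
    out$category <- categorize_expression(out$fold, thresholds)
  }
  structure(out, class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("ddCt = %.4g, fold = 2^-ddCt = %.4g\n",
              x$delta_delta_ct, x$fold))
  if (!is.null(x$category)) cat("category:", x$category, "\n")
  invisible(x)
}

#' Categorize MDR1 fold expression as weak/moderate/strong
#'
#' Ordinal categorisation of a relative-expression fold change. The interval
#' is right-closed on the lower side: a fold exactly at a threshold takes the
#' lower category. The default thresholds (2- and 10-fold) are package
#' defaults, not values from any particular assay protocol, and should be set
#' to match the laboratory's own calibration.
#'
#' @param fold positive fold change (vectorised).
#' @param thresholds ordered pair `c(t1, t2)` with `0 < t1 < t2`.
#' @return character vector in `c("weak", "moderate", "strong")`.
#' @examples
#' categorize_expression(c(0.5, 2, 5, 30))
#' @export
categorize_expression <- function(fold, thresholds = c(2, 10)) {
  if (length(thresholds) != 2L || !all(is.finite(thresholds)) ||
      thresholds[1L] <= 0 || thresholds[1L] >= thresholds[2L]) {
    stop_field("thresholds", "must be an ordered pair 0 < t1 < t2")
  }
  if (any(!is.na(fold) & (!is.finite(fold) | fold <= 0))) {
    stop_field("fold", "must be > 0")
  }
  out <- ifelse(fold <= thresholds[1L], "weak",
                ifelse(fold <= thresholds[2L], "moderate", "strong"))
  out[is.na(fold)] <- NA_character_
  out
}
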