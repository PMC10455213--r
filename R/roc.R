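#' ROC analysis with Youden-index cutoff
#'
#' Evaluates a score as a predictor of a binary outcome. The AUC is computed
#' from the rank statistic (Wilcoxon-Mann-Whitney with ties counted one
#' half), its standard error by the Hanley-McNeil formula, the 95%
#' confidence interval as AUC +/- 1.96 SE truncated to \[0, 1\], and the
#' p-value from the normal test of AUC against 0.5. The operating cutoff
#' maximizes the Youden index J = sensitivity + specificity - 1 over all
#' observed score values (subjects with score >= cutoff are called
#' positive); on ties the lowest such cutoff is taken. A quality band
#' ([auc_quality_band()]) and a validity verdict (significant p < 0.05,
#' AUC > 0.5, sensitivity and specificity both above 60%) are attached.
#'
#' @param score numeric predictor (higher = more likely positive).
#' @param label binary outcome (0/1 or logical); both classes must be
#'   present.
#' @return object of class `roc_result`: list with `auc`, `se`, `ci95`, `p`,
#'   `cutoff`, `youden_j`, `sensitivity`, `specificity`, `quality_band`,
#'   `valid`, `n_pos`, `n_neg`.
#' @examples
#' roc_analysis(c(1, 2, 3, 8, 9, 10), c(0, 0, 0, 1, 1, 1))
#' @export
roc_analysis <- function(score, label) {
  if (length(score) != length(label)) {
    stop("score and label must have equal length", call. = FALSE)
  }
  label <- as.integer(label)
  ok <- is.finite(score) & !is.na(label)
  score <- score[ok]; label <- label[ok]
  if (!all(label %in% c(0L, 1L))) stop_field("label", "must be binary 0/1")
  n1 <- sum(label == 1L); n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  # AUC by midrank statistic (ties counted one half)
  rk <- rank(score)
  auc <- (sum(rk[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))
  p <- if (se == 0) {
    if (abs(auc - 0.5) < .Machine$double.eps) 1 else 0
  } else {
    2 * pnorm(-abs(auc - 0.5) / se)
  }
  # Youden cutoff over all observed thresholds (call positive if >= cutoff)
  cand <- sort(unique(score))
  sens <- vapply(cand, function(th) mean(score[label == 1L] >= th),
                 numeric(1L))
  spec <- vapply(cand, function(th) mean(score[label == 0L] < th),
                 numeric(1L))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1L]  # lowest cutoff on ties
  structure(list(auc = auc, se = se, ci95 = ci, p = p,
                 cutoff = cand[best], youden_j = j[best],
                 sensitivity = sens[best], specificity = spec[best],
                 quality_band = auc_quality_band(auc),
                 valid = p < 0.05 && auc > 0.5 && sens[best] > 0.6 &&
                   spec[best] > 0.6,
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("ROC analysis: AUC = %.3f +/- %.3f (95%% CI",
                     " %.3f-%.3f), p = %.3g [%s]\n"),
              x$auc, x$se, x$ci95[1L], x$ci95[2L], x$p, x$quality_band))
  cat(sprintf(paste0("  Youden cutoff %.3g: sensitivity %.1f%%,",
                     " specificity %.1f%% (J = %.3f); model %s\n"),
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity,
              x$youden_j, if (x$valid) "valid" else "not valid"))
  invisible(x)
}

#' AUC quality band
#'
#' Bands the area under the ROC curve: 0.9-1.0 excellent, 0.8-0.9 very
#' good, 0.7-0.8 good, 0.6-0.7 moderate, 0.5-0.6 bad (an AUC below 0.5,
#' worse than chance, is also banded bad).
#'
#' @param auc numeric in \[0, 1\] (vectorised).
#' @return character vector of bands.
#' @examples
#' auc_quality_band(c(0.816, 0.773, 0.55))
#' @export
auc_quality_band <- function(auc) {
  if (any(!is.na(auc) & (auc < 0 | auc > 1))) {
    stop_field("auc", "must lie in [0, 1]")
  }
  ifelse(auc >= 0.9, "excellent",
         ifelse(auc >= 0.8, "very good",
                ifelse(auc >= 0.7, "good",
                       ifelse(auc >= 0.6, "moderate", "bad"))))
}
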