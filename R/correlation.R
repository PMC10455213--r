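#' Ordinal coding of categorical cohort variables
#'
#' Spearman correlation of categorical variables requires a total order on
#' the levels, and the sign of r depends on it. The default coding orders
#' every variable from best to worst outcome: therapy response remission 1 /
#' relapse 2 / refractory 3; risk groups and karyotype risk favorable 1 /
#' intermediate 2 / adverse (high) 3; prognosis favorable 1 / unfavorable 2;
#' MDR1 weak 1 / moderate 2 / strong 3; sensitivity and P-gp categories
#' 1/2/3; origin primary 0 / secondary 1; binary flags 0/1. The coding used
#' is echoed into every report so that reversing a level order is always
#' visible.
#'
#' @param overrides named list of named numeric vectors replacing default
#'   level codes per variable.
#' @return object of class `variable_coding`: a named list of level->code
#'   maps.
#' @export
variable_coding <- function(overrides = list()) {
  coding <- list(
    therapy_response = c(remission = 1, relapse = 2, refractory = 3),
    risk_group = c(low = 1, intermediate = 2, high = 3),
    karyotype_risk = c(favorable = 1, intermediate = 2, adverse = 3),
    standard_prognosis = c(favorable = 1, unfavorable = 2),
    mdr1_category = c(weak = 1, moderate = 2, strong = 3),
    origin = c(primary = 0, secondary = 1),
    n_unfavorable_mutations = c(`0` = 0, `1` = 1, `2` = 2)
  )
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (!is.numeric(v) || is.null(names(v))) {
      stop_field(nm, "coding override must be a named numeric vector")
    }
    coding[[nm]] <- v
  }
  structure(coding, class = "variable_coding")
}

# apply a coding to one column; unknown/unmapped levels become NA
code_variable <- function(x, name, coding) {
  if (is.numeric(x)) return(x)
  if (is.factor(x)) x <- as.character(x)
  map <- coding[[name]]
  if (is.null(map)) {
    stop(sprintf("no ordinal coding defined for variable '%s'", name),
         call. = FALSE)
  }
  unname(map[x])
}

#' Spearman rank correlation with banded strength
#'
#' Computes Spearman's r as the Pearson correlation of midranks (so ties are
#' handled by averaging), with a two-sided p-value that is exact by full
#' permutation enumeration for n <= 10 complete pairs and the
#' t-approximation otherwise. Incomplete pairs are dropped. A constant
#' vector makes r undefined; such results are flagged and banded
#' `uninformative`.
#'
#' @param x,y numeric vectors of equal length.
#' @param exact_n largest n for which the permutation-exact p is used.
#' @return object of class `correlation_result`: list with `r`, `p`, `n`,
#'   `band`, `method` and `degenerate`.
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))  # r = 0.7
#' @export
spearman_cor <- function(x, y, exact_n = 10L) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    return(structure(list(r = NA_real_, p = NA_real_, n = n,
                          band = "uninformative", method = "none",
                          degenerate = TRUE),
                     class = "correlation_result"))
  }
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(structure(list(r = NA_real_, p = NA_real_, n = n,
                          band = "uninformative", method = "none",
                          degenerate = TRUE),
                     class = "correlation_result"))
  }
  r <- cor(rx, ry)
  if (n <= exact_n) {
    p <- spearman_perm_p(rx, ry)
    method <- "exact_permutation"
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tstat), df = n - 2)
    method <- "t_approximation"
  }
  structure(list(r = r, p = p, n = n, band = strength_band(r),
                 method = method, degenerate = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Spearman r: undefined (degenerate input, n = %d)\n", x$n))
  } else {
    cat(sprintf("Spearman r = %.3f (%s), p = %.4g (%s), n = %d\n",
                x$r, x$band, x$p, x$method, x$n))
  }
  invisible(x)
}

# all permutations of 1..n as an n! x n matrix, built by insertion
all_permutations <- function(n) {
  p <- matrix(1L, 1L, 1L)
  for (k in 2L:n) {
    m <- nrow(p)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1L) * m + seq_len(m)
      if (pos > 1L) out[rows, seq_len(pos - 1L)] <- p[, seq_len(pos - 1L)]
      out[rows, pos] <- k
      if (pos < k) out[rows, (pos + 1L):k] <- p[, pos:(k - 1L), drop = FALSE]
    }
    p <- out
  }
  p
}

# exact two-sided permutation p-value for the rank correlation
spearman_perm_p <- function(rx, ry) {
  n <- length(rx)
  perms <- all_permutations(n)
  # correlation is monotone in sum(rx * ry[perm]); center for two-sidedness
  s_obs <- sum(rx * ry)
  s <- numeric(nrow(perms))
  for (j in seq_len(n)) s <- s + rx[j] * ry[perms[, j]]
  center <- n * mean(rx) * mean(ry)
  mean(abs(s - center) >= abs(s_obs - center) - 1e-9)
}

#' Correlation strength band
#'
#' Bands the magnitude of a Spearman coefficient: |r| below 0.01 is
#' uninformative, 0.01-0.29 weak, 0.30-0.69 moderate, 0.70-1.00 strong.
#' Negative correlations are banded by magnitude; the sign is carried by r
#' itself.
#'
#' @param r correlation coefficient(s), |r| <= 1.
#' @return character vector of bands.
#' @examples
#' strength_band(c(0.72, 0.5, 0.1, 0, -0.8))
#' @export
strength_band <- function(r) {
  if (any(!is.na(r) & abs(r) > 1 + 1e-12)) stop_field("r", "|r| must be <= 1")
  a <- abs(r)
  out <- ifelse(a < 0.01, "uninformative",
                ifelse(a < 0.30, "weak",
                       ifelse(a < 0.70, "moderate", "strong")))
  out[is.na(r)] <- "uninformative"
  out
}

#' Pairwise Spearman correlation matrix
#'
#' Correlates every pair of the requested variables over pairwise-complete
#' observations, applying the ordinal coding to categorical variables.
#' Returns symmetric matrices of r, p, n and strength band, with the
#' diagonal left `NA` (as in a report table, the diagonal is omitted), a
#' significance indicator at `p <= 0.05` and cells with fewer than 3
#' overlapping observations marked unavailable.
#'
#' @param table cohort data frame (typically scored, so `risk_group` etc.
#'   are available).
#' @param variables character vector of column names to correlate.
#' @param coding a [variable_coding()].
#' @return object of class `correlation_matrix`: list of matrices `r`, `p`,
#'   `n`, `band`, `significant`, plus the `coding` used.
#' @export
correlation_matrix <- function(table, variables,
                               coding = variable_coding()) {
  miss <- setdiff(variables, names(table))
  if (length(miss)) {
    stop("unknown variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  coded <- lapply(variables, function(v) {
    xs <- table[[v]]
    if (identical(v, "risk_group")) xs <- as.character(xs)
    code_variable(xs, v, coding)
  })
  names(coded) <- variables
  k <- length(variables)
  mk <- function(fill) {
    matrix(fill, k, k, dimnames = list(variables, variables))
  }
  r <- mk(NA_real_); p <- mk(NA_real_); n <- mk(NA_integer_)
  band <- mk(NA_character_); sig <- mk(NA)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      res <- spearman_cor(coded[[i]], coded[[j]])
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p
      n[i, j] <- n[j, i] <- res$n
      band[i, j] <- band[j, i] <- res$band
      sig[i, j] <- sig[j, i] <- !is.na(res$p) && res$p <= 0.05
    }
  }
  structure(list(r = r, p = p, n = n, band = band, significant = sig,
                 coding = coding),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("Spearman correlation matrix (", nrow(x$r), " variables); * p <= 0.05\n",
      sep = "")
  disp <- matrix("", nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  for (i in seq_len(nrow(x$r))) {
    for (j in seq_len(ncol(x$r))) {
      if (i == j) { disp[i, j] <- ""; next }
      if (is.na(x$r[i, j])) { disp[i, j] <- "-"; next }
      disp[i, j] <- paste0(formatC(x$r[i, j], digits = digits,
                                   format = "f"),
                           ifelse(isTRUE(x$significant[i, j]), " *", ""))
    }
  }
  print(disp, quote = FALSE)
  invisible(x)
}

# long-format export used by the report bundle
correlation_matrix_long <- function(cm) {
  vars <- rownames(cm$r)
  idx <- which(upper.tri(cm$r), arr.ind = TRUE)
  data.frame(
    var1 = vars[idx[, 1L]], var2 = vars[idx[, 2L]],
    r = cm$r[idx], p = cm$p[idx], n = cm$n[idx], band = cm$band[idx],
    significant = cm$significant[idx], stringsAsFactors = FALSE)
}
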