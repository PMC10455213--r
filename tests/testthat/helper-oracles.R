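# independent brute-force oracles used across the suite

`%||%` <- function(a, b) if (is.null(a)) b else a

# AUC by exhaustive concordant-pair counting (ties count one half)
auc_pair_oracle <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# exhaustive Youden search over all observed thresholds (>= rule)
youden_oracle <- function(score, label) {
  cand <- sort(unique(score))
  best <- -Inf
  best_cut <- NA_real_
  for (th in cand) {
    sens <- mean(score[label == 1] >= th)
    spec <- mean(score[label == 0] < th)
    j <- sens + spec - 1
    if (j > best + 1e-12) {
      best <- j
      best_cut <- th
    }
  }
  list(cutoff = best_cut, j = best)
}

# two-group log-rank chi-square from first principles (O - E and
# hypergeometric variance summed over distinct event times)
logrank_oracle <- function(times, events, group) {
  group <- as.integer(factor(group))
  stopifnot(length(unique(group)) == 2L)
  taus <- sort(unique(times[events == 1]))
  o_minus_e <- 0
  v <- 0
  for (tau in taus) {
    at_risk <- times >= tau
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d <- sum(events == 1 & times == tau)
    d1 <- sum(events == 1 & times == tau & group == 1L)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# empirical survivor function (valid when there is no censoring)
empirical_survival <- function(times, t) {
  vapply(t, function(tt) mean(times > tt), numeric(1L))
}

# expected scale total for one combination of parameter levels, scored by
# direct table lookup (independent of score_patient's internals)
scale_total_oracle <- function(sens_cat, mdr1, origin, n_mut, age_band,
                               n_markers) {
  sens_pts <- c(`1` = 0, `2` = 1, `3` = 2)[[as.character(sens_cat)]]
  mdr_pts <- c(weak = 0, moderate = 1, strong = 2)[[mdr1]]
  origin_pts <- if (origin == "secondary") 2 else 0
  cyto_pts <- min(n_mut, 2)
  age_pts <- c(young = 0, middle = 1, old = 2)[[age_band]]
  imm_pts <- min(n_markers, 2)
  sens_pts + mdr_pts + origin_pts + cyto_pts + age_pts + imm_pts
}

risk_band_oracle <- function(total) {
  if (total <= 2) "low" else if (total <= 5) "intermediate" else "high"
}

# minimal survival data with a binary covariate and a known rate ratio
make_exponential_cohort <- function(n, hr, base_rate = 0.01,
                                    censor_at = Inf) {
  x <- rep(c(0L, 1L), length.out = n)
  t <- rexp(n, base_rate * hr^x)
  e <- as.integer(t < censor_at)
  data.frame(os_days = pmin(t, censor_at), death_event = e, x = x)
}
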