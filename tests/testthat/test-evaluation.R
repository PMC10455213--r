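test_that("therapy response classification applies the CR criteria", {
  expect_equal(classify_therapy_response(3, FALSE, FALSE, 1.5, 120),
               "remission")
  # any failed CR criterion blocks remission
  expect_equal(classify_therapy_response(6, FALSE, FALSE, 1.5, 120),
               "refractory")
  expect_equal(classify_therapy_response(3, TRUE, FALSE, 1.5, 120),
               "refractory")
  expect_equal(classify_therapy_response(3, FALSE, FALSE, 0.5, 120),
               "refractory")
  expect_equal(classify_therapy_response(3, FALSE, FALSE, 1.5, 80),
               "refractory")
  # relapse requires a prior CR
  expect_equal(classify_therapy_response(7, FALSE, FALSE, 1.5, 120,
                                         prior_cr = TRUE), "relapse")
  expect_equal(classify_therapy_response(3, TRUE, FALSE, 0.5, 80,
                                         prior_cr = TRUE), "relapse")
  expect_equal(classify_therapy_response(30, TRUE, FALSE, 0.5, 40,
                                         courses_completed = 2),
               "refractory")
  expect_error(classify_therapy_response(120, FALSE, FALSE, 1, 100),
               "bm_blasts")
  expect_error(classify_therapy_response(10, FALSE, FALSE, 1, 100,
                                         courses_completed = 3),
               "courses_completed")
})

test_that("spearman correlation matches closed forms and stays rank-based", {
  x <- 1:8
  expect_equal(spearman_cor(x, x)$r, 1)
  expect_equal(spearman_cor(x, rev(x))$r, -1)
  # hand-computed 1 - 6 sum(d^2) / (n (n^2 - 1)): d^2 sums to 4, so r = 0.8
  res <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(res$r, 1 - 6 * 4 / (5 * 24), tolerance = 1e-12)
  expect_equal(res$method, "exact_permutation")
  # exact permutation p agrees with cor.test's exact p (no ties)
  ct <- cor.test(1:5, c(2, 1, 4, 3, 5), method = "spearman")
  expect_equal(res$p, unname(ct$p.value), tolerance = 1e-12)
  # invariant under strictly monotone transforms of either argument
  set.seed(4)
  a <- rnorm(30); b <- rnorm(30)
  r0 <- spearman_cor(a, b)$r
  expect_equal(spearman_cor(exp(a), b)$r, r0, tolerance = 1e-12)
  expect_equal(spearman_cor(a, b^3)$r, r0, tolerance = 1e-12)
  expect_equal(spearman_cor(exp(a), atan(b))$r, r0, tolerance = 1e-12)
  # degenerate input is flagged, not fabricated
  res <- spearman_cor(rep(1, 10), rnorm(10))
  expect_true(res$degenerate)
  expect_equal(res$band, "uninformative")
})

test_that("correlation strength bands follow the published cut points", {
  expect_equal(strength_band(0.72), "strong")
  expect_equal(strength_band(0.5), "moderate")
  expect_equal(strength_band(0.15), "weak")
  expect_equal(strength_band(0), "uninformative")
  expect_equal(strength_band(-0.8), "strong")  # banded by magnitude
  expect_error(strength_band(1.2), "r")
})

test_that("correlation matrices are symmetric with coded variables", {
  coh <- score_cohort(generate_cohort(synthetic_config(n_patients = 53,
                                                       seed = 21)))
  vars <- c("therapy_response", "age_years", "mdr1_category", "risk_group",
            "leukocytes")
  cm <- correlation_matrix(coh, vars)
  expect_equal(cm$r, t(cm$r))
  expect_true(all(is.na(diag(cm$r))))
  expect_true(all(abs(cm$r[upper.tri(cm$r)]) <= 1, na.rm = TRUE))
  expect_error(correlation_matrix(coh, c("age_years", "shoe_size")),
               "shoe_size")
  # therapy response worsens with the scale total under default coding
  expect_gt(cm$r["therapy_response", "risk_group"], 0)
})

test_that("under a null generator large correlations appear at chance rates", {
  cfg <- synthetic_config(
    n_patients = 53, seed = 301,
    covariate_loadings = c(ic50 = 0, mdr1 = 0, mutations = 0, markers = 0,
                           pgp = 0, origin = 0, karyotype = 0,
                           prognosis = 0),
    log_hr_per_risk_step = 0)
  vars <- c("age_years", "mdr1_category", "pgp_category", "leukocytes",
            "hemoglobin", "platelets", "ldh")
  hits <- 0; cells <- 0
  for (i in 1:40) {
    cfg$seed <- 301L + i
    cm <- correlation_matrix(generate_cohort(cfg), vars)
    rs <- cm$r[upper.tri(cm$r)]
    hits <- hits + sum(abs(rs) >= 0.3, na.rm = TRUE)
    cells <- cells + sum(!is.na(rs))
  }
  # |r| >= 0.3 at n = 53 under independence is a ~2.8% event
  expect_lt(hits / cells, 0.08)
})

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  # textbook 6-subject example: times 1, 2+, 3, 4+, 5, 6
  km <- km_estimate(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 0, 1, 1))
  s_at <- function(t) km$surv[match(t, km$time)]
  expect_equal(s_at(1), 5 / 6, tolerance = 1e-12)
  expect_equal(s_at(3), 5 / 6 * 3 / 4, tolerance = 1e-12)
  expect_equal(s_at(5), 5 / 6 * 3 / 4 * 1 / 2, tolerance = 1e-12)
  expect_equal(s_at(6), 0, tolerance = 1e-12)
  expect_equal(km$median, 5)

  # without censoring the curve is the empirical survivor function
  set.seed(8)
  tt <- sample(1:400, 60, replace = TRUE)
  km <- km_estimate(tt, rep(1, 60))
  expect_equal(km$surv, empirical_survival(tt, km$time), tolerance = 1e-12)

  # all censored: flat at 1, median not reached
  km <- km_estimate(c(10, 20, 30), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  expect_true(is.na(km$median))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("log-rank statistic equals the O-E/V oracle and detects effects", {
  # two identical groups -> statistic 0
  lr <- log_rank(rep(c(5, 10, 15), 2), rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$df, 1)

  # random 10-subject toys against the first-principles statistic
  set.seed(12)
  for (i in 1:20) {
    tt <- sample(1:30, 10, replace = TRUE)
    ev <- rbinom(10, 1, 0.8)
    gg <- rep(c("a", "b"), each = 5)
    if (sum(ev) == 0) next
    lr <- log_rank(tt, ev, gg)
    expect_equal(lr$chisq, logrank_oracle(tt, ev, gg), tolerance = 1e-8)
  }

  # strongly separated groups are detected
  set.seed(13)
  t1 <- rexp(200, 0.01); t2 <- rexp(200, 0.04)
  lr <- log_rank(c(t1, t2), rep(1, 400), rep(c("a", "b"), each = 200))
  expect_lt(lr$p, 0.001)
  expect_error(log_rank(1:3, c(1, 1, 1), rep("a", 3)), "2 non-empty|groups")
})

test_that("ROC analysis matches the pair-counting oracle and pROC", {
  # perfect separation
  r <- roc_analysis(c(1, 2, 3, 8, 9, 10), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$youden_j, 1)

  set.seed(31)
  for (i in 1:30) {
    n <- sample(6:25, 1)
    score <- sample(0:12, n, replace = TRUE)   # discrete, forces ties
    label <- rbinom(n, 1, 0.5)
    if (length(unique(label)) < 2) next
    r <- roc_analysis(score, label)
    expect_equal(r$auc, auc_pair_oracle(score, label), tolerance = 1e-12)
    yo <- youden_oracle(score, label)
    expect_equal(r$cutoff, yo$cutoff)
    expect_equal(r$youden_j, yo$j, tolerance = 1e-12)
    expect_equal(r$youden_j, r$sensitivity + r$specificity - 1,
                 tolerance = 1e-12)
  }

  # independent cross-check of the rank AUC against pROC
  set.seed(32)
  score <- rnorm(80); label <- rbinom(80, 1, 0.4)
  r <- roc_analysis(score, label)
  p_auc <- as.numeric(pROC::auc(pROC::roc(label, score, quiet = TRUE,
                                          direction = "<")))
  expect_equal(r$auc, p_auc, tolerance = 1e-12)

  # label-independent scores sit near 0.5
  set.seed(33)
  r <- roc_analysis(rnorm(10000), rbinom(10000, 1, 0.5))
  expect_lt(abs(r$auc - 0.5), 0.02)
  expect_error(roc_analysis(1:5, rep(1, 5)), "both outcome classes")
})

test_that("AUC quality bands and the validity verdict follow the rules", {
  expect_equal(auc_quality_band(0.816), "very good")
  expect_equal(auc_quality_band(0.773), "good")
  expect_equal(auc_quality_band(0.55), "bad")
  expect_equal(auc_quality_band(0.95), "excellent")
  expect_equal(auc_quality_band(0.65), "moderate")
  r <- roc_analysis(c(1, 2, 3, 8, 9, 10, 2, 9), c(0, 0, 0, 1, 1, 1, 0, 1))
  expect_identical(r$valid,
                   r$p < 0.05 && r$auc > 0.5 && r$sensitivity > 0.6 &&
                     r$specificity > 0.6)
})

test_that("Cox fits recover known hazard ratios and respect PH invariance", {
  set.seed(41)
  d <- make_exponential_cohort(2000, hr = 2)
  fit <- cox_univariate(d, "x")
  co <- fit$coefficients
  se <- (log(co$ci_high) - log(co$ci_low)) / (2 * 1.96)
  expect_lt(abs(co$beta - log(2)), 3 * se)
  expect_true(co$ci_low < co$hr && co$hr < co$ci_high)

  # rescaling time leaves the hazard ratio unchanged
  d_months <- within(d, os_days <- os_days / 30.44)
  fit_m <- cox_univariate(d_months, "x")
  expect_equal(fit_m$coefficients$hr, co$hr, tolerance = 1e-8)

  # complete separation is flagged, not silently reported
  sep <- data.frame(os_days = c(1:5, 100:104),
                    death_event = rep(1, 10),
                    x = rep(c(1, 0), each = 5))
  fit_sep <- cox_univariate(sep, "x")
  expect_true(fit_sep$flagged)
})

test_that("multivariate Cox honours its covariate-selection policy", {
  set.seed(42)
  n <- 600
  x1 <- rbinom(n, 1, 0.5)      # real effect
  x2 <- rnorm(n)               # noise
  t <- rexp(n, 0.01 * exp(log(2) * x1))
  d <- data.frame(os_days = t, death_event = 1L, x1 = x1, x2 = x2)
  full <- cox_multivariate(d, c("x1", "x2"))
  expect_equal(full$policy, "enter_all")
  expect_setequal(full$retained, c("x1", "x2"))
  bw <- cox_multivariate(d, c("x1", "x2"),
                         policy = "backward_elimination")
  expect_true("x1" %in% bw$retained)
  expect_false("x2" %in% bw$retained)
  expect_error(cox_multivariate(d, c("x1", "nope")), "nope")
})
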