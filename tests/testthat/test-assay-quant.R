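test_that("viability follows the dual-wavelength blank-subtraction arithmetic", {
  # 3-replicate toy plate with hand-computable means
  mk_rows <- function(conc, a450, type) {
    data.frame(drug = "daunorubicin", concentration_uM = conc,
               replicate = seq_along(a450), a450 = a450, a620 = 0.05,
               well_type = type)
  }
  plate <- rbind(
    mk_rows(0, c(1.05, 1.15, 1.10), "untreated"),   # mean signal 1.05
    mk_rows(0, c(0.10, 0.10, 0.10), "blank"),       # mean blank 0.05
    mk_rows(0.1, c(0.85, 0.95, 0.90), "treated"),   # (0.90 - .05 - .05)/1.00
    mk_rows(0.2, c(0.55, 0.65, 0.60), "treated"),
    mk_rows(0.5, c(0.30, 0.40, 0.35), "treated"),
    mk_rows(1.0, c(0.10, 0.20, 0.15), "treated"))
  cv <- compute_viability(plate)
  expect_equal(cv$points$viability[cv$points$concentration == 0], 1)
  expect_equal(cv$points$viability[cv$points$concentration == 0.1], 0.80,
               tolerance = 1e-12)
  expect_equal(cv$points$viability[cv$points$concentration == 0.2], 0.50,
               tolerance = 1e-12)
  expect_equal(cv$points$viability[cv$points$concentration == 1.0], 0.05,
               tolerance = 1e-12)

  # treated signal equal to the zero-dose signal -> viability 1 everywhere
  same <- rbind(mk_rows(0, rep(1.05, 3), "untreated"),
                mk_rows(0, rep(0.10, 3), "blank"),
                mk_rows(0.1, rep(1.05, 3), "treated"),
                mk_rows(0.2, rep(1.05, 3), "treated"),
                mk_rows(0.5, rep(1.05, 3), "treated"),
                mk_rows(1, rep(1.05, 3), "treated"))
  expect_true(all(compute_viability(same)$points$viability == 1))

  # treated signal equal to blank -> viability 0
  dead <- rbind(mk_rows(0, rep(1.05, 3), "untreated"),
                mk_rows(0, rep(0.10, 3), "blank"),
                mk_rows(0.1, rep(0.10, 3), "treated"),
                mk_rows(0.2, rep(0.10, 3), "treated"),
                mk_rows(0.5, rep(0.10, 3), "treated"),
                mk_rows(1, rep(0.10, 3), "treated"))
  v <- compute_viability(dead)$points
  expect_true(all(v$viability[v$concentration > 0] == 0))

  # zero-dose signal at or below blank is a degenerate plate
  degen <- rbind(mk_rows(0, rep(0.10, 3), "untreated"),
                 mk_rows(0, rep(0.10, 3), "blank"),
                 mk_rows(0.1, rep(0.05, 3), "treated"),
                 mk_rows(0.2, rep(0.05, 3), "treated"),
                 mk_rows(0.5, rep(0.05, 3), "treated"),
                 mk_rows(1, rep(0.05, 3), "treated"))
  expect_error(compute_viability(degen), "degenerate")
})

test_that("noiseless plates invert exactly and stay monotone", {
  pl <- generate_plate("daunorubicin", ic50_true = 0.4, hill = 1,
                       noise_sd = 0, seed = 7)
  cv <- compute_viability(pl)
  # viability at c = IC50 is exactly one half
  expect_equal(cv$points$viability[cv$points$concentration == 0.4], 0.5)
  expect_true(all(diff(cv$points$viability) <= 1e-12))
  est <- estimate_ic50(cv)
  expect_equal(est$method, "loglogistic_fit")
  expect_equal(est$value, 0.4, tolerance = 1e-6)
  expect_equal(est$hill, 1, tolerance = 1e-4)
})

test_that("resistant samples are right-censored at the top tested dose", {
  pts <- data.frame(concentration = c(0, 0.05, 0.1, 0.2, 0.4, 0.6, 1, 2),
                    viability = c(1, 0.98, 0.96, 0.95, 0.92, 0.9, 0.85, 0.8))
  est <- estimate_ic50(pts)
  expect_true(est$censored)
  expect_equal(est$value, 2)
  expect_equal(est$method, "censored")
  # censored IC50 classifies as category 3 (low sensitivity)
  expect_equal(classify_drug_sensitivity(est$value, "daunorubicin",
                                         censored = est$censored), 3L)
})

test_that("IC50 estimation is scale-equivariant", {
  conc <- c(0, 0.05, 0.1, 0.2, 0.4, 0.6, 1, 2)
  v <- 1 / (1 + (conc / 0.3)^1.4); v[1] <- 1
  base <- estimate_ic50(data.frame(concentration = conc, viability = v))
  for (k in c(0.1, 10)) {
    scaled <- estimate_ic50(data.frame(concentration = conc * k,
                                       viability = v))
    expect_equal(scaled$value, base$value * k, tolerance = 1e-4)
  }
})

test_that("fit and interpolation agree on noiseless curves across slopes", {
  conc <- c(0, 0.05, 0.1, 0.2, 0.4, 0.6, 1, 2)
  for (h in c(0.5, 1, 2, 3)) {
    v <- 1 / (1 + (conc / 0.35)^h); v[1] <- 1
    fit <- estimate_ic50(data.frame(concentration = conc, viability = v))
    interp <- amlrisk:::interpolate_ic50(conc[-1], v[-1])
    expect_equal(fit$value, interp, tolerance = 0.05)
  }
})

test_that("estimate_ic50 rejects underpowered curves", {
  expect_error(
    estimate_ic50(data.frame(concentration = c(0, 0.1, 0.4),
                             viability = c(1, 0.6, 0.3))),
    "insufficient|at least 4")
})

test_that("delta-delta-Ct quantification follows hand arithmetic", {
  expect_equal(relative_expression(25, 20, 25, 20)$fold, 1)    # ddCt = 0
  expect_equal(relative_expression(24, 20, 25, 20)$fold, 2)    # ddCt = -1
  re <- relative_expression(c(25, 25.2, 24.8), c(20, 20, 20),
                            c(27, 27, 27), c(20, 20, 20))
  expect_equal(re$delta_delta_ct, -2, tolerance = 1e-12)
  expect_equal(re$fold, 4, tolerance = 1e-12)
  expect_error(relative_expression(numeric(0), 20, 25, 20), "empty")
  # reciprocal symmetry: fold(ddCt) * fold(-ddCt) = 1
  for (d in c(-3.2, -0.5, 0, 0.7, 2.4)) {
    f1 <- relative_expression(20 + d, 20, 20, 20)$fold
    f2 <- relative_expression(20 - d, 20, 20, 20)$fold
    expect_equal(f1 * f2, 1, tolerance = 1e-12)
  }
})

test_that("expression categories are ordered and right-closed below", {
  expect_equal(categorize_expression(c(1.9, 2, 2.1, 10, 10.1)),
               c("weak", "weak", "moderate", "moderate", "strong"))
  expect_error(categorize_expression(-1), "fold")
  expect_error(categorize_expression(3, thresholds = c(5, 2)), "thresholds")
  # monotone in fold for any valid thresholds
  lv <- c(weak = 1, moderate = 2, strong = 3)
  for (th in list(c(1.5, 4), c(2, 10), c(0.5, 20))) {
    folds <- sort(exp(seq(-2, 4, length.out = 25)))
    codes <- lv[categorize_expression(folds, th)]
    expect_true(all(diff(codes) >= 0))
  }
})

test_that("qPCR CSV ingestion pairs samples with the calibrator", {
  df <- data.frame(
    sample_id = rep(c("S1", "S1", "CAL", "CAL"), each = 3),
    gene = rep(c("MDR1", "GAPDH", "MDR1", "GAPDH"), each = 3),
    condition = rep(c("sample", "sample", "calibrator", "calibrator"),
                    each = 3),
    replicate = rep(1:3, 4),
    ct = c(25, 25.2, 24.8, 20, 20, 20, 27, 27, 27, 20, 20, 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  out <- quantify_qpcr(read_qpcr(path))
  expect_equal(out$fold, 4, tolerance = 1e-12)
  expect_equal(out$category, "moderate")
})
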