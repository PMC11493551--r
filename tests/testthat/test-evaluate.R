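test_that("McFadden's R2 is zero for the null model and large under separation-like signal", {
  tbl <- generate_outcomes(truth_params(amplitude = 0), n = 2000, seed = 1)
  m0 <- fit_bglm(tbl, "EP~1")
  expect_equal(mcfadden_r2(m0), 0, tolerance = 1e-10)

  # a nearly separated table: direct likelihood computation puts R2 > 0.9
  strong <- truth_params(b0 = -66, b_ps = 6, b_se = 0, b_ps_se = 0,
                         b_pn2 = 0, b_pn3 = 0, amplitude = 0)
  tbl2 <- generate_outcomes(strong, n = 4000, seed = 2)
  m <- fit_bglm(tbl2, "EP~PS")
  if (!m$degenerate) {
    ll <- sum(dbinom(tbl2$established, 1, fitted(m$fit), log = TRUE))
    expect_equal(1 - ll / m$null_loglik, mcfadden_r2(m), tolerance = 1e-8)
    expect_gt(mcfadden_r2(m), 0.9)
  }
})

test_that("McFadden is monotone non-decreasing with model complexity", {
  tbl <- generate_outcomes(truth_params(), n = 6000, seed = 3)
  r <- vapply(c("EP~PS", "EP~PS*PN", "EP~PS*PN*SE"),
              function(f) mcfadden_r2(fit_bglm(tbl, f)), 1)
  expect_true(all(diff(r) >= -1e-12))
})

test_that("rank AUC equals trapezoidal ROC integration on random score vectors", {
  set.seed(4)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 6), 1)) # induce ties sometimes
    expect_equal(auc_rank(scores, labels), auc_trapezoid_oracle(scores, labels),
                 tolerance = 1e-10)
  }
})

test_that("cross-validation metrics reconcile with the pooled confusion matrix", {
  tbl <- generate_outcomes(truth_params(amplitude = 0), n = 2000, seed = 5)
  cv <- cross_validate(tbl, "EP~PS", k = 10, seed = 1)
  pred <- as.integer(cv$predictions >= cv$threshold)
  y <- tbl$established
  tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y); tn <- sum(!pred & !y)
  expect_equal(unname(cv$pooled[["accuracy"]]), (tp + tn) / 2000)
  expect_equal(unname(cv$pooled[["precision"]]), tp / (tp + fp))
  expect_equal(unname(cv$pooled[["recall"]]), tp / (tp + fn))
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  expect_equal(unname(cv$pooled[["f1"]]), 2 * prec * rec / (prec + rec))
  expect_identical(sum(cv$per_fold$n), 2000L)
})

test_that("a perfect predictor scores 1 on every metric", {
  set.seed(6)
  tbl <- data.frame(PS = 2:20, PN = 1, SE = "site1", intro_day = 1)
  tbl <- tbl[rep(1:19, 40), ]
  tbl$established <- as.integer(tbl$PS >= 10)
  tbl$perfect <- tbl$established
  tbl <- as_outcome_table(tbl)
  cv <- cross_validate(tbl, established ~ perfect, k = 10, seed = 2)
  expect_equal(unname(cv$pooled), rep(1, 5), tolerance = 1e-12)
})

test_that("permuted labels drive pooled AUC to chance", {
  set.seed(7)
  aucs <- replicate(20, {
    tbl <- generate_outcomes(truth_params(amplitude = 0), n = 1200,
                             seed = sample.int(1e6, 1))
    tbl$established <- sample(tbl$established)
    cross_validate(tbl, "EP~PS", k = 10, seed = 1)$pooled[["auc"]]
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("hand confusion-matrix arithmetic is reproduced", {
  pred <- c(rep(1, 8), rep(1, 2), rep(0, 4), rep(0, 6))
  obs <- c(rep(1, 8), rep(0, 2), rep(1, 4), rep(0, 6))
  met <- estabsim:::confusion_metrics(pred, obs)
  expect_equal(unname(met["precision"]), 0.8)
  expect_equal(unname(met["recall"]), 8 / 12, tolerance = 1e-3)
  expect_equal(unname(met["f1"]), 0.727, tolerance = 1e-3)
  expect_equal(unname(met["accuracy"]), 0.7)
})

test_that("nested-model ANOVA reports deviance drops and rejects non-nested pairs", {
  tbl <- generate_outcomes(truth_params(), n = 6000, seed = 8)
  m1 <- fit_bglm(tbl, "EP~PS")
  m3 <- fit_bglm(tbl, "EP~PS*PN*SE")
  an <- anova_nested(m1, m3)
  expect_equal(an$deviance_change, m1$deviance - m3$deviance)
  expect_identical(an$df, m1$df_residual - m3$df_residual)
  expect_lt(an$p_chisq, 0.05)
  expect_true(is.finite(an$F))
  # identical formulas: zero change, p = 1
  an0 <- anova_nested(m1, fit_bglm(tbl, "EP~PS"))
  expect_equal(an0$deviance_change, 0)
  expect_equal(an0$p_chisq, 1)
  # non-nested pair
  ma <- fit_bglm(tbl, established ~ SE)
  expect_error(anova_nested(ma, fit_bglm(tbl, "EP~PS")), "not nested")
})

test_that("the null distribution of the nested test is roughly uniform", {
  set.seed(9)
  pvals <- replicate(200, {
    n <- 300
    df <- data.frame(PS = sample(2:20, n, TRUE), PN = sample(1:3, n, TRUE),
                     SE = sample(c("site1", "site2"), n, TRUE),
                     intro_day = sample(730, n, TRUE))
    df$established <- rbinom(n, 1, plogis(-1 + 0.15 * df$PS))
    tbl <- as_outcome_table(df)
    anova_nested(fit_bglm(tbl, "EP~PS"), fit_bglm(tbl, established ~ PS + SE))$p_chisq
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.001)
})

test_that("binned residuals partition rows into near-equal bins", {
  tbl <- generate_outcomes(truth_params(), n = 2000, seed = 10)
  m <- fit_bglm(tbl, "EP~PS*PN*SE")
  br <- binned_residuals(m)
  expect_identical(sum(br$n), 2000L)
  expect_lte(diff(range(br$n)), 1L)
  expect_error(binned_residuals(m, n_bins = 5000), "exceeds")
})

test_that("a well-specified model keeps most bins inside the 2 SE band", {
  set.seed(11)
  frac <- replicate(20, {
    tbl <- generate_outcomes(truth_params(amplitude = 0), n = 1500,
                             seed = sample.int(1e6, 1))
    mean(binned_residuals(fit_bglm(tbl, "EP~PS*PN*SE"))$inside)
  })
  expect_gt(mean(frac), 0.90)
})

test_that("omitting a strong site effect leaves site-signed residual structure", {
  truth <- truth_params(b_se = -2.5, amplitude = 0)
  tbl <- generate_outcomes(truth, n = 6000, seed = 12)
  m <- fit_bglm(tbl, "EP~PS") # misspecified: SE omitted
  res <- tbl$established - fitted(m$fit)
  expect_gt(mean(res[tbl$SE == "site1"]), 0)
  expect_lt(mean(res[tbl$SE == "site2"]), 0)
})

test_that("Tukey HSD separates distant group means and covers all pairs", {
  set.seed(13)
  df <- data.frame(PS = 10, PN = rep(1:3, each = 200), SE = "site1",
                   intro_day = 1,
                   established = rbinom(600, 1, rep(c(0.1, 0.1, 0.9), each = 200)))
  tbl <- as_outcome_table(df)
  tk <- tukey_hsd(tbl, group = tbl$PN)
  expect_identical(nrow(tk), 3L)
  p31 <- tk$p_adj[tk$group1 == "3" & tk$group2 == "1"]
  expect_lt(p31, 0.05)
  p21 <- tk$p_adj[tk$group1 == "2" & tk$group2 == "1"]
  expect_gt(p21, 0.5)
})

test_that("compiled series cover every day of year and track a flat signal flatly", {
  tbl <- generate_outcomes(truth_params(amplitude = 0), n = 12000, seed = 14)
  ws <- running_window_fit(tbl, "EP~PS")
  ws <- evaluate_windows(ws)
  ts <- compile_series(ws, "mcfadden")
  expect_identical(nrow(ts), 365L)
  dev <- compile_series(ws, "residual_deviance")
  expect_true(all(is.finite(dev$value[!dev$flag])))
  # flat generator: the intercept series shows no seasonal swing
  int <- compile_series(ws, "estimate:(Intercept)")
  expect_lt(sd(int$value, na.rm = TRUE), 0.25)
})

test_that("series extrema align with the generator phase", {
  truth <- truth_params(amplitude = 1.2, phase = 310)
  tbl <- generate_outcomes(truth, n = 18000, seed = 15)
  ws <- running_window_fit(tbl, "EP~PS")
  int <- compile_series(ws, "estimate:(Intercept)")
  # phase of the best-fitting cosine through the series
  th <- 2 * pi * int$day_of_year / 365
  cf <- coef(lm(int$value ~ cos(th) + sin(th)))
  peak <- (atan2(cf[3], cf[2]) / (2 * pi) * 365) %% 365
  delta <- min(abs(peak - 310), 365 - abs(peak - 310))
  expect_lte(delta, 15)
})
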