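make_table <- function(n, truth = truth_params(amplitude = 0), seed = 1) {
  generate_outcomes(truth, n = n, seed = seed)
}

test_that("an intercept-only fit recovers logit of the observed rate", {
  tbl <- make_table(400, seed = 2)
  m <- fit_bglm(tbl, "EP~1")
  expect_false(m$degenerate)
  expect_equal(unname(m$coefficients[1]), qlogis(mean(tbl$established)),
               tolerance = 1e-8)
  expect_equal(m$loglik, m$null_loglik, tolerance = 1e-8)
})

test_that("the fitter matches a brute-force likelihood-grid oracle", {
  set.seed(3)
  for (rep in 1:3) {
    tbl <- make_table(40, seed = 30 + rep)
    m <- fit_bglm(tbl, "EP~PS")
    oracle <- grid_logit_oracle(tbl$PS, tbl$established)
    expect_lt(max(abs(unname(m$coefficients) - oracle)), 1e-3)
  }
})

test_that("complete separation is detected and coefficients withheld", {
  tbl <- data.frame(PS = rep(2:20, 4), PN = 1, SE = "site1", intro_day = 1)
  tbl$established <- as.integer(tbl$PS >= 10)
  tbl <- as_outcome_table(tbl)
  m <- fit_bglm(tbl, "EP~PS")
  expect_true(m$degenerate)
  expect_match(m$reason, "separation")
  expect_null(m$coefficients)
})

test_that("single-class outcomes are flagged degenerate, never a crash", {
  tbl <- make_table(50, seed = 4)
  tbl$established <- 1L
  m <- fit_bglm(tbl, "EP~PS")
  expect_true(m$degenerate)
  expect_match(m$reason, "single-class")
})

test_that("deviance additivity and model nesting hold on every fit", {
  tbl <- make_table(3000, truth_params(amplitude = 0.3), seed = 5)
  m1 <- fit_bglm(tbl, "EP~PS")
  m2 <- fit_bglm(tbl, "EP~PS*PN")
  m3 <- fit_bglm(tbl, "EP~PS*PN*SE")
  for (m in list(m1, m2, m3))
    expect_equal(m$null_deviance - m$deviance, 2 * (m$loglik - m$null_loglik),
                 tolerance = 1e-8)
  expect_gte(m1$deviance, m2$deviance)
  expect_gte(m2$deviance, m3$deviance)
  expect_lte(m1$loglik, m2$loglik)
  expect_lte(m2$loglik, m3$loglik)
})

test_that("the running window builds 365 centre-indexed entries", {
  tbl <- make_table(8000, truth_params(amplitude = 0.4), seed = 6)
  ws <- running_window_fit(tbl, "EP~PS")
  expect_length(ws$fits, 365)
  expect_identical(ws$window_start[1], 1L)
  expect_identical(ws$day_of_year[1], 45L)
  expect_identical(ws$day_of_year[365], ((365L + 44L - 1L) %% 365L) + 1L)
  # window 1 equals a direct fit on intro days 1-90
  direct <- fit_bglm(tbl[tbl$intro_day <= 90, ], "EP~PS")
  expect_equal(ws$fits[[1]]$coefficients, direct$coefficients, tolerance = 1e-10)
  expect_identical(ws$n_obs[1], sum(tbl$intro_day <= 90))
})

test_that("a window spanning the whole design reduces to the static fit", {
  tbl <- make_table(2000, seed = 7)
  ws <- running_window_fit(tbl, "EP~PS", window = 730, n_windows = 1)
  static <- fit_bglm(tbl, "EP~PS")
  expect_equal(ws$fits[[1]]$coefficients, static$coefficients, tolerance = 1e-10)
})

test_that("thin windows are flagged against the n floor, not fitted", {
  tbl <- make_table(400, seed = 8)
  tbl <- tbl[tbl$intro_day > 200, ] # windows early in the year go empty
  ws <- running_window_fit(tbl, "EP~PS", min_n = 30)
  expect_true(any(ws$degenerate))
  expect_true(all(ws$n_obs[ws$degenerate &
                             grepl("floor", ws$reason)] < 30))
  expect_length(ws$fits, 365)
})

test_that("predictions are probabilities bracketed by their Wald interval", {
  tbl <- make_table(2000, seed = 9)
  m <- fit_bglm(tbl, "EP~PS*PN*SE")
  nd <- expand.grid(PS = c(2, 10, 20), PN = factor(1:3), SE = c("site1", "site2"))
  p <- predict_ep(m, nd)
  expect_true(all(p$lo <= p$ep & p$ep <= p$hi))
  expect_true(all(p$lo >= 0 & p$hi <= 1))
})

test_that("the Wald interval matches the closed form on an intercept-only model", {
  tbl <- make_table(100, seed = 10)
  tbl$established <- rep(c(0L, 1L), 50) # exactly 50 successes
  m <- fit_bglm(tbl, "EP~1")
  p <- predict_ep(m, data.frame(PS = 1))
  se <- sqrt(1 / 50 + 1 / 50) # textbook SE of a logit with n=100, k=50
  expect_equal(p$ep, 0.5, tolerance = 1e-8)
  expect_equal(p$lo, plogis(0 - 1.959964 * se), tolerance = 1e-6)
  expect_equal(p$hi, plogis(0 + 1.959964 * se), tolerance = 1e-6)
})

test_that("unseen factor levels are rejected by name", {
  tbl <- make_table(500, seed = 11)
  m <- fit_bglm(tbl, established ~ PS * SE)
  expect_error(predict_ep(m, data.frame(PS = 5, SE = "site3")), "site3")
})

test_that("interval-overlap significance follows the half-arm overlap rule", {
  expect_identical(ci_overlap_significance(0.5, 0.4, 0.6, 0.5, 0.4, 0.6),
                   "not_significant")
  expect_identical(ci_overlap_significance(0.2, 0.1, 0.3, 0.8, 0.7, 0.9),
                   "significant")
  # overlap exactly half the shorter proximal arm
  expect_identical(ci_overlap_significance(0.4, 0.3, 0.5, 0.55, 0.45, 0.65),
                   "borderline")
  # order of arguments is irrelevant
  expect_identical(ci_overlap_significance(0.8, 0.7, 0.9, 0.2, 0.1, 0.3),
                   "significant")
})
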