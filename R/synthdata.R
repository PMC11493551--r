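#' Ground-truth parameters for synthetic outcome tables
#'
#' The generating logistic model for [generate_outcomes()]:
#' `logit(p) = b0 + b_ps*PS + b_se*[SE=site2] + b_ps_se*PS*[SE=site2] +
#' b_pn2*[PN=2] + b_pn3*[PN=3] + A*cos(2*pi*(intro_day - phase)/365)`.
#' Seasonality enters through the intercept only, on the logit scale;
#' establishment probability peaks for introductions `phase` days into
#' the year. Defaults caricature the study system: establishment rises
#' steeply with propagule size, the fragmented site2 sits below the
#' packed site1, propagule number matters little, and timing peaks just
#' before the wet-season breeding pulse.
#'
#' @param b0,b_ps,b_se,b_ps_se,b_pn2,b_pn3 logit-scale coefficients.
#' @param amplitude seasonal amplitude `A >= 0` (logit scale).
#' @param phase peak day of year in `[1, 365]`.
#' @return a `truth_params` list.
#' @export
truth_params <- function(b0 = -1.5, b_ps = 0.22, b_se = -1.1, b_ps_se = 0.03,
                         b_pn2 = 0.15, b_pn3 = 0.2, amplitude = 0.5, phase = 310) {
  if (amplitude < 0) stop_with("amplitude must be >= 0")
  if (phase < 1 || phase > 365) stop_with("phase must lie in [1, 365]")
  p <- list(b0 = b0, b_ps = b_ps, b_se = b_se, b_ps_se = b_ps_se,
            b_pn2 = b_pn2, b_pn3 = b_pn3, amplitude = amplitude, phase = phase)
  if (any(!vapply(p, is.finite, TRUE))) stop_with("truth parameters must be finite")
  class(p) <- "truth_params"
  p
}

#' Linear predictor of the generating model
#'
#' @param truth a [truth_params()] list.
#' @param PS,PN,SE,intro_day predictor vectors (PN in 1-3, SE
#'   `"site1"`/`"site2"`).
#' @return logit-scale linear predictor.
#' @export
truth_logit <- function(truth, PS, PN, SE, intro_day) {
  s2 <- as.integer(as.character(SE) == "site2")
  pn <- as.integer(as.character(PN))
  truth$b0 + truth$b_ps * PS + truth$b_se * s2 + truth$b_ps_se * PS * s2 +
    truth$b_pn2 * (pn == 2L) + truth$b_pn3 * (pn == 3L) +
    truth$amplitude * cos(2 * pi * (day_of_year(intro_day) - truth$phase) / 365)
}

#' Generate a synthetic outcome table with known structure
#'
#' Samples predictors as in the scenario design (PS uniform on 2-20, PN
#' on 1-3, SE on the two sites, first introduction day on 1-730) and
#' draws `established ~ Bernoulli(plogis(truth_logit(...)))`, so every
#' statistical stage can be tested against known coefficients and a known
#' seasonal signal without running the simulator.
#'
#' @param truth a [truth_params()] list.
#' @param n number of rows (default 18000, the study-scale batch size).
#' @param seed integer seed.
#' @return an [as_outcome_table()] data frame, with `truth` attached as
#'   an attribute.
#' @export
generate_outcomes <- function(truth = truth_params(), n = 18000L, seed = 1L) {
  stopifnot(inherits(truth, "truth_params"), n >= 1)
  set.seed(as.integer(seed))
  n <- as.integer(n)
  df <- data.frame(
    PS = sample(2:20, n, replace = TRUE),
    PN = sample(1:3, n, replace = TRUE),
    SE = sample(c("site1", "site2"), n, replace = TRUE),
    intro_day = sample(1:730, n, replace = TRUE))
  p <- stats::plogis(truth_logit(truth, df$PS, df$PN, df$SE, df$intro_day))
  df$established <- as.integer(stats::runif(n) < p)
  out <- as_outcome_table(df)
  attr(out, "truth") <- truth
  out
}

#' Write the truth parameters of a synthetic table to a sidecar JSON
#'
#' @param table a [generate_outcomes()] result.
#' @param path JSON path.
#' @export
write_truth_sidecar <- function(table, path) {
  truth <- attr(table, "truth")
  if (is.null(truth)) stop_with("table carries no truth attribute")
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
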