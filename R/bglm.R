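#' Model formulas of the establishment GLMs
#'
#' The three nested binomial GLMs of establishment probability: propagule
#' size only (`"EP~PS"`), its interaction with propagule number
#' (`"EP~PS*PN"`), and the full interaction with the spatial environment
#' (`"EP~PS*PN*SE"`). Any other R formula on the outcome-table columns is
#' also accepted by the fitting functions.
#'
#' @param tag one of `"EP~PS"`, `"EP~PS*PN"`, `"EP~PS*PN*SE"`, `"EP~1"`,
#'   or an R formula.
#' @return an R formula with `established` as the response.
#' @export
bglm_formula <- function(tag) {
  if (inherits(tag, "formula")) return(tag)
  switch(tag,
         "EP~1" = established ~ 1,
         "EP~PS" = established ~ PS,
         "EP~PS*PN" = established ~ PS * PN,
         "EP~PS*PN*SE" = established ~ PS * PN * SE,
         stop_with("unknown model tag '%s'", tag))
}

#' Fit a binomial GLM of establishment
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]) of the binary establishment outcome on the
#' design predictors, with treatment contrasts (reference levels PN = 1,
#' SE = site1). Degenerate inputs -- a single outcome class, complete
#' separation, or non-convergence -- are flagged rather than crashing:
#' the returned fit carries `degenerate = TRUE` with a reason, and its
#' coefficients are withheld.
#'
#' @param table an [as_outcome_table()] data frame.
#' @param formula a tag or formula accepted by [bglm_formula()].
#' @return a `bglm_fit`: the formula tag, coefficients, covariance,
#'   log-likelihoods (model and intercept-only null), deviances, residual
#'   df, `n`, `degenerate` flag and the underlying `glm` object.
#' @export
fit_bglm <- function(table, formula = "EP~PS") {
  if (nrow(table) == 0) stop_with("cannot fit a bGLM on an empty table")
  fml <- bglm_formula(formula)
  tag <- if (is.character(formula)) formula else deparse(fml)
  mk <- function(degenerate, reason, fit = NULL, null_ll = NA_real_) {
    structure(list(
      formula = tag, fit = fit,
      coefficients = if (!degenerate && !is.null(fit)) stats::coef(fit) else NULL,
      vcov = if (!degenerate && !is.null(fit)) stats::vcov(fit) else NULL,
      loglik = if (!is.null(fit)) as.numeric(stats::logLik(fit)) else NA_real_,
      null_loglik = null_ll,
      deviance = if (!is.null(fit)) fit$deviance else NA_real_,
      null_deviance = if (!is.null(fit)) fit$null.deviance else NA_real_,
      df_residual = if (!is.null(fit)) fit$df.residual else NA_integer_,
      n = nrow(table),
      degenerate = degenerate, reason = reason), class = "bglm_fit")
  }
  y <- table$established
  if (length(unique(y)) < 2 && !identical(fml, established ~ 1)) {
    return(mk(TRUE, "single-class outcome"))
  }
  separated <- FALSE
  w <- NULL
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = table),
    warning = function(cond) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(cond)))
        separated <<- TRUE
      else w <<- cond
      invokeRestart("muffleWarning")
    })
  null_ll <- {
    p0 <- mean(y)
    if (p0 %in% c(0, 1)) 0 else sum(y * log(p0) + (1 - y) * log(1 - p0))
  }
  if (separated) {
    # perfect separation: fitted values collapse onto the observed classes
    fv <- stats::fitted(fit)
    if (all(abs(fv - y) < 1e-6)) return(mk(TRUE, "complete separation", fit, null_ll))
  }
  if (!fit$converged) return(mk(TRUE, "did not converge", fit, null_ll))
  mk(FALSE, NA_character_, fit, null_ll)
}

#' @export
print.bglm_fit <- function(x, ...) {
  cat(sprintf("<bglm_fit> %s on n=%d\n", x$formula, x$n))
  if (x$degenerate) {
    cat("  degenerate:", x$reason, "\n")
  } else {
    cat(sprintf("  logLik %.2f (null %.2f), residual deviance %.2f on %d df\n",
                x$loglik, x$null_loglik, x$deviance, x$df_residual))
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

#' Fit the running-window series of establishment GLMs
#'
#' Orders outcomes by first-introduction day and fits the model on every
#' 90-day window of introduction days advanced one day at a time: window
#' `k` covers first-introduction days `[k, k+89]` for `k = 1..365` over
#' the two-year introduction span, and is indexed to day of year
#' `((k + 44 - 1) mod 365) + 1`, the centre of the window (window 1 =
#' days 1-90, centred on day 45, 14 February). Windows with fewer than
#' `min_n` rows or a degenerate fit are carried with a flag, not fitted.
#'
#' @param table an [as_outcome_table()] data frame whose `intro_day`
#'   spans the windows requested.
#' @param formula a tag or formula accepted by [bglm_formula()].
#' @param window window length in days (default 90).
#' @param step step between successive windows (default 1 day).
#' @param n_windows number of windows (default 365, one per day of year).
#' @param min_n minimum rows for a window to be fitted (default 30).
#' @return a `window_series` with one entry per window: `window_start`,
#'   `day_of_year`, `n_obs`, `degenerate`, and the `bglm_fit` objects.
#' @export
running_window_fit <- function(table, formula = "EP~PS*PN*SE", window = 90L,
                               step = 1L, n_windows = 365L, min_n = 30L) {
  stopifnot(window >= 1, step >= 1, n_windows >= 1)
  starts <- 1L + (seq_len(n_windows) - 1L) * as.integer(step)
  half <- (as.integer(window) %/% 2L)
  centre <- starts + half - 1L
  doy <- ((centre - 1L) %% 365L) + 1L
  ord <- order(table$intro_day)
  table <- table[ord, , drop = FALSE]
  fits <- vector("list", n_windows)
  n_obs <- integer(n_windows)
  degenerate <- logical(n_windows)
  reason <- character(n_windows)
  for (i in seq_len(n_windows)) {
    k <- starts[i]
    rows <- table$intro_day >= k & table$intro_day <= k + window - 1L
    n_obs[i] <- sum(rows)
    if (n_obs[i] < min_n) {
      degenerate[i] <- TRUE
      reason[i] <- sprintf("n below floor (%d < %d)", n_obs[i], min_n)
      next
    }
    f <- fit_bglm(table[rows, , drop = FALSE], formula)
    fits[[i]] <- f
    degenerate[i] <- f$degenerate
    reason[i] <- if (f$degenerate) f$reason else NA_character_
  }
  structure(list(formula = if (is.character(formula)) formula else deparse(bglm_formula(formula)),
                 window = as.integer(window), step = as.integer(step),
                 window_start = starts, day_of_year = doy,
                 n_obs = n_obs, degenerate = degenerate, reason = reason,
                 fits = fits),
            class = "window_series")
}

#' @export
print.window_series <- function(x, ...) {
  cat(sprintf("<window_series> %s: %d windows of %d days (step %d), %d fitted, %d flagged\n",
              x$formula, length(x$window_start), x$window, x$step,
              sum(!x$degenerate), sum(x$degenerate)))
  invisible(x)
}

#' Extract a term-level data frame from a window series
#'
#' @param x a [running_window_fit()] result.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data frame `day_of_year,term,estimate,se,n_obs,degenerate`.
#' @export
as.data.frame.window_series <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- lapply(seq_along(x$fits), function(i) {
    f <- x$fits[[i]]
    if (is.null(f) || f$degenerate) {
      data.frame(day_of_year = x$day_of_year[i], term = NA_character_,
                 estimate = NA_real_, se = NA_real_,
                 n_obs = x$n_obs[i], degenerate = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(day_of_year = x$day_of_year[i], term = names(f$coefficients),
                 estimate = unname(f$coefficients),
                 se = sqrt(diag(f$vcov)),
                 n_obs = x$n_obs[i], degenerate = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict establishment probability with a Wald interval
#'
#' Point estimate `plogis(x'beta)` with a 95% confidence interval from
#' the Wald interval `x'beta +/- 1.96 sqrt(x' Sigma x)` on the link
#' scale, back-transformed, so all three outputs lie in `[0, 1]` and
#' bracket the point estimate.
#'
#' @param model a non-degenerate `bglm_fit`.
#' @param newdata data frame of predictor values; factor levels must have
#'   been seen in training.
#' @param level confidence level (default 0.95).
#' @return data frame `ep`, `lo`, `hi`, one row per `newdata` row.
#' @export
predict_ep <- function(model, newdata, level = 0.95) {
  stopifnot(inherits(model, "bglm_fit"))
  if (model$degenerate)
    stop_with("cannot predict from a degenerate fit (%s)", model$reason)
  tt <- stats::delete.response(stats::terms(model$fit))
  xl <- model$fit$xlevels
  for (v in names(xl)) {
    if (v %in% names(newdata)) {
      vals <- as.character(newdata[[v]])
      bad <- setdiff(unique(vals), xl[[v]])
      if (length(bad))
        stop_with("factor '%s' has level(s) not seen in training: %s",
                  v, paste(bad, collapse = ", "))
      newdata[[v]] <- factor(vals, levels = xl[[v]])
    }
  }
  mf <- stats::model.frame(tt, newdata, xlev = xl)
  X <- stats::model.matrix(tt, mf, contrasts.arg = model$fit$contrasts)
  eta <- drop(X %*% model$coefficients)
  se <- sqrt(rowSums((X %*% model$vcov) * X))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(ep = stats::plogis(eta),
             lo = stats::plogis(eta - z * se),
             hi = stats::plogis(eta + z * se))
}

#' Approximate significance from confidence-interval overlap
#'
#' Implements the visual-inference rule that an overlap of half the
#' length of one 95% confidence-interval arm corresponds approximately to
#' significance at p = 0.05 (the standard visual-inference half-arm rule):
#' two estimates are flagged
#' `"significant"` when their intervals overlap by less than half the
#' shorter of the two proximal arms, `"borderline"` at exactly half, and
#' `"not_significant"` otherwise.
#'
#' @param est1,est2 point estimates.
#' @param lo1,hi1,lo2,hi2 interval endpoints.
#' @param tol numeric tolerance for the boundary case.
#' @return character flag.
#' @export
ci_overlap_significance <- function(est1, lo1, hi1, est2, lo2, hi2, tol = 1e-9) {
  stopifnot(lo1 <= est1, est1 <= hi1, lo2 <= est2, est2 <= hi2)
  if (est1 > est2) {
    # ensure estimate 1 is the lower one; proximal arms face each other
    return(ci_overlap_significance(est2, lo2, hi2, est1, lo1, hi1, tol))
  }
  overlap <- hi1 - lo2 # signed: negative means disjoint
  arm1 <- hi1 - est1 # upper arm of the lower estimate
  arm2 <- est2 - lo2 # lower arm of the upper estimate
  half_arm <- min(arm1, arm2) / 2
  if (overlap < half_arm - tol) "significant"
  else if (overlap <= half_arm + tol) "borderline"
  else "not_significant"
}
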