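#' McFadden's pseudo R-squared
#'
#' `1 - l_model / l_null`, the proportional improvement in log-likelihood
#' over the intercept-only model; 0 for a model with no predictive power,
#' approaching 1 for near-perfect fits.
#'
#' @param model a `bglm_fit`.
#' @return a value in `[0, 1)`, or `NA` with a warning when the null
#'   log-likelihood is zero (all outcomes identical).
#' @export
mcfadden_r2 <- function(model) {
  stopifnot(inherits(model, "bglm_fit"))
  if (is.na(model$loglik) || model$degenerate && is.null(model$fit)) return(NA_real_)
  if (model$null_loglik == 0) {
    warning("null log-likelihood is 0 (degenerate all-equal outcome); McFadden undefined")
    return(NA_real_)
  }
  1 - model$loglik / model$null_loglik
}

#' AUC by the rank (Mann-Whitney) formulation
#'
#' Probability that a random positive scores above a random negative,
#' with ties counted half -- computed from midranks.
#'
#' @param scores numeric predicted scores.
#' @param labels binary 0/1 outcomes.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_with("AUC needs both outcome classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_metrics <- function(pred, obs) {
  tp <- sum(pred == 1 & obs == 1); fp <- sum(pred == 1 & obs == 0)
  fn <- sum(pred == 0 & obs == 1); tn <- sum(pred == 0 & obs == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(accuracy = (tp + tn) / (tp + fp + fn + tn),
    precision = precision, recall = recall, f1 = f1)
}

#' Stratified k-fold cross-validation of an establishment GLM
#'
#' Rows are partitioned into `k` folds stratified by outcome; each fold
#' is held out once while the model is refit on the remaining `k - 1`
#' folds and scored on the held-out rows. Class metrics use the
#' `threshold` on predicted probability; AUC uses the rank formulation.
#' If a fold would lose an outcome class the partition is redrawn with a
#' fresh seed (recorded in `refolds`).
#'
#' @param table an [as_outcome_table()] data frame.
#' @param formula a tag or formula accepted by [bglm_formula()].
#' @param k folds (default 10).
#' @param seed fold-assignment seed.
#' @param threshold classification threshold (default 0.5).
#' @return a `cv_report`: `pooled` metrics (accuracy, precision, recall,
#'   F1, AUC over all held-out predictions), `per_fold` data frame,
#'   `k`, `seed`, `threshold`, `refolds`.
#' @export
cross_validate <- function(table, formula = "EP~PS", k = 10L, seed = 1L,
                           threshold = 0.5) {
  n <- nrow(table)
  stopifnot(n >= k, k >= 2)
  y <- table$established
  if (length(unique(y)) < 2) stop_with("cross-validation needs both outcome classes")
  refolds <- 0L
  repeat {
    set.seed(as.integer(seed) + refolds)
    fold <- integer(n)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    ok <- all(vapply(seq_len(k), function(f) length(unique(y[fold != f])) == 2, TRUE))
    if (ok) break
    refolds <- refolds + 1L
    if (refolds > 25L) stop_with("could not build folds keeping both classes; table too small")
  }
  pred <- numeric(n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    train <- table[fold != f, , drop = FALSE]
    test <- table[fold == f, , drop = FALSE]
    m <- fit_bglm(train, formula)
    p <- if (!m$degenerate) {
      predict_ep(m, test)$ep
    } else if (!is.null(m$fit)) {
      # separated or unconverged training folds can still score the held-out
      # rows from the fitted surface; intervals are meaningless, points not
      suppressWarnings(unname(stats::predict(m$fit, test, type = "response")))
    } else {
      rep(mean(train$established), nrow(test))
    }
    pred[fold == f] <- p
    cls <- as.integer(p >= threshold)
    met <- confusion_metrics(cls, test$established)
    auc <- if (length(unique(test$established)) == 2) auc_rank(p, test$established) else NA_real_
    per_fold[[f]] <- data.frame(fold = f, n = nrow(test), t(met), auc = auc)
  }
  cls <- as.integer(pred >= threshold)
  pooled <- c(confusion_metrics(cls, y), auc = auc_rank(pred, y))
  structure(list(pooled = pooled, per_fold = do.call(rbind, per_fold),
                 predictions = pred, k = as.integer(k), seed = as.integer(seed),
                 threshold = threshold, refolds = refolds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold (seed %d, threshold %.2f)%s\n", x$k, x$seed,
              x$threshold, if (x$refolds) sprintf(", %d refolds", x$refolds) else ""))
  print(round(x$pooled, 3))
  invisible(x)
}

#' Nested-model deviance ANOVA
#'
#' Compares two nested establishment GLMs by the change in residual
#' deviance. The chi-square test is the primary test for binomial GLMs;
#' an F statistic (mean deviance change over the Pearson dispersion of
#' the larger model) is reported alongside.
#'
#' @param model_small,model_big nested `bglm_fit`s on the same data (the
#'   smaller model's terms must be a subset of the larger's).
#' @return data frame with `df`, `deviance_change`, `p_chisq`, `F`,
#'   `p_F`.
#' @export
anova_nested <- function(model_small, model_big) {
  stopifnot(inherits(model_small, "bglm_fit"), inherits(model_big, "bglm_fit"))
  if (model_small$degenerate || model_big$degenerate)
    stop_with("cannot compare degenerate fits")
  if (model_small$n != model_big$n)
    stop_with("models were fitted on different numbers of rows")
  t_small <- attr(stats::terms(model_small$fit), "term.labels")
  t_big <- attr(stats::terms(model_big$fit), "term.labels")
  if (!all(t_small %in% t_big))
    stop_with("models are not nested: '%s' is not contained in '%s'",
              model_small$formula, model_big$formula)
  dd <- model_small$deviance - model_big$deviance
  dfd <- model_small$df_residual - model_big$df_residual
  if (dfd == 0) {
    return(data.frame(df = 0L, deviance_change = dd, p_chisq = 1,
                      F = NA_real_, p_F = 1))
  }
  p_chi <- stats::pchisq(dd, dfd, lower.tail = FALSE)
  disp <- sum(stats::residuals(model_big$fit, type = "pearson")^2) /
    model_big$df_residual
  Fstat <- (dd / dfd) / disp
  p_F <- stats::pf(Fstat, dfd, model_big$df_residual, lower.tail = FALSE)
  data.frame(df = dfd, deviance_change = dd, p_chisq = p_chi, F = Fstat, p_F = p_F)
}

#' Binned residual diagnostics
#'
#' Rows are sorted by fitted probability and cut into near-equal bins
#' (default `floor(sqrt(n))`); each bin reports its mean fitted value,
#' mean raw residual and a `+/- 2 SE` band from the binomial variance of
#' the fitted probabilities. A well-specified model keeps most bin means
#' inside the band.
#'
#' @param model a non-degenerate `bglm_fit`.
#' @param n_bins number of bins (default `floor(sqrt(n))`).
#' @return a `binned_residuals` data frame: `bin`, `n`, `mean_fitted`,
#'   `mean_residual`, `se`, `lo`, `hi`, `inside`.
#' @export
binned_residuals <- function(model, n_bins = NULL) {
  stopifnot(inherits(model, "bglm_fit"))
  if (model$degenerate) stop_with("cannot bin residuals of a degenerate fit")
  p <- stats::fitted(model$fit)
  y <- model$fit$y
  n <- length(p)
  n_bins <- as.integer(n_bins %||% floor(sqrt(n)))
  if (n_bins > n) stop_with("n_bins (%d) exceeds the number of rows (%d)", n_bins, n)
  ord <- order(p)
  bin <- rep(seq_len(n_bins), times = diff(floor(seq(0, n, length.out = n_bins + 1))))
  bin <- bin[order(ord)] # map back to row order
  res <- y - p
  agg <- function(v, f) as.numeric(tapply(v, bin, f))
  nb <- as.integer(tapply(rep(1, n), bin, sum))
  mf <- agg(p, mean)
  mr <- agg(res, mean)
  se <- sqrt(as.numeric(tapply(p * (1 - p), bin, sum))) / nb
  out <- data.frame(bin = seq_len(n_bins), n = nb, mean_fitted = mf,
                    mean_residual = mr, se = se, lo = -2 * se, hi = 2 * se,
                    inside = abs(mr) <= 2 * se)
  class(out) <- c("binned_residuals", "data.frame")
  out
}

#' Tukey honest-significant-difference test on grouped outcomes
#'
#' All pairwise mean differences of replicate-level establishment
#' outcomes between factor-combination groups, with studentised-range
#' adjusted intervals and p-values ([stats::TukeyHSD()] on a one-way
#' `aov`). Groups default to the spatial-environment by propagule-number
#' combinations. Singleton groups are excluded with a message.
#'
#' @param table an outcome table.
#' @param group a factor of group labels (default `interaction(SE, PN)`).
#' @param conf_level confidence level.
#' @return data frame `group1,group2,diff,lwr,upr,p_adj` with
#'   `k*(k-1)/2` rows for `k` groups.
#' @export
tukey_hsd <- function(table, group = NULL, conf_level = 0.95) {
  group <- group %||% interaction(table$SE, table$PN, drop = TRUE)
  group <- factor(group)
  y <- table$established
  sizes <- table(group)
  if (any(sizes < 2)) {
    drop <- names(sizes)[sizes < 2]
    message("excluding singleton group(s): ", paste(drop, collapse = ", "))
    keep <- !group %in% drop
    group <- droplevels(group[keep]); y <- y[keep]
  }
  if (nlevels(group) < 2) stop_with("Tukey HSD needs at least two groups with n >= 2")
  fit <- stats::aov(y ~ g, data = data.frame(y = y, g = group))
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group1 = vapply(pairs, `[`, "", 1L),
             group2 = vapply(pairs, `[`, "", 2L),
             diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"], row.names = NULL)
}

#' Evaluate every window of a running-window series
#'
#' Computes per-window goodness-of-fit (McFadden's R2, residual deviance)
#' and, optionally, 10-fold cross-validation metrics, for compilation
#' into day-of-year time series.
#'
#' @param ws a [running_window_fit()] result.
#' @param table the outcome table the series was fitted on (needed for
#'   cross-validation).
#' @param cv also run [cross_validate()] per window (slower).
#' @param cv_seed,cv_k cross-validation controls.
#' @return the `window_series` with an `evaluation` data frame attached
#'   (one row per window).
#' @export
evaluate_windows <- function(ws, table = NULL, cv = FALSE, cv_seed = 1L, cv_k = 10L) {
  stopifnot(inherits(ws, "window_series"))
  n <- length(ws$window_start)
  ev <- data.frame(day_of_year = ws$day_of_year, n_obs = ws$n_obs,
                   degenerate = ws$degenerate,
                   mcfadden = NA_real_, residual_deviance = NA_real_,
                   auc = NA_real_, accuracy = NA_real_, precision = NA_real_,
                   recall = NA_real_, f1 = NA_real_)
  if (cv && is.null(table)) stop_with("cross-validation needs the outcome table")
  if (cv) table <- table[order(table$intro_day), , drop = FALSE]
  for (i in seq_len(n)) {
    f <- ws$fits[[i]]
    if (is.null(f) || f$degenerate) next
    ev$mcfadden[i] <- suppressWarnings(mcfadden_r2(f))
    ev$residual_deviance[i] <- f$deviance
    if (cv) {
      k <- ws$window_start[i]
      rows <- table$intro_day >= k & table$intro_day <= k + ws$window - 1L
      rep <- tryCatch(cross_validate(table[rows, , drop = FALSE], ws$formula,
                                     k = cv_k, seed = cv_seed),
                      error = function(e) NULL)
      if (!is.null(rep)) {
        ev$auc[i] <- rep$pooled[["auc"]]
        ev$accuracy[i] <- rep$pooled[["accuracy"]]
        ev$precision[i] <- rep$pooled[["precision"]]
        ev$recall[i] <- rep$pooled[["recall"]]
        ev$f1[i] <- rep$pooled[["f1"]]
      }
    }
  }
  ws$evaluation <- ev
  ws
}

#' Compile a day-of-year metric time series from a window series
#'
#' Extracts one value per window (365 by default, one per day of year):
#' an evaluation metric (`"mcfadden"`, `"residual_deviance"`, `"auc"`,
#' `"accuracy"`, `"precision"`, `"recall"`, `"f1"`, `"n_obs"`), a
#' coefficient (`"estimate:<term>"`, e.g. `"estimate:(Intercept)"`), or a
#' prediction (`"ep"`, requiring `newdata`). Degenerate windows carry
#' `NA` with `flag = TRUE`.
#'
#' @param ws a [running_window_fit()] result, through
#'   [evaluate_windows()] if an evaluation metric is requested.
#' @param metric metric name as above.
#' @param newdata single-row data frame for `metric = "ep"`.
#' @return data frame `day_of_year,metric,value,flag`.
#' @export
compile_series <- function(ws, metric = "mcfadden", newdata = NULL) {
  stopifnot(inherits(ws, "window_series"))
  n <- length(ws$window_start)
  value <- rep(NA_real_, n)
  if (startsWith(metric, "estimate:")) {
    term <- sub("^estimate:", "", metric)
    for (i in seq_len(n)) {
      f <- ws$fits[[i]]
      if (!is.null(f) && !f$degenerate && term %in% names(f$coefficients))
        value[i] <- f$coefficients[[term]]
    }
  } else if (metric == "ep") {
    if (is.null(newdata)) stop_with("metric 'ep' needs newdata")
    for (i in seq_len(n)) {
      f <- ws$fits[[i]]
      if (!is.null(f) && !f$degenerate)
        value[i] <- predict_ep(f, newdata)$ep[1]
    }
  } else if (metric == "n_obs") {
    value <- as.numeric(ws$n_obs)
  } else {
    if (is.null(ws$evaluation))
      stop_with("run evaluate_windows() before compiling metric '%s'", metric)
    if (!metric %in% names(ws$evaluation))
      stop_with("unknown metric '%s'", metric)
    value <- ws$evaluation[[metric]]
  }
  data.frame(day_of_year = ws$day_of_year, metric = metric, value = value,
             flag = ws$degenerate, stringsAsFactors = FALSE)
}

#' Table of model-comparison metrics
#'
#' Fits the three nested establishment GLMs and summarises McFadden's R2
#' plus pooled 10-fold cross-validation metrics for each, one row per
#' model.
#'
#' @param table an [as_outcome_table()] data frame.
#' @param formulas model tags to include.
#' @param cv_seed cross-validation seed.
#' @return data frame with one row per model.
#' @export
evaluation_report <- function(table, formulas = c("EP~PS", "EP~PS*PN", "EP~PS*PN*SE"),
                              cv_seed = 1L) {
  rows <- lapply(formulas, function(f) {
    m <- fit_bglm(table, f)
    cvr <- cross_validate(table, f, seed = cv_seed)
    data.frame(model = f, mcfadden = mcfadden_r2(m),
               residual_deviance = m$deviance, df = m$n - m$df_residual - 1L,
               auc = cvr$pooled[["auc"]], accuracy = cvr$pooled[["accuracy"]],
               precision = cvr$pooled[["precision"]],
               recall = cvr$pooled[["recall"]], f1 = cvr$pooled[["f1"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
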