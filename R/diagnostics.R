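# Fit and predictive-performance statistics, misspecification tests and the
# four-fold cross-validation protocol.

#' Mean squared and root mean squared prediction error
#'
#' @param observed,predicted Aligned utility vectors.
#' @return Named numeric `c(mse, rmse)`.
#' @export
prediction_errors <- function(observed, predicted) {
  if (!length(observed)) stop("empty vectors")
  if (length(observed) != length(predicted)) stop("vectors must be aligned")
  mse <- mean((observed - predicted)^2)
  c(mse = mse, rmse = sqrt(mse))
}

#' Intraclass correlation between observed and predicted values
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC (ICC(A,1))
#' computed from the mean squares of the stacked (observed, predicted) pairs.
#' Unlike the Pearson correlation it penalises systematic shifts between the
#' two series.
#'
#' @param observed,predicted Aligned vectors, length >= 3.
#' @return ICC in \[-1, 1\].
#' @export
icc_agreement <- function(observed, predicted) {
  n <- length(observed)
  if (n < 3) stop("need at least 3 paired observations")
  if (length(predicted) != n) stop("vectors must be aligned")
  Y <- cbind(observed, predicted)
  k <- 2
  row_m <- rowMeans(Y); col_m <- colMeans(Y); g <- mean(Y)
  if (sum((Y - g)^2) == 0) stop("ICC undefined: zero total variance")
  msr <- k * sum((row_m - g)^2) / (n - 1)
  msc <- n * sum((col_m - g)^2) / (k - 1)
  resid <- Y - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + g
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on the others.
#' Values above `flag_above` (default 10) indicate problematic collinearity;
#' perfectly collinear predictors are reported as infinite.
#'
#' @param X Numeric predictor table with at least two columns.
#' @param flag_above Flagging threshold.
#' @return Data frame with `predictor`, `vif`, logical `flagged`.
#' @export
vif <- function(X, flag_above = 10) {
  X <- as_design(X)
  if (is.null(X) || ncol(X) < 2) stop("need at least two predictors")
  v <- apply(X, 2, stats::sd)
  if (any(v == 0)) stop("constant predictor(s): ",
                        paste(colnames(X)[v == 0], collapse = ", "))
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = colnames(X), vif = out,
             flagged = !is.finite(out) | out > flag_above,
             stringsAsFactors = FALSE)
}

#' Ramsey RESET misspecification test for OLS fits
#'
#' Augments the design with powers 2-4 of the fitted values and jointly
#' F-tests the added terms. A p-value below `alpha` flags misspecification.
#'
#' @param fit A `fitted_mapper` of family `"ols"` (with stored fitted
#'   values), from [fit_ols()].
#' @param X The predictor table used in the fit.
#' @param y The outcome used in the fit.
#' @param powers Powers of the fitted values to add (default 2:4).
#' @param alpha Verdict threshold.
#' @return List with `statistic` (F), `df`, `p_value`, `misspecified`.
#' @export
reset_test <- function(fit, X, y, powers = 2:4, alpha = 0.05) {
  if (!inherits(fit, "fitted_mapper") || fit$family != "ols")
    stop("RESET applies to OLS fits")
  X <- as_design(X)
  n <- length(y)
  M <- full_design(X, n)
  yh <- fit$fitted
  if (n <= ncol(M) + length(powers))
    stop("too few observations for ", length(powers), " added power terms")
  A <- cbind(M, vapply(powers, function(p) yh^p, numeric(n)))
  check_full_rank(A)
  rss0 <- sum(stats::lm.fit(M, y)$residuals^2)
  rss1 <- sum(stats::lm.fit(A, y)$residuals^2)
  q <- length(powers)
  df2 <- n - ncol(A)
  f <- ((rss0 - rss1) / q) / (rss1 / df2)
  p <- stats::pf(f, q, df2, lower.tail = FALSE)
  list(statistic = f, df = c(q, df2), p_value = p, misspecified = p < alpha)
}

#' Linktest for misspecification of any mapper family
#'
#' Refits the same family on the fit's linear predictor and its square; a
#' significant squared term at `alpha` flags misspecification. Used for the
#' Tobit model and the second (truncated) part of the two-part model; for an
#' OLS fit it coincides with a RESET restricted to the second power.
#'
#' @param fit A `fitted_mapper` (family ols, tobit, logit or truncated).
#' @param X Predictor table used in the fit.
#' @param y Outcome used in the fit.
#' @param alpha Verdict threshold.
#' @return List with `coefficient` and `p_value` of the squared linear
#'   predictor, and `misspecified`.
#' @export
linktest <- function(fit, X, y, alpha = 0.05) {
  X <- as_design(X)
  n <- length(y)
  M <- full_design(X, n)
  nm <- names(fit$coef)
  lp <- drop(M[, nm, drop = FALSE] %*% fit$coef)
  if (stats::sd(lp) == 0) stop("constant linear predictor")
  H <- cbind(hat = lp, hat_sq = lp^2)
  refit <- switch(fit$family,
                  ols = fit_ols(H, y),
                  tobit = fit_tobit(H, y, upper = fit$upper),
                  logit = fit_logit(H, y),
                  truncated = fit_truncated(H, y, bounds = fit$bounds))
  b <- refit$coef["hat_sq"]
  p <- 2 * stats::pnorm(-abs(b / refit$se["hat_sq"]))
  list(coefficient = unname(b), p_value = unname(p),
       misspecified = unname(p) < alpha, refit = refit)
}

#' Default observed-utility bands
#'
#' Left-closed, right-open bands over the utility scale (the last band is
#' closed at 1), matching the reporting bands of the reference analysis.
#' @export
utility_bands <- function() {
  c(-0.594, 0.1, 0.3, 0.6, 0.7, 0.8, 0.9, 1)
}

#' Observed/predicted summary by subgroup with one-way ANOVA
#'
#' Summarises observed and predicted utilities within bands of the observed
#' utility (or within an arbitrary grouping factor such as FEV1 severity) and
#' tests for differences in predicted means across groups with a one-way
#' ANOVA. Empty bands are reported with n = 0 and excluded from the ANOVA.
#'
#' @param observed,predicted Aligned utility vectors.
#' @param bands Numeric cut-points (see [utility_bands()]), or a factor/
#'   character vector of group labels of the same length as `observed`.
#' @param spread `"sd"` or `"rmse"`: what the per-band spread column reports.
#' @return List with `table` (per-band n, observed mean, predicted mean,
#'   spread) and `anova` (`F`, `df`, `p_value`).
#' @export
subgroup_summary <- function(observed, predicted, bands = utility_bands(),
                             spread = c("sd", "rmse")) {
  spread <- match.arg(spread)
  if (is.numeric(bands)) {
    # left-closed, right-open bands; the final band is closed at the ceiling
    grp <- cut(observed, bands, right = FALSE, include.lowest = TRUE)
  } else {
    grp <- factor(bands)
  }
  tab <- do.call(rbind, lapply(levels(grp), function(g) {
    i <- which(grp == g)
    data.frame(group = g, n = length(i),
               observed_mean = if (length(i)) mean(observed[i]) else NA_real_,
               predicted_mean = if (length(i)) mean(predicted[i]) else NA_real_,
               spread = if (!length(i)) NA_real_
                        else if (spread == "sd") stats::sd(predicted[i])
                        else sqrt(mean((observed[i] - predicted[i])^2)),
               stringsAsFactors = FALSE)
  }))
  names(tab)[names(tab) == "spread"] <- paste0("predicted_", spread)
  used <- droplevels(grp[!is.na(grp)])
  anova_res <- if (nlevels(used) < 2) {
    list(F = NA_real_, df = c(NA, NA), p_value = NA_real_,
         note = "fewer than two non-empty groups: ANOVA undefined")
  } else {
    tryCatch({
      a <- stats::oneway.test(predicted[!is.na(grp)] ~ used, var.equal = TRUE)
      list(F = unname(a$statistic),
           df = unname(c(a$parameter[1], a$parameter[2])),
           p_value = unname(a$p.value))
    }, error = function(e)
      list(F = NA_real_, df = c(NA, NA), p_value = NA_real_,
           note = paste("ANOVA undefined:", conditionMessage(e))))
  }
  list(table = tab, anova = anova_res, spread = spread)
}

#' Full-sample validation report for one fitted specification
#'
#' @param object A `spec_fit`.
#' @param data The respondent table it was fitted on.
#' @param bands Utility bands for the subgroup table.
#' @return List of class `validation_report`: predicted mean/SD/range, ICC,
#'   RMSE/MSE, per-part AIC/BIC, subgroup tables by utility band and (when a
#'   `fev1_severity` column is present) by FEV1 severity.
#' @export
validation_report <- function(object, data, bands = utility_bands()) {
  obs <- data$utility
  pred <- stats::predict(object, data)
  err <- prediction_errors(obs, pred)
  ic <- if (object$family == "tpm") {
    list(part1 = c(aic = object$fit$part1$aic, bic = object$fit$part1$bic),
         part2 = c(aic = object$fit$part2$aic, bic = object$fit$part2$bic))
  } else list(c(aic = object$fit$aic, bic = object$fit$bic))
  out <- list(model = object$spec$model, family = object$family,
              n = length(obs),
              predicted_mean = mean(pred), predicted_sd = stats::sd(pred),
              predicted_range = range(pred),
              icc = icc_agreement(obs, pred),
              mse = unname(err["mse"]), rmse = unname(err["rmse"]),
              information_criteria = ic,
              r2 = if (object$family != "tpm") object$fit$r2 else NULL,
              by_utility = subgroup_summary(obs, pred, bands))
  if (!is.null(data$fev1_severity))
    out$by_severity <- subgroup_summary(obs, pred, data$fev1_severity)
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report: model %d, family %s, n = %d\n",
              x$model, x$family, x$n))
  cat(sprintf("  predicted mean %.3f (SD %.3f), range [%.3f, %.3f]\n",
              x$predicted_mean, x$predicted_sd, x$predicted_range[1],
              x$predicted_range[2]))
  cat(sprintf("  ICC %.3f, RMSE %.3f, MSE %.3f\n", x$icc, x$rmse, x$mse))
  invisible(x)
}

#' Assign cross-validation folds
#'
#' Random partition into `folds` groups; when n is not divisible by the fold
#' count the remainder is spread one per fold, so sizes differ by at most 1.
#'
#' @param n Number of respondents.
#' @param folds Number of folds (default 4, i.e. 25% held out per fold).
#' @param seed Integer seed.
#' @return Integer fold assignment of length n.
#' @export
cv_folds <- function(n, folds = 4, seed = 1) {
  set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

#' Cross-validate a model specification
#'
#' For each fold, refits the specification on the remaining folds and
#' predicts the held-out respondents, reporting per-fold summary statistics
#' plus a one-way ANOVA comparing observed means across folds (the balance
#' check of the reference protocol).
#'
#' @param data Respondent table (see [fit_spec()]).
#' @param model Model number 1-8.
#' @param family `"ols"`, `"tobit"` or `"tpm"`.
#' @param folds Number of folds (default 4).
#' @param seed Seed for fold assignment.
#' @param ... Passed to [fit_spec()].
#' @return List of class `cv_report` with `fold_table` (per-fold n, observed
#'   and predicted means/SDs, range, RMSE, ICC), `assignments`, the balance
#'   `anova`, `seed`.
#' @export
cross_validate <- function(data, model, family = "ols", folds = 4, seed = 1,
                           ...) {
  n <- nrow(data)
  assign <- cv_folds(n, folds, seed)
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    train <- data[assign != f, , drop = FALSE]
    test <- data[assign == f, , drop = FALSE]
    fit_f <- fit_spec(train, model, family, ...)
    pred <- stats::predict(fit_f, test)
    err <- prediction_errors(test$utility, pred)
    rows[[f]] <- data.frame(
      fold = f, n = nrow(test),
      observed_mean = mean(test$utility),
      predicted_mean = mean(pred), predicted_sd = stats::sd(pred),
      predicted_min = min(pred), predicted_max = max(pred),
      rmse = unname(err["rmse"]),
      icc = icc_agreement(test$utility, pred))
  }
  bal <- stats::oneway.test(data$utility ~ factor(assign), var.equal = TRUE)
  structure(list(fold_table = do.call(rbind, rows), assignments = assign,
                 anova = list(F = unname(bal$statistic),
                              df = unname(c(bal$parameter[1], bal$parameter[2])),
                              p_value = unname(bal$p.value)),
                 model = model, family = family, folds = folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: model %d, family %s (seed %d)\n",
              x$folds, x$model, x$family, x$seed))
  print(x$fold_table, row.names = FALSE)
  cat(sprintf("Observed-mean balance ANOVA: F = %.3f, p = %.3f\n",
              x$anova$F, x$anova$p_value))
  invisible(x)
}
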