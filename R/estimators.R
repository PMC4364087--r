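# Estimation back-ends for utility mapping: OLS, upper-censored Tobit,
# logit, doubly-truncated Gaussian regression, and the two-part model.
# All fitters take a numeric predictor table X (no intercept column) and
# return a 'fitted_mapper' carrying named coefficients (intercept first),
# standard errors, log-likelihood and information criteria.

as_design <- function(X) {
  if (is.null(X) || (is.data.frame(X) && ncol(X) == 0) ||
      (is.matrix(X) && ncol(X) == 0)) {
    return(NULL)
  }
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("predictors must be numeric")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

full_design <- function(X, n) {
  if (is.null(X)) {
    matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cbind("(Intercept)" = 1, X)
  }
}

check_full_rank <- function(M) {
  q <- qr(M)
  if (q$rank < ncol(M)) {
    dropped <- colnames(M)[q$pivot[(q$rank + 1):ncol(M)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(q)
}

new_mapper <- function(family, coef, se, vcov, loglik, n, k, extra = list()) {
  obj <- c(list(family = family, coef = coef, se = se, vcov = vcov,
                loglik = loglik, n = n, k = k,
                aic = 2 * k - 2 * loglik,
                bic = k * log(n) - 2 * loglik,
                se_type = "iid"),
           extra)
  ci <- cbind(lower = coef - stats::qnorm(0.975) * se,
              upper = coef + stats::qnorm(0.975) * se)
  obj$ci <- ci
  class(obj) <- "fitted_mapper"
  obj
}

#' @export
print.fitted_mapper <- function(x, ...) {
  cat(sprintf("Fitted mapper [%s], n = %d, logLik = %.3f, AIC = %.1f, BIC = %.1f\n",
              x$family, x$n, x$loglik, x$aic, x$bic))
  tab <- cbind(Estimate = x$coef, `Std. Error` = x$se,
               z = x$coef / x$se,
               `p` = 2 * stats::pnorm(-abs(x$coef / x$se)))
  print(round(tab, 5))
  if (!is.null(x$r2)) cat(sprintf("R2 (%s): %.4f\n", x$r2_type, x$r2))
  invisible(x)
}

#' @export
logLik.fitted_mapper <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
coef.fitted_mapper <- function(object, ...) object$coef

mapper_lp <- function(object, newdata) {
  nm <- names(object$coef)
  vars <- setdiff(nm, "(Intercept)")
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(vars, names(newdata))
  if (length(missing_cols))
    stop("newdata is missing predictor(s): ", paste(missing_cols, collapse = ", "))
  M <- full_design(as_design(newdata[, vars, drop = FALSE]), nrow(newdata))
  drop(M[, nm, drop = FALSE] %*% object$coef)
}

#' Predict from a fitted mapper
#'
#' @param object A `fitted_mapper`.
#' @param newdata Data frame/matrix containing the model's predictor columns.
#' @param type `"response"`: the natural prediction for the family (linear
#'   predictor for OLS/Tobit/truncated, probability for logit).
#'   `"link"`: the linear predictor. For truncated fits,
#'   `"conditional"` gives the truncated-normal conditional mean
#'   E\[y | a < y < b\].
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.fitted_mapper <- function(object, newdata,
                                  type = c("response", "link", "conditional"),
                                  ...) {
  type <- match.arg(type)
  lp <- mapper_lp(object, newdata)
  if (type == "link") return(lp)
  switch(object$family,
         logit = if (type == "conditional")
                   stop("type 'conditional' applies to truncated fits only")
                 else stats::plogis(lp),
         truncated = if (type == "conditional") {
           trunc_cond_mean(lp, object$sigma, object$bounds[1], object$bounds[2])
         } else lp,
         lp)
}

# ---------------------------------------------------------------- OLS ----

#' Fit the ordinary least squares mapper
#'
#' Closed-form least squares of utilities on the predictor table, with
#' Gaussian log-likelihood information criteria and either classical or
#' heteroskedasticity-robust (HC1) standard errors.
#'
#' @param X Numeric predictor table (no intercept column); `NULL` for an
#'   intercept-only fit.
#' @param y Numeric outcome (utilities).
#' @param se_type `"iid"` (classical) or `"hc1"` (robust sandwich).
#' @return A `fitted_mapper` with family `"ols"`.
#' @export
fit_ols <- function(X, y, se_type = c("iid", "hc1")) {
  se_type <- match.arg(se_type)
  X <- as_design(X)
  n <- length(y)
  M <- full_design(X, n)
  if (n <= ncol(M)) stop("need more observations than coefficients")
  check_full_rank(M)
  fit <- stats::lm.fit(M, y)
  beta <- fit$coefficients
  res <- fit$residuals
  rss <- sum(res^2)
  p <- ncol(M)
  sigma2_mle <- rss / n
  loglik <- -n / 2 * (log(2 * pi * sigma2_mle) + 1)
  XtXinv <- chol2inv(qr.R(fit$qr))
  dimnames(XtXinv) <- list(names(beta), names(beta))
  if (se_type == "hc1") {
    meat <- crossprod(M * res)
    vc <- XtXinv %*% meat %*% XtXinv * n / (n - p)
  } else {
    vc <- XtXinv * rss / (n - p)
  }
  tss <- sum((y - mean(y))^2)
  adj_r2 <- if (tss > 0) 1 - (rss / (n - p)) / (tss / (n - 1)) else NA_real_
  out <- new_mapper("ols", beta, sqrt(diag(vc)), vc, loglik, n, p + 1,
                    extra = list(sigma = sqrt(rss / (n - p)),
                                 r2 = adj_r2, r2_type = "adjusted",
                                 fitted = drop(M %*% beta), residuals = res,
                                 converged = TRUE))
  out$se_type <- se_type
  out
}

# -------------------------------------------------------------- Tobit ----

# Hessian by central differences of an analytic gradient; steps scale with
# each parameter so badly scaled designs (e.g. squared domain scores) keep
# well-conditioned curvature estimates.
hess_from_grad <- function(gr, par, ...) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- 1e-6 * max(abs(par[j]), 1e-3)
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    H[, j] <- (gr(up, ...) - gr(dn, ...)) / (2 * h)
  }
  (H + t(H)) / 2
}


tobit_nll <- function(par, M, y, ulim, cens) {
  beta <- par[-length(par)]
  sigma <- exp(par[length(par)])
  xb <- drop(M %*% beta)
  ll <- 0
  if (any(!cens)) {
    r <- (y[!cens] - xb[!cens]) / sigma
    ll <- ll + sum(stats::dnorm(r, log = TRUE) - log(sigma))
  }
  if (any(cens)) {
    z <- (ulim - xb[cens]) / sigma
    ll <- ll + sum(stats::pnorm(z, lower.tail = FALSE, log.p = TRUE))
  }
  -ll
}

tobit_grad <- function(par, M, y, ulim, cens) {
  beta <- par[-length(par)]
  sigma <- exp(par[length(par)])
  xb <- drop(M %*% beta)
  gb <- numeric(ncol(M)); gs <- 0
  if (any(!cens)) {
    r <- (y[!cens] - xb[!cens]) / sigma
    gb <- gb + drop(crossprod(M[!cens, , drop = FALSE], r / sigma))
    gs <- gs + sum(r^2 - 1)
  }
  if (any(cens)) {
    z <- (ulim - xb[cens]) / sigma
    lambda <- exp(stats::dnorm(z, log = TRUE) -
                  stats::pnorm(z, lower.tail = FALSE, log.p = TRUE))
    gb <- gb + drop(crossprod(M[cens, , drop = FALSE], lambda / sigma))
    gs <- gs + sum(lambda * z)
  }
  -c(gb, gs)
}

#' Fit an upper-censored Tobit mapper
#'
#' Maximum-likelihood Gaussian regression with the outcome censored above at
#' `upper` (default 1, the EQ-5D ceiling). With zero censored observations
#' the likelihood reduces to the Gaussian likelihood and the fit matches OLS.
#'
#' @inheritParams fit_ols
#' @param upper Censoring limit; observations with `y >= upper` are treated
#'   as censored at the limit.
#' @param tol Gradient-norm convergence tolerance.
#' @return A `fitted_mapper` with family `"tobit"`, McFadden pseudo-R2
#'   against the intercept-only Tobit, and `sigma`.
#' @export
fit_tobit <- function(X, y, upper = 1, tol = 1e-8) {
  X <- as_design(X)
  n <- length(y)
  M <- full_design(X, n)
  if (any(y > upper + 1e-8)) stop("outcome values exceed the censoring limit")
  check_full_rank(M)
  cens <- y >= upper - 1e-12
  if (all(cens)) stop("all observations censored: Tobit not identifiable")
  fit <- tobit_mle(M, y, upper, cens, tol)
  ll0 <- -tobit_mle(M[, 1, drop = FALSE], y, upper, cens, tol)$nll
  pseudo_r2 <- 1 - (-fit$nll) / ll0
  new_mapper("tobit", fit$beta, fit$se, fit$vcov, -fit$nll, n, ncol(M) + 1,
             extra = list(sigma = fit$sigma, upper = upper,
                          n_censored = sum(cens),
                          r2 = pseudo_r2, r2_type = "McFadden pseudo",
                          converged = fit$converged,
                          fitted = drop(M %*% fit$beta)))
}

tobit_mle <- function(M, y, upper, cens, tol) {
  ols <- stats::lm.fit(M, ifelse(cens, upper, y))
  s0 <- stats::sd(ols$residuals)
  if (!is.finite(s0) || s0 <= 0) s0 <- max(stats::sd(y), 1e-3)
  start <- c(ols$coefficients, log(s0))
  opt <- stats::optim(start, tobit_nll, tobit_grad, M = M, y = y,
                      ulim = upper, cens = cens, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  g <- tobit_grad(opt$par, M, y, upper, cens)
  # gradient norm relative to the log-likelihood scale (per observation)
  converged <- opt$convergence == 0 &&
    sqrt(sum(g^2)) / length(y) < sqrt(tol)
  if (opt$convergence != 0)
    stop("Tobit MLE did not converge (optim code ", opt$convergence,
         ", gradient norm ", format(sqrt(sum(g^2))), ")")
  p <- ncol(M)
  H <- hess_from_grad(tobit_grad, opt$par, M = M, y = y, ulim = upper,
                      cens = cens)
  vc_all <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, p + 1, p + 1)
  })
  vc <- vc_all[seq_len(p), seq_len(p), drop = FALSE]
  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(M)
  dimnames(vc) <- list(names(beta), names(beta))
  list(beta = beta, sigma = exp(opt$par[p + 1]), se = sqrt(pmax(diag(vc), 0)),
       vcov = vc, nll = opt$value, converged = converged)
}

# -------------------------------------------------------------- logit ----

#' Fit the logit model for the probability of full health
#'
#' Part 1 of the two-part model: logistic regression of the full-health
#' indicator (utility equal to 1) on the predictor table.
#'
#' @inheritParams fit_ols
#' @param z Logical/0-1 indicator of being at the utility ceiling.
#' @return A `fitted_mapper` with family `"logit"`.
#' @export
fit_logit <- function(X, z) {
  X <- as_design(X)
  z <- as.numeric(z)
  if (!all(z %in% c(0, 1))) stop("outcome must be a 0/1 ceiling indicator")
  if (length(unique(z)) < 2) stop("both outcome classes must be present")
  n <- length(z)
  M <- full_design(X, n)
  check_full_rank(M)
  fit <- suppressWarnings(
    stats::glm.fit(M, z, family = stats::binomial(),
                   control = stats::glm.control(maxit = 100)))
  mu <- fit$fitted.values
  # perfect separation: the classes do not overlap on the fitted scale
  if (max(mu[z == 0]) < min(mu[z == 1]) &&
      (min(mu[z == 1]) > 1 - 1e-8 || max(mu[z == 0]) < 1e-8)) {
    std <- abs(fit$coefficients[-1]) * apply(M[, -1, drop = FALSE], 2, stats::sd)
    worst <- if (length(std)) names(which.max(std)) else "(Intercept)"
    stop("perfect separation detected; separating predictor: ", worst)
  }
  beta <- fit$coefficients
  W <- mu * (1 - mu)
  vc <- tryCatch(solve(crossprod(M * sqrt(W))), error = function(e)
    matrix(NA_real_, ncol(M), ncol(M)))
  dimnames(vc) <- list(names(beta), names(beta))
  ll <- sum(stats::dbinom(z, 1, mu, log = TRUE))
  new_mapper("logit", beta, sqrt(diag(vc)), vc, ll, n, ncol(M),
             extra = list(fitted = mu, converged = fit$converged))
}

# ---------------------------------------------------- truncated normal ----

trunc_nll <- function(par, M, y, a, b) {
  beta <- par[-length(par)]
  sigma <- exp(par[length(par)])
  xb <- drop(M %*% beta)
  r <- (y - xb) / sigma
  za <- (a - xb) / sigma
  zb <- (b - xb) / sigma
  logD <- log(stats::pnorm(zb) - stats::pnorm(za))
  if (any(!is.finite(logD))) return(1e10)
  -sum(stats::dnorm(r, log = TRUE) - log(sigma) - logD)
}

trunc_grad <- function(par, M, y, a, b) {
  beta <- par[-length(par)]
  sigma <- exp(par[length(par)])
  xb <- drop(M %*% beta)
  r <- (y - xb) / sigma
  za <- (a - xb) / sigma
  zb <- (b - xb) / sigma
  D <- stats::pnorm(zb) - stats::pnorm(za)
  pa <- stats::dnorm(za); pb <- stats::dnorm(zb)
  gb <- drop(crossprod(M, (r + (pb - pa) / D) / sigma))
  zpa <- ifelse(is.finite(za), za * pa, 0)
  zpb <- ifelse(is.finite(zb), zb * pb, 0)
  gs <- sum(r^2 - 1 + (zpb - zpa) / D)
  -c(gb, gs)
}

trunc_cond_mean <- function(lp, sigma, a, b) {
  za <- (a - lp) / sigma
  zb <- (b - lp) / sigma
  D <- stats::pnorm(zb) - stats::pnorm(za)
  lp + sigma * (stats::dnorm(za) - stats::dnorm(zb)) / D
}

#' Fit a doubly-truncated Gaussian regression (two-part model part 2)
#'
#' Maximum-likelihood Gaussian regression conditional on the outcome lying
#' strictly inside `bounds`. The default bounds are the interval available to
#' non-full-health EQ-5D utilities under the UK tariff, (-0.594, 0.99).
#' Predictions default to the linear predictor; the truncated-normal
#' conditional mean is available via `predict(..., type = "conditional")`.
#'
#' @inheritParams fit_ols
#' @param bounds Length-2 numeric, the (lower, upper) truncation interval;
#'   may be infinite, in which case the fit reduces to OLS.
#' @param tol Gradient-norm convergence tolerance.
#' @return A `fitted_mapper` with family `"truncated"`.
#' @export
fit_truncated <- function(X, y, bounds = c(-0.594, 0.99), tol = 1e-8) {
  X <- as_design(X)
  n <- length(y)
  if (any(y <= bounds[1]) || any(y >= bounds[2]))
    stop("all outcome values must lie strictly inside the truncation bounds")
  M <- full_design(X, n)
  check_full_rank(M)
  ols <- stats::lm.fit(M, y)
  s0 <- stats::sd(ols$residuals)
  if (!is.finite(s0) || s0 <= 0) s0 <- max(stats::sd(y), 1e-3)
  start <- c(ols$coefficients, log(s0))
  opt <- stats::optim(start, trunc_nll, trunc_grad, M = M, y = y,
                      a = bounds[1], b = bounds[2], method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  if (opt$convergence != 0)
    stop("truncated-regression MLE did not converge (optim code ",
         opt$convergence, ")")
  g <- trunc_grad(opt$par, M, y, bounds[1], bounds[2])
  converged <- sqrt(sum(g^2)) / length(y) < sqrt(tol)
  p <- ncol(M)
  H <- hess_from_grad(trunc_grad, opt$par, M = M, y = y, a = bounds[1],
                      b = bounds[2])
  vc_all <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, p + 1, p + 1))
  vc <- vc_all[seq_len(p), seq_len(p), drop = FALSE]
  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(M)
  dimnames(vc) <- list(names(beta), names(beta))
  new_mapper("truncated", beta, sqrt(pmax(diag(vc), 0)), vc, -opt$value, n,
             p + 1,
             extra = list(sigma = exp(opt$par[p + 1]), bounds = bounds,
                          converged = converged,
                          fitted = drop(M %*% beta)))
}

# ----------------------------------------------------- two-part model ----

#' Expected-value combination of the two-part model
#'
#' Combines the probability of full health with the part-2 prediction:
#' `EV = p * 1 + (1 - p) * yhat2`.
#'
#' @param p Probability of being at the utility ceiling, in \[0, 1\].
#' @param yhat2 Part-2 (truncated regression) prediction on the utility
#'   scale.
#' @return Expected utility, vectorized over respondents.
#' @export
tpm_predict <- function(p, yhat2) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("ceiling probabilities must lie in [0, 1]")
  p * 1 + (1 - p) * yhat2
}

#' Fit a two-part model for ceiling-inflated utilities
#'
#' Part 1: logit for Pr(utility = ceiling). Part 2: doubly-truncated
#' Gaussian regression on the respondents below the ceiling. Predictions
#' combine the parts with the expected-value formula ([tpm_predict()]).
#' Information criteria are reported per part, never summed.
#'
#' @param X1,X2 Predictor tables for parts 1 and 2 (default: same table).
#' @param y Utilities.
#' @param ceiling Utility ceiling (default 1).
#' @param bounds Truncation interval for part 2.
#' @return An object of class `tpm_mapper` with elements `part1`, `part2`.
#' @export
fit_tpm <- function(X1, y, X2 = X1, ceiling = 1, bounds = c(-0.594, 0.99)) {
  z <- as.numeric(y >= ceiling - 1e-12)
  part1 <- fit_logit(X1, z)
  below <- z == 0
  X2d <- as_design(X2)
  part2 <- fit_truncated(if (is.null(X2d)) NULL else X2d[below, , drop = FALSE],
                         y[below], bounds = bounds)
  structure(list(part1 = part1, part2 = part2, ceiling = ceiling,
                 bounds = bounds, n = length(y), family = "tpm"),
            class = "tpm_mapper")
}

#' @export
print.tpm_mapper <- function(x, ...) {
  cat("Two-part model (n =", x$n, ")\nPart 1 (logit, Pr[utility = ",
      x$ceiling, "]):\n", sep = "")
  print(x$part1)
  cat("Part 2 (truncated regression on (", x$bounds[1], ", ", x$bounds[2],
      ")):\n", sep = "")
  print(x$part2)
  invisible(x)
}

#' @export
predict.tpm_mapper <- function(object, newdata, type = "response", ...) {
  p <- predict.fitted_mapper(object$part1, newdata, type = "response")
  yhat2 <- predict.fitted_mapper(object$part2, newdata, type = "response")
  tpm_predict(p, yhat2)
}

# ---------------------------------------------------------- bootstrap ----

#' Bias-corrected bootstrap standard errors and intervals
#'
#' Resamples respondents with replacement, refits, and reports the bootstrap
#' SE (SD over replicates) and the bias-corrected (BC) percentile interval:
#' `z0` is the normal quantile of the share of replicates below the point
#' estimate, and the interval endpoints are the bootstrap quantiles at
#' `pnorm(2 * z0 +/- qnorm(0.975))`. No acceleration term is used.
#'
#' @param fitter Function taking a data frame and returning a named numeric
#'   vector of statistics (e.g. coefficients).
#' @param data Data frame of respondents.
#' @param reps Bootstrap replications (the reference analysis used 2000).
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level.
#' @param max_fail Maximum tolerated share of failed refits.
#' @return List with `estimate`, `se`, `ci` (matrix), `z0`, `reps`, `seed`,
#'   `n_failed`.
#' @export
bootstrap_bc <- function(fitter, data, reps = 2000, seed = 1, conf = 0.95,
                         max_fail = 0.1) {
  if (reps < 2) stop("need at least 2 bootstrap replications")
  t0 <- fitter(data)
  n <- nrow(data)
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = reps, ncol = length(t0),
                  dimnames = list(NULL, names(t0)))
  failed <- 0L
  for (b in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    tb <- tryCatch(fitter(data[idx, , drop = FALSE]), error = function(e) NULL)
    if (is.null(tb)) failed <- failed + 1L else draws[b, ] <- tb[names(t0)]
  }
  if (failed > max_fail * reps)
    stop(sprintf("bootstrap refits failed in %.1f%% of resamples", 100 * failed / reps))
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  alpha <- (1 - conf) / 2
  se <- apply(draws, 2, stats::sd)
  ci <- t(vapply(seq_along(t0), function(j) {
    tj <- draws[, j]
    if (se[j] == 0) return(c(t0[j], t0[j]))
    prop_below <- (sum(tj < t0[j]) + 0.5 * sum(tj == t0[j])) / length(tj)
    prop_below <- min(max(prop_below, 1 / (length(tj) + 1)),
                      length(tj) / (length(tj) + 1))
    z0 <- stats::qnorm(prop_below)
    probs <- stats::pnorm(2 * z0 + stats::qnorm(c(alpha, 1 - alpha)))
    stats::quantile(tj, probs, names = FALSE)
  }, numeric(2)))
  dimnames(ci) <- list(names(t0), c("lower", "upper"))
  list(estimate = t0, se = se, ci = ci, reps = reps, seed = seed,
       n_failed = failed, conf = conf)
}

# ------------------------------------------------------- serialization ----

#' Serialize and restore fitted mappers
#'
#' Fitted mappers round-trip to a structured JSON text format recording the
#' family, coefficients, standard errors, bounds/limits and package version,
#' so a mapping is portable and auditable.
#'
#' @param fit A `fitted_mapper` or `tpm_mapper`.
#' @param path Output/input file path.
#' @return `read_mapper` returns the restored object.
#' @export
write_mapper <- function(fit, path) {
  ser <- function(m) list(
    family = m$family, coef = as.list(m$coef), se = as.list(m$se),
    loglik = m$loglik, n = m$n, k = m$k, aic = m$aic, bic = m$bic,
    sigma = m$sigma, bounds = m$bounds, upper = m$upper,
    se_type = m$se_type)
  obj <- if (inherits(fit, "tpm_mapper")) {
    list(family = "tpm", ceiling = fit$ceiling, bounds = fit$bounds,
         n = fit$n, part1 = ser(fit$part1), part2 = ser(fit$part2))
  } else ser(fit)
  obj$package_version <- as.character(utils::packageVersion("cfqrmap"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_mapper
#' @export
read_mapper <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  deser <- function(o) {
    coef <- unlist(o$coef); se <- unlist(o$se)
    m <- new_mapper(o$family, coef, se, NULL, o$loglik, o$n, o$k,
                    extra = list(sigma = o$sigma, bounds = o$bounds,
                                 upper = o$upper))
    if (!is.null(o$se_type)) m$se_type <- o$se_type
    m
  }
  if (identical(obj$family, "tpm")) {
    structure(list(part1 = deser(obj$part1), part2 = deser(obj$part2),
                   ceiling = obj$ceiling, bounds = obj$bounds, n = obj$n,
                   family = "tpm"),
              class = "tpm_mapper")
  } else deser(obj)
}
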