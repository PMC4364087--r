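test_that("OLS recovers exact linear structure and closed forms", {
  set.seed(1)
  X <- data.frame(a = runif(40), b = runif(40))
  y <- 0.3 + 1.5 * X$a - 2 * X$b
  f <- fit_ols(X, y)
  expect_equal(unname(f$coef), c(0.3, 1.5, -2), tolerance = 1e-10)
  f0 <- fit_ols(NULL, y)
  expect_equal(unname(f0$coef), mean(y))
  # rank deficiency names the collinear column
  X$c <- X$a + X$b
  expect_error(fit_ols(X, y), "collinear.*c")
})

test_that("OLS information criteria match the stats conventions", {
  set.seed(2)
  X <- data.frame(a = runif(60))
  y <- 1 + X$a + rnorm(60, 0, 0.2)
  f <- fit_ols(X, y)
  ref <- lm(y ~ a, data = X)
  expect_equal(f$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(f$aic, AIC(ref), tolerance = 1e-8)
  expect_equal(f$bic, BIC(ref), tolerance = 1e-8)
  expect_equal(unname(f$se), unname(coef(summary(ref))[, 2]), tolerance = 1e-8)
  expect_gt(f$bic, f$aic)  # n > e^2
})

test_that("Tobit equals OLS with zero censored observations", {
  set.seed(3)
  X <- data.frame(x = runif(300, 0, 2))
  y <- 0.1 + 0.2 * X$x + rnorm(300, 0, 0.1)  # well below 1
  ft <- fit_tobit(X, y, upper = 10)
  fo <- fit_ols(X, y)
  expect_lt(max(abs(ft$coef - fo$coef)), 1e-4)
})

test_that("Tobit undoes censoring attenuation and matches the survreg oracle", {
  skip_if_not_installed("survival")
  set.seed(4)
  n <- 2000
  x <- runif(n, 0, 2)
  y <- pmin(0.2 + 0.5 * x + rnorm(n, 0, 0.3), 1)
  expect_gt(mean(y == 1), 0.2)
  ft <- fit_tobit(data.frame(x = x), y)
  expect_true(ft$converged)
  expect_lt(abs(ft$coef["x"] - 0.5), 3 * ft$se["x"])
  # naive OLS on censored data is attenuated
  expect_lt(fit_ols(data.frame(x = x), y)$coef["x"], ft$coef["x"] - 0.05)
  sv <- survival::survreg(survival::Surv(y, y < 1, type = "right") ~ x,
                          dist = "gaussian")
  expect_equal(unname(ft$coef), unname(coef(sv)), tolerance = 1e-6)
  # stationarity: analytic gradient ~ 0 at the optimum
  g <- cfqrmap:::tobit_grad(c(ft$coef, log(ft$sigma)), cbind(1, x), y, 1,
                            y >= 1)
  expect_lt(sqrt(sum(g^2)) / n, 1e-4)
  expect_error(fit_tobit(data.frame(x = x), rep(1, n)), "censored")
})

test_that("logit closed form, symmetry and separation guard", {
  z <- rep(c(1, 0), c(19, 81))
  f <- fit_logit(NULL, z)
  expect_equal(unname(f$coef), log(0.19 / 0.81), tolerance = 1e-8)
  set.seed(5)
  x <- rnorm(400)
  zb <- rep(0:1, each = 200)[sample(400)]
  fb <- fit_logit(data.frame(x = x), zb)
  expect_lt(abs(fb$coef["x"]), 3 * fb$se["x"])
  xs <- c(rnorm(50, -3), rnorm(50, 3))
  zs <- rep(c(0, 1), each = 50)
  expect_error(fit_logit(data.frame(x = xs), zs), "separation.*x")
  expect_error(fit_logit(data.frame(x = x), rep(1, 400)), "both outcome classes")
})

test_that("logit recovers simulated coefficients", {
  set.seed(6)
  n <- 3000
  x <- rnorm(n)
  z <- rbinom(n, 1, plogis(-1 + 0.8 * x))
  f <- fit_logit(data.frame(x = x), z)
  expect_lt(abs(f$coef["x"] - 0.8), 3 * f$se["x"])
  expect_lt(abs(f$coef["(Intercept)"] + 1), 3 * f$se["(Intercept)"])
})

test_that("truncated regression reduces to OLS with wide bounds", {
  set.seed(7)
  X <- data.frame(x = runif(500))
  y <- 0.2 + 0.3 * X$x + rnorm(500, 0, 0.1)
  ftr <- fit_truncated(X, y, bounds = c(-100, 100))
  fo <- fit_ols(X, y)
  expect_lt(max(abs(ftr$coef - fo$coef)), 1e-4)
  expect_error(fit_truncated(X, y, bounds = c(0.2, 0.8)),
               "strictly inside")
})

test_that("truncated MLE dominates its OLS start and recovers truth", {
  set.seed(8)
  n <- 4000
  x <- runif(n, 0, 100)
  lat <- -0.2 + 0.006 * x + rnorm(n, 0, 0.25)
  keep <- lat > -0.594 & lat < 0.99
  yt <- lat[keep]; xt <- x[keep]
  f <- fit_truncated(data.frame(x = xt), yt)
  expect_true(f$converged)
  expect_lt(abs(f$coef["x"] - 0.006), 3 * f$se["x"])
  # log-likelihood at the optimum beats the OLS starting values
  M <- cbind(1, xt)
  ols <- stats::lm.fit(M, yt)
  nll_start <- cfqrmap:::trunc_nll(c(ols$coefficients,
                                     log(sd(ols$residuals))),
                                   M, yt, -0.594, 0.99)
  expect_gte(f$loglik, -nll_start)
  # conditional-mean predictions shrink toward the interval
  cm <- predict(f, data.frame(x = xt), type = "conditional")
  expect_true(all(cm < 0.99 & cm > -0.594))
})

test_that("tpm_predict implements the expected-value formula", {
  expect_equal(tpm_predict(1, -5), 1)
  expect_equal(tpm_predict(0, 0.5), 0.5)
  expect_equal(tpm_predict(0.4, 0.7), 0.82)
  expect_error(tpm_predict(1.2, 0.5), "\\[0, 1\\]")
  # monotone increasing in both arguments
  p <- seq(0, 1, 0.1)
  expect_true(all(diff(tpm_predict(p, 0.3)) > 0))
  expect_true(all(diff(tpm_predict(0.3, p)) > 0))
  grid <- expand.grid(p = seq(0, 1, 0.25), y = seq(-0.5, 0.9, 0.2))
  expect_equal(tpm_predict(grid$p, grid$y), grid$p + (1 - grid$p) * grid$y)
})

test_that("the two-part model fits and predicts on cohort data", {
  coh <- test_cohort(800, 13)
  X <- coh[, c("physical", "role", "emotion", "vitality")]
  tf <- fit_tpm(X, coh$utility)
  expect_s3_class(tf$part1, "fitted_mapper")
  expect_equal(tf$part1$family, "logit")
  expect_equal(tf$part2$family, "truncated")
  expect_equal(tf$part2$n, sum(coh$utility < 1))
  pr <- predict(tf, coh)
  expect_length(pr, nrow(coh))
  p1 <- predict(tf$part1, coh)
  expect_true(all(pr <= pmax(1, predict(tf$part2, coh))))
  expect_true(all(p1 > 0 & p1 < 1))
})

test_that("bias-corrected bootstrap: degenerate and symmetric cases", {
  d <- data.frame(y = rep(5, 30))
  bb <- bootstrap_bc(function(dd) c(m = mean(dd$y)), d, reps = 50, seed = 1)
  expect_equal(unname(bb$se), 0)
  expect_equal(unname(bb$ci["m", ]), c(5, 5), ignore_attr = TRUE)
  # with z0 = 0 the BC interval equals the percentile interval
  set.seed(2)
  d2 <- data.frame(y = rnorm(200))
  fitter <- function(dd) c(m = mean(dd$y))
  bb2 <- bootstrap_bc(fitter, d2, reps = 400, seed = 3)
  set.seed(3)
  draws <- replicate(400, mean(sample(d2$y, 200, replace = TRUE)))
  pct <- quantile(draws, c(0.025, 0.975), names = FALSE)
  # the BC endpoints differ from plain percentile only through z0, which is
  # near 0 for the sample mean
  expect_lt(max(abs(unname(bb2$ci["m", ]) - pct)), 0.05)
  expect_error(bootstrap_bc(fitter, d2, reps = 1), "at least 2")
})

test_that("bootstrap BC intervals achieve nominal coverage", {
  set.seed(9)
  hits <- 0L
  n_mc <- 120
  for (i in seq_len(n_mc)) {
    x <- runif(40)
    d <- data.frame(x = x, y = 1 + 2 * x + rnorm(40, 0, 0.5))
    bb <- bootstrap_bc(function(dd) fit_ols(dd["x"], dd$y)$coef,
                       d, reps = 199, seed = i)
    ci <- bb$ci["x", ]
    if (ci[1] <= 2 && 2 <= ci[2]) hits <- hits + 1L
  }
  cover <- hits / n_mc
  # 0.95 nominal; binomial noise at 120 reps allows roughly +/- 0.06
  expect_gt(cover, 0.86)
})

test_that("fitted mappers serialize losslessly", {
  coh <- test_cohort(300, 17)
  X <- coh[, c("physical", "emotion")]
  f <- fit_tobit(X, coh$utility)
  path <- withr::local_tempfile(fileext = ".json")
  write_mapper(f, path)
  f2 <- read_mapper(path)
  expect_equal(f2$coef, f$coef)
  expect_equal(f2$se, f$se)
  expect_equal(f2$family, "tobit")
  expect_equal(predict(f2, coh), predict(f, coh))
  tf <- fit_tpm(X, coh$utility)
  write_mapper(tf, path)
  tf2 <- read_mapper(path)
  expect_equal(predict(tf2, coh), predict(tf, coh))
})
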