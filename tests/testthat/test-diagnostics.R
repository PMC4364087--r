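test_that("prediction errors match hand computations", {
  expect_equal(unname(prediction_errors(c(1, 2, 3), c(1, 2, 3))), c(0, 0))
  expect_equal(unname(prediction_errors(rep(0.5, 4), rep(0.6, 4))["rmse"]),
               0.1)
  e <- prediction_errors(c(0, 1), c(0.5, 0.5))
  expect_equal(unname(e), c(0.25, 0.5))
  expect_equal(unname(e["rmse"]^2), unname(e["mse"]))
  expect_error(prediction_errors(numeric(0), numeric(0)), "empty")
})

test_that("ICC measures agreement, not correlation", {
  set.seed(1)
  x <- rnorm(50)
  expect_equal(icc_agreement(x, x), 1)
  shifted <- x + 2
  expect_lt(icc_agreement(x, shifted), 0.5)
  expect_equal(cor(x, shifted), 1)
  expect_error(icc_agreement(rep(1, 10), rep(1, 10)), "zero total variance")
  expect_error(icc_agreement(1:2, 1:2), "at least 3")
})

test_that("ICC matches the two-way mean-squares oracle on a hand-worked table", {
  obs <- c(9, 6, 8, 7, 10, 6)
  pred <- c(2, 1, 4, 1, 5, 2)
  # independent oracle: two-way ANOVA mean squares via aov()
  d <- data.frame(y = c(obs, pred),
                  subj = factor(rep(1:6, 2)),
                  rater = factor(rep(1:2, each = 6)))
  ms <- summary(aov(y ~ subj + rater, data = d))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2; n <- 6
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(icc_agreement(obs, pred), oracle, tolerance = 1e-12)
})

test_that("VIF flags collinearity as specified", {
  set.seed(2)
  X <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  v <- vif(X)
  expect_true(all(v$vif >= 1 & v$vif < 1.2))
  expect_false(any(v$flagged))
  X$dup <- X$a
  v2 <- vif(X)
  expect_true(is.infinite(v2$vif[v2$predictor == "dup"]))
  expect_true(v2$flagged[v2$predictor == "dup"])
  X2 <- data.frame(a = X$a, near = X$a + rnorm(200, 0, 0.05))
  v3 <- vif(X2)
  expect_true(all(v3$vif > 10))
  expect_error(vif(data.frame(a = 1:5)), "two predictors")
  expect_error(vif(data.frame(a = 1:5, b = rep(2, 5))), "constant")
})

test_that("RESET detects an omitted quadratic and respects df guards", {
  set.seed(3)
  x <- runif(300, 0, 10)
  y_bad <- 0.5 + 0.3 * x - 0.04 * x^2 + rnorm(300, 0.3)
  fb <- fit_ols(data.frame(x = x), y_bad)
  rb <- reset_test(fb, data.frame(x = x), y_bad)
  expect_true(rb$misspecified)
  y_ok <- 0.5 + 0.3 * x + rnorm(300, 0, 0.3)
  fo <- fit_ols(data.frame(x = x), y_ok)
  ro <- reset_test(fo, data.frame(x = x), y_ok)
  expect_gt(ro$p_value, 0.001)
  expect_error(reset_test(fo, data.frame(x = x[1:4]), y_ok[1:4]),
               "too few observations")
  expect_error(reset_test(fit_tobit(data.frame(x = x), y_ok, upper = 100),
                          data.frame(x = x), y_ok), "OLS")
})

test_that("linktest on OLS equals a RESET restricted to the second power", {
  set.seed(4)
  x <- runif(150, 0, 10)
  y <- 1 + 0.2 * x - 0.03 * x^2 + rnorm(150, 0, 0.4)
  f <- fit_ols(data.frame(x = x), y)
  lt <- linktest(f, data.frame(x = x), y)
  r2 <- reset_test(f, data.frame(x = x), y, powers = 2)
  expect_equal(lt$p_value, r2$p_value, tolerance = 1e-6)
  expect_true(lt$misspecified)
  expect_error(linktest(fit_ols(NULL, y), NULL, y), "constant linear predictor")
})

test_that("linktest works for tobit and truncated families", {
  set.seed(5)
  x <- runif(800, 0, 100)
  y <- pmin(-0.1 + 0.011 * x + rnorm(800, 0, 0.2), 1)
  ft <- fit_tobit(data.frame(x = x), y)
  lt <- linktest(ft, data.frame(x = x), y)
  expect_true(is.finite(lt$p_value))
  yy <- y[y < 0.99 & y > -0.594]
  xx <- x[y < 0.99 & y > -0.594]
  ftr <- fit_truncated(data.frame(x = xx), yy)
  lt2 <- linktest(ftr, data.frame(x = xx), yy)
  expect_true(is.finite(lt2$p_value))
})

test_that("subgroup summaries match a hand ANOVA and handle edge cases", {
  obs <- c(0.1, 0.2, 0.5, 0.55, 0.9, 0.95)
  pred <- c(0.2, 0.25, 0.5, 0.5, 0.8, 0.85)
  grp <- c("a", "a", "b", "b", "c", "c")
  s <- subgroup_summary(obs, pred, grp)
  expect_equal(s$table$n, c(2, 2, 2))
  # brute-force between/within mean squares
  gm <- mean(pred)
  means <- tapply(pred, grp, mean)
  ssb <- sum(2 * (means - gm)^2); msb <- ssb / 2
  ssw <- sum((pred - means[grp])^2); msw <- ssw / 3
  expect_equal(s$anova$F, msb / msw, tolerance = 1e-10)
  # single band: ANOVA undefined, flagged
  s1 <- subgroup_summary(obs, pred, rep("a", 6))
  expect_true(is.na(s1$anova$F))
  # two groups with equal predicted means -> F ~ 0
  s2 <- subgroup_summary(obs, c(0.4, 0.6, 0.4, 0.6, 0.5, 0.5),
                         c("a", "a", "b", "b", "a", "b"))
  expect_lt(s2$anova$F, 1e-10)
  # default utility bands cover the scale; empty bands reported with n = 0
  s3 <- subgroup_summary(c(-0.594, 1, 0.65), c(0, 1, 0.6))
  expect_equal(sum(s3$table$n), 3)
  expect_true(any(s3$table$n == 0))
})

test_that("cross-validation partitions the sample and is seed-reproducible", {
  coh <- test_cohort(401, 42)
  cv <- cross_validate(coh, 3, "ols", folds = 4, seed = 5)
  expect_equal(sort(unique(cv$assignments)), 1:4)
  expect_equal(length(cv$assignments), 401)
  expect_equal(sum(cv$fold_table$n), 401)
  expect_true(max(cv$fold_table$n) - min(cv$fold_table$n) <= 1)
  cv2 <- cross_validate(coh, 3, "ols", folds = 4, seed = 5)
  expect_identical(cv$fold_table, cv2$fold_table)
  cv3 <- cross_validate(coh, 3, "ols", folds = 4, seed = 6)
  expect_false(identical(cv$assignments, cv3$assignments))
})

test_that("a correct noiseless model cross-validates with near-zero error", {
  cf <- c("(Intercept)" = -0.1,
          setNames(runif(11, 0.001, 0.005), cfqr_model_domains()))
  d <- generate_linear(cf, n = 400, noise_sd = 0, seed = 7)
  d$utility <- d$outcome
  cv <- cross_validate(d, 1, "ols", folds = 4, seed = 8)
  expect_lt(max(cv$fold_table$rmse), 1e-8)
})
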