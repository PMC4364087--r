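test_that("the specification ladder is declared as enumerated", {
  s1 <- model_spec(1)
  expect_equal(s1$level, "domain")
  expect_null(s1$screening)
  expect_false(s1$squared)
  s3 <- model_spec(3)
  expect_equal(s3$screening, 0.10)
  expect_true(s3$squared)
  expect_false(s3$interactions)
  s4 <- model_spec(4)
  expect_true(s4$interactions)
  s7 <- model_spec(7)
  expect_true(s7$collapse_unordered)
  s8 <- model_spec(8, base = 5)
  expect_equal(s8$level, "item")
  expect_equal(s8$covariates, c("age", "male"))
  expect_error(model_spec(9), "1-8")
  path <- withr::local_tempfile(fileext = ".json")
  write_spec(s8, path)
  expect_equal(read_spec(path), s8)
})

test_that("screening retains exactly the sub-threshold predictors", {
  set.seed(1)
  n <- 400
  X <- data.frame(strong = rnorm(n), null = rnorm(n))
  y <- 0.5 * X$strong + rnorm(n)
  f <- fit_ols(X, y)
  sc <- screen_predictors(f, 0.10)
  expect_true("strong" %in% sc$retained)
  expect_true(all(sc$p_values[sc$retained] < 0.10))
  expect_true(all(sc$p_values[sc$dropped] >= 0.10))
  expect_setequal(c(sc$retained, sc$dropped), c("strong", "null"))
  # threshold 1 retains everything; threshold 0 retains nothing (error)
  expect_setequal(screen_predictors(f, 1)$retained, c("strong", "null"))
  expect_error(screen_predictors(f, 0), "no predictor survives")
})

test_that("a true null predictor survives screening about 10% of the time", {
  set.seed(2)
  n_reps <- 400
  kept <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    X <- data.frame(signal = rnorm(120), noise = rnorm(120))
    y <- 0.8 * X$signal + rnorm(120)
    sc <- screen_predictors(fit_ols(X, y), 0.10)
    kept[i] <- "noise" %in% sc$retained
  }
  rate <- mean(kept)
  # binomial SE at 400 reps ~ 0.015; allow 4 SEs around 0.10
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.16)
})

test_that("unordered items are detected from dummy coefficient monotonicity", {
  fake <- list(coef = c("(Intercept)" = 0,
                        i1_l2 = 0.1, i1_l3 = 0.2, i1_l4 = 0.3,
                        i2_l2 = 0.1, i2_l3 = 0.3, i2_l4 = 0.2),
               se = rep(0.01, 7), family = "ols")
  class(fake) <- "fitted_mapper"
  blocks <- list(`1` = c("i1_l2", "i1_l3", "i1_l4"),
                 `2` = c("i2_l2", "i2_l3", "i2_l4"))
  v <- detect_unordered_items(fake, blocks)
  expect_true(v$ordered[v$item == "1"])
  expect_false(v$ordered[v$item == "2"])
  expect_warning(detect_unordered_items(fake, c(blocks, list(`3` = "absent"))),
                 "fewer than two observed levels")
})

test_that("part-1 level collapsing merges sparse cells toward worse health", {
  set.seed(3)
  # level 1 never observed among ceiling respondents -> {1,2} merged
  r <- c(rep(1:4, each = 40), rep(2:4, each = 40))
  z <- rep(c(0, 1), c(160, 120))
  g <- collapse_for_part1(r, z)
  expect_equal(g[[1]], c(1L, 2L))
  expect_lte(length(g), 3)
  # all levels well populated in both classes -> 3-level cap merges the two worst
  r2 <- rep(1:4, times = 60)
  z2 <- rep(c(0, 1), each = 120)
  g2 <- collapse_for_part1(r2, z2)
  expect_equal(g2, list(c(1L, 2L), 3L, 4L))
  expect_warning(collapse_for_part1(rep(4, 100), rep_len(0:1, 100)),
                 "dropped")
})

test_that("item dummy designs satisfy the one-hot property", {
  coh <- test_cohort(250, 19)
  im <- cfqr_item_map()
  items <- cfqr_model_items(im)[1:5]
  terms <- list()
  rec <- cfqrmap:::recoded_items(coh, im)
  for (it in items)
    terms <- c(terms, cfqrmap:::item_dummy_terms(it, sort(unique(rec[, as.character(it)]))))
  M <- cfqrmap:::build_design(coh, terms, im)
  for (it in items) {
    cols <- grep(paste0("^item", it, "_"), colnames(M))
    ref <- rec[, as.character(it)] == min(rec[, as.character(it)])
    expect_equal(rowSums(M[, cols, drop = FALSE]), 1 - as.numeric(ref))
  }
})

test_that("fit_spec builds the documented predictor sets", {
  coh <- test_cohort(401, 42)
  f1 <- fit_spec(coh, 1, "ols")
  expect_setequal(vapply(f1$terms, cfqrmap:::term_name, character(1)),
                  cfqr_model_domains())
  f3 <- fit_spec(coh, 3, "ols")
  nm3 <- vapply(f3$terms, cfqrmap:::term_name, character(1))
  expect_true(all(sub("_sq$", "", nm3[grepl("_sq$", nm3)]) %in% nm3))
  expect_true(all(nm3[!grepl("_sq$", nm3)] %in% f3$screening$domains$retained))
  expect_false("health" %in% nm3)
  f8 <- fit_spec(coh, 8, "ols", base = 5)
  nm8 <- vapply(f8$terms, cfqrmap:::term_name, character(1))
  expect_true(all(c("age", "male") %in% nm8))
  expect_false(any(grepl("^item43_", nm8)))
  # tpm parts are screened independently
  f3t <- fit_spec(coh, 3, "tpm")
  expect_s3_class(f3t$fit, "tpm_mapper")
  expect_true(length(f3t$screening$part1$domains$retained) >= 1)
  expect_true(length(f3t$screening$part2$domains$retained) >= 1)
})

test_that("spec fits predict out of sample", {
  coh <- test_cohort(401, 42)
  new <- test_cohort(150, 31)
  for (fam in c("ols", "tobit", "tpm")) {
    f <- fit_spec(coh, 3, fam)
    pr <- predict(f, new)
    expect_length(pr, 150)
    expect_true(all(is.finite(pr)))
  }
})
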