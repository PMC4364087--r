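# Shared fixtures, built once per test run.

# Published domain-level OLS coefficients in generate_linear() layout.
table6_ols_coef <- c("(Intercept)" = -0.09898,
                     physical = 0.00651, role = 0.00287, emotion = 0.00693,
                     vitality = 0.00127, eat = 0.00154, weight = -0.00058,
                     digest = 0.00094,
                     physical_sq = -0.00004, emotion_sq = -0.00004)

table6_tpm2_coef <- c("(Intercept)" = -0.22122,
                      physical = 0.00615, role = 0.00336, emotion = 0.00821,
                      vitality = 0.00592, eat = 0.00206, weight = -0.00090,
                      digest = 0.00106,
                      physical_sq = -0.00004, vitality_sq = -0.00005,
                      emotion_sq = -0.00006)

.fixtures <- new.env()

test_cohort <- function(n = 401, seed = 42) {
  key <- paste0("coh_", n, "_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_cohort(cohort_config(n = n, seed = seed))
  .fixtures[[key]]
}

# complete CFQ-R item response table at a single raw level
flat_items <- function(n, level, item_map = cfqr_item_map()) {
  out <- as.data.frame(matrix(level, nrow = n, ncol = nrow(item_map)))
  names(out) <- paste0("item_", item_map$item)
  out
}
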