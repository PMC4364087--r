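# Synthetic cohort generator. One shared latent health trait drives EQ-5D
# dimension levels, CFQ-R item responses and lung function, so the generated
# data carry the cross-instrument dependence a mapping function needs.
# EQ-5D thresholds are calibrated deterministically (quadrature + enumeration
# of the 243 states) against the study's printed marginals: 19% at the
# utility ceiling, 3% negative, mean 0.67.

# Table 2 total-sample domain means (0-100) the item thresholds reproduce.
cfqr_domain_means <- c(physical = 45.71, role = 59.87, vitality = 40.69,
                       emotion = 57.47, social = 56.12, body_image = 58.38,
                       eat = 74.70, treatment = 49.40, health = 44.25,
                       weight = 60.76, respiratory = 49.63, digest = 71.27)

# Latent-trait loadings per domain. Digestive symptoms gets a near-zero
# loading: it was the only domain not tracking FEV1 severity.
cfqr_domain_loadings <- c(physical = 0.85, role = 0.75, vitality = 0.65,
                          emotion = 0.55, social = 0.45, body_image = 0.55,
                          eat = 0.45, treatment = 0.50, health = 0.80,
                          weight = 0.50, respiratory = 0.70, digest = 0.05)

#' Default synthetic cohort configuration
#'
#' The defaults encode the study population: age 28.7 +/- 8.88 on 18-62,
#' 38.9% male, FEV1 %-predicted 65.7 +/- 27.3 on 17-99 with severity bands
#' mild > 70, moderate 41-70, severe < 41, and EQ-5D utility marginals of
#' 19% at ceiling, 3% negative, mean 0.67.
#'
#' @param n Number of respondents.
#' @param seed Integer seed.
#' @param targets Named vector of EQ-5D marginal targets
#'   (`ceiling`, `negative`, `mean`).
#' @param domain_means,domain_loadings Per-domain CFQ-R calibration inputs.
#' @param domain_noise_share Share of an item's non-trait variance shared
#'   within its domain.
#' @param age_mean,age_sd,age_range,male_share,fev1_mean,fev1_sd,fev1_range
#'   Demographic and lung-function distributions.
#' @param fev1_loading Correlation of FEV1 with the latent trait.
#' @param severity_cutpoints FEV1 cut-points (severe below first, mild above
#'   second).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 401, seed = 1,
                          targets = c(ceiling = 0.19, negative = 0.03,
                                      mean = 0.67),
                          domain_means = cfqr_domain_means,
                          domain_loadings = cfqr_domain_loadings,
                          domain_noise_share = 0.5,
                          age_mean = 28.7, age_sd = 8.88,
                          age_range = c(18, 62),
                          male_share = 0.389,
                          fev1_mean = 65.7, fev1_sd = 27.3,
                          fev1_range = c(17, 99), fev1_loading = 0.6,
                          severity_cutpoints = c(41, 70)) {
  stopifnot(n >= 0, all(targets >= 0 & targets <= 1),
            severity_cutpoints[1] < severity_cutpoints[2])
  structure(as.list(environment()), class = "cohort_config")
}

# Quadrature grid over the latent trait (deterministic; fine enough that
# discretization error is far below the calibration tolerance).
trait_grid <- function(k = 121, lim = 5.5) {
  x <- seq(-lim, lim, length.out = k)
  w <- stats::dnorm(x)
  list(x = x, w = w / sum(w))
}

# Marginals of the scored utility implied by thresholds (2 x 5 matrix,
# rows = c("t1","t2"), level 3 below t1, level 2 below t2) and loading rho.
eq5d_implied_marginals <- function(thresholds, rho, value_set, grid = trait_grid()) {
  s <- sqrt(1 - rho^2)
  states <- as.matrix(eq5d_states())
  u <- score_eq5d(states, value_set)
  idx_ceiling <- which(rowSums(states == 1) == 5)
  ceiling_p <- 0; neg_p <- 0; mu <- 0
  for (i in seq_along(grid$x)) {
    z1 <- stats::pnorm((thresholds["t1", ] - rho * grid$x[i]) / s)  # P(level 3)
    z2 <- stats::pnorm((thresholds["t2", ] - rho * grid$x[i]) / s)  # P(level >= 2)
    pl <- rbind(`1` = 1 - z2, `2` = z2 - z1, `3` = z1)
    pr <- pl[cbind(states[, 1], 1)] * pl[cbind(states[, 2], 2)] *
      pl[cbind(states[, 3], 3)] * pl[cbind(states[, 4], 4)] *
      pl[cbind(states[, 5], 5)]
    ceiling_p <- ceiling_p + grid$w[i] * pr[idx_ceiling]
    neg_p <- neg_p + grid$w[i] * sum(pr[u < 0])
    mu <- mu + grid$w[i] * sum(pr * u)
  }
  c(ceiling = unname(ceiling_p), negative = unname(neg_p), mean = unname(mu))
}

# Baseline threshold profile: relative prevalence of problems across the
# five dimensions for an adult CF population (more problems with usual
# activities, pain and mood than with self-care). Shift/gap/rho are the
# calibrated free parameters.
eq5d_base_t2 <- c(mobility = -0.3, self_care = -1.1, usual_activity = 0.2,
                  pain_discomfort = 0.4, anxiety_depression = 0.3)
eq5d_base_gap <- c(mobility = 1.8, self_care = 1.4, usual_activity = 1.6,
                   pain_discomfort = 1.9, anxiety_depression = 1.7)

#' Calibrate EQ-5D ordinal thresholds to target utility marginals
#'
#' Chooses a global threshold shift, a level-3 gap scale and the latent-trait
#' loading so the implied distribution over the 243 EQ-5D states (computed
#' exactly by quadrature over the trait, no Monte Carlo) matches the target
#' ceiling share, negative share and mean utility. The result is
#' deterministic: rerunning yields identical thresholds.
#'
#' @param targets Named numeric: `ceiling`, `negative`, `mean`.
#' @param value_set EQ-5D value set used for scoring.
#' @param tol Named tolerances on the achieved marginals.
#' @param max_iter Optimizer iteration budget.
#' @return List with `thresholds` (2 x 5 matrix, rows `t1` < `t2`), `rho`,
#'   and `achieved` marginals.
#' @export
calibrate_thresholds <- function(targets = c(ceiling = 0.19, negative = 0.03,
                                             mean = 0.67),
                                 value_set = uk_tto_value_set(),
                                 tol = c(ceiling = 0.02, negative = 0.01,
                                         mean = 0.02),
                                 max_iter = 500) {
  stopifnot(all(c("ceiling", "negative", "mean") %in% names(targets)))
  if (targets["ceiling"] >= 1) {
    # degenerate: everyone in full health
    th <- rbind(t1 = rep(-Inf, 5), t2 = rep(-Inf, 5))
    colnames(th) <- eq5d_dimensions
    return(list(thresholds = th, rho = 0.7,
                achieved = c(ceiling = 1, negative = 0, mean = 1)))
  }
  grid <- trait_grid()
  build <- function(par) {
    shift <- par[1]; gap_scale <- exp(par[2])
    t2 <- eq5d_base_t2 + shift
    t1 <- t2 - eq5d_base_gap * gap_scale
    th <- rbind(t1 = t1, t2 = t2)
    colnames(th) <- eq5d_dimensions
    th
  }
  scale <- c(ceiling = 0.01, negative = 0.005, mean = 0.01)
  obj <- function(par) {
    rho <- stats::plogis(par[3])
    m <- eq5d_implied_marginals(build(par), rho, value_set, grid)
    sum(((m - targets[names(m)]) / scale[names(m)])^2)
  }
  opt <- stats::optim(c(0, 0, stats::qlogis(0.7)), obj, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = 1e-12))
  th <- build(opt$par)
  rho <- stats::plogis(opt$par[3])
  achieved <- eq5d_implied_marginals(th, rho, value_set, grid)
  off <- abs(achieved - targets[names(achieved)]) > tol[names(achieved)]
  if (any(off))
    stop("threshold calibration failed; achieved marginals: ",
         paste(sprintf("%s = %.4f", names(achieved), achieved), collapse = ", "))
  list(thresholds = th, rho = rho, achieved = achieved)
}

default_calibration <- function(value_set = uk_tto_value_set()) {
  if (is.null(.cfqrmap_cache$calibration))
    .cfqrmap_cache$calibration <- calibrate_thresholds(value_set = value_set)
  .cfqrmap_cache$calibration
}

# Solve the per-domain item-threshold shift so the marginal expected domain
# score matches the target mean: E[recoded response] = 4 - sum_k Phi(q_k).
item_threshold_shift <- function(target_mean) {
  target_r <- 1 + 3 * target_mean / 100
  f <- function(s) (4 - sum(stats::pnorm(c(-1, 0, 1) + s))) - target_r
  stats::uniroot(f, c(-6, 6), tol = 1e-10)$root
}

#' Generate a synthetic CF cohort
#'
#' Draws a cohort in which one standard-normal latent health trait drives
#' (i) the five EQ-5D dimensions, through calibrated ordinal thresholds,
#' (ii) the 50 CFQ-R item responses, through per-domain loadings and
#' item thresholds solved to reproduce the published domain means, and
#' (iii) FEV1 %-predicted. Utilities are scored from the generated EQ-5D
#' states with the UK tariff, so they always lie on the 243 attainable
#' tariff values. Reproducible under a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param value_set EQ-5D value set used for scoring.
#' @param item_map CFQ-R item map.
#' @return Data frame with one row per respondent: `id`, `age`, `male`,
#'   `fev1`, `fev1_severity`, `trait`, `item_1` ... `item_50` (raw 1-4),
#'   the 12 domain scores, the five EQ-5D dimension levels, `eq5d_state`
#'   and `utility`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            value_set = uk_tto_value_set(),
                            item_map = cfqr_item_map()) {
  n <- config$n
  cal <- if (identical(unname(config$targets),
                       c(0.19, 0.03, 0.67)) &&
             identical(names(config$targets), c("ceiling", "negative", "mean")))
    default_calibration(value_set)
  else calibrate_thresholds(config$targets, value_set)
  schema_cols <- c("id", "age", "male", "fev1", "fev1_severity", "trait",
                   paste0("item_", item_map$item), names(cfqr_domains),
                   eq5d_dimensions, "eq5d_state", "utility")
  if (n == 0) {
    out <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = length(schema_cols),
                                dimnames = list(NULL, schema_cols)))
    out$eq5d_state <- character(0)
    out$fev1_severity <- character(0)
    return(out)
  }
  set.seed(config$seed)
  trait <- stats::rnorm(n)

  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                   config$age_range[1]), config$age_range[2])
  male <- as.integer(stats::runif(n) < config$male_share)
  rf <- config$fev1_loading
  fev1 <- config$fev1_mean +
    config$fev1_sd * (rf * trait + sqrt(1 - rf^2) * stats::rnorm(n))
  fev1 <- pmin(pmax(fev1, config$fev1_range[1]), config$fev1_range[2])
  sev <- cut(fev1, c(-Inf, config$severity_cutpoints, Inf),
             labels = c("severe", "moderate", "mild"), right = TRUE)

  out <- data.frame(id = seq_len(n), age = age, male = male,
                    fev1 = fev1, fev1_severity = as.character(sev),
                    trait = trait)

  # CFQ-R items: shared trait + domain-shared noise + item noise
  w <- sqrt(config$domain_noise_share)
  dom_noise <- matrix(stats::rnorm(n * length(cfqr_domains)), nrow = n,
                      dimnames = list(NULL, names(cfqr_domains)))
  for (i in seq_len(nrow(item_map))) {
    d <- item_map$domain[i]
    lam <- config$domain_loadings[[d]]
    resid_sd <- sqrt(1 - lam^2)
    x <- lam * trait + resid_sd * (w * dom_noise[, d] +
                                   sqrt(1 - w^2) * stats::rnorm(n))
    q <- c(-1, 0, 1) + item_threshold_shift(config$domain_means[[d]])
    recoded <- 1L + (x > q[1]) + (x > q[2]) + (x > q[3])
    out[[paste0("item_", item_map$item[i])]] <-
      if (item_map$reverse[i]) 5L - recoded else recoded
  }
  out <- score_cfqr(out, item_map)

  # EQ-5D dimensions from calibrated thresholds
  rho <- cal$rho; s <- sqrt(1 - rho^2)
  th <- cal$thresholds
  for (j in seq_along(eq5d_dimensions)) {
    h <- rho * trait + s * stats::rnorm(n)
    out[[eq5d_dimensions[j]]] <-
      ifelse(h < th["t1", j], 3L, ifelse(h < th["t2", j], 2L, 1L))
  }
  out$eq5d_state <- apply(out[, eq5d_dimensions], 1, paste, collapse = "")
  out$utility <- score_eq5d(out[, eq5d_dimensions], value_set)
  out[, schema_cols]
}

#' Generate data from a known linear model
#'
#' Parameter-recovery harness: draws predictors uniformly over given ranges,
#' appends squared terms named `<predictor>_sq`, and generates
#' `outcome = linear predictor + Gaussian noise`. Optionally censors the
#' outcome at an upper limit or rejects draws outside a truncation interval
#' (for Tobit / two-part-model tests).
#'
#' @param coef Named coefficient vector; must include `"(Intercept)"`. Names
#'   ending in `_sq` are squares of the matching base predictor.
#' @param n Sample size.
#' @param noise_sd Gaussian noise SD (> 0, or 0 for the noiseless limit).
#' @param ranges Named list of length-2 predictor sampling ranges; default
#'   `c(0, 100)` for every base predictor (the CFQ-R domain scale).
#' @param seed Integer seed.
#' @param mode `"none"`, `"censor"` (outcomes above `limit` set to `limit`)
#'   or `"truncate"` (draws rejected until inside `bounds`).
#' @param limit Censoring limit for `mode = "censor"`.
#' @param bounds Truncation interval for `mode = "truncate"`.
#' @return Data frame of predictors (base columns and `_sq` columns) plus
#'   `outcome`.
#' @export
generate_linear <- function(coef, n, noise_sd = 0.12, ranges = NULL, seed = 1,
                            mode = c("none", "censor", "truncate"), limit = 1,
                            bounds = c(-0.594, 0.99)) {
  mode <- match.arg(mode)
  if (!"(Intercept)" %in% names(coef))
    stop("coefficient vector must include an '(Intercept)' term")
  if (noise_sd < 0) stop("noise SD must be non-negative")
  terms <- setdiff(names(coef), "(Intercept)")
  sq <- grepl("_sq$", terms)
  base <- unique(c(terms[!sq], sub("_sq$", "", terms[sq])))
  bad <- setdiff(names(ranges), base)
  if (length(bad)) stop("range(s) given for unknown predictor(s): ",
                        paste(bad, collapse = ", "))
  set.seed(seed)
  draw <- function(m) {
    X <- as.data.frame(lapply(base, function(v) {
      r <- if (!is.null(ranges[[v]])) ranges[[v]] else c(0, 100)
      stats::runif(m, r[1], r[2])
    }))
    names(X) <- base
    for (v in terms[sq]) X[[v]] <- X[[sub("_sq$", "", v)]]^2
    lp <- coef["(Intercept)"] +
      as.matrix(X[, terms, drop = FALSE]) %*% coef[terms]
    X$outcome <- drop(lp) + if (noise_sd > 0) stats::rnorm(m, 0, noise_sd) else 0
    X
  }
  out <- draw(n)
  if (mode == "censor") {
    out$outcome <- pmin(out$outcome, limit)
  } else if (mode == "truncate") {
    keep <- out$outcome > bounds[1] & out$outcome < bounds[2]
    out <- out[keep, , drop = FALSE]
    guard <- 0L
    while (nrow(out) < n) {
      guard <- guard + 1L
      if (guard > 1000) stop("truncation rejected too many draws")
      extra <- draw(n)
      extra <- extra[extra$outcome > bounds[1] & extra$outcome < bounds[2], ,
                     drop = FALSE]
      out <- rbind(out, extra)
    }
    out <- out[seq_len(n), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
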