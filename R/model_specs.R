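# The eight model specifications, as declarative predictor constructions
# applied ahead of any estimator:
#   1 all domains (Health excluded)        5 all items (Health items, item 43 excluded)
#   2 domains significant at 10%           6 items significant at 10% (joint block test)
#   3 model 2 + significant squared terms  7 model 6 with unordered items dichotomised
#   4 model 3 + interaction terms          8 best-fitting model + gender and age
# Items are dummy coded after reverse coding with level 1 (poor health) as
# the reference. Designs are built from 'term' objects so a fitted pipeline
# can be re-applied to new data.

#' Describe one of the eight model specifications
#'
#' Pure data: building a spec never touches respondent data. Screening and
#' collapsing decisions are made later, by [fit_spec()], from fitted models.
#'
#' @param model Integer 1-8.
#' @param base For model 8, the model number whose specification is extended
#'   with age and gender (default 5, the item-level base used in the
#'   reference analysis).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(model, base = 5) {
  if (!model %in% 1:8) stop("model number must be 1-8")
  level <- if (model %in% 1:4) "domain" else if (model %in% 5:7) "item" else
    if (base %in% 1:4) "domain" else "item"
  structure(list(
    model = model,
    level = level,
    base = if (model == 8) base else NULL,
    screening = if (model %in% c(2, 3, 4, 6, 7) ||
                    (model == 8 && base %in% c(2, 3, 4, 6, 7))) 0.10 else NULL,
    squared = model %in% c(3, 4) || (model == 8 && base %in% c(3, 4)),
    interactions = model == 4 || (model == 8 && base == 4),
    collapse_unordered = model == 7 || (model == 8 && base == 7),
    covariates = if (model == 8) c("age", "male") else character(0)
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model %d (%s level)%s\n", x$model, x$level,
              if (length(x$covariates)) " + age and gender" else ""))
  if (!is.null(x$screening))
    cat("  predictor screening at p <", x$screening, "\n")
  if (x$squared) cat("  screened squared terms\n")
  if (x$interactions) cat("  screened pairwise interactions\n")
  if (x$collapse_unordered) cat("  unordered items dichotomised\n")
  invisible(x)
}

#' Serialize model specifications
#'
#' @param spec A `model_spec`.
#' @param path File path (JSON text).
#' @return `read_spec` returns the restored `model_spec`.
#' @export
write_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- model_spec(obj$model, base = if (!is.null(obj$base)) obj$base else 5)
  spec
}

# ------------------------------------------------------------- terms ----

term_var <- function(name) list(type = "var", name = name)
term_square <- function(name) list(type = "square", name = name)
term_inter <- function(a, b) list(type = "interaction", a = a, b = b)
# indicator that an item's recoded response falls in `levels`
term_item <- function(item, levels) list(type = "item", item = item,
                                         levels = as.integer(levels))

term_name <- function(t) {
  switch(t$type,
         var = t$name,
         square = paste0(t$name, "_sq"),
         interaction = paste0(t$a, ":", t$b),
         item = paste0("item", t$item, "_g", paste(t$levels, collapse = "")))
}

recoded_items <- function(data, item_map) {
  cols <- paste0("item_", item_map$item)
  found <- cols %in% names(data)
  m <- matrix(NA_integer_, nrow(data), nrow(item_map),
              dimnames = list(NULL, as.character(item_map$item)))
  for (i in which(found))
    m[, i] <- reverse_code(data[[cols[i]]], item_map$reverse[i])
  m
}

#' Build a design matrix from term descriptions
#'
#' @param data Respondent table (domain scores, raw item columns,
#'   covariates).
#' @param terms List of term objects as stored in a fitted pipeline.
#' @param item_map CFQ-R item map (needed when item terms are present).
#' @return Numeric matrix, one column per term.
#' @keywords internal
build_design <- function(data, terms, item_map = cfqr_item_map()) {
  rec <- NULL
  cols <- lapply(terms, function(t) {
    switch(t$type,
           var = {
             if (is.null(data[[t$name]])) stop("missing column: ", t$name)
             as.numeric(data[[t$name]])
           },
           square = as.numeric(data[[t$name]])^2,
           interaction = as.numeric(data[[t$a]]) * as.numeric(data[[t$b]]),
           item = {
             if (is.null(rec)) rec <<- recoded_items(data, item_map)
             as.numeric(rec[, as.character(t$item)] %in% t$levels)
           })
  })
  M <- do.call(cbind, cols)
  colnames(M) <- vapply(terms, term_name, character(1))
  M
}

# default dummy terms for one item: indicators for levels 2, 3, 4
# (reference = level 1, poor health), restricted to observed levels
item_dummy_terms <- function(item, observed_levels) {
  lv <- sort(setdiff(observed_levels, min(observed_levels)))
  lapply(lv, function(l) term_item(item, l))
}

# ---------------------------------------------------------- screening ----

#' Screen predictors of a fitted model at a significance threshold
#'
#' Single-pass screen on the full fit: a predictor (or a whole item block,
#' via a joint Wald test across its dummies) is retained when its p-value is
#' below the threshold. The caller refits on the retained set.
#'
#' @param fit A `fitted_mapper`.
#' @param threshold Significance level (default 0.10).
#' @param blocks Optional named list mapping a block label (e.g. item id) to
#'   the coefficient names tested jointly.
#' @return List with `retained`, `dropped` (character vectors of predictor /
#'   block names), `p_values`, and `threshold`.
#' @export
screen_predictors <- function(fit, threshold = 0.10, blocks = NULL) {
  cf <- fit$coef[setdiff(names(fit$coef), "(Intercept)")]
  if (is.null(blocks)) {
    p <- 2 * stats::pnorm(-abs(cf / fit$se[names(cf)]))
  } else {
    p <- vapply(blocks, function(nm) {
      nm <- intersect(nm, names(cf))
      if (!length(nm)) return(NA_real_)
      b <- fit$coef[nm]
      V <- fit$vcov[nm, nm, drop = FALSE]
      W <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
      stats::pchisq(W, df = length(nm), lower.tail = FALSE)
    }, numeric(1))
  }
  keep <- !is.na(p) & p < threshold
  res <- list(retained = names(p)[keep], dropped = names(p)[!keep],
              p_values = p, threshold = threshold)
  if (!length(res$retained))
    stop("no predictor survives screening at p < ", threshold,
         "; use the unscreened specification (Model 1 or 5)")
  res
}

#' Flag items whose dummy coefficients are not ordered
#'
#' An item is `ordered` when its level-2/3/4 dummy coefficients (reference =
#' level 1, poor health) are monotone non-decreasing starting from the
#' implicit 0 of the reference: better response options should carry larger
#' utility. Non-monotone items are flagged for dichotomisation into
#' 'no problems' (best level) versus 'other'.
#'
#' @param fit A `fitted_mapper` from an item-level design.
#' @param blocks Named list: item id -> dummy coefficient names in
#'   increasing-level order.
#' @return Data frame with `item` and logical `ordered`. Items contributing
#'   fewer than one dummy (fewer than two observed levels) are excluded with
#'   a warning.
#' @export
detect_unordered_items <- function(fit, blocks) {
  items <- names(blocks)
  present <- vapply(blocks, function(nm)
    length(intersect(nm, names(fit$coef))) >= 1, logical(1))
  if (any(!present)) {
    warning("item(s) with fewer than two observed levels excluded: ",
            paste(items[!present], collapse = ", "))
    blocks <- blocks[present]; items <- items[present]
  }
  ordered <- vapply(blocks, function(nm) {
    b <- fit$coef[intersect(nm, names(fit$coef))]
    all(diff(c(0, unname(b))) >= 0)
  }, logical(1))
  data.frame(item = items, ordered = unname(ordered),
             stringsAsFactors = FALSE)
}

#' Collapse an item's levels for the two-part model's logit part
#'
#' Levels with a cell count below `min_count` in either outcome class
#' (ceiling versus below-ceiling) are merged with the adjacent level toward
#' worse health; the result is further capped at 3 levels by merging the two
#' worst groups. Returns `NULL` (with a warning) when the item is constant
#' within the ceiling class and should be dropped.
#'
#' @param responses Recoded item responses (1 worst - 4 best).
#' @param z 0/1 ceiling indicator, same length.
#' @param min_count Minimum per-class cell count (default 5).
#' @return List of integer vectors (level groups ordered worst to best;
#'   the first group is the reference), or `NULL`.
#' @export
collapse_for_part1 <- function(responses, z, min_count = 5) {
  keep <- !is.na(responses)
  responses <- responses[keep]; z <- z[keep]
  if (length(unique(responses[z == 1])) <= 1 &&
      length(unique(responses)) <= 1) {
    warning("item constant; dropped from the part-1 design")
    return(NULL)
  }
  groups <- as.list(1:4)
  count_ok <- function(g) {
    ing <- responses %in% g
    sum(ing & z == 1) >= min_count && sum(ing & z == 0) >= min_count
  }
  repeat {
    bad <- which(!vapply(groups, count_ok, logical(1)))
    if (!length(bad) || length(groups) == 1) break
    i <- bad[1]
    j <- if (i > 1) i - 1 else i + 1
    groups[[min(i, j)]] <- sort(c(groups[[min(i, j)]], groups[[max(i, j)]]))
    groups[[max(i, j)]] <- NULL
  }
  while (length(groups) > 3) {
    groups[[1]] <- sort(c(groups[[1]], groups[[2]]))
    groups[[2]] <- NULL
  }
  if (length(groups) < 2) {
    warning("item constant within the ceiling class; dropped from the part-1 design")
    return(NULL)
  }
  groups
}

# ------------------------------------------------------------ fitting ----

fit_family_design <- function(M, y, family, bounds, ceiling) {
  X <- if (is.null(M) || ncol(M) == 0) NULL else M
  switch(family,
         ols = fit_ols(X, y),
         tobit = fit_tobit(X, y, upper = ceiling),
         logit = fit_logit(X, as.numeric(y)),
         truncated = fit_truncated(X, y, bounds = bounds))
}

# screen-and-refit for one single-equation family given candidate terms
ladder_single <- function(data, y, family, spec, item_map, bounds, ceiling,
                          threshold) {
  screening <- list()
  if (spec$level == "domain") {
    terms <- lapply(cfqr_model_domains(), term_var)
    fit <- fit_family_design(build_design(data, terms, item_map), y, family,
                             bounds, ceiling)
    if (!is.null(spec$screening)) {
      sc <- screen_predictors(fit, threshold)
      screening$domains <- sc
      terms <- lapply(sc$retained, term_var)
      fit <- fit_family_design(build_design(data, terms, item_map), y, family,
                               bounds, ceiling)
    }
    retained_domains <- vapply(terms, term_name, character(1))
    if (spec$squared) {
      cand <- lapply(retained_domains, term_square)
      trial <- c(terms, cand)
      fit_all <- fit_family_design(build_design(data, trial, item_map), y,
                                   family, bounds, ceiling)
      p <- 2 * stats::pnorm(-abs(fit_all$coef / fit_all$se))
      sq_names <- vapply(cand, term_name, character(1))
      keep_sq <- sq_names[p[sq_names] < threshold]
      screening$squares <- list(retained = keep_sq,
                                dropped = setdiff(sq_names, keep_sq),
                                p_values = p[sq_names], threshold = threshold)
      terms <- c(terms, cand[sq_names %in% keep_sq])
      fit <- fit_family_design(build_design(data, terms, item_map), y, family,
                               bounds, ceiling)
    }
    if (spec$interactions) {
      if (length(retained_domains) >= 2) {
        prs <- utils::combn(retained_domains, 2, simplify = FALSE)
        cand <- lapply(prs, function(p2) term_inter(p2[1], p2[2]))
        trial <- c(terms, cand)
        fit_all <- fit_family_design(build_design(data, trial, item_map), y,
                                     family, bounds, ceiling)
        p <- 2 * stats::pnorm(-abs(fit_all$coef / fit_all$se))
        in_names <- vapply(cand, term_name, character(1))
        keep_in <- in_names[p[in_names] < threshold]
        screening$interactions <- list(retained = keep_in,
                                       dropped = setdiff(in_names, keep_in),
                                       p_values = p[in_names],
                                       threshold = threshold)
        terms <- c(terms, cand[in_names %in% keep_in])
        fit <- fit_family_design(build_design(data, terms, item_map), y,
                                 family, bounds, ceiling)
      } else {
        screening$interactions <- list(retained = character(0),
                                       dropped = character(0),
                                       note = "fewer than two retained domains: no interaction candidates")
      }
    }
  } else {
    rec <- recoded_items(data, item_map)
    items <- cfqr_model_items(item_map)
    terms <- list()
    for (it in items) {
      obs <- sort(unique(rec[, as.character(it)]))
      terms <- c(terms, item_dummy_terms(it, obs))
    }
    if (family == "logit") {
      # collapse sparse levels for the full-health part
      terms <- list()
      for (it in items) {
        groups <- collapse_for_part1(rec[, as.character(it)], as.numeric(y))
        if (is.null(groups)) next
        terms <- c(terms, lapply(groups[-1], function(g) term_item(it, g)))
      }
    }
    fit <- fit_family_design(build_design(data, terms, item_map), y, family,
                             bounds, ceiling)
    if (!is.null(spec$screening)) {
      blocks <- split(vapply(terms, term_name, character(1)),
                      vapply(terms, function(t) t$item, numeric(1)))
      sc <- screen_predictors(fit, threshold, blocks = blocks)
      screening$items <- sc
      terms <- terms[vapply(terms, function(t)
        as.character(t$item) %in% sc$retained, logical(1))]
      fit <- fit_family_design(build_design(data, terms, item_map), y, family,
                               bounds, ceiling)
    }
    if (spec$collapse_unordered && family != "logit") {
      blocks <- split(vapply(terms, term_name, character(1)),
                      vapply(terms, function(t) t$item, numeric(1)))
      verdict <- detect_unordered_items(fit, blocks)
      unordered <- as.numeric(verdict$item[!verdict$ordered])
      if (length(unordered)) {
        terms <- terms[!vapply(terms, function(t) t$item %in% unordered,
                               logical(1))]
        terms <- c(terms, lapply(unordered, function(it) term_item(it, 4L)))
        fit <- fit_family_design(build_design(data, terms, item_map), y,
                                 family, bounds, ceiling)
      }
      screening$unordered <- verdict
    }
  }
  if (length(spec$covariates)) {
    terms <- c(terms, lapply(spec$covariates, term_var))
    fit <- fit_family_design(build_design(data, terms, item_map), y, family,
                             bounds, ceiling)
  }
  list(fit = fit, terms = terms, screening = screening)
}

#' Fit one model specification with one estimator family
#'
#' Executes the specification ladder (screening, squared terms,
#' interactions, item collapsing) and fits the requested estimator. For the
#' two-part model each part is screened on its own p-values, so the logit
#' and truncated parts may retain different predictor sets.
#'
#' @param data Respondent table containing the 12 domain-score columns (see
#'   [score_cfqr()]), raw `item_*` columns for item-level models, `utility`,
#'   and `age`/`male` for model 8.
#' @param model Model number 1-8 (or a [model_spec()]).
#' @param family `"ols"`, `"tobit"` or `"tpm"`.
#' @param base Base model number for model 8 (default 5).
#' @param threshold Screening significance level (default 0.10).
#' @param ceiling Utility ceiling (default 1).
#' @param bounds Truncation interval for the two-part model's part 2.
#' @param item_map CFQ-R item map.
#' @return An object of class `spec_fit`: the fitted mapper(s), the resolved
#'   term lists, and the screening trail.
#' @export
fit_spec <- function(data, model, family = c("ols", "tobit", "tpm"),
                     base = 5, threshold = 0.10, ceiling = 1,
                     bounds = c(-0.594, 0.99), item_map = cfqr_item_map()) {
  family <- match.arg(family)
  spec <- if (inherits(model, "model_spec")) model else model_spec(model, base)
  y <- data$utility
  if (is.null(y)) stop("data must contain a 'utility' column")
  if (family %in% c("ols", "tobit")) {
    lad <- ladder_single(data, y, family, spec, item_map, bounds, ceiling,
                         threshold)
    out <- list(spec = spec, family = family, fit = lad$fit,
                terms = lad$terms, screening = lad$screening,
                item_map_id = "default")
  } else {
    z <- as.numeric(y >= ceiling - 1e-12)
    lad1 <- ladder_single(data, z, "logit", spec, item_map, bounds, ceiling,
                          threshold)
    below <- z == 0
    lad2 <- ladder_single(data[below, , drop = FALSE], y[below], "truncated",
                          spec, item_map, bounds, ceiling, threshold)
    tpm <- structure(list(part1 = lad1$fit, part2 = lad2$fit,
                          ceiling = ceiling, bounds = bounds,
                          n = length(y), family = "tpm"),
                     class = "tpm_mapper")
    out <- list(spec = spec, family = "tpm", fit = tpm,
                terms = list(part1 = lad1$terms, part2 = lad2$terms),
                screening = list(part1 = lad1$screening,
                                 part2 = lad2$screening),
                item_map_id = "default")
  }
  class(out) <- "spec_fit"
  out
}

#' @export
print.spec_fit <- function(x, ...) {
  cat(sprintf("Specification fit: model %d, %s level, family %s\n",
              x$spec$model, x$spec$level, x$family))
  print(x$fit)
  invisible(x)
}

#' Predict utilities from a fitted specification
#'
#' @param object A `spec_fit` from [fit_spec()].
#' @param newdata Respondent table with the columns the specification needs.
#' @param item_map CFQ-R item map.
#' @param ... unused.
#' @return Predicted utilities.
#' @export
predict.spec_fit <- function(object, newdata, item_map = cfqr_item_map(), ...) {
  lp_from <- function(fit, M) {
    nm <- setdiff(names(fit$coef), "(Intercept)")
    drop(fit$coef["(Intercept)"] + M[, nm, drop = FALSE] %*% fit$coef[nm])
  }
  if (object$family == "tpm") {
    M1 <- build_design(newdata, object$terms$part1, item_map)
    M2 <- build_design(newdata, object$terms$part2, item_map)
    p <- stats::plogis(lp_from(object$fit$part1, M1))
    tpm_predict(p, lp_from(object$fit$part2, M2))
  } else {
    lp_from(object$fit, build_design(newdata, object$terms, item_map))
  }
}
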