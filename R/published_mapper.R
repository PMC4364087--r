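# Applicator for the published domain-level mapping coefficients (the
# recommended OLS Model 3 and two-part Model 3). Coefficients ship as a
# provenance-annotated text file at full printed precision and are never
# hard-coded inline.

published_domains <- c("physical", "role", "emotion", "vitality", "eat",
                       "weight", "digest")

#' Domain-name aliases accepted by the published mapper
#'
#' Maps the long descriptive labels (and the short labels used in the
#' published coefficient table) onto the package's domain keys.
#' @export
domain_aliases <- function() {
  c("physical functioning" = "physical", "physical" = "physical",
    "role functioning" = "role", "role" = "role",
    "emotional functioning" = "emotion", "emotion" = "emotion",
    "emotions" = "emotion",
    "vitality" = "vitality",
    "eating disturbances" = "eat", "eating disturbance" = "eat", "eat" = "eat",
    "weight" = "weight",
    "digestive symptoms" = "digest", "digestion" = "digest", "digest" = "digest")
}

#' Load the published Model 3 mapping coefficients
#'
#' @param model One of `"ols_model3"`, `"tpm_model3_part1"`,
#'   `"tpm_model3_part2"`.
#' @return Data frame with `term`, `coefficient`, `se`, `ci_low`, `ci_high`.
#'   The part-1 constant was not published and is stored as `NA`, never as
#'   zero.
#' @export
published_coefficients <- function(model = c("ols_model3", "tpm_model3_part1",
                                             "tpm_model3_part2")) {
  model <- match.arg(model)
  if (is.null(.cfqrmap_cache$table6)) {
    path <- system.file("extdata", "table6_model3.tsv", package = "cfqrmap",
                        mustWork = TRUE)
    .cfqrmap_cache$table6 <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  tab <- .cfqrmap_cache$table6
  tab[tab$model == model, setdiff(names(tab), "model")]
}

check_domain_scores <- function(scores, required) {
  names(scores) <- tolower(names(scores))
  al <- domain_aliases()
  hit <- names(scores) %in% names(al)
  names(scores)[hit] <- al[names(scores)[hit]]
  missing_d <- setdiff(required, names(scores))
  if (length(missing_d))
    stop("missing required domain score(s): ",
         paste(missing_d, collapse = ", "))
  s <- unlist(scores[required])
  if (any(is.na(s))) stop("missing (NA) domain score(s): ",
                          paste(required[is.na(s)], collapse = ", "))
  if (any(s < 0 | s > 100))
    stop("domain score(s) outside [0, 100]: ",
         paste(required[s < 0 | s > 100], collapse = ", "))
  s
}

eval_published_lp <- function(scores, coefs) {
  terms <- coefs$term[coefs$term != "constant"]
  beta <- stats::setNames(coefs$coefficient[coefs$term != "constant"], terms)
  const <- coefs$coefficient[coefs$term == "constant"]
  base <- sub("_sq$", "", terms)
  x <- scores[base]
  x[grepl("_sq$", terms)] <- x[grepl("_sq$", terms)]^2
  drop(const + sum(beta * x))
}

#' Map CFQ-R domain scores to an EQ-5D utility with the published OLS model
#'
#' Evaluates the published domain-level OLS mapping (Model 3): a
#' linear-quadratic function of the Physical, Role, Emotion, Vitality,
#' Eating, Weight and Digestive domain scores with Physical and Emotion
#' squared terms. Predictions are not clamped by default (the reference
#' analysis reported unclamped OLS predictions up to 1.183); with
#' `clamp = TRUE` they are restricted to the utility scale and flagged.
#'
#' @param scores Named numeric vector or list of domain scores on 0-100.
#'   Long labels such as `"Emotional functioning"` are accepted (see
#'   [domain_aliases()]).
#' @param clamp Clamp predictions to `[-0.594, 1]`?
#' @return List of class `mapped_utility`: `prediction`, `clamped` flag,
#'   `model`.
#' @export
map_ols_model3 <- function(scores, clamp = FALSE) {
  coefs <- published_coefficients("ols_model3")
  s <- check_domain_scores(as.list(scores), published_domains)
  pred <- eval_published_lp(s, coefs)
  out_of_scale <- pred < -0.594 || pred > 1
  structure(list(prediction = if (clamp) min(max(pred, -0.594), 1) else pred,
                 unclamped = pred, clamped = clamp && out_of_scale,
                 out_of_scale = out_of_scale, model = "ols_model3"),
            class = "mapped_utility")
}

#' Map CFQ-R domain scores with the published two-part Model 3
#'
#' Part 1 (logit for full health) uses the published Physical, Role and
#' Emotion coefficients; part 2 is the published truncated-regression linear
#' predictor (seven domains plus Physical, Vitality and Emotion squared
#' terms). The two parts combine by the expected-value formula. The
#' published table prints no part-1 constant, so it must be supplied (for
#' example refitted on local data); without it the mapping refuses to run
#' rather than guessing.
#'
#' @inheritParams map_ols_model3
#' @param part1_constant Intercept for the part-1 logit.
#' @return List of class `mapped_utility` with `prediction`, `p_full_health`,
#'   `part2_prediction`.
#' @export
map_tpm_model3 <- function(scores, part1_constant = NULL, clamp = FALSE) {
  if (is.null(part1_constant) || is.na(part1_constant))
    stop("the published table prints no part-1 constant; supply ",
         "'part1_constant' (e.g. refit the logit part on local data)")
  c1 <- published_coefficients("tpm_model3_part1")
  c2 <- published_coefficients("tpm_model3_part2")
  s <- check_domain_scores(as.list(scores), published_domains)
  c1$coefficient[c1$term == "constant"] <- part1_constant
  p <- stats::plogis(eval_published_lp(s, c1))
  yhat2 <- eval_published_lp(s, c2)
  pred <- tpm_predict(p, yhat2)
  out_of_scale <- pred < -0.594 || pred > 1
  structure(list(prediction = if (clamp) min(max(pred, -0.594), 1) else pred,
                 unclamped = pred, clamped = clamp && out_of_scale,
                 out_of_scale = out_of_scale, p_full_health = p,
                 part2_prediction = yhat2, model = "tpm_model3"),
            class = "mapped_utility")
}

#' @export
print.mapped_utility <- function(x, ...) {
  cat(sprintf("Mapped utility [%s]: %.5f%s\n", x$model, x$prediction,
              if (isTRUE(x$clamped)) " (clamped)" else
                if (isTRUE(x$out_of_scale)) " (outside utility scale)" else ""))
  invisible(x)
}

#' Map a table of CFQ-R domain scores to utilities
#'
#' Row-wise application of a published mapping to a respondent table whose
#' domain columns are resolved through [domain_aliases()]. Rows with missing
#' or out-of-range domain scores are emitted with a missing prediction and a
#' reason.
#'
#' @param data Data frame with domain-score columns.
#' @param model `"ols_model3"` or `"tpm_model3"`.
#' @param clamp Clamp predictions to the utility scale?
#' @param part1_constant Required for `"tpm_model3"`.
#' @return List with `table` (input ids plus `prediction`, `clamped`,
#'   `reason`) and `summary` (n mapped, n skipped, mean/SD of predictions).
#' @export
map_table <- function(data, model = c("ols_model3", "tpm_model3"),
                      clamp = FALSE, part1_constant = NULL) {
  model <- match.arg(model)
  al <- domain_aliases()
  cols <- names(data)
  resolved <- al[match(tolower(cols), names(al))]
  if (!any(published_domains %in% resolved))
    stop("no resolvable domain columns found; expected columns such as ",
         paste(published_domains, collapse = ", "))
  names(data)[!is.na(resolved)] <- resolved[!is.na(resolved)]
  nr <- nrow(data)
  out <- data.frame(row = seq_len(nr), prediction = rep(NA_real_, nr),
                    clamped = rep(FALSE, nr), reason = rep(NA_character_, nr),
                    stringsAsFactors = FALSE)
  if ("id" %in% cols) out$id <- data$id
  for (i in seq_len(nrow(data))) {
    res <- tryCatch({
      sc <- as.list(data[i, intersect(published_domains, names(data)),
                         drop = FALSE])
      if (model == "ols_model3") map_ols_model3(sc, clamp = clamp)
      else map_tpm_model3(sc, part1_constant = part1_constant, clamp = clamp)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      out$reason[i] <- res
    } else {
      out$prediction[i] <- res$prediction
      out$clamped[i] <- isTRUE(res$clamped)
    }
  }
  ok <- !is.na(out$prediction)
  list(table = out,
       summary = list(n_mapped = sum(ok), n_skipped = sum(!ok),
                      mean = if (any(ok)) mean(out$prediction[ok]) else NA_real_,
                      sd = if (sum(ok) > 1) stats::sd(out$prediction[ok])
                           else NA_real_,
                      model = model, clamp = clamp))
}
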