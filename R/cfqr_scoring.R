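#' CFQ-R domain labels
#'
#' Short keys for the 12 domains of the teen/adult CFQ-R, with the display
#' labels used in descriptive tables.
#' @export
cfqr_domains <- c(physical = "Physical functioning",
                  role = "Role functioning",
                  vitality = "Vitality",
                  emotion = "Emotional functioning",
                  social = "Social functioning",
                  body_image = "Body image",
                  eat = "Eating disturbances",
                  treatment = "Treatment burden",
                  health = "Health perceptions",
                  weight = "Weight",
                  respiratory = "Respiratory symptoms",
                  digest = "Digestive symptoms")

#' Read a CFQ-R item map
#'
#' The item map assigns each of the 50 teen/adult CFQ-R items to one of the
#' 12 domains and records which items are reverse-coded and which item is the
#' mucus sub-question (item 43, answered only by a subset of respondents and
#' excluded, with the whole Health-perceptions domain, from all regression
#' models). The CFQ-R manual's official map is licensed separately, so the
#' bundled default is a declared assumption consistent with the instrument's
#' published structure; supply your own file to override it.
#'
#' @param path Tab-separated file with columns `item`, `domain`, `reverse`,
#'   `subquestion`. Defaults to the bundled map.
#' @return A data frame with one row per item and class `cfqr_item_map`.
#' @export
cfqr_item_map <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.cfqrmap_cache$item_map)) return(.cfqrmap_cache$item_map)
    path <- system.file("extdata", "cfqr_item_map.tsv",
                        package = "cfqrmap", mustWork = TRUE)
    default <- TRUE
  } else default <- FALSE
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("item", "domain", "reverse", "subquestion")
  if (!all(need %in% names(m)))
    stop("item map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$item)) stop("duplicate item ids in item map")
  bad <- setdiff(unique(m$domain), names(cfqr_domains))
  if (length(bad)) stop("unknown domain(s) in item map: ",
                        paste(bad, collapse = ", "))
  m$reverse <- as.logical(m$reverse)
  m$subquestion <- as.logical(m$subquestion)
  class(m) <- c("cfqr_item_map", "data.frame")
  if (default) .cfqrmap_cache$item_map <- m
  m
}

#' Reverse-code CFQ-R item responses
#'
#' Flagged items are mapped r -> 5 - r on the 1-4 response scale so that,
#' after recoding, higher always means better health. Applying the recode
#' twice returns the input (involution).
#'
#' @param response Integer responses in 1-4 (NA allowed).
#' @param flag Logical, recycled: is the item reverse-coded?
#' @return Recoded responses on the same 1-4 scale.
#' @export
reverse_code <- function(response, flag) {
  ok <- is.na(response) | (response %in% 1:4)
  if (!all(ok))
    stop("invalid CFQ-R response(s): ",
         paste(unique(response[!ok]), collapse = ", "),
         " (must be 1-4 or missing)")
  ifelse(rep_len(flag, length(response)), 5L - as.integer(response),
         as.integer(response))
}

#' Score one CFQ-R domain
#'
#' Linear 0-100 rescaling of the mean recoded response:
#' `100 * (mean - 1) / 3`. All items at the best level (4) score 100; all at
#' the worst level (1) score 0. Missing items are dropped from the mean;
#' if fewer than `min_answered` of the domain's items were answered the
#' domain score is `NA`.
#'
#' @param responses Recoded responses (1-4, higher = better) for the items of
#'   one domain.
#' @param min_answered Minimum fraction of items that must be non-missing
#'   (half-scale rule; default 0.5).
#' @return Domain score in `[0, 100]`, or `NA` if too few items answered.
#' @export
score_domain <- function(responses, min_answered = 0.5) {
  ok <- is.na(responses) | (responses %in% 1:4)
  if (!all(ok)) stop("invalid recoded response(s): must be 1-4 or missing")
  n_ans <- sum(!is.na(responses))
  if (length(responses) == 0 || n_ans < min_answered * length(responses))
    return(NA_real_)
  100 * (mean(responses, na.rm = TRUE) - 1) / 3
}

#' Score CFQ-R records to domain scores
#'
#' Takes a table with item columns `item_1` ... `item_50` (raw 1-4
#' responses), applies reverse coding per the item map, and returns the 12
#' domain scores on 0-100 for each respondent. All 12 domains are scored for
#' description; [cfqr_model_domains()] and [cfqr_model_items()] give the
#' views eligible for regression modelling, which exclude the Health
#' perceptions domain and item 43 (the mucus sub-question).
#'
#' @param data Data frame with columns `item_1` ... `item_50`; extra columns
#'   are preserved in the output.
#' @param item_map A [cfqr_item_map()].
#' @param min_answered Half-scale rule passed to [score_domain()].
#' @return `data` with 12 domain-score columns appended (short keys of
#'   [cfqr_domains]).
#' @export
score_cfqr <- function(data, item_map = cfqr_item_map(), min_answered = 0.5) {
  item_cols <- paste0("item_", item_map$item)
  present <- item_cols %in% names(data)
  if (!any(present)) stop("no CFQ-R item columns (item_1 ... item_50) found")
  recoded <- matrix(NA_integer_, nrow = nrow(data), ncol = nrow(item_map),
                    dimnames = list(NULL, item_cols))
  for (i in seq_len(nrow(item_map))) {
    if (present[i])
      recoded[, i] <- reverse_code(data[[item_cols[i]]], item_map$reverse[i])
  }
  for (d in names(cfqr_domains)) {
    idx <- which(item_map$domain == d)
    data[[d]] <- apply(recoded[, idx, drop = FALSE], 1, score_domain,
                       min_answered = min_answered)
  }
  data
}

#' Modelling views of the CFQ-R
#'
#' `cfqr_model_domains()` returns the 11 domain keys eligible as regression
#' predictors (Health perceptions excluded: its items measure overall health
#' and would be redundant/collinear with the outcome construct).
#' `cfqr_model_items()` returns the 49 eligible item ids (item 43 excluded
#' as a sub-question, plus the Health-perceptions items).
#'
#' @param item_map A [cfqr_item_map()].
#' @return Character vector of domain keys / integer vector of item ids.
#' @export
cfqr_model_domains <- function() {
  setdiff(names(cfqr_domains), "health")
}

#' @rdname cfqr_model_domains
#' @export
cfqr_model_items <- function(item_map = cfqr_item_map()) {
  keep <- !item_map$subquestion & item_map$domain != "health"
  item_map$item[keep]
}
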