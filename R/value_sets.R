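#' @keywords internal
"_PACKAGE"

#' EQ-5D-3L dimension names
#'
#' The five dimensions of the EQ-5D-3L descriptive system, in conventional
#' order: mobility, self-care, usual activity, pain/discomfort,
#' anxiety/depression.
#' @export
eq5d_dimensions <- c("mobility", "self_care", "usual_activity",
                     "pain_discomfort", "anxiety_depression")

#' Read an EQ-5D-3L value set from a key/value text file
#'
#' A value set (tariff) converts an EQ-5D-3L descriptive-system state into a
#' utility. The file format is Debian-control-style `key: value` text with a
#' `constant` (decrement applied once for any move away from full health), an
#' `n3` term (decrement applied once if any dimension is at level 3), and a
#' decrement per dimension and level (`<dimension>_2`, `<dimension>_3`).
#'
#' @param path Path to the value-set file. The default is the bundled UK
#'   general-population time-trade-off tariff, whose utilities span
#'   \eqn{[-0.594, 1]}.
#' @param validate If `TRUE`, check the loaded tariff against its anchors:
#'   full health scores exactly 1 and every decrement is non-negative with
#'   the level-3 decrement at least the level-2 decrement.
#' @return An object of class `eq5d_value_set`: a list with elements `id`,
#'   `constant`, `n3`, and `decrements` (a 2 x 5 matrix, rows = levels 2 and
#'   3, columns = dimensions).
#' @examples
#' vs <- uk_tto_value_set()
#' score_eq5d_state(c(1, 1, 1, 1, 1), vs)
#' @export
read_value_set <- function(path, validate = TRUE) {
  raw <- read.dcf(path)
  kv <- as.list(raw[1, ])
  need <- c("id", "constant", "n3",
            paste0(rep(eq5d_dimensions, each = 2), "_", 2:3))
  missing_keys <- setdiff(need, names(kv))
  if (length(missing_keys))
    stop("value-set file is missing keys: ", paste(missing_keys, collapse = ", "))
  dec <- matrix(NA_real_, nrow = 2, ncol = 5,
                dimnames = list(c("2", "3"), eq5d_dimensions))
  for (d in eq5d_dimensions) {
    dec["2", d] <- as.numeric(kv[[paste0(d, "_2")]])
    dec["3", d] <- as.numeric(kv[[paste0(d, "_3")]])
  }
  vs <- structure(list(id = kv$id,
                       constant = as.numeric(kv$constant),
                       n3 = as.numeric(kv$n3),
                       decrements = dec),
                  class = "eq5d_value_set")
  if (validate) {
    if (any(dec < 0) || vs$constant < 0 || vs$n3 < 0)
      stop("value set '", vs$id, "' has negative decrements")
    if (any(dec["3", ] < dec["2", ]))
      stop("value set '", vs$id, "' has level-3 decrements below level-2")
  }
  vs
}

.cfqrmap_cache <- new.env(parent = emptyenv())

#' @rdname read_value_set
#' @export
uk_tto_value_set <- function() {
  if (is.null(.cfqrmap_cache$uk_tto)) {
    vs <- read_value_set(system.file("extdata", "uk_tto.dcf",
                                     package = "cfqrmap", mustWork = TRUE))
    b <- utility_bounds(vs)
    # anchors printed for the UK tariff: full health 1, worst state -0.594
    stopifnot(b[2] == 1, abs(b[1] - (-0.594)) < 1e-12)
    .cfqrmap_cache$uk_tto <- vs
  }
  .cfqrmap_cache$uk_tto
}

#' @export
print.eq5d_value_set <- function(x, ...) {
  b <- utility_bounds(x)
  cat("EQ-5D-3L value set:", x$id, "\n")
  cat(sprintf("  constant %.3f, N3 %.3f, utility range [%.3f, %.3f]\n",
              x$constant, x$n3, b[1], b[2]))
  invisible(x)
}

check_eq5d_levels <- function(state) {
  state <- as.integer(state)
  if (length(state) != 5)
    stop("an EQ-5D-3L state has exactly five dimensions")
  bad <- which(is.na(state) | state < 1L | state > 3L)
  if (length(bad))
    stop("invalid EQ-5D level in dimension '", eq5d_dimensions[bad[1]],
         "': levels must be 1, 2 or 3")
  state
}

#' Score EQ-5D-3L states to utilities
#'
#' `score_eq5d_state()` scores a single five-level state;
#' `score_eq5d()` scores a matrix or data frame of states row-wise, or a
#' character vector of 5-digit state strings such as `"21132"`.
#'
#' Full health (1,1,1,1,1) scores exactly 1. Any other state subtracts the
#' tariff constant, the per-dimension decrements for levels 2/3, and the N3
#' term if any dimension is at level 3.
#'
#' @param state Integer vector of length 5 (levels 1-3 for mobility,
#'   self-care, usual activity, pain/discomfort, anxiety/depression).
#' @param states A matrix/data frame with five level columns, or a character
#'   vector of 5-digit strings.
#' @param value_set An `eq5d_value_set`; defaults to the UK TTO tariff.
#' @return Utility value(s) in `[min utility, 1]`.
#' @examples
#' score_eq5d_state(c(3, 3, 3, 3, 3))  # -0.594 under the UK tariff
#' score_eq5d(c("11111", "11112"))
#' @export
score_eq5d_state <- function(state, value_set = uk_tto_value_set()) {
  state <- check_eq5d_levels(state)
  if (all(state == 1L)) return(1)
  dec <- value_set$decrements
  u <- 1 - value_set$constant
  for (j in seq_len(5)) {
    if (state[j] > 1L) u <- u - dec[state[j] - 1L, j]
  }
  if (any(state == 3L)) u <- u - value_set$n3
  u
}

#' @rdname score_eq5d_state
#' @export
score_eq5d <- function(states, value_set = uk_tto_value_set()) {
  if (is.character(states)) {
    if (any(nchar(states) != 5 & !is.na(states)))
      stop("EQ-5D state strings must have exactly 5 digits")
    states <- t(vapply(states, function(s) {
      if (is.na(s)) rep(NA_integer_, 5)
      else as.integer(strsplit(s, "")[[1]])
    }, integer(5)))
    rownames(states) <- NULL
  }
  states <- as.matrix(states)
  if (ncol(states) != 5) stop("expected five EQ-5D level columns")
  apply(states, 1, function(s) {
    if (anyNA(s)) NA_real_ else score_eq5d_state(s, value_set)
  })
}

#' Enumerate all 243 EQ-5D-3L states
#'
#' @param value_set Optionally, a value set; if supplied, a `utility` column
#'   is appended.
#' @return A data frame with 243 rows, one per descriptive-system state.
#' @export
eq5d_states <- function(value_set = NULL) {
  g <- expand.grid(mobility = 1:3, self_care = 1:3, usual_activity = 1:3,
                   pain_discomfort = 1:3, anxiety_depression = 1:3,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[do.call(order, g), , drop = FALSE]
  rownames(g) <- apply(g, 1, paste, collapse = "")
  if (!is.null(value_set))
    g$utility <- score_eq5d(g[, eq5d_dimensions], value_set)
  g
}

#' Utility range attainable under a value set
#'
#' Computes the minimum by brute force over all 243 states (for any
#' monotone tariff this equals the score of the all-3s state) and the
#' maximum (full health, 1).
#'
#' @inheritParams score_eq5d_state
#' @return Numeric vector `c(min, max)`.
#' @export
utility_bounds <- function(value_set = uk_tto_value_set()) {
  u <- score_eq5d(as.matrix(eq5d_states()), value_set)
  c(min(u), 1)
}
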