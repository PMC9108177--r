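# Internal helpers shared across modules.

# Run `fn()` under `set.seed(seed)`, restoring the caller's RNG state.
with_preserved_seed <- function(seed, fn) {
  if (is.null(seed)) {
    return(fn())
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  fn()
}

# Deterministic per-stage seed derived from a global seed and a stage name,
# kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(global_seed, stage) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(global_seed) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# ---- expression matrices ----------------------------------------------------

#' Construct a tagged expression matrix
#'
#' An expression matrix is a plain numeric matrix (features in rows, samples
#' in columns) carrying a `unit` attribute that records what the values are:
#' raw read counts (`"counts"`), reads per million (`"RPM"`), or
#' log2-transformed expression (`"log2"`). Downstream operations check the
#' tag so that, e.g., activity calling is only run on RPM values.
#'
#' @param values Numeric matrix with unique, non-empty rownames (feature ids)
#'   and colnames (sample ids).
#' @param unit One of `"counts"`, `"RPM"`, `"log2"`.
#' @return The matrix with its `unit` attribute set.
#' @examples
#' m <- matrix(rpois(6, 10), 2, 3,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' em <- expr_matrix(m, "counts")
#' expr_unit(em)
#' @export
expr_matrix <- function(values, unit = c("counts", "RPM", "log2")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("expression matrix needs feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) abort("duplicate feature ids")
  if (anyDuplicated(colnames(values))) abort("duplicate sample ids")
  if (anyNA(values)) abort("expression matrix contains missing values")
  if (unit == "counts" && any(values < 0)) abort("counts must be non-negative")
  attr(values, "unit") <- unit
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @rdname expr_matrix
#' @param i,j,drop Standard matrix subsetting arguments; matrix results
#'   keep their unit tag.
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = TRUE) {
  unit <- attr(x, "unit", exact = TRUE)
  cl <- oldClass(x)
  out <- NextMethod()
  if (is.matrix(out)) {
    attr(out, "unit") <- unit
    class(out) <- cl
  }
  out
}

#' @method print expr_matrix
#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix: %d features x %d samples, unit = %s>\n",
              nrow(x), ncol(x), attr(x, "unit", exact = TRUE)))
  print(utils::head(unclass(x)[, seq_len(min(6, ncol(x))), drop = FALSE]))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x A matrix produced by [expr_matrix()].
#' @export
expr_unit <- function(x) {
  u <- attr(x, "unit", exact = TRUE)
  if (is.null(u)) abort("matrix has no `unit` tag; use expr_matrix()")
  u
}

require_unit <- function(x, unit) {
  if (!identical(expr_unit(x), unit)) {
    abort(sprintf("expected a %s matrix, got %s", unit, expr_unit(x)))
  }
  invisible(x)
}

# Shared samples between two expression matrices (columns), with a logged count.
shared_samples <- function(a, b, min_n = 3L) {
  common <- intersect(colnames(a), colnames(b))
  if (length(common) < min_n) {
    abort(sprintf("need at least %d shared samples, found %d", min_n, length(common)))
  }
  if (length(common) < ncol(a) || length(common) < ncol(b)) {
    inform(sprintf("using %d shared samples (of %d and %d)",
                   length(common), ncol(a), ncol(b)))
  }
  common
}

# Row-wise z-score; rows with zero variance become all-zero.
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  s[s == 0] <- 1
  (x - mu) / s
}
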