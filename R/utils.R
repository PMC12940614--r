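#' Evaluate an expression under a private RNG stream
#'
#' All generators in this package take an explicit seed and restore the
#' caller's RNG state on exit, so simulation never perturbs (or depends on)
#' global random state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
#' @noRd
with_rng <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

## derive a reproducible child seed (kept < 2^31)
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629L) + 1L
}

#' @noRd
is_expression_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && !is.null(rownames(x)) && !is.null(colnames(x))
}

assert_expression <- function(expr, allow_negative = FALSE) {
  if (!is_expression_matrix(expr))
    stop("expression must be a numeric matrix with gene rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene symbols in expression matrix", call. = FALSE)
  if (anyNA(expr)) stop("expression matrix contains missing values", call. = FALSE)
  if (!allow_negative && any(expr < 0))
    stop("expression values must be >= 0 on the log2(x+1) input scale", call. = FALSE)
  invisible(expr)
}

## fixed 6-significant-digit formatting for all floating-point table output,
## so text artifacts (and their hashes) are portable across platforms
format_num <- function(x, digits = 6L) {
  ifelse(is.na(x), NA_character_, formatC(signif(x, digits), format = "g", digits = digits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
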