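# Internal helpers shared across modules.

ms_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "microshift_error"), ...)
}

ms_warn <- function(message, class = "microshift_warning") {
  rlang::warn(message, class = class)
}

#' Derive a reproducible per-stage seed from a top-level seed
#'
#' Hashes a stage name into an integer offset so that each pipeline stage
#' receives its own deterministic RNG stream from a single top-level seed.
#' The result is always a valid 32-bit integer seed.
#'
#' @param seed Integer top-level seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) * 7919
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# centered log-ratio of a strictly positive composition
clr <- function(p) {
  lp <- log(p)
  lp - mean(lp)
}

# Coerce a samples-by-genera tibble (first column sample_id) to a numeric
# matrix with sample ids as rownames.  Used by every numerical stage.
as_sample_matrix <- function(x, what = "count table") {
  if (!is.data.frame(x)) {
    ms_abort(sprintf("%s must be a data frame", what), "ms_validation_error")
  }
  if (!"sample_id" %in% names(x)) {
    ms_abort(sprintf("%s must have a 'sample_id' column", what),
             "ms_schema_error")
  }
  ids <- as.character(x$sample_id)
  num <- x[setdiff(names(x), "sample_id")]
  bad <- names(num)[!vapply(num, is.numeric, logical(1))]
  if (length(bad) > 0) {
    ms_abort(sprintf("non-numeric genus columns in %s: %s", what,
                     paste(bad, collapse = ", ")),
             "ms_format_error")
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  m
}

# Numeric matrix back to wide tibble with sample_id first.
matrix_to_tibble <- function(m) {
  out <- as_tibble(m)
  dplyr::bind_cols(tibble(sample_id = rownames(m)), out)
}

check_simplex <- function(p, tol = 1e-6, arg = "p") {
  if (!is.numeric(p) || length(p) < 1) {
    ms_abort(sprintf("%s must be a numeric vector", arg), "ms_validation_error")
  }
  if (any(!is.finite(p)) || any(p < -tol)) {
    ms_abort(sprintf("%s must be non-negative and finite", arg),
             "ms_validation_error")
  }
  if (abs(sum(p) - 1) > tol) {
    ms_abort(sprintf("%s must sum to 1 (simplex); got %.8f", arg, sum(p)),
             "ms_validation_error")
  }
  invisible(TRUE)
}

trapezoid <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}
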