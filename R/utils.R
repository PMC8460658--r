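#' @keywords internal
"_PACKAGE"

# Oral sites and HUMAnN2 bookkeeping rows used throughout.
ORAL_SITES <- c("plaque", "tongue", "saliva")
HEALTH_STATUS <- c("healthy", "periodontitis")
SPECIAL_FEATURES <- c("UNMAPPED", "UNINTEGRATED")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific child seed from a master seed
#'
#' Deterministic fan-out so that pipeline stages can be rerun in isolation
#' with the same random stream they received inside the full run. The result
#' always fits in a 32-bit integer.
#'
#' @param master integer master seed.
#' @param stage integer stage index (>= 0).
#' @return an integer seed.
#' @export
child_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.numeric(stage))
  as.integer((abs(as.numeric(master)) %% 1e6) * 2011 + stage * 7919) %% 2147483647L
}

# Row variances without matrixStats.
row_vars <- function(x, means = rowMeans(x)) {
  n <- ncol(x)
  rowSums((x - means)^2) / (n - 1)
}

# Vectorized row medians: one order() call sorts within rows.
row_medians <- function(x) {
  n <- ncol(x)
  xs <- matrix(x[order(row(x), x)], nrow(x), n, byrow = TRUE)
  if (n %% 2) xs[, (n + 1) / 2] else (xs[, n / 2] + xs[, n / 2 + 1]) / 2
}

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

assert_matrix_nonneg <- function(m, what = "abundance") {
  if (any(!is.finite(m))) stop_format("%s contains non-finite values", what)
  if (any(m < 0)) stop_format("%s contains negative values", what)
  invisible(m)
}
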