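#' Construct a peri-event trace matrix
#'
#' A trace matrix is the common currency of all analyses in this package: an
#' aligned collection of peri-event dF traces (one row per subject or trial,
#' one column per timepoint), all sharing a sampling rate.
#'
#' @param values Numeric matrix (rows = traces, columns = timepoints) of
#'   finite dF values.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param condition Optional condition label (e.g. `"null"`, `"ert"`,
#'   `"baseline"`) carried as metadata.
#' @return An object of class `trace_matrix` (a numeric matrix with `fs` and
#'   `condition` attributes).
#' @examples
#' tm <- trace_matrix(matrix(rnorm(50), 5, 10), fs = 10)
#' sampling_rate(tm)
#' @export
trace_matrix <- function(values, fs, condition = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 1L || ncol(values) < 1L)
    stop("'values' must be a non-empty numeric matrix")
  if (!all(is.finite(values)))
    stop("trace values must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number")
  if (!is.null(condition)) condition <- as.character(condition)[1L]
  structure(values, fs = as.numeric(fs), condition = condition,
            class = c("trace_matrix", class(values)))
}

#' @rdname trace_matrix
#' @param x A `trace_matrix`.
#' @export
sampling_rate <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) stop("object carries no sampling rate")
  fs
}

#' @rdname trace_matrix
#' @export
trace_times <- function(x) {
  (seq_len(ncol(x)) - 1L) / sampling_rate(x)
}

#' @export
print.trace_matrix <- function(x, ...) {
  cond <- attr(x, "condition")
  cat(sprintf("trace_matrix: %d trace(s) x %d timepoints @ %g Hz%s\n",
              nrow(x), ncol(x), sampling_rate(x),
              if (is.null(cond)) "" else paste0(" [", cond, "]")))
  invisible(x)
}

#' @export
`[.trace_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, fs = attr(x, "fs"), condition = attr(x, "condition"),
                     class = class(x))
  out
}

# Accept either a trace_matrix or a bare matrix in analysis entry points.
as_matrix_ <- function(x) {
  if (inherits(x, "trace_matrix")) class(x) <- setdiff(class(x), "trace_matrix")
  as.matrix(x)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
# A NULL seed means "use the current stream as-is".
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
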