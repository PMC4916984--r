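#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor lm.fit predict rnorm runif sd t.test quantile coef fitted residuals setNames
#' @importFrom utils read.table write.table head
#' @importFrom graphics plot abline
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
# All stochastic operations in the package go through this so that results are
# reproducible from their `seed` arguments without clobbering the session RNG.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop(sprintf("'%s' must be a single finite number >= %s", name, min),
         call. = FALSE)
  }
  invisible(x)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

DNA_BASES <- c("A", "C", "G", "T")
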