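# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# seed for a named substream, kept inside the 32-bit integer range
substream_seed <- function(seed, stream) {
  offsets <- c(generator = 0L, missingness = 1L, imputation = 2L,
               sampler = 3L, permutation = 4L, ppc = 5L, pipeline = 6L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 7L + off) %% 2147483647)
}

stop_input <- function(...) stop(..., call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x == round(x) && x >= 0

`%||%` <- function(a, b) if (is.null(a)) b else a

# quantile helper returning named lo/hi columns for a central interval
central_interval <- function(x, level) {
  a <- (1 - level) / 2
  unname(quantile(x, c(a, 1 - a), names = FALSE, type = 7))
}
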