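#' Derive a named substream seed from a master seed
#'
#' Each generator in the package draws from its own substream so that any
#' component can be regenerated independently of the others. The substream
#' seed is a deterministic hash of the master seed and a stream name, kept
#' within the 32-bit integer range.
#'
#' @param master integer master seed.
#' @param name character stream name.
#' @return an integer seed.
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(master) %% 2147483647 + h * 7919) %% 2147483647)
}

# Run an expression with a local RNG state seeded by `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# z-score a numeric vector; errors on constant input with the column name.
zscore <- function(x, name = deparse(substitute(x))) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize constant column: ", name, call. = FALSE)
  }
  (x - mean(x)) / s
}
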