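#' @useDynLib binamr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim pbinom dt rnorm runif setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All randomized operations in the package route through this
# so that identical (inputs, seed) give bitwise-identical results.
with_seed <- function(seed, expr) {
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
  force(expr)
}

stopifnot_scalar_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

stopifnot_binary_matrix <- function(x, name) {
  if (!is.matrix(x) || !all(x %in% c(0, 1)))
    stop(sprintf("`%s` must be a binary (0/1) matrix", name), call. = FALSE)
  storage.mode(x) <- "integer"
  x
}

# log2 of the generalized binomial coefficient C(a, b) via log-gamma;
# reduces to the ordinary binomial for integer arguments.
lchoose2 <- function(a, b) {
  (lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)) / log(2)
}
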