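#' Data parameters of a binary associative memory
#'
#' Bundles the dimensions of a BiNAM experiment: input/output vector lengths
#' \code{m}, \code{n}, the number of ones per input pattern \code{c} and per
#' output pattern \code{d}, and the sample count \code{N}.
#'
#' @param m Input vector length (number of input channels), positive integer.
#' @param n Output vector length (number of output neurons), positive integer.
#' @param c Ones per input pattern, \code{1 <= c <= m}.
#' @param d Ones per output pattern, \code{1 <= d <= n}.
#' @param N Number of key/value pairs to store, non-negative integer. Use
#'   \code{NULL} to defer to [optimal_sample_count()].
#' @return An object of class \code{"binam_data_params"}.
#' @examples
#' data_params(m = 16, n = 16, c = 4, d = 4, N = 10)
#' @export
data_params <- function(m, n, c, d, N = NULL) {
  m <- stopifnot_scalar_int(m, "m")
  n <- stopifnot_scalar_int(n, "n")
  c <- stopifnot_scalar_int(c, "c")
  d <- stopifnot_scalar_int(d, "d")
  if (c > m) stop("`c` must satisfy 1 <= c <= m", call. = FALSE)
  if (d > n) stop("`d` must satisfy 1 <= d <= n", call. = FALSE)
  if (is.null(N)) N <- optimal_sample_count(m, n, c, d)
  N <- stopifnot_scalar_int(N, "N", min = 0L)
  structure(list(m = m, n = n, c = c, d = d, N = N),
            class = "binam_data_params")
}

#' @export
print.binam_data_params <- function(x, ...) {
  cat(sprintf("BiNAM data parameters: m = %d, n = %d, c = %d, d = %d, N = %d\n",
              x$m, x$n, x$c, x$d, x$N))
  invisible(x)
}

# Draw one sparse binary row of length `m` with `w` ones, preferring the
# currently least-used columns. `greedy = TRUE` picks the minimal-usage
# columns outright (random tie-break); otherwise columns are sampled
# without replacement with probability decreasing in current usage.
draw_balanced_row <- function(usage, w, greedy = TRUE) {
  m <- length(usage)
  if (greedy) {
    ord <- order(usage, runif(m))
    ord[seq_len(w)]
  } else {
    wt <- max(usage) - usage + 1
    sample.int(m, w, prob = wt)
  }
}

generate_matrix <- function(nrow, ncol, weight, label) {
  n_distinct <- exp(lchoose(ncol, weight))
  if (nrow > n_distinct)
    stop(sprintf("cannot generate %d distinct %s patterns: only %.0f vectors of length %d with %d ones exist",
                 nrow, label, n_distinct, ncol, weight), call. = FALSE)
  X <- matrix(0L, nrow, ncol)
  usage <- integer(ncol)
  keys <- character(0)
  for (k in seq_len(nrow)) {
    ok <- FALSE
    for (attempt in seq_len(1000L)) {
      idx <- sort(draw_balanced_row(usage, weight, greedy = attempt == 1L))
      key <- paste(idx, collapse = ",")
      if (!key %in% keys) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf("failed to draw a distinct %s pattern for row %d", label, k),
           call. = FALSE)
    X[k, idx] <- 1L
    usage[idx] <- usage[idx] + 1L
    keys <- c(keys, key)
  }
  X
}

# Unconstrained uniform sampling of distinct sparse rows (no balancing);
# matches the independence assumptions behind the expected-false-positive
# formula and is used by the Monte-Carlo capacity checks.
generate_matrix_uniform <- function(nrow, ncol, weight, label) {
  X <- matrix(0L, nrow, ncol)
  keys <- character(0)
  for (k in seq_len(nrow)) {
    ok <- FALSE
    for (attempt in seq_len(10000L)) {
      idx <- sort(sample.int(ncol, weight))
      key <- paste(idx, collapse = ",")
      if (!key %in% keys) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf("failed to draw a distinct %s pattern for row %d", label, k),
           call. = FALSE)
    X[k, idx] <- 1L
    keys <- c(keys, key)
  }
  X
}

#' Generate a reproducible balanced pattern dataset
#'
#' Draws \code{N} distinct key patterns (length \code{m}, \code{c} ones) and
#' \code{N} distinct value patterns (length \code{n}, \code{d} ones). The
#' default generator balances column usage greedily: each new pattern places
#' its ones on the currently least-used columns (random tie-break), so for
#' every prefix of the dataset the column sums are as uniform as a greedy
#' rule permits. Keys and values are drawn from independent RNG streams, so
#' the same seed yields the same keys regardless of \code{n} and \code{d}.
#'
#' @param params A [data_params()] object.
#' @param seed Integer RNG seed; identical \code{(params, seed)} give
#'   identical datasets.
#' @param balance If \code{FALSE}, draw patterns uniformly at random
#'   (still pairwise distinct) without usage balancing.
#' @return An object of class \code{"binam_dataset"} with binary matrices
#'   \code{X} (\code{N x m}) and \code{Y} (\code{N x n}).
#' @examples
#' ds <- generate_dataset(data_params(16, 16, 4, 4, N = 20), seed = 1)
#' rowSums(ds$X)   # all 4
#' @export
generate_dataset <- function(params, seed = 1L, balance = TRUE) {
  stopifnot(inherits(params, "binam_data_params"))
  gen <- if (balance) generate_matrix else generate_matrix_uniform
  X <- with_seed(seed, gen(params$N, params$m, params$c, "key"))
  Y <- with_seed(seed + 779L, gen(params$N, params$n, params$d, "value"))
  structure(list(params = params, X = X, Y = Y, seed = as.integer(seed),
                 balance = balance),
            class = "binam_dataset")
}

#' @export
print.binam_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf("BiNAM dataset: %d pairs, keys %d/%d ones, values %d/%d ones (seed %d)\n",
              p$N, p$c, p$m, p$d, p$n, x$seed))
  invisible(x)
}

#' Write or read a pattern dataset as plain text
#'
#' Patterns are stored one row per line as 0/1 characters (files
#' \code{<stem>_keys.txt} and \code{<stem>_values.txt}) with a JSON sidecar
#' \code{<stem>.json} holding the data parameters and seed.
#'
#' @param dataset A \code{"binam_dataset"}.
#' @param stem Path stem for the three files.
#' @return \code{write_dataset} returns \code{stem} invisibly;
#'   \code{read_dataset} returns the reconstructed \code{"binam_dataset"}.
#' @export
write_dataset <- function(dataset, stem) {
  stopifnot(inherits(dataset, "binam_dataset"))
  writeLines(apply(dataset$X, 1, paste, collapse = ""), paste0(stem, "_keys.txt"))
  writeLines(apply(dataset$Y, 1, paste, collapse = ""), paste0(stem, "_values.txt"))
  meta <- c(dataset$params[c("m", "n", "c", "d", "N")],
            list(seed = dataset$seed, balance = dataset$balance))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

read_binary_rows <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(strsplit(lines, ""), function(ch) as.integer(ch)))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  params <- data_params(meta$m, meta$n, meta$c, meta$d, meta$N)
  structure(list(params = params,
                 X = read_binary_rows(paste0(stem, "_keys.txt")),
                 Y = read_binary_rows(paste0(stem, "_values.txt")),
                 seed = as.integer(meta$seed),
                 balance = isTRUE(meta$balance)),
            class = "binam_dataset")
}
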