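#' Train a binary neural associative memory
#'
#' Stores key/value pairs in a clipped Hebbian (Willshaw/Palm) binary matrix:
#' \code{M[i, j] = 1} iff some stored pair has key bit \code{i} and value bit
#' \code{j} both set. Training is the element-wise OR of the outer products
#' of all pairs, hence idempotent and order-independent.
#'
#' @param x Either a \code{"binam_dataset"} (in which case \code{y} is
#'   ignored) or an \code{N x m} binary matrix of keys.
#' @param y \code{N x n} binary matrix of values when \code{x} is a matrix.
#' @return An object of class \code{"binam"} with elements \code{M} (the
#'   \code{m x n} binary storage matrix), \code{m}, \code{n} and, when
#'   trained from a dataset, the originating \code{dataset}.
#' @seealso [predict.binam()] for recall, [generate_dataset()].
#' @examples
#' ds <- generate_dataset(data_params(16, 16, 4, 4, N = 10), seed = 1)
#' fit <- binam(ds)
#' all(predict(fit, ds$X) >= ds$Y)  # no false negatives
#' @export
binam <- function(x, y = NULL) {
  dataset <- NULL
  if (inherits(x, "binam_dataset")) {
    dataset <- x
    y <- x$Y
    x <- x$X
  }
  x <- stopifnot_binary_matrix(x, "x")
  y <- stopifnot_binary_matrix(y, "y")
  if (nrow(x) != nrow(y))
    stop("`x` and `y` must have the same number of rows", call. = FALSE)
  if (nrow(x) == 0L) stop("cannot train on an empty dataset", call. = FALSE)
  M <- (crossprod(x, y) > 0) + 0L
  structure(list(M = M, m = nrow(M), n = ncol(M), dataset = dataset),
            class = "binam")
}

#' @export
print.binam <- function(x, ...) {
  cat(sprintf("BiNAM storage matrix: %d x %d, %d ones (density %.3f)\n",
              x$m, x$n, sum(x$M), mean(x$M)))
  invisible(x)
}

#' @export
summary.binam <- function(object, ...) {
  cat(sprintf("BiNAM: m = %d inputs, n = %d outputs, |M| = %d (density %.3f)\n",
              object$m, object$n, sum(object$M), mean(object$M)))
  if (!is.null(object$dataset)) {
    p <- object$dataset$params
    rec <- predict(object, object$dataset$X)
    fp <- rowSums(rec == 1L & object$dataset$Y == 0L)
    cat(sprintf("Trained from %d pairs (c = %d, d = %d); recall false positives per sample: mean %.3f (expected %.3f)\n",
                p$N, p$c, p$d, mean(fp), expected_false_positives(p)))
  }
  invisible(object)
}

#' Recall from a trained binary associative memory
#'
#' Threshold recall: output bit \code{j} is set iff the number of active key
#' bits connected to it, \code{sum_i x_i M[i, j]}, reaches \code{threshold}.
#' The default threshold is the key weight \code{||x||_1}, under which a
#' trained key always recalls a superset of its stored value (no false
#' negatives).
#'
#' @param object A \code{"binam"} fit.
#' @param x A binary key vector of length \code{m}, or a matrix with one key
#'   per row.
#' @param threshold Positive integer recall threshold; defaults to the
#'   per-row key weight. An all-zero key with the default threshold is
#'   rejected (a zero threshold would set every output bit).
#' @param ... Unused.
#' @return A binary vector of length \code{n} (or a matrix, one recall per
#'   row).
#' @export
predict.binam <- function(object, x, threshold = NULL, ...) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1L)
  x <- stopifnot_binary_matrix(x, "x")
  if (ncol(x) != object$m)
    stop(sprintf("key length %d does not match memory input dimension %d",
                 ncol(x), object$m), call. = FALSE)
  if (is.null(threshold)) {
    threshold <- rowSums(x)
    if (any(threshold == 0L))
      stop("all-zero key with default threshold: recall is undefined (would return all ones)",
           call. = FALSE)
  } else {
    threshold <- rep_len(stopifnot_scalar_int(threshold, "threshold"), nrow(x))
  }
  out <- (x %*% object$M >= threshold) + 0L
  if (single) out[1L, ] else out
}

#' Expected false positives per recalled sample
#'
#' Palm's approximation of the mean number of spurious ones in a recall from
#' a memory storing \code{N} random pairs:
#' \deqn{\tilde\alpha = (n - d) (1 - (1 - cd/(mn))^N)^c.}
#'
#' @param params A [data_params()] object.
#' @param N Optional sample-count override (vectorized); defaults to
#'   \code{params$N}.
#' @return Expected false-positive count(s), in \code{[0, n - d]}.
#' @export
expected_false_positives <- function(params, N = params$N) {
  stopifnot(inherits(params, "binam_data_params"))
  (params$n - params$d) *
    (1 - (1 - params$c * params$d / (params$m * params$n))^N)^params$c
}

#' Information recallable from a binary associative memory
#'
#' The recallable information in bits given per-sample false-positive counts
#' \code{alphas} and false-negative counts \code{betas}:
#' \deqn{I = \sum_k \log_2 C(n,d) - \log_2 C(\alpha_k + d - \beta_k, d - \beta_k)
#'       - \log_2 C(n - \alpha_k - d + \beta_k, \beta_k).}
#' Non-integer \code{alphas} are permitted for theoretical evaluation; the
#' binomial coefficients are then generalized through the gamma function.
#'
#' @param n Output vector length.
#' @param d Ones per stored value pattern.
#' @param alphas Per-sample false-positive counts, each in \code{[0, n - d]}.
#' @param betas Per-sample false-negative counts, each in \code{[0, d]};
#'   recycled against \code{alphas}.
#' @return Total information in bits.
#' @export
information_bits <- function(n, d, alphas, betas = 0) {
  k <- max(length(alphas), length(betas))
  alphas <- rep_len(alphas, k)
  betas <- rep_len(betas, k)
  if (any(alphas < 0 | alphas > n - d))
    stop("false-positive counts must lie in [0, n - d]", call. = FALSE)
  if (any(betas < 0 | betas > d))
    stop("false-negative counts must lie in [0, d]", call. = FALSE)
  sum(lchoose2(n, d) -
      lchoose2(alphas + d - betas, d - betas) -
      lchoose2(n - alphas - d + betas, betas))
}

#' Sample count maximizing the expected memory capacity
#'
#' Scans integer sample counts \code{N} and returns the argmax of the
#' expected recallable information \code{I(N) = N (log2 C(n,d) -
#' log2 C(alpha_tilde(N) + d, d))}, combining the information formula (with
#' all false-positive counts at their expectation and no false negatives)
#' with the expected-false-positive approximation. Binomial coefficients are
#' generalized via log-gamma so the objective is smooth in the non-integer
#' expectation; ties break toward the smaller \code{N}.
#'
#' @param m,n,c,d Data parameters (see [data_params()]).
#' @param profile If \code{TRUE}, also return the scanned objective.
#' @return The optimal integer sample count, or (with \code{profile}) a list
#'   with elements \code{N}, \code{objective} (vector over \code{1:N_hi}).
#' @examples
#' optimal_sample_count(16, 16, 4, 4)
#' @export
optimal_sample_count <- function(m, n, c, d, profile = FALSE) {
  params1 <- data_params(m, n, c, d, N = 0L)
  # scan up to the N at which the memory is essentially saturated
  p <- c * d / (m * n)
  n_hi <- ceiling(log(1 - 0.99^(1 / c)) / log(1 - p)) + 1
  repeat {
    N <- seq_len(n_hi)
    alpha <- expected_false_positives(params1, N)
    obj <- N * (lchoose2(n, d) - lchoose2(alpha + d, d))
    best <- which.max(obj)
    if (best < n_hi) break
    n_hi <- n_hi * 2  # saturation heuristic undershot; widen the scan
  }
  if (profile) list(N = best, objective = obj) else best
}

#' Random-matrix recall baseline
#'
#' Estimates what a recall from a saturated random storage matrix with
#' \code{P(M[i,j] = 1) = 1/2} would score: the probability that an output
#' bit is set is the binomial tail \code{p = P(Binom(m, c/(2m)) >= c_th)},
#' from which baseline per-sample false-positive/negative counts and the
#' apparent information \code{I_rand} follow. \code{I_rand} must be close to
#' zero for the normalized information of a benchmark run to be meaningful.
#'
#' Note the orientation: with \code{p} the probability of a one, a stored
#' one is missed with probability \code{1 - p} and a stored zero is set with
#' probability \code{p}, giving \code{alpha_rand = (n - d) p} and
#' \code{beta_rand = d (1 - p)}. Set \code{eq12_as_printed = TRUE} for the
#' transposed assignment.
#'
#' @param params A [data_params()] object.
#' @param c_th Recall threshold encoded in the network (default \code{c}).
#' @param eq12_as_printed Use the transposed error-count orientation.
#' @return A list with \code{p_one}, \code{alpha_rand}, \code{beta_rand} and
#'   \code{I_rand} (bits).
#' @export
random_baseline <- function(params, c_th = params$c, eq12_as_printed = FALSE) {
  stopifnot(inherits(params, "binam_data_params"))
  m <- params$m; n <- params$n; d <- params$d
  p_one <- if (c_th <= 0) 1 else pbinom(c_th - 1, m, params$c / (2 * m),
                                        lower.tail = FALSE)
  if (eq12_as_printed) {
    alpha_rand <- (n - d) * (1 - p_one); beta_rand <- d * p_one
  } else {
    alpha_rand <- (n - d) * p_one; beta_rand <- d * (1 - p_one)
  }
  I_rand <- information_bits(n, d, rep(alpha_rand, params$N),
                             rep(beta_rand, params$N))
  list(p_one = p_one, alpha_rand = alpha_rand, beta_rand = beta_rand,
       I_rand = max(I_rand, 0))
}
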