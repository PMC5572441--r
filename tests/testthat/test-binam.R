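test_that("training is the clipped outer-product superposition", {
  x <- matrix(c(1, 0, 0, 0), 1)
  y <- matrix(c(0, 1, 0, 0), 1)
  fit <- binam(x, y)
  expect_equal(sum(fit$M), 1)
  expect_equal(fit$M[1, 2], 1L)

  ds <- tiny_dataset(seed = 2)
  fit1 <- binam(ds)
  # idempotent: storing the same pairs twice changes nothing
  fit2 <- binam(rbind(ds$X, ds$X), rbind(ds$Y, ds$Y))
  expect_identical(fit1$M, fit2$M)
  # order-independent
  perm <- rev(seq_len(nrow(ds$X)))
  fit3 <- binam(ds$X[perm, ], ds$Y[perm, ])
  expect_identical(fit1$M, fit3$M)

  ones <- matrix(1L, 3, 5)
  expect_true(all(binam(ones, matrix(1L, 3, 4))$M == 1L))
  expect_error(binam(matrix(1L, 2, 3), matrix(1L, 3, 3)), "rows")
})

test_that("recall of a stored key has no false negatives and no spurious memory", {
  x <- matrix(c(1, 1, 0, 0), 1)
  y <- matrix(c(0, 1, 1, 0), 1)
  fit <- binam(x, y)
  expect_equal(predict(fit, x[1, ]), y[1, ])

  # property over random instances: recalled bits are a superset of stored
  for (seed in 1:10) {
    ds <- tiny_dataset(seed = seed, N = 12)
    fit <- binam(ds)
    rec <- predict(fit, ds$X)
    expect_true(all(rec >= ds$Y))
  }

  zero_fit <- structure(list(M = matrix(0L, 4, 4), m = 4L, n = 4L,
                             dataset = NULL), class = "binam")
  expect_equal(predict(zero_fit, c(1, 1, 0, 0)), rep(0L, 4))
  expect_error(predict(zero_fit, rep(0, 4)), "all-zero")
})

test_that("expected false positives follow the capacity approximation", {
  p <- data_params(112, 128, 4, 4, N = 735)
  expect_equal(expected_false_positives(p, N = 0), 0)
  expect_equal(expected_false_positives(p, N = 1e7), p$n - p$d, tolerance = 1e-9)
  expect_equal(expected_false_positives(p), 12.187, tolerance = 1e-3)
  # strictly increasing in N
  a <- expected_false_positives(p, N = 1:2000)
  expect_true(all(diff(a) > 0))
})

test_that("information formula matches a direct log-factorial oracle", {
  n <- 16; d <- 4
  expect_equal(information_bits(n, d, rep(0, 7), 0), 7 * log2(choose(n, d)))
  expect_equal(information_bits(n, d, 0, d), 0)
  expect_equal(information_bits(128, 4, 0, 0), log2(10668000), tolerance = 1e-12)

  lfact <- function(k) sum(log2(seq_len(k)))
  oracle <- function(n, d, a, b)
    (lfact(n) - lfact(d) - lfact(n - d)) -
    (lfact(a + d - b) - lfact(d - b) - lfact(a)) -
    (lfact(n - a - d + b) - lfact(b) - lfact(n - a - d))
  for (case in list(c(2, 1), c(5, 0), c(0, 3), c(7, 2))) {
    expect_equal(information_bits(n, d, case[1], case[2]),
                 oracle(n, d, case[1], case[2]), tolerance = 1e-10)
  }
  expect_error(information_bits(n, d, n, 0), "0, n - d")
  expect_error(information_bits(n, d, 0, d + 1), "0, d")
})

test_that("optimal sample count maximizes a locally unimodal objective", {
  res <- optimal_sample_count(64, 96, 4, 4, profile = TRUE)
  obj <- res$objective
  k <- res$N
  expect_true(all(diff(obj[max(1, k - 20):k]) > 0))       # rising into the optimum
  expect_true(all(diff(obj[k:(k + 20)]) < 0))             # falling beyond it
  # independent exhaustive oracle on a small memory
  scan <- sapply(1:300, function(N) {
    a <- (16 - 3) * (1 - (1 - 3 * 3 / 256)^N)^3
    lb <- function(x, y) (lgamma(x + 1) - lgamma(y + 1) - lgamma(x - y + 1)) / log(2)
    N * (lb(16, 3) - lb(a + 3, 3))
  })
  expect_equal(optimal_sample_count(16, 16, 3, 3), which.max(scan))
})

test_that("random-matrix baseline follows the binomial tail", {
  p <- data_params(112, 128, 4, 4, N = 100)
  rb <- random_baseline(p, c_th = 4)
  # brute-force pmf summation oracle
  expect_equal(rb$p_one, sum(dbinom(4:112, 112, 4 / 224)), tolerance = 1e-12)
  expect_equal(rb$p_one, 0.1412, tolerance = 1e-3)
  expect_equal(random_baseline(p, c_th = 0)$p_one, 1)
  far <- random_baseline(p, c_th = 200)
  expect_equal(far$p_one, 0)
  expect_equal(far$I_rand, 0)
  # the printed-orientation flag transposes the error counts
  alt <- random_baseline(p, c_th = 4, eq12_as_printed = TRUE)
  expect_equal(alt$alpha_rand, (p$n - p$d) * (1 - rb$p_one))
  expect_equal(alt$beta_rand, p$d * rb$p_one)
})
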