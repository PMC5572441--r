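test_that("metrics score perfect reproduction of the binary memory as 1/0/0", {
  ds <- tiny_dataset(seed = 3, N = 12)
  fit <- binam(ds)
  rec <- predict(fit, ds$X)     # binary recall including its false positives
  res <- evaluate_metrics(rec, ds)
  expect_equal(res$I_n, 1)
  expect_equal(res$alpha_n, 0)
  expect_equal(res$beta_n, 0)
  expect_gt(res$alpha_bar, 0)   # the baseline carries genuine false positives
})

test_that("the normalized false-positive scale spans [-1, 1]", {
  ds <- tiny_dataset(seed = 3, N = 12)
  p <- ds$params
  # every zero bit turned on: alpha = n - d per sample
  all_on <- matrix(1L, p$N, p$n)
  expect_equal(evaluate_metrics(all_on, ds)$alpha_n, 1)
  # exact values only (no false positives) with a positive baseline: -1
  expect_equal(evaluate_metrics(ds$Y, ds)$alpha_n, -1)
  expect_equal(evaluate_metrics(ds$Y, ds)$beta_n, 0)
  # all-zero recall loses everything
  silent <- evaluate_metrics(matrix(0L, p$N, p$n), ds)
  expect_equal(silent$beta_n, 1)
  expect_equal(silent$I, 0)
  expect_error(evaluate_metrics(matrix(0L, 2, 2), ds), "dimensions")
})

test_that("benchmark runs are reproducible and reject empty workloads", {
  cfg <- benchmark_setup("b", m = 16, n = 16, N = 12, data_seed = 4,
                         jitter_seed = 400)
  a <- suppressWarnings(run_benchmark(cfg))
  b <- suppressWarnings(run_benchmark(cfg))
  expect_equal(a$I_n, b$I_n)
  expect_identical(a$per_sample, b$per_sample)
  expect_error(run_benchmark(benchmark_setup("a", m = 16, n = 16, N = 0)),
               "N = 0")
})

test_that("the information peak follows the tuned input weight in a c sweep", {
  base <- benchmark_setup("b", m = 20, n = 16, N = 12, data_seed = 2,
                          jitter_seed = 7)
  tab <- sweep_1d(base, "c", values = c(3, 4, 5), repetitions = 2)
  expect_equal(nrow(tab), 3)
  expect_false(any(tab$failed))
  expect_equal(tab$c[which.max(tab$I_n)], 4)
  # empty sweep yields an empty table
  expect_equal(nrow(sweep_1d(base, "c", values = numeric(0))), 0)
  # infeasible values are marked failed without aborting the sweep
  bad <- sweep_1d(base, "N", values = c(6, 1e9), repetitions = 1)
  expect_false(bad$failed[1])
  expect_true(bad$failed[2])
})

test_that("the 2-D neuron sweep flags dead and invalid corners", {
  base <- benchmark_setup("b", m = 12, n = 12, N = 8, data_seed = 5,
                          jitter_seed = 55)
  grid <- sweep_2d(base, v_th_values = c(-85, -73.8), w_values = c(0, 1))
  expect_true(is.na(grid$I_n[1, 2]))          # threshold below rest is invalid
  expect_equal(grid$beta_n["-73.8", "0"], 1)  # zero weight: no spikes at all
  expect_equal(grid$I_n["-73.8", "0"], 0)
  expect_gt(grid$I_n["-73.8", "1"], 0.9)      # tuned corner works
})

test_that("energy efficiency is samples per joule weighted by information", {
  # printed benchmark operating point: I_n = 0.917 at 112.9 mJ per sample
  N <- 113648
  eff <- energy_efficiency(I_n = 0.917, N = N, power_w = 1.12,
                           t_s = N * 0.1129 / 1.12)
  expect_equal(eff$E_eff, 8.1, tolerance = 0.4 / 8.1)
  expect_equal(energy_efficiency(0, 10, 1, 1)$E_eff, 0)
  half <- energy_efficiency(0.917, N, 2 * 1.12, N * 0.1129 / 1.12)
  expect_equal(half$E_eff, eff$E_eff / 2)
  expect_error(energy_efficiency(1, 10, 0, 1), "positive")
})

test_that("externally recorded spike trains score through the CSV path", {
  p <- data_params(12, 12, 4, 3, N = 6)
  ds <- generate_dataset(p, seed = 12)
  fit <- binam(ds)
  enc <- encoding_spec(s = 1, sigma_t = 0, omega = 1)
  net <- build_network(fit, omega = 1, params = parameter_set("I"))
  out <- run_backend(net, encode_patterns(ds$X, enc, seed = 1))
  path <- file.path(tempdir(), "recorded.csv")
  write_spike_csv(out$spikes, path)
  rec <- read_spike_csv(path, channels = net$neurons, duration = p$N * enc$T)
  direct <- score_output(out$spikes, ds, enc)
  via_csv <- score_output(rec, ds, enc)
  expect_equal(via_csv$I_n, direct$I_n)
  expect_equal(via_csv$alpha_bar, direct$alpha_bar)
})

test_that("a saturated memory triggers the random-baseline guard", {
  cfg <- benchmark_setup("b", m = 16, n = 16, N = 12, data_seed = 4,
                         jitter_seed = 400)
  expect_warning(run_benchmark(cfg), "random information baseline")
})
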