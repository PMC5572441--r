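test_that("the resting state is a fixed point of the dynamics", {
  for (method in c("euler", "rkf45")) {
    r <- simulate_single_neuron(parameter_set("I"), t_end = 50,
                                integ = integrator_config(method))
    expect_equal(length(r$spike_times), 0)
    expect_true(all(r$trace == -80))
  }
})

test_that("single weak inputs stay sub-threshold, coincident volleys cross", {
  # one 1 nS spike against set II: peak EPSP far below threshold
  r1 <- simulate_single_neuron(parameter_set("II"), times = 0, weights = 1)
  expect_equal(length(r1$spike_times), 0)
  expect_lt(r1$vmax, parameter_set("II")$v_th)

  # set I implements the threshold function at c = 4 coincident spikes
  r4 <- simulate_single_neuron(parameter_set("I"), times = rep(0, 4), weights = 10)
  r3 <- simulate_single_neuron(parameter_set("I"), times = rep(0, 3), weights = 10)
  r5 <- simulate_single_neuron(parameter_set("I"), times = rep(0, 5), weights = 10)
  expect_equal(length(r4$spike_times), 1)
  expect_equal(length(r3$spike_times), 0)
  expect_equal(length(r5$spike_times), 1)
})

test_that("zero-weight inputs are equivalent to no input", {
  a <- simulate_single_neuron(parameter_set("I"), times = c(5, 10), weights = 0,
                              t_end = 40)
  b <- simulate_single_neuron(parameter_set("I"), t_end = 40)
  expect_equal(a$trace, b$trace)
})

test_that("a dominant inhibitory offset current keeps the membrane below rest", {
  # the 30 nS volley injects at most 2.4 nA; -3 nA outweighs it throughout
  r <- simulate_single_neuron(parameter_set("I"), times = rep(0, 3), weights = 10,
                              t_end = 60, i_offset = -3)
  expect_lte(r$vmax, -80)
})

test_that("same-time spikes superpose linearly in conductance", {
  p <- parameter_set("II")
  ab <- simulate_single_neuron(p, times = c(3, 3), weights = c(2, 5), t_end = 40)
  s <- simulate_single_neuron(p, times = 3, weights = 7, t_end = 40)
  expect_equal(ab$trace, s$trace, tolerance = 1e-12)
})

test_that("the refractory period separates consecutive spikes", {
  p <- parameter_set("I")
  r <- simulate_single_neuron(p, times = rep(seq(0, 90, 2), each = 4),
                              weights = 10, t_end = 100, i_offset = 0.5)
  expect_gt(length(r$spike_times), 3)
  expect_true(all(diff(r$spike_times) >= p$tau_ref))
})

test_that("Euler converges to the adaptive reference as the step shrinks", {
  p <- parameter_set("I")
  stim <- rep(0, 4)
  ref <- simulate_single_neuron(p, stim, 10, t_end = 60,
                                integ = integrator_config("rkf45", dt = 0.1))
  counts <- sapply(c(0.5, 0.1, 0.02), function(dt)
    length(simulate_single_neuron(p, stim, 10, t_end = 60,
                                  integ = integrator_config("euler", dt = dt))$spike_times))
  expect_equal(counts[2], length(ref$spike_times))
  expect_equal(counts[3], length(ref$spike_times))
  # spike-time error decreases with the step
  t_ref <- ref$spike_times[1]
  errs <- sapply(c(0.5, 0.1, 0.02), function(dt) {
    st <- simulate_single_neuron(p, stim, 10, t_end = 60,
                                 integ = integrator_config("euler", dt = dt))$spike_times
    abs(st[1] - t_ref)
  })
  expect_true(all(diff(errs) <= 0))
  expect_lt(errs[3], 0.1)
})

test_that("the coarse Euler step remains finite under heavy drive", {
  # threshold reset and the conductance floor bound the naive Euler state
  p <- parameter_set("II")
  r <- simulate_single_neuron(p, times = rep(seq(0, 18, 2), each = 16),
                              weights = 1, t_end = 100,
                              integ = integrator_config("euler", dt = 1))
  expect_true(all(is.finite(r$trace)))
})

test_that("noiseless spiking recall equals binary recall sample by sample", {
  for (seed in 1:3) {
    p <- data_params(16, 16, 4, 4, N = 10)
    ds <- generate_dataset(p, seed = seed)
    fit <- binam(ds)
    enc <- encoding_spec(s = 1, sigma_t = 0, omega = 4)
    net <- build_network(fit, omega = 4, params = parameter_set("II"))
    inputs <- encode_patterns(ds$X, enc, seed = seed)
    out <- run_backend(net, inputs, backend = "builtin")
    dec <- decode_spikes(out$spikes, p$n, 4, enc$T, p$N)
    expect_identical(dec, predict(fit, ds$X))
  }
})
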