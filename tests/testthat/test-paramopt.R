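test_that("stimulus construction counts spikes as s * omega * active inputs", {
  st <- stimulus_spec(3, s = 4, omega = 2, w = 1)
  expect_equal(st$k_spikes, 24)
  expect_equal(length(st$times), 24)
  expect_equal(sort(unique(st$times)), c(0, 2, 4, 6))
  expect_equal(threshold_spike_count(4, 4, 4), 49)
  expect_equal(threshold_spike_count(1, 1, 4), 4)
})

test_that("perturbation currents satisfy their defining inequalities", {
  p <- parameter_set("I")
  stim <- det_stimulus(4, w = 10)           # fires exactly once unperturbed
  n0 <- length(simulate_single_neuron(p, stim$times, 10)$spike_times)
  jp <- perturb_plus(p, stim)
  expect_gt(jp, 0)
  expect_gt(length(simulate_single_neuron(p, stim$times, 10,
                                          i_offset = jp)$spike_times), n0)
  expect_equal(length(simulate_single_neuron(p, stim$times, 10,
                                             i_offset = jp * 0.99)$spike_times), n0)
  jm <- perturb_minus(p, stim)
  expect_gt(jm, 0)
  expect_lt(length(simulate_single_neuron(p, stim$times, 10,
                                          i_offset = -jm)$spike_times), n0)

  # sub-threshold stimulus: j- suppresses the EPSP below rest
  sub <- det_stimulus(3, w = 10)
  jm0 <- perturb_minus(p, sub)
  expect_gt(jm0, 0)
  expect_lte(simulate_single_neuron(p, sub$times, 10, i_offset = -jm0)$vmax,
             -80 + 1e-6)

  # no input: the membrane already sits at rest, j- = 0
  expect_equal(perturb_minus(p, det_stimulus(0, w = 10)), 0)
})

test_that("excitatory perturbation weakens as the synapses strengthen", {
  p <- parameter_set("II")
  js <- sapply(c(0.4, 0.55, 0.7), function(w)
    perturb_plus(neuron_params(v_th = -73.8, g_leak = 20, w = w),
                 det_stimulus(4, omega = 4, w = w)))
  expect_true(all(diff(js) < 0))
})

test_that("the fractional spike count is zero at rest and bounded in [n, n+1]", {
  p <- parameter_set("I")
  q0 <- fractional_spike_count(p, det_stimulus(0, w = 10))
  expect_equal(q0$q, 0)
  expect_equal(q0$n, 0)
  q4 <- fractional_spike_count(p, det_stimulus(4, w = 10))
  expect_equal(q4$n, 1)
  expect_gte(q4$p, 0); expect_lte(q4$p, 1)
})

test_that("the fractional count varies smoothly across the weight axis", {
  # sweep w through the firing boundary of a 4-input volley
  ws <- seq(6, 14, length.out = 17)
  qs <- sapply(ws, function(w)
    fractional_spike_count(parameter_set("I"), det_stimulus(4, w = w),
                           T = 50)$q)
  expect_true(all(qs >= 0))
  expect_lt(max(abs(diff(qs))), 0.5)
  expect_true(any(floor(qs) == 0) && any(floor(qs) >= 1))  # crosses a count boundary
})

test_that("the heavy-tailed surrogate is finite and peaks at matched counts", {
  obj <- objective_set(c = 4, s = 1, omega = 1, w = 10)
  good <- surrogate_objective(parameter_set("I"), obj)
  # detuned thresholds miss at least one target and must score worse
  off1 <- surrogate_objective(neuron_params(v_th = -75, g_leak = 20, w = 10), obj)
  off2 <- surrogate_objective(neuron_params(v_th = -58, g_leak = 20, w = 10), obj)
  expect_true(is.finite(good) && is.finite(off1) && is.finite(off2))
  expect_gt(good, off1)
  expect_gt(good, off2)
})

test_that("empirical probabilities are exact indicators without jitter", {
  obj <- objective_set(c = 4, s = 1, omega = 1, w = 10)
  pr <- empirical_probability(parameter_set("I"), obj, trials = 1, sigma_t = 0)
  expect_equal(pr, rep(1, 4))
  bad <- empirical_probability(neuron_params(v_th = -58, g_leak = 20, w = 10),
                               obj, trials = 1, sigma_t = 0)
  expect_true(all(bad %in% c(0, 1)))
  expect_lt(sum(bad), 4)
  # jittered probabilities are frequencies in [0, 1]
  pj <- empirical_probability(parameter_set("I"), obj, trials = 20, sigma_t = 2,
                              seed = 3)
  expect_true(all(pj >= 0 & pj <= 1))
  expect_lte(prod(pj), min(pj))
  expect_error(empirical_probability(parameter_set("I"), obj, trials = 0), "trials")
})

test_that("the optimizer never returns worse than a feasible incumbent", {
  obj <- objective_set(c = 4, s = 1, omega = 1, w = 10)
  init <- parameter_set("I")
  init_val <- surrogate_objective(init, obj)
  fit <- optimize_neuron(obj, initial = init, free = c("v_th", "g_leak"),
                         restarts = 1, seed = 2, maxit = 40)
  expect_gte(fit$value, init_val - 1e-9)
  expect_true(fit$feasible)
  expect_equal(fit$empirical, rep(1, 4))
})
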