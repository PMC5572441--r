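# small reusable fixtures, all generated in code

tiny_dataset <- function(seed = 1L, m = 16, n = 16, c = 4, d = 4, N = 10) {
  generate_dataset(data_params(m, n, c, d, N = N), seed = seed)
}

# deterministic stimulus of `h` active logical inputs under (s, omega) coding
det_stimulus <- function(h, s = 1L, omega = 1L, w = 10) {
  stimulus_spec(h, s = s, delta_t = 2, omega = omega, w = w)
}

quick_integ <- integrator_config("rkf45", dt = 0.1, abs_tol = 1e-3)
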