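#' Benchmark experiment configuration
#'
#' Bundles everything a benchmark run needs: data parameters, spike
#' encoding, neuron parameters, integrator, back-end and seeds.
#'
#' @param data A [data_params()] object (\code{N} may come from
#'   [optimal_sample_count()]).
#' @param encoding An [encoding_spec()].
#' @param neuron A [neuron_params()] object.
#' @param integrator An [integrator_config()].
#' @param backend Back-end identifier (see [register_backend()]).
#' @param c_th Recall threshold encoded in the data baseline (default
#'   \code{c}).
#' @param repetitions Number of averaged runs.
#' @param repeat_mode \code{"input"} re-runs the identical input (averaging
#'   substrate stochasticity), \code{"seed"} redraws data and jitter.
#' @param data_seed,jitter_seed RNG seeds.
#' @return An object of class \code{"experiment_config"}.
#' @export
experiment_config <- function(data, encoding = encoding_spec(),
                              neuron = parameter_set("I"),
                              integrator = integrator_config(),
                              backend = "builtin", c_th = data$c,
                              repetitions = 1L,
                              repeat_mode = c("input", "seed"),
                              data_seed = 1L, jitter_seed = 1000L) {
  stopifnot(inherits(data, "binam_data_params"),
            inherits(encoding, "encoding_spec"),
            inherits(neuron, "neuron_params"),
            inherits(integrator, "integrator_config"))
  structure(list(data = data, encoding = encoding, neuron = neuron,
                 integrator = integrator, backend = backend,
                 c_th = stopifnot_scalar_int(c_th, "c_th"),
                 repetitions = stopifnot_scalar_int(repetitions, "repetitions"),
                 repeat_mode = match.arg(repeat_mode),
                 data_seed = as.integer(data_seed),
                 jitter_seed = as.integer(jitter_seed)),
            class = "experiment_config")
}

#' Normalized benchmark metrics from a decoded recall
#'
#' Scores a decoded binary recall matrix against the stored values. The
#' theoretical baseline is the exact non-spiking recall of each trained key
#' (per-sample false-positive counts \code{alpha_th}, no false negatives):
#' a substrate that reproduces the McCulloch-Pitts memory perfectly scores
#' \code{I_n = 1, alpha_n = 0, beta_n = 0}. \code{alpha_n} is scaled to
#' \code{[-1, 1]}: negative for a shortage of false positives relative to
#' the baseline, positive for a surplus.
#'
#' @param Y_recalled \code{N x n} binary matrix decoded from the substrate.
#' @param dataset The originating [generate_dataset()] dataset.
#' @param alpha_th Baseline per-sample false-positive counts (vector or
#'   scalar); defaults to exact binary recall at threshold \code{c_th}.
#' @param c_th Recall threshold for the default baseline.
#' @param wall_time Execution time in seconds to attach (optional).
#' @return An object of class \code{"benchmark_result"} with \code{I},
#'   \code{I_th}, \code{I_n}, \code{alpha_bar}, \code{beta_bar},
#'   \code{alpha_n}, \code{beta_n}, per-sample counts and timing.
#' @export
evaluate_metrics <- function(Y_recalled, dataset, alpha_th = NULL,
                             c_th = dataset$params$c, wall_time = NA_real_) {
  stopifnot(inherits(dataset, "binam_dataset"))
  Y_recalled <- stopifnot_binary_matrix(Y_recalled, "Y_recalled")
  p <- dataset$params
  if (!all(dim(Y_recalled) == c(p$N, p$n)))
    stop("recalled matrix dimensions do not match the dataset", call. = FALSE)
  if (is.null(alpha_th)) {
    fit <- binam(dataset)
    Y_ref <- predict(fit, dataset$X, threshold = c_th)
    alpha_th <- rowSums(Y_ref == 1L & dataset$Y == 0L)
  }
  alpha_th <- rep_len(alpha_th, p$N)
  alpha_k <- rowSums(Y_recalled == 1L & dataset$Y == 0L)
  beta_k <- rowSums(Y_recalled == 0L & dataset$Y == 1L)
  I <- information_bits(p$n, p$d, alpha_k, beta_k)
  I_th <- information_bits(p$n, p$d, alpha_th, 0)
  ab <- mean(alpha_k); bb <- mean(beta_k); at <- mean(alpha_th)
  alpha_n <- if (ab <= at) {
    if (at > 0) ab / at - 1 else 0
  } else (ab - at) / (p$n - p$d - at)
  structure(list(I = I, I_th = I_th, I_n = I / I_th,
                 alpha_bar = ab, beta_bar = bb, alpha_th = at,
                 alpha_n = alpha_n, beta_n = bb / p$d,
                 wall_time = wall_time,
                 per_sample = list(alpha = alpha_k, beta = beta_k)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("BiNAM benchmark: I = %.1f / I_th = %.1f bits, I_n = %.3f, alpha_n = %+.3f, beta_n = %.3f",
              x$I, x$I_th, x$I_n, x$alpha_n, x$beta_n))
  if (is.finite(x$wall_time)) cat(sprintf(", t = %.2f s", x$wall_time))
  cat("\n")
  invisible(x)
}

# one full pipeline pass: generate -> train -> build -> encode -> execute ->
# decode -> score
run_benchmark_once <- function(config, data_seed, jitter_seed) {
  p <- config$data
  if (p$N == 0L) stop("N = 0: nothing to benchmark", call. = FALSE)
  dataset <- generate_dataset(p, seed = data_seed)
  fit <- binam(dataset)
  net <- build_network(fit, omega = config$encoding$omega,
                       params = config$neuron)
  inputs <- encode_patterns(dataset$X, config$encoding, seed = jitter_seed)
  out <- run_backend(net, inputs, backend = config$backend,
                     integ = config$integrator)
  Y_rec <- decode_spikes(out$spikes, p$n, config$encoding$omega,
                         config$encoding$T, p$N)
  Y_ref <- predict(fit, dataset$X, threshold = config$c_th)
  alpha_th <- rowSums(Y_ref == 1L & dataset$Y == 0L)
  evaluate_metrics(Y_rec, dataset, alpha_th = alpha_th,
                   wall_time = out$wall_time)
}

#' Run a full benchmark experiment
#'
#' Executes the pipeline generate data, train the memory, build the spiking
#' network, encode the keys as spike trains, run the back-end, decode the
#' output and compute normalized metrics, averaging over
#' \code{config$repetitions} runs. Emits a warning when the random-matrix
#' information baseline is not negligible (\code{I_rand / I_th > 0.05}),
#' in which case the normalized information is not a meaningful benchmark
#' indicator.
#'
#' @param config An [experiment_config()].
#' @return A \code{"benchmark_result"} (metrics averaged over repetitions;
#'   \code{runs} holds the individual results when \code{repetitions > 1}).
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  runs <- vector("list", config$repetitions)
  for (r in seq_len(config$repetitions)) {
    if (config$repeat_mode == "seed") {
      ds <- config$data_seed + (r - 1L)
      js <- config$jitter_seed + (r - 1L)
    } else {
      ds <- config$data_seed; js <- config$jitter_seed
    }
    runs[[r]] <- run_benchmark_once(config, ds, js)
  }
  rb <- random_baseline(config$data, c_th = config$c_th)
  avg <- runs[[1L]]
  if (config$repetitions > 1L) {
    for (nm in c("I", "I_th", "I_n", "alpha_bar", "beta_bar", "alpha_th",
                 "alpha_n", "beta_n", "wall_time"))
      avg[[nm]] <- mean(vapply(runs, `[[`, numeric(1), nm))
    avg$per_sample <- NULL
    avg$runs <- runs
  }
  avg$I_rand <- rb$I_rand
  if (rb$I_rand / avg$I_th > 0.05)
    warning(sprintf("random information baseline is not negligible (I_rand/I_th = %.3f); I_n is not meaningful",
                    rb$I_rand / avg$I_th))
  avg
}

#' One-dimensional data-parameter sweep
#'
#' Re-runs a benchmark while varying one data parameter (\code{m}, \code{n},
#' \code{c}, \code{d} or \code{N}), averaging each point over
#' \code{repetitions} runs with different data/jitter seeds. Infeasible
#' values are marked failed and the sweep continues.
#'
#' @param base An [experiment_config()].
#' @param parameter One of \code{"m", "n", "c", "d", "N"}.
#' @param values Values to sweep.
#' @param repetitions Seed-averaged runs per value.
#' @return A data frame with one row per value: the normalized metrics, the
#'   random baseline \code{I_rand}, and \code{failed}.
#' @export
sweep_1d <- function(base, parameter = c("m", "n", "c", "d", "N"), values,
                     repetitions = base$repetitions) {
  stopifnot(inherits(base, "experiment_config"))
  parameter <- match.arg(parameter)
  rows <- lapply(values, function(v) {
    cfg <- base
    d <- unclass(cfg$data)
    d[[parameter]] <- v
    # a default recall threshold (c_th = c) tracks the swept input weight
    if (parameter == "c" && base$c_th == base$data$c) cfg$c_th <- as.integer(v)
    out <- tryCatch({
      cfg$data <- do.call(data_params, d)
      cfg$repetitions <- repetitions
      cfg$repeat_mode <- "seed"
      res <- suppressWarnings(run_benchmark(cfg))
      rb <- random_baseline(cfg$data, c_th = min(cfg$c_th, cfg$data$m))
      data.frame(value = v, I_n = res$I_n, alpha_n = res$alpha_n,
                 beta_n = res$beta_n, I = res$I, I_th = res$I_th,
                 I_rand = rb$I_rand, failed = FALSE)
    }, error = function(e)
      data.frame(value = v, I_n = NA_real_, alpha_n = NA_real_,
                 beta_n = NA_real_, I = NA_real_, I_th = NA_real_,
                 I_rand = NA_real_, failed = TRUE))
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(value = numeric(0), I_n = numeric(0),
                                      alpha_n = numeric(0), beta_n = numeric(0),
                                      I = numeric(0), I_th = numeric(0),
                                      I_rand = numeric(0), failed = logical(0))
  names(out)[1] <- parameter
  out
}

#' Two-dimensional neuron-parameter sweep
#'
#' Sweeps the threshold potential and synaptic weight on a fixed dataset and
#' returns the grid of normalized information values (plus the error-count
#' grids). All grid cells share the same data and jitter seeds so the grid
#' isolates the neuron-parameter dependence.
#'
#' @param base An [experiment_config()].
#' @param v_th_values,w_values Grid axes (mV, nS).
#' @return A list with matrices \code{I_n}, \code{alpha_n}, \code{beta_n}
#'   (rows = \code{v_th_values}, columns = \code{w_values}) and the axes.
#' @export
sweep_2d <- function(base, v_th_values, w_values) {
  stopifnot(inherits(base, "experiment_config"),
            length(v_th_values) > 0, length(w_values) > 0)
  I_n <- a_n <- b_n <- matrix(NA_real_, length(v_th_values), length(w_values),
                              dimnames = list(v_th_values, w_values))
  for (i in seq_along(v_th_values)) for (j in seq_along(w_values)) {
    cfg <- base
    np <- unclass(cfg$neuron)
    np$v_th <- v_th_values[i]; np$w <- w_values[j]
    res <- tryCatch({
      cfg$neuron <- do.call(neuron_params, np)
      suppressWarnings(run_benchmark(cfg))
    }, error = function(e) NULL)
    if (!is.null(res)) {
      I_n[i, j] <- res$I_n; a_n[i, j] <- res$alpha_n; b_n[i, j] <- res$beta_n
    }
  }
  list(I_n = I_n, alpha_n = a_n, beta_n = b_n,
       v_th = v_th_values, w = w_values)
}

#' Standard benchmark setup fixtures
#'
#' The four canonical operating modes of the spiking associative-memory
#' benchmark: (a) single spike, single neuron (s = 1, omega = 1, parameter
#' set I); (b) single spike, population (s = 1, omega = 4, set II);
#' (c) burst, single neuron (s = 4, omega = 1, set II); (d) burst,
#' population (s = 4, omega = 4, set III). Data dimensions are free so the
#' same mode can be scaled to any platform size; \code{N} defaults to the
#' capacity-optimal sample count.
#'
#' @param setup One of \code{"a"}, \code{"b"}, \code{"c"}, \code{"d"}.
#' @param m,n Input/output dimensions.
#' @param N Sample count (\code{NULL} = [optimal_sample_count()]).
#' @param c,d Pattern weights (default 4, the tuned value).
#' @param sigma_t Jitter SD in ms.
#' @param ... Passed on to [experiment_config()].
#' @return An [experiment_config()].
#' @examples
#' cfg <- benchmark_setup("b", m = 28, n = 32, N = 54)
#' @export
benchmark_setup <- function(setup = c("a", "b", "c", "d"), m, n, N = NULL,
                            c = 4L, d = 4L, sigma_t = 2, ...) {
  setup <- match.arg(setup)
  enc <- switch(setup,
    a = encoding_spec(s = 1L, sigma_t = sigma_t, omega = 1L),
    b = encoding_spec(s = 1L, sigma_t = sigma_t, omega = 4L),
    c = encoding_spec(s = 4L, sigma_t = sigma_t, omega = 1L),
    d = encoding_spec(s = 4L, sigma_t = sigma_t, omega = 4L))
  np <- switch(setup, a = parameter_set("I"), b = parameter_set("II"),
               c = parameter_set("II"), d = parameter_set("III"))
  experiment_config(data = data_params(m, n, c, d, N), encoding = enc,
                    neuron = np, ...)
}

#' Energy efficiency of a benchmark run
#'
#' The number of samples recallable per joule, weighted by the normalized
#' information: \code{E_eff = I_n * N / E} with \code{E = P * t}.
#'
#' @param I_n Normalized information of the run.
#' @param N Sample count.
#' @param power_w Measured power draw in watts (> 0).
#' @param t_s Execution time in seconds (> 0).
#' @return A list of class \code{"efficiency_result"} with \code{E_eff}
#'   (1/J), \code{E} (J), \code{E_per_sample} (J) and the inputs.
#' @export
energy_efficiency <- function(I_n, N, power_w, t_s) {
  if (!is.numeric(power_w) || power_w <= 0 || !is.numeric(t_s) || t_s <= 0)
    stop("power and execution time must be positive", call. = FALSE)
  E <- power_w * t_s
  structure(list(E_eff = I_n * N / E, E = E, E_per_sample = E / N,
                 P = power_w, t = t_s, I_n = I_n, N = N),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("Energy efficiency: E_eff = %.2f 1/J (E = %.3f J, %.1f mJ/sample, I_n = %.3f)\n",
              x$E_eff, x$E, 1000 * x$E_per_sample, x$I_n))
  invisible(x)
}

#' Score externally produced output spike trains
#'
#' The black-box hardware scoring path: decode a recorded spike-train set
#' (e.g. read with [read_spike_csv()]) against the dataset it was produced
#' from and compute the normalized metrics.
#'
#' @param output Output [spike_train_set()] with \code{n * omega} channels.
#' @param dataset The [generate_dataset()] dataset presented to the
#'   substrate.
#' @param encoding The [encoding_spec()] used for the input.
#' @param c_th Recall threshold of the baseline.
#' @return A \code{"benchmark_result"}.
#' @export
score_output <- function(output, dataset, encoding, c_th = dataset$params$c) {
  stopifnot(inherits(dataset, "binam_dataset"))
  p <- dataset$params
  Y_rec <- decode_spikes(output, p$n, encoding$omega, encoding$T, p$N)
  evaluate_metrics(Y_rec, dataset, c_th = c_th)
}

#' Flatten benchmark results to a data frame row
#'
#' @param x A \code{"benchmark_result"}.
#' @param config Optional [experiment_config()] whose settings are prepended.
#' @param ... Unused.
#' @return A one-row data frame suitable for CSV result logs.
#' @export
as.data.frame.benchmark_result <- function(x, config = NULL, ...) {
  row <- data.frame(I_bits = x$I, I_th_bits = x$I_th, I_n = x$I_n,
                    alpha_bar = x$alpha_bar, beta_bar = x$beta_bar,
                    alpha_n = x$alpha_n, beta_n = x$beta_n,
                    t_s = x$wall_time)
  if (!is.null(config)) {
    p <- config$data; e <- config$encoding
    row <- cbind(data.frame(m = p$m, n = p$n, c = p$c, d = p$d, N = p$N,
                            s = e$s, omega = e$omega,
                            backend = config$backend,
                            integrator = config$integrator$method,
                            dt = config$integrator$dt,
                            data_seed = config$data_seed), row)
  }
  row
}
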