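#' Integrator configuration for the reference simulator
#'
#' The reference substrate advances the neuron ODE between grid points
#' either with a deliberately naive fixed-step explicit Euler method (one
#' step per grid interval) or with an adaptive Runge-Kutta-Fehlberg 4(5)
#' integrator targeting an absolute local error. In both cases input spike
#' delivery and threshold detection are synchronous on the \code{dt} grid.
#'
#' @param method \code{"rkf45"} (default) or \code{"euler"}.
#' @param dt Grid step in ms: the Euler step, or the threshold-check grid
#'   for rkf45 (default 0.1 ms).
#' @param abs_tol Absolute local error target for rkf45 (default 1e-3).
#' @return An object of class \code{"integrator_config"}.
#' @export
integrator_config <- function(method = c("rkf45", "euler"), dt = 0.1,
                              abs_tol = 1e-3) {
  method <- match.arg(method)
  stopifnot(dt > 0, abs_tol > 0)
  structure(list(method = method, dt = dt, abs_tol = abs_tol),
            class = "integrator_config")
}

#' Simulate a spiking BiNAM network
#'
#' Runs the built-in conductance-based LIF simulator on a network
#' description and input spike trains.
#'
#' @param net A [build_network()] description.
#' @param inputs Input [spike_train_set()] with \code{net$input_channels}
#'   channels.
#' @param t_end Simulation end time in ms (default: input duration).
#' @param integ An [integrator_config()].
#' @param i_offset Constant offset current per neuron in nA.
#' @param trace_neurons Integer vector of neuron indices (1-based) whose
#'   membrane potential is sampled at every grid time.
#' @return An object of class \code{"lif_result"} with \code{spikes} (a
#'   [spike_train_set()] over all neurons), \code{trace} (matrix, one column
#'   per traced neuron), \code{times} (grid times of the trace rows),
#'   \code{vmax} (per-neuron maximum membrane potential over all evaluated
#'   points) and \code{wall_time} (seconds).
#' @export
simulate_network <- function(net, inputs, t_end = NULL,
                             integ = integrator_config(), i_offset = 0,
                             trace_neurons = integer(0)) {
  stopifnot(inherits(net, "binam_network"), inherits(inputs, "spike_train_set"),
            inherits(integ, "integrator_config"))
  if (inputs$channels != net$input_channels)
    stop("input channel count does not match the network", call. = FALSE)
  if (is.null(t_end)) t_end <- inputs$duration
  last <- suppressWarnings(max(unlist(inputs$trains, use.names = FALSE), -Inf))
  if (is.finite(last) && t_end < last)
    stop("t_end must not precede the last input spike", call. = FALSE)

  spike_time <- unlist(inputs$trains, use.names = FALSE)
  spike_channel <- rep.int(seq_along(inputs$trains), lengths(inputs$trains)) - 1L
  syn <- net$synapses[order(net$synapses$source), , drop = FALSE]
  syn_start <- c(0L, cumsum(tabulate(syn$source, nbins = net$input_channels)))

  t0 <- proc.time()[["elapsed"]]
  res <- lif_run_cpp(net$neurons,
                     as.numeric(spike_time), as.integer(spike_channel),
                     as.integer(syn_start), as.integer(syn$target) - 1L,
                     as.numeric(syn$weight),
                     t_end, integ$dt, match(integ$method, c("euler", "rkf45")) - 1L,
                     integ$abs_tol,
                     unlist(net$params[c("v_rest", "v_th", "v_reset", "tau_ref",
                                         "g_leak", "c_m", "e_exc", "tau_exc")]),
                     i_offset, as.integer(trace_neurons) - 1L)
  wall <- proc.time()[["elapsed"]] - t0
  structure(list(spikes = spike_train_set(res$spikes, t_end),
                 trace = res$trace,
                 times = if (length(trace_neurons)) seq(0, by = integ$dt,
                                                        length.out = res$n_steps + 1)
                         else numeric(0),
                 vmax = res$vmax, wall_time = wall),
            class = "lif_result")
}

#' @export
print.lif_result <- function(x, ...) {
  cat(sprintf("LIF simulation: %d neurons, %d output spikes, %.1f ms (%.2f s wall)\n",
              x$spikes$channels, sum(lengths(x$spikes$trains)),
              x$spikes$duration, x$wall_time))
  invisible(x)
}

#' Simulate a single neuron under an explicit stimulus
#'
#' Convenience wrapper around the network simulator for one neuron receiving
#' a list of timed synaptic events; the membrane trace is always recorded.
#'
#' @param params A [neuron_params()] object.
#' @param times Input spike times in ms.
#' @param weights Synaptic conductance increments in nS, one per spike
#'   (recycled).
#' @param t_end Simulation end time in ms.
#' @param integ An [integrator_config()].
#' @param i_offset Constant offset current in nA.
#' @return A list with \code{spike_times}, \code{trace} (membrane potential
#'   at grid times), \code{times} and \code{vmax}.
#' @export
simulate_single_neuron <- function(params, times = numeric(0), weights = params$w,
                                   t_end = 100, integ = integrator_config(),
                                   i_offset = 0) {
  stopifnot(inherits(params, "neuron_params"))
  times <- as.numeric(times)
  weights <- rep_len(as.numeric(weights), length(times))
  # one private synapse per event so arbitrary per-spike weights are allowed
  net <- structure(list(input_channels = max(1L, length(times)), neurons = 1L,
                        omega = 1L, params = params,
                        synapses = data.frame(source = seq_along(times),
                                              target = rep(1L, length(times)),
                                              weight = weights)),
                   class = "binam_network")
  trains <- rep(list(numeric(0)), net$input_channels)
  for (i in seq_along(times)) trains[[i]] <- times[i]
  inputs <- spike_train_set(trains, max(t_end, times, 0))
  res <- simulate_network(net, inputs, t_end = t_end, integ = integ,
                          i_offset = i_offset, trace_neurons = 1L)
  list(spike_times = res$spikes$trains[[1L]], trace = res$trace[, 1L],
       times = res$times, vmax = res$vmax[1L])
}

# built-in back-ends ---------------------------------------------------------

backend_builtin <- function(net, inputs, integ = integrator_config(),
                            t_end = NULL, i_offset = 0, ...) {
  simulate_network(net, inputs, t_end = t_end, integ = integ,
                   i_offset = i_offset)$spikes
}

backend_null <- function(net, inputs, ...) inputs

.onLoad <- function(libname, pkgname) {
  register_backend("builtin", backend_builtin)
  register_backend("null", backend_null)
}
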