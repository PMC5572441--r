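#' Spike encoding specification
#'
#' Describes how binary patterns are translated to input spike trains: each
#' set bit becomes a burst of \code{s} spikes with inter-spike interval
#' \code{delta_t}, Gaussian jitter of standard deviation \code{sigma_t} is
#' added to every spike independently, one sample is presented every
#' \code{T} milliseconds, and each logical channel is replicated
#' \code{omega} times (population coding). The nominal per-synapse rate
#' during a burst is \code{1000/delta_t} per second (500/s at the default
#' 2 ms interval).
#'
#' @param s Spikes per burst (positive integer).
#' @param delta_t Inter-spike interval within a burst, ms.
#' @param sigma_t Gaussian jitter standard deviation, ms (0 disables jitter).
#' @param T Sample presentation period, ms.
#' @param omega Population multiplicity (positive integer).
#' @return An object of class \code{"encoding_spec"}.
#' @export
encoding_spec <- function(s = 1L, delta_t = 2, sigma_t = 2, T = 100, omega = 1L) {
  s <- stopifnot_scalar_int(s, "s")
  omega <- stopifnot_scalar_int(omega, "omega")
  stopifnot(delta_t > 0, sigma_t >= 0, T > 0)
  if (s * delta_t >= T)
    stop("burst length s*delta_t must fit well inside the presentation period T",
         call. = FALSE)
  structure(list(s = s, delta_t = delta_t, sigma_t = sigma_t, T = T,
                 omega = omega),
            class = "encoding_spec")
}

#' @export
print.encoding_spec <- function(x, ...) {
  cat(sprintf("Spike encoding: s = %d, delta_t = %g ms, sigma_t = %g ms, T = %g ms, omega = %d\n",
              x$s, x$delta_t, x$sigma_t, x$T, x$omega))
  invisible(x)
}

#' Per-synapse nominal burst rate
#'
#' @param spec An [encoding_spec()].
#' @return Spikes per second during a burst (\code{1000/delta_t}).
#' @export
burst_rate <- function(spec) 1000 / spec$delta_t

#' Construct a spike train set
#'
#' The interchange unit between the codec, the simulator and external
#' back-ends: one sorted vector of spike times (ms) per channel.
#'
#' @param trains List of numeric vectors of spike times in ms.
#' @param duration Total duration in ms.
#' @return An object of class \code{"spike_train_set"}.
#' @export
spike_train_set <- function(trains, duration) {
  trains <- lapply(trains, function(t) sort(as.numeric(t)))
  bad <- vapply(trains, function(t) length(t) && (t[1] < 0 || t[length(t)] > duration),
                logical(1))
  if (any(bad))
    stop("spike times must lie in [0, duration]", call. = FALSE)
  structure(list(channels = length(trains), trains = trains,
                 duration = as.numeric(duration)),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("Spike train set: %d channels, %d spikes, %.1f ms\n",
              x$channels, sum(lengths(x$trains)), x$duration))
  invisible(x)
}

#' Encode binary patterns as input spike trains
#'
#' Pattern \code{k} (row \code{k} of \code{X}, presented in window
#' \code{[(k-1)T, kT)}) contributes, for every set bit \code{i}, a burst of
#' \code{s} nominal spikes at \code{(k-1)T + (0:(s-1)) delta_t} on each of
#' the \code{omega} channels of population \code{i}. Independent Gaussian
#' jitter is added per spike per channel; jittered times are clamped at 0
#' and re-sorted. The jitter RNG is seeded explicitly, decoupled from data
#' generation, so equal \code{(X, spec, seed)} give bitwise-identical trains.
#'
#' @param X \code{N x m} binary matrix of input patterns.
#' @param spec An [encoding_spec()].
#' @param seed Jitter RNG seed.
#' @return A [spike_train_set()] with \code{m * omega} channels and duration
#'   \code{N * T}.
#' @export
encode_patterns <- function(X, spec, seed = 1L) {
  X <- stopifnot_binary_matrix(X, "X")
  stopifnot(inherits(spec, "encoding_spec"))
  N <- nrow(X); m <- ncol(X)
  omega <- spec$omega
  duration <- N * spec$T
  burst <- (seq_len(spec$s) - 1) * spec$delta_t
  trains <- rep(list(numeric(0)), m * omega)
  nominal <- vector("list", m)
  for (i in seq_len(m)) {
    ks <- which(X[, i] == 1L)
    nominal[[i]] <- as.vector(outer(burst, (ks - 1) * spec$T, `+`))
  }
  with_seed(seed, {
    for (i in seq_len(m)) {
      base <- nominal[[i]]
      if (!length(base)) next
      for (r in seq_len(omega)) {
        t <- base
        if (spec$sigma_t > 0)
          t <- pmax(0, t + rnorm(length(t), sd = spec$sigma_t))
        trains[[(i - 1) * omega + r]] <- sort(t)
      }
    }
  })
  out <- structure(list(channels = m * omega, trains = trains,
                        duration = duration),
                   class = "spike_train_set")
  # jitter may push a spike slightly past the last window; keep it but
  # never beyond the declared duration
  out$trains <- lapply(out$trains, function(t) pmin(t, duration))
  out
}

#' Decode output spike trains into binary patterns
#'
#' Counts, for each presentation window \code{[(k-1)T, kT)} and each output
#' population \code{j} (the \code{omega} consecutive channels
#' \code{(j-1)omega + 1:omega}), the summed spike count; the output bit is
#' set when the count reaches \code{min_count} (default \code{omega}, i.e.
#' on average one spike per population member).
#'
#' @param output A [spike_train_set()] with \code{n * omega} channels.
#' @param n Number of logical output components.
#' @param omega Population multiplicity used when building the network.
#' @param T Presentation period in ms.
#' @param N Number of samples (windows).
#' @param min_count Decision threshold on the per-window population count.
#' @return An \code{N x n} binary matrix.
#' @export
decode_spikes <- function(output, n, omega, T, N, min_count = omega) {
  stopifnot(inherits(output, "spike_train_set"))
  if (output$channels != n * omega)
    stop(sprintf("expected %d output channels (n * omega), got %d",
                 n * omega, output$channels), call. = FALSE)
  counts <- matrix(0L, N, n)
  for (j in seq_len(n)) {
    t <- unlist(output$trains[(j - 1) * omega + seq_len(omega)], use.names = FALSE)
    if (!length(t)) next
    if (any(t < 0 | t >= N * T)) {
      warning("spikes outside [0, N*T) attributed to the nearest window")
      t <- pmin(pmax(t, 0), N * T - 1e-9)
    }
    w <- tabulate(floor(t / T) + 1L, nbins = N)
    counts[, j] <- w
  }
  (counts >= min_count) + 0L
}

#' Spike-train CSV exchange format
#'
#' Two-column CSV \code{(channel_id, time_ms)} with a header line, channel
#' ids 1-based, times in ms with 0.01 ms precision. Used both for simulator
#' output and for scoring externally produced recordings.
#'
#' @param spikes A [spike_train_set()].
#' @param path File path.
#' @param channels Channel count on read (defaults to the largest id seen).
#' @param duration Duration on read (defaults to the last spike time).
#' @return \code{read_spike_csv} returns a [spike_train_set()].
#' @export
write_spike_csv <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train_set"))
  ch <- rep(seq_along(spikes$trains), lengths(spikes$trains))
  df <- data.frame(channel_id = ch,
                   time_ms = sprintf("%.2f", unlist(spikes$trains, use.names = FALSE)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path, channels = NULL, duration = NULL) {
  df <- read.csv(path)
  if (!all(c("channel_id", "time_ms") %in% names(df)))
    stop("spike CSV must have columns channel_id, time_ms", call. = FALSE)
  if (is.null(channels)) channels <- if (nrow(df)) max(df$channel_id) else 0L
  if (is.null(duration)) duration <- if (nrow(df)) max(df$time_ms) else 0
  trains <- lapply(seq_len(channels), function(i) sort(df$time_ms[df$channel_id == i]))
  spike_train_set(trains, duration)
}
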