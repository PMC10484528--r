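#' Set of presynaptic spike trains
#'
#' @param spikes A data frame with columns `source_id` (0-based integer) and
#'   `time_ms`.
#' @param n_sources Number of spike sources.
#' @param duration Duration of the stimulus window (ms).
#' @return An object of class `"spike_train_set"`.
#' @details Invariants enforced: `0 <= source_id < n_sources`,
#'   `0 <= time_ms <= duration`, and spike times strictly increasing within
#'   each source.
#' @export
spike_train_set <- function(spikes, n_sources, duration) {
  stopifnot(is.data.frame(spikes),
            all(c("source_id", "time_ms") %in% names(spikes)),
            length(n_sources) == 1L, n_sources >= 1,
            length(duration) == 1L, duration >= 0)
  spikes <- data.frame(source_id = as.integer(spikes$source_id),
                       time_ms = as.numeric(spikes$time_ms))
  spikes <- spikes[order(spikes$source_id, spikes$time_ms), , drop = FALSE]
  rownames(spikes) <- NULL
  if (nrow(spikes) > 0L) {
    if (any(spikes$source_id < 0 | spikes$source_id >= n_sources))
      stop("'source_id' out of range [0, n_sources)")
    if (any(spikes$time_ms < 0 | spikes$time_ms > duration))
      stop("spike times outside [0, duration]")
    dup <- stats::ave(spikes$time_ms, spikes$source_id,
                      FUN = function(t) c(FALSE, diff(t) <= 0))
    if (any(dup > 0))
      stop("spike times must be strictly increasing within each source")
  }
  structure(
    list(n_sources = as.integer(n_sources), spikes = spikes,
         duration = duration),
    class = "spike_train_set"
  )
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("Spike train set: %d source(s), %d spike(s), %g ms\n",
              x$n_sources, nrow(x$spikes), x$duration))
  invisible(x)
}

#' The frozen five-source stimulus table
#'
#' Returns the fixed set of external spike timestamps used as the canonical
#' network stimulus: five independent sources, eleven spikes over 500 ms,
#' generated once from low-rate Poisson processes and then frozen. The same
#' table ships as a CSV fixture under `extdata/table1_spikes.csv`.
#'
#' @return A [spike_train_set()] with 5 sources and 11 spikes.
#' @examples
#' stimulus_table1()
#' @export
stimulus_table1 <- function() {
  times <- list(`0` = 446, `1` = 355, `2` = c(53, 258, 300, 424, 457),
                `3` = c(88, 466), `4` = c(100, 212))
  spikes <- data.frame(
    source_id = rep(0:4, times = lengths(times)),
    time_ms = unlist(times, use.names = FALSE)
  )
  spike_train_set(spikes, n_sources = 5, duration = 500)
}

#' Homogeneous Poisson spike trains
#'
#' Generates independent Poisson spike trains, one per source, with times
#' snapped to the `dt` sampling grid by truncation. Re-running with the same
#' seed reproduces the identical ("frozen") set.
#'
#' @param n_sources Number of independent sources.
#' @param max_rate Firing rate ceiling (Hz). With
#'   `heterogeneous_rates = FALSE` (default) every source fires at exactly
#'   `max_rate`; otherwise each source draws its own rate uniformly from
#'   `(0, max_rate]`.
#' @param duration Stimulus duration (ms).
#' @param seed Optional integer seed.
#' @param dt Sampling step (ms) the spike times are snapped to.
#' @param heterogeneous_rates Draw per-source rates instead of using
#'   `max_rate` for all sources.
#' @return A [spike_train_set()].
#' @examples
#' poisson_spikes(5, max_rate = 5, duration = 500, seed = 1)
#' @export
poisson_spikes <- function(n_sources = 5, max_rate = 5, duration = 500,
                           seed = NULL, dt = 1,
                           heterogeneous_rates = FALSE) {
  stopifnot(n_sources >= 1, max_rate > 0, duration >= 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  src <- integer(0)
  tms <- numeric(0)
  for (s in seq_len(n_sources)) {
    rate <- if (heterogeneous_rates) runif(1) * max_rate else max_rate
    t <- 0
    repeat {
      t <- t + rexp(1, rate = rate / 1000)  # Hz -> events per ms
      if (t > duration) break
      src <- c(src, s - 1L)
      tms <- c(tms, trunc(t / dt) * dt)
    }
  }
  spikes <- data.frame(source_id = src, time_ms = tms)
  ## grid snapping can collapse two events onto one sample; keep the first
  spikes <- spikes[!duplicated(spikes[c("source_id", "time_ms")]), ,
                   drop = FALSE]
  spike_train_set(spikes, n_sources = n_sources, duration = duration)
}

#' Random excitatory/inhibitory network
#'
#' Builds a directed Erdos-Renyi style network with independent
#' Bernoulli(`p`) edges (no self-edges). The first block of neurons is
#' excitatory (positive outgoing weights), the rest inhibitory (negative).
#' Provided as a demo builder for small network simulations; the package's
#' validation pipeline operates on single neurons.
#'
#' @param n Number of neurons (>= 2).
#' @param ei_ratio Excitatory:inhibitory ratio, as a string `"1:1"` or a
#'   numeric ratio (1 means equal halves).
#' @param p Connection probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param w_exc,w_inh Synaptic weights (mV) assigned to excitatory and
#'   inhibitory sources.
#' @return An object of class `"ei_network"`: a list with `n_neurons`,
#'   `ei_ratio`, `connection_probability`, `edges` (data frame
#'   `src,dst,weight`, 0-based ids) and `seed`.
#' @examples
#' net <- random_ei_network(20, "1:1", p = 0.1, seed = 42)
#' nrow(net$edges)
#' @export
random_ei_network <- function(n, ei_ratio = "1:1", p = 0.1, seed = NULL,
                              w_exc = 0.5, w_inh = -0.5) {
  stopifnot(n >= 2, p >= 0, p <= 1)
  if (is.character(ei_ratio)) {
    parts <- as.numeric(strsplit(ei_ratio, ":", fixed = TRUE)[[1]])
    if (length(parts) != 2L || any(!is.finite(parts)) || any(parts <= 0))
      stop("'ei_ratio' must look like \"1:1\"")
    ratio <- parts[1] / parts[2]
  } else {
    ratio <- as.numeric(ei_ratio)
  }
  if (!is.null(seed)) set.seed(seed)
  n_exc <- round(n * ratio / (1 + ratio))
  pairs <- expand.grid(src = seq_len(n) - 1L, dst = seq_len(n) - 1L)
  pairs <- pairs[pairs$src != pairs$dst, , drop = FALSE]
  keep <- runif(nrow(pairs)) < p
  edges <- data.frame(src = pairs$src[keep], dst = pairs$dst[keep])
  edges$weight <- ifelse(edges$src < n_exc, w_exc, w_inh)
  structure(
    list(n_neurons = as.integer(n), ei_ratio = ratio,
         connection_probability = p, n_excitatory = as.integer(n_exc),
         edges = edges, seed = seed),
    class = "ei_network"
  )
}

#' @export
print.ei_network <- function(x, ...) {
  cat(sprintf(
    "E/I network: %d neurons (%d exc), p = %g, %d directed edges\n",
    x$n_neurons, x$n_excitatory, x$connection_probability, nrow(x$edges)))
  invisible(x)
}

#' Read and write spike trains as CSV
#'
#' The on-disk dialect is a two-column CSV with header
#' `source_id,time_ms`, one row per spike.
#'
#' @param x A [spike_train_set()].
#' @param path File path.
#' @param n_sources,duration Metadata for [read_spike_csv()]; when `NULL`
#'   they are inferred from the file contents (`max(source_id) + 1` and
#'   `max(time_ms)`).
#' @return `write_spike_csv()` returns `path` invisibly;
#'   `read_spike_csv()` returns a [spike_train_set()].
#' @export
write_spike_csv <- function(x, path) {
  stopifnot(inherits(x, "spike_train_set"))
  write.csv(x$spikes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path, n_sources = NULL, duration = NULL) {
  spikes <- read.csv(path)
  if (is.null(n_sources))
    n_sources <- if (nrow(spikes)) max(spikes$source_id) + 1L else 1L
  if (is.null(duration))
    duration <- if (nrow(spikes)) max(spikes$time_ms) else 0
  spike_train_set(spikes, n_sources, duration)
}

#' Write a network edge list as CSV (`src,dst,weight`)
#'
#' @param net An [random_ei_network()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(net, path) {
  stopifnot(inherits(net, "ei_network"))
  write.csv(net$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
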