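#' Spike raster object
#'
#' A timestamped spike record: the interchange object between the simulator,
#' the fixture generators and every statistics routine. Times are in ms and
#' neuron ids are 1-based; each neuron carries a population label ("E" or
#' "I"). `discard` marks an initial transient that statistics should skip
#' (helpers default to the post-discard window).
#'
#' @param time numeric vector of spike times (ms), non-decreasing overall.
#' @param id integer vector of neuron ids (1-based), same length as `time`.
#' @param population character vector, one label per neuron id ("E"/"I").
#' @param t_start,t_end record span in ms.
#' @param discard initial transient (ms) flagged for exclusion from statistics.
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(time, id, population, t_start = 0,
                         t_end = max(time, t_start), discard = 0) {
  stopifnot(length(time) == length(id))
  if (length(time) && is.unsorted(time)) {
    o <- order(time, id)
    time <- time[o]; id <- id[o]
  }
  stopifnot(all(population %in% c("E", "I")))
  structure(list(time = as.numeric(time), id = as.integer(id),
                 population = as.character(population),
                 t_start = t_start, t_end = t_end, discard = discard),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  n_e <- sum(x$population == "E")
  cat(sprintf("<spike_raster> %d spikes, %d neurons (%d E / %d I), span [%g, %g] ms (discard %g ms)\n",
              length(x$time), length(x$population), n_e,
              length(x$population) - n_e, x$t_start, x$t_end, x$discard))
  invisible(x)
}

#' Number of neurons in a raster
#' @param raster a [spike_raster()].
#' @return integer count of neurons (including silent ones).
#' @export
n_neurons <- function(raster) length(raster$population)

#' Restrict a raster to one population and/or a time window
#'
#' @param raster a [spike_raster()].
#' @param population `"E"`, `"I"`, or `NULL` for all neurons.
#' @param from,to window in ms; defaults to the post-discard span.
#' @return a `spike_raster` over the selected spikes. Neuron ids are kept
#'   as in the parent raster; `population` is subset accordingly only when
#'   all neurons are retained, otherwise an `ids` attribute maps rows.
#' @export
raster_window <- function(raster, population = NULL, from = NULL, to = NULL) {
  if (is.null(from)) from <- raster$t_start + raster$discard
  if (is.null(to)) to <- raster$t_end
  keep <- raster$time >= from & raster$time < to
  ids_keep <- seq_along(raster$population)
  if (!is.null(population)) {
    ids_keep <- which(raster$population == population)
    keep <- keep & raster$id %in% ids_keep
  }
  out <- spike_raster(raster$time[keep], raster$id[keep],
                      raster$population, t_start = from, t_end = to)
  attr(out, "ids") <- ids_keep
  out
}

#' Windowed spike-count series
#'
#' @param counts numeric vector of counts per window (integers for raw
#'   series, reals after filtering).
#' @param dt window size in ms.
#' @param t0 time of the left edge of the first window (ms).
#' @param scope `"population"` or `"neuron"`.
#' @param n_neurons number of neurons aggregated (for the rate view).
#' @return An object of class `count_series`.
#' @export
count_series <- function(counts, dt, t0 = 0, scope = "population", n_neurons = 1L) {
  structure(list(counts = as.numeric(counts), dt = dt, t0 = t0,
                 scope = scope, n_neurons = as.integer(n_neurons)),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> %d windows of %g ms (%s scope, %d neurons), mean count %.3g\n",
              length(x$counts), x$dt, x$scope, x$n_neurons, mean(x$counts)))
  invisible(x)
}

#' Population rate view of a count series, in Hz per neuron
#' @param series a [count_series()].
#' @return numeric vector: counts / (n_neurons * dt) in Hz.
#' @export
rate_series <- function(series) {
  series$counts / (series$n_neurons * series$dt) * 1000
}

#' Membrane-potential trace sampled on a regular grid
#'
#' @param t sample times (ms).
#' @param V matrix, neurons in rows, samples in columns (mV).
#' @param ids neuron ids of the rows.
#' @param population population label per row.
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(t, V, ids, population) {
  stopifnot(nrow(V) == length(ids), length(ids) == length(population))
  structure(list(t = t, V = V, ids = as.integer(ids),
                 population = as.character(population)),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d neurons x %d samples (%g ms grid)\n",
              nrow(x$V), ncol(x$V), if (length(x$t) > 1) diff(x$t[1:2]) else NA))
  invisible(x)
}
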