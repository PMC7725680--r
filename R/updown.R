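#' Detect up-states in a spike raster
#'
#' Population rate at `dt`-ms bins, trailing square-kernel filtering over
#' `T` ms, threshold at `frac` of the maximum of the filtered series
#' (switchable to the raw series), and maximal supra-threshold runs of at
#' least `min_duration` ms.
#'
#' @param raster a [spike_raster()] (whole span used; `discard` ignored,
#'   matching the treatment of continuous recordings).
#' @param dt rate bin, ms (default 10).
#' @param T square-kernel length, ms (default 100).
#' @param frac threshold fraction of the maximum rate (default 0.3).
#' @param min_duration minimum up-state length, ms (default 1000).
#' @param threshold_on `"filtered"` (default) or `"raw"`: which series the
#'   maximum defining the threshold is taken from.
#' @return An object of class `up_state_segments`: data.frame `segments`
#'   with `start`, `end` (ms), plus the detection parameters.
#' @export
detect_up_states <- function(raster, dt = 10, T = 100, frac = 0.3,
                             min_duration = 1000,
                             threshold_on = c("filtered", "raw")) {
  threshold_on <- match.arg(threshold_on)
  if (!length(raster$time)) stop("empty raster")
  raw <- spike_count_series(raster, dt, from = raster$t_start, to = raster$t_end)
  filt <- square_filter(raw, T)
  thr <- frac * max(if (threshold_on == "filtered") filt$counts else raw$counts)
  up <- filt$counts > thr
  r <- rle(up)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths * dt >= min_duration)
  seg <- data.frame(start = filt$t0 + (starts[runs] - 1) * dt,
                    end = filt$t0 + ends[runs] * dt)
  structure(list(segments = seg, dt = dt, T = T, frac = frac,
                 min_duration = min_duration, threshold = thr),
            class = "up_state_segments")
}

#' @export
print.up_state_segments <- function(x, ...) {
  cat(sprintf("<up_state_segments> %d segment(s), total %.1f s\n",
              nrow(x$segments),
              sum(x$segments$end - x$segments$start) / 1000))
  invisible(x)
}

#' Shuffle inter-spike intervals within up-states
#'
#' Per neuron and per segment, the ISIs are permuted uniformly at random
#' with the first spike anchored, preserving the spike count and the
#' segment-local first and last spike times while destroying temporal
#' correlation structure. Neurons with at most two spikes in a segment
#' are left unchanged. Spikes outside all segments are untouched.
#'
#' @param raster a [spike_raster()].
#' @param segments an [detect_up_states()] result (or data.frame with
#'   `start`, `end`).
#' @param seed integer seed.
#' @return a shuffled [spike_raster()].
#' @export
shuffle_isi <- function(raster, segments, seed = 1L) {
  seg <- if (inherits(segments, "up_state_segments")) segments$segments else segments
  time <- raster$time; id <- raster$id
  with_seed(as.integer(seed), {
    for (s in seq_len(nrow(seg))) {
      in_seg <- which(time >= seg$start[s] & time < seg$end[s])
      if (!length(in_seg)) next
      for (spl in split(in_seg, id[in_seg])) {
        if (length(spl) <= 2) next
        tt <- sort(time[spl])
        isi <- diff(tt)
        time[spl] <- tt[1] + c(0, cumsum(sample(isi)))
      }
    }
    spike_raster(time, id, raster$population, raster$t_start, raster$t_end,
                 raster$discard)
  })
}
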