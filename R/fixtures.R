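#' Independent homogeneous Poisson raster
#'
#' Emulates the asynchronous-state null: independent Poisson spike trains
#' at a common rate.
#'
#' @param n_neurons neuron count.
#' @param rate_hz per-neuron rate, Hz.
#' @param duration record length, ms.
#' @param seed integer seed (mandatory for reproducibility).
#' @param population label applied to every neuron (default "E").
#' @return a [spike_raster()].
#' @export
generate_poisson_raster <- function(n_neurons, rate_hz, duration, seed,
                                    population = "E") {
  stopifnot(rate_hz >= 0, duration > 0)
  with_seed(as.integer(seed), {
    counts <- rpois(n_neurons, rate_hz / 1000 * duration)
    id <- rep.int(seq_len(n_neurons), counts)
    time <- runif(sum(counts), 0, duration)
    spike_raster(time, id, rep(population, n_neurons), 0, duration)
  })
}

#' Oscillation-modulated Poisson raster
#'
#' Inhomogeneous Poisson trains with sinusoidal rate
#' `r(t) = base * (1 + depth * sin(2 pi f t))`, generated by thinning.
#' Emulates sparse synchrony: the population rate spectrum peaks at the
#' modulation frequency while individual trains stay irregular.
#'
#' @param n_neurons neuron count.
#' @param base_rate_hz mean per-neuron rate, Hz.
#' @param mod_freq_hz modulation frequency, Hz.
#' @param depth modulation depth in [0, 1].
#' @param duration record length, ms.
#' @param seed integer seed.
#' @param population label (default "E").
#' @return a [spike_raster()].
#' @export
generate_modulated_raster <- function(n_neurons, base_rate_hz, mod_freq_hz,
                                      depth, duration, seed,
                                      population = "E") {
  if (depth < 0 || depth > 1) stop("modulation depth must lie in [0, 1]")
  rmax <- base_rate_hz * (1 + depth)
  with_seed(as.integer(seed), {
    counts <- rpois(n_neurons, rmax / 1000 * duration)
    id <- rep.int(seq_len(n_neurons), counts)
    time <- runif(sum(counts), 0, duration)
    r <- base_rate_hz * (1 + depth * sin(2 * pi * mod_freq_hz * time / 1000))
    keep <- runif(length(time)) < r / rmax
    spike_raster(time[keep], id[keep], rep(population, n_neurons), 0, duration)
  })
}

#' Telegraph up-down modulated raster
#'
#' Deterministic alternation between an up rate and a down rate with half
#' period `switch_period` ms (the record starts in the up phase), with
#' heterogeneous per-neuron lognormal rate multipliers emulating the broad
#' firing-rate distribution of cultured recordings. Ground-truth switch
#' times are attached as attribute `switch_times`.
#'
#' @param n_neurons neuron count.
#' @param rate_up_hz,rate_down_hz mean per-neuron rates in the two phases.
#' @param switch_period half period of the alternation, ms (default 5000,
#'   i.e. a full up-down cycle of 0.1 Hz).
#' @param duration record length, ms.
#' @param seed integer seed.
#' @param sdlog lognormal spread of the per-neuron multipliers (default 1;
#'   meanlog is set so the multiplier mean is 1).
#' @param population label (default "E").
#' @return a [spike_raster()] with attributes `switch_times` (ms) and
#'   `up_intervals` (data.frame start/end).
#' @export
generate_updown_raster <- function(n_neurons, rate_up_hz, rate_down_hz,
                                   switch_period = 5000, duration, seed,
                                   sdlog = 1, population = "E") {
  stopifnot(rate_up_hz > rate_down_hz, rate_down_hz >= 0)
  with_seed(as.integer(seed), {
    mult <- exp(rnorm(n_neurons, -sdlog^2 / 2, sdlog))
    rmax_i <- rate_up_hz * mult
    counts <- rpois(n_neurons, rmax_i / 1000 * duration)
    id <- rep.int(seq_len(n_neurons), counts)
    time <- runif(sum(counts), 0, duration)
    phase_up <- (floor(time / switch_period) %% 2) == 0
    r <- ifelse(phase_up, rate_up_hz, rate_down_hz) * mult[id]
    keep <- runif(length(time)) < r / rmax_i[id]
    out <- spike_raster(time[keep], id[keep], rep(population, n_neurons),
                        0, duration)
    switches <- seq(switch_period, duration, by = switch_period)
    switches <- switches[switches < duration]
    ups <- seq(0, duration, by = 2 * switch_period)
    ups <- ups[ups < duration - 1e-6]
    attr(out, "switch_times") <- switches
    attr(out, "up_intervals") <- data.frame(
      start = ups, end = pmin(ups + switch_period, duration))
    out
  })
}

#' Count series with planted power-law avalanches
#'
#' Concatenates avalanches whose sizes are drawn from a doubly truncated
#' discrete power law; each avalanche of size S spans
#' `T = max(1, round(S^(1/2)))` bins (the S ~ T^2 crackling allocation),
#' every bin gets at least one spike and the remainder is spread
#' multinomially. Avalanches are separated by single empty bins and the
#' series is padded with one empty bin at each end, so extraction returns
#' exactly the planted sizes.
#'
#' @param n_avalanches avalanche count.
#' @param tau size exponent (> 1).
#' @param xmin,xmax truncation bounds of the size distribution.
#' @param seed integer seed.
#' @param dt nominal bin width, ms (default 1).
#' @return a [count_series()] with attributes `sizes` and `durations`.
#' @export
generate_powerlaw_avalanche_counts <- function(n_avalanches, tau, xmin = 1,
                                               xmax = 1000, seed, dt = 1) {
  if (tau <= 1) stop("size exponent tau must exceed 1")
  with_seed(as.integer(seed), {
    sizes <- .dpl_sample(n_avalanches, tau, xmin, xmax)
    durations <- pmax(1L, as.integer(round(sqrt(sizes))))
    durations <- pmin(durations, sizes)  # at least one spike per bin
    chunks <- vector("list", n_avalanches)
    for (k in seq_len(n_avalanches)) {
      S <- sizes[k]; Tk <- durations[k]
      extra <- if (S > Tk) as.integer(stats::rmultinom(1, S - Tk, rep(1, Tk)))
               else integer(Tk)
      chunks[[k]] <- c(rep(1L, Tk) + extra, 0L)
    }
    counts <- c(0L, unlist(chunks))
    out <- count_series(counts, dt, scope = "population")
    attr(out, "sizes") <- sizes
    attr(out, "durations") <- durations
    out
  })
}
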