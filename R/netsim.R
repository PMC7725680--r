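#' Network configuration
#'
#' Single source of truth for one simulation run of the current-based leaky
#' integrate-and-fire E-I network. Defaults reproduce the reference
#' parameterization: N = 10^4 neurons at 4:1 E:I ratio, connection density
#' p = 0.2, external drive of n_o = p N_E independent Poisson sources per
#' neuron, synaptic weights (mV) J_EO = 0.45, J_IO = 0.72, J_EE = 0.36,
#' J_IE = 0.72, J_EI = -0.81, J_II = -1.44 satisfying the balanced
#' condition, membrane constants 20/10 ms, bi-exponential synapses with rise
#' 0.5 ms and decay 2 ms (E); the inhibitory decay `tau_d_I` is the control
#' parameter of the synchronous transition (1 to 4.5 ms).
#'
#' @param N total neuron count.
#' @param frac_E excitatory fraction.
#' @param p connection density (directed Erdos-Renyi).
#' @param n_o external input count per neuron; default p * N * frac_E.
#' @param Q_o external Poisson rate per source, Hz.
#' @param J_EO,J_IO,J_EE,J_IE,J_EI,J_II synaptic weights, mV. The two
#'   inhibitory weights must be negative, the rest positive.
#' @param V_rest_E,V_rest_I,V_th,V_reset potentials, mV.
#' @param tau_m_E,tau_m_I membrane time constants, ms.
#' @param tau_r synaptic rise time, ms (shared by E and I synapses).
#' @param tau_d_E,tau_d_I synaptic decay times, ms.
#' @param t_ref_E,t_ref_I refractory periods, ms.
#' @param tau_l_E,tau_l_I synaptic latencies, ms. Carried for completeness;
#'   the integrator assumes zero delay and rejects nonzero values.
#' @param dt integration step, ms (must be < tau_r).
#' @param duration,discard total simulated time and initial transient
#'   flagged for exclusion from statistics, ms.
#' @param seed integer seed recorded with the run.
#' @return An object of class `network_config` (named list).
#' @export
network_config <- function(N = 10000, frac_E = 0.8, p = 0.2,
                           n_o = NULL, Q_o = 5,
                           J_EO = 0.45, J_IO = 0.72, J_EE = 0.36,
                           J_IE = 0.72, J_EI = -0.81, J_II = -1.44,
                           V_rest_E = -70, V_rest_I = -70,
                           V_th = -50, V_reset = -60,
                           tau_m_E = 20, tau_m_I = 10,
                           tau_r = 0.5, tau_d_E = 2, tau_d_I = 1,
                           t_ref_E = 2, t_ref_I = 1,
                           tau_l_E = 0, tau_l_I = 0,
                           dt = 0.05, duration = 16000, discard = 1000,
                           seed = 1L) {
  N_E <- round(N * frac_E)
  if (is.null(n_o)) n_o <- p * N_E
  cfg <- list(N = as.integer(N), frac_E = frac_E, N_E = as.integer(N_E),
              N_I = as.integer(N - N_E), p = p, n_o = n_o, Q_o = Q_o,
              J_EO = J_EO, J_IO = J_IO, J_EE = J_EE, J_IE = J_IE,
              J_EI = J_EI, J_II = J_II,
              V_rest_E = V_rest_E, V_rest_I = V_rest_I,
              V_th = V_th, V_reset = V_reset,
              tau_m_E = tau_m_E, tau_m_I = tau_m_I,
              tau_r = tau_r, tau_d_E = tau_d_E, tau_d_I = tau_d_I,
              t_ref_E = t_ref_E, t_ref_I = t_ref_I,
              tau_l_E = tau_l_E, tau_l_I = tau_l_I,
              dt = dt, duration = duration, discard = discard,
              seed = as.integer(seed))
  class(cfg) <- "network_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!(cfg$p > 0 && cfg$p <= 1)) stop("connection density p must be in (0, 1]")
  if (!(cfg$J_EI < 0 && cfg$J_II < 0)) stop("inhibitory weights J_EI, J_II must be negative")
  if (!all(c(cfg$J_EO, cfg$J_IO, cfg$J_EE, cfg$J_IE) > 0))
    stop("excitatory weights J_EO, J_IO, J_EE, J_IE must be positive")
  if (!(cfg$V_reset < cfg$V_th)) stop("V_reset must lie below V_th")
  if (!(cfg$tau_r < min(cfg$tau_d_E, cfg$tau_d_I)))
    stop("tau_r must be smaller than both decay times (bi-exponential filter)")
  if (!(cfg$dt < cfg$tau_r)) stop("dt must be smaller than tau_r")
  if (cfg$tau_l_E != 0 || cfg$tau_l_I != 0)
    stop("nonzero synaptic latencies are not supported by the integrator")
  invisible(cfg)
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> N=%d (E:I %d:%d), p=%g, Q_o=%g Hz, tau_d_I=%g ms, dt=%g ms, %g ms run\n",
              x$N, x$N_E, x$N_I, x$p, x$Q_o, x$tau_d_I, x$dt, x$duration))
  invisible(x)
}

#' Bi-exponential synaptic kernel
#'
#' `F(t) = [exp(-t/tau_d) - exp(-t/tau_r)] / (tau_d - tau_r)` for `t >= 0`;
#' normalized so the kernel integrates to one (each presynaptic spike
#' delivers total charge equal to its weight).
#'
#' @param t time since the presynaptic spike, ms (vectorized; `t < 0` gives 0).
#' @param tau_r,tau_d rise and decay times, ms, with `0 < tau_r < tau_d`.
#' @return kernel density values (per ms).
#' @export
synaptic_kernel <- function(t, tau_r, tau_d) {
  if (!(tau_r > 0 && tau_r < tau_d))
    stop("degenerate filter: need 0 < tau_r < tau_d (alpha-function limit not implemented)")
  ifelse(t >= 0, (exp(-t / tau_d) - exp(-t / tau_r)) / (tau_d - tau_r), 0)
}

#' Build random connectivity
#'
#' Directed Erdos-Renyi graph on ordered pairs: each edge j -> i (j != i) is
#' present independently with probability `p`. "Neighbors" throughout the
#' package are presynaptic (in-neighbors), matching the input sums of the
#' membrane equation.
#'
#' @param config a [network_config()].
#' @param seed integer seed (reproducible connectivity).
#' @return An object of class `ei_connectivity`: CSR out-lists (`offsets`,
#'   0-based `targets0`), `N`, `N_E`.
#' @export
build_connectivity <- function(config, seed = config$seed) {
  validate_config(config)
  csr <- with_seed(as.integer(seed), .cpp_build_connectivity(config$N, config$p))
  structure(list(offsets = csr$offsets, targets0 = csr$targets0,
                 N = config$N, N_E = config$N_E, seed = as.integer(seed)),
            class = "ei_connectivity")
}

#' @export
print.ei_connectivity <- function(x, ...) {
  cat(sprintf("<ei_connectivity> %d neurons, %d directed edges\n",
              x$N, length(x$targets0)))
  invisible(x)
}

#' In-degrees by presynaptic population
#'
#' @param conn an [build_connectivity()] result.
#' @param from `"E"` or `"I"`: count in-edges whose presynaptic neuron
#'   belongs to that population.
#' @return integer vector of in-degrees over all `N` neurons.
#' @export
in_degrees <- function(conn, from = c("E", "I")) {
  from <- match.arg(from)
  deg_per_pre <- diff(conn$offsets)
  pre <- rep.int(seq_len(conn$N), deg_per_pre)
  keep <- if (from == "E") pre <= conn$N_E else pre > conn$N_E
  tabulate(conn$targets0[keep] + 1L, nbins = conn$N)
}

#' Simulate the spiking network
#'
#' Integrates the membrane equation with the Heun (second-order) scheme,
#' sub-step threshold-crossing interpolation and refractory clamping at
#' `V_reset` (synaptic integration halted, filter states keep evolving).
#' External drive per neuron is the superposition of `n_o` Poisson sources
#' at `Q_o` Hz each, filtered through the excitatory kernel.
#'
#' @param config a [network_config()].
#' @param conn a [build_connectivity()] result consistent with `config`.
#' @param seed integer seed for the external drive (and initial voltages if
#'   `init_V = "uniform"`).
#' @param init_V `"rest"` (all at the resting potential), `"uniform"`
#'   (uniform in `[V_reset, V_th]`), or a numeric vector of length N.
#' @param record_ids neuron ids whose membrane potential is recorded at 1-ms
#'   samples; `NULL` records all neurons when N <= 2000, otherwise a
#'   deterministic stride sample of 1000 neurons preserving the E:I ratio.
#'   `integer(0)` disables voltage recording.
#' @param record_every_ms voltage sampling interval, ms (default 1; the
#'   full-resolution grid `record_every_ms = config$dt` is available for
#'   convergence checks).
#' @param const_input constant current injected into every neuron, mV/ms
#'   (used for closed-form single-neuron checks).
#' @return list with elements `raster` (a [spike_raster()], `discard`
#'   flagged from the config) and `voltage` (a [voltage_trace()], or `NULL`).
#' @export
simulate_network <- function(config, conn = NULL, seed = config$seed,
                             init_V = c("rest", "uniform"),
                             record_ids = NULL, record_every_ms = 1,
                             const_input = 0) {
  validate_config(config)
  if (is.null(conn)) conn <- build_connectivity(config)
  stopifnot(inherits(conn, "ei_connectivity"), conn$N == config$N)
  N <- config$N; NE <- config$N_E
  pop <- rep(c("E", "I"), c(NE, N - NE))

  if (is.null(record_ids)) {
    record_ids <- if (N <= 2000) seq_len(N) else {
      nE <- 800; nI <- 200
      c(round(seq(1, NE, length.out = nE)),
        round(seq(NE + 1, N, length.out = nI)))
    }
  }
  record_ids <- as.integer(record_ids)

  out <- with_seed(as.integer(seed), {
    V0 <- if (is.numeric(init_V)) {
      stopifnot(length(init_V) == N)
      init_V
    } else switch(match.arg(init_V),
      rest = c(rep(config$V_rest_E, NE), rep(config$V_rest_I, N - NE)),
      uniform = runif(N, config$V_reset, config$V_th))
    .cpp_simulate_network(conn$offsets, conn$targets0, N, NE, config$p,
                          config$J_EO, config$J_IO, config$J_EE, config$J_IE,
                          config$J_EI, config$J_II,
                          config$V_rest_E, config$V_rest_I,
                          config$V_th, config$V_reset,
                          config$tau_m_E, config$tau_m_I,
                          config$tau_r, config$tau_d_E, config$tau_d_I,
                          config$t_ref_E, config$t_ref_I,
                          config$dt, config$duration,
                          config$n_o, config$Q_o / 1000,
                          V0, const_input,
                          record_ids - 1L, record_every_ms)
  })
  raster <- spike_raster(out$time, out$id, pop, t_start = 0,
                         t_end = config$duration, discard = config$discard)
  voltage <- if (length(record_ids)) {
    voltage_trace(out$t_samp, out$V, record_ids, pop[record_ids])
  }
  list(raster = raster, voltage = voltage)
}

#' Run repeated trials with shared connectivity
#'
#' Trials differ in external drive realization and in the uniformly random
#' initial membrane potentials (in `[V_reset, V_th]`); seeds are derived
#' deterministically from `base_seed`.
#'
#' @param config a [network_config()].
#' @param n_trials number of trials (>= 1).
#' @param base_seed integer; trial k uses seed `base_seed + 7919 * k`.
#' @param resample_connectivity if `TRUE`, redraw the graph each trial.
#' @param ... passed to [simulate_network()].
#' @return list of [simulate_network()] results, one per trial.
#' @export
run_trials <- function(config, n_trials, base_seed = config$seed,
                       resample_connectivity = FALSE, ...) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  conn <- build_connectivity(config, seed = base_seed)
  lapply(seq_len(n_trials), function(k) {
    if (resample_connectivity && k > 1)
      conn <- build_connectivity(config, seed = base_seed + 104729L * k)
    tryCatch(
      simulate_network(config, conn, seed = base_seed + 7919L * k,
                       init_V = "uniform", ...),
      error = function(e) stop(sprintf("trial %d: %s", k, conditionMessage(e))))
  })
}
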