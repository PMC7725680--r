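#' Spike-count series from a raster
#'
#' Half-open bins `[k dt, (k+1) dt)` over the analysis window (post-discard
#' by default). Population scope sums all member neurons; neuron scope
#' returns one series for a single neuron.
#'
#' @param raster a [spike_raster()].
#' @param dt bin size, ms.
#' @param scope `"population"` or `"neuron"`.
#' @param population `"E"`, `"I"` or `NULL` (all), for population scope.
#' @param neuron neuron id, for neuron scope.
#' @param from,to analysis window, ms; default post-discard span.
#' @return a [count_series()].
#' @export
spike_count_series <- function(raster, dt, scope = c("population", "neuron"),
                               population = NULL, neuron = NULL,
                               from = NULL, to = NULL) {
  scope <- match.arg(scope)
  stopifnot(dt > 0)
  if (is.null(from)) from <- raster$t_start + raster$discard
  if (is.null(to)) to <- raster$t_end
  nbin <- floor((to - from) / dt)
  keep <- raster$time >= from & raster$time < from + nbin * dt
  n_mem <- 1L
  if (scope == "population") {
    if (!is.null(population)) {
      ids <- which(raster$population == population)
      keep <- keep & raster$id %in% ids
      n_mem <- length(ids)
    } else n_mem <- n_neurons(raster)
  } else {
    stopifnot(!is.null(neuron))
    keep <- keep & raster$id == neuron
  }
  tms <- raster$time[keep]
  counts <- tabulate(pmin(floor((tms - from) / dt) + 1L, nbin), nbins = nbin)
  count_series(counts, dt, t0 = from, scope = scope, n_neurons = n_mem)
}

#' Trailing square-kernel filter
#'
#' Moving average with kernel support `[-T, 0]` (each output bin averages
#' the current and preceding `T/dt - 1` bins). The first `T/dt - 1` bins,
#' where the kernel is not fully supported, are dropped and the series
#' origin is shifted accordingly, so a constant series is returned
#' unchanged and the kernel mean is preserved.
#'
#' @param series a [count_series()].
#' @param T kernel length, ms; must be a multiple of the bin size.
#' @return a filtered [count_series()] (real-valued counts).
#' @export
square_filter <- function(series, T) {
  k <- T / series$dt
  if (T < series$dt || abs(k - round(k)) > 1e-9)
    stop("kernel length T must be a positive multiple of the bin size")
  k <- round(k)
  f <- as.numeric(stats::filter(series$counts, rep(1 / k, k), sides = 1))
  f <- f[!is.na(f)]
  count_series(f, series$dt, t0 = series$t0 + (k - 1) * series$dt,
               scope = series$scope, n_neurons = series$n_neurons)
}

#' Coefficient of variation of inter-spike intervals
#'
#' `SD(ISI) / mean(ISI)` per neuron over the analysis window. Neurons with
#' fewer than `min_spikes` spikes are returned as `NA` (population
#' averages should skip them).
#'
#' @param raster a [spike_raster()].
#' @param ids neuron ids to evaluate; default all neurons, or all neurons
#'   of `population` if given.
#' @param population optional population filter used when `ids` is NULL.
#' @param min_spikes minimum spikes required (default 3).
#' @param from,to analysis window, ms; default post-discard span.
#' @return named numeric vector of CVs (NA where flagged).
#' @export
cv_isi <- function(raster, ids = NULL, population = NULL, min_spikes = 3,
                   from = NULL, to = NULL) {
  if (is.null(from)) from <- raster$t_start + raster$discard
  if (is.null(to)) to <- raster$t_end
  if (is.null(ids)) {
    ids <- if (is.null(population)) seq_along(raster$population)
           else which(raster$population == population)
  }
  keep <- raster$time >= from & raster$time < to & raster$id %in% ids
  spl <- split(raster$time[keep], factor(raster$id[keep], levels = ids))
  vapply(spl, function(tt) {
    if (length(tt) < min_spikes) return(NA_real_)
    isi <- diff(tt)
    sd(isi) / mean(isi)
  }, numeric(1))
}

#' Fano factor of a count series
#'
#' @param series a [count_series()] (conventionally with 50-ms windows).
#' @return `var(counts) / mean(counts)`.
#' @export
fano_factor <- function(series) {
  m <- mean(series$counts)
  if (m <= 0) stop("zero mean count; Fano factor undefined")
  var(series$counts) / m
}

#' Mean pairwise Pearson correlation of filtered spike counts
#'
#' Each neuron's 1-ms count series is filtered by a trailing square kernel
#' (length `T`), then Pearson correlations are averaged over excitatory
#' pairs. When the population exceeds `exact_limit` neurons, a seeded
#' subset sized so that its pair count is about `max_pairs` is used.
#' Zero-variance neurons are excluded.
#'
#' @param raster a [spike_raster()].
#' @param dt bin size, ms (default 1).
#' @param T square-kernel length, ms (default 50).
#' @param population population whose pairs are averaged (default "E").
#' @param exact_limit use all pairs when the population has at most this
#'   many neurons (default 500).
#' @param max_pairs approximate pair budget for the subsampled case.
#' @param seed seed for the neuron subsample.
#' @param from,to analysis window, ms.
#' @return mean pairwise correlation coefficient.
#' @export
mean_pairwise_pcc <- function(raster, dt = 1, T = 50, population = "E",
                              exact_limit = 500, max_pairs = 1e4, seed = 1L,
                              from = NULL, to = NULL) {
  ids <- which(raster$population == population)
  if (length(ids) > exact_limit) {
    n_sub <- ceiling((1 + sqrt(1 + 8 * max_pairs)) / 2)
    ids <- with_seed(as.integer(seed), sort(sample(ids, min(n_sub, length(ids)))))
  }
  mats <- lapply(ids, function(i) {
    s <- spike_count_series(raster, dt, scope = "neuron", neuron = i,
                            from = from, to = to)
    square_filter(s, T)$counts
  })
  M <- do.call(cbind, mats)
  v <- apply(M, 2, var)
  M <- M[, v > 0, drop = FALSE]
  if (ncol(M) < 2) stop("fewer than two neurons with nonzero variance")
  C <- stats::cor(M)
  mean(C[upper.tri(C)])
}

#' Voltage coherence
#'
#' Temporal variance of the population-mean voltage divided by the mean
#' over neurons of the individual temporal variances. 1 for identical
#' traces; about 1/N for independent ones.
#'
#' @param trace a [voltage_trace()].
#' @param population `"E"`, `"I"` or `NULL` (all recorded neurons).
#' @param from discard samples before this time, ms (default 0).
#' @return coherence in (0, 1].
#' @export
voltage_coherence <- function(trace, population = "E", from = 0) {
  rows <- if (is.null(population)) seq_len(nrow(trace$V))
          else which(trace$population == population)
  if (length(rows) < 2) stop("need at least two recorded neurons")
  V <- trace$V[rows, trace$t >= from, drop = FALSE]
  vi <- apply(V, 1, var)
  if (mean(vi) <= 0) stop("zero individual voltage variance")
  var(colMeans(V)) / mean(vi)
}

#' CV of the population firing-rate series
#'
#' Temporal coefficient of variation of the 1-ms population rate,
#' quantifying firing-rate variability at short timescales.
#'
#' @param raster a [spike_raster()].
#' @param dt bin size, ms (default 1).
#' @param population population filter (default "E").
#' @param from,to analysis window, ms.
#' @return `SD / mean` of the binned population rate.
#' @export
population_rate_cv <- function(raster, dt = 1, population = "E",
                               from = NULL, to = NULL) {
  s <- spike_count_series(raster, dt, population = population,
                          from = from, to = to)
  m <- mean(s$counts)
  if (m <= 0) stop("zero mean population rate")
  sd(s$counts) / m
}

# Welch power spectral density: Hann segments, 50% overlap, mean-detrended,
# one-sided, normalized so that sum(P) * df ~ var(x).
welch_psd <- function(x, fs, segment_length, overlap = 0.5) {
  L <- min(segment_length, length(x))
  step <- max(1, floor(L * (1 - overlap)))
  starts <- seq(1, length(x) - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  U <- mean(w^2)
  nf <- floor(L / 2)
  P <- rep(0, nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[2:(nf + 1)])^2 / (fs * L * U)
    P <- P + 2 * sp
  }
  list(freq = (1:nf) * fs / L, power = P / length(starts))
}

#' Welch power spectrum of a rate series, peak and decay exponent
#'
#' Welch-averaged periodogram of the population rate (1-s Hann segments,
#' 50% overlap, mean-detrended). The spectral peak is the argmax above
#' `peak_min_hz`; the decay exponent beta is fitted by least squares on
#' `log10 P` vs `log10 f` over `fit_range` (default from 1.5x the peak up
#' to 1000 Hz, clipped to the Nyquist frequency).
#'
#' @param series a [count_series()] (1-ms bins are conventional).
#' @param segment_ms Welch segment length, ms (default 1000).
#' @param peak_min_hz lower bound for the peak search (default 10).
#' @param fit_range optional `c(lo, hi)` in Hz for the beta fit.
#' @return An object of class `psd_result`: `freq` (Hz), `power`,
#'   `peak_hz`, `beta`, `fit_range`.
#' @export
rate_psd <- function(series, segment_ms = 1000, peak_min_hz = 10,
                     fit_range = NULL) {
  fs <- 1000 / series$dt
  L <- round(segment_ms / series$dt)
  if (length(series$counts) < 2 * L)
    stop("series too short for Welch averaging (need >= 4 half-overlapped segments)")
  q <- rate_series(series)
  ps <- welch_psd(q, fs, L)
  sel <- ps$freq >= peak_min_hz
  peak_hz <- ps$freq[sel][which.max(ps$power[sel])]
  if (is.null(fit_range)) fit_range <- c(1.5 * peak_hz, 1000)
  fit_range[2] <- min(fit_range[2], max(ps$freq))
  fsel <- ps$freq >= fit_range[1] & ps$freq <= fit_range[2] & ps$power > 0
  beta <- NA_real_
  if (sum(fsel) >= 5) {
    co <- coef(lm(log10(ps$power[fsel]) ~ log10(ps$freq[fsel])))
    beta <- -unname(co[2])
  }
  structure(list(freq = ps$freq, power = ps$power, peak_hz = peak_hz,
                 beta = beta, fit_range = fit_range),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result> peak %.1f Hz, beta = %.2f over [%.0f, %.0f] Hz\n",
              x$peak_hz, x$beta, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Skewness and kurtosis of the pooled voltage distribution
#'
#' Third central moment / SD^3 and fourth central moment / SD^4 of the
#' pooled (neurons x time samples) membrane-potential distribution.
#'
#' @param trace a [voltage_trace()].
#' @param population optional population filter.
#' @param from discard samples before this time, ms.
#' @return named numeric `c(skewness, kurtosis)`.
#' @export
voltage_moments <- function(trace, population = NULL, from = 0) {
  rows <- if (is.null(population)) seq_len(nrow(trace$V))
          else which(trace$population == population)
  v <- as.numeric(trace$V[rows, trace$t >= from, drop = FALSE])
  if (length(v) < 1000) stop("need at least 1000 pooled voltage samples")
  m <- mean(v); s <- sqrt(mean((v - m)^2))
  if (s <= 0) stop("zero voltage variance")
  c(skewness = mean((v - m)^3) / s^3, kurtosis = mean((v - m)^4) / s^4)
}
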