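#' Mean inter-spike interval of the merged spike train
#'
#' All spikes of the chosen population are pooled and sorted; the mean of
#' consecutive differences is the conventional avalanche bin width (the
#' "optimal" window that places sizes and durations of different datasets
#' on comparable scales).
#'
#' @param raster a [spike_raster()].
#' @param population optional population filter.
#' @param from,to analysis window, ms; default post-discard span.
#' @return mean merged ISI, ms.
#' @export
merged_mean_isi <- function(raster, population = NULL, from = NULL, to = NULL) {
  if (is.null(from)) from <- raster$t_start + raster$discard
  if (is.null(to)) to <- raster$t_end
  keep <- raster$time >= from & raster$time < to
  if (!is.null(population))
    keep <- keep & raster$id %in% which(raster$population == population)
  tt <- sort(raster$time[keep])
  if (length(tt) < 2) stop("need at least two spikes to compute the merged ISI")
  mean(diff(tt))
}

#' Extract avalanches from a count series
#'
#' An avalanche is a maximal run of consecutive non-empty bins delimited by
#' empty bins; size is the run's total spike count and duration its bin
#' count. Runs touching the series boundary are discarded as incomplete.
#'
#' @param series a [count_series()] of integer counts.
#' @return An object of class `avalanche_set`: integer vectors `sizes` and
#'   `durations`, plus the bin width `dt`.
#' @export
extract_avalanches <- function(series) {
  x <- series$counts
  stopifnot(all(x >= 0), all(abs(x - round(x)) < 1e-9))
  occ <- x > 0
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  # drop runs touching either boundary (incomplete avalanches)
  runs <- runs[starts[runs] > 1 & ends[runs] < length(x)]
  cs <- c(0, cumsum(x))
  sizes <- cs[ends[runs] + 1] - cs[starts[runs]]
  structure(list(sizes = as.integer(round(sizes)),
                 durations = as.integer(r$lengths[runs]),
                 dt = series$dt),
            class = "avalanche_set")
}

#' @export
print.avalanche_set <- function(x, ...) {
  cat(sprintf("<avalanche_set> %d avalanches (bin %g ms), size range [%d, %d]\n",
              length(x$sizes), x$dt,
              if (length(x$sizes)) min(x$sizes) else NA,
              if (length(x$sizes)) max(x$sizes) else NA))
  invisible(x)
}

#' Normalized distance to the best-fit power law
#'
#' Histogram of the size distribution on `nbins` bins from the minimum to
#' the maximum size (logarithmically spaced by default, since the fit
#' lives in log-log coordinates; empty bins are excluded), least-squares
#' line fit of `log10 P` on `log10 S`, then
#' `D = sum_S S |P(S) - P_fit(S)| / sum_S S P(S)`: the mean absolute size
#' discrepancy per avalanche, normalized by the mean size.
#'
#' @param sizes positive integer avalanche sizes (>= 100 recommended).
#' @param nbins histogram bin count (default 80).
#' @param log_bins logarithmic (default) or linear bin spacing.
#' @return distance `D` (unitless, >= 0).
#' @export
powerlaw_distance_D <- function(sizes, nbins = 80, log_bins = TRUE) {
  stopifnot(length(sizes) >= 2, all(sizes > 0))
  lo <- min(sizes); hi <- max(sizes)
  if (hi <= lo) stop("degenerate size range")
  breaks <- if (log_bins) exp(seq(log(lo), log(hi), length.out = nbins + 1))
            else seq(lo, hi, length.out = nbins + 1)
  breaks[1] <- lo - 1e-9; breaks[nbins + 1] <- hi + 1e-9
  h <- hist(sizes, breaks = breaks, plot = FALSE)
  P <- h$counts / length(sizes) / diff(breaks)  # density per unit size
  S <- sqrt(breaks[-1] * breaks[-(nbins + 1)])  # geometric bin centers
  if (!log_bins) S <- h$mids
  keep <- P > 0
  if (sum(keep) < 3) stop("too few occupied bins for a line fit")
  co <- coef(lm(log10(P[keep]) ~ log10(S[keep])))
  Pfit <- 10^(co[1] + co[2] * log10(S[keep]))
  sum(S[keep] * abs(P[keep] - Pfit)) / sum(S[keep] * P[keep])
}

# log-likelihood of a discrete power law truncated to [xmin, xmax]
.dpl_loglik <- function(tau, x, xmin, xmax) {
  Z <- sum((xmin:xmax)^(-tau))
  -tau * sum(log(x)) - length(x) * log(Z)
}

.dpl_fit_tau <- function(x, xmin, xmax) {
  optimize(function(tau) .dpl_loglik(tau, x, xmin, xmax),
           interval = c(1.001, 6), maximum = TRUE)$maximum
}

.dpl_ks <- function(x, tau, xmin, xmax) {
  supp <- xmin:xmax
  cdf <- cumsum(supp^(-tau)); cdf <- cdf / cdf[length(cdf)]
  n <- length(x)
  ecdf_at <- cumsum(tabulate(x - xmin + 1L, nbins = length(supp))) / n
  max(abs(ecdf_at - cdf))
}

.dpl_sample <- function(n, tau, xmin, xmax) {
  supp <- xmin:xmax
  sample(supp, n, replace = TRUE, prob = supp^(-tau))
}

#' Doubly truncated discrete power-law fit with KS surrogate test
#'
#' Maximum-likelihood fit of `P(x) ~ x^-tau` on integer support
#' `[xmin, xmax]`, searching a grid of candidate truncation bounds
#' (observed unique values, subsampled to at most `max_candidates` per
#' bound). For a candidate range the p-value is the fraction of
#' `n_surrogates` synthetic datasets, drawn from the fitted truncated
#' power law at the same tail size and refitted, whose KS statistic
#' exceeds the data's. The accepted fit is the widest log-range candidate
#' with `p > 0.1` spanning at least one third of the whole observed range
#' on the log scale; if none passes, the best (smallest-KS) candidate is
#' returned flagged `accepted = FALSE`.
#'
#' @param x positive integer samples (>= 200).
#' @param n_surrogates surrogate count for the KS test (default 100).
#' @param p_threshold acceptance threshold on the p-value (default 0.1).
#' @param min_range_frac minimum fraction of the whole log range (1/3).
#' @param max_candidates truncation candidates per bound (default 50).
#' @param min_tail_n minimum samples inside a candidate range (default 100).
#' @param max_p_evals cap on candidates receiving a surrogate p-value.
#' @param seed seed for the surrogate draws.
#' @return An object of class `powerlaw_fit`: `exponent`, `xmin`, `xmax`,
#'   `ks`, `p_value`, `log_range_frac`, `n_tail`, `accepted`.
#' @export
fit_truncated_powerlaw <- function(x, n_surrogates = 100, p_threshold = 0.1,
                                   min_range_frac = 1 / 3, max_candidates = 50,
                                   min_tail_n = 100, max_p_evals = 25,
                                   seed = 1L) {
  x <- as.integer(round(x))
  if (length(x) < 200) stop("need at least 200 samples")
  if (min(x) < 1) stop("samples must be positive integers")
  u <- sort(unique(x))
  if (length(u) < 5) stop("degenerate sample range")
  whole_log <- log10(max(u) / min(u))
  if (whole_log <= 0) stop("degenerate sample range")

  pick <- function(v) if (length(v) <= max_candidates) v
    else v[unique(round(seq(1, length(v), length.out = max_candidates)))]
  lo_cands <- pick(u[u <= quantile(u, 0.5, type = 1)])
  hi_cands <- pick(u[u >= quantile(u, 0.5, type = 1)])

  cands <- list()
  for (lo in lo_cands) for (hi in hi_cands) {
    if (hi <= lo) next
    frac <- log10(hi / lo) / whole_log
    if (frac < min_range_frac) next
    n_tail <- sum(x >= lo & x <= hi)
    if (n_tail < min_tail_n) next
    cands[[length(cands) + 1]] <- list(lo = lo, hi = hi, frac = frac, n = n_tail)
  }
  if (!length(cands)) stop("no admissible truncation range")

  for (k in seq_along(cands)) {
    cc <- cands[[k]]
    xt <- x[x >= cc$lo & x <= cc$hi]
    cc$tau <- .dpl_fit_tau(xt, cc$lo, cc$hi)
    cc$ks <- .dpl_ks(xt, cc$tau, cc$lo, cc$hi)
    cands[[k]] <- cc
  }
  ord <- order(vapply(cands, `[[`, numeric(1), "frac"), decreasing = TRUE)

  p_of <- function(cc) {
    xt <- x[x >= cc$lo & x <= cc$hi]
    with_seed(as.integer(seed), {
      worse <- 0L
      for (s in seq_len(n_surrogates)) {
        xs <- .dpl_sample(length(xt), cc$tau, cc$lo, cc$hi)
        tau_s <- .dpl_fit_tau(xs, cc$lo, cc$hi)
        if (.dpl_ks(xs, tau_s, cc$lo, cc$hi) >= cc$ks) worse <- worse + 1L
      }
      worse / n_surrogates
    })
  }

  result <- function(cc, p, accepted) {
    structure(list(exponent = cc$tau, xmin = cc$lo, xmax = cc$hi,
                   ks = cc$ks, p_value = p, log_range_frac = cc$frac,
                   n_tail = cc$n, accepted = accepted),
              class = "powerlaw_fit")
  }

  for (k in head(ord, max_p_evals)) {
    p <- p_of(cands[[k]])
    if (p > p_threshold) return(result(cands[[k]], p, TRUE))
  }
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "ks"))]]
  p_best <- p_of(best)
  result(best, p_best, p_best > p_threshold)
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> exponent %.3f on [%d, %d] (%.0f%% of log range), KS %.4f, p = %.2f, %s\n",
              x$exponent, x$xmin, x$xmax, 100 * x$log_range_frac, x$ks,
              x$p_value, if (x$accepted) "accepted" else "not accepted"))
  invisible(x)
}

#' Size-versus-duration scaling exponent
#'
#' Weighted least-squares slope of `log10` mean size against `log10`
#' duration, over avalanches whose duration falls in `duration_range`
#' (conventionally the truncated range accepted for the duration
#' exponent); weights are the avalanche counts per distinct duration.
#'
#' @param avs an [extract_avalanches()] result.
#' @param duration_range `c(lo, hi)` in bins.
#' @return the `1/(sigma nu z)` estimate (slope).
#' @export
size_duration_exponent <- function(avs, duration_range = range(avs$durations)) {
  keep <- avs$durations >= duration_range[1] & avs$durations <= duration_range[2]
  d <- avs$durations[keep]; s <- avs$sizes[keep]
  if (length(unique(d)) < 5) stop("need at least 5 distinct durations in range")
  mean_s <- tapply(s, d, mean)
  w <- tapply(s, d, length)
  td <- as.numeric(names(mean_s))
  fit <- lm(log10(mean_s) ~ log10(td), weights = as.numeric(w))
  unname(coef(fit)[2])
}

#' Crackling-noise scaling relation
#'
#' Compares the exponent combination `(alpha - 1) / (tau - 1)` predicted
#' from the size and duration exponents with the independently fitted
#' size-duration exponent `1/(sigma nu z)`; at criticality the two agree.
#'
#' @param tau avalanche size exponent (> 1).
#' @param alpha avalanche duration exponent.
#' @param one_over_snz fitted size-duration exponent.
#' @return list with `predicted` = (alpha-1)/(tau-1), `one_over_snz`,
#'   `error` = absolute difference.
#' @export
scaling_relation <- function(tau, alpha, one_over_snz) {
  if (abs(tau - 1) < 1e-12) stop("tau = 1 makes the relation undefined")
  pred <- (alpha - 1) / (tau - 1)
  list(tau = tau, alpha = alpha, predicted = pred,
       one_over_snz = one_over_snz, error = abs(pred - one_over_snz))
}

# Sparse equivalent of spike_count_series + extract_avalanches for very fine
# bins (the merged-ISI bin makes the dense series enormous): consecutive
# spikes belong to one avalanche iff their bin indices differ by at most 1;
# duration = bins spanned, size = spikes contained. Boundary-touching
# avalanches are dropped, as in the dense path.
extract_avalanches_sparse <- function(times, dt, from, to) {
  nbin <- floor((to - from) / dt)
  tt <- sort(times[times >= from & times < from + nbin * dt])
  b <- pmin(floor((tt - from) / dt), nbin - 1)
  new_av <- c(TRUE, diff(b) > 1)
  grp <- cumsum(new_av)
  sizes <- tabulate(grp)
  first_bin <- b[new_av]
  last_bin <- c(b[which(new_av) - 1 + sizes])
  durations <- last_bin - first_bin + 1
  keep <- first_bin > 0 & last_bin < nbin - 1
  structure(list(sizes = as.integer(sizes[keep]),
                 durations = as.integer(durations[keep]), dt = dt),
            class = "avalanche_set")
}

#' Full avalanche criticality pipeline
#'
#' Bin width set to the merged mean ISI of the chosen population; count
#' series; avalanche extraction; distance D; doubly truncated power-law
#' fits for sizes and durations; size-duration exponent over the duration
#' fit's truncated range; scaling-relation check.
#'
#' @param raster a [spike_raster()].
#' @param population population analyzed (default "E").
#' @param seed seed passed to the KS surrogate draws.
#' @param ... further arguments to [fit_truncated_powerlaw()].
#' @return An object of class `avalanche_report`: `dt_ms`, `avalanches`,
#'   `distance_D`, `size_fit`, `duration_fit`, `one_over_snz`, `scaling`.
#' @export
avalanche_pipeline <- function(raster, population = "E", seed = 1L, ...) {
  dt <- merged_mean_isi(raster, population = population)
  from <- raster$t_start + raster$discard
  ids <- which(raster$population == population)
  keep <- raster$id %in% ids
  avs <- extract_avalanches_sparse(raster$time[keep], dt, from, raster$t_end)
  if (length(avs$sizes) < 200)
    stop("too few avalanches for the criticality battery")
  D <- powerlaw_distance_D(avs$sizes)
  size_fit <- fit_truncated_powerlaw(avs$sizes, seed = seed, ...)
  duration_fit <- fit_truncated_powerlaw(avs$durations, seed = seed + 1L, ...)
  snz <- tryCatch(
    size_duration_exponent(avs, c(duration_fit$xmin, duration_fit$xmax)),
    error = function(e) NA_real_)
  sc <- if (is.finite(snz))
    scaling_relation(size_fit$exponent, duration_fit$exponent, snz) else NULL
  structure(list(dt_ms = dt, avalanches = avs, distance_D = D,
                 size_fit = size_fit, duration_fit = duration_fit,
                 one_over_snz = snz, scaling = sc),
            class = "avalanche_report")
}

#' @export
print.avalanche_report <- function(x, ...) {
  cat(sprintf("<avalanche_report> bin %.3f ms, %d avalanches, D = %.4f\n",
              x$dt_ms, length(x$avalanches$sizes), x$distance_D))
  cat("  size:     "); print(x$size_fit)
  cat("  duration: "); print(x$duration_fit)
  if (!is.null(x$scaling))
    cat(sprintf("  1/(sigma nu z) = %.3f vs (alpha-1)/(tau-1) = %.3f (error %.3f)\n",
                x$scaling$one_over_snz, x$scaling$predicted, x$scaling$error))
  invisible(x)
}
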