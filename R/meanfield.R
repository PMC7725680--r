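#' Mean-field parameterization
#'
#' Macroscopic parameters of the six-dimensional field equations. Rates are
#' per-ms internally; `Q_o` is accepted in Hz. The effective voltage
#' standard deviations `sigma_E`, `sigma_I` close the model: they are
#' calibrated once from an asynchronous-state network run (see
#' [estimate_sigma()]) or from the closed-form diffusion value
#' ([sigma_diffusion()]).
#'
#' @param config a [network_config()] supplying sizes, weights and time
#'   constants.
#' @param sigma_E,sigma_I effective voltage SDs, mV (> 0).
#' @return An object of class `field_params`.
#' @export
field_params <- function(config, sigma_E, sigma_I) {
  stopifnot(sigma_E > 0, sigma_I > 0)
  p <- list(sigma_E = sigma_E, sigma_I = sigma_I,
            n_E = config$p * config$N_E, n_I = config$p * config$N_I,
            n_o = config$n_o, Q_o = config$Q_o / 1000,
            J_EO = config$J_EO, J_IO = config$J_IO,
            J_EE = config$J_EE, J_IE = config$J_IE,
            J_EI = config$J_EI, J_II = config$J_II,
            tau_m_E = config$tau_m_E, tau_m_I = config$tau_m_I,
            tau_r = config$tau_r, tau_d_E = config$tau_d_E,
            tau_d_I = config$tau_d_I,
            N_E = config$N_E, N_I = config$N_I,
            V_th = config$V_th,
            V_rest_E = config$V_rest_E, V_rest_I = config$V_rest_I)
  class(p) <- "field_params"
  p
}

#' Voltage-to-rate transfer function
#'
#' Logistic closure of the population firing rate: the proportion of neurons
#' above threshold under a Gaussian voltage distribution with mean `V` and
#' SD `sigma`, with the error function approximated by a tanh of matched
#' slope, giving `Q = 1 / (1 + exp((V_th - V) * pi / (sqrt(3) * sigma)))`
#' in units of per ms.
#'
#' @param V mean membrane potential, mV (vectorized).
#' @param sigma effective voltage SD, mV (> 0).
#' @param V_th spiking threshold, mV.
#' @return firing rate per ms, in (0, 1).
#' @export
transfer_rate <- function(V, sigma, V_th = -50) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  1 / (1 + exp((V_th - V) * pi / (sqrt(3) * sigma)))
}

# derivative dQ/dV of transfer_rate, per ms per mV
transfer_rate_deriv <- function(V, sigma, V_th = -50) {
  z <- (V_th - V) * pi / (sqrt(3) * sigma)
  pi * exp(z) / (sqrt(3) * sigma * (1 + exp(z))^2)
}

#' Calibrate the effective voltage SD from steady-state observables
#'
#' Algebraic inverse of [transfer_rate()]: given the steady-state mean
#' voltage and mean rate of one population in the asynchronous state,
#' returns the `sigma` that makes the transfer function reproduce that rate,
#' `sigma = (V_th - V_ss) * pi / (sqrt(3) * log(1/Q_ss - 1))`.
#'
#' @param V_ss steady-state mean voltage, mV.
#' @param Q_ss steady-state rate per ms, in (0, 1), not 0.5.
#' @param V_th spiking threshold, mV.
#' @return sigma in mV (> 0).
#' @export
estimate_sigma <- function(V_ss, Q_ss, V_th = -50) {
  if (any(Q_ss <= 0) || any(Q_ss >= 1)) stop("Q_ss must lie in (0, 1) per ms")
  l <- log(1 / Q_ss - 1)
  if (any(abs(l) < 1e-12)) stop("Q_ss = 0.5 makes the inversion degenerate")
  sigma <- (V_th - V_ss) * pi / (sqrt(3) * l)
  if (any(sigma <= 0)) stop("sign mismatch between V_th - V_ss and Q_ss yields sigma <= 0")
  sigma
}

#' Closed-form diffusion value of the voltage SD
#'
#' Stationary SD of an Ornstein-Uhlenbeck leaky integrator driven by white
#' noise of intensity `J^2 n_o Q_o`: `sigma = J * sqrt(n_o * Q_o * tau_m / 2)`.
#' Set `half_factor = FALSE` to drop the /2 (the variance of the unlagged
#' shot-noise input rather than of the filtered voltage).
#'
#' @param J_ao external weight, mV.
#' @param n_o external source count.
#' @param Q_o external rate per source; interpreted in Hz if `hz = TRUE`
#'   (default), per ms otherwise.
#' @param tau_m membrane constant, ms.
#' @param half_factor include the OU stationary 1/2 (default TRUE).
#' @param hz whether `Q_o` is in Hz.
#' @return sigma in mV.
#' @export
sigma_diffusion <- function(J_ao, n_o, Q_o, tau_m, half_factor = TRUE, hz = TRUE) {
  stopifnot(J_ao > 0, n_o > 0, Q_o > 0, tau_m > 0)
  q <- if (hz) Q_o / 1000 else Q_o
  J_ao * sqrt(n_o * q * tau_m / (if (half_factor) 2 else 1))
}

#' Check the balanced condition on the weight matrix
#'
#' The large-N balanced linear system has a unique positive rate solution
#' iff the ratio sequence `{J_EO/J_IO, J_EI/J_II, J_EE/J_IE}` is strictly
#' monotone (ascending or descending).
#'
#' @param J_EO,J_IO,J_EE,J_IE,J_EI,J_II synaptic weights, mV (signs as in
#'   [network_config()]).
#' @return logical.
#' @export
check_balanced_condition <- function(J_EO, J_IO, J_EE, J_IE, J_EI, J_II) {
  if (any(c(J_IO, J_II, J_IE) == 0)) stop("zero denominator in balance ratios")
  r <- c(J_EO / J_IO, J_EI / J_II, J_EE / J_IE)
  all(diff(r) > 0) || all(diff(r) < 0)
}

#' Balanced-limit steady rates
#'
#' Solves the linear system `J_aO n_o Q_o + J_aE n_E Q_E + J_aI n_I Q_I = 0`
#' for both populations (the large-N limit in which the leak is negligible).
#'
#' @param params a [field_params()] (sigma values unused here).
#' @return named numeric `c(Q_E, Q_I)` in Hz.
#' @export
solve_balanced_rates <- function(params) {
  A <- matrix(c(params$J_EE * params$n_E, params$J_EI * params$n_I,
                params$J_IE * params$n_E, params$J_II * params$n_I),
              2, 2, byrow = TRUE)
  b <- -c(params$J_EO, params$J_IO) * params$n_o * params$Q_o
  if (abs(det(A)) < 1e-12 * max(abs(A))^2) stop("singular balanced system")
  q <- solve(A, b)
  if (any(q < -1e-12)) stop("balanced system has no positive solution")
  setNames(pmax(q, 0) * 1000, c("Q_E", "Q_I"))
}

# 6-D field vector: X = (V_E, V_I, Phi_E, dPhi_E, Phi_I, dPhi_I)
field_drift <- function(X, p) {
  Q_E <- transfer_rate(X[1], p$sigma_E, p$V_th)
  Q_I <- transfer_rate(X[2], p$sigma_I, p$V_th)
  c((p$V_rest_E - X[1]) / p$tau_m_E + p$J_EO * p$n_o * p$Q_o +
      p$J_EE * X[3] + p$J_EI * X[5],
    (p$V_rest_I - X[2]) / p$tau_m_I + p$J_IO * p$n_o * p$Q_o +
      p$J_IE * X[3] + p$J_II * X[5],
    X[4],
    (p$n_E * Q_E - X[3] - (p$tau_d_E + p$tau_r) * X[4]) / (p$tau_d_E * p$tau_r),
    X[6],
    (p$n_I * Q_I - X[5] - (p$tau_d_I + p$tau_r) * X[6]) / (p$tau_d_I * p$tau_r))
}

#' Deterministic fixed point of the field equations
#'
#' Solves `f_a(V_a) + J_aO n_o Q_o + J_aE n_E Q_E(V_E) + J_aI n_I Q_I(V_I)
#' = 0` for both populations by damped Newton iteration with multistart
#' (from the resting potentials and from the balanced-limit rates mapped
#' through the inverse transfer function). The fixed point does not depend
#' on the synaptic rise/decay times.
#'
#' @param params a [field_params()].
#' @param tol residual tolerance (mV/ms), default 1e-10.
#' @return An object of class `field_fixed_point`: `V_E`, `V_I` (mV),
#'   `Q_E`, `Q_I` (Hz), `residual`, `eigenvalues` (6 complex), `stable`.
#' @export
solve_fixed_point <- function(params, tol = 1e-10) {
  p <- params
  g <- function(v) {
    Q_E <- transfer_rate(v[1], p$sigma_E, p$V_th)
    Q_I <- transfer_rate(v[2], p$sigma_I, p$V_th)
    c((p$V_rest_E - v[1]) / p$tau_m_E + p$J_EO * p$n_o * p$Q_o +
        p$J_EE * p$n_E * Q_E + p$J_EI * p$n_I * Q_I,
      (p$V_rest_I - v[2]) / p$tau_m_I + p$J_IO * p$n_o * p$Q_o +
        p$J_IE * p$n_E * Q_E + p$J_II * p$n_I * Q_I)
  }
  gjac <- function(v) {
    dQE <- transfer_rate_deriv(v[1], p$sigma_E, p$V_th)
    dQI <- transfer_rate_deriv(v[2], p$sigma_I, p$V_th)
    matrix(c(-1 / p$tau_m_E + p$J_EE * p$n_E * dQE, p$J_EI * p$n_I * dQI,
             p$J_IE * p$n_E * dQE, -1 / p$tau_m_I + p$J_II * p$n_I * dQI),
           2, 2, byrow = TRUE)
  }
  inv_transfer <- function(Q, sigma) p$V_th - log(1 / Q - 1) * sqrt(3) * sigma / pi
  starts <- list(c(p$V_rest_E, p$V_rest_I))
  bal <- tryCatch(solve_balanced_rates(p) / 1000, error = function(e) NULL)
  if (!is.null(bal) && all(bal > 0 & bal < 1)) {
    starts <- c(starts, list(c(inv_transfer(bal[1], p$sigma_E),
                               inv_transfer(bal[2], p$sigma_I))))
  }
  starts <- c(starts, list(c(p$V_th - 3, p$V_th - 3), c(p$V_th - 8, p$V_th - 8)))

  best <- NULL
  for (v in starts) {
    for (it in 1:200) {
      r <- g(v)
      if (max(abs(r)) < tol) break
      step <- tryCatch(solve(gjac(v), -r), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        vn <- v + lam * step
        if (max(abs(g(vn))) < max(abs(r)) || lam < 1e-6) break
        lam <- lam / 2
      }
      v <- v + lam * step
    }
    r <- max(abs(g(v)))
    if (is.null(best) || r < best$r) best <- list(v = v, r = r)
    if (best$r < tol) break
  }
  if (best$r >= tol)
    stop(sprintf("fixed-point solver failed to converge (residual %.3g)", best$r))
  v <- best$v
  fp <- structure(list(V_E = v[1], V_I = v[2],
                       Q_E = 1000 * transfer_rate(v[1], p$sigma_E, p$V_th),
                       Q_I = 1000 * transfer_rate(v[2], p$sigma_I, p$V_th),
                       residual = best$r),
                  class = "field_fixed_point")
  ev <- eigen(field_jacobian(p, fp), only.values = TRUE)$values
  fp$eigenvalues <- ev
  fp$stable <- all(Re(ev) < 0)
  fp
}

#' @export
print.field_fixed_point <- function(x, ...) {
  cat(sprintf("<field_fixed_point> V*=(%.3f, %.3f) mV, Q*=(%.3f, %.3f) Hz, %s (max Re lambda = %.4g)\n",
              x$V_E, x$V_I, x$Q_E, x$Q_I,
              if (x$stable) "stable" else "unstable", max(Re(x$eigenvalues))))
  invisible(x)
}

#' Jacobian of the six-dimensional field system at a fixed point
#'
#' State order `(V_E, V_I, Phi_E, dPhi_E, Phi_I, dPhi_I)`; rows 3 and 5 are
#' pure shift rows. Transfer-function slopes are evaluated analytically at
#' the fixed-point voltages.
#'
#' @param params a [field_params()].
#' @param fp a [solve_fixed_point()] result (or list with `V_E`, `V_I`).
#' @return 6x6 numeric matrix (units 1/ms).
#' @export
field_jacobian <- function(params, fp) {
  p <- params
  dQE <- transfer_rate_deriv(fp$V_E, p$sigma_E, p$V_th)
  dQI <- transfer_rate_deriv(fp$V_I, p$sigma_I, p$V_th)
  J <- matrix(0, 6, 6)
  J[1, ] <- c(-1 / p$tau_m_E, 0, p$J_EE, 0, p$J_EI, 0)
  J[2, ] <- c(0, -1 / p$tau_m_I, p$J_IE, 0, p$J_II, 0)
  J[3, 4] <- 1
  J[4, ] <- c(p$n_E * dQE / (p$tau_d_E * p$tau_r), 0,
              -1 / (p$tau_d_E * p$tau_r), -(1 / p$tau_d_E + 1 / p$tau_r), 0, 0)
  J[5, 6] <- 1
  J[6, ] <- c(0, p$n_I * dQI / (p$tau_d_I * p$tau_r), 0, 0,
              -1 / (p$tau_d_I * p$tau_r), -(1 / p$tau_d_I + 1 / p$tau_r))
  J
}

# dominant eigenpair by eigenvector-overlap tracking (avoids branch swaps)
dominant_pair_from <- function(e, prev_vec = NULL) {
  idx <- which(Im(e$values) >= 0)
  if (!is.null(prev_vec)) {
    ov <- vapply(idx, function(k) Mod(sum(Conj(e$vectors[, k]) * prev_vec)),
                 numeric(1))
    k <- idx[which.max(ov)]
  } else {
    k <- idx[which.max(Re(e$values[idx]))]
  }
  list(value = e$values[k], vector = e$vectors[, k] / sqrt(sum(Mod(e$vectors[, k])^2)))
}

#' Hopf-bifurcation scan over the inhibitory decay time
#'
#' For each `tau_d_I` on the grid, solves the fixed point (which is
#' invariant to the decay times) and computes the 6x6 Jacobian spectrum.
#' Stability is decided by the maximal real part over all eigenvalues; the
#' critical decay time is located by bisection on its sign change. The
#' reported eigenvalue curves follow the oscillatory branch continuously by
#' eigenvector-overlap tracking anchored just above the crossing (where
#' that branch is dominant), so branch swaps at small `tau_d_I` do not
#' corrupt the frequency curve.
#'
#' @param params a [field_params()] (its `tau_d_I` entry is overridden).
#' @param tau_dI_grid ascending grid of inhibitory decay times, ms.
#' @param bisect_tol bisection tolerance on tau_d_I, ms.
#' @return An object of class `hopf_scan`: `tau_dI_grid`, `re_lambda` and
#'   `freq_hz` (tracked oscillatory branch, 1/ms and Hz), `re_max`
#'   (stability curve, 1/ms), `tau_c` (critical decay time, ms, or `NA`
#'   when no sign change: `bifurcation = FALSE`), `freq_at_tau_c` (Hz),
#'   `fixed_point`.
#' @export
hopf_scan <- function(params, tau_dI_grid = seq(1, 4.5, by = 0.05),
                      bisect_tol = 1e-4) {
  stopifnot(!is.unsorted(tau_dI_grid))
  fp <- solve_fixed_point(params)
  jac_at <- function(tau) {
    p <- params; p$tau_d_I <- tau
    field_jacobian(p, fp)
  }
  n <- length(tau_dI_grid)
  eigs <- lapply(tau_dI_grid, function(tau) eigen(jac_at(tau)))
  # stability is decided by the maximal real part over all eigenvalues
  re_max <- vapply(eigs, function(e) max(Re(e$values)), numeric(1))
  cross <- which(re_max[-1] > 0 & re_max[-n] <= 0)
  tau_c <- NA_real_; freq_c <- NA_real_
  if (length(cross)) {
    lo <- tau_dI_grid[cross[1]]; hi <- tau_dI_grid[cross[1] + 1]
    while (hi - lo > bisect_tol) {
      mid <- (lo + hi) / 2
      if (max(Re(eigen(jac_at(mid), only.values = TRUE)$values)) > 0)
        hi <- mid else lo <- mid
    }
    tau_c <- (lo + hi) / 2
    ec <- eigen(jac_at(tau_c), only.values = TRUE)$values
    freq_c <- abs(Im(ec[which.max(Re(ec))])) / (2 * pi) * 1000
  }
  # continuous curves of the oscillatory (Hopf) branch: anchor the
  # eigenvector-overlap tracker just above the crossing, where that branch
  # is dominant, and sweep outward in both directions
  anchor <- if (length(cross)) cross[1] + 1L else 1L
  re <- numeric(n); im <- numeric(n)
  d <- dominant_pair_from(eigs[[anchor]], NULL)
  re[anchor] <- Re(d$value); im[anchor] <- abs(Im(d$value))
  prev <- d$vector
  for (k in seq(anchor + 1L, length.out = max(0L, n - anchor))) {
    d <- dominant_pair_from(eigs[[k]], prev)
    re[k] <- Re(d$value); im[k] <- abs(Im(d$value)); prev <- d$vector
  }
  prev <- dominant_pair_from(eigs[[anchor]], NULL)$vector
  for (k in rev(seq_len(anchor - 1L))) {
    d <- dominant_pair_from(eigs[[k]], prev)
    re[k] <- Re(d$value); im[k] <- abs(Im(d$value)); prev <- d$vector
  }
  structure(list(tau_dI_grid = tau_dI_grid, re_lambda = re,
                 re_max = re_max,
                 freq_hz = im / (2 * pi) * 1000,
                 bifurcation = length(cross) > 0,
                 tau_c = tau_c, freq_at_tau_c = freq_c, fixed_point = fp),
            class = "hopf_scan")
}

#' @export
print.hopf_scan <- function(x, ...) {
  if (x$bifurcation) {
    cat(sprintf("<hopf_scan> Hopf crossing at tau_d_I = %.3f ms (frequency %.1f Hz)\n",
                x$tau_c, x$freq_at_tau_c))
  } else {
    cat("<hopf_scan> no eigenvalue crossing on the grid\n")
  }
  invisible(x)
}

#' Integrate the stochastic field equations
#'
#' Euler-Maruyama on the six-dimensional system; the finite-size noise term
#' `J_aO sqrt(n_o Q_o / N_a) xi_a(t)` enters only the two voltage rows.
#'
#' @param params a [field_params()].
#' @param duration total time, ms.
#' @param dt step, ms (<= 0.05).
#' @param noise logical; include the demographic noise terms.
#' @param seed integer seed.
#' @param X0 optional initial state (defaults to the fixed point, slightly
#'   perturbed when `noise = FALSE` starts would be stationary).
#' @param sample_every_ms output sampling interval, ms.
#' @return list with `t` (ms), `V_E`, `V_I` (mV), `Q_E`, `Q_I` (Hz),
#'   `Phi_E`, `Phi_I`.
#' @export
integrate_field <- function(params, duration = 2000, dt = 0.01, noise = TRUE,
                            seed = 1L, X0 = NULL, sample_every_ms = 1) {
  stopifnot(dt <= 0.05)
  p <- params
  if (is.null(X0)) {
    fp <- solve_fixed_point(p)
    X0 <- c(fp$V_E, fp$V_I, p$n_E * fp$Q_E / 1000, 0, p$n_I * fp$Q_I / 1000, 0)
    if (!noise) X0[1] <- X0[1] + 0.5
  }
  nsteps <- round(duration / dt)
  every <- max(1L, round(sample_every_ms / dt))
  n_out <- nsteps %/% every
  amp_E <- p$J_EO * sqrt(p$n_o * p$Q_o / p$N_E) * sqrt(dt)
  amp_I <- p$J_IO * sqrt(p$n_o * p$Q_o / p$N_I) * sqrt(dt)
  with_seed(as.integer(seed), {
    X <- X0
    out <- matrix(NA_real_, n_out, 6)
    tt <- numeric(n_out); k <- 0L
    noise_E <- if (noise) rnorm(nsteps) * amp_E else numeric(nsteps)
    noise_I <- if (noise) rnorm(nsteps) * amp_I else numeric(nsteps)
    for (s in seq_len(nsteps)) {
      X <- X + dt * field_drift(X, p)
      X[1] <- X[1] + noise_E[s]
      X[2] <- X[2] + noise_I[s]
      if (any(abs(X[1:2]) > 1e3))
        stop(sprintf("field integration blew up; reduce dt (currently %g ms)", dt))
      if (s %% every == 0) {
        k <- k + 1L
        out[k, ] <- X; tt[k] <- s * dt
      }
    }
    list(t = tt, V_E = out[, 1], V_I = out[, 2],
         Q_E = 1000 * transfer_rate(out[, 1], p$sigma_E, p$V_th),
         Q_I = 1000 * transfer_rate(out[, 2], p$sigma_I, p$V_th),
         Phi_E = out[, 3], Phi_I = out[, 5])
  })
}

#' Population Fano factor predicted by the field model
#'
#' Converts the field rate `Q_E(t)` to deterministic population counts
#' `N_E * Q_E * dt` per 1-ms bin, aggregates them into windows, and returns
#' var/mean. No extra Poisson sampling is applied.
#'
#' @param params a [field_params()].
#' @param window counting window, ms (default 50).
#' @param duration integration time, ms.
#' @param seed integer seed.
#' @param discard initial transient excluded, ms.
#' @param noise include the demographic noise (default TRUE).
#' @return Fano factor (unitless).
#' @export
field_population_ff <- function(params, window = 50, duration = 10000,
                                seed = 1L, discard = 500, noise = TRUE) {
  stopifnot(window >= 1)
  tr <- integrate_field(params, duration = duration, dt = 0.01, noise = noise,
                        seed = seed, sample_every_ms = 1)
  keep <- tr$t > discard
  counts_1ms <- params$N_E * (tr$Q_E[keep] / 1000)  # per 1-ms sample
  k <- floor(length(counts_1ms) / window)
  w <- colSums(matrix(counts_1ms[seq_len(k * window)], nrow = window))
  if (mean(w) <= 0) stop("zero mean count; Fano factor undefined")
  var(w) / mean(w)
}
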