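test_that("transfer_rate is a logistic in V with the stated slope and limits", {
  expect_equal(transfer_rate(-50, 4), 0.5)
  expect_equal(transfer_rate(-70, 4),
               1 / (1 + exp(20 * pi / (4 * sqrt(3)))))
  v <- seq(-90, -10, by = 0.5)
  q <- transfer_rate(v, 3)
  expect_true(all(diff(q) > 0))
  expect_true(all(q > 0 & q < 1))
  expect_error(transfer_rate(-60, -1), "sigma")
})

test_that("estimate_sigma inverts transfer_rate to machine precision", {
  for (vss in c(-68, -60, -52)) {
    for (qss in c(0.001, 0.02, 0.3)) {
      s <- estimate_sigma(vss, qss)
      expect_equal(transfer_rate(vss, s), qss, tolerance = 1e-12)
    }
  }
  expect_equal(estimate_sigma(-60, 0.005),
               10 * pi / (sqrt(3) * log(199)), tolerance = 1e-12)
  expect_error(estimate_sigma(-50, 0.5), "degenerate")
  expect_error(estimate_sigma(-40, 0.005), "sigma")
})

test_that("sigma_diffusion matches the OU closed form and an OU simulation", {
  expect_equal(sigma_diffusion(0.45, 1600, 5, 20), 0.45 * sqrt(80))
  expect_equal(sigma_diffusion(0.9, 1600, 5, 20), 2 * sigma_diffusion(0.45, 1600, 5, 20))
  expect_equal(sigma_diffusion(0.45, 1600, 20, 20), 2 * sigma_diffusion(0.45, 1600, 5, 20))
  expect_equal(sigma_diffusion(0.45, 1600, 5, 20, half_factor = FALSE),
               sqrt(2) * sigma_diffusion(0.45, 1600, 5, 20))
  # Euler-Maruyama OU oracle: dV = -V/tau dt + J sqrt(n Q) dW
  withr::with_seed(4, {
    tau <- 20; J <- 0.45; nq <- 1600 * 0.005
    dt <- 0.01; n <- 4e6
    v <- numeric(1); out <- numeric(n)
    noise <- rnorm(n, sd = J * sqrt(nq * dt))
    for (i in seq_len(n)) {
      v <- v - v / tau * dt + noise[i]
      out[i] <- v
    }
    expect_equal(sd(out[-(1:5e4)]), sigma_diffusion(J, 1600, 5, tau),
                 tolerance = 0.02)
  })
})

test_that("the balanced condition and linear solve reproduce the printed rates", {
  expect_true(check_balanced_condition(0.45, 0.72, 0.36, 0.72, -0.81, -1.44))
  expect_false(check_balanced_condition(0.45, 0.72, 0.81, 0.72, -0.36, -1.44))
  expect_false(check_balanced_condition(0.5, 1, 0.5, 1, -0.5, -1))
  p <- default_field_params()
  expect_equal(solve_balanced_rates(p), c(Q_E = 5, Q_I = 20))
  p0 <- default_field_params(Q_o = 1e-12)
  expect_equal(unname(solve_balanced_rates(p0)), c(0, 0), tolerance = 1e-9)
  p2 <- default_field_params(Q_o = 10)
  expect_equal(solve_balanced_rates(p2), 2 * solve_balanced_rates(p))
})

test_that("the fixed point meets its residual contract and is invariant to decay times", {
  p <- default_field_params(sigma_E = 7.5, sigma_I = 8.3)
  fp <- solve_fixed_point(p)
  expect_lt(fp$residual, 1e-10)
  expect_true(fp$Q_E / 1000 > 0 && fp$Q_E / 1000 < 1)
  for (td in c(1, 3, 4.5)) {
    p2 <- p; p2$tau_d_I <- td
    fp2 <- solve_fixed_point(p2)
    expect_equal(fp2$V_E, fp$V_E, tolerance = 1e-9)
    expect_equal(fp2$Q_I, fp$Q_I, tolerance = 1e-9)
  }
})

test_that("fixed-point rates approach the balanced-limit solution as coupling grows", {
  # rescale weights upward at fixed sigma: the leak term becomes negligible
  p <- default_field_params(sigma_E = 6, sigma_I = 6)
  bal <- solve_balanced_rates(p)
  err <- vapply(c(1, 4, 16), function(s) {
    ps <- p
    for (w in c("J_EO", "J_IO", "J_EE", "J_IE", "J_EI", "J_II"))
      ps[[w]] <- ps[[w]] * s
    fp <- solve_fixed_point(ps)
    abs(fp$Q_E - bal["Q_E"]) / bal["Q_E"]
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.05)
})

test_that("the analytic Jacobian has the printed structure and matches finite differences", {
  p <- default_field_params(sigma_E = 7.5, sigma_I = 8.3, tau_d_I = 3)
  fp <- solve_fixed_point(p)
  J <- field_jacobian(p, fp)
  expect_equal(J[3, ], c(0, 0, 0, 1, 0, 0))
  expect_equal(J[5, ], c(0, 0, 0, 0, 0, 1))
  expect_equal(J[1, c(2, 4, 6)], c(0, 0, 0))
  # central finite differences of the implemented vector field
  X0 <- c(fp$V_E, fp$V_I, p$n_E * fp$Q_E / 1000, 0, p$n_I * fp$Q_I / 1000, 0)
  drift <- function(X) eicrit:::field_drift(X, p)
  h <- 1e-6
  Jfd <- sapply(seq_len(6), function(j) {
    e <- numeric(6); e[j] <- h
    (drift(X0 + e) - drift(X0 - e)) / (2 * h)
  })
  expect_equal(J, Jfd, tolerance = 1e-6)
})

test_that("the fixed point is a stable focus for fast inhibition", {
  p <- default_field_params(sigma_E = 7.5, sigma_I = 8.3, tau_d_I = 1)
  fp <- solve_fixed_point(p)
  expect_true(fp$stable)
  dom <- fp$eigenvalues[which.max(Re(fp$eigenvalues))]
  expect_gt(abs(Im(dom)), 0)
})

test_that("hopf_scan finds a crossing with continuous frequency tracking", {
  p <- default_field_params(sigma_E = 7.5, sigma_I = 8.3)
  hs <- hopf_scan(p, seq(1, 4.5, by = 0.05))
  expect_true(hs$bifurcation)
  expect_gt(hs$tau_c, 1)
  expect_lt(hs$tau_c, 4.5)
  expect_gt(hs$freq_at_tau_c, 20)
  # frequency branch is continuous (no branch jumps)
  expect_lt(max(abs(diff(hs$freq_hz))), 0.15 * max(hs$freq_hz))
  # instantaneous synapse limit: the 2-D reduced system has no Hopf crossing
  p2 <- p; p2$tau_r <- 1e-4; p2$tau_d_E <- 2e-4; p2$tau_d_I <- 2e-4
  # eigenvalues of the voltage sub-system with instantaneous filters
  fp2 <- solve_fixed_point(p2)
  dQE <- eicrit:::transfer_rate_deriv(fp2$V_E, p$sigma_E, p$V_th)
  dQI <- eicrit:::transfer_rate_deriv(fp2$V_I, p$sigma_I, p$V_th)
  A2 <- matrix(c(-1 / p$tau_m_E + p$J_EE * p$n_E * dQE, p$J_EI * p$n_I * dQI,
                 p$J_IE * p$n_E * dQE, -1 / p$tau_m_I + p$J_II * p$n_I * dQI),
               2, 2, byrow = TRUE)
  expect_true(all(Re(eigen(A2)$values) < 0))
})

test_that("the noiseless field converges below and oscillates above the bifurcation", {
  p <- default_field_params(sigma_E = 7.5, sigma_I = 8.3)
  hs <- hopf_scan(p, seq(1, 4.5, by = 0.1))
  p_lo <- p; p_lo$tau_d_I <- hs$tau_c - 0.8
  tr <- integrate_field(p_lo, duration = 3000, dt = 0.02, noise = FALSE, seed = 2)
  late <- tr$Q_E[tr$t > 2500]
  expect_lt(sd(late), 1e-4 * mean(late))
  amp_of <- function(tau) {
    ph <- p; ph$tau_d_I <- tau
    trh <- integrate_field(ph, duration = 4000, dt = 0.02, noise = FALSE, seed = 2)
    lateh <- trh$Q_E[trh$t > 3000]
    (max(lateh) - min(lateh)) / 2
  }
  amps <- vapply(hs$tau_c + c(0.1, 0.2, 0.4), amp_of, numeric(1))
  expect_true(all(diff(amps) > 0))
  # supercritical normal form: amplitude ~ sqrt(tau - tau_c)
  ratio <- amps[3] / amps[1]
  expect_equal(ratio, 2, tolerance = 0.5)
})

test_that("the field-model population Fano factor rises across the bifurcation", {
  p <- default_field_params(sigma_E = 7.5, sigma_I = 8.3)
  p1 <- p; p1$tau_d_I <- 1
  p4 <- p; p4$tau_d_I <- 4
  # deterministic equilibrated counts have (near) zero Fano factor
  ff_det <- field_population_ff(p1, duration = 4000, noise = FALSE, seed = 5)
  expect_lt(ff_det, 1e-6)
  ff1 <- field_population_ff(p1, duration = 6000, seed = 5)
  ff4 <- field_population_ff(p4, duration = 6000, seed = 5)
  expect_gt(ff4, ff1)
})
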