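test_that("connectivity has the right density, no self-edges, and is reproducible", {
  cfg <- network_config(N = 5, frac_E = 0.8, p = 1, Q_o = 1)
  conn <- build_connectivity(cfg, seed = 1)
  expect_equal(length(conn$targets0), 5 * 4)
  expect_equal(unname(in_degrees(conn, "E") + in_degrees(conn, "I")), rep(4L, 5))
  pre <- rep.int(seq_len(5), diff(conn$offsets))
  expect_true(all(conn$targets0 + 1L != pre))

  cfg2 <- network_config(N = 400, p = 0.2, Q_o = 1)
  c1 <- build_connectivity(cfg2, seed = 9)
  c2 <- build_connectivity(cfg2, seed = 9)
  expect_identical(c1$targets0, c2$targets0)
  # binomial moments: mean E in-degree p * N_E within 3 binomial SEs of the mean
  degE <- in_degrees(c1, "E")
  n_E <- cfg2$N_E
  expect_lt(abs(mean(degE) - 0.2 * n_E),
            3 * sqrt(n_E * 0.2 * 0.8 / cfg2$N))
})

test_that("invalid configurations are rejected", {
  expect_error(network_config(p = 0), "density")
  expect_error(network_config(J_EI = 0.5), "negative")
  expect_error(network_config(tau_r = 3, tau_d_E = 2), "tau_r")
  expect_error(network_config(dt = 0.6), "dt")
  expect_error(network_config(tau_l_E = 1), "latencies")
  expect_error(synaptic_kernel(1, 2, 2), "degenerate")
})

test_that("the synaptic kernel is normalized, starts at zero, peaks where predicted", {
  expect_equal(integrate(synaptic_kernel, 0, Inf, tau_r = 0.5, tau_d = 2)$value,
               1, tolerance = 1e-8)
  expect_equal(synaptic_kernel(0, 0.5, 2), 0)
  t_star <- optimize(function(t) synaptic_kernel(t, 0.5, 2), c(0, 5),
                     maximum = TRUE)$maximum
  expect_equal(t_star, 0.5 * 2 / (2 - 0.5) * log(2 / 0.5), tolerance = 1e-5)
})

test_that("a quiescent network stays at rest and an LIF neuron matches the closed-form period", {
  cfg <- tiny_uncoupled_config()
  conn <- build_connectivity(cfg, seed = 1)
  quiet <- simulate_network(cfg, conn, seed = 1, init_V = "rest")
  expect_length(quiet$raster$time, 0)
  expect_true(all(abs(quiet$voltage$V - cfg$V_rest_E) < 1e-9))

  # constant drive 1.5 mV/ms: V_inf = -40, ISI = t_ref + tau ln 2 for E
  drv <- simulate_network(cfg, conn, seed = 1, init_V = "rest",
                          const_input = 1.5, record_ids = integer(0))
  isi <- diff(drv$raster$time[drv$raster$id == 1])
  exact <- 2 + 20 * log((-40 + 60) / (-40 + 50))
  expect_gt(length(isi), 20)
  expect_lt(max(abs(isi - exact)), 1e-3)
})

test_that("refractory periods are respected and voltage samples stay below threshold", {
  cfg <- small_net_config(N = 400, duration = 1500, discard = 0)
  conn <- build_connectivity(cfg, seed = 3)
  sim <- simulate_network(cfg, conn, seed = 5, init_V = "uniform")
  r <- sim$raster
  isi_by_neuron <- split(r$time, r$id)
  t_ref <- ifelse(r$population == "E", cfg$t_ref_E, cfg$t_ref_I)
  for (i in names(isi_by_neuron)) {
    tt <- isi_by_neuron[[i]]
    if (length(tt) > 1)
      expect_gte(min(diff(tt)), t_ref[as.integer(i)] - 1e-9)
  }
  expect_true(all(sim$voltage$V <= cfg$V_th + 1e-9))
})

test_that("spike times converge at second order in dt against the closed-form oscillator", {
  # single neuron under constant drive: error of the n-th spike time vs exact
  exact <- 2 + 20 * log(2)
  err <- vapply(c(0.05, 0.025, 0.0125), function(dt) {
    cfg <- tiny_uncoupled_config(duration = 400, dt = dt)
    conn <- build_connectivity(cfg, seed = 1)
    sim <- simulate_network(cfg, conn, seed = 1, init_V = "rest",
                            const_input = 1.5, record_ids = integer(0))
    tt <- sim$raster$time[sim$raster$id == 1]
    max(abs(diff(tt) - exact))
  }, numeric(1))
  # halving dt should shrink the error by about 4 (allow 2.5 for safety)
  expect_lt(err[2], err[1] / 2.5)
  expect_lt(err[3], err[2] / 2.5)
})

test_that("total synaptic charge per presynaptic spike equals the weight", {
  # two neurons, edge 1 -> 2 only; neuron 1 forced to spike once via current
  cfg <- network_config(N = 2, frac_E = 0.5, p = 1e-9, Q_o = 1e-9,
                        duration = 150, discard = 0)
  conn <- build_connectivity(cfg, seed = 1)
  conn$offsets <- c(0L, 1L, 1L)
  conn$targets0 <- 1L  # neuron 1 (E) -> neuron 2 (I)
  # neuron 1 starts above threshold and fires exactly once
  v0 <- c(cfg$V_th + 0.5, cfg$V_rest_I)
  sim <- simulate_network(cfg, conn, seed = 1, init_V = v0,
                          record_ids = 2L, record_every_ms = cfg$dt)
  expect_equal(sum(sim$raster$id == 1), 1L)
  # for the leaky integrator, integral of (V - V_rest)/tau over the full
  # response to one filtered impulse equals the delivered charge J_IE
  v <- sim$voltage$V[1, ]
  charge <- sum(v - cfg$V_rest_I) * cfg$dt / cfg$tau_m_I
  expect_equal(charge, cfg$J_IE, tolerance = 0.02)
})

test_that("the printed weights satisfy the monotone balanced condition", {
  cfg <- network_config()
  expect_true(check_balanced_condition(cfg$J_EO, cfg$J_IO, cfg$J_EE,
                                       cfg$J_IE, cfg$J_EI, cfg$J_II))
  r <- c(cfg$J_EO / cfg$J_IO, cfg$J_EI / cfg$J_II, cfg$J_EE / cfg$J_IE)
  expect_equal(r, c(0.625, 0.5625, 0.5))
})

test_that("run_trials is deterministic under a fixed base seed and rejects n_trials = 0", {
  cfg <- small_net_config(N = 200, duration = 800, discard = 200)
  a <- run_trials(cfg, 2, base_seed = 31, record_ids = integer(0))
  b <- run_trials(cfg, 2, base_seed = 31, record_ids = integer(0))
  expect_identical(a[[1]]$raster$time, b[[1]]$raster$time)
  expect_identical(a[[2]]$raster$id, b[[2]]$raster$id)
  expect_false(identical(a[[1]]$raster$time, a[[2]]$raster$time))
  expect_error(run_trials(cfg, 0), "n_trials")
})

test_that("trial-to-trial E-rate dispersion is small in the asynchronous state", {
  cfg <- small_net_config(N = 500, tau_d_I = 1, duration = 2000, discard = 500)
  trials <- run_trials(cfg, 5, base_seed = 77, record_ids = integer(0))
  rates <- vapply(trials, function(s) {
    w <- raster_window(s$raster, "E")
    length(w$time) / cfg$N_E / ((cfg$duration - cfg$discard) / 1000)
  }, numeric(1))
  expect_lt(sd(rates) / mean(rates), 0.1)
})
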