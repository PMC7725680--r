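test_that("merged mean ISI reduces to the telescoping mean and pooled-rate inverse", {
  r <- spike_raster(c(1, 3, 9), c(1, 2, 1), c("E", "E"), 0, 10)
  expect_equal(merged_mean_isi(r), (9 - 1) / 2)
  # two interleaved regular trains at offset delta
  t1 <- seq(0, 990, by = 10); t2 <- t1 + 4
  r2 <- spike_raster(c(t1, t2), rep(1:2, each = 100), c("E", "E"), 0, 1000)
  expect_equal(merged_mean_isi(r2), mean(diff(sort(c(t1, t2)))))
  pois <- generate_poisson_raster(20, 25, 2e4, seed = 2)  # aggregate 0.5/ms
  expect_equal(merged_mean_isi(pois), 2, tolerance = 0.05)
  expect_error(merged_mean_isi(spike_raster(1, 1, "E", 0, 2)), "two spikes")
})

test_that("avalanche extraction follows the run definition and drops boundary runs", {
  s <- count_series(c(0, 1, 0, 2, 3, 0, 1, 1, 0), 1)
  avs <- extract_avalanches(s)
  expect_equal(avs$sizes, c(1L, 5L, 2L))
  expect_equal(avs$durations, c(1L, 2L, 2L))
  expect_length(extract_avalanches(count_series(rep(0, 20), 1))$sizes, 0)
  # boundary-touching runs discarded
  sb <- count_series(c(2, 1, 0, 3, 0, 1), 1)
  avb <- extract_avalanches(sb)
  expect_equal(avb$sizes, 3L)
  # every avalanche has at least one spike per occupied bin
  expect_true(all(avs$sizes >= avs$durations))
})

test_that("sparse extraction agrees with the dense path and geometric-run oracle", {
  withr::with_seed(7, {
    x <- rpois(5000, 0.6)
    s <- count_series(x, 1)
    dense <- extract_avalanches(s)
    times <- rep(seq_along(x) - 0.5, x)  # one spike mid-bin per count
    sparse <- eicrit:::extract_avalanches_sparse(times, 1, 0, 5000)
    expect_equal(sparse$sizes, dense$sizes)
    expect_equal(sparse$durations, dense$durations)
    # iid occupancy: run durations are geometric with mean 1/p0
    p0 <- exp(-0.6)
    expect_equal(mean(dense$durations), 1 / p0, tolerance = 0.1)
  })
})

test_that("coarser bins merge avalanches, conserving spikes and reducing counts", {
  r <- generate_poisson_raster(30, 20, 4e4, seed = 9)
  tm <- merged_mean_isi(r)
  a1 <- eicrit:::extract_avalanches_sparse(r$time, tm, 0, r$t_end)
  a2 <- eicrit:::extract_avalanches_sparse(r$time, 2 * tm, 0, r$t_end)
  expect_lte(length(a2$sizes), length(a1$sizes))
  # spike totals match up to boundary-discarded avalanches
  expect_equal(sum(a2$sizes), sum(a1$sizes), tolerance = 0.01)
})

test_that("distance D separates power-law from exponential samples and is permutation-invariant", {
  pl <- attr(generate_powerlaw_avalanche_counts(3e4, 1.8, 1, 3000, seed = 5), "sizes")
  withr::with_seed(6, ex <- pmax(1L, as.integer(round(rexp(3e4, 1 / mean(pl))))))
  D_pl <- powerlaw_distance_D(pl)
  D_ex <- powerlaw_distance_D(ex)
  expect_lt(D_pl, D_ex)
  expect_equal(powerlaw_distance_D(sample(pl)), D_pl)
  expect_error(powerlaw_distance_D(rep(3L, 500)), "degenerate")
})

test_that("the truncated MLE recovers planted exponents and rejects misspecified tails", {
  fits <- lapply(c(1.3, 1.5, 1.8, 2.1), function(tau) {
    errs <- vapply(1:5, function(k) {
      x <- eicrit:::.dpl_sample(10000, tau, 1, 1000)
      f <- fit_truncated_powerlaw(x, max_candidates = 10, max_p_evals = 4,
                                  n_surrogates = 50, seed = k)
      f$exponent - tau
    }, numeric(1))
    errs
  })
  errs <- unlist(fits)
  expect_lt(median(abs(errs)), 0.05)
  expect_gt(mean(abs(errs) < 0.1), 0.9)
  # exponential samples: not accepted
  withr::with_seed(77, xe <- pmax(1L, as.integer(round(rexp(10000, 1 / 30)))))
  fe <- fit_truncated_powerlaw(xe, max_candidates = 10, max_p_evals = 4,
                               n_surrogates = 50, seed = 1)
  expect_false(fe$accepted)
  expect_error(fit_truncated_powerlaw(rep(5L, 500)), "degenerate")
})

test_that("size-duration exponent is exact on deterministic data and ~2 on random walks", {
  d <- rep(2:40, times = 5)
  avs <- structure(list(sizes = 3 * d^2, durations = d, dt = 1),
                   class = "avalanche_set")
  expect_equal(size_duration_exponent(avs), 2, tolerance = 1e-10)
  lv <- simulate_normal_form(a = 0, h = 0, eps = 1e-2, dt = 1e-4,
                             n_avalanches = 5000, seed = 10, max_steps = 1e6)
  rw <- structure(list(sizes = pmax(1, round(lv$sizes / 1e-4)),
                       durations = pmax(1, round(lv$durations / 1e-4)),
                       dt = 1), class = "avalanche_set")
  # fit above the X ~ eps crossover (short excursions scale as S ~ eps T,
  # slope 1; the diffusive regime S ~ T^2 holds for T well above eps)
  slope <- size_duration_exponent(rw, quantile(rw$durations, c(0.8, 0.995)))
  expect_equal(slope, 2, tolerance = 0.15)
  expect_error(size_duration_exponent(structure(list(sizes = c(1, 2),
    durations = c(1, 2), dt = 1), class = "avalanche_set")), "distinct")
})

test_that("the scaling relation computes the crackling-noise identity", {
  sc <- scaling_relation(1.5, 2, 2)
  expect_equal(sc$predicted, 2)
  expect_equal(sc$error, 0)
  expect_equal(scaling_relation(1.5, 2, 1.5)$error, 0.5)
  expect_error(scaling_relation(1, 2, 2), "undefined")
})

test_that("the pipeline accepts planted power-law avalanches and rejects Poisson rasters", {
  s <- generate_powerlaw_avalanche_counts(20000, 1.8, 1, 2000, seed = 15)
  avs <- extract_avalanches(s)
  expect_equal(sort(avs$sizes), sort(attr(s, "sizes")))
  f <- fit_truncated_powerlaw(avs$sizes, max_candidates = 10, max_p_evals = 4,
                              n_surrogates = 50, seed = 1)
  expect_true(f$accepted)
  expect_equal(f$exponent, 1.8, tolerance = 0.1 / 1.8)
  # independent-Poisson raster: exponential-like avalanche sizes, not accepted
  pr <- generate_poisson_raster(200, 10, 1.2e5, seed = 18)
  rep1 <- avalanche_pipeline(pr, max_candidates = 10, max_p_evals = 4,
                             n_surrogates = 50, seed = 4)
  expect_false(rep1$size_fit$accepted && rep1$duration_fit$accepted)
  # deterministic given raster + seed
  rep2 <- avalanche_pipeline(pr, max_candidates = 10, max_p_evals = 4,
                             n_surrogates = 50, seed = 4)
  expect_identical(rep1$size_fit$exponent, rep2$size_fit$exponent)
})
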