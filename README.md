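# eicrit

Tools for studying how irregular single-neuron spiking coexists with
collective oscillations and scale-free avalanches in excitation-inhibition
(E-I) balanced spiking networks — for computational neuroscientists who
want a fast, reproducible pipeline from a leaky integrate-and-fire (LIF)
simulation to a criticality verdict, and a mean-field theory that predicts
where the transition sits.

The package implements three connected layers:

1. **Network simulator** (`network_config()`, `build_connectivity()`,
   `simulate_network()`, `run_trials()`): a current-based LIF E-I network
   (default N = 10⁴, 4:1 E:I, Erdős–Rényi density p = 0.2) with
   bi-exponential synaptic filtering
   F(t) = [e^(−t/τ_d) − e^(−t/τ_r)]/(τ_d − τ_r), Poisson external drive,
   refractoriness, and a compiled second-order integrator with sub-step
   threshold interpolation. The inhibitory decay time τ_d^I (1–4.5 ms) is
   the control parameter of the synchronous transition.
2. **Mean-field reduction** (`field_params()`, `transfer_rate()`,
   `estimate_sigma()`, `solve_fixed_point()`, `field_jacobian()`,
   `hopf_scan()`, `integrate_field()`): six-dimensional field equations in
   (V_E, V_I, Φ_E, Φ̇_E, Φ_I, Φ̇_I) closed by the logistic transfer
   Q = 1/(1 + exp((V_th − V)π/(√3 σ))), with fixed points, analytic
   Jacobian, and Hopf-bifurcation scanning that predicts the onset and
   frequency of the population oscillation.
3. **Statistics** (`cv_isi()`, `fano_factor()`, `mean_pairwise_pcc()`,
   `voltage_coherence()`, `rate_psd()`, `avalanche_pipeline()`,
   `fit_truncated_powerlaw()`, `scaling_relation()`,
   `simulate_normal_form()`, `detect_up_states()`, `shuffle_isi()`, and
   seeded fixture generators): spike-train irregularity and synchrony
   indices, Welch spectra, and the full avalanche battery — merged-ISI
   binning, distance to the best-fit power law, doubly truncated discrete
   power-law MLE with KS surrogate testing, and the crackling-noise
   scaling relation (α − 1)/(τ − 1) = 1/σνz.

## Worked example

A reduced copy of the reference network (N = 2500, weights rescaled by
√(10⁴/N) to preserve the balanced coupling scale), simulated in the
asynchronous regime and pushed through the main statistics:

```r
library(eicrit)

s <- sqrt(10000 / 2500)
cfg <- network_config(N = 2500, tau_d_I = 1, Q_o = 5, duration = 6000,
                      J_EO = 0.45*s, J_IO = 0.72*s, J_EE = 0.36*s,
                      J_IE = 0.72*s, J_EI = -0.81*s, J_II = -1.44*s)
conn <- build_connectivity(cfg, seed = 11)
sim  <- simulate_network(cfg, conn, seed = 21, init_V = "uniform")

sim$raster
#> <spike_raster> 197098 spikes, 2500 neurons (2000 E / 500 I), span [0, 6000] ms (discard 1000 ms)

mean(cv_isi(sim$raster, population = "E"), na.rm = TRUE)
#> [1] 1.013789

voltage_moments(sim$voltage, population = "E", from = 1000)
#>   skewness   kurtosis
#> -0.7647834  3.1875684
```

The CV near 1 says individual spiking is Poisson-like; the left-skewed,
near-Gaussian voltage distribution (skewness ≈ −0.76, kurtosis ≈ 3.2) is
the signature of fluctuation-driven threshold dynamics.

Locating the synchronous transition uses the full-size network (about a
minute of simulation for a 16-s record): calibrate σ from the
asynchronous run via `estimate_sigma()`, then scan the inhibitory decay
time:

```r
cfg  <- network_config(N = 10000, tau_d_I = 1, Q_o = 5)   # 16-s record
conn <- build_connectivity(cfg, seed = 42)
sim  <- simulate_network(cfg, conn, seed = 7, init_V = "uniform")
V <- sim$voltage; keep <- V$t > 1000
sigma_E <- estimate_sigma(mean(V$V[V$population == "E", keep]),
                          length(raster_window(sim$raster, "E")$time) / 8000 / 15000)
sigma_I <- estimate_sigma(mean(V$V[V$population == "I", keep]),
                          length(raster_window(sim$raster, "I")$time) / 2000 / 15000)
c(sigma_E, sigma_I)
#> [1] 7.511 8.320
hopf_scan(field_params(cfg, sigma_E, sigma_I))
#> <hopf_scan> Hopf crossing at tau_d_I = 3.399 ms (frequency 87.6 Hz)
```

The scan locates the inhibitory decay time at which the balanced fixed
point loses stability through a Hopf bifurcation and a gamma-band
population oscillation is born. Near that crossing, avalanches extracted
by `avalanche_pipeline()` become scale-free: both tails pass the
truncated KS test and the fitted exponents satisfy the scaling relation
to within a few hundredths. (Reduced copies of the network have larger
effective σ and correspondingly later crossings, which is why the scan is
shown at full size.)

A thin command-line wrapper is available at `exec/eicrit`
(`eicrit fixtures | stats | avalanche | macro | meanfield`).

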