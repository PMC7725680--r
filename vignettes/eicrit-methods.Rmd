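---
title: "Methods: balanced-network criticality, the mean-field reduction, and the avalanche battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: balanced-network criticality, the mean-field reduction, and the avalanche battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eicrit)
```

# The model

`eicrit` studies how irregular single-neuron spiking and collective
population dynamics — oscillations and scale-free avalanches — coexist in
excitation-inhibition (E-I) balanced circuits. The microscopic model is a
current-based leaky integrate-and-fire (LIF) network of $N$ neurons
($N_E : N_I = 4{:}1$) on a directed Erdős–Rényi graph of density $p$:

$$\frac{dV_i}{dt} = \frac{V^{\alpha}_{rest} - V_i}{\tau_\alpha}
 + J_{\alpha O} \sum_{j \in \partial_i^O} F_E * s_j
 + J_{\alpha E} \sum_{j \in \partial_i^E} F_E * s_j
 + J_{\alpha I} \sum_{j \in \partial_i^I} F_I * s_j,$$

with bi-exponential synaptic filters
$F_\alpha(t) = [e^{-t/\tau_d^\alpha} - e^{-t/\tau_r}]/(\tau_d^\alpha - \tau_r)$
normalized to unit charge. Each neuron receives $n_o = pN_E$ independent
external Poisson sources at rate $Q_o$. The default weights
(0.45, 0.72, 0.36, 0.72, −0.81, −1.44 mV) satisfy the balanced condition:
the ratio sequence $\{J_{EO}/J_{IO},\ J_{EI}/J_{II},\ J_{EE}/J_{IE}\}
= \{0.625, 0.5625, 0.5\}$ is strictly monotone, which guarantees a unique
positive solution of the balanced rate equations (5 and 20 Hz for E and I
at $Q_o = 5$ Hz).

The inhibitory synaptic decay time $\tau_d^I$ is the control parameter:
fast inhibition (1 ms) tracks excitation closely (strict balance,
asynchronous spiking), slow inhibition (≥ 3.5 ms) delays the cancellation
and lets excitation transiently dominate, producing sparse population
oscillations in the gamma range; at ~4.3 ms the network bursts. Individual
CV of inter-spike intervals stays near 1 throughout.

## Tunable parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `tau_d_I` | 1 (scanned 1–4.5) | ms | control parameter of the synchronous transition |
| `Q_o` | 5 | Hz | external drive per source; scales rates linearly in the balanced limit |
| `p` | 0.2 | — | connection density; with N fixes in-degrees $n_\alpha = pN_\alpha$ |
| `dt` | 0.05 | ms | integration step; must be < `tau_r` (0.5 ms) |
| `duration`, `discard` | 16000, 1000 | ms | record length and transient excluded from statistics |

Internally everything is mV and ms; rates cross every interface in Hz.

# Numerical scheme

The integrator advances each neuron's two second-order synaptic filter
states exactly between events (each filter is a weighted pair of
exponentials with precomputed per-step decay factors), so the cost is
O(N) per step plus O(out-degree) per spike. The membrane equation is
integrated with Heun's method (second order on smooth segments). Threshold
crossings are detected at step end and the crossing time is linearly
interpolated inside the step; the neuron is then clamped at `V_reset` with
synaptic integration halted for the refractory period (2 ms E, 1 ms I),
and integration resumes with a partial step when the period ends inside a
step. This sub-step treatment is what lets an isolated neuron under
constant drive reproduce the closed-form LIF period
$t_{ref} + \tau \ln\frac{V_\infty - V_{reset}}{V_\infty - V_{th}}$ to
better than $10^{-3}$ ms at `dt = 0.05`; with boundary-snapped spike
times the error would be O(dt). The refractory convention (clamp, leak
suspended) is one of two defensible readings of "synaptic integration is
halted"; it is isolated in one code path and flagged for sensitivity
testing.

The superposition of `n_o` Poisson sources per neuron is drawn as one
population-level Poisson count per step assigned to uniform random
neurons — statistically identical and much cheaper. All randomness flows
through R's RNG, so every simulation is bit-reproducible from
`(config, connectivity seed, run seed)`.

# The semi-analytical mean-field reduction

Averaging the network equations over populations and closing the hierarchy
with a Gaussian ansatz for the voltage distribution yields a 6-dimensional
ODE/SDE system in $X = (V_E, V_I, \Phi_E, \dot\Phi_E, \Phi_I, \dot\Phi_I)$,
where $\Phi_\alpha$ is the population-filtered input and the closure is the
logistic transfer

$$Q_\alpha = \frac{1}{1 + \exp\!\big((V_{th} - V_\alpha)\pi / (\sqrt{3}\sigma_\alpha)\big)}
\quad \text{(rate per ms)},$$

the tanh approximation of the Gaussian threshold-crossing fraction. The
effective SDs $\sigma_\alpha$ absorb everything the first-order closure
neglects (higher moments, correlations, refractoriness), so they are
calibrated **once** from one asynchronous-state simulation
($\tau_d^I = 1$ ms): measure the pooled mean voltage and the mean rate per
population, then invert the transfer function
($\sigma = (V_{th} - V_{ss})\pi / (\sqrt{3}\ln(Q_{ss}^{-1} - 1))$, exact
inverse, `estimate_sigma()`). Because the fixed point is provably
independent of the synaptic rise/decay times (the filters are normalized),
a calibration from any asynchronous run is consistent across the whole
$\tau_d^I$ scan; the package asserts this invariance. A closed-form
alternative, the Ornstein–Uhlenbeck stationary SD
$\sigma = J\sqrt{n_o Q_o \tau_m / 2}$ (`sigma_diffusion()`), predicts the
linear rate response but not the absolute rate; a switch drops the /2
factor for comparison because its rendering in the source material is
ambiguous.

Stability analysis uses the analytic 6×6 Jacobian (structural zeros and
shift rows exactly as in the first-order form; slopes $Q'_\alpha$
evaluated at the fixed point). `hopf_scan()` tracks the dominant complex
pair across the $\tau_d^I$ grid by eigenvector overlap — not by sorting
real parts, which swaps branches at crossings — and locates the critical
$\tau_c$ by bisection. The linear-order oscillation frequency is
$\mathrm{Im}\,\lambda / 2\pi$. With $\sigma$ calibrated from the
asynchronous run of the default network the scan crosses near 3.4 ms with
an onset frequency near 88 Hz; the crossing location is sensitive to
$\sigma$ at about the 10% level, which should be kept in mind when
comparing against any particular reference value near 3 ms.

The stochastic field equations add demographic noise
$J_{\alpha O}\sqrt{n_o Q_o / N_\alpha}\,\xi_\alpha(t)$ to the two voltage
rows only, integrated by Euler–Maruyama at `dt = 0.01` ms. The field-level
population Fano factor converts $Q_E(t)$ to deterministic counts
$N_E Q_E \Delta t$ (no extra Poisson sampling) aggregated in 50-ms
windows.

# Spike statistics

Count series use half-open bins; the square filter is a trailing moving
average whose not-fully-supported head is dropped (so constants are
preserved exactly and an impulse spreads into $T/\Delta t$ bins of mass
$\Delta t/T$ — the only convention consistent with both limits). Pairwise
correlation averages Pearson coefficients of 50-ms-filtered 1-ms count
series over excitatory pairs; above 500 neurons a seeded subset whose pair
count is ~10⁴ is used instead of all ~3×10⁷ pairs, trading an unbiased
subsample for tractable memory. The PSD is a Welch average (1-s Hann
segments, 50% overlap, mean detrended, window-power normalized so that
total one-sided power matches the series variance within 1%); the decay
exponent β is a least-squares log-log slope from 1.5× the spectral peak up
to 1 kHz (clipped to Nyquist), both ends configurable. Voltage moments
are pooled over recorded neurons × 1-ms samples; for networks above 2000
neurons the default recording is a deterministic stride sample of 1000
neurons preserving the E:I ratio, which leaves pooled-moment sampling
error well below the tolerances of interest.

# Avalanche battery

Avalanches are maximal runs of non-empty bins of the excitatory population
count series, with the bin width set to the mean ISI of the merged spike
train (`merged_mean_isi()`), the conventional "optimal" window. For the
default network this bin is ~0.016 ms, so the pipeline uses an
O(n spikes) sparse run-length extraction (consecutive spikes at most one
bin apart) rather than materializing ~10⁹ dense bins; the two paths are
asserted equal on dense fixtures. Runs touching the record boundary are
discarded as incomplete.

The distance `D` to the best-fit power law histograms sizes into 80
logarithmically spaced bins (the fit lives in log-log coordinates;
empty bins are excluded; linear bins available), fits a line to
$\log_{10} P$ vs $\log_{10} S$, and reports the size-weighted mean
absolute deviation normalized by the mean size. `D` is a screening index;
statistical evidence comes from the doubly truncated discrete power-law
MLE: candidate truncation bounds are drawn from the observed unique
values (≤ 50 per bound), each candidate is fitted by maximizing the
discrete truncated likelihood, and a candidate is accepted when it spans
at least one third of the whole observed log range and its KS statistic is
exceeded by more than 10% of refitted synthetic datasets drawn from the
fitted law (100 surrogates, seeded, p-resolution 0.01). Candidates are
tested widest-range first; if none passes, the smallest-KS candidate is
returned with its p-value and flagged. The size-vs-duration exponent
$1/\sigma\nu z$ is a count-weighted least-squares slope of
$\log\langle S\rangle(T)$ over the duration fit's truncated range, and the
crackling-noise identity $(\alpha - 1)/(\tau - 1) = 1/\sigma\nu z$ is the
criticality check. At the critical point of the default network the
scaling error is ~0.02–0.1 and both tails are accepted; exponent pairs
measured across $Q_o \in \{4,\dots,8\}$ Hz fall near a line of slope ~1.1–1.2.

# Macroscopic first-passage theory

The normal-form Langevin model
$dX = (aX - X^3 + h)\,dt + \sqrt{\max(X,0)}\,dW$, started at
$X(0) = \varepsilon$ and absorbed at zero, is the demographic-noise caricature
of a macroscopic avalanche near the bifurcation. Negative excursions within
a step are absorbed, not reflected; the default step is $10^{-4}$ time
units with $\varepsilon = 10^{-2}$ (convergence checked by halving). A
closed-form first-passage density with tail exponent $4h - 3/2$ and
essential small-time cutoff $\exp(-2\varepsilon^2/t)$ is provided verbatim
as `fpt_density()`. Two caveats, surfaced deliberately: that form
integrates to $\sqrt{2}$ rather than 1, and at $h = 0$ the *simulated*
process is exactly a Feller branching diffusion whose absorption law is
$P(T \le t) = e^{-2\varepsilon/t}$ — median $2\varepsilon/\ln 2$, duration
tail $T^{-2}$ (the classical branching value $\alpha = 2$), with short
durations exponentially suppressed because the $\sqrt{X}$ noise vanishes
at the boundary. The closed form instead describes a walker with constant
noise at a positive threshold (tail $-3/2$). The test suite pins the
simulation to the exact Feller law (KS < 0.05 at 10⁴ samples) and checks
the closed form's own printed properties; the $-3/2$-vs-$-2$ tension is
reported rather than resolved by fiat, with the simulation as arbiter.
The area scaling $\langle S\rangle(T) \sim T^2$ holds above the
$X \approx \varepsilon$ crossover (short excursions scale as
$S \approx \varepsilon T$).

# Up-states and surrogates

For spontaneous-activity recordings with slow (~0.1 Hz) up-down
alternation, `detect_up_states()` thresholds the 100-ms-filtered 10-ms
population rate at 30% of its maximum (filtered by default — the source
convention is ambiguous, so the raw-series variant is a switch) and keeps
supra-threshold runs of at least 1 s. No gap-merging is applied. ISI
shuffling permutes each neuron's intervals within each up-state with the
first spike anchored, preserving counts and segment-local endpoints while
destroying temporal correlations; planted power-law avalanche structure
does not survive it.

# Synthetic fixtures and what they do not show

The fixture generators emulate the statistical structure needed to test
every estimator without a network run: homogeneous Poisson (CV = FF = 1,
PCC = 0 null), sinusoidally modulated Poisson by thinning (spectral peak at
the modulation frequency), telegraph up-down alternation with 5-s half
periods and lognormal ($\sigma_{\log} = 1$, mean-1) per-neuron rate
multipliers emulating the broad firing-rate heterogeneity of cultured
recordings, and planted truncated power-law avalanches with the $S \sim
T^2$ allocation. They are deterministic under a fixed seed and their
headline parameters are recoverable by the corresponding estimators. They
do not emulate electrode-array geometry, refractoriness, or genuine
network correlations, so passing fixture tests validates the estimators,
not the biology.

# Problem sizes used by the shipped checks

The acceptance script simulates the reference $N = 10^4$ network for 16 s
(1 s discarded) at $\tau_d^I \in \{1, 3, 3.5, 4.3\}$ ms and reruns the
calibration + eigenvalue scan from scratch; the test suite uses the same
network at 8 s (and 6-s runs for the $Q_o$ sweep), plus reduced copies
(N = 200–2500, weights rescaled by $\sqrt{10^4/N}$ to preserve the
balanced coupling scale) for integrator-level properties. These sizes were
chosen so the whole battery reruns comfortably on a single CPU; note that
reduced copies have larger effective $\sigma_\alpha$ and correspondingly
later Hopf crossings, which is why transition-location checks use the
full-size network.

# Known limitations

- Zero synaptic latency only; the delay-differential stability problem is
  out of scope (the config carries the fields but the integrator rejects
  nonzero values).
- Current-based synapses only; no conductance dynamics, plasticity, or
  structured topology.
- The mean-field closure is first-order: it predicts rates, the
  transition, and the onset frequency, but not refractory corrections or
  higher-moment effects; everything neglected is folded into
  $\sigma_\alpha$.
- The avalanche definition is temporal binning (as in experiments), not
  causal spreading; exponents need not match directed-percolation values.
- The up-down fixture alternates deterministically; real cultures switch
  stochastically and carry adaptation, which the LIF model lacks.
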