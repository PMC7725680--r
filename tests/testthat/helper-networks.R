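# Small network configurations shared across test files. Weights are scaled
# by sqrt(N_ref / N) when a reduced copy of the reference network is needed,
# preserving the O(N^(-1/2)) coupling scale of the balanced regime.

tiny_uncoupled_config <- function(duration = 500, dt = 0.05) {
  network_config(N = 2, frac_E = 0.5, p = 1e-9, Q_o = 1e-9,
                 duration = duration, discard = 0, dt = dt)
}

small_net_config <- function(N = 500, tau_d_I = 1, Q_o = 5, duration = 3000,
                             discard = 500, ...) {
  s <- sqrt(10000 / N)
  network_config(N = N, tau_d_I = tau_d_I, Q_o = Q_o, duration = duration,
                 discard = discard,
                 J_EO = 0.45 * s, J_IO = 0.72 * s, J_EE = 0.36 * s,
                 J_IE = 0.72 * s, J_EI = -0.81 * s, J_II = -1.44 * s, ...)
}

default_field_params <- function(sigma_E = 4, sigma_I = 4, ...) {
  field_params(network_config(...), sigma_E, sigma_I)
}
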