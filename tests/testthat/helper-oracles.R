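# Independent oracles used across the suite. The Euler integrator writes the
# rate law out explicitly rather than calling the package, so agreement checks
# are two-route.

# Fixed-step explicit Euler for dP/dt = kcat*E0*S / (Km*(1+P/Kp) + S*(1+S/Ks)),
# S = S0 - P. Returns P at the requested times (linear interpolation between
# the two bracketing Euler nodes).
euler_progress <- function(k_cat, K_m, K_p, K_s, E0, S0, times, dt = 1e-3) {
  inv_kp <- if (is.finite(K_p)) 1 / K_p else 0
  inv_ks <- if (is.finite(K_s)) 1 / K_s else 0
  t_end <- max(times)
  n <- ceiling(t_end / dt)
  P <- numeric(n + 1)
  for (i in seq_len(n)) {
    S <- S0 - P[i]
    if (S < 0) S <- 0
    v <- k_cat * E0 * S / (K_m * (1 + P[i] * inv_kp) + S * (1 + S * inv_ks))
    P[i + 1] <- min(P[i] + dt * v, S0)
  }
  grid <- seq(0, by = dt, length.out = n + 1)
  approx(grid, P, xout = times, rule = 2)$y
}

# Reference truth rows used repeatedly in tests (wild type with each luciferin)
wt_ctz <- function() kinetic_params(k_cat = 2.48, K_m = 0.57, K_p = 0.256)
wt_fmz <- function() kinetic_params(k_cat = 7.88, K_m = 0.123, K_p = 0.56)

# One-series truth tibble for study generation
truth_row <- function(variant = "WT", luciferin = "CTZ", k_cat = 2.48,
                      K_m = 0.57, K_p = 0.256, K_s = Inf, E0_uM = 0.01,
                      scaling_f = 1e6) {
  tibble::tibble(variant = variant, luciferin = luciferin, k_cat = k_cat,
                 K_m = K_m, K_p = K_p, K_s = K_s, E0_uM = E0_uM,
                 scaling_f = scaling_f)
}
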