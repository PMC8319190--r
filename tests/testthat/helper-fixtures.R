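# Shared fixtures: the measured in-vivo parameter set and small synthetic
# inputs, built in code at test time.

invivo <- invivo_params()

# variant with v_e/k_av split out (k_av * v_e = v_e_av = 0.28), used by the
# permeability-fit recovery tests
invivo_split <- validate_params(
  tumor_transport(v_p = 0.23, v_e = 0.56, k_av = 0.5, v_e_av = 0.28,
                  PS = 0.012, TT = 5.0,
                  sd = list(v_p = 0.07, v_e_av = 0.13, TT = 0.5, PS = 0.005)),
  invivo$pk, invivo$geometry, dose_spec(100, "encapsulated"))

ftsl <- synthetic_release_table("fTSL")
stsl <- synthetic_release_table("sTSL")

heat_trace <- gen_temperature_trace()          # 42 degC, 10-min heating
hold42 <- temperature_trace(c(0, 1e5), c(42, 42))
cold37 <- temperature_trace(c(0, 1e5), c(37, 37))

# brute-force fixed-step RK4 integration (in x) of the gradient equations,
# independent of the closed-form path; vectorized across parameter sets.
# Integration is split at the source-exhaustion point of each parameter
# set (per-set step sizes) so the fixed-step scheme keeps its order across
# the release switch.
oracle_gradient <- function(k, r, c_e, c_p_in, c_dds_sys, n = 1e5) {
  m <- max(length(k), length(r), length(c_e), length(c_p_in),
           length(c_dds_sys))
  k <- rep_len(k, m); r <- rep_len(r, m); c_e <- rep_len(c_e, m)
  c_p_in <- rep_len(c_p_in, m); c_dds_sys <- rep_len(c_dds_sys, m)
  s <- r * c_dds_sys
  xs <- ifelse(s > 0, pmin(1 / r, 1), 1)       # c_dds_in = c_dds_sys here
  y <- c_p_in; extr <- numeric(m); integ <- numeric(m)
  half <- n %/% 2
  run_phase <- function(x0, len, src, nstep) {
    h <- len / nstep
    rhs <- function(y) k * (c_e - y) + src
    for (i in seq_len(nstep)) {
      k1 <- rhs(y); k2 <- rhs(y + h / 2 * k1)
      k3 <- rhs(y + h / 2 * k2); k4 <- rhs(y + h * k3)
      ynew <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      extr <<- extr + h * k * ((y - c_e) + (ynew - c_e)) / 2
      integ <<- integ + h * (y + ynew) / 2
      y <<- ynew
    }
  }
  run_phase(0, xs, s, half)
  run_phase(xs, 1 - xs, 0, n - half)
  list(c_p_out = y, c_extr = extr, c_p_mean = integ)
}

# closed-form two-compartment plasma curve for the reading of the
# compartment-model equations (plasma loss k_e + k_p, return k_t)
biexp_oracle <- function(k_p, k_t, k_e, C0, times) {
  a <- k_e + k_p; b <- k_t
  l1 <- ((a + b) + sqrt((a + b)^2 - 4 * k_e * b)) / 2
  l2 <- ((a + b) - sqrt((a + b)^2 - 4 * k_e * b)) / 2
  al <- (a - l2) / (l1 - l2)
  C0 * (al * exp(-l1 * times) + (1 - al) * exp(-l2 * times))
}
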