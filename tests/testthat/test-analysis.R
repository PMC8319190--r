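test_that("RMSE objective matches closed forms", {
  t <- seq(0, 1200, by = 1)
  base <- data.frame(t = t, v = exp(-t / 400))
  expect_equal(rmse_objective(base, base), 0)
  shifted <- data.frame(t = t, v = base$v + 0.25)
  expect_equal(rmse_objective(base, shifted), 0.25, tolerance = 1e-12)
  # sinusoidal discrepancy of amplitude a over whole periods: a/sqrt(2)
  tt <- seq(0, 100, by = 0.01)
  a <- 0.8
  expect_equal(rmse_objective(data.frame(t = tt, v = a * sin(2 * pi * tt / 10)),
                              data.frame(t = tt, v = 0 * tt)),
               a / sqrt(2), tolerance = 1e-4)
  expect_error(rmse_objective(base, data.frame(t = t + 5000, v = base$v)),
               "overlap")
})

test_that("moment-matched log-normal sampler hits requested moments", {
  set.seed(1)
  x <- rlnorm_matched(1e5, mean = 5, sd = 2)
  expect_equal(mean(x), 5, tolerance = 0.02)
  expect_equal(sd(x), 2, tolerance = 0.02)
  expect_true(all(x > 0))
  expect_identical(rlnorm_matched(10, 3, 0), rep(3, 10))
})

test_that("sampled-parameter table excludes derived parameters", {
  d <- param_distributions(invivo, "ivdds", t_rel = 8.2)
  expect_false(any(c("F_p", "v_e", "k_av", "V_p_T", "EF") %in% d$name))
  expect_true(all(c("v_p", "v_e_av", "TT", "PS", "t_rel", "VT") %in% d$name))
  # measured SDs pass through; 10%-of-mean applied where no SD exists
  expect_equal(d$sd[d$name == "PS"], 0.005)
  expect_equal(d$sd[d$name == "t_rel"], 0.82)
  expect_equal(d$sd[d$name == "VT"], 0.1 * invivo$geometry$VT)
  expect_equal(d$sd[d$name == "V_p_S"], 0)  # body-weight derived, held fixed
  d2 <- param_distributions(invivo, "free")
  expect_false("t_rel" %in% d2$name)
})

test_that("parametric map reproduces the measured operating points", {
  RI <- exp(seq(log(0.1), log(100), length.out = 30))
  PI <- exp(seq(log(0.01), log(10), length.out = 40))
  t0 <- Sys.time()
  m <- parametric_map(RI, PI)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 10)          # ~1200 cells via the fixed point
  expect_equal(dim(m$plateau), c(30, 40))
  expect_true(all(m$plateau > 0 & m$plateau <= 1 + 1e-12))
  # monotone: decreasing along RI, increasing along PI
  expect_true(all(apply(m$plateau, 2, diff) < 1e-14))
  expect_true(all(apply(m$plateau, 1, diff) > -1e-14))
  # measured slow-release cell: 4% of maximum
  expect_equal(plateau_concentration(12.6, 0.26), 0.04, tolerance = 0.05)
  # fast-release limit of the grid approaches c_max
  m2 <- parametric_map(c(1e-4, 1e-3), c(0.5, 1))
  expect_true(all(m2$plateau > 0.99))
  # EF second axis matches the extraction formula
  expect_equal(m$EF, extraction_fraction(PI, 1))
})

test_that("fixed-point and full-simulation maps agree", {
  RI <- exp(seq(log(0.5), log(20), length.out = 5))
  PI <- exp(seq(log(0.1), log(5), length.out = 5))
  fp <- parametric_map(RI, PI)
  # idealized plateau assumptions: agreement is tight
  fs0 <- parametric_map(RI, PI, method = "full_simulation", params = invivo,
                        systemic_feedback = FALSE)
  expect_lt(max(abs(fs0$plateau - fp$plateau) / fp$plateau), 0.02)
  # full recirculating dynamics: within 15%
  fs1 <- parametric_map(RI, PI, method = "full_simulation", params = invivo)
  expect_lt(max(abs(fs1$plateau - fp$plateau) / fp$plateau), 0.15)
})

test_that("Monte Carlo uncertainty collapses to the deterministic run at zero SD", {
  p0 <- validate_params(
    tumor_transport(v_p = 0.23, v_e_av = 0.28, PS = 0.012, TT = 5,
                    sd = list(v_p = 0, v_e_av = 0, TT = 0, PS = 0)),
    systemic_pk(8.99, 1.2, 1.29e-3, 0.9e-3, 0.8e-3,
                sd = list(V_D = 0, V_p_S = 0, k_p = 0, k_t = 0, k_e = 0)),
    tumor_geometry(0.00745, 0.23, sd = list(VT = 0)))
  mc <- monte_carlo_uncertainty(p0, "ivdds", ftsl, heat_trace,
                                dose = dose_spec(100, "encapsulated"),
                                n = 16, seed = 5, duration = 600,
                                default_rel_sd = 0)
  expect_equal(max(mc$c_e_T[, "sd"]), 0)
  ref <- simulate_batch(ivdds:::.par_row(p0), "ivdds", ID = 100,
                        release = ftsl, temperature = heat_trace,
                        duration = 600, dt = 0.5, output_dt = 20)
  expect_equal(mc$c_e_T[, "mean"], ref$c_e_T[, 1], ignore_attr = TRUE)
})

test_that("Monte Carlo uncertainty is reproducible under a fixed seed", {
  a <- monte_carlo_uncertainty(invivo, "ivdds", ftsl, heat_trace,
                               dose = dose_spec(100, "encapsulated"),
                               n = 50, seed = 42, duration = 600)
  b <- monte_carlo_uncertainty(invivo, "ivdds", ftsl, heat_trace,
                               dose = dose_spec(100, "encapsulated"),
                               n = 50, seed = 42, duration = 600)
  expect_identical(a$c_e_T, b$c_e_T)
  expect_identical(a$c_p_T_mean, b$c_p_T_mean)
  c2 <- monte_carlo_uncertainty(invivo, "ivdds", ftsl, heat_trace,
                                dose = dose_spec(100, "encapsulated"),
                                n = 50, seed = 43, duration = 600)
  expect_false(identical(a$c_e_T, c2$c_e_T))
})

test_that("Sobol estimators recover analytic indices of an additive model", {
  dist <- data.frame(name = c("a", "b"), mean = c(1, 1), sd = c(0.5, 0.25))
  res <- sobol_sensitivity(NULL, "free", dose = dose_spec(1, "free"),
                           n_base = 4096, seed = 3,
                           model_fn = function(S) S$a + S$b, dist = dist)
  va <- 0.5^2; vb <- 0.25^2
  expect_equal(res$S1[res$parameter == "a"], va / (va + vb), tolerance = 0.05)
  expect_equal(res$S1[res$parameter == "b"], vb / (va + vb), tolerance = 0.05)
  expect_equal(res$ST[res$parameter == "a"], va / (va + vb), tolerance = 0.05)
  expect_equal(res$ST[res$parameter == "b"], vb / (va + vb), tolerance = 0.05)
  # additive model: first-order indices sum to ~1
  expect_equal(sum(res$S1), 1, tolerance = 0.05)
})

test_that("a parameter that does not enter the model gets a null index", {
  d <- param_distributions(invivo, "ivdds", t_rel = 8.2)
  res <- sobol_sensitivity(NULL, "ivdds", dose = dose_spec(100, "encapsulated"),
                           n_base = 1024, seed = 2, dist = d,
                           model_fn = function(S) S$TT + S$v_e_av)
  expect_equal(res$S1[res$parameter == "t_rel"], 0, tolerance = 0.02)
  expect_equal(res$ST[res$parameter == "t_rel"], 0, tolerance = 0.02)
  expect_gt(res$ST[res$parameter == "TT"], 0.5)
})

test_that("batch integrator matches the adaptive reference solver", {
  b <- simulate_batch(ivdds:::.par_row(invivo), "ivdds", ID = 100,
                      release = ftsl, temperature = heat_trace,
                      duration = 900, dt = 0.25, output_dt = 30)
  a <- simulate_ivdds(invivo, ftsl, heat_trace,
                      dose_spec(100, "encapsulated"), duration = 900,
                      output_dt = 30)
  i <- match(b$times, a$t_s)
  # fixed-step RK4 through the heater switch-off kink: sub-percent accuracy
  expect_lt(max(abs(b$c_e_T[, 1] - a$c_e_T[i])) / max(a$c_e_T), 0.01)
  bf <- simulate_batch(ivdds:::.par_row(invivo), "free", ID = 100,
                       duration = 900, dt = 0.25, output_dt = 30)
  af <- simulate_free(invivo, dose_spec(100, "free"), duration = 900,
                      output_dt = 30)
  expect_equal(bf$c_e_T[, 1], af$c_e_T[i], tolerance = 1e-4,
               ignore_attr = TRUE)
})
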