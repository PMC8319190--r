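test_that("permeability fit recovers parameters from its own forward model", {
  times <- seq(0, 600, by = 4)
  Iv <- 100 * (1 - exp(-times / 8)) * exp(-times / 300)
  Ie <- ivdds:::.forward_Ie(times, Iv, PS = 0.012, k_av = 0.5, v_e = 0.56,
                            Hct_mv = 0.19)
  fit <- fit_permeability(fluorescence_trace(times, Iv, Ie), v_e = 0.56)
  expect_equal(fit$PS, 0.012, tolerance = 1e-3)
  expect_equal(fit$k_av, 0.5, tolerance = 1e-3)
  # invariance under common positive rescaling of both channels
  fit2 <- fit_permeability(fluorescence_trace(times, 57 * Iv, 57 * Ie),
                           v_e = 0.56)
  expect_equal(fit2$PS, fit$PS, tolerance = 1e-6)
  expect_equal(fit2$k_av, fit$k_av, tolerance = 1e-6)
  expect_error(fit_permeability(fluorescence_trace(times, Iv * 0, Ie * 0),
                                v_e = 0.56), "unidentifiable")
})

test_that("permeability fit recovers parameters from simulated imaging data", {
  calib <- calibration_spec(scale = 0.01, k_av = 0.5)
  tr <- gen_fluorescence_traces(invivo_split, dose_spec(100, "free"),
                                "free", calib, duration = 1200)
  fit <- fit_permeability(tr, v_e = 0.56)
  expect_equal(fit$PS, 0.012, tolerance = 1e-3)
  expect_equal(fit$k_av, 0.5, tolerance = 1e-3)
})

test_that("permeability fit degrades gracefully under 5% noise", {
  times <- seq(0, 600, by = 4)
  Iv <- 100 * (1 - exp(-times / 8)) * exp(-times / 300)
  Ie <- ivdds:::.forward_Ie(times, Iv, PS = 0.012, k_av = 0.5, v_e = 0.56,
                            Hct_mv = 0.19)
  rel_err <- vapply(1:100, function(s) {
    set.seed(s)
    sdlog <- sqrt(log(1 + 0.05^2))
    Ie_n <- Ie * rlnorm(length(Ie), -sdlog^2 / 2, sdlog)
    f <- fit_permeability(fluorescence_trace(times, Iv, Ie_n), v_e = 0.56)
    abs(f$PS - 0.012) / 0.012
  }, numeric(1))
  expect_lt(mean(rel_err), 0.10)
  expect_lt(median(rel_err), 0.10)
})

test_that("transit time is recovered from the step-response model", {
  t <- seq(0, 30, by = 0.5)
  y <- ifelse(t >= 2, 1 - exp(-(t - 2) / 5), 0)
  tr <- fluorescence_trace(t, y, y * 0)
  expect_equal(estimate_transit_time(tr), 5.0, tolerance = 1e-4)
  flat <- fluorescence_trace(t, rep(0, length(t)), rep(0, length(t)))
  expect_error(estimate_transit_time(flat), "does not rise")
})

test_that("transit-time recovery spans the reported human tumor range", {
  for (TT in c(2, 5, 11, 30)) {
    w <- max(30, 3 * TT)
    t <- seq(0, w, by = 0.5)
    err <- vapply(1:10, function(s) {
      set.seed(1000 + s)
      y <- ifelse(t >= 2, 1 - exp(-(t - 2) / TT), 0) + rnorm(length(t), 0, 0.02)
      est <- estimate_transit_time(fluorescence_trace(t, y, y * 0),
                                   window = w)
      abs(est - TT) / TT
    }, numeric(1))
    expect_lt(mean(err), 0.10)
  }
})

test_that("bi-exponential fit round-trips noise-free parameters", {
  truth <- biexponential(C0 = 11.1, alpha = 0.6, lambda1 = 2.5e-3,
                         lambda2 = 3e-4)
  times <- c(2, 4, 8, 16, 32, 64, 128) * 60
  s <- blood_samples(times, predict(truth, times))
  fit <- fit_biexponential(s)
  expect_equal(fit$C0, truth$C0, tolerance = 1e-6)
  expect_equal(fit$alpha, truth$alpha, tolerance = 1e-6)
  expect_equal(fit$lambda1, truth$lambda1, tolerance = 1e-6)
  expect_equal(fit$lambda2, truth$lambda2, tolerance = 1e-6)
  expect_false(attr(fit, "degenerate"))
})

test_that("mono-exponential data are flagged as degenerate", {
  times <- c(2, 4, 8, 16, 32, 64, 128) * 60
  s <- blood_samples(times, 10 * exp(-5e-4 * times))
  fit <- fit_biexponential(s)
  expect_true(attr(fit, "degenerate"))
})

test_that("micro rate constants follow the printed formulas", {
  # hand evaluation: alpha = 0.5, lambda = (2, 1)
  rc <- rate_constants(biexponential(1, 0.5, 2, 1))
  expect_equal(rc$k_p, 1.5)
  expect_equal(rc$k_e, 2 / 1.5)
  expect_equal(rc$k_t, 0.25 / 1.5)
  # equal eigenvalues collapse the tissue exchange
  rc2 <- rate_constants(biexponential(1, 0.3, 1 + 1e-12, 1))
  expect_equal(rc2$k_t, 0, tolerance = 1e-9)
  expect_equal(rc2$k_p, 1, tolerance = 1e-9)
  expect_equal(rc2$k_e, 1, tolerance = 1e-9)
})

test_that("measured rate constants round-trip through simulate + fit + invert", {
  # directional convention: k_t plasma->tissue, k_p tissue->plasma
  k_t <- 0.90e-3; k_p <- 1.29e-3; k_e <- 0.80e-3
  s <- gen_blood_samples(k_t, k_p, k_e, ID = 100, V_D = 8.99)
  rc <- rate_constants(fit_biexponential(s))
  expect_equal(rc$k_t, k_t, tolerance = 1e-6)
  expect_equal(rc$k_p, k_p, tolerance = 1e-6)
  expect_equal(rc$k_e, k_e, tolerance = 1e-6)
})

test_that("initial distribution volume is dose over first concentration", {
  expect_equal(initial_distribution_volume(100 / 8.99, 100), 8.99)
  expect_equal(initial_distribution_volume(5, 5), 1)
  expect_equal(initial_distribution_volume(5, 20),
               2 * initial_distribution_volume(5, 10))
  expect_error(initial_distribution_volume(0, 10), "concentration")
})

test_that("fluorescence converts to concentration in both modes", {
  calib <- calibration_spec(scale = 0.02, k_av = 0.5)
  t <- c(0, 10, 20, 30)
  # tsl mode: intensity at baseline -> zero released drug
  tr <- fluorescence_trace(t, c(100, 100, 100, 100), c(0, 1, 2, 3))
  out <- fluorescence_to_concentration(tr, calib, "tsl",
                                       baseline_window = 10,
                                       c_dds_baseline = 80)
  expect_equal(out$c_plasma, rep(0, 4))
  expect_equal(out$c_ees, 0.02 * c(0, 1, 2, 3) / 0.5)
  # complete local release: intensity = dequench x baseline -> full conc
  tr2 <- fluorescence_trace(t, c(100, 100, 30.2 * 100, 30.2 * 100),
                            rep(0, 4))
  out2 <- fluorescence_to_concentration(tr2, calib, "tsl",
                                        baseline_window = 5,
                                        c_dds_baseline = 80)
  expect_equal(out2$c_plasma[3], 80)
  # affine linearity: doubling (I - baseline) doubles released conc
  tr3 <- fluorescence_trace(t, c(100, 100, 150, 200), rep(0, 4))
  out3 <- fluorescence_to_concentration(tr3, calib, "tsl",
                                        baseline_window = 5,
                                        c_dds_baseline = 80)
  expect_equal(out3$c_plasma[4], 2 * out3$c_plasma[3])
  # free mode scaling
  tr4 <- fluorescence_trace(t, c(0, 81, 162, 243), c(0, 10, 20, 30))
  out4 <- fluorescence_to_concentration(tr4, calib, "free")
  expect_equal(out4$c_plasma, 0.02 * c(0, 81, 162, 243) / 0.81)
  expect_error(fluorescence_to_concentration(tr4, calib, "tsl"),
               "baseline")
})
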