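#' Noise specification for synthetic data
#'
#' Multiplicative log-normal noise (signal-proportional detector noise)
#' plus an optional additive floor.
#'
#' @param multiplicative_sd SD of the multiplicative factor (fraction).
#' @param additive_sd SD of the additive term (a.u.).
#' @param seed integer seed; all generator randomness flows through it.
#' @return object of class `"noise_spec"`.
#' @export
noise_spec <- function(multiplicative_sd = 0, additive_sd = 0, seed = 1L) {
  .chk(.is_num1(multiplicative_sd) && multiplicative_sd >= 0,
       "multiplicative_sd must be >= 0")
  .chk(.is_num1(additive_sd) && additive_sd >= 0, "additive_sd must be >= 0")
  structure(list(multiplicative_sd = multiplicative_sd,
                 additive_sd = additive_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

.apply_noise <- function(x, noise) {
  if (noise$multiplicative_sd > 0) {
    sdlog <- sqrt(log(1 + noise$multiplicative_sd^2))
    x <- x * rlnorm(length(x), -sdlog^2 / 2, sdlog)
  }
  if (noise$additive_sd > 0) x <- x + rnorm(length(x), 0, noise$additive_sd)
  x
}

#' Synthetic hyperthermia temperature trace
#'
#' Piecewise trace emulating a tumor heating session: exponential approach
#' from baseline to the plateau, a hold, then exponential cool-down back to
#' baseline.
#'
#' @param ramp_s time constant of the heating ramp (s).
#' @param plateau_C plateau temperature (degC).
#' @param hold_s total heating duration from onset to switch-off (s).
#' @param baseline_C starting/body temperature (degC), default 37.
#' @param cool_tau_s cool-down time constant (s).
#' @param dt sampling interval (s), default 2 (thermocouple cadence).
#' @param total_s total trace duration (s); default heating plus 10 min.
#' @return a [temperature_trace()].
#' @export
gen_temperature_trace <- function(ramp_s = 60, plateau_C = 42, hold_s = 600,
                                  baseline_C = 37, cool_tau_s = 60, dt = 2,
                                  total_s = hold_s + 600) {
  .chk(all(c(ramp_s, hold_s, cool_tau_s, dt, total_s) > 0),
       "all durations must be > 0")
  times <- seq(0, total_s, by = dt)
  Tup <- plateau_C - (plateau_C - baseline_C) * exp(-times / ramp_s)
  T_off <- plateau_C - (plateau_C - baseline_C) * exp(-hold_s / ramp_s)
  Tc <- baseline_C + (T_off - baseline_C) * exp(-(times - hold_s) / cool_tau_s)
  temperature_trace(times, ifelse(times <= hold_s, Tup, Tc))
}

#' Synthetic blood-sample series from two-compartment kinetics
#'
#' Evaluates the closed-form two-compartment plasma concentration (bolus
#' `C(0) = ID / V_D`, directional micro-constant convention: `k_t`
#' plasma-to-tissue, `k_p` tissue-to-plasma, `k_e` elimination) at the
#' given sampling times and applies multiplicative noise.
#'
#' @param k_t,k_p,k_e rate constants (1/s).
#' @param ID injected dose (amount).
#' @param V_D initial volume of distribution (mL).
#' @param times sampling times (s); default the classical 2-128 min
#'   doubling design.
#' @param noise a [noise_spec()].
#' @return a [blood_samples()] with attribute `truth` (the generating
#'   [biexponential()]).
#' @export
gen_blood_samples <- function(k_t, k_p, k_e, ID, V_D,
                              times = c(2, 4, 8, 16, 32, 64, 128) * 60,
                              noise = noise_spec()) {
  .chk(length(times) >= 3, "times must have >= 3 entries")
  truth <- .biexp_from_rates(k_t, k_p, k_e, C0 = ID / V_D)
  set.seed(noise$seed)
  conc <- .apply_noise(predict(truth, times), noise)
  out <- blood_samples(times, conc, ID = ID)
  attr(out, "truth") <- truth
  out
}

#' Synthetic in vitro release trace
#'
#' Zero-order release: percent release `min(100, 100 * t / t_rel)` mapped
#' back to raw fluorescence through the inverse of the percent-release
#' formula, with noise applied to the raw signal.
#'
#' @param t_rel true release time (s).
#' @param duration trace duration (s).
#' @param dt sampling interval (s), default 1 (recording every second).
#' @param Fl_b background fluorescence (a.u.).
#' @param Fl_m 100%-release fluorescence (a.u.).
#' @param temperature assay temperature recorded with the trace (degC).
#' @param noise a [noise_spec()].
#' @return a [release_trace()] with attribute `truth` (`t_rel`).
#' @export
gen_release_trace <- function(t_rel, duration = 60, dt = 1, Fl_b = 50,
                              Fl_m = 1050, temperature = 42,
                              noise = noise_spec()) {
  .chk(.is_num1(t_rel) && t_rel > 0, "t_rel must be > 0")
  times <- seq(0, duration, by = dt)
  rel <- pmin(100, 100 * times / t_rel)
  Fl <- Fl_b + rel / 100 * (Fl_m - Fl_b)
  set.seed(noise$seed)
  Fl <- .apply_noise(Fl, noise)
  out <- release_trace(times, Fl, Fl_b = Fl_b, Fl_m = Fl_m,
                       temperature = temperature)
  attr(out, "truth") <- t_rel
  out
}

#' Synthetic intravital fluorescence traces
#'
#' Simulates the true concentration trajectory for the requested scenario
#' and inverts the fluorescence-to-concentration conversion to produce
#' intra- and extravascular intensity traces, including quenched-baseline
#' behavior and dequenching in the IV-DDS scenario. Ground truth is
#' attached as the `truth` attribute so recovery tests never re-derive it.
#'
#' @param params validated [validate_params()] bundle.
#' @param dose a [dose_spec()] matching the scenario.
#' @param scenario `"free"` or `"ivdds"`.
#' @param calib a [calibration_spec()].
#' @param noise a [noise_spec()].
#' @param frame_dt frame interval (s); defaults to 4 s (free) or 10 s
#'   (IV-DDS), the usual acquisition cadences.
#' @param duration imaging duration (s).
#' @param release,temperature required for `scenario = "ivdds"`.
#' @return a [fluorescence_trace()] with attribute `truth` (list with the
#'   trajectory and generating parameters).
#' @export
gen_fluorescence_traces <- function(params, dose, scenario = c("free", "ivdds"),
                                    calib, noise = noise_spec(),
                                    frame_dt = NULL, duration = 1200,
                                    release = NULL, temperature = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(frame_dt)) frame_dt <- if (scenario == "free") 4 else 10
  if (scenario == "free") {
    traj <- simulate_free(params, dose, duration = duration,
                          output_dt = frame_dt)
    I_v <- traj$c_p_T_mean * (1 - calib$Hct_mv) / calib$scale
  } else {
    .chk(!is.null(release) && !is.null(temperature),
         "ivdds scenario requires release and temperature")
    traj <- simulate_ivdds(params, release, temperature, dose,
                           duration = duration, output_dt = frame_dt)
    c_dds0 <- dose$ID / params$pk$V_p_S
    I_base <- c_dds0 * (1 - calib$Hct_mv) / calib$scale
    # quenched encapsulated signal plus dequenched released signal
    I_v <- I_base * (1 + (calib$dequench_factor - 1) *
                       traj$c_p_T_mean / c_dds0)
  }
  I_e <- traj$c_e_T * calib$k_av / calib$scale
  set.seed(noise$seed)
  I_v <- .apply_noise(I_v, noise)
  I_e <- .apply_noise(I_e, noise)
  times <- traj$t_s
  keep <- which(diff(c(-Inf, times)) > 0)
  out <- fluorescence_trace(times[keep], I_v[keep], I_e[keep])
  attr(out, "truth") <- list(trajectory = traj, params = params,
                             dose = dose, scenario = scenario, calib = calib)
  out
}
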