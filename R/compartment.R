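#' Temperature trace
#'
#' @param times sampling times (s), strictly increasing.
#' @param T_C temperature (degC) at each time.
#' @return object of class `"temperature_trace"`.
#' @export
temperature_trace <- function(times, T_C) {
  .chk(length(times) == length(T_C) && length(times) >= 1,
       "times and T_C must be non-empty and equal length")
  .chk(all(diff(times) > 0), "times must be strictly increasing")
  structure(list(times = as.numeric(times), T_C = as.numeric(T_C)),
            class = "temperature_trace")
}

## Lean, vectorized evaluation of the quasi-steady gradient closed form.
## Returns outlet free concentration, total extracted amount, spatial mean
## of the free profile, and outlet encapsulated concentration. All
## arguments recycle; the piecewise-exponential algebra matches
## .gradient_closed_form exactly.
.gradient_eval <- function(k, r, c_e, c_p_in, c_dds_sys, c_dds_in = c_dds_sys) {
  n <- max(length(k), length(r), length(c_e), length(c_p_in),
           length(c_dds_sys), length(c_dds_in))
  k <- rep_len(k, n); r <- rep_len(r, n); c_e <- rep_len(c_e, n)
  c_p_in <- rep_len(c_p_in, n); c_dds_sys <- rep_len(c_dds_sys, n)
  c_dds_in <- rep_len(c_dds_in, n)
  s <- r * c_dds_sys
  x1 <- ifelse(s > 0, pmin(c_dds_in / s, 1), 1)
  kpos <- k > 0
  ks <- ifelse(kpos, k, 1)                   # safeguarded divisor
  A1 <- c_e + s / ks
  E1 <- exp(-ks * x1)
  c1 <- A1 + (c_p_in - A1) * E1
  extr1 <- s * x1 + (c_p_in - A1) * (1 - E1)
  int1 <- A1 * x1 + (c_p_in - A1) * (1 - E1) / ks
  L2 <- 1 - x1
  E2 <- exp(-ks * L2)
  c_out <- c_e + (c1 - c_e) * E2
  extr2 <- (c1 - c_e) * (1 - E2)
  int2 <- c_e * L2 + (c1 - c_e) * (1 - E2) / ks
  if (any(!kpos)) {                          # pure-transport limit, k = 0
    i <- !kpos
    c1i <- c_p_in[i] + s[i] * x1[i]
    c_out[i] <- c1i
    extr1[i] <- 0; extr2[i] <- 0
    int1[i] <- c_p_in[i] * x1[i] + s[i] * x1[i]^2 / 2
    int2[i] <- c1i * L2[i]
    c1[i] <- c1i
  }
  list(c_p_out = c_out,
       c_extr = extr1 + extr2,
       c_p_mean = int1 + int2,
       c_dds_out = pmax(0, c_dds_in - s))
}

.temp_fun <- function(temperature, duration) {
  .chk(inherits(temperature, "temperature_trace"),
       "temperature must be a temperature_trace")
  if (max(temperature$times) < duration)
    warning("temperature trace shorter than duration; holding last value",
            call. = FALSE)
  if (length(temperature$times) == 1L) {
    val <- temperature$T_C[1]
    function(t) rep_len(val, length(t))
  } else {
    approxfun(temperature$times, temperature$T_C, rule = 2)
  }
}

.sim_core <- function(params, rate_fun, dose, duration, output_dt,
                      f_distr, use_v_e_av, systemic_feedback,
                      rtol, atol) {
  tt <- params$tumor; pk <- params$pk
  F_p <- params$F_p
  k <- tt$PS / F_p
  Q <- F_p * params$geometry$VT
  v_e_div <- if (use_v_e_av) tt$v_e_av else {
    .chk(!is.null(tt$v_e), "literal v_e requested but v_e not set")
    tt$v_e
  }
  V_D <- pk$V_D; V_p_S <- pk$V_p_S; V_p_T <- params$V_p_T
  TTs <- tt$TT
  encapsulated <- dose$form == "encapsulated"
  y0 <- c(c_e_T = 0, c_p_S = if (encapsulated) 0 else dose$ID / V_D,
          c_t_S = 0,
          c_p_DDS_S = if (encapsulated) dose$ID / V_p_S else 0,
          eliminated = 0)
  rhs <- function(t, y, p) {
    r <- if (encapsulated) TTs * rate_fun(t) else 0
    cdds <- max(y[4], 0)
    g <- .gradient_eval(k, r, max(y[1], 0), max(y[2], 0), cdds)
    delta <- g$c_p_out - y[2]
    tumor_term <- switch(f_distr,
      vd = Q * delta / V_D,
      hybrid = if (delta > 0) Q * delta / V_D else Q * delta / V_p_S,
      printed = if (delta > 0) Q * delta * V_p_T / (V_p_S * V_D)
                else Q * delta / V_p_S)
    d1 <- F_p * g$c_extr / v_e_div
    if (systemic_feedback) {
      d2 <- tumor_term - (pk$k_e + pk$k_p) * y[2] + pk$k_t * y[3]
      d3 <- pk$k_p * y[2] - pk$k_t * y[3]
      d4 <- Q * (g$c_dds_out - cdds) / V_p_S
      d5 <- pk$k_e * max(y[2], 0) * V_D
    } else {
      d2 <- 0; d3 <- 0; d4 <- 0; d5 <- 0
    }
    list(c(d1, d2, d3, d4, d5), c_p_T_mean = g$c_p_mean)
  }
  times <- seq(0, duration, by = output_dt)
  if (times[length(times)] < duration) times <- c(times, duration)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  sol <- as.data.frame(sol)
  neg <- c("c_e_T", "c_p_S", "c_t_S", "c_p_DDS_S")
  worst <- min(vapply(sol[neg], min, numeric(1)))
  if (worst < -1e-8)
    warning(sprintf("negative concentrations down to %.3g clipped to 0", worst),
            call. = FALSE)
  for (nm in neg) sol[[nm]] <- pmax(sol[[nm]], 0)
  traj <- data.frame(t_s = sol$time, c_e_T = sol$c_e_T,
                     c_p_T_mean = sol$c_p_T_mean, c_p_S = sol$c_p_S,
                     c_t_S = sol$c_t_S, c_p_DDS_S = sol$c_p_DDS_S,
                     eliminated = sol$eliminated)
  structure(traj,
            params = params, dose = dose, f_distr = f_distr,
            v_e_div = v_e_div, systemic_feedback = systemic_feedback,
            solver = list(method = "ode45", rtol = rtol, atol = atol),
            class = c("ivdds_trajectory", "data.frame"))
}

#' Simulate triggered IV-DDS delivery
#'
#' Integrates the coupled system: tumor EES free-drug concentration,
#' systemic plasma free and encapsulated drug, and systemic tissue, with
#' the quasi-steady microvascular gradient re-solved in closed form at
#' every solver evaluation. The normalized release rate is
#' `r = TT * release_rate_at_temperature(table, T(t))`; below the release
#' table's minimum temperature the trigger is absent and `r = 0`. Initial
#' condition: all free-drug states 0, encapsulated `c_p_DDS_S(0) = ID / V_p_S`.
#'
#' @param params validated [validate_params()] bundle.
#' @param release a [release_table()].
#' @param temperature a [temperature_trace()]; linearly interpolated, last
#'   value held (with a warning) if shorter than `duration`.
#' @param dose [dose_spec()] with `form = "encapsulated"` (defaults to the
#'   bundle's dose).
#' @param duration simulated time (s).
#' @param output_dt output sampling interval (s); sampling only, the
#'   integrator is adaptive.
#' @param f_distr distribution-volume bookkeeping for drug exchanged
#'   between tumor and systemic plasma: `"vd"` (default; uniform pool
#'   volume `V_D`, exactly mass-conserving), `"hybrid"` (`V_D` for
#'   tumor-to-systemic flux, `V_p_S` otherwise), or `"printed"` (literal
#'   as-printed switching factor; not mass-conserving).
#' @param use_v_e_av use the available volume fraction `v_e_av` in the EES
#'   equation (default); `FALSE` restores the literal `v_e`.
#' @param systemic_feedback if `FALSE`, systemic recirculation is disabled:
#'   systemic states are frozen (encapsulated concentration constant, free
#'   systemic concentration 0), isolating the tumor plateau dynamics.
#' @param rtol,atol solver tolerances.
#' @return an `"ivdds_trajectory"` data.frame with columns `t_s`, `c_e_T`,
#'   `c_p_T_mean` (spatial mean of tumor plasma free drug, the quantity
#'   comparable to intravascular imaging signal), `c_p_S`, `c_t_S`,
#'   `c_p_DDS_S`, `eliminated`.
#' @export
simulate_ivdds <- function(params, release, temperature, dose = params$dose,
                           duration, output_dt = 1,
                           f_distr = c("vd", "hybrid", "printed"),
                           use_v_e_av = TRUE, systemic_feedback = TRUE,
                           rtol = 1e-8, atol = 1e-12) {
  .chk(inherits(params, "ivdds_params"), "params must be a validated bundle")
  .chk(inherits(dose, "dose_spec") && dose$form == "encapsulated",
       "dose must be encapsulated for simulate_ivdds")
  .chk(.is_num1(duration) && duration > 0, "duration must be > 0")
  f_distr <- match.arg(f_distr)
  tf <- .temp_fun(temperature, duration)
  rate_fun <- function(t) release_rate_at_temperature(release, tf(t))
  .sim_core(params, rate_fun, dose, duration, output_dt, f_distr,
            use_v_e_av, systemic_feedback, rtol, atol)
}

#' Simulate an unencapsulated (free) drug bolus
#'
#' Same system with the release terms removed: bolus into systemic plasma
#' at `t = 0` with immediate distribution, `c_p_S(0) = ID / V_D`; tumor
#' uptake follows the gradient model with `r = 0`.
#'
#' @inheritParams simulate_ivdds
#' @param dose [dose_spec()] with `form = "free"`.
#' @return an `"ivdds_trajectory"` data.frame.
#' @export
simulate_free <- function(params, dose = params$dose, duration,
                          output_dt = 1,
                          f_distr = c("vd", "hybrid", "printed"),
                          use_v_e_av = TRUE, systemic_feedback = TRUE,
                          rtol = 1e-8, atol = 1e-12) {
  .chk(inherits(params, "ivdds_params"), "params must be a validated bundle")
  .chk(inherits(dose, "dose_spec") && dose$form == "free",
       "dose must be free for simulate_free")
  .chk(.is_num1(duration) && duration > 0, "duration must be > 0")
  f_distr <- match.arg(f_distr)
  .sim_core(params, rate_fun = function(t) 0, dose, duration, output_dt,
            f_distr, use_v_e_av, systemic_feedback, rtol, atol)
}

#' Mass ledger of a trajectory
#'
#' Total drug amount accounted for at each output time: tumor EES
#' (`c_e_T * v_e_av * VT` with the volume actually used by the run),
#' systemic free drug in plasma and tissue (pool volume `V_D`),
#' encapsulated drug (`c_p_DDS_S * V_p_S`) and the cumulative eliminated
#' amount. For the default `f_distr = "vd"` bookkeeping this equals the
#' injected dose up to solver tolerance at every time point.
#'
#' @param traj an `"ivdds_trajectory"`.
#' @return numeric vector of total amounts, one per output time.
#' @export
mass_ledger <- function(traj) {
  .chk(inherits(traj, "ivdds_trajectory"), "traj must be an ivdds_trajectory")
  p <- attr(traj, "params")
  v_e_div <- attr(traj, "v_e_div")
  traj$c_e_T * v_e_div * p$geometry$VT +
    (traj$c_p_S + traj$c_t_S) * p$pk$V_D +
    traj$c_p_DDS_S * p$pk$V_p_S +
    traj$eliminated
}

.union_interp <- function(xa, ya, xb, yb, lo, hi) {
  grid <- sort(unique(c(xa, xb, lo, hi)))
  grid <- grid[grid >= lo & grid <= hi]
  list(grid = grid,
       a = approx(xa, ya, xout = grid, rule = 2)$y,
       b = approx(xb, yb, xout = grid, rule = 2)$y)
}

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Mean absolute error against an observed EES time course
#'
#' `MAE = (1/T) * integral_0^T |c_obs(t) - c_sim(t)| dt`, evaluated by the
#' trapezoidal rule on the union of the simulation and observation grids
#' with linear interpolation. The normalized MAE divides by the maximum
#' observed concentration.
#'
#' @param sim an `"ivdds_trajectory"` (its `c_e_T` column is compared), or
#'   a two-column data.frame `(t, value)`.
#' @param obs_times observation times (s).
#' @param obs observed EES concentrations (amount/mL).
#' @param horizon integration horizon `T` (s); defaults to the last
#'   observation inside the simulated range.
#' @return list with `MAE` (amount/mL) and `nMAE` (fraction of max obs).
#' @export
mean_absolute_error <- function(sim, obs_times, obs, horizon = NULL) {
  if (inherits(sim, "ivdds_trajectory")) {
    st <- sim$t_s; sv <- sim$c_e_T
  } else {
    st <- sim[[1]]; sv <- sim[[2]]
  }
  .chk(length(obs_times) == length(obs) && length(obs) >= 2,
       "need at least 2 observations")
  if (is.null(horizon)) horizon <- min(max(obs_times), max(st))
  lo <- max(min(obs_times), min(st))
  .chk(horizon > lo, "empty overlap between simulation and observations")
  u <- .union_interp(st, sv, obs_times, obs, lo, horizon)
  mae <- .trapz(u$grid, abs(u$a - u$b)) / (horizon - lo)
  list(MAE = mae, nMAE = mae / max(obs))
}
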