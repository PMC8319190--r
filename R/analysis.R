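#' Moment-matched log-normal sampler
#'
#' Draws from a log-normal whose *arithmetic* mean and SD equal the
#' requested values: `sdlog^2 = log(1 + sd^2/mean^2)`,
#' `meanlog = log(mean) - sdlog^2/2`. With `sd = 0` the mean is returned
#' deterministically.
#'
#' @param n number of draws.
#' @param mean arithmetic mean (`> 0`).
#' @param sd arithmetic standard deviation (`>= 0`).
#' @return numeric vector of length `n`.
#' @export
rlnorm_matched <- function(n, mean, sd) {
  .chk(.is_num1(mean) && mean > 0, "mean must be > 0")
  .chk(.is_num1(sd) && sd >= 0, "sd must be >= 0")
  if (sd == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + sd^2 / mean^2))
  rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

.qlnorm_matched <- function(p, mean, sd) {
  if (sd == 0) return(rep(mean, length(p)))
  sdlog <- sqrt(log(1 + sd^2 / mean^2))
  qlnorm(p, log(mean) - sdlog^2 / 2, sdlog)
}

#' Sampled-parameter table for uncertainty and sensitivity analyses
#'
#' Lists the primitive (non-derived) model parameters with their means and
#' standard deviations. Derived parameters (`v_e`, `k_av`, `V_p_T`, `F_p`)
#' are never sampled independently; they are recomputed from the sampled
#' primitives. Parameters without a stored SD get `default_rel_sd` times
#' the mean (used for `t_rel` and the volumes, for which no experimental
#' spread is available).
#'
#' @param params validated bundle; per-field SDs are taken from the `sd`
#'   lists of its components.
#' @param scenario `"free"` or `"ivdds"`; the latter adds `t_rel`.
#' @param t_rel release time mean (s), required for the IV-DDS scenario.
#' @param default_rel_sd relative SD used where no SD is stored
#'   (default 0.10).
#' @param exclude parameters held fixed at their means. Default `"V_p_S"`:
#'   the systemic plasma volume is computed from body weight, a measured
#'   covariate rather than an uncertain model parameter, and sampling it
#'   would directly (and artificially) scale the maximum achievable
#'   concentration `c_max = ID / V_p_S`.
#' @return data.frame with columns `name`, `mean`, `sd`.
#' @export
param_distributions <- function(params, scenario = c("ivdds", "free"),
                                t_rel = NULL, default_rel_sd = 0.10,
                                exclude = "V_p_S") {
  scenario <- match.arg(scenario)
  tt <- params$tumor; pk <- params$pk
  get_sd <- function(lst, nm, mean) {
    v <- lst[[nm]]
    if (is.null(v)) default_rel_sd * mean else v
  }
  rows <- list(
    c("v_p", tt$v_p, get_sd(tt$sd, "v_p", tt$v_p)),
    c("v_e_av", tt$v_e_av, get_sd(tt$sd, "v_e_av", tt$v_e_av)),
    c("TT", tt$TT, get_sd(tt$sd, "TT", tt$TT)),
    c("PS", tt$PS, get_sd(tt$sd, "PS", tt$PS)),
    c("V_D", pk$V_D, get_sd(pk$sd, "V_D", pk$V_D)),
    c("V_p_S", pk$V_p_S, get_sd(pk$sd, "V_p_S", pk$V_p_S)),
    c("k_p", pk$k_p, get_sd(pk$sd, "k_p", pk$k_p)),
    c("k_t", pk$k_t, get_sd(pk$sd, "k_t", pk$k_t)),
    c("k_e", pk$k_e, get_sd(pk$sd, "k_e", pk$k_e)),
    c("VT", params$geometry$VT,
      get_sd(params$geometry$sd, "VT", params$geometry$VT))
  )
  if (scenario == "ivdds") {
    .chk(!is.null(t_rel) && t_rel > 0, "ivdds scenario requires t_rel > 0")
    rows <- c(rows, list(c("t_rel", t_rel, default_rel_sd * t_rel)))
  }
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[1], mean = as.numeric(r[2]), sd = as.numeric(r[3]))))
  df$sd[df$name %in% exclude] <- 0
  rownames(df) <- NULL
  df
}

## Map a matrix of sampled primitives (columns named as in
## param_distributions) to the batch parameter layout.
.samples_to_par <- function(S, t_rel_ref = NULL) {
  S <- as.data.frame(S)
  par <- S[c("v_p", "v_e_av", "TT", "PS", "V_D", "V_p_S", "k_p", "k_t",
             "k_e", "VT")]
  par$t_rel_scale <- if ("t_rel" %in% names(S)) S$t_rel / t_rel_ref else 1
  par
}

#' Monte Carlo uncertainty propagation
#'
#' Samples every primitive parameter from a moment-matched log-normal
#' (derived parameters are recomputed per sample), runs the requested
#' scenario for each sample, and returns the per-time-point mean and
#' standard deviation of the spatially averaged tumor plasma concentration
#' and of the tumor EES concentration.
#'
#' @param params validated bundle carrying per-field SDs.
#' @param scenario `"free"` or `"ivdds"`.
#' @param release,temperature IV-DDS trigger inputs (as in
#'   [simulate_ivdds()]).
#' @param dose a [dose_spec()] matching the scenario.
#' @param n number of Monte Carlo samples (default 1000).
#' @param seed integer seed; fixed seed gives bit-identical results.
#' @param duration,output_dt,dt simulation horizon (s), output sampling and
#'   integrator step of the batch path.
#' @param default_rel_sd relative SD for parameters without stored SDs.
#' @return object of class `"uncertainty_result"`: list with `times`,
#'   matrices `mean`/`sd` (columns `c_p_T_mean`, `c_e_T`), `n`, `seed`.
#' @export
monte_carlo_uncertainty <- function(params, scenario = c("ivdds", "free"),
                                    release = NULL, temperature = NULL,
                                    dose, n = 1000, seed = 1L,
                                    duration = 1200, output_dt = 20,
                                    dt = 0.5, default_rel_sd = 0.10) {
  scenario <- match.arg(scenario)
  .chk(.is_num1(n) && n >= 2, "n must be >= 2")
  t_rel_ref <- NULL
  if (scenario == "ivdds") {
    .chk(!is.null(release), "ivdds scenario requires a release table")
    t_rel_ref <- release$t_rel_s[nrow(release)]
  }
  dist <- param_distributions(params, scenario, t_rel = t_rel_ref,
                              default_rel_sd = default_rel_sd)
  set.seed(seed)
  S <- vapply(seq_len(nrow(dist)), function(i)
    rlnorm_matched(n, dist$mean[i], dist$sd[i]), numeric(n))
  colnames(S) <- dist$name
  par <- .samples_to_par(S, t_rel_ref)
  sim <- simulate_batch(par, scenario, ID = dose$ID, release = release,
                        temperature = temperature, duration = duration,
                        dt = dt, output_dt = output_dt)
  summ <- function(M) cbind(mean = rowMeans(M),
                            sd = apply(M, 1, sd))
  structure(list(times = sim$times,
                 c_p_T_mean = summ(sim$c_p_T_mean),
                 c_e_T = summ(sim$c_e_T),
                 n = n, seed = seed, scenario = scenario),
            class = "uncertainty_result")
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat(sprintf("Monte Carlo uncertainty (%s scenario, n = %d, seed = %d)\n",
              x$scenario, x$n, x$seed))
  i <- which.max(x$c_e_T[, "mean"])
  cat(sprintf("  peak EES: %.4g +/- %.4g at t = %g s\n",
              x$c_e_T[i, "mean"], x$c_e_T[i, "sd"], x$times[i]))
  invisible(x)
}

#' Root-mean-square error objective between two trajectories
#'
#' `Err = sqrt( (1/T) * integral_0^T (c_e - c_e_ref)^2 dt )`, evaluated by
#' the trapezoidal rule on the union grid with linear interpolation.
#'
#' @param sim,ref trajectories (`"ivdds_trajectory"`), two-column frames
#'   `(t, value)`, or numeric vectors on the common grid `times`.
#' @param horizon integration horizon `T` (s).
#' @param times common time grid when `sim`/`ref` are plain vectors.
#' @return the `Err` value (amount/mL).
#' @export
rmse_objective <- function(sim, ref, horizon = NULL, times = NULL) {
  pick <- function(x) {
    if (inherits(x, "ivdds_trajectory")) list(t = x$t_s, v = x$c_e_T)
    else if (is.data.frame(x)) list(t = x[[1]], v = x[[2]])
    else list(t = times, v = x)
  }
  a <- pick(sim); b <- pick(ref)
  .chk(!is.null(a$t) && !is.null(b$t), "times required for plain vectors")
  if (is.null(horizon)) horizon <- min(max(a$t), max(b$t))
  lo <- max(min(a$t), min(b$t))
  .chk(horizon > lo, "empty overlap")
  u <- .union_interp(a$t, a$v, b$t, b$v, lo, horizon)
  sqrt(.trapz(u$grid, (u$a - u$b)^2) / (horizon - lo))
}

#' Sobol global sensitivity analysis
#'
#' Variance decomposition of the RMSE objective ([rmse_objective()],
#' computed against the all-means reference run) with respect to the
#' primitive model parameters. Sample matrices follow the Saltelli design
#' built from Latin hypercube samples mapped through the moment-matched
#' log-normal quantile function; first-order indices use the Saltelli
#' estimator `S_i = mean(f_B * (f_ABi - f_A)) / V` and total indices the
#' Jansen estimator `T_i = mean((f_A - f_ABi)^2) / (2V)`. The full design
#' costs `n_base * (d + 2)` model runs, executed through the vectorized
#' batch integrator.
#'
#' @inheritParams monte_carlo_uncertainty
#' @param n_base number of base samples (default 512; index estimates at
#'   this size support parameter ranking rather than precise values).
#' @param horizon objective horizon `T` (s), default 1200 (20 min).
#' @param objective optional custom objective `function(t, ce_matrix,
#'   ce_ref)` returning one value per column; defaults to the RMSE
#'   objective against the reference run.
#' @param model_fn optional direct model `function(samples)` mapping a
#'   data.frame of sampled primitives (columns named as in
#'   [param_distributions()]) to one output value per row, bypassing the
#'   simulator entirely. Intended for estimator validation against models
#'   with known analytic Sobol indices.
#' @param dist optional data.frame overriding [param_distributions()].
#' @return object of class `"sensitivity_result"`: data.frame with
#'   `parameter`, `S1`, `ST`, plus attributes `n_base`, `seed`, `n_runs`,
#'   `variance`.
#' @export
sobol_sensitivity <- function(params, scenario = c("ivdds", "free"),
                              release = NULL, temperature = NULL, dose,
                              n_base = 512, seed = 1L, duration = 1200,
                              horizon = 1200, dt = 0.5, output_dt = 20,
                              default_rel_sd = 0.10, objective = NULL,
                              model_fn = NULL, dist = NULL) {
  scenario <- match.arg(scenario)
  .chk(.is_num1(n_base) && n_base >= 8, "n_base must be >= 8")
  t_rel_ref <- NULL
  if (scenario == "ivdds" && is.null(model_fn)) {
    .chk(!is.null(release), "ivdds scenario requires a release table")
    t_rel_ref <- release$t_rel_s[nrow(release)]
  }
  if (is.null(dist))
    dist <- param_distributions(params, scenario, t_rel = t_rel_ref,
                                default_rel_sd = default_rel_sd)
  d <- nrow(dist)
  set.seed(seed)
  U <- lhs::randomLHS(n_base, 2 * d)
  to_pars <- function(P) {
    S <- vapply(seq_len(d), function(i)
      .qlnorm_matched(P[, i], dist$mean[i], dist$sd[i]),
      numeric(nrow(P)))
    colnames(S) <- dist$name
    S
  }
  A <- to_pars(U[, seq_len(d), drop = FALSE])
  B <- to_pars(U[, d + seq_len(d), drop = FALSE])
  blocks <- list(A, B)
  for (i in seq_len(d)) {
    ABi <- A; ABi[, i] <- B[, i]
    blocks[[i + 2L]] <- ABi
  }
  S_all <- do.call(rbind, blocks)
  if (!is.null(model_fn)) {
    objective_vals <- model_fn(as.data.frame(S_all))
  } else {
  par_all <- .samples_to_par(S_all, t_rel_ref)
  sim <- simulate_batch(par_all, scenario, ID = dose$ID, release = release,
                        temperature = temperature, duration = duration,
                        dt = dt, output_dt = output_dt)
  ref_par <- .samples_to_par(
    matrix(dist$mean, 1, d, dimnames = list(NULL, dist$name)), t_rel_ref)
  ref <- simulate_batch(ref_par, scenario, ID = dose$ID, release = release,
                        temperature = temperature, duration = duration,
                        dt = dt, output_dt = output_dt)
  if (is.null(objective)) {
    sel <- sim$times <= horizon
    tgrid <- sim$times[sel]
    ce_ref <- ref$c_e_T[sel, 1]
    w <- diff(tgrid)
    objective_vals <- apply(sim$c_e_T[sel, , drop = FALSE], 2, function(ce) {
      d2 <- (ce - ce_ref)^2
      sqrt(sum(w * (d2[-1] + d2[-length(d2)]) / 2) / (max(tgrid) - min(tgrid)))
    })
  } else {
    objective_vals <- objective(sim$times, sim$c_e_T, ref$c_e_T[, 1])
  }
  }
  fA <- objective_vals[seq_len(n_base)]
  fB <- objective_vals[n_base + seq_len(n_base)]
  V <- stats::var(c(fA, fB))
  S1 <- ST <- numeric(d)
  for (i in seq_len(d)) {
    fABi <- objective_vals[(i + 1L) * n_base + seq_len(n_base)]
    S1[i] <- mean(fB * (fABi - fA)) / V
    ST[i] <- mean((fA - fABi)^2) / (2 * V)
  }
  structure(data.frame(parameter = dist$name, S1 = S1, ST = ST),
            n_base = n_base, seed = seed, n_runs = n_base * (d + 2L),
            variance = V, scenario = scenario,
            class = c("sensitivity_result", "data.frame"))
}

#' Parametric map of the plateau concentration over the two key indices
#'
#' Evaluates the plateau fraction `c_plateau / c_max` over a grid of the
#' release index (RI) and permeability index (PI). The `fixed_point`
#' method evaluates the closed-form plateau for every cell (milliseconds
#' for the ~1200-cell map); `full_simulation` runs the coupled model at a
#' constant trigger to quasi-steady state for every cell, adjusting
#' `t_rel` and `PS` per cell to hit the target indices while all other
#' parameters stay at their bundle values.
#'
#' @param RI_grid,PI_grid positive index grids (typically log-spaced).
#' @param method `"fixed_point"` or `"full_simulation"`.
#' @param params validated bundle (required for `full_simulation`).
#' @param systemic_feedback for `full_simulation`: keep systemic
#'   recirculation on (the in-vivo configuration) or freeze it (the
#'   idealized plateau assumptions).
#' @param dt batch integrator step (s) for `full_simulation`.
#' @return object of class `"parametric_map"`: list with `RI`, `PI`,
#'   matrix `plateau` (`RI x PI`), `EF` (the extraction-fraction second
#'   axis, one value per PI), and `method`.
#' @export
parametric_map <- function(RI_grid, PI_grid,
                           method = c("fixed_point", "full_simulation"),
                           params = NULL, systemic_feedback = TRUE,
                           dt = 0.5) {
  method <- match.arg(method)
  .chk(all(RI_grid > 0) && all(PI_grid > 0), "index grids must be positive")
  nR <- length(RI_grid); nP <- length(PI_grid)
  if (method == "fixed_point") {
    plateau <- outer(RI_grid, PI_grid, function(ri, pi)
      plateau_concentration(ri, pi))
  } else {
    .chk(inherits(params, "ivdds_params"),
         "full_simulation requires a validated bundle")
    cells <- expand.grid(RI = RI_grid, PI = PI_grid)
    m <- nrow(cells)
    if (m > 400)
      warning("large grid for full_simulation; consider fixed_point",
              call. = FALSE)
    par <- .par_row(params)[rep(1, m), ]
    F_p <- params$F_p
    par$PS <- cells$PI * F_p
    t_rel_cell <- cells$RI * params$tumor$TT
    # constant unit trigger; per-cell release time enters via the scale
    par$t_rel_scale <- t_rel_cell
    lam <- (F_p / params$tumor$v_e_av) * (1 - exp(-cells$PI))
    duration <- min(max(600, 10 / min(lam)), 20000)
    sim <- simulate_batch(par, "ivdds", ID = params$pk$V_p_S,  # c_dds(0)=1
                          const_rate = 1, duration = duration, dt = dt,
                          output_dt = duration / 10,
                          systemic_feedback = systemic_feedback)
    nt <- length(sim$times)
    plateau <- matrix(sim$c_e_T[nt, ] / pmax(sim$c_p_DDS_S[nt, ], 1e-300),
                      nR, nP)
  }
  structure(list(RI = RI_grid, PI = PI_grid, plateau = plateau,
                 EF = extraction_fraction(PI_grid, 1), method = method),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("parametric map (%s): %d x %d cells, plateau in [%.3g, %.3g]\n",
              x$method, length(x$RI), length(x$PI), min(x$plateau),
              max(x$plateau)))
  invisible(x)
}
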