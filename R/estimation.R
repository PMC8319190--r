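#' Intravital fluorescence trace
#'
#' Time courses of mean intra- and extravascular fluorescence intensity
#' extracted from intravital microscopy (background already subtracted).
#'
#' @param times frame times (s), strictly increasing.
#' @param I_v mean intravascular intensity (a.u.).
#' @param I_e mean extravascular intensity (a.u.).
#' @param background_subtracted flag recorded with the trace.
#' @return object of class `"fluorescence_trace"`.
#' @export
fluorescence_trace <- function(times, I_v, I_e, background_subtracted = TRUE) {
  .chk(length(times) == length(I_v) && length(times) == length(I_e),
       "times, I_v, I_e lengths differ")
  .chk(all(diff(times) > 0), "times must be strictly increasing")
  .chk(all(is.finite(I_v)) && all(is.finite(I_e)), "intensities must be finite")
  structure(list(times = as.numeric(times), I_v = as.numeric(I_v),
                 I_e = as.numeric(I_e),
                 background_subtracted = background_subtracted),
            class = "fluorescence_trace")
}

#' Blood sample concentration series
#'
#' @param times sampling times (s), strictly increasing, `>= 3` points.
#' @param concentration plasma concentration (amount/mL).
#' @param ID injected dose (amount).
#' @return object of class `"blood_samples"`.
#' @export
blood_samples <- function(times, concentration, ID = NA_real_) {
  .chk(length(times) == length(concentration) && length(times) >= 3,
       "need >= 3 samples")
  .chk(all(diff(times) > 0), "times must be strictly increasing")
  structure(list(times = as.numeric(times),
                 concentration = as.numeric(concentration), ID = ID),
            class = "blood_samples")
}

#' Bi-exponential plasma decay
#'
#' `C(t) = C0 * (alpha * exp(-lambda1 t) + (1 - alpha) * exp(-lambda2 t))`,
#' with the convention `lambda1 >= lambda2` (fast phase first).
#'
#' @param C0 zero-time intercept (amount/mL).
#' @param alpha fast-phase fraction in \[0,1\].
#' @param lambda1,lambda2 decay rates (1/s); `lambda2 = 0` is admitted as
#'   the limit of a non-eliminating slow phase.
#' @return object of class `"biexponential"`, callable via [predict()].
#' @export
biexponential <- function(C0, alpha, lambda1, lambda2) {
  .chk(.is_num1(C0) && C0 > 0, "C0 must be > 0")
  .chk(.is_num1(alpha) && alpha >= 0 && alpha <= 1, "alpha must be in [0,1]")
  .chk(.is_num1(lambda1) && lambda1 > 0, "lambda1 must be > 0")
  .chk(.is_num1(lambda2) && lambda2 >= 0, "lambda2 must be >= 0")
  if (lambda1 < lambda2) {           # enforce fast-first convention
    tmp <- lambda1; lambda1 <- lambda2; lambda2 <- tmp
    alpha <- 1 - alpha
  }
  structure(list(C0 = C0, alpha = alpha, lambda1 = lambda1,
                 lambda2 = lambda2),
            class = "biexponential")
}

#' @export
predict.biexponential <- function(object, times, ...) {
  with(object, C0 * (alpha * exp(-lambda1 * times) +
                       (1 - alpha) * exp(-lambda2 * times)))
}

## Closed-form two-compartment plasma decay. Directional convention of the
## micro-constant formulas: k_t is plasma->tissue, k_p tissue->plasma, k_e
## elimination from plasma (plasma loss rate = k_e + k_t, return = k_p).
.biexp_from_rates <- function(k_t, k_p, k_e, C0) {
  a <- k_e + k_t; b <- k_p
  disc <- (a + b)^2 - 4 * k_p * k_e
  .chk(disc >= 0, "degenerate kinetics: negative discriminant")
  lambda1 <- ((a + b) + sqrt(disc)) / 2
  lambda2 <- max(((a + b) - sqrt(disc)) / 2, 0)
  if (lambda1 == lambda2) {
    return(biexponential(C0, 1, lambda1, lambda2))
  }
  alpha <- (a - lambda2) / (lambda1 - lambda2)
  biexponential(C0, alpha, lambda1, lambda2)
}

#' Micro rate constants from a bi-exponential fit
#'
#' Literal evaluation of the printed micro-constant formulas:
#' `k_p = (1-alpha) lambda1 + alpha lambda2`,
#' `k_e = lambda1 lambda2 / k_p`,
#' `k_t = alpha (1-alpha) (lambda2 - lambda1)^2 / k_p`.
#' Under this parameterization `k_p` is the tissue-to-plasma constant and
#' `k_t` the plasma-to-tissue constant (the classical two-compartment
#' macro-to-micro inversion); see the methods vignette for how these labels
#' relate to the compartment-model equations.
#'
#' @param fit a [biexponential()].
#' @return named list `k_t`, `k_p`, `k_e` (1/s).
#' @examples
#' rate_constants(biexponential(1, 0.5, 2, 1))
#' @export
rate_constants <- function(fit) {
  .chk(inherits(fit, "biexponential"), "fit must be a biexponential")
  a <- fit$alpha; l1 <- fit$lambda1; l2 <- fit$lambda2
  k_p <- (1 - a) * l1 + a * l2
  if (k_p <= 0) stop("degenerate kinetics: zero denominator", call. = FALSE)
  list(k_t = a * (1 - a) * (l2 - l1)^2 / k_p,
       k_p = k_p,
       k_e = l1 * l2 / k_p)
}

#' Fit a bi-exponential to plasma concentration data
#'
#' Nonlinear least squares on log-concentration residuals, initialized by a
#' log-linear tail fit plus curve peeling of the fast phase. The returned
#' fit follows the `lambda1 >= lambda2` convention. A near mono-exponential
#' data set (fast phase indistinguishable) is flagged via the `degenerate`
#' attribute.
#'
#' @param samples a [blood_samples()] series with `>= 4` points.
#' @return a [biexponential()] with attributes `rss` and `degenerate`.
#' @export
fit_biexponential <- function(samples) {
  .chk(inherits(samples, "blood_samples"), "samples must be blood_samples")
  t <- samples$times; y <- samples$concentration
  .chk(length(t) >= 4, "need >= 4 samples")
  .chk(all(y > 0), "concentrations must be positive for the log-space fit")
  n <- length(t)
  tail_i <- seq.int(max(2L, n - max(2L, n %/% 2) + 1L), n)
  tail_fit <- lm(log(y[tail_i]) ~ t[tail_i])
  l2_0 <- max(-unname(coef(tail_fit)[2]), 1e-9)
  c2_0 <- exp(unname(coef(tail_fit)[1]))
  resid_early <- y - c2_0 * exp(-l2_0 * t)
  pos <- which(resid_early > 0 & seq_len(n) <= ceiling(n / 2))
  if (length(pos) >= 2) {
    peel <- lm(log(resid_early[pos]) ~ t[pos])
    l1_0 <- max(-unname(coef(peel)[2]), l2_0 * 2)
    c1_0 <- exp(unname(coef(peel)[1]))
  } else {
    l1_0 <- l2_0 * 10
    c1_0 <- max(y[1] - c2_0, 0.1 * c2_0)
  }
  df <- data.frame(t = t, ly = log(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ly ~ log(C1 * exp(-l1 * t) + C2 * exp(-l2 * t)),
      data = df,
      start = list(C1 = c1_0, C2 = c2_0, l1 = l1_0, l2 = l2_0),
      lower = c(1e-12, 1e-12, 1e-12, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # effectively mono-exponential data leave the second phase
    # unidentifiable and the two-phase fit singular; fall back to the
    # log-linear single-phase fit and flag the result
    mono <- lm(log(y) ~ t)
    lam <- max(-unname(coef(mono)[2]), 1e-12)
    sigma <- suppressWarnings(summary(mono)$sigma)  # may be ~0 on exact data
    if (sigma > 0.05)
      stop("bi-exponential fit failed (initializers: l1=",
           signif(l1_0, 3), ", l2=", signif(l2_0, 3), "): ",
           conditionMessage(fit), call. = FALSE)
    out <- biexponential(exp(unname(coef(mono)[1])), 1, lam,
                         lam * (1 - 1e-6))
    attr(out, "rss") <- sum(residuals(mono)^2)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  p <- coef(fit)
  C0 <- p[["C1"]] + p[["C2"]]
  out <- biexponential(C0, p[["C1"]] / C0, p[["l1"]], p[["l2"]])
  attr(out, "rss") <- sum(residuals(fit)^2)
  attr(out, "degenerate") <-
    (out$lambda1 - out$lambda2) / out$lambda1 < 1e-3 ||
    out$alpha < 1e-3 || out$alpha > 1 - 1e-3
  out
}

#' Initial volume of distribution
#'
#' `V_D = ID / C(2 min)`: injected dose divided by the first plasma
#' concentration time point.
#'
#' @param conc plasma concentration at the first sampling time (amount/mL).
#' @param ID injected dose (amount).
#' @return initial volume of distribution (mL).
#' @export
initial_distribution_volume <- function(conc, ID) {
  .chk(.is_num1(conc) && conc > 0, "concentration must be > 0")
  .chk(.is_num1(ID) && ID > 0, "ID must be > 0")
  ID / conc
}

## Exact per-linear-segment propagation of
##   dI_e/dt = alpha_c * I_v(t) - beta * I_e,   I_v linear per interval,
## with alpha_c = PS/(v_e (1-Hct)), beta = PS/(v_e k_av).
.forward_Ie <- function(times, I_v, PS, k_av, v_e, Hct_mv, Ie0 = I_v[1] * 0) {
  alpha_c <- PS / (v_e * (1 - Hct_mv))
  beta <- PS / (v_e * k_av)
  n <- length(times)
  Ie <- numeric(n)
  Ie[1] <- Ie0
  for (i in seq_len(n - 1L)) {
    h <- times[i + 1L] - times[i]
    a0 <- I_v[i]
    b0 <- (I_v[i + 1L] - I_v[i]) / h
    E <- exp(-beta * h)
    # particular solution of I_e' = alpha_c (a0 + b0 tau) - beta I_e
    Ie[i + 1L] <- Ie[i] * E +
      alpha_c * (a0 * (1 - E) / beta + b0 * (h / beta - (1 - E) / beta^2))
  }
  Ie
}

#' Fit vascular permeability and available volume fraction
#'
#' Forward-simulates the intensity-space exchange equation
#' `dI_e/dt = (PS / v_e) * (I_v(t)/(1 - Hct_mv) - I_e(t)/k_av)` with the
#' intravascular signal linearly interpolated, and minimizes the sum of
#' squared residuals to the observed extravascular signal over
#' `(PS, k_av)` by unconstrained optimization on transformed parameters
#' (log PS, logit k_av), multi-started from data-driven initializers.
#' Estimates are invariant to a common positive rescaling of
#' `(I_v, I_e)`.
#'
#' @param trace a [fluorescence_trace()] covering the uptake phase.
#' @param v_e extravascular volume fraction (known).
#' @param Hct_mv microvascular hematocrit (default 0.19).
#' @return list with `PS` (1/s), `k_av`, `rss`, `convergence` and the
#'   fitted extravascular curve `I_e_hat`; an unidentifiable trace
#'   (flat or zero intravascular signal) raises an error.
#' @export
fit_permeability <- function(trace, v_e, Hct_mv = 0.19) {
  .chk(inherits(trace, "fluorescence_trace"), "trace must be a fluorescence_trace")
  .chk(.is_num1(v_e) && v_e > 0 && v_e <= 1, "v_e must be in (0,1]")
  t <- trace$times; Iv <- trace$I_v; Ie <- trace$I_e
  if (max(abs(Iv)) <= 0)
    stop("unidentifiable: intravascular signal is identically zero",
         call. = FALSE)
  scale <- max(abs(Iv))                      # rescale for optimizer hygiene
  Iv <- Iv / scale; Ie_s <- Ie / scale
  obj <- function(par) {
    PS <- exp(par[1]); k_av <- stats::plogis(par[2])
    pred <- .forward_Ie(t, Iv, PS, k_av, v_e, Hct_mv, Ie0 = Ie_s[1])
    sum((pred - Ie_s)^2)
  }
  # slope-ratio initializers: early uptake slope ~ (PS/v_e) Iv/(1-Hct);
  # late-time ratio Ie/Iv ~ k_av/(1-Hct)
  early <- seq_len(max(3L, length(t) %/% 5))
  sl <- unname(coef(lm(Ie_s[early] ~ t[early]))[2])
  mIv <- mean(Iv[early])
  PS0 <- max(sl * v_e * (1 - Hct_mv) / max(mIv, 1e-6), 1e-5)
  late <- seq.int(max(1L, length(t) - 4L), length(t))
  k0 <- median(Ie_s[late] / pmax(Iv[late], 1e-9)) * (1 - Hct_mv)
  k0 <- min(max(k0, 0.05), 0.95)
  starts <- rbind(c(log(PS0), stats::qlogis(k0)),
                  c(log(PS0 * 5), stats::qlogis(0.5)),
                  c(log(PS0 / 5), stats::qlogis(0.5)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- optim(starts[i, ], obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || res$value < best$value) best <- res
  }
  PS <- exp(best$par[1]); k_av <- stats::plogis(best$par[2])
  if (k_av < 1e-4)
    stop("fit failure: k_av collapsed to the boundary", call. = FALSE)
  list(PS = PS, k_av = k_av, rss = best$value * scale^2,
       convergence = best$convergence,
       I_e_hat = .forward_Ie(t, Iv, PS, k_av, v_e, Hct_mv,
                             Ie0 = Ie_s[1]) * scale)
}

#' Tissue transit time from the early intravascular signal
#'
#' After a rapid bolus the arterial input is effectively a step, and with
#' exponential washout the tissue residue gives a step response
#' `I_v(t) = A * (1 - exp(-(t - t0)/TT))` for `t >= t0` (0 before). The
#' three parameters `(A, t0, TT)` are fit by least squares over the first
#' `window` seconds, with `A` profiled out analytically on a `(t0, TT)`
#' grid before a local refinement.
#'
#' @param trace a [fluorescence_trace()] whose segment starts before bolus
#'   arrival (only `I_v` is used).
#' @param window fit window (s), default 30.
#' @return transit time `TT` (s).
#' @export
estimate_transit_time <- function(trace, window = 30) {
  .chk(inherits(trace, "fluorescence_trace"), "trace must be a fluorescence_trace")
  sel <- trace$times <= window + 1e-12
  t <- trace$times[sel]; y <- trace$I_v[sel]
  .chk(length(t) >= 4, "window must cover >= 4 samples")
  if (max(y) - min(y) <= 0 || max(y) <= 0 ||
      unname(coef(lm(y ~ t))[2]) <= 0)
    stop("estimation error: intravascular signal does not rise",
         call. = FALSE)
  model <- function(t, t0, TT) ifelse(t >= t0, 1 - exp(-(t - t0) / TT), 0)
  sse <- function(t0, TT) {
    m <- model(t, t0, TT)
    denom <- sum(m^2)
    if (denom == 0) return(list(sse = sum(y^2), A = 0))
    A <- sum(m * y) / denom
    list(sse = sum((y - A * m)^2), A = A)
  }
  t0_grid <- seq(min(t), min(t) + (max(t) - min(t)) / 2, length.out = 25)
  TT_grid <- exp(seq(log(0.2), log(window * 2), length.out = 30))
  best <- list(sse = Inf)
  for (t0 in t0_grid) for (TT in TT_grid) {
    s <- sse(t0, TT)
    if (s$sse < best$sse) best <- c(s, t0 = t0, TT = TT)
  }
  ref <- optim(c(best$t0, log(best$TT)),
               function(p) sse(p[1], exp(p[2]))$sse,
               method = "Nelder-Mead",
               control = list(maxit = 1000, reltol = 1e-12))
  unname(exp(ref$par[2]))
}

#' Calibration for fluorescence-to-concentration conversion
#'
#' @param scale concentration per intensity unit (amount/mL per a.u.),
#'   from quantified plasma samples.
#' @param dequench_factor fold fluorescence increase upon complete release
#'   of the self-quenched dye (default 30.2).
#' @param Hct_mv microvascular hematocrit.
#' @param k_av available fraction of extravascular volume.
#' @return object of class `"calibration_spec"`.
#' @export
calibration_spec <- function(scale, dequench_factor = 30.2, Hct_mv = 0.19,
                             k_av) {
  .chk(.is_num1(scale) && scale > 0, "scale must be > 0")
  .chk(.is_num1(dequench_factor) && dequench_factor > 1,
       "dequench_factor must be > 1")
  .chk(.is_num1(k_av) && k_av > 0 && k_av <= 1, "k_av must be in (0,1]")
  structure(list(scale = scale, dequench_factor = dequench_factor,
                 Hct_mv = Hct_mv, k_av = k_av),
            class = "calibration_spec")
}

#' Convert fluorescence intensities to concentrations
#'
#' Free mode: plasma concentration `scale * I_v / (1 - Hct_mv)` (only the
#' plasma fraction of the vessel carries dye), EES concentration
#' `scale * I_e / k_av`. TSL mode: the pre-release intravascular baseline
#' is the quenched encapsulated signal; released drug dequenches by
#' `dequench_factor`, so the released plasma concentration is
#' `c_dds_baseline * (I_v - I_baseline) / ((dequench - 1) * I_baseline)`,
#' where `c_dds_baseline` is the known encapsulated plasma concentration;
#' EES as in free mode.
#'
#' @param trace a [fluorescence_trace()].
#' @param calib a [calibration_spec()].
#' @param mode `"free"` or `"tsl"`.
#' @param baseline_window for `mode = "tsl"`: time (s) before which frames
#'   are averaged into the pre-release baseline.
#' @param c_dds_baseline for `mode = "tsl"`: encapsulated plasma
#'   concentration at baseline (amount/mL).
#' @return data.frame with columns `t_s`, `c_plasma` (free/released drug in
#'   plasma) and `c_ees`.
#' @export
fluorescence_to_concentration <- function(trace, calib,
                                          mode = c("free", "tsl"),
                                          baseline_window = NULL,
                                          c_dds_baseline = NULL) {
  .chk(inherits(trace, "fluorescence_trace"), "trace must be a fluorescence_trace")
  .chk(inherits(calib, "calibration_spec"), "calib must be a calibration_spec")
  mode <- match.arg(mode)
  c_ees <- calib$scale * trace$I_e / calib$k_av
  if (mode == "free") {
    c_plasma <- calib$scale * trace$I_v / (1 - calib$Hct_mv)
  } else {
    .chk(!is.null(baseline_window) && !is.null(c_dds_baseline),
         "tsl mode requires baseline_window and c_dds_baseline")
    base_i <- trace$times <= baseline_window
    .chk(any(base_i), "no frames inside the baseline window")
    I0 <- mean(trace$I_v[base_i])
    .chk(I0 > 0, "baseline intravascular intensity must be positive")
    c_plasma <- c_dds_baseline * (trace$I_v - I0) /
      ((calib$dequench_factor - 1) * I0)
  }
  data.frame(t_s = trace$times, c_plasma = c_plasma, c_ees = c_ees)
}
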