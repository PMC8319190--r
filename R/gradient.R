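#' Inputs to the microvascular gradient model
#'
#' Dimensionless form of the quasi-steady gradient equations along the
#' normalized capillary coordinate `x` in \[0,1\]:
#' `dc_p/dx = k (c_e - c_p) + r * c_dds_sys` while encapsulated drug
#' remains (`c_dds(x) > 0`), with the release term switched off once the
#' local encapsulated concentration is exhausted. The encapsulated profile
#' is the linear ramp `c_dds(x) = max(0, c_dds_in - r * c_dds_sys * x)`.
#'
#' @param k permeability-to-perfusion ratio `PS/F_p` (dimensionless, `>= 0`).
#' @param r normalized release rate `TT/t_rel` (dimensionless, `>= 0`;
#'   0 means no release).
#' @param c_e_T tumor EES concentration (amount/mL), constant in `x`.
#' @param c_p_in inlet free-drug concentration (systemic free plasma
#'   concentration at the boundary), amount/mL.
#' @param c_dds_sys systemic encapsulated concentration driving the
#'   zero-order release term (amount/mL).
#' @param c_dds_in inlet encapsulated concentration (defaults to
#'   `c_dds_sys`), amount/mL.
#' @return object of class `"gradient_inputs"`.
#' @export
gradient_inputs <- function(k, r = 0, c_e_T = 0, c_p_in = 0,
                            c_dds_sys = 0, c_dds_in = c_dds_sys) {
  .chk(.is_num1(k) && k >= 0, "k must be >= 0")
  .chk(.is_num1(r) && r >= 0, "r must be >= 0")
  for (nm in c("c_e_T", "c_p_in", "c_dds_sys", "c_dds_in")) {
    val <- get(nm)
    .chk(.is_num1(val) && val >= 0, sprintf("%s must be >= 0", nm))
  }
  structure(list(k = k, r = r, c_e_T = c_e_T, c_p_in = c_p_in,
                 c_dds_sys = c_dds_sys, c_dds_in = c_dds_in),
            class = "gradient_inputs")
}

## Piecewise closed form of the quasi-steady profile.
## Segment with constant source s and exchange rate k, from (x0, c0):
##   k > 0: c_p(x) = A + (c0 - A) exp(-k (x - x0)),  A = c_e + s/k
##   k = 0: c_p(x) = c0 + s (x - x0)
## c_extr picks up k * integral(c_p - c_e) segment-wise in closed form.
.gradient_closed_form <- function(inp) {
  k <- inp$k; r <- inp$r
  s <- r * inp$c_dds_sys
  xstar <- if (s > 0) inp$c_dds_in / s else Inf
  x1 <- min(xstar, 1)
  segs <- list()
  add_seg <- function(x0, x1, c0, s) {
    if (x1 <= x0) return(NULL)
    list(x0 = x0, x1 = x1, c0 = c0, s = s)
  }
  segs["s1"] <- list(add_seg(0, x1, inp$c_p_in, s))
  c_at <- function(seg, x) {
    if (is.null(seg)) return(NULL)
    d <- x - seg$x0
    if (k > 0) {
      A <- inp$c_e_T + seg$s / k
      A + (seg$c0 - A) * exp(-k * d)
    } else seg$c0 + seg$s * d
  }
  extr_seg <- function(seg, x) {
    # k * integral_{x0}^{x} (c_p - c_e) dxi
    if (is.null(seg) || k == 0) return(0 * x)
    d <- x - seg$x0
    A <- inp$c_e_T + seg$s / k
    k * (A - inp$c_e_T) * d + (seg$c0 - A) * (1 - exp(-k * d))
  }
  int_seg <- function(seg, x) {
    # integral_{x0}^{x} c_p dxi
    if (is.null(seg)) return(0 * x)
    d <- x - seg$x0
    if (k > 0) {
      A <- inp$c_e_T + seg$s / k
      A * d + (seg$c0 - A) * (1 - exp(-k * d)) / k
    } else seg$c0 * d + seg$s * d^2 / 2
  }
  if (x1 < 1) {
    c_sw <- c_at(segs$s1, x1)
    if (is.null(c_sw)) c_sw <- inp$c_p_in   # degenerate: release exhausted at inlet
    segs["s2"] <- list(add_seg(x1, 1, c_sw, 0))
  }
  eval_all <- function(x, fun) {
    out <- numeric(length(x))
    for (seg in segs) {
      if (is.null(seg)) next
      lo <- x >= seg$x0 & x <= seg$x1
      out[lo] <- fun(seg, x[lo])
    }
    out
  }
  cum_before <- function(x, fun) {
    # cumulative quantity: segment contributions completed before x
    out <- numeric(length(x))
    for (seg in segs) {
      if (is.null(seg)) next
      inside <- x >= seg$x0 & x <= seg$x1
      after <- x > seg$x1
      out[inside] <- out[inside] + fun(seg, x[inside])
      out[after] <- out[after] + fun(seg, seg$x1)
    }
    out
  }
  list(
    xstar = xstar,
    c_p = function(x) eval_all(x, c_at),
    c_dds = function(x) pmax(0, inp$c_dds_in - s * x),
    c_extr = function(x) cum_before(x, extr_seg),
    c_p_int = function(x) cum_before(x, int_seg)
  )
}

#' Solve the microvascular concentration profile
#'
#' Evaluates the exact piecewise closed form of the quasi-steady gradient
#' equations on a grid of the normalized capillary coordinate. No iterative
#' solver is involved; the profile is deterministic in the inputs.
#'
#' @param inputs a [gradient_inputs()].
#' @param n_grid number of grid points (`>= 2`).
#' @return object of class `"gradient_profile"`: list with grid `x`, free
#'   profile `c_p_T`, encapsulated profile `c_p_DDS_T`, cumulative
#'   extracted amount `c_extr_T`, the spatial mean `c_p_mean`
#'   (`integral of c_p over [0,1]`), the switch point `xstar`, and the
#'   echoed `inputs`.
#' @export
solve_profile <- function(inputs, n_grid = 101) {
  .chk(inherits(inputs, "gradient_inputs"), "inputs must be gradient_inputs")
  .chk(.is_num1(n_grid) && n_grid >= 2, "n_grid must be >= 2")
  cf <- .gradient_closed_form(inputs)
  x <- seq(0, 1, length.out = n_grid)
  structure(list(
    x = x,
    c_p_T = cf$c_p(x),
    c_p_DDS_T = cf$c_dds(x),
    c_extr_T = cf$c_extr(x),
    c_p_mean = cf$c_p_int(1),
    xstar = cf$xstar,
    inputs = inputs,
    closed_form = cf
  ), class = "gradient_profile")
}

#' Total extracted amount at the venous end
#'
#' Closed-form value of `c_extr(x = 1) = k * integral (c_p - c_e) dx`
#' (amount per mL of plasma flow). May be negative when net back-diffusion
#' from the EES into plasma occurs.
#'
#' @param profile a solved [solve_profile()] result.
#' @return extracted amount at `x = 1` (amount/mL).
#' @export
extracted_amount <- function(profile) {
  .chk(inherits(profile, "gradient_profile"), "profile must be a gradient_profile")
  profile$closed_form$c_extr(1)
}

#' Plateau concentration from the two key indices
#'
#' During sustained triggered release both plasma and EES concentrations
#' converge to a plateau at which net extraction vanishes, so the EES
#' concentration equals the spatial mean of the plasma profile:
#' `C = integral c_p(xi; C) dxi`. Under the plateau assumptions (constant
#' systemic encapsulated concentration normalized to 1, zero inlet free
#' concentration) the right-hand side is affine in `C`, and the fixed point
#' is solved in closed form with `r = 1/RI` and `k = PI`. The result is the
#' plateau as a fraction of the maximum achievable concentration `c_max`
#' (the systemic encapsulated plasma concentration), in (0, 1\].
#'
#' @param RI release index `t_rel/TT`, `> 0` (vectorized).
#' @param PI permeability index `PS/F_p`, `> 0` (vectorized, recycled).
#' @return plateau fraction(s) `c_plateau / c_max`.
#' @examples
#' plateau_concentration(12.6, 0.26) # ~0.041, i.e. 4% of maximum
#' @export
plateau_concentration <- function(RI, PI) {
  .chk(is.numeric(RI) && all(is.finite(RI) & RI > 0), "RI must be > 0 and finite")
  .chk(is.numeric(PI) && all(is.finite(PI) & PI > 0), "PI must be > 0 and finite")
  n <- max(length(RI), length(PI))
  RI <- rep_len(RI, n); PI <- rep_len(PI, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    r <- 1 / RI[i]; k <- PI[i]
    I_of <- function(C) {
      inp <- gradient_inputs(k = k, r = r, c_e_T = C, c_p_in = 0,
                             c_dds_sys = 1, c_dds_in = 1)
      .gradient_closed_form(inp)$c_p_int(1)
    }
    i0 <- I_of(0); slope <- I_of(1) - i0
    out[i] <- i0 / (1 - slope)
  }
  out
}
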