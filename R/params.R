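#' ivdds: transport kinetics of intravascular triggered drug delivery systems
#'
#' Simulates local drug delivery by stimuli-responsive nanoparticles that
#' release their payload inside the target tissue's microvasculature
#' (IV-DDS, e.g. temperature-sensitive liposomes under hyperthermia).
#' The model couples a quasi-steady concentration gradient along the
#' normalized capillary coordinate to a compartmental pharmacokinetic
#' model of tumor interstitium, systemic plasma and systemic tissue.
#'
#' Units are fixed package-wide: time in seconds, volumes in mL, rate
#' constants in 1/s, concentrations in amount/mL.
#'
#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @importFrom deSolve ode
#' @importFrom jsonlite read_json write_json
#' @importFrom lhs randomLHS
#' @importFrom minpack.lm nlsLM nls.lm.control
#' @importFrom stats approx approxfun coef lm median optim plogis predict
#'   qlnorm qlogis qnorm residuals rlnorm rnorm runif sd splinefun var
#' @importFrom tools md5sum
#' @importFrom utils modifyList read.csv write.csv packageVersion
## usethis namespace: end
NULL

.chk <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}

.is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Tumor transport parameter set
#'
#' Bundles the microvascular transport parameters of the imaged tumor
#' segment: volume fractions, permeability-surface area product and tissue
#' transit time. Derivable fields (`v_p` from `v_v`, `v_e_av` from
#' `k_av * v_e`) are filled in and cross-checked when both sides are given.
#'
#' @param v_p plasma volume fraction (dimensionless, in \[0,1\]).
#' @param v_v vascular volume fraction; if given, `v_p = v_v * (1 - Hct_mv)`.
#' @param v_e extravascular volume fraction.
#' @param k_av available fraction of extravascular volume.
#' @param v_e_av available volume fraction (`k_av * v_e`).
#' @param PS vascular permeability-surface area product (1/s), `>= 0`.
#' @param TT tissue transit time (s), `> 0`.
#' @param Hct_mv microvascular hematocrit (default 0.19).
#' @param sd named list of per-field standard deviations (same units as the
#'   means) used by the uncertainty and sensitivity analyses.
#' @return object of class `"tumor_transport"`.
#' @export
tumor_transport <- function(v_p = NULL, v_v = NULL, v_e = NULL, k_av = NULL,
                            v_e_av = NULL, PS, TT, Hct_mv = 0.19, sd = list()) {
  .chk(.is_num1(PS) && PS >= 0, "PS must be a single finite number >= 0")
  .chk(.is_num1(TT) && TT > 0, "TT must be a single finite number > 0")
  .chk(.is_num1(Hct_mv) && Hct_mv >= 0 && Hct_mv < 1,
       "Hct_mv must be a fraction in [0,1)")
  if (is.null(v_p) && !is.null(v_v)) v_p <- v_v * (1 - Hct_mv)
  .chk(!is.null(v_p), "one of v_p or v_v is required")
  frac_fields <- list(v_p = v_p, v_v = v_v, v_e = v_e, k_av = k_av,
                      v_e_av = v_e_av)
  for (nm in names(frac_fields)) {
    val <- frac_fields[[nm]]
    if (!is.null(val))
      .chk(.is_num1(val) && val >= 0 && val <= 1,
           sprintf("%s must be a fraction in [0,1], got %s", nm,
                   format(val)))
  }
  if (!is.null(v_v) && !is.null(v_p)) {
    .chk(abs(v_p - v_v * (1 - Hct_mv)) < 1e-8,
         "inconsistent v_p: expected v_v * (1 - Hct_mv)")
  }
  if (is.null(v_e_av) && !is.null(k_av) && !is.null(v_e)) v_e_av <- k_av * v_e
  if (!is.null(v_e_av) && !is.null(k_av) && !is.null(v_e)) {
    .chk(abs(v_e_av - k_av * v_e) < 1e-8,
         "inconsistent v_e_av: expected k_av * v_e")
  }
  .chk(!is.null(v_e_av), "one of v_e_av or (k_av, v_e) is required")
  .chk(.is_num1(v_p) && v_p > 0, "v_p must be > 0")
  structure(list(v_p = v_p, v_v = v_v, v_e = v_e, k_av = k_av,
                 v_e_av = v_e_av, PS = PS, TT = TT, Hct_mv = Hct_mv,
                 sd = sd),
            class = "tumor_transport")
}

#' Systemic pharmacokinetic parameter set
#'
#' Two-compartment (plasma + tissue) systemic pharmacokinetics of the free
#' drug, with first-order elimination from plasma. Note on conventions: in
#' the compartment-model equations `k_p` multiplies the systemic plasma
#' concentration and `k_t` the systemic tissue concentration, whereas the
#' bi-exponential micro-constant formulas used in fitting label `k_p` the
#' tissue-to-plasma constant (see [rate_constants()] and the methods
#' vignette); the two conventions assign opposite roles to the same symbols
#' and are kept as-is, not swapped.
#'
#' @param V_D initial volume of distribution (mL), `> 0`.
#' @param V_p_S systemic plasma volume (mL), `> 0`.
#' @param k_p,k_t,k_e rate constants (1/s), `>= 0`.
#' @param sd named list of per-field standard deviations.
#' @return object of class `"systemic_pk"`.
#' @export
systemic_pk <- function(V_D, V_p_S, k_p, k_t, k_e, sd = list()) {
  for (nm in c("V_D", "V_p_S")) {
    val <- get(nm)
    .chk(.is_num1(val) && val > 0, sprintf("%s must be > 0", nm))
  }
  for (nm in c("k_p", "k_t", "k_e")) {
    val <- get(nm)
    .chk(.is_num1(val) && val >= 0, sprintf("%s must be >= 0", nm))
  }
  structure(list(V_D = V_D, V_p_S = V_p_S, k_p = k_p, k_t = k_t, k_e = k_e,
                 sd = sd),
            class = "systemic_pk")
}

#' Tumor geometry
#'
#' @param VT tumor (imaged segment) volume (mL).
#' @param v_p plasma volume fraction used to derive the tumor plasma volume
#'   `V_p_T = VT * v_p`.
#' @param sd named list of per-field standard deviations (for `VT`).
#' @return object of class `"tumor_geometry"` with fields `VT`, `V_p_T`.
#' @export
tumor_geometry <- function(VT, v_p, sd = list()) {
  .chk(.is_num1(VT) && VT > 0, "VT must be > 0")
  .chk(.is_num1(v_p) && v_p > 0 && v_p <= 1, "v_p must be in (0,1]")
  structure(list(VT = VT, V_p_T = VT * v_p, sd = sd),
            class = "tumor_geometry")
}

#' Dose specification
#'
#' @param ID injected dose (amount, e.g. ug or nmol), `> 0`.
#' @param form `"free"` (unencapsulated bolus) or `"encapsulated"` (IV-DDS).
#' @return object of class `"dose_spec"`.
#' @export
dose_spec <- function(ID, form = c("encapsulated", "free")) {
  .chk(.is_num1(ID) && ID > 0, "ID must be > 0")
  form <- match.arg(form)
  structure(list(ID = ID, form = form), class = "dose_spec")
}

#' Plasma perfusion from plasma volume fraction and transit time
#'
#' `F_p = v_p / TT`. The same relation links blood perfusion and vascular
#' volume fraction: `F / v_v = F_p / v_p = 1 / TT`.
#'
#' @param v_p plasma volume fraction, in (0, 1\].
#' @param TT tissue transit time (s), `> 0` (may be `Inf`, giving 0).
#' @return plasma perfusion rate `F_p` (mL plasma / mL tissue / s).
#' @examples
#' derive_perfusion(0.23, 5) # 0.046
#' @export
derive_perfusion <- function(v_p, TT) {
  .chk(is.numeric(v_p) && all(v_p > 0 & v_p <= 1),
       "v_p must be in (0,1]")
  .chk(is.numeric(TT) && all(TT > 0), "TT must be > 0")
  v_p / TT
}

#' First-pass extraction fraction
#'
#' Fraction of free drug removed from plasma by tissue during a single
#' microvascular pass: `EF = 1 - exp(-PS / F_p)`. Bounded in \[0, 1) and
#' strictly increasing in `PS` for fixed `F_p`.
#'
#' @param PS permeability-surface area product (1/s), `>= 0`. May also be
#'   given directly as the dimensionless ratio `PS/F_p` with `F_p = 1`.
#' @param F_p plasma perfusion (1/s), `> 0`.
#' @return extraction fraction in \[0, 1).
#' @examples
#' extraction_fraction(0.5, 1)      # ~0.39, rounds to 0.4
#' extraction_fraction(0.012, 0.047)
#' @export
extraction_fraction <- function(PS, F_p = 1) {
  .chk(is.numeric(F_p) && all(F_p > 0), "F_p must be > 0")
  .chk(is.numeric(PS) && all(PS >= 0), "PS must be >= 0")
  1 - exp(-PS / F_p)
}

#' Release and permeability indices
#'
#' The two dimensionless ratios that exclusively determine the plateau
#' concentration of an IV-DDS: the release index `RI = t_rel / TT` and the
#' permeability index `PI = PS / F_p`.
#'
#' @param t_rel release time (s), `> 0`.
#' @param TT tissue transit time (s), `> 0`.
#' @param PS permeability-surface area product (1/s).
#' @param F_p plasma perfusion (1/s), `> 0`.
#' @return object of class `"index_pair"`: list with `RI`, `PI`.
#' @examples
#' compute_indices(t_rel = 63, TT = 5, PS = 0.012, F_p = 0.047)
#' @export
compute_indices <- function(t_rel, TT, PS, F_p) {
  .chk(is.numeric(t_rel) && all(t_rel > 0), "t_rel must be > 0")
  .chk(is.numeric(TT) && all(TT > 0), "TT must be > 0")
  .chk(is.numeric(F_p) && all(F_p > 0), "F_p must be > 0")
  .chk(is.numeric(PS) && all(PS >= 0), "PS must be >= 0")
  structure(list(RI = t_rel / TT, PI = PS / F_p), class = "index_pair")
}

#' @export
print.index_pair <- function(x, ...) {
  cat(sprintf("release index R.I. = %.4g, permeability index P.I. = %.4g\n",
              x$RI, x$PI))
  invisible(x)
}

#' Validate and assemble a model parameter bundle
#'
#' Checks all parameter invariants, fills in derived quantities
#' (`F_p`, `EF`, `V_p_T`) and returns the bundle consumed by the
#' simulators. `F_p` is derived from `v_p / TT` unless explicitly
#' overridden; an override deviating from `v_p / TT` by more than 10%
#' triggers a warning.
#'
#' @param tumor a [tumor_transport()] object.
#' @param pk a [systemic_pk()] object.
#' @param geometry a [tumor_geometry()] object.
#' @param dose optional [dose_spec()].
#' @param F_p optional override for the derived plasma perfusion (1/s).
#' @return object of class `"ivdds_params"`.
#' @export
validate_params <- function(tumor, pk, geometry, dose = NULL, F_p = NULL) {
  .chk(inherits(tumor, "tumor_transport"), "tumor must be a tumor_transport object")
  .chk(inherits(pk, "systemic_pk"), "pk must be a systemic_pk object")
  .chk(inherits(geometry, "tumor_geometry"), "geometry must be a tumor_geometry object")
  if (!is.null(dose))
    .chk(inherits(dose, "dose_spec"), "dose must be a dose_spec object")
  F_p_derived <- derive_perfusion(tumor$v_p, tumor$TT)
  if (is.null(F_p)) {
    F_p <- F_p_derived
  } else {
    .chk(.is_num1(F_p) && F_p > 0, "F_p override must be > 0")
    if (abs(F_p - F_p_derived) / F_p_derived > 0.10)
      warning(sprintf(
        "F_p override %.4g deviates from v_p/TT = %.4g by more than 10%%",
        F_p, F_p_derived), call. = FALSE)
  }
  .chk(geometry$V_p_T <= geometry$VT, "V_p_T must not exceed VT")
  bundle <- structure(list(
    tumor = tumor, pk = pk, geometry = geometry, dose = dose,
    F_p = F_p, EF = extraction_fraction(tumor$PS, F_p),
    V_p_T = geometry$V_p_T,
    plasma_ratio = geometry$V_p_T / pk$V_p_S
  ), class = "ivdds_params")
  bundle
}

#' @export
print.ivdds_params <- function(x, ...) {
  cat("IV-DDS model parameter bundle\n")
  cat(sprintf("  tumor: v_p = %.3g, v_e_av = %.3g, TT = %.3g s, PS = %.3g /s\n",
              x$tumor$v_p, x$tumor$v_e_av, x$tumor$TT, x$tumor$PS))
  cat(sprintf("  derived: F_p = %.3g /s, EF = %.3g, V_p_T = %.3g mL (1:%.0f of V_p_S)\n",
              x$F_p, x$EF, x$V_p_T, 1 / x$plasma_ratio))
  cat(sprintf("  systemic: V_D = %.3g mL, V_p_S = %.3g mL, k_p = %.3g, k_t = %.3g, k_e = %.3g /s\n",
              x$pk$V_D, x$pk$V_p_S, x$pk$k_p, x$pk$k_t, x$pk$k_e))
  if (!is.null(x$dose))
    cat(sprintf("  dose: %g (%s)\n", x$dose$ID, x$dose$form))
  invisible(x)
}

#' Normal-theory confidence-interval half-width in SD units
#'
#' Half-width of a normal-theory confidence interval for a mean of `n`
#' replicates, expressed in units of one standard deviation:
#' `z_{1-(1-level)/2} / sqrt(n)`. For `n = 3` at the 90% level this is
#' 0.95 SD.
#'
#' @param n number of replicates.
#' @param level confidence level (default 0.90).
#' @return half-width in SD units.
#' @export
replication_ci_halfwidth <- function(n, level = 0.90) {
  .chk(.is_num1(n) && n >= 1, "n must be >= 1")
  .chk(.is_num1(level) && level > 0 && level < 1, "level must be in (0,1)")
  qnorm(1 - (1 - level) / 2) / sqrt(n)
}
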