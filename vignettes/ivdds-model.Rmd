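---
title: "Modeling drug transport for intravascular triggered delivery systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling drug transport for intravascular triggered delivery systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivdds)
```

## The delivery problem

Intravascular triggered drug delivery systems (IV-DDS) — temperature-sensitive
liposomes under local hyperthermia being the canonical example — do not rely
on nanoparticle extravasation. The carrier stays in the blood; the payload is
released *inside* the microvasculature of the target region, where an external
or internal trigger is present, and the released free drug then crosses the
vessel wall into the interstitium (the extravascular–extracellular space, EES).
Delivery is therefore governed by a race between three rates: how fast the
carrier releases (release time $t_{rel}$), how long the carrier spends inside
the target microvasculature (tissue transit time $TT$), and how fast released
drug is extracted across the vessel wall (permeability–surface area product
$PS$ relative to plasma perfusion $F_p$).

`ivdds` implements this transport model end to end: the axial concentration
gradient along the capillary, the coupled compartmental pharmacokinetics, the
estimation procedures that extract every model parameter from imaging and
blood-sampling data, and the three computational studies built on top
(parametric index map, Monte Carlo uncertainty propagation, Sobol sensitivity
analysis), plus seeded generators for every input so the whole pipeline is
testable without external data.

Units are fixed package-wide: time in seconds, volumes in mL, rate constants
in 1/s, concentrations in amount/mL.

## The vascular gradient model

Plasma traverses the tissue segment in time $TT$; position along the
capillary is expressed on the normalized coordinate $x \in [0,1]$, which is
equivalent to residence time. In quasi-steady state the free-drug plasma
concentration obeys

$$\frac{dc_p(x)}{dx} = \frac{PS}{F_p}\,\bigl(c_e - c_p(x)\bigr)
  + \frac{TT}{t_{rel}}\, c^{S}_{p,DDS}, $$

where the first term is transvascular exchange with the (well-mixed) EES
concentration $c_e$ and the second is zero-order release driven by the
systemic encapsulated concentration; the release term switches off at the
point $x^\*$ where the local encapsulated concentration
$c_{DDS}(x) = c_{DDS}(0) - (TT/t_{rel})\,c^{S}_{p,DDS}\,x$ reaches zero.
The cumulative extracted amount is
$c_{extr}(x) = (PS/F_p)\int_0^x (c_p - c_e)\,d\xi$.

Because $c_e$ and the release source are constant within one evaluation, the
profile is a piecewise linear first-order ODE with an exact
piecewise-exponential solution. `solve_profile()` evaluates that closed form
directly — there is no iterative solver in the inner loop — and the brute-force
Runge–Kutta integration of the same equations is kept in the test suite as an
independent oracle (agreement is checked to $10^{-6}$ over a $10\times10$
index grid). With no release and zero EES concentration the extracted
fraction at $x=1$ reduces to the first-pass extraction fraction
$EF = 1 - e^{-PS/F_p}$, which anchors the gradient model to the classical
perfusion/permeability-limited transport picture.

Exhausting the carrier early ($t_{rel} < TT$) simply truncates the source:
that is the "complete release during transit" regime in which the free-drug
profile approaches the profile of an ideal intra-arterial infusion.

### The plateau fixed point and the two indices

During sustained triggered release, plasma and EES concentrations converge to
a plateau at which net extraction vanishes, so the EES concentration equals
the spatial mean of the plasma profile:
$C = \int_0^1 c_p(\xi; C)\, d\xi$. Under the plateau assumptions (constant
systemic encapsulated concentration, normalized to 1; zero inlet free-drug
concentration) the right-hand side is affine in $C$, so
`plateau_concentration()` solves the fixed point in closed form. Writing
$k = PS/F_p$ (the permeability index *P.I.*) and $r = TT/t_{rel}$ (the
reciprocal of the release index *R.I.*), for $r \le 1$:

$$C = \frac{A\,r}{k\,(1-A)}, \qquad A = 1 - \frac{1 - e^{-k}}{k},$$

and for $r > 1$ the same affine solve applies to the two-segment profile.
The plateau depends on *nothing but* these two dimensionless ratios — that is
the central structural result the package exposes. At the measured
slow-release operating point ($R.I. = 12.6$, $P.I. = 0.26$):

```{r plateau}
plateau_concentration(RI = 12.6, PI = 0.26)
```

i.e. about 4% of the maximum possible uptake $c_{max}$ (the systemic
encapsulated plasma concentration), against roughly 32% for the fast-release
formulation ($R.I. = 1.6$). `parametric_map()` evaluates the whole
$R.I. \times P.I.$ landscape; the ~1200-cell map costs milliseconds through
the fixed point, and a constant-trigger full simulation of every cell is
available as a cross-check (`method = "full_simulation"`).

## The compartment model

The gradient model is embedded in a compartmental system: tumor EES, systemic
plasma (free and encapsulated drug), and systemic tissue. At every solver
evaluation the gradient profile is re-solved in closed form with the current
boundary values, the EES gains $F_p\,c_{extr}(1)/v_{e,av}$, and the outlet
concentration couples the tumor back to the systemic pool. Systemic free drug
follows two-compartment kinetics with elimination; the encapsulated pool is
depleted only by tumor release. Release is gated purely by the trigger:
`release_rate_at_temperature()` returns $1/t_{rel}(T)$, zero below the lowest
tabulated temperature, so no separate on/off switch exists.

Design choices worth stating explicitly:

* **Available volume fraction.** The EES equation uses
  $v_{e,av} = k_{av} \cdot v_e$, the volume fraction actually available to the
  drug, because only the product of the two factors is identifiable;
  `use_v_e_av = FALSE` restores the literal extravascular fraction.
* **Distribution-volume bookkeeping (`f_distr`).** Drug released into tumor
  plasma distributes rapidly into the initial distribution volume $V_D$
  rather than the (smaller) plasma volume. Three bookkeepings are
  implemented. The default (`"vd"`) treats $V_D$ as the systemic free-drug
  pool volume throughout, consistent with the bolus initial condition
  $c_p^S(0) = ID/V_D$; it is the only variant that conserves mass exactly
  (the test suite asserts the ledger to solver tolerance), because a single
  state variable cannot carry two direction-dependent pool volumes without
  creating or destroying amount. `"hybrid"` divides the exchanged amount by
  $V_D$ only for tumor-to-systemic flux (and by $V_p^S$ otherwise), and
  `"printed"` applies the literal switching factor $V_p^T/V_D$ to the
  concentration-based exchange term; both are retained for comparison and
  both leak ledger mass by construction.
* **Rate-constant conventions.** The micro-constant formulas used by the
  fitting path (`rate_constants()`) follow the classical two-compartment
  inversion, under which $k_p$ is the tissue-to-plasma constant and $k_t$ the
  plasma-to-tissue constant. The compartment-model equations, however, apply
  $k_p$ to the plasma concentration and $k_t$ to the tissue concentration —
  the opposite roles. The package evaluates each context exactly as written
  and does not silently swap: the estimation/generation path
  (`gen_blood_samples()`, `fit_biexponential()` + `rate_constants()`) is
  round-trip consistent in the directional convention, and
  `simulate_free()`/`simulate_ivdds()` evaluate the model equations with the
  bundle's named constants. The numerical difference for the measured values
  is small (the two constants differ by 1.4:1), but users combining the two
  paths should be aware of the labeling conflict.
* **Integrator.** Single runs use an adaptive explicit Runge–Kutta 4(5)
  (`deSolve`, `ode45`), relative tolerance $10^{-8}$, absolute $10^{-12}$;
  output sampling is interpolation only and does not affect the solution.
  Negative concentrations from solver overshoot are clipped to zero with a
  warning. The release switch ($c_{DDS} > 0$) is handled inside the gradient
  closed form, so no event detection is needed in time.
* **Boundary condition.** The inlet free-drug concentration is taken to be
  the systemic free plasma concentration — the natural reading of the
  arterial boundary for a recirculating pool — and is exposed through the
  gradient inputs rather than hard-coded.
* **Temperature.** Traces are linearly interpolated (in vivo sampling is
  every 2 s); a trace shorter than the simulation holds its last value and
  warns.

### Geometry assumptions

The systemic plasma volume and the simulated tumor-segment volume are not
identifiable from the transport data. The packaged configuration uses
$V_p^S = 1.2$ mL (typical mouse plasma volume, in practice computed from body
weight) and $VT$ chosen so the tumor-to-systemic plasma ratio is exactly
1:700. Under these values a 10-minute heating session releases roughly 7–11%
of the injected encapsulated dose — small enough that the single-pass
assumption (no re-release bookkeeping for recirculating carriers) holds, and
the test suite asserts the released fraction stays in the 5–15% band.

## Parameter estimation

Every transport parameter is estimated from data the synthetic module can
generate:

* `fit_permeability()` fits $(PS, k_{av})$ by forward-simulating the
  intensity-space exchange equation
  $dI_e/dt = (PS/v_e)\,\bigl(I_v/(1-Hct^{MV}) - I_e/k_{av}\bigr)$
  (exact per-segment propagation of the linear ODE with the intravascular
  signal interpolated linearly), minimizing squared residuals from
  multi-started transformed-parameter optimization. A useful consistency
  property: with the intravascular signal taken as the *spatial mean* of the
  gradient profile, the gradient model's EES equation is exactly this
  exchange equation with $v_e \to v_{e,av}$ — so the estimator is unbiased
  against the package's own simulator, which the recovery tests confirm to
  0.1%.
* `estimate_transit_time()` fits the step-response of an exponential-washout
  residue model, $I_v(t) = A(1 - e^{-(t-t_0)/TT})$, over the first 30 s
  after bolus arrival (the arterial input of a rapid bolus is effectively a
  step). The exact deconvolution family behind the published analyses is not
  fully specified; the step-response exponential fit is this package's
  declared, testable choice consistent with exponential washout, and
  recovery is verified across the 2–30 s span reported for human tumors.
* `fit_biexponential()` fits $C(t) = C_0(\alpha e^{-\lambda_1 t} +
  (1-\alpha)e^{-\lambda_2 t})$ in log space, initialized by tail fitting and
  curve peeling, with the fast-phase-first convention $\lambda_1 \ge
  \lambda_2$ (the convention is round-trip tested; effectively
  mono-exponential data fall back to a flagged single-phase fit).
  `rate_constants()` then evaluates the printed micro-constant formulas
  literally, and `initial_distribution_volume()` is dose over the first
  (2-minute) concentration.
* `fluorescence_to_concentration()` converts intensities using the plasma
  fraction $(1-Hct^{MV})$, the available volume fraction $k_{av}$, and — for
  triggered studies — the quenched-baseline referencing with the measured
  30.2-fold dequenching factor.

## Synthetic data

The generators emulate the *statistical structure* the estimators assume:
two-compartment bolus kinetics for blood samples, zero-order release mapped
through the percent-release formula for in vitro traces, an
exponential-ramp/hold/cool-down heating session sampled every 2 s, and
imaging traces produced by inverting the fluorescence conversion on a
simulated trajectory (including the quenched baseline and dequenching in the
triggered scenario). Noise is multiplicative log-normal (signal-proportional
detector noise) with an optional additive floor; the measurement-noise model
is a package choice, not an empirical calibration. Every generator is the
measurable inverse of its estimator at zero noise, and all randomness flows
through one integer seed. What passing recovery tests show is therefore
internal consistency under the assumed noise model — not robustness to
drift, motion artifacts, photobleaching, or model misspecification present
in real intravital data.

## Uncertainty and sensitivity analyses

Both analyses sample only *primitive* parameters; derived quantities
($F_p = v_p/TT$, $v_{e,av}$ as a single primitive, $V_p^T = VT \cdot v_p$)
are recomputed per sample, never sampled independently. Parameters are drawn
from log-normals moment-matched on the arithmetic mean and SD (the
distribution family is stated for the biological parameters; the
parameterization is this package's choice, unit-tested at $n = 10^5$).
Parameters without measured spread ($t_{rel}$, $VT$) get a 10%-of-mean SD.
The systemic plasma volume is held fixed by default (`exclude = "V_p_S"`):
it is computed from body weight, and sampling it would directly scale
$c_{max} = ID/V_p^S$ and swamp the transport parameters with what is really
dosimetry uncertainty. Parameter independence is assumed throughout — a
stated limitation, not a modeling claim.

`monte_carlo_uncertainty()` (default $n = 1000$, bit-reproducible under a
fixed seed, self-convergent against $n = 4000$ within 5%) returns per-time
mean and SD of the tumor plasma mean and EES concentrations.
`sobol_sensitivity()` uses a Saltelli design built from Latin hypercube
samples, with the Saltelli first-order and Jansen total-order estimators —
the published analyses cite an approximation whose formulas are not
reproducible from the text, so the estimator pair here is documented and
swappable, and only ranking-level agreement is claimed. At the desk scale
used in the tests (512 base samples, ~6700 model runs through the vectorized
batch integrator, under a minute on one CPU) the dominant-parameter ranking
$\{t_{rel}, TT, PS\}$ is stable across seeds; precise index values would
need the cluster-scale sample counts of the original studies.

The batch path (`simulate_batch()`) integrates all samples in lockstep with
fixed-step RK4 ($\Delta t = 0.5$ s by default), trading event-sharp accuracy
at the heater switch-off (sub-percent) for a ~1000-fold throughput gain over
per-sample adaptive integration; it is cross-checked against the adaptive
solver in the tests.

## Numerical edge cases

* $PS = 0$ (or $k = 0$): pure transport, closed form degenerates to a linear
  ramp; the free-drug simulation then reduces exactly to the analytic
  two-compartment decay (oracle-tested).
* Release exhausted at the inlet ($c_{DDS}(0) = 0$ with an active trigger):
  the release segment has zero length and the profile is pure exchange.
* Below-range temperatures yield *zero* release rather than extrapolation
  (the trigger is absent); above-range temperatures clamp at the highest
  tabulated rate. Interpolation of $t_{rel}(T)$ uses a shape-preserving
  monotone cubic (Fritsch–Carlson), not a global polynomial, because
  overshoot would produce negative release times; interpolation is done on
  release time and then inverted to a rate.
* Slope $\le 0$ in the release-time window, flat intravascular signals, and
  mono-exponential clearance data raise typed errors or degeneracy flags
  rather than returning misleading estimates.

## Problem sizes used by the checks

The packaged studies are sized for a single CPU: gradient-oracle grids of
$10\times10$ at $10^5$ integration steps, parametric maps of $30\times40$
cells (fixed point) and $5\times5$ (full simulation), Monte Carlo at
$n = 1000$ vs $4000$, Sobol at 512 base samples, and 100-replicate noisy
recovery studies. These reproduce the structure and rankings of the
full-scale analyses; absolute index values at cluster-scale sample counts
are out of scope.

## Known limitations

* No cellular uptake sink (the model drug is chosen for negligible cell
  uptake); EES concentration represents drug *available* for uptake.
* No carrier extravasation, no multi-pass re-release bookkeeping beyond the
  well-mixed systemic pool, no hyperthermia-induced perfusion changes, no
  spatial heterogeneity of transport parameters.
* The in vivo plateau for fast-release carriers sits above the idealized
  fixed point (recirculating released drug raises the inlet concentration);
  the package reproduces both numbers but does not force agreement — the
  with-recirculation plateau is asserted only to within 15% of the fixed
  point.
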