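# ivdds — transport kinetics of intravascular triggered drug delivery systems

Stimuli-responsive nanoparticles such as temperature-sensitive liposomes
(TSL) can release their drug payload *inside* the blood vessels of a target
region — a tumor under local hyperthermia — instead of relying on slow
nanoparticle extravasation. The released free drug then crosses the vessel
wall into the interstitium within seconds. How much drug such an
intravascular triggered drug delivery system (IV-DDS) can deliver is decided
by a race between three rates: carrier release (release time *t*<sub>rel</sub>),
microvascular transit (tissue transit time *TT*), and transvascular
extraction (permeability–surface area product *PS* relative to plasma
perfusion *F*<sub>p</sub>, summarized by the first-pass extraction fraction
*EF* = 1 − e<sup>−PS/F<sub>p</sub></sup>).

`ivdds` implements the complete computational model of this process for
pharmacologists and delivery-system engineers:

* a **quasi-steady vascular gradient model** — the exact piecewise closed
  form of the free- and encapsulated-drug concentration profiles along the
  normalized capillary coordinate, with zero-order triggered release;
* a **compartmental model** coupling the tumor interstitium (EES) to
  systemic plasma and tissue, driven by a measured temperature trace and a
  temperature-dependent release-time table;
* the **plateau analysis**: the maximum achievable tumor concentration
  depends *only* on two dimensionless ratios, the release index
  *R.I.* = *t*<sub>rel</sub>/*TT* and the permeability index
  *P.I.* = *PS*/*F*<sub>p</sub>, and is solved as a closed-form fixed point
  (`plateau_concentration()`, `parametric_map()`);
* **parameter estimation** from intravital fluorescence and blood-sampling
  data: permeability and available-volume fitting, transit-time
  step-response deconvolution, bi-exponential pharmacokinetic fitting with
  micro rate-constant inversion, fluorescence-to-concentration conversion
  including the 30.2× dequenching of a self-quenched dye;
* **Monte Carlo uncertainty propagation** (moment-matched log-normal
  parameter sampling) and **Sobol global sensitivity analysis**
  (Saltelli/Jansen estimators over an LHS design), run through a vectorized
  batch integrator;
* **seeded synthetic-data generators** for every input the pipeline
  consumes, each the exact inverse of its estimator at zero noise.

## Worked example

The packaged configuration carries the in-vivo measured transport and
pharmacokinetic parameters of a rodent tumor segment:

```r
library(ivdds)
params <- invivo_params()
params
#> IV-DDS model parameter bundle
#>   tumor: v_p = 0.23, v_e_av = 0.28, TT = 5 s, PS = 0.012 /s
#>   derived: F_p = 0.047 /s, EF = 0.225, V_p_T = 0.00171 mL (1:700 of V_p_S)
#>   systemic: V_D = 8.99 mL, V_p_S = 1.2 mL, k_p = 0.00129, k_t = 0.0009, k_e = 0.0008 /s
#>   dose: 100 (encapsulated)
```

The two key indices for the fast- and slow-release formulations
(*t*<sub>rel</sub> = 8.2 s and 63.0 s at 42 °C), and their plateau
concentrations as fractions of the maximum possible uptake *c*<sub>max</sub>:

```r
compute_indices(t_rel = 8.2,  TT = 5.0, PS = params$tumor$PS, F_p = params$F_p)
#> release index R.I. = 1.64, permeability index P.I. = 0.2553
compute_indices(t_rel = 63.0, TT = 5.0, PS = params$tumor$PS, F_p = params$F_p)
#> release index R.I. = 12.6, permeability index P.I. = 0.2553

plateau_concentration(RI = c(1.64, 12.6), PI = 0.2553)
#> [1] 0.31812835 0.04149425
```

The fast formulation can reach ~32% of *c*<sub>max</sub>, the slow one only
~4% — an ~8× faster release buys an ~8–10× higher plateau, which is why
release time is the single most important engineering parameter. A full
triggered-delivery simulation (10-minute 42 °C heating session, 100 units
encapsulated dose):

```r
heat <- gen_temperature_trace()                    # ramp, hold to 600 s, cool-down
traj <- simulate_ivdds(params, synthetic_release_table("fTSL"), heat,
                       dose_spec(100, "encapsulated"),
                       duration = 1200, output_dt = 60)
traj[traj$t_s %in% c(0, 300, 600, 660, 1200), ]
#>     t_s   c_e_T c_p_T_mean  c_p_S  c_t_S c_p_DDS_S eliminated
#> 1     0  0.0000     0.0000 0.0000 0.0000   83.3333     0.0000
#> 6   300 23.2922    24.1218 0.2283 0.0253   81.2691     0.1491
#> 11  600 25.1289    25.0562 0.5531 0.1589   77.1047     1.0214
#> 12  660  4.0937     0.9346 0.5141 0.1911   76.9978     1.2539
#> 21 1200  0.2544     0.2484 0.2476 0.3063   76.9978     2.6227
```

Columns are the tumor EES concentration, the spatial mean of tumor plasma
free drug (the quantity an intravascular imaging signal sees), systemic
plasma and tissue free drug, the encapsulated pool, and the cumulative
eliminated amount (all concentrations in amount/mL). The EES climbs to a
plateau of ~25 amount/mL (~30% of *c*<sub>max</sub> = 83.3) while the
trigger is on, then washes out rapidly once heating stops; only ~7% of the
injected dose is released during the session, the rest keeps circulating
encapsulated. `mass_ledger(traj)` confirms the amount balance closes to
solver tolerance at every time point.

## Package layout

| Area | Functions |
| --- | --- |
| Parameters & indices | `tumor_transport()`, `systemic_pk()`, `validate_params()`, `derive_perfusion()`, `extraction_fraction()`, `compute_indices()` |
| Release kinetics | `percent_release()`, `estimate_release_time()`, `release_rate_at_temperature()`, `synthetic_release_table()` |
| Gradient model | `gradient_inputs()`, `solve_profile()`, `extracted_amount()`, `plateau_concentration()` |
| Compartment model | `simulate_ivdds()`, `simulate_free()`, `mass_ledger()`, `mean_absolute_error()` |
| Estimation | `fit_permeability()`, `estimate_transit_time()`, `fit_biexponential()`, `rate_constants()`, `initial_distribution_volume()`, `fluorescence_to_concentration()` |
| Studies | `parametric_map()`, `monte_carlo_uncertainty()`, `sobol_sensitivity()`, `rmse_objective()`, `simulate_batch()` |
| Synthetic data | `gen_temperature_trace()`, `gen_fluorescence_traces()`, `gen_blood_samples()`, `gen_release_trace()` |
| I/O & CLI | `load_config()`, `save_config()`, `read_timeseries_csv()`, `write_timeseries_csv()`, `ivdds_cli()` |

The methods vignette (`vignettes/ivdds-model.Rmd`) documents the model
equations, conventions (rate-constant labeling, distribution-volume
bookkeeping, interpolation and noise-model choices), the geometry
assumptions behind the packaged configuration, and known limitations.
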