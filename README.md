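# ureadose

Urea kinetic dosing and treatment-frequency prescription for home
haemodialysis (HHD).

Patients on HHD with portable low-dialysate-flow machines dialyse on
flexible weekly rhythms — one to seven sessions a week, usually short.
Adequacy guidelines pose the weekly target as a standard Kt/V (stdKt/V) of
2.3 volumes/week pooling dialytic and residual kidney clearance, but give no
direct way to choose the per-session dose (eKt/V) and the number of weekly
sessions (TF) that *reach* it. `ureadose` closes that loop for clinicians
and modellers:

* a **two-pool variable-volume urea kinetic simulator** of weekly dialysis
  cycles at periodic steady state, with spKt/V, eKt/V and stdKt/V
  (`simulate_weekly_cycle()`), plus the usual bedside estimators
  (`spktv_daugirdas()`, `ektv_from_spktv()`, `kru_from_urine()`);
* **simulation-grid regression** per treatment schedule and blood-sampling
  day (480-point grids over Kru, Kd, G, Td) yielding the linear dose
  formula, with the canonical published constants built in:

  stdKt/V = a + b · KRUn + c · eKt/V,  KRUn = Kru/V × 35

  (`derive_coefficients()`, `canonical_coefficients()`);
* a **prescription engine** inverting the formula,
  eKt/V_req = (2.3 − a − b·KRUn)/c, selecting the minimum feasible weekly
  frequency under a deliverable-dose cap and drawing the prescription graph
  (`prescribe_frequency()`, `prescription_graph()`);
* a **seeded synthetic cohort generator** emulating the session-level
  moment structure of an HHD population, and **agreement statistics**
  (Bland–Altman, regression, paired t) to validate formula against
  simulator with no clinical data (`generate_cohort()`,
  `evaluate_agreement()`, `frequency_reduction_report()`).

## Worked example

A patient with residual clearance Kru = 2 mL/min and urea distribution
volume V = 30 L on five sessions a week, delivering eKt/V 0.6 per session:

```r
library(ureadose)
stdktv_formula(canonical_coefficients(5), normalize_kru(2, 30), ektv = 0.6)
#> [1] 2.891133
```

2.89 volumes/week — above the 2.3 target, so there is room to reduce. The
prescription engine scans frequencies under the 0.7 per-session dose cap:

```r
prescribe_frequency(Kru = 2, V = 30)
#> Prescription for Kru = 2.00 mL/min, V = 30.0 L (KRUn = 2.33):
#>  frequency ektv_req renal_sufficient feasible
#>          1   2.7661            FALSE    FALSE
#>          2   1.1607            FALSE    FALSE
#>          3   0.7322            FALSE    FALSE
#>          4   0.4955            FALSE     TRUE
#>          5   0.4092            FALSE     TRUE
#>          6   0.2943            FALSE     TRUE
#>          7   0.1953            FALSE     TRUE
#> -> 4 session(s)/week at eKt/V >= 0.496 (predicted stdKt/V 2.30)
```

Four sessions a week at eKt/V ≥ 0.50 suffice; three would need 0.73, just
over the cap. The full kinetic route for the same patient:

```r
pt  <- patient_kinetics(V_total = 30000, Kru = 2, G = 6)
cyc <- simulate_weekly_cycle(pt, parse_schedule("12345", 1),
                             session_rx(Kd = 160, Td = 150),
                             weekly_uf = 5000)
cyc
#> Weekly cycle at periodic steady state (5 sessions/week, affine solver)
#>   day pre_conc_equilibrated post_conc_equilibrated  spktv   ektv
#> 1   1                0.8716                 0.4619 0.8573 0.6963
#> 2   2                0.6573                 0.3474 0.8568 0.7023
#> 3   3                0.5543                 0.2959 0.8577 0.7057
#> 4   4                0.5079                 0.2726 0.8582 0.7076
#> 5   5                0.4870                 0.2621 0.8585 0.7086
#> stdKt/V = 3.319 v/wk; mass balance error 6.86e-15; converged: TRUE
```

Concentrations are urea nitrogen in mg/mL of water; the Monday session
follows the weekend gap, hence its higher pre-dialysis level. See the
vignette (`vignettes/urea-kinetic-dosing.Rmd`) for the model, its closure
parameters, the stdKt/V definition and the derivation plan.

A thin CLI wrapping the same functions ships in `inst/cli/ureadose`
(`prescribe`, `graph`, `synth-cohort`, `derive`).

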