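# bindkin

Quantitative analysis of protease–substrate interaction data for the
streptococcal C5a peptidase (ScpA) and its substrate, the complement
anaphylatoxin C5a — and, more generally, for any 1:1 enzyme–ligand system
characterized by the same four assay types. The package is aimed at protein
biochemists and biophysicists who need a reproducible, scriptable workup of:

- **fluorogenic progress-curve kinetics** under the minimal Van Slyke–Cullen
  mechanism (E + S →<sup>k1</sup> ES →<sup>k2</sup> E + P, both steps
  irreversible; k<sub>cat</sub> = k2, K<sub>m</sub> = k2/k1),
- **SPR sensorgrams** fit globally with the 1:1 Langmuir model plus a
  drifting baseline (dR/dt = k<sub>a</sub>C(R<sub>max</sub> − R) −
  k<sub>d</sub>R; K<sub>D</sub> = k<sub>d</sub>/k<sub>a</sub>),
- **solution competition binding**, where the equilibrium surface response
  R<sub>eq</sub> reports free enzyme after competition with a solution
  ligand; the solution complex is the exact quadratic root of the
  mass-action equilibrium, giving K<sub>D,sol</sub>,
- **isothermal titration calorimetry** under the one-set-of-sites (Wiseman)
  isotherm with perfusion-cell displacement bookkeeping, giving K<sub>A</sub>,
  N and ΔH, and
- a **thermodynamic linkage report**: ΔG°<sub>bind</sub> = RT ln K<sub>D</sub>,
  ΔΔG° = RT ln (K<sub>D</sub>/K<sub>D,ref</sub>), energy partition between
  exosite and active-site contacts, fold changes, and salt-series summaries
  (R = 1.986 cal mol⁻¹ K⁻¹, T = 298 K).

Because no raw instrument files are publicly deposited for this system, the
package ships synthetic-data generators that emulate each instrument at the
published assay designs (substrate ladders, analyte dilution series,
titration schedules) with a seeded Gaussian noise model, so every fitting
stage is testable end to end.

## Worked example

Simulate a noisy SPR concentration series at the reference interaction
(k<sub>a</sub> = 13.1 × 10⁴ M⁻¹s⁻¹, k<sub>d</sub> = 4.4 × 10⁻³ s⁻¹,
top analyte concentration 90 nM, 2-fold dilutions, 200 s per phase) and
refit it globally:

```r
library(bindkin)
params <- langmuir_params(ka = 13.1e4, kd = 4.4e-3, Rmax = 35, drift = -0.01)
design <- spr_design(top_conc = 90e-9)
cycles <- gen_sensorgrams(params, design,
                         noise_model("gaussian", sd = 0.5, seed = 1))
fit <- fit_sensorgrams_global(cycles)
print(fit)
#> 1:1 Langmuir global fit (2406 points, chi2 = 0.269)
#>   ka = 1.316e+05 +/- 1.9e+03 M^-1 s^-1
#>   kd = 0.004402 +/- 0.00013 s^-1
#>   KD = 33.44 nM
delta_g_bind(fit$KD)
#> -10.2 kcal/mol (1 d.p.)
```

The fitted rate constants recover the generating values within their
standard errors, and the derived K<sub>D</sub> of ~33 nM corresponds to a
binding free energy of −10.2 kcal/mol. The report layer assembles the full
ligand-panel table from mean constants, recomputing ΔΔG° against a declared
reference:

```r
rep <- build_report(c5a_binding_constants(), "rhC5a (150 mM NaCl)")
rep$table[c(1, 6, 7), c("label", "ka_e4", "kd_e3", "KD_nM", "dG_bind", "ddG")]
#>                 label ka_e4 kd_e3 KD_nM dG_bind ddG
#> 1 rhC5a (150 mM NaCl) 13.10   4.4    34   -10.2 0.0
#> 6          rhC5a_core  3.52   8.5   240    -9.0 1.2
#> 7            rhC5a_dR  6.17  11.8   191    -9.2 1.0
```

Here the core fragment binds 1.2 kcal/mol more weakly than full-length C5a
and the des-Arg form 1.0 kcal/mol more weakly, quantifying the exosite
(core) versus C-terminal tail contributions to substrate recognition.

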