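---
title: "Models and methods: enzyme kinetics and binding thermodynamics of a C5a peptidase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: enzyme kinetics and binding thermodynamics of a C5a peptidase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindkin)
```

`bindkin` implements the complete quantitative workup of a
protease–substrate interaction study: the streptococcal C5a peptidase ScpA
(assayed as the catalytically dead S512A mutant for binding work) against
the complement anaphylatoxin C5a and a panel of truncations and point
mutants. Four assay types feed one thermodynamic report. This vignette
documents the models, their assumptions, the tunable parameters, the
synthetic-data generators, and the numerical choices — in enough detail that
a reader can judge what a passing test suite does and does not establish.

## Progress-curve kinetics: the Van Slyke–Cullen mechanism

Cleavage of a self-quenched fluorogenic C5a substrate is monitored as a
fluorescence rise. Curves are fit with the minimal Van Slyke–Cullen
mechanism,

$$\mathrm{E} + \mathrm{S} \xrightarrow{k_1} \mathrm{ES} \xrightarrow{k_2}
\mathrm{E} + \mathrm{P},$$

with both steps irreversible, so $k_{cat} = k_2$ and $K_m = k_2/k_1$.
**This $K_m$ is not the Michaelis constant** $(k_{-1}+k_2)/k_1$ of the
reversible scheme — there is no $k_{-1}$. Users comparing constants across
mechanisms should keep the distinction in mind; under both schemes the
steady-state rate law is $v = k_{cat} E_0 S/(K_m + S)$, which is what the
data constrain.

`simulate_progress()` integrates the full mass-action system (no
steady-state approximation) with `deSolve::lsoda`, rtol $10^{-8}$ and
atol $10^{-12} S_0$. The system is mildly stiff — ES equilibrates on a
$1/(k_1 S + k_2) \approx 1$ s timescale while product formation takes
$\sim 10^3$ s at the assay's 180 pM enzyme — hence the stiff-capable
integrator. The observable is $F(t) = F_0 + \varphi\,[\mathrm{P}](t)$ with a
shared gain $\varphi$ (AU per M product) and baseline $F_0$.

`fit_progress_global()` fits one $(k_{cat}, K_m, \varphi, F_0)$ set to all
curves of an experiment simultaneously, parameterized in
$(\log k_{cat}, \log K_m, \log\varphi, F_0)$ for positivity and
conditioning. Initial guesses are deterministic and data-driven: $F_0$ from
the first signal points, $\varphi$ from the amplitude of the largest curve,
$K_m$ at the median substrate concentration, $k_{cat}$ from the initial
slope. The gain and baseline are shared across curves (one substrate lot,
one plate); this is the configuration the assay design justifies.
Spontaneous substrate hydrolysis is handled by subtracting matched
enzyme-free control wells (`correct_background()`), modelled in the
generator as a slow linear rise (default 0.1% of full scale per 1000 s).

A limiting-case subtlety the tests encode explicitly: for
$E_0 \ll S_0 \ll K_m$ the product curve approaches the pseudo-first-order
form $P(t) = S_0(1 - e^{-(k_{cat}/K_m) E_0 t})$, but the leading correction
is first order in $S_0/K_m$. At the assay's lowest design point
($S_0 = 16$ nM, $S_0/K_m \approx 0.09$) the deviation is $\sim$2% of full
scale; the 2% closed-form agreement is therefore asserted at $K_m/100$,
genuinely inside the limit, together with a scaling check that the
deviation is proportional to $S_0/K_m$.

## SPR: global 1:1 Langmuir fitting with a drifting baseline

Sensorgrams follow $dR'/dt = k_a C (R_{max} - R') - k_d R'$ for the bound
signal $R'$, solved in closed form per phase: during association
$R'(t) = R_{eq}(1 - e^{-(k_a C + k_d)t})$ with
$R_{eq} = k_a C R_{max}/(k_a C + k_d)$, and after the buffer switch at
$t_{assoc}$ the bound signal decays as $e^{-k_d (t - t_{assoc})}$. A linear
baseline drift and a response offset are added per cycle. The analytic form
is verified against numeric integration of the rate law to
$10^{-6} R_{max}$ in the tests.

`fit_sensorgrams_global()` shares $k_a$, $k_d$, $R_{max}$ across all cycles
of a dilution series and fits drift and offset per cycle (a shared drift is
an option). $k_a$ and $R_{max}$ are fitted on the log scale; $k_d$ on the
natural scale with a lower bound of zero so a no-dissociation limit is
representable rather than asymptotic. Design conventions: six 2-fold
dilutions from the top concentration (a 32-fold range), 200 s per phase,
1 s sampling, dissociation modelled as an instantaneous switch to $C = 0$
(no injection-dispersion model); mass-transport limitation is deliberately
out of model, as the analysis this package reproduces fit pure 1:1
Langmuir.

Replicate statistics follow the per-experiment-first convention:
$K_{D,i} = k_{d,i}/k_{a,i}$ per experiment, then mean ± sample (n−1) SD
across experiments. `mean(kd)/mean(ka)` differs from `mean(KD)` by a few
percent on real scatter; the tests bound this discrepancy at 3% across the
bundled 13-row reference panel, and `summarize_binding_constants()` makes
the convention explicit.

## Competition binding: exact mass-action quadratic

Pre-incubated mixtures of enzyme (fixed total $E_{tot}$ = 700 nM) and a
solution competitor (0–2000 nM) are injected over a surface bearing the
core ligand. The equilibrium response reports free enzyme:

$$R_{eq} = R_{min} + (R_{max} - R_{min})
\frac{E_{free}}{K_{D,core} + E_{free}}, \qquad
E_{free} = E_{tot} - [\mathrm{EC}],$$

with the solution complex the physically valid (minus) root of the 1:1
mass-action quadratic,

$$[\mathrm{EC}] = \tfrac{1}{2}\left(s - \sqrt{s^2 - 4 E_{tot} C_{tot}}
\right), \quad s = E_{tot} + C_{tot} + K_{D,sol}.$$

The plus branch exceeds $\min(E_{tot}, C_{tot})$ and is rejected by
construction. Numerically the root is evaluated in the conjugate form
$2 E_{tot} C_{tot} / (s + \sqrt{s^2 - 4 E_{tot} C_{tot}})$, which is immune
to the cancellation that the textbook form suffers when competitor is in
large excess; the tests verify agreement with a bisection oracle to
$10^{-12}$ M over a $10^{-10}$–$10^{-5}$ M grid and at concentration ratios
up to $10^6$.

`fit_kdsol()` fits $(K_{D,sol}, R_{max})$ with $E_{tot}$, $K_{D,core}$ and
$R_{min}$ fixed (the convention of the solution-affinity method this
implements: only $R_{max}$ among the response parameters is floated). The
surface-response expression is the hyperbolic free-ligand form; re-binding
and surface-site depletion are not modelled, and the mixture is assumed at
equilibrium at injection time. A titration whose curve never drops
(unidentifiable $K_{D,sol}$) is flagged rather than reported with a tight
wrong answer: the fit sets `identifiable = FALSE` when the standard error
on $\log K_{D,sol}$ exceeds one decade. A missing zero-competitor anchor is
recorded as a warning in the fit object.

## ITC: one set of sites with perfusion bookkeeping

For a perfusion (overflow) cell of volume $V_0$, after $i$ injections of
volume $v$ the working concentrations are

$$M_{t,i} = M_0\frac{1 - \Delta V/2V_0}{1 + \Delta V/2V_0}, \qquad
X_{t,i} = X_s\frac{\Delta V/V_0}{1 + \Delta V/2V_0}, \qquad
\Delta V = i\,v.$$

The cumulative heat of the one-set-of-sites isotherm is the closed form
$Q = (N M_t \Delta H V_0/2)\,[B - \sqrt{B^2 - 4X_t/(N M_t)}]$ with
$B = 1 + X_t/(N M_t) + 1/(N K_A M_t)$, equal to
$\Delta H V_0 [\mathrm{bound}]$ — verified against a bisection equilibrium
oracle to $10^{-9}$ relative. Per-injection heats include the displacement
correction $\Delta Q_i = Q_i - Q_{i-1} + (v/V_0)(Q_i + Q_{i-1})/2$.

At the default design (18 µM cell, 170 µM syringe, 19 × 2.5 µL) each
injection advances the molar ratio by ≈ 0.118; with displacement
bookkeeping the ratio reaches ≈ 2.5 by injection 19 — a saturating
titration. The 19-injection default was chosen to pass molar ratio 2 with
margin; note that naive bookkeeping (19 × 0.118 ≈ 2.2) understates the
final ratio because displacement concentrates the titrant relative to the
macromolecule.

`fit_one_site()` fits $(N, \log K_A, \Delta H)$ plus an optional constant
dilution-heat offset, discarding the first injection by default (the
universal partial-delivery artifact; on noise-free synthetic data exclusion
moves $K_A$ by <1%, which the tests assert). At the system's affinity the
c-value $N K_A M_0 \approx 585$ — a steep but fittable isotherm; fits with
c > $10^4$ carry an identifiability warning on $K_A$. Derived quantities
use $K_D = 1/K_A$, $\Delta G = -RT\ln K_A$,
$\Delta S = (\Delta H - \Delta G)\cdot 1000/T$, so
$\Delta G = \Delta H - T\Delta S/1000$ holds exactly. The instrument runs
at 298.15 K but derived energies are reported at the 298 K reference
temperature of the energy tables (both exposed as arguments). The derived
$\Delta S$ from $\Delta H = -9.4$ kcal/mol and $K_D = 30.8$ nM is
+2.8 cal mol⁻¹ K⁻¹; published summary tables for this system quote 2.3,
presumably an independent mean over experiments — the package always
reports the self-consistent derived value and does not force agreement.

## Thermodynamic report and sign conventions

Energies use R = 1.986 cal mol⁻¹ K⁻¹ and T = 298 K.
$\Delta G^\circ_{bind} = RT\ln K_D$ (−10.2 kcal/mol at 34 nM) and

$$\Delta\Delta G^\circ = +RT\ln(K_D/K_{D,ref}),$$

**positive for weaker binders**. Published footnotes sometimes print this
formula with a leading minus sign while tabulating positive values for
weaker binders; this package fixes the convention stated above, which
reproduces the tabulated column, and documents it here rather than
following the printed formula literally.

`energy_fraction()` has two explicit modes because the two headline
percentages of this analysis use different denominators: the *remainder*
mode, $100(|\Delta G_{tot}| - \Delta\Delta G)/|\Delta G_{tot}|$, expresses
the share of binding energy retained by the core interaction (≈ 88% of
10.2 kcal/mol); the *component* mode, $100\,\Delta\Delta G/|\Delta G_{tot}|$,
expresses one residue's share of a stated sub-total (≈ 83% of the
1.2 kcal/mol tail contribution). No implicit mode inference is performed.
Display rounding follows the tabulation conventions: $k_a$ to 3 s.f. on the
$\times 10^4$ scale, $k_d$ on the $\times 10^{-3}$ scale, $K_D$ in nM,
energies to 1 d.p.

## Synthetic data: what it emulates and what it does not

The generators (`gen_progress()`, `gen_sensorgrams()`, `gen_competition()`,
`gen_itc()`) reproduce the published assay designs as defaults: substrate
ladder 16–500 nM with 180 pM enzyme, 8000 s at 2 s sampling in
quadruplicate; six 2-fold analyte dilutions with 200 s phases; 700 nM
enzyme vs 0–2000 nM competitor (2-fold ladder plus the zero anchor); and
the calorimeter schedule above. Noise is homoscedastic additive Gaussian
with seeded, restartable RNG (the caller's RNG state is restored, so there
is no hidden global random state); identical parameters, design and seed
give bit-identical output. Default noise levels — 0.5% of full scale
(fluorescence), 0.5 RU (SPR), 1 RU (competition), 0.2 µcal (ITC) — are
conventional instrument figures chosen once; the true replicate variances
of the original instruments are unreported.

What the generators do **not** emulate: photobleaching and inner-filter
effects, mass-transport limitation and injection dispersion on the sensor
surface, capture-chip ligand leaching, baseline/peak integration of raw
calorimeter power traces, and heteroscedastic or correlated noise.
Parameter-recovery tests on this synthetic data therefore establish the
correctness and identifiability of the estimators under the stated designs
— not robustness to instrument artifacts absent from the noise model.

## Numerical choices, degenerate inputs, limitations

- All fits use Levenberg–Marquardt (`minpack.lm::nls.lm`) with numeric
  Jacobians; standard errors come from the fit covariance
  ($\sigma^2 (J^\top J)^{-1}$) with delta-method transfer to the natural
  scale for log-fitted parameters.
- Flat progress curves (no signal) are rejected with an error rather than
  returning a confident near-zero $k_{cat}$; singular fit covariances mark
  the fit unidentifiable with infinite SEs.
- The quadratic and Wiseman discriminants are clamped at zero against
  rounding; analytically they are strictly positive for valid inputs.
- File I/O is tidy long CSV (`series_id`, `x`, `y`) plus a JSON sidecar for
  metadata; all writes are atomic (temp file + rename) and a run manifest
  records package version, seeds and configuration. The package is a
  library, not a shell tool: the exported functions and this document are
  the interface, and `scripts/acceptance.R` is the reproducibility entry
  point.
- Problem sizes in the tests are chosen for a desk-scale run: the
  noise-free acceptance round trips use the full published designs (24,006
  progress points; 2,406 sensorgram points; 9 titration points; 18
  injections), while module-level unit tests use coarser sampling of the
  same designs.
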