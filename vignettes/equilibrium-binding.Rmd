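---
title: "Equilibrium binding analysis: models, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium binding analysis: models, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equibind)
```

`equibind` implements the quantitative workflow used to characterize how a
nucleic-acid-binding protein domain (the motivating case is an HMG-box domain
that binds both DNA and double-stranded RNA with high affinity and low
specificity) engages its ligands at equilibrium: anisotropy titrations,
competition experiments, salt-dependence electrostatics, stoichiometric gel
shifts, and an alanine-scan panel comparison. This vignette is the package's
account of the underlying models, the tunable parameters, and the places
where we had to make a genuine design choice.

## The binding model and ligand depletion

A fluorescence anisotropy titration holds a labeled probe (nucleic acid) at a
fixed total concentration $R_t$ and titrates protein to a total $L_t$. The
probe's anisotropy rises from a lower baseline $A_0$ to an upper baseline as
it is bound. Because the probes used in this kind of work bind with $K_D$
values of a few nM while the probe itself is at 2–3 nM, the free protein is
*not* approximately equal to the total: the hyperbolic (Langmuir) isotherm is
wrong and the bound fraction must come from the mass-balance quadratic

$$f_q(R_t, L_t, K_{D1}) =
\frac{(R_t + L_t + K_{D1}) - \sqrt{(R_t + L_t + K_{D1})^2 - 4R_tL_t}}{2R_t}.$$

High-affinity ligands additionally show a weak second transition at high
protein concentration (a low-specificity binding event in the µM range), so
the full observed anisotropy is modeled as two transitions, the second one
hyperbolic because no depletion is possible at µM protein:

$$A = A_0 + (A_1 - A_0)\, f_q(R_t, L_t, K_{D1})
        + (A_2 - A_1)\frac{L_t}{L_t + K_{D2}}.$$

Numerical choices:

* `bound_fraction_quadratic()` evaluates the root in the multiply-conjugate
  form $2L_t / (b + \sqrt{b^2 - 4R_tL_t})$, $b = R_t+L_t+K_{D1}$, which does
  not cancel catastrophically at $L_t \gg K_{D1}$.
* Below $R_t = 10^{-15}$ M the quadratic is numerically degenerate
  (difference of nearly equal numbers divided by $R_t$), and the function
  switches to the Langmuir limit, which is exact there to better than
  $10^{-7}$ relative.
* All concentrations are molar everywhere inside the package; table headers
  carry an explicit `_M` suffix. Unit conversions happen only at I/O.

## Fitting titrations

`fit_single_titration()` minimizes unweighted squared residuals (the data are
plate-reader anisotropies with approximately constant noise, and the
historical practice this reproduces — spreadsheet-style fitting — is also
unweighted). Dissociation constants are optimized as $\log_{10} K_D$ with
bounds $[10^{-12}, 10^{-3}]$ M, which enforces positivity and makes the step
size scale-free; baselines are unbounded. Because the SSR surface in
$\log_{10} K_D$ can have shallow side basins, the optimizer
(Levenberg–Marquardt, `minpack.lm`) is started from every decade spanned by
the titrant range (and for the two-transition model from every ordered pair
of decades); the best converged start wins. Standard errors come from the
Gauss–Newton covariance $\hat\sigma^2 (J^\top J)^{-1}$ at the optimum and are
mapped to the natural scale by the delta method.

Replicates are fitted independently and then summarized
(`aggregate_replicates()`: mean, sd, sem of the per-replicate $K_{D1}$),
matching the "average ± s.e.m. of *n* technical replicates" convention,
rather than fitted globally. Repeated instrument reads of the same well are
averaged before fitting.

### When is a second transition "detected"?

The one- vs two-transition decision is not stated as a rule in the source
experiments, so `select_model()` makes it explicit and testable. The second
transition is accepted only if **all** of:

* the two-transition fit improves AICc by ≥ 2;
* $K_{D2} > K_{D1}$ (the second transition is the weaker one);
* $K_{D2} \le 10\times$ the maximum titrant concentration — a transition
  entirely beyond the range of the data is not evidence;
* $|A_2 - A_1|$ exceeds 3× the residual noise of the fit.

All four thresholds are arguments with these defaults. In 200 simulated
clean one-site titrations the rule claims a spurious second transition in
well under 5% of cases (checked in the test suite).

## Competition and the IC50 → K_I conversion

Mutually exclusive binding of a labeled ligand L and unlabeled competitor C
to protein P is solved exactly by `solve_competition()`: the free-protein
residual is strictly monotone on $[0, P_t]$, so a bracketed root plus Newton
polishing gives the unique speciation with mass-balance residuals below
$10^{-12}$ relative. `ic50_from_exact_model()` then finds, again by monotone
search, the total competitor that halves the labeled complex.

Measured curves are fitted with a four-parameter logistic in
$\log_{10} C_t$ (`fit_competition_curve()`), and the IC50 is converted with
the Nikolovska–Coleska depletion-corrected equation

$$K_I = \frac{[I]_{50}}{[L]_{50}/K_{DL} + [P]_0/K_{DL} + 1},$$

with the free concentrations computed from the totals via the binary
quadratic. The literature using this equation does not always state how the
free concentrations are obtained; with this choice the conversion round-trips
against the exact speciation solver to machine precision throughout the
regime $P_t \le 5K_{DL}$, $L_t \le P_t$ (the test suite enforces ≤ 15%,
which is the documented validity claim; the observed error is ~$10^{-13}$).
A flat curve — e.g. the no-protein control — is recognized by an AICc
comparison against a constant model and flagged rather than fitted.

## Salt dependence and counterion release

Protein–nucleic-acid association releases territorially bound cations from
the polyanion; polyelectrolyte theory predicts
$\mathrm{d}\log_{10}K_A / \mathrm{d}\log_{10}[M^+] = -Z\psi$, a straight
line in log–log space. `fit_log_linear()` regresses $\log_{10}(1/K_D)$ on
$\log_{10}[M^+]$ by OLS — the association-constant convention makes
salt-weakened binding give the familiar negative slopes.

* $\psi$, the degree of cation association per phosphate, defaults to
  **0.695**. The slope/counterion pairs this package is built to reproduce
  (−5.7 → 8.2 and −6.0 → 8.7) imply $\psi$ = 0.695 and 0.690 respectively —
  the difference is rounding of the printed slopes; both values are
  double-stranded-polymer-like, and $\psi$ is a plain argument everywhere it
  enters.
* Temperature defaults to 298.15 K (room-temperature binding reactions).
* The salt axis is total monovalent cation (e.g. a 9:1 KCl:NaCl series),
  not ionic strength.

`decompose_binding_energy()` splits the observed free energy at a reference
salt $M_{ref}$ (default 0.15 M, the physiological end of a typical series)
into $\Delta G_{nel} = -RT\ln(10)\,b$ (the 1 M extrapolation, where the
electrostatic term vanishes by the standard-state choice) and
$\Delta G_{el} = -RT\ln(10)\,m\log_{10}M_{ref}$. The additivity
$\Delta G_{obs} = \Delta G_{el} + \Delta G_{nel}$ is an identity by
construction and is asserted, not approximated.

## Stoichiometric EMSA and breakpoint detection

A stoichiometric titration runs at nucleic acid far above $K_D$ (2 µM versus
low-nM constants), so added protein is quantitatively bound and species
fractions rise linearly until a stoichiometric corner.
`simulate_sequential_binding()` solves the sequential, non-cooperative model
$P + N \rightleftharpoons PN$, $P + PN \rightleftharpoons P_2N$ exactly.

Two design points deserve emphasis, because we got both wrong before
simulating:

1. **Which series shows the 2:1 point.** The bound *nucleic-acid* fraction
   $f_{B1} + f_{B2}$ saturates near ratio 1 — once every ligand carries at
   least one protein, it stops moving. The series that saturates at the
   final stoichiometry is the cumulative **protein occupancy per ligand**,
   $f_{B1} + 2f_{B2}$ (`protein_occupancy()`), which rises with unit slope
   to 2.
2. **Breakpoint model.** For a monotone rise-to-plateau series the classical
   continuous two-segment broken stick is right, and `find_breakpoint()`
   uses it. But the B1 fraction is *not* monotone: it peaks at the 1:1 point
   and decays as the 2:1 complex cannibalizes it. A two-segment line fitted
   to that rise–fall–flat shape puts its knot far below the apex even on
   ideal sharp-cornered data (at 0.85 for a perfect unit tent) — the model
   is misspecified, not the data noisy. For series detected as
   rise-then-fall (interior maximum, terminal drop > 25% of the rise),
   `find_breakpoint()` therefore fits a two-knot (three-segment) continuous
   piecewise line and reports the apex knot, i.e. the end of the rising
   phase. A single straight line is preferred (no breakpoint reported) when
   the broken model does not improve AICc by ≥ 2.

With stepwise constants 2 nM and 20 nM at 2 µM ligand, the simulated B1
series saturates at ratio 0.957 and the occupancy at 1.961 — the corners are
rounded because the separation $K_{D2}/K_{D1} = 10$ permits some 2:1 complex
before the 1:1 point is reached. The corners sharpen to exactly 1 and 2 only
when *both* $K_{D2}/K_{D1}$ and $N_t/K_{D2}$ diverge (tested as a monotone
convergence property); increasing $N_t/K_{D1}$ alone does not sharpen the B1
apex at fixed $K_{D2}/K_{D1}$, a point easy to get wrong when reasoning
about "stoichiometric" conditions.

## Alanine-scan panel analysis

`compute_krel()` forms $K_{rel} = \bar K_{D}(\text{mutant})/\bar
K_{D}(\text{wild type})$ per substrate with first-order error propagation
(relative sds in quadrature) — matching a ± s.d. reporting style; a
bootstrap is deliberately not the default. `compare_substrates()` tests
DNA-vs-RNA impact on $\log_{10}K_D$ replicates with Welch's unequal-variance
t-test. The phrase sometimes seen in figure legends, "Student's t-test
assuming non-parametric distribution", is self-contradictory; log-scale
Welch is the defensible reading (affinities are ratio-scale, their logs
approximately normal), and a Wilcoxon rank-sum alternative is available via
`method = "wilcoxon"`. Degenerate zero-variance inputs are resolved exactly
(equal constants → p = 1, separated constants → p = 0) rather than erroring.
The test's empirical size at $\alpha = 0.05$ under a lognormal null with
n = 3 per group is confirmed to sit in [0.03, 0.07] by simulation.

`classify_panel()` counts mutants weakened ≥ `fold_threshold` (default
2.5-fold) for either substrate, those among them hit harder on RNA, and the
same counts restricted to basic residues. The basic/other annotation is a
required input column: whether histidine counts as basic is a judgment call
that belongs to the annotator, not to string matching inside the package.

## The synthetic-data generators

No raw instrument data accompany the experiments this package models, so
`simulate_titration()`, `simulate_competition()`, `simulate_salt_series()`,
`simulate_emsa()` and `simulate_mutant_panel()` generate every input class
the pipeline consumes. They emulate the experimental designs: triplicate
titrations read three times each, 16 two-fold dilutions from 1 µM, probe at
2 nM (DNA) or 3 nM (RNA), Gaussian anisotropy noise of sd 0.003 per read (a
plausible plate-reader magnitude; none is reported in the source
experiments, so this was chosen once to match typical error bars and is
configurable), lognormal scatter on salt-series $K_D$s, lane-loading
variation on gels, and a 48-mutant panel with apparent affinities spanning
~0.7–590 nM whose designed composition (17 affected basic residues, 11 of
them RNA-dominant) mirrors the published panel's printed summary counts.
Every generator is a pure function of (parameters, seed): the caller's RNG
stream is saved and restored, and identical seeds give identical output.

What the generators do **not** emulate: fluorescence-intensity weighting of
anisotropy when the quantum yield changes on binding, plate-position or
drift artifacts, smeared or partially transferred gel bands, and any
systematic (non-random) error. Parameter-recovery results on synthetic data
therefore validate the estimators under the stated noise model, not the
instruments.

## Validation scale

The property suite runs at fixed problem sizes chosen to make the checks
statistically meaningful while keeping the default test run fast: 10,000
random systems for the closed-form vs numeric-root equivalence, 1,000 for
speciation mass balances, 200 seeded simulations for parameter recovery at
the triplicate design (median $|K_{D1}|$ error ≤ 10%) and for the
model-selection false-positive rate (≤ 5%), 150 for the K_I round trip, and
100 for interval coverage (≥ 80%). These sizes are the package's validation
conditions and are stated here so they can be reproduced or scaled up.

## Known limitations

* No cooperative (Hill) or kinetic models; everything is equilibrium.
* Competition handles exactly one competitor species.
* The two-transition model treats the second site as depletion-free; if a
  second transition occurred at nM protein this would be wrong, but then it
  would not be a "weak" transition.
* Langmuir gel fits assume complete transfer unless the amplitude is freed.
* The broken-stick breakpoint is a description of saturation geometry, not a
  mechanistic estimator; with heavily rounded corners (poorly separated
  stepwise constants) the apex knot underestimates the stoichiometric ratio
  by a few percent, as quantified above.
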