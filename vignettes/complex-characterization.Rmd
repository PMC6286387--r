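---
title: "Methods: thermodynamic and structural analysis of receptor/DELLA complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamic and structural analysis of receptor/DELLA complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dellakit)
```

`dellakit` implements the quantitative core of a solution study of how a
DELLA protein binds its gibberellin-bound receptor (GID1): isothermal
titration calorimetry (ITC) with two forward models and their
least-squares fits, small-angle X-ray scattering (SAXS) analysis,
secondary Cα chemical-shift helicity analysis, and size-exclusion
calibration. Every modality has a seeded synthetic generator so the
whole pipeline runs, and is tested, without instrument data. This
vignette records the models, the tunable parameters and their defaults,
the numerical choices, and the limits of what the synthetic closures
demonstrate.

## Thermodynamic conventions

All energies are in kcal/mol with the gas constant fixed at
R = 1.9872 × 10⁻³ kcal mol⁻¹ K⁻¹, temperatures in kelvin
(T/K = t/°C + 273.15; the titrations are at 30 °C = 303.15 K), and
association constants Kb in M⁻¹. `binding_thermo()` derives
ΔG = −RT ln Kb and −TΔS = ΔG − ΔH at construction, so the identities
hold for every fit result by design. Values are carried at full
precision; `display_round()` (half-away-from-zero, the convention of
published tables) exists only for formatting. This matters because
one-decimal table entries re-derived from their own Kb and ΔH columns
can disagree with exact recomputation by up to ~0.06 kcal/mol — within
rounding, but enough that tests of one-decimal values use a ±0.1
tolerance while two-decimal values are checked at ±0.01.

## ITC forward models

Both simulators use the perfusion-cell bookkeeping of a
constant-volume injection calorimeter. After cumulative dispensed
volume dV into a cell of volume V₀, the species initially in the cell
is diluted to M = M₀(1 − dV/2V₀)/(1 + dV/2V₀) and the accumulated
titrant concentration is X = X₀(dV/V₀)(1 − dV/2V₀). The default
design — twenty 10 µl injections of 400 µM titrant into 1.4482 ml of
50 µM partner at 30 °C — is the standard configuration of the study
this package emulates.

**One-site association** (`simulate_one_site()`): with r = X/(nM) and
s = 1/(n Kb M), the cumulative heat content after injection i is

$$Q_i = \frac{n M_i \Delta H V_0}{2}\left[1 + r + s -
\sqrt{(1+r+s)^2 - 4r}\right],$$

and the measured heat of injection i is
q_i = Q_i − Q_{i−1} + (dv_i/V₀)(Q_i + Q_{i−1})/2, the usual
displaced-volume correction. Heats are reported per mole of injectant.
The closed-form occupancy is verified in the test suite against an
independent bisection mass-balance solver (10⁻¹² relative tolerance)
over 1000 random parameter draws, and the tight-binder injection
vector is frozen as a regression fixture.

**Monomer–dimer dilution** (`simulate_dilution_dimer()`): dilution of a
self-dimerizing protein into protein-free buffer. The equilibrium
2M ⇌ D with *dissociation* constant K_dim = [M]²/[D] (mM units, as
printed in the source tables; an association constant would carry
M⁻¹) gives [M] = 2C/(1 + √(1 + 8C/K_dim)) at total monomer-equivalent
concentration C — this form is used instead of the textbook
(−K + √(K² + 8KC))/4 because it remains accurate when K ≫ C. Each
injection delivers dimers at the syringe equilibrium; the heat is
q_i = −ΔH_dim (n_D^before + n_D^injected − n_D^after), with ΔH_dim the
enthalpy per mole of dimer *formed* (negative, i.e. exothermic
dimerization, hence endothermic dilution). Injections re-equilibrate
the whole cell — the coupled model — rather than being treated
independently; the recovered parameters are validated by closure
(simulate → refit), not by comparison to any external fitting code.

## ITC fitting

`fit_one_site()` and `fit_dilution_dimer()` minimize squared residuals
on the normalized heats with Levenberg–Marquardt, parameterized as
(ln Kb, n, ΔH) and (ln K_dim, ΔH_dim): equilibrium constants spanning
decades are searched in log space, bounded to ln Kb ∈ [ln 10², ln 10¹²].
The data-driven start (ΔH from the first plateau, n from the molar
ratio at the steepest descent, Kb from the transition width) is
supplemented by a small multi-start grid over ln Kb, which keeps the
fit robust at c = Kb·n·[cell] well above 1000 where the isotherm is
nearly a step. Noiseless closures recover all parameters to ≪0.1%
for every ground truth used in the study, including the
half-stoichiometry (n = 0.50) construct.

A run is reported as `no_binding` — the analogue of an "n.d." table
row — when the fitted |ΔH| or the whole fitted curve lies below three
times the residual RMS, when Kb pins at the lower search bound, or
when the binding model explains less than half of the heat variance.
The variance criterion is needed because a structureless noise series
can otherwise be "fit" by a shallow isotherm with a tiny Kb and an
inflated |ΔH|.

Identifiability of Kb degrades at very high c, but only once injection
noise is appreciable relative to the transition heats: in seeded
Monte-Carlo runs at the default design, the spread of recovered ln Kb
at c ≈ 1450 exceeds that at c ≈ 10 clearly at 4 µcal injection noise,
while at sub-µcal noise the two are indistinguishable. The test suite
asserts the comparison in the noise-limited regime.

## SAXS analysis

**Generators.** `synth_sphere()` uses the uniform-sphere form factor
with R = Rg√(5/3); `synth_debye_chain()` the Debye function of an ideal
chain. Both switch to series/`expm1` forms at small arguments, where
the closed forms lose all precision to cancellation. Optional noise is
Gaussian with σ ∝ √I (counting statistics), scaled by the relative
level at the profile maximum, and the matching σ column is carried into
the profile.

**Guinier fit** (`guinier_fit()`): weighted regression of ln I on q²
(weights (I/σ)² when σ is available), over the window
{q : q·Rg_fit ≤ 1.3} found by fixed-point iteration from the lowest 10
points, after discarding a beamstop guard region (q < 0.008 Å⁻¹,
configurable). Degenerate (flat), aggregated (strong low-q upturn:
significant positive curvature contributing >30% of the linear decay at
the window edge — the threshold leaves the mild intrinsic curvature of
ideal chains untouched), and too-short profiles are flagged rather than
fitted.

Two systematic biases of this estimator are intrinsic and documented
rather than corrected, because the qRg ≤ 1.3 window is part of the
method being reproduced. For a uniform sphere, ln I carries a quartic
term −(qR)⁴/350, so the straight-line fit over the full window
overestimates Rg by ≈1.9% (31.90 Å for a truth of 31.3 Å), independent
of grid density and weighting; the analytic factor is
√(1 + (q_max Rg)²/49). For an ideal chain the curvature is positive
(+q⁴Rg⁴/36), the window self-consistently enlarges, and Rg is
underestimated by ≈7%. Closure tests assert these true bounds (2.5%
and 8%), and the acceptance suite keeps the nominal ±0.3 Å expectation
for the sphere, which the window bias genuinely exceeds.

**Kratky classification** (`kratky_classify()`): on y = q²I(q), a
globular call requires an interior peak below 0.15 Å⁻¹ with ≥20%
prominence decaying ≥30% toward 0.3 Å⁻¹; an unfolded call requires a
peak-free curve that is non-decreasing into a plateau over
[0.1, 0.3] Å⁻¹ (relative slope <10% per 0.1 Å⁻¹) *or* still rising but
decelerating there — the latter covers short chains (Rg ≈ 15 Å) whose
plateau lies beyond the measured range; anything else, including
profiles spanning <0.2 Å⁻¹, is ambiguous. For a Gaussian (ideal
Guinier) curve the Kratky peak sits exactly at q·Rg = √3 with height
3I(0)/(e·Rg²); a uniform sphere peaks at q·Rg = 1.61 with height ~7%
below that law. `Rg_from_peak` therefore uses √3/q_peak. Slope and
curvature tests are regression-based so counting noise cannot flip a
call; the sphere/chain truth table holds across Rg 15–40 Å at 2% noise.

**Molecular weight** (`mw_from_i0()`): concentration-normalized I(0)
ratio against a single reference standard — the primary method that
needs no external calibration table. Apparent/theoretical ratios ≥1.4
carry an "extended/oligomeric" annotation (`mw_anomaly()`), agnostic
between self-association and disordered-chain swelling, since both
inflate apparent size.

**p(r)** (`pr_transform()`): a generic regularized indirect transform —
p(r) on a uniform histogram over (0, Dmax) with p(0) = p(Dmax) = 0 by
construction, solved from I(q) = 4π∫p(r) sinc(qr) dr under a
second-difference Tikhonov penalty (λ = 10⁻⁴ relative to the
normal-matrix scale) with non-negativity via NNLS. Against the
analytic sphere distance distribution the recovered shape deviates by
<1% of the peak, the support ends within a few percent of 2R, and
Rg_from_pr matches the generating value to <0.1% — tighter than the
windowed Guinier estimate, as expected. Over-large Dmax is reported
through a condition-number warning rather than silently smoothed.

## NMR secondary shifts

`secondary_shifts()` subtracts a random-coil reference from observed
Cα shifts; only Cα is analysed. The coil set ships as an editable
per-residue-type table (`random_coil_ca()`), with no neighbour
corrections, and all tests run against synthetic coils, so no claim
depends on a particular published coil set. Residue numbering is that
of the full-length protein even for truncated constructs, and
unobserved (e.g. exchange-broadened) residues propagate as missing and
are excluded from calling.

`call_helices()` seeds stable helices at Δδ ≥ 3.0 ppm — the canonical
helical downfield offset is ~3.1 ppm — and marginal helices at
≥2.0 ppm, the level seen for transiently structured segments; runs may
bridge ≤1 missing/sub-threshold residue and must span ≥4 residues.
The length and gap defaults are choices (no published rule exists) and
are exposed as parameters; calling is monotone in the thresholds, and
boundary recovery is exact to ±1 residue for offsets ≥3σ above
threshold at σ = 0.3 ppm noise. `compare_states()` classifies a state
as folded at ≥50% stable coverage of observed residues,
molten-globule-like when marginal structure exists below that, else
disordered, and tabulates segments gained/lost on binding
(antisymmetric under argument swap). Amide ¹H dispersion (<1 ppm
suggesting disorder) is reported by `amide_dispersion()` but never used
for calling.

The shipped residue-type vector (`slr1_like_sequence()`) is a synthetic
stand-in: motif anchors are fixed, filler positions are a neutral
deterministic cycle. Helicity calling never uses residue identity
beyond matching observed and coil tables, so this choice is inert for
the analyses.

## Gel filtration

`fit_calibration()` is the standard log₁₀(MW)-vs-elution-volume line
(slope necessarily negative; non-monotone or duplicated standards are
rejected). `call_oligomeric_state()` bands the apparent/theoretical
ratio: monomer <1.4, dimer within [1.4, 2.5] (both boundaries belong to
the dimer band), oligomer above. The 1.4/2.5 defaults are package
choices set so that a ratio of 2.05 — a 60.0 kDa apparent size for a
29.3 kDa disordered construct — reads as a dimer; because disordered
monomers also elute early, ratios ≥1.4 additionally carry the
extended/oligomeric annotation rather than a distinct state. Supplying
an expected complex MW switches to consistency mode (within 10% →
"complex-consistent"). Kav-style axes are not needed for the shipped
analyses; raw volume is the default abscissa.

## Synthetic scenarios and what the closures show

`make_fixture_bundle()` writes, per modality, standard-format files
plus a `truth.json` manifest; each modality draws from its own RNG
stream derived from the master seed, so adding modalities never
perturbs existing fixtures and identical configurations are
byte-identical. The default truths are the headline study conditions:
Kb = 2.9 × 10⁷ M⁻¹, n = 1.06, ΔH = −6.9 kcal/mol; K_dim = 1.6 mM,
ΔH_dim = −66 kcal/mol; Rg = 31.3 Å (globular) and 30.4 Å (chain);
bound-state helices at E39–A44, R50–G69, D81–A88, L99–E109 (+3.5 ppm,
V92–N95 unobserved) and free-state marginal helices at E39–A44 and
A55–E62 (+2.0 ppm); and a log-linear column with samples at 60.0 and
91.8 kDa.

The generators emulate integrated, baseline-corrected observables with
idealized noise (i.i.d. Gaussian on heats; counting-statistics noise on
intensities; i.i.d. ppm noise on shifts). They do not emulate raw
power traces or baseline drift, detector artefacts, buffer-mismatch
signals, concentration-series structure factors, oligomer mixtures, or
assignment errors. Passing closures therefore demonstrate that the
estimators invert their own forward models correctly and stably at the
study's design and noise levels — not that real instrument data of the
published quality would yield the published numbers. Where the paper's
numbers depend on unpublished calibrations (SAXS molecular weights,
elution-volume axes), they enter only as inputs or constructed-fixture
targets, never as blind predictions.

## Problem sizes

All analyses are desk-scale: 20-injection titrations, ~300-point
scattering profiles, 85-residue shift tables. The heaviest routines in
the test and acceptance runs are the 100-replicate noisy dilution
recovery (~1 s) and the 80-replicate c-value Monte-Carlo (~1 min); the
p(r) NNLS solves a ~350 × 60 system. These sizes were chosen as
representative of the experiments being modelled.
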