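# dellakit

Quantitative solution biophysics of gibberellin signalling complexes.
The gibberellin receptor GID1 binds a gibberellin (GA), and the
GID1/GA complex then binds a DELLA protein — the negative regulator
whose degradation transmits the GA growth signal. `dellakit`
implements, as tested reusable R code, the analyses used to
characterize that interaction in solution for the rice proteins
(OsGID1 and the DELLA protein SLR1):

- **ITC** (`itc-*`): forward simulation and nonlinear least-squares
  fitting of two calorimetric models — the one-site association
  isotherm in a perfusion cell,

  Q_i = (n·M_i·ΔH·V₀/2)·[1 + r + s − √((1 + r + s)² − 4r)],
  r = X/(nM), s = 1/(n·Kb·M),

  and dilution-induced dimer dissociation (2M ⇌ D,
  K_dim = [M]²/[D]) — with the full decomposition
  ΔG = −RT·ln Kb, −TΔS = ΔG − ΔH.
- **SAXS** (`saxs-*`): iterative Guinier fit
  (I(q) = I(0)·exp(−q²Rg²/3) over qRg ≤ 1.3), Kratky-plot shape
  classification (globular peak vs unfolded plateau, peak law
  3I(0)/(e·Rg²)), concentration-normalized molecular weight from I(0),
  and a regularized p(r) indirect transform.
- **NMR** (`nmr-*`): secondary Cα chemical shifts (observed minus
  random coil), helix-segment calling (stable ≥ 3.0 ppm, marginal
  ≥ 2.0 ppm), and free-vs-bound state comparison (disordered /
  molten-globule-like / folded).
- **Gel filtration** (`gf-*`): log-linear size-exclusion calibration
  and oligomeric-state calls from apparent/theoretical MW ratios.
- **Synthetic data** (`make_fixture_bundle()`): seeded generators for
  every modality with truth manifests, so the whole pipeline runs
  offline.

It is aimed at structural biologists and biophysicists who want these
textbook analyses as scriptable, testable functions rather than
instrument-vendor GUIs.

## Worked example

```r
library(dellakit)

## titrate 400 uM receptor/GA into 50 uM DELLA-domain construct
## (20 x 10 ul, 1.4482 ml cell, 30 C) and refit the simulated heats
design <- titration_design()
tg  <- simulate_one_site(design, Kb = 2.9e7, n = 1.06, dH = -6.9)
fit_one_site(tg)
#> One-site titration fit: ok
#> Binding thermodynamics at 303.15 K
#>   Kb    = 2.9e+07 M^-1
#>   n     = 1.060
#>   dH    = -6.90 kcal/mol
#>   dG    = -10.35 kcal/mol
#>   -TdS  = -3.45 kcal/mol
#>   c-value = 1537, residual RMS = 1.26e-13 kcal/mol

## endothermic dilution of a self-dimerizing construct into buffer
d0 <- titration_design(cell_conc = 0)
fit_dilution_dimer(simulate_dilution_dimer(d0, K_dim = 1.6e-3, dH_dim = -66))
#> Monomer-dimer dilution fit: ok
#>   K_dim = 1.6 mM, dH_dim = -66.0 kcal/mol dimer, RMS = 2.89e-14

## scattering of a globular particle: Guinier + Kratky
prof <- synth_sphere(Rg = 31.3)
g <- guinier_fit(prof)
g
#> Guinier fit: Rg = 31.90 +/- 0.03 A, I(0) = 1 (33 pts, q <= 0.0400, r2 = 0.99989)
kratky_classify(prof, g)
#> Kratky classification: globular
#>   q_peak = 0.0520 1/A, height = 0.00105, Rg_from_peak = 33.3 A

## a 29.3 kDa construct eluting as a 60 kDa species
call_oligomeric_state(60.0, 29.3)
#> Apparent MW 60.0 kDa / theoretical 29.3 kDa (ratio 2.05) -> dimer
```

The one-site refit returns the generating parameters to machine
precision and derives the free-energy split at 303.15 K (binding is
enthalpy-driven: ΔH = −6.9 of the −10.35 kcal/mol total). The dilution
fit recovers a millimolar dimer dissociation constant from the decaying
endothermic injection series. The Guinier estimate exceeds the
generating 31.3 Å by the known ~2% window bias of a uniform sphere at
the qRg ≤ 1.3 cut (see the methods vignette), and the Kratky peak
identifies the particle as globular. The 60/29.3 ≈ 2.05 size ratio is
read as a dimer.

A thin command-line front end over the same functions is installed at
`inst/cli/dellakit` (`dellakit itc-fit --file heats.csv`, etc.; see
`?run`).

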