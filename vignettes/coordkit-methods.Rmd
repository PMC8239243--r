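---
title: "Methods: characterization arithmetic for metal-drug complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterization arithmetic for metal-drug complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coordkit)
```

coordkit implements the arithmetic that sits downstream of the instruments in
a metal-drug complexation study: everything between the raw titration,
spectroscopy, thermogravimetry and plate readings and the numbers a
characterization table prints. This vignette records the models, the
parameter choices, and the numerical decisions, including the places where
the underlying methods have known limitations.

## Composition arithmetic

Molecular formulas are parsed into element counts (nested groups, integer
multipliers, an optional `·nH2O` hydrate suffix kept separate from the core
composition) and priced against a single embedded IUPAC/CIAAW 2021 abridged
atomic-weight table, so two-decimal comparisons against printed elemental
analyses are reproducible. Percent composition always sums to 100; hydrate
waters contribute both mass and H/O counts when the hydrate basis is chosen.

Thermogravimetric ledgers mix bases in practice — water-loss steps are quoted
on the hydrate mass while the oxide residue is quoted on the anhydrous
mass — so every mass-percent operation takes an explicit basis argument and
`step_mass_balance()` declares the basis per step. Published fragment
assignments are frequently mass-approximate rather than atom-balanced (a
step list can require more hydrogen atoms than the complex holds while still
summing to the right mass), so the ledger errors only when fragments exceed
the parent's *mass* and downgrades element-count excess to a classed
warning; the stricter primitive `fragment_loss_percent()` keeps the
element-wise error.

Molar-conductance classification (DMF, 1e-3 M) uses cut-offs of <20
(non-electrolyte), 60-95 (1:1 electrolyte) and >120 (2:1); the gaps are
reported as ambiguous rather than silently assigned. The cut-offs bracket
the conductances such complexes typically show and are configurable.

## ML2 equilibria and the stability constant

The titration forward model is the mass-action equilibrium M + 2L <-> ML2
read out by Beer's law. For totals `C_M`, `C_L` the complex concentration
`x` solves `Kf = x / ((C_M - x)(C_L - 2x)^2)`; the right-hand side's
numerator grows and denominator shrinks monotonically in `x` on
`[0, min(C_M, C_L/2))`, so the root is unique and is found by bisection to
relative machine tolerance.

`stability_constant()` reports two estimates. The pointwise estimate applies
the mass-action expression at each titration point with `x = A/(eps b)` and
averages; it is exact on clean data but amplifies noise near saturation
(where `C_M - x` approaches 0). The headline estimate is therefore a
one-parameter least-squares fit of the forward model over `log10 Kf`.
When the complex's molar absorptivity is unknown it is estimated from the
saturation plateau as `max(A)/(b C_M)`; plateau points are then excluded
from the pointwise estimate because they sit on the singular boundary.
Round-trips against the generator recover `Kf` to better than 0.1% across
`1e3`-`1e8` M^-2.

Stoichiometry comes from the molar-ratio breakpoint: two least-squares lines
with the split chosen to minimize total residual (ties toward the smaller
ratio), intersected. A breakpoint near 1/3 on the metal mole-fraction axis
implies one metal per two ligands; near 1/2, a 1:1 complex. The default
synthetic grid follows the study conditions (metal constant at 0.36e-4 M,
ligand 0.18e-4 to 1.25e-4 M; ten points, a choice made once since the
protocol does not state a count).

## DNA binding

The Wolfe-Shimer linearization `[DNA]/(eps_a - eps_f) = [DNA]/(eps_b -
eps_f) + 1/(Kb (eps_b - eps_f))` is algebraically exact for the two-state
hyperbolic binding model, so the noise-free round-trip through the generator
is a machine-precision identity and is tested as such. `[DNA]` is base-pair
molarity throughout. The fit refuses series where `eps_a - eps_f` changes
sign (inconsistent chromism) and where the intercept vanishes (unbounded
`Kb`). Binding free energy is `deltaG = -RT ln Kb` with R = 8.314 J/(K mol)
at 298 K; chromism is reported signed (negative hypochromic, positive
hyperchromic). Noise robustness: with 1% multiplicative noise on six points,
the median `Kb` error stays within 10%.

## Ligand-field and EPR parameters

For octahedral d7 and d8 ions the package evaluates the closed forms that
relate the two visible d-d transition energies to the splitting parameter
Dq and the Racah interelectronic-repulsion parameter B, with the
nephelauxetic ratio `beta = B/B0` against free-ion values B0 = 971 cm^-1
(d7 Co) and 1030 cm^-1 (d8 Ni). Two defects of these closed forms are
handled explicitly rather than papered over:

* the d8 Dq expression has a negative radicand for many realistic band
  pairs (including the worked Ni case in this package); the function then
  requires a tabulated `ten_dq` and records that the closed form failed,
  rather than guessing an alternative band assignment;
* for the worked d7 case the B formula evaluated on the printed bands gives
  ~742 cm^-1 while the characterization table prints 708 — no band pair
  reproduces both the printed splitting and the printed B. The function
  returns the computed value; comparisons against the printed B are done by
  feeding that B to `nephelauxetic_ratio()` directly.

The band-set generator inverts the d8 relations exactly
(`V2 + V3 = 30 Dq + 15 B`), so generated bands round-trip B to machine
precision; its radicand `225 B^2 + 100 Dq^2 - 180 Dq B` equals
`(15B - 6Dq)^2 + 64 Dq^2` and is never negative for positive inputs. Only
the d8 inverse exists in closed form, so d7 generation is refused loudly.

EPR analysis reduces the axial pair to `g_av = (g_par + 2 g_perp)/3` and
classifies the metal-ligand bond as covalent below the conventional 2.3
threshold (configurable). Spin-only moments `sqrt(n(n+2))` are provided for
geometry arguments from measured magnetic moments.

## Thermogravimetric kinetics

The generator integrates first-order non-isothermal kinetics
`dalpha/dT = (A/beta) exp(-Ea/RT) (1 - alpha)` per step on a fixed 0.5 K
grid under the study's heating rate (10 K/min, 25-800 degC by default). The
update is an exponential integrator — exact for the linear ODE, with Simpson
(fourth-order) quadrature of the Arrhenius rate over each interval — chosen
over a classical Runge-Kutta step because the rate coefficient can exceed
the stability limit of explicit schemes late in a step at high `A`; the
exponential update is unconditionally stable at the same order. Generated
conversions agree with adaptive-quadrature evaluation of the exact solution
to ~1e-6.

Segmentation smooths the trace (centered moving average, default 7 points),
differentiates, and takes contiguous regions where the DTG rate exceeds a
threshold (default 2% of the peak rate with a 0.02 %/K floor). Step losses
are measured plateau-to-plateau at the rate minima between steps, so the
losses plus residue telescope to the initial mass — conservation is a tested
invariant. The DTG peak temperature `T_s` of each step anchors the
Horowitz-Metzger fit and the activation thermodynamics (the source
literature does not define `T_s`; the DTG peak is the conventional choice).

Both kinetic fits assume first order (configurable nowhere on purpose: the
classic linearizations cited in this literature are the n = 1 forms) and
use the conversion window alpha in [0.05, 0.95] to avoid the log
singularities. Coats-Redfern regresses `ln[-ln(1-alpha)/T^2]` on `1/T`,
with the conventional intercept approximation `ln(AR/(beta Ea))`; it
recovers constructed activation energies to a fraction of a percent
(median ~0.3% over an Ea 80-200 kJ/mol by A 1e8-1e12 s^-1 grid).

Horowitz-Metzger deserves a caveat that the package states rather than
hides: its slope at the DTG peak is exactly `(Ea/R T_s^2)(1 + 2R T_s/Ea)`
once the `T^2` prefactor its derivation drops is accounted for, so the
method carries a structural upward bias of `2 R T_s` (~6-8% for realistic
parameters) plus a few percent more from the curvature of the linearized
plot over a wide, asymmetric conversion window. Measured recovery on the
same grid is ~8-13% high — consistent with published critiques of the
method — and the tests assert this honest behaviour (upward bias below 15%)
instead of an accuracy the method does not possess. Where the two methods
disagree, Coats-Redfern is the one to trust.

Activation thermodynamics follow `deltaH = Ea - R T_s`,
`deltaS = R ln(A h/(kB T_s))`, `deltaG = deltaH - T_s deltaS` with CODATA
h and kB; `deltaG = deltaH - T_s deltaS` holds exactly by construction and
`deltaH < Ea` always.

One pathological corner of the test grid is worth naming: Ea = 80 kJ/mol
with A = 1e12 s^-1 decomposes essentially at room temperature, so the
0-to-T integral approximation underlying both linearizations fails and
neither method recovers Ea there. The property suites use medians across
the grid, which absorb that cell.

## Reactivity descriptors

From HOMO/LUMO energies in eV: gap `Eg`, chemical potential
`mu = (E_HOMO + E_LUMO)/2` (the negative-midpoint Koopmans convention),
hardness `eta = Eg/2`, softness `S = 1/(2 eta)` and electrophilicity
`omega = mu^2/(2 eta)`. Source texts in this area often print these
formulas garbled (and sometimes print the two orbital energies in swapped
order); the package uses the standard forms and *refuses* inverted input
with a swap hint rather than guessing which energy is which.
`eta * S = 1/2` is an exact invariant.

## Cytotoxicity

MTT reduction: survival is `100 (OD_treated - OD_bg)/(OD_control - OD_bg)`
with a per-plate scalar background (mean of the 620 nm background wells)
and replicate averaging; the quantity is invariant to a common OD gain.
IC50 is interpolated linearly in log10 dose between the bracketing points
(the potency literature this serves never states its interpolation
procedure; log-dose linearity is the least-structured choice consistent
with sigmoidal response). Exact 50% hits return the measured dose;
non-monotone series use the first crossing with a warning; series that
never cross return a censored result instead of an error. Potency bands
have inclusive upper edges: (0,10] very strong, (10,20] strong, (20,50]
moderate, (50,100] weak, >100 non-cytotoxic, in ug/ml (the band footnotes
in this literature sometimes say mg/ml, but the classifications actually
applied are consistent with ug/ml).

The plate generator maps a Hill curve (slope 1 by default) onto ODs between
background and control, with Gaussian noise expressed as a fraction of the
corrected control OD and a twofold dilution ladder, mirroring the assay
protocol. Recovery under 2% noise is within 10% median error across IC50
10-200 ug/ml.

## What the generators do and do not emulate

Every raw input the analyses consume has a seeded generator with recorded
ground truth, so all estimators are testable without any external data:
titration absorbances (equilibrium model + additive noise), DNA titrations
(hyperbolic binding + additive or multiplicative noise), TGA traces
(first-order steps, optional noise), MTT plates (Hill response), and d8
band sets. Deliberately not emulated: baseline drift, stray light, buoyancy
effects, plate edge effects, competing equilibria (1:1/1:2 mixtures),
multi-wavelength structure. Passing round-trip tests therefore demonstrates
estimator correctness under the stated models, not robustness to every
instrumental artifact of real spectra.

## Problem sizes used in the test suite

Titration series use 10 points, DNA titrations 6, TGA grids 0.5 K spacing
over 25-800 degC (to 1300 degC for the kinetics grid so that slow high-Ea
steps complete), MTT plates 8 doses x 3 replicates. Monte-Carlo suites use
200 seeds for the breakpoint and IC50 recovery checks and 100 for the noisy
Wolfe-Shimer check; these sizes give stable medians while keeping the whole
suite fast.
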