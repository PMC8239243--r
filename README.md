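# coordkit

Characterization arithmetic for transition-metal drug complexes.

When a new metal complex of a drug ligand is characterized, a large amount
of the published evidence is not raw instrument output but arithmetic
applied to it: elemental percentages from a proposed formula, stability
constants from spectrophotometric titrations, ligand-field and EPR
parameters from band positions and g-values, activation energies from
thermogravimetric traces, DNA-binding constants from titration spectra,
reactivity descriptors from frontier-orbital energies, and IC50 potency
classes from MTT plates. coordkit implements that entire downstream layer
as a tested, reusable R package — for coordination chemists checking or
reproducing characterization tables, and for anyone validating such
estimators against synthetic data with known ground truth.

## The models at the core

* **ML2 equilibrium** — M + 2L ⇌ ML2 with
  `Kf = [ML2] / ([M][L]^2) = x / ((C_M − x)(C_L − 2x)^2)`, read out by
  Beer's law `A = ε b x`. Stoichiometry from the molar-ratio breakpoint of
  A versus [M]/([M]+[L]).
* **Wolfe–Shimer DNA binding** —
  `[DNA]/(ε_a − ε_f) = [DNA]/(ε_b − ε_f) + 1/(K_b(ε_b − ε_f))`;
  `K_b` = slope/intercept, `ΔG = −RT ln K_b`, signed chromism.
* **Ligand field / EPR** — octahedral d7/d8 closed forms for Dq and Racah
  B, nephelauxetic ratio `β = B/B0`; `g_av = (g‖ + 2g⊥)/3` with a 2.3
  covalency threshold; spin-only moments `√(n(n+2))`.
* **Thermal kinetics** — DTG-based step segmentation; Coats–Redfern
  (`ln[−ln(1−α)/T²]` vs `1/T`) and Horowitz–Metzger (`ln[−ln(1−α)]` vs
  `θ = T − T_s`) first-order fits; `ΔH = Ea − RT_s`,
  `ΔS = R ln(Ah/k_B T_s)`, `ΔG = ΔH − T_s ΔS`.
* **Conceptual-DFT descriptors** — `μ = (E_HOMO + E_LUMO)/2`, `η = E_g/2`,
  `S = 1/(2η)`, `ω = μ²/(2η)`.
* **Cytotoxicity** — MTT survival fractions, log-dose IC50 interpolation,
  potency bands (≤10 very strong … >100 non-cytotoxic µg/ml).

Every raw input also has a seeded generator (`gen_*()`) with recorded
ground truth (`truth()`), so each estimator is tested by round-trip.

## Worked example

```r
library(coordkit)

# a simulated titration at constant metal concentration, fitted back
ser <- gen_metal_titration(kf = 2.5e9, noise_sigma = 0.002, seed = 42)
stability_constant(ser, epsilon = 1e4)
#> ML2 stability-constant fit
#>   Kf (model fit)      : 2.589e+09 M^-2
#>   Kf (pointwise mean) : 2.619e+09 M^-2
#>   epsilon (supplied) : 1e+04 L mol^-1 cm^-1
#>   n = 10 points, RSS = 2.58e-05

# DNA binding: noise-free data recovers the generating constant exactly
ti <- gen_dna_titration(kb = 9e5, noise_sigma = 0)
wolfe_shimer_fit(ti, epsilon_free = 10000)
#> Wolfe-Shimer DNA-binding fit
#>   Kb        : 9e+05 M^-1
#>   eps_bound : 5000 L mol^-1 cm^-1
#>   deltaG    : -33.97 kJ/mol at 298 K
#>   chromism  : -50.0% (hypochromic)
#>   R^2 = 1.00000 over 6 points

# a two-step decomposition: segment, then fit the big step
cur <- gen_tga_curve(steps = list(c(ea = 9e4, a = 1e10, fraction = 0.05),
                                  c(ea = 1.6e5, a = 1e12, fraction = 0.75)))
st <- segment_steps(cur)
st[, c("step", "temp_start_C", "temp_end_C", "t_s_K", "mass_loss_pct")]
#>   step temp_start_C temp_end_C  t_s_K mass_loss_pct
#> 1    1         90.5        140 393.65      5.000234
#> 2    2        244.5        358 595.15     74.999766
coats_redfern_fit(extract_step(cur, st, 2), heating_rate = 10)
#> Coats-Redfern kinetic fit (first order)
#>   Ea  : 159.74 kJ/mol
#>   A   : 8.94e+11 s^-1
#>   R^2 = 1.00000 over 135 points (alpha 0.05-0.95)

g_average(2.044, 2.189)
#> # A tibble: 1 x 4
#>   g_parallel g_perpendicular  g_av covalency
#>        <dbl>           <dbl> <dbl> <chr>
#> 1       2.04            2.19  2.14 covalent
```

The titration fit recovers the generating `Kf` to ~4% under noise (and to
<0.1% noise-free); the Coats–Redfern fit recovers the constructed 160
kJ/mol activation energy to 0.2%; the EPR average of 2.14 < 2.3 classifies
the metal–ligand bond as covalent. See `vignette` source
`vignettes/coordkit-methods.Rmd` for the models, assumptions and known
limitations (including the documented upward bias of the Horowitz–Metzger
method).

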