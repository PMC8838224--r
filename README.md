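# vanchar

Tidyverse-style R toolkit for the physico-chemical characterization of
oxidovanadium(IV) ("vanadyl", VO²⁺) coordination complexes — the class of
drug-based metal complexes studied as DNA binders and anticancer candidates.
It is aimed at inorganic/medicinal chemists who have the usual
characterization data in hand (elemental analyses, IR frequencies,
frontier-orbital energies, UV–vis titrations, thermograms, molar-ratio
series, molecular descriptors) and want the derived quantities computed
reproducibly, with every published-table inconsistency flagged rather than
silently absorbed.

## What it computes

- **Formula arithmetic** — molecular-formula parsing (including hydrate
  notation such as `[VO(CTZ)2] 2H2O` written as `"C42H52Cl2N4O9V"` plus
  `"2H2O"` fragments), molar masses, percent elemental composition, and
  thermogravimetric mass-loss assignment
  (`mass_loss_percent(fragment, parent) = 100·M_frag/M_parent`), with a
  bounded fragment-enumeration search (`suggest_fragments()`).
- **V=O bond length from IR** — the empirical correlation
  ν = 21349·exp(−1.9176·R) between the V=O stretch (cm⁻¹) and the bond
  length R (Å), in both directions.
- **Conceptual-DFT reactivity descriptors** — from HOMO/LUMO energies (eV):
  gap ΔE = E_LUMO − E_HOMO, electronegativity χ = −(E_HOMO + E_LUMO)/2,
  hardness η = ΔE/2, chemical potential μ = −χ, softness S = 1/(2η),
  electrophilicity ω = μ²/(2η), and maximum charge transfer ΔN_max = χ/η —
  plus a per-cell consistency report against printed descriptor tables.
- **DNA binding** — Benesi–Hildebrand double-reciprocal analysis of
  absorption titrations, A₀/(A−A₀) vs 1/[DNA], with K_b = intercept/slope,
  and hyper/hypochromism classification.
- **TGA kinetics** — DTG-based step segmentation, then first-order
  Coats–Redfern (ln[−ln(1−α)/T²] vs 1/T) and Horowitz–Metzger
  (ln[ln(1/(1−α))] vs θ = T − T_s) fits with activation thermodynamics
  ΔH = E_a − RT_s, ΔS = R·ln(Ah/k_BT_s), ΔG = ΔH − T_sΔS.
- **Molar-ratio stoichiometry** — two-segment breakpoint fit of absorbance
  vs [M]/([M]+[L]); break near 1/2 ⇒ 1:1, near 1/3 ⇒ 1:2.
- **QSAR** — the four-descriptor multiple linear regression
  IC₅₀ = b₁·ASA_P + b₂·ASA_H + b₃·h_pkp + b₄·dipole + C with diagnostics
  (R, R², residuals, leave-one-out q²) and test-set prediction.
- **Synthetic data** — seeded generators (`gen_titration()`,
  `gen_thermogram()`, `gen_molar_ratio()`, `gen_qsar_table()`,
  `simulate_bundle()`) whose zero-noise output is an exact fixed point of
  the corresponding estimator, so the whole pipeline is testable without
  instrument files.

Everything is data-frame-first and pipe-friendly: fits return objects with
`tidy()`/`glance()` methods and `autoplot()` diagnostics, and
`run_characterization()` drives all stages from one YAML config.

## Worked example

```r
library(vanchar)

# V=O bond lengths from the four experimental stretching frequencies
round(bond_length_from_frequency(c(980, 963, 968, 987)), 3)
#> [1] 1.607 1.616 1.613 1.603
```

All four lengths fall in the 1.603–1.616 Å window typical of
square-pyramidal vanadyl complexes; higher stretch ⇒ shorter bond.

```r
# DNA binding from a titration (here synthetic, K_b = 1.40e6 1/M, 1% noise)
tt <- gen_titration(true_k = 1.40e6, noise_sd = 0.01, seed = 42)
benesi_hildebrand_fit(tt)
#> Benesi-Hildebrand binding fit
#>   K_b       = 1.47e+06 M^-1  (intercept/slope)
#>   r^2       = 0.9977  (n = 20 used)
#>   chromism  = hyperchromic, shift = blue
```

The recovered constant sits within 5 % of the generating value; a K_b of
order 10⁶ M⁻¹ with hyperchromism indicates strong electrostatic/groove
binding to CT-DNA.

```r
# decomposition kinetics of a 9.44% mass-loss step (the VO2 residue share)
tg <- gen_thermogram(steps = list(list(loss = 9.44, e_a = 120, a = 1e10)))
st <- segment_steps(tg)
coats_redfern_fit(st[1, ], beta = 10)
#> Coats-Redfern kinetic fit (first order, beta = 10 K/min)
#>   E_a  = 119.9 kJ/mol   A = 9.02e+09 1/min   r^2 = 1.00000
#>   T_s  = 602.5 K   dH = 114.9 kJ/mol   dS = -94.2 J/mol/K   dG = 171.6 kJ/mol
```

E_a is recovered to 0.1 %; the negative ΔS and positive ΔH, ΔG are the
signature of a slow, endothermic, non-spontaneous decomposition step.

```r
# stoichiometry of an ML2 complex from a seven-flask molar-ratio series
glance(fit_breakpoint(gen_molar_ratio("1:2", noise_sd = 0.02, seed = 1)))
#> # A tibble: 1 × 4
#>   breakpoint ratio_label      rss     n
#>        <dbl> <chr>          <dbl> <int>
#> 1      0.342 1:2         0.000995     7

# QSAR: fit on 100 synthetic training compounds, predict new ones
m <- fit_mlr(gen_qsar_table(n = 100, noise_sd = 2, seed = 1))
m
#> QSAR multiple linear regression
#>   asa_p = 0.4988, asa_h = -0.1999, h_pkp = 3.084, dipole = 1.007
#>   intercept = 6.571   R = 0.9983   R^2 = 0.9967   n = 100
predict(m, gen_qsar_table(n = 6, noise_sd = 0, seed = 2))
#> # A tibble: 6 × 2
#>   compound_id pred_activity
#>   <chr>               <dbl>
#> 1 cpd001               26.2
#> 2 cpd002              -11.9
#> # …
```

The coefficients land on the generating values (0.5, −0.2, 3, 1, C = 7)
within their standard errors. The small reference tables for the four
complexes (formulas and nominal masses, orbital energies with printed
descriptor columns, V=O frequencies, binding parameters) ship under
`inst/extdata/` and feed `compound_report()`, `descriptor_consistency()`
and the pipeline examples.

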