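---
title: "Characterization methods for oxidovanadium(IV) complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterization methods for oxidovanadium(IV) complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vanchar)
```

This vignette is the package's account of the science it implements: the
models behind each stage, the parameters that matter and their defaults,
what the synthetic-data generators emulate (and deliberately do not), and
the numerical choices made where the literature leaves them open.

## The characterization problem

Drug-based oxidovanadium(IV) complexes — a vanadyl VO²⁺ core coordinated by
pharmaceutical ligands — are characterized by a standard battery:
elemental analysis against the proposed formula, IR (the ~950–990 cm⁻¹
V=O stretch diagnoses the square-pyramidal geometry), frontier-orbital
energies from electronic-structure calculations, UV–vis DNA titrations,
thermogravimetry, molar-ratio stoichiometry, and descriptor-based activity
models. Each stage reduces to a small, well-defined computation on a small
table. This package implements those computations as a tested pipeline;
the measurements themselves (and quantum-chemical or docking calculations)
are inputs, not things the package attempts.

## Formula arithmetic

Masses use one fixed table of abridged standard atomic weights
(`atomic_weights()`), with conventional single values for interval
elements, so 2-decimal percentages are reproducible. Formula strings accept
typeset noise (underscores, Unicode subscripts), parenthesised groups, and
hydrate/adduct segments with leading integer multiplicities (`"2H2O"`).
Reported masses and percentages are conventionally rounded half away from
zero at 2 decimals; all functions return full precision and leave rounding
to the caller or the report layer.

Published tables of this family are not always internally consistent:
recomputing the shipped compound table flags four of eight nominal masses
(e.g. a ligand printed at 185.2 g mol⁻¹ whose formula gives 186.23, and a
complex printed at 906.6 whose printed formula gives 874.62 — consistent
instead with two more oxygens). `compound_report()` reports the recomputed
values and flags deviations beyond `flag_tol` (default 0.2 g mol⁻¹); it
never silently corrects either side.

`suggest_fragments()` enumerates every sub-multiset of the parent
composition (optionally restricted to an element pool, capped at
`max_atoms`) whose mass-loss percentage falls within a tolerance of a
target; ordering is deterministic (|deviation|, then fewer atoms, then
formula string), and the enumeration refuses to start above two million
combinations rather than hang.

## V=O stretch ↔ bond length

The empirical correlation ν = 21349·exp(−1.9176·R) (ν in cm⁻¹, R in Å) is
used exactly as published; the constants are fixed, never refitted. The
forward and inverse forms round-trip to machine precision, and the map is
strictly decreasing — higher stretching frequency, shorter bond. Valid
input frequencies are (0, 21349) cm⁻¹; outside that the implied length is
non-positive and the input is rejected. Note the correlation and
quantum-chemically computed frequencies need not agree: evaluating the
correlation at a DFT bond length of 1.579 Å gives 1034 cm⁻¹ even where a
DFT frequency of 1068 cm⁻¹ is tabulated for the same complex.

## Global reactivity descriptors

From HOMO/LUMO energies in eV: ΔE = E_LUMO − E_HOMO,
χ = −(E_HOMO + E_LUMO)/2, η = ΔE/2, μ = −χ, S = 1/(2η), ω = μ²/(2η) (the
Parr electrophilicity index), ΔN_max = χ/η. Two conventions deserve
comment because printed tables in this field are loose about them. First,
"χ = −E_HOMO + E_LUMO/2" only reproduces tabulated electronegativities when
read with the conventional bracketing −(E_HOMO + E_LUMO)/2; the literal
reading fails every row, so the conventional form is implemented. Second,
"ω = π²/2η"-style typos are read as μ²/(2η), which reproduces the
reference ligand row exactly.

Rather than chase every printed cell, `descriptor_consistency()` recomputes
all descriptors and flags each printed cell that deviates beyond a
half-unit-of-last-digit tolerance (default 0.0105 for 2-decimal tables).
On the shipped table this flags, as expected: the ω column everywhere
except the one row that follows μ²/(2η); one complex's χ and η, which do
not follow from its own orbital energies (though its ΔN_max does follow
from the printed χ/η pair — checked separately as `dn_max_printed_pair`);
and the duplicated σ/S columns, which disagree with the stated S = 1/(2η).
A degenerate or inverted gap (E_HOMO ≥ E_LUMO) is rejected because η ≤ 0
breaks every derived quantity.

## Benesi–Hildebrand DNA binding

For 1:1 binding at fixed compound concentration, the isotherm linearizes to

A₀/(A − A₀) = ε + ε/(K·[DNA]),  with ε = ε_G/(ε_HG − ε_G),

so the double-reciprocal plot of y = A₀/(A−A₀) against x = 1/[DNA] is a
line with K = intercept/slope. The estimator is unweighted ordinary least
squares on the transformed variables, as the conventional graphical
analysis implies; an optional nonlinear refit of the untransformed isotherm
(`nonlinear_check = TRUE`) serves as a cross-check, never as the default
path. Numerical guards: points with |A−A₀| below a configurable floor
(default 10⁻³ absorbance units, where the transform diverges) are excluded
and reported; mixed hyper/hypochromic signs fit the majority-sign subset
with a warning and an indeterminate chromism label; a slope
indistinguishable from zero is "no concentration dependence", an error
rather than an infinite K.

Chromism is classified from the relative change of the final absorbance
against A₀ (default threshold 1 %, since published labels are qualitative),
with the band shift (blue/red/none/unknown) taken from the free- and
bound-form maxima carried as metadata. Analysis is single-wavelength; the
package does not model full spectra.

`gen_titration()` inverts the isotherm exactly and multiplies A by
(1 + N(0, noise_sd)) — instrument-like relative noise. Default conditions:
A₀ = 0.6, twenty additions log-spaced over [10⁻⁷, 10⁻⁵] M, ε = 0.4. The
ε default corresponds to strong hyperchromism (the regime reported for
these complexes) and keeps the smallest absorbance change about an order
of magnitude above 1 % noise, which is what makes the unweighted
double-reciprocal estimator recover K to a median ≈3 % at 1 % noise; with
weaker chromism the transform's noise amplification at low [DNA] degrades
recovery quickly, a genuine property of the graphical method, not of the
implementation. For recovery studies across K ∈ [10⁵, 10⁷] M⁻¹ the
titration window is generated bracketing 1/K ([0.1/K, 10/K]), as an
experimentalist designs a titration; a fixed window spanning the wrong
binding regime yields the large errors one would expect.

## Thermogravimetric kinetics

`segment_steps()` smooths the remaining-mass curve (Savitzky–Golay, default
11-point cubic window), takes the derivative (DTG), and finds steps as
contiguous regions where the loss rate exceeds 5 % of the global DTG peak,
merging regions closer than 20 K, extending each to its plateaus (0.2 % of
the step's own peak rate), and discarding losses under `min_loss_percent`.
Conversion within a step is α = (m_start − m)/(m_start − m_end), clipped
to [0, 1]; it is invariant to the initial sample mass. A curve that rises
by more than 0.5 mass-% after smoothing is rejected as non-monotone.

Kinetics assume first order (n = 1) throughout — single activation energy
per step, no reaction-order analysis. Coats–Redfern regresses
ln[−ln(1−α)/T²] on 1/T over α ∈ [0.05, 0.95]: E_a = −slope·R, and A from
intercept = ln[AR/(βE_a)] (the (1 − 2RT/E_a) correction is neglected by
default, per common practice, and toggleable). On exact first-order data
this recovers E_a to ~0.3 % with r² ≈ 1.

Horowitz–Metzger regresses ln[ln(1/(1−α))] on θ = T − T_s, with T_s the
DTG-peak temperature. The textbook estimator E_a = slope·R·T_s² carries an
intrinsic +2RT_s bias on exact first-order data (the chord picks up the
T² prefactor of the temperature integral — about 8–11 % at typical
conditions), so the default applies the corrected form
E_a = slope·R·T_s² − 2R·T_s and fits the window α ∈ [0.2, 0.8], where the
linearization is locally valid; residual error is ~2.5–3 %, and
`ts_correction = FALSE` restores the textbook estimator. Activation
thermodynamics are evaluated at T_s with CODATA constants:
ΔH = E_a − RT_s, ΔS = R·ln(A·h/(k_B·T_s)) with A converted to s⁻¹,
ΔG = ΔH − T_s·ΔS. For pre-exponentials up to 10¹² min⁻¹ this yields the
characteristic slow-decomposition signature ΔS < 0, ΔH > 0, ΔG > 0.

`gen_thermogram()` integrates dα/dT = (A/β)e^(−E_a/RT)(1−α) by cumulative
trapezoid on a 0.5 K grid (exact to far better than fit tolerances) and
superposes steps; noise is additive in mass-%. Defaults (4.1 % step at
80 kJ mol⁻¹ then 86.5 % at 200 kJ mol⁻¹, β = 10 K min⁻¹, 300–1100 K)
emulate a hydrated complex: lattice-water loss near 400 K, organic
decomposition near 840 K, a ~9.4 % oxide residue. Small steps under
realistic noise carry large kinetic uncertainty — at 0.1 mass-% noise the
4.1 % step's E_a is only good to ~15–25 % while the main step stays within
a few percent; the tight recovery tolerances (2 % CR / 5 % HM) apply to
noise-free curves.

## Molar-ratio stoichiometry

Under effectively complete formation of ML_n, absorbance against the metal
mole fraction x = [M]/([M]+[L]) is proportional to min(x, (1−x)/n): two
straight branches intersecting at x = 1/(n+1). `fit_breakpoint()` tries
every split with at least 3 points per side, fits each side by OLS, keeps
the split with minimal total RSS (ties broken towards the smaller
breakpoint, deterministically), and intersects the branch lines. Labels:
1:1 within 0.05 of 1/2, 1:2 within 0.05 of 1/3, otherwise unassigned —
including parallel branches (collinear data) and intersections at or
outside the endpoints. The breakpoint is invariant to affine rescaling of
absorbance. The default grid is the classical seven-flask design
(x = 0, 1/6, …, 1); the generator scales the ideal triangle so its peak is
`max_abs` and adds noise proportional to `max_abs`, and at 2 % noise both
stoichiometries are labelled correctly in 100/100 seeded replicates. The
ideal-complexation model deliberately omits curvature near the break from
finite formation constants; no formation-constant refinement is attempted.

## QSAR regression

The activity model is ordinary least squares with intercept on four
descriptors in natural units (no standardization, so coefficients match
the printed model form): polar and hydrophobic surface areas, the
protonation basicity at pH 7, and the dipole moment. The response is the
activity itself by default, with an optional log10 transform (back-
transformed predictions) since QSAR convention often prefers it; both
paths are provided because the original modelling environment does not
state which it used. Guards: more records than parameters (and at least
six), explicit rank-deficiency errors naming the collinear columns, and a
constant response flagged with undefined R². `validate_qsar()` recomputes
R and R² from scratch and adds leave-one-out q² = 1 − PRESS/TSS, the
standard internal validation for small training sets; on pure-noise
responses q² drops below R², as it should. The published 100-compound
training set behind the original R² = 0.9766 is not available, so the
regression stage is validated by synthetic recovery: exact coefficient
recovery at zero noise, residual orthogonality, and unbiased recovery
(within two standard errors of the replicate mean over 200 seeded
replicates) at 5 % response noise. The default generator coefficients
(0.5, −0.2, 3, 1; C = 7) over realistic descriptor ranges make the
response a linear surrogate for activity, not literal micromolar values —
negative responses can occur and are harmless for the regression testbed.

## What the synthetic data do and do not show

Every generator is a pure function of its configuration including the
seed, and its zero-noise output is an exact fixed point of its estimator —
that round-trip is the backbone of the test suite. The generators emulate
the *statistical structure* each stage assumes: exact 1:1 binding with
relative absorbance noise, exact first-order kinetics with additive mass
noise, ideal sharp-break stoichiometry, exact linear descriptor-activity
tables. Passing tests therefore demonstrate that the estimators recover
what their models assume, at realistic noise, with honest uncertainty on
hard cases (small TGA steps, weak chromism, out-of-window binding
constants). They do not demonstrate robustness to phenomena the models
exclude: baseline drift, overlapping multi-step kinetics with non-integer
order, cooperative or multi-site DNA binding, finite formation constants,
or descriptor error in QSAR (the model assumes noise only in the
response).

## Problem sizes

The shipped tests and the acceptance script run at the scale the methods
are actually used at: 8-compound tables, 20-point titrations (200
replicates for recovery statistics), 1601-point thermograms, 7-point
molar-ratio series (100 replicates per stoichiometry), and n = 100
QSAR tables (200 replicates). These sizes were chosen as representative of
the instruments and designs being emulated.
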