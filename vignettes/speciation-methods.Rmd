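---
title: "Speciation, titration simulation and stability-constant refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speciation, titration simulation and stability-constant refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betafit)
```

## The model

A speciation model consists of *components* — a metal ion M, one or two
ligands L, L' in their fully deprotonated reference forms, and the proton
H — and *species* formed from them.  Each species $\mathrm{M}_p\mathrm{L}_q
\mathrm{H}_r\mathrm{L'}_s$ is characterized by its overall stability
constant on the molar concentration scale,

$$\beta_{pqrs} = \frac{[\mathrm{M}_p\mathrm{L}_q\mathrm{H}_r\mathrm{L'}_s]}
{[\mathrm{M}]^p[\mathrm{L}]^q[\mathrm{H}]^r[\mathrm{L'}]^s},$$

stored as $\log_{10}\beta$.  Coordinated hydroxide is represented by a
proton coefficient of $-1$ per OH (so Cu(OH)$_2$ has $r = -2$ and a
negative $\log\beta$), the convention that lets hydrolysis and
hydroxo-complex equilibria live in the same bookkeeping as protonation.
All constants are *conditional* constants at the stated medium (0.1 M
KNO$_3$, 20 °C for the bundled systems); no activity corrections are
applied anywhere, which matches how such constants are determined and
used.  Species charges are carried as optional metadata only — no charge
balance is enforced on species.

Five ready-made models are bundled: the Cu(II)/tyrosine binary system and
the Cu(II)/tyrosine/adenosine, /AMP, /ADP and /ATP mixed-ligand ternary
systems, with the published constants for the ternary species, the binary
Cu/Tyr complexes, the ligand protonation ladders, the auxiliary binary
Cu/nucleotide complexes and Cu(OH)$_2$.  The binary model contains exactly
the seven published binary/protonation species; each ternary model adds
only what is published for it.  Whether further mononuclear Cu hydrolysis
species took part in the original ternary refinements is not documented;
the fixtures deliberately include only the printed set.

The water autoprotolysis product is not documented for the bundled data
either; the models default to p$K_w$ = 13.78, a typical concentration
product for a 0.1 M inert electrolyte medium, and the value is
configurable per model.  It only matters for the hydroxo species and the
basic branch of titration curves.

## Solving the mass balances

At fixed pH the unknowns are the free concentrations of the non-proton
components.  For every component $j$ the analytical total must equal the
stoichiometry-weighted sum over species, $T_j = \sum_i \nu_{ij} c_i +
f_j$.  `solve_speciation()` runs Newton–Raphson iteration on
$\log_{10}$ free concentrations — the standard choice, since
concentrations span many decades and must stay positive — with three
safeguards: the step is clamped to 1 log unit per component, each step is
halved until the scaled residual decreases, and the logarithm of any
species concentration is capped to avoid overflow during wild trial
steps.  Convergence requires every mass balance to close to a relative
$10^{-10}$ (the default `tol`); non-convergence is an error carrying the
residual, never a silent result.  The initial guess is half the totals,
or the previous grid point when a distribution diagram is scanned.
Components with zero total, and species containing them, are excluded
from the solve and reported as exactly zero.

The pH convention throughout is $\mathrm{pH} = -\log_{10}[\mathrm{H}^+]$
on the concentration scale, the glass-electrode-calibrated-to-
concentration convention under which the bundled constants were
determined.  In fixed-pH mode the proton mass balance is *not* solved;
the electrode fixes $[\mathrm{H}^+]$.

`distribution()` scans a pH grid (default step 0.01, inclusive endpoints,
so 2.5–11.0 gives 851 points — fine enough that the curves are visually
smooth) and reports each species containing the reference component as a
percentage of that component's total, $100\,\nu_{\mathrm{ref},i}
c_i/T_\mathrm{ref}$.  Percentages referenced to a ligand are obtained by
re-running with that ligand as reference; they are never mixed into the
metal-referenced table.  Free reference is always computed and included
as a column; presentation can drop it.

## Simulating titrations

A titration is described as data (`titration_protocol()`): 30 mL initial
volume, ~0.20 M NaOH titrant, the analytical millimoles of each
component, the strong-acid content, and the number of titratable protons
each ligand carries *as weighed* (zwitterionic tyrosine 2, neutral
adenosine 0, the AMP and ATP salts 2, the ADP mono-salt 1).  Counterions
are inert spectators.  At titrant volume $v$ all totals are diluted by
$v_0/(v_0+v)$ and the base enters as negative acidity, giving the full
proton condition

$$T_\mathrm{H}(v) = \sum_i \nu_{\mathrm{H},i}\,c_i + [\mathrm{H}^+] -
K_w/[\mathrm{H}^+].$$

Each point solves this condition *simultaneously* with all component
balances by the same damped Newton iteration, with the proton as an
additional unknown and OH$^-$ as a pseudo-species with
$\log\beta = -\mathrm{p}K_w$.  One multidimensional solve per point,
warm-started from the previous point, is roughly an order of magnitude
cheaper than nesting a scalar pH root search around fixed-pH solves; the
scalar monotone-bracketing solve is retained as an automatic fallback
for cold starts and difficult points, and the test suite checks that
both routes agree to solver tolerance.

The initial acid content of the original experiments is not published;
`design_protocol()` therefore solves for the strong-acid amount that
makes each curve start at pH 2.5 and for the titrant volume that ends it
at pH 11.0 — the documented working window — rather than inventing a
particular acid recipe.  The concentration designs are the documented
ones: binary M:L = 1:2 at $C_\mathrm{Cu} = 10^{-3}$ M, ternary equimolar
1:1:1 at $10^{-3}$ M each, 250 readings uniform in titrant volume.

## Synthetic studies

`generate_study()` stands in for the unpublished raw data: it simulates
the protocol exactly and adds i.i.d. Gaussian noise to the pH axis only
(default $\sigma_\mathrm{pH}$ = 0.005, an electrode-grade figure chosen
once; burette volumes are treated as exact, the simplest error model
when the real error budget is unknown).  Replicate curves derive their
seeds deterministically from the base seed (`seed + index`), so a study
is reproducible as a whole, and the generator restores the global RNG
state.  What the generator does *not* emulate — electrode drift,
junction potentials, carbonate contamination, correlated errors — bounds
what a passing recovery test can show about real data: it validates the
estimator under the stated noise model, not the chemistry of a real
electrode.

## Refining constants

`refine()` emulates the role of a potentiometric refinement program: it
minimizes $\Sigma = \sum_i w_i(\mathrm{pH}^\mathrm{obs}_i -
\mathrm{pH}^\mathrm{calc}_i)^2$ over all points of all curves by
Levenberg–Marquardt, where $\mathrm{pH}^\mathrm{calc}$ re-simulates each
curve with the current constants.  Residuals are formed in pH, the
observed variable; unit weights are the default and
$w = 1/\sigma_\mathrm{pH}^2$ is available.  The $\Sigma$ statistic here
is defined as this weighted sum of squared pH residuals — internally
consistent and usable for ranking, but not numerically comparable with
the output of other refinement software whose weighting schemes differ.
The Jacobian uses central finite differences with a step of $10^{-4}$
log units (small against any chemically meaningful change in
$\log\beta$, large against solver noise at tolerance $10^{-10}$).
Standard deviations come from the scaled inverse normal matrix,
$s^2(J^TWJ)^{-1}$, $s^2 = \Sigma/(n-p)$.  A species that the optimizer
drives out of existence leaves a null Jacobian column; its standard
deviation is reported as infinite rather than failing the whole fit,
which is exactly the signal model selection needs.  Ligand protonation
and auxiliary binary constants are held fixed while ternary species are
refined, mirroring the usual staged treatment.

`select_model()` ranks candidate species sets the way potentiometric
practice does: most accepted species first, then lowest mean standard
deviation, then lowest $\Sigma$.  A species is rejected when its
standard deviation exceeds `sigma_max` (default 0.1) or its maximal
formation percentage stays below 2% of its reference component — a floor
below anything that would register in a published distribution diagram;
no printed threshold exists, so the default is deliberately
conservative.

## Equilibrium-constant bookkeeping

`log_Ke()` computes the constant of any reaction balanced in the model
components as the signed sum of $\log\beta$ values (products minus
reactants), with free components at $\log\beta = 0$.  Reaction strings
are parsed with H$_2$O treated as solvent of unit activity and dropped,
which makes hydroxo formation reactions written with explicit water
balance under the H$_{-1}$ convention.  Comparisons against printed
two-decimal values use `round()` (round-half-even) on the computed
difference.  `stepwise_protonation()` returns successive differences of
the protonation ladder, highest-p$K_a$ step first.

## Numerical choices and degenerate inputs

* Mass-balance tolerance $10^{-10}$ relative; titration root tolerance
  the same; refinement convergence at relative $\Sigma$ change
  $< 10^{-8}$ or gradient norm $< 10^{-8}$, at most 50 LM iterations.
* Residual scaling uses the larger of the analytical total and the gross
  positive species mass, so near-zero proton totals around the
  equivalence point do not inflate the convergence test.
* Ties in `dominant_species()` break lexicographically, with a warning.
* A species identically absent (zero total of a constituent component)
  reports a 0% peak at the first grid point.
* Empty `free_species` makes `refine()` a pure evaluation (0 iterations).

## Problem sizes used in the checks

The bundled end-to-end checks run at the documented design: 6 replicate
curves of 250 points each (1500 residuals, 4 free constants) for the
binary recovery, and 851-point distribution grids.  The full five-system
recovery check refines 4–6 constants per system from 6 curves each.
With these sizes the complete binary refinement takes tens of seconds on
one core; nothing in the methods requires larger problems.

## Known limitations

* No polynuclear species beyond what the fixtures contain, no
  precipitation equilibria, no temperature or ionic-strength
  extrapolation of constants.
* Simulated curves are protocol-parameterized, not replicas of any
  particular experimental burette record: the true initial acid content
  and titrant factor of the original experiments are unpublished.
* $\Sigma$ values are not comparable in absolute terms with other
  refinement programs.
* The pH-noise model is white and homoscedastic; recovery results under
  correlated or drifting errors would be less favorable.
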