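---
title: "Quantifying algal food contributions to Daphnia growth: dosing, endpoint statistics, and isotope mixing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying algal food contributions to Daphnia growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daphniafeed)
```

## The problem

A standard way to ask whether food *quality* (not just quantity) limits
zooplankton growth is to raise a grazer — here the cladoceran *Daphnia
magna* — on two phytoplankton foods supplied at *equal carbon*: a green
alga (*Chlorella vulgaris*, treatment CHL), a diatom (*Stephanodiscus
hantzschii*, STE), and their 50/50 mixture (MIX). Growth endpoints (adult
and offspring body length, offspring per adult) say *whether* the diets
differ; foregut cell counts say what was *ingested*; and stable-isotope
signatures say what was actually *assimilated* into tissue. The
scientifically interesting contrast is that ingestion and assimilation can
disagree: a grazer may ingest two foods roughly 50/50 yet build its tissue
almost entirely from one of them. `daphniafeed` implements each stage of
that analysis and a seeded generator of synthetic experiments with exactly
this structure, so the whole pipeline is testable end to end without
external data.

## Carbon-based dosing

Foods are dosed by carbon, not by cell count. Cells are treated as spheres
(only mean diameters are measured), so biovolume is $V = (\pi/6)d^3$ in
µm³, and per-cell carbon (pg) comes from the classical log-log
biovolume regressions, with a separate fit for diatoms whose vacuole-rich
cells carry less carbon per unit volume:

$$\log_{10} C = 0.866\,\log_{10} V - 0.460 \quad\text{(non-diatoms)},\qquad
  \log_{10} C = 0.758\,\log_{10} V - 0.422 \quad\text{(diatoms)}.$$

Both are configuration (`carbon_regression()`), not constants of the
method. The daily cell dose for a target of $T$ mg C L⁻¹ in $W$ litres is
$T \cdot W \cdot 10^9 / C$ cells (kept as a real number; rounding to whole
cells is a reporting step, half-up), and the stock injection volume is
cells ÷ stock density, rounded to 0.01 mL — the measurement precision of a
pipette. In a mixture each species carries a *carbon fraction* of the
target (0.5 each for a 50/50-by-carbon diet), and the planned carbon is
conserved exactly across any split:

```{r dosing}
plan <- build_dose_plan(default_species(), c(0.5, 0.5))
plan
plan_total_carbon_pg(plan) / 1e9   # = 2.5 mg C/L x 0.5 L
```

A protocol-level worked example the package reproduces: injecting
`injection_volume(8802, 687)` = `r injection_volume(8802, 687)` mL of a
687 cells mL⁻¹ diatom stock delivers ≈ 8800 cells. Note that printed
whole-experiment cell doses of a few thousand cells per beaker cannot be
reconciled with micrometre-scale cells under any published carbon
regression (they would supply nanograms, not milligrams, of carbon); the
package treats such printed doses as configuration inputs and never forces
agreement.

## Growth-endpoint statistics

Beakers are the experimental units and individuals within a beaker are
subsamples, so treating individuals as independent replicates would be
pseudo-replication. `nested_anova()` therefore decomposes individual-level
variance sequentially (Type-I, in the nesting order) into treatment,
beaker-within-treatment, and residual components, and — because beakers
are a *random* factor — tests the treatment against the
beaker-within-treatment mean square:

$$F_\text{treatment} = \frac{MS_\text{treatment}}{MS_\text{beaker(treatment)}},
\qquad
F_\text{beaker} = \frac{MS_\text{beaker(treatment)}}{MS_\text{residual}}.$$

Degrees of freedom always follow from the actual design: with $t$
treatments and $b$ beakers each, the treatment test has
$(t-1,\ t(b-1))$ df — for 3 × 10 that is (2, 27). Published tables for
this design sometimes print other beaker df; the package never adjusts its
df to match a printed table. Sequential SS means unbalanced (synthetic
edge-case) designs are decomposed in the stated order; the emulated design
is balanced, where Type-I and Type-III coincide.

Per-beaker fecundity (total offspring ÷ adults per beaker,
`offspring_per_adult()`) is already beaker-level, so it gets a classical
one-way ANOVA. Tukey HSD post-hoc tests (`tukey_hsd()`) run on
individual-level values with the residual MS by default; a
`"beaker_mean"` option aggregates to beaker means first for a
conservative beaker-level error term, since the original analysis does
not state its error term. Gut-content comparisons use pooled-variance
t-tests, either from raw counts (`t_test_raw()`) or directly from printed
means/SDs (`t_test_summary()`), which lets published summary tables be
re-analysed:

```{r gut-t}
t_test_summary(1966.0, 235.3, 20, 2130.0, 460.4, 20)
```

Degenerate inputs are defined, not errors: a response with no variance in
a stratum gives $F = 0$ for that stratum (negligible SS — rounding noise
from the least-squares fit — is zapped relative to the total before
ratios are formed).

## Two-source isotope mixing

Isotope signatures are in δ notation,
$\delta = (R_\text{sample}/R_\text{standard} - 1)\times 1000$ ‰, vs PDB
for ¹³C/¹²C and air N₂ for ¹⁵N/¹⁴N (`delta_value()`). A consumer eating
two isotopically distinct sources X and Y sits, after one trophic step, at

$$\delta_M = f\,\delta_X + (1-f)\,\delta_Y + \Delta,$$

where $\Delta$ is the trophic fractionation (the systematic diet-to-tissue
shift) and $f$ the fraction of assimilated material from source X. The
closed-form solution $f = (\delta_M - \Delta - \delta_Y)/(\delta_X -
\delta_Y)$ is implemented in `two_source_mixing()`. Design choices:

* **Mixing isotope: carbon.** The two algae separate strongly in δ¹³C;
  δ¹⁵N is carried through the tables for trophic-level context only.
  Consumer carbon samples must be lipid-extracted (lipids are ¹³C-depleted
  relative to protein), which the report enforces as a validation rule;
  lipid arithmetic itself is out of scope — extraction is a
  sample-preparation flag.
* **Fractionation is an assumption, reported side by side.** Both
  conventional values, 3.4‰ and 2.4‰ per trophic step, are computed for
  every consumer group (`contribution_report()`), since which one underlies
  a published point estimate is often unstated. A fractionation misjudged
  by $\epsilon$ biases $f$ by $\epsilon/(\delta_X-\delta_Y)$ — with
  sources 12‰ apart, 1‰ of Δ moves $f$ by ≈ 8 points, which is exactly
  the spread visible between the two Δ rows of a report.
* **Out-of-range solutions clamp with a flag.** Noise or a wrong Δ can
  push the raw $f$ outside $[0,1]$; the estimate is clamped to the nearest
  bound and `clamped = TRUE` surfaces in every table rather than crashing
  a pipeline run. $f_X + f_Y = 1$ always holds exactly.
* **Uncertainty: seeded percentile bootstrap on group means**
  (`mixing_uncertainty()`, default 2000 replicates). Each draw resamples
  the replicate δ values of mixture and both sources, recomputes the three
  means, and re-solves the model (clamped like the point estimate).
  Analytic first-order variance propagation was deliberately left out: the
  bootstrap handles the clamped, ratio-form estimator without linearity
  assumptions. With ~15 replicates per group the percentile interval's
  coverage sits slightly below nominal (≈ 92–94% for a 95% interval in the
  package's own simulations) — a known small-sample property of percentile
  intervals, acceptable here and stated rather than corrected.

```{r mixing}
two_source_mixing(-20, -16, -30, 2.4)
```

## What the generator emulates — and what it does not

`generator_config()` / `generate_experiment()` produce a complete
synthetic experiment with the design of the emulated study: 3 treatments
× 10 beakers × 5 adults (150 adults), 2 offspring measured and 2 foreguts
enumerated per beaker, triplicate isotope samples per group. Calibrated
defaults are the published endpoint summaries: adult length 2.78 ± 0.07
(CHL), 3.18 ± 0.05 (STE), 2.99 ± 0.07 mm (MIX); offspring length
1.08/1.14/1.08 mm; offspring per adult 11.4 ± 1.8, 26.2 ± 1.8,
18.5 ± 2.67 (beaker-level SDs — treating them so reproduces the
published one-way F ≈ 120 in expectation, a useful external consistency
check the tests do not assert). Structure:

* **Lengths**: treatment mean + beaker effect ~ N(0, `beaker_sd_mm`) +
  individual noise, with non-positive draws *resampled*, not clipped, so
  configured means stay unbiased. Between-beaker variance is not published
  separately; the default `beaker_sd_mm = 0.03` mm was chosen once as a
  modest but detectable beaker effect (beaker F ≈ 2–3 at the default
  design) and is a free knob.
* **Fecundity**: per-beaker offspring-per-adult ~ zero-truncated normal;
  totals rounded to whole animals, with the stored quotient recomputed
  from the rounded total so the tables are internally exact.
* **Guts vs isotopes — the central decoupling.** MIX foregut totals
  (~N(4096, 500), the sum of the published per-species gut means) split
  *binomially* with `ingestion_prop_X` (default 0.5), while consumer
  isotope signatures are mixed with `assimilation_prop_X` (default 0.92)
  and shifted by Δ (default 2.4‰ for carbon, 3.4‰ for nitrogen, noise SD
  0.1‰ — the instrument precision for δ¹³C). The two proportions are
  independently settable, and a regression test pins that changing one
  never perturbs the other's draws. Source δ¹³C defaults (−18‰ diatom,
  −30‰ green alga) are deliberately well-separated *placeholders* — real
  source values for a given culture must be configured, as published
  figures rarely print them as numbers.
* **Seeding**: one master seed spawns independent per-table substreams,
  so regenerating or adding a table never perturbs the others, and
  identical (config, seed) give byte-identical CSV output.

What the generator does **not** emulate: isotopic turnover dynamics (it
assumes the 8-day/second-clutch endpoint has fully equilibrated tissue),
selective feeding, gut-passage breakage of cells, algal growth or settling
within a day (daily renewal makes dosing memoryless), correlated endpoint
noise within an individual, and any predator or crowding effects. Passing
tests therefore show the *inference machinery* is correct under the
assumed hierarchical-normal/binomial structure — not that real data meet
that structure.

## Numerical and validation choices

Carbon-fraction sums are checked to 10⁻⁹; carbon conservation holds to
better than 1 part in 10⁶ before cell rounding. The mixing closed form is
cross-checked against a 10⁻⁶-step grid search in the test suite. Identical
source signatures raise an unidentifiability error rather than returning
an infinite estimate. Table validation (`validate_input_tables()`) flags
unknown treatment labels, non-positive lengths, inconsistent
offspring-per-adult quotients, beakers without records, and gut rows
referencing nonexistent individuals, each with table/row/column; a
pipeline run aborts naming its failing stage. Reports contain no
timestamps or machine-dependent values, so `write_report()` bundles are
byte-identical under identical (config, seed).

## Problem sizes used in the package's own simulations

The test suite and acceptance script use: 1000 random inputs for the
closed-form-vs-grid check; 500 repeats × 2000 bootstrap draws (n = 15 per
group, noise 0.1‰) for CI coverage; 2000 null datasets (3 treatments × 4
beakers × 3 observations, beaker SD 0.7) for the nested-ANOVA type-I
check; and 500 simulated experiments at the calibrated adult-size
defaults with 2 adults measured per beaker (n = 20 per group, as in the
emulated protocol) for power, where rejection is essentially certain — a
0.2 mm treatment separation is enormous against a ≈ 0.06 mm residual and
0.03 mm beaker SD. These sizes give Monte-Carlo standard errors
comfortably below the tolerances they are compared against.

## Known limitations

Two-source, one-isotope mixing only: no ≥3-source systems, no
concentration-dependent mixing, no Bayesian mixing (e.g. MixSIAR-style
priors), no lipid-normalisation arithmetic. The nested ANOVA is the
classical fixed-computation F-test, not a REML mixed model — variance
components are reported as mean squares, not estimated with shrinkage.
And the dosing module's printed-dose discrepancy (above) means per-beaker
cell doses from real protocols should be taken as configuration, not
re-derived.
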