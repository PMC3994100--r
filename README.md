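# daphniafeed

Analysis toolkit for controlled zooplankton feeding experiments in which a
cladoceran grazer (*Daphnia magna*) is raised on one or two phytoplankton
foods supplied at a fixed carbon concentration — a green alga
(*Chlorella vulgaris*, "CHL"), a diatom (*Stephanodiscus hantzschii*,
"STE"), or their 50/50-by-carbon mixture ("MIX"). It is written for
trophic ecologists who want the full quantitative chain of such an
experiment as tested, reproducible code:

1. **Carbon-based dosing** — spherical biovolume V = (π/6)d³ and the
   log-log carbon regressions (log₁₀C = 0.866·log₁₀V − 0.460 for
   non-diatoms, 0.758·log₁₀V − 0.422 for diatoms) convert cell diameters
   to per-cell carbon, daily cell doses for a 2.5 mg C L⁻¹ target, and
   stock injection volumes.
2. **Growth-endpoint statistics** — nested ANOVA with beakers as a random
   factor nested in treatment (F_treatment = MS_treatment /
   MS_beaker-within, guarding against pseudo-replication), one-way ANOVA
   and Tukey HSD for per-beaker fecundity, and pooled t-tests from raw
   data or from printed means/SDs.
3. **Two-source stable-isotope mixing** — the consumer signature is a
   fractionation-shifted convex combination of the two source signatures,
   δ_M = f·δ_X + (1−f)·δ_Y + Δ, solved for the assimilated fraction f at
   both conventional trophic fractionations (Δ = 3.4‰ and 2.4‰) with a
   seeded percentile-bootstrap interval.
4. **A synthetic-experiment generator** — 3 treatments × 10 beakers × 5
   adults with beaker-level random effects, calibrated to published
   endpoint summaries, in which the *ingested* gut-content split and the
   *assimilated* isotopic split are independent knobs. That decoupling is
   the scientific point: a grazer can ingest two foods ~50/50 yet
   assimilate them ~92/8.

## Worked example

```r
library(daphniafeed)

# dose plan for the mixed diet (each species at 1.25 mg C/L in 0.5 L)
build_dose_plan(default_species(), c(0.5, 0.5))
#> <carbon_dose_plan> 2.50 mg C/L in 0.50 L
#>        species carbon_fraction carbon_pg_per_cell cells_required injection_volume_mL
#>    C. vulgaris             0.5           6.527477       95749098            22096.12
#>  S. hantzschii             0.5           5.513973      113348398           164918.37

injection_volume(8802, 687)   # protocol worked example: 12.81 mL ~ 8800 cells
#> [1] 12.81

# simulate an experiment and run the whole analysis
report <- run_pipeline(run_config(seed = 101, n_boot = 2000))
report$endpoint_stats[1, c("endpoint", "test", "statistic", "p")]
#>          endpoint                   test statistic            p
#>   adult_length_mm nested_anova_treatment  188.9189 1.334216e-16
subset(report$mixing, group == "MIX" & fractionation_permil == 2.4)
#>   group fractionation_permil       f_X        f_Y pct_X pct_Y clamped    ci_low   ci_high
#>     MIX                  2.4 0.9240946 0.07590542    92     8   FALSE 0.9152876 0.9327847
```

The nested-ANOVA row says adult body length differs strongly among diets
when tested against between-beaker variation (F(2, 27) ≈ 189 here). The
mixing row says the mixed-diet consumers built ~92% of their assimilated
carbon from the diatom and ~8% from the green alga — even though their
foregut contents (ingestion) split ~50/50 — with a tight bootstrap CI
because the synthetic δ noise is the 0.1‰ instrument precision.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (`01_dose_plan.R` … `05_full_run.R`), writing tables under
`results/`.

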