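# mpnflux

Growth kinetics, ¹⁴C radiotracer flux calculus and carbon/phosphorus budget
closure for microbial methylphosphonate (MPn) utilization.

## What this package is for

In phosphate-depleted ocean regions, phosphonates — organophosphorus
compounds with a direct C–P bond — are a major phosphorus source.  Cells
that cleave MPn oxidatively (the PhnY/PhnZ pathway) release its single
carbon as formate instead of methane, and the fate of that carbon —
excreted, assimilated into biomass (specifically purine nucleotides), or
oxidized to CO₂ — decides what MPn degradation does to the marine carbon
cycle.

`mpnflux` is for experimentalists and modellers who need to turn
batch-culture measurements into that budget:

- **Growth kinetics** — specific growth rates µ (d⁻¹), logistic fits
  N(t) = K·N₀·e^{µt} / (K + N₀(e^{µt} − 1)) on ln-density, and maximum cell
  yields, from density time series.
- **Radiotracer fluxes** — per-cell carbon rates from scintillation counts:
  dpm / (effective specific activity × 2.22×10¹² dpm Ci⁻¹) normalised by
  cell inventory and incubation time, with isotope-dilution correction for
  unlabelled carrier.
- **Budget closure** — the cell-quota calculus µ_P = v_assim / Q_P, the
  growth-rate deficit µ_obs − µ_P, excess formate, and the three-way
  partition of cleaved carbon among excretion, assimilation and CO₂.
- **Fractionation accounting** — radiolabel shares per macromolecular
  fraction, brucite (Mg(OH)₂) coprecipitation splits, 2-D TLC spot
  assignment to nucleotide standards, linear assay calibration.
- **Survey statistics** — one-way ANOVA and Tukey HSD from closed forms,
  Yates-corrected two-proportion tests, and a presence screen over tabular
  protein-alignment output for pathway biogeography.
- **A seeded synthetic-data generator** for every input stream, with known
  ground truth, so the whole pipeline is testable end to end.

All user-facing functions take data frames first and return tibbles, so
calls chain with the pipe; fitted objects have `tidy()`/`glance()` methods
and `autoplot()`/`plot_*()` figures.

## Worked example

Close the carbon/phosphorus budget from the measured per-cell figures —
assimilation 4.3 amol C cell⁻¹ d⁻¹, CO₂ production 0.09 amol C cell⁻¹ d⁻¹,
P quota 20 amol cell⁻¹, observed growth 0.43 d⁻¹, per-cell formate 48
(MPn-grown) vs 27 (phosphate-grown) amol cell⁻¹:

```r
library(mpnflux)

b <- close_budget(
  v_assim = 4.3, v_co2 = 0.09, quota_P = 20,
  mu_obs = 0.43, formate_mpn = 48, formate_ref = 27
)
b
#> <carbon_budget> reconciliation
#>   P-specific growth rate: 0.22 /d (assimilation 4.3 amol C/cell/d over quota 20 amol P/cell)
#>   deficit vs observed 0.43 /d: 0.21 /d (from 2-d.p. rates; 0.215 /d unrounded)
#>   excess formate: 21 amol/cell (178% of reference level)
#>   formate-supported rate: 0.20 /d -> deficit explained 95% (raw) / 95% (2-d.p. inputs; capped at 100%)
#>   CO2: 2% of assimilation; quota-equivalent rate 0.0045 /d explains 2% of the deficit
#>   carbon fate partition (inventory_rate):
#>     excreted     4.51 amol C/cell/d  (51%)
#>     assimilated   4.3 amol C/cell/d  (48%)
#>     oxidized     0.09 amol C/cell/d  (1%)
```

Reading the report: phosphorus supply through MPn can only sustain
0.22 d⁻¹ of growth, 0.21 d⁻¹ short of what the cultures actually did — so
the cells must cleave far more MPn than they assimilate.  The excess
formate they excrete (21 amol cell⁻¹, nearly equal to the 20 amol P
cell⁻¹ quota) accounts for that extra cleavage, and the partition says
roughly half the cleaved carbon leaves the cell as formate, half ends up in
biomass, and under 1% is respired to CO₂.

The biogeographic screen works from a 12-column alignment table plus genome
metadata:

```r
ref <- phn_survey_reference()
rec <- screen_presence(ref$alignments, ref$metadata,
  reference_ids = c("MIT9301", "MIT9303"))
count_by_ocean(rec)
#> # A tibble: 3 × 3
#>   ocean n_present n_screened
#>   <chr>     <int>      <int>
#> 1 NAO          12         12
#> 2 NPO           1          1
#> 3 RS            3          3

ocean_enrichment(rec, c(NAO = 219, NPO = 187))$test
#> <prop_test_result> 14/219 vs 1/187 (0.0639 vs 0.00535)
#>   chi2 = 8.151, df = 1, p = 0.00215129 (greater, Yates-corrected)
```

So 6.4% of North Atlantic genomes carry the pathway against 0.5% in the
North Pacific — a significant enrichment in the basin where phosphate is
scarcest.

See the methods vignette (`vignettes/mpn-carbon-budget.Rmd`) for the model,
the conventions (window selection, excretion-flux construction, rounding,
one-sided continuity-corrected testing) and what the synthetic generator
does and does not emulate.

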