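# phycocarbon

Carbon-balance assessment of phycocyanin — the blue Spirulina
(*Arthrospira platensis*) food colorant — produced in an integrated system
where the extraction waste stream is applied as a soil biostimulant and
credited with soil organic carbon (SOC) sequestration. The package is
aimed at LCA practitioners and carbon-accounting analysts who want the
whole chain — functional-unit arithmetic, inventory characterization, SOC
crediting, sensitivity/scenario analysis, product and corporate case
studies, and field-trial statistics — as tested, configurable functions
rather than spreadsheet formulas.

## The model

The functional unit is one color unit (CU) of phycocyanin extract,

    CU/kg = A618 × 10 × DF / (g × 100),

equivalent to 7.12 g pigment. With an extraction yield of 3.22% of dry
biomass and a waste fraction of 15.8%, one CU implies 221.1 g dry biomass
and 34.94 g of biostimulant waste. Each gram of waste applied annually is
credited with 25.0 kg SOC/yr, converted at 44/12 to CO₂-eq and halved by a
50% reversal buffer (45.83 kg CO₂-eq/g). The net footprint per CU is

    net = (cultivation + extraction) − sequestration
        = (0.15 + 4.83) − 1602.48 = −1597.50 kg CO₂-eq/CU,

a strongly carbon-negative ingredient; a further 30% uncertainty margin
(case-study mode) gives −1118.25 kg CO₂-eq/CU. One-at-a-time sensitivity,
four system scenarios, a chocolate-dragee substitution case study, and
Kruskal–Wallis / bootstrap statistics for the two-site soil-core trial sit
on top, plus a seeded generator of synthetic trial data.

## Worked example

```r
library(phycocarbon)
run <- run_full(seed = 1)
run
#> Integrated phycocyanin carbon-balance run (seed 1 )
#>   Net footprint:            -1597.50 kg CO2-eq/CU
#>   Conservative (margin):    -1118.25 kg CO2-eq/CU
#>   Waste per CU:                34.94 g
#>   Trial 90% lower bound:       -0.13 tC/ha/yr (p = 0.125)
```

The net footprint is the headline: each color unit delivered removes about
1.6 t CO₂-eq net (1.12 t under the conservative margin). The trial line
comes from a synthetic two-site soil-core experiment simulated under the
default design (9/6 cores at baseline, 9/9 a year later, between-core CV
12%) and analysed by difference-in-differences with a seeded percentile
bootstrap — with this deliberately generic variability the bound is wide.
Individual pieces are plain functions:

```r
net_gwp_per_cu()                            # -1597.5
oat_sensitivity(parameters = "sequestration_rate")
#>            parameter delta net_kg_per_cu pct_change
#> 1 sequestration_rate  -0.2     -1277.004   20.06235
#> 2 sequestration_rate   0.2     -1917.996  -20.06235
run_scenario(scenario_spec("S4_high_pc_content"))$net_kg_per_cu
#> [1] -257.1975                              # 83.9% less carbon-negative
```

A thin command-line front end is at `inst/cli/phycocarbon-run.R`, and
`make_fixtures(dir)` writes the canonical inventory, recipe, factor and
config files (also shipped under `inst/extdata/`).

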