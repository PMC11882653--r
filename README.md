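# hydroniche

Quantifying the **fundamental niche of poikilohydric lichens** from
hydration-resolved CO2 gas-exchange measurements — and linking the
extracted physiology to an ordinal rank of temperate-rainforest habitat
association.

Lichens equilibrate their water status with the environment, so net
photosynthesis (NP) depends jointly on thallus water content (WC) and
irradiance: NP falls off when the thallus is desiccated *and* when it is
suprasaturated (excess water raises CO2 diffusion resistance). The
standard laboratory protocol records a series of light-response curves
(PPFD steps 0–1500 µmol photons m⁻² s⁻¹) while a thallus dries in a
minicuvette, weighing it between curves. `hydroniche` turns those drying
runs into the field's core parameters and runs the downstream species
comparisons:

| Parameter | Meaning | Unit |
|---|---|---|
| LCP / LSP | light compensation / saturation point (zero / 90%-of-max NP crossing) | µmol photons m⁻² s⁻¹ |
| MaxNP, DR | maximum net photosynthesis; dark respiration magnitude | nmol g⁻¹ DM s⁻¹ |
| CGE | carbon gain efficiency, MaxNP / DR | – |
| MinWC, MaxWC, OptWC | WC bounds where NP ≥ 90% of MaxNP; OptWC = MaxWC − MinWC | % of DM and mm rainfall equivalent |
| STM, WHC | dry mass per area; water storage per area | mg cm⁻²; mm |
| Chl | chlorophyll a, a+b per mg DM (DMSO extracts, A665/A649) | µg mg⁻¹ DM |

(1 mm rainfall equivalent ≡ 100 mg H2O cm⁻²; `wc_mm = wc_pct · STM / 10⁴`.)

The package also ships:

* a **calibrated simulator** of the measurement protocol (seven study
  species, configurations solved so the noise-free model reproduces the
  published species means), giving every stage a known ground truth;
* the **inference layer** implemented from first principles: Shapiro–Wilk
  screening with a log/sqrt transformation ladder, one-way ANOVA, Tukey
  pairwise tests with an insert-and-absorb compact letter display, Pearson
  correlation, and a proportional-odds ordinal regression
  (`P(Y ≤ j|x) = plogis(ζ_j − βx)`, observed-information SEs) used to scan
  every core parameter against the 1–7 habitat-association rank;
* a desk-scale **realised-niche module** (occurrence cleaning with audit
  counts, nearest-cell climate joins, precipitation-breadth summaries);
* a **pipeline/CLI** (`inst/cli/hydroniche.R`, subcommands
  `simulate | extract | stats | niche | run`).

## Worked example

```r
library(hydroniche)

# simulate the seven-species panel (3 replicates, 10 curves per drying run)
panel <- fixture_panel(seed = 42, n_replicates = 3, n_curves = 10)

# extract core parameters from every drying run
core <- extract_core_parameters(panel$runs)
head(core[c("sample_id", "lcp", "lsp", "max_np", "dr_max", "cge",
            "min_wc_mm", "max_wc_mm", "opt_wc_mm")], 4)
#>         sample_id   lcp  lsp max_np dr_max  cge min_wc_mm max_wc_mm opt_wc_mm
#> 1 L_pulmonaria_r1 143.9  972  30.97   6.83 8.68    0.0692     0.154    0.0847
#> 2 L_pulmonaria_r2  97.4  926  14.55   4.64 3.38    0.0521     0.107    0.0547
#> 3 L_pulmonaria_r3  76.4  906  20.60   6.32 4.78    0.0522     0.115    0.0625
#> 4  R_calicaris_r1 123.3 1146   9.56   2.65 4.88    0.0880     0.126    0.0379

# ordinal habitat-association scan (per-sample rows inherit species ranks)
scan <- habitat_association_scan(core, panel$ranks)
head(scan$table, 4)
#>   parameter   beta     se     t       p converged
#> 1 max_wc_mm 19.022 5.3096  3.58 0.00034      TRUE
#> 2 min_wc_mm 30.107 9.1658  3.28 0.00102      TRUE
#> 3 opt_wc_mm 21.616 7.2338  2.99 0.00281      TRUE
#> 4    max_np -0.199 0.0737 -2.69 0.00705      TRUE

# Tukey compact letter display for (log) MaxNP across species
tukey_cld(log(core$max_np), core$species_code)$letters
#>  P_atlantica  H_laevigata  R_calicaris     R_virens  S_sylvatica L_pulmonaria
#>          "a"         "ab"         "ab"        "abc"        "bcd"         "cd"
#>    S_limbata
#>          "d"
```

Reading it: the water-relations parameters (MaxWC, MinWC, OptWC in mm)
show the strongest positive slopes on the habitat-rank scale — species
more strongly associated with the temperate rainforest need more water to
reach and hold maximal photosynthesis — while S. limbata sits alone at the
top of the MaxNP letter display. Both patterns reproduce the published
findings on fully synthetic, calibrated data.

The same thing from the shell:

```sh
Rscript inst/cli/hydroniche.R simulate --seed 42 --out-dir demo
Rscript inst/cli/hydroniche.R extract --gas-exchange demo/gas_exchange.csv \
        --samples demo/samples.csv --out demo/core.tsv
Rscript inst/cli/hydroniche.R stats --core demo/core.tsv --out demo/stats.json
```

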