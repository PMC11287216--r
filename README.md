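# sedguilds

Depth-resolved functional guild profiling of sediment MAG communities,
plus dark dissolved-inorganic-carbon (DIC) assimilation rate
normalization.

## The problem

In aphotic, often hypersaline sediments, primary production is carried
out in the dark by chemotrophic autotrophs. Shotgun metagenomics of such
sediments yields metagenome-assembled genomes (MAGs) that are incomplete
and redundant, and the interesting biology — who fixes CO2, with which
pathway, using which electron donors and acceptors, and how that changes
with depth — has to be inferred from marker-gene presence calls.
`sedguilds` implements that annotation-level analysis as a tested,
reusable pipeline for anyone working with per-MAG quality estimates,
marker tables and pairwise average nucleotide identity (ANI) values:

1. **QC filtering** — retain MAGs with completeness > 50% and
   contamination < 10% (strict inequalities).
2. **OTU collapsing** — single-linkage clustering of MAGs at
   symmetrized ANI > 95% (the approximate species boundary), with
   representative selection that maximizes completeness, then minimizes
   contamination, then maximizes read-mapping abundance.
3. **Guild classification** — a configurable rulebook maps marker
   presence to the six recognized autotrophic CO2-fixation pathways
   (CBB keyed by RuBisCO + PRK; rTCA by ATP-citrate lyase or the
   citryl-CoA synthetase/lyase couple; Wood–Ljungdahl by CODH/ACS +
   FHS; 3HP; 3HP/4HB; DC/4HB by differential diagnosis via pyruvate
   synthase), to an oxygen relationship (cytochrome *c* oxidase →
   aerobe; cytochrome *bd* only → aerotolerant anaerobe; neither →
   anaerobe), to a trophic class (autotroph, facultative autotroph,
   heterotroph, fermenter) and to an electron donor/acceptor
   repertoire (H2, sulfide, thiosulfate, arsenite, methane; O2,
   nitrate, sulfate, S0/polysulfide, and more). OTU-level calls pool
   evidence across member MAGs, since absence in an incomplete genome
   is weak evidence.
4. **Depth profiling** — community fractions per guild and per
   CO2-fixation pathway at each depth, with the standard >2% display
   filter.
5. **Rate normalization** — 14C-bicarbonate uptake (DPM gdws⁻¹ h⁻¹) is
   converted to total DIC assimilation (nmol C gdws⁻¹ h⁻¹) using
   two-species carbonate speciation, [HCO3⁻] = [CO2]·10^(pH−pKa) with
   pKa = 6.3, DIC = CO2 + HCO3⁻, the tracer specific activity (52 µCi
   µmol⁻¹, 2.22×10⁶ DPM µCi⁻¹) and the isotope dilution factor
   (total DIC / label added). Published volumetric rates
   (µmol C cm⁻³ day⁻¹) convert to gravimetric hourly rates via an
   assumed sediment density (default 2.0 g cm⁻³).

A synthetic community generator (`generate_community()`) plants a
depth-structured guild composition with known ground truth —
completeness-driven marker dropout, contamination-driven foreign
markers, within-OTU ANI block structure, porewater gradients — so the
whole pipeline is testable end to end without any sequence data.

## Worked example

```r
library(sedguilds)

# published intertidal surface rates, converted to gravimetric units
signif(volumetric_to_gravimetric(0.18, density_g_per_cm3 = 2.0), 2)
#> [1] 3.8      # nmol C gdws^-1 h^-1
signif(volumetric_to_gravimetric(0.1, 2.0), 2)
#> [1] 2.1

# a synthetic sediment column, run end to end
com <- generate_community(seed = 7)
res <- run_pipeline(com$mags, com$ani, com$marker_table, com$porewater,
                    verbose = FALSE)
res$pathway_profile
#> # A tibble: 9 x 3
#>   depth_cm pathway_id fraction_pct
#> 1        0 CBB                15.8
#> 2        0 WL                 14.8
#> 3        0 rTCA                0
#> 4        5 CBB                10.8
#> 5        5 WL                 31.0
#> 6        5 rTCA                0
#> 7       30 CBB                 0
#> 8       30 WL                 45.9
#> 9       30 rTCA               10.8
res$rates[, c("depth_cm", "dic_uM", "rate_nmol_per_gdws_h")]
#> # A tibble: 3 x 3
#>   depth_cm dic_uM rate_nmol_per_gdws_h
#> 1        0  4077.                21.2
#> 2        5  3422.                17.8
#> 3       30  1316.                 6.84
```

The pathway profile recovers the planted depth structure: the
Wood–Ljungdahl fraction (the cheapest CO2-fixation route, ~1 ATP per
pyruvate vs 7 for CBB) grows with depth as the community turns anaerobic,
CBB autotrophs disappear below the suboxic zone, and an rTCA autotroph
appears only in the deepest interval. The normalized DIC assimilation
rates fall in the 5–20 nmol C gdws⁻¹ h⁻¹ range typical of aquatic
sediments.

A thin command-line wrapper is included:

```sh
Rscript exec/sedguilds simulate --out in/ --seed 7
Rscript exec/sedguilds run-all --mags in/mags.tsv --ani in/ani.tsv \
    --markers in/markers.tsv --porewater in/porewater.tsv --out out/
Rscript exec/sedguilds catalog-export --out my_rules.yaml
```

## Package layout

- `R/` — marker catalog (`load_catalog`), geochemistry
  (`normalize_rates` and friends), clustering (`cluster_otus`),
  classification (`classify_otus`), profiling (`guild_profile`,
  `pathway_profile`), synthetic data (`generate_community`), pipeline
  (`run_pipeline`).
- `inst/extdata/default_catalog.yaml` — the editable default rulebook.
- `vignettes/guild-profiling.Rmd` — the methods vignette: model,
  assumptions, parameter choices, limitations.
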