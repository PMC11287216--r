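---
title: "Guild profiling of sediment MAG communities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guild profiling of sediment MAG communities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedguilds)
```

This vignette is the package's own account of the science it implements:
the models and decision rules, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## Rate normalization

Dark DIC assimilation in sediments is usually measured by incubating
sediment with a spike of ^14^C-bicarbonate and counting assimilated
label (DPM per gram dry-weight sediment per hour). Two corrections turn
that signal into a total DIC assimilation rate.

**Carbonate speciation.** Porewater measurements typically give
dissolved CO~2~ and pH but not bicarbonate. Assuming the CO~2~/HCO~3~^−^
couple is at equilibrium, the Henderson–Hasselbalch relation gives

$$[\mathrm{HCO_3^-}] = [\mathrm{CO_2}]\cdot 10^{\,\mathrm{pH} - pK_a},
\qquad \mathrm{DIC} = [\mathrm{CO_2}] + [\mathrm{HCO_3^-}],$$

with an apparent $pK_a = 6.3$. This is deliberately a two-species
treatment: carbonate ion, activity coefficients and salinity-corrected
equilibrium constants are out of scope, which overstates nothing at
circumneutral pH where CO~3~^2−^ is negligible, but users working above
pH ≈ 9 should use a full carbonate-system model instead.

**Isotope dilution.** The label is a tracer within a much larger
unlabeled DIC pool, so measured label uptake underestimates total DIC
uptake by the ratio of pool to label. `radiotracer_rate()` computes

$$r = \frac{\mathrm{DPM}}{2.22\times 10^{6}\,\mathrm{DPM/\mu Ci}
 \cdot a}\; \cdot d \cdot 1000
 \quad [\mathrm{nmol\,C\,gdws^{-1}\,h^{-1}}],$$

with specific activity $a$ (default 52 µCi µmol^−1^) and dilution
factor $d$ = total DIC amount / label amount (default label 1 µmol).
Design notes:

* The 2.22×10^6^ DPM/µCi constant is definitional; it is still exposed
  as a parameter so a lab using Bq-based bookkeeping can adapt.
* The dilution factor multiplies (not divides): a larger unlabeled pool
  means each counted disintegration represents more carbon. The factor
  is caller-supplied and dimensionless, so the opposite convention can
  be exercised if someone wants to reproduce a differently worded
  protocol.
* Converting a DIC *concentration* (µM) into an *amount* needs the
  incubation porewater volume, which protocols often leave implicit;
  `dic_dilution_factor()` makes it explicit (default 10 mL in
  `normalize_rates()`).
* Report output rounds to 2 significant figures, the precision at which
  such rates are conventionally quoted.

`volumetric_to_gravimetric()` converts literature rates in
µmol C cm^−3^ day^−1^ to nmol C gdws^−1^ h^−1^ via an assumed sediment
density, default 2.0 g cm^−3^ (sand-rich sediments span roughly
1.7–2.3). E.g. 0.18 µmol cm^−3^ day^−1^ → 3.75 → "3.8" at 2 s.f.

## QC, OTU collapsing, representatives

MAGs pass QC when completeness > 50% **and** contamination < 10%, both
strict — a MAG at exactly 10.0% contamination is rejected. OTUs are the
connected components of the graph whose edges are MAG pairs with
symmetrized ANI strictly above 95%. Choices made here:

* **Symmetrization**: ANI estimators are directed; the two directions
  are averaged by default (`max`/`min` available), with a missing
  direction falling back to the present one.
* **Linkage**: single linkage (connected components) is the common
  dereplication interpretation of "collapse at a threshold" and is
  independent of input order, which we assert by property test.
* **Strictness**: a pair at exactly 95.0% does not link.
* OTUs may span depths; an OTU's abundance at a depth is the sum of its
  members' read fractions there (zero where it has no member).

Representatives maximize completeness, then minimize contamination,
then maximize read-mapping abundance; a residual tie goes to the
lexicographically smallest id so results are reproducible.

## The rulebook

The catalog (`inst/extdata/default_catalog.yaml`) declares every marker
(id, EC number, role, hydrogenase group) and every decision rule, and
`load_catalog()` validates that all references resolve. The default
rules:

| pathway | rule | ATP/pyruvate |
|---|---|---|
| CBB | RuBisCO **and** PRK | 7 |
| rTCA | ACLY **or** (ccs **and** cit) | 2.5 |
| WL | CODH/ACS **and** FHS | 1 |
| 3HP | PCC, MCR, MCL, ACC (all) | n/a |
| 3HP/4HB | 3HP set **and** 4-BUDH | 9 |
| DC/4HB | 4-BUDH **and** POR, **while** 3HP set incomplete | 5 |

Open-design decisions, and why they went the way they did:

* **rTCA as a disjunction.** ATP-citrate lyase and the citryl-CoA
  synthetase/lyase couple are alternative citrate-cleavage systems;
  requiring all three markers jointly would miss genomes that encode
  only one complete system. This is a judgment call — marker lists in
  the literature rarely state the boolean combination — recorded here
  as a `required_any` rule that users can tighten in a catalog copy.
* **CBB conjunction.** RuBisCO-like proteins occur outside the CBB
  cycle; co-requiring phosphoribulokinase guards against false
  positives at the cost of sensitivity in very incomplete genomes.
* **DC/4HB differential.** No single enzyme is diagnostic for DC/4HB;
  it shares enzymes with rTCA and 3HP/4HB and is operationally
  distinguished by pyruvate synthase. The rule fires on 4-BUDH + POR
  only while the 3HP set is incomplete and is flagged low-confidence.
  This makes the rule deliberately **non-monotone**: completing the 3HP
  set converts the call into 3HP + 3HP/4HB. Every other rule in the
  engine is monotone in presence evidence (adding markers never removes
  a call), and the property tests assert monotonicity for exactly that
  monotone portion.
* **3HP ATP cost.** The package stores no ATP figure for the 3HP
  bicycle and prints "n/a" rather than inventing a number.
* **Oxygen classes.** Cytochrome *c* oxidase implies O~2~ respiration
  (aerobe, and O~2~ joins the acceptor list); cytochrome *bd* alone is
  treated as detoxification (aerotolerant anaerobe, O~2~ **not** an
  acceptor); neither means anaerobe.
* **Hydrogenase semantics.** Group 1a/1c are uptake, 4d/4g and FeFe are
  H~2~-evolving, 3b is bidirectional (both), 3c is an uptake-type
  bifurcating complex. Uptake capability puts H~2~ in the donor list;
  an evolving group supports the fermenter call.
* **Central-set completeness.** Glycolysis, TCA and pentose-phosphate
  status are assessed from small configurable marker sets; "complete"
  means all members present with an `allow_missing` knob (default 0,
  set 1 to accommodate "nearly complete" pathways in partial genomes).
* **Carbon classes.** Fixation pathway present → autotroph; plus all
  three central sets complete → facultative autotroph. No pathway, no
  terminal oxidase, complete glycolysis and an H~2~-evolving
  hydrogenase → fermenter; otherwise heterotroph.
* **OTU cross-check.** OTU calls re-run the classifiers on the *union*
  of member marker sets, with an evidence map recording which member
  contributed each marker. Union semantics is the right default because
  genome incompleteness makes absence weak evidence; it does mean a
  contaminant marker in any member can propagate to the OTU call, which
  is why contamination is QC-capped upstream.
* **Literature overrides** (expert adjustment of calls from cultured
  relatives) are not automatable and are out of scope for the rule
  engine; they can be applied downstream on the call table.

## Depth profiles

`guild_profile()` sums OTU abundances per (oxygen class × carbon class)
guild and depth. Fractions are renormalized over classified OTUs by
default — so they sum to 100 at each depth — because display filters
and unclassifiable OTUs otherwise make depths incomparable;
`renormalize = FALSE` keeps raw percentages of all mapped reads and
reports the unclassified remainder. `abundance_filter()` implements the
usual display rule (> 2% in at least one depth) with a strict
inequality. An OTU encoding several fixation pathways contributes its
full abundance to each pathway fraction; overlap is documented rather
than split, since pathway fractions answer "how much of the community
*could* fix carbon this way".

## The synthetic community generator

`generate_community()` plants ground truth and emits every input table
the pipeline reads. What it emulates:

* **Seven guild archetypes** with one canonical marker template each
  (aerobic heterotroph; sulfur-oxidizing CBB facultative autotroph;
  WL acetogen; aerotolerant WL sulfate reducer; anaerobic rTCA
  autotroph; fermentative H~2~-evolving heterotroph; anaerobic
  heterotroph), chosen so each template exercises a distinct path
  through the rule engine (asserted by test).
* **A depth-structured mixture** over depths 0, 5 and 30 cm in which
  aerobes decline (60% → 40% → 8% expected), autotrophs and the WL
  fraction grow with depth, CBB is confined to the upper suboxic
  intervals and rTCA appears only at depth — the canonical redox
  stratification of a euxinic sediment column.
* **MAG quality**: completeness ~ N(85, 10) truncated to (50, 100] and
  contamination ~ N(2, 2) truncated to [0, 10), realistic for
  moderate-to-high-quality bins and intentionally inside the QC gate so
  the planted partition stays recoverable.
* **Marker dropout**: each template marker is retained with probability
  completeness/100 (the simplest model under which marker absence is
  exactly as informative as genome incompleteness allows), plus
  Poisson-distributed foreign markers at 0.1 per contamination percent.
* **ANI block structure**: directed within-OTU values ~ N(98, 0.5) and
  between-OTU ~ N(85, 3). The configuration validator enforces
  mean~within~ − 2sd > 95 > mean~between~ + 2sd, which makes
  misclustering improbable by design — the seed-sweep recovery
  experiment measures exactly how improbable.
* **Abundances**: one Dirichlet draw per depth over the OTUs present
  there, with concentration 500 split proportionally to the planted
  guild mixture; per-depth read fractions scale to exactly 100.
* **Porewater**: deterministic linear gradients (pH 7.4 − 0.01·depth,
  CO~2~ 300 − 4·depth µM, flat 60 000 DPM gdws^−1^ h^−1^) chosen so
  normalized rates land at ~7–21 nmol C gdws^−1^ h^−1^, the range
  typical of dark DIC assimilation in aquatic sediments.

One root seed drives all draws through R's default generator, so a seed
reproduces a community exactly. `mags_per_otu` (default 3–5) is a
total-size range; the generator first places one MAG at every depth
where the OTU's guild is planted so the planted per-depth abundances
are realizable, then spreads extras across those depths.

What it does **not** emulate — and hence what passing tests do not show
about real data: no sequences or read mapping (abundances are exact, not
estimated), no taxonomy, no correlated marker loss (real assembly drops
whole genomic regions, not independent genes), no chimeric bins beyond
uniform foreign-marker draws, no ANI values near the threshold (real
populations can straddle the species boundary), and no depth compaction
or porewater volume uncertainty. Recovery rates on synthetic data are
therefore upper bounds on real-data performance.

## Problem sizes and numerical choices

The default scenario (14 OTUs, ~60 MAGs, 3 depths) runs the full
pipeline in well under a second, so the test suite sweeps 20 seeds and
the clustering property test checks 100 random matrices of up to 12
MAGs against a brute-force transitive-closure oracle while keeping the
whole suite under a minute. Tolerances: exact identities are asserted
exactly (DIC sum, speciation at pKa); floating comparisons use 1e−9
(profile sums) or 1e−12 relative (unit-conversion round trip). Ties in
representative selection and OTU numbering are broken lexicographically;
generated OTU ids are zero-padded so file sorts match numeric order.

## Known limitations

* Marker presence is taken at face value; there is no homology
  searching, no hydrogenase motif inspection, and no per-gene
  confidence.
* The strict-conjunction pathway rules may be more conservative than
  manual curation practice (a lone RuBisCO is never called CBB); the
  `allow_missing` knob applies to central metabolism only, not to
  pathway diagnostics.
* Union-based OTU calls can be poisoned by a contaminated member (see
  above).
* The two-species carbonate model and the fixed density conversion are
  approximations appropriate to circumneutral, sand-rich sediment
  settings.
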