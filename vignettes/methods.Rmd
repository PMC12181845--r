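---
title: "Identifying parasites in eDNA metabarcoding surveys: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying parasites in eDNA metabarcoding surveys: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parafind)
```

## The problem

Environmental DNA (eDNA) metabarcoding of lake water yields thousands of
amplicon sequence variants (ASVs), only a fraction of which belong to
parasitic taxa. Deciding which ASVs are parasites is not a taxonomy lookup:
reference databases rarely label parasitism, and the evidence has to be
assembled from the metadata of similar reference sequences (whose "host"
fields reveal what the organism was isolated from) and from the literature
on the species an ASV can be confidently assigned to. `parafind` implements
that evidence-integration procedure as a deterministic, testable rule
engine, together with the downstream community statistics a warming-contrast
lake survey needs: negative-control decontamination, habitat-indicator
permutation tests, and Poisson richness models.

The package is organised around a survey design of paired habitat classes
— artificially heated lakes versus unheated control lakes, sampled each
season over two years — but every stage takes plain tables and is usable
for any two-class eDNA survey.

## Classification rules

An ASV's similarity hits (tabular, `outfmt 6` plus a query-cover column)
are thresholded at **>= 90% identity and 100% query cover** (both
inclusive; cover is compared after rounding to one decimal, tolerating
tools that print 99.97 as 100). At most the **top ten** qualifying hits per
query are kept, ordered by descending bitscore. Ties in bitscore are
resolved by ascending e-value, then descending identity, then accession;
this four-level key is total, so the best hit is a pure function of the hit
set and results are reproducible across platforms and input orderings.
Whether thresholds apply before or after the top-ten truncation is
configurable (`filter_first`); the default filters first.

Host evidence is read from the **top-bitscore hit only** (an optional mode
scanning all retained hits exists but is off by default). Each host string
of the hit's reference record is classified against three substring
lexicons, in order: **abiotic** samples (water, soil, mud sediment, ...),
**non-living substrates** (decaying log, fallen branch, ...), and
**symbiont context** (endosymbiont, lichen-associated, pathobiome, ...);
a string matching none denotes a live host. A record whose host strings or
source note indicate symbiont context is disqualified outright. Otherwise
the record is GenBank-positive when at least one live-host string is
present; abiotic strings alongside a live host are treated as sample
context, not disqualifying.

Literature evidence is keyed on the species assignment. An ASV is assigned
to species when its best hit is **strictly above 98% identity** to a
species-rank record, or when the dataset's native taxonomic assignment is
already at species level. A matching literature row with
`is_parasite = TRUE` makes the ASV literature-positive; without a species
assignment an ASV cannot be literature-positive. The final verdict is:

* `both` / `genbank_only` / `literature_only` — parasite, with provenance;
* `none` — non-parasite, with the most informative exclusion reason
  (symbiont > abiotic > non-living > no host evidence).

When literature explicitly marks a species non-parasitic while the record
carries live-host metadata, the default policy lets host metadata win and
flags the conflict (`conflict_policy = "literature"` reverses this). The
published procedure this engine reconstructs resolved such cases manually
and did not state a rule, so the policy is explicit and logged.

Host strings of parasites are mapped to broad host groups (green algae,
diatoms, dinoflagellates, crustaceans, terrestrial plants, humans,
salamanders, ...) by ordered rules — exact species name, then genus, then
lineage fragment; first match wins, with an `unresolved` fallback. The map
is data, not code, and ships as an editable table
(`default_host_group_map()`), as do the exclusion lexicons and the taxon
scopes used to assemble reference collections (`build_collection()`): these
reconstruct published supplementary lists and are intended to be replaced
by the user's own.

## Decontamination

Contaminants are defined by presence (count >= 1) in a no-template
negative control; no frequency-based inference is attempted. Removal is
per sequencing run by default — an ASV contaminating run 1's control is
zeroed only in run 1's samples — because surveys report per-run contaminant
counts; `per_run = FALSE` removes globally. The per-run report gives the
contaminant ids and the removed read fraction of that run.

## Indicator analysis

Habitat preference is tested on presence/absence. For each ASV the
statistic is the **occurrence frequency within each habitat class**; the
preferred class is the larger one. The null distribution permutes the
sample-to-class labelling (9999 permutations by default, one shared
permutation stream across ASVs so joint summaries keep their cross-ASV
correlation), recomputes the max-class statistic, and applies the add-one
estimator `p = (1 + #{perm >= obs}) / (1 + n_perm)`, which never returns
zero. When the design admits no more distinct labelings than requested
permutations, the null is enumerated exhaustively instead. P-values are
Sidak-corrected with k = number of classes (2). This is a documented
reimplementation of the group-association idea, not a bit-exact port of
any existing function; numerical identity with other implementations is
not claimed.

One calibration property deserves emphasis. With 35 + 35 samples the
statistic takes values on a grid of 1/35, and the tie mass at the observed
value makes the permutation test **structurally conservative**: across
simulated null ASVs the empirical rate of `p < 0.05` is about 0.02–0.03,
not 0.05. This is a property of any discrete permutation statistic under
the `>=` counting convention, not an implementation error; the test never
exceeds its nominal level. Significance calls (`p_sidak < alpha`) are kept
separate from display filtering (e.g. showing only indicators present in
more than 20% of samples).

## Richness models

Group richness is the count of distinct present ASVs of a focal group per
sample. Focal groups default to the four most ASV-rich parasite groups of
the survey this design mirrors — chytrids, aphelids, Peronosporomycetes
(from Gyrista, protist dataset) and Cryptomycota (fungal dataset) — after
excluding ASVs whose hosts are exclusively terrestrial; chytrids with
salamander hosts stay in the richness group but are dropped from the
host-correlation analysis, whose host richness covariate counts ASVs of
the Chlorophyta, Charophyta, Chromista, Gyrista and Dinoflagellata
subdivisions.

The model is `richness ~ lake_type * season` with a **Poisson log link**
and sum-to-zero contrasts, optionally with random intercepts for lake,
sequencing run and year through a mixed-effects backend; a singular or
failed mixed fit falls back to fixed effects and says so in the fit
metadata. (The source procedure describes both a log transformation of
richness and a Poisson family; these are incompatible as written, and the
family statement wins here — counts are modelled untransformed on the log
link, while the host-richness covariate enters as `log(host + 1)`.)
Type-III Wald chi-square tests come from `car::Anova`; sum-to-zero
contrasts make them invariant to factor-level relabelling, which the test
suite checks.

Effect sizes use the deviance partial R-squared,
`(dev_reduced - dev_full) / dev_reduced`, clipped to [0, 1], for a reduced
model dropping exactly one term. The package cited in the source used one
of several R-squared variants without saying which; the deviance ratio is
the documented default here and should be read as an approximation when
comparing against published values. The per-lake-type post-hoc analysis
(`host_correlation_posthoc()`) fits fixed-effects GLMs
`richness ~ log(host_richness + 1) + season`, mirroring the published
post-hoc choice of dropping random effects after singular fits.

`lake_type_contrast()` reports the heated-minus-control difference in
linear predictor averaged over seasons. Under a multiplicative habitat
effect *m* on expected richness it estimates log *m* whatever the contrast
scheme — the sum-to-zero main-effect coefficient itself is only half the
habitat difference, a detail that matters when validating effect recovery.

## The synthetic-study generator

Real surveys of this kind cannot be regenerated at desk scale (raw reads,
live reference metadata), so validation rests on a seeded generator whose
defaults encode the emulated design: 5 heated + 5 control lakes, four
seasons over two years with no summer sampling in year 2 (70 lake samples;
an `autumn_extra_year1` flag reproduces the variant with a second autumn
visit in year 1), one no-template negative control per run, and about 450
ASVs across parasite groups (60 chytrids, 35 aphelids, 31
Peronosporomycetes, 30 Cryptomycota, terrestrial-host parasites) and
non-parasite groups (hosts, bystanders, 5 trace-level contaminants).

Occupancy is Bernoulli per sample with a multiplicative structure on the
log-probability scale: baseline 0.08, season offsets
(winter −0.2, spring 0.1, summer 0.3, autumn 0.2), a per-lake lognormal
offset (sd 0.15), and a ×2 heated-lake multiplier for chytrids and
aphelids. The multiplicative (log) form, rather than a logit-additive one,
is deliberate: it makes an injected multiplier *m* correspond exactly to a
log-link coefficient of log *m*, since expected richness is the sum of
occupancy probabilities. A shared per-sample latent factor (sd 0.3) scales
host-group occupancy by `exp(u)` and chytrid occupancy by `exp(0.5 u)`,
producing the positive host–parasite richness coupling the correlation
analysis expects. Planted indicator ASVs (8 heated, 4 control by default)
occupy their preferred habitat with probability 0.9 and the other with
0.1. Read counts for present ASVs are `1 + Poisson(29)` — magnitudes are
inert, since every analysis uses presence/absence or richness. No
lake-type × season interaction is built in, so the interaction test has a
true null in synthetic data.

Evidence artefacts are constructed to be recoverable by design: qualifying
hits (identity >= 90, cover 100) whose top-bitscore record carries the
planned host strings; species-resolvable hits (> 98%) or dataset-native
species assignments for literature-backed ASVs; abiotic / non-living /
symbiont records or sub-threshold hits for planned non-parasites. On
noise-free inputs classification recovers 100% of planned labels, which
the end-to-end tests assert at the >= 99% level.

What the generator does **not** emulate: sequencing error, chimeras, read
abundance structure, taxonomic mis-annotation in references, ambiguous or
multilingual host strings, and environmental covariates (temperature,
phosphorus). Passing tests therefore demonstrate correctness of the rules
and statistics, not robustness to noisy real-world metadata.

## Validation experiments and problem sizes

Two calibration experiments back the statistical claims, both run by the
test suite and `scripts/acceptance.R`:

* **Multiplier recovery** (`multiplier_recovery()`): studies injecting
  only the heated multiplier (planted indicators off, lake offsets off,
  measured on aphelids — the focal group without host coupling) are
  generated 100 times; the 95% Wald interval of the lake-type contrast
  covers log 2 in ~96–99% of fits, and with multiplier 1 the Type-III
  lake-type test rejects in ~4–5% of fits. Isolating the multiplier is the
  point of the experiment: planted indicators and between-lake
  heterogeneity are separate, deliberate effects that would otherwise
  confound the measured contrast.
* **Permutation type-I error**: 2000 null ASVs (iid presence, 0.3
  occupancy) over 70 samples with 999 permutations give a rejection rate
  of ~0.02–0.03 at the 0.05 level — conservative, as explained above.

Problem sizes throughout (455 ASVs, 70 samples, 999 permutations in tests,
100-replicate calibrations) were chosen as the smallest at which these
properties are statistically visible; the exported defaults
(`n_perm = 9999`) match survey practice.

## Known limitations

* The indicator statistic is a reconstruction; published results from
  other implementations may differ in tie handling and correction
  multiplicity.
* Overdispersion is not modelled (no negative binomial option); richness
  from occupancy-style data is if anything underdispersed, but real
  surveys may not be.
* The partial R-squared variant is the deviance ratio only.
* Literature and reference tables are inputs; the package neither queries
  databases nor scores the quality of literature evidence.
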