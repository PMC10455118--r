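---
title: "Methods: CAZyme repertoires, sugar-specific expression, and growth concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAZyme repertoires, sugar-specific expression, and growth concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazyspec)
```

## Scope and data model

`cazyspec` analyses fungal plant-biomass degradation from three kinds of
input, all plain TSV: gene-level CAZy family annotations (`species`,
`gene_id`, `family`), gene × sample FPKM matrices with sample metadata
(`sample_id`, `condition`, `replicate`), and ordinal growth profiles
(`species`, `carbon_source`, `score`). Read alignment, FPKM quantification
and library normalisation are upstream of the package; differential
expression testing is out of scope. The five stages are: a curated
family→substrate catalog; repertoire aggregation; expression processing; the
sugar-specificity classifier; and repertoire–growth concordance. A seeded
simulator generates all three input kinds with known ground truth.

## The packaged catalog

The catalog maps CAZy (sub-)families through enzyme-activity abbreviations
(EGL, CBH, BGL, XLN, ABF, MAN, PGA, AMY, …) to seven plant polysaccharides:
cellulose, xylan, xyloglucan, mannan, pectin, starch, inulin. It was
reconstructed from the comparative-genomics literature on six taxonomically
distant fungi (three Eurotiomycetes, one Sordariomycete, two Basidiomycetes);
each row carries a provenance note. Two conventions matter:

* **Subfamily resolution vs roll-up.** Entries are stored at the resolution
  the field reports them: GH5 appears only through its subfamilies GH5_4,
  GH5_5, GH5_22 (cellulose), GH5_7 (mannan) and GH5_16 (pectin), while GH11
  is a family-level entry. *Counting* distinct families per class rolls
  subfamilies up (GH5 counts once, giving 39 GH, 6 CE, 5 PL and 4 AA
  families), but *multifunctionality* — mapping to two or more substrates —
  is evaluated per stored key. This is deliberate: subfamilies exist
  precisely because they have narrower substrate specificity, so a family
  whose subfamilies each serve one polysaccharide (GH5, GH13, GH30, AA3) is
  not multifunctional in any biologically meaningful sense. Under this
  convention exactly ten keys are multifunctional: GH2, GH3, GH12, GH31,
  GH35, GH43, GH51, GH54, CE16 and FAE.
* **FAE as pseudo-family.** Feruloyl esterases are scattered across CAZy
  esterase families, so the field treats "FAE" as its own group. The catalog
  models it as a class of its own with no family number; it maps to xylan and
  pectin, whose arabinose-bearing side chains carry the ferulic-acid esters
  FAEs cleave.

Lookups are total: a subfamily query with no subfamily entry falls back to
the family-level entries and a family query aggregates its subfamilies, so
`substrates_of()` and `families_for_substrate()` are mutually inverse on the
packaged table. User catalogs in the same dialect replace the packaged one
everywhere.

## Repertoire aggregation

`count_families()` tallies genes per species and (sub-)family. Families
absent from the catalog (including the whole GT class) are kept in a separate
side table — the analysis restricts itself to biomass-degradation families,
but input genes are never silently dropped. `substrate_totals()` credits a
multifunctional family's genes once to *each* of its substrates rather than
splitting them fractionally; totals are therefore monotone in the annotation
set and additive over concatenated inputs, at the cost of substrate columns
not summing to the gene count. Ortholog group sets from two callers are
merged by transitive closure (union-find over co-grouping edges), which is
commutative, associative and idempotent; singletons stay singletons.

## Expression processing

Replicates are collapsed by the arithmetic mean on the FPKM scale before any
specificity computation. The mean (not the median) is the natural choice
because the specificity index is linear in the normalised expression values,
and with 2–3 replicates per condition the median is noisier. Genes whose
maximum FPKM over conditions is below 10 are removed; "below" is strict, so
a maximum of exactly 10 is retained. No log transform is applied anywhere in
the computation: the index operates on raw FPKM ratios and is invariant to
the overall scale of a gene's profile, so between-gene magnitude differences
never leak into it. Missing values are rejected at read time; upstream
quantification must emit complete matrices. Per-substrate expression
summaries (the numbers behind grouped boxplots) use type-7 quantiles and the
1.5 × IQR outlier rule, pooling each substrate's genes per condition;
distributions are computed on replicate means, the package's single
convention.

## The sugar specificity index

For mean expression $x_1, \dots, x_n$ over $n \ge 2$ sugar conditions,

$$\mathrm{SSI} = \frac{\sum_{i=1}^{n}(1 - \hat{x}_i)}{n - 1},
  \qquad \hat{x}_i = \frac{x_i}{\max_j x_j}.$$

Properties the tests enforce: $\mathrm{SSI} \in [0, 1]$; scale invariance;
0 iff the profile is uniform; 1 iff exactly one condition is non-zero;
monotone under concentration (lowering a non-maximal entry never lowers it);
and the planted-pattern closed form $\mathrm{SSI} = 1 - \lambda$ for a
profile with one peak and leakage $\lambda$ elsewhere — the lever the
simulator's recovery guarantees rest on. An all-zero profile has no defined
index: `ssi()` errors, while `classify_ssg()` records `NA` for such genes so
one record per input gene is always produced.

Classification uses a **strict** inequality at the SSI threshold (default
0.7) and an **inclusive** one at the FPKM threshold (default 10). The number
of conditions $n$ is taken from the data, never hard-coded to nine, since
real condition sets vary (one of the six study species has reduced
transcriptome coverage). The inducing sugar is the argmax condition; exact
ties are broken by the configured condition order and flagged explicitly —
with continuous FPKM data ties essentially only arise in degenerate or
constructed inputs, but the classifier must be deterministic on them. SSI is
computed per species on its own condition matrix; expression is never pooled
across species. Cross-tabulation of SSGs by substrate × inducing sugar again
counts multifunctional-family genes once per mapped substrate, and tallies
unannotated or off-catalog SSGs under `other`.

## Growth profiles and concordance

Growth is ordinal, 0–3, because plate assays report relative growth:
0 means growth indistinguishable from the no-carbon control, 3 means good
growth, and D-glucose serves as the internal reference (its row is required
for every species). Plate carbon sources map to catalog substrates through an
editable table (beechwood xylan→xylan; guar gum→mannan; apple and citrus
pectin→pectin; soluble starch and maltose→starch; inulin and sucrose→inulin;
cellulose and cellobiose→cellulose); when two sources map to one substrate
the better score is kept, reading the pair as two assays of the same
degradative capability. Concordance per species is the tie-adjusted
(midrank) Spearman correlation between per-substrate gene totals and growth
scores over the substrates present in both tables, computed only when at
least three substrates are shared — with fewer, a rank correlation over
ordinal scores is mostly noise, so the result is reported absent with a
reason instead. Discordance flags are quantile-based: a species is
`repertoire_low_growth_high` on a substrate when its total is at or below the
25% quantile of that substrate's totals across species yet growth is ≥ 2,
and `repertoire_high_growth_low` when the total is at or above the 75%
quantile yet growth is ≤ 1. The two directions are mutually exclusive per
(species, substrate) because the growth conditions are disjoint.

## The simulator and what it does (not) emulate

Each simulated gene draws an expression scale $e_g$ from a lognormal with
meanlog $\log 100$ and sdlog 1 — a typical spread for actively expressed
genes on the FPKM scale, spanning roughly 10–1000 for the central 95%. A
*specific* gene has pre-noise mean $e_g$ in one uniformly drawn inducing
condition and $\lambda e_g$ elsewhere (noiseless SSI exactly $1-\lambda$); a
*background* gene is uniform at $e_g$; a *silent* gene is uniform at a scale
drawn below the FPKM filter (uniform on 0.5–9.5 by default), exercising the
low-expression path. Non-silent scales are drawn from the lognormal truncated
below at the filter ceiling (inverse-CDF sampling; about 1% of mass), so the
three truth labels partition cleanly into detectable versus sub-threshold
genes and noiseless recovery of the planted structure is exact by
construction. Every sample value is multiplied by independent lognormal
noise (sdlog 0.2 by default), mimicking the multiplicative dispersion of
FPKM estimates. One seed drives all draws; sub-streams for expression and
annotations are derived deterministically from it.

Defaults — 1000 genes, the nine monosaccharides, 3 replicates, 10% specific,
10% silent, $\lambda = 0.1$, noise sdlog 0.2 — are the package's reference
operating point, at which the classifier's sensitivity and inducing-sugar
accuracy exceed 0.95 with FDR below 0.05.

What the simulator does *not* emulate, and hence what passing recovery tests
do not show about real data: count-level sampling noise (no negative-binomial
read model), correlated co-regulation of genes in one regulon, condition-
dependent library effects, partially specific genes induced by two or three
sugars, and annotation errors. Recovery on simulated data bounds what the
classifier can do when its model holds; it does not validate the biological
threshold choice of 0.7.

## Numerical choices and degenerate inputs

Quantiles are type 7 (R's default) throughout. The specificity threshold
comparison is exact floating-point `>`; profiles engineered to land exactly
on 0.7 are classified negative. Duplicate gene ids, negative FPKM, metadata
mismatches, growth scores outside 0–3 and a missing glucose reference all
fail fast with messages naming the offending record. The pipeline writes a
JSON manifest (package version, thresholds, input MD5s, per-stage gene
ledger) so any run is auditable; reruns on identical inputs are
byte-identical.

## Problem sizes

The test suite and the reproduction script run simulations of 200–1000 genes
with 9 conditions and 1–3 replicates, and property suites of $10^2$–$10^4$
random instances; these sizes give stable stochastic metrics (binomial
standard error on sensitivity at $n = 100$ planted genes is about 2 points)
while keeping a full run in minutes on one core.

## Known limitations

The packaged catalog is a reconstruction from published family enumerations,
not an export of any database; families a user's annotation pipeline reports
at different subfamily granularity than the catalog stores will be matched
via the roll-up fallback, which may differ from genome-portal conventions.
Growth scoring conventions beyond the 4-level scale (e.g. finer colony
measurements) must be discretised by the user. The concordance statistic is
descriptive; no significance test is attached because the per-species
substrate sample is tiny (≤ 7) and scores are ordinal.
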