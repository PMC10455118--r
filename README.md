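# cazyspec

Comparative analysis of fungal plant-biomass-degrading CAZymes
(carbohydrate-active enzymes): genomic repertoire comparison, sugar-specific
expression classification, and genotype–phenotype concordance.

## The problem

Fungi decompose plant polysaccharides — cellulose, xylan, xyloglucan, mannan,
pectin, starch and inulin — by secreting CAZymes drawn from dozens of GH, CE,
PL and AA families plus feruloyl esterases (FAE). Two questions recur in
comparative studies of such fungi:

1. **Degradative potential.** Which CAZy families, and how many genes per
   family, does each genome encode, and what does that imply per
   polysaccharide?
2. **Transcriptional commitment.** When a fungus is grown on the monomeric
   sugars released from those polymers (nine monosaccharides: D-glucose,
   D-fructose, D-galactose, D-mannose, L-rhamnose, D-xylose, L-arabinose,
   D-galacturonic acid, D-glucuronic acid), which CAZyme genes respond
   specifically to one sugar — and does the inducing sugar match the polymer
   the gene's family degrades?

`cazyspec` implements this analysis as a reusable pipeline for users with
gene-level CAZy annotations and FPKM expression matrices (quantification is
upstream), plus a synthetic-data generator so every stage is testable without
any downloads.

## The statistic at the core

For a gene with mean expression \(x_i\) (FPKM) in condition
\(i = 1, \dots, n\) (\(n \ge 2\)), the **sugar specificity index** is the
tau-type statistic

SSI = Σᵢ (1 − x̂ᵢ) / (n − 1),   x̂ᵢ = xᵢ / maxⱼ xⱼ

SSI ∈ [0, 1]: 0 for perfectly uniform expression, 1 for expression confined
to a single sugar, and exactly 1 − λ for a profile with one peak and uniform
leakage at fraction λ of the peak. A gene is called a **sugar-specific gene
(SSG)** when SSI > 0.7 and its maximum FPKM is at least 10 (genes whose
maximum is below 10 in every condition are treated as not expressed); its
**inducing sugar** is the condition of maximal expression.

Per-substrate gene totals are compared against ordinal growth scores
(0 = no growth … 3 = good, D-glucose as internal reference) by tie-adjusted
Spearman rank correlation, and (species, substrate) pairs where genomic
potential and observed growth point in opposite directions are flagged.

## Worked example

Simulate a transcriptome with planted sugar-specific genes, classify, and
check recovery:

```r
library(cazyspec)

cfg <- simulation_config(n_genes = 200, seed = 42)  # 9 sugars, 3 replicates
sim <- simulate_expression(cfg)
cm  <- collapse_replicates(sim$expression)          # replicate means
fit <- classify_ssg(cm)
fit
#> Sugar-specificity classification of 200 genes over 9 conditions
#>   SSI > 0.7 and max FPKM >= 10: 20 sugar-specific genes

summary(fit)
#> Genes: 200  SSGs: 20  below FPKM threshold: 17
#> SSI quartiles:
#>    0%   25%   50%   75%  100%
#> 0.075 0.140 0.175 0.225 0.922
#> SSGs per inducing sugar:
#>           D-glucose          D-fructose         D-galactose           D-mannose
#>                   2                   2                   1                   4
#>          L-rhamnose            D-xylose         L-arabinose D-galacturonic acid
#>                   3                   4                   2                   2
#>   D-glucuronic acid
#>                   0
```

The 200 simulated genes are 10% planted sugar-specific (leakage λ = 0.1, so
their noiseless SSI is 0.9), 10% silent (below the FPKM filter) and the rest
uniform background; under the default multiplicative noise (log-sd 0.2) the
classifier recovers the planted structure:

```r
str(recovery_metrics(fit, sim$truth))
#> List of 4
#>  $ sensitivity                : num 1
#>  $ specificity                : num 1
#>  $ false_discovery_rate       : num 0
#>  $ inducing_condition_accuracy: num 1
```

The packaged family→substrate catalog drives all repertoire aggregation:

```r
catalog <- load_catalog()
catalog
#> CAZy family-substrate catalog: 77 entries, 61 (sub-)families, 7 substrates
#>   entries per substrate: cellulose=13, xylan=16, xyloglucan=13, mannan=7,
#>   pectin=20, starch=7, inulin=1
multifunctional_families(catalog)
#>  [1] "GH2"  "GH3"  "GH12" "GH31" "GH35" "GH43" "GH51" "GH54" "CE16" "FAE"
```

`run_pipeline()` orchestrates the full analysis (repertoire counts, substrate
totals, expression summaries, SSG cross-tabulation, growth concordance) from
one YAML or list configuration and writes every stage's TSV plus a JSON run
manifest; `inst/scripts/cazyspec.R` wraps it for the shell.

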