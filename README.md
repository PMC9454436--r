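# comutscreen

Pan-cancer co-mutation screening for tumor registries built from
heterogeneous targeted sequencing panels.

Clinical sequencing consortia aggregate tens of thousands of tumor
samples, each profiled on one of many gene panels that cover different
gene subsets. That heterogeneity breaks naive co-mutation counting: a
pair of genes can only be assessed in samples whose panel covers both,
so every gene pair has its own denominator. comutscreen is for cancer
genomicists who want to ask, across such a registry: which gene pairs
are mutated together more (or less) often than chance within each
detailed cancer type, is the co-mutated genotype clinically more
aggressive, and what molecular or pharmacological vulnerabilities does
it carry in cell-line panels?

## The statistics at the core

For a gene pair and one detailed cancer type, restrict to the `N` cases
whose panel covers both genes and form the 2×2 table of alteration
status. Conditional on the margins `m1`, `m2` (cases altered in each
gene), the co-altered count is hypergeometric:

    X ~ Hypergeom(N, m1, m2)

- **concurrence** (enrichment): one-tailed Fisher p = P(X ≥ x)
- **mutual exclusivity** (depletion): p = P(X ≤ x)

Both directions are Benjamini–Hochberg adjusted over an explicit family
(by default, all cancer types within one pair and direction); adjusted
p < 0.05 is called significant. Pairs are ranked by the number of
cancer types with significant enrichment — co-mutation *diversity* —
then by total co-altered cases.

Around that core: alteration integration folds discrete copy-number
loss (value < 0) and gene fusions into mutation status, gated per gene
by Cancer Gene Census mutation types ("D" for deletion, "A" for
amplification) with per-gene overrides; clinical association tests the
co-altered oncogenotype against vital status and sample type per cancer
type with the same directional machinery; and cell-line screens fit,
per feature, `value ~ lineage + mutation status` by least squares and
FDR-adjust the mutation-term p-values within each data source. Seeded
simulators generate registry-style and cell-line data with known ground
truth (configurable marginal rates, injected pairwise odds ratios with
exactly preserved marginals, genotype-coupled clinical labels).

## Worked example

Simulate a small registry with an odds-ratio-12 RB1/TP53 co-mutation
injected into three of six cancer types, then screen all 435 pairs of
the 30-gene universe:

```r
library(comutscreen)
library(data.table)

sim <- simulate_registry(registry_sim_config(
  n_cancer_types = 6, cases_per_type = 250, baseline_rate = 0.2,
  enrichment = data.frame(gene1 = "RB1", gene2 = "TP53",
                          cancer_type = sprintf("cancer_type_%02d", 1:3),
                          or = 12),
  seed = 11))
scr <- run_screen(sim$registry, default_sim_genes())
scr$full_results[gene1 == "RB1" & gene2 == "TP53",
                 .(cancer_type, comutant, total, co.frac,
                   expected.co.frac, concurrent.padj)]
#>       cancer_type comutant total co.frac expected.co.frac concurrent.padj
#> 1: cancer_type_01       24   250   0.096         0.035328    2.332121e-08
#> 2: cancer_type_02       27   250   0.108         0.039856    1.987949e-09
#> 3: cancer_type_03       30   250   0.120         0.037600    2.861259e-13
#> 4: cancer_type_04       14   250   0.056         0.051408    5.294348e-01
#> 5: cancer_type_05        9   250   0.036         0.044928    8.500315e-01
#> 6: cancer_type_06       10   250   0.040         0.036800    5.294348e-01
```

The three injected strata show co-mutation fractions around 0.10–0.12
against an independence expectation near 0.04 and are flagged at
adjusted p ≪ 0.05; the three null strata sit at their expectation. The
injected pair tops the diversity ranking:

```r
head(diversity_ranking(scr), 2)[, .(rank, gene1, gene2,
                                    concurrent.padj.sig, total.comutant)]
#>    rank gene1  gene2 concurrent.padj.sig total.comutant
#> 1:    1   RB1   TP53                   3            114
#> 2:    2   MYC NOTCH1                   2             44
```

A command-line wrapper is installed at `exec/comut` inside the package
(`comut screen | pair | clinical | celldiff | simulate`), driven by a
YAML run config; every output TSV carries a header with the package
version, config hash and input checksums.

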