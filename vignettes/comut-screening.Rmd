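---
title: "Coverage-aware co-mutation screening: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-aware co-mutation screening: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comutscreen)
library(data.table)
```

comutscreen screens somatic co-mutation across tumor registries assembled
from heterogeneous targeted sequencing panels, of the kind aggregated by
multi-center clinical sequencing projects. This vignette is the package's
account of the statistical model, the tunable parameters, the simulators
used to validate it, and the design decisions taken where more than one
reasonable choice existed.

## The screening model

A *panel* is the set of genes a sequencing assay covers; a *case* is one
sequenced tumor sample carrying a detailed cancer-type label, a vital
status, a sample type and a panel assignment. Because panels differ, a
gene pair $(g_1, g_2)$ is only assessable in cases whose panel covers
*both* genes, so the denominator varies from pair to pair. All coverage
restriction goes through `cases_covering()`; nothing downstream ever sees
a case that could not have reported both genes.

Within one pair and one detailed cancer type, the covered cases form a
2×2 table: co-altered, $g_1$ only, $g_2$ only, neither. Conditional on
both margins, the co-altered count $X$ is hypergeometric,

$$X \sim \mathrm{Hypergeom}(N,\, m_1,\, m_2),$$

with $N$ covered cases and marginal altered counts $m_1, m_2$. The
concurrence p-value is the upper tail $P(X \ge x)$, the exclusivity
p-value the lower tail $P(X \le x)$ — the two one-tailed Fisher exact
tests on the same table. Both tails are reported from one screen; they
overlap in the observed point, so $p_{up} + p_{low} = 1 + P(X = x)$,
an identity the test suite checks exhaustively against a combinatorial
oracle on all tables with $N \le 12$.

**Degenerate strata.** When a margin is 0 or $N$ the table carries no
information about association; both p-values are set to 1 and the
stratum stays in the multiplicity family. This is conservative and makes
results independent of the order in which strata are enumerated.

**Multiplicity.** Benjamini–Hochberg step-up with an explicit family
size (`bh_adjust(p, family_size)`), so strata skipped for being below
`min_cases` are still counted — a skipped test behaves exactly like
p = 1 at the top of the ranking. Two family scopes are offered because
the published style of statement ("enriched in $k$ of $n$ cancer
types" for a named pair) reads naturally as a per-pair family:

* `per_pair` (default): adjust across cancer types within one pair and
  one direction;
* `global`: one family over the whole pair × cancer-type grid per
  direction, appropriate when the screen itself is the discovery unit.

Significance is fixed at adjusted p < 0.05; nominal-p flags are also
emitted (`*.pv.sig`) since both counts appear in the result tables.

**Ranking.** `diversity_ranking()` orders pairs by the number of
BH-significant concurrently-enriched cancer types, then total co-altered
cases, then lexicographically — a deterministic total order that puts
lineage-diverse co-mutations first rather than pairs dominated by one
common cancer type.

Key defaults: `alpha = 0.05`; `min_cases = 0` for the mutation-only
screen and 5 for the integrated pair analysis (strata smaller than five
cases cannot reach one-tailed significance anyway and only dilute the
family); gene selection threshold `min_panels = 50` panels, inclusive.

## Alteration integration

Beyond point mutations, a gene can be lost through copy-number deletion
or disrupted by fusion. `integrate_alterations()` folds three evidence
layers into one `altered` flag per (gene, sample):

* any recorded mutation row counts, regardless of variant class (an
  exclusion list is available but defaults to empty);
* a discrete copy-number value **< 0** counts as loss — both −1 and −2,
  a deliberate literal reading of "below zero" rather than
  deep-deletion-only;
* a value > 0 counts as amplification;
* fusion evidence is gene-symbol membership in the fusion table; no
  breakpoint logic.

Copy-number events are gated by a Cancer Gene Census-style annotation:
deletion only counts for genes whose mutation types include "D",
amplification "A". The gate has per-gene overrides because curation
lags biology — the canonical example is TP53, whose annotation omits
"D" although TP53 deletion is biologically a loss event; an override
row re-admits it. Genes missing from the annotation are blocked (and
logged once) rather than silently admitted.

A sample absent from the copy-number matrix contributes no copy-number
evidence but remains assessable on mutations — absence of profiling is
not evidence of wild-type status. The same convention applies to
fusion data, which many contributing centers do not submit.

## Clinical association

For a chosen pair, each covered case has one of four oncogenotypes:
co-altered, $g_1$-only, $g_2$-only, wild-type. `outcome_association()`
tests co-altered **vs. all others pooled** against a dichotomized
outcome (dead/alive, metastasis/primary) per cancer type, one direction
at a time, using the same hypergeometric tail machinery; BH families
span the cancer types within one outcome × one direction. Cases with
unknown outcome are excluded before the table is built; cancer types
left empty are skipped but counted in the family.

`oncogenotype_death_rates()` reports the raw death fraction per
genotype class with its denominator, since registries of this kind
record vital status but no follow-up time — rates, not survival curves,
are the honest summary, and no Cox or Kaplan–Meier machinery is
offered.

Cancer types are grouped into categories (small cell, neuroendocrine,
sarcoma, other) by case-insensitive substring rules on the type name,
editable in the run config; the names follow OncoTree-style vocabulary,
so substring matching is the right granularity and an ontology would be
false precision. Category-level comparisons of per-type co-mutation
fractions use the one-sided Mann–Whitney test: exact tail enumeration
when $m \cdot n \le 400$ with no ties, otherwise the normal
approximation with tie and continuity correction.

## Cell-line differential screens

Per feature (protein level, gene dependency, drug sensitivity),
`fit_feature_model()` fits ordinary least squares

$$y = \beta_0 + \sum_l \beta_l\,\mathbb{1}[\text{lineage} = l] +
  \beta_m\,\mathbb{1}[\text{mutant}] + \varepsilon,$$

and records the mutation-term estimate $\hat\beta_m$, its $t$ statistic
and two-sided p-value. Lineage enters as a fixed-effect covariate so
that mutation-associated differences are not confounded by lineage
composition. Missing values drop listwise per feature and lineage
dummies are rebuilt on the retained lines, since screening coverage is
feature-specific. With a single retained lineage the model reduces to
the pooled-variance two-sample $t$ test (checked in closed form).

Two comparisons are run — co-mutant vs. double wild-type and
TP53-only vs. double wild-type; RB1-only lines are excluded from both
because such lines are too rare for a powered comparison. Guard rails:
each group needs `min_per_group = 3` retained lines; a design where
lineage perfectly predicts mutation status is flagged `inestimable` and
excluded from the BH family; a zero-residual fit is flagged
`degenerate` (estimate reported, no test). BH runs within each data
source × comparison, never pooled across sources, because the sources
measure different quantities on different scales. Reporting tiers at
FDR < 10% and < 2% are configurable flags, not filters.

## The simulators and what they do (not) show

`simulate_registry()` draws a latent per-(gene, case) loss status and
emits observable evidence conditionally on it, only for genes on the
case's panel. Pair enrichment is injected by conditional tilting: the
second gene is drawn from $P(g_2 \mid g_1)$ chosen so the joint
probability solves the 2×2 odds-ratio equation with both marginals
preserved exactly — $O(n)$ generation with exact marginals, rather than
rejection sampling. Clinical couplings assign per-genotype death and
metastasis probabilities. Everything is bit-for-bit reproducible from
the mandatory seed.

The standard test fixture ("mini registry") is 20 cancer types × 400
cases, 30 genes, 5 heterogeneous panels, baseline mutation rate 0.3.
The rate is at the high end of what frequently mutated cancer genes
show; it is chosen so that per-stratum 2×2 tables are well populated
and the exact test's discreteness does not dominate the calibration
picture at this scale (at 400 cases and rate 0.3 the attained size of
the one-tailed test at 0.05 is ≈ 0.04). Test problem sizes — 8,700
null pair-strata for calibration, 100 strata of 200 cases at odds
ratio 8 for recovery, 50 replicates of 150-case cohorts for the
clinical coupling — are the package's validation scale, small enough
to run routinely while keeping Monte-Carlo error well inside the
asserted bands.

`simulate_cellline_panel()` builds feature = lineage baseline +
genotype effect + Gaussian noise. Lineage and genotype proportions are
realized as exact counts in randomized order: the composition of a
cell-line panel is a fixed property of the dataset being emulated, not
a sampling outcome, and leaving it multinomial would make power
statements depend on the luck of the class sizes.

What the generators deliberately do **not** model: mutational
signatures, subclonality, panel-specific variant-calling sensitivity,
physically linked genes (which inflate co-deletion counts in real
integrated screens), viral inactivation of pathways, or dose–response
preprocessing of drug screens. Passing tests therefore demonstrate
statistical correctness and calibration of the machinery under clean
conditions, not robustness to these real-data artifacts.

## Other design decisions

* The analysis unit is the sequenced case; patient-level deduplication
  (`dedupe_patients()`, first case per patient) exists but defaults
  off, matching registry practice of testing on samples.
* Gene symbols are upper-cased and compared exactly; alias resolution
  is out of scope.
* Vital-status and sample-type strings normalize through explicit
  lookup tables; unmapped strings become `unknown`, never guessed.
* The reader exposes the observed cancer-type label set as-is and
  leaves any subsetting to the caller, since label granularity differs
  between registry releases and analyses.
* Nominal-significance counts (`*.pv.sig`) count strata at p < 0.05
  before adjustment; adjusted counts (`*.padj.sig`) after. Both are
  emitted.
* Untested pairs (no co-covering panel) appear as explicit rows flagged
  `tested = FALSE` rather than vanishing, so result tables always
  enumerate the requested grid.
* Every output TSV starts with comment lines carrying the package
  version, an MD5 hash of the run configuration and checksums of the
  input files.

## Worked example

```{r example}
sim <- simulate_registry(registry_sim_config(
  n_cancer_types = 6, cases_per_type = 250, baseline_rate = 0.2,
  enrichment = data.frame(gene1 = "RB1", gene2 = "TP53",
                          cancer_type = sprintf("cancer_type_%02d", 1:3),
                          or = 12),
  seed = 11))
scr <- run_screen(sim$registry, default_sim_genes())
scr$full_results[gene1 == "RB1" & gene2 == "TP53",
                 .(cancer_type, comutant, g1_mutant, g2_mutant, total,
                   co.frac, expected.co.frac, concurrent.padj)]
head(diversity_ranking(scr), 3)
```

## Known limitations

Fisher's exact test is conservative in small strata, so significance
counts under-report weak enrichment in rare cancer types — the result
tables carry `avg.total` precisely so readers can weigh power. No
permutation- or network-based exclusivity model is provided; the lower
hypergeometric tail is the only exclusivity statistic. The linear model
treats lineage as a fixed effect and assumes homoscedastic Gaussian
noise per feature; heavy-tailed screen artifacts will inflate its error
rates. Identifier harmonization across cell-line and compound sources
is assumed done upstream.
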