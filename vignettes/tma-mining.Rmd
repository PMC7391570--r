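---
title: "Mining metagenomes for TMA-synthesis potential: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining metagenomes for TMA-synthesis potential: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmanet)
```

`tmanet` quantifies the trimethylamine (TMA) synthesis potential of a gut
microbiome cohort and contrasts it between two clinical groups (controls,
CTR, and atrial fibrillation, AF). This vignette explains the statistical
model behind each stage, the parameters that matter and the design choices
made where the procedure was genuinely open.

## From read counts to abundance

The input is a non-redundant gene catalog with mapped-read counts per gene
and sample. Two conventions govern the profiling stage:

* **Gene inclusion.** A gene is kept when it attracts at least
  `min_total_reads = 2` mapped reads *in total across samples*. A
  per-sample reading of the threshold would discard genes that are rare
  everywhere but real; the total-count reading is the laxer and, in our
  view, the intended one. The threshold is a parameter of
  `filter_genes()`.
* **Length normalization.** Abundance is `count / length_bp` — a pure
  ratio, not per-kilobase. Since every downstream statistic (odds ratio,
  rank tests, Spearman correlations) is invariant to a global rescaling,
  the 1000x factor of an RPK-style unit would cancel anyway.

Feature abundance (KEGG ortholog, module, enzyme family, genus) is the sum
of its member genes' abundances. A KO belonging to several modules
contributes to each of them. Relative abundance is computed **within each
feature universe separately** — each universe's sample column is rescaled
to sum to 1. The alternative (normalizing against the whole gene catalog)
would make the four universes' relative abundances non-comparable across
datasets with different annotation rates; per-universe closure matches how
per-figure feature families are usually presented.

## Annotation rules

KEGG assignment considers hits whose subject carries a KO label and whose
score exceeds 60 (strict), and takes the highest-scoring one. The tabular
`bitscore` column is treated as the score; raw HSP scores are not available
in `outfmt 6` output, so the bit score is the operational interpretation.
Enzyme-family assignment (CutC, CntA, GrdH, TorA) is best-hit under three
strict filters: e-value < 1e-5, identity > 50%, coverage > 50%. Coverage is
defined on the **query** (the catalog gene), `100 * alignment_length /
query_length`, because the filter is meant to guarantee that most of the
candidate gene aligns to the reference enzyme, not the reverse. Ties on bit
score are broken by smaller e-value, then lexicographically smallest
subject id, making assignment deterministic; a gene may hold both a KO and
an enzyme family, as the two searches are independent alignment passes.

## Taxonomic attribution

For each enzyme gene, the *valid matches* are the hits with e-value at most
10 times the top hit's e-value. A top e-value of exactly 0 is handled
exactly — `10 * 0 = 0`, so only other zero-e-value hits qualify; no epsilon
is injected. The gene is placed at the lowest common ancestor (LCA) of the
valid matches' taxa. Genes whose LCA lies above genus rank are reported but
excluded from genus-level abundance tables, mirroring MEGAN-style
summaries. No minimum number of valid matches is imposed: a single match
assigns, and `n_valid_matches` is reported so users can filter. No other
MEGAN parameters (min-support, min-score) are emulated — only the 10x rule
is part of the procedure.

## The odds-ratio statistic

For feature $k$ with abundance $A_{sk}$ in sample $s$,

$$\mathrm{OR}(k) = \frac{\sum_{s \in AF} A_{sk} \,/\, \sum_{s \in AF}\sum_{i \neq k} A_{si}}
                        {\sum_{s \in CTR} A_{sk} \,/\, \sum_{s \in CTR}\sum_{i \neq k} A_{si}},$$

the ratio of the feature's abundance odds (its mass against the rest of its
universe) between the groups. Classification is by the OR alone: strictly
above 2 is AF-enriched, strictly below 0.5 CTR-enriched, the boundary
values not significant.

Two points were genuinely open:

* **Orientation.** Written with the control group in the numerator, the
  formula's large values would flag *control* enrichment, contradicting the
  classification labels attached to it (OR > 2 = enriched in cases). The
  package puts the AF share in the numerator so that OR > 2 ⇔ AF-enriched —
  the classification semantics are the operative result — and offers
  `orientation = "ctr_numerator"` for the literal reading; the two are
  exact reciprocals.
* **Zero sums.** Any of the four sums can be zero (a feature absent from
  one group). The default pseudo-sum rule replaces a zero by half the
  smallest nonzero value of its kind (feature sums and complement sums
  pooled over both groups), keeping every OR finite and classifiable —
  analogous to a pseudo-count at half the detection limit.
  `zero_handling = "exact"` returns Inf / 0 / NaN instead; an infinite OR
  classifies as AF-enriched, NaN as not significant.

The complement $\sum_{i \neq k}$ is always computed within a single
universe at a time (KOs against KOs, modules against modules); mixing
universes would double-count genes that sit in both a KO and its modules.

## Hypothesis tests

Differential abundance per feature uses the two-sided Wilcoxon rank-sum
test: exact when both arms have at most 12 samples and the pooled data are
tie-free, the tie-corrected normal approximation otherwise; a feature
constant across all samples is defined to have p = 1. Benjamini–Hochberg
q-values are computed within each feature universe and contrast separately
— each universe is its own testing family. Three contrasts are built in:
CTR vs AF, paroxysmal vs persistent AF, and persistent AF split at 12
months; the odds ratio is attached only to the CTR-vs-AF contrast, where
its groups are defined. Z-score profiles standardize each feature row to
mean 0, sample standard deviation 1; zero-variance rows become zero rows.

## Correlation network

Spearman correlations (midrank ties; two-sided p from the t approximation
on $n-2$ degrees of freedom; constant vectors recorded as rho = 0, p = 1)
are computed between genus and enzyme-family abundances, and between enzyme
families and a functional universe (modules by default, KOs via
`function_universe = "ko"`). Correlations use relative abundances across
**all samples pooled**: the network describes cohort-wide co-occurrence
structure, and pooling doubles the sample size; within-group networks can
be built by subsetting the metadata. BH correction runs over all tested
pairs of a block; edges require q < 0.05 and |rho| > 0.4 (strict), with
|rho| > 0.6 flagged strong and a q < 0.01 / q < 0.05 tier column. The
tripartite network keeps genera and functions with at least one enzyme
edge, orders nodes by layer, descending degree, then id, and exports to a
node-link JSON (Sankey-ready) and a flat edge TSV.

Note that relative abundances are compositional: within small universes
(four enzyme families) closure alone induces negative correlations between
features, and a genus layer built from the same enzyme genes shares mass
with the enzyme layer by construction. Edges are co-occurrence statements,
not causal or even independent-measurement statements.

## The synthetic-study generator

`simulate_study()` emulates the full input bundle with known ground truth.
Defaults encode the study conditions the pipeline is meant for: 50 + 50
samples, the AF arm split 30/12/8 into PAF / Pers<12m / Pers>12m, and a
per-sample depth factor with log-sd 0.15 (a depth coefficient of variation
of about 16%, matching a cohort sequenced at ~6.1 ± 1.0 million reads per
sample). Counts are drawn as
$\mathrm{NB}(\mu = \lambda_g \cdot d_s \cdot f_{gs},\ \mathrm{size} = 1/0.2)$
with $\lambda_g$ log-normal(log 20, 1) and planted fold changes $f_{gs}$
applied in AF samples only. The catalog-scale parameters (2000 genes, 150
KOs, 25 modules, 30 genera by default) are desk-scale: large enough for
stable rank tests and BH families, small enough that the whole suite runs
in seconds.

Decoy alignment hits come in two flavors so each filter is exercised
independently: functional decoys fail exactly one annotation filter (score
≤ 60, unmapped subject, e-value ≥ 1e-5, identity ≤ 50, coverage ≤ 50), and
taxonomy decoys point to a wrong genus at 100–10000x the top e-value,
outside the 10x window. Every planted KO is guaranteed at least two member
genes (topped up from unannotated genes), since a plant with no members
would be vacuous. One genus per gene keeps ground truth well-defined;
taxonomic ambiguity enters only through decoys. A single integer seed
drives one generator stream in a fixed draw order, so a bundle is
byte-identical across runs.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: sequence content and read-level error,
alignment score distributions of real homology (scores are drawn, not
computed), horizontally transferred genes spanning genera, correlated
community structure beyond planted effects, and zero-inflation beyond what
the negative binomial produces. Recovery rates on synthetic plants are
sanity floors, not field performance estimates.

## Numerical conventions, at a glance

| Quantity | Convention |
|---|---|
| Gene filter | total reads ≥ 2, across samples |
| Annotation thresholds | strict inequalities (60; 1e-5, 50%, 50%) |
| Best-hit ties | bit score, then e-value, then subject id |
| Valid-match window | e ≤ 10 × top e; exact at e = 0 |
| OR zero sums | pseudo-sum: half smallest nonzero of its kind |
| OR boundaries | OR = 2 and OR = 0.5 are *not* significant |
| All-tied Wilcoxon | p = 1 |
| BH families | per universe × contrast; per correlation block |
| Network thresholds | q < 0.05 and \|rho\| > 0.4 strict; \|rho\| > 0.6 strong |
| Constant rows | Z scores 0; Spearman rho 0, p 1 |

## Test problem sizes

The test suite checks the odds ratio against a transliterated-formula
oracle on 1000 random matrices (up to 8 × 20), LCA against a
root-path-intersection oracle on 100 node sets over random 500-node trees,
and the annotation rules against brute-force filter-plus-argmax oracles on
randomized hit tables with forced boundary rows. Calibration uses 20 null
simulations of 200 features at 50 + 50 samples (AF-enriched calls with
q < 0.05 must stay ≤ 7%); power uses 12 features planted at fold 4 in a
2000-gene catalog (≥ 90% recovery required) with four planted
enzyme-carrying genera (≥ 95% of their genes recovered at genus rank); edge
recovery uses 20 fixtures with one noisy monotone genus–enzyme dependence
among otherwise independent features. These sizes keep the suite in the
tens of seconds on one CPU while leaving the statistical margins wide.

## Known limitations

* The pipeline consumes alignment *output*; it neither runs nor models the
  aligner, so its guarantees start at the hit tables.
* No covariate adjustment: enrichment is marginal, and confounders (age,
  diabetes, medication) must be handled upstream or by stratification.
* The OR has no attached standard error; significance comes from the
  Wilcoxon/BH track, and the OR thresholds are descriptive classification
  rules.
* Compositional closure affects both the OR (through the complement sums)
  and the correlation network; strong planted effects visibly shift other
  features' relative abundances. This is a property of relative data, not
  an artifact the package attempts to undo.
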