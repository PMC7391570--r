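# tmanet

Gut bacteria produce trimethylamine (TMA) from dietary choline, carnitine
and glycine betaine; the liver oxidizes it to TMAO, a metabolite linked to
cardiovascular disease. `tmanet` is an R package for asking, from shotgun
metagenomes of a case-control cohort (here: atrial fibrillation, AF, vs
controls, CTR), whether the microbiome's *TMA-synthesis potential* — its
KEGG orthologs and modules, the four TMA enzyme families (CutC, CntA, GrdH,
TorA), and the genera that harbor them — is enriched in cases.

The package implements the full mining pipeline downstream of read mapping:

1. **Abundance profiling** — keep genes with ≥ 2 mapped reads in total,
   divide counts by gene length (bp), sum gene abundances into feature
   abundances, and normalize per sample within each feature universe.
2. **Functional annotation** from BLAST/DIAMOND tabular hits — a gene gets
   the KO of its highest-scoring hit with score > 60; enzyme families are
   assigned best-hit with E-value < 1e-5, identity > 50% and query
   coverage > 50% (all strict).
3. **Taxonomic attribution** of enzyme genes — valid matches are hits with
   e-value ≤ 10 × the top hit's e-value; the gene is placed at the lowest
   common ancestor (LCA) of their taxa, and genus-level placements are
   aggregated into genus abundance.
4. **Differential enrichment** — for feature *k* with abundance
   *A(s,k)* in sample *s*,

   ```
   OR(k) = [ Σ_{s∈AF} A(s,k) / Σ_{s∈AF} Σ_{i≠k} A(s,i) ] /
           [ Σ_{s∈CTR} A(s,k) / Σ_{s∈CTR} Σ_{i≠k} A(s,i) ]
   ```

   with OR > 2 classified AF-enriched and OR < 0.5 CTR-enriched, alongside
   two-sided Wilcoxon rank-sum tests with Benjamini–Hochberg q-values and
   Z-score profiles.
5. **Correlation network** — Spearman correlations between genera, enzyme
   families and functional features, kept at FDR-corrected p < 0.05 and
   |r| > 0.4 (|r| > 0.6 flagged strong), assembled into a tripartite
   genera → enzymes → functions network with JSON/TSV export.

A synthetic-study generator (`simulate_study()`) produces a complete input
bundle — gene catalog, overdispersed counts, metadata, alignment hits with
filter-failing and taxonomy-conflicting decoys, taxonomy tree, feature
maps — with known planted effects, so every stage is testable end to end
without external data.

## Worked example

```r
library(tmanet)

sim <- simulate_study(simulation_config(
  seed = 7, n_genes = 800, n_kos = 80,
  planted_features = data.frame(feature_id = sprintf("K%05d", 1:5),
                                fold_change = 4),
  planted_taxa = data.frame(genus = c("Genus001", "Genus002"),
                            enzyme_family = c("CutC", "CntA"),
                            fold_change = 4)))
res <- run_pipeline(sim, pipeline_config())
et  <- res$enrichment[["ko.CTR_vs_AF"]]
head(et[order(et$q_value), c("feature_id", "or_value", "class", "q_value")], 5)
#>   feature_id or_value       class      q_value
#> 1     K00001 3.231669 AF_enriched 1.130572e-16
#> 2     K00002 3.076123 AF_enriched 1.130572e-16
#> 3     K00003 3.010333 AF_enriched 1.130572e-16
#> 4     K00004 3.408070 AF_enriched 1.130572e-16
#> 5     K00005 3.544184 AF_enriched 1.130572e-16
res$network
#> tripartite_network: genera=7, enzyme_genes=4, functions=14 | 44 edges
```

All five planted orthologs come out AF-enriched (OR > 2; compositional
closure pulls the OR below the planted fold of 4) at vanishing q-values,
and the genus–enzyme–module network recovers the planted CutC and CntA
carriers (e.g. the Genus001–CutC edge at rho = 0.82).

With `pipeline_config(output_dir = ...)` every stage writes a TSV stamped
with the parameters that produced it, plus a node-link `network.json` and a
run manifest with file checksums. A thin command-line wrapper lives at
`inst/scripts/tma-pipeline.R` (subcommands `simulate` and `run`).

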