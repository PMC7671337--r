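# genelossr

Detection and comparative analysis of gene losses in mammalian genomes.

Genes are sometimes inactivated and lost during evolution: premature stop
codons, frameshifting insertions and deletions, splice-site disruptions
(donor deviating from GT/GC, acceptor from AG), and deletions of exons or
whole genes accumulate until a lineage can no longer make the protein.
`genelossr` is for comparative genomicists who want to screen a reference
gene annotation against many query genomes and ask: which genes are lost,
in how many independent lineages, and what kinds of genes tolerate loss?

The package implements the full analysis as composable stages over
standard formats (BED12/GTF, FASTA, MAF, Newick, OBO, TSV):

1. **Mutation scanning** of pairwise coding-exon alignments for all five
   inactivating-mutation classes, with assembly gaps (N-runs) carefully
   separated from real deletions so that missing sequence is never
   counted as evidence.
2. **Loss classification**: per species, a gene is lost when less than
   60% of its reading frame remains intact — measured as the larger clean
   terminal segment `max((f−1)/L, (L−l)/L)` of the codon axis, where
   `f`/`l` are the first/last codon affected by a mutation — *and* at
   least 20% of its exons carry inactivating mutations (single-exon
   genes: at least two mutations). A gene with several principal isoforms
   is lost only if every isoform is lost.
3. **Dollo parsimony** on the species tree: an intact gene is never
   regained, so losses in sister species collapse to one ancestral event;
   the number of maximal all-lost subtrees is the gene's count of
   independent loss lineages.
4. **Pleiotropy**: knockout-phenotype annotations from single-gene
   knockouts are propagated up the phenotype ontology and counted per
   gene at ontology levels 2, 3 and 4; loss groups are compared with
   two-sided Wilcoxon rank-sum tests.
5. **Enrichment**: two-sided Fisher's exact tests for
   depletion/enrichment of disease, essential, lethal and dispensable
   gene classes among lost genes.
6. **Read validation**: a mutation is confirmed when at least five
   unassembled reads support it (within ±50 bp contexts) and none
   supports the ancestral allele.

A **synthetic-data generator** (`simulate_dataset()`) emits a complete,
seeded cohort — genome, gene models, alignments with injected mutations
and neutral noise, tree, ontology, annotations, class labels, read sets —
together with a truth ledger that pins down the expected output of every
stage, so the whole pipeline is testable end to end without downloads.

## Worked example

```r
library(genelossr)

cfg <- sim_config(seed = 1, n_genes = 200, n_species = 8)
simulate_dataset(cfg, "cohort/")
res <- run_pipeline("cohort/", "results/")

res$summary$pct_lost
#> [1] 22
res$summary$pct_multi_among_lost
#> [1] 40.9091
```

22% of the 200 genes are lost in at least one of the 8 species, and 41%
of those are lost in more than one independent lineage. The per-class
comparisons (pooled lost vs never-lost) recover the configured pattern —
lost genes depleted in disease/essential/lethal genes, enriched in
dispensable ones:

```r
res$enrichment[res$enrichment$group == "lost_any",
               c("class", "odds_ratio", "p_value", "direction")]
#>          class odds_ratio p_value direction
#>        DISEASE      0.438  0.1698  DEPLETED
#>      ESSENTIAL      0.430  0.6868  DEPLETED
#>         LETHAL      0.134  0.0321  DEPLETED
#>    DISPENSABLE      2.852  0.0119  ENRICHED
```

Multi-lineage-lost genes affect fewer distinct knockout phenotypes per
gene than never-lost genes at every ontology level (medians 3 vs 6 at
level 2; Wilcoxon p ≈ 0.001–0.004), and all emitted mutation loci are
confirmed by their read sets (10 supporting reads, 0 ancestral). The
scanner's per-exon mutation map is written as a TSV, e.g.:

```
gene_id species kind            exon_index codon_position
G0001   sp01    SPLICE_DONOR    0          143
G0001   sp01    PREMATURE_STOP  2          383
G0004   sp01    PREMATURE_STOP  2          165
G0004   sp01    EXON_DELETED    3          NA
```

A thin command-line wrapper ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/geneloss", package="genelossr"))')" \
  simulate --seed 1 --out cohort/
```

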