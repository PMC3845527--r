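# melopav

Gene presence/absence variation (PAV) calling from resequencing read depth,
with gene-family and tandem-cluster context and enrichment statistics.

## What it does and for whom

When several cultivars of a crop are resequenced against one reference
assembly, a gene deleted in a cultivar shows near-zero read depth at its
locus while the other cultivars cover it normally. `melopav` is for
population/comparative genomicists who have per-gene read counts (from
coordinate-sorted indexed BAMs, or precomputed tables) for a cohort of
genotypes and want:

1. **PAV calls** per gene and cultivar (`present` / `partial` / `absent`),
2. **gene families** from filtered pairwise BLASTN hits and **tandem
   clusters** on the annotation backbone, and
3. **enrichment tests** asking whether PAV concentrates in multi-copy or
   clustered genes.

The motivating cohort is five melon cultivars (the DHL92 reference line,
its parents T111 and PI 161375, and two unrelated accessions) at 13–16×
depth over 27,427 annotated genes. A synthetic-cohort generator reproduces
that structure — family-size spectrum, tandem arrays, planted full/partial
deletions enriched in multi-copy genes — so the entire pipeline is testable
without the original sequencing data.

## The method in brief

Counts follow the region-query convention `samtools view -c -F 4 -q 1`
(any ≥1 bp overlap; unmapped and MAPQ<1 excluded; nothing else filtered)
and are normalized as `norm(g,c) = count(g,c) · 10⁷ / N_c` with `N_c` the
cultivar's total mapped reads. Candidates satisfy either screen (strict
inequalities throughout):

* **ratio**: some ordered cultivar pair with `norm_a / norm_b < 0.5` or
  `> 2` (zero cells require ≥10 raw reads in some cultivar instead of a
  division);
* **absolute**: raw count `< 6` in one cultivar and `> 29` in another;

minus candidates with `< 10` reads in *every* cultivar. A deterministic
reviewer replaces manual browser inspection: absent when
`norm ≤ 0.05 · max_c norm` and breadth of coverage ≤ 0.10; partial when
breadth lies in (0.10, 0.80). Families are single-linkage components of
hits with e-value ≤ 1e-20 and mutual coverage > 40%; tandem clusters chain
same-family genes with ≤ 8 annotated genes between consecutive members.
Enrichment is the df = 1 chi-square

χ² = N(|ad − bc| − N/2)² / [(a+b)(c+d)(a+c)(b+d)]

with Yates continuity correction (the published multi-copy table
[739, 476; 6026, 20186] gives 892).

## Worked example

```r
library(melopav)

p   <- sim_params(n_genes = 3000, n_scaffolds = 10, seed = 1)
sim <- simulate_cohort(p, "cohort_dir")
pav <- call_pav(sim$counts, sim$breadth, reference = "DHL92",
                parents = c("T111", "PI161375"))
pav$accounting
#>          ratio_screen       absolute_screen                merged
#>                   181                   139                   181
#> low_support_discarded   reviewed_candidates             pav_genes
#>                     0                   181                   179
summarize_pav(pav$calls, nrow(sim$genes))
#> PAV genes: 179 (6.0% of complement), events: 188
#> genes by number of affected cultivars:
#>   1   2
#> 170   9
#> events per cultivar:
#>   C-1012    C-836 PI161375     T111
#>       30       52       55       51
```

181 genes trip the ratio screen (the absolute screen adds none here), 179
survive review with at least one affected cultivar, and most PAV genes are
absent from a single cultivar — the cohort-shape the generator plants.
Family context and enrichment:

```r
fams <- build_families(filter_hits(sim$hits, sim$genes), sim$genes)
pav_genes <- unique(pav$calls$gene_id[pav$calls$status != "present" &
                                        !pav$calls$artifact_flag])
crosstab(pav_genes, fams$families$gene_id, sim$genes$gene_id)
#>          pav
#> attribute yes   no
#>       yes  88  648
#>       no   91 2173
#> chi2 = 61.0 (df = 1), p < 1e-04
#> attribute share: 49.2% of PAV vs 23.0% of non-PAV genes
#> PAV rate: 12.0% in attribute+ vs 4.0% in attribute- (ratio 3.0)
```

Multi-copy genes are ~3× more likely to be PAV in this small cohort; the
planted enrichment (5× for multi-copy, ×2 more for tandem genes) is
recovered in full at the default 10,000-gene test scale. `run_pipeline()`
ties the stages together from a YAML or list configuration and writes
calls, BED regions, family/cluster tables, a summary JSON and a markdown
report; `count_matrix_from_bam()` produces the count/breadth tables
directly from indexed BAMs.

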