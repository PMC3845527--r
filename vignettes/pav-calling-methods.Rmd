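---
title: "Calling gene presence/absence variation from read depth: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling gene presence/absence variation from read depth: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melopav)
```

## The problem

When several cultivars of a crop are resequenced and their reads are mapped
back to a single reference assembly, a gene that is deleted in one cultivar
leaves a footprint: its locus collects almost no reads from that cultivar
while collecting normal coverage from the others.  `melopav` turns that
footprint into presence/absence-variation (PAV) calls over an annotated gene
complement — in the melon cohort that motivates the package, ~27,000 genes
across five cultivars (the DHL92 reference line, its two parents T111 and
PI 161375, and two unrelated accessions) at roughly 13–16× depth — and then
asks the downstream question: are multi-copy and tandem-arrayed genes more
likely to be dispensable than singletons?

## The calling procedure

Per-gene evidence is the number of alignment records overlapping the gene
span, with unmapped records and records below MAPQ 1 excluded and nothing
else filtered (the region-query convention; duplicates and secondary records
count).  Counts are made comparable across cultivars by library-size
scaling, `norm(g,c) = count(g,c) * 1e7 / library_size(c)`; the scale
constant is arbitrary and cancels from every ratio the screens use.

Candidates come from two screens, whose inequalities are all strict:

* **ratio screen** — some ordered cultivar pair has a normalized ratio below
  0.5 or above 2.  Zero cells are handled by a support rule rather than a
  division: a gene with a zero is a candidate only if some cultivar carries
  at least `min_support` (10) raw reads, which keeps "0 against 3 reads"
  genes out.  Ratios among the positive cells are screened regardless.
* **absolute screen** — fewer than 6 raw reads in some cultivar and more
  than 29 in another.  This operates on raw counts deliberately; it
  rescues low-coverage genes whose ratios are too noisy.

Candidates with fewer than 10 reads in *every* cultivar are discarded: at
that support, absence cannot be distinguished from an unmappable locus.

The historical step of eyeballing each candidate in a genome browser is
replaced by a deterministic reviewer with two exposed thresholds: a cultivar
is called **absent** when its normalized count is at most `absence_rel`
(default 0.05) of the gene's maximum across cultivars and its breadth of
coverage is at most `breadth_absent` (0.10); it is called **partial** when
breadth falls strictly between `breadth_absent` and `breadth_partial`
(0.80).  Breadth — the fraction of gene bases touched by at least one
qualifying read — is the package's proxy for what a person sees in a
browser: a partially deleted gene keeps a block of covered sequence.  These
two defaults are artifact parameters, not published constants; the original
inspection step is not reproducible, so they are surfaced in the
configuration rather than hidden.

The partial rule is breadth-only by design.  A consequence worth knowing:
a deletion that retains half or more of a gene's copy number rarely trips
either screen (its ratio sits above 0.5), so shallow partial deletions are
below the method's detection floor.  That is a property of the screens, not
of the reviewer.

Absences called in the reference cultivar itself cannot be real — the
reference's own reads are being mapped to its own assembly — and are flagged
as mapping artifacts; when the reference's parents are known, a reference
absence with both parents present is additionally tagged as
parent-inconsistent.  Flagged events stay in the event total (they are
reported that way) but are excluded from the per-cultivar average.

## Families and tandem clusters

Multi-copy families are connected components of a filtered pairwise-homology
graph built from 12-column tabular BLASTN hits: a hit survives when its
e-value is ≤ 1e-20 and both query and subject coverage exceed 40% (strictly),
coverage being the best-bitscore HSP's span over the gene length (a summed
non-overlapping-HSP mode and a reciprocal-edge requirement exist as toggles;
both default off, matching the looser reading of the original grouping).
Single-linkage components are the only clustering consistent with "grouped
by their hits" when no algorithm is named; an optional identity floor exists
but defaults off, since the observed ≥69% identity of surviving hits is an
outcome of the filters, not an input.

A tandem cluster is a within-family chain on the annotation backbone: family
members on one scaffold, sorted by positional rank, are chained while at
most `max_intervening` annotated genes (of any family) separate consecutive
members.  "Fewer than nine genes between homologs" is read strictly as
`max_intervening = 8`; the phrasing admits 9, so the bound is a parameter.
Chaining is transitive, interleaved families stay separate, and the rare
curated exception is an explicit overrides table (add a same-family gene,
merge two same-family clusters) that is logged, never silent.

Enrichment of PAV status in an attribute (multi-copy, clustered, or any
curated list) is a 2×2 contingency test.  The df = 1 statistic is computed
from the closed form `N(|ad−bc|−N/2)²/((a+b)(c+d)(a+c)(b+d))` with Yates
continuity correction on by default: the published multi-copy table
[739, 476; 6026, 20186] yields 892 corrected and ≈894 uncorrected, so the
corrected form is what the reported value used.  Reported percentages are
rounded half-up to one decimal.  The analogous clustered-gene statistic
printed as 92 does not reproduce from its own printed table (≈90 by either
form); the package treats the proportions (16.5% vs 8.5%) as the reliable
quantities there.

One bookkeeping subtlety: the cohort's PAV list is reported as 1,215 genes
in one place and 1,214 in another, and the printed histogram percentages
(70.3% one-cultivar, 21.7% two-cultivar) reproduce exactly only on the
1,214 denominator.  The package reports counts as given and computes those
two shares on the 1,214 basis.

## The synthetic cohort

No generative model was published, so the simulator is calibrated to the
cohort's summary structure and is explicit about being an artifact:

* **architecture** — 27,427 genes on 20 scaffolds; a binomial draw with
  singleton fraction 0.753 fixes the multi-copy gene count; family sizes
  follow weights with 64% two-member and 16% three-member families and a
  geometric tail to twenty; a family is laid down as a tandem run with
  probability 0.36 (the clustered share of multi-copy genes), otherwise its
  members scatter over distinct scaffolds where the scaffold count allows,
  so planted tandem runs are the only within-family positional clusters.
  Family members get near-equal lengths (±5% of a family base length drawn
  from a Gamma with mean 1,500 bp) — an idealization of real homolog
  families that guarantees emitted hits pass the mutual-coverage filter.
* **deletions** — per gene and non-reference cultivar, a deletion seeds with
  probability 0.004, times 5 for multi-copy genes and a further 2 for
  tandem-placed ones (the observed enrichment structure); with probability
  0.3 it extends downstream over a geometric run of mean 3 genes; 35% of
  events are partial, retaining Uniform(0.2, 0.8) of the span.  The
  reference cultivar never carries deletions, mirroring a reference line
  mapped to its own assembly; reference artifacts are injected in tests,
  not baked in.
* **counts** — gene g in cultivar c expects
  `depth(c) × (len(g)+read_len)/read_len × retained(g,c)` reads (read
  starts whose alignment touches the span), Poisson by default, negative
  binomial with `size = 1/overdispersion` when overdispersion is positive;
  an optional background mis-mapping rate adds reads per kb of deleted
  sequence.  At 15× and 150 bp reads a present 1,500 bp gene expects 165
  reads.  Breadth equals the retained fraction under tight Beta noise
  (concentration 200 by default; 0 disables it).  Library sizes are the
  genic column sums plus a Poisson draw for the simulated intergenic space.
* **homology hits** — every intra-family ordered pair emits a tabular hit
  with identity ~ Uniform(69, 100), aligned fraction ~ Uniform(0.5, 1) of
  the shorter gene and e-value ≤ 1e-20; decoy hits between unrelated genes
  are constructed to fail the filters on e-value or coverage.

Each sub-generator draws from its own stream derived from the master seed,
so enabling decoys never perturbs the counts, and a fixed seed makes every
output file byte-identical across runs.

What passing recovery tests show — and what they do not: on these cohorts
full deletions are recovered perfectly and the false-positive rate is
essentially zero, because the simulator has no mappability structure, no
repeat-induced coverage dips, no GC bias and no shared-paralog read
stealing.  Real data contain all four; the recovery numbers bound the
method's statistical behaviour, not its behaviour on a real genome.

## Numerical and engineering choices

Coordinates are 1-based inclusive throughout the package, the GFF3/GRanges
convention native to R's genomics stack; only BED export converts to
0-based half-open.  Count/breadth tables are TSV with a `__library_size__`
footer row and full-precision numbers, so write/read round-trips are exact
and columns are matched by cultivar name, not position.  BAM counting
delegates to `Rsamtools::countBam` with the flag/MAPQ filters above;
degenerate inputs (zero library sizes, zero table margins, unknown genes or
scaffolds, cross-family overrides) are errors that name the offending item,
while a missing breadth table merely disables partial calling with a
warning.  Problem sizes in the test suite are chosen so the whole suite
runs in about a minute: oracle equivalences use 200×5 matrices, ≤50-node
graphs and ≤100-gene scaffolds; recovery runs use 10,000-gene cohorts, the
size at which the planted architecture is comfortably represented.

## Worked example

```{r example}
p <- sim_params(n_genes = 3000, n_scaffolds = 10, seed = 1)
sim <- simulate_cohort(p, file.path(tempdir(), "cohort"))
pav <- call_pav(sim$counts, sim$breadth, reference = "DHL92",
                parents = c("T111", "PI161375"))
pav$accounting
summarize_pav(pav$calls, nrow(sim$genes))

edges <- filter_hits(sim$hits, sim$genes)
fams <- build_families(edges, sim$genes)
clusters <- detect_clusters(fams$families, sim$genes)
pav_genes <- unique(pav$calls$gene_id[pav$calls$status != "present" &
                                        !pav$calls$artifact_flag])
crosstab(pav_genes, fams$families$gene_id, sim$genes$gene_id)
```

## Known limitations

Breakpoint-resolution calling, split-read or discordant-pair evidence, and
detection of sequence *insertions* relative to the reference are out of
scope; so are alignment, read QC and functional annotation.  The reviewer
thresholds (`absence_rel`, the breadth windows) stand in for a manual step
that cannot be reproduced, so cohort-scale discovery counts from the
original data are not recoverable — the package instead guarantees the
screens' arithmetic, the graph and chaining semantics, the published
summary statistics, and full recovery of planted truth under its own
generative model.
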