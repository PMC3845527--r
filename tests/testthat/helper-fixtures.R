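# Shared fixtures: a small cohort parameter set and a hand-built SAM/BAM.

small_params <- function(n_genes = 1500, seed = 42, ...) {
  sim_params(n_genes = n_genes, n_scaffolds = 6, seed = seed, ...)
}

# SAM fixture with exactly known content, converted to an indexed BAM.
#
# Scaffolds: s1 (1000 bp), s2 (500 bp).  All aligned reads are 20M.
# On s1:
#   r1-r3  pos 110/130/150 mapq 30   fully inside 101-200
#   r4     pos 200         mapq 30   overlaps 101-200 by exactly 1 bp
#   r5     pos 140         mapq 0    inside but filtered at -q 1
#   r6-r8  pos 300/400/500 mapq 30   outside 101-200
#   u1     unmapped
# On s2 (breadth fixture over 1-100; covered: 1-50 and 91-100 = 60 bp):
#   b1 pos 1  len 30, b2 pos 21 len 30, b3 pos 91 len 20, all mapq 30
#   u2 unmapped
# Totals with -F 4 -q 1: s1 -> 7, s2 -> 3, file -> 10.
make_test_bam <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "fixture.sam")
  aligned <- function(name, rname, pos, mapq, len = 20)
    sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
            name, rname, pos, mapq, len,
            paste(rep("A", len), collapse = ""))
  unmapped <- function(name)
    sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\tAAAA\t*", name)
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:s1\tLN:1000",
    "@SQ\tSN:s2\tLN:500",
    aligned("r1", "s1", 110, 30),
    aligned("r2", "s1", 130, 30),
    aligned("r5", "s1", 140, 0),
    aligned("r3", "s1", 150, 30),
    aligned("r4", "s1", 200, 30),
    aligned("r6", "s1", 300, 30),
    aligned("r7", "s1", 400, 30),
    aligned("r8", "s1", 500, 30),
    aligned("b1", "s2", 1, 30, 30),
    aligned("b2", "s2", 21, 30, 30),
    aligned("b3", "s2", 91, 30, 20),
    unmapped("u1"),
    unmapped("u2")
  ), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "fixture"),
                          overwrite = TRUE, indexDestination = TRUE)
  bam
}

make_empty_bam <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "empty.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:s1\tLN:1000"), sam)
  Rsamtools::asBam(sam, file.path(dir, "empty"),
                   overwrite = TRUE, indexDestination = TRUE)
}

# Minimal union-find, the independent oracle for graph components.
uf_components <- function(edges, nodes) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (nrow(edges)) for (i in seq_len(nrow(edges)))
    parent[[find(edges$gene1[i])]] <- find(edges$gene2[i])
  comps <- split(nodes, vapply(nodes, find, character(1)))
  unname(lapply(comps, sort))
}

# Canonical form of a family partition for set equality.
partition_of <- function(families) {
  sets <- lapply(split(families$gene_id, families$family_id), sort)
  unname(sets[order(vapply(sets, `[`, character(1), 1))])
}
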