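#' Count qualifying reads overlapping a region
#'
#' Reproduces the semantics of `samtools view -c -F 4 -q 1 file.bam
#' scaffold:start-end`: every alignment record overlapping the region by at
#' least one base is counted, unmapped records are excluded, records with
#' MAPQ below `min_mapq` are excluded, and nothing else is filtered —
#' secondary/supplementary records and duplicates count.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param scaffold reference sequence name.
#' @param start,end 1-based inclusive interval.
#' @param min_mapq minimum mapping quality retained (default 1).
#' @return integer record count.
#' @export
count_reads_in_interval <- function(bam, scaffold, start, end, min_mapq = 1L) {
  check_bam_region(bam, scaffold)
  which <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(start, end))
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    mapqFilter = as.integer(min_mapq),
    which = which)
  as.integer(Rsamtools::countBam(bam, param = param)$records)
}

#' Total qualifying mapped reads in a BAM file
#'
#' Same filters as [count_reads_in_interval()] applied to the whole file —
#' the `samtools view -c -F 4 -q 1 file.bam` total used as the library size
#' for cross-cultivar normalization.
#'
#' @inheritParams count_reads_in_interval
#' @return integer record count.
#' @export
total_mapped_reads <- function(bam, min_mapq = 1L) {
  check_bam_index(bam)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    mapqFilter = as.integer(min_mapq))
  as.integer(Rsamtools::countBam(bam, param = param)$records)
}

#' Breadth of coverage of a region
#'
#' Fraction of interval positions covered by at least one qualifying read
#' (same filters as [count_reads_in_interval()]), computed from the aligned
#' blocks of overlapping records.  Used to separate partial from full gene
#' absence.
#'
#' @inheritParams count_reads_in_interval
#' @return fraction in \[0, 1\].
#' @export
breadth_in_interval <- function(bam, scaffold, start, end, min_mapq = 1L) {
  check_bam_region(bam, scaffold)
  which <- GenomicRanges::GRanges(scaffold, IRanges::IRanges(start, end))
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    mapqFilter = as.integer(min_mapq),
    which = which)
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  if (!length(aln)) return(0)
  cov <- GenomicRanges::coverage(aln)[[scaffold]]
  upto <- min(end, length(cov))
  if (upto < start) return(0)
  covered <- sum(as.integer(cov[start:upto]) > 0L)
  covered / (end - start + 1)
}

#' Build a count (and breadth) matrix from BAM files
#'
#' Applies [count_reads_in_interval()] to every gene of the annotation, for
#' one BAM per cultivar, and records each file's [total_mapped_reads()] as
#' the library size.
#'
#' @param bams named character vector of BAM paths, one per cultivar.
#' @param genes a [gene_table()].
#' @param min_mapq minimum mapping quality retained.
#' @param breadth if `TRUE`, also compute a [breadth_matrix()].
#' @return a [count_matrix()], or a list with `counts` and `breadth` when
#'   `breadth = TRUE`.
#' @export
count_matrix_from_bam <- function(bams, genes, min_mapq = 1L, breadth = FALSE) {
  if (is.null(names(bams)) || any(names(bams) == ""))
    stop("bams must be named by cultivar")
  which <- as_granges(genes)
  counts <- sapply(bams, function(b) {
    check_bam_index(b)
    param <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
      mapqFilter = as.integer(min_mapq), which = which)
    Rsamtools::countBam(b, param = param)$records
  })
  counts <- matrix(as.integer(counts), nrow = nrow(genes),
                   dimnames = list(genes$gene_id, names(bams)))
  lib <- vapply(bams, total_mapped_reads, integer(1), min_mapq = min_mapq)
  cm <- count_matrix(counts, lib)
  if (!breadth) return(cm)
  bm <- sapply(names(bams), function(cv) {
    vapply(seq_len(nrow(genes)), function(i)
      breadth_in_interval(bams[[cv]], genes$scaffold[i],
                          genes$start[i], genes$end[i], min_mapq),
      numeric(1))
  })
  bm <- matrix(bm, nrow = nrow(genes),
               dimnames = list(genes$gene_id, names(bams)))
  list(counts = cm, breadth = breadth_matrix(bm))
}

check_bam_index <- function(bam) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  idx <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
  if (!any(file.exists(idx)))
    stop("BAM index (.bai) missing for: ", bam)
  invisible(bam)
}

check_bam_region <- function(bam, scaffold) {
  check_bam_index(bam)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!scaffold %in% names(hdr))
    stop("scaffold not present in BAM header: ", scaffold)
  invisible(bam)
}
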