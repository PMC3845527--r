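#' Construct a gene table
#'
#' The gene table is the positional backbone of the analysis: one row per
#' annotated gene, ordered within each scaffold by start coordinate, with an
#' integer positional rank.  Ranks (0-based, contiguous per scaffold) are what
#' tandem-cluster detection chains over.  Coordinates are 1-based inclusive,
#' the GFF3/GRanges convention, and are used as-is internally.
#'
#' @param gene_id character, unique genome-wide.
#' @param scaffold character scaffold/contig name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return A `data.frame` of class `gene_table` with columns `gene_id`,
#'   `scaffold`, `start`, `end`, `strand`, `length`, `rank`, sorted by
#'   scaffold then start.
#' @export
gene_table <- function(gene_id, scaffold, start, end, strand = "+") {
  stopifnot(length(start) == length(end),
            length(gene_id) == length(start))
  scaffold <- rep_len(as.character(scaffold), length(gene_id))
  if (anyDuplicated(gene_id))
    stop("gene_ids must be unique genome-wide; duplicated: ",
         paste(unique(gene_id[duplicated(gene_id)])[1:3], collapse = ", "))
  if (any(start > end))
    stop("start > end for gene(s): ",
         paste(gene_id[start > end][1:3], collapse = ", "))
  gt <- data.frame(
    gene_id  = as.character(gene_id),
    scaffold = as.character(scaffold),
    start    = as.integer(start),
    end      = as.integer(end),
    strand   = rep_len(as.character(strand), length(gene_id)),
    stringsAsFactors = FALSE
  )
  gt <- gt[order(gt$scaffold, gt$start, gt$end, gt$gene_id), , drop = FALSE]
  gt$length <- gt$end - gt$start + 1L
  gt$rank <- stats::ave(seq_len(nrow(gt)), gt$scaffold,
                        FUN = function(i) seq_along(i) - 1L)
  gt$rank <- as.integer(gt$rank)
  rownames(gt) <- NULL
  class(gt) <- c("gene_table", "data.frame")
  gt
}

#' Read a gene annotation from GFF3
#'
#' Imports gene features (`type == "gene"`, or all features if none are typed
#' `gene`) and builds the ranked [gene_table()].  The `ID` attribute becomes
#' the gene id.
#'
#' @param path GFF3 file.
#' @return A `gene_table`.
#' @export
read_gene_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) stop("GFF3 gene features must carry an ID attribute: ", path)
  gene_table(
    gene_id  = ids,
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start    = GenomicRanges::start(gr),
    end      = GenomicRanges::end(gr),
    strand   = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+")
  )
}

#' Write a gene table as GFF3
#'
#' Emits one `gene` feature per row with an `ID` attribute; output is
#' deterministic for a given table (fixed column order and formatting), so
#' fixed-seed simulations round-trip byte-identically.
#'
#' @param genes a `gene_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tmelopav\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$scaffold, genes$start, genes$end, genes$strand,
                     genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' @keywords internal
as_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$scaffold,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
}

#' Look up gene lengths by id
#' @keywords internal
gene_lengths <- function(genes) {
  stats::setNames(genes$length, genes$gene_id)
}
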