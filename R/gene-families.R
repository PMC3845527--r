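#' Filter pairwise homology hits into family edges
#'
#' Keeps a hit when its e-value is at most `e_max` (1e-20) and both the query
#' and the subject coverage — aligned length over gene length — are strictly
#' greater than `cov_min` (40%).  Self-hits are dropped.  Surviving hits
#' become undirected edges; by default an edge exists when either direction
#' of a pair passes (`reciprocal = FALSE`).  Coverage is computed from the
#' single best HSP per directed pair (highest bitscore); set
#' `sum_hsp = TRUE` to instead sum non-overlapping HSP spans per pair.
#'
#' @param hits data.frame in BLAST tabular column order
#'   (see [read_hits_table()]).
#' @param genes a [gene_table()] supplying gene lengths.
#' @param e_max e-value ceiling (default 1e-20).
#' @param cov_min mutual-coverage floor, strict (default 0.40).
#' @param min_identity optional percent-identity floor (default `NULL`, off);
#'   surviving hits in practice all exceed ~69% identity anyway.
#' @param reciprocal require both directions of a pair to pass.
#' @param sum_hsp sum non-overlapping HSP coverage instead of best-HSP.
#' @return data.frame of undirected edges: `gene1`, `gene2`
#'   (lexicographically ordered, unique rows).
#' @export
filter_hits <- function(hits, genes, e_max = 1e-20, cov_min = 0.40,
                        min_identity = NULL, reciprocal = FALSE,
                        sum_hsp = FALSE) {
  len <- gene_lengths(genes)
  unknown <- setdiff(c(hits$qseqid, hits$sseqid), names(len))
  if (length(unknown))
    stop("hit references unknown gene: ", unknown[1])
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      stringsAsFactors = FALSE))
  key <- paste(hits$qseqid, hits$sseqid)
  if (sum_hsp) {
    qcov <- vapply(split(seq_len(nrow(hits)), key), function(i) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(hits$qstart[i], hits$qend[i]))))
    }, numeric(1))[key] / len[hits$qseqid]
    scov <- vapply(split(seq_len(nrow(hits)), key), function(i) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(pmin(hits$sstart[i], hits$send[i]),
                         pmax(hits$sstart[i], hits$send[i])))))
    }, numeric(1))[key] / len[hits$sseqid]
  } else {
    # keep only the best-bitscore HSP per directed pair
    ord <- order(key, -hits$bitscore)
    hits <- hits[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
    qcov <- (hits$qend - hits$qstart + 1) / len[hits$qseqid]
    scov <- (abs(hits$send - hits$sstart) + 1) / len[hits$sseqid]
  }
  if (any(qcov > 1.5 | scov > 1.5))
    stop("alignment longer than 1.5x the gene: annotation/hit mismatch for ",
         hits$qseqid[which(qcov > 1.5 | scov > 1.5)[1]])
  pass <- hits$evalue <= e_max & qcov > cov_min & scov > cov_min
  if (!is.null(min_identity)) pass <- pass & hits$pident >= min_identity
  hits <- hits[pass, , drop = FALSE]
  g1 <- pmin(hits$qseqid, hits$sseqid)
  g2 <- pmax(hits$qseqid, hits$sseqid)
  und <- unique(data.frame(gene1 = g1, gene2 = g2, stringsAsFactors = FALSE))
  if (reciprocal) {
    fwd <- paste(hits$qseqid, hits$sseqid)
    rev <- paste(hits$sseqid, hits$qseqid)
    both <- fwd %in% rev
    und <- unique(data.frame(gene1 = pmin(hits$qseqid, hits$sseqid)[both],
                             gene2 = pmax(hits$qseqid, hits$sseqid)[both],
                             stringsAsFactors = FALSE))
  }
  und <- und[order(und$gene1, und$gene2), , drop = FALSE]
  rownames(und) <- NULL
  und
}

#' Group genes into multi-copy families
#'
#' Families are the connected components (single-linkage closure) of the
#' undirected filtered-hit graph with at least two members; genes with no
#' surviving edge are singletons.  Family ids are deterministic: `F_` plus
#' the lexicographically smallest member.
#'
#' @param edges data.frame from [filter_hits()].
#' @param all_genes character vector of every annotated gene id (or a
#'   [gene_table()]).
#' @return list with `families` (data.frame `gene_id`, `family_id`,
#'   `family_size`) and `singletons` (character vector).
#' @export
build_families <- function(edges, all_genes) {
  if (inherits(all_genes, "gene_table")) all_genes <- all_genes$gene_id
  unknown <- setdiff(c(edges$gene1, edges$gene2), all_genes)
  if (length(unknown)) stop("edge references unknown gene: ", unknown[1])
  if (!nrow(edges)) {
    return(list(families = data.frame(gene_id = character(0),
                                      family_id = character(0),
                                      family_size = integer(0),
                                      stringsAsFactors = FALSE),
                singletons = sort(all_genes)))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  member <- data.frame(gene_id = names(comp$membership),
                       comp = as.integer(comp$membership),
                       stringsAsFactors = FALSE)
  fam_min <- tapply(member$gene_id, member$comp, min)
  fam_n <- tapply(member$gene_id, member$comp, length)
  fams <- data.frame(
    gene_id = member$gene_id,
    family_id = paste0("F_", fam_min[as.character(member$comp)]),
    family_size = as.integer(fam_n[as.character(member$comp)]),
    stringsAsFactors = FALSE)
  fams <- fams[order(fams$family_id, fams$gene_id), , drop = FALSE]
  rownames(fams) <- NULL
  list(families = fams,
       singletons = sort(setdiff(all_genes, fams$gene_id)))
}

#' Family size distribution
#'
#' Per-size family counts and percentages, the singleton fraction of the
#' gene complement, and the share of multi-copy genes falling in the small
#' (2-3), medium (4-6) and large (7+) size bands.
#'
#' @param families data.frame from [build_families()].
#' @param n_genes_total size of the annotated complement.
#' @return list with `table` (size, n_families, pct_families, n_genes),
#'   `n_families`, `n_multicopy_genes`, `singleton_fraction_pct` and
#'   `band_gene_shares`.
#' @export
family_size_distribution <- function(families, n_genes_total) {
  if (!nrow(families)) {
    return(list(table = data.frame(size = integer(0), n_families = integer(0),
                                   pct_families = numeric(0),
                                   n_genes = integer(0)),
                n_families = 0L, n_multicopy_genes = 0L,
                singleton_fraction_pct =
                  round(100 * n_genes_total / max(n_genes_total, 1), 1),
                band_gene_shares = c(`2-3` = NA_real_, `4-6` = NA_real_,
                                     `7+` = NA_real_)))
  }
  per_fam <- unique(families[c("family_id", "family_size")])
  tab <- as.data.frame(table(per_fam$family_size), stringsAsFactors = FALSE)
  names(tab) <- c("size", "n_families")
  tab$size <- as.integer(tab$size)
  nfam <- sum(tab$n_families)
  tab$pct_families <- round(100 * tab$n_families / nfam)
  tab$n_genes <- tab$size * tab$n_families
  n_mc <- sum(tab$n_genes)
  band <- cut(per_fam$family_size, c(1, 3, 6, Inf), labels = c("2-3", "4-6", "7+"))
  band_genes <- tapply(per_fam$family_size, band, sum)
  band_genes[is.na(band_genes)] <- 0
  list(table = tab,
       n_families = nfam,
       n_multicopy_genes = n_mc,
       singleton_fraction_pct = round(100 * (n_genes_total - n_mc) /
                                        n_genes_total, 1),
       band_gene_shares = round(100 * band_genes / n_mc, 1))
}

#' Write / read the families table
#' @param fams list from [build_families()].
#' @param path TSV file.
#' @export
write_families_table <- function(fams, path) {
  utils::write.table(fams$families, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_families_table
#' @export
read_families_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(gene_id = "character",
                                   family_id = "character",
                                   family_size = "integer"))
}
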