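#' Detect tandem clusters of homologous genes
#'
#' Within each family and scaffold, members are sorted by positional rank and
#' chained whenever the number of intervening annotated genes (rank
#' difference minus one, counting genes of any family) is at most
#' `max_intervening`; the default 8 is the strict reading of "fewer than nine
#' genes between homologs".  Chaining is transitive along the chain, and
#' chains of two or more members become clusters.  Interleaved families
#' yield separate clusters even when spatially mixed.
#'
#' @param families data.frame with `gene_id` and `family_id` (from
#'   [build_families()] or planted truth).
#' @param genes a [gene_table()] with per-scaffold ranks.
#' @param max_intervening maximum annotated genes allowed between consecutive
#'   members (default 8).
#' @return data.frame of class `tandem_clusters`: `cluster_id`, `scaffold`,
#'   `gene_id`, `rank`, `family_id`, ordered by cluster and rank.
#' @export
detect_clusters <- function(families, genes, max_intervening = 8L) {
  missing <- setdiff(families$gene_id, genes$gene_id)
  if (length(missing))
    stop("family gene missing from the gene table: ", missing[1])
  idx <- match(families$gene_id, genes$gene_id)
  df <- data.frame(gene_id = families$gene_id,
                   family_id = families$family_id,
                   scaffold = genes$scaffold[idx],
                   rank = genes$rank[idx],
                   start = genes$start[idx],
                   end = genes$end[idx],
                   stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(paste(df$family_id, df$scaffold))) {
    sub <- df[paste(df$family_id, df$scaffold) == key, , drop = FALSE]
    if (nrow(sub) < 2) next
    sub <- sub[order(sub$rank), , drop = FALSE]
    chain <- cumsum(c(0L, diff(sub$rank) - 1L > max_intervening))
    for (ch in split(seq_len(nrow(sub)), chain)) {
      if (length(ch) < 2) next
      m <- sub[ch, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        cluster_id = sprintf("C_%s", m$gene_id[1]),
        scaffold = m$scaffold, gene_id = m$gene_id, rank = m$rank,
        family_id = m$family_id, stringsAsFactors = FALSE)
    }
  }
  cl <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster_id = character(0), scaffold = character(0),
               gene_id = character(0), rank = integer(0),
               family_id = character(0), stringsAsFactors = FALSE)
  cl <- cl[order(cl$cluster_id, cl$rank), , drop = FALSE]
  rownames(cl) <- NULL
  class(cl) <- c("tandem_clusters", "data.frame")
  cl
}

#' Cluster size distribution
#'
#' Per-size counts and percentages of tandem clusters, plus the share of
#' clustered genes sitting in clusters of five or more members.
#'
#' @param clusters a `tandem_clusters` data.frame.
#' @return list with `table` (size, n_clusters, pct_clusters), `n_clusters`,
#'   `n_clustered_genes`, `longest` and `pct_genes_in_ge5`.
#' @export
cluster_size_distribution <- function(clusters) {
  if (!nrow(clusters)) {
    return(list(table = data.frame(size = integer(0), n_clusters = integer(0),
                                   pct_clusters = numeric(0)),
                n_clusters = 0L, n_clustered_genes = 0L, longest = 0L,
                pct_genes_in_ge5 = NA_real_))
  }
  sz <- table(clusters$cluster_id)
  tab <- as.data.frame(table(as.integer(sz)), stringsAsFactors = FALSE)
  names(tab) <- c("size", "n_clusters")
  tab$size <- as.integer(tab$size)
  ncl <- sum(tab$n_clusters)
  tab$pct_clusters <- round(100 * tab$n_clusters / ncl)
  n_genes <- sum(tab$size * tab$n_clusters)
  ge5 <- sum(tab$size[tab$size >= 5] * tab$n_clusters[tab$size >= 5])
  list(table = tab, n_clusters = ncl, n_clustered_genes = n_genes,
       longest = max(tab$size),
       pct_genes_in_ge5 = round(100 * ge5 / n_genes, 1))
}

#' Apply curated cluster-membership overrides
#'
#' Replaces the occasional relaxation of the intervening-gene criterion that
#' was historically done by eye: an overrides table can `add` a gene of the
#' same family to an existing cluster or `merge` two clusters of the same
#' family.  Overrides crossing families are rejected; every applied override
#' is recorded in the returned attribute `override_log`.
#'
#' @param clusters a `tandem_clusters` data.frame.
#' @param overrides data.frame with columns `action` (`"add"`/`"merge"`),
#'   `target` (cluster id) and `value` (gene id for `add`, cluster id for
#'   `merge`), or a path to such a TSV; `NULL`/empty is the identity.
#' @param families family membership table (needed to validate `add`).
#' @param genes a [gene_table()] (ranks for added genes).
#' @return updated `tandem_clusters` with an `override_log` attribute.
#' @export
override_membership <- function(clusters, overrides, families, genes) {
  if (is.null(overrides)) return(clusters)
  if (is.character(overrides) && length(overrides) == 1)
    overrides <- utils::read.delim(overrides, stringsAsFactors = FALSE)
  if (!nrow(overrides)) return(clusters)
  stopifnot(all(c("action", "target", "value") %in% names(overrides)))
  log <- character(0)
  for (i in seq_len(nrow(overrides))) {
    act <- overrides$action[i]
    tgt <- overrides$target[i]
    val <- overrides$value[i]
    if (!tgt %in% clusters$cluster_id)
      stop("override targets unknown cluster: ", tgt)
    fam <- unique(clusters$family_id[clusters$cluster_id == tgt])
    if (act == "add") {
      gfam <- families$family_id[families$gene_id == val]
      if (!length(gfam) || gfam != fam)
        stop("cannot add gene ", val, " to cluster ", tgt,
             ": not a member of family ", fam)
      if (val %in% clusters$gene_id[clusters$cluster_id == tgt]) next
      idx <- match(val, genes$gene_id)
      clusters <- rbind(clusters, data.frame(
        cluster_id = tgt, scaffold = genes$scaffold[idx], gene_id = val,
        rank = genes$rank[idx], family_id = fam, stringsAsFactors = FALSE))
      log <- c(log, sprintf("add %s -> %s", val, tgt))
    } else if (act == "merge") {
      fam2 <- unique(clusters$family_id[clusters$cluster_id == val])
      if (!length(fam2)) stop("override targets unknown cluster: ", val)
      if (!identical(fam, fam2))
        stop("cannot merge clusters of different families: ",
             tgt, " (", fam, ") and ", val, " (", fam2, ")")
      clusters$cluster_id[clusters$cluster_id == val] <- tgt
      log <- c(log, sprintf("merge %s -> %s", val, tgt))
    } else stop("unknown override action: ", act)
  }
  clusters <- clusters[order(clusters$cluster_id, clusters$rank), ,
                       drop = FALSE]
  rownames(clusters) <- NULL
  class(clusters) <- c("tandem_clusters", "data.frame")
  attr(clusters, "override_log") <- log
  clusters
}

#' Write the clusters table and a BED of cluster spans
#' @param clusters a `tandem_clusters` data.frame.
#' @param genes a [gene_table()].
#' @param path TSV output; `bed_path` optional BED (0-based half-open spans).
#' @export
write_clusters_table <- function(clusters, genes, path, bed_path = NULL) {
  df <- clusters
  class(df) <- "data.frame"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    idx <- match(clusters$gene_id, genes$gene_id)
    span <- do.call(rbind, lapply(split(seq_len(nrow(clusters)),
                                        clusters$cluster_id), function(i) {
      data.frame(chrom = clusters$scaffold[i[1]],
                 start = min(genes$start[idx[i]]) - 1L,
                 end = max(genes$end[idx[i]]),
                 name = clusters$cluster_id[i[1]],
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(span, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
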