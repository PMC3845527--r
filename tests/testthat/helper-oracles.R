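# Independent oracles shared by the unit and cohort-level tests.

# Brute-force enumeration over ordered cultivar pairs: the independent
# oracle for the ratio screen (zero cells governed by the support rule).
oracle_ratio <- function(cm, th = pav_thresholds()) {
  nm <- normalize_counts(cm)
  cand <- character(0)
  for (g in rownames(nm$norm)) {
    hit <- FALSE
    for (a in colnames(nm$norm)) for (b in colnames(nm$norm)) {
      if (a == b) next
      na <- nm$norm[g, a]; nb <- nm$norm[g, b]
      if (na > 0 && nb > 0 &&
          (na / nb < th$ratio_low || na / nb > th$ratio_high)) hit <- TRUE
      if (nb == 0 && na > 0 && cm$counts[g, a] >= th$min_support) hit <- TRUE
    }
    if (hit) cand <- c(cand, g)
  }
  cand
}

rand_counts <- function(n = 200, k = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * k, lambda = sample(c(0, 3, 20, 100), n * k,
                                           replace = TRUE)),
              n, k, dimnames = list(sprintf("g%03d", 1:n), LETTERS[1:k]))
  count_matrix(m, stats::setNames(runif(k, 1e6, 3e6), LETTERS[1:k]))
}

# Exhaustive oracle: connect every within-family, within-scaffold pair with
# at most max_intervening genes between them, then take graph components.
oracle_clusters <- function(families, genes, max_intervening = 8) {
  out <- list()
  for (fid in unique(families$family_id)) {
    mem <- families$gene_id[families$family_id == fid]
    sub <- genes[genes$gene_id %in% mem, ]
    for (sc in unique(sub$scaffold)) {
      s2 <- sub[sub$scaffold == sc, ]
      if (nrow(s2) < 2) next
      edges <- data.frame(gene1 = character(0), gene2 = character(0))
      for (i in seq_len(nrow(s2))) for (j in seq_len(nrow(s2))) {
        if (i < j && abs(s2$rank[i] - s2$rank[j]) - 1 <= max_intervening)
          edges <- rbind(edges, data.frame(gene1 = s2$gene_id[i],
                                           gene2 = s2$gene_id[j]))
      }
      comps <- uf_components(edges, s2$gene_id)
      for (cc in comps) if (length(cc) >= 2) out[[length(out) + 1]] <- sort(cc)
    }
  }
  unname(out[order(vapply(out, `[`, character(1), 1))])
}

cluster_sets <- function(clusters) {
  sets <- lapply(split(clusters$gene_id, clusters$cluster_id), sort)
  unname(sets[order(vapply(sets, `[`, character(1), 1))])
}
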