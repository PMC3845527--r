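#' Simulation parameters for a synthetic resequencing cohort
#'
#' The generator emulates the structure the PAV analysis assumes: ~27k genes
#' on a handful of scaffolds, five cultivars (one of them the reference
#' genotype the reads are mapped back to) at 13-16x depth, about a quarter of
#' genes in multi-copy families (mostly of size two or three, tail to twenty),
#' a fraction of families laid down as tandem runs, and planted full/partial
#' gene deletions whose rate is boosted for multi-copy and tandem genes.
#'
#' @param n_genes total annotated genes.
#' @param n_scaffolds scaffolds the genes are spread over.
#' @param mean_gene_len,mean_intergenic mean gene length / intergenic gap (bp).
#' @param singleton_fraction expected fraction of genes in single-member
#'   families (default 0.753).
#' @param family_size_weights named probability vector over family sizes
#'   2..20; must sum to 1.
#' @param p_tandem probability a multi-copy family is placed as a tandem run
#'   of consecutive genes rather than scattered across scaffolds.
#' @param cultivars cultivar names; `reference` must be one of them and never
#'   carries planted deletions (its reads map back to its own assembly).
#' @param reference the reference cultivar.
#' @param depth_per_cultivar named fold-coverage vector (x genome).
#' @param read_len read length (bp).
#' @param base_del_rate per-gene, per-cultivar deletion seed probability for
#'   singleton, non-clustered genes.
#' @param multi_copy_multiplier,cluster_multiplier rate multipliers applied to
#'   multi-copy and tandem-placed genes respectively.
#' @param segment_del_prob probability a seeded deletion extends over a run of
#'   adjacent genes; run length is geometric with mean `segment_run_mean`.
#' @param segment_run_mean mean multi-gene run length (genes).
#' @param partial_del_prob probability a deletion event is partial rather than
#'   full; partial genes retain a Uniform(0.2, 0.8) fraction of their span.
#' @param background_mismap_rate expected mis-mapped reads per kb of deleted
#'   sequence (0 = clean deletions).
#' @param overdispersion negative-binomial dispersion of read counts; 0 means
#'   Poisson.
#' @param breadth_noise Beta concentration of the simulated breadth of
#'   coverage around the retained fraction; 0 means exact.
#' @param n_decoys decoy homology hits that must fail the downstream filters.
#' @param seed master seed; each sub-generator (annotation, deletions, counts,
#'   hits) draws from its own stream derived from it, so e.g. adding decoy
#'   hits never perturbs the simulated counts.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 27427L,
                       n_scaffolds = 20L,
                       mean_gene_len = 1500,
                       mean_intergenic = 14000,
                       singleton_fraction = 0.753,
                       family_size_weights = default_family_size_weights(),
                       p_tandem = 0.36,
                       cultivars = c("DHL92", "T111", "PI161375",
                                     "C-836", "C-1012"),
                       reference = "DHL92",
                       depth_per_cultivar = c(DHL92 = 14, T111 = 15,
                                              PI161375 = 15, `C-836` = 13,
                                              `C-1012` = 16),
                       read_len = 150L,
                       base_del_rate = 0.004,
                       multi_copy_multiplier = 5,
                       cluster_multiplier = 2,
                       segment_del_prob = 0.3,
                       segment_run_mean = 3,
                       partial_del_prob = 0.35,
                       background_mismap_rate = 0,
                       overdispersion = 0,
                       breadth_noise = 200,
                       n_decoys = round(0.02 * n_genes),
                       seed = 1L) {
  p <- list(n_genes = as.integer(n_genes), n_scaffolds = as.integer(n_scaffolds),
            mean_gene_len = mean_gene_len, mean_intergenic = mean_intergenic,
            singleton_fraction = singleton_fraction,
            family_size_weights = family_size_weights,
            p_tandem = p_tandem, cultivars = cultivars, reference = reference,
            depth_per_cultivar = depth_per_cultivar, read_len = as.integer(read_len),
            base_del_rate = base_del_rate,
            multi_copy_multiplier = multi_copy_multiplier,
            cluster_multiplier = cluster_multiplier,
            segment_del_prob = segment_del_prob,
            segment_run_mean = segment_run_mean,
            partial_del_prob = partial_del_prob,
            background_mismap_rate = background_mismap_rate,
            overdispersion = overdispersion, breadth_noise = breadth_noise,
            n_decoys = as.integer(n_decoys), seed = as.integer(seed))
  probs <- c(singleton_fraction, p_tandem, base_del_rate, segment_del_prob,
             partial_del_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(family_size_weights) - 1) > 1e-8)
    stop("family_size_weights must sum to 1")
  sz <- as.integer(names(family_size_weights))
  if (anyNA(sz) || any(sz < 2)) stop("family sizes must be integers >= 2")
  if (!reference %in% cultivars) stop("reference must be one of the cultivars")
  p$depth_per_cultivar <- depth_per_cultivar[cultivars]
  if (anyNA(p$depth_per_cultivar) || any(p$depth_per_cultivar <= 0))
    stop("every cultivar needs a positive fold-coverage")
  if (multi_copy_multiplier < 1 || cluster_multiplier < 1)
    stop("rate multipliers must be >= 1")
  if (p$n_genes < 1) stop("n_genes must be positive")
  class(p) <- "sim_params"
  p
}

#' Default family-size distribution
#'
#' Calibrated to the observed cohort: 64% of multi-copy families have two
#' members and 16% have three; the remainder decays geometrically out to
#' twenty members.
#' @return named probability vector over sizes 2..20.
#' @export
default_family_size_weights <- function() {
  w <- c(`2` = 0.644, `3` = 0.159, `4` = 0.070, `5` = 0.040, `6` = 0.025)
  tail_sizes <- 7:20
  tail <- 0.75^(tail_sizes - 7)
  tail <- tail / sum(tail) * (1 - sum(w))
  names(tail) <- tail_sizes
  c(w, tail)
}

# Independent RNG stream per sub-generator, derived from the master seed.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Generate a synthetic gene annotation with planted family architecture
#'
#' Draws the number of multi-copy genes binomially from
#' `1 - singleton_fraction`, partitions them into families by
#' `family_size_weights`, and places each family either as a tandem run of
#' consecutive genes on one scaffold (probability `p_tandem`) or scattered
#' over distinct scaffolds.  Gene lengths within a family vary by at most
#' +/-5% around a family base length (homologs are near-full-length copies);
#' singleton lengths are Gamma-distributed.  Coordinates are 1-based
#' inclusive and genes never overlap.
#'
#' @param params a [sim_params()].
#' @return list with `genes` (a [gene_table()]) and `families`, a data.frame
#'   of the planted truth: `gene_id`, `family_id`, `family_size`, `tandem`.
#' @export
generate_annotation <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(sub_seed(params$seed, 1L))
  n <- params$n_genes

  # family sizes to cover a binomial draw of multi-copy genes
  n_mc <- if (params$singleton_fraction >= 1) 0L else
    stats::rbinom(1L, n, 1 - params$singleton_fraction)
  sizes <- integer(0)
  if (n_mc >= 2L) {
    szs <- as.integer(names(params$family_size_weights))
    if (min(szs) > n)
      stop("n_genes too small for the requested family architecture")
    while (sum(sizes) < n_mc) {
      s <- sample(szs, 1L, prob = params$family_size_weights)
      sizes <- c(sizes, s)
    }
    over <- sum(sizes) - n_mc
    if (over > 0) {
      last <- sizes[length(sizes)]
      if (last - over >= 2L) sizes[length(sizes)] <- last - over
      else sizes <- sizes[-length(sizes)]
    }
    if (sum(sizes) > n)
      stop("n_genes too small for the requested family architecture")
  }
  n_fam_genes <- sum(sizes)
  n_single <- n - n_fam_genes
  tandem <- if (length(sizes)) stats::runif(length(sizes)) < params$p_tandem
            else logical(0)

  # near-even scaffold capacities
  cap <- rep(n %/% params$n_scaffolds, params$n_scaffolds)
  extra <- n %% params$n_scaffolds
  if (extra > 0) cap[seq_len(extra)] <- cap[seq_len(extra)] + 1L
  scaf_names <- sprintf("scaffold%02d", seq_len(params$n_scaffolds))

  # a unit is a maximal block of genes that must stay consecutive:
  # tandem families are one unit, everything else units of one gene
  unit_scaffold <- integer(0)
  unit_family <- integer(0)   # 0 = singleton
  unit_len <- integer(0)
  add_unit <- function(scaf, fam, len) {
    unit_scaffold[[length(unit_scaffold) + 1L]] <<- scaf
    unit_family[[length(unit_family) + 1L]] <<- fam
    unit_len[[length(unit_len) + 1L]] <<- len
    cap[scaf] <<- cap[scaf] - len
  }
  fam_order <- if (length(sizes)) order(-sizes) else integer(0) # big first
  for (fi in fam_order) {
    s <- sizes[fi]
    if (tandem[fi]) {
      ok <- which(cap >= s)
      if (!length(ok))
        stop("n_genes too small for the requested family architecture")
      scaf <- if (length(ok) == 1L) ok else
        sample(ok, 1L, prob = cap[ok])
      add_unit(scaf, fi, s)
    } else {
      # scattered members go to distinct scaffolds where possible, so that
      # planted tandem runs are the only within-family positional clusters
      for (m in seq_len(s)) {
        ok <- which(cap > 0)
        used <- unit_scaffold[unit_family == fi]
        pref <- setdiff(ok, used)
        pool <- if (length(pref)) pref else ok
        if (!length(pool))
          stop("n_genes too small for the requested family architecture")
        scaf <- if (length(pool) == 1L) pool else
          sample(pool, 1L, prob = cap[pool])
        add_unit(scaf, fi, 1L)
      }
    }
  }
  if (n_single > 0) {
    ok <- rep(seq_along(cap), cap)
    for (scaf in seq_along(cap)) {
      k <- cap[scaf]
      if (k > 0) for (i in seq_len(k)) add_unit(scaf, 0L, 1L)
    }
  }

  # per-scaffold random unit order -> genome order
  ord <- sample.int(length(unit_len))
  unit_scaffold <- unit_scaffold[ord]
  unit_family <- unit_family[ord]
  unit_len <- unit_len[ord]
  ord2 <- order(unit_scaffold)
  unit_scaffold <- unit_scaffold[ord2]
  unit_family <- unit_family[ord2]
  unit_len <- unit_len[ord2]

  gene_scaf <- rep.int(unit_scaffold, unit_len)
  gene_fam <- rep.int(unit_family, unit_len)

  # lengths: family base length +/-5%, singletons Gamma(shape 4)
  fam_base <- if (length(sizes))
    pmax(300, round(stats::rgamma(length(sizes), shape = 4,
                                  scale = params$mean_gene_len / 4)))
    else numeric(0)
  len <- integer(n)
  is_fam <- gene_fam > 0L
  len[is_fam] <- pmax(300L, as.integer(round(
    fam_base[gene_fam[is_fam]] * stats::runif(sum(is_fam), 0.95, 1.05))))
  len[!is_fam] <- pmax(300L, as.integer(round(
    stats::rgamma(sum(!is_fam), shape = 4,
                  scale = params$mean_gene_len / 4))))

  gap <- as.integer(round(stats::rexp(n, 1 / params$mean_intergenic))) + 1L
  start <- integer(n)
  end <- integer(n)
  pos <- 0L
  cur_scaf <- 0L
  for (i in seq_len(n)) {
    if (gene_scaf[i] != cur_scaf) { cur_scaf <- gene_scaf[i]; pos <- 0L }
    start[i] <- pos + gap[i] + 1L
    end[i] <- start[i] + len[i] - 1L
    pos <- end[i]
  }
  ids <- sprintf("g%06d", seq_len(n))
  genes <- gene_table(ids, scaf_names[gene_scaf], start, end,
                      sample(c("+", "-"), n, replace = TRUE))
  # gene_table preserves genomic order, so ids line up row-wise
  stopifnot(identical(genes$gene_id, ids))

  families <- data.frame(gene_id = ids[is_fam],
                         family_idx = gene_fam[is_fam],
                         stringsAsFactors = FALSE)
  if (nrow(families)) {
    fam_min <- tapply(families$gene_id, families$family_idx, min)
    families$family_id <- paste0("F_", fam_min[as.character(families$family_idx)])
    fam_n <- table(families$family_idx)
    families$family_size <- as.integer(fam_n[as.character(families$family_idx)])
    families$tandem <- tandem[families$family_idx]
    families$family_idx <- NULL
  } else {
    families <- data.frame(gene_id = character(0), family_id = character(0),
                           family_size = integer(0), tandem = logical(0),
                           stringsAsFactors = FALSE)
  }
  list(genes = genes, families = families)
}

#' Plant presence/absence deletions in a synthetic cohort
#'
#' For every gene and non-reference cultivar a deletion is seeded with
#' probability `base_del_rate`, multiplied by `multi_copy_multiplier` for
#' multi-copy genes and additionally by `cluster_multiplier` for genes in
#' tandem-placed families.  With probability `segment_del_prob` the deletion
#' extends downstream over a geometric run of adjacent genes (mean
#' `segment_run_mean`), emulating multi-gene deletion segments.  Each event is
#' partial with probability `partial_del_prob`; partial genes retain a
#' Uniform(0.2, 0.8) fraction of their span.  The reference cultivar never
#' carries deletions.
#'
#' @param genes a [gene_table()].
#' @param families planted family truth from [generate_annotation()].
#' @param params a [sim_params()].
#' @return data.frame of class `deletion_truth` with columns `gene_id`,
#'   `cultivar`, `kind` (`"full"`/`"partial"`) and `retained_fraction`.
#' @export
generate_pav_truth <- function(genes, families, params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(sub_seed(params$seed, 2L))
  n <- nrow(genes)
  is_mc <- genes$gene_id %in% families$gene_id
  is_cl <- genes$gene_id %in% families$gene_id[families$tandem]
  p_gene <- params$base_del_rate *
    ifelse(is_mc, params$multi_copy_multiplier, 1) *
    ifelse(is_cl, params$cluster_multiplier, 1)
  p_gene <- pmin(p_gene, 1)

  out <- list()
  non_ref <- setdiff(params$cultivars, params$reference)
  for (cv in non_ref) {
    seeds <- which(stats::runif(n) < p_gene)
    if (!length(seeds)) next
    rows <- integer(0)
    kind <- character(0)
    for (i in seeds) {
      run <- i
      if (stats::runif(1) < params$segment_del_prob) {
        L <- stats::rgeom(1, 1 / max(params$segment_run_mean, 1)) + 1L
        if (L > 1L) {
          j <- i + seq_len(L - 1L)
          j <- j[j <= n & genes$scaffold[j] == genes$scaffold[i]]
          run <- c(i, j)
        }
      }
      k <- if (stats::runif(1) < params$partial_del_prob) "partial" else "full"
      rows <- c(rows, run)
      kind <- c(kind, rep(k, length(run)))
    }
    keep <- !duplicated(rows)
    rows <- rows[keep]; kind <- kind[keep]
    retained <- ifelse(kind == "partial",
                       stats::runif(length(rows), 0.2, 0.8), 0)
    out[[cv]] <- data.frame(gene_id = genes$gene_id[rows], cultivar = cv,
                            kind = kind, retained_fraction = retained,
                            stringsAsFactors = FALSE)
  }
  truth <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), cultivar = character(0),
               kind = character(0), retained_fraction = numeric(0),
               stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  class(truth) <- c("deletion_truth", "data.frame")
  truth
}

#' Simulate per-gene read counts and breadth of coverage
#'
#' The expected mapped-read count of gene g in cultivar c is
#' `depth(c) * (len(g) + read_len) / read_len * retained(g, c)` — the number
#' of read starts whose alignment overlaps the gene span by at least one base
#' at the given fold-coverage — plus
#' `background_mismap_rate * len(g)/1000 * (1 - retained)` for deleted spans.
#' Counts are Poisson, or negative binomial when `overdispersion > 0`
#' (`size = 1/overdispersion`).  Breadth equals the retained fraction, with
#' Beta noise of concentration `breadth_noise` when that is positive.
#' Library sizes are the genic column sums plus a Poisson draw of reads
#' falling in the simulated intergenic space.
#'
#' @inheritParams generate_pav_truth
#' @param truth a `deletion_truth` from [generate_pav_truth()].
#' @return list with `counts` (a [count_matrix()]) and `breadth`
#'   (a [breadth_matrix()]).
#' @export
simulate_counts <- function(genes, truth, params) {
  stopifnot(inherits(params, "sim_params"))
  if (any(params$depth_per_cultivar <= 0)) stop("depth must be positive")
  bad <- setdiff(truth$gene_id, genes$gene_id)
  if (length(bad)) stop("truth references unknown gene(s): ", bad[1])
  set.seed(sub_seed(params$seed, 3L))
  n <- nrow(genes)
  cvs <- params$cultivars
  retained <- matrix(1, n, length(cvs),
                     dimnames = list(genes$gene_id, cvs))
  if (nrow(truth)) {
    idx <- cbind(match(truth$gene_id, genes$gene_id),
                 match(truth$cultivar, cvs))
    retained[idx] <- truth$retained_fraction
  }
  per_copy <- (genes$length + params$read_len) / params$read_len
  lambda <- sweep(retained * per_copy, 2, params$depth_per_cultivar, "*") +
    params$background_mismap_rate * (genes$length / 1000) * (1 - retained)
  counts <- matrix(0L, n, length(cvs), dimnames = dimnames(retained))
  for (j in seq_along(cvs)) {
    counts[, j] <- if (params$overdispersion > 0)
      stats::rnbinom(n, mu = lambda[, j], size = 1 / params$overdispersion)
    else stats::rpois(n, lambda[, j])
  }
  breadth <- retained
  if (params$breadth_noise > 0) {
    c0 <- params$breadth_noise
    b <- stats::rbeta(length(retained), 1 + c0 * retained,
                      1 + c0 * (1 - retained))
    breadth <- matrix(pmin(1, pmax(0, b)), n, length(cvs),
                      dimnames = dimnames(retained))
    # exact endpoints stay informative: fully deleted spans can still draw
    # a trickle of breadth, which is what the caller's thresholds absorb
  }
  span <- tapply(genes$end, genes$scaffold, max)
  intergenic_bp <- max(sum(span) - sum(genes$length), 0)
  lib <- colSums(counts) +
    stats::rpois(length(cvs),
                 params$depth_per_cultivar * intergenic_bp / params$read_len)
  names(lib) <- cvs
  list(counts = count_matrix(counts, lib),
       breadth = breadth_matrix(breadth))
}

#' Emit synthetic pairwise homology hits
#'
#' Every ordered pair of genes within a planted family yields a 12-column
#' tabular hit with identity ~ Uniform(69, 100)%, aligned length a
#' Uniform(0.5, 1) fraction of the shorter gene, and e-value at most 1e-20,
#' so all true pairs survive the downstream filters.  `n_decoys` additional
#' hits between unrelated genes are constructed to fail them (e-value above
#' 1e-20 or coverage at or below 40%).
#'
#' @inheritParams generate_pav_truth
#' @return data.frame in BLAST tabular (outfmt 6) column order: `qseqid
#'   sseqid pident length mismatch gapopen qstart qend sstart send evalue
#'   bitscore`.
#' @export
emit_homology_hits <- function(families, genes, params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(sub_seed(params$seed, 4L))
  len <- gene_lengths(genes)
  pairs_q <- character(0); pairs_s <- character(0)
  if (nrow(families)) {
    for (fid in unique(families$family_id)) {
      mem <- families$gene_id[families$family_id == fid]
      grid <- expand.grid(q = mem, s = mem, stringsAsFactors = FALSE)
      grid <- grid[grid$q != grid$s, ]
      pairs_q <- c(pairs_q, grid$q)
      pairs_s <- c(pairs_s, grid$s)
    }
  }
  mk <- function(q, s, frac, pid, eval_exp) {
    alen <- pmax(30L, as.integer(round(frac * pmin(len[q], len[s]))))
    data.frame(qseqid = q, sseqid = s,
               pident = round(pid, 2), length = alen,
               mismatch = as.integer(round((1 - pid / 100) * alen)),
               gapopen = 0L, qstart = 1L, qend = alen,
               sstart = 1L, send = alen,
               evalue = 10^(-eval_exp),
               bitscore = round(2 * alen * pid / 100, 1),
               stringsAsFactors = FALSE)
  }
  real <- if (length(pairs_q))
    mk(pairs_q, pairs_s, stats::runif(length(pairs_q), 0.5, 1),
       stats::runif(length(pairs_q), 69, 100),
       stats::runif(length(pairs_q), 20, 180))
  else NULL
  decoy <- NULL
  nd <- params$n_decoys
  if (nd > 0 && nrow(genes) >= 2) {
    q <- sample(genes$gene_id, nd, replace = TRUE)
    s <- sample(genes$gene_id, nd, replace = TRUE)
    ok <- q != s
    q <- q[ok]; s <- s[ok]
    if (length(q)) {
      half <- stats::runif(length(q)) < 0.5
      # half fail on e-value, half on mutual coverage
      decoy <- rbind(
        if (any(half)) mk(q[half], s[half],
                          stats::runif(sum(half), 0.5, 1),
                          stats::runif(sum(half), 69, 100),
                          stats::runif(sum(half), 1, 19)),
        if (any(!half)) mk(q[!half], s[!half],
                           stats::runif(sum(!half), 0.05, 0.35),
                           stats::runif(sum(!half), 69, 100),
                           stats::runif(sum(!half), 20, 180))
      )
    }
  }
  hits <- rbind(real, decoy)
  if (is.null(hits))
    hits <- mk(character(0), character(0), numeric(0), numeric(0), numeric(0))
  rownames(hits) <- NULL
  hits
}

#' Write / read BLAST tabular hit files
#'
#' Standard 12-column tab-separated format (outfmt 6), no header.
#' @param hits data.frame as produced by [emit_homology_hits()].
#' @param path TSV file.
#' @export
write_hits_table <- function(hits, path) {
  df <- hits
  df$evalue <- sprintf("%.6g", df$evalue)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_table
#' @export
read_hits_table <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, col.names = cols,
                          stringsAsFactors = FALSE)
  df$qseqid <- as.character(df$qseqid)
  df$sseqid <- as.character(df$sseqid)
  df
}

#' Simulate a full cohort and write its files
#'
#' Runs annotation, deletion-truth, count/breadth and homology-hit generation
#' and writes `genes.gff3`, `counts.tsv`, `breadth.tsv`, `hits.tsv` and
#' `truth.json` into `dir`.  Fixed seed implies byte-identical outputs.
#'
#' @param params a [sim_params()].
#' @param dir output directory (created if missing).
#' @return invisibly, a list with all in-memory objects and file paths.
#' @export
simulate_cohort <- function(params, dir) {
  stopifnot(inherits(params, "sim_params"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(params)
  truth <- generate_pav_truth(ann$genes, ann$families, params)
  mats <- simulate_counts(ann$genes, truth, params)
  hits <- emit_homology_hits(ann$families, ann$genes, params)
  paths <- list(gff3 = file.path(dir, "genes.gff3"),
                counts = file.path(dir, "counts.tsv"),
                breadth = file.path(dir, "breadth.tsv"),
                hits = file.path(dir, "hits.tsv"),
                truth = file.path(dir, "truth.json"))
  write_gene_gff3(ann$genes, paths$gff3)
  write_count_table(mats$counts, paths$counts)
  write_breadth_table(mats$breadth, paths$breadth)
  write_hits_table(hits, paths$hits)
  jsonlite::write_json(truth, paths$truth, digits = NA)
  invisible(list(genes = ann$genes, families = ann$families, truth = truth,
                 counts = mats$counts, breadth = mats$breadth, hits = hits,
                 paths = paths))
}
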