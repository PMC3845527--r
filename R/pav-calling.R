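#' Screening thresholds for PAV calling
#'
#' Houses every constant of the two-screen candidate search and the
#' downstream absence reviewer.  All screen inequalities are strict, exactly
#' as the method defines them: a pairwise normalized ratio below 0.5 (or
#' above 2), fewer than 6 raw reads against more than 29, and candidates with
#' fewer than 10 reads in every cultivar are discarded.
#'
#' @param ratio_low,ratio_high pairwise normalized-ratio bounds (default
#'   0.5 / 2).
#' @param abs_low,abs_high raw-count bounds of the absolute screen: candidate
#'   needs some cultivar strictly below `abs_low` (6) and some other strictly
#'   above `abs_high` (29).
#' @param min_support low-support filter: a candidate with fewer than this
#'   many raw reads in all cultivars is discarded (default 10); also the
#'   support required of the non-zero cultivar in zero-denominator ratios.
#' @param absence_rel a cultivar is called absent when its normalized count
#'   is at most this fraction of the gene's maximum across cultivars
#'   (default 0.05).
#' @param breadth_absent,breadth_partial breadth-of-coverage windows: breadth
#'   at or below `breadth_absent` (0.10) supports full absence; breadth
#'   strictly between `breadth_absent` and `breadth_partial` (0.80) is called
#'   partial.
#' @return list of class `pav_thresholds`.
#' @export
pav_thresholds <- function(ratio_low = 0.5, ratio_high = 2,
                           abs_low = 6L, abs_high = 29L,
                           min_support = 10L,
                           absence_rel = 0.05,
                           breadth_absent = 0.10, breadth_partial = 0.80) {
  th <- list(ratio_low = ratio_low, ratio_high = ratio_high,
             abs_low = as.integer(abs_low), abs_high = as.integer(abs_high),
             min_support = as.integer(min_support),
             absence_rel = absence_rel,
             breadth_absent = breadth_absent,
             breadth_partial = breadth_partial)
  if (!(ratio_low > 0 && ratio_low < 1 && ratio_high > 1))
    stop("need 0 < ratio_low < 1 < ratio_high")
  if (th$abs_low > th$abs_high) stop("abs_low must not exceed abs_high")
  if (!(breadth_absent >= 0 && breadth_absent < breadth_partial &&
        breadth_partial <= 1))
    stop("need 0 <= breadth_absent < breadth_partial <= 1")
  class(th) <- "pav_thresholds"
  th
}

#' Ratio screen for PAV candidates
#'
#' A gene is a candidate when at least one ordered cultivar pair has a
#' normalized count ratio strictly below `ratio_low` or strictly above
#' `ratio_high` — equivalently, when min/max < ratio_low or max/min >
#' ratio_high over positive values.  When the smaller count is exactly zero
#' the ratio is taken as a candidate signal only if the larger cultivar has
#' at least `min_support` raw reads' worth of normalized coverage, avoiding
#' candidates driven by two near-empty cultivars.
#'
#' @param norm a `normalized_matrix` from [normalize_counts()].
#' @param th a [pav_thresholds()].
#' @return character vector of candidate gene ids.
#' @export
screen_ratio <- function(norm, th = pav_thresholds()) {
  stopifnot(inherits(norm, "normalized_matrix"))
  m <- norm$norm
  if (ncol(m) < 2) stop("ratio screen needs at least two cultivars")
  # ratios among positive cells: min/max and max/min of the positive values
  mpos <- m
  mpos[mpos == 0] <- Inf
  lo_pos <- apply(mpos, 1, min)           # Inf when all cells are zero
  hi <- apply(m, 1, max)
  n_pos <- rowSums(m > 0)
  ratio_viol <- n_pos >= 2 &
    (lo_pos / hi < th$ratio_low | hi / lo_pos > th$ratio_high)
  # a zero cell is a candidate signal iff some cultivar carries at least
  # min_support raw reads (its normalized equivalent, per library size)
  support <- th$min_support * norm$scale / norm$library_sizes
  supported <- rowSums(sweep(m, 2, support, ">=")) > 0
  cand <- ratio_viol | (apply(m, 1, min) == 0 & supported)
  rownames(m)[cand]
}

#' Absolute-count screen for PAV candidates
#'
#' A gene is a candidate when some cultivar has strictly fewer than `abs_low`
#' raw mapped reads while another has strictly more than `abs_high`.  Raw
#' counts are used deliberately — this screen catches genes the ratio screen
#' misses at very low coverage.
#'
#' @param counts a [count_matrix()].
#' @param th a [pav_thresholds()].
#' @return character vector of candidate gene ids.
#' @export
screen_absolute <- function(counts, th = pav_thresholds()) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  cand <- apply(m, 1, min) < th$abs_low & apply(m, 1, max) > th$abs_high
  rownames(m)[cand]
}

#' Discard candidates with negligible support everywhere
#'
#' A candidate with fewer than `min_support` raw reads in all cultivars is
#' discarded: with that little evidence anywhere, absence cannot be
#' distinguished from an unmappable locus.
#'
#' @param counts a [count_matrix()].
#' @param candidates character vector of candidate gene ids.
#' @param th a [pav_thresholds()].
#' @return list with `retained` and `discarded` gene id vectors
#'   (disjoint, union = candidates).
#' @export
filter_low_support <- function(counts, candidates, th = pav_thresholds()) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts[candidates, , drop = FALSE]
  weak <- apply(m, 1, max) < th$min_support
  list(retained = candidates[!weak], discarded = candidates[weak])
}

#' Merge candidate sets with screen provenance
#'
#' Union of the ratio screen, the absolute screen and optional manually
#' curated additions (one gene id per line in a text file, replacing ad-hoc
#' genome-browser finds), remembering which screens flagged each gene.
#'
#' @param ratio_set,absolute_set character vectors of gene ids.
#' @param manual_additions character vector of gene ids, or a path to a text
#'   file with one id per line, or `NULL`.
#' @return data.frame with `gene_id` and `screens` (comma-separated subset of
#'   `ratio`, `absolute`, `manual`).
#' @export
merge_candidates <- function(ratio_set, absolute_set, manual_additions = NULL) {
  manual <- character(0)
  if (!is.null(manual_additions)) {
    manual <- if (length(manual_additions) == 1 &&
                  file.exists(manual_additions))
      readLines(manual_additions, warn = FALSE) else manual_additions
    manual <- trimws(manual)
    manual <- manual[nzchar(manual)]
  }
  all <- sort(unique(c(ratio_set, absolute_set, manual)))
  screens <- vapply(all, function(g) {
    paste(c("ratio"[g %in% ratio_set],
            "absolute"[g %in% absolute_set],
            "manual"[g %in% manual]), collapse = ",")
  }, character(1))
  data.frame(gene_id = all, screens = unname(screens),
             stringsAsFactors = FALSE)
}

#' Review candidates and assign absence status per cultivar
#'
#' Deterministic replacement for the manual inspection step: for each
#' candidate gene and cultivar, the call is `absent` when the normalized
#' count is at most `absence_rel` of the gene's maximum across cultivars and
#' breadth of coverage (when available) is at or below `breadth_absent`;
#' `partial` when breadth lies strictly between `breadth_absent` and
#' `breadth_partial`; otherwise `present`.  Candidates with no absent or
#' partial cultivar are dropped from the final PAV list.
#'
#' @param candidates data.frame from [merge_candidates()] (or a character
#'   vector of gene ids).
#' @param counts a [count_matrix()] (raw evidence carried into the calls).
#' @param norm a `normalized_matrix` from [normalize_counts()].
#' @param breadth a [breadth_matrix()] or `NULL`; without it partial calling
#'   is disabled (a warning is issued, not an error).
#' @param th a [pav_thresholds()].
#' @return data.frame of class `pav_calls`: `gene_id`, `cultivar`, `status`
#'   (`present`/`partial`/`absent`), `screens`, `raw`, `norm`, `breadth`
#'   (NA when unavailable), `artifact_flag`.
#' @export
assign_absences <- function(candidates, counts, norm, breadth = NULL,
                            th = pav_thresholds()) {
  if (is.character(candidates))
    candidates <- data.frame(gene_id = candidates, screens = "",
                             stringsAsFactors = FALSE)
  stopifnot(inherits(norm, "normalized_matrix"))
  if (is.null(breadth)) {
    warning("no breadth matrix supplied; partial-absence calling disabled")
    bm <- NULL
  } else {
    stopifnot(inherits(breadth, "breadth_matrix"))
    bm <- breadth$breadth
  }
  genes <- candidates$gene_id
  missing <- setdiff(genes, rownames(norm$norm))
  if (length(missing))
    stop("candidate gene not in count matrix: ", missing[1])
  cvs <- colnames(norm$norm)
  out <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    g <- genes[k]
    nv <- norm$norm[g, ]
    rv <- counts$counts[g, ]
    bv <- if (is.null(bm)) rep(NA_real_, length(cvs)) else bm[g, ]
    mx <- max(nv)
    low_depth <- nv <= th$absence_rel * mx
    status <- rep("present", length(cvs))
    if (!is.null(bm)) {
      status[bv > th$breadth_absent & bv < th$breadth_partial] <- "partial"
      status[low_depth & bv <= th$breadth_absent] <- "absent"
    } else {
      status[low_depth] <- "absent"
    }
    if (mx == 0) status[] <- "present"  # no evidence of the gene anywhere
    if (!any(status != "present")) next
    out[[k]] <- data.frame(gene_id = g, cultivar = cvs, status = status,
                           screens = candidates$screens[k],
                           raw = as.numeric(rv), norm = as.numeric(nv),
                           breadth = as.numeric(bv),
                           artifact_flag = FALSE,
                           stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out)
  if (is.null(calls))
    calls <- data.frame(gene_id = character(0), cultivar = character(0),
                        status = character(0), screens = character(0),
                        raw = numeric(0), norm = numeric(0),
                        breadth = numeric(0), artifact_flag = logical(0),
                        stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  class(calls) <- c("pav_calls", "data.frame")
  calls
}

#' Flag reference-cultivar absences as mapping artifacts
#'
#' An apparent absence in the reference cultivar — whose own reads were
#' mapped back to its assembly — cannot be a real PAV and is flagged as a
#' mapping artifact.  When the reference's two parental lines are given, a
#' gene absent in the reference but present in both parents additionally
#' receives a `parent_inconsistent` tag (a clear false positive, since the
#' reference genome derives entirely from its parents).
#'
#' @param calls a `pav_calls` data.frame.
#' @param reference reference cultivar name.
#' @param parents optional character vector of the two parental cultivars.
#' @return `calls` with `artifact_flag` set and, when parents are given, a
#'   `parent_inconsistent` logical column.
#' @export
flag_reference_artifacts <- function(calls, reference, parents = NULL) {
  is_event <- calls$status %in% c("absent", "partial")
  calls$artifact_flag <- is_event & calls$cultivar == reference
  if (!is.null(parents)) {
    if (length(parents) != 2) stop("parents must name exactly two cultivars")
    calls$parent_inconsistent <- FALSE
    ref_absent <- unique(calls$gene_id[calls$artifact_flag &
                                         calls$status == "absent"])
    for (g in ref_absent) {
      sub <- calls[calls$gene_id == g, ]
      par_status <- sub$status[match(parents, sub$cultivar)]
      if (all(!is.na(par_status)) && all(par_status == "present"))
        calls$parent_inconsistent[calls$gene_id == g &
                                    calls$cultivar == reference] <- TRUE
    }
  }
  calls
}

#' Summarize PAV calls cohort-wide
#'
#' Tabulates the final PAV gene list: total events (each absent or partial
#' gene-cultivar pair is one event), genes by number of affected cultivars,
#' per-cultivar event counts and their percentage of all events, and the PAV
#' fraction of the annotated gene complement.  The per-cultivar *average*
#' excludes reference-artifact events, which are reported separately.
#'
#' @param calls a `pav_calls` data.frame (after
#'   [flag_reference_artifacts()] if a reference is in play).
#' @param n_genes_total size of the annotated gene complement.
#' @return list of class `pav_summary`.
#' @export
summarize_pav <- function(calls, n_genes_total) {
  ev <- calls[calls$status %in% c("absent", "partial"), , drop = FALSE]
  n_events <- nrow(ev)
  genes <- unique(ev$gene_id)
  n_pav <- length(genes)
  per_gene <- table(ev$gene_id)
  hist <- table(factor(as.integer(per_gene)))
  hist <- stats::setNames(as.integer(hist), names(hist))
  per_cv <- table(ev$cultivar)
  per_cv <- stats::setNames(as.integer(per_cv), names(per_cv))
  pct_cv <- if (n_events > 0) round(100 * per_cv / n_events, 1) else per_cv
  n_artifact <- sum(ev$artifact_flag)
  non_ref_events <- n_events - n_artifact
  n_non_ref_cv <- length(setdiff(names(per_cv),
                                 unique(ev$cultivar[ev$artifact_flag])))
  out <- list(
    n_pav_genes = n_pav,
    pav_fraction_of_complement = if (n_genes_total > 0)
      round(100 * n_pav / n_genes_total, 1) else NA_real_,
    n_events = n_events,
    events_per_cultivar = per_cv,
    events_per_cultivar_pct = pct_cv,
    genes_by_n_absent_cultivars = hist,
    reference_artifact_events = n_artifact,
    mean_absent_per_cultivar = if (n_non_ref_cv > 0)
      non_ref_events / n_non_ref_cv else 0
  )
  stopifnot(sum(hist) == n_pav,
            sum(as.integer(names(hist)) * hist) == n_events)
  class(out) <- "pav_summary"
  out
}

#' @export
print.pav_summary <- function(x, ...) {
  cat(sprintf("PAV genes: %d (%.1f%% of complement), events: %d\n",
              x$n_pav_genes, x$pav_fraction_of_complement, x$n_events))
  cat("genes by number of affected cultivars:\n")
  print(x$genes_by_n_absent_cultivars)
  cat("events per cultivar:\n")
  print(x$events_per_cultivar)
  invisible(x)
}

#' Export absent-gene runs as BED
#'
#' Merges runs of consecutively absent genes per cultivar into regions and
#' writes them as BED (0-based half-open), one file-wide `name` column
#' `cultivar:first_gene-last_gene`.
#'
#' @param calls a `pav_calls` data.frame.
#' @param genes a [gene_table()].
#' @param path output BED file.
#' @export
write_pav_bed <- function(calls, genes, path) {
  ev <- calls[calls$status == "absent", , drop = FALSE]
  rows <- list()
  for (cv in unique(ev$cultivar)) {
    sub <- genes[genes$gene_id %in% ev$gene_id[ev$cultivar == cv], ,
                 drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(sub$scaffold, sub$rank), ]
    grp <- cumsum(c(TRUE, diff(sub$rank) != 1 |
                      sub$scaffold[-1] != sub$scaffold[-nrow(sub)]))
    for (g in split(seq_len(nrow(sub)), grp)) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = sub$scaffold[g[1]],
        start = min(sub$start[g]) - 1L,  # BED is 0-based half-open
        end = max(sub$end[g]),
        name = sprintf("%s:%s-%s", cv, sub$gene_id[g[1]],
                       sub$gene_id[g[length(g)]]),
        stringsAsFactors = FALSE)
    }
  }
  bed <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the full calling stage
#'
#' Convenience wrapper: both screens, low-support filter, merge, review,
#' artifact flagging.  Returns calls plus the per-stage accounting (how many
#' genes survived each screen/filter), which the pipeline log records.
#'
#' @param counts a [count_matrix()].
#' @param breadth a [breadth_matrix()] or `NULL`.
#' @param reference reference cultivar, or `NULL`.
#' @param parents optional two parental cultivars of the reference.
#' @param manual_additions see [merge_candidates()].
#' @param th a [pav_thresholds()].
#' @return list with `calls`, `summary`-ready inputs and `accounting`.
#' @export
call_pav <- function(counts, breadth = NULL, reference = NULL,
                     parents = NULL, manual_additions = NULL,
                     th = pav_thresholds()) {
  norm <- normalize_counts(counts)
  rset <- screen_ratio(norm, th)
  aset <- screen_absolute(counts, th)
  cand <- merge_candidates(rset, aset, manual_additions)
  flt <- filter_low_support(counts, cand$gene_id, th)
  cand <- cand[cand$gene_id %in% flt$retained, , drop = FALSE]
  calls <- assign_absences(cand, counts, norm, breadth, th)
  if (!is.null(reference))
    calls <- flag_reference_artifacts(calls, reference, parents)
  list(calls = calls,
       accounting = c(ratio_screen = length(rset),
                      absolute_screen = length(aset),
                      merged = length(unique(c(rset, aset))) +
                        sum(!cand$gene_id %in% c(rset, aset)),
                      low_support_discarded = length(flt$discarded),
                      reviewed_candidates = nrow(cand),
                      pav_genes = length(unique(calls$gene_id))))
}
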