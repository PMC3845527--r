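#' Pipeline configuration
#'
#' Validates and normalizes a configuration for [run_pipeline()]: input
#' paths, cultivar roles, thresholds and family/cluster parameters.  Accepts
#' a list or a YAML file path.  Validation happens before any stage runs:
#' referenced files must exist and the cultivar roles must match the count
#' matrix columns.
#'
#' @param config list or YAML path with elements: `counts` (TSV path,
#'   required), `gff3` (optional; needed for families/clusters), `breadth`,
#'   `hits`, `manual_additions`, `overrides` (optional paths); `reference`,
#'   `parents` (cultivar roles); `thresholds` (arguments to
#'   [pav_thresholds()]); `e_max`, `cov_min`, `max_intervening`; `out`
#'   (output directory); `seed`.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$counts)) stop("config needs a 'counts' TSV path")
  for (f in c("counts", "gff3", "breadth", "hits", "manual_additions",
              "overrides")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("configured ", f, " file does not exist: ", config[[f]])
  }
  cm <- load_count_table(config$counts)
  cvs <- colnames(cm$counts)
  for (role in c("reference", "parents")) {
    bad <- setdiff(config[[role]], cvs)
    if (length(bad))
      stop("configured ", role, " cultivar not in count matrix: ", bad[1])
  }
  config$thresholds <- do.call(pav_thresholds,
                               as.list(config$thresholds %||% list()))
  config$e_max <- config$e_max %||% 1e-20
  config$cov_min <- config$cov_min %||% 0.40
  config$max_intervening <- config$max_intervening %||% 8L
  config$out <- config$out %||% "melopav_run"
  config$seed <- config$seed %||% 1L
  class(config) <- c("pipeline_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full PAV analysis pipeline
#'
#' Executes counting input, PAV calling, family construction, tandem-cluster
#' detection and enrichment in order, writing versioned outputs into the run
#' directory: `calls.tsv`, `pav_regions.bed`, `families.tsv`,
#' `clusters.tsv`, a machine-readable `summary.json` holding every summary
#' and contingency field, a rendered `report.md`, and a `run.log` recording
#' each threshold used and the gene counts surviving each screen and filter.
#' Deterministic for fixed inputs and configuration.
#'
#' @param config a [pipeline_config()] (or list / YAML path coercible to
#'   one).
#' @return the run directory, invisibly; the parsed summary is attached as
#'   attribute `summary`.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out, "run.log")
  log <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                           append = TRUE)
  cat("", file = logf)
  th <- config$thresholds
  log("thresholds: %s", paste(names(th), unlist(th), sep = "=",
                              collapse = " "))

  stage <- "counts"
  res <- tryCatch({
    counts <- load_count_table(config$counts)
    breadth <- if (!is.null(config$breadth))
      load_breadth_table(config$breadth) else NULL

    stage <- "pav_calling"
    pav <- call_pav(counts, breadth, reference = config$reference,
                    parents = config$parents,
                    manual_additions = config$manual_additions, th = th)
    log("accounting: %s", paste(names(pav$accounting), pav$accounting,
                                sep = "=", collapse = " "))
    calls_df <- pav$calls
    class(calls_df) <- "data.frame"
    utils::write.table(calls_df, file.path(config$out, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    genes <- NULL
    fams <- NULL
    clusters <- NULL
    if (!is.null(config$gff3)) {
      stage <- "gene_table"
      genes <- read_gene_gff3(config$gff3)
      write_pav_bed(pav$calls, genes, file.path(config$out, "pav_regions.bed"))
    }
    if (!is.null(config$hits) && !is.null(genes)) {
      stage <- "gene_families"
      hits <- read_hits_table(config$hits)
      edges <- filter_hits(hits, genes, e_max = config$e_max,
                           cov_min = config$cov_min)
      fams <- build_families(edges, genes)
      write_families_table(fams, file.path(config$out, "families.tsv"))
      log("families: %d families, %d singletons",
          length(unique(fams$families$family_id)), length(fams$singletons))

      stage <- "tandem_clusters"
      clusters <- detect_clusters(fams$families, genes,
                                  max_intervening = config$max_intervening)
      if (!is.null(config$overrides))
        clusters <- override_membership(clusters, config$overrides,
                                        fams$families, genes)
      write_clusters_table(clusters, genes,
                           file.path(config$out, "clusters.tsv"),
                           file.path(config$out, "clusters.bed"))
    }

    stage <- "summary"
    n_universe <- if (!is.null(genes)) nrow(genes) else nrow(counts$counts)
    summ <- summarize_pav(pav$calls, n_universe)

    enr <- list()
    if (!is.null(fams)) {
      stage <- "enrichment"
      universe <- if (!is.null(genes)) genes$gene_id else
        rownames(counts$counts)
      pav_genes <- unique(pav$calls$gene_id[
        pav$calls$status %in% c("absent", "partial") &
          !pav$calls$artifact_flag])
      enr$multicopy <- crosstab(pav_genes, fams$families$gene_id, universe)
      if (!is.null(clusters) && nrow(clusters))
        enr$clustered <- crosstab(pav_genes, unique(clusters$gene_id),
                                  universe)
    }

    summary_json <- list(
      n_genes = n_universe,
      accounting = as.list(pav$accounting),
      pav = unclass(summ),
      families = if (!is.null(fams))
        family_size_distribution(fams$families, n_universe) else NULL,
      clusters = if (!is.null(clusters))
        cluster_size_distribution(clusters) else NULL,
      enrichment = lapply(enr, function(e) {
        list(table = as.vector(e$table), chi2 = e$chi2, p_value = e$p_value,
             pct_attr_in_pav = e$pct_attr_in_pav,
             pct_attr_in_nonpav = e$pct_attr_in_nonpav,
             pct_pav_in_attr = e$pct_pav_in_attr,
             pct_pav_in_nonattr = e$pct_pav_in_nonattr,
             rate_ratio = e$rate_ratio)
      }))
    jsonlite::write_json(summary_json,
                         file.path(config$out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(render_report(summary_json),
               file.path(config$out, "report.md"))
    log("done")
    summary_json
  }, error = function(e) {
    log("FAILED at stage '%s': %s", stage, conditionMessage(e))
    writeLines("incomplete", file.path(config$out, "INCOMPLETE"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  out <- config$out
  attr(out, "summary") <- res
  invisible(out)
}

#' Render a summary as a markdown report
#'
#' Tabulates the analysis summaries — PAV fraction, absence histogram,
#' per-cultivar shares, family and cluster size tables, enrichment tests —
#' purely from the fields of the summary list; nothing is recomputed at
#' render time.
#'
#' @param summary summary list as written by [run_pipeline()] (or read back
#'   from its `summary.json`).
#' @return character vector of markdown lines.
#' @export
render_report <- function(summary) {
  s <- summary
  ln <- c("# PAV analysis report", "")
  p <- s$pav
  ln <- c(ln, sprintf("Annotated genes: %d", s$n_genes),
          sprintf("PAV genes: %d (%.1f%% of the complement); events: %d",
                  p$n_pav_genes,
                  ifelse(is.null(p$pav_fraction_of_complement) ||
                           is.na(p$pav_fraction_of_complement), 0,
                         p$pav_fraction_of_complement),
                  p$n_events), "")
  if (length(p$genes_by_n_absent_cultivars)) {
    ln <- c(ln, "## Genes by number of affected cultivars", "",
            "| cultivars | genes |", "|---|---|",
            sprintf("| %s | %d |", names(p$genes_by_n_absent_cultivars),
                    unlist(p$genes_by_n_absent_cultivars)), "")
  }
  if (length(p$events_per_cultivar)) {
    ln <- c(ln, "## Events per cultivar", "",
            "| cultivar | events | % of events |", "|---|---|---|",
            sprintf("| %s | %d | %.1f |", names(p$events_per_cultivar),
                    unlist(p$events_per_cultivar),
                    unlist(p$events_per_cultivar_pct)), "")
  }
  if (!is.null(s$families) && length(s$families$table) &&
      NROW(s$families$table)) {
    tb <- as.data.frame(s$families$table)
    ln <- c(ln, "## Family sizes", "",
            sprintf("%d families, %d multi-copy genes, singleton fraction %.1f%%",
                    s$families$n_families, s$families$n_multicopy_genes,
                    s$families$singleton_fraction_pct), "",
            "| size | families | % |", "|---|---|---|",
            sprintf("| %d | %d | %d |", tb$size, tb$n_families,
                    tb$pct_families), "")
  }
  if (!is.null(s$clusters) && length(s$clusters$table) &&
      NROW(s$clusters$table)) {
    tb <- as.data.frame(s$clusters$table)
    ln <- c(ln, "## Tandem clusters", "",
            sprintf("%d clusters over %d genes; longest has %d members",
                    s$clusters$n_clusters, s$clusters$n_clustered_genes,
                    s$clusters$longest), "",
            "| size | clusters | % |", "|---|---|---|",
            sprintf("| %d | %d | %d |", tb$size, tb$n_clusters,
                    tb$pct_clusters), "")
  }
  for (nm in names(s$enrichment)) {
    e <- s$enrichment[[nm]]
    ln <- c(ln, sprintf("## Enrichment: %s", nm), "",
            sprintf("chi2 = %.1f (df = 1), p %s", e$chi2,
                    format.pval(e$p_value, eps = 1e-4)),
            sprintf("%s share: %.1f%% of PAV vs %.1f%% of non-PAV genes",
                    nm, e$pct_attr_in_pav, e$pct_attr_in_nonpav),
            sprintf("PAV rate: %.1f%% in %s vs %.1f%% elsewhere (ratio %.2f)",
                    e$pct_pav_in_attr, nm, e$pct_pav_in_nonattr,
                    e$rate_ratio), "")
  }
  ln
}
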