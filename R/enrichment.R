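#' Chi-square test of a 2x2 table
#'
#' The df = 1 statistic in closed form,
#' `N * (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the `N/2`
#' continuity term (Yates) dropped when `yates = FALSE`; the p-value is the
#' upper tail of the chi-square distribution with one degree of freedom.
#' Continuity correction is on by default, which is the convention this
#' analysis reports.
#'
#' @param table 2x2 matrix of non-negative counts (rows: attribute +/-,
#'   columns: PAV +/-).
#' @param yates apply the continuity correction (default `TRUE`).
#' @return list with `chi2`, `p_value` and `df = 1`.
#' @export
chisq_2x2 <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  storage.mode(table) <- "double"   # genome-scale margins overflow integers
  if (any(table < 0)) stop("cell counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-square undefined: a table margin is zero")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (yates) num <- max(num - n / 2, 0)
  chi2 <- n * num^2 / (sum(table[1, ]) * sum(table[2, ]) *
                         sum(table[, 1]) * sum(table[, 2]))
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Cross-tabulate PAV status against a gene attribute
#'
#' Builds the 2x2 table (attribute +/- by PAV +/-) over a gene universe by
#' set intersection and reports the chi-square statistic, the attribute rate
#' within the PAV and non-PAV columns, the PAV rate within the attribute
#' rows, and their ratio (e.g. "multi-copy genes are five times more likely
#' to be affected").  Percentages are rounded half-up to one decimal.
#'
#' @param pav_genes character vector of PAV gene ids.
#' @param attribute_genes character vector of attribute-positive gene ids
#'   (e.g. multi-copy or clustered genes).
#' @param universe character vector of all annotated genes.
#' @param yates continuity correction for the chi-square.
#' @return list of class `contingency_result`.
#' @export
crosstab <- function(pav_genes, attribute_genes, universe, yates = TRUE) {
  out1 <- setdiff(pav_genes, universe)
  if (length(out1)) stop("PAV gene outside the universe: ", out1[1])
  out2 <- setdiff(attribute_genes, universe)
  if (length(out2)) stop("attribute gene outside the universe: ", out2[1])
  pav <- unique(pav_genes); attr_g <- unique(attribute_genes)
  n <- length(unique(universe))
  a <- length(intersect(attr_g, pav))            # attr+, PAV+
  b <- length(setdiff(attr_g, pav))              # attr+, PAV-
  c <- length(setdiff(pav, attr_g))              # attr-, PAV+
  d <- n - a - b - c                             # attr-, PAV-
  tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE,
                dimnames = list(attribute = c("yes", "no"),
                                pav = c("yes", "no")))
  chi <- chisq_2x2(tab, yates = yates)
  rate_attr_pos <- a / (a + b)   # PAV rate among attribute+
  rate_attr_neg <- c / (c + d)   # PAV rate among attribute-
  res <- list(
    table = tab,
    chi2 = chi$chi2, p_value = chi$p_value, df = 1L,
    pct_attr_in_pav = round_half_up(100 * a / (a + c), 1),
    pct_attr_in_nonpav = round_half_up(100 * b / (b + d), 1),
    pct_pav_in_attr = round_half_up(100 * rate_attr_pos, 1),
    pct_pav_in_nonattr = round_half_up(100 * rate_attr_neg, 1),
    rate_ratio = if (rate_attr_neg > 0) rate_attr_pos / rate_attr_neg
                 else Inf)
  class(res) <- "contingency_result"
  res
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi2 = %.1f (df = 1), p %s\n", x$chi2,
              format.pval(x$p_value, eps = 1e-4)))
  cat(sprintf("attribute share: %.1f%% of PAV vs %.1f%% of non-PAV genes\n",
              x$pct_attr_in_pav, x$pct_attr_in_nonpav))
  cat(sprintf("PAV rate: %.1f%% in attribute+ vs %.1f%% in attribute- (ratio %.1f)\n",
              x$pct_pav_in_attr, x$pct_pav_in_nonattr, x$rate_ratio))
  invisible(x)
}

# round half away from zero, the convention of the reported percentages
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Overlap of the PAV set with an external gene list
#'
#' `|PAV intersect list| / |list|`, as a percentage — a generic utility for
#' curated lists (e.g. lineage-specific expanded families).
#'
#' @param pav_genes,external_list character vectors of gene ids.
#' @return percentage (one decimal).
#' @export
overlap_report <- function(pav_genes, external_list) {
  if (!length(external_list)) return(NA_real_)
  round_half_up(100 * length(intersect(unique(pav_genes),
                                       unique(external_list))) /
                  length(unique(external_list)), 1)
}

#' Tabulate a PCR validation table into a confirmation rate
#'
#' Given per-amplicon validation records (gene, variety, partial/full,
#' comment), counts distinct genes tested, treats any gene whose comment
#' marks a false PAV as unconfirmed, and returns the confirmation
#' percentage.
#'
#' @param records data.frame with at least `gene` and `comment` columns, as
#'   loaded by [load_validation_records()].
#' @return list with `n_tested`, `n_false`, `confirmation_pct`.
#' @export
validation_tabulation <- function(records) {
  genes <- unique(records$gene)
  false_genes <- unique(records$gene[grepl("false pav", records$comment,
                                           ignore.case = TRUE)])
  n <- length(genes)
  nf <- length(false_genes)
  list(n_tested = n, n_false = nf,
       confirmation_pct = round_half_up(100 * (n - nf) / n))
}

#' Load packaged PCR-validation records
#'
#' The package ships a transcription of the published PCR validation of
#' candidate PAV regions (40 genes amplified across cultivars with primers
#' flanking each candidate region) as a plain TSV with columns `gene`,
#' `kind` (p/f), `variety` and `comment`.
#'
#' @param path TSV file; default the packaged table.
#' @return data.frame of validation records.
#' @export
load_validation_records <- function(path = system.file(
    "extdata", "pcr_validation_records.tsv", package = "melopav")) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
}
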