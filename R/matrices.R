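#' Count and breadth matrices
#'
#' A `count_matrix` bundles a genes x cultivars matrix of raw mapped-read
#' counts with the per-cultivar library sizes (total reads mapped anywhere on
#' the reference) used for cross-cultivar normalization.  A `breadth_matrix`
#' holds, for the same genes and cultivars, the fraction of gene bases covered
#' by at least one qualifying read; it is optional and only needed to separate
#' partial from full absence.
#'
#' @param x numeric matrix, genes in rows (rownames = gene ids), cultivars in
#'   columns (colnames = cultivar names).
#' @param library_sizes named numeric vector, one positive total per cultivar.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `library_sizes`.
#' @export
count_matrix <- function(x, library_sizes) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count matrix needs gene rownames and cultivar colnames")
  if (anyNA(x) || any(x < 0))
    stop("counts must be non-negative and complete")
  if (all(x == floor(x)) && max(x) < .Machine$integer.max)
    storage.mode(x) <- "integer"
  library_sizes <- as.numeric(library_sizes)[match(colnames(x),
                                                   names(library_sizes))]
  names(library_sizes) <- colnames(x)
  if (anyNA(library_sizes) || any(library_sizes <= 0))
    stop("every cultivar needs a positive library size")
  bad <- colnames(x)[apply(x, 2, max) > library_sizes]
  if (length(bad))
    stop("library size smaller than a per-gene count for: ",
         paste(bad, collapse = ", "))
  structure(list(counts = x, library_sizes = library_sizes),
            class = "count_matrix")
}

#' @rdname count_matrix
#' @export
breadth_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("breadth matrix needs gene rownames and cultivar colnames")
  if (anyNA(x) || any(x < 0) || any(x > 1))
    stop("breadth values must lie in [0, 1]")
  structure(list(breadth = x), class = "breadth_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cultivars\n",
              nrow(x$counts), ncol(x$counts)))
  cat("library sizes:",
      paste(sprintf("%s=%s", names(x$library_sizes),
                    format(x$library_sizes, big.mark = ",")), collapse = "  "),
      "\n")
  invisible(x)
}

#' Normalize counts by library size
#'
#' Rescales every cultivar's per-gene counts by its total mapped reads so that
#' cross-cultivar ratios reflect copy differences rather than sequencing
#' depth: `norm(g, c) = count(g, c) * scale / library_size(c)`.  The default
#' scale is counts-per-10-million; all pairwise ratios between cultivars are
#' invariant to this choice.  Zeros are preserved exactly.
#'
#' @param counts a [count_matrix()].
#' @param scale scaling constant (reads), default 1e7.
#' @return An object of class `normalized_matrix`: list with the normalized
#'   `norm` matrix, the `library_sizes` it was computed from, and `scale`.
#' @export
normalize_counts <- function(counts, scale = 1e7) {
  stopifnot(inherits(counts, "count_matrix"))
  if (any(counts$library_sizes <= 0)) stop("library sizes must be positive")
  norm <- sweep(counts$counts, 2, counts$library_sizes / scale, "/")
  structure(list(norm = norm,
                 library_sizes = counts$library_sizes,
                 scale = scale),
            class = "normalized_matrix")
}

# TSV dialect shared by the writers and loaders: gene_id column, one column
# per cultivar, header row, and a final "__library_size__" row for counts.
LIBSIZE_ROW <- "__library_size__"

#' Write / read count and breadth tables
#'
#' Plain TSV with a `gene_id` column and one column per cultivar.  Count
#' tables carry a final `__library_size__` row holding each cultivar's total
#' mapped reads.  Numbers are written with full precision so write/read
#' round-trips are exact; columns are matched by cultivar name, not position.
#'
#' @param counts a [count_matrix()]; `breadth` a [breadth_matrix()].
#' @param path TSV file.
#' @return the path (writers, invisibly) or the loaded object (loaders).
#' @export
write_count_table <- function(counts, path) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- rbind(counts$counts,
             matrix(counts$library_sizes, nrow = 1,
                    dimnames = list(LIBSIZE_ROW, colnames(counts$counts))))
  write_num_tsv(m, path)
}

#' @rdname write_count_table
#' @export
write_breadth_table <- function(breadth, path) {
  stopifnot(inherits(breadth, "breadth_matrix"))
  write_num_tsv(breadth$breadth, path)
}

#' @rdname write_count_table
#' @export
load_count_table <- function(path) {
  m <- read_num_tsv(path)
  if (!(LIBSIZE_ROW %in% rownames(m)))
    stop("count table has no '", LIBSIZE_ROW, "' row: ", path)
  lib <- stats::setNames(as.numeric(m[LIBSIZE_ROW, , drop = FALSE]),
                         colnames(m))
  counts <- m[setdiff(rownames(m), LIBSIZE_ROW), , drop = FALSE]
  count_matrix(counts, lib)
}

#' @rdname write_count_table
#' @export
load_breadth_table <- function(path) {
  m <- read_num_tsv(path)
  m <- m[setdiff(rownames(m), LIBSIZE_ROW), , drop = FALSE]
  breadth_matrix(m)
}

#' @keywords internal
write_num_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m),
                   apply(m, 2, function(col) sprintf("%.17g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  # integers render without exponent under %.17g, fractions keep full precision
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
read_num_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id: ", path)
  ids <- df$gene_id
  vals <- df[, -1, drop = FALSE]
  m <- vapply(vals, function(col) {
    x <- suppressWarnings(as.numeric(col))
    x
  }, numeric(nrow(df)))
  m <- matrix(m, nrow = nrow(df),
              dimnames = list(ids, names(vals)))
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing cell at row '%s', column '%s' in %s",
                 ids[idx[1]], names(vals)[idx[2]], path))
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative cell at row '%s', column '%s' in %s",
                 ids[idx[1]], colnames(m)[idx[2]], path))
  }
  m
}
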