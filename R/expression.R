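#' Read a gene expression matrix from delimited text
#'
#' Expression data are genes (or probes) x samples: the first column holds
#' gene/probe identifiers, the header row holds sample identifiers, and all
#' remaining cells are raw, platform-native, non-negative expression values.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator; tab by default, use \code{","} for CSV.
#' @param transpose If \code{TRUE} the file stores samples as rows and is
#'   transposed after reading. Orientation is never auto-detected.
#' @return A numeric matrix (genes x samples) with gene identifiers as row
#'   names and sample identifiers as column names. Row names may contain
#'   duplicates only when a probe-level matrix is to be collapsed with
#'   \code{\link{collapse_probes}}; column names must be unique.
#' @seealso \code{\link{write_expression}}, \code{\link{collapse_probes}}
#' @export
read_expression <- function(path, sep = "\t", transpose = FALSE) {
  raw <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2L)
    stop("malformed expression file '", path, "': need an id column plus at least one sample column")
  ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  vals <- suppressWarnings(vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  vals <- matrix(as.numeric(vals), nrow = nrow(raw), ncol = length(sample_ids),
                 dimnames = list(ids, sample_ids))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric or missing cell at gene '", ids[bad[1L, 1L]],
         "', sample '", sample_ids[bad[1L, 2L]], "' in '", path, "'")
  if (transpose) vals <- t(vals)
  validate_expression(vals, where = path)
  vals
}

validate_expression <- function(values, where = "expression matrix") {
  if (!is.matrix(values) || !is.numeric(values))
    stop(where, ": expression data must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop(where, ": gene and sample identifiers are required as dimnames")
  if (anyDuplicated(colnames(values)))
    stop(where, ": duplicated sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  neg <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(where, ": negative or non-finite value at gene '",
         rownames(values)[neg[1L, 1L]], "', sample '",
         colnames(values)[neg[1L, 2L]], "'")
  invisible(values)
}

#' Write an expression matrix as delimited text
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param path Output file path.
#' @param sep Field separator (tab by default).
#' @export
write_expression <- function(expr, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' Two delimited columns: probe identifier, gene identifier. Every probe must
#' map to exactly one gene (many probes may map to the same gene).
#'
#' @param path Path to the table (with a header row).
#' @param sep Field separator.
#' @return A data.frame with columns \code{probe_id} and \code{gene_id}.
#' @export
read_probe_map <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("probe map '", path, "' needs two columns (probe_id, gene_id)")
  map <- data.frame(probe_id = df[[1L]], gene_id = df[[2L]], stringsAsFactors = FALSE)
  if (anyDuplicated(map$probe_id))
    stop("probe map '", path, "': probes mapping to more than one gene: ",
         paste(unique(map$probe_id[duplicated(map$probe_id)]), collapse = ", "))
  map
}

#' Collapse a probe-level matrix to one row per gene
#'
#' When several probes measure the same gene, one representative probe is kept
#' per gene. Two conventions are supported. \code{"iqr"} keeps the probe with
#' the largest interquartile range across the cohort and is appropriate for
#' cohort-level rank-sum analysis (\code{\link{roi}}). \code{"max"} keeps the
#' probe with the highest raw expression and is single-sample-safe, as required
#' by the absolute classifier: on a one-column matrix it uses that profile's
#' own values and never consults any other sample; on a multi-column matrix it
#' uses the probe's mean raw expression across the matrix.
#'
#' @param expr Probe-level matrix (probes x samples; row names are probe ids).
#' @param map Probe map as returned by \code{\link{read_probe_map}}, or any
#'   data.frame with columns \code{probe_id} and \code{gene_id}.
#' @param mode \code{"iqr"} or \code{"max"} (see above).
#' @return Gene-level matrix, one row per mapped gene, rows sorted by gene id.
#'   Ties (equal IQR or equal expression) keep the lexicographically smallest
#'   probe id so results are deterministic.
#' @export
collapse_probes <- function(expr, map, mode = c("iqr", "max")) {
  mode <- match.arg(mode)
  validate_expression(expr, where = "collapse_probes input")
  probes <- rownames(expr)
  hit <- match(probes, map$probe_id)
  unmapped <- sum(is.na(hit))
  if (unmapped > 0L)
    message("collapse_probes: skipping ", unmapped, " unmapped probe(s)")
  keep <- !is.na(hit)
  if (!any(keep)) stop("collapse_probes: no probe maps to a gene")
  expr <- expr[keep, , drop = FALSE]
  genes <- map$gene_id[hit[keep]]

  stat <- switch(mode,
    iqr = apply(expr, 1L, stats::IQR),
    max = if (ncol(expr) == 1L) expr[, 1L] else rowMeans(expr))
  # deterministic winner: best statistic, ties to smallest probe id
  ord <- order(genes, -stat, rownames(expr), method = "radix")
  first <- !duplicated(genes[ord])
  sel <- ord[first]
  out <- expr[sel, , drop = FALSE]
  rownames(out) <- genes[sel]
  out
}

#' Restrict a set of expression matrices to their shared gene universe
#'
#' Multi-dataset training must operate on the gene identifiers present on all
#' platforms. This is applied explicitly by the caller, never implicitly.
#'
#' @param datasets A list of gene-level expression matrices.
#' @return The list with every matrix restricted to the common genes, in a
#'   common (sorted) row order.
#' @export
intersect_genes <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  shared <- Reduce(intersect, lapply(datasets, rownames))
  if (length(shared) == 0L) stop("intersect_genes: no genes shared by all datasets")
  shared <- sort(shared)
  lapply(datasets, function(m) m[shared, , drop = FALSE])
}

#' Randomly permute the gene labels of an expression matrix
#'
#' Row vectors are left untouched; only the gene identifiers are shuffled.
#' Applied to a whole dataset this breaks gene-gene correlation within every
#' signature and is the negative control used by \code{\link{winnow}}.
#'
#' @param expr Expression matrix.
#' @param seed Optional integer seed for reproducibility.
#' @return The matrix with permuted row names.
#' @export
permute_gene_labels <- function(expr, seed = NULL) {
  perm <- with_seed(seed, sample.int(nrow(expr)))
  rownames(expr) <- rownames(expr)[perm]
  expr
}
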