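#' Construct a directed gene signature
#'
#' A gene signature is a named set of genes marking the activation of a
#' biological process, partitioned into an up-regulated subset (expression
#' rises with activation) and a down-regulated subset (expression falls).
#' Undirected signatures place every gene in the up subset: all genes then
#' order samples in the same direction, which is how undirected collections
#' are treated throughout.
#'
#' @param signature_id Signature name.
#' @param up Character vector of up-regulated gene ids.
#' @param down Character vector of down-regulated gene ids.
#' @param source Free-text provenance (e.g. the collection the set came from).
#' @return An object of class \code{gene_signature} with elements
#'   \code{signature_id}, \code{source}, \code{up}, \code{down}.
#' @export
gene_signature <- function(signature_id, up, down = character(), source = "") {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(up) + length(down) == 0L)
    stop("gene_signature '", signature_id, "': empty gene set")
  both <- intersect(up, down)
  if (length(both) > 0L)
    stop("gene_signature '", signature_id, "': genes in both directions: ",
         paste(both, collapse = ", "))
  structure(list(signature_id = as.character(signature_id),
                 source = as.character(source), up = up, down = down),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature '", x$signature_id, "': ", length(x$up), " up, ",
      length(x$down), " down gene(s)\n", sep = "")
  invisible(x)
}

signature_genes <- function(sig) c(sig$up, sig$down)

#' Read gene signatures from a GMT file
#'
#' Standard GMT: one signature per line, fields \code{name}, \code{description},
#' then one gene id per field. Directionality can be encoded two ways:
#' \itemize{
#'   \item the \code{"_UP"}/\code{"_DN"} suffix convention: two lines sharing a
#'     stem (e.g. \code{SIGA_UP}, \code{SIGA_DN}) are merged into one directed
#'     signature named by the stem;
#'   \item an optional sidecar table (\code{direction_file}) with two columns,
#'     gene id and direction (\code{up}/\code{down}), moving listed genes of
#'     every signature into the stated subset.
#' }
#' Genes with no direction information default to up.
#'
#' @param path Path to the GMT file.
#' @param direction_file Optional path to a two-column (gene, direction)
#'   delimited table with a header row.
#' @return A named list of \code{\link{gene_signature}} objects.
#' @export
read_gmt <- function(path, direction_file = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  down_genes <- character()
  if (!is.null(direction_file)) {
    dd <- utils::read.delim(direction_file, header = TRUE, stringsAsFactors = FALSE)
    if (ncol(dd) < 2L) stop("direction file '", direction_file, "' needs two columns")
    down_genes <- as.character(dd[[1L]][tolower(dd[[2L]]) %in% c("down", "dn")])
  }
  parsed <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, " in '", path, "': fewer than 3 fields")
    list(name = f[[1L]], source = f[[2L]], genes = unique(f[-(1:2)]))
  })
  names(parsed) <- vapply(parsed, `[[`, "", "name")

  stems <- sub("_(UP|DN)$", "", names(parsed))
  sigs <- list()
  for (stem in unique(stems)) {
    members <- parsed[stems == stem]
    up <- character(); down <- character(); src <- members[[1L]]$source
    for (m in members) {
      if (grepl("_DN$", m$name)) down <- union(down, m$genes)
      else up <- union(up, m$genes)
    }
    if (length(down_genes) > 0L) {
      move <- intersect(up, down_genes)
      up <- setdiff(up, move); down <- union(down, move)
    }
    sigs[[stem]] <- gene_signature(stem, up = up, down = down, source = src)
  }
  sigs
}

#' Write gene signatures to a GMT file
#'
#' Directed signatures are written as an \code{_UP}/\code{_DN} line pair so the
#' file round-trips through \code{\link{read_gmt}}.
#'
#' @param signatures A list of \code{\link{gene_signature}} objects.
#' @param path Output path.
#' @export
write_gmt <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- unlist(lapply(signatures, function(s) {
    src <- if (nzchar(s$source)) s$source else "sigact"
    if (length(s$down) == 0L)
      paste(c(s$signature_id, src, s$up), collapse = "\t")
    else {
      out <- paste(c(paste0(s$signature_id, "_DN"), src, s$down), collapse = "\t")
      if (length(s$up) > 0L)
        out <- c(paste(c(paste0(s$signature_id, "_UP"), src, s$up), collapse = "\t"), out)
      out
    }
  }))
  writeLines(lines, path)
  invisible(path)
}
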