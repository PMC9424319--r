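#' Construct a gene signature
#'
#' An ordered, duplicate-free list of gene identifiers with a name.
#' Identifiers are matched case-sensitively after whitespace stripping.
#'
#' @param genes Character vector of gene ids (non-empty, no duplicates).
#' @param name Signature name.
#' @return Object of class `GeneSignature` with fields `name` and `genes`.
#' @export
gene_signature <- function(genes, name = "signature") {
  if (!is.character(genes))
    stop("`genes` must be a character vector", call. = FALSE)
  genes <- trimws(genes)
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0)
    stop("signature must contain at least one gene", call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate genes in signature: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  structure(list(name = as.character(name)[1], genes = genes),
            class = "GeneSignature")
}

as_gene_signature <- function(x, name = "signature") {
  if (inherits(x, "GeneSignature")) x else gene_signature(x, name)
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s' (%d genes): %s\n", x$name, length(x$genes),
              paste(x$genes, collapse = ", ")))
  invisible(x)
}

#' @export
length.GeneSignature <- function(x) length(x$genes)

#' Read a signature file (one gene per line)
#'
#' @param path Path to a plain-text file, one gene identifier per line.
#' @param name Signature name; defaults to the file name without extension.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  genes <- readLines(path, warn = FALSE)
  gene_signature(genes, name)
}

#' The packaged nine-gene epithelial-tumor signature (ET-9)
#'
#' The nine-gene breast-cancer prognostic signature distributed with the
#' package: seven genes selected jointly by single-gene-removal refinement
#' and k-top-scoring-pairs analysis (CCDC69, CX3CL1, GDPD5, IGFBP5, CACNG4,
#' FIBCD1, MAP6) plus two single-marker genes (SUSD2, ADGRG1).
#'
#' @return A [gene_signature()] named "ET-9".
#' @export
et9_signature <- function() {
  path <- system.file("extdata", "et9_signature.txt", package = "sigforge",
                      mustWork = TRUE)
  read_signature(path, name = "ET-9")
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: each line holds a set name, a description,
#' and one or more member genes. Duplicate genes within a set are collapsed
#' (first occurrence kept); set order is preserved.
#'
#' @param path Path to the GMT file.
#' @return Object of class `GeneSetCollection`: list with element `sets`, a
#'   list of `list(name, description, genes)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description and at least one gene",
                   i, length(fields)), call. = FALSE)
    genes <- unique(trimws(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0)
      stop(sprintf("GMT line %d has no gene members", i), call. = FALSE)
    sets[[i]] <- list(name = trimws(fields[1]), description = fields[2],
                      genes = genes)
  }
  gene_set_collection(sets)
}

#' Construct a gene-set collection
#'
#' @param sets List of `list(name, description, genes)` entries; names must
#'   be unique and every set non-empty.
#' @return Object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets) {
  if (length(sets) == 0)
    stop("collection must contain at least one gene set", call. = FALSE)
  nms <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate set names in collection: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  sizes <- vapply(sets, function(s) length(s$genes), integer(1))
  if (any(sizes == 0))
    stop("empty gene set(s): ", paste(nms[sizes == 0], collapse = ", "),
         call. = FALSE)
  structure(list(sets = sets), class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, median size %d\n",
              length(x$sets),
              as.integer(stats::median(vapply(x$sets, function(s)
                length(s$genes), integer(1))))))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)
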