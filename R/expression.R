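#' Construct an expression matrix
#'
#' A gene-by-sample matrix of continuous expression values (arbitrary units
#' or z-scores) with unique gene and sample identifiers and a per-sample
#' flag marking the reference ("diploid") panel used for z-scoring.
#'
#' @param values Numeric matrix, genes in rows (row names = gene ids),
#'   samples in columns (column names = sample ids). Missing values are
#'   rejected, not imputed.
#' @param is_reference Logical vector of length `ncol(values)` flagging
#'   reference samples. Defaults to all `FALSE`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `is_reference`.
#' @export
expression_matrix <- function(values, is_reference = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("`values` must have gene row names and sample column names", call. = FALSE)
  gene_ids <- trimws(gene_ids)
  sample_ids <- trimws(sample_ids)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("missing or non-finite expression values are not allowed", call. = FALSE)
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  if (is.null(is_reference)) is_reference <- rep(FALSE, ncol(values))
  if (!is.logical(is_reference) || length(is_reference) != ncol(values) ||
      anyNA(is_reference))
    stop("`is_reference` must be a logical vector with one flag per sample",
         call. = FALSE)
  names(is_reference) <- sample_ids
  structure(list(values = values, is_reference = is_reference),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d reference)\n",
              nrow(x$values), ncol(x$values), sum(x$is_reference)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

as_values_matrix <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected an ExpressionMatrix or a numeric matrix", call. = FALSE)
}

#' Read an expression TSV
#'
#' Expects a tab-separated file with one header row of sample identifiers,
#' a first column of gene identifiers, and a fully numeric body.
#'
#' @param path Path to the TSV file.
#' @param reference_ids Optional character vector of sample ids to flag as
#'   the reference ("diploid") panel; must all be present in the header.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, reference_ids = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2)
    stop("expression file needs a gene id column plus at least one sample column",
         call. = FALSE)
  genes <- trimws(raw[[1]])
  samples <- trimws(colnames(raw)[-1])
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  body <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                 genes[bad[1, 1]], samples[bad[1, 2]]), call. = FALSE)
  rownames(vals) <- genes
  colnames(vals) <- samples
  is_ref <- rep(FALSE, length(samples))
  if (!is.null(reference_ids)) {
    reference_ids <- trimws(reference_ids)
    missing <- setdiff(reference_ids, samples)
    if (length(missing) > 0)
      stop("reference sample(s) not found in header: ",
           paste(missing, collapse = ", "), call. = FALSE)
    is_ref <- samples %in% reference_ids
  }
  expression_matrix(vals, is_ref)
}

#' Write an expression matrix as TSV
#'
#' @param x An `ExpressionMatrix` or numeric matrix.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  vals <- as_values_matrix(x)
  df <- data.frame(gene_id = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Z-score tumor samples against the reference panel
#'
#' For every gene g and non-reference sample s computes
#' z_gs = (x_gs - mean_ref(g)) / sd_ref(g), where mean and sd are taken over
#' the reference ("diploid") samples and sd uses the n-1 denominator.
#' Reference samples are dropped from the output.
#'
#' @param m An [expression_matrix()] with at least two reference samples.
#' @return An `ExpressionMatrix` of z-scores over the non-reference samples.
#' @export
zscore_vs_reference <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  n_ref <- sum(m$is_reference)
  if (n_ref < 2)
    stop("at least 2 reference samples are required for z-scoring", call. = FALSE)
  if (all(m$is_reference))
    stop("no non-reference samples to z-score", call. = FALSE)
  ref <- m$values[, m$is_reference, drop = FALSE]
  mu <- rowMeans(ref)
  sd_ref <- apply(ref, 1, stats::sd)
  degenerate <- sd_ref == 0
  if (any(degenerate))
    stop("zero reference standard deviation for gene(s): ",
         paste(rownames(ref)[degenerate], collapse = ", "), call. = FALSE)
  tum <- m$values[, !m$is_reference, drop = FALSE]
  z <- (tum - mu) / sd_ref
  expression_matrix(z)
}

#' Call binary alterations from z-scores
#'
#' A gene is called altered in a sample when |z| strictly exceeds the
#' threshold; z-scores between -threshold and +threshold inclusive are
#' non-altered.
#'
#' @param z An `ExpressionMatrix` of z-scores (see [zscore_vs_reference()]).
#' @param threshold Positive real; default 2.
#' @return An `AlterationMatrix`: list with binary `calls` matrix (1 =
#'   altered) and the `threshold` used.
#' @export
call_alterations <- function(z, threshold = 2) {
  vals <- as_values_matrix(z)
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0)
    stop("`threshold` must be a single positive number", call. = FALSE)
  calls <- (abs(vals) > threshold) * 1L
  storage.mode(calls) <- "integer"
  structure(list(calls = calls, threshold = threshold),
            class = "AlterationMatrix")
}

#' @export
print.AlterationMatrix <- function(x, ...) {
  cat(sprintf("AlterationMatrix: %d genes x %d samples, |z| > %g; %.1f%% altered calls\n",
              nrow(x$calls), ncol(x$calls), x$threshold, 100 * mean(x$calls)))
  invisible(x)
}

#' Per-sample signature alteration status
#'
#' A sample is signature-altered (status 1) when at least one signature gene
#' is altered in that sample — the altered/unaltered cohort convention used
#' by cBioPortal-style survival comparisons.
#'
#' @param a An `AlterationMatrix`.
#' @param sig A [gene_signature()] or character vector of gene ids; all must
#'   be present in `a`.
#' @return Named integer vector of 0/1 per sample.
#' @export
signature_status <- function(a, sig) {
  stopifnot(inherits(a, "AlterationMatrix"))
  sig <- as_gene_signature(sig)
  missing <- setdiff(sig$genes, rownames(a$calls))
  if (length(missing) > 0)
    stop("signature gene(s) not in alteration matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  status <- as.integer(colSums(a$calls[sig$genes, , drop = FALSE]) > 0)
  names(status) <- colnames(a$calls)
  status
}
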