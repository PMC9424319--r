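#' Single-gene survival significance
#'
#' For each gene, compares altered vs non-altered samples with a log-rank
#' test and a univariate Cox fit. Genes altered in none or all samples are
#' flagged untestable rather than dropped.
#'
#' @param a An `AlterationMatrix`.
#' @param clin A [clinical_table()] covering every sample in `a`.
#' @param genes Genes to test (default: all genes in `a`).
#' @return Data frame with columns `gene`, `n_altered`, `logrank_p`, `hr`,
#'   `untestable`.
#' @export
single_gene_significance <- function(a, clin, genes = NULL) {
  stopifnot(inherits(a, "AlterationMatrix"))
  if (is.null(genes)) genes <- rownames(a$calls)
  if (inherits(genes, "GeneSignature")) genes <- genes$genes
  missing <- setdiff(genes, rownames(a$calls))
  if (length(missing) > 0)
    stop("gene(s) not in alteration matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  idx <- align_with_clinical(colnames(a$calls), clin)
  time <- clin$time_months[idx]
  event <- clin$event[idx]
  n <- length(time)
  res <- lapply(genes, function(g) {
    status <- a$calls[g, ]
    n_alt <- sum(status)
    if (n_alt == 0 || n_alt == n)
      return(data.frame(gene = g, n_altered = n_alt, logrank_p = NA_real_,
                        hr = NA_real_, untestable = TRUE,
                        stringsAsFactors = FALSE))
    lr <- logrank_test(time, event, factor(status))
    hr <- tryCatch(cox_fit(as.numeric(status), time, event)$hr,
                   error = function(e) NA_real_)
    data.frame(gene = g, n_altered = n_alt, logrank_p = lr$p,
               hr = unname(hr), untestable = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Log-rank p of the any-gene-altered signature status; constant status
# carries no grouping information and scores p = 1.
sgr_objective <- function(calls, genes, time, event) {
  status <- as.integer(colSums(calls[genes, , drop = FALSE]) > 0)
  if (all(status == status[1])) return(1)
  logrank_test(time, event, factor(status))$p
}

#' Single-gene-removal (SGR) greedy signature refinement
#'
#' Backward elimination on a gene signature: at each step every single-gene
#' removal is evaluated by the log-rank p-value of the remaining
#' signature's altered-vs-unaltered sample status, and the removal giving
#' the lowest p is applied (ties broken lexicographically by gene id). The
#' loop stops at `target_size`, or, under `stop_rule = "no-improvement"`,
#' as soon as the best candidate p exceeds the current signature's p.
#' Candidates whose removal makes the status vector constant score p = 1.
#'
#' @param a An `AlterationMatrix`.
#' @param clin A [clinical_table()] covering every sample in `a`.
#' @param start Starting [gene_signature()] (or character vector).
#' @param target_size Desired final size (required for
#'   `stop_rule = "size"`; optional floor, default 1, otherwise).
#' @param stop_rule `"size"` (default) or `"no-improvement"`.
#' @return Object of class `SGRTrace`: `steps` (data frame of
#'   `step`, `removed_gene`, `logrank_p`, `size_after`), `remaining` (list
#'   of signatures after each step), `final_signature`, `initial_p`.
#' @export
sgr_refine <- function(a, clin, start, target_size = NULL,
                       stop_rule = c("size", "no-improvement")) {
  stopifnot(inherits(a, "AlterationMatrix"))
  stop_rule <- match.arg(stop_rule)
  start <- as_gene_signature(start, name = "start")
  missing <- setdiff(start$genes, rownames(a$calls))
  if (length(missing) > 0)
    stop("signature gene(s) not in alteration matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (stop_rule == "size") {
    if (is.null(target_size))
      stop("`target_size` is required with stop_rule = \"size\"", call. = FALSE)
    if (target_size < 1 || target_size >= length(start$genes))
      stop("`target_size` must be in [1, signature size)", call. = FALSE)
  }
  floor_size <- if (is.null(target_size)) 1L else as.integer(target_size)
  idx <- align_with_clinical(colnames(a$calls), clin)
  time <- clin$time_months[idx]
  event <- clin$event[idx]
  calls <- a$calls

  current <- start$genes
  current_p <- sgr_objective(calls, current, time, event)
  initial_p <- current_p
  steps <- list()
  remaining <- list()
  while (length(current) > floor_size) {
    candidates <- sort(current)
    best_p <- Inf
    best_gene <- NULL
    for (g in candidates) {
      p <- sgr_objective(calls, setdiff(current, g), time, event)
      if (p < best_p) {
        best_p <- p
        best_gene <- g
      }
    }
    if (stop_rule == "no-improvement" && best_p > current_p) break
    current <- current[current != best_gene]
    current_p <- best_p
    steps[[length(steps) + 1L]] <-
      data.frame(step = length(steps) + 1L, removed_gene = best_gene,
                 logrank_p = best_p, size_after = length(current),
                 stringsAsFactors = FALSE)
    remaining[[length(remaining) + 1L]] <- current
  }
  steps <- if (length(steps) > 0) do.call(rbind, steps) else
    data.frame(step = integer(0), removed_gene = character(0),
               logrank_p = numeric(0), size_after = integer(0))
  structure(list(steps = steps, remaining = remaining,
                 final_signature = gene_signature(current,
                                                  paste0(start$name, "_sgr")),
                 initial_p = initial_p, final_p = current_p,
                 stop_rule = stop_rule),
            class = "SGRTrace")
}

#' @export
print.SGRTrace <- function(x, ...) {
  cat(sprintf("SGR trace: %d removal step(s), p %.3g -> %.3g\n",
              nrow(x$steps), x$initial_p, x$final_p))
  if (nrow(x$steps) > 0)
    cat(sprintf("  removed: %s\n", paste(x$steps$removed_gene, collapse = ", ")))
  print(x$final_signature)
  invisible(x)
}

#' Combine SGR, k-TSP and single-marker candidates into one signature
#'
#' Takes the union of the SGR final signature, the genes used by the
#' selected k-TSP pairs, and any single-marker genes, de-duplicated in a
#' deterministic order (SGR genes first, then k-TSP genes in pair order,
#' then singles).
#'
#' @param sgr An `SGRTrace`, `GeneSignature` or character vector.
#' @param tsp A `TSPClassifier`, `TSPPairScores` rows, or character vector.
#' @param singles Character vector of single-marker genes (may be empty).
#' @param name Name for the combined signature.
#' @return A [gene_signature()].
#' @export
combine_candidates <- function(sgr, tsp, singles = character(0),
                               name = "combined") {
  sgr_genes <- if (inherits(sgr, "SGRTrace")) sgr$final_signature$genes
    else if (inherits(sgr, "GeneSignature")) sgr$genes
    else as.character(sgr)
  tsp_genes <- if (inherits(tsp, "TSPClassifier"))
      as.character(rbind(tsp$pairs$gene_i, tsp$pairs$gene_j))
    else if (is.data.frame(tsp))
      as.character(rbind(tsp$gene_i, tsp$gene_j))
    else as.character(tsp)
  combined <- unique(c(sgr_genes, tsp_genes, as.character(singles)))
  if (length(combined) == 0)
    stop("combined signature is empty", call. = FALSE)
  gene_signature(combined, name)
}
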