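coerce_two_class <- function(labels, n) {
  labels <- factor(labels)
  if (length(labels) != n)
    stop("`labels` must have one label per sample", call. = FALSE)
  if (anyNA(labels)) stop("`labels` contains missing values", call. = FALSE)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2)
    stop("`labels` must contain exactly two non-empty classes", call. = FALSE)
  labels
}

#' Score all gene pairs by class-conditional order flips (k-TSP)
#'
#' For every unordered gene pair (i, j), listed once in lexicographic gene
#' order, computes the rank-based pair score
#' delta = |P(X_i < X_j | class 1) - P(X_i < X_j | class 2)|, where
#' within-sample ties X_i = X_j contribute 0.5 to the "less-than"
#' frequency, and the secondary tie-break score gamma, the absolute
#' between-class difference of the mean within-sample rank difference of
#' the two genes. Both scores depend only on within-sample orderings, so
#' they are invariant to any monotone per-sample transformation of the
#' data.
#'
#' @param z `ExpressionMatrix` (or numeric genes-by-samples matrix) with at
#'   least two genes.
#' @param labels Two-class labels, one per sample (factor, character or
#'   0/1); class 1 is the first factor level.
#' @return Data frame of class `TSPPairScores`, sorted by decreasing
#'   (delta, gamma), with columns `gene_i`, `gene_j`, `delta`, `gamma`,
#'   `p_less_class1`, `p_less_class2`, `less_predicts_class1`. The class
#'   levels are stored in `attr(, "class_levels")`.
#' @export
ktsp_score_pairs <- function(z, labels) {
  X <- as_values_matrix(z)
  if (nrow(X) < 2) stop("need at least 2 genes", call. = FALSE)
  labels <- coerce_two_class(labels, ncol(X))
  X <- X[order(rownames(X)), , drop = FALSE]
  genes <- rownames(X)
  R <- apply(X, 2, rank)
  in1 <- labels == levels(labels)[1]
  pairs <- utils::combn(length(genes), 2)
  np <- ncol(pairs)
  gene_i <- genes[pairs[1, ]]
  gene_j <- genes[pairs[2, ]]
  p1 <- p2 <- delta <- gamma <- numeric(np)
  for (m in seq_len(np)) {
    i <- pairs[1, m]; j <- pairs[2, m]
    less <- (X[i, ] < X[j, ]) + 0.5 * (X[i, ] == X[j, ])
    p1[m] <- mean(less[in1])
    p2[m] <- mean(less[!in1])
    rd <- R[i, ] - R[j, ]
    gamma[m] <- abs(mean(rd[in1]) - mean(rd[!in1]))
  }
  delta <- abs(p1 - p2)
  out <- data.frame(gene_i = gene_i, gene_j = gene_j, delta = delta,
                    gamma = gamma, p_less_class1 = p1, p_less_class2 = p2,
                    less_predicts_class1 = p1 >= p2,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$delta, -out$gamma, out$gene_i, out$gene_j), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "class_levels") <- levels(labels)
  class(out) <- c("TSPPairScores", "data.frame")
  out
}

#' Select k disjoint top-scoring pairs
#'
#' Greedily takes pairs in decreasing (delta, gamma) order, skipping any
#' pair that shares a gene with an already-selected pair, until k pairs are
#' chosen. Each pair votes for class 1 when the observed ordering of its
#' two genes matches the class-1-enriched ordering; k is odd so the
#' majority vote is always decided.
#'
#' @param scores A `TSPPairScores` table from [ktsp_score_pairs()].
#' @param k Odd positive integer.
#' @return Object of class `TSPClassifier`: `pairs` (selected rows), `k`,
#'   `class_levels`.
#' @export
ktsp_select <- function(scores, k) {
  stopifnot(inherits(scores, "TSPPairScores"))
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 ||
      k != round(k) || k %% 2 == 0)
    stop("`k` must be an odd positive integer", call. = FALSE)
  used <- character(0)
  picked <- integer(0)
  for (m in seq_len(nrow(scores))) {
    gi <- scores$gene_i[m]; gj <- scores$gene_j[m]
    if (gi %in% used || gj %in% used) next
    picked <- c(picked, m)
    used <- c(used, gi, gj)
    if (length(picked) == k) break
  }
  if (length(picked) < k)
    stop(sprintf("only %d disjoint pair(s) available; requested k = %d",
                 length(picked), k), call. = FALSE)
  structure(list(pairs = scores[picked, , drop = FALSE], k = as.integer(k),
                 class_levels = attr(scores, "class_levels")),
            class = "TSPClassifier")
}

#' @export
print.TSPClassifier <- function(x, ...) {
  cat(sprintf("k-TSP classifier (k = %d; classes %s vs %s)\n", x$k,
              x$class_levels[1], x$class_levels[2]))
  for (m in seq_len(nrow(x$pairs)))
    cat(sprintf("  %s %s %s  (delta = %.3f, gamma = %.2f)\n",
                x$pairs$gene_i[m],
                if (x$pairs$less_predicts_class1[m]) "<" else ">",
                x$pairs$gene_j[m], x$pairs$delta[m], x$pairs$gamma[m]))
  invisible(x)
}

#' Classify samples with a k-TSP model
#'
#' Each selected pair casts a vote for class 1 when the sample's ordering
#' of the pair matches the class-1-enriched orientation (within-sample ties
#' vote for class 2); the sample is assigned the class with the majority of
#' the k votes.
#'
#' @param z `ExpressionMatrix` (or numeric matrix) containing every model
#'   gene.
#' @param model A `TSPClassifier` from [ktsp_select()].
#' @return Factor of predicted labels with the training class levels.
#' @export
ktsp_classify <- function(z, model) {
  stopifnot(inherits(model, "TSPClassifier"))
  X <- as_values_matrix(z)
  needed <- unique(c(model$pairs$gene_i, model$pairs$gene_j))
  missing <- setdiff(needed, rownames(X))
  if (length(missing) > 0)
    stop("model gene(s) not in expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  votes1 <- rep(0L, ncol(X))
  for (m in seq_len(nrow(model$pairs))) {
    xi <- X[model$pairs$gene_i[m], ]
    xj <- X[model$pairs$gene_j[m], ]
    vote <- if (model$pairs$less_predicts_class1[m]) xi < xj else xi > xj
    votes1 <- votes1 + as.integer(vote)
  }
  pred <- ifelse(votes1 > model$k / 2, model$class_levels[1],
                 model$class_levels[2])
  factor(stats::setNames(pred, colnames(X)), levels = model$class_levels)
}
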