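#' Construct a risk-score vector
#'
#' @param sample_id Character vector of unique sample ids.
#' @param score Finite numeric score per sample.
#' @return Data frame of class `RiskScoreVector` with columns `sample_id`
#'   and `score`.
#' @export
risk_scores <- function(sample_id, score) {
  sample_id <- trimws(as.character(sample_id))
  if (anyDuplicated(sample_id))
    stop("duplicate sample identifiers in risk scores", call. = FALSE)
  if (length(score) != length(sample_id) || !is.numeric(score) ||
      any(!is.finite(score)))
    stop("`score` must be finite with one value per sample", call. = FALSE)
  structure(data.frame(sample_id = sample_id, score = as.numeric(score),
                       stringsAsFactors = FALSE),
            class = c("RiskScoreVector", "data.frame"))
}

as_risk_scores <- function(x) {
  if (inherits(x, "RiskScoreVector")) return(x)
  if (is.numeric(x) && !is.null(names(x))) return(risk_scores(names(x), x))
  if (is.data.frame(x) && all(c("sample_id", "score") %in% colnames(x)))
    return(risk_scores(x$sample_id, x$score))
  stop("expected a RiskScoreVector, a named numeric vector, or a data frame with sample_id/score",
       call. = FALSE)
}

#' Prognostic index (risk score)
#'
#' The per-sample prognostic index PI_s = sum over signature genes g of
#' beta_g * z_gs: Cox beta coefficients multiplied by expression values.
#'
#' @param beta Numeric vector of per-gene coefficients; if named, names
#'   must cover the signature genes, otherwise it is matched positionally.
#' @param z `ExpressionMatrix` of expression values or z-scores.
#' @param sig Signature whose genes enter the sum.
#' @return A [risk_scores()] vector.
#' @export
prognostic_index <- function(beta, z, sig) {
  sig <- as_gene_signature(sig)
  vals <- as_values_matrix(z)
  missing <- setdiff(sig$genes, rownames(vals))
  if (length(missing) > 0)
    stop("gene(s) not in expression matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(names(beta))) {
    if (length(beta) != length(sig$genes))
      stop("unnamed `beta` must have one coefficient per signature gene",
           call. = FALSE)
    names(beta) <- sig$genes
  }
  missing_beta <- setdiff(sig$genes, names(beta))
  if (length(missing_beta) > 0)
    stop("missing beta coefficient(s) for: ",
         paste(missing_beta, collapse = ", "), call. = FALSE)
  score <- as.numeric(crossprod(vals[sig$genes, , drop = FALSE],
                                beta[sig$genes]))
  risk_scores(colnames(vals), score)
}

#' Equal-weight meta-gene score
#'
#' The unweighted mean of the signature genes' values per sample; a
#' coefficient-free alternative to [prognostic_index()].
#'
#' @inheritParams prognostic_index
#' @return A [risk_scores()] vector.
#' @export
metagene_score <- function(z, sig) {
  sig <- as_gene_signature(sig)
  vals <- as_values_matrix(z)
  missing <- setdiff(sig$genes, rownames(vals))
  if (length(missing) > 0)
    stop("gene(s) not in expression matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  risk_scores(colnames(vals), colMeans(vals[sig$genes, , drop = FALSE]))
}

new_risk_partition <- function(method, sample_id, group, cutpoints, logrank,
                               cox, extra = list()) {
  n_per_group <- table(group)
  out <- c(list(method = method,
                sample_id = sample_id,
                group = group,
                cutpoints = unname(cutpoints),
                logrank = logrank,
                cox = cox,
                n_per_group = n_per_group),
           extra)
  structure(out, class = "RiskPartition")
}

#' @export
print.RiskPartition <- function(x, ...) {
  sizes <- paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                 collapse = ", ")
  cat(sprintf("RiskPartition (%s): groups [%s], cutpoint(s) %s\n", x$method,
              sizes, paste(format(x$cutpoints, digits = 4), collapse = ", ")))
  if (!is.null(x$logrank)) print(x$logrank)
  if (!is.null(x$cox)) print(x$cox)
  invisible(x)
}

group_labels <- function(n_groups) {
  if (n_groups == 2) c("low", "high") else c("low", "medium", "high")
}

# log-rank p for a candidate grouping; assumes events exist overall.
candidate_logrank_p <- function(time, event, group) {
  stats::pchisq(survival::survdiff(survival::Surv(time, event) ~ group)$chisq,
                df = length(unique(group)) - 1, lower.tail = FALSE)
}

cox_on_groups <- function(group, time, event) {
  lev <- levels(group)
  x <- sapply(lev[-1], function(l) as.numeric(group == l))
  x <- matrix(x, nrow = length(group),
              dimnames = list(NULL, paste0("risk_", lev[-1])))
  tryCatch(cox_fit(x, time, event), error = function(e) NULL)
}

#' Minimum-p-value maximized risk groups
#'
#' Splits a risk-score vector into 2 or 3 ordered groups by exhaustively
#' scanning candidate cut-points (midpoints between consecutive distinct
#' sorted scores; all pairs of cuts for 3 groups) and keeping the partition
#' whose log-rank p-value is smallest, subject to every group holding at
#' least `min_frac` of the samples. Tied scores fall deterministically on
#' the lower side of a cut. The median-split p-value is reported alongside
#' for comparison.
#'
#' @param scores A [risk_scores()] vector (or named numeric vector).
#' @param clin A [clinical_table()] covering every scored sample.
#' @param n_groups 2 or 3.
#' @param min_frac Minimum fraction of samples per group (default 0.1);
#'   `min_frac * n` must be at least 2.
#' @return Object of class `RiskPartition` with per-sample `group` labels
#'   (ordered low to high score), the selected `cutpoints`, the log-rank
#'   result, a Cox fit on the group indicators, and `median_split` with the
#'   median-cut comparison p-value.
#' @export
maximize_risk_groups <- function(scores, clin, n_groups = 2, min_frac = 0.1) {
  scores <- as_risk_scores(scores)
  if (!n_groups %in% c(2, 3)) stop("`n_groups` must be 2 or 3", call. = FALSE)
  n <- nrow(scores)
  if (!is.numeric(min_frac) || min_frac <= 0)
    stop("`min_frac` must be positive", call. = FALSE)
  if (min_frac * n < 2)
    stop("`min_frac` too small: each group must be allowed at least 2 samples",
         call. = FALSE)
  if (n_groups * min_frac > 1)
    stop(sprintf("infeasible constraint: %d groups each holding >= %.0f%% of samples",
                 n_groups, 100 * min_frac), call. = FALSE)
  idx <- align_with_clinical(scores$sample_id, clin)
  time <- clin$time_months[idx]
  event <- clin$event[idx]
  if (sum(event) == 0)
    stop("no events: log-rank statistic undefined", call. = FALSE)
  s <- scores$score
  u <- sort(unique(s))
  if (length(u) < n_groups)
    stop("too few distinct scores for the requested number of groups",
         call. = FALSE)
  cuts <- (u[-1] + u[-length(u)]) / 2
  min_size <- min_frac * n

  best <- list(p = Inf, cut = NULL)
  if (n_groups == 2) {
    for (c1 in cuts) {
      g <- s > c1
      if (sum(g) < min_size || sum(!g) < min_size) next
      p <- candidate_logrank_p(time, event, g)
      if (p < best$p) best <- list(p = p, cut = c1)
    }
  } else {
    nc <- length(cuts)
    for (i in seq_len(nc - 1)) {
      g1 <- s <= cuts[i]
      if (sum(g1) < min_size) next
      for (j in (i + 1):nc) {
        g3 <- s > cuts[j]
        n3 <- sum(g3)
        n2 <- n - sum(g1) - n3
        if (n3 < min_size || n2 < min_size) next
        g <- ifelse(g1, 1L, ifelse(g3, 3L, 2L))
        p <- candidate_logrank_p(time, event, g)
        if (p < best$p) best <- list(p = p, cut = c(cuts[i], cuts[j]))
      }
    }
  }
  if (is.null(best$cut))
    stop("no feasible partition under the group-size constraint", call. = FALSE)

  labs <- group_labels(n_groups)
  group <- factor(labs[findInterval(s, c(-Inf, best$cut, Inf))], levels = labs)
  names(group) <- scores$sample_id
  lr <- logrank_test(time, event, group)
  cox <- cox_on_groups(group, time, event)

  med_cut <- stats::median(s)
  med_g <- s > med_cut
  med_p <- if (sum(med_g) > 0 && sum(!med_g) > 0)
    candidate_logrank_p(time, event, med_g) else NA_real_

  new_risk_partition("maximized", scores$sample_id, group, best$cut, lr, cox,
                     extra = list(min_frac = min_frac,
                                  median_split = list(cutpoint = med_cut,
                                                      p = med_p)))
}

#' Quantile-based risk splits
#'
#' Cohort-splitting strategies on a risk score: `median` (two groups at the
#' 50th percentile), `quartile` (Q1 vs Q4, middle half excluded) and
#' `tertile` (T1 vs T3, middle third excluded). Excluded samples carry an
#' `NA` group label and are omitted from testing.
#'
#' @inheritParams maximize_risk_groups
#' @param clin Optional clinical table; when supplied the log-rank and Cox
#'   comparisons of the retained groups are computed.
#' @param mode One of `"median"`, `"quartile"`, `"tertile"`.
#' @return A `RiskPartition`.
#' @export
quantile_split <- function(scores, clin = NULL,
                           mode = c("median", "quartile", "tertile")) {
  scores <- as_risk_scores(scores)
  mode <- match.arg(mode)
  s <- scores$score
  n <- length(s)
  if (n < 4) stop("need at least 4 samples to split", call. = FALSE)
  if (length(unique(s)) < 2)
    stop("all scores tied: no valid quantile boundary", call. = FALSE)
  if (mode == "median") {
    cutpoints <- stats::median(s)
    group <- ifelse(s > cutpoints, "high", "low")
  } else {
    probs <- if (mode == "quartile") c(0.25, 0.75) else c(1, 2) / 3
    cutpoints <- stats::quantile(s, probs, names = FALSE)
    group <- rep(NA_character_, n)
    group[s <= cutpoints[1]] <- "low"
    group[s >= cutpoints[2]] <- "high"
  }
  group <- factor(group, levels = c("low", "high"))
  names(group) <- scores$sample_id
  if (!any(group == "low", na.rm = TRUE) || !any(group == "high", na.rm = TRUE))
    stop("degenerate split: a group is empty", call. = FALSE)
  lr <- cox <- NULL
  if (!is.null(clin)) {
    keep <- !is.na(group)
    idx <- align_with_clinical(scores$sample_id[keep], clin)
    lr <- logrank_test(clin$time_months[idx], clin$event[idx], group[keep])
    cox <- cox_on_groups(droplevels(group[keep]), clin$time_months[idx],
                         clin$event[idx])
  }
  new_risk_partition(mode, scores$sample_id, group, cutpoints, lr, cox,
                     extra = list(n_excluded = sum(is.na(group))))
}

#' Best-cutoff scan with Benjamini-Hochberg correction
#'
#' Tests every candidate cutoff (midpoints between consecutive distinct
#' scores) whose value lies between the lower and upper quantile bounds of
#' the score distribution, computing a two-group log-rank p-value at each,
#' then applies the Benjamini-Hochberg correction across the scanned
#' family. The selected cutoff is the one with minimum raw p; both its raw
#' and adjusted p are reported.
#'
#' @inheritParams maximize_risk_groups
#' @param window Length-2 numeric in (0,1): quantile window bounding the
#'   candidate cutoffs (default the interquartile range, `c(0.25, 0.75)`).
#' @return Object of class `CutoffScan`: `cutoffs`, `p`, `q`,
#'   `selected_cutoff`, `selected_p`, `selected_q`.
#' @export
best_cutoff_fdr <- function(scores, clin, window = c(0.25, 0.75)) {
  scores <- as_risk_scores(scores)
  if (!is.numeric(window) || length(window) != 2 || any(is.na(window)) ||
      window[1] <= 0 || window[2] >= 1 || window[1] >= window[2])
    stop("`window` must be an increasing pair inside (0, 1)", call. = FALSE)
  idx <- align_with_clinical(scores$sample_id, clin)
  time <- clin$time_months[idx]
  event <- clin$event[idx]
  if (sum(event) == 0)
    stop("no events: log-rank statistic undefined", call. = FALSE)
  s <- scores$score
  u <- sort(unique(s))
  if (length(u) < 2) stop("all scores tied: nothing to scan", call. = FALSE)
  cuts <- (u[-1] + u[-length(u)]) / 2
  bounds <- stats::quantile(s, window, names = FALSE)
  cuts <- cuts[cuts >= bounds[1] & cuts <= bounds[2]]
  if (length(cuts) < 3)
    stop("need at least 3 candidate cutoffs inside the window", call. = FALSE)
  p <- vapply(cuts, function(c1) candidate_logrank_p(time, event, s > c1),
              numeric(1))
  q <- bh_fdr(p)
  sel <- which.min(p)
  structure(list(cutoffs = cuts, p = p, q = q, window = window,
                 selected_index = sel, selected_cutoff = cuts[sel],
                 selected_p = p[sel], selected_q = q[sel]),
            class = "CutoffScan")
}

#' @export
print.CutoffScan <- function(x, ...) {
  cat(sprintf("Cutoff scan: %d candidates in the (%.0f%%, %.0f%%) quantile window\n",
              length(x$cutoffs), 100 * x$window[1], 100 * x$window[2]))
  cat(sprintf("  selected cutoff %.4g: raw p = %.3g, BH-adjusted p = %.3g\n",
              x$selected_cutoff, x$selected_p, x$selected_q))
  invisible(x)
}
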