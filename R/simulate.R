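#' Synthetic-cohort configuration
#'
#' Parameters of the synthetic breast-cancer-style cohort generator: a
#' reference ("diploid") panel of standard-normal expression, tumor samples
#' in which each prognostic gene is mean-shifted in its own latent
#' high-risk subset of tumors (independent Bernoulli per gene and sample,
#' so the planted markers are non-redundant), exponential event times under
#' a proportional-hazards model on the expression values, and independent
#' exponential censoring truncated at an administrative horizon.
#'
#' Defaults describe the "demo" cohort used throughout the package: 300
#' tumors, 100 reference samples, 10 genes of which the first 3 are
#' prognostic with log-hazard 0.7 per expression unit, a +3 mean shift in a
#' latent high-risk subset covering 25% of tumors per gene (so planted
#' genes cross the |z| > 2 alteration threshold at roughly 25% prevalence),
#' baseline hazard 0.01/month and censoring rate 0.004/month (about 30%
#' censoring) with a 240-month administrative horizon.
#'
#' @param n_tumor,n_reference,n_genes Positive integer cohort dimensions.
#' @param prognostic_genes Gene ids carrying survival effect; default the
#'   first 3 simulated genes.
#' @param effect_beta Log-hazard per expression unit for each prognostic
#'   gene (recycled).
#' @param alteration_shift Mean shift added to a prognostic gene in its
#'   latent high-risk tumor subset.
#' @param highrisk_fraction Expected fraction of tumors shifted per
#'   prognostic gene.
#' @param baseline_hazard Baseline event hazard per month.
#' @param censor_rate Censoring hazard per month.
#' @param admin_horizon Administrative censoring horizon (months).
#' @param class_horizon_T Horizon (months) defining the two survival
#'   classes for k-TSP labeling.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @param prefix Sample-id prefix (avoids collisions when cohorts are
#'   concatenated).
#' @return Object of class `CohortConfig` (a validated list, including the
#'   simulated `gene_ids`).
#' @export
cohort_config <- function(n_tumor = 300, n_reference = 100, n_genes = 10,
                          prognostic_genes = NULL, effect_beta = 0.7,
                          alteration_shift = 3, highrisk_fraction = 0.25,
                          baseline_hazard = 0.01, censor_rate = 0.004,
                          admin_horizon = 240, class_horizon_T = 120,
                          seed = 1, prefix = "S") {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != round(x))
      stop(sprintf("`%s` must be a positive integer", nm), call. = FALSE)
    as.integer(x)
  }
  chk_rate <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
      stop(sprintf("`%s` must be positive", nm), call. = FALSE)
    as.numeric(x)
  }
  n_tumor <- chk_count(n_tumor, "n_tumor")
  n_reference <- chk_count(n_reference, "n_reference")
  n_genes <- chk_count(n_genes, "n_genes")
  width <- max(2, nchar(as.character(n_genes)))
  gene_ids <- sprintf("G%0*d", width, seq_len(n_genes))
  if (is.null(prognostic_genes))
    prognostic_genes <- utils::head(gene_ids, min(3L, n_genes))
  prognostic_genes <- as.character(prognostic_genes)
  if (!all(prognostic_genes %in% gene_ids))
    stop("`prognostic_genes` must be a subset of the simulated genes (",
         paste(utils::head(gene_ids, 3), collapse = ", "), ", ...)",
         call. = FALSE)
  effect_beta <- rep_len(as.numeric(effect_beta), length(prognostic_genes))
  if (anyNA(effect_beta)) stop("`effect_beta` must be numeric", call. = FALSE)
  if (!is.numeric(highrisk_fraction) || highrisk_fraction < 0 ||
      highrisk_fraction > 1)
    stop("`highrisk_fraction` must be in [0, 1]", call. = FALSE)
  cfg <- list(n_tumor = n_tumor, n_reference = n_reference, n_genes = n_genes,
              gene_ids = gene_ids, prognostic_genes = prognostic_genes,
              effect_beta = stats::setNames(effect_beta, prognostic_genes),
              alteration_shift = as.numeric(alteration_shift),
              highrisk_fraction = as.numeric(highrisk_fraction),
              baseline_hazard = chk_rate(baseline_hazard, "baseline_hazard"),
              censor_rate = chk_rate(censor_rate, "censor_rate"),
              admin_horizon = chk_rate(admin_horizon, "admin_horizon"),
              class_horizon_T = chk_rate(class_horizon_T, "class_horizon_T"),
              seed = as.integer(seed), prefix = as.character(prefix)[1])
  structure(cfg, class = "CohortConfig")
}

as_cohort_config <- function(x) {
  if (inherits(x, "CohortConfig")) return(x)
  if (is.list(x)) {
    x$gene_ids <- NULL
    return(do.call(cohort_config, x))
  }
  stop("expected a CohortConfig or a parameter list", call. = FALSE)
}

#' Simulate a synthetic cohort with planted prognostic structure
#'
#' Reference samples are drawn standard normal per gene. Tumor samples are
#' standard normal except that each prognostic gene is shifted by
#' `alteration_shift` in an independent latent high-risk subset of tumors
#' (Bernoulli `highrisk_fraction` per gene and sample). Event times are
#' exponential with hazard
#' `baseline_hazard * exp(sum_g beta_g * x_gs)` over the prognostic genes;
#' censoring times are exponential(`censor_rate`) truncated at
#' `admin_horizon`; observed time is the minimum with the usual event
#' indicator. All draws occur under the configured seed in a fixed order
#' (reference matrix, tumor matrix, shift indicators, event times,
#' censoring), so identical configurations are bit-identical.
#'
#' @param cfg A [cohort_config()] (or parameter list).
#' @return List of class `SyntheticCohort`: `expression`
#'   (an [expression_matrix()] with reference flags), `clinical`
#'   (a [clinical_table()] for the tumor samples), and `truth`
#'   (per-gene shift indicators, per-sample latent risk and hazard, planted
#'   genes and coefficients), plus the `config`.
#' @export
simulate_cohort <- function(cfg) {
  cfg <- as_cohort_config(cfg)
  withr::with_seed(cfg$seed, {
    G <- cfg$n_genes
    ref <- matrix(stats::rnorm(G * cfg$n_reference), nrow = G)
    tum <- matrix(stats::rnorm(G * cfg$n_tumor), nrow = G)
    prog <- match(cfg$prognostic_genes, cfg$gene_ids)
    shifted <- matrix(stats::rbinom(length(prog) * cfg$n_tumor, 1,
                                    cfg$highrisk_fraction),
                      nrow = length(prog))
    tum[prog, ] <- tum[prog, , drop = FALSE] + cfg$alteration_shift * shifted
    linpred <- as.numeric(crossprod(tum[prog, , drop = FALSE], cfg$effect_beta))
    hazard <- cfg$baseline_hazard * exp(linpred)
    t_event <- stats::rexp(cfg$n_tumor, rate = hazard)
    t_censor <- pmin(stats::rexp(cfg$n_tumor, rate = cfg$censor_rate),
                     cfg$admin_horizon)
    time <- pmin(t_event, t_censor)
    event <- as.integer(t_event <= t_censor)

    ref_ids <- sprintf("%sR%04d", cfg$prefix, seq_len(cfg$n_reference))
    tum_ids <- sprintf("%sT%04d", cfg$prefix, seq_len(cfg$n_tumor))
    values <- cbind(ref, tum)
    rownames(values) <- cfg$gene_ids
    colnames(values) <- c(ref_ids, tum_ids)
    expr <- expression_matrix(values,
                              c(rep(TRUE, cfg$n_reference),
                                rep(FALSE, cfg$n_tumor)))
    clin <- clinical_table(data.frame(sample_id = tum_ids,
                                      time_months = time, event = event,
                                      stringsAsFactors = FALSE))
    dimnames(shifted) <- list(cfg$prognostic_genes, tum_ids)
    truth <- list(shifted = shifted,
                  latent_risk = stats::setNames(colSums(shifted), tum_ids),
                  hazard = stats::setNames(hazard, tum_ids),
                  prognostic_genes = cfg$prognostic_genes,
                  effect_beta = cfg$effect_beta)
    structure(list(expression = expr, clinical = clin, truth = truth,
                   config = cfg),
              class = "SyntheticCohort")
  })
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d tumors, %d reference samples, %d genes (%d prognostic); %.0f%% events observed\n",
              x$config$n_tumor, x$config$n_reference, x$config$n_genes,
              length(x$config$prognostic_genes), 100 * mean(x$clinical$event)))
  invisible(x)
}

# Two survival classes at horizon T: class 1 = event observed by T,
# class 0 = event-free follow-up of at least T; censored before T is NA.
two_class_labels <- function(clin, horizon) {
  ifelse(clin$event == 1 & clin$time_months <= horizon, 1L,
         ifelse(clin$time_months >= horizon, 0L, NA_integer_))
}

#' Simulate a two-class expression dataset for k-TSP
#'
#' Runs [simulate_cohort()] and labels tumors by survival class at the
#' configured horizon T: label 1 for an event observed by T, label 0 for
#' event-free follow-up of at least T; samples censored before T are
#' dropped. Optionally injects a "switched pair": two genes whose
#' within-sample order is i < j in class 1 and i > j in class 0 with
#' probability `fidelity` (0.5 makes the pair uninformative).
#'
#' @param cfg A [cohort_config()]; `class_horizon_T` must not exceed
#'   `admin_horizon`.
#' @param switched_pair Optional length-2 character vector of gene ids.
#' @param fidelity Probability in \[0, 1\] that a sample respects its
#'   class's pair orientation (default 1).
#' @return List: `expression` (tumor-only `ExpressionMatrix` over kept
#'   samples), `labels` (named 0/1 integer vector, 1 = event by T),
#'   `clinical` (kept rows), `n_dropped`.
#' @export
simulate_two_class <- function(cfg, switched_pair = NULL, fidelity = 1) {
  cfg <- as_cohort_config(cfg)
  if (cfg$class_horizon_T > cfg$admin_horizon)
    stop("`class_horizon_T` exceeds `admin_horizon`", call. = FALSE)
  coh <- simulate_cohort(cfg)
  lab <- two_class_labels(coh$clinical, cfg$class_horizon_T)
  keep <- !is.na(lab)
  if (sum(lab[keep] == 1) == 0 || sum(lab[keep] == 0) == 0)
    stop("a survival class is empty after labeling; adjust class_horizon_T or the hazard rates",
         call. = FALSE)
  kept_ids <- coh$clinical$sample_id[keep]
  vals <- coh$expression$values[, kept_ids, drop = FALSE]
  labels <- stats::setNames(lab[keep], kept_ids)
  if (!is.null(switched_pair)) {
    switched_pair <- as.character(switched_pair)
    if (length(switched_pair) != 2 ||
        !all(switched_pair %in% rownames(vals)))
      stop("`switched_pair` must name two simulated genes", call. = FALSE)
    if (!is.numeric(fidelity) || fidelity < 0 || fidelity > 1)
      stop("`fidelity` must be in [0, 1]", call. = FALSE)
    nk <- length(kept_ids)
    withr::with_seed(cfg$seed + 1L, {
      a <- stats::rnorm(nk); b <- stats::rnorm(nk)
      lo <- pmin(a, b); hi <- pmax(a, b)
      respects <- stats::runif(nk) < fidelity
      # class 1: gene_i < gene_j when the draw respects the orientation
      i_less <- ifelse(labels == 1L, respects, !respects)
      vals[switched_pair[1], ] <- ifelse(i_less, lo, hi)
      vals[switched_pair[2], ] <- ifelse(i_less, hi, lo)
    })
  }
  list(expression = expression_matrix(vals), labels = labels,
       clinical = coh$clinical[keep, , drop = FALSE],
       n_dropped = sum(!keep))
}
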