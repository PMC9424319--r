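#' Default demo pipeline configuration
#'
#' A self-contained configuration that simulates the demo cohort (see
#' [cohort_config()]), refines its full gene panel down to the planted
#' prognostic core with SGR and k-TSP, adds significant single markers,
#' scores the prognostic index and maximizes two risk groups, and tests a
#' small built-in gene-set collection for over-representation.
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed for the simulated cohort.
#' @return A pipeline configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("sigforge_demo_"), seed = 1) {
  list(
    simulate = list(seed = seed),
    stages = list(enrichment = TRUE, refine = TRUE, ktsp = TRUE,
                  stratify = TRUE, subgroup = FALSE),
    params = list(threshold = 2, target_size = 3, k = 3, groups = 2,
                  min_frac = 0.1, q_max = 0.05, class_horizon_T = 120,
                  singles_alpha = 0.05),
    plots = TRUE,
    out_dir = out_dir
  )
}

# Deterministic toy collection over the simulated gene panel: the planted
# module, a shifted decoy, and the full panel.
demo_collection <- function(gene_ids, prognostic) {
  others <- setdiff(gene_ids, prognostic)
  sets <- list(
    list(name = "planted_module", description = "planted prognostic genes",
         genes = prognostic),
    list(name = "decoy_module", description = "non-prognostic decoy",
         genes = utils::head(others, max(2, length(prognostic)))),
    list(name = "full_panel", description = "all simulated genes",
         genes = gene_ids)
  )
  gene_set_collection(sets)
}

read_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    coh <- simulate_cohort(config$simulate)
    list(expression = coh$expression, clinical = coh$clinical,
         truth = coh$truth, config = coh$config)
  } else {
    if (is.null(config$expression) || is.null(config$clinical))
      stop("config must provide either `simulate` parameters or `expression` and `clinical` paths",
           call. = FALSE)
    list(expression = read_expression(config$expression,
                                      reference_ids = config$reference_ids),
         clinical = read_clinical(config$clinical), truth = NULL,
         config = NULL)
  }
}

km_plot <- function(time, event, group, path, main) {
  grDevices::png(path, width = 720, height = 540)
  on.exit(grDevices::dev.off())
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  cols <- c("#2166ac", "#1a9850", "#b2182b")[seq_len(nlevels(group))]
  plot(fit, col = cols, lwd = 2, xlab = "Months", ylab = "Survival fraction",
       main = main)
  graphics::legend("topright", legend = levels(group), col = cols, lwd = 2,
                   bty = "n")
  invisible(path)
}

unclass_for_json <- function(x) {
  if (inherits(x, "GeneSignature")) return(list(name = x$name, genes = x$genes))
  if (is.factor(x)) return(as.character(x))
  if (is.table(x)) return(as.list(stats::setNames(as.integer(x), names(x))))
  x
}

#' Run the end-to-end signature-discovery pipeline
#'
#' Orchestrates the full workflow on one cohort: reference-relative
#' z-scoring, alteration calling, optional gene-set over-representation of
#' the starting panel, SGR refinement and k-TSP pair selection, addition of
#' significant single markers, the combined signature, Cox-based prognostic
#' index scoring, minimum-p-value risk-group maximization, and optional
#' per-subgroup survival testing. Writes a versioned JSON report, TSV
#' tables, and (optionally) Kaplan-Meier plot images to `out_dir`.
#' Identical configurations produce byte-identical TSV/JSON outputs.
#'
#' @param config Configuration list (see [demo_config()]) or path to a
#'   YAML file holding one.
#' @return Invisibly, a list with the in-memory results (`report`,
#'   `signature`, `trace`, `tsp`, `partition`, `enrichment`, `files`).
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must set `out_dir`", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- utils::modifyList(list(enrichment = TRUE, refine = TRUE,
                                   ktsp = TRUE, stratify = TRUE,
                                   subgroup = FALSE),
                              if (is.null(config$stages)) list() else config$stages)
  params <- utils::modifyList(list(threshold = 2, target_size = 3, k = 3,
                                   groups = 2, min_frac = 0.1, q_max = 0.05,
                                   class_horizon_T = 120,
                                   singles_alpha = 0.05),
                              if (is.null(config$params)) list() else config$params)

  stage <- "input"
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  inputs <- run_stage("input", read_pipeline_inputs(config))
  expr <- inputs$expression
  clin <- inputs$clinical

  z <- run_stage("zscore", zscore_vs_reference(expr))
  alt <- run_stage("alteration", call_alterations(z, params$threshold))

  start <- if (!is.null(config$signature)) {
    if (is.character(config$signature) && length(config$signature) == 1 &&
        file.exists(config$signature))
      read_signature(config$signature)
    else as_gene_signature(config$signature, "start")
  } else gene_signature(rownames(z$values), "panel")

  report <- list(schema_version = "1.0",
                 params = params,
                 n_genes = nrow(z$values), n_samples = ncol(z$values),
                 n_reference = sum(expr$is_reference),
                 start_signature = unclass_for_json(start))
  files <- character(0)

  enr <- NULL
  if (isTRUE(stages$enrichment)) {
    enr <- run_stage("enrichment", {
      coll <- if (!is.null(config$gmt)) read_gmt(config$gmt)
        else demo_collection(rownames(z$values),
                             if (!is.null(inputs$truth))
                               inputs$truth$prognostic_genes
                             else start$genes)
      universe <- if (!is.null(config$universe)) readLines(config$universe)
        else unique(c(rownames(z$values),
                      unlist(lapply(coll$sets, `[[`, "genes"))))
      enrich_collection(start$genes, coll, universe, q_max = params$q_max,
                        filter = FALSE)
    })
    f <- file.path(out_dir, "enrichment.tsv")
    write_enrichment(enr, f)
    files <- c(files, f)
    report$enrichment <- list(n_sets = nrow(enr),
                              top_set = enr$set_name[1],
                              top_p = enr$p[1], top_q = enr$q[1])
  }

  trace <- NULL
  if (isTRUE(stages$refine)) {
    trace <- run_stage("sgr", sgr_refine(alt, clin, start,
                                         target_size = params$target_size))
    report$sgr <- list(steps = trace$steps,
                       final_signature = trace$final_signature$genes,
                       initial_p = trace$initial_p, final_p = trace$final_p)
  }

  tsp <- NULL
  if (isTRUE(stages$ktsp)) {
    tsp <- run_stage("ktsp", {
      lab <- two_class_labels(clin, params$class_horizon_T)
      keep <- !is.na(lab)
      if (sum(lab[keep] == 1) == 0 || sum(lab[keep] == 0) == 0)
        stop("a survival class at the k-TSP horizon is empty")
      zz <- z$values[, clin$sample_id[keep], drop = FALSE]
      ktsp_select(ktsp_score_pairs(zz, lab[keep]), k = params$k)
    })
    report$ktsp <- list(k = tsp$k,
                        pairs = tsp$pairs[, c("gene_i", "gene_j", "delta",
                                              "gamma")])
  }

  singles <- character(0)
  if (isTRUE(stages$refine)) {
    sgs <- run_stage("single_gene", single_gene_significance(alt, clin,
                                                             start$genes))
    singles <- sgs$gene[!sgs$untestable &
                          sgs$logrank_p < params$singles_alpha]
    f <- file.path(out_dir, "single_gene_significance.tsv")
    utils::write.table(sgs, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    report$single_markers <- singles
  }

  signature <- run_stage("combine", {
    if (is.null(trace) && is.null(tsp) && length(singles) == 0) start
    else combine_candidates(if (is.null(trace)) character(0) else trace,
                            if (is.null(tsp)) character(0) else tsp,
                            singles)
  })
  report$signature <- unclass_for_json(signature)

  part <- NULL
  if (isTRUE(stages$stratify)) {
    part <- run_stage("stratify", {
      cox <- cox_fit(t(z$values[signature$genes, , drop = FALSE]),
                     clin$time_months[align_with_clinical(colnames(z$values),
                                                          clin)],
                     clin$event[align_with_clinical(colnames(z$values), clin)])
      beta <- stats::setNames(cox$beta, signature$genes)
      pi <- prognostic_index(beta, z, signature)
      f <- file.path(out_dir, "prognostic_index.tsv")
      utils::write.table(as.data.frame(pi), f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f)
      maximize_risk_groups(pi, clin, n_groups = params$groups,
                           min_frac = params$min_frac)
    })
    f <- file.path(out_dir, "risk_partition.tsv")
    utils::write.table(data.frame(sample_id = part$sample_id,
                                  group = as.character(part$group)),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    report$partition <- list(method = part$method,
                             cutpoints = part$cutpoints,
                             n_per_group = unclass_for_json(part$n_per_group),
                             logrank_p = part$logrank$p,
                             hr = if (!is.null(part$cox))
                               as.list(part$cox$hr) else NULL,
                             median_split_p = part$median_split$p)
    if (isTRUE(config$plots)) {
      idx <- align_with_clinical(part$sample_id, clin)
      km_plot(clin$time_months[idx], clin$event[idx], part$group,
              file.path(out_dir, "km_maximized_groups.png"),
              "Maximized risk groups")
    }
  }

  if (isTRUE(stages$subgroup)) {
    sub <- run_stage("subgroup", subgroup_survival(
      signature_status(alt, signature), clin))
    f <- file.path(out_dir, "subgroup_survival.tsv")
    utils::write.table(sub, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    report$subgroup <- sub
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  files <- c(files, report_path)
  invisible(list(report = report, signature = signature, trace = trace,
                 tsp = tsp, partition = part, enrichment = enr,
                 files = files))
}

#' Survival association within clinical subgroups
#'
#' Runs the log-rank test and a univariate Cox fit of a binary per-sample
#' status (e.g. signature altered vs unaltered) independently within each
#' level of the clinical `subgroup` column. Subgroups in which the status
#' does not vary are reported untestable rather than dropped.
#'
#' @param status Named 0/1 vector per sample (names = sample ids), e.g.
#'   from [signature_status()].
#' @param clin A [clinical_table()] with a `subgroup` column.
#' @return Data frame with one row per subgroup: `subgroup`, `n`,
#'   `n_altered`, `logrank_p`, `hr`, `ci_low`, `ci_high`, `untestable`.
#' @export
subgroup_survival <- function(status, clin) {
  if (is.null(clin$subgroup))
    stop("clinical table has no `subgroup` column", call. = FALSE)
  if (is.null(names(status)))
    stop("`status` must be named by sample id", call. = FALSE)
  idx <- align_with_clinical(names(status), clin)
  levels_sub <- unique(as.character(clin$subgroup[idx]))
  rows <- lapply(levels_sub, function(lv) {
    in_sub <- as.character(clin$subgroup[idx]) == lv
    st <- status[in_sub]
    time <- clin$time_months[idx][in_sub]
    event <- clin$event[idx][in_sub]
    if (length(unique(st)) < 2)
      return(data.frame(subgroup = lv, n = length(st), n_altered = sum(st),
                        logrank_p = NA_real_, hr = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        untestable = TRUE, stringsAsFactors = FALSE))
    lr <- logrank_test(time, event, factor(st))
    cox <- tryCatch(cox_fit(as.numeric(st), time, event),
                    error = function(e) NULL)
    data.frame(subgroup = lv, n = length(st), n_altered = sum(st),
               logrank_p = lr$p,
               hr = if (is.null(cox)) NA_real_ else unname(cox$hr),
               ci_low = if (is.null(cox)) NA_real_ else unname(cox$ci_low),
               ci_high = if (is.null(cox)) NA_real_ else unname(cox$ci_high),
               untestable = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
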