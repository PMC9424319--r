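#' Construct a clinical table
#'
#' Per-sample follow-up time (months), event indicator (1 = death/relapse
#' observed, 0 = censored) and an optional subgroup label.
#'
#' @param x Data frame with columns `sample_id`, `time_months`, `event` and
#'   optionally `subgroup`.
#' @return The validated data frame with class `ClinicalTable` prepended.
#' @export
clinical_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("sample_id", "time_months", "event")
  missing <- setdiff(required, colnames(x))
  if (length(missing) > 0)
    stop("clinical table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  x$sample_id <- trimws(as.character(x$sample_id))
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample identifiers in clinical table", call. = FALSE)
  if (!is.numeric(x$time_months) || anyNA(x$time_months) || any(x$time_months < 0))
    stop("`time_months` must be non-negative and complete", call. = FALSE)
  if (anyNA(x$event) || !all(x$event %in% c(0, 1)))
    stop("`event` must be 0 or 1 for every sample", call. = FALSE)
  x$event <- as.integer(x$event)
  class(x) <- unique(c("ClinicalTable", class(x)))
  x
}

#' Read a clinical TSV
#'
#' Expects columns `sample_id`, `time_months`, `event` and optionally
#' `subgroup`.
#'
#' @param path Path to the TSV file.
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path) {
  clinical_table(utils::read.delim(path, stringsAsFactors = FALSE,
                                   check.names = FALSE))
}

#' Write a clinical table as TSV
#'
#' @param x A [clinical_table()].
#' @param path Output path.
#' @export
write_clinical <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Align a per-sample vector (named or in a RiskScoreVector) with a clinical
# table; errors if any sample lacks clinical follow-up.
align_with_clinical <- function(sample_id, clin) {
  idx <- match(sample_id, clin$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from clinical table: ",
         paste(utils::head(sample_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  idx
}
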