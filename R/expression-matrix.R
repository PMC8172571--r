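#' Build an expression matrix container
#'
#' Thin constructor around [SummarizedExperiment::SummarizedExperiment()]:
#' one counts (or normalized-value) assay, per-sample metadata (`group`,
#' `timepoint`, `replicate`) in `colData`, the RNA species and normalization
#' state in `metadata`, and optional per-feature transcript lengths (needed
#' for FPKM) in `rowData`.
#'
#' @param counts Numeric matrix, features x samples, with feature IDs as
#'   rownames and sample IDs as colnames; no negative values.
#' @param samples `data.frame` with columns `sample_id`, `group`,
#'   `timepoint`, `replicate` covering all columns of `counts`.
#' @param species One of `"circRNA"`, `"miRNA"`, `"mRNA"`.
#' @param lengths Optional positive per-feature lengths (bp), same order as
#'   `counts` rows.
#' @return A `SummarizedExperiment` with assay `"values"`.
#' @examples
#' m <- matrix(rpois(8, 10), 2, 4,
#'             dimnames = list(c("f1", "f2"), paste0("s", 1:4)))
#' sheet <- data.frame(sample_id = paste0("s", 1:4),
#'                     group = rep(c("Sham", "ICH"), each = 2),
#'                     timepoint = "day7", replicate = c(1, 2, 1, 2))
#' se <- expression_matrix(m, sheet, "miRNA")
#' @export
expression_matrix <- function(counts, samples, species, lengths = NULL) {
  species <- match.arg(species, c("circRNA", "miRNA", "mRNA"))
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  need <- c("sample_id", "group", "timepoint", "replicate")
  if (!all(need %in% names(samples))) {
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(colnames(counts) %in% samples$sample_id)) {
    stop("sample sheet does not cover all count columns")
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rd <- NULL
  if (!is.null(lengths)) {
    if (length(lengths) != nrow(counts)) stop("lengths must match feature count")
    if (any(lengths <= 0)) stop("feature lengths must be positive")
    rd <- S4Vectors::DataFrame(length = as.numeric(lengths),
                               row.names = rownames(counts))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = counts),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
  if (!is.null(rd)) SummarizedExperiment::rowData(se) <- rd
  S4Vectors::metadata(se)$species <- species
  S4Vectors::metadata(se)$normalized <- "counts"
  se
}

em_values <- function(se) SummarizedExperiment::assay(se, "values")

em_species <- function(se) S4Vectors::metadata(se)$species %||% "unknown"

em_samples <- function(se) {
  as.data.frame(SummarizedExperiment::colData(se))
}

#' Subset an expression matrix to one timepoint
#' @noRd
em_timepoint <- function(se, timepoint) {
  cd <- SummarizedExperiment::colData(se)
  if (!timepoint %in% cd$timepoint) {
    stop("timepoint not present: ", timepoint)
  }
  se[, cd$timepoint == timepoint]
}
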