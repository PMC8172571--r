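#' Run the full ceRNA analysis for one timepoint
#'
#' Convenience driver chaining the pipeline stages on in-memory inputs:
#' TPM/FPKM normalization, per-species differential expression at the
#' timepoint, seed-site prediction of miRNAs against circRNA sequences
#' and mRNA 3'UTRs, DE-filtered pair candidates, triplet assembly,
#' Pearson correlation edges, and hub selection.
#'
#' @param matrices Named list of counts `SummarizedExperiment`s
#'   (`circRNA`, `miRNA`, `mRNA`).
#' @param sequences List with `mirna`, `circ`, `utr` named sequence
#'   vectors (as from [emit_sequences()] or [read_fasta()]).
#' @param timepoint `"day7"` or `"day28"`.
#' @param alpha DE significance threshold (adjusted p).
#' @param r_max,p_max Hub-selection thresholds (see [select_hubs()]).
#' @param cohort Correlation cohort (see [pearson_edges()]).
#' @param sites Optional precomputed site table (e.g. from an external
#'   predictor) to use instead of [find_all_sites()].
#' @return List with `de` (per-species `de_table`s), `normalized`
#'   matrices, `sites`, `pairs`, `triplets` (with correlation columns),
#'   `hubs`, and the `network` graph of all triplets.
#' @export
run_cerna_pipeline <- function(matrices, sequences, timepoint,
                               alpha = 0.05, r_max = -0.5, p_max = 0.05,
                               cohort = "pooled", sites = NULL) {
  de <- list(
    circRNA = de_test(matrices$circRNA, timepoint, alpha),
    miRNA = de_test(matrices$miRNA, timepoint, alpha),
    mRNA = de_test(matrices$mRNA, timepoint, alpha))

  normalized <- list(
    circRNA = tpm_normalize(matrices$circRNA),
    miRNA = tpm_normalize(matrices$miRNA),
    mRNA = fpkm_normalize(matrices$mRNA))

  if (is.null(sites)) {
    # only DE miRNAs can enter pairs; restrict the scan accordingly
    de_mir <- de$miRNA$feature_id[de$miRNA$direction != "ns"]
    de_circ <- de$circRNA$feature_id[de$circRNA$direction != "ns"]
    de_mrna <- de$mRNA$feature_id[de$mRNA$direction != "ns"]
    sites <- rbind(
      find_all_sites(sequences$mirna[names(sequences$mirna) %in% de_mir],
                     sequences$circ[names(sequences$circ) %in% de_circ],
                     "circ"),
      find_all_sites(sequences$mirna[names(sequences$mirna) %in% de_mir],
                     sequences$utr[names(sequences$utr) %in% de_mrna],
                     "mrna"))
  }

  pairs <- pair_candidates(sites, de$circRNA, de$miRNA, de$mRNA)
  triplets <- assemble_triplets(pairs$circ_mir, pairs$mir_mrna)
  if (nrow(triplets)) {
    triplets <- pearson_edges(triplets, normalized, timepoint,
                              cohort = cohort)
  } else {
    triplets$r_circ_mir <- triplets$p_circ_mir <- numeric(0)
    triplets$r_mir_mrna <- triplets$p_mir_mrna <- numeric(0)
    triplets$hub_eligible <- logical(0)
  }
  hubs <- select_hubs(triplets, r_max = r_max, p_max = p_max)
  network <- cerna_network(triplets, de_tables = de, timepoint = timepoint)

  list(de = de, normalized = normalized, sites = sites, pairs = pairs,
       triplets = triplets, hubs = hubs, network = network)
}
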