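# File readers and writers for the pipeline's tabular and sequence formats.
# Counts and caller tables are plain TSV; annotation is GTF (1-based,
# closed intervals) via rtracklayer; sequences are FASTA via Biostrings.

#' Write / read a counts matrix as TSV
#'
#' The TSV has a `feature_id` column followed by one column per sample.
#'
#' @param se `SummarizedExperiment` from [expression_matrix()].
#' @param path Output file.
#' @export
write_counts_tsv <- function(se, path) {
  df <- data.frame(feature_id = rownames(se), em_values(se),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param samples Sample sheet `data.frame` (see [expression_matrix()]).
#' @param species RNA species of the matrix.
#' @param lengths Optional per-feature lengths.
#' @export
read_counts_tsv <- function(path, samples, species, lengths = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  expression_matrix(m, samples, species, lengths = lengths)
}

#' Write / read the sample sheet
#' @param samples Sample sheet `data.frame`.
#' @param path File path.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a back-splice-junction caller table
#'
#' Columns: `chrom`, `start`, `end`, `strand`, `caller`, then one
#' `reads_<sample>` column per sample; coordinates 1-based inclusive.
#' @param calls Caller table `data.frame`.
#' @param path File path.
#' @export
write_bsj_table <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bsj_table
#' @param sample_sheet Sample sheet the read columns must match; checked.
#' @export
read_bsj_table <- function(path, sample_sheet = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_bsj_table(df, sample_sheet)
}

validate_bsj_table <- function(df, sample_sheet = NULL) {
  need <- c("chrom", "start", "end", "strand", "caller")
  if (!all(need %in% names(df))) {
    stop("caller table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$start > df$end)) stop("malformed interval: start > end")
  rcols <- grep("^reads_", names(df), value = TRUE)
  if (!is.null(sample_sheet)) {
    expect <- paste0("reads_", sample_sheet$sample_id)
    if (!setequal(rcols, expect)) {
      stop("junction-read columns do not match the sample sheet")
    }
    df <- df[, c(need, expect)]
  }
  df
}

#' Write sequences as FASTA
#' @param seqs Named character vector (DNA or RNA strings).
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  xs <- if (any(grepl("U", seqs, fixed = TRUE))) {
    Biostrings::RNAStringSet(seqs)
  } else {
    Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' @rdname write_fasta
#' @param alphabet `"DNA"` or `"RNA"`.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  xs <- if (alphabet == "DNA") Biostrings::readDNAStringSet(path)
        else Biostrings::readRNAStringSet(path)
  setNames(as.character(xs), names(xs))
}

#' Write / read gene annotation as GTF
#' @param annotation `GRanges` with `type`, `gene_id`, `transcript_id`
#'   metadata columns (as produced by [emit_caller_tables()]).
#' @param path File path.
#' @export
write_gtf <- function(annotation, path) {
  rtracklayer::export(annotation, path, format = "gtf")
  invisible(path)
}

#' @rdname write_gtf
#' @export
read_gtf <- function(path) {
  rtracklayer::import(path, format = "gtf")
}

#' Write all simulated study inputs to a directory
#'
#' Materialises one simulated study as the plain-text files a real study
#' would provide: per-species counts TSVs, sample sheet, two caller
#' tables, GTF annotation, and FASTA sequences.
#'
#' @param sim Result of [simulate_counts()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_sim_outputs <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tabs <- emit_caller_tables(sim$truth, sim$config)
  seqs <- emit_sequences(sim$truth, sim$config)
  paths <- c(
    circ_counts = write_counts_tsv(sim$matrices$circRNA,
                                   file.path(outdir, "circ_counts.tsv")),
    mir_counts = write_counts_tsv(sim$matrices$miRNA,
                                  file.path(outdir, "mir_counts.tsv")),
    mrna_counts = write_counts_tsv(sim$matrices$mRNA,
                                   file.path(outdir, "mrna_counts.tsv")),
    sample_sheet = write_sample_sheet(sim$sample_sheet,
                                      file.path(outdir, "samples.tsv")),
    calls_a = write_bsj_table(tabs$calls_a, file.path(outdir, "calls_a.tsv")),
    calls_b = write_bsj_table(tabs$calls_b, file.path(outdir, "calls_b.tsv")),
    gtf = write_gtf(tabs$annotation, file.path(outdir, "annotation.gtf")),
    mir_fa = write_fasta(seqs$mirna, file.path(outdir, "mirna.fa")),
    circ_fa = write_fasta(seqs$circ, file.path(outdir, "circ.fa")),
    utr_fa = write_fasta(seqs$utr, file.path(outdir, "utr.fa")))
  invisible(paths)
}
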