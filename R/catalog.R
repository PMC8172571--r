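# circRNA catalogue construction: dual-caller intersection, junction-read
# replicate filter, genomic classification and class composition.

#' Intersect two callers' back-splice-junction calls
#'
#' Back-splice-junction callers have high false-positive rates; keeping
#' only junctions reported by two independent callers at the same genomic
#' position is the standard guard. Two calls match when they share
#' `chrom` and `strand` and their start and end coordinates each differ by
#' at most `slack` (default 0, i.e. identical coordinates). Each call is
#' used at most once; candidate matches are paired in (chrom, start, end)
#' order. Merged junction reads are the per-sample maximum of the two
#' callers (the two calls are evidence for the same molecule, so summing
#' would double-count).
#'
#' @param calls_a,calls_b Caller tables (see [read_bsj_table()]) sharing
#'   the same `reads_` columns.
#' @param slack Maximum per-endpoint coordinate difference for a match.
#' @return Merged caller table sorted by (chrom, start, end), with
#'   `caller = "intersection"`.
#' @examples
#' a <- data.frame(chrom = "chr1", start = 100, end = 500, strand = "+",
#'                 caller = "A", reads_s1 = 5)
#' b <- data.frame(chrom = "chr1", start = 100, end = 500, strand = "+",
#'                 caller = "B", reads_s1 = 3)
#' intersect_callers(a, b)
#' @export
intersect_callers <- function(calls_a, calls_b, slack = 0L) {
  calls_a <- validate_bsj_table(calls_a)
  calls_b <- validate_bsj_table(calls_b)
  rcols <- grep("^reads_", names(calls_a), value = TRUE)
  if (!setequal(rcols, grep("^reads_", names(calls_b), value = TRUE))) {
    stop("caller tables were built against different sample sheets")
  }
  calls_b <- calls_b[, names(calls_a)]

  ord_a <- order(calls_a$chrom, calls_a$start, calls_a$end)
  ord_b <- order(calls_b$chrom, calls_b$start, calls_b$end)
  calls_a <- calls_a[ord_a, , drop = FALSE]
  calls_b <- calls_b[ord_b, , drop = FALSE]

  used_b <- rep(FALSE, nrow(calls_b))
  keep <- integer(0); partner <- integer(0)
  key_b <- paste(calls_b$chrom, calls_b$strand)
  for (i in seq_len(nrow(calls_a))) {
    cand <- which(!used_b &
                  key_b == paste(calls_a$chrom[i], calls_a$strand[i]) &
                  abs(calls_b$start - calls_a$start[i]) <= slack &
                  abs(calls_b$end - calls_a$end[i]) <= slack)
    if (length(cand)) {
      j <- cand[1]
      used_b[j] <- TRUE
      keep <- c(keep, i); partner <- c(partner, j)
    }
  }
  out <- calls_a[keep, , drop = FALSE]
  if (length(keep)) {
    out[, rcols] <- pmax(as.matrix(calls_a[keep, rcols, drop = FALSE]),
                         as.matrix(calls_b[partner, rcols, drop = FALSE]))
  }
  out$caller <- rep("intersection", nrow(out))
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter junctions by replicate-set read support
#'
#' Keeps a back-splice junction if and only if there exists at least one
#' replicate set (one group x timepoint cell of the design) in which every
#' sample has at least `min_reads` junction reads.
#'
#' @param calls Caller table.
#' @param sample_sheet Sample sheet defining the replicate sets.
#' @param min_reads Minimum junction reads per sample (default 2).
#' @return The retained rows of `calls`.
#' @export
filter_junction_reads <- function(calls, sample_sheet, min_reads = 2L) {
  calls <- validate_bsj_table(calls, sample_sheet)
  sets <- split(sample_sheet$sample_id,
                paste(sample_sheet$group, sample_sheet$timepoint))
  if (any(lengths(sets) == 0) || length(sets) == 0) {
    stop("sample sheet defines an empty replicate set")
  }
  keep <- rep(FALSE, nrow(calls))
  for (s in sets) {
    cols <- paste0("reads_", s)
    keep <- keep | apply(calls[, cols, drop = FALSE] >= min_reads, 1, all)
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an annotation index from GTF annotation
#'
#' @param annotation A `GRanges` (from [read_gtf()]) or a GTF file path.
#' @return List of class `annotation_index` with `genes` and `exons`
#'   `GRanges`, each carrying `gene_id`.
#' @export
annotation_index <- function(annotation) {
  if (is.character(annotation)) annotation <- read_gtf(annotation)
  type <- S4Vectors::mcols(annotation)$type
  genes <- annotation[type == "gene"]
  exons <- annotation[type == "exon"]
  if (length(genes) == 0 && length(exons) > 0) {
    # GTFs without explicit gene rows: infer gene spans from exons
    spl <- S4Vectors::split(exons, S4Vectors::mcols(exons)$gene_id)
    genes <- unlist(range(spl))
    S4Vectors::mcols(genes)$gene_id <- names(genes)
  }
  structure(list(genes = genes, exons = exons), class = "annotation_index")
}

#' Classify circRNAs as exonic, intronic or intergenic
#'
#' A circRNA is \emph{exonic} when both back-splice endpoints coincide
#' with annotated exon boundaries (an exon start and an exon end) of one
#' gene; \emph{intronic} when its span lies entirely inside a single
#' intron of one gene; \emph{intergenic} when the span overlaps no gene.
#' Ambiguous cases (partial overlap) fall back to exonic if at least 1 bp
#' of exon overlap exists, else intronic; with several candidate host
#' genes the one with the longest overlap wins. Classification ignores
#' strand: the genomic position, not the transcribed strand, determines
#' the class. Calls on chromosomes absent from the annotation are classed
#' intergenic with a warning.
#'
#' @param calls Caller table (typically the filtered intersection).
#' @param annotation An [annotation_index()], `GRanges`, or GTF path.
#' @return `data.frame` of circRNA records: `circ_id`
#'   (`chrom:start|end:strand`), locus columns, `class`, `host_gene`, and
#'   the per-sample junction-read columns.
#' @export
classify_catalog <- function(calls, annotation) {
  if (!inherits(annotation, "annotation_index")) {
    annotation <- annotation_index(annotation)
  }
  calls <- validate_bsj_table(calls)
  n <- nrow(calls)
  cls <- character(n); host <- rep(NA_character_, n)
  if (n == 0) {
    return(cbind(data.frame(circ_id = character(0)), calls[, 0],
                 class = character(0), host_gene = character(0)))
  }

  if (!all(calls$chrom %in% as.character(
        GenomicRanges::seqnames(annotation$genes)))) {
    warning("calls on chromosomes absent from the annotation ",
            "are classified intergenic")
  }
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$start, calls$end))
  genes <- annotation$genes
  exons <- annotation$exons
  # seqlevel-mismatch warnings are expected for unannotated chromosomes;
  # the explicit warning above already covers them
  hits_gene <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, genes, ignore.strand = TRUE))
  hits_exon <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, exons, ignore.strand = TRUE))
  gene_ids <- S4Vectors::mcols(genes)$gene_id
  exon_gene <- S4Vectors::mcols(exons)$gene_id

  for (i in seq_len(n)) {
    gi <- S4Vectors::subjectHits(hits_gene)[S4Vectors::queryHits(hits_gene) == i]
    if (length(gi) == 0) { cls[i] <- "intergenic"; next }
    ei <- S4Vectors::subjectHits(hits_exon)[S4Vectors::queryHits(hits_exon) == i]

    # exonic: both endpoints on exon boundaries of one gene
    exonic_gene <- NA_character_
    for (g in gi) {
      gex <- exons[exon_gene == gene_ids[g]]
      if (any(GenomicRanges::start(gex) == calls$start[i]) &&
          any(GenomicRanges::end(gex) == calls$end[i])) {
        exonic_gene <- gene_ids[g]; break
      }
    }
    if (!is.na(exonic_gene)) {
      cls[i] <- "exonic"; host[i] <- exonic_gene; next
    }

    # intronic: inside a single gene, overlapping none of its exons
    within_gene <- gi[GenomicRanges::start(genes)[gi] <= calls$start[i] &
                      GenomicRanges::end(genes)[gi] >= calls$end[i]]
    intronic_gene <- NA_character_
    for (g in within_gene) {
      gex_i <- which(exon_gene == gene_ids[g])
      if (!any(gex_i %in% ei)) { intronic_gene <- gene_ids[g]; break }
    }
    if (!is.na(intronic_gene)) {
      cls[i] <- "intronic"; host[i] <- intronic_gene; next
    }

    # ambiguity rule: exon overlap wins, then longest-overlap gene
    ov <- GenomicRanges::pintersect(
      rep(gr[i], length(gi)), genes[gi], resolve.empty = "start.x")
    best <- gi[which.max(GenomicRanges::width(ov))]
    cls[i] <- if (length(ei) > 0) "exonic" else "intronic"
    host[i] <- gene_ids[best]
  }

  rcols <- grep("^reads_", names(calls), value = TRUE)
  out <- data.frame(
    circ_id = sprintf("%s:%d|%d:%s", calls$chrom, calls$start, calls$end,
                      calls$strand),
    chrom = calls$chrom, start = calls$start, end = calls$end,
    strand = calls$strand, class = cls, host_gene = host,
    stringsAsFactors = FALSE)
  cbind(out, calls[, rcols, drop = FALSE])
}

#' Class composition of a circRNA catalogue
#'
#' @param catalog `data.frame` from [classify_catalog()], or a named vector
#'   of class counts.
#' @return List with `counts`, `percentages` (rounded half-up to 2
#'   decimals) and `total`. Percentages are computed on the unrounded
#'   values, so they sum to 100 within rounding error.
#' @examples
#' composition_report(c(exonic = 9625, intronic = 730, intergenic = 1265))
#' @export
composition_report <- function(catalog) {
  lv <- c("exonic", "intronic", "intergenic")
  if (is.data.frame(catalog)) {
    if (nrow(catalog) == 0) stop("empty catalogue")
    counts <- table(factor(catalog$class, levels = lv))
  } else {
    if (sum(catalog) == 0) stop("empty catalogue")
    counts <- table(factor(rep(names(catalog), catalog), levels = lv))
  }
  counts <- setNames(as.integer(counts), lv)
  total <- sum(counts)
  pct <- round_half_up(100 * counts / total, 2)
  list(counts = counts, percentages = pct, total = total)
}

#' Write a composition report as JSON
#' @param report Result of [composition_report()].
#' @param path Output file.
#' @export
write_composition_json <- function(report, path) {
  jsonlite::write_json(
    list(total = report$total, counts = as.list(report$counts),
         percentages = as.list(report$percentages)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
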