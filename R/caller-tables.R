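#' Emit synthetic back-splice-junction caller tables and gene annotation
#'
#' Builds a small synthetic genome annotation (non-overlapping multi-exon
#' genes laid out along chromosomes with intergenic gaps) and places every
#' true circRNA of the simulation according to its ground-truth class:
#' exonic circRNAs span annotated exon boundaries of one gene, intronic
#' ones lie strictly inside a single intron, intergenic ones fall outside
#' any gene. Two caller tables are then produced in the style of
#' independent back-splice-junction callers: every true circRNA appears in
#' both tables with identical coordinates, while caller-specific false
#' positives (fractions `fp_frac_a` / `fp_frac_b` of the true count)
#' appear in exactly one table. Per-sample junction-read counts are drawn
#' so that a `low_support_frac` subset of true circRNAs fails the
#' "junction reads >= 2 in all samples of at least one replicate set" rule
#' in every replicate set.
#'
#' @param truth Ground truth from [simulate_counts()].
#' @param config The matching [sim_config()].
#' @return List with elements `calls_a`, `calls_b` (caller tables:
#'   `chrom`, `start`, `end`, `strand`, `caller`, one `reads_<sample>`
#'   column per sample; 1-based inclusive coordinates), `annotation`
#'   (a `GRanges` with gene/transcript/exon rows, exportable as GTF),
#'   `loci` (`data.frame` mapping each true `circ_id` to its locus, class
#'   and host gene), and `low_support` (ids of deliberately under-supported
#'   circRNAs).
#' @examples
#' cfg <- sim_config(n_circ = 30, n_mirna = 10, n_mrna = 40, n_triplets = 2)
#' sim <- simulate_counts(cfg)
#' tabs <- emit_caller_tables(sim$truth, cfg)
#' @export
emit_caller_tables <- function(truth, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 2L))

  classes <- truth$classes
  circ_ids <- names(classes)
  n_circ <- length(circ_ids)
  n_ex <- sum(classes == "exonic")
  n_in <- sum(classes == "intronic")

  genome <- build_synthetic_genome(
    n_genes = max(20L, ceiling(n_ex / 3), ceiling(n_in / 2)))

  loci <- place_circ_loci(circ_ids, classes, genome)

  sheet <- make_sample_sheet(config)
  n_fp_a <- round(config$fp_frac_a * n_circ)
  n_fp_b <- round(config$fp_frac_b * n_circ)
  fp_a <- place_intergenic(genome, n_fp_a, avoid = loci)
  fp_b <- place_intergenic(genome, n_fp_b,
                           avoid = rbind(loci[, names(fp_a)], fp_a))

  n_low <- round(config$low_support_frac * n_circ)
  low_ids <- if (n_low > 0) sample(circ_ids, n_low) else character(0)

  reads_for <- function(n_calls, which_low = logical(n_calls)) {
    m <- matrix(2L + rnbinom(n_calls * nrow(sheet), mu = 8, size = 2),
                nrow = n_calls)
    colnames(m) <- paste0("reads_", sheet$sample_id)
    sets <- interaction(sheet$group, sheet$timepoint, drop = TRUE)
    for (i in which(which_low)) {
      for (s in levels(sets)) {
        members <- which(sets == s)
        m[i, sample(members, 1)] <- sample(0:1, 1)
      }
    }
    m
  }

  # both callers count the same junction-spanning reads for a true
  # junction, so true calls share one reads matrix: a junction planted as
  # low-support stays low-support after the per-sample-max merge
  true_reads <- reads_for(n_circ, circ_ids %in% low_ids)
  true_tab <- loci[, c("chrom", "start", "end", "strand")]
  mk_table <- function(extra_fp, caller) {
    tab <- rbind(true_tab, extra_fp[, c("chrom", "start", "end", "strand")])
    fp_reads <- reads_for(nrow(extra_fp))
    cbind(data.frame(tab, caller = caller, stringsAsFactors = FALSE),
          as.data.frame(rbind(true_reads, fp_reads)))
  }

  list(calls_a = mk_table(fp_a, "callerA"),
       calls_b = mk_table(fp_b, "callerB"),
       annotation = genome$gtf,
       loci = loci,
       low_support = low_ids)
}

# Non-overlapping genes with 3-8 exons each, laid out left to right with
# intergenic gaps, 100 genes per chromosome.
build_synthetic_genome <- function(n_genes, genes_per_chrom = 100L) {
  genes <- vector("list", n_genes)
  pos <- 1L; chrom_i <- 1L
  for (g in seq_len(n_genes)) {
    if ((g - 1L) %% genes_per_chrom == 0L && g > 1L) {
      chrom_i <- chrom_i + 1L; pos <- 1L
    }
    gap <- sample(5000:20000, 1)
    start <- pos + gap
    n_exon <- sample(3:8, 1)
    exon_len <- sample(100:300, n_exon, replace = TRUE)
    intron_len <- if (n_exon > 1) sample(500:3000, n_exon - 1, replace = TRUE)
                  else integer(0)
    exon_start <- start + c(0L, cumsum(exon_len[-n_exon] + intron_len))
    exon_end <- exon_start + exon_len - 1L
    genes[[g]] <- list(
      gene_id = sprintf("gene_%04d", g),
      chrom = paste0("chr", chrom_i),
      strand = sample(c("+", "-"), 1),
      start = start, end = exon_end[n_exon],
      exon_start = exon_start, exon_end = exon_end)
    pos <- exon_end[n_exon]
  }
  gtf <- genome_to_granges(genes)
  list(genes = genes, gtf = gtf,
       chrom_len = vapply(split(vapply(genes, function(g) g$end, numeric(1)),
                                vapply(genes, function(g) g$chrom, character(1))),
                          max, numeric(1)))
}

genome_to_granges <- function(genes) {
  rows <- lapply(genes, function(g) {
    n <- length(g$exon_start)
    data.frame(
      chrom = g$chrom,
      start = c(g$start, g$start, g$exon_start),
      end = c(g$end, g$end, g$exon_end),
      strand = g$strand,
      type = c("gene", "transcript", rep("exon", n)),
      gene_id = g$gene_id,
      transcript_id = c(NA, rep(paste0(g$gene_id, ".t1"), n + 1)),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$transcript_id <- df$transcript_id
  S4Vectors::mcols(gr)$source <- "cernet_sim"
  gr
}

place_circ_loci <- function(circ_ids, classes, genome) {
  genes <- genome$genes
  multi_exon <- which(vapply(genes, function(g) length(g$exon_start) > 1,
                             logical(1)))
  used <- new.env(parent = emptyenv())
  claim <- function(chrom, start, end, strand) {
    key <- paste(chrom, start, end, strand, sep = ":")
    if (!is.null(used[[key]])) return(FALSE)
    used[[key]] <- TRUE
    TRUE
  }
  out <- vector("list", length(circ_ids))
  for (i in seq_along(circ_ids)) {
    cls <- classes[[circ_ids[i]]]
    repeat {
      if (cls == "exonic") {
        g <- genes[[sample(length(genes), 1)]]
        n <- length(g$exon_start)
        ij <- sort(sample(n, 2, replace = TRUE))
        loc <- list(chrom = g$chrom, start = g$exon_start[ij[1]],
                    end = g$exon_end[ij[2]], strand = g$strand,
                    host_gene = g$gene_id)
      } else if (cls == "intronic") {
        g <- genes[[sample(multi_exon, 1)]]
        k <- sample(length(g$exon_start) - 1, 1)
        lo <- g$exon_end[k] + 2L
        hi <- g$exon_start[k + 1] - 2L
        if (hi - lo < 50L) next
        a <- sample(lo:(hi - 50L), 1)
        b <- a + sample(50:min(400L, hi - a), 1) - 1L
        loc <- list(chrom = g$chrom, start = a, end = min(b, hi),
                    strand = g$strand, host_gene = g$gene_id)
      } else {
        loc <- sample_intergenic(genome)
        loc$host_gene <- NA_character_
      }
      if (claim(loc$chrom, loc$start, loc$end, loc$strand)) break
    }
    out[[i]] <- data.frame(circ_id = circ_ids[i], chrom = loc$chrom,
                           start = loc$start, end = loc$end,
                           strand = loc$strand, class = cls,
                           host_gene = loc$host_gene,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# a random locus in an intergenic gap, >= 1 kb away from flanking genes
sample_intergenic <- function(genome) {
  genes <- genome$genes
  repeat {
    gi <- sample(length(genes), 1)
    g <- genes[[gi]]
    gap_start <- g$end + 1000L
    next_start <- if (gi < length(genes) &&
                      genes[[gi + 1]]$chrom == g$chrom)
      genes[[gi + 1]]$start else g$end + 25000L
    gap_end <- next_start - 1000L
    if (gap_end - gap_start < 300L) next
    len <- sample(200:1000, 1)
    if (gap_end - gap_start < len) next
    a <- sample(gap_start:(gap_end - len), 1)
    return(list(chrom = g$chrom, start = a, end = a + len - 1L,
                strand = sample(c("+", "-"), 1)))
  }
}

place_intergenic <- function(genome, n, avoid) {
  keys <- paste(avoid$chrom, avoid$start, avoid$end, avoid$strand, sep = ":")
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    loc <- sample_intergenic(genome)
    key <- paste(loc$chrom, loc$start, loc$end, loc$strand, sep = ":")
    if (key %in% keys) next
    keys <- c(keys, key)
    out[[i]] <- as.data.frame(loc, stringsAsFactors = FALSE)
    i <- i + 1L
  }
  if (n == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  do.call(rbind, out)
}
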