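# Shared fixtures: small simulation configs, hand-built annotation, and
# brute-force oracle implementations kept deliberately independent of the
# package internals they check.

tiny_config <- function(...) {
  args <- list(n_circ = 40L, n_mirna = 20L, n_mrna = 60L, n_reps = 4L,
               n_triplets = 2L, seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# one gene on chr1 with 4 exons at fixed coordinates (introns between),
# plus a second single-exon-free zone beyond 50 kb
toy_annotation <- function() {
  exon_start <- c(1001, 2001, 3001, 4001)
  exon_end <- c(1200, 2200, 3200, 4200)
  df <- data.frame(
    start = c(1001, 1001, exon_start),
    end = c(4200, 4200, exon_end),
    type = c("gene", "transcript", rep("exon", 4)))
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(df$start, df$end), "+")
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$gene_id <- "geneX"
  S4Vectors::mcols(gr)$transcript_id <- c(NA, rep("geneX.t1", 5))
  gr
}

toy_sheet <- function(n_reps = 2) {
  g <- expand.grid(replicate = seq_len(n_reps),
                   group = c("Sham", "ICH"),
                   timepoint = c("day7", "day28"),
                   stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%s_r%d", g$group, g$timepoint,
                                 g$replicate),
             group = g$group, timepoint = g$timepoint,
             replicate = g$replicate, stringsAsFactors = FALSE)
}

bsj_row <- function(chrom, start, end, strand, caller, reads) {
  cbind(data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   caller = caller, stringsAsFactors = FALSE),
        as.data.frame(as.list(reads)))
}

random_bsj_table <- function(n, sheet, caller = "X",
                             chroms = c("chr1", "chr2"), max_pos = 1000) {
  reads <- matrix(sample(0:10, n * nrow(sheet), replace = TRUE), nrow = n)
  colnames(reads) <- paste0("reads_", sheet$sample_id)
  start <- sample(max_pos, n, replace = TRUE)
  cbind(data.frame(chrom = sample(chroms, n, replace = TRUE),
                   start = start,
                   end = start + sample(50:500, n, replace = TRUE),
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   caller = caller, stringsAsFactors = FALSE),
        as.data.frame(reads))
}

# a minimal DE table with the attributes the pipeline relies on
fake_de_table <- function(ids, directions, timepoint = "day7",
                          species = "circRNA", p_adj = NULL) {
  stopifnot(length(ids) == length(directions))
  out <- data.frame(feature_id = ids,
                    log2fc = ifelse(directions == "up", 2,
                                    ifelse(directions == "down", -2, 0)),
                    p_raw = ifelse(directions == "ns", 0.5, 1e-4),
                    p_adj = if (is.null(p_adj))
                      ifelse(directions == "ns", 0.8, 1e-3) else p_adj,
                    direction = directions, stringsAsFactors = FALSE)
  attr(out, "timepoint") <- timepoint
  attr(out, "species") <- species
  attr(out, "alpha") <- 0.05
  class(out) <- c("de_table", "data.frame")
  out
}

# ---- independent brute-force oracles -------------------------------------

# all-pairs caller intersection (first unused match in b, in input order)
oracle_intersect <- function(a, b, slack = 0) {
  rcols <- grep("^reads_", names(a), value = TRUE)
  a <- a[order(a$chrom, a$start, a$end), , drop = FALSE]
  b <- b[order(b$chrom, b$start, b$end), , drop = FALSE]
  used <- rep(FALSE, nrow(b))
  res <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (used[j]) next
      if (a$chrom[i] == b$chrom[j] && a$strand[i] == b$strand[j] &&
          abs(a$start[i] - b$start[j]) <= slack &&
          abs(a$end[i] - b$end[j]) <= slack) {
        used[j] <- TRUE
        row <- a[i, , drop = FALSE]
        row[, rcols] <- pmax(unlist(a[i, rcols]), unlist(b[j, rcols]))
        res[[length(res) + 1]] <- row
        break
      }
    }
  }
  if (!length(res)) return(a[0, , drop = FALSE])
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# exhaustive evaluation of the replicate-set junction filter
oracle_filter <- function(calls, sheet, min_reads = 2) {
  sets <- split(sheet$sample_id, paste(sheet$group, sheet$timepoint))
  keep <- vapply(seq_len(nrow(calls)), function(i) {
    any(vapply(sets, function(s) {
      all(unlist(calls[i, paste0("reads_", s)]) >= min_reads)
    }, logical(1)))
  }, logical(1))
  calls[keep, , drop = FALSE]
}

# naive sliding-window seed-site finder (position by position)
oracle_seed_sites <- function(mir_seq, target_seq) {
  comp <- c(A = "T", C = "G", G = "C", U = "A")
  mir <- strsplit(mir_seq, "")[[1]]
  tgt <- strsplit(target_seq, "")[[1]]
  pairs_at <- function(tpos, mpos) {
    tpos >= 1 && tpos <= length(tgt) && tgt[tpos] == comp[[mir[mpos]]]
  }
  out <- data.frame(offset = integer(0), site_type = character(0))
  for (p in seq_len(length(tgt))) {
    # candidate 7mer: target p..p+6 pairs miR 8..2
    if (p + 6 <= length(tgt) &&
        all(vapply(0:6, function(k) pairs_at(p + k, 8 - k), logical(1)))) {
      a1 <- p + 7
      type <- if (a1 <= length(tgt) && tgt[a1] == "A") "8mer" else "7mer-m8"
      out <- rbind(out, data.frame(offset = p - 1L, site_type = type))
    }
    # candidate 7mer-A1: target p..p+5 pairs miR 7..2, then A, no m8
    if (p + 6 <= length(tgt) &&
        all(vapply(0:5, function(k) pairs_at(p + k, 7 - k), logical(1))) &&
        tgt[p + 6] == "A" && !pairs_at(p - 1, 8)) {
      out <- rbind(out, data.frame(offset = p - 1L, site_type = "7mer-A1"))
    }
  }
  out
}

# step-up BH computed from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# nested-loop triplet assembly
oracle_triplets <- function(cm, mm) {
  res <- list()
  for (i in seq_len(nrow(cm))) {
    for (j in seq_len(nrow(mm))) {
      if (cm$mir_id[i] == mm$mir_id[j]) {
        res[[length(res) + 1]] <- data.frame(
          circ_id = cm$circ_id[i], mir_id = cm$mir_id[i],
          mrna_id = mm$mrna_id[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(circ_id = character(0), mir_id = character(0),
                      mrna_id = character(0)))
  }
  out <- unique(do.call(rbind, res))
  out[order(out$circ_id, out$mir_id, out$mrna_id), , drop = FALSE]
}

# correlation and t-test p from the covariance formula and t CDF
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}
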