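# miRNA seed-match target-site prediction on circRNA exonic sequences and
# mRNA 3'UTRs, and assembly of DE-filtered pair candidates.

#' Find canonical miRNA seed-match sites in a target sequence
#'
#' Scans the transcribed sense strand of a DNA target for canonical seed
#' sites of one miRNA. The seed is miRNA positions 2--8 (7 nt). Site
#' types follow the canonical definitions:
#' \describe{
#'   \item{8mer}{perfect Watson-Crick match of positions 2--8 plus an `A`
#'     in the target opposite miRNA position 1.}
#'   \item{7mer-m8}{perfect match of positions 2--8 without the A1.}
#'   \item{7mer-A1}{perfect match of positions 2--7 plus the A1 (and no
#'     match at position 8, which would make it an 8mer).}
#' }
#' Matches are located as occurrences of the DNA reverse complement of the
#' seed; overlapping occurrences are all reported. The score is the site
#' type rank: 8mer = 3, 7mer-m8 = 2, 7mer-A1 = 1. With
#' `allow_wobble = TRUE`, G:U wobble pairs are also accepted within the
#' seed match (a target `T` opposite a miRNA `G`, or a target `G`
#' opposite a miRNA `U`).
#'
#' @param mir_id miRNA identifier.
#' @param mir_seq Mature miRNA sequence, RNA alphabet (ACGU), 18--26 nt.
#' @param target_id Target identifier.
#' @param target_seq Target sequence, DNA alphabet (ACGT), sense strand.
#' @param target_kind `"circ"` or `"mrna"`.
#' @param allow_wobble Permit G:U wobble pairs in the seed match
#'   (default `FALSE`).
#' @return `data.frame` of sites: `mir_id`, `target_id`, `target_kind`,
#'   `offset` (0-based start of the matched region in the target),
#'   `site_type`, `score`.
#' @examples
#' find_seed_sites("let7", "UGAGGUAGUAGGUUGUAUAGUU", "t1",
#'                 paste0(strrep("G", 40), "CTACCTC", strrep("G", 40)),
#'                 "mrna")
#' @export
find_seed_sites <- function(mir_id, mir_seq, target_id, target_seq,
                            target_kind = c("circ", "mrna"),
                            allow_wobble = FALSE) {
  target_kind <- match.arg(target_kind)
  check_alphabet(mir_seq, "ACGU", "miRNA (RNA)")
  check_alphabet(target_seq, "ACGT", "target (DNA)")
  mir_seq <- toupper(mir_seq); target_seq <- toupper(target_seq)
  nc <- nchar(mir_seq)
  if (nc < 18 || nc > 26) stop("miRNA sequence must be 18-26 nt")
  tlen <- nchar(target_seq)

  seed7 <- substr(mir_seq, 2, 8)   # positions 2-8
  seed6 <- substr(mir_seq, 2, 7)   # positions 2-7
  m8_comp <- comp_base(substr(mir_seq, 8, 8), allow_wobble)

  hit7 <- seed_match_positions(target_seq, seed7, allow_wobble)
  sites <- list()
  for (p in hit7) {              # p: 1-based start of the 7-nt match
    a1 <- p + 7                  # target base opposite miRNA position 1
    a1_is_A <- a1 <= tlen && substr(target_seq, a1, a1) == "A"
    sites[[length(sites) + 1]] <- data.frame(
      offset = p - 1L,
      site_type = if (a1_is_A) "8mer" else "7mer-m8",
      stringsAsFactors = FALSE)
  }
  # 7mer-A1: 6-nt match (2-7) + A1, not extensible to position 8
  hit6 <- seed_match_positions(target_seq, seed6, allow_wobble)
  for (q in hit6) {
    a1 <- q + 6
    if (a1 > tlen || substr(target_seq, a1, a1) != "A") next
    m8_pos <- q - 1
    m8_matches <- m8_pos >= 1 &&
      substr(target_seq, m8_pos, m8_pos) %in% m8_comp
    if (m8_matches) next         # already counted as 8mer / 7mer-m8
    sites[[length(sites) + 1]] <- data.frame(
      offset = q - 1L, site_type = "7mer-A1", stringsAsFactors = FALSE)
  }
  if (length(sites) == 0) {
    return(data.frame(mir_id = character(0), target_id = character(0),
                      target_kind = character(0), offset = integer(0),
                      site_type = character(0), score = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, sites)
  out <- data.frame(mir_id = mir_id, target_id = target_id,
                    target_kind = target_kind, out,
                    stringsAsFactors = FALSE)
  out$score <- c(`8mer` = 3L, `7mer-m8` = 2L, `7mer-A1` = 1L)[out$site_type]
  out <- out[order(out$offset, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 1-based start positions (overlapping included) at which the reverse
# complement of an RNA seed fragment matches the DNA target
seed_match_positions <- function(target, seed_rna, allow_wobble) {
  if (!allow_wobble) {
    pat <- paste0("(?=", revcomp_rna_to_dna(seed_rna), ")")
  } else {
    bases <- rev(strsplit(seed_rna, "")[[1]])
    pat <- paste0("(?=",
                  paste(vapply(bases, function(b) {
                    alt <- comp_base(b, TRUE)
                    if (length(alt) > 1) paste0("[", paste(alt, collapse = ""), "]")
                    else alt
                  }, character(1)), collapse = ""), ")")
  }
  m <- gregexpr(pat, target, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# DNA bases in the target that pair a given miRNA (RNA) base; with wobble,
# G:U pairs (miR G : target T is already Watson-Crick in DNA space, so the
# wobble additions are target T for miR G and target G for miR U)
comp_base <- function(rna_base, allow_wobble = FALSE) {
  wc <- c(A = "T", C = "G", G = "C", U = "A")
  out <- wc[[rna_base]]
  if (allow_wobble) {
    if (rna_base == "G") out <- c(out, "T")
    if (rna_base == "U") out <- c(out, "G")
  }
  out
}

check_alphabet <- function(seq, allowed, what) {
  if (length(seq) != 1 || !is.character(seq) || nchar(seq) == 0) {
    stop("invalid ", what, " sequence")
  }
  if (grepl(paste0("[^", allowed, "]"), toupper(seq))) {
    stop(what, " sequence contains characters outside [", allowed, "]")
  }
}

#' Find all seed sites of a miRNA set against a target set
#'
#' Vectorised driver over [find_seed_sites()].
#'
#' @param mirnas Named character vector of miRNA sequences (RNA).
#' @param targets Named character vector of target sequences (DNA).
#' @param target_kind `"circ"` or `"mrna"`.
#' @param allow_wobble Passed through.
#' @return Combined site `data.frame`.
#' @export
find_all_sites <- function(mirnas, targets, target_kind,
                           allow_wobble = FALSE) {
  res <- list()
  for (mid in names(mirnas)) {
    for (tid in names(targets)) {
      s <- find_seed_sites(mid, mirnas[[mid]], tid, targets[[tid]],
                           target_kind, allow_wobble)
      if (nrow(s)) res[[length(res) + 1]] <- s
    }
  }
  if (length(res) == 0) {
    return(find_seed_sites("x", strrep("A", 20), "y", strrep("C", 30),
                           target_kind)[0, ])
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Filter site candidates to differentially expressed pairs
#'
#' Keeps a circ--miR pair iff at least one predicted site exists and both
#' members are differentially expressed (direction not `ns`) at the same
#' timepoint; likewise for miR--mRNA pairs. Pairs are deduplicated to one
#' row per (miRNA, target) with the number of supporting sites retained.
#'
#' @param sites Site table from [find_all_sites()] (both kinds may be
#'   mixed; `target_kind` separates them).
#' @param de_circ,de_mir,de_mrna `de_table`s for the same timepoint.
#' @return List with `circ_mir` and `mir_mrna` pair `data.frame`s
#'   (`mir_id`, target id column, `site_count`, `best_score`), carrying
#'   the timepoint as an attribute.
#' @export
pair_candidates <- function(sites, de_circ, de_mir, de_mrna) {
  tps <- c(attr(de_circ, "timepoint"), attr(de_mir, "timepoint"),
           attr(de_mrna, "timepoint"))
  if (length(unique(tps)) != 1) {
    stop("DE tables come from different timepoints: ",
         paste(tps, collapse = ", "))
  }
  de_ids <- function(tab) tab$feature_id[tab$direction != "ns"]
  mir_ok <- de_ids(de_mir)
  dedup <- function(s, target_ok, target_col) {
    s <- s[s$mir_id %in% mir_ok & s$target_id %in% target_ok, , drop = FALSE]
    if (nrow(s) == 0) {
      out <- data.frame(mir_id = character(0), t = character(0),
                        site_count = integer(0), best_score = integer(0),
                        stringsAsFactors = FALSE)
      names(out)[2] <- target_col
      return(out)
    }
    key <- paste(s$mir_id, s$target_id)
    agg <- do.call(rbind, lapply(split(s, key), function(g) {
      data.frame(mir_id = g$mir_id[1], t = g$target_id[1],
                 site_count = nrow(g), best_score = max(g$score),
                 stringsAsFactors = FALSE)
    }))
    names(agg)[2] <- target_col
    agg <- agg[order(agg$mir_id, agg[[target_col]]), , drop = FALSE]
    rownames(agg) <- NULL
    agg
  }
  out <- list(
    circ_mir = dedup(sites[sites$target_kind == "circ", , drop = FALSE],
                     de_ids(de_circ), "circ_id"),
    mir_mrna = dedup(sites[sites$target_kind == "mrna", , drop = FALSE],
                     de_ids(de_mrna), "mrna_id"))
  attr(out, "timepoint") <- tps[1]
  out
}
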