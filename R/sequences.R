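#' Emit miRNA, circRNA and 3'UTR sequences with planted target sites
#'
#' Generates random-background sequences for every feature of the
#' simulation: mature miRNA sequences in RNA alphabet (18--26 nt, per the
#' size range of small-RNA libraries), circRNA exonic sequences and mRNA
#' 3'UTR sequences in DNA alphabet. For every planted sponge triplet the
#' DNA reverse complement of the miRNA seed (positions 2--8) is embedded at
#' a recorded offset in both the circRNA sequence and the mRNA 3'UTR, so
#' [find_seed_sites()] is guaranteed to recover the planted sites.
#'
#' @param truth Ground truth from [simulate_counts()] (the `truth` element).
#' @param config The matching [sim_config()].
#' @param circ_len,utr_len Lengths (nt) of the circRNA exonic and 3'UTR
#'   background sequences.
#' @return List with elements `mirna` (named RNA strings), `circ`, `utr`
#'   (named DNA strings), and `sites`: a `data.frame` of planted site
#'   coordinates (`mir_id`, `target_id`, `target_kind`, `offset`, 0-based).
#' @examples
#' cfg <- sim_config(n_circ = 10, n_mirna = 5, n_mrna = 10, n_triplets = 2)
#' sim <- simulate_counts(cfg)
#' seqs <- emit_sequences(sim$truth, cfg)
#' @export
emit_sequences <- function(truth, config, circ_len = 500L, utr_len = 800L) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))
  if (circ_len < 8L || utr_len < 8L) {
    stop("target sequences must be at least as long as a seed site")
  }

  mir_ids  <- sprintf("mir_%04d",  seq_len(config$n_features["miRNA"]))
  circ_ids <- sprintf("circ_%05d", seq_len(config$n_features["circRNA"]))
  mrna_ids <- sprintf("mrna_%05d", seq_len(config$n_features["mRNA"]))

  mir_len <- sample(18:26, length(mir_ids), replace = TRUE)
  mirna <- setNames(random_seq(length(mir_ids), mir_len,
                               c("A", "C", "G", "U")), mir_ids)
  circ <- setNames(random_seq(length(circ_ids), rep(circ_len, length(circ_ids)),
                              c("A", "C", "G", "T")), circ_ids)
  utr <- setNames(random_seq(length(mrna_ids), rep(utr_len, length(mrna_ids)),
                             c("A", "C", "G", "T")), mrna_ids)

  sites <- data.frame(mir_id = character(0), target_id = character(0),
                      target_kind = character(0), offset = integer(0),
                      stringsAsFactors = FALSE)
  tr <- truth$triplets
  if (!is.null(tr) && nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      seed_rna <- substr(mirna[[tr$mir_id[i]]], 2, 8)
      site_dna <- revcomp_rna_to_dna(seed_rna)
      pc <- plant_site(circ[[tr$circ_id[i]]], site_dna)
      circ[tr$circ_id[i]] <- as.character(pc)
      pu <- plant_site(utr[[tr$mrna_id[i]]], site_dna)
      utr[tr$mrna_id[i]] <- as.character(pu)
      sites <- rbind(sites, data.frame(
        mir_id = tr$mir_id[i],
        target_id = c(tr$circ_id[i], tr$mrna_id[i]),
        target_kind = c("circ", "mrna"),
        offset = c(attr(pc, "offset"), attr(pu, "offset")),
        stringsAsFactors = FALSE))
    }
  }
  list(mirna = mirna, circ = circ, utr = utr, sites = sites)
}

# overwrite a random window of `target` with `site`; the offset is
# recoverable because the site string then occurs at that position
plant_site <- function(target, site) {
  n <- nchar(target); k <- nchar(site)
  if (n < k) stop("target sequence shorter than the site to plant")
  off <- sample.int(n - k + 1L, 1L) - 1L  # 0-based
  out <- paste0(substr(target, 1, off), site,
                substr(target, off + k + 1L, n))
  attr(out, "offset") <- off
  out
}
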