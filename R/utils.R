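# Shared internal helpers.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages use the
#' conventional half-up rule (82.825 -> 82.83).
#' @noRd
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse complement of a DNA string
#' @noRd
revcomp_dna <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    s <- chartr("ACGTacgt", "TGCAtgca", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' DNA reverse complement of an RNA string (U treated as T)
#' @noRd
revcomp_rna_to_dna <- function(x) {
  revcomp_dna(chartr("Uu", "Tt", x))
}

#' Random sequence over an alphabet
#' @noRd
random_seq <- function(n, len, alphabet) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len[min(i, length(len))], replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Stable derived seed (kept below 2^31)
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
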