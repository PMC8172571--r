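#' Simulation configuration
#'
#' Parameters of the synthetic multi-omic experiment emulated by
#' [simulate_counts()], [emit_sequences()] and [emit_caller_tables()]: a
#' two-group (Sham vs ICH), two-timepoint (day7 / day28) rat-brain design
#' with `n_reps` biological replicates per group and timepoint, negative
#' binomial counts for three RNA species, a planted fraction of
#' differentially expressed features per species, and planted ceRNA sponge
#' triplets whose members are driven by a shared latent activity so that
#' circ--miR and miR--mRNA expression correlate negatively.
#'
#' @param n_circ,n_mirna,n_mrna Number of circRNA / miRNA / mRNA features.
#'   Defaults mirror the catalogue sizes of the emulated study (11,620
#'   circRNAs, 918 miRNAs, 28,937 mRNAs).
#' @param n_reps Biological replicates per group per timepoint (default 4).
#' @param de_fraction Fraction of features planted as differentially
#'   expressed, a single number or a named vector with entries `circRNA`,
#'   `miRNA`, `mRNA`.
#' @param log2fc_range Range (absolute log2 fold change) from which planted
#'   effect sizes are drawn uniformly.
#' @param nb_dispersion Negative binomial dispersion (1/size); counts have
#'   variance `mu + nb_dispersion * mu^2`.
#' @param depth_mean Expected library size per sample; realised library
#'   sizes are drawn uniformly within +/-20% of this value.
#' @param n_triplets Number of planted sponge triplets.
#' @param sponge_strength Strength of the latent sponge activity in (0, 1]:
#'   a per-sample standard-normal activity shifts the log2 mean of the
#'   triplet's circRNA and mRNA by `+sponge_strength * z` and of its miRNA
#'   by `-sponge_strength * z`.
#' @param frac_exonic,frac_intronic,frac_intergenic circRNA class mix; must
#'   sum to 1. Defaults are the class proportions of the emulated study.
#' @param fp_frac_a,fp_frac_b Fractions (of the true circRNA count) of
#'   caller-specific false-positive calls added to caller A / B tables.
#' @param low_support_frac Fraction of true circRNAs generated with
#'   junction-read support below the >=2-in-all-replicates rule in every
#'   replicate set.
#' @param seed Integer RNG seed; all generator outputs are deterministic
#'   given the configuration.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_circ = 50, n_mirna = 20, n_mrna = 80, n_triplets = 3)
#' @export
sim_config <- function(n_circ = 11620L, n_mirna = 918L, n_mrna = 28937L,
                       n_reps = 4L,
                       de_fraction = c(circRNA = 0.015, miRNA = 0.065,
                                       mRNA = 0.022),
                       log2fc_range = c(1, 3),
                       nb_dispersion = 0.1,
                       depth_mean = 1e6,
                       n_triplets = 8L,
                       sponge_strength = 0.9,
                       frac_exonic = 0.8283,
                       frac_intronic = 0.0628,
                       frac_intergenic = 0.1089,
                       fp_frac_a = 0.15, fp_frac_b = 0.15,
                       low_support_frac = 0.1,
                       seed = 1L) {
  species <- c("circRNA", "miRNA", "mRNA")
  if (length(de_fraction) == 1L) {
    de_fraction <- setNames(rep(de_fraction, 3L), species)
  }
  if (!all(species %in% names(de_fraction))) {
    stop("de_fraction must be a single number or named for circRNA, miRNA, mRNA")
  }
  de_fraction <- de_fraction[species]
  cfg <- list(
    n_features = c(circRNA = as.integer(n_circ), miRNA = as.integer(n_mirna),
                   mRNA = as.integer(n_mrna)),
    n_reps = as.integer(n_reps),
    groups = c("Sham", "ICH"),
    timepoints = c("day7", "day28"),
    de_fraction = de_fraction,
    log2fc_range = sort(as.numeric(log2fc_range)),
    nb_dispersion = as.numeric(nb_dispersion),
    depth_mean = as.numeric(depth_mean),
    n_triplets = as.integer(n_triplets),
    sponge_strength = as.numeric(sponge_strength),
    class_fracs = c(exonic = frac_exonic, intronic = frac_intronic,
                    intergenic = frac_intergenic),
    fp_frac_a = as.numeric(fp_frac_a), fp_frac_b = as.numeric(fp_frac_b),
    low_support_frac = as.numeric(low_support_frac),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (any(cfg$n_features < 1L)) stop("feature counts must be positive")
  if (cfg$n_reps < 2L) stop("n_reps must be at least 2")
  if (any(cfg$de_fraction < 0 | cfg$de_fraction > 1)) {
    stop("de_fraction must lie in [0, 1]")
  }
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be non-negative")
  if (cfg$depth_mean <= 0) stop("depth_mean must be positive")
  if (cfg$n_triplets > min(cfg$n_features)) {
    stop("n_triplets must not exceed min(n_circ, n_mirna, n_mrna)")
  }
  if (cfg$n_triplets > 0 &&
      (cfg$sponge_strength <= 0 || cfg$sponge_strength > 1)) {
    stop("sponge_strength must lie in (0, 1]")
  }
  if (abs(sum(cfg$class_fracs) - 1) > 1e-9) {
    stop("circRNA class fractions must sum to 1")
  }
  if (any(cfg$class_fracs < 0)) stop("class fractions must be non-negative")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic ceRNA study configuration\n")
  cat(sprintf("  features : %d circRNA, %d miRNA, %d mRNA\n",
              x$n_features["circRNA"], x$n_features["miRNA"],
              x$n_features["mRNA"]))
  cat(sprintf("  design   : %s x %s, %d replicates per cell\n",
              paste(x$groups, collapse = "/"),
              paste(x$timepoints, collapse = "/"), x$n_reps))
  cat(sprintf("  DE       : %s\n",
              paste(sprintf("%s %.1f%%", names(x$de_fraction),
                            100 * x$de_fraction), collapse = ", ")))
  cat(sprintf("  triplets : %d planted, sponge strength %.2f\n",
              x$n_triplets, x$sponge_strength))
  cat(sprintf("  seed     : %d\n", x$seed))
  invisible(x)
}
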