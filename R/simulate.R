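#' Simulate circRNA / miRNA / mRNA count matrices with known ground truth
#'
#' Generates negative binomial count matrices for the three RNA species
#' under the Sham-vs-ICH, day7/day28 replicated design described by the
#' configuration, together with the ground truth needed to score every
#' downstream stage: which features are differentially expressed (and in
#' which direction), which (circ, miR, mRNA) triplets act as ceRNA sponges,
#' and the genomic class of every circRNA.
#'
#' Per-feature baseline abundances are drawn log-normal and scaled to the
#' per-sample library size (drawn within +/-20% of `depth_mean`). Planted
#' DE features have their ICH-group mean multiplied by `2^log2fc` at the
#' affected timepoint. Each planted triplet is driven, within each
#' timepoint, by its own per-sample standard-normal latent activity `z`:
#' the circRNA and mRNA log2 means are shifted by `+sponge_strength * z`
#' and the miRNA log2 mean by `-sponge_strength * z`, which induces the
#' negative circ--miR and miR--mRNA correlations that the ceRNA hub
#' selection looks for. Triplet members are always differentially expressed
#' at both timepoints with the coherent sponge pattern (circ and mRNA in
#' one direction, miRNA in the other).
#'
#' @param config A [sim_config()].
#' @return A list of class `cerna_sim` with elements
#'   \describe{
#'     \item{matrices}{named list of three `SummarizedExperiment` count
#'       matrices (`circRNA`, `miRNA`, `mRNA`; the mRNA matrix carries
#'       transcript lengths in `rowData` for FPKM).}
#'     \item{sample_sheet}{`data.frame` of sample metadata.}
#'     \item{truth}{ground truth: `de[[species]][[timepoint]]` tables,
#'       `triplets`, circRNA `classes`.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_counts(sim_config(n_circ = 40, n_mirna = 20, n_mrna = 60,
#'                                   n_triplets = 2, seed = 7))
#' dim(SummarizedExperiment::assay(sim$matrices$circRNA))
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)

  sheet <- make_sample_sheet(config)
  n_samp <- nrow(sheet)
  species <- names(config$n_features)

  ids <- list(
    circRNA = sprintf("circ_%05d", seq_len(config$n_features["circRNA"])),
    miRNA   = sprintf("mir_%04d",  seq_len(config$n_features["miRNA"])),
    mRNA    = sprintf("mrna_%05d", seq_len(config$n_features["mRNA"])))

  # planted sponge triplets: one feature per species per triplet,
  # coherent direction pattern (circ/mRNA = pattern, miRNA = -pattern)
  nt <- config$n_triplets
  trip_idx <- lapply(species, function(sp)
    if (nt > 0) sample(config$n_features[sp], nt) else integer(0))
  names(trip_idx) <- species
  pattern <- if (nt > 0) sample(c(1, -1), nt, replace = TRUE) else numeric(0)
  triplets <- data.frame(
    circ_id = ids$circRNA[trip_idx$circRNA],
    mir_id  = ids$miRNA[trip_idx$miRNA],
    mrna_id = ids$mRNA[trip_idx$mRNA],
    pattern = pattern,
    stringsAsFactors = FALSE)

  lib_sizes <- config$depth_mean * runif(n_samp, 0.8, 1.2)

  # latent sponge activity: per triplet, per timepoint, per sample
  z <- array(rnorm(nt * n_samp), dim = c(max(nt, 1L), n_samp))

  truth_de <- list()
  matrices <- list()
  for (sp in species) {
    n <- config$n_features[[sp]]
    abund <- rlnorm(n, meanlog = log(20), sdlog = 1.5)
    ti <- trip_idx[[sp]]
    if (length(ti)) {
      # sponge members sit in the upper abundance range so their
      # correlation signal is not drowned by shot noise
      abund[ti] <- pmax(abund[ti], quantile(abund, 0.8))
    }
    p <- abund / sum(abund)
    mu <- outer(p, lib_sizes)

    trip_sign <- if (sp == "miRNA") -pattern else pattern
    sp_de <- list()
    for (tp in config$timepoints) {
      in_tp <- sheet$timepoint == tp
      n_de <- round(config$de_fraction[[sp]] * n)
      extra <- setdiff(sample(n, n), ti)
      de_idx <- c(ti, extra[seq_len(max(0, n_de - length(ti)))])
      if (length(de_idx) == 0) {
        sp_de[[tp]] <- data.frame(feature_id = character(0),
                                  direction = character(0),
                                  log2fc = numeric(0))
        next
      }
      sgn <- c(trip_sign,
               sample(c(1, -1), max(0, length(de_idx) - length(ti)),
                      replace = TRUE))
      lfc <- sgn * runif(length(de_idx), config$log2fc_range[1],
                         config$log2fc_range[2])
      ich_tp <- in_tp & sheet$group == "ICH"
      mu[de_idx, ich_tp] <- mu[de_idx, ich_tp, drop = FALSE] *
        2^(lfc %o% rep(1, sum(ich_tp)))
      sp_de[[tp]] <- data.frame(
        feature_id = ids[[sp]][de_idx],
        direction = ifelse(lfc > 0, "up", "down"),
        log2fc = lfc, stringsAsFactors = FALSE)
    }
    if (length(ti)) {
      for (t in seq_along(ti)) {
        mu[ti[t], ] <- mu[ti[t], ] *
          2^(if (sp == "miRNA") -config$sponge_strength * z[t, ]
             else config$sponge_strength * z[t, ])
      }
    }
    counts <- matrix(
      if (config$nb_dispersion > 0)
        rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
      else stats::rpois(length(mu), lambda = mu),
      nrow = n,
      dimnames = list(ids[[sp]], sheet$sample_id))
    lengths <- if (sp == "mRNA") round(rlnorm(n, log(1500), 0.5)) else NULL
    matrices[[sp]] <- expression_matrix(counts, sheet, sp, lengths = lengths)
    truth_de[[sp]] <- sp_de
  }

  classes <- assign_circ_classes(ids$circRNA, config$class_fracs)

  structure(list(
    matrices = matrices,
    sample_sheet = sheet,
    truth = list(de = truth_de, triplets = triplets, classes = classes),
    config = config), class = "cerna_sim")
}

make_sample_sheet <- function(config) {
  g <- expand.grid(replicate = seq_len(config$n_reps),
                   group = config$groups,
                   timepoint = config$timepoints,
                   stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_r%d", g$group, g$timepoint, g$replicate),
    group = g$group, timepoint = g$timepoint, replicate = g$replicate,
    stringsAsFactors = FALSE)
}

# largest-remainder apportionment of n features to the class mix, so the
# realised counts sum to n and track the fractions as closely as possible
assign_circ_classes <- function(circ_ids, fracs) {
  n <- length(circ_ids)
  raw <- fracs * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    order_rem <- order(raw - cnt, decreasing = TRUE)
    cnt[order_rem[seq_len(rem)]] <- cnt[order_rem[seq_len(rem)]] + 1
  }
  labels <- rep(names(fracs), cnt)
  setNames(sample(labels), circ_ids)
}

#' @export
print.cerna_sim <- function(x, ...) {
  cat("Synthetic ceRNA study\n")
  for (sp in names(x$matrices)) {
    cat(sprintf("  %-7s: %d features x %d samples\n", sp,
                nrow(x$matrices[[sp]]), ncol(x$matrices[[sp]])))
  }
  cat(sprintf("  planted triplets: %d\n", nrow(x$truth$triplets)))
  invisible(x)
}
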