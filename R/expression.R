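# Normalization (TPM / FPKM), negative binomial differential expression
# with Benjamini-Hochberg correction, and the DDCT fold-change utility.

#' TPM normalization
#'
#' Normalized expression level = mapped read count * 1e6 / libsize, where
#' libsize is the per-sample sum of read counts of the same RNA species.
#' Every normalized column therefore sums to exactly 1e6.
#'
#' @param se Counts `SummarizedExperiment` from [expression_matrix()].
#' @return The same object with the assay replaced by TPM values.
#' @examples
#' m <- matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' sheet <- data.frame(sample_id = "s1", group = "Sham",
#'                     timepoint = "day7", replicate = 1)
#' SummarizedExperiment::assay(tpm_normalize(expression_matrix(m, sheet, "miRNA")))
#' @export
tpm_normalize <- function(se) {
  m <- em_values(se)
  lib <- colSums(m)
  if (any(lib <= 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(m)[lib <= 0], collapse = ", "))
  }
  SummarizedExperiment::assay(se, "values") <- sweep(m, 2, lib, "/") * 1e6
  S4Vectors::metadata(se)$normalized <- "TPM"
  se
}

#' FPKM normalization
#'
#' value = count * 1e9 / (length * libsize): fragments per kilobase of
#' transcript per million mapped fragments. Lengths are taken from
#' `rowData(se)$length` unless supplied.
#'
#' @param se Counts `SummarizedExperiment` (mRNA).
#' @param lengths Optional per-feature transcript lengths (bp).
#' @return The same object with the assay replaced by FPKM values.
#' @export
fpkm_normalize <- function(se, lengths = NULL) {
  m <- em_values(se)
  if (is.null(lengths)) {
    lengths <- SummarizedExperiment::rowData(se)$length
  }
  if (is.null(lengths)) stop("feature lengths are required for FPKM")
  if (length(lengths) != nrow(m) || any(!is.finite(lengths)) ||
      any(lengths <= 0)) {
    stop("invalid feature lengths")
  }
  lib <- colSums(m)
  if (any(lib <= 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(m)[lib <= 0], collapse = ", "))
  }
  SummarizedExperiment::assay(se, "values") <-
    sweep(m / lengths, 2, lib, "/") * 1e9
  S4Vectors::metadata(se)$normalized <- "FPKM"
  se
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (delegates to [stats::p.adjust()] after validating the
#' input).
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Median-of-ratios size factors
#' @noRd
size_factors <- function(counts) {
  lg <- rowMeans(log(counts))
  ok <- is.finite(lg)
  if (!any(ok)) stop("no feature with positive counts in all samples")
  sf <- apply(counts, 2, function(col) {
    exp(median((log(col) - lg)[ok & col > 0]))
  })
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors")
  sf
}

#' Negative binomial Wald differential expression test
#'
#' Tests ICH vs Sham per feature at one timepoint on a counts matrix,
#' following the DESeq model family: counts are modelled as negative
#' binomial with sample-specific size factors (median-of-ratios) and a
#' per-feature dispersion. Dispersion is estimated by method of moments on
#' size-factor-normalized counts (pooled within-group variance), floored
#' at 1e-8 and shrunk 50/50 toward a parametric mean--dispersion trend
#' `a0 + a1/mean`. The Wald statistic is the log fold change over its
#' delta-method standard error, referred to the standard normal; p values
#' are two-sided and BH-adjusted across all tested features. The reported
#' `log2fc` is `log2((mean_ICH + 0.5) / (mean_Sham + 0.5))` on normalized
#' means (pseudocount 0.5 guards against zeros).
#'
#' @param se Counts `SummarizedExperiment`.
#' @param timepoint `"day7"` or `"day28"`; the test uses only that
#'   timepoint's samples and requires >= 2 replicates per group.
#' @param alpha Adjusted-p threshold for the `direction` call
#'   (default 0.05).
#' @return `data.frame` of class `de_table`: `feature_id`, `log2fc`,
#'   `p_raw`, `p_adj`, `direction` (`up` / `down` / `ns`), with the
#'   timepoint and species stored as attributes.
#' @export
de_test <- function(se, timepoint, alpha = 0.05) {
  sub <- em_timepoint(se, timepoint)
  cd <- em_samples(sub)
  grp <- cd$group
  if (sum(grp == "Sham") < 2 || sum(grp == "ICH") < 2) {
    stop("need at least 2 replicates per group at ", timepoint)
  }
  counts <- em_values(sub)
  res <- nb_wald(counts, grp == "ICH")
  res$p_adj <- bh_adjust(res$p_raw)
  res$direction <- ifelse(is.na(res$p_adj) | res$p_adj >= alpha, "ns",
                          ifelse(res$log2fc > 0, "up", "down"))
  out <- data.frame(feature_id = rownames(counts), res,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "timepoint") <- timepoint
  attr(out, "species") <- em_species(se)
  attr(out, "alpha") <- alpha
  class(out) <- c("de_table", "data.frame")
  out
}

# core Wald machinery on a raw counts matrix; `treated` is a logical
# column mask (ICH samples)
nb_wald <- function(counts, treated) {
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  a <- !treated; b <- treated
  na <- sum(a); nb <- sum(b)
  mA <- rowMeans(norm[, a, drop = FALSE])
  mB <- rowMeans(norm[, b, drop = FALSE])
  vA <- apply(norm[, a, drop = FALSE], 1, var)
  vB <- apply(norm[, b, drop = FALSE], 1, var)
  vw <- ((na - 1) * vA + (nb - 1) * vB) / (na + nb - 2)
  m <- (na * mA + nb * mB) / (na + nb)

  # method-of-moments dispersion: excess of the pooled variance over the
  # shot-noise term mu * mean(1/s), relative to mu^2
  disp_mom <- (vw - m * mean(1 / sf)) / m^2
  disp_mom[!is.finite(disp_mom)] <- 1e-8
  disp_mom <- pmax(disp_mom, 1e-8)

  use <- is.finite(m) & m > 0 & disp_mom > 1e-7
  if (sum(use) > 10) {
    fit <- lm(disp_mom[use] ~ I(1 / m[use]))
    a0 <- max(coef(fit)[1], 1e-8)
    a1 <- max(coef(fit)[2], 0)
  } else {
    a0 <- mean(disp_mom); a1 <- 0
  }
  disp_trend <- a0 + a1 / pmax(m, 1e-8)
  disp <- 0.5 * disp_mom + 0.5 * disp_trend

  log2fc <- log2((mB + 0.5) / (mA + 0.5))
  # delta-method variance of log group means under NB(mu = s_j * q, disp)
  vlA <- (mA * sum(1 / sf[a]) + disp * mA^2 * na) / (na * pmax(mA, 1e-8))^2
  vlB <- (mB * sum(1 / sf[b]) + disp * mB^2 * nb) / (nb * pmax(mB, 1e-8))^2
  se_l2 <- sqrt(vlA + vlB) / log(2)
  z <- log2fc / se_l2
  p <- 2 * pnorm(-abs(z))
  p[mA == 0 & mB == 0] <- NA_real_
  data.frame(log2fc = log2fc, p_raw = p)
}

#' Tabulate significant calls of a differential expression analysis
#'
#' @param records One `de_table` or a (possibly nested) list of them.
#' @return `data.frame` with `species`, `timepoint`, `n_down`, `n_up`,
#'   `n_total` (`n_total = n_down + n_up`, the number of significant
#'   features).
#' @export
de_summary <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  flat <- list()
  collect <- function(x) {
    if (is.data.frame(x)) flat[[length(flat) + 1]] <<- x
    else lapply(x, collect)
  }
  collect(records)
  rows <- lapply(flat, function(r) {
    data.frame(species = attr(r, "species") %||% NA_character_,
               timepoint = attr(r, "timepoint") %||% NA_character_,
               n_down = sum(r$direction == "down"),
               n_up = sum(r$direction == "up"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$n_total <- out$n_down + out$n_up
  out
}

#' Fold change from the DDCT method
#'
#' Relative qPCR quantification: `fold = 2^-(DDCT)` with
#' `DDCT = DCT_treated - DCT_control`.
#'
#' @param delta_ct_treated,delta_ct_control Finite delta-CT values
#'   (target CT minus endogenous-control CT), vectorised.
#' @return Fold change of treated relative to control.
#' @examples
#' ddct_fold_change(5, 5)      # 1.0
#' ddct_fold_change(6, 5)      # 0.5
#' @export
ddct_fold_change <- function(delta_ct_treated, delta_ct_control) {
  if (any(!is.finite(delta_ct_treated)) || any(!is.finite(delta_ct_control))) {
    stop("delta-CT inputs must be finite")
  }
  2^-(delta_ct_treated - delta_ct_control)
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf("Differential expression: %s, %s (alpha = %g)\n",
              attr(x, "species"), attr(x, "timepoint"), attr(x, "alpha")))
  s <- de_summary(x)
  cat(sprintf("  %d features tested; %d down, %d up\n",
              nrow(x), s$n_down, s$n_up))
  print(head(as.data.frame(x)))
  invisible(x)
}
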