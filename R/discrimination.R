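# Expression-signature discrimination: hierarchical clustering of DE
# feature profiles and PCA, per species and for species combinations.

#' Build a z-scored DE signature matrix
#'
#' Takes the union of differentially expressed features per selected
#' species (direction not `ns` in at least one supplied DE table of that
#' species), row-concatenates their `log2(normalized + 1)` profiles
#' across the shared samples, and z-scores every row (mean 0, SD 1).
#' Features with zero variance across the samples are dropped with a
#' warning (their z-score is undefined).
#'
#' @param matrices Named list of normalized `SummarizedExperiment`s.
#' @param de_tables Nested list `de_tables[[species]][[timepoint]]` of
#'   `de_table`s (a plain list of tables per species also works).
#' @param species_set Character subset of `c("circRNA", "miRNA", "mRNA")`.
#' @param samples Optional sample-id subset (default: all shared samples).
#' @return Matrix (features x samples) of class `signature_matrix` with a
#'   `species_set` attribute.
#' @export
build_signature <- function(matrices, de_tables, species_set,
                            samples = NULL) {
  species_set <- match.arg(species_set, c("circRNA", "miRNA", "mRNA"),
                           several.ok = TRUE)
  shared <- Reduce(intersect, lapply(matrices[species_set], colnames))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  if (length(shared) < 2) stop("need at least 2 shared samples")
  rows <- list()
  for (sp in species_set) {
    tabs <- de_tables[[sp]]
    if (is.data.frame(tabs)) tabs <- list(tabs)
    de_ids <- unique(unlist(lapply(tabs, function(t)
      t$feature_id[t$direction != "ns"])))
    if (length(de_ids) == 0) next
    x <- log2(em_values(matrices[[sp]])[de_ids, shared, drop = FALSE] + 1)
    rownames(x) <- paste(sp, de_ids, sep = ":")
    rows[[sp]] <- x
  }
  if (length(rows) == 0) stop("no differentially expressed features in ",
                              paste(species_set, collapse = "+"))
  x <- do.call(rbind, rows)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature(s) dropped from signature")
    x <- x[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (x - rowMeans(x)) / sds
  structure(z, class = c("signature_matrix", "matrix"),
            species_set = species_set)
}

#' Clustering accuracy of a signature against known classes
#'
#' Clusters the samples by agglomerative hierarchical clustering
#' (Euclidean distance, average linkage by default), cuts the dendrogram
#' at `k` clusters and scores the agreement with the given class labels:
#' when `k` does not exceed the number of classes, by the optimal
#' one-to-one cluster-to-class assignment (maximum total agreement over
#' all assignments); when `k` exceeds the number of classes, each cluster
#' is credited with its majority class. Deterministic given the input.
#'
#' @param signature Matrix from [build_signature()] (features x samples).
#' @param classes Class label per sample (character or factor), in column
#'   order of `signature`.
#' @param k Number of clusters; must not exceed the sample count.
#' @param distance,linkage Dissimilarity and agglomeration method.
#' @return List of class `discrimination_result`: `k`, `accuracy`,
#'   `n_correct` per class, `assignment` (cluster per sample).
#' @export
cluster_accuracy <- function(signature, classes, k,
                             distance = "euclidean", linkage = "average") {
  n <- ncol(signature)
  if (k > n) stop("k must not exceed the number of samples")
  if (length(classes) != n) stop("one class label per sample is required")
  classes <- as.character(classes)
  hc <- hclust(dist(t(signature), method = distance), method = linkage)
  cl <- cutree(hc, k = k)
  acc <- label_agreement(cl, classes)
  correct <- acc$correct
  n_correct <- vapply(split(correct, classes), sum, numeric(1))
  structure(list(k = k, accuracy = acc$accuracy, n_correct = n_correct,
                 assignment = cl, classes = classes),
            class = "discrimination_result")
}

# maximum agreement between a clustering and reference labels:
# one-to-one optimal assignment (enumerated; k and class counts are small
# by design: 2 or 4) when k <= n_classes, majority vote otherwise
label_agreement <- function(cl, classes) {
  cls <- sort(unique(classes))
  ks <- sort(unique(cl))
  n <- length(cl)
  cont <- table(factor(cl, levels = ks), factor(classes, levels = cls))
  if (length(ks) <= length(cls)) {
    perms <- permutations_of(seq_along(cls), length(ks))
    best <- -1; best_map <- NULL
    for (p in perms) {
      s <- sum(cont[cbind(seq_along(ks), p)])
      if (s > best) { best <- s; best_map <- p }
    }
    mapped <- cls[best_map][match(cl, ks)]
  } else {
    maj <- cls[apply(cont, 1, which.max)]
    mapped <- maj[match(cl, ks)]
    best <- sum(mapped == classes)
  }
  list(accuracy = best / n, correct = mapped == classes)
}

# all ordered selections of `r` distinct elements from `v`
permutations_of <- function(v, r) {
  if (r == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i], r - 1)) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

#' Principal component analysis of a signature
#'
#' PCA on the sample vectors (features as dimensions, centred, not
#' rescaled). Returns PC scores and the percentage of variance explained;
#' components are ordered so PC1 >= PC2.
#'
#' @param signature Matrix (features x samples), >= 2 samples.
#' @return List with `scores` (samples x PCs), `variance_pct`
#'   (percentage of variance per PC), `pc12_pct` (variance explained by
#'   PC1 and PC2), `degenerate` (`TRUE` when total variance is zero).
#' @export
pca_variance <- function(signature) {
  if (ncol(signature) < 2) stop("need at least 2 samples")
  pc <- prcomp(t(signature), center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) == 0) {
    return(list(scores = pc$x, variance_pct = rep(0, length(v)),
                pc12_pct = c(PC1 = 0, PC2 = 0), degenerate = TRUE))
  }
  pct <- 100 * v / sum(v)
  list(scores = pc$x, variance_pct = pct,
       pc12_pct = c(PC1 = pct[1], PC2 = if (length(pct) > 1) pct[2] else 0),
       degenerate = FALSE)
}

#' Compare the discriminatory power of RNA species and combinations
#'
#' Runs [cluster_accuracy()] for each species and species combination
#' ({circ, mRNA, miR, mRNA+miR, circ+miR, circ+mRNA+miR}) in two modes:
#' `k = 4` on all samples against the four Group x Timepoint classes, and
#' `k = 2` within each timepoint against Sham vs ICH. Species with no DE
#' features are skipped with a warning.
#'
#' @param matrices Named list of normalized `SummarizedExperiment`s.
#' @param de_tables Nested DE tables as in [build_signature()].
#' @return `data.frame` ranked by decreasing k = 4 accuracy: one row per
#'   combination with `accuracy_k4`, `accuracy_day7_k2`,
#'   `accuracy_day28_k2`, `pc1_pct`, `pc2_pct`.
#' @export
species_comparison <- function(matrices, de_tables) {
  combos <- list(circRNA = "circRNA", mRNA = "mRNA", miRNA = "miRNA",
                 `mRNA+miRNA` = c("mRNA", "miRNA"),
                 `circRNA+miRNA` = c("circRNA", "miRNA"),
                 `circRNA+mRNA+miRNA` = c("circRNA", "mRNA", "miRNA"))
  sheet <- em_samples(matrices[[1]])
  rows <- list()
  for (nm in names(combos)) {
    sig <- tryCatch(build_signature(matrices, de_tables, combos[[nm]]),
                    error = function(e) {
                      warning("skipping ", nm, ": ", conditionMessage(e))
                      NULL
                    })
    if (is.null(sig)) next
    meta <- sheet[match(colnames(sig), sheet$sample_id), ]
    cls4 <- paste(meta$group, meta$timepoint)
    acc4 <- cluster_accuracy(sig, cls4, k = 4)
    acc2 <- vapply(c("day7", "day28"), function(tp) {
      sel <- meta$timepoint == tp
      if (sum(sel) < 2) return(NA_real_)
      cluster_accuracy(sig[, sel, drop = FALSE], meta$group[sel],
                       k = 2)$accuracy
    }, numeric(1))
    pv <- pca_variance(sig)
    rows[[nm]] <- data.frame(
      combination = nm, accuracy_k4 = acc4$accuracy,
      accuracy_day7_k2 = acc2[["day7"]],
      accuracy_day28_k2 = acc2[["day28"]],
      pc1_pct = pv$pc12_pct[["PC1"]], pc2_pct = pv$pc12_pct[["PC2"]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$accuracy_k4), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("Clustering at k = %d: accuracy %.3f\n", x$k, x$accuracy))
  cat("  correct per class: ",
      paste(sprintf("%s %d/%d", names(x$n_correct), x$n_correct,
                    as.integer(table(x$classes)[names(x$n_correct)])),
            collapse = ", "), "\n")
  invisible(x)
}
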