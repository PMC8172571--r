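# ceRNA triplet assembly, correlation edges, hub selection and network
# construction / export (GraphML and SIF via igraph).

#' Assemble circRNA-miRNA-mRNA triplets sharing a miRNA
#'
#' One triplet for every (circ, miR) pair in the first table combined with
#' every (miR, mRNA) pair in the second table that shares the miRNA:
#' circRNA as the decoy, miRNA as the core, mRNA as the target. The
#' triplet count therefore equals `sum_m |circ(m)| * |mrna(m)|`.
#'
#' @param circ_mir_pairs,mir_mrna_pairs Pair tables from
#'   [pair_candidates()] (columns `mir_id` + `circ_id` / `mrna_id`).
#' @return `data.frame` of triplets (`circ_id`, `mir_id`, `mrna_id`),
#'   sorted lexicographically.
#' @export
assemble_triplets <- function(circ_mir_pairs, mir_mrna_pairs) {
  tp_a <- attr(circ_mir_pairs, "timepoint")
  tp_b <- attr(mir_mrna_pairs, "timepoint")
  if (!is.null(tp_a) && !is.null(tp_b) && !identical(tp_a, tp_b)) {
    stop("pair tables come from different timepoints")
  }
  out <- merge(circ_mir_pairs[, c("mir_id", "circ_id")],
               mir_mrna_pairs[, c("mir_id", "mrna_id")],
               by = "mir_id")
  out <- out[, c("circ_id", "mir_id", "mrna_id")]
  out <- out[order(out$circ_id, out$mir_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "timepoint") <- tp_a %||% tp_b
  out
}

#' Pearson correlation with a two-sided t-test p value
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return `c(r = ..., p = ...)`; `r` is `NA` for constant vectors.
#' @export
pearson_cor_test <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need >= 3 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(r = NA_real_, p = NA_real_))
  }
  r <- cor(x, y)
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) return(c(r = r, p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * pt(-abs(tstat), df = n - 2))
}

#' Attach Pearson correlation edges to ceRNA triplets
#'
#' Computes, for every triplet, the Pearson correlation and two-sided
#' t-test p value of its circ--miR and miR--mRNA expression pairs on
#' `log2(normalized + 1)` values across the samples of one timepoint.
#' By default the correlation cohort pools Sham and ICH samples of the
#' timepoint (`cohort = "pooled"`, 2 x n_reps samples); `cohort = "ICH"`
#' restricts to ICH samples. Edges involving a constant expression vector
#' get `r = NA` and are flagged ineligible for hub selection.
#'
#' @param triplets Triplet `data.frame` from [assemble_triplets()].
#' @param matrices Named list of normalized `SummarizedExperiment`s
#'   (`circRNA`, `miRNA`, `mRNA`).
#' @param timepoint Timepoint whose samples define the correlation cohort.
#' @param cohort `"pooled"` (Sham + ICH, default) or `"ICH"`.
#' @return The triplets with columns `r_circ_mir`, `p_circ_mir`,
#'   `r_mir_mrna`, `p_mir_mrna`, `hub_eligible`.
#' @export
pearson_edges <- function(triplets, matrices, timepoint,
                          cohort = c("pooled", "ICH")) {
  cohort <- match.arg(cohort)
  logm <- lapply(matrices, function(se) {
    sub <- em_timepoint(se, timepoint)
    if (cohort == "ICH") sub <- sub[, em_samples(sub)$group == "ICH"]
    if (ncol(sub) < 3) stop("need >= 3 samples in the correlation cohort")
    log2(em_values(sub) + 1)
  })
  need <- list(circRNA = triplets$circ_id, miRNA = triplets$mir_id,
               mRNA = triplets$mrna_id)
  for (sp in names(need)) {
    missing <- setdiff(unique(need[[sp]]), rownames(logm[[sp]]))
    if (length(missing)) {
      stop("features absent from ", sp, " matrix: ",
           paste(head(missing, 3), collapse = ", "))
    }
  }
  edge <- function(ids_a, mat_a, ids_b, mat_b) {
    key <- paste(ids_a, ids_b)
    uniq <- !duplicated(key)
    vals <- t(vapply(which(uniq), function(i) {
      pearson_cor_test(mat_a[ids_a[i], ], mat_b[ids_b[i], ])
    }, c(r = 0, p = 0)))
    vals[match(key, key[uniq]), , drop = FALSE]
  }
  cm <- edge(triplets$circ_id, logm$circRNA, triplets$mir_id, logm$miRNA)
  mm <- edge(triplets$mir_id, logm$miRNA, triplets$mrna_id, logm$mRNA)
  triplets$r_circ_mir <- cm[, "r"]; triplets$p_circ_mir <- cm[, "p"]
  triplets$r_mir_mrna <- mm[, "r"]; triplets$p_mir_mrna <- mm[, "p"]
  triplets$hub_eligible <- !is.na(cm[, "r"]) & !is.na(mm[, "r"])
  attr(triplets, "timepoint") <- attr(triplets, "timepoint") %||% timepoint
  triplets
}

#' Select hub triplets and hub nodes
#'
#' A triplet survives when both of its correlation edges are strictly
#' below `r_max` (default -0.5) with p values no more than `p_max`
#' (default 0.05): strict inequality for r, non-strict for p. Hub nodes
#' are the distinct members of surviving triplets.
#'
#' @param triplets Triplets with correlation columns
#'   (from [pearson_edges()]).
#' @param r_max Correlation threshold (default -0.5, exclusive).
#' @param p_max p-value threshold (default 0.05, inclusive).
#' @return List with `triplets` (survivors) and `nodes`
#'   (`data.frame` of `id`, `species`).
#' @export
select_hubs <- function(triplets, r_max = -0.5, p_max = 0.05) {
  ok <- !is.na(triplets$r_circ_mir) & !is.na(triplets$r_mir_mrna) &
    triplets$r_circ_mir < r_max & triplets$r_mir_mrna < r_max &
    triplets$p_circ_mir <= p_max & triplets$p_mir_mrna <= p_max
  if (!is.null(triplets$hub_eligible)) ok <- ok & triplets$hub_eligible
  surv <- triplets[ok, , drop = FALSE]
  rownames(surv) <- NULL
  nodes <- node_table(surv)
  list(triplets = surv, nodes = nodes)
}

# distinct nodes of a triplet table, with their species roles
node_table <- function(triplets) {
  ids <- list(circRNA = unique(triplets$circ_id),
              miRNA = unique(triplets$mir_id),
              mRNA = unique(triplets$mrna_id))
  data.frame(id = unlist(ids, use.names = FALSE),
             species = rep(names(ids), lengths(ids)),
             stringsAsFactors = FALSE)
}

#' Build a ceRNA network graph
#'
#' Bipartite-by-construction graph with circ--miR and miR--mRNA edges
#' only. Node attributes: `species`, `direction`, `p_adj` (from the DE
#' tables when given); edge attributes: `type`, `r`, `p`.
#'
#' @param triplets Triplet table, with correlation columns if available.
#' @param de_tables Optional named list of `de_table`s (`circRNA`,
#'   `miRNA`, `mRNA`) supplying node direction and adjusted p.
#' @param timepoint Timepoint label stored on the graph.
#' @return An `igraph` graph of class `cerna_network`.
#' @export
cerna_network <- function(triplets, de_tables = NULL, timepoint = NULL) {
  nodes <- node_table(triplets)
  nodes$direction <- rep(NA_character_, nrow(nodes))
  nodes$p_adj <- rep(NA_real_, nrow(nodes))
  if (!is.null(de_tables)) {
    for (sp in names(de_tables)) {
      tab <- de_tables[[sp]]
      idx <- match(nodes$id, tab$feature_id)
      sel <- !is.na(idx)
      nodes$direction[sel] <- tab$direction[idx[sel]]
      nodes$p_adj[sel] <- tab$p_adj[idx[sel]]
    }
  }
  has_r <- "r_circ_mir" %in% names(triplets)
  nt <- nrow(triplets)
  e_cm <- unique(data.frame(
    from = triplets$circ_id, to = triplets$mir_id,
    type = rep("circ_mir", nt),
    r = if (has_r) triplets$r_circ_mir else rep(NA_real_, nt),
    p = if (has_r) triplets$p_circ_mir else rep(NA_real_, nt),
    stringsAsFactors = FALSE))
  e_mm <- unique(data.frame(
    from = triplets$mir_id, to = triplets$mrna_id,
    type = rep("mir_mrna", nt),
    r = if (has_r) triplets$r_mir_mrna else rep(NA_real_, nt),
    p = if (has_r) triplets$p_mir_mrna else rep(NA_real_, nt),
    stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(rbind(e_cm, e_mm), directed = FALSE,
                                     vertices = nodes)
  g$timepoint <- timepoint %||% attr(triplets, "timepoint") %||% NA_character_
  class(g) <- c("cerna_network", class(g))
  g
}

#' Summarise a ceRNA network
#'
#' @param network A `cerna_network` (igraph) graph.
#' @return List with `nodes` (`data.frame`: species, n_down, n_up, n_other,
#'   n_total) and `n_edges` (relationship count).
#' @export
network_summary <- function(network) {
  sp <- igraph::V(network)$species
  dirn <- igraph::V(network)$direction
  if (length(sp) == 0) {
    tab <- data.frame(species = c("circRNA", "miRNA", "mRNA"),
                      n_down = 0L, n_up = 0L, n_other = 0L, n_total = 0L)
    return(list(nodes = tab, n_edges = 0L))
  }
  rows <- lapply(c("circRNA", "miRNA", "mRNA"), function(s) {
    d <- dirn[sp == s]
    data.frame(species = s,
               n_down = sum(d == "down", na.rm = TRUE),
               n_up = sum(d == "up", na.rm = TRUE),
               n_other = sum(is.na(d) | !(d %in% c("down", "up"))),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$n_total <- tab$n_down + tab$n_up + tab$n_other
  list(nodes = tab, n_edges = igraph::ecount(network))
}

#' Export / import a ceRNA network
#'
#' GraphML preserves all node (`species`, `direction`, `p_adj`) and edge
#' (`type`, `r`, `p`) attributes and round-trips losslessly; SIF is the
#' minimal Cytoscape interaction format (`source type target`) and keeps
#' topology only.
#'
#' @param network A `cerna_network` graph.
#' @param path Output file.
#' @param format `"graphml"` or `"sif"`.
#' @export
export_network <- function(network, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    # igraph's writer rejects NA for some attribute types; encode as strings
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(network, what = "edges")
    lines <- sprintf("%s\t%s\t%s", el$from, el$type, el$to)
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname export_network
#' @return `read_network()` returns the re-imported `cerna_network`.
#' @export
read_network <- function(path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
  } else {
    el <- read.delim(path, header = FALSE,
                     col.names = c("from", "type", "to"),
                     stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(el[, c("from", "to", "type")],
                                       directed = FALSE)
  }
  class(g) <- c("cerna_network", class(g))
  g
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("ceRNA network (%s): %d nodes, %d edges\n",
              x$timepoint %||% "?", igraph::vcount(x), s$n_edges))
  print(s$nodes)
  invisible(x)
}
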