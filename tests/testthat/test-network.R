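# Triplet assembly, correlation edges, hub selection, network summaries
# and export.

pair_tab <- function(mir, target, col) {
  out <- data.frame(mir_id = mir, t = target, site_count = 1L,
                    best_score = 2L, stringsAsFactors = FALSE)
  names(out)[2] <- col
  out
}

test_that("triplet assembly is the per-miRNA product", {
  cm <- pair_tab(rep("m1", 2), c("c1", "c2"), "circ_id")
  mm <- pair_tab(rep("m1", 3), c("g1", "g2", "g3"), "mrna_id")
  tr <- assemble_triplets(cm, mm)
  expect_equal(nrow(tr), 6L)
  expect_equal(tr$circ_id, rep(c("c1", "c2"), each = 3))

  mm2 <- pair_tab("m9", "g1", "mrna_id")
  expect_equal(nrow(assemble_triplets(cm, mm2)), 0L)
})

test_that("triplet assembly matches the nested-loop oracle and count identity", {
  set.seed(505)
  for (rep in 1:20) {
    cm <- unique(pair_tab(sample(paste0("m", 1:5), 12, TRUE),
                          sample(paste0("c", 1:6), 12, TRUE), "circ_id"))
    mm <- unique(pair_tab(sample(paste0("m", 1:5), 12, TRUE),
                          sample(paste0("g", 1:6), 12, TRUE), "mrna_id"))
    got <- assemble_triplets(cm, mm)
    want <- oracle_triplets(cm, mm)
    expect_equal(got[, c("circ_id", "mir_id", "mrna_id")], want,
                 ignore_attr = TRUE)
    # count identity: sum over miRNAs of |circ(m)| * |mrna(m)|
    count <- sum(vapply(unique(cm$mir_id), function(m) {
      sum(cm$mir_id == m) * sum(mm$mir_id == m)
    }, numeric(1)))
    expect_equal(nrow(got), count)
  }
})

test_that("Pearson edges match closed forms and the formula oracle", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  out <- pearson_cor_test(x, -x)
  expect_equal(unname(out["r"]), -1)
  expect_lt(out["p"], 1e-6)

  # orthogonal contrast vectors are exactly uncorrelated
  a <- c(1, 1, -1, -1)
  b <- c(1, -1, 1, -1)
  expect_equal(unname(pearson_cor_test(a, b)["r"]), 0)

  expect_true(is.na(pearson_cor_test(rep(1, 5), 1:5)["r"]))
  expect_error(pearson_cor_test(1:2, 1:2), ">= 3")

  set.seed(606)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearson_cor_test(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got, want, tolerance = 1e-9)
    # and agreement with stats::cor.test as an independent check
    ct <- cor.test(x, y)
    expect_equal(unname(got["p"]), ct$p.value, tolerance = 1e-9)
  }
})

test_that("hub selection applies strict r and inclusive p thresholds", {
  tr <- data.frame(
    circ_id = paste0("c", 1:4), mir_id = paste0("m", 1:4),
    mrna_id = paste0("g", 1:4),
    r_circ_mir = c(-0.5, -0.51, -0.9, -0.6),
    p_circ_mir = c(0.01, 0.05, 0.04, 0.051),
    r_mir_mrna = c(-0.9, -0.9, -0.5000001, -0.9),
    p_mir_mrna = c(0.01, 0.05, 0.05, 0.01),
    stringsAsFactors = FALSE)
  hubs <- select_hubs(tr)
  # c1: r = -0.5 exactly -> excluded; c2: p = 0.05 -> included;
  # c3: r just below -0.5, p at boundary -> included; c4: p > 0.05 -> out
  expect_setequal(hubs$triplets$circ_id, c("c2", "c3"))
  expect_equal(nrow(hubs$nodes), 6L)

  # monotonicity: relaxing thresholds never removes a survivor
  relaxed <- select_hubs(tr, r_max = -0.4, p_max = 0.1)
  expect_true(all(hubs$triplets$circ_id %in% relaxed$triplets$circ_id))

  # NA-correlation edges are ineligible
  tr$r_circ_mir[2] <- NA
  expect_setequal(select_hubs(tr)$triplets$circ_id, "c3")
})

test_that("hub selection matches a filter-comprehension oracle", {
  set.seed(707)
  for (rep in 1:20) {
    n <- 30
    tr <- data.frame(
      circ_id = paste0("c", 1:n), mir_id = paste0("m", 1:n),
      mrna_id = paste0("g", 1:n),
      r_circ_mir = runif(n, -1, 1), p_circ_mir = runif(n),
      r_mir_mrna = runif(n, -1, 1), p_mir_mrna = runif(n),
      stringsAsFactors = FALSE)
    got <- select_hubs(tr, r_max = -0.3, p_max = 0.2)$triplets$circ_id
    want <- tr$circ_id[tr$r_circ_mir < -0.3 & tr$r_mir_mrna < -0.3 &
                       tr$p_circ_mir <= 0.2 & tr$p_mir_mrna <= 0.2]
    expect_setequal(got, want)
  }
})

test_that("network summaries reproduce role and direction totals", {
  mk_net <- function(n_circ_dn, n_circ_up, n_mir, n_mrna) {
    circ <- paste0("c", seq_len(n_circ_dn + n_circ_up))
    mir <- paste0("m", seq_len(n_mir))
    mrna <- paste0("g", seq_len(n_mrna))
    tr <- data.frame(circ_id = circ,
                     mir_id = rep(mir, length.out = length(circ)),
                     mrna_id = rep(mrna, length.out = length(circ)),
                     stringsAsFactors = FALSE)
    de <- list(
      circRNA = fake_de_table(circ, rep(c("down", "up"),
                                        c(n_circ_dn, n_circ_up))),
      miRNA = fake_de_table(mir, rep("down", n_mir), species = "miRNA"),
      mRNA = fake_de_table(mrna, rep("up", n_mrna), species = "mRNA"))
    cerna_network(tr, de_tables = de, timepoint = "day7")
  }
  # day-7 ceRNA decoys: 50 down + 47 up = 97; day-28: 49 + 32 = 81
  s7 <- network_summary(mk_net(50, 47, 32, 89))
  circ_row <- s7$nodes[s7$nodes$species == "circRNA", ]
  expect_equal(circ_row$n_down, 50)
  expect_equal(circ_row$n_up, 47)
  expect_equal(circ_row$n_total, 97)
  s28 <- network_summary(mk_net(49, 32, 15, 77))
  expect_equal(s28$nodes$n_total[s28$nodes$species == "circRNA"], 81)

  empty <- cerna_network(data.frame(circ_id = character(0),
                                    mir_id = character(0),
                                    mrna_id = character(0)))
  s0 <- network_summary(empty)
  expect_true(all(s0$nodes$n_total == 0))
  expect_equal(s0$n_edges, 0L)
})

test_that("hub node counts follow the surviving triplets", {
  # day-7-like fixture: 8 qualifying triplets over 4 circ + 3 miR + 5 mRNA
  tr7 <- data.frame(
    circ_id = c("c1", "c1", "c2", "c2", "c3", "c3", "c4", "c4"),
    mir_id  = c("m1", "m1", "m1", "m2", "m2", "m3", "m3", "m3"),
    mrna_id = c("g1", "g2", "g3", "g3", "g4", "g4", "g5", "g1"),
    stringsAsFactors = FALSE)
  tr7$r_circ_mir <- -0.8; tr7$p_circ_mir <- 0.01
  tr7$r_mir_mrna <- -0.7; tr7$p_mir_mrna <- 0.02
  # plus non-qualifying triplets that must not contribute nodes
  extra <- data.frame(circ_id = "c9", mir_id = "m9", mrna_id = "g9",
                      r_circ_mir = -0.2, p_circ_mir = 0.5,
                      r_mir_mrna = -0.9, p_mir_mrna = 0.01)
  hubs7 <- select_hubs(rbind(tr7, extra))
  expect_equal(nrow(hubs7$triplets), 8L)
  expect_equal(nrow(hubs7$nodes), 12L)

  # day-28-like fixture: 3 disjoint qualifying triplets -> 9 hub nodes
  tr28 <- data.frame(
    circ_id = paste0("c", 1:3), mir_id = paste0("m", 1:3),
    mrna_id = paste0("g", 1:3),
    r_circ_mir = -0.9, p_circ_mir = 0.001,
    r_mir_mrna = -0.8, p_mir_mrna = 0.003, stringsAsFactors = FALSE)
  expect_equal(nrow(select_hubs(tr28)$nodes), 9L)
})

test_that("networks are bipartite circ-miR / miR-mRNA and export losslessly", {
  tr <- data.frame(
    circ_id = c("c1", "c2"), mir_id = c("m1", "m1"),
    mrna_id = c("g1", "g2"),
    r_circ_mir = c(-0.8, -0.6), p_circ_mir = c(0.01, 0.02),
    r_mir_mrna = c(-0.7, -0.55), p_mir_mrna = c(0.03, 0.04),
    stringsAsFactors = FALSE)
  de <- list(circRNA = fake_de_table(c("c1", "c2"), c("up", "down")),
             miRNA = fake_de_table("m1", "down", species = "miRNA"),
             mRNA = fake_de_table(c("g1", "g2"), c("up", "up"),
                                  species = "mRNA"))
  net <- cerna_network(tr, de, timepoint = "day7")
  expect_equal(igraph::vcount(net), 5L)
  expect_equal(igraph::ecount(net), 4L)
  # bipartite: every edge touches the miRNA layer, no circ-mRNA edge
  ends <- igraph::as_data_frame(net, "edges")
  sp <- setNames(igraph::V(net)$species, igraph::V(net)$name)
  expect_true(all(sp[ends$from] == "miRNA" | sp[ends$to] == "miRNA"))

  f <- tempfile(fileext = ".graphml")
  export_network(net, f, "graphml")
  back <- read_network(f, "graphml")
  expect_true(igraph::isomorphic(net, back))
  bv <- igraph::as_data_frame(back, "vertices")
  nv <- igraph::as_data_frame(net, "vertices")
  expect_equal(bv[order(bv$name), c("species", "direction")],
               nv[order(nv$name), c("species", "direction")],
               ignore_attr = TRUE)
  be <- igraph::as_data_frame(back, "edges")
  expect_equal(sort(be$r), sort(ends$r), tolerance = 1e-12)

  f2 <- tempfile(fileext = ".sif")
  export_network(net, f2, "sif")
  sif <- read_network(f2, "sif")
  expect_true(igraph::isomorphic(net, sif))
  expect_error(export_network(net, tempfile(), "xlsx"), "graphml")
  unlink(c(f, f2))
})

test_that("3-node toy triplet exports a 3-node 2-edge GraphML", {
  tr <- data.frame(circ_id = "c1", mir_id = "m1", mrna_id = "g1",
                   stringsAsFactors = FALSE)
  net <- cerna_network(tr)
  f <- tempfile(fileext = ".graphml")
  export_network(net, f)
  back <- read_network(f)
  expect_equal(igraph::vcount(back), 3L)
  expect_equal(igraph::ecount(back), 2L)
  unlink(f)
})

test_that("pearson_edges attaches per-pair correlations from the matrices", {
  sim <- simulate_counts(tiny_config(n_triplets = 3L, n_reps = 4L,
                                     seed = 91L))
  norm <- list(circRNA = tpm_normalize(sim$matrices$circRNA),
               miRNA = tpm_normalize(sim$matrices$miRNA),
               mRNA = fpkm_normalize(sim$matrices$mRNA))
  tr <- sim$truth$triplets[, c("circ_id", "mir_id", "mrna_id")]
  got <- pearson_edges(tr, norm, "day7")
  # recompute one edge by hand
  tp <- sim$sample_sheet$sample_id[sim$sample_sheet$timepoint == "day7"]
  x <- log2(SummarizedExperiment::assay(norm$circRNA)[tr$circ_id[1], tp] + 1)
  y <- log2(SummarizedExperiment::assay(norm$miRNA)[tr$mir_id[1], tp] + 1)
  expect_equal(got$r_circ_mir[1], unname(cor(x, y)), tolerance = 1e-9)
  expect_true(all(got$hub_eligible))
  expect_error(pearson_edges(data.frame(circ_id = "nope", mir_id = "m",
                                        mrna_id = "g"), norm, "day7"),
               "absent")
})
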