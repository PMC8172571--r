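# Signature construction, clustering accuracy, PCA and species comparison.

sig_fixture <- function(n_per_class = 4, n_feat = 30, shift = 5, sd = 0.5,
                        classes = c("Sham", "ICH"), seed = 1) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  x <- matrix(rnorm(n_feat * n, sd = sd), n_feat, n)
  for (k in seq_along(classes)) {
    cols <- (k - 1) * n_per_class + seq_len(n_per_class)
    x[, cols] <- x[, cols] + shift * (k - 1)
  }
  colnames(x) <- paste0("s", seq_len(n))
  rownames(x) <- paste0("f", seq_len(n_feat))
  list(x = x, classes = rep(classes, each = n_per_class))
}

test_that("signatures are the z-scored union of DE features", {
  sim <- simulate_counts(tiny_config(seed = 17L))
  norm <- list(circRNA = tpm_normalize(sim$matrices$circRNA),
               miRNA = tpm_normalize(sim$matrices$miRNA),
               mRNA = fpkm_normalize(sim$matrices$mRNA))
  de <- list(
    circRNA = list(day7 = de_test(sim$matrices$circRNA, "day7"),
                   day28 = de_test(sim$matrices$circRNA, "day28")),
    miRNA = list(day7 = de_test(sim$matrices$miRNA, "day7")),
    mRNA = list(day7 = de_test(sim$matrices$mRNA, "day7")))
  n_de <- function(sp) length(unique(unlist(lapply(de[[sp]], function(t)
    t$feature_id[t$direction != "ns"]))))
  sig_c <- build_signature(norm, de, "circRNA")
  expect_equal(nrow(sig_c), n_de("circRNA"))
  sig_cm <- build_signature(norm, de, c("circRNA", "miRNA"))
  expect_equal(nrow(sig_cm), n_de("circRNA") + n_de("miRNA"))
  # rows are z-scored
  expect_equal(unname(rowMeans(sig_c)), rep(0, nrow(sig_c)),
               tolerance = 1e-9)
  expect_equal(unname(apply(sig_c, 1, sd)), rep(1, nrow(sig_c)),
               tolerance = 1e-9)
  # z-scoring is idempotent
  z2 <- (sig_c - rowMeans(sig_c)) / apply(sig_c, 1, sd)
  expect_equal(unclass(sig_c), unclass(z2), tolerance = 1e-9,
               ignore_attr = TRUE)
  # empty DE set errors
  de_none <- list(mRNA = list(day7 = fake_de_table("x", "ns",
                                                   species = "mRNA")))
  expect_error(build_signature(norm, de_none, "mRNA"), "no differentially")
})

test_that("well-separated groups cluster perfectly; k = n is trivially exact", {
  fx <- sig_fixture()
  res <- cluster_accuracy(fx$x, fx$classes, k = 2)
  expect_equal(res$accuracy, 1.0)
  expect_equal(unname(res$n_correct), c(4, 4))

  res_n <- cluster_accuracy(fx$x, fx$classes, k = ncol(fx$x))
  expect_equal(res_n$accuracy, 1.0)
  expect_error(cluster_accuracy(fx$x, fx$classes, k = 99), "exceed")

  # four separated classes at k = 4
  fx4 <- sig_fixture(classes = c("a", "b", "c", "d"), shift = 8, seed = 2)
  expect_equal(cluster_accuracy(fx4$x, fx4$classes, k = 4)$accuracy, 1.0)
})

test_that("accuracy is invariant to feature order and label renaming", {
  fx <- sig_fixture(seed = 3)
  base <- cluster_accuracy(fx$x, fx$classes, k = 2)$accuracy
  perm <- sample(nrow(fx$x))
  expect_equal(cluster_accuracy(fx$x[perm, ], fx$classes, k = 2)$accuracy,
               base)
  renamed <- ifelse(fx$classes == "Sham", "grpA", "grpB")
  expect_equal(cluster_accuracy(fx$x, renamed, k = 2)$accuracy, base)
})

test_that("randomly permuted labels score near chance", {
  # with 2 balanced classes of 8 and a fixed 2-cluster structure, optimal
  # matching of shuffled labels has expectation just above 0.5; a
  # permutation run (1,000 shuffles, estimated beforehand) centres near
  # 0.56 with essentially no mass above 0.9
  fx <- sig_fixture(n_per_class = 8, seed = 4)
  set.seed(99)
  accs <- replicate(200, {
    cluster_accuracy(fx$x, sample(fx$classes), k = 2)$accuracy
  })
  expect_gt(mean(accs), 0.5 - 0.05)
  expect_lt(mean(accs), 0.75)
})

test_that("PCA variance percentages follow the eigen structure", {
  # rank-1 data: PC1 explains everything
  u <- rnorm(20); v <- seq_len(8)
  x1 <- outer(u, v)
  rownames(x1) <- paste0("f", 1:20); colnames(x1) <- paste0("s", 1:8)
  pv <- pca_variance(x1)
  expect_equal(unname(pv$pc12_pct[["PC1"]]), 100, tolerance = 1e-8)
  expect_false(pv$degenerate)
  expect_gte(pv$pc12_pct[["PC1"]], pv$pc12_pct[["PC2"]])

  # isotropic 2-D samples: PC1 and PC2 each near 50%
  set.seed(12)
  x2 <- matrix(rnorm(2 * 2000), 2, 2000)
  rownames(x2) <- c("f1", "f2"); colnames(x2) <- paste0("s", 1:2000)
  pv2 <- pca_variance(x2)
  expect_equal(unname(pv2$pc12_pct[["PC1"]]), 50, tolerance = 0.1)

  # scores match the eigendecomposition of the sample covariance
  set.seed(13)
  x3 <- matrix(rnorm(15 * 10), 15, 10,
               dimnames = list(paste0("f", 1:15), paste0("s", 1:10)))
  pv3 <- pca_variance(x3)
  cv <- cov(scale(t(x3), center = TRUE, scale = FALSE))
  ev <- eigen(cv, symmetric = TRUE)
  want_pct <- 100 * ev$values / sum(ev$values)
  expect_equal(unname(pv3$variance_pct[1:5]), want_pct[1:5],
               tolerance = 1e-8)
  # scores agree up to sign
  sc <- scale(t(x3), center = TRUE, scale = FALSE) %*% ev$vectors
  for (j in 1:2) {
    expect_equal(abs(unname(pv3$scores[, j])), abs(unname(sc[, j])),
                 tolerance = 1e-8)
  }

  # degenerate all-equal samples flagged
  x0 <- matrix(1, 5, 4, dimnames = list(paste0("f", 1:5), paste0("s", 1:4)))
  expect_true(pca_variance(x0)$degenerate)
})

test_that("stronger planted effects give the stronger discriminator", {
  # circRNA effects planted at twice the miRNA effect size
  cfg <- sim_config(n_circ = 120L, n_mirna = 120L, n_mrna = 30L,
                    n_reps = 4L, n_triplets = 0L,
                    de_fraction = c(circRNA = 0.3, miRNA = 0.3, mRNA = 0.1),
                    log2fc_range = c(1, 2), seed = 23L)
  sim <- simulate_counts(cfg)
  # rescale miRNA planted effects down by applying the generator twice
  cfg_weak <- sim_config(n_circ = 120L, n_mirna = 120L, n_mrna = 30L,
                         n_reps = 4L, n_triplets = 0L,
                         de_fraction = c(circRNA = 0.3, miRNA = 0.3,
                                         mRNA = 0.1),
                         log2fc_range = c(0.3, 0.6), seed = 23L)
  sim_weak <- simulate_counts(cfg_weak)
  norm <- list(circRNA = tpm_normalize(sim$matrices$circRNA),
               miRNA = tpm_normalize(sim_weak$matrices$miRNA),
               mRNA = fpkm_normalize(sim$matrices$mRNA))
  de <- list(
    circRNA = list(day7 = de_test(sim$matrices$circRNA, "day7")),
    miRNA = list(day7 = fake_de_table(
      sim_weak$truth$de$miRNA$day7$feature_id,
      sim_weak$truth$de$miRNA$day7$direction,
      species = "miRNA")),
    mRNA = list(day7 = de_test(sim$matrices$mRNA, "day7")))
  sheet <- sim$sample_sheet
  d7 <- sheet$sample_id[sheet$timepoint == "day7"]
  grp <- sheet$group[sheet$timepoint == "day7"]
  acc <- function(sp) {
    sig <- build_signature(norm, de, sp, samples = d7)
    cluster_accuracy(sig, grp, k = 2)$accuracy
  }
  expect_gte(acc("circRNA"), acc("miRNA"))
})

test_that("species comparison ranks combinations and skips empty species", {
  sim <- simulate_counts(tiny_config(n_circ = 80L, n_mirna = 40L,
                                     n_mrna = 80L,
                                     de_fraction = 0.2, seed = 29L))
  norm <- list(circRNA = tpm_normalize(sim$matrices$circRNA),
               miRNA = tpm_normalize(sim$matrices$miRNA),
               mRNA = fpkm_normalize(sim$matrices$mRNA))
  de <- lapply(setNames(nm = names(norm)), function(sp) {
    list(day7 = de_test(sim$matrices[[sp]], "day7"),
         day28 = de_test(sim$matrices[[sp]], "day28"))
  })
  tab <- species_comparison(norm, de)
  expect_true(all(c("accuracy_k4", "accuracy_day7_k2", "pc1_pct")
                  %in% names(tab)))
  expect_true(all(diff(tab$accuracy_k4) <= 0))  # ranked
  expect_true(all(tab$pc1_pct >= tab$pc2_pct))
  # a species with no DE features is skipped with a warning
  de$mRNA <- list(day7 = fake_de_table("x", "ns", species = "mRNA"))
  expect_warning(tab2 <- species_comparison(norm, de), "skipping")
  expect_false("mRNA" %in% tab2$combination)
})
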