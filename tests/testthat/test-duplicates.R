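test_that("partition summary reproduces the printed grass percentages", {
  tab <- grass_table("duplicate_partition")
  s <- partition_summary(tab$dated_pairs, tab$retained)
  expect_equal(s$shuffled, c(177, 120, 165, 400))
  expect_equal(s$shuffled_pct, c(29, 25, 40, 62))
  expect_equal(s$retained_pct + s$shuffled_pct >= 100, rep(TRUE, 4))
  # row-sum identity: retained + shuffled = total, always
  expect_equal(s$retained + s$shuffled, tab$dated_pairs)
  expect_error(partition_summary(10, 12), "exceed")
})

test_that("pairs inside one paralogon are retained, others shuffled", {
  segments <- data.frame(
    seg = 1:4, genome = "sp", chrom = c("c1", "c2", "c3", "c4"),
    start = 0, end = 1e6,
    ancestry_label = c("G1", "G1", "G2", "G2"),
    compartment_label = c("C1", "C2", "C3", "C4"))
  gene_pos <- data.frame(
    gene_id = c("r1", "r2", "s1", "s2", "out"),
    genome = "sp",
    chrom = c("c1", "c2", "c1", "c3", "c9"),
    mid = c(5e5, 5e5, 2e5, 2e5, 100))
  pairs <- data.frame(gene_a = c("r1", "s1"), gene_b = c("r2", "s2"))
  out <- classify_duplicates(pairs, segments, gene_pos)
  expect_equal(out$calls$status, c("retained", "shuffled"))
  expect_equal(out$calls$paralogon[1], "G1")
  expect_equal(out$summary$retained_pct, 50)
  # unannotated chromosome -> skipped with a warning
  p2 <- rbind(pairs, data.frame(gene_a = "r1", gene_b = "nope"))
  expect_warning(classify_duplicates(p2, segments, gene_pos), "skipped")
})

test_that("zero shuffling yields 100% retained on simulated data", {
  cfg <- small_config(p_shuffle = 0, inversion_rate = 0, tandem_rate = 0,
                      pav_rate = 0)
  sim <- simulate_genomes(cfg)
  res <- run_pipeline(sim)
  expect_true(all(res$duplicates$summary$retained_pct == 100))
})

test_that("shuffled-gene clustering follows the gap and intervening rules", {
  gp <- data.frame(gene_id = paste0("f", 1:6), genome = "sp", chrom = "c1",
                   mid = c(1e5, 2e5, 6e5, 6.2e5, 6.4e5, 1.4e6))
  # two genes 500 kb apart stay singletons
  s1 <- cluster_shuffled(gp[c(1, 3), ], gp)
  expect_true(all(s1$class == "singleton"))
  # three genes within 40 kb and no intervening genes merge
  s2 <- cluster_shuffled(gp[3:5, ], gp)
  expect_true(all(s2$cluster_size == 3))
  expect_true(all(s2$class == "small"))
  # an intervening-gene excess splits the cluster
  many <- data.frame(gene_id = paste0("bg", 1:10), genome = "sp",
                     chrom = "c1", mid = seq(6.05e5, 6.15e5, length.out = 10))
  s3 <- cluster_shuffled(gp[3:4, ], rbind(gp, many))
  expect_true(all(s3$class == "singleton"))
})

test_that("the published small-cluster rate is 12 per mil", {
  expect_equal(small_cluster_permil(10, 824), 12)
  expect_equal(small_cluster_permil(0, 100), 0)
})

test_that("deletion chronology places losses by minimal clade cover", {
  tree <- ape::read.tree(
    text = "((rice:40,brachypodium:40)BEP:10,(sorghum:40,maize:40)PACCAD:10)root;")
  mk <- function(...) {
    pres <- c(...)
    data.frame(protogene = 1, copy = "S", rice = pres[1],
               brachypodium = pres[2], sorghum = pres[3], maize = pres[4])
  }
  expect_equal(classify_chronology(mk(FALSE, FALSE, FALSE, FALSE),
                                   tree)$call, "ancestral")
  expect_equal(classify_chronology(mk(TRUE, TRUE, FALSE, FALSE),
                                   tree)$call, "lineage_PACCAD")
  expect_equal(classify_chronology(mk(FALSE, FALSE, TRUE, TRUE),
                                   tree)$call, "lineage_BEP")
  expect_equal(classify_chronology(mk(TRUE, TRUE, TRUE, FALSE),
                                   tree)$call, "species_specific")
  # cross-clade absence decomposes into two species-specific losses
  cc <- classify_chronology(mk(FALSE, TRUE, FALSE, TRUE), tree)
  expect_equal(cc$n_events, 2)
  expect_match(cc$events, "rice")
  expect_match(cc$events, "sorghum")
  expect_error(classify_chronology(mk(TRUE, TRUE, TRUE, TRUE)[0, ], tree),
               "empty")
})

test_that("chronology event counts equal the brute-force cover oracle", {
  tree <- ape::read.tree(
    text = "((rice:40,brachypodium:40)BEP:10,(sorghum:40,maize:40)PACCAD:10)root;")
  species <- tree$tip.label
  clades <- list(sort(species), c("brachypodium", "rice"),
                 c("maize", "sorghum"),
                 as.list(species))
  clades <- c(clades[1:3], as.list(species))
  for (mask in 1:15) {
    pres <- bitwAnd(mask, 2^(0:3)) == 0
    absent <- sort(species[!pres])
    row <- data.frame(protogene = 1, copy = "S", rice = pres[1],
                      brachypodium = pres[2], sorghum = pres[3],
                      maize = pres[4])
    got <- classify_chronology(row, tree)
    expect_equal(got$n_events, oracle_min_cover(absent, clades),
                 info = paste("pattern", mask))
  }
})

test_that("chronology calls are invariant to leaf ordering", {
  tree <- ape::read.tree(
    text = "((rice:40,brachypodium:40)BEP:10,(sorghum:40,maize:40)PACCAD:10)root;")
  row <- data.frame(protogene = 1, copy = "S", maize = FALSE,
                    sorghum = FALSE, rice = TRUE, brachypodium = TRUE)
  expect_equal(classify_chronology(row, tree)$call, "lineage_PACCAD")
})

test_that("feature contrast reports means and rank-sum p-values", {
  set.seed(8)
  a <- data.frame(glen = rlnorm(100, log(4700), 0.3),
                  exon_count = rpois(100, 8) + 1)
  fc_same <- feature_contrast(a, a)
  expect_equal(fc_same$p_length, c(1, 1))
  expect_equal(fc_same$mean_length_bp[1], fc_same$mean_length_bp[2])
  b <- data.frame(glen = rlnorm(100, log(2900), 0.3),
                  exon_count = rpois(100, 4) + 1)
  fc <- feature_contrast(a, b)
  expect_gt(fc$mean_length_bp[1], fc$mean_length_bp[2])
  expect_lt(fc$p_length[1], 0.01)
  expect_error(feature_contrast(a[0, ], b), "non-empty")
})

test_that("a transposition bias toward short genes shows in the contrast", {
  cfg <- small_config(p_shuffle = 0.01, move_short_bias = 2, seed = 13)
  sim <- simulate_genomes(cfg)
  g <- do.call(rbind, lapply(sim$genomes, `[[`, "genes"))
  expect_lt(mean(g$glen[g$moved]), mean(g$glen[!g$moved]))
})
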