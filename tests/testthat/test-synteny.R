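diag_anchors <- function(n, spacing = 12000, sign = 1) {
  data.frame(gene_a = paste0("a", seq_len(n)),
             gene_b = paste0("b", seq_len(n)),
             pos_a = seq_len(n) * spacing,
             pos_b = sign * seq_len(n) * spacing + ifelse(sign < 0,
                                                          (n + 1) * spacing,
                                                          0))
}

test_that("an ideal diagonal chains into a single block", {
  bl <- chain_anchors(diag_anchors(10))
  expect_length(bl, 1)
  expect_equal(bl[[1]]$anchor_count, 10)
  expect_equal(bl[[1]]$orientation, "same")
  # reversed side-b order gives one inverted block
  bl2 <- chain_anchors(diag_anchors(10, sign = -1))
  expect_length(bl2, 1)
  expect_equal(bl2[[1]]$orientation, "inverted")
})

test_that("a >100 kb gap splits the chain and short fragments are dropped", {
  an <- diag_anchors(10)
  an$pos_a[6:10] <- an$pos_a[6:10] + 150000
  an$pos_b[6:10] <- an$pos_b[6:10] + 150000
  # two 5-anchor fragments fail the >5-anchor rule
  expect_length(chain_anchors(an, synteny_params(min_anchors = 6)), 0)
  bl <- chain_anchors(an, synteny_params(min_anchors = 5,
                                         min_span_bp = 40000))
  expect_length(bl, 2)
  expect_equal(vapply(bl, `[[`, 0L, "anchor_count"), c(5L, 5L))
})

test_that("cleaning parameters are enforced exactly at the edges", {
  # exactly 6 anchors pass, 5 do not
  expect_length(chain_anchors(diag_anchors(6, spacing = 25000),
                              synteny_params()), 1)
  expect_length(chain_anchors(diag_anchors(5, spacing = 25000),
                              synteny_params()), 0)
  # a 100,001 bp gap breaks the chain, 100,000 does not
  an <- diag_anchors(12, spacing = 20000)
  an2 <- an
  an2$pos_a[7:12] <- an2$pos_a[7:12] + 80001 # gap becomes 100,001
  bl <- chain_anchors(an2, synteny_params())
  expect_equal(max(vapply(bl, `[[`, 0L, "anchor_count")), 6L)
  an3 <- an
  an3$pos_a[7:12] <- an3$pos_a[7:12] + 80000 # gap exactly 100,000
  bl3 <- chain_anchors(an3, synteny_params())
  expect_equal(bl3[[1]]$anchor_count, 12L)
  # span below 100 kb on both sides is discarded
  tight <- diag_anchors(8, spacing = 9000) # span 63 kb both sides
  expect_length(chain_anchors(tight, synteny_params()), 0)
  expect_length(chain_anchors(tight, synteny_params(min_span_bp = 50000)),
                1)
})

test_that("chaining matches the exhaustive-search oracle on random cases", {
  set.seed(99)
  params <- synteny_params(min_anchors = 1, min_span_bp = 0)
  for (rep in 1:100) {
    n <- sample(6:15, 1)
    an <- data.frame(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
                     pos_a = sample.int(400000, n),
                     pos_b = sample.int(400000, n))
    bl <- chain_anchors(an, params)
    got <- if (length(bl)) max(vapply(bl, `[[`, 0L, "anchor_count")) else 0L
    expect_equal(got, oracle_max_chain(an, params$max_gap_bp))
  }
})

test_that("chaining is symmetric in the two sides", {
  set.seed(17)
  an <- data.frame(gene_a = paste0("a", 1:30), gene_b = paste0("b", 1:30),
                   pos_a = sort(sample.int(300000, 30)),
                   pos_b = sort(sample.int(300000, 30)))
  sw <- data.frame(gene_a = an$gene_b, gene_b = an$gene_a,
                   pos_a = an$pos_b, pos_b = an$pos_a)
  b1 <- chain_anchors(an, synteny_params(min_anchors = 3, min_span_bp = 0))
  b2 <- chain_anchors(sw, synteny_params(min_anchors = 3, min_span_bp = 0))
  expect_equal(length(b1), length(b2))
  s1 <- lapply(b1, function(b) sort(b$anchors$gene_a))
  s2 <- lapply(b2, function(b) sort(b$anchors$gene_b))
  expect_setequal(vapply(s1, paste, "", collapse = ","),
                  vapply(s2, paste, "", collapse = ","))
})

test_that("no anchor is assigned to two blocks", {
  set.seed(31)
  an <- data.frame(gene_a = paste0("a", 1:60), gene_b = paste0("b", 1:60),
                   pos_a = sample.int(600000, 60),
                   pos_b = sample.int(600000, 60))
  bl <- chain_anchors(an, synteny_params(min_anchors = 2, min_span_bp = 0))
  all_ids <- unlist(lapply(bl, function(b) b$anchors$gene_a))
  expect_equal(anyDuplicated(all_ids), 0)
})

test_that("tandem paralog pairs are excluded from paralogy anchors", {
  pairs <- data.frame(query = c("g1", "g3"), subject = c("g2", "g4"))
  pos <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    genome = "sp", chrom = c("c1", "c1", "c1", "c2"),
                    mid = c(10000, 50000, 100000, 900000))
  an <- anchors_from_pairs(pairs, pos, "paralog")
  # g1-g2 sit 40 kb apart on one chromosome: CNV candidate, dropped
  expect_equal(nrow(an), 1)
  expect_setequal(c(an$gene_a, an$gene_b), c("g3", "g4"))
})

test_that("ancestry components reproduce the protochromosome partition", {
  sim <- default_sim()
  res <- default_pipeline()
  gp <- gene_pos_table(sim$genomes, drop_tandem = TRUE)
  gp$proto_chrom <- unname(sim$truth$proto_map[as.character(gp$protogene)])
  gseg <- genes_in_segments(res$segments, gp)
  # transposed genes truly reside in foreign territory; the partition
  # claim concerns genes still at ancestral positions
  gseg <- gseg[!is.na(gseg$ancestry_label) & !gseg$moved, ]
  maj <- tapply(gseg$proto_chrom, gseg$ancestry_label, function(p)
    names(which.max(table(p))))
  acc <- mean(unname(maj[gseg$ancestry_label]) == gseg$proto_chrom)
  expect_gte(acc, 0.95)
  # one component per protochromosome among the ancestral-duplication set
  big <- res$block_summary[res$block_summary$ancestral_dup, ]
  expect_equal(nrow(big), sim$config$n_proto)
})

test_that("paralogy confined to one genome is flagged lineage-specific", {
  mk_anchor <- function(g, pfx, n) data.frame(
    gene_a = paste0(pfx, "x", 1:n), gene_b = paste0(pfx, "y", 1:n),
    genome_a = g, chrom_a = "c1", pos_a = (1:n) * 25000,
    genome_b = g, chrom_b = "c2", pos_b = (1:n) * 25000, scope = "paralog")
  blocks <- synteny_blocks(rbind(mk_anchor("spA", "a", 8)),
                           synteny_params())
  out <- assign_block_ancestry(blocks)
  expect_true(all(out$summary$lineage_specific))
  expect_false(any(out$summary$ancestral_dup))
})
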