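test_that("ancestor construction lays out the requested karyotype", {
  cfg <- simulation_config(n_proto = 7, genes_per_chrom = 100)
  anc <- build_ancestor(cfg)
  expect_equal(nrow(anc$chroms), 7)
  expect_equal(nrow(anc$genes), 700)
  expect_true(all(anc$chroms$cen_functional))
  expect_equal(anyDuplicated(anc$genes$protogene), 0)

  one <- build_ancestor(simulation_config(n_proto = 1, genes_per_chrom = 1))
  expect_equal(nrow(one$genes), 1)
  expect_true(one$chroms$cen_functional)

  # full published scale: 7 x 2352 = 16,464 protogenes
  big <- build_ancestor(simulation_config(n_proto = 7,
                                          genes_per_chrom = 2352))
  expect_equal(nrow(big$genes), 16464)

  expect_error(build_ancestor(simulation_config(n_proto = 0)),
               "positive")
})

test_that("WGD duplicates every chromosome with one D and one S copy", {
  anc <- build_ancestor(simulation_config(n_proto = 7,
                                          genes_per_chrom = 20))
  res <- apply_wgd(anc, time = 60, seed = 5)
  expect_equal(nrow(res$genome$chroms), 14)
  expect_equal(sum(res$genome$chroms$paleo == "D"), 7)
  expect_equal(sum(res$genome$chroms$paleo == "S"), 7)
  expect_equal(nrow(res$pairs), nrow(anc$genes))
  expect_true(all(res$pairs$status == "retained"))
  # one D and one S copy per ancestral chromosome
  expect_true(all(res$ds_assignment$chrom_d != res$ds_assignment$chrom_s))
})

test_that("two successive WGDs give four copies per surviving protogene", {
  cfg <- small_config(p_del_D = 0, p_del_S = 0, p_shuffle = 0,
                      inversion_rate = 0, tandem_rate = 0, pav_rate = 0,
                      wgd_times = list(shared = 60, maize = 5))
  sim <- simulate_genomes(cfg)
  mz <- sim$genomes$maize$genes
  copies <- table(mz$protogene)
  expect_true(all(copies == 4))
})

test_that("zero rates leave the leaves identical to the post-WGD ancestor", {
  cfg <- small_config(p_del_D = 0, p_del_S = 0, p_shuffle = 0,
                      inversion_rate = 0, tandem_rate = 0, pav_rate = 0,
                      wgd_times = list(shared = 60))
  sim <- simulate_genomes(cfg)
  base <- NULL
  for (sp in names(sim$genomes)) {
    g <- sim$genomes[[sp]]$genes
    ids <- sub(paste0("^", sp, "_"), "", g$gene_id[order(g$chrom, g$idx)])
    if (is.null(base)) base <- ids else expect_identical(ids, base)
  }
  expect_equal(length(base), 2 * 2 * 60)
})

test_that("sensitive compartments retain fewer genes than dominant ones", {
  sim <- default_sim()
  for (sp in names(sim$genomes)) {
    g <- sim$genomes[[sp]]$genes
    d_ret <- length(unique(g$protogene[g$paleo == "D"]))
    s_ret <- length(unique(g$protogene[g$paleo == "S"]))
    expect_lt(s_ret, d_ret)
  }
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- small_config()
  s1 <- simulate_genomes(cfg)
  s2 <- simulate_genomes(cfg)
  for (sp in names(s1$genomes))
    expect_identical(s1$genomes[[sp]]$genes, s2$genomes[[sp]]$genes)
  expect_identical(s1$truth$events, s2$truth$events)
  expect_identical(s1$truth$true_pairs, s2$truth$true_pairs)
})

test_that("copy conservation: every protogene accounts for two WGD copies", {
  cfg <- small_config(wgd_times = list(shared = 60))
  sim <- simulate_genomes(cfg)
  for (sp in names(sim$genomes)) {
    g <- sim$genomes[[sp]]$genes
    g <- g[g$origin != "tandem", ]
    per <- table(paste(g$protogene, g$paleo))
    expect_true(all(per <= 1)) # at most one surviving copy per compartment
    tp <- sim$truth$true_pairs
    tp <- tp[tp$genome == sp & tp$event == "ancient_wgd", ]
    # survivors + deleted entries cover every protogene exactly once
    expect_lte(nrow(tp), 120)
    expect_equal(anyDuplicated(tp$protogene), 0)
  }
})

test_that("stronger deletion bias strictly lowers S-compartment retention", {
  s_retention <- function(ratio, seed) {
    cfg <- small_config(p_del_D = 0.003, p_del_S = 0.003 * ratio,
                        seed = seed)
    sim <- simulate_genomes(cfg)
    mean(vapply(sim$genomes, function(gn)
      sum(gn$genes$paleo == "S", na.rm = TRUE) / 120, 0))
  }
  reps <- 1:5
  r1 <- mean(vapply(reps, function(s) s_retention(1, s), 0))
  r2 <- mean(vapply(reps, function(s) s_retention(2, s), 0))
  r4 <- mean(vapply(reps, function(s) s_retention(4, s), 0))
  expect_gt(r1, r2)
  expect_gt(r2, r4)
})

test_that("moved genes travel in small clusters at the configured rate", {
  cfg <- small_config(p_shuffle = 0.02, seed = 9)
  sim <- simulate_genomes(cfg)
  ev <- sim$truth$events
  mv <- ev[ev$kind == "transposition", "detail"]
  sizes <- lengths(strsplit(mv, ","))
  frac <- sum(sizes[sizes > 1]) / sum(sizes)
  d <- cfg$cluster_size_dist
  expected <- sum(as.integer(names(d))[-1] * d[-1]) /
    sum(as.integer(names(d)) * d)
  expect_lt(abs(frac - expected), 0.02)
})

test_that("emitted Ks tracks the molecular clock", {
  sim <- default_sim()
  pt <- grasskaryo:::sim_pair_table(sim)
  anc <- pt[pt$relation == "ancient_wgd", ]
  expect_gt(nrow(anc), 500)
  expected <- 2 * sim$config$ks_rate * 60e6
  se <- stats::sd(anc$ks) / sqrt(nrow(anc))
  expect_lt(abs(mean(anc$ks) - expected), 3 * se)
})

test_that("an invalid fusion plan or emptied chromosome is reported", {
  cfg <- small_config(fusion_plan = list(
    list(lineage = "rice", time = 20, kind = "CCF",
         chroms = c("c1", "nope"))))
  expect_error(simulate_genomes(cfg), "absent chromosome")
  expect_error(simulation_config(p_del_D = 1.5), "\\[0, 1\\]")
  expect_error(
    simulation_config(wgd_times = list(shared = 60, rice = 5, rice = 5)),
    "repeated WGD")
})

test_that("emitted dataset round-trips through the readers", {
  sim_dir <- withr::local_tempdir()
  cfg <- small_config()
  sim <- simulate_genomes(cfg)
  emit_dataset(sim, sim_dir)
  for (sp in names(sim$genomes)) {
    g1 <- load_genome(file.path(sim_dir, paste0(sp, ".gff3")))
    g2 <- load_genome(file.path(sim_dir, paste0(sp, ".bed")))
    expect_equal(nrow(g1$genes), nrow(sim$genomes[[sp]]$genes))
    expect_setequal(g1$genes$gene_id, sim$genomes[[sp]]$genes$gene_id)
    expect_equal(g1$genes[, c("gene_id", "chrom", "start", "end")],
                 g2$genes[, c("gene_id", "chrom", "start", "end")])
  }
  ks <- utils::read.table(file.path(sim_dir, "ks.tsv"), header = TRUE)
  expect_true(all(ks$ks > 0))
  # byte-identical re-emission under the same seed
  dir2 <- withr::local_tempdir()
  emit_dataset(simulate_genomes(cfg), dir2)
  for (f in list.files(sim_dir)) {
    expect_identical(readLines(file.path(sim_dir, f)),
                     readLines(file.path(dir2, f)))
  }
})
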