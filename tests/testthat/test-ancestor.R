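mk_orders <- function(perms, strands = NULL) {
  do.call(rbind, lapply(names(perms), function(g) {
    m <- perms[[g]]
    data.frame(genome = g, chrom = "c1", idx = seq_along(m), marker = m,
               strand = if (is.null(strands)) "+" else strands[[g]],
               ancestry_label = "G1", stringsAsFactors = FALSE)
  }))
}

grass_clades <- list(c("rice", "brachypodium"), c("sorghum", "maize"))

test_that("identical gene orders support every adjacency in all genomes", {
  ord <- mk_orders(list(rice = letters[1:6], brachypodium = letters[1:6],
                        sorghum = letters[1:6], maize = letters[1:6]))
  adj <- conserved_adjacencies(ord, grass_clades)
  expect_equal(nrow(adj), 5)
  expect_true(all(adj$weight == 4))
  expect_true(all(adj$candidate))
})

test_that("clade-restricted adjacencies are excluded from candidates", {
  ord <- mk_orders(list(rice = c("a", "b", "c"),
                        brachypodium = c("a", "b", "c"),
                        sorghum = c("a", "c", "b"),
                        maize = c("a", "c", "b")))
  adj <- conserved_adjacencies(ord, grass_clades)
  ab <- adj[adj$u == "a" & adj$v == "b", ]
  expect_equal(ab$n_genomes, 2)
  expect_false(ab$candidate) # BEP only: not root-spanning
  ac <- adj[adj$u == "a" & adj$v == "c", ]
  expect_false(ac$candidate) # PACCAD only
  bc <- adj[adj$u == "b" & adj$v == "c", ]
  expect_true(bc$candidate) # seen (in either order) in both clades
  expect_equal(bc$weight, 4)
})

test_that("markers missing from a whole clade are dropped before voting", {
  ord <- mk_orders(list(rice = c("a", "x", "b"),
                        brachypodium = c("a", "b"),
                        sorghum = c("a", "b"), maize = c("a", "b")))
  adj <- conserved_adjacencies(ord, grass_clades)
  # x exists only in the BEP clade: (a,b) must still be supported 4x
  ab <- adj[adj$u == "a" & adj$v == "b", ]
  expect_equal(ab$weight, 4)
  expect_false("x" %in% c(adj$u, adj$v))
})

test_that("orientation mismatches reduce the adjacency weight", {
  ord <- mk_orders(list(rice = c("a", "b"), brachypodium = c("a", "b"),
                        sorghum = c("a", "b"), maize = c("a", "b")),
                   strands = list(rice = c("+", "+"),
                                  brachypodium = c("+", "+"),
                                  sorghum = c("+", "+"),
                                  maize = c("+", "-")))
  adj <- conserved_adjacencies(ord, grass_clades)
  expect_equal(adj$weight, 3.5)
})

test_that("conflict-free adjacencies linearize into the unique order", {
  adj <- data.frame(u = c("a", "b", "c"), v = c("b", "c", "d"),
                    orient = "same", weight = c(4, 4, 4), candidate = TRUE)
  cars <- linearize_cars(adj)
  expect_length(cars, 1)
  expect_true(identical(cars[[1]]$marker, c("a", "b", "c", "d")) ||
                identical(cars[[1]]$marker, c("d", "c", "b", "a")))
})

test_that("the weakest edge of a three-neighbour conflict is dropped", {
  adj <- data.frame(u = c("a", "c", "e", "x"), v = c("b", "b", "b", "a"),
                    orient = "same", weight = c(4, 4, 1, 2),
                    candidate = TRUE)
  cars <- linearize_cars(adj)
  sel <- unlist(lapply(cars, function(d) d$marker))
  # b keeps its two weight-4 neighbours; the weight-1 edge to e goes
  car_of_b <- cars[[which(vapply(cars, function(d) "b" %in% d$marker,
                                 TRUE))]]
  expect_setequal(intersect(c("a", "c"), car_of_b$marker), c("a", "c"))
  expect_false("e" %in% car_of_b$marker)
})

test_that("small conflict instances reach the brute-force optimum", {
  set.seed(12)
  for (rep in 1:25) {
    nv <- sample(5:9, 1)
    verts <- letters[1:nv]
    ne <- sample(5:11, 1)
    ed <- unique(data.frame(
      u = sample(verts, ne, replace = TRUE),
      v = sample(verts, ne, replace = TRUE)))
    ed <- ed[ed$u < ed$v, , drop = FALSE]
    if (nrow(ed) < 2) next
    ed$orient <- "same"
    ed$weight <- sample(4, nrow(ed), replace = TRUE)
    ed$candidate <- TRUE
    cars <- linearize_cars(ed)
    # selected weight = sum over consecutive pairs present in the edge set
    got <- sum(unlist(lapply(cars, function(d) {
      if (nrow(d) < 2) return(0)
      u <- d$marker[-nrow(d)]; v <- d$marker[-1]
      key <- paste(pmin(u, v), pmax(u, v))
      ed$weight[match(key, paste(ed$u, ed$v))]
    })))
    expect_equal(got, oracle_linear_forest_weight(ed))
  }
})

test_that("every marker lands in exactly one CAR and paths never branch", {
  set.seed(23)
  ed <- data.frame(u = sample(letters[1:12], 30, replace = TRUE),
                   v = sample(letters[1:12], 30, replace = TRUE))
  ed <- unique(ed[ed$u < ed$v, ])
  ed$orient <- "same"
  ed$weight <- runif(nrow(ed), 1, 4)
  ed$candidate <- TRUE
  cars <- linearize_cars(ed)
  all_m <- unlist(lapply(cars, function(d) d$marker))
  expect_equal(anyDuplicated(all_m), 0)
  expect_setequal(all_m, unique(c(ed$u, ed$v)))
})

test_that("identical sister CARs merge into the same pre-WGD order", {
  cars <- list(
    data.frame(rank = 1:4, marker = paste0("d", 1:4), orientation = "+"),
    data.frame(rank = 1:4, marker = paste0("s", 1:4), orientation = "+"))
  m2p <- stats::setNames(rep(paste0("p", 1:4), 2),
                         c(paste0("d", 1:4), paste0("s", 1:4)))
  orders <- rbind(
    data.frame(genome = "rice", chrom = "c1", idx = 1:4,
               marker = paste0("d", 1:4), ancestry_label = "G1"),
    data.frame(genome = "rice", chrom = "c2", idx = 1:4,
               marker = paste0("s", 1:4), ancestry_label = "G1"))
  pre <- preduplication_order(cars, m2p, orders)
  expect_length(pre, 1)
  expect_equal(pre[[1]]$marker, paste0("p", 1:4))
})

test_that("complementary losses keep only doubly attested genes", {
  # d-side lost p3, s-side lost p2: only p1 and p4 survive in both
  cars <- list(
    data.frame(rank = 1:3, marker = c("d1", "d2", "d4"), orientation = "+"),
    data.frame(rank = 1:3, marker = c("s1", "s3", "s4"), orientation = "+"))
  m2p <- stats::setNames(c("p1", "p2", "p4", "p1", "p3", "p4"),
                         c("d1", "d2", "d4", "s1", "s3", "s4"))
  orders <- rbind(
    data.frame(genome = "rice", chrom = "c1", idx = 1:3,
               marker = c("d1", "d2", "d4"), ancestry_label = "G1"),
    data.frame(genome = "rice", chrom = "c2", idx = 1:3,
               marker = c("s1", "s3", "s4"), ancestry_label = "G1"))
  pre <- preduplication_order(cars, m2p, orders)
  expect_length(pre, 1)
  expect_setequal(pre[[1]]$marker, c("p1", "p4"))
})

test_that("reconstruction attains most of the survival-limited ceiling", {
  sim <- default_sim()
  res <- default_pipeline()
  adjr <- adjacency_recovery(sim, res$adjacencies, res$orders)
  ceil <- adjacency_support_ceiling(sim)
  expect_gte(adjr$recovery, 0.85 * ceil$ceiling)
})

test_that("higher shuffling never improves adjacency recovery (trend)", {
  rec_at <- function(p_shuffle) {
    mean(vapply(1:3, function(s) {
      sim <- simulate_genomes(small_config(p_shuffle = p_shuffle,
                                           seed = 100 + s))
      gp <- gene_pos_table(sim$genomes, drop_tandem = TRUE)
      gp$marker <- paste0(gp$protogene, "_", gp$paleo)
      gp$ancestry_label <- "G1"
      adj <- conserved_adjacencies(gp, grass_clades)
      adjr <- adjacency_recovery(sim, adj, gp)
      adjr$recovery
    }, 0))
  }
  r0 <- rec_at(0)
  r1 <- rec_at(0.005)
  r2 <- rec_at(0.02)
  expect_gte(r0, r1 - 0.02)
  expect_gt(r1, r2)
})
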