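test_that("fusion dominance algebra and centromere bookkeeping hold", {
  kar <- proto_karyotype(data.frame(name = c("X", "Y", "Z"),
                                    dom = c("D", "S", "D")))
  # D + S = D with ordered segments
  k1 <- apply_event(kar, list(kind = "ccf", chroms = c("X", "Y"),
                              product = "XY"))
  expect_equal(k1$chroms$XY$dom, "D")
  expect_equal(k1$chroms$XY$segments$dom, c("D", "S"))
  expect_true(k1$chroms$XY$cen)
  # D + D = D (supradominant)
  k2 <- apply_event(kar, list(kind = "tcf", chroms = c("X", "Z")))
  expect_equal(k2$chroms$XZ$dom, "D")
  # centromeric fission leaves two nonfunctional products
  k3 <- apply_event(kar, list(kind = "fission", chrom = "X",
                              products = c("Xp", "Xq")))
  expect_false(k3$chroms$Xp$cen)
  expect_false(k3$chroms$Xq$cen)
  expect_error(apply_event(kar, list(kind = "ccf", chroms = c("X", "X"))),
               "distinct")
  expect_error(apply_event(kar, list(kind = "ccf", chroms = c("X", "Q"))),
               "absent")
  expect_error(apply_event(kar, list(kind = "warp", chrom = "X")),
               "unknown")
})

test_that("a WGD copy of a sensitive chromosome can never be dominant", {
  kar <- proto_karyotype(data.frame(name = c("A", "B"), dom = c("D", "S")))
  k <- apply_event(kar, list(kind = "wgd", copies = list(
    list(parent = "A", copy = "A2", copy_dom = "S"),
    list(parent = "B", copy = "B2", copy_dom = "D"))))
  expect_equal(k$chroms$A2$dom, "S")
  expect_equal(k$chroms$B2$dom, "S") # request for D is overridden
  expect_equal(k$chroms$B2$anc_dom, "S")
})

test_that("no event sequence maps a sensitive origin to dominance", {
  set.seed(6)
  doms <- c("D", "S")
  for (rep in 1:30) {
    n0 <- sample(3:6, 1)
    kar <- proto_karyotype(data.frame(
      name = paste0("K", 1:n0), dom = sample(doms, n0, replace = TRUE)))
    expected_n <- n0
    for (step in 1:8) {
      nm <- names(kar$chroms)
      kind <- sample(c("wgd", "ccf", "tcf", "fission", "deletion"), 1,
                     prob = c(0.1, 0.3, 0.2, 0.25, 0.15))
      if (kind == "wgd") {
        kar <- apply_event(kar, list(kind = "wgd", copies = lapply(
          nm, function(x) list(parent = x, copy = paste0(x, "w", step),
                               copy_dom = sample(doms, 1)))))
        expected_n <- expected_n * 2
      } else if (kind %in% c("ccf", "tcf")) {
        if (length(nm) < 2) next
        ab <- sample(nm, 2)
        kar <- apply_event(kar, list(kind = kind, chroms = ab,
                                     product = paste0(ab[1], step)))
        expected_n <- expected_n - 1
      } else if (kind == "fission") {
        x <- sample(nm, 1)
        kar <- apply_event(kar, list(
          kind = "fission", chrom = x,
          products = paste0(x, step, c("p", "q"))))
        expected_n <- expected_n + 1
      } else {
        if (length(nm) < 2) next
        kar <- apply_event(kar, list(kind = "deletion",
                                     chrom = sample(nm, 1)))
        expected_n <- expected_n - 1
      }
      for (ch in kar$chroms) {
        expect_true(ch$dom %in% doms)
        if (ch$anc_dom == "S") expect_equal(ch$dom, "S")
      }
      # chromosome-count bookkeeping after every event
      expect_equal(length(kar$chroms), expected_n)
    }
  }
})

test_that("chromosome counts follow n0 doublings, fissions and fusions", {
  kar <- proto_karyotype(data.frame(name = c("A", "B"), dom = c("D", "D")))
  k <- apply_event(kar, list(kind = "wgd", copies = list(
    list(parent = "A", copy = "A2", copy_dom = "S"),
    list(parent = "B", copy = "B2", copy_dom = "S"))))
  k <- apply_event(k, list(kind = "fission", chrom = "A2",
                           products = c("A2p", "A2q")))
  k <- apply_event(k, list(kind = "ccf", chroms = c("A", "B"),
                           product = "AB"))
  k <- apply_event(k, list(kind = "deletion", chrom = "A2q"))
  # 2 * 2 + 1 fission - 1 fusion - 1 loss = 3
  expect_equal(length(k$chroms), 3)
  expect_equal(k$n_fission + k$n_fusion, 2)
})

test_that("the event ledger reproduces the published lineage totals", {
  ev <- grass_table("lineage_events")
  led <- build_event_ledger(ev)
  expect_equal(led$large_scale_total, 71)
  expect_equal(led$gene_movement_total, 2067)
  expect_equal(unname(led$totals["ccf"]), 16)
  expect_equal(unname(led$totals["tcf"]), 10)
  expect_equal(unname(led$totals["inversion"]), 45)
  # totals equal per-lineage sums
  expect_equal(sum(led$counts), sum(ev$count))
  empty <- build_event_ledger(data.frame(lineage = character(),
                                         kind = character(),
                                         count = integer()))
  expect_equal(sum(empty$totals), 0)
  expect_error(build_event_ledger(data.frame(lineage = "x", kind = "boom",
                                             count = 1)), "unknown")
})

test_that("candidate scenario fixtures evaluate as published", {
  out <- evaluate_candidate_scenarios()
  ev <- out$evaluations
  # n = 7: no violations, one fission + two fusions
  e3 <- ev$scenario3
  expect_equal(nrow(e3$violations), 0)
  expect_true(e3$accepted)
  expect_equal(e3$karyotype$n_fission, 1)
  expect_equal(e3$karyotype$n_fusion, 2)
  expect_equal(e3$parsimony_score, 3)
  # scenario 1: sensitive ancestors observed dominant
  expect_true("R-c" %in% ev$scenario1$violations$rule)
  expect_equal(ev$scenario1$parsimony_score, 8)
  # scenario 2: nonfunctional centromeres
  expect_true("R-a" %in% ev$scenario2$violations$rule)
  # the two n = 6 hybrids also fail
  expect_gte(nrow(ev$scenario4$violations), 1)
  expect_gte(nrow(ev$scenario5$violations), 1)
  # ranking: the n = 7 scenario is the single accepted one and ranks first
  expect_equal(out$ranking$scenario[1], "scenario3")
  expect_equal(sum(out$ranking$accepted), 1)
})

test_that("ties between identical candidates preserve input order", {
  obs <- load_scenario_fixture("observed")
  fx <- load_scenario_fixture("scenario3")
  e <- validate_scenario(fx$ancestor, fx$events, obs)
  ranked <- score_scenarios(list(first = e, second = e))
  expect_equal(ranked$scenario, c("first", "second"))
})
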