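# Forward simulator of paleopolyploid grass-like genome evolution.
#
# The simulator produces modern genomes descending from an n-protochromosome
# ancestor through a shared WGD, optional lineage-specific WGDs, compartment-
# biased gene deletion, single-gene/small-cluster transposition, tandem
# duplication (CNV), segmental deletion (PAV), inversions and planned
# chromosome fusions/fissions, together with a ground-truth event log.

#' Simulation configuration
#'
#' Builds and validates the configuration of the genome-evolution simulator.
#' Defaults describe the grass study system: an n = 7 ancestor, a shared WGD
#' at 60 Ma, one maize-like lineage-specific WGD at 5 Ma, deletion biased 2:1
#' against the sensitive (S) compartment with a pre-speciation burst so that
#' roughly 43\% of duplicate deletions are ancestral, and a per-gene
#' transposition rate placing about 12 per-mil of moved genes in clusters of
#' two to four.
#'
#' @param n_proto number of ancestral protochromosomes
#' @param genes_per_chrom protogenes per protochromosome
#' @param gene_spacing bp between successive gene starts
#' @param gene_length bp per gene model (coordinate grid)
#' @param tree rooted newick with branch lengths in Myr; internal node labels
#'   name lineages for event scheduling
#' @param wgd_times named list lineage -> Myr before present; the entry named
#'   `"shared"` is applied on the stem above the root
#' @param p_del_D,p_del_S per-gene deletion hazard per Myr for the dominant /
#'   sensitive compartment (S >= D enables biased fractionation)
#' @param del_burst multiplier on the deletion hazard on the pre-speciation
#'   stem (fractionation concentrates just after WGD)
#' @param p_shuffle per-gene transposition hazard per Myr
#' @param cluster_size_dist named probabilities over cluster sizes 1..4 for
#'   a transposition event
#' @param inversion_rate,tandem_rate,pav_rate per-lineage event rates per Myr
#' @param inversion_span gene-count range of an inversion
#' @param pav_span gene-count range of a segmental deletion (PAV)
#' @param fusion_plan list of planned karyotype events, each a list with
#'   `lineage`, `time`, `kind` ("CCF", "TCF" or "fission") and `chroms`
#'   (two names) or `chrom` (one name, fission)
#' @param ks_rate substitution rate r (substitutions/synonymous site/year)
#' @param ks_lognoise_sd sd of multiplicative log-normal noise on emitted Ks
#' @param move_short_bias exponent >= 0; transposition picks genes with
#'   weight (1/length)^bias, 0 = unweighted
#' @param ssd_mode if TRUE a transposition is recorded as duplication of the
#'   remaining copy followed by deletion of the donor (SSD hypothesis); the
#'   resulting gene content is identical, only the event taxonomy differs
#' @param seed integer root seed; all lineage streams derive from it
#' @return a validated list of class `sim_config`
#' @export
simulation_config <- function(n_proto = 7L,
                              genes_per_chrom = 200L,
                              gene_spacing = 10000L,
                              gene_length = 3000L,
                              tree = "((rice:40,brachypodium:40)BEP:10,(sorghum:40,maize:40)PACCAD:10)root;",
                              wgd_times = list(shared = 60, maize = 5),
                              p_del_D = 0.002,
                              p_del_S = 0.004,
                              del_burst = 4,
                              p_shuffle = 0.0025,
                              cluster_size_dist = c(`1` = 0.9955, `2` = 0.0020,
                                                    `3` = 0.0015, `4` = 0.0010),
                              inversion_rate = 0.10,
                              inversion_span = c(10L, 40L),
                              tandem_rate = 0.02,
                              pav_rate = 0.02,
                              pav_span = c(2L, 6L),
                              fusion_plan = default_fusion_plan(),
                              ks_rate = 6.5e-9,
                              ks_lognoise_sd = 0.08,
                              move_short_bias = 0,
                              ssd_mode = FALSE,
                              seed = 1L) {
  cfg <- list(n_proto = as.integer(n_proto),
              genes_per_chrom = as.integer(genes_per_chrom),
              gene_spacing = as.integer(gene_spacing),
              gene_length = as.integer(gene_length),
              tree = tree, wgd_times = wgd_times,
              p_del_D = p_del_D, p_del_S = p_del_S, del_burst = del_burst,
              p_shuffle = p_shuffle,
              cluster_size_dist = cluster_size_dist,
              inversion_rate = inversion_rate,
              inversion_span = as.integer(inversion_span),
              tandem_rate = tandem_rate, pav_rate = pav_rate,
              pav_span = as.integer(pav_span),
              fusion_plan = fusion_plan,
              ks_rate = ks_rate, ks_lognoise_sd = ks_lognoise_sd,
              move_short_bias = move_short_bias, ssd_mode = ssd_mode,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_proto < 1L || cfg$genes_per_chrom < 1L)
    stop_user("n_proto and genes_per_chrom must be positive")
  probs <- c(cfg$p_del_D, cfg$p_del_S, cfg$p_shuffle)
  if (any(probs < 0 | probs > 1))
    stop_user("per-Myr probabilities must lie in [0, 1]")
  if (abs(sum(cfg$cluster_size_dist) - 1) > 1e-8)
    stop_user("cluster_size_dist must sum to 1")
  if (cfg$ks_rate <= 0) stop_user("ks_rate must be positive")
  tr <- ape::read.tree(text = cfg$tree)
  if (is.null(tr) || any(tr$edge.length <= 0))
    stop_user("tree must parse and have positive branch lengths")
  wl <- paste(names(cfg$wgd_times), unlist(cfg$wgd_times))
  if (anyDuplicated(wl))
    stop_user("repeated WGD on the same lineage at the same time")
  invisible(cfg)
}

#' Default planned karyotype events for the 4-genome grass-like simulation
#'
#' Lineage-specific centromeric/telomeric fusions emulating the reduction of
#' chromosome numbers in Brachypodium, the Panicoideae ancestor and
#' post-WGD maize. Chromosome names: ancestor chromosomes are `c1..c7`,
#' shared-WGD copies carry suffix `B`, recent-WGD copies suffix `R`.
#'
#' @return list of event descriptions consumed by [simulate_genomes()]
#' @export
default_fusion_plan <- function() {
  list(
    list(lineage = "brachypodium", time = 20, kind = "CCF", chroms = c("c2", "c5B")),
    list(lineage = "brachypodium", time = 18, kind = "CCF", chroms = c("c6", "c3B")),
    list(lineage = "sorghum", time = 30, kind = "CCF", chroms = c("c4", "c7B")),
    list(lineage = "maize", time = 3, kind = "CCF", chroms = c("c1", "c2R")),
    list(lineage = "maize", time = 2, kind = "TCF", chroms = c("c5B", "c6R"))
  )
}

#' Build the ancestral genome
#'
#' Lays out `n_proto` protochromosomes with `genes_per_chrom` protogenes each
#' on a uniform coordinate grid, one functional centromere per chromosome at
#' its midpoint. Annotated gene lengths and exon counts vary log-normally
#' around rice-like means so downstream structural contrasts are meaningful.
#'
#' @param config a [simulation_config()]
#' @return a `genome` for species `"ancestor"`
#' @export
build_ancestor <- function(config) {
  if (config$n_proto < 1L || config$genes_per_chrom < 1L)
    stop_user("n_proto and genes_per_chrom must be positive")
  set.seed(derive_seed(config$seed, "ancestor"))
  n <- config$n_proto * config$genes_per_chrom
  chrom <- rep(paste0("c", seq_len(config$n_proto)),
               each = config$genes_per_chrom)
  idx <- rep(seq_len(config$genes_per_chrom), config$n_proto)
  glen <- pmax(300L, as.integer(round(stats::rlnorm(n, log(3000), 0.45))))
  genes <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = chrom, idx = as.numeric(idx),
    start = 0L, end = 0L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    protogene = seq_len(n),
    paleo = NA_character_, neo = NA_integer_,
    origin = "ancestral", moved = FALSE,
    glen = glen,
    exon_count = pmax(1L, stats::rpois(n, glen / 550)),
    stringsAsFactors = FALSE)
  chroms <- data.frame(
    chrom = paste0("c", seq_len(config$n_proto)),
    cen_after = floor(config$genes_per_chrom / 2),
    cen_functional = TRUE,
    paleo = NA_character_,
    stringsAsFactors = FALSE)
  relayout_genome(new_genome("ancestor", genes, chroms),
                  config$gene_spacing, config$gene_length)
}

#' Apply a whole-genome duplication
#'
#' Every chromosome is duplicated. For the shared (paleo) WGD, one chromosome
#' of each ancestral pair is labelled dominant (D) and the other sensitive
#' (S), drawn at random; copy genes receive suffixed ids. For a
#' lineage-specific (neo) WGD on an already-duplicated genome the existing
#' D/S labels are inherited and the two neo subgenomes are recorded as 1/2.
#' All gene pairs born at the WGD are returned with status `"retained"`.
#'
#' @param genome a `genome`
#' @param time Myr before present of the event
#' @param seed integer seed for the D/S draw
#' @param class `"paleo"` (first, shared WGD) or `"neo"`
#' @return list with elements `genome`, `ds_assignment` (data.frame
#'   chrom_d / chrom_s per ancestral chromosome) and `pairs` (gene_a, gene_b,
#'   protogene, time, status)
#' @export
apply_wgd <- function(genome, time, seed = 1L, class = c("paleo", "neo")) {
  class <- match.arg(class)
  set.seed(seed)
  g <- genome$genes
  ch <- genome$chroms
  suf <- if (class == "paleo") "B" else "R"
  copy <- g
  copy$gene_id <- paste0(g$gene_id, tolower(suf))
  copy$chrom <- paste0(g$chrom, suf)
  ch2 <- ch
  ch2$chrom <- paste0(ch$chrom, suf)
  if (class == "paleo") {
    d_is_orig <- stats::runif(nrow(ch)) < 0.5
    ch$paleo <- ifelse(d_is_orig, "D", "S")
    ch2$paleo <- ifelse(d_is_orig, "S", "D")
    lab <- stats::setNames(c(ch$paleo, ch2$paleo), c(ch$chrom, ch2$chrom))
    g$paleo <- unname(lab[g$chrom])
    copy$paleo <- unname(lab[copy$chrom])
    ds <- data.frame(ancestral = ch$chrom,
                     chrom_d = ifelse(d_is_orig, ch$chrom, ch2$chrom),
                     chrom_s = ifelse(d_is_orig, ch2$chrom, ch$chrom),
                     time = time, stringsAsFactors = FALSE)
  } else {
    g$neo <- 1L
    copy$neo <- 2L
    ds <- data.frame(ancestral = ch$chrom, chrom_d = ch$chrom,
                     chrom_s = ch2$chrom, time = time,
                     stringsAsFactors = FALSE)
  }
  copy$origin <- if (class == "paleo") "wgd" else "neo_wgd"
  pairs <- data.frame(gene_a = g$gene_id, gene_b = copy$gene_id,
                      protogene = g$protogene, time = time,
                      status = "retained", stringsAsFactors = FALSE)
  out <- new_genome(genome$species, rbind(g, copy), rbind(ch, ch2))
  list(genome = out, ds_assignment = ds, pairs = pairs)
}

# ---- per-branch evolution -------------------------------------------------

# continuous processes over a time slice of length dt (Myr)
evolve_segment <- function(genome, cfg, lineage, t_from, t_to, truth,
                           burst = 1) {
  dt <- t_from - t_to
  if (dt <= 0) return(genome)
  g <- genome$genes
  ev <- list()
  t_mid <- (t_from + t_to) / 2

  # biased whole-gene deletion
  haz <- ifelse(!is.na(g$paleo) & g$paleo == "S", cfg$p_del_S, cfg$p_del_D)
  kill <- stats::runif(nrow(g)) < (1 - exp(-haz * burst * dt))
  if (any(kill)) {
    ev[[length(ev) + 1L]] <- data.frame(
      kind = "deletion", lineage = lineage, time = t_mid,
      chrom = g$chrom[kill], detail = g$gene_id[kill],
      stringsAsFactors = FALSE)
    g <- g[!kill, , drop = FALSE]
  }

  # transposition of single genes / small clusters
  w <- if (cfg$move_short_bias > 0) (1 / g$glen)^cfg$move_short_bias else
    rep(1, nrow(g))
  p_move <- (1 - exp(-cfg$p_shuffle * dt)) * w / mean(w)
  movers <- which(stats::runif(nrow(g)) < p_move)
  if (length(movers)) {
    sizes <- as.integer(sample(names(cfg$cluster_size_dist), length(movers),
                               replace = TRUE, prob = cfg$cluster_size_dist))
    taken <- rep(FALSE, nrow(g))
    for (j in seq_along(movers)) {
      i <- movers[j]
      if (taken[i]) next
      same <- which(g$chrom == g$chrom[i])
      same <- same[order(g$idx[same])]
      pos <- match(i, same)
      blk <- same[pos:min(pos + sizes[j] - 1L, length(same))]
      blk <- blk[!taken[blk]]
      if (!length(blk)) next
      taken[blk] <- TRUE
      dest_chrom <- sample(unique(g$chrom), 1L)
      dest_idx <- stats::runif(1, 0, max(g$idx[g$chrom == dest_chrom]) + 1)
      g$chrom[blk] <- dest_chrom
      g$idx[blk] <- dest_idx + seq_along(blk) * 1e-3
      g$moved[blk] <- TRUE
      ev[[length(ev) + 1L]] <- data.frame(
        kind = if (cfg$ssd_mode) "ssd_move" else "transposition",
        lineage = lineage, time = t_mid, chrom = dest_chrom,
        detail = paste(g$gene_id[blk], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }

  # inversions
  n_inv <- stats::rpois(1, cfg$inversion_rate * dt)
  for (k in seq_len(n_inv)) {
    cands <- names(which(table(g$chrom) >= cfg$inversion_span[1] + 2L))
    if (!length(cands)) break
    cc <- sample(cands, 1L)
    rows <- which(g$chrom == cc)
    rows <- rows[order(g$idx[rows])]
    span <- sample(seq(cfg$inversion_span[1], cfg$inversion_span[2]), 1L)
    span <- min(span, length(rows) - 1L)
    i0 <- sample(seq_len(length(rows) - span + 1L), 1L)
    seg <- rows[i0:(i0 + span - 1L)]
    g$idx[seg] <- rev(g$idx[seg])
    g$strand[seg] <- ifelse(g$strand[seg] == "+", "-", "+")
    ev[[length(ev) + 1L]] <- data.frame(
      kind = "inversion", lineage = lineage, time = t_mid, chrom = cc,
      detail = sprintf("%d genes at rank %d", span, i0),
      stringsAsFactors = FALSE)
  }

  # tandem duplications (CNV)
  n_td <- stats::rpois(1, cfg$tandem_rate * dt)
  for (k in seq_len(n_td)) {
    i <- sample(nrow(g), 1L)
    dup <- g[i, , drop = FALSE]
    dup$gene_id <- paste0(g$gene_id[i], ".t", truth$tandem_counter)
    truth$tandem_counter <- truth$tandem_counter + 1L
    dup$idx <- g$idx[i] + 1e-3
    dup$origin <- "tandem"
    g <- rbind(g, dup)
    truth$tandem_pairs[[length(truth$tandem_pairs) + 1L]] <-
      data.frame(gene_a = g$gene_id[i], gene_b = dup$gene_id,
                 time = t_mid, lineage = lineage, stringsAsFactors = FALSE)
    ev[[length(ev) + 1L]] <- data.frame(
      kind = "tandem_duplication", lineage = lineage, time = t_mid,
      chrom = g$chrom[i], detail = dup$gene_id, stringsAsFactors = FALSE)
  }

  # segmental deletions (PAV)
  n_pav <- stats::rpois(1, cfg$pav_rate * dt)
  for (k in seq_len(n_pav)) {
    cc <- sample(unique(g$chrom), 1L)
    rows <- which(g$chrom == cc)
    rows <- rows[order(g$idx[rows])]
    span <- sample(seq(cfg$pav_span[1], cfg$pav_span[2]), 1L)
    if (length(rows) <= span + 1L) next
    i0 <- sample(seq_len(length(rows) - span), 1L)
    seg <- rows[i0:(i0 + span - 1L)]
    ev[[length(ev) + 1L]] <- data.frame(
      kind = "segmental_deletion", lineage = lineage, time = t_mid,
      chrom = cc, detail = paste(g$gene_id[seg], collapse = ","),
      stringsAsFactors = FALSE)
    g <- g[-seg, , drop = FALSE]
  }

  truth$events <- c(truth$events, ev)
  genome$genes <- g
  genome <- drop_empty_chroms(genome)
  relayout_genome(genome, cfg$gene_spacing, cfg$gene_length)
}

# planned karyotype event (fusion/fission) on an evolving genome
apply_karyotype_event <- function(genome, evt, cfg, truth) {
  ch <- genome$chroms
  g <- genome$genes
  if (evt$kind %in% c("CCF", "TCF")) {
    ab <- evt$chroms
    if (!all(ab %in% ch$chrom))
      stop_user("fusion_plan references absent chromosome(s): ",
                paste(setdiff(ab, ch$chrom), collapse = ", "))
    a <- ab[1]; b <- ab[2]
    ra <- which(g$chrom == a); ra <- ra[order(g$idx[ra])]
    rb <- which(g$chrom == b); rb <- rb[order(g$idx[rb])]
    ia <- ch$chrom == a; ib <- ch$chrom == b
    if (evt$kind == "CCF") {
      # insert b at a's centromere; b's centromere stays functional
      cen_a <- min(ch$cen_after[ia], length(ra))
      new_idx <- c(seq_along(ra)[seq_len(cen_a)],
                   cen_a + seq_along(rb),
                   if (cen_a < length(ra))
                     cen_a + length(rb) + seq_len(length(ra) - cen_a))
      g$idx[c(ra[seq_len(cen_a)], rb,
              if (cen_a < length(ra)) ra[(cen_a + 1):length(ra)])] <- new_idx
      g$chrom[rb] <- a
      ch$cen_after[ia] <- cen_a + min(ch$cen_after[ib], length(rb))
    } else {
      # telomeric fusion: append reversed b; a's centromere stays functional
      g$chrom[rb] <- a
      g$idx[rb] <- length(ra) + rev(seq_along(rb))
      g$strand[rb] <- ifelse(g$strand[rb] == "+", "-", "+")
    }
    pal <- unique(stats::na.omit(c(ch$paleo[ia], ch$paleo[ib])))
    ch$paleo[ia] <- if (length(pal)) paste(pal, collapse = "+") else NA
    ch <- ch[!ib, , drop = FALSE]
  } else if (evt$kind == "fission") {
    a <- evt$chrom %||% evt$chroms[1]
    if (!a %in% ch$chrom)
      stop_user("fusion_plan references absent chromosome: ", a)
    ra <- which(g$chrom == a); ra <- ra[order(g$idx[ra])]
    ia <- which(ch$chrom == a)
    at <- min(max(1L, ch$cen_after[ia]), length(ra) - 1L)
    newname <- paste0(a, "q")
    g$chrom[ra[(at + 1):length(ra)]] <- newname
    g$idx[ra[(at + 1):length(ra)]] <- seq_len(length(ra) - at)
    ch$cen_after[ia] <- max(1L, at %/% 2L)
    ch$cen_functional[ia] <- FALSE
    ch <- rbind(ch, data.frame(chrom = newname,
                               cen_after = max(1L, (length(ra) - at) %/% 2L),
                               cen_functional = FALSE,
                               paleo = ch$paleo[ia],
                               stringsAsFactors = FALSE))
  } else stop_user("unknown planned event kind: ", evt$kind)
  truth$events <- c(truth$events, list(data.frame(
    kind = evt$kind, lineage = evt$lineage, time = evt$time,
    chrom = paste(evt$chroms %||% evt$chrom, collapse = "+"),
    detail = "", stringsAsFactors = FALSE)))
  genome$genes <- g
  genome$chroms <- ch
  relayout_genome(genome, cfg$gene_spacing, cfg$gene_length)
}

# evolve one tree branch from age t_from down to t_to, honouring scheduled
# WGDs and planned karyotype events on that lineage
evolve_branch <- function(genome, cfg, lineage, t_from, t_to, truth,
                          burst = 1) {
  set.seed(derive_seed(cfg$seed, lineage))
  sched <- list()
  wt <- cfg$wgd_times[[lineage]]
  if (!is.null(wt) && wt < t_from && wt >= t_to)
    sched[[length(sched) + 1L]] <- list(kind = "WGD", time = wt,
                                        lineage = lineage)
  for (evt in cfg$fusion_plan)
    if (identical(evt$lineage, lineage) && evt$time < t_from &&
        evt$time >= t_to)
      sched[[length(sched) + 1L]] <- evt
  if (length(sched))
    sched <- sched[order(-vapply(sched, function(e) e$time, 0))]
  t_cur <- t_from
  for (evt in sched) {
    genome <- evolve_segment(genome, cfg, lineage, t_cur, evt$time, truth,
                             burst)
    if (evt$kind == "WGD") {
      res <- apply_wgd(genome, evt$time,
                       seed = derive_seed(cfg$seed, paste0(lineage, ":wgd")),
                       class = "neo")
      genome <- relayout_genome(res$genome, cfg$gene_spacing,
                                cfg$gene_length)
      truth$neo_pairs[[lineage]] <- res$pairs
      truth$ds_neo[[lineage]] <- res$ds_assignment
      truth$events <- c(truth$events, list(data.frame(
        kind = "WGD", lineage = lineage, time = evt$time, chrom = "*",
        detail = "lineage-specific WGD", stringsAsFactors = FALSE)))
    } else {
      genome <- apply_karyotype_event(genome, evt, cfg, truth)
    }
    t_cur <- evt$time
  }
  evolve_segment(genome, cfg, lineage, t_cur, t_to, truth, burst)
}

#' Run the full genome-evolution simulation
#'
#' Builds the ancestor, applies the shared WGD on the stem, evolves every
#' branch of the species tree in age order (deletions, transpositions,
#' inversions, tandem duplications, segmental deletions, planned fusions and
#' fissions, lineage-specific WGDs) and returns the leaf genomes plus the
#' ground truth needed to score downstream inference.
#'
#' @param config a [simulation_config()]
#' @return list of class `grass_sim` with elements `genomes` (named list of
#'   leaf `genome`s), `truth` (see [simulation_truth()]), `config`, `tree`
#' @export
simulate_genomes <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else
    do.call(simulation_config, config)
  tr <- ape::read.tree(text = cfg$tree)
  depth <- ape::node.depth.edgelength(tr)
  age <- max(depth[seq_len(ape::Ntip(tr))]) - depth
  node_name <- function(nd) {
    if (nd <= ape::Ntip(tr)) return(tr$tip.label[nd])
    lb <- tr$node.label[nd - ape::Ntip(tr)]
    if (is.null(lb) || is.na(lb) || lb == "") paste0("node", nd) else lb
  }
  root <- ape::Ntip(tr) + 1L
  root_age <- age[root]
  t_shared <- cfg$wgd_times[["shared"]]
  if (is.null(t_shared))
    stop_user("wgd_times must contain a 'shared' entry (stem WGD)")
  if (t_shared <= root_age)
    stop_user("shared WGD must predate the root (", root_age, " Ma)")

  truth <- new.env(parent = emptyenv())
  truth$events <- list()
  truth$tandem_pairs <- list()
  truth$neo_pairs <- list()
  truth$ds_neo <- list()
  truth$tandem_counter <- 1L

  anc <- build_ancestor(cfg)
  res <- apply_wgd(anc, t_shared,
                   seed = derive_seed(cfg$seed, "shared:wgd"),
                   class = "paleo")
  truth$ds_assignment <- res$ds_assignment
  truth$birth_pairs <- res$pairs
  truth$proto_map <- stats::setNames(anc$genes$chrom, anc$genes$protogene)
  truth$ancestor_order <- anc$genes[, c("gene_id", "chrom", "idx",
                                        "protogene")]
  truth$events <- c(truth$events, list(data.frame(
    kind = "WGD", lineage = "stem", time = t_shared, chrom = "*",
    detail = "shared WGD", stringsAsFactors = FALSE)))
  cur <- relayout_genome(res$genome, cfg$gene_spacing, cfg$gene_length)
  cur <- evolve_branch(cur, cfg, "stem", t_shared, root_age, truth,
                       burst = cfg$del_burst)

  genomes <- list()
  recurse <- function(node, genome) {
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    for (kid in kids) {
      nm <- node_name(kid)
      gk <- genome
      gk$species <- nm
      gk <- evolve_branch(gk, cfg, nm, age[node], age[kid], truth)
      if (kid <= ape::Ntip(tr)) {
        gk$genes$gene_id <- paste0(nm, "_", gk$genes$gene_id)
        genomes[[nm]] <<- gk
      } else recurse(kid, gk)
    }
  }
  recurse(root, cur)

  out <- list(genomes = genomes,
              truth = finalize_truth(genomes, truth, cfg, tr, age),
              config = cfg, tree = tr)
  class(out) <- "grass_sim"
  out
}

#' Assemble the simulation ground truth
#'
#' Derives, from the leaf genomes and the event log: the ancestral registry
#' (protogene -> surviving copies per genome), per-leaf true WGD pair calls
#' (`retained` when both copies survive unmoved, `shuffled` when at least one
#' copy was transposed, `deleted` otherwise), and the ordered event list.
#'
#' @param genomes named list of leaf genomes
#' @param truth internal accumulator environment
#' @param cfg simulation config
#' @param tr,age phylo + node ages
#' @return list with `events`, `ds_assignment`, `true_pairs`, `registry`,
#'   `ancestor_order`, `neo_pairs`, `tandem_pairs`
#' @keywords internal
finalize_truth <- function(genomes, truth, cfg, tr, age) {
  events <- do.call(rbind, truth$events)
  pairs <- list()
  for (sp in names(genomes)) {
    g <- genomes[[sp]]$genes
    g <- g[g$origin != "tandem", , drop = FALSE]
    sp_pref <- paste0(sp, "_")
    for (p in split(g, g$protogene)) {
      d <- p[p$paleo == "D", , drop = FALSE]
      s <- p[p$paleo == "S", , drop = FALSE]
      if (nrow(d) && nrow(s)) {
        combos <- expand.grid(a = seq_len(nrow(d)), b = seq_len(nrow(s)))
        pairs[[length(pairs) + 1L]] <- data.frame(
          genome = sp, protogene = p$protogene[1],
          gene_a = d$gene_id[combos$a], gene_b = s$gene_id[combos$b],
          event = "ancient_wgd",
          status = ifelse(d$moved[combos$a] | s$moved[combos$b],
                          "shuffled", "retained"),
          stringsAsFactors = FALSE)
      } else {
        pairs[[length(pairs) + 1L]] <- data.frame(
          genome = sp, protogene = p$protogene[1],
          gene_a = if (nrow(d)) d$gene_id[1] else NA,
          gene_b = if (nrow(s)) s$gene_id[1] else NA,
          event = "ancient_wgd", status = "deleted",
          stringsAsFactors = FALSE)
      }
      # lineage-specific WGD pairs within each paleo compartment
      for (cmp in list(d, s)) {
        if (nrow(cmp) >= 2 && any(cmp$neo == 1L, na.rm = TRUE) &&
            any(cmp$neo == 2L, na.rm = TRUE)) {
          c1 <- cmp[which(cmp$neo == 1L), , drop = FALSE]
          c2 <- cmp[which(cmp$neo == 2L), , drop = FALSE]
          cb <- expand.grid(a = seq_len(nrow(c1)), b = seq_len(nrow(c2)))
          pairs[[length(pairs) + 1L]] <- data.frame(
            genome = sp, protogene = p$protogene[1],
            gene_a = c1$gene_id[cb$a], gene_b = c2$gene_id[cb$b],
            event = "recent_wgd",
            status = ifelse(c1$moved[cb$a] | c2$moved[cb$b],
                            "shuffled", "retained"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  true_pairs <- do.call(rbind, pairs)
  registry <- lapply(genomes, function(gn) {
    split(gn$genes$gene_id, gn$genes$protogene)
  })
  list(events = events,
       proto_map = truth$proto_map,
       ds_assignment = truth$ds_assignment,
       ds_neo = truth$ds_neo,
       true_pairs = true_pairs,
       registry = registry,
       ancestor_order = truth$ancestor_order,
       birth_pairs = truth$birth_pairs,
       tandem_pairs = do.call(rbind, truth$tandem_pairs))
}
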