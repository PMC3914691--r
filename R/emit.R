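# Emission of analysis-ready inputs (gene models, homology, Ks) from a
# simulation, with divergence-dependent alignment identity.

# species divergence times (Myr) from the tree, as a symmetric matrix
species_divergence <- function(tree) {
  d <- ape::cophenetic.phylo(tree) / 2
  d
}

#' Build the homologous-pair table of a simulation
#'
#' Enumerates intra-genome pairs (shared-WGD duplicates, lineage-specific WGD
#' duplicates, tandem duplicates) and inter-genome pairs (orthologs within a
#' subgenome compartment, and cross-compartment paralog relationships dating
#' to the shared WGD), each with its true age. Ks is drawn as
#' 2 r T exp(N(0, sd) - sd^2/2), i.e. log-normal noise whose mean is exactly
#' the molecular-clock expectation, and percent identity decays linearly
#' with age.
#'
#' @param sim a `grass_sim`
#' @param decoy_frac fraction of additional random non-homologous rows
#'   (low identity, short alignment), exercising the homology filters
#' @return data.frame with gene_a, gene_b, genome_a, genome_b, scope,
#'   relation, age, ks, pident, qlen, slen
#' @export
sim_pair_table <- function(sim, decoy_frac = 0.05) {
  cfg <- sim$config
  set.seed(derive_seed(cfg$seed, "emit"))
  div <- species_divergence(sim$tree)
  glen <- unlist(lapply(sim$genomes, function(g)
    stats::setNames(g$genes$glen, g$genes$gene_id)), use.names = TRUE)
  names(glen) <- sub("^[^.]*\\.", "", names(glen))
  rows <- list()
  tp <- sim$truth$true_pairs
  tp <- tp[tp$status != "deleted", , drop = FALSE]
  rows[[1]] <- data.frame(gene_a = tp$gene_a, gene_b = tp$gene_b,
                          genome_a = tp$genome, genome_b = tp$genome,
                          scope = "intra", relation = tp$event,
                          age = ifelse(tp$event == "ancient_wgd",
                                       cfg$wgd_times$shared,
                                       unlist(cfg$wgd_times[setdiff(
                                         names(cfg$wgd_times), "shared")])[1]),
                          stringsAsFactors = FALSE)
  tnd <- sim$truth$tandem_pairs
  if (!is.null(tnd) && nrow(tnd)) {
    sp <- sub("_g.*$", "", tnd$gene_a)
    keep <- mapply(function(a, b, s) {
      gg <- sim$genomes[[s]]$genes$gene_id
      a %in% gg && b %in% gg
    }, tnd$gene_a, tnd$gene_b, sp)
    tnd <- tnd[keep, , drop = FALSE]
    if (nrow(tnd))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = tnd$gene_a, gene_b = tnd$gene_b,
        genome_a = sub("_g.*$", "", tnd$gene_a),
        genome_b = sub("_g.*$", "", tnd$gene_a),
        scope = "intra", relation = "tandem", age = tnd$time,
        stringsAsFactors = FALSE)
  }
  sps <- names(sim$genomes)
  for (i in seq_along(sps)) for (j in seq_along(sps)) {
    if (i >= j) next
    a <- sim$genomes[[sps[i]]]$genes
    b <- sim$genomes[[sps[j]]]$genes
    a <- a[a$origin != "tandem", c("gene_id", "protogene", "paleo")]
    b <- b[b$origin != "tandem", c("gene_id", "protogene", "paleo")]
    m <- merge(a, b, by = "protogene", suffixes = c("_a", "_b"))
    same <- m$paleo_a == m$paleo_b
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = m$gene_id_a, gene_b = m$gene_id_b,
      genome_a = sps[i], genome_b = sps[j], scope = "inter",
      relation = ifelse(same, "ortholog", "cross_paralog"),
      age = ifelse(same, div[sps[i], sps[j]], cfg$wgd_times$shared),
      stringsAsFactors = FALSE)
  }
  pr <- do.call(rbind, rows)
  sd <- cfg$ks_lognoise_sd
  pr$ks <- 2 * cfg$ks_rate * pr$age * 1e6 *
    exp(stats::rnorm(nrow(pr), -sd^2 / 2, sd))
  pr$pident <- pmin(100, pmax(55, 100 - 0.30 * pr$age +
                                stats::rnorm(nrow(pr), 0, 0.5)))
  pr$pident[pr$age == 0] <- 100
  pr$qlen <- unname(glen[pr$gene_a])
  pr$slen <- unname(glen[pr$gene_b])
  if (decoy_frac > 0) {
    nd <- ceiling(nrow(pr) * decoy_frac)
    all_ids <- unlist(lapply(sim$genomes, function(g) g$genes$gene_id))
    da <- sample(all_ids, nd, replace = TRUE)
    db <- sample(all_ids, nd, replace = TRUE)
    ok <- da != db
    dec <- data.frame(gene_a = da[ok], gene_b = db[ok],
                      genome_a = sub("_g.*$", "", da[ok]),
                      genome_b = sub("_g.*$", "", db[ok]),
                      scope = NA, relation = "decoy", age = NA, ks = NA,
                      pident = stats::runif(sum(ok), 45, 60),
                      qlen = unname(glen[da[ok]]), slen = unname(glen[db[ok]]),
                      stringsAsFactors = FALSE)
    dec$scope <- ifelse(dec$genome_a == dec$genome_b, "intra", "inter")
    pr <- rbind(pr, dec)
  }
  rownames(pr) <- NULL
  pr
}

# BLAST tabular rows from a pair table; true pairs align near-fully (1-2
# HSPs), decoys align a short fragment only
pairs_to_hsps <- function(pairs, seed = 1L) {
  set.seed(seed)
  n <- nrow(pairs)
  frac <- ifelse(pairs$relation == "decoy",
                 stats::runif(n, 0.15, 0.45),
                 stats::runif(n, 0.96, 1.0))
  alen <- pmax(60L, as.integer(round(pmin(pairs$qlen, pairs$slen) * frac)))
  split2 <- pairs$relation != "decoy" & stats::runif(n) < 0.3
  cut <- as.integer(alen * stats::runif(n, 0.3, 0.7))
  gap <- sample(5:30, n, replace = TRUE)
  # one row per HSP segment: unsplit pairs contribute one, split pairs two
  i1 <- seq_len(n)
  i2 <- which(split2)
  idx <- c(i1, i2)
  qstart <- c(ifelse(split2, 1L, 1L), cut[i2] + gap[i2])
  qend <- c(ifelse(split2, cut, alen), alen[i2] + gap[i2] - 1L)
  len <- qend - qstart + 1L
  mism <- as.integer(round(len * (1 - pairs$pident[idx] / 100)))
  # blastn-like reward/penalty so identity dominates the ranking
  out <- data.frame(
    qseqid = pairs$gene_a[idx], sseqid = pairs$gene_b[idx],
    pident = round(pairs$pident[idx], 2), length = len,
    mismatch = mism, gapopen = 0L,
    qstart = qstart, qend = pmin(qend, pairs$qlen[idx]),
    sstart = qstart, send = pmin(qend, pairs$slen[idx]),
    evalue = 1e-50,
    bitscore = round(pmax(0, 2 * (len - mism) - 3 * mism) * 0.5, 1),
    stringsAsFactors = FALSE)
  out[order(idx, out$qstart), , drop = FALSE]
}

#' Write a simulated dataset to disk
#'
#' Emits per-genome gene models (GFF3 + BED6), homology as 12-column BLAST
#' tabular rows synthesised from true divergence, a Ks table, the truth JSON,
#' and — in `sequences` mode — paired codon CDS FASTA whose realised Ks
#' tracks 2 r T through an explicit synonymous-substitution process.
#'
#' @param sim a `grass_sim`
#' @param dir output directory (created if needed)
#' @param mode `"ks_table"` or `"sequences"`
#' @return invisibly, the list of written paths
#' @export
emit_dataset <- function(sim, dir, mode = c("ks_table", "sequences")) {
  mode <- match.arg(mode)
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  paths <- character()
  for (sp in names(sim$genomes)) {
    p1 <- file.path(dir, paste0(sp, ".gff3"))
    p2 <- file.path(dir, paste0(sp, ".bed"))
    write_gff3(sim$genomes[[sp]], p1)
    write_bed(sim$genomes[[sp]], p2)
    paths <- c(paths, p1, p2)
  }
  pairs <- sim_pair_table(sim)
  hp <- file.path(dir, "homology.blast.tsv")
  utils::write.table(pairs_to_hsps(pairs,
                                   derive_seed(sim$config$seed, "hsp")),
                     hp, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  kp <- file.path(dir, "ks.tsv")
  kst <- pairs[!is.na(pairs$ks), c("gene_a", "gene_b", "ks")]
  utils::write.table(kst, kp, sep = "\t", quote = FALSE, row.names = FALSE)
  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    ds_assignment = sim$truth$ds_assignment,
    true_pairs = sim$truth$true_pairs,
    events = sim$truth$events), tj, dataframe = "rows", auto_unbox = TRUE)
  paths <- c(paths, hp, kp, tj)
  if (mode == "sequences") {
    fq <- file.path(dir, "pairs.fasta")
    wgd <- pairs[pairs$scope == "intra" & !is.na(pairs$age), , drop = FALSE]
    con <- file(fq, "w")
    on.exit(close(con))
    set.seed(derive_seed(sim$config$seed, "seqs"))
    for (i in seq_len(nrow(wgd))) {
      sq <- simulate_pair_sequences(age_myr = wgd$age[i],
                                    n_codons = 120L,
                                    rate = sim$config$ks_rate)
      writeLines(c(paste0(">", wgd$gene_a[i]), sq[1],
                   paste0(">", wgd$gene_b[i]), sq[2]), con)
    }
    paths <- c(paths, fq)
  }
  invisible(paths)
}

# codons with no stop
.sense_codons <- function() {
  b <- c("T", "C", "A", "G")
  cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(cods, c("TAA", "TAG", "TGA"))
}

# synonymous single-nucleotide neighbours of each sense codon
.syn_neighbours <- function() {
  aa <- .codon_aa_table()
  cods <- .sense_codons()
  out <- lapply(cods, function(cd) {
    nb <- character()
    for (p in 1:3) for (n in c("T", "C", "A", "G")) {
      if (substr(cd, p, p) == n) next
      alt <- cd
      substr(alt, p, p) <- n
      if (!is.na(aa[alt]) && aa[alt] == aa[cd]) nb <- c(nb, alt)
    }
    nb
  })
  stats::setNames(out, cods)
}

#' Simulate a codon-aligned duplicate pair of a given age
#'
#' Each copy of a random ancestral CDS accumulates
#' Poisson(r * T * synonymous sites) synonymous substitutions independently,
#' so the Nei-Gojobori Ks of the pair is close to 2 r T.
#'
#' @param age_myr divergence age in Myr
#' @param n_codons codons per sequence
#' @param rate substitutions per synonymous site per year
#' @return character vector of two equal-length CDS strings
#' @export
simulate_pair_sequences <- function(age_myr, n_codons = 100L,
                                    rate = 6.5e-9) {
  cods <- .sense_codons()
  syn <- .syn_neighbours()
  anc <- sample(cods, n_codons, replace = TRUE)
  mutate <- function(seq_cod) {
    s_sites <- sum(ng86_codon_sites(seq_cod)[, "S"])
    n_ev <- stats::rpois(1, rate * age_myr * 1e6 * s_sites)
    mutable <- which(lengths(syn[seq_cod]) > 0)
    for (k in seq_len(n_ev)) {
      i <- sample(mutable, 1L)
      seq_cod[i] <- sample(syn[[seq_cod[i]]], 1L)
    }
    seq_cod
  }
  c(paste(mutate(anc), collapse = ""), paste(mutate(anc), collapse = ""))
}
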