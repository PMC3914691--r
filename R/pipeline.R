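# End-to-end orchestration: homology -> dating -> synteny -> duplicates ->
# dominance -> ancestral reconstruction -> scenario evaluation.

#' Pipeline parameters
#'
#' @param close,distant [filter_policy()] objects for genome pairs sharing
#'   an ancestor below / above 50 Ma
#' @param dating a [dating_params()]
#' @param synteny a [synteny_params()]
#' @param alpha dominance test significance level
#' @param fit_mixture also fit a Ks mixture (1..4 components) per genome
#' @return list of class `pipeline_params`
#' @export
pipeline_params <- function(close = filter_policy("close"),
                            distant = filter_policy("distant"),
                            dating = dating_params(),
                            synteny = synteny_params(),
                            alpha = 0.05,
                            fit_mixture = FALSE) {
  structure(list(close = close, distant = distant, dating = dating,
                 synteny = synteny, alpha = alpha,
                 fit_mixture = fit_mixture),
            class = "pipeline_params")
}

# unordered pair key
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Run the full pipeline on a simulated dataset
#'
#' Stages: (1) CIP/CALP scoring of the synthesised HSP table and policy
#' filtering; (2) Ks dating and event labelling of intra-genome pairs;
#' (3) reciprocal-best orthologs and synteny-block chaining of ortholog and
#' ancient-paralog anchors; (4) ancestry labelling of blocks and
#' retained/shuffled classification of ancient duplicates; (5) chi-square
#' dominance tests and compartment rates; (6) orthogroup-based conserved
#' adjacencies, CAR linearization and the pre-duplication order; (7) the
#' packaged candidate-scenario evaluation. All stages consume only the
#' emitted observables (never the simulation truth).
#'
#' @param sim a `grass_sim` from [simulate_genomes()]
#' @param params a [pipeline_params()]
#' @param outdir optional directory; when given, summary tables are written
#'   as headered TSV plus a JSON run log of all parameters used
#' @return list with per-stage results (see details in the vignette)
#' @export
run_pipeline <- function(sim, params = pipeline_params(), outdir = NULL) {
  pairs_tbl <- sim_pair_table(sim)
  hsps <- pairs_to_hsps(pairs_tbl, derive_seed(sim$config$seed, "hsp"))
  ks_table <- pairs_tbl[!is.na(pairs_tbl$ks),
                        c("gene_a", "gene_b", "ks")]
  run_pipeline_core(sim$genomes, hsps, ks_table, sim$tree, params,
                    seed = sim$config$seed, outdir = outdir)
}

#' Run the pipeline from an emitted file set
#'
#' Loads per-genome GFF3 gene models, the BLAST tabular homology table and
#' the Ks table written by [emit_dataset()] (or equivalently formatted
#' files) and runs the same stages as [run_pipeline()].
#'
#' @param dir directory holding `<species>.gff3`, `homology.blast.tsv` and
#'   `ks.tsv`
#' @param tree newick string or `phylo` giving the species tree (tip labels
#'   must match the GFF3 file stems)
#' @param params a [pipeline_params()]
#' @param outdir optional output directory
#' @param seed integer seed recorded in the run log
#' @return as [run_pipeline()]
#' @export
run_pipeline_dir <- function(dir, tree, params = pipeline_params(),
                             outdir = NULL, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  genomes <- list()
  for (sp in tree$tip.label) {
    path <- file.path(dir, paste0(sp, ".gff3"))
    if (!file.exists(path)) stop_user("missing gene models: ", path)
    genomes[[sp]] <- load_genome(path, species = sp)
  }
  hsps <- load_hsps(file.path(dir, "homology.blast.tsv"))
  ks_table <- utils::read.table(file.path(dir, "ks.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  run_pipeline_core(genomes, hsps, ks_table, tree, params, seed = seed,
                    outdir = outdir)
}

run_pipeline_core <- function(genomes, hsps, ks_table, tree, params,
                              seed = 1L, outdir = NULL) {
  gp <- gene_pos_table(genomes)
  qlen <- stats::setNames(gp$glen, gp$gene_id)
  div <- species_divergence(tree)

  # stage 1: homology metrics + filtering
  metrics <- score_hsp_table(hsps, qlen)
  gq <- gp$genome[match(metrics$query, gp$gene_id)]
  gs <- gp$genome[match(metrics$subject, gp$gene_id)]
  intra <- metrics[gq == gs, , drop = FALSE]
  inter <- metrics[gq != gs, , drop = FALSE]
  intra_acc <- filter_pairs(intra, params$distant)
  pol_for <- function(a, b) if (div[a, b] <= 50) params$close else
    params$distant
  inter_acc <- do.call(rbind, lapply(
    split(inter, paste(gq[gq != gs], gs[gq != gs])), function(d) {
      a <- gp$genome[match(d$query[1], gp$gene_id)]
      b <- gp$genome[match(d$subject[1], gp$gene_id)]
      filter_pairs(d, pol_for(a, b))
    }))

  # stage 2: Ks dating of intra-genome (duplicate) pairs
  ksmap <- stats::setNames(ks_table$ks,
                           pair_key(ks_table$gene_a, ks_table$gene_b))
  intra_acc$ks <- unname(ksmap[pair_key(intra_acc$query, intra_acc$subject)])
  intra_acc <- intra_acc[!is.na(intra_acc$ks), , drop = FALSE]
  intra_acc$t_mya <- date_pair(intra_acc$ks, params$dating)
  intra_acc$label <- label_wgd_pairs(intra_acc$ks, params$dating)
  intra_acc$genome <- gp$genome[match(intra_acc$query, gp$gene_id)]
  mixtures <- NULL
  if (params$fit_mixture)
    mixtures <- lapply(split(intra_acc$ks, intra_acc$genome), function(k)
      tryCatch(fit_ks_mixture(k, seed = seed),
               error = function(e) NULL))
  ancient <- intra_acc[intra_acc$label == "ancient_wgd", , drop = FALSE]

  # stage 3: orthologs + synteny blocks
  # symmetrise so reciprocal-best sees both directions of each genome pair
  swapped <- inter_acc
  swapped$query <- inter_acc$subject
  swapped$subject <- inter_acc$query
  inter_sym <- rbind(inter_acc, swapped)
  gq2 <- gp$genome[match(inter_sym$query, gp$gene_id)]
  gs2 <- gp$genome[match(inter_sym$subject, gp$gene_id)]
  ortho <- do.call(rbind, lapply(
    split(inter_sym, paste(pmin(gq2, gs2), pmax(gq2, gs2))),
    reciprocal_best_pairs, scope = "inter_genome"))
  anchors <- rbind(
    anchors_from_pairs(ortho, gp, "ortholog"),
    anchors_from_pairs(data.frame(query = ancient$query,
                                  subject = ancient$subject,
                                  stringsAsFactors = FALSE),
                       gp, "paralog",
                       tandem_exclude_bp = params$synteny$max_gap_bp))
  blocks <- synteny_blocks(anchors, params$synteny)
  ancestry <- assign_block_ancestry(blocks)

  # stage 4: retained / shuffled duplicates
  anc_labels <- ancestry$summary$ancestry_label[
    ancestry$summary$ancestral_dup]
  dup <- classify_duplicates(
    data.frame(gene_a = ancient$query, gene_b = ancient$subject,
               ks = ancient$ks, t_mya = ancient$t_mya,
               stringsAsFactors = FALSE),
    ancestry$segments, gp, ancestral_labels = anc_labels)
  # shuffled copies = pair members outside any paralogon territory
  gseg <- genes_in_segments(ancestry$segments, gp)
  shuf <- dup$calls[dup$calls$status == "shuffled", , drop = FALSE]
  shuf_genes <- unique(data.frame(
    gene_id = c(shuf$gene_a, shuf$gene_b), stringsAsFactors = FALSE))
  shuf_genes <- cbind(shuf_genes,
                      gp[match(shuf_genes$gene_id, gp$gene_id),
                         c("genome", "chrom", "mid")])
  covered <- !is.na(gseg$ancestry_label[match(shuf_genes$gene_id,
                                              gseg$gene_id)])
  shuf_genes <- shuf_genes[!covered, , drop = FALSE]
  clusters <- cluster_shuffled(shuf_genes, gp,
                               max_gap_bp = params$synteny$max_gap_bp)

  # stage 5: dominance per ancestral paralogon, segment-wise compartments
  has_ortho <- unique(c(ortho$query, ortho$subject))
  in_par <- !is.na(gseg$ancestry_label) &
    gseg$ancestry_label %in% anc_labels
  gpar <- gseg[in_par, , drop = FALSE]
  comps <- do.call(rbind, lapply(
    split(gpar, paste(gpar$genome, gpar$chrom, gpar$ancestry_label)),
    function(d) data.frame(
      genome = d$genome[1], chrom = d$chrom[1],
      ancestry_label = d$ancestry_label[1],
      annotated = nrow(d),
      retained = sum(d$gene_id %in% has_ortho),
      shuffled = sum(d$gene_id %in% c(shuf$gene_a, shuf$gene_b)),
      stringsAsFactors = FALSE)))
  if (!is.null(comps)) rownames(comps) <- NULL
  dom <- NULL
  if (!is.null(comps)) {
    dom <- do.call(rbind, lapply(
      split(comps, paste(comps$genome, comps$ancestry_label)), function(d) {
        if (nrow(d) < 2) return(NULL)
        d <- d[order(-d$annotated), , drop = FALSE]
        cbind(data.frame(genome = d$genome[1],
                         ancestry_label = d$ancestry_label[1],
                         side_a = d$chrom[1], side_b = d$chrom[2],
                         stringsAsFactors = FALSE),
              chi_square_dominance(d$retained[1], d$retained[2],
                                   params$alpha))
      }))
    if (!is.null(dom)) rownames(dom) <- NULL
  }
  rates <- if (is.null(comps)) NULL else
    compartment_rates(data.frame(compartment = comps$ancestry_label,
                                 species = comps$genome,
                                 annotated = comps$annotated,
                                 retained = comps$retained,
                                 shuffled = comps$shuffled,
                                 stringsAsFactors = FALSE))

  # stage 6: orthogroups, conserved adjacencies, CARs
  # a marker is an orthogroup restricted to one subgenome compartment, so
  # merged D/S orthogroups (best hits across compartments after reciprocal
  # loss) do not collapse the two ancestral orders
  og <- igraph::graph_from_data_frame(ortho[, c("query", "subject")],
                                      directed = FALSE)
  memb <- igraph::components(og)$membership
  orders <- gp[gp$origin != "tandem", , drop = FALSE]
  orders$ancestry_label <- gseg$ancestry_label[match(orders$gene_id,
                                                     gseg$gene_id)]
  orders$compartment_label <- gseg$compartment_label[match(orders$gene_id,
                                                           gseg$gene_id)]
  og_id <- ifelse(orders$gene_id %in% names(memb),
                  memb[orders$gene_id], NA)
  # orthogroups holding two copies in some genome straddle the D/S
  # compartments (reciprocal-loss best hits); only those are split
  merged_og <- unique(og_id[!is.na(og_id)][duplicated(
    paste(og_id[!is.na(og_id)],
          orders$genome[!is.na(og_id)], sep = "\r"))])
  orders$marker <- ifelse(
    is.na(og_id), NA,
    ifelse(og_id %in% merged_og,
           ifelse(is.na(orders$compartment_label), NA,
                  paste0("m", og_id, "|", orders$compartment_label)),
           paste0("m", og_id)))
  root_kids <- tree$edge[tree$edge[, 1] == ape::Ntip(tree) + 1L, 2]
  clades <- lapply(root_kids, function(nd)
    if (nd <= ape::Ntip(tree)) tree$tip.label[nd] else
      ape::extract.clade(tree, nd)$tip.label)
  adj <- conserved_adjacencies(orders, clades)
  cars <- linearize_cars(adj)
  # sister markers (duplicate copies of one ancestral gene) are linked
  # through the retained duplicate pairs
  ret <- dup$calls[dup$calls$status == "retained", , drop = FALSE]
  ma <- orders$marker[match(ret$gene_a, orders$gene_id)]
  mb <- orders$marker[match(ret$gene_b, orders$gene_id)]
  ok <- !is.na(ma) & !is.na(mb) & ma != mb
  marker_to_proto <- NULL
  pre_cars <- list()
  if (any(ok)) {
    mg <- igraph::graph_from_data_frame(
      unique(data.frame(u = ma[ok], v = mb[ok])), directed = FALSE)
    pm <- igraph::components(mg)$membership
    marker_to_proto <- stats::setNames(paste0("p", pm), names(pm))
    lone <- setdiff(unique(stats::na.omit(orders$marker)),
                    names(marker_to_proto))
    marker_to_proto <- c(marker_to_proto,
                         stats::setNames(paste0("q", seq_along(lone)),
                                         lone))
    pre_cars <- suppressWarnings(
      preduplication_order(cars, marker_to_proto, orders))
  }

  # stage 7: candidate ancestral scenarios (packaged fixtures)
  scenarios <- evaluate_candidate_scenarios()

  out <- list(metrics = metrics, intra_accepted = intra_acc,
              inter_accepted = inter_acc, orthologs = ortho,
              mixtures = mixtures, ancient_pairs = ancient,
              blocks = ancestry$blocks, block_summary = ancestry$summary,
              segments = ancestry$segments,
              duplicates = dup, shuffled_clusters = clusters,
              compartments = comps, dominance = dom, rates = rates,
              adjacencies = adj, cars = cars, pre_cars = pre_cars,
              orders = orders, marker_to_proto = marker_to_proto,
              scenarios = scenarios, params = params)
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir, seed)
  out
}

# headered TSVs + a JSON run log
write_pipeline_outputs <- function(res, outdir, seed) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(res$duplicates$summary, "duplicate_partition.tsv")
  wt(res$duplicates$calls, "duplicate_calls.tsv")
  if (!is.null(res$dominance)) wt(res$dominance, "dominance.tsv")
  if (!is.null(res$rates)) {
    wt(res$rates$rates, "compartment_rates.tsv")
    wt(res$rates$means, "compartment_means.tsv")
  }
  bl <- res$blocks
  bl$anchors <- NULL
  wt(bl, "synteny_blocks.tsv")
  wt(res$adjacencies, "adjacencies.tsv")
  car_tab <- do.call(rbind, lapply(seq_along(res$cars), function(i)
    cbind(car_id = sprintf("CAR%02d", i), res$cars[[i]])))
  if (!is.null(car_tab)) wt(car_tab, "cars.tsv")
  pre_tab <- do.call(rbind, lapply(seq_along(res$pre_cars), function(i)
    cbind(car_id = sprintf("preCAR%02d", i), res$pre_cars[[i]])))
  if (!is.null(pre_tab)) wt(pre_tab, "pre_wgd_cars.tsv")
  wt(res$scenarios$ranking, "scenario_ranking.tsv")
  jsonlite::write_json(list(
    seed = seed,
    filter_close = unclass(res$params$close),
    filter_distant = unclass(res$params$distant),
    dating = unclass(res$params$dating),
    synteny = unclass(res$params$synteny),
    alpha = res$params$alpha), file.path(outdir, "run_log.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
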