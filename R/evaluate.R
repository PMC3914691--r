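# Benchmarking inferred results against the simulation ground truth.

#' Agreement of retained/shuffled calls with the simulation truth
#'
#' Joins the pipeline's duplicate calls to the true ancient-WGD pair
#' statuses by unordered gene pair and reports the agreement fraction.
#'
#' @param sim a `grass_sim`
#' @param calls data.frame from [classify_duplicates()] (`$calls`)
#' @return list with `n_matched`, `n_agree`, `recovery` (fraction)
#' @export
truth_status_recovery <- function(sim, calls) {
  tp <- sim$truth$true_pairs
  tp <- tp[tp$event == "ancient_wgd" & tp$status != "deleted", ,
           drop = FALSE]
  tkey <- pair_key(tp$gene_a, tp$gene_b)
  ckey <- pair_key(calls$gene_a, calls$gene_b)
  i <- match(ckey, tkey)
  ok <- !is.na(i)
  agree <- calls$status[ok] == tp$status[i[ok]]
  list(n_matched = sum(ok), n_agree = sum(agree),
       recovery = mean(agree))
}

# protogenes observable under the root-spanning rule: a surviving
# (non-tandem) copy in at least one genome of each clade
recoverable_protogenes <- function(sim) {
  root_kids <- sim$tree$edge[sim$tree$edge[, 1] == ape::Ntip(sim$tree) + 1L,
                             2]
  clades <- lapply(root_kids, function(nd)
    if (nd <= ape::Ntip(sim$tree)) sim$tree$tip.label[nd] else
      ape::extract.clade(sim$tree, nd)$tip.label)
  per_clade <- lapply(clades, function(cl) {
    unique(unlist(lapply(sim$genomes[cl], function(gn)
      gn$genes$protogene[gn$genes$origin != "tandem"])))
  })
  Reduce(intersect, per_clade)
}

#' Recovery of true ancestral adjacencies by the candidate set
#'
#' The reconstructible truth is the set of consecutive protogene pairs in
#' the ancestor after restriction to protogenes surviving in at least one
#' genome of each clade; an adjacency counts as recovered when any candidate
#' marker adjacency (either subgenome copy) links the two protogenes.
#'
#' @param sim a `grass_sim`
#' @param adjacencies data.frame from [conserved_adjacencies()]
#' @param orders the marker-annotated gene orders used to build them
#' @return list with `n_truth`, `n_recovered`, `recovery`
#' @export
adjacency_recovery <- function(sim, adjacencies, orders) {
  known <- orders[!is.na(orders$marker), , drop = FALSE]
  mp <- vapply(split(known$protogene, known$marker), function(p)
    as.integer(names(which.max(table(p)))), 0L)
  rec <- recoverable_protogenes(sim)
  ao <- sim$truth$ancestor_order
  ao <- ao[ao$protogene %in% rec, , drop = FALSE]
  ao <- ao[order(ao$chrom, ao$idx), , drop = FALSE]
  truth_keys <- unlist(lapply(split(ao$protogene, ao$chrom), function(p) {
    if (length(p) < 2) return(character())
    pair_key(p[-length(p)], p[-1])
  }))
  cand <- adjacencies[adjacencies$candidate, , drop = FALSE]
  cand_keys <- unique(pair_key(mp[cand$u], mp[cand$v]))
  hit <- truth_keys %in% cand_keys
  list(n_truth = length(truth_keys), n_recovered = sum(hit),
       recovery = mean(hit))
}

#' Data ceiling of root-spanning adjacency recovery
#'
#' An ancestral adjacency can only become a candidate if, in at least one
#' genome of each clade, both protogenes keep an unmoved copy of the same
#' subgenome compartment. This function measures that bound directly from
#' the simulated survival pattern, before any inference: it is the best any
#' consecutive-marker reconstruction can do under the chosen fractionation
#' regime.
#'
#' @param sim a `grass_sim`
#' @return list with `n_truth`, `n_supportable`, `ceiling` (fraction)
#' @export
adjacency_support_ceiling <- function(sim) {
  gp <- gene_pos_table(sim$genomes, drop_tandem = TRUE)
  root_kids <- sim$tree$edge[sim$tree$edge[, 1] == ape::Ntip(sim$tree) + 1L,
                             2]
  clades <- lapply(root_kids, function(nd)
    if (nd <= ape::Ntip(sim$tree)) sim$tree$tip.label[nd] else
      ape::extract.clade(sim$tree, nd)$tip.label)
  rec <- recoverable_protogenes(sim)
  gps <- split(gp, gp$genome)
  adjset <- function(g, cmp) {
    gg <- gps[[g]]
    gg <- gg[gg$paleo == cmp & !gg$moved & gg$protogene %in% rec, ,
             drop = FALSE]
    gg <- gg[order(gg$chrom, gg$idx), , drop = FALSE]
    unique(unlist(lapply(split(gg$protogene, gg$chrom), function(p) {
      if (length(p) < 2) return(character())
      pair_key(p[-length(p)], p[-1])
    })))
  }
  clade_adj <- lapply(clades, function(cl)
    unique(unlist(lapply(cl, function(g)
      c(adjset(g, "D"), adjset(g, "S"))))))
  ao <- sim$truth$ancestor_order
  ao <- ao[ao$protogene %in% rec, , drop = FALSE]
  ao <- ao[order(ao$chrom, ao$idx), , drop = FALSE]
  truth_keys <- unlist(lapply(split(ao$protogene, ao$chrom), function(p) {
    if (length(p) < 2) return(character())
    pair_key(p[-length(p)], p[-1])
  }))
  ok <- Reduce(`&`, lapply(clade_adj, function(a) truth_keys %in% a))
  list(n_truth = length(truth_keys), n_supportable = sum(ok),
       ceiling = mean(ok))
}

#' Compartment D/S label agreement with the simulation truth
#'
#' Maps each tested compartment side to its majority true subgenome label
#' and reports how often the significant chi-square labels match.
#'
#' @param sim a `grass_sim`
#' @param dominance data.frame from the pipeline's dominance stage
#' @param gp gene position table with truth columns
#' @return fraction of significant tests whose D/S orientation matches the
#'   truth (NA when no test is significant)
#' @export
ds_label_recovery <- function(sim, dominance, gp) {
  if (is.null(dominance) || !nrow(dominance)) return(NA_real_)
  maj_paleo <- function(genome, chrom) {
    g <- gp[gp$genome == genome & gp$chrom == chrom, "paleo"]
    names(which.max(table(g)))
  }
  sig <- dominance[dominance$label_a != "ns", , drop = FALSE]
  if (!nrow(sig)) return(NA_real_)
  good <- vapply(seq_len(nrow(sig)), function(i) {
    ta <- maj_paleo(sig$genome[i], sig$side_a[i])
    tb <- maj_paleo(sig$genome[i], sig$side_b[i])
    if (ta == tb) return(NA)
    sig$label_a[i] == ta && sig$label_b[i] == tb
  }, TRUE)
  mean(good, na.rm = TRUE)
}
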