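# Classification of WGD-dated duplicate pairs into retained (both copies in
# a paralogon) versus shuffled, clustering of shuffled genes, deletion
# chronology on the species tree, and structural contrasts.

#' Partition-summary arithmetic for dated duplicates
#'
#' The printed-table identity: retained + shuffled = total, with percentages
#' rounded half away from zero.
#'
#' @param total dated duplicate pairs
#' @param retained pairs with both copies in ancestral paralogous blocks
#' @return data.frame with counts and integer percentages
#' @export
partition_summary <- function(total, retained) {
  if (any(retained > total)) stop_user("retained cannot exceed total")
  shuffled <- total - retained
  data.frame(total = total, retained = retained, shuffled = shuffled,
             retained_pct = round_half_away(100 * retained / total),
             shuffled_pct = round_half_away(100 * shuffled / total))
}

#' Classify dated duplicate pairs as retained or shuffled
#'
#' A pair is retained when both copies lie inside known paralogous-block
#' territory of the same ancestral group (a paralogon): each gene must fall
#' in an ancestry segment, the two segments must carry the same ancestry
#' label (flagged ancestral when `ancestral_labels` is given), and the two
#' copies must not sit in the same compartment. Otherwise the pair is
#' shuffled. Pairs with a gene on an unannotated chromosome are skipped
#' with a warning.
#'
#' @param pairs data.frame with gene_a, gene_b (+ any other columns kept)
#' @param segments segment table from [assign_block_ancestry()]
#' @param gene_pos data.frame gene_id, genome, chrom, mid
#' @param ancestral_labels optional character vector of ancestry labels
#'   accepted as ancestral duplications (from the block summary)
#' @return list with `calls` (pairs + status, paralogon) and `summary`
#'   (per genome: total, retained, shuffled and percentages)
#' @export
classify_duplicates <- function(pairs, segments, gene_pos,
                                ancestral_labels = NULL) {
  gp2 <- genes_in_segments(segments,
                           gene_pos[, c("gene_id", "genome", "chrom",
                                        "mid")])
  ga <- gp2[match(pairs$gene_a, gp2$gene_id), ]
  gb <- gp2[match(pairs$gene_b, gp2$gene_id), ]
  known <- !is.na(ga$chrom) & !is.na(gb$chrom)
  if (any(!known))
    warning(sum(!known), " pair(s) skipped: gene on unannotated chromosome",
            call. = FALSE)
  pairs <- pairs[known, , drop = FALSE]
  ga <- ga[known, ]; gb <- gb[known, ]
  retained <- !is.na(ga$ancestry_label) & !is.na(gb$ancestry_label) &
    ga$ancestry_label == gb$ancestry_label &
    !(ga$compartment_label == gb$compartment_label &
        ga$chrom == gb$chrom)
  if (!is.null(ancestral_labels))
    retained <- retained & ga$ancestry_label %in% ancestral_labels
  status <- ifelse(retained, "retained", "shuffled")
  calls <- cbind(pairs, data.frame(
    status = status,
    paralogon = ifelse(retained, ga$ancestry_label, NA_character_),
    stringsAsFactors = FALSE))
  genome <- ga$genome
  summ <- do.call(rbind, lapply(split(seq_along(status), genome),
                                function(rows) {
    partition_summary(length(rows), sum(status[rows] == "retained"))
  }))
  summ <- cbind(data.frame(genome = rownames(summ),
                           stringsAsFactors = FALSE), summ)
  rownames(summ) <- NULL
  list(calls = calls, summary = summ)
}

#' Cluster shuffled genes by destination proximity
#'
#' Shuffled genes on the same chromosome merge into one cluster when within
#' `max_gap_bp` and separated by at most `max_intervening` annotated genes.
#' Clusters of 2-4 genes are flagged `small`; larger ones `large`.
#'
#' @param shuffled_genes data.frame gene_id, genome, chrom, mid
#' @param gene_pos all annotated positions (to count intervening genes)
#' @param max_gap_bp bp cutoff
#' @param max_intervening maximum annotated genes between cluster members
#' @return data.frame gene_id, cluster_id, cluster_size, class
#'   (`singleton`/`small`/`large`)
#' @export
cluster_shuffled <- function(shuffled_genes, gene_pos,
                             max_gap_bp = 100000, max_intervening = 3L) {
  if (!nrow(shuffled_genes))
    return(data.frame(gene_id = character(), cluster_id = character(),
                      cluster_size = integer(), class = character()))
  sg <- shuffled_genes[order(shuffled_genes$genome, shuffled_genes$chrom,
                             shuffled_genes$mid), , drop = FALSE]
  cl <- integer(nrow(sg))
  cur <- 1L
  cl[1] <- cur
  for (i in seq_len(nrow(sg))[-1]) {
    same <- sg$genome[i] == sg$genome[i - 1] && sg$chrom[i] == sg$chrom[i - 1]
    near <- same && (sg$mid[i] - sg$mid[i - 1]) <= max_gap_bp
    if (near) {
      between <- sum(gene_pos$genome == sg$genome[i] &
                       gene_pos$chrom == sg$chrom[i] &
                       gene_pos$mid > sg$mid[i - 1] &
                       gene_pos$mid < sg$mid[i])
      near <- between <= max_intervening
    }
    if (!near) cur <- cur + 1L
    cl[i] <- cur
  }
  size <- as.integer(table(cl)[as.character(cl)])
  data.frame(gene_id = sg$gene_id,
             cluster_id = sprintf("cl%04d", cl),
             cluster_size = size,
             class = ifelse(size == 1, "singleton",
                            ifelse(size <= 4, "small", "large")),
             stringsAsFactors = FALSE)
}

#' Small-cluster rate in per mil
#'
#' @param n_clustered shuffled genes moved in clusters of 2-4
#' @param n_total all nonsyntenic (shuffled) duplicates
#' @return per-mil rate, rounded half away from zero
#' @export
small_cluster_permil <- function(n_clustered, n_total) {
  round_half_away(1000 * n_clustered / n_total)
}

# clades of a rooted tree as a list of leaf-name vectors, largest first
tree_clades <- function(tree) {
  nt <- ape::Ntip(tree)
  subt <- lapply((nt + 1):(nt + tree$Nnode), function(nd)
    ape::extract.clade(tree, nd)$tip.label)
  cl <- c(list(tree$tip.label), subt, as.list(tree$tip.label))
  cl <- unique(lapply(cl, sort))
  cl[order(-lengths(cl))]
}

#' Deletion chronology of duplicate copies on the species tree
#'
#' For each lost copy, the minimal set of clade-level loss events explaining
#' the absence pattern is found (for a laminar clade family this cover is
#' unique: take maximal clades entirely absent). Absence in all species is
#' ancestral (pre-speciation); absence in exactly one clade is a lineage
#' loss; absence in single species is species-specific; cross-clade patterns
#' decompose into several events.
#'
#' @param presence data.frame: protogene, copy, then one logical column per
#'   species (TRUE = copy present)
#' @param tree rooted `phylo` whose tip labels match the species columns
#' @return data.frame: protogene, copy, call, events (";"-separated clade
#'   descriptors), n_events
#' @export
classify_chronology <- function(presence, tree) {
  if (!nrow(presence)) stop_user("empty presence matrix")
  species <- tree$tip.label
  if (!all(species %in% names(presence)))
    stop_user("presence matrix lacks column(s): ",
              paste(setdiff(species, names(presence)), collapse = ", "))
  clades <- tree_clades(tree)
  clade_name <- function(cl) {
    if (length(cl) == length(species)) return("ancestral")
    if (length(cl) == 1) return(paste0("species_specific(", cl, ")"))
    nt <- ape::Ntip(tree)
    for (nd in (nt + 1):(nt + tree$Nnode)) {
      if (setequal(ape::extract.clade(tree, nd)$tip.label, cl)) {
        lb <- tree$node.label[nd - nt]
        if (!is.null(lb) && !is.na(lb) && lb != "")
          return(paste0("lineage_", lb))
      }
    }
    paste0("lineage_(", paste(cl, collapse = ","), ")")
  }
  out <- lapply(seq_len(nrow(presence)), function(i) {
    absent <- species[!as.logical(presence[i, species])]
    if (!length(absent))
      return(data.frame(protogene = presence$protogene[i],
                        copy = presence$copy[i], call = "present",
                        events = "", n_events = 0L,
                        stringsAsFactors = FALSE))
    rest <- sort(absent)
    evs <- character()
    for (cl in clades) {
      if (length(cl) <= length(rest) && all(cl %in% rest)) {
        evs <- c(evs, clade_name(cl))
        rest <- setdiff(rest, cl)
      }
      if (!length(rest)) break
    }
    call <- if (length(evs) == 1) {
      sub("\\(.*", "", sub("species_specific\\((.*)\\)", "species_specific",
                           evs))
    } else "multiple"
    data.frame(protogene = presence$protogene[i], copy = presence$copy[i],
               call = call, events = paste(evs, collapse = ";"),
               n_events = length(evs), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Contrast structural features of retained vs shuffled genes
#'
#' @param retained,shuffled data.frames with columns glen (gene length, bp),
#'   exon_count and optionally `expressed` (logical)
#' @return data.frame with per-set means and two-sided Wilcoxon rank-sum
#'   p-values for length and exon count
#' @export
feature_contrast <- function(retained, shuffled) {
  if (!nrow(retained) || !nrow(shuffled))
    stop_user("both gene sets must be non-empty")
  p_len <- stats::wilcox.test(retained$glen, shuffled$glen,
                              exact = FALSE)$p.value
  p_ex <- stats::wilcox.test(retained$exon_count, shuffled$exon_count,
                             exact = FALSE)$p.value
  if (identical(retained, shuffled)) p_len <- p_ex <- 1
  data.frame(
    set = c("retained", "shuffled"),
    n = c(nrow(retained), nrow(shuffled)),
    mean_length_bp = c(mean(retained$glen), mean(shuffled$glen)),
    mean_exons = c(mean(retained$exon_count), mean(shuffled$exon_count)),
    expressed_frac = c(
      if (is.null(retained$expressed)) NA else mean(retained$expressed),
      if (is.null(shuffled$expressed)) NA else mean(shuffled$expressed)),
    p_length = p_len, p_exons = p_ex,
    stringsAsFactors = FALSE)
}
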