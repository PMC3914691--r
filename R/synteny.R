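# Collinear anchor chaining into synteny blocks (dynamic programming with
# the grass cleaning parameters) and ancestry labelling of blocks via a
# segment graph.

#' Synteny cleaning parameters
#'
#' Defaults follow the grass comparisons: blocks need more than 5 anchors
#' (i.e. >= 6), anchor-to-anchor gaps of at most 100 kb on either side, and
#' a span of at least 100 kb (the published range is 100-500 kb).
#'
#' @param min_anchors minimum anchors per block
#' @param max_gap_bp maximum gap between consecutive anchors, per side
#' @param min_span_bp minimum block span; a block is discarded when both
#'   sides fall short
#' @return list of class `synteny_params`
#' @export
synteny_params <- function(min_anchors = 6L, max_gap_bp = 100000L,
                           min_span_bp = 100000L) {
  stopifnot(min_anchors >= 1, max_gap_bp > 0, min_span_bp >= 0)
  structure(list(min_anchors = as.integer(min_anchors),
                 max_gap_bp = as.numeric(max_gap_bp),
                 min_span_bp = as.numeric(min_span_bp)),
            class = "synteny_params")
}

# longest collinear chain among anchors (pos_a, pos_b), one orientation;
# returns integer indices into the anchor table, or NULL
best_chain_one_orient <- function(pos_a, pos_b, max_gap, sign_b) {
  n <- length(pos_a)
  o <- order(pos_a, sign_b * pos_b)
  pa <- pos_a[o]
  pb <- sign_b * pos_b[o]
  len <- rep(1L, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (pa[i] <= pa[j]) next
      if (pa[i] - pa[j] > max_gap) next
      if (pb[i] <= pb[j]) next
      if (pb[i] - pb[j] > max_gap) next
      if (len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  best <- which.max(len)
  chain <- integer()
  i <- best
  while (i != 0L) {
    chain <- c(i, chain)
    i <- prev[i]
  }
  o[chain]
}

#' Chain anchors of one chromosome pair into synteny blocks
#'
#' Dynamic-programming longest collinear chains are extracted greedily (by
#' anchor count, ties by span, then leftmost); a chain is broken wherever the
#' gap on either side exceeds `max_gap_bp`, and a chain is kept only with at
#' least `min_anchors` anchors and a span reaching `min_span_bp` on at least
#' one side. Each anchor ends up in at most one block.
#'
#' @param anchors data.frame with columns gene_a, gene_b, pos_a, pos_b
#'   (bp midpoints on side a / side b)
#' @param params a [synteny_params()]
#' @return list of blocks; each block is a list with `anchors` (ordered
#'   data.frame), `orientation` ("same"/"inverted"), `anchor_count`,
#'   `span_a`, `span_b`, `start_a`, `end_a`, `start_b`, `end_b`
#' @export
chain_anchors <- function(anchors, params = synteny_params()) {
  anchors <- unique(anchors)
  blocks <- list()
  remaining <- anchors
  while (nrow(remaining) >= 1L) {
    cands <- list()
    for (sg in c(1, -1)) {
      idx <- best_chain_one_orient(remaining$pos_a, remaining$pos_b,
                                   params$max_gap_bp, sg)
      if (length(idx))
        cands[[length(cands) + 1L]] <-
          list(idx = idx, sign = sg,
               count = length(idx),
               span = max(remaining$pos_a[idx]) - min(remaining$pos_a[idx]),
               left = min(remaining$pos_a[idx]))
    }
    if (!length(cands)) break
    pick <- order(-vapply(cands, `[[`, 0, "count"),
                  -vapply(cands, `[[`, 0, "span"),
                  vapply(cands, `[[`, 0, "left"))[1]
    ch <- cands[[pick]]
    if (ch$count < params$min_anchors) break
    an <- remaining[ch$idx, , drop = FALSE]
    remaining <- remaining[-ch$idx, , drop = FALSE]
    span_a <- max(an$pos_a) - min(an$pos_a)
    span_b <- max(an$pos_b) - min(an$pos_b)
    if (span_a < params$min_span_bp && span_b < params$min_span_bp) next
    blocks[[length(blocks) + 1L]] <- list(
      anchors = an[order(an$pos_a), , drop = FALSE],
      orientation = if (ch$sign > 0) "same" else "inverted",
      anchor_count = ch$count,
      span_a = span_a, span_b = span_b,
      start_a = min(an$pos_a), end_a = max(an$pos_a),
      start_b = min(an$pos_b), end_b = max(an$pos_b))
  }
  blocks
}

#' Chain a full anchor table across all chromosome pairs
#'
#' @param anchor_table data.frame with genome_a, chrom_a, pos_a, gene_a,
#'   genome_b, chrom_b, pos_b, gene_b, scope ("ortholog"/"paralog")
#' @param params a [synteny_params()]
#' @return data.frame of blocks (one row each, anchors as a list column)
#' @export
synteny_blocks <- function(anchor_table, params = synteny_params()) {
  key <- paste(anchor_table$genome_a, anchor_table$chrom_a,
               anchor_table$genome_b, anchor_table$chrom_b,
               anchor_table$scope, sep = "\r")
  rows <- list()
  for (grp in split(anchor_table, key)) {
    bl <- chain_anchors(grp[, c("gene_a", "gene_b", "pos_a", "pos_b")],
                        params)
    for (b in bl) {
      rows[[length(rows) + 1L]] <- data.frame(
        genome_a = grp$genome_a[1], chrom_a = grp$chrom_a[1],
        genome_b = grp$genome_b[1], chrom_b = grp$chrom_b[1],
        scope = grp$scope[1],
        start_a = b$start_a, end_a = b$end_a,
        start_b = b$start_b, end_b = b$end_b,
        anchor_count = b$anchor_count, orientation = b$orientation,
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$anchors <- list(b$anchors)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$block_id <- sprintf("blk%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Assign ancestral-group labels to synteny blocks
#'
#' Builds a graph whose vertices are chromosome segments covered by block
#' sides (overlapping sides on the same chromosome are merged into one
#' segment) and whose edges are the orthology/paralogy block links.
#' Connected components define ancestral groups (protochromosome labels).
#' A second labelling using orthology edges only separates the two
#' subgenome compartments of each group. A component whose paralogy blocks
#' occur in two or more genomes is flagged an ancestral duplication;
#' paralogy confined to one genome is lineage-specific.
#'
#' @param blocks data.frame from [synteny_blocks()]
#' @return list with `blocks` (ancestry_label, ancestral_dup added),
#'   `segments` (genome, chrom, start, end, ancestry_label,
#'   compartment_label) and `summary` (per label: n_blocks,
#'   n_genomes_paralog, ancestral_dup, lineage_specific)
#' @export
assign_block_ancestry <- function(blocks) {
  n <- nrow(blocks)
  sides <- rbind(
    data.frame(genome = blocks$genome_a, chrom = blocks$chrom_a,
               start = blocks$start_a, end = blocks$end_a,
               block = seq_len(n), side = "a", stringsAsFactors = FALSE),
    data.frame(genome = blocks$genome_b, chrom = blocks$chrom_b,
               start = blocks$start_b, end = blocks$end_b,
               block = seq_len(n), side = "b", stringsAsFactors = FALSE))
  # merge sides on the same chromosome into segments when they overlap
  # substantially (>= 30% of the side); marginal overlaps at fusion
  # junctions must not bridge distinct ancestral groups
  sides$seg <- NA_integer_
  seg_counter <- 0L
  for (rows in split(seq_len(nrow(sides)),
                     paste(sides$genome, sides$chrom, sep = "\r"))) {
    rows <- rows[order(sides$start[rows])]
    cur_end <- -Inf
    for (r in rows) {
      ov <- cur_end - sides$start[r]
      len <- sides$end[r] - sides$start[r]
      if (ov < 0.3 * max(len, 1)) seg_counter <- seg_counter + 1L
      sides$seg[r] <- seg_counter
      cur_end <- max(cur_end, sides$end[r])
    }
  }
  seg_a <- sides$seg[sides$side == "a"][order(sides$block[sides$side == "a"])]
  seg_b <- sides$seg[sides$side == "b"][order(sides$block[sides$side == "b"])]
  segs <- as.character(seq_len(seg_counter))
  comp_of <- function(edge_sel) {
    gr <- igraph::graph_from_data_frame(
      data.frame(u = as.character(seg_a[edge_sel]),
                 v = as.character(seg_b[edge_sel])),
      directed = FALSE, vertices = segs)
    cm <- igraph::components(gr)
    ord <- order(-cm$csize)
    relabel <- integer(cm$no)
    relabel[ord] <- seq_len(cm$no)
    stats::setNames(relabel[cm$membership], igraph::V(gr)$name)
  }
  anc_comp <- comp_of(rep(TRUE, n))
  ort_comp <- comp_of(blocks$scope == "ortholog")
  blocks$ancestry_label <- paste0("G", anc_comp[as.character(seg_a)])
  par_tab <- table(blocks$ancestry_label[blocks$scope == "paralog"],
                   blocks$genome_a[blocks$scope == "paralog"])
  n_gen_par <- if (nrow(par_tab)) rowSums(par_tab > 0) else integer()
  blocks$ancestral_dup <- blocks$scope == "paralog" &
    blocks$ancestry_label %in% names(n_gen_par)[n_gen_par >= 2]
  # merged segment extents
  seg_tab <- do.call(rbind, lapply(split(sides, sides$seg), function(d)
    data.frame(seg = d$seg[1], genome = d$genome[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)))
  seg_tab$ancestry_label <- paste0("G", anc_comp[as.character(seg_tab$seg)])
  seg_tab$compartment_label <-
    paste0("C", ort_comp[as.character(seg_tab$seg)])
  rownames(seg_tab) <- NULL
  labs <- sort(unique(blocks$ancestry_label))
  summary <- data.frame(
    ancestry_label = labs,
    n_blocks = as.integer(table(blocks$ancestry_label)[labs]),
    n_genomes_paralog = as.integer(
      ifelse(labs %in% names(n_gen_par), n_gen_par[labs], 0L)),
    stringsAsFactors = FALSE)
  summary$ancestral_dup <- summary$n_genomes_paralog >= 2
  summary$lineage_specific <- summary$n_genomes_paralog == 1
  list(blocks = blocks, segments = seg_tab, summary = summary)
}

#' Locate genes inside ancestry segments
#'
#' @param segments segment table from [assign_block_ancestry()]
#' @param gene_pos data.frame with gene_id, genome, chrom, mid
#' @return `gene_pos` with ancestry_label and compartment_label columns
#'   (NA for genes outside every segment)
#' @export
genes_in_segments <- function(segments, gene_pos) {
  gene_pos$ancestry_label <- NA_character_
  gene_pos$compartment_label <- NA_character_
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    sel <- gene_pos$genome == s$genome & gene_pos$chrom == s$chrom &
      gene_pos$mid >= s$start & gene_pos$mid <= s$end
    gene_pos$ancestry_label[sel] <- s$ancestry_label
    gene_pos$compartment_label[sel] <- s$compartment_label
  }
  gene_pos
}

#' Build an anchor table from accepted homolog pairs and gene positions
#'
#' Tandem paralog pairs (same chromosome, closer than `tandem_exclude_bp`)
#' are excluded from paralogy anchors: they are CNV candidates, not WGD
#' relics.
#'
#' @param pairs data.frame with query, subject (gene ids)
#' @param gene_pos data.frame with gene_id, genome, chrom, mid (bp midpoint)
#' @param scope `"ortholog"` or `"paralog"`
#' @param tandem_exclude_bp proximity cutoff for tandem exclusion
#' @return anchor table for [synteny_blocks()]
#' @export
anchors_from_pairs <- function(pairs, gene_pos, scope,
                               tandem_exclude_bp = 100000) {
  if (is.null(pairs) || !nrow(pairs))
    return(data.frame(gene_a = character(), gene_b = character(),
                      genome_a = character(), chrom_a = character(),
                      pos_a = double(), genome_b = character(),
                      chrom_b = character(), pos_b = double(),
                      scope = character(), stringsAsFactors = FALSE))
  gp <- gene_pos[match(pairs$query, gene_pos$gene_id), ]
  gs <- gene_pos[match(pairs$subject, gene_pos$gene_id), ]
  ok <- !is.na(gp$gene_id) & !is.na(gs$gene_id)
  out <- data.frame(gene_a = pairs$query[ok], gene_b = pairs$subject[ok],
                    genome_a = gp$genome[ok], chrom_a = gp$chrom[ok],
                    pos_a = gp$mid[ok],
                    genome_b = gs$genome[ok], chrom_b = gs$chrom[ok],
                    pos_b = gs$mid[ok], scope = scope,
                    stringsAsFactors = FALSE)
  if (scope == "paralog") {
    tandem <- out$chrom_a == out$chrom_b &
      abs(out$pos_a - out$pos_b) <= tandem_exclude_bp
    out <- out[!tandem, , drop = FALSE]
  }
  # canonical side order within a genome pair
  swap <- out$genome_a > out$genome_b |
    (out$genome_a == out$genome_b & out$chrom_a > out$chrom_b)
  if (any(swap)) {
    tmp <- out[swap, ]
    out[swap, c("gene_a", "genome_a", "chrom_a", "pos_a")] <-
      tmp[, c("gene_b", "genome_b", "chrom_b", "pos_b")]
    out[swap, c("gene_b", "genome_b", "chrom_b", "pos_b")] <-
      tmp[, c("gene_a", "genome_a", "chrom_a", "pos_a")]
  }
  unique(out)
}
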