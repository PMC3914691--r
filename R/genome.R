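#' Genome container
#'
#' A light container for an annotated genome used throughout the pipeline.
#' `genes` is a data.frame with one row per gene model:
#' \describe{
#'   \item{gene_id}{unique, stable identifier}
#'   \item{chrom}{chromosome name}
#'   \item{idx}{rank of the gene along its chromosome (1-based)}
#'   \item{start,end}{0-based half-open coordinates}
#'   \item{strand}{"+" or "-"}
#'   \item{protogene}{integer id of the ancestral protogene the gene traces
#'     to (NA for genes without ancestry labels, e.g. loaded real data)}
#'   \item{paleo}{"D"/"S" subgenome compartment from the shared WGD, or NA}
#'   \item{neo}{1/2 subgenome from a lineage-specific WGD, or NA}
#'   \item{origin}{"ancestral", "wgd", "neo_wgd" or "tandem"}
#'   \item{moved}{logical, TRUE once a transposition displaced the gene}
#'   \item{exon_count}{integer, exons per gene model}
#' }
#' `chroms` carries per-chromosome centromere bookkeeping: `cen_after` is the
#' number of genes preceding the centromere (the centromere sits between gene
#' ranks `cen_after` and `cen_after + 1`) and `cen_functional` its state.
#'
#' @param species character scalar
#' @param genes data.frame as described above
#' @param chroms data.frame with columns chrom, cen_after, cen_functional
#' @return an object of class `genome`
#' @export
new_genome <- function(species, genes, chroms) {
  stopifnot(is.data.frame(genes), is.data.frame(chroms))
  if (anyDuplicated(genes$gene_id))
    stop_user("duplicate gene ids in genome '", species, "'")
  g <- list(species = species, genes = genes, chroms = chroms)
  class(g) <- "genome"
  g
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d genes on %d chromosomes\n",
              x$species, nrow(x$genes), nrow(x$chroms)))
  invisible(x)
}

#' Recompute gene coordinates on a uniform grid
#'
#' Genes are placed `spacing` bp apart in chromosome order with fixed length,
#' emulating loss of intervening DNA after deletions: coordinates always
#' reflect the current gene order. Centromere bp positions are derived from
#' the `cen_after` gene rank.
#'
#' @param genome a `genome`
#' @param spacing bp between successive gene starts
#' @param gene_length bp per gene model
#' @return the genome with refreshed `idx`, `start`, `end` and chromosome
#'   lengths
#' @export
relayout_genome <- function(genome, spacing = 10000L, gene_length = 3000L) {
  g <- genome$genes
  if (nrow(g)) {
    o <- order(g$chrom, g$idx)
    g <- g[o, , drop = FALSE]
    r <- stats::ave(seq_len(nrow(g)), g$chrom, FUN = seq_along)
    g$idx <- r
    g$start <- (r - 1) * spacing
    g$end <- g$start + gene_length
    rownames(g) <- NULL
  }
  genome$genes <- g
  n_per <- table(g$chrom)
  genome$chroms$n_genes <- as.integer(n_per[genome$chroms$chrom])
  genome$chroms$n_genes[is.na(genome$chroms$n_genes)] <- 0L
  genome$chroms$length <- pmax(genome$chroms$n_genes, 1L) * spacing
  genome$chroms$cen_pos <- pmin(genome$chroms$cen_after,
                                genome$chroms$n_genes) * spacing
  genome
}

# drop chromosomes that lost all their genes (with a warning)
drop_empty_chroms <- function(genome) {
  keep <- genome$chroms$chrom %in% unique(genome$genes$chrom)
  if (!all(keep)) {
    warning(sprintf("%s: dropping emptied chromosome(s) %s", genome$species,
                    paste(genome$chroms$chrom[!keep], collapse = ", ")),
            call. = FALSE)
    genome$chroms <- genome$chroms[keep, , drop = FALSE]
  }
  genome
}
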