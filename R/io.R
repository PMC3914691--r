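# Readers and writers for the standard formats used by the pipeline:
# gene-feature GFF3, BED6 and 12-column BLAST tabular.

#' Write gene models as GFF3
#'
#' Gene features only, `ID=` attribute; internal 0-based half-open
#' coordinates are converted to GFF3 1-based inclusive.
#'
#' @param genome a `genome`
#' @param path output file
#' @param write_exons also write `exon` child features (uniformly split
#'   within the gene) so exon counts round-trip
#' @return invisibly, `path`
#' @export
write_gff3 <- function(genome, path, write_exons = FALSE) {
  g <- genome$genes
  lines <- c("##gff-version 3",
             sprintf("%s\tgrasskaryo\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$chrom, g$start + 1L, g$end, g$strand, g$gene_id))
  if (write_exons && !is.null(g$exon_count)) {
    ex <- lapply(seq_len(nrow(g)), function(i) {
      k <- g$exon_count[i]
      bnd <- round(seq(g$start[i], g$end[i], length.out = k + 1))
      sprintf("%s\tgrasskaryo\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              g$chrom[i], utils::head(bnd, -1) + 1L, bnd[-1], g$strand[i],
              g$gene_id[i])
    })
    lines <- c(lines, unlist(ex))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write gene models as BED6
#'
#' @param genome a `genome`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_bed <- function(genome, path) {
  g <- genome$genes
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", g$chrom, g$start, g$end,
                     g$gene_id, 0L, g$strand), path)
  invisible(path)
}

parse_gff3_attr <- function(attr, key) {
  m <- regmatches(attr, regexpr(paste0("(?:^|;)", key, "=[^;]*"), attr))
  out <- rep(NA_character_, length(attr))
  ok <- lengths(regmatches(attr, gregexpr(paste0(key, "="), attr))) > 0
  out[ok] <- sub(paste0("^;?", key, "="), "", m)
  out
}

#' Load gene models from GFF3 or BED
#'
#' GFF3 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention; BED is taken as is. Genes are sorted by
#' (chrom, start); exon counts come from `exon` features when present,
#' else 1. Duplicate gene ids are an error.
#'
#' @param path file ending in .gff3/.gff or .bed
#' @param species species name to attach (default: file stem)
#' @return a `genome`
#' @export
load_genome <- function(path, species = NULL) {
  species <- species %||% sub("\\.[^.]*$", "", basename(path))
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    raw <- utils::read.table(path, sep = "\t", quote = "",
                             comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(raw) != 9) stop_user("malformed GFF3: expected 9 columns")
    genes_raw <- raw[raw$V3 == "gene", , drop = FALSE]
    genes <- data.frame(
      gene_id = parse_gff3_attr(genes_raw$V9, "ID"),
      chrom = genes_raw$V1,
      start = genes_raw$V4 - 1L, # 1-based inclusive -> 0-based half-open
      end = genes_raw$V5,
      strand = genes_raw$V7,
      stringsAsFactors = FALSE)
    ex <- raw[raw$V3 == "exon", , drop = FALSE]
    if (nrow(ex)) {
      par <- parse_gff3_attr(ex$V9, "Parent")
      cnt <- table(par)
      genes$exon_count <- as.integer(ifelse(
        genes$gene_id %in% names(cnt), cnt[genes$gene_id], 1L))
    } else genes$exon_count <- 1L
  } else if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = raw$V4, chrom = raw$V1, start = raw$V2,
                        end = raw$V3,
                        strand = if (ncol(raw) >= 6) raw$V6 else "+",
                        exon_count = 1L, stringsAsFactors = FALSE)
  } else stop_user("unrecognised gene-model format: ", path)
  if (anyDuplicated(genes$gene_id))
    stop_user("duplicate gene IDs in ", path)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  genes$idx <- stats::ave(seq_len(nrow(genes)), genes$chrom, FUN = seq_along)
  genes$protogene <- NA_integer_
  genes$paleo <- NA_character_
  genes$neo <- NA_integer_
  genes$origin <- "loaded"
  genes$moved <- FALSE
  genes$glen <- genes$end - genes$start
  rownames(genes) <- NULL
  chroms <- data.frame(chrom = unique(genes$chrom), cen_after = NA_integer_,
                       cen_functional = NA, paleo = NA_character_,
                       stringsAsFactors = FALSE)
  new_genome(species, genes, chroms)
}

#' Load 12-column BLAST tabular HSPs
#'
#' Rows are grouped downstream by (qseqid, sseqid); identities are derived
#' as round(pident * length / 100) and reverse-coordinate HSPs are
#' normalised so start <= end.
#'
#' @param path BLAST `-outfmt 6` file
#' @return data.frame with the 12 standard columns plus `identities`
#' @export
load_hsps <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (file.size(path) == 0) {
    warning("empty HSP file: ", path, call. = FALSE)
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), 12), cols), stringsAsFactors = FALSE)
    out$identities <- numeric(0)
    return(out)
  }
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stop_user("malformed BLAST tabular file: ",
                                  conditionMessage(e)))
  if (ncol(raw) != 12) {
    bad <- which(utils::count.fields(path, sep = "\t") != 12)[1]
    stop_user("malformed BLAST tabular row at line ", bad %||% NA)
  }
  names(raw) <- cols
  qs <- pmin(raw$qstart, raw$qend); qe <- pmax(raw$qstart, raw$qend)
  ss <- pmin(raw$sstart, raw$send); se <- pmax(raw$sstart, raw$send)
  raw$qstart <- qs; raw$qend <- qe; raw$sstart <- ss; raw$send <- se
  raw$identities <- round(raw$pident * raw$length / 100)
  raw
}

#' Gene position table across genomes
#'
#' @param genomes named list of `genome`s
#' @param drop_tandem drop tandem-duplicate gene models
#' @return data.frame gene_id, genome, chrom, mid, glen, exon_count, strand,
#'   idx (plus ancestry columns when present)
#' @export
gene_pos_table <- function(genomes, drop_tandem = FALSE) {
  out <- do.call(rbind, lapply(genomes, function(gn) {
    g <- gn$genes
    if (drop_tandem) g <- g[g$origin != "tandem", , drop = FALSE]
    data.frame(gene_id = g$gene_id, genome = gn$species, chrom = g$chrom,
               mid = (g$start + g$end) / 2, glen = g$glen,
               exon_count = g$exon_count, strand = g$strand, idx = g$idx,
               protogene = g$protogene, paleo = g$paleo, neo = g$neo,
               moved = g$moved, origin = g$origin,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
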