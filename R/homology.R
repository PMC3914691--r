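# CIP/CALP homology metrics from HSP sets, divergence-dependent acceptance
# thresholds, and reciprocal-best pairing.

#' Compute AL, CIP and CALP for one gene pair
#'
#' Aggregates the HSPs of a (query, subject) pair: HSPs are sorted by query
#' start and overlapping query intervals are clipped so that each query
#' column counts once, identities being prorated by the clipped fraction.
#' AL is the clipped cumulative aligned length (query columns),
#' CIP = 100 * sum(identities) / AL and CALP = 100 * AL / query_length.
#'
#' @param hsps data.frame with columns qstart, qend (1-based inclusive,
#'   normalised so qstart <= qend), length (alignment columns) and either
#'   `identities` (matching columns) or `pident`
#' @param query_length query CDS length in bp
#' @return data.frame row with AL, CIP, CALP
#' @export
compute_homology_metrics <- function(hsps, query_length) {
  if (!nrow(hsps)) stop_user("empty HSP set: metrics undefined")
  if (query_length <= 0) stop_user("query_length must be positive")
  if (is.null(hsps$identities))
    hsps$identities <- round(hsps$pident * hsps$length / 100)
  if (any(hsps$identities > hsps$length))
    stop_user("malformed HSP: identities exceed alignment length")
  qs <- pmin(hsps$qstart, hsps$qend)
  qe <- pmax(hsps$qstart, hsps$qend)
  o <- order(qs, qe)
  qs <- qs[o]; qe <- qe[o]
  id <- hsps$identities[o]
  len <- (qe - qs + 1)
  al <- 0
  idc <- 0
  covered_to <- 0 # rightmost query column already counted
  for (i in seq_along(qs)) {
    lo <- max(qs[i], covered_to + 1)
    if (lo > qe[i]) next
    kept <- qe[i] - lo + 1
    al <- al + kept
    idc <- idc + id[i] * kept / len[i]
    covered_to <- qe[i]
  }
  if (al == 0) stop_user("HSP set covers no query columns")
  data.frame(AL = al, CIP = 100 * idc / al,
             CALP = 100 * min(al, query_length) / query_length)
}

#' Divergence-dependent acceptance policy
#'
#' The close policy (genomes sharing an ancestor < 50 Ma) demands CIP and
#' CALP of at least 70\%; the distant policy (> 50 Ma) 50\%.
#'
#' @param relationship `"close"` or `"distant"`
#' @param cip_min,calp_min optional overrides in (0, 100]
#' @return list of class `filter_policy`
#' @export
filter_policy <- function(relationship = c("close", "distant"),
                          cip_min = NULL, calp_min = NULL) {
  relationship <- match.arg(relationship)
  def <- if (relationship == "close") 70 else 50
  pol <- list(relationship = relationship,
              cip_min = cip_min %||% def,
              calp_min = calp_min %||% def)
  if (any(c(pol$cip_min, pol$calp_min) <= 0 |
            c(pol$cip_min, pol$calp_min) > 100))
    stop_user("thresholds must lie in (0, 100]")
  class(pol) <- "filter_policy"
  pol
}

#' Filter scored gene pairs by a CIP/CALP policy
#'
#' @param metrics data.frame with columns query, subject, CIP, CALP (e.g.
#'   from [score_hsp_table()])
#' @param policy a [filter_policy()]
#' @return the accepted subset (self-pairs always removed)
#' @export
filter_pairs <- function(metrics, policy = filter_policy("close")) {
  keep <- metrics$CIP >= policy$cip_min & metrics$CALP >= policy$calp_min &
    metrics$query != metrics$subject
  metrics[keep, , drop = FALSE]
}

#' Score a full HSP table pair by pair
#'
#' Groups BLAST tabular rows by (query, subject) and computes AL/CIP/CALP
#' for each pair.
#'
#' @param hsps data.frame from [load_hsps()] (columns qseqid, sseqid,
#'   pident, length, qstart, qend, bitscore, ...)
#' @param query_lengths named vector, query gene id -> CDS length
#' @return data.frame: query, subject, AL, CIP, CALP, bitscore (summed)
#' @export
score_hsp_table <- function(hsps, query_lengths) {
  key <- paste(hsps$qseqid, hsps$sseqid, sep = "\r")
  single <- !(key %in% key[duplicated(key)])
  # fast path: single-HSP pairs need no overlap clipping
  out1 <- NULL
  h1 <- hsps[single, , drop = FALSE]
  if (nrow(h1)) {
    ql <- unname(query_lengths[h1$qseqid])
    ident <- if (!is.null(h1$identities)) h1$identities else
      round(h1$pident * h1$length / 100)
    al <- abs(h1$qend - h1$qstart) + 1
    keep <- !is.na(ql)
    out1 <- data.frame(query = h1$qseqid, subject = h1$sseqid,
                       AL = al, CIP = 100 * ident / al,
                       CALP = 100 * pmin(al, ql) / ql,
                       bitscore = h1$bitscore,
                       stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  hm <- hsps[!single, , drop = FALSE]
  out2 <- lapply(split(seq_len(nrow(hm)), key[!single]), function(rows) {
    h <- hm[rows, , drop = FALSE]
    ql <- query_lengths[[h$qseqid[1]]]
    if (is.null(ql) || is.na(ql)) return(NULL)
    m <- compute_homology_metrics(h, ql)
    data.frame(query = h$qseqid[1], subject = h$sseqid[1],
               AL = m$AL, CIP = m$CIP, CALP = m$CALP,
               bitscore = sum(h$bitscore %||% NA),
               stringsAsFactors = FALSE)
  })
  res <- rbind(out1, do.call(rbind, out2))
  rownames(res) <- NULL
  res
}

#' Reciprocal-best pairing of accepted homologs
#'
#' Inter-genome scope keeps (a, b) iff b is a's best subject and a is b's
#' best subject (candidate orthologs). Intra-genome scope keeps each gene's
#' best non-self hit, deduplicated to unordered pairs (candidate paralogs).
#' Pairs are ranked by bit score when present, else CIP x CALP; ties break
#' lexicographically by subject id.
#'
#' @param pairs accepted pair data.frame (query, subject, CIP, CALP,
#'   optional bitscore)
#' @param scope `"inter_genome"` or `"intra_genome"`
#' @return data.frame of retained pairs
#' @export
reciprocal_best_pairs <- function(pairs,
                                  scope = c("inter_genome", "intra_genome")) {
  scope <- match.arg(scope)
  if (!nrow(pairs)) return(pairs)
  score <- if (!is.null(pairs$bitscore) && !all(is.na(pairs$bitscore)))
    pairs$bitscore else pairs$CIP * pairs$CALP
  o <- order(pairs$query, -score, pairs$subject)
  p <- pairs[o, , drop = FALSE]
  best <- p[!duplicated(p$query), , drop = FALSE]
  if (scope == "intra_genome") {
    a <- pmin(best$query, best$subject)
    b <- pmax(best$query, best$subject)
    keep <- !duplicated(paste(a, b, sep = "\r"))
    out <- best[keep, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  bb <- stats::setNames(best$subject, best$query)
  keep <- !is.na(bb[best$subject]) & bb[best$subject] == best$query
  out <- best[keep & best$query < best$subject, , drop = FALSE]
  rownames(out) <- NULL
  out
}
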