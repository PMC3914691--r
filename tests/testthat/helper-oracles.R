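# Independent brute-force oracles used to validate the package's
# implementations on small instances. These share only the stated
# conventions (stop-codon handling, gap rules), never code paths.

# --- NG86 oracle -----------------------------------------------------------

# explicit standard genetic code (independent of the package's table)
oracle_code <- c(
  TTT = "Phe", TTC = "Phe", TTA = "Leu", TTG = "Leu",
  CTT = "Leu", CTC = "Leu", CTA = "Leu", CTG = "Leu",
  ATT = "Ile", ATC = "Ile", ATA = "Ile", ATG = "Met",
  GTT = "Val", GTC = "Val", GTA = "Val", GTG = "Val",
  TCT = "Ser", TCC = "Ser", TCA = "Ser", TCG = "Ser",
  CCT = "Pro", CCC = "Pro", CCA = "Pro", CCG = "Pro",
  ACT = "Thr", ACC = "Thr", ACA = "Thr", ACG = "Thr",
  GCT = "Ala", GCC = "Ala", GCA = "Ala", GCG = "Ala",
  TAT = "Tyr", TAC = "Tyr", TAA = "Stop", TAG = "Stop",
  CAT = "His", CAC = "His", CAA = "Gln", CAG = "Gln",
  AAT = "Asn", AAC = "Asn", AAA = "Lys", AAG = "Lys",
  GAT = "Asp", GAC = "Asp", GAA = "Glu", GAG = "Glu",
  TGT = "Cys", TGC = "Cys", TGA = "Stop", TGG = "Trp",
  CGT = "Arg", CGC = "Arg", CGA = "Arg", CGG = "Arg",
  AGT = "Ser", AGC = "Ser", AGA = "Arg", AGG = "Arg",
  GGT = "Gly", GGC = "Gly", GGA = "Gly", GGG = "Gly")

oracle_codon_sites <- function(codon) {
  s <- 0
  for (p in 1:3) for (nt in c("A", "C", "G", "T")) {
    if (substr(codon, p, p) == nt) next
    alt <- codon
    substr(alt, p, p) <- nt
    if (oracle_code[[alt]] != "Stop" &&
        oracle_code[[alt]] == oracle_code[[codon]]) s <- s + 1 / 3
  }
  s
}

oracle_codon_paths <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  walk <- function(cur, remaining, allow_stop) {
    if (!length(remaining)) return(list(c(0, 0)))
    res <- list()
    for (k in seq_along(remaining)) {
      p <- remaining[k]
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && oracle_code[[nxt]] == "Stop") next
      step <- if (oracle_code[[nxt]] != "Stop" &&
                    oracle_code[[nxt]] == oracle_code[[cur]]) c(1, 0) else
        c(0, 1)
      for (tail in walk(nxt, remaining[-k], allow_stop))
        res[[length(res) + 1]] <- step + tail
    }
    res
  }
  paths <- walk(c1, pos, allow_stop = FALSE)
  if (!length(paths)) paths <- walk(c1, pos, allow_stop = TRUE)
  colMeans(do.call(rbind, paths))
}

oracle_ng86_ks <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  s_sites <- (sum(vapply(ca, oracle_codon_sites, 0)) +
                sum(vapply(cb, oracle_codon_sites, 0))) / 2
  sd_tot <- sum(vapply(which(ca != cb), function(i)
    oracle_codon_paths(ca[i], cb[i])[1], 0))
  ps <- sd_tot / s_sites
  if (1 - 4 / 3 * ps <= 0) return(NA_real_)
  -3 / 4 * log(1 - 4 / 3 * ps)
}

# random codon pair with a few random (syn or nonsyn, stop-free) changes
random_codon_pair <- function(n_codons = 100, n_changes = 8) {
  sense <- names(oracle_code)[oracle_code != "Stop"]
  a <- sample(sense, n_codons, replace = TRUE)
  b <- a
  for (k in seq_len(n_changes)) {
    repeat {
      i <- sample(n_codons, 1)
      p <- sample(3, 1)
      nt <- sample(c("A", "C", "G", "T"), 1)
      alt <- b[i]
      substr(alt, p, p) <- nt
      if (alt != b[i] && oracle_code[[alt]] != "Stop") {
        b[i] <- alt
        break
      }
    }
  }
  c(paste(a, collapse = ""), paste(b, collapse = ""))
}

# --- collinear chain oracle ------------------------------------------------

# exhaustive enumeration of every valid chain (no DP, no greedy): maximum
# anchor count over chains monotone on both sides with per-step gaps within
# max_gap, for both orientations
oracle_max_chain <- function(anchors, max_gap) {
  n <- nrow(anchors)
  best <- 0
  extend <- function(last, size, sign) {
    best <<- max(best, size)
    for (j in seq_len(n)) {
      if (anchors$pos_a[j] <= anchors$pos_a[last]) next
      if (anchors$pos_a[j] - anchors$pos_a[last] > max_gap) next
      db <- sign * (anchors$pos_b[j] - anchors$pos_b[last])
      if (db <= 0 || abs(anchors$pos_b[j] - anchors$pos_b[last]) > max_gap)
        next
      extend(j, size + 1, sign)
    }
  }
  for (sign in c(1, -1)) for (i in seq_len(n)) extend(i, 1, sign)
  best
}

# --- maximum-weight linear forest oracle -----------------------------------

oracle_linear_forest_weight <- function(edges) {
  m <- nrow(edges)
  best <- 0
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (!length(sel)) next
    deg <- table(c(edges$u[sel], edges$v[sel]))
    if (any(deg > 2)) next
    gr <- igraph::graph_from_data_frame(edges[sel, c("u", "v")],
                                        directed = FALSE)
    if (igraph::gsize(gr) > igraph::vcount(gr) -
          igraph::components(gr)$no) next # contains a cycle
    w <- sum(edges$weight[sel])
    if (w > best) best <- w
  }
  best
}

# --- chronology (minimum clade cover) oracle -------------------------------

oracle_min_cover <- function(absent, clades) {
  best <- NULL
  m <- length(clades)
  for (mask in 1:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    un <- unlist(clades[sel])
    if (anyDuplicated(un)) next
    if (!setequal(un, absent)) next
    if (is.null(best) || length(sel) < best) best <- length(sel)
  }
  best
}
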