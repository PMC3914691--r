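# Ancestral gene-order reconstruction: conserved-adjacency voting across
# genomes with root-spanning clade support, linearization into contiguous
# ancestral regions (CARs), and derivation of the pre-duplication order.

#' Conserved marker adjacencies across genomes
#'
#' Each genome's chromosomes are restricted to genes carrying a
#' root-spanning marker (an orthogroup / ancestral-gene id present in at
#' least one genome of each clade); consecutive markers after restriction
#' yield one adjacency vote per genome (counted once per genome). An
#' adjacency is an ancestral candidate only when supported by at least one
#' genome in each clade of the root split (root-spanning support). A
#' relative-orientation mismatch between the supporting genomes lowers the
#' weight by 0.5.
#'
#' @param orders data.frame with columns genome, chrom, idx, marker, strand;
#'   rows with NA marker are skipped
#' @param clades list of two character vectors of genome names (the root
#'   split)
#' @return data.frame: u, v (markers, u < v), orient ("same"/"opposite"),
#'   weight, n_genomes, candidate
#' @export
conserved_adjacencies <- function(orders, clades) {
  orders <- orders[!is.na(orders$marker), , drop = FALSE]
  # only root-spanning markers are ancestral-gene candidates; restricting
  # the orders to them first keeps clade-specific survivors from
  # interrupting true ancestral adjacencies
  support <- split(orders$genome, orders$marker)
  spanning <- names(support)[vapply(support, function(g)
    all(vapply(clades, function(cl) any(g %in% cl), TRUE)), TRUE)]
  orders <- orders[orders$marker %in% spanning, , drop = FALSE]
  votes <- list()
  for (gn in unique(orders$genome)) {
    og <- orders[orders$genome == gn, , drop = FALSE]
    seen <- character()
    for (cc in unique(og$chrom)) {
      oc <- og[og$chrom == cc, , drop = FALSE]
      oc <- oc[order(oc$idx), , drop = FALSE]
      if (nrow(oc) < 2) next
      u <- oc$marker[-nrow(oc)]
      v <- oc$marker[-1]
      same_strand <- oc$strand[-nrow(oc)] == oc$strand[-1]
      flip <- u > v
      key <- paste(ifelse(flip, v, u), ifelse(flip, u, v), sep = "\r")
      new <- !(key %in% seen) & u != v
      seen <- c(seen, key[new])
      votes[[length(votes) + 1L]] <- data.frame(
        u = ifelse(flip, v, u)[new], v = ifelse(flip, u, v)[new],
        orient = ifelse(same_strand, "same", "opposite")[new],
        genome = gn, stringsAsFactors = FALSE)
    }
  }
  av <- do.call(rbind, votes)
  if (is.null(av))
    return(data.frame(u = character(), v = character(), orient = character(),
                      weight = double(), n_genomes = integer(),
                      candidate = logical()))
  out <- do.call(rbind, lapply(split(av, paste(av$u, av$v, sep = "\r")),
                               function(d) {
    orient <- names(which.max(table(d$orient)))
    mism <- sum(d$orient != orient)
    data.frame(u = d$u[1], v = d$v[1], orient = orient,
               weight = nrow(d) - 0.5 * mism,
               n_genomes = nrow(d),
               candidate = any(d$genome %in% clades[[1]]) &&
                 any(d$genome %in% clades[[2]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# exact maximum-weight linear forest (every vertex degree <= 2, no cycles)
# by depth-first branch and bound over the edge list; edges must be few
solve_linear_forest_exact <- function(edges) {
  n <- nrow(edges)
  verts <- unique(c(edges$u, edges$v))
  best <- list(w = -Inf, sel = logical(n))
  deg <- stats::setNames(integer(length(verts)), verts)
  parent <- stats::setNames(seq_along(verts), verts) # union-find
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  o <- order(-edges$weight)
  ed <- edges[o, , drop = FALSE]
  suffix <- rev(cumsum(rev(ed$weight)))
  rec <- function(i, w, deg, parent, sel) {
    if (w + (if (i <= n) suffix[i] else 0) <= best$w) return()
    if (i > n) {
      if (w > best$w) best <<- list(w = w, sel = sel)
      return()
    }
    ui <- ed$u[i]; vi <- ed$v[i]
    ru <- find_in(parent, ui); rv <- find_in(parent, vi)
    if (deg[ui] < 2 && deg[vi] < 2 && ru != rv) {
      deg2 <- deg
      deg2[ui] <- deg2[ui] + 1L
      deg2[vi] <- deg2[vi] + 1L
      parent2 <- parent
      parent2[ru] <- rv
      sel2 <- sel
      sel2[i] <- TRUE
      rec(i + 1L, w + ed$weight[i], deg2, parent2, sel2)
    }
    rec(i + 1L, w, deg, parent, sel)
  }
  find_in <- function(parent, x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  parent0 <- stats::setNames(verts, verts)
  rec(1L, 0, deg, parent0, logical(n))
  ed[best$sel, , drop = FALSE]
}

# greedy variant for large components
solve_linear_forest_greedy <- function(edges) {
  ed <- edges[order(-edges$weight, edges$u, edges$v), , drop = FALSE]
  verts <- unique(c(ed$u, ed$v))
  deg <- stats::setNames(integer(length(verts)), verts)
  parent <- stats::setNames(verts, verts)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  keep <- logical(nrow(ed))
  for (i in seq_len(nrow(ed))) {
    u <- ed$u[i]; v <- ed$v[i]
    if (deg[u] >= 2 || deg[v] >= 2) next
    ru <- find(u); rv <- find(v)
    if (ru == rv) next # would close a cycle
    keep[i] <- TRUE
    deg[u] <- deg[u] + 1L
    deg[v] <- deg[v] + 1L
    parent[ru] <- rv
  }
  ed[keep, , drop = FALSE]
}

#' Linearize candidate adjacencies into CARs
#'
#' Selects a maximum-weight set of adjacencies such that every marker keeps
#' at most two neighbours and no cycle forms, then reads off the connected
#' paths as contiguous ancestral regions. Components with at most
#' `exact_max_edges` candidate edges are solved exactly (branch and bound);
#' larger ones greedily by descending weight with lexicographic tie-breaks.
#'
#' @param adjacencies data.frame from [conserved_adjacencies()] (only rows
#'   with `candidate = TRUE` are used when the column is present)
#' @param exact_max_edges exact-solver size limit per connected component
#' @return list of CARs; each CAR is a data.frame with rank, marker,
#'   orientation ("+" arbitrary for the first marker, then propagated
#'   through adjacency orientations)
#' @export
linearize_cars <- function(adjacencies, exact_max_edges = 18L) {
  adj <- adjacencies
  if (!is.null(adj$candidate)) adj <- adj[adj$candidate, , drop = FALSE]
  if (!nrow(adj)) return(list())
  gr <- igraph::graph_from_data_frame(adj[, c("u", "v")], directed = FALSE)
  comp <- igraph::components(gr)$membership
  sel <- list()
  for (cid in unique(comp)) {
    vs <- names(comp)[comp == cid]
    ce <- adj[adj$u %in% vs & adj$v %in% vs, , drop = FALSE]
    sel[[length(sel) + 1L]] <-
      if (nrow(ce) <= exact_max_edges) solve_linear_forest_exact(ce)
      else solve_linear_forest_greedy(ce)
  }
  sel <- do.call(rbind, sel)
  # read paths off the selected linear forest
  nbr <- list()
  addn <- function(a, b, orient) {
    nbr[[a]] <<- c(nbr[[a]], stats::setNames(orient, b))
  }
  for (i in seq_len(nrow(sel))) {
    addn(sel$u[i], sel$v[i], sel$orient[i])
    addn(sel$v[i], sel$u[i], sel$orient[i])
  }
  all_markers <- unique(c(adj$u, adj$v))
  visited <- character()
  cars <- list()
  deg1 <- all_markers[vapply(all_markers,
                             function(m) length(nbr[[m]] %||% character()),
                             0L) <= 1L]
  starts <- c(sort(deg1), sort(all_markers))
  for (s in starts) {
    if (s %in% visited) next
    path <- s
    ori <- "+"
    cur <- s
    prev <- NA_character_
    ocur <- "+"
    repeat {
      nxts <- nbr[[cur]] %||% character()
      nxts <- nxts[!(names(nxts) %in% c(prev, path))]
      if (!length(nxts)) break
      nx <- names(nxts)[1]
      ocur <- if (nxts[[1]] == "same") ocur else
        if (ocur == "+") "-" else "+"
      path <- c(path, nx)
      ori <- c(ori, ocur)
      prev <- cur
      cur <- nx
    }
    visited <- c(visited, path)
    cars[[length(cars) + 1L]] <-
      data.frame(rank = seq_along(path), marker = path, orientation = ori,
                 stringsAsFactors = FALSE)
  }
  cars[order(-vapply(cars, nrow, 0L),
             vapply(cars, function(d) d$marker[1], ""))]
}

#' Derive the pre-duplication gene order from sister CARs
#'
#' Post-duplication CARs descending from the same ancestral duplication
#' group (paralogon ancestry label) are merged: markers are projected onto
#' protogene ids via retained duplicate pairs, only protogenes whose
#' duplicate survives in a sister marker are kept, the CAR orders vote for
#' protogene adjacencies, and the votes are linearized. Path fragments of a
#' group are then stitched in the order of their mean position along the
#' group's best-conserved modern carrier chromosome, giving one
#' pre-duplication CAR per ancestral group.
#'
#' @param cars list of CARs over markers (from [linearize_cars()])
#' @param marker_to_proto named vector mapping marker -> protogene-group id;
#'   markers sharing a value are duplicates of one ancestral gene
#' @param orders marker-annotated gene orders (genome, chrom, idx, marker,
#'   ancestry_label) used for group assignment and fragment stitching
#' @return list of pre-duplication CARs (marker column holds protogene ids)
#' @export
preduplication_order <- function(cars, marker_to_proto, orders) {
  known <- orders[!is.na(orders$marker) & !is.na(orders$ancestry_label), ,
                  drop = FALSE]
  mgrp <- vapply(split(known$ancestry_label, known$marker),
                 function(g) names(which.max(table(g))), "")
  # sister-attested protogenes: >= 2 markers share the protogene id
  proto_n <- table(marker_to_proto)
  keep_proto <- names(proto_n)[proto_n >= 2]
  car_group <- vapply(cars, function(d) {
    g <- mgrp[d$marker]
    g <- g[!is.na(g)]
    if (!length(g)) NA_character_ else names(which.max(table(g)))
  }, "")
  out <- list()
  for (grp in sort(unique(stats::na.omit(car_group)))) {
    votes <- list()
    protos_here <- character()
    for (k in which(car_group == grp)) {
      pr <- unname(marker_to_proto[cars[[k]]$marker])
      pr <- pr[!is.na(pr) & pr %in% keep_proto]
      pr <- pr[!duplicated(pr)]
      protos_here <- union(protos_here, pr)
      if (length(pr) < 2) next
      u <- pr[-length(pr)]; v <- pr[-1]
      flip <- u > v
      votes[[length(votes) + 1L]] <- data.frame(
        u = ifelse(flip, v, u), v = ifelse(flip, u, v),
        orient = "same", stringsAsFactors = FALSE)
    }
    if (!length(protos_here)) {
      warning("ancestral group ", grp,
              " has no sister-attested protogenes; skipped", call. = FALSE)
      next
    }
    av <- do.call(rbind, votes)
    frags <- if (is.null(av)) list() else {
      agg <- stats::aggregate(list(weight = rep(1, nrow(av))),
                              av[, c("u", "v", "orient")], sum)
      linearize_cars(cbind(agg, candidate = TRUE))
    }
    placed <- unlist(lapply(frags, function(d) d$marker))
    for (p in setdiff(protos_here, placed))
      frags[[length(frags) + 1L]] <- data.frame(
        rank = 1L, marker = p, orientation = "+",
        stringsAsFactors = FALSE)
    # stitch fragments along the best-conserved modern carrier
    kn <- known[mgrp[known$marker] == grp, , drop = FALSE]
    kn$proto <- unname(marker_to_proto[kn$marker])
    carrier <- names(sort(table(paste(kn$genome, kn$chrom, sep = "\r")),
                          decreasing = TRUE))[1]
    kc <- kn[paste(kn$genome, kn$chrom, sep = "\r") == carrier, ,
             drop = FALSE]
    pos <- vapply(frags, function(d) {
      m <- kc$idx[kc$proto %in% d$marker]
      if (!length(m)) Inf else mean(m)
    }, 0)
    frags <- frags[order(pos)]
    merged <- do.call(rbind, frags)
    merged$rank <- seq_len(nrow(merged))
    rownames(merged) <- NULL
    out[[length(out) + 1L]] <- merged
  }
  out
}
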