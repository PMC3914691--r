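# Rule-based evaluation of ancestral karyotype scenarios: dominance algebra
# (D+D=D, D+S=D, S+S=S; S never recovers dominance), centromere
# functionality bookkeeping through fusions and fissions, and parsimony
# ranking of candidate ancestors.

#' Build a proto-karyotype
#'
#' @param chroms data.frame with columns name, dom ("D"/"S"); optional
#'   cen_functional (default TRUE)
#' @return list of class `proto_karyotype`
#' @export
proto_karyotype <- function(chroms) {
  k <- lapply(seq_len(nrow(chroms)), function(i) {
    list(name = chroms$name[i], dom = chroms$dom[i],
         cen = if (is.null(chroms$cen_functional)) TRUE else
           chroms$cen_functional[i],
         anc_dom = chroms$dom[i],
         segments = data.frame(name = chroms$name[i], dom = chroms$dom[i],
                               stringsAsFactors = FALSE))
  })
  names(k) <- chroms$name
  structure(list(chroms = k, algebra_notes = list(),
                 n_wgd = 0L, n_fusion = 0L, n_fission = 0L, n_lost = 0L),
            class = "proto_karyotype")
}

#' @export
print.proto_karyotype <- function(x, ...) {
  for (ch in x$chroms)
    cat(sprintf("%-6s %s cen=%s segments=[%s]\n", ch$name, ch$dom,
                ifelse(ch$cen, "func", "non-func"),
                paste(paste0(ch$segments$name, ":", ch$segments$dom),
                      collapse = ", ")))
  invisible(x)
}

fusion_algebra <- function(dom_a, dom_b) {
  if (dom_a == "D" || dom_b == "D") "D" else "S"
}

#' Apply one karyotype event
#'
#' * `wgd` duplicates every chromosome; each copy of a dominant chromosome
#'   is labelled as declared (one D, one S per ancestral pair, Rule 1) while
#'   copies of a sensitive chromosome are sensitive — an ancestral S
#'   chromosome cannot recover dominance.
#' * `ccf`/`tcf` merge two chromosomes; dominance follows the algebra
#'   D+D=D, D+S=D, S+S=S, exactly one centromere stays functional, and
#'   per-segment dominance is preserved. A `declared_dom` contradicting the
#'   algebra is recorded as an algebra note (surfacing later as a rule-b
#'   violation).
#' * `fission` splits a chromosome at its centromere: both products carry
#'   nonfunctional centromeres.
#' * `deletion` removes a (typically acentric) chromosome.
#' * `inversion`/`translocation` only enter the event ledger.
#'
#' @param kar a [proto_karyotype()]
#' @param event list with `kind` and kind-specific fields (`copies` for wgd;
#'   `chroms`, `product`, `declared_dom` for fusions; `chrom`, `products`
#'   for fission; `chrom` for deletion)
#' @return the updated karyotype
#' @export
apply_event <- function(kar, event) {
  kind <- tolower(event$kind)
  ch <- kar$chroms
  if (kind == "wgd") {
    cps <- event$copies
    declared <- stats::setNames(
      vapply(cps, function(x) x$copy_dom %||% "S", ""),
      vapply(cps, function(x) x$parent, ""))
    copy_name <- stats::setNames(
      vapply(cps, function(x) x$copy, ""),
      vapply(cps, function(x) x$parent, ""))
    for (nm in names(ch)) {
      parent <- ch[[nm]]
      cn <- if (nm %in% names(copy_name)) copy_name[[nm]] else
        paste0(nm, "'")
      cd <- if (parent$dom == "S") "S" else
        if (nm %in% names(declared)) declared[[nm]] else "S"
      if (parent$dom == "D" && cd == "D") {
        # declared dominant copy: the sister (parent) becomes sensitive
        ch[[nm]]$dom <- "S"
        ch[[nm]]$segments$dom <- "S"
      }
      ch[[cn]] <- list(name = cn, dom = cd, cen = parent$cen,
                       anc_dom = if (parent$dom == "S") "S" else cd,
                       segments = data.frame(name = parent$segments$name,
                                             dom = cd,
                                             stringsAsFactors = FALSE))
    }
    kar$n_wgd <- kar$n_wgd + 1L
  } else if (kind %in% c("ccf", "tcf")) {
    ab <- event$chroms
    if (length(unique(ab)) != 2L)
      stop_user("fusion needs two distinct chromosomes")
    if (!all(ab %in% names(ch)))
      stop_user("fusion of absent chromosome(s): ",
                paste(setdiff(ab, names(ch)), collapse = ", "))
    a <- ch[[ab[1]]]; b <- ch[[ab[2]]]
    dom <- fusion_algebra(a$dom, b$dom)
    dd <- event$declared_dom %||% dom
    if (dd != dom)
      kar$algebra_notes[[length(kar$algebra_notes) + 1L]] <-
        sprintf("%s: %s(%s) + %s(%s) declared %s but algebra gives %s",
                toupper(kind), a$name, a$dom, b$name, b$dom, dd, dom)
    prod <- event$product %||% paste0(ab[1], ab[2])
    ch[[prod]] <- list(name = prod, dom = dom,
                       cen = a$cen || b$cen, # exactly one stays functional
                       anc_dom = dom,
                       segments = rbind(a$segments, b$segments))
    ch[setdiff(ab, prod)] <- NULL
    kar$n_fusion <- kar$n_fusion + 1L
  } else if (kind == "fission") {
    nm <- event$chrom
    if (is.null(ch[[nm]])) stop_user("fission of absent chromosome: ", nm)
    a <- ch[[nm]]
    prods <- event$products %||% paste0(nm, c("p", "q"))
    segs <- a$segments
    cut <- max(1L, nrow(segs) %/% 2L)
    s1 <- segs[seq_len(cut), , drop = FALSE]
    s2 <- if (cut < nrow(segs)) segs[(cut + 1):nrow(segs), , drop = FALSE]
      else data.frame(name = paste0(segs$name[cut], "-distal"),
                      dom = segs$dom[cut], stringsAsFactors = FALSE)
    ch[[nm]] <- NULL
    ch[[prods[1]]] <- list(name = prods[1], dom = a$dom, cen = FALSE,
                           anc_dom = a$anc_dom, segments = s1)
    ch[[prods[2]]] <- list(name = prods[2], dom = a$dom, cen = FALSE,
                           anc_dom = a$anc_dom, segments = s2)
    kar$n_fission <- kar$n_fission + 1L
  } else if (kind == "deletion") {
    nm <- event$chrom
    if (is.null(ch[[nm]])) stop_user("deletion of absent chromosome: ", nm)
    ch[[nm]] <- NULL
    kar$n_lost <- kar$n_lost + 1L
  } else if (kind %in% c("inversion", "translocation")) {
    # structure-neutral at this resolution; ledger only
  } else stop_user("unknown karyotype event kind: ", event$kind)
  kar$chroms <- ch
  kar
}

#' Validate a candidate scenario against observed subgenome labels
#'
#' Applies the event list to the candidate ancestor and collects rule
#' violations:
#' \describe{
#'   \item{R-a}{a terminal chromosome lacks a functional centromere}
#'   \item{R-b}{a fusion's declared dominance contradicts the algebra
#'     (S+S declared D, or D+D declared S)}
#'   \item{R-c}{an ancestrally sensitive chromosome is observed dominant}
#'   \item{R-d}{other terminal dominance/segment labels contradicting the
#'     observed labels}
#' }
#' A chromosome-count mismatch is reported as a structural error, not a
#' rule violation.
#'
#' @param ancestor data.frame (name, dom) or `proto_karyotype`
#' @param events list of events for [apply_event()]
#' @param observed data.frame with columns name, dom and optional
#'   `segments` (list column of segment dominance vectors, e.g. c("D","S"))
#' @return list of class `scenario_evaluation`: `karyotype`, `violations`
#'   (data.frame rule, description), `structural` (character), `ledger`,
#'   `parsimony_score`, `n_ancestor`, `accepted`
#' @export
validate_scenario <- function(ancestor, events, observed) {
  kar <- if (inherits(ancestor, "proto_karyotype")) ancestor else
    proto_karyotype(ancestor)
  n0 <- length(kar$chroms)
  for (ev in events) kar <- apply_event(kar, ev)
  viol <- list()
  add <- function(rule, desc)
    viol[[length(viol) + 1L]] <<- data.frame(rule = rule, description = desc,
                                             stringsAsFactors = FALSE)
  structural <- character()
  if (length(kar$chroms) != nrow(observed))
    structural <- sprintf(
      "terminal karyotype has %d chromosomes, observed %d",
      length(kar$chroms), nrow(observed))
  for (note in kar$algebra_notes) add("R-b", note)
  for (ch in kar$chroms) {
    if (!ch$cen)
      add("R-a", sprintf("%s carries a nonfunctional centromere", ch$name))
    i <- match(ch$name, observed$name)
    if (is.na(i)) next
    if (ch$dom != observed$dom[i]) {
      if (ch$dom == "S" && observed$dom[i] == "D" && ch$anc_dom == "S")
        add("R-c", sprintf(
          "%s descends from a sensitive ancestor but is observed dominant",
          ch$name))
      else
        add("R-d", sprintf("%s derived %s but observed %s", ch$name,
                           ch$dom, observed$dom[i]))
    }
    obs_seg <- if (!is.null(observed$segments)) observed$segments[[i]] else
      NULL
    if (!is.null(obs_seg)) {
      der <- ch$segments$dom
      if (!(identical(der, obs_seg) || identical(rev(der), obs_seg)))
        add("R-d", sprintf("%s segment labels [%s] do not match observed [%s]",
                           ch$name, paste(der, collapse = ","),
                           paste(obs_seg, collapse = ",")))
    }
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(rule = character(), description = character())
  ev_kinds <- vapply(events, function(e) tolower(e$kind), "")
  ledger <- build_event_ledger(data.frame(
    lineage = "ancestral", kind = ev_kinds, count = 1L,
    stringsAsFactors = FALSE))
  structure(list(karyotype = kar, violations = viol,
                 structural = structural, ledger = ledger,
                 parsimony_score = kar$n_fission + kar$n_fusion,
                 n_ancestor = n0,
                 accepted = nrow(viol) == 0L),
            class = "scenario_evaluation")
}

#' Rank candidate scenarios
#'
#' Sorted by violation count (ascending), then parsimony score (fissions +
#' fusions, ascending), then ancestor chromosome number (descending); ties
#' keep input order.
#'
#' @param evaluations named list of `scenario_evaluation`s
#' @return data.frame ranking with one row per scenario
#' @export
score_scenarios <- function(evaluations) {
  tab <- data.frame(
    scenario = names(evaluations) %||%
      paste0("scenario", seq_along(evaluations)),
    n_ancestor = vapply(evaluations, `[[`, 0L, "n_ancestor"),
    n_violations = vapply(evaluations,
                          function(e) nrow(e$violations), 0L),
    parsimony_score = vapply(evaluations, `[[`, 0, "parsimony_score"),
    accepted = vapply(evaluations, `[[`, TRUE, "accepted"),
    stringsAsFactors = FALSE)
  o <- order(tab$n_violations, tab$parsimony_score, -tab$n_ancestor)
  out <- tab[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

.ledger_kinds <- c("wgd", "ccf", "tcf", "fission", "inversion",
                   "translocation", "transposition", "ssd_move", "deletion",
                   "tandem_duplication", "segmental_deletion")

#' Build an event ledger
#'
#' Accepts either a per-lineage count table (columns lineage, kind, count)
#' or a raw event list (columns lineage, kind; each row one event).
#' Large-scale events are CCF + TCF + inversions (CIs); gene movements are
#' transpositions (including SSD-mode moves).
#'
#' @param events data.frame as above
#' @return list of class `event_ledger`: `counts` (lineage x kind table),
#'   `totals` (named vector per kind), `large_scale_total`,
#'   `gene_movement_total`
#' @export
build_event_ledger <- function(events) {
  ev <- events
  ev$kind <- tolower(ev$kind)
  if (!all(ev$kind %in% .ledger_kinds))
    stop_user("unknown event kind(s): ",
              paste(setdiff(unique(ev$kind), .ledger_kinds), collapse = ", "))
  if (is.null(ev$count)) ev$count <- 1L
  counts <- stats::xtabs(count ~ lineage + kind, data = ev)
  totals <- stats::setNames(rep(0, length(.ledger_kinds)), .ledger_kinds)
  got <- colSums(counts)
  totals[names(got)] <- got
  structure(list(
    counts = counts,
    totals = totals,
    large_scale_total = unname(totals["ccf"] + totals["tcf"] +
                                 totals["inversion"]),
    gene_movement_total = unname(totals["transposition"] +
                                   totals["ssd_move"])),
    class = "event_ledger")
}

#' Load a packaged karyotype-scenario fixture
#'
#' The five candidate grass scenarios (n = 5 to n = 7 ancestors) and the
#' observed post-WGD dominance/centromere labels ship as JSON under
#' `extdata/scenarios`.
#'
#' @param name fixture name, e.g. `"scenario3"` or `"observed"`
#' @return parsed fixture: for scenarios a list with `id`, `n`, `ancestor`
#'   (data.frame), `events` (list); for `observed` a data.frame
#' @export
load_scenario_fixture <- function(name) {
  path <- system.file("extdata", "scenarios", paste0(name, ".json"),
                      package = "grasskaryo")
  if (path == "") stop_user("no packaged fixture named ", name)
  raw <- jsonlite::read_json(path)
  if (identical(name, "observed")) {
    df <- data.frame(
      name = vapply(raw$chromosomes, `[[`, "", "name"),
      dom = vapply(raw$chromosomes, `[[`, "", "dom"),
      stringsAsFactors = FALSE)
    df$segments <- lapply(raw$chromosomes, function(x)
      unlist(x$segments) %||% x$dom)
    return(df)
  }
  anc <- data.frame(
    name = vapply(raw$ancestor, `[[`, "", "name"),
    dom = vapply(raw$ancestor, `[[`, "", "dom"),
    stringsAsFactors = FALSE)
  list(id = raw$id, n = raw$n, description = raw$description %||% "",
       ancestor = anc,
       events = lapply(raw$events, function(e) {
         e$chroms <- unlist(e$chroms)
         e$products <- unlist(e$products)
         e
       }))
}

#' Evaluate and rank the five packaged candidate scenarios
#'
#' @return list with `evaluations` (named list) and `ranking` (data.frame)
#' @export
evaluate_candidate_scenarios <- function() {
  observed <- load_scenario_fixture("observed")
  evals <- list()
  for (nm in paste0("scenario", 1:5)) {
    fx <- load_scenario_fixture(nm)
    evals[[nm]] <- validate_scenario(fx$ancestor, fx$events, observed)
  }
  list(evaluations = evals, ranking = score_scenarios(evals))
}
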