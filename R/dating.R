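# Ks estimation (Nei-Gojobori 1986 with Jukes-Cantor correction), molecular
# clock dating T = Ks / 2r, and log-normal mixture modelling of Ks
# distributions with BIC model selection.

# standard genetic code, codon -> amino acid ("*" = stop)
.codon_aa_table <- function() {
  if (!is.null(.grasskaryo_cache$aa)) return(.grasskaryo_cache$aa)
  b <- c("T", "C", "A", "G")
  cods <- character(64)
  k <- 0L
  for (p1 in b) for (p2 in b) for (p3 in b) {
    k <- k + 1L
    cods[k] <- paste0(p1, p2, p3)
  }
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  aa <- stats::setNames(aas, cods)
  .grasskaryo_cache$aa <- aa
  aa
}

.grasskaryo_cache <- new.env(parent = emptyenv())

#' Synonymous/nonsynonymous site counts per codon (NG86)
#'
#' For each codon, each position contributes the fraction of its three
#' possible single-nucleotide changes that are synonymous. Changes creating
#' a stop codon are counted as nonsynonymous.
#'
#' @param codons character vector of codons
#' @return matrix with columns `S` and `N` (S + N = 3 per codon)
#' @export
ng86_codon_sites <- function(codons) {
  aa <- .codon_aa_table()
  key <- "sites"
  if (is.null(.grasskaryo_cache[[key]])) {
    b <- c("T", "C", "A", "G")
    tab <- t(vapply(names(aa), function(cd) {
      if (aa[cd] == "*") return(c(S = 0, N = 0))
      s <- 0
      for (p in 1:3) for (n in b) {
        if (substr(cd, p, p) == n) next
        alt <- cd
        substr(alt, p, p) <- n
        if (aa[alt] != "*" && aa[alt] == aa[cd]) s <- s + 1 / 3
      }
      c(S = s, N = 3 - s)
    }, c(S = 0, N = 0)))
    .grasskaryo_cache[[key]] <- tab
  }
  .grasskaryo_cache[[key]][codons, , drop = FALSE]
}

# average synonymous/nonsynonymous differences between two codons over all
# minimal substitution paths; paths through stop codons are excluded unless
# every path hits a stop
ng86_codon_diff <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0(c1, c2)
  hit <- .grasskaryo_cache$diff[[key]]
  if (!is.null(hit)) return(hit)
  aa <- .codon_aa_table()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- if (length(pos) == 1) list(pos) else
    apply(permutations_of(pos), 1, identity, simplify = FALSE)
  score_path <- function(ord) {
    cur <- c1
    s <- 0; n <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (aa[nxt] == "*") return(NULL)
      if (aa[nxt] == aa[cur]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  res <- lapply(paths, score_path)
  ok <- !vapply(res, is.null, TRUE)
  if (any(ok)) res <- res[ok] else {
    # all paths pass through a stop: count steps ignoring the stop rule
    res <- lapply(paths, function(ord) {
      cur <- c1; s <- 0; n <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (aa[nxt] != "*" && aa[nxt] == aa[cur]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s, n)
    })
  }
  m <- colMeans(do.call(rbind, res))
  out <- c(sd = m[[1]], nd = m[[2]])
  if (is.null(.grasskaryo_cache$diff))
    .grasskaryo_cache$diff <- new.env(parent = emptyenv())
  .grasskaryo_cache$diff[[key]] <- out
  out
}

permutations_of <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], permutations_of(x[-i])))
  out
}

#' Estimate Ks for one aligned CDS pair (NG86)
#'
#' Nei-Gojobori counting: per-codon synonymous site fractions averaged over
#' both sequences; synonymous differences averaged over all minimal
#' substitution paths between differing codons; Jukes-Cantor correction
#' Ks = -(3/4) ln(1 - (4/3) ps). Gapped codon columns are dropped.
#'
#' @param seq_a,seq_b aligned CDS strings of equal length divisible by 3
#' @return list with `ks` (NA when saturated), `ps`, `S` (sites), `Sd`
#'   (differences), `saturated`
#' @export
estimate_ks <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop_user("aligned sequences must have equal length")
  if (nchar(seq_a) %% 3 != 0)
    stop_user("alignment length must be a multiple of 3")
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  keep <- !grepl("-", ca) & !grepl("-", cb)
  ca <- ca[keep]; cb <- cb[keep]
  if (!length(ca)) stop_user("no ungapped codons in alignment")
  aa <- .codon_aa_table()
  if (any(aa[ca] == "*") || any(aa[cb] == "*"))
    stop_user("internal stop codon in CDS")
  s_sites <- (sum(ng86_codon_sites(ca)[, "S"]) +
                sum(ng86_codon_sites(cb)[, "S"])) / 2
  sd_tot <- 0
  for (i in which(ca != cb)) sd_tot <- sd_tot + ng86_codon_diff(ca[i], cb[i])[["sd"]]
  ps <- sd_tot / s_sites
  arg <- 1 - 4 / 3 * ps
  if (arg <= 0)
    return(list(ks = NA_real_, ps = ps, S = s_sites, Sd = sd_tot,
                saturated = TRUE))
  list(ks = -3 / 4 * log(arg), ps = ps, S = s_sites, Sd = sd_tot,
       saturated = FALSE)
}

#' Dating parameters
#'
#' @param r substitution rate, substitutions per synonymous site per year
#' @param wgd_window_mya inclusive age window (Myr) of the shared ancient WGD
#' @param recent_window_mya inclusive age window of a lineage-specific WGD
#' @param ks_max saturation cutoff; larger Ks values are excluded from dating
#' @return list of class `dating_params`
#' @export
dating_params <- function(r = 6.5e-9, wgd_window_mya = c(50, 70),
                          recent_window_mya = c(1, 15), ks_max = 3) {
  if (r <= 0) stop_user("r must be positive")
  if (wgd_window_mya[1] >= wgd_window_mya[2])
    stop_user("wgd window must have T_min < T_max")
  structure(list(r = r, wgd_window_mya = wgd_window_mya,
                 recent_window_mya = recent_window_mya, ks_max = ks_max),
            class = "dating_params")
}

#' Convert Ks to an age in Myr (T = Ks / 2r)
#'
#' @param ks numeric vector of Ks values (NA = saturated, returns NA)
#' @param params a [dating_params()]
#' @return ages in Myr before present
#' @export
date_pair <- function(ks, params = dating_params()) {
  if (any(ks < 0, na.rm = TRUE)) stop_user("Ks must be non-negative")
  ks / (2 * params$r) / 1e6
}

#' Fit a mixture of log-normal components to a Ks distribution
#'
#' EM on ln(Ks) (Gaussian components on the log scale), k-means
#' initialisation with seeded restarts, variance floor 1e-6, and model
#' selection by BIC = -2 logLik + (3k - 1) ln n.
#'
#' @param ks positive Ks values; values <= 0 or > `ks_max` are dropped
#' @param k_range candidate component counts
#' @param ks_max saturation cutoff
#' @param tol convergence tolerance on the log-likelihood
#' @param max_iter maximum EM iterations
#' @param restarts number of seeded k-means restarts per k
#' @param seed integer seed for the restarts
#' @return list of class `ks_mixture`: `k`, `weight`, `mean_lnks`,
#'   `sd_lnks`, `loglik`, `bic`, `n`, `bic_table`
#' @export
fit_ks_mixture <- function(ks, k_range = 1:4, ks_max = 3, tol = 1e-6,
                           max_iter = 500L, restarts = 10L, seed = 1L) {
  x <- log(ks[!is.na(ks) & ks > 0 & ks <= ks_max])
  n <- length(x)
  if (n < 30) stop_user("need at least 30 usable Ks values, got ", n)
  best <- NULL
  bic_table <- data.frame(k = integer(), loglik = double(), bic = double())
  for (k in k_range) {
    fit_k <- NULL
    for (r in seq_len(restarts)) {
      set.seed(seed + 1000L * k + r)
      init <- if (k == 1 || length(unique(x)) < k) {
        list(mu = rep(mean(x), k) + stats::rnorm(k, 0, 1e-3),
             sd = rep(max(stats::sd(x), 1e-3), k),
             w = rep(1 / k, k))
      } else {
        km <- stats::kmeans(x, k, nstart = 1)
        list(mu = as.numeric(km$centers),
             sd = pmax(sqrt(km$withinss / pmax(km$size, 1)), 1e-3),
             w = km$size / n)
      }
      em <- em_lognormal(x, init, tol, max_iter)
      if (is.null(fit_k) || em$loglik > fit_k$loglik) fit_k <- em
    }
    bic <- -2 * fit_k$loglik + (3 * k - 1) * log(n)
    bic_table <- rbind(bic_table,
                       data.frame(k = k, loglik = fit_k$loglik, bic = bic))
    if (is.null(best) || bic < best$bic) {
      o <- order(fit_k$mu)
      best <- list(k = k, weight = fit_k$w[o], mean_lnks = fit_k$mu[o],
                   sd_lnks = fit_k$sd[o], loglik = fit_k$loglik, bic = bic,
                   n = n)
    }
  }
  best$bic_table <- bic_table
  class(best) <- "ks_mixture"
  best
}

# EM for a k-component Gaussian mixture on x; asserts the log-likelihood
# never decreases between iterations
em_lognormal <- function(x, init, tol, max_iter) {
  mu <- init$mu; sd <- pmax(init$sd, 1e-3); w <- init$w / sum(init$w)
  k <- length(mu)
  n <- length(x)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sd[j]),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- pmax(rowSums(dens), 1e-300)
    ll <- sum(log(rowsum_d))
    if (ll < ll_old - 1e-8)
      stop("internal error: EM log-likelihood decreased")
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
    resp <- dens / rowsum_d
    nk <- pmax(colSums(resp), 1e-12)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sd <- sqrt(pmax(colSums(resp * (x - rep(mu, each = n))^2) / nk, 1e-6))
  }
  list(mu = mu, sd = sd, w = w, loglik = ll)
}

#' Label dated pairs by duplication event
#'
#' Default windowing: `ancient_wgd` for ages inside the inclusive
#' `wgd_window_mya`, `recent_wgd` inside `recent_window_mya`, else `other`.
#' With a fitted [fit_ks_mixture()] model, each pair is assigned its
#' maximum-posterior component and the component's mean age is window-tested.
#'
#' @param ks numeric Ks vector (NA = saturated, labelled `saturated`)
#' @param params a [dating_params()]
#' @param model optional `ks_mixture`
#' @return character vector of labels
#' @export
label_wgd_pairs <- function(ks, params = dating_params(), model = NULL) {
  t_mya <- date_pair(ks, params)
  lab_window <- function(t) {
    ifelse(is.na(t), "saturated",
      ifelse(t >= params$wgd_window_mya[1] & t <= params$wgd_window_mya[2],
             "ancient_wgd",
        ifelse(t >= params$recent_window_mya[1] &
                 t <= params$recent_window_mya[2], "recent_wgd", "other")))
  }
  if (is.null(model)) return(lab_window(t_mya))
  comp_t <- date_pair(exp(model$mean_lnks), params)
  comp_lab <- lab_window(comp_t)
  x <- log(ks)
  post <- vapply(seq_len(model$k), function(j)
    model$weight[j] * stats::dnorm(x, model$mean_lnks[j], model$sd_lnks[j]),
    numeric(length(x)))
  post <- matrix(post, nrow = length(x))
  out <- comp_lab[max.col(post)]
  out[is.na(ks)] <- "saturated"
  out
}
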