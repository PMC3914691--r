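# Chi-square tests of equal duplicate retention between paralogous
# compartments, dominant/sensitive labelling, and compartment
# retention/shuffling rates.

#' Chi-square test of equal retention between two paralogous compartments
#'
#' Under the null of random duplicate deletion the retained genes split
#' evenly: E = (n_a + n_b) / 2 and chi2 = (n_a - E)^2/E + (n_b - E)^2/E with
#' one degree of freedom (Pearson, no continuity correction). When p < alpha
#' the larger compartment is labelled dominant (D) and the smaller sensitive
#' (S); otherwise both are `ns`.
#'
#' @param n_a,n_b retained ancestral gene counts of the two compartments
#' @param alpha significance level (per-pair 0.05; no multiple-testing
#'   correction by default, use `p.adjust` on the returned p externally for
#'   a Bonferroni variant)
#' @return data.frame with n_a, n_b, chi2, p, label_a, label_b
#' @export
chi_square_dominance <- function(n_a, n_b, alpha = 0.05) {
  if (any(n_a < 0 | n_b < 0)) stop_user("counts must be non-negative")
  if (any(n_a + n_b == 0)) stop_user("both counts zero: test undefined")
  e <- (n_a + n_b) / 2
  chi2 <- (n_a - e)^2 / e + (n_b - e)^2 / e
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  sig <- p < alpha
  label_a <- ifelse(sig, ifelse(n_a > n_b, "D", "S"), "ns")
  label_b <- ifelse(sig, ifelse(n_b > n_a, "D", "S"), "ns")
  data.frame(n_a = n_a, n_b = n_b, chi2 = chi2, p = p,
             label_a = label_a, label_b = label_b,
             stringsAsFactors = FALSE)
}

#' Retention accounting for one compartment
#'
#' @param annotated total annotated genes in the compartment
#' @param retained ancestral genes retained (ortholog repertoire)
#' @return data.frame with annotated, retained, retention_pct and
#'   deleted_pct (integer, rounded half away from zero)
#' @export
count_retention <- function(annotated, retained) {
  if (any(annotated == 0)) stop_user("annotated gene count is zero")
  if (any(retained > annotated))
    stop_user("retained cannot exceed annotated")
  data.frame(annotated = annotated, retained = retained,
             retention_pct = round_half_away(100 * retained / annotated),
             deleted_pct = round_half_away(100 * (1 - retained / annotated)))
}

#' Per-compartment retention and shuffling rates with cross-species means
#'
#' Retention is reported in percent of annotated genes, shuffling in per mil
#' of annotated genes; cross-species summaries are unweighted arithmetic
#' means (integer rounding for display).
#'
#' @param compartments data.frame with columns compartment, species,
#'   annotated, retained, shuffled
#' @return list with `rates` (per row: retention_pct, shuffle_permil) and
#'   `means` (per compartment across species)
#' @export
compartment_rates <- function(compartments) {
  r <- compartments
  r$retention_pct <- 100 * r$retained / r$annotated
  r$shuffle_permil <- 1000 * r$shuffled / r$annotated
  means <- do.call(rbind, lapply(split(r, r$compartment), function(d)
    data.frame(compartment = d$compartment[1],
               n_species = nrow(d),
               mean_retained = round_half_away(mean(d$retained)),
               mean_retention_pct = round_half_away(mean(d$retention_pct)),
               mean_shuffle_permil = round_half_away(mean(d$shuffle_permil)),
               stringsAsFactors = FALSE)))
  rownames(means) <- NULL
  list(rates = r, means = means)
}

#' Dominance tests over all paralogon pairs of a genome
#'
#' Composite compartments (fused chromosomes) are expected to be split into
#' ancestry segments by the caller, so D+S fusions are tested segment-wise.
#'
#' @param counts data.frame with columns pair (paralogon id), side_a,
#'   side_b (compartment names), n_a, n_b
#' @param alpha significance level
#' @return `counts` with chi2, p and D/S labels appended
#' @export
dominance_table <- function(counts, alpha = 0.05) {
  res <- chi_square_dominance(counts$n_a, counts$n_b, alpha)
  cbind(counts, res[, c("chi2", "p", "label_a", "label_b")])
}
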