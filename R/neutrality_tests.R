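## Frequency-spectrum neutrality tests: Tajima's D and the outgroup
## (polarized) versions of Fu & Li's D and F.
##
## Notation: S = segregating sites, eta = total mutations (= S under
## infinite sites; alleles - 1 summed per site on real alignments),
## eta_e = mutations whose derived allele occurs in exactly one haplotype
## (external-branch mutations), pi_hat = mean pairwise difference count
## (not per site).

#' Constants for frequency-spectrum neutrality tests
#'
#' The sample-size-dependent constants of Tajima's D (a1, a2, b1, b2, c1,
#' c2, e1, e2) and of Fu & Li's D and F with outgroup polarization (c_n,
#' u_D, v_D, u_F, v_F; the F-test constants follow the corrected published
#' formulas).
#'
#' @param n number of sampled haplotypes; must be >= 4.
#' @return A list of class `neutrality_constants`.
#' @export
neutrality_constants <- function(n) {
  if (n < 4L) stop("neutrality test constants require n >= 4")
  a1 <- harmonic1(n)
  a2 <- harmonic2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + (a1^2 / (a2 + a1^2)) * (cn - (n + 1) / (n - 1))
  uD <- a1 - 1 - vD
  an1 <- a1 + 1 / n  # a_{n+1}
  vF <- (cn + b2 - 2 / (n - 1)) / (a1^2 + a2)
  uF <- (1 + b1 - 4 * ((n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / a1 - vF
  structure(list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
                 c1 = c1, c2 = c2, e1 = e1, e2 = e2,
                 c_n = cn, u_D = uD, v_D = vD, u_F = uF, v_F = vF),
            class = "neutrality_constants")
}

## core formulas on sufficient statistics; return flagged NA when the
## statistic is undefined (no polymorphism)
tajimas_d_sfs <- function(S, pi_hat, n, k = neutrality_constants(n)) {
  if (S == 0) return(NA_real_)
  (pi_hat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

fu_li_d_sfs <- function(eta, eta_e, n, k = neutrality_constants(n)) {
  if (eta == 0) return(NA_real_)
  (eta - k$a1 * eta_e) / sqrt(k$u_D * eta + k$v_D * eta^2)
}

fu_li_f_sfs <- function(eta, eta_e, pi_hat, n, k = neutrality_constants(n)) {
  if (eta == 0) return(NA_real_)
  (pi_hat - eta_e) / sqrt(k$u_F * eta + k$v_F * eta^2)
}

## derived-allele counts of a haplotype matrix
derived_counts <- function(hm) {
  if (ncol(hm$mat) == 0L) return(integer())
  colSums(hm$mat)
}

## mean pairwise difference count from derived counts
pi_hat_from_counts <- function(counts, n) {
  if (length(counts) == 0L) return(0)
  sum(counts * (n - counts)) / (n * (n - 1) / 2)
}

#' Tajima's D
#'
#' Normalized difference between the mean pairwise difference count and the
#' scaled number of segregating sites. Negative values indicate an excess
#' of rare variants (sweep- or expansion-like spectra), positive values an
#' excess of intermediate-frequency variants (balancing selection or a
#' bottleneck). Operates on unpolarized data; no outgroup is needed.
#' Returns `NA` when there is no polymorphism (the statistic is undefined
#' for monomorphic loci).
#'
#' @param x a [haplotype_matrix] or a [seq_alignment].
#' @param ... passed to methods.
#' @return Tajima's D (numeric scalar), `NA` if `S` = 0.
#' @export
tajimas_d <- function(x, ...) UseMethod("tajimas_d")

#' @rdname tajimas_d
#' @export
tajimas_d.haplotype_matrix <- function(x, ...) {
  counts <- derived_counts(x)
  tajimas_d_sfs(length(counts), pi_hat_from_counts(counts, x$n), x$n)
}

#' @rdname tajimas_d
#' @param samples sample ids to analyze (alignment method; default: all).
#' @export
tajimas_d.seq_alignment <- function(x, samples = NULL, ...) {
  nd <- nucleotide_diversity(x, samples)
  tajimas_d_sfs(nd$S, nd$pi_hat, nd$n)
}

#' Fu & Li's D (outgroup version)
#'
#' Contrasts the total number of mutations eta with the number of
#' external-branch mutations eta_e (derived singletons), which requires
#' outgroup-polarized data: \eqn{D = (\eta - a_1 \eta_e) /
#' \sqrt{u_D \eta + v_D \eta^2}}.
#'
#' @param x a [haplotype_matrix], e.g. from [polarize()] or the coalescent
#'   simulator.
#' @return List of class `fu_li_result`: `statistic`, `eta`, `eta_e`.
#'   `statistic` is `NA` when `eta` = 0.
#' @export
fu_li_d <- function(x) {
  stopifnot(inherits(x, "haplotype_matrix"))
  counts <- derived_counts(x)
  eta <- length(counts)
  eta_e <- sum(counts == 1L)
  structure(list(statistic = fu_li_d_sfs(eta, eta_e, x$n),
                 eta = eta, eta_e = eta_e),
            class = "fu_li_result")
}

#' Fu & Li's F (outgroup version)
#'
#' Contrasts the mean pairwise difference count pi_hat with the number of
#' external-branch mutations eta_e:
#' \eqn{F = (\hat\pi - \eta_e) / \sqrt{u_F \eta + v_F \eta^2}}, with the
#' corrected u_F, v_F constants. Positive values indicate an excess of
#' intermediate-frequency derived alleles.
#'
#' @param x a [haplotype_matrix] of polarized sites.
#' @param pi_hat mean pairwise difference count from the same sample;
#'   computed from `x` when omitted. Supply it from the full alignment when
#'   unpolarizable sites should still contribute to pairwise differences.
#' @return List of class `fu_li_result`: `statistic`, `eta`, `eta_e`,
#'   `pi_hat`. `statistic` is `NA` when `eta` = 0.
#' @export
fu_li_f <- function(x, pi_hat = NULL) {
  stopifnot(inherits(x, "haplotype_matrix"))
  counts <- derived_counts(x)
  eta <- length(counts)
  eta_e <- sum(counts == 1L)
  if (is.null(pi_hat)) pi_hat <- pi_hat_from_counts(counts, x$n)
  structure(list(statistic = fu_li_f_sfs(eta, eta_e, pi_hat, x$n),
                 eta = eta, eta_e = eta_e, pi_hat = pi_hat),
            class = "fu_li_result")
}

#' All neutrality statistics for one locus
#'
#' Computes Tajima's D from the (unpolarized) ingroup alignment and Fu &
#' Li's D and F from the outgroup-polarized haplotype matrix, optionally
#' placing each statistic in simulated null distributions and Tajima's D in
#' a genome-wide empirical distribution.
#'
#' @param aln a [seq_alignment] with ingroup and outgroup sequences.
#' @param popmap a [pop_map].
#' @param outgroup_id outgroup sample to polarize against (see [polarize()]).
#' @param samples ingroup sample ids to analyze (default: all ingroup).
#' @param null_dists optional named list of `null_distribution` objects
#'   (names among `tajima_d`, `fu_li_d`, `fu_li_f`) from [simulate_null()].
#' @param empirical optional numeric vector: genome-wide empirical
#'   distribution of Tajima's D.
#' @return A one-row `data.frame` with `n`, `S`, `eta`, `eta_e`, `pi_hat`,
#'   `tajima_d`, `fu_li_d`, `fu_li_f`, the matching percentile columns
#'   (`NA` when no distribution is supplied), and the polarization
#'   diagnostics `unpolarizable` and `triallelic`.
#' @export
neutrality_scan <- function(aln, popmap, outgroup_id = NULL, samples = NULL,
                            null_dists = NULL, empirical = NULL) {
  if (is.null(samples)) samples <- intersect(ingroup_ids(popmap), aln$sample_ids)
  nd <- nucleotide_diversity(aln, samples)
  D <- tajimas_d_sfs(nd$S, nd$pi_hat, nd$n)
  hm <- polarize(aln, popmap, outgroup_id = outgroup_id, samples = samples)
  diag <- attr(hm, "diagnostics")
  fld <- fu_li_d(hm)
  flf <- fu_li_f(hm)
  pct <- function(value, name) {
    if (is.null(null_dists) || is.null(null_dists[[name]]) || is.na(value)) {
      return(NA_real_)
    }
    percentile_of(value, null_dists[[name]])
  }
  pcts <- c(tajima_d = pct(D, "tajima_d"),
            fu_li_d = pct(fld$statistic, "fu_li_d"),
            fu_li_f = pct(flf$statistic, "fu_li_f"))
  data.frame(
    n = nd$n, S = nd$S, eta = fld$eta, eta_e = fld$eta_e, pi_hat = nd$pi_hat,
    tajima_d = D, fu_li_d = fld$statistic, fu_li_f = flf$statistic,
    tajima_d_pct_sim = unname(pcts["tajima_d"]),
    fu_li_d_pct_sim = unname(pcts["fu_li_d"]),
    fu_li_f_pct_sim = unname(pcts["fu_li_f"]),
    tajima_d_call = significance_call(unname(pcts["tajima_d"])),
    fu_li_d_call = significance_call(unname(pcts["fu_li_d"])),
    fu_li_f_call = significance_call(unname(pcts["fu_li_f"])),
    tajima_d_pct_empirical = if (!is.null(empirical) && !is.na(D)) {
      percentile_of(D, empirical)
    } else NA_real_,
    unpolarizable = unname(diag["unpolarizable"]),
    triallelic = unname(diag["triallelic"]))
}
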