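## Per-region sequence-diversity estimators: pi (Nei-Li), Watterson's
## theta, nonsynonymous/synonymous diversity (pi_a, pi_s) via the
## Nei-Gojobori codon engine, and amino-acid polymorphism rates.

## harmonic numbers a1 = sum_{i<n} 1/i and a2 = sum_{i<n} 1/i^2
harmonic1 <- function(n) sum(1 / seq_len(n - 1L))
harmonic2 <- function(n) sum(1 / seq_len(n - 1L)^2)

## per-column pairwise-difference counts and allele counts for a character
## matrix already restricted to complete-deletion columns
column_pair_diffs <- function(mm) {
  n <- nrow(mm)
  cnt <- vapply(c("A", "C", "G", "T"),
                function(b) colSums(mm == b), numeric(ncol(mm)))
  if (ncol(mm) == 1L) cnt <- matrix(cnt, nrow = 1L)
  same <- rowSums(cnt * (cnt - 1) / 2)
  tot <- n * (n - 1) / 2
  list(diffs = tot - same,                       # pairwise diffs per column
       n_alleles = rowSums(cnt > 0),             # distinct alleles per column
       total_pairs = tot)
}

#' Nucleotide diversity (pi) of an alignment
#'
#' Average number of nucleotide differences per site between two sequences
#' in the sample (Nei-Li pi), computed over complete-deletion columns.
#' Pairwise differences count all mismatches, including at columns with
#' more than two alleles.
#'
#' @param aln a [seq_alignment].
#' @param samples sample ids to analyze (default: all); needs >= 2.
#' @param variance `"total"` (default) uses the no-recombination total
#'   variance of Tajima/Nei,
#'   \eqn{V = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2};
#'   `"sampling"` uses the empirical standard error of the per-column mean
#'   pairwise difference across sites. The two options are provided because
#'   reported standard errors in the literature are not always attributable
#'   to a single formula.
#' @return List of class `diversity_result`: `pi`, `pi_se`, `S` (segregating
#'   sites), `L_eff` (analyzed columns), `pi_hat` (mean pairwise difference
#'   count, not per site), `n`.
#' @export
nucleotide_diversity <- function(aln, samples = NULL,
                                 variance = c("total", "sampling")) {
  variance <- match.arg(variance)
  m <- aln_matrix(aln, samples)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  keep <- which(colSums(m == "-" | m == "N") == 0L)
  L_eff <- length(keep)
  if (L_eff == 0L) stop("no sites left after complete deletion")
  mm <- m[, keep, drop = FALSE]
  pc <- column_pair_diffs(mm)
  pi_hat <- sum(pc$diffs) / pc$total_pairs
  pi <- pi_hat / L_eff
  S <- sum(pc$n_alleles >= 2L)
  if (variance == "total") {
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    pi_se <- sqrt(b1 * pi / L_eff + b2 * pi^2)
  } else {
    percol <- pc$diffs / pc$total_pairs
    pi_se <- if (L_eff > 1L) sd(percol) / sqrt(L_eff) else NA_real_
  }
  structure(list(pi = pi, pi_se = pi_se, S = S, L_eff = L_eff,
                 pi_hat = pi_hat, n = n, variance = variance),
            class = "diversity_result")
}

#' Watterson's theta per site
#'
#' Scaled number of segregating sites, \eqn{\theta_W = S / (a_1 L)}
#' with \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}, over complete-deletion columns.
#'
#' @inheritParams nucleotide_diversity
#' @return Per-site Watterson estimate (numeric scalar) with attributes
#'   `S` and `L_eff`.
#' @export
watterson_theta <- function(aln, samples = NULL) {
  m <- aln_matrix(aln, samples)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  keep <- which(colSums(m == "-" | m == "N") == 0L)
  L_eff <- length(keep)
  if (L_eff == 0L) stop("no sites left after complete deletion")
  mm <- m[, keep, drop = FALSE]
  S <- sum(column_pair_diffs(mm)$n_alleles >= 2L)
  theta <- S / (harmonic1(n) * L_eff)
  attr(theta, "S") <- S
  attr(theta, "L_eff") <- L_eff
  theta
}

#' Nonsynonymous and synonymous nucleotide diversity (pi_a, pi_s)
#'
#' Within-sample analog of dN/dS: mean pairwise synonymous
#' (nonsynonymous) differences divided by mean synonymous (nonsynonymous)
#' sites, using Nei-Gojobori codon counting. Codon columns containing a
#' gap, `N` or a stop codon in any analyzed sample are excluded (complete
#' deletion at the codon level). No distance correction is applied by
#' default because within-species diversity is small; set `jc = TRUE` for
#' Jukes-Cantor correction of the per-pair proportions.
#'
#' @param aln an in-frame coding [seq_alignment].
#' @param samples sample ids to analyze (default: all); needs >= 2.
#' @param jc apply Jukes-Cantor correction (default `FALSE`).
#' @return List of class `pi_as_result`: `pi_a`, `pi_s`, `ratio` (`NA` with
#'   attribute `undefined = TRUE` when `pi_s` = 0), `N_sites`, `S_sites`
#'   (mean fractional site counts), `codons` (analyzed codon columns), `n`.
#' @export
pi_a_pi_s <- function(aln, samples = NULL, jc = FALSE) {
  if (is.null(samples)) samples <- aln$sample_ids
  if (length(samples) < 2L) stop("need at least 2 sequences")
  cim <- codon_index_matrix(aln, samples)
  ok <- colSums(is.na(cim)) == 0L
  if (!any(ok)) stop("no complete codons after codon-level deletion")
  cim <- cim[, ok, drop = FALSE]
  tb <- ng_tables()
  n <- length(samples)
  syn_sites_per_seq <- rowSums(matrix(tb$syn_sites[cim], nrow = n))
  mean_syn_sites <- mean(syn_sites_per_seq)
  mean_nonsyn_sites <- 3 * ncol(cim) - mean_syn_sites
  pairs <- utils::combn(n, 2L)
  sdiffs <- ndiffs <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i1 <- cim[pairs[1L, k], ]; i2 <- cim[pairs[2L, k], ]
    sdiffs[k] <- sum(tb$sd[cbind(i1, i2)])
    ndiffs[k] <- sum(tb$nd[cbind(i1, i2)])
  }
  if (jc) {
    pi_s <- mean(jukes_cantor(sdiffs / mean_syn_sites))
    pi_a <- mean(jukes_cantor(ndiffs / mean_nonsyn_sites))
  } else {
    pi_s <- mean(sdiffs) / mean_syn_sites
    pi_a <- mean(ndiffs) / mean_nonsyn_sites
  }
  ratio <- if (pi_s == 0) NA_real_ else pi_a / pi_s
  out <- list(pi_a = pi_a, pi_s = pi_s, ratio = ratio,
              N_sites = mean_nonsyn_sites, S_sites = mean_syn_sites,
              codons = ncol(cim), n = n)
  if (pi_s == 0) attr(out$ratio, "undefined") <- TRUE
  structure(out, class = "pi_as_result")
}

#' Amino-acid polymorphism rate per 100 residues
#'
#' Percentage of analyzed protein-alignment columns with at least two
#' distinct residues. Columns containing `X` (masked codons) in any sample
#' are excluded from the denominator.
#'
#' @param prot an `aa_alignment` from [translate_coding()] (or any named
#'   character vector of equal-length protein sequences).
#' @return Polymorphic residues per 100 residues (numeric scalar) with
#'   attributes `polymorphic` and `analyzed`.
#' @export
aa_polymorphism_rate <- function(prot) {
  m <- do.call(rbind, strsplit(unname(as.character(prot)), ""))
  keep <- colSums(m == "X") == 0L
  analyzed <- sum(keep)
  if (analyzed == 0L) stop("no analyzable residue columns (all masked)")
  mm <- m[, keep, drop = FALSE]
  poly <- sum(apply(mm, 2L, function(col) length(unique(col))) >= 2L)
  rate <- 100 * poly / analyzed
  attr(rate, "polymorphic") <- poly
  attr(rate, "analyzed") <- analyzed
  rate
}

#' Full diversity summary for one alignment region
#'
#' Convenience wrapper assembling the per-locus diversity row: n, effective
#' length, segregating sites, pi (+SE), Watterson's theta, and -- when the
#' region is coding -- pi_a, pi_s, their ratio, and the amino-acid
#' polymorphism rate.
#'
#' @param aln a [seq_alignment] for one region (in frame if `coding = TRUE`).
#' @param samples sample ids to analyze (default: all).
#' @param coding whether to add codon-based statistics.
#' @return A one-row `data.frame` with columns `n`, `L_eff`, `S`, `pi`,
#'   `pi_se`, `theta_w`, `pi_a`, `pi_s`, `pi_a_over_pi_s`, `aa_poly_per_100`
#'   (the last four `NA` for non-coding regions).
#' @export
diversity_summary <- function(aln, samples = NULL, coding = FALSE) {
  nd <- nucleotide_diversity(aln, samples)
  tw <- watterson_theta(aln, samples)
  row <- data.frame(n = nd$n, L_eff = nd$L_eff, S = nd$S,
                    pi = nd$pi, pi_se = nd$pi_se, theta_w = as.numeric(tw),
                    pi_a = NA_real_, pi_s = NA_real_,
                    pi_a_over_pi_s = NA_real_, aa_poly_per_100 = NA_real_)
  if (coding) {
    pas <- pi_a_pi_s(aln, samples)
    row$pi_a <- pas$pi_a
    row$pi_s <- pas$pi_s
    row$pi_a_over_pi_s <- as.numeric(pas$ratio)
    ids <- if (is.null(samples)) aln$sample_ids else samples
    prot <- translate_coding(seq_alignment(aln$sequences[ids], ids))
    row$aa_poly_per_100 <- as.numeric(aa_polymorphism_rate(prot))
  }
  row
}
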