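## Divergence measures: Nei-Gojobori dN/dS against an outgroup, Tajima's 1D
## relative-rate test, and the least-squares K scale factor between trees.
##
## The Nei-Gojobori codon engine below (site fractions and pathway-averaged
## difference counts) is shared with the within-species pi_a/pi_s estimator.

.ng_env <- new.env(parent = emptyenv())

## Build 64x64 lookup tables for the Nei-Gojobori method:
##  - syn_sites[c]: fractional synonymous sites of codon c (out of 3);
##    mutations creating a stop codon count as nonsynonymous, so
##    synonymous + nonsynonymous sites = 3 exactly for every codon;
##  - sd[c1,c2]/nd[c1,c2]: synonymous/nonsynonymous differences averaged
##    over all shortest mutational pathways; pathways passing through a stop
##    codon are excluded unless every pathway does.
ng_tables <- function() {
  if (!is.null(.ng_env$tables)) return(.ng_env$tables)
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases, stringsAsFactors = FALSE)[, 3:1],
                  1L, paste, collapse = "")
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  names(aa) <- codons
  idx <- setNames(seq_along(codons), codons)

  syn_sites <- vapply(codons, function(c1) {
    tot <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, substr(c1, p, p))) {
        c2 <- c1; substr(c2, p, p) <- b
        if (aa[[c2]] != "*" && aa[[c2]] == aa[[c1]]) tot <- tot + 1 / 3
      }
    }
    tot
  }, 0)

  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  sdm <- matrix(0, 64L, 64L, dimnames = list(codons, codons))
  ndm <- matrix(0, 64L, 64L, dimnames = list(codons, codons))
  for (c1 in codons) {
    for (c2 in codons) {
      diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
      d <- length(diffpos)
      if (d == 0L) next
      paths <- lapply(perms[[as.character(d)]], function(ord) diffpos[ord])
      res <- lapply(paths, function(ord) {
        cur <- c1; s <- 0; n <- 0; stopped <- FALSE
        for (k in seq_along(ord)) {
          nxt <- cur
          substr(nxt, ord[k], ord[k]) <- substr(c2, ord[k], ord[k])
          if (aa[[nxt]] == "*" && k < length(ord)) stopped <- TRUE
          if (aa[[nxt]] == aa[[cur]]) s <- s + 1 else n <- n + 1
          cur <- nxt
        }
        c(s = s, n = n, stopped = as.numeric(stopped))
      })
      res <- do.call(rbind, res)
      use <- res[, "stopped"] == 0
      if (!any(use)) use <- rep(TRUE, nrow(res))
      sdm[c1, c2] <- mean(res[use, "s"])
      ndm[c1, c2] <- mean(res[use, "n"])
    }
  }
  .ng_env$tables <- list(codons = codons, idx = idx, aa = aa,
                         syn_sites = syn_sites, sd = sdm, nd = ndm)
  .ng_env$tables
}

## Map each sequence of an in-frame coding alignment to codon indices;
## codons containing non-ACGT characters or encoding a stop map to NA.
codon_index_matrix <- function(aln, samples = NULL) {
  tb <- ng_tables()
  if (is.null(samples)) samples <- aln$sample_ids
  ncod <- aln$L %/% 3L
  if (ncod == 0L) stop("no complete codons")
  out <- matrix(NA_integer_, nrow = length(samples), ncol = ncod,
                dimnames = list(samples, NULL))
  for (id in samples) {
    s <- aln$sequences[[id]]
    codons <- substring(s, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
    j <- match(codons, tb$codons)
    is_stop <- !is.na(j)
    is_stop[is_stop] <- tb$aa[codons[is_stop]] == "*"
    j[is_stop] <- NA_integer_
    out[id, ] <- j
  }
  out
}

## Nei-Gojobori counts for one pair of codon-index vectors. Codon columns
## where either member is NA (gap/N/stop) are skipped.
ng_pair_counts <- function(i1, i2) {
  tb <- ng_tables()
  ok <- !is.na(i1) & !is.na(i2)
  i1 <- i1[ok]; i2 <- i2[ok]
  s1 <- sum(tb$syn_sites[i1]); s2 <- sum(tb$syn_sites[i2])
  list(codons = length(i1),
       syn_sites = (s1 + s2) / 2,
       nonsyn_sites = 3 * length(i1) - (s1 + s2) / 2,
       syn_diffs = sum(tb$sd[cbind(i1, i2)]),
       nonsyn_diffs = sum(tb$nd[cbind(i1, i2)]))
}

#' Jukes-Cantor distance correction
#'
#' @param p proportion of differences per site.
#' @return Corrected distance \eqn{d = -\frac{3}{4}\log(1 - \frac{4p}{3})}.
#' @export
jukes_cantor <- function(p) {
  if (any(p >= 0.75, na.rm = TRUE)) {
    stop("Jukes-Cantor correction undefined for p >= 3/4")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori dN/dS against an outgroup
#'
#' Counts synonymous and nonsynonymous sites and differences per
#' Nei & Gojobori (1986): fractional synonymous sites from single-step
#' mutation enumeration, differences apportioned by averaging over all
#' shortest mutational pathways (pathways through stop codons excluded),
#' Jukes-Cantor correction applied to the proportions. By default each
#' ingroup haplotype is compared to the outgroup and d_N and d_S are
#' averaged before forming the ratio; `mode = "consensus"` compares a
#' majority-rule ingroup consensus instead.
#'
#' @param aln an in-frame coding [seq_alignment] containing ingroup and
#'   outgroup sequences (slice with [slice_region()] first if needed).
#' @param outgroup_id sample id of the outgroup sequence.
#' @param samples ingroup sample ids (default: everything but the outgroup).
#' @param mode `"average"` (default) or `"consensus"`.
#' @return List of class `divergence_result`: `d_n`, `d_s`, `ratio`
#'   (`NA` when `d_s` = 0), `p_n`, `p_s`, `N_sites`, `S_sites` (mean
#'   fractional site counts), `codons`, `outgroup_id`, `mode`.
#' @export
nei_gojobori_dn_ds <- function(aln, outgroup_id, samples = NULL,
                               mode = c("average", "consensus")) {
  mode <- match.arg(mode)
  if (!outgroup_id %in% aln$sample_ids) {
    stop("outgroup '", outgroup_id, "' not in alignment")
  }
  if (is.null(samples)) samples <- setdiff(aln$sample_ids, outgroup_id)
  if (length(samples) < 1L) stop("no ingroup samples")
  if (mode == "consensus") {
    cons <- consensus_sequence(aln, samples)
    caln <- seq_alignment(c(consensus = cons,
                            setNames(aln$sequences[outgroup_id], outgroup_id)))
    samples <- "consensus"
    cim <- codon_index_matrix(caln)
  } else {
    cim <- codon_index_matrix(aln, c(samples, outgroup_id))
  }
  og <- cim[outgroup_id, ]
  dn <- ds <- pn <- ps <- numeric(length(samples))
  Ns <- Ss <- cod <- numeric(length(samples))
  for (k in seq_along(samples)) {
    cnt <- ng_pair_counts(cim[samples[k], ], og)
    if (cnt$codons == 0L) stop("no analyzable codons (all gapped/ambiguous)")
    ps[k] <- cnt$syn_diffs / cnt$syn_sites
    pn[k] <- cnt$nonsyn_diffs / cnt$nonsyn_sites
    ds[k] <- jukes_cantor(ps[k])
    dn[k] <- jukes_cantor(pn[k])
    Ns[k] <- cnt$nonsyn_sites; Ss[k] <- cnt$syn_sites; cod[k] <- cnt$codons
  }
  d_n <- mean(dn); d_s <- mean(ds)
  structure(list(d_n = d_n, d_s = d_s,
                 ratio = if (d_s == 0) NA_real_ else d_n / d_s,
                 p_n = mean(pn), p_s = mean(ps),
                 N_sites = mean(Ns), S_sites = mean(Ss),
                 codons = mean(cod), outgroup_id = outgroup_id, mode = mode),
            class = "divergence_result")
}

## Majority-rule consensus over non-gap characters; ties broken
## alphabetically for determinism. Columns that are gap/N in every sample
## stay 'N'.
consensus_sequence <- function(aln, samples = NULL) {
  m <- aln_matrix(aln, samples)
  cons <- apply(m, 2L, function(col) {
    col <- col[!col %in% c("-", "N")]
    if (length(col) == 0L) return("N")
    tab <- table(col)
    names(tab)[which.max(tab)]  # which.max takes the first = alphabetical
  })
  paste(cons, collapse = "")
}

#' Tajima's 1D relative-rate test
#'
#' Tests whether two lineages evolve at equal rates relative to an outgroup
#' by contrasting the counts of sites where each lineage uniquely differs:
#' `m_A` = sites where A differs from both B and the outgroup while B
#' equals the outgroup, and symmetrically `m_B`. Under rate equality
#' \eqn{\chi^2 = (m_A - m_B)^2 / (m_A + m_B)} with 1 degree of freedom.
#'
#' @param seq_a,seq_b,outgroup aligned sequences (character scalars of equal
#'   length); complete deletion is applied across the three.
#' @return List of class `relative_rate_result`: `m_a`, `m_b`, `chi2`,
#'   `p_value` (both `NA` when `m_a + m_b` = 0).
#' @export
relative_rate_test <- function(seq_a, seq_b, outgroup) {
  aln <- seq_alignment(c(A = seq_a, B = seq_b, O = outgroup))
  m <- aln_matrix(aln)
  keep <- colSums(m == "-" | m == "N") == 0L
  a <- m["A", keep]; b <- m["B", keep]; o <- m["O", keep]
  m_a <- sum(a != b & a != o & b == o)
  m_b <- sum(a != b & b != o & a == o)
  if (m_a + m_b == 0L) {
    chi2 <- NA_real_; p <- NA_real_
  } else {
    chi2 <- (m_a - m_b)^2 / (m_a + m_b)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(m_a = m_a, m_b = m_b, chi2 = chi2, p_value = p),
            class = "relative_rate_result")
}

## canonical bipartition keys (one per edge) of an unrooted ape::phylo;
## each key is the sorted tip set on the side not containing the
## alphabetically first tip, so keys are comparable across trees.
edge_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  ntip <- length(tips)
  ref <- sort(tips)[1]
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tips[i]
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; chd <- po$edge[k, 2]
    desc[[par]] <- c(desc[[par]], desc[[chd]])
  }
  keys <- character(nrow(po$edge))
  for (k in seq_len(nrow(po$edge))) {
    side <- desc[[po$edge[k, 2]]]
    if (ref %in% side) side <- setdiff(tips, side)
    keys[k] <- paste(sort(side), collapse = ",")
  }
  lens <- if (is.null(po$edge.length)) stop("tree has no branch lengths") else
    po$edge.length
  setNames(lens, keys)
}

#' K scale factor between two phylogenetic trees
#'
#' Least-squares scale factor aligning the branch lengths of a comparison
#' tree to a reference tree over matched branches:
#' \eqn{K = \sum l_{ref} l_{comp} / \sum l_{comp}^2}, the minimizer of
#' \eqn{\sum (l_{ref} - K\, l_{comp})^2}. Branches are matched by leaf
#' bipartition, so the two trees must share the same leaf set and the same
#' unrooted topology. Smaller K means the comparison tree is larger (more
#' diverged) than the reference.
#'
#' @param reference,comparison trees as `ape::phylo` objects, newick
#'   strings, or paths to newick files; branch lengths required.
#' @return List of class `k_score_result`: `K`, `n_branches`.
#' @export
k_score <- function(reference, comparison) {
  ref <- as_phylo(reference)
  comp <- as_phylo(comparison)
  if (!setequal(ref$tip.label, comp$tip.label)) {
    stop("trees have different leaf sets")
  }
  br <- edge_bipartitions(ref)
  bc <- edge_bipartitions(comp)
  unmatched <- c(setdiff(names(br), names(bc)), setdiff(names(bc), names(br)))
  if (length(unmatched)) {
    stop("tree topologies differ; unmatched bipartitions: ",
         paste(unique(unmatched), collapse = " | "))
  }
  lc <- bc[names(br)]
  K <- sum(br * lc) / sum(lc^2)
  structure(list(K = K, n_branches = length(br)), class = "k_score_result")
}

as_phylo <- function(x) {
  if (inherits(x, "phylo")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (file.exists(x)) return(ape::read.tree(x))
    return(ape::read.tree(text = x))
  }
  stop("cannot interpret tree input")
}
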