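## Population differentiation: Hudson-Slatkin-Maddison F_ST = 1 - Hw/Hb.

#' Hudson's F_ST between two populations
#'
#' Sequence-based fixation index \eqn{F_{ST} = 1 - H_w / H_b}, where
#' \eqn{H_w} is the unweighted mean of the two within-population mean
#' pairwise difference counts and \eqn{H_b} the mean pairwise difference
#' count over all between-population pairs. Complete deletion is applied
#' across the union of the two samples. A value of 1 means the populations
#' share no genetic diversity; values near 0 mean no differentiation.
#' Negative estimates (possible when differentiation is near zero) are
#' reported as computed, not clipped.
#'
#' @param aln a [seq_alignment].
#' @param popmap a [pop_map].
#' @param pop_a,pop_b population labels to compare; each must contribute at
#'   least 2 haplotypes present in the alignment.
#' @return List of class `fst_result`: `fst` (`NA` when `H_b` = 0), `h_w`,
#'   `h_b`, `n1`, `n2`.
#' @export
hudson_fst <- function(aln, popmap, pop_a, pop_b) {
  ids_a <- intersect(ingroup_ids(popmap, pop_a), aln$sample_ids)
  ids_b <- intersect(ingroup_ids(popmap, pop_b), aln$sample_ids)
  if (length(ids_a) < 2L) stop("population '", pop_a, "' has < 2 samples")
  if (length(ids_b) < 2L) stop("population '", pop_b, "' has < 2 samples")
  m <- aln_matrix(aln, c(ids_a, ids_b))
  keep <- which(colSums(m == "-" | m == "N") == 0L)
  if (length(keep) == 0L) stop("no sites left after complete deletion")
  mm <- m[, keep, drop = FALSE]
  n1 <- length(ids_a); n2 <- length(ids_b)
  ma <- mm[ids_a, , drop = FALSE]
  mb <- mm[ids_b, , drop = FALSE]

  within_mean <- function(mx) {
    pc <- column_pair_diffs(mx)
    sum(pc$diffs) / pc$total_pairs
  }
  hw <- (within_mean(ma) + within_mean(mb)) / 2

  ## between-population mean: per column, matching cross pairs per allele
  cnt_a <- vapply(c("A", "C", "G", "T"),
                  function(b) colSums(ma == b), numeric(ncol(mm)))
  cnt_b <- vapply(c("A", "C", "G", "T"),
                  function(b) colSums(mb == b), numeric(ncol(mm)))
  if (ncol(mm) == 1L) {
    cnt_a <- matrix(cnt_a, nrow = 1L)
    cnt_b <- matrix(cnt_b, nrow = 1L)
  }
  same_cross <- rowSums(cnt_a * cnt_b)
  hb <- sum(n1 * n2 - same_cross) / (n1 * n2)

  fst <- if (hb == 0) NA_real_ else 1 - hw / hb
  structure(list(fst = fst, h_w = hw, h_b = hb, n1 = n1, n2 = n2),
            class = "fst_result")
}
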