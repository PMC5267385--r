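test_that("pi matches its definition on small worked cases", {
  # 2 sequences, L = 100, 3 differences -> pi = 0.03
  s1 <- strrep("A", 100)
  s2 <- paste0("TTT", strrep("A", 97))
  aln <- seq_alignment(c(a = s1, b = s2))
  nd <- nucleotide_diversity(aln)
  expect_equal(nd$pi, 0.03)
  expect_equal(nd$S, 3)

  # identical sequences
  nd0 <- nucleotide_diversity(seq_alignment(c(a = s1, b = s1)))
  expect_equal(nd0$pi, 0)
  expect_equal(nd0$S, 0)

  # 4 haplotypes over L = 10 realizing the 000/100/110/111 matrix:
  # mean pairwise count 10/6, pi = 1/6
  base <- strrep("A", 7)
  aln4 <- seq_alignment(c(h1 = paste0("AAA", base), h2 = paste0("TAA", base),
                          h3 = paste0("TTA", base), h4 = paste0("TTT", base)))
  nd4 <- nucleotide_diversity(aln4)
  expect_equal(nd4$pi_hat, 10 / 6, tolerance = 1e-12)
  expect_equal(nd4$pi, 10 / 60, tolerance = 1e-12)

  expect_error(nucleotide_diversity(seq_alignment(c(a = s1))), "at least 2")
  expect_error(nucleotide_diversity(seq_alignment(c(a = "--", b = "AA"))),
               "complete deletion")
})

test_that("pi equals the brute-force pair enumeration on random alignments", {
  set.seed(81)
  for (rep in 1:15) {
    n <- sample(3:6, 1)
    L <- 40
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
    aln <- seq_alignment(seqs, paste0("s", seq_len(n)))
    nd <- nucleotide_diversity(aln)
    expect_equal(nd$pi_hat, oracle_pairwise_diffs(seqs), tolerance = 1e-12)
    # invariance under row permutation
    perm <- sample(n)
    nd_p <- nucleotide_diversity(seq_alignment(seqs[perm],
                                               paste0("s", seq_len(n))))
    expect_equal(nd_p$pi, nd$pi, tolerance = 1e-12)
  }
})

test_that("Watterson's theta follows S / (a1 L)", {
  # n = 4, S = 3, L = 100
  base <- strrep("A", 97)
  aln <- seq_alignment(c(h1 = paste0("AAA", base), h2 = paste0("TAA", base),
                         h3 = paste0("TTA", base), h4 = paste0("TTT", base)))
  tw <- watterson_theta(aln)
  expect_equal(as.numeric(tw), 3 / ((1 + 1 / 2 + 1 / 3) * 100),
               tolerance = 1e-9)

  # S = 0
  mono <- seq_alignment(c(a = strrep("A", 50), b = strrep("A", 50)))
  expect_equal(as.numeric(watterson_theta(mono)), 0)

  # n = 2: a1 = 1, and pi = theta_w exactly
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("T", 5), strrep("A", 95))
  two <- seq_alignment(c(a = s1, b = s2))
  expect_equal(as.numeric(watterson_theta(two)), 0.05)
  expect_equal(nucleotide_diversity(two)$pi, as.numeric(watterson_theta(two)))
})

test_that("pi_a/pi_s separates synonymous from nonsynonymous diversity", {
  # all differences synonymous (third-position GCx Ala wobble)
  a <- strrep("ATGGCTAAATTACGTGAT", 4)
  b <- sub("GCT", "GCC", a)
  aln <- seq_alignment(c(s1 = a, s2 = b))
  r <- pi_a_pi_s(aln)
  expect_equal(r$pi_a, 0)
  expect_gt(r$pi_s, 0)
  expect_equal(as.numeric(r$ratio), 0)

  # identical sequences: both zero, ratio undefined
  r0 <- pi_a_pi_s(seq_alignment(c(s1 = a, s2 = a)))
  expect_equal(r0$pi_a, 0)
  expect_equal(r0$pi_s, 0)
  expect_true(is.na(r0$ratio))
  expect_true(isTRUE(attr(r0$ratio, "undefined")))
})

test_that("pi_a/pi_s pair counts equal the exhaustive pathway oracle", {
  set.seed(91)
  sense <- sense_codons()
  for (rep in 1:10) {
    c1 <- sample(sense, 100, replace = TRUE)
    c2 <- c1
    mut <- sample(100, 12)
    c2[mut] <- sample(sense, 12, replace = TRUE)
    aln <- seq_alignment(c(x = paste(c1, collapse = ""),
                           y = paste(c2, collapse = "")))
    r <- pi_a_pi_s(aln)
    o_s <- sum(vapply(seq_len(100), function(i) {
      oracle_ng_diffs(c1[i], c2[i])["s"]
    }, 0))
    o_n <- sum(vapply(seq_len(100), function(i) {
      oracle_ng_diffs(c1[i], c2[i])["n"]
    }, 0))
    sites1 <- sum(vapply(c1, oracle_ng_sites, 0))
    sites2 <- sum(vapply(c2, oracle_ng_sites, 0))
    expect_equal(r$pi_s, o_s / ((sites1 + sites2) / 2), tolerance = 1e-9)
    expect_equal(r$pi_a, o_n / (300 - (sites1 + sites2) / 2), tolerance = 1e-9)
  }
})

test_that("amino-acid polymorphism rate masks X columns", {
  expect_equal(as.numeric(aa_polymorphism_rate(c("MKV", "MKV"))), 0)
  expect_equal(as.numeric(aa_polymorphism_rate(c("MKV", "MRV"))), 100 / 3,
               tolerance = 1e-9)
  r <- aa_polymorphism_rate(c("MKV", "MXV"))
  expect_equal(unname(attr(r, "analyzed")), 2)
  expect_equal(as.numeric(r), 0)
  expect_error(aa_polymorphism_rate(c("X", "X")), "no analyzable")
})

test_that("adding an identical haplotype moves pi toward its fixation structure", {
  set.seed(101)
  seqs <- vapply(1:4, function(i) {
    paste(sample(c("A", "T"), 30, replace = TRUE), collapse = "")
  }, "")
  aln <- seq_alignment(seqs, paste0("s", 1:4))
  pi4 <- nucleotide_diversity(aln)$pi
  aln5 <- seq_alignment(c(seqs, seqs[1]), paste0("s", 1:5))
  pi5 <- nucleotide_diversity(aln5)$pi
  expect_equal(pi5, oracle_pairwise_diffs(c(seqs, seqs[1])) / 30,
               tolerance = 1e-12)
  expect_lt(pi5, pi4)  # duplicating a haplotype lowers mean pairwise diversity
})
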