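test_that("FASTA reading preserves order, folds case, enforces the alphabet", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "acgt", ">s2", "ACGA"), tf)
  aln <- read_fasta(tf)
  expect_s3_class(aln, "seq_alignment")
  expect_identical(aln$sample_ids, c("s1", "s2"))
  expect_identical(unname(aln$sequences), c("ACGT", "ACGA"))
  expect_equal(aln$L, 4)

  writeLines(c(">a", "ACGT", ">b", "ACGTA"), tf)
  expect_error(read_fasta(tf), "unequal lengths")

  writeLines(c(">a", "ACGU", ">b", "ACGA"), tf)
  expect_error(read_fasta(tf), "illegal character")

  writeLines(character(), tf)
  expect_error(read_fasta(tf), "FASTA")

  writeLines(c(">only", "ACGT"), tf)
  expect_error(read_fasta(tf), "at least 2")
})

test_that("FASTA round-trip is byte-identical for canonical input", {
  aln <- seq_alignment(c(a = "ACGTN-AC", b = "ACCTNNAC", c = "ACGTACGT"))
  tf1 <- withr::local_tempfile(fileext = ".fasta")
  tf2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(aln, tf1)
  write_fasta(read_fasta(tf1), tf2)
  expect_identical(readLines(tf1), readLines(tf2))
})

test_that("population map parsing extracts outgroups and rejects bad input", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpopulation", "B73\ttemperate", "Ki3\ttropical",
               "TL92B\toutgroup"), tf)
  pm <- read_population_map(tf)
  expect_identical(pm$outgroup_ids, "TL92B")
  expect_setequal(ingroup_ids(pm), c("B73", "Ki3"))
  expect_identical(ingroup_ids(pm, "tropical"), "Ki3")

  writeLines(c("sample_id\tpopulation", "B73\ttemperate", "B73\ttropical"), tf)
  expect_error(read_population_map(tf), "duplicate")

  writeLines(c("sample_id\tpopulation", "X\toutgroup", "Y\toutgroup"), tf)
  expect_error(read_population_map(tf), "no ingroup")
})

test_that("complete deletion drops exactly the gapped/ambiguous columns", {
  aln <- seq_alignment(c(a = "AC-T", b = "ACGT"))
  expect_identical(complete_deletion_mask(aln), c(1L, 2L, 4L))

  aln2 <- seq_alignment(c(a = "ACGT", b = "ACGA"))
  expect_identical(complete_deletion_mask(aln2), 1:4)

  aln3 <- seq_alignment(c(a = "A-GT", b = "A-GN"))
  expect_identical(complete_deletion_mask(aln3), c(1L, 3L))
  # column gapped in every sequence is excluded too
  expect_false(2L %in% complete_deletion_mask(aln3))
})

test_that("polarization follows the outgroup-ancestral rule", {
  pm <- pop_map(c("i1", "i2", "og"), c("p", "p", "outgroup"))

  # outgroup carries one of the two ingroup alleles -> polarized site
  aln <- seq_alignment(c(i1 = "AA", i2 = "AT", og = "AA"))
  hm <- polarize(aln, pm)
  expect_equal(ncol(hm$mat), 1)
  expect_identical(as.integer(hm$mat[, 1]), c(0L, 1L))

  # outgroup carries a third allele -> excluded, counted unpolarizable
  aln2 <- seq_alignment(c(i1 = "AA", i2 = "AT", og = "AG"))
  hm2 <- polarize(aln2, pm)
  expect_equal(ncol(hm2$mat), 0)  # col 1 monomorphic, col 2 unpolarizable
  expect_equal(unname(attr(hm2, "diagnostics")["unpolarizable"]), 1)
  expect_equal(unname(attr(hm2, "diagnostics")["monomorphic"]), 1)

  # monomorphic ingroup column emits no site
  aln3 <- seq_alignment(c(i1 = "AA", i2 = "AA", og = "AT"))
  hm3 <- polarize(aln3, pm)
  expect_equal(ncol(hm3$mat), 0)

  # no outgroup -> error
  pm2 <- pop_map(c("i1", "i2"), c("p", "p"))
  expect_error(polarize(aln, pm2), "outgroup")
})

test_that("polarization bookkeeping conserves analyzed columns", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    L <- 60
    seqs <- vapply(seq_len(n + 1), function(i) {
      paste(sample(c("A", "C", "G", "T", "-"), L, replace = TRUE,
                   prob = c(0.3, 0.3, 0.17, 0.17, 0.06)), collapse = "")
    }, "")
    ids <- c(paste0("s", seq_len(n)), "og")
    aln <- seq_alignment(seqs, ids)
    pm <- pop_map(ids, c(rep("p", n), "outgroup"))
    hm <- polarize(aln, pm)
    d <- attr(hm, "diagnostics")
    expect_equal(ncol(hm$mat) + sum(d[c("monomorphic", "unpolarizable",
                                        "triallelic")]),
                 unname(d["analyzed_columns"]))
    # invariant to ingroup row permutation (site set and counts)
    perm <- sample(n)
    aln_p <- seq_alignment(seqs[c(perm, n + 1)], ids[c(perm, n + 1)])
    hm_p <- polarize(aln_p, pm)
    expect_equal(hm_p$positions, hm$positions)
    expect_equal(colSums(hm_p$mat), colSums(hm$mat))
  }
})

test_that("region slicing and translation follow the frame conventions", {
  reg <- region_annotation(c(0L, 4L), c(4L, 10L), c("five_prime", "coding"))
  aln <- seq_alignment(c(a = "GGGGATGAAA", b = "GGGGATGA-A"))
  cod <- slice_region(aln, reg, "coding")
  expect_equal(unname(cod$sequences), c("ATGAAA", "ATGA-A"))
  prot <- translate_coding(cod)
  expect_identical(unname(unclass(prot)), c("MK", "MX"))

  # frame offset trims leading bases before translation
  aln2 <- seq_alignment(c(a = "AATGAAA", b = "AATGAAA"))
  p2 <- translate_coding(aln2, frame_offset = 1)
  expect_identical(unname(unclass(p2)), c("MK", "MK"))
  # a trailing partial codon is dropped with a warning (one per sequence)
  aln2b <- seq_alignment(c(a = "AATGAAAC", b = "AATGAAAC"))
  w <- capture_warnings(p2b <- translate_coding(aln2b, frame_offset = 1))
  expect_match(w, "trailing", all = TRUE)
  expect_identical(unname(unclass(p2b)), c("MK", "MK"))

  # internal stop retained with a warning
  aln3 <- seq_alignment(c(a = "TAAAAA", b = "TACAAA"))
  expect_warning(p3 <- translate_coding(aln3), "stop codon")
  expect_identical(unname(unclass(p3))[1], "*K")

  # coding length not divisible by 3 is rejected at annotation time
  expect_error(region_annotation(0L, 4L, "coding"), "multiple of 3")
  expect_error(region_annotation(c(0L, 2L), c(3L, 5L),
                                 c("coding", "coding")), "overlap|multiple")
})

test_that("BED round trip preserves the annotation", {
  reg <- region_annotation(c(0L, 240L, 840L), c(240L, 840L, 1440L),
                           c("five_prime", "coding", "intron"))
  tf <- withr::local_tempfile(fileext = ".bed")
  write_region_bed(reg, tf, chrom = "g1")
  reg2 <- read_region_bed(tf)
  expect_equal(reg2$start, reg$start)
  expect_equal(reg2$end, reg$end)
  expect_equal(reg2$klass, reg$klass)
})
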