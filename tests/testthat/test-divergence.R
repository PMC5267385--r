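test_that("Nei-Gojobori fractional sites sum to 3 for every codon", {
  tb <- popgenscan:::ng_tables()
  expect_length(tb$syn_sites, 64)
  # nonsynonymous sites are defined as 3 - synonymous, so the identity is
  # structural; check the synonymous fractions themselves against the oracle
  for (codon in tb$codons) {
    expect_equal(unname(tb$syn_sites[codon]), oracle_ng_sites(codon),
                 tolerance = 1e-12)
  }
  # spot values: ATG (Met) has no synonymous site, GCT (Ala) has one
  expect_equal(unname(tb$syn_sites["ATG"]), 0)
  expect_equal(unname(tb$syn_sites["GCT"]), 1)
})

test_that("pathway-averaged difference counts match exhaustive enumeration", {
  set.seed(17)
  tb <- popgenscan:::ng_tables()
  sense <- sense_codons()
  pairs <- cbind(sample(sense, 200, replace = TRUE),
                 sample(sense, 200, replace = TRUE))
  for (k in seq_len(nrow(pairs))) {
    o <- oracle_ng_diffs(pairs[k, 1], pairs[k, 2])
    expect_equal(unname(tb$sd[pairs[k, 1], pairs[k, 2]]), unname(o["s"]),
                 tolerance = 1e-12)
    expect_equal(unname(tb$nd[pairs[k, 1], pairs[k, 2]]), unname(o["n"]),
                 tolerance = 1e-12)
  }
})

test_that("dN/dS handles the canonical boundary cases", {
  base <- strrep("ATGGCTAAATTACGTGAT", 5)
  # identical sequences: d_n = d_s = 0, ratio undefined
  r0 <- nei_gojobori_dn_ds(seq_alignment(c(i = base, o = base)), "o")
  expect_equal(r0$d_n, 0)
  expect_equal(r0$d_s, 0)
  expect_true(is.na(r0$ratio))

  # a single synonymous change in a long gene: d_n = 0, ratio = 0
  synvar <- sub("GCT", "GCC", base)
  r1 <- nei_gojobori_dn_ds(seq_alignment(c(i = base, o = synvar)), "o")
  expect_equal(r1$d_n, 0)
  expect_gt(r1$d_s, 0)
  expect_equal(r1$ratio, 0)

  # gapped codons are skipped
  gapped <- sub("GAT$", "GA-", base)
  r2 <- nei_gojobori_dn_ds(seq_alignment(c(i = gapped, o = synvar)), "o")
  expect_equal(r2$codons, nchar(base) / 3 - 1)

  # averaged and consensus modes agree for a single ingroup haplotype
  r3 <- nei_gojobori_dn_ds(seq_alignment(c(i = base, o = synvar)), "o",
                           mode = "consensus")
  expect_equal(r3$d_s, r1$d_s, tolerance = 1e-12)
})

test_that("relative rate test counts unique differences and is symmetric", {
  # construct m_A = 15, m_B = 5 over 100 bp
  a <- rep("A", 100); b <- rep("A", 100); o <- rep("A", 100)
  a[1:15] <- "T"              # A differs, B = O
  b[21:25] <- "G"             # B differs, A = O
  rr <- relative_rate_test(paste(a, collapse = ""), paste(b, collapse = ""),
                           paste(o, collapse = ""))
  expect_equal(rr$m_a, 15)
  expect_equal(rr$m_b, 5)
  expect_equal(rr$chi2, 5.0)
  expect_true(abs(rr$p_value - 0.02535) < 1e-4)

  rr_sym <- relative_rate_test(paste(b, collapse = ""),
                               paste(a, collapse = ""),
                               paste(o, collapse = ""))
  expect_equal(rr_sym$chi2, rr$chi2)
  expect_equal(rr_sym$p_value, rr$p_value)

  # equal counts: chi2 = 0, p = 1
  b2 <- rep("A", 100); b2[1:15] <- "C"
  a2 <- rep("A", 100); a2[16:30] <- "T"
  rr_eq <- relative_rate_test(paste(a2, collapse = ""),
                              paste(b2, collapse = ""),
                              paste(o, collapse = ""))
  expect_equal(rr_eq$chi2, 0)
  expect_equal(rr_eq$p_value, 1)

  # no informative sites -> flagged NA
  rr_na <- relative_rate_test(strrep("A", 50), strrep("A", 50), strrep("A", 50))
  expect_true(is.na(rr_na$chi2))
  expect_true(is.na(rr_na$p_value))
})

test_that("K scale factor satisfies its closed forms", {
  nwk <- "((a:1,b:2):0.5,(c:1.5,d:1):0.7,e:2);"
  tr <- ape::read.tree(text = nwk)

  expect_equal(k_score(tr, tr)$K, 1, tolerance = 1e-12)

  doubled <- tr
  doubled$edge.length <- tr$edge.length * 2
  expect_equal(k_score(tr, doubled)$K, 0.5, tolerance = 1e-12)

  set.seed(5)
  for (cval in c(0.3, 2, 7.5)) {
    rt <- ape::rtree(5)
    scaled <- rt
    scaled$edge.length <- rt$edge.length / cval
    expect_equal(k_score(rt, scaled)$K, cval, tolerance = 1e-9)
  }

  # topology mismatch is rejected with the offending bipartitions listed
  other <- ape::read.tree(text = "((a:1,c:2):0.5,(b:1.5,d:1):0.7,e:2);")
  expect_error(k_score(tr, other), "unmatched bipartitions")
  # different leaf sets rejected
  other2 <- ape::read.tree(text = "((a:1,b:2):0.5,(c:1.5,f:1):0.7,e:2);")
  expect_error(k_score(tr, other2), "leaf sets")
})
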