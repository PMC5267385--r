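test_that("demographic models validate their epochs", {
  m <- bottleneck_model()
  expect_equal(attr(m, "severity_k"), 2.45, tolerance = 1e-12)
  expect_equal(nrow(m$epochs), 3)
  expect_error(demographic_model(data.frame(time = c(0, 0.1, 0.05),
                                            size = c(1, 1, 1))),
               "strictly increasing")
  expect_error(demographic_model(data.frame(time = 0, size = 0)), "> 0")
  expect_error(demographic_model(data.frame(time = 0.1, size = 1)), "time 0")
})

test_that("single replicates honor the infinite-sites contract", {
  cfg <- sim_config(8, 4, seed = 1)
  set.seed(2)
  hm <- simulate_replicate(cfg)
  expect_s3_class(hm, "haplotype_matrix")
  if (ncol(hm$mat) > 1) {
    expect_true(all(diff(hm$positions) > 0))
    expect_true(all(hm$positions > 0 & hm$positions < 1))
  }
  d <- colSums(hm$mat)
  expect_true(all(d >= 1 & d <= 7))

  # theta -> 0 limit: no polymorphism
  set.seed(3)
  hm0 <- simulate_replicate(sim_config(8, 1e-9, seed = 1))
  expect_equal(ncol(hm0$mat), 0)

  # determinism of the R engine
  set.seed(11); a <- simulate_replicate(cfg)
  set.seed(11); b <- simulate_replicate(cfg)
  expect_identical(a$mat, b$mat)
  expect_identical(a$positions, b$positions)
})

test_that("null distributions are reproducible and mean-centered", {
  cfg <- sim_config(12, 4, reps = 4000, seed = 19)
  n1 <- simulate_null(cfg)
  n2 <- simulate_null(cfg)
  expect_identical(n1$tajima_d$values, n2$tajima_d$values)
  expect_identical(n1$fu_li_f$values, n2$fu_li_f$values)
  expect_equal(length(n1$tajima_d$values) + n1$tajima_d$n_na, cfg$reps)
  # loose neutral centering at modest replicate count (the strict check
  # runs at full size in the acceptance suite)
  expect_lt(abs(mean(n1$tajima_d$values)), 0.2)

  # reps = 1 yields a distribution of length <= 1
  tiny <- simulate_null(sim_config(12, 4, reps = 1, seed = 3))
  expect_lte(length(tiny$tajima_d$values), 1)
})

test_that("R and C++ simulation paths agree distributionally", {
  cfg <- sim_config(9, 5, reps = 3000, seed = 23)
  cpp_S <- simulate_null(cfg, statistics = "S")$S$values
  set.seed(23)
  r_S <- replicate(3000, ncol(simulate_replicate(cfg)$mat))
  set.seed(1)
  kt <- stats::ks.test(cpp_S + runif(length(cpp_S), -0.5, 0.5),
                       r_S + runif(length(r_S), -0.5, 0.5))
  expect_gt(kt$p.value, 0.01)
})

test_that("segregating-site distribution matches an independent coalescent
          implementation", {
  # cross-oracle: msprime with matching haploid time scale
  script <- c(
    "import msprime",
    "vals = []",
    "for i, ts in enumerate(msprime.sim_ancestry(samples=10, ploidy=1,",
    "        sequence_length=1, population_size=0.5,",
    "        num_replicates=10000, random_seed=1234)):",
    "    mts = msprime.sim_mutations(ts, rate=5.0, discrete_genome=False,",
    "                                random_seed=1235 + i)",
    "    vals.append(mts.num_sites)",
    "print('\\n'.join(str(v) for v in vals))")
  tf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, tf)
  ms_S <- suppressWarnings(as.integer(system2("python", tf, stdout = TRUE)))
  skip_if(length(ms_S) != 10000 || anyNA(ms_S),
          "reference coalescent implementation unavailable")
  ours <- simulate_null(sim_config(10, 5, reps = 10000, seed = 31),
                        statistics = "S")$S$values
  set.seed(1)
  kt <- stats::ks.test(ms_S + runif(length(ms_S), -0.5, 0.5),
                       ours + runif(length(ours), -0.5, 0.5))
  expect_gt(kt$p.value, 0.01)
})

test_that("a severe bottleneck reshapes the Tajima's D null", {
  const <- simulate_null(sim_config(25, 5, reps = 10000, seed = 41),
                         constant_size_model(), "tajima_d")$tajima_d$values
  bott <- simulate_null(sim_config(25, 5, reps = 10000, seed = 42),
                        bottleneck_model(t_d = 0.01, t_b = 0.0204,
                                         x_b = 0.05),
                        "tajima_d")$tajima_d$values
  kt <- suppressWarnings(stats::ks.test(const, bott))
  expect_lt(kt$p.value, 0.01)
})

test_that("fixed-S conditioning yields exactly S sites per replicate", {
  tab <- simulate_stats_table(sim_config(10, 5, reps = 500, seed = 13,
                                         fixed_s = 7))
  expect_true(all(tab$S == 7))
  # frequency spectrum still neutral-centered under conditioning
  expect_lt(abs(mean(tab$tajima_d)), 0.25)
})

test_that("significance calls follow the two-tailed 2.5/5/95/97.5 bands", {
  expect_identical(significance_call(c(1, 3, 50, 96, 99, NA)),
                   c("significant_low", "marginal_low", "ns",
                     "marginal_high", "significant_high", NA))
})

test_that("percentile placement follows the mid-rank counting rule", {
  d <- c(-2, -1, 0, 1, 2)
  expect_equal(percentile_of(-3, d), 0)
  expect_equal(percentile_of(0, d), 50)          # median of odd length
  expect_equal(percentile_of(-1.75, d), 20)      # 1 below, none equal
  expect_equal(percentile_of(3, d), 100)
  expect_equal(percentile_of(-2, d), 10)         # ties get half weight
  expect_error(percentile_of(0, numeric()), "empty")
})

test_that("critical values are empirical two-sided quantiles", {
  set.seed(8)
  v <- rnorm(10000)
  cv <- critical_values(v, alpha = 0.05)
  expect_equal(unname(cv["lower"]),
               quantile(v, 0.025, type = 7, names = FALSE))
  expect_equal(unname(cv["upper"]),
               quantile(v, 0.975, type = 7, names = FALSE))
  # symmetric distribution: lower ~ -upper
  expect_equal(unname(cv["lower"]), -unname(cv["upper"]), tolerance = 0.1)
  # degenerate alpha = 1 flagged
  cv1 <- critical_values(v, alpha = 1)
  expect_true(isTRUE(attr(cv1, "degenerate")))
  expect_equal(as.numeric(cv1), range(v))
  expect_error(critical_values(v[1:10]), "too small")
})
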