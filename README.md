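# popgenscan

Per-locus molecular population genetics for candidate-gene resequencing
panels: diversity and divergence estimators, outgroup-polarized neutrality
tests, population differentiation, and coalescent-simulation null
distributions that turn raw test statistics into percentile-based
significance calls.

The package targets the study design used to ask how domestication and
subsequent breeding shaped the molecular evolution of specific gene
families (for example, meiotic recombination genes in maize): per-gene
alignments of a few dozen ingroup haplotypes — often split into tropical
and temperate germplasm — plus a sample of the wild sister subspecies and
one distant outgroup, with each gene annotated into coding, intron and 5′
regions.

## What it computes

For each gene and population subset:

- **Diversity** (coding, intron, 5′): Nei–Li π (with two SE options),
  Watterson's θ_W, Nei–Gojobori π_a and π_s with their ratio, and
  polymorphic amino-acid residues per 100 residues.
- **Neutrality tests**: Tajima's D (unpolarized), Fu & Li's D and F (the
  outgroup versions, on alleles polarized against a per-locus outgroup),
  with flagged `NA` for monomorphic loci.
- **Significance machinery**: each statistic is placed, by mid-rank
  percentile, in a null distribution from a built-in infinite-sites
  coalescent simulator (Hudson `ms` conventions; piecewise-constant
  demography including a domestication-bottleneck model with severity
  k = x_b/t_b = 2.45 at the defaults), and Tajima's D optionally in a
  genome-wide empirical distribution; percentiles ≤ 2.5 or ≥ 97.5 are
  two-tailed significant at P < 0.05, 5/95 marginal.
- **Differentiation**: Hudson–Slatkin–Maddison F_ST = 1 − Hw/Hb between
  the two demes.
- **Divergence**: Nei–Gojobori dN/dS against the outgroup (Jukes–Cantor
  corrected), Tajima's 1D relative-rate χ² test, and the least-squares K
  scale factor comparing overall phylogenetic tree sizes.

A synthetic-data module generates complete maize/teosinte-like multi-gene
datasets (FASTA + population map + BED + truth tables), with optional
sweep-like or balancing-like distortions of the site frequency spectrum,
so the entire pipeline is testable end to end without any downloads.

## Worked example

Generate a 3-gene synthetic panel (31 ingroup haplotypes in two demes,
9 sister-subspecies haplotypes, 1 outgroup) and scan it with
10,000-replicate nulls per gene:

```r
library(popgenscan)

cfg <- synthetic_config(genes = 3, seed = 42)
generate_dataset(cfg, "data")
res <- scan_synthetic_dataset("data", "results", null_reps = 10000, seed = 7)

res$table1[res$table1$region == "coding",
           c("gene","n","L_eff","S","pi","theta_w","pi_a_over_pi_s","dn_ds")]
#>     gene  n L_eff  S       pi  theta_w pi_a_over_pi_s  dn_ds
#>  gene001 31  1200 32 0.008039 0.006675         0.2277 0.2119
#>  gene002 31  1200 18 0.002978 0.003755         0.2090 0.1669
#>  gene003 31  1200 19 0.004430 0.003963         0.6157 0.3201
```

Coding-region diversity sits in the expected per-site range (~0.003–0.008
here), π_a/π_s well below 1 and dN/dS ≈ 0.2–0.3 reflect purifying
selection on the simulated coding regions.

```r
res$table2[, c("gene","S","tajima_d","fu_li_d","fu_li_f",
               "tajima_d_pct_sim","tajima_d_call")]
#>     gene  S tajima_d fu_li_d fu_li_f tajima_d_pct_sim tajima_d_call
#>  gene001 32   0.7378  0.7472  0.9041            60.83            ns
#>  gene002 18  -0.7075  0.5891  0.1789            31.28            ns
#>  gene003 19   0.4056  0.2839  0.3929            53.57            ns
```

These neutral genes land mid-distribution (percentiles 31–61, all calls
`ns`). A gene generated with `distortion = "sweep_like"` drops to the
bottom 2.5% of its null; `balancing_like` rises past the 97.5th
percentile.

```r
res$fst[, c("gene","fst","h_w","h_b")]
#>     gene      fst   h_w   h_b
#>  gene001 -0.03613 9.856 9.513
#>  gene002  0.13412 3.103 3.584
#>  gene003 -0.03511 5.445 5.261
```

With the recent default deme split (0.01 × 4N₀ generations), F_ST
hovers near zero — negative estimates are reported as computed, the
estimator's honest signal of "no differentiation".

Single statistics are available directly, e.g. the worked 4-haplotype,
3-site polarized matrix:

```r
hm <- haplotype_matrix(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(1,1,1)))
tajimas_d(hm)              #> 0.1677
fu_li_d(hm)$statistic      #> 0.6441
```

Command-line wrappers over the same functions live in `inst/cli/`
(`simulate-data.R`, `scan.R`, `coalsim.R`, `percentile.R`).

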