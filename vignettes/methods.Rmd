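---
title: "Methods: diversity, neutrality tests and coalescent nulls in popgenscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, neutrality tests and coalescent nulls in popgenscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenscan)
```

# Scope and data model

`popgenscan` analyzes per-gene multiple-sequence alignments from
resequencing panels of the kind used to study molecular evolution of
candidate genes in domesticated crops and their wild relatives: a few
dozen ingroup haplotypes (possibly structured into subpopulations such as
tropical and temperate germplasm), a sample from a sister subspecies, and
a single distant outgroup used to orient ancestral versus derived alleles.

Three containers carry the data. A `seq_alignment` holds equal-length
uppercase DNA sequences over `{A, C, G, T, N, -}`; a `pop_map` assigns
samples to populations, with the label `"outgroup"` reserved; a
`region_annotation` classifies alignment intervals as `coding`, `intron`
or `five_prime` in BED-style 0-based half-open coordinates (converted to
R's 1-based columns at the boundary). All analyses assume pre-oriented
(forward-strand) alignments; alignment itself is out of scope.

Missing data are handled by **complete deletion** throughout: every column
carrying `-` or `N` in the sample set under analysis is excluded, and the
number of surviving columns is the effective length $L$ used for per-site
scaling. This is the most reproducible convention for effective-length
accounting; pairwise-deletion alternatives change $L$ per pair and make
per-site quantities harder to compare across statistics.

# Diversity estimators

Nucleotide diversity is the Nei–Li estimator
$$\pi = \frac{1}{L\binom{n}{2}} \sum_{i<j} d_{ij},$$
with $d_{ij}$ the count of mismatching complete-deletion columns between
haplotypes $i$ and $j$; mismatches at columns with three or more alleles
all count. Watterson's estimator is $\theta_W = S/(a_1 L)$ with
$a_1 = \sum_{i=1}^{n-1} 1/i$.

Two standard errors for $\pi$ are offered because published tables rarely
state which variance their "±SE" comes from. The default is the
no-recombination total variance
$$V(\pi) = \frac{n+1}{3(n-1)L}\,\pi + \frac{2(n^2+n+3)}{9n(n-1)}\,\pi^2,$$
which includes the evolutionary (coalescent) variance; the `"sampling"`
option is the empirical standard error of the per-column mean pairwise
difference across columns, which reflects only sampling over sites.
Neither option is privileged; they answer different questions.

# Synonymous and nonsynonymous sites: the codon engine

Both $\pi_a/\pi_s$ (within-sample) and $d_N/d_S$ (against the outgroup)
use the same Nei–Gojobori machinery:

* **Sites.** For each codon, each of the nine single-base changes is
  classified; the synonymous site count is the summed fraction of
  synonymous changes per position. Changes that create a stop codon are
  counted as nonsynonymous rather than discarded, so synonymous plus
  nonsynonymous sites equal exactly 3 per codon and site totals are
  conserved. (Published variants of the method differ on this point;
  discarding stop mutations shrinks the denominator by a few percent at
  most.)
* **Differences.** Codon pairs differing at 2 or 3 positions are scored by
  averaging over all orderings of the single steps; pathways passing
  through an intermediate stop codon are excluded unless every pathway
  does. All 64×64 site and difference tables are computed once by
  exhaustive enumeration and cached.
* **Deletion.** For $\pi_a/\pi_s$, codon columns containing a gap, `N` or
  a stop codon in any analyzed sample are excluded (codon-level complete
  deletion). For pairwise $d_N/d_S$, codons are skipped per pair.

$\pi_a$ and $\pi_s$ divide mean pairwise differences by mean sites with no
distance correction by default — within-species diversity is far too small
for multiple hits to matter — with Jukes–Cantor correction available.
$d_N/d_S$ always applies Jukes–Cantor, $d = -\tfrac{3}{4}\log(1-4p/3)$,
and refuses $p \ge 3/4$ where the correction is undefined. When all
pairwise differences are synonymous the ratio is 0; when $d_S = 0$ (or
$\pi_s = 0$) the ratio is undefined and reported as `NA` — a situation
that genuinely occurs in low-diversity genes where every observed
substitution is nonsynonymous.

Because panels rarely state whether a consensus or per-haplotype
comparison produced a published $d_N/d_S$, both are implemented: the
default compares each ingroup haplotype to the outgroup and averages
$d_N$ and $d_S$ before taking the ratio; `mode = "consensus"` uses a
majority-rule consensus (ties broken alphabetically, for determinism).

# Outgroup polarization

Fu & Li's tests need to know which allele is derived. `polarize()` keeps,
after complete deletion over ingroup plus outgroup, exactly the biallelic
ingroup sites at which the outgroup carries one of the two segregating
alleles; that allele is coded ancestral. Sites where the outgroup shows a
third state are *unpolarizable*; ingroup sites with three or more alleles
violate the infinite-sites coding and are excluded. Both counts are
reported as diagnostics, and the bookkeeping identity
(sites emitted + monomorphic + unpolarizable + triallelic = analyzed
columns) is enforced by tests. The outgroup is chosen per locus — panels
sometimes must switch to a more distant relative for an individual gene
when no sequence from the preferred outgroup can be obtained.

# Neutrality tests

With $S$ segregating sites, $\hat\pi$ the mean pairwise difference count,
$\eta$ the number of mutations ($= S$ under infinite sites; polarization
excludes multi-allelic sites, so the two coincide on real alignments too)
and $\eta_e$ the derived singletons:

* Tajima's $D = (\hat\pi - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ — computed
  from unpolarized data; no outgroup needed.
* Fu & Li's $D = (\eta - a_1\eta_e)/\sqrt{u_D\eta + v_D\eta^2}$ and
  $F = (\hat\pi - \eta_e)/\sqrt{u_F\eta + v_F\eta^2}$ — the outgroup
  ("original") versions, since polarized data are available; the $F$
  constants follow the corrected published formulas
  ($v_F = [c_n + b_2 - 2/(n-1)]/(a_1^2+a_2)$ and
  $u_F = [1 + b_1 - 4\frac{n+1}{(n-1)^2}(a_{n+1} - \frac{2n}{n+1})]/a_1 - v_F$).
  Correctness is pinned down two ways: a hand evaluation on a 4-haplotype,
  3-site worked matrix frozen into the tests, and the requirement that all
  three statistics average near zero over 10,000 neutral coalescent
  replicates.

Monomorphic loci make all three statistics undefined; they propagate as
`NA` (rendered as the string `NA` in output tables) rather than crashing a
scan. Constants require $n \ge 4$ for stability of $c_n$.

# Population differentiation

$F_{ST}$ uses the Hudson–Slatkin–Maddison form $1 - H_w/H_b$, where $H_w$
is the unweighted mean of the two within-population mean pairwise
difference counts and $H_b$ the mean over all between-population pairs,
on complete-deletion columns of the union. Fixed differences with no
within-deme variation give exactly 1. Estimates can be negative when
differentiation is near zero — notably, two demes with literally identical
haplotype contents estimate below zero, because $H_b$ pairs each haplotype
with its own copy while $H_w$ does not; the exact-zero case is realized by
configurations with $H_w = H_b$ (e.g. mutually equidistant haplotypes
split arbitrarily). Negative values are reported as computed, never
clipped, so near-zero differentiation is visible as such.
Weir–Cockerham and hierarchical F-statistics are out of scope.

# Divergence rate comparisons

The relative-rate test compares two lineages A and B against an outgroup
by counting sites where exactly one lineage differs while the other
matches the outgroup; under rate equality
$\chi^2 = (m_A - m_B)^2/(m_A + m_B)$ with 1 df. Zero informative sites
yield a flagged `NA`.

The K scale factor compares the overall sizes of two phylogenies with
identical leaf sets and unrooted topology: branches are matched by leaf
bipartition and $K = \sum l_{ref} l_{comp} / \sum l_{comp}^2$, the least
squares minimizer of $\sum(l_{ref} - K l_{comp})^2$. Doubling all branch
lengths of the comparison tree halves $K$; smaller $K$ means a larger
(more diverged) comparison tree. Topology mismatches are an error listing
the unmatched bipartitions — restricting to identical topologies avoids
confounding size with topology, and only the scale factor (not partition
metrics) is implemented.

# The coalescent null

Significance of the neutrality statistics is assessed against null
distributions from a built-in Kingman coalescent with infinite-sites
mutation, written to match Hudson's `ms` conventions so published
demographies port directly: time in units of $4N_0$ generations, $k$
lineages coalescing at rate $k(k-1)/x(t)$ under piecewise-constant
relative size $x(t)$, and $\theta = 4N_0\mu$ per locus, giving
$E[S] = \theta a_1$, $E[\hat\pi] = \theta$ and
$E[T_{MRCA}] = 1 - 1/n$. Mutations are Poisson with mean $\theta$ times
total branch length, placed on branches proportionally to length
(fixed-$\theta$ mode, the default; conditioning on a fixed $S$ is
available via `sim_config(fixed_s = )`). Replicates use the simulator's
known ancestral states, i.e. perfect polarization. Intra-locus
recombination is deliberately absent — the conservative assumption for
these tests — as are migration and selection.

The domestication bottleneck is parameterized as three epochs: present
size 1 back to onset $t_d$, bottleneck size $x_b$ for duration $t_b$, then
ancestral size $x_a$. The bottleneck severity $k = x_b/t_b$ — the ratio of
bottleneck population size to duration — is 2.45 at the defaults
($x_b = 0.05$, $t_b = 0.05/2.45$, $t_d = 0.01$, $x_a = 1$), the severity
proposed for the maize domestication bottleneck. Only the severity ratio
is published for that bottleneck; the individual defaults are therefore
illustrative, and locus-specific percentiles from any particular
published table are not expected to be reproducible without the original
per-locus $\theta$ and absolute bottleneck calibration.

Per-locus $\theta$ for a null is taken from the scan configuration when
given, and otherwise estimated as Watterson's $\theta$ (per locus) from
the wild-ancestor population in the panel (`theta_from`, default
`"parviglumis"`), mirroring the practice of calibrating the mutation
parameter on the less-bottlenecked taxon; it falls back to the analyzed
subset when no such population is present.

Percentiles use the mid-rank convention,
$100\,(\#\{v < x\} + \tfrac12\#\{v = x\})/|v|$, which is symmetric and
well defined under ties; published analyses of this kind never state a tie
rule, and with 10,000-replicate nulls the choice moves percentiles by at
most a hundredth. Two-tailed calls flag percentiles at or beyond
2.5/97.5 as significant ($P < 0.05$) and 5/95 as marginal ($P < 0.10$).
Critical values are empirical type-7 quantiles and require at least 40
values; `alpha = 1` degenerates to the range and is flagged.

The implementation is validated three ways: closed-form expectations
($E[S]$, $E[\hat\pi]$, $E[T_{MRCA}]$ within 2% at 50,000 replicates),
near-zero means of all three test statistics under neutrality, and a
distributional cross-check of $S$ against an independent coalescent
implementation (msprime) by Kolmogorov–Smirnov test on tie-broken values.
The simulation core is C++ (via Rcpp) driven by R's RNG, so a single
`set.seed()`/`seed` argument makes every run bit-reproducible; a pure-R
genealogy engine with labeled populations backs single-replicate
simulation and the data generator, and the two paths are checked against
each other distributionally.

# The synthetic data generator

`generate_dataset()` produces complete, analyzable gene datasets so the
whole pipeline can be exercised without any external data. Defaults are
fixed once to emulate a maize-style diversity panel: 14 + 17 ingroup
haplotypes in two demes (temperate/tropical analog) splitting cleanly at
0.01 (in $4N_0$ units; recent enough to give the weak differentiation
typical of such panels), 9 haplotypes from a sister subspecies merging at
0.08, and one outgroup lineage joining at 0.5 with 1.5 time units of
extra private divergence so that most sites polarize (total outgroup
divergence around 0.75% per site); genes carry 240 bp of 5' sequence,
1.5 kb of intron and 1.2 kb of in-frame coding sequence, with
$\theta = 0.003$ per site, the middle of the per-gene diversity range
such panels report (roughly 0.001–0.007).

Rendering maps each infinite-sites mutation to a distinct alignment
column: coding-region mutations land on third codon positions with
probability 0.7 (yielding realistic $\pi_a/\pi_s < 1$), ancestral coding
codons avoid stops and derived bases avoid creating them where possible
(so translations are clean), and every derived base differs from the
ancestral one. The truth table records $\theta$, demography, distortion
and realized per-region site counts, whose sum equals the matrix site
count by construction.

Selection footprints are emulated by resampling site frequencies:
`sweep_like` pushes a fraction `strength` of ingroup sites to derived
singletons (excess rare variants, $D < 0$), `balancing_like` to
$\lfloor n/2 \rfloor$ carriers (excess intermediate frequencies,
$D > 0$), preserving the site count. This is deliberately a
frequency-spectrum operation, explicit and auditable; it does **not**
model linkage around a sweep, background selection, indels, codon-level
substitution processes, or migration between the demes (the split is
clean). Passing tests on these data therefore demonstrate that the
estimators and the significance machinery behave correctly on data
satisfying their assumptions — not that real maize alignments satisfy
those assumptions.

# Scan orchestration

`run_scan()` iterates a gene table (FASTA + BED + per-locus outgroup id,
optional per-locus $\theta$), computing per-region diversity summaries,
neutrality statistics with percentiles for the full two-deme panel and
for each deme separately (each against its own gene- and subset-specific
null, since $n$ and $\theta$ differ per locus), $F_{ST}$ between the
demes, and $d_N/d_S$ against the outgroup. Populations outside the two
demes (the wild-ancestor sample) are not pooled into the analysis panel;
they inform the null's $\theta$ and can be scanned as their own panel.
Every random draw derives from the master seed (gene $i$, subset $j$ uses
`seed + 1000 i + j`), the run log records each null's exact seed so any
percentile can be replayed, and the log carries no timestamps — reruns
with the same seed are byte-identical, which the test suite asserts.
Monomorphic genes yield `NA` rows rather than failures.

# Problem sizes and numerical choices

The test suite and the acceptance script size their simulations as
follows, chosen to keep Monte-Carlo error comfortably inside the asserted
tolerances: 50,000 replicates for the analytic-expectation checks (2%),
10,000 for neutral centering (|mean| ≤ 0.15) and for each null
distribution backing percentile calls, 200 genes for the
parameter-recovery check (5%), and 100 trials per arm for the
sweep/balancing detection check (≥ 70% required; observed rates are at or
near 100%). Degenerate inputs are errors with specific messages (empty
distributions, populations under 2 haplotypes, zero analyzable codons,
$p \ge 3/4$ under Jukes–Cantor) except where a flagged `NA` is the
documented behavior (monomorphic loci, $H_b = 0$, $d_S = 0$,
$m_A + m_B = 0$).

# Known limitations

Beyond the explicit non-goals above: the Fu & Li statistics assume the
polarized site set is unbiased, but unpolarizable and triallelic sites
are simply excluded (and counted), which is conservative when such sites
are rare; $\theta$ estimation from a small wild-ancestor sample is noisy
and propagates into percentile placement; the no-recombination assumption
makes the nulls conservative for loci with substantial intragenic
recombination; and the two-deme machinery does not extend to hierarchical
or many-population designs.
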