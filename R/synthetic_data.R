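## Synthetic maize/teosinte-like multi-gene datasets: coalescent haplotypes
## for a two-deme ingroup (temperate/tropical analog), a sister subspecies
## sample and one distant outgroup, rendered to nucleotide alignments with
## a 5'/intron/coding region layout, plus population map, BED annotation
## and a truth table. Everything is driven by one seed, so outputs are
## byte-identical across reruns.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate a diversity panel of 31 maize inbreds (14 temperate +
#' 17 tropical), nine accessions of a sister subspecies (Balsas-teosinte
#' analog) and one distant outgroup, with genes carrying up to 240 bp of
#' 5' sequence, intron fragments and an in-frame coding region, and
#' per-site diversity on the order of 0.003. Times are in 4N0 units.
#'
#' @param genes number of genes to generate.
#' @param n_temperate,n_tropical ingroup deme sample sizes.
#' @param n_sister sister-subspecies sample size.
#' @param five_prime_len,intron_len,coding_len region lengths in bp
#'   (coding must be a multiple of 3).
#' @param theta_site population mutation parameter per site (4 N0 mu).
#' @param split_time ingroup deme split time (clean split, no migration).
#' @param sister_time time the sister taxon merges with the ingroup.
#' @param outgroup_time time the outgroup lineage joins.
#' @param outgroup_extra extra private divergence time added to the
#'   outgroup branch (mutations Poisson with rate `theta_site * L * outgroup_extra`),
#'   guaranteeing polarizability at most sites.
#' @param p_syn probability that a coding mutation is placed at a third
#'   codon position (yields realistic pi_a/pi_s < 1).
#' @param distortion site-frequency-spectrum distortion applied to the
#'   ingroup: `"none"`, `"sweep_like"` or `"balancing_like"`.
#' @param strength distortion strength in `(0, 1]` (fraction of sites
#'   resampled); 0 disables distortion.
#' @param model [demographic_model] for the coalescent (default constant
#'   size).
#' @param seed integer master seed; gene `i` uses `seed + i`.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(genes = 1L,
                             n_temperate = 14L, n_tropical = 17L,
                             n_sister = 9L,
                             five_prime_len = 240L, intron_len = 1500L,
                             coding_len = 1200L,
                             theta_site = 0.003,
                             split_time = 0.01, sister_time = 0.08,
                             outgroup_time = 0.5, outgroup_extra = 1.5,
                             p_syn = 0.7,
                             distortion = c("none", "sweep_like",
                                            "balancing_like"),
                             strength = 0.8,
                             model = constant_size_model(),
                             seed = 1L) {
  distortion <- match.arg(distortion)
  if (coding_len %% 3L != 0L) stop("coding_len must be a multiple of 3")
  if (n_temperate + n_tropical < 4L) stop("ingroup must have >= 4 haplotypes")
  stopifnot(split_time >= 0, sister_time > split_time,
            outgroup_time > sister_time, theta_site > 0,
            p_syn >= 0, p_syn <= 1, strength >= 0, strength <= 1)
  structure(list(genes = as.integer(genes),
                 n_temperate = as.integer(n_temperate),
                 n_tropical = as.integer(n_tropical),
                 n_sister = as.integer(n_sister),
                 five_prime_len = as.integer(five_prime_len),
                 intron_len = as.integer(intron_len),
                 coding_len = as.integer(coding_len),
                 theta_site = theta_site, split_time = split_time,
                 sister_time = sister_time, outgroup_time = outgroup_time,
                 outgroup_extra = outgroup_extra, p_syn = p_syn,
                 distortion = distortion, strength = strength,
                 model = model, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Distort the site frequency spectrum of a haplotype matrix
#'
#' Resamples a fraction `strength` of sites to emulate the footprints of
#' selection on the frequency spectrum: `sweep_like` sets the derived
#' allele of resampled sites to a single random carrier (excess rare
#' variants, Tajima's D < 0); `balancing_like` sets it to `floor(n/2)`
#' random carriers (excess intermediate frequencies, D > 0). The total
#' site count is preserved. This operates on frequencies only; it does not
#' model linkage around a sweep.
#'
#' @param hm a [haplotype_matrix].
#' @param mode `"sweep_like"` or `"balancing_like"`.
#' @param strength fraction of sites resampled, in `(0, 1]`; 0 returns the
#'   input unchanged.
#' @param rows optional row indices to restrict the distortion to (e.g.
#'   ingroup haplotypes); derived counts are then relative to those rows.
#' @return A [haplotype_matrix] of the same dimensions.
#' @export
distort_sfs <- function(hm, mode = c("sweep_like", "balancing_like"),
                        strength = 0.8, rows = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(hm, "haplotype_matrix"), strength >= 0, strength <= 1)
  if (strength == 0 || ncol(hm$mat) == 0L) return(hm)
  mat <- hm$mat
  if (is.null(rows)) rows <- seq_len(nrow(mat))
  nr <- length(rows)
  S <- ncol(mat)
  pick <- sort(sample.int(S, round(strength * S)))
  target <- if (mode == "sweep_like") 1L else max(1L, nr %/% 2L)
  for (s in pick) {
    carriers <- rows[sample.int(nr, target)]
    mat[rows, s] <- 0L
    mat[carriers, s] <- 1L
  }
  seg <- colSums(mat) >= 1L & colSums(mat) <= nrow(mat) - 1L
  haplotype_matrix(mat[, seg, drop = FALSE],
                   positions = hm$positions[seg],
                   sample_ids = hm$sample_ids)
}

## region layout: five_prime | exon1 | intron | exon2 (frame offset 0)
synthetic_regions <- function(config) {
  fp <- config$five_prime_len
  ex1 <- (config$coding_len %/% 2L) - (config$coding_len %/% 2L) %% 3L
  ex2 <- config$coding_len - ex1
  intr <- config$intron_len
  region_annotation(
    start = c(0L, fp, fp + ex1, fp + ex1 + intr),
    end = c(fp, fp + ex1, fp + ex1 + intr, fp + ex1 + intr + ex2),
    klass = c("five_prime", "coding", "intron", "coding"),
    frame_offset = 0L)
}

## deterministic sample naming
synthetic_sample_ids <- function(config) {
  c(sprintf("temp%02d", seq_len(config$n_temperate)),
    sprintf("trop%02d", seq_len(config$n_tropical)),
    sprintf("parv%02d", seq_len(config$n_sister)),
    "outgroup1")
}

synthetic_popmap <- function(config) {
  ids <- synthetic_sample_ids(config)
  pop_map(ids, c(rep("temperate", config$n_temperate),
                 rep("tropical", config$n_tropical),
                 rep("parviglumis", config$n_sister),
                 "outgroup"))
}

#' Generate one synthetic gene dataset
#'
#' Simulates a genealogy for the two ingroup demes (clean split at
#' `split_time`), the sister taxon (merging at `sister_time`) and a single
#' outgroup lineage (joining at `outgroup_time`, with extra private
#' mutations on its branch), drops infinite-sites mutations, optionally
#' distorts the ingroup site frequency spectrum, and renders the result to
#' a nucleotide alignment over a random ancestral sequence. Each mutation
#' occupies a distinct alignment column; mutations falling in the coding
#' region are placed at third codon positions with probability `p_syn`.
#'
#' @param config a [synthetic_config].
#' @param gene_index 1-based gene index (drives the per-gene seed
#'   `config$seed + gene_index` and the gene name).
#' @param outdir optional directory; when given, writes `<gene>.fasta`,
#'   `<gene>.bed` and returns the paths.
#' @return List with `gene` (name), `aln` ([seq_alignment]), `regions`,
#'   `popmap`, `matrix` (the [haplotype_matrix] over all samples), `truth`
#'   (one-row data frame: theta, region site counts, distortion, seed) and,
#'   if `outdir` was given, `fasta`/`bed` paths.
#' @export
generate_gene_dataset <- function(config, gene_index = 1L, outdir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  gene <- sprintf("gene%03d", gene_index)
  set.seed(config$seed + gene_index)
  regions <- synthetic_regions(config)
  L <- max(regions$end)
  theta_locus <- config$theta_site * L
  ids <- synthetic_sample_ids(config)
  popmap <- synthetic_popmap(config)

  pops <- c(temperate = config$n_temperate, tropical = config$n_tropical,
            parviglumis = config$n_sister, outgroup = 1L)
  merges <- data.frame(
    time = c(config$split_time, config$sister_time, config$outgroup_time),
    from = c("tropical", "parviglumis", "outgroup"),
    to = c("temperate", "temperate", "temperate"),
    stringsAsFactors = FALSE)
  merges <- merges[merges$time > 0, , drop = FALSE]
  if (config$split_time == 0) {
    pops <- c(temperate = config$n_temperate + config$n_tropical,
              parviglumis = config$n_sister, outgroup = 1L)
    pops <- pops[pops > 0]
  }
  g <- sim_genealogy(pops, merges = merges, model = config$model)
  hm <- mutate_genealogy(g, theta_locus, sample_ids = ids)

  ## extra outgroup-private mutations emulating deeper species divergence
  S_extra <- rpois(1L, theta_locus * config$outgroup_extra)
  if (S_extra > 0L) {
    extra <- matrix(0L, nrow = length(ids), ncol = S_extra)
    extra[length(ids), ] <- 1L
    mat <- cbind(hm$mat, extra)
    pos <- c(hm$positions, sort(runif(S_extra)))
    o <- order(pos)
    hm <- haplotype_matrix(mat[, o, drop = FALSE], positions = pos[o],
                           sample_ids = ids)
  }

  if (config$distortion != "none" && config$strength > 0) {
    ing <- seq_len(config$n_temperate + config$n_tropical)
    hm <- distort_sfs(hm, config$distortion, config$strength, rows = ing)
  }

  rendered <- render_alignment(hm, regions, config$p_syn)
  aln <- seq_alignment(rendered$sequences, ids)

  klass_of <- rep(NA_character_, L)
  for (r in seq_len(nrow(regions))) {
    klass_of[(regions$start[r] + 1L):regions$end[r]] <- regions$klass[r]
  }
  site_klass <- klass_of[rendered$columns]
  truth <- data.frame(
    gene = gene, L = L, theta_site = config$theta_site,
    theta_locus = theta_locus, S_total = ncol(hm$mat),
    S_coding = sum(site_klass == "coding"),
    S_intron = sum(site_klass == "intron"),
    S_five_prime = sum(site_klass == "five_prime"),
    distortion = config$distortion,
    strength = if (config$distortion == "none") 0 else config$strength,
    split_time = config$split_time, seed = config$seed + gene_index)

  out <- list(gene = gene, aln = aln, regions = regions, popmap = popmap,
              matrix = hm, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    out$fasta <- file.path(outdir, paste0(gene, ".fasta"))
    out$bed <- file.path(outdir, paste0(gene, ".bed"))
    write_fasta(aln, out$fasta)
    write_region_bed(regions, out$bed, chrom = gene)
  }
  out
}

## Render a haplotype matrix to nucleotides: each segregating site gets a
## distinct alignment column (coding mutations at third codon positions
## with probability p_syn) and a random derived base; the backbone is a
## random ancestral sequence.
render_alignment <- function(hm, regions, p_syn) {
  L <- max(regions$end)
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  anc <- sample(bases, L, replace = TRUE)
  klass_of <- rep(NA_character_, L)
  for (r in seq_len(nrow(regions))) {
    klass_of[(regions$start[r] + 1L):regions$end[r]] <- regions$klass[r]
  }
  coding_cols <- which(klass_of == "coding")
  third_pos <- coding_cols[seq_along(coding_cols) %% 3L == 0L]
  noncoding_cols <- which(klass_of != "coding")

  ## coding frame must stay open: resample ancestral stop codons
  codon_starts <- seq(1L, length(coding_cols), by = 3L)
  for (cs in codon_starts) {
    cols3 <- coding_cols[cs:(cs + 2L)]
    while (paste(anc[cols3], collapse = "") %in% stops) {
      anc[cols3] <- sample(bases, 3L, replace = TRUE)
    }
  }

  S <- ncol(hm$mat)
  region_len <- c(coding = length(coding_cols),
                  noncoding = length(noncoding_cols))
  avail_third <- third_pos
  avail_coding <- setdiff(coding_cols, third_pos)
  avail_non <- noncoding_cols
  cols <- integer(S)
  for (s in seq_len(S)) {
    in_coding <- runif(1) < region_len["coding"] / L
    if (in_coding) {
      use_third <- runif(1) < p_syn && length(avail_third) > 0L
      if (use_third) {
        k <- sample.int(length(avail_third), 1L)
        cols[s] <- avail_third[k]; avail_third <- avail_third[-k]
      } else if (length(avail_coding) > 0L) {
        k <- sample.int(length(avail_coding), 1L)
        cols[s] <- avail_coding[k]; avail_coding <- avail_coding[-k]
      } else if (length(avail_third) > 0L) {
        k <- sample.int(length(avail_third), 1L)
        cols[s] <- avail_third[k]; avail_third <- avail_third[-k]
      } else {
        stop("column exhaustion in coding region: use a longer gene")
      }
    } else {
      if (length(avail_non) == 0L) {
        stop("column exhaustion in noncoding regions: use a longer gene")
      }
      k <- sample.int(length(avail_non), 1L)
      cols[s] <- avail_non[k]; avail_non <- avail_non[-k]
    }
  }

  ## derived base: uniform among the 3 alternatives, but in coding columns
  ## prefer alternatives that do not create a stop codon in the ancestral
  ## codon context
  codon_of <- match(cols, coding_cols)  # NA for noncoding
  n <- nrow(hm$mat)
  seqmat <- matrix(rep(anc, each = n), nrow = n)
  for (s in seq_len(S)) {
    alts <- setdiff(bases, anc[cols[s]])
    if (!is.na(codon_of[s])) {
      cs <- codon_of[s] - (codon_of[s] - 1L) %% 3L
      cols3 <- coding_cols[cs:(cs + 2L)]
      within <- match(cols[s], cols3)
      ok <- vapply(alts, function(b) {
        cod <- anc[cols3]; cod[within] <- b
        !(paste(cod, collapse = "") %in% stops)
      }, TRUE)
      if (any(ok)) alts <- alts[ok]
    }
    derived <- if (length(alts) == 1L) alts else sample(alts, 1L)
    seqmat[hm$mat[, s] == 1L, cols[s]] <- derived
  }
  list(sequences = apply(seqmat, 1L, paste, collapse = ""),
       columns = cols, ancestral = anc)
}

#' Generate a complete multi-gene synthetic dataset
#'
#' Writes, per gene, `<gene>.fasta` and `<gene>.bed`, plus a shared
#' `populations.tsv` and a `truth.tsv` with the generating parameters and
#' realized per-region site counts. Fully deterministic given
#' `config$seed`.
#'
#' @param config a [synthetic_config].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with `genes` (per-gene results from
#'   [generate_gene_dataset()]), `popmap_path`, `truth_path`.
#' @export
generate_dataset <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- lapply(seq_len(config$genes), function(i) {
    generate_gene_dataset(config, i, outdir = outdir)
  })
  popmap <- synthetic_popmap(config)
  popmap_path <- file.path(outdir, "populations.tsv")
  write.table(data.frame(sample_id = names(popmap$assignments),
                         population = unname(popmap$assignments)),
              popmap_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- do.call(rbind, lapply(res, `[[`, "truth"))
  truth_path <- file.path(outdir, "truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(genes = res, popmap_path = popmap_path,
                 truth_path = truth_path))
}
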