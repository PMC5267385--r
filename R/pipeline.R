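## Per-gene scan orchestration: iterate a gene list, compute per-region
## diversity, neutrality tests with simulated-null and empirical
## percentiles, F_ST between two demes, and dN/dS against the outgroup;
## emit summary tables and a replayable run log.

#' Build a scan configuration
#'
#' @param genes `data.frame` with one row per gene and columns `gene`,
#'   `fasta`, `bed`, `outgroup` (outgroup sample id for this locus; the
#'   outgroup choice is per locus because suitable outgroup sequence may
#'   differ between genes), and optionally `theta` (per-locus theta for the
#'   null; when `NA` it is estimated from the `theta_from` population) and
#'   `frame_offset` (default 0).
#' @param popmap path to a population-map TSV or a [pop_map].
#' @param demes character vector of exactly 2 population labels used for
#'   F_ST and the per-subpopulation analysis.
#' @param null_reps replicates per null distribution; 0 disables the
#'   simulated null. A warning is issued below 1000 (percentiles are then
#'   coarse).
#' @param null_model [demographic_model] for the null (default: the
#'   domestication-bottleneck model).
#' @param theta_from population label whose Watterson estimate supplies the
#'   per-locus theta when `genes$theta` is `NA` (default `"parviglumis"`,
#'   i.e. the wild-ancestor sample; falls back to the ingroup when that
#'   population is absent).
#' @param empirical optional path to a genome-wide empirical distribution
#'   of Tajima's D (one value per line).
#' @param seed master seed; gene `i`/analysis-subset `j` uses
#'   `seed + 1000 * i + j`.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(genes, popmap, demes = c("tropical", "temperate"),
                        null_reps = 10000L,
                        null_model = bottleneck_model(),
                        theta_from = "parviglumis",
                        empirical = NULL, seed = 1L) {
  need <- c("gene", "fasta", "bed", "outgroup")
  if (!is.data.frame(genes) || !all(need %in% names(genes))) {
    stop("genes must be a data.frame with columns: ",
         paste(need, collapse = ", "))
  }
  if (is.null(genes$theta)) genes$theta <- NA_real_
  if (is.null(genes$frame_offset)) genes$frame_offset <- 0L
  if (length(demes) != 2L) stop("demes must name exactly 2 populations")
  if (null_reps > 0L && null_reps < 1000L) {
    warning("null_reps < 1000: percentile calls will be coarse")
  }
  if (is.character(popmap)) popmap <- read_population_map(popmap)
  stopifnot(inherits(popmap, "pop_map"))
  structure(list(genes = genes, popmap = popmap, demes = demes,
                 null_reps = as.integer(null_reps), null_model = null_model,
                 theta_from = theta_from, empirical = empirical,
                 seed = as.integer(seed)),
            class = "scan_config")
}

## per-locus theta for the null: configured value, else Watterson estimate
## (per locus) from the reference population, else from the ingroup subset
null_theta <- function(aln, popmap, theta_from, samples, configured) {
  if (!is.na(configured)) return(configured)
  ref <- intersect(ingroup_ids(popmap, theta_from), aln$sample_ids)
  use <- if (length(ref) >= 2L) ref else samples
  tw <- tryCatch(watterson_theta(aln, use), error = function(e) NULL)
  if (is.null(tw)) return(NA_real_)
  as.numeric(tw) * attr(tw, "L_eff")
}

#' Run a per-gene scan
#'
#' For every gene: per-region diversity summaries (coding, intron,
#' five_prime where annotated), neutrality statistics for the full ingroup
#' and for each deme with percentiles against gene-specific simulated null
#' distributions (one null per gene and subset, since n and theta differ
#' per locus) and against the empirical distribution, F_ST between the two
#' demes, and Nei-Gojobori dN/dS against the gene's outgroup. Monomorphic
#' loci yield rows with `NA` statistics rather than errors. All outputs are
#' deterministic given `config$seed`; the run log records the exact null
#' seed per gene and subset so any percentile can be replayed.
#'
#' @param config a [scan_config].
#' @param outdir output directory; writes `table1.tsv` (diversity),
#'   `table2.tsv` (neutrality, full ingroup), `fst.tsv`, `per_subpop.tsv`
#'   (per-deme neutrality) and `run.log`.
#' @param keep_going continue past per-gene errors (default `FALSE`),
#'   recording them in the log.
#' @return Invisibly, a named list of the four tables.
#' @export
run_scan <- function(config, outdir, keep_going = FALSE) {
  stopifnot(inherits(config, "scan_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  popmap <- config$popmap
  empirical <- NULL
  if (!is.null(config$empirical)) {
    empirical <- scan(config$empirical, what = numeric(), quiet = TRUE)
  }
  log_lines <- c(
    paste0("popgenscan ", as.character(packageVersion("popgenscan"))),
    paste0("seed ", config$seed),
    paste0("null_reps ", config$null_reps),
    paste0("null_model epochs ",
           paste(sprintf("%g:%g", config$null_model$epochs$time,
                         config$null_model$epochs$size), collapse = " ")),
    paste0("demes ", paste(config$demes, collapse = ",")))

  tab1 <- tab2 <- fst_tab <- subpop <- list()
  for (i in seq_len(nrow(config$genes))) {
    grow <- config$genes[i, ]
    res <- tryCatch(
      scan_one_gene(grow, popmap, config, empirical, i),
      error = function(e) e)
    if (inherits(res, "error")) {
      msg <- paste0("ERROR gene ", grow$gene, ": ", conditionMessage(res))
      if (!keep_going) stop(msg)
      log_lines <- c(log_lines, msg)
      next
    }
    tab1[[i]] <- res$table1
    tab2[[i]] <- res$table2
    fst_tab[[i]] <- res$fst
    subpop[[i]] <- res$subpop
    log_lines <- c(log_lines, res$log)
  }
  out <- list(table1 = do.call(rbind, tab1), table2 = do.call(rbind, tab2),
              fst = do.call(rbind, fst_tab), per_subpop = do.call(rbind, subpop))
  for (nm in names(out)) {
    if (is.null(out[[nm]])) next
    write.table(out[[nm]],
                file.path(outdir, paste0(sub("per_subpop", "per_subpop", nm),
                                         ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(out)
}

scan_one_gene <- function(grow, popmap, config, empirical, gene_index) {
  gene <- grow$gene
  aln <- read_fasta(grow$fasta)
  regions <- read_region_bed(grow$bed, frame_offset = grow$frame_offset)
  outgroup_id <- grow$outgroup
  ## the analysis panel is the union of the two demes; other ingroup
  ## populations (e.g. the wild-ancestor sample used for theta) are not
  ## pooled with them
  ingroup <- intersect(
    unlist(lapply(config$demes, function(d) ingroup_ids(popmap, d))),
    aln$sample_ids)
  if (length(ingroup) < 2L) {
    ingroup <- intersect(ingroup_ids(popmap), aln$sample_ids)
  }
  coding <- slice_region(aln, regions, "coding")

  ## --- diversity per region class (full ingroup)
  t1 <- list()
  for (kl in intersect(unique(regions$klass), REGION_CLASSES)) {
    sub <- slice_region(aln, regions, kl)
    row <- diversity_summary(sub, ingroup, coding = (kl == "coding"))
    t1[[kl]] <- cbind(data.frame(gene = gene, region = kl), row)
  }
  table1 <- do.call(rbind, t1)
  rownames(table1) <- NULL

  ## dN/dS against the outgroup appended to the coding row
  dnds <- tryCatch(
    nei_gojobori_dn_ds(coding, outgroup_id, samples = ingroup),
    error = function(e) NULL)
  table1$dn_ds <- NA_real_
  if (!is.null(dnds)) {
    table1$dn_ds[table1$region == "coding"] <-
      if (is.na(dnds$ratio)) NA_real_ else dnds$ratio
  }

  ## --- neutrality: full ingroup + each deme; a fresh gene-specific null
  ## per subset because n and theta differ per locus and subset
  subsets <- c(list(all = ingroup),
               setNames(lapply(config$demes, function(d) {
                 intersect(ingroup_ids(popmap, d), aln$sample_ids)
               }), config$demes))
  log <- character()
  rows <- list()
  for (j in seq_along(subsets)) {
    sname <- names(subsets)[j]
    samples <- subsets[[j]]
    if (length(samples) < 4L) next
    nulls <- NULL
    seed_ij <- config$seed + 1000L * gene_index + j
    if (config$null_reps > 0L) {
      theta <- null_theta(aln, popmap, config$theta_from, samples, grow$theta)
      if (!is.na(theta) && theta > 0) {
        cfg <- sim_config(length(samples), theta, config$null_reps,
                          seed = seed_ij)
        nulls <- simulate_null(cfg, config$null_model)
        log <- c(log, sprintf("gene %s subset %s null: n=%d theta=%.6g seed=%d",
                              gene, sname, length(samples), theta, seed_ij))
      } else {
        log <- c(log, sprintf("gene %s subset %s null: skipped (theta unavailable)",
                              gene, sname))
      }
    }
    row <- neutrality_scan(coding, popmap, outgroup_id = outgroup_id,
                           samples = samples, null_dists = nulls,
                           empirical = if (sname == "all") empirical else NULL)
    rows[[sname]] <- cbind(data.frame(gene = gene, subset = sname), row)
  }
  allrows <- do.call(rbind, rows)
  rownames(allrows) <- NULL
  table2 <- allrows[allrows$subset == "all", , drop = FALSE]
  subpop <- allrows[allrows$subset != "all", , drop = FALSE]

  ## --- F_ST between the two demes (coding region)
  fst <- tryCatch(hudson_fst(coding, popmap, config$demes[1], config$demes[2]),
                  error = function(e) NULL)
  fst_row <- data.frame(gene = gene,
                        pop_a = config$demes[1], pop_b = config$demes[2],
                        fst = if (is.null(fst)) NA_real_ else fst$fst,
                        h_w = if (is.null(fst)) NA_real_ else fst$h_w,
                        h_b = if (is.null(fst)) NA_real_ else fst$h_b,
                        n1 = if (is.null(fst)) NA_integer_ else fst$n1,
                        n2 = if (is.null(fst)) NA_integer_ else fst$n2)

  list(table1 = table1, table2 = table2, subpop = subpop, fst = fst_row,
       log = c(sprintf("gene %s: n_ingroup=%d L=%d outgroup=%s",
                       gene, length(ingroup), aln$L, outgroup_id), log))
}

#' Scan a synthetic dataset directory
#'
#' Convenience wrapper: builds a [scan_config] for a directory produced by
#' [generate_dataset()] (per-gene FASTA/BED, shared `populations.tsv`) and
#' runs [run_scan()].
#'
#' @param datadir directory holding the synthetic dataset.
#' @param outdir output directory for the scan tables.
#' @param outgroup outgroup sample id (default `"outgroup1"`, the
#'   generator's naming).
#' @param ... passed to [scan_config()] (e.g. `null_reps`, `seed`).
#' @return Invisibly, the [run_scan()] result.
#' @export
scan_synthetic_dataset <- function(datadir, outdir, outgroup = "outgroup1",
                                   ...) {
  fastas <- sort(list.files(datadir, pattern = "\\.fasta$", full.names = TRUE))
  if (length(fastas) == 0L) stop("no .fasta files in ", datadir)
  genes <- data.frame(
    gene = sub("\\.fasta$", "", basename(fastas)),
    fasta = fastas,
    bed = sub("\\.fasta$", ".bed", fastas),
    outgroup = outgroup, stringsAsFactors = FALSE)
  cfg <- scan_config(genes, file.path(datadir, "populations.tsv"), ...)
  run_scan(cfg, outdir)
}
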