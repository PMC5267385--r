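## Alignment containers, standard-format I/O, masking, polarization and
## region slicing.
##
## Conventions used throughout the package:
##  - alignment columns are indexed 1-based inside R; BED input/output is
##    0-based half-open and converted at the boundary;
##  - sequences are uppercase DNA over {A, C, G, T, N, -}, forward strand;
##  - "complete deletion" drops every column carrying '-' or 'N' in the
##    sample set under analysis.

ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")
REGION_CLASSES <- c("coding", "intron", "five_prime")

#' Construct a sequence alignment
#'
#' An aligned set of equal-length uppercase DNA sequences with unique sample
#' identifiers. This is the central container consumed by all per-locus
#' statistics.
#'
#' @param sequences character vector of aligned sequences (equal length,
#'   alphabet `A,C,G,T,N,-`; lowercase is accepted and folded to uppercase).
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `names(sequences)`.
#' @return An object of class `seq_alignment` with elements `sample_ids`,
#'   `sequences` (named character vector) and `L` (alignment length in bp).
#' @export
seq_alignment <- function(sequences, sample_ids = names(sequences)) {
  if (is.null(sample_ids)) {
    sample_ids <- paste0("seq", seq_along(sequences))
  }
  sequences <- toupper(as.character(sequences))
  if (length(sequences) < 1L) {
    stop("alignment must contain at least one sequence")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("unequal lengths: aligned sequences must all have the same length")
  }
  if (lens[1] < 1L) stop("alignment length must be >= 1")
  bad <- grepl(sprintf("[^%s]", paste(ALN_ALPHABET, collapse = "")), sequences)
  if (any(bad)) {
    stop("illegal character in sequence(s): ",
         paste(sample_ids[bad], collapse = ", "),
         " (allowed: A, C, G, T, N, -)")
  }
  names(sequences) <- sample_ids
  structure(list(sample_ids = sample_ids, sequences = sequences,
                 L = unname(lens[1])),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("seq_alignment:", length(x$sample_ids), "sequences,", x$L, "bp\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Reads a multiple-sequence alignment in FASTA format. Record order is
#' preserved, lowercase is folded to uppercase, and characters outside the
#' alignment alphabet (e.g. RNA `U` or IUPAC ambiguity codes) are rejected.
#'
#' @param path path to a FASTA file with at least two records.
#' @return A [seq_alignment]. Sample ids are the first whitespace-delimited
#'   token of each header line.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) {
                     stop("not a valid FASTA file (", conditionMessage(e), ")")
                   })
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  if (length(recs) < 2L) stop("FASTA must contain at least 2 records: ", path)
  ids <- vapply(strsplit(names(recs), "[ \t]"), `[`, "", 1L)
  seq_alignment(as.character(recs), sample_ids = ids)
}

#' Write an alignment to FASTA
#'
#' @param aln a [seq_alignment].
#' @param path output path.
#' @param width line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 60L) {
  stopifnot(inherits(aln, "seq_alignment"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in aln$sample_ids) {
    writeLines(paste0(">", id), con)
    s <- aln$sequences[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a population map
#'
#' Maps sample ids to population labels; the label `"outgroup"` marks
#' outgroup samples used for allele polarization and divergence.
#'
#' @param sample_ids character vector of sample ids.
#' @param populations character vector of population labels, same length.
#' @return An object of class `pop_map` with elements `assignments` (named
#'   character vector) and `outgroup_ids`.
#' @export
pop_map <- function(sample_ids, populations) {
  if (length(sample_ids) != length(populations)) {
    stop("sample_ids and populations must have the same length")
  }
  if (length(sample_ids) == 0L) stop("empty population map")
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id in population map: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  assignments <- setNames(as.character(populations), sample_ids)
  outgroup_ids <- sample_ids[populations == "outgroup"]
  if (length(setdiff(sample_ids, outgroup_ids)) == 0L) {
    stop("no ingroup samples: every sample is labeled 'outgroup'")
  }
  structure(list(assignments = assignments, outgroup_ids = outgroup_ids),
            class = "pop_map")
}

#' Read a sample-to-population map (TSV)
#'
#' Expects a tab-separated file with header columns `sample_id` and
#' `population`; the population value `"outgroup"` marks outgroup samples.
#'
#' @param path path to the TSV file.
#' @return A [pop_map].
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", strip.white = TRUE)
  if (nrow(df) == 0L) stop("empty population map: ", path)
  need <- c("sample_id", "population")
  if (!all(need %in% names(df))) {
    stop("population map must have columns 'sample_id' and 'population'")
  }
  pop_map(df$sample_id, df$population)
}

#' Ingroup sample ids of a population map
#'
#' @param popmap a [pop_map].
#' @param population optional label to restrict to one population.
#' @return Character vector of non-outgroup sample ids.
#' @export
ingroup_ids <- function(popmap, population = NULL) {
  ids <- names(popmap$assignments)
  keep <- !(ids %in% popmap$outgroup_ids)
  if (!is.null(population)) keep <- keep & popmap$assignments == population
  ids[keep]
}

## alignment as a character matrix (rows = samples), optionally subset
aln_matrix <- function(aln, samples = NULL) {
  if (is.null(samples)) samples <- aln$sample_ids
  missing <- setdiff(samples, aln$sample_ids)
  if (length(missing)) {
    stop("samples not in alignment: ", paste(missing, collapse = ", "))
  }
  m <- do.call(rbind, strsplit(unname(aln$sequences[samples]), ""))
  rownames(m) <- samples
  m
}

#' Complete-deletion column mask
#'
#' Returns the alignment columns (1-based) where none of the selected
#' samples carries a gap (`-`) or an ambiguous base (`N`). All per-locus
#' statistics in this package operate on these columns.
#'
#' @param aln a [seq_alignment].
#' @param samples sample ids to consider (default: all).
#' @return Integer vector of retained column indices (possibly empty),
#'   in increasing order.
#' @export
complete_deletion_mask <- function(aln, samples = NULL) {
  m <- aln_matrix(aln, samples)
  which(colSums(m == "-" | m == "N") == 0L)
}

#' Construct a region annotation
#'
#' Non-overlapping intervals classifying alignment regions as `coding`,
#' `intron` or `five_prime`. Coordinates are 0-based half-open
#' (BED-compatible); the coding intervals, concatenated in coordinate order
#' and after removing `frame_offset` leading bases, must have length
#' divisible by 3.
#'
#' @param start,end integer vectors, 0-based half-open interval bounds.
#' @param klass character vector in `c("coding", "intron", "five_prime")`.
#' @param frame_offset number of bases (0, 1 or 2) to trim from the start of
#'   the concatenated coding sequence before translation.
#' @return An object of class `region_annotation` (a data frame with
#'   attribute `frame_offset`).
#' @export
region_annotation <- function(start, end, klass, frame_offset = 0L) {
  stopifnot(length(start) == length(end), length(start) == length(klass))
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  if (!all(klass %in% REGION_CLASSES)) {
    stop("region class must be one of: ", paste(REGION_CLASSES, collapse = ", "))
  }
  if (any(end <= start) || any(start < 0)) {
    stop("invalid interval bounds (need 0 <= start < end)")
  }
  o <- order(start)
  df <- data.frame(start = as.integer(start[o]), end = as.integer(end[o]),
                   klass = as.character(klass[o]), stringsAsFactors = FALSE)
  if (nrow(df) > 1L && any(df$start[-1] < df$end[-nrow(df)])) {
    stop("region intervals overlap")
  }
  clen <- sum(df$end[df$klass == "coding"] - df$start[df$klass == "coding"])
  if (clen > 0L && (clen - frame_offset) %% 3L != 0L) {
    stop("concatenated coding length minus frame_offset is not a multiple of 3")
  }
  structure(df, frame_offset = as.integer(frame_offset),
            class = c("region_annotation", "data.frame"))
}

#' Read a 4-column BED region annotation
#'
#' Columns: chrom (ignored beyond bookkeeping), start, end, name; the name
#' field must be one of `coding`, `intron`, `five_prime`.
#'
#' @param path path to the BED file.
#' @param frame_offset see [region_annotation()].
#' @return A [region_annotation].
#' @export
read_region_bed <- function(path, frame_offset = 0L) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("chrom", "start", "end", "name"),
                   colClasses = c("character", "integer", "integer", "character"))
  if (nrow(df) == 0L) stop("empty BED file: ", path)
  region_annotation(df$start, df$end, df$name, frame_offset = frame_offset)
}

#' Write a region annotation as 4-column BED
#'
#' @param regions a [region_annotation].
#' @param path output path.
#' @param chrom chromosome/gene name for column 1.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(regions, path, chrom = "gene") {
  df <- data.frame(chrom = chrom, start = regions$start, end = regions$end,
                   name = regions$klass)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract one region class from an alignment
#'
#' Concatenates, in coordinate order, the intervals of the requested class
#' and returns the corresponding sub-alignment.
#'
#' @param aln a [seq_alignment].
#' @param regions a [region_annotation].
#' @param klass one of `"coding"`, `"intron"`, `"five_prime"`.
#' @return A [seq_alignment] over the concatenated region, with attribute
#'   `columns` giving the original 1-based column indices.
#' @export
slice_region <- function(aln, regions, klass) {
  stopifnot(klass %in% REGION_CLASSES)
  rr <- regions[regions$klass == klass, , drop = FALSE]
  if (nrow(rr) == 0L) stop("no intervals of class '", klass, "'")
  if (any(rr$end > aln$L)) stop("region interval extends past alignment end")
  cols <- unlist(lapply(seq_len(nrow(rr)),
                        function(i) seq.int(rr$start[i] + 1L, rr$end[i])))
  seqs <- vapply(aln$sequences, function(s) {
    paste(strsplit(s, "")[[1]][cols], collapse = "")
  }, "")
  out <- seq_alignment(seqs, aln$sample_ids)
  attr(out, "columns") <- cols
  out
}

#' Construct a haplotype matrix of polarized segregating sites
#'
#' A binary derived/ancestral matrix under the infinite-sites convention:
#' 0 = ancestral, 1 = derived; each site segregates (derived count between 1
#' and n-1) and positions are strictly increasing. This mirrors the output
#' of infinite-sites coalescent simulators.
#'
#' @param mat integer matrix (haplotypes x sites) of 0/1 derived flags.
#' @param positions numeric vector of strictly increasing site positions
#'   (alignment columns or unit-interval coordinates); default `1..S`.
#' @param sample_ids optional row (haplotype) identifiers.
#' @return An object of class `haplotype_matrix` with elements `n`, `mat`,
#'   `positions`, `sample_ids`.
#' @export
haplotype_matrix <- function(mat, positions = NULL, sample_ids = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  n <- nrow(mat)
  if (n < 2L) stop("haplotype matrix needs at least 2 haplotypes")
  if (ncol(mat) > 0L) {
    if (!all(mat %in% c(0L, 1L))) stop("haplotype matrix must be 0/1")
    d <- colSums(mat)
    if (any(d < 1L | d > n - 1L)) {
      stop("every site must segregate (derived count in [1, n-1])")
    }
  }
  if (is.null(positions)) positions <- seq_len(ncol(mat))
  if (length(positions) != ncol(mat)) {
    stop("positions length must equal the number of sites")
  }
  if (ncol(mat) > 1L && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  if (!is.null(sample_ids)) rownames(mat) <- sample_ids
  structure(list(n = n, mat = mat, positions = as.numeric(positions),
                 sample_ids = sample_ids),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix:", x$n, "haplotypes,", ncol(x$mat), "segregating sites\n")
  invisible(x)
}

#' Polarize ingroup alleles against an outgroup
#'
#' Classifies ingroup segregating sites as ancestral/derived using a single
#' outgroup sequence: after complete deletion over ingroup + outgroup,
#' biallelic ingroup sites where the outgroup carries one of the two alleles
#' become matrix sites with the outgroup allele coded ancestral (0). Sites
#' where the outgroup carries a third allele are unpolarizable; triallelic
#' ingroup sites are excluded (infinite-sites polarization undefined). Both
#' are counted in the returned diagnostics.
#'
#' @param aln a [seq_alignment] containing ingroup and outgroup sequences.
#' @param popmap a [pop_map] whose `"outgroup"` population identifies the
#'   outgroup.
#' @param outgroup_id which outgroup sample to use; required when the map
#'   lists several outgroups present in the alignment.
#' @param samples optional subset of ingroup sample ids to analyze.
#' @return A [haplotype_matrix] over the ingroup haplotypes, with attribute
#'   `diagnostics`: counts of `monomorphic`, `unpolarizable`, `triallelic`
#'   and `analyzed_columns` (columns surviving complete deletion).
#' @export
polarize <- function(aln, popmap, outgroup_id = NULL, samples = NULL) {
  og_avail <- intersect(popmap$outgroup_ids, aln$sample_ids)
  if (length(og_avail) == 0L) stop("no outgroup sample in population map/alignment")
  if (is.null(outgroup_id)) {
    if (length(og_avail) > 1L) {
      stop("several outgroup samples available (",
           paste(og_avail, collapse = ", "),
           "); specify outgroup_id")
    }
    outgroup_id <- og_avail
  } else if (!outgroup_id %in% og_avail) {
    stop("outgroup_id '", outgroup_id, "' not an available outgroup sample")
  }
  if (is.null(samples)) {
    samples <- intersect(ingroup_ids(popmap), aln$sample_ids)
  }
  if (length(samples) < 2L) stop("need at least 2 ingroup haplotypes")
  m <- aln_matrix(aln, c(samples, outgroup_id))
  keep <- which(colSums(m == "-" | m == "N") == 0L)
  ing <- m[samples, keep, drop = FALSE]
  og <- m[outgroup_id, keep]

  monomorphic <- 0L; unpolarizable <- 0L; triallelic <- 0L
  flags <- list(); pos <- integer()
  for (j in seq_along(keep)) {
    col <- ing[, j]
    alleles <- unique(col)
    if (length(alleles) == 1L) {
      monomorphic <- monomorphic + 1L
    } else if (length(alleles) > 2L) {
      triallelic <- triallelic + 1L
    } else if (!og[j] %in% alleles) {
      unpolarizable <- unpolarizable + 1L
    } else {
      flags[[length(flags) + 1L]] <- as.integer(col != og[j])
      pos <- c(pos, keep[j])
    }
  }
  mat <- if (length(flags)) do.call(cbind, flags) else
    matrix(integer(), nrow = length(samples), ncol = 0L)
  out <- haplotype_matrix(mat, positions = pos, sample_ids = samples)
  attr(out, "diagnostics") <- c(monomorphic = monomorphic,
                                unpolarizable = unpolarizable,
                                triallelic = triallelic,
                                analyzed_columns = length(keep))
  attr(out, "outgroup_id") <- outgroup_id
  out
}

#' Translate the coding region of an alignment
#'
#' Concatenates the coding intervals, trims `frame_offset` leading bases
#' (dropping any trailing partial codon with a warning) and translates each
#' haplotype with the standard genetic code. Codons containing `-` or `N`
#' translate to `X`; internal stop codons are retained as `*` with a
#' warning.
#'
#' @param aln a [seq_alignment]; either a full-gene alignment together with
#'   `regions`, or an already-sliced in-frame coding alignment.
#' @param regions optional [region_annotation] used to slice the coding
#'   region and supply the frame offset.
#' @param frame_offset overrides the annotation's frame offset.
#' @return Named character vector of amino-acid sequences (class
#'   `aa_alignment`).
#' @export
translate_coding <- function(aln, regions = NULL, frame_offset = NULL) {
  if (!is.null(regions)) {
    if (is.null(frame_offset)) frame_offset <- attr(regions, "frame_offset")
    aln <- slice_region(aln, regions, "coding")
  }
  if (is.null(frame_offset)) frame_offset <- 0L
  code <- Biostrings::GENETIC_CODE
  prots <- vapply(aln$sample_ids, function(id) {
    s <- substring(aln$sequences[[id]], frame_offset + 1L)
    ncod <- nchar(s) %/% 3L
    if (ncod == 0L) stop("no complete codons to translate")
    if (nchar(s) %% 3L != 0L) {
      warning("coding length not a multiple of 3 after frame offset; ",
              "trailing ", nchar(s) %% 3L, " base(s) dropped")
    }
    codons <- substring(s, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
    aa <- ifelse(codons %in% names(code), code[codons], "X")
    if (any(aa[-length(aa)] == "*")) {
      warning("internal stop codon in ", id, "; retained as '*'")
    }
    paste(aa, collapse = "")
  }, "")
  structure(prots, class = "aa_alignment")
}
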