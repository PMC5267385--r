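# Independent oracles used to freeze expected values. These deliberately
# re-derive each quantity by direct enumeration, separate from the package
# implementation paths.

# mean pairwise difference count by explicit double loop over sequence pairs
oracle_pairwise_diffs <- function(seqs) {
  n <- length(seqs)
  chars <- strsplit(seqs, "")
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(chars[[i]] != chars[[j]])
    }
  }
  tot / (n * (n - 1) / 2)
}

# Nei-Gojobori synonymous site fraction of one codon, by enumerating the
# nine single-base changes; stop-codon targets count as nonsynonymous
oracle_ng_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    for (b in bases) {
      if (b == substr(codon, p, p)) next
      alt <- codon
      substr(alt, p, p) <- b
      if (code[[alt]] != "*" && code[[alt]] == code[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

# Nei-Gojobori difference apportionment by recursive enumeration of every
# ordering of the differing positions; paths through intermediate stop
# codons are excluded unless every path hits one
oracle_ng_diffs <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  walk <- function(cur, remaining) {
    if (length(remaining) == 0) {
      return(list(list(s = 0, n = 0, stopped = FALSE)))
    }
    out <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      step_syn <- code[[nxt]] == code[[cur]]
      hit_stop <- code[[nxt]] == "*" && length(remaining) > 1
      for (tail in walk(nxt, setdiff(remaining, p))) {
        out[[length(out) + 1]] <- list(
          s = tail$s + as.numeric(step_syn),
          n = tail$n + as.numeric(!step_syn),
          stopped = tail$stopped || hit_stop)
      }
    }
    out
  }
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diffpos) == 0) return(c(s = 0, n = 0))
  paths <- walk(c1, diffpos)
  keep <- Filter(function(p) !p$stopped, paths)
  if (length(keep) == 0) keep <- paths
  c(s = mean(vapply(keep, `[[`, 0, "s")),
    n = mean(vapply(keep, `[[`, 0, "n")))
}

# Hudson F_ST by explicit enumeration of all within- and between-pairs
oracle_fst <- function(seqs_a, seqs_b) {
  pair_diff <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  within <- function(seqs) {
    n <- length(seqs)
    tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      tot <- tot + pair_diff(seqs[i], seqs[j])
    }
    tot / (n * (n - 1) / 2)
  }
  hb <- 0
  for (x in seqs_a) for (y in seqs_b) hb <- hb + pair_diff(x, y)
  hb <- hb / (length(seqs_a) * length(seqs_b))
  hw <- (within(seqs_a) + within(seqs_b)) / 2
  list(fst = 1 - hw / hb, h_w = hw, h_b = hb)
}

# the 61 sense codons, for random codon draws
sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

# the worked 4-haplotype / 3-site polarized matrix used across tests
worked_matrix <- function() {
  haplotype_matrix(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)))
}

# the default sample naming of the synthetic generator
synthetic_sample_ids_for_test <- function() {
  c(sprintf("temp%02d", 1:14), sprintf("trop%02d", 1:17),
    sprintf("parv%02d", 1:9), "outgroup1")
}
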