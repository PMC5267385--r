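## Coalescent null-distribution engine: infinite-sites simulation under
## piecewise-constant demography (including a domestication-bottleneck
## parameterization), null distributions of the neutrality statistics, and
## percentile placement.
##
## Conventions follow Hudson's ms so published demographies port directly:
## time in units of 4N0 generations backwards from the present, relative
## population sizes x(t), theta = 4*N0*mu per locus. With k lineages the
## coalescence rate is k(k-1)/x(t), so E[pairwise coalescence time] = 0.5
## at x = 1, E[S] = theta * a1 and E[pi_hat] = theta.

#' Piecewise-constant demographic model
#'
#' @param epochs `data.frame` with columns `time` (epoch start, in 4N0
#'   units, strictly increasing, first row 0) and `size` (relative
#'   population size, > 0).
#' @return An object of class `demographic_model`.
#' @export
demographic_model <- function(epochs = data.frame(time = 0, size = 1)) {
  stopifnot(is.data.frame(epochs), all(c("time", "size") %in% names(epochs)))
  if (epochs$time[1] != 0) stop("first epoch must start at time 0")
  if (nrow(epochs) > 1L && any(diff(epochs$time) <= 0)) {
    stop("epoch times must be strictly increasing")
  }
  if (any(epochs$size <= 0)) stop("relative sizes must be > 0")
  structure(list(epochs = epochs), class = "demographic_model")
}

#' Constant-size demographic model
#'
#' @return A [demographic_model] with a single epoch of relative size 1.
#' @export
constant_size_model <- function() demographic_model()

#' Domestication-bottleneck demographic model
#'
#' Three-epoch history: present-day relative size 1 until `t_d` (bottleneck
#' onset, backwards in time), relative size `x_b` during the bottleneck of
#' duration `t_b`, then ancestral relative size `x_a`. The bottleneck
#' severity is reported as `k = x_b / t_b` (the ratio of bottleneck
#' population size to bottleneck duration); the default parameters give
#' k = 2.45, the severity proposed for the maize domestication bottleneck.
#' Since only the severity ratio is published, the individual defaults are
#' illustrative rather than calibrated.
#'
#' @param t_d bottleneck onset, 4N0 units backwards from the present.
#' @param t_b bottleneck duration.
#' @param x_b relative size during the bottleneck.
#' @param x_a relative ancestral size after (before, forwards in time) the
#'   bottleneck.
#' @return A [demographic_model] with attribute `severity_k = x_b / t_b`.
#' @export
bottleneck_model <- function(t_d = 0.01, t_b = 0.05 / 2.45, x_b = 0.05,
                             x_a = 1) {
  stopifnot(t_d > 0, t_b > 0, x_b > 0, x_a > 0)
  m <- demographic_model(data.frame(time = c(0, t_d, t_d + t_b),
                                    size = c(1, x_b, x_a)))
  attr(m, "severity_k") <- x_b / t_b
  m
}

#' Simulation configuration
#'
#' @param n sample size (haplotypes); >= 4 so all neutrality statistics are
#'   defined.
#' @param theta population mutation parameter per locus (4 N0 mu L).
#' @param reps number of replicates.
#' @param seed integer seed; every simulation entry point seeds R's RNG
#'   with it, making runs bit-reproducible.
#' @param fixed_s optional integer: condition every replicate on exactly
#'   this many segregating sites (placed proportionally to branch length)
#'   instead of the default Poisson(`theta` x branch length) mutation draw.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n, theta, reps = 10000L, seed = 1L, fixed_s = NULL) {
  stopifnot(n >= 4L, theta > 0, reps >= 1L)
  if (!is.null(fixed_s)) stopifnot(fixed_s >= 0)
  structure(list(n = as.integer(n), theta = theta, reps = as.integer(reps),
                 seed = as.integer(seed),
                 fixed_s = if (is.null(fixed_s)) NULL else as.integer(fixed_s)),
            class = "sim_config")
}

## ----------------------------------------------------------------------
## R genealogy engine (tracks tip identity; used for single replicates and
## by the synthetic-data generator, which needs labeled populations).
## Populations coalesce only within themselves until merge events join
## them; the piecewise size history applies globally.

## pops: named integer vector of sample counts per population
## merges: data.frame(time, from, to) sorted by time; lineages of `from`
##   are relabeled `to` at `time`
sim_genealogy <- function(pops, merges = NULL,
                          model = constant_size_model()) {
  times <- model$epochs$time
  sizes <- model$epochs$size
  if (is.null(merges)) {
    merges <- data.frame(time = numeric(), from = character(),
                         to = character(), stringsAsFactors = FALSE)
  } else {
    merges <- merges[order(merges$time), , drop = FALSE]
  }
  n <- sum(pops)
  lab <- rep(names(pops), pops)
  lin_tips <- as.list(seq_len(n))
  lin_birth <- rep(0, n)
  lin_pop <- lab
  br_tips <- vector("list", 2L * n)
  br_len <- numeric(2L * n)
  nbr <- 0L
  t <- 0; ep <- 1L; mg <- 1L
  while (length(lin_tips) > 1L) {
    kp <- table(lin_pop)
    rates <- kp * (pmax(kp - 1L, 0L)) / sizes[ep]
    tot <- sum(rates)
    t_ep <- if (ep < length(times)) times[ep + 1L] else Inf
    t_mg <- if (mg <= nrow(merges)) merges$time[mg] else Inf
    w <- if (tot > 0) rexp(1L, tot) else Inf
    nxt <- min(t_ep, t_mg)
    if (t + w > nxt) {
      if (is.infinite(nxt)) {
        stop("coalescent cannot finish: isolated lineages with no merge event")
      }
      t <- nxt
      if (t_mg <= t_ep) {
        lin_pop[lin_pop == merges$from[mg]] <- merges$to[mg]
        mg <- mg + 1L
      } else {
        ep <- ep + 1L
      }
      next
    }
    t <- t + w
    p <- sample(names(rates), 1L, prob = as.numeric(rates))
    members <- which(lin_pop == p)
    pair <- members[sample.int(length(members), 2L)]
    i <- pair[1]; j <- pair[2]
    for (idx in c(i, j)) {
      nbr <- nbr + 1L
      br_tips[[nbr]] <- lin_tips[[idx]]
      br_len[nbr] <- t - lin_birth[idx]
    }
    lin_tips[[i]] <- c(lin_tips[[i]], lin_tips[[j]])
    lin_birth[i] <- t
    lin_tips[[j]] <- NULL
    lin_birth <- lin_birth[-j]
    lin_pop <- lin_pop[-j]
  }
  list(n = n, labels = lab, branch_tips = br_tips[seq_len(nbr)],
       branch_len = br_len[seq_len(nbr)], tmrca = t,
       total_len = sum(br_len[seq_len(nbr)]))
}

## Drop infinite-sites mutations on a genealogy: Poisson(theta * L) total,
## placed on branches proportionally to length, positions uniform on (0,1).
mutate_genealogy <- function(g, theta, sample_ids = NULL) {
  S <- rpois(1L, theta * g$total_len)
  mat <- matrix(0L, nrow = g$n, ncol = S)
  if (S > 0L) {
    b <- sample.int(length(g$branch_len), S, replace = TRUE,
                    prob = g$branch_len)
    for (s in seq_len(S)) mat[g$branch_tips[[b[s]]], s] <- 1L
    o <- order(runif(S))
    mat <- mat[, o, drop = FALSE]
  }
  pos <- sort(runif(S))
  haplotype_matrix(mat, positions = pos, sample_ids = sample_ids)
}

#' Simulate one coalescent replicate
#'
#' Draws a single genealogy under the Kingman coalescent with the given
#' piecewise-constant size history and drops infinite-sites mutations on
#' it (Poisson with mean `theta` times the total branch length, placed
#' uniformly on branches; positions uniform on (0,1); ancestral state 0).
#' Uses the current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param config a [sim_config] (`reps` is ignored here).
#' @param model a [demographic_model].
#' @return A [haplotype_matrix] with attributes `tmrca` and `total_len`.
#' @export
simulate_replicate <- function(config, model = constant_size_model()) {
  g <- sim_genealogy(c(pop = config$n), model = model)
  hm <- mutate_genealogy(g, config$theta)
  attr(hm, "tmrca") <- g$tmrca
  attr(hm, "total_len") <- g$total_len
  hm
}

## fast path: per-replicate derived-allele counts via the C++ core
coal_counts <- function(config, model = constant_size_model()) {
  fs <- if (is.null(config$fixed_s)) -1L else config$fixed_s
  coal_sim_counts_cpp(config$n, model$epochs$time, model$epochs$size,
                      config$theta, config$reps, fs)
}

#' Per-replicate neutrality statistics under a coalescent model
#'
#' Generates `config$reps` infinite-sites coalescent replicates under the
#' given demography and computes every frequency-spectrum statistic on
#' each, using the simulator's known ancestral states (perfect
#' polarization) for the Fu & Li statistics. Under infinite sites the
#' mutation count eta equals S. Statistics are `NA` for replicates with no
#' polymorphism.
#'
#' @param config a [sim_config]; `config$seed` seeds the run.
#' @param model a [demographic_model].
#' @return A `data.frame` with one row per replicate and columns `rep`,
#'   `S`, `eta_e`, `pi_hat`, `tajima_d`, `fu_li_d`, `fu_li_f`.
#' @export
simulate_stats_table <- function(config, model = constant_size_model()) {
  set.seed(config$seed)
  sim <- coal_counts(config, model)
  counts <- sim$counts
  n <- config$n
  S <- lengths(counts)
  eta_e <- vapply(counts, function(x) sum(x == 1L), 0L)
  pi_hat <- vapply(counts, function(x) sum(x * (n - x)), 0) / (n * (n - 1) / 2)
  k <- neutrality_constants(n)
  data.frame(
    rep = seq_along(counts),
    S = S,
    eta_e = eta_e,
    pi_hat = pi_hat,
    tajima_d = ifelse(S == 0L, NA_real_,
                      (pi_hat - S / k$a1) /
                        sqrt(k$e1 * S + k$e2 * S * (S - 1))),
    fu_li_d = ifelse(S == 0L, NA_real_,
                     (S - k$a1 * eta_e) / sqrt(k$u_D * S + k$v_D * S^2)),
    fu_li_f = ifelse(S == 0L, NA_real_,
                     (pi_hat - eta_e) / sqrt(k$u_F * S + k$v_F * S^2)))
}

#' Null distributions of neutrality statistics by coalescent simulation
#'
#' Wraps [simulate_stats_table()]: runs the replicates and packages each
#' requested statistic as a sorted null distribution. Replicates with no
#' polymorphism, where the test statistics are undefined, are recorded in
#' `n_na` and excluded from the values.
#'
#' @param config a [sim_config]; `config$seed` seeds the run.
#' @param model a [demographic_model].
#' @param statistics subset of
#'   `c("tajima_d", "fu_li_d", "fu_li_f", "S", "pi_hat")`.
#' @return Named list of `null_distribution` objects, each with `statistic`
#'   (name), `values` (sorted, NA-dropped), `n_na`, `config`, `seed`.
#' @export
simulate_null <- function(config, model = constant_size_model(),
                          statistics = c("tajima_d", "fu_li_d", "fu_li_f")) {
  allowed <- c("tajima_d", "fu_li_d", "fu_li_f", "S", "pi_hat")
  statistics <- match.arg(statistics, allowed, several.ok = TRUE)
  tab <- simulate_stats_table(config, model)
  if (all(tab$S == 0L)) stop("theta too small: every replicate is monomorphic")
  out <- lapply(statistics, function(nm) {
    v <- as.numeric(tab[[nm]])
    structure(list(statistic = nm, values = sort(v[!is.na(v)]),
                   n_na = sum(is.na(v)), config = config, model = model,
                   seed = config$seed),
              class = "null_distribution")
  })
  setNames(out, statistics)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("null_distribution of", x$statistic, ":", length(x$values),
      "values (", x$n_na, "NA replicates ), seed", x$seed, "\n")
  invisible(x)
}

#' Percentile of a value within a distribution
#'
#' Mid-rank percentile: `100 * (#values < value + 0.5 * #values == value) /
#' size`. In two-tailed use, values at or beyond the 2.5th/97.5th
#' percentiles of a simulated null are significant at P < 0.05.
#'
#' @param value numeric scalar.
#' @param distribution a `null_distribution` or numeric vector (need not be
#'   sorted).
#' @return Percentile in `[0, 100]`.
#' @export
percentile_of <- function(value, distribution) {
  v <- if (inherits(distribution, "null_distribution")) {
    distribution$values
  } else {
    as.numeric(distribution)
  }
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("empty distribution")
  100 * (sum(v < value) + 0.5 * sum(v == value)) / length(v)
}

#' Two-tailed significance call from a percentile
#'
#' Labels a percentile within a null distribution: at or beyond the
#' 2.5th/97.5th percentiles the departure is significant at P < 0.05
#' (two-tailed); between 2.5 and 5 (or 95 and 97.5) it is marginal
#' (P < 0.10).
#'
#' @param percentile numeric in `[0, 100]` (NA allowed).
#' @return One of `"significant_low"`, `"marginal_low"`, `"ns"`,
#'   `"marginal_high"`, `"significant_high"`, or `NA`.
#' @export
significance_call <- function(percentile) {
  vapply(percentile, function(p) {
    if (is.na(p)) return(NA_character_)
    if (p <= 2.5) "significant_low"
    else if (p <= 5) "marginal_low"
    else if (p >= 97.5) "significant_high"
    else if (p >= 95) "marginal_high"
    else "ns"
  }, "")
}

#' Empirical critical values of a null distribution
#'
#' Two-sided critical values at level `alpha`: the `alpha/2` and
#' `1 - alpha/2` empirical quantiles (linear interpolation).
#'
#' @param distribution a `null_distribution` or numeric vector of at least
#'   40 values.
#' @param alpha significance level (default 0.05). `alpha = 1` returns the
#'   degenerate bounds `(min, max)` flagged with attribute `degenerate`.
#' @return Numeric vector `c(lower, upper)`.
#' @export
critical_values <- function(distribution, alpha = 0.05) {
  v <- if (inherits(distribution, "null_distribution")) {
    distribution$values
  } else {
    as.numeric(distribution)
  }
  v <- v[!is.na(v)]
  if (length(v) < 40L) stop("distribution too small for critical values (< 40)")
  if (alpha >= 1) {
    out <- c(lower = min(v), upper = max(v))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  q <- quantile(v, c(alpha / 2, 1 - alpha / 2), type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}
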