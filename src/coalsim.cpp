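#include <Rcpp.h>
using namespace Rcpp;

// Infinite-sites Kingman coalescent with piecewise-constant population
// size. Time is measured in units of 4N0 generations backwards from the
// present; with k lineages and relative size x the coalescence rate is
// k(k-1)/x, so a pair coalesces after expected time 0.5 at x = 1, and
// theta = 4*N0*mu per locus gives E[S] = theta * a1 and E[pi_hat] = theta.
// Uses R's RNG, so runs seeded with set.seed() are reproducible.
//
// Returns, per replicate, the derived-allele count of every mutation
// (sufficient for the site-frequency-spectrum statistics), plus the time
// to the MRCA and the total branch length.

// fixed_s >= 0 conditions each replicate on exactly fixed_s mutations
// (placed proportionally to branch length) instead of Poisson(theta * L).

// [[Rcpp::export]]
List coal_sim_counts_cpp(int n, NumericVector epoch_times,
                         NumericVector epoch_sizes, double theta, int reps,
                         int fixed_s = -1) {
  if (n < 2) stop("n must be >= 2");
  if (theta < 0) stop("theta must be >= 0");
  int n_epochs = epoch_times.size();
  List counts(reps);
  NumericVector tmrca(reps), total_len(reps);

  std::vector<int> tips(n);        // descendant-tip count per active lineage
  std::vector<double> birth(n);    // time the active lineage started
  std::vector<int> br_tips(2 * n); // per recorded branch
  std::vector<double> br_len(2 * n);

  for (int r = 0; r < reps; ++r) {
    int k = n;
    for (int i = 0; i < n; ++i) { tips[i] = 1; birth[i] = 0.0; }
    int nbr = 0;
    double t = 0.0;
    int ep = 0;
    while (k > 1) {
      double x = epoch_sizes[ep];
      double rate = (double)k * (k - 1) / x;
      double w = exp_rand() / rate;
      double nxt = (ep + 1 < n_epochs) ? epoch_times[ep + 1] : R_PosInf;
      if (t + w > nxt) { t = nxt; ++ep; continue; }
      t += w;
      // pick an unordered pair uniformly
      int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
      if (j >= i) ++j;
      if (i > j) std::swap(i, j);
      br_tips[nbr] = tips[i]; br_len[nbr] = t - birth[i]; ++nbr;
      br_tips[nbr] = tips[j]; br_len[nbr] = t - birth[j]; ++nbr;
      tips[i] += tips[j];
      birth[i] = t;
      tips[j] = tips[k - 1];
      birth[j] = birth[k - 1];
      --k;
    }
    tmrca[r] = t;
    double L = 0.0;
    for (int b = 0; b < nbr; ++b) L += br_len[b];
    total_len[r] = L;
    int S = (fixed_s >= 0) ? fixed_s
              : ((theta > 0 && L > 0) ? (int)R::rpois(theta * L) : 0);
    IntegerVector cts(S);
    if (S > 0) {
      // cumulative branch lengths for placement proportional to length
      std::vector<double> cum(nbr);
      double acc = 0.0;
      for (int b = 0; b < nbr; ++b) { acc += br_len[b]; cum[b] = acc; }
      for (int s = 0; s < S; ++s) {
        double u = unif_rand() * L;
        int lo = 0, hi = nbr - 1;
        while (lo < hi) {
          int mid = (lo + hi) / 2;
          if (cum[mid] < u) lo = mid + 1; else hi = mid;
        }
        cts[s] = br_tips[lo];
      }
    }
    counts[r] = cts;
  }
  return List::create(_["counts"] = counts, _["tmrca"] = tmrca,
                      _["total_len"] = total_len);
}
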