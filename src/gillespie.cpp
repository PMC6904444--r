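#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie) of the 8-type
// birth-death-mutation process. Genotype index g in 0..7 encodes the
// resistance bits as (pre << 2) | (on << 1) | post, matching the
// lexicographic (pre, on, post) order used on the R side.
//
// Events: birth at rate b*N_g (the new daughter activates each inactive
// mechanism independently with probability u), death at rate d*N_g.

static inline int n_inactive(int g) {
  return 3 - (((g >> 2) & 1) + ((g >> 1) & 1) + (g & 1));
}

// [[Rcpp::export(name = ".gillespie_interval")]]
List gillespie_interval(NumericVector counts, double b, double d,
                        double u, double duration,
                        double stop_total = 0.0,
                        double max_events = 5e9) {
  if (counts.size() != 8) stop("counts must have length 8");
  long long n[8];
  long long ntot = 0;
  for (int i = 0; i < 8; ++i) {
    double c = counts[i];
    if (c < 0 || c != std::floor(c))
      stop("exact engine requires nonnegative integer counts");
    n[i] = (long long) c;
    ntot += n[i];
  }

  // inactive-mechanism bit masks per genotype, and the probability of a
  // division producing an unmutated daughter
  int inact_bits[8][3];
  int n_inact[8];
  double p_nomut[8];
  for (int g = 0; g < 8; ++g) {
    n_inact[g] = 0;
    int masks[3] = {4, 2, 1};  // pre, on, post
    for (int m = 0; m < 3; ++m)
      if (!(g & masks[m])) inact_bits[g][n_inact[g]++] = masks[m];
    p_nomut[g] = std::pow(1.0 - u, n_inact[g]);
  }

  double t = 0.0;
  double ev = 0.0;
  std::string stopped = "duration";

  while (ntot > 0) {
    if (stop_total > 0 && (double) ntot >= stop_total) {
      stopped = "threshold";
      break;
    }
    double rate = (b + d) * (double) ntot;
    t += R::exp_rand() / rate;
    if (t >= duration) {
      t = duration;
      break;
    }
    if (++ev > max_events) stop("exact engine exceeded max_events");

    // one uniform picks the genotype (proportional to its count) and,
    // through its position within that genotype's block, the event
    // type (birth with probability b / (b + d))
    double pick = unif_rand() * (double) ntot;
    int g = 0;
    double cum = 0.0, within = 0.0;
    for (; g < 8; ++g) {
      double ng = (double) n[g];
      if (pick < cum + ng || g == 7) {
        within = (pick - cum) / ng;
        break;
      }
      cum += ng;
    }
    if (within < 0.0) within = 0.0;
    if (within >= 1.0) within = 0.9999999999;

    if (within * (b + d) < b) {
      // birth: daughter may activate inactive mechanisms
      int dg = g;
      int m = n_inact[g];
      if (m > 0 && unif_rand() >= p_nomut[g]) {
        // conditioned on >= 1 activation: enumerate nonempty subsets
        double norm = 1.0 - p_nomut[g];
        double r = unif_rand() * norm;
        double acc = 0.0;
        int nsub = (1 << m) - 1;
        for (int s = 1; s <= nsub; ++s) {
          int k = 0;
          for (int j = 0; j < m; ++j) if (s & (1 << j)) ++k;
          acc += std::pow(u, k) * std::pow(1.0 - u, m - k);
          if (r < acc || s == nsub) {
            for (int j = 0; j < m; ++j)
              if (s & (1 << j)) dg |= inact_bits[g][j];
            break;
          }
        }
      }
      n[dg] += 1;
      ntot += 1;
    } else {
      n[g] -= 1;
      ntot -= 1;
      if (ntot == 0) stopped = "extinct";
    }
  }
  if (ntot == 0) stopped = "extinct";

  NumericVector out(8);
  for (int i = 0; i < 8; ++i) out[i] = (double) n[i];
  return List::create(_["counts"] = out, _["time"] = t,
                      _["stopped"] = stopped, _["events"] = ev);
}

// Survival of a single-cell lineage: simulate a one-type birth-death
// process from one cell until extinction or reaching n_stop cells.
// Returns the fraction of replicates that reach n_stop, an estimate of
// the drift-survival probability (b - d) / b for supercritical rates.
// [[Rcpp::export(name = ".lineage_survival_mc")]]
double lineage_survival_mc(int reps, double b, double d, long long n_stop) {
  long long survived = 0;
  for (int r = 0; r < reps; ++r) {
    long long nn = 1;
    while (nn > 0 && nn < n_stop) {
      // embedded jump chain: birth w.p. b/(b+d)
      if (unif_rand() * (b + d) < b) ++nn; else --nn;
    }
    if (nn >= n_stop) ++survived;
  }
  return (double) survived / (double) reps;
}
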