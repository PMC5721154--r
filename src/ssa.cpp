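#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation of mass-action chemistry for one cell over a
// fixed time interval. Draws are consumed strictly event by event from R's
// RNG stream, so rerunning with the same seed and a shorter duration
// reproduces a prefix of the same trajectory (used to reconstruct cell
// states at arbitrary ages from per-cell seeds).
//
// reactants/change: reactions x species matrices; rates: per reaction;
// burst_mean: NA for ordinary reactions, else the mean of a geometric
// burst (on {0,1,...}) applied to the reaction's single product species.
//
// record_ages (sorted, within [0, duration]): molecule states sampled at
// these ages are returned alongside the final state.

// [[Rcpp::export]]
List ssa_advance_cpp(IntegerVector x0, IntegerMatrix reactants,
                     IntegerMatrix change, NumericVector rates,
                     NumericVector burst_mean, double duration,
                     NumericVector record_ages) {
  const int ns = x0.size();
  const int nr = reactants.nrow();
  std::vector<double> x(ns);
  for (int i = 0; i < ns; ++i) x[i] = x0[i];

  const int nrec = record_ages.size();
  NumericMatrix rec(nrec, ns);
  int irec = 0;

  // burst product index per reaction (-1 if not a burst reaction)
  std::vector<int> burst_prod(nr, -1);
  for (int r = 0; r < nr; ++r) {
    if (!NumericVector::is_na(burst_mean[r])) {
      for (int i = 0; i < ns; ++i)
        if (change(r, i) > 0) { burst_prod[r] = i; break; }
    }
  }

  double t = 0.0;
  std::vector<double> w(nr);
  while (true) {
    double wtot = 0.0;
    for (int r = 0; r < nr; ++r) {
      double wr = rates[r];
      for (int i = 0; i < ns && wr > 0; ++i) {
        int m = reactants(r, i);
        for (int k = 0; k < m; ++k) wr *= std::max(x[i] - k, 0.0);
      }
      w[r] = wr;
      wtot += wr;
    }
    double tnext = (wtot > 0) ? t + R::exp_rand() / wtot : duration;
    if (tnext > duration) tnext = duration;
    // flush recordings that fall before the next event
    while (irec < nrec && record_ages[irec] <= tnext) {
      for (int i = 0; i < ns; ++i) rec(irec, i) = x[i];
      ++irec;
    }
    if (wtot <= 0 || tnext >= duration) { t = duration; break; }
    t = tnext;
    double u = unif_rand() * wtot;
    int r = 0;
    for (; r < nr - 1; ++r) { if (u < w[r]) break; u -= w[r]; }
    if (burst_prod[r] >= 0) {
      // geometric burst on {0,1,...} with mean b: success prob 1/(1+b)
      double b = burst_mean[r];
      double m = R::rgeom(1.0 / (1.0 + b));
      x[burst_prod[r]] += m;
    } else {
      for (int i = 0; i < ns; ++i) x[i] += change(r, i);
    }
  }
  while (irec < nrec) {
    for (int i = 0; i < ns; ++i) rec(irec, i) = x[i];
    ++irec;
  }
  IntegerVector xf(ns);
  for (int i = 0; i < ns; ++i) xf[i] = (int)x[i];
  return List::create(_["x"] = xf, _["trajectory"] = rec);
}

// Deterministic 31-bit per-cell seed derived from the root seed and cell
// id by a 64-bit mix, so per-cell RNG substreams are independent of event
// interleaving.
// [[Rcpp::export]]
int cell_seed_cpp(int root_seed, int cell_id) {
  uint64_t z = (uint64_t)(uint32_t)root_seed * 0x9E3779B97F4A7C15ULL
             + (uint64_t)(uint32_t)cell_id * 0xBF58476D1CE4E5B9ULL;
  z ^= z >> 30; z *= 0xBF58476D1CE4E5B9ULL;
  z ^= z >> 27; z *= 0x94D049BB133111EBULL;
  z ^= z >> 31;
  return (int)(z & 0x7FFFFFFFULL);
}
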