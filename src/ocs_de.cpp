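#include <Rcpp.h>
using namespace Rcpp;

// Differential-evolution core for optimal cross selection.
//
// A genotype is a real vector of length 2n: per-candidate contribution
// scores followed by per-candidate rank keys (keys matter only for pairing
// the final plan, not for fitness, since expected gain x'a and group
// coancestry x'Cx depend on contributions alone).
//
// Decoding (per pool): scores clamped to [0, cap] act as desired
// contributions, water-filled so that after scaling to the pool total n_c
// no contribution exceeds cap, then rounded to integers by largest
// remainder. Every decoded genotype is feasible by construction:
// per-pool contributions sum to n_c with entries in {0, ..., cap}.

namespace {

struct Problem {
  const double* a;
  const double* C;   // column-major n x n
  int n;
  std::vector<int> females, males;
  int nc, cap;
  int mode;          // 1 = minimise coancestry, 2 = penalised degree target
  double gain_off, gain_scl, c_off, c_scl, c_target, mult;
};

void decode_pool(const std::vector<int>& idx, const double* sc, int nc, int cap,
                 std::vector<int>& n_out) {
  const int m = (int) idx.size();
  std::vector<double> d(m);
  double s = 0.0;
  for (int i = 0; i < m; ++i) {
    double v = sc[idx[i]];
    if (v < 0.0) v = 0.0; else if (v > cap) v = cap;
    d[i] = v; s += v;
  }
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int i, int j) { return sc[idx[i]] > sc[idx[j]]; });
  if (s <= 0.0) {
    // degenerate genotype: fall back to greedy fill in score order
    int left = nc;
    for (int i = 0; i < m && left > 0; ++i) {
      int take = left < cap ? left : cap;
      d[ord[i]] = take; left -= take;
    }
  } else {
    // water-filling at the cap
    std::vector<bool> capped(m, false);
    double remaining = nc;
    for (;;) {
      double sa = 0.0;
      for (int i = 0; i < m; ++i) if (!capped[i]) sa += d[i];
      if (sa <= 0.0) break;
      double scale = remaining / sa;
      bool newcap = false;
      for (int i = 0; i < m; ++i) {
        if (!capped[i] && d[i] * scale >= cap) {
          d[i] = cap; capped[i] = true; remaining -= cap; newcap = true;
        }
      }
      if (!newcap) {
        for (int i = 0; i < m; ++i) if (!capped[i]) d[i] *= scale;
        break;
      }
    }
    if (remaining > 0.0) {
      double live = 0.0;
      for (int i = 0; i < m; ++i) if (!capped[i]) live += d[i];
      if (live <= 0.0) {
        // all mass capped; spread the remainder over unused members
        for (int i = 0; i < m && remaining > 0.5; ++i) {
          int j = ord[i];
          if (!capped[j] && d[j] <= 0.0) {
            double take = remaining < cap ? remaining : cap;
            d[j] = take; remaining -= take;
          }
        }
      }
    }
  }
  // largest-remainder rounding to integer contributions
  std::vector<double> frac(m);
  int tot = 0;
  std::vector<int> ni(m);
  for (int i = 0; i < m; ++i) {
    ni[i] = (int) std::floor(d[i] + 1e-12);
    if (ni[i] > cap) ni[i] = cap;
    frac[i] = d[i] - ni[i];
    tot += ni[i];
  }
  std::sort(ord.begin(), ord.end(), [&](int i, int j) {
    if (frac[i] != frac[j]) return frac[i] > frac[j];
    return sc[idx[i]] > sc[idx[j]];
  });
  int left = nc - tot, guard = 0;
  while (left > 0 && guard < 4 * m + 8) {
    for (int i = 0; i < m && left > 0; ++i) {
      int j = ord[i];
      if (ni[j] < cap) { ++ni[j]; --left; }
    }
    ++guard;
  }
  for (int i = 0; i < m; ++i) n_out[idx[i]] = ni[i];
}

void decode(const Problem& P, const double* genome, std::vector<int>& n_out) {
  std::fill(n_out.begin(), n_out.end(), 0);
  decode_pool(P.females, genome, P.nc, P.cap, n_out);
  decode_pool(P.males, genome, P.nc, P.cap, n_out);
}

void evaluate(const Problem& P, const std::vector<int>& n, double& gain, double& cbar) {
  const double denom = 2.0 * P.nc;
  gain = 0.0; cbar = 0.0;
  std::vector<int> sup;
  sup.reserve(64);
  for (int i = 0; i < P.n; ++i) if (n[i] > 0) sup.push_back(i);
  for (size_t ii = 0; ii < sup.size(); ++ii) {
    const int i = sup[ii];
    const double xi = n[i] / denom;
    gain += xi * P.a[i];
    const double* Ci = P.C + (size_t) i * P.n;
    for (size_t jj = 0; jj < sup.size(); ++jj) {
      const int j = sup[jj];
      cbar += xi * (n[j] / denom) * Ci[j];
    }
  }
}

double fitness(const Problem& P, const std::vector<int>& n) {
  double gain, cbar;
  evaluate(P, n, gain, cbar);
  if (P.mode == 1) return -cbar;
  const double gn = (gain - P.gain_off) * P.gain_scl;
  const double cn = (cbar - P.c_off) * P.c_scl;
  double excess = cn - P.c_target;
  if (excess < 0.0) excess = 0.0;
  return gn - P.mult * excess;
}

// Integer local search: move one contribution unit at a time between
// candidates of the same pool while it improves the fitness. Keeps per-pool
// sums and the per-parent cap intact, and turns a near-optimal DE solution
// into a locally optimal integer allocation.
void polish(const Problem& P, std::vector<int>& n) {
  const std::vector<int>* pools[2] = { &P.females, &P.males };
  bool improved = true;
  int guard = 0;
  double best = fitness(P, n);
  while (improved && guard++ < 500) {
    improved = false;
    for (int p = 0; p < 2; ++p) {
      const std::vector<int>& idx = *pools[p];
      for (size_t di = 0; di < idx.size(); ++di) {
        const int i = idx[di];
        for (size_t dj = 0; dj < idx.size() && n[i] > 0; ++dj) {
          const int j = idx[dj];
          if (j == i || n[j] >= P.cap) continue;
          --n[i]; ++n[j];
          const double f = fitness(P, n);
          if (f > best + 1e-15) {
            best = f;
            improved = true;
          } else {
            ++n[i]; --n[j];
          }
        }
      }
    }
  }
}

} // namespace

// init: optional warm-start genotypes (rows of length 2n) copied into the
// initial population before random fill.
// [[Rcpp::export]]
List cpp_ocs_de(const NumericVector& a, const NumericMatrix& C,
                const IntegerVector& pool, int nc, int cap, int mode,
                double gain_off, double gain_scl, double c_off, double c_scl,
                double c_target, double mult,
                int np, double Fw, double CR, int gens, int stagnation,
                const NumericMatrix& init) {
  Problem P;
  P.a = REAL(a); P.C = REAL(C); P.n = a.size();
  for (int i = 0; i < P.n; ++i) {
    if (pool[i] == 0) P.females.push_back(i); else P.males.push_back(i);
  }
  P.nc = nc; P.cap = cap; P.mode = mode;
  P.gain_off = gain_off; P.gain_scl = gain_scl;
  P.c_off = c_off; P.c_scl = c_scl; P.c_target = c_target; P.mult = mult;

  const int dim = 2 * P.n;
  std::vector<std::vector<double> > popu(np, std::vector<double>(dim));
  std::vector<double> fit(np);
  std::vector<int> nwork(P.n);
  const int n_init = std::min((int) init.nrow(), np);
  for (int i = 0; i < np; ++i) {
    if (i < n_init && init.ncol() == dim) {
      for (int j = 0; j < dim; ++j) popu[i][j] = init(i, j);
    } else {
      for (int j = 0; j < P.n; ++j) popu[i][j] = -1.0 + unif_rand() * (cap + 2.0);
      for (int j = P.n; j < dim; ++j) popu[i][j] = unif_rand();
    }
    decode(P, popu[i].data(), nwork);
    fit[i] = fitness(P, nwork);
  }
  int best = 0;
  for (int i = 1; i < np; ++i) if (fit[i] > fit[best]) best = i;
  double best_fit = fit[best];
  std::vector<double> best_genome = popu[best];

  std::vector<double> trial(dim);
  int stagnant = 0;
  for (int g = 0; g < gens && stagnant < stagnation; ++g) {
    bool improved = false;
    for (int i = 0; i < np; ++i) {
      int r1, r2, r3;
      do { r1 = (int) (unif_rand() * np); } while (r1 == i);
      do { r2 = (int) (unif_rand() * np); } while (r2 == i || r2 == r1);
      do { r3 = (int) (unif_rand() * np); } while (r3 == i || r3 == r1 || r3 == r2);
      // per-trial parameter dither: keeps the search robust across both
      // fine-grained allocation moves (low CR) and larger jumps
      const double Fi = 0.5 * Fw + Fw * unif_rand();
      const double u = unif_rand();
      const double CRi = (u < 0.8) ? CR : CR + (1.0 - CR) * unif_rand();
      const int jrand = (int) (unif_rand() * dim);
      for (int j = 0; j < dim; ++j) {
        if (j == jrand || unif_rand() < CRi)
          trial[j] = popu[r1][j] + Fi * (popu[r2][j] - popu[r3][j]);
        else
          trial[j] = popu[i][j];
      }
      decode(P, trial.data(), nwork);
      const double f = fitness(P, nwork);
      if (f >= fit[i]) { popu[i] = trial; fit[i] = f; }
      if (f > best_fit) { best_fit = f; best_genome = trial; improved = true; }
    }
    stagnant = improved ? 0 : stagnant + 1;
  }

  decode(P, best_genome.data(), nwork);
  polish(P, nwork);
  best_fit = fitness(P, nwork);
  double gain, cbar;
  evaluate(P, nwork, gain, cbar);
  IntegerVector nvec(P.n);
  NumericVector keys(P.n);
  for (int i = 0; i < P.n; ++i) {
    nvec[i] = nwork[i];
    keys[i] = best_genome[P.n + i];
  }
  return List::create(_["n"] = nvec, _["keys"] = keys,
                      _["fitness"] = best_fit, _["gain"] = gain,
                      _["coancestry"] = cbar);
}

// Decode + evaluate a raw score vector without running the optimizer
// (exposed for the greedy anchor and for tests).
// [[Rcpp::export]]
List cpp_ocs_decode(const NumericVector& scores, const NumericVector& a,
                    const NumericMatrix& C, const IntegerVector& pool,
                    int nc, int cap) {
  Problem P;
  P.a = REAL(a); P.C = REAL(C); P.n = a.size();
  for (int i = 0; i < P.n; ++i) {
    if (pool[i] == 0) P.females.push_back(i); else P.males.push_back(i);
  }
  P.nc = nc; P.cap = cap; P.mode = 1;
  P.gain_off = P.c_off = 0.0; P.gain_scl = P.c_scl = 1.0;
  P.c_target = 0.0; P.mult = 0.0;
  std::vector<int> nwork(P.n);
  decode(P, REAL(scores), nwork);
  double gain, cbar;
  evaluate(P, nwork, gain, cbar);
  return List::create(_["n"] = IntegerVector(nwork.begin(), nwork.end()),
                      _["gain"] = gain, _["coancestry"] = cbar);
}
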