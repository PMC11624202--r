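// Forward Wright-Fisher generation kernel for a single random-mating deme.
//
// Haplotypes live in a flat row-major byte buffer (2N rows x S segregating
// sites). Column order is insertion order, not genomic order: a crossover
// mosaic only needs each site's coordinate, so new infinite-sites mutations
// are appended as fresh columns and the sample is sorted by position on the
// R side. Fixed and lost sites are compacted away every generation unless
// pruning is disabled (the fixation / drift calibration helpers track an
// allele into its absorbing states). Crossovers are Poissonised across the
// whole gamete pool: the total count is one Poisson draw per generation and
// each crossover lands on a uniform gamete at a uniform position, which is
// distributionally identical to per-gamete Poisson(rec L) draws. All
// randomness comes from R's RNG, so runs reproduce under set.seed.

// hot loops index flat byte buffers; container bounds assertions (enabled
// by some toolchains) cost several-fold here and are redundant given the
// explicit size bookkeeping
#ifdef _GLIBCXX_ASSERTIONS
#undef _GLIBCXX_ASSERTIONS
#endif

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export(name = ".wf_run_cpp")]]
List wf_run_cpp(IntegerMatrix H0, NumericVector pos0, NumericVector s0,
                LogicalVector sel0, int gens, int n_next, double mu,
                double rec, double L, double s_new, double h, double eps,
                double neutral_fraction, bool eps_loci, bool prune,
                double max_entries) {
  RNGScope scope;
  int n_hap = H0.nrow();
  int S = H0.ncol();
  std::vector<unsigned char> cur((size_t) n_hap * S);
  for (int i = 0; i < n_hap; ++i)
    for (int j = 0; j < S; ++j)
      cur[(size_t) i * S + j] = (unsigned char) H0(i, j);
  std::vector<double> pos(pos0.begin(), pos0.end());
  std::vector<double> ssite(s0.begin(), s0.end());
  std::vector<unsigned char> sel(S);
  for (int j = 0; j < S; ++j) sel[j] = sel0[j] ? 1 : 0;

  const double log_floor = std::log(1e-12);
  const double log_eps = eps > 0 ?
      (1 - eps > 1e-12 ? std::log(1 - eps) : log_floor) : 0.0;

  std::vector<unsigned char> next;
  std::vector<double> cumw, logw, loghet, loghom, cuts;
  std::vector<int> del, cs, keep, co_gam;
  std::vector<double> co_pos;

  for (int g = 0; g < gens; ++g) {
    int N = n_hap / 2;
    S = (int) pos.size();

    // per-site log-fitness contributions of the deleterious sites
    del.clear(); loghet.clear(); loghom.clear();
    for (int j = 0; j < S; ++j) {
      if (ssite[j] < 0) {
        del.push_back(j);
        double whet = 1 + h * ssite[j], whom = 1 + ssite[j];
        loghet.push_back(whet > 1e-12 ? std::log(whet) : log_floor);
        loghom.push_back(whom > 1e-12 ? std::log(whom) : log_floor);
      }
    }

    // cumulative relative fitness over the N parents
    cumw.resize(N);
    if (del.empty()) {
      for (int i = 0; i < N; ++i) cumw[i] = i + 1.0;
    } else {
      logw.assign(N, 0.0);
      double mx = -1e300;
      for (int i = 0; i < N; ++i) {
        const unsigned char *a = &cur[(size_t) (2 * i) * S];
        const unsigned char *b = &cur[(size_t) (2 * i + 1) * S];
        int k = 0;
        double lw = 0.0;
        for (size_t d = 0; d < del.size(); ++d) {
          int dose = a[del[d]] + b[del[d]];
          if (dose == 1) { lw += loghet[d]; k += 1; }
          else if (dose == 2) { lw += loghom[d]; k += eps_loci ? 1 : 2; }
        }
        if (eps > 0 && k > 1) lw += log_eps * (k * (k - 1.0) / 2.0);
        logw[i] = lw;
        if (lw > mx) mx = lw;
      }
      double acc = 0.0;
      for (int i = 0; i < N; ++i) {
        acc += std::exp(logw[i] - mx);
        cumw[i] = acc;
      }
    }
    double wtot = cumw[N - 1];

    int m2 = 2 * n_next;
    int n_new = (int) R::rpois((double) m2 * mu * L);
    int S_out = S + n_new;
    if ((double) m2 * S_out > max_entries)
      stop("population state exceeds memory budget; increase scaling_factor");

    // Poissonised crossovers over the gamete pool, grouped by gamete
    int n_co = (rec > 0 && S > 0) ?
        (int) R::rpois((double) m2 * rec * L) : 0;
    co_gam.assign(n_co, 0);
    co_pos.assign(n_co, 0.0);
    for (int c = 0; c < n_co; ++c) {
      int gidx = (int) (unif_rand() * m2);
      co_gam[c] = gidx >= m2 ? m2 - 1 : gidx;
      co_pos[c] = unif_rand() * L;
    }

    next.assign((size_t) m2 * S_out, 0);
    for (int gam = 0; gam < m2; ++gam) {
      double u = unif_rand() * wtot;
      int p = (int) (std::lower_bound(cumw.begin(), cumw.end(), u) -
                     cumw.begin());
      if (p >= N) p = N - 1;
      int start = unif_rand() < 0.5 ? 0 : 1;
      if (S > 0) {
        unsigned char *dst = &next[(size_t) gam * S_out];
        cuts.clear();
        for (int c = 0; c < n_co; ++c)
          if (co_gam[c] == gam) cuts.push_back(co_pos[c]);
        const unsigned char *h1 = &cur[(size_t) (2 * p + start) * S];
        if (cuts.empty()) {
          std::memcpy(dst, h1, S);
        } else {
          std::sort(cuts.begin(), cuts.end());
          const unsigned char *h2 =
              &cur[(size_t) (2 * p + 1 - start) * S];
          for (int j = 0; j < S; ++j) {
            int seg = (int) (std::upper_bound(cuts.begin(), cuts.end(),
                                              pos[j]) - cuts.begin());
            dst[j] = (seg % 2 == 0) ? h1[j] : h2[j];
          }
        }
      }
    }

    // new infinite-sites mutations, one carrier gamete each
    for (int mnew = 0; mnew < n_new; ++mnew) {
      int target = (int) (unif_rand() * m2);
      if (target >= m2) target = m2 - 1;
      next[(size_t) target * S_out + S + mnew] = 1;
      pos.push_back(unif_rand() * L);
      bool is_sel = unif_rand() >= neutral_fraction;
      sel.push_back(is_sel ? 1 : 0);
      ssite.push_back(is_sel ? s_new : 0.0);
    }
    S = S_out;

    if (prune && S > 0) {
      cs.assign(S, 0);
      for (int gam = 0; gam < m2; ++gam) {
        const unsigned char *row = &next[(size_t) gam * S];
        for (int j = 0; j < S; ++j) cs[j] += row[j];
      }
      keep.clear();
      for (int j = 0; j < S; ++j)
        if (cs[j] > 0 && cs[j] < m2) keep.push_back(j);
      int S2 = (int) keep.size();
      if (S2 < S) {
        for (int gam = 0; gam < m2; ++gam) {
          const unsigned char *src = &next[(size_t) gam * S];
          unsigned char *dst = &next[(size_t) gam * S2];
          for (int k = 0; k < S2; ++k) dst[k] = src[keep[k]];
        }
        next.resize((size_t) m2 * S2);
        for (int k = 0; k < S2; ++k) {
          pos[k] = pos[keep[k]];
          ssite[k] = ssite[keep[k]];
          sel[k] = sel[keep[k]];
        }
        pos.resize(S2); ssite.resize(S2); sel.resize(S2);
        S = S2;
      }
    }
    cur.swap(next);
    n_hap = m2;
  }

  S = (int) pos.size();
  IntegerMatrix H(n_hap, S);
  for (int i = 0; i < n_hap; ++i)
    for (int j = 0; j < S; ++j) H(i, j) = cur[(size_t) i * S + j];
  return List::create(_["H"] = H,
                      _["pos"] = NumericVector(pos.begin(), pos.end()),
                      _["s_site"] = NumericVector(ssite.begin(),
                                                  ssite.end()),
                      _["sel_site"] = LogicalVector(sel.begin(),
                                                    sel.end()));
}
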