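// Monte-Carlo oracle for the two-locus sampling distribution: simulates the
// two-locus ancestral recombination graph and accumulates, per replicate,
// marginal-tree branch lengths indexed by descendant set.  Used by the test
// suite as an estimator of the factored likelihood g that is independent of
// the recursion solver.

#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

static inline int popcount32(unsigned x) {
  int c = 0;
  while (x) { c += x & 1u; x >>= 1; }
  return c;
}

// [[Rcpp::export(name = ".tl_mc_oracle")]]
DataFrame tl_mc_oracle(int n, double theta, double rho, int reps) {
  if (n < 2 || n > 16) stop("oracle supports 2 <= n <= 16");
  std::map<unsigned long long, std::pair<double, double>> bins; // key -> (sum, sumsq)
  std::vector<char> hasA(2 * n), hasB(2 * n);
  std::vector<unsigned> mA(2 * n), mB(2 * n);

  for (int rep = 0; rep < reps; ++rep) {
    int cap = 2 * n;
    for (int i = 0; i < cap; ++i) {
      hasA[i] = hasB[i] = (i < n);
      mA[i] = mB[i] = (i < n) ? (1u << i) : 0u;
    }
    std::map<unsigned, double> LA, LB;
    double LAtot = 0, LBtot = 0;
    bool doneA = false, doneB = false;
    while (true) {
      int nA = 0, nB = 0, nfull = 0, k = 0;
      for (int i = 0; i < cap; ++i) {
        if (hasA[i]) ++nA;
        if (hasB[i]) ++nB;
      }
      if (!doneA && nA <= 1) {
        doneA = true;
        for (int i = 0; i < cap; ++i) hasA[i] = 0;
        nA = 0;
      }
      if (!doneB && nB <= 1) {
        doneB = true;
        for (int i = 0; i < cap; ++i) hasB[i] = 0;
        nB = 0;
      }
      if (doneA && doneB) break;
      std::vector<int> alive;
      for (int i = 0; i < cap; ++i) {
        if (hasA[i] || hasB[i]) alive.push_back(i);
        if (hasA[i] && hasB[i]) ++nfull;
      }
      k = (int)alive.size();
      double rate_c = k * (k - 1) / 2.0;
      double rate_r = rho / 2.0 * nfull;
      double tot = rate_c + rate_r;
      double dt = R::rexp(1.0 / tot);
      for (int i = 0; i < cap; ++i) {
        if (hasA[i]) { LA[mA[i]] += dt; LAtot += dt; }
        if (hasB[i]) { LB[mB[i]] += dt; LBtot += dt; }
      }
      if (R::unif_rand() < rate_c / tot) {
        int ii = (int)(R::unif_rand() * k); if (ii == k) ii = k - 1;
        int jj = (int)(R::unif_rand() * (k - 1)); if (jj == k - 1) jj = k - 2;
        if (jj >= ii) ++jj;
        int a = alive[ii], b = alive[jj];
        hasA[a] = hasA[a] || hasA[b];
        hasB[a] = hasB[a] || hasB[b];
        mA[a] |= mA[b]; mB[a] |= mB[b];
        hasA[b] = hasB[b] = 0; mA[b] = mB[b] = 0;
      } else {
        std::vector<int> fulls;
        for (int i = 0; i < cap; ++i) if (hasA[i] && hasB[i]) fulls.push_back(i);
        int ii = (int)(R::unif_rand() * fulls.size());
        if (ii == (int)fulls.size()) --ii;
        int a = fulls[ii];
        int slot = -1;
        for (int i = 0; i < cap; ++i) if (!hasA[i] && !hasB[i]) { slot = i; break; }
        if (slot < 0) {
          hasA.push_back(0); hasB.push_back(1);
          mA.push_back(0); mB.push_back(mB[a]);
          ++cap;
        } else {
          hasA[slot] = 0; hasB[slot] = 1; mA[slot] = 0; mB[slot] = mB[a];
        }
        hasB[a] = 0; mB[a] = 0;
      }
    }
    double wbase = std::exp(-(theta / 2.0) * (LAtot + LBtot)) / 4.0;
    std::map<unsigned long long, double> repsum;
    for (auto &pa : LA) for (auto &pb : LB) {
      unsigned maskA = pa.first, maskB = pb.first;
      int c11 = popcount32(maskA & maskB);
      int c10 = popcount32(maskA) - c11;
      int c01 = popcount32(maskB) - c11;
      int c00 = n - c11 - c10 - c01;
      unsigned long long key = ((unsigned long long)c00 << 24) |
        ((unsigned long long)c01 << 16) | ((unsigned long long)c10 << 8) |
        (unsigned long long)c11;
      repsum[key] += pa.second * pb.second * wbase;
    }
    for (auto &kv : repsum) {
      bins[kv.first].first += kv.second;
      bins[kv.first].second += kv.second * kv.second;
    }
  }

  int nb = (int)bins.size();
  IntegerVector c00(nb), c01(nb), c10(nb), c11(nb);
  NumericVector ghat(nb), gse(nb);
  int r = 0;
  for (auto &kv : bins) {
    int v00 = (int)(kv.first >> 24) & 255, v01 = (int)(kv.first >> 16) & 255,
        v10 = (int)(kv.first >> 8) & 255, v11 = (int)kv.first & 255;
    double mean = kv.second.first / reps;
    double varr = (kv.second.second / reps - mean * mean) / reps;
    // ordered probability: divide by the number of labelled arrangements
    double lmult = R::lgammafn(n + 1.0) - R::lgammafn(v00 + 1.0) -
      R::lgammafn(v01 + 1.0) - R::lgammafn(v10 + 1.0) - R::lgammafn(v11 + 1.0);
    double mult = std::exp(lmult);
    c00[r] = v00; c01[r] = v01; c10[r] = v10; c11[r] = v11;
    ghat[r] = mean / mult;
    gse[r] = std::sqrt(std::max(varr, 0.0)) / mult;
    ++r;
  }
  return DataFrame::create(_["c00"] = c00, _["c01"] = c01, _["c10"] = c10,
                           _["c11"] = c11, _["g"] = ghat, _["se"] = gse);
}
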