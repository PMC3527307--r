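// Coalescent-with-recombination simulator (Hudson-style, backwards in time)
// with a piecewise-constant recombination map, piecewise demography with
// optional within-epoch exponential growth, and finite-sites quadra-allelic
// mutation via a 4x4 transition matrix.  Time is measured in units of 2N
// generations: pairwise coalescence rate 1/N(t), per-lineage recombination
// rate rho_span/2, per-site mutation rate theta/2.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Seg {
  int l, r;                 // inclusive site range, 1-based
  unsigned long long mask;  // descendant samples
};

struct Lineage {
  std::vector<Seg> segs;    // sorted, disjoint
};

struct Mut {
  int site;
  unsigned long long mask;
  double t;
};

static void prune(Lineage &lin, unsigned long long full) {
  std::vector<Seg> keep;
  for (auto &s : lin.segs) if (s.mask != full) keep.push_back(s);
  lin.segs.swap(keep);
}

// merge two disjoint-sorted segment lists, unioning masks on overlap
static std::vector<Seg> merge_segs(const std::vector<Seg> &A,
                                   const std::vector<Seg> &B) {
  // collect cut points
  std::vector<int> cuts;
  for (auto &s : A) { cuts.push_back(s.l); cuts.push_back(s.r + 1); }
  for (auto &s : B) { cuts.push_back(s.l); cuts.push_back(s.r + 1); }
  std::sort(cuts.begin(), cuts.end());
  cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
  std::vector<Seg> out;
  size_t ia = 0, ib = 0;
  for (size_t c = 0; c + 1 < cuts.size(); ++c) {
    int l = cuts[c], r = cuts[c + 1] - 1;
    unsigned long long m = 0;
    while (ia < A.size() && A[ia].r < l) ++ia;
    if (ia < A.size() && A[ia].l <= l && A[ia].r >= r) m |= A[ia].mask;
    while (ib < B.size() && B[ib].r < l) ++ib;
    if (ib < B.size() && B[ib].l <= l && B[ib].r >= r) m |= B[ib].mask;
    if (m) {
      if (!out.empty() && out.back().r + 1 == l && out.back().mask == m) {
        out.back().r = r;
      } else {
        out.push_back({l, r, m});
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".arg_simulate")]]
List arg_simulate(int n, int L,
                  NumericVector w_prefix,   // length L cumulative map prefix
                  double theta,
                  NumericMatrix Q, NumericVector pi,
                  NumericVector ep_t, NumericVector ep_size,
                  NumericVector ep_growth) {
  if (n < 2 || n > 63) stop("simulator supports 2 <= n <= 63");
  unsigned long long full =
    (n == 63) ? ~0ULL >> 1 : ((1ULL << n) - 1ULL);
  std::vector<Lineage> lin(n);
  for (int i = 0; i < n; ++i) lin[i].segs.push_back({1, L, 1ULL << i});
  std::vector<Mut> muts;
  double t = 0;
  int epoch = 0, nep = ep_t.size();

  auto lin_rec_rate = [&](const Lineage &x) {
    if (x.segs.empty()) return 0.0;
    int lo = x.segs.front().l, hi = x.segs.back().r;
    if (hi <= lo) return 0.0;
    return (w_prefix[hi - 1] - w_prefix[lo - 1]) / 2.0;
  };
  auto lin_sites = [&](const Lineage &x) {
    long tot = 0;
    for (auto &s : x.segs) tot += s.r - s.l + 1;
    return (double)tot;
  };

  while (true) {
    // drop empty lineages
    std::vector<int> act;
    for (size_t i = 0; i < lin.size(); ++i)
      if (!lin[i].segs.empty()) act.push_back((int)i);
    int k = (int)act.size();
    if (k <= 1) break;
    double C = k * (k - 1) / 2.0;
    double Rtot = 0;
    for (int i : act) Rtot += lin_rec_rate(lin[i]);

    // next event time across epochs
    double dt_r = (Rtot > 0) ? R::rexp(1.0 / Rtot) : R_PosInf;
    double dt_c;
    {
      double tt = t;
      int ep = epoch;
      while (true) {
        double te = ep_t[ep], sz = ep_size[ep], gr = ep_growth[ep];
        double bound = (ep + 1 < nep) ? ep_t[ep + 1] : R_PosInf;
        double E = R::exp_rand();
        double cand;
        if (gr == 0) {
          cand = E * sz / C;
        } else {
          double base = std::exp(gr * (tt - te));
          double arg = base + gr * E * sz / C;
          cand = (arg > 0) ? std::log(arg) / gr - (tt - te) : R_PosInf;
        }
        if (tt + cand <= bound) { dt_c = tt + cand - t; break; }
        tt = bound; ++ep;
        if (ep >= nep) stop("internal: demography epochs exhausted");
      }
    }
    double dt = std::min(dt_r, dt_c);

    // mutation exposure over dt
    for (int i : act) {
      double ns = lin_sites(lin[i]);
      int nm = (int)R::rpois(theta / 2.0 * dt * ns);
      for (int mth = 0; mth < nm; ++mth) {
        double u = R::unif_rand() * ns;
        int site = -1;
        unsigned long long mask = 0;
        double acc = 0;
        for (auto &s : lin[i].segs) {
          double len = s.r - s.l + 1;
          if (u < acc + len) {
            site = s.l + (int)(u - acc);
            if (site > s.r) site = s.r;
            mask = s.mask;
            break;
          }
          acc += len;
        }
        if (site > 0) muts.push_back({site, mask, t + R::unif_rand() * dt});
      }
    }
    t += dt;
    while (epoch + 1 < nep && t >= ep_t[epoch + 1]) ++epoch;

    if (dt_r < dt_c) {
      // recombination: pick lineage proportional to its rate
      double u = R::unif_rand() * Rtot, acc = 0;
      int pick = act.back();
      for (int i : act) {
        acc += lin_rec_rate(lin[i]);
        if (u < acc) { pick = i; break; }
      }
      Lineage &x = lin[pick];
      int lo = x.segs.front().l, hi = x.segs.back().r;
      // breakpoint a in [lo, hi): weight w_a = W[a+1]-W[a]
      double wlo = w_prefix[lo - 1], whi = w_prefix[hi - 1];
      double uu = wlo + R::unif_rand() * (whi - wlo);
      // binary search for a with W[a] <= uu < W[a+1], a in [lo, hi)
      int a = lo, b = hi;
      while (a + 1 < b) {
        int mid = (a + b) / 2;
        if (w_prefix[mid - 1] <= uu) a = mid; else b = mid;
      }
      Lineage left, right;
      for (auto &s : x.segs) {
        if (s.r <= a) left.segs.push_back(s);
        else if (s.l > a) right.segs.push_back(s);
        else {
          left.segs.push_back({s.l, a, s.mask});
          right.segs.push_back({a + 1, s.r, s.mask});
        }
      }
      if (left.segs.empty() || right.segs.empty()) continue;  // no-op split
      lin[pick] = left;
      lin.push_back(right);
    } else {
      // coalescence of a uniform pair
      int ii = (int)(R::unif_rand() * k); if (ii >= k) ii = k - 1;
      int jj = (int)(R::unif_rand() * (k - 1)); if (jj >= k - 1) jj = k - 2;
      if (jj >= ii) ++jj;
      Lineage merged;
      merged.segs = merge_segs(lin[act[ii]].segs, lin[act[jj]].segs);
      prune(merged, full);
      lin[act[ii]] = merged;
      lin[act[jj]].segs.clear();
    }
  }

  // realize mutations, oldest first
  std::sort(muts.begin(), muts.end(),
            [](const Mut &a, const Mut &b) { return a.t > b.t; });
  std::vector<int> sites;
  for (auto &m : muts) sites.push_back(m.site);
  std::sort(sites.begin(), sites.end());
  sites.erase(std::unique(sites.begin(), sites.end()), sites.end());
  std::vector<int> site_of(L + 1, -1);
  for (size_t s = 0; s < sites.size(); ++s) site_of[sites[s]] = (int)s;
  int S = (int)sites.size();
  std::vector<std::vector<int>> base(S, std::vector<int>(n));
  double cum[4];
  for (int s = 0; s < S; ++s) {
    double u = R::unif_rand(), acc = 0;
    int b0 = 3;
    for (int b = 0; b < 4; ++b) { acc += pi[b]; if (u < acc) { b0 = b; break; } }
    for (int i = 0; i < n; ++i) base[s][i] = b0;
  }
  for (auto &m : muts) {
    int s = site_of[m.site];
    int cur = -1;
    for (int i = 0; i < n; ++i)
      if (m.mask & (1ULL << i)) { cur = base[s][i]; break; }
    if (cur < 0) continue;
    double u = R::unif_rand(), acc = 0;
    int nb = 3;
    for (int b = 0; b < 4; ++b) {
      cum[b] = Q(cur, b); acc += cum[b];
      if (u < acc) { nb = b; break; }
    }
    for (int i = 0; i < n; ++i)
      if (m.mask & (1ULL << i)) base[s][i] = nb;
  }
  // keep segregating sites
  std::vector<int> segsite;
  for (int s = 0; s < S; ++s) {
    int first = base[s][0];
    for (int i = 1; i < n; ++i)
      if (base[s][i] != first) { segsite.push_back(s); break; }
  }
  IntegerVector pos(segsite.size());
  IntegerMatrix alle(n, segsite.size());
  for (size_t c = 0; c < segsite.size(); ++c) {
    pos[c] = sites[segsite[c]];
    for (int i = 0; i < n; ++i) alle(i, c) = base[segsite[c]][i] + 1;
  }
  return List::create(_["positions"] = pos, _["alleles"] = alle,
                      _["n_mutations"] = (int)muts.size());
}
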