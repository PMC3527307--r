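// Reversible-jump MCMC over piecewise-constant recombination maps under the
// pairwise composite likelihood.  Change points live at midpoints between
// adjacent SNPs; the prior is Poisson(lambda) on their number, uniform on
// their positions, iid (exponential / gamma / log-normal) on segment heights.
// Birth/death moves follow the standard change-point construction: a birth
// draws u ~ U(0,1), splits the containing segment's height h into
// h1, h2 with h1^w1 h2^w2 = h and h1/h2 = u/(1-u), and carries the
// dimension-matching Jacobian (h1+h2)^2 / h.
//
// Pair log-likelihoods are monotone-cubic interpolants (precomputed values
// and slopes on a rho knot grid, extended beyond the exact grid by Pade
// evaluation) of the two-locus lookup table; beyond the last knot the
// log-likelihood is held at its asymptotic (independent-loci) value.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// interpolation context with an O(1) acceleration index into the knots;
// values and slopes are interleaved per curve (knot-contiguous) so one
// evaluation touches one cache line pair
struct InterpCtx {
  const double *knots;
  std::vector<double> VM;    // per curve: K values then K slopes
  int K, U;
  std::vector<int> accel;    // cell -> starting knot index
  double inv_cell, xmax;
  void init(const NumericVector &kn, const NumericMatrix &Vm,
            const NumericMatrix &Mm) {
    knots = REAL(kn);
    K = kn.size(); U = Vm.nrow();
    VM.resize(2 * (size_t)K * U);
    const double *V = REAL(Vm), *M = REAL(Mm);
    for (int u = 0; u < U; ++u) {
      for (int k = 0; k < K; ++k) {
        VM[2 * (size_t)K * u + 2 * k] = V[u + (size_t)k * U];
        VM[2 * (size_t)K * u + 2 * k + 1] = M[u + (size_t)k * U];
      }
    }
    xmax = knots[K - 1];
    int ncell = 4096;
    accel.assign(ncell + 1, 0);
    inv_cell = ncell / xmax;
    int j = 0;
    for (int c = 0; c <= ncell; ++c) {
      double x = c / inv_cell;
      while (j + 1 < K - 1 && knots[j + 1] <= x) ++j;
      accel[c] = j;
    }
  }
  inline double eval(int u, double x) const {
    const double *row = &VM[2 * (size_t)K * u];
    if (!(x < xmax)) return row[2 * (K - 1)];  // incl. NaN guard
    if (x <= 0) return row[0];
    int lo = accel[(int)(x * inv_cell)];
    while (knots[lo + 1] <= x) ++lo;
    double h = knots[lo + 1] - knots[lo];
    double t = (x - knots[lo]) / h;
    double t2 = t * t, t3 = t2 * t;
    double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + t;
    double h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
    const double *c0 = row + 2 * lo;
    return h00 * c0[0] + h10 * h * c0[1] + h01 * c0[2] + h11 * h * c0[3];
  }
};

static double log_height_prior(double h, int type, const NumericVector &par) {
  if (type == 0) return -std::log(par[0]) - h / par[0];
  if (type == 1) return R::dgamma(h, par[0], 1.0 / par[1], 1);
  return R::dlnorm(h, par[0], par[1], 1);
}

static double draw_height_prior(int type, const NumericVector &par) {
  if (type == 0) return R::rexp(par[0]);
  if (type == 1) return R::rgamma(par[0], 1.0 / par[1]);
  return R::rlnorm(par[0], par[1]);
}

// [[Rcpp::export(name = ".rj_mcmc")]]
List rj_mcmc(NumericVector pos, IntegerVector pair_i, IntegerVector pair_j,
             IntegerVector pair_sig,
             NumericVector knots, NumericMatrix V, NumericMatrix Msl,
             double x0, double x1, int cp_prior_type, double cp_par,
             int prior_type, NumericVector prior_par,
             int iters, int burn_in, int thin,
             bool likelihood_on, double sigma_height, int pair_span,
             IntegerVector init_cps, NumericVector init_hts) {
  int S = pos.size();
  int M = S - 1;                    // candidate change-point slots
  int P = pair_i.size();
  std::vector<double> mid(M);
  InterpCtx ictx;
  ictx.init(knots, V, Msl);
  for (int s = 0; s < M; ++s) mid[s] = (pos[s] + pos[s + 1]) / 2.0;

  std::vector<int> cps;             // sorted midpoint indices
  std::vector<double> hts;
  std::vector<char> occ(M, 0);
  if (init_hts.size() == init_cps.size() + 1) {
    for (int i = 0; i < init_cps.size(); ++i) {
      cps.push_back(init_cps[i]);
      occ[init_cps[i]] = 1;
    }
    for (int i = 0; i < init_hts.size(); ++i) hts.push_back(init_hts[i]);
  } else {
    hts.push_back(draw_height_prior(prior_type, prior_par));
  }

  // cumulative rho at each SNP and per-pair cached log-likelihoods
  std::vector<double> Cm(S, 0.0), Cm_new(S, 0.0);
  std::vector<double> pll(P, 0.0), pll_new;
  std::vector<int> pair_first(S + 1, 0);  // pairs sorted by i
  for (int p = 0; p < P; ++p) pair_first[pair_i[p] + 1]++;
  for (int s = 0; s < S; ++s) pair_first[s + 1] += pair_first[s];

  auto seg_of_mid = [&](int w) {
    // segment index containing midpoint w = #change points with index <= w
    return (int)(std::upper_bound(cps.begin(), cps.end(), w) - cps.begin());
  };
  auto seg_bounds = [&](int g, double &l, double &r) {
    int k = (int)cps.size();
    l = (g == 0) ? x0 : mid[cps[g - 1]];
    r = (g == k) ? x1 : mid[cps[g]];
  };
  auto rebuild_C = [&](std::vector<double> &C, const std::vector<int> &cc,
                       const std::vector<double> &hh, int from) {
    int k = (int)cc.size();
    int seg = 0;
    while (seg < k && cc[seg] < from) ++seg;
    if (from == 0) C[0] = 0;
    for (int s = from; s < S - 1; ++s) {
      double add;
      if (seg < k && cc[seg] == s) {
        add = hh[seg] * (mid[s] - pos[s]) + hh[seg + 1] * (pos[s + 1] - mid[s]);
        ++seg;
      } else {
        add = hh[seg] * (pos[s + 1] - pos[s]);
      }
      C[s + 1] = C[s] + add;
    }
  };
  rebuild_C(Cm, cps, hts, 0);
  if (likelihood_on) {
    for (int p = 0; p < P; ++p) {
      pll[p] = ictx.eval(pair_sig[p], Cm[pair_j[p]] - Cm[pair_i[p]]);
    }
  }
  double CL = 0;
  for (int p = 0; p < P; ++p) CL += pll[p];

  // proposal evaluation: recompute Cm from interval u onwards and affected
  // pairs (i <= v, j >= u+1); returns delta CL, staging new values
  std::vector<int> touched;
  auto delta_CL = [&](const std::vector<int> &cc, const std::vector<double> &hh,
                      int u, int v) {
    if (!likelihood_on) return 0.0;
    Cm_new = Cm;
    rebuild_C(Cm_new, cc, hh, u);
    touched.clear();
    double d = 0;
    int ilo = std::max(0, u - pair_span + 1);
    for (int i = ilo; i <= v && i < S; ++i) {
      for (int p = pair_first[i]; p < pair_first[i + 1]; ++p) {
        if (pair_j[p] < u + 1) continue;
        double nv = ictx.eval(pair_sig[p], Cm_new[pair_j[p]] - Cm_new[pair_i[p]]);
        pll_new.push_back(nv);
        touched.push_back(p);
        d += nv - pll[p];
      }
    }
    return d;
  };
  auto commit = [&]() {
    Cm.swap(Cm_new);
    for (size_t q = 0; q < touched.size(); ++q) pll[touched[q]] = pll_new[q];
  };

  int n_samp = (iters - burn_in) / thin;
  NumericMatrix rate_samples(likelihood_on ? n_samp : 0,
                             likelihood_on ? (S - 1) : 0);
  IntegerVector k_samples(n_samp);
  NumericVector h_samples(n_samp), cl_trace(n_samp);
  IntegerVector prop(4), acc(4);
  double qmid = (x0 + x1) / 2.0;
  int samp = 0;
  long consec_reject = 0;
  bool stalled = false;

  for (int it = 0; it < iters; ++it) {
    int k = (int)cps.size();
    double u01 = R::unif_rand();
    int mv = (int)(u01 * 4); if (mv > 3) mv = 3;
    bool accepted = false;
    ++prop[mv];
    pll_new.clear();

    if (mv == 0 && k < M) {  // birth
      int r = (int)(R::unif_rand() * (M - k)); if (r >= M - k) r = M - k - 1;
      int w = -1;
      for (int s = 0, cnt = 0; s < M; ++s) {
        if (!occ[s]) { if (cnt == r) { w = s; break; } ++cnt; }
      }
      int g = seg_of_mid(w);
      double segl, segr; seg_bounds(g, segl, segr);
      double h = hts[g];
      // U-shaped split distribution favours occasional extreme height
      // ratios (hotspot-scale jumps); its density enters the ratio below
      double uu = R::rbeta(0.3, 0.3);
      if (uu < 1e-9) uu = 1e-9;
      if (uu > 1 - 1e-9) uu = 1 - 1e-9;
      double w1 = (mid[w] - segl) / (segr - segl), w2 = 1.0 - w1;
      double h1 = h * std::pow(uu / (1 - uu), w2);
      double h2 = h * std::pow((1 - uu) / uu, w1);
      std::vector<int> cc = cps; cc.insert(cc.begin() + g, w);
      std::vector<double> hh = hts;
      hh[g] = h1; hh.insert(hh.begin() + g + 1, h2);
      int u = (g == 0) ? 0 : cps[g - 1];
      int v = (g == k) ? S - 2 : cps[g];
      double cp_ratio = (cp_prior_type == 0)
        ? std::log(cp_par) - std::log(k + 1.0)   // Poisson(mean cp_par)
        : -cp_par;                               // penalty per change point
      double la = delta_CL(cc, hh, u, v) + cp_ratio +
        log_height_prior(h1, prior_type, prior_par) +
        log_height_prior(h2, prior_type, prior_par) -
        log_height_prior(h, prior_type, prior_par) +
        2.0 * std::log(h1 + h2) - std::log(h) -
        R::dbeta(uu, 0.3, 0.3, 1);
      if (std::log(R::unif_rand()) < la) {
        cps = cc; hts = hh; occ[w] = 1;
        if (likelihood_on) commit();
        accepted = true;
      }
    } else if (mv == 1 && k > 0) {  // death
      int d = (int)(R::unif_rand() * k); if (d >= k) d = k - 1;
      int w = cps[d];
      double segl, segr;
      segl = (d == 0) ? x0 : mid[cps[d - 1]];
      segr = (d == k - 1) ? x1 : mid[cps[d + 1]];
      double w1 = (mid[w] - segl) / (segr - segl), w2 = 1.0 - w1;
      double h1 = hts[d], h2 = hts[d + 1];
      double h = std::pow(h1, w1) * std::pow(h2, w2);
      std::vector<int> cc = cps; cc.erase(cc.begin() + d);
      std::vector<double> hh = hts;
      hh[d] = h; hh.erase(hh.begin() + d + 1);
      int u = (d == 0) ? 0 : cps[d - 1];
      int v = (d == k - 1) ? S - 2 : cps[d + 1];
      double cp_ratio = (cp_prior_type == 0)
        ? std::log((double)k) - std::log(cp_par)
        : cp_par;
      double la = delta_CL(cc, hh, u, v) + cp_ratio +
        log_height_prior(h, prior_type, prior_par) -
        log_height_prior(h1, prior_type, prior_par) -
        log_height_prior(h2, prior_type, prior_par) +
        std::log(h) - 2.0 * std::log(h1 + h2) +
        R::dbeta(h1 / (h1 + h2), 0.3, 0.3, 1);
      if (std::log(R::unif_rand()) < la) {
        cps = cc; hts = hh; occ[w] = 0;
        if (likelihood_on) commit();
        accepted = true;
      }
    } else if (mv == 2 && k > 0) {  // position move
      int d = (int)(R::unif_rand() * k); if (d >= k) d = k - 1;
      int lo = (d == 0) ? -1 : cps[d - 1];
      int hi = (d == k - 1) ? M : cps[d + 1];
      int ncand = hi - lo - 1;
      int r = (int)(R::unif_rand() * ncand); if (r >= ncand) r = ncand - 1;
      int w_new = lo + 1 + r;
      int w_old = cps[d];
      if (w_new == w_old) {
        accepted = true;
      } else {
        std::vector<int> cc = cps; cc[d] = w_new;
        int u = std::min(w_old, w_new), v = std::max(w_old, w_new);
        double la = delta_CL(cc, hts, u, v);
        if (std::log(R::unif_rand()) < la) {
          occ[w_old] = 0; occ[w_new] = 1; cps = cc;
          if (likelihood_on) commit();
          accepted = true;
        }
      }
    } else if (mv == 3) {  // height change
      int g = (int)(R::unif_rand() * (k + 1)); if (g > k) g = k;
      double h = hts[g];
      // symmetric log-scale mixture kernel: mostly local, sometimes bold
      double sig = (R::unif_rand() < 0.85) ? sigma_height : 5.0 * sigma_height;
      double hp = h * std::exp(sig * R::norm_rand());
      std::vector<double> hh = hts; hh[g] = hp;
      int u = (g == 0) ? 0 : cps[g - 1];
      int v = (g == k) ? S - 2 : cps[g];
      double la = delta_CL(cps, hh, u, v) +
        log_height_prior(hp, prior_type, prior_par) -
        log_height_prior(h, prior_type, prior_par) +
        std::log(hp) - std::log(h);
      if (std::log(R::unif_rand()) < la) {
        hts = hh;
        if (likelihood_on) commit();
        accepted = true;
      }
    }

    if (accepted) { ++acc[mv]; consec_reject = 0; }
    else if (++consec_reject > 10000 && it > 20000) stalled = true;

    if (it >= burn_in && (it - burn_in) % thin == 0 && samp < n_samp) {
      k_samples[samp] = (int)cps.size();
      int gq = 0;
      for (size_t d = 0; d < cps.size(); ++d) if (mid[cps[d]] <= qmid) ++gq;
      h_samples[samp] = hts[gq];
      if (likelihood_on) {
        CL = 0; for (int p = 0; p < P; ++p) CL += pll[p];
        cl_trace[samp] = CL;
        for (int s = 0; s < S - 1; ++s) {
          rate_samples(samp, s) = (Cm[s + 1] - Cm[s]) / (pos[s + 1] - pos[s]);
        }
      }
      ++samp;
    }
  }

  return List::create(
    _["rate_samples"] = rate_samples, _["k_samples"] = k_samples,
    _["height_samples"] = h_samples, _["cl_trace"] = cl_trace,
    _["proposed"] = prop, _["accepted"] = acc, _["stalled"] = stalled);
}
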