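#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// ---- beta-MNTD engine ------------------------------------------------------
//
// Communities are mapped into "tip space" per null (taxon k occupies tip
// perm[k]); nearest-taxon minima are then contiguous column scans over the
// unpermuted distance matrix.

// MN(j, t) = min over tips b occupied by sample j of D(t, b), for all tips t.
static void nearest_taxon_tips(const NumericMatrix &D,
                               const std::vector<std::vector<int> > &occ,
                               std::vector<double> &MN, int S) {
  const int n = (int)occ.size();
  for (int j = 0; j < n; ++j) {
    double *mj = &MN[(size_t)j * S];
    std::fill(mj, mj + S, R_PosInf);
    for (size_t a = 0; a < occ[j].size(); ++a) {
      const double *col = &D(0, occ[j][a]);
      for (int t = 0; t < S; ++t)
        if (col[t] < mj[t]) mj[t] = col[t];
    }
  }
}

// B(i,j) = 0.5 * (sum_k w_ik MN(j, tip_ik) + sum_l w_jl MN(i, tip_jl))
static void bmntd_pairs(const std::vector<std::vector<int> > &occ,
                        const std::vector<std::vector<double> > &w,
                        const std::vector<double> &MN, int S,
                        NumericMatrix &B) {
  const int n = (int)occ.size();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      const double *mj = &MN[(size_t)j * S];
      for (size_t a = 0; a < occ[i].size(); ++a)
        s += w[i][a] * mj[occ[i][a]];
      const double *mi = &MN[(size_t)i * S];
      for (size_t a = 0; a < occ[j].size(); ++a)
        s += w[j][a] * mi[occ[j][a]];
      B(i, j) = B(j, i) = 0.5 * s;
    }
}

static void occupy(const NumericMatrix &F, const std::vector<int> &perm,
                   std::vector<std::vector<int> > &occ,
                   std::vector<std::vector<double> > &w) {
  const int n = F.nrow(), S = F.ncol();
  for (int i = 0; i < n; ++i) {
    occ[i].clear();
    w[i].clear();
  }
  for (int k = 0; k < S; ++k) {
    int t = perm[k];
    for (int i = 0; i < n; ++i)
      if (F(i, k) > 0) {
        occ[i].push_back(t);
        w[i].push_back(F(i, k));
      }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_bmntd(NumericMatrix F, NumericMatrix D) {
  const int n = F.nrow(), S = F.ncol();
  std::vector<int> id(S);
  for (int k = 0; k < S; ++k) id[k] = k;
  std::vector<std::vector<int> > occ(n);
  std::vector<std::vector<double> > w(n);
  occupy(F, id, occ, w);
  std::vector<double> MN((size_t)n * S);
  NumericMatrix B(n, n);
  nearest_taxon_tips(D, occ, MN, S);
  bmntd_pairs(occ, w, MN, S, B);
  return B;
}

// Observed beta-MNTD plus null mean/sd from shuffling taxa across tree tips.
// Uses R's RNG (set.seed upstream controls reproducibility).
// [[Rcpp::export]]
List cpp_bnti_null(NumericMatrix F, NumericMatrix D, int n_null) {
  const int n = F.nrow(), S = F.ncol();
  std::vector<int> perm(S);
  for (int k = 0; k < S; ++k) perm[k] = k;
  std::vector<std::vector<int> > occ(n);
  std::vector<std::vector<double> > w(n);
  std::vector<double> MN((size_t)n * S);
  NumericMatrix B(n, n), obs(n, n);
  occupy(F, perm, occ, w);
  nearest_taxon_tips(D, occ, MN, S);
  bmntd_pairs(occ, w, MN, S, obs);

  NumericMatrix msum(n, n), m2(n, n);
  for (int r = 0; r < n_null; ++r) {
    for (int k = S - 1; k > 0; --k) {
      int j = (int)std::floor(unif_rand() * (k + 1));
      if (j > k) j = k;
      std::swap(perm[k], perm[j]);
    }
    occupy(F, perm, occ, w);
    nearest_taxon_tips(D, occ, MN, S);
    bmntd_pairs(occ, w, MN, S, B);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double x = B(i, j);
        double d = x - msum(i, j);
        msum(i, j) += d / (r + 1);
        m2(i, j) += d * (x - msum(i, j));
      }
  }
  NumericMatrix mu(n, n), sd(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      mu(i, j) = mu(j, i) = msum(i, j);
      double v = n_null > 1 ? m2(i, j) / (n_null - 1) : 0.0;
      sd(i, j) = sd(j, i) = std::sqrt(v);
    }
  return List::create(_["obs"] = obs, _["null_mean"] = mu, _["null_sd"] = sd);
}

// ---- Raup-Crick engine -----------------------------------------------------

static double bray_curtis_pair(const int *x, const int *y, int S) {
  double num = 0.0, den = 0.0;
  for (int k = 0; k < S; ++k) {
    num += std::abs((double)x[k] - (double)y[k]);
    den += (double)x[k] + (double)y[k];
  }
  return den > 0 ? num / den : 0.0;
}

// Draw one null community preserving richness r and total reads N: taxa
// chosen without replacement with probability proportional to occurrence
// frequency (Efraimidis-Spirakis keys), one read seeded per chosen taxon,
// the remainder multinomial proportional to regional relative abundance.
static void null_community(int r, int N, const NumericVector &occf,
                           const NumericVector &gamma, int S,
                           std::vector<int> &out,
                           std::vector<double> &keys, std::vector<int> &ord,
                           std::vector<double> &prob, std::vector<int> &draw) {
  for (int k = 0; k < S; ++k) {
    double u = unif_rand();
    keys[k] = occf[k] > 0 ? std::pow(u, 1.0 / occf[k]) : -1.0;
    ord[k] = k;
  }
  std::partial_sort(ord.begin(), ord.begin() + r, ord.end(),
                    [&](int a, int b) { return keys[a] > keys[b]; });
  std::fill(out.begin(), out.end(), 0);
  double gs = 0.0;
  for (int a = 0; a < r; ++a) gs += gamma[ord[a]];
  for (int a = 0; a < r; ++a) prob[a] = gs > 0 ? gamma[ord[a]] / gs : 1.0 / r;
  int rest = N - r;
  if (rest > 0) {
    ::rmultinom(rest, prob.data(), r, draw.data());
    for (int a = 0; a < r; ++a) out[ord[a]] = 1 + draw[a];
  } else {
    for (int a = 0; a < r; ++a) out[ord[a]] = 1;
  }
}

// Raup-Crick (Bray-Curtis) for all sample pairs; per replicate one null
// community per sample, all pairwise Bray-Curtis values compared to observed.
// [[Rcpp::export]]
NumericMatrix cpp_rc_bray(IntegerMatrix counts, int n_null) {
  const int n = counts.nrow(), S = counts.ncol();
  NumericVector occf(S), gamma(S);
  double grand = 0.0;
  for (int k = 0; k < S; ++k) {
    double tot = 0.0;
    int oc = 0;
    for (int i = 0; i < n; ++i) {
      tot += counts(i, k);
      if (counts(i, k) > 0) ++oc;
    }
    occf[k] = oc;
    gamma[k] = tot;
    grand += tot;
  }
  for (int k = 0; k < S; ++k) gamma[k] /= grand;

  std::vector<int> rich(n), reads(n);
  std::vector<std::vector<int> > rows(n, std::vector<int>(S));
  for (int i = 0; i < n; ++i) {
    int r = 0, N = 0;
    for (int k = 0; k < S; ++k) {
      int c = counts(i, k);
      rows[i][k] = c;
      if (c > 0) ++r;
      N += c;
    }
    rich[i] = r;
    reads[i] = N;
  }

  NumericMatrix obs(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      obs(i, j) = bray_curtis_pair(rows[i].data(), rows[j].data(), S);

  NumericMatrix lt(n, n), eq(n, n);
  std::vector<std::vector<int> > nullc(n, std::vector<int>(S));
  std::vector<double> keys(S), prob(S);
  std::vector<int> ord(S), draw(S);
  const double tol = 1e-12;
  for (int r = 0; r < n_null; ++r) {
    for (int i = 0; i < n; ++i)
      null_community(rich[i], reads[i], occf, gamma, S, nullc[i],
                     keys, ord, prob, draw);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double b = bray_curtis_pair(nullc[i].data(), nullc[j].data(), S);
        if (b < obs(i, j) - tol) lt(i, j) += 1.0;
        else if (b <= obs(i, j) + tol) eq(i, j) += 1.0;
      }
  }
  NumericMatrix rc(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double v = 2.0 * ((lt(i, j) + 0.5 * eq(i, j)) / n_null) - 1.0;
      rc(i, j) = rc(j, i) = v;
    }
  return rc;
}

// ---- neutral drift engine --------------------------------------------------

// Fenwick tree over per-taxon weights for O(log S) categorical sampling with
// updates.
struct Fenwick {
  std::vector<double> t;
  int n, pw;
  Fenwick(int n_) : t(n_ + 1, 0.0), n(n_) {
    pw = 1;
    while ((pw << 1) <= n) pw <<= 1;
  }
  void add(int i, double v) {
    for (++i; i <= n; i += i & (-i)) t[i] += v;
  }
  // smallest 0-based index with cumulative sum >= v
  int find(double v) const {
    int pos = 0;
    for (int step = pw; step > 0; step >>= 1)
      if (pos + step <= n && t[pos + step] < v) {
        pos += step;
        v -= t[pos];
      }
    return pos; // 0-based
  }
};

// Hubbell-type zero-sum drift for one local community: initialize by a
// multinomial draw from the regional pool, then iterate death-replacement
// events; the replacement comes from the regional pool with probability m,
// otherwise from the local community.
// [[Rcpp::export]]
IntegerVector cpp_neutral_drift(NumericVector gamma, int reads, double m,
                                int sweeps) {
  const int S = gamma.size();
  std::vector<double> cumg(S), p(S);
  double acc = 0.0;
  for (int k = 0; k < S; ++k) { acc += gamma[k]; cumg[k] = acc; }
  for (int k = 0; k < S; ++k) p[k] = gamma[k] / acc;
  std::vector<int> counts(S);
  ::rmultinom(reads, p.data(), S, counts.data());

  Fenwick fw(S);
  for (int k = 0; k < S; ++k)
    if (counts[k] > 0) fw.add(k, counts[k]);

  const long events = (long)sweeps * reads;
  for (long e = 0; e < events; ++e) {
    int victim = fw.find(unif_rand() * reads + 1e-12);
    if (victim >= S) victim = S - 1;
    counts[victim]--;
    fw.add(victim, -1.0);
    int born;
    if (unif_rand() < m) {
      double v = unif_rand() * acc;
      born = (int)(std::lower_bound(cumg.begin(), cumg.end(), v) -
                   cumg.begin());
      if (born >= S) born = S - 1;
    } else {
      born = fw.find(unif_rand() * (reads - 1) + 1e-12);
      if (born >= S) born = S - 1;
    }
    counts[born]++;
    fw.add(born, 1.0);
  }
  return IntegerVector(counts.begin(), counts.end());
}
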