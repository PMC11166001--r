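#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Between-community mean nearest taxon distance (bMNTD) for every sample
// pair, given
//   D    : tip-by-tip patristic distance matrix (T x T)
//   W    : sample-by-OTU weight matrix (S x K); rows sum to 1, zero = absent
//   tip  : 0-based tip index in D for each OTU column of W (length K)
//   perm : 0-based permutation of the T tips (tip-label shuffle); identity
//          gives the observed statistic
// bMNTD(a,b) = 0.5 * ( sum_i W[a,i] * min_{j in b} d(i,j)
//                    + sum_j W[b,j] * min_{i in a} d(j,i) )
static void bmntd_fill(const NumericMatrix& D, const NumericMatrix& W,
                       const std::vector< std::vector<int> >& present,
                       const std::vector<int>& tip, const int* perm,
                       std::vector<double>& M, NumericMatrix& out) {
  const int S = W.nrow(), K = W.ncol(), T = D.nrow();
  const double* dp = &D(0, 0);
  std::vector<double> minbuf(T);
  // M[i + s*K] = min over j present in sample s of d(tip_i, tip_j).
  // Computed column-sequentially: running min over the selected columns of D
  // (one contiguous pass per present OTU), then gathered per OTU.
  for (int s = 0; s < S; ++s) {
    const std::vector<int>& pr = present[s];
    const size_t off = (size_t)s * K;
    std::fill(minbuf.begin(), minbuf.end(), R_PosInf);
    for (size_t t = 0; t < pr.size(); ++t) {
      const double* col = dp + (size_t)perm[tip[pr[t]]] * T;
      for (int r = 0; r < T; ++r)
        if (col[r] < minbuf[r]) minbuf[r] = col[r];
    }
    for (int i = 0; i < K; ++i) M[off + i] = minbuf[perm[tip[i]]];
  }
  for (int a = 0; a < S; ++a) {
    out(a, a) = 0.0;
    const std::vector<int>& pa = present[a];
    for (int b = a + 1; b < S; ++b) {
      const std::vector<int>& pb = present[b];
      double s1 = 0.0, s2 = 0.0;
      const size_t offb = (size_t)b * K, offa = (size_t)a * K;
      for (size_t t = 0; t < pa.size(); ++t) {
        const int i = pa[t];
        s1 += W(a, i) * M[offb + i];
      }
      for (size_t t = 0; t < pb.size(); ++t) {
        const int j = pb[t];
        s2 += W(b, j) * M[offa + j];
      }
      const double v = 0.5 * (s1 + s2);
      out(a, b) = v;
      out(b, a) = v;
    }
  }
}

static std::vector< std::vector<int> > presence_lists(const NumericMatrix& W) {
  const int S = W.nrow(), K = W.ncol();
  std::vector< std::vector<int> > present(S);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < K; ++i)
      if (W(s, i) > 0) present[s].push_back(i);
  return present;
}

// [[Rcpp::export]]
NumericMatrix bmntd_cpp(NumericMatrix D, NumericMatrix W, IntegerVector tip1) {
  const int S = W.nrow(), K = W.ncol(), T = D.nrow();
  std::vector<int> tip(K), id(T);
  for (int i = 0; i < K; ++i) tip[i] = tip1[i] - 1;
  for (int t = 0; t < T; ++t) id[t] = t;
  std::vector< std::vector<int> > present = presence_lists(W);
  std::vector<double> M((size_t)S * K);
  NumericMatrix out(S, S);
  bmntd_fill(D, W, present, tip, id.data(), M, out);
  return out;
}

// Observed bMNTD plus null mean and sd over tip-shuffle permutations.
// perms: n_null x T matrix of 1-based tip permutations (generated in R so the
// caller's seed governs them).
// [[Rcpp::export]]
List bmntd_null_cpp(NumericMatrix D, NumericMatrix W, IntegerVector tip1,
                    IntegerMatrix perms) {
  const int S = W.nrow(), K = W.ncol(), T = D.nrow();
  const int n_null = perms.nrow();
  std::vector<int> tip(K), id(T), pm(T);
  for (int i = 0; i < K; ++i) tip[i] = tip1[i] - 1;
  for (int t = 0; t < T; ++t) id[t] = t;
  std::vector< std::vector<int> > present = presence_lists(W);
  std::vector<double> M((size_t)S * K);
  NumericMatrix obs(S, S), nm(S, S), nsd(S, S), rep(S, S);
  NumericMatrix sum(S, S), sumsq(S, S);
  NumericMatrix nmin(S, S), nmax(S, S);
  std::fill(nmin.begin(), nmin.end(), R_PosInf);
  std::fill(nmax.begin(), nmax.end(), R_NegInf);
  bmntd_fill(D, W, present, tip, id.data(), M, obs);
  for (int r = 0; r < n_null; ++r) {
    for (int t = 0; t < T; ++t) pm[t] = perms(r, t) - 1;
    bmntd_fill(D, W, present, tip, pm.data(), M, rep);
    for (int a = 0; a < S; ++a)
      for (int b = a + 1; b < S; ++b) {
        const double v = rep(a, b);
        sum(a, b) += v;
        sumsq(a, b) += v * v;
        if (v < nmin(a, b)) nmin(a, b) = v;
        if (v > nmax(a, b)) nmax(a, b) = v;
      }
    Rcpp::checkUserInterrupt();
  }
  for (int a = 0; a < S; ++a)
    for (int b = a + 1; b < S; ++b) {
      const double mu = sum(a, b) / n_null;
      double var = (sumsq(a, b) - n_null * mu * mu) / (n_null - 1.0);
      if (var < 0) var = 0;
      nm(a, b) = nm(b, a) = mu;
      nsd(a, b) = nsd(b, a) = std::sqrt(var);
      nmin(b, a) = nmin(a, b);
      nmax(b, a) = nmax(a, b);
    }
  return List::create(_["obs"] = obs, _["null_mean"] = nm, _["null_sd"] = nsd,
                      _["null_min"] = nmin, _["null_max"] = nmax);
}

// Weighted sampling without replacement of `size` indices from weights w
// (Efraimidis-Spirakis keys through R's RNG), writing into out.
static void sample_weighted(const std::vector<double>& w, int size,
                            std::vector<double>& key,
                            std::vector<int>& order, std::vector<int>& out) {
  const int K = (int)w.size();
  for (int k = 0; k < K; ++k) {
    key[k] = std::log(unif_rand()) / w[k]; // larger is better
    order[k] = k;
  }
  std::nth_element(order.begin(), order.begin() + size, order.end(),
                   [&key](int a, int b) { return key[a] > key[b]; });
  out.assign(order.begin(), order.begin() + size);
}

// Raup-Crick on Bray-Curtis. Null communities preserve each sample's
// richness and total; species enter with probability proportional to their
// occurrence frequency across samples, then individuals are assigned with
// probability proportional to metacommunity relative abundance. One full set
// of null communities is generated per replicate and all pairwise
// Bray-Curtis computed, so every pair's null distribution has the prescribed
// marginal law and RC(A,B) = RC(B,A) by construction.
// RC = 2 * ((#{null < obs} + 0.5 #{null == obs}) / n_null) - 1
// [[Rcpp::export]]
NumericMatrix rc_bray_cpp(IntegerMatrix counts, int n_null) {
  const int S = counts.nrow(), K = counts.ncol();
  std::vector<double> occ(K, 0.0), meta(K, 0.0);
  std::vector<int> rich(S, 0);
  std::vector<double> tot(S, 0.0);
  for (int s = 0; s < S; ++s)
    for (int k = 0; k < K; ++k) {
      const int c = counts(s, k);
      if (c > 0) {
        occ[k] += 1.0;
        rich[s] += 1;
        tot[s] += c;
        meta[k] += c;
      }
    }
  for (int k = 0; k < K; ++k)
    if (occ[k] <= 0) stop("OTU with zero occurrence passed to rc_bray");
  // observed Bray-Curtis
  NumericMatrix obs(S, S);
  for (int a = 0; a < S; ++a)
    for (int b = a + 1; b < S; ++b) {
      double num = 0.0;
      for (int k = 0; k < K; ++k)
        num += std::abs((double)counts(a, k) - counts(b, k));
      obs(a, b) = num / (tot[a] + tot[b]);
    }
  std::vector<double> key(K);
  std::vector<int> order(K), chosen;
  std::vector< std::vector<int> > nullc(S, std::vector<int>(K, 0));
  NumericMatrix less(S, S), eq(S, S);
  const double epsv = 1e-10;
  for (int r = 0; r < n_null; ++r) {
    for (int s = 0; s < S; ++s) {
      std::fill(nullc[s].begin(), nullc[s].end(), 0);
      sample_weighted(occ, rich[s], key, order, chosen);
      double psum = 0.0;
      for (int t = 0; t < rich[s]; ++t) psum += meta[chosen[t]];
      int remaining = (int)tot[s] - rich[s];
      for (int t = 0; t < rich[s]; ++t) {
        const int k = chosen[t];
        int extra;
        if (t == rich[s] - 1) {
          extra = remaining;
        } else {
          const double p = meta[k] / psum;
          extra = (remaining > 0) ? (int)R::rbinom(remaining, std::min(1.0, p)) : 0;
        }
        nullc[s][k] = 1 + extra;
        remaining -= extra;
        psum -= meta[k];
      }
    }
    for (int a = 0; a < S; ++a)
      for (int b = a + 1; b < S; ++b) {
        double num = 0.0;
        const std::vector<int>& xa = nullc[a];
        const std::vector<int>& xb = nullc[b];
        for (int k = 0; k < K; ++k)
          num += std::abs((double)xa[k] - xb[k]);
        const double bc = num / (tot[a] + tot[b]);
        if (bc < obs(a, b) - epsv) less(a, b) += 1.0;
        else if (bc <= obs(a, b) + epsv) eq(a, b) += 1.0;
      }
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix rc(S, S);
  for (int a = 0; a < S; ++a) {
    rc(a, a) = NA_REAL;
    for (int b = a + 1; b < S; ++b) {
      const double v =
        2.0 * ((less(a, b) + 0.5 * eq(a, b)) / (double)n_null) - 1.0;
      rc(a, b) = v;
      rc(b, a) = v;
    }
  }
  return rc;
}
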