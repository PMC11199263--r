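// Polarity-invariant modified k-means on unit-norm topographies, plus the
// per-timepoint robust neighbour filter. Hot loops only; all randomness
// (initial sample choices) is drawn in R and passed in.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Principal eigenvector of Uc * Uc.t() by power iteration, warm-started
// from m0 (dominant eigenvalue, so convergence is fast and the outer
// k-means loop tolerates the residual).
static vec principal_axis(const mat& Uc, vec m0) {
  if (norm(m0) < 1e-300) m0 = Uc.col(0);
  m0 /= norm(m0);
  for (int it = 0; it < 500; ++it) {
    vec y = Uc * (Uc.t() * m0);
    double n = norm(y);
    if (n < 1e-300) return m0;
    y /= n;
    if (norm(y - m0) < 1e-13 || norm(y + m0) < 1e-13) return y;
    m0 = y;
  }
  return m0;
}

// U: channels x M matrix of zero-mean unit-norm sample topographies.
// w2: M GEV weights (proportional to squared GFP of the original samples).
// inits: k x n_repeats, 0-based column indices of U used as initial maps.
// Assignment maximizes the squared dot product (polarity ignored); the
// update sets each map to the principal eigenvector of the scatter of its
// assigned samples; empty clusters are re-seeded from the worst-fitted
// sample. Returns the best repeat by GEV.
// [[Rcpp::export]]
Rcpp::List mk_kmeans_core(const arma::mat& U, const arma::vec& w2, int k,
                          const arma::umat& inits, int max_iter, double tol) {
  const uword M = U.n_cols;
  const double wsum = accu(w2);
  double best_gev = -1.0;
  mat best_maps;
  urowvec best_assign;
  vec best_fit;

  for (uword rep = 0; rep < inits.n_cols; ++rep) {
    mat maps(U.n_rows, k);
    for (int c = 0; c < k; ++c) maps.col(c) = U.col(inits(c, rep));
    double prev_gev = -1.0;
    urowvec assign(M, fill::zeros);
    rowvec fit(M, fill::zeros);

    for (int iter = 0; iter < max_iter; ++iter) {
      mat C2 = square(maps.t() * U);           // k x M
      assign = index_max(C2, 0);               // first max: smallest index
      fit = max(C2, 0);
      double gev = dot(w2, fit.t()) / wsum;
      if (iter > 0 &&
          std::fabs(gev - prev_gev) <= tol * std::max(prev_gev, 1e-12)) {
        prev_gev = gev;
        break;
      }
      prev_gev = gev;
      if (iter == max_iter - 1) break;

      // update step
      uvec order_fit = sort_index(fit.t());    // worst-fitted first
      uword reseed_ptr = 0;
      for (int c = 0; c < k; ++c) {
        uvec members = find(assign == (uword)c);
        if (members.n_elem == 0) {
          // deterministic re-seed from the worst-fitted samples
          maps.col(c) = U.col(order_fit(reseed_ptr++));
        } else {
          maps.col(c) = principal_axis(U.cols(members), maps.col(c));
        }
      }
    }
    if (prev_gev > best_gev) {
      best_gev = prev_gev;
      best_maps = maps;
      best_assign = assign;
      best_fit = fit.t();
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("maps") = best_maps,
      Rcpp::Named("assignment") = best_assign.t() + 1,
      Rcpp::Named("fit") = best_fit,
      Rcpp::Named("gev") = best_gev);
}

// Robust neighbour filter applied independently at every time point.
// X: channels x T. nbr: channels x n_neighbors (0-based indices of the
// spatially nearest channels, self excluded). A channel whose deviation
// from its neighbour median exceeds mad_factor times the MAD of all
// channel-vs-median residuals is replaced by that median; all channels are
// then blended (1-blend)*value + blend*median.
// [[Rcpp::export]]
arma::mat spatial_filter_core(const arma::mat& X, const arma::umat& nbr,
                              double mad_factor, double blend) {
  const uword N = X.n_rows, T = X.n_cols, nn = nbr.n_cols;
  mat out(N, T);
  vec buf(nn), med(N), resid(N);
  for (uword t = 0; t < T; ++t) {
    for (uword i = 0; i < N; ++i) {
      for (uword j = 0; j < nn; ++j) buf(j) = X(nbr(i, j), t);
      med(i) = median(buf);
      resid(i) = X(i, t) - med(i);
    }
    double center = median(resid);
    double mad = median(abs(resid - center));
    for (uword i = 0; i < N; ++i) {
      double v = X(i, t);
      if (mad > 0 && std::fabs(resid(i)) > mad_factor * mad) v = med(i);
      out(i, t) = (1.0 - blend) * v + blend * med(i);
    }
  }
  return out;
}

// Sufficient statistics over sample pairs for the validity criteria, in
// one pass over the dissimilarity matrix: within/between sums and counts,
// extreme distances (Dunn), and mean silhouette width. lab is 0-based.
// [[Rcpp::export]]
Rcpp::List criteria_stats_core(const arma::mat& D, const arma::uvec& lab,
                               int k) {
  const uword M = D.n_cols;
  vec cnt(k, fill::zeros);
  for (uword i = 0; i < M; ++i) cnt(lab(i)) += 1.0;
  double sw = 0, sb = 0, nw = 0, nb = 0;
  double min_between = datum::inf, max_within = 0;
  mat G(k, M, fill::zeros);  // G(c, i): sum of d(i, j) over j in cluster c
  for (uword j = 1; j < M; ++j) {     // inner index walks down column j
    const uword lj = lab(j);
    const double* col = D.colptr(j);
    for (uword i = 0; i < j; ++i) {
      const double d = col[i];
      const uword li = lab(i);
      G(lj, i) += d;
      G(li, j) += d;
      if (li == lj) {
        sw += d; nw += 1.0;
        if (d > max_within) max_within = d;
      } else {
        sb += d; nb += 1.0;
        if (d < min_between) min_between = d;
      }
    }
  }
  double sil = 0;
  for (uword i = 0; i < M; ++i) {
    const uword own = lab(i);
    if (cnt(own) <= 1.0) continue;          // singleton: width 0
    const double a = G(own, i) / (cnt(own) - 1.0);
    double b = datum::inf;
    for (int c = 0; c < k; ++c) {
      if ((uword)c == own || cnt(c) == 0) continue;
      const double v = G(c, i) / cnt(c);
      if (v < b) b = v;
    }
    if (std::isfinite(b)) sil += (b - a) / std::max(a, b);
  }
  sil /= (double)M;
  return Rcpp::List::create(
      Rcpp::Named("counts") = cnt, Rcpp::Named("sum_within") = sw,
      Rcpp::Named("sum_between") = sb, Rcpp::Named("n_within") = nw,
      Rcpp::Named("n_between") = nb,
      Rcpp::Named("min_between") = min_between,
      Rcpp::Named("max_within") = max_within,
      Rcpp::Named("silhouette") = sil);
}

// Iterative windowed relabeling (label smoothing). labels: 0 = unlabeled
// (never relabeled, never counted as neighbour). corr2: K x T squared
// correlations; g2: squared GFP. Candidate k at sample t scores
// (1 - corr2(k, t)) * g2(t) - lambda * N_k(t), N_k counting labelled
// neighbours within +/- w (self excluded); all samples are relabeled
// simultaneously per sweep until a fixed point or max_sweeps.
// [[Rcpp::export]]
Rcpp::IntegerVector smooth_labels_core(const Rcpp::IntegerVector& labels,
                                       const arma::mat& corr2,
                                       const arma::vec& g2, int w,
                                       double lambda, int max_sweeps) {
  const int T = labels.size();
  const int K = corr2.n_rows;
  std::vector<int> old(labels.begin(), labels.end());
  std::vector<int> cur(T);
  std::vector<double> cnt(K + 1, 0.0);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int t = 0; t <= w && t < T; ++t) cnt[old[t]] += 1.0;
    bool changed = false;
    for (int t = 0; t < T; ++t) {
      if (t + w < T && t > 0) cnt[old[t + w]] += 1.0;
      if (t - w - 1 >= 0) cnt[old[t - w - 1]] -= 1.0;
      if (old[t] == 0) { cur[t] = 0; continue; }
      int best = 0;
      double best_score = std::numeric_limits<double>::infinity();
      for (int k = 1; k <= K; ++k) {
        double nk = cnt[k] - (old[t] == k ? 1.0 : 0.0);
        double score = (1.0 - corr2(k - 1, t)) * g2(t) - lambda * nk;
        if (score < best_score) { best_score = score; best = k; }
      }
      cur[t] = best;
      if (best != old[t]) changed = true;
    }
    old = cur;
    if (!changed) break;
  }
  return Rcpp::IntegerVector(old.begin(), old.end());
}

// Small-segment rejection on the run-length encoding: repeatedly take the
// shortest run below min_len (leftmost on ties); its first ceil(L/2)
// samples join the preceding run and the rest the following run (edge
// runs merge entirely into their single neighbour); adjacent equal-valued
// runs merge. Returns the expanded label vector.
// [[Rcpp::export]]
Rcpp::IntegerVector reject_small_core(const Rcpp::IntegerVector& labels,
                                      int min_len) {
  std::list<std::pair<int, long long>> runs;  // (value, length)
  const int T = labels.size();
  for (int t = 0; t < T; ++t) {
    if (!runs.empty() && runs.back().first == labels[t])
      runs.back().second += 1;
    else
      runs.emplace_back(labels[t], 1LL);
  }
  while (runs.size() > 1) {
    // shortest short run, leftmost on ties
    auto best = runs.end();
    long long best_len = min_len;
    for (auto it = runs.begin(); it != runs.end(); ++it)
      if (it->second < best_len) { best_len = it->second; best = it; }
    if (best == runs.end()) break;
    if (best == runs.begin()) {
      auto next = std::next(best);
      next->second += best->second;
      runs.erase(best);
    } else if (std::next(best) == runs.end()) {
      auto prev = std::prev(best);
      prev->second += best->second;
      runs.erase(best);
    } else {
      auto prev = std::prev(best), next = std::next(best);
      long long L = best->second;
      long long nfirst = (L + 1) / 2;
      prev->second += nfirst;
      next->second += L - nfirst;
      runs.erase(best);
      if (prev->first == next->first) {
        prev->second += next->second;
        runs.erase(next);
      }
    }
  }
  Rcpp::IntegerVector out(T);
  int t = 0;
  for (auto& r : runs)
    for (long long i = 0; i < r.second; ++i) out[t++] = r.first;
  return out;
}

// In-place transform of a correlation (Gram) matrix of unit-norm samples
// into the polarity-invariant dissimilarity sqrt(max(1 - c^2, 0)). The
// Gram matrix itself comes from R's crossprod (symmetric rank-k BLAS).
// [[Rcpp::export]]
arma::mat dissim_from_cross(arma::mat C) {
  C.transform([](double c) {
    double v = 1.0 - c * c;
    return v > 0 ? std::sqrt(v) : 0.0;
  });
  C.diag().zeros();
  return C;
}

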