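#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shared layout: per-mutation CCF posteriors are stored as an
// n x (G * T) matrix, timepoint blocks of length G (the CCF grid),
// each block a normalized probability vector (logp = its log, floored).

// Normalized cluster weight vector for one timepoint block from the
// running log-sum S (product of member posteriors, uniform prior).
static void block_weights(const std::vector<double>& S, int t, int G,
                          std::vector<double>& w) {
  int off = t * G;
  double mx = S[off];
  for (int i = 1; i < G; ++i) if (S[off + i] > mx) mx = S[off + i];
  double tot = 0.0;
  for (int i = 0; i < G; ++i) {
    double d = S[off + i] - mx;
    w[i] = (d < -45.0) ? 0.0 : std::exp(d);  // below double-precision relevance
    tot += w[i];
  }
  for (int i = 0; i < G; ++i) w[i] /= tot;
}

// Collapsed Gibbs sampler for the Dirichlet-process mixture over
// multi-timepoint CCF posteriors. A cluster's latent CCF vector is
// discretized to the grid with probabilities proportional to the product
// of member posteriors per timepoint; a mutation's likelihood under a
// cluster is the per-timepoint grid dot product, multiplied over
// timepoints. Concentration gamma is resampled each sweep from its
// conditional under a Gamma(1,1) prior (auxiliary-variable scheme).
// [[Rcpp::export]]
List dp_gibbs_chain(NumericMatrix logp, int G, int Tn,
                    int n_iter, int burn_in) {
  int n = logp.nrow();
  int D = G * Tn;
  if (logp.ncol() != D) stop("logp has wrong width");
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in");

  NumericMatrix P(n, D);
  for (int j = 0; j < n; ++j)
    for (int d = 0; d < D; ++d) P(j, d) = std::exp(logp(j, d));

  // cluster state: log-sum matrices, member counts, cached weights
  std::vector< std::vector<double> > S;     // K x D
  std::vector< std::vector<double> > Wc;    // K x D (normalized per block)
  std::vector<bool> dirty;
  std::vector<int> cnt;
  std::vector<int> z(n, 0);

  // init: all mutations in one cluster
  S.push_back(std::vector<double>(D, 0.0));
  for (int j = 0; j < n; ++j)
    for (int d = 0; d < D; ++d) S[0][d] += logp(j, d);
  Wc.push_back(std::vector<double>(D, 0.0));
  dirty.push_back(true);
  cnt.push_back(n);

  double gamma = 1.0;
  double log_new = -Tn * std::log((double)G);  // uniform prior predictive

  IntegerMatrix assign(n_iter, n);
  NumericVector gamma_trace(n_iter);
  IntegerVector K_trace(n_iter);
  NumericMatrix coclust(n, n);
  int n_saved = 0;

  std::vector<double> w(G), logw;
  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < n; ++j) {
      int k0 = z[j];
      // remove j from its cluster
      cnt[k0] -= 1;
      if (cnt[k0] == 0) {
        // swap-remove empty cluster
        int last = (int)S.size() - 1;
        if (k0 != last) {
          S[k0] = S[last]; Wc[k0] = Wc[last];
          dirty[k0] = dirty[last]; cnt[k0] = cnt[last];
          for (int l = 0; l < n; ++l) if (z[l] == last) z[l] = k0;
        }
        S.pop_back(); Wc.pop_back(); dirty.pop_back(); cnt.pop_back();
      } else {
        for (int d = 0; d < D; ++d) S[k0][d] -= logp(j, d);
        dirty[k0] = true;
      }

      int K = (int)S.size();
      logw.assign(K + 1, 0.0);
      for (int k = 0; k < K; ++k) {
        if (dirty[k]) {
          for (int t = 0; t < Tn; ++t) {
            block_weights(S[k], t, G, w);
            for (int i = 0; i < G; ++i) Wc[k][t * G + i] = w[i];
          }
          dirty[k] = false;
        }
        double ll = 0.0;
        for (int t = 0; t < Tn; ++t) {
          double dot = 0.0;
          int off = t * G;
          for (int i = 0; i < G; ++i) dot += Wc[k][off + i] * P(j, off + i);
          ll += std::log(dot > 1e-300 ? dot : 1e-300);
        }
        logw[k] = std::log((double)cnt[k]) + ll;
      }
      logw[K] = std::log(gamma) + log_new;

      double mx = logw[0];
      for (int k = 1; k <= K; ++k) if (logw[k] > mx) mx = logw[k];
      double tot = 0.0;
      for (int k = 0; k <= K; ++k) { logw[k] = std::exp(logw[k] - mx); tot += logw[k]; }
      double u = unif_rand() * tot, acc = 0.0;
      int knew = K;
      for (int k = 0; k <= K; ++k) { acc += logw[k]; if (u <= acc) { knew = k; break; } }

      if (knew == K) {
        S.push_back(std::vector<double>(D, 0.0));
        Wc.push_back(std::vector<double>(D, 0.0));
        dirty.push_back(true);
        cnt.push_back(0);
      }
      for (int d = 0; d < D; ++d) S[knew][d] += logp(j, d);
      dirty[knew] = true;
      cnt[knew] += 1;
      z[j] = knew;
    }

    // resample concentration (Escobar-West), prior Gamma(1, 1)
    int K = (int)S.size();
    double a = 1.0, b = 1.0;
    double eta = R::rbeta(gamma + 1.0, (double)n);
    double mix = (a + K - 1.0) / (a + K - 1.0 + n * (b - std::log(eta)));
    if (unif_rand() < mix)
      gamma = R::rgamma(a + K, 1.0 / (b - std::log(eta)));
    else
      gamma = R::rgamma(a + K - 1.0, 1.0 / (b - std::log(eta)));

    for (int j = 0; j < n; ++j) assign(it, j) = z[j] + 1;
    gamma_trace[it] = gamma;
    K_trace[it] = K;
    if (it >= burn_in) {
      ++n_saved;
      for (int j = 0; j < n; ++j)
        for (int l = j; l < n; ++l)
          if (z[j] == z[l]) { coclust(j, l) += 1.0; }
    }
  }
  for (int j = 0; j < n; ++j)
    for (int l = j; l < n; ++l) {
      coclust(j, l) /= n_saved;
      coclust(l, j) = coclust(j, l);
    }

  return List::create(_["assign"] = assign, _["cocluster"] = coclust,
                      _["gamma"] = gamma_trace, _["K"] = K_trace);
}

// Mutation-reassignment MCMC for clone growth rates. Clusters and the
// phylogeny are fixed; each iteration reassigns every mutation to a
// clone from a multinomial with the precomputed membership likelihoods
// (cumW = row-wise cumulative probabilities), recomputes each clone's
// CCF mode per timepoint from the product of its members' posteriors,
// converts the clone-exclusive CCF (cluster minus children, clipped at
// 0) to circulating cell counts via scale_t = ALC * purity * blood
// volume, and fits log-linear exponential growth.
// [[Rcpp::export]]
List kinetics_chain(NumericMatrix logp, NumericMatrix cumW,
                    IntegerVector parent, NumericVector grid,
                    NumericVector scale_t, NumericVector days,
                    int n_iter, bool draw_ccf, double ccf_floor) {
  int n = logp.nrow();
  int K = cumW.ncol();
  int Tn = scale_t.size();
  int G = grid.size();
  if (logp.ncol() != G * Tn) stop("logp has wrong width");

  NumericMatrix g_out(n_iter, K), n0_out(n_iter, K), r2_out(n_iter, K);
  std::vector<double> S((size_t)K * G * Tn);
  std::vector<double> ccf((size_t)K * Tn), ccf_ex((size_t)K * Tn);
  std::vector<double> ccf_draw_buf(G);
  std::vector<int> z(n);
  RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    // multinomial reassignment
    for (int j = 0; j < n; ++j) {
      double u = unif_rand();
      int k = K - 1;
      for (int c = 0; c < K; ++c) if (u <= cumW(j, c)) { k = c; break; }
      z[j] = k;
    }
    std::fill(S.begin(), S.end(), 0.0);
    std::vector<int> members(K, 0);
    for (int j = 0; j < n; ++j) {
      double* Sk = &S[(size_t)z[j] * G * Tn];
      for (int d = 0; d < G * Tn; ++d) Sk[d] += logp(j, d);
      members[z[j]] += 1;
    }
    // clone CCF per timepoint: posterior draw from the member-product
    // distribution (draw_ccf = true) or its mode
    for (int k = 0; k < K; ++k) {
      for (int t = 0; t < Tn; ++t) {
        const double* Sk = &S[(size_t)k * G * Tn + (size_t)t * G];
        int best = 0;
        for (int i = 1; i < G; ++i) if (Sk[i] > Sk[best]) best = i;
        if (draw_ccf && members[k] > 0) {
          double mx = Sk[best], tot = 0.0;
          std::vector<double>& w = ccf_draw_buf;
          for (int i = 0; i < G; ++i) {
            double d = Sk[i] - mx;
            w[i] = (d < -45.0) ? 0.0 : std::exp(d);
            tot += w[i];
          }
          double u = unif_rand() * tot, acc = 0.0;
          int pick = best;
          for (int i = 0; i < G; ++i) {
            acc += w[i];
            if (u <= acc) { pick = i; break; }
          }
          ccf[(size_t)k * Tn + t] = grid[pick];
        } else {
          ccf[(size_t)k * Tn + t] = grid[best];
        }
      }
    }
    // clone-exclusive CCF: subtract children, clip at 0
    for (size_t d = 0; d < ccf.size(); ++d) ccf_ex[d] = ccf[d];
    for (int k = 0; k < K; ++k) {
      int pa = parent[k];
      if (pa >= 0)
        for (int t = 0; t < Tn; ++t)
          ccf_ex[(size_t)pa * Tn + t] -= ccf[(size_t)k * Tn + t];
    }
    // exponential fit on log cell counts
    for (int k = 0; k < K; ++k) {
      if (members[k] == 0) {
        g_out(it, k) = NA_REAL; n0_out(it, k) = NA_REAL; r2_out(it, k) = NA_REAL;
        continue;
      }
      double sx = 0, sy = 0, sxx = 0, sxy = 0, syy = 0;
      int np = 0;
      // timepoints where the clone sits at or below the grid
      // resolution are indistinguishable from absence: treat them as
      // non-detections rather than as exact measurements
      for (int t = 0; t < Tn; ++t) {
        double c = ccf_ex[(size_t)k * Tn + t];
        if (c < ccf_floor) c = 0;
        double cntv = c * scale_t[t];
        if (cntv > 0) {
          double x = days[t], y = std::log(cntv);
          sx += x; sy += y; sxx += x * x; sxy += x * y; syy += y * y;
          ++np;
        }
      }
      if (np < 2) {
        g_out(it, k) = NA_REAL; n0_out(it, k) = NA_REAL; r2_out(it, k) = NA_REAL;
        continue;
      }
      double denom = np * sxx - sx * sx;
      double slope = (np * sxy - sx * sy) / denom;
      double inter = (sy - slope * sx) / np;
      double sst = syy - sy * sy / np;
      double ssr = 0.0;
      // recompute residual SS for numerical clarity
      for (int t = 0; t < Tn; ++t) {
        double c = ccf_ex[(size_t)k * Tn + t];
        if (c < ccf_floor) c = 0;
        double cntv = c * scale_t[t];
        if (cntv > 0) {
          double r = std::log(cntv) - (inter + slope * days[t]);
          ssr += r * r;
        }
      }
      g_out(it, k) = slope;
      n0_out(it, k) = std::exp(inter);
      r2_out(it, k) = (sst > 1e-12) ? (1.0 - ssr / sst) : 1.0;
    }
  }
  return List::create(_["g"] = g_out, _["n0"] = n0_out, _["r2"] = r2_out);
}
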