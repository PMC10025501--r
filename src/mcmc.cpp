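// Adaptive random-walk Metropolis-within-Gibbs sampler for the three-node
// MPP IRTree model on decomposed (pseudo-item) data.
//
// Model: for node k, item j, person i with observed code y,
//   P(y = 1) = logit^{-1}(alpha[k][j] * theta[i][k] + d[k][j]),  d = alpha*b.
// Structurally missing cells (agreement/extreme codes of midpoint
// responses) are skipped entirely via precomputed index lists.
//
// Blocks: per-person trait 3-vectors (joint RW proposal, MVN(0, R) prior
// via the supplied precision matrix) and per-node-item (log alpha, b) pairs
// (joint RW proposal; normal priors on log alpha and b). Proposal scales
// adapt toward a target acceptance rate during burn-in only, so the
// post-burn-in chain is a valid fixed-kernel Metropolis sampler.
//
// Current Bernoulli log-likelihood terms are cached per person (L) with
// per-person totals and per-item column sums maintained incrementally, so
// each update evaluates only its own proposed block.
//
// Uses R's RNG throughout: draws are reproducible via set.seed() in R.

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Bernoulli log-probability for code y (0/1) at linear predictor eta
static inline double bern_ll(int y, double eta) {
  return (y ? eta : 0.0) - softplus(eta);
}

// [[Rcpp::export]]
List mpp_mcmc_chain(IntegerMatrix yM, IntegerMatrix yA, IntegerMatrix yE,
                    NumericVector alpha_meanlog, NumericVector alpha_sdlog,
                    NumericVector b_mean, NumericVector b_sd,
                    NumericMatrix theta_init,
                    NumericMatrix loga_init, NumericMatrix b_init,
                    NumericMatrix R_prec,
                    int iterations, int burnin, int thin,
                    bool update_traits,
                    int adapt_window, double target_accept) {
  const int N = yM.nrow();
  const int J = yM.ncol();
  const int K = 3;
  const int KJ = K * J;

  // ---- flat, person-major copies of the data ----
  // y*_p[i*J + j]; -1 = structurally missing
  std::vector<signed char> yM_p((size_t)N * J), yA_p((size_t)N * J),
      yE_p((size_t)N * J);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < J; ++j) {
      int m = yM(i, j), a = yA(i, j), e = yE(i, j);
      yM_p[(size_t)i * J + j] = (signed char)m;
      yA_p[(size_t)i * J + j] = (a == NA_INTEGER) ? -1 : (signed char)a;
      yE_p[(size_t)i * J + j] = (e == NA_INTEGER) ? -1 : (signed char)e;
    }

  // per-person directed-response item lists (cells observed at nodes A/E)
  std::vector<int> dir_start(N + 1, 0);
  for (int i = 0; i < N; ++i) {
    int c = 0;
    for (int j = 0; j < J; ++j) if (yA_p[(size_t)i * J + j] >= 0) ++c;
    dir_start[i + 1] = dir_start[i] + c;
  }
  std::vector<int> dir_j(dir_start[N]);
  for (int i = 0, t = 0; i < N; ++i)
    for (int j = 0; j < J; ++j)
      if (yA_p[(size_t)i * J + j] >= 0) dir_j[t++] = j;

  // per-item observed-person lists for nodes A/E (same mask for both)
  std::vector<int> obs_start(J + 1, 0);
  {
    std::vector<int> cnt(J, 0);
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < J; ++j)
        if (yA_p[(size_t)i * J + j] >= 0) ++cnt[j];
    for (int j = 0; j < J; ++j) obs_start[j + 1] = obs_start[j] + cnt[j];
  }
  std::vector<int> obs_i(obs_start[J]);
  std::vector<signed char> obsA_y(obs_start[J]), obsE_y(obs_start[J]);
  {
    std::vector<int> pos(obs_start.begin(), obs_start.end() - 1);
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < J; ++j)
        if (yA_p[(size_t)i * J + j] >= 0) {
          int t = pos[j]++;
          obs_i[t] = i;
          obsA_y[t] = yA_p[(size_t)i * J + j];
          obsE_y[t] = yE_p[(size_t)i * J + j];
        }
  }

  // ---- state (flat) ----
  std::vector<double> th((size_t)std::max(N, 1) * K); // th[i*3 + k]
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) th[(size_t)i * K + k] = theta_init(i, k);
  std::vector<double> loga(KJ), alpha(KJ), b(KJ), d(KJ); // [k*J + j]
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < J; ++j) {
      loga[k * J + j] = loga_init(k, j);
      alpha[k * J + j] = std::exp(loga_init(k, j));
      b[k * J + j] = b_init(k, j);
      d[k * J + j] = alpha[k * J + j] * b[k * J + j];
    }
  double Rp[9];
  for (int a = 0; a < 3; ++a)
    for (int c = 0; c < 3; ++c) Rp[a * 3 + c] = R_prec(a, c);

  // prior constants
  double inv2_asd[3], inv2_bsd[3];
  for (int k = 0; k < K; ++k) {
    inv2_asd[k] = 0.5 / (alpha_sdlog[k] * alpha_sdlog[k]);
    inv2_bsd[k] = 0.5 / (b_sd[k] * b_sd[k]);
  }

  // ---- likelihood cache ----
  // L[i*KJ + k*J + j]: current Bernoulli log-lik term (0 where missing)
  std::vector<double> L((size_t)std::max(N, 1) * KJ, 0.0);
  std::vector<double> personTot(std::max(N, 1), 0.0);
  std::vector<double> sumL(KJ, 0.0);
  for (int i = 0; i < N; ++i) {
    double *Li = &L[(size_t)i * KJ];
    double tot = 0.0;
    const double thM = th[(size_t)i * K + 0], thA = th[(size_t)i * K + 1],
                 thE = th[(size_t)i * K + 2];
    for (int j = 0; j < J; ++j) {
      double ll = bern_ll(yM_p[(size_t)i * J + j], alpha[j] * thM + d[j]);
      Li[j] = ll; tot += ll; sumL[j] += ll;
    }
    for (int t = dir_start[i]; t < dir_start[i + 1]; ++t) {
      int j = dir_j[t];
      double llA = bern_ll(yA_p[(size_t)i * J + j],
                           alpha[J + j] * thA + d[J + j]);
      double llE = bern_ll(yE_p[(size_t)i * J + j],
                           alpha[2 * J + j] * thE + d[2 * J + j]);
      Li[J + j] = llA; Li[2 * J + j] = llE;
      tot += llA + llE;
      sumL[J + j] += llA; sumL[2 * J + j] += llE;
    }
    personTot[i] = tot;
  }

  // proposal scales
  double s_theta[3] = {0.5, 0.5, 0.5};
  std::vector<double> s_item(KJ, 0.2);

  // running moments of (log alpha, b) per item for the adaptive proposal
  // covariance (estimated during burn-in, frozen afterwards)
  std::vector<double> m_la(KJ, 0.0), m_b(KJ, 0.0);
  std::vector<double> c_aa(KJ, 0.0), c_ab(KJ, 0.0), c_bb(KJ, 0.0);
  long mom_n = 0;
  const int cov_warmup = 100; // isotropic proposals until this many samples

  // adaptation accumulators
  double acc_theta[3] = {0, 0, 0};
  std::vector<double> acc_item(KJ, 0.0);
  int window_count = 0;

  const int n_keep = iterations > burnin
    ? (iterations - burnin + thin - 1) / thin : 0;
  NumericMatrix draws(std::max(n_keep, 0), 2 * KJ);
  NumericMatrix theta_sum(std::max(N, 1), K), theta_sumsq(std::max(N, 1), K);
  int kept = 0;

  double post_acc_theta[3] = {0, 0, 0};
  std::vector<double> post_acc_item(KJ, 0.0);
  int post_iters = 0;

  std::vector<double> buf(KJ, 0.0);   // proposed per-person terms
  std::vector<double> colbuf(std::max(N, 1));

  for (int it = 0; it < iterations; ++it) {
    const bool adapting = it < burnin;

    // ---- trait updates ----
    if (update_traits && N > 0) {
      for (int i = 0; i < N; ++i) {
        double *thi = &th[(size_t)i * K];
        double prop[3];
        for (int k = 0; k < K; ++k)
          prop[k] = thi[k] + s_theta[k] * R::norm_rand();
        const signed char *ymi = &yM_p[(size_t)i * J];
        const signed char *yai = &yA_p[(size_t)i * J];
        const signed char *yei = &yE_p[(size_t)i * J];
        double newll = 0.0;
        for (int j = 0; j < J; ++j) {
          double ll = bern_ll(ymi[j], alpha[j] * prop[0] + d[j]);
          buf[j] = ll; newll += ll;
        }
        for (int t = dir_start[i]; t < dir_start[i + 1]; ++t) {
          int j = dir_j[t];
          double llA = bern_ll(yai[j], alpha[J + j] * prop[1] + d[J + j]);
          double llE = bern_ll(yei[j], alpha[2 * J + j] * prop[2] + d[2 * J + j]);
          buf[J + j] = llA; buf[2 * J + j] = llE;
          newll += llA + llE;
        }
        // MVN(0, R) prior quadratic forms
        double qn = 0.0, qo = 0.0;
        for (int a = 0; a < 3; ++a)
          for (int c = 0; c < 3; ++c) {
            qn += prop[a] * Rp[a * 3 + c] * prop[c];
            qo += thi[a] * Rp[a * 3 + c] * thi[c];
          }
        double logr = newll - 0.5 * qn - personTot[i] + 0.5 * qo;
        if (logr >= 0.0 || std::log(R::unif_rand()) < logr) {
          double *Li = &L[(size_t)i * KJ];
          for (int j = 0; j < J; ++j) {
            sumL[j] += buf[j] - Li[j];
            Li[j] = buf[j];
          }
          for (int t = dir_start[i]; t < dir_start[i + 1]; ++t) {
            int j = dir_j[t];
            sumL[J + j] += buf[J + j] - Li[J + j];
            sumL[2 * J + j] += buf[2 * J + j] - Li[2 * J + j];
            Li[J + j] = buf[J + j];
            Li[2 * J + j] = buf[2 * J + j];
          }
          personTot[i] = newll;
          thi[0] = prop[0]; thi[1] = prop[1]; thi[2] = prop[2];
          const double w = 1.0 / N;
          for (int k = 0; k < K; ++k) acc_theta[k] += w;
          if (!adapting)
            for (int k = 0; k < K; ++k) post_acc_theta[k] += w;
        }
      }
    }

    // ---- item updates ----
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < J; ++j) {
        const int kj = k * J + j;
        const double s = s_item[kj];
        const double z1 = R::norm_rand(), z2 = R::norm_rand();
        double la_p, b_p;
        if (mom_n >= cov_warmup) {
          // proposal from the estimated (log alpha, b) covariance: shaped
          // steps travel the alpha-b posterior ridge (d = alpha * b)
          double vaa = c_aa[kj] / (mom_n - 1) + 1e-6;
          double vab = c_ab[kj] / (mom_n - 1);
          double vbb = c_bb[kj] / (mom_n - 1) + 1e-6;
          double l11 = std::sqrt(vaa);
          double l21 = vab / l11;
          double l22 = std::sqrt(std::max(vbb - l21 * l21, 1e-8));
          la_p = loga[kj] + s * l11 * z1;
          b_p = b[kj] + s * (l21 * z1 + l22 * z2);
        } else {
          la_p = loga[kj] + s * z1;
          b_p = b[kj] + s * z2;
        }
        const double a_p = std::exp(la_p);
        const double d_p = a_p * b_p;
        double neu = 0.0;
        int nobs = 0;
        if (k == 0) {
          for (int i = 0; i < N; ++i) {
            double ll = bern_ll(yM_p[(size_t)i * J + j],
                                a_p * th[(size_t)i * K] + d_p);
            colbuf[i] = ll; neu += ll;
          }
          nobs = N;
        } else {
          const signed char *yv = (k == 1) ? obsA_y.data() : obsE_y.data();
          for (int t = obs_start[j]; t < obs_start[j + 1]; ++t) {
            double ll = bern_ll(yv[t],
                                a_p * th[(size_t)obs_i[t] * K + k] + d_p);
            colbuf[t - obs_start[j]] = ll; neu += ll;
          }
          nobs = obs_start[j + 1] - obs_start[j];
        }
        double zla_p = la_p - alpha_meanlog[k], zla = loga[kj] - alpha_meanlog[k];
        double zb_p = b_p - b_mean[k], zb = b[kj] - b_mean[k];
        double logr = neu - sumL[kj]
          - inv2_asd[k] * (zla_p * zla_p - zla * zla)
          - inv2_bsd[k] * (zb_p * zb_p - zb * zb);
        if (logr >= 0.0 || std::log(R::unif_rand()) < logr) {
          loga[kj] = la_p; alpha[kj] = a_p; b[kj] = b_p; d[kj] = d_p;
          if (k == 0) {
            for (int i = 0; i < N; ++i) {
              double *cell = &L[(size_t)i * KJ + j];
              personTot[i] += colbuf[i] - *cell;
              *cell = colbuf[i];
            }
          } else {
            for (int t = obs_start[j]; t < obs_start[j + 1]; ++t) {
              int i = obs_i[t];
              double *cell = &L[(size_t)i * KJ + kj];
              double nl = colbuf[t - obs_start[j]];
              personTot[i] += nl - *cell;
              *cell = nl;
            }
          }
          sumL[kj] = neu;
          acc_item[kj] += 1.0;
          if (!adapting) post_acc_item[kj] += 1.0;
        }
        (void)nobs;
      }
    }
    if (!adapting) ++post_iters;

    // ---- proposal-covariance moments (burn-in only, Welford) ----
    if (adapting) {
      ++mom_n;
      for (int kj = 0; kj < KJ; ++kj) {
        double dla = loga[kj] - m_la[kj];
        double db = b[kj] - m_b[kj];
        m_la[kj] += dla / mom_n;
        m_b[kj] += db / mom_n;
        c_aa[kj] += dla * (loga[kj] - m_la[kj]);
        c_bb[kj] += db * (b[kj] - m_b[kj]);
        c_ab[kj] += dla * (b[kj] - m_b[kj]);
      }
      if (mom_n == cov_warmup) // rescale for the shaped proposal
        std::fill(s_item.begin(), s_item.end(), 1.7);
    }

    // ---- adaptation (burn-in only) ----
    if (adapting && ++window_count == adapt_window) {
      for (int k = 0; k < K; ++k) {
        double rate = acc_theta[k] / adapt_window;
        s_theta[k] *= std::exp(rate - target_accept);
        s_theta[k] = std::min(std::max(s_theta[k], 1e-3), 25.0);
        acc_theta[k] = 0.0;
        for (int j = 0; j < J; ++j) {
          const int kj = k * J + j;
          double rj = acc_item[kj] / adapt_window;
          s_item[kj] *= std::exp(rj - target_accept);
          s_item[kj] = std::min(std::max(s_item[kj], 1e-3), 25.0);
          acc_item[kj] = 0.0;
        }
      }
      window_count = 0;
    }

    // ---- record ----
    if (it >= burnin && (it - burnin) % thin == 0) {
      for (int kj = 0; kj < KJ; ++kj) {
        draws(kept, kj) = alpha[kj];
        draws(kept, KJ + kj) = b[kj];
      }
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) {
          double v = th[(size_t)i * K + k];
          theta_sum(i, k) += v;
          theta_sumsq(i, k) += v * v;
        }
      ++kept;
    }

    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc_t(K);
  for (int k = 0; k < K; ++k)
    acc_t[k] = post_iters > 0 ? post_acc_theta[k] / post_iters : NA_REAL;
  NumericMatrix acc_i(K, J);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < J; ++j)
      acc_i(k, j) = post_iters > 0 ? post_acc_item[k * J + j] / post_iters
                                   : NA_REAL;
  NumericMatrix ps_i(K, J);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < J; ++j) ps_i(k, j) = s_item[k * J + j];

  return List::create(
    _["draws"] = draws,
    _["kept"] = kept,
    _["theta_sum"] = theta_sum,
    _["theta_sumsq"] = theta_sumsq,
    _["accept_theta"] = acc_t,
    _["accept_item"] = acc_i,
    _["prop_scale_theta"] = NumericVector(s_theta, s_theta + K),
    _["prop_scale_item"] = ps_i);
}
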