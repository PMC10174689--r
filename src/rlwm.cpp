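// RL-WM likelihood and adaptive Metropolis-within-Gibbs sampler.
//
// The likelihood walks each participant's trials in experienced order,
// maintaining per-block Q (RL) and W (working memory) matrices. States are
// updated with the observed actions/rewards; missed trials contribute
// nothing and trigger no update. Pointwise log-likelihood is accumulated at
// the participant-block unit (a block's test trials pool into its unit).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Pack {
  int nA = 0, nB = 0, n_stim = 0;
  std::vector<int> sizes;     // set size per block (1-based block index - 1)
  std::vector<int> offset;    // global stimulus offset per block
  std::vector<int> correct;   // correct action per global stimulus (1..nA)
  std::vector<int> lb, ls, la, lr;  // learning: block, local stim, action (0=missed), reward
  std::vector<int> tb, ts, ta;      // test: block, local stim, action (0=missed)
};

static Pack unpack(const List& pk) {
  Pack p;
  p.nA = as<int>(pk["n_actions"]);
  p.nB = as<int>(pk["n_blocks"]);
  p.sizes = as<std::vector<int>>(pk["block_sizes"]);
  p.correct = as<std::vector<int>>(pk["correct"]);
  p.lb = as<std::vector<int>>(pk["learn_block"]);
  p.ls = as<std::vector<int>>(pk["learn_stim"]);
  p.la = as<std::vector<int>>(pk["learn_action"]);
  p.lr = as<std::vector<int>>(pk["learn_reward"]);
  p.tb = as<std::vector<int>>(pk["test_block"]);
  p.ts = as<std::vector<int>>(pk["test_stim"]);
  p.ta = as<std::vector<int>>(pk["test_action"]);
  p.offset.resize(p.nB);
  int off = 0;
  for (int b = 0; b < p.nB; ++b) { p.offset[b] = off; off += p.sizes[b]; }
  p.n_stim = off;
  return p;
}

// theta = [alpha_pos, alpha_neg, beta_test, epsilon, phi, omega3, omega6]
static double participant_loglik(const Pack& pk, const double* th,
                                 double betaL, double* unit) {
  const double a_pos = th[0], a_neg = th[1], bT = th[2], eps = th[3],
               phi = th[4], w3 = th[5], w6 = th[6];
  const double nu = a_neg / a_pos;
  const int nA = pk.nA;
  const double w0 = 1.0 / nA;
  std::vector<double> Q((size_t)pk.n_stim * nA, w0), W((size_t)pk.n_stim * nA, w0);
  std::vector<double> eW(nA), eQ(nA);
  if (unit) std::fill(unit, unit + pk.nB, 0.0);
  double total = 0.0;

  const size_t nL = pk.lb.size();
  for (size_t t = 0; t < nL; ++t) {
    const int b = pk.lb[t] - 1;
    const int g = pk.offset[b] + pk.ls[t] - 1;
    const int act = pk.la[t];
    if (act == 0) continue;               // missed: no likelihood, no update
    const int a = act - 1;
    const double om = (pk.sizes[b] == 3) ? w3 : w6;
    double* Wr = &W[(size_t)g * nA];
    double* Qr = &Q[(size_t)g * nA];
    double mW = Wr[0], mQ = Qr[0];
    for (int k = 1; k < nA; ++k) {
      if (Wr[k] > mW) mW = Wr[k];
      if (Qr[k] > mQ) mQ = Qr[k];
    }
    double sW = 0.0, sQ = 0.0;
    for (int k = 0; k < nA; ++k) {
      eW[k] = std::exp(betaL * (Wr[k] - mW)); sW += eW[k];
      eQ[k] = std::exp(betaL * (Qr[k] - mQ)); sQ += eQ[k];
    }
    const double p = (1.0 - eps) * (om * eW[a] / sW + (1.0 - om) * eQ[a] / sQ)
                     + eps / nA;
    const double lp = std::log(p);
    total += lp;
    if (unit) unit[b] += lp;
    // decay all of this block's W entries except the observed pair
    const int lo = pk.offset[b], hi = pk.offset[b] + pk.sizes[b];
    const double keep = Wr[a];
    for (int gg = lo; gg < hi; ++gg) {
      double* ww = &W[(size_t)gg * nA];
      for (int k = 0; k < nA; ++k) ww[k] += phi * (w0 - ww[k]);
    }
    Wr[a] = keep;
    // delta-rule and one-shot updates on the observed pair
    const double r = (double)pk.lr[t];
    const double dRL = r - Qr[a];
    Qr[a] += (dRL > 0 ? a_pos : a_neg) * dRL;
    const double dWM = r - Wr[a];
    Wr[a] = (dWM > 0) ? r : Wr[a] + nu * dWM;
  }

  const size_t nT = pk.tb.size();
  for (size_t t = 0; t < nT; ++t) {
    const int act = pk.ta[t];
    if (act == 0) continue;
    const int b = pk.tb[t] - 1;
    const int g = pk.offset[b] + pk.ts[t] - 1;
    const double* Qr = &Q[(size_t)g * nA];
    double mQ = Qr[0];
    for (int k = 1; k < nA; ++k) if (Qr[k] > mQ) mQ = Qr[k];
    double sQ = 0.0;
    for (int k = 0; k < nA; ++k) { eQ[k] = std::exp(bT * (Qr[k] - mQ)); sQ += eQ[k]; }
    const double p = (1.0 - eps) * eQ[act - 1] / sQ + eps / nA;
    const double lp = std::log(p);
    total += lp;
    if (unit) unit[b] += lp;
  }
  return total;
}

// [[Rcpp::export]]
NumericVector cpp_session_loglik(List pack, NumericVector theta, double beta_learn) {
  Pack pk = unpack(pack);
  NumericVector unit(pk.nB);
  participant_loglik(pk, theta.begin(), beta_learn, unit.begin());
  return unit;
}

// ---------------------------------------------------------------------------
// Sampler

static inline double logit(double x) { return std::log(x / (1.0 - x)); }
static inline double inv_logit(double x) {
  if (x > 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

struct Adapt {
  double scale = 0.3;
  int n = 0, acc = 0;
  void tick(bool accepted) { ++n; if (accepted) ++acc; }
  void batch(int batch_no) {
    if (n == 0) return;
    double rate = (double)acc / n;
    double delta = std::min(0.25, 1.0 / std::sqrt((double)batch_no));
    scale *= std::exp(rate > 0.44 ? delta : -delta);
    n = acc = 0;
  }
};

// indices of unit-interval parameters within theta
static const int UNIT_IDX[6] = {0, 1, 3, 4, 5, 6};

// [[Rcpp::export]]
List cpp_rlwm_chain(List packs, IntegerVector group, IntegerVector hgroup,
                    int n_groups, int n_hgroups, List prior, List init,
                    int n_warmup, int n_kept, int n_thin) {
  const int P = packs.size();
  std::vector<Pack> dat(P);
  for (int p = 0; p < P; ++p) dat[p] = unpack(packs[p]);
  const int nB = dat[0].nB;
  const bool hier = n_hgroups > 0;

  // prior constants
  const double hy_shape = as<double>(prior["hyper_ab_shape"]);
  const double hy_rate = as<double>(prior["hyper_ab_rate"]);
  const double bl_shape = as<double>(prior["beta_learn_shape"]);
  const double bl_rate = as<double>(prior["beta_learn_rate"]);
  const double bt_shape = as<double>(prior["beta_test_shape"]);
  const double bt_rate = as<double>(prior["beta_test_rate"]);
  const double mu0 = as<double>(prior["beta_test_meanlog"]);
  const double mu_sd = as<double>(prior["beta_test_meanlog_sd"]);
  const double sg_sd = as<double>(prior["beta_test_sdlog_sd"]);
  const double flat_a = as<double>(prior["flat_beta_shape1"]);
  const double flat_b = as<double>(prior["flat_beta_shape2"]);

  // state
  NumericMatrix th0 = init["theta"];           // P x 7
  std::vector<double> theta((size_t)P * 7);
  for (int p = 0; p < P; ++p)
    for (int j = 0; j < 7; ++j) theta[(size_t)p * 7 + j] = th0(p, j);
  std::vector<double> betaL = as<std::vector<double>>(init["beta_learn"]);
  // hypers: [h][j] for 6 unit params
  std::vector<double> hyA((size_t)std::max(1, n_hgroups) * 6, 1.0);
  std::vector<double> hyB((size_t)std::max(1, n_hgroups) * 6, 1.0);
  std::vector<double> btMu(std::max(1, n_hgroups), mu0);
  std::vector<double> btSg(std::max(1, n_hgroups), 0.5);
  if (hier) {
    NumericMatrix ha = init["hyper_a"], hb = init["hyper_b"];
    NumericVector hm = init["bt_meanlog"], hs = init["bt_sdlog"];
    for (int h = 0; h < n_hgroups; ++h) {
      for (int j = 0; j < 6; ++j) { hyA[h * 6 + j] = ha(h, j); hyB[h * 6 + j] = hb(h, j); }
      btMu[h] = hm[h]; btSg[h] = hs[h];
    }
  }

  auto lp_unit_param = [&](double x, int h, int j) {
    double a = hier ? hyA[h * 6 + j] : flat_a - 1.0;
    double b = hier ? hyB[h * 6 + j] : flat_b - 1.0;
    return R::dbeta(x, 1.0 + a, 1.0 + b, 1);
  };
  auto lp_btest = [&](double x, int h) {
    if (hier) return R::dlnorm(x, btMu[h], btSg[h], 1);
    return R::dgamma(x, bt_shape, 1.0 / bt_rate, 1);
  };

  std::vector<double> ll(P);
  for (int p = 0; p < P; ++p)
    ll[p] = participant_loglik(dat[p], &theta[(size_t)p * 7], betaL[group[p] - 1], nullptr);

  // adaptation bookkeeping
  std::vector<Adapt> adTheta((size_t)P * 7);
  std::vector<Adapt> adBetaL(n_groups);
  std::vector<Adapt> adHyA((size_t)std::max(1, n_hgroups) * 6),
                     adHyB((size_t)std::max(1, n_hgroups) * 6);
  std::vector<Adapt> adMu(std::max(1, n_hgroups)), adSg(std::max(1, n_hgroups));
  for (auto& a : adBetaL) a.scale = 0.1;
  for (auto& a : adMu) a.scale = 0.2;
  for (auto& a : adSg) a.scale = 0.2;

  // output
  NumericMatrix outTheta(n_kept, P * 7);
  NumericMatrix outBetaL(n_kept, n_groups);
  const int nHyCols = hier ? n_hgroups * 14 : 0;  // 6*(a,b) + mu + sigma
  NumericMatrix outHyper(n_kept, std::max(1, nHyCols));
  NumericMatrix outPw(n_kept, P * nB);

  std::vector<double> unit_buf(nB);
  const int n_iter = n_warmup + n_kept * n_thin;
  int kept = 0, batch_no = 0;

  for (int it = 1; it <= n_iter; ++it) {
    const bool warm = it <= n_warmup;
    // --- participant-level parameters, single-site random walk
    for (int p = 0; p < P; ++p) {
      double* th = &theta[(size_t)p * 7];
      const int g = group[p] - 1;
      const int h = hier ? hgroup[p] - 1 : 0;
      for (int j = 0; j < 7; ++j) {
        Adapt& ad = adTheta[(size_t)p * 7 + j];
        const double cur = th[j];
        double cand, ljac;
        if (j == 2) {                         // beta_test, log scale
          cand = cur * std::exp(ad.scale * norm_rand());
          ljac = std::log(cand) - std::log(cur);
        } else {                              // unit interval, logit scale
          double x = logit(cur) + ad.scale * norm_rand();
          if (std::fabs(x) > 30.0) { ad.tick(false); continue; }
          cand = inv_logit(x);
          ljac = std::log(cand * (1.0 - cand)) - std::log(cur * (1.0 - cur));
        }
        double lp_cur, lp_cand;
        if (j == 2) { lp_cur = lp_btest(cur, h); lp_cand = lp_btest(cand, h); }
        else {
          int ju = (j < 2) ? j : j - 1;       // map theta index to unit index
          lp_cur = lp_unit_param(cur, h, ju);
          lp_cand = lp_unit_param(cand, h, ju);
        }
        th[j] = cand;
        const double ll_cand = participant_loglik(dat[p], th, betaL[g], nullptr);
        const double lr = (ll_cand - ll[p]) + (lp_cand - lp_cur) + ljac;
        if (std::log(unif_rand()) < lr) { ll[p] = ll_cand; ad.tick(true); }
        else { th[j] = cur; ad.tick(false); }
      }
    }
    // --- group-shared learning-phase inverse temperature (repeated: it is
    // the slowest-mixing quantity and each update costs one group sweep)
    for (int rep = 0; rep < 3; ++rep)
    for (int g = 0; g < n_groups; ++g) {
      Adapt& ad = adBetaL[g];
      const double cur = betaL[g];
      const double cand = cur * std::exp(ad.scale * norm_rand());
      double dll = 0.0;
      std::vector<double> ll_new(P, 0.0);
      for (int p = 0; p < P; ++p) {
        if (group[p] - 1 != g) continue;
        ll_new[p] = participant_loglik(dat[p], &theta[(size_t)p * 7], cand, nullptr);
        dll += ll_new[p] - ll[p];
      }
      const double lr = dll
        + R::dgamma(cand, bl_shape, 1.0 / bl_rate, 1)
        - R::dgamma(cur, bl_shape, 1.0 / bl_rate, 1)
        + std::log(cand) - std::log(cur);
      if (std::log(unif_rand()) < lr) {
        betaL[g] = cand;
        for (int p = 0; p < P; ++p) if (group[p] - 1 == g) ll[p] = ll_new[p];
        ad.tick(true);
      } else ad.tick(false);
    }
    // --- hyperparameters (no data likelihood, so extra scans are cheap)
    if (hier) {
      for (int rep = 0; rep < 5; ++rep)
      for (int h = 0; h < n_hgroups; ++h) {
        for (int j = 0; j < 6; ++j) {
          const int tj = UNIT_IDX[j];
          for (int side = 0; side < 2; ++side) {
            Adapt& ad = side == 0 ? adHyA[h * 6 + j] : adHyB[h * 6 + j];
            double& ref = side == 0 ? hyA[h * 6 + j] : hyB[h * 6 + j];
            const double cur = ref;
            const double cand = cur * std::exp(ad.scale * norm_rand());
            double lr = R::dgamma(cand, hy_shape, 1.0 / hy_rate, 1)
                      - R::dgamma(cur, hy_shape, 1.0 / hy_rate, 1)
                      + std::log(cand) - std::log(cur);
            const double a_cur = hyA[h * 6 + j], b_cur = hyB[h * 6 + j];
            double a_new = side == 0 ? cand : a_cur;
            double b_new = side == 1 ? cand : b_cur;
            for (int p = 0; p < P; ++p) {
              if (hgroup[p] - 1 != h) continue;
              const double x = theta[(size_t)p * 7 + tj];
              lr += R::dbeta(x, 1.0 + a_new, 1.0 + b_new, 1)
                  - R::dbeta(x, 1.0 + a_cur, 1.0 + b_cur, 1);
            }
            if (std::log(unif_rand()) < lr) { ref = cand; ad.tick(true); }
            else ad.tick(false);
          }
        }
        // lognormal hypers for beta_test
        {
          Adapt& ad = adMu[h];
          const double cur = btMu[h];
          const double cand = cur + ad.scale * norm_rand();
          double lr = R::dnorm(cand, mu0, mu_sd, 1) - R::dnorm(cur, mu0, mu_sd, 1);
          for (int p = 0; p < P; ++p) {
            if (hgroup[p] - 1 != h) continue;
            const double x = theta[(size_t)p * 7 + 2];
            lr += R::dlnorm(x, cand, btSg[h], 1) - R::dlnorm(x, cur, btSg[h], 1);
          }
          if (std::log(unif_rand()) < lr) { btMu[h] = cand; ad.tick(true); }
          else ad.tick(false);
        }
        {
          Adapt& ad = adSg[h];
          const double cur = btSg[h];
          const double cand = cur * std::exp(ad.scale * norm_rand());
          double lr = -0.5 * (cand * cand - cur * cur) / (sg_sd * sg_sd)
                    + std::log(cand) - std::log(cur);  // half-normal prior + jacobian
          for (int p = 0; p < P; ++p) {
            if (hgroup[p] - 1 != h) continue;
            const double x = theta[(size_t)p * 7 + 2];
            lr += R::dlnorm(x, btMu[h], cand, 1) - R::dlnorm(x, btMu[h], cur, 1);
          }
          if (std::log(unif_rand()) < lr) { btSg[h] = cand; ad.tick(true); }
          else ad.tick(false);
        }
      }
    }
    // --- adaptation in warmup, in batches of 25 sweeps
    if (warm && it % 25 == 0) {
      ++batch_no;
      for (auto& a : adTheta) a.batch(batch_no);
      for (auto& a : adBetaL) a.batch(batch_no);
      if (hier) {
        for (auto& a : adHyA) a.batch(batch_no);
        for (auto& a : adHyB) a.batch(batch_no);
        for (auto& a : adMu) a.batch(batch_no);
        for (auto& a : adSg) a.batch(batch_no);
      }
    }
    // --- store
    if (!warm && (it - n_warmup) % n_thin == 0) {
      for (int p = 0; p < P; ++p) {
        participant_loglik(dat[p], &theta[(size_t)p * 7], betaL[group[p] - 1],
                           unit_buf.data());
        for (int b = 0; b < nB; ++b) outPw(kept, p * nB + b) = unit_buf[b];
        for (int j = 0; j < 7; ++j) outTheta(kept, p * 7 + j) = theta[(size_t)p * 7 + j];
      }
      for (int g = 0; g < n_groups; ++g) outBetaL(kept, g) = betaL[g];
      if (hier) {
        for (int h = 0; h < n_hgroups; ++h) {
          for (int j = 0; j < 6; ++j) {
            outHyper(kept, h * 14 + 2 * j) = hyA[h * 6 + j];
            outHyper(kept, h * 14 + 2 * j + 1) = hyB[h * 6 + j];
          }
          outHyper(kept, h * 14 + 12) = btMu[h];
          outHyper(kept, h * 14 + 13) = btSg[h];
        }
      }
      ++kept;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["theta"] = outTheta, _["beta_learn"] = outBetaL,
                      _["hyper"] = outHyper, _["pointwise"] = outPw);
}
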