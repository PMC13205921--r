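// Adaptive Metropolis-within-Gibbs sampler for the per-SNP binomial mixed
// model  logit(p_gt) = beta0 + alpha_g + gamma_t  with
//   beta0   ~ Normal(0, priorInterceptSd^2)
//   alpha_g ~ Normal(0, sigma_g^2),  gamma_t ~ Normal(0, sigma_t^2)
//   sigma_g, sigma_t ~ HalfNormal(priorSigmaSd)
// Random-walk proposals per parameter; step sizes adapted toward a 0.44
// acceptance rate during warmup only. Uses R's RNG so draws are reproducible
// under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// sum of binomial log-likelihood terms (up to the constant binomial
// coefficient) for observations idx, with a shift d added to their eta
static double dataLL(const std::vector<int>& idx,
                     const NumericVector& y, const NumericVector& n,
                     const std::vector<double>& eta, double d) {
  double s = 0.0;
  for (size_t k = 0; k < idx.size(); ++k) {
    int i = idx[k];
    double e = eta[i] + d;
    s += y[i] * e - n[i] * softplus(e);
  }
  return s;
}

struct StepAdapter {
  double lstep;
  int acc = 0, tries = 0;
  explicit StepAdapter(double s) : lstep(std::log(s)) {}
  double step() const { return std::exp(lstep); }
  void tally(bool accepted, bool adapting) {
    ++tries;
    if (accepted) ++acc;
    if (adapting && tries == 50) {
      double rate = acc / 50.0;
      lstep += 0.6 * (rate - 0.44);
      lstep = std::min(std::max(lstep, -6.0), 3.0);
      acc = 0; tries = 0;
    }
  }
};

// [[Rcpp::export(name = ".aseGlmmSampler")]]
List aseGlmmSampler(NumericVector y, NumericVector n,
                    IntegerVector g, IntegerVector t,
                    int nG, int nT, int chains, int warmup, int iter,
                    double priorInterceptSd, double priorSigmaSd,
                    double initBeta0) {
  const int nObs = y.size();
  std::vector< std::vector<int> > idxG(nG), idxT(nT);
  std::vector<int> idxAll(nObs);
  for (int i = 0; i < nObs; ++i) {
    idxG[g[i]].push_back(i);
    idxT[t[i]].push_back(i);
    idxAll[i] = i;
  }
  NumericMatrix beta0Draws(iter, chains);
  NumericMatrix sgDraws(iter, chains);
  NumericMatrix stDraws(iter, chains);

  for (int c = 0; c < chains; ++c) {
    double beta0 = initBeta0 + 0.3 * norm_rand();
    std::vector<double> alpha(nG, 0.0), gamma(nT, 0.0);
    double lsa = std::log(0.5) + 0.2 * norm_rand();
    double lsg = std::log(0.3) + 0.2 * norm_rand();
    std::vector<double> eta(nObs);
    for (int i = 0; i < nObs; ++i) eta[i] = beta0 + alpha[g[i]] + gamma[t[i]];

    StepAdapter sB(0.2);
    std::vector<StepAdapter> sA(nG, StepAdapter(0.4));
    std::vector<StepAdapter> sT(nT, StepAdapter(0.3));
    StepAdapter sLsa(0.5), sLsg(0.5), sRecA(0.3), sRecT(0.3);

    for (int it = 0; it < warmup + iter; ++it) {
      bool adapting = it < warmup;
      double sa = std::exp(lsa), sg2;

      // beta0
      {
        double d = sB.step() * norm_rand();
        double dll = dataLL(idxAll, y, n, eta, d) -
                     dataLL(idxAll, y, n, eta, 0.0);
        double b1 = beta0 + d;
        dll += (beta0 * beta0 - b1 * b1) /
               (2.0 * priorInterceptSd * priorInterceptSd);
        bool ok = std::log(unif_rand()) < dll;
        if (ok) {
          beta0 = b1;
          for (int i = 0; i < nObs; ++i) eta[i] += d;
        }
        sB.tally(ok, adapting);
      }
      // alpha_g
      sa = std::exp(lsa);
      for (int j = 0; j < nG; ++j) {
        if (idxG[j].empty()) continue;
        double d = sA[j].step() * norm_rand();
        double a1 = alpha[j] + d;
        double dll = dataLL(idxG[j], y, n, eta, d) -
                     dataLL(idxG[j], y, n, eta, 0.0);
        dll += (alpha[j] * alpha[j] - a1 * a1) / (2.0 * sa * sa);
        bool ok = std::log(unif_rand()) < dll;
        if (ok) {
          alpha[j] = a1;
          for (size_t k = 0; k < idxG[j].size(); ++k) eta[idxG[j][k]] += d;
        }
        sA[j].tally(ok, adapting);
      }
      // gamma_t
      sg2 = std::exp(lsg);
      for (int j = 0; j < nT; ++j) {
        if (idxT[j].empty()) continue;
        double d = sT[j].step() * norm_rand();
        double g1 = gamma[j] + d;
        double dll = dataLL(idxT[j], y, n, eta, d) -
                     dataLL(idxT[j], y, n, eta, 0.0);
        dll += (gamma[j] * gamma[j] - g1 * g1) / (2.0 * sg2 * sg2);
        bool ok = std::log(unif_rand()) < dll;
        if (ok) {
          gamma[j] = g1;
          for (size_t k = 0; k < idxT[j].size(); ++k) eta[idxT[j][k]] += d;
        }
        sT[j].tally(ok, adapting);
      }
      // recentering moves: shift beta0 against a whole random-effect block.
      // eta (hence the likelihood) is invariant; only the priors change.
      // These traverse the translation ridge between the intercept and the
      // block mean that single-site updates cross slowly.
      {
        double d = sRecA.step() * norm_rand();
        double b1 = beta0 + d;
        double sa2 = std::exp(2.0 * lsa);
        double dll = (beta0 * beta0 - b1 * b1) /
                     (2.0 * priorInterceptSd * priorInterceptSd);
        for (int j = 0; j < nG; ++j) {
          double a1 = alpha[j] - d;
          dll += (alpha[j] * alpha[j] - a1 * a1) / (2.0 * sa2);
        }
        bool ok = std::log(unif_rand()) < dll;
        if (ok) {
          beta0 = b1;
          for (int j = 0; j < nG; ++j) alpha[j] -= d;
        }
        sRecA.tally(ok, adapting);
      }
      {
        double d = sRecT.step() * norm_rand();
        double b1 = beta0 + d;
        double st2 = std::exp(2.0 * lsg);
        double dll = (beta0 * beta0 - b1 * b1) /
                     (2.0 * priorInterceptSd * priorInterceptSd);
        for (int j = 0; j < nT; ++j) {
          double g1 = gamma[j] - d;
          dll += (gamma[j] * gamma[j] - g1 * g1) / (2.0 * st2);
        }
        bool ok = std::log(unif_rand()) < dll;
        if (ok) {
          beta0 = b1;
          for (int j = 0; j < nT; ++j) gamma[j] -= d;
        }
        sRecT.tally(ok, adapting);
      }
      // log sigma_g (alpha scale)
      {
        double l1 = lsa + sLsa.step() * norm_rand();
        double s0 = std::exp(lsa), s1 = std::exp(l1);
        double sumA2 = 0.0;
        for (int j = 0; j < nG; ++j) sumA2 += alpha[j] * alpha[j];
        double dll = -nG * (l1 - lsa) -
                     sumA2 / 2.0 * (1.0 / (s1 * s1) - 1.0 / (s0 * s0));
        dll += (s0 * s0 - s1 * s1) / (2.0 * priorSigmaSd * priorSigmaSd);
        dll += (l1 - lsa);  // Jacobian of sigma = exp(lsigma)
        bool ok = std::log(unif_rand()) < dll;
        if (ok) lsa = l1;
        sLsa.tally(ok, adapting);
      }
      // log sigma_t (gamma scale)
      {
        double l1 = lsg + sLsg.step() * norm_rand();
        double s0 = std::exp(lsg), s1 = std::exp(l1);
        double sumG2 = 0.0;
        for (int j = 0; j < nT; ++j) sumG2 += gamma[j] * gamma[j];
        double dll = -nT * (l1 - lsg) -
                     sumG2 / 2.0 * (1.0 / (s1 * s1) - 1.0 / (s0 * s0));
        dll += (s0 * s0 - s1 * s1) / (2.0 * priorSigmaSd * priorSigmaSd);
        dll += (l1 - lsg);
        bool ok = std::log(unif_rand()) < dll;
        if (ok) lsg = l1;
        sLsg.tally(ok, adapting);
      }

      if (it >= warmup) {
        beta0Draws(it - warmup, c) = beta0;
        sgDraws(it - warmup, c) = std::exp(lsa);
        stDraws(it - warmup, c) = std::exp(lsg);
      }
    }
  }
  return List::create(_["beta0"] = beta0Draws,
                      _["sigma_g"] = sgDraws,
                      _["sigma_t"] = stDraws);
}
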