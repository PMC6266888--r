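// Fast path for the censored first-order Markov likelihood with GPD
// exceedance margins and bivariate logistic dependence, plus the sequential
// conditional sampler of the stationary logistic chain.  The R level keeps
// reference implementations of the same formulas; tests pin the two routes
// together.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct MarPar {
  double u, sigma, xi, lambda, lambda_t, alpha;
  double log_lambda;        // log lambda (marginal density factor above u)
  double log1mlam;          // log(1 - lambda): censored marginal mass
  double logz_u;            // log Frechet value at the censoring point
  double t_u;               // z_u^{-1/alpha}
  double log_both_below;    // log F(u,u) = 2^alpha * log(1 - lambda)
  double c_alpha;           // (1 - alpha)/alpha
};

// Marginal quantities for one above-threshold observation on the negated
// scale: GPD log density, log of the full marginal cdf F(x) = 1 -
// lambda_t * (1 - H(x)), log Frechet value, z^{-1/alpha}, and the log
// Jacobian of x -> z, dz/dx = lambda_t h(x) z^2 / F(x).
struct ExcQ {
  double logh, logF, logz, t, logJ;
};

inline bool exc_quant(double x, const MarPar& mp, ExcQ& q) {
  const double a = (x - mp.u) / mp.sigma;
  double logsurv;  // log(1 - H(x))
  if (std::fabs(mp.xi) < 1e-8) {
    logsurv = -a;
    q.logh = -std::log(mp.sigma) - a;
  } else {
    const double w = 1.0 + mp.xi * a;
    if (w <= 0.0) return false;  // outside GPD support
    const double lw = std::log1p(mp.xi * a);
    logsurv = -lw / mp.xi;
    q.logh = -std::log(mp.sigma) - (1.0 / mp.xi + 1.0) * lw;
  }
  const double sF = mp.lambda_t * std::exp(logsurv);  // 1 - F(x)
  if (sF >= 1.0 || sF <= 0.0) return false;
  q.logF = std::log1p(-sF);
  q.logz = -std::log(-q.logF);
  q.t = std::exp(-q.logz / mp.alpha);
  q.logJ = std::log(mp.lambda_t) + q.logh + 2.0 * q.logz - q.logF;
  return true;
}

// log of the bivariate density term for two above-threshold observations:
// d2F/dx1 dx2 with F = exp(-V(z1, z2)), V = (z1^{-1/a} + z2^{-1/a})^a.
inline double log_pair_above(const ExcQ& a, const ExcQ& b, const MarPar& mp) {
  const double s = a.t + b.t;
  const double ls = std::log(s);
  const double V = std::exp(mp.alpha * ls);
  const double logfz = -V - (1.0 / mp.alpha + 1.0) * (a.logz + b.logz) +
                       (mp.alpha - 2.0) * ls + std::log(V + mp.c_alpha);
  return logfz + a.logJ + b.logJ;
}

// log dF/dx for the uncensored argument, other argument censored at u.
inline double log_pair_one(const ExcQ& a, const MarPar& mp) {
  const double s = a.t + mp.t_u;
  return (mp.alpha - 1.0) * std::log(s) - (1.0 / mp.alpha + 1.0) * a.logz -
         std::pow(s, mp.alpha) + a.logJ;
}

const double kPenalty = 1e10;  // flat penalty outside the feasible box

}  // namespace

// Negative log-likelihood of the censored Markov-extremes model.  `chains`
// is a list of numeric vectors (independent site chains / gap segments) on
// the negated scale.  lambda is the (fixed, empirical) exceedance rate;
// paper_literal reproduces the literal marginal transform (lambda_t = 1)
// above the threshold.
// [[Rcpp::export]]
double cpp_markov_nll(NumericVector par, List chains, double u,
                      double lambda, bool paper_literal) {
  const double sigma = par[0], xi = par[1], alpha = par[2];
  if (!(sigma > 1e-8) || !(alpha > 0.0) || alpha > 1.0 || xi <= -0.99 ||
      xi > 5.0 || !(lambda > 0.0) || lambda >= 1.0)
    return kPenalty;

  MarPar mp;
  mp.u = u;
  mp.sigma = sigma;
  mp.xi = xi;
  mp.alpha = alpha;
  mp.lambda = lambda;
  mp.lambda_t = paper_literal ? 1.0 : lambda;
  mp.log_lambda = std::log(lambda);
  mp.log1mlam = std::log1p(-lambda);
  mp.logz_u = -std::log(-mp.log1mlam);
  mp.t_u = std::exp(-mp.logz_u / alpha);
  mp.log_both_below = std::pow(2.0, alpha) * mp.log1mlam;
  mp.c_alpha = (1.0 - alpha) / alpha;

  double nll = 0.0;
  const int nc = chains.size();
  for (int c = 0; c < nc; ++c) {
    NumericVector x = chains[c];
    const int n = x.size();
    if (n == 0) continue;

    ExcQ prev;
    bool prev_above = x[0] > u;
    if (prev_above) {
      if (!exc_quant(x[0], mp, prev)) return kPenalty;
      nll -= mp.log_lambda + prev.logh;
    } else {
      nll -= mp.log1mlam;
    }

    for (int t = 1; t < n; ++t) {
      ExcQ cur;
      const bool cur_above = x[t] > u;
      if (cur_above && !exc_quant(x[t], mp, cur)) return kPenalty;

      double logpair, logm_prev;
      if (cur_above && prev_above) {
        logpair = log_pair_above(cur, prev, mp);
        logm_prev = mp.log_lambda + prev.logh;
      } else if (cur_above) {
        logpair = log_pair_one(cur, mp);
        logm_prev = mp.log1mlam;
      } else if (prev_above) {
        logpair = log_pair_one(prev, mp);
        logm_prev = mp.log_lambda + prev.logh;
      } else {
        logpair = mp.log_both_below;
        logm_prev = mp.log1mlam;
      }
      nll -= logpair - logm_prev;
      prev = cur;
      prev_above = cur_above;
    }
  }
  if (!R_finite(nll)) return kPenalty;
  return nll;
}

// Stationary first-order Markov chain with the bivariate logistic
// extreme-value law on consecutive pairs and standard Frechet margins.
// Returns the chain on the uniform marginal scale p_t = exp(-1/z_t).
// z_1 is drawn from the standard Frechet marginal (the pair law has
// Frechet margins, so the chain is stationary from t = 1); z_t | z_{t-1}
// is drawn by numerically inverting the conditional cdf
//   C(z2 | z1) = dF/dz1 (z1, z2) / f_Frechet(z1)
//              = z1^{1 - 1/a} s^{a-1} exp(1/z1 - s^a),  s = z1^{-1/a}+z2^{-1/a}
// by monotone bisection in log z2.  Uses R's RNG (reproducible under
// set.seed()).
// [[Rcpp::export]]
NumericVector cpp_simulate_logistic_uniform(int n, double alpha) {
  if (n < 1) stop("n must be >= 1");
  if (!(alpha > 0.0) || alpha > 1.0) stop("alpha must be in (0, 1]");
  NumericVector p(n);
  double lz1 = -std::log(-std::log(R::runif(0.0, 1.0)));
  p[0] = std::exp(-std::exp(-lz1));
  for (int t = 1; t < n; ++t) {
    const double lw = std::log(R::runif(0.0, 1.0));
    const double t1 = std::exp(-lz1 / alpha);
    const double base = (1.0 - 1.0 / alpha) * lz1 + std::exp(-lz1);
    double lo = -60.0, hi = 60.0;
    // log conditional cdf at log z2 = v
    const auto logC = [&](double v) {
      const double s = t1 + std::exp(-v / alpha);
      return base + (alpha - 1.0) * std::log(s) - std::pow(s, alpha);
    };
    int guard = 0;
    while (logC(hi) < lw && hi < 600.0 && ++guard < 10) hi += 60.0;
    for (int it = 0; it < 60; ++it) {
      const double mid = 0.5 * (lo + hi);
      if (logC(mid) < lw) lo = mid; else hi = mid;
    }
    lz1 = 0.5 * (lo + hi);
    p[t] = std::exp(-std::exp(-lz1));
  }
  return p;
}
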