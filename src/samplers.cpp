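// Slice-within-Gibbs samplers for the two Bayesian growth models.
//
// Both models share the latent process N[i,t] = N[i,t-1] * lambda[i,t] with
// lambda[i,t] ~ Gamma(r, beta), r = lbar^2/sigma^2, beta = lbar/sigma^2.
// The process is sampled in the exactly equivalent parameterization
//   N[i,t] | N[i,t-1] ~ Gamma(r, beta / N[i,t-1]),
// which makes every N[i,t] a stochastic node with only local neighbours
// (N[i,t-1], N[i,t+1], data), so univariate slice updates mix well and cost
// O(1) each.  All N updates run on the log scale.
//
// State-space observation: y[i,t] ~ Poisson(N[i,t]) on max counts (NA ok).
// N-mixture observation:  X[i,t] ~ Poisson(N[i,t]),
//                         y[i,j,t] ~ Binomial(X[i,t], p),
// with the integer X updated by exact draws from its full conditional
// (terms accumulated via the ratio recurrence) and p conjugate Beta.

#include <Rcpp.h>
#include <functional>
#include <vector>
using namespace Rcpp;

static const double LOGN_FLOOR = -300.0;

// Univariate slice sampler (Neal 2003: stepping out + shrinkage).
static double slice1(double x0, const std::function<double(double)> &logf,
                     double w, int m, double lower, double upper) {
  double f0 = logf(x0);
  if (!R_FINITE(f0)) return x0;  // defensive: never move from a bad state
  double logy = f0 + std::log(R::unif_rand());
  double u = R::unif_rand() * w;
  double L = x0 - u, Rr = L + w;
  int j = (int)std::floor(R::unif_rand() * m);
  int k = m - 1 - j;
  while (j-- > 0 && L > lower && logf(L) > logy) L -= w;
  while (k-- > 0 && Rr < upper && logf(Rr) > logy) Rr += w;
  if (L < lower) L = lower;
  if (Rr > upper) Rr = upper;
  for (int it = 0; it < 200; ++it) {
    double x1 = L + R::unif_rand() * (Rr - L);
    if (logf(x1) > logy) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;
}

struct GrowthPrior {
  double lbar_shape, lbar_rate, sigma_shape, sigma_rate;
};

// One sweep of (lbar, sigma) given sufficient statistics of the n realized
// growth ratios: Lsum = sum log lambda, Ssum = sum lambda.
static void update_growth(double &lbar, double &sigma, int n, double Lsum,
                          double Ssum, const GrowthPrior &pr) {
  // joint log-density as a function of (lbar, sigma), up to constants
  auto loglik = [&](double lb, double sg) {
    double r = lb * lb / (sg * sg);
    double beta = lb / (sg * sg);
    double lp = n * (r * std::log(beta) - R::lgammafn(r)) + r * Lsum -
                beta * Ssum;
    lp += (pr.lbar_shape - 1.0) * std::log(lb) - pr.lbar_rate * lb;
    lp += (pr.sigma_shape - 1.0) * std::log(sg) - pr.sigma_rate * sg;
    return lp;
  };
  for (int rep = 0; rep < 3; ++rep) {
    double ul = std::log(lbar);
    ul = slice1(ul, [&](double u) {
      double lb = std::exp(u);
      return loglik(lb, sigma) + u;  // + Jacobian
    }, 0.5, 50, -40.0, 40.0);
    lbar = std::exp(ul);
    double us = std::log(sigma);
    us = slice1(us, [&](double u) {
      double sg = std::exp(u);
      return loglik(lbar, sg) + u;
    }, 0.5, 50, -40.0, 40.0);
    sigma = std::exp(us);
  }
}

// Log full conditional of logN[i,t] given neighbours and the Poisson count
// "obs" (obs < 0 means missing).  lnPrev/lnNext = NA_REAL-like flags via
// has_prev/has_next.  For t = 1 the prior is Uniform(0, U) (upper bound
// enforced by the slice bounds; the +x Jacobian applies).
static double logn_cond(double x, double obs, bool has_prev, double lnPrev,
                        bool has_next, double lnNext, double r, double beta,
                        int init_prior) {
  double lp = 0.0;
  if (obs >= 0.0) lp += obs * x - std::exp(x);
  if (has_prev) {
    lp += r * x - beta * std::exp(x - lnPrev);  // (r-1)logN + Jacobian
  } else if (init_prior == 1) {
    lp += x;  // Uniform(0,U) on N1 + log-scale Jacobian
  }           // else flat on log N1 (scale-neutral), bounded by the slicer
  if (has_next) lp += -r * x - beta * std::exp(lnNext - x);
  return lp;
}

static void update_logN(NumericMatrix &logN, const NumericMatrix &obs,
                        double r, double beta, double logU,
                        int init_prior) {
  int I = logN.nrow(), T = logN.ncol();
  for (int i = 0; i < I; ++i) {
    // a fully unobserved site has its prior as exact full conditional:
    // draw the whole row forward instead of slice-stepping it
    bool any_obs = false;
    for (int t = 0; t < T; ++t)
      if (obs(i, t) >= 0.0) { any_obs = true; break; }
    if (!any_obs) {
      double x;
      if (init_prior == 1) {
        // Uniform(0,U) on N1
        x = std::log(R::unif_rand() * std::exp(logU));
        if (!R_FINITE(x) || x < LOGN_FLOOR) x = LOGN_FLOOR;
      } else {
        x = LOGN_FLOOR + R::unif_rand() * (logU - LOGN_FLOOR);
      }
      logN(i, 0) = x;
      for (int t = 1; t < T; ++t) {
        double lam = R::rgamma(r, 1.0 / beta);  // shape, scale
        x += std::log(lam);
        if (!R_FINITE(x) || x < LOGN_FLOOR) x = LOGN_FLOOR;
        if (x > 60.0) x = 60.0;
        logN(i, t) = x;
      }
      continue;
    }
    for (int t = 0; t < T; ++t) {
      bool has_prev = t > 0, has_next = t < T - 1;
      double lnPrev = has_prev ? logN(i, t - 1) : 0.0;
      double lnNext = has_next ? logN(i, t + 1) : 0.0;
      double ob = obs(i, t);
      double upper = has_prev ? 60.0 : logU;
      logN(i, t) = slice1(logN(i, t), [&](double x) {
        return logn_cond(x, ob, has_prev, lnPrev, has_next, lnNext, r,
                         beta, init_prior);
      }, 1.0, 40, LOGN_FLOOR, upper);
    }
  }
}

// Sufficient statistics of the realized growth ratios.  Fully unobserved
// sites are excluded: their rows contribute nothing to the likelihood and
// integrate out of the posterior exactly (they are only forward-simulated
// for reporting), so including their floor-clamped ratios would distort
// the (lbar, sigma) conditional.
static void growth_stats(const NumericMatrix &logN, const NumericMatrix &obs,
                         int &n, double &Lsum, double &Ssum) {
  int I = logN.nrow(), T = logN.ncol();
  n = 0;
  Lsum = 0.0;
  Ssum = 0.0;
  for (int i = 0; i < I; ++i) {
    bool any_obs = false;
    for (int t = 0; t < T; ++t)
      if (obs(i, t) >= 0.0) { any_obs = true; break; }
    if (!any_obs) continue;
    for (int t = 1; t < T; ++t) {
      double d = logN(i, t) - logN(i, t - 1);
      Lsum += d;
      Ssum += std::exp(d);
      ++n;
    }
  }
}

// [[Rcpp::export(rng = true)]]
List ss_sampler_cpp(NumericMatrix y, double U, int n_warmup, int n_draws,
                    NumericMatrix logN0, double lbar0, double sigma0,
                    NumericVector prior, int init_prior) {
  int I = y.nrow(), T = y.ncol();
  GrowthPrior pr{prior[0], prior[1], prior[2], prior[3]};
  NumericMatrix logN = clone(logN0);
  double lbar = lbar0, sigma = sigma0;
  double logU = std::log(U);

  NumericVector lbar_draws(n_draws), sigma_draws(n_draws);
  NumericMatrix ntot_draws(n_draws, T);
  NumericMatrix nmean(I, T);

  for (int iter = 0; iter < n_warmup + n_draws; ++iter) {
    double r = lbar * lbar / (sigma * sigma);
    double beta = lbar / (sigma * sigma);
    update_logN(logN, y, r, beta, logU, init_prior);
    int n; double Lsum, Ssum;
    growth_stats(logN, y, n, Lsum, Ssum);
    update_growth(lbar, sigma, n, Lsum, Ssum, pr);
    if (iter >= n_warmup) {
      int k = iter - n_warmup;
      lbar_draws[k] = lbar;
      sigma_draws[k] = sigma;
      for (int t = 0; t < T; ++t) {
        double tot = 0.0;
        for (int i = 0; i < I; ++i) {
          double N = std::exp(logN(i, t));
          tot += N;
          nmean(i, t) += N / n_draws;
        }
        ntot_draws(k, t) = tot;
      }
    }
  }
  return List::create(_["lambda_bar"] = lbar_draws,
                      _["sigma_lambda"] = sigma_draws,
                      _["ntot"] = ntot_draws, _["nmean"] = nmean);
}

// Exact draw of X[i,t] from its full conditional:
//   f(X) propto [N q]^X (X!)^(J-1) / prod_j (X - y_j)!,  X >= max_j y_j,
// with q = (1-p)^J, via the ratio recurrence
//   f(X+1)/f(X) = N q (X+1)^(J-1) / prod_j (X+1-y_j).
static int draw_X(double N, double p, const std::vector<int> &yv) {
  int J = (int)yv.size();
  int xmin = 0;
  for (int j = 0; j < J; ++j) xmin = std::max(xmin, yv[j]);
  double q = 1.0;
  for (int j = 0; j < J; ++j) q *= (1.0 - p);
  double Nq = N * q;
  if (Nq <= 0.0) return xmin;
  static std::vector<double> terms;
  terms.clear();
  double term = 1.0, total = 1.0;
  terms.push_back(term);
  int x = xmin;
  for (int step = 0; step < 2000000; ++step) {
    double ratio = Nq;
    double xp1 = (double)(x + 1);
    for (int j = 0; j < J - 1; ++j) ratio *= xp1;
    for (int j = 0; j < J; ++j) ratio /= (xp1 - (double)yv[j]);
    term *= ratio;
    if (!R_FINITE(term)) break;
    terms.push_back(term);
    total += term;
    ++x;
    if (ratio < 1.0 && term < total * 1e-12) break;
  }
  double u = R::unif_rand() * total, cum = 0.0;
  for (size_t k = 0; k < terms.size(); ++k) {
    cum += terms[k];
    if (u <= cum) return xmin + (int)k;
  }
  return xmin + (int)terms.size() - 1;
}

// log of the X-marginalized observation factor of one site-year cell,
//   m(y | N, p) = sum_X Poisson(X; N) prod_j Binomial(y_j; X, p),
// dropping the X-free constants (binomial coefficients at ymax, ymax!)
// that cancel in acceptance ratios.
static double log_m_cell(double N, double p, const std::vector<int> &yv) {
  int J = (int)yv.size();
  int ymax = 0, ysum = 0;
  for (int j = 0; j < J; ++j) {
    ymax = std::max(ymax, yv[j]);
    ysum += yv[j];
  }
  double lp = ymax * std::log(std::max(N, 1e-300)) - N +
              ysum * std::log(p) + (J * ymax - ysum) * std::log1p(-p);
  double q = std::pow(1.0 - p, J);
  double Nq = N * q;
  double term = 1.0, S = 1.0;
  int x = ymax;
  for (int step = 0; step < 2000000; ++step) {
    double ratio = Nq;
    double xp1 = (double)(x + 1);
    for (int j = 0; j < J - 1; ++j) ratio *= xp1;
    for (int j = 0; j < J; ++j) ratio /= (xp1 - (double)yv[j]);
    term *= ratio;
    if (!R_FINITE(term)) break;
    S += term;
    ++x;
    if (ratio < 1.0 && term < S * 1e-12) break;
  }
  return lp + std::log(S);
}

// Joint move along the detection/abundance ridge: shift all year-level
// detection probabilities by a common amount on the logit scale and
// rescale the latent N field per year by p_t / p'_t, with the integer X
// marginalized out of the acceptance ratio (it is re-drawn from its full
// conditional at the start of the next sweep).  Exact MH on the collapsed
// (p, N) space; the transition-density change of the per-year rescaling is
// accounted for explicitly, so the move is valid for shared and by-year
// detection structures.
static bool pscale_move(NumericMatrix &logN, NumericMatrix &pmat,
                        const IntegerMatrix &y, int J, double r,
                        double beta, double logU, double step_sd,
                        int init_prior) {
  int I = logN.nrow(), T = logN.ncol();
  double eps = R::norm_rand() * step_sd;
  std::vector<double> pnew(T), delta(T);
  double lacc = 0.0;
  for (int t = 0; t < T; ++t) {
    double p = pmat(0, t);
    double lo = std::log(p) - std::log1p(-p) + eps;
    double pn = 1.0 / (1.0 + std::exp(-lo));
    if (pn <= 1e-12 || pn >= 1.0 - 1e-12) return false;
    pnew[t] = pn;
    delta[t] = std::log(p) - std::log(pn);
    // Beta(1,1) prior through the logit Jacobian
    lacc += std::log(pn * (1.0 - pn)) - std::log(p * (1.0 - p));
  }
  // initial-abundance prior: bound always, log-scale Jacobian only for
  // the uniform-in-N option (the flat-on-log default is shift-invariant)
  for (int i = 0; i < I; ++i) {
    double ln1 = logN(i, 0) + delta[0];
    if (ln1 >= logU || ln1 <= LOGN_FLOOR) return false;
    if (init_prior == 1) lacc += delta[0];
  }
  // growth-transition change of the per-year rescaling
  for (int i = 0; i < I; ++i)
    for (int t = 1; t < T; ++t) {
      double d = logN(i, t) - logN(i, t - 1);
      double dn = d + delta[t] - delta[t - 1];
      lacc += r * (dn - d) - beta * (std::exp(dn) - std::exp(d));
    }
  // X-marginalized observation factors
  std::vector<int> yv(J);
  for (int i = 0; i < I; ++i)
    for (int t = 0; t < T; ++t) {
      for (int j = 0; j < J; ++j) yv[j] = y(i, t * J + j);
      double N0 = std::exp(logN(i, t));
      double N1 = std::exp(logN(i, t) + delta[t]);
      lacc += log_m_cell(N1, pnew[t], yv) - log_m_cell(N0, pmat(0, t), yv);
    }
  if (std::log(R::unif_rand()) < lacc) {
    for (int t = 0; t < T; ++t) {
      for (int i = 0; i < I; ++i) {
        logN(i, t) += delta[t];
        pmat(i, t) = pnew[t];
      }
    }
    return true;
  }
  return false;
}

// p_structure: 0 = shared, 1 = by_year, 2 = by_site_year
// y: I x (T*J) matrix, column t*J + j holds occasion j of year t.
// [[Rcpp::export(rng = true)]]
List nmix_sampler_cpp(IntegerMatrix y, int J, double U, int n_warmup,
                      int n_draws, NumericMatrix logN0, double lbar0,
                      double sigma0, NumericVector prior, int p_structure,
                      int init_prior) {
  int I = y.nrow(), T = y.ncol() / J;
  GrowthPrior pr{prior[0], prior[1], prior[2], prior[3]};
  NumericMatrix logN = clone(logN0);
  double lbar = lbar0, sigma = sigma0;
  double logU = std::log(U);

  IntegerMatrix X(I, T);
  NumericMatrix pmat(I, T);
  IntegerMatrix ysum(I, T);
  for (int i = 0; i < I; ++i)
    for (int t = 0; t < T; ++t) {
      int mx = 0, sm = 0;
      for (int j = 0; j < J; ++j) {
        int v = y(i, t * J + j);
        mx = std::max(mx, v);
        sm += v;
      }
      X(i, t) = mx;
      ysum(i, t) = sm;
      pmat(i, t) = 0.5;
    }

  NumericVector lbar_draws(n_draws), sigma_draws(n_draws);
  NumericMatrix ntot_draws(n_draws, T), xtot_draws(n_draws, T);
  NumericMatrix p_draws(n_draws, T);  // site-averaged p per year
  NumericMatrix nmean(I, T);
  NumericMatrix Xobs(I, T);  // X as the "count" seen by the logN update

  std::vector<int> yv(J);
  double step_sd = 0.15;
  int acc = 0, tried = 0;
  for (int iter = 0; iter < n_warmup + n_draws; ++iter) {
    double r = lbar * lbar / (sigma * sigma);
    double beta = lbar / (sigma * sigma);

    // collapsed detection/abundance ridge move (X marginalized; X is
    // re-drawn from its full conditional immediately below)
    if (p_structure != 2) {
      ++tried;
      if (pscale_move(logN, pmat, y, J, r, beta, logU, step_sd,
                      init_prior)) ++acc;
      if (iter < n_warmup && tried % 50 == 0) {
        double rate = (double)acc / tried;
        step_sd *= std::exp(0.5 * (rate - 0.35));
        step_sd = std::min(std::max(step_sd, 0.01), 2.0);
        acc = 0;
        tried = 0;
      }
    }

    // latent integer abundance
    for (int i = 0; i < I; ++i)
      for (int t = 0; t < T; ++t) {
        for (int j = 0; j < J; ++j) yv[j] = y(i, t * J + j);
        X(i, t) = draw_X(std::exp(logN(i, t)), pmat(i, t), yv);
        Xobs(i, t) = (double)X(i, t);
      }

    // detection probability, conjugate Beta(1,1) posterior at the chosen
    // pooling level
    if (p_structure == 0) {
      double a = 1.0, b = 1.0;
      for (int i = 0; i < I; ++i)
        for (int t = 0; t < T; ++t) {
          a += ysum(i, t);
          b += J * X(i, t) - ysum(i, t);
        }
      double pv = R::rbeta(a, b);
      std::fill(pmat.begin(), pmat.end(), pv);
    } else if (p_structure == 1) {
      for (int t = 0; t < T; ++t) {
        double a = 1.0, b = 1.0;
        for (int i = 0; i < I; ++i) {
          a += ysum(i, t);
          b += J * X(i, t) - ysum(i, t);
        }
        double pv = R::rbeta(a, b);
        for (int i = 0; i < I; ++i) pmat(i, t) = pv;
      }
    } else {
      for (int i = 0; i < I; ++i)
        for (int t = 0; t < T; ++t)
          pmat(i, t) = R::rbeta(1.0 + ysum(i, t),
                                1.0 + J * X(i, t) - ysum(i, t));
    }

    update_logN(logN, Xobs, r, beta, logU, init_prior);
    int n; double Lsum, Ssum;
    growth_stats(logN, Xobs, n, Lsum, Ssum);
    update_growth(lbar, sigma, n, Lsum, Ssum, pr);

    if (iter >= n_warmup) {
      int k = iter - n_warmup;
      lbar_draws[k] = lbar;
      sigma_draws[k] = sigma;
      for (int t = 0; t < T; ++t) {
        double tot = 0.0, xtot = 0.0, pbar = 0.0;
        for (int i = 0; i < I; ++i) {
          double N = std::exp(logN(i, t));
          tot += N;
          xtot += X(i, t);
          pbar += pmat(i, t);
          nmean(i, t) += N / n_draws;
        }
        ntot_draws(k, t) = tot;
        xtot_draws(k, t) = xtot;
        p_draws(k, t) = pbar / I;
      }
    }
  }
  return List::create(_["lambda_bar"] = lbar_draws,
                      _["sigma_lambda"] = sigma_draws,
                      _["ntot"] = ntot_draws, _["xtot"] = xtot_draws,
                      _["p"] = p_draws, _["nmean"] = nmean);
}
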