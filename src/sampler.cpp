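// Compiled core of the pool-fish distribution model: the marginalized
// Poisson-Bernoulli likelihood and an adaptive Metropolis-within-Gibbs
// sampler. Species coefficients, random effects, effort exponents and
// spread parameters get componentwise adaptive random-walk updates
// (sigma on log scale, upsilon / the 5-m seine scalar on logit scale);
// the fourth-corner (eta1, eta2) pairs get exact conjugate Gibbs draws.
// All randomness comes from R's RNG so seeds set in R are honoured.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int GEAR_OFF[4] = {0, 6, 12, 17};  // phi column offsets
static const int GEAR_NPHI[4] = {6, 6, 5, 5};   // conductivity: EF only
static const int NFAM = 32;                     // 10 beta + 22 phi

struct PFModel {
  // dimensions
  int S, J, P, Ny, nsamp;
  // visit-level data
  std::vector<int> visit_pool, visit_year;
  std::vector<double> vD, vM, vT, vS, vR, vlogD;
  // sample-level data
  std::vector<int> samp_visit, samp_gear, samp_is5m;
  std::vector<double> samp_E, samp_Dk, samp_T, samp_Sk, samp_C;
  IntegerMatrix y;                 // S x nsamp
  std::vector<double> L;           // standardized species length
  // index lists
  std::vector<std::vector<int> > visit_samples, pool_visits, year_visits,
      gear_samples;
  std::vector<int> lm5_samples;
  // parameters (natural scale)
  NumericMatrix beta;              // S x 10
  NumericMatrix phi;               // S x 22
  std::vector<double> eta1, eta2, sigf;  // 32 families
  std::vector<double> eps_pool, eps_time;
  double sigma_pool, sigma_time;
  double upsilon[4];
  double lm_scalar;
  // priors
  double eta1_sd, eta2_sd, sig_s_scale, sig_pool_scale, sig_time_scale;
  // truncation control
  double nmax_tail; int nmax_floor, nmax_cap;
  // repetition counts of the block moves per sweep
  int am_reps, seesaw_reps;
  // caches
  NumericMatrix logLam, lam;       // S x J
  NumericMatrix r;                 // S x nsamp
  NumericMatrix U;                 // S x J unit log-likelihoods
  // visit-level multiplier of each linearly-entering beta family
  // (beta2/beta4 enter through the Ricker decay and are non-linear)
  std::vector<std::vector<double> > shiftx;  // 10 x J, empty for 1,3
  std::vector<double> loglut;                // log(N), N = 0..nmax_cap
  std::vector<double> effpow;                // E^upsilon[gear] per sample
  std::vector<std::vector<double> > poolx;   // 10 x P pool-level shiftx

  void init_from(List data, List init, List priors, List control) {
    S = as<int>(data["S"]); J = as<int>(data["J"]);
    P = as<int>(data["P"]); Ny = as<int>(data["Ny"]);
    visit_pool = as<std::vector<int> >(data["visit_pool"]);
    visit_year = as<std::vector<int> >(data["visit_year"]);
    vD = as<std::vector<double> >(data["vD"]);
    vM = as<std::vector<double> >(data["vM"]);
    vT = as<std::vector<double> >(data["vT"]);
    vS = as<std::vector<double> >(data["vS"]);
    vR = as<std::vector<double> >(data["vR"]);
    vlogD.resize(J);
    for (int j = 0; j < J; j++)
      vlogD[j] = vD[j] > 0 ? std::log(vD[j]) : R_NegInf;
    samp_visit = as<std::vector<int> >(data["samp_visit"]);
    samp_gear = as<std::vector<int> >(data["samp_gear"]);
    samp_is5m = as<std::vector<int> >(data["samp_is5m"]);
    samp_E = as<std::vector<double> >(data["samp_E"]);
    samp_Dk = as<std::vector<double> >(data["samp_Dk"]);
    samp_T = as<std::vector<double> >(data["samp_T"]);
    samp_Sk = as<std::vector<double> >(data["samp_Sk"]);
    samp_C = as<std::vector<double> >(data["samp_C"]);
    y = as<IntegerMatrix>(data["y"]);
    L = as<std::vector<double> >(data["L"]);
    nsamp = (int) samp_visit.size();

    visit_samples.assign(J, std::vector<int>());
    for (int n = 0; n < nsamp; n++)
      visit_samples[samp_visit[n]].push_back(n);
    pool_visits.assign(P, std::vector<int>());
    year_visits.assign(Ny, std::vector<int>());
    for (int j = 0; j < J; j++) {
      pool_visits[visit_pool[j]].push_back(j);
      year_visits[visit_year[j]].push_back(j);
    }
    gear_samples.assign(4, std::vector<int>());
    for (int n = 0; n < nsamp; n++) {
      gear_samples[samp_gear[n]].push_back(n);
      if (samp_is5m[n]) lm5_samples.push_back(n);
    }

    beta = clone(as<NumericMatrix>(init["beta"]));
    phi = clone(as<NumericMatrix>(init["phi"]));
    eta1 = as<std::vector<double> >(init["eta1"]);
    eta2 = as<std::vector<double> >(init["eta2"]);
    sigf = as<std::vector<double> >(init["sigma"]);
    eps_pool = as<std::vector<double> >(init["eps_pool"]);
    eps_time = as<std::vector<double> >(init["eps_time"]);
    sigma_pool = as<double>(init["sigma_pool"]);
    sigma_time = as<double>(init["sigma_time"]);
    NumericVector u = init["upsilon"];
    for (int g = 0; g < 4; g++) upsilon[g] = u[g];
    lm_scalar = as<double>(init["lm_scalar"]);

    eta1_sd = as<double>(priors["eta1_sd"]);
    eta2_sd = as<double>(priors["eta2_sd"]);
    sig_s_scale = as<double>(priors["sigma_s_scale"]);
    sig_pool_scale = as<double>(priors["sigma_pool_scale"]);
    sig_time_scale = as<double>(priors["sigma_time_scale"]);

    nmax_tail = as<double>(control["nmax_tail"]);
    nmax_floor = as<int>(control["nmax_floor"]);
    nmax_cap = as<int>(control["nmax_cap"]);
    am_reps = as<int>(control["am_reps"]);
    seesaw_reps = as<int>(control["seesaw_reps"]);
    loglut.resize(nmax_cap + 1);
    loglut[0] = 0.0;
    for (int n = 1; n <= nmax_cap; n++) loglut[n] = std::log((double) n);

    shiftx.assign(10, std::vector<double>());
    for (int f = 0; f < 10; f++) {
      if (f == 1 || f == 3) continue;
      shiftx[f].resize(J);
      for (int j = 0; j < J; j++) {
        double x = 1.0;
        switch (f) {
          case 0: x = 1.0; break;
          case 2: x = vM[j]; break;
          case 4: x = vT[j]; break;
          case 5: x = vT[j] * vM[j]; break;
          case 6: x = vS[j]; break;
          case 7: x = vS[j] * vM[j]; break;
          case 8: x = vR[j]; break;
          case 9: x = vR[j] * vM[j]; break;
        }
        shiftx[f][j] = x;
      }
    }
    poolx.assign(10, std::vector<double>());
    for (int f = 0; f < 10; f++) {
      if (f == 1 || f == 3) continue;
      poolx[f].assign(P, 0.0);
      for (int j = 0; j < J; j++) poolx[f][visit_pool[j]] = shiftx[f][j];
    }
    effpow.resize(nsamp);
    for (int g = 0; g < 4; g++) refresh_effpow(g);
    logLam = NumericMatrix(S, J);
    lam = NumericMatrix(S, J);
    r = NumericMatrix(S, nsamp);
    U = NumericMatrix(S, J);
    for (int i = 0; i < S; i++) {
      refresh_loglam_row(i);
      refresh_r_row(i);
      refresh_U_row(i);
    }
  }

  // family index of a beta column (0..9) is the column; phi column c
  // maps to family 10 + c
  double fam_mean(int f, int i) const { return eta1[f] + eta2[f] * L[i]; }

  void refresh_loglam_row(int i) {
    for (int j = 0; j < J; j++) {
      double M = vM[j];
      double ll = vlogD[j] + (beta(i, 0) + beta(i, 2) * M) -
        std::exp(beta(i, 1) + beta(i, 3) * M) * vD[j] +
        beta(i, 4) * vT[j] + beta(i, 5) * vT[j] * M +
        beta(i, 6) * vS[j] + beta(i, 7) * vS[j] * M +
        beta(i, 8) * vR[j] + beta(i, 9) * vR[j] * M +
        eps_pool[visit_pool[j]] + eps_time[visit_year[j]];
      logLam(i, j) = ll;
      lam(i, j) = std::exp(ll);
    }
  }

  void refresh_effpow(int g) {
    const double u = upsilon[g];
    for (size_t a = 0; a < gear_samples[g].size(); a++) {
      int n = gear_samples[g][a];
      effpow[n] = std::pow(samp_E[n], u);
    }
  }

  double r_one(int i, int n) const {
    int g = samp_gear[n], o = GEAR_OFF[g];
    double lq = phi(i, o) + std::log(samp_Dk[n]) -
      std::exp(phi(i, o + 1)) * samp_Dk[n] +
      phi(i, o + 2) * samp_T[n] + phi(i, o + 3) * samp_T[n] * samp_T[n] +
      phi(i, o + 4) * samp_Sk[n];
    if (g < 2) lq += phi(i, o + 5) * samp_C[n];
    double mult = samp_is5m[n] ? lm_scalar : 1.0;
    return mult * effpow[n] * (-std::expm1(-std::exp(lq)));
  }

  void refresh_r_row(int i) {
    for (int n = 0; n < nsamp; n++) r(i, n) = r_one(i, n);
  }

  // marginal log-likelihood of the (i, j) detection history given the
  // current caches. All-zero histories have the closed form
  // lambda * (prod_k (1 - r_k) - 1) via the Poisson generating
  // function; histories with detections use the truncated Poisson sum
  // (online log-sum-exp, terminated once later terms are provably
  // negligible).
  double unit_ll(int i, int j) const {
    const std::vector<int>& ks = visit_samples[j];
    double lm = lam(i, j);
    if (!std::isfinite(lm)) return R_NegInf;  // absurd proposal
    int n1 = 0;
    double s0 = 0.0;
    double w1[64];                 // 1 - r of detected samples
    for (size_t a = 0; a < ks.size(); a++) {
      int n = ks[a];
      double rv = r(i, n);
      if (rv > 1.0 - 1e-12) rv = 1.0 - 1e-12;
      if (y(i, n) == 1) { if (n1 < 64) w1[n1++] = 1.0 - rv; }
      else s0 += std::log1p(-rv);
    }
    if (lm <= 0.0) return n1 > 0 ? R_NegInf : 0.0;
    if (n1 == 0) return lm * std::expm1(s0);
    double t0 = std::exp(s0);      // prod(1-r) over non-detections
    if (n1 == 1) {
      // P = e^{lm(t0-1)} - e^{lm(t0 w1 - 1)} via the generating
      // function; exact and stable through expm1
      return lm * (t0 - 1.0) +
        std::log(-std::expm1(lm * t0 * (w1[0] - 1.0)));
    }
    if (n1 == 2 && (1.0 - w1[0]) > 1e-9 && (1.0 - w1[1]) > 1e-9) {
      // inclusion-exclusion over the two detected samples, grouped so
      // each difference goes through expm1
      double a2 = lm * t0 * (w1[1] - 1.0);
      double term1 = -std::expm1(lm * t0 * (w1[0] - 1.0));
      double term2 = std::exp(a2) *
        (-std::expm1(lm * t0 * w1[1] * (w1[0] - 1.0)));
      double p = term1 - term2;
      if (p > 0.0) return lm * (t0 - 1.0) + std::log(p);
      // fall through to the truncated sum on (rare) cancellation
    }
    // conservative truncation: mean + 10 sd + 20 leaves far less than
    // the configured tail mass beyond it (floor/cap still apply)
    int Nmax = (int) (lm + 10.0 * std::sqrt(lm) + 20.0);
    if (Nmax < nmax_floor) Nmax = nmax_floor;
    if (Nmax > nmax_cap) Nmax = nmax_cap;
    double loglm = std::log(lm);
    double lp_pois = -lm;          // log Pois(0 | lam)
    double m = R_NegInf, acc = 0.0;
    double pw[64];                 // running (1-r)^N per detected sample
    for (int a = 0; a < n1; a++) pw[a] = 1.0;
    for (int N = 1; N <= Nmax; N++) {
      lp_pois += loglm - loglut[N];
      double t = lp_pois + N * s0;
      // once past the Poisson mode, lp_pois + N*s0 bounds all later
      // terms (detection factors are <= 1), so stop when negligible
      if (N > lm && t < m - 36.0) break;
      for (int a = 0; a < n1; a++) {
        pw[a] *= w1[a];
        t += pw[a] > 1e-8 ? std::log1p(-pw[a]) : -pw[a];
      }
      if (t == R_NegInf || std::isnan(t)) continue;
      if (t > m) { acc = acc * std::exp(m - t) + 1.0; m = t; }
      else acc += std::exp(t - m);
    }
    return m == R_NegInf ? R_NegInf : m + std::log(acc);
  }

  void refresh_U_row(int i) {
    for (int j = 0; j < J; j++) U(i, j) = unit_ll(i, j);
  }

  double row_U_sum(int i) const {
    double s = 0.0;
    for (int j = 0; j < J; j++) s += U(i, j);
    return s;
  }

  double total_loglik() const {
    double s = 0.0;
    for (int i = 0; i < S; i++) s += row_U_sum(i);
    return s;
  }

  double coef(int f, int i) const {
    return f < 10 ? beta(i, f) : phi(i, f - 10);
  }
  void set_coef(int f, int i, double v) {
    if (f < 10) beta(i, f) = v; else phi(i, f - 10) = v;
  }

  // natural-scale joint log posterior (matches the R reference; no
  // transform Jacobians)
  double total_lp() const {
    double lp = total_loglik();
    for (int f = 0; f < NFAM; f++) {
      for (int i = 0; i < S; i++)
        lp += R::dnorm(coef(f, i), fam_mean(f, i), sigf[f], 1);
      lp += R::dnorm(eta1[f], 0.0, eta1_sd, 1);
      lp += R::dnorm(eta2[f], 0.0, eta2_sd, 1);
      lp += M_LN2 + R::dnorm(sigf[f], 0.0, sig_s_scale, 1);
    }
    for (int p = 0; p < P; p++)
      lp += R::dnorm(eps_pool[p], 0.0, sigma_pool, 1);
    for (int t = 0; t < Ny; t++)
      lp += R::dnorm(eps_time[t], 0.0, sigma_time, 1);
    lp += M_LN2 + R::dnorm(sigma_pool, 0.0, sig_pool_scale, 1);
    lp += M_LN2 + R::dnorm(sigma_time, 0.0, sig_time_scale, 1);
    return lp;
  }
};

// adaptive-Metropolis state for the joint family-intercept move:
// running mean/covariance of the 32-vector eta1, Cholesky refreshed
// periodically during warmup (Haario-style diminishing adaptation)
static const int AMD = 2 * NFAM;  // (eta1, eta2) stacked
struct AMState {
  int n;
  double mean[AMD], cov[AMD][AMD], chol[AMD][AMD];
  double lscale;
  bool has_chol;
  AMState() : n(0), lscale(std::log(0.05)), has_chol(false) {
    for (int a = 0; a < AMD; a++) {
      mean[a] = 0.0;
      for (int b = 0; b < AMD; b++) cov[a][b] = 0.0;
    }
  }
  void update(const std::vector<double>& x) {
    n++;
    double w = 1.0 / n;
    for (int a = 0; a < AMD; a++) {
      double da = x[a] - mean[a];
      mean[a] += w * da;
      for (int b = 0; b <= a; b++)
        cov[a][b] += w * ((x[a] - mean[a]) * (x[b] - mean[b]) -
                          cov[a][b]);
    }
  }
  bool refresh_chol() {
    double a_[AMD][AMD];
    for (int i = 0; i < AMD; i++)
      for (int j = 0; j <= i; j++) {
        a_[i][j] = cov[i][j];
        if (i == j) a_[i][j] += 1e-6;
      }
    for (int i = 0; i < AMD; i++) {
      for (int j = 0; j <= i; j++) {
        double s = a_[i][j];
        for (int q = 0; q < j; q++) s -= chol[i][q] * chol[j][q];
        if (i == j) {
          if (s <= 0) return false;
          chol[i][i] = std::sqrt(s);
        } else chol[i][j] = s / chol[j][j];
      }
      for (int j = i + 1; j < AMD; j++) chol[i][j] = 0.0;
    }
    has_chol = true;
    return true;
  }
};

// adaptive step-size bookkeeping (Robbins-Monro toward target
// acceptance during warmup, frozen afterwards)
struct Adapt {
  std::vector<double> lstep;
  double target;
  Adapt() : target(0.44) {}
  void init(int n, double s0) { lstep.assign(n, std::log(s0)); }
  void tune(int k, double aprob, int iter, bool warm) {
    // diminishing Robbins-Monro adaptation continues past warmup
    // (gain ~ t^-0.6, so the kernel change vanishes asymptotically)
    (void) warm;
    double g = 1.0 / std::pow(iter + 1.0, 0.6);
    lstep[k] += g * (aprob - target);
    if (lstep[k] < -10) lstep[k] = -10;
    if (lstep[k] > 4) lstep[k] = 4;
  }
  double step(int k) const { return std::exp(lstep[k]); }
};

static double half_norm_lp(double x, double scale) {
  return x > 0 ? M_LN2 + R::dnorm(x, 0.0, scale, 1) : R_NegInf;
}

// one full sweep over all parameters; `iter` drives adaptation
static void sweep(PFModel& M, Adapt& A, AMState& AM, int iter, bool warm,
                  bool gibbs_hyper,
                  std::vector<double>& scratchU,
                  std::vector<double>& scratchLam) {
  int S = M.S, J = M.J;
  int k = 0;  // running adaptive-scalar index

  // --- species coefficients: componentwise adaptive random walk
  for (int f = 0; f < NFAM; f++) {
    bool is_beta = f < 10;
    int gear = -1;
    if (!is_beta) {
      int c = f - 10;
      for (int g = 3; g >= 0; g--) if (c >= GEAR_OFF[g]) { gear = g; break; }
    }
    for (int i = 0; i < S; i++, k++) {
      double cur = M.coef(f, i);
      double prop = cur + A.step(k) * norm_rand();
      double mu = M.fam_mean(f, i), sg = M.sigf[f];
      double dprior = R::dnorm(prop, mu, sg, 1) - R::dnorm(cur, mu, sg, 1);
      double dlik = 0.0;
      if (is_beta) {
        // lambda row changes; r unchanged
        for (int j = 0; j < J; j++) {
          scratchLam[j] = M.logLam(i, j); // save
        }
        std::vector<double> oldU(J);
        for (int j = 0; j < J; j++) oldU[j] = M.U(i, j);
        M.set_coef(f, i, prop);
        M.refresh_loglam_row(i);
        double newsum = 0.0, oldsum = 0.0;
        for (int j = 0; j < J; j++) {
          scratchU[j] = M.unit_ll(i, j);
          newsum += scratchU[j]; oldsum += oldU[j];
        }
        dlik = newsum - oldsum;
        double lacc = dlik + dprior;
        double ap = lacc >= 0 ? 1.0 : std::exp(lacc);
        if (unif_rand() < ap) {
          for (int j = 0; j < J; j++) M.U(i, j) = scratchU[j];
        } else {
          M.set_coef(f, i, cur);
          for (int j = 0; j < J; j++) {
            M.logLam(i, j) = scratchLam[j];
            M.lam(i, j) = std::exp(scratchLam[j]);
          }
        }
        A.tune(k, ap > 1 ? 1 : ap, iter, warm);
      } else {
        // r changes for this species' gear-g samples only
        const std::vector<int>& gs = M.gear_samples[gear];
        std::vector<double> oldr(gs.size());
        for (size_t a = 0; a < gs.size(); a++) oldr[a] = M.r(i, gs[a]);
        M.set_coef(f, i, prop);
        for (size_t a = 0; a < gs.size(); a++)
          M.r(i, gs[a]) = M.r_one(i, gs[a]);
        // affected visits = visits containing gear-g samples
        double newsum = 0.0, oldsum = 0.0;
        for (int j = 0; j < J; j++) {
          bool touched = false;
          for (size_t a = 0; a < M.visit_samples[j].size(); a++)
            if (M.samp_gear[M.visit_samples[j][a]] == gear) {
              touched = true; break;
            }
          if (touched) {
            scratchU[j] = M.unit_ll(i, j);
            newsum += scratchU[j]; oldsum += M.U(i, j);
          } else scratchU[j] = NA_REAL;
        }
        double lacc = newsum - oldsum + dprior;
        double ap = lacc >= 0 ? 1.0 : std::exp(lacc);
        if (unif_rand() < ap) {
          for (int j = 0; j < J; j++)
            if (!ISNA(scratchU[j])) M.U(i, j) = scratchU[j];
        } else {
          M.set_coef(f, i, cur);
          for (size_t a = 0; a < gs.size(); a++) M.r(i, gs[a]) = oldr[a];
        }
        A.tune(k, ap > 1 ? 1 : ap, iter, warm);
      }
    }
  }

  // --- fourth-corner hyperparameters
  for (int f = 0; f < NFAM; f++) {
    if (gibbs_hyper) {
      // exact bivariate-normal Gibbs draw for (eta1, eta2)
      double is2 = 1.0 / (M.sigf[f] * M.sigf[f]);
      double n = (double) S, sx = 0, sxx = 0, sy = 0, sxy = 0;
      for (int i = 0; i < S; i++) {
        double c = M.coef(f, i);
        sx += M.L[i]; sxx += M.L[i] * M.L[i];
        sy += c; sxy += c * M.L[i];
      }
      double A11 = n * is2 + 1.0 / (M.eta1_sd * M.eta1_sd);
      double A12 = sx * is2;
      double A22 = sxx * is2 + 1.0 / (M.eta2_sd * M.eta2_sd);
      double b1 = sy * is2, b2 = sxy * is2;
      double det = A11 * A22 - A12 * A12;
      double m1 = (A22 * b1 - A12 * b2) / det;
      double m2 = (A11 * b2 - A12 * b1) / det;
      double S11 = A22 / det, S12 = -A12 / det, S22 = A11 / det;
      double Lc11 = std::sqrt(S11);
      double Lc21 = S12 / Lc11;
      double Lc22 = std::sqrt(S22 - Lc21 * Lc21);
      double z1 = norm_rand(), z2 = norm_rand();
      M.eta1[f] = m1 + Lc11 * z1;
      M.eta2[f] = m2 + Lc21 * z1 + Lc22 * z2;
    } else {
      for (int h = 0; h < 2; h++, k += 0) {
        double cur = h == 0 ? M.eta1[f] : M.eta2[f];
        double sdp = h == 0 ? M.eta1_sd : M.eta2_sd;
        double prop = cur + 0.1 * norm_rand();
        double d = R::dnorm(prop, 0.0, sdp, 1) - R::dnorm(cur, 0.0, sdp, 1);
        for (int i = 0; i < S; i++) {
          double c = M.coef(f, i), Lx = h == 0 ? 1.0 : M.L[i];
          double mu_cur = M.fam_mean(f, i);
          double mu_prop = mu_cur + (prop - cur) * Lx;
          d += R::dnorm(c, mu_prop, M.sigf[f], 1) -
               R::dnorm(c, mu_cur, M.sigf[f], 1);
        }
        if (std::log(unif_rand()) < d) {
          if (h == 0) M.eta1[f] = prop; else M.eta2[f] = prop;
        }
      }
    }
    // sigma_s: adaptive random walk on log sigma (half-normal prior,
    // log-scale Jacobian)
    double ls = std::log(M.sigf[f]);
    double lsp = ls + A.step(k) * norm_rand();
    double sp = std::exp(lsp), sc = M.sigf[f];
    double d = half_norm_lp(sp, M.sig_s_scale) -
               half_norm_lp(sc, M.sig_s_scale) + (lsp - ls);
    for (int i = 0; i < S; i++) {
      double c = M.coef(f, i), mu = M.fam_mean(f, i);
      d += R::dnorm(c, mu, sp, 1) - R::dnorm(c, mu, sc, 1);
    }
    double ap = d >= 0 ? 1.0 : std::exp(d);
    if (unif_rand() < ap) M.sigf[f] = sp;
    A.tune(k, ap, iter, warm);
    k++;
  }

  // --- joint family-shift moves: translate a whole coefficient family
  // together with its eta1 (or, in the slope direction, add
  // delta * L_i to every coefficient and delta to eta2). The
  // fourth-corner terms are invariant under these moves, so only the
  // likelihood and the eta hyperprior change. They traverse the
  // family-level directions (coefficients moving with their
  // hyperparameters) that componentwise updates cross only slowly in a
  // centered hierarchy.
  for (int f = 0; f < NFAM; f++) {
    bool is_beta = f < 10;
    int gear = 0;
    if (!is_beta)
      for (int g = 3; g >= 0; g--)
        if (f - 10 >= GEAR_OFF[g]) { gear = g; break; }
    const std::vector<int>& gs = M.gear_samples[gear];
    // mode 0/1: shift eta1/eta2 with the coefficients; mode 2: rescale
    // the family deviations together with sigma_s (the group analogue
    // of a non-centered step, defeating the sigma funnel)
    for (int mrep = 0; mrep < 4; mrep++, k++) {
      int mode = mrep == 3 ? 2 : mrep;  // scale move repeated: the
                                        // sigma funnels are stiffest
      if (!is_beta && gs.empty()) continue;
      double delta = A.step(k) * norm_rand();
      double cfac = std::exp(delta);  // mode 2 only
      double d;
      std::vector<double> off(S);
      if (mode < 2) {
        double cur_eta = mode == 0 ? M.eta1[f] : M.eta2[f];
        double sd_eta = mode == 0 ? M.eta1_sd : M.eta2_sd;
        d = R::dnorm(cur_eta + delta, 0.0, sd_eta, 1) -
            R::dnorm(cur_eta, 0.0, sd_eta, 1);
        for (int i = 0; i < S; i++)
          off[i] = delta * (mode == 0 ? 1.0 : M.L[i]);
      } else {
        // prior ratio x Jacobian of the scaling reduces to
        // half-normal ratio on sigma plus log c
        d = half_norm_lp(M.sigf[f] * cfac, M.sig_s_scale) -
            half_norm_lp(M.sigf[f], M.sig_s_scale) + delta;
        for (int i = 0; i < S; i++)
          off[i] = (M.coef(f, i) - M.fam_mean(f, i)) * (cfac - 1.0);
      }
      for (int i = 0; i < S; i++)
        M.set_coef(f, i, M.coef(f, i) + off[i]);
      double newsum = 0, oldsum = 0;
      std::vector<double> newU(S * J, NA_REAL);
      std::vector<bool> touched(J, is_beta);
      bool linear = is_beta && f != 1 && f != 3;
      if (is_beta) {
        for (int i = 0; i < S; i++) {
          if (linear) {
            for (int j = 0; j < J; j++) {
              M.logLam(i, j) += off[i] * M.shiftx[f][j];
              M.lam(i, j) = std::exp(M.logLam(i, j));
            }
          } else M.refresh_loglam_row(i);
          for (int j = 0; j < J; j++) {
            double u = M.unit_ll(i, j);
            newU[j * S + i] = u;
            newsum += u; oldsum += M.U(i, j);
          }
        }
      } else {
        for (int i = 0; i < S; i++)
          for (size_t a = 0; a < gs.size(); a++)
            M.r(i, gs[a]) = M.r_one(i, gs[a]);
        for (size_t a = 0; a < gs.size(); a++)
          touched[M.samp_visit[gs[a]]] = true;
        for (int j = 0; j < J; j++) {
          if (!touched[j]) continue;
          for (int i = 0; i < S; i++) {
            double u = M.unit_ll(i, j);
            newU[j * S + i] = u;
            newsum += u; oldsum += M.U(i, j);
          }
        }
      }
      double lacc = d + newsum - oldsum;
      double ap = lacc >= 0 ? 1.0 : std::exp(lacc);
      if (unif_rand() < ap) {
        if (mode == 0) M.eta1[f] += delta;
        else if (mode == 1) M.eta2[f] += delta;
        else M.sigf[f] *= cfac;
        for (int j = 0; j < J; j++) {
          if (!touched[j]) continue;
          for (int i = 0; i < S; i++) M.U(i, j) = newU[j * S + i];
        }
      } else {
        for (int i = 0; i < S; i++) {
          M.set_coef(f, i, M.coef(f, i) - off[i]);
          if (linear) {
            for (int j = 0; j < J; j++) {
              M.logLam(i, j) -= off[i] * M.shiftx[f][j];
              M.lam(i, j) = std::exp(M.logLam(i, j));
            }
          }
        }
        if (is_beta && !linear) {
          for (int i = 0; i < S; i++) M.refresh_loglam_row(i);
        } else if (!is_beta) {
          for (int i = 0; i < S; i++)
            for (size_t a = 0; a < gs.size(); a++)
              M.r(i, gs[a]) = M.r_one(i, gs[a]);
        }
      }
      A.tune(k, ap, iter, warm);
    }
  }

  // --- joint adaptive-Metropolis move on the 32 family intercepts,
  // coefficients translated along (fourth-corner terms invariant):
  // the learned covariance captures the cross-family ridges (abundance
  // vs catchability level, depth intercept vs Ricker decay, main
  // channel vs floodplain offset) in one correlated proposal
  if (AM.has_chol) {
    for (int rep = 0; rep < M.am_reps; rep++) {
      double z[AMD], dl[AMD];
      double s = std::exp(AM.lscale);
      double d = 0.0;
      for (int a = 0; a < AMD; a++) z[a] = norm_rand();
      for (int a = 0; a < AMD; a++) {
        double t = 0.0;
        for (int b = 0; b <= a; b++) t += AM.chol[a][b] * z[b];
        dl[a] = s * t;
        double cur = a < NFAM ? M.eta1[a] : M.eta2[a - NFAM];
        double sd = a < NFAM ? M.eta1_sd : M.eta2_sd;
        d += R::dnorm(cur + dl[a], 0.0, sd, 1) -
             R::dnorm(cur, 0.0, sd, 1);
      }
      for (int f = 0; f < NFAM; f++)
        for (int i = 0; i < S; i++)
          M.set_coef(f, i, M.coef(f, i) + dl[f] +
                             dl[NFAM + f] * M.L[i]);
      double newsum = 0, oldsum = 0;
      std::vector<double> newU(S * J);
      for (int i = 0; i < S; i++) {
        M.refresh_loglam_row(i);
        M.refresh_r_row(i);
        for (int j = 0; j < J; j++) {
          double u = M.unit_ll(i, j);
          newU[j * S + i] = u;
          newsum += u; oldsum += M.U(i, j);
        }
      }
      double lacc = d + newsum - oldsum;
      double ap = lacc >= 0 ? 1.0 : std::exp(lacc);
      if (unif_rand() < ap) {
        for (int f = 0; f < NFAM; f++) {
          M.eta1[f] += dl[f];
          M.eta2[f] += dl[NFAM + f];
        }
        for (int i = 0; i < S; i++)
          for (int j = 0; j < J; j++) M.U(i, j) = newU[j * S + i];
      } else {
        for (int f = 0; f < NFAM; f++)
          for (int i = 0; i < S; i++)
            M.set_coef(f, i, M.coef(f, i) - dl[f] -
                               dl[NFAM + f] * M.L[i]);
        for (int i = 0; i < S; i++) {
          M.refresh_loglam_row(i);
          M.refresh_r_row(i);
        }
      }
      AM.lscale += (ap - 0.25) / std::pow(iter + 1.0, 0.6);
    }
  }

  // --- see-saw moves along the global abundance / catchability ridge:
  // raise the abundance intercept family while lowering all four
  // catchability intercept families (expected detections are nearly
  // invariant, so the move travels the weakly identified direction);
  // repeated because this is the stiffest posterior direction
  for (int ssrep = 0; ssrep < M.seesaw_reps; ssrep++) {
    double delta = A.step(k) * norm_rand();
    double d = R::dnorm(M.eta1[0] + delta, 0.0, M.eta1_sd, 1) -
               R::dnorm(M.eta1[0], 0.0, M.eta1_sd, 1);
    for (int g = 0; g < 4; g++) {
      int fg = 10 + GEAR_OFF[g];
      d += R::dnorm(M.eta1[fg] - delta, 0.0, M.eta1_sd, 1) -
           R::dnorm(M.eta1[fg], 0.0, M.eta1_sd, 1);
    }
    for (int i = 0; i < S; i++) {
      M.beta(i, 0) += delta;
      for (int g = 0; g < 4; g++) M.phi(i, GEAR_OFF[g]) -= delta;
      for (int j = 0; j < J; j++) {
        M.logLam(i, j) += delta;
        M.lam(i, j) = std::exp(M.logLam(i, j));
      }
      M.refresh_r_row(i);
    }
    double newsum = 0, oldsum = 0;
    std::vector<double> newU(S * J);
    for (int i = 0; i < S; i++)
      for (int j = 0; j < J; j++) {
        double u = M.unit_ll(i, j);
        newU[j * S + i] = u;
        newsum += u; oldsum += M.U(i, j);
      }
    double lacc = d + newsum - oldsum;
    double ap = lacc >= 0 ? 1.0 : std::exp(lacc);
    if (unif_rand() < ap) {
      M.eta1[0] += delta;
      for (int g = 0; g < 4; g++) M.eta1[10 + GEAR_OFF[g]] -= delta;
      for (int i = 0; i < S; i++)
        for (int j = 0; j < J; j++) M.U(i, j) = newU[j * S + i];
    } else {
      for (int i = 0; i < S; i++) {
        M.beta(i, 0) -= delta;
        for (int g = 0; g < 4; g++) M.phi(i, GEAR_OFF[g]) += delta;
        for (int j = 0; j < J; j++) {
          M.logLam(i, j) -= delta;
          M.lam(i, j) = std::exp(M.logLam(i, j));
        }
        M.refresh_r_row(i);
      }
    }
    A.tune(k, ap, iter, warm);
  }
  k++;

  // --- prior-only swap moves: every abundance family whose covariate
  // is constant within a pool is exactly collinear with a patterned
  // shift of the pool random effects (and the intercept family also
  // with the year effects). Translate the family (with its eta1) by
  // delta and the random-effect block by -delta * x_p: log(lambda) is
  // exactly invariant, so no likelihood recomputation is needed and
  // only the random-effect and eta1 priors arbitrate.
  {
    static const int SWAP_FAMS[8] = {0, 2, 4, 5, 6, 7, 8, 9};
    for (int h = 0; h < 9; h++, k++) {
      bool year = h == 8;             // intercept vs year effects
      int f = year ? 0 : SWAP_FAMS[h];
      std::vector<double>& e = year ? M.eps_time : M.eps_pool;
      double sig = year ? M.sigma_time : M.sigma_pool;
      double delta = A.step(k) * norm_rand();
      double d = R::dnorm(M.eta1[f] + delta, 0.0, M.eta1_sd, 1) -
                 R::dnorm(M.eta1[f], 0.0, M.eta1_sd, 1);
      for (size_t a = 0; a < e.size(); a++) {
        double x = year ? 1.0 : M.poolx[f][a];
        d += R::dnorm(e[a] - delta * x, 0.0, sig, 1) -
             R::dnorm(e[a], 0.0, sig, 1);
      }
      double ap = d >= 0 ? 1.0 : std::exp(d);
      if (unif_rand() < ap) {
        for (size_t a = 0; a < e.size(); a++)
          e[a] -= delta * (year ? 1.0 : M.poolx[f][a]);
        for (int i = 0; i < S; i++)
          M.beta(i, f) += delta;
        M.eta1[f] += delta;
      }
      A.tune(k, ap, iter, warm);
    }
  }

  // --- pool random effects (lambda shifts multiplicatively)
  for (int p = 0; p < M.P; p++, k++) {
    double cur = M.eps_pool[p];
    double delta = A.step(k) * norm_rand();
    double prop = cur + delta;
    double d = R::dnorm(prop, 0.0, M.sigma_pool, 1) -
               R::dnorm(cur, 0.0, M.sigma_pool, 1);
    const std::vector<int>& vs = M.pool_visits[p];
    std::vector<double> newU(vs.size() * S);
    M.eps_pool[p] = prop;
    double newsum = 0, oldsum = 0;
    for (size_t a = 0; a < vs.size(); a++) {
      int j = vs[a];
      for (int i = 0; i < S; i++) {
        M.logLam(i, j) += delta;
        M.lam(i, j) = std::exp(M.logLam(i, j));
      }
      for (int i = 0; i < S; i++) {
        double u = M.unit_ll(i, j);
        newU[a * S + i] = u;
        newsum += u; oldsum += M.U(i, j);
      }
    }
    double lacc = d + newsum - oldsum;
    double ap = lacc >= 0 ? 1.0 : std::exp(lacc);
    if (unif_rand() < ap) {
      for (size_t a = 0; a < vs.size(); a++)
        for (int i = 0; i < S; i++) M.U(i, vs[a]) = newU[a * S + i];
    } else {
      M.eps_pool[p] = cur;
      for (size_t a = 0; a < vs.size(); a++) {
        int j = vs[a];
        for (int i = 0; i < S; i++) {
          M.logLam(i, j) -= delta;
          M.lam(i, j) = std::exp(M.logLam(i, j));
        }
      }
    }
    A.tune(k, ap, iter, warm);
  }

  // --- year random effects
  for (int t = 0; t < M.Ny; t++, k++) {
    double cur = M.eps_time[t];
    double delta = A.step(k) * norm_rand();
    double prop = cur + delta;
    double d = R::dnorm(prop, 0.0, M.sigma_time, 1) -
               R::dnorm(cur, 0.0, M.sigma_time, 1);
    const std::vector<int>& vs = M.year_visits[t];
    std::vector<double> newU(vs.size() * S);
    M.eps_time[t] = prop;
    double newsum = 0, oldsum = 0;
    for (size_t a = 0; a < vs.size(); a++) {
      int j = vs[a];
      for (int i = 0; i < S; i++) {
        M.logLam(i, j) += delta;
        M.lam(i, j) = std::exp(M.logLam(i, j));
      }
      for (int i = 0; i < S; i++) {
        double u = M.unit_ll(i, j);
        newU[a * S + i] = u;
        newsum += u; oldsum += M.U(i, j);
      }
    }
    double lacc = d + newsum - oldsum;
    double ap = lacc >= 0 ? 1.0 : std::exp(lacc);
    if (unif_rand() < ap) {
      for (size_t a = 0; a < vs.size(); a++)
        for (int i = 0; i < S; i++) M.U(i, vs[a]) = newU[a * S + i];
    } else {
      M.eps_time[t] = cur;
      for (size_t a = 0; a < vs.size(); a++) {
        int j = vs[a];
        for (int i = 0; i < S; i++) {
          M.logLam(i, j) -= delta;
          M.lam(i, j) = std::exp(M.logLam(i, j));
        }
      }
    }
    A.tune(k, ap, iter, warm);
  }

  // --- random-effect spreads: log-scale adaptive random walk
  for (int h = 0; h < 2; h++, k++) {
    double cur = h == 0 ? M.sigma_pool : M.sigma_time;
    double scale = h == 0 ? M.sig_pool_scale : M.sig_time_scale;
    const std::vector<double>& e = h == 0 ? M.eps_pool : M.eps_time;
    double ls = std::log(cur);
    double lsp = ls + A.step(k) * norm_rand();
    double sp = std::exp(lsp);
    double d = half_norm_lp(sp, scale) - half_norm_lp(cur, scale) +
               (lsp - ls);
    for (size_t a = 0; a < e.size(); a++)
      d += R::dnorm(e[a], 0.0, sp, 1) - R::dnorm(e[a], 0.0, cur, 1);
    double ap = d >= 0 ? 1.0 : std::exp(d);
    if (unif_rand() < ap) {
      if (h == 0) M.sigma_pool = sp; else M.sigma_time = sp;
    }
    A.tune(k, ap, iter, warm);
  }

  // --- random-effect scale moves: rescale a whole random-effect block
  // with its spread (same funnel-defeating logic as the family scale
  // moves; the likelihood sees per-group shifts eps * (c - 1))
  for (int h = 0; h < 2; h++, k++) {
    double delta = A.step(k) * norm_rand();
    double cfac = std::exp(delta);
    double cur = h == 0 ? M.sigma_pool : M.sigma_time;
    double scale = h == 0 ? M.sig_pool_scale : M.sig_time_scale;
    std::vector<double>& e = h == 0 ? M.eps_pool : M.eps_time;
    const std::vector<int>& vp = h == 0 ? M.visit_pool : M.visit_year;
    double d = half_norm_lp(cur * cfac, scale) -
               half_norm_lp(cur, scale) + delta;
    for (int j = 0; j < J; j++) {
      double sh = e[vp[j]] * (cfac - 1.0);
      for (int i = 0; i < S; i++) {
        M.logLam(i, j) += sh;
        M.lam(i, j) = std::exp(M.logLam(i, j));
      }
    }
    double newsum = 0, oldsum = 0;
    std::vector<double> newU(S * J);
    for (int i = 0; i < S; i++)
      for (int j = 0; j < J; j++) {
        double u = M.unit_ll(i, j);
        newU[j * S + i] = u;
        newsum += u; oldsum += M.U(i, j);
      }
    double lacc = d + newsum - oldsum;
    double ap = lacc >= 0 ? 1.0 : std::exp(lacc);
    if (unif_rand() < ap) {
      for (size_t a = 0; a < e.size(); a++) e[a] *= cfac;
      if (h == 0) M.sigma_pool *= cfac; else M.sigma_time *= cfac;
      for (int i = 0; i < S; i++)
        for (int j = 0; j < J; j++) M.U(i, j) = newU[j * S + i];
    } else {
      for (int j = 0; j < J; j++) {
        double sh = e[vp[j]] * (cfac - 1.0);
        for (int i = 0; i < S; i++) {
          M.logLam(i, j) -= sh;
          M.lam(i, j) = std::exp(M.logLam(i, j));
        }
      }
    }
    A.tune(k, ap, iter, warm);
  }

  // --- effort exponents (logit scale, uniform(0,1) prior) and the 5-m
  // seine scalar; these touch many samples, so refresh caches wholesale
  for (int g = 0; g <= 4; g++, k++) {
    bool is_lm5 = g == 4;
    const std::vector<int>& gs = is_lm5 ? M.lm5_samples
                                        : M.gear_samples[g];
    if (gs.empty()) { continue; }
    double cur = is_lm5 ? M.lm_scalar : M.upsilon[g];
    double lcur = std::log(cur / (1.0 - cur));
    double lprop = lcur + A.step(k) * norm_rand();
    double prop = 1.0 / (1.0 + std::exp(-lprop));
    // uniform prior + logit Jacobian
    double d = std::log(prop * (1.0 - prop)) -
               std::log(cur * (1.0 - cur));
    std::vector<double> oldr(gs.size() * S);
    for (size_t a = 0; a < gs.size(); a++)
      for (int i = 0; i < S; i++) oldr[a * S + i] = M.r(i, gs[a]);
    if (is_lm5) M.lm_scalar = prop; else M.upsilon[g] = prop;
    if (is_lm5) {
      double ratio = prop / cur;
      for (size_t a = 0; a < gs.size(); a++)
        for (int i = 0; i < S; i++) M.r(i, gs[a]) *= ratio;
    } else {
      M.refresh_effpow(g);
      for (size_t a = 0; a < gs.size(); a++)
        for (int i = 0; i < S; i++)
          M.r(i, gs[a]) = M.r_one(i, gs[a]);
    }
    std::vector<bool> touched(M.J, false);
    for (size_t a = 0; a < gs.size(); a++)
      touched[M.samp_visit[gs[a]]] = true;
    double newsum = 0, oldsum = 0;
    std::vector<double> newU(S * M.J, NA_REAL);
    for (int j = 0; j < M.J; j++) {
      if (!touched[j]) continue;
      for (int i = 0; i < S; i++) {
        double u = M.unit_ll(i, j);
        newU[j * S + i] = u;
        newsum += u; oldsum += M.U(i, j);
      }
    }
    double lacc = d + newsum - oldsum;
    double ap = lacc >= 0 ? 1.0 : std::exp(lacc);
    if (unif_rand() < ap) {
      for (int j = 0; j < M.J; j++) {
        if (!touched[j]) continue;
        for (int i = 0; i < S; i++) M.U(i, j) = newU[j * S + i];
      }
    } else {
      if (is_lm5) M.lm_scalar = cur;
      else { M.upsilon[g] = cur; M.refresh_effpow(g); }
      for (size_t a = 0; a < gs.size(); a++)
        for (int i = 0; i < S; i++) M.r(i, gs[a]) = oldr[a * S + i];
    }
    A.tune(k, ap, iter, warm);
  }
}

// flatten the state in the same order as flatten_params() in R
static void store_draw(const PFModel& M, double* out) {
  int S = M.S, k = 0;
  for (int c = 0; c < 10; c++)
    for (int i = 0; i < S; i++) out[k++] = M.beta(i, c);
  for (int g = 0; g < 4; g++)
    for (int c = 0; c < GEAR_NPHI[g]; c++)
      for (int i = 0; i < S; i++) out[k++] = M.phi(i, GEAR_OFF[g] + c);
  for (int f = 0; f < NFAM; f++) out[k++] = M.eta1[f];
  for (int f = 0; f < NFAM; f++) out[k++] = M.eta2[f];
  for (int f = 0; f < NFAM; f++) out[k++] = M.sigf[f];
  for (int p = 0; p < M.P; p++) out[k++] = M.eps_pool[p];
  for (int t = 0; t < M.Ny; t++) out[k++] = M.eps_time[t];
  out[k++] = M.sigma_pool;
  out[k++] = M.sigma_time;
  for (int g = 0; g < 4; g++) out[k++] = M.upsilon[g];
  out[k++] = M.lm_scalar;
}

// [[Rcpp::export]]
List cpp_run_chain(List data, List init, List priors, List control) {
  RNGScope scope;
  PFModel M;
  M.init_from(data, init, priors, control);
  int n_warmup = as<int>(control["n_warmup"]);
  int n_draws = as<int>(control["n_draws"]);
  int thin = as<int>(control["thin"]);
  bool gibbs_hyper = as<bool>(control["gibbs_hyper"]);

  int n_scalars = NFAM * M.S + NFAM + 4 * NFAM + 1 + 9 + M.P + M.Ny +
                  2 + 2 + 5 + 4;
  Adapt A;
  A.init(n_scalars, 0.2);

  int npar = 32 * M.S + 3 * NFAM + M.P + M.Ny + 2 + 4 + 1;
  NumericMatrix draws(n_draws, npar);
  NumericVector lp(n_draws);
  std::vector<double> scratchU(M.J), scratchLam(M.J), tmp(npar);

  int total = n_warmup + n_draws * thin;
  int d = 0;
  AMState AM;
  for (int iter = 0; iter < total; iter++) {
    bool warm = iter < n_warmup;
    sweep(M, A, AM, iter, warm, gibbs_hyper, scratchU, scratchLam);
    {
      std::vector<double> st(M.eta1.begin(), M.eta1.end());
      st.insert(st.end(), M.eta2.begin(), M.eta2.end());
      AM.update(st);
      if (iter >= 100 && iter % 100 == 0) AM.refresh_chol();
    }
    if (!warm && ((iter - n_warmup + 1) % thin == 0)) {
      store_draw(M, tmp.data());
      for (int q = 0; q < npar; q++) draws(d, q) = tmp[q];
      lp[d] = M.total_lp();
      d++;
    }
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["draws"] = draws, _["lp"] = lp,
                      _["adapt_lstep"] = NumericVector(A.lstep.begin(),
                                                       A.lstep.end()),
                      _["am_lscale"] = AM.lscale);
}

// [[Rcpp::export]]
double cpp_log_posterior(List data, List init, List priors,
                         List control) {
  PFModel M;
  M.init_from(data, init, priors, control);
  return M.total_lp();
}

// [[Rcpp::export]]
double cpp_loglik_total(List data, List init, List priors,
                        List control) {
  PFModel M;
  M.init_from(data, init, priors, control);
  return M.total_loglik();
}
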