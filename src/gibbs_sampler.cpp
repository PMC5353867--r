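// Gibbs sampler for the two-population multi-trait Bayesian rrBLUP model.
//
// Model (heterogeneous form; the homogeneous model drops the region channel):
//   y_i = u_i + W_i a_i + e_i,            e_i ~ N(0, D_i sigma2_e_i)
//   a_ik = r_i s0_k + r_{i,j(k)} s1_k + a*_ik
//   s0_k, s1_k ~ N(0,1);  a*_ik ~ N(0, sigma2_a*_i);  r_ij ~ N(0, sigma2_r_i)
//   r_i, variances: flat priors (variances truncated by a divergence ceiling)
//
// All full conditionals are Gaussian or scaled inverse chi-square; residuals
// are maintained incrementally (adjust-on-update) so one cycle is O(n m).
// Randomness comes from R's RNG only, so set.seed() in R fixes the chain.

#include <Rcpp.h>
using namespace Rcpp;

static inline double rnorm1(double mean, double var) {
  return mean + sqrt(var) * norm_rand();
}

// scaled inverse chi-square draw: SS / chisq(df); flat prior on the variance
// gives df = n - 2, improper for n <= 2, in which case fall back to df = n
// (Jeffreys-style), documented in the methods vignette.
static inline double rinvchisq(double ss, int n) {
  double df = (n > 2) ? n - 2.0 : (double)n;
  double x = R::rchisq(df);
  if (x < 1e-300) x = 1e-300;
  double v = ss / x;
  return (v < 1e-30) ? 1e-30 : v;
}

static void check_ceiling(double v, double ceiling, const char* name,
                          int cycle) {
  if (v > ceiling)
    stop("divergence guard: %s = %g exceeded ceiling %g at cycle %d",
         name, v, ceiling, cycle + 1);
}

// [[Rcpp::export(name = ".gibbs_core")]]
List gibbs_core(NumericMatrix W1, NumericMatrix W2,
                NumericVector y1, NumericVector y2,
                NumericVector d1, NumericVector d2,
                IntegerVector reg,          // 1-based region label per marker
                int n_regions,
                NumericVector wv1, NumericVector wv2, NumericVector wc,
                int n_cycles, int burn_in, int thin,
                bool heterogeneous,
                bool update_shared,         // r_i * s0 channel on/off
                bool update_variances,      // hyper-variance updates on/off
                NumericVector start_sigma2_e, NumericVector start_sigma2_a,
                NumericVector start_r, NumericVector start_sigma2_r,
                double var_ceiling) {
  const int n1 = W1.nrow(), n2 = W2.nrow(), m = W1.ncol();
  if (W2.ncol() != m) stop("panels disagree on marker count");
  const int J = n_regions;

  // raw column-major access and precomputed inverse weights: the per-cycle
  // cost is dominated by column dot products / axpy, so avoid NumericMatrix
  // element indexing and divisions in the inner loops
  const double* W1p = W1.begin();
  const double* W2p = W2.begin();
  std::vector<double> id1(n1), id2(n2);
  double cu1 = 0.0, cu2 = 0.0, logd1 = 0.0, logd2 = 0.0;
  for (int n = 0; n < n1; ++n) {
    id1[n] = 1.0 / d1[n]; cu1 += id1[n]; logd1 += log(d1[n]);
  }
  for (int n = 0; n < n2; ++n) {
    id2[n] = 1.0 / d2[n]; cu2 += id2[n]; logd2 += log(d2[n]);
  }
  // weighted column cross-products (fixed over cycles)
  std::vector<double> c1(m), c2(m);
  for (int k = 0; k < m; ++k) {
    const double* w1k = W1p + (size_t)k * n1;
    const double* w2k = W2p + (size_t)k * n2;
    double s = 0.0;
    for (int n = 0; n < n1; ++n) s += w1k[n] * w1k[n] * id1[n];
    c1[k] = s;
    s = 0.0;
    for (int n = 0; n < n2; ++n) s += w2k[n] * w2k[n] * id2[n];
    c2[k] = s;
  }

  // state
  double sig2e1 = start_sigma2_e[0], sig2e2 = start_sigma2_e[1];
  double sig2a1 = start_sigma2_a[0], sig2a2 = start_sigma2_a[1];
  double r1 = start_r[0], r2 = start_r[1];
  double sig2r1 = start_sigma2_r[0], sig2r2 = start_sigma2_r[1];
  std::vector<double> s0(m, 0.0), s1v(m, 0.0);
  std::vector<double> a1s(m, 0.0), a2s(m, 0.0);
  std::vector<double> r1j(J, 0.0), r2j(J, 0.0);
  double u1, u2;
  {
    double sy1 = 0.0, sy2 = 0.0;
    for (int n = 0; n < n1; ++n) sy1 += y1[n] / d1[n];
    for (int n = 0; n < n2; ++n) sy2 += y2[n] / d2[n];
    u1 = sy1 / cu1; u2 = sy2 / cu2;
  }
  std::vector<double> e1(n1), e2(n2);
  for (int n = 0; n < n1; ++n) e1[n] = y1[n] - u1;
  for (int n = 0; n < n2; ++n) e2[n] = y2[n] - u2;

  // output layout
  const int n_saved = (burn_in < n_cycles) ? (n_cycles - burn_in) / thin : 0;
  const int n_scalar = 11; // u1 u2 r1 r2 s2a1 s2a2 s2r1 s2r2 s2e1 s2e2 dev
  const int ncols = n_scalar + 8 * J + 3;
  NumericMatrix samples(n_saved, ncols);
  CharacterVector cn(ncols);
  {
    const char* base[] = {"u1", "u2", "r1", "r2", "sigma2_a1", "sigma2_a2",
                          "sigma2_r1", "sigma2_r2", "sigma2_e1", "sigma2_e2",
                          "deviance"};
    for (int i = 0; i < n_scalar; ++i) cn[i] = base[i];
    const char* stub[] = {"var_a1", "var_a2", "cov_a", "r1j", "r2j",
                          "vg1", "vg2", "cov"};
    int col = n_scalar;
    for (int b = 0; b < 8; ++b)
      for (int j = 0; j < J; ++j)
        cn[col++] = std::string(stub[b]) + "_" + std::to_string(j + 1);
    cn[col++] = "vg1_total"; cn[col++] = "vg2_total"; cn[col++] = "cov_total";
  }
  colnames(samples) = cn;

  // posterior-mean accumulators (for DIC's D(theta_bar) and GEBV)
  std::vector<double> acc_a1(m, 0.0), acc_a2(m, 0.0);
  double acc_u1 = 0.0, acc_u2 = 0.0, acc_s2e1 = 0.0, acc_s2e2 = 0.0;

  std::vector<double> xbuf(std::max(n1, n2));
  int saved = 0;

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    const double lam1 = 1.0 / sig2e1, lam2 = 1.0 / sig2e2;

    // --- overall means (flat prior) ---
    {
      double t = 0.0;
      for (int n = 0; n < n1; ++n) t += e1[n] / d1[n];
      double mean = (t + u1 * cu1) / cu1, v = sig2e1 / cu1;
      double un = rnorm1(mean, v);
      for (int n = 0; n < n1; ++n) e1[n] += (u1 - un);
      u1 = un;
      t = 0.0;
      for (int n = 0; n < n2; ++n) t += e2[n] / d2[n];
      mean = (t + u2 * cu2) / cu2; v = sig2e2 / cu2;
      un = rnorm1(mean, v);
      for (int n = 0; n < n2; ++n) e2[n] += (u2 - un);
      u2 = un;
    }

    // --- per-marker sweep: s0, s1, a*_1, a*_2 ---
    for (int k = 0; k < m; ++k) {
      const double* w1k = W1p + (size_t)k * n1;
      const double* w2k = W2p + (size_t)k * n2;
      double t1 = 0.0, t2 = 0.0;
      for (int n = 0; n < n1; ++n) t1 += w1k[n] * e1[n] * id1[n];
      for (int n = 0; n < n2; ++n) t2 += w2k[n] * e2[n] * id2[n];
      double del1 = 0.0, del2 = 0.0; // accumulated column delta per pop

      if (update_shared) {           // shared latent vector s0
        double b = s0[k];
        double lhs = r1 * r1 * c1[k] * lam1 + r2 * r2 * c2[k] * lam2 + 1.0;
        double rhs = r1 * lam1 * (t1 + r1 * c1[k] * b) +
                     r2 * lam2 * (t2 + r2 * c2[k] * b);
        double bn = rnorm1(rhs / lhs, 1.0 / lhs);
        double d = bn - b;
        s0[k] = bn;
        t1 -= r1 * c1[k] * d; t2 -= r2 * c2[k] * d;
        del1 += r1 * d; del2 += r2 * d;
      }

      if (heterogeneous) {           // region-channel latent vector s1
        const int j = reg[k] - 1;
        double p1 = r1j[j], p2 = r2j[j];
        double b = s1v[k];
        double lhs = p1 * p1 * c1[k] * lam1 + p2 * p2 * c2[k] * lam2 + 1.0;
        double rhs = p1 * lam1 * (t1 + p1 * c1[k] * b) +
                     p2 * lam2 * (t2 + p2 * c2[k] * b);
        double bn = rnorm1(rhs / lhs, 1.0 / lhs);
        double d = bn - b;
        s1v[k] = bn;
        t1 -= p1 * c1[k] * d; t2 -= p2 * c2[k] * d;
        del1 += p1 * d; del2 += p2 * d;
      }

      { // residual SNP effect, population 1
        double b = a1s[k];
        double lhs = c1[k] * lam1 + 1.0 / sig2a1;
        double rhs = lam1 * (t1 + c1[k] * b);
        double bn = rnorm1(rhs / lhs, 1.0 / lhs);
        double d = bn - b;
        a1s[k] = bn;
        t1 -= c1[k] * d;
        del1 += d;
      }
      { // residual SNP effect, population 2
        double b = a2s[k];
        double lhs = c2[k] * lam2 + 1.0 / sig2a2;
        double rhs = lam2 * (t2 + c2[k] * b);
        double bn = rnorm1(rhs / lhs, 1.0 / lhs);
        double d = bn - b;
        a2s[k] = bn;
        t2 -= c2[k] * d;
        del2 += d;
      }

      if (del1 != 0.0)
        for (int n = 0; n < n1; ++n) e1[n] -= w1k[n] * del1;
      if (del2 != 0.0)
        for (int n = 0; n < n2; ++n) e2[n] -= w2k[n] * del2;
    }

    // --- population scaling scalars r_i on the shared channel ---
    if (update_shared) {
      for (int pop = 0; pop < 2; ++pop) {
        const double* Wp = (pop == 0) ? W1p : W2p;
        std::vector<double>& e = (pop == 0) ? e1 : e2;
        std::vector<double>& id = (pop == 0) ? id1 : id2;
        const int nn = (pop == 0) ? n1 : n2;
        const double lam = (pop == 0) ? lam1 : lam2;
        double& r = (pop == 0) ? r1 : r2;
        std::fill(xbuf.begin(), xbuf.begin() + nn, 0.0);
        for (int k = 0; k < m; ++k) {      // x = W s0, column-wise
          const double b = s0[k];
          if (b == 0.0) continue;
          const double* wk = Wp + (size_t)k * nn;
          for (int n = 0; n < nn; ++n) xbuf[n] += wk[n] * b;
        }
        double xx = 0.0, xe = 0.0;
        for (int n = 0; n < nn; ++n) {
          xx += xbuf[n] * xbuf[n] * id[n];
          xe += xbuf[n] * e[n] * id[n];
        }
        if (xx > 1e-300) {
          double lhs = lam * xx;  // flat prior
          double rn = rnorm1(lam * (xe + xx * r) / lhs, 1.0 / lhs);
          double del = rn - r;
          r = rn;
          for (int n = 0; n < nn; ++n) e[n] -= xbuf[n] * del;
        }
      }
    }

    // --- region scaling scalars r_ij, prior N(0, sigma2_r_i) ---
    if (heterogeneous) {
      // contiguous column range per region (regions are contiguous by
      // construction; verified in the R wrapper)
      for (int pop = 0; pop < 2; ++pop) {
        const double* Wp = (pop == 0) ? W1p : W2p;
        std::vector<double>& e = (pop == 0) ? e1 : e2;
        std::vector<double>& id = (pop == 0) ? id1 : id2;
        const int nn = (pop == 0) ? n1 : n2;
        const double lam = (pop == 0) ? lam1 : lam2;
        const double s2r = (pop == 0) ? sig2r1 : sig2r2;
        std::vector<double>& rj = (pop == 0) ? r1j : r2j;
        int k0 = 0;
        for (int j = 0; j < J; ++j) {
          int k1 = k0;
          while (k1 < m && reg[k1] - 1 == j) ++k1;
          std::fill(xbuf.begin(), xbuf.begin() + nn, 0.0);
          for (int k = k0; k < k1; ++k) {  // x = W_j s1_j, column-wise
            const double b = s1v[k];
            if (b == 0.0) continue;
            const double* wk = Wp + (size_t)k * nn;
            for (int n = 0; n < nn; ++n) xbuf[n] += wk[n] * b;
          }
          double xx = 0.0, xe = 0.0;
          for (int n = 0; n < nn; ++n) {
            xx += xbuf[n] * xbuf[n] * id[n];
            xe += xbuf[n] * e[n] * id[n];
          }
          double lhs = lam * xx + 1.0 / s2r;
          double rhs = lam * (xe + xx * rj[j]);
          double rn = rnorm1(rhs / lhs, 1.0 / lhs);
          double del = rn - rj[j];
          rj[j] = rn;
          if (del != 0.0)
            for (int n = 0; n < nn; ++n) e[n] -= xbuf[n] * del;
          k0 = k1;
        }
      }
    }

    // --- variances (scaled inverse chi-square under flat priors) ---
    double sse1 = 0.0, sse2 = 0.0;
    for (int n = 0; n < n1; ++n) sse1 += e1[n] * e1[n] / d1[n];
    for (int n = 0; n < n2; ++n) sse2 += e2[n] * e2[n] / d2[n];
    if (update_variances) {
      double ss = 0.0;
      for (int k = 0; k < m; ++k) ss += a1s[k] * a1s[k];
      sig2a1 = rinvchisq(ss, m);
      check_ceiling(sig2a1, var_ceiling, "sigma2_a1", cyc);
      ss = 0.0;
      for (int k = 0; k < m; ++k) ss += a2s[k] * a2s[k];
      sig2a2 = rinvchisq(ss, m);
      check_ceiling(sig2a2, var_ceiling, "sigma2_a2", cyc);
      if (heterogeneous) {
        ss = 0.0;
        for (int j = 0; j < J; ++j) ss += r1j[j] * r1j[j];
        sig2r1 = rinvchisq(ss, J);
        check_ceiling(sig2r1, var_ceiling, "sigma2_r1", cyc);
        ss = 0.0;
        for (int j = 0; j < J; ++j) ss += r2j[j] * r2j[j];
        sig2r2 = rinvchisq(ss, J);
        check_ceiling(sig2r2, var_ceiling, "sigma2_r2", cyc);
      }
      sig2e1 = rinvchisq(sse1, n1);
      check_ceiling(sig2e1, var_ceiling, "sigma2_e1", cyc);
      sig2e2 = rinvchisq(sse2, n2);
      check_ceiling(sig2e2, var_ceiling, "sigma2_e2", cyc);
    }

    // --- deviance of the current state ---
    const double deviance =
      n1 * log(2.0 * M_PI * sig2e1) + logd1 + sse1 / sig2e1 +
      n2 * log(2.0 * M_PI * sig2e2) + logd2 + sse2 / sig2e2;

    // --- store thinned draw ---
    const int c1based = cyc + 1;
    if (c1based > burn_in && (c1based - burn_in) % thin == 0 &&
        saved < n_saved) {
      int col = 0;
      samples(saved, col++) = u1; samples(saved, col++) = u2;
      samples(saved, col++) = r1; samples(saved, col++) = r2;
      samples(saved, col++) = sig2a1; samples(saved, col++) = sig2a2;
      samples(saved, col++) = sig2r1; samples(saved, col++) = sig2r2;
      samples(saved, col++) = sig2e1; samples(saved, col++) = sig2e2;
      samples(saved, col++) = deviance;
      double tot1 = 0.0, tot2 = 0.0, totc = 0.0;
      const double shared_v1 = update_shared ? r1 * r1 : 0.0;
      const double shared_v2 = update_shared ? r2 * r2 : 0.0;
      const double shared_c = update_shared ? r1 * r2 : 0.0;
      for (int j = 0; j < J; ++j) {
        double q1 = heterogeneous ? r1j[j] : 0.0;
        double q2 = heterogeneous ? r2j[j] : 0.0;
        double va1 = shared_v1 + q1 * q1 + sig2a1;
        double va2 = shared_v2 + q2 * q2 + sig2a2;
        double cva = shared_c + q1 * q2;
        samples(saved, n_scalar + 0 * J + j) = va1;
        samples(saved, n_scalar + 1 * J + j) = va2;
        samples(saved, n_scalar + 2 * J + j) = cva;
        samples(saved, n_scalar + 3 * J + j) = q1;
        samples(saved, n_scalar + 4 * J + j) = q2;
        double vg1 = wv1[j] * va1, vg2 = wv2[j] * va2, vgc = wc[j] * cva;
        samples(saved, n_scalar + 5 * J + j) = vg1;
        samples(saved, n_scalar + 6 * J + j) = vg2;
        samples(saved, n_scalar + 7 * J + j) = vgc;
        tot1 += vg1; tot2 += vg2; totc += vgc;
      }
      samples(saved, n_scalar + 8 * J + 0) = tot1;
      samples(saved, n_scalar + 8 * J + 1) = tot2;
      samples(saved, n_scalar + 8 * J + 2) = totc;
      for (int k = 0; k < m; ++k) {
        double q1 = heterogeneous ? r1j[reg[k] - 1] : 0.0;
        double q2 = heterogeneous ? r2j[reg[k] - 1] : 0.0;
        double sh = update_shared ? s0[k] : 0.0;
        acc_a1[k] += r1 * sh + q1 * s1v[k] + a1s[k];
        acc_a2[k] += r2 * sh + q2 * s1v[k] + a2s[k];
      }
      acc_u1 += u1; acc_u2 += u2; acc_s2e1 += sig2e1; acc_s2e2 += sig2e2;
      ++saved;
    }

    if ((cyc % 256) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector pm_a1(m), pm_a2(m);
  if (saved > 0)
    for (int k = 0; k < m; ++k) {
      pm_a1[k] = acc_a1[k] / saved;
      pm_a2[k] = acc_a2[k] / saved;
    }

  return List::create(
    _["samples"] = samples,
    _["n_saved"] = saved,
    _["post_mean_a1"] = pm_a1,
    _["post_mean_a2"] = pm_a2,
    _["post_mean_u"] = NumericVector::create(
        saved ? acc_u1 / saved : u1, saved ? acc_u2 / saved : u2),
    _["post_mean_sigma2_e"] = NumericVector::create(
        saved ? acc_s2e1 / saved : sig2e1, saved ? acc_s2e2 / saved : sig2e2));
}
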