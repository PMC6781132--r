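#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model with uncorrelated allele
// frequencies, extended with ploidy-aware data augmentation: for entries
// whose dosage is not observed (unknown-dosage tetraploid heterozygotes,
// dominant presence phenotypes) the latent dosage d and the per-copy
// cluster origins z are resampled jointly by enumeration over the <=
// ploidy+1 phenotype-legal dosages.
//
// Observation coding (see prepare_bayes_data() on the R side):
//   enc 0 (known dosage): value = dosage 0..ploidy
//   enc 1 (unknown dosage): -1 = ambiguous tetraploid heterozygote,
//         otherwise dosage
//   enc 2 (dominant): 0 = band absent (dosage 0), 1 = band present
//         (dosage in 1..ploidy)
//   NA = missing, skipped in all updates and in the likelihood.
//
// Uses R's RNG so set.seed() on the R side fixes the chain.

static const double CHOOSE2[3] = {1, 2, 1};
static const double CHOOSE4[5] = {1, 4, 6, 4, 1};

// legal dosage range [lo, hi] for an observed value; returns false for NA
static inline bool legal_range(int obs, int pl, int enc, int& lo, int& hi) {
  if (obs == NA_INTEGER) return false;
  if (enc == 0) { lo = hi = obs; return true; }
  if (enc == 1) {
    if (obs == -1) { lo = 1; hi = pl - 1; } else { lo = hi = obs; }
    return true;
  }
  // dominant
  if (obs == 0) { lo = hi = 0; } else { lo = 1; hi = pl; }
  return true;
}

// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix obs, IntegerVector ploidy, int enc,
                         int k, int burnin, int iters, double alpha_init,
                         double alpha_max, double prop_sd, double lambda,
                         bool fix_P, NumericMatrix P_init) {
  const int N = obs.nrow(), L = obs.ncol();
  const int total = burnin + iters;

  NumericMatrix P(k, L);       // cluster allele-A frequencies, k x L
  NumericMatrix Q(N, k);       // admixture proportions, N x k
  double alpha = alpha_init;

  if (fix_P) {
    for (int c = 0; c < k; ++c)
      for (int l = 0; l < L; ++l) P(c, l) = P_init(c, l);
  } else {
    for (int c = 0; c < k; ++c)
      for (int l = 0; l < L; ++l) P(c, l) = R::runif(0.0, 1.0);
  }
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < k; ++c) Q(i, c) = 1.0 / k;

  NumericMatrix meanQ(N, k), meanD(N, L);
  NumericVector ll_trace(total), alpha_trace(total);
  double ll_sum = 0.0;
  int kept = 0;

  double* Pp = REAL(P);
  double* Qp = REAL(Q);
  double* mDp = REAL(meanD);
  const int* obsp = INTEGER(obs);

  std::vector<double> nA(k * L), nB(k * L);  // copies assigned, cluster x locus
  std::vector<double> mcnt(N * k);           // copies per individual x cluster
  double w[8], xa[8], xb[8];
  std::vector<double> pz(std::max(8, k));

  for (int it = 0; it < total; ++it) {
    std::fill(nA.begin(), nA.end(), 0.0);
    std::fill(nB.begin(), nB.end(), 0.0);
    std::fill(mcnt.begin(), mcnt.end(), 0.0);
    double ll = 0.0;

    for (int i = 0; i < N; ++i) {
      const int pl = ploidy[i];
      const double* ch = (pl == 2) ? CHOOSE2 : CHOOSE4;
      const double* qi = Qp + (size_t)i;         // Q(i, c) = qi[c * N]
      double* mci = &mcnt[(size_t)i * k];
      for (int l = 0; l < L; ++l) {
        int lo, hi;
        if (!legal_range(obsp[i + (size_t)l * N], pl, enc, lo, hi)) continue;
        const double* pc = Pp + (size_t)l * k;   // P(c, l) = pc[c]

        // per-copy marginal P(allele A) under the individual's admixture
        double x = 0.0;
        for (int c = 0; c < k; ++c) x += qi[(size_t)c * N] * pc[c];
        if (x < 1e-12) x = 1e-12;
        if (x > 1.0 - 1e-12) x = 1.0 - 1e-12;

        // dosage full conditional: w_d ~ C(pl,d) x^d (1-x)^(pl-d)
        xa[0] = 1.0; xb[0] = 1.0;
        for (int t = 1; t <= pl; ++t) {
          xa[t] = xa[t - 1] * x;
          xb[t] = xb[t - 1] * (1.0 - x);
        }
        int d = lo;
        if (hi > lo) {
          double wsum = 0.0;
          for (int j = lo; j <= hi; ++j) {
            w[j - lo] = ch[j] * xa[j] * xb[pl - j];
            wsum += w[j - lo];
          }
          ll += std::log(wsum);
          double u = R::unif_rand() * wsum, acc = 0.0;
          for (int j = lo; j <= hi; ++j) {
            acc += w[j - lo];
            d = j;
            if (u <= acc) break;
          }
        } else {
          ll += std::log(ch[d] * xa[d] * xb[pl - d]);
        }
        if (it >= burnin) mDp[i + (size_t)l * N] += d;

        // per-copy origins given alleles: A-copy ~ q_c p_cl, B-copy ~ q_c (1-p_cl)
        if (k == 2) {
          const double q0 = qi[0], q1 = qi[(size_t)N];
          if (d > 0) {
            double a0 = q0 * pc[0], a1 = q1 * pc[1], s = a0 + a1;
            double thr = (s > 0) ? a0 / s : 0.5;
            for (int t = 0; t < d; ++t) {
              int z = (R::unif_rand() <= thr) ? 0 : 1;
              nA[(size_t)z * L + l] += 1.0;
              mci[z] += 1.0;
            }
          }
          if (d < pl) {
            double b0 = q0 * (1.0 - pc[0]), b1 = q1 * (1.0 - pc[1]);
            double s = b0 + b1;
            double thr = (s > 0) ? b0 / s : 0.5;
            for (int t = 0; t < pl - d; ++t) {
              int z = (R::unif_rand() <= thr) ? 0 : 1;
              nB[(size_t)z * L + l] += 1.0;
              mci[z] += 1.0;
            }
          }
        } else {
          for (int a = 0; a < 2; ++a) {       // a=0: A copies, a=1: B copies
            int ncop = (a == 0) ? d : pl - d;
            if (ncop == 0) continue;
            double s = 0.0;
            for (int c = 0; c < k; ++c) {
              pz[c] = qi[(size_t)c * N] * (a == 0 ? pc[c] : 1.0 - pc[c]);
              s += pz[c];
            }
            if (s <= 0.0) { for (int c = 0; c < k; ++c) pz[c] = 1.0; s = k; }
            for (int t = 0; t < ncop; ++t) {
              double u = R::unif_rand() * s, acc = 0.0;
              int z = k - 1;
              for (int c = 0; c < k; ++c) {
                acc += pz[c];
                if (u <= acc) { z = c; break; }
              }
              if (a == 0) nA[(size_t)z * L + l] += 1.0;
              else        nB[(size_t)z * L + l] += 1.0;
              mci[z] += 1.0;
            }
          }
        }
      }
    }

    // conjugate updates
    if (!fix_P) {
      for (int c = 0; c < k; ++c)
        for (int l = 0; l < L; ++l)
          P(c, l) = R::rbeta(lambda + nA[(size_t)c * L + l],
                             lambda + nB[(size_t)c * L + l]);
    }
    double sum_log_q = 0.0;
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int c = 0; c < k; ++c) {
        double g = R::rgamma(alpha + mcnt[(size_t)i * k + c], 1.0);
        if (g < 1e-300) g = 1e-300;
        Q(i, c) = g;
        s += g;
      }
      for (int c = 0; c < k; ++c) {
        Q(i, c) /= s;
        sum_log_q += std::log(std::max(Q(i, c), 1e-300));
      }
    }

    // Metropolis step on alpha, uniform prior on (0, alpha_max]
    double prop = alpha + prop_sd * R::norm_rand();
    if (prop > 0.0 && prop <= alpha_max) {
      double logr = N * (R::lgammafn(k * prop) - k * R::lgammafn(prop))
                  - N * (R::lgammafn(k * alpha) - k * R::lgammafn(alpha))
                  + (prop - alpha) * sum_log_q;
      if (std::log(R::unif_rand()) < logr) alpha = prop;
    }

    ll_trace[it] = ll;
    alpha_trace[it] = alpha;
    if (it >= burnin) {
      for (int i = 0; i < N; ++i)
        for (int c = 0; c < k; ++c) meanQ(i, c) += Q(i, c);
      ll_sum += ll;
      ++kept;
    }
  }

  if (kept > 0) {
    for (int i = 0; i < N; ++i) {
      for (int c = 0; c < k; ++c) meanQ(i, c) /= kept;
      for (int l = 0; l < L; ++l) meanD(i, l) /= kept;
    }
  }

  return List::create(
    _["mean_Q"] = meanQ,
    _["mean_loglik"] = kept > 0 ? ll_sum / kept : NA_REAL,
    _["loglik_trace"] = ll_trace,
    _["alpha_trace"] = alpha_trace,
    _["mean_dosage"] = meanD,
    _["alpha_final"] = alpha);
}
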