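// Admixture-model Gibbs sampler for multilocus genotype data.
//
// State: per-gene-copy cluster origins z, per-cluster allele frequencies P
// (Dirichlet-conjugate update), per-individual admixture proportions q
// (Dirichlet), symmetric Dirichlet parameter alpha (Metropolis), and for the
// correlated-frequency (F-model) prior, ancestral frequencies pa per locus
// plus a per-cluster drift parameter F_k (both Metropolis).
//
// All randomness comes from R's RNG, so set.seed() makes runs reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static int sample_cat(const double *w, int K, double tot) {
  double u = R::runif(0.0, tot);
  double acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

static void rdirichlet(double *out, const double *par, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    out[i] = R::rgamma(par[i] > 1e-8 ? par[i] : 1e-8, 1.0);
    if (out[i] < 1e-300) out[i] = 1e-300;
    s += out[i];
  }
  for (int i = 0; i < n; ++i) out[i] /= s;
}

static double ldirichlet(const double *x, const double *par, int n) {
  double s = 0.0, sp = 0.0;
  for (int i = 0; i < n; ++i) {
    double a = par[i] > 1e-8 ? par[i] : 1e-8;
    s += (a - 1.0) * log(x[i]);
    sp += a;
    s -= R::lgammafn(a);
  }
  return s + R::lgammafn(sp);
}

// [[Rcpp::export(name = ".admixture_gibbs_cpp")]]
List admixture_gibbs_cpp(IntegerMatrix geno, IntegerVector n_alleles,
                         int K, int burnin, int iters,
                         double alpha_init, bool update_alpha,
                         bool correlated) {
  const int N = geno.nrow();
  const int L = n_alleles.size();
  RNGScope scope;

  // flat storage: P[l] is K x J_l, z parallel to geno
  std::vector<NumericMatrix> P(L);
  std::vector<NumericVector> pa(L);
  for (int l = 0; l < L; ++l) {
    P[l] = NumericMatrix(K, n_alleles[l]);
    pa[l] = NumericVector(n_alleles[l], 1.0 / n_alleles[l]);
    std::vector<double> par(n_alleles[l], 1.0);
    std::vector<double> row(n_alleles[l]);
    for (int k = 0; k < K; ++k) {
      rdirichlet(row.data(), par.data(), n_alleles[l]);
      for (int j = 0; j < n_alleles[l]; ++j) P[l](k, j) = row[j];
    }
  }
  NumericMatrix q(N, K);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) q(i, k) = 1.0 / K;
  IntegerMatrix z(N, 2 * L);
  NumericVector Fk(K, 0.1);
  double alpha = alpha_init;

  NumericMatrix qsum(N, K);
  std::vector<NumericMatrix> Psum(L);
  for (int l = 0; l < L; ++l) Psum[l] = NumericMatrix(K, n_alleles[l]);
  NumericVector lnl_trace(iters);
  double alpha_sum = 0.0;

  std::vector<double> w(K), mpar(K), qrow(K);
  const int total = burnin + iters;

  for (int sweep = 0; sweep < total; ++sweep) {
    // 1. z | q, P
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a == 0) { z(i, 2 * l + c) = -1; continue; }
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            w[k] = q(i, k) * P[l](k, a - 1);
            tot += w[k];
          }
          z(i, 2 * l + c) = (tot > 0) ? sample_cat(w.data(), K, tot)
                                      : (int)floor(R::unif_rand() * K);
        }
      }
    }

    // 2. P | z  (Dirichlet posterior; prior = lambda or F-model)
    for (int l = 0; l < L; ++l) {
      int J = n_alleles[l];
      std::vector<double> cnt(K * J, 0.0);
      for (int i = 0; i < N; ++i)
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a == 0) continue;
          cnt[z(i, 2 * l + c) * J + (a - 1)] += 1.0;
        }
      std::vector<double> par(J), row(J);
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < J; ++j) {
          double prior = correlated
            ? pa[l][j] * (1.0 - Fk[k]) / Fk[k]
            : 1.0;
          par[j] = prior + cnt[k * J + j];
        }
        rdirichlet(row.data(), par.data(), J);
        for (int j = 0; j < J; ++j) P[l](k, j) = row[j];
      }
    }

    // 3. q | z
    for (int i = 0; i < N; ++i) {
      for (int k = 0; k < K; ++k) mpar[k] = alpha;
      for (int l = 0; l < 2 * L; ++l)
        if (z(i, l) >= 0) mpar[z(i, l)] += 1.0;
      rdirichlet(qrow.data(), mpar.data(), K);
      for (int k = 0; k < K; ++k) q(i, k) = qrow[k];
    }

    // 4. alpha | q (Metropolis, log-scale random walk, uniform(0,10) prior)
    if (update_alpha && K > 1) {
      double prop = alpha * exp(R::norm_rand() * 0.1);
      if (prop > 0.0 && prop < 10.0) {
        double sumlq = 0.0;
        for (int i = 0; i < N; ++i)
          for (int k = 0; k < K; ++k) sumlq += log(q(i, k));
        double ll_cur = N * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha))
          + (alpha - 1.0) * sumlq;
        double ll_prop = N * (R::lgammafn(K * prop) - K * R::lgammafn(prop))
          + (prop - 1.0) * sumlq;
        // include Jacobian of the log-scale proposal
        if (log(R::unif_rand()) < ll_prop - ll_cur + log(prop) - log(alpha))
          alpha = prop;
      }
    }

    // 5. F-model hyperparameters
    if (correlated) {
      // drift F_k: random walk on logit scale, uniform(0,1) prior
      for (int k = 0; k < K; ++k) {
        double cur = Fk[k];
        double lo = log(cur / (1.0 - cur)) + R::norm_rand() * 0.3;
        double prop = 1.0 / (1.0 + exp(-lo));
        double ll = 0.0;
        for (int l = 0; l < L; ++l) {
          int J = n_alleles[l];
          std::vector<double> x(J), pc(J), pp(J);
          for (int j = 0; j < J; ++j) {
            x[j] = P[l](k, j);
            pc[j] = pa[l][j] * (1.0 - cur) / cur;
            pp[j] = pa[l][j] * (1.0 - prop) / prop;
          }
          ll += ldirichlet(x.data(), pp.data(), J)
              - ldirichlet(x.data(), pc.data(), J);
        }
        // Jacobian of the logit random walk
        ll += log(prop * (1.0 - prop)) - log(cur * (1.0 - cur));
        if (log(R::unif_rand()) < ll) Fk[k] = prop;
      }
      // ancestral frequencies pa_l: Dirichlet proposal centred at current
      for (int l = 0; l < L; ++l) {
        int J = n_alleles[l];
        std::vector<double> cur(J), prop(J), parc(J), parp(J), x(J);
        for (int j = 0; j < J; ++j) {
          cur[j] = pa[l][j];
          parc[j] = 50.0 * cur[j] + 0.1;
        }
        rdirichlet(prop.data(), parc.data(), J);
        for (int j = 0; j < J; ++j) parp[j] = 50.0 * prop[j] + 0.1;
        double ll = 0.0;
        for (int k = 0; k < K; ++k) {
          std::vector<double> pc(J), pp(J);
          for (int j = 0; j < J; ++j) {
            x[j] = P[l](k, j);
            pc[j] = cur[j] * (1.0 - Fk[k]) / Fk[k];
            pp[j] = prop[j] * (1.0 - Fk[k]) / Fk[k];
          }
          ll += ldirichlet(x.data(), pp.data(), J)
              - ldirichlet(x.data(), pc.data(), J);
        }
        // symmetric Dirichlet(1) prior cancels; proposal correction:
        ll += ldirichlet(cur.data(), parp.data(), J)
            - ldirichlet(prop.data(), parc.data(), J);
        if (log(R::unif_rand()) < ll)
          for (int j = 0; j < J; ++j) pa[l][j] = prop[j];
      }
    }

    // 6. record
    if (sweep >= burnin) {
      double lnl = 0.0;
      for (int i = 0; i < N; ++i)
        for (int l = 0; l < L; ++l)
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a == 0) continue;
            double s = 0.0;
            for (int k = 0; k < K; ++k) s += q(i, k) * P[l](k, a - 1);
            lnl += log(s > 1e-300 ? s : 1e-300);
          }
      lnl_trace[sweep - burnin] = lnl;
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) qsum(i, k) += q(i, k);
      for (int l = 0; l < L; ++l)
        for (int k = 0; k < K; ++k)
          for (int j = 0; j < n_alleles[l]; ++j)
            Psum[l](k, j) += P[l](k, j);
      alpha_sum += alpha;
    }
  }

  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) qsum(i, k) /= iters;
  List Pout(L);
  for (int l = 0; l < L; ++l) {
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < n_alleles[l]; ++j) Psum[l](k, j) /= iters;
    Pout[l] = Psum[l];
  }
  return List::create(_["q"] = qsum, _["P"] = Pout,
                      _["lnl"] = lnl_trace,
                      _["alpha"] = alpha_sum / iters);
}
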