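// Collapsed Gibbs samplers for (i) no-admixture genotype clustering and
// (ii) genotype-frequency-class (hybrid) classification.
//
// Allele labels must be remapped to 1..J per locus by the caller; 0 marks
// a missing genotype.  All randomness comes from R's RNG so results are
// reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static int sample_from_logprobs(std::vector<double> &logp) {
  int K = logp.size();
  double m = logp[0];
  for (int k = 1; k < K; ++k) if (logp[k] > m) m = logp[k];
  double tot = 0.0;
  for (int k = 0; k < K; ++k) { logp[k] = std::exp(logp[k] - m); tot += logp[k]; }
  double u = unif_rand() * tot, c = 0.0;
  for (int k = 0; k < K; ++k) { c += logp[k]; if (u <= c) return k; }
  return K - 1;
}

// [[Rcpp::export(name = ".gibbs_cluster_cpp")]]
List gibbs_cluster_cpp(IntegerMatrix a1, IntegerMatrix a2,
                       IntegerVector nAlleles, int K,
                       int burnin, int sweeps, int thin) {
  RNGScope scope;
  int n = a1.nrow(), L = a1.ncol();
  std::vector<int> offset(L, 0);
  int totA = 0;
  for (int l = 0; l < L; ++l) { offset[l] = totA; totA += nAlleles[l]; }

  // counts[k * totA + offset[l] + a] = gene copies of allele a at locus l
  std::vector<double> counts((size_t)K * totA, 0.0);
  std::vector<double> geneN((size_t)K * L, 0.0); // gene copies per k, l
  std::vector<int> z(n);

  for (int i = 0; i < n; ++i)
    z[i] = (int)(unif_rand() * K) % K;
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l) {
      int x = a1(i, l);
      if (x == 0) continue;
      int y = a2(i, l);
      counts[(size_t)z[i] * totA + offset[l] + x - 1] += 1;
      counts[(size_t)z[i] * totA + offset[l] + y - 1] += 1;
      geneN[(size_t)z[i] * L + l] += 2;
    }

  NumericMatrix occ(n, K);
  NumericMatrix coassign(n, n);
  double sumLL = 0.0;
  int nRecLik = 0, nRecCo = 0;
  std::vector<double> logp(K);

  int total = burnin + sweeps;
  for (int s = 0; s < total; ++s) {
    for (int i = 0; i < n; ++i) {
      // remove individual i
      int zi = z[i];
      for (int l = 0; l < L; ++l) {
        int x = a1(i, l);
        if (x == 0) continue;
        int y = a2(i, l);
        counts[(size_t)zi * totA + offset[l] + x - 1] -= 1;
        counts[(size_t)zi * totA + offset[l] + y - 1] -= 1;
        geneN[(size_t)zi * L + l] -= 2;
      }
      // collapsed predictive under Dirichlet(1) allele-frequency prior
      for (int k = 0; k < K; ++k) {
        double lp = 0.0;
        for (int l = 0; l < L; ++l) {
          int x = a1(i, l);
          if (x == 0) continue;
          int y = a2(i, l);
          double N = geneN[(size_t)k * L + l];
          double J = nAlleles[l];
          double cx = counts[(size_t)k * totA + offset[l] + x - 1];
          if (x == y)
            lp += std::log((cx + 1.0) * (cx + 2.0)) -
                  std::log((N + J) * (N + J + 1.0));
          else {
            double cy = counts[(size_t)k * totA + offset[l] + y - 1];
            lp += std::log(2.0 * (cx + 1.0) * (cy + 1.0)) -
                  std::log((N + J) * (N + J + 1.0));
          }
        }
        logp[k] = lp;
      }
      zi = sample_from_logprobs(logp);
      z[i] = zi;
      for (int l = 0; l < L; ++l) {
        int x = a1(i, l);
        if (x == 0) continue;
        int y = a2(i, l);
        counts[(size_t)zi * totA + offset[l] + x - 1] += 1;
        counts[(size_t)zi * totA + offset[l] + y - 1] += 1;
        geneN[(size_t)zi * L + l] += 2;
      }
    }
    if (s >= burnin) {
      for (int i = 0; i < n; ++i) occ(i, z[i]) += 1.0;
      if ((s - burnin) % thin == 0) {
        // log P(X | Z, posterior-mean frequencies) for the current
        // assignment; averaged over recorded sweeps
        double ll = 0.0;
        for (int i = 0; i < n; ++i) {
          int k = z[i];
          for (int l = 0; l < L; ++l) {
            int x = a1(i, l);
            if (x == 0) continue;
            int y = a2(i, l);
            double N = geneN[(size_t)k * L + l];
            double J = nAlleles[l];
            double px = (counts[(size_t)k * totA + offset[l] + x - 1] + 1.0) /
                        (N + J);
            if (x == y) ll += 2.0 * std::log(px);
            else {
              double py = (counts[(size_t)k * totA + offset[l] + y - 1] + 1.0) /
                          (N + J);
              ll += std::log(2.0 * px * py);
            }
          }
        }
        sumLL += ll; ++nRecLik;
        for (int i = 0; i < n; ++i)
          for (int j = i + 1; j < n; ++j)
            if (z[i] == z[j]) coassign(i, j) += 1.0;
        ++nRecCo;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < K; ++k) occ(i, k) /= (double)sweeps;
    coassign(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      coassign(i, j) /= (double)nRecCo;
      coassign(j, i) = coassign(i, j);
    }
  }
  return List::create(_["posterior"] = occ, _["coassignment"] = coassign,
                      _["meanLogLik"] = sumLL / nRecLik);
}

// genotype probability at one locus given origin category and pool freqs
static inline double geno_prob(int x, int y, int cat,
                               const double *pA, const double *pB) {
  if (cat == 0) { // both gene copies from pool A
    return (x == y) ? pA[x - 1] * pA[x - 1]
                    : 2.0 * pA[x - 1] * pA[y - 1];
  } else if (cat == 2) {
    return (x == y) ? pB[x - 1] * pB[x - 1]
                    : 2.0 * pB[x - 1] * pB[y - 1];
  }
  // one copy from each pool
  return (x == y) ? pA[x - 1] * pB[x - 1]
                  : pA[x - 1] * pB[y - 1] + pA[y - 1] * pB[x - 1];
}

// class -> (both A, one each, both B) ancestry-pair weights
static const double CLASS_W[6][3] = {
  {1.0, 0.0, 0.0},    // Pure_A
  {0.0, 0.0, 1.0},    // Pure_B
  {0.0, 1.0, 0.0},    // F1
  {0.25, 0.5, 0.25},  // F2
  {0.5, 0.5, 0.0},    // BC_A
  {0.0, 0.5, 0.5}     // BC_B
};

// [[Rcpp::export(name = ".gibbs_hybrids_cpp")]]
NumericMatrix gibbs_hybrids_cpp(IntegerMatrix a1, IntegerMatrix a2,
                                IntegerVector nAlleles,
                                IntegerVector initClass,
                                IntegerVector fixedClass,
                                int burnin, int sweeps) {
  RNGScope scope;
  int n = a1.nrow(), L = a1.ncol();
  std::vector<int> offset(L, 0);
  int totA = 0;
  for (int l = 0; l < L; ++l) { offset[l] = totA; totA += nAlleles[l]; }

  std::vector<double> pA(totA), pB(totA);
  std::vector<double> cntA(totA), cntB(totA);
  std::vector<int> z(n);
  for (int i = 0; i < n; ++i) z[i] = initClass[i] - 1;

  // initial pool frequencies: posterior mean given the initial pure split
  std::fill(cntA.begin(), cntA.end(), 0.0);
  std::fill(cntB.begin(), cntB.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    if (z[i] != 0 && z[i] != 1) continue;
    std::vector<double> &cnt = (z[i] == 0) ? cntA : cntB;
    for (int l = 0; l < L; ++l) {
      int x = a1(i, l);
      if (x == 0) continue;
      cnt[offset[l] + x - 1] += 1;
      cnt[offset[l] + a2(i, l) - 1] += 1;
    }
  }
  for (int l = 0; l < L; ++l) {
    double sa = 0, sb = 0;
    for (int a = 0; a < nAlleles[l]; ++a) {
      pA[offset[l] + a] = cntA[offset[l] + a] + 1.0;
      pB[offset[l] + a] = cntB[offset[l] + a] + 1.0;
      sa += pA[offset[l] + a]; sb += pB[offset[l] + a];
    }
    for (int a = 0; a < nAlleles[l]; ++a) {
      pA[offset[l] + a] /= sa; pB[offset[l] + a] /= sb;
    }
  }

  NumericMatrix occ(n, 6);
  std::vector<double> logp(6);
  int total = burnin + sweeps;
  for (int s = 0; s < total; ++s) {
    // (i) class per individual given pool frequencies
    for (int i = 0; i < n; ++i) {
      if (fixedClass[i] > 0) { z[i] = fixedClass[i] - 1; continue; }
      for (int c = 0; c < 6; ++c) {
        double lp = 0.0;
        for (int l = 0; l < L; ++l) {
          int x = a1(i, l);
          if (x == 0) continue;
          int y = a2(i, l);
          double pr = 0.0;
          for (int cat = 0; cat < 3; ++cat)
            if (CLASS_W[c][cat] > 0.0)
              pr += CLASS_W[c][cat] *
                    geno_prob(x, y, cat, &pA[offset[l]], &pB[offset[l]]);
          lp += std::log(pr + 1e-300);
        }
        logp[c] = lp;
      }
      z[i] = sample_from_logprobs(logp);
    }
    // (ii) gene-copy pool origins given class, accumulating counts
    std::fill(cntA.begin(), cntA.end(), 0.0);
    std::fill(cntB.begin(), cntB.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double *w = CLASS_W[z[i]];
      for (int l = 0; l < L; ++l) {
        int x = a1(i, l);
        if (x == 0) continue;
        int y = a2(i, l);
        double p0 = w[0] * geno_prob(x, y, 0, &pA[offset[l]], &pB[offset[l]]);
        double p1 = w[1] * geno_prob(x, y, 1, &pA[offset[l]], &pB[offset[l]]);
        double p2 = w[2] * geno_prob(x, y, 2, &pA[offset[l]], &pB[offset[l]]);
        double tot = p0 + p1 + p2;
        int cat;
        if (tot <= 0.0) cat = 1;
        else {
          double u = unif_rand() * tot;
          cat = (u <= p0) ? 0 : ((u <= p0 + p1) ? 1 : 2);
        }
        if (cat == 0) {
          cntA[offset[l] + x - 1] += 1; cntA[offset[l] + y - 1] += 1;
        } else if (cat == 2) {
          cntB[offset[l] + x - 1] += 1; cntB[offset[l] + y - 1] += 1;
        } else if (x == y) {
          cntA[offset[l] + x - 1] += 1; cntB[offset[l] + x - 1] += 1;
        } else {
          // heterozygote with one copy from each pool: which allele is A's?
          double qx = pA[offset[l] + x - 1] * pB[offset[l] + y - 1];
          double qy = pA[offset[l] + y - 1] * pB[offset[l] + x - 1];
          if (unif_rand() * (qx + qy) <= qx) {
            cntA[offset[l] + x - 1] += 1; cntB[offset[l] + y - 1] += 1;
          } else {
            cntA[offset[l] + y - 1] += 1; cntB[offset[l] + x - 1] += 1;
          }
        }
      }
    }
    // (iii) pool frequencies ~ Dirichlet(1 + counts)
    for (int l = 0; l < L; ++l) {
      double sa = 0, sb = 0;
      for (int a = 0; a < nAlleles[l]; ++a) {
        pA[offset[l] + a] = R::rgamma(cntA[offset[l] + a] + 1.0, 1.0);
        pB[offset[l] + a] = R::rgamma(cntB[offset[l] + a] + 1.0, 1.0);
        sa += pA[offset[l] + a]; sb += pB[offset[l] + a];
      }
      for (int a = 0; a < nAlleles[l]; ++a) {
        pA[offset[l] + a] /= sa; pB[offset[l] + a] /= sb;
      }
    }
    if (s >= burnin)
      for (int i = 0; i < n; ++i) occ(i, z[i]) += 1.0;
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 6; ++c) occ(i, c) /= (double)sweeps;
  return occ;
}
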