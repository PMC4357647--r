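#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo null distribution of the heterozygote-excess U score under the
// Levene distribution: allele copies are randomly paired conditional on the
// observed allele counts. `copies` holds 0-based allele codes (length 2n);
// `w` holds (1 - p_i) / p_i per allele code. U = n_het - sum_i n_ii * w_i.
// Uses R's RNG so set.seed() in R controls reproducibility.
// [[Rcpp::export]]
NumericVector cpp_hwe_null_u(IntegerVector copies, NumericVector w, int n_mc) {
  int m = copies.size();
  std::vector<int> v(copies.begin(), copies.end());
  NumericVector out(n_mc);
  for (int r = 0; r < n_mc; ++r) {
    for (int i = m - 1; i > 0; --i) {          // Fisher-Yates
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(v[i], v[j]);
    }
    double u = 0.0;
    for (int i = 0; i < m; i += 2) {
      if (v[i] == v[i + 1]) u -= w[v[i]];
      else u += 1.0;
    }
    out[r] = u;
  }
  return out;
}

// EM for two-locus haplotype frequencies from unphased diploid genotypes.
// geno: n x 4 matrix of 0-based allele codes (a1, a2, b1, b2) with a1 <= a2,
// b1 <= b2. Returns haplotype frequency matrix (kA x kB), the log-likelihood
// trace, and a convergence flag. Genotype probabilities under haplotype HWE:
// both hom: h^2; one het: 2 h1 h2; double het: 2 h11 h22 + 2 h12 h21.
static double em_haplo_core(const IntegerMatrix &geno, int kA, int kB,
                            double tol, int max_iter,
                            std::vector<double> &h,
                            std::vector<double> *trace, bool *converged) {
  int n = geno.nrow();
  int K = kA * kB;
  // init: uniform over haplotypes
  h.assign(K, 1.0 / K);
  std::vector<double> cnt(K);
  double logL = R_NegInf;
  if (converged) *converged = false;
  for (int it = 0; it < max_iter; ++it) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      int a1 = geno(i, 0), a2 = geno(i, 1), b1 = geno(i, 2), b2 = geno(i, 3);
      bool hetA = a1 != a2, hetB = b1 != b2;
      int i11 = a1 * kB + b1, i22 = a2 * kB + b2;
      int i12 = a1 * kB + b2, i21 = a2 * kB + b1;
      if (hetA && hetB) {
        double t1 = 2.0 * h[i11] * h[i22];
        double t2 = 2.0 * h[i12] * h[i21];
        double p = t1 + t2;
        if (p <= 0) { p = 1e-300; t1 = t2 = 5e-301; }
        ll += std::log(p);
        double w1 = t1 / p, w2 = t2 / p;
        cnt[i11] += w1; cnt[i22] += w1;
        cnt[i12] += w2; cnt[i21] += w2;
      } else if (hetA || hetB) {
        double p = 2.0 * h[i11] * h[i22];
        if (p <= 0) p = 1e-300;
        ll += std::log(p);
        cnt[i11] += 1.0; cnt[i22] += 1.0;
      } else {
        double p = h[i11] * h[i11];
        if (p <= 0) p = 1e-300;
        ll += std::log(p);
        cnt[i11] += 2.0;
      }
    }
    for (int k = 0; k < K; ++k) h[k] = cnt[k] / (2.0 * n);
    if (trace) trace->push_back(ll);
    if (it > 0 && std::fabs(ll - logL) < tol) {
      logL = ll;
      if (converged) *converged = true;
      break;
    }
    logL = ll;
  }
  return logL;
}

// [[Rcpp::export]]
List cpp_em_haplo(IntegerMatrix geno, int kA, int kB, double tol,
                  int max_iter) {
  std::vector<double> h;
  std::vector<double> trace;
  bool conv = false;
  double logL = em_haplo_core(geno, kA, kB, tol, max_iter, h, &trace, &conv);
  NumericMatrix hm(kA, kB);
  for (int a = 0; a < kA; ++a)
    for (int b = 0; b < kB; ++b) hm(a, b) = h[a * kB + b];
  return List::create(_["h"] = hm, _["logL"] = logL,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["converged"] = conv);
}

// Permutation null of the EM log-likelihood: locus-B genotype rows are
// shuffled among individuals, breaking any gametic association while keeping
// both single-locus genotype arrays fixed.
// [[Rcpp::export]]
NumericVector cpp_ld_perm_logl(IntegerMatrix geno, int kA, int kB, int n_perm,
                               double tol, int max_iter) {
  int n = geno.nrow();
  NumericVector out(n_perm);
  IntegerMatrix g(n, 4);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) {
    idx[i] = i;
    for (int j = 0; j < 4; ++j) g(i, j) = geno(i, j);
  }
  std::vector<double> h;
  for (int r = 0; r < n_perm; ++r) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    for (int i = 0; i < n; ++i) {
      g(i, 2) = geno(idx[i], 2);
      g(i, 3) = geno(idx[i], 3);
    }
    out[r] = em_haplo_core(g, kA, kB, tol, max_iter, h, nullptr, nullptr);
  }
  return out;
}
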