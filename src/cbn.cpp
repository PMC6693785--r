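// Exact genotype-occupancy probabilities for a conjunctive Bayesian network:
// a continuous-time Markov chain on the lattice of poset-compatible
// genotypes (each feature j mutates at rate lambda_j once its parents are
// mutated), observed at an Exp(1) sampling time, convolved with a symmetric
// per-bit observation error eps. For an upper-triangular generator the
// occupancy at an Exp(1) time solves a forward recursion:
//   rho(0) = 1 / (1 + Lambda_0)
//   rho(g) = sum_{j in g, addable from g\j} rho(g\j) lambda_j / (1 + Lambda_g)
// with Lambda_g the total rate out of g.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

inline int pc(int x) {
  int c = 0;
  while (x) { c += x & 1; x >>= 1; }
  return c;
}

// occupancy probabilities over compatible genotypes; idx maps mask -> slot
void cbn_rho(int nG, const int* pm, const double* lambda,
             std::vector<int>& masks, std::vector<int>& idx,
             std::vector<double>& rho) {
  const int M = 1 << nG;
  idx.assign(M, -1);
  masks.clear();
  for (int g = 0; g < M; ++g) {
    bool ok = true;
    for (int j = 0; j < nG && ok; ++j)
      if ((g >> j) & 1)
        if ((g & pm[j]) != pm[j]) ok = false;
    if (ok) { idx[g] = masks.size(); masks.push_back(g); }
  }
  rho.assign(masks.size(), 0.0);
  for (size_t s = 0; s < masks.size(); ++s) {  // masks ascending: parents first
    int g = masks[s];
    double Lg = 0.0;
    for (int j = 0; j < nG; ++j)
      if (!((g >> j) & 1) && (g & pm[j]) == pm[j]) Lg += lambda[j];
    double in = 0.0;
    if (g == 0) in = 1.0;
    for (int j = 0; j < nG; ++j)
      if ((g >> j) & 1) {
        int h = g & ~(1 << j);
        if (idx[h] >= 0 && (h & pm[j]) == pm[j]) in += rho[idx[h]] * lambda[j];
      }
    rho[s] = in / (1.0 + Lg);
  }
}

} // namespace

// [[Rcpp::export(name = ".cbn_rho_cpp")]]
List cbn_rho_cpp(int n_genes, IntegerVector parent_masks,
                 NumericVector lambda) {
  std::vector<int> masks, idx;
  std::vector<double> rho;
  cbn_rho(n_genes, &parent_masks[0], &lambda[0], masks, idx, rho);
  return List::create(_["masks"] = IntegerVector(masks.begin(), masks.end()),
                      _["rho"] = NumericVector(rho.begin(), rho.end()));
}

// [[Rcpp::export(name = ".cbn_loglik_cpp")]]
double cbn_loglik_cpp(int n_genes, IntegerVector parent_masks,
                      NumericVector lambda, double eps,
                      IntegerVector obs, NumericVector counts) {
  const int nG = n_genes;
  std::vector<int> masks, idx;
  std::vector<double> rho;
  cbn_rho(nG, &parent_masks[0], &lambda[0], masks, idx, rho);

  // precompute eps^d (1-eps)^(K-d) for d = 0..K
  std::vector<double> ed(nG + 1);
  for (int d = 0; d <= nG; ++d)
    ed[d] = std::pow(eps, d) * std::pow(1.0 - eps, nG - d);

  double ll = 0.0;
  for (int i = 0; i < obs.size(); ++i) {
    double p = 0.0;
    if (eps <= 0.0) {
      if (idx[obs[i]] >= 0) p = rho[idx[obs[i]]];
    } else {
      for (size_t s = 0; s < masks.size(); ++s)
        p += rho[s] * ed[pc(obs[i] ^ masks[s])];
    }
    if (p <= 0.0) return R_NegInf;
    ll += counts[i] * std::log(p);
  }
  return ll;
}

// posterior expected per-bit mismatch count between observed genotypes and
// latent true genotypes; used by the EM update of eps
// [[Rcpp::export(name = ".cbn_emismatch_cpp")]]
double cbn_emismatch_cpp(int n_genes, IntegerVector parent_masks,
                         NumericVector lambda, double eps,
                         IntegerVector obs, NumericVector counts) {
  const int nG = n_genes;
  std::vector<int> masks, idx;
  std::vector<double> rho;
  cbn_rho(nG, &parent_masks[0], &lambda[0], masks, idx, rho);
  std::vector<double> ed(nG + 1);
  for (int d = 0; d <= nG; ++d)
    ed[d] = std::pow(eps, d) * std::pow(1.0 - eps, nG - d);
  double tot = 0.0, wsum = 0.0;
  for (int i = 0; i < obs.size(); ++i) {
    double p = 0.0, md = 0.0;
    for (size_t s = 0; s < masks.size(); ++s) {
      int d = pc(obs[i] ^ masks[s]);
      double w = rho[s] * ed[d];
      p += w;
      md += w * d;
    }
    if (p > 0.0) {
      tot += counts[i] * md / p;
      wsum += counts[i];
    }
  }
  return wsum > 0 ? tot / (wsum * nG) : eps;
}
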