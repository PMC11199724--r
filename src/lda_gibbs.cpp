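#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// doc_id / word_id: 0-based token stream (one entry per token occurrence).
// Returns final-state counts smoothed with the symmetric priors:
//   theta[d,k] = (n_dk + alpha) / (n_d + K alpha)
//   phi[k,v]   = (n_kv + beta)  / (n_k + V beta)
// Uses R's RNG so set.seed() controls the chain.
// [[Rcpp::export]]
List lda_gibbs_fit(IntegerVector doc_id, IntegerVector word_id,
                   int n_docs, int n_vocab, int K,
                   double alpha, double beta, int iterations) {
  int N = doc_id.size();
  IntegerMatrix ndk(n_docs, K);
  IntegerMatrix nkv(K, n_vocab);
  IntegerVector nk(K);
  IntegerVector nd(n_docs);
  IntegerVector z(N);

  // random initial assignment
  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    ndk(doc_id[i], k)++;
    nkv(k, word_id[i])++;
    nk[k]++;
    nd[doc_id[i]]++;
  }

  std::vector<double> p(K);
  double Vbeta = n_vocab * beta;
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < N; ++i) {
      int d = doc_id[i], w = word_id[i], k = z[i];
      ndk(d, k)--; nkv(k, w)--; nk[k]--;
      double tot = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        p[kk] = (ndk(d, kk) + alpha) * (nkv(kk, w) + beta) / (nk[kk] + Vbeta);
        tot += p[kk];
      }
      double u = unif_rand() * tot;
      int knew = 0;
      double cum = p[0];
      while (u > cum && knew < K - 1) { cum += p[++knew]; }
      z[i] = knew;
      ndk(d, knew)++; nkv(knew, w)++; nk[knew]++;
    }
  }

  NumericMatrix theta(n_docs, K);
  for (int d = 0; d < n_docs; ++d)
    for (int k = 0; k < K; ++k)
      theta(d, k) = (ndk(d, k) + alpha) / (nd[d] + K * alpha);
  NumericMatrix phi(K, n_vocab);
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < n_vocab; ++v)
      phi(k, v) = (nkv(k, v) + beta) / (nk[k] + Vbeta);

  return List::create(_["theta"] = theta, _["phi"] = phi);
}

// Fold-in inference: sample topic assignments for one held-out document
// with the topic-word distributions phi held fixed.
// [[Rcpp::export]]
NumericVector lda_gibbs_infer(IntegerVector word_id, NumericMatrix phi,
                              double alpha, int iterations) {
  int K = phi.nrow();
  int N = word_id.size();
  NumericVector theta(K);
  if (N == 0) {
    theta.fill(1.0 / K);
    return theta;
  }
  IntegerVector z(N);
  IntegerVector nk(K);
  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    nk[k]++;
  }
  std::vector<double> p(K);
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < N; ++i) {
      int w = word_id[i], k = z[i];
      nk[k]--;
      double tot = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        p[kk] = (nk[kk] + alpha) * phi(kk, w);
        tot += p[kk];
      }
      double u = unif_rand() * tot;
      int knew = 0;
      double cum = p[0];
      while (u > cum && knew < K - 1) { cum += p[++knew]; }
      z[i] = knew;
      nk[knew]++;
    }
  }
  for (int k = 0; k < K; ++k) theta[k] = (nk[k] + alpha) / (N + K * alpha);
  return theta;
}
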