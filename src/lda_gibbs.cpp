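#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
// word, doc: 0-based token word-ids and document-ids, one entry per token.
// Returns final assignments and count tables, the per-sweep collapsed log
// joint, and a per-sweep token-conservation trace (sum of the topic count
// table, which must equal the corpus size at every sweep).
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector word, IntegerVector doc, int n_docs, int V,
                   int K, double alpha, double eta, int iters) {
  int N = word.size();
  IntegerVector z(N);
  IntegerMatrix ndk(n_docs, K), nkw(K, V);
  IntegerVector nk(K), nd(n_docs);
  RNGScope scope;

  for (int i = 0; i < N; ++i) {
    int k = (int)std::floor(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    ndk(doc[i], k)++; nkw(k, word[i])++; nk[k]++; nd[doc[i]]++;
  }

  NumericVector loglik(iters);
  IntegerVector tokens_assigned(iters);
  std::vector<double> p(K);

  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < N; ++i) {
      int d = doc[i], w = word[i], k = z[i];
      ndk(d, k)--; nkw(k, w)--; nk[k]--;
      double tot = 0.0;
      for (int k2 = 0; k2 < K; ++k2) {
        double val = (ndk(d, k2) + alpha) * (nkw(k2, w) + eta) /
                     (nk[k2] + V * eta);
        p[k2] = val;
        tot += val;
      }
      double u = unif_rand() * tot, acc = 0.0;
      int knew = K - 1;
      for (int k2 = 0; k2 < K; ++k2) {
        acc += p[k2];
        if (u <= acc) { knew = k2; break; }
      }
      z[i] = knew;
      ndk(d, knew)++; nkw(knew, w)++; nk[knew]++;
    }
    // collapsed log joint: log p(w | z) + log p(z)
    double lw = K * (R::lgammafn(V * eta) - V * R::lgammafn(eta));
    for (int k = 0; k < K; ++k) {
      for (int w = 0; w < V; ++w) lw += R::lgammafn(nkw(k, w) + eta);
      lw -= R::lgammafn(nk[k] + V * eta);
    }
    double lz = n_docs * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha));
    for (int d = 0; d < n_docs; ++d) {
      for (int k = 0; k < K; ++k) lz += R::lgammafn(ndk(d, k) + alpha);
      lz -= R::lgammafn(nd[d] + K * alpha);
    }
    loglik[it] = lw + lz;
    int tot_nk = 0;
    for (int k = 0; k < K; ++k) tot_nk += nk[k];
    tokens_assigned[it] = tot_nk;
  }

  return List::create(_["z"] = z, _["ndk"] = ndk, _["nkw"] = nkw,
                      _["nk"] = nk,
                      _["loglik"] = loglik,
                      _["tokens_assigned"] = tokens_assigned);
}
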