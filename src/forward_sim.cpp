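#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Forward-time Wright-Fisher metapopulation with backward migration and
// stepwise mutation. State layout: allele[l + nloci*(c + 2*(i + N*d))]
// for locus l, chromosome c, individual i, deme d. Migration happens at
// reproduction: each offspring in deme d first draws a source deme from
// row d of the cumulative migration matrix, then two parents (with
// replacement) from that deme; each transmitted allele mutates +/-1 repeat
// with probability mu, reflecting at [amin, amax]. Uses R's RNG so results
// are reproducible via set.seed().

// [[Rcpp::export]]
IntegerVector forward_sim_cpp(IntegerVector state, int nloci, int N,
                              int ndeme, NumericMatrix mig_cum, int gens,
                              double mu, int amin, int amax) {
  const R_xlen_t sz = (R_xlen_t)nloci * 2 * N * ndeme;
  if (state.size() != sz) stop("state vector has wrong length");
  std::vector<int> cur(state.begin(), state.end());
  std::vector<int> nxt(cur.size());
  for (int g = 0; g < gens; ++g) {
    for (int d = 0; d < ndeme; ++d) {
      for (int i = 0; i < N; ++i) {
        double u = unif_rand();
        int s = 0;
        while (s < ndeme - 1 && u > mig_cum(d, s)) ++s;
        int mom = (int)(unif_rand() * N); if (mom == N) mom = N - 1;
        int dad = (int)(unif_rand() * N); if (dad == N) dad = N - 1;
        const size_t base_mom = (size_t)nloci * 2 * (mom + (size_t)N * s);
        const size_t base_dad = (size_t)nloci * 2 * (dad + (size_t)N * s);
        const size_t base_off = (size_t)nloci * 2 * (i + (size_t)N * d);
        for (int l = 0; l < nloci; ++l) {
          for (int c = 0; c < 2; ++c) {
            size_t pbase = (c == 0) ? base_mom : base_dad;
            int gam = (unif_rand() < 0.5) ? 0 : 1;
            int allele = cur[l + nloci * gam + pbase];
            if (mu > 0 && unif_rand() < mu) {
              allele += (unif_rand() < 0.5) ? -1 : 1;
              if (allele < amin) allele = amin + 1;      // reflect
              if (allele > amax) allele = amax - 1;
            }
            nxt[l + nloci * c + base_off] = allele;
          }
        }
      }
    }
    cur.swap(nxt);
  }
  return IntegerVector(cur.begin(), cur.end());
}
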