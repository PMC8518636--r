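#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Number of failures before the first success of a Bernoulli(p) sequence.
// Lets the gamete builder skip directly to the next crossover / mutation
// event instead of drawing one uniform per interval.
static inline int geom_skip(double p) {
  double u = unif_rand();
  if (u <= 0.0) u = 1e-300;
  return (int) std::floor(std::log(u) / std::log1p(-p));
}

// One Wright-Fisher generation: fill 'nxt' with H gametes drawn from 'cur'.
static void wf_generation(const std::vector<unsigned char> &cur,
                          std::vector<unsigned char> &nxt,
                          int K, int H, const NumericVector &cAdj,
                          double cmax, double mu, bool mutate,
                          std::vector<int> &xo) {
  const int N = H / 2;
  for (int g = 0; g < H; ++g) {
    int parent = (int) (unif_rand() * N);
    if (parent >= N) parent = N - 1;
    const unsigned char *hapA = &cur[(size_t) (2 * parent) * K];
    const unsigned char *hapB = &cur[(size_t) (2 * parent + 1) * K];
    bool useA = unif_rand() < 0.5;
    unsigned char *out = &nxt[(size_t) g * K];

    xo.clear();
    if (cmax > 0.0 && K > 1) {
      int k = geom_skip(cmax);
      while (k < K - 1) {
        if (cAdj[k] >= cmax || unif_rand() * cmax < cAdj[k])
          xo.push_back(k + 1);            // switch template before locus k+1
        k += 1 + geom_skip(cmax);
      }
    }
    int prev = 0;
    for (size_t e = 0; e <= xo.size(); ++e) {
      int end = (e < xo.size()) ? xo[e] : K;
      const unsigned char *src = useA ? hapA : hapB;
      std::memcpy(out + prev, src + prev, (size_t) (end - prev));
      prev = end;
      useA = !useA;
    }
    if (mutate && mu > 0.0) {
      int k = geom_skip(mu);
      while (k < K) {
        out[k] = 1 - out[k];
        k += 1 + geom_skip(mu);
      }
    }
  }
}

// Forward Wright-Fisher simulation of a diploid population of H/2
// individuals carrying K ordered biallelic marker loci. Gametes are formed
// by choosing a random parent, starting on one of its two haplotypes at
// random, and switching haplotype at each adjacent-marker interval k
// independently with probability cAdj[k] (interference-free Bernoulli
// process). During burn-in, site turnover keeps the marker columns at
// mutation-drift equilibrium: any column fixed for either allele is
// re-injected as a singleton on one random haplotype (recycle = true), and
// optional symmetric per-locus flip mutation runs at rate mu. Both are off
// between the two samples (drift only). Returns the K x H population
// haplotype matrices at the end of burn-in (generation 0) and tGen
// generations later.
// [[Rcpp::export(name = ".forwardSimCpp")]]
List forwardSimCpp(IntegerMatrix founders, NumericVector cAdj,
                   int burnIn, int tGen, double mu, bool recycle) {
  const int K = founders.nrow();
  const int H = founders.ncol();
  if (H < 2 || H % 2 != 0)
    stop("population must hold an even number >= 2 of haplotypes");
  if (cAdj.size() != K - 1) stop("cAdj must have length K - 1");
  if (burnIn < 0 || tGen < 0) stop("generation counts must be >= 0");

  std::vector<unsigned char> cur((size_t) K * H), nxt((size_t) K * H);
  for (int h = 0; h < H; ++h)
    for (int k = 0; k < K; ++k)
      cur[(size_t) h * K + k] = (unsigned char) founders(k, h);

  double cmax = 0.0;
  for (int k = 0; k < K - 1; ++k) {
    if (cAdj[k] < 0.0 || cAdj[k] > 0.5)
      stop("cAdj entries must lie in [0, 0.5]");
    if (cAdj[k] > cmax) cmax = cAdj[k];
  }

  RNGScope scope;
  std::vector<int> xo;
  xo.reserve(16);

  std::vector<int> count(K);
  for (int gen = 0; gen < burnIn; ++gen) {
    wf_generation(cur, nxt, K, H, cAdj, cmax, mu, true, xo);
    cur.swap(nxt);
    if (recycle) {
      std::fill(count.begin(), count.end(), 0);
      for (int h = 0; h < H; ++h) {
        const unsigned char *hap = &cur[(size_t) h * K];
        for (int k = 0; k < K; ++k) count[k] += hap[k];
      }
      for (int k = 0; k < K; ++k) {
        if (count[k] == 0 || count[k] == H) {
          int h = (int) (unif_rand() * H);
          if (h >= H) h = H - 1;
          cur[(size_t) h * K + k] = (unsigned char) (count[k] == 0 ? 1 : 0);
        }
      }
    }
  }
  IntegerMatrix H0(K, H);
  for (int h = 0; h < H; ++h)
    for (int k = 0; k < K; ++k) H0(k, h) = cur[(size_t) h * K + k];

  for (int gen = 0; gen < tGen; ++gen) {
    wf_generation(cur, nxt, K, H, cAdj, cmax, 0.0, false, xo);
    cur.swap(nxt);
  }
  IntegerMatrix Ht(K, H);
  for (int h = 0; h < H; ++h)
    for (int k = 0; k < K; ++k) Ht(k, h) = cur[(size_t) h * K + k];

  return List::create(Named("H0") = H0, Named("Ht") = Ht);
}
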