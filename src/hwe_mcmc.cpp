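#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Markov chain over the diploid pairing of the 2n alleles at a locus,
// allele counts fixed.  State: ordered allele types per pair slot.  The
// proposal swaps one member between two random pairs; in this
// representation the stationary law over states is uniform, so every
// proposal is accepted, and the induced distribution over genotype-count
// arrays is the Hardy-Weinberg conditional law  P ~ 2^h * n! / prod n_ab!.

namespace {

struct Rng {  // splitmix64; rejection-bounded draws, platform-deterministic
  std::uint64_t s;
  explicit Rng(std::uint64_t seed) : s(seed) {}
  std::uint64_t next() {
    std::uint64_t z = (s += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  std::uint64_t bounded(std::uint64_t n) {
    std::uint64_t threshold = (~n + 1) % n;  // 2^64 mod n
    for (;;) {
      std::uint64_t x = next();
      if (x >= threshold) return x % n;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector hwe_mcmc_chain(IntegerMatrix counts, int batches,
                             int dememorization, int iters_per_batch,
                             int seed) {
  const int k = counts.nrow();
  // expand genotype cells into pair slots
  std::vector<int> x1, x2;
  for (int a = 0; a < k; ++a)
    for (int b = a; b < k; ++b)
      for (int c = 0; c < counts(a, b); ++c) { x1.push_back(a); x2.push_back(b); }
  const int n = static_cast<int>(x1.size());
  NumericVector out(batches);
  if (n < 2) { std::fill(out.begin(), out.end(), 1.0); return out; }

  std::vector<double> lgam(2 * n + 2);
  for (int i = 0; i <= 2 * n + 1; ++i) lgam[i] = std::lgamma(double(i) + 1.0);
  const double ln2 = std::log(2.0);

  std::vector<int> cnt(k * k, 0);
  auto idx = [k](int a, int b) { return a <= b ? a * k + b : b * k + a; };
  int h = 0;
  for (int i = 0; i < n; ++i) {
    ++cnt[idx(x1[i], x2[i])];
    if (x1[i] != x2[i]) ++h;
  }
  auto neg_lgam_sum = [&]() {
    double acc = 0.0;
    for (int a = 0; a < k; ++a)
      for (int b = a; b < k; ++b) acc -= lgam[cnt[a * k + b]];
    return acc;
  };
  double lv = neg_lgam_sum();              // -sum lgamma(n_ab!)
  const double lv_obs = lv + h * ln2 + 1e-9;

  Rng rng(static_cast<std::uint64_t>(static_cast<std::uint32_t>(seed)));
  auto step = [&]() {
    std::uint64_t i = rng.bounded(n);
    std::uint64_t j = rng.bounded(n - 1);
    if (j >= i) ++j;
    std::uint64_t mm = rng.bounded(4);
    int &ai = (mm & 1) ? x1[i] : x2[i];
    int &aj = (mm & 2) ? x1[j] : x2[j];
    if (ai == aj) return;  // self-loop
    int gi = idx(x1[i], x2[i]), gj = idx(x1[j], x2[j]);
    h -= (x1[i] != x2[i]) + (x1[j] != x2[j]);
    lv += std::log(double(cnt[gi]--));     // cell c -> c-1: lgamma drops log c
    lv += std::log(double(cnt[gj]--));
    std::swap(ai, aj);
    gi = idx(x1[i], x2[i]); gj = idx(x1[j], x2[j]);
    lv -= std::log(double(++cnt[gi]));
    lv -= std::log(double(++cnt[gj]));
    h += (x1[i] != x2[i]) + (x1[j] != x2[j]);
  };

  for (int t = 0; t < dememorization; ++t) step();
  for (int b = 0; b < batches; ++b) {
    lv = neg_lgam_sum();                   // re-anchor against drift
    long hits = 0;
    for (int t = 0; t < iters_per_batch; ++t) {
      step();
      if (lv + h * ln2 <= lv_obs) ++hits;
    }
    out[b] = double(hits) / double(iters_per_batch);
  }
  return out;
}
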