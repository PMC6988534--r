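#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Structured Kingman coalescent with migration.  Lineages within a deme are
// exchangeable, so the state is tracked as per-deme id lists; coalescence in
// deme i has total rate k_i (k_i - 1) / (4 Ne_i) (diploid Ne, rate 1/(2 Ne)
// per lineage pair) and a lineage in deme i migrates to deme j at the
// backward rate mig(i, j).
//
// SNP conditioning: a pool of independent genealogies is simulated and each
// SNP's mutation is placed uniformly at random on the pool's total branch
// length, i.e. a genealogy carries a SNP with probability proportional to
// its total branch length.  This is the low-mutation-rate limit of drawing
// segregating sites from simulated sequences, and reproduces the classical
// conditioned spectra (folded single-deme SFS proportional to
// 1/i + 1/(2n - i)); every locus is polymorphic in the pooled sample.

// xoshiro256++ (public-domain algorithm), seeded via splitmix64.  A private
// generator keeps the event loop off R's RNG; the seed is supplied from R so
// set.seed() still governs reproducibility.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0,1]; never 0 so log() is safe
  inline double unif() {
    return (double)((next() >> 11) + 1) * 1.1102230246251565e-16; // 2^-53
  }
  inline int below(int n) { return (int)(unif() * n) % n; }
};

// [[Rcpp::export]]
IntegerMatrix sim_snp_matrix_cpp(IntegerVector n_dip, NumericVector ne,
                                 NumericMatrix mig, int n_snps,
                                 double seed, double max_events,
                                 double pool_factor) {
  const int d = n_dip.size();
  if (d < 1 || d > 32) stop("between 1 and 32 demes supported");
  if (ne.size() != d || mig.nrow() != d || mig.ncol() != d)
    stop("deme dimension mismatch between sample sizes, Ne and migration matrix");
  int total_dip = 0;
  for (int i = 0; i < d; ++i) {
    if (n_dip[i] < 1) stop("each deme needs at least one diploid sample");
    if (!(ne[i] > 0)) stop("effective sizes must be positive");
    total_dip += n_dip[i];
  }
  const int nt = 2 * total_dip;            // haploid tips
  const int n_nodes = 2 * nt - 1;
  Xoshiro rng((uint64_t)seed);

  double row_sum[32], inv_row_sum[32];
  double inv4ne[32];
  double mrow[32][32];                      // contiguous copy of mig rows
  for (int i = 0; i < d; ++i) {
    row_sum[i] = 0.0;
    inv4ne[i] = 1.0 / (4.0 * ne[i]);
    for (int j = 0; j < d; ++j) {
      double r = mig(i, j);
      if (r < 0) stop("migration rates must be non-negative");
      mrow[i][j] = (i == j) ? 0.0 : r;
      if (i != j) row_sum[i] += r;
    }
    inv_row_sum[i] = row_sum[i] > 0 ? 1.0 / row_sum[i] : 0.0;
  }

  const int n_pool = std::max(1, (int)std::ceil(pool_factor * n_snps));
  IntegerMatrix out(total_dip, n_snps);
  std::vector<int> parent(n_nodes), child1(n_nodes), child2(n_nodes);
  std::vector<double> node_time(n_nodes), blen(n_nodes);
  // flat per-deme lineage lists (each deme can hold at most nt ids)
  std::vector<int> lin(d * nt);
  int kcount[32];
  double coal_rate[32];
  std::vector<char> carrier(nt);
  std::vector<int> stk;
  stk.reserve(nt);
  // pooled genealogies: per-tree child pointers and node times, plus the
  // cumulative total branch length used for length-weighted SNP draws
  std::vector<int> pool_c1((size_t)n_pool * n_nodes), pool_c2((size_t)n_pool * n_nodes);
  std::vector<double> pool_time((size_t)n_pool * n_nodes);
  std::vector<double> cum_len(n_pool);
  double len_total = 0.0;

  for (int tree = 0; tree < n_pool; ++tree) {
    int tip = 0;
    for (int i = 0; i < d; ++i) {
      kcount[i] = 2 * n_dip[i];
      for (int k = 0; k < kcount[i]; ++k) lin[i * nt + k] = tip++;
    }
    for (int v = 0; v < nt; ++v) { node_time[v] = 0.0; child1[v] = -1; child2[v] = -1; }
    for (int i = 0; i < d; ++i)
      coal_rate[i] = (double)kcount[i] * (kcount[i] - 1) * inv4ne[i];
    int next_node = nt, n_active = nt;
    double t = 0.0, events = 0.0;

    while (n_active > 1) {
      // totals are re-summed every event (d is tiny); per-deme rates are
      // exact, so a deme with < 2 lineages can never be selected by drift
      double coal_total = 0.0, mig_total = 0.0;
      for (int i = 0; i < d; ++i) {
        coal_total += coal_rate[i];
        mig_total += kcount[i] * row_sum[i];
      }
      double total = coal_total + mig_total;
      if (total <= 0.0)
        stop("lineages cannot reach a common ancestor under this migration structure");
      if (++events > max_events)
        stop("event cap exceeded before coalescence; migration structure may not connect all demes");
      t += -std::log(rng.unif()) / total;
      double u = rng.unif() * total;
      if (u < coal_total) {
        int i = 0;
        while (i < d - 1 && u >= coal_rate[i]) { u -= coal_rate[i]; ++i; }
        if (kcount[i] < 2) {            // fp guard: redirect to a valid deme
          for (int q = 0; q < d; ++q) if (coal_rate[q] > 0) { i = q; break; }
        }
        int k = kcount[i];
        int a = rng.below(k);
        int b = rng.below(k - 1);
        if (b >= a) ++b;
        int *li = &lin[i * nt];
        int na = li[a], nb = li[b];
        int p = next_node++;
        node_time[p] = t; child1[p] = na; child2[p] = nb;
        parent[na] = p; parent[nb] = p;
        if (a > b) std::swap(a, b);
        li[b] = li[k - 1];
        li[a] = p;
        kcount[i] = --k;
        coal_rate[i] = (double)k * (k - 1) * inv4ne[i];
        --n_active;
      } else {
        u -= coal_total;
        // pick source deme by k_i * row_sum[i], then destination and lineage
        // index from the residual of the same uniform (product space)
        int i = 0;
        double w = (double)kcount[i] * row_sum[i];
        while (i < d - 1 && u >= w) { u -= w; w = (double)kcount[++i] * row_sum[i]; }
        if (kcount[i] < 1 || row_sum[i] <= 0) { // fp guard
          for (int q = 0; q < d; ++q)
            if (kcount[q] > 0 && row_sum[q] > 0) { i = q; break; }
          u = rng.unif() * kcount[i] * row_sum[i];
        }
        // u is uniform on [0, k_i * row_sum[i]); split it into an independent
        // lineage index a = floor(u / row_sum) and residual v for destination
        int a = (int)(u * inv_row_sum[i]);
        int k = kcount[i];
        if (a >= k) a = k - 1;
        double v = u - a * row_sum[i];       // in [0, row_sum[i])
        int j = 0;
        while (j < d - 1 && (j == i || v >= mrow[i][j])) {
          if (j != i) v -= mrow[i][j];
          ++j;
        }
        if (j == i) j = (i + 1) % d;          // fp guard; unreachable in theory
        int *li = &lin[i * nt];
        int node = li[a];
        li[a] = li[k - 1];
        kcount[i] = k - 1;
        lin[j * nt + kcount[j]] = node;
        ++kcount[j];
        coal_rate[i] = (double)(k - 1) * (k - 2) * inv4ne[i];
        coal_rate[j] = (double)kcount[j] * (kcount[j] - 1) * inv4ne[j];
      }
    }

    // archive the tree and its total branch length (root excluded)
    const int root = n_nodes - 1;
    double L = 0.0;
    for (int v = 0; v < root; ++v)
      L += node_time[parent[v]] - node_time[v];
    std::copy(child1.begin(), child1.end(), pool_c1.begin() + (size_t)tree * n_nodes);
    std::copy(child2.begin(), child2.end(), pool_c2.begin() + (size_t)tree * n_nodes);
    std::copy(node_time.begin(), node_time.end(), pool_time.begin() + (size_t)tree * n_nodes);
    len_total += L;
    cum_len[tree] = len_total;
  }

  // each SNP: pick a genealogy proportional to branch length, then place
  // the mutation uniformly on that genealogy's branches
  const int root = n_nodes - 1;
  for (int locus = 0; locus < n_snps; ++locus) {
    double uT = rng.unif() * len_total;
    int tree = (int)(std::lower_bound(cum_len.begin(), cum_len.end(), uT) -
                     cum_len.begin());
    if (tree >= n_pool) tree = n_pool - 1;
    const int *c1 = &pool_c1[(size_t)tree * n_nodes];
    const int *c2 = &pool_c2[(size_t)tree * n_nodes];
    const double *tm = &pool_time[(size_t)tree * n_nodes];
    // recover branch lengths via children (parent time minus child time)
    double L = 0.0;
    for (int v = nt; v < n_nodes; ++v) {
      blen[c1[v]] = tm[v] - tm[c1[v]];
      blen[c2[v]] = tm[v] - tm[c2[v]];
    }
    for (int v = 0; v < root; ++v) L += blen[v];
    double uL = rng.unif() * L;
    int mut = root - 1;
    for (int v = 0; v < root; ++v) {
      if (uL < blen[v]) { mut = v; break; }
      uL -= blen[v];
    }
    // derived (alternate) allele = tips descending from the mutated branch
    std::fill(carrier.begin(), carrier.end(), 0);
    stk.clear(); stk.push_back(mut);
    while (!stk.empty()) {
      int v = stk.back(); stk.pop_back();
      if (v < nt) carrier[v] = 1;
      else { stk.push_back(c1[v]); stk.push_back(c2[v]); }
    }
    for (int s = 0; s < total_dip; ++s)
      out(s, locus) = carrier[2 * s] + carrier[2 * s + 1];
  }
  return out;
}
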