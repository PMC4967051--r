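// Kinetic Monte Carlo inner loop: independent random walkers confined to a
// fractal vascular lattice, stochastically colonizing adjacent tissue.
// The default run is ~5e8 elementary steps, hence C++.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// xoshiro256++ (Blackman & Vigna), seeded via splitmix64: a named, fast,
// seedable generator giving bit-reproducible runs independent of R's RNG.
struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion of the scalar seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
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
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
  inline int below(int n) { return (int)(unif() * n); }        // {0, .., n-1}
};

static const int DX[6] = { 1, -1, 0, 0, 0, 0 };
static const int DY[6] = { 0, 0, 1, -1, 0, 0 };
static const int DZ[6] = { 0, 0, 0, 0, 1, -1 };

// [[Rcpp::export]]
List kmc_run_cpp(int L,
                 IntegerVector net_sites,   // 0-based linear indices of network sites
                 int n_walkers,
                 double p_infect,
                 double t_total,            // sweeps (= per-walker steps)
                 double record_every,       // sampling stride, sweeps
                 double seed,
                 NumericVector snapshot_at, // sorted sweep times for snapshots
                 bool myopic) {
  const long long L3 = (long long)L * L * L;
  const long long T = (long long)t_total;
  const long long rec = record_every >= 1 ? (long long)record_every : 1;

  std::vector<uint8_t> net(L3, 0), infected(L3, 0);
  for (R_xlen_t i = 0; i < net_sites.size(); ++i) net[net_sites[i]] = 1;

  Xoshiro256pp rng((uint64_t)(int64_t)seed);

  std::vector<int> wx(n_walkers), wy(n_walkers), wz(n_walkers);
  IntegerVector start_idx(n_walkers);
  for (int w = 0; w < n_walkers; ++w) {
    int idx = net_sites[rng.below(net_sites.size())];
    start_idx[w] = idx;
    wx[w] = idx % L; wy[w] = (idx / L) % L; wz[w] = idx / (L * L);
  }

  long long n_inf = 0;
  std::vector<double> ser_t; std::vector<double> ser_n;
  ser_t.reserve(T / rec + 2); ser_n.reserve(T / rec + 2);
  ser_t.push_back(0.0); ser_n.push_back(0.0);

  List snapshots(snapshot_at.size());
  R_xlen_t si = 0;
  // snapshots requested at sweep 0 capture the empty initial state
  while (si < snapshot_at.size() && snapshot_at[si] <= 0) {
    snapshots[si] = IntegerVector(0);
    ++si;
  }

  for (long long sweep = 1; sweep <= T; ++sweep) {
    for (int w = 0; w < n_walkers; ++w) {
      int x = wx[w], y = wy[w], z = wz[w];
      if (!myopic) {
        // blind ant: pick one of 6 directions; rejected moves waste the step
        int d = rng.below(6);
        int nx = x + DX[d], ny = y + DY[d], nz = z + DZ[d];
        if (nx >= 0 && nx < L && ny >= 0 && ny < L && nz >= 0 && nz < L &&
            net[nx + (long long)L * (ny + (long long)L * nz)]) {
          x = nx; y = ny; z = nz;
        }
      } else {
        // myopic ant: uniform over accessible network neighbors
        int cand[6]; int nc = 0;
        for (int d = 0; d < 6; ++d) {
          int nx = x + DX[d], ny = y + DY[d], nz = z + DZ[d];
          if (nx >= 0 && nx < L && ny >= 0 && ny < L && nz >= 0 && nz < L &&
              net[nx + (long long)L * (ny + (long long)L * nz)])
            cand[nc++] = d;
        }
        if (nc > 0) {
          int d = cand[rng.below(nc)];
          x += DX[d]; y += DY[d]; z += DZ[d];
        }
      }
      wx[w] = x; wy[w] = y; wz[w] = z;

      // colonization attempt: uniform among uninfected non-network 6-neighbors
      // of the current site; if none, the event lapses (no resampling)
      if (p_infect > 0 && rng.unif() < p_infect) {
        long long cand[6]; int nc = 0;
        for (int d = 0; d < 6; ++d) {
          int nx = x + DX[d], ny = y + DY[d], nz = z + DZ[d];
          if (nx >= 0 && nx < L && ny >= 0 && ny < L && nz >= 0 && nz < L) {
            long long idx = nx + (long long)L * (ny + (long long)L * nz);
            if (!net[idx] && !infected[idx]) cand[nc++] = idx;
          }
        }
        if (nc > 0) {
          infected[cand[rng.below(nc)]] = 1;
          ++n_inf;
        }
      }
    }

    if (sweep % rec == 0 || sweep == T) {
      ser_t.push_back((double)sweep);
      ser_n.push_back((double)n_inf);
    }
    while (si < snapshot_at.size() && (long long)snapshot_at[si] == sweep) {
      std::vector<int> snap; snap.reserve(n_inf);
      for (long long i = 0; i < L3; ++i) if (infected[i]) snap.push_back((int)i);
      snapshots[si] = IntegerVector(snap.begin(), snap.end());
      ++si;
    }
    if (sweep % 1048576 == 0) Rcpp::checkUserInterrupt();
  }

  std::vector<int> inf_idx; inf_idx.reserve(n_inf);
  for (long long i = 0; i < L3; ++i) if (infected[i]) inf_idx.push_back((int)i);

  IntegerVector walker_idx(n_walkers);
  bool walkers_on_network = true;
  for (int w = 0; w < n_walkers; ++w) {
    long long idx = wx[w] + (long long)L * (wy[w] + (long long)L * wz[w]);
    walker_idx[w] = (int)idx;
    if (!net[idx]) walkers_on_network = false;
  }

  return List::create(
    _["t_sweep"] = NumericVector(ser_t.begin(), ser_t.end()),
    _["n_m"] = NumericVector(ser_n.begin(), ser_n.end()),
    _["infected"] = IntegerVector(inf_idx.begin(), inf_idx.end()),
    _["walkers"] = walker_idx,
    _["walker_starts"] = start_idx,
    _["walkers_on_network"] = walkers_on_network,
    _["snapshots"] = snapshots);
}
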