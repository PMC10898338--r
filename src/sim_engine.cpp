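#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Branching-process engine for the spermatogonial stem-cell models.
//
// Only mutant lineages are materialised: the wild-type pool is the fixed
// background of 2^G stem cells.  A clone is (size, position); positions are
// points on the unit circle and a clone occupies the contiguous arc
// [pos, pos + size/2^G) (descendants stay in close proximity).
//
// Clones that go extinct before rendering contribute nothing, so the engine
// never simulates them: arrival processes are Poisson-thinned by the exact
// extinction probabilities q_j (generating-function recursion
// q_j = (1-p) + p q_{j-1}^2, q_0 = 0), and surviving clones follow the
// transition law conditioned on survival,
//   P(n' | n, j left, survive) = P(n' | n) (1 - q_{j-1}^{n'})/(1 - q_j^n),
// sampled by rejection from the unconditioned binomial with acceptance
// probability (1 - q_{j-1}^{n'})/(1 - q_{j-1}^{2n}) <= 1.  This is exact in
// distribution (clones are independent); the test suite checks it against a
// plain stepwise simulator and a cell-by-cell oracle.
//
// Randomness: arrivals and large binomials come from R's RNG (so set.seed()
// governs everything); small binomials of the critical model are drawn as
// popcounts of xoshiro256++ bits, the xoshiro state itself being seeded from
// R's RNG at entry.  Same R seed => same output.

namespace {

struct Xoshiro {
  uint64_t s[4];
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  void seed_from_R() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(i + 1));
    }
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 0x106689D45497FDB5ULL;
    for (int i = 0; i < 8; ++i) next();
  }
  // exact Binomial(n, 1/2): popcount of n fair bits
  inline long long binom_half(long long n) {
    long long k = 0;
    while (n >= 64) { k += __builtin_popcountll(next()); n -= 64; }
    if (n > 0)
      k += __builtin_popcountll(next() & ((1ULL << n) - 1ULL));
    return k;
  }
};

inline long long draw_binom(long long n, double p, bool fair, Xoshiro& xo) {
  if (n <= 0) return 0;
  if (fair && n <= 512) return xo.binom_half(n);
  return (long long) R::rbinom((double) n, p);
}

// final size of a clone of initial size n0 after k update cycles,
// conditioned on being alive at the end; lq[j] = log q_j; returns -1 when
// the clone outgrows sat_cap (saturated regime)
long long surviving_path(long long n0, long long k, double p, bool fair,
                         const std::vector<double>& lq, long long sat_cap,
                         Xoshiro& xo) {
  long long n = n0;
  for (long long j = k; j >= 1; --j) {
    const double lqj1 = lq[(size_t)(j - 1)];
    for (;;) {
      long long b = draw_binom(n, p, fair, xo);
      if (b == 0) continue;                 // extinct next cycle: cannot survive
      long long np = 2 * b;
      double num_e = (double) np * lqj1;    // log q_{j-1}^{n'}
      if (num_e < -37.0) { n = np; break; } // acceptance ratio 1 to double precision
      double num = -expm1(num_e);
      double den = -expm1(2.0 * (double) n * lqj1);
      if (xo.unif() * den <= num) { n = np; break; }
    }
    if (n > sat_cap) return -1;
  }
  return n;
}

struct RepResult { double avg; double maxp; bool saturated; };

RepResult saturated_result(double ploidy, std::vector<double>& piece) {
  std::fill(piece.begin(), piece.end(), 1.0);
  RepResult r; r.avg = ploidy; r.maxp = ploidy; r.saturated = true;
  return r;
}

RepResult sim_once(int G, long long T, double mu, double p_sym, int n_pieces,
                   double ploidy, const std::vector<double>& lq,
                   const std::vector<double>& surv, Xoshiro& xo,
                   std::vector<long long>& sz, std::vector<double>& pos,
                   std::vector<double>& piece) {
  sz.clear(); pos.clear();
  const double pool = ldexp(1.0, G);
  const long long poolL = 1LL << G;
  const bool fair = (p_sym == 0.5);

  // growth phase: layer g (0-based) produces 2^(g+1) daughters, each mutating
  // with probability mu; a lineage born at layer g has 2^(G-g-1) cells at
  // puberty, then runs through all T adult cycles
  for (int g = 0; g < G; ++g) {
    long long n0 = 1LL << (G - g - 1);
    double ps;                                   // P(alive at rendering)
    if (T == 0) ps = 1.0;
    else {
      double e = (double) n0 * lq[(size_t) T];
      ps = e < -37.0 ? 1.0 : -expm1(e);
    }
    double lam = ldexp(2.0, g) * mu * ps;        // thinned arrival rate
    int m = (int) R::rpois(lam);
    for (int j = 0; j < m; ++j) {
      long long s_fin = T == 0 ? n0
        : surviving_path(n0, T, p_sym, fair, lq, poolL, xo);
      if (s_fin < 0) return saturated_result(ploidy, piece);
      sz.push_back(s_fin); pos.push_back(xo.unif());
    }
  }

  // adult phase: 2^G stem daughters per cycle, so new mutant lineages arrive
  // as Poisson(2^G mu) clones of size 1; an arrival in cycle t (0-based) is
  // updated in the k = T-1-t remaining cycles
  const double lam_adult = pool * mu;
  if (lam_adult > 0) {
    for (long long t = 0; t < T; ++t) {
      long long k = T - 1 - t;
      int m = (int) R::rpois(lam_adult * surv[(size_t) k]);
      for (int j = 0; j < m; ++j) {
        long long s_fin = surviving_path(1, k, p_sym, fair, lq, poolL, xo);
        if (s_fin < 0) return saturated_result(ploidy, piece);
        sz.push_back(s_fin); pos.push_back(xo.unif());
      }
    }
  }

  // saturation across clones: mutant lineages cannot exceed the stem pool
  long long total = 0;
  for (size_t i = 0; i < sz.size(); ++i) {
    total += sz[i];
    if (total > poolL) return saturated_result(ploidy, piece);
  }

  // render: circle cut into n_pieces equal arcs; piece[i] accumulates the
  // covered fraction of piece i (mutant cells / piece cells)
  std::fill(piece.begin(), piece.end(), 0.0);
  for (size_t i = 0; i < sz.size(); ++i) {
    double x = pos[i] * n_pieces;                 // start, in piece units
    int p0 = (int) x; if (p0 >= n_pieces) p0 = n_pieces - 1;
    double remain = ((double) sz[i] / pool) * n_pieces;
    double first = (double) (p0 + 1) - x;
    if (first > remain) first = remain;
    piece[p0] += first; remain -= first;
    int pi = (p0 + 1) % n_pieces;
    while (remain > 0) {
      double add = remain < 1.0 ? remain : 1.0;
      piece[pi] += add; remain -= add;
      pi = (pi + 1) % n_pieces;
    }
  }
  double mx = 0.0;
  for (int i = 0; i < n_pieces; ++i) if (piece[i] > mx) mx = piece[i];
  RepResult r;
  r.avg = ploidy * (double) total / pool;
  r.maxp = ploidy * mx;
  r.saturated = false;
  return r;
}

} // namespace

// [[Rcpp::export]]
List cpp_sim_reps(int n_reps, int G, double T, double mu, double p_sym,
                  int n_pieces, double ploidy, bool return_pieces) {
  if (G < 1 || G > 62) stop("growth_generations must be in [1, 62]");
  if (T < 0) stop("adult cycles must be >= 0");
  if (mu < 0 || mu >= 1) stop("mutation rate must be in [0, 1)");
  if (p_sym <= 0 || p_sym >= 1) stop("symmetric-division probability must be in (0, 1)");
  if (n_pieces < 1) stop("n_pieces must be >= 1");
  long long Tc = (long long) T;

  Xoshiro xo;
  xo.seed_from_R();

  // extinction probabilities of a single-cell lineage over j cycles:
  // q_0 = 0, q_j = (1-p) + p q_{j-1}^2
  std::vector<double> q((size_t) Tc + 1), lq(q.size()), surv(q.size());
  q[0] = 0.0; lq[0] = R_NegInf; surv[0] = 1.0;
  for (long long j = 1; j <= Tc; ++j) {
    q[(size_t) j] = (1.0 - p_sym) + p_sym * q[(size_t)(j - 1)] * q[(size_t)(j - 1)];
    lq[(size_t) j] = std::log(q[(size_t) j]);
    surv[(size_t) j] = 1.0 - q[(size_t) j];
  }

  NumericVector avg(n_reps), mx(n_reps);
  LogicalVector sat(n_reps);
  NumericMatrix pieces_out = return_pieces ? NumericMatrix(n_reps, n_pieces)
                                           : NumericMatrix(0, 0);
  std::vector<long long> sz; sz.reserve(4096);
  std::vector<double> pos; pos.reserve(4096);
  std::vector<double> piece((size_t) n_pieces, 0.0);

  for (int r = 0; r < n_reps; ++r) {
    if ((r & 63) == 0) Rcpp::checkUserInterrupt();
    RepResult res = sim_once(G, Tc, mu, p_sym, n_pieces, ploidy,
                             lq, surv, xo, sz, pos, piece);
    avg[r] = res.avg; mx[r] = res.maxp; sat[r] = res.saturated;
    if (return_pieces)
      for (int i = 0; i < n_pieces; ++i) pieces_out(r, i) = ploidy * piece[i];
  }
  List out = List::create(_["avg_freq"] = avg, _["max_piece_freq"] = mx,
                          _["saturated"] = sat);
  if (return_pieces) out["piece_freqs"] = pieces_out;
  return out;
}
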