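// Core lattice engine.
//
// The lattice is stored column-major (R layout): linear index i = col*H + row.
// A cached field ps[i] holds the sum of production over the Moore
// neighbourhood of i plus i itself (truncated at the edges under no-flux
// boundaries); it is updated incrementally on every birth, death and move so
// that fitness evaluation during the replication lottery is O(1) per
// competitor. The cache is recomputed and verified against the state at the
// end of every run.

#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <cstring>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Random stream: xoshiro256++ seeded through splitmix64. One stream drives
// every stochastic draw in a simulation; it is held by R as an external
// pointer so that chunked kernel calls continue the same sequence.
// ---------------------------------------------------------------------------

struct Xoshiro256 {
  uint64_t s[4];

  explicit Xoshiro256(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t w = z;
      w = (w ^ (w >> 30)) * 0xbf58476d1ce4e5b9ULL;
      w = (w ^ (w >> 27)) * 0x94d049bb133111ebULL;
      s[i] = w ^ (w >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  inline double unif() {  // uniform on [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }

  inline int below(int n) {  // uniform integer on {0, ..., n-1}
    return (int)(((__uint128_t)next() * (uint64_t)n) >> 64);
  }
};

static Xoshiro256* get_rng(SEXP ptr) {
  Rcpp::XPtr<Xoshiro256> x(ptr);
  return x.get();
}

// [[Rcpp::export]]
SEXP rng_create_(double seed) {
  Xoshiro256* r = new Xoshiro256((uint64_t)seed);
  Rcpp::XPtr<Xoshiro256> ptr(r, true);
  return ptr;
}

// [[Rcpp::export]]
NumericVector rng_unif_(SEXP ptr, int n) {
  Xoshiro256* r = get_rng(ptr);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = r->unif();
  return out;
}

// [[Rcpp::export]]
CharacterVector rng_get_state_(SEXP ptr) {
  Xoshiro256* r = get_rng(ptr);
  CharacterVector out(4);
  char buf[17];
  for (int i = 0; i < 4; ++i) {
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)r->s[i]);
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
void rng_set_state_(SEXP ptr, CharacterVector state) {
  if (state.size() != 4) stop("RNG state must have 4 words");
  Xoshiro256* r = get_rng(ptr);
  for (int i = 0; i < 4; ++i) {
    const char* str = CHAR(STRING_ELT(state, i));
    uint64_t w = 0;
    int nd = 0;
    for (; *str; ++str, ++nd) {
      char c = *str;
      int v;
      if (c >= '0' && c <= '9') v = c - '0';
      else if (c >= 'a' && c <= 'f') v = c - 'a' + 10;
      else if (c >= 'A' && c <= 'F') v = c - 'A' + 10;
      else stop("malformed RNG state word");
      w = (w << 4) | (uint64_t)v;
    }
    if (nd == 0 || nd > 16) stop("malformed RNG state word");
    r->s[i] = w;
  }
}

// ---------------------------------------------------------------------------
// Parameters and geometry
// ---------------------------------------------------------------------------

struct Par {
  double b, cost, kdeath, kmove, mu, delta, pmax;
  bool toroidal;
  int altruism;    // 0 = weak (self share p/9), 1 = strong (no self benefit)
  int strong_den;  // 8 (neighbours split everything) or 9 (self share wasted)
};

static Par as_par(List params) {
  Par p;
  p.b = as<double>(params["b"]);
  p.cost = as<double>(params["cost"]);
  p.kdeath = as<double>(params["k_death"]);
  p.kmove = as<double>(params["k_move"]);
  p.mu = as<double>(params["mu"]);
  p.delta = as<double>(params["delta"]);
  p.pmax = as<double>(params["p_max"]);
  p.toroidal = as<std::string>(params["boundary"]) == "toroidal";
  p.altruism = as<std::string>(params["altruism"]) == "strong" ? 1 : 0;
  p.strong_den = as<int>(params["strong_share_n"]);
  return p;
}

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Moore neighbour table: nb[i*8 + d], -1 where the neighbour falls outside a
// non-wrapping lattice.
static std::vector<int> build_nbr(int H, int W, bool toroidal) {
  std::vector<int> nb((size_t)H * W * 8);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      size_t i = (size_t)c * H + r;
      for (int d = 0; d < 8; ++d) {
        int rr = r + DR[d], cc = c + DC[d];
        if (toroidal) {
          rr = (rr + H) % H;
          cc = (cc + W) % W;
          nb[i * 8 + d] = cc * H + rr;
        } else {
          nb[i * 8 + d] = (rr < 0 || rr >= H || cc < 0 || cc >= W)
                              ? -1
                              : cc * H + rr;
        }
      }
    }
  }
  return nb;
}

// Benefit from a neighbourhood production sum (psum includes the focal
// individual's own production). Weak altruism: everyone in the 3x3 block,
// self included, receives p/9 from each producer. Strong altruism: the focal
// individual receives nothing from itself; each neighbour's good arrives as
// p/strong_den.
static inline double benefit_from_sum(double psum, double pi, const Par& par) {
  if (par.altruism == 0) return par.b * psum / 9.0;
  return par.b * (psum - pi) / (double)par.strong_den;
}

static inline double fitness_from_sum(double psum, double pi, const Par& par) {
  double f = benefit_from_sum(psum, pi, par) - par.cost * pi;
  return std::fmax(f, 0.0);
}

// Direct (uncached) neighbourhood production sum including self.
static double local_psum(const uint8_t* occ, const double* p,
                         const std::vector<int>& nb, int i) {
  double s = occ[i] ? p[i] : 0.0;
  for (int d = 0; d < 8; ++d) {
    int j = nb[(size_t)i * 8 + d];
    if (j >= 0 && occ[j]) s += p[j];
  }
  return s;
}

// ---------------------------------------------------------------------------
// Single-site operations (R-facing; used by the engine wrappers and oracles)
// ---------------------------------------------------------------------------

static void check_site(int H, int W, int row0, int col0) {
  if (row0 < 0 || row0 >= H || col0 < 0 || col0 >= W)
    stop("site out of range");
}

// [[Rcpp::export]]
IntegerVector cpp_neighbor_sites(int H, int W, bool toroidal, int row0,
                                 int col0) {
  check_site(H, W, row0, col0);
  std::vector<int> out;
  out.reserve(8);
  for (int d = 0; d < 8; ++d) {
    int rr = row0 + DR[d], cc = col0 + DC[d];
    if (toroidal) {
      rr = (rr + H) % H;
      cc = (cc + W) % W;
      out.push_back(cc * H + rr);
    } else if (rr >= 0 && rr < H && cc >= 0 && cc < W) {
      out.push_back(cc * H + rr);
    }
  }
  return wrap(out);
}

static std::vector<uint8_t> occ_vec(const IntegerMatrix& occ) {
  std::vector<uint8_t> v(occ.size());
  for (int i = 0; i < occ.size(); ++i) v[i] = occ[i] != 0;
  return v;
}

// [[Rcpp::export]]
double cpp_benefit(IntegerMatrix occ, NumericMatrix prod, List params,
                   int row0, int col0) {
  int H = occ.nrow(), W = occ.ncol();
  check_site(H, W, row0, col0);
  Par par = as_par(params);
  int i = col0 * H + row0;
  if (!occ[i]) stop("site is empty");
  std::vector<uint8_t> o = occ_vec(occ);
  std::vector<int> nb = build_nbr(H, W, par.toroidal);
  return benefit_from_sum(local_psum(o.data(), REAL(prod), nb, i), prod[i],
                          par);
}

// [[Rcpp::export]]
double cpp_fitness(IntegerMatrix occ, NumericMatrix prod, List params,
                   int row0, int col0) {
  int H = occ.nrow(), W = occ.ncol();
  check_site(H, W, row0, col0);
  Par par = as_par(params);
  int i = col0 * H + row0;
  if (!occ[i]) stop("site is empty");
  std::vector<uint8_t> o = occ_vec(occ);
  std::vector<int> nb = build_nbr(H, W, par.toroidal);
  return fitness_from_sum(local_psum(o.data(), REAL(prod), nb, i), prod[i],
                          par);
}

// Gather occupied competitors of an empty site with positive fitness.
static int gather_competitors(const uint8_t* occ, const double* p,
                              const std::vector<int>& nb, int i,
                              const Par& par, int* who, double* fs,
                              double* ftot_out) {
  int m = 0;
  double ftot = 0.0;
  for (int d = 0; d < 8; ++d) {
    int j = nb[(size_t)i * 8 + d];
    if (j >= 0 && occ[j]) {
      double f = fitness_from_sum(local_psum(occ, p, nb, j), p[j], par);
      if (f > 0.0) {
        who[m] = j;
        fs[m] = f;
        ++m;
        ftot += f;
      }
    }
  }
  *ftot_out = ftot;
  return m;
}

// One lottery draw given competitors; returns index into who[] or -1 (none).
// A single uniform decides both whether anyone replicates (with probability
// 1 - exp(-ftot)) and, conditionally, who (proportional to fitness).
static inline int lottery_pick(int m, const double* fs, double ftot,
                               Xoshiro256& rng) {
  if (m == 0 || ftot <= 0.0) return -1;
  double u = rng.unif();
  // 1 - exp(-x) <= min(1, x): u >= ftot is a certain "none" without exp
  if (u >= ftot) return -1;
  // for ftot > 38, exp(-ftot) < 2^-54 and 1 - exp(-ftot) rounds to exactly 1
  double p_any = (ftot > 38.0) ? 1.0 : 1.0 - std::exp(-ftot);
  if (u >= p_any) return -1;
  if (m == 1) return 0;
  double r = u / p_any * ftot;
  double cum = 0.0;
  for (int k = 0; k < m; ++k) {
    cum += fs[k];
    if (r < cum) return k;
  }
  return m - 1;  // guard against fp round-off on the last boundary
}

// [[Rcpp::export]]
int cpp_select_replicator(IntegerMatrix occ, NumericMatrix prod, List params,
                          int row0, int col0, SEXP rng_ptr) {
  int H = occ.nrow(), W = occ.ncol();
  check_site(H, W, row0, col0);
  Par par = as_par(params);
  int i = col0 * H + row0;
  if (occ[i]) stop("site is occupied");
  std::vector<uint8_t> o = occ_vec(occ);
  std::vector<int> nb = build_nbr(H, W, par.toroidal);
  int who[8];
  double fs[8], ftot;
  int m = gather_competitors(o.data(), REAL(prod), nb, i, par, who, fs, &ftot);
  int k = lottery_pick(m, fs, ftot, *get_rng(rng_ptr));
  return k < 0 ? -1 : who[k];
}

// Repeated lottery draws from a frozen state, for frequency tests.
// [[Rcpp::export]]
List cpp_lottery_counts(IntegerMatrix occ, NumericMatrix prod, List params,
                        int row0, int col0, int n, SEXP rng_ptr) {
  int H = occ.nrow(), W = occ.ncol();
  check_site(H, W, row0, col0);
  Par par = as_par(params);
  int i = col0 * H + row0;
  if (occ[i]) stop("site is occupied");
  std::vector<uint8_t> o = occ_vec(occ);
  std::vector<int> nb = build_nbr(H, W, par.toroidal);
  int who[8];
  double fs[8], ftot;
  int m = gather_competitors(o.data(), REAL(prod), nb, i, par, who, fs, &ftot);
  std::vector<int> counts(m, 0);
  int none = 0;
  Xoshiro256& rng = *get_rng(rng_ptr);
  for (int it = 0; it < n; ++it) {
    int k = lottery_pick(m, fs, ftot, rng);
    if (k < 0)
      ++none;
    else
      ++counts[k];
  }
  return List::create(_["sites"] = IntegerVector(who, who + m),
                      _["fitness"] = NumericVector(fs, fs + m),
                      _["counts"] = wrap(counts), _["none"] = none);
}

// [[Rcpp::export]]
NumericVector cpp_mutate_production(NumericVector p, List params,
                                    SEXP rng_ptr) {
  Par par = as_par(params);
  Xoshiro256& rng = *get_rng(rng_ptr);
  NumericVector out(p.size());
  for (int i = 0; i < p.size(); ++i) {
    double v = p[i];
    if (par.mu > 0 && rng.unif() < par.mu) {
      v += (rng.unif() - 0.5) * par.delta;
      if (v < 0.0) v = 0.0;
      if (v > par.pmax) v = par.pmax;
    }
    out[i] = v;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Mutable world used by the step loop
// ---------------------------------------------------------------------------

struct World {
  int H, W, N;
  std::vector<uint8_t> occ;
  std::vector<double> p;
  std::vector<int> strain;
  std::vector<double> ps;         // cached 3x3 production sums
  std::vector<uint8_t> absorbing; // boundary ring under no-flux
  std::vector<int> nb;
  long pop;
  Par par;

  World(IntegerMatrix occm, NumericMatrix prodm, IntegerMatrix strainm,
        const Par& par_)
      : H(occm.nrow()), W(occm.ncol()), N(H * W), par(par_) {
    occ = occ_vec(occm);
    p.assign(REAL(prodm), REAL(prodm) + N);
    strain.assign(INTEGER(strainm), INTEGER(strainm) + N);
    nb = build_nbr(H, W, par.toroidal);
    absorbing.assign(N, 0);
    if (!par.toroidal) {
      for (int c = 0; c < W; ++c)
        for (int r = 0; r < H; ++r)
          if (r == 0 || r == H - 1 || c == 0 || c == W - 1)
            absorbing[c * H + r] = 1;
    }
    pop = 0;
    for (int i = 0; i < N; ++i) {
      if (occ[i]) ++pop;
      else p[i] = 0.0;  // production is meaningful only where occupied
    }
    ps.assign(N, 0.0);
    rebuild_ps();
  }

  // Canonical cache rebuild: separable 3x1 then 1x3 sums in a fixed order,
  // so the cache is a pure function of the state. Relies on p == 0 at
  // every empty node (maintained by remove_at and the constructor).
  std::vector<double> colsum;
  void rebuild_ps() {
    colsum.resize(N);
    if (par.toroidal) {
      for (int c = 0; c < W; ++c) {
        const double* q = &p[(size_t)c * H];
        double* t = &colsum[(size_t)c * H];
        for (int r = 0; r < H; ++r) {
          int rm = (r == 0) ? H - 1 : r - 1;
          int rp = (r == H - 1) ? 0 : r + 1;
          t[r] = q[rm] + q[r] + q[rp];
        }
      }
      for (int c = 0; c < W; ++c) {
        const double* tm = &colsum[(size_t)((c == 0) ? W - 1 : c - 1) * H];
        const double* t0 = &colsum[(size_t)c * H];
        const double* tp = &colsum[(size_t)((c == W - 1) ? 0 : c + 1) * H];
        double* out = &ps[(size_t)c * H];
        for (int r = 0; r < H; ++r) out[r] = tm[r] + t0[r] + tp[r];
      }
    } else {
      for (int c = 0; c < W; ++c) {
        const double* q = &p[(size_t)c * H];
        double* t = &colsum[(size_t)c * H];
        for (int r = 0; r < H; ++r) {
          double s = q[r];
          if (r > 0) s += q[r - 1];
          if (r < H - 1) s += q[r + 1];
          t[r] = s;
        }
      }
      for (int c = 0; c < W; ++c) {
        double* out = &ps[(size_t)c * H];
        const double* t0 = &colsum[(size_t)c * H];
        const double* tm = (c > 0) ? &colsum[(size_t)(c - 1) * H] : nullptr;
        const double* tp = (c < W - 1) ? &colsum[(size_t)(c + 1) * H]
                                       : nullptr;
        for (int r = 0; r < H; ++r) {
          double s = t0[r];
          if (tm) s += tm[r];
          if (tp) s += tp[r];
          out[r] = s;
        }
      }
    }
  }

  inline void ps_add(int i, double dv) {
    ps[i] += dv;
    const int* row = &nb[(size_t)i * 8];
    for (int d = 0; d < 8; ++d)
      if (row[d] >= 0) ps[row[d]] += dv;
  }

  inline double fitness_at(int i) const {
    return fitness_from_sum(ps[i], p[i], par);
  }

  inline void remove_at(int i) {
    if (p[i] != 0.0) ps_add(i, -p[i]);
    occ[i] = 0;
    p[i] = 0.0;
    strain[i] = 0;
    --pop;
  }

  inline void place_at(int i, double pv, int sv) {
    occ[i] = 1;
    p[i] = pv;
    strain[i] = sv;
    if (pv != 0.0) ps_add(i, pv);
    ++pop;
  }

  void verify_ps() const {
    double worst = 0.0;
    for (int i = 0; i < N; ++i) {
      double direct = local_psum(occ.data(), p.data(), nb, i);
      double d = std::fabs(direct - ps[i]);
      if (d > worst) worst = d;
    }
    if (worst > 1e-5) stop("internal error: production-sum cache drifted");
  }
};

// Swap the full contents of two nodes (movement / shuffling).
static inline void swap_nodes(World& w, int a, int b) {
  std::swap(w.occ[a], w.occ[b]);
  std::swap(w.p[a], w.p[b]);
  std::swap(w.strain[a], w.strain[b]);
  double dp = w.p[a] - w.p[b];  // post-swap difference
  if (dp != 0.0) {
    w.ps_add(a, dp);
    w.ps_add(b, -dp);
  }
}

static void shuffle_contents(World& w, Xoshiro256& rng) {
  for (int i = w.N - 1; i > 0; --i) {
    int j = rng.below(i + 1);
    if (j == i) continue;
    std::swap(w.occ[i], w.occ[j]);
    std::swap(w.p[i], w.p[j]);
    std::swap(w.strain[i], w.strain[j]);
  }
  w.rebuild_ps();
}

// [[Rcpp::export]]
List cpp_shuffle_world(IntegerMatrix occ, NumericMatrix prod,
                       IntegerMatrix strain, List params, SEXP rng_ptr) {
  Par par = as_par(params);
  World w(occ, prod, strain, par);
  shuffle_contents(w, *get_rng(rng_ptr));
  IntegerMatrix o(w.H, w.W);
  NumericMatrix pm(w.H, w.W);
  IntegerMatrix sm(w.H, w.W);
  for (int i = 0; i < w.N; ++i) {
    o[i] = w.occ[i];
    pm[i] = w.p[i];
    sm[i] = w.strain[i];
  }
  return List::create(_["occupancy"] = o, _["production"] = pm,
                      _["strain"] = sm);
}

// ---------------------------------------------------------------------------
// Per-node update rules
// ---------------------------------------------------------------------------

// Visit an occupied node: movement test first, then a death test applied to
// whatever occupies the visited node afterwards. The two independent
// Bernoulli tests share one uniform on the common no-move path: given
// u >= k_move, (u - k_move)/(1 - k_move) is again Uniform(0,1) and
// independent of the movement outcome.
static inline void visit_occupied(World& w, int i, Xoshiro256& rng) {
  const Par& par = w.par;
  double u = rng.unif();
  if (par.kmove > 0.0 && u < par.kmove) {
    int d = rng.below(8);
    int tgt = w.nb[(size_t)i * 8 + d];
    if (tgt < 0 || w.absorbing[tgt]) {
      // stepping onto (or beyond) the boundary ring removes the individual
      w.remove_at(i);
    } else {
      swap_nodes(w, i, tgt);
    }
    if (w.occ[i] && par.kdeath > 0.0 && rng.unif() < par.kdeath)
      w.remove_at(i);
  } else if (par.kdeath > 0.0 &&
             u < par.kmove + (1.0 - par.kmove) * par.kdeath) {
    w.remove_at(i);
  }
}

// Visit an empty node: run the replication lottery among its occupied
// neighbours; the winner's offspring (possibly mutated) fills the node.
// The gather is branchless: every neighbour slot enters the lottery with
// weight fitness * occupied, and zero-weight slots can never win the
// cumulative walk, so outcomes match the filtered enumeration exactly.
static inline void visit_empty(World& w, int i, Xoshiro256& rng) {
  const Par& par = w.par;
  int who[8];
  double fs[8];
  double ftot = 0.0;
  const int* row = &w.nb[(size_t)i * 8];
  int m = 0;
  for (int d = 0; d < 8; ++d) {
    int j = row[d];
    if (j < 0) continue;  // outside a non-wrapping lattice
    double f = w.fitness_at(j) * (double)w.occ[j];
    who[m] = j;
    fs[m] = f;
    ++m;
    ftot += f;
  }
  int k = lottery_pick(m, fs, ftot, rng);
  if (k < 0) return;
  int parent = who[k];
  double child_p = w.p[parent];
  if (par.mu > 0.0 && rng.unif() < par.mu) {
    child_p += (rng.unif() - 0.5) * par.delta;
    if (child_p < 0.0) child_p = 0.0;
    if (child_p > par.pmax) child_p = par.pmax;
  }
  w.place_at(i, child_p, w.strain[parent]);
}

// ---------------------------------------------------------------------------
// The Monte-Carlo driver
// ---------------------------------------------------------------------------

// variant_mode: 0 spatial, 1 well-mixed (shuffle before every step),
//               2 mix_from_t (shuffle before steps once t >= mix_start).
// detect_col >= 0 activates arrival detection on that (0-based) column;
// detect_label >= 0 restricts detection (and extinction tracking) to one
// strain, -1 matches any occupant.
// [[Rcpp::export]]
List cpp_run(IntegerMatrix occm, NumericMatrix prodm, IntegerMatrix strainm,
             int t0, List params, int n_steps, int sample_every, int n_bins,
             int variant_mode, int mix_start, int detect_col, int detect_label,
             SEXP rng_ptr) {
  if (n_steps < 0) stop("n_steps must be >= 0");
  if (sample_every < 1) stop("sample_every must be >= 1");
  if (n_bins < 2) stop("n_bins must be >= 2");
  Par par = as_par(params);
  World w(occm, prodm, strainm, par);
  Xoshiro256& rng = *get_rng(rng_ptr);
  if (detect_col >= w.W) stop("detection column out of range");

  std::vector<int> perm(w.N);
  for (int i = 0; i < w.N; ++i) perm[i] = i;

  // trajectory rows: t, pop, mean_p, bin counts
  int ncol_traj = 3 + n_bins;
  std::vector<double> traj;
  traj.reserve((size_t)(n_steps / sample_every + 3) * ncol_traj);

  double bw = par.pmax > 0 ? par.pmax : 1.0;
  auto record = [&](int t) {
    std::vector<double> row(ncol_traj, 0.0);
    row[0] = t;
    row[1] = (double)w.pop;
    double sum = 0.0;
    for (int i = 0; i < w.N; ++i) {
      if (!w.occ[i]) continue;
      sum += w.p[i];
      int b = (int)(w.p[i] / bw * n_bins);
      if (b >= n_bins) b = n_bins - 1;
      if (b < 0) b = 0;
      row[3 + b] += 1.0;
    }
    row[2] = w.pop > 0 ? sum / w.pop : NA_REAL;
    traj.insert(traj.end(), row.begin(), row.end());
  };

  record(t0);
  int t = t0;
  bool extinct = (w.pop == 0);
  int extinction_step = extinct ? t0 : NA_INTEGER;
  int arrival_step = NA_INTEGER;
  bool invader_lost = false;

  for (int step = 0; step < n_steps; ++step) {
    if (variant_mode == 1 || (variant_mode == 2 && t >= mix_start))
      shuffle_contents(w, rng);  // rebuilds the cache
    else
      w.rebuild_ps();
    // The cache is rebuilt canonically at every step start so that the
    // draw sequence depends only on the state, not on how a run is
    // chunked: incremental updates are exact only within a step.

    // fresh uniform permutation of node visit order (reset to the identity
    // first so the realised order is a function of state and stream alone)
    for (int i = 0; i < w.N; ++i) perm[i] = i;
    for (int i = w.N - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(perm[i], perm[j]);
    }
    for (int k = 0; k < w.N; ++k) {
      int i = perm[k];
      if (w.occ[i])
        visit_occupied(w, i, rng);
      else if (!w.absorbing[i])
        visit_empty(w, i, rng);
    }
    ++t;

    bool stop_now = false;
    if (w.pop == 0) {
      if (!extinct) {
        extinct = true;
        extinction_step = t;
      }
      stop_now = true;
    }
    if (!stop_now && detect_col >= 0) {
      for (int r = 0; r < w.H; ++r) {
        int i = detect_col * w.H + r;
        if (w.occ[i] && (detect_label < 0 || w.strain[i] == detect_label)) {
          arrival_step = t;
          stop_now = true;
          break;
        }
      }
      if (!stop_now && detect_label >= 0) {
        long nlab = 0;
        for (int i = 0; i < w.N; ++i)
          if (w.occ[i] && w.strain[i] == detect_label) ++nlab;
        if (nlab == 0) {
          invader_lost = true;
          stop_now = true;
        }
      }
    }
    if (stop_now || (t - t0) % sample_every == 0 || step == n_steps - 1)
      record(t);
    if (stop_now) break;
  }

  w.verify_ps();

  int nrow_traj = traj.size() / ncol_traj;
  NumericMatrix tm(nrow_traj, ncol_traj);
  for (int r = 0; r < nrow_traj; ++r)
    for (int c = 0; c < ncol_traj; ++c) tm(r, c) = traj[(size_t)r * ncol_traj + c];

  IntegerMatrix o(w.H, w.W);
  NumericMatrix pm(w.H, w.W);
  IntegerMatrix sm(w.H, w.W);
  for (int i = 0; i < w.N; ++i) {
    o[i] = w.occ[i];
    pm[i] = w.p[i];
    sm[i] = w.strain[i];
  }

  return List::create(
      _["occupancy"] = o, _["production"] = pm, _["strain"] = sm, _["t"] = t,
      _["trajectory"] = tm, _["extinct"] = extinct,
      _["extinction_step"] = extinction_step, _["arrival_step"] = arrival_step,
      _["invader_lost"] = invader_lost, _["pop"] = (double)w.pop);
}

// ---------------------------------------------------------------------------
// Single-event wrappers used by the step-level R interface
// ---------------------------------------------------------------------------

static List world_out(World& w, List extra) {
  IntegerMatrix o(w.H, w.W);
  NumericMatrix pm(w.H, w.W);
  IntegerMatrix sm(w.H, w.W);
  for (int i = 0; i < w.N; ++i) {
    o[i] = w.occ[i];
    pm[i] = w.p[i];
    sm[i] = w.strain[i];
  }
  List out = List::create(_["occupancy"] = o, _["production"] = pm,
                          _["strain"] = sm);
  CharacterVector nm = extra.names();
  for (int i = 0; i < extra.size(); ++i) out[as<std::string>(nm[i])] = extra[i];
  return out;
}

// [[Rcpp::export]]
List cpp_apply_move(IntegerMatrix occ, NumericMatrix prod,
                    IntegerMatrix strain, List params, int row0, int col0,
                    SEXP rng_ptr) {
  int H = occ.nrow(), W = occ.ncol();
  check_site(H, W, row0, col0);
  Par par = as_par(params);
  int i = col0 * H + row0;
  if (!occ[i]) stop("site is empty");
  World w(occ, prod, strain, par);
  Xoshiro256& rng = *get_rng(rng_ptr);
  bool moved = false, removed = false;
  if (par.kmove > 0.0 && rng.unif() < par.kmove) {
    int d = rng.below(8);
    int tgt = w.nb[(size_t)i * 8 + d];
    if (tgt < 0 || w.absorbing[tgt]) {
      w.remove_at(i);
      removed = true;
    } else {
      swap_nodes(w, i, tgt);
    }
    moved = true;
  }
  return world_out(w, List::create(_["moved"] = moved, _["removed"] = removed));
}

// [[Rcpp::export]]
List cpp_apply_death(IntegerMatrix occ, NumericMatrix prod,
                     IntegerMatrix strain, List params, int row0, int col0,
                     SEXP rng_ptr) {
  int H = occ.nrow(), W = occ.ncol();
  check_site(H, W, row0, col0);
  Par par = as_par(params);
  int i = col0 * H + row0;
  if (!occ[i]) stop("site is empty");
  World w(occ, prod, strain, par);
  Xoshiro256& rng = *get_rng(rng_ptr);
  bool died = false;
  if (par.kdeath > 0.0 && rng.unif() < par.kdeath) {
    w.remove_at(i);
    died = true;
  }
  return world_out(w, List::create(_["died"] = died));
}
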