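#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cfloat>
#include <cstdint>
#include <unordered_map>
using namespace Rcpp;

// Boolean rules are compiled in R to postfix programs: flat integer vectors of
// (op, arg) pairs. op codes: 1 = push gene value (arg = 1-based gene index),
// 2 = push constant (arg = 0/1), 3 = NOT, 4 = AND, 5 = OR (arg ignored).

static inline int eval_rpn(const int* prog, int len, const int* state, int* stack) {
  int sp = 0;
  for (int t = 0; t < len; t += 2) {
    const int op = prog[t], arg = prog[t + 1];
    switch (op) {
    case 1: stack[sp++] = state[arg - 1]; break;
    case 2: stack[sp++] = arg; break;
    case 3: stack[sp - 1] = 1 - stack[sp - 1]; break;
    case 4: { int b = stack[--sp]; stack[sp - 1] = stack[sp - 1] & b; break; }
    case 5: { int b = stack[--sp]; stack[sp - 1] = stack[sp - 1] | b; break; }
    default: return NA_INTEGER;
    }
  }
  return stack[0];
}

struct Network {
  int n;
  std::vector<std::vector<int> > prog;   // one program per gene
  std::vector<int> frozen_idx;           // 1-based
  std::vector<int> frozen_val;
  int max_stack;

  Network(List prog_, IntegerVector fidx, IntegerVector fval) {
    n = prog_.size();
    max_stack = 2;
    for (int g = 0; g < n; ++g) {
      IntegerVector v = prog_[g];
      prog.push_back(std::vector<int>(v.begin(), v.end()));
      int sz = v.size() / 2 + 2;
      if (sz > max_stack) max_stack = sz;
    }
    frozen_idx.assign(fidx.begin(), fidx.end());
    frozen_val.assign(fval.begin(), fval.end());
  }

  // frozen genes are pinned: neither the rules nor the perturbation noise
  // can move them ("stuck" mutations), so flips only target free genes
  std::vector<int> free_genes() const {
    std::vector<char> froz(n, 0);
    for (size_t k = 0; k < frozen_idx.size(); ++k) froz[frozen_idx[k] - 1] = 1;
    std::vector<int> out;
    for (int j = 0; j < n; ++j) if (!froz[j]) out.push_back(j);
    return out;
  }

  // noise-free update: out = f(state)
  void apply(const int* state, int* out, int* stack) const {
    for (int g = 0; g < n; ++g)
      out[g] = eval_rpn(prog[g].data(), (int)prog[g].size(), state, stack);
    for (size_t k = 0; k < frozen_idx.size(); ++k)
      out[frozen_idx[k] - 1] = frozen_val[k];
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_eval_states(IntegerMatrix states, List prog,
                              IntegerVector frozenIdx, IntegerVector frozenVal) {
  Network net(prog, frozenIdx, frozenVal);
  const int m = states.nrow(), n = states.ncol();
  if (n != net.n) stop("state dimension mismatch: expected %d genes, got %d", net.n, n);
  IntegerMatrix out(m, n);
  std::vector<int> st(n), nx(n), stack(net.max_stack);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) st[j] = states(i, j);
    net.apply(st.data(), nx.data(), stack.data());
    for (int j = 0; j < n; ++j) out(i, j) = nx[j];
  }
  return out;
}

// Draws from the perturbed chain: one long chain from a uniform-random start,
// recording every state after burn-in. Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_chain_pool(List prog, IntegerVector frozenIdx, IntegerVector frozenVal,
                             double p, int nsteps, int burnin) {
  Network net(prog, frozenIdx, frozenVal);
  const int n = net.n;
  IntegerMatrix out(nsteps, n);
  std::vector<int> st(n), nx(n), stack(net.max_stack);
  std::vector<char> froz(n, 0);
  for (size_t k = 0; k < net.frozen_idx.size(); ++k) froz[net.frozen_idx[k] - 1] = 1;
  for (int j = 0; j < n; ++j) st[j] = (unif_rand() < 0.5) ? 1 : 0;
  for (size_t k = 0; k < net.frozen_idx.size(); ++k)
    st[net.frozen_idx[k] - 1] = net.frozen_val[k];
  for (int k = 0; k < burnin + nsteps; ++k) {
    net.apply(st.data(), nx.data(), stack.data());
    for (int j = 0; j < n; ++j) {
      st[j] = (!froz[j] && unif_rand() < p) ? 1 - nx[j] : nx[j];
      if (k >= burnin) out(k - burnin, j) = st[j];
    }
  }
  return out;
}

// Simulate m trajectories of length T from time-0 states x0 (m x n).
// X_k = f(X_{k-1}) xor Bernoulli(p); Y_k observed from X_k, k = 1..T.
// Rows of the outputs are ordered (trajectory-major): row (i-1)*T + k - 1.
// Uses R's RNG.
// [[Rcpp::export]]
List cpp_simulate_traj(IntegerMatrix x0, int T, List prog,
                       IntegerVector frozenIdx, IntegerVector frozenVal,
                       double p, NumericVector lambda, NumericVector delta,
                       double sigma, int family) {
  Network net(prog, frozenIdx, frozenVal);
  const int m = x0.nrow(), n = x0.ncol();
  if (n != net.n) stop("state dimension mismatch");
  IntegerMatrix X(m * T, n);
  NumericMatrix Y(m * T, n);
  std::vector<int> st(n), nx(n), stack(net.max_stack);
  std::vector<char> froz(n, 0);
  for (size_t kk = 0; kk < net.frozen_idx.size(); ++kk) froz[net.frozen_idx[kk] - 1] = 1;
  const double s2 = sigma * sigma;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) st[j] = x0(i, j);
    for (int k = 0; k < T; ++k) {
      net.apply(st.data(), nx.data(), stack.data());
      const int row = i * T + k;
      for (int j = 0; j < n; ++j) {
        st[j] = (!froz[j] && unif_rand() < p) ? 1 - nx[j] : nx[j];
        X(row, j) = st[j];
        const double mu = lambda[j] + delta[j] * st[j];
        if (family == 0) {
          Y(row, j) = mu + sigma * norm_rand();
        } else if (family == 1) {
          Y(row, j) = R::rpois(mu);
        } else {
          const double r = mu * mu / (s2 - mu);
          Y(row, j) = R::rnbinom(r, r / (r + mu));
        }
      }
    }
  }
  return List::create(_["x"] = X, _["y"] = Y);
}

// ---------------------------------------------------------------------------
// Particle filters. Boolean states are bit-packed into 64-bit words (gene j
// is bit j-1, matching the canonical index encoding), so network updates can
// be memoized per distinct state, propagation is an XOR with a random mask,
// and observation densities reduce to a per-step lookup over set bits. The
// packed kernels therefore support networks of up to 63 genes.
// ---------------------------------------------------------------------------

// Fast local RNG (xoshiro256++), seeded from R's RNG stream at kernel entry
// so that set.seed() still governs every draw.
struct FastRng {
  uint64_t s[4];
  FastRng() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double uniform() { return (next() >> 11) * 0x1.0p-53; }
};

// binomial sampling by CDF inversion with a precomputed table (number of
// perturbed genes per step; n is small and p is fixed within a filter run)
struct BinomTable {
  std::vector<double> cdf;
  BinomTable(int n, double p) : cdf(n + 1) {
    double q = std::pow(1.0 - p, n), c = 0.0;
    const double r = p / (1.0 - p);
    for (int k = 0; k <= n; ++k) {
      c += q;
      cdf[k] = c;
      q *= r * (double)(n - k) / (double)(k + 1);
    }
    cdf[n] = 1.0;
  }
  inline int draw(double u) const {
    int k = 0;
    const int n = (int)cdf.size() - 1;
    while (k < n && cdf[k] < u) ++k;
    return k;
  }
};

// a Bernoulli(p) flip mask over the free (non-frozen) genes: Binomial(nf, p)
// flips at a uniform random k-subset of the free positions (Floyd's
// algorithm); frozen genes are never perturbed
static inline uint64_t flip_mask(const std::vector<int>& freePos,
                                 const BinomTable& bt, FastRng& rng) {
  const int nf = (int)freePos.size();
  const int k = bt.draw(rng.uniform());
  if (k == 0) return 0;
  uint64_t chosen = 0, m = 0;
  for (int j = nf - k; j < nf; ++j) {
    int t = (int)(rng.uniform() * (j + 1));
    if (t > j) t = j;
    if ((chosen >> t) & 1) { chosen |= (1ULL << j); m |= (1ULL << freePos[j]); }
    else { chosen |= (1ULL << t); m |= (1ULL << freePos[t]); }
  }
  return m;
}

// network function on packed states, memoized per distinct state
struct PackedNet {
  const Network& net;
  std::unordered_map<uint64_t, uint64_t> memo;
  std::vector<int> in, out, stack;
  PackedNet(const Network& net_) : net(net_), in(net_.n), out(net_.n),
                                   stack(net_.max_stack) {}
  uint64_t f(uint64_t x) {
    std::unordered_map<uint64_t, uint64_t>::iterator it = memo.find(x);
    if (it != memo.end()) return it->second;
    for (int j = 0; j < net.n; ++j) in[j] = (int)((x >> j) & 1);
    net.apply(in.data(), out.data(), stack.data());
    uint64_t y = 0;
    for (int j = 0; j < net.n; ++j) y |= ((uint64_t)(out[j] & 1)) << j;
    memo.emplace(x, y);
    return y;
  }
};

// per-step observation log-density of a packed state:
// offSum + sum over set bits of diff[j], where diff[j] is the ON-vs-OFF
// log-density difference of gene j at the current observation
struct StepDensity {
  double offSum;
  std::vector<double> diff;
  void compute(const double* y, int n, const double* lambda,
               const double* delta, double sigma, int family) {
    diff.resize(n);
    offSum = 0.0;
    if (family == 0) { // gaussian
      const double c = -0.5 * std::log(2.0 * M_PI * sigma * sigma);
      const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
      for (int j = 0; j < n; ++j) {
        const double r0 = y[j] - lambda[j];
        const double r1 = r0 - delta[j];
        offSum += c - r0 * r0 * inv2s2;
        diff[j] = (r0 * r0 - r1 * r1) * inv2s2;
      }
    } else if (family == 1) { // poisson
      for (int j = 0; j < n; ++j) {
        const double l0 = R::dpois(y[j], lambda[j], 1);
        const double l1 = R::dpois(y[j], lambda[j] + delta[j], 1);
        offSum += l0;
        diff[j] = l1 - l0;
      }
    } else { // negative binomial, mean m, variance sigma^2
      const double s2 = sigma * sigma;
      for (int j = 0; j < n; ++j) {
        const double m0 = lambda[j], m1 = lambda[j] + delta[j];
        const double r0 = m0 * m0 / (s2 - m0), r1 = m1 * m1 / (s2 - m1);
        const double l0 = R::dnbinom(y[j], r0, r0 / (r0 + m0), 1);
        const double l1 = R::dnbinom(y[j], r1, r1 / (r1 + m1), 1);
        offSum += l0;
        diff[j] = l1 - l0;
      }
    }
  }
  inline double operator()(uint64_t x) const {
    double s = offSum;
    while (x) { s += diff[__builtin_ctzll(x)]; x &= x - 1; }
    return s;
  }
};

// deduplicate packed states; persistent map keeps its buckets across calls
struct StateDedup {
  std::vector<int> uid;        // per-particle unique-state id
  std::vector<uint64_t> uniq;  // distinct states
  std::unordered_map<uint64_t, int> map;
  int build(const std::vector<uint64_t>& states, int N) {
    uid.resize(N);
    uniq.clear();
    map.clear();
    if (map.bucket_count() < (size_t)(2 * N)) map.reserve(2 * N);
    for (int i = 0; i < N; ++i) {
      std::pair<std::unordered_map<uint64_t, int>::iterator, bool> ins =
        map.emplace(states[i], (int)uniq.size());
      if (ins.second) uniq.push_back(states[i]);
      uid[i] = ins.first->second;
    }
    return (int)uniq.size();
  }
};

static double log_mean_exp(const std::vector<double>& lw) {
  double mx = R_NegInf;
  for (size_t i = 0; i < lw.size(); ++i) if (lw[i] > mx) mx = lw[i];
  if (!R_FINITE(mx)) return R_NegInf;
  double s = 0.0;
  for (size_t i = 0; i < lw.size(); ++i) s += std::exp(lw[i] - mx);
  return mx + std::log(s / lw.size());
}

// reusable buffers shared across filter steps and trajectories of a batch
struct FilterWorkspace {
  StateDedup din, dprop;
  std::vector<uint64_t> umodes, newstates, scratch;
  std::vector<int> zeta;
  std::vector<double> uld, logv, cum, pld, logw;
};

// One auxiliary-particle-filter step on packed states; weights normalized to
// mean 1 on entry and exit. Returns the log-likelihood increment
// log(mean v) + log(mean w); optionally reports the normalized first-stage
// probabilities.
static double apf_step_packed(std::vector<uint64_t>& states,
                              std::vector<double>& weights,
                              PackedNet& pnet, const StepDensity& dens,
                              const std::vector<int>& freePos,
                              const BinomTable& bt, FastRng& rng,
                              FilterWorkspace& W, std::vector<double>* vprob_out,
                              int systematic) {
  const int N = (int)states.size();
  // modes and their densities, once per distinct incoming state
  const int U = W.din.build(states, N);
  W.umodes.resize(U);
  W.uld.resize(U);
  for (int u = 0; u < U; ++u) {
    W.umodes[u] = pnet.f(W.din.uniq[u]);
    W.uld[u] = dens(W.umodes[u]);
  }
  // floor weights at eps * max weight so a zero weight cannot by itself zero
  // out a first-stage probability (collapse guard)
  double wmax = 0.0;
  for (int i = 0; i < N; ++i) if (weights[i] > wmax) wmax = weights[i];
  const double wfloor = wmax * DBL_EPSILON;
  W.logv.resize(N);
  for (int i = 0; i < N; ++i) {
    const double wi = (weights[i] > wfloor) ? weights[i] : wfloor;
    W.logv[i] = W.uld[W.din.uid[i]] + std::log(wi);
  }
  double mx = R_NegInf;
  for (int i = 0; i < N; ++i) if (W.logv[i] > mx) mx = W.logv[i];
  if (!R_FINITE(mx))
    stop("particle filter collapse: all first-stage probabilities underflow");
  W.cum.resize(N);
  double vsum = 0.0;
  for (int i = 0; i < N; ++i) { vsum += std::exp(W.logv[i] - mx); W.cum[i] = vsum; }
  const double log_mean_v = mx + std::log(vsum / N);
  if (vprob_out) {
    vprob_out->resize(N);
    (*vprob_out)[0] = W.cum[0] / vsum;
    for (int i = 1; i < N; ++i) (*vprob_out)[i] = (W.cum[i] - W.cum[i - 1]) / vsum;
  }
  // ancestor indices: multinomial inverse-CDF draws by default, or
  // systematic (stratified, one uniform) resampling on request; then
  // propagation of the selected modes through the Bernoulli noise
  W.zeta.resize(N);
  W.newstates.resize(N);
  if (systematic) {
    const double u0 = rng.uniform();
    int lo = 0;
    for (int i = 0; i < N; ++i) {
      const double u = (i + u0) / N * vsum;
      while (lo < N - 1 && W.cum[lo] < u) ++lo;
      W.zeta[i] = lo;
    }
  } else {
    for (int i = 0; i < N; ++i) {
      const double u = rng.uniform() * vsum;
      int lo = 0, hi = N - 1;
      while (lo < hi) { int mid = (lo + hi) / 2; if (W.cum[mid] < u) lo = mid + 1; else hi = mid; }
      W.zeta[i] = lo;
    }
  }
  for (int i = 0; i < N; ++i)
    W.newstates[i] = W.umodes[W.din.uid[W.zeta[i]]] ^ flip_mask(freePos, bt, rng);
  // second-stage weights, densities once per distinct propagated state
  const int P = W.dprop.build(W.newstates, N);
  W.pld.resize(P);
  for (int u = 0; u < P; ++u) W.pld[u] = dens(W.dprop.uniq[u]);
  W.logw.resize(N);
  for (int i = 0; i < N; ++i)
    W.logw[i] = W.pld[W.dprop.uid[i]] - W.uld[W.din.uid[W.zeta[i]]];
  const double log_mean_w = log_mean_exp(W.logw);
  if (!R_FINITE(log_mean_w))
    stop("particle filter collapse: all second-stage weights underflow");
  states.swap(W.newstates);
  for (int i = 0; i < N; ++i) weights[i] = std::exp(W.logw[i] - log_mean_w);
  return log_mean_v + log_mean_w;
}

// One bootstrap (SIR) step: blind propagation, importance weight =
// observation density, increment = log(mean weight), multinomial resampling
// back to uniform weights.
static double sir_step_packed(std::vector<uint64_t>& states, PackedNet& pnet,
                              const StepDensity& dens,
                              const std::vector<int>& freePos,
                              const BinomTable& bt, FastRng& rng,
                              FilterWorkspace& W) {
  const int N = (int)states.size();
  const int U = W.din.build(states, N);
  W.umodes.resize(U);
  for (int u = 0; u < U; ++u) W.umodes[u] = pnet.f(W.din.uniq[u]);
  W.newstates.resize(N);
  for (int i = 0; i < N; ++i)
    W.newstates[i] = W.umodes[W.din.uid[i]] ^ flip_mask(freePos, bt, rng);
  const int P = W.dprop.build(W.newstates, N);
  W.pld.resize(P);
  for (int u = 0; u < P; ++u) W.pld[u] = dens(W.dprop.uniq[u]);
  W.logw.resize(N);
  for (int i = 0; i < N; ++i) W.logw[i] = W.pld[W.dprop.uid[i]];
  const double inc = log_mean_exp(W.logw);
  if (!R_FINITE(inc))
    stop("particle filter collapse: all SIR weights underflow");
  double mx = R_NegInf;
  for (int i = 0; i < N; ++i) if (W.logw[i] > mx) mx = W.logw[i];
  W.cum.resize(N);
  double s = 0.0;
  for (int i = 0; i < N; ++i) { s += std::exp(W.logw[i] - mx); W.cum[i] = s; }
  W.scratch.resize(N);
  for (int i = 0; i < N; ++i) {
    const double u = rng.uniform() * s;
    int lo = 0, hi = N - 1;
    while (lo < hi) { int mid = (lo + hi) / 2; if (W.cum[mid] < u) lo = mid + 1; else hi = mid; }
    W.scratch[i] = W.newstates[lo];
  }
  states.swap(W.scratch);
  return inc;
}

static std::vector<uint64_t> pack_states(IntegerMatrix m) {
  const int N = m.nrow(), n = m.ncol();
  if (n > 63) stop("the packed particle kernels support up to 63 genes");
  std::vector<uint64_t> out(N);
  for (int i = 0; i < N; ++i) {
    uint64_t x = 0;
    for (int j = 0; j < n; ++j) x |= ((uint64_t)(m(i, j) & 1)) << j;
    out[i] = x;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_apf_step(IntegerMatrix states, NumericVector weights, List prog,
                  IntegerVector frozenIdx, IntegerVector frozenVal,
                  double p, NumericVector lambda, NumericVector delta,
                  double sigma, int family, NumericVector y, int systematic) {
  Network net(prog, frozenIdx, frozenVal);
  const int N = states.nrow(), n = states.ncol();
  if (n != net.n) stop("state dimension mismatch");
  std::vector<uint64_t> st = pack_states(states);
  double wsum = 0.0;
  for (int i = 0; i < N; ++i) wsum += weights[i];
  if (wsum <= 0) stop("invalid particle weights");
  std::vector<double> w(N);
  for (int i = 0; i < N; ++i) w[i] = weights[i] * N / wsum;
  FastRng rng;
  const std::vector<int> freePos = net.free_genes();
  BinomTable bt((int)freePos.size(), p);
  PackedNet pnet(net);
  StepDensity dens;
  dens.compute(y.begin(), n, lambda.begin(), delta.begin(), sigma, family);
  FilterWorkspace W;
  std::vector<double> vprob;
  const double inc = apf_step_packed(st, w, pnet, dens, freePos, bt, rng, W,
                                     &vprob, systematic);
  IntegerMatrix outS(N, n);
  NumericVector outW(N), outV(N);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < n; ++j) outS(i, j) = (int)((st[i] >> j) & 1);
    outW[i] = w[i];
    outV[i] = vprob[i];
  }
  return List::create(_["states"] = outS, _["weights"] = outW,
                      _["auxProbs"] = outV, _["logIncrement"] = inc);
}

// [[Rcpp::export]]
NumericVector cpp_apf_loglik_batch(List trajs, IntegerMatrix init, List prog,
                                   IntegerVector frozenIdx, IntegerVector frozenVal,
                                   double p, NumericVector lambda, NumericVector delta,
                                   double sigma, int family, int systematic) {
  Network net(prog, frozenIdx, frozenVal);
  const int N = init.nrow(), n = init.ncol();
  if (n != net.n) stop("state dimension mismatch");
  const std::vector<uint64_t> init_packed = pack_states(init);
  const int B = trajs.size();
  NumericVector out(B);
  FastRng rng;
  const std::vector<int> freePos = net.free_genes();
  BinomTable bt((int)freePos.size(), p);
  PackedNet pnet(net);
  StepDensity dens;
  FilterWorkspace W;
  std::vector<uint64_t> st;
  std::vector<double> w, yk(n);
  for (int b = 0; b < B; ++b) {
    NumericMatrix Y = trajs[b];
    if (Y.ncol() != n) stop("trajectory %d has %d genes, model has %d", b + 1, Y.ncol(), n);
    st = init_packed;
    w.assign(N, 1.0);
    double ll = 0.0;
    for (int k = 0; k < Y.nrow(); ++k) {
      for (int j = 0; j < n; ++j) yk[j] = Y(k, j);
      dens.compute(yk.data(), n, lambda.begin(), delta.begin(), sigma, family);
      ll += apf_step_packed(st, w, pnet, dens, freePos, bt, rng, W,
                            (std::vector<double>*)0, systematic);
    }
    out[b] = ll;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sir_loglik_batch(List trajs, IntegerMatrix init, List prog,
                                   IntegerVector frozenIdx, IntegerVector frozenVal,
                                   double p, NumericVector lambda, NumericVector delta,
                                   double sigma, int family) {
  Network net(prog, frozenIdx, frozenVal);
  const int N = init.nrow(), n = init.ncol();
  if (n != net.n) stop("state dimension mismatch");
  const std::vector<uint64_t> init_packed = pack_states(init);
  const int B = trajs.size();
  NumericVector out(B);
  FastRng rng;
  const std::vector<int> freePos = net.free_genes();
  BinomTable bt((int)freePos.size(), p);
  PackedNet pnet(net);
  StepDensity dens;
  FilterWorkspace W;
  std::vector<uint64_t> st;
  std::vector<double> yk(n);
  for (int b = 0; b < B; ++b) {
    NumericMatrix Y = trajs[b];
    if (Y.ncol() != n) stop("trajectory gene count mismatch");
    st = init_packed;
    double ll = 0.0;
    for (int k = 0; k < Y.nrow(); ++k) {
      for (int j = 0; j < n; ++j) yk[j] = Y(k, j);
      dens.compute(yk.data(), n, lambda.begin(), delta.begin(), sigma, family);
      ll += sir_step_packed(st, pnet, dens, freePos, bt, rng, W);
    }
    out[b] = ll;
  }
  return out;
}
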