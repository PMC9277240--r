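// Exact stochastic simulation of mass-action reaction networks:
// Gillespie direct method, and Extrande thinning for signal-modulated
// propensities. States are nonnegative integer vectors; reactions may
// carry geometric bursts (jump size drawn per firing) and complement
// factors (1 - x) on 0/1 promoter-state species.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

// splitmix64: used both as a seed mixer (per-cell child streams) and as
// the core generator; passes BigCrush and is bit-reproducible everywhere.
inline uint64_t splitmix64_next(uint64_t &state) {
  state += 0x9E3779B97F4A7C15ULL;
  uint64_t z = state;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed) {}
  // uniform on (0, 1): 53-bit mantissa, zero excluded
  double unif() {
    uint64_t bits = splitmix64_next(state) >> 11;
    double u = (static_cast<double>(bits) + 0.5) * (1.0 / 9007199254740992.0);
    return u;
  }
  double expo(double rate) { return -std::log(unif()) / rate; }
  // geometric burst on {0,1,...} with mean b: P(k) = b^k / (1+b)^(k+1)
  int geom_burst(double b) {
    if (b <= 0.0) return 0;
    double logq = std::log(b / (1.0 + b));
    double k = std::floor(std::log(unif()) / logq);
    if (k > 2147483000.0) k = 2147483000.0;
    return static_cast<int>(k);
  }
};

inline uint64_t child_seed(uint64_t master, uint64_t idx) {
  uint64_t s = master ^ (0xD1342543DE82EF95ULL * (idx + 1));
  return splitmix64_next(s);
}

// falling factorial x(x-1)...(x-k+1)
inline double ffact(int x, int k) {
  double out = 1.0;
  for (int i = 0; i < k; ++i) {
    if (x - i <= 0) return 0.0;
    out *= static_cast<double>(x - i);
  }
  return out;
}

struct Net {
  IntegerMatrix change;      // R x S
  IntegerMatrix orders;      // R x S
  IntegerMatrix comp;        // R x S, complement orders on 0/1 species
  NumericVector rates;       // R
  IntegerVector burstTarget; // R, 0-based species index or -1
  NumericVector burstMean;   // R
  LogicalVector modulated;   // R
  int nr, ns;
  // sparse propensity terms: per reaction, the (species, order) and
  // complement-species entries actually present (the matrices are sparse)
  std::vector<std::vector<std::pair<int, int>>> terms;
  std::vector<std::vector<int>> compIdx;
};

// base propensity (everything except the signal factor)
inline double base_propensity(const Net &net, int r, const std::vector<int> &x) {
  double a = net.rates[r];
  if (a == 0.0) return 0.0;
  for (const auto &t : net.terms[r]) {
    a *= (t.second == 1) ? static_cast<double>(x[t.first])
                         : ffact(x[t.first], t.second);
    if (a == 0.0) return 0.0;
  }
  for (int s : net.compIdx[r])
    if (x[s] != 0) return 0.0;
  return a;
}

inline void apply_reaction(const Net &net, int r, std::vector<int> &x, Rng &rng) {
  for (int s = 0; s < net.ns; ++s) x[s] += net.change(r, s);
  int tgt = net.burstTarget[r];
  if (tgt >= 0) x[tgt] += rng.geom_burst(net.burstMean[r]);
}

struct Signal {
  NumericVector times, values;
  int interp; // 0 = previous, 1 = linear
  double upper;
  bool present;
  double at(double t) const {
    int n = times.size();
    if (t <= times[0]) return values[0];
    if (t >= times[n - 1]) return values[n - 1];
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (times[mid] <= t) lo = mid; else hi = mid;
    }
    if (interp == 0) return values[lo];
    double w = (t - times[lo]) / (times[hi] - times[lo]);
    return values[lo] * (1.0 - w) + values[hi] * w;
  }
};

Net make_net(IntegerMatrix change, IntegerMatrix orders, IntegerMatrix comp,
             NumericVector rates, IntegerVector burstTarget,
             NumericVector burstMean, LogicalVector modulated) {
  Net net{change, orders, comp, rates, burstTarget, burstMean, modulated,
          static_cast<int>(change.nrow()), static_cast<int>(change.ncol()),
          {}, {}};
  net.terms.resize(net.nr);
  net.compIdx.resize(net.nr);
  for (int r = 0; r < net.nr; ++r)
    for (int s = 0; s < net.ns; ++s) {
      if (orders(r, s) > 0) net.terms[r].emplace_back(s, orders(r, s));
      if (comp(r, s) > 0) net.compIdx[r].push_back(s);
    }
  return net;
}

// one trajectory, recording the state just before each observation time
// (left-limit convention at exact ties). Writes into out[cell, t, s].
void run_cell(const Net &net, const Signal &sig, const std::vector<int> &init,
              const NumericVector &obsTimes, Rng &rng, double maxEvents,
              IntegerVector &out, int cell, int nCells) {
  const int T = obsTimes.size();
  std::vector<int> x = init;
  std::vector<double> a(net.nr);
  double t = 0.0;
  int obsIdx = 0;
  double events = 0.0;
  const double tEnd = obsTimes[T - 1];

  auto record_upto = [&](double tNext) {
    while (obsIdx < T && obsTimes[obsIdx] <= tNext) {
      for (int s = 0; s < net.ns; ++s)
        out[cell + nCells * (obsIdx + T * s)] = x[s];
      ++obsIdx;
    }
  };

  while (obsIdx < T) {
    double B = 0.0; // total rate bound (exact total when no signal)
    for (int r = 0; r < net.nr; ++r) {
      a[r] = base_propensity(net, r, x);
      if (net.modulated[r] && sig.present) a[r] *= sig.upper;
      B += a[r];
    }
    if (!std::isfinite(B) || B > 1e12)
      stop("propensity overflow (total rate %g at t=%g)", B, t);
    if (B <= 0.0) { record_upto(tEnd); break; }
    double tNext = t + rng.expo(B);
    record_upto(tNext);
    if (obsIdx >= T) break;
    if (sig.present) {
      // thinning: accept with probability (actual total)/(bound)
      double f = sig.at(tNext);
      double atot = 0.0;
      for (int r = 0; r < net.nr; ++r) {
        if (net.modulated[r]) {
          if (f > sig.upper * (1.0 + 1e-12))
            stop("signal exceeds its declared upper bound at t=%g", tNext);
          a[r] = a[r] / sig.upper * f;
        }
        atot += a[r];
      }
      double u = rng.unif() * B;
      if (u < atot) {
        double cum = 0.0;
        int pick = net.nr - 1;
        for (int r = 0; r < net.nr; ++r) {
          cum += a[r];
          if (u <= cum) { pick = r; break; }
        }
        apply_reaction(net, pick, x, rng);
      }
    } else {
      double u = rng.unif() * B;
      double cum = 0.0;
      int pick = net.nr - 1;
      for (int r = 0; r < net.nr; ++r) {
        cum += a[r];
        if (u <= cum) { pick = r; break; }
      }
      apply_reaction(net, pick, x, rng);
    }
    t = tNext;
    events += 1.0;
    if (events > maxEvents)
      stop("event cap exceeded (%g events before t=%g of %g); "
           "check rates/units", maxEvents, t, tEnd);
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_simulate_dataset")]]
IntegerVector cpp_simulate_dataset(IntegerMatrix change, IntegerMatrix orders,
                                   IntegerMatrix comp, NumericVector rates,
                                   IntegerVector burstTarget,
                                   NumericVector burstMean,
                                   LogicalVector modulated,
                                   IntegerVector init, NumericVector obsTimes,
                                   int nCells, double masterSeed,
                                   double maxEvents,
                                   Nullable<List> signal = R_NilValue) {
  Net net = make_net(change, orders, comp, rates, burstTarget, burstMean,
                     modulated);
  Signal sig;
  sig.present = signal.isNotNull();
  if (sig.present) {
    List sl(signal);
    sig.times = sl["times"];
    sig.values = sl["values"];
    sig.interp = as<int>(sl["interp"]);
    sig.upper = as<double>(sl["upper"]);
  }
  const int T = obsTimes.size();
  std::vector<int> x0(init.begin(), init.end());
  IntegerVector out(nCells * T * net.ns);
  out.attr("dim") = IntegerVector::create(nCells, T, net.ns);
  uint64_t master = static_cast<uint64_t>(masterSeed);
  for (int c = 0; c < nCells; ++c) {
    Rng rng(child_seed(master, static_cast<uint64_t>(c)));
    run_cell(net, sig, x0, obsTimes, rng, maxEvents, out, c, nCells);
  }
  return out;
}
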