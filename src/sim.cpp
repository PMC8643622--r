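// Brownian-dynamics / photon-emission core for the PIE-FCCS simulator.
//
// Units inside this file: lengths in um, times in s, rates in 1/s,
// brightnesses in counts/s.  All unit conversion happens on the R side.
//
// Randomness: a self-contained xoshiro256++ generator seeded through
// splitmix64, so that streams are fully reproducible from a single integer
// seed independently of R's RNG state, and cheap enough for ~1e9 draws.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s[4];
  bool have_norm;
  double cached_norm;

  explicit Rng(uint64_t seed) : have_norm(false), cached_norm(0.0) {
    // splitmix64 expansion of the seed into the xoshiro state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1); never exactly 0 so logs are safe
  inline double u01() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }

  inline double norm() {
    if (have_norm) {
      have_norm = false;
      return cached_norm;
    }
    double u1 = u01(), u2 = u01();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    cached_norm = r * std::sin(a);
    have_norm = true;
    return r * std::cos(a);
  }

  // Knuth sampler; mu is < ~1 in all hot paths here
  inline int pois(double mu) {
    if (mu <= 0.0) return 0;
    if (mu > 30.0) {
      // split to keep the product method numerically safe
      int k = pois(mu * 0.5);
      return k + pois(mu - mu * 0.5);
    }
    double L = std::exp(-mu);
    int k = 0;
    double p = 1.0;
    do {
      ++k;
      p *= u01();
    } while (p > L);
    return k - 1;
  }
};

inline double wrap(double x, double half, double len) {
  while (x >= half) x -= len;
  while (x < -half) x += len;
  return x;
}

// Gaussian detection weight exp(-2 r^2/w^2 - 2 z^2/(kappa w)^2), with a
// cutoff on the exponent so distant molecules cost one comparison only.
struct Psf {
  double inv_w2;   // 2 / w^2
  double inv_wz2;  // 2 / (kappa w)^2
  double qmax;
  Psf(double w, double kappa) {
    inv_w2 = 2.0 / (w * w);
    inv_wz2 = 2.0 / (kappa * w * kappa * w);
    qmax = 14.0;  // exp(-14) ~ 8e-7: below any per-step photon probability
  }
  inline double weight(double x, double y, double z) const {
    double q = (x * x + y * y) * inv_w2 + z * z * inv_wz2;
    return (q < qmax) ? std::exp(-q) : 0.0;
  }
};

// two-state telegraph update: state 0/1, rates r01 (0->1), r10 (1->0)
struct Telegraph {
  double p01, p10, occ1;
  Telegraph(double r01, double r10, double dt) {
    p01 = (r01 > 0.0) ? -std::expm1(-r01 * dt) : 0.0;
    p10 = (r10 > 0.0) ? -std::expm1(-r10 * dt) : 0.0;
    double tot = r01 + r10;
    occ1 = (tot > 0.0) ? r01 / tot : (r01 > 0.0 ? 1.0 : 0.0);
  }
  inline int init(Rng &rng) const { return (rng.u01() < occ1) ? 1 : 0; }
  inline int step(int s, Rng &rng) const {
    if (s == 1) {
      if (p10 > 0.0 && rng.u01() < p10) return 0;
      return 1;
    }
    if (p01 > 0.0 && rng.u01() < p01) return 1;
    return 0;
  }
};

}  // namespace

// [[Rcpp::export(name = ".sim_states_cpp")]]
IntegerMatrix sim_states_cpp(int n_molecules, int n_steps, double k_on_s,
                             double k_off_s, double dt_s, double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  Telegraph kin(k_on_s, k_off_s, dt_s);  // state 1 = bound
  IntegerMatrix out(n_steps, n_molecules);
  for (int j = 0; j < n_molecules; ++j) {
    int s = kin.init(rng);
    for (int i = 0; i < n_steps; ++i) {
      s = kin.step(s, rng);
      out(i, j) = s;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".sim_diffusion_cpp")]]
NumericVector sim_diffusion_cpp(int n_molecules, int n_steps, double D_um2s,
                                double dt_s, double box_um, double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  double sd = std::sqrt(2.0 * D_um2s * dt_s);
  double half = box_um / 2.0;
  NumericVector out(Dimension(n_steps, 3, n_molecules));
  for (int j = 0; j < n_molecules; ++j) {
    double x = (rng.u01() - 0.5) * box_um;
    double y = (rng.u01() - 0.5) * box_um;
    double z = (rng.u01() - 0.5) * box_um;
    double *base = REAL(out) + static_cast<size_t>(j) * n_steps * 3;
    for (int i = 0; i < n_steps; ++i) {
      x = wrap(x + sd * rng.norm(), half, box_um);
      y = wrap(y + sd * rng.norm(), half, box_um);
      z = wrap(z + sd * rng.norm(), half, box_um);
      base[i] = x;
      base[i + n_steps] = y;
      base[i + 2 * n_steps] = z;
    }
  }
  return out;
}

// Species codes used below: 0 = green-only, 1 = red-only, 2 = dual-labelled.
//
// Emission rules (per molecule, per step, detection weight wgt):
//   green-only : donor detector, green gate, rate qG * wgt
//   red-only   : acceptor detector, red gate, rate qR * wgt
//   dual       : donor-excited emission split by the current FRET efficiency
//                E(t): donor detector (1-E)*qG*wgt, acceptor detector (FRET)
//                E*qG*wgt, both in the green gate; acceptor detector, red
//                gate, qR * wgt.  E(t) = E1 while bound, E2 while unbound.
// Optional donor->acceptor spectral crosstalk and direct green excitation of
// the acceptor are applied when nonzero (both default 0 upstream).
//
// The dual/free identity of each red-pool molecule is itself a slow telegraph
// ("engagement", occupancy occ_dual, correlation time tau_ex) so that the
// time average of the dual-labelled population matches its configured
// concentration without small-number quantisation.

struct SimParams {
  double duration, dt, bin;
  double box, waist, kappa;
  int n_g, n_red;
  double D_g, D_r, D_gr;
  double k_on_s, k_off_s, occ_bound;
  double occ_dual, tau_ex;
  double E1, E2;
  double qG, qR, bgD, bgA;
  double trip_frac, trip_tau;
  double crosstalk, direct_exc;
  int pos_stride;  // position updates every pos_stride steps (weight cached)
};

static SimParams unpack(const List &p) {
  SimParams sp;
  sp.duration = as<double>(p["duration_s"]);
  sp.dt = as<double>(p["dt_s"]);
  sp.bin = as<double>(p["bin_s"]);
  sp.box = as<double>(p["box_um"]);
  sp.waist = as<double>(p["waist_um"]);
  sp.kappa = as<double>(p["kappa"]);
  sp.n_g = as<int>(p["n_green"]);
  sp.n_red = as<int>(p["n_red"]);
  sp.D_g = as<double>(p["D_g"]);
  sp.D_r = as<double>(p["D_r"]);
  sp.D_gr = as<double>(p["D_gr"]);
  sp.k_on_s = as<double>(p["k_on_s"]);
  sp.k_off_s = as<double>(p["k_off_s"]);
  sp.occ_bound = as<double>(p["occ_bound"]);
  sp.occ_dual = as<double>(p["occ_dual"]);
  sp.tau_ex = as<double>(p["tau_ex_s"]);
  sp.E1 = as<double>(p["E1"]);
  sp.E2 = as<double>(p["E2"]);
  sp.qG = as<double>(p["brightness_g_cps"]);
  sp.qR = as<double>(p["brightness_r_cps"]);
  sp.bgD = as<double>(p["background_d_cps"]);
  sp.bgA = as<double>(p["background_a_cps"]);
  sp.trip_frac = as<double>(p["triplet_frac"]);
  sp.trip_tau = as<double>(p["triplet_tau_s"]);
  sp.crosstalk = as<double>(p["crosstalk"]);
  sp.direct_exc = as<double>(p["direct_exc_cps"]);
  sp.pos_stride = p.containsElementNamed("pos_stride") ? as<int>(p["pos_stride"]) : 1;
  if (sp.pos_stride < 1) sp.pos_stride = 1;
  return sp;
}

// Shared engine: accumulates binned counts, and optionally also emits photon
// records (detector + absolute time) when `photons` is true.
static List sim_engine(const List &params, double seed, bool photons) {
  SimParams sp = unpack(params);
  Rng rng(static_cast<uint64_t>(seed));
  Psf psf(sp.waist, sp.kappa);

  const int bps = static_cast<int>(std::lround(sp.dt / sp.bin));
  const long n_steps = std::lround(sp.duration / sp.dt);
  const long n_bins = n_steps * bps;
  const double half = sp.box / 2.0;

  IntegerVector DexDem(n_bins), DexAem(n_bins), AexAem(n_bins), AexDem(n_bins);
  int *dd = INTEGER(DexDem), *da = INTEGER(DexAem);
  int *aa = INTEGER(AexAem), *ad = INTEGER(AexDem);

  std::vector<double> ph_time;
  std::vector<int> ph_det;   // 0 donor, 1 acceptor
  std::vector<int> ph_gate;  // 0 green-excited, 1 red-excited, 2 background

  Telegraph kin(sp.k_on_s, sp.k_off_s, sp.dt);  // bound/unbound
  double ex_rate = (sp.tau_ex > 0.0) ? 1.0 / sp.tau_ex : 0.0;
  Telegraph eng(ex_rate * sp.occ_dual, ex_rate * (1.0 - sp.occ_dual), sp.dt);
  bool triplet = sp.trip_frac > 0.0;
  Telegraph trp(triplet ? sp.trip_frac / sp.trip_tau : 0.0,
                triplet ? (1.0 - sp.trip_frac) / sp.trip_tau : 0.0, sp.dt);
  // trp state 1 = dark

  // positions advance every pos_stride steps with correspondingly larger
  // rms displacement; the cached detection weight is reused in between
  const int stride = sp.pos_stride;
  const double dtp = sp.dt * stride;
  double sd_g = std::sqrt(2.0 * sp.D_g * dtp);
  double sd_r = std::sqrt(2.0 * sp.D_r * dtp);
  double sd_gr = std::sqrt(2.0 * sp.D_gr * dtp);

  const int n_tot = sp.n_g + sp.n_red;

  auto emit = [&](double mu, int *chan, long step, int det, int gate) {
    int n = rng.pois(mu);
    for (int k = 0; k < n; ++k) {
      double frac = rng.u01();
      long b = step * bps + static_cast<long>(frac * bps);
      if (b >= n_bins) b = n_bins - 1;
      chan[b]++;
      if (photons) {
        ph_time.push_back((step + frac) * sp.dt);
        ph_det.push_back(det);
        ph_gate.push_back(gate);
      }
    }
  };

  for (int j = 0; j < n_tot; ++j) {
    bool is_green = j < sp.n_g;
    double sd0 = is_green ? sd_g : sd_r;
    double x = (rng.u01() - 0.5) * sp.box;
    double y = (rng.u01() - 0.5) * sp.box;
    double z = (rng.u01() - 0.5) * sp.box;
    int bound = (rng.u01() < sp.occ_bound) ? 1 : 0;
    int engaged = is_green ? 0 : ((sp.occ_dual >= 1.0) ? 1
                    : (sp.occ_dual <= 0.0) ? 0 : eng.init(rng));
    int dark_d = triplet ? trp.init(rng) : 0;
    int dark_a = triplet ? trp.init(rng) : 0;

    double wgt = 0.0;
    for (long i = 0; i < n_steps; ++i) {
      if (i % stride == 0) {
        double sd = is_green ? sd0 : (engaged ? sd_gr : sd_r);
        x = wrap(x + sd * rng.norm(), half, sp.box);
        y = wrap(y + sd * rng.norm(), half, sp.box);
        z = wrap(z + sd * rng.norm(), half, sp.box);
        wgt = psf.weight(x, y, z);
        // a quiescent green molecule far from the focus can fast-forward
        // through the whole stride
        if (is_green && !triplet && wgt <= 0.0) {
          i += stride - 1;
          continue;
        }
      }

      if (!is_green) {
        if (sp.occ_dual > 0.0 && sp.occ_dual < 1.0 && ex_rate > 0.0)
          engaged = eng.step(engaged, rng);
        if (engaged) bound = kin.step(bound, rng);
      }
      if (triplet) {
        dark_d = trp.step(dark_d, rng);
        dark_a = trp.step(dark_a, rng);
      }

      if (wgt <= 0.0) continue;

      if (is_green) {
        if (!dark_d) {
          double mu = sp.qG * wgt * sp.dt;
          if (sp.crosstalk > 0.0) {
            emit(mu * (1.0 - sp.crosstalk), dd, i, 0, 0);
            emit(mu * sp.crosstalk, da, i, 1, 0);
          } else {
            emit(mu, dd, i, 0, 0);
          }
        }
      } else {
        if (engaged && !dark_d) {
          double E = bound ? sp.E1 : sp.E2;
          if (dark_a) E = 0.0;  // dark acceptor cannot accept transfer
          double muG = sp.qG * wgt * sp.dt;
          double mu_don = muG * (1.0 - E);
          if (sp.crosstalk > 0.0) {
            emit(mu_don * (1.0 - sp.crosstalk), dd, i, 0, 0);
            emit(mu_don * sp.crosstalk + muG * E, da, i, 1, 0);
          } else {
            emit(mu_don, dd, i, 0, 0);
            if (E > 0.0) emit(muG * E, da, i, 1, 0);
          }
        }
        if (!dark_a) {
          emit(sp.qR * wgt * sp.dt, aa, i, 1, 1);
          if (sp.direct_exc > 0.0 && (!engaged || !dark_d))
            emit(sp.direct_exc * wgt * sp.dt, da, i, 1, 0);
        }
      }
    }
  }

  // detector background: homogeneous Poisson, split evenly across gates
  if (sp.bgD > 0.0 || sp.bgA > 0.0) {
    double muD = sp.bgD * sp.bin, muA = sp.bgA * sp.bin;
    for (long b = 0; b < n_bins; ++b) {
      if (muD > 0.0) {
        int n = rng.pois(muD);
        for (int k = 0; k < n; ++k) {
          if (rng.u01() < 0.5) dd[b]++; else ad[b]++;
          if (photons) {
            ph_time.push_back((b + rng.u01()) * sp.bin);
            ph_det.push_back(0);
            ph_gate.push_back(2);
          }
        }
      }
      if (muA > 0.0) {
        int n = rng.pois(muA);
        for (int k = 0; k < n; ++k) {
          if (rng.u01() < 0.5) da[b]++; else aa[b]++;
          if (photons) {
            ph_time.push_back((b + rng.u01()) * sp.bin);
            ph_det.push_back(1);
            ph_gate.push_back(2);
          }
        }
      }
    }
  }

  List out = List::create(
      _["DexDem"] = DexDem, _["DexAem"] = DexAem, _["AexAem"] = AexAem,
      _["AexDem"] = AexDem, _["n_bins"] = static_cast<double>(n_bins));
  if (photons) {
    out["photon_time"] = wrap(ph_time);
    out["photon_det"] = wrap(ph_det);
    out["photon_gate"] = wrap(ph_gate);
  }
  return out;
}

// [[Rcpp::export(name = ".sim_traces_cpp")]]
List sim_traces_cpp(List params, double seed) {
  return sim_engine(params, seed, false);
}

// [[Rcpp::export(name = ".sim_photons_cpp")]]
List sim_photons_cpp(List params, double seed) {
  return sim_engine(params, seed, true);
}

// Photon emission from externally supplied state/position paths (the
// small-scale, fully inspectable path used by unit tests).
// positions: n_steps x 3 x n_molecules; states: n_steps x n_molecules
// species: length n_molecules, codes 0/1/2 as above.
// [[Rcpp::export(name = ".emit_photons_cpp")]]
List emit_photons_cpp(NumericVector positions, IntegerMatrix states,
                      IntegerVector species, List params, double seed) {
  SimParams sp = unpack(params);
  Rng rng(static_cast<uint64_t>(seed));
  Psf psf(sp.waist, sp.kappa);
  IntegerVector dims = positions.attr("dim");
  int n_steps = dims[0], n_mol = dims[2];

  std::vector<double> ph_time;
  std::vector<int> ph_det, ph_gate;
  const double *pos = REAL(positions);

  for (int j = 0; j < n_mol; ++j) {
    int code = species[j];
    const double *base = pos + static_cast<size_t>(j) * n_steps * 3;
    for (int i = 0; i < n_steps; ++i) {
      double wgt = psf.weight(base[i], base[i + n_steps], base[i + 2 * n_steps]);
      if (wgt <= 0.0) continue;
      auto emit = [&](double mu, int det, int gate) {
        int n = rng.pois(mu);
        for (int k = 0; k < n; ++k) {
          ph_time.push_back((i + rng.u01()) * sp.dt);
          ph_det.push_back(det);
          ph_gate.push_back(gate);
        }
      };
      if (code == 0) {
        emit(sp.qG * wgt * sp.dt, 0, 0);
      } else if (code == 1) {
        emit(sp.qR * wgt * sp.dt, 1, 1);
      } else {
        double E = states(i, j) ? sp.E1 : sp.E2;
        double muG = sp.qG * wgt * sp.dt;
        emit(muG * (1.0 - E), 0, 0);
        if (E > 0.0) emit(muG * E, 1, 0);
        emit(sp.qR * wgt * sp.dt, 1, 1);
      }
    }
  }
  double T = n_steps * sp.dt;
  if (sp.bgD > 0.0) {
    int n = rng.pois(sp.bgD * T);
    for (int k = 0; k < n; ++k) {
      ph_time.push_back(rng.u01() * T);
      ph_det.push_back(0);
      ph_gate.push_back(2);
    }
  }
  if (sp.bgA > 0.0) {
    int n = rng.pois(sp.bgA * T);
    for (int k = 0; k < n; ++k) {
      ph_time.push_back(rng.u01() * T);
      ph_det.push_back(1);
      ph_gate.push_back(2);
    }
  }
  return List::create(_["photon_time"] = wrap(ph_time),
                      _["photon_det"] = wrap(ph_det),
                      _["photon_gate"] = wrap(ph_gate));
}
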