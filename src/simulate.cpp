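// Brownian-dynamics core for confined bead-spring chains with transient
// crosslinking of nucleolar beads. Overdamped Euler-Maruyama integration,
// wormlike-chain (Marko-Siggia) springs, soft excluded-volume repulsion,
// spherical confinement with hard projection, and a two-state (active /
// inactive) crosslink kinetics model with greedy proximity matching.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding; normal deviates via the polar
// method with a cached spare. Much faster than std::normal_distribution
// and fully deterministic from the seed.
struct FastRng {
  uint64_t s[4];
  double spare;
  bool has_spare;
  void seed(uint64_t x) {
    has_spare = false; spare = 0.0;
    for (int i = 0; i < 4; ++i) {            // splitmix64
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {            // uniform in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

struct Pars {
  double mu, on_mean, on_sd, off_mean, off_sd;
  double d_link, R;
  double dt, kT, drag, L0, Lp, link_L0, link_Lp, max_ext;
  double rep_radius, rep_strength, wall_strength;
};

Pars read_pars(const List& p) {
  Pars q;
  q.mu = as<double>(p["mu"]);
  q.on_mean = as<double>(p["on_mean"]);
  q.on_sd = as<double>(p["on_sd"]);
  q.off_mean = as<double>(p["off_mean"]);
  q.off_sd = as<double>(p["off_sd"]);
  q.d_link = as<double>(p["d_link"]);
  q.R = as<double>(p["nucleus_radius"]);
  q.dt = as<double>(p["dt"]);
  q.kT = as<double>(p["kT"]);
  q.drag = as<double>(p["drag"]);
  q.L0 = as<double>(p["contour_length"]);
  q.Lp = as<double>(p["persistence_scale"]);
  q.link_L0 = as<double>(p["link_contour_length"]);
  q.link_Lp = as<double>(p["link_persistence_scale"]);
  q.max_ext = as<double>(p["max_extension"]);
  q.rep_radius = as<double>(p["repulsion_radius"]);
  q.rep_strength = as<double>(p["repulsion_strength"]);
  q.wall_strength = as<double>(p["wall_strength"]);
  return q;
}

// Marko-Siggia interpolation force magnitude (attractive, pulls the pair
// together); extension ratio capped at max_ext so the force stays finite.
inline double wlc_force(double r, double L0, double Lp, const Pars& p) {
  double u = r / L0;
  if (u > p.max_ext) u = p.max_ext;
  double omu = 1.0 - u;
  return (p.kT / Lp) * (0.25 / (omu * omu) - 0.25 + u);
}

inline void add_pair_force(std::vector<double>& fx, std::vector<double>& fy,
                           std::vector<double>& fz, const std::vector<double>& x,
                           const std::vector<double>& y, const std::vector<double>& z,
                           int i, int j, double fmag_over_r) {
  // positive fmag_over_r pushes apart, negative pulls together
  double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
  fx[i] += fmag_over_r * dx; fy[i] += fmag_over_r * dy; fz[i] += fmag_over_r * dz;
  fx[j] -= fmag_over_r * dx; fy[j] -= fmag_over_r * dy; fz[j] -= fmag_over_r * dz;
}

struct Sim {
  int N;
  std::vector<double> x, y, z;
  std::vector<int> chain;           // chain id per bead
  std::vector<char> teth, nucl;
  std::vector<std::pair<int,int> > springs;
  Pars p;

  // neighbour (Verlet) list
  std::vector<int> nb_i, nb_j;
  std::vector<char> nb_nucl;        // both ends nucleolar
  std::vector<double> ref_x, ref_y, ref_z;
  double cutoff, skin;

  // crosslink state
  std::vector<int> partner;         // -1 when unlinked
  std::vector<int> link_row;        // open link -> row in link log
  std::vector<char> active;
  std::vector<double> timer;

  // logs
  std::vector<int> log_i, log_j;
  std::vector<double> log_t_on, log_t_off;
  std::vector<int> act_bead; std::vector<char> act_state;
  std::vector<double> act_dur;
  bool log_activity;

  FastRng rng;

  double draw_duration(bool becomes_active) {
    // duration of the *new* state
    double m = becomes_active ? p.on_mean : p.off_mean;
    double s = becomes_active ? p.on_sd : p.off_sd;
    double d = m + s * rng.norm();
    return d < p.dt ? p.dt : d;
  }

  void rebuild_neighbours() {
    nb_i.clear(); nb_j.clear(); nb_nucl.clear();
    double c2 = cutoff * cutoff;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double dx = x[i]-x[j], dy = y[i]-y[j], dz = z[i]-z[j];
        if (dx*dx + dy*dy + dz*dz < c2) {
          nb_i.push_back(i); nb_j.push_back(j);
          nb_nucl.push_back(nucl[i] && nucl[j]);
        }
      }
    ref_x = x; ref_y = y; ref_z = z;
  }

  bool neighbours_stale() const {
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < N; ++i) {
      double dx = x[i]-ref_x[i], dy = y[i]-ref_y[i], dz = z[i]-ref_z[i];
      if (dx*dx + dy*dy + dz*dz > lim2) return true;
    }
    return false;
  }

  void compute_forces(std::vector<double>& fx, std::vector<double>& fy,
                      std::vector<double>& fz) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    // backbone springs
    for (size_t k = 0; k < springs.size(); ++k) {
      int i = springs[k].first, j = springs[k].second;
      double dx = x[i]-x[j], dy = y[i]-y[j], dz = z[i]-z[j];
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r > 1e-12)
        add_pair_force(fx, fy, fz, x, y, z, i, j,
                       -wlc_force(r, p.L0, p.Lp, p)/r);
    }
    // crosslink springs (same WLC law, independent stiffness scale)
    for (int i = 0; i < N; ++i) {
      int j = partner[i];
      if (j > i) {
        double dx = x[i]-x[j], dy = y[i]-y[j], dz = z[i]-z[j];
        double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (r > 1e-12)
          add_pair_force(fx, fy, fz, x, y, z, i, j,
                         -wlc_force(r, p.link_L0, p.link_Lp, p)/r);
      }
    }
    // soft excluded-volume repulsion within 2 * rep_radius
    double d0 = 2.0 * p.rep_radius, d02 = d0 * d0;
    for (size_t k = 0; k < nb_i.size(); ++k) {
      int i = nb_i[k], j = nb_j[k];
      double dx = x[i]-x[j], dy = y[i]-y[j], dz = z[i]-z[j];
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 < d02 && r2 > 1e-24) {
        double r = std::sqrt(r2);
        add_pair_force(fx, fy, fz, x, y, z, i, j, p.rep_strength * (d0 - r)/r);
      }
    }
    // inward wall restoring force outside the sphere
    for (int i = 0; i < N; ++i) {
      double r = std::sqrt(x[i]*x[i] + y[i]*y[i] + z[i]*z[i]);
      if (r > p.R && r > 1e-12) {
        double f = -p.wall_strength * (r - p.R) / r;
        fx[i] += f * x[i]; fy[i] += f * y[i]; fz[i] += f * z[i];
      }
    }
  }

  void update_activity(double t) {
    for (int i = 0; i < N; ++i) {
      if (!nucl[i]) continue;
      timer[i] -= p.dt;
      if (timer[i] <= 0.0) {
        bool was_active = active[i];
        if (log_activity) {
          act_bead.push_back(i); act_state.push_back(was_active ? 1 : 0);
          // completed duration is recovered in R from the draw log; here we
          // store the realized (drawn) duration directly
          act_dur.push_back(drawn_dur[i]);
        }
        active[i] = !was_active;
        double d = draw_duration(active[i]);
        timer[i] += d;          // carry the overshoot so realized means stay unbiased
        if (timer[i] <= 0.0) timer[i] = p.dt;
        drawn_dur[i] = d;
        if (was_active && partner[i] >= 0) {
          int j = partner[i];
          log_t_off[link_row[i]] = t;
          partner[i] = -1; partner[j] = -1;
          link_row[i] = -1; link_row[j] = -1;
        }
      }
    }
  }
  std::vector<double> drawn_dur;

  void match_crosslinks(double t) {
    // candidate pairs: unlinked, active, non-adjacent nucleolar pairs
    // within d_link; greedy ascending-distance matching, ties broken by
    // (i, j) index order
    cand.clear();
    double d2 = p.d_link * p.d_link;
    for (size_t k = 0; k < nb_i.size(); ++k) {
      if (!nb_nucl[k]) continue;
      int i = nb_i[k], j = nb_j[k];
      if (!active[i] || !active[j]) continue;
      if (partner[i] >= 0 || partner[j] >= 0) continue;
      if (chain[i] == chain[j] && std::abs(i - j) <= 1) continue;
      double dx = x[i]-x[j], dy = y[i]-y[j], dz = z[i]-z[j];
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 < d2) cand.push_back(Cand{r2, i, j});
    }
    std::sort(cand.begin(), cand.end());
    for (size_t k = 0; k < cand.size(); ++k) {
      int i = cand[k].i, j = cand[k].j;
      if (partner[i] >= 0 || partner[j] >= 0) continue;
      partner[i] = j; partner[j] = i;
      link_row[i] = (int)log_i.size(); link_row[j] = link_row[i];
      log_i.push_back(i); log_j.push_back(j);
      log_t_on.push_back(t); log_t_off.push_back(NA_REAL);
    }
  }
  struct Cand {
    double r2; int i, j;
    bool operator<(const Cand& o) const {
      if (r2 != o.r2) return r2 < o.r2;
      if (i != o.i) return i < o.i;
      return j < o.j;
    }
  };
  std::vector<Cand> cand;
};

} // namespace

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix pos0, LogicalVector tethered,
                  LogicalVector nucleolar, IntegerVector chain_id,
                  IntegerMatrix springs0, List params, double total_time,
                  double save_interval, int seed, bool log_activity) {
  Sim s;
  s.p = read_pars(params);
  s.N = pos0.nrow();
  s.x.resize(s.N); s.y.resize(s.N); s.z.resize(s.N);
  for (int i = 0; i < s.N; ++i) {
    s.x[i] = pos0(i,0); s.y[i] = pos0(i,1); s.z[i] = pos0(i,2);
  }
  s.teth.assign(s.N, 0); s.nucl.assign(s.N, 0);
  s.chain.resize(s.N);
  for (int i = 0; i < s.N; ++i) {
    s.teth[i] = tethered[i] ? 1 : 0;
    s.nucl[i] = nucleolar[i] ? 1 : 0;
    s.chain[i] = chain_id[i];
  }
  for (int k = 0; k < springs0.nrow(); ++k)
    s.springs.push_back(std::make_pair(springs0(k,0), springs0(k,1)));

  s.skin = 30.0;
  s.cutoff = std::max(s.p.d_link, 2.0 * s.p.rep_radius) + s.skin;
  s.partner.assign(s.N, -1);
  s.link_row.assign(s.N, -1);
  s.active.assign(s.N, 0);
  s.timer.assign(s.N, 0.0);
  s.drawn_dur.assign(s.N, 0.0);
  s.log_activity = log_activity;
  s.rng.seed((uint64_t)seed);

  // stationary initialization: active with probability
  // on_mean / (on_mean + off_mean); fresh duration draw for the state
  double p_active = s.p.on_mean / (s.p.on_mean + s.p.off_mean);
  for (int i = 0; i < s.N; ++i) {
    if (!s.nucl[i]) continue;
    s.active[i] = s.rng.unif() < p_active ? 1 : 0;
    double d = s.draw_duration(s.active[i]);
    s.timer[i] = d;
    s.drawn_dur[i] = d;
  }

  int n_steps = (int)std::lround(total_time / s.p.dt);
  int save_every = (int)std::lround(save_interval / s.p.dt);
  if (save_every < 1) save_every = 1;
  int n_frames = n_steps / save_every + 1;

  NumericVector pos_out((R_xlen_t)n_frames * s.N * 3);
  NumericVector times(n_frames);
  auto save_frame = [&](int f, double t) {
    times[f] = t;
    R_xlen_t T = n_frames, N = s.N;
    for (int i = 0; i < s.N; ++i) {
      pos_out[f + T * (R_xlen_t)i]             = s.x[i];
      pos_out[f + T * ((R_xlen_t)i + N)]       = s.y[i];
      pos_out[f + T * ((R_xlen_t)i + 2 * N)]   = s.z[i];
    }
  };

  s.rebuild_neighbours();
  save_frame(0, 0.0);

  std::vector<double> fx(s.N), fy(s.N), fz(s.N);
  double noise = std::sqrt(2.0 * s.p.kT / s.p.drag * s.p.dt);
  double max_step = 0.5 * s.p.rep_radius;
  int frame = 1;

  for (int step = 1; step <= n_steps; ++step) {
    double t = step * s.p.dt;
    s.compute_forces(fx, fy, fz);
    for (int i = 0; i < s.N; ++i) {
      if (s.teth[i]) continue;
      double mx = fx[i] / s.p.drag * s.p.dt, my = fy[i] / s.p.drag * s.p.dt,
             mz = fz[i] / s.p.drag * s.p.dt;
      double m2 = mx*mx + my*my + mz*mz;
      if (m2 > max_step * max_step)
        stop("integration unstable at t = %f (bead %d moved %f nm in one step)",
             t, i + 1, std::sqrt(m2));
      s.x[i] += mx + noise * s.rng.norm();
      s.y[i] += my + noise * s.rng.norm();
      s.z[i] += mz + noise * s.rng.norm();
      double r2 = s.x[i]*s.x[i] + s.y[i]*s.y[i] + s.z[i]*s.z[i];
      if (r2 > s.p.R * s.p.R) {
        double f = s.p.R / std::sqrt(r2);
        s.x[i] *= f; s.y[i] *= f; s.z[i] *= f;
      }
    }
    s.update_activity(t);
    if (s.neighbours_stale()) s.rebuild_neighbours();
    s.match_crosslinks(t);
    if (step % save_every == 0) save_frame(frame++, t);
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  pos_out.attr("dim") = IntegerVector::create(n_frames, s.N, 3);

  int nl = (int)s.log_i.size();
  IntegerVector li(nl), lj(nl);
  NumericVector lt_on(nl), lt_off(nl);
  for (int k = 0; k < nl; ++k) {
    li[k] = s.log_i[k] + 1; lj[k] = s.log_j[k] + 1;
    lt_on[k] = s.log_t_on[k]; lt_off[k] = s.log_t_off[k];
  }
  List link_log = List::create(_["bead_i"] = li, _["bead_j"] = lj,
                               _["t_formed"] = lt_on, _["t_broken"] = lt_off);

  List act = R_NilValue;
  if (log_activity) {
    int na = (int)s.act_bead.size();
    IntegerVector ab(na); LogicalVector as_(na); NumericVector ad(na);
    for (int k = 0; k < na; ++k) {
      ab[k] = s.act_bead[k] + 1; as_[k] = s.act_state[k] == 1;
      ad[k] = s.act_dur[k];
    }
    act = List::create(_["bead"] = ab, _["was_active"] = as_,
                       _["duration"] = ad);
  }

  LogicalVector fin_active(s.N);
  for (int i = 0; i < s.N; ++i) fin_active[i] = s.active[i] == 1;

  return List::create(_["times"] = times, _["positions"] = pos_out,
                      _["link_log"] = link_log, _["activity_log"] = act,
                      _["final_active"] = fin_active);
}

// Deterministic force evaluation on a single configuration (shared with the
// integrator); exposed for direct inspection and testing.
// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, IntegerMatrix springs0,
                         IntegerMatrix links0, List params) {
  Sim s;
  s.p = read_pars(params);
  s.N = pos.nrow();
  s.x.resize(s.N); s.y.resize(s.N); s.z.resize(s.N);
  for (int i = 0; i < s.N; ++i) {
    s.x[i] = pos(i,0); s.y[i] = pos(i,1); s.z[i] = pos(i,2);
    if (!R_finite(s.x[i]) || !R_finite(s.y[i]) || !R_finite(s.z[i]))
      stop("non-finite bead position");
  }
  s.nucl.assign(s.N, 1); s.teth.assign(s.N, 0);
  s.chain.assign(s.N, 1);
  for (int k = 0; k < springs0.nrow(); ++k)
    s.springs.push_back(std::make_pair(springs0(k,0) - 1, springs0(k,1) - 1));
  s.partner.assign(s.N, -1);
  for (int k = 0; k < links0.nrow(); ++k) {
    int i = links0(k,0) - 1, j = links0(k,1) - 1;
    s.partner[i] = j; s.partner[j] = i;
  }
  s.skin = 30.0;
  s.cutoff = std::max(s.p.d_link, 2.0 * s.p.rep_radius) + s.skin;
  s.rebuild_neighbours();
  std::vector<double> fx(s.N), fy(s.N), fz(s.N);
  s.compute_forces(fx, fy, fz);
  NumericMatrix out(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    out(i,0) = fx[i]; out(i,1) = fy[i]; out(i,2) = fz[i];
  }
  return out;
}
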