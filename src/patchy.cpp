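// Coarse-grained patchy-particle reaction-diffusion simulator.
//
// Enzymes are rigid bodies: a spherical core with two massless patch sites at
// fixed antipodal offsets (a specific protein-interaction patch and an
// active-site patch).  Ligands are point spheres carrying a chemical state
// S_0..S_{K-1} or the absorbing product P.  Non-specific interactions are
// truncated-and-shifted Lennard-Jones; specific interactions (PPI patch-patch
// and cognate active-site/ligand) are exclusive Morse bonds with short capture
// ranges enforcing single valence.  Integrators: inertial Langevin (BAOAB;
// reduces to velocity Verlet when the drag is zero) and overdamped Brownian
// dynamics.  Internal units: Angstrom, amu, k_B T = 1 at the configured
// temperature; the time unit is sqrt(amu A^2 / k_B T).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <algorithm>
#include <functional>
using namespace Rcpp;

static const double KB_SI = 1.380649e-23;     // J/K
static const double AMU_SI = 1.66053906660e-27; // kg

struct Vec3 {
  double x, y, z;
  Vec3(double x_ = 0, double y_ = 0, double z_ = 0) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  Vec3& operator+=(const Vec3& o) { x += o.x; y += o.y; z += o.z; return *this; }
  Vec3& operator-=(const Vec3& o) { x -= o.x; y -= o.y; z -= o.z; return *this; }
  double norm2() const { return x * x + y * y + z * z; }
  double norm() const { return std::sqrt(norm2()); }
};

static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}

struct Quat {
  double w, x, y, z;
  Quat(double w_ = 1, double x_ = 0, double y_ = 0, double z_ = 0)
    : w(w_), x(x_), y(y_), z(z_) {}
  void normalize() {
    double n = std::sqrt(w * w + x * x + y * y + z * z);
    w /= n; x /= n; y /= n; z /= n;
  }
};

static inline Quat qmul(const Quat& a, const Quat& b) {
  return Quat(a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z,
              a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y,
              a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x,
              a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w);
}

// rotate vector v by quaternion q
static inline Vec3 qrot(const Quat& q, const Vec3& v) {
  Vec3 u(q.x, q.y, q.z);
  Vec3 t = cross(u, v) * 2.0;
  return v + t * q.w + cross(u, t);
}

// quaternion for rotation vector theta (axis * angle)
static inline Quat qfromrot(const Vec3& th) {
  double a = th.norm();
  if (a < 1e-12) return Quat(1, th.x * 0.5, th.y * 0.5, th.z * 0.5);
  double h = 0.5 * a, s = std::sin(h) / a;
  return Quat(std::cos(h), th.x * s, th.y * s, th.z * s);
}

struct Sim {
  // sizes
  int n_types, n_enz, n_lig, n_react;
  // geometry / physics (internal units)
  double L;                 // box side
  double r_enz, r_lig;
  double eps_pp, eps_pl, eps_nc;
  double ppi_alpha, ppi_r0, ppi_cutoff, ppi_capture;
  double co_de, co_alpha, co_r0, co_cutoff;
  double ppi_offset, active_offset;
  double m_enz, m_lig, I_enz;
  double g_enz, g_lig, g_rot;   // drags
  double dt;
  bool brownian;
  double kT;                    // 1 unless a zero-temperature run
  double confine_radius, confine_k;
  long confine_steps;
  // state
  std::vector<Vec3> epos, evel, eang;   // enzyme com, velocity, angular velocity
  std::vector<Quat> equat;
  std::vector<int> etype;
  std::vector<Vec3> lpos, lvel;
  std::vector<int> lstate;
  std::vector<int> ppi_partner;         // enzyme -> enzyme or -1
  std::vector<int> site_ligand;         // enzyme -> ligand or -1
  std::vector<int> lig_enzyme;          // ligand -> enzyme or -1
  // interaction tables
  std::vector<double> de_ppi;           // n_types x n_types
  std::vector<double> p_react;          // per reaction
  // forces / torques scratch
  std::vector<Vec3> efor, etor, lfor;
  double pe;                            // potential energy of last force eval
  // neighbour lists (index pairs), rebuilt on displacement
  std::vector<std::pair<int,int>> nl_ee, nl_el, nl_ll;
  std::vector<Vec3> ref_epos, ref_lpos;
  double skin;
  // unwrapped tracking
  std::vector<Vec3> epos_unwrap, lpos_unwrap;
  // counters
  std::vector<long> rcount;
  long max_valence_seen;
  std::mt19937_64 rng;
  std::normal_distribution<double> gauss;

  double min_img(double d) const {
    if (d >  0.5 * L) d -= L;
    if (d < -0.5 * L) d += L;
    return d;
  }
  Vec3 min_img(Vec3 d) const {
    return Vec3(min_img(d.x), min_img(d.y), min_img(d.z));
  }
  Vec3 wrap(Vec3 p) const {
    p.x -= L * std::floor(p.x / L);
    p.y -= L * std::floor(p.y / L);
    p.z -= L * std::floor(p.z / L);
    return p;
  }
  Vec3 ppi_site(int i) const {
    return qrot(equat[i], Vec3(0, 0, 1)) * ppi_offset;
  }
  Vec3 active_site(int i) const {
    return qrot(equat[i], Vec3(0, 0, 1)) * (-active_offset);
  }

  void build_neighbours() {
    nl_ee.clear(); nl_el.clear(); nl_ll.clear();
    double c_ee = std::max(2.5 * 2.0 * r_enz,
                           ppi_cutoff + 2.0 * ppi_offset) + skin;
    double c_el = std::max(2.5 * (r_enz + r_lig),
                           std::max(2.5 * 2.0 * r_lig + active_offset,
                                    co_cutoff + active_offset)) + skin;
    double c_ll = 2.5 * 2.0 * r_lig + skin;
    double c_ee2 = c_ee * c_ee, c_el2 = c_el * c_el, c_ll2 = c_ll * c_ll;
    for (int i = 0; i < n_enz; ++i)
      for (int j = i + 1; j < n_enz; ++j)
        if (min_img(epos[j] - epos[i]).norm2() < c_ee2) nl_ee.push_back({i, j});
    for (int i = 0; i < n_enz; ++i)
      for (int j = 0; j < n_lig; ++j)
        if (min_img(lpos[j] - epos[i]).norm2() < c_el2) nl_el.push_back({i, j});
    for (int i = 0; i < n_lig; ++i)
      for (int j = i + 1; j < n_lig; ++j)
        if (min_img(lpos[j] - lpos[i]).norm2() < c_ll2) nl_ll.push_back({i, j});
    ref_epos = epos; ref_lpos = lpos;
  }

  bool need_rebuild() const {
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n_enz; ++i)
      if (min_img(epos[i] - ref_epos[i]).norm2() > lim2) return true;
    for (int i = 0; i < n_lig; ++i)
      if (min_img(lpos[i] - ref_lpos[i]).norm2() > lim2) return true;
    return false;
  }

  // per-pair force cap (kT/A): steeply repulsive cores (r^-12, Morse
  // exponential) are clamped so that a pair created deep inside its
  // repulsive wall (e.g. a specific bond formed off-equilibrium) relaxes
  // smoothly instead of exploding the overdamped update.  The cap is far
  // above any force reached in equilibrated configurations, so sampled
  // physics is unaffected.
  double fcap;

  // truncated-and-shifted LJ; adds force on "i side" along unit vector of d
  // (d points from i to j).  Returns energy.
  inline double lj_pair(const Vec3& d, double r2, double eps, double sigma,
                        Vec3& fi) {
    double rc = 2.5 * sigma;
    if (r2 >= rc * rc) return 0.0;
    double s2 = sigma * sigma / r2;
    double s6 = s2 * s2 * s2;
    double s6c = std::pow(sigma / rc, 6.0);
    double u = 4.0 * eps * (s6 * s6 - s6) - 4.0 * eps * (s6c * s6c - s6c);
    double fmag = 24.0 * eps * (2.0 * s6 * s6 - s6) / r2; // F = fmag * d (on j)
    double r = std::sqrt(r2);
    if (std::fabs(fmag) * r > fcap) fmag = (fmag > 0 ? fcap : -fcap) / r;
    fi -= d * fmag;  // force on i is -F
    return u;
  }

  // shifted Morse on a bonded pair; d from i-site to j-site
  inline double morse_pair(const Vec3& d, double de, double alpha, double r0,
                           double cutoff, Vec3& f_on_i) {
    double r = d.norm();
    if (r >= cutoff || de <= 0.0) return 0.0;
    double e = std::exp(-alpha * (r - r0));
    double ec = std::exp(-alpha * (cutoff - r0));
    double u = de * (e * e - 2.0 * e) - de * (ec * ec - 2.0 * ec);
    double dudr = de * (-2.0 * alpha * e * e + 2.0 * alpha * e);
    if (std::fabs(dudr) > fcap) dudr = (dudr > 0 ? fcap : -fcap);
    // force on i = -dU/dr * (-d/r) = dudr * d / r
    f_on_i += d * (dudr / r);
    return u;
  }

  void compute_forces(long step) {
    std::fill(efor.begin(), efor.end(), Vec3());
    std::fill(etor.begin(), etor.end(), Vec3());
    std::fill(lfor.begin(), lfor.end(), Vec3());
    pe = 0.0;
    double sig_ee = 2.0 * r_enz, sig_el = r_enz + r_lig, sig_ll = 2.0 * r_lig;
    // enzyme-enzyme: core LJ + bonded PPI Morse
    for (auto& pr : nl_ee) {
      int i = pr.first, j = pr.second;
      Vec3 d = min_img(epos[j] - epos[i]);
      double r2 = d.norm2();
      Vec3 fi(0, 0, 0);
      pe += lj_pair(d, r2, eps_pp, sig_ee, fi);
      efor[i] += fi; efor[j] -= fi;
      // specific patch-patch Morse for every pair within its cutoff: the
      // short range plus the core excluded volume is what limits valence
      double de = de_ppi[etype[i] * n_types + etype[j]];
      if (de > 0) {
        Vec3 si = ppi_site(i), sj = ppi_site(j);
        Vec3 dp = d + sj - si;  // patch i -> patch j
        if (dp.norm2() < ppi_cutoff * ppi_cutoff) {
          Vec3 fpi(0, 0, 0);
          pe += morse_pair(dp, de, ppi_alpha, ppi_r0, ppi_cutoff, fpi);
          efor[i] += fpi; etor[i] += cross(si, fpi);
          efor[j] -= fpi; etor[j] -= cross(sj, fpi);
        }
      }
    }
    // enzyme-ligand: core LJ, patch LJ (non-cognate), bonded cognate Morse
    for (auto& pr : nl_el) {
      int i = pr.first, j = pr.second;
      Vec3 d = min_img(lpos[j] - epos[i]);
      double r2 = d.norm2();
      Vec3 fi(0, 0, 0);
      pe += lj_pair(d, r2, eps_pl, sig_el, fi);
      efor[i] += fi; lfor[j] -= fi;
      // active-site patch
      Vec3 sa = active_site(i);
      Vec3 da = d - sa;  // active site -> ligand
      if (site_ligand[i] == j) {
        Vec3 fpi(0, 0, 0);
        pe += morse_pair(da, co_de, co_alpha, co_r0, co_cutoff, fpi);
        efor[i] += fpi; etor[i] += cross(sa, fpi);
        lfor[j] -= fpi;
      } else {
        Vec3 fpa(0, 0, 0);
        pe += lj_pair(da, da.norm2(), eps_nc, sig_ll, fpa);
        efor[i] += fpa; etor[i] += cross(sa, fpa);
        lfor[j] -= fpa;
      }
      // PPI patch vs ligand: non-specific only
      Vec3 sp = ppi_site(i);
      Vec3 dp = d - sp;
      Vec3 fpp(0, 0, 0);
      pe += lj_pair(dp, dp.norm2(), eps_nc, sig_ll, fpp);
      efor[i] += fpp; etor[i] += cross(sp, fpp);
      lfor[j] -= fpp;
    }
    // ligand-ligand LJ
    for (auto& pr : nl_ll) {
      int i = pr.first, j = pr.second;
      Vec3 d = min_img(lpos[j] - lpos[i]);
      Vec3 fi(0, 0, 0);
      pe += lj_pair(d, d.norm2(), eps_pl, sig_ll, fi);
      lfor[i] += fi; lfor[j] -= fi;
    }
    // confinement of enzymes (harmonic outside the sphere) during the
    // confinement phase
    if (step < confine_steps) {
      Vec3 ctr(L / 2, L / 2, L / 2);
      for (int i = 0; i < n_enz; ++i) {
        Vec3 d = epos[i] - ctr;   // confinement works in unwrapped box coords
        double r = d.norm();
        if (r > confine_radius) {
          double exc = r - confine_radius;
          pe += 0.5 * confine_k * exc * exc;
          efor[i] -= d * (confine_k * exc / r);
        }
      }
    }
  }

  // cognate-bond bookkeeping: break out-of-range bonds, then greedily form
  // new ones (shortest distance first; deterministic ordering).  One ligand
  // per active site, one site per ligand.
  void update_bonds(bool /*ppi_on*/) {
    // break
    for (int i = 0; i < n_enz; ++i) {
      int l = site_ligand[i];
      if (l >= 0) {
        Vec3 da = min_img(lpos[l] - epos[i]) - active_site(i);
        if (da.norm() >= co_cutoff) {
          site_ligand[i] = -1; lig_enzyme[l] = -1;
        }
      }
    }
    // form cognate bonds (enzyme type k binds ligand state k)
    {
      std::vector<std::pair<double, std::pair<int,int>>> cand;
      double cap = co_cutoff;  // capture region = r0 + capture = cutoff
      for (auto& pr : nl_el) {
        int i = pr.first, j = pr.second;
        if (site_ligand[i] >= 0 || lig_enzyme[j] >= 0) continue;
        if (lstate[j] != etype[i]) continue;  // product P never matches
        Vec3 da = min_img(lpos[j] - epos[i]) - active_site(i);
        double r = da.norm();
        if (r <= cap) cand.push_back({r, {i, j}});
      }
      std::sort(cand.begin(), cand.end());
      for (auto& c : cand) {
        int i = c.second.first, j = c.second.second;
        if (site_ligand[i] < 0 && lig_enzyme[j] < 0) {
          site_ligand[i] = j; lig_enzyme[j] = i;
        }
      }
    }
  }

  std::uniform_real_distribution<double> unif{0.0, 1.0};

  void attempt_reactions() {
    for (int i = 0; i < n_enz; ++i) {
      int l = site_ligand[i];
      if (l < 0) continue;
      int k = etype[i];  // reaction index: S_k -> S_{k+1}
      if (p_react[k] <= 0) continue;
      if (unif(rng) < p_react[k]) {
        lstate[l] += 1;            // n_react means product P (absorbing)
        rcount[k] += 1;
        site_ligand[i] = -1;
        lig_enzyme[l] = -1;
      }
    }
  }

  // ---- integrators ----
  double max_disp2;

  void drift_half() {
    double h = 0.5 * dt;
    for (int i = 0; i < n_enz; ++i) {
      Vec3 dx = evel[i] * h;
      max_disp2 = std::max(max_disp2, dx.norm2());
      epos[i] = wrap(epos[i] + dx);
      epos_unwrap[i] += dx;
      Vec3 th = eang[i] * h;
      equat[i] = qmul(qfromrot(th), equat[i]);
      equat[i].normalize();
    }
    for (int i = 0; i < n_lig; ++i) {
      Vec3 dx = lvel[i] * h;
      max_disp2 = std::max(max_disp2, dx.norm2());
      lpos[i] = wrap(lpos[i] + dx);
      lpos_unwrap[i] += dx;
    }
  }

  void kick_half() {
    double h = 0.5 * dt;
    for (int i = 0; i < n_enz; ++i) {
      evel[i] += efor[i] * (h / m_enz);
      eang[i] += etor[i] * (h / I_enz);
    }
    for (int i = 0; i < n_lig; ++i) lvel[i] += lfor[i] * (h / m_lig);
  }

  void ou_full() {
    if (g_enz <= 0 && g_lig <= 0) return;
    double c1e = std::exp(-g_enz * dt / m_enz);
    double c2e = std::sqrt((1.0 - c1e * c1e) * kT / m_enz);
    double c1r = std::exp(-g_rot * dt / I_enz);
    double c2r = std::sqrt((1.0 - c1r * c1r) * kT / I_enz);
    double c1l = std::exp(-g_lig * dt / m_lig);
    double c2l = std::sqrt((1.0 - c1l * c1l) * kT / m_lig);
    for (int i = 0; i < n_enz; ++i) {
      evel[i] = evel[i] * c1e +
        Vec3(gauss(rng), gauss(rng), gauss(rng)) * c2e;
      eang[i] = eang[i] * c1r +
        Vec3(gauss(rng), gauss(rng), gauss(rng)) * c2r;
    }
    for (int i = 0; i < n_lig; ++i) {
      lvel[i] = lvel[i] * c1l +
        Vec3(gauss(rng), gauss(rng), gauss(rng)) * c2l;
    }
  }

  void step_langevin(long step, bool ppi_on) {
    max_disp2 = 0.0;
    kick_half();
    drift_half();
    ou_full();
    drift_half();
    if (need_rebuild()) build_neighbours();
    update_bonds(ppi_on);
    compute_forces(step);
    kick_half();
  }

  void step_brownian(long step, bool ppi_on) {
    max_disp2 = 0.0;
    double se = std::sqrt(2.0 * kT * dt / g_enz);
    double sr = std::sqrt(2.0 * kT * dt / g_rot);
    double sl = std::sqrt(2.0 * kT * dt / g_lig);
    for (int i = 0; i < n_enz; ++i) {
      Vec3 dx = efor[i] * (dt / g_enz) +
        Vec3(gauss(rng), gauss(rng), gauss(rng)) * se;
      max_disp2 = std::max(max_disp2, dx.norm2());
      epos[i] = wrap(epos[i] + dx);
      epos_unwrap[i] += dx;
      Vec3 th = etor[i] * (dt / g_rot) +
        Vec3(gauss(rng), gauss(rng), gauss(rng)) * sr;
      equat[i] = qmul(qfromrot(th), equat[i]);
      equat[i].normalize();
    }
    for (int i = 0; i < n_lig; ++i) {
      Vec3 dx = lfor[i] * (dt / g_lig) +
        Vec3(gauss(rng), gauss(rng), gauss(rng)) * sl;
      max_disp2 = std::max(max_disp2, dx.norm2());
      lpos[i] = wrap(lpos[i] + dx);
      lpos_unwrap[i] += dx;
    }
    if (need_rebuild()) build_neighbours();
    update_bonds(ppi_on);
    compute_forces(step);
  }

  double kinetic_energy() const {
    double ke = 0.0;
    for (int i = 0; i < n_enz; ++i) {
      ke += 0.5 * m_enz * evel[i].norm2() + 0.5 * I_enz * eang[i].norm2();
    }
    for (int i = 0; i < n_lig; ++i) ke += 0.5 * m_lig * lvel[i].norm2();
    return ke;
  }
  double trans_ke() const {
    double ke = 0.0;
    for (int i = 0; i < n_enz; ++i) ke += 0.5 * m_enz * evel[i].norm2();
    for (int i = 0; i < n_lig; ++i) ke += 0.5 * m_lig * lvel[i].norm2();
    return ke / (n_enz + n_lig);
  }

  // assertion-mode diagnostic: the worst-case number of partner patches
  // within the capture range (r0 + capture) of any one interaction patch
  long check_valence() const {
    long worst = 0;
    std::vector<long> cnt(n_enz, 0);
    double cap = ppi_r0 + ppi_capture;
    double cap2 = cap * cap;
    for (auto& pr : nl_ee) {
      int i = pr.first, j = pr.second;
      if (de_ppi[etype[i] * n_types + etype[j]] <= 0) continue;
      Vec3 dp = min_img(epos[j] - epos[i]) + ppi_site(j) - ppi_site(i);
      if (dp.norm2() <= cap2) { cnt[i]++; cnt[j]++; }
    }
    for (int i = 0; i < n_enz; ++i) worst = std::max(worst, cnt[i]);
    return worst;
  }
};

// [[Rcpp::export(name = ".patchy_run")]]
List patchy_run(List cfg, NumericMatrix de_matrix, NumericVector p_react,
                bool ppi_on, int seed, int n_steps_override = -1,
                bool compute_energy = false, int n_track = 0,
                bool zero_drag = false, bool zero_noise = false,
                bool interactions_on = true, double init_kT = 1.0) {
  Sim s;
  s.n_types = as<int>(cfg["n_types"]);
  s.n_enz = as<int>(cfg["n_enzymes"]);
  s.n_lig = as<int>(cfg["n_ligands"]);
  s.n_react = s.n_types;
  s.L = as<double>(cfg["box_side"]);
  s.r_enz = as<double>(cfg["enzyme_radius"]);
  s.r_lig = as<double>(cfg["ligand_radius"]);
  double T = as<double>(cfg["temperature"]);
  double eta = as<double>(cfg["viscosity"]);
  s.eps_pp = interactions_on ? as<double>(cfg["epsilon_pp"]) : 0.0;
  s.eps_pl = interactions_on ? as<double>(cfg["epsilon_pl"]) : 0.0;
  s.eps_nc = interactions_on ? as<double>(cfg["epsilon_nc"]) : 0.0;
  s.ppi_alpha = as<double>(cfg["ppi_alpha"]);
  s.ppi_r0 = as<double>(cfg["ppi_r0"]);
  s.ppi_cutoff = as<double>(cfg["ppi_cutoff"]);
  s.ppi_capture = as<double>(cfg["ppi_capture"]);
  s.co_de = interactions_on ? as<double>(cfg["co_de"]) : 0.0;
  s.co_alpha = as<double>(cfg["co_alpha"]);
  s.co_r0 = as<double>(cfg["co_r0"]);
  s.co_cutoff = as<double>(cfg["co_cutoff"]);
  s.ppi_offset = as<double>(cfg["ppi_offset"]);
  s.active_offset = as<double>(cfg["active_offset"]);
  s.m_enz = as<double>(cfg["enzyme_mass"]);
  s.m_lig = as<double>(cfg["ligand_mass"]);
  s.I_enz = 0.4 * s.m_enz * s.r_enz * s.r_enz;  // solid sphere
  s.brownian = as<std::string>(cfg["integrator"]) == "brownian";
  s.fcap = as<double>(cfg["force_cap"]);
  s.confine_radius = as<double>(cfg["confine_radius"]);
  s.confine_k = 10.0;  // kT/A^2; stiff enough to hold, soft enough for dt

  long n_steps = (n_steps_override > 0) ? n_steps_override
                                        : as<int>(cfg["n_steps"]);
  s.confine_steps = (long)std::floor(as<double>(cfg["confine_frac"]) * n_steps);
  int record_every = as<int>(cfg["record_every"]);

  // unit conversions: kT = 1 internal at temperature T
  double kT_J = KB_SI * T;
  double t0 = std::sqrt(AMU_SI * 1e-20 / kT_J);   // seconds
  s.dt = as<double>(cfg["dt_fs"]) * 1e-15 / t0;
  s.kT = 1.0;
  auto stokes = [&](double radiusA) {  // translational drag, internal units
    double g_si = 6.0 * M_PI * eta * radiusA * 1e-10;      // kg/s
    return g_si * t0 / AMU_SI;
  };
  s.g_enz = stokes(s.r_enz);
  s.g_lig = stokes(s.r_lig);
  {
    double gr_si = 8.0 * M_PI * eta * std::pow(s.r_enz * 1e-10, 3.0); // kg m^2/s
    s.g_rot = gr_si * t0 / (AMU_SI * 1e-20);
  }
  if (zero_drag) { s.g_enz = s.g_lig = s.g_rot = 0.0; }
  if (zero_noise) { s.kT = 0.0; }
  if (s.brownian && (s.g_enz <= 0 || s.g_lig <= 0)) {
    stop("the Brownian integrator requires a positive drag");
  }

  if (de_matrix.nrow() != s.n_types || de_matrix.ncol() != s.n_types)
    stop("de_matrix must be n_types x n_types");
  s.de_ppi.assign(s.n_types * s.n_types, 0.0);
  for (int i = 0; i < s.n_types; ++i)
    for (int j = 0; j < s.n_types; ++j)
      s.de_ppi[i * s.n_types + j] = ppi_on ? de_matrix(i, j) : 0.0;
  s.p_react.assign(p_react.begin(), p_react.end());
  if ((int)s.p_react.size() != s.n_react)
    stop("p_react must have one entry per enzyme type");

  s.rng.seed((uint64_t)seed * 2654435761u + 1u);
  s.gauss = std::normal_distribution<double>(0.0, 1.0);

  // ---- placement ----
  s.epos.resize(s.n_enz); s.evel.assign(s.n_enz, Vec3());
  s.eang.assign(s.n_enz, Vec3()); s.equat.resize(s.n_enz);
  s.etype.resize(s.n_enz);
  s.lpos.resize(s.n_lig); s.lvel.assign(s.n_lig, Vec3());
  s.lstate.assign(s.n_lig, 0);
  s.ppi_partner.assign(s.n_enz, -1);
  s.site_ligand.assign(s.n_enz, -1);
  s.lig_enzyme.assign(s.n_lig, -1);
  s.efor.resize(s.n_enz); s.etor.resize(s.n_enz); s.lfor.resize(s.n_lig);
  s.rcount.assign(s.n_react, 0);
  s.skin = 5.0;

  std::uniform_real_distribution<double> u01(0.0, 1.0);
  Vec3 ctr(s.L / 2, s.L / 2, s.L / 2);
  int copies = as<int>(cfg["copies_per_type"]);
  double min_ee2 = std::pow(2.0 * s.r_enz, 2.0);
  for (int i = 0; i < s.n_enz; ++i) {
    s.etype[i] = i / copies;
    bool placed = false;
    for (int attempt = 0; attempt < 20000 && !placed; ++attempt) {
      // uniform in the confinement sphere
      Vec3 p;
      do {
        p = Vec3(2 * u01(s.rng) - 1, 2 * u01(s.rng) - 1, 2 * u01(s.rng) - 1);
      } while (p.norm2() > 1.0);
      p = ctr + p * s.confine_radius;
      bool ok = true;
      for (int j = 0; j < i && ok; ++j)
        if (s.min_img(p - s.epos[j]).norm2() < min_ee2) ok = false;
      if (ok) { s.epos[i] = s.wrap(p); placed = true; }
    }
    if (!placed)
      stop("could not place enzymes without overlap; packing too dense");
    // random orientation via random rotation vector of random angle
    Vec3 ax(s.gauss(s.rng), s.gauss(s.rng), s.gauss(s.rng));
    double axn = ax.norm(); if (axn < 1e-12) { ax = Vec3(0, 0, 1); axn = 1; }
    double angle = 2.0 * M_PI * u01(s.rng);
    s.equat[i] = qfromrot(ax * (angle / axn));
    s.equat[i].normalize();
  }
  double min_el2 = std::pow(s.r_enz + s.r_lig, 2.0);
  double min_ll2 = std::pow(2.0 * s.r_lig, 2.0);
  for (int i = 0; i < s.n_lig; ++i) {
    bool placed = false;
    for (int attempt = 0; attempt < 20000 && !placed; ++attempt) {
      Vec3 p(u01(s.rng) * s.L, u01(s.rng) * s.L, u01(s.rng) * s.L);
      bool ok = true;
      for (int j = 0; j < s.n_enz && ok; ++j)
        if (s.min_img(p - s.epos[j]).norm2() < min_el2) ok = false;
      for (int j = 0; j < i && ok; ++j)
        if (s.min_img(p - s.lpos[j]).norm2() < min_ll2) ok = false;
      if (ok) { s.lpos[i] = p; placed = true; }
    }
    if (!placed)
      stop("could not place ligands without overlap; packing too dense");
  }
  // Maxwell-Boltzmann velocities at init_kT (pass 0 for a cold start)
  double vstd_e = std::sqrt(init_kT / s.m_enz),
         vstd_l = std::sqrt(init_kT / s.m_lig);
  double wstd = std::sqrt(init_kT / s.I_enz);
  for (int i = 0; i < s.n_enz; ++i) {
    s.evel[i] = Vec3(s.gauss(s.rng), s.gauss(s.rng), s.gauss(s.rng)) * vstd_e;
    s.eang[i] = Vec3(s.gauss(s.rng), s.gauss(s.rng), s.gauss(s.rng)) * wstd;
  }
  for (int i = 0; i < s.n_lig; ++i)
    s.lvel[i] = Vec3(s.gauss(s.rng), s.gauss(s.rng), s.gauss(s.rng)) * vstd_l;

  s.epos_unwrap = s.epos; s.lpos_unwrap = s.lpos;
  s.build_neighbours();
  s.update_bonds(ppi_on);
  s.compute_forces(0);
  s.max_valence_seen = 0;

  // ---- recording buffers ----
  int n_rec = (int)(n_steps / record_every);
  NumericMatrix rec_counts(n_rec, s.n_react);
  NumericVector rec_step(n_rec), rec_ke(n_rec), rec_energy(n_rec);
  NumericMatrix contact_counts(s.n_types, s.n_types);
  std::vector<long> cluster_hist(s.n_enz + 1, 0);
  long n_cluster_frames = 0;
  n_track = std::min(n_track, s.n_lig);
  NumericMatrix track_x(n_track > 0 ? n_rec : 0, n_track),
                track_y(n_track > 0 ? n_rec : 0, n_track),
                track_z(n_track > 0 ? n_rec : 0, n_track);

  double disp_limit2 = std::pow(2.0 * s.r_lig, 2.0); // sigma_patch = 8 A

  int rec_i = 0;
  for (long st = 1; st <= n_steps; ++st) {
    if (s.brownian) s.step_brownian(st, ppi_on);
    else s.step_langevin(st, ppi_on);
    if (s.max_disp2 > disp_limit2)
      stop("instability: displacement per step exceeded the patch diameter; "
           "reduce dt_fs");
    s.attempt_reactions();
    if (st % record_every == 0 && rec_i < n_rec) {
      s.max_valence_seen = std::max(s.max_valence_seen, s.check_valence());
      rec_step[rec_i] = (double)st;
      for (int k = 0; k < s.n_react; ++k)
        rec_counts(rec_i, k) = (double)s.rcount[k];
      rec_ke[rec_i] = s.trans_ke();
      if (compute_energy) rec_energy[rec_i] = s.pe + s.kinetic_energy();
      if (n_track > 0) {
        for (int t = 0; t < n_track; ++t) {
          track_x(rec_i, t) = s.lpos_unwrap[t].x;
          track_y(rec_i, t) = s.lpos_unwrap[t].y;
          track_z(rec_i, t) = s.lpos_unwrap[t].z;
        }
      }
      // contact matrix + cluster sizes from PPI patch proximity
      {
        std::vector<int> parent(s.n_enz);
        for (int i = 0; i < s.n_enz; ++i) parent[i] = i;
        std::function<int(int)> find = [&](int a) {
          while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
          return a;
        };
        double cut2 = s.ppi_cutoff * s.ppi_cutoff;
        for (auto& pr : s.nl_ee) {
          int i = pr.first, j = pr.second;
          Vec3 dp = s.min_img(s.epos[j] - s.epos[i]) + s.ppi_site(j) - s.ppi_site(i);
          if (dp.norm2() <= cut2) {
            contact_counts(s.etype[i], s.etype[j]) += 1;
            if (s.etype[i] != s.etype[j])
              contact_counts(s.etype[j], s.etype[i]) += 1;
            int a = find(i), b = find(j);
            if (a != b) parent[a] = b;
          }
        }
        std::vector<int> csize(s.n_enz, 0);
        for (int i = 0; i < s.n_enz; ++i) csize[find(i)]++;
        for (int i = 0; i < s.n_enz; ++i)
          if (csize[i] > 0) cluster_hist[csize[i]]++;
        n_cluster_frames++;
      }
      rec_i++;
    }
  }

  // final frame export
  NumericMatrix enz_pos(s.n_enz, 3), enz_axis(s.n_enz, 3), lig_pos(s.n_lig, 3);
  IntegerVector enz_type(s.n_enz), lig_state(s.n_lig), site_bond(s.n_enz);
  for (int i = 0; i < s.n_enz; ++i) {
    enz_pos(i, 0) = s.epos[i].x; enz_pos(i, 1) = s.epos[i].y;
    enz_pos(i, 2) = s.epos[i].z;
    Vec3 ax = qrot(s.equat[i], Vec3(0, 0, 1));
    enz_axis(i, 0) = ax.x; enz_axis(i, 1) = ax.y; enz_axis(i, 2) = ax.z;
    enz_type[i] = s.etype[i] + 1;
    site_bond[i] = s.site_ligand[i] + 1;  // 0 = none (R-side 1-based)
  }
  for (int i = 0; i < s.n_lig; ++i) {
    lig_pos(i, 0) = s.lpos[i].x; lig_pos(i, 1) = s.lpos[i].y;
    lig_pos(i, 2) = s.lpos[i].z;
    lig_state[i] = s.lstate[i];
  }
  NumericVector hist(s.n_enz);
  for (int k = 1; k <= s.n_enz; ++k) {
    hist[k - 1] = n_cluster_frames > 0
      ? (double)cluster_hist[k] / n_cluster_frames : 0.0;
  }

  return List::create(
    _["steps"] = rec_step,
    _["reaction_counts"] = rec_counts,
    _["ke_per_particle"] = rec_ke,
    _["total_energy"] = rec_energy,
    _["contact_matrix"] = contact_counts,
    _["n_contact_frames"] = (double)n_cluster_frames,
    _["cluster_size_hist"] = hist,
    _["track_x"] = track_x, _["track_y"] = track_y, _["track_z"] = track_z,
    _["enzyme_pos"] = enz_pos, _["enzyme_axis"] = enz_axis,
    _["enzyme_type"] = enz_type,
    _["ligand_pos"] = lig_pos, _["ligand_state"] = lig_state,
    _["site_bond"] = site_bond,
    _["max_bond_valence"] = (double)s.max_valence_seen,
    _["box_side"] = s.L,
    _["dt_internal"] = s.dt,
    _["time_unit_s"] = t0,
    _["diffusion_enzyme"] = s.g_enz > 0 ? 1.0 / s.g_enz : NA_REAL,
    _["diffusion_ligand"] = s.g_lig > 0 ? 1.0 / s.g_lig : NA_REAL
  );
}
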