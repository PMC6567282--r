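// Reduced-unit bead-spring MD core: shifted FENE bonds, cosine angle
// bending, expanded WCA repulsion with per-site excluded-volume
// diameters, complementary-base LJ attraction, harmonic tethers,
// Langevin / Nose-Hoover NVT, and a Berendsen-style P = 0 barostat.
// Triclinic periodic boxes (row-vector convention, as in the R code).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <stdint.h>
using namespace Rcpp;

static const double TWO16 = 1.1224620483093730;  // 2^(1/6)

// xorshift128+ RNG: deterministic across platforms
struct RNG {
  uint64_t s0, s1;
  explicit RNG(uint64_t seed) {
    s0 = seed * 2685821657736338717ULL + 1ULL;
    s1 = seed ^ 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 10; ++i) next();
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y; x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {
    double u1 = unif(), u2 = unif();
    while (u1 <= 1e-300) u1 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

struct Box {
  double H[3][3], Hinv[3][3];
  bool per[3];
  void set(const NumericMatrix& h, const LogicalVector& p) {
    for (int i = 0; i < 3; ++i) {
      per[i] = p[i];
      for (int j = 0; j < 3; ++j) H[i][j] = h(i, j);
    }
    invert();
  }
  void invert() {
    double a = H[0][0], b = H[0][1], c = H[0][2];
    double d = H[1][0], e = H[1][1], f = H[1][2];
    double g = H[2][0], h2 = H[2][1], i2 = H[2][2];
    double det = a * (e * i2 - f * h2) - b * (d * i2 - f * g) +
                 c * (d * h2 - e * g);
    double id = 1.0 / det;
    Hinv[0][0] = (e * i2 - f * h2) * id;
    Hinv[0][1] = (c * h2 - b * i2) * id;
    Hinv[0][2] = (b * f - c * e) * id;
    Hinv[1][0] = (f * g - d * i2) * id;
    Hinv[1][1] = (a * i2 - c * g) * id;
    Hinv[1][2] = (c * d - a * f) * id;
    Hinv[2][0] = (d * h2 - e * g) * id;
    Hinv[2][1] = (b * g - a * h2) * id;
    Hinv[2][2] = (a * e - b * d) * id;
  }
  // minimum image of dr (row vector)
  void minimg(double* dr) const {
    double f[3];
    for (int k = 0; k < 3; ++k)
      f[k] = dr[0] * Hinv[0][k] + dr[1] * Hinv[1][k] + dr[2] * Hinv[2][k];
    for (int k = 0; k < 3; ++k)
      if (per[k]) f[k] -= std::round(f[k]);
    for (int k = 0; k < 3; ++k)
      dr[k] = f[0] * H[0][k] + f[1] * H[1][k] + f[2] * H[2][k];
  }
  double volume() const {
    return std::fabs(
      H[0][0] * (H[1][1] * H[2][2] - H[1][2] * H[2][1]) -
      H[0][1] * (H[1][0] * H[2][2] - H[1][2] * H[2][0]) +
      H[0][2] * (H[1][0] * H[2][1] - H[1][1] * H[2][0]));
  }
};

struct System {
  int n;
  std::vector<double> x, v, f, mass;
  std::vector<double> pdiam;       // excluded-volume diameter per site
  std::vector<int> basecode;       // 0 none, 1 A, 2 T, 3 C, 4 G
  std::vector<int> strand;         // global strand id, 0 = not DNA
  Box box;
  // bonds
  std::vector<int> bi, bj;
  std::vector<double> bkb, bR0, beps, bDel;
  // angles
  std::vector<int> ai, aj, ak;
  std::vector<double> aka;
  // tethers
  std::vector<int> ti;
  std::vector<double> tx, tk;
  // base-pair attraction
  double eps_bp, sig_bp, rc_bp;
  // exclusions (sorted pair keys)
  std::vector<int64_t> excl;
  // neighbour list
  std::vector<int> nb_i, nb_j;
  std::vector<double> x_at_build;
  double skin;
  double maxdiam;

  bool excluded(int i, int j) const {
    int64_t key = (int64_t)std::min(i, j) * 1000000LL + std::max(i, j);
    return std::binary_search(excl.begin(), excl.end(), key);
  }
  bool complementary(int i, int j) const {
    int bi_ = basecode[i], bj_ = basecode[j];
    if (!bi_ || !bj_) return false;
    if (strand[i] == strand[j]) return false;
    return (bi_ == 1 && bj_ == 2) || (bi_ == 2 && bj_ == 1) ||
           (bi_ == 3 && bj_ == 4) || (bi_ == 4 && bj_ == 3);
  }
  double cutoff(int i, int j) const {
    if (complementary(i, j)) return rc_bp;
    return 0.5 * (pdiam[i] + pdiam[j]);    // = Delta_ij + 2^(1/6)
  }
  void build_nblist() {
    nb_i.clear(); nb_j.clear();
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double rc = cutoff(i, j) + skin;
        double dr[3] = { x[3*j] - x[3*i], x[3*j+1] - x[3*i+1],
                         x[3*j+2] - x[3*i+2] };
        box.minimg(dr);
        double r2 = dr[0]*dr[0] + dr[1]*dr[1] + dr[2]*dr[2];
        if (r2 < rc * rc && !excluded(i, j)) {
          nb_i.push_back(i); nb_j.push_back(j);
        }
      }
    }
    x_at_build = x;
  }
  bool need_rebuild() const {
    double md2 = 0;
    for (int i = 0; i < n; ++i) {
      double d2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = x[3*i+k] - x_at_build[3*i+k];
        d2 += d * d;
      }
      if (d2 > md2) md2 = d2;
    }
    return md2 > 0.25 * skin * skin;
  }
};

// Energy + forces; returns energies by term and the scalar virial.
struct EnergyReport {
  double fene, angle, wca, bp, tether, virial;
  bool overstretch; int bad_bond;
  double total() const { return fene + angle + wca + bp + tether; }
};

static EnergyReport compute_forces(System& S) {
  EnergyReport er = {0, 0, 0, 0, 0, 0, false, -1};
  std::fill(S.f.begin(), S.f.end(), 0.0);

  // FENE bonds (with the embedded truncated LJ part)
  for (size_t b = 0; b < S.bi.size(); ++b) {
    int i = S.bi[b], j = S.bj[b];
    double dr[3] = { S.x[3*j] - S.x[3*i], S.x[3*j+1] - S.x[3*i+1],
                     S.x[3*j+2] - S.x[3*i+2] };
    S.box.minimg(dr);
    double r = std::sqrt(dr[0]*dr[0] + dr[1]*dr[1] + dr[2]*dr[2]);
    double s = r - S.bDel[b];
    double R0 = S.bR0[b];
    if (s <= 0.0 || s >= R0) { er.overstretch = true; er.bad_bond = (int)b; continue; }
    double kb = S.bkb[b], eps = S.beps[b];
    double q = s / R0;
    er.fene += -0.5 * kb * R0 * R0 * std::log(1.0 - q * q);
    double dVdr = kb * s / (1.0 - q * q);
    if (s < TWO16) {
      double ir6 = 1.0 / (s*s*s*s*s*s), ir12 = ir6 * ir6;
      er.fene += 4.0 * eps * (ir12 - ir6) + eps;
      dVdr += 4.0 * eps * (-12.0 * ir12 + 6.0 * ir6) / s;
    }
    double fpr = -dVdr / r;          // force on j along +dr
    for (int k = 0; k < 3; ++k) {
      S.f[3*j+k] += fpr * dr[k];
      S.f[3*i+k] -= fpr * dr[k];
    }
    er.virial += -dVdr * r;
  }

  // angle bending V = ka (1 + cos theta), angle at j
  for (size_t a = 0; a < S.ai.size(); ++a) {
    int i = S.ai[a], j = S.aj[a], k = S.ak[a];
    double r1[3] = { S.x[3*i] - S.x[3*j], S.x[3*i+1] - S.x[3*j+1],
                     S.x[3*i+2] - S.x[3*j+2] };
    double r2[3] = { S.x[3*k] - S.x[3*j], S.x[3*k+1] - S.x[3*j+1],
                     S.x[3*k+2] - S.x[3*j+2] };
    S.box.minimg(r1); S.box.minimg(r2);
    double n1 = std::sqrt(r1[0]*r1[0] + r1[1]*r1[1] + r1[2]*r1[2]);
    double n2 = std::sqrt(r2[0]*r2[0] + r2[1]*r2[1] + r2[2]*r2[2]);
    double cth = (r1[0]*r2[0] + r1[1]*r2[1] + r1[2]*r2[2]) / (n1 * n2);
    if (cth > 1.0) cth = 1.0; if (cth < -1.0) cth = -1.0;
    double ka = S.aka[a];
    er.angle += ka * (1.0 + cth);
    // dV/dcos = ka ; grad cth wrt r1, r2
    double fi[3], fk[3];
    for (int d = 0; d < 3; ++d) {
      fi[d] = -ka * (r2[d] / (n1 * n2) - cth * r1[d] / (n1 * n1));
      fk[d] = -ka * (r1[d] / (n1 * n2) - cth * r2[d] / (n2 * n2));
    }
    for (int d = 0; d < 3; ++d) {
      S.f[3*i+d] += fi[d];
      S.f[3*k+d] += fk[d];
      S.f[3*j+d] -= fi[d] + fk[d];
    }
    er.virial += fi[0]*r1[0] + fi[1]*r1[1] + fi[2]*r1[2] +
                 fk[0]*r2[0] + fk[1]*r2[1] + fk[2]*r2[2];
  }

  // non-bonded pairs from the neighbour list
  for (size_t p = 0; p < S.nb_i.size(); ++p) {
    int i = S.nb_i[p], j = S.nb_j[p];
    double dr[3] = { S.x[3*j] - S.x[3*i], S.x[3*j+1] - S.x[3*i+1],
                     S.x[3*j+2] - S.x[3*i+2] };
    S.box.minimg(dr);
    double r2 = dr[0]*dr[0] + dr[1]*dr[1] + dr[2]*dr[2];
    double dVdr = 0.0, E = 0.0;
    if (S.complementary(i, j)) {
      if (r2 >= S.rc_bp * S.rc_bp) continue;
      double r = std::sqrt(r2);
      double sr = S.sig_bp / r;
      double sr6 = sr*sr*sr*sr*sr*sr, sr12 = sr6 * sr6;
      double src = S.sig_bp / S.rc_bp;
      double src6 = src*src*src*src*src*src, src12 = src6 * src6;
      E = 4.0 * S.eps_bp * (sr12 - sr6) - 4.0 * S.eps_bp * (src12 - src6);
      dVdr = 4.0 * S.eps_bp * (-12.0 * sr12 + 6.0 * sr6) / r;
      er.bp += E;
      double fpr = -dVdr / r;
      for (int k = 0; k < 3; ++k) {
        S.f[3*j+k] += fpr * dr[k];
        S.f[3*i+k] -= fpr * dr[k];
      }
      er.virial += -dVdr * r;
    } else {
      double Del = 0.5 * (S.pdiam[i] + S.pdiam[j]) - TWO16;
      double rc = Del + TWO16;
      if (r2 >= rc * rc) continue;
      double r = std::sqrt(r2);
      double s = r - Del;
      if (s <= 0) s = 1e-9;
      double is6 = 1.0 / (s*s*s*s*s*s), is12 = is6 * is6;
      E = 4.0 * (is12 - is6) + 1.0;
      dVdr = 4.0 * (-12.0 * is12 + 6.0 * is6) / s;
      er.wca += E;
      double fpr = -dVdr / r;
      for (int k = 0; k < 3; ++k) {
        S.f[3*j+k] += fpr * dr[k];
        S.f[3*i+k] -= fpr * dr[k];
      }
      er.virial += -dVdr * r;
    }
  }

  // harmonic tethers to fixed points (no virial: external field)
  for (size_t t = 0; t < S.ti.size(); ++t) {
    int i = S.ti[t];
    for (int k = 0; k < 3; ++k) {
      double d = S.x[3*i+k] - S.tx[3*t+k];
      er.tether += 0.5 * S.tk[t] * d * d;
      S.f[3*i+k] -= S.tk[t] * d;
    }
  }
  return er;
}

static System make_system(List sys) {
  System S;
  NumericMatrix X = sys["x"];
  S.n = X.nrow();
  S.x.resize(3 * S.n); S.v.assign(3 * S.n, 0.0); S.f.assign(3 * S.n, 0.0);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) S.x[3*i+k] = X(i, k);
  S.mass = as<std::vector<double> >(sys["mass"]);
  S.pdiam = as<std::vector<double> >(sys["pair_diameter"]);
  S.basecode = as<std::vector<int> >(sys["basecode"]);
  S.strand = as<std::vector<int> >(sys["strand_gid"]);
  S.box.set(as<NumericMatrix>(sys["box"]), as<LogicalVector>(sys["periodic"]));
  S.bi = as<std::vector<int> >(sys["bond_i"]);
  S.bj = as<std::vector<int> >(sys["bond_j"]);
  S.bkb = as<std::vector<double> >(sys["bond_kb"]);
  S.bR0 = as<std::vector<double> >(sys["bond_R0"]);
  S.beps = as<std::vector<double> >(sys["bond_eps"]);
  S.bDel = as<std::vector<double> >(sys["bond_Delta"]);
  S.ai = as<std::vector<int> >(sys["ang_i"]);
  S.aj = as<std::vector<int> >(sys["ang_j"]);
  S.ak = as<std::vector<int> >(sys["ang_k"]);
  S.aka = as<std::vector<double> >(sys["ang_ka"]);
  S.eps_bp = as<double>(sys["eps_bp"]);
  S.sig_bp = as<double>(sys["sig_bp"]);
  S.rc_bp = as<double>(sys["rc_bp"]);
  S.skin = as<double>(sys["skin"]);
  if (sys.containsElementNamed("tether_i")) {
    S.ti = as<std::vector<int> >(sys["tether_i"]);
    NumericMatrix TP = sys["tether_pos"];
    S.tk = as<std::vector<double> >(sys["tether_k"]);
    S.tx.resize(3 * S.ti.size());
    for (size_t t = 0; t < S.ti.size(); ++t)
      for (int k = 0; k < 3; ++k) S.tx[3*t+k] = TP(t, k);
  }
  // exclusions: all bonded pairs, plus any explicit extra pairs
  for (size_t b = 0; b < S.bi.size(); ++b) {
    int i = S.bi[b], j = S.bj[b];
    S.excl.push_back((int64_t)std::min(i, j) * 1000000LL + std::max(i, j));
  }
  if (sys.containsElementNamed("excl_i")) {
    std::vector<int> ei = as<std::vector<int> >(sys["excl_i"]);
    std::vector<int> ej = as<std::vector<int> >(sys["excl_j"]);
    for (size_t t = 0; t < ei.size(); ++t)
      S.excl.push_back((int64_t)std::min(ei[t], ej[t]) * 1000000LL +
                       std::max(ei[t], ej[t]));
  }
  std::sort(S.excl.begin(), S.excl.end());
  S.excl.erase(std::unique(S.excl.begin(), S.excl.end()), S.excl.end());
  S.build_nblist();
  return S;
}

static List report(const System& S, const EnergyReport& er) {
  NumericMatrix X(S.n, 3), F(S.n, 3), V(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int k = 0; k < 3; ++k) {
      X(i, k) = S.x[3*i+k]; F(i, k) = S.f[3*i+k]; V(i, k) = S.v[3*i+k];
    }
  NumericMatrix H(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) H(i, j) = S.box.H[i][j];
  return List::create(
    _["x"] = X, _["v"] = V, _["forces"] = F, _["box"] = H,
    _["energy"] = List::create(
      _["fene"] = er.fene, _["angle"] = er.angle, _["wca"] = er.wca,
      _["base_pair"] = er.bp, _["tether"] = er.tether,
      _["total"] = er.total()),
    _["virial"] = er.virial,
    _["overstretch"] = er.overstretch, _["bad_bond"] = er.bad_bond + 1);
}

// [[Rcpp::export]]
List md_energy_forces(List sys) {
  System S = make_system(sys);
  EnergyReport er = compute_forces(S);
  return report(S, er);
}

// [[Rcpp::export]]
List md_run(List sys, int n_steps, double dt, double T,
            std::string mode, double damp_t, double damp_p,
            int seed, int stride, int thermo_stride,
            Rcpp::Nullable<Rcpp::NumericMatrix> v0 = R_NilValue) {
  System S = make_system(sys);
  RNG rng((uint64_t)seed);
  bool langevin = (mode == "nvt_langevin");
  bool nose = (mode == "nvt_nh" || mode == "npt");
  bool npt = (mode == "npt");
  bool nve = (mode == "nve");
  bool minim = (mode == "min");

  int ndof = 3 * S.n;
  if (v0.isNotNull()) {
    NumericMatrix V0(v0);
    for (int i = 0; i < S.n; ++i)
      for (int k = 0; k < 3; ++k) S.v[3*i+k] = V0(i, k);
  } else if (!minim) {
    // Maxwell-Boltzmann draw, zero total momentum
    double ptot[3] = {0, 0, 0}, mtot = 0;
    for (int i = 0; i < S.n; ++i) {
      double sd = std::sqrt(T / S.mass[i]);
      for (int k = 0; k < 3; ++k) {
        S.v[3*i+k] = sd * rng.norm();
        ptot[k] += S.mass[i] * S.v[3*i+k];
      }
      mtot += S.mass[i];
    }
    for (int i = 0; i < S.n; ++i)
      for (int k = 0; k < 3; ++k) S.v[3*i+k] -= ptot[k] / mtot;
  }

  EnergyReport er = compute_forces(S);
  double xi = 0.0;                       // Nose-Hoover friction
  double Q = ndof * T * damp_t * damp_t; // thermostat inertia
  double lcool = 0.0;                    // minimisation step scale

  std::vector<NumericMatrix> frames;
  std::vector<double> th_step, th_T, th_E, th_K, th_P, th_V;
  std::vector<double> th_fene, th_ang, th_wca, th_bp;
  bool aborted = false; int abort_step = -1;

  for (int step = 1; step <= n_steps; ++step) {
    if (minim) {
      // steepest descent with adaptive step
      double fmax = 0;
      for (int i = 0; i < ndof; ++i)
        fmax = std::max(fmax, std::fabs(S.f[i]));
      if (fmax < 1e-10) break;
      double alpha = (lcool > 0 ? lcool : 0.05 / fmax);
      std::vector<double> xold = S.x;
      double eold = er.total();
      for (int i = 0; i < ndof; ++i) S.x[i] += alpha * S.f[i];
      if (S.need_rebuild()) S.build_nblist();
      er = compute_forces(S);
      if (er.total() > eold || er.overstretch) {
        S.x = xold; lcool = alpha * 0.5;
        er = compute_forces(S);
      } else lcool = alpha * 1.1;
    } else {
      // velocity Verlet; thermostats applied symmetrically
      if (nose) {
        double K = 0;
        for (int i = 0; i < S.n; ++i)
          for (int k = 0; k < 3; ++k)
            K += 0.5 * S.mass[i] * S.v[3*i+k] * S.v[3*i+k];
        xi += dt / 2.0 * (2.0 * K - ndof * T) / Q;
        double sc = std::exp(-xi * dt / 2.0);
        for (int i = 0; i < ndof; ++i) S.v[i] *= sc;
      }
      for (int i = 0; i < S.n; ++i)
        for (int k = 0; k < 3; ++k)
          S.v[3*i+k] += 0.5 * dt * S.f[3*i+k] / S.mass[i];
      for (int i = 0; i < ndof; ++i) S.x[i] += dt * S.v[i];
      if (S.need_rebuild()) S.build_nblist();
      er = compute_forces(S);
      for (int i = 0; i < S.n; ++i)
        for (int k = 0; k < 3; ++k)
          S.v[3*i+k] += 0.5 * dt * S.f[3*i+k] / S.mass[i];
      if (nose) {
        double K = 0;
        for (int i = 0; i < S.n; ++i)
          for (int k = 0; k < 3; ++k)
            K += 0.5 * S.mass[i] * S.v[3*i+k] * S.v[3*i+k];
        xi += dt / 2.0 * (2.0 * K - ndof * T) / Q;
        double sc = std::exp(-xi * dt / 2.0);
        for (int i = 0; i < ndof; ++i) S.v[i] *= sc;
      }
      if (langevin) {
        double c1 = std::exp(-dt / damp_t);
        for (int i = 0; i < S.n; ++i) {
          double sd = std::sqrt(T / S.mass[i] * (1.0 - c1 * c1));
          for (int k = 0; k < 3; ++k)
            S.v[3*i+k] = c1 * S.v[3*i+k] + sd * rng.norm();
        }
      }
      if (npt) {
        // Berendsen-style isotropic relaxation toward P = 0
        double K = 0;
        for (int i = 0; i < S.n; ++i)
          for (int k = 0; k < 3; ++k)
            K += 0.5 * S.mass[i] * S.v[3*i+k] * S.v[3*i+k];
        double vol = S.box.volume();
        double P = (2.0 * K / 3.0 + er.virial / 3.0) / vol;
        double mu = std::cbrt(1.0 + dt / damp_p * P * 0.02);
        if (mu < 0.999) mu = 0.999;
        if (mu > 1.001) mu = 1.001;
        for (int i = 0; i < ndof; ++i) S.x[i] *= mu;
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) S.box.H[i][j] *= mu;
        S.box.invert();
      }
      // abort on non-finite coordinates
      bool bad = false;
      for (int i = 0; i < ndof; ++i)
        if (!std::isfinite(S.x[i])) { bad = true; break; }
      if (bad || er.overstretch) {
        aborted = true; abort_step = step;
        break;
      }
    }

    if (stride > 0 && step % stride == 0) {
      NumericMatrix Xf(S.n, 3);
      for (int i = 0; i < S.n; ++i)
        for (int k = 0; k < 3; ++k) Xf(i, k) = S.x[3*i+k];
      frames.push_back(Xf);
    }
    if (thermo_stride > 0 && step % thermo_stride == 0) {
      double K = 0;
      for (int i = 0; i < S.n; ++i)
        for (int k = 0; k < 3; ++k)
          K += 0.5 * S.mass[i] * S.v[3*i+k] * S.v[3*i+k];
      double vol = S.box.volume();
      th_step.push_back(step);
      th_T.push_back(2.0 * K / ndof);
      th_E.push_back(er.total());
      th_K.push_back(K);
      th_P.push_back((2.0 * K / 3.0 + er.virial / 3.0) / vol);
      th_V.push_back(vol);
      th_fene.push_back(er.fene); th_ang.push_back(er.angle);
      th_wca.push_back(er.wca); th_bp.push_back(er.bp);
    }
  }

  List out = report(S, er);
  out["frames"] = frames;
  out["thermo"] = DataFrame::create(
    _["step"] = th_step, _["T"] = th_T, _["E_pot"] = th_E,
    _["E_kin"] = th_K, _["P"] = th_P, _["volume"] = th_V,
    _["E_fene"] = th_fene, _["E_angle"] = th_ang, _["E_wca"] = th_wca,
    _["E_bp"] = th_bp);
  out["aborted"] = aborted;
  out["abort_step"] = abort_step;
  return out;
}
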