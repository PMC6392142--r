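#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Coarse-grained vacuum Langevin dynamics (BAOAB splitting).
// Energy kJ/mol, length A, mass Da, time ps. With these units
// 1 kJ mol^-1 Da^-1 = 100 A^2 ps^-2, hence the EKIN factor.
// Force terms: harmonic chain bonds, intra-body elastic network,
// 12-6 Lennard-Jones between all non-excluded pairs (no cutoff: the
// attractive tail is the compaction driver), Coulomb between charged
// beads at the supplied dielectric. No solvent.

static const double EKIN = 100.0;      // (A/ps)^2 per kJ/mol/Da
static const double KB = 0.008314462;  // kJ/mol/K

namespace {

struct System {
  int n;
  std::vector<double> x, f, m, q;
  std::vector<int> bi, bj, ei, ej;
  std::vector<double> br0, er0;
  double bond_k, elastic_k, lj_eps, lj_sigma6, coul_k;
  std::vector<char> excl;  // n*n LJ exclusion mask

  void forces() {
    std::fill(f.begin(), f.end(), 0.0);
    // bonds
    for (size_t b = 0; b < bi.size(); ++b) add_harm(bi[b], bj[b], br0[b], bond_k);
    // elastic network
    for (size_t b = 0; b < ei.size(); ++b) add_harm(ei[b], ej[b], er0[b], elastic_k);
    // nonbonded
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (excl[(size_t)i * n + j]) continue;
        double dx = x[3 * i] - x[3 * j];
        double dy = x[3 * i + 1] - x[3 * j + 1];
        double dz = x[3 * i + 2] - x[3 * j + 2];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < 1e-6) r2 = 1e-6;
        double fr = 0.0;  // dU/dr * (-1/r)
        double s6 = lj_sigma6 / (r2 * r2 * r2);
        // F = 24 eps (2 s^12 - s^6) / r, divided by r for vector form
        fr += 24.0 * lj_eps * (2.0 * s6 * s6 - s6) / r2;
        if (q[i] != 0.0 && q[j] != 0.0) {
          double r = std::sqrt(r2);
          fr += coul_k * q[i] * q[j] / (r2 * r);
        }
        f[3 * i] += fr * dx;
        f[3 * i + 1] += fr * dy;
        f[3 * i + 2] += fr * dz;
        f[3 * j] -= fr * dx;
        f[3 * j + 1] -= fr * dy;
        f[3 * j + 2] -= fr * dz;
      }
    }
  }

  void add_harm(int i, int j, double r0, double k) {
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-9) return;
    double fr = -k * (r - r0) / r;
    f[3 * i] += fr * dx;
    f[3 * i + 1] += fr * dy;
    f[3 * i + 2] += fr * dz;
    f[3 * j] -= fr * dx;
    f[3 * j + 1] -= fr * dy;
    f[3 * j + 2] -= fr * dz;
  }
};

}  // namespace

// [[Rcpp::export(name = ".langevin_cg")]]
List langevin_cg(NumericMatrix coords, NumericVector mass, NumericVector charge,
                 IntegerMatrix bonds, NumericVector bond_r0, double bond_k,
                 IntegerMatrix enet, NumericVector enet_r0, double elastic_k,
                 double lj_eps, double lj_sigma, double coul_k,
                 double temperature, double friction, double dt,
                 int n_steps, int report_stride, double seed,
                 int minimize_steps, double minimize_max_disp) {
  System sys;
  sys.n = coords.nrow();
  const int n = sys.n;
  sys.x.resize(3 * n);
  sys.f.resize(3 * n);
  sys.m.resize(n);
  sys.q.resize(n);
  for (int i = 0; i < n; ++i) {
    sys.x[3 * i] = coords(i, 0);
    sys.x[3 * i + 1] = coords(i, 1);
    sys.x[3 * i + 2] = coords(i, 2);
    sys.m[i] = mass[i];
    sys.q[i] = charge[i];
  }
  sys.bond_k = bond_k;
  sys.elastic_k = elastic_k;
  sys.lj_eps = lj_eps;
  sys.lj_sigma6 = std::pow(lj_sigma, 6);
  sys.coul_k = coul_k;
  sys.excl.assign((size_t)n * n, 0);
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    sys.bi.push_back(i);
    sys.bj.push_back(j);
    sys.br0.push_back(bond_r0[b]);
    sys.excl[(size_t)i * n + j] = sys.excl[(size_t)j * n + i] = 1;
  }
  for (int b = 0; b < enet.nrow(); ++b) {
    int i = enet(b, 0) - 1, j = enet(b, 1) - 1;
    sys.ei.push_back(i);
    sys.ej.push_back(j);
    sys.er0.push_back(enet_r0[b]);
    sys.excl[(size_t)i * n + j] = sys.excl[(size_t)j * n + i] = 1;
  }

  // capped-displacement steepest descent before dynamics: relaxes steric
  // overlaps (e.g. tight inter-domain contacts of compact conformers) into
  // the LJ well so the integrator starts from finite forces. The recorded
  // initial frame is the unminimised input.
  std::vector<double> x0(sys.x);
  for (int it = 0; it < minimize_steps; ++it) {
    sys.forces();
    double fmax = 0.0;
    for (size_t k = 0; k < sys.f.size(); ++k)
      fmax = std::max(fmax, std::fabs(sys.f[k]));
    if (fmax < 1.0) break;
    double alpha = minimize_max_disp / fmax;
    for (size_t k = 0; k < sys.x.size(); ++k) sys.x[k] += alpha * sys.f[k];
  }

  abgas::Rng rng(static_cast<uint64_t>(seed));
  std::vector<double> v(3 * n);
  const double kT = KB * temperature;
  for (int i = 0; i < n; ++i) {
    double sd = std::sqrt(EKIN * kT / sys.m[i]);
    for (int d = 0; d < 3; ++d) v[3 * i + d] = sd * rng.norm();
  }

  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);

  // record initial frame; then every report_stride steps; final always
  std::vector<double> frames;
  std::vector<int> frame_steps;
  auto record = [&](int step) {
    frames.insert(frames.end(), sys.x.begin(), sys.x.end());
    frame_steps.push_back(step);
  };
  // frame 0 is the unminimised input conformation
  frames.insert(frames.end(), x0.begin(), x0.end());
  frame_steps.push_back(0);

  sys.forces();
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double am = EKIN * 0.5 * dt / sys.m[i];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += am * sys.f[3 * i + d];
    }
    for (size_t k = 0; k < sys.x.size(); ++k) sys.x[k] += 0.5 * dt * v[k];
    for (int i = 0; i < n; ++i) {
      double sd = std::sqrt(EKIN * kT / sys.m[i]);
      for (int d = 0; d < 3; ++d)
        v[3 * i + d] = c1 * v[3 * i + d] + c2 * sd * rng.norm();
    }
    for (size_t k = 0; k < sys.x.size(); ++k) sys.x[k] += 0.5 * dt * v[k];
    sys.forces();
    for (int i = 0; i < n; ++i) {
      double am = EKIN * 0.5 * dt / sys.m[i];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += am * sys.f[3 * i + d];
    }
    if (step % 50 == 0 || step == n_steps || step % report_stride == 0) {
      for (size_t k = 0; k < sys.x.size(); ++k)
        if (!std::isfinite(sys.x[k]))
          stop("coordinates became non-finite at step %d; reduce dt", step);
    }
    if (step % report_stride == 0 || step == n_steps) record(step);
  }

  const int nf = static_cast<int>(frame_steps.size());
  NumericVector out(frames.begin(), frames.end());
  out.attr("dim") = IntegerVector::create(3, n, nf);
  return List::create(_["frames"] = out,
                      _["steps"] = IntegerVector(frame_steps.begin(), frame_steps.end()));
}
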