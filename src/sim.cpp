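// Core integration loop for the 3D off-lattice center-based model.
//
// Agents are spheres inside a spherical cell. Self-propelled vesicles move
// with intrinsic speed v0 and a heading that is redrawn with probability
// dt/tau per step, where the persistence time tau grows with distance from
// the cell center. Passive objects move only through contact forces.
//
// All randomness goes through R's RNG (unif_rand), so a simulation is fully
// reproducible from set.seed() on the R side, and a pure-R reference stepper
// consuming draws in the same order reproduces trajectories bitwise.
//
// Units: um, min, pN (gamma in pN.min.um^-2 so force/friction is um/min).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

const double PI_ = 3.14159265358979323846;

inline double tau_at(double dist, double tau0, double tau_r, int form,
                     bool gradient_on, double tau_const) {
  if (!gradient_on) return tau_const;
  if (form == 0) return tau0 + tau_r * dist;       // additive
  return tau0 * (1.0 + tau_r * dist);              // multiplicative
}

inline void draw_direction(double *b) {
  // uniform on the unit sphere; consumes exactly two uniforms
  double z = 2.0 * unif_rand() - 1.0;
  double phi = 2.0 * PI_ * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - z * z));
  b[0] = s * std::cos(phi);
  b[1] = s * std::sin(phi);
  b[2] = z;
}

struct Grid {
  double h, lo;
  int nx;
  std::vector<int> head, nxt;

  Grid(double radius, double cell, int n) {
    h = cell;
    lo = -radius;
    nx = std::max(1, (int)std::ceil(2.0 * radius / h));
    head.assign((size_t)nx * nx * nx, -1);
    nxt.assign(n, -1);
  }
  inline int clampi(int i) const { return i < 0 ? 0 : (i >= nx ? nx - 1 : i); }
  inline int cell_of(const double *x) const {
    int ix = clampi((int)std::floor((x[0] - lo) / h));
    int iy = clampi((int)std::floor((x[1] - lo) / h));
    int iz = clampi((int)std::floor((x[2] - lo) / h));
    return ix + nx * (iy + nx * iz);
  }
  void rebuild(const std::vector<double> &pos, const std::vector<int> &ids) {
    std::fill(head.begin(), head.end(), -1);
    for (int k = (int)ids.size() - 1; k >= 0; --k) {
      int i = ids[k];
      int c = cell_of(&pos[3 * i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(NumericMatrix pos0, NumericMatrix dir0, NumericVector radii,
                 IntegerVector kind, List par) {
  const int n = pos0.nrow();
  const double R = as<double>(par["oocyte_radius"]);
  const double v0 = as<double>(par["v0"]);
  const double tau0 = as<double>(par["tau0"]);
  const double tau_r = as<double>(par["tau_r"]);
  const int form = as<int>(par["gradient_form"]);      // 0 additive, 1 multiplicative
  const bool gradient_on = as<bool>(par["gradient_on"]);
  const double tau_const = as<double>(par["tau_const"]);
  const double c_r = as<double>(par["c_r"]);
  const double c_c = as<double>(par["c_c"]);
  const double conf_exp = as<double>(par["confinement_exponent"]);
  const double gamma = as<double>(par["gamma"]);
  const double dt = as<double>(par["dt"]);
  const int n_steps = as<int>(par["n_steps"]);
  const int record_every = as<int>(par["record_every"]);
  const int prob_model = as<int>(par["prob_model"]);   // 0 linear clamp, 1 exponential
  const bool object_motile = as<bool>(par["object_motile"]);

  std::vector<double> pos(3 * n), dir(3 * n), vprev(3 * n, 0.0),
      frc(3 * n, 0.0);
  std::vector<double> eta(n), rad(n);
  std::vector<bool> motile(n);
  std::vector<int> ves_ids;
  std::vector<int> obj_ids;

  double r_ves_max = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) {
      pos[3 * i + d] = pos0(i, d);
      dir[3 * i + d] = dir0(i, d);
    }
    rad[i] = radii[i];
    eta[i] = 6.0 * PI_ * rad[i] * gamma;
    if (kind[i] == 1) {                 // vesicle
      motile[i] = true;
      ves_ids.push_back(i);
      if (rad[i] > r_ves_max) r_ves_max = rad[i];
    } else {                            // passive object
      motile[i] = object_motile;
      obj_ids.push_back(i);
    }
  }

  // pair-list skin: how far beyond contact candidate pairs are collected
  const double skin0 = std::max(0.5, 4.0 * v0 * dt);
  // grid cell >= largest vesicle candidate range (contact + skin);
  // >= 2R/24 keeps the grid cache-resident
  const double cell_h = std::max(2.0 * r_ves_max + skin0, 2.0 * R / 24.0);
  Grid grid(R, cell_h, n);

  const int n_rec = n_steps / record_every + 1;
  NumericVector rec_time(n_rec);
  // recorded positions: n_rec blocks of n x 3
  NumericVector rec_pos((R_xlen_t)n_rec * n * 3);

  auto record = [&](int slot, double t) {
    rec_time[slot] = t;
    R_xlen_t off = (R_xlen_t)slot * n * 3;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        rec_pos[off + 3 * i + d] = pos[3 * i + d];
  };
  record(0, 0.0);

  double max_step_disp = 0.0;
  int slot = 1;

  // Verlet pair list: vesicle-vesicle candidate pairs within deq + skin,
  // rebuilt from the cell grid whenever accumulated drift could let an
  // unlisted pair come into contact (conservative: twice the running
  // per-step maximum displacement must stay below the skin)
  const double skin = skin0;
  std::vector<int> pair_i, pair_j;
  double drift = skin;                   // force a build on the first step

  static const int fwd[13][3] = {
      {1, 0, 0},  {-1, 1, 0}, {0, 1, 0},  {1, 1, 0},
      {-1, -1, 1}, {0, -1, 1}, {1, -1, 1}, {-1, 0, 1},
      {0, 0, 1},  {1, 0, 1},  {-1, 1, 1}, {0, 1, 1}, {1, 1, 1}};

  for (int step = 0; step < n_steps; ++step) {
    // ---- forces ----
    std::fill(frc.begin(), frc.end(), 0.0);

    if (2.0 * drift >= skin) {
      // rebuild candidate pairs via the grid, each pair visited once
      // (own cell with j > i, plus 13 forward neighbour cells)
      drift = 0.0;
      pair_i.clear();
      pair_j.clear();
      grid.rebuild(pos, ves_ids);
      for (size_t k = 0; k < ves_ids.size(); ++k) {
        int i = ves_ids[k];
        const double x0 = pos[3 * i], x1 = pos[3 * i + 1], x2 = pos[3 * i + 2];
        const double ri = rad[i];
        int ix = grid.clampi((int)std::floor((x0 - grid.lo) / grid.h));
        int iy = grid.clampi((int)std::floor((x1 - grid.lo) / grid.h));
        int iz = grid.clampi((int)std::floor((x2 - grid.lo) / grid.h));
        for (int cc = 0; cc <= 13; ++cc) {
          int cx, cy, cz;
          if (cc == 0) { cx = ix; cy = iy; cz = iz; }
          else {
            cx = ix + fwd[cc - 1][0]; cy = iy + fwd[cc - 1][1];
            cz = iz + fwd[cc - 1][2];
            if (cx < 0 || cx >= grid.nx || cy < 0 || cy >= grid.nx ||
                cz < 0 || cz >= grid.nx) continue;
          }
          int c = cx + grid.nx * (cy + grid.nx * cz);
          for (int j = grid.head[c]; j != -1; j = grid.nxt[j]) {
            if (cc == 0 && j <= i) continue;
            double d0 = pos[3 * j] - x0;
            double d1 = pos[3 * j + 1] - x1;
            double d2 = pos[3 * j + 2] - x2;
            double rng_ = ri + rad[j] + skin;
            if (d0 * d0 + d1 * d1 + d2 * d2 < rng_ * rng_) {
              pair_i.push_back(i);
              pair_j.push_back(j);
            }
          }
        }
      }
      // the grid cell reach (one cell = cell_h >= 2 r_ves_max) must cover
      // deq + skin; grow cells if a huge skin ever outruns it
      // (cell_h >= 2 r_ves_max and skin <= cell_h guaranteed by ctor choice)
    }

    // vesicle-vesicle contacts from the pair list
    for (size_t q = 0; q < pair_i.size(); ++q) {
      int i = pair_i[q], j = pair_j[q];
      double d0 = pos[3 * j] - pos[3 * i];
      double d1 = pos[3 * j + 1] - pos[3 * i + 1];
      double d2 = pos[3 * j + 2] - pos[3 * i + 2];
      double deq = rad[i] + rad[j];
      double dist2 = d0 * d0 + d1 * d1 + d2 * d2;
      if (dist2 >= deq * deq || dist2 == 0.0) continue;
      double dist = std::sqrt(dist2);
      double mag = c_r * (1.0 - dist / deq) / dist;
      // push j away from i, i away from j (equal and opposite)
      frc[3 * j] += mag * d0;     frc[3 * i] -= mag * d0;
      frc[3 * j + 1] += mag * d1; frc[3 * i + 1] -= mag * d1;
      frc[3 * j + 2] += mag * d2; frc[3 * i + 2] -= mag * d2;
    }

    // object contacts: brute force against everything else
    for (size_t a = 0; a < obj_ids.size(); ++a) {
      int i = obj_ids[a];
      const double *xi = &pos[3 * i];
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        if (kind[j] == 0 && j < i) continue;  // object-object pair once
        double d0 = pos[3 * j] - xi[0];
        double d1 = pos[3 * j + 1] - xi[1];
        double d2 = pos[3 * j + 2] - xi[2];
        double deq = rad[i] + rad[j];
        double dist2 = d0 * d0 + d1 * d1 + d2 * d2;
        if (dist2 >= deq * deq || dist2 == 0.0) continue;
        double dist = std::sqrt(dist2);
        double mag = c_r * (1.0 - dist / deq) / dist;
        frc[3 * j] += mag * d0;     frc[3 * i] -= mag * d0;
        frc[3 * j + 1] += mag * d1; frc[3 * i + 1] -= mag * d1;
        frc[3 * j + 2] += mag * d2; frc[3 * i + 2] -= mag * d2;
      }
    }

    // ---- per-agent pass: cortex force, heading redraw (in id order),
    //      overdamped velocity and two-step (Adams-Bashforth) update ----
    // pair forces above were all computed from pre-step positions, so
    // updating agent i here cannot affect agent j > i within this step
    double step_dx2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double *xi = &pos[3 * i];
      double dist2c = xi[0] * xi[0] + xi[1] * xi[1] + xi[2] * xi[2];
      double dist = std::sqrt(dist2c);
      double gap = R - dist;               // distance center -> cortex surface
      if (gap < rad[i] && dist > 0.0) {
        // confinement, inward as soon as the sphere touches the boundary
        double u = 1.0 - gap / rad[i];
        double mag = (conf_exp == 2.0) ? c_c * u * u
                                       : c_c * std::pow(u, conf_exp);
        mag /= dist;
        frc[3 * i] -= mag * xi[0];
        frc[3 * i + 1] -= mag * xi[1];
        frc[3 * i + 2] -= mag * xi[2];
      }
      if (motile[i]) {
        double tau = tau_at(dist, tau0, tau_r, form, gradient_on, tau_const);
        double p = (prob_model == 0) ? std::min(1.0, dt / tau)
                                     : 1.0 - std::exp(-dt / tau);
        if (unif_rand() < p) draw_direction(&dir[3 * i]);
      }
      double dx2 = 0.0;
      double dxv[3];
      const double inv_eta = 1.0 / eta[i];
      for (int d = 0; d < 3; ++d) {
        double v = frc[3 * i + d] * inv_eta;
        if (motile[i]) v += v0 * dir[3 * i + d];
        double v_eff = (step == 0) ? v : 1.5 * v - 0.5 * vprev[3 * i + d];
        dxv[d] = dt * v_eff;
        dx2 += dxv[d] * dxv[d];
        vprev[3 * i + d] = v;
      }
      // bounded step: pathological transients (deep overlaps, ejections)
      // cannot run away, and no displacement can outrun the pair-list skin
      const double cap = 0.45 * skin;
      if (dx2 > cap * cap) {
        double sc = cap / std::sqrt(dx2);
        for (int d = 0; d < 3; ++d) dxv[d] *= sc;
        dx2 = cap * cap;
      }
      for (int d = 0; d < 3; ++d) xi[d] += dxv[d];
      if (dx2 > step_dx2) step_dx2 = dx2;
    }
    if (step_dx2 > max_step_disp) max_step_disp = step_dx2;
    drift += std::sqrt(step_dx2);

    if ((step + 1) % record_every == 0) record(slot++, (step + 1) * dt);
  }

  rec_pos.attr("dim") = IntegerVector::create(3, n, n_rec);
  return List::create(_["time"] = rec_time, _["pos"] = rec_pos,
                      _["max_step_disp"] = std::sqrt(max_step_disp));
}
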