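// 3D Vicsek model with a central harmonic force, open boundaries.
// Update rule per step (synchronous, dt = 1):
//   w_i = mean{ v_j : |x_j - x_i| <= rc }  (self included)  - beta * x_i
//   v_i(t+1) = v0 * CapRot_eta( w_i / |w_i| )
//   x_i(t+1) = x_i(t) + v_i(t+1)
// CapRot_eta rotates the unit argument to a direction drawn uniformly from
// the spherical cap of solid angle 4*pi*eta around it (eta = 1: full sphere).
// Neighbour search uses a flat cell grid (cell size rc, counting sort,
// buffers reused across steps); when the bounding box would need too many
// cells the exact brute-force path is used instead, and that path can be
// forced for verification. RNG is R's own stream, so set.seed() makes runs
// bit-reproducible.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct CellGrid {
  std::vector<int> cellof, order, start;
  int ncx, ncy, ncz;
  double minx, miny, minz, rc;

  // Returns false when the grid would be wastefully large (sparse box);
  // caller then falls back to the brute-force scan.
  bool build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, double rc_) {
    rc = rc_;
    const int n = (int)x.size();
    double maxx, maxy, maxz;
    minx = maxx = x[0]; miny = maxy = y[0]; minz = maxz = z[0];
    for (int i = 1; i < n; ++i) {
      if (x[i] < minx) minx = x[i]; else if (x[i] > maxx) maxx = x[i];
      if (y[i] < miny) miny = y[i]; else if (y[i] > maxy) maxy = y[i];
      if (z[i] < minz) minz = z[i]; else if (z[i] > maxz) maxz = z[i];
    }
    ncx = (int)((maxx - minx) / rc) + 1;
    ncy = (int)((maxy - miny) / rc) + 1;
    ncz = (int)((maxz - minz) / rc) + 1;
    double ncells = (double)ncx * ncy * ncz;
    if (ncells > 16.0 * n + 4096.0) return false;
    const int nc = (int)ncells;
    cellof.resize(n); order.resize(n);
    start.assign(nc + 1, 0);
    for (int i = 0; i < n; ++i) {
      int cx = (int)((x[i] - minx) / rc), cy = (int)((y[i] - miny) / rc),
          cz = (int)((z[i] - minz) / rc);
      cellof[i] = cx + ncx * (cy + ncy * cz);
      ++start[cellof[i] + 1];
    }
    for (int c = 0; c < nc; ++c) start[c + 1] += start[c];
    std::vector<int> cursor(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) order[cursor[cellof[i]]++] = i;
    return true;
  }
};

// Direction uniformly distributed on the spherical cap of solid angle
// 4*pi*eta around unit vector d.
inline void cap_rotate(double dx, double dy, double dz, double eta,
                       double& ox, double& oy, double& oz) {
  if (eta <= 0.0) { ox = dx; oy = dy; oz = dz; return; }
  double c = 1.0 - 2.0 * eta * unif_rand();   // cos(theta) ~ U[1-2eta, 1]
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  double phi = 2.0 * M_PI * unif_rand();
  // orthonormal basis (e1, e2) perpendicular to d
  double ax, ay, az;
  if (std::fabs(dx) < 0.9) { ax = 1.0; ay = 0.0; az = 0.0; }
  else { ax = 0.0; ay = 1.0; az = 0.0; }
  double e1x = ay * dz - az * dy, e1y = az * dx - ax * dz,
         e1z = ax * dy - ay * dx;
  double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
  e1x /= n1; e1y /= n1; e1z /= n1;
  double e2x = dy * e1z - dz * e1y, e2y = dz * e1x - dx * e1z,
         e2z = dx * e1y - dy * e1x;
  double pc = std::cos(phi), ps = std::sin(phi);
  ox = c * dx + s * (pc * e1x + ps * e2x);
  oy = c * dy + s * (pc * e1y + ps * e2y);
  oz = c * dz + s * (pc * e1z + ps * e2z);
}

void neighbour_means(const std::vector<double>& x, const std::vector<double>& y,
                     const std::vector<double>& z, const std::vector<double>& vx,
                     const std::vector<double>& vy, const std::vector<double>& vz,
                     double rc, bool use_cells, CellGrid& grid,
                     std::vector<double>& mx, std::vector<double>& my,
                     std::vector<double>& mz) {
  const int n = (int)x.size();
  const double rc2 = rc * rc;
  if (use_cells && grid.build(x, y, z, rc)) {
    for (int i = 0; i < n; ++i) {
      int cx = (int)((x[i] - grid.minx) / rc),
          cy = (int)((y[i] - grid.miny) / rc),
          cz = (int)((z[i] - grid.minz) / rc);
      double sx = 0, sy = 0, sz = 0; int cnt = 0;
      for (int a = std::max(0, cx - 1); a <= std::min(grid.ncx - 1, cx + 1); ++a)
        for (int b = std::max(0, cy - 1); b <= std::min(grid.ncy - 1, cy + 1); ++b)
          for (int c = std::max(0, cz - 1); c <= std::min(grid.ncz - 1, cz + 1); ++c) {
            int cell = a + grid.ncx * (b + grid.ncy * c);
            for (int k = grid.start[cell]; k < grid.start[cell + 1]; ++k) {
              int j = grid.order[k];
              double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
              if (dx * dx + dy * dy + dz * dz <= rc2) {
                sx += vx[j]; sy += vy[j]; sz += vz[j]; ++cnt;
              }
            }
          }
      mx[i] = sx / cnt; my[i] = sy / cnt; mz[i] = sz / cnt;
    }
    return;
  }
  for (int i = 0; i < n; ++i) {
    double sx = 0, sy = 0, sz = 0; int cnt = 0;
    for (int j = 0; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      if (dx * dx + dy * dy + dz * dz <= rc2) {
        sx += vx[j]; sy += vy[j]; sz += vz[j]; ++cnt;
      }
    }
    mx[i] = sx / cnt; my[i] = sy / cnt; mz[i] = sz / cnt;
  }
}

} // namespace

// Mean neighbour velocity for each particle (exposed for verifying the
// cell grid against the brute-force path on small systems).
// [[Rcpp::export]]
NumericMatrix vicsek_neighbour_means_cpp(NumericMatrix pos, NumericMatrix vel,
                                         double rc, bool use_cells) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n),
      mx(n), my(n), mz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  CellGrid grid;
  neighbour_means(x, y, z, vx, vy, vz, rc, use_cells, grid, mx, my, mz);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = mx[i]; out(i, 1) = my[i]; out(i, 2) = mz[i];
  }
  return out;
}

// [[Rcpp::export]]
List vicsek_sim_cpp(int n, double v0, double rc, double eta, double beta,
                    int steps, int transient, int sample_every, int n_samples,
                    double init_radius, bool use_cells,
                    Nullable<NumericMatrix> init_pos,
                    Nullable<NumericMatrix> init_vel) {
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  if (init_pos.isNotNull() && init_vel.isNotNull()) {
    NumericMatrix p(init_pos), v(init_vel);
    for (int i = 0; i < n; ++i) {
      x[i] = p(i, 0); y[i] = p(i, 1); z[i] = p(i, 2);
      vx[i] = v(i, 0); vy[i] = v(i, 1); vz[i] = v(i, 2);
    }
  } else {
    for (int i = 0; i < n; ++i) {
      // uniform in a sphere of radius init_radius
      double r = init_radius * std::cbrt(unif_rand());
      double cz = 1.0 - 2.0 * unif_rand();
      double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
      double ph = 2.0 * M_PI * unif_rand();
      x[i] = r * sz * std::cos(ph); y[i] = r * sz * std::sin(ph); z[i] = r * cz;
      // uniform direction
      double cv = 1.0 - 2.0 * unif_rand();
      double sv = std::sqrt(std::max(0.0, 1.0 - cv * cv));
      double pv = 2.0 * M_PI * unif_rand();
      vx[i] = v0 * sv * std::cos(pv); vy[i] = v0 * sv * std::sin(pv);
      vz[i] = v0 * cv;
    }
  }
  CellGrid grid;
  std::vector<double> mx(n), my(n), mz(n);
  List samples;
  int total = transient + steps;
  for (int step = 1; step <= total; ++step) {
    bool sampling = step > transient &&
      ((step - transient) % sample_every == 0) &&
      samples.size() < (R_xlen_t)n_samples;
    NumericMatrix x_prev;
    if (sampling) {
      x_prev = NumericMatrix(n, 3);
      for (int i = 0; i < n; ++i) {
        x_prev(i, 0) = x[i]; x_prev(i, 1) = y[i]; x_prev(i, 2) = z[i];
      }
    }
    neighbour_means(x, y, z, vx, vy, vz, rc, use_cells, grid, mx, my, mz);
    for (int i = 0; i < n; ++i) {
      double wx = mx[i] - beta * x[i], wy = my[i] - beta * y[i],
             wz = mz[i] - beta * z[i];
      double wn = std::sqrt(wx * wx + wy * wy + wz * wz);
      double dx, dy, dz;
      if (wn > 0) { dx = wx / wn; dy = wy / wn; dz = wz / wn; }
      else {       // degenerate argument: keep previous direction
        double vn = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
        dx = vx[i] / vn; dy = vy[i] / vn; dz = vz[i] / vn;
      }
      double ox, oy, oz;
      cap_rotate(dx, dy, dz, eta, ox, oy, oz);
      vx[i] = v0 * ox; vy[i] = v0 * oy; vz[i] = v0 * oz;
    }
    bool finite = true;
    for (int i = 0; i < n; ++i) {
      x[i] += vx[i]; y[i] += vy[i]; z[i] += vz[i];
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]))
        finite = false;
    }
    if (!finite) stop("non-finite Vicsek state at step %d", step);
    if (sampling) {
      NumericMatrix x_now(n, 3);
      for (int i = 0; i < n; ++i) {
        x_now(i, 0) = x[i]; x_now(i, 1) = y[i]; x_now(i, 2) = z[i];
      }
      samples.push_back(List::create(_["x0"] = x_prev, _["x1"] = x_now,
                                     _["fps"] = 1.0,
                                     _["time_index"] = step));
    }
  }
  return samples;
}
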