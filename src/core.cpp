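// Numerical core: screened-Coulomb grid construction, trilinear
// interpolation, grid-based interaction energies, finite-difference
// forces/torques and the Ermak-McCammon rigid-body propagator.
//
// Unit system: Angstrom, ps, kT, elementary charge. All RNG draws go
// through R's generator (norm_rand), so set.seed() in R controls the
// stream bit-for-bit.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Grid {
  const double *v;
  double ox, oy, oz, h;
  int nx, ny, nz;
  bool empty;

  Grid() : v(nullptr), empty(true) {}
  Grid(const NumericVector &values, const NumericVector &origin,
       double spacing, const IntegerVector &dims) {
    empty = values.size() == 0;
    if (!empty) {
      v = REAL(values);
      ox = origin[0]; oy = origin[1]; oz = origin[2];
      h = spacing;
      nx = dims[0]; ny = dims[1]; nz = dims[2];
      if ((R_xlen_t)nx * ny * nz != values.size())
        stop("grid dims do not match value length");
    }
  }

  // trilinear interpolation; throws if (x,y,z) outside the grid box
  double at(double x, double y, double z, int bead = -1) const {
    double fx = (x - ox) / h, fy = (y - oy) / h, fz = (z - oz) / h;
    if (fx < 0 || fy < 0 || fz < 0 ||
        fx > nx - 1 || fy > ny - 1 || fz > nz - 1) {
      if (bead >= 0)
        stop("bead %d at (%.2f, %.2f, %.2f) is outside the grid",
             bead + 1, x, y, z);
      stop("point (%.2f, %.2f, %.2f) is outside the grid", x, y, z);
    }
    int i = std::min((int)fx, nx - 2), j = std::min((int)fy, ny - 2),
        k = std::min((int)fz, nz - 2);
    double tx = fx - i, ty = fy - j, tz = fz - k;
    const double *p = v;
    auto V = [&](int a, int b, int c) {
      return p[(R_xlen_t)a + (R_xlen_t)nx * (b + (R_xlen_t)ny * c)];
    };
    double c00 = V(i, j, k) * (1 - tx) + V(i + 1, j, k) * tx;
    double c10 = V(i, j + 1, k) * (1 - tx) + V(i + 1, j + 1, k) * tx;
    double c01 = V(i, j, k + 1) * (1 - tx) + V(i + 1, j, k + 1) * tx;
    double c11 = V(i, j + 1, k + 1) * (1 - tx) + V(i + 1, j + 1, k + 1) * tx;
    double c0 = c00 * (1 - ty) + c10 * ty;
    double c1 = c01 * (1 - ty) + c11 * ty;
    return c0 * (1 - tz) + c1 * tz;
  }
};

// quaternion (w,x,y,z) to rotation matrix, row-major
static void quat_to_R(const double q[4], double R[9]) {
  double n = std::sqrt(q[0]*q[0]+q[1]*q[1]+q[2]*q[2]+q[3]*q[3]);
  double w = q[0]/n, x = q[1]/n, y = q[2]/n, z = q[3]/n;
  R[0] = 1-2*(y*y+z*z); R[1] = 2*(x*y-w*z); R[2] = 2*(x*z+w*y);
  R[3] = 2*(x*y+w*z);   R[4] = 1-2*(x*x+z*z); R[5] = 2*(y*z-w*x);
  R[6] = 2*(x*z-w*y);   R[7] = 2*(y*z+w*x);   R[8] = 1-2*(x*x+y*y);
}

static void quat_mult(const double a[4], const double b[4], double out[4]) {
  out[0] = a[0]*b[0]-a[1]*b[1]-a[2]*b[2]-a[3]*b[3];
  out[1] = a[0]*b[1]+a[1]*b[0]+a[2]*b[3]-a[3]*b[2];
  out[2] = a[0]*b[2]-a[1]*b[3]+a[2]*b[0]+a[3]*b[1];
  out[3] = a[0]*b[3]+a[1]*b[2]-a[2]*b[1]+a[3]*b[0];
}

static void quat_from_rotvec(const double w[3], double q[4]) {
  double ang = std::sqrt(w[0]*w[0]+w[1]*w[1]+w[2]*w[2]);
  if (ang < 1e-300) { q[0] = 1; q[1] = q[2] = q[3] = 0; return; }
  double s = std::sin(ang/2) / ang;
  q[0] = std::cos(ang/2); q[1] = s*w[0]; q[2] = s*w[1]; q[3] = s*w[2];
}

// U = sum_i q_i Phi(x_i) + sum_i q_i^2 g(x_i) for beads in pose (pos, R)
static double pose_energy(const double pos[3], const double R[9],
                          const NumericMatrix &coords,
                          const NumericVector &charges,
                          const Grid &pot, const Grid &des) {
  int n = coords.nrow();
  double U = 0.0;
  for (int i = 0; i < n; ++i) {
    double bx = coords(i,0), by = coords(i,1), bz = coords(i,2);
    double x = R[0]*bx + R[1]*by + R[2]*bz + pos[0];
    double y = R[3]*bx + R[4]*by + R[5]*bz + pos[1];
    double z = R[6]*bx + R[7]*by + R[8]*bz + pos[2];
    double q = charges[i];
    U += q * pot.at(x, y, z, i);
    if (!des.empty) U += q * q * des.at(x, y, z, i);
  }
  return U;
}

// lowest lab-frame bead z for the reflecting wall
static double min_bead_z(const double pos[3], const double R[9],
                         const NumericMatrix &coords) {
  int n = coords.nrow();
  double mz = R_PosInf;
  for (int i = 0; i < n; ++i) {
    double z = R[6]*coords(i,0) + R[7]*coords(i,1) + R[8]*coords(i,2) + pos[2];
    if (z < mz) mz = z;
  }
  return mz;
}

// force (kT/A, lab frame) and torque (kT/rad, lab axes) by central
// differences of the pose energy
static void force_torque(const double pos[3], const double quat[4],
                         const NumericMatrix &coords,
                         const NumericVector &charges,
                         const Grid &pot, const Grid &des,
                         double dtr, double drot,
                         double F[3], double T[3]) {
  double R[9];
  quat_to_R(quat, R);
  for (int a = 0; a < 3; ++a) {
    double pp[3] = {pos[0], pos[1], pos[2]};
    pp[a] = pos[a] + dtr;
    double Up = pose_energy(pp, R, coords, charges, pot, des);
    pp[a] = pos[a] - dtr;
    double Um = pose_energy(pp, R, coords, charges, pot, des);
    F[a] = -(Up - Um) / (2 * dtr);
  }
  for (int a = 0; a < 3; ++a) {
    double w[3] = {0, 0, 0}, dq[4], qp[4], qm[4], Rp[9];
    w[a] = drot;
    quat_from_rotvec(w, dq);
    quat_mult(dq, quat, qp);
    w[a] = -drot;
    quat_from_rotvec(w, dq);
    quat_mult(dq, quat, qm);
    quat_to_R(qp, Rp);
    double Up = pose_energy(pos, Rp, coords, charges, pot, des);
    quat_to_R(qm, Rp);
    double Um = pose_energy(pos, Rp, coords, charges, pot, des);
    T[a] = -(Up - Um) / (2 * drot);
  }
}

// [[Rcpp::export]]
NumericVector cpp_dh_grid(NumericVector origin, double spacing,
                          IntegerVector dims, NumericMatrix src,
                          NumericVector q, double kappa_inv, double eps_r,
                          double prefactor, double cap_radius,
                          double cutoff) {
  int nx = dims[0], ny = dims[1], nz = dims[2], ns = src.nrow();
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = REAL(out);
  bool screened = R_finite(kappa_inv);
  double cut2 = cutoff * cutoff;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + k * spacing;
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + j * spacing;
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = origin[0] + i * spacing, phi = 0.0;
        for (int s = 0; s < ns; ++s) {
          double dx = x - src(s,0), dy = y - src(s,1), dz = z - src(s,2);
          double r2 = dx*dx + dy*dy + dz*dz;
          if (r2 > cut2) continue;
          double r = std::sqrt(r2);
          if (r < cap_radius) r = cap_radius;
          double t = prefactor * q[s] / (eps_r * r);
          if (screened) t *= std::exp(-r / kappa_inv);
          phi += t;
        }
        o[idx] = phi;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_desolv_grid(NumericVector origin, double spacing,
                              IntegerVector dims, NumericMatrix src,
                              NumericVector vol, double kappa,
                              double K, double cap_radius, double cutoff) {
  int nx = dims[0], ny = dims[1], nz = dims[2], ns = src.nrow();
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = REAL(out);
  double cut2 = cutoff * cutoff;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + k * spacing;
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + j * spacing;
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = origin[0] + i * spacing, g = 0.0;
        for (int s = 0; s < ns; ++s) {
          double dx = x - src(s,0), dy = y - src(s,1), dz = z - src(s,2);
          double r2 = dx*dx + dy*dy + dz*dz;
          if (r2 > cut2) continue;
          double r = std::sqrt(r2);
          if (r < cap_radius) r = cap_radius;
          double kr = kappa * r;
          g += vol[s] * (1 + kr) * (1 + kr) * std::exp(-2 * kr) / (r2 * r2);
        }
        o[idx] = K * g;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector values, NumericVector origin,
                            double spacing, IntegerVector dims,
                            NumericMatrix pts) {
  Grid g(values, origin, spacing, dims);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = g.at(pts(i,0), pts(i,1), pts(i,2));
  return out;
}

// [[Rcpp::export]]
double cpp_energy(NumericVector pos, NumericVector quat,
                  NumericMatrix coords, NumericVector charges,
                  NumericVector pot_values, NumericVector pot_origin,
                  double pot_spacing, IntegerVector pot_dims,
                  NumericVector des_values, NumericVector des_origin,
                  double des_spacing, IntegerVector des_dims) {
  Grid pot(pot_values, pot_origin, pot_spacing, pot_dims);
  Grid des(des_values, des_origin, des_spacing, des_dims);
  double p[3] = {pos[0], pos[1], pos[2]};
  double q[4] = {quat[0], quat[1], quat[2], quat[3]};
  double R[9];
  quat_to_R(q, R);
  return pose_energy(p, R, coords, charges, pot, des);
}

// [[Rcpp::export]]
List cpp_force_torque(NumericVector pos, NumericVector quat,
                      NumericMatrix coords, NumericVector charges,
                      NumericVector pot_values, NumericVector pot_origin,
                      double pot_spacing, IntegerVector pot_dims,
                      NumericVector des_values, NumericVector des_origin,
                      double des_spacing, IntegerVector des_dims,
                      double delta_trans, double delta_rot) {
  Grid pot(pot_values, pot_origin, pot_spacing, pot_dims);
  Grid des(des_values, des_origin, des_spacing, des_dims);
  double p[3] = {pos[0], pos[1], pos[2]};
  double q[4] = {quat[0], quat[1], quat[2], quat[3]};
  double F[3], T[3];
  force_torque(p, q, coords, charges, pot, des, delta_trans, delta_rot, F, T);
  return List::create(_["force"] = NumericVector::create(F[0], F[1], F[2]),
                      _["torque"] = NumericVector::create(T[0], T[1], T[2]));
}

// steering coordinates for the current pose
static void steer_coords(const double pos[3], const double R[9],
                         const double pip3[3], const double ref[3],
                         double out[3]) {
  double dx = pos[0] - pip3[0], dy = pos[1] - pip3[1];
  out[0] = std::sqrt(dx*dx + dy*dy);
  out[1] = pos[2] - pip3[2];
  double rz = R[6]*ref[0] + R[7]*ref[1] + R[8]*ref[2]; // lab z of ref vector
  double c = -rz;  // angle to -z
  if (c > 1) c = 1; else if (c < -1) c = -1;
  out[2] = std::acos(c) * 180.0 / M_PI;
}

// Propagate one trajectory. Returns recorded samples (time, r, d, theta),
// termination code (1 encounter, 2 escape, 3 timeout), first-encounter
// coordinates (or NULL) and the number of steps taken.
// [[Rcpp::export]]
List cpp_run_trajectory(NumericVector pos0, NumericVector quat0,
                        NumericMatrix coords, NumericVector charges,
                        NumericVector pot_values, NumericVector pot_origin,
                        double pot_spacing, IntegerVector pot_dims,
                        NumericVector des_values, NumericVector des_origin,
                        double des_spacing, IntegerVector des_dims,
                        NumericVector pip3_pos, NumericVector ref_vec,
                        double D_trans, double D_rot,
                        double dt_near, double dt_far, double dt_switch_height,
                        double q_radius, double wall_z, double contact_height,
                        double max_time, double sample_interval,
                        double delta_trans, double delta_rot,
                        double noise_scale, bool forces_on) {
  RNGScope scope;
  Grid pot(pot_values, pot_origin, pot_spacing, pot_dims);
  Grid des(des_values, des_origin, des_spacing, des_dims);

  double pos[3] = {pos0[0], pos0[1], pos0[2]};
  double quat[4] = {quat0[0], quat0[1], quat0[2], quat0[3]};
  double pip3[3] = {pip3_pos[0], pip3_pos[1], pip3_pos[2]};
  double ref[3] = {ref_vec[0], ref_vec[1], ref_vec[2]};

  int max_samples = (int)(max_time / std::max(sample_interval, 1e-12)) + 2;
  if (max_samples > 5000000) stop("sample_interval too small for max_time");
  NumericMatrix samples(max_samples, 4);
  int ns = 0;

  double t = 0.0;
  bool encountered = false;
  int termination = 3; // timeout
  double fe[3] = {NA_REAL, NA_REAL, NA_REAL};
  double sc[3], R[9];
  long n_steps = 0;

  quat_to_R(quat, R);
  steer_coords(pos, R, pip3, ref, sc);
  samples(ns,0) = t; samples(ns,1) = sc[0]; samples(ns,2) = sc[1];
  samples(ns,3) = sc[2]; ++ns;
  double next_sample = sample_interval;

  // initial encounter check (degenerate starts)
  if (min_bead_z(pos, R, coords) <= wall_z + contact_height) {
    encountered = true;
    fe[0] = sc[0]; fe[1] = sc[1]; fe[2] = sc[2];
  }

  while (t < max_time) {
    double dt = (pos[2] < dt_switch_height) ? dt_near : dt_far;
    double F[3] = {0, 0, 0}, T[3] = {0, 0, 0};
    if (forces_on)
      force_torque(pos, quat, coords, charges, pot, des,
                   delta_trans, delta_rot, F, T);

    double st = noise_scale * std::sqrt(2 * D_trans * dt);
    double sr = noise_scale * std::sqrt(2 * D_rot * dt);
    double w[3];
    for (int a = 0; a < 3; ++a) {
      pos[a] += D_trans * dt * F[a] + st * norm_rand();
      w[a] = D_rot * dt * T[a] + sr * norm_rand();
    }
    double dq[4], qn[4];
    quat_from_rotvec(w, dq);
    quat_mult(dq, quat, qn);
    double nq = std::sqrt(qn[0]*qn[0]+qn[1]*qn[1]+qn[2]*qn[2]+qn[3]*qn[3]);
    for (int a = 0; a < 4; ++a) quat[a] = qn[a] / nq;
    quat_to_R(quat, R);

    // reflecting wall at the upper-leaflet headgroup plane
    double mz = min_bead_z(pos, R, coords);
    if (mz < wall_z) {
      pos[2] += 2 * (wall_z - mz);
      mz = min_bead_z(pos, R, coords);
    }
    t += dt;
    ++n_steps;

    if (!encountered && mz <= wall_z + contact_height) {
      encountered = true;
      steer_coords(pos, R, pip3, ref, fe);
    }
    if (t >= next_sample - 1e-9 && ns < max_samples) {
      steer_coords(pos, R, pip3, ref, sc);
      samples(ns,0) = t; samples(ns,1) = sc[0]; samples(ns,2) = sc[1];
      samples(ns,3) = sc[2]; ++ns;
      while (next_sample <= t + 1e-9) next_sample += sample_interval;
    }
    if (pos[0]*pos[0] + pos[1]*pos[1] + pos[2]*pos[2] >= q_radius * q_radius) {
      termination = 2; // escape
      break;
    }
    if ((n_steps & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  if (encountered) termination = 1;

  NumericMatrix out(ns, 4);
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < 4; ++j) out(i,j) = samples(i,j);
  colnames(out) = CharacterVector::create("time", "r", "d", "theta");

  return List::create(
    _["samples"] = out,
    _["termination"] = termination,
    _["first_encounter"] = encountered ?
        (SEXP)NumericVector::create(_["r"] = fe[0], _["d"] = fe[1],
                                    _["theta"] = fe[2]) : R_NilValue,
    _["final_pos"] = NumericVector::create(pos[0], pos[1], pos[2]),
    _["final_quat"] = NumericVector::create(quat[0], quat[1], quat[2], quat[3]),
    _["n_steps"] = (double)n_steps);
}
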