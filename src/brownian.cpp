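#include <Rcpp.h>
using namespace Rcpp;

// Smooth (C1) radial well: U(r) = -depth * (1 - 3t^2 + 2t^3), t = r/radius in [0,1].
// dU/dr = depth * 6 t (1 - t) / radius  (>= 0: force points toward the well center).
static inline void add_well_force(double x, double y, double z,
                                  const double *wc, double radius, double depth,
                                  double &fx, double &fy, double &fz) {
  double dx = x - wc[0], dy = y - wc[1], dz = z - wc[2];
  double r2 = dx * dx + dy * dy + dz * dz;
  double R2 = radius * radius;
  if (r2 >= R2 || r2 < 1e-24) return;
  double r = std::sqrt(r2);
  double t = r / radius;
  double dUdr = depth * 6.0 * t * (1.0 - t) / radius;
  // force = -dU/dr * (unit radial vector)
  double s = -dUdr / r;
  fx += s * dx;
  fy += s * dy;
  fz += s * dz;
}

static inline void total_force(double x, double y, double z,
                               const NumericMatrix &wells,
                               double &fx, double &fy, double &fz) {
  fx = 0.0; fy = 0.0; fz = 0.0;
  for (int w = 0; w < wells.nrow(); ++w) {
    double wc[3] = {wells(w, 0), wells(w, 1), wells(w, 2)};
    add_well_force(x, y, z, wc, wells(w, 3), wells(w, 4), fx, fy, fz);
  }
}

static inline double reflect_coord(double v, double box) {
  // fold into [-box, box]; steps are small so at most a few folds
  while (v > box || v < -box) {
    if (v > box) v = 2.0 * box - v;
    if (v < -box) v = -2.0 * box - v;
  }
  return v;
}

// Overdamped Euler-Maruyama: x <- x + F*D*dt + sqrt(2 D dt) xi, reflecting cube walls.
// Returns saved positions, dims (n_saves, n_mol, 3); frame 0 is the initial state.
// [[Rcpp::export]]
NumericVector bd_simulate_cpp(NumericMatrix x0, int n_steps, double dt, double D,
                              double box_half, NumericMatrix wells, int save_every) {
  int n_mol = x0.nrow();
  int n_saves = n_steps / save_every + 1;
  NumericVector out(Dimension(n_saves, n_mol, 3));
  std::vector<double> px(n_mol), py(n_mol), pz(n_mol);
  for (int m = 0; m < n_mol; ++m) {
    px[m] = x0(m, 0); py[m] = x0(m, 1); pz[m] = x0(m, 2);
    out[0 + (std::size_t)n_saves * m] = px[m];
    out[0 + (std::size_t)n_saves * (m + n_mol)] = py[m];
    out[0 + (std::size_t)n_saves * (m + 2 * n_mol)] = pz[m];
  }
  double sig = std::sqrt(2.0 * D * dt);
  bool has_wells = wells.nrow() > 0;
  int save_idx = 1;
  for (int s = 1; s <= n_steps; ++s) {
    for (int m = 0; m < n_mol; ++m) {
      double fx = 0.0, fy = 0.0, fz = 0.0;
      if (has_wells) total_force(px[m], py[m], pz[m], wells, fx, fy, fz);
      px[m] = reflect_coord(px[m] + D * fx * dt + sig * norm_rand(), box_half);
      py[m] = reflect_coord(py[m] + D * fy * dt + sig * norm_rand(), box_half);
      pz[m] = reflect_coord(pz[m] + D * fz * dt + sig * norm_rand(), box_half);
    }
    if (s % save_every == 0) {
      for (int m = 0; m < n_mol; ++m) {
        out[save_idx + (std::size_t)n_saves * m] = px[m];
        out[save_idx + (std::size_t)n_saves * (m + n_mol)] = py[m];
        out[save_idx + (std::size_t)n_saves * (m + 2 * n_mol)] = pz[m];
      }
      ++save_idx;
    }
  }
  return out;
}

// First-passage sampler: start uniform on the sphere r = r_source, absorb at
// r <= r_sink. Outer boundary reflecting: sphere of radius `b` (outer_type 0)
// or cube of half-edge `b` (outer_type 1). A Brownian-bridge crossing test at
// the absorbing sphere removes the O(sqrt(dt)) overshoot bias: for endpoint
// distances d1, d2 > 0 to the barrier, P(cross) = exp(-d1*d2/(D*dt)).
// [[Rcpp::export]]
List bd_first_passage_cpp(int n_events, double r_source, double r_sink,
                          double D, double dt, int outer_type, double b,
                          NumericMatrix wells, double max_steps,
                          bool bridge_correction) {
  NumericVector times(n_events, NA_REAL);
  int censored = 0;
  double sig = std::sqrt(2.0 * D * dt);
  bool has_wells = wells.nrow() > 0;
  for (int e = 0; e < n_events; ++e) {
    // uniform point on source shell
    double gx = norm_rand(), gy = norm_rand(), gz = norm_rand();
    double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
    if (gn < 1e-12) gn = 1.0;
    double x = r_source * gx / gn, y = r_source * gy / gn, z = r_source * gz / gn;
    double d_old = r_source - r_sink;
    double step = 0.0;
    bool absorbed = false;
    while (step < max_steps) {
      double fx = 0.0, fy = 0.0, fz = 0.0;
      if (has_wells) total_force(x, y, z, wells, fx, fy, fz);
      x += D * fx * dt + sig * norm_rand();
      y += D * fy * dt + sig * norm_rand();
      z += D * fz * dt + sig * norm_rand();
      if (outer_type == 0) {
        double r = std::sqrt(x * x + y * y + z * z);
        if (r > b) {
          double rr = (2.0 * b - r) / r;
          x *= rr; y *= rr; z *= rr;
        }
      } else {
        x = reflect_coord(x, b);
        y = reflect_coord(y, b);
        z = reflect_coord(z, b);
      }
      step += 1.0;
      double r = std::sqrt(x * x + y * y + z * z);
      double d_new = r - r_sink;
      if (d_new <= 0.0) { absorbed = true; break; }
      if (bridge_correction) {
        double q = d_old * d_new / (D * dt);
        if (q < 27.0 && unif_rand() < std::exp(-q)) { absorbed = true; break; }
      }
      d_old = d_new;
      if (step == max_steps) break;
      if (e == 0 && ((long long)step) % 1048576 == 0) checkUserInterrupt();
    }
    if (absorbed) times[e] = step * dt; else ++censored;
  }
  return List::create(_["times"] = times, _["censored"] = censored);
}
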