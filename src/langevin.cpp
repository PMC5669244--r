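#include <Rcpp.h>
using namespace Rcpp;

// Analytic toy adsorption landscapes on the CV s (peptide com height, nm).
// kind: 0 = square_well (tanh-smoothed edges), 1 = gaussian_well,
// 2 = double_well, 3 = harmonic (calibration landscape; depth = force
// constant, no mirror image). Wells 0-2 are mirrored about the midplane
// between the two walls, matching the slab + periodic-image geometry the
// symmetrised profile construction exploits.
struct Landscape {
  int kind;
  double depth, w, edge;
  double c1, c2;        // primary well center and its mirror image
  double d2, c1b, c2b;  // secondary well (double_well only)
};

static inline double sech2(double x) {
  double c = std::cosh(x);
  return 1.0 / (c * c);
}

// smoothed indicator of [c - w/2, c + w/2]
static inline double bump(double s, double c, double w, double e) {
  return 0.5 * (std::tanh((s - (c - 0.5 * w)) / e) - std::tanh((s - (c + 0.5 * w)) / e));
}

static inline double dbump(double s, double c, double w, double e) {
  return 0.5 / e * (sech2((s - (c - 0.5 * w)) / e) - sech2((s - (c + 0.5 * w)) / e));
}

static inline double gwell(double s, double c, double w) {
  double u = (s - c) / w;
  return std::exp(-0.5 * u * u);
}

static double potential(const Landscape& L, double s) {
  switch (L.kind) {
  case 0:
    return -L.depth * (bump(s, L.c1, L.w, L.edge) + bump(s, L.c2, L.w, L.edge));
  case 1:
    return -L.depth * (gwell(s, L.c1, L.w) + gwell(s, L.c2, L.w));
  case 3:
    return 0.5 * L.depth * (s - L.c1) * (s - L.c1);
  default:
    return -L.depth * (gwell(s, L.c1, L.w) + gwell(s, L.c2, L.w))
           - L.d2 * (gwell(s, L.c1b, L.w) + gwell(s, L.c2b, L.w));
  }
}

static double dpotential(const Landscape& L, double s) {
  switch (L.kind) {
  case 0:
    return -L.depth * (dbump(s, L.c1, L.w, L.edge) + dbump(s, L.c2, L.w, L.edge));
  case 1:
    return -L.depth * (-(s - L.c1) / (L.w * L.w) * gwell(s, L.c1, L.w)
                       - (s - L.c2) / (L.w * L.w) * gwell(s, L.c2, L.w));
  case 3:
    return L.depth * (s - L.c1);
  default:
    return -L.depth * (-(s - L.c1) / (L.w * L.w) * gwell(s, L.c1, L.w)
                       - (s - L.c2) / (L.w * L.w) * gwell(s, L.c2, L.w))
           - L.d2 * (-(s - L.c1b) / (L.w * L.w) * gwell(s, L.c1b, L.w)
                     - (s - L.c2b) / (L.w * L.w) * gwell(s, L.c2b, L.w));
  }
}

// [[Rcpp::export(name = ".landscape_potential_cpp")]]
NumericVector landscape_potential_cpp(NumericVector s, List lpar) {
  Landscape L;
  L.kind = as<int>(lpar["kind"]);
  L.depth = as<double>(lpar["depth"]);
  L.w = as<double>(lpar["w"]);
  L.edge = as<double>(lpar["edge"]);
  L.c1 = as<double>(lpar["c1"]);
  L.c2 = as<double>(lpar["c2"]);
  L.d2 = as<double>(lpar["d2"]);
  L.c1b = as<double>(lpar["c1b"]);
  L.c2b = as<double>(lpar["c2b"]);
  NumericVector out(s.size());
  for (R_xlen_t i = 0; i < s.size(); ++i) out[i] = potential(L, s[i]);
  return out;
}

// Overdamped Euler-Maruyama on the landscape plus an accumulating metadynamics
// bias kept on an internal grid (bias value and bias force, linearly
// interpolated). Uses R's RNG so runs are reproducible under set.seed().
// [[Rcpp::export(name = ".run_langevin_cpp")]]
List run_langevin_cpp(List lpar, double s0, int n_steps, double dt,
                      double friction, double kT, int out_stride,
                      bool do_metad, double hill_height, double hill_sigma,
                      int hill_stride, bool well_tempered, double bias_factor,
                      int grid_n) {
  Landscape L;
  L.kind = as<int>(lpar["kind"]);
  L.depth = as<double>(lpar["depth"]);
  L.w = as<double>(lpar["w"]);
  L.edge = as<double>(lpar["edge"]);
  L.c1 = as<double>(lpar["c1"]);
  L.c2 = as<double>(lpar["c2"]);
  L.d2 = as<double>(lpar["d2"]);
  L.c1b = as<double>(lpar["c1b"]);
  L.c2b = as<double>(lpar["c2b"]);
  const double lo = as<double>(lpar["wall_z"]);
  const double hi = as<double>(lpar["image_wall_z"]);
  const double span = hi - lo;

  std::vector<double> Vg(grid_n, 0.0), Fg(grid_n, 0.0);
  const double dx = span / (grid_n - 1);

  const int n_out = n_steps / out_stride;
  NumericVector f_time(n_out), f_cv(n_out);
  std::vector<double> h_time, h_center, h_sigma, h_height;

  const double mob = dt / friction;
  const double noise = std::sqrt(2.0 * kT * dt / friction);
  double s = s0;
  int iout = 0;

  for (int step = 1; step <= n_steps; ++step) {
    double F = -dpotential(L, s);
    if (do_metad) {
      double u = (s - lo) / dx;
      int i = (int)u;
      if (i < 0) i = 0;
      if (i > grid_n - 2) i = grid_n - 2;
      double f = u - i;
      F += (1.0 - f) * Fg[i] + f * Fg[i + 1];
    }
    s += mob * F + noise * norm_rand();
    if (!R_finite(s) || s < lo - 10.0 * span || s > hi + 10.0 * span)
      stop("trajectory diverged at step %d (s = %g); use a smaller dt", step, s);
    while (s < lo || s > hi) {
      if (s < lo) s = 2.0 * lo - s; else s = 2.0 * hi - s;
    }

    if (do_metad && step % hill_stride == 0) {
      double h = hill_height;
      if (well_tempered) {
        // current bias at the deposition point
        double u = (s - lo) / dx;
        int i = (int)u;
        if (i > grid_n - 2) i = grid_n - 2;
        double f = u - i;
        double Vcur = (1.0 - f) * Vg[i] + f * Vg[i + 1];
        h *= std::exp(-Vcur / ((bias_factor - 1.0) * kT));
      }
      int jlo = (int)std::floor((s - 6.0 * hill_sigma - lo) / dx);
      int jhi = (int)std::ceil((s + 6.0 * hill_sigma - lo) / dx);
      if (jlo < 0) jlo = 0;
      if (jhi > grid_n - 1) jhi = grid_n - 1;
      for (int j = jlo; j <= jhi; ++j) {
        double x = lo + j * dx;
        double g = h * std::exp(-0.5 * (x - s) * (x - s) / (hill_sigma * hill_sigma));
        Vg[j] += g;
        Fg[j] += g * (x - s) / (hill_sigma * hill_sigma);
      }
      h_time.push_back(step * dt);
      h_center.push_back(s);
      h_sigma.push_back(hill_sigma);
      h_height.push_back(h);
    }

    if (step % out_stride == 0) {
      f_time[iout] = step * dt;
      f_cv[iout] = s;
      ++iout;
    }
  }

  return List::create(
    _["times"] = f_time, _["cv"] = f_cv,
    _["hill_time"] = wrap(h_time), _["hill_center"] = wrap(h_center),
    _["hill_sigma"] = wrap(h_sigma), _["hill_height"] = wrap(h_height),
    _["final_bias_grid"] = wrap(Vg));
}
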