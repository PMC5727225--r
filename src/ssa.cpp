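#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Predation rate f(g, k) = p * g^(m * k / kmax).  Increasing in g (a fast
// grower is poorly defended), decreasing in k (a predator investing in
// reproduction predates less efficiently).
static inline double fpred(double g, double k, double p, double m, double kmax) {
  return p * std::pow(g, m * k / kmax);
}

// Uniform trait draw on (0, upper]: R's unif_rand() lies in (0, 1), so
// upper * u is already strictly positive; redraw guards against underflow.
static inline double draw_uniform_trait(double upper) {
  double v;
  do {
    v = upper * unif_rand();
  } while (v <= 0.0);
  return v;
}

// Parent-centred normal draw, resampled until inside (0, upper].
// Resampling (rather than reflecting or clipping) keeps the stated open
// support with no probability mass at the bounds.
static inline double draw_normal_trait(double parent, double sigma, double upper) {
  for (int it = 0; it < 1000; ++it) {
    double v = parent + sigma * norm_rand();
    if (v > 0.0 && v <= upper) return v;
  }
  stop("mutation kernel: no admissible trait after 1000 resampling attempts");
  return NA_REAL; // not reached
}

// [[Rcpp::export]]
NumericVector draw_trait_uniform_cpp(int n, double upper) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = draw_uniform_trait(upper);
  return out;
}

// [[Rcpp::export]]
NumericVector draw_trait_normal_cpp(int n, double parent, double sigma, double upper) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = draw_normal_trait(parent, sigma, upper);
  return out;
}

// Per-species type registry: every type ever created, with genealogy.
struct Registry {
  std::vector<int> parent;      // 0 = ancestor (no parent)
  std::vector<double> trait;
  std::vector<double> t_origin;
  std::vector<double> t_extinct; // NaN while extant
  int add(int parent_id, double trait_value, double t) {
    parent.push_back(parent_id);
    trait.push_back(trait_value);
    t_origin.push_back(t);
    t_extinct.push_back(NA_REAL);
    return (int)parent.size(); // 1-based id
  }
};

// Direct-method SSA for the coevolution reaction system.
//
// Reaction channels per extant prey type i (count x_i, trait g_i) and
// predator type l (count y_l, trait k_l):
//   prey birth            b_x * g_i * x_i   (mutant with prob mu_x)
//   competition death     r_c * x_i * (N_x - 1)
//   intrinsic prey death  d_x * x_i
//   predation (pair i,l)  f(g_i, k_l) * x_i * y_l, branching post-draw:
//       prob (1 - k_l)            prey dies only
//       prob k_l * (1 - mu_y)     prey dies, predator l reproduces
//       prob k_l * mu_y           prey dies, mutant predator born
//   predator death        d_y * y_l
//
// Predation is one channel per pair with post-draw branching; the three
// branches have exactly the rates of the separate reactions.
// [[Rcpp::export]]
List ssa_run_cpp(List par,
                 NumericVector init_g, IntegerVector init_x,
                 NumericVector init_k, IntegerVector init_y,
                 double t_max, double sample_dt, double max_events) {
  const double bx = par["b_x"], dx = par["d_x"], rc = par["r_c"], mux = par["mu_x"];
  const double dy = par["d_y"], p = par["p"], m = par["m"], kmax = par["k_max"];
  const bool pred_evolves = par["predator_evolves"];
  const double muy = pred_evolves ? (double)par["mu_y"] : 0.0;
  const bool kernel_normal = as<std::string>(par["mutation_kernel"]) == "normal";
  const double sg = par["sigma_g"], sk = par["sigma_k"];

  Registry regx, regy;

  // active type arrays (parallel); F[i][l] caches f(g_i, k_l)
  std::vector<int> idx, idy;        // registry ids of active types
  std::vector<double> g, x, k, y;   // traits and counts
  std::vector<std::vector<double> > F;

  for (int i = 0; i < init_g.size(); ++i) {
    if (init_x[i] <= 0) continue;
    int id = regx.add(0, init_g[i], 0.0);
    idx.push_back(id); g.push_back(init_g[i]); x.push_back((double)init_x[i]);
  }
  for (int l = 0; l < init_k.size(); ++l) {
    if (init_y[l] <= 0) continue;
    int id = regy.add(0, init_k[l], 0.0);
    idy.push_back(id); k.push_back(init_k[l]); y.push_back((double)init_y[l]);
  }
  for (size_t i = 0; i < g.size(); ++i) {
    std::vector<double> row(k.size());
    for (size_t l = 0; l < k.size(); ++l) row[l] = fpred(g[i], k[l], p, m, kmax);
    F.push_back(row);
  }

  const int n_samples = (int)std::floor(t_max / sample_dt + 1e-9) + 1;
  std::vector<int> sx_idx, sx_type, sy_idx, sy_type;
  std::vector<double> sx_cnt, sy_cnt;
  int next_sample = 0; // 0-based index into the grid

  // event tallies
  long long n_birth = 0, n_birth_mut = 0, n_comp = 0, n_pdeath = 0;
  long long n_pred_only = 0, n_pred_repro = 0, n_pred_mut = 0, n_ydeath = 0;

  double t = 0.0;
  std::vector<double> rowP; // per-prey-type predation propensity buffer
  long long n_events = 0;

  auto record_sample = [&](int sidx) {
    for (size_t i = 0; i < x.size(); ++i) {
      sx_idx.push_back(sidx + 1); sx_type.push_back(idx[i]); sx_cnt.push_back(x[i]);
    }
    for (size_t l = 0; l < y.size(); ++l) {
      sy_idx.push_back(sidx + 1); sy_type.push_back(idy[l]); sy_cnt.push_back(y[l]);
    }
  };

  auto prune_prey = [&](size_t i) {
    regx.t_extinct[idx[i] - 1] = t;
    idx[i] = idx.back(); idx.pop_back();
    g[i] = g.back(); g.pop_back();
    x[i] = x.back(); x.pop_back();
    F[i] = F.back(); F.pop_back();
  };
  auto prune_pred = [&](size_t l) {
    regy.t_extinct[idy[l] - 1] = t;
    idy[l] = idy.back(); idy.pop_back();
    k[l] = k.back(); k.pop_back();
    y[l] = y.back(); y.pop_back();
    for (size_t i = 0; i < F.size(); ++i) {
      F[i][l] = F[i].back(); F[i].pop_back();
    }
  };

  while (t < t_max) {
    if ((++n_events & 0xFFFFF) == 0) checkUserInterrupt();
    if (n_events > (long long)max_events)
      stop("event cap exceeded (max_events = %g); raise it or shorten the run", max_events);

    const size_t nx = x.size(), ny = y.size();
    double Nx = 0.0, Sgx = 0.0;
    for (size_t i = 0; i < nx; ++i) { Nx += x[i]; Sgx += g[i] * x[i]; }
    double Ny = 0.0;
    for (size_t l = 0; l < ny; ++l) Ny += y[l];

    const double a_birth = bx * Sgx;
    const double a_comp  = (Nx > 1.0) ? rc * Nx * (Nx - 1.0) : 0.0;
    const double a_pdie  = dx * Nx;
    rowP.assign(nx, 0.0);
    double a_pred = 0.0;
    for (size_t i = 0; i < nx; ++i) {
      double s = 0.0;
      for (size_t l = 0; l < ny; ++l) s += F[i][l] * y[l];
      rowP[i] = x[i] * s;
      a_pred += rowP[i];
    }
    const double a_ydie = dy * Ny;
    const double R = a_birth + a_comp + a_pdie + a_pred + a_ydie;

    if (R <= 0.0) break; // absorbing: nothing can happen any more

    const double dt = exp_rand() / R;
    const double t_new = t + dt;
    while (next_sample < n_samples && next_sample * sample_dt < t_new) {
      record_sample(next_sample); // state held constant between events
      ++next_sample;
    }
    t = t_new;
    if (t >= t_max) break;

    double u = unif_rand() * R;

    if (u < a_birth) {
      // prey birth, type i chosen with probability proportional to g_i * x_i
      double cum = 0.0; size_t i = 0;
      for (; i < nx; ++i) { cum += bx * g[i] * x[i]; if (u < cum) break; }
      if (i == nx) i = nx - 1;
      if (mux > 0.0 && unif_rand() < mux) {
        ++n_birth_mut;
        double gnew = kernel_normal ? draw_normal_trait(g[i], sg, 1.0)
                                    : draw_uniform_trait(1.0);
        int id = regx.add(idx[i], gnew, t);
        idx.push_back(id); g.push_back(gnew); x.push_back(1.0);
        std::vector<double> row(ny);
        for (size_t l = 0; l < ny; ++l) row[l] = fpred(gnew, k[l], p, m, kmax);
        F.push_back(row);
      } else {
        ++n_birth;
        x[i] += 1.0;
      }
    } else if (u < a_birth + a_comp) {
      // competition death: per-type rate r_c * x_i * (Nx - 1) is prop. to x_i
      double v = (u - a_birth) / (rc * (Nx - 1.0));
      double cum = 0.0; size_t i = 0;
      for (; i < nx; ++i) { cum += x[i]; if (v < cum) break; }
      if (i == nx) i = nx - 1;
      ++n_comp;
      x[i] -= 1.0;
      if (x[i] <= 0.0) prune_prey(i);
    } else if (u < a_birth + a_comp + a_pdie) {
      double v = (u - a_birth - a_comp) / dx;
      double cum = 0.0; size_t i = 0;
      for (; i < nx; ++i) { cum += x[i]; if (v < cum) break; }
      if (i == nx) i = nx - 1;
      ++n_pdeath;
      x[i] -= 1.0;
      if (x[i] <= 0.0) prune_prey(i);
    } else if (u < a_birth + a_comp + a_pdie + a_pred) {
      double v = u - a_birth - a_comp - a_pdie;
      double cum = 0.0; size_t i = 0;
      for (; i < nx; ++i) { cum += rowP[i]; if (v < cum) break; }
      if (i == nx) i = nx - 1;
      // predator type within the row, prob. proportional to F[i][l] * y_l
      double w = unif_rand();
      double rs = 0.0;
      for (size_t l = 0; l < ny; ++l) rs += F[i][l] * y[l];
      double cum2 = 0.0; size_t l = 0;
      for (; l < ny; ++l) { cum2 += F[i][l] * y[l] / rs; if (w < cum2) break; }
      if (l == ny) l = ny - 1;
      const double kl = k[l];
      double b = unif_rand();
      if (b < 1.0 - kl) {
        ++n_pred_only;            // prey consumed, no predator offspring
      } else if (b < 1.0 - kl + kl * (1.0 - muy)) {
        ++n_pred_repro;
        y[l] += 1.0;
      } else {
        ++n_pred_mut;
        double knew = kernel_normal ? draw_normal_trait(kl, sk, kmax)
                                    : draw_uniform_trait(kmax);
        int id = regy.add(idy[l], knew, t);
        idy.push_back(id); k.push_back(knew); y.push_back(1.0);
        for (size_t ii = 0; ii < F.size(); ++ii)
          F[ii].push_back(fpred(g[ii], knew, p, m, kmax));
      }
      x[i] -= 1.0;
      if (x[i] <= 0.0) prune_prey(i);
    } else {
      double v = (u - a_birth - a_comp - a_pdie - a_pred) / dy;
      double cum = 0.0; size_t l = 0;
      for (; l < ny; ++l) { cum += y[l]; if (v < cum) break; }
      if (l == ny) l = ny - 1;
      ++n_ydeath;
      y[l] -= 1.0;
      if (y[l] <= 0.0) prune_pred(l);
    }
  }

  // fill remaining grid points with the final (possibly empty) state
  while (next_sample < n_samples) {
    record_sample(next_sample);
    ++next_sample;
  }

  double Nx_end = 0.0, Ny_end = 0.0;
  for (size_t i = 0; i < x.size(); ++i) Nx_end += x[i];
  for (size_t l = 0; l < y.size(); ++l) Ny_end += y[l];
  std::string status = (Nx_end > 0 && Ny_end > 0) ? "coexistence"
                     : (Nx_end > 0)               ? "predator_extinct"
                     : (Ny_end > 0)               ? "prey_extinct"
                                                  : "both_extinct";

  return List::create(
    _["n_samples"] = n_samples,
    _["sample_dt"] = sample_dt,
    _["prey_sample"] = sx_idx, _["prey_type"] = sx_type, _["prey_count"] = sx_cnt,
    _["pred_sample"] = sy_idx, _["pred_type"] = sy_type, _["pred_count"] = sy_cnt,
    _["prey_registry"] = List::create(
      _["parent"] = regx.parent, _["trait"] = regx.trait,
      _["t_origin"] = regx.t_origin, _["t_extinct"] = regx.t_extinct),
    _["pred_registry"] = List::create(
      _["parent"] = regy.parent, _["trait"] = regy.trait,
      _["t_origin"] = regy.t_origin, _["t_extinct"] = regy.t_extinct),
    _["tallies"] = NumericVector::create(
      _["prey_birth"] = (double)n_birth,
      _["prey_birth_mutant"] = (double)n_birth_mut,
      _["prey_competition_death"] = (double)n_comp,
      _["prey_intrinsic_death"] = (double)n_pdeath,
      _["predation"] = (double)n_pred_only,
      _["predation_reproduction"] = (double)n_pred_repro,
      _["predation_reproduction_mutant"] = (double)n_pred_mut,
      _["predator_death"] = (double)n_ydeath),
    _["status"] = status,
    _["n_events"] = (double)n_events,
    _["t_end"] = t);
}
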