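// Off-lattice cell-centre engine for the colonic crypt simulator.
//
// The crypt is an unrolled cylinder: a laterally periodic 2D rectangle with
// the base at y = 0 and the orifice at y = height.  Cells are elastic discs
// interacting through a linear (Hookean) contact force with an equilibrium
// overlap and an optional constant attraction within a finite reach.  The
// dynamics are overdamped: velocity = sum of force-over-drag contributions,
// integrated with a forward Euler step (the inertialess limit of the
// published scheme); an instability detector aborts if any displacement in a
// single step exceeds the cell radius.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <sstream>

using namespace Rcpp;

static const int PH_A = 0, PH_S = 1, PH_G2 = 2, PH_M = 3, PH_G0 = 4;
static const int CL_STEM = 0, CL_TA = 1;

// ---------------------------------------------------------------------------
// parameters

struct Par {
  // geometry
  double width, height;
  int n_circ, n_len;
  // mechanics (lengths um, times s)
  double k;          // spring constant over drag, 1/s
  double attr;       // attractive force over drag, um/s
  double attr_dist;  // attraction reach beyond physical contact, um
  double delta_eq;   // equilibrium overlap, um
  double dt;         // integration step, s
  bool active, lateral, stem_attached;
  double drift;      // active-migration upward speed, um/s
  // cell cycle (hours, radii um)
  double stem_g1, stem_s, stem_g2, stem_m;
  double ta_g1, ta_s, ta_g2, ta_m;
  double r_min, r_max, mean_radius;
  bool deterministic_cycle;
  bool vertical_only;
  // lineage
  int model;              // 0 = pedigree, 1 = niche
  int n_gen;              // TA generations (pedigree)
  double region;          // proliferation region, fraction of height (niche)
  bool only_new_mature;   // niche scheme A (TRUE) vs B (FALSE)
  bool use_pdf;           // adapted niche: probabilistic maturation
  double pdf_hw;          // ramp half-width, fraction of height
  // run control (hours)
  double max_hours, measure_hours, window, ss_tol;
  // experiments
  bool li_enabled;
  double li_mark, li_chase;   // hours after steady-state onset; chase length
  int clones_n;
  double clones_mark;         // hours after onset
};

static double getd(const List& L, const char* nm) { return as<double>(L[nm]); }
static int geti(const List& L, const char* nm) { return as<int>(L[nm]); }
static bool getb(const List& L, const char* nm) { return as<bool>(L[nm]); }

static Par par_from_list(const List& cfg) {
  Par p;
  p.width = getd(cfg, "width"); p.height = getd(cfg, "height");
  p.n_circ = geti(cfg, "n_circ"); p.n_len = geti(cfg, "n_len");
  p.k = getd(cfg, "k"); p.attr = getd(cfg, "attr");
  p.attr_dist = getd(cfg, "attr_dist"); p.delta_eq = getd(cfg, "delta_eq");
  p.dt = getd(cfg, "dt");
  p.active = getb(cfg, "active"); p.lateral = getb(cfg, "lateral");
  p.stem_attached = getb(cfg, "stem_attached");
  p.drift = getd(cfg, "drift");
  p.stem_g1 = getd(cfg, "stem_g1"); p.stem_s = getd(cfg, "stem_s");
  p.stem_g2 = getd(cfg, "stem_g2"); p.stem_m = getd(cfg, "stem_m");
  p.ta_g1 = getd(cfg, "ta_g1"); p.ta_s = getd(cfg, "ta_s");
  p.ta_g2 = getd(cfg, "ta_g2"); p.ta_m = getd(cfg, "ta_m");
  p.r_min = getd(cfg, "r_min"); p.r_max = getd(cfg, "r_max");
  p.mean_radius = getd(cfg, "mean_radius");
  p.deterministic_cycle = getb(cfg, "deterministic_cycle");
  p.vertical_only = getb(cfg, "vertical_only");
  p.model = geti(cfg, "model"); p.n_gen = geti(cfg, "n_gen");
  p.region = getd(cfg, "region");
  p.only_new_mature = getb(cfg, "only_new_mature");
  p.use_pdf = getb(cfg, "use_pdf"); p.pdf_hw = getd(cfg, "pdf_hw");
  p.max_hours = getd(cfg, "max_hours");
  p.measure_hours = getd(cfg, "measure_hours");
  p.window = getd(cfg, "window"); p.ss_tol = getd(cfg, "ss_tol");
  p.li_enabled = getb(cfg, "li_enabled");
  p.li_mark = getd(cfg, "li_mark"); p.li_chase = getd(cfg, "li_chase");
  p.clones_n = geti(cfg, "clones_n"); p.clones_mark = getd(cfg, "clones_mark");
  return p;
}

// ---------------------------------------------------------------------------
// periodic lateral metric

static inline double wrapx(double x, double w) {
  x -= w * std::floor(x / w);
  if (x >= w) x -= w;   // guard against floating round-up
  return x;
}

// signed minimal lateral separation in (-w/2, w/2]
static inline double wrapdx(double dx, double w) {
  dx -= w * std::round(dx / w);
  return dx;
}

// ---------------------------------------------------------------------------
// population (structure of arrays)

struct Pop {
  std::vector<double> x, y, r, clock_h, ay;
  std::vector<int> phase, cls, gen, clone, id;
  std::vector<char> label, anchored;
  long next_id = 1;

  size_t n() const { return x.size(); }

  void add(double X, double Y, double R, int PH, double CK, int CLS, int GEN,
           char LAB, int CLONE, char ANCH, double AY) {
    x.push_back(X); y.push_back(Y); r.push_back(R);
    phase.push_back(PH); clock_h.push_back(CK);
    cls.push_back(CLS); gen.push_back(GEN);
    label.push_back(LAB); clone.push_back(CLONE);
    anchored.push_back(ANCH); ay.push_back(AY);
    id.push_back((int)next_id++);
  }
};

// ---------------------------------------------------------------------------
// neighbour search: uniform bin grid over the periodic rectangle

template <typename F>
static void for_pairs(const std::vector<double>& x, const std::vector<double>& y,
                      const std::vector<double>& r, double width, double reach,
                      double r_max_hint, F&& fn) {
  const size_t n = x.size();
  if (n < 2) return;
  double cell = 2.0 * r_max_hint + reach + 1e-9;
  int nx = (int)std::floor(width / cell);
  if (nx < 3) {
    // domain too narrow for a periodic stencil: all pairs
    for (size_t i = 0; i + 1 < n; ++i)
      for (size_t j = i + 1; j < n; ++j) {
        double dx = wrapdx(x[j] - x[i], width), dy = y[j] - y[i];
        double lim = r[i] + r[j] + reach;
        if (dx * dx + dy * dy < lim * lim) fn((int)i, (int)j, dx, dy);
      }
    return;
  }
  double binw = width / nx;
  double ymax = 0;
  for (size_t i = 0; i < n; ++i) ymax = std::max(ymax, y[i]);
  int ny = (int)std::floor(ymax / cell) + 1;
  std::vector<int> head((size_t)nx * ny, -1), nxt(n, -1);
  std::vector<int> bx(n), by(n);
  for (size_t i = 0; i < n; ++i) {
    int cx = (int)std::floor(wrapx(x[i], width) / binw); if (cx >= nx) cx = nx - 1;
    int cy = (int)std::floor(std::max(0.0, y[i]) / cell); if (cy >= ny) cy = ny - 1;
    bx[i] = cx; by[i] = cy;
    size_t b = (size_t)cy * nx + cx;
    nxt[i] = head[b]; head[b] = (int)i;
  }
  // half stencil to visit each neighbouring bin pair once
  const int offs[5][2] = { {0,0}, {1,0}, {-1,1}, {0,1}, {1,1} };
  for (int cy = 0; cy < ny; ++cy) {
    for (int cx = 0; cx < nx; ++cx) {
      int a = head[(size_t)cy * nx + cx];
      if (a < 0) continue;
      for (int o = 0; o < 5; ++o) {
        int ox = cx + offs[o][0], oy = cy + offs[o][1];
        if (oy >= ny) continue;
        ox = (ox % nx + nx) % nx;
        int b0 = head[(size_t)oy * nx + ox];
        for (int i = a; i >= 0; i = nxt[i]) {
          int j0 = (o == 0) ? nxt[i] : b0;
          for (int j = j0; j >= 0; j = nxt[j]) {
            double dx = wrapdx(x[j] - x[i], width), dy = y[j] - y[i];
            double lim = r[i] + r[j] + reach;
            if (dx * dx + dy * dy < lim * lim) fn(i, j, dx, dy);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix contact_pairs_cpp(NumericVector x, NumericVector y,
                                NumericVector r, double width, double reach) {
  std::vector<double> X(x.begin(), x.end()), Y(y.begin(), y.end()),
      R(r.begin(), r.end());
  double rmax = 0;
  for (double v : R) rmax = std::max(rmax, v);
  std::vector<std::pair<int, int>> out;
  for_pairs(X, Y, R, width, reach, rmax,
            [&](int i, int j, double, double) {
              out.emplace_back(std::min(i, j) + 1, std::max(i, j) + 1);
            });
  IntegerMatrix m((int)out.size(), 2);
  for (size_t k = 0; k < out.size(); ++k) {
    m(k, 0) = out[k].first; m(k, 1) = out[k].second;
  }
  return m;
}

// ---------------------------------------------------------------------------
// pairwise force (Hooke with equilibrium overlap + constant attraction)

// signed speed along the i->j axis applied to cell i (positive = toward j);
// cell j receives the opposite.
static inline double pair_speed(double dist, double sumr, const Par& p) {
  double delta = sumr - dist;               // overlap (negative if separated)
  if (delta > p.delta_eq) return -p.k * (delta - p.delta_eq);  // repulsion
  if (delta < p.delta_eq) return p.attr;                       // attraction
  return 0.0;
}

// [[Rcpp::export]]
NumericVector pair_force_cpp(double xi, double yi, double xj, double yj,
                             double ri, double rj, double width,
                             double k, double attr, double attr_dist,
                             double delta_eq) {
  Par p{}; p.k = k; p.attr = attr; p.attr_dist = attr_dist; p.delta_eq = delta_eq;
  double dx = wrapdx(xj - xi, width), dy = yj - yi;
  double dist = std::sqrt(dx * dx + dy * dy);
  double ux, uy;
  if (dist < 1e-12) {
    double a = unif_rand() * 2 * M_PI;  // degenerate: random direction
    ux = std::cos(a); uy = std::sin(a); dist = 0.0;
  } else { ux = dx / dist; uy = dy / dist; }
  double s = pair_speed(dist, ri + rj, p);
  return NumericVector::create(ux * s, uy * s);
}

// ---------------------------------------------------------------------------
// one synchronous mechanics step; returns the largest displacement taken

static double mech_step(Pop& P, const Par& p) {
  const size_t n = P.n();
  std::vector<double> vx(n, 0.0), vy(n, 0.0);
  for_pairs(P.x, P.y, P.r, p.width, p.attr_dist, p.r_max,
            [&](int i, int j, double dx, double dy) {
              double dist = std::sqrt(dx * dx + dy * dy);
              double ux, uy;
              if (dist < 1e-12) {
                double a = unif_rand() * 2 * M_PI;
                ux = std::cos(a); uy = std::sin(a);
              } else { ux = dx / dist; uy = dy / dist; }
              double s = pair_speed(dist, P.r[i] + P.r[j], p);
              vx[i] += ux * s; vy[i] += uy * s;
              vx[j] -= ux * s; vy[j] -= uy * s;
            });
  double maxd2 = 0.0;
  for (size_t i = 0; i < n; ++i) {
    if (p.active && !P.anchored[i]) vy[i] += p.drift;
    if (!p.lateral) vx[i] = 0.0;
    if (P.anchored[i]) vy[i] = 0.0;
    double ddx = vx[i] * p.dt, ddy = vy[i] * p.dt;
    double d2 = ddx * ddx + ddy * ddy;
    if (d2 > P.r[i] * P.r[i]) {
      std::ostringstream ss;
      ss << "mechanics instability: cell " << P.id[i] << " displacement "
         << std::sqrt(d2) << " um exceeds its radius " << P.r[i]
         << " um in one step; reduce dt or k_over_eta";
      stop(ss.str());
    }
    if (d2 > maxd2) maxd2 = d2;
    P.x[i] = wrapx(P.x[i] + ddx, p.width);
    P.y[i] = P.y[i] + ddy;
    if (P.y[i] < 0) P.y[i] = 0;
    if (P.anchored[i]) P.y[i] = P.ay[i];
  }
  return std::sqrt(maxd2);
}

// [[Rcpp::export]]
List mechanics_step_cpp(NumericVector x, NumericVector y, NumericVector r,
                        LogicalVector anchored, List mech) {
  Par p{};
  p.width = getd(mech, "width");
  p.k = getd(mech, "k"); p.attr = getd(mech, "attr");
  p.attr_dist = getd(mech, "attr_dist"); p.delta_eq = getd(mech, "delta_eq");
  p.dt = getd(mech, "dt");
  p.active = getb(mech, "active"); p.lateral = getb(mech, "lateral");
  p.drift = getd(mech, "drift");
  p.r_max = 0;
  for (double v : r) p.r_max = std::max(p.r_max, v);
  Pop P;
  for (int i = 0; i < x.size(); ++i)
    P.add(x[i], y[i], r[i], PH_G0, 0, CL_TA, 0, 0, 0, anchored[i] ? 1 : 0, y[i]);
  double md = mech_step(P, p);
  return List::create(_["x"] = NumericVector(P.x.begin(), P.x.end()),
                      _["y"] = NumericVector(P.y.begin(), P.y.end()),
                      _["max_displacement"] = md);
}

// ---------------------------------------------------------------------------
// Smith-Martin phase A sampler (the engine's per-step exit rule, isolated)

// [[Rcpp::export]]
NumericVector phase_a_durations_cpp(int n, double g1_mean, double dt_seconds) {
  double dt_h = dt_seconds / 3600.0;
  double pexit = 1.0 - std::exp(-dt_h / g1_mean);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    long steps = 1;
    while (unif_rand() >= pexit) ++steps;
    out[i] = steps * dt_h;
  }
  return out;
}

// ---------------------------------------------------------------------------
// engine

struct Engine {
  Par p;
  Pop P;
  double dt_h;
  double grow_stem, grow_ta;   // area growth rates, um^2 / h
  double pexit_stem, pexit_ta;
  long births_hour = 0, exits_hour = 0;

  Engine(const Par& par) : p(par) {
    dt_h = p.dt / 3600.0;
    double a0 = M_PI * p.mean_radius * p.mean_radius;
    grow_stem = a0 / (p.stem_g1 + p.stem_g2);
    grow_ta = a0 / (p.ta_g1 + p.ta_g2);
    pexit_stem = 1.0 - std::exp(-dt_h / p.stem_g1);
    pexit_ta = 1.0 - std::exp(-dt_h / p.ta_g1);
  }

  double boundary() const { return p.region * p.height; }

  double pdf_prob(double y) const {
    double hw = p.pdf_hw * p.height, b = boundary();
    if (y <= b - hw) return 0.0;
    if (y >= b + hw) return 1.0;
    return (y - (b - hw)) / (2.0 * hw);
  }

  void init() {
    // one row of cells, evenly spaced, at the crypt base
    double spacing = p.width / p.n_circ;
    for (int i = 0; i < p.n_circ; ++i) {
      double x0 = (i + 0.5) * spacing;
      int cls = (p.model == 0) ? CL_STEM : CL_TA;
      char anch = (p.model == 0 && p.stem_attached) ? 1 : 0;
      // unsynchronised start: random point of the expected cycle
      double g1 = (cls == CL_STEM) ? p.stem_g1 : p.ta_g1;
      double s = (cls == CL_STEM) ? p.stem_s : p.ta_s;
      double g2 = (cls == CL_STEM) ? p.stem_g2 : p.ta_g2;
      double m = (cls == CL_STEM) ? p.stem_m : p.ta_m;
      double tb = s + g2 + m, tc = g1 + tb;
      double u = unif_rand() * tc;
      int ph; double ck, rad = p.mean_radius;
      if (u < g1 || p.deterministic_cycle) {
        ph = PH_A; ck = p.deterministic_cycle ? unif_rand() * g1 : 0.0;
      } else {
        double v = u - g1;
        if (v < s) { ph = PH_S; ck = v; }
        else if (v < s + g2) { ph = PH_G2; ck = v - s; }
        else { ph = PH_M; ck = v - s - g2; }
        rad = p.r_min;  // part-grown when already past G1
      }
      P.add(x0, p.mean_radius, rad, ph, ck, cls, 0, 0, 0, anch, p.mean_radius);
    }
  }

  // --- cycle advance + growth; fills `dividing`
  void cycle_step(std::vector<int>& dividing) {
    dividing.clear();
    const size_t n = P.n();
    for (size_t i = 0; i < n; ++i) {
      int ph = P.phase[i];
      if (ph == PH_G0) continue;
      bool stem = (P.cls[i] == CL_STEM);
      double g1 = stem ? p.stem_g1 : p.ta_g1;
      double s = stem ? p.stem_s : p.ta_s;
      double g2 = stem ? p.stem_g2 : p.ta_g2;
      double m = stem ? p.stem_m : p.ta_m;
      double pexit = stem ? pexit_stem : pexit_ta;
      if (ph == PH_A) {
        if (p.deterministic_cycle) {
          P.clock_h[i] += dt_h;
          if (P.clock_h[i] >= g1 && P.r[i] >= p.r_min) {
            P.clock_h[i] = 0; P.phase[i] = PH_S;
          }
        } else if (P.r[i] >= p.r_min && unif_rand() < pexit) {
          P.clock_h[i] = 0; P.phase[i] = PH_S;
        }
      } else if (ph == PH_S) {
        P.clock_h[i] += dt_h;
        if (P.clock_h[i] >= s) { P.clock_h[i] -= s; P.phase[i] = PH_G2; }
      } else if (ph == PH_G2) {
        P.clock_h[i] += dt_h;
        if (P.clock_h[i] >= g2) { P.clock_h[i] -= g2; P.phase[i] = PH_M; }
      } else if (ph == PH_M) {
        P.clock_h[i] += dt_h;
        if (P.clock_h[i] >= m) dividing.push_back((int)i);
      }
      // growth during G1 (=A) and G2 only
      int ph2 = P.phase[i];
      if (ph2 == PH_A || ph2 == PH_G2) {
        double area = M_PI * P.r[i] * P.r[i] + (stem ? grow_stem : grow_ta) * dt_h;
        double rr = std::sqrt(area / M_PI);
        P.r[i] = std::min(rr, p.r_max);
      }
    }
  }

  // --- niche scheme-B / pdf fate checks (G1 cells above the boundary mature)
  void fate_step(bool hourly_tick) {
    if (p.model != 1) return;
    if (p.only_new_mature) return;  // scheme A: birth-time rule only
    double b = boundary();
    for (size_t i = 0; i < P.n(); ++i) {
      if (P.phase[i] != PH_A) continue;
      if (p.use_pdf) {
        // probabilistic maturation, evaluated at hourly checkpoints
        if (hourly_tick && unif_rand() < pdf_prob(P.y[i])) P.phase[i] = PH_G0;
      } else if (P.y[i] > b) {
        P.phase[i] = PH_G0;
      }
    }
  }

  // maturity of a newborn niche daughter
  int newborn_phase(double yb) {
    if (p.model != 1) return PH_A;
    if (p.use_pdf) return (unif_rand() < pdf_prob(yb)) ? PH_G0 : PH_A;
    return (yb > boundary()) ? PH_G0 : PH_A;
  }

  void do_divisions(const std::vector<int>& dividing) {
    for (int i : dividing) {
      double rm = P.r[i];
      double rd = rm / std::sqrt(2.0);  // each daughter has half the area
      double axx = 0.0, axy = 1.0;
      if (!p.vertical_only) {
        double a = unif_rand() * 2 * M_PI;
        axx = std::cos(a); axy = std::sin(a);
      }
      if (unif_rand() < 0.5) { axx = -axx; axy = -axy; }
      double x0 = P.x[i], y0 = P.y[i];
      char lab = P.label[i];
      int cln = P.clone[i];
      if (p.model == 0 && P.cls[i] == CL_STEM) {
        // asymmetric division: one daughter is the renewed stem.  An
        // anchored stem is pinned to its basal station, so it stays put and
        // the TA1 daughter buds off upward at touching distance.  A free
        // stem divides like any other cell: the daughters straddle the
        // mother centre, the stem taking the slot given by the (random)
        // axis sign.
        P.r[i] = rd; P.phase[i] = PH_A; P.clock_h[i] = 0;
        double xd, yd;
        if (P.anchored[i]) {
          double dxx = axx, dxy = axy;
          if (dxy < 0) { dxx = -dxx; dxy = -dxy; }
          xd = wrapx(x0 + dxx * 2 * rd, p.width);
          yd = std::max(0.0, y0 + dxy * 2 * rd);
        } else {
          P.x[i] = wrapx(x0 - axx * rd, p.width);
          P.y[i] = std::max(0.0, y0 - axy * rd);
          xd = wrapx(x0 + axx * rd, p.width);
          yd = std::max(0.0, y0 + axy * rd);
        }
        P.add(xd, yd, rd, PH_A, 0, CL_TA, 1, lab, cln, 0, 0);
        ++births_hour;
        continue;
      }
      // symmetric division: daughters straddle the mother centre
      int cls_d = CL_TA, gen_d = 0;
      bool both_mature = false;
      if (p.model == 0) {
        gen_d = P.gen[i] + 1;
        if (P.gen[i] >= p.n_gen) both_mature = true;  // TA_n -> two mature
        if (both_mature) gen_d = P.gen[i];
      }
      double x1 = wrapx(x0 + axx * rd, p.width), y1 = std::max(0.0, y0 + axy * rd);
      double x2 = wrapx(x0 - axx * rd, p.width), y2 = std::max(0.0, y0 - axy * rd);
      int ph1, ph2;
      if (p.model == 0) {
        ph1 = ph2 = both_mature ? PH_G0 : PH_A;
      } else {
        ph1 = newborn_phase(y1); ph2 = newborn_phase(y2);
      }
      // mother slot becomes daughter 1
      P.x[i] = x1; P.y[i] = y1; P.r[i] = rd;
      P.phase[i] = ph1; P.clock_h[i] = 0; P.cls[i] = cls_d; P.gen[i] = gen_d;
      P.add(x2, y2, rd, ph2, 0, cls_d, gen_d, lab, cln, 0, 0);
      ++births_hour;  // two daughters replace the mother: one net new cell
    }
  }

  int remove_exited() {
    size_t w = 0;
    int removed = 0;
    for (size_t i = 0; i < P.n(); ++i) {
      if (P.y[i] > p.height) { ++removed; continue; }
      if (w != i) {
        P.x[w] = P.x[i]; P.y[w] = P.y[i]; P.r[w] = P.r[i];
        P.phase[w] = P.phase[i]; P.clock_h[w] = P.clock_h[i];
        P.cls[w] = P.cls[i]; P.gen[w] = P.gen[i];
        P.label[w] = P.label[i]; P.clone[w] = P.clone[i];
        P.anchored[w] = P.anchored[i]; P.ay[w] = P.ay[i];
        P.id[w] = P.id[i];
      }
      ++w;
    }
    P.x.resize(w); P.y.resize(w); P.r.resize(w);
    P.phase.resize(w); P.clock_h.resize(w); P.cls.resize(w); P.gen.resize(w);
    P.label.resize(w); P.clone.resize(w); P.anchored.resize(w); P.ay.resize(w);
    P.id.resize(w);
    return removed;
  }

  void mark_li() {
    for (size_t i = 0; i < P.n(); ++i)
      if (P.phase[i] == PH_S) P.label[i] = 1;
  }

  void mark_clones() {
    double rowh = p.height / p.n_len;
    std::vector<int> base;
    for (size_t i = 0; i < P.n(); ++i)
      if (P.y[i] < rowh) base.push_back((int)i);
    if ((int)base.size() < p.clones_n)
      stop("cannot mark %d clones: only %d cells in the base row",
           p.clones_n, (int)base.size());
    // sample without replacement from the run's stream
    for (int c = 1; c <= p.clones_n; ++c) {
      int pick = (int)std::floor(unif_rand() * base.size());
      if (pick >= (int)base.size()) pick = (int)base.size() - 1;
      P.clone[base[pick]] = c;
      base.erase(base.begin() + pick);
    }
  }

  List state_list() const {
    size_t n = P.n();
    return List::create(
        _["id"] = IntegerVector(P.id.begin(), P.id.end()),
        _["x"] = NumericVector(P.x.begin(), P.x.end()),
        _["y"] = NumericVector(P.y.begin(), P.y.end()),
        _["radius"] = NumericVector(P.r.begin(), P.r.end()),
        _["phase"] = IntegerVector(P.phase.begin(), P.phase.end()),
        _["clock"] = NumericVector(P.clock_h.begin(), P.clock_h.end()),
        _["class"] = IntegerVector(P.cls.begin(), P.cls.end()),
        _["generation"] = IntegerVector(P.gen.begin(), P.gen.end()),
        _["label"] = IntegerVector(P.label.begin(), P.label.end()),
        _["clone"] = IntegerVector(P.clone.begin(), P.clone.end()),
        _["n"] = (int)n);
  }
};

// [[Rcpp::export]]
List run_crypt_cpp(List cfg, NumericVector snapshot_hours) {
  Par p = par_from_list(cfg);
  Engine E(p);
  E.init();

  long steps_per_hour = std::lround(3600.0 / p.dt);
  if (std::fabs(steps_per_hour * p.dt - 3600.0) > 1e-6)
    stop("dt must divide one hour exactly (got %f s)", p.dt);

  std::vector<double> hrs, tot, prolif, mature, stems, births, exits;
  std::vector<double> totals;  // hourly totals for the gradient window
  double onset = NA_REAL;
  long pos_hours = 0;          // consecutive hours with gradient > tol
  bool seen_positive = false;
  bool li_marked = false, clones_marked = false;
  double stop_hour = p.max_hours;
  bool have_stop = false;

  double max_snap = 0;
  for (double h : snapshot_hours) max_snap = std::max(max_snap, h);
  List snaps;
  CharacterVector snap_names;

  // record the initial state (hour 0)
  auto record = [&](double hour) {
    int np = 0, nm = 0, ns = 0;
    for (size_t i = 0; i < E.P.n(); ++i) {
      if (E.P.phase[i] == PH_G0) ++nm; else ++np;
      if (E.P.cls[i] == CL_STEM) ++ns;
    }
    hrs.push_back(hour); tot.push_back((double)E.P.n());
    prolif.push_back(np); mature.push_back(nm); stems.push_back(ns);
    births.push_back((double)E.births_hour);
    exits.push_back((double)E.exits_hour);
    E.births_hour = 0; E.exits_hour = 0;
    totals.push_back((double)E.P.n());
  };
  record(0.0);

  std::vector<int> dividing;
  long hour = 0;
  while (hour < (long)std::ceil(p.max_hours)) {
    for (long s = 0; s < steps_per_hour; ++s) {
      E.cycle_step(dividing);
      E.fate_step(s == steps_per_hour - 1);
      E.do_divisions(dividing);
      mech_step(E.P, p);
      E.exits_hour += E.remove_exited();
      if (E.P.n() > 50000) stop("population exploded (>50000 cells)");
    }
    ++hour;
    record((double)hour);

    // 12-h moving-average gradient of total cell number
    long w = (long)p.window;
    if (!have_stop && hour >= w) {
      double g = (totals[hour] - totals[hour - w]) / (double)w;
      // arm only after the gradient has been clearly positive for a full
      // window: early division lulls in the small founding population must
      // not masquerade as the post-growth plateau
      if (g > p.ss_tol) {
        if (++pos_hours >= w) seen_positive = true;
      } else if (!seen_positive) {
        pos_hours = 0;
      }
      if (seen_positive && std::fabs(g) < p.ss_tol) {
        onset = (double)hour;
        if (p.li_enabled)
          stop_hour = onset + p.li_mark + p.li_chase;
        else
          stop_hour = onset + p.measure_hours;
        stop_hour = std::max(stop_hour, max_snap);
        stop_hour = std::min(stop_hour, p.max_hours);
        have_stop = true;
      }
    }
    if (have_stop) {
      if (p.li_enabled && !li_marked && hour >= (long)(onset + p.li_mark)) {
        E.mark_li(); li_marked = true;
      }
      if (p.clones_n > 0 && !clones_marked &&
          hour >= (long)(onset + p.clones_mark)) {
        E.mark_clones(); clones_marked = true;
      }
    }
    for (double h : snapshot_hours) {
      if ((long)h == hour) {
        snaps.push_back(E.state_list());
        snap_names.push_back(std::to_string(hour));
      }
    }
    if (have_stop && hour >= (long)std::ceil(stop_hour)) break;
    Rcpp::checkUserInterrupt();
  }

  size_t nh = hrs.size();
  NumericMatrix series(nh, 7);
  for (size_t i = 0; i < nh; ++i) {
    series(i, 0) = hrs[i]; series(i, 1) = tot[i]; series(i, 2) = prolif[i];
    series(i, 3) = mature[i]; series(i, 4) = stems[i];
    series(i, 5) = births[i]; series(i, 6) = exits[i];
  }
  colnames(series) = CharacterVector::create(
      "hour", "total", "proliferative", "mature", "stem", "births", "exits");
  if (snaps.size() > 0) snaps.attr("names") = snap_names;
  return List::create(_["series"] = series, _["onset"] = onset,
                      _["state"] = E.state_list(), _["snapshots"] = snaps,
                      _["reached_steady_state"] = have_stop);
}
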