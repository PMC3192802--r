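// 3D Brownian dynamics with analytic ray-traced reflections in a
// cylindrical dendrite with annular barrier disks (narrow openings),
// optional spine (neck cylinder + tangent head sphere on the lateral
// wall) and absorbing/reflecting end caps. Euler scheme with adaptive
// step size; per-particle clocks reconciled at sampling ticks.
//
// Units: um, s, um^2/s. RNG: R's own generator (seeded determinism).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double PUSH = 1e-9;   // push-off distance after a reflection
static const double TGEO = 1e-12;  // parametric tolerance

struct Spine {
  bool present = false;
  double x0 = 0, neck_r = 0, neck_len = 0, head_r = 0;
  bool head_absorbing = false;
  double z_top = 0, z_c = 0; // neck top plane, head sphere center z
};

struct SceneC {
  double R, L;
  int cap0, cap1;            // 0 reflect, 1 absorb, 2 reflect + absorbing axial hole
  double cap0_hole, cap1_hole;
  std::vector<double> bx, br, bcy, bcz;
  Spine sp;
  double min_scale;          // smallest geometric feature to resolve
};

struct P3 { double x, y, z; };

static inline double lat2(const SceneC& sc, const P3& p) {
  double dx = p.x - sc.sp.x0;
  return dx * dx + p.y * p.y;
}

static bool inside(const SceneC& sc, const P3& p) {
  double r2 = p.y * p.y + p.z * p.z;
  bool in_cyl = r2 <= sc.R * sc.R * (1 + 1e-9) && p.x >= -1e-9 && p.x <= sc.L + 1e-9;
  if (in_cyl) return true;
  if (!sc.sp.present) return false;
  if (p.z > 0 && p.z <= sc.sp.z_top + 1e-9 && lat2(sc, p) <= sc.sp.neck_r * sc.sp.neck_r * (1 + 1e-9))
    return true;
  double ddx = p.x - sc.sp.x0, ddy = p.y, ddz = p.z - sc.sp.z_c;
  if (p.z >= sc.sp.z_top - 1e-9 &&
      ddx * ddx + ddy * ddy + ddz * ddz <= sc.sp.head_r * sc.sp.head_r * (1 + 1e-9))
    return true;
  return false;
}

static bool in_spine(const SceneC& sc, const P3& p) {
  if (!sc.sp.present) return false;
  double r2 = p.y * p.y + p.z * p.z;
  return r2 > sc.R * sc.R && inside(sc, p);
}

// earliest event on segment p -> p + d; returns event code:
// 0 none, 1 reflect (normal in n), 2 absorbed
struct Event { int code = 0; double t = 2.0; P3 n{0, 0, 0}; };

static void consider_reflect(Event& ev, double t, double nx, double ny, double nz) {
  if (t > TGEO && t <= 1.0 && t < ev.t) { ev.code = 1; ev.t = t; ev.n = {nx, ny, nz}; }
}
static void consider_absorb(Event& ev, double t) {
  if (t > TGEO && t <= 1.0 && t < ev.t) { ev.code = 2; ev.t = t; }
}

static Event next_event(const SceneC& sc, const P3& p, const P3& d) {
  Event ev;
  const Spine& sp = sc.sp;

  // --- cylinder lateral wall (outward crossings only) ---
  double a2 = d.y * d.y + d.z * d.z;
  if (a2 > 0) {
    double b = 2 * (p.y * d.y + p.z * d.z);
    double c = p.y * p.y + p.z * p.z - sc.R * sc.R;
    double disc = b * b - 4 * a2 * c;
    if (disc > 0) {
      double sq = std::sqrt(disc);
      for (double t : { (-b - sq) / (2 * a2), (-b + sq) / (2 * a2) }) {
        if (t <= TGEO || t > 1.0 || t >= ev.t) continue;
        double yy = p.y + t * d.y, zz = p.z + t * d.z;
        if (yy * d.y + zz * d.z <= 0) continue;       // inward crossing
        P3 q{p.x + t * d.x, yy, zz};
        if (sp.present && zz > 0 && lat2(sc, q) < sp.neck_r * sp.neck_r)
          continue;                                    // spine opening: pass
        consider_reflect(ev, t, 0, yy / sc.R, zz / sc.R);
      }
    }
  }

  // --- end caps ---
  for (int side = 0; side < 2; ++side) {
    double plane = side == 0 ? 0.0 : sc.L;
    int mode = side == 0 ? sc.cap0 : sc.cap1;
    double hole = side == 0 ? sc.cap0_hole : sc.cap1_hole;
    if (d.x == 0) continue;
    double t = (plane - p.x) / d.x;
    if (t <= TGEO || t > 1.0 || t >= ev.t) continue;
    if ((side == 0 && d.x >= 0) || (side == 1 && d.x <= 0)) continue;
    double yy = p.y + t * d.y, zz = p.z + t * d.z;
    if (yy * yy + zz * zz > sc.R * sc.R) continue;    // outside the disk (in spine)
    double nx = side == 0 ? -1.0 : 1.0;
    if (mode == 1) consider_absorb(ev, t);
    else if (mode == 2) {
      if (yy * yy + zz * zz < hole * hole) consider_absorb(ev, t);
      else consider_reflect(ev, t, nx, 0, 0);
    } else consider_reflect(ev, t, nx, 0, 0);
  }

  // --- barrier disks with holes ---
  if (d.x != 0) {
    for (size_t i = 0; i < sc.bx.size(); ++i) {
      double t = (sc.bx[i] - p.x) / d.x;
      if (t <= TGEO || t > 1.0 || t >= ev.t) continue;
      double yy = p.y + t * d.y, zz = p.z + t * d.z;
      if (yy * yy + zz * zz > sc.R * sc.R) continue;  // above wall (spine side)
      double hy = yy - sc.bcy[i], hz = zz - sc.bcz[i];
      if (hy * hy + hz * hz < sc.br[i] * sc.br[i]) continue;  // through the hole
      consider_reflect(ev, t, d.x > 0 ? 1.0 : -1.0, 0, 0);
    }
  }

  if (sp.present) {
    // --- neck lateral wall: boundary only where outside the cylinder ---
    double ax = d.x, ay = d.y;
    double qa = ax * ax + ay * ay;
    if (qa > 0) {
      double px = p.x - sp.x0;
      double qb = 2 * (px * ax + p.y * ay);
      double qc = px * px + p.y * p.y - sp.neck_r * sp.neck_r;
      double disc = qb * qb - 4 * qa * qc;
      if (disc > 0) {
        double sq = std::sqrt(disc);
        for (double t : { (-qb - sq) / (2 * qa), (-qb + sq) / (2 * qa) }) {
          if (t <= TGEO || t > 1.0 || t >= ev.t) continue;
          double xx = px + t * ax, yy = p.y + t * ay;
          if (xx * ax + yy * ay <= 0) continue;       // inward
          P3 q{p.x + t * d.x, p.y + t * d.y, p.z + t * d.z};
          double r2 = q.y * q.y + q.z * q.z;
          if (r2 <= sc.R * sc.R || q.z > sp.z_top) continue; // interior or head zone
          consider_reflect(ev, t, xx / sp.neck_r, yy / sp.neck_r, 0);
        }
      }
    }
    // --- head sphere: boundary only above the neck top plane ---
    double cx = sp.x0, cy = 0, cz = sp.z_c;
    double ox = p.x - cx, oy = p.y - cy, oz = p.z - cz;
    double qa2 = d.x * d.x + d.y * d.y + d.z * d.z;
    if (qa2 > 0) {
      double qb = 2 * (ox * d.x + oy * d.y + oz * d.z);
      double qc = ox * ox + oy * oy + oz * oz - sp.head_r * sp.head_r;
      double disc = qb * qb - 4 * qa2 * qc;
      if (disc > 0) {
        double sq = std::sqrt(disc);
        for (double t : { (-qb - sq) / (2 * qa2), (-qb + sq) / (2 * qa2) }) {
          if (t <= TGEO || t > 1.0 || t >= ev.t) continue;
          P3 q{p.x + t * d.x, p.y + t * d.y, p.z + t * d.z};
          if (q.z <= sp.z_top) continue;              // interior chord
          double rx = q.x - cx, ry = q.y - cy, rz = q.z - cz;
          if (rx * d.x + ry * d.y + rz * d.z <= 0) continue;  // inward
          if (sp.head_absorbing) consider_absorb(ev, t);
          else consider_reflect(ev, t, rx / sp.head_r, ry / sp.head_r, rz / sp.head_r);
        }
      }
    }
  }
  return ev;
}

// resolution length for adaptive stepping: the minimum over features
// of max(distance to feature, floor_frac * feature's own size).
// Features: absorbing caps, cap-hole disks, barrier-opening edges, the
// spine opening and the spine's curved walls. Flat reflecting planes
// are exact under specular reflection and do not constrain the step.
static double near_dist(const SceneC& sc, const P3& p, double floor_frac) {
  double d = 1e30;
  double r = std::sqrt(p.y * p.y + p.z * p.z);
  auto feat = [&](double dist, double scale) {
    d = std::min(d, std::max(dist, floor_frac * scale));
  };
  if (in_spine(sc, p)) {
    double lr = std::sqrt(lat2(sc, p));
    feat(std::max(sc.sp.neck_r - lr, 0.0), sc.sp.neck_r);
    if (p.z > sc.sp.z_top) {
      double dx = p.x - sc.sp.x0, dz = p.z - sc.sp.z_c;
      double dd = sc.sp.head_r - std::sqrt(dx * dx + p.y * p.y + dz * dz);
      // head wall: coarse when reflecting, fine when absorbing
      feat(std::max(dd, 0.0),
           sc.sp.head_absorbing ? 0.1 * sc.sp.head_r : sc.sp.head_r);
    }
    return d;
  }
  for (int side = 0; side < 2; ++side) {
    int mode = side == 0 ? sc.cap0 : sc.cap1;
    double dx = side == 0 ? p.x : sc.L - p.x;
    if (mode == 1) feat(dx, 0.1 * sc.R);
    else if (mode == 2) {
      double hole = side == 0 ? sc.cap0_hole : sc.cap1_hole;
      double lat = std::max(r - hole, 0.0);
      feat(std::sqrt(dx * dx + lat * lat), hole);
    }
  }
  for (size_t i = 0; i < sc.bx.size(); ++i) {
    double dx = p.x - sc.bx[i];
    double hy = p.y - sc.bcy[i], hz = p.z - sc.bcz[i];
    double rl = std::sqrt(hy * hy + hz * hz) - sc.br[i]; // to the edge ring
    feat(std::sqrt(dx * dx + rl * rl), sc.br[i]);
  }
  if (sc.sp.present) {
    double lr = std::sqrt(lat2(sc, p)) - sc.sp.neck_r;
    double dz = p.z - sc.R;
    feat(std::sqrt(lr * lr + dz * dz), sc.sp.neck_r);
  }
  if (d > 1e29) d = sc.R;   // no constraining feature: bulk scale
  return d;
}

// advance one particle by one Euler step of duration dt; returns
// 0 active, 1 absorbed (t_event receives fraction of dt elapsed),
// 2 reverted (membership guard tripped)
static int do_step(const SceneC& sc, P3& p, double sigma, double& frac_elapsed) {
  P3 start = p;
  P3 d{sigma * norm_rand(), sigma * norm_rand(), sigma * norm_rand()};
  double total = 1.0, done = 0.0;
  for (int bounce = 0; bounce < 64; ++bounce) {
    Event ev = next_event(sc, p, d);
    if (ev.code == 0) {
      p.x += d.x; p.y += d.y; p.z += d.z;
      if (!inside(sc, p)) { p = start; return 2; }
      frac_elapsed = 1.0;
      return 0;
    }
    P3 q{p.x + ev.t * d.x, p.y + ev.t * d.y, p.z + ev.t * d.z};
    done += ev.t * total;
    if (ev.code == 2) { p = q; frac_elapsed = done; return 1; }
    // specular reflection of the remaining sub-segment
    double rx = (1 - ev.t) * d.x, ry = (1 - ev.t) * d.y, rz = (1 - ev.t) * d.z;
    double dot = rx * ev.n.x + ry * ev.n.y + rz * ev.n.z;
    d = {rx - 2 * dot * ev.n.x, ry - 2 * dot * ev.n.y, rz - 2 * dot * ev.n.z};
    p = {q.x - PUSH * ev.n.x, q.y - PUSH * ev.n.y, q.z - PUSH * ev.n.z};
    total *= (1 - ev.t);
  }
  if (!inside(sc, p)) { p = start; return 2; }
  frac_elapsed = 1.0;
  return 0;
}

static SceneC parse_scene(List scene) {
  SceneC sc;
  sc.R = as<double>(scene["radius"]);
  sc.L = as<double>(scene["length"]);
  CharacterVector caps = scene["caps"];
  NumericVector holes = scene["cap_holes"];
  auto capmode = [](const String& s) {
    if (s == "reflecting") return 0;
    if (s == "absorbing") return 1;
    return 2; // "absorbing_hole"
  };
  sc.cap0 = capmode(caps[0]); sc.cap1 = capmode(caps[1]);
  sc.cap0_hole = holes[0]; sc.cap1_hole = holes[1];
  sc.bx = as<std::vector<double>>(scene["barrier_x"]);
  sc.br = as<std::vector<double>>(scene["hole_r"]);
  sc.bcy = as<std::vector<double>>(scene["hole_cy"]);
  sc.bcz = as<std::vector<double>>(scene["hole_cz"]);
  sc.min_scale = sc.R;
  for (double r : sc.br) sc.min_scale = std::min(sc.min_scale, r);
  if (sc.cap0 == 2) sc.min_scale = std::min(sc.min_scale, sc.cap0_hole);
  if (sc.cap1 == 2) sc.min_scale = std::min(sc.min_scale, sc.cap1_hole);
  if (scene.containsElementNamed("spine") && !Rf_isNull(scene["spine"])) {
    List s = scene["spine"];
    sc.sp.present = true;
    sc.sp.x0 = as<double>(s["attach_position"]);
    sc.sp.neck_r = as<double>(s["neck_radius"]);
    sc.sp.neck_len = as<double>(s["neck_length"]);
    sc.sp.head_r = as<double>(s["head_radius"]);
    sc.sp.head_absorbing = as<bool>(s["head_absorbing"]);
    sc.sp.z_top = sc.R + sc.sp.neck_len;
    sc.sp.z_c = sc.sp.z_top +
      std::sqrt(std::max(sc.sp.head_r * sc.sp.head_r - sc.sp.neck_r * sc.sp.neck_r, 0.0));
    sc.min_scale = std::min(sc.min_scale, sc.sp.neck_r);
  }
  return sc;
}

static double adaptive_dt(const SceneC& sc, const P3& p, double D,
                          double base_step, double frac, double floor_frac) {
  double len = frac * near_dist(sc, p, floor_frac);
  double dt = len * len / (6.0 * D);
  return std::min(dt, base_step);
}

// [[Rcpp::export]]
List bd_run(NumericMatrix pos0, List scene, double D, double base_step,
            double frac, NumericVector sample_times, NumericMatrix vols,
            bool record_moments, bool record_x, double floor_frac) {
  RNGScope rngScope;
  SceneC sc = parse_scene(scene);
  int n = pos0.nrow(), nt = sample_times.size(), nv = vols.nrow();
  IntegerMatrix counts(nt, nv);
  NumericMatrix xs(record_x ? nt : 0, record_x ? n : 0);
  if (record_x) std::fill(xs.begin(), xs.end(), NA_REAL);
  NumericVector sum_x(nt), sum_x2(nt);
  IntegerVector n_active(nt), n_inspine(nt);
  NumericMatrix fin(n, 3);
  IntegerVector status(n);     // 0 active, 1 absorbed
  NumericVector t_abs(n, NA_REAL);
  long leak_reverts = 0;

  for (int i = 0; i < n; ++i) {
    P3 p{pos0(i, 0), pos0(i, 1), pos0(i, 2)};
    double t = 0;
    bool absorbed = false;
    if (D > 0) {
      for (int k = 0; k < nt && !absorbed; ++k) {
        double target = sample_times[k];
        while (t < target - 1e-15) {
          double dt = std::min(adaptive_dt(sc, p, D, base_step, frac, floor_frac), target - t);
          double sigma = std::sqrt(2.0 * D * dt);
          double fe = 1.0;
          int code = do_step(sc, p, sigma, fe);
          if (code == 2) { ++leak_reverts; t += dt; continue; }
          t += dt * fe;
          if (code == 1) {
            absorbed = true; status[i] = 1; t_abs[i] = t;
            break;
          }
        }
        if (!absorbed) {
          bool insp = in_spine(sc, p);
          n_active[k] += 1;
          if (insp) n_inspine[k] += 1;
          else {
            for (int v = 0; v < nv; ++v)
              if (p.x >= vols(v, 0) && p.x < vols(v, 1)) counts(k, v) += 1;
          }
          if (record_moments && !insp) { sum_x[k] += p.x; sum_x2[k] += p.x * p.x; }
          if (record_x) xs(k, i) = p.x;
        }
      }
    } else {
      for (int k = 0; k < nt; ++k) {
        n_active[k] += 1;
        for (int v = 0; v < nv; ++v)
          if (p.x >= vols(v, 0) && p.x < vols(v, 1)) counts(k, v) += 1;
        if (record_moments) { sum_x[k] += p.x; sum_x2[k] += p.x * p.x; }
        if (record_x) xs(k, i) = p.x;
      }
    }
    fin(i, 0) = p.x; fin(i, 1) = p.y; fin(i, 2) = p.z;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["counts"] = counts, _["sum_x"] = sum_x, _["sum_x2"] = sum_x2,
    _["n_active"] = n_active, _["n_inspine"] = n_inspine,
    _["final_positions"] = fin, _["status"] = status,
    _["absorption_times"] = t_abs, _["leak_reverts"] = leak_reverts,
    _["xs"] = xs);
}

// [[Rcpp::export]]
List bd_mfpt(NumericMatrix pos0, List scene, double D, double base_step,
             double frac, double t_cap, double floor_frac) {
  RNGScope rngScope;
  SceneC sc = parse_scene(scene);
  int n = pos0.nrow();
  NumericVector times(n, NA_REAL);
  LogicalVector censored(n);
  long leak_reverts = 0;
  for (int i = 0; i < n; ++i) {
    P3 p{pos0(i, 0), pos0(i, 1), pos0(i, 2)};
    double t = 0;
    bool escaped = false;
    while (t < t_cap) {
      double dt = adaptive_dt(sc, p, D, base_step, frac, floor_frac);
      double sigma = std::sqrt(2.0 * D * dt);
      double fe = 1.0;
      int code = do_step(sc, p, sigma, fe);
      if (code == 2) { ++leak_reverts; t += dt; continue; }
      t += dt * fe;
      if (code == 1) { times[i] = t; escaped = true; break; }
    }
    censored[i] = !escaped;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["times"] = times, _["censored"] = censored,
                      _["leak_reverts"] = leak_reverts);
}
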