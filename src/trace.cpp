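#include "core.h"
using namespace Rcpp;

// Adaptive RK4 integration of dr/ds = +/- grad(rho)/|grad(rho)| with
//  - per-step monotonicity guard on rho,
//  - step clamp near listed critical points,
//  - separatrix continuation: a path stalling at a saddle is nudged along
//    the downhill (descent) or uphill (ascent) Hessian eigenspace,
//  - termination on CP capture, truncation isovalue, domain exit, or budget.

static inline double norm3(const double* g) {
  return std::sqrt(g[0]*g[0] + g[1]*g[1] + g[2]*g[2]);
}

static bool unit_dir(const Field* f, const double* x, int dir, double* d) {
  double g[3];
  f->valgrad(x, g);
  double n = norm3(g);
  if (n < 1e-300) return false;
  for (int i = 0; i < 3; ++i) d[i] = dir * g[i] / n;
  return true;
}

TraceResult trace_one(const Field* f, const double* seed,
                             const TraceOpts& o, const NumericMatrix& cps,
                             const IntegerVector& cp_sig) {
  TraceResult res;
  res.cp_index = 0;
  double x[3] = { seed[0], seed[1], seed[2] };
  std::array<double,3> xa = { x[0], x[1], x[2] };
  res.pts.push_back(xa);
  double g[3];
  double v = f->valgrad(x, g);
  res.rho.push_back(v);
  double h = o.h0;
  int ncp = cps.nrow();
  double lastdir[3] = { 0, 0, 0 };
  bool have_dir = false;
  int nudges = 0;

  for (int step = 0; step < o.max_steps; ++step) {
    v = f->valgrad(x, g);
    double gn = norm3(g);

    // capture at a CP of terminal type (max for ascent, min for descent)
    for (int i = 0; i < ncp; ++i) {
      int sig = cp_sig[i];
      bool terminal = (o.direction > 0 && sig == -3) ||
                      (o.direction < 0 && sig == 3);
      if (!terminal) continue;
      double dx = x[0] - cps(i,0), dy = x[1] - cps(i,1), dz = x[2] - cps(i,2);
      if (dx*dx + dy*dy + dz*dz < o.capture * o.capture) {
        res.status = "cp";
        res.cp_index = i + 1;
        return res;
      }
    }

    bool stalled = gn < o.gtol || h < o.hmin;
    if (stalled) {
      // at a stationary point: classify locally and either stop or continue
      double H[9], eval[3], evec[9];
      f->hessian(x, H);
      eig3(H, eval, evec);
      // continuation subspace: eigenvectors with descending (ascent: ascending)
      // curvature sign matching the travel direction
      std::vector<int> cont;
      for (int i = 0; i < 3; ++i) {
        if (o.direction < 0 && eval[i] < 0) cont.push_back(i);
        if (o.direction > 0 && eval[i] > 0) cont.push_back(i);
      }
      if (cont.empty() || nudges > 24) {
        // genuine terminus (minimum for descent, maximum for ascent)
        res.status = nudges > 24 ? "stalled" : "cp";
        // identify nearest supplied CP if any
        double best = 1e30; int bi = 0;
        for (int i = 0; i < ncp; ++i) {
          double dx = x[0]-cps(i,0), dy = x[1]-cps(i,1), dz = x[2]-cps(i,2);
          double d2 = dx*dx + dy*dy + dz*dz;
          if (d2 < best) { best = d2; bi = i + 1; }
        }
        if (best < 0.25) res.cp_index = bi;
        return res;
      }
      // project incoming direction onto continuation subspace
      double d[3] = { 0, 0, 0 };
      for (size_t k = 0; k < cont.size(); ++k) {
        int i = cont[k];
        double e[3] = { evec[i], evec[3+i], evec[6+i] };
        double dp = have_dir ? lastdir[0]*e[0] + lastdir[1]*e[1] + lastdir[2]*e[2]
                             : 0.0;
        for (int j = 0; j < 3; ++j) d[j] += dp * e[j];
      }
      double dn = norm3(d);
      if (dn < 1e-10) {
        int i = cont[0];
        d[0] = evec[i]; d[1] = evec[3+i]; d[2] = evec[6+i];
        if (have_dir && (d[0]*lastdir[0] + d[1]*lastdir[1] + d[2]*lastdir[2]) < 0) {
          d[0] = -d[0]; d[1] = -d[1]; d[2] = -d[2];
        }
        dn = 1.0;
      }
      for (int j = 0; j < 3; ++j) x[j] += o.nudge * d[j] / dn;
      ++nudges;
      v = f->valgrad(x, g);
      std::array<double,3> xn = { x[0], x[1], x[2] };
      res.pts.push_back(xn);
      // enforce a strictly monotone recorded profile for re-parameterization
      double vrec = o.direction < 0 ? std::min(v, res.rho.back() * (1 - 1e-12))
                                    : std::max(v, res.rho.back() * (1 + 1e-12));
      res.rho.push_back(vrec);
      h = o.h0;
      have_dir = false;
      continue;
    }

    // distance clamp near CPs so steps cannot jump across separatrices
    double hh = std::min(h, o.hmax);
    if (ncp > 0) {
      double dmin = 1e30;
      for (int i = 0; i < ncp; ++i) {
        double dx = x[0]-cps(i,0), dy = x[1]-cps(i,1), dz = x[2]-cps(i,2);
        dmin = std::min(dmin, dx*dx + dy*dy + dz*dz);
      }
      dmin = std::sqrt(dmin);
      hh = std::min(hh, std::max(0.25 * dmin, 4.0 * o.hmin));
    }

    // RK4 on the unit vector field
    double k1[3] = { o.direction * g[0] / gn, o.direction * g[1] / gn,
                     o.direction * g[2] / gn };
    double y[3], k2[3], k3[3], k4[3];
    for (int j = 0; j < 3; ++j) y[j] = x[j] + 0.5 * hh * k1[j];
    if (!unit_dir(f, y, o.direction, k2)) { res.status = "stalled"; return res; }
    for (int j = 0; j < 3; ++j) y[j] = x[j] + 0.5 * hh * k2[j];
    if (!unit_dir(f, y, o.direction, k3)) { res.status = "stalled"; return res; }
    for (int j = 0; j < 3; ++j) y[j] = x[j] + hh * k3[j];
    if (!unit_dir(f, y, o.direction, k4)) { res.status = "stalled"; return res; }
    double xn[3];
    for (int j = 0; j < 3; ++j)
      xn[j] = x[j] + hh / 6.0 * (k1[j] + 2*k2[j] + 2*k3[j] + k4[j]);

    if (!f->in_domain(xn)) {
      res.status = "boundary";
      return res;
    }
    double vn = f->value(xn);
    bool mono_ok = o.direction < 0 ? (vn < v) : (vn > v);
    if (!mono_ok) {
      h = hh * 0.5;
      continue;
    }
    for (int j = 0; j < 3; ++j) lastdir[j] = (xn[j] - x[j]);
    double ln = norm3(lastdir);
    if (ln > 0) for (int j = 0; j < 3; ++j) lastdir[j] /= ln;
    have_dir = true;
    for (int j = 0; j < 3; ++j) x[j] = xn[j];
    std::array<double,3> xa2 = { x[0], x[1], x[2] };
    res.pts.push_back(xa2);
    res.rho.push_back(vn);
    h = std::min(hh * 1.3, o.hmax);
    if (o.direction < 0 && vn < o.trunc) {
      res.status = "truncated";
      return res;
    }
  }
  res.status = "maxsteps";
  return res;
}

TraceOpts opts_from_list(List control, int direction) {
  TraceOpts o;
  o.h0 = control["h0"]; o.hmax = control["hmax"]; o.hmin = control["hmin"];
  o.gtol = control["gtol"]; o.trunc = control["trunc"];
  o.capture = control["capture"]; o.nudge = control["nudge"];
  o.max_steps = control["max_steps"];
  o.direction = direction;
  return o;
}

static List result_to_list(const TraceResult& r) {
  int n = r.pts.size();
  NumericMatrix pts(n, 3);
  NumericVector rho(n), s(n);
  double acc = 0;
  for (int i = 0; i < n; ++i) {
    pts(i,0) = r.pts[i][0]; pts(i,1) = r.pts[i][1]; pts(i,2) = r.pts[i][2];
    rho[i] = r.rho[i];
    if (i > 0) {
      double dx = r.pts[i][0]-r.pts[i-1][0], dy = r.pts[i][1]-r.pts[i-1][1],
             dz = r.pts[i][2]-r.pts[i-1][2];
      acc += std::sqrt(dx*dx + dy*dy + dz*dz);
    }
    s[i] = acc;
  }
  return List::create(_["points"] = pts, _["rho"] = rho, _["s"] = s,
                      _["status"] = r.status, _["cp_index"] = r.cp_index);
}

// [[Rcpp::export(name = ".cpp_trace_path")]]
List cpp_trace_path(SEXP fptr, NumericVector seed, int direction, List control,
                    NumericMatrix cps, IntegerVector cp_sig) {
  XPtr<Field> f(fptr);
  TraceOpts o = opts_from_list(control, direction);
  double s[3] = { seed[0], seed[1], seed[2] };
  return result_to_list(trace_one(f.get(), s, o, cps, cp_sig));
}

// [[Rcpp::export(name = ".cpp_trace_batch")]]
List cpp_trace_batch(SEXP fptr, NumericMatrix seeds, int direction,
                     List control, NumericMatrix cps, IntegerVector cp_sig) {
  XPtr<Field> f(fptr);
  TraceOpts o = opts_from_list(control, direction);
  int n = seeds.nrow();
  List out(n);
  for (int i = 0; i < n; ++i) {
    double s[3] = { seeds(i,0), seeds(i,1), seeds(i,2) };
    out[i] = result_to_list(trace_one(f.get(), s, o, cps, cp_sig));
  }
  return out;
}

// Terminal atom of an ascent path from each point (Bader assignment).
// nuclei: positions of nuclear maxima. Returns 1-based index or NA.
// [[Rcpp::export(name = ".cpp_ascend_to_nucleus")]]
IntegerVector cpp_ascend_to_nucleus(SEXP fptr, NumericMatrix pts, List control,
                                    NumericMatrix nuclei) {
  XPtr<Field> f(fptr);
  TraceOpts o = opts_from_list(control, +1);
  int ncp = nuclei.nrow();
  IntegerVector sig(ncp, -3);
  IntegerVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) {
    double s[3] = { pts(i,0), pts(i,1), pts(i,2) };
    TraceResult r = trace_one(f.get(), s, o, nuclei, sig);
    if ((r.status == "cp" || r.status == "stalled") && r.cp_index > 0)
      out[i] = r.cp_index;
    else if (r.status == "cp" || r.status == "stalled") {
      // terminated at an unlisted attractor: report nearest nucleus if close
      const std::array<double,3>& e = r.pts.back();
      double best = 1e30; int bi = NA_INTEGER;
      for (int k = 0; k < ncp; ++k) {
        double dx = e[0]-nuclei(k,0), dy = e[1]-nuclei(k,1), dz = e[2]-nuclei(k,2);
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 < best) { best = d2; bi = k + 1; }
      }
      out[i] = best < 1e-2 ? bi : NA_INTEGER;
    } else {
      out[i] = NA_INTEGER;
    }
  }
  return out;
}
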