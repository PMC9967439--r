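#include "core.h"
#include <map>
using namespace Rcpp;

// Station-matched quadrature over differential gradient bundles with
// adaptive face subdivision.
//
// Each sphere vertex carries a descent path (points + strictly decreasing
// rho), re-parameterized ("stations") at common rho levels by log-linear
// interpolation.  A triangular face defines, at each level, a cross-section
// triangle spanned by its three vertex stations, and a field integrates as
// sum (mean f) x (mean area) x (mean step).  Faces whose stations fan out
// much further than the radial expectation (bundles flattening onto an
// interatomic surface) are subdivided: new vertices at edge midpoints get
// freshly traced paths (cached), and children are accepted when the
// parent/child difference is within tolerance.

static inline double dist3(const double* a, const double* b) {
  return std::sqrt((a[0]-b[0])*(a[0]-b[0]) + (a[1]-b[1])*(a[1]-b[1]) +
                   (a[2]-b[2])*(a[2]-b[2]));
}

static inline double tri_area3(const double* a, const double* b,
                               const double* c) {
  double u[3] = { b[0]-a[0], b[1]-a[1], b[2]-a[2] };
  double w[3] = { c[0]-a[0], c[1]-a[1], c[2]-a[2] };
  double n0 = u[1]*w[2] - u[2]*w[1];
  double n1 = u[2]*w[0] - u[0]*w[2];
  double n2 = u[0]*w[1] - u[1]*w[0];
  return 0.5 * std::sqrt(n0*n0 + n1*n1 + n2*n2);
}

struct StatHolder {
  std::vector<double> xyz; // 3 * L
  std::vector<double> fv;  // L (empty when condensing the unit field)
};

class AdaptiveCondenser {
public:
  const Field* rho;
  const Field* f;   // null => unit field
  std::vector<std::array<double,3> > dirs;
  std::vector<StatHolder> st;
  std::map<std::pair<int,int>, int> midcache;
  std::vector<double> loglev;
  int L;
  TraceOpts opts;
  NumericMatrix cps;
  IntegerVector cp_sig;
  double center[3], dr, rtol, atol, fan_thresh;
  int maxdepth;
  long n_traced;

  void resample(const TraceResult& r, StatHolder& out) {
    int n = r.pts.size();
    std::vector<double> lr(n);
    for (int i = 0; i < n; ++i)
      lr[i] = std::log(std::max(r.rho[i], 1e-300));
    out.xyz.resize((size_t)L * 3);
    int j = 0;
    for (int k = 0; k < L; ++k) {
      double target = loglev[k];
      double x[3];
      if (target >= lr[0]) {
        x[0] = r.pts[0][0]; x[1] = r.pts[0][1]; x[2] = r.pts[0][2];
      } else if (target <= lr[n-1]) {
        x[0] = r.pts[n-1][0]; x[1] = r.pts[n-1][1]; x[2] = r.pts[n-1][2];
      } else {
        while (j < n - 1 && lr[j+1] > target) ++j;
        double t = (target - lr[j]) / (lr[j+1] - lr[j]);
        for (int d = 0; d < 3; ++d)
          x[d] = r.pts[j][d] + t * (r.pts[j+1][d] - r.pts[j][d]);
      }
      out.xyz[(size_t)k*3] = x[0];
      out.xyz[(size_t)k*3+1] = x[1];
      out.xyz[(size_t)k*3+2] = x[2];
    }
    if (f) {
      out.fv.resize(L);
      for (int k = 0; k < L; ++k)
        out.fv[k] = f->value(&out.xyz[(size_t)k*3]);
    }
  }

  int add_vertex(const std::array<double,3>& u) {
    double seed[3] = { center[0] + dr * u[0], center[1] + dr * u[1],
                       center[2] + dr * u[2] };
    TraceResult r = trace_one(rho, seed, opts, cps, cp_sig);
    ++n_traced;
    if (r.status == "maxsteps")
      stop("non-terminating gradient path during condensation refinement");
    dirs.push_back(u);
    st.push_back(StatHolder());
    resample(r, st.back());
    return (int)dirs.size() - 1;
  }

  int midpoint(int a, int b) {
    std::pair<int,int> key(std::min(a, b), std::max(a, b));
    std::map<std::pair<int,int>, int>::iterator it = midcache.find(key);
    if (it != midcache.end()) return it->second;
    std::array<double,3> u;
    for (int d = 0; d < 3; ++d) u[d] = dirs[a][d] + dirs[b][d];
    double n = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
    for (int d = 0; d < 3; ++d) u[d] /= n;
    int id = add_vertex(u);
    midcache[key] = id;
    return id;
  }

  // spherical/flat area ratio of the unit-direction triangle (curvature
  // correction for flat cross-section triangles)
  double sph_corr(int a, int b, int c) const {
    const std::array<double,3>& A = dirs[a];
    const std::array<double,3>& B = dirs[b];
    const std::array<double,3>& C = dirs[c];
    double triple = A[0]*(B[1]*C[2]-B[2]*C[1]) - A[1]*(B[0]*C[2]-B[2]*C[0])
                  + A[2]*(B[0]*C[1]-B[1]*C[0]);
    double ab = A[0]*B[0]+A[1]*B[1]+A[2]*B[2];
    double bc = B[0]*C[0]+B[1]*C[1]+B[2]*C[2];
    double ca = C[0]*A[0]+C[1]*A[1]+C[2]*A[2];
    double omega = 2.0 * std::atan2(std::fabs(triple), 1 + ab + bc + ca);
    double flat = tri_area3(A.data(), B.data(), C.data());
    return flat > 0 ? omega / flat : 1.0;
  }

  // signed volume of tetrahedron (p,q,r,s) / 6
  static inline double tet6(const double* p, const double* q, const double* r,
                            const double* s) {
    double u[3] = { q[0]-p[0], q[1]-p[1], q[2]-p[2] };
    double v[3] = { r[0]-p[0], r[1]-p[1], r[2]-p[2] };
    double w[3] = { s[0]-p[0], s[1]-p[1], s[2]-p[2] };
    return u[0]*(v[1]*w[2]-v[2]*w[1]) - u[1]*(v[0]*w[2]-v[2]*w[0])
         + u[2]*(v[0]*w[1]-v[1]*w[0]);
  }

  double tri_integral(int a, int b, int c, bool* flag) {
    const double* pa = st[a].xyz.data();
    const double* pb = st[b].xyz.data();
    const double* pc = st[c].xyz.data();
    // angular scale of the face
    double cab = dirs[a][0]*dirs[b][0]+dirs[a][1]*dirs[b][1]+dirs[a][2]*dirs[b][2];
    double cbc = dirs[b][0]*dirs[c][0]+dirs[b][1]*dirs[c][1]+dirs[b][2]*dirs[c][2];
    double cca = dirs[c][0]*dirs[a][0]+dirs[c][1]*dirs[a][1]+dirs[c][2]*dirs[a][2];
    double cmin = std::min(cab, std::min(cbc, cca));
    double theta0 = std::acos(std::max(-1.0, std::min(1.0, cmin)));
    double acc = 0.0, fanmax = 0.0;
    for (int k = 1; k < L; ++k) {
      const double* qa = pa + (size_t)k*3;
      const double* qb = pb + (size_t)k*3;
      const double* qc = pc + (size_t)k*3;
      const double* ra = qa - 3;
      const double* rb = qb - 3;
      const double* rc = qc - 3;
      // cell volume between the two station triangles: triangular prism
      // (possibly sheared/degenerate) split into three tetrahedra; the
      // signed sum is orientation-consistent so numerical folds cancel
      // rather than double count
      double v6 = tet6(ra, rb, rc, qa) + tet6(rb, rc, qa, qb) +
                  tet6(rc, qa, qb, qc);
      double vol = std::fabs(v6) / 6.0;
      double fv = 1.0;
      if (f) fv = (st[a].fv[k] + st[b].fv[k] + st[c].fv[k] +
                   st[a].fv[k-1] + st[b].fv[k-1] + st[c].fv[k-1]) / 6.0;
      acc += fv * vol;
      // fan metric: station spread vs radial expectation
      double emax = std::max(dist3(qa, qb), std::max(dist3(qb, qc),
                                                     dist3(qc, qa)));
      double rbar = (dist3(qa, center) + dist3(qb, center) +
                     dist3(qc, center)) / 3.0;
      double fanr = emax / (std::max(rbar, dr) * std::max(theta0, 1e-12));
      if (fanr > fanmax) fanmax = fanr;
    }
    *flag = fanmax > fan_thresh;
    return acc * sph_corr(a, b, c);
  }

  // Separatrix caps: the elements around a bond-path direction own a full
  // annular neighborhood of the interatomic-surface rim; their flat
  // station triangles sweep the curved surface and accumulate phantom
  // volume.  The cap (pierced element plus its vertex 1-ring) is instead
  // integrated as one surface of revolution about the bond axis: at each
  // level the cross-section is the Pappus ring swept by the segment from
  // the cap's perimeter stations to the traced separatrix station (before
  // the bond CP this degenerates to the polar-cap disc).  The cap total is
  // then shared among its elements in proportion to their areas.
  double cap_integral(const std::vector<int>& perim, int sep,
                      const double* axis) {
    int np = perim.size();
    double acc = 0.0, area_prev = 0.0;
    for (int k = 0; k < L; ++k) {
      const double* ps = st[sep].xyz.data() + (size_t)k*3;
      double dsp[3] = { ps[0]-center[0], ps[1]-center[1], ps[2]-center[2] };
      double Z = dsp[0]*axis[0] + dsp[1]*axis[1] + dsp[2]*axis[2];
      double R2 = dsp[0]*dsp[0] + dsp[1]*dsp[1] + dsp[2]*dsp[2] - Z*Z;
      double R = std::sqrt(std::max(R2, 0.0));
      double area = 0.0;
      for (int m = 0; m < np; ++m) {
        const double* p = st[perim[m]].xyz.data() + (size_t)k*3;
        double d[3] = { p[0]-center[0], p[1]-center[1], p[2]-center[2] };
        double z = d[0]*axis[0] + d[1]*axis[1] + d[2]*axis[2];
        double rr2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2] - z*z;
        double rin = std::sqrt(std::max(rr2, 0.0));
        double seg = std::sqrt((R-rin)*(R-rin) + (Z-z)*(Z-z));
        area += M_PI * (R + rin) * seg;
      }
      area /= np;
      if (k > 0) {
        double step = dist3(ps, ps - 3);
        for (int m = 0; m < np; ++m) {
          const double* p = st[perim[m]].xyz.data() + (size_t)k*3;
          step += dist3(p, p - 3);
        }
        step /= (np + 1);
        double fv = 1.0;
        if (f) {
          fv = st[sep].fv[k] + st[sep].fv[k-1];
          for (int m = 0; m < np; ++m) {
            fv += st[perim[m]].fv[k] + st[perim[m]].fv[k-1];
          }
          fv /= 2.0 * (np + 1);
        }
        acc += fv * 0.5 * (area_prev + area) * step;
      }
      area_prev = area;
    }
    return acc;
  }

  double face_value(int a, int b, int c, int depth) {
    bool flag = false;
    double v0 = tri_integral(a, b, c, &flag);
    if (depth >= maxdepth) return v0;
    if (depth >= 1 && !flag) return v0;
    int ab = midpoint(a, b), bc = midpoint(b, c), ca = midpoint(c, a);
    bool f1, f2, f3, f4;
    double v1 = tri_integral(a, ab, ca, &f1) + tri_integral(ab, b, bc, &f2) +
                tri_integral(ca, bc, c, &f3) + tri_integral(ab, bc, ca, &f4);
    bool childflag = f1 || f2 || f3 || f4;
    if (!childflag &&
        std::fabs(v1 - v0) <= std::max(rtol * std::fabs(v1), atol))
      return v1;
    return face_value(a, ab, ca, depth + 1) +
           face_value(ab, b, bc, depth + 1) +
           face_value(ca, bc, c, depth + 1) +
           face_value(ab, bc, ca, depth + 1);
  }
};

// [[Rcpp::export(name = ".cpp_condense_adaptive")]]
List cpp_condense_adaptive(SEXP rho_ptr, SEXP f_ptr, bool unit,
                           NumericMatrix verts, IntegerMatrix faces,
                           List base_paths, NumericVector center, double dr,
                           NumericVector levels, List control,
                           NumericMatrix cps, IntegerVector cp_sig,
                           double rtol, double atol, int maxdepth,
                           double fan_thresh, List sep_caps) {
  XPtr<Field> rho(rho_ptr);
  AdaptiveCondenser ac;
  ac.rho = rho.get();
  ac.f = NULL;
  if (!unit) {
    XPtr<Field> fxp(f_ptr);
    ac.f = fxp.get();
  }
  ac.L = levels.size();
  ac.loglev.resize(ac.L);
  for (int k = 0; k < ac.L; ++k) ac.loglev[k] = std::log(levels[k]);
  ac.opts = opts_from_list(control, -1);
  ac.cps = cps;
  ac.cp_sig = cp_sig;
  for (int d = 0; d < 3; ++d) ac.center[d] = center[d];
  ac.dr = dr;
  ac.rtol = rtol; ac.atol = atol;
  ac.maxdepth = maxdepth; ac.fan_thresh = fan_thresh;
  ac.n_traced = 0;
  int V = verts.nrow();
  ac.dirs.reserve(V * 3);
  ac.st.reserve(V * 3);
  for (int i = 0; i < V; ++i) {
    std::array<double,3> u = { verts(i,0), verts(i,1), verts(i,2) };
    ac.dirs.push_back(u);
    ac.st.push_back(StatHolder());
    List p = base_paths[i];
    NumericMatrix pts = p["points"];
    NumericVector rv = p["rho"];
    TraceResult tr;
    tr.pts.resize(pts.nrow());
    tr.rho.resize(pts.nrow());
    for (int j = 0; j < pts.nrow(); ++j) {
      tr.pts[j][0] = pts(j,0); tr.pts[j][1] = pts(j,1); tr.pts[j][2] = pts(j,2);
      tr.rho[j] = rv[j];
    }
    ac.resample(tr, ac.st[i]);
  }
  int F = faces.nrow();
  NumericVector out(F);
  std::vector<bool> in_cap(F, false);
  // separatrix caps (around bond-path directions): one revolution
  // quadrature per cap, shared among its elements by area
  for (int m = 0; m < sep_caps.size(); ++m) {
    List cap = sep_caps[m];
    NumericVector dir = cap["dir"];
    IntegerVector cf = cap["faces"];
    IntegerVector pv = cap["perim"];
    NumericVector fa = cap["areas"];
    std::array<double,3> u = { dir[0], dir[1], dir[2] };
    int id = ac.add_vertex(u);
    std::vector<int> perim(pv.size());
    for (int j = 0; j < pv.size(); ++j) perim[j] = pv[j] - 1;
    double total = ac.cap_integral(perim, id, u.data());
    double asum = 0.0;
    for (int j = 0; j < fa.size(); ++j) asum += fa[j];
    for (int j = 0; j < cf.size(); ++j) {
      out[cf[j] - 1] = total * fa[j] / asum;
      in_cap[cf[j] - 1] = true;
    }
  }
  for (int i = 0; i < F; ++i) {
    if (in_cap[i]) continue;
    out[i] = ac.face_value(faces(i,0) - 1, faces(i,1) - 1, faces(i,2) - 1,
                           0);
  }
  return List::create(_["values"] = out, _["n_traced"] = (double)ac.n_traced,
                      _["n_vertices"] = (double)ac.dirs.size());
}

// Voxel steepest-ascent basin labeling (near-grid Bader oracle).
// rho: nx*ny*nz values in R column-major order (x fastest).  Returns for each
// voxel the flat index of its steepest uphill neighbor (1-based), or 0 for
// local maxima.
// [[Rcpp::export(name = ".cpp_voxel_uphill")]]
IntegerVector cpp_voxel_uphill(NumericVector rho, IntegerVector dim,
                               bool periodic) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector out(n);
  const double* r = REAL(rho);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t idx = (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
        double best = 0.0;
        long long bi = -1;
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj)
            for (int dk = -1; dk <= 1; ++dk) {
              if (!di && !dj && !dk) continue;
              int a = i + di, b = j + dj, c = k + dk;
              if (periodic) {
                a = (a + nx) % nx; b = (b + ny) % ny; c = (c + nz) % nz;
              } else if (a < 0 || b < 0 || c < 0 || a >= nx || b >= ny || c >= nz)
                continue;
              size_t nidx = (size_t)a + (size_t)nx * ((size_t)b + (size_t)ny * c);
              double g = (r[nidx] - r[idx]) /
                         std::sqrt((double)(di*di + dj*dj + dk*dk));
              if (g > best) { best = g; bi = (long long)nidx; }
            }
        out[idx] = bi < 0 ? 0 : (int)(bi + 1);
      }
  return out;
}
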