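#include "core.h"
using namespace Rcpp;

// ---------------------------------------------------------------- promolecular

// radial shell value/derivatives with fast paths for small even integer p
static inline double shell_val(const Shell& s, double r2, double r) {
  double e = std::exp(-s.a * r);
  switch (s.ip) {
    case 0: return s.c * e;
    case 2: return s.c * r2 * e;
    case 4: return s.c * r2 * r2 * e;
    case 6: return s.c * r2 * r2 * r2 * e;
    default: return s.c * std::exp(s.p * std::log(r) - s.a * r);
  }
}

static inline void shell_derivs(const Shell& s, double r, double& f,
                                double& fp, double& fpp) {
  double r2 = r * r;
  f = shell_val(s, r2, r);
  if (s.p == 0.0) {
    fp = -s.a * f;
    fpp = s.a * s.a * f;
  } else {
    // f = c r^p e^{-ar}: f' = f (p/r - a); f'' = f ((p/r - a)^2 - p/r^2)
    double q = s.p / r - s.a;
    fp = f * q;
    fpp = f * (q * q - s.p / r2);
  }
}

void PromolField::finalize() {
  rcut2_atom.clear();
  for (size_t ia = 0; ia < shells.size(); ++ia) {
    double m = 0;
    for (size_t is = 0; is < shells[ia].size(); ++is) {
      Shell& sh = shells[ia][is];
      sh.rcut2 = sh.rcut * sh.rcut;
      sh.ip = -1;
      for (int q = 0; q <= 6; q += 2)
        if (std::fabs(sh.p - q) < 1e-12) sh.ip = q;
      m = std::max(m, sh.rcut2);
    }
    rcut2_atom.push_back(m);
  }
}

double PromolField::value(const double* x) const {
  double v = 0.0;
  for (size_t im = 0; im < images.size(); ++im) {
    for (size_t ia = 0; ia < pos.size(); ++ia) {
      double dx = x[0] - pos[ia][0] - images[im][0];
      double dy = x[1] - pos[ia][1] - images[im][1];
      double dz = x[2] - pos[ia][2] - images[im][2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > rcut2_atom[ia]) continue;
      double r = std::sqrt(r2);
      if (r < 1e-12) { r = 1e-12; r2 = r * r; }
      const std::vector<Shell>& sh = shells[ia];
      for (size_t is = 0; is < sh.size(); ++is) {
        if (r2 > sh[is].rcut2) continue;
        v += shell_val(sh[is], r2, r);
      }
    }
  }
  return v;
}

double PromolField::valgrad(const double* x, double* g) const {
  double v = 0.0;
  g[0] = g[1] = g[2] = 0.0;
  for (size_t im = 0; im < images.size(); ++im) {
    for (size_t ia = 0; ia < pos.size(); ++ia) {
      double d[3] = { x[0] - pos[ia][0] - images[im][0],
                      x[1] - pos[ia][1] - images[im][1],
                      x[2] - pos[ia][2] - images[im][2] };
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 > rcut2_atom[ia]) continue;
      double rr = std::sqrt(r2);
      if (rr < 1e-12) rr = 1e-12;
      const std::vector<Shell>& sh = shells[ia];
      for (size_t is = 0; is < sh.size(); ++is) {
        if (r2 > sh[is].rcut2) continue;
        double f, fp, fpp;
        shell_derivs(sh[is], rr, f, fp, fpp);
        v += f;
        double s = fp / rr;
        g[0] += s * d[0]; g[1] += s * d[1]; g[2] += s * d[2];
      }
    }
  }
  return v;
}

void PromolField::hessian(const double* x, double* H) const {
  for (int i = 0; i < 9; ++i) H[i] = 0.0;
  for (size_t im = 0; im < images.size(); ++im) {
    for (size_t ia = 0; ia < pos.size(); ++ia) {
      double d[3] = { x[0] - pos[ia][0] - images[im][0],
                      x[1] - pos[ia][1] - images[im][1],
                      x[2] - pos[ia][2] - images[im][2] };
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 > rcut2_atom[ia]) continue;
      double rr = std::sqrt(r2);
      if (rr < 1e-10) rr = 1e-10;
      const std::vector<Shell>& sh = shells[ia];
      for (size_t is = 0; is < sh.size(); ++is) {
        if (r2 > sh[is].rcut2) continue;
        double f, fp, fpp;
        shell_derivs(sh[is], rr, f, fp, fpp);
        // H = (fpp - fp/r) u u^T + (fp/r) I,  u = d/r
        double a = (fpp - fp / rr) / (rr * rr);
        double b = fp / rr;
        H[0] += a * d[0]*d[0] + b;
        H[4] += a * d[1]*d[1] + b;
        H[8] += a * d[2]*d[2] + b;
        H[1] += a * d[0]*d[1];
        H[2] += a * d[0]*d[2];
        H[5] += a * d[1]*d[2];
      }
    }
  }
  H[3] = H[1]; H[6] = H[2]; H[7] = H[5];
}

// ---------------------------------------------------------------- grid field

static inline void cr_weights(double t, double* w, double* wd, double* wdd) {
  // Catmull-Rom cubic convolution weights for nodes at -1,0,1,2
  w[0] = 0.5 * (-t*t*t + 2*t*t - t);
  w[1] = 0.5 * (3*t*t*t - 5*t*t + 2);
  w[2] = 0.5 * (-3*t*t*t + 4*t*t + t);
  w[3] = 0.5 * (t*t*t - t*t);
  wd[0] = 0.5 * (-3*t*t + 4*t - 1);
  wd[1] = 0.5 * (9*t*t - 10*t);
  wd[2] = 0.5 * (-9*t*t + 8*t + 1);
  wd[3] = 0.5 * (3*t*t - 2*t);
  wdd[0] = 0.5 * (-6*t + 4);
  wdd[1] = 0.5 * (18*t - 10);
  wdd[2] = 0.5 * (-18*t + 8);
  wdd[3] = 0.5 * (6*t - 2);
}

void GridField::frac(const double* x, double* u) const {
  double d[3] = { x[0] - origin[0], x[1] - origin[1], x[2] - origin[2] };
  for (int i = 0; i < 3; ++i)
    u[i] = Minv[3*i] * d[0] + Minv[3*i+1] * d[1] + Minv[3*i+2] * d[2];
}

bool GridField::in_domain(const double* x) const {
  if (periodic) return true;
  double u[3];
  frac(x, u);
  return u[0] >= 0 && u[0] <= nx - 1 && u[1] >= 0 && u[1] <= ny - 1 &&
         u[2] >= 0 && u[2] <= nz - 1;
}

double GridField::value(const double* x) const {
  double g[3];
  return const_cast<GridField*>(this)->GridField::valgrad(x, g);
}

double GridField::valgrad(const double* x, double* g) const {
  double u[3];
  frac(x, u);
  int i0[3]; double t[3];
  int dims[3] = { nx, ny, nz };
  for (int d = 0; d < 3; ++d) {
    double uf = std::floor(u[d]);
    i0[d] = (int)uf;
    t[d] = u[d] - uf;
    if (!periodic) { // clamp so grid nodes at the upper edge evaluate exactly
      if (i0[d] < 0) { i0[d] = 0; t[d] = u[d]; }
      if (i0[d] > dims[d] - 2) { i0[d] = dims[d] - 2; t[d] = u[d] - i0[d]; }
    }
  }
  double wx[4], wxd[4], wxdd[4], wy[4], wyd[4], wydd[4], wz[4], wzd[4], wzdd[4];
  cr_weights(t[0], wx, wxd, wxdd);
  cr_weights(t[1], wy, wyd, wydd);
  cr_weights(t[2], wz, wzd, wzdd);
  double v = 0, gu[3] = {0, 0, 0};
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      for (int c = 0; c < 4; ++c) {
        double val = at(i0[0] + a - 1, i0[1] + b - 1, i0[2] + c - 1);
        v += wx[a] * wy[b] * wz[c] * val;
        gu[0] += wxd[a] * wy[b] * wz[c] * val;
        gu[1] += wx[a] * wyd[b] * wz[c] * val;
        gu[2] += wx[a] * wy[b] * wzd[c] * val;
      }
  // grad_x = Minv^T grad_u
  for (int i = 0; i < 3; ++i)
    g[i] = Minv[i] * gu[0] + Minv[3 + i] * gu[1] + Minv[6 + i] * gu[2];
  return v;
}

void GridField::hessian(const double* x, double* H) const {
  double u[3];
  frac(x, u);
  int i0[3]; double t[3];
  int dims[3] = { nx, ny, nz };
  for (int d = 0; d < 3; ++d) {
    double uf = std::floor(u[d]);
    i0[d] = (int)uf;
    t[d] = u[d] - uf;
    if (!periodic) {
      if (i0[d] < 0) { i0[d] = 0; t[d] = u[d]; }
      if (i0[d] > dims[d] - 2) { i0[d] = dims[d] - 2; t[d] = u[d] - i0[d]; }
    }
  }
  double wx[4], wxd[4], wxdd[4], wy[4], wyd[4], wydd[4], wz[4], wzd[4], wzdd[4];
  cr_weights(t[0], wx, wxd, wxdd);
  cr_weights(t[1], wy, wyd, wydd);
  cr_weights(t[2], wz, wzd, wzdd);
  double Hu[9] = {0,0,0,0,0,0,0,0,0};
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      for (int c = 0; c < 4; ++c) {
        double val = at(i0[0] + a - 1, i0[1] + b - 1, i0[2] + c - 1);
        Hu[0] += wxdd[a] * wy[b] * wz[c] * val;
        Hu[4] += wx[a] * wydd[b] * wz[c] * val;
        Hu[8] += wx[a] * wy[b] * wzdd[c] * val;
        Hu[1] += wxd[a] * wyd[b] * wz[c] * val;
        Hu[2] += wxd[a] * wy[b] * wzd[c] * val;
        Hu[5] += wx[a] * wyd[b] * wzd[c] * val;
      }
  Hu[3] = Hu[1]; Hu[6] = Hu[2]; Hu[7] = Hu[5];
  // H_x = Minv^T Hu Minv
  double T[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      T[3*i+j] = Hu[3*i] * Minv[j] + Hu[3*i+1] * Minv[3+j] + Hu[3*i+2] * Minv[6+j];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      H[3*i+j] = Minv[i] * T[j] + Minv[3+i] * T[3+j] + Minv[6+i] * T[6+j];
}

// ---------------------------------------------------------------- derived

static const double CTF = 2.8712340001881918; // (3/10)(3 pi^2)^{2/3}

double DerivedField::value(const double* x) const {
  if (kind == "vw" || kind == "tfvw") {
    double g[3];
    double r = base->valgrad(x, g);
    double vw = r > 1e-30 ? (g[0]*g[0] + g[1]*g[1] + g[2]*g[2]) / (8.0 * r) : 0.0;
    if (kind == "vw") return c * vw;
    return c * (CTF * std::pow(r, 5.0 / 3.0) + lam * vw);
  }
  double r = base->value(x);
  if (kind == "scale") return c * r;
  if (kind == "shift") return r + c;
  if (kind == "power") return c * std::pow(r, k);
  if (kind == "tf")    return c * CTF * std::pow(r, 5.0 / 3.0);
  Rcpp::stop("unknown derived field kind");
}

double DerivedField::valgrad(const double* x, double* g) const {
  if (kind == "scale" || kind == "shift" || kind == "power" || kind == "tf") {
    double r = base->valgrad(x, g);
    double s, v;
    if (kind == "scale") { v = c * r; s = c; }
    else if (kind == "shift") { v = r + c; s = 1.0; }
    else if (kind == "power") { v = c * std::pow(r, k); s = c * k * std::pow(r, k - 1.0); }
    else { v = c * CTF * std::pow(r, 5.0/3.0); s = c * CTF * (5.0/3.0) * std::pow(r, 2.0/3.0); }
    g[0] *= s; g[1] *= s; g[2] *= s;
    return v;
  }
  Rcpp::stop("gradient not available for derived field kind '%s'", kind.c_str());
}

void DerivedField::hessian(const double* x, double* H) const {
  if (kind == "scale" || kind == "shift") {
    base->hessian(x, H);
    if (kind == "scale") for (int i = 0; i < 9; ++i) H[i] *= c;
    return;
  }
  Rcpp::stop("hessian not available for derived field kind '%s'", kind.c_str());
}

// ---------------------------------------------------------------- eig3

void eig3(const double* Hin, double* eval, double* evec) {
  double A[9];
  for (int i = 0; i < 9; ++i) A[i] = Hin[i];
  double V[9] = {1,0,0, 0,1,0, 0,0,1};
  for (int sweep = 0; sweep < 64; ++sweep) {
    double off = std::fabs(A[1]) + std::fabs(A[2]) + std::fabs(A[5]);
    if (off < 1e-14 * (std::fabs(A[0]) + std::fabs(A[4]) + std::fabs(A[8]) + 1e-300))
      break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        double apq = A[3*p+q];
        if (std::fabs(apq) < 1e-300) continue;
        double app = A[3*p+p], aqq = A[3*q+q];
        double phi = 0.5 * std::atan2(2 * apq, aqq - app);
        double ct = std::cos(phi), st = std::sin(phi);
        for (int k2 = 0; k2 < 3; ++k2) {
          double akp = A[3*k2+p], akq = A[3*k2+q];
          A[3*k2+p] = ct * akp - st * akq;
          A[3*k2+q] = st * akp + ct * akq;
        }
        for (int k2 = 0; k2 < 3; ++k2) {
          double apk = A[3*p+k2], aqk = A[3*q+k2];
          A[3*p+k2] = ct * apk - st * aqk;
          A[3*q+k2] = st * apk + ct * aqk;
        }
        for (int k2 = 0; k2 < 3; ++k2) {
          double vkp = V[3*k2+p], vkq = V[3*k2+q];
          V[3*k2+p] = ct * vkp - st * vkq;
          V[3*k2+q] = st * vkp + ct * vkq;
        }
      }
  }
  int ord[3] = {0, 1, 2};
  double d[3] = { A[0], A[4], A[8] };
  for (int i = 0; i < 2; ++i)
    for (int j = i + 1; j < 3; ++j)
      if (d[ord[j]] < d[ord[i]]) std::swap(ord[i], ord[j]);
  for (int i = 0; i < 3; ++i) {
    eval[i] = d[ord[i]];
    for (int k2 = 0; k2 < 3; ++k2) evec[3*k2+i] = V[3*k2+ord[i]];
  }
}

// ---------------------------------------------------------------- R bindings

static void finalize_field(Field* f) { delete f; }

// [[Rcpp::export(name = ".cpp_promol_field")]]
SEXP cpp_promol_field(NumericMatrix positions, List shell_list,
                      Nullable<NumericMatrix> lattice, double tail_tol) {
  PromolField* f = new PromolField();
  int n = positions.nrow();
  for (int i = 0; i < n; ++i) {
    std::array<double,3> p = { positions(i,0), positions(i,1), positions(i,2) };
    f->pos.push_back(p);
    NumericMatrix sm = shell_list[i]; // columns c, p, a
    std::vector<Shell> sv;
    for (int s = 0; s < sm.nrow(); ++s) {
      Shell sh;
      sh.c = sm(s,0); sh.p = sm(s,1); sh.a = sm(s,2);
      // solve c r^p exp(-a r) = tail_tol by iteration
      double r = std::max(1.0, (sh.p + 2.0) / sh.a);
      for (int it = 0; it < 80; ++it) {
        double lhs = std::log(std::fabs(sh.c) + 1e-300) + sh.p * std::log(r) - sh.a * r;
        r = (std::log(std::fabs(sh.c) + 1e-300) + sh.p * std::log(r) - std::log(tail_tol)) / sh.a;
        if (r < 0.5) { r = 0.5; break; }
        (void)lhs;
      }
      sh.rcut = r + 1.0;
      sv.push_back(sh);
    }
    f->shells.push_back(sv);
  }
  f->periodic = lattice.isNotNull();
  if (f->periodic) {
    NumericMatrix L(lattice);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) f->lat[3*i+j] = L(i,j);
    // image shells out to the largest shell cutoff plus one cell
    double rmax = 0;
    for (size_t ia = 0; ia < f->shells.size(); ++ia)
      for (size_t is = 0; is < f->shells[ia].size(); ++is)
        rmax = std::max(rmax, f->shells[ia][is].rcut);
    double lmin = 1e30;
    for (int i = 0; i < 3; ++i) {
      double l = std::sqrt(f->lat[3*i]*f->lat[3*i] + f->lat[3*i+1]*f->lat[3*i+1] +
                           f->lat[3*i+2]*f->lat[3*i+2]);
      lmin = std::min(lmin, l);
    }
    int m = (int)std::ceil(rmax / lmin) + 1;
    // keep only shifts that can bring some atom within rmax of the cell
    double diag = 0;
    for (int j = 0; j < 3; ++j) {
      double t = f->lat[j] + f->lat[3+j] + f->lat[6+j];
      diag += t * t;
    }
    diag = std::sqrt(diag);
    for (int a = -m; a <= m; ++a)
      for (int b = -m; b <= m; ++b)
        for (int c = -m; c <= m; ++c) {
          std::array<double,3> s;
          for (int j = 0; j < 3; ++j)
            s[j] = a * f->lat[j] + b * f->lat[3+j] + c * f->lat[6+j];
          double sn = std::sqrt(s[0]*s[0] + s[1]*s[1] + s[2]*s[2]);
          if (sn > rmax + diag) continue;
          f->images.push_back(s);
        }
  } else {
    std::array<double,3> zero = {0, 0, 0};
    f->images.push_back(zero);
  }
  f->finalize();
  XPtr<Field> ptr(f, true);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_grid_field")]]
SEXP cpp_grid_field(NumericVector origin, NumericMatrix axes,
                    IntegerVector dim, NumericVector values, bool periodic) {
  GridField* f = new GridField();
  for (int i = 0; i < 3; ++i) f->origin[i] = origin[i];
  // axes rows are the three voxel step vectors; M columns are steps
  double M[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) M[3*j+i] = axes(i, j);
  for (int i = 0; i < 9; ++i) f->M[i] = M[i];
  double det = M[0]*(M[4]*M[8]-M[5]*M[7]) - M[1]*(M[3]*M[8]-M[5]*M[6])
             + M[2]*(M[3]*M[7]-M[4]*M[6]);
  if (std::fabs(det) < 1e-300) stop("grid axes are singular");
  double inv[9] = {
    (M[4]*M[8]-M[5]*M[7]), (M[2]*M[7]-M[1]*M[8]), (M[1]*M[5]-M[2]*M[4]),
    (M[5]*M[6]-M[3]*M[8]), (M[0]*M[8]-M[2]*M[6]), (M[2]*M[3]-M[0]*M[5]),
    (M[3]*M[7]-M[4]*M[6]), (M[1]*M[6]-M[0]*M[7]), (M[0]*M[4]-M[1]*M[3]) };
  for (int i = 0; i < 9; ++i) f->Minv[i] = inv[i] / det;
  f->nx = dim[0]; f->ny = dim[1]; f->nz = dim[2];
  if ((size_t)f->nx * f->ny * f->nz != (size_t)values.size())
    stop("grid dimensions do not match value count");
  f->v.assign(values.begin(), values.end());
  f->periodic = periodic;
  XPtr<Field> ptr(f, true);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_derived_field")]]
SEXP cpp_derived_field(SEXP basePtr, std::string kind, double c, double k,
                       double lam) {
  XPtr<Field> base(basePtr);
  DerivedField* f = new DerivedField();
  f->base = base.get();
  f->kind = kind; f->c = c; f->k = k; f->lam = lam;
  XPtr<Field> ptr(f, true);
  // keep the base alive alongside the derived field
  ptr.attr("base") = base;
  return ptr;
}

// [[Rcpp::export(name = ".cpp_field_eval")]]
List cpp_field_eval(SEXP fptr, NumericMatrix pts, bool want_grad,
                    bool want_hess) {
  XPtr<Field> f(fptr);
  int n = pts.nrow();
  NumericVector val(n);
  NumericMatrix grad(want_grad ? n : 0, 3);
  NumericVector hess(want_hess ? n * 9 : 0);
  for (int i = 0; i < n; ++i) {
    double x[3] = { pts(i,0), pts(i,1), pts(i,2) };
    if (want_grad) {
      double g[3];
      val[i] = f->valgrad(x, g);
      grad(i,0) = g[0]; grad(i,1) = g[1]; grad(i,2) = g[2];
    } else {
      val[i] = f->value(x);
    }
    if (want_hess) {
      double H[9];
      f->hessian(x, H);
      for (int j = 0; j < 9; ++j) hess[i*9 + j] = H[j];
    }
  }
  List out = List::create(_["value"] = val);
  if (want_grad) out["gradient"] = grad;
  if (want_hess) {
    hess.attr("dim") = IntegerVector::create(9, n);
    out["hessian"] = hess;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_in_domain")]]
LogicalVector cpp_in_domain(SEXP fptr, NumericMatrix pts) {
  XPtr<Field> f(fptr);
  int n = pts.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    double x[3] = { pts(i,0), pts(i,1), pts(i,2) };
    out[i] = f->in_domain(x);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_eig3")]]
List cpp_eig3(NumericVector H) {
  double eval[3], evec[9];
  eig3(REAL(H), eval, evec);
  NumericVector ev(3);
  NumericMatrix V(3, 3);
  for (int i = 0; i < 3; ++i) {
    ev[i] = eval[i];
    for (int j = 0; j < 3; ++j) V(j, i) = evec[3*j+i];
  }
  return List::create(_["values"] = ev, _["vectors"] = V);
}
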