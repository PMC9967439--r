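#ifndef BONDBUNDLES_CORE_H
#define BONDBUNDLES_CORE_H

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>

// Abstract 3D scalar field.  All coordinates in bohr, values in atomic units.
struct Field {
  virtual double value(const double* x) const = 0;
  // returns value, fills g[3]
  virtual double valgrad(const double* x, double* g) const = 0;
  // fills H[9] row-major (symmetric)
  virtual void hessian(const double* x, double* H) const = 0;
  virtual bool in_domain(const double* x) const { return true; }
  virtual ~Field() {}
};

// One Slater-type radial shell: contributes c * r^p * exp(-a r) to rho.
struct Shell {
  double c, p, a;
  double rcut;  // radius beyond which the shell is negligible
  double rcut2; // rcut^2 (early-out on squared distance)
  int ip;       // p when p is a small even integer, else -1
};

struct PromolField : Field {
  std::vector<std::array<double,3> > pos;   // nuclear positions
  std::vector<std::vector<Shell> > shells;  // per atom
  std::vector<double> rcut2_atom;           // max shell rcut^2 per atom
  bool periodic;
  double lat[9];                            // rows are lattice vectors
  std::vector<std::array<double,3> > images; // lattice image shifts (incl. 0)

  void finalize();
  double value(const double* x) const override;
  double valgrad(const double* x, double* g) const override;
  void hessian(const double* x, double* H) const override;
};

// Tricubic (Catmull-Rom) interpolated grid field.
struct GridField : Field {
  double origin[3];
  double M[9];     // columns are voxel step vectors: x = origin + M u
  double Minv[9];  // inverse
  int nx, ny, nz;
  std::vector<double> v; // R column-major: idx = i + nx*(j + ny*k)
  bool periodic;

  inline double at(int i, int j, int k) const {
    if (periodic) {
      i %= nx; if (i < 0) i += nx;
      j %= ny; if (j < 0) j += ny;
      k %= nz; if (k < 0) k += nz;
    } else {
      if (i < 0) i = 0; if (i >= nx) i = nx - 1;
      if (j < 0) j = 0; if (j >= ny) j = ny - 1;
      if (k < 0) k = 0; if (k >= nz) k = nz - 1;
    }
    return v[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
  }
  bool in_domain(const double* x) const override;
  void frac(const double* x, double* u) const;
  double value(const double* x) const override;
  double valgrad(const double* x, double* g) const override;
  void hessian(const double* x, double* H) const override;
};

// Field derived pointwise from a base field:
//   scale: c * f ;  power: c * f^k ;  tf: cTF * rho^{5/3} ;
//   vw: |grad rho|^2/(8 rho) ;  tfvw: tf + lam * vw ;  shift: f + c
struct DerivedField : Field {
  const Field* base;
  std::string kind;
  double c, k, lam;
  double value(const double* x) const override;
  double valgrad(const double* x, double* g) const override;
  void hessian(const double* x, double* H) const override;
  bool in_domain(const double* x) const override { return base->in_domain(x); }
};

// symmetric 3x3 eigen-decomposition (Jacobi); evals ascending, evecs in columns
void eig3(const double* H, double* eval, double* evec);

// ---- gradient path tracer (trace.cpp) ----
struct TraceOpts {
  double h0, hmax, hmin, gtol, trunc, capture, nudge;
  int max_steps;
  int direction; // +1 ascent, -1 descent
};

struct TraceResult {
  std::vector<std::array<double,3> > pts;
  std::vector<double> rho;
  std::string status; // "cp", "truncated", "boundary", "maxsteps", "stalled"
  int cp_index;       // 1-based index into supplied CP list, 0 = none
};

TraceResult trace_one(const Field* f, const double* seed, const TraceOpts& o,
                      const Rcpp::NumericMatrix& cps,
                      const Rcpp::IntegerVector& cp_sig);
TraceOpts opts_from_list(Rcpp::List control, int direction);

#endif
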