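#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Red-black successive over-relaxation for the finite-difference
// Poisson-Boltzmann equation on a uniform grid.
//
//   sum_f eps_f (phi_nbr - phi0) - h^2 * K * S(phi0) + src = 0
//
// with S = phi (linear) or sinh(phi) (nonlinear, local Newton update),
// K = eps_out * kappa^2 at ionic nodes (0 inside the solute), phi in
// kT/e, lengths in Angstrom. Boundary nodes are Dirichlet (preset in
// phi). Returns iterations used and the residual history (max |dphi|
// per sweep); conv == false if tol was not reached.
// [[Rcpp::export]]
List pb_sor(NumericVector phi, IntegerVector dims,
            NumericVector epsx, NumericVector epsy, NumericVector epsz,
            NumericVector kap2, NumericVector src,
            double h, bool nonlinear, double tol, int maxit, double omega) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double h2 = h * h;
  std::vector<double> hist;
  hist.reserve(maxit);
  double *p = REAL(phi);
  const double *ex = REAL(epsx), *ey = REAL(epsy), *ez = REAL(epsz);
  const double *kk = REAL(kap2), *q = REAL(src);

  // face index helpers: epsx has (nx-1) x ny x nz etc., node-major
  #define IDX(i, j, k) ((i) + (size_t)nx * ((j) + (size_t)ny * (k)))
  #define IEX(i, j, k) ((i) + (size_t)(nx - 1) * ((j) + (size_t)ny * (k)))
  #define IEY(i, j, k) ((i) + (size_t)nx * ((j) + (size_t)(ny - 1) * (k)))
  #define IEZ(i, j, k) ((i) + (size_t)nx * ((j) + (size_t)ny * (k)))

  bool conv = false;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    double maxd = 0.0;
    for (int color = 0; color < 2; ++color) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          int i0 = 1 + ((j + k + 1 + color) & 1);
          for (int i = i0; i < nx - 1; i += 2) {
            size_t id = IDX(i, j, k);
            double exm = ex[IEX(i - 1, j, k)], exp_ = ex[IEX(i, j, k)];
            double eym = ey[IEY(i, j - 1, k)], eyp = ey[IEY(i, j, k)];
            double ezm = ez[IEZ(i, j, k - 1)], ezp = ez[IEZ(i, j, k)];
            double seps = exm + exp_ + eym + eyp + ezm + ezp;
            double nbr = exm * p[id - 1] + exp_ * p[id + 1]
                       + eym * p[id - nx] + eyp * p[id + nx]
                       + ezm * p[id - (size_t)nx * ny]
                       + ezp * p[id + (size_t)nx * ny];
            double phi0 = p[id];
            double K = kk[id];
            double res, den;
            if (nonlinear && K > 0.0) {
              double sh = std::sinh(phi0), ch = std::cosh(phi0);
              res = nbr - seps * phi0 - h2 * K * sh + q[id];
              den = seps + h2 * K * ch;
            } else {
              res = nbr - seps * phi0 - h2 * K * phi0 + q[id];
              den = seps + h2 * K;
            }
            double d = omega * res / den;
            p[id] = phi0 + d;
            double ad = std::fabs(d);
            if (ad > maxd) maxd = ad;
          }
        }
      }
    }
    hist.push_back(maxd);
    if (maxd < tol) { conv = true; break; }
  }
  #undef IDX
  #undef IEX
  #undef IEY
  #undef IEZ
  return List::create(_["phi"] = phi, _["iterations"] = std::min(it, maxit),
                      _["converged"] = conv,
                      _["residual_history"] = NumericVector(hist.begin(),
                                                            hist.end()));
}

// Mark grid nodes lying inside any probe-inflated atom sphere.
// [[Rcpp::export]]
LogicalVector grid_inside(IntegerVector dims, NumericVector origin, double h,
                          NumericVector ax, NumericVector ay,
                          NumericVector az, NumericVector ar) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector inside((size_t)nx * ny * nz, false);
  int *ins = LOGICAL(inside);
  for (int a = 0; a < ax.size(); ++a) {
    double r = ar[a], r2 = r * r;
    int i0 = std::max(0, (int)std::floor((ax[a] - r - origin[0]) / h));
    int i1 = std::min(nx - 1, (int)std::ceil((ax[a] + r - origin[0]) / h));
    int j0 = std::max(0, (int)std::floor((ay[a] - r - origin[1]) / h));
    int j1 = std::min(ny - 1, (int)std::ceil((ay[a] + r - origin[1]) / h));
    int k0 = std::max(0, (int)std::floor((az[a] - r - origin[2]) / h));
    int k1 = std::min(nz - 1, (int)std::ceil((az[a] + r - origin[2]) / h));
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * h - az[a], dz2 = dz * dz;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * h - ay[a], d2 = dy * dy + dz2;
        if (d2 > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * h - ax[a];
          if (dx * dx + d2 <= r2)
            ins[i + (size_t)nx * (j + (size_t)ny * k)] = 1;
        }
      }
    }
  }
  return inside;
}
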