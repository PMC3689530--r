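// Direct summation of macromolecular structure factors:
//   F_H = sum_S sum_n w_n f_n(d*) exp(-2 pi^2 u_n d*^2)
//                 exp(2 pi i H . (R_S x_n + T_S))
// Templated on the working precision so the 32-bit path really performs
// every inner operation (d*, form factor, Debye-Waller, phases, trig,
// accumulation) in IEEE single precision.  Accumulation order is fixed
// (scatterers innermost, operators outer) and the single-precision path
// uses Kahan compensated summation so results are independent of any
// chunking chosen by the caller.
#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

template <typename T>
struct Kahan {
  T sum = 0, comp = 0;
  inline void add(T v) {
    T y = v - comp;
    T t = sum + y;
    comp = (t - sum) - y;
    sum = t;
  }
};

template <typename T, bool compensated>
static void sf_direct_t(const NumericMatrix& hkl,
                        const NumericMatrix& xyz,
                        const NumericVector& occ,
                        const NumericVector& uiso,
                        const IntegerVector& ffidx,
                        const NumericMatrix& ff_a,
                        const NumericMatrix& ff_b,
                        const NumericVector& ff_c,
                        const NumericMatrix& rot,
                        const NumericMatrix& tra,
                        const NumericMatrix& gstar,
                        ComplexVector& out) {
  const int nh = hkl.nrow(), nat = xyz.nrow(), nsym = tra.nrow();
  const int nff = ff_a.nrow(), ng = ff_a.ncol();
  const T two_pi = static_cast<T>(2.0 * M_PI);
  const T two_pi2 = static_cast<T>(2.0 * M_PI * M_PI);

  std::vector<T> X(nat), Y(nat), Z(nat), W(nat), U(nat);
  for (int n = 0; n < nat; ++n) {
    X[n] = static_cast<T>(xyz(n, 0)); Y[n] = static_cast<T>(xyz(n, 1));
    Z[n] = static_cast<T>(xyz(n, 2));
    W[n] = static_cast<T>(occ[n]);    U[n] = static_cast<T>(uiso[n]);
  }
  std::vector<T> A(nff * ng), B(nff * ng), C(nff);
  for (int r = 0; r < nff; ++r) {
    C[r] = static_cast<T>(ff_c[r]);
    for (int g = 0; g < ng; ++g) {
      A[r * ng + g] = static_cast<T>(ff_a(r, g));
      B[r * ng + g] = static_cast<T>(ff_b(r, g));
    }
  }
  std::vector<T> G(9);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) G[3 * i + j] = static_cast<T>(gstar(i, j));

  std::vector<T> coef(nat), fval(nff);

  for (int m = 0; m < nh; ++m) {
    const T h = static_cast<T>(hkl(m, 0)), k = static_cast<T>(hkl(m, 1)),
            l = static_cast<T>(hkl(m, 2));
    // d*^2 = H^T G* H
    const T ds2 = h * (G[0] * h + G[1] * k + G[2] * l) +
                  k * (G[3] * h + G[4] * k + G[5] * l) +
                  l * (G[6] * h + G[7] * k + G[8] * l);
    const T s2 = ds2 / static_cast<T>(4);  // (d*/2)^2
    for (int r = 0; r < nff; ++r) {
      T f = C[r];
      for (int g = 0; g < ng; ++g)
        f += A[r * ng + g] * std::exp(-B[r * ng + g] * s2);
      fval[r] = f;
    }
    for (int n = 0; n < nat; ++n)
      coef[n] = W[n] * fval[ffidx[n]] * std::exp(-two_pi2 * U[n] * ds2);

    Kahan<T> re_k, im_k;
    T re_p = 0, im_p = 0;
    for (int s = 0; s < nsym; ++s) {
      // row vector H.R and phase offset H.T
      const T hr1 = h * static_cast<T>(rot(3 * s + 0, 0)) +
                    k * static_cast<T>(rot(3 * s + 1, 0)) +
                    l * static_cast<T>(rot(3 * s + 2, 0));
      const T hr2 = h * static_cast<T>(rot(3 * s + 0, 1)) +
                    k * static_cast<T>(rot(3 * s + 1, 1)) +
                    l * static_cast<T>(rot(3 * s + 2, 1));
      const T hr3 = h * static_cast<T>(rot(3 * s + 0, 2)) +
                    k * static_cast<T>(rot(3 * s + 1, 2)) +
                    l * static_cast<T>(rot(3 * s + 2, 2));
      const T ph0 = h * static_cast<T>(tra(s, 0)) +
                    k * static_cast<T>(tra(s, 1)) +
                    l * static_cast<T>(tra(s, 2));
      for (int n = 0; n < nat; ++n) {
        const T phase = two_pi * (hr1 * X[n] + hr2 * Y[n] + hr3 * Z[n] + ph0);
        const T cre = coef[n] * std::cos(phase);
        const T cim = coef[n] * std::sin(phase);
        if (compensated) { re_k.add(cre); im_k.add(cim); }
        else             { re_p += cre;   im_p += cim; }
      }
    }
    Rcomplex z;
    z.r = static_cast<double>(compensated ? re_k.sum : re_p);
    z.i = static_cast<double>(compensated ? im_k.sum : im_p);
    out[m] = z;
  }
}

// [[Rcpp::export(name = ".sf_direct_cpp")]]
ComplexVector sf_direct_cpp(NumericMatrix hkl, NumericMatrix xyz,
                            NumericVector occ, NumericVector uiso,
                            IntegerVector ffidx, NumericMatrix ff_a,
                            NumericMatrix ff_b, NumericVector ff_c,
                            NumericMatrix rot, NumericMatrix tra,
                            NumericMatrix gstar, bool single) {
  ComplexVector out(hkl.nrow());
  if (single)
    sf_direct_t<float, true>(hkl, xyz, occ, uiso, ffidx, ff_a, ff_b, ff_c,
                             rot, tra, gstar, out);
  else
    sf_direct_t<double, false>(hkl, xyz, occ, uiso, ffidx, ff_a, ff_b, ff_c,
                               rot, tra, gstar, out);
  return out;
}
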