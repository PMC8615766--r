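// Harmonic-balance solver for the axially symmetric Brown rotational
// Fokker-Planck equation.
//
// The orientation distribution W(x, t), x = cos(theta), evolves under the
// reduced energy beta*E = -xi(t)*x - sig_a*x^2 with
// xi(t) = xi0 + xi1*sin(w t). Expanding W in Legendre polynomials,
// f_l = <P_l>, gives the coupled mode system
//
//   2*tau * df_l/dt = -l(l+1) f_l
//                     + F_l * xi(t) * (f_{l-1} - f_{l+1})
//                     + am_l f_{l-2} + ad_l f_l + ap_l f_{l+2}
//
// with F_l = l(l+1)/(2l+1) and, writing G_l = 2*sig_a*F_l,
//   am_l = G_l (l-1)/(2l-1)
//   ad_l = G_l ( l/(2l-1) - (l+1)/(2l+3) )
//   ap_l = -G_l (l+2)/(2l+3),
// f_0 = 1.  Seeking the periodic steady state f_l(t) = sum_n c_{l,n} e^{inwt}
// (|n| <= nmax, l <= lmax) turns this into a sparse linear system that is
// block tridiagonal in n (xi1 couples n -> n+-1).  It is solved by block
// Thomas elimination with dense lmax x lmax complex blocks.
//
// The quantity returned is c_{1,2}, the complex e^{2iwt} amplitude of <x>:
// the physical 2w waveform of <x> is
//   2*Re(c_{1,2}) cos(2wt) - 2*Im(c_{1,2}) sin(2wt).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static cx_double hb_single(double xi0, double xi1, double omega_tau,
                           double sig_a, int lmax, int nmax, bool &ok) {
  const cx_double I(0.0, 1.0);
  const int nb = 2 * nmax + 1;            // blocks n = -nmax..nmax
  const int L = lmax;

  // per-l coefficients (index 0 holds l = 1)
  vec Fl(L), am(L), ad(L), ap(L), lap(L);
  for (int i = 0; i < L; ++i) {
    double l = i + 1.0;
    double F = l * (l + 1.0) / (2.0 * l + 1.0);
    double G = 2.0 * sig_a * F;
    Fl(i) = F;
    lap(i) = l * (l + 1.0);
    am(i) = G * (l - 1.0) / (2.0 * l - 1.0);
    ad(i) = G * (l / (2.0 * l - 1.0) - (l + 1.0) / (2.0 * l + 3.0));
    ap(i) = -G * (l + 2.0) / (2.0 * l + 3.0);
  }

  // off-diagonal (in n) block: couples block n to n-1; block to n+1 is -Loff
  cx_mat Loff(L, L, fill::zeros);
  for (int i = 0; i < L; ++i) {
    if (i - 1 >= 0) Loff(i, i - 1) = 0.5 * I * xi1 * Fl(i);
    if (i + 1 < L)  Loff(i, i + 1) = -0.5 * I * xi1 * Fl(i);
  }
  cx_mat Uoff = -Loff;

  // diagonal block for harmonic n
  auto diag_block = [&](int n) {
    cx_mat D(L, L, fill::zeros);
    for (int i = 0; i < L; ++i) {
      D(i, i) = cx_double(lap(i) - ad(i), 2.0 * n * omega_tau);
      if (i - 1 >= 0) D(i, i - 1) = -Fl(i) * xi0;
      if (i + 1 < L)  D(i, i + 1) = Fl(i) * xi0;
      if (i - 2 >= 0) D(i, i - 2) = -am(i);
      if (i + 2 < L)  D(i, i + 2) = -ap(i);
    }
    return D;
  };

  // right-hand side blocks (forcing from the known f_0 = 1)
  std::vector<cx_vec> b(nb, cx_vec(L, fill::zeros));
  b[nmax](0) = Fl(0) * xi0;                       // (l=1, n=0)
  if (L >= 2) b[nmax](1) = am(1);                 // (l=2, n=0)
  if (nmax >= 1) {
    b[nmax + 1](0) = -0.5 * I * xi1 * Fl(0);      // (l=1, n=+1)
    b[nmax - 1](0) = 0.5 * I * xi1 * Fl(0);       // (l=1, n=-1)
  }

  // block Thomas: forward elimination over n-blocks
  std::vector<cx_mat> Bt(nb);
  std::vector<cx_vec> bt(nb);
  ok = true;
  const auto opts = solve_opts::fast + solve_opts::no_approx;
  Bt[0] = diag_block(-nmax);
  bt[0] = b[0];
  for (int k = 1; k < nb; ++k) {
    cx_mat X;
    // X = Loff * inv(Bt[k-1]) computed as solve(Bt', Loff')'
    if (!solve(X, Bt[k - 1].st(), Loff.st(), opts)) { ok = false; return cx_double(0, 0); }
    X = X.st();
    Bt[k] = diag_block(-nmax + k) - X * Uoff;
    bt[k] = b[k] - X * bt[k - 1];
  }
  // back substitution
  std::vector<cx_vec> c(nb);
  if (!solve(c[nb - 1], Bt[nb - 1], bt[nb - 1], opts)) { ok = false; return cx_double(0, 0); }
  for (int k = nb - 2; k >= 0; --k) {
    cx_vec rhs = bt[k] - Uoff * c[k + 1];
    if (!solve(c[k], Bt[k], rhs, opts)) { ok = false; return cx_double(0, 0); }
  }

  if (nmax < 2) return cx_double(0, 0);
  return c[nmax + 2](0);                          // c_{l=1, n=+2}
}

// Batched harmonic-balance solve.  All argument vectors are parallel; each
// element is one (dc field, moment) node with its own truncation orders.
// Returns the complex c_{1,2} amplitude per node.
// [[Rcpp::export]]
Rcpp::ComplexVector hb_solve_batch(Rcpp::NumericVector xi0,
                                   Rcpp::NumericVector xi1,
                                   Rcpp::NumericVector omega_tau,
                                   Rcpp::NumericVector sig_a,
                                   Rcpp::IntegerVector lmax,
                                   Rcpp::IntegerVector nmax) {
  int n = xi0.size();
  Rcpp::ComplexVector out(n);
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    cx_double a = hb_single(xi0[i], xi1[i], omega_tau[i], sig_a[i],
                            lmax[i], nmax[i], ok);
    if (!ok)
      Rcpp::stop("harmonic-balance linear solve failed at node %d (xi0 = %g)",
                 i + 1, xi0[i]);
    out[i] = Rcomplex{a.real(), a.imag()};
  }
  return out;
}
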