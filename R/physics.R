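#' Langevin function
#'
#' Equilibrium magnetization fraction L(xi) = coth(xi) - 1/xi of an isotropic
#' classical moment at reduced field xi = m*H/(k_B*T). For |xi| below 1e-3
#' the series xi/3 - xi^3/45 is used to avoid catastrophic cancellation.
#'
#' @param xi reduced field (dimensionless), any finite numeric vector.
#' @return L(xi), same shape as `xi`. Odd, bounded in (-1, 1).
#' @examples
#' langevin(1)      # 0.31304
#' langevin(-2) == -langevin(2)
#' @export
langevin <- function(xi) {
  stopifnot(is.numeric(xi))
  out <- xi
  small <- abs(xi) < 1e-3
  xs <- xi[small]
  out[small] <- xs / 3 - xs^3 / 45
  xl <- xi[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

# first and second derivatives of the Langevin function (used by the
# quasi-static perturbative response and the fit initializer)
langevin_d2 <- function(xi) {
  out <- xi
  small <- abs(xi) < 1e-3
  xs <- xi[small]
  # L(x) = x/3 - x^3/45 + 2x^5/945 => L'' = -6x/45 + 40x^3/945
  out[small] <- -2 * xs / 15 + 8 * xs^3 / 189
  xl <- xi[!small]
  out[!small] <- 2 / tanh(xl) / sinh(xl)^2 - 2 / xl^3
  out
}

#' Free-diffusion (Neel) relaxation time
#'
#' Longitudinal free-relaxation time of a single-domain moment,
#' tau = (1 + alpha^2) * m / (2 * gamma * alpha * k_B * T) with
#' m = M_C * mu_B, returned in nanoseconds. This ties the damping factor and
#' the relaxation time together so that fitted `(alpha, tau_N)` pairs are
#' always mutually consistent.
#'
#' @param M_C aggregate moment (Bohr magnetons), > 0. Vectorized.
#' @param alpha dimensionless damping factor, > 0. Vectorized.
#' @param T absolute temperature (K), > 0.
#' @return Relaxation time in ns.
#' @examples
#' neel_time(31580, 0.2057, 300)  # ~1.02 ns
#' @export
neel_time <- function(M_C, alpha, T = 300) {
  stopifnot(is.numeric(M_C), is.numeric(alpha), is.numeric(T))
  if (any(M_C <= 0) || any(T <= 0)) abort("`M_C` and `T` must be positive.")
  if (any(alpha <= 0)) abort("`alpha` must be > 0: the relaxation time diverges as alpha -> 0.")
  cst <- m2_constants()
  (1 + alpha^2) * M_C * cst$mu_B / (2 * cst$gamma * alpha * cst$k_B * T) * 1e9
}

# equilibrium reduced magnetization <cos theta> at reduced field xi and
# reduced easy-axis anisotropy sig_a = E_A / T (easy axis along the field).
# sig_a = 0 reduces to the Langevin function; otherwise a 64-node
# Gauss-Legendre quadrature of the Boltzmann average over x = cos(theta).
equilibrium_mean_x <- function(xi, sig_a = 0) {
  if (sig_a == 0) return(langevin(xi))
  gl <- pracma::gaussLegendre(64, -1, 1)
  vapply(xi, function(x1) {
    lw <- x1 * gl$x + sig_a * gl$x^2
    lw <- lw - max(lw)                    # overflow guard
    w <- gl$w * exp(lw)
    sum(w * gl$x) / sum(w)
  }, numeric(1))
}

#' Quasi-static second-harmonic response (perturbative analytic limit)
#'
#' The f -> 0, small-h limit of the second harmonic of a single
#' superparamagnetic moment: under a drive h*sin(wt) the cos(2wt) coefficient
#' of the magnetization is -(h^2/4) * d^2 M_eq / dH^2 with
#' M_eq(H) = m*mu_B*L(m*mu_B*H/(k_B*T)); the quadrature component vanishes.
#' Serves as an analytic cross-check of the dynamic solver.
#'
#' @param H dc field (Oe), vectorized.
#' @param m moment (Bohr magnetons).
#' @param h ac amplitude (Oe), > 0.
#' @param T temperature (K).
#' @return A tibble with columns `H`, `re`, `im` (emu per particle).
#' @examples
#' quasistatic_m2_perturbative(c(0, 100), m = 30000, h = 13.8, T = 300)
#' @export
quasistatic_m2_perturbative <- function(H, m, h = 13.8, T = 300) {
  if (h <= 0) abort("`h` must be > 0.")
  cst <- m2_constants()
  beta_m <- m * cst$mu_B / (cst$k_B * T)       # 1/Oe
  xi <- beta_m * H
  re <- -(h^2 / 4) * m * cst$mu_B * beta_m^2 * langevin_d2(xi)
  tibble(H = H, re = re, im = rep(0, length(H)))
}

#' Quasi-static second-harmonic response (Fourier oracle)
#'
#' Non-perturbative quasi-static second harmonic: the equilibrium
#' magnetization is sampled along one drive period at instantaneous field
#' H + h*sin(wt) and the complex 2w Fourier coefficient extracted by
#' discrete projection. Exact in h in the f -> 0 limit; with `E_A > 0` the
#' equilibrium average includes the uniaxial anisotropy weight (easy axis
#' along the field).
#'
#' @inheritParams quasistatic_m2_perturbative
#' @param n_samples samples per period (>= 64).
#' @param E_A anisotropy energy (K), >= 0.
#' @return A tibble with columns `H`, `re` (cos 2wt coefficient), `im`
#'   (sin 2wt coefficient), emu per particle.
#' @export
quasistatic_m2_fft <- function(H, m, h = 13.8, T = 300, n_samples = 256,
                               E_A = 0) {
  if (n_samples < 64) abort("`n_samples` must be >= 64.")
  if (h <= 0) abort("`h` must be > 0.")
  cst <- m2_constants()
  beta_m <- m * cst$mu_B / (cst$k_B * T)
  sig_a <- E_A / T
  wt <- 2 * pi * (seq_len(n_samples) - 1) / n_samples
  drive <- h * sin(wt)
  res <- vapply(H, function(H0) {
    Mt <- m * cst$mu_B * equilibrium_mean_x(beta_m * (H0 + drive), sig_a)
    a2 <- 2 * mean(Mt * cos(2 * wt))
    b2 <- 2 * mean(Mt * sin(2 * wt))
    c(a2, b2)
  }, numeric(2))
  tibble(H = H, re = res[1, ], im = res[2, ])
}
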