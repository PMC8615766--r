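#' Magnetic parameter set of a superparamagnetic ensemble
#'
#' The parameter vector describing one specimen's ensemble of magnetically
#' active centers (nanoparticle aggregates): per-gram saturation
#' magnetization, mean aggregate moment, lognormal moment-distribution width,
#' damping factor, and anisotropy energy. The longitudinal free-relaxation
#' time `tau_N` is, by default, derived from `(M_C, alpha, T)` through
#' [neel_time()] so that the reported `(alpha, tau_N)` pair is always
#' self-consistent; pass `tau_N` explicitly to decouple them.
#'
#' @param M_tilde saturation magnetization (emu/g), >= 0.
#' @param M_C mean magnetic moment of an aggregate (Bohr magnetons), > 0.
#' @param sigma dimensionless log-width of the lognormal moment
#'   distribution, >= 0.
#' @param alpha dimensionless damping factor, > 0.
#' @param E_A magnetic anisotropy energy (K), >= 0.
#' @param tau_N longitudinal free-relaxation time (ns); if `NULL` (default),
#'   derived via [neel_time()] at temperature `T`.
#' @param T temperature (K) used when deriving `tau_N`.
#' @return An object of class `ensemble_params` (a named list).
#' @examples
#' # the injected MSC-SPION solution
#' ensemble_params(M_tilde = 3.633e-6, M_C = 31580, sigma = 0.734,
#'                 alpha = 0.2057, E_A = 8.3)
#' @export
ensemble_params <- function(M_tilde, M_C, sigma, alpha, E_A,
                            tau_N = NULL, T = 300) {
  for (nm in c("M_tilde", "M_C", "sigma", "alpha", "E_A")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      abort(sprintf("`%s` must be a single finite number.", nm))
  }
  if (M_tilde < 0) abort("`M_tilde` must be >= 0.")
  if (M_C <= 0) abort("`M_C` must be > 0.")
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (alpha <= 0) abort("`alpha` must be > 0 (relaxation time diverges at 0).")
  if (E_A < 0) abort("`E_A` must be >= 0.")
  if (is.null(tau_N)) tau_N <- neel_time(M_C, alpha, T)
  if (tau_N <= 0) abort("`tau_N` must be > 0.")
  structure(
    list(M_tilde = M_tilde, M_C = M_C, sigma = sigma, alpha = alpha,
         E_A = E_A, tau_N = tau_N),
    class = "ensemble_params")
}

#' @export
print.ensemble_params <- function(x, ...) {
  cat("<ensemble_params>\n")
  cat(sprintf("  M_tilde = %.4g emu/g   M_C = %.4g mu_B   sigma = %.3g\n",
              x$M_tilde, x$M_C, x$sigma))
  cat(sprintf("  alpha = %.4g   tau_N = %.4g ns   E_A = %.3g K\n",
              x$alpha, x$tau_N, x$E_A))
  invisible(x)
}

#' @export
as_tibble.ensemble_params <- function(x, ...) {
  tibble(M_tilde = x$M_tilde, M_C = x$M_C, sigma = x$sigma,
         alpha = x$alpha, tau_N = x$tau_N, E_A = x$E_A)
}
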