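#' Physical constants (CGS-Gaussian)
#'
#' Fixed constants used throughout the package. The whole package works in
#' CGS-Gaussian units (Oe, emu, erg, K); magnetic moments are stored in Bohr
#' magnetons.
#'
#' @return A named list with components
#'   \describe{
#'     \item{mu_B}{Bohr magneton, emu (erg/G): 9.274e-21.}
#'     \item{k_B}{Boltzmann constant, erg/K: 1.3807e-16.}
#'     \item{gamma}{Gyromagnetic ratio, rad s^-1 Oe^-1: 1.76e7.}
#'   }
#' @examples
#' m2_constants()$mu_B
#' @export
m2_constants <- function() {
  list(
    mu_B  = 9.274e-21,
    k_B   = 1.3807e-16,
    gamma = 1.76e7
  )
}

# internal shorthands
.mu_B  <- 9.274e-21
.k_B   <- 1.3807e-16
.gamma <- 1.76e7

# field scale (Oe) where |L''(xi)| peaks; xi_peak solves d|L''|/dxi = 0.
# Computed numerically from the Langevin function (see test-physics.R).
.xi_peak <- 1.372263
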