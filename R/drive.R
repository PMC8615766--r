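#' Drive conditions for a second-harmonic measurement
#'
#' Bundles the ac drive and dc field grid of an NLR-M2 acquisition: a weak ac
#' field h*sin(2*pi*f*t) applied parallel to a slowly swept dc field H, at
#' temperature T. Defaults follow the measurement protocol this package
#' models: h = 13.8 Oe, f = 15.7 MHz, dc sweep over -300..300 Oe.
#'
#' @param h ac field amplitude (Oe), > 0.
#' @param f ac frequency (Hz), > 0.
#' @param T absolute temperature (K), > 0.
#' @param H_grid ordered dc-field values (Oe), strictly increasing.
#' @return An object of class `drive_conditions` (a named list).
#' @examples
#' drv <- drive_conditions()
#' drv$h
#' @export
drive_conditions <- function(h = 13.8, f = 15.7e6, T = 300,
                             H_grid = seq(-300, 300, length.out = 301)) {
  stopifnot(is.numeric(h), length(h) == 1, is.finite(h),
            is.numeric(f), length(f) == 1, is.finite(f),
            is.numeric(T), length(T) == 1, is.finite(T))
  if (h <= 0) abort("`h` must be positive.")
  if (f <= 0) abort("`f` must be positive.")
  if (T <= 0) abort("`T` must be positive.")
  H_grid <- as.numeric(H_grid)
  if (length(H_grid) < 1 || anyNA(H_grid)) abort("`H_grid` must be numeric and non-missing.")
  if (length(H_grid) > 1 && any(diff(H_grid) <= 0))
    abort("`H_grid` must be strictly increasing.")
  structure(list(h = h, f = f, T = T, H_grid = H_grid),
            class = "drive_conditions")
}

#' @export
print.drive_conditions <- function(x, ...) {
  cat(sprintf(
    "<drive_conditions> h = %g Oe, f = %g Hz, T = %g K, H in [%g, %g] Oe (%d pts)\n",
    x$h, x$f, x$T, min(x$H_grid), max(x$H_grid), length(x$H_grid)))
  invisible(x)
}

same_drive <- function(a, b, tol = 1e-9) {
  isTRUE(all.equal(a$h, b$h, tolerance = tol)) &&
    isTRUE(all.equal(a$f, b$f, tolerance = tol)) &&
    isTRUE(all.equal(a$T, b$T, tolerance = tol))
}
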