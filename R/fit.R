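# Inversion of a preprocessed M2 curve into ensemble parameters by joint
# nonlinear least squares on the real and imaginary parts.

default_fit_bounds <- function() {
  # envelopes around the parameter ranges observed for these ensembles; the
  # anisotropy ceiling covers every reported value plus its uncertainty
  # (largest: 0 +/- 29 K)
  list(M_C = c(1e3, 1e6), sigma = c(0, 2), alpha = c(0.01, 5),
       E_A = c(0, 30))
}

#' Initial parameter guess from a curve
#'
#' The mean moment is estimated from the field of the |Re M2| extremum: in
#' the quasi-static limit the extremum sits at the reduced field where the
#' second derivative of the Langevin function peaks
#' (xi = m*mu_B*H/(k_B*T) = 1.3723, computed numerically). The saturation
#' magnetization guess scales a unit-amplitude model curve to the observed
#' peak; the shape and dynamics parameters start from mid-range defaults
#' (sigma = 0.5, alpha = 0.2, E_A = 10 K).
#'
#' @param curve an `m2_curve` (from [preprocess_sweeps()] or
#'   [antisymmetrize()]).
#' @param drive a [drive_conditions()] object.
#' @return An [ensemble_params()] initial guess.
#' @export
initialize_params <- function(curve, drive) {
  cst <- m2_constants()
  i <- which.max(abs(curve$re))
  if (length(i) != 1 || abs(curve$re[i]) <= 0)
    abort("Curve has no resolvable extremum in Re M2 (flat signal).")
  if (i == nrow(curve))
    abort(paste("Re M2 is monotone over the measured field range;",
                "widen the range so the extremum is resolved."))
  H_star <- curve$H[i]
  # the extremum field tracks the typical responding moment; under a
  # lognormal with width sigma the response-weighted moment exceeds the mean
  # by ~exp(sigma^2), corrected here at the default sigma = 0.5
  M_C0 <- .xi_peak * cst$k_B * drive$T / (cst$mu_B * H_star) / exp(0.5^2)
  guess <- ensemble_params(M_tilde = 1, M_C = M_C0, sigma = 0.5,
                           alpha = 0.2, E_A = 10, T = drive$T)
  coarse <- drive
  coarse$H_grid <- seq(0, max(curve$H), length.out = 25)
  unit <- ensemble_m2(guess, coarse, tol = 1e-3)
  scale <- abs(curve$re[i]) / max(abs(unit$re))
  ensemble_params(M_tilde = scale, M_C = M_C0, sigma = 0.5, alpha = 0.2,
                  E_A = 10, T = drive$T)
}

# pack/unpack between the optimizer space (logs for the positive scale
# parameters) and natural parameters
pack_theta <- function(p, free_tau = FALSE) {
  th <- c(lMt = log10(p$M_tilde), lMc = log10(p$M_C), sigma = p$sigma,
          lal = log10(p$alpha), E_A = p$E_A)
  if (free_tau) th <- c(th, ltau = log10(p$tau_N))
  th
}

unpack_theta <- function(th, T = 300, free_tau = FALSE) {
  alpha <- 10^th[["lal"]]
  M_C <- 10^th[["lMc"]]
  tau_N <- if (free_tau) 10^th[["ltau"]] else neel_time(M_C, alpha, T)
  ensemble_params(M_tilde = 10^th[["lMt"]], M_C = M_C,
                  sigma = th[["sigma"]], alpha = alpha, E_A = th[["E_A"]],
                  tau_N = tau_N, T = T)
}

# model curve on the data grid; evaluated on a coarse grid and interpolated
# by cubic spline when the data grid is dense (the curve is smooth; this
# keeps fits fast without touching the physics)
model_on_grid <- function(params, drive, H_data, n_interp = 33, tol = 3e-4) {
  dv <- drive
  if (length(H_data) <= n_interp) {
    dv$H_grid <- H_data
    m <- ensemble_m2(params, dv, tol = tol)
    return(m)
  }
  dv$H_grid <- seq(min(H_data), max(H_data), length.out = n_interp)
  m <- ensemble_m2(params, dv, tol = tol)
  tibble(H = H_data,
         re = stats::spline(dv$H_grid, m$re, xout = H_data)$y,
         im = stats::spline(dv$H_grid, m$im, xout = H_data)$y)
}

#' Fit ensemble parameters to a preprocessed curve
#'
#' Minimizes the joint sum of squared residuals over the concatenated real
#' and imaginary samples of an antisymmetrized curve, with free parameters
#' (M_tilde, M_C, sigma, alpha, E_A); tau_N is derived from (M_C, alpha)
#' through [neel_time()] (set `free_tau = TRUE` to fit it independently).
#' Levenberg-Marquardt with box bounds is run from `multistart` perturbed
#' versions of the initial guess (deterministic given `seed`), each screened
#' with the weakly identifiable anisotropy energy frozen, and the best start
#' is polished with all parameters free. 1-sigma uncertainties come from the
#' Jacobian-based covariance at the optimum, floored by the parameter
#' displacement along the E_A likelihood valley (profiled at the ends of the
#' E_A envelope) so that intervals remain honest when the optimum sits on an
#' E_A bound.
#'
#' @param curve an `m2_curve`; its `applicability` attribute, if present,
#'   must not be FAIL (see `force`).
#' @param drive a [drive_conditions()] object.
#' @param init optional [ensemble_params()] initial guess; default
#'   [initialize_params()].
#' @param bounds named list of `c(lower, upper)` bounds for `M_C`, `sigma`,
#'   `alpha`, `E_A` (see `default_fit_bounds()`).
#' @param multistart number of perturbed starts (default 5).
#' @param seed seed for the start perturbations.
#' @param weighting `"equal"` (default) or `"amplitude"` (residuals scaled
#'   by the local signal modulus).
#' @param free_tau fit tau_N as an independent parameter instead of
#'   deriving it from (M_C, alpha).
#' @param force fit even when the applicability screen returned FAIL.
#' @param control list of optimizer settings: `maxiter_screen`,
#'   `maxiter`, `n_interp`, `tol`.
#' @return An object of class `m2_fit`.
#' @export
fit_m2 <- function(curve, drive, init = NULL, bounds = default_fit_bounds(),
                   multistart = 5, seed = 1L, weighting = c("equal", "amplitude"),
                   free_tau = FALSE, force = FALSE, control = list()) {
  weighting <- match.arg(weighting)
  ctl <- modifyList(list(maxiter_screen = 8, maxiter = 100, n_interp = 33,
                         tol = 3e-4, profile_EA = TRUE, maxiter_profile = 40,
                         n_polish = 2), control)
  app <- attr(curve, "applicability")
  app_flag <- if (is.null(app)) "PASS" else app$flag
  if (app_flag == "FAIL" && !force)
    abort(paste("Applicability screen returned FAIL: scan-rate independent",
                "field hysteresis indicates a multi-domain fraction -- the",
                "superparamagnetic formalism is inapplicable.",
                "Use force = TRUE to fit anyway."))
  if (is.null(init)) init <- initialize_params(curve, drive)

  obs <- c(curve$re, curve$im)
  wts <- if (weighting == "equal") rep(1, length(obs)) else {
    a <- Mod(complex(real = curve$re, imaginary = curve$im))
    rep(a / max(a) + 0.05, 2)
  }
  n_eval <- 0L
  resid_fn <- function(th) {
    n_eval <<- n_eval + 1L
    p <- unpack_theta(th, T = drive$T, free_tau = free_tau)
    m <- tryCatch(
      model_on_grid(p, drive, curve$H, n_interp = ctl$n_interp, tol = ctl$tol),
      error = function(e) NULL)
    if (is.null(m)) return(rep(1e6, length(obs)))
    wts * (c(m$re, m$im) - obs)
  }

  b <- modifyList(default_fit_bounds(), bounds)
  lower <- c(lMt = log10(init$M_tilde) - 6, lMc = log10(b$M_C[1]),
             sigma = b$sigma[1], lal = log10(b$alpha[1]), E_A = b$E_A[1])
  upper <- c(lMt = log10(init$M_tilde) + 6, lMc = log10(b$M_C[2]),
             sigma = b$sigma[2], lal = log10(b$alpha[2]), E_A = b$E_A[2])
  if (free_tau) {
    lower <- c(lower, ltau = log10(1e-3)); upper <- c(upper, ltau = log10(1e3))
  }
  th0 <- pmin(pmax(pack_theta(init, free_tau), lower), upper)

  # perturbed starts (first = the plain init), deterministic given seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  starts <- list(th0)
  if (multistart > 1) {
    for (k in seq_len(multistart - 1)) {
      pert <- th0 + c(rnorm(1, 0, 0.15), rnorm(1, 0, 0.12),
                      rnorm(1, 0, 0.2), rnorm(1, 0, 0.3),
                      runif(1, -8, 8), if (free_tau) rnorm(1, 0, 0.3))
      starts[[k + 1]] <- pmin(pmax(pert, lower), upper)
    }
  }

  run_lm <- function(th, maxiter, lo = lower, up = upper) {
    minpack.lm::nls.lm(par = th, lower = lo, upper = up,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = 1e-10, ptol = 1e-8))
  }
  # Stage 1: screen the starts with the anisotropy energy frozen -- E_A is
  # weakly identifiable (a long, curved likelihood valley trades E_A against
  # M_C and sigma) and freezing it keeps the screening well conditioned.
  freeze <- function(v, at) { v["E_A"] <- at; v }
  screened <- lapply(starts, function(th)
    run_lm(th, ctl$maxiter_screen,
           lo = freeze(lower, th[["E_A"]]), up = freeze(upper, th[["E_A"]])))
  ord <- order(vapply(screened, function(f) f$deviance, numeric(1)))
  # Stage 2: release all parameters from the best screened starts (the top
  # two basins are polished; screening deviances can misrank close basins)
  polish <- lapply(ord[seq_len(min(ctl$n_polish, length(ord)))],
                   function(i) run_lm(screened[[i]]$par, maxiter = ctl$maxiter))
  fit <- polish[[which.min(vapply(polish, function(f) f$deviance, numeric(1)))]]
  converged <- fit$info %in% c(1, 2, 3, 4)

  th_hat <- fit$par
  p_hat <- unpack_theta(th_hat, T = drive$T, free_tau = free_tau)
  n_obs <- length(obs)
  n_par <- length(th_hat)
  sigma2 <- fit$deviance / max(1, n_obs - n_par)
  # eigen pseudo-inverse of J'J: directions with negligible curvature (the
  # flat E_A valley) are dropped here and accounted for by the profile floor
  # below, instead of exploding the covariance
  ev <- eigen(fit$hessian, symmetric = TRUE)
  keep <- ev$values > 1e-6 * max(ev$values)
  cov_th <- sigma2 * ev$vectors[, keep, drop = FALSE] %*%
    diag(1 / ev$values[keep], sum(keep)) %*%
    t(ev$vectors[, keep, drop = FALSE])
  dimnames(cov_th) <- list(names(th_hat), names(th_hat))
  unc <- fit_uncertainties(th_hat, cov_th, drive$T, free_tau)

  # Valley-aware floor on the uncertainties: the anisotropy energy is weakly
  # identifiable (the likelihood is nearly flat along a curved valley
  # trading E_A against M_C and sigma), and the Jacobian covariance at a
  # solution sitting on an E_A bound does not see the displacement of the
  # other parameters along that valley. Profile the valley by refitting with
  # E_A frozen at both ends of its envelope (warm-started from the optimum)
  # and floor each parameter's uncertainty by its distance to the farthest
  # valley end -- at an interior optimum this reduces to the valley
  # half-width already captured by the covariance.
  if (!free_tau && isTRUE(ctl$profile_EA)) {
    ends <- lapply(c(lower[["E_A"]], upper[["E_A"]]), function(ea) {
      f <- run_lm(freeze(th_hat, ea), ctl$maxiter_profile,
                  lo = freeze(lower, ea), up = freeze(upper, ea))
      unpack_theta(f$par, T = drive$T, free_tau = FALSE)
    })
    ridge <- vapply(c("M_tilde", "M_C", "sigma", "alpha", "tau_N"),
                    function(nm) max(abs(ends[[1]][[nm]] - p_hat[[nm]]),
                                     abs(ends[[2]][[nm]] - p_hat[[nm]])),
                    numeric(1))
    # valley spread and conditional width add linearly: along a curved
    # valley the marginal spread of a parameter is not Gaussian and the
    # quadrature sum was found to undercover
    unc[names(ridge)] <- unc[names(ridge)] + ridge
    # E_A itself is envelope-constrained, not resolved: report its distance
    # to the farther envelope end as the uncertainty floor
    unc[["E_A"]] <- max(unc[["E_A"]],
                        p_hat$E_A - lower[["E_A"]],
                        upper[["E_A"]] - p_hat$E_A)
  }

  m_hat <- model_on_grid(p_hat, drive, curve$H, n_interp = ctl$n_interp,
                         tol = ctl$tol)
  rrms <- sqrt(fit$deviance / n_obs)

  structure(list(
    params = p_hat, uncertainties = unc,
    residual_rms = rrms, n_points = nrow(curve),
    converged = converged, applicability = app_flag,
    data = curve, fitted = m_hat, deviance = fit$deviance,
    cov = cov_th, n_eval = n_eval, info = fit$info,
    message = fit$message, free_tau = free_tau, drive = drive),
    class = "m2_fit")
}

# delta-method 1-sigma uncertainties on the natural scale, including the
# derived relaxation time
fit_uncertainties <- function(th, cov_th, T, free_tau) {
  ln10 <- log(10)
  M_t <- 10^th[["lMt"]]; M_C <- 10^th[["lMc"]]; alpha <- 10^th[["lal"]]
  se <- sqrt(pmax(diag(cov_th), 0))
  out <- c(M_tilde = M_t * ln10 * se[["lMt"]],
           M_C = M_C * ln10 * se[["lMc"]],
           sigma = se[["sigma"]],
           alpha = alpha * ln10 * se[["lal"]],
           E_A = se[["E_A"]])
  if (free_tau) {
    out <- c(out, tau_N = 10^th[["ltau"]] * ln10 * se[["ltau"]])
  } else {
    # tau ~ M_C (1+alpha^2)/alpha: gradient in (lMc, lal) space
    tau <- neel_time(M_C, alpha, T)
    g <- c(tau * ln10,                                   # d tau / d lMc
           tau * ln10 * alpha * (2 * alpha / (1 + alpha^2) - 1 / alpha))
    V <- cov_th[c("lMc", "lal"), c("lMc", "lal")]
    out <- c(out, tau_N = sqrt(max(0, drop(t(g) %*% V %*% g))))
  }
  out
}

#' @export
print.m2_fit <- function(x, ...) {
  cat("<m2_fit>", if (x$converged) "converged" else "NOT CONVERGED",
      sprintf("(applicability %s, %d points, residual rms %.3g emu/g)\n",
              x$applicability, x$n_points, x$residual_rms))
  print(tidy.m2_fit(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy method for M2 fits
#'
#' @param x an `m2_fit`.
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.m2_fit <- function(x, ...) {
  p <- x$params
  est <- c(M_tilde = p$M_tilde, M_C = p$M_C, sigma = p$sigma,
           alpha = p$alpha, tau_N = p$tau_N, E_A = p$E_A)
  tibble(term = names(est), estimate = unname(est),
         std.error = unname(x$uncertainties[names(est)]))
}

#' Glance method for M2 fits
#'
#' @param x an `m2_fit`.
#' @param ... unused.
#' @return A one-row tibble of fit-level summaries.
#' @export
glance.m2_fit <- function(x, ...) {
  tibble(residual_rms = x$residual_rms, deviance = x$deviance,
         n_points = x$n_points, converged = x$converged,
         applicability = x$applicability, n_eval = x$n_eval)
}

#' Plot an M2 fit
#'
#' Data points and fitted model curves for the real and imaginary
#' second-harmonic components.
#'
#' @param object an `m2_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.m2_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$data[, c("H", "re", "im")],
                           c("re", "im"), names_to = "part")
  f <- tidyr::pivot_longer(object$fitted[, c("H", "re", "im")],
                           c("re", "im"), names_to = "part")
  ggplot2::ggplot(d, ggplot2::aes(.data$H, .data$value)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = f, color = "firebrick") +
    ggplot2::facet_wrap(~part, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(re = "Re M2", im = "Im M2"))) +
    ggplot2::labs(x = "H (Oe)", y = "M2 (emu/g)") +
    ggplot2::theme_minimal()
}

#' Plot a preprocessed curve
#'
#' @param object an `m2_curve`.
#' @param ... unused.
#' @return A ggplot of the real and imaginary components versus field.
#' @export
autoplot.m2_curve <- function(object, ...) {
  d <- tidyr::pivot_longer(object[, c("H", "re", "im")],
                           c("re", "im"), names_to = "part")
  ggplot2::ggplot(d, ggplot2::aes(.data$H, .data$value, color = .data$part)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "H (Oe)", y = "M2 (emu/g)", color = NULL) +
    ggplot2::theme_minimal()
}
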