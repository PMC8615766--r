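# Sweep preprocessing: branch averaging, antisymmetrization, and the
# field-hysteresis applicability screen.

interp_branch <- function(b, H_out) {
  o <- order(b$H)
  list(re = approx(b$H[o], b$re[o], xout = H_out)$y,
       im = approx(b$H[o], b$im[o], xout = H_out)$y)
}

#' Average direct and reverse field-sweep branches
#'
#' Interpolates both branches linearly onto a common grid (the union of
#' their sample points clipped to the overlapping field range) and returns
#' the pointwise complex mean as a new branch. Raw sweeps are averaged this
#' way before antisymmetrization so that a weak branch hysteresis cancels to
#' first order.
#'
#' @param direct,reverse [field_sweep_branch()] objects with matching drive
#'   conditions and scan frequency.
#' @return A `sweep_branch` with direction `"averaged"`.
#' @export
average_branches <- function(direct, reverse) {
  md <- branch_meta(direct); mr <- branch_meta(reverse)
  if (!same_drive(md$drive, mr$drive))
    abort("Branches were acquired under different drive conditions.")
  if (!isTRUE(all.equal(md$F_sc, mr$F_sc)))
    abort("Branches have different scan frequencies F_sc.")
  lo <- max(min(direct$H), min(reverse$H))
  hi <- min(max(direct$H), max(reverse$H))
  span <- function(b) diff(range(b$H))
  if (hi <= lo || (hi - lo) < 0.5 * max(span(direct), span(reverse)))
    abort("Branches overlap over less than 50% of the field range.")
  H <- sort(unique(c(direct$H, reverse$H)))
  H <- H[H >= lo & H <= hi]
  d <- interp_branch(direct, H)
  r <- interp_branch(reverse, H)
  field_sweep_branch(H, (d$re + r$re) / 2, (d$im + r$im) / 2,
                     direction = "averaged", F_sc = md$F_sc,
                     drive = md$drive, label = md$label,
                     specimen_mass = md$specimen_mass)
}

#' Antisymmetrize a sweep about H = 0
#'
#' Extracts the odd part (s(H) - s(-H)) / 2 of a branch on the nonnegative
#' field grid, interpolating the mirrored field values as needed. The model
#' response of a superparamagnetic ensemble is odd in H, so the even part of
#' a recorded sweep is instrumental offset and is discarded. The returned
#' curve passes through zero at H = 0 exactly.
#'
#' @param branch a [field_sweep_branch()], typically the output of
#'   [average_branches()]; its field range must cover both signs.
#' @return An `m2_curve`: a tibble with columns `H >= 0`, `re`, `im`, and
#'   provenance attributes.
#' @export
antisymmetrize <- function(branch) {
  m <- branch_meta(branch)
  if (min(branch$H) >= 0 || max(branch$H) <= 0)
    abort("Field range must cover both signs of H to antisymmetrize.")
  hi <- min(max(branch$H), -min(branch$H))   # need -H within range
  H_pos <- sort(unique(branch$H[branch$H >= 0 & branch$H <= hi]))
  H_out <- unique(c(0, H_pos))
  p <- interp_branch(branch, H_out)
  n <- interp_branch(branch, -H_out)
  re <- (p$re - n$re) / 2
  im <- (p$im - n$im) / 2
  re[H_out == 0] <- 0
  im[H_out == 0] <- 0
  out <- tibble(H = H_out, re = re, im = im)
  class(out) <- c("m2_curve", class(out))
  attr(out, "label") <- m$label
  attr(out, "F_sc") <- m$F_sc
  attr(out, "drive") <- m$drive
  attr(out, "provenance") <- sprintf("%s (%s branch, F_sc = %g Hz)",
                                     m$label, m$direction, m$F_sc)
  out
}

#' @export
print.m2_curve <- function(x, ...) {
  cat(sprintf("<m2_curve> %s, %d pts, H in [0, %g] Oe\n",
              attr(x, "label") %||% "?", nrow(x), max(x$H)))
  if (!is.null(attr(x, "hysteresis_index")))
    cat(sprintf("  hysteresis index: %.4g\n", attr(x, "hysteresis_index")))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Field-hysteresis index of a branch pair
#'
#' Dimensionless measure of the separation between direct and reverse
#' scans: the mean modulus of the complex branch difference divided by the
#' peak-to-peak amplitude of the branch mean (the diameter of the mean curve
#' in the complex plane, which for a purely real signal reduces to
#' max - min). Zero for identical branches; invariant under a global
#' rescaling of both branches.
#'
#' @inheritParams average_branches
#' @return A single nonnegative number.
#' @export
hysteresis_index <- function(direct, reverse) {
  avg <- average_branches(direct, reverse)   # validates and builds the grid
  H <- avg$H
  d <- interp_branch(direct, H)
  r <- interp_branch(reverse, H)
  diff_mean <- mean(Mod(complex(real = d$re - r$re, imaginary = d$im - r$im)))
  z <- complex(real = avg$re, imaginary = avg$im)
  ptp <- complex_diameter(z)
  if (ptp <= .Machine$double.eps * max(1, diff_mean))
    abort("Hysteresis index undefined: the mean signal is flat (zero amplitude).")
  diff_mean / ptp
}

# diameter of a set of points in the complex plane (max pairwise distance)
complex_diameter <- function(z) {
  if (length(z) < 2) return(0)
  max(stats::dist(cbind(Re(z), Im(z))))
}

#' Superparamagnetic applicability screen
#'
#' The quantification formalism assumes a superparamagnetic (single-domain,
#' thermally relaxing) particle ensemble, diagnosed by the absence of field
#' hysteresis or by hysteresis that shrinks as the dc scan slows. The screen
#' compares the hysteresis index of the fast (8 Hz) and slow (0.25 Hz) scan
#' pairs:
#' \itemize{
#'   \item PASS when the fast-scan index is below `threshold`, or when the
#'     index decreases by at least `decrease_frac` from fast to slow scan
#'     and the slow-scan index is below `threshold`;
#'   \item FAIL when both indices are above `threshold` and within 10% of
#'     each other (scan-rate independent hysteresis: a multi-domain or
#'     ferromagnetic fraction is suspected and the formalism is
#'     inapplicable);
#'   \item WARN otherwise.
#' }
#'
#' @param sweeps_fast,sweeps_slow lists with elements `direct` and `reverse`
#'   ([field_sweep_branch()]s) for the fast (8 Hz) and slow (0.25 Hz) scan.
#' @param threshold hysteresis-index threshold for "small" (default 0.05).
#' @param decrease_frac required fractional decrease of the index from fast
#'   to slow scan (default 0.3).
#' @param same_frac fractional closeness of the two indices that counts as
#'   "the same hysteresis at both scan frequencies" (default 0.1).
#' @return A list of class `sp_check`: `flag` ("PASS"/"WARN"/"FAIL"),
#'   `index_fast`, `index_slow`, `notes`.
#' @export
superparamagnetic_check <- function(sweeps_fast, sweeps_slow,
                                    threshold = 0.05, decrease_frac = 0.3,
                                    same_frac = 0.1) {
  i_fast <- hysteresis_index(sweeps_fast$direct, sweeps_fast$reverse)
  i_slow <- hysteresis_index(sweeps_slow$direct, sweeps_slow$reverse)
  notes <- character()
  both_above <- i_fast >= threshold && i_slow >= threshold
  same <- abs(i_fast - i_slow) <= same_frac * max(i_fast, i_slow)
  decreasing <- i_slow <= (1 - decrease_frac) * i_fast
  if (both_above && same) {
    flag <- "FAIL"
    notes <- c(notes, paste("practically the same hysteresis at both scan",
                            "frequencies: multi-domain / ferromagnetic",
                            "fraction suspected"))
  } else if (i_fast < threshold) {
    flag <- "PASS"
    if (i_fast > 0 && decreasing)
      notes <- c(notes, "hysteresis decreases with scan frequency")
  } else if (decreasing && i_slow < threshold) {
    flag <- "PASS"
    notes <- c(notes, "hysteresis decreases with scan frequency")
  } else {
    flag <- "WARN"
    notes <- c(notes, "hysteresis above threshold; inspect branches")
  }
  structure(list(flag = flag, index_fast = i_fast, index_slow = i_slow,
                 threshold = threshold, notes = notes),
            class = "sp_check")
}

#' @export
print.sp_check <- function(x, ...) {
  cat(sprintf("<sp_check> %s  (index 8 Hz: %.4g, 0.25 Hz: %.4g, threshold %g)\n",
              x$flag, x$index_fast, x$index_slow, x$threshold))
  for (n in x$notes) cat("  -", n, "\n")
  invisible(x)
}

#' Preprocess a set of raw sweeps into a fit-ready curve
#'
#' Runs the full preprocessing chain: applicability screen on the fast/slow
#' branch pairs, branch averaging within each pair, combination of the two
#' scan frequencies (they record the same response, so their branch-averaged
#' curves are averaged again to halve the noise), and antisymmetrization.
#' The resulting curve carries the applicability flag and hysteresis index
#' as attributes and is the expected input of [fit_m2()].
#'
#' @inheritParams superparamagnetic_check
#' @return An `m2_curve` with attributes `applicability` (an `sp_check`) and
#'   `hysteresis_index` (slow-scan index).
#' @export
preprocess_sweeps <- function(sweeps_fast, sweeps_slow, threshold = 0.05,
                              decrease_frac = 0.3, same_frac = 0.1) {
  chk <- superparamagnetic_check(sweeps_fast, sweeps_slow,
                                 threshold = threshold,
                                 decrease_frac = decrease_frac,
                                 same_frac = same_frac)
  avg_fast <- average_branches(sweeps_fast$direct, sweeps_fast$reverse)
  avg_slow <- average_branches(sweeps_slow$direct, sweeps_slow$reverse)
  # branch averaging cancels an antisymmetric branch offset, so both scan
  # frequencies estimate the same underlying curve; combine them
  f <- interp_branch(avg_fast, avg_slow$H)
  ok <- is.finite(f$re) & is.finite(f$im)
  comb <- avg_slow
  comb$re[ok] <- (avg_slow$re[ok] + f$re[ok]) / 2
  comb$im[ok] <- (avg_slow$im[ok] + f$im[ok]) / 2
  curve <- antisymmetrize(comb)
  attr(curve, "applicability") <- chk
  attr(curve, "hysteresis_index") <- chk$index_slow
  curve
}
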