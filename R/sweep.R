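# Field-sweep branch container: one directional dc-field scan of the
# second-harmonic response, stored as a tibble (H, re, im) with acquisition
# metadata in attributes.

#' Construct a field-sweep branch
#'
#' One raw directional scan of the complex second-harmonic response versus
#' dc field, with acquisition metadata. The underlying data structure is a
#' tibble with columns `H` (Oe), `re`, `im` (emu/g).
#'
#' @param H dc-field samples (Oe), ordered (increasing for a direct scan,
#'   decreasing for a reverse scan).
#' @param re,im real and imaginary second-harmonic components (emu/g).
#' @param direction `"direct"` or `"reverse"` (or `"averaged"` for derived
#'   branches).
#' @param F_sc field scan frequency (Hz).
#' @param drive a [drive_conditions()] object.
#' @param label specimen identifier.
#' @param specimen_mass specimen mass (g), optional.
#' @return A tibble of class `sweep_branch`.
#' @export
field_sweep_branch <- function(H, re, im, direction, F_sc, drive,
                               label = "specimen", specimen_mass = NA_real_) {
  direction <- match.arg(direction, c("direct", "reverse", "averaged"))
  H <- as.numeric(H); re <- as.numeric(re); im <- as.numeric(im)
  if (length(H) != length(re) || length(H) != length(im))
    abort("`H`, `re` and `im` must have equal length.")
  if (anyNA(H) || !all(is.finite(re)) || !all(is.finite(im)))
    abort("Sweep values must be finite.")
  stopifnot(inherits(drive, "drive_conditions"))
  out <- tibble(H = H, re = re, im = im)
  class(out) <- c("sweep_branch", class(out))
  attr(out, "direction") <- direction
  attr(out, "F_sc") <- as.numeric(F_sc)
  attr(out, "drive") <- drive
  attr(out, "label") <- label
  attr(out, "specimen_mass") <- specimen_mass
  out
}

branch_meta <- function(b) {
  list(direction = attr(b, "direction"), F_sc = attr(b, "F_sc"),
       drive = attr(b, "drive"), label = attr(b, "label"),
       specimen_mass = attr(b, "specimen_mass"))
}

#' @export
print.sweep_branch <- function(x, ...) {
  cat(sprintf("<sweep_branch> %s (%s, F_sc = %g Hz, %d pts, H in [%g, %g] Oe)\n",
              attr(x, "label"), attr(x, "direction"), attr(x, "F_sc"),
              nrow(x), min(x$H), max(x$H)))
  NextMethod()
}
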