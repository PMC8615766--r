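# Plain-text sweep file format and run configuration.
#
# Sweep files are tab-delimited with '#'-prefixed key=value header lines:
#   # label=rat1_liver
#   # h_Oe=13.8
#   # f_Hz=15700000
#   # Fsc_Hz=8
#   # T_K=300
#   H_Oe  ReM2_emu_per_g  ImM2_emu_per_g  branch
# Units are fixed in the column names to prevent silent unit mixing.

sweep_required_keys <- c("label", "h_Oe", "f_Hz", "Fsc_Hz", "T_K")

#' Write field-sweep branches to a text file
#'
#' @param branches a single [field_sweep_branch()] or a list of branches
#'   sharing drive conditions, scan frequency and label.
#' @param path output file path.
#' @param organ,subject optional metadata recorded in the header.
#' @param seed optional generator seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(branches, path, organ = NULL, subject = NULL,
                        seed = NULL) {
  if (inherits(branches, "sweep_branch")) branches <- list(branches)
  m <- branch_meta(branches[[1]])
  hdr <- c(label = m$label, organ = organ, subject = subject,
           h_Oe = fmt9(m$drive$h), f_Hz = fmt9(m$drive$f),
           Fsc_Hz = fmt9(m$F_sc), T_K = fmt9(m$drive$T))
  if (!is.na(m$specimen_mass)) hdr <- c(hdr, mass_g = fmt9(m$specimen_mass))
  if (!is.null(seed)) hdr <- c(hdr, seed = as.character(seed))
  lines <- c(paste0("# ", names(hdr), "=", unname(hdr)),
             paste("H_Oe", "ReM2_emu_per_g", "ImM2_emu_per_g", "branch",
                   sep = "\t"))
  body <- unlist(lapply(branches, function(b) {
    paste(fmt9(b$H), fmt9(b$re), fmt9(b$im), attr(b, "direction"), sep = "\t")
  }))
  writeLines(c(lines, body), path)
  invisible(path)
}

fmt9 <- function(x) sprintf("%.9g", x)

#' Read field-sweep branches from a text file
#'
#' Strict parser for the sweep format written by [write_sweep()]: malformed
#' header lines, missing required metadata keys, or non-numeric body rows
#' raise errors naming the offending line.
#'
#' @param path file path.
#' @return A named list of [field_sweep_branch()]s keyed by branch
#'   direction, with an attribute `meta` holding the header fields.
#' @export
read_sweep <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such sweep file: '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  is_hdr <- grepl("^#", lines)
  hdr_lines <- lines[is_hdr]
  kv <- regmatches(hdr_lines, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)\\s*$", hdr_lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad))
    abort(sprintf("Malformed header at line %d of '%s'.",
                  which(is_hdr)[bad[1]], path))
  meta <- setNames(vapply(kv, `[`, character(1), 3),
                   vapply(kv, `[`, character(1), 2))
  missing_keys <- setdiff(sweep_required_keys, names(meta))
  if (length(missing_keys))
    abort(sprintf("Sweep file '%s' is missing required metadata key(s): %s.",
                  path, paste(missing_keys, collapse = ", ")))

  body_idx <- which(!is_hdr)
  header_row <- body_idx[1]
  cols <- strsplit(lines[header_row], "\t")[[1]]
  need_cols <- c("H_Oe", "ReM2_emu_per_g", "ImM2_emu_per_g", "branch")
  if (!identical(cols, need_cols))
    abort(sprintf("Unexpected column header at line %d of '%s' (need: %s).",
                  header_row, path, paste(need_cols, collapse = ", ")))
  rows <- lines[body_idx[-1]]
  rows <- rows[nzchar(rows)]
  parts <- strsplit(rows, "\t")
  nf <- which(lengths(parts) != 4)
  if (length(nf))
    abort(sprintf("Malformed data row at line %d of '%s'.",
                  body_idx[1] + nf[1], path))
  H <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1)))
  re <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
  im <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3)))
  br <- vapply(parts, `[`, character(1), 4)
  badnum <- which(is.na(H) | is.na(re) | is.na(im))
  if (length(badnum))
    abort(sprintf("Non-numeric value at line %d of '%s'.",
                  body_idx[1] + badnum[1], path))
  badbr <- which(!br %in% c("direct", "reverse", "averaged"))
  if (length(badbr))
    abort(sprintf("Unknown branch label '%s' at line %d of '%s'.",
                  br[badbr[1]], body_idx[1] + badbr[1], path))

  drv <- drive_conditions(h = as.numeric(meta[["h_Oe"]]),
                          f = as.numeric(meta[["f_Hz"]]),
                          T = as.numeric(meta[["T_K"]]),
                          H_grid = sort(unique(H)))
  mass <- if ("mass_g" %in% names(meta)) as.numeric(meta[["mass_g"]]) else NA_real_
  out <- lapply(split(seq_along(H), br), function(idx) {
    dH <- diff(H[idx])
    if (length(dH) && !(all(dH > 0) || all(dH < 0)))
      abort(sprintf(
        "Duplicate '%s' branch in '%s': field values are not monotone.",
        br[idx[1]], path))
    field_sweep_branch(H[idx], re[idx], im[idx],
                       direction = br[idx[1]],
                       F_sc = as.numeric(meta[["Fsc_Hz"]]),
                       drive = drv, label = meta[["label"]],
                       specimen_mass = mass)
  })
  attr(out, "meta") <- as.list(meta)
  out
}

#' Run configuration
#'
#' Schema-validated settings controlling thresholds, fit options and
#' constants overrides. Unknown keys are rejected.
#'
#' @param path optional YAML file; values there override the defaults.
#' @param ... named overrides applied on top.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    hysteresis_threshold = 0.05,
    hysteresis_decrease_frac = 0.3,
    hysteresis_same_frac = 0.1,
    fit_multistart = 5,
    fit_seed = 1,
    fit_weighting = "equal",
    fit_free_tau = FALSE,
    fit_maxiter = 100,
    fit_profile = TRUE,
    quad_nodes = 21,
    solver_tol = 3e-4,
    sign_flip = FALSE,
    aggregates_per_cell = 8.27e4)
  user <- list(...)
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    user <- modifyList(if (is.null(y)) list() else y, user)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  structure(modifyList(defaults, user), class = "run_config")
}
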