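# End-to-end pipeline over a study directory: preprocess -> fit -> counts.
# These functions back the command-line interface (inst/cli/nlrm2.R) and are
# equally usable interactively.

# discover sweep files and group them by specimen and scan frequency
collect_sweeps <- function(in_dir) {
  files <- list.files(in_dir, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(files)) abort(sprintf("No sweep files (*.tsv) in '%s'.", in_dir))
  entries <- lapply(files, function(f) {
    brs <- read_sweep(f)
    meta <- attr(brs, "meta")
    lapply(brs, function(b) list(branch = b, meta = meta, file = f))
  })
  entries <- unlist(entries, recursive = FALSE)
  labels <- vapply(entries, function(e) e$meta$label, character(1))
  split(entries, labels)
}

pair_for_fsc <- function(specimen, fsc, tol = 1e-6) {
  hit <- Filter(function(e) abs(attr(e$branch, "F_sc") - fsc) < tol, specimen)
  dirs <- vapply(hit, function(e) attr(e$branch, "direction"), character(1))
  if (!all(c("direct", "reverse") %in% dirs)) return(NULL)
  list(direct = hit[[match("direct", dirs)]]$branch,
       reverse = hit[[match("reverse", dirs)]]$branch)
}

#' Preprocess every specimen in a study directory
#'
#' Reads all sweep files, pairs direct/reverse branches at the fast (8 Hz)
#' and slow (0.25 Hz) scan frequencies, runs the applicability screen, and
#' builds antisymmetrized curves.
#'
#' @param in_dir directory of sweep files (as written by
#'   [make_phantom_study()] or [write_sweep()]).
#' @param config a [run_config()].
#' @return A list with `curves` (named list of `m2_curve`s) and `report`
#'   (tibble: label, flag, hysteresis indices, file provenance).
#' @export
pipeline_preprocess <- function(in_dir, config = run_config()) {
  specimens <- collect_sweeps(in_dir)
  curves <- list()
  rows <- list()
  for (label in names(specimens)) {
    sp <- specimens[[label]]
    fast <- pair_for_fsc(sp, 8)
    slow <- pair_for_fsc(sp, 0.25)
    if (is.null(fast) || is.null(slow)) {
      warn(sprintf("Specimen '%s': missing a complete 8 Hz / 0.25 Hz branch pair; skipped.", label))
      next
    }
    curve <- preprocess_sweeps(fast, slow,
                               threshold = config$hysteresis_threshold,
                               decrease_frac = config$hysteresis_decrease_frac,
                               same_frac = config$hysteresis_same_frac)
    if (isTRUE(config$sign_flip)) {
      curve$re <- -curve$re
      curve$im <- -curve$im
    }
    chk <- attr(curve, "applicability")
    meta <- sp[[1]]$meta
    curves[[label]] <- curve
    rows[[label]] <- tibble(
      label = label,
      organ = meta$organ %||% NA_character_,
      subject = meta$subject %||% NA_character_,
      flag = chk$flag, index_fast = chk$index_fast,
      index_slow = chk$index_slow,
      files = paste(unique(vapply(sp, function(e) basename(e$file),
                                  character(1))), collapse = ";"))
  }
  list(curves = curves, report = dplyr::bind_rows(rows))
}

#' Fit every applicable curve of a preprocessed study
#'
#' @param prep output of [pipeline_preprocess()].
#' @param config a [run_config()].
#' @param force fit FAIL-flagged specimens anyway.
#' @return A list with `fits` (named list of `m2_fit`) and `table` (tibble
#'   of per-specimen parameter estimates and standard errors).
#' @export
pipeline_fit <- function(prep, config = run_config(), force = FALSE) {
  fits <- list()
  rows <- list()
  for (label in names(prep$curves)) {
    curve <- prep$curves[[label]]
    drv <- attr(curve, "drive")
    fit <- fit_m2(curve, drv,
                  multistart = config$fit_multistart,
                  seed = config$fit_seed,
                  weighting = config$fit_weighting,
                  free_tau = config$fit_free_tau,
                  force = force,
                  control = list(maxiter = config$fit_maxiter,
                                 tol = config$solver_tol,
                                 profile_EA = config$fit_profile))
    fits[[label]] <- fit
    td <- tidy(fit)
    wide <- setNames(as.list(td$estimate), td$term)
    se <- setNames(as.list(td$std.error), paste0(td$term, "_se"))
    rows[[label]] <- as_tibble(c(list(label = label,
                                      flag = fit$applicability,
                                      residual_rms = fit$residual_rms,
                                      converged = fit$converged),
                                 wide, se))
  }
  list(fits = fits, table = dplyr::bind_rows(rows))
}

#' Quantify a fitted study into organ records
#'
#' @param fitted output of [pipeline_fit()].
#' @param prep output of [pipeline_preprocess()] (for organ/subject
#'   metadata).
#' @param cal a [calibration_reference()].
#' @return A list with `records` (organ records tibble incl. fitted
#'   magnetic parameters), `ranking` (per-subject ascending N_MSC order) and
#'   `summary` ([summary_table()] output).
#' @export
pipeline_biodist <- function(fitted, prep, cal = calibration_reference()) {
  recs <- list()
  for (label in names(fitted$fits)) {
    fit <- fitted$fits[[label]]
    meta <- prep$report[prep$report$label == label, ]
    p <- fit$params
    rec <- organ_record(organ = meta$organ %||% label,
                        subject = meta$subject %||% "study",
                        M_tilde = p$M_tilde, M_C = p$M_C,
                        status = "fitted", cal = cal)
    rec$sigma <- p$sigma; rec$alpha <- p$alpha
    rec$tau_N <- p$tau_N; rec$E_A <- p$E_A
    recs[[label]] <- rec
  }
  records <- dplyr::bind_rows(recs)
  ranking <- records |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) >= 2) rank_organs(dplyr::mutate(d, subject = key$subject))[, setdiff(names(d), "subject")] else d
    }) |>
    dplyr::ungroup()
  list(records = records, ranking = ranking, summary = summary_table(records))
}

#' Full study report with optional ground-truth comparison
#'
#' Runs preprocess, fit and quantification over a study directory; when a
#' `manifest.csv` ground-truth file (as written by [make_phantom_study()])
#' is present, recovered counts are joined against the truth and relative
#' errors reported.
#'
#' @param in_dir study directory.
#' @param config a [run_config()].
#' @param force fit FAIL-flagged specimens anyway.
#' @return A list with `prep`, `fits`, `biodist`, and (when a manifest
#'   exists) `comparison` (tibble with true/recovered N_MSC and relative
#'   errors).
#' @export
pipeline_report <- function(in_dir, config = run_config(), force = FALSE) {
  prep <- pipeline_preprocess(in_dir, config)
  fitted <- pipeline_fit(prep, config, force = force)
  cal <- calibration_reference(aggregates_per_cell = config$aggregates_per_cell)
  bio <- pipeline_biodist(fitted, prep, cal = cal)
  out <- list(prep = prep, fits = fitted, biodist = bio)
  mf <- file.path(in_dir, "manifest.csv")
  if (file.exists(mf)) {
    truth <- as_tibble(utils::read.csv(mf))
    cmp <- dplyr::inner_join(
      dplyr::select(bio$records, "organ", "subject",
                    N_MSC_fit = "N_MSC", M_tilde_fit = "M_tilde"),
      dplyr::select(truth, "organ", "subject",
                    N_MSC_true = "N_MSC", M_tilde_true = "M_tilde"),
      by = c("organ", "subject"))
    cmp$rel_err_N_MSC <- cmp$N_MSC_fit / cmp$N_MSC_true - 1
    cmp$rel_err_M_tilde <- cmp$M_tilde_fit / cmp$M_tilde_true - 1
    out$comparison <- cmp
  }
  out
}
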