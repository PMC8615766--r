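# Conversion of fitted magnetics into per-gram counts of magnetically
# active centers and labeled stem cells, organ ranking, and reporting.

#' Calibration reference of the injection solution
#'
#' Facts linking the magnetic signal to cell numbers: in the injected
#' colloidal solution the nanoparticles form aggregates (the magnetically
#' active centers) of on average 160 nanoparticles, and each labeled stem
#' cell carries on average 8.27e4 aggregates; 1.5e5 cells were injected.
#'
#' @param aggregates_per_cell mean number of aggregates per labeled cell.
#' @param nanoparticles_per_aggregate mean nanoparticles per aggregate.
#' @param cells_injected number of cells in the injected dose.
#' @param solution_params optional [ensemble_params()] of the injection
#'   solution.
#' @return A list of class `calibration_reference`.
#' @export
calibration_reference <- function(aggregates_per_cell = 8.27e4,
                                  nanoparticles_per_aggregate = 160,
                                  cells_injected = 1.5e5,
                                  solution_params = NULL) {
  stopifnot(aggregates_per_cell > 0, nanoparticles_per_aggregate > 0,
            cells_injected > 0)
  structure(list(aggregates_per_cell = aggregates_per_cell,
                 nanoparticles_per_aggregate = nanoparticles_per_aggregate,
                 cells_injected = cells_injected,
                 solution_params = solution_params),
            class = "calibration_reference")
}

#' Number of magnetically active centers per gram
#'
#' N_P = M_tilde / (M_C * mu_B): the per-gram count of aggregates follows
#' from the saturation magnetization and the mean aggregate moment, because
#' the magnetically uncoupled aggregates contribute additively to the
#' response.
#'
#' @param M_tilde saturation magnetization (emu/g), >= 0. Vectorized.
#' @param M_C mean aggregate moment (Bohr magnetons), > 0. Vectorized.
#' @return Centers per gram.
#' @examples
#' count_centers(3.633e-6, 31580)   # ~1.24e10
#' @export
count_centers <- function(M_tilde, M_C) {
  stopifnot(is.numeric(M_tilde), is.numeric(M_C))
  if (any(M_C <= 0)) abort("`M_C` must be > 0.")
  if (any(M_tilde < 0)) abort("`M_tilde` must be >= 0.")
  M_tilde / (M_C * m2_constants()$mu_B)
}

#' Number of labeled stem cells per gram
#'
#' Divides the aggregate count by the mean number of aggregates carried per
#' cell, comparing the organ signal to the injection solution of known cell
#' content.
#'
#' @param N_P centers per gram, >= 0. Vectorized.
#' @param cal a [calibration_reference()].
#' @return Labeled cells per gram.
#' @examples
#' count_mscs(1.24e10)   # ~1.5e5
#' @export
count_mscs <- function(N_P, cal = calibration_reference()) {
  stopifnot(is.numeric(N_P))
  if (any(N_P < 0)) abort("`N_P` must be >= 0.")
  N_P / cal$aggregates_per_cell
}

#' Build an organ quantification record
#'
#' One row of the per-organ quantification table. For `status = "fitted"`
#' the counts satisfy N_P = M_tilde / (M_C * mu_B) by construction.
#'
#' @param organ organ name.
#' @param subject subject identifier.
#' @param M_tilde saturation magnetization (emu/g).
#' @param M_C mean aggregate moment (mu_B) used for the counts.
#' @param status `"fitted"`, `"mass-scaled"` or `"amplitude-scaled"`.
#' @param cal a [calibration_reference()].
#' @param source_fit optional [fit_m2()] result the record derives from.
#' @return A one-row tibble with columns organ, subject, M_tilde, N_P,
#'   N_MSC, M_C, status.
#' @export
organ_record <- function(organ, subject, M_tilde, M_C,
                         status = c("fitted", "mass-scaled", "amplitude-scaled"),
                         cal = calibration_reference(), source_fit = NULL) {
  status <- match.arg(status)
  N_P <- count_centers(M_tilde, M_C)
  out <- tibble(organ = organ, subject = subject, M_tilde = M_tilde,
                N_P = N_P, N_MSC = count_mscs(N_P, cal), M_C = M_C,
                status = status)
  if (!is.null(source_fit)) attr(out, "source_fit") <- source_fit
  out
}

#' Estimate an unprocessed organ by amplitude scaling
#'
#' For organs whose sweeps could not be fitted, the saturation magnetization
#' is estimated from a fitted reference organ by the ratio of the
#' per-gram-normalized response amplitudes, assuming the aggregate moments
#' are close: M_tilde_target = M_tilde_ref * amp_target / amp_ref. Counts
#' are computed with the reference moment and the record is flagged
#' approximate (status `"amplitude-scaled"`).
#'
#' @param reference a one-row record from [organ_record()] with status
#'   `"fitted"`.
#' @param amp_ref,amp_target response amplitudes (peak |re| of the
#'   per-gram-normalized curves) of the reference and target specimens.
#' @param organ,subject identifiers of the target record.
#' @param cal a [calibration_reference()].
#' @return A one-row record with status `"amplitude-scaled"`.
#' @export
amplitude_scaled_estimate <- function(reference, amp_ref, amp_target,
                                      organ, subject = reference$subject,
                                      cal = calibration_reference()) {
  stopifnot(nrow(reference) == 1)
  if (!identical(reference$status, "fitted"))
    abort("`reference` must be a fitted record.")
  if (amp_ref <= 0) abort("Reference amplitude must be > 0.")
  if (amp_target < 0) abort("Target amplitude must be >= 0.")
  organ_record(organ, subject,
               M_tilde = reference$M_tilde * amp_target / amp_ref,
               M_C = reference$M_C, status = "amplitude-scaled", cal = cal)
}

#' Rank organs by labeled-cell density
#'
#' Stable ascending sort of one subject's records by N_MSC; ties are broken
#' alphabetically by organ name and flagged.
#'
#' @param records a tibble of records ([organ_record()] rows) for a single
#'   subject, at least two.
#' @return The records sorted ascending by `N_MSC`, with columns `rank` and
#'   `tied` added.
#' @export
rank_organs <- function(records) {
  if (nrow(records) < 2) abort("Need at least two records to rank.")
  if (length(unique(records$subject)) != 1)
    abort("`rank_organs()` ranks one subject at a time; split by subject first.")
  out <- dplyr::arrange(records, .data$N_MSC, .data$organ)
  out$rank <- seq_len(nrow(out))
  out$tied <- duplicated(out$N_MSC) | duplicated(out$N_MSC, fromLast = TRUE)
  if (any(out$tied)) warn("Ties in N_MSC broken alphabetically.")
  out
}

#' Quantification summary table
#'
#' Formats organ records into the standard biodistribution report layout:
#' one row per specimen with magnetization, center and cell counts, and the
#' fitted magnetic parameters where available. Approximate
#' (amplitude-scaled) rows are prefixed with "~"; magnetic-parameter cells
#' without a fit are rendered as "-".
#'
#' @param records a tibble of records; may carry columns `sigma`, `alpha`,
#'   `tau_N`, `E_A` for fitted rows.
#' @return A list with `table` (character-formatted tibble) and
#'   `chart_data` (tidy organ x subject N_MSC tibble for bar charts).
#' @export
summary_table <- function(records) {
  fmt <- function(x, digits = 3) ifelse(is.na(x), "-", signif(x, digits))
  approx_row <- records$status == "amplitude-scaled"
  tag <- function(x) ifelse(approx_row, paste0("~", x), as.character(x))
  opt <- function(nm) if (nm %in% names(records)) records[[nm]] else rep(NA_real_, nrow(records))
  tab <- tibble(
    organ = records$organ,
    subject = records$subject,
    M_tilde = tag(fmt(records$M_tilde, 4)),
    N_P = tag(fmt(records$N_P, 3)),
    N_MSC = tag(fmt(signif(records$N_MSC, 2), 2)),
    M_C = ifelse(records$status == "fitted", fmt(records$M_C, 4), "-"),
    sigma = ifelse(records$status == "fitted", fmt(opt("sigma")), "-"),
    alpha = ifelse(records$status == "fitted", fmt(opt("alpha")), "-"),
    tau_N = ifelse(records$status == "fitted", fmt(opt("tau_N")), "-"),
    E_A = ifelse(records$status == "fitted", fmt(opt("E_A")), "-"),
    status = records$status)
  chart <- records |>
    dplyr::select("organ", "subject", "N_MSC") |>
    dplyr::arrange(.data$subject, .data$N_MSC)
  list(table = tab, chart_data = chart)
}

#' Reference biodistribution table
#'
#' The published per-organ quantification of SPION-labeled MSCs in two
#' glioma-bearing rats 24 h after intravenous injection, plus the injection
#' solution ("solution" row): saturation magnetization, center and cell
#' counts, and, for the directly fitted specimens, the ensemble magnetic
#' parameters. Approximate (amplitude/mass-scaled) rows have
#' `approximate = TRUE` and carry no magnetic parameters.
#'
#' @return A tibble with one row per (organ, subject).
#' @export
reference_biodistribution <- function() {
  tribble_df <- tibble(
    organ = c("solution",
              "tumor", "brain", "lungs", "spleen", "muscle", "liver",
              "skin", "pancreas",
              "tumor", "brain", "lungs", "spleen", "muscle", "liver",
              "skin", "pancreas"),
    subject = c("solution", rep("rat1", 8), rep("rat2", 8)),
    M_tilde = c(3.633e-6,
                6.495e-6, 4.303e-7, 4.26e-6, 4.093e-6, 6.77e-6, 6.618e-6,
                1.52e-6, 2.64e-7,
                3.17e-6, 2.17e-7, 2.479e-5, 2.61e-6, 1.572e-6, 6.64e-6,
                8.78e-6, 5.44e-7),
    N_P = c(1.24e10,
            2.65e10, 1.18e9, 1.74e10, 1.578e10, 2.85e10, 3.24e10,
            4.17e9, 0.72e9,
            1.29e10, 0.59e9, 1.01e11, 1.01e10, 0.662e10, 3.48e10,
            2.41e10, 1.49e9),
    N_MSC = c(1.5e5,
              3.2e5, 1.4e4, 2.1e5, 1.9e5, 3.4e5, 3.9e5, 5.0e4, 8.7e3,
              1.6e5, 7.1e3, 1.2e6, 1.2e5, 8.0e4, 4.2e5, 2.9e5, 1.8e4),
    M_C = c(31580,
            26400, 39400, NA, 28000, NA, NA, NA, NA,
            NA, NA, 26700, NA, 25700, 20600, NA, NA),
    sigma = c(0.734,
              0.485, 0.241, NA, 0.758, NA, NA, NA, NA,
              NA, NA, 0.786, NA, 0.283, 0.862, NA, NA),
    alpha = c(0.2057,
              0.287, 0.207, NA, 0.2374, NA, NA, NA, NA,
              NA, NA, 0.2421, NA, 1.036, 0.291, NA, NA),
    tau_N = c(1.020,
              0.651, 1.29, NA, 0.810, NA, NA, NA, NA,
              NA, NA, 0.759, NA, 0.332, 0.502, NA, NA),
    E_A = c(8.3,
            0, 0, NA, 17.4, NA, NA, NA, NA,
            NA, NA, 13.3, NA, 8.22, 0, NA, NA),
    approximate = c(FALSE,
                    FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                    FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  tribble_df
}

#' Bar chart of a biodistribution
#'
#' @param records a tibble with columns `organ`, `subject`, `N_MSC`.
#' @return A ggplot: labeled cells per gram by organ, one panel per subject.
#' @export
plot_biodistribution <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = stats::reorder(.data$organ, .data$N_MSC),
                               y = .data$N_MSC)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~subject, scales = "free_x") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = expression(N[MSC] ~ (g^-1))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
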