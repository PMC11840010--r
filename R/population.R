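#' Active algal abundance in cells per litre
#'
#' Scales the total microscopic cell count (cells ml-1) by the active
#' population fraction determined from single-cell isotope imaging, and
#' converts to cells L-1. The SD scales linearly; the binomial uncertainty
#' of the active fraction itself is not propagated (no SD is available for
#' it), which is a documented simplification.
#'
#' @param total_cells_per_ml Mean total abundance (cells ml-1).
#' @param sd_cells_per_ml SD of the total abundance (cells ml-1).
#' @param active_fraction Fraction of cells active (0-1; default 0.90).
#' @return List with `mean` and `sd` (cells L-1) and `active_fraction`.
#' @export
#' @examples
#' active_abundance(16.2e3, 1.2e3)  # 1.458e7 cells L-1
active_abundance <- function(total_cells_per_ml, sd_cells_per_ml = 0,
                             active_fraction = 0.90) {
  stopifnot(total_cells_per_ml >= 0, sd_cells_per_ml >= 0,
            active_fraction >= 0, active_fraction <= 1)
  list(mean = total_cells_per_ml * active_fraction * 1e3,
       sd = sd_cells_per_ml * active_fraction * 1e3,
       active_fraction = active_fraction)
}

#' Contribution of single-cell uptake to the bulk community rate
#'
#' \deqn{contribution\,(\%) = 100 \times \frac{rate_{cell} \times N_{cell}}{rate_{bulk}}}
#'
#' where the cell rate is the mean rate of active cells (pmol or fmol
#' cell-1 day-1), the abundance is in active cells L-1, and the bulk rate
#' in umol L-1 day-1. Units are reconciled internally.
#'
#' @param cell_rate Mean single-cell rate of the active population.
#' @param active_cells_per_l Active abundance (cells L-1).
#' @param bulk_rate Bulk assimilation rate (umol L-1 day-1).
#' @param cell_rate_unit `"pmol"` (default) or `"fmol"` per cell per day.
#' @return Contribution in percent.
#' @export
#' @examples
#' contribution(4.6, 1.458e7, 448)  # ~15%
contribution <- function(cell_rate, active_cells_per_l, bulk_rate,
                         cell_rate_unit = c("pmol", "fmol")) {
  cell_rate_unit <- match.arg(cell_rate_unit)
  if (any(bulk_rate <= 0)) stop("bulk rate must be positive")
  stopifnot(all(active_cells_per_l >= 0))
  to_umol <- switch(cell_rate_unit, pmol = 1e-6, fmol = 1e-9)
  100 * (cell_rate * to_umol * active_cells_per_l) / bulk_rate
}

#' First-order uncertainty of the contribution estimate
#'
#' Delta-method propagation for a product/quotient of independent factors:
#' relative SDs combine in quadrature,
#' \deqn{sd_{\%} = contribution \times \sqrt{\sum_i (sd_i / mean_i)^2}.}
#'
#' @param percent The contribution estimate (%) whose uncertainty is sought.
#' @param means Numeric vector of the factor means (cell rate, abundance,
#'   bulk rate — any consistent units, since only relative SDs enter).
#' @param sds Numeric vector of the matching SDs.
#' @return One-sigma uncertainty of the contribution, in percent.
#' @export
#' @examples
#' pct <- contribution(4.6, active_abundance(16.2e3, 1.2e3)$mean, 448)
#' propagate_contribution_uncertainty(pct, c(4.6, 16.2e3, 448),
#'                                    c(3.46, 1.2e3, 101))  # ~12
propagate_contribution_uncertainty <- function(percent, means, sds) {
  stopifnot(length(means) == length(sds), all(sds >= 0))
  if (any(means <= 0)) stop("factor means must be positive")
  percent * sqrt(sum((sds / means)^2))
}

#' Abundance corrected for the change in POC standing stock
#'
#' Biomass is unevenly distributed between incubation bottles and changes
#' over the incubation; scaling the T0 cell count by the fractional change
#' in POC gives an abundance estimate matched to the bottle actually
#' measured.
#'
#' @param abundance_t0 Cell abundance at T0 (any unit).
#' @param poc_t0 POC at T0 (umol C L-1, > 0).
#' @param poc_tx POC at the rate timepoint (same units).
#' @return Corrected abundance, same unit as `abundance_t0`.
#' @export
poc_corrected_abundance <- function(abundance_t0, poc_t0, poc_tx) {
  if (any(poc_t0 <= 0)) stop("reference POC must be positive")
  stopifnot(all(poc_tx >= 0))
  abundance_t0 * (poc_tx / poc_t0)
}

#' Contribution table across substrates and timepoints
#'
#' Driver combining the single-cell rate summary, the bulk rate table and
#' the abundance estimate into the community-contribution estimates with
#' propagated uncertainty, optionally adding the POC-corrected abundance
#' variant.
#'
#' @param cell_summary Active-population summary from [population_summary()]
#'   (`$active`), with columns `fix_c_pmol_d`(_sd) and/or
#'   `assim_n_fmol_d`(_sd).
#' @param bulk_table Output of [bulk_rate_table()].
#' @param total_cells_per_ml,sd_cells_per_ml,active_fraction Passed to
#'   [active_abundance()].
#' @param poc_by_timepoint Optional named numeric vector of mean POC
#'   (umol C L-1) including `"T0"`; when supplied, rows with
#'   `abundance_source = "poc_corrected"` are added.
#' @return Tidy data frame: treatment, timepoint, substrate,
#'   abundance_source, percent, sd_percent.
#' @export
contribution_table <- function(cell_summary, bulk_table,
                               total_cells_per_ml = 16.2e3,
                               sd_cells_per_ml = 1.2e3,
                               active_fraction = 0.90,
                               poc_by_timepoint = NULL) {
  ab <- active_abundance(total_cells_per_ml, sd_cells_per_ml, active_fraction)
  specs <- list(
    DIC = list(rate = "fix_c_pmol_d", unit = "pmol"),
    NH4 = list(rate = "assim_n_fmol_d", unit = "fmol"),
    NO3 = list(rate = "assim_n_fmol_d", unit = "fmol")
  )
  rows <- list()
  for (i in seq_len(nrow(bulk_table))) {
    b <- bulk_table[i, ]
    spec <- specs[[b$substrate]]
    cs <- cell_summary[cell_summary$treatment == b$treatment &
                         cell_summary$timepoint == b$timepoint, , drop = FALSE]
    if (nrow(cs) != 1 || !spec$rate %in% names(cs)) next
    cr <- cs[[spec$rate]]
    cr_sd <- cs[[paste0(spec$rate, "_sd")]]
    if (is.na(cr) || b$assim_umol_l_d <= 0) next
    sources <- list(counts = ab$mean)
    if (!is.null(poc_by_timepoint) &&
        all(c("T0", b$timepoint) %in% names(poc_by_timepoint))) {
      sources$poc_corrected <- poc_corrected_abundance(
        ab$mean, poc_by_timepoint[["T0"]], poc_by_timepoint[[b$timepoint]])
    }
    for (src in names(sources)) {
      pct <- contribution(cr, sources[[src]], b$assim_umol_l_d, spec$unit)
      sdp <- propagate_contribution_uncertainty(
        pct,
        means = c(cr, sources[[src]], b$assim_umol_l_d),
        sds = c(ifelse(is.na(cr_sd), 0, cr_sd),
                ab$sd * sources[[src]] / ab$mean,
                ifelse(is.na(b$assim_umol_l_d_sd), 0, b$assim_umol_l_d_sd)))
      rows[[length(rows) + 1]] <- data.frame(
        treatment = b$treatment, timepoint = b$timepoint,
        substrate = b$substrate, abundance_source = src,
        cell_rate = cr, active_cells_per_l = sources[[src]],
        bulk_rate = b$assim_umol_l_d,
        percent = pct, sd_percent = sdp, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
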