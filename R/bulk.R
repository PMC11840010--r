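#' Bulk assimilation rate from isotope mass balance
#'
#' Converts the isotopic enrichment of particulate organic matter into an
#' element uptake rate: the fraction of the POM label relative to the source
#' pool label, times the POM standing stock, per unit time.
#'
#' \deqn{rate = \frac{excess_{POM}}{excess_{pool}} \times \frac{POM}{\Delta t}}
#'
#' The same formula serves C (POC against the DIC pool) and N (PON against
#' the NH4+ or NO3- pool). Rates are net over the incubation: label respired
#' or released again is not recovered on the filter.
#'
#' @param excess_pom Atom% excess of the particulate fraction.
#' @param excess_pool Atom% excess of the dissolved source pool (> 0).
#' @param pom_conc POM concentration (umol element L-1).
#' @param dt Incubation duration (days).
#' @return Assimilation rate (umol element L-1 day-1).
#' @export
#' @examples
#' bulk_assimilation_rate(1.64, 3.9, 2849, 1.25)
bulk_assimilation_rate <- function(excess_pom, excess_pool, pom_conc, dt) {
  if (any(excess_pool <= 0)) {
    stop("pool atom% excess must be positive (tracer accounting broken)")
  }
  stopifnot(all(dt > 0), all(pom_conc >= 0))
  (excess_pom / excess_pool) * pom_conc / dt
}

#' Convert an element amount from umol to mg
#'
#' @param umol Amount (umol of the element).
#' @param element "C", "N" or "P".
#' @return Mass (mg).
#' @export
#' @examples
#' umol_to_mg(2849, "C")  # 34.22 mg C
umol_to_mg <- function(umol, element = c("C", "N", "P")) {
  element <- match.arg(element)
  umol * ATOMIC_MASS[[element]] / 1000
}

#' Biomass-normalised assimilation rate
#'
#' Divides a volumetric rate by the standing POM mass of the same element,
#' yielding a biomass-specific turnover (umol mg-1 day-1).
#'
#' @param rate Volumetric assimilation rate (umol L-1 day-1).
#' @param pom_mass_mg POM mass concentration (mg element L-1); convert from
#'   umol with [umol_to_mg()].
#' @return Rate per mg of POM element (umol mg-1 day-1).
#' @export
biomass_normalized_rate <- function(rate, pom_mass_mg) {
  if (any(pom_mass_mg <= 0)) stop("POM mass must be positive")
  rate / pom_mass_mg
}

#' Isotope-based specific growth rate
#'
#' Under exponential growth where all newly incorporated label reflects new
#' biomass, the base-2 growth rate follows from the fraction of biomass that
#' is newly synthesised:
#'
#' \deqn{\mu = \log_2\left[\frac{excess_{pool}}{excess_{pool} - excess_{biomass}}\right] / \Delta t}
#'
#' A rate of 1 day-1 means the population doubles its C (or N) content once
#' per day. The estimate is independent of the biomass concentration and
#' applies identically to bulk POM and single cells.
#'
#' @param excess_pool Atom% excess of the dissolved source pool (> 0).
#' @param excess_biomass Atom% excess of the biomass (0 <= x < excess_pool).
#' @param dt Incubation duration (days).
#' @return Specific growth rate (day-1).
#' @export
#' @examples
#' growth_rate(3.9, 3.9 * (1 - 2^(-0.63 * 1.25)), 1.25)  # 0.63
growth_rate <- function(excess_pool, excess_biomass, dt) {
  stopifnot(all(excess_pool > 0), all(dt > 0), all(excess_biomass >= 0))
  if (any(excess_biomass >= excess_pool)) {
    stop("biomass more labelled than source pool: excess_biomass must be < excess_pool")
  }
  log2(excess_pool / (excess_pool - excess_biomass)) / dt
}

#' Population doubling time
#'
#' The reciprocal of the specific growth rate under the exponential-growth
#' assumption of the isotope model. Non-positive growth rates have no
#' defined doubling time and return `NaN` with a warning.
#'
#' @param growth Specific growth rate (day-1).
#' @return Doubling time (days).
#' @export
#' @examples
#' doubling_time(0.62)  # 1.61 days
doubling_time <- function(growth) {
  out <- ifelse(growth > 0, 1 / growth, NaN)
  if (any(!is.finite(out))) {
    warning("doubling time undefined for non-positive growth rate (NaN returned)")
  }
  out
}

#' Molar POC:PON ratio
#'
#' @param poc Particulate organic carbon (umol C L-1).
#' @param pon Particulate organic nitrogen (umol N L-1).
#' @return Dimensionless molar C:N ratio of the particulate fraction.
#' @export
poc_pon_ratio <- function(poc, pon) {
  if (any(pon <= 0)) stop("PON must be positive")
  poc / pon
}

#' Dissolved organic N and P by difference
#'
#' DON = TDN - DIN (DIN being the sum of the measured inorganic N species)
#' and DOP = TDP - PO4. Negative differences, which arise when components
#' sit below detection, are preserved and flagged with a warning.
#'
#' @param tdn Total dissolved nitrogen (uM).
#' @param din_components Numeric vector of inorganic N species (uM):
#'   NO3-, NH4+, NO2- as available.
#' @param tdp Total dissolved phosphorus (uM), or `NA` to skip DOP.
#' @param po4 Phosphate (uM).
#' @return A list with `don`, `dop` and `din` (uM).
#' @export
#' @examples
#' derived_organic_nutrients(0.78, c(0.08, 0.05, 0), 0.11, 0.01)
derived_organic_nutrients <- function(tdn, din_components, tdp = NA, po4 = NA) {
  stopifnot(tdn >= 0, all(din_components >= 0))
  din <- sum(din_components)
  don <- tdn - din
  dop <- if (is.na(tdp)) NA_real_ else tdp - po4
  if (isTRUE(don < 0) || isTRUE(dop < 0)) {
    warning("negative organic-nutrient difference (below-detection artefact?)")
  }
  list(don = don, dop = dop, din = din)
}

#' Analytical detection and quantification limits
#'
#' LOD and LOQ as 3x and 10x the standard deviation of replicate
#' measurements of the lowest standard.
#'
#' @param sd_low_standard Standard deviation of the lowest standard, in
#'   concentration units.
#' @return A list with `lod` and `loq` in the same units.
#' @export
detection_limits <- function(sd_low_standard) {
  stopifnot(all(sd_low_standard >= 0))
  list(lod = 3 * sd_low_standard, loq = 10 * sd_low_standard)
}

#' Bulk rate table across treatments, timepoints and substrates
#'
#' Driver over the bulk mass-balance operations: for every treatment x
#' timepoint x substrate it computes per-bottle assimilation rates,
#' biomass-normalised rates, growth rates and doubling times, then
#' aggregates replicate bottles to mean +/- SD with n.
#'
#' Pool-excess convention: rates at T1 use the pool excess measured at T1;
#' rates at T2 use the mean of the T1 and T2 pool excess
#' ([pool_excess_timeavg()]), reflecting the label decline during the
#' incubation. Bottles with missing POM atom% are dropped with a message.
#'
#' @param bulk Data frame with columns `treatment`, `timepoint` ("T1"/"T2"),
#'   `replicate`, `poc_umol_l`, `pon_umol_l`, `ap13c_poc`, `ap15n_pon`.
#' @param pools Data frame with columns `treatment`, `substrate`
#'   ("DIC", "NH4", "NO3"), `timepoint`, `excess` (atom% excess).
#' @param t1_h,t2_h Elapsed incubation hours at T1 and T2.
#' @param na_c,na_n Natural-abundance baselines for POC and PON atom%.
#' @return Tidy data frame, one row per treatment x timepoint x substrate,
#'   with mean/sd/n for `assim_umol_l_d`, `assim_umol_mg_d`, `mu_d` and
#'   `doubling_d`.
#' @export
bulk_rate_table <- function(bulk, pools, t1_h = 6, t2_h = 30,
                            na_c = natural_abundance("C"),
                            na_n = natural_abundance("N")) {
  stopifnot(all(c("treatment", "timepoint", "replicate", "poc_umol_l",
                  "pon_umol_l", "ap13c_poc", "ap15n_pon") %in% names(bulk)))
  dt_days <- c(T1 = t1_h / 24, T2 = t2_h / 24)
  substrate_cfg <- list(
    DIC = list(pom = "poc_umol_l", ap = "ap13c_poc", el = "C", na = na_c),
    NH4 = list(pom = "pon_umol_l", ap = "ap15n_pon", el = "N", na = na_n),
    NO3 = list(pom = "pon_umol_l", ap = "ap15n_pon", el = "N", na = na_n)
  )
  rows <- list()
  for (tr in unique(bulk$treatment)) {
    for (tp in intersect(c("T1", "T2"), unique(bulk$timepoint))) {
      sub <- bulk[bulk$treatment == tr & bulk$timepoint == tp, , drop = FALSE]
      if (nrow(sub) == 0) next
      ptr <- pools[pools$treatment == tr, , drop = FALSE]
      for (ss in intersect(names(substrate_cfg), unique(ptr$substrate))) {
        cfg <- substrate_cfg[[ss]]
        e1 <- ptr$excess[ptr$substrate == ss & ptr$timepoint == "T1"]
        e2 <- ptr$excess[ptr$substrate == ss & ptr$timepoint == "T2"]
        if (length(e1) != 1) next
        pool_excess <- if (tp == "T1" || length(e2) != 1) e1 else
          pool_excess_timeavg(e1, e2)
        ap <- sub[[cfg$ap]]
        keep <- !is.na(ap)
        if (any(!keep)) {
          message(sprintf("dropping %d bottle(s) with missing %s atom%% (%s %s)",
                          sum(!keep), ss, tr, tp))
        }
        sub_k <- sub[keep, , drop = FALSE]
        if (nrow(sub_k) == 0) next
        excess_pom <- sub_k[[cfg$ap]] - cfg$na$atom_percent
        pom <- sub_k[[cfg$pom]]
        dt <- dt_days[[tp]]
        assim <- bulk_assimilation_rate(excess_pom, pool_excess, pom, dt)
        assim_mg <- biomass_normalized_rate(assim, umol_to_mg(pom, cfg$el))
        mu <- growth_rate(pool_excess, pmax(excess_pom, 0), dt)
        dbl <- suppressWarnings(doubling_time(mu))
        agg <- function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x))
        rows[[length(rows) + 1]] <- data.frame(
          treatment = tr, timepoint = tp, substrate = ss,
          element = cfg$el, pool_excess = pool_excess, dt_days = dt,
          n = nrow(sub_k),
          assim_umol_l_d = mean(assim), assim_umol_l_d_sd = stats::sd(assim),
          assim_umol_mg_d = mean(assim_mg), assim_umol_mg_d_sd = stats::sd(assim_mg),
          mu_d = mean(mu), mu_d_sd = stats::sd(mu),
          doubling_d = mean(dbl), doubling_d_sd = stats::sd(dbl),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
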