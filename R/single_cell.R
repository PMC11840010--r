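#' Quantify isotope fractions per region of interest in ion-count images
#'
#' Computes per-cell heavy-isotope fractions from secondary-ion-mass-
#' spectrometry count rasters of the isotopologues 12C14N-, 13C14N- and
#' 12C15N-, given an integer label mask (0 = background, each positive
#' integer = one cell ROI).
#'
#' Per pixel, the 13C fraction is `13C14N / (13C14N + 12C14N)` and the 15N
#' fraction `12C15N / (12C15N + 12C14N)`. The default ROI estimator is the
#' mean of the per-pixel ratios; `method = "count_sum"` instead sums counts
#' over the ROI before forming the ratio, which is the lower-variance
#' estimator at low counts. Pixels with a zero denominator are excluded.
#' ROIs whose denominators are all zero are skipped with a warning.
#'
#' @param images Named list of equally sized numeric matrices with elements
#'   `c12n14`, `c13n14` and optionally `c12n15`.
#' @param labels Integer matrix of the same dimension; 0 is background.
#' @param method ROI estimator: `"pixel_mean"` (default) or `"count_sum"`.
#' @return Data frame with one row per ROI: `cell_id`, `frac13c`,
#'   `frac15n` (NA when `c12n15` absent), `roi_pixels`.
#' @export
roi_quantify <- function(images, labels, method = c("pixel_mean", "count_sum")) {
  method <- match.arg(method)
  stopifnot(all(c("c12n14", "c13n14") %in% names(images)))
  dims <- lapply(c(images, list(labels)), dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("all rasters and the label mask must share the same shape")
  }
  if (any(unlist(images) < 0)) stop("ion count rasters must be non-negative")
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  has_n <- "c12n15" %in% names(images)

  roi_fraction <- function(heavy, light, idx) {
    den <- heavy[idx] + light[idx]
    ok <- den > 0
    if (!any(ok)) return(NA_real_)
    if (method == "pixel_mean") mean(heavy[idx][ok] / den[ok])
    else sum(heavy[idx][ok]) / sum(den[ok])
  }

  rows <- lapply(ids, function(id) {
    idx <- which(labels == id)
    f13 <- roi_fraction(images$c13n14, images$c12n14, idx)
    f15 <- if (has_n) roi_fraction(images$c12n15, images$c12n14, idx) else NA_real_
    data.frame(cell_id = id, frac13c = f13, frac15n = f15,
               roi_pixels = length(idx))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(cell_id = integer(), frac13c = numeric(),
                      frac15n = numeric(), roi_pixels = integer()))
  }
  bad <- is.na(out$frac13c)
  if (any(bad)) {
    warning(sprintf("skipping %d ROI(s) with all-zero denominators", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Cell biovolume assuming a cylindrical shape
#'
#' \deqn{V = \frac{\pi}{4} \, w^2 \, l}
#'
#' appropriate for the elongate cells of glacier ice algae.
#'
#' @param length_um Cell length (um).
#' @param width_um Cell width / diameter (um).
#' @return Biovolume (um^3).
#' @export
#' @examples
#' biovolume_cylinder(16.0, 10.6)  # ~1412 um^3
biovolume_cylinder <- function(length_um, width_um) {
  if (any(length_um <= 0) || any(width_um <= 0)) {
    stop("cell dimensions must be positive")
  }
  (pi / 4) * width_um^2 * length_um
}

#' Cell dry weight from biovolume
#'
#' Dry weight = biovolume x buoyant density x dry mass fraction. With
#' biovolume in um^3 and density in kg m-3, 1 um^3 at 1000 kg m-3 equals
#' 1 pg, so the result is in pg. Defaults are the glacier-ice-algal
#' buoyant density (1160 kg m-3) and a mean dry fraction of 0.28.
#'
#' @param biovolume_um3 Biovolume (um^3).
#' @param density_kg_m3 Buoyant density (kg m-3).
#' @param dry_fraction Dry mass / wet mass (0-1).
#' @return Dry weight (pg cell-1).
#' @export
#' @examples
#' cell_dry_weight(1414)  # ~459 pg
cell_dry_weight <- function(biovolume_um3, density_kg_m3 = 1160,
                            dry_fraction = 0.28) {
  stopifnot(all(biovolume_um3 >= 0), density_kg_m3 > 0,
            dry_fraction > 0, dry_fraction <= 1)
  biovolume_um3 * (density_kg_m3 / 1000) * dry_fraction
}

#' Elemental content of a cell from its dry weight
#'
#' Multiplies the dry weight by per-element mass fractions (defaults: the
#' median glacier-ice-algal fractions 0.72 C, 0.04 N, 0.04 P from SEM-EDS)
#' and converts to molar content via atomic masses.
#'
#' @param dry_weight_pg Dry weight (pg cell-1).
#' @param mass_fractions Named numeric vector of element mass fractions;
#'   names among "C", "N", "P". Need not sum to 1 (other elements are
#'   simply not listed).
#' @return Data frame with `dry_weight_pg` and `content_C`, `content_N`,
#'   `content_P` in pmol cell-1 (per element present in `mass_fractions`).
#' @export
#' @examples
#' cell_elemental_content(459.3)  # C ~27.5 pmol, N ~1.31 pmol
cell_elemental_content <- function(dry_weight_pg,
                                   mass_fractions = c(C = 0.72, N = 0.04, P = 0.04)) {
  stopifnot(all(dry_weight_pg >= 0), all(mass_fractions >= 0),
            all(mass_fractions <= 1),
            all(names(mass_fractions) %in% c("C", "N", "P")))
  out <- data.frame(dry_weight_pg = dry_weight_pg)
  for (el in names(mass_fractions)) {
    # pg * (g/g) / (g/mol) = pmol
    out[[paste0("content_", el)]] <-
      dry_weight_pg * mass_fractions[[el]] / ATOMIC_MASS[[el]]
  }
  out
}

#' Single-cell fixation / assimilation rate
#'
#' The per-cell analogue of the bulk mass balance: the cell's label relative
#' to the source pool, times the cell's elemental content, per unit time.
#'
#' \deqn{rate = \frac{excess_{cell}}{excess_{pool}} \times \frac{content}{\Delta t}}
#'
#' @param excess_cell Atom% excess of the cell.
#' @param excess_pool Atom% excess of the dissolved source pool (> 0).
#' @param content Cellular content of the element (pmol cell-1); by
#'   convention the population mean content is used for all cells.
#' @param dt Incubation duration (days).
#' @return Fixation rate (pmol cell-1 day-1; multiply by 1000 for fmol).
#' @export
cell_fixation_rate <- function(excess_cell, excess_pool, content, dt) {
  if (any(excess_pool <= 0)) stop("pool atom% excess must be positive")
  stopifnot(all(dt > 0), all(content >= 0))
  (excess_cell / excess_pool) * content / dt
}

#' Single-cell isotope-based growth rate
#'
#' [growth_rate()] applied per cell. Inactive cells (below the activity
#' threshold) should be excluded from active-population summaries but are
#' retained in full-population output; see [population_summary()].
#'
#' @inheritParams growth_rate
#' @param excess_cell Atom% excess of the cell.
#' @return Specific growth rate (day-1).
#' @export
cell_growth_rate <- function(excess_pool, excess_cell, dt) {
  growth_rate(excess_pool, excess_cell, dt)
}

#' Per-cell C:N assimilation ratio
#'
#' Ratio of the C-fixation rate to the N-assimilation rate of the same cell
#' (both in the same molar units). Population summaries should average the
#' per-cell ratios, not take the ratio of population means. Cells with a
#' non-positive N rate are excluded with a warning.
#'
#' @param c_rate,n_rate Per-cell rates (pmol cell-1 day-1).
#' @return Per-cell ratios (NA where excluded).
#' @export
assimilation_cn_ratio <- function(c_rate, n_rate) {
  out <- ifelse(n_rate > 0, c_rate / n_rate, NA_real_)
  if (any(is.na(out))) {
    warning(sprintf("%d cell(s) with non-positive N rate excluded from C:N ratio",
                    sum(is.na(out))))
  }
  out
}

#' Single-cell C:N:P stoichiometry from SEM-EDS atom percentages
#'
#' Computes per-cell C:N, C:P and N:P atomic ratios from energy-dispersive
#' X-ray spectroscopy atom% values, and summarises them as mean +/- SD with
#' n. Redfield reference ratios (C:N 6.6, C:P 116, N:P 16) are attached for
#' comparison. Cells with a zero denominator are excluded with a warning.
#'
#' @param records Data frame with per-cell columns `atom_pct_c`,
#'   `atom_pct_n`, `atom_pct_p` (and optionally `cell_id`).
#' @return List with `per_cell` (data frame of per-cell ratios), `summary`
#'   (data frame: ratio, mean, sd, n, redfield) — `sd` is NA when n = 1.
#' @export
stoichiometry_from_eds <- function(records) {
  stopifnot(all(c("atom_pct_c", "atom_pct_n", "atom_pct_p") %in% names(records)))
  ok <- records$atom_pct_n > 0 & records$atom_pct_p > 0 & records$atom_pct_c >= 0
  if (any(!ok)) {
    warning(sprintf("%d cell(s) with zero denominator excluded from stoichiometry",
                    sum(!ok)))
  }
  r <- records[ok, , drop = FALSE]
  per_cell <- data.frame(
    cell_id = if ("cell_id" %in% names(r)) r$cell_id else seq_len(nrow(r)),
    cn = r$atom_pct_c / r$atom_pct_n,
    cp = r$atom_pct_c / r$atom_pct_p,
    np = r$atom_pct_n / r$atom_pct_p
  )
  summ <- do.call(rbind, lapply(c("cn", "cp", "np"), function(col) {
    x <- per_cell[[col]]
    data.frame(ratio = toupper(sub("(.)(.)", "\\1:\\2", col)),
               mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               n = length(x),
               redfield = unname(REDFIELD[[toupper(gsub("[^a-z]", "", col))]]))
  }))
  list(per_cell = per_cell, summary = summ)
}

#' Summarise per-cell rates by treatment and timepoint
#'
#' Produces the population summary twice: over the active fraction only
#' (the convention for headline rates, since inactive cells carry no tracer
#' signal) and over all imaged cells. Requires an `active` logical column.
#'
#' @param cells Data frame with columns `treatment`, `timepoint`, `active`
#'   and any numeric per-cell columns to summarise.
#' @param value_cols Character vector of numeric columns to summarise;
#'   defaults to all numeric columns except identifiers.
#' @return List with `active` and `all` data frames: one row per treatment
#'   x timepoint with `n` and `<col>` / `<col>_sd` for each value column.
#'   Empty active sets yield an empty summary with a warning.
#' @export
population_summary <- function(cells, value_cols = NULL) {
  stopifnot(all(c("treatment", "timepoint", "active") %in% names(cells)))
  if (is.null(value_cols)) {
    num <- vapply(cells, is.numeric, logical(1))
    value_cols <- setdiff(names(cells)[num],
                          c("cell_id", "roi_pixels"))
  }
  summarise <- function(d) {
    if (nrow(d) == 0) {
      warning("empty cell set: returning empty summary")
      return(data.frame(treatment = character(), timepoint = character(),
                        n = integer()))
    }
    groups <- split(d, list(d$treatment, d$timepoint), drop = TRUE)
    do.call(rbind, lapply(groups, function(g) {
      row <- data.frame(treatment = g$treatment[1], timepoint = g$timepoint[1],
                        n = nrow(g), stringsAsFactors = FALSE)
      for (col in value_cols) {
        x <- g[[col]][!is.na(g[[col]])]
        row[[col]] <- if (length(x)) mean(x) else NA_real_
        row[[paste0(col, "_sd")]] <- if (length(x) > 1) stats::sd(x) else NA_real_
      }
      row
    })) -> out
    rownames(out) <- NULL
    out[order(out$treatment, out$timepoint), , drop = FALSE]
  }
  list(active = summarise(cells[cells$active, , drop = FALSE]),
       all = summarise(cells))
}

#' Per-cell rate table from an ROI cell table and pool excesses
#'
#' Driver over the single-cell operations: converts measured isotope
#' fractions to atom%, classifies activity against the 13C baseline,
#' derives the population-mean cellular C and N content from cell geometry
#' (biovolume -> dry weight -> content), and computes per-cell C-fixation
#' and N-assimilation rates, growth rates, doubling times and C:N
#' assimilation ratios.
#'
#' Pool-excess convention matches [bulk_rate_table()]: T1 cells use the T1
#' pool excess, T2 cells the T1/T2 time-average. Per convention the
#' population-mean content is applied to every cell
#' (`content = "population_mean"`); `"per_cell"` uses each cell's own
#' geometry instead. Cells without usable geometry receive the population
#' mean and are flagged in `geometry_imputed`.
#'
#' @param cells Data frame with columns `cell_id`, `treatment`, `timepoint`,
#'   `frac13c`, `frac15n` (fractions, 0-1), `length_um`, `width_um`.
#' @param pools Data frame as in [bulk_rate_table()].
#' @param t1_h,t2_h Elapsed incubation hours at T1 and T2.
#' @param na_c,na_n Natural-abundance baselines.
#' @param content `"population_mean"` or `"per_cell"`.
#' @param k Activity-threshold multiplier (see [classify_active()]).
#' @return The input data frame with added columns: `ap13c`, `ap15n`,
#'   `excess13c`, `excess15n`, `active`, `biovolume_um3`, `content_c_pmol`,
#'   `content_n_pmol`, `fix_c_pmol_d`, `assim_n_fmol_d`, `mu_c`, `mu_n`,
#'   `doubling_c_d`, `cn_assim`, `geometry_imputed`.
#' @export
cell_rate_table <- function(cells, pools, t1_h = 6, t2_h = 30,
                            na_c = natural_abundance("C"),
                            na_n = natural_abundance("N"),
                            content = c("population_mean", "per_cell"),
                            k = 3) {
  content <- match.arg(content)
  stopifnot(all(c("cell_id", "treatment", "timepoint", "frac13c") %in% names(cells)))
  if (any(cells$frac13c > 1, na.rm = TRUE)) {
    stop("frac13c must be a fraction (0-1); got values > 1")
  }
  dt_days <- c(T1 = t1_h / 24, T2 = t2_h / 24)
  out <- cells
  out$ap13c <- 100 * cells$frac13c
  out$ap15n <- if ("frac15n" %in% names(cells)) 100 * cells$frac15n else NA_real_
  out$excess13c <- out$ap13c - na_c$atom_percent
  out$excess15n <- out$ap15n - na_n$atom_percent
  out$active <- classify_active(out$ap13c, na_c, k)$active

  # geometry -> composition; impute population mean where missing
  has_geom <- !is.na(cells$length_um) & !is.na(cells$width_um) &
    cells$length_um > 0 & cells$width_um > 0
  out$geometry_imputed <- !has_geom
  bv <- rep(NA_real_, nrow(cells))
  bv[has_geom] <- biovolume_cylinder(cells$length_um[has_geom],
                                     cells$width_um[has_geom])
  bv[!has_geom] <- mean(bv[has_geom])
  out$biovolume_um3 <- bv
  comp <- cell_elemental_content(cell_dry_weight(bv))
  mean_c <- mean(comp$content_C)
  mean_n <- mean(comp$content_N)
  out$content_c_pmol <- if (content == "population_mean") mean_c else comp$content_C
  out$content_n_pmol <- if (content == "population_mean") mean_n else comp$content_N

  out$fix_c_pmol_d <- NA_real_
  out$assim_n_fmol_d <- NA_real_
  out$mu_c <- NA_real_
  out$mu_n <- NA_real_

  pool_for <- function(tr, ss, tp) {
    p <- pools[pools$treatment == tr & pools$substrate == ss, , drop = FALSE]
    e1 <- p$excess[p$timepoint == "T1"]
    e2 <- p$excess[p$timepoint == "T2"]
    if (length(e1) != 1) return(NA_real_)
    if (tp == "T1" || length(e2) != 1) e1 else pool_excess_timeavg(e1, e2)
  }
  n_substrate <- function(tr) {
    ss <- intersect(c("NH4", "NO3"),
                    pools$substrate[pools$treatment == tr])
    if (length(ss)) ss[1] else NA_character_
  }

  for (i in seq_len(nrow(out))) {
    tp <- out$timepoint[i]
    dt <- dt_days[[tp]]
    ec <- pool_for(out$treatment[i], "DIC", tp)
    if (!is.na(ec) && ec > 0) {
      exc <- out$excess13c[i]
      out$fix_c_pmol_d[i] <- cell_fixation_rate(exc, ec, out$content_c_pmol[i], dt)
      out$mu_c[i] <- if (exc > 0 && exc < ec) cell_growth_rate(ec, exc, dt) else
        if (exc <= 0) 0 else NA_real_
    }
    ssn <- n_substrate(out$treatment[i])
    if (!is.na(ssn) && !is.na(out$excess15n[i])) {
      en <- pool_for(out$treatment[i], ssn, tp)
      if (!is.na(en) && en > 0) {
        exn <- out$excess15n[i]
        out$assim_n_fmol_d[i] <-
          1000 * cell_fixation_rate(exn, en, out$content_n_pmol[i], dt)
        out$mu_n[i] <- if (exn > 0 && exn < en) cell_growth_rate(en, exn, dt) else
          if (exn <= 0) 0 else NA_real_
      }
    }
  }
  out$doubling_c_d <- suppressWarnings(doubling_time(out$mu_c))
  out$cn_assim <- suppressWarnings(
    assimilation_cn_ratio(out$fix_c_pmol_d, out$assim_n_fmol_d / 1000))
  out
}
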