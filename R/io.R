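#' Read a per-cell ROI table
#'
#' Expects a CSV/TSV with columns `cell_id`, `treatment`, `timepoint`,
#' `frac13c`, `frac15n`, `length_um`, `width_um` (UTF-8, "." decimal).
#' Isotope columns must be fractions on the 0-1 scale; values above 1
#' (atom% supplied by mistake) are a validation error. Rows failing
#' row-level validation are skipped with a logged reason.
#'
#' @param path File path.
#' @return Validated data frame; skipped rows are reported via messages and
#'   counted in the `skipped` attribute.
#' @export
read_cell_table <- function(path) {
  d <- read_delim_auto(path)
  require_columns(d, c("cell_id", "treatment", "timepoint", "frac13c"), path)
  for (col in intersect(c("frac13c", "frac15n"), names(d))) {
    if (any(d[[col]] > 1, na.rm = TRUE)) {
      stop(sprintf("%s: column '%s' contains values > 1; fractions (0-1) required, not atom%%",
                   path, col))
    }
  }
  bad <- !is.finite(d$frac13c) | d$frac13c < 0
  if ("length_um" %in% names(d) && "width_um" %in% names(d)) {
    bad_geom <- !is.na(d$length_um) & !is.na(d$width_um) &
      (d$width_um > d$length_um | d$width_um <= 0)
    if (any(bad_geom)) {
      message(sprintf("%s: %d row(s) with width > length or non-positive width skipped (rows: %s)",
                      path, sum(bad_geom),
                      paste(which(bad_geom), collapse = ", ")))
    }
    bad <- bad | bad_geom
  }
  if (any(bad & !is.na(bad))) {
    message(sprintf("%s: skipping %d unparseable row(s)", path, sum(bad, na.rm = TRUE)))
  }
  out <- d[!bad | is.na(bad), , drop = FALSE]
  attr(out, "skipped") <- sum(bad, na.rm = TRUE)
  out
}

#' Read a bulk EA-IRMS sample table
#'
#' Expects columns `treatment`, `timepoint`, `replicate`, `poc_umol_l`,
#' `pon_umol_l`, `ap13c_poc`, `ap15n_pon` (atom%, 0-100).
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_bulk_table <- function(path) {
  d <- read_delim_auto(path)
  require_columns(d, c("treatment", "timepoint", "replicate",
                       "poc_umol_l", "pon_umol_l", "ap13c_poc", "ap15n_pon"),
                  path)
  for (col in c("ap13c_poc", "ap15n_pon")) {
    if (any(d[[col]] < 0 | d[[col]] > 100, na.rm = TRUE)) {
      stop(sprintf("%s: column '%s' must be atom%% in [0, 100]", path, col))
    }
  }
  bad <- is.na(d$poc_umol_l) | d$poc_umol_l < 0
  if (any(bad)) message(sprintf("%s: skipping %d row(s) with invalid POC", path, sum(bad)))
  d[!bad, , drop = FALSE]
}

#' Read an isotope-pool excess table
#'
#' Expects columns `treatment`, `substrate`, `timepoint`, `excess`.
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_pool_table <- function(path) {
  d <- read_delim_auto(path)
  require_columns(d, c("treatment", "substrate", "timepoint", "excess"), path)
  d
}

#' Read a SEM-EDS per-cell composition table
#'
#' Expects at least `atom_pct_c`, `atom_pct_n`, `atom_pct_p`.
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_eds_table <- function(path) {
  d <- read_delim_auto(path)
  require_columns(d, c("atom_pct_c", "atom_pct_n", "atom_pct_p"), path)
  neg <- vapply(c("atom_pct_c", "atom_pct_n", "atom_pct_p"),
                function(col) any(d[[col]] < 0, na.rm = TRUE), logical(1))
  if (any(neg)) stop(sprintf("%s: negative atom%% values", path))
  d
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

require_columns <- function(d, cols, path) {
  missing <- setdiff(cols, names(d))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
  invisible(d)
}

#' Write an ion-count raster as a 16-bit TIFF
#'
#' Counts are stored as 16-bit unsigned integers (values above 65535 are an
#' error). [read_ion_tiff()] inverts the scaling exactly.
#'
#' @param counts Numeric matrix of non-negative counts.
#' @param path Output path.
#' @export
write_ion_tiff <- function(counts, path) {
  stopifnot(all(counts >= 0))
  if (any(counts > 65535)) stop("counts exceed 16-bit range")
  tiff::writeTIFF(round(counts) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an ion-count raster written by [write_ion_tiff()]
#'
#' @param path TIFF path.
#' @return Integer-valued numeric matrix of counts.
#' @export
read_ion_tiff <- function(path) {
  round(tiff::readTIFF(path) * 65535)
}

#' Percent community composition from labelled counts
#'
#' @param counts Named non-negative numeric vector of counts per taxon.
#' @return Named numeric vector of percentages summing to 100.
#' @export
#' @examples
#' composition_percentages(c(nordenskioeldii = 10700, alaskanum = 5580))
composition_percentages <- function(counts) {
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive")
  100 * counts / total
}

#' Compare treatment groups: Kruskal-Wallis with Holm-adjusted pairwise tests
#'
#' Omnibus Kruskal-Wallis rank test (chi-squared approximation,
#' df = groups - 1), followed by pairwise rank-sum comparisons with Holm's
#' p-adjustment (ties in the Holm ordering are broken by the original
#' comparison order, which is how [stats::p.adjust()] resolves them).
#' Groups that are not significantly different share a letter in the
#' compact letter display. Inactive cells should be excluded upstream.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor or character vector of group labels (>= 2 groups).
#' @param alpha Significance level for the letter display.
#' @return List with `statistic` (H), `df`, `p_value`, `pairwise` (data
#'   frame: group1, group2, p, p_holm) and `letters` (named character
#'   vector).
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) >= 2, length(values) == length(groups))
  kw <- stats::kruskal.test(values, groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    x <- values[groups == pairs[1, i]]
    y <- values[groups == pairs[2, i]]
    pw$p[i] <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
  pw$p_holm <- stats::p.adjust(pw$p, method = "holm")

  # compact letter display: groups ordered by mean rank; a group joins an
  # existing letter class if it differs significantly from none of its members
  rk <- rank(values)
  mean_rank <- tapply(rk, groups, mean)
  ord <- names(sort(mean_rank))
  differs <- function(a, b) {
    hit <- (pw$group1 == a & pw$group2 == b) | (pw$group1 == b & pw$group2 == a)
    any(pw$p_holm[hit] < alpha, na.rm = TRUE)
  }
  classes <- list()
  for (g in ord) {
    joined <- FALSE
    for (j in seq_along(classes)) {
      if (!any(vapply(classes[[j]], differs, logical(1), a = g))) {
        classes[[j]] <- c(classes[[j]], g)
        joined <- TRUE
      }
    }
    if (!joined) classes[[length(classes) + 1]] <- g
  }
  letters_out <- stats::setNames(rep("", length(lev)), lev)
  for (j in seq_along(classes)) {
    for (g in classes[[j]]) {
      letters_out[g] <- paste0(letters_out[g], letters[j])
    }
  }
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, pairwise = pw, letters = letters_out)
}

#' Pipeline run configuration
#'
#' Bundles paths, incubation times, physical constants and analysis
#' switches for [run_pipeline()]. With `paths = NULL` the pipeline runs on
#' a synthetic experiment generated from `sim` (so the full analysis is
#' exercisable without any input files).
#'
#' @param paths Optional named list with `cells`, `bulk`, `pools`, `eds`
#'   file paths.
#' @param out_dir Output directory for tidy CSVs and the JSON run summary.
#' @param t1_h,t2_h Incubation times (h).
#' @param k Activity-threshold multiplier.
#' @param roi_method ROI estimator for image-based runs.
#' @param abundance_per_ml,abundance_sd_per_ml,active_fraction Community
#'   abundance inputs for the contribution stage.
#' @param seed Seed (also used for the synthetic experiment).
#' @param sim Optional [sim_config()] used when `paths` is NULL.
#' @return List of class `run_config`.
#' @export
run_config <- function(paths = NULL, out_dir = tempfile("sip_run_"),
                       t1_h = 6, t2_h = 30, k = 3,
                       roi_method = "pixel_mean",
                       abundance_per_ml = 16.2e3,
                       abundance_sd_per_ml = 1.2e3,
                       active_fraction = 0.90,
                       seed = 1L, sim = NULL) {
  stopifnot(k > 0, t1_h > 0, t2_h > t1_h)
  if (is.null(sim)) sim <- sim_config(seed = seed)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the bulk-rate, single-cell, stoichiometry and contribution
#' stages over the configured inputs (files, or a synthetic experiment when
#' no paths are given), writes tidy CSVs plus a JSON run summary recording
#' the seed and constants used, and returns the result tables. A failure in
#' any stage aborts with an error naming the stage.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `bulk_rates`, `cell_rates`,
#'   `cell_summary`, `stoichiometry`, `contribution` and `files`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  inputs <- stage("read", {
    if (is.null(config$paths)) {
      simulate_experiment(config$sim)
    } else {
      list(cells = read_cell_table(config$paths$cells),
           bulk = read_bulk_table(config$paths$bulk),
           pools = read_pool_table(config$paths$pools),
           eds = if (!is.null(config$paths$eds)) read_eds_table(config$paths$eds))
    }
  })
  bulk_rates <- stage("bulk_rates",
                      bulk_rate_table(inputs$bulk[inputs$bulk$timepoint != "T0", ],
                                      inputs$pools,
                                      t1_h = config$t1_h, t2_h = config$t2_h))
  cell_rates <- stage("cell_rates",
                      cell_rate_table(inputs$cells, inputs$pools,
                                      t1_h = config$t1_h, t2_h = config$t2_h,
                                      k = config$k))
  cell_summary <- stage("cell_summary", population_summary(cell_rates))
  stoich <- if (!is.null(inputs$eds)) {
    stage("stoichiometry", stoichiometry_from_eds(inputs$eds))
  }
  poc_tp <- tapply(inputs$bulk$poc_umol_l, inputs$bulk$timepoint, mean)
  contrib <- stage("contribution",
                   contribution_table(cell_summary$active, bulk_rates,
                                      total_cells_per_ml = config$abundance_per_ml,
                                      sd_cells_per_ml = config$abundance_sd_per_ml,
                                      active_fraction = config$active_fraction,
                                      poc_by_timepoint = poc_tp))
  files <- stage("write", {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(bulk_rates = "bulk_rates.csv", cell_rates = "cell_rates.csv",
               cell_summary_active = "cell_summary_active.csv",
               contribution = "contribution.csv")
    utils::write.csv(bulk_rates, file.path(config$out_dir, paths["bulk_rates"]),
                     row.names = FALSE)
    utils::write.csv(cell_rates, file.path(config$out_dir, paths["cell_rates"]),
                     row.names = FALSE)
    utils::write.csv(cell_summary$active,
                     file.path(config$out_dir, paths["cell_summary_active"]),
                     row.names = FALSE)
    utils::write.csv(contrib, file.path(config$out_dir, paths["contribution"]),
                     row.names = FALSE)
    if (!is.null(stoich)) {
      utils::write.csv(stoich$summary,
                       file.path(config$out_dir, "stoichiometry_summary.csv"),
                       row.names = FALSE)
    }
    summary_json <- list(
      package_version = as.character(utils::packageVersion("glacierSIP")),
      seed = config$seed,
      t1_h = config$t1_h, t2_h = config$t2_h, k = config$k,
      natural_abundance = NATURAL_ABUNDANCE_DEFAULTS,
      abundance_per_ml = config$abundance_per_ml,
      active_fraction = config$active_fraction)
    jsonlite::write_json(summary_json,
                         file.path(config$out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    file.path(config$out_dir, c(paths, "run_summary.json"))
  })
  invisible(list(bulk_rates = bulk_rates, cell_rates = cell_rates,
                 cell_summary = cell_summary, stoichiometry = stoich,
                 contribution = contrib, files = files))
}
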