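#' Configuration for a synthetic tracer-incubation experiment
#'
#' Defines the study conditions emulated by [simulate_experiment()]: a
#' supraglacial algal population with lognormal growth heterogeneity and an
#' inactive subpopulation, dual 13C-DIC / 15N tracer additions with pool
#' depletion over the incubation, bulk POM composed of algal plus non-algal
#' material, SEM-EDS composition tables, and Poisson ion-count rasters.
#'
#' Defaults mirror the field experiment the pipeline was built for: 244
#' imaged cells of which ~10% are inactive; lognormal growth with median
#' 0.419 day-1 and geometric SD 1.62 (arithmetic mean 0.47, SD 0.24 day-1);
#' sampling at 6 h (T1) and 30 h (T2); 10 uM 15N tracer at 98 atom% into
#' ambient NH4+ (0.078 uM) or NO3- (0.05 uM) at 0.36 atom%; a DIC pool
#' whose measured excess declines from 4.4 (T1) to 3.6 (T2) atom%;
#' an algal abundance of 16.2e3 cells ml-1 embedded in ~2850 umol C L-1
#' total POC.
#'
#' @param seed Integer seed; fixing it fixes every output byte.
#' @param n_cells Number of imaged cells across all groups.
#' @param inactive_fraction Expected fraction of cells without DIC uptake.
#' @param growth_median,growth_gsd Lognormal growth-rate distribution
#'   (median day-1, geometric SD).
#' @param t1_h,t2_h Sampling times (hours since tracer addition).
#' @param treatments Subset of `c("control", "NH4", "NO3")`.
#' @param ambient_nh4_um,ambient_no3_um Ambient N concentrations (uM).
#' @param n_natural_ap Natural 15N atom% of the ambient pools.
#' @param tracer_add_um,tracer_label_ap 15N tracer addition (uM, atom%).
#' @param dic_excess_t1,dic_excess_t2 Measured 13C-DIC atom% excess at
#'   T1/T2 (the DIC pool is parameterised by its measured trajectory, not
#'   by mixing arithmetic, since DIC equilibrates with a large and
#'   variable ambient pool). Equal values give a non-depleting pool.
#' @param nh4_excess_halflife_h,no3_excess_halflife_h Exponential
#'   half-lives (h) of the N pool atom% excess (dilution by regenerated
#'   substrate); `Inf` disables depletion.
#' @param abundance_per_ml Algal abundance (cells ml-1).
#' @param non_algal_poc_umol_l Non-algal background POC (umol C L-1).
#' @param non_algal_mu Specific labelling rate of the background (day-1).
#' @param non_algal_cn Molar C:N of the background POM.
#' @param length_median_um,length_gsd,width_ratio_median,width_ratio_gsd
#'   Lognormal cell geometry (width drawn as a ratio of length, capped at 1).
#' @param n_bottles_t1,n_bottles_t2 Replicate bottles per timepoint.
#' @param bottle_cv Lognormal CV of bottle-to-bottle biomass loading.
#' @param ap_noise_sd Gaussian measurement noise on bulk atom% (atom%).
#' @param eds_n_cells Cells in the SEM-EDS table.
#' @param eds_mass_fractions Mean C/N/P mass fractions of dry weight.
#' @param eds_cv Lognormal CVs of the per-cell mass fractions.
#' @param counts_per_cell Expected total 12C14N counts per cell in rendered
#'   rasters.
#' @param raster_size Raster side length (pixels).
#' @param pixel_um Pixel edge (um).
#' @param background_per_pixel Expected background counts per pixel
#'   (detector background; 0 gives the zero-background mode).
#' @param noise Master switch: `FALSE` yields the deterministic noise-free
#'   mode (no measurement noise, no bottle variability, Poisson rasters
#'   replaced by their expectations, inactive cells at exactly zero excess).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cells = 244L,
                       inactive_fraction = 0.10,
                       growth_median = 0.419,
                       growth_gsd = 1.62,
                       t1_h = 6, t2_h = 30,
                       treatments = c("control", "NH4", "NO3"),
                       ambient_nh4_um = 0.078,
                       ambient_no3_um = 0.05,
                       n_natural_ap = 0.36,
                       tracer_add_um = 10,
                       tracer_label_ap = 98,
                       dic_excess_t1 = 4.4,
                       dic_excess_t2 = 3.6,
                       nh4_excess_halflife_h = 12,
                       no3_excess_halflife_h = 24,
                       abundance_per_ml = 16.2e3,
                       non_algal_poc_umol_l = 2400,
                       non_algal_mu = 0.7,
                       non_algal_cn = 20,
                       length_median_um = 16,
                       length_gsd = 1.35,
                       width_ratio_median = 0.66,
                       width_ratio_gsd = 1.15,
                       n_bottles_t1 = 1L,
                       n_bottles_t2 = 3L,
                       bottle_cv = 0.3,
                       ap_noise_sd = 0.02,
                       eds_n_cells = 48L,
                       eds_mass_fractions = c(C = 0.72, N = 0.04, P = 0.04),
                       eds_cv = c(C = 0.08, N = 0.15, P = 0.30),
                       counts_per_cell = 2e4,
                       raster_size = 256L,
                       pixel_um = 0.5,
                       background_per_pixel = 1e-4,
                       noise = TRUE) {
  stopifnot(inactive_fraction >= 0, inactive_fraction <= 1,
            growth_median > 0, growth_gsd >= 1,
            0 < t1_h, t1_h < t2_h,
            dic_excess_t1 > 0, dic_excess_t2 > 0,
            dic_excess_t2 <= dic_excess_t1,
            counts_per_cell > 0, raster_size > 0,
            all(treatments %in% c("control", "NH4", "NO3")))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Closed-form cell atom% excess under a decaying pool
#'
#' A cell growing exponentially at rate `mu` (base-2, day-1) incorporates
#' label from a pool whose atom% excess decays exponentially,
#' `E(s) = E0 exp(-k s)`. Weighting the pool excess by when each unit of
#' biomass was synthesised gives the cell's excess at time t:
#'
#' \deqn{excess(t) = E_0\, r \,\frac{e^{(r-k)t} - 1}{(r-k)\, e^{rt}}, \qquad r = \mu \ln 2}
#'
#' With `k = 0` this reduces to the textbook inversion
#' `E0 (1 - 2^(-mu t))`, so a non-depleting pool makes the rate equations
#' exactly invertible.
#'
#' @param excess0 Pool atom% excess at t = 0.
#' @param decay_per_day Pool excess decay constant k (day-1; 0 = none).
#' @param mu Cell growth rate (day-1); vectorised.
#' @param t_days Elapsed time (days).
#' @return Cell atom% excess.
#' @export
tracer_cell_excess <- function(excess0, decay_per_day, mu, t_days) {
  r <- mu * log(2)
  k <- decay_per_day
  out <- numeric(length(r))
  zero <- r <= 0
  degenerate <- !zero & abs(r - k) < 1e-12
  general <- !zero & !degenerate
  out[degenerate] <- excess0 * r[degenerate] * t_days *
    exp(-r[degenerate] * t_days)
  rg <- r[general]
  out[general] <- excess0 * rg * (exp((rg - k) * t_days) - 1) /
    ((rg - k) * exp(rg * t_days))
  out
}

# Pool excess trajectory parameters implied by a config: for each substrate,
# the excess at t = 0 and the decay constant (day-1).
pool_trajectories <- function(cfg) {
  dt_h <- cfg$t2_h - cfg$t1_h
  k_dic_h <- if (cfg$dic_excess_t1 == cfg$dic_excess_t2) 0 else
    log(cfg$dic_excess_t1 / cfg$dic_excess_t2) / dt_h
  traj <- list(DIC = list(excess0 = cfg$dic_excess_t1 * exp(k_dic_h * cfg$t1_h),
                          k_day = k_dic_h * 24))
  mix <- function(ambient) {
    tracer_pool_mixing(ambient, cfg$n_natural_ap, cfg$tracer_add_um,
                       cfg$tracer_label_ap, element = "N")$excess
  }
  if ("NH4" %in% cfg$treatments) {
    traj$NH4 <- list(excess0 = mix(cfg$ambient_nh4_um),
                     k_day = if (is.finite(cfg$nh4_excess_halflife_h))
                       log(2) / cfg$nh4_excess_halflife_h * 24 else 0)
  }
  if ("NO3" %in% cfg$treatments) {
    traj$NO3 <- list(excess0 = mix(cfg$ambient_no3_um),
                     k_day = if (is.finite(cfg$no3_excess_halflife_h))
                       log(2) / cfg$no3_excess_halflife_h * 24 else 0)
  }
  traj
}

pool_excess_at <- function(traj, t_days) traj$excess0 * exp(-traj$k_day * t_days)

#' Simulate a complete tracer-incubation experiment with known ground truth
#'
#' Generates every table the analysis modules consume — per-cell ROI
#' isotope fractions with geometry, bulk POM samples, pool excess values
#' and an SEM-EDS composition table — from a known underlying population,
#' and returns the ground truth alongside.
#'
#' The labelling model inverts the growth-rate equation: an active cell
#' with growth rate mu has, at time t, an atom% excess of
#' [tracer_cell_excess()] under the configured pool trajectory. Inactive
#' cells sit on the natural-abundance distribution. Bulk POM is the algal
#' aggregate plus a non-algal background with its own (configured)
#' labelling rate; bottle-level biomass loading is lognormal.
#'
#' @param config A [sim_config()].
#' @return List with elements `config`, `cells` (ROI-table layout:
#'   cell_id, treatment, timepoint, frac13c, frac15n, length_um, width_um),
#'   `bulk` (layout of [bulk_rate_table()] input, including T0 rows),
#'   `pools` (treatment, substrate, timepoint, excess), `eds`
#'   (atom%/mass% per cell) and `truth` (per-cell mu/active/excess,
#'   pool trajectories, true bulk rates and true contributions).
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  traj <- pool_trajectories(cfg)
  na_c <- natural_abundance("C")
  na_n <- natural_abundance("N")
  t_days <- c(T1 = cfg$t1_h / 24, T2 = cfg$t2_h / 24)

  # -- group allocation: T1 imaging only for control and NH4 (as sampled) --
  grp <- expand.grid(treatment = cfg$treatments, timepoint = c("T1", "T2"),
                     stringsAsFactors = FALSE)
  grp <- grp[!(grp$treatment == "NO3" & grp$timepoint == "T1"), , drop = FALSE]
  n_grp <- nrow(grp)
  alloc <- diff(round(seq(0, cfg$n_cells, length.out = n_grp + 1)))

  cells <- do.call(rbind, lapply(seq_len(n_grp)[alloc > 0], function(i) {
    data.frame(treatment = grp$treatment[i], timepoint = grp$timepoint[i],
               n = seq_len(alloc[i]), stringsAsFactors = FALSE)
  }))
  n <- nrow(cells)
  cells$cell_id <- seq_len(n)

  mu <- stats::rlnorm(n, log(cfg$growth_median), log(cfg$growth_gsd))
  inactive <- if (cfg$noise) stats::rbinom(n, 1, cfg$inactive_fraction) == 1 else
    seq_len(n) <= round(cfg$inactive_fraction * n)
  mu[inactive] <- 0

  len <- stats::rlnorm(n, log(cfg$length_median_um), log(cfg$length_gsd))
  wratio <- pmin(1, stats::rlnorm(n, log(cfg$width_ratio_median),
                                  log(cfg$width_ratio_gsd)))
  wid <- len * wratio

  t_cell <- t_days[cells$timepoint]
  excess13 <- vapply(seq_len(n), function(i)
    tracer_cell_excess(traj$DIC$excess0, traj$DIC$k_day, mu[i], t_cell[i]),
    numeric(1))
  excess15 <- vapply(seq_len(n), function(i) {
    tr <- cells$treatment[i]
    if (!tr %in% c("NH4", "NO3")) return(NA_real_)
    tracer_cell_excess(traj[[tr]]$excess0, traj[[tr]]$k_day, mu[i], t_cell[i])
  }, numeric(1))

  meas13 <- if (cfg$noise) stats::rnorm(n, 0, na_c$sd_fraction) else 0
  meas15 <- if (cfg$noise) stats::rnorm(n, 0, na_n$sd_fraction) else 0
  frac13c <- na_c$mean_fraction + excess13 / 100 + meas13
  frac15n <- ifelse(is.na(excess15), NA_real_,
                    na_n$mean_fraction + excess15 / 100 + meas15)

  cell_tab <- data.frame(cell_id = cells$cell_id,
                         treatment = cells$treatment,
                         timepoint = cells$timepoint,
                         frac13c = frac13c, frac15n = frac15n,
                         length_um = len, width_um = wid,
                         stringsAsFactors = FALSE)

  comp <- cell_elemental_content(cell_dry_weight(biovolume_cylinder(len, wid)))
  truth_cells <- data.frame(cell_id = cells$cell_id,
                            treatment = cells$treatment,
                            timepoint = cells$timepoint,
                            mu_true = mu, active_true = !inactive,
                            excess13_true = excess13,
                            excess15_true = excess15,
                            biovolume_um3 = biovolume_cylinder(len, wid),
                            content_c_pmol = comp$content_C,
                            content_n_pmol = comp$content_N,
                            stringsAsFactors = FALSE)

  # -- pool table (as measured at the sampling timepoints) --
  pools <- do.call(rbind, lapply(names(traj), function(ss) {
    trts <- if (ss == "DIC") cfg$treatments else ss
    do.call(rbind, lapply(trts, function(tr) {
      data.frame(treatment = tr, substrate = ss,
                 timepoint = c("T1", "T2"),
                 excess = pool_excess_at(traj[[ss]], t_days),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(pools) <- NULL

  # -- bulk POM: algal aggregate + non-algal background --
  abundance_l <- cfg$abundance_per_ml * 1e3
  mean_c <- mean(comp$content_C)            # pmol cell-1
  mean_n <- mean(comp$content_N)
  algal_poc <- abundance_l * mean_c * 1e-6  # umol C L-1
  algal_pon <- abundance_l * mean_n * 1e-6
  bg_poc <- cfg$non_algal_poc_umol_l
  bg_pon <- bg_poc / cfg$non_algal_cn

  pop_excess <- function(tr, ss, td) {
    # content-weighted: larger cells contribute more label to the filter
    idx <- which(cells$treatment == tr)
    ex <- vapply(idx, function(i)
      tracer_cell_excess(traj[[ss]]$excess0, traj[[ss]]$k_day, mu[i], td),
      numeric(1))
    stats::weighted.mean(ex, comp$content_C[idx])
  }
  bg_excess <- function(ss, td)
    tracer_cell_excess(traj[[ss]]$excess0, traj[[ss]]$k_day, cfg$non_algal_mu, td)

  bulk_rows <- list()
  truth_bulk <- list()
  for (tr in cfg$treatments) {
    for (tp in c("T0", "T1", "T2")) {
      nb <- switch(tp, T0 = cfg$n_bottles_t2, T1 = cfg$n_bottles_t1,
                   T2 = cfg$n_bottles_t2)
      td <- if (tp == "T0") 0 else t_days[[tp]]
      e13_alg <- if (tp == "T0") 0 else pop_excess(tr, "DIC", td)
      e13_bg <- if (tp == "T0") 0 else bg_excess("DIC", td)
      e13_pom <- (algal_poc * e13_alg + bg_poc * e13_bg) / (algal_poc + bg_poc)
      has_n <- tr %in% c("NH4", "NO3")
      if (has_n && tp != "T0") {
        e15_alg <- pop_excess(tr, tr, td)
        e15_bg <- bg_excess(tr, td)
        e15_pom <- (algal_pon * e15_alg + bg_pon * e15_bg) /
          (algal_pon + bg_pon)
      } else e15_pom <- 0
      for (b in seq_len(nb)) {
        s <- if (cfg$noise) stats::rlnorm(1, -cfg$bottle_cv^2 / 2,
                                          cfg$bottle_cv) else 1
        ap_eps <- function() if (cfg$noise) stats::rnorm(1, 0, cfg$ap_noise_sd) else 0
        bulk_rows[[length(bulk_rows) + 1]] <- data.frame(
          treatment = tr, timepoint = tp, replicate = b,
          poc_umol_l = (algal_poc + bg_poc) * s,
          pon_umol_l = (algal_pon + bg_pon) * s,
          ap13c_poc = max(0, na_c$atom_percent + e13_pom + ap_eps()),
          ap15n_pon = max(0, na_n$atom_percent + e15_pom +
                            if (has_n && tp != "T0") ap_eps() else 0),
          stringsAsFactors = FALSE)
      }
      if (tp != "T0") {
        # true rates: new element per day, independent of the isotope route
        idx <- cells$treatment == tr
        newfrac <- 1 - 2^(-mu[idx] * td)
        alg_rate_cells <- comp$content_C[idx] * newfrac / td      # pmol cell-1 d-1
        act <- !inactive[idx]
        alg_bulk <- abundance_l * mean(alg_rate_cells) * 1e-6     # umol L-1 d-1
        bgr <- bg_poc * (1 - 2^(-cfg$non_algal_mu * td)) / td
        mean_active_rate <- if (any(act)) mean(alg_rate_cells[act]) else 0
        truth_bulk[[length(truth_bulk) + 1]] <- data.frame(
          treatment = tr, timepoint = tp,
          true_bulk_c_umol_l_d = alg_bulk + bgr,
          true_algal_c_umol_l_d = alg_bulk,
          true_mean_active_cell_rate_pmol_d = mean_active_rate,
          true_contribution_pct = 100 * mean_active_rate *
            (abundance_l * (1 - cfg$inactive_fraction)) * 1e-6 / (alg_bulk + bgr),
          stringsAsFactors = FALSE)
      }
    }
  }
  bulk <- do.call(rbind, bulk_rows)
  rownames(bulk) <- NULL

  # -- SEM-EDS table --
  m <- cfg$eds_n_cells
  draw_w <- function(mean, cv) {
    if (!cfg$noise) return(rep(mean, m))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(m, log(mean) - sdlog^2 / 2, sdlog)
  }
  wc <- draw_w(cfg$eds_mass_fractions[["C"]], cfg$eds_cv[["C"]])
  wn <- draw_w(cfg$eds_mass_fractions[["N"]], cfg$eds_cv[["N"]])
  wp <- draw_w(cfg$eds_mass_fractions[["P"]], cfg$eds_cv[["P"]])
  wo <- pmax(0.05, 1 - wc - wn - wp)
  mol <- cbind(C = wc / ATOMIC_MASS[["C"]], N = wn / ATOMIC_MASS[["N"]],
               O = wo / ATOMIC_MASS[["O"]], P = wp / ATOMIC_MASS[["P"]])
  atom_pct <- 100 * mol / rowSums(mol)
  tot_w <- wc + wn + wo + wp
  eds <- data.frame(cell_id = seq_len(m),
                    atom_pct_c = atom_pct[, "C"], atom_pct_n = atom_pct[, "N"],
                    atom_pct_o = atom_pct[, "O"], atom_pct_p = atom_pct[, "P"],
                    mass_pct_c = 100 * wc / tot_w, mass_pct_n = 100 * wn / tot_w,
                    mass_pct_o = 100 * wo / tot_w, mass_pct_p = 100 * wp / tot_w)

  list(config = cfg,
       cells = cell_tab,
       bulk = bulk,
       pools = pools,
       eds = eds,
       truth = list(cells = truth_cells,
                    pools = traj,
                    bulk = do.call(rbind, truth_bulk),
                    abundance_per_l = abundance_l,
                    mean_content_c_pmol = mean_c,
                    mean_content_n_pmol = mean_n))
}

#' Render synthetic ion-count rasters for a set of cells
#'
#' Places cells as axis-aligned rectangles (cylinder projections) in one or
#' more square rasters and draws per-pixel Poisson counts for the
#' isotopologues 12C14N, 13C14N and 12C15N, with per-pixel means consistent
#' with each cell's true isotope fractions. Background pixels receive
#' near-zero detector background counts. The accompanying integer label
#' mask maps pixels to `cell_id`.
#'
#' @param cells Data frame with columns `cell_id`, `frac13c`, `frac15n`
#'   (true fractions, 0-1; `frac15n` may be NA for a C-only render),
#'   `length_um`, `width_um`.
#' @param config A [sim_config()] (raster size, pixel size, counts per
#'   cell, background, noise switch).
#' @param seed Seed for placement and Poisson draws (defaults to
#'   `config$seed`).
#' @return List of fields; each field is a list with `images` (named list
#'   of matrices `c12n14`, `c13n14`, `c12n15`), `labels` (integer matrix)
#'   and `cell_ids`.
#' @export
render_sims_images <- function(cells, config = sim_config(),
                               seed = config$seed) {
  stopifnot(all(c("cell_id", "frac13c", "length_um", "width_um") %in% names(cells)))
  set.seed(seed)
  S <- config$raster_size
  px <- config$pixel_um
  lp <- pmax(1L, pmin(S, as.integer(round(cells$length_um / px))))
  wp <- pmax(1L, pmin(S, as.integer(round(cells$width_um / px))))
  areas <- as.numeric(lp) * as.numeric(wp)
  if (any(areas > 0.5 * S^2)) stop("cell larger than half the raster: enlarge raster_size")
  per_field <- max(1L, floor(0.25 * S^2 / max(areas)))
  idx_chunks <- split(seq_len(nrow(cells)),
                      ceiling(seq_len(nrow(cells)) / per_field))

  lapply(idx_chunks, function(idx) {
    labels <- matrix(0L, S, S)
    imgs <- list(c12n14 = matrix(0, S, S), c13n14 = matrix(0, S, S),
                 c12n15 = matrix(0, S, S))
    for (i in idx) {
      placed <- FALSE
      for (try in seq_len(500)) {
        r0 <- sample.int(S - lp[i] + 1L, 1L)
        c0 <- sample.int(S - wp[i] + 1L, 1L)
        rr <- r0:(r0 + lp[i] - 1L)
        cc <- c0:(c0 + wp[i] - 1L)
        # 1-px margin so ROIs never touch
        rr_m <- max(1, r0 - 1):min(S, r0 + lp[i])
        cc_m <- max(1, c0 - 1):min(S, c0 + wp[i])
        if (all(labels[rr_m, cc_m] == 0L)) {
          labels[rr, cc] <- cells$cell_id[i]
          npix <- length(rr) * length(cc)
          f13 <- cells$frac13c[i]
          f15 <- if ("frac15n" %in% names(cells) && !is.na(cells$frac15n[i]))
            cells$frac15n[i] else 0
          lam12 <- config$counts_per_cell / npix
          lam13 <- lam12 * f13 / (1 - f13)
          lam15 <- lam12 * f15 / (1 - f15)
          draw <- function(lam) {
            if (config$noise) matrix(stats::rpois(npix, lam), length(rr))
            else matrix(lam, length(rr), length(cc))
          }
          imgs$c12n14[rr, cc] <- draw(lam12)
          imgs$c13n14[rr, cc] <- draw(lam13)
          imgs$c12n15[rr, cc] <- draw(lam15)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("raster overcrowded: could not place cell ", cells$cell_id[i])
    }
    if (config$background_per_pixel > 0 && config$noise) {
      bg <- labels == 0L
      nbg <- sum(bg)
      for (ch in names(imgs)) {
        imgs[[ch]][bg] <- stats::rpois(nbg, config$background_per_pixel)
      }
    }
    list(images = imgs, labels = labels, cell_ids = cells$cell_id[idx])
  })
}
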