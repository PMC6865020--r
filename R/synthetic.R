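#' Configure a synthetic ecohydrological landscape
#'
#' Builds the configuration for the seeded synthetic-landscape
#' generator. The generator emulates the statistical structure the
#' state-space analysis assumes — a coarse reanalysis-like flux grid,
#' an annual greenness series, and a fine nighttime-brightness grid —
#' with ground-truth labels for every deliberate perturbation, so the
#' whole pipeline can be exercised and scored without any download.
#'
#' Default geometry is a 60 x 80 pixel grid at 0.75 degrees (4800
#' pixels, the same order as a continental reanalysis domain but
#' desk-fast), years 1982-2015 split into 1982-1998 and 1999-2015.
#' The base dryness index increases log-linearly west to east across
#' the configured `dryness_range` with a gentle north-south harmonic,
#' so every limitation regime is represented.
#'
#' Perturbation patches are step changes applied uniformly to all
#' period-2 years (the analysis compares two period means, so a step
#' is the minimal sufficient structure):
#' * internal patches change evapotranspiration only (`dE`, m/yr) at
#'   fixed forcing — the anthropogenic signature;
#' * external patches change the forcing (`dN`, `dP`, m/yr) at fixed
#'   evapotranspiration — the climate signature.
#'
#' @param n_rows,n_cols,lat_max,lon_min,spacing Coarse grid geometry,
#'   see [grid_spec()].
#' @param years Annual time axis (strictly increasing integers).
#' @param period_split_year First year of the second averaging period;
#'   must lie strictly inside `years`.
#' @param dryness_range Range the base dryness index spans (length 2).
#' @param noise_sd Interannual noise, as a standard-deviation fraction
#'   of the mean; applied multiplicatively (lognormal) to P and N,
#'   with E re-closed through the Schreiber relation each year.
#' @param dE,dN,dP Perturbation magnitudes (m/yr) used by the default
#'   patch set: internal patches get `+dE` / `-dE`; the external
#'   drying patch gets `(+dN, +dP)` and the wetting patch the negated
#'   pair.
#' @param patches Data frame of perturbation patches with columns
#'   `label` (one of `internal_pos_dE`, `internal_neg_dE`,
#'   `external_drying`, `external_wetting`), `row0`, `row1`, `col0`,
#'   `col1` (inclusive pixel bounds) and `dE`, `dN`, `dP` (m/yr).
#'   `NULL` (default) builds four disjoint rectangles in the
#'   moderate-dryness belt from `dE`, `dN`, `dP`.
#' @param greenness_trend Magnitude of the period-2 minus period-1
#'   greenness shift applied with the per-pixel trend sign
#'   (NDVI units).
#' @param greenness_noise_sd Interannual greenness noise (absolute
#'   NDVI units).
#' @param p_background_increase Probability that an unperturbed pixel
#'   is assigned a positive greenness trend (defaults to 0.7, the
#'   prevailing-greening situation typical of recent decades).
#' @param n_city_clusters Number of compact bright clusters.
#' @param city_dn Cluster brightness level (digital number), must lie
#'   in `[12, 63]` so the cluster is detectable.
#' @param city_halfwidth Cluster half-width in fine pixels (a cluster
#'   is a `(2h+1)^2` block); must fit inside one coarse cell.
#' @param background_dn_max Maximum background digital number
#'   (strictly below the 12-DN city threshold).
#' @param fine_factor Odd refinement factor of the brightness grid
#'   relative to the coarse grid.
#' @param seed Integer seed; every generator draw derives from it.
#'
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_rows = 60, n_cols = 80, lat_max = 55,
                            lon_min = 60, spacing = 0.75,
                            years = 1982:2015, period_split_year = 1999,
                            dryness_range = c(0.1, 5), noise_sd = 0.05,
                            dE = 0.1, dN = 0.2, dP = -0.2,
                            patches = NULL,
                            greenness_trend = 0.05,
                            greenness_noise_sd = 0.02,
                            p_background_increase = 0.7,
                            n_city_clusters = 12, city_dn = 40,
                            city_halfwidth = 1, background_dn_max = 6,
                            fine_factor = 5, seed = 1L) {
  if (length(years) < 4 || any(diff(years) <= 0)) {
    stop("`years` must be strictly increasing with at least 4 entries.",
         call. = FALSE)
  }
  if (period_split_year <= years[1] || period_split_year > years[length(years)]) {
    stop("`period_split_year` must lie strictly inside `years`.", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)
  if (greenness_noise_sd < 0) stop("`greenness_noise_sd` must be >= 0.", call. = FALSE)
  if (length(dryness_range) != 2 || any(dryness_range <= 0) ||
      diff(dryness_range) <= 0) {
    stop("`dryness_range` must be two increasing positive numbers.", call. = FALSE)
  }
  if (n_city_clusters < 0) stop("`n_city_clusters` must be >= 0.", call. = FALSE)
  if (city_dn < 12 || city_dn > 63) {
    stop("`city_dn` must lie in [12, 63]: dimmer clusters are below the ",
         "detection threshold.", call. = FALSE)
  }
  if (fine_factor %% 2 != 1 || fine_factor < 1) {
    stop("`fine_factor` must be a positive odd integer.", call. = FALSE)
  }
  if (city_halfwidth < 0 || 2 * city_halfwidth + 1 > fine_factor) {
    stop("`city_halfwidth` must satisfy 2*h + 1 <= fine_factor.", call. = FALSE)
  }
  if (background_dn_max < 0 || background_dn_max >= 12) {
    stop("`background_dn_max` must lie in [0, 12).", call. = FALSE)
  }
  grid <- grid_spec(n_rows, n_cols, lat_max, lon_min, spacing)
  if (is.null(patches)) {
    patches <- default_patches(n_rows, n_cols, dE, dN, dP)
  }
  patches <- tibble::as_tibble(patches)
  need <- c("label", "row0", "row1", "col0", "col1", "dE", "dN", "dP")
  stopifnot(all(need %in% names(patches)))
  if (any(patches$row0 < 1 | patches$row1 > n_rows |
          patches$col0 < 1 | patches$col1 > n_cols |
          patches$row0 > patches$row1 | patches$col0 > patches$col1)) {
    stop("Perturbation patches must be non-empty and lie inside the grid.",
         call. = FALSE)
  }
  structure(
    list(grid = grid, years = as.integer(years),
         period_split_year = as.integer(period_split_year),
         dryness_range = dryness_range, noise_sd = noise_sd,
         patches = patches, greenness_trend = greenness_trend,
         greenness_noise_sd = greenness_noise_sd,
         p_background_increase = p_background_increase,
         n_city_clusters = as.integer(n_city_clusters),
         city_dn = as.integer(city_dn),
         city_halfwidth = as.integer(city_halfwidth),
         background_dn_max = as.integer(background_dn_max),
         fine_factor = as.integer(fine_factor), seed = as.integer(seed)),
    class = "scenario_config"
  )
}

# four disjoint rectangles in the moderate-dryness belt; positions are
# fractions of the grid so non-default grids still carry valid patches
default_patches <- function(n_rows, n_cols, dE, dN, dP) {
  rr <- function(f0, f1) pmax(1L, pmin(n_rows, round(c(f0, f1) * n_rows)))
  cc <- function(f0, f1) pmax(1L, pmin(n_cols, round(c(f0, f1) * n_cols)))
  r1 <- rr(0.14, 0.26); r2 <- rr(0.40, 0.52); r3 <- rr(0.67, 0.79)
  r4 <- rr(0.84, 0.96)
  # the drying patch sits in the wetter belt so that runoff always
  # exceeds |dP| and the E-fixed perturbation stays physically valid
  c_int <- cc(0.55, 0.66); c_dry <- cc(0.40, 0.50); c_wet <- cc(0.66, 0.77)
  tibble::tibble(
    label = c("internal_pos_dE", "internal_neg_dE",
              "external_drying", "external_wetting"),
    row0 = c(r1[1], r2[1], r3[1], r4[1]),
    row1 = c(r1[2], r2[2], r3[2], r4[2]),
    col0 = c(c_int[1], c_int[1], c_dry[1], c_wet[1]),
    col1 = c(c_int[2], c_int[2], c_dry[2], c_wet[2]),
    dE = c(dE, -dE, 0, 0),
    dN = c(0, 0, dN, -dN),
    dP = c(0, 0, dP, -dP)
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %d x %d grid, years %d-%d (split %d)\n",
              x$grid$n_rows, x$grid$n_cols, x$years[1],
              x$years[length(x$years)], x$period_split_year))
  cat(sprintf("  dryness %.3g-%.3g, noise sd %.3g, %d patches, %d cities, seed %d\n",
              x$dryness_range[1], x$dryness_range[2], x$noise_sd,
              nrow(x$patches), x$n_city_clusters, x$seed))
  invisible(x)
}

# smooth base fields: log D ramps west->east across the configured
# range with a mild north-south harmonic; P is a smooth O(1 m/yr) field
base_mean_fields <- function(config) {
  g <- config$grid
  px <- grid_pixels(g)
  t_col <- (px$col - 1) / max(1, g$n_cols - 1)
  t_row <- (px$row - 1) / max(1, g$n_rows - 1)
  ld <- log(config$dryness_range[1]) +
    t_col * diff(log(config$dryness_range)) +
    0.2 * sin(2 * pi * t_row)
  ld <- pmin(pmax(ld, log(config$dryness_range[1])),
             log(config$dryness_range[2]))
  px$P0 <- 1 + 0.15 * sin(2 * pi * t_row) * cos(2 * pi * t_col)
  px$N0 <- exp(ld) * px$P0
  px
}

#' Generate the base annual flux series
#'
#' Draws the annual precipitation and net-radiation series from smooth
#' mean fields with multiplicative lognormal interannual noise, and
#' closes evapotranspiration through the Schreiber relation each year
#' (`E = P - Ro = P(1 - exp(-N/P))`), which keeps every year
#' physically valid (`0 <= E <= min(P, N)`) without clipping. With
#' `noise_sd = 0` the fields equal their means exactly.
#'
#' @param config A [scenario_config()].
#' @return A tibble with one row per pixel-year: `year`, `row`, `col`,
#'   `lat`, `lon`, `P`, `N`, `E` (m/yr).
#' @export
generate_base_fluxes <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  base <- base_mean_fields(config)
  ny <- length(config$years)
  np <- nrow(base)
  set.seed(config$seed)
  # lognormal with unit mean: sdlog chosen so the cv equals noise_sd
  sdlog <- sqrt(log(1 + config$noise_sd^2))
  noise_p <- if (config$noise_sd > 0) {
    exp(stats::rnorm(np * ny, -sdlog^2 / 2, sdlog))
  } else rep(1, np * ny)
  noise_n <- if (config$noise_sd > 0) {
    exp(stats::rnorm(np * ny, -sdlog^2 / 2, sdlog))
  } else rep(1, np * ny)
  out <- tidyr::crossing(year = config$years,
                         dplyr::select(base, "row", "col"))
  out <- dplyr::left_join(out, base, by = c("row", "col"))
  out$P <- out$P0 * noise_p
  out$N <- out$N0 * noise_n
  out$E <- out$P - schreiber_runoff(out$P, out$N)
  dplyr::select(out, "year", "row", "col", "lat", "lon", "P", "N", "E")
}

#' Apply labeled step perturbations to a flux series
#'
#' Internal patches add `dE` to evapotranspiration in every period-2
#' year at fixed `P` and `N` (flux-partitioning change). External
#' patches add `dN`/`dP` to the forcing at fixed `E` (climate change).
#' The perturbed series is validated: any pixel-year driven to
#' `E < 0`, `E > min(P, N)`, `P <= 0` or `N < 0` aborts with a
#' validity error.
#'
#' @param fluxes Base flux tibble from [generate_base_fluxes()].
#' @param config The [scenario_config()] whose `patches` to apply.
#' @return A list: `fluxes` (perturbed tibble) and `truth` (per-pixel
#'   tibble `row`, `col`, `label`, with `"none"` outside patches).
#' @export
apply_perturbations <- function(fluxes, config) {
  stopifnot(inherits(config, "scenario_config"))
  g <- config$grid
  truth <- grid_pixels(g)
  truth$label <- "none"
  for (i in seq_len(nrow(config$patches))) {
    p <- config$patches[i, ]
    in_patch <- truth$row >= p$row0 & truth$row <= p$row1 &
      truth$col >= p$col0 & truth$col <= p$col1
    if (any(truth$label[in_patch] != "none")) {
      stop("Perturbation patches overlap; each pixel may carry one label.",
           call. = FALSE)
    }
    truth$label[in_patch] <- p$label
  }
  out <- dplyr::left_join(fluxes,
                          dplyr::select(truth, "row", "col", "label"),
                          by = c("row", "col"))
  period2 <- out$year >= config$period_split_year
  for (i in seq_len(nrow(config$patches))) {
    p <- config$patches[i, ]
    sel <- period2 & out$label == p$label
    out$E[sel] <- out$E[sel] + p$dE
    out$N[sel] <- out$N[sel] + p$dN
    out$P[sel] <- out$P[sel] + p$dP
  }
  bad <- out$P <= 0 | out$N < 0 | out$E < 0 | out$E > pmin(out$P, out$N)
  if (any(bad)) {
    stop(sprintf(
      "Perturbation drives %d pixel-years outside physical bounds (E in [0, min(P, N)], P > 0, N >= 0).",
      sum(bad)), call. = FALSE)
  }
  list(fluxes = dplyr::select(out, -"label"),
       truth = dplyr::select(truth, "row", "col", "lat", "lon", "label"))
}

#' Generate the annual greenness series
#'
#' Per-pixel annual greenness (NDVI-like, bounded in `[-0.2, 1]`) is a
#' smooth dryness-dependent base level plus a signed two-period step
#' of magnitude `greenness_trend` and Gaussian interannual noise.
#' Trend signs follow the scenario: afforestation-like and wetting
#' patches green up, deforestation-like and drying patches brown down,
#' and background pixels draw a sign with
#' `P(increase) = p_background_increase`.
#'
#' @param config A [scenario_config()].
#' @param truth Ground-truth label tibble from [apply_perturbations()].
#' @return A list: `greenness` (tibble `year`, `row`, `col`,
#'   `greenness`) and `truth` (input `truth` with a
#'   `greenness_trend_sign` column, +1 or -1).
#' @export
generate_greenness <- function(config, truth) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 1L)
  base <- base_mean_fields(config)
  d0 <- base$N0 / base$P0
  g0 <- 0.15 + 0.55 * exp(-0.5 * d0)
  sign_map <- c(internal_pos_dE = 1, internal_neg_dE = -1,
                external_drying = -1, external_wetting = 1)
  trend_sign <- unname(sign_map[truth$label])
  n_bg <- sum(is.na(trend_sign))
  trend_sign[is.na(trend_sign)] <-
    ifelse(stats::runif(n_bg) < config$p_background_increase, 1, -1)
  truth$greenness_trend_sign <- as.integer(trend_sign)
  out <- tidyr::crossing(year = config$years,
                         tibble::tibble(row = base$row, col = base$col,
                                        g0 = g0, sgn = trend_sign))
  in_p2 <- out$year >= config$period_split_year
  noise <- if (config$greenness_noise_sd > 0) {
    stats::rnorm(nrow(out), 0, config$greenness_noise_sd)
  } else 0
  # step of +/- trend/... full step so period-2 mean - period-1 mean = sgn * trend
  out$greenness <- out$g0 + ifelse(in_p2, out$sgn * config$greenness_trend, 0) +
    noise
  out$greenness <- pmin(pmax(out$greenness, -0.2), 1)
  list(greenness = dplyr::select(out, "year", "row", "col", "greenness"),
       truth = truth)
}

#' Refine a coarse grid for the fine brightness layer
#'
#' @param grid Coarse [grid_spec()].
#' @param factor Odd refinement factor.
#' @return Fine [grid_spec()] whose pixel centers nest inside the
#'   coarse cells (the central fine pixel of each coarse cell
#'   coincides with the coarse center).
#' @export
grid_refine <- function(grid, factor) {
  stopifnot(inherits(grid, "grid_spec"), factor >= 1, factor %% 2 == 1)
  sf <- grid$spacing / factor
  grid_spec(grid$n_rows * factor, grid$n_cols * factor,
            lat_max = grid$lat[1] + grid$spacing / 2 - sf / 2,
            lon_min = grid$lon[1] - grid$spacing / 2 + sf / 2,
            spacing = sf)
}

#' Generate the fine-resolution nighttime brightness grid
#'
#' Places `n_city_clusters` compact square bright clusters (digital
#' number `city_dn`) on a dim random background (`DN <=
#' background_dn_max < 12`). Cluster centers are snapped to the
#' centers of distinct, pairwise non-adjacent coarse cells, so
#' clusters are disjoint under either connectivity and each coarse
#' truth cell contains exactly one cluster.
#'
#' @param config A [scenario_config()].
#' @param truth Ground-truth tibble (coarse grid) to be augmented.
#' @return A list: `nightlights` (fine tibble `row`, `col`, `lat`,
#'   `lon`, `dn`), `fine_grid` (the fine [grid_spec()]), and `truth`
#'   with a logical `city` column marking host coarse cells.
#' @export
generate_nightlights <- function(config, truth) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 2L)
  g <- config$grid
  f <- config$fine_factor
  fine <- grid_refine(g, f)
  dn <- matrix(sample(0:config$background_dn_max,
                      fine$n_rows * fine$n_cols, replace = TRUE),
               fine$n_rows, fine$n_cols)
  k <- config$n_city_clusters
  host <- matrix(FALSE, g$n_rows, g$n_cols)
  if (k > 0) {
    cand <- grid_pixels(g)
    cand <- cand[sample.int(nrow(cand)), ]
    chosen <- matrix(NA_integer_, 0, 2)
    for (i in seq_len(nrow(cand))) {
      if (nrow(chosen) == k) break
      r <- cand$row[i]; c <- cand$col[i]
      # require chebyshev distance >= 2 from accepted hosts so the
      # clusters can never touch, even diagonally
      if (nrow(chosen) == 0 ||
          all(pmax(abs(chosen[, 1] - r), abs(chosen[, 2] - c)) >= 2)) {
        chosen <- rbind(chosen, c(r, c))
      }
    }
    if (nrow(chosen) < k) {
      stop(sprintf("Could not place %d non-adjacent city clusters on a %d x %d grid.",
                   k, g$n_rows, g$n_cols), call. = FALSE)
    }
    h <- config$city_halfwidth
    mid <- (f + 1L) %/% 2L
    for (i in seq_len(k)) {
      fr <- (chosen[i, 1] - 1L) * f + mid
      fc <- (chosen[i, 2] - 1L) * f + mid
      dn[(fr - h):(fr + h), (fc - h):(fc + h)] <- config$city_dn
      host[chosen[i, 1], chosen[i, 2]] <- TRUE
    }
  }
  truth$city <- as.vector(t(host))
  nl <- matrix_to_layer(dn, fine, value = "dn")
  nl$dn <- as.integer(nl$dn)
  list(nightlights = nl, fine_grid = fine, truth = truth)
}

#' Generate a complete synthetic landscape
#'
#' Runs the full generator chain — base fluxes, labeled perturbations,
#' greenness, nightlights — under a single seed.
#'
#' @param config A [scenario_config()].
#' @return A list of class `uw_landscape`: `config`, `grid`,
#'   `fine_grid`, `fluxes`, `greenness`, `nightlights`, `truth`
#'   (per-coarse-pixel `label`, `greenness_trend_sign`, `city`).
#' @examples
#' land <- generate_landscape(scenario_config(n_rows = 12, n_cols = 16,
#'                                            n_city_clusters = 2, seed = 7))
#' dplyr::count(land$truth, label)
#' @export
generate_landscape <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  base <- generate_base_fluxes(config)
  pert <- apply_perturbations(base, config)
  grn <- generate_greenness(config, pert$truth)
  nl <- generate_nightlights(config, grn$truth)
  structure(
    list(config = config, grid = config$grid, fine_grid = nl$fine_grid,
         fluxes = pert$fluxes, greenness = grn$greenness,
         nightlights = nl$nightlights, truth = nl$truth),
    class = "uw_landscape"
  )
}

#' @export
print.uw_landscape <- function(x, ...) {
  cat(sprintf("<uw_landscape> %d x %d coarse grid, %d years, %d labeled pixels, %d city cells\n",
              x$grid$n_rows, x$grid$n_cols, length(x$config$years),
              sum(x$truth$label != "none"), sum(x$truth$city)))
  invisible(x)
}

#' Write a generated landscape to a directory
#'
#' Serializes the flux and greenness series as long CSV with JSON
#' headers, the brightness grid as ESRI ASCII, the ground truth as
#' CSV, and a JSON sidecar echoing the full configuration and seed.
#'
#' @param landscape A `uw_landscape` from [generate_landscape()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  stopifnot(inherits(landscape, "uw_landscape"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_series(landscape$fluxes, landscape$grid,
               file.path(dir, "fluxes.csv"),
               units = list(P = "m yr-1", N = "m yr-1 (water equivalent)",
                            E = "m yr-1"))
  write_series(landscape$greenness, landscape$grid,
               file.path(dir, "greenness.csv"),
               units = list(greenness = "NDVI-like index"))
  write_layer(landscape$nightlights, landscape$fine_grid,
              file.path(dir, "nightlights.asc"), value = "dn",
              units = "digital number 0-63")
  utils::write.csv(landscape$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg <- landscape$config
  jsonlite::write_json(
    list(n_rows = cfg$grid$n_rows, n_cols = cfg$grid$n_cols,
         lat_max = cfg$grid$lat[1], lon_min = cfg$grid$lon[1],
         spacing = cfg$grid$spacing,
         years = cfg$years, period_split_year = cfg$period_split_year,
         dryness_range = cfg$dryness_range, noise_sd = cfg$noise_sd,
         patches = cfg$patches, greenness_trend = cfg$greenness_trend,
         greenness_noise_sd = cfg$greenness_noise_sd,
         p_background_increase = cfg$p_background_increase,
         n_city_clusters = cfg$n_city_clusters, city_dn = cfg$city_dn,
         city_halfwidth = cfg$city_halfwidth,
         background_dn_max = cfg$background_dn_max,
         fine_factor = cfg$fine_factor, seed = cfg$seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
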