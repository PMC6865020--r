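#' Configure a full pipeline run
#'
#' Collects every knob of the analysis chain in one place so the
#' under-specified choices (threshold, connectivity, binning,
#' attribution axes, significance rule) are explicit, overridable and
#' echoed in the run report.
#'
#' @param scenario A [scenario_config()] (used when `input_dir` is
#'   `NULL`, and as the source of the period split).
#' @param input_dir Optional directory written by [write_landscape()];
#'   when given, inputs are read instead of generated.
#' @param attribution_mode `"diagonal"` or `"local_D"`, see
#'   [decompose_change()].
#' @param connectivity City contiguity, 4 or 8.
#' @param dn_threshold Brightness threshold for city detection.
#' @param urban_mode Coarse urban-mask mode, see [urban_coarse_mask()].
#' @param bins Density bins per axis.
#' @param out_dir Optional output directory; when given, all result
#'   tables and the JSON run report are written there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scenario = scenario_config(), input_dir = NULL,
                       attribution_mode = c("diagonal", "local_D"),
                       connectivity = 8, dn_threshold = 12,
                       urban_mode = c("resample_first", "threshold_first"),
                       bins = 50, out_dir = NULL) {
  structure(
    list(scenario = scenario, input_dir = input_dir,
         attribution_mode = match.arg(attribution_mode),
         connectivity = connectivity, dn_threshold = dn_threshold,
         urban_mode = match.arg(urban_mode), bins = bins,
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a landscape bundle from disk
#'
#' Counterpart of [write_landscape()]: rebuilds a `uw_landscape` from
#' `config.json`, `fluxes.csv`, `greenness.csv`, `nightlights.asc`
#' and `truth.csv`. A missing file aborts naming it.
#'
#' @param dir Directory containing the bundle.
#' @return A `uw_landscape` list.
#' @export
read_landscape <- function(dir) {
  need <- c("config.json", "fluxes.csv", "greenness.csv",
            "nightlights.asc", "truth.csv")
  paths <- file.path(dir, need)
  absent <- need[!file.exists(paths)]
  if (length(absent)) {
    stop("Landscape bundle incomplete; missing file(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  config <- scenario_config(
    n_rows = cfg_raw$n_rows, n_cols = cfg_raw$n_cols,
    lat_max = cfg_raw$lat_max, lon_min = cfg_raw$lon_min,
    spacing = cfg_raw$spacing, years = cfg_raw$years,
    period_split_year = cfg_raw$period_split_year,
    dryness_range = cfg_raw$dryness_range, noise_sd = cfg_raw$noise_sd,
    patches = cfg_raw$patches, greenness_trend = cfg_raw$greenness_trend,
    greenness_noise_sd = cfg_raw$greenness_noise_sd,
    p_background_increase = cfg_raw$p_background_increase,
    n_city_clusters = cfg_raw$n_city_clusters, city_dn = cfg_raw$city_dn,
    city_halfwidth = cfg_raw$city_halfwidth,
    background_dn_max = cfg_raw$background_dn_max,
    fine_factor = cfg_raw$fine_factor, seed = cfg_raw$seed)
  fluxes <- read_series(file.path(dir, "fluxes.csv"))
  greenness <- read_series(file.path(dir, "greenness.csv"))
  nl <- read_layer(file.path(dir, "nightlights.asc"))
  nl$data$dn <- as.integer(nl$data$value)
  truth <- tibble::as_tibble(utils::read.csv(file.path(dir, "truth.csv")))
  structure(
    list(config = config, grid = config$grid, fine_grid = nl$grid,
         fluxes = fluxes$data, greenness = greenness$data,
         nightlights = dplyr::select(nl$data, -"value"), truth = truth),
    class = "uw_landscape"
  )
}

#' Validate a landscape bundle before analysis
#'
#' Pure reporting: checks grid consistency, year coverage of flux and
#' greenness series, physical flux bounds and brightness bounds, and
#' returns a pass/fail table without computing anything else.
#'
#' @param landscape A `uw_landscape`.
#' @return A tibble `check`, `pass`, `detail`. Overall validity is
#'   `all(pass)`.
#' @export
validate_inputs <- function(landscape) {
  cfg <- landscape$config
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- tibble::tibble(
      check = check, pass = pass, detail = detail)
  }
  np <- cfg$grid$n_rows * cfg$grid$n_cols
  counts <- dplyr::count(landscape$fluxes, .data$year)
  add("flux_grid_complete", all(counts$n == np),
      sprintf("%d pixels expected per year", np))
  missing_years <- setdiff(cfg$years, unique(landscape$fluxes$year))
  add("flux_years_complete", length(missing_years) == 0,
      if (length(missing_years)) paste("missing:",
        paste(missing_years, collapse = ", ")) else "")
  gmiss <- setdiff(cfg$years, unique(landscape$greenness$year))
  add("greenness_years_complete", length(gmiss) == 0,
      if (length(gmiss)) paste("missing:", paste(gmiss, collapse = ", "))
      else "")
  fl <- landscape$fluxes
  add("flux_physical_bounds",
      all(fl$P > 0 & fl$N >= 0 & fl$E >= 0 & fl$E <= pmin(fl$P, fl$N)),
      "requires P > 0, N >= 0, 0 <= E <= min(P, N)")
  dn <- landscape$nightlights$dn
  dn_ok <- all(!is.na(dn) & dn >= 0 & dn <= 63 & dn == floor(dn))
  add("dn_bounds", dn_ok,
      if (!dn_ok) sprintf("out-of-range values present (range %s-%s)",
                          min(dn, na.rm = TRUE), max(dn, na.rm = TRUE))
      else "integers in [0, 63]")
  g <- landscape$greenness$greenness
  add("greenness_bounds", all(g >= -0.2 & g <= 1), "values in [-0.2, 1]")
  add("fine_grid_nested",
      landscape$fine_grid$n_rows %% cfg$grid$n_rows == 0 &&
        landscape$fine_grid$n_cols %% cfg$grid$n_cols == 0,
      "fine grid must refine the coarse grid")
  dplyr::bind_rows(checks)
}

#' Run the full state-space diagnostic pipeline
#'
#' Executes the whole chain from one configuration: landscape
#' (generated or read) -> annual states -> two-period change
#' statistics and significance mask -> greenness categories -> urban
#' detection (fine-scale cities plus coarse urban stratum) ->
#' internal/external attribution -> stratified state-space densities
#' and dryness-band masses -> JSON-serializable run report. Every
#' random draw derives from the scenario seed, so two runs with the
#' same configuration are byte-identical.
#'
#' @param config A [run_config()].
#' @return An object of class `uw_pipeline`: list with `landscape`,
#'   `annual` (annual states), `pixels` (per-pixel master table:
#'   change statistics, significance, greenness category, urban flag,
#'   attribution, climate-mean `U`/`W`, truth labels), `cities`
#'   (fine-scale city table), `summary` (stratified attribution),
#'   `densities`, `regime` (dryness-band mass per stratum),
#'   `report` (plain list), and `config`.
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(scenario_config(n_rows = 16, n_cols = 20,
#'                                                n_city_clusters = 3,
#'                                                seed = 42)))
#' glance(res)
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("Pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  land <- stage("landscape",
                if (is.null(config$input_dir)) {
                  generate_landscape(config$scenario)
                } else {
                  read_landscape(config$input_dir)
                })
  cfg <- land$config
  periods <- period_pair(cfg$years[cfg$years < cfg$period_split_year],
                         cfg$years[cfg$years >= cfg$period_split_year])
  checks <- stage("validate", validate_inputs(land))
  if (!all(checks$pass)) {
    stop("Input validation failed: ",
         paste(checks$check[!checks$pass], collapse = ", "), call. = FALSE)
  }
  annual <- stage("annual_states", annual_states(land$fluxes, cfg$years))
  stats <- stage("change_stats",
                 significant_change_mask(change_stats(annual, periods)))
  green <- stage("greenness_masks", greenness_masks(land$greenness, periods))
  urb <- stage("urban_mask",
               urban_coarse_mask(land$nightlights, land$fine_grid, land$grid,
                                 config$dn_threshold, config$urban_mode))
  cities <- stage("cities", {
    lit <- lighted_mask(land$nightlights, config$dn_threshold)
    lab <- label_cities(lit, land$fine_grid, config$connectivity)
    city_table(lab, land$fine_grid)
  })
  attributed <- stage("attribution",
                      attribute_changes(stats, config$attribution_mode))
  clim <- annual |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(U = mean(.data$U), W = mean(.data$W), .groups = "drop")
  pixels <- attributed |>
    dplyr::left_join(dplyr::select(green, "row", "col",
                                   "greenness_category"),
                     by = c("row", "col")) |>
    dplyr::left_join(dplyr::select(urb, "row", "col", "urban"),
                     by = c("row", "col")) |>
    dplyr::left_join(clim, by = c("row", "col")) |>
    dplyr::left_join(
      dplyr::select(land$truth, "row", "col", "label",
                    dplyr::any_of(c("greenness_trend_sign", "city"))),
      by = c("row", "col"))
  summary_tbl <- stage("summary", attribution_summary(
    attributed,
    dplyr::select(pixels, "row", "col", "significant", "urban",
                  "greenness_category")))
  dens <- stage("densities", stratified_densities(pixels, config$bins))
  regime <- dens |>
    dplyr::filter(.data$greenness_category == "all") |>
    dplyr::mutate(mass = purrr::map(.data$density, regime_mass)) |>
    dplyr::select("stratum", "mass") |>
    tidyr::unnest("mass")
  report <- stage("report", build_report(config, land, periods, pixels,
                                         summary_tbl, cities))
  res <- structure(
    list(landscape = land, annual = annual, pixels = pixels,
         cities = cities, summary = summary_tbl, densities = dens,
         regime = regime, checks = checks, report = report,
         config = config),
    class = "uw_pipeline"
  )
  if (!is.null(config$out_dir)) write_pipeline(res, config$out_dir)
  res
}

build_report <- function(config, land, periods, pixels, summary_tbl,
                         cities) {
  cfg <- land$config
  n_pix <- nrow(pixels)
  n_valid <- sum(pixels$valid)
  n_sig <- sum(pixels$significant, na.rm = TRUE)
  n_urb <- sum(pixels$urban, na.rm = TRUE)
  dom <- function(sel) {
    sub <- pixels[sel & pixels$valid & !is.na(pixels$dominant_cause), ]
    if (nrow(sub) == 0) return(list(internal = NA, external = NA, tie = NA))
    tab <- table(sub$dominant_cause) / nrow(sub)
    list(internal = unname(tab["internal"]), external = unname(tab["external"]),
         tie = unname(tab["tie"]))
  }
  quad_frac <- summary_tbl[summary_tbl$stratum == "all" &
                             summary_tbl$greenness_category == "all" &
                             summary_tbl$quadrant != "no_change", ]
  list(
    package_version = as.character(utils::packageVersion("hydrostate")),
    seed = cfg$seed,
    config = list(
      n_rows = cfg$grid$n_rows, n_cols = cfg$grid$n_cols,
      years = range(cfg$years), period_split_year = cfg$period_split_year,
      noise_sd = cfg$noise_sd, dn_threshold = config$dn_threshold,
      connectivity = config$connectivity, bins = config$bins,
      attribution_mode = config$attribution_mode,
      urban_mode = config$urban_mode,
      significance_rule = "abs(dU) > std_U OR abs(dW) > std_W (strict)"
    ),
    counts = list(
      n_pixels = n_pix, n_valid = n_valid,
      n_significant = n_sig, n_urban = n_urb,
      n_cities = nrow(cities),
      significant_fraction = n_sig / n_valid,
      urban_fraction = n_urb / n_valid
    ),
    greenness = list(
      increase_fraction = mean(pixels$greenness_category == "increase",
                               na.rm = TRUE),
      decrease_fraction = mean(pixels$greenness_category == "decrease",
                               na.rm = TRUE)
    ),
    dominant_cause = list(
      all = dom(rep(TRUE, n_pix)),
      significant = dom(!is.na(pixels$significant) & pixels$significant),
      urban = dom(!is.na(pixels$urban) & pixels$urban)
    ),
    quadrant_fractions = stats::setNames(
      as.list(quad_frac$fraction), quad_frac$quadrant),
    total_city_area_km2 = sum(cities$size_km2)
  )
}

write_pipeline <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(res$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(res$summary, file.path(dir, "attribution_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(res$pixels, file.path(dir, "pixels.csv"),
                   row.names = FALSE)
  utils::write.csv(res$cities, file.path(dir, "cities.csv"),
                   row.names = FALSE)
  utils::write.csv(res$regime, file.path(dir, "regime_mass.csv"),
                   row.names = FALSE)
  for (i in seq_len(nrow(res$densities))) {
    d <- res$densities$density[[i]]
    name <- gsub("/", "_", d$stratum)
    utils::write.csv(d$counts,
                     file.path(dir, sprintf("density_%s.csv", name)),
                     row.names = FALSE)
    jsonlite::write_json(
      list(stratum = d$stratum, total = d$total, overflow = d$overflow,
           u_edges = d$u_edges, w_edges = d$w_edges),
      file.path(dir, sprintf("density_%s.json", name)),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @export
print.uw_pipeline <- function(x, ...) {
  r <- x$report
  cat(sprintf("<uw_pipeline> %d pixels (%d valid): %.1f%% significant change, %.1f%% urban, %d cities\n",
              r$counts$n_pixels, r$counts$n_valid,
              100 * r$counts$significant_fraction,
              100 * r$counts$urban_fraction, r$counts$n_cities))
  cat(sprintf("  greenness: %.1f%% increase / %.1f%% decrease; external-dominant (all): %.1f%%\n",
              100 * r$greenness$increase_fraction,
              100 * r$greenness$decrease_fraction,
              100 * r$dominant_cause$all$external))
  invisible(x)
}
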