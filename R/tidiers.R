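#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pipeline result
#'
#' Returns the stratified attribution summary as a tibble, one row
#' per stratum by greenness category by quadrant.
#'
#' @param x A `uw_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble (see [attribution_summary()]).
#' @export
tidy.uw_pipeline <- function(x, ...) {
  x$summary
}

#' One-row summary of a pipeline result
#'
#' @param x A `uw_pipeline`.
#' @param ... Unused.
#' @return A one-row tibble with the headline quantities: pixel and
#'   stratum counts, significant/urban fractions, greenness split,
#'   and external-dominance fractions per stratum.
#' @export
glance.uw_pipeline <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_pixels = r$counts$n_pixels,
    n_valid = r$counts$n_valid,
    n_significant = r$counts$n_significant,
    n_urban = r$counts$n_urban,
    n_cities = r$counts$n_cities,
    significant_fraction = r$counts$significant_fraction,
    urban_fraction = r$counts$urban_fraction,
    greenness_increase_fraction = r$greenness$increase_fraction,
    greenness_decrease_fraction = r$greenness$decrease_fraction,
    external_fraction_all = r$dominant_cause$all$external,
    external_fraction_significant = r$dominant_cause$significant$external,
    external_fraction_urban = r$dominant_cause$urban$external,
    total_city_area_km2 = r$total_city_area_km2
  )
}

#' Tidy a state-space density
#'
#' @param x A `uw_density` from [state_density()].
#' @param ... Unused.
#' @return A long tibble with one row per bin: `u_mid`, `w_mid`,
#'   `count`, plus the stratum label.
#' @export
tidy.uw_density <- function(x, ...) {
  bins_u <- nrow(x$counts)
  bins_w <- ncol(x$counts)
  uc <- (x$u_edges[-1] + x$u_edges[-(bins_u + 1)]) / 2
  wc <- (x$w_edges[-1] + x$w_edges[-(bins_w + 1)]) / 2
  tibble::tibble(
    u_mid = rep(uc, times = bins_w),
    w_mid = rep(wc, each = bins_u),
    count = as.vector(x$counts),
    stratum = x$stratum
  )
}
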