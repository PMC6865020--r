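#' Threshold a brightness grid into a lighted mask
#'
#' Nighttime stable-light digital numbers (DN, integers 0-63) are
#' thresholded at `DN >= threshold`; the default 12 suppresses
#' overglow around bright centers. Values outside `[0, 63]` are
#' rejected as invalid input.
#'
#' @param data Tibble with `row`, `col`, `dn`.
#' @param threshold Brightness threshold (default 12).
#' @return The input with a logical `lighted` column appended.
#' @export
lighted_mask <- function(data, threshold = 12) {
  stopifnot("dn" %in% names(data))
  dn <- data$dn
  if (any(!is.na(dn) & (dn < 0 | dn > 63 | dn != floor(dn)))) {
    stop("`dn` must be integer digital numbers in [0, 63].", call. = FALSE)
  }
  dplyr::mutate(data, lighted = !is.na(dn) & dn >= threshold)
}

# queue-based flood fill on a logical matrix; labels assigned in
# row-major order of each region's first-encountered pixel
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  }
  next_label <- 0L
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (!mask[r0, c0] || lab[r0, c0] != 0L) next
      next_label <- next_label + 1L
      queue <- matrix(c(r0, c0), 1, 2)
      lab[r0, c0] <- next_label
      while (nrow(queue) > 0) {
        r <- queue[1, 1]; c <- queue[1, 2]
        queue <- queue[-1, , drop = FALSE]
        for (k in seq_along(dr)) {
          rr <- r + dr[k]; cc <- c + dc[k]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- next_label
            queue <- rbind(queue, c(rr, cc))
          }
        }
      }
    }
  }
  lab
}

#' Label contiguous lighted regions as cities
#'
#' Groups lighted pixels into spatially contiguous regions
#' ("cities"). Contiguity defaults to 8-connectivity (diagonal
#' neighbors merge — the conservative reading of "spatially
#' contiguous"); 4-connectivity is available. City ids are
#' deterministic: numbered by each region's first pixel in a
#' row-major scan.
#'
#' @param data Tibble with `row`, `col` and logical `lighted` (from
#'   [lighted_mask()]).
#' @param grid The [grid_spec()] the mask lives on.
#' @param connectivity 4 or 8 (default 8).
#' @return The input with an integer `city_id` column (`NA` off-mask).
#' @export
label_cities <- function(data, grid, connectivity = 8) {
  stopifnot("lighted" %in% names(data), inherits(grid, "grid_spec"))
  m <- layer_to_matrix(dplyr::mutate(data, value = as.numeric(.data$lighted)),
                       grid) == 1
  m[is.na(m)] <- FALSE
  lab <- label_components(m, connectivity)
  out <- dplyr::left_join(
    data,
    matrix_to_layer(lab, grid, value = "city_id")[c("row", "col", "city_id")],
    by = c("row", "col"))
  out$city_id <- ifelse(out$city_id == 0, NA_integer_,
                        as.integer(out$city_id))
  out
}

#' Per-city summary with latitude-weighted sizes
#'
#' City size is the sum of member-pixel spherical areas,
#' `size(j) = sum_i a_i(j)` in km2, so sizes are additive over
#' disjoint cities and their total equals the total lighted area.
#'
#' @param labeled Tibble from [label_cities()].
#' @param grid The [grid_spec()] (used for pixel areas).
#' @return A tibble per city: `city_id`, `n_pixels`, `size_km2`,
#'   `row_min`, `row_max`, `col_min`, `col_max`.
#' @export
city_table <- function(labeled, grid) {
  stopifnot("city_id" %in% names(labeled))
  areas <- pixel_area(grid)[c("row", "col", "area_km2")]
  labeled |>
    dplyr::filter(!is.na(.data$city_id)) |>
    dplyr::left_join(areas, by = c("row", "col")) |>
    dplyr::group_by(.data$city_id) |>
    dplyr::summarise(
      n_pixels = dplyr::n(),
      size_km2 = sum(.data$area_km2),
      row_min = min(.data$row), row_max = max(.data$row),
      col_min = min(.data$col), col_max = max(.data$col),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$city_id)
}

#' Urban mask on the coarse analysis grid
#'
#' Brings the fine brightness grid onto the coarse analysis grid and
#' marks urban cells. The default follows the
#' resample-everything-first convention of reanalysis-based analyses:
#' the DN field is bilinearly resampled to the coarse pixel centers
#' and then thresholded at `DN >= threshold`. The alternative
#' `"threshold_first"` mode thresholds at fine scale and marks a
#' coarse cell urban when at least half of its fine pixels are
#' lighted.
#'
#' @param data Fine tibble `row`, `col`, `dn`.
#' @param fine_grid,coarse_grid Source and destination [grid_spec()]s.
#' @param threshold DN threshold (default 12).
#' @param mode `"resample_first"` (default) or `"threshold_first"`.
#' @return Coarse tibble `row`, `col`, `lat`, `lon`, `dn_coarse`,
#'   logical `urban`.
#' @export
urban_coarse_mask <- function(data, fine_grid, coarse_grid, threshold = 12,
                              mode = c("resample_first", "threshold_first")) {
  mode <- match.arg(mode)
  stopifnot("dn" %in% names(data))
  if (mode == "resample_first") {
    res <- bilinear_resample(dplyr::mutate(data, value = as.numeric(.data$dn)),
                             fine_grid, coarse_grid)
    res$dn_coarse <- res$value
    res$urban <- !is.na(res$value) & res$value >= threshold
    dplyr::select(res, "row", "col", "lat", "lon", "dn_coarse", "urban")
  } else {
    f <- fine_grid$n_rows / coarse_grid$n_rows
    if (f != round(f) || fine_grid$n_cols / coarse_grid$n_cols != f) {
      stop("threshold_first mode needs the fine grid to nest the coarse grid ",
           "by an integer factor.", call. = FALSE)
    }
    agg <- data |>
      dplyr::mutate(crow = (.data$row - 1) %/% f + 1,
                    ccol = (.data$col - 1) %/% f + 1) |>
      dplyr::group_by(row = .data$crow, col = .data$ccol) |>
      dplyr::summarise(dn_coarse = mean(.data$dn),
                       lighted_frac = mean(.data$dn >= threshold),
                       .groups = "drop")
    out <- dplyr::left_join(grid_pixels(coarse_grid), agg,
                            by = c("row", "col"))
    out$urban <- !is.na(out$lighted_frac) & out$lighted_frac >= 0.5
    dplyr::select(out, "row", "col", "lat", "lon", "dn_coarse", "urban")
  }
}
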