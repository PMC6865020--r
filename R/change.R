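#' Define the two averaging periods
#'
#' @param period1,period2 Integer year vectors; non-overlapping, each
#'   with at least 2 years. Defaults are 1982-1998 and 1999-2015, a
#'   split suggested by the late-1990s change in the warming tendency.
#' @return A list of class `period_pair`.
#' @export
period_pair <- function(period1 = 1982:1998, period2 = 1999:2015) {
  if (length(period1) < 2 || length(period2) < 2) {
    stop("Each period needs at least 2 years.", call. = FALSE)
  }
  if (length(intersect(period1, period2))) {
    stop("Periods must not overlap.", call. = FALSE)
  }
  structure(list(period1 = as.integer(period1),
                 period2 = as.integer(period2)),
            class = "period_pair")
}

#' @export
print.period_pair <- function(x, ...) {
  cat(sprintf("<period_pair> %d-%d vs %d-%d\n",
              min(x$period1), max(x$period1), min(x$period2), max(x$period2)))
  invisible(x)
}

#' Annual (U, W) states from a flux series
#'
#' Applies the state equations year by year. Every requested year must
#' be present for every pixel; gaps abort with the missing years
#' listed.
#'
#' @param fluxes Long tibble `year`, `row`, `col`, `P`, `N`, `E`.
#' @param years Years that must be covered (default: all years
#'   present).
#' @return The input with `U`, `W`, `D`, `valid` columns appended.
#' @export
annual_states <- function(fluxes, years = NULL) {
  stopifnot(all(c("year", "row", "col", "P", "N", "E") %in% names(fluxes)))
  if (!is.null(years)) {
    missing_years <- setdiff(years, unique(fluxes$year))
    if (length(missing_years)) {
      stop("Flux series has gaps; missing year(s): ",
           paste(missing_years, collapse = ", "), call. = FALSE)
    }
  }
  counts <- dplyr::count(fluxes, .data$year)
  if (length(unique(counts$n)) > 1) {
    stop("Flux series is ragged: years cover different pixel sets.",
         call. = FALSE)
  }
  compute_states(fluxes)
}

#' Two-period change statistics per pixel
#'
#' For every pixel, computes the period means of `U` and `W`, the
#' displacement `dU = U2 - U1`, `dW = W2 - W1`, and the interannual
#' variability `std_U`, `std_W` as the population standard deviation
#' (divide by n) of the annual values pooled over the whole record —
#' the spread about the full-record mean against which a period-mean
#' shift is judged. Period dryness `D1`, `D2` is recomputed from the
#' period-mean states (not averaged over annual `D`, which differs).
#'
#' A pixel is `valid` only if its annual states are valid in every
#' year of both periods.
#'
#' @param states Annual state tibble from [annual_states()].
#' @param periods A [period_pair()].
#' @return A tibble with one row per pixel: `row`, `col`, `lat`,
#'   `lon` (if present), `U1`, `W1`, `U2`, `W2`, `D1`, `D2`, `dU`,
#'   `dW`, `std_U`, `std_W`, `valid`.
#' @export
change_stats <- function(states, periods = period_pair()) {
  stopifnot(inherits(periods, "period_pair"))
  all_years <- c(periods$period1, periods$period2)
  missing_years <- setdiff(all_years, unique(states$year))
  if (length(missing_years)) {
    stop("State series misses period year(s): ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  df <- dplyr::filter(states, .data$year %in% all_years)
  df$in_p2 <- df$year %in% periods$period2
  keys <- intersect(c("row", "col", "lat", "lon"), names(df))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      U1 = mean(.data$U[!.data$in_p2]),
      W1 = mean(.data$W[!.data$in_p2]),
      U2 = mean(.data$U[.data$in_p2]),
      W2 = mean(.data$W[.data$in_p2]),
      std_U = pop_sd(.data$U),
      std_W = pop_sd(.data$W),
      valid = all(.data$valid),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      D1 = dryness(.data$U1, .data$W1),
      D2 = dryness(.data$U2, .data$W2),
      dU = .data$U2 - .data$U1,
      dW = .data$W2 - .data$W1
    )
  dplyr::select(out, dplyr::all_of(keys), "U1", "W1", "U2", "W2",
                "D1", "D2", "dU", "dW", "std_U", "std_W", "valid")
}

#' Significant-change mask from interannual variability
#'
#' A pixel shows significant state change when either period-mean
#' shift exceeds the corresponding interannual standard deviation:
#' `|dU| > std_U` OR `|dW| > std_W`, with strict inequality so that
#' degenerate constant pixels (`std = 0`, `d = 0`) are never
#' significant. Invalid pixels are never significant.
#'
#' @param stats Per-pixel tibble from [change_stats()].
#' @return The input with a logical `significant` column appended.
#' @export
significant_change_mask <- function(stats) {
  stopifnot(all(c("dU", "dW", "std_U", "std_W") %in% names(stats)))
  dplyr::mutate(
    stats,
    significant = .data$valid &
      (abs(.data$dU) > .data$std_U | abs(.data$dW) > .data$std_W)
  )
}

#' Greenness increase/decrease masks from period means
#'
#' Compares per-pixel mean greenness between the two periods:
#' `increase` where the period-2 mean is strictly greater,
#' `decrease` where strictly smaller; exact ties belong to neither
#' (category `"tie"`). The two masks are disjoint by construction.
#'
#' @param greenness Long tibble `year`, `row`, `col`, `greenness`.
#' @param periods A [period_pair()].
#' @return A tibble per pixel: `row`, `col`, `g1`, `g2`,
#'   `greenness_category` (factor increase/decrease/tie), and logical
#'   `increase`, `decrease`.
#' @export
greenness_masks <- function(greenness, periods = period_pair()) {
  stopifnot(inherits(periods, "period_pair"))
  all_years <- c(periods$period1, periods$period2)
  missing_years <- setdiff(all_years, unique(greenness$year))
  if (length(missing_years)) {
    stop("Greenness series misses period year(s): ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  df <- dplyr::filter(greenness, .data$year %in% all_years)
  df$in_p2 <- df$year %in% periods$period2
  out <- df |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(
      g1 = mean(.data$greenness[!.data$in_p2]),
      g2 = mean(.data$greenness[.data$in_p2]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      greenness_category = factor(
        dplyr::case_when(
          .data$g2 > .data$g1 ~ "increase",
          .data$g2 < .data$g1 ~ "decrease",
          TRUE ~ "tie"
        ),
        levels = c("increase", "decrease", "tie")
      ),
      increase = .data$greenness_category == "increase",
      decrease = .data$greenness_category == "decrease"
    )
  out
}
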