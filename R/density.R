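#' Frequency distribution of pixels in (U, W) space
#'
#' Histograms the masked pixels' state coordinates on a regular
#' `bins x bins` grid over the unit square, left-closed bins
#' (`[0, 1/bins), ...`), with values exactly equal to 1 counted in
#' the top bin. Pixels with finite states outside `[0, 1]^2` are
#' counted in an explicit `overflow` bucket, never silently dropped,
#' so total mass is conserved:
#' `sum(counts) + overflow = number of masked pixels with finite
#' states`.
#'
#' @param states Per-pixel tibble with `U` and `W` columns (e.g.
#'   period or climate means).
#' @param mask Optional logical vector (length `nrow(states)`) or
#'   column name selecting the stratum; `NULL` uses all pixels.
#' @param bins Number of bins per axis (default 50).
#' @param stratum Label stored with the result.
#' @return An object of class `uw_density`: list with `counts`
#'   (matrix, rows = U bins, cols = W bins, bin 1 at 0), `u_edges`,
#'   `w_edges`, `overflow`, `total`, `stratum`.
#' @examples
#' d <- state_density(tibble::tibble(U = 0.5, W = 0.5), bins = 50)
#' which(d$counts == 1, arr.ind = TRUE)  # bin (26, 26), 1-based
#' @export
state_density <- function(states, mask = NULL, bins = 50,
                          stratum = "all") {
  stopifnot(all(c("U", "W") %in% names(states)))
  if (is.character(mask)) mask <- states[[mask]]
  if (is.null(mask)) mask <- rep(TRUE, nrow(states))
  sub <- states[mask & is.finite(states$U) & is.finite(states$W), ]
  edges <- seq(0, 1, length.out = bins + 1)
  counts <- matrix(0L, bins, bins)
  inside <- sub$U >= 0 & sub$U <= 1 & sub$W >= 0 & sub$W <= 1
  ui <- pmin(floor(sub$U[inside] * bins), bins - 1) + 1L
  wi <- pmin(floor(sub$W[inside] * bins), bins - 1) + 1L
  for (k in seq_along(ui)) {
    counts[ui[k], wi[k]] <- counts[ui[k], wi[k]] + 1L
  }
  structure(
    list(counts = counts, u_edges = edges, w_edges = edges,
         overflow = sum(!inside), total = nrow(sub), stratum = stratum),
    class = "uw_density"
  )
}

#' @export
print.uw_density <- function(x, ...) {
  cat(sprintf("<uw_density> stratum '%s': %d pixels (%d overflow), %d x %d bins\n",
              x$stratum, x$total, x$overflow, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Densities for all strata and greenness categories
#'
#' Builds the 3 x 3 family of state-space frequency distributions:
#' land-surface strata (all valid pixels, significant-change pixels,
#' urban pixels) crossed with greenness categories (all, increase,
#' decrease). Strata are nested (significant and urban are subsets of
#' all) and each stratum's increase + decrease + tie counts equal its
#' total.
#'
#' @param states Per-pixel tibble with `U`, `W`, `valid`, joined with
#'   `significant`, `urban`, `greenness_category` columns.
#' @param bins Bins per axis.
#' @return A tibble with columns `stratum`, `greenness_category` and
#'   a list-column `density` of [state_density()] objects.
#' @export
stratified_densities <- function(states, bins = 50) {
  need <- c("U", "W", "valid", "significant", "urban", "greenness_category")
  stopifnot(all(need %in% names(states)))
  strata <- list(
    all = states$valid,
    significant = states$valid & states$significant,
    urban = states$valid & states$urban
  )
  cats <- list(
    all = rep(TRUE, nrow(states)),
    increase = states$greenness_category == "increase",
    decrease = states$greenness_category == "decrease"
  )
  out <- tidyr::crossing(stratum = names(strata),
                         greenness_category = names(cats))
  out$density <- purrr::map2(out$stratum, out$greenness_category, function(s, g) {
    state_density(states, strata[[s]] & cats[[g]], bins,
                  stratum = paste(s, g, sep = "/"))
  })
  out[order(match(out$stratum, names(strata)),
            match(out$greenness_category, names(cats))), ]
}

DRYNESS_BANDS <- c(0, 1 / 3, 1, 2, 3, Inf)
DRYNESS_BAND_LABELS <- c("D<1/3", "1/3-1", "1-2", "2-3", "D>3")

#' Histogram mass per dryness band
#'
#' Assigns each occupied (U, W) bin to a dryness band by its bin
#' center, `D = (1 - Wc)/(1 - Uc)`, bands closed on the left
#' (`D < 1/3`, `1/3 <= D < 1`, `1 <= D < 2`, `2 <= D < 3`,
#' `D >= 3`) — a deterministic, refinement-stable rule. With bins
#' strictly inside the unit square, bin centers never reach `U = 1`,
#' so every bin classifies.
#'
#' @param density A [state_density()] result.
#' @return A tibble `band`, `n`, `fraction` (fractions over
#'   classified mass).
#' @export
regime_mass <- function(density) {
  stopifnot(inherits(density, "uw_density"))
  bins_u <- nrow(density$counts)
  bins_w <- ncol(density$counts)
  uc <- (density$u_edges[-1] + density$u_edges[-(bins_u + 1)]) / 2
  wc <- (density$w_edges[-1] + density$w_edges[-(bins_w + 1)]) / 2
  d_center <- outer(uc, wc, function(u, w) (1 - w) / (1 - u))
  band <- cut(as.vector(d_center), DRYNESS_BANDS,
              labels = DRYNESS_BAND_LABELS, right = FALSE,
              include.lowest = TRUE)
  counts_by_band <- tapply(as.vector(density$counts), band, sum,
                           default = 0L)[DRYNESS_BAND_LABELS]
  total <- sum(counts_by_band)
  tibble::tibble(
    band = factor(DRYNESS_BAND_LABELS, levels = DRYNESS_BAND_LABELS),
    n = as.integer(counts_by_band),
    fraction = if (total > 0) as.numeric(counts_by_band) / total
               else rep(NA_real_, length(DRYNESS_BAND_LABELS))
  )
}

#' Mean distance of a stratum's states to the Schreiber curve
#'
#' For each masked pixel, the shortest distance in (U, W) space from
#' its state to the balanced-state curve `U = 1 + (1 - W)/ln(W)`,
#' found numerically; the sign is positive above the curve (state U
#' greater than the balanced U at the nearest point). Summarizes how
#' far a stratum sits from flux-closure balance.
#'
#' @param states Tibble with `U`, `W`.
#' @param mask Optional logical selector.
#' @return A one-row tibble `n`, `mean_distance`,
#'   `mean_signed_offset` (mean of `U - U_curve(W)`).
#' @export
curve_distance <- function(states, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(states))
  sub <- states[mask & is.finite(states$U) & is.finite(states$W), ]
  if (nrow(sub) == 0) {
    return(tibble::tibble(n = 0L, mean_distance = NA_real_,
                          mean_signed_offset = NA_real_))
  }
  wgrid <- seq(1e-6, 1 - 1e-6, length.out = 512)
  ugrid <- schreiber_curve_u(wgrid)
  dmin <- vapply(seq_len(nrow(sub)), function(i) {
    min(sqrt((sub$W[i] - wgrid)^2 + (sub$U[i] - ugrid)^2))
  }, 0)
  offset <- sub$U - schreiber_curve_u(pmin(pmax(sub$W, 0), 1))
  tibble::tibble(n = nrow(sub), mean_distance = mean(dmin),
                 mean_signed_offset = mean(offset))
}
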