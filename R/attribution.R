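#' Displacement between two state points
#'
#' @param U1,W1,U2,W2 State coordinates of the first and second
#'   period. Vectorized.
#' @return A tibble with `dW`, `dU` (`NA` where an endpoint is `NA`).
#' @export
displacement <- function(U1, W1, U2, W2) {
  tibble::tibble(dW = W2 - W1, dU = U2 - U1)
}

#' Decompose a state displacement into internal and external parts
#'
#' In (U, W) space, anthropogenic (internal) change of the flux
#' partitioning moves a state along the positive diagonal — a change
#' `dE` at fixed forcing gives `dU = -dE/N` and `dW = -dE/P`, equal
#' signs — while climate (external) change of the forcing at fixed
#' `E` moves it along the negative diagonal (the aridity axis). The
#' displacement is therefore projected onto an orthonormal pair of
#' axes:
#'
#' * `mode = "diagonal"` (default): the fixed +/-45-degree diagonals
#'   (the direction of the `D = 1` line), giving
#'   `c_int = (dU + dW)/sqrt(2)` (positive toward (1,1)) and
#'   `c_ext = (dU - dW)/sqrt(2)` (positive toward drying).
#' * `mode = "local_D"`: the internal axis is the unit vector of the
#'   constant-dryness line through the origin point `(U1, W1)` toward
#'   `(1, 1)`; the external axis is its perpendicular, oriented so
#'   that drying (`dU > 0`, `dW < 0`) is positive. The two modes
#'   coincide exactly where `D(U1, W1) = 1`.
#'
#' Both modes are orthonormal, so
#' `c_int^2 + c_ext^2 = dU^2 + dW^2` holds identically.
#'
#' @param data Tibble with columns `dW`, `dU` (and `U1`, `W1` for
#'   `mode = "local_D"`).
#' @param mode `"diagonal"` or `"local_D"`.
#' @return The input with `c_int`, `c_ext` and `dominant_cause`
#'   (factor internal/external/tie; a zero displacement is a tie with
#'   zero components) appended.
#' @examples
#' decompose_change(tibble::tibble(dW = -0.1, dU = 0.1))  # pure external
#' @export
decompose_change <- function(data, mode = c("diagonal", "local_D")) {
  mode <- match.arg(mode)
  stopifnot(all(c("dW", "dU") %in% names(data)))
  if (mode == "diagonal") {
    a <- rep(1 / sqrt(2), nrow(data))
    b <- a
  } else {
    stopifnot(all(c("U1", "W1") %in% names(data)))
    # internal axis along the constant-D ray from (W1, U1) to (1, 1)
    dw1 <- 1 - data$W1
    du1 <- 1 - data$U1
    len <- sqrt(dw1^2 + du1^2)
    a <- dw1 / len   # dW-component of the internal unit vector
    b <- du1 / len   # dU-component
  }
  c_int <- a * data$dW + b * data$dU
  c_ext <- -b * data$dW + a * data$dU  # positive toward drying (dU>0, dW<0)
  dominant <- factor(
    dplyr::case_when(
      abs(c_int) > abs(c_ext) ~ "internal",
      abs(c_int) < abs(c_ext) ~ "external",
      TRUE ~ "tie"
    ),
    levels = c("internal", "external", "tie")
  )
  dplyr::mutate(data, c_int = c_int, c_ext = c_ext,
                dominant_cause = dominant)
}

QUADRANT_LEVELS <- c("Q1_pink", "Q2_yellow", "Q3_lightblue", "Q4_darkblue",
                     "no_change")

#' Classify a displacement into attribution quadrants
#'
#' The four quadrants of the displacement plane carry the standard
#' color semantics:
#' * `Q1_pink` (`dW > 0, dU > 0`): internal, reduced evapotranspiration
#'   (`dE < 0`, deforestation-like);
#' * `Q2_yellow` (`dW < 0, dU > 0`): external, increasing aridity;
#' * `Q3_lightblue` (`dW < 0, dU < 0`): internal, increased
#'   evapotranspiration (`dE > 0`, afforestation-like);
#' * `Q4_darkblue` (`dW > 0, dU < 0`): external, decreasing aridity.
#'
#' Axis-aligned displacements follow a fixed deterministic rule:
#' `dW = 0` goes to the external quadrant matching `sign(dU)` (such a
#' displacement is purely external), and `dU = 0` to the internal
#' quadrant matching `sign(dW)`. An exactly zero displacement is
#' `no_change`.
#'
#' @param dW,dU Displacement components. Vectorized.
#' @return A factor with levels `Q1_pink`, `Q2_yellow`,
#'   `Q3_lightblue`, `Q4_darkblue`, `no_change`.
#' @export
quadrant_class <- function(dW, dU) {
  q <- dplyr::case_when(
    is.na(dW) | is.na(dU) ~ NA_character_,
    dW == 0 & dU == 0 ~ "no_change",
    dW == 0 ~ ifelse(dU > 0, "Q2_yellow", "Q4_darkblue"),
    dU == 0 ~ ifelse(dW > 0, "Q1_pink", "Q3_lightblue"),
    dW > 0 & dU > 0 ~ "Q1_pink",
    dW < 0 & dU > 0 ~ "Q2_yellow",
    dW < 0 & dU < 0 ~ "Q3_lightblue",
    TRUE ~ "Q4_darkblue"
  )
  factor(q, levels = QUADRANT_LEVELS)
}

#' Per-pixel change attribution
#'
#' Convenience wrapper: takes the per-pixel change statistics and
#' appends the attribution columns (`c_int`, `c_ext`,
#' `dominant_cause`, `quadrant`). Invalid pixels get `NA` attribution.
#'
#' @param stats Tibble from [change_stats()] (or any tibble with
#'   `dW`, `dU`, and `U1`, `W1` for the local mode).
#' @param mode Attribution axes, see [decompose_change()].
#' @return The input with attribution columns appended.
#' @export
attribute_changes <- function(stats, mode = c("diagonal", "local_D")) {
  mode <- match.arg(mode)
  out <- decompose_change(stats, mode)
  out$quadrant <- quadrant_class(out$dW, out$dU)
  if ("valid" %in% names(out)) {
    bad <- !out$valid
    out$c_int[bad] <- NA_real_
    out$c_ext[bad] <- NA_real_
    out$dominant_cause[bad] <- NA
    out$quadrant[bad] <- NA
  }
  out
}

#' Stratified attribution summary
#'
#' Cross-tabulates quadrant membership and dominant cause over the
#' land-surface strata (`all`, `significant`, `urban`) and greenness
#' categories (`all`, `increase`, `decrease`). Within each stratum by
#' category cell, quadrant fractions are computed over the four
#' directional quadrants (zero-displacement pixels sit in their own
#' `no_change` bin with an `NA` fraction), and the dominant-cause
#' fractions (`internal_fraction`, `external_fraction`,
#' `tie_fraction`) are computed over all attributed pixels, so they
#' sum to one. Empty cells are reported with `n_total = 0` and `NA`
#' fractions rather than dropped.
#'
#' @param attributed Per-pixel tibble from [attribute_changes()].
#' @param masks Per-pixel tibble with `row`, `col`, logical
#'   `significant` and `urban`, and `greenness_category`
#'   (increase/decrease/tie), as assembled by [run_pipeline()] or by
#'   joining [significant_change_mask()], [urban_coarse_mask()] and
#'   [greenness_masks()] output.
#' @return A tibble with columns `stratum`, `greenness_category`,
#'   `quadrant`, `n_pixels`, `fraction`, `n_total`,
#'   `internal_fraction`, `external_fraction`, `tie_fraction`.
#' @export
attribution_summary <- function(attributed, masks) {
  df <- dplyr::inner_join(attributed, masks, by = c("row", "col"),
                          suffix = c("", ".mask"))
  df <- dplyr::filter(df, .data$valid, !is.na(.data$quadrant))
  strata <- list(
    all = rep(TRUE, nrow(df)),
    significant = df$significant,
    urban = df$urban
  )
  cats <- list(
    all = rep(TRUE, nrow(df)),
    increase = df$greenness_category == "increase",
    decrease = df$greenness_category == "decrease"
  )
  rows <- list()
  for (s in names(strata)) {
    for (g in names(cats)) {
      sel <- strata[[s]] & cats[[g]]
      sub <- df[sel, ]
      n_total <- nrow(sub)
      n_quad <- table(factor(sub$quadrant, levels = QUADRANT_LEVELS))
      n_dir <- sum(n_quad[setdiff(QUADRANT_LEVELS, "no_change")])
      n_dom <- table(factor(sub$dominant_cause,
                            levels = c("internal", "external", "tie")))
      for (q in QUADRANT_LEVELS) {
        frac <- if (q == "no_change" || n_dir == 0) NA_real_ else
          unname(n_quad[q]) / n_dir
        rows[[length(rows) + 1L]] <- tibble::tibble(
          stratum = s, greenness_category = g, quadrant = q,
          n_pixels = as.integer(n_quad[q]), fraction = frac,
          n_total = n_total,
          internal_fraction = if (n_total) unname(n_dom["internal"]) / n_total else NA_real_,
          external_fraction = if (n_total) unname(n_dom["external"]) / n_total else NA_real_,
          tie_fraction = if (n_total) unname(n_dom["tie"]) / n_total else NA_real_
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
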