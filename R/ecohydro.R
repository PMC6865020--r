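#' Ecohydrological state equations
#'
#' The state space is spanned by two dimensionless flux ratios computed
#' from annual precipitation `P`, net radiation `N` (in water-flux
#' equivalents, m/yr) and evapotranspiration `E`:
#'
#' * relative excess energy `U = H/N = 1 - E/N` (energy not used by
#'   evapotranspiration, available for sensible heating), and
#' * relative excess water `W = Ro/P = 1 - E/P` (water not used by
#'   evapotranspiration, available as runoff).
#'
#' The dryness index `D = N/P = (1 - W)/(1 - U)` separates
#' energy-limited (`D < 1`) from water-limited (`D > 1`) regimes.
#' Physically balanced states lie on the Schreiber curve
#' `U = 1 + (1 - W)/ln(W)`, the state-space image of the empirical
#' runoff closure `Ro = P exp(-N/P)`.
#'
#' Out-of-range ratios (e.g. `E > N` in imperfect input data) are
#' returned as computed and flagged `NA`-invalid by the callers that
#' build state tables; they are never clipped, so density diagnostics
#' are not distorted.
#'
#' @param E,N,P Evapotranspiration, net radiation, precipitation
#'   (m/yr water-flux equivalent). Vectorized.
#' @return Numeric vectors of the same length.
#' @name state_equations
NULL

#' @rdname state_equations
#' @examples
#' excess_energy(E = 0.5, N = 1)   # 0.5
#' @export
excess_energy <- function(E, N) {
  ifelse(N > 0, 1 - E / N, NA_real_)
}

#' @rdname state_equations
#' @examples
#' excess_water(E = 0.25, P = 1)   # 0.75
#' @export
excess_water <- function(E, P) {
  ifelse(P > 0, 1 - E / P, NA_real_)
}

#' @rdname state_equations
#' @examples
#' schreiber_runoff(P = 1, N = 1)  # exp(-1)
#' @export
schreiber_runoff <- function(P, N) {
  ifelse(P > 0 & N >= 0, P * exp(-N / P), NA_real_)
}

#' Balanced-state curve: U as a function of W
#'
#' `schreiber_curve_u()` evaluates `U = 1 + (1 - W)/ln(W)`, the locus
#' of states consistent with the Schreiber runoff closure. The
#' removable endpoint singularities are defined by continuity:
#' `U(W -> 1) = 0` and `U(W -> 0+) = 1`.
#'
#' @param W Relative excess water in `[0, 1]`.
#' @return `U` on the balanced curve; errors if `W` is outside `[0, 1]`.
#' @examples
#' schreiber_curve_u(exp(-1))  # exp(-1)
#' @export
schreiber_curve_u <- function(W) {
  if (any(!is.na(W) & (W < 0 | W > 1))) {
    stop("`W` must lie in [0, 1].", call. = FALSE)
  }
  u <- 1 + (1 - W) / log(W)
  u[!is.na(W) & W == 0] <- 1
  u[!is.na(W) & W == 1] <- 0
  u
}

#' Dryness index from states or from fluxes
#'
#' `dryness()` computes `D = (1 - W)/(1 - U)` (since `1 - U = E/N` and
#' `1 - W = E/P`, this ratio is exactly `N/P`);
#' `dryness_from_fluxes()` computes `D = N/P` directly. When `U` and
#' `W` derive from the same fluxes the two agree to floating-point
#' accuracy. `U = 1` with `W < 1` (all energy consumed, water left
#' over is impossible, so this marks the dry limit `E = N`) yields
#' `Inf` as the infinitely-dry sentinel; callers flag such pixels.
#'
#' @param U,W State coordinates.
#' @param N,P Net radiation and precipitation (m/yr equivalents).
#' @return Dryness index `D >= 0` (or `Inf`/`NA` sentinels).
#' @examples
#' dryness(U = 0.5, W = 0.25)       # 1.5
#' dryness_from_fluxes(N = 2, P = 1) # 2
#' @export
dryness <- function(U, W) {
  ifelse(U < 1, (1 - W) / (1 - U),
         ifelse(W < 1, Inf, NaN))
}

#' @rdname dryness
#' @export
dryness_from_fluxes <- function(N, P) {
  ifelse(P > 0, N / P, NA_real_)
}

BIOME_BREAKS <- c(0, 0.3, 1, 2, 3, Inf)
BIOME_LEVELS <- c("tundra", "forest", "steppe_savanna", "semidesert", "desert")

#' Classify dryness into biome bands and limitation regime
#'
#' Biome bands follow the classical dryness ladder: tundra (`D < 0.3`),
#' forest (`0.3 <= D < 1`), steppe/savanna (`1 <= D < 2`), semidesert
#' (`2 <= D < 3`), desert (`D >= 3`). Intervals are closed on the left;
#' in particular `D = 1` is steppe/savanna and water-limited. The
#' regime is `energy_limited` for `D < 1` and `water_limited` for
#' `D >= 1`.
#'
#' @param D Dryness index values (`>= 0`).
#' @return A tibble with columns `D`, `biome` (factor) and `regime`
#'   (factor).
#' @examples
#' biome_class(c(0.2, 0.5, 1, 2.5, 4))
#' @export
biome_class <- function(D) {
  if (any(!is.na(D) & D < 0)) stop("`D` must be non-negative.", call. = FALSE)
  biome <- cut(D, breaks = BIOME_BREAKS, labels = BIOME_LEVELS,
               right = FALSE, include.lowest = TRUE)
  regime <- factor(ifelse(D < 1, "energy_limited", "water_limited"),
                   levels = c("energy_limited", "water_limited"))
  tibble::tibble(D = D, biome = biome, regime = regime)
}

#' Add (U, W, D) state coordinates to a flux table
#'
#' Takes a tibble of per-pixel fluxes and appends the state
#' coordinates plus a validity flag. A pixel-state is valid when
#' `P > 0`, `N > 0` and both `U` and `W` fall inside `[0, 1]`;
#' out-of-range values are kept (not clipped) but flagged.
#'
#' @param data Tibble with numeric columns `P`, `N`, `E` (m/yr).
#' @return The input with columns `U`, `W`, `D`, `valid` appended.
#' @export
compute_states <- function(data) {
  stopifnot(all(c("P", "N", "E") %in% names(data)))
  out <- dplyr::mutate(
    data,
    U = excess_energy(.data$E, .data$N),
    W = excess_water(.data$E, .data$P),
    D = dryness(.data$U, .data$W),
    valid = !is.na(.data$U) & !is.na(.data$W) &
      .data$U >= 0 & .data$U <= 1 & .data$W >= 0 & .data$W <= 1
  )
  tibble::as_tibble(out)
}
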