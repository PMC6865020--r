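# small scenario for fast tests: 12 x 16 grid, short record
tiny_config <- function(seed = 1, noise_sd = 0, n_city_clusters = 2,
                        greenness_trend = 0.05) {
  scenario_config(
    n_rows = 12, n_cols = 16, years = 1982:1989, period_split_year = 1986,
    noise_sd = noise_sd, greenness_noise_sd = noise_sd,
    greenness_trend = greenness_trend,
    patches = tibble::tibble(
      label = c("internal_pos_dE", "external_drying"),
      row0 = c(2, 8), row1 = c(4, 10), col0 = c(9, 5), col1 = c(11, 7),
      dE = c(0.1, 0), dN = c(0, 0.2), dP = c(0, -0.2)
    ),
    n_city_clusters = n_city_clusters, fine_factor = 3, seed = seed
  )
}

# independent connected-component oracle: iterative minimum-label
# propagation over the neighborhood until a fixed point, then labels
# renumbered by first occurrence in a row-major scan
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- which(mask)  # unique seed labels
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  if (connectivity == 4) {
    offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  }
  labf <- matrix(Inf, nr, nc)
  labf[mask] <- lab[mask]
  repeat {
    cand <- labf
    for (o in offs) {
      s <- shift(labf, o[1], o[2])
      cand <- pmin(cand, s)
    }
    cand[!mask] <- Inf
    if (identical(cand, labf)) break
    labf <- cand
  }
  out <- matrix(0L, nr, nc)
  vals <- as.vector(t(labf))  # row-major order
  seen <- unique(vals[is.finite(vals)])
  remap <- stats::setNames(seq_along(seen), seen)
  fin <- is.finite(labf)
  out[fin] <- remap[as.character(labf[fin])]
  out
}
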