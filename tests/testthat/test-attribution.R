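test_that("displacement is the coordinate difference of the two period states", {
  d <- displacement(U1 = 0.5, W1 = 0.5, U2 = 0.4, W2 = 0.4)
  expect_equal(c(d$dW, d$dU), c(-0.1, -0.1))
  d2 <- displacement(0.5, 0.5, 0.5, 0.5)
  expect_equal(c(d2$dW, d2$dU), c(0, 0))
  d3 <- displacement(U1 = 0.5, W1 = 0.5, U2 = 0.6, W2 = 0.4)
  expect_equal(c(d3$dW, d3$dU), c(-0.1, 0.1))
})

test_that("diagonal decomposition reproduces the worked projections", {
  ext <- decompose_change(tibble::tibble(dW = -0.1, dU = 0.1))
  expect_equal(ext$c_int, 0)
  expect_equal(ext$c_ext, 0.1414213562373095, tolerance = 1e-12)
  expect_equal(as.character(ext$dominant_cause), "external")
  int <- decompose_change(tibble::tibble(dW = -0.1, dU = -0.1))
  expect_equal(int$c_int, -0.1414213562373095, tolerance = 1e-12)
  expect_equal(int$c_ext, 0)
  expect_equal(as.character(int$dominant_cause), "internal")
  zero <- decompose_change(tibble::tibble(dW = 0, dU = 0))
  expect_equal(c(zero$c_int, zero$c_ext), c(0, 0))
  expect_equal(as.character(zero$dominant_cause), "tie")
})

test_that("both decomposition modes are orthonormal (Pythagoras) and agree at D = 1", {
  set.seed(7)
  n <- 5000
  df <- tibble::tibble(
    U1 = runif(n, 0.05, 0.95), W1 = runif(n, 0.05, 0.95),
    dU = runif(n, -0.3, 0.3), dW = runif(n, -0.3, 0.3))
  for (mode in c("diagonal", "local_D")) {
    out <- decompose_change(df, mode)
    expect_lt(max(abs(out$c_int^2 + out$c_ext^2 - (out$dU^2 + out$dW^2))),
              1e-12)
  }
  on_diag <- dplyr::mutate(df, W1 = U1)  # D(U1, W1) = 1
  a <- decompose_change(on_diag, "diagonal")
  b <- decompose_change(on_diag, "local_D")
  expect_equal(b$c_int, a$c_int, tolerance = 1e-12)
  expect_equal(b$c_ext, a$c_ext, tolerance = 1e-12)
})

test_that("quadrants follow the sign pattern and the axis tie rule", {
  expect_equal(as.character(quadrant_class(-0.05, -0.02)), "Q3_lightblue")
  expect_equal(as.character(quadrant_class(0.03, 0.08)), "Q1_pink")
  expect_equal(as.character(quadrant_class(-0.03, 0.08)), "Q2_yellow")
  expect_equal(as.character(quadrant_class(0.03, -0.08)), "Q4_darkblue")
  # axis-aligned: dW = 0 is purely external, dU = 0 purely internal
  expect_equal(as.character(quadrant_class(0, 0.1)), "Q2_yellow")
  expect_equal(as.character(quadrant_class(0, -0.1)), "Q4_darkblue")
  expect_equal(as.character(quadrant_class(0.1, 0)), "Q1_pink")
  expect_equal(as.character(quadrant_class(-0.1, 0)), "Q3_lightblue")
  expect_equal(as.character(quadrant_class(0, 0)), "no_change")
})

test_that("pure internal perturbations land in Q3/Q1 for any dryness", {
  # dE != 0 at fixed N, P: dU and dW share the sign of -dE
  set.seed(1)
  P <- runif(200, 0.4, 1.5); N <- P * exp(runif(200, log(0.1), log(5)))
  E <- P - schreiber_runoff(P, N)
  dE <- ifelse(seq_along(P) %% 2 == 0, 0.05, -0.05)
  ok <- E + dE >= 0 & E + dE <= pmin(P, N)
  dU <- -dE / N; dW <- -dE / P
  q <- as.character(quadrant_class(dW[ok], dU[ok]))
  expect_true(all(q[dE[ok] > 0] == "Q3_lightblue"))
  expect_true(all(q[dE[ok] < 0] == "Q1_pink"))
})

test_that("pure external aridity increase never lands in an internal quadrant", {
  set.seed(2)
  P <- runif(200, 0.6, 1.5); N <- P * exp(runif(200, log(0.2), log(3)))
  E <- P - schreiber_runoff(P, N)
  dN <- runif(200, 0, 0.3); dP <- -runif(200, 0, 0.2)
  ok <- E <= pmin(P + dP, N + dN) & P + dP > 0
  dU <- excess_energy(E, N + dN) - excess_energy(E, N)
  dW <- excess_water(E, P + dP) - excess_water(E, P)
  q <- as.character(quadrant_class(dW[ok], dU[ok]))
  expect_false(any(q %in% c("Q3_lightblue", "Q1_pink")))
})

test_that("attribution summary partitions strata and normalizes fractions", {
  set.seed(3)
  n <- 400
  px <- tibble::tibble(
    row = rep(1:20, each = 20), col = rep(1:20, times = 20),
    U1 = runif(n, 0.2, 0.8), W1 = runif(n, 0.2, 0.8),
    dU = rnorm(n, 0, 0.05), dW = rnorm(n, 0, 0.05), valid = TRUE)
  att <- attribute_changes(px)
  masks <- tibble::tibble(
    row = px$row, col = px$col,
    significant = runif(n) < 0.3, urban = runif(n) < 0.1,
    greenness_category = factor(sample(c("increase", "decrease", "tie"), n,
                                       replace = TRUE, prob = c(0.6, 0.3, 0.1)),
                                levels = c("increase", "decrease", "tie")))
  s <- attribution_summary(att, masks)
  for (str in c("all", "significant", "urban")) {
    for (g in c("all", "increase", "decrease")) {
      cell <- s[s$stratum == str & s$greenness_category == g, ]
      quad <- cell[cell$quadrant != "no_change", ]
      if (cell$n_total[1] > 0) {
        expect_equal(sum(quad$fraction), 1)
        expect_equal(sum(quad$n_pixels) +
                       cell$n_pixels[cell$quadrant == "no_change"],
                     cell$n_total[1])
        expect_equal(cell$internal_fraction[1] + cell$external_fraction[1] +
                       cell$tie_fraction[1], 1)
      }
    }
  }
  # counts respect nesting and category partition
  tot <- function(str, g) s$n_total[s$stratum == str &
                                      s$greenness_category == g][1]
  expect_lte(tot("urban", "all"), tot("all", "all"))
  expect_lte(tot("significant", "all"), tot("all", "all"))
  expect_lte(tot("all", "increase") + tot("all", "decrease"), tot("all", "all"))
})

test_that("all-external input yields external fraction one", {
  px <- tibble::tibble(row = 1:10, col = 1,
                       dU = rep(0.1, 10), dW = rep(-0.1, 10), valid = TRUE)
  att <- attribute_changes(px)
  masks <- tibble::tibble(row = 1:10, col = 1, significant = TRUE,
                          urban = FALSE,
                          greenness_category = factor("increase",
                            levels = c("increase", "decrease", "tie")))
  s <- attribution_summary(att, masks)
  expect_equal(s$external_fraction[s$stratum == "all" &
                                     s$greenness_category == "all"][1], 1)
  expect_true(all(s$n_total[s$stratum == "urban"] == 0))
  expect_true(all(is.na(s$fraction[s$stratum == "urban"])))
})

test_that("internal patches with N = P are pure positive-diagonal displacements", {
  # dU = -dE/N equals dW = -dE/P when N = P: c_ext = 0 exactly
  cfg <- scenario_config(
    n_rows = 4, n_cols = 4, years = 1982:1989, period_split_year = 1986,
    dryness_range = c(1, 1 + 1e-9), noise_sd = 0, greenness_noise_sd = 0,
    patches = tibble::tibble(label = "internal_pos_dE", row0 = 1, row1 = 2,
                             col0 = 1, col1 = 2, dE = 0.1, dN = 0, dP = 0),
    n_city_clusters = 0, fine_factor = 3, seed = 1)
  land <- generate_landscape(cfg)
  stats <- change_stats(annual_states(land$fluxes),
                        period_pair(1982:1985, 1986:1989))
  att <- attribute_changes(stats)
  hit <- dplyr::left_join(att, land$truth, by = c("row", "col", "lat", "lon"))
  on_patch <- hit[hit$label == "internal_pos_dE", ]
  expect_true(all(as.character(on_patch$quadrant) == "Q3_lightblue"))
  expect_true(all(as.character(on_patch$dominant_cause) == "internal"))
  expect_lt(max(abs(on_patch$c_ext)), 1e-9)
})
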