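test_that("scenario_config rejects invalid study designs", {
  expect_error(scenario_config(years = 2000:2001), "4 entries")
  expect_error(scenario_config(period_split_year = 1982), "inside")
  expect_error(scenario_config(noise_sd = -0.1), ">= 0")
  expect_error(scenario_config(city_dn = 11), "detection threshold")
  expect_error(scenario_config(fine_factor = 4), "odd")
  expect_error(scenario_config(background_dn_max = 12), "\\[0, 12\\)")
  bad_patch <- tibble::tibble(label = "internal_pos_dE", row0 = 0, row1 = 2,
                              col0 = 1, col1 = 2, dE = 0.1, dN = 0, dP = 0)
  expect_error(scenario_config(patches = bad_patch), "inside the grid")
})

test_that("noise-free base fluxes satisfy the runoff closure exactly", {
  cfg <- tiny_config(noise_sd = 0)
  fl <- generate_base_fluxes(cfg)
  expect_lt(max(abs(fl$E / (fl$P * (1 - exp(-fl$N / fl$P))) - 1)), 1e-12)
  expect_true(all(fl$E >= 0 & fl$E <= pmin(fl$P, fl$N)))
  # single-pixel closed form: P = N = 1 gives E = 1 - exp(-1)
  expect_equal(unique(round(1 * (1 - exp(-1)), 15)), 0.632120558828558,
               tolerance = 1e-15)
})

test_that("generated fields are deterministic under a fixed seed", {
  a <- generate_landscape(tiny_config(seed = 9, noise_sd = 0.05))
  b <- generate_landscape(tiny_config(seed = 9, noise_sd = 0.05))
  expect_identical(a$fluxes, b$fluxes)
  expect_identical(a$greenness, b$greenness)
  expect_identical(a$nightlights, b$nightlights)
  expect_identical(a$truth, b$truth)
  c <- generate_landscape(tiny_config(seed = 10, noise_sd = 0.05))
  expect_false(identical(a$fluxes, c$fluxes))
})

test_that("noisy annual fluxes stay physically valid and centered", {
  cfg <- tiny_config(seed = 3, noise_sd = 0.05)
  fl <- generate_base_fluxes(cfg)
  expect_true(all(fl$P > 0 & fl$N >= 0))
  expect_true(all(fl$E >= 0 & fl$E <= pmin(fl$P, fl$N) + 1e-12))
  # multiplicative lognormal with unit mean: annual means near the base
  base <- generate_base_fluxes(tiny_config(seed = 3, noise_sd = 0))
  ratio <- tapply(fl$P, paste(fl$row, fl$col), mean) /
    tapply(base$P, paste(base$row, base$col), mean)
  expect_lt(max(abs(ratio - 1)), 0.1)
})

test_that("internal perturbation shifts U and W by -dE/N and -dE/P", {
  # one-pixel patch with P = N = 1 via a flat dryness range near 1
  cfg <- scenario_config(
    n_rows = 4, n_cols = 4, years = 1982:1989, period_split_year = 1986,
    dryness_range = c(1, 1.0000001), noise_sd = 0, greenness_noise_sd = 0,
    patches = tibble::tibble(label = "internal_pos_dE", row0 = 1, row1 = 1,
                             col0 = 1, col1 = 1, dE = 0.1, dN = 0, dP = 0),
    n_city_clusters = 0, fine_factor = 3, seed = 1)
  base <- generate_base_fluxes(cfg)
  pert <- apply_perturbations(base, cfg)
  st <- compute_states(pert$fluxes)
  px <- st[st$row == 1 & st$col == 1, ]
  p1 <- px[px$year < 1986, ]; p2 <- px[px$year >= 1986, ]
  n_val <- base$N[base$row == 1 & base$col == 1][1]
  p_val <- base$P[base$row == 1 & base$col == 1][1]
  expect_equal(mean(p2$U) - mean(p1$U), -0.1 / n_val, tolerance = 1e-12)
  expect_equal(mean(p2$W) - mean(p1$W), -0.1 / p_val, tolerance = 1e-12)
})

test_that("external drying leaves W untouched when only N changes", {
  cfg <- scenario_config(
    n_rows = 4, n_cols = 4, years = 1982:1989, period_split_year = 1986,
    noise_sd = 0, greenness_noise_sd = 0,
    patches = tibble::tibble(label = "external_drying", row0 = 2, row1 = 2,
                             col0 = 2, col1 = 2, dE = 0, dN = 0.2, dP = 0),
    n_city_clusters = 0, fine_factor = 3, seed = 1)
  pert <- apply_perturbations(generate_base_fluxes(cfg), cfg)
  st <- compute_states(pert$fluxes)
  px <- st[st$row == 2 & st$col == 2, ]
  dU <- mean(px$U[px$year >= 1986]) - mean(px$U[px$year < 1986])
  dW <- mean(px$W[px$year >= 1986]) - mean(px$W[px$year < 1986])
  expect_gt(dU, 0)
  expect_equal(dW, 0)
})

test_that("empty patch set is the identity with all labels none", {
  cfg <- tiny_config(noise_sd = 0)
  cfg$patches <- cfg$patches[0, ]
  base <- generate_base_fluxes(cfg)
  pert <- apply_perturbations(base, cfg)
  expect_equal(pert$fluxes$E, base$E)
  expect_true(all(pert$truth$label == "none"))
})

test_that("perturbations that break physical validity are rejected", {
  cfg <- scenario_config(
    n_rows = 4, n_cols = 4, years = 1982:1989, period_split_year = 1986,
    noise_sd = 0, greenness_noise_sd = 0,
    patches = tibble::tibble(label = "internal_neg_dE", row0 = 1, row1 = 1,
                             col0 = 1, col1 = 1, dE = -5, dN = 0, dP = 0),
    n_city_clusters = 0, fine_factor = 3, seed = 1)
  expect_error(apply_perturbations(generate_base_fluxes(cfg), cfg),
               "physical bounds")
  cfg$patches$dE <- 0; cfg$patches$dP <- -5
  expect_error(apply_perturbations(generate_base_fluxes(cfg), cfg),
               "physical bounds")
})

test_that("overlapping patches are rejected: labels must partition", {
  cfg <- tiny_config()
  cfg$patches <- tibble::tibble(
    label = c("internal_pos_dE", "internal_neg_dE"),
    row0 = c(1, 2), row1 = c(3, 4), col0 = c(1, 1), col1 = c(3, 3),
    dE = c(0.05, -0.05), dN = 0, dP = 0)
  expect_error(apply_perturbations(generate_base_fluxes(cfg), cfg),
               "overlap")
})

test_that("greenness carries the configured two-period step exactly when noise-free", {
  cfg <- tiny_config(noise_sd = 0)
  base <- generate_base_fluxes(cfg)
  pert <- apply_perturbations(base, cfg)
  grn <- generate_greenness(cfg, pert$truth)
  g <- grn$greenness
  d <- g |>
    dplyr::group_by(row, col) |>
    dplyr::summarise(diff = mean(greenness[year >= 1986]) -
                       mean(greenness[year < 1986]), .groups = "drop") |>
    dplyr::left_join(grn$truth, by = c("row", "col"))
  expect_equal(d$diff, d$greenness_trend_sign * cfg$greenness_trend,
               tolerance = 1e-12)
  expect_true(all(g$greenness >= -0.2 & g$greenness <= 1))
  # zero trend magnitude: no period shift at all
  cfg0 <- tiny_config(noise_sd = 0, greenness_trend = 0)
  grn0 <- generate_greenness(cfg0, pert$truth)
  d0 <- grn0$greenness |>
    dplyr::group_by(row, col) |>
    dplyr::summarise(diff = mean(greenness[year >= 1986]) -
                       mean(greenness[year < 1986]), .groups = "drop")
  expect_equal(d0$diff, rep(0, nrow(d0)))
})

test_that("greenness trend signs follow the perturbation scenario", {
  land <- generate_landscape(tiny_config(seed = 2))
  tr <- land$truth
  expect_true(all(tr$greenness_trend_sign[tr$label == "internal_pos_dE"] == 1))
  expect_true(all(tr$greenness_trend_sign[tr$label == "external_drying"] == -1))
  expect_true(all(tr$greenness_trend_sign %in% c(-1L, 1L)))
})

test_that("nightlights produce the configured disjoint clusters on a dim background", {
  cfg <- tiny_config(seed = 6)
  land <- generate_landscape(cfg)
  dn <- land$nightlights$dn
  expect_true(all(dn == floor(dn) & dn >= 0 & dn <= 63))
  lit <- lighted_mask(land$nightlights)
  lab <- label_cities(lit, land$fine_grid, connectivity = 8)
  expect_equal(max(lab$city_id, na.rm = TRUE), cfg$n_city_clusters)
  tab <- city_table(lab, land$fine_grid)
  expect_equal(tab$n_pixels,
               rep((2 * cfg$city_halfwidth + 1)^2, cfg$n_city_clusters))
  expect_equal(sum(land$truth$city), cfg$n_city_clusters)
  # zero clusters: nothing lighted
  land0 <- generate_landscape(tiny_config(n_city_clusters = 0))
  expect_true(all(land0$nightlights$dn < 12))
})
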