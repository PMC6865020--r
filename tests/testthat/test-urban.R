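grid_for <- function(nr, nc) grid_spec(nr, nc, lat_max = 30, lon_min = 0,
                                       spacing = 0.75)

mask_tbl <- function(m, grid) {
  dplyr::mutate(matrix_layer(m, grid), lighted = value == 1)
}

# minimal local stand-in for the internal matrix_to_layer
matrix_layer <- function(m, grid) {
  px <- grid_pixels(grid)
  px$value <- as.vector(t(m))
  px
}

test_that("lighted mask uses >= threshold and validates DN range", {
  g <- grid_for(1, 3)
  df <- dplyr::mutate(grid_pixels(g), dn = c(11, 12, 63))
  out <- lighted_mask(df)
  expect_equal(out$lighted, c(FALSE, TRUE, TRUE))
  expect_error(lighted_mask(dplyr::mutate(df, dn = c(1, 70, 3))), "\\[0, 63\\]")
  expect_error(lighted_mask(dplyr::mutate(df, dn = c(1, -2, 3))), "\\[0, 63\\]")
  expect_equal(sum(lighted_mask(dplyr::mutate(df, dn = 0))$lighted), 0)
})

test_that("a solid block is one region; diagonal touch splits under 4-connectivity", {
  g <- grid_for(6, 6)
  m <- matrix(FALSE, 6, 6)
  m[2:4, 2:4] <- TRUE
  lab8 <- label_cities(mask_tbl(m, g), g, 8)
  expect_equal(max(lab8$city_id, na.rm = TRUE), 1)
  expect_equal(sum(!is.na(lab8$city_id)), 9)

  m2 <- matrix(FALSE, 6, 6)
  m2[2, 2] <- TRUE; m2[3, 3] <- TRUE  # touch only diagonally
  expect_equal(max(label_cities(mask_tbl(m2, g), g, 8)$city_id, na.rm = TRUE), 1)
  expect_equal(max(label_cities(mask_tbl(m2, g), g, 4)$city_id, na.rm = TRUE), 2)
})

test_that("labels are deterministic in row-major first-encounter order", {
  g <- grid_for(5, 5)
  m <- matrix(FALSE, 5, 5)
  m[1, 4] <- TRUE          # first region encountered (row 1)
  m[3:4, 1:2] <- TRUE      # second region
  lab <- label_cities(mask_tbl(m, g), g, 8)
  expect_equal(lab$city_id[lab$row == 1 & lab$col == 4], 1L)
  expect_true(all(lab$city_id[lab$row %in% 3:4 & lab$col %in% 1:2] == 2L))
})

test_that("labeling matches the flood-fill oracle on random masks", {
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(runif(400) < 0.4, 20, 20)
    g <- grid_for(20, 20)
    for (conn in c(4, 8)) {
      got <- label_cities(mask_tbl(m, g), g, conn)
      want <- oracle_label(m, conn)
      got_m <- matrix(0L, 20, 20)
      got_m[cbind(got$row, got$col)] <- ifelse(is.na(got$city_id), 0L,
                                               got$city_id)
      expect_identical(got_m, want)
    }
  }
})

test_that("city sizes are cos-weighted area sums, additive to the lighted total", {
  g <- grid_spec(40, 3, lat_max = 60, lon_min = 0, spacing = 0.75)
  m <- matrix(FALSE, 40, 3)
  m[5:25, 2] <- TRUE   # one city spanning 15 degrees of latitude
  m[30, 1] <- TRUE     # a second, single-pixel city
  lab <- label_cities(mask_tbl(m, g), g, 8)
  tab <- city_table(lab, g)
  d <- 0.75 * pi / 180
  hand <- sum(6371^2 * d^2 * cos(g$lat[5:25] * pi / 180))
  expect_equal(tab$size_km2[1], hand, tolerance = 1e-9)
  areas <- pixel_area(g)
  lit_total <- sum(areas$area_km2[m[cbind(areas$row, areas$col)]])
  expect_equal(sum(tab$size_km2), lit_total, tolerance = 1e-12)
})

test_that("region count is monotone non-increasing in the threshold", {
  g <- grid_for(15, 15)
  set.seed(5)
  dn <- matrix(sample(0:63, 225, replace = TRUE), 15, 15)
  df <- matrix_layer(dn, g)
  df$dn <- df$value
  n_regions <- vapply(c(5, 12, 25, 45, 60), function(th) {
    lab <- label_cities(lighted_mask(df, th), g, 8)
    if (all(is.na(lab$city_id))) 0L else max(lab$city_id, na.rm = TRUE)
  }, 0L)
  counts <- vapply(c(5, 12, 25, 45, 60),
                   function(th) sum(df$dn >= th), 0L)
  expect_true(all(diff(counts) <= 0))  # shrinking mask ...
  # ... and a mask that is a subset cannot have more merged area than pixels
  expect_true(all(n_regions <= counts))
})

test_that("labeling is invariant under translation of the whole mask", {
  g <- grid_for(12, 12)
  m <- matrix(FALSE, 12, 12)
  m[2:3, 2:5] <- TRUE; m[6, 7] <- TRUE; m[8:9, 9] <- TRUE
  shifted <- matrix(FALSE, 12, 12)
  shifted[4:11, 3:12] <- m[1:8, 1:10]
  for (conn in c(4, 8)) {
    a <- label_cities(mask_tbl(m, g), g, conn)
    b <- label_cities(mask_tbl(shifted, g), g, conn)
    am <- matrix(NA_integer_, 12, 12); am[cbind(a$row, a$col)] <- a$city_id
    bm <- matrix(NA_integer_, 12, 12); bm[cbind(b$row, b$col)] <- b$city_id
    expect_identical(am[1:8, 1:10], bm[4:11, 3:12])
  }
})

test_that("coarse urban mask recovers cells hosting synthetic city clusters", {
  cfg <- tiny_config(seed = 8)
  land <- generate_landscape(cfg)
  urb <- urban_coarse_mask(land$nightlights, land$fine_grid, land$grid)
  joined <- dplyr::left_join(urb, land$truth, by = c("row", "col"))
  # cluster blocks are centered on coarse centers at DN 40: detected
  expect_true(all(joined$urban[joined$city]))
  expect_equal(sum(joined$urban), sum(joined$city))
  # no clusters -> all-false coarse mask
  land0 <- generate_landscape(tiny_config(seed = 8, n_city_clusters = 0))
  urb0 <- urban_coarse_mask(land0$nightlights, land0$fine_grid, land0$grid)
  expect_false(any(urb0$urban))
})

test_that("threshold-first aggregation mode marks majority-lighted cells", {
  cfg <- tiny_config(seed = 8)
  land <- generate_landscape(cfg)
  # halfwidth 1 with fine_factor 3: the 3x3 block fills its cell exactly
  urb <- urban_coarse_mask(land$nightlights, land$fine_grid, land$grid,
                           mode = "threshold_first")
  joined <- dplyr::left_join(urb, land$truth, by = c("row", "col"))
  expect_true(all(joined$urban[joined$city]))
  expect_equal(sum(joined$urban), sum(joined$city))
})
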