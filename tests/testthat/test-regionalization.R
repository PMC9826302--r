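mk_monthly <- function(temps, def = grid_def(0, 0, 2, 2, 1)) {
  # 12 constant grids at the given monthly temperatures
  monthly_temperature(lapply(temps, function(t)
    clim_grid(matrix(t, def$nrow, def$ncol), def$xmin, def$ymin,
              def$cellsize)))
}

test_that("biotemperature averages monthly values clamped to [0, 30]", {
  b <- biotemperature(mk_monthly(rep(25, 12)))
  expect_true(all(b$values == 25))
  b <- biotemperature(mk_monthly(c(rep(-5, 6), rep(20, 6))))
  expect_true(all(b$values == 10))          # (6*0 + 6*20) / 12
  b <- biotemperature(mk_monthly(rep(35, 12)))
  expect_true(all(b$values == 0))           # above 30 clamps to 0
  expect_error(biotemperature(mk_monthly(rep(10, 11))), "12")
  bad <- c(lapply(rep(10, 11), function(t)
    clim_grid(matrix(t, 2, 2), 0, 0, 1)),
    list(clim_grid(matrix(10, 2, 2), 5, 0, 1)))
  expect_error(monthly_temperature(bad), "co-registered")
})

test_that("biotemperature output is bounded in [0, 30] for any input", {
  set.seed(1)
  for (i in 1:10) {
    m <- mk_monthly(runif(12, -40, 45))
    b <- biotemperature(m)
    expect_true(all(b$values >= 0 & b$values <= 30))
  }
})

test_that("NoData in any month propagates to biotemperature", {
  def <- grid_def(0, 0, 2, 2, 1)
  grids <- lapply(rep(20, 12), function(t)
    clim_grid(matrix(t, 2, 2), 0, 0, 1))
  for (g in seq_along(grids)) grids[[g]]$values[1, 1] <- NA
  b <- biotemperature(monthly_temperature(grids))
  expect_true(is.na(b$values[1, 1]))
  expect_equal(b$values[2, 2], 20)
})

test_that("Holdridge zones partition [0, 30] with warm-side-closed bounds", {
  expect_equal(holdridge_classify(25), "tropical")
  expect_equal(holdridge_classify(13), "warm temperate")
  eps <- 1e-9
  bounds <- c(1.5, 3, 6, 12, 17, 24)
  upper <- c("subpolar", "boreal", "cool temperate", "warm temperate",
             "subtropical", "tropical")
  lower <- c("polar", "subpolar", "boreal", "cool temperate",
             "warm temperate", "subtropical")
  for (i in seq_along(bounds)) {
    expect_equal(holdridge_classify(bounds[i]), upper[i])       # closed
    expect_equal(holdridge_classify(bounds[i] - eps), lower[i]) # open
    expect_equal(holdridge_classify(bounds[i] + eps), upper[i])
  }
  expect_equal(holdridge_classify(0), "polar")
  expect_equal(holdridge_classify(30), "tropical")
  # every valid value maps to exactly one of the seven zones
  grid_vals <- seq(0, 30, by = 0.01)
  z <- holdridge_classify(grid_vals)
  expect_false(anyNA(z))
  expect_equal(sort(unique(z)),
               sort(c("polar", "subpolar", "boreal", "cool temperate",
                      "warm temperate", "subtropical", "tropical")))
  expect_error(holdridge_classify(31), "outside")
  expect_error(holdridge_classify(-0.1), "outside")
})

test_that("latitudinal zonation is hemispherically symmetric with stated limits", {
  expect_equal(latitudinal_classify(0), "tropical")
  expect_equal(latitudinal_classify(-30), "subtropical")
  expect_equal(latitudinal_classify(70), "polar")
  eps <- 1e-9
  for (b in c(23.5, 40, 66.5)) {
    expect_equal(latitudinal_classify(b), latitudinal_classify(-b))
    expect_false(latitudinal_classify(b - eps) ==
                   latitudinal_classify(b + eps))
  }
  expect_equal(latitudinal_classify(23.5), "subtropical")  # boundary up
  expect_equal(latitudinal_classify(40), "temperate")
  expect_equal(latitudinal_classify(66.5), "polar")
  lats <- seq(-90, 90, by = 0.25)
  expect_false(anyNA(latitudinal_classify(lats)))
  expect_error(latitudinal_classify(91), "outside")
})

test_that("Koppen aggregation maps codes to the six main classes", {
  expect_equal(koppen_aggregate(c("Af", "Am", "BWh", "Cfb", "Dfc",
                                  "ET", "EF")),
               c("tropical", "tropical", "dry", "temperate",
                 "continental", "tundra", "polar"))
  expect_error(koppen_aggregate("Xq"), "Xq")
  # total and surjective on a full code vocabulary
  vocab <- c("Af", "Am", "Aw", "BWh", "BWk", "BSh", "BSk", "Csa", "Csb",
             "Cwa", "Cfa", "Cfb", "Cfc", "Dsa", "Dwa", "Dfa", "Dfb",
             "Dfc", "Dfd", "ET", "EF")
  out <- koppen_aggregate(vocab)
  expect_false(anyNA(out))
  expect_setequal(unique(out), c("tropical", "dry", "temperate",
                                 "continental", "tundra", "polar"))
})

test_that("ecoregion simplification merges the listed biomes and passes the rest", {
  expect_equal(ecoregion_simplify("tropical and subtropical moist broadleaf forests"),
               "tropical and subtropical")
  expect_equal(ecoregion_simplify("Temperate Conifer Forests"), "temperate")
  expect_equal(ecoregion_simplify("Mangroves"), "Mangroves")
  expect_error(ecoregion_simplify("lunar maria"), "unknown biome")
  all14 <- c(occuclim:::ecoregion_tropical, occuclim:::ecoregion_temperate,
             occuclim:::ecoregion_other)
  out <- ecoregion_simplify(all14)
  expect_equal(length(unique(out)), 9)  # 14 biomes -> 9 categories
})

test_that("latitudinal raster equals per-cell-center classification (oracle)", {
  def <- grid_def(-10, -80, 4, 32, 5)
  layer <- build_latitudinal_raster(def)
  for (i in seq_len(def$nrow)) for (j in seq_len(def$ncol)) {
    ctr <- cell_centers(layer$grid, i, j)
    expect_equal(layer$legend[as.character(layer$grid$values[i, j])],
                 latitudinal_classify(ctr$lat), ignore_attr = TRUE)
  }
  # equatorial symmetry of a symmetric grid
  sym <- build_latitudinal_raster(grid_def(0, -40, 2, 16, 5))
  expect_equal(sym$grid$values, sym$grid$values[16:1, ])
  # the stated 40-degree limit splits adjacent 1-degree cells
  lim <- build_latitudinal_raster(grid_def(0, 39, 1, 2, 1))
  expect_equal(unname(lim$legend[as.character(lim$grid$values[, 1])]),
               c("temperate", "subtropical"))  # centers 40.5, 39.5
})

test_that("Holdridge raster bands sit at the closed-form gradient latitudes", {
  # noise-free linear climate: t = 28 - 0.35 * |lat|; zone bound b is
  # crossed at |lat| = (28 - b) / 0.35
  def <- grid_def(0, 0, 1, 360, 0.25)  # lat 0..90, fine bands
  monthly <- gen_monthly_climate(def, intercept = 28, gradient = 0.35,
                                 seasonality = 0, noise_sd = 0)
  layer <- build_holdridge_raster(monthly)
  lat <- cell_centers(layer$grid)$lat
  got <- layer$legend[as.character(layer$grid$values)]
  biot_expect <- pmin(pmax(28 - 0.35 * abs(lat), 0), 30)
  expect_equal(unname(got), holdridge_classify(biot_expect))
  # boundary latitude for tropical/subtropical: (28-24)/.35 = 11.43
  tropical_lats <- lat[got == "tropical"]
  expect_lt(max(tropical_lats), (28 - 24) / 0.35)
  expect_gt(max(tropical_lats), (28 - 24) / 0.35 - 0.25)
})

test_that("NoData propagates from months into the Holdridge raster", {
  def <- grid_def(0, 0, 2, 2, 1)
  grids <- lapply(rep(20, 12), function(t)
    clim_grid(matrix(t, 2, 2), 0, 0, 1))
  for (g in seq_along(grids)) grids[[g]]$values[1, 2] <- NA
  layer <- build_holdridge_raster(monthly_temperature(grids))
  expect_true(is.na(layer$grid$values[1, 2]))
  expect_false(anyNA(layer$grid$values[2, ]))
})

test_that("sampling a regionalization respects half-open cells and NoData", {
  g <- clim_grid(matrix(c(1, 2, 3, NA), 2, 2, byrow = TRUE), 0, 0, 1)
  layer <- regionalization(g, c("1" = "a", "2" = "b", "3" = "c"), "toy")
  # cell centers
  expect_equal(as.vector(sample_regionalization(c(0.5, 1.5, 0.5),
                                                c(1.5, 1.5, 0.5), layer)),
               c("a", "b", "c"))
  # shared edge at x = 1 belongs to the cell on its east (half-open)
  expect_equal(as.vector(sample_regionalization(1, 1.5, layer)), "b")
  # NoData cell and out-of-extent points are unclassified and counted
  got <- sample_regionalization(c(1.5, 99), c(0.5, 0.5), layer)
  expect_equal(as.vector(got), c("unclassified", "unclassified"))
  expect_equal(attr(got, "n_unclassified"), 2)
})

test_that("regionalizations round-trip through ascii grid + legend sidecar", {
  def <- grid_def(-10, 20, 6, 8, 2.5)
  layer <- build_latitudinal_raster(def)
  path <- tempfile(fileext = ".asc")
  write_regionalization(layer, path)
  back <- read_regionalization(path)
  expect_equal(back$grid$values, layer$grid$values)
  expect_equal(back$legend, layer$legend)
  expect_equal(back$name, layer$name)
})
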