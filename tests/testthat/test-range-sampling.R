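test_that("grid counts conserve records and use half-open integer cells", {
  rec <- toy_records(lon = c(0.2, 0.4, 0.9, 3.5), lat = c(0.5, 0.5, 0.5, 2.5))
  gc_ <- grid_counts(rec)
  expect_equal(sum(gc_$grid$values), 4)
  expect_equal(gc_$n_records, 4)
  expect_equal(grid_extract(gc_$grid, 0.5, 0.5), 3)
  # a record exactly on an integer corner counts in the cell NE of it
  corner <- grid_counts(toy_records(lon = 1, lat = 1),
                        extent = c(0, 2, 0, 2))
  expect_equal(grid_extract(corner$grid, 1.5, 1.5), 1)
  expect_equal(grid_extract(corner$grid, 0.5, 0.5), 0)
  # out-of-extent records are counted separately, conservation holds
  clipped <- grid_counts(rec, extent = c(0, 1, 0, 1))
  expect_equal(sum(clipped$grid$values) + clipped$n_outside, 4)
})

test_that("jenks_breaks separates well-spaced clusters and handles edge k", {
  jb <- jenks_breaks(c(1, 2, 3, 100, 101, 102), 2)
  expect_equal(jb$classes$min, c(1, 100))
  expect_equal(jb$classes$max, c(3, 102))
  expect_equal(jb$ssd, 2 + 2)  # each cluster has ssd 2
  one <- jenks_breaks(c(4, 8, 15, 16), 1)
  expect_equal(one$ssd, sum((c(4, 8, 15, 16) - mean(c(4, 8, 15, 16)))^2))
  perfect <- jenks_breaks(c(5, 9, 2, 7), 4)
  expect_equal(perfect$ssd, 0)
  expect_error(jenks_breaks(c(1, 1, 2), 3), "distinct")
})

test_that("jenks DP equals exhaustive enumeration for n <= 12, all k", {
  set.seed(21)
  for (rep_ in 1:12) {
    n <- sample(3:12, 1)
    vals <- sample(0:500, n, replace = TRUE)
    for (k in seq_len(length(unique(vals)))) {
      jb <- jenks_breaks(vals, k)
      expect_equal(jb$ssd, jenks_oracle_ssd(vals, k), tolerance = 1e-9,
                   info = sprintf("n=%d k=%d vals=%s", n, k,
                                  paste(vals, collapse = ",")))
      # classes partition the sorted data
      expect_equal(sum(jb$classes$n), n)
      expect_true(all(diff(jb$breaks) >= 0))
    }
  }
})

test_that("jenks assignments respect class ranges", {
  vals <- c(7, 1, 3, 9, 2, 8)
  jb <- jenks_breaks(vals, 2)
  for (i in seq_along(vals)) {
    cl <- jb$assignment[i]
    expect_true(vals[i] >= jb$classes$min[cl] &
                  vals[i] <= jb$classes$max[cl])
  }
})

test_that("hotspot threshold arithmetic and flags follow the 25% rule", {
  # grid whose maximum cell count is 8093
  rec <- toy_records(lon = rep(0.5, 3), lat = rep(0.5, 3))
  gc_ <- grid_counts(rec, extent = c(0, 3, 0, 1))
  gc_$grid$values[1, ] <- c(8093, 2315, 1000)
  jb <- jenks_breaks(c(8093, 2315, 1000), 3)
  hs <- hotspot_categories(gc_, jb)
  expect_equal(hs$threshold, 0.25 * 8093)
  expect_equal(hs$threshold_records, 2024)  # ceiling(2023.25)
  flagged <- hs$classes[hs$classes$hotspot, ]
  expect_true(8093 %in% flagged$max)
  expect_true(2315 %in% flagged$max)        # class max 2315 >= 2024
  expect_false(1000 %in% flagged$max)
  # monotone: every class above a flagged class is flagged
  expect_true(all(diff(hs$classes$hotspot) >= 0))
  # single class grid: always a hotspot
  one <- grid_counts(toy_records(lon = 0.5, lat = 0.5))
  hs1 <- hotspot_categories(one, jenks_breaks(1, 1))
  expect_true(hs1$classes$hotspot)
})

test_that("AOO counts occupied equal-area 2-km cells", {
  expect_equal(aoo(0.5, 0.5), 4)                      # one point, 4 km2
  expect_equal(aoo(c(0.5, 1.5), c(0.5, 0.5)), 8)      # ~111 km apart
  # two points 500 m apart straddling a cell line still occupy 2 cells:
  # the fixed-origin grid has a boundary at x = 0
  lon_m <- 1000 / (6371007.2 * pi / 180)   # ~1000 m in degrees at equator
  expect_equal(aoo(c(-lon_m / 4, lon_m / 4), c(0.2, 0.2)), 8)
  # monotone under adding points, invariant to order
  set.seed(5)
  lon <- runif(30, 0, 3); lat <- runif(30, 40, 43)
  a_all <- aoo(lon, lat)
  expect_gte(a_all, aoo(lon[1:10], lat[1:10]))
  o <- sample(30)
  expect_equal(aoo(lon[o], lat[o]), a_all)
})

test_that("EOO is the geodesic hull area, zero when degenerate", {
  expect_equal(eoo(c(1, 2), c(1, 1)), 0)              # two points
  expect_equal(eoo(c(1, 2, 3), c(1, 2, 3)), 0)        # collinear
  # 1x1 degree square at the equator vs independent ellipsoidal
  # integration oracle
  sq <- eoo(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(sq, wgs84_rect_area_km2(c(0, 1), c(0, 1)),
               tolerance = 0.005)
  # a mid-latitude rectangle too
  r <- eoo(c(10, 14, 14, 10), c(40, 40, 42, 42))
  expect_equal(r, wgs84_rect_area_km2(c(10, 14), c(40, 42)),
               tolerance = 0.005)
  # invariant under permutation and duplication
  lon <- c(0, 1, 1, 0, 0.5); lat <- c(0, 0, 1, 1, 0.5)
  expect_equal(eoo(rev(lon), rev(lat)), eoo(lon, lat))
  expect_equal(eoo(c(lon, lon), c(lat, lat)), eoo(lon, lat))
})

test_that("trans-antimeridian point sets are unwrapped before the hull", {
  # points around +-179 longitude: compact hull, not wrapped the long way
  lon <- c(179, 179.5, -179.5, -179); lat <- c(0, 1, 1, 0)
  a <- eoo(lon, lat)
  expect_lt(a, 5 * wgs84_rect_area_km2(c(0, 2), c(0, 1)))
})

test_that("range size classes apply the strict AOO thresholds", {
  expect_equal(range_size_class(88), "restricted")
  expect_equal(range_size_class(190564), "widespread")
  expect_equal(range_size_class(2000), "intermediate")   # strict <
  expect_equal(range_size_class(10000), "intermediate")  # strict >
  expect_equal(range_size_class(c(1999.9, 10000.1)),
               c("restricted", "widespread"))
})

test_that("range_metrics summarizes per genus", {
  set.seed(2)
  rec <- rbind(
    toy_records(lon = runif(20, 0, 0.1), lat = runif(20, 0, 0.1),
                genus = "GenusA", catalog = sprintf("A%02d", 1:20)),
    toy_records(lon = runif(20, 0, 8), lat = runif(20, 0, 8),
                genus = "GenusB", catalog = sprintf("B%02d", 1:20)))
  rm_ <- range_metrics(rec)
  expect_equal(rm_$genus, c("GenusA", "GenusB"))
  expect_true(all(rm_$aoo_km2 %% 4 == 0))
  expect_equal(rm_$size_class[1], "restricted")
  expect_gt(rm_$eoo_km2[2], rm_$eoo_km2[1])
})

test_that("temporal series accumulate from 1900 and locate quantile years", {
  regions <- rect_regions("ALL", 0, 10, 0, 10)
  labels <- c(GenusA = "tropical")
  # uniform one record per year 1900-1999
  rec <- toy_records(lon = rep(5, 100), lat = rep(5, 100),
                     catalog = sprintf("C%03d", 1:100))
  rec$year <- 1900:1999
  ts_ <- temporal_series(rec, regions, labels)
  expect_equal(ts_$n_excluded, 0)
  q <- ts_$quantile_years
  expect_equal(q$year, c(1924, 1949, 1974))
  expect_true(all(diff(ts_$series$cumulative) >= 0))
  # all in one year: step function, all quantiles that year
  rec1 <- rec; rec1$year <- 1950L
  q1 <- temporal_series(rec1, regions, labels)$quantile_years
  expect_equal(q1$year, rep(1950, 3))
  # pre-1900 and undated records are excluded and counted
  rec2 <- rec; rec2$year[1] <- 1850L; rec2$year[2] <- NA
  ts2 <- temporal_series(rec2, regions, labels)
  expect_equal(ts2$n_excluded, 2)
  expect_equal(max(ts2$series$cumulative), 98)
})

test_that("richness per unit counts distinct genera with composition labels", {
  rec <- rbind(
    toy_records(lon = 1, lat = 1, genus = "GenusA", tdwg = "AAA"),
    toy_records(lon = 1.1, lat = 1, genus = "GenusA", tdwg = "AAA"),
    toy_records(lon = 1.2, lat = 1, genus = "GenusB", tdwg = "AAA"),
    toy_records(lon = 5, lat = 1, genus = "GenusB", tdwg = "AAB"))
  labels <- c(GenusA = "tropical", GenusB = "temperate")
  got <- richness_by_unit(rec, c("AAA", "AAB", "ABA"), labels)
  expect_equal(got$n_genera, c(2, 1, 0))  # duplicates count once
  expect_equal(got$composition, c("both", "temperate-only", "none"))
})
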