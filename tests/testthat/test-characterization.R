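test_that("genus profile computes shares over unique coordinates", {
  layer <- band_layer(5, labels = c("tropical", "temperate"))
  # 8 unique points south of lat 5, 2 north
  rec <- toy_records(lon = rep(2.5, 10) + (1:10) / 100,
                     lat = c(rep(2.5, 8), 7.5, 8.5))
  p <- genus_profile(rec, layer)
  expect_equal(unname(p$shares[c("tropical", "temperate")]), c(80, 20))
  expect_equal(p$assignment, "tropical")
  expect_equal(p$n_used, 10)
  expect_equal(sum(p$shares), 100, tolerance = 5e-4)
})

test_that("a share of exactly 75% is equivocal (strictly-greater rule)", {
  layer <- band_layer(5, labels = c("tropical", "temperate"))
  rec <- toy_records(lon = c(1.1, 2.2, 3.3, 4.4),
                     lat = c(2, 2, 2, 8))
  p <- genus_profile(rec, layer)
  expect_equal(max(p$shares), 75)
  expect_equal(p$assignment, "equivocal")
  # one more southern point crosses the threshold: 4/5 = 80 > 75
  rec2 <- rbind(rec, toy_records(lon = 2.9, lat = 2))
  expect_equal(genus_profile(rec2, layer)$assignment, "tropical")
})

test_that("repeated coordinates collapse to one record before profiling", {
  layer <- constant_layer("tropical")
  rec <- toy_records(lon = rep(1.5, 5), lat = rep(1.5, 5))
  p <- genus_profile(rec, layer)
  expect_equal(p$n_used, 1)
  expect_equal(unname(p$shares), 100)
  expect_equal(p$assignment, "tropical")
})

test_that("unclassified points leave the denominator but are reported", {
  g <- clim_grid(matrix(c(1, NA), 1, 2), 0, 0, 1)
  layer <- regionalization(g, c("1" = "tropical"), "toy")
  rec <- toy_records(lon = c(0.5, 0.6, 1.5), lat = rep(0.5, 3))
  p <- genus_profile(rec, layer)
  expect_equal(p$n_used, 2)
  expect_equal(p$n_unclassified, 1)
  expect_equal(unname(p$shares), 100)
  expect_error(genus_profile(toy_records(1.5, 0.5), layer),
               "no classifiable")
})

test_that("profile shares recover planted zone fractions on generator data", {
  layer <- band_layer(5, def = grid_def(0, 0, 10, 10, 1),
                      labels = c("Z", "other"))
  set.seed(31)
  for (p_target in c(0.3, 0.6, 0.9)) {
    n <- 40
    n_in <- round(p_target * n)
    rec <- toy_records(
      lon = runif(n, 0.2, 9.8),
      lat = c(runif(n_in, 0.2, 4.8), runif(n - n_in, 5.2, 9.8)))
    p <- genus_profile(rec, layer)
    expect_equal(unname(p$shares["Z"]), 100 * n_in / n)
  }
})

test_that("shares are invariant to record order", {
  layer <- band_layer(5, labels = c("a", "b"))
  set.seed(8)
  rec <- toy_records(lon = runif(30, 0.5, 9.5), lat = runif(30, 0.5, 9.5))
  p1 <- genus_profile(rec, layer)
  p2 <- genus_profile(rec[sample(30), ], layer)
  expect_equal(p1$shares[sort(names(p1$shares))],
               p2$shares[sort(names(p2$shares))])
})

test_that("regular subsampling returns the exact target, deterministically", {
  set.seed(12)
  rec <- toy_records(lon = runif(2000, 0, 10), lat = runif(2000, 0, 10),
                     catalog = sprintf("C%04d", 1:2000))
  sub1 <- regular_subsample(rec, target = 1000, seed = 99)
  sub2 <- regular_subsample(rec, target = 1000, seed = 99)
  expect_equal(nrow(sub1), 1000)
  expect_identical(sub1, sub2)
  # below-target input passes through unchanged
  small <- rec[1:900, ]
  expect_identical(regular_subsample(small, target = 1000), small)
})

test_that("regular subsample is spatially more even than a random pick", {
  set.seed(13)
  rec <- toy_records(lon = runif(2000, 0, 10), lat = runif(2000, 0, 10),
                     catalog = sprintf("C%04d", 1:2000))
  sub <- regular_subsample(rec, target = 1000, seed = 7)
  nn_mean <- function(df) {
    d <- as.matrix(stats::dist(cbind(df$longitude, df$latitude)))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  rand <- rec[sample(2000, 1000), ]
  expect_gt(nn_mean(sub), nn_mean(rand))
})

test_that("clade profile pools genera, subsampling only the oversampled", {
  layer <- band_layer(5, labels = c("X", "Y"))
  mk_genus <- function(genus, n, lat_rng, cat0) {
    set.seed(cat0)
    toy_records(lon = runif(n, 0.2, 9.8),
                lat = runif(n, lat_rng[1], lat_rng[2]), genus = genus,
                catalog = sprintf("G%d-%05d", cat0, 1:n))
  }
  # no genus oversampled: pooled percentage of all records
  two <- rbind(mk_genus("GenusA", 100, c(0.2, 4.8), 1),
               mk_genus("GenusB", 100, c(5.2, 9.8), 2))
  p <- clade_profile(two, layer)
  expect_equal(unname(p$shares[c("X", "Y")]), c(50, 50))
  expect_equal(p$n_used, 200)
  # 2000-record genus (all in X) enters as 1000; 100-record genus in Y
  big <- rbind(mk_genus("GenusA", 2000, c(0.2, 4.8), 3),
               mk_genus("GenusB", 100, c(5.2, 9.8), 4))
  p <- clade_profile(big, layer, oversample_cap = 1500, target = 1000)
  expect_equal(p$n_used, 1100)
  expect_equal(unname(p$shares["X"]), 100 * 1000 / 1100)
  # exactly 1500 records is NOT oversampled (strict >)
  atcap <- rbind(mk_genus("GenusA", 1500, c(0.2, 4.8), 5),
                 mk_genus("GenusB", 100, c(5.2, 9.8), 6))
  expect_equal(clade_profile(atcap, layer)$n_used, 1600)
})

test_that("a single-category layer assigns every genus at 100%", {
  layer <- constant_layer("tropical", grid_def(0, 0, 10, 10, 1))
  set.seed(3)
  for (g in c("GenusA", "GenusB")) {
    rec <- toy_records(lon = runif(12, 0.5, 9.5), lat = runif(12, 0.5, 9.5),
                       genus = g)
    p <- genus_profile(rec, layer)
    expect_equal(unname(p$shares), 100)
    expect_equal(p$assignment, "tropical")
  }
})

test_that("qualitative comparison distinguishes direct, merged and equivocal", {
  mkprof <- function(taxon, shares) {
    p <- genus_profile(toy_records(1.5, 1.5, genus = taxon),
                       constant_layer("x"))
    p$shares <- shares
    p$assignment <- if (max(shares) > 75)
      names(shares)[which.max(shares)] else "equivocal"
    p
  }
  profs <- list(mkprof("GenusA", c(tropical = 90, subtropical = 10)),
                mkprof("GenusB", c(subtropical = 80, tropical = 20)),
                mkprof("GenusC", c(tropical = 60, temperate = 40)),
                mkprof("GenusD", c(temperate = 85, tropical = 15)))
  labels <- c(GenusA = "tropical", GenusB = "tropical",
              GenusC = "tropical", GenusD = "tropical")
  got <- compare_to_qualitative(profs, labels,
                                merge_rules = c(subtropical = "tropical"))
  expect_equal(got$agreement,
               c("agree", "agree-after-merge", "equivocal", "disagree"))
  expect_error(compare_to_qualitative(profs, labels[-1], character(0)),
               "GenusA")
})

test_that("profiles export to a long-format table", {
  layer <- band_layer(5, labels = c("a", "b"))
  rec <- toy_records(lon = c(1, 2, 3) + 0.2, lat = c(2, 2, 8))
  tab <- profiles_to_table(list(genus_profile(rec, layer)))
  expect_named(tab, c("taxon", "classification", "category", "share",
                      "n_used", "n_unclassified", "assignment"))
  expect_equal(sum(tab$share), 100)
})
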