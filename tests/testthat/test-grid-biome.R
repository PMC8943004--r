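test_that("ESRI ASCII grids round-trip through write and read", {
  set.seed(5)
  g <- ascii_grid(matrix(sample(c(1:14, NA), 48, TRUE), 6, 8), -10, 20, 0.5)
  p <- file.path(tempdir(), "g.asc")
  write_ascii_grid(g, p)
  g2 <- read_ascii_grid(p)
  expect_equal(g2$values, g$values)
  expect_equal(g2[c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")],
               g[c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")])
})

test_that("standard header permutations and case variants are accepted", {
  p <- file.path(tempdir(), "perm.asc")
  writeLines(c("NROWS 2", "ncols 3", "CellSize 1.0", "xllcorner 0",
               "NODATA_value -1", "yllcorner 10",
               "1 2 3", "4 -1 6"), p)
  g <- read_ascii_grid(p)
  expect_equal(g$ncols, 3)
  expect_equal(g$values[2, 2], NA_real_)
  expect_equal(g$values[1, ], c(1, 2, 3))
  # missing mandatory key is an error
  writeLines(c("ncols 2", "nrows 1", "cellsize 1", "yllcorner 0", "1 2"), p)
  expect_error(read_ascii_grid(p), "xllcorner")
  # body size mismatch is an error
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "1 2 3"), p)
  expect_error(read_ascii_grid(p), "expected")
})

test_that("point sampling uses the half-open east/north edge convention", {
  g <- ascii_grid(matrix(1:9, 3, 3, byrow = TRUE), 0, 0, 1)
  # cell centre
  expect_equal(sample_point(g, 0.5, 2.5), 1)
  expect_equal(sample_point(g, 2.5, 0.5), 9)
  # a point on the shared edge belongs to the cell to its east / north
  expect_equal(sample_point(g, 1, 0.5), 8)   # east neighbour of col 1
  expect_equal(sample_point(g, 0.5, 1), 4)   # north neighbour of row 3
  # random points equal brute-force index arithmetic
  set.seed(6)
  lon <- runif(50, 0, 3 - 1e-9); lat <- runif(50, 0, 3 - 1e-9)
  m <- g$values
  expect_equal(sample_point(g, lon, lat),
               m[cbind(3 - floor(lat), floor(lon) + 1)])
  expect_warning(out <- sample_point(g, -1, 1), "outside")
  expect_true(is.na(out))
})

test_that("zonal majority counts cell centres with area weighting", {
  # 16 cells in one latitude row-band: 10 of code 7, 6 of code 13
  m <- matrix(c(rep(7, 10), rep(13, 6)), 1, 16)
  g <- ascii_grid(m, 0, 10, 1)
  z <- zonal_majority(g, 0, 16, 10, 11)
  expect_equal(z$majority, 7)
  expect_equal(z$fraction, 0.625)
  expect_false(z$tie)
  expect_equal(sum(z$fractions), 1)
  # uniform raster: fraction 1
  zu <- zonal_majority(ascii_grid(matrix(13, 4, 4), 0, 0, 1), 0, 4, 0, 4)
  expect_equal(zu$majority, 13); expect_equal(zu$fraction, 1)
  # 8 vs 8 tie at equal latitude: lower code wins, tie flagged
  zt <- zonal_majority(ascii_grid(matrix(c(rep(4, 8), rep(2, 8)), 1, 16), 0, 0, 1),
                       0, 16, 0, 1)
  expect_equal(zt$majority, 2)
  expect_true(zt$tie)
})

test_that("area weighting favours lower-latitude cells of equal count", {
  # code 1 occupies a high-latitude row, code 2 a lower-latitude row
  m <- rbind(rep(1, 4), rep(2, 4))
  g <- ascii_grid(m, 0, 59, 1)   # rows at lat 60.5 (code 1) and 59.5 (code 2)
  z <- zonal_majority(g, 0, 4, 59, 61)
  o <- oracle_zonal(g, c(0, 4, 59, 61))
  expect_equal(z$majority, 2)
  expect_equal(z$fraction, unname(o$fraction))
  expect_gt(z$fractions[["2"]], z$fractions[["1"]])
  # unweighted counts tie back to the lower code
  zc <- zonal_majority(g, 0, 4, 59, 61, area_weighted = FALSE)
  expect_true(zc$tie)
})

test_that("zonal majority equals brute-force enumeration on random boxes", {
  set.seed(8)
  m <- matrix(sample(1:5, 30 * 40, TRUE), 30, 40)
  g <- ascii_grid(m, -20, 10, 1)
  for (i in 1:25) {
    lon0 <- runif(1, -20, 15); lat0 <- runif(1, 10, 35)
    box <- c(lon0, lon0 + runif(1, 1, 8), lat0, lat0 + runif(1, 1, 8))
    z <- zonal_majority(g, box[1], box[2], box[3], box[4])
    o <- oracle_zonal(g, box)
    if (is.null(o)) {
      expect_true(is.na(z$majority))
    } else {
      expect_equal(z$majority, o$majority)
      expect_equal(unname(z$fractions), unname(o$fractions))
    }
  }
})

test_that("shrinking the CI box converges zonal majority to point sampling", {
  set.seed(12)
  m <- matrix(sample(1:5, 400, TRUE), 20, 20)
  g <- ascii_grid(m, 0, 0, 1)
  for (i in 1:10) {
    lon <- runif(1, 2, 18); lat <- runif(1, 2, 18)
    # a box tight around the containing cell's centre holds only that cell
    cx <- floor(lon) + 0.5; cy <- floor(lat) + 0.5
    z <- zonal_majority(g, cx - 0.499, cx + 0.499, cy - 0.499, cy + 0.499)
    expect_equal(z$majority, sample_point(g, lon, lat))
    expect_equal(z$fraction, 1)
  }
})

test_that("biome categories follow the barrier map and reject unknown codes", {
  expect_identical(categorize_biome(13), "barrier")    # Deserts & Xeric Shrublands
  expect_identical(categorize_biome(12), "barrier")    # Mediterranean scrub
  expect_identical(categorize_biome(1), "barrier")     # Tropical moist forest (soft)
  expect_identical(categorize_biome(8), "hospitable")  # Temperate grasslands
  expect_identical(categorize_biome(7), "hospitable")
  expect_error(categorize_biome(99), "99")
  expect_identical(categorize_biome(NA), NA_character_)
})

test_that("singleton biomes are excluded per grouping", {
  rec <- data.frame(biome_code = c(rep(13, 30), rep(7, 19), 6))
  out <- exclude_singleton_biomes(rec)
  expect_identical(nrow(out), 49L)
  expect_false(6 %in% out$biome_code)
  # all codes at >= 2 occurrences: unchanged
  rec2 <- data.frame(biome_code = rep(c(1, 2), 5))
  expect_identical(nrow(exclude_singleton_biomes(rec2)), 10L)
  # crafted counts equal a brute-force frequency filter
  set.seed(13)
  rec3 <- data.frame(biome_code = sample(1:6, 40, TRUE))
  grp <- sample(c("a", "b"), 40, TRUE)
  out3 <- exclude_singleton_biomes(rec3, group = grp)
  keep <- ave(rec3$biome_code, grp, rec3$biome_code, FUN = length) >= 2
  expect_identical(nrow(out3), sum(keep))
})
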