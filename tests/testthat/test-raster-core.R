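test_that("grid geometry round-trips between indices and coordinates", {
  g <- grid_spec(5, 31, 0.25, 20, 30)
  lon <- cell_lons(g); lat <- cell_lats(g)
  expect_length(lon, 30)
  expect_length(lat, 20)
  expect_gt(lat[1], lat[20])  # row 1 is northernmost
  loc <- locate_cells(g, rep(lon, times = 20), rep(lat, each = 30))
  expect_equal(loc$row, rep(1:20, each = 30))
  expect_equal(loc$col, rep(1:30, times = 20))
  out <- locate_cells(g, c(4.9, 100), c(35, 35))
  expect_true(all(is.na(out$cell)))
})

test_that("resampling preserves constants and matches hand arithmetic", {
  const <- toy_layer(rep(7, 16), 4, 4, cell_size = 0.1)
  tgt_coarse <- grid_spec(0, 40, 0.2, 2, 2)
  tgt_fine <- grid_spec(0.05, 40.05, 0.05, 6, 6)
  down <- resample_layer(const, tgt_coarse, "mean_downscale")
  up <- resample_layer(const, tgt_fine, "bilinear_upscale")
  expect_true(all(down$values == 7))
  expect_true(all(up$values == 7, na.rm = TRUE))

  # 2x2 {0,2,4,6} averaged into one cell -> 3
  src <- toy_layer(c(0, 2, 4, 6), 2, 2, cell_size = 0.1)
  one <- resample_layer(src, grid_spec(0, 40, 0.2, 1, 1), "mean_downscale")
  expect_equal(one$values[1, 1], 3)

  # bilinear at the exact centre of 4 source centres: mean of the corners
  src2 <- toy_layer(c(0, 1, 1, 2), 2, 2, cell_size = 0.1)
  mid <- grid_spec(0.05, 40.05, 0.1, 1, 1)  # centre at (0.1, 40.1)
  expect_equal(resample_layer(src2, mid, "bilinear_upscale")$values[1, 1], 1)
})

test_that("resampling to the identical grid is the identity", {
  ly <- toy_layer(rnorm(25), 5, 5)
  ly$values[3, 3] <- NA
  for (dir in c("mean_downscale", "bilinear_upscale"))
    expect_equal(resample_layer(ly, ly$grid, dir)$values, ly$values)
})

test_that("mean downscale conserves the global mean on nested grids", {
  set.seed(3)
  ly <- toy_layer(rnorm(144), 12, 12, cell_size = 0.1)
  down <- resample_layer(ly, grid_spec(0, 40, 0.3, 4, 4), "mean_downscale")
  expect_equal(mean(down$values), mean(ly$values))
})

test_that("resampling rejects inconsistent directions and empty overlap", {
  ly <- toy_layer(rnorm(25), 5, 5, cell_size = 0.1)
  expect_error(resample_layer(ly, grid_spec(0, 40, 0.05, 10, 10),
                              "mean_downscale"), "cell_size")
  expect_error(resample_layer(ly, grid_spec(0, 40, 0.2, 2, 2),
                              "bilinear_upscale"), "cell_size")
  expect_error(resample_layer(ly, grid_spec(50, 0, 0.2, 2, 2),
                              "mean_downscale"), "overlap")
  expect_error(resample_layer(ly, grid_spec(50, 0, 0.05, 2, 2),
                              "bilinear_upscale"), "overlap")
})

test_that("Horn slope is zero on a flat surface and exact on a plane", {
  flat <- toy_layer(rep(-500, 100), 10, 10)
  s <- horn_slope(flat)
  expect_true(all(s$values[2:9, 2:9] == 0))
  expect_true(all(is.na(s$values[1, ])))  # border nodata

  # plane rising 0.1 m per metre eastward: slope = atan(0.1) everywhere
  g <- grid_spec(0, 40, 0.01, 12, 12)
  dx_m <- 0.01 * pi / 180 * 6371000 * cos(cell_lats(g) * pi / 180)
  z <- outer(seq_len(12), seq_len(12),
             function(i, j) 0.1 * (j - 1) * dx_m[i])
  # make the plane exact per row (dx varies with latitude row)
  ramp <- raster_layer(g, z, "bathy", "m")
  s2 <- horn_slope(ramp)
  inner <- s2$values[3:10, 2:11]
  expect_equal(inner, matrix(atan(0.1) * 180 / pi, 8, 10),
               tolerance = 1e-3)
})

test_that("Horn slope at a hand-built 3x3 window matches the formula", {
  g <- grid_spec(10, 38, 0.041, 3, 3)
  z <- matrix(c(-640, -650, -660,
                -630, -645, -655,
                -625, -640, -648), 3, 3, byrow = TRUE)
  s <- horn_slope(raster_layer(g, z, "b", "m"))
  dy <- 0.041 * pi / 180 * 6371000
  dx <- dy * cos(cell_lats(g)[2] * pi / 180)
  dzdx <- ((z[1, 3] + 2 * z[2, 3] + z[3, 3]) -
             (z[1, 1] + 2 * z[2, 1] + z[3, 1])) / (8 * dx)
  dzdy <- ((z[1, 1] + 2 * z[1, 2] + z[1, 3]) -
             (z[3, 1] + 2 * z[3, 2] + z[3, 3])) / (8 * dy)
  expect_equal(s$values[2, 2],
               atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi)
  expect_true(all(is.na(s$values[-2, ])))
})

test_that("Horn slope stays in [0, 90) and propagates nodata", {
  set.seed(9)
  ly <- toy_layer(-500 + 400 * rnorm(400), 20, 20)
  ly$values[10, 10] <- NA
  s <- horn_slope(ly)
  v <- s$values[!is.na(s$values)]
  expect_true(all(v >= 0 & v < 90))
  # the 8 neighbours of the nodata cell (and itself) are nodata
  expect_true(all(is.na(s$values[9:11, 9:11])))
  expect_error(horn_slope(toy_layer(rep(1, 4), 2, 2)), "3x3")
})

test_that("cell areas follow the spherical area element", {
  g <- grid_spec(0, 0, 0.041, 200, 4)
  a <- cell_area(g)
  expect_true(all(a$values[, 1] == a$values[, 3]))  # same latitude, same area
  # strictly decreasing toward higher latitude
  expect_true(all(diff(a$values[, 1]) > 0))  # row 1 = north = smaller

  # quadrature oracle for a 0.041-degree cell centred at 38 N
  g38 <- grid_spec(10, 38 - 0.0205, 0.041, 1, 1)
  f <- function(phi) 6371^2 * (0.041 * pi / 180) * cos(phi)
  oracle <- stats::integrate(f, (38 - 0.0205) * pi / 180,
                             (38 + 0.0205) * pi / 180, rel.tol = 1e-12)$value
  expect_equal(cell_area(g38)$values[1, 1], oracle, tolerance = 1e-10)
})

test_that("cell areas over a 1x1 degree box match the closed form", {
  g <- grid_spec(7, 40, 0.05, 20, 20)
  total <- sum(cell_area(g)$values)
  closed <- 6371^2 * (pi / 180) * (sin(41 * pi / 180) - sin(40 * pi / 180))
  expect_equal(total, closed, tolerance = 1e-10)
})

test_that("ASCII grid write/read round-trips values, mask and grid", {
  set.seed(5)
  ly <- toy_layer(rnorm(48), 6, 8, lon_min = 3.2, lat_min = 35.7,
                  cell_size = 0.041)
  ly$values[2, 5] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(ly, path)
  back <- read_raster(path)
  expect_identical(back$values, ly$values)
  expect_equal(back$grid, ly$grid)
})

test_that("nodata sentinel and malformed headers are handled", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 40",
               "cellsize 0.1", "NODATA_value -9999",
               "1 -9999", "3 4"), path)
  ly <- read_raster(path)
  expect_true(is.na(ly$values[1, 2]))
  expect_equal(ly$values[2, 2], 4)

  bad <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcenter 0", "yllcenter 40",
               "cellsize 0.1", "NODATA_value -9999", "1 2", "3 4"), bad)
  expect_error(read_raster(bad), "corner-registered")

  twoband <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 40",
               "cellsize 0.1", "NODATA_value -9999",
               "1 2", "3 4", "5 6", "7 8"), twoband)
  expect_error(read_raster(twoband), "multi-band")
})
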