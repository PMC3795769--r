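# Raster model, terrain derivatives, distances, extraction and ASCII I/O.

test_that("slope is zero on flat surfaces and 45 degrees on a unit plane", {
  flat <- new_grid(matrix(7, 6, 6), cell_size = 5, y_origin = 30)
  s <- derive_slope(flat)
  expect_true(all(interior(s$values) == 0))
  expect_true(all(is.na(s$values[1, ])))  # edges are nodata

  plane <- plane_dem(ax = 1, ay = 0)
  s <- derive_slope(plane)
  expect_equal(unname(interior(s$values)),
               matrix(45, 5, 5), tolerance = 1e-12)
})

test_that("slope matches a direct per-cell Horn stencil on a random DEM", {
  dem <- rand_dem(5, 5, seed = 1, cell_size = 10)
  s <- derive_slope(dem)
  m <- dem$values
  for (r in 2:4) for (c in 2:4) {
    a <- m[r - 1, c - 1]; b <- m[r - 1, c]; cc <- m[r - 1, c + 1]
    d <- m[r, c - 1]; f <- m[r, c + 1]
    g <- m[r + 1, c - 1]; h <- m[r + 1, c]; i <- m[r + 1, c + 1]
    gx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * 10)
    gy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * 10)
    expect_equal(s$values[r, c], atan(sqrt(gx^2 + gy^2)) * 180 / pi)
  }
})

test_that("slope rejects grids smaller than the stencil", {
  expect_error(derive_slope(new_grid(matrix(1, 2, 5))), "3 x 3")
})

test_that("aspect components recover axis-aligned and diagonal dips", {
  # z = -x: descends eastward -> eastness 1
  east <- derive_aspect_components(plane_dem(-1, 0))
  expect_equal(unname(interior(east$eastness$values)), matrix(1, 5, 5))
  expect_equal(unname(interior(east$northness$values)),
               matrix(0, 5, 5), tolerance = 1e-12)
  # z = -y: descends northward -> northness 1
  north <- derive_aspect_components(plane_dem(0, -1))
  expect_equal(unname(interior(north$northness$values)), matrix(1, 5, 5))
  # equal gradients northeast-ward: azimuth 45 degrees
  ne <- derive_aspect_components(plane_dem(-1, -1))
  expect_equal(unname(interior(ne$eastness$values)),
               matrix(sqrt(2) / 2, 5, 5), tolerance = 1e-12)
  expect_equal(unname(interior(ne$northness$values)),
               matrix(sqrt(2) / 2, 5, 5), tolerance = 1e-12)
})

test_that("eastness^2 + northness^2 is 1 on sloped cells and 0 on flat ones", {
  dem <- rand_dem(8, 8, seed = 3)
  a <- derive_aspect_components(dem)
  ss <- a$eastness$values^2 + a$northness$values^2
  expect_equal(unname(interior(ss)), matrix(1, 6, 6), tolerance = 1e-12)
  flat <- new_grid(matrix(2, 5, 5))
  af <- derive_aspect_components(flat)
  expect_true(all(interior(af$eastness$values) == 0))
  expect_true(all(interior(af$northness$values) == 0))
})

test_that("terrain derivatives commute with translation of the origin", {
  dem <- rand_dem(6, 7, seed = 8)
  moved <- dem; moved$x_origin <- 1234.5; moved$y_origin <- dem$y_origin - 987
  expect_identical(derive_slope(dem)$values, derive_slope(moved)$values)
  a1 <- derive_aspect_components(dem); a2 <- derive_aspect_components(moved)
  expect_identical(a1$eastness$values, a2$eastness$values)
  expect_identical(a1$northness$values, a2$northness$values)
})

test_that("distance to shore handles collinear and 3-4-5 offsets exactly", {
  m <- matrix(0, 8, 8); m[2, 2] <- 1
  g <- new_grid(m, cell_size = 90, y_origin = 8 * 90)
  d <- distance_to_shore(g)
  expect_equal(d$values[2, 2], 0)
  expect_equal(d$values[2, 5], 270)      # 3 cells due east
  expect_equal(d$values[6, 5], 450)      # (3, 4) cells: 3-4-5 triangle
  expect_error(distance_to_shore(new_grid(matrix(0, 5, 5))), "no shore")
})

test_that("distance to shore equals brute force over all shore cells", {
  set.seed(11)
  m <- matrix(as.numeric(runif(30 * 25) < 0.05), 30, 25)
  m[1, 1] <- 1
  g <- new_grid(m, cell_size = 7, y_origin = 30 * 7)
  d <- distance_to_shore(g)
  ctr <- cell_centers(g)
  shore <- which(m != 0)
  brute <- apply(ctr, 1, function(p)
    min(sqrt((p[1] - ctr[shore, 1])^2 + (p[2] - ctr[shore, 2])^2)))
  expect_equal(as.vector(d$values), brute, tolerance = 1e-12)
})

test_that("point extraction follows the half-open cell convention", {
  g <- new_grid(matrix(1:12, 3, 4), cell_size = 10, y_origin = 30)
  st <- new_stack(list(v = g))
  # centre of cell (2, 3): x in [20, 30), y in (0, 10]... row 2 -> y in (10, 20]
  out <- extract_at_points(st, data.frame(x = 25, y = 15), quiet = TRUE)
  expect_equal(out$v, g$values[2, 3])
  # x on the shared edge x = 20 belongs to the right-hand cell (half-open)
  out <- extract_at_points(st, data.frame(x = 20, y = 15), quiet = TRUE)
  expect_equal(out$v, g$values[2, 3])
  # y on the shared edge y = 20 is the closed top edge of row 2
  out <- extract_at_points(st, data.frame(x = 25, y = 20), quiet = TRUE)
  expect_equal(out$v, g$values[2, 3])
  # brute-force containment check on random points
  set.seed(4)
  pts <- data.frame(x = runif(60, -5, 45), y = runif(60, -5, 35))
  loc <- locate_cells(g, pts$x, pts$y)
  for (i in seq_len(60)) {
    inside <- pts$x[i] >= 0 & pts$x[i] < 40 & pts$y[i] > 0 & pts$y[i] <= 30
    expect_equal(loc$inside[i], inside)
    if (inside) {
      r <- loc$row[i]; c <- loc$col[i]
      expect_true(pts$x[i] >= (c - 1) * 10 && pts$x[i] < c * 10)
      expect_true(pts$y[i] > 30 - r * 10 && pts$y[i] <= 30 - (r - 1) * 10)
    }
  }
})

test_that("points on nodata or outside the grid are flagged and excluded", {
  m <- matrix(1, 3, 3); m[2, 2] <- NA
  st <- new_stack(list(v = new_grid(m, cell_size = 1, y_origin = 3)))
  pts <- data.frame(x = c(0.5, 1.5, 9), y = c(0.5, 1.5, 9))
  expect_message(out <- extract_at_points(st, pts), "2 point")
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "excluded"), c(2L, 3L))
  expect_error(extract_at_points(st, data.frame(x = 99, y = 99)),
               "no point")
})

test_that("ESRI ASCII round trip is bit-exact including mask and transform", {
  set.seed(5)
  m <- matrix(rnorm(20 * 15), 20, 15)
  m[sample(300, 12)] <- NA
  g <- new_grid(m, x_origin = 123456.789, y_origin = 654321.5,
                cell_size = 90.125)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, path)
  g2 <- read_ascii_grid(path)
  expect_identical(g2$values, g$values)
  expect_identical(c(g2$x_origin, g2$y_origin, g2$cell_size),
                   c(g$x_origin, g$y_origin, g$cell_size))
})

test_that("stacks reject non-co-registered layers", {
  a <- new_grid(matrix(1, 4, 4)); b <- new_grid(matrix(1, 4, 4), cell_size = 2)
  expect_error(new_stack(list(a = a, b = b)), "co-registered")
})
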