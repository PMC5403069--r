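test_that("calibration converts raster size and field width to mm/px", {
  expect_equal(calibrate(300, 3.0)$mm_per_px_x, 0.01)
  expect_equal(calibrate(304, 3.0)$mm_per_px_x, 3 / 304)
  expect_equal(calibrate(1, 3.0)$mm_per_px_y, 3.0)
  expect_error(calibrate(0, 3), class = "octaquant_parameter_error")
  expect_error(calibrate(304, -1), class = "octaquant_parameter_error")
})

test_that("contour area matches closed forms on simple shapes", {
  sq <- faz_contour(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
  expect_equal(contour_area(sq, calibrate(300, 3)), 1.0)
  tri <- faz_contour(cbind(c(0, 10, 0), c(0, 0, 10)))
  expect_equal(contour_area(tri, 0.01), 0.005)
})

test_that("area and perimeter are orientation-invariant and scale-equivariant", {
  set.seed(41)
  th <- sort(runif(12, 0, 2 * pi))
  r <- runif(12, 5, 20)
  v <- cbind(50 + r * cos(th), 50 + r * sin(th))
  poly <- faz_contour(v)
  rev_poly <- faz_contour(v[nrow(v):1, ])
  expect_equal(contour_area(poly, 0.01), contour_area(rev_poly, 0.01))
  expect_equal(contour_perimeter(poly, 0.01), contour_perimeter(rev_poly, 0.01))
  # doubling the scale doubles perimeter and quadruples area exactly
  expect_equal(contour_area(poly, 0.02), 4 * contour_area(poly, 0.01))
  expect_equal(contour_perimeter(poly, 0.02), 2 * contour_perimeter(poly, 0.01))
})

test_that("shoelace area agrees with a Monte-Carlo point-in-polygon oracle", {
  set.seed(7)
  th <- sort(runif(12, 0, 2 * pi))
  r <- runif(12, 10, 30)
  v <- cbind(40 + r * cos(th), 40 + r * sin(th))
  area_px <- contour_area(faz_contour(v), 1)
  mc <- mc_polygon_area(v, n_points = 1e6)
  expect_lt(abs(area_px - mc) / area_px, 0.005)
})

test_that("perimeter handles squares, collinear traces, and fine circles", {
  sq <- faz_contour(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
  expect_equal(contour_perimeter(sq, 0.01), 4.0)
  # degenerate collinear trace: out-and-back, twice the segment length
  flat <- faz_contour(cbind(c(0, 5, 10), c(0, 0, 0)))
  expect_warning(p <- contour_perimeter(flat, 1), "degenerate")
  expect_equal(p, 20)
  # 360-gon approximation of a circle of radius 0.5 mm
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- faz_contour(cbind(50 * cos(th), 50 * sin(th)))
  exact_ngon <- 360 * 2 * 50 * sin(pi / 360) * 0.01
  expect_equal(contour_perimeter(circ, 0.01), exact_ngon)
  expect_lt(abs(contour_perimeter(circ, 0.01) - 2 * pi * 0.5) / (pi), 1e-4)
})

test_that("self-intersecting traces are rejected with the crossing named", {
  bowtie <- cbind(c(0, 10, 10, 0), c(0, 10, 0, 10))
  expect_error(contour_area(faz_contour(bowtie), 0.01),
               regexp = "self-intersecting.*edge",
               class = "octaquant_validation_error")
})

test_that("contour constructor validates input and deduplicates closure", {
  expect_error(faz_contour(cbind(c(0, 1), c(0, 1))),
               class = "octaquant_validation_error")
  expect_warning(v <- faz_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 0))),
                 "duplicate closing vertex")
  expect_equal(nrow(v), 3L)
})

test_that("FAZ grade follows the 0-4 band definition and is monotone", {
  expect_identical(grade_faz(0), 0L)
  expect_identical(grade_faz(1), 4L)
  expect_identical(grade_faz(0.6), 3L)
  # dense-grid sweep against the piecewise definition
  eps <- 0.05
  f <- seq(0, 1, by = 0.001)
  ref <- ifelse(f == 0, 0L,
          ifelse(f <= eps, 1L,
            ifelse(f < 0.5, 2L,
              ifelse(f < 1, 3L, 4L))))
  g <- grade_faz(f, questionable_epsilon = eps)
  expect_identical(as.integer(g), ref)
  expect_true(all(diff(g) >= 0))  # monotone step function
  expect_error(grade_faz(-0.1), class = "octaquant_parameter_error")
  expect_error(grade_faz(1.5), class = "octaquant_parameter_error")
})

test_that("disrupted-border fraction recovers generator ground truth", {
  full <- small_scene(seed = 21, size = 160, speckle_sd = 0)
  expect_equal(measure_disruption(full$truth$masks$vessel, full$truth$polygon), 0)
  half <- generate_angiogram(vascular_scene_params(
    image_size_px = 160, seed = 22, arcade_disruption_fraction = 0.5,
    speckle_sd = 0))
  m <- measure_disruption(half$truth$masks$vessel, half$truth$polygon)
  expect_lt(abs(m - 0.5), 0.05)
  empty <- matrix(FALSE, 160, 160)
  expect_warning(d <- measure_disruption(empty, half$truth$polygon),
                 "empty arcade mask")
  expect_equal(d, 1.0)
})

test_that("morphometry on ground-truth polygons matches stored truth", {
  # recovery invariant: speckle off, grid of FAZ areas
  scale_err <- function(area) {
    sc <- generate_angiogram(vascular_scene_params(
      faz_area_mm2 = area, speckle_sd = 0, seed = 31))
    px <- sc$image$scale$mm_per_px_x
    c(area_err = abs(contour_area(sc$truth$polygon, sc$image$scale) -
                       sc$truth$area_mm2) / px^2,
      per_err = abs(contour_perimeter(sc$truth$polygon, sc$image$scale) -
                      sc$truth$perimeter_mm) / px)
  }
  errs <- vapply(c(0.15, 0.45, 0.9), scale_err, numeric(2L))
  expect_true(all(errs["area_err", ] < 1))   # within 1 pixel-area
  expect_true(all(errs["per_err", ] < 2))    # within 2 pixel-lengths
})

test_that("isoperimetric inequality holds for measured FAZ metrics", {
  for (seed in 1:5) {
    sc <- small_scene(seed = seed, faz_irregularity = runif(1))
    a <- contour_area(sc$truth$polygon, sc$image$scale)
    p <- contour_perimeter(sc$truth$polygon, sc$image$scale)
    expect_gte(p^2, 4 * pi * a)
  }
})
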