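#' Pixel-to-millimetre calibration for an en-face field
#'
#' En-face angiograms cover a known square field (3 x 3 mm in the standard
#' macular protocol); metric measurements first set the image scale from the
#' raster size and the field width.
#'
#' @param image_size_px side of the square raster in pixels.
#' @param field_mm physical side of the imaged field in millimetres.
#' @return A `pixel_scale` object with `mm_per_px_x` and `mm_per_px_y`.
#' @examples
#' calibrate(304, 3.0)
#' @export
calibrate <- function(image_size_px, field_mm = 3.0) {
  check_positive(image_size_px, "image_size_px")
  check_positive(field_mm, "field_mm")
  s <- field_mm / image_size_px
  structure(list(mm_per_px_x = s, mm_per_px_y = s), class = "pixel_scale")
}

#' @export
print.pixel_scale <- function(x, ...) {
  cat(sprintf("<pixel_scale> %.6g mm/px (x) x %.6g mm/px (y)\n",
              x$mm_per_px_x, x$mm_per_px_y))
  invisible(x)
}

as_pixel_scale <- function(scale) {
  if (inherits(scale, "pixel_scale")) return(scale)
  if (is.numeric(scale) && length(scale) == 1L && scale > 0) {
    return(structure(list(mm_per_px_x = scale, mm_per_px_y = scale),
                     class = "pixel_scale"))
  }
  stop_param("`scale` must be a pixel_scale or a single positive mm/px value")
}

#' FAZ surface from a traced contour
#'
#' Absolute shoelace area of the closed polygon, converted to mm^2 by the
#' pixel scale. Orientation-independent; a self-intersecting trace is
#' rejected with the offending edge pair named.
#'
#' @param contour a [faz_contour()] (or n x 2 vertex matrix).
#' @param scale a [calibrate()] result, or a single mm/px value.
#' @return surface in mm^2.
#' @examples
#' sq <- faz_contour(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
#' contour_area(sq, calibrate(300, 3))  # 1 mm^2
#' @export
contour_area <- function(contour, scale) {
  v <- if (inherits(contour, "faz_contour")) contour else faz_contour(contour)
  scale <- as_pixel_scale(scale)
  assert_simple_polygon(v)
  abs(polygon_area_px(v)) * scale$mm_per_px_x * scale$mm_per_px_y
}

#' FAZ perimeter from a traced contour
#'
#' Sum of Euclidean edge lengths including the closing edge, in mm. The
#' polygon is used exactly as traced (no smoothing), so the value is
#' reproducible across reruns.
#'
#' @inheritParams contour_area
#' @return perimeter in mm.
#' @export
contour_perimeter <- function(contour, scale) {
  v <- if (inherits(contour, "faz_contour")) contour else faz_contour(contour)
  scale <- as_pixel_scale(scale)
  assert_simple_polygon(v)
  if (abs(polygon_area_px(v)) < .Machine$double.eps * nrow(v)) {
    warning("degenerate (collinear) contour: zero enclosed area", call. = FALSE)
  }
  # anisotropic scale: convert each edge component before taking lengths
  dx <- diff(c(v[, 1L], v[1L, 1L])) * scale$mm_per_px_x
  dy <- diff(c(v[, 2L], v[1L, 2L])) * scale$mm_per_px_y
  sum(sqrt(dx^2 + dy^2))
}

#' Ordinal FAZ contour grade from the disrupted-border fraction
#'
#' Maps the fraction of the FAZ border lacking the perifoveal capillary
#' arcade to the 0-4 ordinal grading convention: 0 = normal contour,
#' 1 = questionable disruption (fraction at most `questionable_epsilon`),
#' 2 = less than half disrupted, 3 = half or more disrupted,
#' 4 = contour completely altered. Monotone nondecreasing in the fraction.
#'
#' @param disrupted_fraction fraction of the border circumference without
#'   arcade, in [0, 1].
#' @param questionable_epsilon upper bound of the "questionable" band
#'   (grade 1); default 0.05.
#' @return integer grade in 0..4.
#' @examples
#' grade_faz(c(0, 0.03, 0.3, 0.6, 1))
#' @export
grade_faz <- function(disrupted_fraction, questionable_epsilon = 0.05) {
  if (!is.numeric(disrupted_fraction) || anyNA(disrupted_fraction) ||
      any(disrupted_fraction < 0) || any(disrupted_fraction > 1)) {
    stop_param("`disrupted_fraction` must lie in [0, 1]")
  }
  check_fraction(questionable_epsilon, "questionable_epsilon")
  f <- disrupted_fraction
  ifelse(f == 0, 0L,
    ifelse(f <= questionable_epsilon, 1L,
      ifelse(f < 0.5, 2L,
        ifelse(f < 1, 3L, 4L))))
}

#' Automated disrupted-border fraction from a vessel mask
#'
#' A surrogate for the human contour grader: the FAZ border is sampled at
#' regular intervals and a border sample counts as disrupted when the window
#' just outside it, along the outward normal, contains no perfused-vessel
#' pixel. Returns the disrupted fraction in [0, 1].
#'
#' @param arcade_mask logical matrix (same raster as the image, rows = y),
#'   TRUE where vessel/arcade pixels are present.
#' @param contour the FAZ contour in pixel coordinates.
#' @param n_samples number of border samples.
#' @param reach outward depth of the search window, pixels.
#' @param halfwidth tangential half-width of the search window, pixels.
#' @return disrupted fraction in [0, 1].
#' @export
measure_disruption <- function(arcade_mask, contour, n_samples = 180L,
                               reach = 6, halfwidth = 2) {
  if (!is.logical(arcade_mask) || !is.matrix(arcade_mask)) {
    stop_param("`arcade_mask` must be a logical matrix")
  }
  v <- if (inherits(contour, "faz_contour")) contour else faz_contour(contour)
  if (!any(arcade_mask)) {
    warning("empty arcade mask: whole border counted as disrupted", call. = FALSE)
    return(1.0)
  }
  nr <- nrow(arcade_mask); nc <- ncol(arcade_mask)
  # resample the closed polyline at arc-length-uniform positions
  closed <- rbind(v, v[1L, , drop = FALSE])
  seglen <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = n_samples + 1L)[-(n_samples + 1L)]
  px <- approx(cum, closed[, 1L], xout = s)$y
  py <- approx(cum, closed[, 2L], xout = s)$y
  # outward = away from the polygon centroid (FAZ contours are star-shaped
  # about the foveal centre, so the centroid normal is a safe outward proxy)
  cx <- mean(v[, 1L]); cy <- mean(v[, 2L])
  nx <- px - cx; ny <- py - cy
  nrm <- sqrt(nx^2 + ny^2); nrm[nrm == 0] <- 1
  nx <- nx / nrm; ny <- ny / nrm
  tx <- -ny; ty <- nx
  offs_out <- seq(1, reach, by = 1)
  offs_tan <- seq(-halfwidth, halfwidth, by = 1)
  disrupted <- vapply(seq_len(n_samples), function(i) {
    qx <- round(rep(px[i] + offs_out * nx[i], each = length(offs_tan)) +
                  rep(offs_tan * tx[i], times = length(offs_out)))
    qy <- round(rep(py[i] + offs_out * ny[i], each = length(offs_tan)) +
                  rep(offs_tan * ty[i], times = length(offs_out)))
    keep <- qx >= 0 & qx <= nc - 1L & qy >= 0 & qy <= nr - 1L
    if (!any(keep)) return(TRUE)
    !any(arcade_mask[cbind(qy[keep] + 1L, qx[keep] + 1L)])
  }, logical(1L))
  mean(disrupted)
}

#' Full FAZ morphometry for one traced contour
#'
#' Convenience wrapper returning surface, perimeter and (when a vessel mask
#' is supplied) the automated contour grade in one record.
#'
#' @inheritParams contour_area
#' @param arcade_mask optional logical vessel mask for automated grading.
#' @param questionable_epsilon passed to [grade_faz()].
#' @return list with `surface_mm2`, `perimeter_mm`, `disrupted_fraction`
#'   (NA without a mask) and `grade` (NA without a mask).
#' @export
faz_metrics <- function(contour, scale, arcade_mask = NULL,
                        questionable_epsilon = 0.05) {
  area <- contour_area(contour, scale)
  per <- contour_perimeter(contour, scale)
  frac <- NA_real_
  grade <- NA_integer_
  if (!is.null(arcade_mask)) {
    frac <- measure_disruption(arcade_mask, contour)
    grade <- grade_faz(frac, questionable_epsilon)
  }
  list(surface_mm2 = area, perimeter_mm = per,
       disrupted_fraction = frac, grade = grade)
}
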