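#' Nonperfusion index of an en-face angiogram
#'
#' The nonperfusion index (NPI) is the ratio between the cumulative area of
#' pixels whose brightness lies beneath a fixed 8-bit threshold (default
#' 45) and the total area of the picture. "Beneath" is read strictly
#' (value < threshold) by default; set `inclusive = TRUE` for a
#' value <= threshold sensitivity analysis. The index is computed over the
#' full frame, avascular zone included, so a single standardized number
#' captures both FAZ enlargement and perifoveal capillary dropout.
#'
#' @param image an [enface_angiogram()] (or a plain 0-255 integer matrix).
#' @param threshold 8-bit brightness threshold in \[0, 255\]; default 45.
#' @param inclusive count pixels equal to the threshold as nonperfused.
#' @return an `npi_result` list: `threshold`, `inclusive`, `below_count`,
#'   `total_count`, `npi` (= below_count / total_count, in \[0, 1\]).
#' @examples
#' img <- enface_angiogram(matrix(c(10, 10, 200, 200), 2), calibrate(2, 3))
#' compute_npi(img)$npi  # 0.5
#' @export
compute_npi <- function(image, threshold = 45L, inclusive = FALSE) {
  px <- angiogram_pixels(image)
  if (length(px) == 0L) stop_param("empty image")
  if (threshold < 0 || threshold > 255) {
    stop_param("`threshold` must lie in [0, 255]")
  }
  if (inherits(image, "enface_angiogram") && image$plexus == "deep") {
    warning("NPI is defined on the superficial plexus; computing on a ",
            "deep-plexus image anyway", call. = FALSE)
  }
  below <- if (inclusive) sum(px <= threshold) else sum(px < threshold)
  structure(list(threshold = as.integer(threshold), inclusive = inclusive,
                 below_count = as.integer(below),
                 total_count = length(px),
                 npi = below / length(px)),
            class = "npi_result")
}

#' @export
print.npi_result <- function(x, ...) {
  cat(sprintf("NPI = %.4f (%d / %d pixels %s %d)\n", x$npi, x$below_count,
              x$total_count, if (x$inclusive) "<=" else "<", x$threshold))
  invisible(x)
}

angiogram_pixels <- function(image) {
  if (inherits(image, "enface_angiogram")) return(image$pixels)
  if (is.matrix(image) && is.numeric(image)) return(image)
  stop_param("`image` must be an enface_angiogram or a numeric matrix")
}

# Frontier-based 4-connected flood fill on a logical matrix; returns the
# logical mask of the component containing (seed_x, seed_y), 0-based.
flood_component <- function(mask, seed_x, seed_y) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(FALSE, nr, nc)
  start <- seed_x * nr + (seed_y + 1L)  # column-major linear index
  if (!mask[start]) return(comp)
  comp[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    row <- (frontier - 1L) %% nr + 1L
    up <- frontier[row > 1L] - 1L
    down <- frontier[row < nr] + 1L
    left <- frontier[frontier > nr] - nr
    right <- frontier[frontier <= nr * (nc - 1L)] + nr
    nb <- c(up, down, left, right)
    nb <- unique(nb[mask[nb] & !comp[nb]])
    comp[nb] <- TRUE
    frontier <- nb
  }
  comp
}

#' Central nonperfused area on a deep-plexus image
#'
#' Measures the surface of the central nonperfused region: the 4-connected
#' component of below-threshold pixels containing the seed point (image
#' centre by default), converted to mm^2 by the pixel scale.
#'
#' @param image an [enface_angiogram()], normally the deep-plexus slab.
#' @param threshold 8-bit brightness threshold (default 45).
#' @param seed_point length-2 (x, y) pixel coordinate (0-based), or
#'   `"center"`.
#' @param inclusive as in [compute_npi()].
#' @return a `nonperfused_area_result` list: `area_mm2`,
#'   `component_pixel_count`, `threshold`, `seed_point`.
#' @export
measure_central_nonperfused_area <- function(image, threshold = 45L,
                                             seed_point = "center",
                                             inclusive = FALSE) {
  px <- angiogram_pixels(image)
  if (length(px) == 0L) stop_param("empty image")
  nr <- nrow(px); nc <- ncol(px)
  if (identical(seed_point, "center")) {
    seed_point <- c(floor((nc - 1) / 2), floor((nr - 1) / 2))
  }
  sx <- round(seed_point[1L]); sy <- round(seed_point[2L])
  if (sx < 0 || sx > nc - 1L || sy < 0 || sy > nr - 1L) {
    stop_param("seed point (", sx, ", ", sy, ") lies outside the raster")
  }
  dark <- if (inclusive) px <= threshold else px < threshold
  comp <- flood_component(dark, sx, sy)
  count <- sum(comp)
  if (count == 0L) {
    warning("seed pixel is not below threshold: empty nonperfused component",
            call. = FALSE)
  }
  scale <- if (inherits(image, "enface_angiogram")) image$scale else {
    structure(list(mm_per_px_x = 1, mm_per_px_y = 1), class = "pixel_scale")
  }
  structure(list(area_mm2 = count * scale$mm_per_px_x * scale$mm_per_px_y,
                 component_pixel_count = as.integer(count),
                 threshold = as.integer(threshold),
                 seed_point = c(sx, sy),
                 component_mask = comp),
            class = "nonperfused_area_result")
}

#' @export
print.nonperfused_area_result <- function(x, ...) {
  cat(sprintf("Central nonperfused area = %.4f mm^2 (%d px, threshold %d)\n",
              x$area_mm2, x$component_pixel_count, x$threshold))
  invisible(x)
}
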