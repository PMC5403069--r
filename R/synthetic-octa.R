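#' Parameters for a synthetic en-face angiogram scene
#'
#' Describes one synthetic 8-bit en-face angiogram: a square macular field
#' with a central avascular zone of controlled area and boundary
#' irregularity, a perifoveal capillary arcade that can be disrupted over a
#' controlled fraction of the border, a jittered capillary mesh, and
#' perifoveal dropout patches covering a controlled fraction of the
#' perifoveal annulus. Brightness is bimodal (vessel vs background) with
#' additive Gaussian speckle applied last.
#'
#' @param image_size_px side of the square raster (default 304 px, typical
#'   for a 3 x 3 mm macular cube export).
#' @param field_mm physical field width (default 3 mm).
#' @param faz_area_mm2 target avascular-zone area; must be smaller than the
#'   field area and fit inside the raster.
#' @param faz_irregularity 0 = circular boundary, 1 = strongly lobed
#'   (low-order Fourier perturbation of the radius).
#' @param arcade_disruption_fraction fraction of the border circumference
#'   lacking the perifoveal capillary arcade.
#' @param dropout_fraction target fraction of the perifoveal annulus
#'   converted to nonperfused patches (union of random disks).
#' @param capillary_density mesh edges per mm^2 (sets the lattice spacing).
#' @param vessel_brightness_mean,background_brightness_mean 8-bit brightness
#'   means; vessels must be brighter than background.
#' @param speckle_sd standard deviation of the additive Gaussian speckle.
#' @param seed RNG seed; same parameters + seed reproduce the image
#'   bit-exactly.
#' @return a validated `vascular_scene_params` list.
#' @export
vascular_scene_params <- function(image_size_px = 304L,
                                  field_mm = 3.0,
                                  faz_area_mm2 = 0.35,
                                  faz_irregularity = 0.3,
                                  arcade_disruption_fraction = 0,
                                  dropout_fraction = 0,
                                  capillary_density = 900,
                                  vessel_brightness_mean = 180L,
                                  background_brightness_mean = 20L,
                                  speckle_sd = 10,
                                  seed = 1L) {
  check_positive(image_size_px, "image_size_px")
  check_positive(field_mm, "field_mm")
  check_positive(faz_area_mm2, "faz_area_mm2")
  check_fraction(faz_irregularity, "faz_irregularity")
  check_fraction(arcade_disruption_fraction, "arcade_disruption_fraction")
  check_fraction(dropout_fraction, "dropout_fraction")
  check_positive(capillary_density, "capillary_density")
  if (speckle_sd < 0) stop_param("`speckle_sd` must be nonnegative")
  if (faz_area_mm2 >= field_mm^2) {
    stop_param("`faz_area_mm2` must be smaller than the field area (",
               field_mm^2, " mm^2)")
  }
  vb <- as.integer(vessel_brightness_mean)
  bb <- as.integer(background_brightness_mean)
  if (vb < 0 || vb > 255 || bb < 0 || bb > 255) {
    stop_param("brightness means must lie in [0, 255]")
  }
  if (vb <= bb) {
    stop_param("vessel brightness mean must exceed background brightness mean")
  }
  structure(list(
    image_size_px = as.integer(image_size_px), field_mm = field_mm,
    faz_area_mm2 = faz_area_mm2, faz_irregularity = faz_irregularity,
    arcade_disruption_fraction = arcade_disruption_fraction,
    dropout_fraction = dropout_fraction, capillary_density = capillary_density,
    vessel_brightness_mean = vb, background_brightness_mean = bb,
    speckle_sd = speckle_sd, seed = as.integer(seed)
  ), class = "vascular_scene_params")
}

#' Construct an en-face angiogram object
#'
#' @param pixels integer matrix (rows = y, columns = x) with values 0..255.
#' @param scale a [calibrate()] pixel scale.
#' @param plexus `"superficial"` or `"deep"`.
#' @param eye_id identifier carried into downstream tables.
#' @export
enface_angiogram <- function(pixels, scale, plexus = c("superficial", "deep"),
                             eye_id = "eye") {
  plexus <- match.arg(plexus)
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L) {
    stop_param("`pixels` must be a non-empty numeric matrix")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop_param("pixel values must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, scale = as_pixel_scale(scale),
                 plexus = plexus, eye_id = eye_id),
            class = "enface_angiogram")
}

#' @export
print.enface_angiogram <- function(x, ...) {
  cat(sprintf("<enface_angiogram> %s plexus, %d x %d px, %.4g mm/px (eye %s)\n",
              x$plexus, nrow(x$pixels), ncol(x$pixels),
              x$scale$mm_per_px_x, x$eye_id))
  invisible(x)
}

# Radial FAZ boundary: low-order Fourier perturbation of a circle, rescaled
# so the shoelace area of the vertex polygon hits the target exactly.
make_faz_polygon <- function(faz_area_mm2, irregularity, mm_per_px,
                             centre_px, n_vertices = 256L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- rep(1, n_vertices)
  if (irregularity > 0) {
    for (k in 2:5) {
      amp <- irregularity * runif(1L, 0.02, 0.10)
      phase <- runif(1L, 0, 2 * pi)
      r <- r + amp * cos(k * theta + phase)
    }
  }
  r <- pmax(r, 0.25)  # keep the boundary star-shaped and simple
  v_mm <- cbind(r * cos(theta), r * sin(theta))
  cur_area <- abs(polygon_area_px(v_mm))
  s <- sqrt(faz_area_mm2 / cur_area)
  r_px <- r * s / mm_per_px
  list(theta = theta, r_px = r_px,
       vertices = cbind(x = centre_px + r_px * cos(theta),
                        y = centre_px + r_px * sin(theta)))
}

# Periodic linear interpolation of vertex radii at query angles.
interp_radius <- function(theta, r_px, query) {
  th <- c(theta, 2 * pi)
  rr <- c(r_px, r_px[1L])
  stats::approx(th, rr, xout = query %% (2 * pi), rule = 2)$y
}

# Rasterise line segments with ~2 px stroke width into a logical mask.
stamp_segments <- function(mask, x1, y1, x2, y2) {
  n <- nrow(mask)
  ns <- pmax(2L, ceiling(pmax(abs(x2 - x1), abs(y2 - y1))) + 1L)
  idx <- rep.int(seq_along(ns), ns)
  t <- (sequence(ns) - 1) / (ns[idx] - 1)
  xs <- x1[idx] + t * (x2 - x1)[idx]
  ys <- y1[idx] + t * (y2 - y1)[idx]
  for (off in list(c(0, 0), c(1, 0), c(0, 1))) {
    xr <- round(xs) + off[1L]
    yr <- round(ys) + off[2L]
    keep <- xr >= 0 & xr < n & yr >= 0 & yr < n
    mask[cbind(yr[keep] + 1L, xr[keep] + 1L)] <- TRUE
  }
  mask
}

#' Generate a synthetic en-face angiogram with full ground truth
#'
#' Builds the scene described by [vascular_scene_params()]: the avascular
#' zone polygon, a perifoveal arcade ring with an optional disrupted arc, a
#' jittered capillary mesh, dropout disks in the perifoveal annulus, then
#' bimodal brightness plus additive Gaussian speckle clipped to \[0, 255\].
#' Identical parameters and seed reproduce the image bit-exactly.
#'
#' @param params a [vascular_scene_params()] object.
#' @param plexus slab label carried on the image (`"superficial"` or
#'   `"deep"`); the deep-plexus scene uses the same construction with its
#'   central nonperfused region in place of the FAZ.
#' @param eye_id identifier carried on the image.
#' @return list with `image` (an [enface_angiogram()]) and `truth`, the
#'   ground-truth record: `polygon` (a [faz_contour()]), `area_mm2`,
#'   `perimeter_mm`, `disruption_fraction`, `dropout_fraction` (achieved,
#'   measured on the union mask), `seed`, and `masks` (logical `faz`,
#'   `vessel`, `dropout`, `annulus` rasters).
#' @examples
#' sc <- generate_angiogram(vascular_scene_params(image_size_px = 128,
#'                                                faz_area_mm2 = 0.3,
#'                                                seed = 7))
#' compute_npi(sc$image)
#' @export
generate_angiogram <- function(params, plexus = c("superficial", "deep"),
                               eye_id = "synthetic") {
  if (!inherits(params, "vascular_scene_params")) {
    params <- do.call(vascular_scene_params, as.list(params))
  }
  plexus <- match.arg(plexus)
  p <- params
  n <- p$image_size_px
  mm_per_px <- p$field_mm / n
  c0 <- (n - 1) / 2
  border_band <- 10   # px cleared of vessels where the arcade is disrupted
                      # (deeper than the default grader search reach)
  annulus_gap <- 12   # px between FAZ border and the dropout annulus

  with_seed(p$seed, {
    faz <- make_faz_polygon(p$faz_area_mm2, p$faz_irregularity, mm_per_px, c0)
    if (max(faz$r_px) > n / 2 - (annulus_gap + 4)) {
      stop_param("FAZ does not fit the raster with its perifoveal annulus; ",
                 "reduce `faz_area_mm2` or enlarge the field")
    }

    # pixel-wise polar coordinates about the field centre (0-based pixels)
    xs <- matrix(rep(0:(n - 1L), each = n), nrow = n) - c0   # column = x
    ys <- matrix(rep(0:(n - 1L), times = n), nrow = n) - c0  # row = y
    r_pix <- sqrt(xs^2 + ys^2)
    th_pix <- atan2(ys, xs) %% (2 * pi)
    r_faz <- matrix(interp_radius(faz$theta, faz$r_px, th_pix), nrow = n)
    faz_mask <- r_pix <= r_faz

    # capillary mesh: jittered square lattice with right/down/diagonal edges
    spacing <- max(4, sqrt(3 / p$capillary_density) / mm_per_px)
    g <- seq(-spacing, n - 1 + spacing, by = spacing)
    gx <- rep(g, times = length(g)) + runif(length(g)^2, -0.35, 0.35) * spacing
    gy <- rep(g, each = length(g)) + runif(length(g)^2, -0.35, 0.35) * spacing
    m <- length(g)
    id <- function(i, j) (j - 1L) * m + i  # i = x index, j = y index
    ii <- rep(1:(m - 1L), times = m - 1L)
    jj <- rep(1:(m - 1L), each = m - 1L)
    from <- c(id(ii, jj), id(ii, jj), id(ii, jj))
    to <- c(id(ii + 1L, jj), id(ii, jj + 1L), id(ii + 1L, jj + 1L))
    keep <- runif(length(from)) < c(rep(0.95, 2 * length(ii)), rep(0.55, length(ii)))
    vessel <- matrix(FALSE, n, n)
    vessel <- stamp_segments(vessel, gx[from[keep]], gy[from[keep]],
                             gx[to[keep]], gy[to[keep]])

    # perifoveal arcade: double ring hugging the FAZ border, skipping the
    # disrupted arc
    d <- p$arcade_disruption_fraction
    theta0 <- runif(1L, 0, 2 * pi)
    th_ring <- seq(0, 2 * pi, length.out = 1024L)
    in_disrupted <- ((th_ring - theta0) %% (2 * pi)) < 2 * pi * d
    r_ring <- interp_radius(faz$theta, faz$r_px, th_ring)
    for (dr in c(1.5, 3)) {
      tk <- th_ring[!in_disrupted]
      rk <- r_ring[!in_disrupted] + dr
      if (length(tk) > 1L) {
        xk <- c0 + rk * cos(tk); yk <- c0 + rk * sin(tk)
        gap_ok <- abs(diff(tk)) < 2 * (2 * pi / 1024)  # don't bridge the arc gap
        vessel <- stamp_segments(vessel, xk[-length(xk)][gap_ok],
                                 yk[-length(yk)][gap_ok],
                                 xk[-1L][gap_ok], yk[-1L][gap_ok])
      }
    }
    # clear the border band over the disrupted arc so no capillary touches it
    if (d > 0) {
      in_arc <- ((th_pix - theta0) %% (2 * pi)) < 2 * pi * d
      band <- in_arc & r_pix > r_faz & r_pix <= r_faz + border_band
      vessel[band] <- FALSE
    }
    vessel[faz_mask] <- FALSE

    # dropout: union of random disks inside the perifoveal annulus
    r_out <- n / 2 - 2
    annulus <- r_pix > r_faz + annulus_gap & r_pix <= r_out
    dropout <- matrix(FALSE, n, n)
    ann_idx <- which(annulus)
    ann_total <- length(ann_idx)
    if (p$dropout_fraction > 0 && ann_total > 0L) {
      iter <- 0L
      while (sum(dropout) / ann_total < p$dropout_fraction && iter < 5000L) {
        iter <- iter + 1L
        ctr <- ann_idx[sample.int(ann_total, 1L)]
        cyx <- c((ctr - 1L) %% n, (ctr - 1L) %/% n)  # (row-1, col-1) = (y, x)
        rad <- runif(1L, 3, 10)
        disk <- (xs - (cyx[2L] - c0))^2 + (ys - (cyx[1L] - c0))^2 <= rad^2
        dropout[disk & annulus] <- TRUE
      }
    }
    vessel[dropout] <- FALSE
    achieved_dropout <- if (ann_total > 0L) sum(dropout) / ann_total else 0

    img <- matrix(as.numeric(p$background_brightness_mean), n, n)
    img[vessel] <- p$vessel_brightness_mean
    if (p$speckle_sd > 0) {
      img <- img + rnorm(n * n, 0, p$speckle_sd)
    }
    img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), n, n)

    polygon <- faz_contour(faz$vertices, source = "ground_truth")
    scale <- calibrate(n, p$field_mm)
    truth <- structure(list(
      polygon = polygon,
      area_mm2 = abs(polygon_area_px(polygon)) * mm_per_px^2,
      perimeter_mm = polygon_perimeter_px(polygon) * mm_per_px,
      disruption_fraction = d,
      dropout_fraction = achieved_dropout,
      seed = p$seed,
      masks = list(faz = faz_mask, vessel = vessel, dropout = dropout,
                   annulus = annulus)
    ), class = "synthetic_ground_truth")

    list(image = enface_angiogram(img, scale, plexus = plexus, eye_id = eye_id),
         truth = truth)
  })
}

#' @export
print.synthetic_ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_ground_truth> FAZ %.4g mm^2, perimeter %.4g mm, ",
                     "disruption %.2f, dropout %.3f (seed %d)\n"),
              x$area_mm2, x$perimeter_mm, x$disruption_fraction,
              x$dropout_fraction, x$seed))
  invisible(x)
}
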