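#' Polygon primitives in pixel space
#'
#' Closed polygons are stored as an n x 2 matrix of (x, y) pixel coordinates
#' with the closing edge implied (first vertex not repeated). The coordinate
#' convention throughout the package: pixel centres at integer coordinates,
#' x rightward, y downward, 0-based.
#'
#' @param vertices numeric n x 2 matrix (or data.frame) of vertex coordinates.
#' @param source provenance of the trace, `"manual_trace"` or `"ground_truth"`.
#' @return An object of class `faz_contour`: the vertex matrix with a
#'   `source` attribute.
#' @examples
#' sq <- faz_contour(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' contour_area(sq, calibrate(300, 3))
#' @export
faz_contour <- function(vertices, source = c("manual_trace", "ground_truth")) {
  source <- match.arg(source)
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L) {
    stop_validation("contour vertices must be an n x 2 numeric matrix")
  }
  if (anyNA(v)) stop_validation("contour vertices contain NA")
  # a duplicated closing vertex is a common export artefact; drop it
  n <- nrow(v)
  if (n >= 2L && all(v[1L, ] == v[n, ])) {
    warning("duplicate closing vertex removed from contour", call. = FALSE)
    v <- v[-n, , drop = FALSE]
  }
  if (nrow(v) < 3L) stop_validation("a contour needs at least 3 vertices")
  dimnames(v) <- list(NULL, c("x", "y"))
  structure(v, source = source, class = c("faz_contour", "matrix", "array"))
}

#' @export
print.faz_contour <- function(x, ...) {
  cat(sprintf("<faz_contour> %d vertices (source: %s)\n", nrow(x), attr(x, "source")))
  invisible(x)
}

# Shoelace area in squared pixels (signed; positive for counter-clockwise in
# a y-down frame the sign flips, callers take abs()).
polygon_area_px <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter_px <- function(v) {
  xn <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])
  sum(sqrt(rowSums((xn - v)^2)))
}

# Proper segment crossing test for the simple-polygon check. Returns the
# indices (i, j) of the first crossing edge pair, or NULL.
polygon_find_crossing <- function(v) {
  n <- nrow(v)
  a <- v
  b <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])
  orient <- function(px, py, qx, qy, rx, ry) {
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  }
  for (i in seq_len(n - 2L)) {
    # skip adjacent edges (shared vertex); for i = 1 also skip the last edge
    jmax <- if (i == 1L) n - 1L else n
    js <- seq(i + 2L, jmax)
    if (length(js) == 0L) next
    o1 <- orient(a[i, 1L], a[i, 2L], b[i, 1L], b[i, 2L], a[js, 1L], a[js, 2L])
    o2 <- orient(a[i, 1L], a[i, 2L], b[i, 1L], b[i, 2L], b[js, 1L], b[js, 2L])
    o3 <- orient(a[js, 1L], a[js, 2L], b[js, 1L], b[js, 2L], a[i, 1L], a[i, 2L])
    o4 <- orient(a[js, 1L], a[js, 2L], b[js, 1L], b[js, 2L], b[i, 1L], b[i, 2L])
    hit <- o1 != o2 & o3 != o4 & o1 != 0 & o2 != 0 & o3 != 0 & o4 != 0
    if (any(hit)) return(c(i, js[which(hit)[1L]]))
  }
  NULL
}

assert_simple_polygon <- function(v) {
  cross <- polygon_find_crossing(v)
  if (!is.null(cross)) {
    stop_validation(sprintf(
      "contour is self-intersecting: edge %d-%d crosses edge %d-%d",
      cross[1L], cross[1L] %% nrow(v) + 1L, cross[2L], cross[2L] %% nrow(v) + 1L
    ))
  }
  invisible(TRUE)
}

# Even-odd point-in-polygon test, vectorised over query points.
points_in_polygon <- function(px, py, v) {
  inside <- rep(FALSE, length(px))
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
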