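#' ROI polygons
#'
#' A region of interest is a simple (non-self-intersecting), implicitly
#' closed planar polygon in 0-based pixel coordinates, standing in for the
#' hand-drawn freehand selections used to delimit apical compartments,
#' half-rings and cells. Polygons live in plain-text files of
#' whitespace-delimited `x y` vertex lines, one polygon per file.
#'
#' @param x,y Vertex coordinates (or `x` a two-column matrix / data frame).
#' @param label Text label carried into downstream tidy outputs.
#' @return An object of class `roi_polygon` with fields `x`, `y`, `label`.
#' @export
roi_polygon <- function(x, y = NULL, label = "roi") {
  if (is.null(y)) {
    m <- as.matrix(x)
    if (ncol(m) != 2L) abort("vertex matrix must have two columns (x, y)")
    x <- m[, 1L]; y <- m[, 2L]
  }
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3L) abort("a polygon needs at least 3 vertices")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("vertices must be finite")
  # drop a duplicated closing vertex
  n <- length(x)
  if (x[1L] == x[n] && y[1L] == y[n]) {
    x <- x[-n]; y <- y[-n]
    if (length(x) < 3L) abort("a polygon needs at least 3 distinct vertices")
  }
  roi <- structure(list(x = as.numeric(x), y = as.numeric(y),
                        label = as.character(label)),
                   class = "roi_polygon")
  if (polygon_self_intersects(roi)) {
    abort("polygon must be simple (non-self-intersecting)")
  }
  if (abs(shoelace_area(roi)) < .Machine$double.eps) {
    abort("polygon has zero enclosed area")
  }
  roi
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat("<roi_polygon> '", x$label, "': ", length(x$x),
      " vertices, area ", format(roi_area(x)), " px^2\n", sep = "")
  invisible(x)
}

shoelace_area <- function(roi) {
  x <- roi$x; y <- roi$y
  j <- c(seq_along(x)[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' @rdname roi_polygon
#' @param roi An `roi_polygon`.
#' @return `roi_area()`: the enclosed area in square pixels (shoelace formula).
#' @export
roi_area <- function(roi) abs(shoelace_area(roi))

polygon_self_intersects <- function(roi) {
  x <- roi$x; y <- roi$y
  n <- length(x)
  j <- c(seq_len(n)[-1L], 1L)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      # skip adjacent edges (share a vertex)
      if (abs(a - b) == 1L || (a == 1L && b == n)) next
      if (segments_cross(x[a], y[a], x[j[a]], y[j[a]],
                         x[b], y[b], x[j[b]], y[j[b]])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(x1, y1, x2, y2, x3, y3, x4, y4) {
  d <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d1 <- d(x3, y3, x4, y4, x1, y1)
  d2 <- d(x3, y3, x4, y4, x2, y2)
  d3 <- d(x1, y1, x2, y2, x3, y3)
  d4 <- d(x1, y1, x2, y2, x4, y4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' @rdname roi_polygon
#' @param path Plain-text file of `x y` vertex lines.
#' @export
read_roi <- function(path, label = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read ROI file '", path, "'"))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 3L) abort("ROI file must list at least 3 vertices")
  parts <- strsplit(lines, "[[:space:],]+")
  xy <- t(vapply(parts, function(p) as.numeric(p[1:2]), numeric(2)))
  if (anyNA(xy)) abort("ROI file has malformed vertex lines")
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  roi_polygon(xy[, 1L], xy[, 2L], label = label)
}

#' @rdname roi_polygon
#' @export
write_roi <- function(roi, path) {
  writeLines(paste(format(roi$x, trim = TRUE), format(roi$y, trim = TRUE)),
             path)
  invisible(path)
}

#' Rasterize a polygon onto a pixel grid
#'
#' A pixel belongs to the mask iff its center (integer 0-based coordinates)
#' lies inside the polygon under the even-odd rule, implemented as the
#' standard strict upward-crossing test: centers exactly on a horizontal
#' edge or on the right/top boundary of an axis-aligned polygon fall
#' outside, making the rule half-open and deterministic — an axis-aligned
#' rectangle with integer corners `(x0, y0)`–`(x1, y1)` covers exactly
#' `(x1 - x0) * (y1 - y0)` pixels.
#'
#' @param roi An [roi_polygon].
#' @param image_shape `c(Y, X)` of the target grid.
#' @return A logical `Y x X` mask.
#' @export
rasterize_roi <- function(roi, image_shape) {
  ny <- image_shape[1L]; nx <- image_shape[2L]
  xs <- 0:(nx - 1L); ys <- 0:(ny - 1L)
  ix0 <- max(floor(min(roi$x)), 0); ix1 <- min(ceiling(max(roi$x)), nx - 1L)
  iy0 <- max(floor(min(roi$y)), 0); iy1 <- min(ceiling(max(roi$y)), ny - 1L)
  mask <- matrix(FALSE, ny, nx)
  if (ix0 > ix1 || iy0 > iy1) return(mask)
  sub_x <- xs[xs >= ix0 & xs <= ix1]
  crossings <- matrix(0L, iy1 - iy0 + 1L, length(sub_x))
  vx <- roi$x; vy <- roi$y
  n <- length(vx)
  j <- c(seq_len(n)[-1L], 1L)
  for (e in seq_len(n)) {
    y1 <- vy[e]; y2 <- vy[j[e]]
    if (y1 == y2) next
    for (row in seq_len(nrow(crossings))) {
      py <- iy0 + row - 1L
      if ((y1 > py) != (y2 > py)) {
        xint <- vx[e] + (py - y1) * (vx[j[e]] - vx[e]) / (y2 - y1)
        crossings[row, ] <- crossings[row, ] + (sub_x < xint)
      }
    }
  }
  mask[(iy0:iy1) + 1L, sub_x + 1L] <- (crossings %% 2L) == 1L
  mask
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask Logical `Y x X` matrix.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(ifelse(mask, 1, 0), path, bits.per.sample = 8L)
  invisible(path)
}
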