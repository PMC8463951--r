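# Tract tables -----------------------------------------------------------
#
# A tract frame is a plain data.frame with one row per census tract, a
# character `tract_id` column and (optionally) a `geometry` list-column in
# which each element is a closed polygon ring: an m x 2 matrix of planar
# coordinates whose last row repeats the first. All spatial computations in
# the package are planar (projected coordinates or synthetic lattices).

new_tract_frame <- function(df) {
  stopifnot(is.data.frame(df), "tract_id" %in% names(df))
  if (anyDuplicated(df$tract_id)) abort_arg("tract IDs must be unique")
  class(df) <- unique(c("tract_frame", class(df)))
  df
}

#' Test or coerce tract tables
#'
#' @param x A data.frame with at least a `tract_id` column and optionally a
#'   `geometry` list-column of closed polygon rings (m x 2 matrices).
#' @return `as_tract_frame()` returns `x` with class `tract_frame`;
#'   `is_tract_frame()` a logical.
#' @export
as_tract_frame <- function(x) new_tract_frame(as.data.frame(x))

#' @rdname as_tract_frame
#' @export
is_tract_frame <- function(x) inherits(x, "tract_frame")

#' @export
print.tract_frame <- function(x, ...) {
  cat(sprintf("Tract frame: %d tracts, %s geometry\n", nrow(x),
              if ("geometry" %in% names(x)) "with" else "no"))
  cols <- setdiff(names(x), "geometry")
  print(utils::head(as.data.frame(x)[, cols, drop = FALSE]), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more tracts\n", nrow(x) - 6L))
  invisible(x)
}

# subsetting keeps the class
#' @export
`[.tract_frame` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "tract_id" %in% names(out)) {
    class(out) <- unique(c("tract_frame", class(out)))
  }
  out
}

# Shoelace signed area of a closed ring.
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  0.5 * sum(x[-n] * y[-1] - x[-1] * y[-n])
}

# Area centroid of a closed ring (falls back to vertex mean for degenerate
# zero-area rings).
polygon_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-300) {
    return(c(mean(x[-n]), mean(y[-n])))
  }
  cx <- sum((x[-n] + x[-1]) * cr) / (6 * a)
  cy <- sum((y[-n] + y[-1]) * cr) / (6 * a)
  c(cx, cy)
}

tract_centroids <- function(tracts) {
  if (!is.null(tracts$centroid_x) && !is.null(tracts$centroid_y)) {
    return(cbind(tracts$centroid_x, tracts$centroid_y))
  }
  if (is.null(tracts$geometry)) {
    abort_arg("tract frame has neither centroids nor geometry")
  }
  t(vapply(tracts$geometry, polygon_centroid, numeric(2)))
}

#' Build a rectangular lattice of square tracts
#'
#' Generates a `rows` x `cols` grid of non-overlapping square polygons of
#' side `cell_size` tiling a rectangle, with deterministic tract IDs. This
#' is the synthetic stand-in for a census-tract map: a regular lattice is
#' sufficient to exercise contiguity, inverse-distance weighting and every
#' estimator in the package.
#'
#' @param rows,cols Positive integer lattice dimensions.
#' @param cell_size Positive side length (planar units).
#' @return A `tract_frame` with columns `tract_id`, `row`, `col`,
#'   `centroid_x`, `centroid_y` and a `geometry` list-column of closed rings.
#' @examples
#' lat <- make_tract_lattice(3, 3)
#' nrow(lat)  # 9
#' @export
make_tract_lattice <- function(rows, cols, cell_size = 1) {
  if (!is.numeric(rows) || !is.numeric(cols) || rows < 1 || cols < 1 ||
      rows != round(rows) || cols != round(cols)) {
    abort_arg("rows and cols must be positive integers")
  }
  if (!is.numeric(cell_size) || cell_size <= 0) {
    abort_arg("cell_size must be a positive real")
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  idx <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  x0 <- (idx$col - 1) * cell_size
  y0 <- (idx$row - 1) * cell_size
  geometry <- Map(function(x, y) {
    cbind(c(x, x + cell_size, x + cell_size, x, x),
          c(y, y, y + cell_size, y + cell_size, y))
  }, x0, y0)
  new_tract_frame(data.frame(
    tract_id = sprintf("T%03d-%03d", idx$row, idx$col),
    row = idx$row, col = idx$col,
    centroid_x = x0 + cell_size / 2,
    centroid_y = y0 + cell_size / 2,
    geometry = I(geometry)
  ))
}
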