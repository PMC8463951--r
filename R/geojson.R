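# GeoJSON / CSV I-O -------------------------------------------------------
#
# Tract tables travel as an RFC 7946 FeatureCollection (geometry + one
# property per table column) with planar coordinates, optionally mirrored by
# a CSV keyed on tract_id. Reals are serialised at full double precision so
# a write/read round trip reproduces the table exactly.

#' Write a tract frame to GeoJSON
#'
#' @param tracts A `tract_frame` with a `geometry` list-column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tract_geojson <- function(tracts, path) {
  stopifnot(is_tract_frame(tracts))
  if (nrow(tracts) == 0) abort_arg("refusing to write an empty tract frame")
  if (is.null(tracts$geometry)) abort_arg("tract frame has no geometry")
  props <- as.data.frame(tracts)[, setdiff(names(tracts), "geometry"),
                                 drop = FALSE]
  features <- lapply(seq_len(nrow(tracts)), function(i) {
    ring <- tracts$geometry[[i]]
    list(
      type = "Feature",
      properties = as.list(props[i, , drop = FALSE]),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(j) as.numeric(ring[j, ])))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       always_decimal = FALSE, na = "null")
  invisible(path)
}

#' Read a tract frame from GeoJSON
#'
#' @param path Path to a GeoJSON FeatureCollection of polygons written by
#'   [write_tract_geojson()] (or compatible: one outer ring per feature,
#'   `tract_id` among the properties).
#' @return A `tract_frame`.
#' @export
read_tract_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    abort_arg("not a GeoJSON FeatureCollection: ", path)
  }
  feats <- fc$features
  if (length(feats) == 0) abort_arg("empty FeatureCollection: ", path)
  props <- lapply(feats, function(f) f$properties)
  nms <- names(props[[1]])
  cols <- lapply(nms, function(nm) {
    v <- lapply(props, `[[`, nm)
    v <- lapply(v, function(x) if (is.null(x)) NA else x)
    if (all(vapply(v, is.numeric, logical(1)) |
            vapply(v, function(x) is.na(x), logical(1)))) {
      as.numeric(unlist(v))
    } else {
      as.character(unlist(v))
    }
  })
  names(cols) <- nms
  geometry <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1]]
    do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
  })
  df <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  df$geometry <- I(geometry)
  new_tract_frame(df)
}

# CSV mirror at full double precision (17 significant digits survive the
# text round trip bit-exactly).
write_precise_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA, sprintf("%.17g", out[[nm]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write a synthetic tract fixture as GeoJSON + CSV
#'
#' Writes the full table (geometry + properties) as a GeoJSON
#' FeatureCollection and a geometry-free CSV mirror keyed by `tract_id`.
#' Reading the pair back with [read_tract_fixture()] reproduces the table
#' exactly, including reals at full precision.
#'
#' @param tracts A complete `tract_frame`.
#' @param path_geojson,path_csv Output file paths.
#' @return Invisible list of the two paths.
#' @export
write_tract_fixture <- function(tracts, path_geojson, path_csv) {
  stopifnot(is_tract_frame(tracts))
  if (nrow(tracts) == 0) abort_arg("refusing to write an empty tract frame")
  write_tract_geojson(tracts, path_geojson)
  tab <- as.data.frame(tracts)[, setdiff(names(tracts), "geometry"),
                               drop = FALSE]
  write_precise_csv(tab, path_csv)
  invisible(list(geojson = path_geojson, csv = path_csv))
}

#' @rdname write_tract_fixture
#' @export
read_tract_fixture <- function(path_geojson, path_csv) {
  geo <- read_tract_geojson(path_geojson)
  tab <- utils::read.csv(path_csv, stringsAsFactors = FALSE)
  stopifnot(identical(sort(tab$tract_id), sort(geo$tract_id)))
  tab <- tab[match(geo$tract_id, tab$tract_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab$geometry <- I(geo$geometry)
  new_tract_frame(tab)
}
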