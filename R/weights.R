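# Spatial weights ---------------------------------------------------------
#
# W summarises the spatial relations between tracts: rook-style contiguity
# (two tracts are neighbours iff their boundaries share a segment of
# positive length; corner contact does not count), inverse centroid-distance
# weights on the neighbour pairs, then row standardisation so every
# non-island row sums to 1 and Wy is a neighbour average.

SHARED_EDGE_TOL <- 1e-9  # minimum shared-boundary length that makes a neighbour

#' Rook-style contiguity from polygon boundaries
#'
#' Two tracts are neighbours iff their boundary rings share a collinear
#' segment of length greater than `tol` (corner-only contact is not
#' adjacency). The relation is symmetric; tracts with no neighbours are
#' islands.
#'
#' @param tracts A `tract_frame` with a `geometry` list-column.
#' @param tol Shared-boundary length tolerance (planar units).
#' @return A list of integer neighbour index vectors, one per tract.
#' @export
contiguity_neighbors <- function(tracts, tol = SHARED_EDGE_TOL) {
  stopifnot(is_tract_frame(tracts))
  if (is.null(tracts$geometry)) abort_arg("tract frame has no geometry")
  n <- nrow(tracts)
  rings <- tracts$geometry
  for (i in seq_len(n)) {
    r <- rings[[i]]
    ok <- is.matrix(r) && ncol(r) == 2 && nrow(r) >= 4 &&
      all(is.finite(r)) && all(r[1, ] == r[nrow(r), ])
    if (!ok) abort_arg("invalid geometry for tract ", tracts$tract_id[i])
  }
  bb <- t(vapply(rings, function(r) {
    c(min(r[, 1]), max(r[, 1]), min(r[, 2]), max(r[, 2]))
  }, numeric(4)))
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (bb[i, 1] > bb[j, 2] + tol || bb[j, 1] > bb[i, 2] + tol ||
          bb[i, 3] > bb[j, 4] + tol || bb[j, 3] > bb[i, 4] + tol) next
      if (shares_edge(rings[[i]], rings[[j]], tol)) {
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
      }
    }
  }
  nb
}

# TRUE iff some segment of ring a overlaps a segment of ring b collinearly
# over a length > tol.
shares_edge <- function(a, b, tol = SHARED_EDGE_TOL) {
  na <- nrow(a) - 1L; nb <- nrow(b) - 1L
  for (i in seq_len(na)) {
    p1 <- a[i, ]; p2 <- a[i + 1L, ]
    u <- p2 - p1
    len2 <- sum(u^2)
    if (len2 < tol^2) next
    len <- sqrt(len2)
    for (j in seq_len(nb)) {
      q1 <- b[j, ]; q2 <- b[j + 1L, ]
      # both endpoints of b's segment must lie on the line through a's
      c1 <- abs(u[1] * (q1[2] - p1[2]) - u[2] * (q1[1] - p1[1])) / len
      if (c1 > tol) next
      c2 <- abs(u[1] * (q2[2] - p1[2]) - u[2] * (q2[1] - p1[1])) / len
      if (c2 > tol) next
      t1 <- sum((q1 - p1) * u) / len2
      t2 <- sum((q2 - p1) * u) / len2
      lo <- max(0, min(t1, t2)); hi <- min(1, max(t1, t2))
      if ((hi - lo) * len > tol) return(TRUE)
    }
  }
  FALSE
}

#' Inverse-distance weights on neighbour pairs
#'
#' Raw weight `1/d` for each neighbour pair, with `d` the Euclidean distance
#' between the two tracts' area centroids in the planar coordinates; zero
#' for non-neighbours.
#'
#' @param tracts A `tract_frame` (centroids taken from `centroid_x/_y`
#'   columns or computed from geometry).
#' @param neighbors Neighbour lists from [contiguity_neighbors()].
#' @return A list of numeric weight vectors aligned with `neighbors`.
#' @export
idw_weights <- function(tracts, neighbors) {
  cen <- tract_centroids(tracts)
  lapply(seq_along(neighbors), function(i) {
    js <- neighbors[[i]]
    if (length(js) == 0) return(numeric(0))
    d <- sqrt((cen[js, 1] - cen[i, 1])^2 + (cen[js, 2] - cen[i, 2])^2)
    if (any(d < 1e-12)) {
      abort_arg("coincident centroids between neighbouring tracts ",
                tracts$tract_id[i], " and ",
                paste(tracts$tract_id[js[d < 1e-12]], collapse = ", "))
    }
    1 / d
  })
}

#' Row-standardise raw weights into a spatial weight matrix
#'
#' Divides each tract's raw weights by their sum so every non-island row of
#' W sums to 1; island rows (no neighbours) stay all-zero and are reported
#' in the object.
#'
#' @param tracts A `tract_frame` (supplies the tract IDs).
#' @param neighbors,raw_weights Parallel neighbour/weight lists, e.g. from
#'   [contiguity_neighbors()] and [idw_weights()].
#' @return A `tract_weights` object.
#' @export
row_standardize <- function(tracts, neighbors, raw_weights) {
  n <- nrow(tracts)
  stopifnot(length(neighbors) == n, length(raw_weights) == n)
  if (any(unlist(raw_weights) < 0)) abort_arg("raw weights must be nonnegative")
  std <- lapply(seq_len(n), function(i) {
    w <- raw_weights[[i]]
    s <- sum(w)
    if (s > 0) w / s else w
  })
  ii <- rep.int(seq_len(n), lengths(neighbors))
  jj <- unlist(neighbors)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = unlist(std), dims = c(n, n))
  islands <- which(lengths(neighbors) == 0L)
  obj <- list(
    n = n,
    ids = tracts$tract_id,
    neighbors = neighbors,
    raw_weights = raw_weights,
    W = W,
    islands = tracts$tract_id[islands],
    row_standardized = TRUE,
    cache = new.env(parent = emptyenv())
  )
  class(obj) <- "tract_weights"
  obj
}

#' Build the full weight matrix in one call
#'
#' Convenience wrapper: rook contiguity, inverse-distance weights, row
#' standardisation.
#'
#' @param tracts A `tract_frame` with geometry.
#' @param tol Shared-edge tolerance passed to [contiguity_neighbors()].
#' @return A `tract_weights` object.
#' @examples
#' w <- tract_weights(make_tract_lattice(3, 3))
#' Matrix::rowSums(weights_matrix(w))  # all 1
#' @export
tract_weights <- function(tracts, tol = SHARED_EDGE_TOL) {
  nb <- contiguity_neighbors(tracts, tol = tol)
  raw <- idw_weights(tracts, nb)
  row_standardize(tracts, nb, raw)
}

#' @export
print.tract_weights <- function(x, ...) {
  cat(sprintf(
    "Spatial weights: %d tracts, %d neighbour pairs, %d island(s), %s\n",
    x$n, sum(lengths(x$neighbors)) %/% 2L, length(x$islands),
    if (x$row_standardized) "row-standardized" else "raw"))
  invisible(x)
}

#' Extract the (sparse) weight matrix
#' @param w A `tract_weights` object.
#' @return A `dgCMatrix` of row-standardised weights.
#' @export
weights_matrix <- function(w) {
  stopifnot(inherits(w, "tract_weights"))
  w$W
}

# Eigenvalues of W, computed once and cached on the object. W = D^-1 B with
# B symmetric nonnegative, hence similar to a symmetric matrix: eigenvalues
# are real (imaginary residue beyond 1e-8 is an error) and lie in [-1, 1].
weights_eigenvalues <- function(w) {
  stopifnot(inherits(w, "tract_weights"))
  ev <- w$cache$eigenvalues
  if (!is.null(ev)) return(ev)
  e <- eigen(as.matrix(w$W), only.values = TRUE)$values
  if (max(abs(Im(e))) > 1e-8) {
    abort_arg("weights not similarity-symmetric: complex eigenvalues")
  }
  ev <- sort(Re(e))
  w$cache$eigenvalues <- ev
  ev
}

#' Subset a weight matrix to a set of tracts
#'
#' Restricts the neighbour relation and raw weights to the selected tracts
#' and re-row-standardises, as needed when fitting on training folds.
#'
#' @param w A `tract_weights` object.
#' @param idx Integer or logical index, or character tract IDs.
#' @return A `tract_weights` object over the selected tracts.
#' @export
subset_weights <- function(w, idx) {
  stopifnot(inherits(w, "tract_weights"))
  if (is.character(idx)) idx <- match(idx, w$ids)
  if (is.logical(idx)) idx <- which(idx)
  stopifnot(!anyNA(idx), all(idx >= 1), all(idx <= w$n))
  pos <- match(seq_len(w$n), idx)  # old index -> new index or NA
  nb <- vector("list", length(idx))
  raw <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    keep <- !is.na(pos[w$neighbors[[i]]])
    nb[[k]] <- pos[w$neighbors[[i]]][keep]
    raw[[k]] <- w$raw_weights[[i]][keep]
  }
  tr <- new_tract_frame(data.frame(tract_id = w$ids[idx]))
  row_standardize(tr, nb, raw)
}

#' Write / read a weight matrix as sparse-triplet CSV + JSON header
#'
#' @param w A `tract_weights` object.
#' @param path_csv Triplet CSV path (columns `i`, `j`, `weight`, 1-based,
#'   raw pre-standardisation weights).
#' @param path_json JSON header path (n, tract IDs, standardisation flag,
#'   island list).
#' @return Invisible paths / the restored object.
#' @export
write_weights <- function(w, path_csv, path_json) {
  stopifnot(inherits(w, "tract_weights"))
  ii <- rep.int(seq_len(w$n), lengths(w$neighbors))
  trip <- data.frame(i = ii, j = unlist(w$neighbors),
                     weight = unlist(w$raw_weights))
  if (nrow(trip) == 0) trip <- data.frame(i = integer(), j = integer(),
                                          weight = numeric())
  write_precise_csv(trip, path_csv)
  hdr <- list(n = w$n, ids = w$ids, row_standardized = w$row_standardized,
              islands = w$islands)
  jsonlite::write_json(hdr, path_json, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = path_csv, json = path_json))
}

#' @rdname write_weights
#' @export
read_weights <- function(path_csv, path_json) {
  hdr <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  trip <- utils::read.csv(path_csv)
  n <- hdr$n
  nb <- vector("list", n); raw <- vector("list", n)
  for (i in seq_len(n)) { nb[[i]] <- integer(0); raw[[i]] <- numeric(0) }
  if (nrow(trip) > 0) {
    sp <- split(seq_len(nrow(trip)), trip$i)
    for (nm in names(sp)) {
      i <- as.integer(nm)
      nb[[i]] <- as.integer(trip$j[sp[[nm]]])
      raw[[i]] <- as.numeric(trip$weight[sp[[nm]]])
    }
  }
  tr <- new_tract_frame(data.frame(tract_id = as.character(hdr$ids)))
  row_standardize(tr, nb, raw)
}
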