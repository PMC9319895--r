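# Leaf contour/midvein annotations (image convention: pixel units, y down)

#' Construct a leaf annotation
#'
#' @param contour closed simple polygon, matrix with >= 64 rows (x, y in
#'   pixel units, y-down image convention); not repeated at the end.
#' @param midvein open polyline base to tip, matrix with >= 2 rows; must lie
#'   inside or on the contour.
#' @param specimen_id,taxon identifiers.
#' @param check validate polygon simplicity and midvein containment
#'   (quadratic in the vertex count; disable in tight loops).
#' @return an object of class `leaf_annotation`.
#' @export
leaf_annotation <- function(contour, midvein, specimen_id = "leaf1",
                            taxon = "taxonA", check = TRUE) {
  contour <- as.matrix(contour)
  midvein <- as.matrix(midvein)
  if (nrow(contour) < 64L) stop("contour needs at least 64 vertices")
  if (nrow(midvein) < 2L) stop("midvein needs at least 2 vertices")
  if (check) {
    if (polygon_self_intersects(contour)) {
      stop("contour polygon is self-intersecting (", specimen_id, ")")
    }
    scale <- max(apply(contour, 2, function(v) diff(range(v))))
    inside <- points_in_polygon(midvein, contour)
    if (!all(inside)) {
      # vertices on (or within digitization accuracy of) the boundary count
      # as inside
      d <- vapply(which(!inside), function(i) {
        .point_segment_dist(midvein[i, ], contour)
      }, 0)
      if (any(d > 1e-3 * scale)) {
        stop("midvein must lie inside or on the contour (", specimen_id, ")")
      }
    }
  }
  structure(list(contour = unname(contour), midvein = unname(midvein),
                 specimen_id = specimen_id, taxon = taxon),
            class = "leaf_annotation")
}

# min distance from point p to the closed polygon boundary
.point_segment_dist <- function(p, poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1L), , drop = FALSE]
  ab <- b - a
  ap <- cbind(p[1] - a[, 1], p[2] - a[, 2])
  len2 <- rowSums(ab^2)
  t <- pmin(1, pmax(0, rowSums(ap * ab) / pmax(len2, 1e-300)))
  proj <- a + ab * t
  min(sqrt((p[1] - proj[, 1])^2 + (p[2] - proj[, 2])^2))
}

#' @export
print.leaf_annotation <- function(x, ...) {
  cat(sprintf("leaf_annotation '%s' (%s): %d contour vertices, %d midvein vertices\n",
              x$specimen_id, x$taxon, nrow(x$contour), nrow(x$midvein)))
  invisible(x)
}

#' Cumulative arc length of a polyline
#' @param xy matrix of vertices.
#' @return vector of cumulative lengths starting at 0.
#' @export
polyline_arclength <- function(xy) {
  d <- sqrt(rowSums(diff(xy)^2))
  c(0, cumsum(d))
}
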