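# CVAT image XML reader/writer for leaf contour (polygon) and midvein
# (polyline) annotations.

.fmt_points <- function(xy) {
  paste(sprintf("%.2f,%.2f", xy[, 1], xy[, 2]), collapse = ";")
}

.parse_points <- function(str) {
  pairs <- strsplit(strsplit(str, ";")[[1]], ",")
  do.call(rbind, lapply(pairs, function(p) as.numeric(p)))
}

#' Write leaf annotations as a CVAT image XML dataset
#'
#' One `<image>` element per annotation with a `polygon` (label "leaf") and
#' a `polyline` (label "midvein") shape.
#'
#' @param leaves list of [leaf_annotation] objects.
#' @param path output XML file.
#' @export
write_cvat_xml <- function(leaves, path) {
  doc <- xml2::xml_new_root("annotations")
  xml2::xml_add_child(doc, "version", "1.1")
  for (i in seq_along(leaves)) {
    lf <- leaves[[i]]
    all_xy <- rbind(lf$contour, lf$midvein)
    img <- xml2::xml_add_child(doc, "image",
                               id = as.character(i - 1L),
                               name = paste0(lf$specimen_id, ".jpg"),
                               width = as.character(ceiling(max(all_xy[, 1])) + 10L),
                               height = as.character(ceiling(max(all_xy[, 2])) + 10L))
    xml2::xml_add_child(img, "polygon", label = "leaf", occluded = "0",
                        source = "manual", points = .fmt_points(lf$contour),
                        z_order = "0")
    xml2::xml_add_child(img, "polyline", label = "midvein", occluded = "0",
                        source = "manual", points = .fmt_points(lf$midvein),
                        z_order = "0")
    tax <- xml2::xml_add_child(img, "tag", label = lf$taxon, source = "manual")
    invisible(tax)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# local contour width near a midvein endpoint: spread of the perpendicular
# offsets of contour points whose axial projection falls near the endpoint
.local_width <- function(endpoint_u, proj_u, offsets, window = 0.15) {
  sel <- abs(proj_u - endpoint_u) <= window
  if (sum(sel) < 2L) return(0)
  diff(range(offsets[sel]))
}

#' Read leaf annotations from a CVAT image XML dataset
#'
#' Pairs each polygon (contour) with the polyline (midvein) it contains, by
#' spatial containment of the polyline's vertices. The midvein is oriented
#' base to tip: the base is the polyline end where the contour is locally
#' wider.
#'
#' @param path CVAT image XML file.
#' @return list of [leaf_annotation] objects.
#' @export
read_cvat_xml <- function(path) {
  doc <- xml2::read_xml(path)
  images <- xml2::xml_find_all(doc, ".//image")
  leaves <- list()
  for (img in images) {
    name <- xml2::xml_attr(img, "name")
    polys <- xml2::xml_find_all(img, "./polygon")
    lines <- xml2::xml_find_all(img, "./polyline")
    if (length(polys) != length(lines)) {
      stop(sprintf("image '%s': %d polygon(s) but %d polyline(s); shapes unpaired",
                   name, length(polys), length(lines)))
    }
    tags <- xml2::xml_find_all(img, "./tag")
    taxon <- if (length(tags)) xml2::xml_attr(tags[[1]], "label") else "unknown"
    contours <- lapply(polys, function(p) .parse_points(xml2::xml_attr(p, "points")))
    for (ct in contours) {
      if (polygon_self_intersects(ct)) {
        stop(sprintf("image '%s': self-intersecting polygon", name))
      }
    }
    used <- rep(FALSE, length(contours))
    for (pl in lines) {
      mv <- .parse_points(xml2::xml_attr(pl, "points"))
      hit <- NA_integer_
      for (ci in seq_along(contours)) {
        if (used[ci]) next
        if (mean(points_in_polygon(mv, contours[[ci]])) >= 0.5) { hit <- ci; break }
      }
      if (is.na(hit)) {
        stop(sprintf("image '%s': polyline not contained in any polygon", name))
      }
      used[hit] <- TRUE
      ct <- contours[[hit]]
      mv <- .orient_midvein(ct, mv)
      leaves[[length(leaves) + 1L]] <-
        leaf_annotation(ct, mv,
                        specimen_id = sprintf("%s_%d", sub("\\.[^.]*$", "", name),
                                              sum(used)),
                        taxon = taxon, check = FALSE)
    }
    if (any(!used)) {
      stop(sprintf("image '%s': polygon without a midvein polyline", name))
    }
  }
  leaves
}

.orient_midvein <- function(contour, midvein) {
  a <- midvein[1, ]; b <- midvein[nrow(midvein), ]
  axis <- b - a
  len <- sqrt(sum(axis^2))
  if (len == 0) return(midvein)
  axis <- axis / len
  normal <- c(-axis[2], axis[1])
  rel <- sweep(contour, 2, a)
  proj_u <- (rel %*% axis) / len
  offs <- rel %*% normal
  w_start <- .local_width(0, proj_u, offs)
  w_end <- .local_width(1, proj_u, offs)
  if (w_end > w_start) midvein[rev(seq_len(nrow(midvein))), , drop = FALSE]
  else midvein
}
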