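# Minimal unprojected (lon/lat) raster container with ESRI ASCII grid I/O,
# plus depth averaging and raster PCA for environmental layer stacks.

#' Construct a raster
#'
#' Row-major grid, cell (1,1) at the top-left; half-open cell intervals.
#' `NA` cells are no-data.
#'
#' @param values numeric matrix (rows = north to south, cols = west to east).
#' @param xll,yll coordinates of the lower-left corner.
#' @param cellsize cell size in degrees.
#' @return an object of class `env_raster`.
#' @export
env_raster <- function(values, xll = 0, yll = 0, cellsize = 1) {
  values <- as.matrix(values)
  if (any(!is.finite(values) & !is.na(values))) {
    stop("raster values must be finite or NA (no-data)")
  }
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize),
            class = "env_raster")
}

#' @export
print.env_raster <- function(x, ...) {
  cat(sprintf("env_raster: %d x %d cells, origin (%g, %g), cellsize %g, %d no-data\n",
              nrow(x$values), ncol(x$values), x$xll, x$yll, x$cellsize,
              sum(is.na(x$values))))
  invisible(x)
}

.check_same_grid <- function(rasters) {
  ref <- rasters[[1]]
  for (r in rasters[-1]) {
    if (!identical(dim(r$values), dim(ref$values)) ||
        r$xll != ref$xll || r$yll != ref$yll || r$cellsize != ref$cellsize) {
      stop("rasters are not co-registered (grids differ)")
    }
  }
  invisible(ref)
}

#' Convert lon/lat points to raster cell indices
#' @param r an [env_raster].
#' @param pts matrix/data.frame with lon, lat columns.
#' @param dedupe drop duplicated cells.
#' @return integer matrix with columns `row`, `col`.
#' @export
cell_index <- function(r, pts, dedupe = TRUE) {
  pts <- as.matrix(pts)
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((pts[, 1] - r$xll) / r$cellsize) + 1L
  row <- nr - floor((pts[, 2] - r$yll) / r$cellsize)
  if (any(col < 1L | col > nc | row < 1L | row > nr)) {
    stop("points outside the raster extent")
  }
  cells <- cbind(row = as.integer(row), col = as.integer(col))
  if (dedupe) cells <- cells[!duplicated(cells), , drop = FALSE]
  cells
}

#' Cell-center coordinates of a raster
#' @param r an [env_raster].
#' @return list with `lon` (per column) and `lat` (per row, top first).
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(lon = r$xll + (seq_len(nc) - 0.5) * r$cellsize,
       lat = r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize)
}

#' Write / read an ESRI ASCII grid
#' @param r an [env_raster].
#' @param path file path.
#' @param nodata no-data sentinel written to file.
#' @export
write_esri_ascii <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", r$xll),
           sprintf("yllcorner %.10g", r$yll),
           sprintf("cellsize %.10g", r$cellsize),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1, function(row) paste(sprintf("%.10g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  v <- do.call(rbind, lapply(body, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA
  env_raster(v, xll = hdr$xllcorner, yll = hdr$yllcorner,
             cellsize = hdr$cellsize)
}

#' Depth-average raster triplets
#'
#' Summarizes soil variables sampled at several depth levels into one layer
#' per variable by the cell-wise mean, ignoring no-data; cells that are
#' no-data at every depth stay no-data.
#'
#' @param stacks list of lists of co-registered [env_raster]s (one inner
#'   list per variable, e.g. its three depth levels).
#' @return list of [env_raster]s, one per variable.
#' @export
depth_average <- function(stacks) {
  lapply(stacks, function(triplet) {
    ref <- .check_same_grid(triplet)
    arr <- vapply(triplet, function(r) r$values, ref$values)
    m <- apply(arr, c(1, 2), function(z) {
      if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
    })
    env_raster(m, ref$xll, ref$yll, ref$cellsize)
  })
}

#' PCA of an environmental raster stack
#'
#' Z-score normalizes each layer over its valid cells, runs a principal
#' component analysis across cells, and returns the leading component
#' rasters. The common no-data mask is propagated exactly.
#'
#' @param stack list of co-registered [env_raster]s.
#' @param n_keep number of component rasters to return (default 3).
#' @return list with `rasters` (the component layers) and
#'   `variance_explained` (all fractions).
#' @export
raster_pca <- function(stack, n_keep = 3L) {
  ref <- .check_same_grid(stack)
  if (length(stack) < n_keep) stop("need at least n_keep layers")
  vals <- vapply(stack, function(r) as.vector(r$values),
                 numeric(length(ref$values)))
  valid <- rowSums(is.na(vals)) == 0L
  z <- scale(vals[valid, , drop = FALSE])
  z[, attr(z, "scaled:scale") == 0] <- 0
  fit <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  out <- lapply(seq_len(n_keep), function(k) {
    v <- rep(NA_real_, length(ref$values))
    v[valid] <- fit$x[, k]
    env_raster(matrix(v, nrow(ref$values), ncol(ref$values)),
               ref$xll, ref$yll, ref$cellsize)
  })
  list(rasters = out, variance_explained = ve)
}

# longitude/latitude coordinate rasters on the grid of `r`
lonlat_rasters <- function(r) {
  cc <- cell_centers(r)
  lon <- matrix(cc$lon, nrow(r$values), ncol(r$values), byrow = TRUE)
  lat <- matrix(cc$lat, nrow(r$values), ncol(r$values))
  mask <- is.na(r$values)
  lon[mask] <- NA; lat[mask] <- NA
  list(env_raster(lon, r$xll, r$yll, r$cellsize),
       env_raster(lat, r$xll, r$yll, r$cellsize))
}

#' Occurrence set
#'
#' @param taxon taxon label.
#' @param points matrix/data.frame of (lon, lat) records.
#' @param raster optional [env_raster] used to derive deduplicated cell
#'   indices.
#' @return object of class `occurrence_set`.
#' @export
occurrence_set <- function(taxon, points, raster = NULL) {
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  colnames(points) <- c("lon", "lat")
  cells <- if (!is.null(raster)) cell_index(raster, points) else NULL
  structure(list(taxon = taxon, points = points, cells = cells),
            class = "occurrence_set")
}

#' Write / read occurrence CSVs (taxon, lon, lat)
#' @param occs list of [occurrence_set]s.
#' @param path CSV path.
#' @export
write_occurrences_csv <- function(occs, path) {
  df <- do.call(rbind, lapply(occs, function(o) {
    data.frame(taxon = o$taxon, lon = o$points[, 1], lat = o$points[, 2])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences_csv
#' @param raster optional raster for cell assignment.
#' @export
read_occurrences_csv <- function(path, raster = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$taxon), function(g) {
    occurrence_set(g$taxon[1], cbind(g$lon, g$lat), raster)
  })
}
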