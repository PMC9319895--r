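# Ecological niche models, distribution approximation by thresholded flood
# fill, Schoener's D niche overlap, and the permutation tests of niche
# equivalency and sympatry.

#' Fit an ecological niche model
#'
#' The builtin model is a Gaussian envelope: per environmental layer, mean
#' and standard deviation are estimated on the occurrence cells and the
#' suitability is the product of per-layer Gaussian responses, rescaled to
#' a maximum of 1. The `external-raster` model validates and passes
#' through a user-supplied suitability raster (e.g. exported from a MaxEnt
#' run).
#'
#' @param occ an [occurrence_set].
#' @param env list of co-registered [env_raster] layers.
#' @param model `"builtin-gaussian"` or `"external-raster"`.
#' @param external_raster suitability [env_raster] for the external model.
#' @param min_occurrences minimum occurrence cells for the builtin model.
#' @param background optional background-point specification (recorded in
#'   the provenance; the builtin Gaussian model does not use background
#'   points).
#' @return suitability [env_raster] with values in `[0, 1]`.
#' @export
fit_enm <- function(occ, env, model = c("builtin-gaussian", "external-raster"),
                    external_raster = NULL, min_occurrences = 5L,
                    background = NULL) {
  model <- match.arg(model)
  ref <- .check_same_grid(env)
  if (model == "external-raster") {
    if (is.null(external_raster)) stop("external model needs a raster")
    v <- external_raster$values
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("external suitability raster must lie in [0, 1]")
    }
    out <- external_raster
    attr(out, "provenance") <- list(model = model, background = background)
    return(out)
  }
  cells <- occ$cells
  if (is.null(cells)) cells <- cell_index(ref, occ$points)
  if (nrow(cells) < min_occurrences) {
    stop(sprintf("builtin model needs >= %d occurrence cells", min_occurrences))
  }
  nr <- nrow(ref$values)
  lin <- (cells[, 2] - 1L) * nr + cells[, 1]
  logsuit <- matrix(0, nr, ncol(ref$values))
  for (r in env) {
    x <- r$values[lin]
    if (any(is.na(x))) stop("occurrences fall on no-data cells")
    mu <- mean(x)
    sd_ <- stats::sd(x)
    if (!is.finite(sd_) || sd_ == 0) {
      # all occurrences share this layer value: exact-match envelope
      eq <- abs(r$values - mu) < 1e-12 * max(1, abs(mu))
      contrib <- ifelse(eq, 0, -Inf)
    } else {
      contrib <- -((r$values - mu)^2) / (2 * sd_^2)
    }
    logsuit <- logsuit + contrib
  }
  s <- exp(logsuit - max(logsuit, na.rm = TRUE))
  s[is.na(ref$values)] <- NA
  out <- env_raster(s, ref$xll, ref$yll, ref$cellsize)
  attr(out, "provenance") <- list(model = model, background = background)
  out
}

#' Approximate a species distribution by thresholded flood fill
#'
#' Depth-first search from every occurrence cell through grid-connected
#' cells with suitability at or above `threshold`; cells never visited are
#' set to 0, visited cells keep their suitability value, and occurrence
#' cells are finally set to 1. This removes suitable areas disconnected
#' from any verified collection site.
#'
#' @param suit suitability [env_raster] in `[0, 1]`.
#' @param occ an [occurrence_set].
#' @param threshold visiting threshold (default 0.25).
#' @param connectivity 8 (default) or 4 neighborhood.
#' @return an [env_raster] distribution map with a `provenance` attribute.
#' @export
approximate_distribution <- function(suit, occ, threshold = 0.25,
                                     connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  v <- suit$values
  nr <- nrow(v); nc <- ncol(v)
  cells <- occ$cells
  if (is.null(cells)) cells <- cell_index(suit, occ$points)
  pass <- !is.na(v) & v >= threshold
  visited <- matrix(FALSE, nr, nc)
  # iterative DFS over the passable cells, seeded at the occurrence cells
  stack_r <- integer(nr * nc); stack_c <- integer(nr * nc)
  top <- 0L
  push <- function(r, c) {
    top <<- top + 1L
    stack_r[top] <<- r; stack_c[top] <<- c
  }
  for (k in seq_len(nrow(cells))) {
    r <- cells[k, 1]; c <- cells[k, 2]
    if (!visited[r, c]) { visited[r, c] <- TRUE; push(r, c) }
  }
  dr4 <- c(-1L, 1L, 0L, 0L); dc4 <- c(0L, 0L, -1L, 1L)
  dr8 <- c(dr4, -1L, -1L, 1L, 1L); dc8 <- c(dc4, -1L, 1L, -1L, 1L)
  dr <- if (connectivity == 8L) dr8 else dr4
  dc <- if (connectivity == 8L) dc8 else dc4
  while (top > 0L) {
    r <- stack_r[top]; c <- stack_c[top]; top <- top - 1L
    for (n in seq_along(dr)) {
      rr <- r + dr[n]; cc <- c + dc[n]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      if (!visited[rr, cc] && pass[rr, cc]) {
        visited[rr, cc] <- TRUE
        top <- top + 1L
        stack_r[top] <- rr; stack_c[top] <- cc
      }
    }
  }
  out <- ifelse(visited & pass, v, 0)
  out[cbind(cells[, 1], cells[, 2])] <- 1
  res <- env_raster(out, suit$xll, suit$yll, suit$cellsize)
  attr(res, "provenance") <- list(threshold = threshold,
                                  connectivity = connectivity)
  res
}

#' Pairwise range overlap of two approximate distributions
#'
#' (1) multiply the distribution rasters, (2) threshold the product, (3)
#' count non-zero cells, (4) divide by the non-zero cell count of the
#' species with the smaller distribution area.
#'
#' @param da,db distribution [env_raster]s (co-registered).
#' @param threshold product threshold (default 0.25).
#' @param denominator `"distribution"` (the printed recipe: non-zero cells
#'   of the species rasters) or `"thresholded"` (non-zero cells after
#'   re-thresholding each species raster).
#' @return overlap in `[0, 1]`; `NA` with a warning when a species has no
#'   non-zero cells.
#' @export
pairwise_overlap <- function(da, db, threshold = 0.25,
                             denominator = c("distribution", "thresholded")) {
  denominator <- match.arg(denominator)
  .check_same_grid(list(da, db))
  a <- da$values; b <- db$values
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  prod_ <- a * b
  prod_[prod_ < threshold] <- 0
  num <- sum(prod_ > 0)
  count_nz <- function(v) {
    if (denominator == "thresholded") sum(v >= threshold) else sum(v > 0)
  }
  na_ <- count_nz(a); nb_ <- count_nz(b)
  if (na_ == 0L || nb_ == 0L) {
    warning("a species has an empty distribution; overlap undefined")
    return(NA_real_)
  }
  num / min(na_, nb_)
}

#' Schoener's D niche overlap
#'
#' Both rasters are normalized to sum 1 over their shared valid cells;
#' `D = 1 - 0.5 * sum(|p_a - p_b|)`.
#'
#' @param sa,sb suitability [env_raster]s (co-registered, positive sums).
#' @return D in `[0, 1]`.
#' @export
schoener_d <- function(sa, sb) {
  .check_same_grid(list(sa, sb))
  a <- as.vector(sa$values); b <- as.vector(sb$values)
  valid <- !is.na(a) & !is.na(b)
  a <- a[valid]; b <- b[valid]
  if (sum(a) <= 0 || sum(b) <= 0) stop("zero-sum suitability raster")
  a <- a / sum(a); b <- b / sum(b)
  1 - 0.5 * sum(abs(a - b))
}

# pooled-label permutation helper shared by both permutation tests; the
# pool is canonicalized (sorted) and the smaller group drawn first so the
# null draws are identical whichever way the two groups are passed
.permute_occurrences <- function(occ_a, occ_b, raster) {
  pool <- rbind(occ_a$points, occ_b$points)
  pool <- pool[order(pool[, 1], pool[, 2]), , drop = FALSE]
  na <- nrow(occ_a$points); nb <- nrow(pool) - na
  nmin <- min(na, nb)
  perm <- sample.int(nrow(pool))
  small <- pool[perm[seq_len(nmin)], , drop = FALSE]
  large <- pool[perm[-seq_len(nmin)], , drop = FALSE]
  if (na <= nb) {
    list(a = occurrence_set(occ_a$taxon, small, raster),
         b = occurrence_set(occ_b$taxon, large, raster))
  } else {
    list(a = occurrence_set(occ_a$taxon, large, raster),
         b = occurrence_set(occ_b$taxon, small, raster))
  }
}

#' Niche-equivalency permutation test
#'
#' Observed Schoener's D between the two fitted suitability rasters is
#' compared with a null distribution obtained by pooling the occurrences,
#' reassigning them randomly to groups of the original sizes, and
#' refitting both models. One-sided toward lower D (niches more different
#' than random splits): `p = (1 + #(null_D <= observed_D)) / (n_perm + 1)`.
#'
#' @param occ_a,occ_b [occurrence_set]s.
#' @param env list of environmental [env_raster] layers.
#' @param enm_model passed to [fit_enm()].
#' @param n_perm permutations (default 200).
#' @param background background specification recorded in provenance
#'   (`n_points`, `radius_km`, `range_km`); used only by ENMs that need
#'   background points.
#' @param seed integer seed.
#' @param m Bonferroni multiplier.
#' @return object of class `overlap_result` with `overlap` (observed D),
#'   `p`, `p_corrected`, `p_corrected_capped`, `null_values`.
#' @export
niche_equivalency_test <- function(occ_a, occ_b, env,
                                   enm_model = "builtin-gaussian",
                                   n_perm = 200, background = list(
                                     n_points = 1000, radius_km = 20,
                                     range_km = 50),
                                   seed = 1L, m = 1) {
  ref <- .check_same_grid(env)
  fit <- function(o) fit_enm(o, env, model = enm_model, background = background)
  observed <- schoener_d(fit(occ_a), fit(occ_b))
  null_vals <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pp <- .permute_occurrences(occ_a, occ_b, ref)
      schoener_d(fit(pp$a), fit(pp$b))
    }, 0)
  })
  p <- (1 + sum(null_vals <= observed)) / (n_perm + 1)
  structure(list(overlap = observed, p = p, p_corrected = p * m,
                 p_corrected_capped = min(1, p * m),
                 n_permutations = n_perm, null_values = null_vals),
            class = "overlap_result")
}

#' Permutation test of sympatry from approximate distributions
#'
#' Observed overlap: fit an ENM per taxon (with longitude/latitude layers
#' appended to the environmental stack), approximate each distribution by
#' the thresholded flood fill, and compute [pairwise_overlap()]. The null
#' permutes taxon labels over the pooled occurrences (preserving group
#' sizes) and redoes the full chain. One-sided toward lower overlap:
#' a significant result is a deviation from sympatry (allopatry signal).
#'
#' @inheritParams niche_equivalency_test
#' @param threshold flood-fill and product threshold.
#' @param connectivity flood-fill connectivity.
#' @param add_lonlat append lon/lat coordinate layers (default `TRUE`).
#' @param n_perm permutations (default 400).
#' @return an `overlap_result`.
#' @export
sympatry_test <- function(occ_a, occ_b, env, enm_model = "builtin-gaussian",
                          n_perm = 400, threshold = 0.25, connectivity = 8L,
                          add_lonlat = TRUE, seed = 1L, m = 1) {
  ref <- .check_same_grid(env)
  env2 <- if (add_lonlat) c(env, lonlat_rasters(ref)) else env
  chain <- function(oa, ob) {
    da <- approximate_distribution(fit_enm(oa, env2, model = enm_model), oa,
                                   threshold, connectivity)
    db <- approximate_distribution(fit_enm(ob, env2, model = enm_model), ob,
                                   threshold, connectivity)
    pairwise_overlap(da, db, threshold)
  }
  observed <- chain(occ_a, occ_b)
  null_vals <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pp <- .permute_occurrences(occ_a, occ_b, ref)
      chain(pp$a, pp$b)
    }, 0)
  })
  p <- (1 + sum(null_vals <= observed, na.rm = TRUE)) / (n_perm + 1)
  structure(list(overlap = observed, p = p, p_corrected = p * m,
                 p_corrected_capped = min(1, p * m),
                 n_permutations = n_perm, null_values = null_vals),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap/equivalency test: observed=%.4f p=%.4f corr. p=%.2f\n",
              x$overlap, x$p, x$p_corrected))
  invisible(x)
}

#' Great-circle distance in kilometers
#' @param p1,p2 (lon, lat) vectors or two-column matrices, degrees.
#' @return distance(s) in km on a sphere of radius 6371 km.
#' @export
haversine_km <- function(p1, p2) {
  p1 <- matrix(p1, ncol = 2); p2 <- matrix(p2, ncol = 2)
  to_rad <- pi / 180
  dlat <- (p2[, 2] - p1[, 2]) * to_rad
  dlon <- (p2[, 1] - p1[, 1]) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(p1[, 2] * to_rad) * cos(p2[, 2] * to_rad) * sin(dlon / 2)^2
  6371 * 2 * asin(pmin(1, sqrt(a)))
}

#' Sample background points within a buffer of occurrences
#'
#' Uniform points inside the union of great-circle buffers around the
#' occurrence records, for ENMs that require background data.
#'
#' @param occ an [occurrence_set].
#' @param raster extent [env_raster].
#' @param n_points number of points (default 1000).
#' @param radius_km buffer radius (default 20).
#' @param seed integer seed.
#' @return matrix of (lon, lat) points.
#' @export
sample_background <- function(occ, raster, n_points = 1000, radius_km = 20,
                              seed = 1L) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  lon_rng <- c(raster$xll, raster$xll + nc * raster$cellsize)
  lat_rng <- c(raster$yll, raster$yll + nr * raster$cellsize)
  with_seed(seed, {
    out <- matrix(NA_real_, 0, 2)
    guard <- 0L
    while (nrow(out) < n_points && guard < 200L) {
      guard <- guard + 1L
      cand <- cbind(stats::runif(n_points, lon_rng[1], lon_rng[2]),
                    stats::runif(n_points, lat_rng[1], lat_rng[2]))
      keep <- vapply(seq_len(nrow(cand)), function(i) {
        min(haversine_km(matrix(cand[i, ], ncol = 2,
                                nrow = nrow(occ$points), byrow = TRUE),
                         occ$points)) <= radius_km
      }, TRUE)
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    out[seq_len(min(n_points, nrow(out))), , drop = FALSE]
  })
}
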