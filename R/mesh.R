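# Conforming constrained Delaunay triangulation of a leaf silhouette.
#
# Incremental Bowyer-Watson Delaunay triangulation, made conforming by
# recursively inserting midpoints of constraint segments (contour and
# midvein edges) that are not yet edges of the triangulation (Steiner
# points), plus centroid insertion for triangle-area control.

.circumcircle <- function(verts, tri) {
  a <- verts[tri[1], ]; b <- verts[tri[2], ]; c <- verts[tri[3], ]
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) {
    return(c((a[1] + b[1] + c[1]) / 3, (a[2] + b[2] + c[2]) / 3, Inf))
  }
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, (ux - a[1])^2 + (uy - a[2])^2)
}

# state: verts (V x 2), tris (T x 3), cc (T x 2), r2 (T)
.bw_insert <- function(state, p_idx) {
  p <- state$verts[p_idx, ]
  bad <- which((state$cc[, 1] - p[1])^2 + (state$cc[, 2] - p[2])^2 <=
                 state$r2 * (1 + 1e-9))
  if (!length(bad)) {
    # numerical fallback: use the triangle whose circumcircle is nearest
    bad <- which.min((state$cc[, 1] - p[1])^2 + (state$cc[, 2] - p[2])^2 -
                       state$r2)
  }
  edges <- rbind(state$tris[bad, c(1, 2), drop = FALSE],
                 state$tris[bad, c(2, 3), drop = FALSE],
                 state$tris[bad, c(3, 1), drop = FALSE])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  once <- !(key %in% key[duplicated(key)])
  boundary <- edges[once, , drop = FALSE]
  new_tris <- cbind(boundary, p_idx)
  keep <- setdiff(seq_len(nrow(state$tris)), bad)
  state$tris <- rbind(state$tris[keep, , drop = FALSE], new_tris)
  state$cc <- state$cc[keep, , drop = FALSE]
  state$r2 <- state$r2[keep]
  for (t in seq_len(nrow(new_tris))) {
    ccr <- .circumcircle(state$verts, new_tris[t, ])
    state$cc <- rbind(state$cc, ccr[1:2])
    state$r2 <- c(state$r2, ccr[3])
  }
  state
}

.bw_triangulate <- function(pts) {
  rng <- apply(pts, 2, range)
  ctr <- colMeans(rng)
  span <- max(rng[2, ] - rng[1, ], 1)
  big <- 50 * span
  super <- rbind(c(ctr[1] - big, ctr[2] - big),
                 c(ctr[1] + big, ctr[2] - big),
                 c(ctr[1], ctr[2] + big))
  state <- list(verts = rbind(super, pts),
                tris = matrix(1:3, nrow = 1L),
                cc = matrix(.circumcircle(super, 1:3)[1:2], nrow = 1L),
                r2 = .circumcircle(super, 1:3)[3])
  for (i in seq_len(nrow(pts))) state <- .bw_insert(state, i + 3L)
  state
}

.edge_keys <- function(tris) {
  e <- rbind(tris[, c(1, 2), drop = FALSE], tris[, c(2, 3), drop = FALSE],
             tris[, c(3, 1), drop = FALSE])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

.tri_areas <- function(verts, tris) {
  a <- verts[tris[, 1], , drop = FALSE]
  b <- verts[tris[, 2], , drop = FALSE]
  c <- verts[tris[, 3], , drop = FALSE]
  0.5 * ((b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
           (c[, 1] - a[, 1]) * (b[, 2] - a[, 2]))
}

# walk a chain of subsegments (two-column index matrix) from start to end
.walk_chain <- function(subs, start, end) {
  adj <- list()
  add <- function(a, b) {
    ka <- as.character(a)
    adj[[ka]] <<- c(adj[[ka]], b)
  }
  for (r in seq_len(nrow(subs))) { add(subs[r, 1], subs[r, 2]); add(subs[r, 2], subs[r, 1]) }
  chain <- start
  prev <- NA_integer_
  cur <- start
  for (step in seq_len(nrow(subs) + 1L)) {
    if (cur == end && step > 1L) break
    nxt <- setdiff(adj[[as.character(cur)]], prev)
    if (!length(nxt)) break
    prev <- cur
    cur <- nxt[1]
    chain <- c(chain, cur)
  }
  chain
}

#' Build a conforming constrained Delaunay mesh of a leaf
#'
#' Triangulates the contour interior with the contour and midvein edges as
#' constraints. Constraint segments absent from the Delaunay triangulation
#' are split at their midpoints (Steiner points) until all are mesh edges;
#' interior grid points plus centroid splitting control triangle size.
#'
#' @param leaf a [leaf_annotation].
#' @param max_triangle_area target maximum triangle area (pixel^2 units);
#'   default `polygon area / 200`.
#' @return an object of class `tri_mesh`: `vertices`, `triangles`
#'   (counter-clockwise), `constrained_edges`, `midvein_vertex_ids`
#'   (ordered base to tip), `contour_vertex_ids` (the original polygon, in
#'   order), `boundary_chain` (full boundary walk incl. Steiner points).
#' @export
build_mesh <- function(leaf, max_triangle_area = NULL) {
  stopifnot(inherits(leaf, "leaf_annotation"))
  C <- leaf$contour; M <- leaf$midvein
  area_poly <- polygon_area(C)
  if (area_poly <= 0) stop("degenerate (zero-area) polygon")
  if (is.null(max_triangle_area)) max_triangle_area <- area_poly / 200
  nc <- nrow(C)
  pts <- C
  # snap midvein vertices onto (near-)coincident contour vertices; the
  # tolerance is relative to the leaf scale so annotation endpoints that sit
  # on the outline do not create degenerate slivers
  snap2 <- (2e-4 * max(apply(C, 2, function(v) diff(range(v)))))^2
  mv_idx <- integer(nrow(M))
  for (k in seq_len(nrow(M))) {
    d2 <- (pts[, 1] - M[k, 1])^2 + (pts[, 2] - M[k, 2])^2
    hit <- which.min(d2)
    if (d2[hit] < snap2) {
      mv_idx[k] <- hit
    } else {
      pts <- rbind(pts, M[k, ])
      mv_idx[k] <- nrow(pts)
    }
  }
  cons <- data.frame(i = c(seq_len(nc), mv_idx[-length(mv_idx)]),
                     j = c(c(2:nc, 1L), mv_idx[-1]),
                     kind = c(rep("contour", nc),
                              rep("midvein", length(mv_idx) - 1L)),
                     orig = c(seq_len(nc), seq_len(length(mv_idx) - 1L)))
  # interior Steiner grid, kept clear of the constraint segments
  h <- sqrt(2 * max_triangle_area)
  gx <- seq(min(C[, 1]) + h / 2, max(C[, 1]), by = h)
  gy <- seq(min(C[, 2]) + h / 2, max(C[, 2]), by = h)
  if (length(gx) && length(gy)) {
    grid <- as.matrix(expand.grid(x = gx, y = gy))
    jit <- 0.1 * h * cbind(sin(9.7 * seq_len(nrow(grid))),
                           cos(5.3 * seq_len(nrow(grid))))
    grid <- grid + jit
    inside <- points_in_polygon(grid, C)
    grid <- grid[inside, , drop = FALSE]
    if (nrow(grid)) {
      segs <- rbind(C, M)  # for distance testing use all constraint polylines
      ok <- vapply(seq_len(nrow(grid)), function(i) {
        dc <- .point_segment_dist(grid[i, ], C)
        dm <- .polyline_dist(grid[i, ], M)
        min(dc, dm) > 0.45 * h
      }, TRUE)
      grid <- grid[ok, , drop = FALSE]
    }
    if (nrow(grid)) pts <- rbind(pts, grid)
  }
  state <- .bw_triangulate(pts)
  # conforming pass: split constraints until all are triangulation edges
  for (round in 1:25) {
    keys <- .edge_keys(state$tris)
    ck <- paste(pmin(cons$i, cons$j) + 3L, pmax(cons$i, cons$j) + 3L)
    missing <- which(!(ck %in% keys))
    if (!length(missing)) break
    if (round == 25L) stop("conforming triangulation did not converge")
    for (r in missing) {
      mid <- (state$verts[cons$i[r] + 3L, ] + state$verts[cons$j[r] + 3L, ]) / 2
      state$verts <- rbind(state$verts, mid)
      new_idx <- nrow(state$verts) - 3L
      state <- .bw_insert(state, new_idx + 3L)
      cons <- rbind(cons,
                    data.frame(i = cons$i[r], j = new_idx, kind = cons$kind[r],
                               orig = cons$orig[r]),
                    data.frame(i = new_idx, j = cons$j[r], kind = cons$kind[r],
                               orig = cons$orig[r]))
    }
    cons <- cons[-missing, , drop = FALSE]
  }
  # centroid splitting of oversized interior triangles (then re-conform)
  for (round in 1:6) {
    areas <- abs(.tri_areas(state$verts, state$tris))
    cent <- (state$verts[state$tris[, 1], , drop = FALSE] +
               state$verts[state$tris[, 2], , drop = FALSE] +
               state$verts[state$tris[, 3], , drop = FALSE]) / 3
    real <- state$tris[, 1] > 3L & state$tris[, 2] > 3L & state$tris[, 3] > 3L
    inside <- points_in_polygon(cent, C)
    big <- which(real & inside & areas > max_triangle_area)
    if (!length(big)) break
    for (t in big) {
      p <- cent[t, ]
      if (.point_segment_dist(p, C) < 0.2 * sqrt(areas[t]) ||
          .polyline_dist(p, M) < 0.2 * sqrt(areas[t])) next
      state$verts <- rbind(state$verts, p)
      state <- .bw_insert(state, nrow(state$verts))
    }
    keys <- .edge_keys(state$tris)
    ck <- paste(pmin(cons$i, cons$j) + 3L, pmax(cons$i, cons$j) + 3L)
    if (any(!(ck %in% keys))) {
      # re-run the conforming pass
      repeat {
        keys <- .edge_keys(state$tris)
        ck <- paste(pmin(cons$i, cons$j) + 3L, pmax(cons$i, cons$j) + 3L)
        missing <- which(!(ck %in% keys))
        if (!length(missing)) break
        for (r in missing) {
          mid <- (state$verts[cons$i[r] + 3L, ] + state$verts[cons$j[r] + 3L, ]) / 2
          state$verts <- rbind(state$verts, mid)
          new_idx <- nrow(state$verts) - 3L
          state <- .bw_insert(state, new_idx + 3L)
          cons <- rbind(cons,
                        data.frame(i = cons$i[r], j = new_idx,
                                   kind = cons$kind[r], orig = cons$orig[r]),
                        data.frame(i = new_idx, j = cons$j[r],
                                   kind = cons$kind[r], orig = cons$orig[r]))
        }
        cons <- cons[-missing, , drop = FALSE]
      }
    }
  }
  # strip super-triangle, keep triangles whose centroid is inside the polygon
  tris <- state$tris
  real <- tris[, 1] > 3L & tris[, 2] > 3L & tris[, 3] > 3L
  tris <- tris[real, , drop = FALSE] - 3L
  verts <- state$verts[-(1:3), , drop = FALSE]
  cent <- (verts[tris[, 1], , drop = FALSE] + verts[tris[, 2], , drop = FALSE] +
             verts[tris[, 3], , drop = FALSE]) / 3
  tris <- tris[points_in_polygon(cent, C), , drop = FALSE]
  # consistent counter-clockwise orientation (in the stored coordinates)
  ar <- .tri_areas(verts, tris)
  flip <- ar < 0
  tmp <- tris[flip, 2]; tris[flip, 2] <- tris[flip, 3]; tris[flip, 3] <- tmp
  if (any(abs(.tri_areas(verts, tris)) < 1e-12 * max(abs(ar)))) {
    tris <- tris[abs(.tri_areas(verts, tris)) > 1e-12 * max(abs(ar)), ,
                 drop = FALSE]
  }
  # ordered midvein chain (base to tip), including split points
  mv_subs <- as.matrix(cons[cons$kind == "midvein", c("i", "j")])
  mv_chain <- .walk_chain(mv_subs, mv_idx[1], mv_idx[length(mv_idx)])
  bd_subs <- as.matrix(cons[cons$kind == "contour", c("i", "j")])
  structure(list(vertices = unname(verts), triangles = unname(tris),
                 constrained_edges = unname(as.matrix(cons[, c("i", "j")])),
                 midvein_vertex_ids = mv_chain,
                 contour_vertex_ids = seq_len(nc),
                 boundary_subsegments = unname(bd_subs),
                 polygon_area = area_poly),
            class = "tri_mesh")
}

.polyline_dist <- function(p, poly) {
  n <- nrow(poly)
  a <- poly[-n, , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  ap <- cbind(p[1] - a[, 1], p[2] - a[, 2])
  len2 <- rowSums(ab^2)
  t <- pmin(1, pmax(0, rowSums(ap * ab) / pmax(len2, 1e-300)))
  proj <- a + ab * t
  min(sqrt((p[1] - proj[, 1])^2 + (p[2] - proj[, 2])^2))
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d triangles, %d midvein chain vertices\n",
              nrow(x$vertices), nrow(x$triangles), length(x$midvein_vertex_ids)))
  invisible(x)
}
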