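# As-rigid-as-possible straightening of leaf meshes.
#
# The midvein chain is pinned to the +x axis with its original consecutive
# spacing (hard constraints); the remaining vertices are solved by ARAP
# local-global iterations with cotangent weights (clamped at zero). The
# initial guess places each vertex at its arc-length / signed-offset
# coordinates relative to the midvein polyline, which is the exact inverse
# for a constant-curvature bend and a good start otherwise.

# cotangent Laplacian edge list: data.frame(i, j, w) with i < j
.cot_edges <- function(verts, tris) {
  cot_at <- function(a, b, c) {
    # cotangent of the angle at vertex a in triangle (a, b, c)
    u <- verts[b, , drop = FALSE] - verts[a, , drop = FALSE]
    v <- verts[c, , drop = FALSE] - verts[a, , drop = FALSE]
    dot <- rowSums(u * v)
    crs <- abs(u[, 1] * v[, 2] - u[, 2] * v[, 1])
    dot / pmax(crs, 1e-300)
  }
  half <- rbind(
    cbind(tris[, 1], tris[, 2], cot_at(tris[, 3], tris[, 1], tris[, 2])),
    cbind(tris[, 2], tris[, 3], cot_at(tris[, 1], tris[, 2], tris[, 3])),
    cbind(tris[, 3], tris[, 1], cot_at(tris[, 2], tris[, 3], tris[, 1])))
  i <- pmin(half[, 1], half[, 2])
  j <- pmax(half[, 1], half[, 2])
  w <- rowsum(half[, 3] / 2, group = paste(i, j))
  keys <- do.call(rbind, strsplit(rownames(w), " "))
  data.frame(i = as.integer(keys[, 1]), j = as.integer(keys[, 2]),
             w = pmax(as.numeric(w), 0))  # clamp negative weights
}

# signed arc-length/offset coordinates of points relative to a polyline
.axis_coords <- function(pts, polyline) {
  n <- nrow(polyline)
  a <- polyline[-n, , drop = FALSE]
  b <- polyline[-1, , drop = FALSE]
  ab <- b - a
  len <- sqrt(rowSums(ab^2))
  cum <- c(0, cumsum(len))
  s <- t_off <- numeric(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    p <- pts[k, ]
    ap1 <- p[1] - a[, 1]; ap2 <- p[2] - a[, 2]
    tt <- pmin(1, pmax(0, (ap1 * ab[, 1] + ap2 * ab[, 2]) / pmax(len^2, 1e-300)))
    px <- a[, 1] + ab[, 1] * tt
    py <- a[, 2] + ab[, 2] * tt
    d2 <- (p[1] - px)^2 + (p[2] - py)^2
    seg <- which.min(d2)
    s[k] <- cum[seg] + tt[seg] * len[seg]
    cross <- ab[seg, 1] * (p[2] - a[seg, 2]) - ab[seg, 2] * (p[1] - a[seg, 1])
    t_off[k] <- sign(cross) * sqrt(d2[seg])
  }
  cbind(s, t_off)
}

#' Straighten a leaf mesh
#'
#' Places the midvein chain on the horizontal axis anchored at the basal
#' vertex with consecutive spacing equal to the original Euclidean spacing,
#' and solves the remaining vertices with ARAP (local-global iterations,
#' cotangent weights, midvein vertices as hard constraints) until the
#' maximum per-iteration vertex displacement falls below `tol` or
#' `max_iter` iterations.
#'
#' @param mesh a [build_mesh()] `tri_mesh`.
#' @param tol convergence tolerance on the per-iteration displacement.
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with a warning and `converged = FALSE`.
#' @return list with `mesh` (the deformed `tri_mesh`), `contour` (deformed
#'   positions of the original contour vertices, original order),
#'   `converged`, `iterations`, `residual`.
#' @export
straighten <- function(mesh, tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(mesh, "tri_mesh"))
  V0 <- mesh$vertices
  nv <- nrow(V0)
  chain <- mesh$midvein_vertex_ids
  if (length(chain) < 2L) stop("midvein chain needs at least two vertices")
  seg <- sqrt(rowSums((V0[chain[-1], , drop = FALSE] -
                         V0[chain[-length(chain)], , drop = FALSE])^2))
  target <- cbind(c(0, cumsum(seg)), 0)
  target_full <- matrix(0, nrow(V0), 2)
  target_full[chain, ] <- target
  edges <- .cot_edges(V0, mesh$triangles)
  # initial guess: arc-length / signed-offset coordinates about the midvein
  P <- .axis_coords(V0, V0[chain, , drop = FALSE])
  P[chain, ] <- target
  fixed <- rep(FALSE, nv)
  fixed[chain] <- TRUE
  free <- which(!fixed)
  if (!length(free)) {
    res_mesh <- mesh; res_mesh$vertices <- P
    return(list(mesh = res_mesh, contour = P[mesh$contour_vertex_ids, ],
                converged = TRUE, iterations = 0L, residual = 0))
  }
  L <- Matrix::sparseMatrix(
    i = c(edges$i, edges$j, edges$i, edges$j),
    j = c(edges$j, edges$i, edges$i, edges$j),
    x = c(-edges$w, -edges$w, rep(0, 2 * nrow(edges))),
    dims = c(nv, nv))
  diag(L) <- -Matrix::rowSums(L) + 1e-12
  Lff <- L[free, free, drop = FALSE]
  Lfc <- L[free, fixed, drop = FALSE]
  fac <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(Lff), "CsparseMatrix"),
                          LDL = FALSE, perm = TRUE)
  # directed edge list for the per-vertex covariance accumulation
  di <- c(edges$i, edges$j)
  dj <- c(edges$j, edges$i)
  dw <- c(edges$w, edges$w)
  e0x <- V0[di, 1] - V0[dj, 1]
  e0y <- V0[di, 2] - V0[dj, 2]
  residual <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # local step: best-fitting rotation per vertex
    e1x <- P[di, 1] - P[dj, 1]
    e1y <- P[di, 2] - P[dj, 2]
    s11 <- rowsum(dw * e0x * e1x, di)
    s12 <- rowsum(dw * e0x * e1y, di)
    s21 <- rowsum(dw * e0y * e1x, di)
    s22 <- rowsum(dw * e0y * e1y, di)
    idx <- as.integer(rownames(s11))
    theta <- numeric(nv)
    theta[idx] <- atan2(s12 - s21, s11 + s22)
    # rotation by -theta? fix sign: R maps e0 toward e1
    cth <- cos(theta); sth <- sin(theta)
    # global step rhs: sum_j w/2 (R_i + R_j) (p0_i - p0_j)
    cc <- cth[di] + cth[dj]
    ss <- sth[di] + sth[dj]
    bx_e <- 0.5 * dw * (cc * e0x - ss * e0y)
    by_e <- 0.5 * dw * (ss * e0x + cc * e0y)
    bx <- numeric(nv); by <- numeric(nv)
    sx <- rowsum(bx_e, di); sy <- rowsum(by_e, di)
    bx[as.integer(rownames(sx))] <- sx
    by[as.integer(rownames(sy))] <- sy
    rhs <- cbind(bx[free], by[free]) -
      as.matrix(Lfc %*% target_full[fixed, , drop = FALSE])
    newP <- as.matrix(Matrix::solve(fac, rhs))
    disp <- max(abs(newP - P[free, , drop = FALSE]))
    P[free, ] <- newP
    residual <- disp
    if (disp < tol) break
  }
  converged <- residual < tol
  if (!converged) {
    warning(sprintf("ARAP did not converge: residual %.3g after %d iterations",
                    residual, it))
  }
  res_mesh <- mesh
  res_mesh$vertices <- P
  list(mesh = res_mesh, contour = P[mesh$contour_vertex_ids, , drop = FALSE],
       converged = converged, iterations = it, residual = residual)
}

#' Map leaf texture between meshes with shared topology
#'
#' Every output pixel whose center lies inside a deformed triangle is
#' sampled (nearest neighbor) from the source image at the position with
#' the same barycentric coordinates in the original triangle; pixels
#' outside the mesh get `background`.
#'
#' @param original,deformed `tri_mesh` objects with identical triangles.
#' @param image numeric matrix (rows = y, columns = x); pixel (r, c) has
#'   center (c - 0.5, r - 0.5).
#' @param out_dim output dimensions `c(rows, cols)`; default `dim(image)`.
#' @param out_origin xy offset of the output frame (default `c(0, 0)`).
#' @param background value for pixels outside the mesh.
#' @return numeric matrix of size `out_dim`.
#' @export
map_texture <- function(original, deformed, image, out_dim = dim(image),
                        out_origin = c(0, 0), background = 0) {
  if (!identical(dim(original$triangles), dim(deformed$triangles)) ||
      !identical(original$triangles, deformed$triangles)) {
    stop("meshes must share topology")
  }
  out <- matrix(background, out_dim[1], out_dim[2])
  tris <- deformed$triangles
  Vd <- deformed$vertices
  Vo <- original$vertices
  nr_in <- nrow(image); nc_in <- ncol(image)
  for (t in seq_len(nrow(tris))) {
    a <- Vd[tris[t, 1], ] - out_origin
    b <- Vd[tris[t, 2], ] - out_origin
    c_ <- Vd[tris[t, 3], ] - out_origin
    cmin <- max(1L, floor(min(a[1], b[1], c_[1]) + 0.5))
    cmax <- min(out_dim[2], ceiling(max(a[1], b[1], c_[1]) + 0.5))
    rmin <- max(1L, floor(min(a[2], b[2], c_[2]) + 0.5))
    rmax <- min(out_dim[1], ceiling(max(a[2], b[2], c_[2]) + 0.5))
    if (cmin > cmax || rmin > rmax) next
    px <- rep(seq(cmin, cmax) - 0.5, each = rmax - rmin + 1L)
    py <- rep(seq(rmin, rmax) - 0.5, times = cmax - cmin + 1L)
    det <- (b[1] - a[1]) * (c_[2] - a[2]) - (c_[1] - a[1]) * (b[2] - a[2])
    if (abs(det) < 1e-300) next
    l1 <- ((b[2] - c_[2]) * (px - c_[1]) + (c_[1] - b[1]) * (py - c_[2])) / det
    l2 <- ((c_[2] - a[2]) * (px - c_[1]) + (a[1] - c_[1]) * (py - c_[2])) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (!any(inside)) next
    sa <- Vo[tris[t, 1], ]; sb <- Vo[tris[t, 2], ]; sc <- Vo[tris[t, 3], ]
    sx <- l1[inside] * sa[1] + l2[inside] * sb[1] + l3[inside] * sc[1]
    sy <- l1[inside] * sa[2] + l2[inside] * sb[2] + l3[inside] * sc[2]
    src_c <- pmin(pmax(floor(sx) + 1L, 1L), nc_in)
    src_r <- pmin(pmax(floor(sy) + 1L, 1L), nr_in)
    out_c <- floor(px[inside]) + 1L
    out_r <- floor(py[inside]) + 1L
    out[cbind(out_r, out_c)] <- image[cbind(src_r, src_c)]
  }
  out
}
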