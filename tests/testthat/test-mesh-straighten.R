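# constrained triangulation and ARAP straightening

quad_leaf <- function() {
  # convex quadrilateral (rounded corners to reach 64 vertices) with a
  # simple 2-vertex midvein
  t <- seq(0, 2 * pi, length.out = 65)[-65]
  contour <- cbind(50 + 48 * sign(cos(t)) * abs(cos(t))^0.2,
                   25 + 23 * sign(sin(t)) * abs(sin(t))^0.2)
  leaf_annotation(contour, rbind(c(5, 25), c(95, 25)), check = FALSE)
}

test_that("meshes partition the polygon and honor the constraints", {
  leaf <- quad_leaf()
  mesh <- build_mesh(leaf, max_triangle_area = 80)
  areas <- intdelim:::.tri_areas(mesh$vertices, mesh$triangles)
  expect_true(all(areas > 0))  # consistent orientation, non-degenerate
  poly_area <- intdelim:::polygon_area(leaf$contour)
  expect_lt(abs(sum(areas) - poly_area) / poly_area, 1e-9)
  # every constrained edge is a mesh edge
  keys <- intdelim:::.edge_keys(mesh$triangles)
  ce <- mesh$constrained_edges
  expect_true(all(paste(pmin(ce[, 1], ce[, 2]),
                        pmax(ce[, 1], ce[, 2])) %in% keys))
  # the boundary of the mesh is the contour (plus collinear Steiner points)
  tab <- table(keys)
  boundary_keys <- names(tab)[tab == 1]
  bd <- mesh$boundary_subsegments
  expect_setequal(boundary_keys,
                  paste(pmin(bd[, 1], bd[, 2]), pmax(bd[, 1], bd[, 2])))
  # midvein chain runs base to tip
  chain <- mesh$midvein_vertex_ids
  expect_equal(mesh$vertices[chain[1], ], c(5, 25), tolerance = 1e-9)
  expect_equal(mesh$vertices[chain[length(chain)], ], c(95, 25),
               tolerance = 1e-9)
})

test_that("a 4x smaller area target at least doubles the triangle count", {
  sim <- simulate_leaf(leaf_model(length = 200, contour_points = 100,
                                  bend_curvature = 0, seed = 5))
  area <- intdelim:::polygon_area(sim$bent$contour)
  coarse <- build_mesh(sim$bent, max_triangle_area = area / 40)
  fine <- build_mesh(sim$bent, max_triangle_area = area / 160)
  expect_gte(nrow(fine$triangles), 2L * nrow(coarse$triangles))
})

test_that("straightening an already straight leaf is the identity", {
  sim <- simulate_leaf(leaf_model(length = 220, bend_curvature = 0, seed = 4))
  mesh <- build_mesh(sim$straight_truth)
  st <- straighten(mesh)
  expect_true(st$converged)
  expect_lt(max(abs(st$mesh$vertices - mesh$vertices)), 1e-6)
})

test_that("bent synthetic leaves straighten back to the ground truth", {
  kappas <- c(0.0015, 0.0026)  # kappa * length up to 0.8 at length 300
  for (k in kappas) {
    sim <- simulate_leaf(leaf_model(length = 300, bend_curvature = k,
                                    dissection = 1, contour_points = 140,
                                    seed = 11))
    mesh <- build_mesh(sim$bent)
    st <- straighten(mesh)
    expect_true(st$converged)
    gt <- sim$straight_truth$contour
    dev <- sqrt(rowSums((st$contour - gt)^2))
    expect_lt(mean(dev) / 300, 0.02)
    a1 <- intdelim:::polygon_area(st$contour)
    a0 <- intdelim:::polygon_area(gt)
    expect_lt(abs(a1 - a0) / a0, 0.05)
    # the output midvein is exactly straight and arc length is conserved
    mv <- st$mesh$vertices[st$mesh$midvein_vertex_ids, ]
    expect_lt(max(abs(mv[, 2])), 1e-9 * 300)
    orig_mv <- mesh$vertices[mesh$midvein_vertex_ids, ]
    expect_equal(sum(sqrt(rowSums(diff(mv)^2))),
                 sum(sqrt(rowSums(diff(orig_mv)^2))), tolerance = 1e-9)
  }
})

test_that("straightening is idempotent", {
  sim <- simulate_leaf(leaf_model(length = 260, bend_curvature = 0.002,
                                  contour_points = 120, seed = 13))
  mesh <- build_mesh(sim$bent)
  st1 <- straighten(mesh)
  st2 <- straighten(st1$mesh)
  expect_lt(max(abs(st2$mesh$vertices - st1$mesh$vertices)), 1e-6)
})

test_that("texture mapping preserves content and foreground mass", {
  sim <- simulate_leaf(leaf_model(length = 90, aspect = 0.3,
                                  bend_curvature = 0, contour_points = 100,
                                  seed = 6))
  # shift the leaf into a positive pixel frame
  lf <- sim$bent
  lf$contour <- sweep(lf$contour, 2, c(5, 40), "+")
  lf$midvein <- sweep(lf$midvein, 2, c(5, 40), "+")
  mesh <- build_mesh(lf)
  img <- matrix(7, 80, 110)
  out <- map_texture(mesh, mesh, img)
  inside <- out != 0
  expect_true(any(inside))
  expect_true(all(out[inside] == 7))  # constant color stays constant
  # identity deformation reproduces the input inside the mesh
  img2 <- matrix(stats::runif(80 * 110), 80, 110)
  out2 <- map_texture(mesh, mesh, img2)
  expect_equal(out2[inside], img2[inside], tolerance = 1e-12)
  # checkerboard under bend + straighten conserves foreground pixel count
  simb <- simulate_leaf(leaf_model(length = 90, aspect = 0.3,
                                   bend_curvature = 0.006,
                                   contour_points = 100, seed = 6))
  lfb <- simb$bent
  lfb$contour <- sweep(lfb$contour, 2, c(5, 40), "+")
  lfb$midvein <- sweep(lfb$midvein, 2, c(5, 40), "+")
  meshb <- build_mesh(lfb)
  stb <- straighten(meshb)
  def <- stb$mesh
  def$vertices <- sweep(def$vertices, 2, c(5, 40), "+")
  checker <- (outer(1:80, 1:110, "+") %% 2) * 1
  checker_out <- map_texture(meshb, def, checker + 1)
  n_in <- sum(checker_out > 0)
  n_src <- sum(intdelim:::points_in_polygon(
    cbind(rep(1:110, each = 80) - 0.5, rep(1:80, 110) - 0.5), lfb$contour))
  expect_lt(abs(n_in - n_src) / n_src, 0.05)
  expect_error(map_texture(mesh, meshb, img), "topology")
})
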