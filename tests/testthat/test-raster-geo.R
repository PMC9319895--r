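# rasters, ENM, flood-fill distribution, overlap and the permutation tests

test_that("ESRI ASCII grids round-trip including no-data", {
  v <- matrix(stats::runif(30), 5, 6)
  v[2, 3] <- NA
  r <- env_raster(v, xll = -3, yll = 40, cellsize = 0.5)
  path <- tempfile(fileext = ".asc")
  write_esri_ascii(r, path)
  got <- read_esri_ascii(path)
  expect_equal(got$values, unname(r$values), tolerance = 1e-9)
  expect_equal(got$xll, -3)
  expect_equal(got$cellsize, 0.5)
  expect_true(is.na(got$values[2, 3]))
})

test_that("depth averaging applies the stated no-data rules", {
  mk <- function(v) env_raster(matrix(v, 1, 3))
  out <- depth_average(list(list(mk(c(1, 1, NA)), mk(c(2, NA, NA)),
                                 mk(c(3, 3, NA)))))[[1]]
  expect_equal(out$values[1, 1], 2)
  expect_equal(out$values[1, 2], 2)   # mean of the two non-missing depths
  expect_true(is.na(out$values[1, 3]))
  same <- depth_average(list(list(mk(1:3), mk(1:3), mk(1:3))))[[1]]
  expect_equal(same$values, matrix(1:3 * 1.0, 1, 3))
})

test_that("raster PCA captures correlated layers and propagates the mask", {
  base <- matrix(stats::runif(100), 10, 10)
  base[1, 1] <- NA
  r1 <- env_raster(base)
  r2 <- env_raster(3 * base - 1)
  out <- raster_pca(list(r1, r2), n_keep = 2)
  expect_equal(out$variance_explained[1], 1, tolerance = 1e-9)
  expect_true(is.na(out$rasters[[1]]$values[1, 1]))
  expect_identical(is.na(out$rasters[[1]]$values), is.na(base))
  # independent equal-variance layers share the variance evenly
  z <- intdelim:::with_seed(2, list(
    env_raster(matrix(stats::rnorm(2500), 50, 50)),
    env_raster(matrix(stats::rnorm(2500), 50, 50)),
    env_raster(matrix(stats::rnorm(2500), 50, 50))))
  ve <- raster_pca(z, n_keep = 3)$variance_explained
  expect_lt(max(ve) - min(ve), 0.15)
  expect_error(raster_pca(list(r1, env_raster(matrix(0, 3, 3)))),
               "co-registered")
})

test_that("the builtin ENM is exact on degenerate input and validates", {
  env <- list(env_raster(matrix(c(1, 1, 2, 2, 1, 2), 2, 3)))
  occ <- occurrence_set("t", cbind(c(0.5, 0.5, 1.5, 0.5, 1.5),
                                   c(1.5, 0.5, 1.5, 1.5, 0.5)), env[[1]])
  # all occurrence cells have value 1 -> suitability 1 exactly where env == 1
  occ1 <- occurrence_set("t", cbind(rep(0.5, 5), rep(c(0.5, 1.5), 3)[1:5]),
                         env[[1]])
  s <- fit_enm(occ1, env, min_occurrences = 2)
  expect_true(all(s$values[env[[1]]$values == 1] == 1))
  expect_true(all(s$values[env[[1]]$values != 1] == 0))
  bad <- env_raster(matrix(1.2, 2, 3))
  expect_error(fit_enm(occ, env, model = "external-raster",
                       external_raster = bad), "\\[0, 1\\]")
  expect_error(fit_enm(occurrence_set("t", cbind(0.5, 0.5), env[[1]]), env),
               ">= 5")
})

test_that("the builtin ENM recovers the true niche ranking", {
  land <- simulate_landscape(landscape_model(n_rows = 40, n_cols = 40,
                                             n_occurrences = 60, seed = 2))
  fitted <- fit_enm(land$occurrences[[1]], land$env)
  rho <- stats::cor(as.vector(fitted$values),
                    as.vector(land$true_suitability[[1]]$values),
                    method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("flood fill equals the dilation oracle on random grids", {
  for (s in 1:6) {
    conn <- if (s %% 2 == 0) 4L else 8L
    vals <- intdelim:::with_seed(s, matrix(stats::runif(400), 20, 20))
    r <- env_raster(vals)
    seeds <- intdelim:::with_seed(100 + s,
                                  cbind(sample(20, 3), sample(20, 3)))
    cc <- cell_centers(r)
    occ <- occurrence_set("t", cbind(cc$lon[seeds[, 2]], cc$lat[seeds[, 1]]),
                          r)
    got <- approximate_distribution(r, occ, threshold = 0.4,
                                    connectivity = conn)
    want <- flood_oracle(vals, occ$cells, 0.4, conn)
    expect_equal(got$values, want, tolerance = 1e-12)
  }
})

test_that("flood fill respects barriers, seeds and the zero threshold", {
  v <- matrix(0.9, 5, 5)
  v[3, ] <- 0
  r <- env_raster(v)
  occ_top <- occurrence_set("t", cbind(1.5, 4.5), r)  # row 1
  d <- approximate_distribution(r, occ_top)
  expect_true(all(d$values[4:5, ] == 0))
  expect_true(all(d$values[2, ] == 0.9))
  expect_equal(d$values[1, 2], 1)  # occurrence cell forced to 1
  # occurrence below threshold still seeds and becomes 1
  low <- env_raster(matrix(0.1, 3, 3))
  occ <- occurrence_set("t", cbind(1.5, 1.5), low)
  dl <- approximate_distribution(low, occ)
  expect_equal(sum(dl$values == 1), 1L)
  expect_equal(sum(dl$values), 1)
  # zero threshold reaches the whole (positively connected) raster
  d0 <- approximate_distribution(low, occ, threshold = 0)
  expect_true(all(d0$values > 0))
})

test_that("pairwise overlap follows the four printed steps", {
  ones <- env_raster(matrix(1, 4, 4))
  expect_equal(pairwise_overlap(ones, ones), 1)
  A <- matrix(0, 3, 3); A[1:2, 1] <- 0.9
  B <- matrix(0, 3, 3); B[1:2, 3] <- 0.9
  expect_equal(pairwise_overlap(env_raster(A), env_raster(B)), 0)
  A2 <- matrix(0, 3, 3); A2[1, 1:2] <- 0.6; A2[2, 1:2] <- 0.6
  B2 <- matrix(0, 3, 3); B2[1, 1:2] <- 0.5; B2[3, 3] <- 0.9
  expect_equal(pairwise_overlap(env_raster(A2), env_raster(B2)), 2 / 3,
               tolerance = 1e-12)
  # symmetry and monotonicity under raising cells
  expect_equal(pairwise_overlap(env_raster(A2), env_raster(B2)),
               pairwise_overlap(env_raster(B2), env_raster(A2)))
  B3 <- B2; B3[2, 1] <- 0.9
  expect_gte(pairwise_overlap(env_raster(A2), env_raster(B3)),
             pairwise_overlap(env_raster(A2), env_raster(B2)))
  empty <- env_raster(matrix(0, 3, 3))
  expect_warning(o <- pairwise_overlap(env_raster(A2), empty), "empty")
  expect_true(is.na(o))
})

test_that("Schoener's D matches identities, hand case and the triangle bound", {
  x <- env_raster(matrix(stats::runif(25), 5, 5))
  expect_equal(schoener_d(x, x), 1, tolerance = 1e-12)
  pa <- env_raster(matrix(c(0.5, 0.5, 0), 1, 3))
  pb <- env_raster(matrix(c(0, 0.5, 0.5), 1, 3))
  expect_equal(schoener_d(pa, pb), 0.5, tolerance = 1e-12)
  da <- env_raster(matrix(c(1, 1, 0, 0), 1, 4))
  db <- env_raster(matrix(c(0, 0, 1, 1), 1, 4))
  expect_equal(schoener_d(da, db), 0)
  for (s in 1:5) {
    rs <- intdelim:::with_seed(s, replicate(3, matrix(stats::runif(16), 4, 4),
                                            simplify = FALSE))
    a <- env_raster(rs[[1]]); b <- env_raster(rs[[2]]); c_ <- env_raster(rs[[3]])
    expect_lte(abs(schoener_d(a, c_) - schoener_d(b, c_)),
               1 - schoener_d(a, b) + 1e-12)
  }
})

test_that("sympatry and equivalency tests hit their extremes and symmetry", {
  land <- simulate_landscape(landscape_model(
    n_rows = 30, n_cols = 30, scenario = "allopatric", niche_widths = 0.45,
    n_occurrences = 40, seed = 6))
  ge <- sympatry_test(land$occurrences[[1]], land$occurrences[[2]],
                      land$env, n_perm = 99, seed = 2)
  expect_equal(ge$p, 1 / 100)
  expect_equal(ge$overlap, 0)
  # identical occurrence sets: full overlap, p ~ 1
  occ <- land$occurrences[[1]]
  occ2 <- occurrence_set("other", occ$points, land$env[[1]])
  gid <- sympatry_test(occ, occ2, land$env, n_perm = 49, seed = 3)
  # identical occurrence sets give the maximal (self-)overlap; it equals 1
  # exactly only when every retained cell is >= 0.5 or an occurrence cell,
  # because the visited cells keep their suitability values
  expect_gte(gid$overlap, max(gid$null_values) - 1e-12)
  expect_gt(gid$overlap, 0.5)
  expect_gt(gid$p, 0.9)
  ne1 <- niche_equivalency_test(land$occurrences[[1]], land$occurrences[[2]],
                                land$env, n_perm = 49, seed = 5)
  ne2 <- niche_equivalency_test(land$occurrences[[2]], land$occurrences[[1]],
                                land$env, n_perm = 49, seed = 5)
  expect_identical(ne1$overlap, ne2$overlap)
  expect_identical(ne1$p, ne2$p)
  expect_equal(ne1$p, 1 / 50)  # disjoint niches at the permutation minimum
})
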