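# consensus K-means, silhouette and Davies-Bouldin

test_that("well-separated clouds give a sharp consensus and exact labels", {
  x <- two_clouds(n_per = 10, gap = 50, seed = 2)
  res <- ckm_run(x, k = 2, ckm_config(replicates = 200, seed = 1))
  within <- c(res$consensus[1:10, 1:10][upper.tri(diag(10))],
              res$consensus[11:20, 11:20][upper.tri(diag(10))])
  between <- res$consensus[1:10, 11:20]
  expect_true(all(within >= 0.99))
  expect_true(all(between <= 0.01))
  labels <- res$labels_per_k[["2"]]
  expect_equal(length(unique(labels[1:10])), 1L)
  expect_equal(length(unique(labels[11:20])), 1L)
  expect_false(labels[1] == labels[11])
})

test_that("the singleton limit k = n gives empty consensus off-diagonal", {
  x <- two_clouds(n_per = 3, gap = 10, seed = 3)  # 6 distinct points
  res <- ckm_run(x, k = 6, ckm_config(replicates = 150, seed = 2,
                                      observation_fraction = 1))
  off <- res$consensus[upper.tri(res$consensus)]
  expect_lt(mean(off, na.rm = TRUE), 0.05)
  expect_equal(length(unique(res$labels_per_k[["6"]])), 6L)
})

test_that("an unstructured cloud at k = 2 yields broadly unstable consensus", {
  x <- intdelim:::with_seed(7, matrix(stats::rnorm(60), 30, 2))
  rownames(x) <- paste0("p", 1:30)
  res <- ckm_run(x, k = 2, ckm_config(replicates = 300, seed = 5))
  off <- res$consensus[upper.tri(res$consensus)]
  q <- stats::quantile(off, c(0.05, 0.95))
  expect_gte(q[[2]] - q[[1]], 0.3)
})

test_that("consensus entries are valid ratios with the expected co-sampling", {
  x <- two_clouds(n_per = 8, gap = 5, seed = 9)
  reps <- 5000
  res <- ckm_run(x, k = 3, ckm_config(replicates = reps, seed = 11))
  expect_true(all(res$cooccurrence_counts <= res$cosample_counts))
  expect_true(all(res$consensus >= 0 & res$consensus <= 1, na.rm = TRUE))
  expect_true(all(diag(res$consensus) == 1))
  # P(pair co-sampled) for 13-of-16 draws: (13/16)(12/15)
  pexp <- (13 / 16) * (12 / 15)
  off <- res$cosample_counts[upper.tri(res$cosample_counts)]
  se <- sqrt(pexp * (1 - pexp) / reps)
  expect_lt(abs(mean(off) / reps - pexp), 3 * se)
})

test_that("silhouette follows its definition including the singleton rule", {
  # hand case: {0, 1} vs {10}; the singleton contributes 0
  val <- silhouette_index(matrix(c(0, 1, 10)), c(1, 1, 2))
  expect_equal(val, (0.9 + 8 / 9 + 0) / 3, tolerance = 1e-12)
  expect_gt(silhouette_index(matrix(c(0, 0.1, 10, 10.1)), c(1, 1, 2, 2)), 0.95)
  x <- intdelim:::with_seed(3, matrix(stats::rnorm(400), 200, 2))
  lab <- rep(1:2, 100)
  expect_lt(abs(silhouette_index(x, lab)), 0.1)
  expect_error(silhouette_index(x, rep(1, 200)), "two clusters")
  # independent cross-check against cluster::silhouette
  x2 <- intdelim:::with_seed(8, matrix(stats::rnorm(60), 30, 2))
  lab2 <- intdelim:::with_seed(9, sample(1:3, 30, TRUE))
  want <- mean(cluster::silhouette(lab2, stats::dist(x2))[, "sil_width"])
  expect_equal(silhouette_index(x2, lab2), want, tolerance = 1e-9)
})

test_that("Davies-Bouldin follows its definition and flags duplicate centroids", {
  expect_equal(davies_bouldin(matrix(c(0, 0.1, 10, 10.1)), c(1, 1, 2, 2)),
               0.01, tolerance = 1e-12)
  x <- rbind(c(0, 0), c(1, 0), c(0, 0), c(1, 0))
  expect_true(is.infinite(davies_bouldin(x, c(1, 1, 2, 2))))
  y <- intdelim:::with_seed(5, matrix(stats::rnorm(200), 100, 2))
  expect_gt(davies_bouldin(y, rep(1:2, 50)), 1)
})

test_that("a k-range scan reports both optima and degenerates to one run", {
  x <- two_clouds(n_per = 8, gap = 30, seed = 4)
  cfg <- ckm_config(k_range = 2:2, replicates = 100, seed = 6)
  scan <- ckm_scan(x, cfg)
  single_cfg <- cfg
  single_cfg$seed <- intdelim:::derive_seeds(6, 1)[1]
  single <- ckm_run(x, 2, single_cfg)
  expect_identical(scan$consensus, single$consensus)
  expect_identical(scan$labels_per_k[["2"]], single$labels_per_k[["2"]])
  expect_identical(scan$best_k_sil, 2L)
})

test_that("the distance-PCoA-scan chain recovers the simulated populations", {
  ok <- 0
  for (s in 1:10) {
    m <- simulate_snp_matrix(species_model(
      "(A:0.3,B:0.3,C:0.3,D:0.3,E:0.3);", 6, 2000, seed = s))
    ord <- pcoa(drop_undefined_samples(k2p_distance(m)))
    scan <- ckm_scan(ord, ckm_config(k_range = 2:8, replicates = 500,
                                     seed = s))
    if (scan$best_k_sil == 5 && scan$best_k_db == 5) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("identical seeds reproduce the full consensus result", {
  x <- two_clouds(n_per = 6, gap = 8, seed = 10)
  cfg <- ckm_config(k_range = 2:4, replicates = 80, seed = 13)
  expect_identical(ckm_scan(x, cfg), ckm_scan(x, cfg))
})
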