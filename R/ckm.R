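# Consensus K-means species discovery
#
# Repeated K-means on random subsamples of observations and features of the
# retained principal-coordinate matrix; pairwise co-clustering frequencies
# form a consensus matrix from which final labels (average-linkage
# agglomeration of 1 - consensus) and validity indices are derived.

#' Consensus K-means configuration
#'
#' @param k_range inclusive integer range of cluster numbers to scan.
#' @param replicates K-means replicates per k (default 5000).
#' @param observation_fraction,feature_fraction fraction of observations /
#'   features subsampled per replicate (default 0.8 each).
#' @param seed integer seed.
#' @param linkage linkage for the final agglomeration of `1 - consensus`.
#' @return an object of class `ckm_config`.
#' @export
ckm_config <- function(k_range = 2:10, replicates = 5000,
                       observation_fraction = 0.8, feature_fraction = 0.8,
                       seed = 1L, linkage = "average") {
  stopifnot_scalar_prob(observation_fraction, "observation_fraction")
  stopifnot_scalar_prob(feature_fraction, "feature_fraction")
  if (observation_fraction <= 0 || feature_fraction <= 0) {
    stop("subsampling fractions must be in (0,1]")
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1)) stop("k must be >= 1")
  structure(list(k_range = k_range, replicates = as.integer(replicates),
                 observation_fraction = observation_fraction,
                 feature_fraction = feature_fraction,
                 seed = seed, linkage = linkage),
            class = "ckm_config")
}

# k-means++ seeding: probabilistic spread of initial centers
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- rowSums((x - rep(centers[1, ], each = n))^2)
    for (c in 2:k) {
      if (all(d2 <= 0)) {
        idx <- sample.int(n, 1L)
      } else {
        idx <- sample.int(n, 1L, prob = d2)
      }
      centers[c, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums((x - rep(centers[c, ], each = n))^2))
    }
  }
  centers
}

.kmeans_once <- function(x, k, iter_max = 25L) {
  if (k >= nrow(x)) return(seq_len(nrow(x)))  # singleton limit
  centers <- .kmeanspp_centers(x, k)
  centers <- centers[!duplicated(round(centers, 12)), , drop = FALSE]
  fit <- tryCatch(
    suppressWarnings(stats::kmeans(x, centers = centers, iter.max = iter_max)),
    error = function(e) suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd")))
  fit$cluster
}

#' Consensus K-means for a single k
#'
#' Per replicate, `ceil(f_obs * n)` observations and `ceil(f_feat * p)`
#' features are subsampled without replacement and K-means (k-means++
#' initialization, one start) is run; co-clustering of co-sampled pairs is
#' accumulated. The consensus entry for a pair is its co-clustered count
#' divided by its co-sampled count. Final labels come from average-linkage
#' agglomerative clustering of `1 - consensus`, cut at k.
#'
#' @param coords a `pcoa_result` or a numeric matrix (samples x features);
#'   for a `pcoa_result` the retained axes are used.
#' @param k number of clusters.
#' @param cfg a [ckm_config].
#' @return an object of class `consensus_result` for this single k.
#' @export
ckm_run <- function(coords, k, cfg = ckm_config()) {
  x <- if (inherits(coords, "pcoa_result")) retained_coords(coords) else as.matrix(coords)
  n <- nrow(x); p <- ncol(x)
  n_obs <- ceiling(cfg$observation_fraction * n)
  n_feat <- max(1L, ceiling(cfg$feature_fraction * p))
  if (k > n_obs) stop("k exceeds the number of sampled observations")
  co_clust <- matrix(0, n, n)
  co_samp <- matrix(0, n, n)
  with_seed(cfg$seed, {
    for (r in seq_len(cfg$replicates)) {
      obs <- sample.int(n, n_obs)
      feat <- if (n_feat == p) seq_len(p) else sample.int(p, n_feat)
      cl <- .kmeans_once(x[obs, feat, drop = FALSE], k)
      co_samp[obs, obs] <- co_samp[obs, obs] + 1
      for (g in unique(cl)) {
        members <- obs[cl == g]
        co_clust[members, members] <- co_clust[members, members] + 1
      }
    }
  })
  if (any(co_samp == 0)) {
    warning("some pairs were never co-sampled; their consensus is NA")
  }
  consensus <- ifelse(co_samp > 0, co_clust / co_samp, NA_real_)
  diag(consensus) <- 1
  labels <- stats::cutree(
    stats::hclust(stats::as.dist(1 - consensus), method = cfg$linkage), k = k)
  names(labels) <- rownames(x)
  dimnames(consensus) <- list(rownames(x), rownames(x))
  res <- structure(list(consensus = consensus,
                        cooccurrence_counts = co_clust,
                        cosample_counts = co_samp,
                        labels_per_k = setNames(list(labels), k),
                        sil_per_k = NULL, db_per_k = NULL,
                        best_k_sil = NA_integer_, best_k_db = NA_integer_,
                        k_range = k, coords = x, cfg = cfg),
                   class = "consensus_result")
  res$sil_per_k <- setNames(.safe_sil(x, labels), k)
  res$db_per_k <- setNames(.safe_db(x, labels), k)
  res
}

.safe_sil <- function(x, labels) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  silhouette_index(x, labels)
}

.safe_db <- function(x, labels) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  davies_bouldin(x, labels)
}

#' Mean silhouette index
#'
#' Mean over samples of `(b - a) / max(a, b)` with Euclidean distances;
#' samples in singleton clusters contribute 0.
#'
#' @param coords numeric matrix (samples x features).
#' @param labels integer cluster labels, at least two non-empty clusters.
#' @return a real in `[-1, 1]`.
#' @export
silhouette_index <- function(coords, labels) {
  x <- as.matrix(coords)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L) stop("need at least two clusters")
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  sizes <- tabulate(labels)
  for (i in seq_len(n)) {
    g <- labels[i]
    if (sizes[g] == 1L) { s[i] <- 0; next }
    a <- sum(d[i, labels == g]) / (sizes[g] - 1L)
    b <- min(vapply(setdiff(unique(labels), g),
                    function(h) mean(d[i, labels == h]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Davies-Bouldin index
#'
#' Mean over clusters of `max_{j != i} (s_i + s_j) / d_ij`, with `s_i` the
#' mean distance of cluster members to their centroid and `d_ij` centroid
#' distances. Lower is better; duplicated centroids yield `Inf`.
#'
#' @inheritParams silhouette_index
#' @return a non-negative real (possibly `Inf`).
#' @export
davies_bouldin <- function(coords, labels) {
  x <- as.matrix(coords)
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("need at least two clusters")
  cent <- do.call(rbind, lapply(ks, function(g) colMeans(x[labels == g, , drop = FALSE])))
  s <- vapply(seq_along(ks), function(gi) {
    rows <- x[labels == ks[gi], , drop = FALSE]
    mean(sqrt(rowSums((rows - rep(cent[gi, ], each = nrow(rows)))^2)))
  }, 0)
  dc <- as.matrix(stats::dist(cent))
  r <- vapply(seq_along(ks), function(i) {
    ratios <- (s[i] + s[-i]) / dc[i, -i]
    ratios[dc[i, -i] == 0] <- Inf
    max(ratios)
  }, 0)
  mean(r)
}

#' Consensus K-means scan over a range of k
#'
#' Runs [ckm_run()] for every k in `cfg$k_range`, computes silhouette and
#' Davies-Bouldin indices on the feature coordinates with each k's
#' consensus-derived labels, and reports both optima (max SIL, min DB) plus
#' any local DB optima, without arbitrating between them.
#'
#' @inheritParams ckm_run
#' @param exclude sample ids to drop before the scan (e.g. flagged hybrids).
#' @return a `consensus_result` covering all k, whose `consensus` matrix is
#'   the one at `best_k_sil`.
#' @export
ckm_scan <- function(coords, cfg = ckm_config(), exclude = NULL) {
  x <- if (inherits(coords, "pcoa_result")) retained_coords(coords) else as.matrix(coords)
  if (!is.null(exclude)) x <- x[!(rownames(x) %in% exclude), , drop = FALSE]
  if (max(cfg$k_range) >= nrow(x)) stop("max k must be < number of samples")
  seeds <- derive_seeds(cfg$seed, length(cfg$k_range))
  runs <- vector("list", length(cfg$k_range))
  for (i in seq_along(cfg$k_range)) {
    cfg_k <- cfg
    cfg_k$seed <- seeds[i]
    runs[[i]] <- ckm_run(x, cfg$k_range[i], cfg_k)
  }
  sil <- vapply(runs, function(r) r$sil_per_k[[1]], 0)
  db <- vapply(runs, function(r) r$db_per_k[[1]], 0)
  names(sil) <- names(db) <- cfg$k_range
  best_sil <- cfg$k_range[which.max(sil)]
  best_db <- cfg$k_range[which.min(db)]
  # local DB minima: sign change of the discrete difference
  local_db <- integer(0)
  if (length(db) >= 3L) {
    dd <- diff(db)
    for (i in 2:(length(db) - 1L)) {
      if (dd[i - 1L] < 0 && dd[i] > 0) local_db <- c(local_db, cfg$k_range[i])
    }
  }
  best <- runs[[which(cfg$k_range == best_sil)]]
  structure(list(consensus = best$consensus,
                 cooccurrence_counts = best$cooccurrence_counts,
                 cosample_counts = best$cosample_counts,
                 labels_per_k = do.call(c, lapply(runs, `[[`, "labels_per_k")),
                 sil_per_k = sil, db_per_k = db,
                 best_k_sil = best_sil, best_k_db = best_db,
                 local_db_optima = local_db,
                 k_range = cfg$k_range, coords = x, cfg = cfg),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: n=%d, k in [%d, %d], best k (SIL)=%s, best k (DB)=%s\n",
              nrow(x$coords), min(x$k_range), max(x$k_range),
              x$best_k_sil, x$best_k_db))
  invisible(x)
}

#' Export per-k validity metrics and the consensus matrix as CSV
#' @param res a `consensus_result`.
#' @param metrics_path,consensus_path output CSV paths (NULL to skip).
#' @export
write_ckm_csv <- function(res, metrics_path = NULL, consensus_path = NULL) {
  if (!is.null(metrics_path)) {
    utils::write.csv(data.frame(k = res$k_range,
                                silhouette = as.numeric(res$sil_per_k),
                                davies_bouldin = as.numeric(res$db_per_k)),
                     metrics_path, row.names = FALSE)
  }
  if (!is.null(consensus_path)) {
    utils::write.csv(as.data.frame(res$consensus), consensus_path)
  }
  invisible(res)
}

#' Plot the consensus matrix as a heat map
#' @param res a `consensus_result`.
#' @param path output PNG path.
#' @param ... passed to [stats::heatmap()].
#' @export
plot_consensus <- function(res, path = NULL, ...) {
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 800)
    on.exit(grDevices::dev.off())
  }
  stats::heatmap(res$consensus, symm = TRUE, scale = "none",
                 col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(res)
}
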