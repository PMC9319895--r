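# Elliptic Fourier analysis of closed leaf outlines, leaf-dissection index,
# and the permutation / Welch tests on the derived shape features.

#' Resample a closed contour by arc length
#' @param xy polygon vertex matrix.
#' @param n number of output points.
#' @return n x 2 matrix of equally spaced points along the outline.
#' @export
resample_contour <- function(xy, n) {
  closed <- rbind(xy, xy[1, ])
  cum <- polyline_arclength(closed)
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  x <- stats::approx(cum, closed[, 1], xout = s)$y
  y <- stats::approx(cum, closed[, 2], xout = s)$y
  cbind(x, y)
}

#' Elliptic Fourier descriptors of a closed outline
#'
#' Kuhl-Giardina coefficients computed from the chain of contour
#' increments. Normalization (default) removes size, rotation, and
#' starting point by first-harmonic standardization: after it, the first
#' harmonic's semi-major coefficient is 1 and its rotation/starting-point
#' degrees of freedom are zeroed. The constant (DC) terms are not part of
#' the returned coefficients.
#'
#' @param contour closed polygon matrix (not repeated at the end).
#' @param harmonics number of harmonics (default 15).
#' @param normalize standardize the descriptors (default `TRUE`).
#' @return object of class `efa_descriptors`: `coefficients` is a
#'   `harmonics x 4` matrix with columns a, b, c, d.
#' @export
efa <- function(contour, harmonics = 15L, normalize = TRUE) {
  xy <- as.matrix(contour)
  if (nrow(xy) < 3L) stop("degenerate contour")
  if (polygon_area(xy) <= 0) stop("degenerate (zero-area) contour")
  if (nrow(xy) < 3L * harmonics) xy <- resample_contour(xy, 4L * harmonics)
  # consistent orientation so descriptors do not depend on vertex direction
  if (polygon_signed_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), ]
  dxy <- diff(rbind(xy, xy[1, ]))
  dt <- sqrt(rowSums(dxy^2))
  keep <- dt > 0
  dxy <- dxy[keep, , drop = FALSE]; dt <- dt[keep]
  t <- c(0, cumsum(dt))
  T_ <- t[length(t)]
  phi <- 2 * pi * t / T_
  coef <- matrix(0, harmonics, 4L,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(harmonics)) {
    cphi <- cos(n * phi); sphi <- sin(n * phi)
    dcos <- diff(cphi); dsin <- diff(sphi)
    k <- T_ / (2 * n^2 * pi^2)
    coef[n, "a"] <- k * sum(dxy[, 1] / dt * dcos)
    coef[n, "b"] <- k * sum(dxy[, 1] / dt * dsin)
    coef[n, "c"] <- k * sum(dxy[, 2] / dt * dcos)
    coef[n, "d"] <- k * sum(dxy[, 2] / dt * dsin)
  }
  if (normalize) coef <- .efa_normalize(coef)
  structure(list(coefficients = coef, harmonics = as.integer(harmonics),
                 normalized = normalize),
            class = "efa_descriptors")
}

.efa_rotate_harmonics <- function(coef, theta) {
  out <- coef
  for (n in seq_len(nrow(coef))) {
    rot <- matrix(c(cos(n * theta), sin(n * theta),
                    -sin(n * theta), cos(n * theta)), 2, 2)
    out[n, ] <- as.vector(t(matrix(coef[n, ], 2, 2, byrow = TRUE) %*% rot))
  }
  out
}

.efa_normalize <- function(coef) {
  a1 <- coef[1, "a"]; b1 <- coef[1, "b"]
  c1 <- coef[1, "c"]; d1 <- coef[1, "d"]
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                       a1^2 + c1^2 - b1^2 - d1^2)
  # pick the starting-point shift putting the semi-MAJOR axis first
  cand <- c(theta, theta + pi / 2)
  mags <- vapply(cand, function(th) {
    at <- a1 * cos(th) + b1 * sin(th)
    ct <- c1 * cos(th) + d1 * sin(th)
    at^2 + ct^2
  }, 0)
  theta <- cand[which.max(mags)]
  rot1 <- .efa_rotate_harmonics(coef, theta)
  psi <- atan2(rot1[1, "c"], rot1[1, "a"])
  scale <- sqrt(rot1[1, "a"]^2 + rot1[1, "c"]^2)
  Rpsi <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2, 2, byrow = TRUE)
  out <- rot1
  for (n in seq_len(nrow(coef))) {
    m <- matrix(rot1[n, ], 2, 2, byrow = TRUE)
    out[n, ] <- as.vector(t(Rpsi %*% m)) / scale
  }
  # resolve the residual theta vs theta+pi ambiguity (it negates the even
  # harmonics only): canonicalize the dominant even-harmonic entry positive
  ev <- seq(2, nrow(out), by = 2)
  if (length(ev)) {
    vals <- as.vector(out[ev, , drop = FALSE])
    lead <- which.max(abs(vals))
    if (length(vals) && abs(vals[lead]) > 1e-9 && vals[lead] < 0) {
      out[ev, ] <- -out[ev, , drop = FALSE]
    }
  }
  out
}

#' Reconstruct an outline from elliptic Fourier descriptors
#' @param desc an `efa_descriptors`.
#' @param n_points points to generate.
#' @param harmonics number of leading harmonics to use.
#' @return matrix of outline points (centered; DC terms are not stored).
#' @export
efa_reconstruct <- function(desc, n_points = 200L,
                            harmonics = desc$harmonics) {
  phi <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  x <- numeric(n_points); y <- numeric(n_points)
  for (n in seq_len(min(harmonics, desc$harmonics))) {
    x <- x + desc$coefficients[n, "a"] * cos(n * phi) +
      desc$coefficients[n, "b"] * sin(n * phi)
    y <- y + desc$coefficients[n, "c"] * cos(n * phi) +
      desc$coefficients[n, "d"] * sin(n * phi)
  }
  cbind(x, y)
}

#' PCA of elliptic Fourier descriptors
#'
#' Flattens the non-constant normalized coefficients of each leaf (the
#' first harmonic's fixed a, b, c entries are dropped) and runs a centered,
#' unscaled principal component analysis. The first two PC scores feed the
#' shape permutation test.
#'
#' @param descriptors list of `efa_descriptors` (same harmonic count).
#' @return list with `scores`, `variance_explained`, `rotation`, `center`.
#' @export
efa_pca <- function(descriptors) {
  if (length(descriptors) < 3L) stop("need at least three leaves")
  feats <- do.call(rbind, lapply(descriptors, function(d) {
    v <- as.vector(t(d$coefficients))
    v[-c(1, 2, 3)]  # a1 = 1, b1 = c1 = 0 after normalization
  }))
  keep_var <- apply(feats, 2, stats::var)
  if (all(keep_var < 1e-30)) {
    scores <- matrix(0, nrow(feats), 2,
                     dimnames = list(NULL, c("PC1", "PC2")))
    return(list(scores = scores, variance_explained = c(0, 0),
                rotation = NULL, center = colMeans(feats)))
  }
  fit <- stats::prcomp(feats, center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x, variance_explained = ve,
       rotation = fit$rotation, center = fit$center)
}

#' Leaf-dissection index
#'
#' `perimeter / (2 sqrt(pi * area))`: 1 for a circle, larger for dissected
#' outlines; invariant under rigid motion and uniform scaling.
#'
#' @param contour simple polygon matrix.
#' @return LDI value.
#' @export
ldi <- function(contour) {
  xy <- as.matrix(contour)
  a <- polygon_area(xy)
  if (a <= 0) stop("degenerate polygon")
  polygon_perimeter(xy) / (2 * sqrt(pi * a))
}

#' Permutation test for shape differences in PC space
#'
#' Observed statistic: mean Euclidean distance between all cross-group
#' pairs in the (first two) PC dimensions. The null distribution comes
#' from random taxon-label swaps; the one-sided p-value (large observed =
#' distinct) uses the add-one correction
#' `p = (1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param scores_a,scores_b score matrices (rows = leaves) for each group.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @param m Bonferroni multiplier supplied by the caller (default 1).
#' @param statistic `"mean-cross-pairs"` (default) or
#'   `"centroid-distance"`.
#' @return object of class `shape_test_result` with `statistic`, `p`,
#'   `p_corrected` (uncapped), `p_corrected_capped`, `n_permutations`.
#' @export
shape_permutation_test <- function(scores_a, scores_b, n_perm = 5000,
                                   seed = 1L, m = 1,
                                   statistic = c("mean-cross-pairs",
                                                 "centroid-distance")) {
  statistic <- match.arg(statistic)
  a <- as.matrix(scores_a); b <- as.matrix(scores_b)
  if (!nrow(a) || !nrow(b)) stop("both groups need at least one leaf")
  dims <- seq_len(min(2L, ncol(a)))
  a <- a[, dims, drop = FALSE]; b <- b[, dims, drop = FALSE]
  pool <- rbind(a, b)
  na <- nrow(a)
  stat_fun <- if (statistic == "mean-cross-pairs") {
    function(x, y) {
      d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
      mean(sqrt(pmax(d2, 0)))
    }
  } else {
    function(x, y) sqrt(sum((colMeans(x) - colMeans(y))^2))
  }
  observed <- stat_fun(a, b)
  # canonicalized pool + smaller-group-first draws make the null identical
  # whichever way the two groups are passed (exact symmetry)
  ord <- do.call(order, as.data.frame(pool))
  cpool <- pool[ord, , drop = FALSE]
  nmin <- min(na, nrow(b))
  null_vals <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- sample.int(nrow(cpool))
      stat_fun(cpool[perm[seq_len(nmin)], , drop = FALSE],
               cpool[perm[-seq_len(nmin)], , drop = FALSE])
    }, 0)
  })
  p <- (1 + sum(null_vals >= observed)) / (n_perm + 1)
  structure(list(statistic = observed, p = p, p_corrected = p * m,
                 p_corrected_capped = min(1, p * m),
                 n_permutations = n_perm, null_values = null_vals),
            class = "shape_test_result")
}

#' @export
print.shape_test_result <- function(x, ...) {
  cat(sprintf("shape permutation test: stat=%.4f p=%.4f corr. p=%.2f (capped %.2f)\n",
              x$statistic, x$p, x$p_corrected, x$p_corrected_capped))
  invisible(x)
}

#' Welch's t-test on leaf-dissection indices
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, two-sided.
#'
#' @param ldi_a,ldi_b numeric LDI vectors (both groups >= 2 values).
#' @param m Bonferroni multiplier (default 1).
#' @return list with `t`, `df`, `p`, `p_corrected`, `p_corrected_capped`,
#'   `zero_variance` flag.
#' @export
ldi_welch_test <- function(ldi_a, ldi_b, m = 1) {
  if (length(ldi_a) < 2L || length(ldi_b) < 2L) {
    stop("both groups need at least two values")
  }
  if (stats::var(ldi_a) == 0 && stats::var(ldi_b) == 0) {
    tied <- isTRUE(all.equal(mean(ldi_a), mean(ldi_b)))
    p <- if (tied) 1 else 0
    return(list(t = if (tied) 0 else Inf * sign(mean(ldi_a) - mean(ldi_b)),
                df = NA_real_, p = p, p_corrected = p * m,
                p_corrected_capped = min(1, p * m), zero_variance = TRUE))
  }
  fit <- stats::t.test(ldi_a, ldi_b, var.equal = FALSE)
  p <- fit$p.value
  list(t = unname(fit$statistic), df = unname(fit$parameter), p = p,
       p_corrected = p * m, p_corrected_capped = min(1, p * m),
       zero_variance = FALSE)
}
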