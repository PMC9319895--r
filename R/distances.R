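# Pairwise genetic distances on SNP matrices and principal coordinates

#' Construct a distance matrix object
#'
#' Square symmetric distance container with explicit flagging of undefined
#' cells (pairs for which the distance does not exist, e.g. no shared sites
#' or a non-positive logarithm argument). Undefined cells are `NA` in `$d`
#' and `TRUE` in `$undefined`; they are never silently zero.
#'
#' @param d square numeric matrix with zero diagonal.
#' @param labels row/column labels.
#' @return an object of class `dist_matrix`.
#' @export
dist_matrix <- function(d, labels = rownames(d)) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(labels)) labels <- paste0("s", seq_len(nrow(d)))
  dimnames(d) <- list(labels, labels)
  undef <- is.na(d)
  diag(undef) <- FALSE
  diag(d) <- 0
  if (max(abs(d - t(d)), na.rm = TRUE) > 1e-12) stop("matrix must be symmetric")
  structure(list(d = d, labels = labels, undefined = undef),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %d samples, %d undefined pair(s)\n",
              length(x$labels), sum(x$undefined) / 2))
  invisible(x)
}

#' Drop samples with undefined distances
#'
#' Greedily removes the samples involved in the most undefined pairs until
#' none remain, so the result is safe for [pcoa()].
#'
#' @param dm a [dist_matrix].
#' @return a [dist_matrix] without undefined cells.
#' @export
drop_undefined_samples <- function(dm) {
  d <- dm$d; undef <- dm$undefined
  while (any(undef)) {
    worst <- which.max(rowSums(undef))
    d <- d[-worst, -worst, drop = FALSE]
    undef <- undef[-worst, -worst, drop = FALSE]
  }
  dist_matrix(d)
}

# encode codes to haploid-style integers for K2P: ACGT -> 1..4, all
# ambiguity/missing -> NA (heterozygous calls are deleted pairwise)
.k2p_encode <- function(codes) {
  tab <- setNames(rep(NA_integer_, length(SNP_ALPHABET)), SNP_ALPHABET)
  tab[c("A", "C", "G", "T")] <- 1:4
  x <- tab[codes]
  dim(x) <- dim(codes)
  x
}

#' Kimura two-parameter distance on concatenated SNPs
#'
#' Pairwise deletion: sites where either call is missing or a heterozygous
#' ambiguity code are excluded for that pair. With transition fraction P
#' (A<->G, C<->T) and transversion fraction Q over retained sites,
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. Pairs with no retained
#' sites or a non-positive logarithm argument are flagged undefined.
#'
#' @param m a [snp_matrix].
#' @param split_alleles if `TRUE`, each diploid call is split into its two
#'   alleles (doubling the site count) instead of deleting heterozygotes.
#' @return a [dist_matrix].
#' @export
k2p_distance <- function(m, split_alleles = FALSE) {
  stopifnot(inherits(m, "snp_matrix"))
  n <- nrow(m$codes)
  if (n < 2) stop("need at least two samples")
  if (split_alleles) {
    al <- snp_alleles(m)
    x <- cbind(al$a1, al$a2)
  } else {
    x <- .k2p_encode(m$codes)
  }
  purine <- matrix(x %in% c(1L, 3L), nrow = n)  # A or G
  d <- matrix(NA_real_, n, n)
  diag(d) <- 0
  for (i in seq_len(n - 1L)) {
    xi <- x[i, ]; pi_ <- purine[i, ]
    for (j in (i + 1L):n) {
      xj <- x[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      nn <- sum(ok)
      if (nn == 0L) next
      diff <- ok & (xi != xj)
      ts <- diff & (pi_ == purine[j, ])  # same purine/pyrimidine class
      P <- sum(ts) / nn
      Q <- (sum(diff) - sum(ts)) / nn
      w1 <- 1 - 2 * P - Q
      w2 <- 1 - 2 * Q
      if (w1 > 0 && w2 > 0) {
        d[i, j] <- d[j, i] <- -0.5 * log(w1) - 0.25 * log(w2)
      }
    }
  }
  dist_matrix(d, m$sample_ids)
}

#' Nei's standard genetic distance at the SNP level
#'
#' Each individual's genotype at a SNP is an allele-frequency vector
#' (1 / 0.5 / 0 entries for diploids). Over sites shared by a pair,
#' `J_xy = mean(sum_a x_a y_a)`, `J_x`, `J_y` analogously;
#' `I = J_xy / sqrt(J_x J_y)` and `d = -log(I)`. Pairs with `I <= 0`
#' (possible only with disjoint alleles everywhere) are flagged undefined.
#'
#' @param m a [snp_matrix].
#' @return a [dist_matrix].
#' @export
nei_snp_distance <- function(m) {
  stopifnot(inherits(m, "snp_matrix"))
  n <- nrow(m$codes)
  if (n < 2) stop("need at least two samples")
  al <- snp_alleles(m)
  a1 <- al$a1; a2 <- al$a2
  het <- !is.na(a1) & a1 != a2
  d <- matrix(NA_real_, n, n)
  diag(d) <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(a1[i, ]) & !is.na(a1[j, ])
      if (!any(ok)) next
      # sum_a x_a y_a = (matches of the four allele pairings) / 4
      mm <- (a1[i, ok] == a1[j, ok]) + (a1[i, ok] == a2[j, ok]) +
            (a2[i, ok] == a1[j, ok]) + (a2[i, ok] == a2[j, ok])
      jxy <- mean(mm / 4)
      jx <- mean(ifelse(het[i, ok], 0.5, 1))
      jy <- mean(ifelse(het[j, ok], 0.5, 1))
      I <- jxy / sqrt(jx * jy)
      if (I > 0) d[i, j] <- d[j, i] <- -log(I)
    }
  }
  dist_matrix(d, m$sample_ids)
}

#' Principal coordinates analysis of a distance matrix
#'
#' Gower double-centering and eigen-decomposition via [stats::cmdscale()].
#' Negative eigenvalues are dropped from both the coordinates and the
#' variance denominator; axis `j` is scaled by `sqrt(eigenvalue_j)`.
#' `retained_axes` is the smallest prefix of axes whose cumulative fraction
#' of positive-eigenvalue variance reaches `variance_threshold`.
#'
#' @param dm a [dist_matrix] without undefined cells (see
#'   [drop_undefined_samples()]).
#' @param variance_threshold fraction of variance the retained axes must
#'   explain (default 0.8).
#' @return an object of class `pcoa_result` with `coords`, `eigenvalues`,
#'   `variance_explained` and `retained_axes`.
#' @export
pcoa <- function(dm, variance_threshold = 0.8) {
  stopifnot(inherits(dm, "dist_matrix"))
  if (any(dm$undefined)) {
    bad <- which(dm$undefined & upper.tri(dm$undefined), arr.ind = TRUE)
    stop("undefined distances present for pairs: ",
         paste(sprintf("%s-%s", dm$labels[bad[, 1]], dm$labels[bad[, 2]]),
               collapse = ", "))
  }
  n <- length(dm$labels)
  # cmdscale warns when fewer than k eigenvalues are positive; we drop the
  # non-positive ones ourselves
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dm$d), k = n - 1L,
                                          eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(eig, 0) * 1e-12)
  if (!length(pos)) {
    coords <- matrix(0, n, 1L, dimnames = list(dm$labels, "PCo1"))
    return(structure(list(coords = coords, eigenvalues = 0,
                          variance_explained = 1, retained_axes = 1L),
                     class = "pcoa_result"))
  }
  eig_pos <- eig[pos]
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  rownames(coords) <- dm$labels
  ve <- eig_pos / sum(eig_pos)
  retained <- which(cumsum(ve) >= variance_threshold - 1e-12)[1]
  structure(list(coords = coords, eigenvalues = eig_pos,
                 variance_explained = ve, retained_axes = as.integer(retained)),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d positive axes, %d retained (%.1f%%)\n",
              nrow(x$coords), length(x$eigenvalues), x$retained_axes,
              100 * sum(x$variance_explained[seq_len(x$retained_axes)])))
  invisible(x)
}

#' Retained principal coordinates
#' @param p a `pcoa_result`.
#' @return matrix of the retained axes.
#' @export
retained_coords <- function(p) {
  p$coords[, seq_len(p$retained_axes), drop = FALSE]
}

#' Write / read a square PHYLIP distance matrix
#' @param dm a [dist_matrix].
#' @param path file path.
#' @export
write_dist_phylip <- function(dm, path) {
  vals <- apply(dm$d, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(as.character(length(dm$labels)),
               sprintf("%s  %s", format(dm$labels), vals)), path)
  invisible(path)
}

#' @rdname write_dist_phylip
#' @export
read_dist_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  labels <- vapply(body, `[[`, "", 1L)
  d <- do.call(rbind, lapply(body, function(x) {
    vals <- x[-1]
    vals[vals == "NA"] <- NA
    as.numeric(vals)
  }))
  dist_matrix(d, labels)
}

#' Write / read a tidy (long-format) distance CSV
#' @param dm a [dist_matrix].
#' @param path file path.
#' @export
write_dist_csv <- function(dm, path) {
  idx <- which(upper.tri(dm$d), arr.ind = TRUE)
  df <- data.frame(a = dm$labels[idx[, 1]], b = dm$labels[idx[, 2]],
                   distance = dm$d[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_csv
#' @export
read_dist_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  labels <- unique(c(df$a, df$b))
  n <- length(labels)
  d <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(d) <- 0
  for (r in seq_len(nrow(df))) {
    d[df$a[r], df$b[r]] <- d[df$b[r], df$a[r]] <- df$distance[r]
  }
  dist_matrix(d, labels)
}
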