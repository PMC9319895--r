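# shared fixture builders (everything is generated in code)

# random genotype-code matrix over the full alphabet
random_codes <- function(n, s, seed, p_het = 0.2, p_missing = 0.1) {
  intdelim:::with_seed(seed, {
    hom <- c("A", "C", "G", "T")
    het <- c("R", "Y", "S", "W", "K", "M")
    pool <- c(sample(hom, 1000, TRUE),
              sample(het, round(1000 * p_het / (1 - p_het - p_missing)), TRUE))
    codes <- matrix(sample(pool, n * s, TRUE), n, s)
    codes[matrix(stats::runif(n * s) < p_missing, n, s)] <- "N"
    # guarantee a non-missing call per row
    codes[, 1] <- sample(hom, n, TRUE)
    rownames(codes) <- paste0("s", seq_len(n))
    codes
  })
}

random_snp_matrix <- function(n = 6, s = 50, seed = 1) {
  snp_matrix(random_codes(n, s, seed), taxon = rep("t", n))
}

dense_circle <- function(n = 2000, r = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th))
}

# brute-force K2P oracle: explicit pair/site loop, no vectorization
k2p_oracle <- function(codes) {
  n <- nrow(codes)
  d <- matrix(NA_real_, n, n); diag(d) <- 0
  base <- c("A", "C", "G", "T")
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    nn <- 0; ts <- 0; tv <- 0
    for (s in seq_len(ncol(codes))) {
      x <- codes[i, s]; y <- codes[j, s]
      if (!(x %in% base) || !(y %in% base)) next
      nn <- nn + 1
      if (x != y) {
        if (purine[[x]] == purine[[y]]) ts <- ts + 1 else tv <- tv + 1
      }
    }
    if (nn == 0) next
    P <- ts / nn; Q <- tv / nn
    if (1 - 2 * P - Q > 0 && 1 - 2 * Q > 0) {
      d[i, j] <- d[j, i] <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    }
  }
  d
}

# brute-force SNP-level Nei oracle via explicit allele-frequency vectors
nei_oracle <- function(codes) {
  two <- list(A = c("A", "A"), C = c("C", "C"), G = c("G", "G"),
              T = c("T", "T"), R = c("A", "G"), Y = c("C", "T"),
              S = c("C", "G"), W = c("A", "T"), K = c("G", "T"),
              M = c("A", "C"))
  n <- nrow(codes)
  d <- matrix(NA_real_, n, n); diag(d) <- 0
  freq_vec <- function(code) {
    if (!code %in% names(two)) return(NULL)
    v <- c(A = 0, C = 0, G = 0, T = 0)
    for (a in two[[code]]) v[a] <- v[a] + 0.5
    v
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    jxy <- jx <- jy <- c(); k <- 0
    for (s in seq_len(ncol(codes))) {
      x <- freq_vec(codes[i, s]); y <- freq_vec(codes[j, s])
      if (is.null(x) || is.null(y)) next
      k <- k + 1
      jxy[k] <- sum(x * y); jx[k] <- sum(x * x); jy[k] <- sum(y * y)
    }
    if (k == 0) next
    I <- mean(jxy) / sqrt(mean(jx) * mean(jy))
    if (I > 0) d[i, j] <- d[j, i] <- -log(I)
  }
  d
}

# pattern-count ABBA-BABA oracle for homozygous-coded matrices
dstat_count_oracle <- function(codes, p1, p2, p3, out) {
  abba <- 0; baba <- 0
  for (s in seq_len(ncol(codes))) {
    g <- codes[c(p1, p2, p3, out), s]
    if (any(!g %in% c("A", "C", "G", "T"))) next
    if (length(unique(g)) != 2) next
    anc <- g[4]
    pat <- unname(g == anc)
    if (identical(pat, c(TRUE, FALSE, FALSE, TRUE))) abba <- abba + 1
    if (identical(pat, c(FALSE, TRUE, FALSE, TRUE))) baba <- baba + 1
  }
  if (abba + baba == 0) return(NA_real_)
  (abba - baba) / (abba + baba)
}

# flood-fill oracle: dilate the seed set to a fixpoint
flood_oracle <- function(values, seeds, threshold, connectivity) {
  nr <- nrow(values); nc <- ncol(values)
  pass <- !is.na(values) & values >= threshold
  vis <- matrix(FALSE, nr, nc)
  vis[seeds] <- TRUE
  repeat {
    new <- vis
    for (r in 1:nr) for (c in 1:nc) {
      if (vis[r, c] || !pass[r, c]) next
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        if (connectivity == 4 && abs(dr) + abs(dc) == 2) next
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && vis[rr, cc]) {
          new[r, c] <- TRUE
        }
      }
    }
    if (identical(new, vis)) break
    vis <- new
  }
  out <- ifelse(vis & pass, values, 0)
  out[seeds] <- 1
  out
}

# two-cluster separated point clouds
two_clouds <- function(n_per = 10, gap = 50, seed = 1) {
  intdelim:::with_seed(seed, {
    x <- rbind(cbind(stats::rnorm(n_per), stats::rnorm(n_per)),
               cbind(stats::rnorm(n_per) + gap, stats::rnorm(n_per)))
    rownames(x) <- paste0("p", seq_len(2 * n_per))
    x
  })
}

expect_equal_tol <- function(a, b, tol) expect_lt(max(abs(a - b)), tol)
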