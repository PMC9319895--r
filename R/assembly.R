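# Replicate-based scoring of RADseq assembly parameters and knee-point
# detection on model-fit-vs-complexity curves.

#' Replicate error rates for an assembly
#'
#' For every replicate pair, the locus error is the fraction of loci
#' recovered in exactly one of the two replicates among loci recovered in at
#' least one; the SNP error is the fraction of mismatching genotype calls
#' among calls compared at loci shared by both. `EL` and `ES` are the means
#' over pairs.
#'
#' @param loci_a,loci_b named lists mapping locus id to the genotype-call
#'   vector of replicate A / replicate B of each sample in `pairs`. For a
#'   single replicate pair these are plain named lists; for several pairs,
#'   lists of such lists (one per pair).
#' @param pairs number of replicate pairs described by `loci_a` / `loci_b`
#'   (default: inferred; 1 when the inputs are plain locus maps).
#' @return list with `EL`, `ES`, and the per-pair values.
#' @export
replicate_error_rates <- function(loci_a, loci_b, pairs = NULL) {
  plain <- function(x) length(x) && !is.list(x[[1]])
  if (plain(loci_a)) { loci_a <- list(loci_a); loci_b <- list(loci_b) }
  if (is.null(pairs)) pairs <- length(loci_a)
  if (pairs < 1) stop("need at least one replicate pair")
  el <- es <- rep(NA_real_, pairs)
  for (i in seq_len(pairs)) {
    a <- loci_a[[i]]; b <- loci_b[[i]]
    union_loci <- union(names(a), names(b))
    shared <- intersect(names(a), names(b))
    if (!length(union_loci)) stop("replicate pair with no loci at all")
    el[i] <- (length(union_loci) - length(shared)) / length(union_loci)
    if (!length(shared)) {
      warning(sprintf("pair %d shares no loci; SNP error undefined, excluded", i))
      next
    }
    ncomp <- 0L; nmis <- 0L
    for (l in shared) {
      ga <- a[[l]]; gb <- b[[l]]
      nn <- min(length(ga), length(gb))
      ncomp <- ncomp + nn
      nmis <- nmis + sum(ga[seq_len(nn)] != gb[seq_len(nn)])
    }
    es[i] <- nmis / ncomp
  }
  list(EL = mean(el), ES = mean(es, na.rm = TRUE),
       EL_per_pair = el, ES_per_pair = es)
}

#' Assembly score from error rates and missing data
#'
#' `(1 - EL) * (1 - ES) * exp(-(MS - mu)^2 / (2 sigma^2))`: the product of
#' the replicate-based accuracy terms with an unnormalized Gaussian kernel
#' expressing a rough target for the allowed percentage of missing data.
#' Higher is better; the best assembly is the maximizer. Note that the
#' kernel is centered at `mu = 50`%: assemblies with *less* missing data
#' than the target score lower, all else equal — this is deliberate, the
#' target expresses a trade-off against overly strict locus filtering.
#'
#' @param EL,ES mean locus / SNP error rates in `[0, 1]`.
#' @param MS percent missing data in `[0, 100]`.
#' @param mu,sigma center and width of the missing-data kernel.
#' @return score in `[0, 1]`.
#' @export
assembly_score <- function(EL, ES, MS, mu = 50, sigma = 50) {
  if (any(EL < 0 | EL > 1) || any(ES < 0 | ES > 1)) {
    stop("EL and ES must lie in [0, 1]")
  }
  if (any(MS < 0 | MS > 100)) stop("MS must lie in [0, 100]")
  (1 - EL) * (1 - ES) * exp(-(MS - mu)^2 / (2 * sigma^2))
}

#' Select the best assembly from a metrics table
#'
#' @param rows data frame with columns `ct`, `msl`, `EL`, `ES`, `MS` (one
#'   row per finished assembly), e.g. read from CSV.
#' @param mu,sigma missing-data kernel parameters for [assembly_score()].
#' @return list with `best` (the winning row, with score) and `table` (all
#'   rows ranked by decreasing score). Ties are broken by lower EL, then
#'   lower ES, then MS nearest `mu`; tie-breaking is reported in the
#'   `tie_broken` attribute of `best`.
#' @export
grid_select <- function(rows, mu = 50, sigma = 50) {
  if (!nrow(rows)) stop("need at least one assembly row")
  rows$score <- assembly_score(rows$EL, rows$ES, rows$MS, mu, sigma)
  ord <- order(-rows$score, rows$EL, rows$ES, abs(rows$MS - mu))
  ranked <- rows[ord, , drop = FALSE]
  tie <- sum(rows$score == max(rows$score)) > 1L
  best <- ranked[1, , drop = FALSE]
  attr(best, "tie_broken") <- tie
  list(best = best, table = ranked)
}

#' Knee-point detection (Kneedle)
#'
#' Min-max normalizes x and y, orients the curve to concave-increasing,
#' forms the difference curve `y_d = y_n - x_n`, and accepts the first
#' local maximum of `y_d` whose subsequent values drop below the threshold
#' `T = y_d(max) - S * mean(diff(x_n))` before the next local maximum.
#'
#' @param x strictly increasing numeric vector (model complexity).
#' @param y numeric vector (model fit, e.g. marginal likelihood).
#' @param sensitivity the Kneedle S parameter (default 1).
#' @param shape curve shape; curves are oriented to concave-increasing
#'   internally, and convex-increasing curves yield no knee under the
#'   default shape.
#' @return list with `knee_x`, `knee_index` (index into `x`), or both `NA`
#'   when no knee exists.
#' @export
kneedle <- function(x, y, sensitivity = 1.0,
                    shape = c("concave-increasing", "concave-decreasing",
                              "convex-increasing", "convex-decreasing")) {
  shape <- match.arg(shape)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least three points for knee detection")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  xn <- (x - min(x)) / (max(x) - min(x))
  ry <- max(y) - min(y)
  if (ry == 0) return(list(knee_x = NA_real_, knee_index = NA_integer_))
  yn <- (y - min(y)) / ry
  # orient to concave-increasing
  yn <- switch(shape,
               "concave-increasing" = yn,
               "concave-decreasing" = rev(yn),
               "convex-increasing" = 1 - rev(yn),
               "convex-decreasing" = 1 - yn)
  yd <- yn - xn
  n <- length(yd)
  is_lmx <- vapply(seq_len(n), function(i) {
    i > 1L && i < n && yd[i] > yd[i - 1L] && yd[i] >= yd[i + 1L]
  }, TRUE)
  lmx <- which(is_lmx)
  if (!length(lmx)) return(list(knee_x = NA_real_, knee_index = NA_integer_))
  thresh_drop <- sensitivity * mean(diff(xn))
  for (i in lmx) {
    threshold <- yd[i] - thresh_drop
    nxt <- if (any(lmx > i)) min(lmx[lmx > i]) else n + 1L
    seg <- yd[seq(i + 1L, min(nxt - 1L, n))]
    if (length(seg) && any(seg < threshold)) {
      idx <- switch(shape,
                    "concave-increasing" = i,
                    "convex-decreasing" = i,
                    n + 1L - i)  # reversed orientations map back
      return(list(knee_x = x[idx], knee_index = idx))
    }
  }
  list(knee_x = NA_real_, knee_index = NA_integer_)
}

#' Read an assembly metrics table / a curve from CSV
#' @param path CSV with columns ct, msl, EL, ES, MS (metrics) or x, y (curve).
#' @export
read_assembly_metrics <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_assembly_metrics
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(x = df[[1]], y = df[[2]])
}
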