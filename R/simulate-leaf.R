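# Parametric pinnately lobed leaf silhouettes with known straight ground
# truth. The bent variant maps the straight leaf through a constant-curvature
# arc transform of the midvein axis (arc length preserved); constant
# curvature is an idealization of real leaf bending chosen because it has an
# analytic inverse, which supplies exact ground truth for the straightening
# stage.

#' Specify a synthetic leaf
#'
#' @param length leaf length in pixel units.
#' @param n_lobes number of lobes per side (0 = entire margin).
#' @param dissection non-negative real controlling lobe depth; 0 gives a
#'   smooth ellipse-like outline. Lobe depth saturates as
#'   `dissection / (1 + dissection)`.
#' @param bend_curvature signed curvature of the midvein arc (1/pixels).
#' @param contour_points number of contour vertices (>= 64).
#' @param aspect maximum half-width as a fraction of length.
#' @param midvein_points vertices on the midvein polyline.
#' @param seed integer seed (controls small shape jitter between leaves).
#' @return an object of class `leaf_model`.
#' @export
leaf_model <- function(length = 300, n_lobes = 4, dissection = 1,
                       bend_curvature = 0, contour_points = 200,
                       aspect = 0.22, midvein_points = 15, seed = 1L) {
  if (length <= 0) stop("length must be positive")
  if (n_lobes < 0) stop("n_lobes must be non-negative")
  if (dissection < 0) stop("dissection must be >= 0")
  if (contour_points < 64L) stop("contour_points must be >= 64")
  structure(list(length = length, n_lobes = as.integer(n_lobes),
                 dissection = dissection, bend_curvature = bend_curvature,
                 contour_points = as.integer(contour_points),
                 aspect = aspect, midvein_points = as.integer(midvein_points),
                 seed = seed),
            class = "leaf_model")
}

# half-width profile on u in [0,1]; vectorized; broader near the base
.leaf_halfwidth <- function(u, model, jitter) {
  base <- u^0.6 * (1 - u)
  base <- base / max((0.6 / 1.6)^0.6 * (1 / 1.6))  # peak normalized to 1
  lam <- 1
  if (model$n_lobes > 0 && model$dissection > 0) {
    depth <- model$dissection / (1 + model$dissection) * (1 + jitter[1])
    depth <- min(max(depth, 0), 0.97)
    lam <- 1 - depth * (0.5 - 0.5 * cos(2 * pi * model$n_lobes * u + jitter[4]))
  }
  wiggle <- 1 + 0.04 * jitter[2] * sin(2 * pi * u) + 0.04 * jitter[3] * cos(pi * u)
  w <- model$aspect * model$length * base * lam * wiggle
  pmax(w, 0)
}

# arc map of a point (s, t): s along the axis, t the signed normal offset
.arc_map <- function(s, t, kappa) {
  if (kappa == 0) return(cbind(s, t))
  R <- 1 / kappa
  cbind((R - t) * sin(kappa * s), R - (R - t) * cos(kappa * s))
}

#' Simulate a bent leaf silhouette with straight ground truth
#'
#' The straight leaf has its midvein on the segment from (0,0) to
#' (length, 0). The bent variant maps contour points through the
#' constant-curvature arc transform; midvein vertices are placed on the arc
#' so that consecutive chord distances equal the straight spacing exactly,
#' making the cumulative midvein polyline length identical in both leaves.
#'
#' @param model a [leaf_model].
#' @param specimen_id,taxon labels for the returned annotations.
#' @return list with `bent` and `straight_truth`, both [leaf_annotation]s
#'   with equal vertex counts.
#' @export
simulate_leaf <- function(model, specimen_id = "leaf1", taxon = "taxonA") {
  stopifnot(inherits(model, "leaf_model"))
  jitter <- with_seed(model$seed, stats::rnorm(4, 0, c(0.05, 1, 1, 0.3)))
  L <- model$length
  n_side <- ceiling(model$contour_points / 2)
  u <- seq(0, 1, length.out = n_side + 1L)
  w <- .leaf_halfwidth(u, model, jitter)
  # closed polygon: base, upper side, tip, lower side (reversed)
  s_up <- u[-c(1L, n_side + 1L)] * L
  w_up <- w[-c(1L, n_side + 1L)]
  s_all <- c(0, s_up, L, rev(s_up))
  t_all <- c(0, w_up, 0, -rev(w_up))
  kappa <- model$bend_curvature
  if (kappa != 0) {
    wmax <- max(w)
    if (abs(kappa) * wmax >= 0.95) {
      stop(sprintf(paste0("bend curvature %.4g too large: the contour would ",
                          "fold (|kappa| * max halfwidth = %.2f >= 0.95)"),
                   kappa, abs(kappa) * wmax))
    }
    if (abs(kappa) * L >= 2 * pi) {
      stop("bend curvature wraps the leaf onto itself")
    }
  }
  straight_contour <- cbind(s_all, t_all)
  sm <- seq(0, L, length.out = model$midvein_points)
  straight_midvein <- cbind(sm, 0)
  if (kappa == 0) {
    bent_contour <- straight_contour
    bent_midvein <- straight_midvein
  } else {
    bent_contour <- .arc_map(s_all, t_all, kappa)
    # chord-preserving placement of midvein vertices on the arc
    R <- 1 / kappa
    dsm <- diff(sm)
    dth <- 2 * asin(pmin(1, abs(kappa) * dsm / 2)) * sign(kappa)
    th <- c(0, cumsum(dth))
    bent_midvein <- cbind(R * sin(th), R * (1 - cos(th)))
  }
  straight <- leaf_annotation(straight_contour, straight_midvein,
                              specimen_id, taxon, check = FALSE)
  bent <- leaf_annotation(bent_contour, bent_midvein, specimen_id, taxon,
                          check = FALSE)
  if (polygon_self_intersects(bent$contour)) {
    stop("bend curvature too large: bent contour self-intersects")
  }
  list(bent = bent, straight_truth = straight)
}
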