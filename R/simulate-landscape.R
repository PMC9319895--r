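# Synthetic landscapes: smooth environmental layer stacks with Gaussian
# niche responses and suitability-proportional occurrence sampling under
# sympatric / parapatric / allopatric scenarios.
#
# The first two layers are deterministic west-east / south-north gradients
# (plus smooth noise), so environmental similarity correlates with
# geographic proximity; the remaining layers are sums of random Gaussian
# bumps. Scenario anchors pick niche centers as the environment at chosen
# anchor cells: identical anchors (sympatric), adjacent anchors
# (parapatric), or opposite-corner anchors (allopatric).

#' Specify a synthetic landscape
#'
#' @param n_rows,n_cols grid dimensions.
#' @param n_layers number of environmental layers (>= 1).
#' @param smoothness Gaussian-bump width in cells.
#' @param n_occurrences occurrence records per taxon; scalar or vector.
#' @param scenario `"sympatric"`, `"parapatric"` or `"allopatric"`.
#' @param n_taxa number of taxa (default 2).
#' @param niche_widths per-taxon niche widths in (z-scored) layer space;
#'   scalar, or list of per-layer vectors.
#' @param niche_centers optional list of per-taxon niche centers in layer
#'   space; default derived from the scenario anchors.
#' @param n_bumps random bumps per stochastic layer.
#' @param seed integer seed.
#' @return an object of class `landscape_model`.
#' @export
landscape_model <- function(n_rows = 40, n_cols = 40, n_layers = 3,
                            smoothness = 8, n_occurrences = 60,
                            scenario = c("sympatric", "parapatric",
                                         "allopatric"),
                            n_taxa = 2L, niche_widths = 0.6,
                            niche_centers = NULL, n_bumps = 12, seed = 1L) {
  scenario <- match.arg(scenario)
  if (n_layers < 1) stop("need at least one layer")
  if (smoothness <= 0) stop("smoothness must be positive")
  if (length(n_occurrences) == 1L) {
    n_occurrences <- rep(n_occurrences, n_taxa)
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_layers = as.integer(n_layers), smoothness = smoothness,
                 n_occurrences = as.integer(n_occurrences),
                 scenario = scenario, n_taxa = as.integer(n_taxa),
                 niche_widths = niche_widths, niche_centers = niche_centers,
                 n_bumps = as.integer(n_bumps), seed = seed),
            class = "landscape_model")
}

#' Simulate a landscape with known niche and sympatry structure
#'
#' @param model a [landscape_model].
#' @return list with `env` (list of [env_raster] layers), `true_suitability`
#'   (per-taxon [env_raster]s, max 1), `occurrences` (per-taxon
#'   [occurrence_set]s) and `niche_centers`.
#' @export
simulate_landscape <- function(model) {
  stopifnot(inherits(model, "landscape_model"))
  nr <- model$n_rows; nc <- model$n_cols
  rowv <- matrix(seq_len(nr), nr, nc)
  colv <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  with_seed(model$seed, {
    layers <- vector("list", model$n_layers)
    for (l in seq_len(model$n_layers)) {
      base <- if (l == 1L) {
        (colv - 1) / max(nc - 1, 1)        # west-east gradient
      } else if (l == 2L) {
        (rowv - 1) / max(nr - 1, 1)        # north-south gradient
      } else {
        matrix(0, nr, nc)
      }
      bump_w <- if (l <= 2L) 0.25 else 1
      bumps <- matrix(0, nr, nc)
      for (b in seq_len(model$n_bumps)) {
        cr <- stats::runif(1, 1, nr); cl <- stats::runif(1, 1, nc)
        amp <- stats::rnorm(1)
        bumps <- bumps + amp *
          exp(-((rowv - cr)^2 + (colv - cl)^2) / (2 * model$smoothness^2))
      }
      v <- base * 3 + bump_w * bumps
      layers[[l]] <- env_raster(v, xll = 0, yll = 0, cellsize = 0.1)
    }
    # z-scored layer values per cell for niche responses
    zvals <- vapply(layers, function(r) as.vector(scale(as.vector(r$values))),
                    numeric(nr * nc))
    anchors <- switch(model$scenario,
      sympatric = rep(list(c(round(nr / 2), round(nc / 2))), model$n_taxa),
      parapatric = lapply(seq_len(model$n_taxa), function(i) {
        c(round(nr / 2), round(nc * (0.35 + 0.3 * (i - 1) / max(model$n_taxa - 1, 1))))
      }),
      allopatric = lapply(seq_len(model$n_taxa), function(i) {
        if (i %% 2 == 1L) c(round(0.12 * nr), round(0.12 * nc))
        else c(round(0.88 * nr), round(0.88 * nc))
      }))
    centers <- model$niche_centers
    if (is.null(centers)) {
      centers <- lapply(anchors, function(a) {
        zvals[(a[2] - 1L) * nr + a[1], ]
      })
    }
    widths <- model$niche_widths
    if (!is.list(widths)) {
      widths <- rep(list(rep(widths, model$n_layers)), model$n_taxa)
    }
    suits <- vector("list", model$n_taxa)
    occs <- vector("list", model$n_taxa)
    for (tx in seq_len(model$n_taxa)) {
      d2 <- sweep(zvals, 2, centers[[tx]])^2
      d2 <- sweep(d2, 2, 2 * widths[[tx]]^2, "/")
      s <- exp(-rowSums(d2))
      s <- s / max(s)
      sr <- env_raster(matrix(s, nr, nc), xll = 0, yll = 0, cellsize = 0.1)
      suits[[tx]] <- sr
      pos <- which(s > 0)
      n_occ <- model$n_occurrences[tx]
      if (n_occ > length(pos)) {
        stop("n_occurrences exceeds cells with positive suitability")
      }
      pick <- sample(pos, n_occ, prob = s[pos])
      rows <- ((pick - 1L) %% nr) + 1L
      cols <- ((pick - 1L) %/% nr) + 1L
      cc <- cell_centers(sr)
      pts <- cbind(lon = cc$lon[cols], lat = cc$lat[rows])
      occs[[tx]] <- occurrence_set(paste0("taxon", LETTERS[tx]), pts, sr)
    }
    names(suits) <- names(occs) <- paste0("taxon", LETTERS[seq_len(model$n_taxa)])
    list(env = layers, true_suitability = suits, occurrences = occs,
         niche_centers = centers)
  })
}
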