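# internal helpers shared across modules

#' Evaluate an expression under a private RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so every generator in the package is a pure function
#' of its arguments (including the seed).
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# derive a stream of child seeds from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_prob <- function(x, name, closed_right = TRUE) {
  hi_ok <- if (closed_right) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || !hi_ok) {
    stop(sprintf("`%s` must be a probability in [0,%s)", name,
                 if (closed_right) "1]" else "1"))
  }
  invisible(x)
}

#' Shoelace area of a simple polygon
#' @param xy two-column matrix of vertices (closed implicitly).
#' @return unsigned area.
#' @keywords internal
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_perimeter <- function(xy, closed = TRUE) {
  n <- nrow(xy)
  j <- if (closed) c(2:n, 1L) else 2:n
  i <- if (closed) 1:n else 1:(n - 1L)
  sum(sqrt(rowSums((xy[j, , drop = FALSE] - xy[i, , drop = FALSE])^2)))
}

# ray-casting point-in-polygon, vectorized over query points
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  x <- pts[, 1]; y <- pts[, 2]
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# TRUE when the closed polygon has at least one pair of properly crossing edges
polygon_self_intersects <- function(xy) {
  n <- nrow(xy)
  a1 <- xy
  a2 <- xy[c(2:n, 1L), , drop = FALSE]
  seg_cross <- function(p1, p2, q1, q2) {
    d1 <- (q2[1] - q1[1]) * (p1[2] - q1[2]) - (q2[2] - q1[2]) * (p1[1] - q1[1])
    d2 <- (q2[1] - q1[1]) * (p2[2] - q1[2]) - (q2[2] - q1[2]) * (p2[1] - q1[1])
    d3 <- (p2[1] - p1[1]) * (q1[2] - p1[2]) - (p2[2] - p1[2]) * (q1[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (q2[2] - p1[2]) - (p2[2] - p1[2]) * (q2[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (k in (i + 2L):n) {
      if (i == 1L && k == n) next  # adjacent through the wrap-around
      if (seg_cross(a1[i, ], a2[i, ], a1[k, ], a2[k, ])) return(TRUE)
    }
  }
  FALSE
}
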