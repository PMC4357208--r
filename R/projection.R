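## 2-D projection of the feasible flux polytope (the published flux-pair
## feasibility plots): directional-sweep support function over the LP.

#' Project the feasible flux set onto a pair of fluxes
#'
#' Computes the convex polygon of attainable `(x, y)` values for a flux pair
#' by a directional LP sweep: for `n_dir` directions on the unit circle the
#' support point is found by maximizing the directional objective, and
#' duplicate vertices are merged. The sweep is exact for a polytope once the
#' directions bracket every facet normal of the projection; doubling
#' `n_dir` can only grow (never shrink) the recovered polygon.
#'
#' @inheritParams solve_flux_lp
#' @param pair Character vector of two flux ids.
#' @param n_dir Number of sweep directions (default 128).
#' @param tol Vertex-merging tolerance.
#' @return Object of class `"feasible_region_2d"`: `pair`, `vertices`
#'   (counter-clockwise matrix, possibly a segment or point when the pair is
#'   linearly linked — flagged in `degenerate`), and `area`.
#' @export
project_pair <- function(system, load, bounds, pair, n_dir = 128, tol = 1e-7) {
  stopifnot(length(pair) == 2)
  miss <- setdiff(pair, system$flux_order)
  if (length(miss)) stop("unknown flux id: ", paste(miss, collapse = ", "), call. = FALSE)
  b <- load_as_b(load, system)
  bl <- lp_blocks(system, b, bounds)
  pts <- matrix(numeric(0), 0, 2)
  for (k in seq_len(n_dir)) {
    th <- 2 * pi * (k - 1) / n_dir
    w <- stats::setNames(numeric(length(bl$fl)), bl$fl)
    w[pair[1]] <- cos(th); w[pair[2]] <- sin(th)
    a <- bl$ext(w)
    s <- lp_dense(a, bl$A1, bl$b1, bl$A2, bl$b2, bl$A3, bl$b3, maxi = TRUE)
    if (identical(s$status, "unbounded"))
      stop("unbounded projection in direction (", signif(cos(th), 3), ", ",
           signif(sin(th), 3), ")", call. = FALSE)
    if (!identical(s$status, "optimal"))
      stop("projection LP ", s$status, call. = FALSE)
    v <- unsplit(s$x, bl)
    pts <- rbind(pts, c(v[pair[1]], v[pair[2]]))
  }
  ## merge duplicates, order counter-clockwise via convex hull
  keep <- !duplicated(round(pts / tol))
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) > 2) {
    h <- grDevices::chull(pts)           # clockwise order
    pts <- pts[rev(h), , drop = FALSE]   # counter-clockwise
  }
  n <- nrow(pts)
  area <- if (n >= 3) {
    i2 <- c(2:n, 1)
    0.5 * abs(sum(pts[, 1] * pts[i2, 2] - pts[i2, 1] * pts[, 2]))
  } else 0
  structure(list(pair = pair, vertices = pts, area = area,
                 degenerate = n < 3 || area < tol),
            class = "feasible_region_2d")
}

#' @export
print.feasible_region_2d <- function(x, ...) {
  cat("feasible_region_2d (", x$pair[1], ",", x$pair[2], "): ",
      nrow(x$vertices), " vertices, area ", signif(x$area, 4),
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Point-in-region test
#'
#' TRUE when the point lies inside or on the boundary of the projected
#' region, inflated by `tol`.
#'
#' @param region A `"feasible_region_2d"`.
#' @param point Numeric `c(x, y)`.
#' @param tol Inflation tolerance.
#' @return Logical.
#' @export
contains_point <- function(region, point, tol = 1e-6) {
  V <- region$vertices
  n <- nrow(V)
  if (n == 0) return(FALSE)
  if (n == 1) return(all(abs(point - V[1, ]) <= tol))
  if (n == 2) {   # segment
    d <- V[2, ] - V[1, ]; l2 <- sum(d^2)
    t <- if (l2 == 0) 0 else max(0, min(1, sum((point - V[1, ]) * d) / l2))
    return(sqrt(sum((point - V[1, ] - t * d)^2)) <= tol)
  }
  i2 <- c(2:n, 1)
  for (i in seq_len(n)) {   # CCW polygon: inside iff every cross product >= -tol
    e <- V[i2[i], ] - V[i, ]
    cr <- e[1] * (point[2] - V[i, 2]) - e[2] * (point[1] - V[i, 1])
    if (cr < -tol * max(1, sqrt(sum(e^2)))) return(FALSE)
  }
  TRUE
}

#' Sign of the trend between two fluxes across scenario extremes
#'
#' Least-squares slope sign of `y` on `x` over the distinct scenario-cluster
#' points of a `"scenario_table"` (or any two-column point matrix): the
#' published flux-pair plots show, e.g., an inverse relationship between the
#' pyruvate-kinase and malic-enzyme fluxes.
#'
#' @param table A `"scenario_table"`, or a numeric matrix/data frame of
#'   points with two columns.
#' @param pair Flux ids (ignored when `table` is already a point matrix).
#' @param tol Degeneracy tolerance on the x-spread.
#' @return `+1`, `-1`, or `NA` (flagged degenerate: no x-spread).
#' @export
pairwise_trend <- function(table, pair = NULL, tol = 1e-9) {
  if (inherits(table, "scenario_table")) {
    stopifnot(length(pair) == 2)
    i <- match(seq_len(table$n_clusters), table$records$cluster)
    pts <- table$vectors[i, pair, drop = FALSE]
  } else pts <- as.matrix(table)
  if (nrow(pts) < 2) return(NA_real_)
  x <- pts[, 1]; y <- pts[, 2]
  sxx <- sum((x - mean(x))^2)
  if (sxx <= tol) return(NA_real_)
  sign(sum((x - mean(x)) * (y - mean(y))) / sxx)
}

#' Scenario points of a flux pair
#'
#' Helper extracting the distinct cluster vertices of a scenario table as a
#' labelled two-column matrix, for overlaying on [project_pair()] regions and
#' for writing the canonical vertices/points CSV.
#'
#' @param table A `"scenario_table"`.
#' @param pair Two flux ids.
#' @return Matrix with rownames `scenario <k>`.
#' @export
scenario_points <- function(table, pair) {
  i <- match(seq_len(table$n_clusters), table$records$cluster)
  pts <- table$vectors[i, pair, drop = FALSE]
  rownames(pts) <- paste("scenario", seq_len(table$n_clusters))
  pts
}
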