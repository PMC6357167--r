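#' Fit a principal curve by the Hastie-Stuetzle algorithm
#'
#' A principal curve is a smooth one-dimensional curve through the middle of a
#' point cloud, generalizing the first principal component: every point on the
#' curve is (approximately) the mean of the data projecting onto it. The fit
#' alternates projection and smoothing:
#' \enumerate{
#'   \item initialize with the projections onto the first principal component;
#'   \item smooth each coordinate against the current arc-length parameter
#'     with a local-averaging smoother (window = `span` fraction of points);
#'   \item re-parameterize the smoothed polyline by arc length and re-project
#'     all points onto it.
#' }
#' Iteration stops when the relative change in total squared projection
#' distance falls below `tol`, at `max_iter`, or — a monotonicity safeguard —
#' when an iteration would increase the residual, in which case the previous
#' curve is kept. The recorded residual trace is therefore non-increasing.
#' The procedure involves no randomness and is fully deterministic.
#'
#' @param points n x d numeric matrix, n >= 4.
#' @param span smoother span as a fraction of points (default 0.3).
#' @param tol relative convergence tolerance on the residual (default 1e-4).
#' @param max_iter maximum number of projection/smoothing rounds.
#' @return object of class `principal_curve_fit` with elements `vertices`
#'   (ordered polyline), `cumulative_arclength`, `total_length`, `lambda`
#'   (arc-length position of each input point), `dist2` (squared projection
#'   distances), and `residual_trace`.
#' @export
fit_principal_curve <- function(points, span = 0.3, tol = 1e-4, max_iter = 30L) {
  points <- as.matrix(points)
  n <- nrow(points); d <- ncol(points)
  if (n < 4) stop("need at least 4 points")
  if (all(apply(points, 2L, function(x) diff(range(x)) == 0)))
    stop("degenerate cloud: all points identical")

  center <- colMeans(points)
  pc <- prcomp(points, center = TRUE, scale. = FALSE)
  lambda <- pc$x[, 1L]
  ord <- order(lambda)
  vertices <- sweep(outer(lambda[ord], pc$rotation[, 1L]), 2L, center, `+`)
  curve <- polyline_curve(vertices)
  proj <- project_to_polyline(curve, points)
  residual <- sum(proj$dist2)
  trace <- residual
  lambda <- proj$lambda

  for (it in seq_len(max_iter)) {
    ord <- order(lambda)
    lam_s <- lambda[ord]
    smoothed <- apply(points[ord, , drop = FALSE], 2L, local_linear_smooth,
                      lambda = lam_s, span = span)
    cand <- polyline_curve(smoothed)
    cand_proj <- project_to_polyline(cand, points)
    cand_residual <- sum(cand_proj$dist2)
    if (cand_residual > residual) break  # safeguard: never accept a worse curve
    converged <- (residual - cand_residual) <= tol * max(residual, .Machine$double.eps)
    curve <- cand; proj <- cand_proj
    residual <- cand_residual; lambda <- proj$lambda
    trace <- c(trace, residual)
    if (converged) break
  }

  curve$lambda <- lambda
  curve$dist2 <- proj$dist2
  curve$residual_trace <- trace
  curve
}

# Build a curve object from ordered vertices, dropping zero-length segments.
polyline_curve <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) > 1) {
    seg <- sqrt(rowSums((vertices[-1, , drop = FALSE] -
                         vertices[-nrow(vertices), , drop = FALSE])^2))
    keep <- c(TRUE, seg > 0)
    vertices <- vertices[keep, , drop = FALSE]
    seg <- seg[seg > 0]
  } else seg <- numeric(0)
  structure(list(vertices = vertices,
                 cumulative_arclength = c(0, cumsum(seg)),
                 total_length = sum(seg)),
            class = "principal_curve_fit")
}

# Local linear scatterplot smoother of one coordinate against arc length:
# at each point, a least-squares line is fitted within a window of
# span * n neighbours (by arc-length order) and evaluated there. Local lines,
# unlike local means, do not flatten the curve at its ends.
local_linear_smooth <- function(x, lambda, span) {
  n <- length(x)
  h <- max(2L, floor(span * n / 2))
  idx <- seq_len(n)
  lo <- pmax(idx - h, 1L); hi <- pmin(idx + h, n)
  m <- hi - lo + 1L
  cl <- cumsum(c(0, lambda)); cx <- cumsum(c(0, x))
  cll <- cumsum(c(0, lambda^2)); clx <- cumsum(c(0, lambda * x))
  Sl <- cl[hi + 1L] - cl[lo]; Sx <- cx[hi + 1L] - cx[lo]
  Sll <- cll[hi + 1L] - cll[lo]; Slx <- clx[hi + 1L] - clx[lo]
  denom <- m * Sll - Sl^2
  beta <- ifelse(denom > .Machine$double.eps * pmax(1, Sll) * m,
                 (m * Slx - Sl * Sx) / denom, 0)
  Sx / m + beta * (lambda - Sl / m)
}

#' Project points onto a fitted curve
#'
#' Orthogonal projection onto the polyline: each point is assigned the arc
#' length of its nearest point on the curve (projections beyond the ends are
#' clamped to the end vertices) and its squared distance to the curve.
#'
#' @param curve a `principal_curve_fit`.
#' @param points n x d matrix in the same space as the curve vertices.
#' @return list with `lambda` (arc lengths in `[0, total_length]`) and `dist2`.
#' @export
project_to_polyline <- function(curve, points) {
  v <- curve$vertices
  points <- matrix(points, ncol = ncol(v))
  n <- nrow(points)
  if (nrow(v) == 1L) {
    d2 <- rowSums(sweep(points, 2L, v[1L, ])^2)
    return(list(lambda = rep(0, n), dist2 = d2))
  }
  best_d2 <- rep(Inf, n)
  best_lam <- rep(0, n)
  cum <- curve$cumulative_arclength
  for (k in seq_len(nrow(v) - 1L)) {
    a <- v[k, ]; b <- v[k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    pa <- sweep(points, 2L, a)
    t <- pmin(1, pmax(0, as.numeric(pa %*% ab) / len2))
    diff <- pa - outer(t, ab)
    d2 <- rowSums(diff^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_lam[upd] <- cum[k] + t[upd] * sqrt(len2)
  }
  list(lambda = best_lam, dist2 = best_d2)
}

# Reverse a curve's direction (arc length measured from the other end).
reverse_curve <- function(curve) {
  out <- polyline_curve(curve$vertices[rev(seq_len(nrow(curve$vertices))), , drop = FALSE])
  out$residual_trace <- curve$residual_trace
  out
}
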