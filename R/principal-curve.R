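#' @include AllClasses.R
NULL

# Project points onto a polyline. Returns arc-length position (lambda),
# signed perpendicular distance (sign = side, by 2D cross product with the
# local tangent) and the foot coordinates. Ties across segments resolve
# to the lowest segment index (strict < comparison).
.project_polyline <- function(pts, poly) {
  n <- nrow(pts)
  m <- nrow(poly)
  seg <- diff(poly)                      # (m-1) x 2
  seglen2 <- rowSums(seg^2)
  seglen <- sqrt(seglen2)
  arc0 <- c(0, cumsum(seglen))
  best_d2 <- rep(Inf, n)
  lambda <- numeric(n)
  signed <- numeric(n)
  foot <- matrix(0, n, 2)
  for (s in seq_len(m - 1)) {
    if (seglen2[s] < 1e-300) next
    dx <- pts[, 1] - poly[s, 1]
    dy <- pts[, 2] - poly[s, 2]
    t <- pmin(1, pmax(0, (dx * seg[s, 1] + dy * seg[s, 2]) / seglen2[s]))
    fx <- poly[s, 1] + t * seg[s, 1]
    fy <- poly[s, 2] + t * seg[s, 2]
    d2 <- (pts[, 1] - fx)^2 + (pts[, 2] - fy)^2
    upd <- d2 < best_d2 - 1e-15
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      lambda[upd] <- arc0[s] + t[upd] * seglen[s]
      cross <- seg[s, 1] * (pts[upd, 2] - poly[s, 2]) -
        seg[s, 2] * (pts[upd, 1] - poly[s, 1])
      signed[upd] <- sign(cross) * sqrt(d2[upd])
      foot[upd, 1] <- fx[upd]
      foot[upd, 2] <- fy[upd]
    }
  }
  list(lambda = lambda, distance = signed, foot = foot)
}

#' Fit a principal curve through a 2D point cloud
#'
#' Iterative projection--smoothing fit in the style of Hastie and
#' Stuetzle: the curve is initialized as the first principal component;
#' each round projects the points onto the current polyline and smooths
#' each coordinate against arc length with a local-regression smoother
#' (\code{lowess}), until the mean projection displacement drops below
#' \code{tol} (micrometers in tissue space) or \code{max_iter} rounds.
#'
#' @param points numeric matrix, n x 2.
#' @param span local-regression span (fraction of points in each window,
#'   default 0.3).
#' @param tol convergence tolerance on mean projection displacement
#'   (default 0.1).
#' @param max_iter maximum projection--smoothing rounds (default 50).
#' @param n_vertices number of polyline vertices the smoothed curve is
#'   resampled to (default \code{min(200, n)}).
#' @return a \linkS4class{PrincipalCurve}; if the tolerance was not met
#'   the best iterate is returned with \code{converged = FALSE} and a
#'   warning.
#' @examples
#' th <- seq(-pi / 6, pi / 6, length.out = 200)
#' pc <- fitPrincipalCurve(cbind(100 * sin(th), 100 * cos(th)))
#' max(pc@arcLength)  # close to 100 * pi / 3
#' @export
fitPrincipalCurve <- function(points, span = 0.3, tol = 0.1,
                              max_iter = 50L, n_vertices = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  n <- nrow(points)
  if (n < 10) stop("need at least 10 points")
  if (max(apply(points, 2, function(v) diff(range(v)))) < 1e-12)
    stop("all points coincident")
  if (is.null(n_vertices)) n_vertices <- min(200L, n)

  ctr <- colMeans(points)
  pc1 <- svd(sweep(points, 2, ctr))$v[, 1]
  # deterministic sign: largest-magnitude loading positive
  if (pc1[which.max(abs(pc1))] < 0) pc1 <- -pc1
  lambda <- as.vector(sweep(points, 2, ctr) %*% pc1)

  prev_foot <- NULL
  converged <- FALSE
  iter <- 0L
  poly <- NULL
  proj <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    o <- order(lambda)
    lo_x <- stats::lowess(lambda[o], points[o, 1], f = span, iter = 0)
    lo_y <- stats::lowess(lambda[o], points[o, 2], f = span, iter = 0)
    grid <- seq(min(lambda), max(lambda), length.out = n_vertices)
    px <- stats::approx(lo_x$x, lo_x$y, xout = grid, rule = 2,
                        ties = mean)$y
    py <- stats::approx(lo_y$x, lo_y$y, xout = grid, rule = 2,
                        ties = mean)$y
    poly <- cbind(px, py)
    # drop duplicate consecutive vertices (flat stretches)
    keep <- c(TRUE, rowSums(abs(diff(poly))) > 1e-12)
    poly <- poly[keep, , drop = FALSE]
    if (nrow(poly) < 2)
      poly <- rbind(ctr - pc1 * stats::sd(lambda),
                    ctr + pc1 * stats::sd(lambda))
    proj <- .project_polyline(points, poly)
    lambda <- proj$lambda
    if (!is.null(prev_foot)) {
      disp <- mean(sqrt(rowSums((proj$foot - prev_foot)^2)))
      if (disp < tol) { converged <- TRUE; break }
    }
    prev_foot <- proj$foot
  }
  if (!converged && max_iter > 1)
    warning("principal curve did not converge in ", max_iter,
            " iterations; returning best iterate")
  arc <- c(0, cumsum(sqrt(rowSums(diff(poly)^2))))
  methods::new("PrincipalCurve", points = poly, arcLength = arc,
               lambda = proj$lambda, distance = proj$distance,
               span = span, converged = converged, iterations = iter)
}

setMethod("show", "PrincipalCurve", function(object) {
  cat("PrincipalCurve:", nrow(object@points), "vertices, arc length",
      sprintf("%.2f", max(object@arcLength)), "\n")
  cat("span", object@span, "|", object@iterations, "iterations |",
      if (object@converged) "converged" else "NOT converged", "\n")
  invisible(NULL)
})

#' Project points onto a fitted principal curve
#'
#' @param curve a \linkS4class{PrincipalCurve}.
#' @param points n x 2 matrix.
#' @return list with \code{lambda} (arc-length positions) and
#'   \code{distance} (signed perpendicular distances).
#' @export
projectOnCurve <- function(curve, points) {
  p <- .project_polyline(as.matrix(points), curve@points)
  list(lambda = p$lambda, distance = p$distance)
}
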