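## Sliding-window circle fitting and per-unit local frames.
##
## The curvature of a repeat region is measured from a circle fitted through
## the centroids of the units inside a sliding window: a reference plane is
## taken from the first two principal components of the window centroids, an
## initial circle is fitted algebraically to the projected centroids, and the
## radius is refined by the "widest crown" criterion on all projected
## C-alpha atoms. Curvature for a pair of consecutive units is the angle the
## two unit centroids subtend at the circle center.

#' Centroid of a repeat unit
#'
#' @param coords numeric matrix (n x 3) of C-alpha coordinates.
#' @return numeric(3), the arithmetic mean of the coordinates.
#' @export
unitCentroid <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3L)
  if (nrow(coords) == 0L) stop("unitCentroid: empty coordinate set")
  colMeans(coords)
}

#' Select the unit window for a consecutive pair
#'
#' For the pair of units (i, i+1) the window holds `min(window, nUnits)`
#' contiguous units roughly centered on the pair: units i-2 .. i+3, clamped
#' at the region ends and extended toward the other side to keep the window
#' full.
#'
#' @param pairIndex 1-based index of the left unit of the pair
#'   (1 .. nUnits - 1).
#' @param nUnits number of units in the region (>= 3).
#' @param window target window length in units (default 6).
#' @return integer vector of unit indices, sorted.
#' @export
selectWindow <- function(pairIndex, nUnits, window = 6L) {
  stopifnot(nUnits >= 3L, pairIndex >= 1L, pairIndex <= nUnits - 1L)
  w <- min(as.integer(window), nUnits)
  lo <- pairIndex - 2L
  hi <- pairIndex + 3L
  if (lo < 1L) { hi <- hi - lo + 1L; lo <- 1L }
  if (hi > nUnits) { lo <- lo - (hi - nUnits); hi <- nUnits }
  lo <- max(1L, lo)
  ## shrink/extend to exactly w units, keeping the pair inside
  while (hi - lo + 1L > w) {
    if (pairIndex - lo > hi - (pairIndex + 1L)) lo <- lo + 1L else hi <- hi - 1L
  }
  seq.int(lo, hi)
}

#' Fit a reference plane through window centroids
#'
#' Principal-component plane: origin at the centroid mean, in-plane basis
#' (u, v) along the first two principal directions, normal n = u x v.
#'
#' @param centroids numeric matrix (>= 3 x 3).
#' @return list with `origin`, `u`, `v`, `n` (unit 3-vectors) and `evals`,
#'   the three principal variances (used upstream to detect near-linear
#'   windows).
#' @export
fitPlane <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 3L) stop("fitPlane: need at least 3 centroids")
  origin <- colMeans(centroids)
  cc <- sweep(centroids, 2L, origin)
  if (max(abs(cc)) < 1e-9) stop("fitPlane: degenerate geometry (all points identical)")
  s <- svd(cc, nu = 0L)
  evals <- s$d^2 / max(1L, nrow(cc) - 1L)
  u <- s$v[, 1L]
  v <- s$v[, 2L]
  n <- .cross3(u, v)           # unit by construction (u, v orthonormal)
  list(origin = origin, u = u, v = v, n = n, evals = evals)
}

#' Project 3D points into a plane's 2D coordinates
#'
#' @param points numeric matrix (n x 3).
#' @param plane a plane as returned by [fitPlane()].
#' @return numeric matrix (n x 2) of in-plane coordinates.
#' @export
projectToPlane <- function(points, plane) {
  pc <- sweep(as.matrix(points), 2L, plane$origin)
  cbind(pc %*% plane$u, pc %*% plane$v)
}

#' Algebraic least-squares circle fit
#'
#' Kasa-style linearized fit: minimizes the algebraic residual
#' sum((x^2 + y^2 + D x + E y + F)^2), a linear least-squares problem. It is
#' deterministic and exact when the points lie exactly on a circle.
#'
#' @param points2d numeric matrix (>= 3 x 2).
#' @return list with `center` (numeric(2)), `radius` (> 0) and `ok`
#'   (FALSE when the points are collinear within tolerance, in which case
#'   `radius` is `Inf`).
#' @export
fitInitialCircle <- function(points2d) {
  p <- as.matrix(points2d)
  if (nrow(p) < 3L) stop("fitInitialCircle: need at least 3 points")
  A <- cbind(2 * p[, 1L], 2 * p[, 2L], 1)
  b <- p[, 1L]^2 + p[, 2L]^2
  qrA <- qr(A)
  if (qrA$rank < 3L) {
    return(list(center = c(NA_real_, NA_real_), radius = Inf, ok = FALSE))
  }
  sol <- qr.coef(qrA, b)
  center <- sol[1:2]
  r2 <- sol[3L] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0) {
    return(list(center = c(NA_real_, NA_real_), radius = Inf, ok = FALSE))
  }
  list(center = unname(center), radius = sqrt(r2), ok = TRUE)
}

#' Refine a fitted circle by the widest-crown criterion
#'
#' Projected C-alpha points are labeled "in" when their distance to the
#' initial center is below the initial radius and "out" otherwise. When the
#' two walls are separated (max inner radius < min outer radius) the crown
#' is that gap and the refined radius is its midpoint; the center is kept.
#' When the walls interleave, the widest empty interval between consecutive
#' sorted radial distances is used instead (ties broken by midpoint closest
#' to the initial radius). With fewer than one point on either side the
#' initial circle is kept and the result is flagged as a fallback.
#'
#' @param points2d all projected C-alpha points of the window (n x 2).
#' @param center numeric(2), initial circle center (kept fixed).
#' @param radius initial circle radius.
#' @return list with `center`, `radius`, `crownInner`, `crownOuter`,
#'   `fallback` (logical).
#' @export
widestCrownRefine <- function(points2d, center, radius) {
  p <- as.matrix(points2d)
  d <- sqrt((p[, 1L] - center[1L])^2 + (p[, 2L] - center[2L])^2)
  inn <- d[d < radius]
  out <- d[d >= radius]
  if (length(inn) == 0L || length(out) == 0L) {
    .log("debug", "widest crown: no points on one side of the initial circle; keeping initial fit")
    return(list(center = center, radius = radius,
                crownInner = NA_real_, crownOuter = NA_real_, fallback = TRUE))
  }
  ci <- max(inn)
  co <- min(out)
  if (co > ci) {
    return(list(center = center, radius = (ci + co) / 2,
                crownInner = ci, crownOuter = co, fallback = FALSE))
  }
  ## interleaved walls: widest empty gap among sorted radial distances,
  ## preferring the gap whose interval contains (else is nearest to) the
  ## initial radius among equally wide gaps
  ds <- sort(unique(d))
  if (length(ds) < 2L) {
    return(list(center = center, radius = radius,
                crownInner = ds[1L], crownOuter = ds[1L], fallback = TRUE))
  }
  gaps <- diff(ds)
  wmax <- max(gaps)
  cand <- which(gaps >= wmax - 1e-12)
  if (length(cand) > 1L) {
    mids <- (ds[cand] + ds[cand + 1L]) / 2
    contains <- ds[cand] <= radius & radius <= ds[cand + 1L]
    cand <- if (any(contains)) cand[contains][1L] else cand[which.min(abs(mids - radius))]
  }
  ci <- ds[cand[1L]]
  co <- ds[cand[1L] + 1L]
  list(center = center, radius = (ci + co) / 2,
       crownInner = ci, crownOuter = co, fallback = FALSE)
}

#' Curvature angle subtended at the circle center
#'
#' @param center3d numeric(3), circle center in 3D.
#' @param centroidA,centroidB numeric(3), centroids of two consecutive units.
#' @return angle in radians, in [0, pi].
#' @export
curvatureAngle <- function(center3d, centroidA, centroidB) {
  a <- centroidA - center3d
  b <- centroidB - center3d
  na <- .vnorm(a); nb <- .vnorm(b)
  if (na < 1e-9 || nb < 1e-9) {
    stop("curvatureAngle: degenerate geometry (centroid coincides with circle center)")
  }
  atan2(.vnorm(.cross3(a, b)), sum(a * b))
}

#' Build the local frame of a unit on the fitted circle
#'
#' Pitch axis y points from the circle center to the unit centroid (along
#' the radius); twist axis x is the centroid-to-centroid travel vector
#' orthogonalized against y (the tangent); curvature axis z = x cross y.
#'
#' @param center3d numeric(3) circle center.
#' @param centroid numeric(3) centroid of the unit the frame is attached to.
#' @param centroidNext numeric(3) centroid defining the direction of travel.
#' @return list with unit vectors `x`, `y`, `z` and `anchor` (the centroid).
#' @export
buildLocalFrame <- function(center3d, centroid, centroidNext) {
  y <- centroid - center3d
  if (.vnorm(y) < 1e-9) stop("buildLocalFrame: centroid coincides with circle center")
  y <- .normalize(y)
  travel <- centroidNext - centroid
  if (.vnorm(travel) < 1e-9) stop("buildLocalFrame: consecutive centroids coincide")
  xr <- travel - sum(travel * y) * y
  if (.vnorm(xr) < 1e-9 * .vnorm(travel)) {
    stop("buildLocalFrame: degenerate frame (travel parallel to the pitch axis)")
  }
  x <- .normalize(xr)
  list(x = x, y = y, z = .cross3(x, y), anchor = centroid)
}

## Frame for near-linear windows: pitch axis from the third principal
## direction, twist axis along travel (orthogonalized), z = x cross y.
.linearFrame <- function(plane, centroid, centroidNext) {
  y <- plane$n
  travel <- centroidNext - centroid
  if (.vnorm(travel) < 1e-9) stop("linear frame: consecutive centroids coincide")
  xr <- travel - sum(travel * y) * y
  if (.vnorm(xr) < 1e-9 * .vnorm(travel)) {
    stop("linear frame: travel parallel to the third principal direction")
  }
  x <- .normalize(xr)
  list(x = x, y = y, z = .cross3(x, y), anchor = centroid)
}
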