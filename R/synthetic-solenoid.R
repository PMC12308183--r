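## Synthetic solenoid backbones with known ground-truth angles.
##
## Ground truth is defined operationally, in the same terms the measurement
## pipeline uses: unit centroids are placed exactly on a circle of the
## prescribed radius with an arc of yaw0 radians between consecutive units,
## and each unit's body accumulates the prescribed roll (twist) and pitch
## rotations expressed in the local tangent/radial/normal frame attached to
## its centroid. By construction the per-pair inter-unit rotation measured
## in those frames is exactly Ry(pitch0) Rx(roll0-as-reported), and the
## centroid circle is the fitted circle, so the pipeline should recover
## (curvature, twist, pitch) = (|yaw0|, roll0, pitch0) on noiseless input.

## Sign constant mapping reported (clockwise-positive) twist to the
## mathematical roll angle; shared with pairDescriptor's default.
.twistSignDefault <- -1

#' Ideal alpha-helix C-alpha template
#'
#' C-alpha trace of an ideal alpha helix (rise 1.5 Angstrom per residue,
#' 100 degrees rotation per residue, helix radius 2.3 Angstrom), centered
#' at its centroid. This mimics one helical repeat unit of an
#' alpha-solenoid and gives non-degenerate superpositions.
#'
#' @param nRes residues in the template (default 10).
#' @param rise rise per residue in Angstrom (default 1.5).
#' @param turnDeg rotation per residue in degrees (default 100).
#' @param helixRadius helix radius in Angstrom (default 2.3).
#' @return numeric matrix (nRes x 3), centroid at the origin.
#' @export
helixTemplate <- function(nRes = 10L, rise = 1.5, turnDeg = 100,
                          helixRadius = 2.3) {
  k <- seq_len(nRes) - 1L
  ang <- k * turnDeg * pi / 180
  m <- cbind(helixRadius * cos(ang), helixRadius * sin(ang), k * rise)
  sweep(m, 2L, colMeans(m))
}

## Local frame on the generating circle at arc angle theta (radius in the
## xy-plane, center at the origin): y radial outward, x along travel.
.circleFrame <- function(theta, yawSign) {
  y <- c(cos(theta), sin(theta), 0)
  x <- yawSign * c(-sin(theta), cos(theta), 0)
  list(x = x, y = y, z = .cross3(x, y))
}

#' Generate a synthetic solenoid with known ground truth
#'
#' Places `nUnits` copies of a template unit with centroids exactly on a
#' circle of the given radius, consecutive centroids separated by an arc of
#' `yaw0` radians, and unit bodies accumulating `roll0` (twist) and
#' `pitch0` per unit in their local frames. `roll0` and `pitch0` are
#' expressed in the reported sign conventions (clockwise-positive twist).
#' Optional isotropic Gaussian coordinate noise is added with the given
#' seed. With `closed = TRUE` the ring closes: `yaw0` is forced to
#' `2 * pi / nUnits` and `pitch0` must be 0.
#'
#' @param nUnits number of units (>= 3).
#' @param yaw0 arc (curvature) angle per unit in radians (nonzero;
#'   overridden when `closed`).
#' @param pitch0 pitch angle per unit in radians (|pitch0| < pi/2).
#' @param roll0 twist angle per unit in radians.
#' @param radius circle radius in Angstrom (default 20).
#' @param template unit C-alpha template (default [helixTemplate()]); it is
#'   re-centered at its centroid.
#' @param noiseSd isotropic Gaussian noise per coordinate in Angstrom
#'   (default 0).
#' @param seed RNG seed for the noise (required when `noiseSd > 0`).
#' @param closed generate a closed ring (default FALSE).
#' @param chain chain identifier (default "A").
#' @return list with `structure` (\linkS4class{CaStructure}), `region`
#'   (\linkS4class{RepeatRegion}) and `truth`, a data.frame of per-pair
#'   ground-truth angles (`curvature`, `twist`, `pitch` in the reported
#'   conventions).
#' @export
generateSolenoid <- function(nUnits, yaw0, pitch0 = 0, roll0 = 0, radius = 20,
                             template = helixTemplate(), noiseSd = 0,
                             seed = NULL, closed = FALSE, chain = "A") {
  nUnits <- as.integer(nUnits)
  if (nUnits < 3L) stop("generateSolenoid: need at least 3 units")
  if (closed) {
    if (pitch0 != 0) stop("generateSolenoid: a closed ring requires pitch0 = 0")
    yaw0 <- 2 * pi / nUnits
  }
  if (abs(yaw0) < 1e-8) stop("generateSolenoid: yaw0 must be nonzero (use generateLinearRod for straight stacks)")
  if (abs(pitch0) >= pi / 2) stop("generateSolenoid: |pitch0| must be < pi/2")
  if (noiseSd > 0 && is.null(seed)) stop("generateSolenoid: noise requires a seed")
  template <- sweep(as.matrix(template), 2L, colMeans(as.matrix(template)))
  nRes <- nrow(template)
  yawSign <- sign(yaw0)
  ## per-unit body step in local-frame coordinates (reported conventions)
  D <- .rotY(pitch0) %*% .rotX(.twistSignDefault * roll0)
  B <- diag(3L)
  coords <- matrix(0, nUnits * nRes, 3L)
  for (k in seq_len(nUnits)) {
    theta <- (k - 1L) * yaw0
    fr <- .circleFrame(theta, yawSign)
    Fm <- cbind(fr$x, fr$y, fr$z)
    ck <- radius * c(cos(theta), sin(theta), 0)
    rows <- ((k - 1L) * nRes + 1L):(k * nRes)
    coords[rows, ] <- sweep(template %*% t(Fm %*% B), 2L, ck, "+")
    B <- t(D) %*% B                     # accumulate the inverse step
  }
  if (noiseSd > 0) {
    coords <- coords + .withSeed(seed, matrix(stats::rnorm(length(coords), 0, noiseSd),
                                              ncol = 3L))
  }
  structure <- methods::new("CaStructure",
    coords = coords,
    chain = rep(chain, nrow(coords)),
    resno = seq_len(nrow(coords)),
    icode = rep("", nrow(coords)),
    model = 1L,
    source = sprintf("synthetic:solenoid(n=%d,yaw=%.4g,pitch=%.4g,roll=%.4g,r=%.4g,noise=%.3g)",
                     nUnits, yaw0, pitch0, roll0, radius, noiseSd))
  region <- newRepeatRegion(
    regionId = "synthetic_solenoid", chain = chain,
    units = data.frame(start = (seq_len(nUnits) - 1L) * nRes + 1L,
                       end = seq_len(nUnits) * nRes))
  truth <- data.frame(pair = seq_len(nUnits - 1L),
                      curvature = abs(yaw0), twist = roll0, pitch = pitch0)
  list(structure = structure, region = region, truth = truth,
       params = list(nUnits = nUnits, yaw0 = yaw0, pitch0 = pitch0,
                     roll0 = roll0, radius = radius, noiseSd = noiseSd,
                     seed = seed, closed = closed))
}

#' Generate a straight (zero-curvature) repeat rod
#'
#' Units are translated copies of the template along one axis, optionally
#' with an accumulated twist (`roll0`) about the travel axis. The pipeline
#' is expected to report curvature 0 with the near-linear flag set.
#'
#' @param nUnits number of units (>= 3).
#' @param spacing centroid-to-centroid distance in Angstrom (default 10).
#' @param template unit C-alpha template (default [helixTemplate()]).
#' @param roll0 twist per unit in radians, reported convention (default 0).
#' @param noiseSd Gaussian coordinate noise in Angstrom (default 0).
#' @param seed RNG seed for the noise.
#' @param chain chain identifier (default "A").
#' @return list with `structure`, `region` and `truth` as in
#'   [generateSolenoid()] (`curvature` 0).
#' @export
generateLinearRod <- function(nUnits, spacing = 10, template = helixTemplate(),
                              roll0 = 0, noiseSd = 0, seed = NULL, chain = "A") {
  nUnits <- as.integer(nUnits)
  if (nUnits < 3L) stop("generateLinearRod: need at least 3 units")
  if (noiseSd > 0 && is.null(seed)) stop("generateLinearRod: noise requires a seed")
  template <- sweep(as.matrix(template), 2L, colMeans(as.matrix(template)))
  nRes <- nrow(template)
  D <- .rotX(.twistSignDefault * roll0)   # body step about the travel axis x
  B <- diag(3L)
  coords <- matrix(0, nUnits * nRes, 3L)
  for (k in seq_len(nUnits)) {
    ck <- c((k - 1L) * spacing, 0, 0)
    rows <- ((k - 1L) * nRes + 1L):(k * nRes)
    coords[rows, ] <- sweep(template %*% t(B), 2L, ck, "+")
    B <- t(D) %*% B
  }
  if (noiseSd > 0) {
    coords <- coords + .withSeed(seed, matrix(stats::rnorm(length(coords), 0, noiseSd),
                                              ncol = 3L))
  }
  structure <- methods::new("CaStructure",
    coords = coords,
    chain = rep(chain, nrow(coords)),
    resno = seq_len(nrow(coords)),
    icode = rep("", nrow(coords)),
    model = 1L,
    source = sprintf("synthetic:rod(n=%d,spacing=%.4g,roll=%.4g,noise=%.3g)",
                     nUnits, spacing, roll0, noiseSd))
  region <- newRepeatRegion(
    regionId = "synthetic_rod", chain = chain,
    units = data.frame(start = (seq_len(nUnits) - 1L) * nRes + 1L,
                       end = seq_len(nUnits) * nRes))
  truth <- data.frame(pair = seq_len(nUnits - 1L),
                      curvature = 0, twist = roll0, pitch = 0)
  list(structure = structure, region = region, truth = truth,
       params = list(nUnits = nUnits, spacing = spacing, roll0 = roll0,
                     noiseSd = noiseSd, seed = seed))
}

#' Mirror-reflect a structure
#'
#' Reflects all coordinates through the xy-plane (z -> -z). Useful for
#' handedness checks: reflection must flip the sign of twist and pitch but
#' preserve curvature.
#'
#' @param structure a \linkS4class{CaStructure}.
#' @return the reflected \linkS4class{CaStructure}.
#' @export
mirrorStructure <- function(structure) {
  coords <- structure@coords
  coords[, 3L] <- -coords[, 3L]
  methods::initialize(structure, coords = coords,
                      source = paste0(structure@source, "|mirrored"))
}

#' Apply a rigid motion to a structure
#'
#' @param structure a \linkS4class{CaStructure}.
#' @param R 3 x 3 rotation matrix.
#' @param t numeric(3) translation (Angstrom).
#' @return the transformed \linkS4class{CaStructure}.
#' @export
transformStructure <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  if (!.isRotation(R, tol = 1e-6)) stop("transformStructure: R is not a rotation")
  methods::initialize(structure,
    coords = sweep(structure@coords %*% t(R), 2L, t, "+"),
    source = paste0(structure@source, "|moved"))
}
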