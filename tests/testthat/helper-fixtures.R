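# Shared fixtures and independent oracles, built in code at test time.

rotZ <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
rotY <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rotX <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)

randomRotation <- function() {
  th <- stats::runif(3, -pi, pi)
  rotZ(th[1]) %*% rotY(th[2] / 2) %*% rotX(th[3])
}

# Independent superposition oracle: Horn's closed-form quaternion method
# (eigendecomposition of the 4x4 profile matrix), algorithmically distinct
# from the package's Kabsch/SVD path. Returns R with fixed ~ R moving.
hornSuperpose <- function(moving, fixed) {
  mc <- sweep(moving, 2, colMeans(moving))
  fc <- sweep(fixed, 2, colMeans(fixed))
  S <- crossprod(mc, fc)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),  2*(x*z+w*y),
    2*(x*y+w*z),  1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),  2*(y*z+w*x),  1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  resid <- mc %*% t(R) - fc
  list(R = R, rmsd = sqrt(mean(rowSums(resid^2))))
}

# Closed-form circumcircle of a 2D triangle (independent of the algebraic
# least-squares fit).
circumcircle2d <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# Minimal hand-written PDB fixture: 4 residues, one lacking a C-alpha,
# one with two altloc C-alpha conformers (B has higher occupancy).
writeTinyPdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2      12.000   7.250  -4.125  1.00  0.00           C",
    "ATOM      4  N   PRO A   3      12.500   8.000  -3.500  1.00  0.00           N",
    "ATOM      5  CA ASER A   4      13.000   8.000  -3.000  0.40  0.00           C",
    "ATOM      6  CA BSER A   4      13.125   8.250  -3.250  0.60  0.00           C",
    "TER",
    "END"), path)
  path
}

writeRegionJson <- function(path, regions) {
  jsonlite::write_json(regions, path, auto_unbox = TRUE)
  path
}
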