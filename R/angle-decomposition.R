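## Canonical re-orientation of consecutive units, rigid superposition, and
## Tait-Bryan decomposition of the inter-unit rotation.
##
## Each unit of a consecutive pair is first expressed in its own local frame
## (twist axis x, pitch axis y, curvature axis z from the fitted circle);
## the later unit is then superposed onto its predecessor by least squares
## and the rotation is factored as R = Rz(yaw) Ry(pitch) Rx(roll)
## (intrinsic z-y'-x''). The yaw component duplicates what circle fitting
## already measures as curvature and is discarded from the report (kept as
## a diagnostic); roll is reported as twist, pitch as pitch.

#' Express unit coordinates in a local frame
#'
#' Maps p to t(F) (p - anchor) where F has columns (x, y, z): a unit whose
#' axes coincide with the global axes becomes a pure translation to its
#' local origin.
#'
#' @param coords numeric matrix (n x 3).
#' @param frame a local frame from [buildLocalFrame()].
#' @return numeric matrix (n x 3) in frame coordinates.
#' @export
canonicalizeUnit <- function(coords, frame) {
  Fm <- cbind(frame$x, frame$y, frame$z)
  sweep(as.matrix(coords), 2L, frame$anchor) %*% Fm
}

## Deterministic 1:1 correspondence for unequal-length units: trim the
## longer unit's termini equally (extra residue trimmed C-terminally on
## ties) until lengths match.
.trimCorrespondence <- function(moving, fixed) {
  nm <- nrow(moving); nf <- nrow(fixed)
  if (nm == nf) return(list(moving = moving, fixed = fixed))
  trim <- function(m, k) {
    nHead <- k %/% 2L
    nTail <- k - nHead            # ties: one extra off the C-terminus
    n <- nrow(m)
    m[seq.int(nHead + 1L, n - nTail), , drop = FALSE]
  }
  if (nm > nf) {
    .log("debug", sprintf("trimming moving unit %d -> %d residues", nm, nf))
    moving <- trim(moving, nm - nf)
  } else {
    .log("debug", sprintf("trimming fixed unit %d -> %d residues", nf, nm))
    fixed <- trim(fixed, nf - nm)
  }
  list(moving = moving, fixed = fixed)
}

#' Rigid superposition of one unit onto its predecessor
#'
#' Establishes a sequence-order-preserving 1:1 correspondence (equal
#' lengths map directly; for unequal lengths the longer unit's termini are
#' trimmed equally) and computes the least-squares rotation R (det +1,
#' reflection corrected by the standard sign fix), translation and RMSD by
#' the Kabsch/SVD method, so that fixed ~ R moving + t.
#'
#' An `"external"` backend slot is provided for a TM-align-compatible
#' aligner found on the PATH; the default internal path never requires it.
#'
#' @param moving numeric matrix (>= 3 x 3), unit i (canonicalized).
#' @param fixed numeric matrix (>= 3 x 3), unit i-1 (canonicalized).
#' @param backend `"internal"` (Kabsch, default) or `"external"`.
#' @return list with `R` (3 x 3 rotation), `t` (numeric(3)), `rmsd`
#'   (Angstrom over the corresponded atoms) and `alignedLength`.
#' @export
superposeUnits <- function(moving, fixed, backend = c("internal", "external")) {
  backend <- match.arg(backend)
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (backend == "external") return(.superposeExternal(moving, fixed))
  pr <- .trimCorrespondence(moving, fixed)
  m <- pr$moving; f <- pr$fixed
  if (nrow(m) < 3L) stop("superposeUnits: need at least 3 corresponding atoms")
  cm <- colMeans(m); cf <- colMeans(f)
  mc <- sweep(m, 2L, cm); fc <- sweep(f, 2L, cf)
  H <- crossprod(mc, fc)                 # sum over atoms of m_i f_i^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  resid <- mc %*% t(R) - fc
  list(R = R,
       t = as.numeric(cf - R %*% cm),
       rmsd = sqrt(mean(rowSums(resid^2))),
       alignedLength = nrow(m))
}

## External aligner boundary. Kept to one function: looks up a
## TM-align-compatible executable at call time, writes the two units as
## temporary single-chain PDB files and reads back the rotation matrix
## (-m output). Errors informatively when no executable is found; the
## internal backend is the default and does not touch this path.
.superposeExternal <- function(moving, fixed) {
  exe <- Sys.which(c("TMalign", "tmalign", "USalign"))
  exe <- exe[exe != ""][1]
  if (is.na(exe)) {
    stop("superposeUnits: no TM-align-compatible executable found on PATH; ",
         "use backend = \"internal\"")
  }
  tmpm <- tempfile(fileext = ".pdb"); tmpf <- tempfile(fileext = ".pdb")
  tmpx <- tempfile(fileext = ".txt")
  on.exit(unlink(c(tmpm, tmpf, tmpx)), add = TRUE)
  .writeCaPdbMatrix(moving, tmpm)
  .writeCaPdbMatrix(fixed, tmpf)
  system2(exe, c(tmpm, tmpf, "-m", tmpx), stdout = FALSE, stderr = FALSE)
  lines <- readLines(tmpx)
  rows <- grep("^\\s*[012]\\s", lines, value = TRUE)[1:3]
  mat <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), function(x) as.numeric(x[2:5])))
  R <- mat[, 2:4]; t <- mat[, 1L]
  moved <- sweep(moving %*% t(R), 2L, t, "+")
  n <- min(nrow(moved), nrow(fixed))
  resid <- moved[seq_len(n), , drop = FALSE] - fixed[seq_len(n), , drop = FALSE]
  list(R = R, t = t, rmsd = sqrt(mean(rowSums(resid^2))), alignedLength = n)
}

.writeCaPdbMatrix <- function(m, path) {
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(m)), seq_len(nrow(m)), m[, 1L], m[, 2L], m[, 3L])
  writeLines(c(lines, "TER", "END"), path)
}

#' Tait-Bryan decomposition of a rotation matrix
#'
#' Factors R = Rz(yaw) Ry(pitch) Rx(roll) (intrinsic z-y'-x'' sequence):
#' yaw about the curvature axis z, then pitch about y, then roll about the
#' twist axis x. Near gimbal lock (|pitch| within 1e-7 of pi/2) yaw is set
#' to 0, the remaining rotation is absorbed into roll, and the result is
#' flagged.
#'
#' @param R 3 x 3 rotation matrix (orthogonal, det +1 within 1e-9... 1e-6
#'   accepted with a warning-free tolerance of 1e-6 on validation).
#' @return list with `yaw`, `pitch`, `roll` (radians; yaw, roll in
#'   (-pi, pi], pitch in [-pi/2, pi/2]) and `gimbal` (logical).
#' @export
decomposeTaitBryan <- function(R) {
  if (!.isRotation(R, tol = 1e-6)) {
    stop("decomposeTaitBryan: input is not a proper rotation matrix")
  }
  sp <- -R[3L, 1L]
  sp <- max(-1, min(1, sp))
  if (abs(abs(sp) - 1) < 1e-7) {
    ## gimbal lock: cos(pitch) ~ 0, yaw and roll act about the same axis
    pitch <- if (sp > 0) pi / 2 else -pi / 2
    yaw <- 0
    ## with yaw = 0: R = Ry(+-pi/2) Rx(roll); R[1,2] = sp*sr... solve from
    ## the (1,2)/(2,2) block: roll = atan2(sp * R[1,2], R[2,2])
    roll <- atan2(sp * R[1L, 2L], R[2L, 2L])
    return(list(yaw = yaw, pitch = pitch, roll = roll, gimbal = TRUE))
  }
  list(yaw = atan2(R[2L, 1L], R[1L, 1L]),
       pitch = asin(sp),
       roll = atan2(R[3L, 2L], R[3L, 3L]),
       gimbal = FALSE)
}

#' Recompose a rotation from Tait-Bryan angles
#'
#' @param yaw,pitch,roll angles in radians.
#' @return 3 x 3 rotation matrix Rz(yaw) Ry(pitch) Rx(roll).
#' @export
recomposeTaitBryan <- function(yaw, pitch, roll) {
  .rotZ(yaw) %*% .rotY(pitch) %*% .rotX(roll)
}

#' Assemble a per-pair descriptor row
#'
#' Maps a Tait-Bryan decomposition to the reported descriptors: twist is
#' the roll component (sign adjusted by the clockwise-positive convention
#' constant `twistSign`), pitch is the pitch component (its sign reconciled
#' with the displacement of the unit along the window normal when that
#' displacement is decisive), yaw is kept only as a diagnostic since
#' curvature comes from circle fitting. Handedness is the sign of the
#' signed angle, with 0 mapping to +1.
#'
#' @param curvature curvature angle from the circle fit (radians, >= 0).
#' @param angles Tait-Bryan decomposition from [decomposeTaitBryan()].
#' @param rmsd superposition RMSD (Angstrom).
#' @param alignedLength number of corresponded residues.
#' @param dispNormal displacement of the later unit's centroid along the
#'   continuity-oriented window normal (Angstrom); used for pitch-sign
#'   reconciliation.
#' @param twistSign +1 or -1: sign constant mapping the mathematical roll
#'   angle to the clockwise-positive twist convention (default -1).
#' @param dispTol minimum |dispNormal| (Angstrom) for the displacement to
#'   override the decomposition's pitch sign (default 0.5).
#' @return list (one descriptor row): curvature, twist, pitch,
#'   twist_handedness, pitch_handedness, rmsd, aligned_length, yaw_diagnostic.
#' @export
pairDescriptor <- function(curvature, angles, rmsd, alignedLength,
                           dispNormal = 0, twistSign = -1, dispTol = 0.5) {
  twist <- twistSign * angles$roll
  pitch <- angles$pitch
  if (abs(dispNormal) > dispTol && pitch != 0 &&
      sign(pitch) != sign(dispNormal)) {
    pitch <- -pitch
  }
  hand <- function(a) if (a < 0) -1L else 1L
  list(curvature = curvature, twist = twist, pitch = pitch,
       twist_handedness = hand(twist), pitch_handedness = hand(pitch),
       rmsd = rmsd, aligned_length = alignedLength,
       yaw_diagnostic = angles$yaw)
}
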