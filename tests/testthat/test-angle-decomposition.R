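test_that("canonicalization expresses a unit in its frame", {
  set.seed(61)
  m <- matrix(rnorm(30), 10, 3)
  idFrame <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
                  anchor = c(0, 0, 0))
  expect_equal(canonicalizeUnit(m, idFrame), m)
  # frame rotated 90 degrees about z: coordinates rotate -90 degrees
  fr <- list(x = c(0, 1, 0), y = c(-1, 0, 0), z = c(0, 0, 1),
             anchor = c(0, 0, 0))
  q <- canonicalizeUnit(m, fr)
  expect_equal(q, m %*% cbind(fr$x, fr$y, fr$z))
  expect_equal(q[, 1], m[, 2])
  expect_equal(q[, 2], -m[, 1])
  # canonicalizing with own frame then self-superposing: identity, RMSD 0
  sup <- superposeUnits(q, q)
  expect_equal(sup$R, diag(3), tolerance = 1e-9)
  expect_equal(sup$rmsd, 0, tolerance = 1e-9)
})

test_that("superposition recovers constructed rotations and matches the quaternion oracle", {
  set.seed(71)
  # construct-and-recover: unit rotated about its centroid by known R0
  m <- helixTemplate()
  R0 <- randomRotation()
  f <- m %*% t(R0)
  sup <- superposeUnits(m, f)
  expect_equal(sup$R, R0, tolerance = 1e-6)
  expect_equal(sup$rmsd, 0, tolerance = 1e-9)
  expect_equal(sup$alignedLength, nrow(m))
  # random noisy toy units of 3..20 points vs Horn's closed form
  for (k in 1:25) {
    n <- sample(3:20, 1)
    a <- matrix(rnorm(3 * n, 0, 3), n, 3)
    b <- a %*% t(randomRotation()) + matrix(rnorm(3 * n, 0, 0.2), n, 3)
    got <- superposeUnits(a, b)
    ora <- hornSuperpose(a, b)
    expect_equal(got$R, ora$R, tolerance = 1e-6)
    expect_equal(got$rmsd, ora$rmsd, tolerance = 1e-6)
    expect_true(abs(det(got$R) - 1) < 1e-9)
  }
})

test_that("unequal-length units are trimmed to a deterministic 1:1 correspondence", {
  m <- helixTemplate(12)
  fx <- helixTemplate(9)
  sup <- superposeUnits(m, fx)
  expect_equal(sup$alignedLength, 9L)
  # trim of 3 residues: 1 off the N-terminus, 2 off the C-terminus
  supRef <- superposeUnits(m[2:10, ], fx)
  expect_equal(sup$R, supRef$R, tolerance = 1e-12)
  expect_equal(sup$rmsd, supRef$rmsd, tolerance = 1e-12)
  expect_error(superposeUnits(m[1:2, ], fx[1:2, ]), "at least 3")
})

test_that("external backend is isolated: absence of an aligner never breaks the default path", {
  m <- helixTemplate()
  haveAligner <- any(nzchar(Sys.which(c("TMalign", "tmalign", "USalign"))))
  if (haveAligner) {
    sup <- superposeUnits(m, m, backend = "external")
    expect_equal(sup$R, diag(3), tolerance = 0.02)
  } else {
    expect_error(superposeUnits(m, m, backend = "external"), "PATH")
  }
  # the internal default works regardless
  expect_equal(superposeUnits(m, m)$rmsd, 0, tolerance = 1e-9)
})

test_that("Tait-Bryan decomposition round-trips and handles gimbal lock", {
  idd <- decomposeTaitBryan(diag(3))
  expect_equal(c(idd$yaw, idd$pitch, idd$roll), c(0, 0, 0))
  rx <- decomposeTaitBryan(recomposeTaitBryan(0, 0, 0.3))
  expect_equal(c(rx$yaw, rx$pitch, rx$roll), c(0, 0, 0.3), tolerance = 1e-12)
  set.seed(81)
  for (k in 1:50) {
    R <- randomRotation()
    d <- decomposeTaitBryan(R)
    expect_equal(recomposeTaitBryan(d$yaw, d$pitch, d$roll), R, tolerance = 1e-9)
    expect_true(d$yaw > -pi && d$yaw <= pi)
    expect_true(abs(d$pitch) <= pi / 2 + 1e-12)
  }
  # gimbal lock: pitch exactly +/- pi/2; yaw absorbed into roll, flagged
  for (s in c(1, -1)) {
    Rg <- recomposeTaitBryan(0.4, s * pi / 2, -0.2)
    dg <- decomposeTaitBryan(Rg)
    expect_true(dg$gimbal)
    expect_equal(dg$yaw, 0)
    expect_equal(recomposeTaitBryan(dg$yaw, dg$pitch, dg$roll), Rg,
                 tolerance = 1e-9)
  }
  expect_error(decomposeTaitBryan(matrix(1, 3, 3)), "not a proper rotation")
})

test_that("pair descriptors map decomposition components with handedness signs", {
  tb <- list(yaw = 0.4, pitch = 0.1, roll = -0.2, gimbal = FALSE)
  # raw mapping (twistSign +1): twist is the roll component verbatim
  d <- pairDescriptor(0.37, tb, rmsd = 0.8, alignedLength = 10, twistSign = 1)
  expect_equal(d$curvature, 0.37)
  expect_equal(d$twist, -0.2)
  expect_equal(d$pitch, 0.1)
  expect_equal(d$twist_handedness, -1L)
  expect_equal(d$pitch_handedness, 1L)
  expect_equal(d$yaw_diagnostic, 0.4)
  # default clockwise-positive convention negates the mathematical roll
  d2 <- pairDescriptor(0.37, tb, 0.8, 10)
  expect_equal(d2$twist, 0.2)
  expect_equal(d2$twist_handedness, 1L)
  # all-zero angles map to +1/+1 by the zero convention
  z <- pairDescriptor(0, list(yaw = 0, pitch = 0, roll = 0, gimbal = FALSE), 0, 10)
  expect_equal(c(z$twist_handedness, z$pitch_handedness), c(1L, 1L))
  # pitch sign is reconciled with a decisive displacement along the normal
  dr <- pairDescriptor(0.3, tb, 0.8, 10, dispNormal = -2, dispTol = 0.5)
  expect_equal(dr$pitch, -0.1)
  expect_equal(dr$pitch_handedness, -1L)
  # sub-threshold displacement leaves the decomposition sign alone
  dk <- pairDescriptor(0.3, tb, 0.8, 10, dispNormal = -0.1, dispTol = 0.5)
  expect_equal(dk$pitch, 0.1)
})
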