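test_that("unit centroids are arithmetic means and translate with the input", {
  expect_equal(unitCentroid(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  expect_equal(unitCentroid(matrix(c(3, -1, 7), 1)), c(3, -1, 7))
  set.seed(11)
  m <- matrix(rnorm(30), 10, 3)
  t0 <- c(4, -2, 9)
  expect_equal(unitCentroid(sweep(m, 2, -t0)), unitCentroid(m) + t0)
  expect_error(unitCentroid(matrix(numeric(0), 0, 3)), "empty")
})

test_that("window selection centers on the pair and clamps at region ends", {
  # interior pair: 2 units before, 3 after (1-based pair index 5 of 10)
  expect_equal(selectWindow(5, 10), 3:8)
  expect_equal(selectWindow(1, 10), 1:6)     # clamp at start
  expect_equal(selectWindow(9, 10), 5:10)    # clamp at end
  expect_equal(selectWindow(2, 4), 1:4)      # N < window: whole region
  expect_equal(selectWindow(5, 10, window = 4), 4:7)
  # every valid pair is inside its window
  for (n in 3:12) for (i in seq_len(n - 1)) {
    w <- selectWindow(i, n)
    expect_true(all(c(i, i + 1) %in% w))
    expect_length(w, min(6, n))
  }
})

test_that("plane fitting recovers coplanar geometry and is rigid-motion invariant", {
  set.seed(21)
  pts <- cbind(rnorm(8), rnorm(8), 0)
  pl <- fitPlane(pts)
  expect_equal(abs(pl$n), c(0, 0, 1), tolerance = 1e-9)
  # 3 non-collinear points lie exactly in their plane
  tri <- rbind(c(0, 0, 0), c(1, 0, 0.5), c(0.2, 1, -0.3))
  pl3 <- fitPlane(tri)
  resid <- sweep(tri, 2, pl3$origin) %*% pl3$n
  expect_equal(as.numeric(resid), rep(0, 3), tolerance = 1e-12)
  # rigid motion: normal rotates with the points, basis stays orthonormal
  for (k in 1:5) {
    R <- randomRotation()
    t0 <- rnorm(3, 0, 10)
    moved <- sweep(pts %*% t(R), 2, t0, "+")
    plm <- fitPlane(moved)
    expect_equal(abs(sum(plm$n * (R %*% pl$n))), 1, tolerance = 1e-9)
    B <- cbind(plm$u, plm$v, plm$n)
    expect_equal(crossprod(B), diag(3), tolerance = 1e-9)
  }
  expect_error(fitPlane(matrix(1, 4, 3)), "degenerate")
})

test_that("algebraic circle fit is exact on exact circles and flags collinear input", {
  ang <- c(0, pi / 2, pi, 3 * pi / 2)
  fit <- fitInitialCircle(cbind(cos(ang), sin(ang)))
  expect_equal(fit$center, c(0, 0), tolerance = 1e-9)
  expect_equal(fit$radius, 1, tolerance = 1e-9)
  set.seed(31)
  for (k in 1:10) {
    c0 <- rnorm(2, 0, 50)
    r0 <- runif(1, 0.5, 80)
    a <- sort(runif(8, 0, 2 * pi))
    fitk <- fitInitialCircle(cbind(c0[1] + r0 * cos(a), c0[2] + r0 * sin(a)))
    expect_equal(fitk$center, c0, tolerance = 1e-6)
    expect_equal(fitk$radius, r0, tolerance = 1e-6)
  }
  # 3 points: the circumscribed circle, against the closed form
  for (k in 1:10) {
    p <- matrix(rnorm(6, 0, 5), 3, 2)
    cc <- circumcircle2d(p[1, ], p[2, ], p[3, ])
    fit3 <- fitInitialCircle(p)
    expect_equal(fit3$center, cc$center, tolerance = 1e-6)
    expect_equal(fit3$radius, cc$radius, tolerance = 1e-6)
  }
  lin <- fitInitialCircle(cbind(1:5, 2 * (1:5) + 3))
  expect_false(lin$ok)
  expect_equal(lin$radius, Inf)
})

test_that("widest-crown refinement matches hand-worked gaps and keeps the center", {
  mkpts <- function(r, ang = seq(0, 2 * pi, length.out = length(r) + 1)[-1]) {
    cbind(r * cos(ang), r * sin(ang))
  }
  # symmetric gap: in {1, 2}, out {5, 6}, initial radius 3.5
  cr <- widestCrownRefine(mkpts(c(1, 2, 5, 6)), c(0, 0), 3.5)
  expect_equal(cr$crownInner, 2)
  expect_equal(cr$crownOuter, 5)
  expect_equal(cr$radius, 3.5)
  expect_false(cr$fallback)
  # asymmetric: in {1, 2.5}, out {4.5, 6}, initial radius 3.0 -> radius 3.5
  cr2 <- widestCrownRefine(mkpts(c(1, 2.5, 4.5, 6)), c(0, 0), 3.0)
  expect_equal(cr2$crownInner, 2.5)
  expect_equal(cr2$crownOuter, 4.5)
  expect_equal(cr2$radius, 3.5)
  # all points at one radius below the initial circle: fallback, flagged
  cr3 <- widestCrownRefine(mkpts(rep(2, 6)), c(0, 0), 2.1)
  expect_true(cr3$fallback)
  expect_equal(cr3$radius, 2.1)
  # crown bounds bracket the refined radius on random annuli
  set.seed(41)
  for (k in 1:10) {
    r <- c(runif(6, 1, 3), runif(6, 5, 8))
    crk <- widestCrownRefine(mkpts(r), c(0, 0), 4)
    expect_true(crk$crownInner <= crk$radius && crk$radius <= crk$crownOuter)
  }
})

test_that("curvature is the center-subtended angle, bounded by [0, pi]", {
  expect_equal(curvatureAngle(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), pi / 2)
  expect_equal(curvatureAngle(c(0, 0, 0), c(1, 2, 3), c(1, 2, 3)), 0)
  # ideal closed ring: every pair subtends 2*pi/12
  ang <- 2 * pi * (0:11) / 12
  cent <- cbind(7 * cos(ang), 7 * sin(ang), 0)
  for (i in 1:11) {
    expect_equal(curvatureAngle(c(0, 0, 0), cent[i, ], cent[i + 1, ]),
                 2 * pi / 12, tolerance = 1e-12)
  }
  expect_error(curvatureAngle(c(1, 2, 3), c(1, 2, 3), c(0, 0, 0)), "degenerate")
})

test_that("local frames are right-handed, orthonormal and equivariant", {
  fr <- buildLocalFrame(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(fr$y, c(1, 0, 0))
  expect_equal(fr$x, c(0, 1, 0))
  expect_equal(fr$z, c(0, 0, -1))
  set.seed(51)
  for (k in 1:20) {
    ctr <- rnorm(3, 0, 5); a <- rnorm(3, 0, 5); b <- rnorm(3, 0, 5)
    if (sqrt(sum((a - ctr)^2)) < 0.1 || sqrt(sum((b - a)^2)) < 0.1) next
    f <- buildLocalFrame(ctr, a, b)
    B <- cbind(f$x, f$y, f$z)
    expect_equal(crossprod(B), diag(3), tolerance = 1e-9)
    expect_equal(det(B), 1, tolerance = 1e-9)
    # equivariance: rigid motion of all inputs rotates the frame
    R <- randomRotation(); t0 <- rnorm(3, 0, 10)
    fm <- buildLocalFrame(as.numeric(R %*% ctr + t0), as.numeric(R %*% a + t0),
                          as.numeric(R %*% b + t0))
    expect_equal(fm$x, as.numeric(R %*% f$x), tolerance = 1e-9)
    expect_equal(fm$y, as.numeric(R %*% f$y), tolerance = 1e-9)
    expect_equal(fm$z, as.numeric(R %*% f$z), tolerance = 1e-9)
  }
  # travel parallel to the pitch axis is degenerate
  expect_error(buildLocalFrame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "degenerate")
})
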