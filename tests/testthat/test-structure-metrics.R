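test_that("Kabsch superposition: identity, pure rotation, noise bracket", {
  set.seed(2)
  X <- matrix(rnorm(30), 10, 3)
  s0 <- superpose(X, X)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  # 30-degree rotation about z is recovered with zero residual
  R30 <- ChannelMech:::.rotationMatrix(c(0, 0, 1), 30 * pi / 180)
  s1 <- superpose(X, X %*% t(R30))
  expect_equal(s1$rmsd, 0, tolerance = 1e-9)
  expect_equal(s1$rotation %*% R30, diag(3), tolerance = 1e-9)
  expect_equal(det(s1$rotation), 1, tolerance = 1e-9)
  # Gaussian perturbation: residual RMSD lands in the expected bracket
  for (seed in 1:5) {
    set.seed(seed)
    Y <- X + matrix(rnorm(30, sd = 0.02), 10, 3)
    s2 <- superpose(X, Y)
    expect_gt(s2$rmsd, 0.01)
    expect_lt(s2$rmsd, 0.04)
  }
  expect_error(superpose(X[1:2, ], X[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("superposition is optimal and matches an independent reference", {
  set.seed(9)
  X <- matrix(rnorm(24), 8, 3)
  Y <- X %*% t(ChannelMech:::.rotationMatrix(c(1, 2, 3), 0.8)) +
    matrix(rnorm(24, sd = 0.05), 8, 3)
  s <- superpose(X, Y)
  # no random rigid transform does better
  for (i in 1:20) {
    R <- ChannelMech:::.rotationMatrix(rnorm(3), runif(1, -pi, pi))
    tr <- rnorm(3, sd = 0.1)
    alt <- sweep(Y %*% t(R), 2, -tr)
    altRmsd <- sqrt(mean(rowSums((alt - X)^2)))
    expect_gte(altRmsd, s$rmsd - 1e-12)
  }
  # cross-check against bio3d's least-squares fit
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(X)), mobile = as.numeric(t(Y))))
  refRmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - X)^2)))
  expect_equal(s$rmsd, refRmsd, tolerance = 1e-6)
})

test_that("helix axis orientation and tilt construction", {
  h <- ChannelMech:::.idealHelix(18)
  ax <- helixAxis(h)
  expect_lt(acos(min(1, abs(ax[3]))) * 180 / pi, 1)  # within 1 deg of z
  expect_gt(ax[3], 0)                                # N-to-C orientation
  expect_equal(helixAxis(h[18:1, ]), -ax, tolerance = 1e-9)
  tilt <- 20 * pi / 180
  h2 <- ChannelMech:::.idealHelix(18, axis = c(sin(tilt), 0, cos(tilt)))
  expect_lt(abs(acos(helixAxis(h2)[3]) * 180 / pi - 20), 0.5)
  expect_error(helixAxis(h[1:4, ]), "at least 5")
})

test_that("rotation/tilt recovery hits constructed angles within 0.5 degree", {
  cases <- list(c(15, 0), c(-10, 0), c(0, 8), c(15, 8), c(-25, -5))
  for (i in seq_along(cases)) {
    hp <- makeHelixPair(rotationDeg = cases[[i]][1], tiltDeg = cases[[i]][2],
                        seed = i)
    r <- rotationTiltAngles(hp$helix1, hp$helix2, hp$scaffold1,
                            hp$scaffold2)
    expect_lt(abs(r@rotationDeg - cases[[i]][1]), 0.5)
    expect_lt(abs(r@tiltChangeDeg - cases[[i]][2]), 0.5)
    expect_lt(r@rmsd, 1e-6)
  }
  # identical states: zero rotation and tilt
  hp0 <- makeHelixPair(rotationDeg = 0, tiltDeg = 0, seed = 1)
  r0 <- rotationTiltAngles(hp0$helix1, hp0$helix2, hp0$scaffold1,
                           hp0$scaffold2)
  expect_lt(abs(r0@rotationDeg), 1e-6)
  expect_lt(abs(r0@tiltChangeDeg), 1e-6)
})

test_that("rotation/tilt angles are antisymmetric under state swap", {
  # shared laboratory frame: the membrane normal is common to both states
  hp <- makeHelixPair(rotationDeg = 12, tiltDeg = 5, seed = 4,
                      rigidMotion = FALSE)
  fwd <- rotationTiltAngles(hp$helix1, hp$helix2, hp$scaffold1,
                            hp$scaffold2)
  bwd <- rotationTiltAngles(hp$helix2, hp$helix1, hp$scaffold2,
                            hp$scaffold1)
  expect_equal(bwd@rotationDeg, -fwd@rotationDeg, tolerance = 1e-6)
  expect_equal(bwd@tiltChangeDeg, -fwd@tiltChangeDeg, tolerance = 1e-6)
})

test_that("metrics are invariant to a global rigid motion of both states", {
  hp <- makeHelixPair(rotationDeg = 15, tiltDeg = 8, seed = 6)
  R <- ChannelMech:::.rotationMatrix(c(2, -1, 1), 1.1)
  mv <- function(X) sweep(X %*% t(R), 2, c(-1, 2, 0.5))
  # note: moving BOTH states together, including the membrane normal, is
  # not meaningful for the absolute angles; instead move only the shared
  # lab frame offset (translation), which must not matter
  fwd <- rotationTiltAngles(hp$helix1, hp$helix2, hp$scaffold1,
                            hp$scaffold2)
  shift <- function(X) X + rep(c(3, -2, 7), each = nrow(X))
  mvd <- rotationTiltAngles(shift(hp$helix1), shift(hp$helix2),
                            shift(hp$scaffold1), shift(hp$scaffold2))
  expect_equal(mvd@rotationDeg, fwd@rotationDeg, tolerance = 1e-8)
  expect_equal(mvd@tiltChangeDeg, fwd@tiltChangeDeg, tolerance = 1e-8)
})

test_that("pore profiler recovers constructed cylinder radii", {
  prof <- data.frame(z = seq(0, 1.0, by = 0.25), radius = 0.35)
  pore <- makePore(prof, vdw = 0.15)
  pp <- poreRadiusProfile(pore$structure, zlim = c(0, 1.0), dz = 0.25,
                          neighborhood = 0.2)
  p <- poreSamples(pp)
  expect_true(all(p$defined))
  expect_lt(max(abs(p$radius - 0.35)), 0.01)
  expect_lt(max(abs(p$cx)), 0.01)
})

test_that("pore profiler locates a planted constriction", {
  prof <- data.frame(z = seq(0, 1.2, by = 0.2),
                     radius = c(0.35, 0.35, 0.10, 0.35, 0.35, 0.35, 0.35))
  pore <- makePore(prof)
  pp <- poreRadiusProfile(pore$structure, zlim = c(0, 1.2), dz = 0.2,
                          neighborhood = 0.15)
  p <- poreSamples(pp)
  expect_equal(p$z[which.min(p$radius)], 0.4, tolerance = 1e-9)
  expect_lt(abs(min(p$radius) - 0.10), 0.01)
  # a slice far outside the molecule is flagged undefined, not zero
  ppOut <- poreRadiusProfile(pore$structure, zlim = c(4, 4.4), dz = 0.2,
                             neighborhood = 0.15)
  expect_true(all(!poreSamples(ppOut)$defined))
})

test_that("gate radius series tracks a widening constriction", {
  # constriction dilates linearly from 0.08 to 0.25 nm across frames
  zs <- seq(0, 0.8, by = 0.2)
  nF <- 6
  radii <- seq(0.08, 0.25, length.out = nF)
  pores <- lapply(radii, function(r) {
    prof <- data.frame(z = zs, radius = c(0.3, 0.3, r, 0.3, 0.3))
    makePore(prof)$structure
  })
  nat <- nAtoms(pores[[1]])
  coords <- array(0, dim = c(nat, 3, nF))
  for (f in seq_len(nF))
    coords[, , f] <- as.matrix(atoms(pores[[f]])[c("x", "y", "z")])
  fr <- new("FrameSequence", coords = coords, times = as.numeric(1:nF),
            box = matrix(NA_real_, nF, 3))
  ser <- minRadiusSeries(fr, pores[[1]], zlim = c(0, 0.8), dz = 0.2,
                         neighborhood = 0.15)
  expect_true(all(diff(ser$rmin_nm) > 0))
  expect_lt(max(abs(ser$rmin_nm - radii)), 0.01)
  # the 0.2 nm dilation criterion is crossed during the series
  expect_lt(ser$rmin_nm[1], 0.2)
  expect_gt(ser$rmin_nm[nF], 0.2)
})
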