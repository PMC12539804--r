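test_that("Coulomb pair force matches the closed form and cutoff contract", {
  # like unit charges at 1 nm, switch-on exactly there: plain Coulomb
  f <- coulombPairForce(1, 1, c(1, 0, 0), switchOn = 1.0, cutoff = 1.2)
  expect_equal(f, c(138.935458, 0, 0), tolerance = 1e-12)
  # beyond cutoff: exactly zero
  expect_identical(coulombPairForce(0.5, -2, c(1.3, 0, 0), 1.0, 1.2),
                   c(0, 0, 0))
  # zero charge: zero vector
  expect_identical(coulombPairForce(0, 1, c(0.5, 0, 0)), c(0, 0, 0))
  # opposite charges attract (force on i points toward j)
  f2 <- coulombPairForce(1, -1, c(0.5, 0, 0))
  expect_lt(f2[1], 0)
  expect_equal(sqrt(sum(f2^2)), 138.935458 / 0.25, tolerance = 1e-9)
  expect_error(coulombPairForce(1, 1, c(0, 0, 0)), "singularity")
})

test_that("LJ pair force matches the 12-6 formula, minimum and cutoff", {
  # at r = sigma: 24 eps (2 - 1) / sigma
  f <- ljPairForce(0.3, 1, c(0.3, 0, 0))
  expect_equal(f[1], 24 * (2 - 1) / 0.3, tolerance = 1e-12)
  expect_gt(f[1], 0)  # repulsive
  # at the potential minimum 2^(1/6) sigma: zero force
  rmin <- 2^(1 / 6) * 0.3
  expect_equal(max(abs(ljPairForce(0.3, 2.5, c(rmin, 0, 0)))), 0,
               tolerance = 1e-10)
  expect_identical(ljPairForce(0.3, 0, c(0.4, 0, 0)), c(0, 0, 0))
  expect_identical(ljPairForce(0.3, 1, c(1.25, 0, 0)), c(0, 0, 0))
})

test_that("nonbonded forces equal -dU/dr of the switched potential", {
  # finite-difference gradient check across the switching region
  uCoul <- function(r) 138.935458 * 0.7 * -0.4 / r * oracleSwitch(r, 1.0, 1.2)
  uLJ <- function(r) {
    4 * 0.8 * ((0.31 / r)^12 - (0.31 / r)^6) * oracleSwitch(r, 1.0, 1.2)
  }
  h <- 1e-6
  for (r in seq(0.82, 1.19, by = 0.02)) {
    fc <- coulombPairForce(0.7, -0.4, c(r, 0, 0))[1]
    fdC <- -(uCoul(r + h) - uCoul(r - h)) / (2 * h)
    expect_equal(fc, fdC, tolerance = 1e-4)
    fl <- ljPairForce(0.31, 0.8, c(r, 0, 0))[1]
    fdL <- -(uLJ(r + h) - uLJ(r - h)) / (2 * h)
    expect_equal(fl, fdL, tolerance = 1e-4)
  }
  # continuity at the cutoff (force vanishes linearly approaching rc)
  expect_lt(abs(coulombPairForce(1, 1, c(1.2 - 1e-9, 0, 0))[1]), 1e-4)
})

test_that("bonded pair forces reproduce harmonic bond mechanics", {
  p <- new("InteractionParameters", charge = c(0, 0), sigma = c(0.3, 0.3),
           epsilon = c(0, 0),
           bonds = data.frame(ai = 1L, aj = 2L, k = 1000, r0 = 0.15),
           angles = data.frame(ai = integer(0), aj = integer(0),
                               ak = integer(0), k = numeric(0),
                               theta0 = numeric(0)),
           dihedrals = data.frame(ai = integer(0), aj = integer(0),
                                  ak = integer(0), al = integer(0),
                                  k = numeric(0), mult = integer(0),
                                  phase = numeric(0)),
           exclusions = c("1-2", "1-3"), scale14 = 1, switchOn = 1.0,
           cutoff = 1.2)
  pos <- rbind(c(0, 0, 0), c(0.16, 0, 0))
  bf <- bondedPairForces(p, pos)
  expect_equal(nrow(bf), 1L)
  expect_equal(abs(bf$Fx), 10, tolerance = 1e-9)    # k (r - r0)
  expect_gt(bf$Fx, 0)  # stretched bond pulls atom 1 toward +x (attractive)
  # at equilibrium: zero
  bf0 <- bondedPairForces(p, rbind(c(0, 0, 0), c(0.15, 0, 0)))
  expect_equal(abs(bf0$Fx) + abs(bf0$Fy) + abs(bf0$Fz), 0, tolerance = 1e-12)
})

test_that("collinear angle at equilibrium produces zero angle force", {
  p <- new("InteractionParameters", charge = rep(0, 3), sigma = rep(0.3, 3),
           epsilon = rep(0, 3),
           bonds = data.frame(ai = c(1L, 2L), aj = c(2L, 3L), k = c(0, 0),
                              r0 = c(0.15, 0.15)),
           angles = data.frame(ai = 1L, aj = 2L, ak = 3L, k = 400,
                               theta0 = pi),
           dihedrals = data.frame(ai = integer(0), aj = integer(0),
                                  ak = integer(0), al = integer(0),
                                  k = numeric(0), mult = integer(0),
                                  phase = numeric(0)),
           exclusions = c("1-2", "1-3"), scale14 = 1, switchOn = 1.0,
           cutoff = 1.2)
  pos <- rbind(c(0, 0, 0), c(0.15, 0, 0), c(0.30, 0, 0))
  bf <- bondedPairForces(p, pos)
  expect_true(nrow(bf) == 0 ||
                max(abs(as.matrix(bf[c("Fx", "Fy", "Fz")]))) < 1e-9)
})

test_that("per-term bonded decomposition reproduces atomic forces exactly", {
  # the tested property behind the dihedral decomposition convention
  for (seed in 1:5) {
    toy <- makeToySystem(nAtoms = 8, seed = seed)
    pos <- as.matrix(atoms(toy$structure)[c("x", "y", "z")])
    bf <- bondedPairForces(toy$params, pos)
    assembled <- matrix(0, 8, 3)
    for (r in seq_len(nrow(bf))) {
      v <- c(bf$Fx[r], bf$Fy[r], bf$Fz[r])
      assembled[bf$ai[r], ] <- assembled[bf$ai[r], ] + v
      assembled[bf$aj[r], ] <- assembled[bf$aj[r], ] - v
    }
    # bonded-only oracle: switch off nonbonded by zeroing charge/epsilon
    pb <- toy$params
    pb@charge[] <- 0
    pb@epsilon[] <- 0
    fd <- oracleForcesFD(pb, pos)
    expect_lt(max(abs(assembled - fd)), 1e-4 * max(1, max(abs(fd))))
  }
})

test_that("residue pairwise forces: two opposite unit charges at 0.5 nm", {
  atomsDF <- data.frame(atom_id = 1:2, atom_name = "X", element = "C",
                        resid = 1:2, resname = "TOY", chain = "A",
                        x = c(0, 0.5), y = 0, z = 0)
  s <- new("MolecularStructure", atoms = atomsDF)
  p <- new("InteractionParameters", charge = c(1, -1), sigma = c(0.3, 0.3),
           epsilon = c(0, 0),
           bonds = data.frame(ai = integer(0), aj = integer(0),
                              k = numeric(0), r0 = numeric(0)),
           angles = data.frame(ai = integer(0), aj = integer(0),
                               ak = integer(0), k = numeric(0),
                               theta0 = numeric(0)),
           dihedrals = data.frame(ai = integer(0), aj = integer(0),
                                  ak = integer(0), al = integer(0),
                                  k = numeric(0), mult = integer(0),
                                  phase = numeric(0)),
           exclusions = c("1-2", "1-3"), scale14 = 1, switchOn = 1.0,
           cutoff = 1.2)
  pt <- residuePairwiseForces(s, framesFromStructure(s), p)
  e <- forceEntries(pt)
  expect_equal(nrow(e), 1L)
  expect_equal(e$class, "coulomb")
  mag <- sqrt(e$Fx^2 + e$Fy^2 + e$Fz^2)
  expect_equal(mag, 138.935458 / 0.25, tolerance = 1e-9)
  expect_gt(e$Fx, 0)  # attraction: force on residue 1 points toward +x
})

test_that("residue totals match the brute-force oracle on toy systems", {
  for (seed in c(1, 4)) {
    toy <- makeToySystem(nAtoms = 15, seed = seed)
    pos <- as.matrix(atoms(toy$structure)[c("x", "y", "z")])
    pt <- residuePairwiseForces(toy$structure, framesFromStructure(toy$structure),
                                toy$params)
    got <- residueTotalsFromTable(pt)
    fd <- oracleForcesFD(toy$params, pos)
    resid <- atoms(toy$structure)$resid
    scale <- max(abs(fd))
    for (rr in unique(resid)) {
      want <- colSums(fd[resid == rr, , drop = FALSE])
      key <- paste("A", rr)
      gotv <- if (key %in% rownames(got)) got[key, ] else c(0, 0, 0)
      expect_lt(max(abs(gotv - want)), 1e-4 * scale)
    }
  }
})

test_that("Newton's third law and translation invariance hold", {
  toy <- makeToySystem(nAtoms = 12, seed = 9)
  pos <- as.matrix(atoms(toy$structure)[c("x", "y", "z")])
  fr <- framesFromStructure(toy$structure)
  pt <- residuePairwiseForces(toy$structure, fr, toy$params)
  # canonical storage means antisymmetry is structural; verify the global
  # consequence: summed inter-residue forces vanish
  e <- forceEntries(pt)
  tot <- residueTotalsFromTable(pt)
  expect_lt(max(abs(colSums(tot))), 1e-8)
  # rigid translation leaves every pairwise force unchanged
  shifted <- toy$structure
  shifted@atoms$x <- shifted@atoms$x + 3.21
  shifted@atoms$y <- shifted@atoms$y - 1.77
  pt2 <- residuePairwiseForces(shifted, framesFromStructure(shifted),
                               toy$params)
  e2 <- forceEntries(pt2)
  expect_equal(e2$Fx, e$Fx, tolerance = 1e-9)
  expect_equal(e2$Fy, e$Fy, tolerance = 1e-9)
  expect_equal(e2$Fz, e$Fz, tolerance = 1e-9)
})

test_that("missing parameters are reported", {
  toy <- makeToySystem(nAtoms = 6, seed = 1)
  short <- toy$params
  short@charge <- short@charge[-1]
  short@sigma <- short@sigma[-1]
  short@epsilon <- short@epsilon[-1]
  expect_error(residuePairwiseForces(toy$structure,
                                     framesFromStructure(toy$structure),
                                     short),
               "parameter error")
})
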