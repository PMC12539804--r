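# Seeded synthetic-data generators. Each generator is deterministic given
# its seed and returns, alongside the data objects, a `truth` manifest
# recording every planted parameter, so tests and scripts can score
# recovery without re-deriving ground truth.
#
# The generators emulate the study conditions of the analysis stages: a
# four-fold symmetric channel with radial TRP helices, paired forced/free
# pairwise-force series with a known injected delta, a bead-spring AR
# bundle whose twist and length follow prescribed elastic constants,
# donor-acceptor geometries with prescribed hydrogen-bond occupancies,
# cylindrical pores with known radius profiles, and helix pairs related by
# known rotation/tilt.

# Ideal alpha-helix C-alpha trace: rise 0.15 nm/residue, radius 0.23 nm,
# 100 degrees/residue, around `axis` starting near `origin`.
.idealHelix <- function(n, axis = c(0, 0, 1), origin = c(0, 0, 0),
                        rise = 0.15, radius = 0.23, phase = 0) {
  u <- .unit3(axis)
  pb <- .planeBasis(u)
  t(vapply(seq_len(n) - 1L, function(k) {
    ang <- phase + k * 100 * pi / 180
    origin + k * rise * u + radius * (cos(ang) * pb$e1 + sin(ang) * pb$e2)
  }, numeric(3)))
}

.atomsDF <- function(xyz, atom_id, atom_name, element, resid, resname,
                     chain, vdw = NA_real_) {
  data.frame(atom_id = as.integer(atom_id), atom_name = atom_name,
             element = element, resid = as.integer(resid),
             resname = resname, chain = chain,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], vdw = vdw,
             stringsAsFactors = FALSE)
}

#' Toy interacting system for force-engine validation
#'
#' A small (<= 100 atoms) randomly placed chain with charges,
#' Lennard-Jones parameters, harmonic bonds along the chain, angles on
#' consecutive triples and periodic dihedrals on consecutive quadruples;
#' atoms are grouped into residues. Deliberately brute-force-oracle
#' friendly.
#'
#' @param nAtoms number of atoms (default 12).
#' @param atomsPerResidue residue grouping (default 3).
#' @param seed RNG seed.
#' @return list(structure, params, truth = list(seed, nAtoms)).
#' @export
makeToySystem <- function(nAtoms = 12, atomsPerResidue = 3, seed = 1) {
  stopifnot(nAtoms >= 2, nAtoms <= 100)
  set.seed(seed)
  # jittered chain layout keeps typical separations ~0.3-0.5 nm
  xyz <- matrix(0, nAtoms, 3)
  for (i in 2:nAtoms) {
    step <- .unit3(stats::rnorm(3)) * stats::runif(1, 0.28, 0.45)
    xyz[i, ] <- xyz[i - 1, ] + step
  }
  charge <- round(stats::runif(nAtoms, -0.8, 0.8), 3)
  sigma <- stats::runif(nAtoms, 0.25, 0.35)
  epsilon <- stats::runif(nAtoms, 0.2, 1.0)
  bonds <- data.frame(ai = 1:(nAtoms - 1), aj = 2:nAtoms,
                      k = stats::runif(nAtoms - 1, 800, 1200),
                      r0 = stats::runif(nAtoms - 1, 0.14, 0.16))
  angles <- if (nAtoms >= 3)
    data.frame(ai = 1:(nAtoms - 2), aj = 2:(nAtoms - 1), ak = 3:nAtoms,
               k = stats::runif(nAtoms - 2, 300, 500),
               theta0 = stats::runif(nAtoms - 2, 1.7, 2.1)) else
    data.frame(ai = integer(0), aj = integer(0), ak = integer(0),
               k = numeric(0), theta0 = numeric(0))
  dihedrals <- if (nAtoms >= 4)
    data.frame(ai = 1:(nAtoms - 3), aj = 2:(nAtoms - 2),
               ak = 3:(nAtoms - 1), al = 4:nAtoms,
               k = stats::runif(nAtoms - 3, 2, 8),
               mult = sample(1:3, nAtoms - 3, replace = TRUE),
               phase = stats::runif(nAtoms - 3, 0, 2 * pi)) else
    data.frame(ai = integer(0), aj = integer(0), ak = integer(0),
               al = integer(0), k = numeric(0), mult = integer(0),
               phase = numeric(0))
  resid <- (seq_len(nAtoms) - 1L) %/% atomsPerResidue + 1L
  structure <- new("MolecularStructure", atoms = .atomsDF(
    xyz, seq_len(nAtoms), "X", "C", resid, "TOY", "A"))
  params <- new("InteractionParameters", charge = charge, sigma = sigma,
                epsilon = epsilon, bonds = bonds, angles = angles,
                dihedrals = dihedrals, exclusions = c("1-2", "1-3"),
                scale14 = 1.0, switchOn = 1.0, cutoff = 1.2)
  list(structure = structure, params = params,
       truth = list(seed = seed, nAtoms = nAtoms))
}

#' Paired forced/free pairwise-force series with a known injected delta
#'
#' Residue-pair force series for two replicates per condition: every pair
#' draws i.i.d. Gaussian per-frame vectors about a common baseline; the
#' forced condition additionally carries a constant injected delta on
#' designated pairs (by default concentrated onto two "TRP" residues,
#' emulating force application focused on a few interface residues).
#'
#' @param nSource,nTarget residues in the source ("LH") and target ("TRP")
#'   domains; source resids 101.., target resids 201...
#' @param nFrames frames per replicate.
#' @param nReplicates replicates per condition (default 2).
#' @param delta named list: entries \code{list(resid_i, resid_j, F)} of
#'   injected vectors (kJ/mol/nm). Default: two concentrated vectors.
#' @param noiseSd per-frame Gaussian noise sd (kJ/mol/nm).
#' @param seed RNG seed.
#' @return list(forced, free: lists of \linkS4class{PairForceTable};
#'   domainMap; truth = list(delta, noiseSd, nFrames, baseline)).
#' @export
makeNetForcePair <- function(nSource = 3, nTarget = 3, nFrames = 100,
                             nReplicates = 2,
                             delta = NULL, noiseSd = 1.0, seed = 1) {
  set.seed(seed)
  src <- 100L + seq_len(nSource)
  tgt <- 200L + seq_len(nTarget)
  if (is.null(delta))
    delta <- list(list(resid_i = src[1], resid_j = tgt[1],
                       F = c(2, 40, 17)),
                  list(resid_i = src[2], resid_j = tgt[2],
                       F = c(8, 55, 35)))
  pairs <- expand.grid(resid_i = src, resid_j = tgt)
  baseline <- matrix(stats::rnorm(nrow(pairs) * 3, sd = 2), ncol = 3)
  dmat <- matrix(0, nrow(pairs), 3)
  for (d in delta) {
    hit <- pairs$resid_i == d$resid_i & pairs$resid_j == d$resid_j
    dmat[hit, ] <- dmat[hit, ] + rep(d$F, each = sum(hit))
  }
  buildTable <- function(withDelta) {
    rows <- lapply(seq_len(nFrames), function(f) {
      noise <- matrix(stats::rnorm(nrow(pairs) * 3, sd = noiseSd), ncol = 3)
      v <- baseline + noise + if (withDelta) dmat else 0
      data.frame(chain_i = "A", resid_i = pairs$resid_i, chain_j = "A",
                 resid_j = pairs$resid_j, class = "coulomb", frame = f,
                 time = 2 * f, Fx = v[, 1], Fy = v[, 2], Fz = v[, 3],
                 stringsAsFactors = FALSE)
    })
    pairForceTable(do.call(rbind, rows), nFrames)
  }
  forced <- lapply(seq_len(nReplicates), function(i) buildTable(TRUE))
  free <- lapply(seq_len(nReplicates), function(i) buildTable(FALSE))
  domainMap <- data.frame(label = c("LH", "TRP"), chain = "A",
                          first = c(min(src), min(tgt)),
                          last = c(max(src), max(tgt)),
                          stringsAsFactors = FALSE)
  list(forced = forced, free = free, domainMap = domainMap,
       truth = list(delta = delta, noiseSd = noiseSd, nFrames = nFrames,
                    seed = seed))
}

#' Bead-spring torsion trajectory with known elastic constants
#'
#' Emulates the twist protocol on the AR bundle: the lower block (units
#' 1-8) is rigidly rotated about z to each window's twist angle while the
#' upper (LH) end stays put; the bundle length follows
#' L = L0 - k_ct * phi. Per window, \code{samplesPerWindow} torque and
#' length samples are drawn (M = c * phi + noise, L + noise), mirroring
#' the windowed relaxation readout whose per-window means feed the
#' elasticity fits. Defaults plant the twist windows at 2.5, 5, 7.5 and 10
#' degrees.
#'
#' @param cTrue torsion coefficient (kJ/mol/rad).
#' @param kctTrue compression-twist coupling (nm/rad).
#' @param L0 untwisted bundle length (nm).
#' @param windowsDeg twist windows (degrees).
#' @param samplesPerWindow torque/length samples per window.
#' @param noiseFracM torque noise sd as a fraction of max |M|.
#' @param noiseFracL length noise sd as a fraction of the full length
#'   change k_ct * max(phi).
#' @param seed RNG seed.
#' @return list(structure, frames (reference frame first, then one frame
#'   per window), series = data.frame(window, phi_rad, M, L) of per-window
#'   means, samples = per-sample data.frame, groups = list(ar18, ar8, lh)
#'   row indices, truth).
#' @export
makeTorsionTrajectory <- function(cTrue = 2300, kctTrue = 1.32, L0 = 10,
                                  windowsDeg = c(2.5, 5, 7.5, 10),
                                  samplesPerWindow = 100,
                                  noiseFracM = 0, noiseFracL = 0,
                                  seed = 1) {
  stopifnot(cTrue > 0)
  set.seed(seed)
  phiW <- windowsDeg * pi / 180
  Mtrue <- cTrue * phiW
  Ltrue <- L0 - kctTrue * phiW
  sdM <- noiseFracM * max(abs(Mtrue))
  sdL <- noiseFracL * kctTrue * max(phiW)
  samples <- do.call(rbind, lapply(seq_along(phiW), function(w) {
    data.frame(window = w, phi_rad = phiW[w],
               M = Mtrue[w] + stats::rnorm(samplesPerWindow, sd = sdM),
               L = Ltrue[w] + stats::rnorm(samplesPerWindow, sd = sdL))
  }))
  series <- do.call(rbind, lapply(split(samples, samples$window),
                                  function(d) data.frame(
                                    window = d$window[1],
                                    phi_rad = d$phi_rad[1],
                                    M = mean(d$M), L = mean(d$L))))
  rownames(series) <- NULL
  # bead model: 4 beads per unit on rings; LH ring on top at z = 0,
  # AR units below; AR8's ring centre sits at distance L from the LH
  # centre; the AR1-8 block is rigidly rotated by phi about z
  nPerRing <- 4L
  unitRing <- function(zc, radius, phase = 0) {
    ang <- phase + (seq_len(nPerRing) - 1) * 2 * pi / nPerRing
    cbind(radius * cos(ang), radius * sin(ang), zc)
  }
  buildFrame <- function(phi, L) {
    rings <- list()
    # LH (resid 30) at z = 0
    rings$lh <- unitRing(0, 1.0)
    # AR units 29..9 stacked between the LH end and AR8
    for (k in 29:9)
      rings[[paste0("ar", k)]] <- unitRing(-L * (30 - k) / 22, 0.8,
                                           phase = (30 - k) * 0.3)
    # AR8..AR1: rigid lower block ending at AR8 centred at z = -L
    for (k in 8:1) {
      ring <- unitRing(-L - (8 - k) * 0.4, 0.8, phase = (30 - k) * 0.3)
      Rz <- .rotationMatrix(c(0, 0, 1), phi)
      rings[[paste0("ar", k)]] <- ring %*% t(Rz)
    }
    ringOrder <- c("lh", paste0("ar", 29:1))
    do.call(rbind, rings[ringOrder])
  }
  resids <- rep(c(30L, 29:1), each = nPerRing)
  ref <- buildFrame(0, L0)
  structure <- new("MolecularStructure", atoms = .atomsDF(
    ref, seq_len(nrow(ref)), "BB", "C", resids,
    ifelse(resids == 30L, "LHD", "ARU"), "A"))
  coords <- array(0, dim = c(nrow(ref), 3, length(phiW) + 1L))
  coords[, , 1] <- ref
  for (w in seq_along(phiW))
    coords[, , w + 1L] <- buildFrame(phiW[w], series$L[w])
  frames <- new("FrameSequence", coords = coords,
                times = c(0, seq_along(phiW)) * 1000,
                box = matrix(NA_real_, length(phiW) + 1L, 3))
  groups <- list(ar18 = which(resids %in% 1:8),
                 ar8 = which(resids == 8L),
                 lh = which(resids == 30L))
  list(structure = structure, frames = frames, series = series,
       samples = samples, groups = groups,
       truth = list(cTrue = cTrue, kctTrue = kctTrue, L0 = L0,
                    phi = phiW, M = Mtrue, L = Ltrue, sdM = sdM, sdL = sdL,
                    samplesPerWindow = samplesPerWindow, seed = seed))
}

#' Four-fold symmetric channel with radial TRP helices
#'
#' One subunit carries a TRP helix whose axis points radially outward from
#' the pore axis (in-plane) plus pore-lining atoms near the axis; chains
#' B, C and D are exact 90/180/270-degree rotations of chain A about z, so
#' the construction is exactly C4-symmetric with its pore centroid on the
#' origin.
#'
#' @param helixResids residue ids of the TRP helix; the default 18-residue
#'   span samples five helical turns at uniformly distributed phases, so
#'   the helix principal axis is exactly radial.
#' @param poreResids residue ids of the pore-lining atoms (default
#'   1550:1553).
#' @param seed RNG seed (layout jitter only; symmetry stays exact).
#' @return list(structure, map = \linkS4class{SymmetryMap}, domainMap,
#'   truth = list(frames: per-chain local-frame axes)).
#' @export
makeChannel <- function(helixResids = 1570:1587, poreResids = 1550:1553,
                        seed = 1) {
  set.seed(seed)
  nH <- length(helixResids)
  helixA <- .idealHelix(nH, axis = c(1, 0, 0), origin = c(1.5, 0, 0))
  poreA <- cbind(0.5 * cos(seq_along(poreResids) * 0.6),
                 0.5 * sin(seq_along(poreResids) * 0.6),
                 -0.4 * seq_along(poreResids) / length(poreResids))
  chainAtoms <- function(chain, k) {
    Rz <- .rotationMatrix(c(0, 0, 1), k * pi / 2)
    xyzH <- helixA %*% t(Rz)
    xyzP <- poreA %*% t(Rz)
    base <- k * (nH + length(poreResids))
    rbind(.atomsDF(xyzH, base + seq_len(nH), "CA", "C", helixResids,
                   "TRP", chain),
          .atomsDF(xyzP, base + nH + seq_along(poreResids), "CA", "C",
                   poreResids, "POR", chain))
  }
  chains <- c("A", "B", "C", "D")
  atoms <- do.call(rbind, lapply(0:3, function(k)
    chainAtoms(chains[k + 1], k)))
  structure <- new("MolecularStructure", atoms = atoms)
  map <- new("SymmetryMap", axis = c(0, 0, 1), center = c(0, 0, 0),
             chains = chains)
  domainMap <- data.frame(label = rep(c("TRP", "PORE"), each = 4),
                          chain = rep(chains, 2),
                          first = rep(c(min(helixResids), min(poreResids)),
                                      each = 4),
                          last = rep(c(max(helixResids), max(poreResids)),
                                     each = 4), stringsAsFactors = FALSE)
  frames <- lapply(0:3, function(k) {
    Rz <- .rotationMatrix(c(0, 0, 1), k * pi / 2)
    list(chain = chains[k + 1], ex = as.numeric(Rz %*% c(1, 0, 0)),
         ey = as.numeric(Rz %*% c(0, 1, 0)), ez = c(0, 0, 1))
  })
  list(structure = structure, map = map, domainMap = domainMap,
       truth = list(frames = frames, seed = seed))
}

#' Frames with prescribed hydrogen-bond occupancies
#'
#' For each requested donor-acceptor residue pair, exactly
#' round(occupancy * nFrames) frames place the acceptor at a valid
#' bonding geometry (D-A 0.29 nm, linear); the remaining frames move it
#' out to 0.45 nm, violating the distance criterion. Pairs are laid out
#' far apart so they cannot cross-bond.
#'
#' @param targets data.frame(residD, residA, occupancy in [0, 1]).
#' @param nFrames number of frames.
#' @param seed RNG seed (selects which frames are bonded).
#' @return list(structure, frames, donors, acceptors, truth).
#' @export
makeHbondFrames <- function(targets, nFrames = 100, seed = 1) {
  stopifnot(all(targets$occupancy >= 0 & targets$occupancy <= 1))
  set.seed(seed)
  np <- nrow(targets)
  atomsList <- list()
  donors <- data.frame(donor = integer(np), hydrogen = integer(np))
  acceptors <- integer(np)
  base <- matrix(0, np * 3, 3)
  for (p in seq_len(np)) {
    off <- c(3 * (p - 1), 0, 0)  # 3 nm spacing between pairs
    iD <- 3L * (p - 1L) + 1L
    base[iD, ] <- off                      # donor N
    base[iD + 1L, ] <- off + c(0.10, 0, 0) # hydrogen
    base[iD + 2L, ] <- off + c(0.29, 0, 0) # acceptor O (bonded position)
    atomsList[[p]] <- rbind(
      .atomsDF(base[iD, , drop = FALSE], iD, "N", "N",
               targets$residD[p], "RES", "A"),
      .atomsDF(base[iD + 1L, , drop = FALSE], iD + 1L, "H", "H",
               targets$residD[p], "RES", "A"),
      .atomsDF(base[iD + 2L, , drop = FALSE], iD + 2L, "O", "O",
               targets$residA[p], "RES", "A"))
    donors$donor[p] <- iD
    donors$hydrogen[p] <- iD + 1L
    acceptors[p] <- iD + 2L
  }
  structure <- new("MolecularStructure", atoms = do.call(rbind, atomsList))
  bondedFrames <- lapply(seq_len(np), function(p)
    sample(nFrames, round(targets$occupancy[p] * nFrames)))
  coords <- array(0, dim = c(np * 3, 3, nFrames))
  for (f in seq_len(nFrames)) {
    m <- base
    for (p in seq_len(np)) {
      if (!(f %in% bondedFrames[[p]]))
        m[3L * (p - 1L) + 3L, 1] <- m[3L * (p - 1L) + 1L, 1] + 0.45
    }
    coords[, , f] <- m
  }
  frames <- new("FrameSequence", coords = coords,
                times = as.numeric(seq_len(nFrames)),
                box = matrix(NA_real_, nFrames, 3))
  list(structure = structure, frames = frames, donors = donors,
       acceptors = acceptors,
       truth = list(targets = targets, nFrames = nFrames,
                    bondedFrames = bondedFrames, seed = seed))
}

#' Cylindrical pore with a prescribed radius profile
#'
#' Rings of atoms are placed at each requested z so that the analytic
#' accessible radius (ring radius minus the vdW radius) equals the
#' prescribed profile exactly on the axis.
#'
#' @param profile data.frame(z, radius) in nm, radius >= 0.
#' @param atomsPerRing atoms per ring (default 12).
#' @param vdw van der Waals radius of the ring atoms (nm, default 0.15).
#' @return list(structure, truth = list(profile, vdw)).
#' @export
makePore <- function(profile, atomsPerRing = 12, vdw = 0.15) {
  stopifnot(all(profile$radius >= 0))
  rows <- list()
  id <- 0L
  for (i in seq_len(nrow(profile))) {
    ringR <- profile$radius[i] + vdw
    ang <- (seq_len(atomsPerRing) - 1) * 2 * pi / atomsPerRing
    xyz <- cbind(ringR * cos(ang), ringR * sin(ang), profile$z[i])
    rows[[i]] <- .atomsDF(xyz, id + seq_len(atomsPerRing), "O", "O",
                          i, "POR", "A", vdw = vdw)
    id <- id + atomsPerRing
  }
  structure <- new("MolecularStructure", atoms = do.call(rbind, rows))
  list(structure = structure, truth = list(profile = profile, vdw = vdw))
}

#' Helix pair with known rotation and tilt over a shared scaffold
#'
#' Builds two states of an amphipathic (membrane-parallel) helix anchored
#' to a rigid four-helix scaffold. In state 2 the helix axis is rotated
#' about the membrane normal by \code{rotationDeg} (positive = clockwise
#' viewed from the intracellular side) and tilted up by \code{tiltDeg};
#' the whole state-2 system then receives a random rigid-body motion so
#' the scaffold superposition is genuinely exercised.
#'
#' @param rotationDeg in-plane rotation, |rotation| <= 180.
#' @param tiltDeg tilt change, |tilt| < 85.
#' @param nHelix helix length in residues; the default 18 samples five
#'   helical turns at uniformly distributed phases, so the principal axis
#'   of the trace aligns with the construction axis.
#' @param seed RNG seed (rigid-body motion).
#' @param rigidMotion apply a random rigid-body motion to state 2 (default
#'   TRUE); disable to keep both states in the same laboratory frame,
#'   where state-swap antisymmetry of the angle readout is exact.
#' @return list(helix1, helix2, scaffold1, scaffold2 (C-alpha matrices),
#'   truth = list(rotationDeg, tiltDeg)).
#' @export
makeHelixPair <- function(rotationDeg = 15, tiltDeg = 0, nHelix = 18,
                          seed = 1, rigidMotion = TRUE) {
  stopifnot(abs(rotationDeg) <= 180, abs(tiltDeg) < 85)
  set.seed(seed)
  scaffold <- do.call(rbind, lapply(0:3, function(k) {
    Rz <- .rotationMatrix(c(0, 0, 1), k * pi / 2)
    .idealHelix(10, axis = c(0, 0, 1),
                origin = as.numeric(Rz %*% c(1.4, 0, 0.2)))
  }))
  anchor <- c(0.9, 0, -0.3)
  axisOf <- function(rotDeg, tilt) {
    u <- as.numeric(.rotationMatrix(c(0, 0, 1), rotDeg * pi / 180) %*%
                      c(1, 0, 0))
    .unit3(cos(tilt * pi / 180) * u + sin(tilt * pi / 180) * c(0, 0, 1))
  }
  helix1 <- .idealHelix(nHelix, axis = axisOf(0, 0), origin = anchor)
  helix2 <- .idealHelix(nHelix, axis = axisOf(rotationDeg, tiltDeg),
                        origin = anchor)
  # random rigid motion of state 2
  move <- if (rigidMotion) {
    ax <- .unit3(stats::rnorm(3))
    R <- .rotationMatrix(ax, stats::runif(1, -pi, pi))
    tr <- stats::rnorm(3)
    function(X) sweep(X %*% t(R), 2, -tr)
  } else identity
  list(helix1 = helix1, helix2 = move(helix2), scaffold1 = scaffold,
       scaffold2 = move(scaffold),
       truth = list(rotationDeg = rotationDeg, tiltDeg = tiltDeg,
                    seed = seed))
}
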