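# Independent oracles, written directly from the defining formulas and
# kept free of the package's internal code paths.

# Switching polynomial (value only), as defined for the switched potential.
oracleSwitch <- function(r, r1, rc) {
  if (r <= r1) return(1)
  if (r >= rc) return(0)
  (rc^2 - r^2)^2 * (rc^2 + 2 * r^2 - 3 * r1^2) / (rc^2 - r1^2)^3
}

# Total potential energy of a toy system at given positions: switched
# Coulomb + Lennard-Jones over non-excluded pairs, plus harmonic bonds,
# harmonic angles and periodic dihedrals.
oracleEnergy <- function(params, positions) {
  n <- nrow(positions)
  KE <- 138.935458
  # bond-graph separations by triple nested loop (slow, independent)
  adj <- matrix(FALSE, n, n)
  b <- params@bonds
  for (i in seq_len(nrow(b))) adj[b$ai[i], b$aj[i]] <- adj[b$aj[i], b$ai[i]] <- TRUE
  sep <- matrix(Inf, n, n)
  diag(sep) <- 0
  for (rep in 1:3) {
    for (i in 1:n) for (j in 1:n) if (adj[i, j])
      for (k in 1:n) sep[i, k] <- min(sep[i, k], sep[j, k] + 1)
  }
  u <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sep[i, j]
      if ((s == 1 && "1-2" %in% params@exclusions) ||
          (s == 2 && "1-3" %in% params@exclusions) ||
          (s == 3 && "1-4" %in% params@exclusions)) next
      scale <- if (s == 3) params@scale14 else 1
      r <- sqrt(sum((positions[i, ] - positions[j, ])^2))
      if (r >= params@cutoff) next
      sw <- oracleSwitch(r, params@switchOn, params@cutoff)
      uc <- KE * params@charge[i] * params@charge[j] / r
      sij <- (params@sigma[i] + params@sigma[j]) / 2
      eij <- sqrt(params@epsilon[i] * params@epsilon[j])
      ul <- 4 * eij * ((sij / r)^12 - (sij / r)^6)
      u <- u + scale * (uc + ul) * sw
    }
  }
  for (i in seq_len(nrow(b))) {
    r <- sqrt(sum((positions[b$ai[i], ] - positions[b$aj[i], ])^2))
    u <- u + b$k[i] / 2 * (r - b$r0[i])^2
  }
  g <- params@angles
  for (i in seq_len(nrow(g))) {
    v1 <- positions[g$ai[i], ] - positions[g$aj[i], ]
    v2 <- positions[g$ak[i], ] - positions[g$aj[i], ]
    th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
    u <- u + g$k[i] / 2 * (th - g$theta0[i])^2
  }
  d <- params@dihedrals
  for (i in seq_len(nrow(d))) {
    b1 <- positions[d$aj[i], ] - positions[d$ai[i], ]
    b2 <- positions[d$ak[i], ] - positions[d$aj[i], ]
    b3 <- positions[d$al[i], ] - positions[d$ak[i], ]
    cx <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    n1 <- cx(b1, b2)
    n2 <- cx(b2, b3)
    m1 <- cx(n1, b2 / sqrt(sum(b2^2)))
    phi <- atan2(sum(m1 * n2), sum(n1 * n2))
    u <- u + d$k[i] * (1 + cos(d$mult[i] * phi - d$phase[i]))
  }
  u
}

# Per-atom forces by central finite difference of the total energy.
oracleForcesFD <- function(params, positions, h = 1e-6) {
  n <- nrow(positions)
  F <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (k in 1:3) {
      xp <- positions; xp[i, k] <- xp[i, k] + h
      xm <- positions; xm[i, k] <- xm[i, k] - h
      F[i, k] <- -(oracleEnergy(params, xp) - oracleEnergy(params, xm)) /
        (2 * h)
    }
  }
  F
}

# Two-pass textbook Pearson correlation.
oraclePearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sxy <- sxx <- syy <- 0
  for (i in seq_along(x)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Build a one-frame FrameSequence from a structure's own coordinates.
framesFromStructure <- function(structure, times = 0) {
  X <- as.matrix(atoms(structure)[c("x", "y", "z")])
  coords <- array(X, dim = c(nrow(X), 3, length(times)))
  new("FrameSequence", coords = coords, times = times,
      box = matrix(NA_real_, length(times), 3))
}

# Residue-level total force on each residue, assembled from a
# PairForceTable's entries for one frame.
residueTotalsFromTable <- function(pt, frame = 1) {
  e <- forceEntries(pt)
  e <- e[e$frame == frame, , drop = FALSE]
  keys <- unique(c(paste(e$chain_i, e$resid_i), paste(e$chain_j, e$resid_j)))
  out <- matrix(0, length(keys), 3, dimnames = list(keys, NULL))
  for (r in seq_len(nrow(e))) {
    ki <- paste(e$chain_i[r], e$resid_i[r])
    kj <- paste(e$chain_j[r], e$resid_j[r])
    v <- c(e$Fx[r], e$Fy[r], e$Fz[r])
    out[ki, ] <- out[ki, ] + v
    out[kj, ] <- out[kj, ] - v
  }
  out
}
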