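# Bonded forces and their pairwise decomposition.
#
# Each bonded term's atomic forces (analytic gradients of harmonic bond,
# harmonic angle, periodic dihedral energies) are decomposed into central
# forces along the inter-atom axes of the term's participating atoms. For
# 3-body (angle) and 4-body (dihedral) terms the decomposition is solved as
# a linear system; because each term has zero net force and zero net torque
# it is exact (residual at numerical zero) for non-degenerate geometries,
# so per-term atomic force sums are reproduced exactly.

# --- analytic per-term atomic forces ------------------------------------

# Harmonic bond: U = k/2 (r - r0)^2. Returns 2 x 3 forces on (ai, aj).
.bondForces <- function(xi, xj, k, r0) {
  d <- xi - xj
  r <- .norm3(d)
  if (r < 1e-12) stop("singularity: zero bond length")
  f <- -k * (r - r0)          # >0 repulsive (compressed), <0 attractive
  rbind(f * d / r, -f * d / r)
}

# Harmonic angle: U = k/2 (theta - theta0)^2 with theta at atom j.
# Returns 3 x 3 forces on (ai, aj, ak).
.angleForces <- function(xi, xj, xk, k, theta0) {
  u <- xi - xj
  v <- xk - xj
  du <- .norm3(u)
  dv <- .norm3(v)
  if (du < 1e-12 || dv < 1e-12) stop("singularity: zero angle arm")
  ct <- max(-1, min(1, sum(u * v) / (du * dv)))
  st <- sqrt(max(0, 1 - ct^2))
  theta <- acos(ct)
  if (st < 1e-8) {
    # collinear: gradient of theta undefined; force taken as zero, which is
    # exact at equilibrium (theta0 = 0 or pi) and the stable convention off it
    return(matrix(0, 3, 3))
  }
  dUdTheta <- k * (theta - theta0)
  dThetaDi <- -(v / (du * dv) - ct * u / du^2) / st
  dThetaDk <- -(u / (du * dv) - ct * v / dv^2) / st
  fi <- -dUdTheta * dThetaDi
  fk <- -dUdTheta * dThetaDk
  rbind(fi, -(fi + fk), fk)
}

# Signed dihedral angle i-j-k-l (rad), atan2 convention.
.dihedralAngle <- function(xi, xj, xk, xl) {
  b1 <- xj - xi
  b2 <- xk - xj
  b3 <- xl - xk
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / .norm3(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# Periodic dihedral: U = k (1 + cos(n phi - phase)).
# Returns 4 x 3 forces on (ai, aj, ak, al).
.dihedralForces <- function(xi, xj, xk, xl, k, mult, phase) {
  b1 <- xj - xi
  b2 <- xk - xj
  b3 <- xl - xk
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  n1sq <- sum(n1 * n1)
  n2sq <- sum(n2 * n2)
  lb2 <- .norm3(b2)
  if (n1sq < 1e-16 || n2sq < 1e-16 || lb2 < 1e-12)
    return(matrix(0, 4, 3))  # degenerate (collinear) dihedral
  phi <- .dihedralAngle(xi, xj, xk, xl)
  dUdPhi <- -k * mult * sin(mult * phi - phase)
  dPhiDi <- lb2 / n1sq * n1
  dPhiDl <- -lb2 / n2sq * n2
  p <- sum(b1 * b2) / lb2^2
  q <- sum(b3 * b2) / lb2^2
  dPhiDj <- -(1 + p) * dPhiDi + q * dPhiDl
  dPhiDk <- -(1 + q) * dPhiDl + p * dPhiDi
  -dUdPhi * rbind(dPhiDi, dPhiDj, dPhiDk, dPhiDl)
}

# --- pairwise decomposition ---------------------------------------------

# Decompose per-atom forces F (m x 3) of one term with atoms at X (m x 3)
# into scalar central forces along all atom pairs: returns data.frame(ai,
# aj, Fx, Fy, Fz) of the force on the FIRST atom of each (local-index) pair.
.decomposeCentral <- function(X, F) {
  m <- nrow(X)
  pairs <- utils::combn(m, 2)
  np <- ncol(pairs)
  A <- matrix(0, 3 * m, np)
  units <- matrix(0, np, 3)
  for (p in seq_len(np)) {
    a <- pairs[1, p]
    b <- pairs[2, p]
    u <- .unit3(X[a, ] - X[b, ])
    units[p, ] <- u
    A[(3 * a - 2):(3 * a), p] <- u
    A[(3 * b - 2):(3 * b), p] <- -u
  }
  fvec <- as.numeric(t(F))
  sol <- tryCatch(qr.solve(A, fvec, tol = 1e-10),
                  error = function(e) NULL)
  if (is.null(sol)) {
    # degenerate (coplanar) geometry: minimum-norm least squares
    sv <- svd(A)
    dinv <- ifelse(sv$d > 1e-9 * max(sv$d), 1 / sv$d, 0)
    sol <- sv$v %*% (dinv * (t(sv$u) %*% fvec))
  }
  data.frame(ai = pairs[1, ], aj = pairs[2, ],
             Fx = sol * units[, 1], Fy = sol * units[, 2],
             Fz = sol * units[, 3])
}

#' Pairwise forces of all bonded terms
#'
#' Evaluates harmonic bonds, harmonic angles and periodic dihedrals at the
#' given positions and distributes each term's atomic forces onto the pairs
#' of its participating atoms as central forces, such that summing a term's
#' pair contributions reproduces each atom's analytic force from that term.
#'
#' @param params an \linkS4class{InteractionParameters}.
#' @param positions natoms x 3 matrix (nm).
#' @return data.frame(ai, aj, Fx, Fy, Fz): force on atom ai by atom aj per
#'   (aggregated) bonded pair, kJ/mol/nm, with ai < aj.
#' @export
bondedPairForces <- function(params, positions) {
  n <- nrow(positions)
  chk <- function(idx) {
    if (any(idx < 1 | idx > n)) stop("index error: bonded term references ",
                                     "atom outside 1..", n)
  }
  out <- list()
  b <- params@bonds
  for (i in seq_len(nrow(b))) {
    chk(c(b$ai[i], b$aj[i]))
    F <- .bondForces(positions[b$ai[i], ], positions[b$aj[i], ],
                     b$k[i], b$r0[i])
    out[[length(out) + 1L]] <- data.frame(
      ai = b$ai[i], aj = b$aj[i], Fx = F[1, 1], Fy = F[1, 2], Fz = F[1, 3])
  }
  g <- params@angles
  for (i in seq_len(nrow(g))) {
    idx <- c(g$ai[i], g$aj[i], g$ak[i])
    chk(idx)
    F <- .angleForces(positions[idx[1], ], positions[idx[2], ],
                      positions[idx[3], ], g$k[i], g$theta0[i])
    if (max(abs(F)) > 0) {
      d <- .decomposeCentral(positions[idx, , drop = FALSE], F)
      d$ai <- idx[d$ai]
      d$aj <- idx[d$aj]
      out[[length(out) + 1L]] <- d
    }
  }
  dh <- params@dihedrals
  for (i in seq_len(nrow(dh))) {
    idx <- c(dh$ai[i], dh$aj[i], dh$ak[i], dh$al[i])
    chk(idx)
    F <- .dihedralForces(positions[idx[1], ], positions[idx[2], ],
                         positions[idx[3], ], positions[idx[4], ],
                         dh$k[i], dh$mult[i], dh$phase[i])
    if (max(abs(F)) > 0) {
      d <- .decomposeCentral(positions[idx, , drop = FALSE], F)
      d$ai <- idx[d$ai]
      d$aj <- idx[d$aj]
      out[[length(out) + 1L]] <- d
    }
  }
  if (!length(out))
    return(data.frame(ai = integer(0), aj = integer(0), Fx = numeric(0),
                      Fy = numeric(0), Fz = numeric(0)))
  all <- do.call(rbind, out)
  # orient every pair as (min, max) and aggregate duplicates
  flip <- all$ai > all$aj
  if (any(flip)) {
    tmp <- all$ai[flip]
    all$ai[flip] <- all$aj[flip]
    all$aj[flip] <- tmp
    all$Fx[flip] <- -all$Fx[flip]
    all$Fy[flip] <- -all$Fy[flip]
    all$Fz[flip] <- -all$Fz[flip]
  }
  agg <- stats::aggregate(all[c("Fx", "Fy", "Fz")],
                          by = all[c("ai", "aj")], FUN = sum)
  agg[order(agg$ai, agg$aj), , drop = FALSE]
}
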