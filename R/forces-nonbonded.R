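# Nonbonded pair forces with a switched potential.
#
# The potential is multiplied by the CHARMM switching polynomial
#   S(r) = (rc^2 - r^2)^2 (rc^2 + 2 r^2 - 3 r1^2) / (rc^2 - r1^2)^3
# on [r1, rc]; S = 1 below r1 and 0 beyond rc, with S' vanishing at both
# ends, so the force -d(U S)/dr is continuous, equals the plain force below
# the switch-on radius, and is exactly zero beyond the cutoff. Only
# short-range pairwise electrostatics are computed; reciprocal-space (PME)
# contributions are outside this pairwise formulation.

# Returns list(s, ds): switching value and radial derivative at r.
.switchFun <- function(r, r1, rc) {
  if (r <= r1) return(list(s = 1, ds = 0))
  if (r >= rc) return(list(s = 0, ds = 0))
  A <- rc^2 - r^2
  B <- rc^2 + 2 * r^2 - 3 * r1^2
  D <- (rc^2 - r1^2)^3
  list(s = A^2 * B / D, ds = -12 * r * A * (r^2 - r1^2) / D)
}

# Radial force magnitude -d(U S)/dr given plain U and U' at r.
.switchedForce <- function(u, du, r, r1, rc) {
  if (r >= rc) return(0)
  sw <- .switchFun(r, r1, rc)
  -(du * sw$s + u * sw$ds)
}

#' Switched Coulomb pair force
#'
#' Force on atom i exerted by atom j, for \code{rvec} = r_i - r_j. Below the
#' switch-on radius the magnitude is ke qi qj / r^2 with
#' ke = 138.935458 kJ mol^-1 nm e^-2; beyond the cutoff it is exactly zero;
#' in between the potential-switched force (continuous). Repulsive for like
#' charges (points along +rvec).
#'
#' @param qi,qj charges (e).
#' @param rvec separation vector r_i - r_j (nm).
#' @param switchOn,cutoff switching radii (nm), defaults 1.0 and 1.2.
#' @return 3-vector force on i (kJ/mol/nm).
#' @export
coulombPairForce <- function(qi, qj, rvec, switchOn = 1.0, cutoff = 1.2) {
  r <- .norm3(rvec)
  if (r < 1e-12) stop("singularity: zero separation")
  if (r >= cutoff || qi == 0 || qj == 0) return(c(0, 0, 0))
  u <- .KE * qi * qj / r
  du <- -.KE * qi * qj / r^2
  .switchedForce(u, du, r, switchOn, cutoff) * rvec / r
}

#' Switched Lennard-Jones pair force
#'
#' 12-6 force 24 eps (2 (s/r)^12 - (s/r)^6) / r along \code{rvec} = r_i -
#' r_j below the switch-on radius, potential-switched to exactly zero at the
#' cutoff.
#'
#' @param sigma,epsilon combined pair parameters (nm, kJ/mol).
#' @param rvec separation vector r_i - r_j (nm).
#' @param switchOn,cutoff switching radii (nm).
#' @return 3-vector force on i (kJ/mol/nm).
#' @export
ljPairForce <- function(sigma, epsilon, rvec, switchOn = 1.0, cutoff = 1.2) {
  r <- .norm3(rvec)
  if (r < 1e-12) stop("singularity: zero separation")
  if (r >= cutoff || epsilon == 0) return(c(0, 0, 0))
  sr6 <- (sigma / r)^6
  u <- 4 * epsilon * (sr6^2 - sr6)
  du <- -24 * epsilon * (2 * sr6^2 - sr6) / r
  .switchedForce(u, du, r, switchOn, cutoff) * rvec / r
}

# Lorentz-Berthelot combination.
.combineLB <- function(si, sj, ei, ej) {
  list(sigma = (si + sj) / 2, epsilon = sqrt(ei * ej))
}
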