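# Shared numerical helpers and physical constants.

# Coulomb constant in MD units: kJ mol^-1 nm e^-2
.KE <- 138.935458

# 1 kJ mol^-1 nm^-1 in piconewtons (divide by Avogadro's number)
.KJ_MOL_NM_TO_PN <- 1.66054

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.norm3 <- function(v) sqrt(sum(v * v))

.unit3 <- function(v) {
  n <- .norm3(v)
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector")
  v / n
}

# Rodrigues rotation matrix for angle theta (rad) about a unit axis.
.rotationMatrix <- function(axis, theta) {
  u <- .unit3(axis)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Orthonormal basis (e1, e2) of the plane perpendicular to a unit axis.
.planeBasis <- function(axis) {
  u <- .unit3(axis)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit3(ref - sum(ref * u) * u)
  e2 <- .cross3(u, e1)
  list(e1 = e1, e2 = e2)
}

#' Convert force values between MD and SI-style units
#'
#' One kJ mol^-1 nm^-1 equals 1.66054 pN (division by Avogadro's number).
#'
#' @param value numeric force value(s).
#' @param from,to one of \code{"kJ/mol/nm"} or \code{"pN"}.
#' @return converted numeric value(s).
#' @examples
#' convertForce(1, "kJ/mol/nm", "pN")    # 1.66054
#' @export
convertForce <- function(value, from = "kJ/mol/nm", to = "pN") {
  # unit values expressed in kJ/mol/nm
  known <- c("kJ/mol/nm" = 1, "pN" = 1 / .KJ_MOL_NM_TO_PN)
  if (!from %in% names(known)) stop("unknown unit: ", from)
  if (!to %in% names(known)) stop("unknown unit: ", to)
  value * known[[from]] / known[[to]]
}

# Bondi-style van der Waals radii (nm) by element; fallback for others.
.BONDI <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
            P = 0.180, F = 0.147, CL = 0.175, BR = 0.185, I = 0.198)
.DEFAULT_VDW <- 0.170

#' Default van der Waals radius for an element
#'
#' Bondi-style radii in nm; unknown elements fall back to 0.17 nm.
#'
#' @param element character vector of element symbols.
#' @return numeric radii (nm).
#' @export
vdwRadius <- function(element) {
  r <- .BONDI[toupper(element)]
  r[is.na(r)] <- .DEFAULT_VDW
  unname(r)
}
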