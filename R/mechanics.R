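# Local frames, force decomposition, torque, rotation/length readouts and
# the elasticity fits of the ankyrin-repeat spring.
#
# Sign convention used throughout the package: the membrane normal +z
# points extracellular; positive rotation/torque about +z (right-hand rule)
# appears clockwise when viewed from the intracellular side.

#' Build the per-subunit local frame
#'
#' z' is the membrane normal (extracellular-positive); x' is the component
#' of the TRP-helix axis perpendicular to z', oriented from the pore centre
#' toward the helix centroid (pore to membrane); y' = z' x x' completes the
#' right-handed frame. The helix axis is the principal axis of the selected
#' C-alpha coordinates, oriented N to C.
#'
#' @param structure a \linkS4class{MolecularStructure}.
#' @param selector selection expression for the TRP helix (see
#'   \code{\link{selectGroup}}), e.g. "chain A and name CA and resid 1570-1590".
#' @param axis membrane normal (default +z).
#' @param center pore centre (default: centroid of all atoms).
#' @return a \linkS4class{LocalFrame} with origin at the helix centroid.
#' @export
buildLocalFrame <- function(structure, selector, axis = c(0, 0, 1),
                            center = NULL) {
  a <- atoms(structure)
  ids <- selectGroup(structure, selector)
  sel <- a[match(ids, a$atom_id), , drop = FALSE]
  X <- as.matrix(sel[c("x", "y", "z")])
  z <- .unit3(axis)
  if (is.null(center))
    center <- colMeans(as.matrix(a[c("x", "y", "z")]))
  centroid <- colMeans(X)
  hax <- if (nrow(X) >= 5) helixAxis(X) else .unit3(centroid - center)
  xin <- hax - sum(hax * z) * z
  if (.norm3(xin) < 1e-8)
    stop("degenerate frame: helix axis parallel to the membrane normal")
  x <- .unit3(xin)
  radial <- centroid - center
  radial <- radial - sum(radial * z) * z
  if (sum(x * radial) < 0) x <- -x   # pore centre -> membrane orientation
  y <- .cross3(z, x)
  new("LocalFrame", origin = centroid, ex = x, ey = y, ez = z)
}

#' Decompose a force in a local frame
#'
#' Membrane-parallel components (projections on x', y') and membrane-normal
#' component (projection on z'); the decomposition is exact
#' (orthonormal basis).
#'
#' @param F 3-vector force.
#' @param frame a \linkS4class{LocalFrame}.
#' @return list(parallel = 2-vector (x', y'), normal = scalar z').
#' @export
decomposeForce <- function(F, frame) {
  validObject(frame)
  list(parallel = c(sum(F * frame@ex), sum(F * frame@ey)),
       normal = sum(F * frame@ez))
}

#' Total torque of a set of force applications about an axis
#'
#' Sum of ((p - origin) x F) . axis. Positive torque points along +axis
#' (extracellular when the axis is the membrane normal) and drives rotation
#' that appears clockwise viewed from the intracellular side.
#'
#' @param points n x 3 matrix of application points (nm).
#' @param forces n x 3 matrix of forces (kJ/mol/nm).
#' @param axis unit 3-vector.
#' @param origin 3-vector pivot (nm), default the origin.
#' @return scalar torque, kJ/mol.
#' @export
torqueAboutAxis <- function(points, forces, axis = c(0, 0, 1),
                            origin = c(0, 0, 0)) {
  points <- rbind(points)
  forces <- rbind(forces)
  if (abs(.norm3(axis) - 1) > 1e-8) stop("axis must be unit-norm")
  tq <- 0
  for (i in seq_len(nrow(points))) {
    tq <- tq + sum(.cross3(points[i, ] - origin, forces[i, ]) * axis)
  }
  tq
}

#' Rotation angle of an atom group about an axis over frames
#'
#' Per frame, the least-squares rotation angle of the group about the axis
#' relative to a reference frame: phi = atan2(sum over atoms of
#' (a x b) . axis, sum of a . b) with a, b the in-plane components of the
#' reference and current positions — the closed-form minimiser of
#' sum |R(phi) a_i - b_i|^2. Angles are unwrapped to a continuous series.
#'
#' @param frames a \linkS4class{FrameSequence}.
#' @param group integer row indices (atom order) of the rotation group.
#' @param reference reference frame index (default 1).
#' @param axis rotation axis (default +z).
#' @param origin pivot point (default: centroid of the group in the
#'   reference frame).
#' @return data.frame(frame, time, phi_rad).
#' @export
rotationAngle <- function(frames, group, reference = 1L, axis = c(0, 0, 1),
                          origin = NULL) {
  if (!length(group)) stop("empty rotation group")
  u <- .unit3(axis)
  ref <- frames@coords[group, , reference, drop = TRUE]
  ref <- rbind(ref)
  if (is.null(origin)) origin <- colMeans(ref)
  inplane <- function(X) {
    X <- sweep(X, 2, origin)
    X - outer(as.numeric(X %*% u), u)
  }
  A <- inplane(ref)
  if (max(sqrt(rowSums(A^2))) < 1e-9)
    stop("degenerate rotation group: all atoms on the axis")
  phi <- numeric(nFrames(frames))
  for (f in seq_len(nFrames(frames))) {
    B <- inplane(rbind(frames@coords[group, , f, drop = TRUE]))
    crossSum <- sum((A[, 2] * B[, 3] - A[, 3] * B[, 2]) * u[1] +
                      (A[, 3] * B[, 1] - A[, 1] * B[, 3]) * u[2] +
                      (A[, 1] * B[, 2] - A[, 2] * B[, 1]) * u[3])
    dotSum <- sum(A * B)
    phi[f] <- atan2(crossSum, dotSum)
  }
  # continuous unwrapping across frames
  if (length(phi) > 1L) {
    for (f in 2:length(phi)) {
      while (phi[f] - phi[f - 1] > pi) phi[f] <- phi[f] - 2 * pi
      while (phi[f] - phi[f - 1] < -pi) phi[f] <- phi[f] + 2 * pi
    }
  }
  data.frame(frame = seq_len(nFrames(frames)), time = frames@times,
             phi_rad = phi)
}

#' Centroid-distance length of the AR bundle over frames
#'
#' Per frame, the Euclidean distance between the (mass-unweighted)
#' centroids of two atom groups — conventionally the linker-helices domain
#' and the AR8 unit, giving the bundle length L(t).
#'
#' @param frames a \linkS4class{FrameSequence}.
#' @param groupA,groupB integer row indices of the two groups.
#' @return data.frame(frame, time, L_nm).
#' @export
arLength <- function(frames, groupA, groupB) {
  if (!length(groupA) || !length(groupB)) stop("empty group")
  L <- vapply(seq_len(nFrames(frames)), function(f) {
    a <- colMeans(rbind(frames@coords[groupA, , f, drop = TRUE]))
    b <- colMeans(rbind(frames@coords[groupB, , f, drop = TRUE]))
    .norm3(a - b)
  }, numeric(1))
  data.frame(frame = seq_len(nFrames(frames)), time = frames@times,
             L_nm = L)
}

#' Fit the torsion coefficient c of M = c phi
#'
#' Origin-constrained least squares (the linear torsion law has no
#' intercept); set \code{intercept = TRUE} for a diagnostic fit with one.
#'
#' @param phi twist angles (rad).
#' @param M torques (kJ/mol).
#' @param intercept fit an intercept (default FALSE).
#' @return an \linkS4class{ElasticityFit} with estimate c (kJ/mol/rad).
#' @export
fitTorsionCoefficient <- function(phi, M, intercept = FALSE) {
  if (length(phi) < 2L) stop("need at least 2 points")
  if (all(phi == 0)) stop("fit error: all twist angles are zero")
  fit <- if (intercept) stats::lm(M ~ phi) else stats::lm(M ~ 0 + phi)
  co <- suppressWarnings(summary(fit))$coefficients
  row <- rownames(co) == "phi"
  new("ElasticityFit", kind = "torsion",
      estimate = unname(co[row, 1]),
      stderr = unname(co[row, 2]),
      intercept = if (intercept) unname(co[!row, 1][1]) else NA_real_,
      residuals = unname(stats::residuals(fit)),
      n = length(phi), extensionCoupled = FALSE)
}

#' Fit the compression-twist coupling k_ct of L = L0 - k_ct phi
#'
#' Ordinary linear fit of bundle length against twist; k_ct is reported
#' positive when the bundle shortens with increasing twist, and flagged
#' extension-coupled when negative.
#'
#' @param phi twist angles (rad), at least 2 distinct values.
#' @param L bundle lengths (nm).
#' @return an \linkS4class{ElasticityFit} with estimate k_ct (nm/rad) and
#'   intercept L0.
#' @export
fitCompressionTwist <- function(phi, L) {
  if (length(phi) < 2L || length(unique(phi)) < 2L)
    stop("fit error: need at least 2 distinct twist angles")
  fit <- stats::lm(L ~ phi)
  co <- suppressWarnings(summary(fit))$coefficients
  kct <- -unname(co["phi", 1])
  new("ElasticityFit", kind = "compression-twist",
      estimate = kct, stderr = unname(co["phi", 2]),
      intercept = unname(co["(Intercept)", 1]),
      residuals = unname(stats::residuals(fit)),
      n = length(phi), extensionCoupled = kct < 0)
}
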