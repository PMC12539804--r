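# Superposition, helix-axis geometry and simplified pore-radius profiling.

#' Least-squares rigid superposition (Kabsch)
#'
#' Proper rotation (det +1) and translation minimising the RMSD of
#' \code{mobile} onto \code{reference}; points must be matched by row.
#'
#' @param reference,mobile n x 3 matrices, n >= 3, not collinear.
#' @return list(rotation 3x3, translation 3-vector, rmsd nm,
#'   transform = function(X) applying the fit to new coordinates).
#' @export
superpose <- function(reference, mobile) {
  reference <- rbind(reference)
  mobile <- rbind(mobile)
  if (nrow(reference) != nrow(mobile))
    stop("point sets must have equal size")
  if (nrow(reference) < 3L) stop("degenerate: need at least 3 points")
  cr <- colMeans(reference)
  cm <- colMeans(mobile)
  Rc <- sweep(reference, 2, cr)
  Mc <- sweep(mobile, 2, cm)
  if (svd(Mc)$d[2] < 1e-9 || svd(Rc)$d[2] < 1e-9)
    stop("degenerate: collinear point set")
  C <- t(Rc) %*% Mc
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  transform <- function(X) {
    X <- rbind(X)
    sweep(sweep(X, 2, cm) %*% t(R), 2, -cr)
  }
  aligned <- transform(mobile)
  rmsd <- sqrt(mean(rowSums((aligned - reference)^2)))
  trans <- as.numeric(cr - R %*% cm)
  list(rotation = R, translation = trans, rmsd = rmsd,
       transform = transform)
}

#' Helix axis from ordered C-alpha coordinates
#'
#' Principal axis of the local helix centres (sliding means of four
#' consecutive C-alphas, which lie essentially on the helical axis and
#' suppress the phase bias a direct PCA of the raw trace carries), falling
#' back to the raw principal axis for very short stretches. Sign-oriented
#' N to C: the projection of last-minus-first C-alpha onto the axis is
#' positive.
#'
#' @param calpha n x 3 matrix of C-alpha positions in N-to-C order, n >= 5.
#' @return unit 3-vector.
#' @export
helixAxis <- function(calpha) {
  calpha <- rbind(calpha)
  n <- nrow(calpha)
  if (n < 5L) stop("need at least 5 residues for a helix axis")
  pts <- if (n >= 8L) {
    t(vapply(seq_len(n - 3L), function(k)
      colMeans(calpha[k:(k + 3L), , drop = FALSE]), numeric(3)))
  } else calpha
  Xc <- sweep(pts, 2, colMeans(pts))
  ax <- svd(Xc)$v[, 1]
  if (sum((calpha[n, ] - calpha[1, ]) * ax) < 0) ax <- -ax
  .unit3(ax)
}

#' Rotation and tilt change of a helix between two states
#'
#' State 2 is rigidly superposed onto state 1 via the shared scaffold
#' (e.g. the S1-S4 helices); the helix axes (N to C) of both states are
#' then compared in the state-1 frame. The rotation is the signed angle
#' between the in-plane projections of the two axes (positive = clockwise
#' viewed from the intracellular side, i.e. positive about the
#' extracellular-pointing normal); the tilt change is the difference of
#' the axes' elevation above the membrane plane (positive = tilt-up, the
#' C-terminal end moving extracellular).
#'
#' @param helix1,helix2 n x 3 C-alpha coordinates of the helix in the two
#'   states (matched, N-to-C order).
#' @param scaffold1,scaffold2 m x 3 matched C-alpha sets used for
#'   superposition.
#' @param normal membrane normal, extracellular-positive (default +z).
#' @return a \linkS4class{HelixStatePair}.
#' @export
rotationTiltAngles <- function(helix1, helix2, scaffold1, scaffold2,
                               normal = c(0, 0, 1)) {
  z <- .unit3(normal)
  sup <- superpose(scaffold1, scaffold2)
  h2 <- sup$transform(helix2)
  a1 <- helixAxis(helix1)
  a2 <- helixAxis(h2)
  tiltOf <- function(ax) asin(max(-1, min(1, sum(ax * z))))
  for (ax in list(a1, a2)) {
    if (acos(min(1, abs(sum(ax * z)))) < 5 * pi / 180)
      stop("degenerate: helix axis within 5 degrees of the membrane normal")
  }
  p1 <- .unit3(a1 - sum(a1 * z) * z)
  p2 <- .unit3(a2 - sum(a2 * z) * z)
  rot <- atan2(sum(.cross3(p1, p2) * z), sum(p1 * p2)) * 180 / pi
  tilt <- (tiltOf(a2) - tiltOf(a1)) * 180 / pi
  new("HelixStatePair", rotationDeg = rot, tiltChangeDeg = tilt,
      rmsd = sup$rmsd, axis1 = a1, axis2 = a2)
}

# Accessible pore radius at an in-plane centre c for one slice: the
# smallest (3-D distance to atom minus its vdW radius) over nearby atoms.
.sliceRadius <- function(cxy, zs, XYZ, vdw) {
  d <- sqrt((XYZ[, 1] - cxy[1])^2 + (XYZ[, 2] - cxy[2])^2 +
              (XYZ[, 3] - zs)^2) - vdw
  min(d)
}

#' Pore radius profile along the channel axis
#'
#' Simplified HOLE-style profiler: the molecule is sliced perpendicular to
#' the axis; in each slice the pore centre is optimised in the plane
#' (Nelder-Mead, warm-started from the previous slice) to maximise the
#' accessible radius min_i(|p - x_i| - vdW_i) over atoms within
#' \code{neighborhood} of the slice; the radius is floored at zero. Slices
#' with no nearby atoms are flagged undefined rather than zero.
#'
#' @param structure a \linkS4class{MolecularStructure}; per-atom radii are
#'   taken from its \code{vdw} column where present, else from
#'   \code{\link{vdwRadius}} of the element.
#' @param positions optional natoms x 3 matrix overriding the structure
#'   coordinates (e.g. one trajectory frame).
#' @param axis pore axis (default +z; other axes are handled by rotating
#'   coordinates into a frame where the axis is z).
#' @param zlim length-2 range along the axis (nm).
#' @param dz slice spacing (nm).
#' @param neighborhood include atoms within this axial distance of a slice
#'   (nm).
#' @param start in-plane starting centre for the first slice (default 0,0).
#' @return a \linkS4class{PoreProfile}.
#' @export
poreRadiusProfile <- function(structure, positions = NULL,
                              axis = c(0, 0, 1), zlim, dz = 0.1,
                              neighborhood = 1.0, start = c(0, 0)) {
  a <- atoms(structure)
  X <- if (is.null(positions)) as.matrix(a[c("x", "y", "z")]) else positions
  vdw <- if ("vdw" %in% names(a) && !all(is.na(a$vdw)))
    ifelse(is.na(a$vdw), vdwRadius(a$element), a$vdw) else
      vdwRadius(a$element)
  u <- .unit3(axis)
  if (max(abs(u - c(0, 0, 1))) > 1e-9) {
    # rotate so the axis becomes +z
    v <- .cross3(u, c(0, 0, 1))
    s <- .norm3(v)
    ang <- atan2(s, u[3])
    R <- if (s < 1e-12) diag(3) else .rotationMatrix(v / s, ang)
    X <- X %*% t(R)
  }
  zs <- seq(zlim[1], zlim[2], by = dz)
  out <- data.frame(z = zs, cx = NA_real_, cy = NA_real_,
                    radius = NA_real_, defined = FALSE)
  centre <- start
  for (i in seq_along(zs)) {
    near <- abs(X[, 3] - zs[i]) <= neighborhood
    if (!any(near)) next
    XYZ <- X[near, , drop = FALSE]
    w <- vdw[near]
    opt <- stats::optim(centre, function(c2) -.sliceRadius(c2, zs[i], XYZ, w),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 500))
    centre <- opt$par
    out$cx[i] <- centre[1]
    out$cy[i] <- centre[2]
    out$radius[i] <- max(0, -opt$value)
    out$defined[i] <- TRUE
  }
  new("PoreProfile", profile = out)
}

#' Minimum gate radius per trajectory frame
#'
#' Per frame, the minimum pore-profile radius within the gate window along
#' the axis (the constriction radius time series used to score channel
#' dilation).
#'
#' @param frames a \linkS4class{FrameSequence}.
#' @param structure the matching \linkS4class{MolecularStructure}.
#' @param axis pore axis.
#' @param zlim gate window along the axis (nm).
#' @param dz,neighborhood,start as in \code{\link{poreRadiusProfile}}.
#' @return data.frame(frame, time, rmin_nm, defined).
#' @export
minRadiusSeries <- function(frames, structure, axis = c(0, 0, 1), zlim,
                            dz = 0.1, neighborhood = 1.0, start = c(0, 0)) {
  res <- lapply(seq_len(nFrames(frames)), function(f) {
    prof <- poreRadiusProfile(structure, frames@coords[, , f, drop = TRUE],
                              axis, zlim, dz, neighborhood, start)
    p <- prof@profile
    ok <- p$defined
    data.frame(frame = f, time = frames@times[f],
               rmin_nm = if (any(ok)) min(p$radius[ok]) else NA_real_,
               defined = any(ok))
  })
  do.call(rbind, res)
}
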